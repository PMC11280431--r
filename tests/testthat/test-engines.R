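# One moderately sized two-group simulation shared by several blocks.
planted_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_mirnas = 500,
                        group_sizes = c("UA-N" = 25, "UA-OC" = 56),
                        frac_de = 0.1, effect_log2fc_range = c(2, 3),
                        seed = 31)
      cache <<- simulate_counts(cfg)
    }
    cache
  }
})

test_that("all engines return a complete, well-formed result table", {
  sim <- planted_sim()
  res <- run_de_engines(sim$counts, sim$samples, "UA-OC:UA-N")
  expect_named(res, c("nb_lrt", "voom_lm", "nb_wald"))
  for (r in res) {
    expect_true(all(c("mirna_id", "log2FC", "FC", "logCPM", "statistic",
                      "p_value", "FDR", "engine") %in% names(r)))
    expect_true(all(r$FDR >= r$p_value))
    expect_true(all(r$p_value > 0 & r$p_value <= 1))
    expect_equal(r$FC, 2^r$log2FC)
    expect_true(all(is.finite(r$log2FC)))
    expect_true(all(r$logCPM > 2))  # abundance filter applied before testing
    # BH step-up monotonicity: sorted by p, adjusted values nondecreasing
    expect_true(all(diff(r$FDR[order(r$p_value)]) >= -1e-12))
  }
  # the three engines share one post-filter universe
  expect_identical(res$nb_lrt$mirna_id, res$voom_lm$mirna_id)
  expect_identical(res$nb_lrt$mirna_id, res$nb_wald$mirna_id)
})

test_that("every engine ranks planted effects above nulls (AUROC > 0.9)", {
  sim <- planted_sim()
  res <- run_de_engines(sim$counts, sim$samples, "UA-OC:UA-N")
  for (r in res) {
    truth <- sim$truth$is_de[match(r$mirna_id, sim$truth$mirna_id)]
    expect_gt(auroc(-log10(r$p_value), truth), 0.9)
  }
})

test_that("permuting sample order leaves engine results unchanged", {
  sim <- simulate_counts(sim_config(
    n_mirnas = 150, group_sizes = c("UA-N" = 8, "UA-OC" = 8),
    frac_de = 0.1, seed = 17))
  perm <- c(9, 3, 16, 1, 12, 5, 14, 7, 2, 11, 4, 13, 6, 15, 8, 10)
  cts2 <- sim$counts[, perm]
  smp2 <- sim$samples[perm, ]
  for (fn in list(engine_nb_lrt, engine_voom_lm, engine_nb_wald)) {
    r1 <- fn(sim$counts, sim$samples, "UA-OC:UA-N")
    r2 <- fn(cts2, smp2, "UA-OC:UA-N")
    expect_equal(r1, r2, tolerance = 1e-8)
  }
})

test_that("swapping the contrast negates log2FC and keeps p-values", {
  sim <- simulate_counts(sim_config(
    n_mirnas = 150, group_sizes = c("UA-N" = 8, "UA-OC" = 8),
    frac_de = 0.1, seed = 18))
  for (fn in list(engine_nb_lrt, engine_voom_lm, engine_nb_wald)) {
    fwd <- fn(sim$counts, sim$samples, "UA-OC:UA-N")
    rev <- fn(sim$counts, sim$samples, "UA-N:UA-OC")
    expect_lt(max(abs(fwd$log2FC + rev$log2FC)), 1e-4)
    expect_lt(max(abs(fwd$p_value - rev$p_value) / fwd$p_value), 1e-3)
  }
})

test_that("NB LRT reduces to the closed-form Poisson deviance at zero phi", {
  set.seed(4)
  m <- matrix(rpois(60 * 10, 200) + 1L, 60,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:10)))
  m[1, 6:10] <- m[1, 6:10] * 4L
  sheet <- data.frame(sample_id = colnames(m),
                      group = rep(c("UA-N", "UA-OC"), each = 5))
  r <- engine_nb_lrt(m, sheet, "UA-OC:UA-N", dispersion = 0)
  # effective library sizes exactly as the engine builds them (TMM-checked
  # against its own brute-force oracle elsewhere)
  eff <- colSums(m) * unname(tmm_factors(m))
  grp <- factor(sheet$group, levels = c("UA-N", "UA-OC"))
  for (g in c("g1", "g2", "g30")) {
    lr <- poisson_lrt_oracle(m[g, ], eff, grp)
    expect_equal(r$statistic[r$mirna_id == g], lr, tolerance = 1e-6)
  }
})

test_that("voom log2FC equals the log-CPM group-mean difference at high counts", {
  # large, homoscedastic counts: precision weights are nearly constant, so
  # the weighted estimator collapses to the plain group-mean difference
  set.seed(5)
  base <- rpois(80, 5000)
  m <- vapply(1:12, function(j) as.integer(rpois(80, base)), integer(80))
  dimnames(m) <- list(paste0("g", 1:80), paste0("s", 1:12))
  sheet <- data.frame(sample_id = colnames(m),
                      group = rep(c("UA-N", "UA-OC"), each = 6))
  r <- engine_voom_lm(m, sheet, "UA-OC:UA-N")
  lc <- log_cpm(m, tmm_factors(m), prior_count = 0.5)
  naive <- rowMeans(lc[r$mirna_id, 7:12]) - rowMeans(lc[r$mirna_id, 1:6])
  expect_lt(median(abs(r$log2FC - naive)), 0.01)

  # flat-trend limit: moderated t close to the ordinary t on log-CPM
  ord_t <- apply(lc[r$mirna_id, ], 1, function(x)
    stats::t.test(x[7:12], x[1:6], var.equal = TRUE)$statistic)
  expect_lt(median(abs(r$statistic - ord_t) / pmax(abs(ord_t), 0.5)), 0.2)
})

test_that("NB Wald log2FC matches normalized group means at low dispersion", {
  set.seed(6)
  mu <- rep(c(500, 2000), c(40, 40))
  m <- matrix(rpois(80 * 12, rep(mu, 12)), 80,
              dimnames = list(paste0("g", 1:80), paste0("s", 1:12)))
  m[1, 7:12] <- as.integer(m[1, 7:12] * 4L)
  sheet <- data.frame(sample_id = colnames(m),
                      group = rep(c("UA-N", "UA-OC"), each = 6))
  r <- engine_nb_wald(m, sheet, "UA-OC:UA-N")
  sf <- median_ratio_factors(m)
  norm <- sweep(m, 2, sf, "/")
  closed <- log2(rowMeans(norm[r$mirna_id, 7:12]) /
                   rowMeans(norm[r$mirna_id, 1:6]))
  expect_lt(median(abs(r$log2FC - closed)), 0.05)
  expect_lt(abs(r$log2FC[r$mirna_id == "g1"] - 2), 0.1)
})

test_that("small groups and thin designs are rejected with clear errors", {
  sim <- simulate_counts(tiny_config(seed = 1))
  one <- sim$samples[c(1, 9:12), ]
  expect_error(engine_nb_lrt(sim$counts, one, "UA-OC:UA-N"),
               "at least 2 samples")
  tiny4 <- sim$samples[c(1:2, 9:10), ]
  expect_error(engine_voom_lm(sim$counts, tiny4, "UA-OC:UA-N"),
               "residual degrees")
  expect_error(engine_nb_lrt(sim$counts, sim$samples, "UA-OC"), "contrast")
})

test_that("the post-hoc filter convention keeps the pre-filter BH denominator", {
  sim <- simulate_counts(sim_config(
    n_mirnas = 200, group_sizes = c("UA-N" = 8, "UA-OC" = 8),
    baseline_logmean_range = c(-18, -4), frac_de = 0, seed = 19))
  pre <- engine_nb_lrt(sim$counts, sim$samples, "UA-OC:UA-N",
                       filter_before = TRUE)
  post <- engine_nb_lrt(sim$counts, sim$samples, "UA-OC:UA-N",
                        filter_before = FALSE)
  expect_identical(pre$mirna_id, post$mirna_id)
  # the conventions share the returned universe but not the BH denominator
  expect_gt(sum(post$FDR != pre$FDR), 0)
  expect_true(all(diff(post$FDR[order(post$p_value)]) >= -1e-12))
})
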