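# hand-built reference set and consensus-like lookup tables
ref_set <- function(ids, dirs) {
  out <- data.frame(mirna_id = ids, direction = dirs,
                    tier = rep("set1", length(ids)),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_set", "data.frame")
  out
}
status_tab <- function(ids, dirs) {
  data.frame(mirna_id = ids, direction = dirs, stringsAsFactors = FALSE)
}

test_that("each reference miRNA lands in the subset its statuses dictate", {
  ref <- ref_set(c("A", "B", "C", "D", "E", "F"),
                 c("up", "up", "down", "down", "up", "up"))
  vs_control <- status_tab(ref$mirna_id,
                           c("up", "up", "down", "down", "ns", "down"))
  vs_case <- status_tab(ref$mirna_id,
                        c("up", "ns", "down", "up", "up", "up"))
  part <- codirectional_partition(ref, vs_control, vs_case, prefix = "3")
  expect_identical(part$subset, c("3a", "3b", "3c", "3d", "e", "f"))
  # exhaustive and disjoint by construction
  expect_setequal(part$mirna_id, ref$mirna_id)
  expect_false(anyDuplicated(part$mirna_id) > 0)
})

test_that("reference miRNAs absent from a comparison universe go to e", {
  ref <- ref_set(c("A", "B"), c("up", "down"))
  vs_control <- status_tab("A", "up")
  vs_case <- status_tab("A", "up")
  # both lookups (vs control and vs case) warn about the missing miRNA
  w <- capture_warnings(
    part <- codirectional_partition(ref, vs_control, vs_case, prefix = "3"))
  expect_true(all(grepl("absent", w)) && length(w) == 2)
  expect_identical(part$subset[part$mirna_id == "B"], "e")
})

test_that("an empty reference set yields empty partitions and panel", {
  ref <- ref_set(character(), character())
  part3 <- codirectional_partition(ref, status_tab(character(), character()),
                                   status_tab(character(), character()), "3")
  part4 <- codirectional_partition(ref, status_tab(character(), character()),
                                   status_tab(character(), character()), "4")
  expect_equal(nrow(part3), 0)
  rep <- select_final_panel(ref_set(character(), character()), part3, part4)
  expect_equal(nrow(rep$panel), 0)
  expect_equal(nrow(rep$set5), 0)
})

test_that("set5 requires co-directional membership in both partitions", {
  ref <- ref_set(c("A", "B", "C"), c("up", "up", "down"))
  p3 <- codirectional_partition(ref, status_tab(ref$mirna_id,
                                                c("up", "up", "down")),
                                status_tab(ref$mirna_id, c("up", "ns", "ns")),
                                prefix = "3")
  p4 <- codirectional_partition(ref, status_tab(ref$mirna_id,
                                                c("up", "ns", "down")),
                                status_tab(ref$mirna_id, c("ns", "ns", "down")),
                                prefix = "4")
  s5 <- build_set5(p3, p4)
  expect_setequal(s5$mirna_id, c("A", "C"))  # B is in 3b only
})

test_that("panel tiers split by one- vs two-fluid co-directionality and f excludes", {
  ref <- ref_set(c("A", "B", "C", "D"), c("up", "up", "down", "down"))
  set2 <- ref; set2$tier <- "set2"
  p3 <- codirectional_partition(ref,
                                status_tab(ref$mirna_id, c("up", "up", "down", "up")),
                                status_tab(ref$mirna_id, rep("ns", 4)), "3")
  p4 <- codirectional_partition(ref,
                                status_tab(ref$mirna_id, c("up", "ns", "down", "down")),
                                status_tab(ref$mirna_id, rep("ns", 4)), "4")
  rep <- select_final_panel(set2, p3, p4)
  # A: both fluids -> three_fluid; B: set3 only -> two_set; C: both;
  # D: opposite direction in AF (subset f) -> excluded even though
  # co-directional in AC
  expect_identical(rep$panel$tier[rep$panel$mirna_id == "A"], "three_fluid")
  expect_identical(rep$panel$tier[rep$panel$mirna_id == "B"], "two_set")
  expect_identical(rep$panel$tier[rep$panel$mirna_id == "C"], "three_fluid")
  expect_false("D" %in% rep$panel$mirna_id)
  # directions always equal the reference direction
  expect_identical(rep$panel$direction,
                   ref$direction[match(rep$panel$mirna_id, ref$mirna_id)])
})

test_that("removing a miRNA from set3/set4 never adds panel members", {
  set.seed(29)
  ids <- paste0("m", 1:40)
  dirs <- sample(c("up", "down"), 40, TRUE)
  ref <- ref_set(ids, dirs)
  set2 <- ref[sample(40, 25), ]
  class(set2) <- c("de_set", "data.frame")
  rand_status <- function() {
    s <- sample(c("same", "opp", "ns"), 40, TRUE, prob = c(0.5, 0.1, 0.4))
    ifelse(s == "same", dirs,
           ifelse(s == "opp", ifelse(dirs == "up", "down", "up"), "ns"))
  }
  p3 <- codirectional_partition(ref, status_tab(ids, rand_status()),
                                status_tab(ids, rand_status()), "3")
  p4 <- codirectional_partition(ref, status_tab(ids, rand_status()),
                                status_tab(ids, rand_status()), "4")
  full <- select_final_panel(set2, p3, p4)$panel$mirna_id
  for (drop_id in sample(ids, 8)) {
    p3d <- p3; p3d$subset[p3d$mirna_id == drop_id] <- "e"
    p4d <- p4; p4d$subset[p4d$mirna_id == drop_id] <- "e"
    reduced <- select_final_panel(set2, p3d, p4d)$panel$mirna_id
    expect_true(all(reduced %in% full))
  }
})

test_that("printed-table classification reproduces the published panel", {
  rep <- classify_table3()
  expect_equal(nrow(rep$panel), 29)
  expect_equal(sum(rep$panel$tier == "three_fluid"), 17)
  expect_equal(sum(rep$panel$tier == "two_set"), 12)
  # spot checks straight from the printed statuses
  expect_identical(rep$panel$tier[rep$panel$mirna_id == "miR-451a"],
                   "three_fluid")
  expect_identical(rep$panel$direction[rep$panel$mirna_id == "miR-451a"],
                   "down")
  r4521 <- rep$panel[rep$panel$mirna_id == "miR-4521", ]
  expect_identical(r4521$tier, "two_set")
  expect_false(r4521$in_set3)  # significant in the AC comparison only
  expect_true(r4521$in_set4)
  expect_false("miR-375-3p" %in% rep$panel$mirna_id)  # ns in both fluids
  # panel directions never contradict the printed result-table signs
  fx <- load_printed_fixture()
  expect_identical(
    rep$panel$direction,
    fx$table2$direction[match(rep$panel$mirna_id, fx$table2$mirna_id)])
})

test_that("simulated monotone effects flow into subsets a/c and the panel", {
  cfg <- sim_config(n_mirnas = 250,
                    group_sizes = c("UA-N" = 12, "UA-OC" = 14,
                                    "AF" = 12, "AC" = 10),
                    frac_de = 0.12, frac_monotone = 1,
                    effect_log2fc_range = c(2, 3), seed = 37)
  # universes can differ across contrasts after filtering: warnings expected
  out <- suppressWarnings(
    run_pipeline(withr::local_tempdir(), config = cfg, top_n = 250))
  tr <- out$sim$truth
  planted <- tr$mirna_id[tr$is_de]
  # planted monotone miRNAs detected in the reference contrast should sit in
  # the co-directional subsets of both partitions, never in e/f
  in_ref <- intersect(planted, out$set1$mirna_id)
  expect_gt(length(in_ref), 0)
  sub3 <- out$set3$subset[match(in_ref, out$set3$mirna_id)]
  sub4 <- out$set4$subset[match(in_ref, out$set4$mirna_id)]
  # monotone effects are at least as large downstream, so nearly all
  # reference detections stay co-directional and none can flip direction
  expect_gte(mean(sub3 %in% c("3a", "3b", "3c", "3d")), 0.9)
  expect_gte(mean(sub4 %in% c("4a", "4b", "4c", "4d")), 0.9)
  expect_false(any(c(sub3, sub4) == "f"))
  # and UA-OC-only planted effects land in subset e of set 4
  cfg2 <- sim_config(n_mirnas = 250,
                     group_sizes = c("UA-N" = 12, "UA-OC" = 14,
                                     "AF" = 12, "AC" = 10),
                     frac_de = 0, seed = 38)
  truth <- ground_truth_table(cfg2)
  truth$is_de[1:5] <- TRUE
  truth$direction[1:5] <- "up"
  truth$`lfc_UA-OC`[1:5] <- 2.5   # AF and AC stay at baseline
  sim2 <- simulate_counts(cfg2, truth = truth)
  out2 <- suppressWarnings(
    run_pipeline(withr::local_tempdir(), counts = sim2$counts,
                 samples = sim2$samples, top_n = 250))
  in_ref2 <- intersect(truth$mirna_id[1:5], out2$set1$mirna_id)
  expect_gt(length(in_ref2), 0)
  expect_true(all(out2$set4$subset[match(in_ref2, out2$set4$mirna_id)] == "e"))
})
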