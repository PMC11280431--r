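#' Run the full analysis pipeline and write its artifacts
#'
#' Orchestrates the end-to-end procedure: simulate (or ingest) a four-group
#' EV miRNA cohort; run the three differential-expression engines on the
#' five study contrasts (UA-OC vs UA-N; AF vs UA-N and vs UA-OC; AC vs UA-N
#' and vs UA-OC); form unanimous consensus calls per contrast; derive the
#' base-tier and strict-tier reference sets, the cross-biofluid
#' co-expression partitions, the all-fluid co-directional set and the tiered
#' final panel; compute MDS sample coordinates; and write every table plus a
#' machine-readable run log. Reruns with the same config are bit-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()]; ignored when \code{counts} is supplied.
#' @param counts,samples optional externally supplied count matrix and
#'   sample sheet (both or neither).
#' @param thresholds named list overriding [run_consensus()] thresholds.
#' @param top_n leading-fold-change window for [mds_coordinates()].
#' @param fixture_only classify the packaged printed-table transcription
#'   instead of running the count-based pipeline.
#' @return invisibly, a list with the in-memory artifacts (consensus tables,
#'   partitions, panel report, MDS result, file paths).
#' @export
run_pipeline <- function(out_dir, config = sim_config(), counts = NULL,
                         samples = NULL, thresholds = list(), top_n = 500,
                         fixture_only = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (fixture_only) {
    report <- classify_table3()
    paths <- write_panel_report(report, out_dir, prefix = "printed_")
    write_run_log(out_dir, list(mode = "fixture_only"))
    return(invisible(list(panel_report = report, paths = paths)))
  }

  if (is.null(counts)) {
    sim <- simulate_counts(config)
    counts <- sim$counts
    samples <- sim$samples
    write_simulation(sim, file.path(out_dir, "sim"))
  } else {
    if (is.null(samples)) stop("'samples' must accompany 'counts'")
    samples <- validate_sample_sheet(samples, groups = unique(samples$group),
                                     counts = counts)
    sim <- NULL
  }

  th <- utils::modifyList(list(fdr = 0.01, fdr_strict = 0.001,
                               min_fc = 2, min_logcpm = 2), thresholds)
  contrasts <- c("UA-OC:UA-N", "AF:UA-N", "AF:UA-OC", "AC:UA-N", "AC:UA-OC")
  have <- unique(samples$group)
  contrasts <- Filter(function(ct) {
    g <- strsplit(ct, ":", fixed = TRUE)[[1]]
    all(g %in% have)
  }, contrasts)
  if (!"UA-OC:UA-N" %in% contrasts)
    stop("pipeline stage 'consensus': the reference contrast UA-OC:UA-N ",
         "requires both groups in the sample sheet")

  de_dir <- file.path(out_dir, "de")
  dir.create(de_dir, showWarnings = FALSE)
  consensus <- list()
  for (ct in contrasts) {
    res <- tryCatch(
      run_de_engines(counts, samples, ct, min_logcpm = th$min_logcpm),
      error = function(e) stop("pipeline stage 'de' failed for contrast ",
                               ct, ": ", conditionMessage(e)))
    for (nm in names(res))
      write_results_tsv(res[[nm]], file.path(de_dir, paste0(
        gsub(":", "_vs_", ct), "_", nm, ".tsv")))
    consensus[[ct]] <- run_consensus(res, fdr = th$fdr,
                                     fdr_strict = th$fdr_strict,
                                     min_fc = th$min_fc,
                                     min_logcpm = th$min_logcpm)
    write_results_tsv(consensus[[ct]], file.path(out_dir, paste0(
      "consensus_", gsub(":", "_vs_", ct), ".tsv")))
  }

  ref <- consensus[["UA-OC:UA-N"]]
  set1 <- de_set(ref, "set1", contrast = "UA-OC:UA-N")
  set2 <- de_set(ref, "set2", contrast = "UA-OC:UA-N")
  write_results_tsv(set1, file.path(out_dir, "set1.tsv"))
  write_results_tsv(set2, file.path(out_dir, "set2.tsv"))
  write_results_tsv(engine_vs_consensus_counts(ref),
                    file.path(out_dir, "engine_vs_consensus.tsv"))

  report <- NULL
  set3 <- set4 <- NULL
  if (all(c("AF:UA-N", "AF:UA-OC", "AC:UA-N", "AC:UA-OC") %in% contrasts)) {
    set3 <- build_set3(set1, consensus[["AF:UA-N"]], consensus[["AF:UA-OC"]])
    set4 <- build_set4(set1, consensus[["AC:UA-N"]], consensus[["AC:UA-OC"]])
    write_results_tsv(set3, file.path(out_dir, "set3_partition.tsv"))
    write_results_tsv(set4, file.path(out_dir, "set4_partition.tsv"))
    report <- select_final_panel(set2, set3, set4)
    write_panel_report(report, out_dir)
  }

  mds <- mds_coordinates(counts, tmm_factors(counts), top_n = top_n)
  write_results_tsv(data.frame(sample_id = rownames(mds$coords),
                               mds$coords,
                               group = samples$group[match(
                                 rownames(mds$coords), samples$sample_id)]),
                    file.path(out_dir, "mds_coordinates.tsv"))

  write_run_log(out_dir, list(
    mode = "counts", seed = if (!is.null(sim)) config$seed else NA,
    thresholds = th, top_n = top_n, contrasts = contrasts,
    n_mirnas = nrow(counts), n_samples = ncol(counts)))

  invisible(list(consensus = consensus, set1 = set1, set2 = set2,
                 set3 = set3, set4 = set4, panel_report = report,
                 mds = mds, sim = sim, out_dir = out_dir))
}

write_panel_report <- function(report, out_dir, prefix = "") {
  paths <- c(panel = file.path(out_dir, paste0(prefix, "panel.tsv")),
             set5 = file.path(out_dir, paste0(prefix, "set5.tsv")),
             venn = file.path(out_dir, paste0(prefix, "venn_counts.tsv")),
             json = file.path(out_dir, paste0(prefix, "panel_report.json")))
  write_results_tsv(report$panel, paths[["panel"]])
  write_results_tsv(report$set5, paths[["set5"]])
  write_results_tsv(report$venn, paths[["venn"]])
  jsonlite::write_json(list(
    panel = report$panel,
    n_panel = nrow(report$panel),
    n_three_fluid = sum(report$panel$tier == "three_fluid"),
    n_two_set = sum(report$panel$tier == "two_set"),
    n_set5 = nrow(report$set5)
  ), paths[["json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

write_run_log <- function(out_dir, extra) {
  log <- c(list(
    package = "evmirpanel",
    package_version = as.character(utils::packageVersion("evmirpanel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    engine_versions = list(
      edgeR = as.character(utils::packageVersion("edgeR")),
      limma = as.character(utils::packageVersion("limma")),
      DESeq2 = as.character(utils::packageVersion("DESeq2")))
  ), extra)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(log)
}
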