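#' Consensus differential-expression calls across engines
#'
#' A miRNA is called up (or down) at the base tier only if \emph{every}
#' engine independently reports FDR below \code{fdr}, fold change above
#' \code{min_fc} (i.e. |log2FC| > log2(min_fc)) and logCPM above
#' \code{min_logcpm}, with all engines agreeing on the sign of log2FC; sign
#' disagreement forces a non-significant call even when every engine is
#' individually significant. The strict tier additionally requires every
#' engine's FDR below \code{fdr_strict}; it is always a subset of the base
#' tier. The fold-change criterion is evaluated per engine on that engine's
#' own estimate.
#'
#' The reported consensus \code{log2FC} is the negative-binomial
#' likelihood-ratio engine's estimate when available (the engine whose
#' values the published result table prints), otherwise the first engine's.
#'
#' @param results named list of at least two engine result data.frames (see
#'   [run_de_engines()]) covering the same miRNA universe.
#' @param fdr base-tier FDR threshold (default 0.01).
#' @param fdr_strict strict-tier FDR threshold (default 0.001).
#' @param min_fc fold-change threshold on the linear scale (default 2).
#' @param min_logcpm abundance threshold (default 2).
#' @return data.frame of class \code{"consensus_table"}: one row per miRNA
#'   with \code{direction} (up/down/ns), \code{tier} (none/set1/set2),
#'   consensus \code{log2FC}/\code{FC}/\code{logCPM}, \code{max_fdr}, and
#'   per-engine pass flags, log2FCs and FDRs.
#' @export
run_consensus <- function(results, fdr = 0.01, fdr_strict = 0.001,
                          min_fc = 2, min_logcpm = 2) {
  stopifnot(is.list(results), length(results) >= 2)
  if (is.null(names(results)))
    names(results) <- vapply(results, function(r) r$engine[1], "")
  ids <- results[[1]]$mirna_id
  for (nm in names(results)[-1]) {
    other <- results[[nm]]$mirna_id
    if (!setequal(ids, other)) {
      d1 <- setdiff(ids, other)
      d2 <- setdiff(other, ids)
      stop("engine result universes differ (", nm, "): missing ",
           paste(utils::head(d1, 5), collapse = ", "),
           if (length(d2)) paste0("; extra ",
                                  paste(utils::head(d2, 5), collapse = ", ")))
    }
  }
  # align every table to the first engine's row order
  aligned <- lapply(results, function(r) r[match(ids, r$mirna_id), ])

  lfc <- vapply(aligned, function(r) r$log2FC, numeric(length(ids)))
  fdrs <- vapply(aligned, function(r) r$FDR, numeric(length(ids)))
  cpm <- vapply(aligned, function(r) r$logCPM, numeric(length(ids)))
  if (length(ids) == 1L) {
    lfc <- matrix(lfc, 1); fdrs <- matrix(fdrs, 1); cpm <- matrix(cpm, 1)
    colnames(lfc) <- colnames(fdrs) <- colnames(cpm) <- names(aligned)
  }

  pass1 <- fdrs < fdr & abs(lfc) > log2(min_fc) & cpm > min_logcpm
  pass2 <- pass1 & fdrs < fdr_strict
  signs_agree <- apply(sign(lfc), 1L, function(s) all(s == s[1]) && s[1] != 0)

  all1 <- rowSums(pass1) == ncol(pass1) & signs_agree
  all2 <- rowSums(pass2) == ncol(pass2) & signs_agree

  ref_engine <- if ("nb_lrt" %in% names(aligned)) "nb_lrt" else names(aligned)[1]
  cons_lfc <- lfc[, ref_engine]
  direction <- ifelse(all1, ifelse(cons_lfc > 0, "up", "down"), "ns")
  tier <- ifelse(all2, "set2", ifelse(all1, "set1", "none"))

  out <- data.frame(mirna_id = ids,
                    direction = direction,
                    tier = tier,
                    log2FC = cons_lfc,
                    FC = 2^cons_lfc,
                    logCPM = cpm[, ref_engine],
                    max_fdr = apply(fdrs, 1L, max),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (nm in names(aligned)) {
    out[[paste0("pass_", nm)]] <- pass1[, nm]
    out[[paste0("lfc_", nm)]] <- lfc[, nm]
    out[[paste0("fdr_", nm)]] <- fdrs[, nm]
  }
  attr(out, "thresholds") <- list(fdr = fdr, fdr_strict = fdr_strict,
                                  min_fc = min_fc, min_logcpm = min_logcpm)
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' Per-engine vs consensus call counts
#'
#' The single-engine inflation report: how many miRNAs each engine alone
#' would call significant at the base-tier criteria, against the strictly
#' smaller unanimous consensus count.
#'
#' @param consensus a [run_consensus()] table.
#' @return data.frame with one row per engine plus a consensus row.
#' @export
engine_vs_consensus_counts <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_table"))
  flags <- grep("^pass_", names(consensus), value = TRUE)
  counts <- vapply(flags, function(f) sum(consensus[[f]]), 0L)
  data.frame(caller = c(sub("^pass_", "", flags), "consensus"),
             n_significant = c(counts, sum(consensus$direction != "ns")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Consensus contrast between metadata-defined subgroups
#'
#' Applies the identical three-engine consensus machinery to a two-group
#' contrast defined by sample metadata within one parent group, e.g.
#' high-grade (G2/G3) versus low-grade (G1) tumours within the UA-OC cohort.
#'
#' @inheritParams de_engines
#' @param parent_group restrict to samples of this group first (NULL: use
#'   all samples).
#' @param split_col metadata column defining the subgroups (default
#'   "grade").
#' @param case_levels,control_levels values of \code{split_col} forming the
#'   case and control subgroups.
#' @param ... thresholds passed to [run_consensus()].
#' @return a \code{consensus_table} for the subgroup contrast (case vs
#'   control).
#' @export
subgroup_contrast <- function(counts, samples, parent_group = NULL,
                              split_col = "grade", case_levels,
                              control_levels, min_logcpm = 2, ...) {
  if (!split_col %in% names(samples))
    stop("sample sheet has no '", split_col, "' column")
  sheet <- samples
  if (!is.null(parent_group))
    sheet <- sheet[sheet$group %in% parent_group, , drop = FALSE]
  if (length(intersect(case_levels, control_levels)))
    stop("case and control levels overlap")
  val <- sheet[[split_col]]
  lab <- ifelse(val %in% case_levels, "case",
                ifelse(val %in% control_levels, "control", NA))
  sheet <- data.frame(sample_id = sheet$sample_id[!is.na(lab)],
                      group = lab[!is.na(lab)], stringsAsFactors = FALSE)
  n_case <- sum(sheet$group == "case")
  n_ctrl <- sum(sheet$group == "control")
  if (n_case < 2 || n_ctrl < 2)
    stop("subgroup too small: ", n_case, " case / ", n_ctrl,
         " control samples (need at least 2 each)")
  sub_counts <- counts[, sheet$sample_id, drop = FALSE]
  res <- run_de_engines(sub_counts, sheet, c("case", "control"),
                        min_logcpm = min_logcpm)
  run_consensus(res, ...)
}
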