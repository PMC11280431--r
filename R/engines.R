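#' @name de_engines
#' @title Three count-based differential-expression engines
#'
#' @description
#' Consensus calling rests on three statistically distinct tests run on the
#' same two-group contrast of a miRNA count matrix:
#'
#' \itemize{
#'   \item \code{engine_nb_lrt}: TMM-normalized negative-binomial GLM with
#'     empirical-Bayes dispersion shrinkage and a likelihood-ratio test
#'     (edgeR's classic pipeline).
#'   \item \code{engine_voom_lm}: precision-weighted linear model on log-CPM
#'     with a lowess mean-variance trend and a moderated t-statistic
#'     (limma-voom).
#'   \item \code{engine_nb_wald}: median-of-ratios size factors, parametric
#'     dispersion trend with log-normal shrinkage, and a Wald test on the
#'     log2FC coefficient (DESeq2).
#' }
#'
#' All engines share one abundance filter (average logCPM above
#' \code{min_logcpm}, computed once from TMM-normalized libraries) applied
#' before testing, so they test the same miRNA universe and the
#' Benjamini-Hochberg denominator is the post-filter count. Setting
#' \code{filter_before = FALSE} instead tests everything, adjusts over all
#' tested miRNAs, and drops low-abundance rows from the returned table.
#'
#' \code{log2FC} is oriented case-over-control: positive means higher in the
#' first-named group of the contrast. \code{FC = 2^log2FC} always.
#'
#' @param counts integer count matrix (miRNA x sample).
#' @param samples sample sheet data.frame with \code{sample_id} and
#'   \code{group} (see [read_sample_sheet()]).
#' @param contrast the two-group comparison, as \code{"case:control"} or
#'   \code{c(case, control)}.
#' @param min_logcpm abundance filter threshold on average logCPM
#'   (default 2).
#' @param filter_before apply the abundance filter before testing (default
#'   TRUE; see Description).
#' @param prior_df prior degrees of freedom for the negative-binomial
#'   dispersion shrinkage of \code{engine_nb_lrt} (default 10).
#' @param dispersion optional fixed dispersion for \code{engine_nb_lrt},
#'   bypassing estimation (a value of 0 gives the Poisson limit); mainly for
#'   validation against closed-form oracles.
#' @return data.frame with columns \code{mirna_id}, \code{log2FC}, \code{FC},
#'   \code{logCPM}, \code{statistic}, \code{p_value}, \code{FDR},
#'   \code{engine}, one row per tested (and retained) miRNA.
NULL

parse_contrast <- function(contrast) {
  if (is.character(contrast) && length(contrast) == 1L)
    contrast <- strsplit(contrast, ":", fixed = TRUE)[[1]]
  if (length(contrast) != 2L || contrast[1] == contrast[2])
    stop("'contrast' must name two distinct groups, case first")
  list(case = contrast[1], control = contrast[2])
}

# Subset to the two contrast groups, order-stable, and build the design.
prepare_contrast <- function(counts, samples, contrast) {
  ct <- parse_contrast(contrast)
  validate_sample_sheet(samples, groups = unique(samples$group))
  keep <- samples$sample_id[samples$group %in% c(ct$case, ct$control)]
  absent <- setdiff(keep, colnames(counts))
  if (length(absent))
    stop("sample(s) in the sheet but not in the count matrix: ",
         paste(absent, collapse = ", "))
  keep <- intersect(colnames(counts), keep)
  sub <- counts[, keep, drop = FALSE]
  grp <- samples$group[match(keep, samples$sample_id)]
  n_case <- sum(grp == ct$case)
  n_ctrl <- sum(grp == ct$control)
  if (n_case < 2 || n_ctrl < 2)
    stop("contrast ", ct$case, ":", ct$control,
         " needs at least 2 samples per group (found ",
         n_case, " and ", n_ctrl, ")")
  group <- factor(grp, levels = c(ct$control, ct$case))
  list(counts = sub, group = group, case = ct$case, control = ct$control)
}

# Shared abundance filter so all engines test one universe.
abundance_keep <- function(counts, min_logcpm) {
  f <- tmm_factors(counts)
  ave <- avg_log_cpm(counts, f)
  list(keep = ave > min_logcpm, ave = ave)
}

floor_p <- function(p) pmax(p, .Machine$double.xmin)

assemble_result <- function(ids, lfc, logcpm, stat, p, engine) {
  p <- floor_p(p)
  data.frame(mirna_id = ids,
             log2FC = lfc,
             FC = 2^lfc,
             logCPM = logcpm,
             statistic = stat,
             p_value = p,
             FDR = bh_adjust(p),
             engine = engine,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

apply_post_filter <- function(res, keep) {
  res[keep, , drop = FALSE]
}

#' @rdname de_engines
#' @export
engine_nb_lrt <- function(counts, samples, contrast, min_logcpm = 2,
                          filter_before = TRUE, prior_df = 10,
                          dispersion = NULL) {
  pc <- prepare_contrast(counts, samples, contrast)
  ab <- abundance_keep(pc$counts, min_logcpm)
  cts <- if (filter_before) pc$counts[ab$keep, , drop = FALSE] else pc$counts
  ave <- if (filter_before) ab$ave[ab$keep] else ab$ave

  design <- stats::model.matrix(~ pc$group)
  y <- edgeR::DGEList(counts = cts, group = pc$group)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  if (is.null(dispersion)) {
    y <- edgeR::estimateDisp(y, design, prior.df = prior_df)
    fit <- edgeR::glmFit(y, design)
  } else {
    fit <- edgeR::glmFit(y, design, dispersion = dispersion)
  }
  lrt <- edgeR::glmLRT(fit, coef = 2)
  tab <- lrt$table
  res <- assemble_result(rownames(cts), tab$logFC, ave, tab$LR, tab$PValue,
                         "nb_lrt")
  if (!filter_before) res <- apply_post_filter(res, ab$keep)
  res
}

#' @rdname de_engines
#' @export
engine_voom_lm <- function(counts, samples, contrast, min_logcpm = 2,
                           filter_before = TRUE) {
  pc <- prepare_contrast(counts, samples, contrast)
  if (ncol(pc$counts) - 2L < 3L)
    stop("fewer than 3 residual degrees of freedom; use larger groups")
  ab <- abundance_keep(pc$counts, min_logcpm)
  cts <- if (filter_before) pc$counts[ab$keep, , drop = FALSE] else pc$counts
  ave <- if (filter_before) ab$ave[ab$keep] else ab$ave

  design <- stats::model.matrix(~ pc$group)
  y <- edgeR::DGEList(counts = cts, group = pc$group)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  v <- limma::voom(y, design, plot = FALSE)
  fit <- limma::eBayes(limma::lmFit(v, design))
  tab <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  res <- assemble_result(rownames(cts), tab$logFC, ave, tab$t, tab$P.Value,
                         "voom_lm")
  if (!filter_before) res <- apply_post_filter(res, ab$keep)
  res
}

#' @rdname de_engines
#' @export
engine_nb_wald <- function(counts, samples, contrast, min_logcpm = 2,
                           filter_before = TRUE) {
  pc <- prepare_contrast(counts, samples, contrast)
  ab <- abundance_keep(pc$counts, min_logcpm)
  cts <- if (filter_before) pc$counts[ab$keep, , drop = FALSE] else pc$counts
  ave <- if (filter_before) ab$ave[ab$keep] else ab$ave

  coldata <- S4Vectors::DataFrame(group = pc$group,
                                  row.names = colnames(cts))
  dds <- suppressMessages(
    DESeq2::DESeqDataSetFromMatrix(countData = cts, colData = coldata,
                                   design = ~ group))
  # parametric dispersion trend; DESeq2 substitutes a local fit (with a
  # message) when the parametric trend cannot be fit
  dds <- suppressMessages(DESeq2::DESeq(dds, test = "Wald", quiet = TRUE))
  r <- DESeq2::results(dds,
                       contrast = c("group", pc$case, pc$control),
                       independentFiltering = FALSE, cooksCutoff = FALSE)
  p <- r$pvalue
  p[is.na(p)] <- 1
  res <- assemble_result(rownames(cts), r$log2FoldChange, ave, r$stat, p,
                         "nb_wald")
  if (!filter_before) res <- apply_post_filter(res, ab$keep)
  res
}

#' Run all three engines on one contrast
#'
#' @inheritParams de_engines
#' @param engines subset of \code{c("nb_lrt", "voom_lm", "nb_wald")}.
#' @param ... passed on to the individual engines.
#' @return named list of engine result data.frames.
#' @export
run_de_engines <- function(counts, samples, contrast,
                           engines = c("nb_lrt", "voom_lm", "nb_wald"),
                           ...) {
  engines <- match.arg(engines, several.ok = TRUE)
  funs <- list(nb_lrt = engine_nb_lrt, voom_lm = engine_voom_lm,
               nb_wald = engine_nb_wald)
  lapply(stats::setNames(engines, engines), function(e)
    funs[[e]](counts, samples, contrast, ...))
}
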