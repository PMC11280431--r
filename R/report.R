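#' Classical MDS of samples on leading log-fold-change distances
#'
#' The distance between two samples is the root-mean-square of the
#' \code{top_n} largest absolute per-miRNA log-CPM differences for that pair
#' (the "leading fold change", recomputed per pair), embedded by classical
#' metric MDS (double-centering and spectral decomposition). Axes follow a
#' deterministic sign convention: the coordinate of largest magnitude on
#' each axis is positive. Coordinates are centered at the origin.
#'
#' @param counts count matrix with at least 3 samples.
#' @param factors optional normalization factors.
#' @param top_n number of leading miRNAs per pair (default 500; clamped with
#'   a warning if it exceeds the miRNA count).
#' @param prior_count prior for the log-CPM transform (default 2).
#' @param k number of dimensions (default 2).
#' @return list of class \code{"mds_result"}: \code{coords} (sample x k),
#'   \code{var_explained}, \code{stress} (normalized residual between input
#'   and embedded distances), \code{distances}, \code{top_n}.
#' @export
mds_coordinates <- function(counts, factors = NULL, top_n = 500,
                            prior_count = 2, k = 2) {
  check_counts(counts)
  if (ncol(counts) < 3) stop("MDS needs at least 3 samples")
  if (top_n > nrow(counts)) {
    warning("top_n (", top_n, ") exceeds miRNA count (", nrow(counts),
            "); clamped")
    top_n <- nrow(counts)
  }
  lcpm <- log_cpm(counts, factors, prior_count = prior_count)
  d <- leading_lfc_dist(lcpm, top_n)
  res <- classical_mds(d, k = k)
  res$distances <- d
  res$top_n <- top_n
  res
}

leading_lfc_dist <- function(lcpm, top_n) {
  n <- ncol(lcpm)
  d <- matrix(0, n, n, dimnames = list(colnames(lcpm), colnames(lcpm)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sq <- (lcpm[, i] - lcpm[, j])^2
      top <- sort(sq, decreasing = TRUE)[seq_len(top_n)]
      d[i, j] <- d[j, i] <- sqrt(mean(top))
    }
  }
  d
}

#' Classical (Torgerson) multidimensional scaling of a distance matrix
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k embedding dimension.
#' @return list of class \code{"mds_result"} with \code{coords},
#'   \code{var_explained} and \code{stress}.
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0))
    stop("'d' must be a symmetric distance matrix with zero diagonal")
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  coords <- fit$points
  # deterministic sign: largest-magnitude coordinate per axis positive
  for (a in seq_len(ncol(coords))) {
    m <- which.max(abs(coords[, a]))
    if (coords[m, a] < 0) coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  pos <- pmax(fit$eig, 0)
  d_hat <- as.matrix(stats::dist(coords))
  stress <- if (sum(d^2) > 0) sqrt(sum((d - d_hat)^2) / sum(d^2)) else 0
  structure(list(coords = coords,
                 var_explained = pos[seq_len(k)] / sum(pos),
                 stress = stress),
            class = "mds_result")
}

#' Per-sample small-RNA class composition
#'
#' Collapses a class-annotated count table to per-sample class proportions
#' (summing to 1 in every sample) and, when a sample sheet is given, group
#' means.
#'
#' @param counts count matrix whose rows carry class labels via
#'   \code{classes}.
#' @param classes character vector of RNA class labels (miRNA, piwiRNA,
#'   ...), one per row; unlabeled rows are rejected.
#' @param samples optional sample sheet for group means.
#' @return list with \code{proportions} (class x sample) and, if requested,
#'   \code{group_means} (class x group).
#' @export
class_composition <- function(counts, classes, samples = NULL) {
  check_counts(counts)
  if (length(classes) != nrow(counts))
    stop("'classes' must label every row")
  if (anyNA(classes) || any(!nzchar(classes)))
    stop("unlabeled row(s): every row needs an RNA class label")
  by_class <- rowsum(counts, classes)
  tot <- colSums(by_class)
  if (any(tot == 0)) stop("sample(s) with zero total counts")
  prop <- sweep(by_class, 2, tot, "/")
  out <- list(proportions = prop)
  if (!is.null(samples)) {
    grp <- samples$group[match(colnames(prop), samples$sample_id)]
    out$group_means <- vapply(split(seq_len(ncol(prop)), grp),
                              function(idx) rowMeans(prop[, idx, drop = FALSE]),
                              numeric(nrow(prop)))
  }
  out
}

#' Exclusive Venn region counts for named sets
#'
#' @param sets named list (>= 2) of membership vectors.
#' @return data.frame with one row per region (every nonempty combination of
#'   set inclusion), logical columns per set, a \code{region} label and the
#'   exclusive \code{count}; counts sum to the size of the union.
#' @export
venn_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, 1,
                                               dimnames = list(NULL, names(sets)))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  combos$region <- apply(combos, 1L, function(r)
    paste(names(sets)[as.logical(r)], collapse = "&"))
  combos$count <- apply(combos[, names(sets), drop = FALSE], 1L, function(r) {
    if (length(universe) == 0) return(0L)
    sum(apply(member, 1L, function(m) all(m == as.logical(r))))
  })
  rownames(combos) <- NULL
  combos
}
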