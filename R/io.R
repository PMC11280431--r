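#' Read a miRNA count matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of miRNA IDs.
#' Validation is strict: duplicated IDs, ragged rows, negative or
#' non-integer cells all raise an error naming the offender.
#'
#' @param path path to a tab-separated file.
#' @return integer matrix (miRNA x sample) with dimnames.
#' @export
read_count_matrix <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged count matrix: row ", bad, " of '", basename(path),
         "' has ", nf[bad], " fields, expected ", nf[1])
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          quote = "")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated miRNA ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samp <- colnames(df)[-1]
  if (anyDuplicated(samp))
    stop("duplicated sample ID(s): ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric count at miRNA '", ids[bad[1]], "', sample '",
         samp[bad[2]], "'")
  }
  if (any(num < 0) || any(num != round(num))) {
    bad <- which(num < 0 | num != round(num), arr.ind = TRUE)[1, ]
    stop("negative or non-integer count at miRNA '", ids[bad[1]],
         "', sample '", samp[bad[2]], "'")
  }
  storage.mode(num) <- "integer"
  dimnames(num) <- list(ids, samp)
  num
}

#' Write a miRNA count matrix as TSV
#'
#' @param counts integer matrix with miRNA IDs as rownames and sample IDs as
#'   colnames. Tabs are not permitted in IDs.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_count_matrix <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(grepl("\t", c(rownames(counts), colnames(counts)))))
    stop("IDs must not contain tab characters")
  df <- data.frame(mirna_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default group vocabulary of the emulated study
#' @keywords internal
default_groups <- function() c("UA-N", "UA-OC", "AF", "AC")

#' Read and validate a sample sheet
#'
#' @param path CSV with required columns \code{sample_id} and \code{group};
#'   optional \code{grade} (G1/G2/G3/unknown) and \code{stage}.
#' @param groups allowed group labels; extend to use a different vocabulary.
#' @param counts optional count matrix; when given, every sample must appear
#'   in the sheet exactly once.
#' @return data.frame with validated columns.
#' @export
read_sample_sheet <- function(path, groups = default_groups(), counts = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df, groups = groups, counts = counts)
}

#' @rdname read_sample_sheet
#' @param sheet an in-memory sample sheet data.frame.
#' @export
validate_sample_sheet <- function(sheet, groups = default_groups(),
                                  counts = NULL) {
  need <- c("sample_id", "group")
  missing <- setdiff(need, names(sheet))
  if (length(missing))
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample_id(s): ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  unknown <- setdiff(unique(sheet$group), groups)
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(groups, collapse = ", "), ")")
  if ("grade" %in% names(sheet)) {
    badg <- setdiff(unique(sheet$grade), c("G1", "G2", "G3", "unknown", NA))
    if (length(badg))
      stop("unknown grade label(s): ", paste(badg, collapse = ", "))
  }
  if (!is.null(counts)) {
    absent <- setdiff(colnames(counts), sheet$sample_id)
    if (length(absent))
      stop("sample(s) missing from sheet: ", paste(absent, collapse = ", "))
  }
  sheet
}

#' Load the machine-readable transcriptions of the published result tables
#'
#' Two fixtures ship with the package: the 35-miRNA strict-tier result table
#' (per-miRNA log2FC, logCPM, likelihood-ratio statistic, p, FDR, FC and
#' direction for the UA-OC vs UA-N contrast) and the cross-biofluid status
#' table (per-miRNA direction in UA-OC plus up/down/ns status and FDR in the
#' AF and AC contrasts). Typographic minus signs are normalised to ASCII on
#' ingest. All structural invariants are checked at load time: 35 rows each,
#' direction consistent with the sign of log2FC, and every status-table
#' miRNA present in the result table.
#'
#' One printed status-table ID ("miR-6393p") matches no result-table row
#' exactly; the fixture records the printed string in \code{printed_id},
#' maps it to the presumed intended row (miR-539-3p) and flags it with
#' \code{ambiguous = TRUE}. The row is non-significant in both comparison
#' columns, so panel arithmetic is unaffected.
#'
#' @return list with data.frames \code{table2} and \code{table3}.
#' @export
load_printed_fixture <- function() {
  p2 <- system.file("extdata", "set2_results_table.tsv",
                    package = "evmirpanel", mustWork = TRUE)
  p3 <- system.file("extdata", "panel_status_table.tsv",
                    package = "evmirpanel", mustWork = TRUE)
  norm_minus <- function(x) gsub("−", "-", x)

  t2 <- utils::read.delim(p2, stringsAsFactors = FALSE)
  t2$mirna_id <- norm_minus(t2$mirna_id)
  t3 <- utils::read.delim(p3, stringsAsFactors = FALSE)
  for (cc in c("mirna_id", "printed_id"))
    t3[[cc]] <- norm_minus(t3[[cc]])

  if (nrow(t2) != 35L) stop("result-table fixture must have 35 rows")
  if (nrow(t3) != 35L) stop("status-table fixture must have 35 rows")
  dir_from_sign <- ifelse(t2$log2fc > 0, "up", "down")
  if (!identical(dir_from_sign, t2$direction))
    stop("fixture direction inconsistent with sign(log2FC)")
  if (!all(t3$mirna_id %in% t2$mirna_id))
    stop("status-table miRNA(s) absent from result table: ",
         paste(setdiff(t3$mirna_id, t2$mirna_id), collapse = ", "))
  ok_status <- c("up", "down", "ns")
  if (!all(t3$af_status %in% ok_status) || !all(t3$ac_status %in% ok_status))
    stop("status columns must be one of up/down/ns")
  list(table2 = t2, table3 = t3)
}

#' Write an analysis results table as TSV
#' @param df data.frame to write.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
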