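#' Extract a direction-aware DE set from a consensus table
#'
#' @param consensus a [run_consensus()] table.
#' @param tier "set1" (base tier, includes strict-tier calls) or "set2"
#'   (strict tier only).
#' @param contrast optional contrast label stored as provenance.
#' @return data.frame of class \code{"de_set"} with \code{mirna_id},
#'   \code{direction}, \code{tier}; only non-ns calls.
#' @export
de_set <- function(consensus, tier = c("set1", "set2"), contrast = NULL) {
  tier <- match.arg(tier)
  stopifnot(inherits(consensus, "consensus_table"))
  keep <- if (tier == "set1") consensus$direction != "ns"
          else consensus$tier == "set2"
  out <- consensus[keep, c("mirna_id", "direction", "tier")]
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  class(out) <- c("de_set", "data.frame")
  out
}

# internal constructor used by both the consensus-driven and fixture-driven
# paths; status vectors are "up"/"down"/"ns" per reference miRNA
make_partition <- function(reference, status_control, status_case, prefix,
                           provenance) {
  dir <- reference$direction
  opp <- ifelse(dir == "up", "down", "up")
  co_ctrl <- status_control == dir
  co_case <- status_case == dir
  subset <- character(nrow(reference))
  subset[co_ctrl & co_case] <- ifelse(dir[co_ctrl & co_case] == "up",
                                      paste0(prefix, "a"), paste0(prefix, "c"))
  subset[co_ctrl & !co_case] <- ifelse(dir[co_ctrl & !co_case] == "up",
                                       paste0(prefix, "b"), paste0(prefix, "d"))
  subset[status_control == "ns"] <- "e"
  subset[status_control == opp] <- "f"
  out <- data.frame(mirna_id = reference$mirna_id, direction = dir,
                    subset = subset, stringsAsFactors = FALSE)
  attr(out, "prefix") <- prefix
  attr(out, "provenance") <- provenance
  class(out) <- c("coexpression_partition", "data.frame")
  validate_partition(out, reference)
}

validate_partition <- function(partition, reference) {
  if (!setequal(partition$mirna_id, reference$mirna_id) ||
      nrow(partition) != nrow(reference))
    stop("partition does not cover the reference set exactly")
  if (anyDuplicated(partition$mirna_id))
    stop("partition assigns a miRNA to more than one subset")
  if (any(!nzchar(partition$subset)))
    stop("partition left miRNA(s) unassigned")
  partition
}

lookup_status <- function(ids, consensus) {
  idx <- match(ids, consensus$mirna_id)
  status <- consensus$direction[idx]
  if (anyNA(idx)) {
    warning("reference miRNA(s) absent from comparison universe, ",
            "treated as non-significant: ",
            paste(ids[is.na(idx)], collapse = ", "))
    status[is.na(idx)] <- "ns"
  }
  status
}

#' Direction-aware co-expression partition of a reference DE set
#'
#' Partitions a reference DE set (e.g. the UA-OC vs UA-N calls) by the
#' behaviour of each member in a second biofluid: subset a/c when the miRNA
#' is significantly changed in the reference direction both against the
#' common control and against the reference case group (up/down
#' respectively); b/d when co-directional against the control only; e when
#' non-significant against the control; f when significantly changed in the
#' opposite direction. The six subsets are exhaustive and pairwise disjoint
#' over the reference set. Reference miRNAs missing from a comparison
#' universe (possible after abundance filtering) are assigned to e with a
#' warning.
#'
#' @param reference a [de_set()] (built on the same control group as
#'   \code{vs_control}).
#' @param vs_control consensus table of the second fluid versus the common
#'   control.
#' @param vs_case consensus table of the second fluid versus the reference
#'   case group.
#' @param prefix subset label prefix ("3" gives 3a-3d, plus e and f).
#' @param provenance free-form label recording the pair of contrasts.
#' @return data.frame of class \code{"coexpression_partition"} with
#'   \code{mirna_id}, \code{direction} (the reference direction) and
#'   \code{subset}.
#' @export
codirectional_partition <- function(reference, vs_control, vs_case,
                                    prefix = "", provenance = NULL) {
  stopifnot(inherits(reference, "de_set"))
  make_partition(reference,
                 lookup_status(reference$mirna_id, vs_control),
                 lookup_status(reference$mirna_id, vs_case),
                 prefix, provenance)
}

#' @rdname codirectional_partition
#' @param set1 the reference DE set (base-tier UA-OC vs UA-N calls).
#' @param af_vs_control,af_vs_case consensus tables for ascitic-fluid EVs
#'   versus the control and versus UA-OC.
#' @export
build_set3 <- function(set1, af_vs_control, af_vs_case) {
  codirectional_partition(set1, af_vs_control, af_vs_case, prefix = "3",
                          provenance = c("AF:UA-N", "AF:UA-OC"))
}

#' @rdname codirectional_partition
#' @param ac_vs_control,ac_vs_case consensus tables for ascites-cell EVs
#'   versus the control and versus UA-OC.
#' @export
build_set4 <- function(set1, ac_vs_control, ac_vs_case) {
  codirectional_partition(set1, ac_vs_control, ac_vs_case, prefix = "4",
                          provenance = c("AC:UA-N", "AC:UA-OC"))
}

codirectional_ids <- function(partition) {
  pfx <- attr(partition, "prefix")
  partition$mirna_id[partition$subset %in% paste0(pfx, c("a", "b", "c", "d"))]
}

opposite_ids <- function(partition) {
  partition$mirna_id[partition$subset == "f"]
}

#' MiRNAs co-directionally changed in all three biofluids
#'
#' The intersection of the co-directional subsets (a-d) of two partitions
#' built on the same reference set, requiring equal direction.
#'
#' @param set3,set4 two [codirectional_partition()] objects sharing the
#'   reference set.
#' @return data.frame with \code{mirna_id} and \code{direction}.
#' @export
build_set5 <- function(set3, set4) {
  stopifnot(inherits(set3, "coexpression_partition"),
            inherits(set4, "coexpression_partition"))
  if (!setequal(set3$mirna_id, set4$mirna_id))
    stop("partitions do not share a reference set")
  ids <- intersect(codirectional_ids(set3), codirectional_ids(set4))
  d3 <- set3$direction[match(ids, set3$mirna_id)]
  d4 <- set4$direction[match(ids, set4$mirna_id)]
  ids <- ids[d3 == d4]
  data.frame(mirna_id = ids,
             direction = set3$direction[match(ids, set3$mirna_id)],
             stringsAsFactors = FALSE)
}

#' Select the tiered final marker panel
#'
#' Panel members are strict-tier (set2) miRNAs that are co-directionally
#' significant (subsets a-d) in the ascitic-fluid partition or the
#' ascites-cell partition; any miRNA significantly changed in the opposite
#' direction (subset f) in either fluid is excluded outright. Members
#' co-directional in both partitions form the \code{three_fluid} tier,
#' members co-directional in exactly one the \code{two_set} tier. Directions
#' always equal the reference (set2) direction.
#'
#' @param set2 a [de_set()] of the strict tier.
#' @param set3,set4 co-expression partitions of the base-tier reference set.
#' @return list of class \code{"panel_report"}: \code{panel} (data.frame:
#'   mirna_id, direction, tier, in_set3, in_set4), \code{set5} (see
#'   [build_set5()]) and \code{venn} (region counts over set2 and the
#'   co-directional memberships).
#' @export
select_final_panel <- function(set2, set3, set4) {
  stopifnot(inherits(set2, "de_set"))
  co3 <- codirectional_ids(set3)
  co4 <- codirectional_ids(set4)
  excl <- union(opposite_ids(set3), opposite_ids(set4))

  in3 <- set2$mirna_id %in% co3
  in4 <- set2$mirna_id %in% co4
  member <- (in3 | in4) & !(set2$mirna_id %in% excl)
  tier <- ifelse(in3 & in4, "three_fluid", "two_set")

  panel <- data.frame(mirna_id = set2$mirna_id[member],
                      direction = set2$direction[member],
                      tier = tier[member],
                      in_set3 = in3[member],
                      in_set4 = in4[member],
                      stringsAsFactors = FALSE, row.names = NULL)
  out <- list(panel = panel,
              set5 = build_set5(set3, set4),
              venn = venn_counts(list(set2 = set2$mirna_id,
                                      set3_codir = co3,
                                      set4_codir = co4)))
  class(out) <- "panel_report"
  out
}

#' @export
print.panel_report <- function(x, ...) {
  cat("Final miRNA panel:", nrow(x$panel), "members (",
      sum(x$panel$tier == "three_fluid"), "three-fluid,",
      sum(x$panel$tier == "two_set"), "two-set )\n")
  cat("Set 5 (co-directional in all three fluids vs control):",
      nrow(x$set5), "miRNAs\n")
  invisible(x)
}

#' Classify the transcribed published status table into the final panel
#'
#' The pure set-logic path: applies [select_final_panel()] directly to the
#' printed per-miRNA statuses (direction in UA-OC; up/down/ns in the AF and
#' AC comparison columns), bypassing the engines entirely. Because the
#' printed table carries no AF-vs-UA-OC or AC-vs-UA-OC columns,
#' co-directional members are placed in subsets b/d; the a-d union that the
#' panel logic consumes is unaffected.
#'
#' @param fixture result of [load_printed_fixture()] (default loads the
#'   packaged transcription).
#' @return a \code{panel_report} (see [select_final_panel()]).
#' @export
classify_table3 <- function(fixture = load_printed_fixture()) {
  t3 <- fixture$table3
  ref <- data.frame(mirna_id = t3$mirna_id, direction = t3$uaoc_direction,
                    tier = "set2", stringsAsFactors = FALSE)
  class(ref) <- c("de_set", "data.frame")
  p3 <- make_partition(ref, t3$af_status, rep("ns", nrow(t3)), "3",
                       provenance = "printed AF status")
  p4 <- make_partition(ref, t3$ac_status, rep("ns", nrow(t3)), "4",
                       provenance = "printed AC status")
  select_final_panel(ref, p3, p4)
}
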