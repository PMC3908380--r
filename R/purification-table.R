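#' Construct a purification table
#'
#' A \code{purification_table} holds one TAP/MS experiment: the runs (bait
#' purifications and negative controls), the sparse spectral counts per
#' (run, prey), and the prey sequence lengths used for NSAF normalization.
#'
#' Bait runs belong to a \emph{bait group}: all replicate runs of one bait
#' under one condition (e.g. a stimulation time point). Each (bait,
#' condition) combination is scored independently, so the bait group id is
#' \code{"<bait>@<condition>"} (or just the bait name when the condition
#' label is empty). Control runs are shared globally across all bait groups.
#'
#' @param runs data.frame with columns \code{run_id}, \code{bait},
#'   \code{condition}, \code{is_control}. \code{bait} must be \code{""} for
#'   control runs and non-empty for test runs.
#' @param counts data.frame with columns \code{run_id}, \code{prey_id},
#'   \code{sc} (non-negative integer spectral counts). Absent (run, prey)
#'   combinations mean SC = 0. Rows with \code{sc == 0} are dropped.
#' @param prey_lengths named numeric vector of protein lengths (residues),
#'   one entry per prey id appearing in \code{counts}.
#' @return An object of class \code{purification_table}.
#' @seealso [read_long_tsv()], [read_saint_triple()], [simulate_apms()]
#' @export
purification_table <- function(runs, counts, prey_lengths) {
  runs <- as.data.frame(runs, stringsAsFactors = FALSE)
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  need <- c("run_id", "bait", "condition", "is_control")
  miss <- setdiff(need, names(runs))
  if (length(miss))
    stop("runs is missing column(s): ", paste(miss, collapse = ", "))
  need <- c("run_id", "prey_id", "sc")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("counts is missing column(s): ", paste(miss, collapse = ", "))

  runs$run_id <- as.character(runs$run_id)
  runs$bait <- as.character(runs$bait)
  runs$condition <- as.character(runs$condition)
  runs$is_control <- as.logical(runs$is_control)
  if (anyDuplicated(runs$run_id))
    stop("duplicate run_id in runs: ",
         paste(unique(runs$run_id[duplicated(runs$run_id)]), collapse = ", "))
  if (any(runs$is_control & nzchar(runs$bait)))
    stop("control runs must have an empty bait label")
  if (any(!runs$is_control & !nzchar(runs$bait)))
    stop("test runs must have a non-empty bait label")

  runs$bait_group_id <- ifelse(runs$is_control, "",
                               bait_group_id(runs$bait, runs$condition))

  counts$run_id <- as.character(counts$run_id)
  counts$prey_id <- as.character(counts$prey_id)
  counts$sc <- as.numeric(counts$sc)
  if (any(!is.finite(counts$sc) | counts$sc < 0 | counts$sc != round(counts$sc)))
    stop("spectral counts must be non-negative integers")
  bad <- setdiff(counts$run_id, runs$run_id)
  if (length(bad))
    stop("counts reference undeclared run(s): ", paste(bad, collapse = ", "))
  key <- paste(counts$run_id, counts$prey_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (run_id, prey_id) entries in counts")
  counts <- counts[counts$sc > 0, , drop = FALSE]

  prey_lengths <- unlist(prey_lengths)
  if (is.null(names(prey_lengths)) && length(prey_lengths))
    stop("prey_lengths must be named by prey id")
  nolen <- setdiff(unique(counts$prey_id), names(prey_lengths))
  if (length(nolen))
    stop("prey(s) without a length entry: ", paste(nolen, collapse = ", "))
  if (any(!is.finite(prey_lengths) | prey_lengths <= 0))
    stop("prey lengths must be positive")

  test_runs <- runs[!runs$is_control, , drop = FALSE]
  groups <- split(test_runs$run_id, test_runs$bait_group_id)
  groups <- groups[order(names(groups))]
  rownames(runs) <- rownames(counts) <- NULL

  structure(
    list(runs = runs, counts = counts,
         prey_lengths = prey_lengths,
         bait_groups = groups,
         control_runs = runs$run_id[runs$is_control]),
    class = "purification_table")
}

#' @export
print.purification_table <- function(x, ...) {
  k <- length(x$bait_groups)
  cat("TAP/MS purification table\n")
  cat(sprintf("  %d runs (%d test in %d bait groups, %d controls)\n",
              nrow(x$runs), sum(!x$runs$is_control), k,
              length(x$control_runs)))
  cat(sprintf("  %d preys with counts, %d nonzero spectral-count entries\n",
              length(unique(x$counts$prey_id)), nrow(x$counts)))
  reps <- lengths(x$bait_groups)
  if (k)
    cat(sprintf("  replicates per bait group: %s\n",
                paste(range(reps), collapse = "-")))
  invisible(x)
}

# bait-group id: "<bait>@<condition>"; just "<bait>" for empty condition.
bait_group_id <- function(bait, condition) {
  ifelse(nzchar(condition), paste(bait, condition, sep = "@"), bait)
}

# bait name of every group id, via the runs table
group_baits <- function(table) {
  tr <- table$runs[!table$runs$is_control, ]
  b <- tr$bait[!duplicated(tr$bait_group_id)]
  names(b) <- tr$bait_group_id[!duplicated(tr$bait_group_id)]
  b[names(table$bait_groups)]
}

group_conditions <- function(table) {
  tr <- table$runs[!table$runs$is_control, ]
  cond <- tr$condition[!duplicated(tr$bait_group_id)]
  names(cond) <- tr$bait_group_id[!duplicated(tr$bait_group_id)]
  cond[names(table$bait_groups)]
}

# SC of one prey across an ordered set of runs, zero-filled
sc_vector <- function(table, run_ids, prey_id) {
  sub <- table$counts[table$counts$prey_id == prey_id, ]
  out <- sub$sc[match(run_ids, sub$run_id)]
  out[is.na(out)] <- 0
  out
}

#' Per-pair spectral-count evidence
#'
#' Collects, for one (bait group, prey) pair, the spectral counts across the
#' group's replicate runs and across all negative-control runs, both
#' zero-filled so that a replicate or control without a detection
#' contributes SC = 0.
#'
#' @param table a [purification_table()].
#' @param bait_group_id bait group id (see [purification_table()]).
#' @param prey_id prey id.
#' @return A list of class \code{pair_evidence} with elements
#'   \code{bait_group_id}, \code{prey_id}, \code{sc_replicates},
#'   \code{sc_controls}, \code{detect_count} (number of replicates with
#'   SC > 0) and \code{detected_any}.
#' @export
collect_pair_evidence <- function(table, bait_group_id, prey_id) {
  stopifnot(inherits(table, "purification_table"))
  runs <- table$bait_groups[[bait_group_id]]
  if (is.null(runs))
    stop("unknown bait group: ", bait_group_id)
  sc_rep <- sc_vector(table, runs, prey_id)
  sc_ctl <- sc_vector(table, table$control_runs, prey_id)
  structure(
    list(bait_group_id = bait_group_id, prey_id = prey_id,
         sc_replicates = sc_rep, sc_controls = sc_ctl,
         detect_count = sum(sc_rep > 0),
         detected_any = any(sc_rep > 0)),
    class = "pair_evidence")
}

# preys detected (SC > 0) in at least one replicate of a group
detected_preys <- function(table, group_id) {
  runs <- table$bait_groups[[group_id]]
  sort(unique(table$counts$prey_id[table$counts$run_id %in% runs]))
}
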