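#' Singleton spectral-count filter
#'
#' Flags pairs supported only by single spectral counts: every replicate
#' SC is at most 1 (with at least one detection). A lone spectrum per
#' replicate is prone to identification error and noise even when it
#' recurs in all replicates. The strict variant requires every replicate
#' SC to equal exactly 1 (the literal three-replicates-of-one case).
#'
#' @param pair a \code{pair_evidence} from [collect_pair_evidence()].
#' @param strict use the literal all-SCs-exactly-1 rule.
#' @return \code{TRUE} if the pair should be filtered out.
#' @export
singleton_filter <- function(pair, strict = FALSE) {
  stopifnot(inherits(pair, "pair_evidence"))
  singleton_filter_sc(pair$sc_replicates, strict = strict)
}

singleton_filter_sc <- function(sc, strict = FALSE) {
  if (!any(sc > 0)) return(FALSE)
  if (strict) all(sc == 1) else all(sc <= 1)
}

#' Read a contaminant-exclusion list
#'
#' Plain-text format: \code{[category]} section headers (e.g.
#' \code{[heat_shock]}, \code{[ribosomal]}, \code{[user]}) followed by one
#' glob pattern per line matched against prey and bait identifiers.
#' Blank lines and \code{#} comments are ignored.
#'
#' @param path path to the list file.
#' @return An \code{exclusion_list} data.frame with columns
#'   \code{pattern} and \code{category}.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cat_now <- "user"
  pats <- character(0); cats <- character(0)
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      cat_now <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!nzchar(cat_now)) stop("empty category header in ", path)
    } else {
      pats <- c(pats, ln); cats <- c(cats, cat_now)
    }
  }
  exclusion_list(pats, cats)
}

#' Construct an exclusion list
#'
#' @param pattern character vector of glob patterns.
#' @param category category tag per pattern (recycled).
#' @return An \code{exclusion_list} data.frame.
#' @export
exclusion_list <- function(pattern, category = "user") {
  stopifnot(all(nzchar(category)))
  out <- data.frame(pattern = as.character(pattern),
                    category = rep_len(as.character(category),
                                       length(pattern)),
                    stringsAsFactors = FALSE)
  # patterns must compile
  lapply(out$pattern, function(p) regexpr(utils::glob2rx(p), ""))
  class(out) <- c("exclusion_list", "data.frame")
  out
}

#' Flag contaminant-class rows of a score table
#'
#' Rows whose prey (or bait) identifier matches an exclusion pattern are
#' flagged \code{filtered} with the pattern's category as reason; ranks
#' are recomputed over the surviving rows. Rows are never deleted, and the
#' operation is idempotent.
#'
#' @param scores a score table from [score_all()].
#' @param exclusions an \code{exclusion_list} (see [exclusion_list()],
#'   [read_exclusion_list()]).
#' @param match_bait also match patterns against the bait name (default
#'   \code{TRUE}).
#' @return The score table with updated \code{filtered},
#'   \code{filter_reason} and \code{rank} columns.
#' @export
exclusion_filter <- function(scores, exclusions, match_bait = TRUE) {
  stopifnot(inherits(exclusions, "exclusion_list"))
  cfg <- attr(scores, "config")
  for (i in seq_len(nrow(exclusions))) {
    rx <- utils::glob2rx(exclusions$pattern[i])
    hit <- grepl(rx, scores$prey_id)
    if (match_bait) hit <- hit | grepl(rx, scores$bait)
    newly <- hit & !scores$filtered
    scores$filtered[newly] <- TRUE
    scores$filter_reason[newly] <- exclusions$category[i]
  }
  scores <- rerank(scores)
  attr(scores, "config") <- cfg
  scores
}
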