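#' Extract a per-method interaction ranking from a score table
#'
#' Collapses a score table to an ordered list of unordered (bait, prey)
#' interactions under one scoring column. Because a bait is purified under
#' several conditions (and two interactors may each serve as bait), the
#' same underlying interaction can appear in several rows; the best score
#' is kept per canonical pair. Filtered rows and self pairs are dropped.
#' Ordering is by descending score with deterministic lexicographic
#' tie-breaking, so top-k cuts are always exactly k pairs.
#'
#' @param scores a score table from [score_all()] / [ppirank()].
#' @param method one of \code{"ppirank"}, \code{"nsaf"}, \code{"z"},
#'   \code{"wd"} (the scoring column used for ordering).
#' @param symbol_map optional named character vector translating prey/bait
#'   identifiers to gene symbols at evaluation time (identity for ids
#'   without an entry).
#' @param drop_filtered drop rows flagged by the filters (default
#'   \code{TRUE}).
#' @return A \code{method_scores} data.frame with columns \code{bait},
#'   \code{prey}, \code{key} (canonical unordered pair) and \code{score},
#'   ordered.
#' @export
method_scores <- function(scores,
                          method = c("ppirank", "nsaf", "z", "wd"),
                          symbol_map = NULL, drop_filtered = TRUE) {
  method <- match.arg(method)
  s <- scores
  if (drop_filtered) s <- s[!s$filtered, , drop = FALSE]
  s <- s[!s$is_self, , drop = FALSE]
  map <- function(id) {
    if (is.null(symbol_map)) return(id)
    hit <- symbol_map[id]
    ifelse(is.na(hit), id, hit)
  }
  bait <- map(s$bait); prey <- map(s$prey_id)
  key <- pair_key(bait, prey)
  score <- s[[method]]
  ord <- order(-score, key)
  bait <- bait[ord]; prey <- prey[ord]; key <- key[ord]
  score <- score[ord]
  keep <- !duplicated(key)
  out <- data.frame(bait = bait[keep], prey = prey[keep],
                    key = key[keep], score = score[keep],
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("method_scores", "data.frame")
  out
}

known_keys <- function(known) {
  stopifnot(inherits(known, "known_interactions"))
  pair_key(known$symbol_a, known$symbol_b)
}

#' Overlap of top-ranked interactions with a known-interaction reference
#'
#' For each cutoff k, counts how many of the method's top-k interactions
#' (as unordered symbol pairs) appear in the reference set.
#'
#' @param scores a [method_scores()] ranking.
#' @param known a \code{known_interactions} reference (see
#'   [read_biogrid_tab()], [known_interactions()]).
#' @param ks ascending integer cutoffs, each at most the number of ranked
#'   pairs.
#' @return data.frame with columns \code{k} and \code{overlap}
#'   (non-decreasing in k).
#' @export
topk_overlap_curve <- function(scores, known, ks) {
  stopifnot(inherits(scores, "method_scores"))
  ks <- as.integer(ks)
  if (any(ks < 1) || any(ks > nrow(scores)))
    stop("each k must lie in 1..", nrow(scores), " (ranked pairs)")
  hit <- cumsum(scores$key %in% known_keys(known))
  data.frame(k = ks, overlap = hit[ks])
}

#' Pairwise agreement between two method rankings
#'
#' For each cutoff k, the number of unordered interactions common to the
#' top-k lists of two methods run on the same experiment.
#'
#' @param a,b [method_scores()] rankings.
#' @param ks ascending integer cutoffs.
#' @return data.frame with columns \code{k} and \code{common}.
#' @export
pairwise_agreement <- function(a, b, ks) {
  stopifnot(inherits(a, "method_scores"), inherits(b, "method_scores"))
  ks <- as.integer(ks)
  if (any(ks < 1) || any(ks > min(nrow(a), nrow(b))))
    stop("each k must lie in 1..", min(nrow(a), nrow(b)))
  common <- vapply(ks, function(k)
    length(intersect(a$key[seq_len(k)], b$key[seq_len(k)])), integer(1))
  data.frame(k = ks, common = common)
}

#' Venn-region counts of several methods' top-k interaction sets
#'
#' Partitions the union of the methods' top-k sets into its intersection
#' regions (e.g. pairs found by all methods, by exactly one, ...).
#'
#' @param methods named list of [method_scores()] rankings (>= 2).
#' @param k cutoff applied to every method.
#' @return Named integer vector: one count per non-empty membership
#'   region, named by \code{"+"}-joined method names; counts sum to the
#'   union size.
#' @export
multiway_intersection <- function(methods, k) {
  stopifnot(length(methods) >= 2)
  if (is.null(names(methods)) || any(!nzchar(names(methods))))
    names(methods) <- paste0("method", seq_along(methods))
  tops <- lapply(methods, function(m) {
    stopifnot(inherits(m, "method_scores"))
    if (k > nrow(m)) stop("k exceeds ranked pairs (", nrow(m), ")")
    m$key[seq_len(k)]
  })
  univ <- unique(unlist(tops))
  memb <- vapply(tops, function(s) univ %in% s, logical(length(univ)))
  memb <- matrix(memb, nrow = length(univ),
                 dimnames = list(NULL, names(methods)))
  region <- apply(memb, 1, function(r)
    paste(names(methods)[r], collapse = "+"))
  out <- table(region)
  stats::setNames(as.integer(out), names(out))
}

#' Choose a score cutoff from a known-interaction reference
#'
#' Sweeps every rank cutoff of the scored list and returns the score at
#' the cutoff maximizing the chosen objective of known-pair recovery,
#' computed over the scored list (recall denominator = known pairs
#' present among the scored pairs). Recommended practice for turning the
#' continuous ranking into significant/insignificant calls.
#'
#' @param scores a [method_scores()] ranking.
#' @param known a \code{known_interactions} reference; must share at
#'   least one pair with the scored list.
#' @param objective \code{"f1"} (default) or \code{"precision_at_recall"}
#'   (highest precision among cutoffs reaching \code{min_recall}).
#' @param min_recall recall floor for the precision objective.
#' @return The score threshold (scores >= it are called significant),
#'   with attributes \code{k}, \code{precision}, \code{recall},
#'   \code{f1}.
#' @export
cutoff_from_reference <- function(scores, known,
                                  objective = c("f1",
                                                "precision_at_recall"),
                                  min_recall = 0.5) {
  objective <- match.arg(objective)
  stopifnot(inherits(scores, "method_scores"))
  is_known <- scores$key %in% known_keys(known)
  n_known <- sum(is_known)
  if (n_known == 0)
    stop("no known pairs among the scored interactions")
  k <- seq_len(nrow(scores))
  tp <- cumsum(is_known)
  precision <- tp / k
  recall <- tp / n_known
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  best <- if (objective == "f1") {
    which.max(f1)
  } else {
    ok <- which(recall >= min_recall)
    if (!length(ok)) stop("no cutoff reaches recall ", min_recall)
    ok[which.max(precision[ok])]
  }
  structure(scores$score[best], k = best,
            precision = precision[best], recall = recall[best],
            f1 = f1[best])
}
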