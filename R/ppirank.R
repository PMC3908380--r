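#' Score and rank bait-prey interactions in a TAP/MS experiment
#'
#' The main entry point: runs the full scoring pipeline ([score_all()]) on
#' a purification table, optionally applies a contaminant exclusion list,
#' and returns a classed fit with \code{print}, \code{summary} and
#' \code{plot} methods.
#'
#' @param table a [purification_table()] (from [read_long_tsv()],
#'   [read_saint_triple()] or [simulate_apms()]).
#' @param config a [ppirank_config()].
#' @param exclusions optional \code{exclusion_list} of contaminant
#'   patterns applied after scoring (flagging, not dropping, rows).
#' @return An object of class \code{ppirank}: a list with elements
#'   \code{scores} (the score table), \code{config}, \code{n_groups},
#'   \code{n_controls} and \code{replicates} (per-group counts).
#' @examples
#' sim <- simulate_apms(simulation_config(n_baits = 2, n_preys = 40,
#'                                        seed = 7))
#' fit <- ppirank(sim$table)
#' head(fit$scores[order(fit$scores$rank), c("bait", "prey_id", "ppirank")])
#' @export
ppirank <- function(table, config = ppirank_config(), exclusions = NULL) {
  scores <- score_all(table, config)
  if (!is.null(exclusions))
    scores <- exclusion_filter(scores, exclusions)
  structure(list(scores = scores, config = config,
                 n_groups = length(table$bait_groups),
                 n_controls = length(table$control_runs),
                 replicates = lengths(table$bait_groups)),
            class = "ppirank")
}

#' @export
print.ppirank <- function(x, ...) {
  s <- x$scores
  cat("PPIRank interaction scoring\n")
  cat(sprintf("  %d bait groups, %d control runs, %s replicates/group\n",
              x$n_groups, x$n_controls,
              paste(unique(range(x$replicates)), collapse = "-")))
  cat(sprintf("  %d detected pairs: %d ranked, %d filtered\n",
              nrow(s), sum(!s$filtered), sum(s$filtered)))
  top <- s[!is.na(s$rank) & s$rank <= 5, ]
  top <- top[order(top$rank), c("rank", "bait_group_id", "prey_id",
                                "ppirank", "fdr")]
  if (nrow(top)) {
    cat("  top pairs:\n")
    print(format(top, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.ppirank <- function(object, ...) {
  s <- object$scores
  out <- list(
    n_pairs = nrow(s),
    n_ranked = sum(!s$filtered),
    filtered = table(s$filter_reason[s$filtered]),
    n_self = sum(s$is_self),
    fdr_quartiles = stats::quantile(s$fdr, c(0, .25, .5, .75, 1)),
    score_quartiles = stats::quantile(s$ppirank, c(0, .25, .5, .75, 1)),
    n_low_fdr = sum(s$fdr < 0.5 & !s$filtered))
  class(out) <- "summary.ppirank"
  out
}

#' @export
print.summary.ppirank <- function(x, ...) {
  cat(sprintf("%d scored pairs (%d ranked, %d self-detections)\n",
              x$n_pairs, x$n_ranked, x$n_self))
  if (length(x$filtered)) {
    cat("filtered by reason:\n")
    print(x$filtered)
  }
  cat(sprintf("%d pairs with FDR < 0.5\n", x$n_low_fdr))
  cat("FDR quartiles:\n"); print(signif(x$fdr_quartiles, 3))
  cat("PPIRank score quartiles:\n"); print(signif(x$score_quartiles, 3))
  invisible(x)
}

#' Plot a PPIRank fit
#'
#' Draws the ranked score profile (log-scale score against rank), marking
#' the FDR of each ranked pair by color, or an FDR histogram.
#'
#' @param x a \code{ppirank} fit.
#' @param type \code{"scores"} (default) or \code{"fdr"}.
#' @param ... passed to the underlying plotting function.
#' @export
plot.ppirank <- function(x, type = c("scores", "fdr"), ...) {
  type <- match.arg(type)
  s <- x$scores[!x$scores$filtered, ]
  if (type == "scores") {
    s <- s[order(s$rank), ]
    graphics::plot(s$rank, pmax(s$ppirank, 1e-12), log = "y",
                   xlab = "rank", ylab = "PPIRank score",
                   col = ifelse(s$fdr < 0.25, "forestgreen",
                                ifelse(s$fdr < 0.5, "orange", "red3")),
                   pch = 16, cex = 0.6, ...)
    graphics::legend("topright", pch = 16, bty = "n",
                     col = c("forestgreen", "orange", "red3"),
                     legend = c("FDR < 0.25", "FDR < 0.5", "FDR = 0.5"))
  } else {
    graphics::hist(s$fdr, breaks = 20, xlab = "per-pair FDR",
                   main = "", ...)
  }
  invisible(x)
}
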