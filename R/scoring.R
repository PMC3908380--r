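#' Scoring configuration
#'
#' Bundles the tunable choices of the scoring pipeline. Defaults follow
#' the method's published form; the alternatives documented here exist for
#' sensitivity checks.
#'
#' @param w_threshold threshold on the coefficient of variation CV =
#'   std/mean above which the variance weight W equals the CV; below or at
#'   it, W = 1. 0 reproduces the published branch ("if std/mean > 0"); 1
#'   reproduces the original CompPASS convention. Other values are
#'   permitted but flagged with a message.
#' @param sd_type \code{"population"} (divide by K; keeps Z well-defined
#'   at K = 2) or \code{"sample"} (K - 1), applied consistently in W and
#'   Z.
#' @param exponent_includes_w when \code{TRUE}, the reproducibility
#'   exponent R applies to the product (K/\eqn{\Sigma}f) x W rather than
#'   to the frequency ratio alone.
#' @param alternative sidedness of the control rank-sum test; default
#'   one-sided \code{"greater"} (bait enriched over control).
#' @param exact_cap pooled-sample-size cap for exact rank-sum enumeration.
#' @param singleton_strict when \code{TRUE} the singleton filter uses the
#'   literal all-replicate-SCs-exactly-1 rule; default generalizes to
#'   every replicate SC <= 1.
#' @param min_replicates_warn warn when a bait group has fewer replicates
#'   (default 3, the recommended minimum design).
#' @return A list of class \code{ppirank_config}.
#' @export
ppirank_config <- function(w_threshold = 0,
                           sd_type = c("population", "sample"),
                           exponent_includes_w = FALSE,
                           alternative = c("greater", "two.sided"),
                           exact_cap = 12L,
                           singleton_strict = FALSE,
                           min_replicates_warn = 3L) {
  if (!w_threshold %in% c(0, 1))
    message("w_threshold = ", w_threshold,
            " is outside the conventional {0, 1}")
  structure(list(w_threshold = w_threshold,
                 sd_type = match.arg(sd_type),
                 exponent_includes_w = isTRUE(exponent_includes_w),
                 alternative = match.arg(alternative),
                 exact_cap = as.integer(exact_cap),
                 singleton_strict = isTRUE(singleton_strict),
                 min_replicates_warn = as.integer(min_replicates_warn)),
            class = "ppirank_config")
}

cfg_sd <- function(x, type) {
  m <- mean(x)
  if (type == "population") sqrt(mean((x - m)^2))
  else stats::sd(x)
}

#' Normalized spectral abundance factors for one run
#'
#' NSAF of prey j in a run is its length-normalized spectral count divided
#' by the run total: \eqn{(SC_j / L_j) / \sum_k (SC_k / L_k)}, summed over
#' the preys detected in that run. Values over a run sum to 1; undetected
#' preys have NSAF 0 (and are absent from the returned mapping).
#'
#' @param table a [purification_table()].
#' @param run_id run to normalize.
#' @return Named numeric vector of NSAF values over the run's detected
#'   preys (empty, with a warning, if the run has no detections).
#' @export
nsaf <- function(table, run_id) {
  stopifnot(inherits(table, "purification_table"))
  if (!run_id %in% table$runs$run_id) stop("unknown run: ", run_id)
  sub <- table$counts[table$counts$run_id == run_id, ]
  if (!nrow(sub)) {
    warning("run ", run_id, " has no detected preys")
    return(stats::setNames(numeric(0), character(0)))
  }
  len <- table$prey_lengths[sub$prey_id]
  if (any(len <= 0)) stop("non-positive prey length")
  saf <- sub$sc / len
  stats::setNames(as.numeric(saf / sum(saf)), sub$prey_id)
}

#' Replicate-averaged NSAF of one bait-prey pair
#'
#' Arithmetic mean of the per-replicate NSAF values over all T replicates
#' of the bait group, counting 0 for replicates in which the prey is not
#' detected.
#'
#' @inheritParams collect_pair_evidence
#' @return A single non-negative number.
#' @export
nsaf_mean <- function(table, bait_group_id, prey_id) {
  runs <- table$bait_groups[[bait_group_id]]
  if (is.null(runs)) stop("unknown bait group: ", bait_group_id)
  vals <- vapply(runs, function(r) {
    v <- suppressWarnings(nsaf(table, r))
    if (prey_id %in% names(v)) v[[prey_id]] else 0
  }, numeric(1))
  mean(vals)
}

# preys x bait-groups matrix of replicate-mean spectral counts
group_mean_sc <- function(table, preys = NULL) {
  groups <- table$bait_groups
  if (is.null(preys)) preys <- sort(unique(table$counts$prey_id))
  m <- matrix(0, length(preys), length(groups),
              dimnames = list(preys, names(groups)))
  cnt <- table$counts[table$counts$prey_id %in% preys, ]
  run_group <- table$runs$bait_group_id[match(cnt$run_id,
                                              table$runs$run_id)]
  keep <- nzchar(run_group)
  cnt <- cnt[keep, ]; run_group <- run_group[keep]
  if (nrow(cnt)) {
    agg <- tapply(cnt$sc, list(cnt$prey_id, run_group), sum)
    agg[is.na(agg)] <- 0
    m[rownames(agg), colnames(agg)] <-
      sweep(agg, 2, lengths(groups)[colnames(agg)], "/")
  }
  m
}

#' Cross-purification variance weight W of a prey
#'
#' Let x be the vector of the prey's replicate-mean spectral counts across
#' all K bait groups (zeros included). W is the coefficient of variation
#' std(x)/mean(x) when it exceeds \code{config$w_threshold}, else 1; a
#' prey never detected (mean 0) has W = 1. Preys concentrated in few bait
#' groups get large W; uniformly present (sticky) preys get W near or
#' below 1.
#'
#' @param table a [purification_table()].
#' @param prey_id prey.
#' @param config a [ppirank_config()].
#' @return W > 0.
#' @export
variance_weight <- function(table, prey_id, config = ppirank_config()) {
  x <- group_mean_sc(table, prey_id)[1, ]
  w_from_x(x, config)
}

w_from_x <- function(x, config) {
  m <- mean(x)
  if (m == 0) return(1)
  cv <- cfg_sd(x, config$sd_type) / m
  if (is.finite(cv) && cv > config$w_threshold) cv else 1
}

#' CompPASS-style Z score of a bait-prey pair
#'
#' Standardizes the pair's replicate-mean spectral count against the
#' prey's mean and standard deviation across all K bait groups
#' (population convention by default). Returns 0 when the cross-
#' purification standard deviation is 0.
#'
#' @inheritParams collect_pair_evidence
#' @param config a [ppirank_config()].
#' @return Z score (any real).
#' @export
compass_z <- function(table, bait_group_id, prey_id,
                      config = ppirank_config()) {
  x <- group_mean_sc(table, prey_id)[1, ]
  if (!bait_group_id %in% names(x))
    stop("unknown bait group: ", bait_group_id)
  z_from_x(x, bait_group_id, config)
}

z_from_x <- function(x, group_id, config) {
  s <- cfg_sd(x, config$sd_type)
  if (s == 0) return(0)
  (x[[group_id]] - mean(x)) / s
}

#' CompPASS weighted-D score of a bait-prey pair
#'
#' \eqn{WD = \sqrt{s \times ((K / \Sigma f) W_j)^N}} where s is the pair's
#' replicate-mean spectral count, \eqn{\Sigma f} the number of bait groups
#' detecting the prey, \eqn{W_j} the variance weight and N the number of
#' replicates detecting the pair. 0 for an undetected pair.
#'
#' @inheritParams compass_z
#' @return WD >= 0.
#' @export
compass_wd <- function(table, bait_group_id, prey_id,
                       config = ppirank_config()) {
  x <- group_mean_sc(table, prey_id)[1, ]
  ev <- collect_pair_evidence(table, bait_group_id, prey_id)
  wd_from_parts(mean(ev$sc_replicates), length(x), sum(x > 0),
                w_from_x(x, config), ev$detect_count)
}

wd_from_parts <- function(s, k, sum_f, w, n) {
  if (s == 0) return(0)
  sqrt(s * ((k / sum_f) * w)^n)
}

#' Reproducibility-weighted frequency term
#'
#' The frequency ratio \eqn{K / \Sigma f} (total bait groups over groups
#' detecting the prey) raised to the reproducibility \eqn{R = N / T}
#' (fraction of the group's replicates detecting the pair), times the
#' variance weight: \eqn{W_j \times (K/\Sigma f)^{N/T}}. Preys unique to
#' one bait and seen in every replicate receive the full factor K; one
#' seen in every bait group receives just \eqn{W_j}.
#'
#' @param pair a \code{pair_evidence} from [collect_pair_evidence()].
#' @param table the [purification_table()] the pair was collected from.
#' @param config a [ppirank_config()].
#' @return The term (> 0). Errors if the prey is undetected in every bait
#'   group.
#' @export
freq_repro_term <- function(pair, table, config = ppirank_config()) {
  stopifnot(inherits(pair, "pair_evidence"))
  x <- group_mean_sc(table, pair$prey_id)[1, ]
  sum_f <- sum(x > 0)
  if (sum_f == 0)
    stop("prey ", pair$prey_id, " is undetected in every bait group")
  t_reps <- length(pair$sc_replicates)
  term_from_parts(length(x), sum_f, w_from_x(x, config),
                  pair$detect_count / t_reps, config)
}

term_from_parts <- function(k, sum_f, w, r, config) {
  if (config$exponent_includes_w) ((k / sum_f) * w)^r
  else w * (k / sum_f)^r
}

#' Composite PPIRank score of a bait-prey pair
#'
#' \deqn{PPIRank = \overline{NSAF} \times (1 - FDR)^T \times W_j \times
#'   (K / \Sigma f)^{N/T}}
#' combining replicate-averaged abundance, a control-based FDR penalty
#' compounded over the T replicates, and the reproducibility-weighted
#' frequency term. Higher scores mean stronger interaction evidence; the
#' score is 0 exactly when the averaged NSAF is 0.
#'
#' @param pair a \code{pair_evidence} from [collect_pair_evidence()].
#' @param table the [purification_table()].
#' @param fdr the pair's calibrated FDR in [0, 0.5] (see
#'   [fdr_for_pair()]).
#' @param config a [ppirank_config()].
#' @return Score >= 0.
#' @export
ppirank_score <- function(pair, table, fdr, config = ppirank_config()) {
  stopifnot(inherits(pair, "pair_evidence"), fdr >= 0, fdr <= 0.5)
  nm <- nsaf_mean(table, pair$bait_group_id, pair$prey_id)
  if (nm == 0) return(0)
  t_reps <- length(pair$sc_replicates)
  nm * (1 - fdr)^t_reps * freq_repro_term(pair, table, config)
}

#' Score every detected bait-prey pair of an experiment
#'
#' Computes, for each (bait group, prey) pair detected in at least one
#' replicate: the averaged NSAF, the variance weight W, the CompPASS Z and
#' WD baseline scores, the one-sided rank-sum p-value against the negative
#' controls, the calibrated FDR, the reproducibility-weighted frequency
#' term and the composite PPIRank score. The singleton filter (every
#' replicate SC at most 1) is applied as a flag; self pairs (prey equals
#' the bait protein) are flagged \code{is_self} but retained. Ranks run
#' 1..n over unfiltered rows by descending PPIRank score, ties broken
#' lexicographically by (bait group, prey).
#'
#' @param table a [purification_table()] with at least one negative
#'   control run.
#' @param config a [ppirank_config()].
#' @return A data.frame (one row per detected pair) with columns
#'   \code{bait_group_id}, \code{bait}, \code{condition}, \code{prey_id},
#'   \code{is_self}, \code{t_reps}, \code{n_detect}, \code{mean_sc},
#'   \code{nsaf}, \code{w}, \code{z}, \code{wd}, \code{r_term},
#'   \code{freq_term}, \code{p_value}, \code{fdr}, \code{ppirank},
#'   \code{rank}, \code{filtered}, \code{filter_reason}; the effective
#'   config is attached as attribute \code{"config"}.
#' @export
score_all <- function(table, config = ppirank_config()) {
  stopifnot(inherits(table, "purification_table"))
  if (length(table$control_runs) == 0)
    stop("PPIRank requires negative controls: the table has no control runs")
  reps <- lengths(table$bait_groups)
  low <- names(reps)[reps < config$min_replicates_warn]
  if (length(low))
    warning("bait group(s) with fewer than ", config$min_replicates_warn,
            " replicates: ", paste(low, collapse = ", "))

  groups <- names(table$bait_groups)
  k <- length(groups)
  baits <- group_baits(table)
  conds <- group_conditions(table)
  msc <- group_mean_sc(table)
  sum_f <- rowSums(msc > 0)
  w_all <- apply(msc, 1, w_from_x, config = config)

  # per-run NSAF, computed once
  nsaf_by_run <- lapply(stats::setNames(table$runs$run_id,
                                        table$runs$run_id),
                        function(r) suppressWarnings(nsaf(table, r)))

  rows <- vector("list", k)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    run_ids <- table$bait_groups[[g]]
    t_reps <- length(run_ids)
    preys <- detected_preys(table, g)
    if (!length(preys)) next
    # replicate SC matrix for this group's detected preys
    scm <- vapply(run_ids, function(r) {
      v <- table$counts[table$counts$run_id == r, ]
      out <- v$sc[match(preys, v$prey_id)]
      out[is.na(out)] <- 0
      out
    }, numeric(length(preys)))
    scm <- matrix(scm, nrow = length(preys),
                  dimnames = list(preys, run_ids))
    ctl <- vapply(table$control_runs, function(r) {
      v <- table$counts[table$counts$run_id == r, ]
      out <- v$sc[match(preys, v$prey_id)]
      out[is.na(out)] <- 0
      out
    }, numeric(length(preys)))
    ctl <- matrix(ctl, nrow = length(preys),
                  dimnames = list(preys, table$control_runs))
    nsafm <- vapply(run_ids, function(r) {
      v <- nsaf_by_run[[r]]
      out <- v[match(preys, names(v))]
      out[is.na(out)] <- 0
      as.numeric(out)
    }, numeric(length(preys)))
    nsafm <- matrix(nsafm, nrow = length(preys))

    n_det <- rowSums(scm > 0)
    mean_sc <- rowMeans(scm)
    r_term <- n_det / t_reps
    p_vals <- vapply(seq_along(preys), function(i)
      ranksum_p(scm[i, ], ctl[i, ], alternative = config$alternative,
                exact_cap = config$exact_cap)$p_value, numeric(1))
    fdrs <- fdr_from_p(p_vals)
    wj <- w_all[preys]
    sf <- sum_f[preys]
    fterm <- vapply(seq_along(preys), function(i)
      term_from_parts(k, sf[i], wj[i], r_term[i], config), numeric(1))
    zs <- vapply(preys, function(p) z_from_x(msc[p, ], g, config),
                 numeric(1))
    wds <- vapply(seq_along(preys), function(i)
      wd_from_parts(mean_sc[i], k, sf[i], wj[i], n_det[i]), numeric(1))
    nm <- rowMeans(nsafm)
    score <- nm * (1 - fdrs)^t_reps * fterm

    single <- vapply(seq_along(preys), function(i)
      singleton_filter_sc(scm[i, ], strict = config$singleton_strict),
      logical(1))
    rows[[gi]] <- data.frame(
      bait_group_id = g, bait = unname(baits[g]),
      condition = unname(conds[g]), prey_id = preys,
      is_self = preys == baits[[g]],
      t_reps = t_reps, n_detect = n_det, mean_sc = mean_sc,
      nsaf = nm, w = unname(wj), z = unname(zs), wd = wds,
      r_term = r_term, freq_term = fterm,
      p_value = p_vals, fdr = fdrs, ppirank = score,
      rank = NA_integer_, filtered = single,
      filter_reason = ifelse(single, "singleton", ""),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(bait_group_id = character(), bait = character(),
                      condition = character(), prey_id = character(),
                      is_self = logical(), t_reps = integer(),
                      n_detect = integer(), mean_sc = numeric(),
                      nsaf = numeric(), w = numeric(), z = numeric(),
                      wd = numeric(), r_term = numeric(),
                      freq_term = numeric(), p_value = numeric(),
                      fdr = numeric(), ppirank = numeric(),
                      rank = integer(), filtered = logical(),
                      filter_reason = character())
  out <- out[order(out$bait_group_id, out$prey_id), , drop = FALSE]
  rownames(out) <- NULL
  out <- rerank(out)
  attr(out, "config") <- unclass(config)
  out
}

# deterministic ranks over unfiltered rows: score desc, then (group, prey)
rerank <- function(scores) {
  scores$rank <- NA_integer_
  idx <- which(!scores$filtered)
  if (length(idx)) {
    ord <- idx[order(-scores$ppirank[idx], scores$bait_group_id[idx],
                     scores$prey_id[idx])]
    scores$rank[ord] <- seq_along(ord)
  }
  scores
}
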