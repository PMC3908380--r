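#' Configuration of the synthetic TAP/MS experiment generator
#'
#' Describes a pathway-style TAP/MS design: several baits purified under
#' several conditions (e.g. stimulation time points) with biological
#' replicates, plus shared negative-control runs. Preys fall into four
#' classes: \emph{true} interactors planted on specific baits (high,
#' reproducible counts, absent from controls), \emph{sticky} background
#' binders (low counts across many baits and carried over into controls),
#' abundant \emph{contaminants} named like heat-shock and ribosomal
#' proteins (to exercise the exclusion filter), and sparse
#' \emph{background} noise.
#'
#' @param n_baits number of bait proteins.
#' @param conditions condition labels; each (bait, condition) is scored as
#'   its own bait group.
#' @param n_replicates biological replicates per bait group (>= 1;
#'   3 is the recommended design).
#' @param n_controls shared negative-control runs.
#' @param n_preys number of non-bait preys.
#' @param true_edges_per_bait planted true interactors per bait (carried
#'   across all conditions).
#' @param lambda_true mean spectral count of a true interactor per
#'   replicate.
#' @param lambda_background mean spectral count of sticky/background
#'   preys.
#' @param lambda_contaminant mean spectral count of contaminant preys
#'   (abundant, heat-shock-like).
#' @param lambda_self mean spectral count of the bait protein in its own
#'   purifications.
#' @param dropout_prob per-replicate probability that a true interactor
#'   is missed entirely.
#' @param sticky_fraction,contaminant_fraction fractions of preys
#'   assigned to the sticky and contaminant classes.
#' @param sticky_presence_prob,contaminant_presence_prob probability that
#'   a sticky/contaminant prey is present in any given bait group.
#' @param control_carryover_prob probability that a sticky/contaminant
#'   prey appears in any given control run.
#' @param background_detect_prob per-(prey, run) probability of a sparse
#'   background detection (applies to test and control runs alike).
#' @param prey_length_range integer pair; prey lengths are uniform over
#'   this range (residues).
#' @param dispersion negative-binomial overdispersion of all counts
#'   (0 = Poisson).
#' @param seed RNG seed; the simulation is a pure function of this
#'   config.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_baits = 6,
                              conditions = c("0", "10", "30"),
                              n_replicates = 3, n_controls = 6,
                              n_preys = 300, true_edges_per_bait = 10,
                              lambda_true = 10, lambda_background = 2,
                              lambda_contaminant = 8, lambda_self = 60,
                              dropout_prob = 0.2,
                              sticky_fraction = 0.10,
                              contaminant_fraction = 0.05,
                              sticky_presence_prob = 0.7,
                              contaminant_presence_prob = 0.8,
                              control_carryover_prob = 0.3,
                              background_detect_prob = 0.05,
                              prey_length_range = c(100L, 1000L),
                              dispersion = 0, seed = 1L) {
  cfg <- list(n_baits = as.integer(n_baits),
              conditions = as.character(conditions),
              n_replicates = as.integer(n_replicates),
              n_controls = as.integer(n_controls),
              n_preys = as.integer(n_preys),
              true_edges_per_bait = as.integer(true_edges_per_bait),
              lambda_true = lambda_true,
              lambda_background = lambda_background,
              lambda_contaminant = lambda_contaminant,
              lambda_self = lambda_self,
              dropout_prob = dropout_prob,
              sticky_fraction = sticky_fraction,
              contaminant_fraction = contaminant_fraction,
              sticky_presence_prob = sticky_presence_prob,
              contaminant_presence_prob = contaminant_presence_prob,
              control_carryover_prob = control_carryover_prob,
              background_detect_prob = background_detect_prob,
              prey_length_range = as.integer(prey_length_range),
              dispersion = dispersion, seed = as.integer(seed))
  probs <- c("dropout_prob", "sticky_fraction", "contaminant_fraction",
             "sticky_presence_prob", "contaminant_presence_prob",
             "control_carryover_prob", "background_detect_prob")
  bad <- character(0)
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] >= 1 + 1e-12) bad <- c(bad, p)
  if (cfg$n_baits < 1) bad <- c(bad, "n_baits")
  if (cfg$n_replicates < 1) bad <- c(bad, "n_replicates")
  if (cfg$n_controls < 1) bad <- c(bad, "n_controls")
  if (any(c(cfg$lambda_true, cfg$lambda_background,
            cfg$lambda_contaminant, cfg$lambda_self,
            cfg$dispersion) < 0)) bad <- c(bad, "rates")
  if (length(cfg$prey_length_range) != 2 ||
      any(cfg$prey_length_range < 1) ||
      diff(cfg$prey_length_range) < 0) bad <- c(bad, "prey_length_range")
  n_classed <- cfg$n_baits * cfg$true_edges_per_bait +
    round(cfg$sticky_fraction * cfg$n_preys) +
    round(cfg$contaminant_fraction * cfg$n_preys)
  if (n_classed > cfg$n_preys) bad <- c(bad, "n_preys (too few for classes)")
  if (length(bad))
    stop("invalid simulation config field(s): ",
         paste(unique(bad), collapse = ", "))
  class(cfg) <- "simulation_config"
  cfg
}

draw_count <- function(n, lambda, dispersion) {
  if (lambda <= 0 || n == 0) return(rep(0L, n))
  if (dispersion > 0)
    stats::rnbinom(n, mu = lambda, size = 1 / dispersion)
  else stats::rpois(n, lambda)
}

#' Simulate a TAP/MS experiment with planted ground truth
#'
#' Generates spectral counts under the design described in
#' [simulation_config()]: true-edge counts are
#' Poisson(\code{lambda_true}) thinned by per-replicate Bernoulli
#' dropout; sticky and contaminant preys receive Poisson counts in a
#' random subset of bait groups and carry over into control runs;
#' background preys contribute sparse Poisson noise in any run; every
#' bait detects itself at high abundance. Fully reproducible from the
#' config (including its seed).
#'
#' @param config a [simulation_config()].
#' @return A list of class \code{apms_simulation} with elements
#'   \code{table} (a [purification_table()]), \code{truth} (data.frame of
#'   planted edges per bait group), \code{prey_classes} (data.frame
#'   \code{prey_id}, \code{class}) and \code{config}.
#' @export
simulate_apms <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cf <- config

  baits <- sprintf("BAIT%02d", seq_len(cf$n_baits))
  n_true <- cf$n_baits * cf$true_edges_per_bait
  n_sticky <- round(cf$sticky_fraction * cf$n_preys)
  n_contam <- round(cf$contaminant_fraction * cf$n_preys)
  preys <- sprintf("P%04d", seq_len(cf$n_preys))
  class_vec <- rep("background", cf$n_preys)
  class_vec[seq_len(n_true)] <- "true"
  if (n_sticky) class_vec[n_true + seq_len(n_sticky)] <- "sticky"
  if (n_contam) {
    idx <- n_true + n_sticky + seq_len(n_contam)
    class_vec[idx] <- "contaminant"
    # heat-shock / ribosomal naming, alternating, to exercise exclusions
    preys[idx] <- ifelse(seq_len(n_contam) %% 2 == 1,
                         sprintf("Hsp%02d", seq_len(n_contam)),
                         sprintf("RpL%02d", seq_len(n_contam)))
  }

  lens <- sample(seq(cf$prey_length_range[1], cf$prey_length_range[2]),
                 cf$n_preys + cf$n_baits, replace = TRUE)
  prey_lengths <- stats::setNames(lens, c(preys, baits))

  runs <- expand.grid(rep = seq_len(cf$n_replicates),
                      condition = cf$conditions, bait = baits,
                      stringsAsFactors = FALSE)
  runs <- data.frame(
    run_id = sprintf("%s_c%s_r%d", runs$bait, runs$condition, runs$rep),
    bait = runs$bait, condition = runs$condition, is_control = FALSE,
    stringsAsFactors = FALSE)
  ctl <- data.frame(run_id = sprintf("CTRL_r%d", seq_len(cf$n_controls)),
                    bait = "", condition = "", is_control = TRUE,
                    stringsAsFactors = FALSE)
  runs <- rbind(runs, ctl)
  test_runs <- runs[!runs$is_control, ]
  group_of_run <- bait_group_id(test_runs$bait, test_runs$condition)
  groups <- unique(group_of_run)

  acc_run <- character(0); acc_prey <- character(0); acc_sc <- integer(0)
  add <- function(run_id, prey_id, sc) {
    keep <- sc > 0
    acc_run <<- c(acc_run, run_id[keep])
    acc_prey <<- c(acc_prey, prey_id[keep])
    acc_sc <<- c(acc_sc, sc[keep])
  }

  # bait self-detection, every replicate of every own group
  for (b in baits) {
    rid <- test_runs$run_id[test_runs$bait == b]
    add(rid, rep(b, length(rid)),
        draw_count(length(rid), cf$lambda_self, cf$dispersion))
  }

  # planted true edges: same interactors for a bait across conditions
  truth <- NULL
  for (bi in seq_len(cf$n_baits)) {
    own <- preys[(bi - 1) * cf$true_edges_per_bait +
                   seq_len(cf$true_edges_per_bait)]
    rid <- test_runs$run_id[test_runs$bait == baits[bi]]
    for (p in own) {
      sc <- draw_count(length(rid), cf$lambda_true, cf$dispersion) *
        stats::rbinom(length(rid), 1, 1 - cf$dropout_prob)
      add(rid, rep(p, length(rid)), sc)
    }
    truth <- rbind(truth, data.frame(
      bait = baits[bi],
      bait_group_id = rep(bait_group_id(baits[bi], cf$conditions),
                          each = cf$true_edges_per_bait),
      condition = rep(cf$conditions, each = cf$true_edges_per_bait),
      prey_id = rep(own, times = length(cf$conditions)),
      lambda = cf$lambda_true, stringsAsFactors = FALSE))
  }

  # sticky and contaminant classes: present across many bait groups,
  # carried over into controls
  for (cls in c("sticky", "contaminant")) {
    ids <- preys[class_vec == cls]
    pres <- if (cls == "sticky") cf$sticky_presence_prob
            else cf$contaminant_presence_prob
    lam <- if (cls == "sticky") cf$lambda_background
           else cf$lambda_contaminant
    for (p in ids) {
      in_group <- groups[stats::runif(length(groups)) < pres]
      rid <- test_runs$run_id[group_of_run %in% in_group]
      add(rid, rep(p, length(rid)),
          draw_count(length(rid), lam, cf$dispersion))
      in_ctl <- ctl$run_id[stats::runif(cf$n_controls) <
                             cf$control_carryover_prob]
      add(in_ctl, rep(p, length(in_ctl)),
          draw_count(length(in_ctl), lam, cf$dispersion))
    }
  }

  # sparse background noise over all runs (controls included)
  bg <- preys[class_vec == "background"]
  if (length(bg) && cf$background_detect_prob > 0) {
    hits <- which(matrix(
      stats::runif(length(bg) * nrow(runs)) < cf$background_detect_prob,
      nrow = length(bg)), arr.ind = TRUE)
    if (nrow(hits))
      add(runs$run_id[hits[, 2]], bg[hits[, 1]],
          draw_count(nrow(hits), cf$lambda_background, cf$dispersion))
  }

  counts <- data.frame(run_id = acc_run, prey_id = acc_prey, sc = acc_sc,
                       stringsAsFactors = FALSE)
  # duplicates cannot arise (classes are disjoint), but keep the
  # constructor's invariant honest
  table <- purification_table(runs, counts, prey_lengths)

  prey_classes <- rbind(
    data.frame(prey_id = preys, class = class_vec,
               stringsAsFactors = FALSE),
    data.frame(prey_id = baits, class = "self",
               stringsAsFactors = FALSE))
  structure(list(table = table, truth = truth,
                 prey_classes = prey_classes, config = config),
            class = "apms_simulation")
}

#' @export
print.apms_simulation <- function(x, ...) {
  cat("Simulated TAP/MS experiment\n")
  print(x$table)
  cat(sprintf("  %d planted true edges (%d per bait group)\n",
              nrow(x$truth), x$config$true_edges_per_bait))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits both input dialects (long TSV and SAINT triple) plus the planted
#' truth, into a directory.
#'
#' @param sim an \code{apms_simulation} from [simulate_apms()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named character vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "apms_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(long = file.path(dir, "experiment.tsv"),
             interaction = file.path(dir, "interaction.tsv"),
             bait = file.path(dir, "bait.tsv"),
             prey = file.path(dir, "prey.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_long_tsv(sim$table, paths[["long"]])
  write_saint_triple(sim$table, paths[["interaction"]],
                     paths[["bait"]], paths[["prey"]],
                     condition_split = "@")
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# tie-aware Mann-Whitney AUROC; NA (with warning) when a class is empty
auroc <- function(score, is_positive) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: ", if (n1 == 0) "no positive"
            else "no negative", " pairs")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Benchmark scoring methods against planted simulation truth
#'
#' Scores the experiment once and evaluates each method's score column as
#' a detector of the planted true edges among all detected non-self
#' (bait group, prey) pairs: AUROC (tie-aware rank statistic), precision
#' at k = number of detected true edges, and the recall-at-k curve.
#'
#' @param table a [purification_table()] from [simulate_apms()].
#' @param truth the matching simulation truth (data.frame with
#'   \code{bait_group_id}, \code{prey_id}).
#' @param methods subset of \code{c("ppirank", "nsaf", "z", "wd")}.
#' @param scores optional precomputed [score_all()] table (avoids
#'   rescoring).
#' @return A list with \code{metrics} (data.frame: method, auroc,
#'   precision_at_truth, n_true, n_other) and \code{recall} (data.frame
#'   of recall-at-k per method).
#' @export
benchmark_methods <- function(table, truth,
                              methods = c("ppirank", "nsaf", "z", "wd"),
                              scores = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(scores)) scores <- score_all(table)
  s <- scores[!scores$is_self, , drop = FALSE]
  lab <- paste(s$bait_group_id, s$prey_id, sep = "\r") %in%
    paste(truth$bait_group_id, truth$prey_id, sep = "\r")
  n1 <- sum(lab)
  metrics <- data.frame(method = methods, auroc = NA_real_,
                        precision_at_truth = NA_real_,
                        n_true = n1, n_other = sum(!lab),
                        stringsAsFactors = FALSE)
  recall <- NULL
  for (i in seq_along(methods)) {
    sc <- s[[methods[i]]]
    metrics$auroc[i] <- auroc(sc, lab)
    ord <- order(-sc, s$bait_group_id, s$prey_id)
    hits <- cumsum(lab[ord])
    if (n1 > 0) {
      metrics$precision_at_truth[i] <- hits[min(n1, length(hits))] / n1
      recall <- rbind(recall, data.frame(
        method = methods[i], k = seq_along(hits),
        recall = hits / n1, stringsAsFactors = FALSE))
    }
  }
  list(metrics = metrics, recall = recall)
}
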