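# Shared fixtures and independent oracles, built in code.

# Canonical toy experiment: 4 single-condition bait groups (G1..G4),
# 3 replicates each, 6 controls. Prey roles:
#   pWD      (9,18,0) in G1 only        - WD / W / Z hand computations
#   pRESCUE  (3,21,0) in G1, no control - the rescue case
#   pSINGLE  (1,1,1)  in G1             - singleton filter
#   pSTICKY  SC 2 everywhere incl. controls - degenerate W/Z, FDR = 0.5
#   pCTL     controls only              - never scored
#   pFULL    (5,6,7) in G2 only         - full-reproducibility case
toy_table <- function() {
  baits <- paste0("G", 1:4)
  runs <- data.frame(
    run_id = c(t(outer(baits, 1:3, paste, sep = "_r")),
               paste0("C_r", 1:6)),
    bait = c(rep(baits, each = 3), rep("", 6)),
    condition = "",
    is_control = rep(c(FALSE, TRUE), c(12, 6)))
  grp_runs <- function(g) paste0(g, "_r", 1:3)
  counts <- rbind(
    data.frame(run_id = grp_runs("G1")[1:2], prey_id = "pWD",
               sc = c(9, 18)),
    data.frame(run_id = grp_runs("G1")[1:2], prey_id = "pRESCUE",
               sc = c(3, 21)),
    data.frame(run_id = grp_runs("G1"), prey_id = "pSINGLE",
               sc = c(1, 1, 1)),
    data.frame(run_id = c(t(outer(baits, 1:3, paste, sep = "_r")),
                          paste0("C_r", 1:6)),
               prey_id = "pSTICKY", sc = 2),
    data.frame(run_id = paste0("C_r", 1:3), prey_id = "pCTL",
               sc = c(4, 5, 6)),
    data.frame(run_id = grp_runs("G2"), prey_id = "pFULL",
               sc = c(5, 6, 7)))
  lens <- c(pWD = 200, pRESCUE = 350, pSINGLE = 100, pSTICKY = 500,
            pCTL = 120, pFULL = 440)
  purification_table(runs, counts, lens)
}

# independent NSAF oracle: plain loop over detected preys
oracle_nsaf <- function(sc, len) {
  saf <- numeric(length(sc))
  for (i in seq_along(sc)) saf[i] <- sc[i] / len[i]
  out <- numeric(length(sc))
  for (i in seq_along(sc)) out[i] <- saf[i] / sum(saf)
  out
}

# independent exact rank-sum oracle: enumerate all C(n, n1) label
# assignments and compute the Mann-Whitney U of each by pairwise
# comparison counting (no rank() call), one-sided greater.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); n1 <- length(x)
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b)
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  u_obs <- u_of(x, y)
  sets <- utils::combn(n, n1)
  hits <- 0
  for (j in seq_len(ncol(sets))) {
    a <- pooled[sets[, j]]; b <- pooled[-sets[, j]]
    if (u_of(a, b) >= u_obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(sets)
}

# closed-form p-value calibration, written out independently
oracle_fdr <- function(p) {
  if (p >= 1 / exp(1)) return(0.5)
  b <- -exp(1) * p * log(p)
  b / (1 + b)
}

# small deterministic simulation for fast end-to-end tests
small_sim <- function(seed = 42, ...) {
  simulate_apms(simulation_config(
    n_baits = 2, conditions = c("0", "10"), n_preys = 60,
    true_edges_per_bait = 5, seed = seed, ...))
}
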