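test_that("NSAF normalizes length-scaled counts within each run", {
  runs <- data.frame(run_id = c("r1", "r2", "c1"),
                     bait = c("A", "B", ""), condition = "",
                     is_control = c(FALSE, FALSE, TRUE))
  counts <- data.frame(run_id = c("r1", "r2", "r2"),
                       prey_id = c("p1", "p1", "p2"),
                       sc = c(7, 10, 5))
  pt <- purification_table(runs, counts,
                           c(p1 = 100, p2 = 50))
  # single detected prey
  expect_equal(unname(nsaf(pt, "r1")), 1)
  # equal SAF symmetry: 10/100 == 5/50
  expect_equal(unname(nsaf(pt, "r2")), c(0.5, 0.5))
  expect_error(nsaf(pt, "r9"), "unknown run")
  expect_warning(v <- nsaf(pt, "c1"), "no detected preys")
  expect_length(v, 0)
})

test_that("NSAF matches a brute-force normalization oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 20
    preys <- sprintf("q%02d", 1:n)
    lens <- sample(80:900, n)
    sc <- rpois(n, 6) + 1
    runs <- data.frame(run_id = c("r1", "c1"), bait = c("A", ""),
                       condition = "", is_control = c(FALSE, TRUE))
    pt <- purification_table(
      runs, data.frame(run_id = "r1", prey_id = preys, sc = sc),
      stats::setNames(lens, preys))
    got <- nsaf(pt, "r1")
    expect_equal(unname(got[preys]), oracle_nsaf(sc, lens),
                 tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("replicate-averaged NSAF counts zeros for missed replicates", {
  pt <- toy_table()
  # pFULL shares G2 runs with pSTICKY: mean of per-replicate shares
  per_rep <- vapply(c(5, 6, 7), function(s)
    (s / 440) / (s / 440 + 2 / 500), numeric(1))
  expect_equal(nsaf_mean(pt, "G2", "pFULL"), mean(per_rep))
  # prey absent everywhere in the group
  expect_equal(nsaf_mean(pt, "G3", "pFULL"), 0)
  # detected in 1 of 3 replicates -> mean of (x, 0, 0)
  one_rep <- vapply(pt$bait_groups[["G1"]], function(r) {
    v <- suppressWarnings(nsaf(pt, r))
    if ("pWD" %in% names(v)) v[["pWD"]] else 0
  }, numeric(1))
  expect_equal(nsaf_mean(pt, "G1", "pWD"), mean(one_rep))
})

test_that("variance weight follows the CV branch convention", {
  pt <- toy_table()
  # constant across all groups and sd = 0 -> W = 1
  expect_equal(variance_weight(pt, "pSTICKY"), 1)
  # single-group prey: x = (s,0,0,0), population CV = sqrt(K-1)
  expect_equal(variance_weight(pt, "pFULL"), sqrt(3))
  # hand computation for x = (9, 0, 0, 0): mean SC of (9,18,0) is 9
  expect_equal(variance_weight(pt, "pWD"), sqrt(3))
  # branch condition: CV below threshold snaps to 1
  cfg <- suppressMessages(ppirank_config(w_threshold = 2))
  expect_equal(variance_weight(pt, "pFULL", cfg), 1)
  # sample-sd convention
  cfg_s <- ppirank_config(sd_type = "sample")
  x <- c(6, 0, 0, 0)   # pFULL group means
  expect_equal(variance_weight(pt, "pFULL", cfg_s),
               stats::sd(x) / mean(x))
})

test_that("Z score standardizes across purifications", {
  pt <- toy_table()
  expect_equal(compass_z(pt, "G1", "pSTICKY"), 0)  # sd = 0 convention
  # x = (s,0,0,0) queried at s: (s - s/4) / (s sqrt(3)/4) = sqrt(3)
  expect_equal(compass_z(pt, "G2", "pFULL"), sqrt(3))
  # standardization identity: Z over all groups sums to 0
  zs <- vapply(names(pt$bait_groups),
               function(g) compass_z(pt, g, "pFULL"), numeric(1))
  expect_equal(sum(zs), 0, tolerance = 1e-12)
})

test_that("weighted-D score matches hand evaluation", {
  pt <- toy_table()
  # undetected pair
  expect_equal(compass_wd(pt, "G3", "pFULL"), 0)
  # pWD in G1: s = 9, K = 4, sum_f = 1, N = 2, W = sqrt(3)
  expect_equal(compass_wd(pt, "G1", "pWD"),
               sqrt(9 * (4 * sqrt(3))^2))
  # with W forced to 1: sqrt(9 * 4^2) = 12
  cfg <- suppressMessages(ppirank_config(w_threshold = 2))
  expect_equal(compass_wd(pt, "G1", "pWD", cfg), 12)
  # prey in every group with W = 1: WD = sqrt(s) regardless of N
  expect_equal(compass_wd(pt, "G4", "pSTICKY"), sqrt(2))
})

test_that("frequency-reproducibility term follows W * (K/sum_f)^(N/T)", {
  pt <- toy_table()
  cfg1 <- suppressMessages(ppirank_config(w_threshold = 2))  # W = 1
  # unique prey, all T replicates: term = K
  ev <- collect_pair_evidence(pt, "G2", "pFULL")
  expect_equal(freq_repro_term(ev, pt, cfg1), 4)
  # detected in 2 of 3 replicates: K^(2/3)
  ev2 <- collect_pair_evidence(pt, "G1", "pRESCUE")
  expect_equal(freq_repro_term(ev2, pt, cfg1), 4^(2 / 3))
  # prey in every group: base 1, term = W
  ev3 <- collect_pair_evidence(pt, "G3", "pSTICKY")
  expect_equal(freq_repro_term(ev3, pt), 1)
  # undetected prey everywhere is a contract violation
  ev4 <- collect_pair_evidence(pt, "G1", "pCTL")
  expect_error(freq_repro_term(ev4, pt), "undetected")
  # alternative grouping: exponent applies to the W product too
  cfg_w <- ppirank_config(exponent_includes_w = TRUE)
  expect_equal(freq_repro_term(ev2, pt, cfg_w),
               (4 * sqrt(3))^(2 / 3))
})

test_that("composite score multiplies its stated components", {
  pt <- toy_table()
  ev <- collect_pair_evidence(pt, "G1", "pRESCUE")
  fdr <- fdr_for_pair(ev)
  got <- ppirank_score(ev, pt, fdr)
  expect_equal(got,
               nsaf_mean(pt, "G1", "pRESCUE") * (1 - fdr)^3 *
                 freq_repro_term(ev, pt))
  expect_gt(got, 0)
  # undetected pair scores 0
  ev0 <- collect_pair_evidence(pt, "G3", "pFULL")
  expect_equal(ppirank_score(ev0, pt, 0.5), 0)
  # FDR = 0 limit removes the penalty entirely
  expect_equal(ppirank_score(ev, pt, 0),
               nsaf_mean(pt, "G1", "pRESCUE") * freq_repro_term(ev, pt))
  expect_error(ppirank_score(ev, pt, 0.7), "fdr")
})

test_that("direct evaluation of the score formula on fixed components", {
  # NSAF 0.02, T = 3, FDR 0.1, W 1.2, K/sum_f = 2, R = 2/3
  expect_equal(0.02 * (1 - 0.1)^3 * 1.2 * 2^(2 / 3), 0.02777317,
               tolerance = 1e-6)
  expect_equal(term_from_parts(4, 2, 1.2, 2 / 3, ppirank_config()),
               1.2 * 2^(2 / 3))
})

test_that("batch scoring equals pair-by-pair recomputation", {
  pt <- toy_table()
  scores <- suppressWarnings(score_all(pt))
  expect_false("pCTL" %in% scores$prey_id)  # control-only: no row
  for (i in seq_len(nrow(scores))) {
    g <- scores$bait_group_id[i]; p <- scores$prey_id[i]
    ev <- collect_pair_evidence(pt, g, p)
    expect_equal(scores$nsaf[i], nsaf_mean(pt, g, p))
    expect_equal(scores$w[i], variance_weight(pt, p))
    expect_equal(scores$z[i], compass_z(pt, g, p))
    expect_equal(scores$wd[i], compass_wd(pt, g, p))
    expect_equal(scores$p_value[i],
                 ranksum_p(ev$sc_replicates, ev$sc_controls)$p_value)
    expect_equal(scores$fdr[i], fdr_for_pair(ev))
    expect_equal(scores$freq_term[i], freq_repro_term(ev, pt))
    expect_equal(scores$ppirank[i],
                 ppirank_score(ev, pt, scores$fdr[i]))
    expect_equal(scores$filtered[i], singleton_filter(ev))
  }
})

test_that("scoring is invariant to input row order and fully ranked", {
  pt <- toy_table()
  scores <- suppressWarnings(score_all(pt))
  set.seed(5)
  shuf <- pt
  shuf$counts <- shuf$counts[sample(nrow(shuf$counts)), ]
  pt2 <- purification_table(shuf$runs, shuf$counts, shuf$prey_lengths)
  scores2 <- suppressWarnings(score_all(pt2))
  expect_equal(scores, scores2)
  # ranks are a permutation of 1..n over unfiltered rows
  expect_setequal(scores$rank[!scores$filtered],
                  seq_len(sum(!scores$filtered)))
  expect_true(all(is.na(scores$rank[scores$filtered])))
  # higher score, smaller rank
  ok <- !scores$filtered
  ord <- order(scores$rank[ok])
  expect_true(all(diff(scores$ppirank[ok][ord]) <= 1e-12))
})

test_that("scoring requires controls and warns below three replicates", {
  runs <- data.frame(run_id = c("r1", "r2"), bait = "B", condition = "",
                     is_control = FALSE)
  counts <- data.frame(run_id = "r1", prey_id = "p1", sc = 5)
  pt <- purification_table(runs, counts, c(p1 = 100))
  expect_error(score_all(pt), "negative controls")

  runs <- rbind(runs, data.frame(run_id = "c1", bait = "",
                                 condition = "", is_control = TRUE))
  pt <- purification_table(runs, counts, c(p1 = 100))
  expect_warning(score_all(pt), "fewer than 3 replicates")
})

test_that("score responds monotonically to abundance, FDR and spread", {
  pt <- toy_table()
  base <- suppressWarnings(score_all(pt))
  # scaling one pair's SCs up cannot worsen its rank
  for (mult in c(2, 5)) {
    boosted <- pt$counts
    sel <- boosted$prey_id == "pRESCUE"
    boosted$sc[sel] <- boosted$sc[sel] * mult
    pt2 <- purification_table(pt$runs, boosted, pt$prey_lengths)
    after <- suppressWarnings(score_all(pt2))
    r0 <- base$rank[base$prey_id == "pRESCUE" & base$bait_group_id == "G1"]
    r1 <- after$rank[after$prey_id == "pRESCUE" &
                       after$bait_group_id == "G1"]
    expect_lte(r1, r0)
  }
  # strictly decreasing in FDR on (0, 0.5]
  ev <- collect_pair_evidence(pt, "G1", "pRESCUE")
  fdrs <- seq(0.01, 0.5, by = 0.01)
  ss <- vapply(fdrs, function(f) ppirank_score(ev, pt, f), numeric(1))
  expect_true(all(diff(ss) < 0))
  # spreading fixed total SC over more replicates never lowers the term
  set.seed(77)
  cfg1 <- suppressMessages(ppirank_config(w_threshold = 2))
  for (i in 1:20) {
    total <- sample(6:30, 1)
    spread2 <- c(ceiling(total / 2), floor(total / 2), 0)
    spread3 <- c(total - 2 * floor(total / 3), floor(total / 3),
                 floor(total / 3))
    mk <- function(sc) {
      cnt <- data.frame(run_id = pt$bait_groups[["G4"]],
                        prey_id = "pNEW", sc = sc)
      purification_table(pt$runs, rbind(pt$counts, cnt[cnt$sc > 0, ]),
                         c(pt$prey_lengths, pNEW = 300))
    }
    t1 <- mk(c(total, 0, 0)); t2 <- mk(spread2); t3 <- mk(spread3)
    f1 <- freq_repro_term(collect_pair_evidence(t1, "G4", "pNEW"), t1, cfg1)
    f2 <- freq_repro_term(collect_pair_evidence(t2, "G4", "pNEW"), t2, cfg1)
    f3 <- freq_repro_term(collect_pair_evidence(t3, "G4", "pNEW"), t3, cfg1)
    expect_lte(f1, f2 + 1e-12)
    expect_lte(f2, f3 + 1e-12)
  }
  # frequency penalty: larger sum_f never increases the term (W fixed)
  for (sum_f in 1:3)
    expect_gte(term_from_parts(4, sum_f, 1, 0.8, ppirank_config()),
               term_from_parts(4, sum_f + 1, 1, 0.8, ppirank_config()))
})

test_that("the ppirank() fit wraps scoring with methods", {
  sim <- small_sim()
  fit <- ppirank(sim$table)
  expect_s3_class(fit, "ppirank")
  expect_equal(fit$scores, score_all(sim$table), ignore_attr = TRUE)
  expect_output(print(fit), "PPIRank interaction scoring")
  expect_output(print(summary(fit)), "scored pairs")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  expect_silent(plot(fit, type = "fdr"))
})
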