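# Independent oracle: enrichment statistics by direct enumeration over the
# sorted list (no shared code with the implementation).
oracle_enrichment <- function(score, label, direction = "lower_better") {
  g <- if (direction == "lower_better") -score else score
  ord <- order(-g, label == "active")   # decoys first on ties
  lab <- label[ord]
  n_dec <- sum(label == "decoy")
  betas <- numeric(0)
  auc_pairs <- 0
  for (i in which(lab == "active"))
    betas <- c(betas, sum(lab[seq_len(i - 1)] == "decoy") / n_dec)
  for (a in which(label == "active")) for (d in which(label == "decoy"))
    auc_pairs <- auc_pairs + (g[a] > g[d]) + 0.5 * (g[a] == g[d])
  list(proc = mean(log10(1 / pmax(betas, 1 / n_dec))),
       roc = auc_pairs / (sum(label == "active") * n_dec))
}

test_that("enrichment matches hand-enumerated screens", {
  # actives at ranks 1 and 3 of four (lower scores better)
  d <- labeled_scores(paste0("l", 1:4), c(-4, -3, -2, -1),
                      c("active", "decoy", "active", "decoy"))
  e <- proc_auc(d)
  expect_equal(e$proc_auc, log10(2))          # betas (clip 0 -> 1/2, 1/2)
  expect_equal(e$betas, c(0.5, 0.5))
  expect_equal(e$n_clipped, 1L)
  expect_equal(e$roc_auc, 0.75)
  expect_equal(e$n, 4L)

  # single active ranked dead last: beta = 1, log term vanishes
  worst <- labeled_scores(paste0("l", 1:4), c(-4, -3, -2, -1),
                          c("decoy", "decoy", "decoy", "active"))
  expect_equal(proc_auc(worst)$proc_auc, 0)

  # perfect separation
  best <- labeled_scores(paste0("l", 1:4), c(-4, -3, -2, -1),
                         c("active", "active", "decoy", "decoy"))
  expect_equal(roc_auc(best), 1.0)
  expect_equal(proc_auc(best)$proc_auc, log10(2))  # both actives clipped

  # all 4-ligand label arrangements against the oracle
  for (pos in utils::combn(4, 2, simplify = FALSE)) {
    label <- rep("decoy", 4); label[pos] <- "active"
    d4 <- labeled_scores(paste0("l", 1:4), c(-4, -3, -2, -1), label)
    o <- oracle_enrichment(c(-4, -3, -2, -1), label)
    expect_equal(proc_auc(d4)$proc_auc, o$proc)
    expect_equal(roc_auc(d4), o$roc)
  }

  expect_error(proc_auc(labeled_scores("a", 1, "active")), "decoy")
  expect_error(proc_auc(labeled_scores("a", 1, "decoy")), "active")
})

test_that("classical ROC AUC agrees with the pROC package", {
  set.seed(99)
  for (i in 1:5) {
    score <- c(rnorm(15, -6.5), rnorm(60, -6))   # mildly enriched actives
    label <- rep(c("active", "decoy"), c(15, 60))
    d <- labeled_scores(paste0("l", 1:75), score, label)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = label, predictor = score, levels = c("decoy", "active"),
      direction = ">", quiet = TRUE)))
    expect_equal(roc_auc(d), ref)
  }
})

test_that("score ties rank decoys first (conservative enrichment)", {
  d <- labeled_scores(paste0("l", 1:3), c(-5, -5, -1),
                      c("active", "decoy", "decoy"))
  # the tied decoy counts as recovered before the active: beta = 1/2
  expect_equal(proc_auc(d)$betas, 0.5)
  expect_equal(proc_auc(d)$proc_auc, log10(2))
  expect_equal(roc_auc(d), 0.75)   # half credit for the tie
})

test_that("enrichment is a rank statistic and direction-consistent", {
  set.seed(5)
  for (i in 1:10) {
    score <- rnorm(60)
    label <- rep(c("active", "decoy"), c(10, 50))
    d <- labeled_scores(paste0("l", 1:60), score, label)
    # strictly monotone transform leaves both AUCs unchanged
    d2 <- labeled_scores(paste0("l", 1:60), -exp(-score) * 3 - 1, label)
    expect_equal(proc_auc(d2)$proc_auc, proc_auc(d)$proc_auc)
    expect_equal(roc_auc(d2), roc_auc(d))
    # negating scores and flipping the direction flag changes nothing
    d3 <- labeled_scores(paste0("l", 1:60), -score, label,
                         direction = "higher_better")
    expect_equal(proc_auc(d3)$proc_auc, proc_auc(d)$proc_auc)
    expect_equal(roc_auc(d3), roc_auc(d))
    # bounds: 0 <= pROC <= log10(n_decoys)
    expect_gte(proc_auc(d)$proc_auc, 0)
    expect_lte(proc_auc(d)$proc_auc, log10(50))
  }
})

test_that("rank correlations reproduce their textbook forms", {
  # d = (0, 1, -1, 0): rho = 1 - 6*2/(4*15) = 0.8
  s <- spearman_rho(paired_measurements(1:4, c(1, 3, 2, 4)))
  expect_equal(s$rho, 0.8)
  expect_equal(s$d, c(0, -1, 1, 0))
  k <- kendall_tau_b(paired_measurements(1:4, c(1, 3, 2, 4)))
  expect_equal(k$C, 5L); expect_equal(k$D, 1L)
  expect_equal(k$T_dock + k$T_exp + k$T_both, 0L)
  expect_equal(k$tau_b, 4 / 6)

  # perfectly monotonic: +1; reversed: -1
  pm <- paired_measurements(1:10, (1:10)^3)
  expect_equal(spearman_rho(pm)$rho, 1)
  expect_equal(kendall_tau_b(pm)$tau_b, 1)
  rev <- paired_measurements(1:10, -(1:10)^3)
  expect_equal(spearman_rho(rev)$rho, -1)
  expect_equal(kendall_tau_b(rev)$tau_b, -1)

  # a constant side leaves both undefined, not an error
  flat <- paired_measurements(1:5, rep(2, 5))
  expect_true(spearman_rho(flat)$undefined)
  expect_true(kendall_tau_b(flat)$undefined)
  expect_true(is.na(kendall_tau_b(flat)$tau_b))
})

test_that("correlations agree with stats::cor and count all pairs", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    x <- sample(1:10, n, replace = TRUE)   # plenty of ties
    y <- sample(1:10, n, replace = TRUE)
    pm <- paired_measurements(x, y)
    k <- kendall_tau_b(pm)
    expect_equal(k$C + k$D + k$T_dock + k$T_exp + k$T_both,
                 n * (n - 1) / 2)
    if (!k$undefined)
      expect_equal(k$tau_b, cor(x, y, method = "kendall"))
    s <- spearman_rho(pm)
    if (!s$undefined)
      expect_equal(s$rho, cor(x, y, method = "spearman"))
    # tie-free data: fractional-rank rho equals the rank-difference form
    xt <- sample(n); yt <- sample(n)
    st <- spearman_rho(paired_measurements(xt, yt))
    d <- rank(xt) - rank(yt)
    expect_equal(st$rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }
})

test_that("direction flags orient correlations, not just signs", {
  # lower_better docking scores that perfectly track potency
  dock <- -(1:8); pot <- 1:8
  pm <- paired_measurements(dock, pot, dock_direction = "lower_better")
  expect_equal(spearman_rho(pm)$rho, 1)
  expect_equal(kendall_tau_b(pm)$tau_b, 1)
})

test_that("thresholds mode classifies quadrants with boundary-as-active", {
  pm <- paired_measurements(c(-5, -5, -1, -1), c(9, 1, 9, 1),
                            dock_direction = "lower_better")
  t <- thresholds_report(pm, -3, 5)
  expect_equal(unname(t$counts), c(1L, 1L, 1L, 1L))
  expect_equal(sum(t$counts), pm$n)
  # all better than both thresholds: one quadrant holds n
  t2 <- thresholds_report(paired_measurements(c(-9, -8), c(7, 8),
                                              dock_direction = "lower_better"),
                          -3, 5)
  expect_equal(unname(t2$counts["TP"]), 2L)
  expect_equal(sum(t2$counts), 2L)
  # points exactly at the experimental threshold (censored LOQ values)
  # fall on the active side
  t3 <- thresholds_report(paired_measurements(c(-9, -1), c(5, 5),
                                              dock_direction = "lower_better"),
                          -3, 5)
  expect_equal(unname(t3$counts["TP"]), 1L)
  expect_equal(unname(t3$counts["FN"]), 1L)
  expect_error(thresholds_report(pm, NA, 5), "finite")
})
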