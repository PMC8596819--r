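test_that("transforms map onto [0,1] with the stated shapes", {
  for (kind in c("sigmoid", "reverse_sigmoid")) {
    ts <- transform_spec(kind, -12, -4, k = 10)
    expect_equal(apply_transform(-8, ts), 0.5)   # anchor midpoint
  }
  rs <- transform_spec("reverse_sigmoid", -12, -4, k = 10)
  x <- seq(-14, -2, by = 0.25)
  expect_true(all(diff(apply_transform(x, rs)) < 0))    # decreasing
  sg <- transform_spec("sigmoid", -12, -4, k = 10)
  expect_true(all(diff(apply_transform(x, sg)) > 0))    # increasing
  expect_true(all(apply_transform(x, rs) >= 0 & apply_transform(x, rs) <= 1))

  # numerically solve for the steepness putting >= 0.99 / <= 0.01 at the
  # anchors, then verify
  f <- function(k) 1 / (1 + exp(k * (-12 - (-8)) / 8)) - 0.99
  k99 <- uniroot(f, c(0.1, 100))$root
  rs2 <- transform_spec("reverse_sigmoid", -12, -4, k = k99 + 1e-6)
  expect_gte(apply_transform(-12, rs2), 0.99)
  expect_lte(apply_transform(-4, rs2), 0.01)

  lc <- transform_spec("linear_clip", 0, 10)
  expect_equal(apply_transform(c(-5, 0, 2.5, 10, 20), lc),
               c(0, 0, 0.25, 1, 1))
  st <- transform_spec("step", 0, 10)
  expect_equal(apply_transform(c(-1, 0, 5, 10, 11), st), c(0, 1, 1, 1, 0))

  # failed-docking sentinel
  expect_equal(apply_transform(c(NA, Inf, NaN), rs), c(0, 0, 0))
  expect_error(transform_spec("sigmoid", 5, 5), "low < high")
  expect_error(transform_spec("sigmoid", 0, 1, k = 0), "steepness")
})

test_that("the weighted geometric mean behaves per its identities", {
  # direct evaluation: P = (0.5, 0.8), w = (1, 2)
  r <- total_score(list(const_component("a", 0.5),
                        const_component("b", 0.8, weight = 2)), "CCO")
  expect_equal(r$total, (0.5 * 0.8^2)^(1 / 3))

  # all components at 1 -> 1; any at 0 annihilates
  expect_equal(total_score(list(const_component("a", 1),
                                const_component("b", 1)), "CCO")$total, 1)
  expect_equal(total_score(list(const_component("a", 0),
                                const_component("b", 0.9)), "CCO")$total, 0)

  # invalid molecule scores 0 with a reason
  bad <- total_score(list(const_component("a", 0.9)), "not-a-molecule")
  expect_equal(bad$total, 0)
  expect_match(bad$reason, "invalid")

  set.seed(21)
  for (i in 1:25) {
    m <- sample(2:5, 1)
    p <- runif(m); w <- runif(m, 0.2, 5)
    comps <- lapply(seq_len(m), function(j)
      const_component(paste0("c", j), p[j], weight = w[j]))
    s <- total_score(comps, "CCO")$total
    expect_gte(s, 0); expect_lte(s, 1)
    # weight-scale invariance: multiplying all weights by c changes nothing
    comps2 <- lapply(seq_len(m), function(j)
      const_component(paste0("c", j), p[j], weight = 3.7 * w[j]))
    expect_equal(total_score(comps2, "CCO")$total, s)
    # equal weights reduce to the plain geometric mean
    comps3 <- lapply(seq_len(m), function(j)
      const_component(paste0("c", j), p[j]))
    expect_equal(total_score(comps3, "CCO")$total, prod(p)^(1 / m))
    # raising one component strictly raises the total
    p2 <- p; p2[1] <- min(1, p2[1] + 0.1)
    comps4 <- lapply(seq_len(m), function(j)
      const_component(paste0("c", j), p2[j], weight = w[j]))
    expect_gt(total_score(comps4, "CCO")$total, s - 1e-12)
  }
})

test_that("builtin descriptor and docking providers feed the objective", {
  rec <- fixture_receptor()
  comps <- list(
    component_spec("mw", "mw", transform_spec("sigmoid", 200, 575)),
    component_spec("hbd", "hbd", transform_spec("reverse_sigmoid", 0, 7)),
    component_spec("dock", list(type = "docking", receptor = rec),
                   transform_spec("reverse_sigmoid", -7, -1)))
  r <- total_score(comps, "CC(=O)Nc1ccc(O)cc1")
  expect_s3_class(r, "mpo_result")
  expect_equal(nrow(r$components), 3L)
  expect_true(all(is.finite(r$components$raw)))
  expect_identical(r$components$raw[3],
                   synthetic_score("CC(=O)Nc1ccc(O)cc1", rec))
  # batch scoring agrees with per-molecule scoring
  batch <- score_batch(comps, c("CC(=O)Nc1ccc(O)cc1", "CCO", "zz-bad"))
  expect_equal(batch[[1]]$total, r$total)
  expect_equal(batch[[3]]$total, 0)
  expect_error(component_spec("x", "nope", transform_spec("sigmoid", 0, 1)),
               "provider")
})
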