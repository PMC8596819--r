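test_that("synthetic screens are reproducible and plant the stated shift", {
  spec <- synthetic_screen_spec(delta = 2, seed = 19)
  s1 <- generate_screen(spec)
  s2 <- generate_screen(spec)
  expect_identical(s1$score, s2$score)
  expect_equal(s1$n, 1240L)
  expect_equal(sum(s1$label == "active"), 40L)
  expect_equal(sum(s1$label == "decoy"), 1200L)

  # empirical active-decoy mean gap ~ delta within 3 standard errors
  gaps <- vapply(1:30, function(i) {
    s <- generate_screen(synthetic_screen_spec(delta = 2, seed = 1000 + i))
    mean(s$score[s$label == "decoy"]) - mean(s$score[s$label == "active"])
  }, 1)
  se <- sqrt(1 / 40 + 1 / 1200)            # sd of a single-replicate gap
  expect_lt(abs(mean(gaps) - 2), 3 * se / sqrt(30))

  # direction-aware: higher_better shifts actives up
  sh <- generate_screen(synthetic_screen_spec(delta = 3, seed = 2,
                                              direction = "higher_better"))
  expect_gt(mean(sh$score[sh$label == "active"]),
            mean(sh$score[sh$label == "decoy"]))
  expect_error(synthetic_screen_spec(delta = 1), "seed")
})

test_that("planted enrichment grows with the shift", {
  mean_proc <- vapply(c(0, 1, 2, 4), function(delta) {
    mean(vapply(1:12, function(i)
      proc_auc(generate_screen(synthetic_screen_spec(
        delta = delta, seed = 5000 + 31 * i + round(100 * delta))))$proc_auc,
      1))
  }, 1)
  expect_true(all(diff(mean_proc) > 0))
  expect_lt(abs(mean_proc[1] - 0.434), 0.08)    # delta = 0 is random
  # heavy-tailed baseline still yields a valid screen
  hv <- generate_screen(synthetic_screen_spec(delta = 0, seed = 3,
                                              baseline = "heavy"))
  expect_true(all(is.finite(hv$score)))
})

test_that("the toy library is valid, mostly unique and deterministic", {
  lib <- generate_toy_library(100, 42)
  expect_length(lib, 100L)
  expect_identical(lib, generate_toy_library(100, 42))
  expect_false(identical(lib, generate_toy_library(100, 43)))
  can <- canonical_smiles(lib)
  expect_false(anyNA(can))                      # all parseable
  expect_gte(length(unique(can)), 95L)
  expect_error(generate_toy_library(0, 1), "positive")
  expect_error(generate_toy_library(1e6, 1), "grammar")
})

test_that("toy molecules survive enumeration and embedding end to end", {
  lib <- generate_toy_library(5, 7)
  for (i in seq_along(lib)) {
    l <- embed_3d(enumerate_states(ligand(paste0("t", i), lib[i])),
                  embedder_spec(max_iterations = 20))
    expect_false(l$failed)
    expect_gte(length(l$enumerations), 1L)
    for (e in l$enumerations) {
      expect_false(e$failed)
      at <- screendock:::molblock_atoms(e$molblock)
      expect_true(all(is.finite(c(at$x, at$y, at$z))))
    }
  }
})
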