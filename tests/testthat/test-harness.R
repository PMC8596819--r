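simple_components <- function(receptor = fixture_receptor()) {
  list(
    component_spec("dock", list(type = "docking", receptor = receptor),
                   transform_spec("reverse_sigmoid", -5, -1, k = 6)),
    component_spec("mw", "mw", transform_spec("step", 100, 600)))
}

test_that("a constant proposer saturates its bucket and plateaus", {
  comps <- simple_components()
  store <- scaffold_bucket_store(capacity = 3, min_score = 0.1)
  proposer <- function(epoch, batch_size, state, feedback)
    list(smiles = rep("c1ccccc1CCN", batch_size), state = NULL)
  out <- rl_step_harness(proposer, comps, store, epochs = 4, batch_size = 4,
                         score_threshold = 0.1)
  rec <- out$records
  expect_equal(nrow(rec), 4L)
  # unique-compound curve is flat after epoch 1 and nondecreasing
  expect_equal(rec$n_unique_cumulative, rep(rec$n_unique_cumulative[1], 4))
  expect_true(all(diff(rec$n_unique_cumulative) >= 0))
  # the single bucket holds one entry (duplicates never stored)
  expect_equal(sum(vapply(out$store$buckets, nrow, 1L)), 1L)
  # accounting: batch_size * epochs proposals consumed
  expect_equal(sum(rec$n_proposed), 4L * 4L)
})

test_that("hill climbing improves the mean docking score over epochs", {
  lib <- generate_toy_library(40, 23)
  comps <- simple_components()
  out <- rl_step_harness(hill_climb_proposer(lib, seed = 5),
                         comps, scaffold_bucket_store(capacity = 25),
                         epochs = 6, batch_size = 16)
  rec <- out$records
  expect_equal(nrow(rec), 6L)
  expect_lt(rec$mean_raw_docking[6], rec$mean_raw_docking[1])
  expect_true(all(diff(rec$n_unique_cumulative) >= 0))
  expect_true(all(rec$mean_total >= 0 & rec$mean_total <= 1))
  # determinism end to end
  out2 <- rl_step_harness(hill_climb_proposer(lib, seed = 5),
                          comps, scaffold_bucket_store(capacity = 25),
                          epochs = 6, batch_size = 16)
  expect_equal(rec, out2$records)
  # top table is deduplicated and sorted by total
  expect_false(any(duplicated(out$top$smiles)))
  expect_true(all(diff(out$top$total) <= 1e-12))
})

test_that("proposer exhaustion stops the loop cleanly", {
  comps <- list(const_component("a", 0.9))
  proposer <- function(epoch, batch_size, state, feedback) {
    if (epoch > 2) return(list(smiles = character(0), state = state))
    list(smiles = rep("CCO", batch_size), state = state)
  }
  out <- rl_step_harness(proposer, comps, scaffold_bucket_store(),
                         epochs = 10, batch_size = 3)
  expect_equal(nrow(out$records), 2L)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "epochs.csv")
  write_epoch_records(out, p)
  expect_equal(nrow(read.csv(p)), 2L)
})
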