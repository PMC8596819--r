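test_that("generic scaffolds are heteroatom- and decoration-insensitive", {
  expect_identical(generic_scaffold("c1ccccc1"),
                   generic_scaffold("c1ccncc1"))     # benzene == pyridine
  expect_identical(generic_scaffold("Cc1ccccc1"),
                   generic_scaffold("Oc1ccccc1"))    # toluene == phenol
  expect_identical(generic_scaffold("c1ccccc1"),
                   generic_scaffold("C1CCCCC1"))     # saturation erased
  expect_identical(generic_scaffold("CC"), "acyclic")
  expect_identical(generic_scaffold("CC(=O)NC"), "acyclic")
  # linkers survive generification
  expect_identical(generic_scaffold("c1ccccc1CCc1ccncc1"),
                   generic_scaffold("C1CCCCC1CCC1CCOCC1"))
  # but decorations do not
  expect_identical(generic_scaffold("c1ccccc1CCc1ccncc1"),
                   generic_scaffold("Fc1ccc(cc1)CCc1ccncc1C(F)(F)F"))
  expect_error(generic_scaffold("zz-bad"), "invalid")
})

test_that("bucket saturation penalizes exactly the overflow compounds", {
  store <- scaffold_bucket_store(capacity = 25, min_score = 0.4)
  same_scaffold <- paste0("c1ccccc1",
                          vapply(1:30, function(i)
                            paste(rep("C", i), collapse = ""), ""))
  penalized <- logical(30); scores <- numeric(30)
  for (i in 1:30) {
    res <- diversity_penalty(same_scaffold[i], 0.9, store)
    store <- res$store
    penalized[i] <- res$penalized
    scores[i] <- res$score
  }
  expect_identical(which(penalized), 26:30)
  expect_equal(scores[1:25], rep(0.9, 25))
  expect_equal(scores[26:30], rep(0, 5))
  expect_equal(nrow(store$buckets[[generic_scaffold("c1ccccc1C")]]), 25L)
})

test_that("filter rules: duplicates, sub-threshold scores, new scaffolds", {
  store <- scaffold_bucket_store(capacity = 3, min_score = 0.4)
  # first compound of a new scaffold: stored, unpenalized
  r1 <- diversity_penalty("Cc1ccccc1", 0.8, store); store <- r1$store
  expect_false(r1$penalized); expect_equal(r1$score, 0.8)
  # exact duplicate: always penalized
  r2 <- diversity_penalty("Cc1ccccc1", 0.95, store); store <- r2$store
  expect_true(r2$penalized); expect_equal(r2$score, 0)
  # below minimum score: unchanged and not stored
  r3 <- diversity_penalty("CCc1ccccc1", 0.2, store); store <- r3$store
  expect_false(r3$penalized); expect_equal(r3$score, 0.2)
  expect_equal(sum(vapply(store$buckets, nrow, 1L)), 1L)
  # a different scaffold opens a fresh bucket
  r4 <- diversity_penalty("C1CCNCC1C1CCNCC1", 0.7, store); store <- r4$store
  expect_false(r4$penalized)
  expect_equal(length(store$buckets), 2L)
})

test_that("occupancy is bounded and penalization is monotone", {
  set.seed(31)
  store <- scaffold_bucket_store(capacity = 4, min_score = 0.3)
  lib <- generate_toy_library(60, 17)
  ever_penalized_full <- character(0)
  for (s in lib) {
    res <- diversity_penalty(s, round(runif(1), 2), store)
    occ <- vapply(res$store$buckets, nrow, 1L)
    expect_true(all(occ <= 4L))
    if (res$penalized && res$score == 0 &&
        !is.null(res$store$buckets[[res$key]]) &&
        nrow(res$store$buckets[[res$key]]) >= 4L)
      ever_penalized_full <- union(ever_penalized_full, res$key)
    # once a bucket is full, every later passing compound of that scaffold
    # is penalized
    if (res$key %in% ever_penalized_full && !res$penalized)
      expect_lt(res$score, store$min_score)
    store <- res$store
  }
})
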