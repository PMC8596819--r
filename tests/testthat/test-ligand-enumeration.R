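test_that("state enumeration covers stereo space deterministically", {
  # no stereocentres, single tautomer: exactly one state
  l <- enumerate_states(ligand("e", "CCO"))
  expect_length(l$enumerations, 1L)
  expect_identical(l$enumerations[[1]]$smiles, "CCO")
  expect_identical(l$enumerations[[1]]$index, 0L)

  # two unspecified stereocentres -> 2^2 states, contiguous 0-based indices,
  # lexicographic order
  l2 <- enumerate_states(ligand("x", "OC(C)C(N)CC"))
  smi <- vapply(l2$enumerations, `[[`, "", "smiles")
  expect_length(smi, 4L)
  expect_identical(smi, sort(smi))
  expect_identical(vapply(l2$enumerations, `[[`, 0L, "index"), 0:3)
  expect_length(unique(smi), 4L)

  # fully specified input: one state, stereo untouched
  l3 <- enumerate_states(ligand("y", "C[C@H](N)C(=O)O"))
  expect_length(l3$enumerations, 1L)
  expect_identical(l3$enumerations[[1]]$smiles,
                   canonical_smiles("C[C@H](N)C(=O)O"))

  # partially specified: only the unspecified centre expands
  l4 <- enumerate_states(ligand("z", "O[C@H](C)C(N)CC"))
  expect_length(l4$enumerations, 2L)
  expect_true(all(grepl("@", vapply(l4$enumerations, `[[`, "", "smiles"))))

  # determinism across calls
  l2b <- enumerate_states(ligand("x", "OC(C)C(N)CC"))
  expect_identical(smi, vapply(l2b$enumerations, `[[`, "", "smiles"))
})

test_that("enumeration is idempotent and honours max_states", {
  l <- enumerate_states(ligand("x", "OC(C)C(N)CC"))
  states <- vapply(l$enumerations, `[[`, "", "smiles")
  again <- sort(unique(unlist(lapply(states, function(s)
    vapply(enumerate_states(ligand("r", s))$enumerations, `[[`, "",
           "smiles")))))
  expect_identical(again, sort(states))

  # min(2^k, max_states) property on stereo-only molecules
  cases <- list(c("CC(O)CC", 1L), c("CC(O)C(N)CC", 2L),
                c("CC(O)C(N)C(F)CC", 3L))
  for (cs in cases) {
    k <- as.integer(cs[2])
    for (cap in c(1L, 2L, 32L)) {
      li <- enumerate_states(ligand("m", cs[1]), max_states = cap)
      expect_length(li$enumerations, min(2^k, cap))
    }
  }
  lc <- enumerate_states(ligand("m", "CC(O)C(O)C(O)C(O)C(O)C(O)CO"),
                         max_states = 8)
  expect_length(lc$enumerations, 8L)
  expect_true(lc$truncated)
})

test_that("tautomer rules expand keto-enol sites but respect ring guard", {
  lt <- enumerate_states(ligand("t", "CC(=O)C"), enumerate_stereo = FALSE,
                         enumerate_tautomers = TRUE)
  smi <- vapply(lt$enumerations, `[[`, "", "smiles")
  expect_setequal(smi, c("CC(=O)C", "CC(=C)O"))
  # phenol's "enol" is aromatic/ring: not touched
  lp <- enumerate_states(ligand("p", "c1ccccc1O"), enumerate_stereo = FALSE,
                         enumerate_tautomers = TRUE)
  expect_length(lp$enumerations, 1L)
  # enol input finds the keto form back (rule closure is symmetric)
  le <- enumerate_states(ligand("v", "CC(=C)O"), enumerate_stereo = FALSE,
                         enumerate_tautomers = TRUE)
  expect_setequal(vapply(le$enumerations, `[[`, "", "smiles"),
                  c("CC(=O)C", "CC(=C)O"))
})

test_that("unparsable input becomes a flagged ligand, not an error", {
  lb <- ligand("bad", "totally not smiles")
  expect_true(lb$failed)
  expect_match(lb$fail_reason, "unparsable")
  expect_identical(enumerate_states(lb)$enumerations, list())
  expect_error(ligand_set(list(ligand("a", "CCO"), ligand("a", "CCN"))),
               "duplicate")
})
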