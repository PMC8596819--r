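test_that("the synthetic backend is a deterministic pure function", {
  rec <- fixture_receptor()
  enums <- screendock:::all_enumerations(fixture_ligands())
  s1 <- synthetic_dock(enums[[1]], rec)
  s2 <- synthetic_dock(enums[[1]], rec)
  expect_identical(s1$poses$score, s2$poses$score)
  expect_equal(nrow(s1$poses), 1L)

  # a ligand sitting exactly on the receptor target reaches the receptor's
  # minimal achievable score -sum(weights)
  probe <- "c1ccc2ccccc2c1CCNC(=O)c1ccncc1O"  # any valid molecule
  d <- mol_descriptors(probe)
  rec2 <- receptor_profile("ideal", synthetic = list(
    target = c(n_heavy = d$n_heavy, n_rings = d$n_rings, hbd = d$hbd,
               hba = d$hba, mw = d$mw, logp = d$logp, tpsa = d$tpsa)))
  expect_equal(synthetic_score(probe, rec2), -7)
  # and every other molecule scores worse (less negative)
  others <- generate_toy_library(10, 77)
  expect_true(all(synthetic_score(others, rec2) > -7))
})

test_that("synthetic scores degrade monotonically with descriptor distance", {
  # ladder of molecules at increasing heavy-atom distance from the target
  ladder <- c("CCCCCC", "CCCCCCCC", "CCCCCCCCCC", "CCCCCCCCCCCC")
  rec <- receptor_profile("ladder", synthetic = list(
    target = c(n_heavy = 6), scales = 5))
  sc <- synthetic_score(ladder, rec)
  expect_true(all(diff(sc) > 0))   # worse (less negative) as distance grows
})

test_that("dock_batch conserves enumerations and is schedule-invariant", {
  rec <- fixture_receptor()
  ligs <- fixture_ligands()
  enums <- screendock:::all_enumerations(ligs)
  r1 <- dock_batch(enums, rec, cores = 1)
  expect_equal(nrow(r1$poses) + nrow(r1$failures), length(enums))
  r4 <- dock_batch(enums, rec, cores = 4, max_per_core = 2)
  expect_identical(r1$poses, r4$poses)
  expect_identical(r1$failures, r4$failures)
  rrev <- dock_batch(rev(enums), rec)
  expect_identical(r1$poses, rrev$poses)

  # a coordinate-less enumeration becomes a failure, not an error
  en2 <- c(enums, list(enumeration("zz_noco", 0L, "CCOC")))
  r2 <- dock_batch(en2, rec)
  expect_equal(nrow(r2$poses), nrow(r1$poses))
  expect_true("zz_noco" %in% r2$failures$ligand_id)
  expect_match(r2$failures$reason[r2$failures$ligand_id == "zz_noco"],
               "coordinates")
  expect_equal(nrow(r2$poses) + nrow(r2$failures), length(en2))

  expect_error(dock_batch(enums, rec, backend = "nosuch"), "unknown")
  empty <- dock_batch(list(), rec)
  expect_equal(nrow(empty$poses), 0L)
  expect_equal(nrow(empty$failures), 0L)
})

test_that("write-out modes reduce the report per their contracts", {
  rec <- fixture_receptor()
  enums <- screendock:::all_enumerations(fixture_ligands())
  rep3 <- dock_batch(enums, rec, params = list(poses = 3))
  t_all <- collate_writeout(rep3, "all")
  t_enu <- collate_writeout(rep3, "best_per_enumeration")
  t_lig <- collate_writeout(rep3, "best_per_ligand")
  expect_equal(nrow(t_all), 3L * length(enums))
  expect_equal(nrow(t_enu), length(enums))
  expect_equal(nrow(t_lig), length(unique(vapply(enums, `[[`, "",
                                                 "ligand_id"))))
  key <- function(t) paste(t$ligand_id, t$enumeration_index, t$pose_index)
  expect_true(all(key(t_lig) %in% key(t_enu)))
  expect_true(all(key(t_enu) %in% key(t_all)))
  # per ligand, best_per_ligand keeps that ligand's minimum (lower_better)
  mins <- tapply(t_all$score, t_all$ligand_id, min)
  expect_equal(as.vector(mins[t_lig$ligand_id]), t_lig$score)
  expect_error(collate_writeout(rep3, "bestest"), "unknown")
})

test_that("best-selection honours score direction and tie-breaks stably", {
  mk_report <- function(direction) {
    structure(list(
      poses = data.frame(
        ligand_id = rep("L1", 4),
        enumeration_index = c(0L, 0L, 1L, 1L),
        pose_index = c(0L, 1L, 0L, 1L),
        score = c(-9.0, -7.5, -9.0, -6.0)),
      pose_blocks = vector("list", 4),
      failures = data.frame(ligand_id = character(0),
                            enumeration_index = integer(0),
                            reason = character(0)),
      backend = "mock", direction = direction, receptor_id = "r"),
      class = "docking_report")
  }
  lo <- collate_writeout(mk_report("lower_better"), "best_per_ligand")
  expect_equal(lo$score, -9.0)
  # tie at -9.0: enumeration 0 wins (ascending tie-break)
  expect_equal(lo$enumeration_index, 0L)
  hi <- collate_writeout(mk_report("higher_better"), "best_per_ligand")
  expect_equal(hi$score, -6.0)  # maximum kept for fitness-style scores
  expect_equal(hi$enumeration_index, 1L)
})

test_that("external engine stubs are registered but refuse to run", {
  expect_true(all(c("vina", "glide", "gold", "hybrid", "rdock", "synthetic")
                  %in% list_backends()))
  expect_identical(get_backend("gold")$score_direction, "higher_better")
  expect_identical(get_backend("vina")$score_direction, "lower_better")
  rec <- fixture_receptor()
  enums <- screendock:::all_enumerations(fixture_ligands())[1]
  expect_error(dock_batch(enums, rec, backend = "glide"), "not enabled")
})

test_that("poses SDF write-out stores scores as tags", {
  dir <- withr::local_tempdir()
  rec <- fixture_receptor()
  enums <- screendock:::all_enumerations(fixture_ligands())
  rep1 <- dock_batch(enums, rec)
  p <- file.path(dir, "poses.sdf")
  n <- write_poses_sdf(rep1, p)
  expect_gt(n, 0)
  txt <- readLines(p)
  expect_equal(sum(txt == "$$$$"), n)
  expect_true(any(grepl("^>  <score>", txt)))
})
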