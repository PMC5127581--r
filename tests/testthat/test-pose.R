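q_can <- canonical_query()

# an active whose features sit exactly on the query centers, in the site frame
make_site_frame_active <- function() {
  mol <- generate_feature_library(1, 1, 0, seed = 17)[[1]]
  match <- match_conformer(perceive_features(mol, 1), q_can, mol$id, 1L)
  pose <- place_by_match(mol, match)
  m <- pose_molecule(pose)        # conformer now in the site frame
  m
}

test_that("identity matches leave coordinates unchanged and inverse transforms undo", {
  mol <- make_site_frame_active()
  match <- match_conformer(perceive_features(mol, 1), q_can, mol$id, 1L)
  pose <- place_by_match(mol, match)
  expect_lt(max(abs(pose$xyz - get_conformer(mol))), 1e-6)
  expect_true(pose$fulfills_query)

  shifted <- mol
  shifted$conformers <- list(get_conformer(mol) + rep(c(3, -7, 1), each = 1))
  shifted$conformers <- list(sweep(get_conformer(mol), 2, c(3, -7, 1), "+"))
  match2 <- match_conformer(perceive_features(shifted, 1), q_can,
                            shifted$id, 1L)
  pose2 <- place_by_match(shifted, match2)
  expect_lt(max(abs(pose2$xyz - get_conformer(mol))), 1e-6)

  other <- mol; other$id <- "someone_else"
  expect_error(place_by_match(other, match2), "not")
})

test_that("clash counting follows the distance definition", {
  # two-atom probe ligand with exactly known geometry
  mol <- molecule("probe", c("C", "C"),
                  data.frame(a1 = 1, a2 = 2, order = 1),
                  list(rbind(c(0, 0, 0), c(10, 0, 0))))
  pose <- structure(list(mol_id = "probe", conformer_index = 1L,
                         xyz = get_conformer(mol), molecule = mol,
                         clash_count = NA_integer_,
                         fulfills_query = TRUE), class = "pose")
  far <- receptor_cloud(matrix(c(500, 500, 500), 1, 3))
  expect_equal(clash_filter(pose, far)$clash_count, 0L)
  near <- receptor_cloud(matrix(c(1.5, 0, 0), 1, 3))
  expect_equal(clash_filter(pose, near)$clash_count, 1L)
  expect_equal(clash_filter(pose, near, clash_distance = 1.0)$clash_count, 0L)
  both <- receptor_cloud(rbind(c(1.5, 0, 0), c(9, 0, 0)))
  expect_equal(clash_filter(pose, both)$clash_count, 2L)
})

test_that("pose score follows its contact/polar/clash formula", {
  mol <- make_site_frame_active()
  match <- match_conformer(perceive_features(mol, 1), q_can, mol$id, 1L)
  pose <- place_by_match(mol, match)
  far <- receptor_cloud(matrix(c(500, 500, 500), 1, 3))
  # isolated pose: no contacts, no clashes, 3 polar points satisfied -> 6
  expect_equal(score_pose(pose, far, q_can), 6)
  expect_equal(score_pose(pose, far, q_can), score_pose(pose, far, q_can))

  # featureless two-atom probe isolates the contact and clash terms
  probe_mol <- molecule("probe", c("C", "C"),
                        data.frame(a1 = 1, a2 = 2, order = 1),
                        list(rbind(c(0, 0, 0), c(10, 0, 0))))
  probe <- structure(list(mol_id = "probe", conformer_index = 1L,
                          xyz = get_conformer(probe_mol),
                          molecule = probe_mol,
                          clash_count = NA_integer_, fulfills_query = TRUE),
                     class = "pose")
  expect_equal(score_pose(probe, far, q_can), 0)
  # one receptor atom within contact range (but beyond clash range): +1 pair
  contact <- receptor_cloud(matrix(c(4.0, 0, 0), 1, 3))
  expect_equal(score_pose(probe, contact, q_can), 1)
  # a clashing atom costs 10 and still counts its contact pair
  clashrec <- receptor_cloud(matrix(c(1.5, 0, 0), 1, 3))
  expect_equal(score_pose(probe, clashrec, q_can), 1 - 10)
})

test_that("score is invariant under a joint rigid transform of pose, receptor and query", {
  mol <- make_site_frame_active()
  match <- match_conformer(perceive_features(mol, 1), q_can, mol$id, 1L)
  pose <- place_by_match(mol, match)
  rec <- generate_receptor_stub(q_can, seed = 31)
  s0 <- score_pose(pose, rec, q_can)
  R <- rotation_z(63); t_ <- c(-4, 2, 11)
  pose2 <- pose
  pose2$xyz <- sweep(pose$xyz %*% t(R), 2, t_, "+")
  pose2$molecule <- transform_molecule(pose2$molecule, R, t_)
  rec2 <- receptor_cloud(sweep(rec$xyz %*% t(R), 2, t_, "+"), rec$labels)
  q2 <- q_can
  q2[, c("x", "y", "z")] <-
    sweep(as.matrix(q_can[, c("x", "y", "z")]) %*% t(R), 2, t_, "+")
  s2 <- score_pose(pose2, rec2, pharmacophore_query(q2))
  expect_equal(s0, s2, tolerance = 1e-6)
})

test_that("refinement keeps fulfilling clash-free poses and drops broken ones", {
  lib <- generate_feature_library(6, 0.5, 0.2, seed = 19)
  hits <- suppressMessages(screen_library(lib, q_can))
  matches <- attr(hits, "matches")
  by_id <- setNames(lib, vapply(lib, function(m) m$id, ""))
  poses <- lapply(matches, function(mm) place_by_match(by_id[[mm$mol_id]],
                                                       mm))
  rec <- generate_receptor_stub(q_can, seed = 31)
  refined <- refine_and_filter(poses, rec, q_can, seed = 4)
  expect_lte(length(refined), length(poses))
  expect_equal(length(refined), length(poses))  # shell leaves room for all
  expect_true(all(vapply(refined, function(p) p$clash_count, 0L) == 0L))
  expect_true(all(vapply(refined, function(p) p$fulfills_query, TRUE)))
  scores <- vapply(refined, function(p) p$score, 0)
  expect_true(all(diff(scores) <= 1e-12))

  # a pose pushed outside the spheres no longer fulfils and is dropped
  broken <- poses[[1]]
  broken$xyz <- broken$xyz + 5
  broken$molecule$conformers <- list(broken$xyz)
  expect_length(refine_and_filter(list(broken), rec, q_can, seed = 4), 0L)
  expect_length(refine_and_filter(list(), rec, q_can, seed = 4), 0L)
})

test_that("the place-filter-score path is reproducible for a fixed seed", {
  lib <- generate_feature_library(4, 0.5, 0.2, seed = 29)
  hits <- suppressMessages(screen_library(lib, q_can))
  matches <- attr(hits, "matches")
  by_id <- setNames(lib, vapply(lib, function(m) m$id, ""))
  rec <- generate_receptor_stub(q_can, seed = 31)
  run <- function() {
    poses <- lapply(matches, function(mm) place_by_match(by_id[[mm$mol_id]],
                                                         mm))
    refine_and_filter(poses, rec, q_can, seed = 77)
  }
  r1 <- run(); r2 <- run()
  expect_identical(lapply(r1, function(p) p$xyz),
                   lapply(r2, function(p) p$xyz))
  expect_identical(vapply(r1, function(p) p$score, 0),
                   vapply(r2, function(p) p$score, 0))
})
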