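#' Receptor heavy-atom point cloud
#'
#' @param xyz n x 3 coordinate matrix (Angstrom), same frame as the query.
#' @param labels Data frame with columns `resno`, `resname`, `atom` (one row
#'   per atom); generated if omitted.
#' @return Object of class `receptor_cloud`.
#' @export
receptor_cloud <- function(xyz, labels = NULL) {
  xyz <- as.matrix(xyz)
  if (!nrow(xyz) || ncol(xyz) != 3L) stop("receptor needs an n x 3 matrix")
  if (!all(is.finite(xyz))) stop("receptor coordinates must be finite")
  if (is.null(labels))
    labels <- data.frame(resno = seq_len(nrow(xyz)), resname = "UNK",
                         atom = "X")
  structure(list(xyz = xyz, labels = labels), class = "receptor_cloud")
}

#' Read a receptor point cloud from a PDB file
#'
#' Heavy atoms only; hydrogens are dropped.
#'
#' @param path PDB file path.
#' @return A [receptor_cloud].
#' @export
read_receptor <- function(path) {
  pdb <- bio3d::read.pdb(path)
  sel <- pdb$atom$elety != "H" & !startsWith(pdb$atom$elety, "H")
  at <- pdb$atom[sel, , drop = FALSE]
  receptor_cloud(as.matrix(at[, c("x", "y", "z")]),
                 data.frame(resno = at$resno, resname = at$resid,
                            atom = at$elety))
}

#' Write a receptor point cloud to a PDB file
#' @param rec A [receptor_cloud].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_receptor <- function(rec, path) {
  bio3d::write.pdb(file = path, xyz = as.numeric(t(rec$xyz)),
                   resno = rec$labels$resno, resid = rec$labels$resname,
                   elety = rec$labels$atom)
  invisible(path)
}

#' Place a matched conformer into the query (site) frame
#'
#' Applies the match's rigid transform to all conformer coordinates. By
#' construction the placed pose fulfils the query before any clash filtering.
#'
#' @param mol The matched [molecule].
#' @param match A `match_result` from [match_conformer] for this molecule.
#' @return Object of class `pose`: transformed coordinates plus bookkeeping
#'   (`clash_count`, `contact_score`, `fulfills_query`).
#' @export
place_by_match <- function(mol, match) {
  if (!is.null(match$mol_id) && !identical(match$mol_id, mol$id))
    stop("match is for molecule '", match$mol_id, "', not '", mol$id, "'")
  k <- match$conformer_index %||% 1L
  xyz <- get_conformer(mol, k)
  placed <- apply_rigid(xyz, match$rotation, match$translation)
  structure(list(mol_id = mol$id, conformer_index = k, xyz = placed,
                 molecule = mol, match = match,
                 clash_count = NA_integer_, contact_score = NA_real_,
                 score = NA_real_, fulfills_query = TRUE),
            class = "pose")
}

# molecule carrying the pose geometry as its single conformer
pose_molecule <- function(pose) {
  m <- pose$molecule
  m$conformers <- list(pose$xyz)
  m
}

# does the pose, in the site frame, still fulfil the query? (injective
# kind-compatible assignment with every feature inside its sphere, no
# further superposition)
pose_fulfills_query <- function(pose, q) {
  feats <- perceive_features(pose_molecule(pose), 1L)
  if (!nrow(feats)) return(FALSE)
  fxyz <- feature_coords(feats)
  centers <- query_centers(q)
  m <- nrow(q)
  cand <- lapply(seq_len(m), function(i) {
    ix <- which(feats$kind == q$kind[i])
    d <- sqrt(rowSums(sweep(fxyz[ix, , drop = FALSE], 2, centers[i, ])^2))
    ix[d <= q$radius[i] + 1e-9]
  })
  if (any(vapply(cand, length, 0L) == 0L)) return(FALSE)
  used <- rep(FALSE, nrow(feats))
  recurse <- function(i) {
    if (i > m) return(TRUE)
    for (f in cand[[i]]) {
      if (used[f]) next
      used[f] <<- TRUE
      if (recurse(i + 1L)) return(TRUE)
      used[f] <<- FALSE
    }
    FALSE
  }
  recurse(1L)
}

# count of query points of the given kinds with a matching-kind feature
# inside the sphere (pose frame)
satisfied_polar_points <- function(pose, q) {
  feats <- perceive_features(pose_molecule(pose), 1L)
  if (!nrow(feats)) return(0L)
  fxyz <- feature_coords(feats)
  centers <- query_centers(q)
  sat <- 0L
  for (i in which(q$kind %in% c("acceptor", "donor"))) {
    ix <- which(feats$kind == q$kind[i])
    if (!length(ix)) next
    d <- sqrt(rowSums(sweep(fxyz[ix, , drop = FALSE], 2, centers[i, ])^2))
    if (any(d <= q$radius[i] + 1e-9)) sat <- sat + 1L
  }
  sat
}

#' Count steric clashes of a pose against the receptor
#'
#' A clash is a ligand heavy atom within `clash_distance` of any receptor
#' atom. Poses with `clash_count > 0` are rejected downstream.
#'
#' @param pose A [place_by_match] pose.
#' @param rec A [receptor_cloud].
#' @param clash_distance Clash cutoff in Angstrom (default 2.0).
#' @return The pose with `clash_count` filled in.
#' @export
clash_filter <- function(pose, rec, clash_distance = 2.0) {
  pose$clash_count <- count_within(pose, rec, clash_distance)
  pose
}

count_within <- function(pose, rec, cutoff) {
  heavy <- heavy_atoms(pose$molecule)
  lig <- pose$xyz[heavy, , drop = FALSE]
  n <- 0L
  for (i in seq_len(nrow(lig))) {
    d2 <- rowSums(sweep(rec$xyz, 2, lig[i, ])^2)
    if (any(d2 <= cutoff^2)) n <- n + 1L
  }
  n
}

count_contact_pairs <- function(pose, rec, cutoff) {
  heavy <- heavy_atoms(pose$molecule)
  lig <- pose$xyz[heavy, , drop = FALSE]
  n <- 0L
  for (i in seq_len(nrow(lig))) {
    d2 <- rowSums(sweep(rec$xyz, 2, lig[i, ])^2)
    n <- n + sum(d2 <= cutoff^2)
  }
  n
}

#' Score a placed pose
#'
#' A deterministic contact-count score standing in for an empirical docking
#' scoring function: (ligand-heavy-atom/receptor-atom pairs within
#' `contact_distance`) + 2 x (satisfied donor/acceptor query points) -
#' 10 x `clash_count`. Higher is better.
#'
#' @param pose A pose that passed [clash_filter].
#' @param rec A [receptor_cloud].
#' @param q A [pharmacophore_query] (for the polar-satisfaction term).
#' @param contact_distance Contact cutoff in Angstrom (default 4.5).
#' @param clash_distance Clash cutoff used if `clash_count` is not yet set.
#' @return The numeric score (also stored in the returned pose by
#'   [refine_and_filter]).
#' @export
score_pose <- function(pose, rec, q, contact_distance = 4.5,
                       clash_distance = 2.0) {
  clash <- pose$clash_count
  if (is.na(clash)) clash <- count_within(pose, rec, clash_distance)
  contacts <- count_contact_pairs(pose, rec, contact_distance)
  contacts + 2 * satisfied_polar_points(pose, q) - 10 * clash
}

#' Locally refine poses and re-apply the pharmacophore/clash funnel
#'
#' Each pose is perturbed by a bounded rigid local search (seeded; up to
#' `max_translation` Angstrom and `max_rotation_deg` degrees about the pose
#' centroid, `n_trials` candidates plus the identity) and the least-clashing
#' variant is kept (ties prefer the earlier candidate, i.e. the unperturbed
#' pose). Pharmacophore fulfilment is then recomputed on the refined
#' coordinates; poses that no longer fulfil the query, or that still clash,
#' are discarded. Survivors are scored with [score_pose] and returned sorted
#' by score (descending), ties by `mol_id` (ascending).
#'
#' @param poses List of poses from [place_by_match].
#' @param rec A [receptor_cloud].
#' @param q A [pharmacophore_query].
#' @param clash_distance,contact_distance Cutoffs in Angstrom.
#' @param max_translation,max_rotation_deg Perturbation bounds.
#' @param n_trials Random perturbations per pose.
#' @param seed RNG seed for the perturbations.
#' @return List of surviving poses with `score`, `clash_count` and
#'   `fulfills_query` filled in.
#' @export
refine_and_filter <- function(poses, rec, q, clash_distance = 2.0,
                              contact_distance = 4.5, max_translation = 0.3,
                              max_rotation_deg = 5, n_trials = 8, seed = 1) {
  out <- with_seed(seed, {
    kept <- list()
    for (pose in poses) {
      cands <- list(pose)
      centroid <- colMeans(pose$xyz)
      for (t in seq_len(n_trials)) {
        R <- rotation_about(runit3(),
                            stats::runif(1, 0, max_rotation_deg * pi / 180))
        shift <- rball3(max_translation)
        xyz <- sweep(sweep(pose$xyz, 2, centroid) %*% t(R), 2,
                     centroid + shift, "+")
        cand <- pose
        cand$xyz <- xyz
        cands[[length(cands) + 1L]] <- cand
      }
      clashes <- vapply(cands, function(p) count_within(p, rec,
                                                        clash_distance), 0L)
      bestix <- which.min(clashes)   # ties resolve to the earliest candidate
      best <- cands[[bestix]]
      best$clash_count <- clashes[bestix]
      best$fulfills_query <- pose_fulfills_query(best, q)
      if (best$clash_count > 0L || !best$fulfills_query) next
      best$contact_score <- count_contact_pairs(best, rec, contact_distance)
      best$score <- score_pose(best, rec, q, contact_distance,
                               clash_distance)
      kept[[length(kept) + 1L]] <- best
    }
    kept
  })
  if (!length(out)) return(out)
  ids <- vapply(out, function(p) p$mol_id, "")
  scores <- vapply(out, function(p) p$score, 0)
  out[order(-scores, ids)]
}

#' Write poses to a multi-record SDF with score and clash properties
#' @param poses List of poses.
#' @param path Output SDF path.
#' @return Invisibly, the path.
#' @export
write_poses <- function(poses, path) {
  mols <- lapply(poses, function(p) {
    m <- pose_molecule(p)
    m$properties$pose_score <- p$score
    m$properties$clash_count <- p$clash_count
    m$properties$conformer_index <- p$conformer_index
    m
  })
  write_molecules(mols, path)
}
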