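#' Construct a coordinate trajectory
#'
#' @param xyz Numeric array `n_frames x n_atoms x 3` (Angstrom), or a list of
#'   `n_atoms x 3` frame matrices.
#' @param labels Data frame with columns `resno`, `resname`, `atom`, one row
#'   per atom. An `label` column (`"RESNAME<resno>:ATOM"`) is derived.
#' @param times Optional frame times (ns).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(xyz, labels, times = NULL) {
  if (is.list(xyz)) {
    xyz <- simplify2array(xyz)       # atoms x 3 x frames
    xyz <- aperm(xyz, c(3, 1, 2))
  }
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    stop("xyz must be an n_frames x n_atoms x 3 array")
  if (!all(is.finite(xyz))) stop("trajectory coordinates must be finite")
  labels <- as.data.frame(labels)
  if (nrow(labels) != dim(xyz)[2])
    stop("labels must have one row per atom")
  labels$label <- atom_label(labels)
  if (!is.null(times) && length(times) != dim(xyz)[1])
    stop("times must have one entry per frame")
  structure(list(xyz = xyz, labels = labels, times = times),
            class = "trajectory")
}

atom_label <- function(labels) {
  sprintf("%s%d:%s", labels$resname, labels$resno, labels$atom)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames x %d atoms>\n", dim(x$xyz)[1],
              dim(x$xyz)[2]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$xyz)[1]

frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, , ], ncol = 3L)
}

# resolve a selection (logical/integer vector, label predicate function, or
# character vector of atom names) to atom indices
resolve_selection <- function(traj, selection) {
  idx <- if (is.null(selection)) seq_len(nrow(traj$labels))
  else if (is.function(selection)) which(selection(traj$labels))
  else if (is.logical(selection)) which(selection)
  else if (is.character(selection)) which(traj$labels$atom %in% selection)
  else as.integer(selection)
  if (!length(idx)) stop("empty atom selection")
  idx
}

#' Read a trajectory from a multi-model PDB file
#' @param path PDB path (MODEL/ENDMDL records).
#' @return A [trajectory].
#' @export
read_trajectory <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  nat <- nrow(pdb$atom)
  nfr <- nrow(pdb$xyz)
  xyz <- array(NA_real_, c(nfr, nat, 3))
  for (f in seq_len(nfr))
    xyz[f, , ] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(xyz, data.frame(resno = pdb$atom$resno,
                             resname = pdb$atom$resid,
                             atom = pdb$atom$elety))
}

#' Write a trajectory as a multi-model PDB file
#' @param traj A [trajectory].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(traj, path) {
  nfr <- n_frames(traj)
  xyz <- t(vapply(seq_len(nfr),
                  function(f) as.numeric(t(frame_coords(traj, f))),
                  numeric(dim(traj$xyz)[2] * 3)))
  bio3d::write.pdb(file = path, xyz = xyz, resno = traj$labels$resno,
                   resid = traj$labels$resname, elety = traj$labels$atom)
  invisible(path)
}

#' Best-fit RMSD time series
#'
#' Per-frame least-squares-superposed RMSD of the selected atoms onto the
#' reference frame.
#'
#' @param traj A [trajectory].
#' @param ref_frame Reference frame index (default 1).
#' @param selection Atom selection (indices, logical, atom-name vector, or a
#'   predicate on the label data frame); default all atoms.
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, ref_frame = 1L, selection = NULL) {
  idx <- resolve_selection(traj, selection)
  ref <- frame_coords(traj, ref_frame)[idx, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(ref, frame_coords(traj, f)[idx, , drop = FALSE])$rmsd
  }, 0)
}

# superpose every frame (selected atoms) onto a reference; returns the
# array of transformed selected coordinates
superpose_frames <- function(traj, idx, ref) {
  nfr <- n_frames(traj)
  out <- array(NA_real_, c(nfr, length(idx), 3))
  for (f in seq_len(nfr)) {
    xyz <- frame_coords(traj, f)[idx, , drop = FALSE]
    fit <- kabsch_fit(xyz, ref)
    out[f, , ] <- apply_rigid(xyz, fit$rotation, fit$translation)
  }
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames after the equilibration cut are superposed onto their iteratively
#' refined mean structure (mean-fit repeated until the mean moves by less
#' than 1e-6 Angstrom), then the fluctuation of each selected atom about its
#' time-mean position is reported, indexed by residue number. The selection
#' is expected to pick one atom per residue (e.g. `"CA"`).
#'
#' @param traj A [trajectory].
#' @param selection Atom selection (default atoms named `CA`).
#' @param equilibration_cut Number of leading frames to drop (default 0).
#' @return Named numeric vector, RMSF (Angstrom) per residue number.
#' @export
rmsf_per_residue <- function(traj, selection = "CA", equilibration_cut = 0L) {
  idx <- resolve_selection(traj, selection)
  keep <- seq_len(n_frames(traj)) > equilibration_cut
  if (sum(keep) < 2L) stop("need at least 2 frames after the equilibration cut")
  sub <- trajectory(traj$xyz[keep, , , drop = FALSE], traj$labels)
  ref <- frame_coords(sub, 1L)[idx, , drop = FALSE]
  for (it in 1:100) {
    aligned <- superpose_frames(sub, idx, ref)
    newref <- apply(aligned, c(2, 3), mean)
    shift <- max(abs(newref - ref))
    ref <- newref
    if (shift < 1e-6) break
  }
  aligned <- superpose_frames(sub, idx, ref)
  mean_pos <- apply(aligned, c(2, 3), mean)
  dev2 <- vapply(seq_along(idx), function(a) {
    mean(rowSums(sweep(aligned[, a, , drop = TRUE], 2, mean_pos[a, ])^2))
  }, 0)
  stats::setNames(sqrt(dev2), traj$labels$resno[idx])
}

#' Detect hydrogen bonds in one coordinate frame
#'
#' Geometric criteria: donor--acceptor distance below `d_cut` and, when the
#' donor hydrogen position is known, a donor-H-acceptor angle of at least
#' `angle_cut` degrees. Donors without a hydrogen atom fall back to
#' distance-only detection at the stricter `d_cut_noh` cutoff and are flagged
#' in the output.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param labels Data frame (`resno`, `resname`, `atom`) for the same atoms.
#' @param donors Character vector of donor heavy-atom labels
#'   (`"RESNAME<resno>:ATOM"`), or a data frame with columns `donor` and `h`
#'   (hydrogen label, `NA` if absent).
#' @param acceptors Character vector of acceptor atom labels.
#' @param d_cut Donor-acceptor distance cutoff (Angstrom, default 3.5).
#' @param angle_cut D-H-A angle cutoff (degrees, default 120).
#' @param d_cut_noh Distance-only cutoff when no hydrogen is given
#'   (default 3.2).
#' @return Data frame of events: `donor`, `acceptor`, `distance`, `angle`
#'   (`NA` without hydrogen), `h_inferred` flag.
#' @export
detect_hbonds <- function(xyz, labels, donors, acceptors, d_cut = 3.5,
                          angle_cut = 120, d_cut_noh = 3.2) {
  labels <- as.data.frame(labels)
  labels$label <- atom_label(labels)
  lookup <- function(lab) {
    i <- match(lab, labels$label)
    if (is.na(i)) stop("unknown atom label: ", lab)
    i
  }
  if (is.character(donors)) donors <- data.frame(donor = donors, h = NA)
  events <- list()
  for (di in seq_len(nrow(donors))) {
    d_idx <- lookup(donors$donor[di])
    h_idx <- if (!is.na(donors$h[di])) lookup(donors$h[di]) else NA_integer_
    for (acc in acceptors) {
      a_idx <- lookup(acc)
      if (a_idx == d_idx) next
      dist_da <- sqrt(sum((xyz[d_idx, ] - xyz[a_idx, ])^2))
      if (is.na(h_idx)) {
        if (dist_da > d_cut_noh) next
        ang <- NA_real_
      } else {
        if (dist_da > d_cut) next
        v1 <- xyz[d_idx, ] - xyz[h_idx, ]
        v2 <- xyz[a_idx, ] - xyz[h_idx, ]
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) *
          180 / pi
        if (ang < angle_cut) next
      }
      events[[length(events) + 1L]] <- data.frame(
        donor = donors$donor[di], acceptor = acc, distance = dist_da,
        angle = ang, h_inferred = is.na(h_idx))
    }
  }
  if (!length(events))
    return(data.frame(donor = character(), acceptor = character(),
                      distance = double(), angle = double(),
                      h_inferred = logical()))
  do.call(rbind, events)
}

#' Hydrogen-bond occupancy along a trajectory
#'
#' Fraction of frames in which each donor-acceptor pair forms a detected
#' hydrogen bond, sorted descending.
#'
#' @param traj A [trajectory].
#' @param pairs Data frame with columns `donor`, `acceptor` and optionally
#'   `h` (donor hydrogen label).
#' @param ... Cutoffs passed to [detect_hbonds].
#' @return Data frame `donor`, `acceptor`, `occupancy`, sorted by occupancy
#'   (descending).
#' @export
hbond_occupancy <- function(traj, pairs, ...) {
  if (n_frames(traj) < 1L) stop("trajectory has no frames")
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$h)) pairs$h <- NA
  counts <- numeric(nrow(pairs))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    for (p in seq_len(nrow(pairs))) {
      ev <- detect_hbonds(xyz, traj$labels,
                          donors = data.frame(donor = pairs$donor[p],
                                              h = pairs$h[p]),
                          acceptors = pairs$acceptor[p], ...)
      if (nrow(ev)) counts[p] <- counts[p] + 1
    }
  }
  out <- data.frame(donor = pairs$donor, acceptor = pairs$acceptor,
                    occupancy = counts / n_frames(traj))
  out[order(-out$occupancy), , drop = FALSE]
}
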