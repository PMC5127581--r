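# Synthetic-data generators. Every pipeline stage can be fed inputs of known
# ground truth: conformer libraries with planted pharmacophore-matching
# actives among geometric decoys, a receptor shell around the query site,
# Michaelis-Menten velocities under known inhibition modes, 4PL dose-response
# curves, and coordinate trajectories with prescribed per-atom fluctuation.
# Actives are geometric constructs, not drug-like chemistry: fixture realism
# is deliberately limited to what the pipeline measures.

# planted-active scaffold: an aromatic six-ring centred on each
# hydrophobic/aromatic query point, an ether oxygen on each acceptor point,
# and an aliphatic amine nitrogen (protonated-donor heuristic) on each donor
# point, all tied into one connected graph; perceived features then sit
# exactly on the (jittered) targets
build_scaffold <- function(targets, kinds) {
  atoms <- data.frame(element = character(), charge = integer())
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  xyz <- matrix(numeric(0), 0, 3)
  ring_attach <- integer(0)      # one free aromatic carbon per ring, for links
  hetero_hosts <- integer(0)     # ring carbons still available for heteroatoms
  add_atom <- function(el, pos, charge = 0L) {
    atoms[nrow(atoms) + 1L, ] <<- list(el, charge)
    xyz <<- rbind(xyz, pos)
    nrow(atoms)
  }
  add_bond <- function(a, b, order = 1L) {
    bonds[nrow(bonds) + 1L, ] <<- list(a, b, order)
  }

  for (i in which(kinds == "hydrophobic_aromatic")) {
    e1 <- runit3()
    e2 <- runit3()
    e2 <- e2 - sum(e1 * e2) * e1
    e2 <- e2 / sqrt(sum(e2^2))
    first <- nrow(atoms) + 1L
    for (v in 0:5) {
      ang <- v * pi / 3
      pos <- targets[i, ] + 1.39 * (cos(ang) * e1 + sin(ang) * e2)
      add_atom("C", pos)
    }
    for (v in 0:5) add_bond(first + v, first + (v + 1L) %% 6L, 4L)
    ring_attach <- c(ring_attach, first)
    hetero_hosts <- c(hetero_hosts, first + 1:5)
  }
  # chain the rings together so the graph is connected
  if (length(ring_attach) > 1L)
    for (k in seq_len(length(ring_attach) - 1L))
      add_bond(ring_attach[k], ring_attach[k + 1L], 1L)

  host_ptr <- 0L
  next_host <- function() {
    host_ptr <<- host_ptr + 1L
    if (host_ptr > length(hetero_hosts))
      stop("scaffold has no free ring carbon to attach a heteroatom")
    hetero_hosts[host_ptr]
  }
  for (i in which(kinds == "acceptor")) {
    o <- add_atom("O", targets[i, ])
    add_bond(o, next_host(), 1L)
    me <- add_atom("C", targets[i, ] + 1.4 * runit3())
    add_bond(o, me, 1L)          # ether oxygen: acceptor, no implicit H
  }
  for (i in which(kinds == "donor")) {
    nn <- add_atom("N", targets[i, ])
    add_bond(nn, next_host(), 1L)
    me <- add_atom("C", targets[i, ] + 1.4 * runit3())
    add_bond(nn, me, 1L)         # secondary aliphatic amine: donor/cation
  }
  list(atoms = atoms, bonds = bonds, xyz = xyz)
}

#' Generate a synthetic feature library for screening
#'
#' Builds `n_molecules` single-conformer molecules: a planted fraction of
#' actives whose perceived features land within `jitter` Angstrom of each
#' query center (with matching kinds), the rest decoys per `decoy_mode`:
#' \describe{
#'   \item{distance_violating}{the scaffold for one acceptor point is built
#'     8 Angstrom away from its center, inflating an interpoint distance far
#'     beyond the radius sum so no rigid placement can match;}
#'   \item{type_mismatched}{donor points get an ether oxygen instead of an
#'     amine, so the library lacks a donor feature;}
#'   \item{random}{the scaffold pieces are scattered uniformly in a 15
#'     Angstrom box.}
#' }
#' Every molecule is then moved by a random rigid transform. Ground truth is
#' attached as properties (`active`, `decoy_mode`). Deterministic per seed.
#'
#' @param n_molecules Library size.
#' @param active_fraction Planted active fraction in `[0, 1]`.
#' @param jitter Feature placement jitter (Angstrom); a warning is issued if
#'   it reaches the smallest query radius (actives may then legitimately
#'   fail).
#' @param seed RNG seed.
#' @param decoy_mode One of `"distance_violating"`, `"type_mismatched"`,
#'   `"random"`.
#' @param q Pharmacophore query (default [canonical_query]).
#' @return List of [molecule] objects; actives first (ids `ACT...`), then
#'   decoys (ids `DEC...`).
#' @export
generate_feature_library <- function(n_molecules = 100L,
                                     active_fraction = 0.1, jitter = 0.3,
                                     seed = 7L,
                                     decoy_mode = c("distance_violating",
                                                    "type_mismatched",
                                                    "random"),
                                     q = canonical_query()) {
  decoy_mode <- match.arg(decoy_mode)
  if (active_fraction < 0 || active_fraction > 1)
    stop("active_fraction must be in [0, 1]")
  if (jitter < 0) stop("jitter must be non-negative")
  if (jitter >= min(q$radius))
    warning("jitter >= smallest query radius; actives may legitimately fail")
  n_active <- round(n_molecules * active_fraction)
  centers <- query_centers(q)
  with_seed(seed, {
    mols <- vector("list", n_molecules)
    for (m in seq_len(n_molecules)) {
      is_active <- m <= n_active
      kinds <- q$kind
      if (is_active || decoy_mode != "type_mismatched") {
        targets <- centers + t(vapply(seq_len(nrow(centers)),
                                      function(i) rball3(jitter), numeric(3)))
      }
      if (!is_active) {
        if (decoy_mode == "distance_violating") {
          bad <- which(kinds == "acceptor")[1]
          away <- targets[bad, ] - colMeans(centers)
          targets[bad, ] <- targets[bad, ] + 8 * away / sqrt(sum(away^2))
        } else if (decoy_mode == "type_mismatched") {
          kinds[kinds == "donor"] <- "acceptor"
          targets <- centers + t(vapply(seq_len(nrow(centers)),
                                        function(i) rball3(jitter),
                                        numeric(3)))
        } else {
          targets <- matrix(stats::runif(3 * nrow(centers), -7.5, 7.5),
                            ncol = 3)
        }
      }
      sc <- build_scaffold(targets, kinds)
      R <- random_rotation()
      t_ <- stats::runif(3, -20, 20)
      xyz <- apply_rigid(sc$xyz, R, t_)
      id <- sprintf("%s%04d", if (is_active) "ACT" else "DEC", m)
      mols[[m]] <- molecule(id, sc$atoms, sc$bonds, list(xyz),
                            properties = list(active = as.integer(is_active),
                                              decoy_mode = if (is_active)
                                                "none" else decoy_mode))
    }
    mols
  })
}

#' Generate a synthetic receptor shell around the query site
#'
#' Pseudo-atoms are scattered on a spherical shell centred on the query
#' centroid, far enough out that no atom comes nearer than `clearance` to any
#' query point center (rejection-sampled guarantee). Deterministic per seed.
#'
#' @param q Pharmacophore query (default [canonical_query]).
#' @param clearance Minimum distance from any query center (Angstrom,
#'   default 2.5; must exceed the clash cutoff you plan to use).
#' @param n_atoms Number of shell atoms (default 200).
#' @param seed RNG seed.
#' @param shell_margin Extra shell radius beyond the query extent plus
#'   clearance (Angstrom, default 3).
#' @return A [receptor_cloud].
#' @export
generate_receptor_stub <- function(q = canonical_query(), clearance = 2.5,
                                   n_atoms = 200L, seed = 11L,
                                   shell_margin = 3) {
  centers <- query_centers(q)
  mid <- colMeans(centers)
  extent <- max(sqrt(rowSums(sweep(centers, 2, mid)^2)))
  radius <- extent + clearance + shell_margin
  with_seed(seed, {
    xyz <- matrix(NA_real_, n_atoms, 3)
    i <- 0L
    while (i < n_atoms) {
      pos <- mid + (radius + stats::runif(1, 0, 2)) * runit3()
      if (min(sqrt(rowSums(sweep(centers, 2, pos)^2))) < clearance) next
      i <- i + 1L
      xyz[i, ] <- pos
    }
    receptor_cloud(xyz, data.frame(resno = seq_len(n_atoms), resname = "GLY",
                                   atom = "CA"))
  })
}

#' Generate Michaelis-Menten velocities under a known inhibition mode
#'
#' Velocities follow `v = Vmax_app * S / (Km_app + S)` with apparent
#' parameters set by the mode (competitive: `Km_app = Km (1 + [I]/Ki)`;
#' noncompetitive: `Vmax_app = Vmax / (1 + [I]/Ki)`; none: unchanged),
#' multiplied by log-normal noise of the requested coefficient of variation
#' (mean 1). Deterministic per seed.
#'
#' @param Km,Vmax Generating control parameters (uM, activity units).
#' @param mode `"competitive"`, `"noncompetitive"` or `"none"`.
#' @param Ki Inhibition constant (uM), required when mode is not "none".
#' @param inhibitor_levels Inhibitor concentrations (uM); 0 (control) is
#'   always included.
#' @param S Substrate grid (uM); default 8 points geometric from 10 to 400.
#' @param noise_cv Multiplicative noise CV (0 = exact values).
#' @param reps Replicates per (S, I) pair.
#' @param seed RNG seed.
#' @return A [kinetics_dataset].
#' @export
generate_kinetics_data <- function(Km = 56, Vmax = 57788,
                                   mode = c("none", "competitive",
                                            "noncompetitive"),
                                   Ki = 20, inhibitor_levels = numeric(0),
                                   S = exp(seq(log(10), log(400),
                                               length.out = 8)),
                                   noise_cv = 0, reps = 1L, seed = 1L) {
  mode <- match.arg(mode)
  if (Km <= 0 || Vmax <= 0) stop("Km and Vmax must be positive")
  if (mode != "none" && (is.null(Ki) || Ki <= 0))
    stop("mode '", mode, "' needs a positive Ki")
  levels <- unique(c(0, inhibitor_levels))
  grid <- expand.grid(substrate = S, inhibitor = levels,
                      replicate = seq_len(reps))
  km_app <- if (mode == "competitive")
    Km * (1 + grid$inhibitor / Ki) else rep(Km, nrow(grid))
  vmax_app <- if (mode == "noncompetitive")
    Vmax / (1 + grid$inhibitor / Ki) else rep(Vmax, nrow(grid))
  v <- vmax_app * grid$substrate / (km_app + grid$substrate)
  if (noise_cv > 0) {
    v <- with_seed(seed, {
      sdlog <- sqrt(log(1 + noise_cv^2))
      v * exp(stats::rnorm(length(v), -sdlog^2 / 2, sdlog))
    })
  }
  kinetics_dataset(grid$substrate, v, grid$inhibitor, grid$replicate)
}

#' Generate a four-parameter logistic dose-response table
#'
#' `response = bottom + (top - bottom) / (1 + (dose/IC50)^hill)` plus
#' log-normal noise of the requested CV on the response. Deterministic per
#' seed.
#'
#' @param IC50 Half-maximal dose (uM).
#' @param hill Hill slope.
#' @param top,bottom Curve asymptotes.
#' @param doses Dose grid (uM); default 10 points log-spaced 0.1 to 1000.
#' @param noise_cv Multiplicative noise CV.
#' @param reps Replicates per dose.
#' @param seed RNG seed.
#' @return Data frame with `dose`, `response`, `replicate`.
#' @export
generate_dose_response <- function(IC50 = 16, hill = 1, top = 100,
                                   bottom = 0,
                                   doses = 10^seq(-1, 3, length.out = 10),
                                   noise_cv = 0, reps = 1L, seed = 1L) {
  if (IC50 <= 0) stop("IC50 must be positive")
  grid <- expand.grid(dose = doses, replicate = seq_len(reps))
  resp <- bottom + (top - bottom) / (1 + (grid$dose / IC50)^hill)
  if (noise_cv > 0) {
    resp <- with_seed(seed, {
      sdlog <- sqrt(log(1 + noise_cv^2))
      resp * exp(stats::rnorm(length(resp), -sdlog^2 / 2, sdlog))
    })
  }
  data.frame(dose = grid$dose, response = resp, replicate = grid$replicate)
}

#' Generate a coordinate trajectory with prescribed per-atom fluctuation
#'
#' Frames are the base coordinates plus isotropic Gaussian jitter (standard
#' deviation `sigma` per axis, per atom) and, optionally, a cumulative global
#' rigid drift. For isotropic jitter the expected RMSF is `sigma * sqrt(3)`.
#' Deterministic per seed.
#'
#' @param base n_atoms x 3 base coordinate matrix (Angstrom).
#' @param n_frames Number of frames.
#' @param sigma Per-atom jitter SD (Angstrom); scalar or per-atom vector.
#' @param labels Optional label data frame (`resno`, `resname`, `atom`);
#'   defaults to one CA per residue.
#' @param drift Optional list `list(translation =, axis =, angle_deg =)`
#'   applied cumulatively per frame (rigid motion).
#' @param seed RNG seed.
#' @return A [trajectory].
#' @export
generate_trajectory <- function(base, n_frames = 100L, sigma = 0,
                                labels = NULL, drift = NULL, seed = 1L) {
  base <- as.matrix(base)
  nat <- nrow(base)
  if (n_frames < 1L) stop("need at least one frame")
  sigma <- rep_len(sigma, nat)
  if (is.null(labels))
    labels <- data.frame(resno = seq_len(nat), resname = "GLY", atom = "CA")
  with_seed(seed, {
    xyz <- array(NA_real_, c(n_frames, nat, 3))
    for (f in seq_len(n_frames)) {
      fr <- base + matrix(stats::rnorm(nat * 3), nat, 3) * sigma
      if (!is.null(drift)) {
        ang <- (drift$angle_deg %||% 0) * (f - 1) * pi / 180
        axis <- drift$axis %||% c(0, 0, 1)
        shift <- (drift$translation %||% c(0, 0, 0)) * (f - 1)
        fr <- apply_rigid(fr, rotation_about(axis, ang), shift)
      }
      xyz[f, , ] <- fr
    }
    trajectory(xyz, labels)
  })
}
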