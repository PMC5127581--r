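# Independent oracles used to cross-check the implementation.

# least-squares rigid superposition via bio3d (independent of the package's
# closed-form implementation); returns mobile transformed onto ref
oracle_superpose <- function(ref, mobile) {
  moved <- matrix(bio3d::rot.lsq(as.vector(t(mobile)), as.vector(t(ref))),
                  ncol = 3, byrow = TRUE)
  list(moved = moved, rmsd = sqrt(mean(rowSums((moved - ref)^2))))
}

# brute-force pharmacophore matcher: exhaustive enumeration of injective
# kind-compatible assignments with NO distance pruning, bio3d superposition,
# per-point sphere acceptance; returns NULL or list(rmsd = best rmsd)
oracle_match <- function(features, q) {
  m <- nrow(q)
  fxyz <- as.matrix(features[, c("x", "y", "z")])
  centers <- as.matrix(q[, c("x", "y", "z")])
  cand <- lapply(seq_len(m), function(i) which(features$kind == q$kind[i]))
  if (any(vapply(cand, length, 0L) == 0L) || nrow(features) < m) return(NULL)
  grid <- as.matrix(expand.grid(cand))
  keep <- apply(grid, 1, function(r) !anyDuplicated(r))
  grid <- grid[keep, , drop = FALSE]
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    sel <- grid[r, ]
    fit <- oracle_superpose(centers, fxyz[sel, , drop = FALSE])
    resid <- sqrt(rowSums((fit$moved - centers)^2))
    if (all(resid <= q$radius + 1e-9)) {
      rmsd <- sqrt(mean(resid^2))
      if (rmsd < best) best <- rmsd
    }
  }
  if (is.infinite(best)) NULL else list(rmsd = best)
}

# random feature set around the query: with probability `p_active` the first
# five features are kind-correct noisy copies of the centers (so accepts
# occur), remaining features are uniform distractors in the query bounding box
random_feature_set <- function(q, p_active = 0.5, noise = NULL) {
  centers <- as.matrix(q[, c("x", "y", "z")])
  n <- sample(5:8, 1)
  kinds <- sample(c("hydrophobic_aromatic", "acceptor", "donor"), n,
                  replace = TRUE)
  lo <- apply(centers, 2, min) - 3
  hi <- apply(centers, 2, max) + 3
  xyz <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  if (runif(1) < p_active) {
    if (is.null(noise)) noise <- runif(1, 0.2, 1.2)
    kinds[1:5] <- q$kind
    jit <- matrix(rnorm(15), 5, 3)
    jit <- jit / sqrt(rowSums(jit^2)) * runif(5)^(1 / 3) * noise
    xyz[1:5, ] <- centers + jit
  }
  make_features(kinds, xyz)
}

# brute-force best-fit rmsd between two point sets by numerical optimisation
# over the 6 rigid degrees of freedom (independent of any closed form)
oracle_rigid_rmsd <- function(ref, mobile) {
  obj <- function(par) {
    R <- rot_xyz(par[1], par[2], par[3])
    moved <- sweep(mobile %*% t(R), 2, par[4:6], "+")
    sqrt(mean(rowSums((moved - ref)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(0.5, -0.3, 0.2, 0, 0, 0))) {
    o <- optim(start, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

rot_xyz <- function(a, b, c) {
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  Rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Rx %*% Ry %*% Rz
}
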