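#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# random unit 3-vector
runit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# uniform point in a ball of given radius
rball3 <- function(radius) {
  runit3() * radius * stats::runif(1)^(1 / 3)
}

# rotation matrix about a unit axis by angle (radians), Rodrigues form
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# random proper rotation matrix
random_rotation <- function() {
  rotation_about(runit3(), stats::runif(1, 0, 2 * pi))
}

# apply rigid transform x -> x R^T + t to an n x 3 coordinate matrix
apply_rigid <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
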