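#' Construct a pharmacophore query
#'
#' A query is an ordered set of labelled, typed points, each a sphere in the
#' receptor frame: a feature of the matching kind must lie inside the sphere
#' after rigid superposition for the point to be fulfilled.
#'
#' @param points Data frame with columns `label`, `kind` (one of
#'   `hydrophobic_aromatic`, `acceptor`, `donor`), `x`, `y`, `z` (Angstrom)
#'   and `radius` (Angstrom, > 0).
#' @return An object of class `pharmacophore_query`.
#' @export
pharmacophore_query <- function(points) {
  points <- as.data.frame(points)
  needed <- c("label", "kind", "x", "y", "z", "radius")
  if (!all(needed %in% names(points)))
    stop("query needs columns: ", paste(needed, collapse = ", "))
  if (nrow(points) < 3L) stop("a pharmacophore query needs at least 3 points")
  if (anyDuplicated(points$label)) stop("query point labels must be unique")
  if (!all(points$kind %in% c("hydrophobic_aromatic", "acceptor", "donor")))
    stop("invalid point kind")
  if (!all(points$radius > 0)) stop("point radii must be positive")
  structure(points[, needed], class = c("pharmacophore_query", "data.frame"))
}

#' The canonical five-point query
#'
#' The five-point pharmacophore describing the peptide-p38alpha interaction at
#' the allosteric (MK2-docking) site: two hydrophobic/aromatic points, two
#' hydrogen-bond acceptors and one donor, with sphere tolerances of 1.5 or
#' 1.2 Angstrom in the crystallographic frame of the complex.
#'
#' @return A [pharmacophore_query] with points P1..P5.
#' @examples
#' q <- canonical_query()
#' interpoint_distances(q)
#' @export
canonical_query <- function() {
  pharmacophore_query(data.frame(
    label = paste0("P", 1:5),
    kind = c("hydrophobic_aromatic", "hydrophobic_aromatic",
             "acceptor", "acceptor", "donor"),
    x = c(43.9, 47.2, 43.6, 39.0, 47.7),
    y = c(54.7, 58.9, 52.9, 61.0, 60.3),
    z = c(45.9, 47.8, 46.5, 49.0, 47.3),
    radius = c(1.5, 1.5, 1.2, 1.2, 1.2)))
}

query_centers <- function(q) as.matrix(q[, c("x", "y", "z")])

#' Pairwise distances between query point centers
#' @param q A [pharmacophore_query].
#' @return Symmetric matrix of Euclidean distances (Angstrom), labelled by
#'   point, zero diagonal.
#' @export
interpoint_distances <- function(q) {
  d <- as.matrix(stats::dist(query_centers(q)))
  dimnames(d) <- list(q$label, q$label)
  d
}

#' Read a pharmacophore query from JSON
#'
#' Expected shape: `{"points": [{"label", "kind", "center": [x,y,z],
#' "radius"}, ...]}`.
#'
#' @param path JSON file path.
#' @return A [pharmacophore_query].
#' @export
read_query <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- j$points
  centers <- do.call(rbind, pts$center)
  pharmacophore_query(data.frame(
    label = pts$label, kind = pts$kind,
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = pts$radius))
}

#' Write a pharmacophore query to JSON
#' @param q A [pharmacophore_query].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_query <- function(q, path) {
  pts <- lapply(seq_len(nrow(q)), function(i) list(
    label = q$label[i], kind = q$kind[i],
    center = c(q$x[i], q$y[i], q$z[i]), radius = q$radius[i]))
  jsonlite::write_json(list(points = pts), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
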