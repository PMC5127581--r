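#' Construct a small-molecule object
#'
#' A `molecule` holds the chemical graph (elements, formal charges, bonds) and
#' any number of 3D conformers, plus a free-form property map (e.g. pose
#' scores, ground-truth labels). Coordinates are in Angstrom throughout.
#'
#' @param id Molecule identifier (single string).
#' @param atoms Either a character vector of element symbols, or a data frame
#'   with columns `element` and `charge` (integer formal charge).
#' @param bonds Data frame with columns `a1`, `a2` (1-based atom indices) and
#'   `order` (1, 2, 3, or 4 for aromatic), or `NULL` for no bonds.
#' @param conformers List of numeric n_atoms x 3 coordinate matrices (Angstrom).
#' @param properties Named list of scalar properties.
#' @return An object of class `molecule`.
#' @examples
#' m <- molecule("mol1", c("C", "O"), data.frame(a1 = 1, a2 = 2, order = 1))
#' n_atoms(m)
#' @export
molecule <- function(id, atoms, bonds = NULL, conformers = list(),
                     properties = list()) {
  if (is.character(atoms))
    atoms <- data.frame(element = atoms, charge = rep(0L, length(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  atoms <- data.frame(element = as.character(atoms$element),
                      charge = as.integer(atoms$charge))
  if (is.null(bonds)) bonds <- data.frame(a1 = integer(), a2 = integer(),
                                          order = integer())
  bonds <- data.frame(a1 = as.integer(bonds$a1), a2 = as.integer(bonds$a2),
                      order = as.integer(bonds$order))
  if (!is.list(conformers)) conformers <- list(conformers)
  conformers <- lapply(conformers, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    dimnames(x) <- NULL
    x
  })
  m <- structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                      conformers = conformers, properties = properties),
                 class = "molecule")
  validate_molecule(m)
  m
}

validate_molecule <- function(m) {
  n <- nrow(m$atoms)
  if (n < 1L) stop("molecule '", m$id, "': must have at least one atom")
  if (nrow(m$bonds)) {
    idx <- c(m$bonds$a1, m$bonds$a2)
    if (any(idx < 1L | idx > n))
      stop("molecule '", m$id, "': bond atom index out of range")
    if (!all(m$bonds$order %in% 1:4))
      stop("molecule '", m$id, "': bond order must be 1, 2, 3 or 4 (aromatic)")
  }
  for (k in seq_along(m$conformers)) {
    xyz <- m$conformers[[k]]
    if (!is.matrix(xyz) || nrow(xyz) != n || ncol(xyz) != 3L)
      stop("molecule '", m$id, "': conformer ", k,
           " must be an n_atoms x 3 matrix")
    if (!all(is.finite(xyz)))
      stop("molecule '", m$id, "': conformer ", k,
           " has non-finite coordinates")
  }
  invisible(m)
}

#' Number of atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Number of conformers of a molecule
#' @param mol A `molecule`.
#' @return Integer conformer count.
#' @export
n_conformers <- function(mol) length(mol$conformers)

#' Extract one conformer's coordinates
#' @param mol A `molecule`.
#' @param conformer_index 1-based conformer index.
#' @return n_atoms x 3 coordinate matrix (Angstrom).
#' @export
get_conformer <- function(mol, conformer_index = 1L) {
  if (conformer_index < 1L || conformer_index > n_conformers(mol))
    stop("molecule '", mol$id, "': no conformer ", conformer_index)
  mol$conformers[[conformer_index]]
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms, %d bonds, %d conformer(s)>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), length(x$conformers)))
  if (length(x$properties))
    cat("  properties:", paste(names(x$properties), collapse = ", "), "\n")
  invisible(x)
}

# heavy-atom (non-hydrogen) index vector
heavy_atoms <- function(mol) which(mol$atoms$element != "H")
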