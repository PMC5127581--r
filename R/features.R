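# Pharmacophoric feature perception.
#
# The typing rules are a documented stand-in for the (proprietary) scheme used
# by commercial screening suites: aromatic rings and aliphatic carbon patches
# as hydrophobic/aromatic points, N/O acceptors with an available lone pair,
# N-H/O-H donors, and a single protonation heuristic that treats aliphatic
# amine nitrogens as charged donors at assay pH.

default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                     F = 1, Cl = 1, Br = 1, I = 1, B = 3)

# adjacency list over all atoms (bond orders kept alongside)
bond_adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  ord <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]; o <- mol$bonds$order[i]
      adj[[a]] <- c(adj[[a]], b); ord[[a]] <- c(ord[[a]], o)
      adj[[b]] <- c(adj[[b]], a); ord[[b]] <- c(ord[[b]], o)
    }
  }
  list(nbr = adj, ord = ord)
}

# smallest rings: for every bond, the shortest cycle through it (BFS on the
# graph minus that bond); unique rings returned as ordered atom index vectors
find_rings <- function(mol) {
  adj <- bond_adjacency(mol)$nbr
  n <- n_atoms(mol)
  rings <- list()
  seen <- character(0)
  if (!nrow(mol$bonds)) return(rings)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    # BFS from a to b avoiding the a-b edge
    parent <- rep(NA_integer_, n)
    visited <- rep(FALSE, n)
    visited[a] <- TRUE
    queue <- a
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == a && w == b) next
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v
          if (w == b) { found <- TRUE; break }
          queue <- c(queue, w)
        }
      }
    }
    if (!found) next
    path <- b
    while (path[1] != a) path <- c(parent[path[1]], path)
    key <- paste(sort(path), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

# is an ordered ring aromatic? explicit aromatic flags win; otherwise an
# even-membered ring with strict single/double alternation passes
ring_is_aromatic <- function(mol, ring) {
  k <- length(ring)
  orders <- integer(k)
  for (i in seq_len(k)) {
    a <- ring[i]; b <- ring[if (i == k) 1L else i + 1L]
    hit <- which((mol$bonds$a1 == a & mol$bonds$a2 == b) |
                 (mol$bonds$a1 == b & mol$bonds$a2 == a))
    if (!length(hit)) return(FALSE)
    orders[i] <- mol$bonds$order[hit[1]]
  }
  if (all(orders == 4L)) return(TRUE)
  if (k %% 2L != 0L) return(FALSE)
  if (!all(orders %in% c(1L, 2L))) return(FALSE)
  all(orders[-k] + orders[-1] == 3L) && orders[1] + orders[k] == 3L
}

#' Perceive per-atom chemical roles
#'
#' Topology-only classification of every atom: aromaticity, implicit hydrogen
#' count (standard valence model, charge-adjusted), donor/acceptor roles, the
#' aliphatic-amine protonation heuristic, and the typed-atom-triangle (TAT)
#' type used by [tat_fingerprint] (`cation`, `anion`, `donor`, `acceptor`,
#' `hydrophobe`, `other`).
#'
#' @param mol A [molecule].
#' @return Data frame with one row per atom.
#' @export
perceive_atoms <- function(mol) {
  n <- n_atoms(mol)
  el <- mol$atoms$element
  chg <- mol$atoms$charge
  bd <- bond_adjacency(mol)
  rings <- find_rings(mol)
  aromatic <- rep(FALSE, n)
  for (r in rings) if (ring_is_aromatic(mol, r)) aromatic[r] <- TRUE

  bondsum <- vapply(seq_len(n), function(i) {
    o <- bd$ord[[i]]
    if (!length(o)) return(0)
    sum(ifelse(o == 4L, 1.5, o))
  }, 0)
  val <- ifelse(el %in% names(default_valence),
                default_valence[el] + chg, bondsum)
  implicit_h <- pmax(0L, as.integer(round(val - bondsum)))
  explicit_h <- vapply(seq_len(n), function(i)
    sum(el[bd$nbr[[i]]] == "H"), 0L)
  n_h <- implicit_h + explicit_h

  heavy_nbr_el <- lapply(seq_len(n), function(i) {
    nb <- bd$nbr[[i]]
    el[nb[el[nb] != "H"]]
  })

  # aliphatic amine N: neutral, non-aromatic, single bonds only, all heavy
  # neighbours carbon and none of them carbonyl/imine-like (conjugation guard)
  conjugated_c <- rep(FALSE, n)
  if (nrow(mol$bonds)) {
    dbl <- mol$bonds[mol$bonds$order %in% c(2L, 3L), , drop = FALSE]
    for (i in seq_len(nrow(dbl))) {
      a <- dbl$a1[i]; b <- dbl$a2[i]
      if (el[a] == "C" && el[b] %in% c("O", "N")) conjugated_c[a] <- TRUE
      if (el[b] == "C" && el[a] %in% c("O", "N")) conjugated_c[b] <- TRUE
    }
  }
  aliphatic_amine <- vapply(seq_len(n), function(i) {
    if (el[i] != "N" || chg[i] != 0L || aromatic[i]) return(FALSE)
    o <- bd$ord[[i]]
    if (length(o) == 0L || any(o != 1L)) return(FALSE)
    nb <- bd$nbr[[i]]
    heavy <- nb[el[nb] != "H"]
    if (!length(heavy) || any(el[heavy] != "C")) return(FALSE)
    !any(conjugated_c[heavy])
  }, FALSE)

  donor <- (el %in% c("N", "O") & n_h >= 1L) | aliphatic_amine
  acceptor <- vapply(seq_len(n), function(i) {
    if (chg[i] > 0L) return(FALSE)
    if (el[i] == "O") return(TRUE)
    if (el[i] != "N") return(FALSE)
    if (aliphatic_amine[i]) return(FALSE)   # treated as protonated
    if (aromatic[i]) return(n_h[i] == 0L)   # pyridine-like yes, pyrrole-like no
    TRUE
  }, FALSE)

  hydrophobe <- vapply(seq_len(n), function(i) {
    el[i] == "C" && (aromatic[i] || all(heavy_nbr_el[[i]] == "C"))
  }, FALSE)

  tat <- rep("other", n)
  tat[hydrophobe] <- "hydrophobe"
  tat[acceptor] <- "acceptor"
  tat[donor] <- "donor"
  tat[chg < 0L] <- "anion"
  tat[chg > 0L | aliphatic_amine] <- "cation"
  tat[el == "H"] <- "other"

  data.frame(element = el, charge = chg, aromatic = aromatic,
             implicit_h = implicit_h, n_h = n_h,
             aliphatic_amine = aliphatic_amine,
             donor = donor & el != "H", acceptor = acceptor & el != "H",
             tat_type = tat, stringsAsFactors = FALSE)
}

#' Perceive pharmacophoric feature points on one conformer
#'
#' Features are the three kinds a five-point pharmacophore query can ask for:
#' \describe{
#'   \item{hydrophobic_aromatic}{centroid of each smallest ring whose atoms are
#'     all aromatic, plus the centroid of each maximal connected patch of three
#'     or more aliphatic carbons having no non-carbon heavy neighbour;}
#'   \item{acceptor}{each N or O with an available lone pair and non-positive
#'     formal charge (ether and carbonyl oxygens, pyridine-type nitrogens);}
#'   \item{donor}{each N or O bearing at least one hydrogen (implicit
#'     hydrogens count), plus aliphatic amine nitrogens, which are treated as
#'     protonated at assay pH and therefore donate while no longer accepting.}
#' }
#'
#' @param mol A [molecule].
#' @param conformer_index 1-based conformer index.
#' @return Data frame with columns `kind`, `x`, `y`, `z`, `conformer_index`
#'   and a list-column `source_atoms` of contributing atom indices.
#' @export
perceive_features <- function(mol, conformer_index = 1L) {
  xyz <- get_conformer(mol, conformer_index)
  pa <- perceive_atoms(mol)
  feats <- list()
  add <- function(kind, pos, atoms_idx) {
    feats[[length(feats) + 1L]] <<- list(kind = kind, pos = pos,
                                         atoms = atoms_idx)
  }

  for (r in find_rings(mol)) {
    if (ring_is_aromatic(mol, r))
      add("hydrophobic_aromatic", colMeans(xyz[r, , drop = FALSE]), r)
  }

  # aliphatic hydrophobic patches
  hn <- bond_adjacency(mol)$nbr
  candidate <- vapply(seq_len(n_atoms(mol)), function(i) {
    if (pa$element[i] != "C" || pa$aromatic[i]) return(FALSE)
    heavy <- hn[[i]][pa$element[hn[[i]]] != "H"]
    all(pa$element[heavy] == "C")
  }, FALSE)
  comp <- rep(NA_integer_, n_atoms(mol))
  cid <- 0L
  for (s in which(candidate)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- hn[[v]]
      stack <- c(stack, nb[candidate[nb] & is.na(comp[nb])])
    }
  }
  if (cid > 0L) for (g in seq_len(cid)) {
    members <- which(comp == g)
    if (length(members) >= 3L)
      add("hydrophobic_aromatic", colMeans(xyz[members, , drop = FALSE]),
          members)
  }

  for (i in which(pa$acceptor)) add("acceptor", xyz[i, ], i)
  for (i in which(pa$donor)) add("donor", xyz[i, ], i)

  if (!length(feats))
    return(data.frame(kind = character(), x = double(), y = double(),
                      z = double(), conformer_index = integer(),
                      source_atoms = I(list())))
  out <- data.frame(
    kind = vapply(feats, `[[`, "", "kind"),
    x = vapply(feats, function(f) f$pos[1], 0),
    y = vapply(feats, function(f) f$pos[2], 0),
    z = vapply(feats, function(f) f$pos[3], 0),
    conformer_index = conformer_index)
  out$source_atoms <- I(lapply(feats, `[[`, "atoms"))
  out
}

# n x 3 coordinate matrix from a feature data frame
feature_coords <- function(features) {
  as.matrix(features[, c("x", "y", "z")])
}
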