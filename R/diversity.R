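#' Typed atom triangle (TAT) fingerprint of one conformer
#'
#' Every heavy atom is typed as one of cation, anion, donor, acceptor,
#' hydrophobe or other (see [perceive_atoms]). All heavy-atom trios containing
#' at least one non-"other" atom are enumerated; each trio is reduced to a
#' canonical triangle descriptor -- its three edges written as
#' (type, type, binned distance) with the two types sorted, the edge list
#' sorted lexicographically -- which makes the descriptor invariant to atom
#' reindexing and rigid motion. Distances are binned at 1 Angstrom over
#' [0, 15); longer edges fall in the last bin. The descriptor is hashed with
#' a deterministic polynomial string hash (base 131, modulus 2^31-1) to a bit
#' index; colliding descriptors OR into the same bit.
#'
#' @param mol A [molecule].
#' @param conformer_index 1-based conformer index.
#' @param n_bits Fingerprint length (default 2048).
#' @param bin_width Distance bin width in Angstrom (default 1).
#' @param max_dist Distance cap in Angstrom (default 15).
#' @return Object of class `fingerprint`: list with `id` and logical `bits`.
#'   Fewer than 3 heavy atoms gives an all-zero fingerprint.
#' @export
tat_fingerprint <- function(mol, conformer_index = 1L, n_bits = 2048L,
                            bin_width = 1, max_dist = 15) {
  xyz <- get_conformer(mol, conformer_index)
  pa <- perceive_atoms(mol)
  heavy <- which(pa$element != "H")
  bits <- logical(n_bits)
  if (length(heavy) >= 3L) {
    types <- pa$tat_type[heavy]
    hxyz <- xyz[heavy, , drop = FALSE]
    nbin <- as.integer(ceiling(max_dist / bin_width))
    dmat <- as.matrix(stats::dist(hxyz))
    binmat <- matrix(pmin(as.integer(dmat / bin_width), nbin - 1L),
                     nrow(dmat))
    trios <- utils::combn(length(heavy), 3L)
    for (c_ in seq_len(ncol(trios))) {
      i <- trios[1L, c_]; j <- trios[2L, c_]; k <- trios[3L, c_]
      if (types[i] == "other" && types[j] == "other" && types[k] == "other")
        next
      edges <- c(edge_descriptor(types[i], types[j], binmat[i, j]),
                 edge_descriptor(types[i], types[k], binmat[i, k]),
                 edge_descriptor(types[j], types[k], binmat[j, k]))
      desc <- paste(sort(edges), collapse = ";")
      bits[hash_string(desc) %% n_bits + 1L] <- TRUE
    }
  }
  structure(list(id = mol$id, bits = bits), class = "fingerprint")
}

edge_descriptor <- function(ta, tb, bin) {
  if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
  sprintf("%s|%s|%02d", ta, tb, bin)
}

# deterministic polynomial rolling hash over UTF-8 bytes:
# h <- (h * 131 + byte) mod (2^31 - 1); platform-independent
hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint '%s': %d/%d bits set>\n", x$id, sum(x$bits),
              length(x$bits)))
  invisible(x)
}

#' Fingerprint as a hexadecimal string
#' @param fp A `fingerprint`.
#' @return Hex string, 4 bits per character, most significant bit first.
#' @export
fingerprint_hex <- function(fp) {
  bits <- fp$bits
  pad <- (4 - length(bits) %% 4) %% 4
  bits <- c(bits, logical(pad))
  nib <- matrix(as.integer(bits), nrow = 4)
  vals <- colSums(nib * c(8, 4, 2, 1))
  paste(sprintf("%x", vals), collapse = "")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A AND B| / |A OR B|` over set bits; defined as 1 when both fingerprints
#' are all-zero (two featureless objects are indistinguishable).
#'
#' @param a,b `fingerprint` objects of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a$bits) != length(b$bits))
    stop("fingerprint lengths differ (", length(a$bits), " vs ",
         length(b$bits), ")")
  u <- sum(a$bits | b$bits)
  if (u == 0L) return(1.0)
  sum(a$bits & b$bits) / u
}

#' Jarvis-Patrick (shared-nearest-neighbour) clustering of fingerprints
#'
#' Neighbour lists are the `K` nearest items by Tanimoto distance
#' (1 - coefficient), self excluded, ties broken by ascending item id (then
#' input position), so the partition does not depend on input order.
#' Two items join iff each appears in the other's neighbour list and their
#' lists share at least `J` common members; clusters are the connected
#' components of the join graph. Cluster labels are non-negative integers,
#' contiguous from 0, assigned in order of each cluster's smallest member
#' index.
#'
#' @param fps List of `fingerprint` objects (equal lengths).
#' @param K Neighbour list size (clipped to n - 1).
#' @param J Required shared-neighbour count.
#' @return Object of class `cluster_assignment`: list with `labels` (named
#'   integer vector, item id -> cluster), `K`, `J`.
#' @export
jarvis_patrick <- function(fps, K = 10L, J = 6L) {
  n <- length(fps)
  if (n < 1L) stop("need at least one fingerprint")
  ids <- vapply(fps, function(f) f$id, "")
  if (n == 1L)
    return(structure(list(labels = stats::setNames(0L, ids), K = 0L, J = J),
                     class = "cluster_assignment"))
  K <- min(as.integer(K), n - 1L)
  M <- do.call(rbind, lapply(fps, function(f) as.integer(f$bits)))
  inter <- tcrossprod(M)
  pop <- diag(inter)
  union <- outer(pop, pop, "+") - inter
  sim <- ifelse(union == 0, 1, inter / pmax(union, 1L))
  dists <- 1 - sim

  nl <- vector("list", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(dists[i, others], ids[others], others)]
    nl[[i]] <- ord[seq_len(K)]
  }

  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (!(j %in% nl[[i]]) || !(i %in% nl[[j]])) next
    if (length(intersect(nl[[i]], nl[[j]])) < J) next
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), find, 0L)
  first_seen <- unique(roots)
  labels <- match(roots, first_seen) - 1L
  structure(list(labels = stats::setNames(labels, ids), K = K, J = as.integer(J)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: %d items, %d clusters (K=%d, J=%d)>\n",
              length(x$labels), length(unique(x$labels)), x$K, x$J))
  invisible(x)
}

#' Pick one representative per cluster by score
#'
#' The highest-scoring member of each cluster is chosen (the diversity-set
#' analogue of keeping the best-docked molecule per chemotype); score ties
#' resolve to the lexicographically smallest id.
#'
#' @param clusters A `cluster_assignment`.
#' @param scores Named numeric vector, id -> score (e.g. pose scores).
#' @return Character vector of representative ids, ordered by cluster label.
#' @export
select_representatives <- function(clusters, scores) {
  ids <- names(clusters$labels)
  missing <- setdiff(ids, names(scores))
  if (length(missing))
    stop("no score for id(s): ", paste(missing, collapse = ", "))
  out <- character(0)
  for (lab in sort(unique(clusters$labels))) {
    members <- sort(ids[clusters$labels == lab])
    s <- scores[members]
    out <- c(out, members[which.max(s)])   # which.max: first (smallest id) wins ties
  }
  out
}

#' Write fingerprints as a hex TSV
#' @param fps List of fingerprints.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fingerprints <- function(fps, path) {
  df <- data.frame(id = vapply(fps, function(f) f$id, ""),
                   n_bits = vapply(fps, function(f) length(f$bits), 0L),
                   hex = vapply(fps, fingerprint_hex, ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
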