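#' Match one conformer's features against a pharmacophore query
#'
#' Enumerates injective assignments of kind-compatible features to all query
#' points, depth-first in query-point order with feature indices ascending.
#' A partial assignment is pruned as soon as one feature-pair distance
#' deviates from the corresponding center-pair distance by more than the sum
#' of the two sphere radii (no rigid motion could then satisfy both spheres).
#' Each surviving complete assignment is superposed onto the centers by
#' closed-form least squares ([kabsch_superpose] machinery, det +1) and
#' accepted iff every transformed feature lies inside its point's sphere.
#' The accepted assignment of minimal RMSD wins; exact ties resolve to the
#' lexicographically smallest assignment (point order, then feature index),
#' which is the first one the enumeration visits.
#'
#' @param features Feature data frame from [perceive_features] (one
#'   conformer).
#' @param q A [pharmacophore_query].
#' @param mol_id,conformer_index Optional identifiers carried into the result.
#' @return A `match_result` (list with `assignment`, `rotation`,
#'   `translation`, `per_point_residual`, `rmsd`), or `NULL` when no
#'   assignment is accepted (including when some kind has too few features).
#' @export
match_conformer <- function(features, q, mol_id = NULL,
                            conformer_index = NULL) {
  m <- nrow(q)
  fxyz <- feature_coords(features)
  centers <- query_centers(q)
  radii <- q$radius
  cand <- lapply(seq_len(m), function(i) which(features$kind == q$kind[i]))
  if (any(vapply(cand, length, 0L) == 0L)) return(NULL)
  if (nrow(features) < m) return(NULL)

  qd <- as.matrix(stats::dist(centers))
  fd <- as.matrix(stats::dist(fxyz))

  best <- NULL
  assign_vec <- integer(m)
  used <- rep(FALSE, nrow(features))

  recurse <- function(i) {
    if (i > m) {
      fit <- kabsch_fit(fxyz[assign_vec, , drop = FALSE], centers)
      moved <- apply_rigid(fxyz[assign_vec, , drop = FALSE],
                           fit$rotation, fit$translation)
      resid <- sqrt(rowSums((moved - centers)^2))
      if (all(resid <= radii + 1e-9)) {
        rmsd <- sqrt(mean(resid^2))
        if (is.null(best) || rmsd < best$rmsd - 1e-12) {
          best <<- list(assignment = assign_vec, rotation = fit$rotation,
                        translation = fit$translation, residual = resid,
                        rmsd = rmsd)
        }
      }
      return(invisible(NULL))
    }
    for (f in cand[[i]]) {
      if (used[f]) next
      ok <- TRUE
      if (i > 1L) for (j in seq_len(i - 1L)) {
        if (abs(fd[f, assign_vec[j]] - qd[i, j]) > radii[i] + radii[j]) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_vec[i] <<- f
      used[f] <<- TRUE
      recurse(i + 1L)
      used[f] <<- FALSE
    }
    invisible(NULL)
  }
  recurse(1L)
  if (is.null(best)) return(NULL)

  structure(list(
    mol_id = mol_id,
    conformer_index = conformer_index,
    assignment = stats::setNames(best$assignment, q$label),
    rotation = best$rotation,
    translation = best$translation,
    per_point_residual = stats::setNames(best$residual, q$label),
    rmsd = best$rmsd), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match%s%s: rmsd %.3f A>\n",
              if (is.null(x$mol_id)) "" else paste0(" ", x$mol_id),
              if (is.null(x$conformer_index)) "" else
                paste0(" conformer ", x$conformer_index),
              x$rmsd))
  print(round(x$per_point_residual, 3))
  invisible(x)
}

#' Screen a conformer library against a pharmacophore query
#'
#' Runs [perceive_features] + [match_conformer] on every conformer of every
#' molecule. One hit row is produced per matching (molecule, conformer); the
#' full `match_result` objects are attached as the `"matches"` attribute for
#' downstream pose placement. Per-run summary counts (molecules screened,
#' molecules hit, conformers hit) are reported via `message()`.
#'
#' @param mols List of [molecule] objects with at least one conformer each.
#' @param q A [pharmacophore_query].
#' @param verbose Emit the summary message (default `TRUE`).
#' @return Data frame with columns `mol_id`, `conformer_index`, `rmsd` and one
#'   `resid_<label>` column per query point; attribute `"matches"` holds the
#'   corresponding `match_result` list, attribute `"summary"` the counts.
#' @export
screen_library <- function(mols, q, verbose = TRUE) {
  rows <- list()
  matches <- list()
  for (mol in mols) {
    if (n_conformers(mol) < 1L)
      stop("molecule '", mol$id, "' has no conformers")
    for (k in seq_len(n_conformers(mol))) {
      feats <- perceive_features(mol, k)
      res <- match_conformer(feats, q, mol_id = mol$id, conformer_index = k)
      if (!is.null(res)) {
        row <- data.frame(mol_id = mol$id, conformer_index = k,
                          rmsd = res$rmsd)
        for (lb in q$label)
          row[[paste0("resid_", lb)]] <- res$per_point_residual[[lb]]
        rows[[length(rows) + 1L]] <- row
        matches[[length(matches) + 1L]] <- res
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else {
    out <- data.frame(mol_id = character(), conformer_index = integer(),
                      rmsd = double())
    for (lb in q$label) out[[paste0("resid_", lb)]] <- double()
    out
  }
  summary <- c(molecules_screened = length(mols),
               molecules_hit = length(unique(hits$mol_id)),
               conformers_hit = nrow(hits))
  if (verbose)
    message(sprintf(
      "screen_library: %d molecules screened, %d molecules hit, %d conformers hit",
      summary[1], summary[2], summary[3]))
  attr(hits, "matches") <- matches
  attr(hits, "summary") <- summary
  hits
}

#' Best match per molecule from a screening hit table
#'
#' A molecule fulfils the query if at least one conformer matches; for pose
#' work the minimal-RMSD conformer per molecule is kept.
#'
#' @param hits Hit table from [screen_library].
#' @return Subset of `hits` (one row per molecule) with pruned `"matches"`.
#' @export
best_hits_per_molecule <- function(hits) {
  matches <- attr(hits, "matches")
  if (!nrow(hits)) return(hits)
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$mol_id),
                        function(ix) ix[which.min(hits$rmsd[ix])]))
  keep <- sort(unname(keep))
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "matches") <- matches[keep]
  attr(out, "summary") <- attr(hits, "summary")
  out
}
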