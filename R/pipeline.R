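#' Run the full screening funnel
#'
#' Screen -> best-conformer pose placement -> clash filter + local refinement
#' with pharmacophore re-check -> TAT fingerprints on the pose geometry ->
#' Jarvis-Patrick clustering -> per-cluster best-scoring representatives.
#' Stage counts are logged and collected in a run manifest whose funnel
#' counts are non-increasing by construction.
#'
#' @param library Path to an SDF library, or a list of [molecule] objects.
#' @param query `"canonical"`, a query JSON path, or a
#'   [pharmacophore_query].
#' @param receptor Path to a receptor PDB, a [receptor_cloud], or `NULL` to
#'   generate a synthetic shell around the query.
#' @param out_dir Output directory for hit TSV, pose SDF, fingerprint TSV,
#'   cluster TSV, representative list and `manifest.json`; `NULL` writes
#'   nothing.
#' @param config Named list overriding defaults: `clash_distance` (2.0),
#'   `contact_distance` (4.5), `n_bits` (2048), `bin_width` (1),
#'   `max_dist` (15), `K` (10), `J` (6), `seed` (1).
#' @return The run manifest (list), invisibly carrying `poses`,
#'   `representatives`, `clusters` and `hits` as attributes.
#' @export
run_screening_pipeline <- function(library, query = "canonical",
                                   receptor = NULL, out_dir = NULL,
                                   config = list()) {
  cfg <- utils::modifyList(list(clash_distance = 2.0, contact_distance = 4.5,
                                n_bits = 2048L, bin_width = 1, max_dist = 15,
                                K = 10L, J = 6L, seed = 1L), config)
  q <- if (inherits(query, "pharmacophore_query")) query
    else if (identical(query, "canonical")) canonical_query()
    else read_query(query)
  mols <- if (is.character(library)) read_molecules(library, "sdf")
    else library
  rec <- if (is.null(receptor))
      generate_receptor_stub(q, seed = cfg$seed)
    else if (inherits(receptor, "receptor_cloud")) receptor
    else read_receptor(receptor)

  hits <- screen_library(mols, q)
  best <- best_hits_per_molecule(hits)
  matches <- attr(best, "matches")
  mol_by_id <- stats::setNames(mols, vapply(mols, function(m) m$id, ""))

  poses <- lapply(matches, function(mm) place_by_match(mol_by_id[[mm$mol_id]],
                                                       mm))
  refined <- refine_and_filter(poses, rec, q,
                               clash_distance = cfg$clash_distance,
                               contact_distance = cfg$contact_distance,
                               seed = cfg$seed)
  message(sprintf("pose funnel: %d placed, %d survive refinement",
                  length(poses), length(refined)))

  fps <- lapply(refined, function(p)
    tat_fingerprint(pose_molecule(p), 1L, n_bits = cfg$n_bits,
                    bin_width = cfg$bin_width, max_dist = cfg$max_dist))
  scores <- vapply(refined, function(p) p$score, 0)
  names(scores) <- vapply(refined, function(p) p$mol_id, "")
  clusters <- NULL
  reps <- character(0)
  if (length(fps)) {
    clusters <- jarvis_patrick(fps, K = cfg$K, J = cfg$J)
    reps <- select_representatives(clusters, scores)
    message(sprintf("diversity: %d clusters, %d representatives",
                    length(unique(clusters$labels)), length(reps)))
  }

  manifest <- list(
    tool = paste0("phorekit ",
                  as.character(utils::packageVersion("phorekit"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    counts = list(
      molecules_screened = length(mols),
      molecules_matched = length(unique(best$mol_id)),
      conformers_matched = nrow(hits),
      post_refinement = length(refined),
      clusters = if (is.null(clusters)) 0L
        else length(unique(clusters$labels)),
      representatives = length(reps)))
  stopifnot(with(manifest$counts,
                 molecules_screened >= molecules_matched &&
                 molecules_matched >= post_refinement &&
                 post_refinement >= representatives))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(hits, file.path(out_dir, "hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (length(refined)) write_poses(refined, file.path(out_dir, "poses.sdf"))
    if (length(fps)) {
      write_fingerprints(fps, file.path(out_dir, "fingerprints.tsv"))
      utils::write.table(
        data.frame(id = names(clusters$labels),
                   cluster = unname(clusters$labels)),
        file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      writeLines(reps, file.path(out_dir, "representatives.txt"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(manifest, "hits") <- hits
  attr(manifest, "poses") <- refined
  attr(manifest, "clusters") <- clusters
  attr(manifest, "representatives") <- reps
  manifest
}

#' Run a kinetics analysis from a CSV (or data frame)
#'
#' @param input CSV path or data frame. Schemas by mode:
#'   \describe{
#'     \item{competition}{`substrate_uM`, `inhibitor_uM`, `replicate`,
#'       `velocity`; fits Michaelis-Menten per inhibitor condition and calls
#'       the inhibition mode;}
#'     \item{ic50}{`dose_uM`, `response`; fits the 4PL curve;}
#'     \item{mutant}{`variant`, `with_ligand`, `without_ligand`; normalises
#'       inhibition within each variant.}
#'   }
#' @param mode `"competition"`, `"ic50"` or `"mutant"`.
#' @param out Optional JSON report path.
#' @param config Named list: `fitter` (`"nonlinear"` default or
#'   `"lineweaver_burk"`), `km_threshold`, `vmax_threshold`.
#' @return Report list (also written as JSON when `out` is given).
#' @export
run_kinetics_analysis <- function(input, mode = c("competition", "ic50",
                                                  "mutant"),
                                  out = NULL, config = list()) {
  mode <- match.arg(mode)
  cfg <- utils::modifyList(list(fitter = "nonlinear", km_threshold = 0.25,
                                vmax_threshold = 0.15), config)
  df <- if (is.character(input)) utils::read.csv(input) else input

  report <- switch(mode,
    competition = {
      needed <- c("substrate_uM", "inhibitor_uM", "replicate", "velocity")
      missing <- setdiff(needed, names(df))
      if (length(missing))
        stop("competition CSV is missing column(s): ",
             paste(missing, collapse = ", "))
      d <- kinetics_dataset(df$substrate_uM, df$velocity, df$inhibitor_uM,
                            df$replicate)
      fitter <- if (cfg$fitter == "lineweaver_burk") fit_lineweaver_burk
        else fit_mm_nonlinear
      levels <- sort(unique(d$inhibitor))
      if (!0 %in% levels) stop("competition data needs a control ([I] = 0)")
      fits <- lapply(levels, function(i) fitter(d, i))
      call <- classify_inhibition(fits[[1]], fits[-1],
                                  km_threshold = cfg$km_threshold,
                                  vmax_threshold = cfg$vmax_threshold)
      list(mode = "competition",
           fits = lapply(fits, function(f)
             list(inhibitor_uM = f$inhibitor, Km_uM = f$Km, Vmax = f$Vmax,
                  method = f$method)),
           call = list(mode = call$mode, Ki_uM = call$Ki, r_Km = call$r_Km,
                       r_Vmax = call$r_Vmax),
           thresholds = list(km = cfg$km_threshold,
                             vmax = cfg$vmax_threshold))
    },
    ic50 = {
      missing <- setdiff(c("dose_uM", "response"), names(df))
      if (length(missing))
        stop("ic50 CSV is missing column(s): ",
             paste(missing, collapse = ", "))
      fit <- fit_ic50(df$dose_uM, df$response)
      list(mode = "ic50", IC50_uM = fit$IC50, hill = fit$hill, top = fit$top,
           bottom = fit$bottom, rss = fit$rss)
    },
    mutant = {
      missing <- setdiff(c("variant", "with_ligand", "without_ligand"),
                         names(df))
      if (length(missing))
        stop("mutant CSV is missing column(s): ",
             paste(missing, collapse = ", "))
      tab <- normalize_mutant_inhibition(df$with_ligand, df$without_ligand,
                                         df$variant)
      list(mode = "mutant", inhibition = tab)
    })
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  report
}
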