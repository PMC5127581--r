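#' Read molecules from SDF or a SMILES table
#'
#' SDF (V2000) records that share an identifier and an identical chemical
#' graph are merged into a single multi-conformer molecule, which is how
#' conformer libraries are normally shipped. A SMILES table (TSV with columns
#' id, smiles) yields topology-only molecules with zero conformers.
#'
#' Formal charges are taken from the atom-block charge column (V2000 coded
#' values). SDF data items become molecule properties, coerced to numeric
#' where possible.
#'
#' @param path Path to the input file.
#' @param format Either `"sdf"` or `"smiles_table"`.
#' @return List of [molecule] objects.
#' @export
read_molecules <- function(path, format = c("sdf", "smiles_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "sdf") read_sdf_molecules(path) else read_smiles_table(path)
}

read_sdf_molecules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    stop("empty SDF file: ", path)
  }
  sdfset <- ChemmineR::read.SDFset(path)
  if (length(sdfset) == 0L) stop("no SDF records in ", path)
  ok <- ChemmineR::validSDF(sdfset)
  if (!all(ok))
    stop("unparseable SDF record(s) at index: ",
         paste(which(!ok), collapse = ", "))
  mols <- lapply(seq_along(sdfset), function(i) sdf_to_molecule(sdfset[[i]], i))
  merge_conformer_records(mols)
}

# decode one ChemmineR SDF object into a single-conformer molecule
sdf_to_molecule <- function(sdf, record_index) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  hd <- ChemmineR::header(sdf)
  id <- trimws(hd[["Molecule_Name"]])
  if (!nzchar(id)) id <- paste0("record_", record_index)
  element <- sub("_.*$", "", rownames(ab))
  # V2000 charge codes live in the 5th atom-block field (after x,y,z,massdiff)
  charge <- integer(nrow(ab))
  if ("C6" %in% colnames(ab)) {
    code <- ab[, "C6"]
    charge <- ifelse(code %in% c(1, 2, 3, 5, 6, 7), 4L - as.integer(code), 0L)
  }
  bonds <- if (is.matrix(bb) && nrow(bb)) {
    data.frame(a1 = bb[, 1], a2 = bb[, 2], order = bb[, 3])
  } else NULL
  props <- as.list(ChemmineR::datablock(sdf))
  props <- lapply(props, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  molecule(id,
           atoms = data.frame(element = element, charge = charge),
           bonds = bonds,
           conformers = list(unname(ab[, 1:3, drop = FALSE])),
           properties = props)
}

# merge consecutive-by-id records with identical topology into multi-conformer
# molecules; same id with a different graph is an input error
merge_conformer_records <- function(mols) {
  ids <- vapply(mols, function(m) m$id, "")
  out <- list()
  for (id in unique(ids)) {
    group <- mols[ids == id]
    base <- group[[1]]
    for (m in group[-1]) {
      if (!identical(base$atoms, m$atoms) || !identical(base$bonds, m$bonds))
        stop("SDF records with id '", id, "' have differing topology; ",
             "cannot merge conformers")
      base$conformers <- c(base$conformers, m$conformers)
      base$properties <- utils::modifyList(base$properties, m$properties)
    }
    out[[length(out) + 1L]] <- base
  }
  out
}

read_smiles_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "smiles"),
                           colClasses = "character")
  if (nrow(tab) && tolower(trimws(tab$id[1])) == "id")
    tab <- tab[-1, , drop = FALSE]
  if (!nrow(tab)) stop("empty SMILES table: ", path)
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES input requires the ChemmineOB package")
  lapply(seq_len(nrow(tab)), function(i) {
    id <- trimws(tab$id[i])
    smi <- trimws(tab$smiles[i])
    m <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smi, id)))
      sdf_to_molecule(sdf[[1]], i)
    }, error = function(e) stop("cannot parse SMILES record ", i, " ('", id,
                                "'): ", conditionMessage(e)))
    m$id <- id
    m$conformers <- list()   # SMILES carries no 3D information
    m
  })
}

#' Write molecules to an SDF file
#'
#' Writes one V2000 record per conformer (multi-conformer molecules become
#' consecutive records sharing the molecule id, the inverse of the
#' [read_molecules] merge rule). Properties are written as SDF data items and
#' formal charges as coded atom-block charges.
#'
#' @param mols List of [molecule] objects, each with at least one conformer.
#' @param path Output file path.
#' @return Invisibly, the output path.
#' @export
write_molecules <- function(mols, path) {
  if (length(mols) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  sdfs <- list()
  for (m in mols) {
    if (n_conformers(m) < 1L)
      stop("molecule '", m$id, "' has no conformers; cannot write SDF")
    for (k in seq_len(n_conformers(m)))
      sdfs[[length(sdfs) + 1L]] <- molecule_to_sdf(m, k)
  }
  ids <- make.unique(vapply(sdfs, function(s)
    ChemmineR::header(s)[["Molecule_Name"]], ""))
  sdfset <- methods::new("SDFset", SDF = sdfs, ID = ids)
  # cid = FALSE: each record's own header line carries the molecule id, so
  # conformer records of one molecule share it (the read-side merge key)
  ChemmineR::write.SDF(sdfset, file = path, cid = FALSE)
  invisible(path)
}

molecule_to_sdf <- function(m, conformer_index) {
  xyz <- round(m$conformers[[conformer_index]], 4)
  n <- nrow(xyz)
  ab <- cbind(xyz, matrix(0L, n, 13))
  chg <- m$atoms$charge
  ab[, 5] <- ifelse(chg != 0L & abs(chg) <= 3L, 4L - chg, 0L)
  rownames(ab) <- paste(m$atoms$element, seq_len(n), sep = "_")
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:17))
  nb <- nrow(m$bonds)
  bb <- cbind(as.matrix(m$bonds[, c("a1", "a2", "order")]), matrix(0L, nb, 4))
  rownames(bb) <- if (nb) seq_len(nb) else NULL
  colnames(bb) <- paste0("C", 1:7)
  db <- character(0)
  if (length(m$properties))
    db <- vapply(m$properties, function(v) as.character(v)[1], "",
                 USE.NAMES = TRUE)
  methods::new("SDF",
               header = c(Molecule_Name = m$id, Source = "phorekit",
                          Comment = "",
                          Counts_Line = sprintf(
                            "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)),
               atomblock = ab, bondblock = bb, datablock = db)
}

#' Read a pharmacophore hit table written by [screen_library]
#' @param path TSV path.
#' @return Data frame of hits.
#' @export
read_hit_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
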