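.ENSEMBLE_SCHEMA_VERSION <- 1L

#' Write a charge ensemble (with conformers) to a JSON archive
#'
#' A versioned, self-contained plain-text archive of a study unit: the
#' molecular graph, the conformer geometries, and every charge set with its
#' provenance. Atom indices in the file are 0-based (the convention used by
#' all of the package's file formats and CLI); the in-memory API is 1-based.
#' Round-trips losslessly through [read_ensemble_json()].
#'
#' @param ens a `charge_ensemble`.
#' @param conformers list of `conformer` objects referenced by the ensemble's
#'   charge sets (may be empty for conformer-independent sets).
#' @param path output file path.
#' @param provenance optional list of parameters/seeds to embed.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(ens, conformers = list(), path,
                                provenance = attr(ens, "provenance")) {
  stopifnot(inherits(ens, "charge_ensemble"))
  mol <- ens$molecule
  bonds0 <- mol$bonds
  bonds0[, c("u", "v")] <- bonds0[, c("u", "v")] - 1L
  obj <- list(
    schema_version = .ENSEMBLE_SCHEMA_VERSION,
    provenance = provenance,
    molecule = list(name = mol$name, elements = mol$elements,
                    formal_charges = mol$formal_charges,
                    bonds = as.data.frame(bonds0)),
    conformers = lapply(conformers, function(cf)
      list(id = cf$id, coords = unname(cf$coords))),
    charge_sets = lapply(ens$sets, function(s)
      list(method = s$method, conformer_id = s$conformer_id,
           platform = s$platform, charges = s$charges)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a charge ensemble JSON archive
#'
#' Rejects unknown schema versions and enforces referential integrity: every
#' charge set whose `conformer_id` is not `NA` must reference a conformer
#' present in the archive (when the archive carries any conformers at all).
#'
#' @param path JSON archive path (see [write_ensemble_json()]).
#' @return list with `molecule` (`mol_graph`), `conformers` (list of
#'   `conformer`), `ensemble` (`charge_ensemble`), and `provenance`.
#' @export
read_ensemble_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) ||
      obj$schema_version != .ENSEMBLE_SCHEMA_VERSION)
    stop(sprintf("unsupported ensemble archive schema version: %s",
                 as.character(obj$schema_version)))
  mb <- obj$molecule
  bonds <- mb$bonds
  bonds$u <- bonds$u + 1L
  bonds$v <- bonds$v + 1L
  mol <- mol_graph(mb$elements, bonds, mb$formal_charges, name = mb$name)
  confs <- list()
  if (length(obj$conformers)) {
    # simplifyVector folds the records into a data.frame of (id, coords)
    ids <- obj$conformers$id
    confs <- lapply(seq_along(ids), function(i)
      conformer(obj$conformers$coords[[i]], mol, id = ids[i]))
    names(confs) <- ids
  }
  cs <- obj$charge_sets
  sets <- lapply(seq_len(nrow(cs)), function(i) {
    cid <- cs$conformer_id[i]
    if (length(confs) > 0L && !is.na(cid) && cid != "NA" &&
        !grepl("\\+", cid) && !cid %in% names(confs))
      stop(sprintf("charge set %d references missing conformer '%s'", i, cid))
    charge_set(cs$charges[[i]], mol, method = cs$method[i],
               conformer_id = cid, platform = cs$platform[i])
  })
  list(molecule = mol, conformers = unname(confs),
       ensemble = charge_ensemble(mol, sets), provenance = obj$provenance)
}

#' Write per-molecule variability metrics to CSV
#'
#' Columns: `molecule`, `n_sets`, `max_partial_charge_diff_e`,
#' `max_dqbond_diff_e`, `argmax_atom`, `argmax_bond`. Indices in the file
#' are 0-based, matching the package's file/CLI convention.
#'
#' @param reports list of `variability_report` objects.
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
write_metrics_csv <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r) data.frame(
    molecule = r$molecule, n_sets = r$n_sets,
    max_partial_charge_diff_e = r$max_atom_range,
    max_dqbond_diff_e = r$max_bond_range,
    argmax_atom = r$argmax_atom - 1L,
    argmax_bond = if (is.na(r$argmax_bond)) NA_integer_ else r$argmax_bond - 1L,
    stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a variability metrics CSV
#' @param path CSV path written by [write_metrics_csv()].
#' @return data.frame of per-molecule metrics.
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a stratified selection to CSV
#'
#' One row per selected molecule with its metric value and stratum
#' (`good` / `average` / `bad`).
#'
#' @param sel a `stratified_selection`.
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
write_selection_csv <- function(sel, path) {
  stopifnot(inherits(sel, "stratified_selection"))
  rows <- do.call(rbind, lapply(c("good", "average", "bad"), function(s) {
    if (length(sel[[s]]) == 0L) return(NULL)
    data.frame(id = sel[[s]], value = unname(sel$values[sel[[s]]]),
               stratum = s, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(id = character(0), value = numeric(0),
                       stratum = character(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
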