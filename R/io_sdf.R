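#' Write molecules to an SDF (V2000) file
#'
#' One record per entry: molfile header, atom and bond blocks, `M  CHG`
#' lines for non-zero formal charges, then data fields. Partial charges go
#' to a `PARTIAL_CHARGES` field (6 decimal places, whitespace-separated in
#' atom order, wrapped 8 per line); charge provenance and the conformer id
#' are carried in `CHARGE_METHOD`, `CONFORMER_ID` and `PLATFORM` fields.
#' Output is byte-deterministic for fixed input.
#'
#' @param records list of records, each a list with elements `molecule`
#'   (`mol_graph`), `conformer` (`conformer`) and optionally `charges`
#'   (`charge_set`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(records, path) {
  out <- character(0)
  for (rec in records) {
    mol <- rec$molecule
    conf <- rec$conformer
    stopifnot(inherits(mol, "mol_graph"), inherits(conf, "conformer"))
    n <- n_atoms(mol)
    nb <- nrow(mol$bonds)
    out <- c(out, mol$name, "  chargevar          3D", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    for (i in seq_len(n)) {
      out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            conf$coords[i, 1], conf$coords[i, 2],
                            conf$coords[i, 3], mol$elements[i]))
    }
    for (b in seq_len(nb)) {
      out <- c(out, sprintf("%3d%3d%3d  0", mol$bonds[b, "u"],
                            mol$bonds[b, "v"], mol$bonds[b, "order"]))
    }
    chg <- which(mol$formal_charges != 0L)
    while (length(chg) > 0L) {
      batch <- chg[seq_len(min(8L, length(chg)))]
      chg <- chg[-seq_along(batch)]
      out <- c(out, paste0(sprintf("M  CHG%3d", length(batch)),
                           paste0(sprintf("%4d%4d", batch,
                                          mol$formal_charges[batch]),
                                  collapse = "")))
    }
    out <- c(out, "M  END")
    field <- function(name, lines) c(sprintf(">  <%s>", name), lines, "")
    out <- c(out, field("CONFORMER_ID", conf$id))
    if (!is.null(rec$charges)) {
      q <- rec$charges
      stopifnot(inherits(q, "charge_set"))
      if (length(q$charges) != n)
        stop("charge count does not equal atom count")
      vals <- sprintf("%.6f", q$charges)
      lines <- vapply(split(vals, ceiling(seq_along(vals) / 8)),
                      paste, character(1), collapse = " ")
      out <- c(out, field("PARTIAL_CHARGES", unname(lines)),
               field("CHARGE_METHOD", q$method))
      if (!is.na(q$platform)) out <- c(out, field("PLATFORM", q$platform))
    }
    out <- c(out, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

.parse_int_field <- function(line, from, to, what) {
  x <- suppressWarnings(as.integer(trimws(substr(line, from, to))))
  if (is.na(x)) stop(sprintf("malformed %s in line: '%s'", what, line))
  x
}

# data fields of one record: named list of character vectors
.parse_data_fields <- function(lines) {
  fields <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^>", lines[i])) {
      nm <- sub(".*<([^>]+)>.*", "\\1", lines[i])
      j <- i + 1L
      vals <- character(0)
      while (j <= length(lines) && nzchar(trimws(lines[j]))) {
        vals <- c(vals, lines[j])
        j <- j + 1L
      }
      fields[[nm]] <- vals
      i <- j
    }
    i <- i + 1L
  }
  fields
}

#' Read an SDF (V2000) file
#'
#' Parses each record into a molecule, a conformer, and -- when present -- a
#' charge set. Charges are taken from a `PARTIAL_CHARGES` data field
#' (whitespace-separated values in atom order) or, failing that, from
#' per-atom lines of an `atom.dprop.PartialCharge` field. Malformed counts
#' lines and charge-count mismatches are rejected, never repaired.
#'
#' @param path SDF file path.
#' @return list of records, each a list with `molecule`, `conformer`, and
#'   `charges` (a `charge_set`, or `NULL` when no charge field is present).
#' @export
read_sdf <- function(path) {
  lines <- readLines(path)
  # split on record terminators
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0L && length(lines) > 0L && any(nzchar(lines)))
    stop("no SDF record terminator ($$$$) found")
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- list()
  for (r in seq_along(ends)) {
    block <- lines[starts[r]:(ends[r] - 1L)]
    if (length(block) < 4L) stop("truncated SDF record")
    name <- block[1L]
    counts <- block[4L]
    na <- .parse_int_field(counts, 1L, 3L, "counts line (atom count)")
    nb <- .parse_int_field(counts, 4L, 6L, "counts line (bond count)")
    if (length(block) < 4L + na + nb) stop("truncated SDF record body")
    atoms <- block[4L + seq_len(na)]
    coords <- t(vapply(atoms, function(l) {
      xyz <- suppressWarnings(as.numeric(c(substr(l, 1, 10), substr(l, 11, 20),
                                           substr(l, 21, 30))))
      if (anyNA(xyz)) stop(sprintf("malformed atom line: '%s'", l))
      xyz
    }, numeric(3)))
    rownames(coords) <- NULL
    elements <- vapply(atoms, function(l) trimws(substr(l, 32, 34)), character(1),
                       USE.NAMES = FALSE)
    bonds <- if (nb > 0L) {
      t(vapply(block[4L + na + seq_len(nb)], function(l)
        c(.parse_int_field(l, 1L, 3L, "bond line"),
          .parse_int_field(l, 4L, 6L, "bond line"),
          .parse_int_field(l, 7L, 9L, "bond line")), integer(3)))
    } else matrix(integer(0), ncol = 3L)
    fc <- integer(na)
    for (l in grep("^M  CHG", block, value = TRUE)) {
      tok <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
      cnt <- tok[1L]
      for (k in seq_len(cnt)) fc[tok[2 * k]] <- tok[2 * k + 1L]
    }
    mol <- mol_graph(elements, bonds, fc, name = name)
    fields <- .parse_data_fields(block)
    conf_id <- if (!is.null(fields$CONFORMER_ID)) fields$CONFORMER_ID[1] else name
    conf <- conformer(coords, mol, id = conf_id)
    charges <- NULL
    if (!is.null(fields$PARTIAL_CHARGES)) {
      q <- as.numeric(strsplit(trimws(paste(fields$PARTIAL_CHARGES, collapse = " ")),
                               "\\s+")[[1]])
      if (length(q) != na)
        stop(sprintf("record '%s': %d charges for %d atoms", name, length(q), na))
      method <- if (!is.null(fields$CHARGE_METHOD)) fields$CHARGE_METHOD[1]
                else "unspecified"
      platform <- if (!is.null(fields$PLATFORM)) fields$PLATFORM[1] else NA_character_
      # charges are quantized to 1e-6 in the file: allow half an ulp per atom
      charges <- charge_set(q, mol, method = method, conformer_id = conf_id,
                            platform = platform,
                            tol = max(1e-6, na * 5e-7))
    } else if (!is.null(fields$atom.dprop.PartialCharge)) {
      q <- suppressWarnings(as.numeric(trimws(fields$atom.dprop.PartialCharge)))
      if (length(q) != na || anyNA(q))
        stop(sprintf("record '%s': malformed atom.dprop.PartialCharge field", name))
      charges <- charge_set(q, mol, conformer_id = conf_id,
                            tol = max(1e-6, na * 5e-7))
    }
    records[[r]] <- list(molecule = mol, conformer = conf, charges = charges)
  }
  records
}
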