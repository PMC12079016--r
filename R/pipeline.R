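#' Configuration for a variability study
#'
#' @param templates character vector of chain templates (optionally named;
#'   names become molecule ids).
#' @param n_conformers conformers (and charge sets) per molecule (default 50).
#' @param alpha perturbation amplitude: a scalar, or one value per template.
#' @param eta hardware jitter scale (default 0).
#' @param n_per_stratum molecules per good/average/bad stratum (default 5).
#' @param elf_batches independently seeded conformer batches for the
#'   ELF-vs-single-conformer comparison (default 20; 0 skips the
#'   comparison).
#' @param elf_batch_size conformers per ELF batch (default 100; the sub-500
#'   recommendation warning is recorded in the manifest, not raised).
#' @param elf_cfg an [elf_config()].
#' @param seed integer master seed for the whole study.
#' @return list of class `study_config`.
#' @export
study_config <- function(templates, n_conformers = 50L, alpha = 0.05,
                         eta = 0, n_per_stratum = 5L, elf_batches = 20L,
                         elf_batch_size = 100L, elf_cfg = elf_config(),
                         seed = 1L) {
  if (is.null(names(templates)))
    names(templates) <- sprintf("mol%02d", seq_along(templates))
  alpha <- rep_len(alpha, length(templates))
  structure(list(templates = templates, n_conformers = as.integer(n_conformers),
                 alpha = alpha, eta = eta, n_per_stratum = as.integer(n_per_stratum),
                 elf_batches = as.integer(elf_batches),
                 elf_batch_size = as.integer(elf_batch_size),
                 elf_cfg = elf_cfg, seed = as.integer(seed)),
            class = "study_config")
}

.log_line <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the end-to-end variability study
#'
#' For every molecule template: generate an ensemble of conformer-dependent
#' charge sets, compute the variability report, and compare the across-batch
#' spread of ELF consensus charges against that of single-conformer charges.
#' Then stratify the molecules into good/average/bad by maximal partial
#' charge difference. The whole run is a pure function of (config, seed):
#' repeated runs write byte-identical outputs. One molecule's failure is
#' isolated -- it is recorded in the manifest and the study continues.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, writes
#'   `metrics.csv`, `elf_comparison.csv`, `selection.csv` and
#'   `manifest.json` into it.
#' @param verbose emit structured progress lines (default `FALSE`).
#' @return list with `metrics` (data.frame), `elf_comparison` (data.frame),
#'   `selection` (`stratified_selection` or `NULL`), `reports`,
#'   `molecules`, and `manifest`.
#' @export
run_variability_study <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  ids <- names(config$templates)
  reports <- list()
  molecules <- list()
  elf_rows <- list()
  status <- stats::setNames(rep("ok", length(ids)), ids)
  notes <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    id <- ids[i]
    seed_i <- config$seed + 1000L * i
    res <- tryCatch({
      warn <- character(0)
      out <- withCallingHandlers({
        p <- synth_params(alpha = config$alpha[i], eta = config$eta,
                          seed = seed_i)
        .log_line(verbose, "generate", "molecule=%s template=%s seed=%d",
                  id, config$templates[i], seed_i)
        bench <- make_benchmark_ensemble(config$templates[i],
                                         config$n_conformers, p)
        rep_i <- variability_report(bench$ensemble)
        rep_i$molecule <- id
        .log_line(verbose, "metrics", "molecule=%s max_atom=%.4f max_bond=%.4f",
                  id, rep_i$max_atom_range, rep_i$max_bond_range)
        # ELF vs single-conformer dispersion across independent batches
        elf_row <- NULL
        cons_sets <- list(); single_sets <- list()
        if (config$elf_batches >= 2L) for (b in seq_len(config$elf_batches)) {
          pb <- synth_params(alpha = config$alpha[i], eta = config$eta,
                             seed = seed_i + b)
          bb <- make_benchmark_ensemble(config$templates[i],
                                        config$elf_batch_size, pb)
          cons_sets[[b]] <- elf_consensus_charges(bb$conformers,
                                                  bb$ensemble$sets,
                                                  config$elf_cfg)
          single_sets[[b]] <- bb$ensemble$sets[[1L]]
        }
        if (length(cons_sets) >= 2L) {
          cons_ens <- charge_ensemble(bench$molecule, cons_sets)
          single_ens <- charge_ensemble(bench$molecule, single_sets)
          elf_row <- data.frame(
            molecule = id,
            n_batches = config$elf_batches,
            single_max_charge_diff_e = max_charge_range(single_ens),
            elf_max_charge_diff_e = max_charge_range(cons_ens),
            single_max_dqbond_diff_e = max_bond_delta_range(single_ens),
            elf_max_dqbond_diff_e = max_bond_delta_range(cons_ens),
            stringsAsFactors = FALSE)
        }
        list(report = rep_i, molecule = bench$molecule, elf_row = elf_row)
      }, warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
      out$warnings <- unique(warn)
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[id] <- paste("error:", conditionMessage(res))
      .log_line(verbose, "error", "molecule=%s %s", id, conditionMessage(res))
      next
    }
    reports[[id]] <- res$report
    molecules[[id]] <- res$molecule
    elf_rows[[id]] <- res$elf_row
    notes[[id]] <- res$warnings
  }
  metrics_df <- if (length(reports)) {
    df <- do.call(rbind, lapply(reports, function(r) data.frame(
      molecule = r$molecule, n_sets = r$n_sets,
      max_partial_charge_diff_e = r$max_atom_range,
      max_dqbond_diff_e = r$max_bond_range,
      argmax_atom = r$argmax_atom - 1L, argmax_bond = r$argmax_bond - 1L,
      stringsAsFactors = FALSE)))
    rownames(df) <- NULL
    df
  } else NULL
  elf_df <- if (length(elf_rows)) {
    df <- do.call(rbind, elf_rows); rownames(df) <- NULL; df
  } else NULL
  selection <- NULL
  sel_status <- "ok"
  if (length(reports) >= 3L) {
    vals <- vapply(reports, function(r) r$max_atom_range, numeric(1))
    selection <- tryCatch(stratify(vals, config$n_per_stratum),
                          error = function(e) {
                            sel_status <<- paste("error:", conditionMessage(e))
                            NULL
                          })
  } else sel_status <- "skipped: fewer than 3 molecules succeeded"
  manifest <- list(
    tool = "chargevar", schema_version = 1L,
    config = list(templates = as.list(config$templates),
                  n_conformers = config$n_conformers,
                  alpha = config$alpha, eta = config$eta,
                  n_per_stratum = config$n_per_stratum,
                  elf_batches = config$elf_batches,
                  elf_batch_size = config$elf_batch_size,
                  seed = config$seed),
    molecule_status = as.list(status),
    molecule_warnings = notes[!vapply(notes, is.null, logical(1))],
    stratification_status = sel_status)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(metrics_df))
      utils::write.csv(metrics_df, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
    if (!is.null(elf_df))
      utils::write.csv(elf_df, file.path(out_dir, "elf_comparison.csv"),
                       row.names = FALSE)
    if (!is.null(selection))
      write_selection_csv(selection, file.path(out_dir, "selection.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(metrics = metrics_df, elf_comparison = elf_df, selection = selection,
       reports = reports, molecules = molecules, manifest = manifest)
}

#' Run the hardware-emulation comparison
#'
#' For each jitter scale on the grid, recharges the same conformers with
#' hardware-style jitter and compares them, conformer by conformer, against
#' the unjittered charges (the matched-pair design used when charging
#' identical conformers on two compute platforms). Jitter noise for a given
#' conformer is drawn once and scaled, so per-conformer maxima are exactly
#' proportional to eta along the grid.
#'
#' @param template chain template of the molecule to study.
#' @param eta_grid numeric vector of jitter scales (e), e.g.
#'   `c(0, 0.001, 0.002, 0.005)`.
#' @param n_conformers conformers per ensemble (default 50).
#' @param params a [synth_params()] for the base generation (its `eta` is
#'   ignored; the grid supplies it).
#' @param out_dir optional output directory for
#'   `hardware_comparison.csv`.
#' @return data.frame with columns `molecule`, `eta_e`, `conformer_id`,
#'   `max_partial_charge_diff_e` -- one row per (eta, conformer) pair, the
#'   per-conformer maxima summarized by hardware-comparison box plots.
#' @export
run_hardware_emulation <- function(template, eta_grid, n_conformers = 50L,
                                   params = synth_params(), out_dir = NULL) {
  base <- synth_params(kappa = params$kappa, alpha = params$alpha,
                       lambda_decay = params$lambda_decay, eta = 0,
                       seed = params$seed)
  bench <- make_benchmark_ensemble(template, n_conformers, base)
  rows <- list()
  for (eta in sort(eta_grid)) {
    jit_sets <- lapply(seq_along(bench$ensemble$sets), function(k)
      hardware_jitter(bench$ensemble$sets[[k]], eta,
                      seed = base$seed + 900000L + k))
    cmp <- if (eta == 0) {
      per <- stats::setNames(numeric(length(jit_sets)),
                             vapply(jit_sets, function(s) s$conformer_id,
                                    character(1)))
      list(per_pair = per, max = 0)
    } else {
      compare_matched_sets(bench$ensemble,
                           charge_ensemble(bench$molecule, jit_sets))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      molecule = bench$molecule$name, eta_e = eta,
      conformer_id = names(cmp$per_pair),
      max_partial_charge_diff_e = unname(cmp$per_pair),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, file.path(out_dir, "hardware_comparison.csv"),
                     row.names = FALSE)
  }
  df
}
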