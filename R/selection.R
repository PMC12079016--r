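#' Sigma windows for good/average/bad stratification
#'
#' From the sample mean and standard deviation (n-1 denominator) of a metric
#' distribution, the three closed selection windows:
#' good `[mean - 1.8 sd, mean - 1.0 sd]`,
#' average `[mean - 0.4 sd, mean + 0.4 sd]`,
#' bad `[mean + 1.0 sd, mean + 1.8 sd]`. Molecules in the good window show
#' little charge variability, those in the bad window a lot.
#'
#' @param values numeric vector of per-molecule metric values (e).
#' @return list of class `stratum_windows` with `mean`, `sd` and a closed
#'   `[lo, hi]` interval per stratum.
#' @export
stratum_windows <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values to stratify")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0)
    stop("degenerate distribution: standard deviation is zero, windows collapse")
  structure(list(mean = m, sd = s,
                 good = c(lo = m - 1.8 * s, hi = m - 1.0 * s),
                 average = c(lo = m - 0.4 * s, hi = m + 0.4 * s),
                 bad = c(lo = m + 1.0 * s, hi = m + 1.8 * s)),
            class = "stratum_windows")
}

.in_window <- function(x, w) x >= w["lo"] & x <= w["hi"]

#' Stratified good/average/bad molecule selection
#'
#' Assigns each molecule's variability value to the good, average or bad
#' sigma window (see [stratum_windows()]; windows are closed intervals, and
#' a value falling in two windows goes to the more extreme stratum) and
#' selects up to `n_per_stratum` molecules per window -- the ones closest to
#' the window midpoint, ties broken by lower molecule id. Strata may be
#' under-filled when few candidates fall inside a window.
#'
#' @param values named numeric vector: molecule id -> metric value (e).
#' @param n_per_stratum molecules to select per stratum (default 5).
#' @return list of class `stratified_selection` with per-stratum id vectors
#'   (`good`, `average`, `bad`), the `windows` used, and the input `values`.
#' @export
stratify <- function(values, n_per_stratum = 5L) {
  n_per_stratum <- as.integer(n_per_stratum)
  if (n_per_stratum < 1L) stop("n_per_stratum must be >= 1")
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("values must be uniquely named by molecule id")
  w <- stratum_windows(values)
  pick <- function(win) {
    cand <- values[.in_window(values, w[[win]])]
    if (length(cand) == 0L) return(character(0))
    mid <- mean(w[[win]])
    ord <- order(abs(cand - mid), names(cand))
    names(cand)[ord[seq_len(min(n_per_stratum, length(cand)))]]
  }
  # extreme strata claim boundary values first, then average among the rest
  good <- pick("good")
  bad <- pick("bad")
  avg_pool <- values[!names(values) %in% c(good, bad)]
  avg_cand <- avg_pool[.in_window(avg_pool, w$average)]
  average <- if (length(avg_cand) == 0L) character(0) else {
    mid <- mean(w$average)
    ord <- order(abs(avg_cand - mid), names(avg_cand))
    names(avg_cand)[ord[seq_len(min(n_per_stratum, length(avg_cand)))]]
  }
  structure(list(good = good, average = average, bad = bad,
                 windows = w, values = values),
            class = "stratified_selection")
}

#' @export
print.stratified_selection <- function(x, ...) {
  w <- x$windows
  cat(sprintf("<stratified_selection> mean %.4f e, sd %.4f e\n", w$mean, w$sd))
  for (s in c("good", "average", "bad"))
    cat(sprintf("  %-7s [%.4f, %.4f]: %s\n", s, w[[s]]["lo"], w[[s]]["hi"],
                if (length(x[[s]])) paste(x[[s]], collapse = ", ") else "(none)"))
  invisible(x)
}

# canonical element-labeled simple paths of 1..max_len bonds
labeled_paths <- function(mol, max_len = 4L) {
  g <- as_igraph(mol)
  els <- mol$elements
  out <- character(0)
  for (v in seq_len(n_atoms(mol))) {
    ps <- igraph::all_simple_paths(g, from = v, cutoff = max_len)
    for (p in ps) {
      idx <- as.integer(igraph::as_ids(p))
      lab <- paste(els[idx], collapse = "-")
      rev_lab <- paste(rev(els[idx]), collapse = "-")
      out <- c(out, if (lab <= rev_lab) lab else rev_lab)
    }
  }
  unique(out)
}

#' Path-based Tanimoto similarity of two molecules
#'
#' A deterministic structural similarity: the Tanimoto coefficient
#' `|P_A intersect P_B| / |P_A union P_B|` over the sets of element-labeled
#' simple paths of 1 to 4 bonds (each path canonicalized against its
#' reversal). Symmetric, in [0, 1], and 1 for labeled-isomorphic graphs with
#' identical path sets. Used to avoid picking near-duplicate molecules in
#' [rank_and_pick()].
#'
#' @param molA,molB `mol_graph` objects.
#' @return numeric similarity in [0, 1].
#' @export
similarity <- function(molA, molB) {
  pa <- labeled_paths(molA)
  pb <- labeled_paths(molB)
  u <- union(pa, pb)
  if (length(u) == 0L) return(1)  # two single-atom molecules of any kind
  length(intersect(pa, pb)) / length(u)
}

#' Rank molecules by bond-charge variability and pick a diverse subset
#'
#' Orders molecules from highest to lowest maximal dq_bond difference (ties
#' broken by lower id), restricts to the top `pool`, then greedily accepts
#' candidates whose [similarity()] to every already-accepted molecule is
#' below `tau` -- a deterministic stand-in for manually skipping
#' near-duplicate structures. Returns up to `k` ids.
#'
#' @param reports named list: molecule id -> `variability_report`.
#' @param k maximum number of molecules to return (default 12).
#' @param pool size of the top-ranked candidate pool (default 25).
#' @param mols named list: molecule id -> `mol_graph` (for similarity).
#' @param tau similarity threshold in [0, 1] (default 0.6); `tau = 1`
#'   disables the filter.
#' @return character vector of up to `k` molecule ids, in acceptance order.
#' @export
rank_and_pick <- function(reports, k = 12L, pool = 25L, mols, tau = 0.6) {
  k <- as.integer(k); pool <- as.integer(pool)
  if (k < 1L) stop("k must be >= 1")
  if (k > pool || pool > length(reports))
    stop("need k <= pool <= number of molecules")
  ids <- names(reports)
  if (is.null(ids)) stop("reports must be named by molecule id")
  vals <- vapply(reports, function(r) r$max_bond_range, numeric(1))
  ord <- ids[order(-vals, ids)][seq_len(pool)]
  accepted <- character(0)
  for (id in ord) {
    if (length(accepted) >= k) break
    ok <- tau >= 1 ||  # tau = 1 disables the similarity screen entirely
      all(vapply(accepted, function(a) similarity(mols[[id]], mols[[a]]) < tau,
                 logical(1)))
    if (ok) accepted <- c(accepted, id)
  }
  accepted
}
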