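# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

# Minimal two-group config with no planted structure (pure log-normal
# noise), used for null-calibration checks.
null_config <- function(groups = c("G1", "G2"), times = c(4, 6),
                        n = 6, elements = ION_ELEMENTS, cv = 0.2) {
  ionome_config(
    groups = groups,
    timepoints_by_group = setNames(rep(list(times), length(groups)), groups),
    n_replicates = n, elements = elements,
    cell_cv = setNames(rep(cv, length(elements)), elements),
    outlier_rate = 0)
}

# Config planting a single rank correlation in one cell of a small panel.
planted_pair_config <- function(rho, a = "Fe", b = "V", group = "G1",
                                time = 4, n = 6,
                                elements = ION_ELEMENTS, cv = 0.2,
                                groups = "G1", times = 4) {
  ionome_config(
    groups = groups,
    timepoints_by_group = setNames(rep(list(times), length(groups)), groups),
    n_replicates = n, elements = elements,
    cell_cv = setNames(rep(cv, length(elements)), elements),
    planted_correlations = tibble::tibble(
      group = group, time_months = time, element_a = a, element_b = b,
      rho = rho),
    outlier_rate = 0)
}

# Config planting the recurring correlation blocks {Zn,Cu}, {Fe,V},
# {Pb,Cd,Bi} in every cell, with no mean structure.
block_config <- function(rho = 0.8, n = 6) {
  cfg <- null_config(groups = c("WT", "AD", "Se"),
                     times = c(2, 4, 6, 8, 10, 12), n = n)
  cells <- tidyr::expand_grid(group = cfg$groups,
                              time_months = c(2, 4, 6, 8, 10, 12))
  pairs <- tibble::tibble(
    element_a = c("Zn", "Fe", "Pb", "Pb", "Cd"),
    element_b = c("Cu", "V", "Cd", "Bi", "Bi"))
  cfg$planted_correlations <- tidyr::expand_grid(cells, pairs) |>
    dplyr::mutate(rho = rho)
  cfg
}

# Direct long-format tibble from per-cell value vectors: values is a named
# list group -> element -> numeric vector (single time point).
manual_dataset <- function(values, time = 4) {
  purrr::imap_dfr(values, function(elts, g) {
    purrr::imap_dfr(elts, function(v, el) {
      tibble::tibble(
        sample_id = sprintf("%s_%02d", g, seq_along(v)),
        group = g, time_months = time, element = el, concentration = v)
    })
  })
}

# Independent oracle: exact two-sided rank-sum p-value by enumeration of
# all C(n+m, n) assignments of ranks to the first sample.
enumerate_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  combos <- utils::combn(length(pooled), length(a))
  w_all <- colSums(matrix(r[combos], nrow = length(a)))
  mean(abs(w_all - mean(w_all)) >= abs(w_obs - mean(w_all)) - 1e-9)
}

# Independent oracle: Spearman rho via the closed form on explicit ranks.
closed_form_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
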