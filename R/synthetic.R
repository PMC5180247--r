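#' Synthetic ionome study configuration
#'
#' Builds a configuration describing a multi-group, multi-time-point ionome
#' study to be simulated by [generate_dataset()]. Concentrations are drawn
#' from log-normal marginals tied together by a Gaussian copula, so planted
#' rank correlations and group/time-dependent mean shifts survive any
#' monotone transformation downstream analyses may apply.
#'
#' @param groups Character vector of group labels.
#' @param timepoints_by_group Named list mapping each group to its vector of
#'   time points (months).
#' @param n_replicates Animals per group x time cell (>= 3; the Dixon Q
#'   screen needs at least 3).
#' @param elements Character vector of element symbols.
#' @param cell_means Tibble with columns `group`, `time_months`, `element`,
#'   `log_mean`: the log-scale location of each cell. Cells absent from the
#'   table fall back to `base_log_mean[element]`.
#' @param base_log_mean Named numeric vector of per-element baseline
#'   log-scale locations (log of arbitrary concentration units).
#' @param cell_cv Named numeric vector of per-element log-scale standard
#'   deviations (coefficient of variation on the natural scale, to first
#'   order).
#' @param planted_correlations Tibble with columns `group`, `time_months`,
#'   `element_a`, `element_b`, `rho`: target Spearman correlations planted
#'   within the named cell. Targets must lie in (-1, 1).
#' @param outlier_rate Per-observation probability of a gross outlier.
#' @param outlier_multiplier Fold change applied to an outlying observation.
#' @param seed Default seed used by [generate_dataset()] when none is given.
#'
#' @return An object of class `ionome_config` (a named list).
#' @seealso [default_config()] for the study-design mirror.
#' @export
ionome_config <- function(groups,
                          timepoints_by_group,
                          n_replicates = 6L,
                          elements = ION_ELEMENTS,
                          cell_means = NULL,
                          base_log_mean = NULL,
                          cell_cv = NULL,
                          planted_correlations = NULL,
                          outlier_rate = 0,
                          outlier_multiplier = 5,
                          seed = 1L) {
  if (is.null(base_log_mean)) {
    base_log_mean <- setNames(rep(0, length(elements)), elements)
  }
  if (is.null(cell_cv)) cell_cv <- setNames(rep(0.2, length(elements)), elements)
  if (length(cell_cv) == 1L && is.null(names(cell_cv))) {
    cell_cv <- setNames(rep(cell_cv, length(elements)), elements)
  }
  if (is.null(cell_means)) {
    cell_means <- tibble(group = character(), time_months = numeric(),
                         element = character(), log_mean = numeric())
  }
  if (is.null(planted_correlations)) {
    planted_correlations <- tibble(group = character(), time_months = numeric(),
                                   element_a = character(),
                                   element_b = character(), rho = numeric())
  }
  cfg <- structure(
    list(groups = groups,
         timepoints_by_group = timepoints_by_group,
         n_replicates = as.integer(n_replicates),
         elements = elements,
         base_log_mean = base_log_mean,
         cell_means = as_tibble(cell_means),
         cell_cv = cell_cv,
         planted_correlations = as_tibble(planted_correlations),
         outlier_rate = outlier_rate,
         outlier_multiplier = outlier_multiplier,
         seed = as.integer(seed)),
    class = "ionome_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  stopifnot(inherits(config, "ionome_config"))
  if (config$n_replicates < 3L) {
    abort("n_replicates must be >= 3 (Dixon's Q needs at least 3 values per cell)")
  }
  if (!all(names(config$timepoints_by_group) %in% config$groups)) {
    abort("timepoints_by_group names must be a subset of groups")
  }
  pc <- config$planted_correlations
  if (nrow(pc)) {
    if (any(pc$rho <= -1 | pc$rho >= 1)) {
      abort("planted correlation targets must lie strictly inside (-1, 1)")
    }
    if (any(pc$element_a == pc$element_b)) {
      abort("planted correlations must reference two distinct elements")
    }
    bad <- setdiff(unique(c(pc$element_a, pc$element_b)), config$elements)
    if (length(bad)) {
      abort(paste0("planted correlations reference unknown element(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  missing_cv <- setdiff(config$elements, names(config$cell_cv))
  if (length(missing_cv)) {
    abort(paste0("cell_cv missing for element(s): ",
                 paste(missing_cv, collapse = ", ")))
  }
  invisible(config)
}

#' Study-design mirror configuration
#'
#' Default configuration matching the three-group brain ionome study design:
#' wild-type (WT) and transgenic Alzheimer's-model (AD) groups sampled at 2,
#' 4, 6, 8, 10 and 12 months, a selenate-treated group (Se) starting at 4
#' months, six animals per cell (102 in total), and the 15-element panel.
#'
#' Planted effects mirror the study's headline pattern: Fe and Zn (with Hg
#' and Cd) elevated and Mn depressed in AD relative to WT at all ages; Se
#' strongly elevated in the treated group from 4 months; Fe fully restored
#' to the WT level and Zn partially restored from 8 months. Rank-correlation
#' structure plants the recurring element blocks Zn-Cu, Fe-V and Pb-Cd-Bi in
#' every cell, the Fe-Mn reversal at 4 months (AD 0.886, WT -0.6, Se
#' -0.319), an AD-only Zn-Se association at 6 months and a treated-group
#' Se-Ca association.
#'
#' @param outlier_rate Per-observation gross-outlier probability.
#' @param outlier_multiplier Fold change applied to outliers.
#' @param seed Default generation seed.
#' @return An `ionome_config`.
#' @export
default_config <- function(outlier_rate = 0.01, outlier_multiplier = 5,
                           seed = 1L) {
  groups <- c("WT", "AD", "Se")
  tps <- list(WT = c(2, 4, 6, 8, 10, 12),
              AD = c(2, 4, 6, 8, 10, 12),
              Se = c(4, 6, 8, 10, 12))
  # Baseline concentrations in arbitrary units, log-scale locations chosen
  # to span realistic relative abundances (Mg/Ca major, Bi ultra-trace).
  base <- log(c(Se = 0.15, Fe = 20, Zn = 15, Cu = 5, Mg = 150, Hg = 0.01,
                Ca = 100, Cr = 0.1, V = 0.02, Mn = 0.4, Cd = 0.01,
                Co = 0.02, Pb = 0.05, As = 0.01, Bi = 0.005))
  cv <- setNames(rep(0.2, 15), ION_ELEMENTS)

  shift <- function(group, times, element, delta) {
    tibble(group = group, time_months = rep(times, each = length(element)),
           element = rep(element, length(times)), log_mean = base[element] + delta)
  }
  all_t <- tps$WT
  late <- c(8, 10, 12)
  cell_means <- bind_rows(
    # AD vs WT: persistent elevation of AD-associated metals, Mn depressed.
    shift("AD", all_t, c("Fe", "Zn"), 0.6),
    shift("AD", all_t, c("Hg", "Cd"), 0.4),
    shift("AD", all_t, "Mn", -0.4),
    # Se group inherits the AD background, plus treatment effects.
    shift("Se", tps$Se, c("Hg", "Cd"), 0.4),
    shift("Se", tps$Se, "Mn", -0.4),
    shift("Se", tps$Se, "Se", 1.0),
    shift("Se", c(4, 6), c("Fe", "Zn"), 0.6),     # not yet reversed
    shift("Se", late, "Fe", 0.6 - 0.6),           # fully restored to WT level
    shift("Se", late, "Zn", 0.6 - 0.3)            # partially restored
  )

  pair <- function(group, times, a, b, rho) {
    tibble(group = rep(group, length(times)), time_months = times,
           element_a = a, element_b = b, rho = rho)
  }
  blocks <- purrr::map_dfr(groups, function(g) {
    ts <- tps[[g]]
    bind_rows(pair(g, ts, "Zn", "Cu", 0.8),
              # Fe-V weakened at 4 months: the planted Fe-Mn correlations
              # leave no positive-definite room for a strong Fe-V edge there.
              pair(g, ts, "Fe", "V", ifelse(ts == 4, 0.3, 0.8)),
              pair(g, ts, "Pb", "Cd", 0.8),
              pair(g, ts, "Pb", "Bi", 0.8),
              pair(g, ts, "Cd", "Bi", 0.8))
  })
  planted <- bind_rows(
    blocks,
    pair("AD", 4, "Fe", "Mn", 0.886),
    pair("WT", 4, "Fe", "Mn", -0.6),
    pair("Se", 4, "Fe", "Mn", -0.319),
    pair("AD", 6, "Zn", "Se", 0.5),
    purrr::map_dfr(tps$Se, function(t) pair("Se", t, "Se", "Ca", 0.5))
  )

  ionome_config(groups = groups, timepoints_by_group = tps,
                n_replicates = 6L, elements = ION_ELEMENTS,
                cell_means = cell_means, base_log_mean = base, cell_cv = cv,
                planted_correlations = planted,
                outlier_rate = outlier_rate,
                outlier_multiplier = outlier_multiplier, seed = seed)
}

# Latent Pearson correlation giving target Spearman rho under a Gaussian
# copula: r = 2 sin(pi * rho / 6).
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

# Build the latent correlation matrix for one (group, time) cell; errors if
# the implied matrix is not positive definite (no silent repair).
cell_latent_matrix <- function(config, group, time) {
  E <- length(config$elements)
  R <- diag(E)
  dimnames(R) <- list(config$elements, config$elements)
  pc <- dplyr::filter(config$planted_correlations,
                      .data$group == !!group, .data$time_months == !!time)
  if (nrow(pc)) {
    for (i in seq_len(nrow(pc))) {
      r <- spearman_to_pearson(pc$rho[i])
      R[pc$element_a[i], pc$element_b[i]] <- r
      R[pc$element_b[i], pc$element_a[i]] <- r
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort(paste0("planted correlations for cell (", group, ", ", time,
                 " months) imply a non-positive-definite latent matrix; ",
                 "adjust the targets (no automatic repair is applied)"))
  }
  R
}

#' Generate a synthetic ionome dataset
#'
#' Draws, for every (group, time) cell, `n_replicates` latent multivariate
#' normal vectors whose correlation encodes the planted Spearman targets via
#' the Gaussian-copula identity r = 2 sin(pi rho / 6), scales them by the
#' per-element log-scale sd, shifts by the cell log-mean and exponentiates.
#' Each resulting observation independently becomes a gross outlier
#' (multiplied by `outlier_multiplier`) with probability `outlier_rate`.
#'
#' @param config An `ionome_config`.
#' @param seed Integer seed; identical (config, seed) pairs give identical
#'   output. Defaults to `config$seed`.
#' @return A tibble with columns `sample_id`, `group`, `time_months`,
#'   `element`, `concentration` (strictly positive, arbitrary units).
#' @export
generate_dataset <- function(config, seed = config$seed) {
  validate_config(config)
  elements <- config$elements
  sds <- config$cell_cv[elements]
  with_seed_opt(seed, {
    out <- purrr::map_dfr(config$groups, function(g) {
      purrr::map_dfr(config$timepoints_by_group[[g]], function(t) {
        R <- cell_latent_matrix(config, g, t)
        L <- chol(R)
        n <- config$n_replicates
        Z <- matrix(rnorm(n * length(elements)), n) %*% L
        mu <- config$base_log_mean[elements]
        cm <- dplyr::filter(config$cell_means, .data$group == g,
                            .data$time_months == t)
        if (nrow(cm)) mu[cm$element] <- cm$log_mean
        X <- exp(sweep(sweep(Z, 2, sds, "*"), 2, mu, "+"))
        is_out <- matrix(stats::runif(n * length(elements)) < config$outlier_rate, n)
        X[is_out] <- X[is_out] * config$outlier_multiplier
        ids <- sprintf("%s_%02.0fm_%d", g, t, seq_len(n))
        tibble(sample_id = rep(ids, times = length(elements)),
               group = g, time_months = t,
               element = rep(elements, each = n),
               concentration = as.vector(X))
      })
    })
    out$element <- factor(out$element, levels = elements)
    out <- arrange(out, .data$group, .data$time_months, .data$element,
                   .data$sample_id)
    out$element <- as.character(out$element)
    out
  })
}

#' Multiply one replicate of one cell by a known factor
#'
#' Fixture helper for outlier-detection tests: returns a copy of the dataset
#' in which the `index`-th replicate (in sample-id order within the cell) of
#' the given (group, time, element) cell is multiplied by `multiplier`; all
#' other records are untouched. Repeated injection at the same index
#' compounds multiplicatively.
#'
#' @param dataset Long-format ionome tibble.
#' @param group,time,element Cell address.
#' @param index Replicate index within the cell (1-based).
#' @param multiplier Positive fold change.
#' @return The modified dataset.
#' @export
inject_known_outlier <- function(dataset, group, time, element, index,
                                 multiplier) {
  stopifnot(multiplier > 0)
  rows <- which(dataset$group == group & dataset$time_months == time &
                  dataset$element == element)
  if (!length(rows)) {
    abort(paste0("no cell (", group, ", ", time, " months, ", element,
                 ") in dataset"))
  }
  rows <- rows[order(dataset$sample_id[rows])]
  if (index < 1 || index > length(rows)) {
    abort(paste0("index ", index, " out of range for cell of size ",
                 length(rows)))
  }
  dataset$concentration[rows[index]] <-
    dataset$concentration[rows[index]] * multiplier
  dataset
}

#' @export
print.ionome_config <- function(x, ...) {
  cells <- sum(lengths(x$timepoints_by_group))
  cat("<ionome_config>\n")
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  cat("  cells:", cells, "x", x$n_replicates, "replicates =",
      cells * x$n_replicates, "samples\n")
  cat("  elements:", length(x$elements), "\n")
  cat("  planted mean shifts:", nrow(x$cell_means),
      "| planted correlations:", nrow(x$planted_correlations), "\n")
  cat("  outlier rate:", x$outlier_rate, "x", x$outlier_multiplier, "\n")
  invisible(x)
}

#' Read or write a configuration as YAML
#'
#' @param config An `ionome_config`.
#' @param path File path.
#' @return `read_ionome_config()` returns an `ionome_config`;
#'   `write_ionome_config()` returns `path` invisibly.
#' @export
write_ionome_config <- function(config, path) {
  validate_config(config)
  obj <- list(
    groups = config$groups,
    timepoints_by_group = config$timepoints_by_group,
    n_replicates = config$n_replicates,
    elements = config$elements,
    base_log_mean = as.list(config$base_log_mean),
    cell_means = purrr::transpose(as.list(config$cell_means)),
    cell_cv = as.list(config$cell_cv),
    planted_correlations = purrr::transpose(as.list(config$planted_correlations)),
    outlier_rate = config$outlier_rate,
    outlier_multiplier = config$outlier_multiplier,
    seed = config$seed)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_ionome_config
#' @export
read_ionome_config <- function(path) {
  obj <- yaml::read_yaml(path)
  tib <- function(x, cols) {
    if (!length(x)) {
      return(as_tibble(setNames(rep(list(logical()), length(cols)), cols)))
    }
    bind_rows(lapply(x, as_tibble))
  }
  num <- function(d) {
    for (col in intersect(c("time_months", "log_mean", "rho"), names(d))) {
      d[[col]] <- as.numeric(d[[col]])
    }
    d
  }
  ionome_config(
    groups = unlist(obj$groups),
    timepoints_by_group = lapply(obj$timepoints_by_group,
                                 function(x) as.numeric(unlist(x))),
    n_replicates = obj$n_replicates,
    elements = unlist(obj$elements),
    cell_means = num(tib(obj$cell_means,
                         c("group", "time_months", "element", "log_mean"))),
    base_log_mean = unlist(obj$base_log_mean),
    cell_cv = unlist(obj$cell_cv),
    planted_correlations = num(tib(obj$planted_correlations,
                                   c("group", "time_months", "element_a",
                                     "element_b", "rho"))),
    outlier_rate = obj$outlier_rate,
    outlier_multiplier = obj$outlier_multiplier,
    seed = obj$seed)
}
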