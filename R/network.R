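#' Spearman rank correlation
#'
#' Spearman correlation with midranks for ties; for tie-free data this
#' equals 1 - 6 sum(d^2) / (n (n^2 - 1)).
#'
#' @param x,y Numeric vectors of equal length >= 3, each non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation undefined for a constant vector")
  }
  cor(x, y, method = "spearman")
}

# Fast draws from the Spearman permutation null at sample size n: the
# correlation of two independent uniform random permutations of 1..n
# (tie-free, closed form on ranks).
null_scc_draws <- function(n, reps) {
  denom <- n * (n^2 - 1)
  vapply(seq_len(reps), function(i) {
    1 - 6 * sum((sample.int(n) - sample.int(n))^2) / denom
  }, numeric(1))
}

new_threshold_estimate <- function(statistic, n, alpha, inner_reps,
                                   outer_reps, quantiles, seed) {
  structure(
    list(statistic = statistic, n = as.integer(n), alpha = alpha,
         inner_reps = as.integer(inner_reps),
         outer_reps = as.integer(outer_reps),
         point = mean(quantiles),
         ci_half_width = unname(diff(quantile(quantiles, c(0.025, 0.975))) / 2),
         quantiles = quantiles, seed = seed),
    class = "threshold_estimate")
}

#' Simulation-derived significance threshold for Spearman correlation
#'
#' One inner run draws `inner_reps` Spearman correlations between two
#' independent random permutations of the ranks 1..n and reduces them to
#' the empirical (1 - alpha) quantile (linear interpolation between order
#' statistics). The inner run is repeated `outer_reps` times; the point
#' estimate is the mean of the inner quantiles and the reported half-width
#' is half the central-95% spread of those quantiles. At the study's n = 6
#' and alpha = 0.05 this reproduces the threshold 0.749.
#'
#' The quantile is taken on the signed null (one-sided); applying the
#' resulting cutoff as |SCC| > tau, as the edge-flagging step does so that
#' strong negative correlations are also called, yields a two-sided null
#' exceedance rate of about 2 alpha.
#'
#' @param n Per-group sample size (>= 3).
#' @param alpha Tail probability of the null quantile.
#' @param inner_reps Null draws per inner run.
#' @param outer_reps Number of inner runs.
#' @param seed Optional seed for reproducibility.
#' @return A `threshold_estimate` object.
#' @export
simulate_scc_threshold <- function(n, alpha = 0.05, inner_reps = 1000,
                                   outer_reps = 1000, seed = NULL) {
  if (n < 3) abort("n must be >= 3")
  qs <- with_seed_opt(seed, {
    vapply(seq_len(outer_reps), function(i) {
      quantile(null_scc_draws(n, inner_reps), 1 - alpha, names = FALSE)
    }, numeric(1))
  })
  new_threshold_estimate("scc", n, alpha, inner_reps, outer_reps, qs, seed)
}

#' Simulation-derived significance threshold for between-group Spearman
#' correlation differences
#'
#' Same protocol as [simulate_scc_threshold()], but each inner draw is the
#' difference of two independent null Spearman correlations at sample size
#' `n` (one per group). At n = 6 and alpha = 0.05 this reproduces the
#' threshold 1.05 used for differentially changed correlations.
#'
#' @inheritParams simulate_scc_threshold
#' @return A `threshold_estimate` object with statistic `"delta_scc"`.
#' @export
simulate_dcc_threshold <- function(n, alpha = 0.05, inner_reps = 1000,
                                   outer_reps = 1000, seed = NULL) {
  if (n < 3) abort("n must be >= 3")
  qs <- with_seed_opt(seed, {
    vapply(seq_len(outer_reps), function(i) {
      d <- null_scc_draws(n, inner_reps) - null_scc_draws(n, inner_reps)
      quantile(d, 1 - alpha, names = FALSE)
    }, numeric(1))
  })
  new_threshold_estimate("delta_scc", n, alpha, inner_reps, outer_reps, qs,
                         seed)
}

# All permutations of 1..n as an n! x n matrix (recursive insertion).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(p[, seq_len(pos - 1), drop = FALSE], n,
          p[, seq.int(pos, length.out = n - pos), drop = FALSE])
  }))
}

#' Exact permutation-null tail probability of the Spearman correlation
#'
#' P(rho >= q) under the null of independent rankings, by full enumeration
#' of all n! permutations against the identity ranking. Serves as the exact
#' reference the threshold simulation is checked against.
#'
#' @param n Sample size (<= 8; factorial enumeration).
#' @param q Threshold.
#' @return Exact tail probability.
#' @export
exact_null_scc_tail <- function(n, q) {
  if (n > 8) abort("exact enumeration supported for n <= 8 only")
  perms <- all_permutations(as.integer(n))
  rho <- 1 - 6 * rowSums((perms - matrix(seq_len(n), nrow(perms), n,
                                         byrow = TRUE))^2) / (n * (n^2 - 1))
  mean(rho >= q - 1e-12)
}

#' Difference of two Spearman correlations
#'
#' The differential-correlation statistic: `scc_1 - scc_2`, antisymmetric
#' under swapping the groups, with |delta| <= 2.
#'
#' @param scc_1,scc_2 Correlations in \[-1, 1\] (vectorised).
#' @return `scc_1 - scc_2`.
#' @export
delta_scc <- function(scc_1, scc_2) {
  stopifnot(all(abs(scc_1) <= 1), all(abs(scc_2) <= 1))
  scc_1 - scc_2
}

# Resolve a threshold argument: numeric override, threshold_estimate, or
# NULL (simulate once per (statistic, n, alpha) and cache).
.threshold_cache <- new.env(parent = emptyenv())

resolve_tau <- function(tau, statistic, n, alpha = 0.05) {
  if (is.numeric(tau)) return(tau)
  if (inherits(tau, "threshold_estimate")) return(tau$point)
  key <- paste(statistic, n, alpha, sep = "|")
  if (is.null(.threshold_cache[[key]])) {
    fun <- if (statistic == "scc") simulate_scc_threshold else simulate_dcc_threshold
    # fixed internal seed: the cached default must not depend on call order
    est <- fun(n, alpha, inner_reps = 1000, outer_reps = 200,
               seed = substream_seed(2016L, key))
    .threshold_cache[[key]] <- est$point
  }
  .threshold_cache[[key]]
}

#' Spearman correlation network for one (group, time) cell
#'
#' Computes the Spearman correlation for every unordered element pair in
#' the cell (15 elements give 105 pairs) and flags edges with |SCC| above
#' the significance threshold.
#'
#' @param dataset Long-format ionome tibble.
#' @param group,time Cell address.
#' @param tau Threshold: a number (e.g. 0.749 for exact replication of the
#'   study cutoff), a `threshold_estimate`, or NULL to simulate one for the
#'   cell's sample size (cached per (n, alpha)).
#' @param alpha Tail probability used when simulating a threshold.
#' @return Tibble of class `ionome_edges`, one row per unordered pair:
#'   `element_a`, `element_b`, `group`, `time_months`, `n`, `scc`,
#'   `significant`.
#' @export
scc_matrix <- function(dataset, group, time, tau = NULL, alpha = 0.05) {
  d <- filter(dataset, .data$group == !!group, .data$time_months == !!time)
  if (!nrow(d)) {
    abort(paste0("no cell (", group, ", ", time, " months) in dataset"))
  }
  elements <- unique(dataset$element)
  wide <- d %>%
    select("sample_id", "element", "concentration") %>%
    tidyr::pivot_wider(names_from = "element", values_from = "concentration") %>%
    arrange(.data$sample_id)
  X <- as.matrix(wide[, elements, drop = FALSE])
  if (nrow(X) < 3) abort("cell has fewer than 3 replicates")
  C <- suppressWarnings(cor(X, method = "spearman"))
  tau_val <- resolve_tau(tau, "scc", nrow(X), alpha)
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  out <- tibble(element_a = elements[pairs[, "row"]],
                element_b = elements[pairs[, "col"]],
                group = group, time_months = time, n = nrow(X),
                scc = C[pairs])
  out$significant <- !is.na(out$scc) & abs(out$scc) > tau_val
  attr(out, "tau_scc") <- tau_val
  class(out) <- c("ionome_edges", class(out))
  out
}

#' Scan for differentially changed correlations (DCCs)
#'
#' For every unordered element pair and every time point shared by the two
#' groups, computes delta = SCC(group1) - SCC(group2) and flags the pair as
#' a DCC when |delta| exceeds the threshold.
#'
#' @param dataset Long-format ionome tibble.
#' @param group1,group2 Group labels; delta is group1 minus group2.
#' @param tau_dcc Threshold: a number (e.g. 1.05 for the study cutoff), a
#'   `threshold_estimate`, or NULL to simulate (cached).
#' @param alpha Tail probability used when simulating.
#' @return Tibble of class `ionome_dcc`: `element_a`, `element_b`,
#'   `time_months`, `group1`, `group2`, `scc_1`, `scc_2`, `delta`,
#'   `significant`.
#' @export
dcc_scan <- function(dataset, group1, group2, tau_dcc = NULL, alpha = 0.05) {
  t1 <- unique(dataset$time_months[dataset$group == group1])
  t2 <- unique(dataset$time_months[dataset$group == group2])
  shared <- sort(intersect(t1, t2))
  if (!length(shared)) abort("groups share no time points")
  out <- purrr::map_dfr(shared, function(tm) {
    e1 <- scc_matrix(dataset, group1, tm, tau = 1)  # flags unused here
    e2 <- scc_matrix(dataset, group2, tm, tau = 1)
    merged <- left_join(
      select(as_tibble(e1), "element_a", "element_b", n1 = "n", scc_1 = "scc"),
      select(as_tibble(e2), "element_a", "element_b", n2 = "n", scc_2 = "scc"),
      by = c("element_a", "element_b"))
    mutate(merged, time_months = tm, group1 = group1, group2 = group2,
           delta = delta_scc(.data$scc_1, .data$scc_2))
  })
  tau_val <- resolve_tau(tau_dcc, "delta_scc",
                         min(c(out$n1, out$n2), na.rm = TRUE), alpha)
  out$significant <- !is.na(out$delta) & abs(out$delta) > tau_val
  out <- out[, c("element_a", "element_b", "time_months", "group1", "group2",
                 "scc_1", "scc_2", "delta", "significant")]
  attr(out, "tau_dcc") <- tau_val
  class(out) <- c("ionome_dcc", class(out))
  out
}

#' Group-specific significant edges
#'
#' Given significance-flagged edge tables for several groups (rows from
#' [scc_matrix()] over multiple cells bound together), reports the pairs
#' that are significant at one or more time points in exactly one group and
#' at no time point in any other.
#'
#' @param edges Edge tibble covering all groups (and times) of interest.
#' @param by_time If TRUE, specificity is assessed per time point (a pair
#'   can be specific to a group at one time while shared at another);
#'   default FALSE assesses specificity across all examined time points.
#' @return Tibble with `group`, `element_a`, `element_b` and
#'   `times` (comma-separated months at which the pair is significant in
#'   that group); with `by_time = TRUE`, a `time_months` column instead.
#' @export
group_specific_edges <- function(edges, by_time = FALSE) {
  sig <- filter(as_tibble(edges), .data$significant)
  if (!nrow(sig)) {
    return(tibble(group = character(), element_a = character(),
                  element_b = character(), times = character()))
  }
  if (by_time) {
    counts <- sig %>%
      distinct(.data$element_a, .data$element_b, .data$time_months, .data$group) %>%
      group_by(.data$element_a, .data$element_b, .data$time_months) %>%
      filter(dplyr::n_distinct(.data$group) == 1) %>%
      ungroup()
    return(arrange(counts[, c("group", "element_a", "element_b", "time_months")],
                   .data$group, .data$element_a, .data$element_b))
  }
  sig %>%
    group_by(.data$element_a, .data$element_b) %>%
    filter(dplyr::n_distinct(.data$group) == 1) %>%
    group_by(.data$group, .data$element_a, .data$element_b) %>%
    summarise(times = paste(sort(unique(.data$time_months)), collapse = ", "),
              .groups = "drop") %>%
    arrange(.data$group, .data$element_a, .data$element_b)
}

#' Overlap and sign reversal between two DCC scans
#'
#' Matches significant differential correlations from two group
#' comparisons (e.g. disease-vs-control and treatment-vs-disease) on
#' (pair, time point). A shared DCC is *reversed* when its two deltas have
#' strictly opposite signs -- the treatment pushing the correlation back
#' toward the control state.
#'
#' @param dccs_a,dccs_b `ionome_dcc` tibbles (or compatible tibbles); only
#'   rows flagged significant are considered.
#' @return List with `shared` (matched records with `delta_a`, `delta_b`
#'   and logical `reversed`) and `reversed` (the subset with opposite
#'   signs).
#' @export
overlap_and_reversed_dccs <- function(dccs_a, dccs_b) {
  sa <- filter(as_tibble(dccs_a), .data$significant)
  sb <- filter(as_tibble(dccs_b), .data$significant)
  shared <- dplyr::inner_join(
    select(sa, "element_a", "element_b", "time_months", delta_a = "delta"),
    select(sb, "element_a", "element_b", "time_months", delta_b = "delta"),
    by = c("element_a", "element_b", "time_months"))
  shared <- mutate(shared, reversed = .data$delta_a * .data$delta_b < 0)
  list(shared = shared, reversed = filter(shared, .data$reversed))
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat("<threshold_estimate> ", x$statistic, " at n = ", x$n,
      ", alpha = ", x$alpha, "\n", sep = "")
  cat(sprintf("  point = %.3f, central-95%% half-width = %.3f (%d x %d draws)\n",
              x$point, x$ci_half_width, x$outer_reps, x$inner_reps))
  invisible(x)
}

#' @method tidy threshold_estimate
#' @export
tidy.threshold_estimate <- function(x, ...) {
  tibble(statistic = x$statistic, n = x$n, alpha = x$alpha,
         point = x$point, ci_half_width = x$ci_half_width,
         inner_reps = x$inner_reps, outer_reps = x$outer_reps)
}

#' @method glance threshold_estimate
#' @export
glance.threshold_estimate <- function(x, ...) tidy(x)
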