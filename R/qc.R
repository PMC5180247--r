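# Classical two-tailed Dixon r10 critical values at alpha = 0.05 for
# n = 3..10 (Dean & Dixon / Rorabacher tabulation).
DIXON_Q_CRIT <- c(`3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625,
                  `7` = 0.568, `8` = 0.526, `9` = 0.493, `10` = 0.466)

#' Dixon's Q statistic for a single suspect value
#'
#' Computes the r10 ratio Q = gap / range at both extremes of the sample
#' (gap = distance from the extreme to its nearest neighbour, range = max -
#' min) and returns the larger of the two together with the index, in the
#' original input order, of the corresponding extreme.
#'
#' @param values Numeric vector of length 3 to 10 (the tabulated range).
#' @return A list with `q_statistic` and `suspect_index` (`NA` when the
#'   range is zero, i.e. all values identical).
#' @export
dixon_q <- function(values) {
  n <- length(values)
  if (n < 3 || n > 10) {
    abort("Dixon's Q is tabulated for 3 <= n <= 10 only")
  }
  rng <- max(values) - min(values)
  if (rng == 0) {
    return(list(q_statistic = 0, suspect_index = NA_integer_))
  }
  s <- sort(values)
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  if (q_high >= q_low) {
    list(q_statistic = q_high,
         suspect_index = which(values == s[n])[1])
  } else {
    list(q_statistic = q_low,
         suspect_index = which(values == s[1])[1])
  }
}

#' Critical value for Dixon's Q
#'
#' @param n Sample size (3..10).
#' @param alpha Significance level; only the classical two-tailed 0.05
#'   table is shipped.
#' @return The critical Q value.
#' @export
dixon_q_critical <- function(n, alpha = 0.05) {
  if (!isTRUE(all.equal(alpha, 0.05))) {
    abort("only the alpha = 0.05 Dixon table is available")
  }
  if (!as.character(n) %in% names(DIXON_Q_CRIT)) {
    abort("Dixon's Q is tabulated for 3 <= n <= 10 only")
  }
  unname(DIXON_Q_CRIT[as.character(n)])
}

#' Detect and mean-replace a single outlier in one measurement cell
#'
#' Single-pass Dixon Q screen: if the Q statistic exceeds the tabulated
#' critical value at `alpha`, the suspect value is replaced by the
#' arithmetic mean of the remaining values. At most one replacement is made
#' (Dixon's Q is defined for a single suspect value).
#'
#' @param values Numeric vector (3..10 values).
#' @param alpha Significance level (0.05).
#' @return A list with `values` (same length, possibly one value replaced),
#'   `q_statistic`, `q_critical`, `outlier_index` (NA if none) and
#'   `replaced_value` (the new value, NA if none).
#' @export
detect_and_replace <- function(values, alpha = 0.05) {
  q <- dixon_q(values)
  crit <- dixon_q_critical(length(values), alpha)
  out <- list(values = values, q_statistic = q$q_statistic,
              q_critical = crit, outlier_index = NA_integer_,
              replaced_value = NA_real_)
  if (!is.na(q$suspect_index) && q$q_statistic > crit) {
    repl <- mean(values[-q$suspect_index])
    out$values[q$suspect_index] <- repl
    out$outlier_index <- q$suspect_index
    out$replaced_value <- repl
  }
  out
}

#' Normality screen for one measurement cell
#'
#' Kolmogorov-Smirnov-type test of composite normality. By default the
#' normal parameters are estimated from the sample and the Lilliefors
#' small-sample calibration is used; with `estimated = FALSE` a plain KS
#' test against the normal with the sample's mean and sd is run instead
#' (anti-conservative, exposed for comparison).
#'
#' @param values Numeric vector (n >= 5 for the Lilliefors branch), non-zero
#'   variance.
#' @param estimated Use the Lilliefors calibration for estimated parameters
#'   (default TRUE).
#' @return The p-value.
#' @export
ks_normality <- function(values, estimated = TRUE) {
  if (sd(values) == 0) abort("normality test undefined for zero-variance data")
  if (estimated) {
    if (length(values) < 5) {
      abort("Lilliefors-corrected KS test needs at least 5 values")
    }
    nortest::lillie.test(values)$p.value
  } else {
    if (length(values) < 4) abort("KS normality test needs at least 4 values")
    suppressWarnings(
      ks.test(values, "pnorm", mean(values), sd(values))$p.value)
  }
}

#' Quality-control scan of an ionome dataset
#'
#' Applies [detect_and_replace()] (Dixon's Q with mean replacement) and
#' [ks_normality()] to every (group, time, element) cell and returns the
#' cleaned dataset together with a per-cell QC report.
#'
#' @param dataset Long-format ionome tibble.
#' @param alpha Dixon significance level.
#' @param ks Run the normality screen per cell (default TRUE).
#' @return An object of class `ionome_qc`: list with `data` (cleaned
#'   tibble, same shape as the input) and `report` (one row per cell:
#'   `group`, `time_months`, `element`, `n`, `q_statistic`, `q_critical`,
#'   `outlier_index`, `replaced_value`, `ks_p`).
#' @export
qc_scan <- function(dataset, alpha = 0.05, ks = TRUE) {
  cleaned <- dataset
  cells <- dataset %>%
    mutate(.row = dplyr::row_number()) %>%
    group_by(.data$group, .data$time_months, .data$element)
  keys <- dplyr::group_keys(cells)
  rows <- dplyr::group_rows(cells)
  report <- purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    idx <- rows[[i]]
    idx <- idx[order(dataset$sample_id[idx])]
    vals <- dataset$concentration[idx]
    dr <- detect_and_replace(vals, alpha)
    cleaned$concentration[idx] <<- dr$values
    ks_p <- if (ks && sd(dr$values) > 0) ks_normality(dr$values) else NA_real_
    tibble(group = keys$group[i], time_months = keys$time_months[i],
           element = keys$element[i], n = length(vals),
           q_statistic = dr$q_statistic, q_critical = dr$q_critical,
           outlier_index = dr$outlier_index,
           replaced_value = dr$replaced_value, ks_p = ks_p)
  })
  structure(list(data = cleaned, report = report, alpha = alpha),
            class = "ionome_qc")
}

#' @export
print.ionome_qc <- function(x, ...) {
  n_rep <- sum(!is.na(x$report$outlier_index))
  cat("<ionome_qc> ", nrow(x$report), " cells screened, ", n_rep,
      " outlier(s) replaced (Dixon Q, alpha = ", x$alpha, ")\n", sep = "")
  if (any(!is.na(x$report$ks_p))) {
    frac <- mean(x$report$ks_p < 0.05, na.rm = TRUE)
    cat("  cells rejecting normality at 0.05: ",
        sprintf("%.1f%%", 100 * frac), "\n", sep = "")
  }
  invisible(x)
}

#' @method tidy ionome_qc
#' @export
tidy.ionome_qc <- function(x, ...) x$report
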