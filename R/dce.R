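#' Two-sample Wilcoxon rank-sum p-value
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test between independent
#' samples. The p-value is exact (full enumeration of the rank-sum null)
#' whenever both samples have at most 8 observations and the pooled data
#' are tie-free; otherwise the normal approximation with midranks and tie
#' correction is used.
#'
#' @param a,b Numeric vectors (each with >= 1 observation; the
#'   differential-element scan requires >= 3 per cell).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- length(a) <= 8 && length(b) <= 8 && !ties
  res <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = !use_exact))
  min(res$p.value, 1)
}

#' Scan for differentially changed elements (DCEs)
#'
#' For every element and every time point shared by the two groups, runs
#' [wilcoxon_rank_sum()] between the comparison and reference cells. An
#' element is flagged as a DCE when p < `alpha`; the direction (increased /
#' decreased) is the sign of the comparison-minus-reference median
#' difference, consistent with the rank-based test.
#'
#' @param dataset Long-format ionome tibble.
#' @param reference,comparison Group labels; direction is
#'   comparison-relative-to-reference.
#' @param alpha Significance level (raw p-values by default, matching the
#'   p < 0.05 rule).
#' @param adjust Multiple-testing correction across the scan: `"none"`
#'   (default) or `"BH"` (Benjamini-Hochberg); when `"BH"`, the DCE flag
#'   uses the adjusted p-value.
#' @return A tibble of class `ionome_dce`, one row per (element, shared
#'   time point), sorted by time then element: columns `element`,
#'   `time_months`, `reference`, `comparison`, `p_value`, `p_adjusted`,
#'   `direction`, `is_dce`.
#' @export
dce_scan <- function(dataset, reference, comparison, alpha = 0.05,
                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  for (g in c(reference, comparison)) {
    if (!g %in% dataset$group) abort(paste0("group not in dataset: ", g))
  }
  t_ref <- unique(dataset$time_months[dataset$group == reference])
  t_cmp <- unique(dataset$time_months[dataset$group == comparison])
  shared <- sort(intersect(t_ref, t_cmp))
  if (!length(shared)) abort("groups share no time points")
  elements <- unique(dataset$element)
  grid <- tidyr::expand_grid(time_months = shared, element = elements)
  out <- purrr::pmap_dfr(grid, function(time_months, element) {
    ref <- dataset$concentration[dataset$group == reference &
                                   dataset$time_months == time_months &
                                   dataset$element == element]
    cmp <- dataset$concentration[dataset$group == comparison &
                                   dataset$time_months == time_months &
                                   dataset$element == element]
    tibble(element = element, time_months = time_months,
           reference = reference, comparison = comparison,
           p_value = wilcoxon_rank_sum(ref, cmp),
           direction = ifelse(median(cmp) >= median(ref),
                              "increased", "decreased"))
  })
  out$p_adjusted <- if (adjust == "BH") p.adjust(out$p_value, "BH") else out$p_value
  out$is_dce <- out$p_adjusted < alpha
  out <- arrange(out, .data$time_months, .data$element)
  out <- out[, c("element", "time_months", "reference", "comparison",
                 "p_value", "p_adjusted", "direction", "is_dce")]
  class(out) <- c("ionome_dce", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Summarise a DCE scan as a per-time table
#'
#' Condenses a [dce_scan()] result into one row per time point with
#' comma-separated lists of increased and decreased elements, the shape in
#' which differentially changed elements are usually reported.
#'
#' @param dce A `ionome_dce` tibble.
#' @return Tibble with `time_months`, `increased`, `decreased`.
#' @export
dce_table <- function(dce) {
  dce %>%
    filter(.data$is_dce) %>%
    group_by(.data$time_months) %>%
    summarise(
      increased = paste(.data$element[.data$direction == "increased"],
                        collapse = ", "),
      decreased = paste(.data$element[.data$direction == "decreased"],
                        collapse = ", "),
      .groups = "drop") %>%
    tidyr::complete(time_months = sort(unique(dce$time_months)),
                    fill = list(increased = "", decreased = ""))
}

#' Two-way group x time ANOVA for one element
#'
#' Fixed-effects two-way analysis of variance of concentration on group,
#' time (as a factor) and their interaction, restricted to the time points
#' shared by the two groups. Animals are sacrificed at each time point, so
#' times index independent cohorts rather than repeated measures of one
#' animal; a fixed-effects model is therefore used.
#'
#' @param dataset Long-format ionome tibble.
#' @param element Element symbol.
#' @param groups Character vector of two group labels.
#' @return Tibble with one row per term (`group`, `time`, `group:time`):
#'   columns `term`, `df`, `statistic` (F), `p_value`.
#' @export
anova_group_time <- function(dataset, element, groups) {
  d <- dataset %>%
    filter(.data$element == !!element, .data$group %in% groups)
  shared <- Reduce(intersect,
                   lapply(groups, function(g) unique(d$time_months[d$group == g])))
  if (length(shared) < 2) abort("need at least 2 shared time points")
  d <- filter(d, .data$time_months %in% shared)
  counts <- d %>% dplyr::count(.data$group, .data$time_months)
  grid <- tidyr::expand_grid(group = groups, time_months = shared)
  miss <- dplyr::anti_join(grid, counts, by = c("group", "time_months"))
  small <- filter(counts, n < 2)
  if (nrow(miss) || nrow(small)) {
    bad <- bind_rows(miss[, c("group", "time_months")],
                     small[, c("group", "time_months")])
    abort(paste0("cell(s) with fewer than 2 observations: ",
                 paste(paste0("(", bad$group, ", ", bad$time_months, "m)"),
                       collapse = ", ")))
  }
  d$group <- factor(d$group, levels = groups)
  d$time_f <- factor(d$time_months)
  fit <- aov(concentration ~ group * time_f, data = d)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  keep <- terms != "Residuals"
  tibble(term = sub("time_f", "time", terms[keep]),
         df = s$Df[keep],
         statistic = s$`F value`[keep],
         p_value = s$`Pr(>F)`[keep])
}

#' @export
print.ionome_dce <- function(x, ...) {
  cat("<ionome_dce> ", x$comparison[1], " vs ", x$reference[1], ": ",
      sum(x$is_dce), " DCE(s) among ", nrow(x), " element x time tests ",
      "(alpha = ", attr(x, "alpha"), ")\n", sep = "")
  NextMethod()
}
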