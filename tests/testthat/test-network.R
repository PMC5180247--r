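test_that("spearman_rho matches the closed form and handles edge cases", {
  expect_equal(spearman_rho(c(1, 5, 9, 12), c(0.1, 0.2, 3, 40)), 1)
  expect_equal(spearman_rho(1:6, c(2, 1, 4, 3, 6, 5)), 1 - 6 * 6 / 210)
  expect_equal(spearman_rho(1:4, 4:1), -1)
  expect_error(spearman_rho(rep(1, 4), 1:4), "constant")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  set.seed(301)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(spearman_rho(x, y), closed_form_rho(x, y))
    expect_equal(spearman_rho(x, y), spearman_rho(y, x))
    expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
    expect_lte(abs(spearman_rho(x, y)), 1)
  }
  # midranks under ties agree with the tie-aware closed form via cor
  x <- c(1, 1, 2, 3); y <- c(2, 4, 4, 5)
  expect_equal(spearman_rho(x, y), cor(rank(x), rank(y)))
})

test_that("scc_matrix enumerates all unordered pairs with a significance
           flag", {
  cfg <- default_config(outlier_rate = 0)
  d <- generate_dataset(cfg, seed = 51)
  e <- scc_matrix(d, "AD", 4, tau = 0.749)
  expect_equal(nrow(e), choose(15, 2))  # 105 pairs
  expect_equal(anyDuplicated(t(apply(e[, c("element_a", "element_b")], 1,
                                     sort))), 0L)
  expect_true(all(e$element_a != e$element_b))
  expect_equal(e$significant, abs(e$scc) > 0.749)

  small <- generate_dataset(null_config(elements = c("Fe", "V", "Zn", "Cu")),
                            seed = 52)
  expect_equal(nrow(scc_matrix(small, "G1", 4, tau = 0.9)), 6)
  expect_error(scc_matrix(d, "AD", 99, tau = 1), "no cell")
})

test_that("a near-perfect planted correlation is detected at n = 6 while
           the two-sided null exceedance sits near twice alpha", {
  hits <- vapply(1:30, function(s) {
    cfg <- planted_pair_config(0.99, elements = c("Fe", "V", "Zn"))
    d <- generate_dataset(cfg, seed = 600 + s)
    e <- scc_matrix(d, "G1", 4, tau = 0.749)
    dplyr::filter(e, element_a == "Fe", element_b == "V")$significant
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # flagging |SCC| > tau at the signed 95% quantile is two-sided: the
  # exact null exceedance at n = 6 is 74/720, about 10%
  set.seed(302)
  null_flags <- replicate(2000, abs(spearman_rho(rnorm(6), rnorm(6))) > 0.749)
  expect_gt(mean(null_flags), 0.06)
  expect_lt(mean(null_flags), 0.15)
  expect_equal(exact_null_scc_tail(6, 0.749) + 1 - exact_null_scc_tail(6, -0.749 + 1e-9),
               74 / 720, tolerance = 1e-9)
})

test_that("exact permutation-null tail matches direct enumeration counts", {
  expect_equal(exact_null_scc_tail(3, 1), 1 / 6)
  expect_equal(exact_null_scc_tail(4, 1), 1 / 24)
  expect_equal(exact_null_scc_tail(5, -1), 1)
  # n = 6 atoms around the 95th percentile
  expect_equal(exact_null_scc_tail(6, 0.8285), 21 / 720)
  expect_equal(exact_null_scc_tail(6, 0.7714), 37 / 720)
  expect_error(exact_null_scc_tail(9, 0.5), "n <= 8")
})

test_that("threshold simulation is seeded, interpolated, monotone in n and
           consistent with the exact null", {
  a <- simulate_scc_threshold(6, outer_reps = 50, seed = 77)
  b <- simulate_scc_threshold(6, outer_reps = 50, seed = 77)
  expect_identical(a$point, b$point)
  expect_gt(a$point, 0)
  expect_gte(a$ci_half_width, 0)

  # monotone non-increasing in n
  pts <- vapply(c(4, 6, 10), function(n) {
    simulate_scc_threshold(n, outer_reps = 100, seed = 78)$point
  }, numeric(1))
  expect_true(all(diff(pts) < 0))

  # alpha -> 0: the quantile approaches the support maximum
  tight <- simulate_scc_threshold(6, alpha = 0.001, outer_reps = 20,
                                  seed = 79)
  expect_gt(tight$point, 0.94)

  # exact tail probability at the simulated point is within 0.02 of alpha
  for (n in c(5, 6, 7)) {
    est <- simulate_scc_threshold(n, outer_reps = 200, seed = 80 + n)
    expect_lt(abs(exact_null_scc_tail(n, est$point) - 0.05), 0.02)
  }

  expect_s3_class(tidy(a), "tbl_df")
  expect_equal(glance(a)$point, a$point)
})

test_that("difference-of-correlations threshold exceeds the single-
           correlation threshold and is monotone in n", {
  scc <- simulate_scc_threshold(6, outer_reps = 100, seed = 90)
  dcc <- simulate_dcc_threshold(6, outer_reps = 100, seed = 90)
  expect_gt(dcc$point, scc$point)
  pts <- vapply(c(4, 6, 10), function(n) {
    simulate_dcc_threshold(n, outer_reps = 50, seed = 91)$point
  }, numeric(1))
  expect_true(all(diff(pts) < 0))
  # independent large-sample check: single-batch Monte-Carlo quantile
  set.seed(92)
  big <- quantile(replicate(2e5, closed_form_rho(sample.int(6), sample.int(6))) -
                    replicate(2e5, closed_form_rho(sample.int(6), sample.int(6))),
                  0.95, names = FALSE)
  expect_lt(abs(dcc$point - big), 2 * dcc$ci_half_width)
})

test_that("delta_scc is the plain difference, antisymmetric and bounded", {
  expect_identical(delta_scc(0.886, -0.6), 0.886 - -0.6)
  expect_identical(delta_scc(-0.319, 0.886), -0.319 - 0.886)
  expect_equal(delta_scc(0.4, 0.4), 0)
  set.seed(303)
  x <- runif(50, -1, 1); y <- runif(50, -1, 1)
  expect_equal(delta_scc(x, y), -delta_scc(y, x))
  expect_true(all(abs(delta_scc(x, y)) <= 2))
  expect_error(delta_scc(1.2, 0), "abs")
})

test_that("dcc_scan flags planted correlation flips and nothing on
           relabeled identical data", {
  cfg <- null_config(times = 4, elements = c("Fe", "Mn", "Zn"))
  d <- generate_dataset(cfg, seed = 61)
  # same observations relabeled as two groups: every delta is exactly 0
  dup <- dplyr::mutate(dplyr::filter(d, group == "G1"), group = "G3",
                       sample_id = paste0(sample_id, "_b"))
  dcc0 <- dcc_scan(dplyr::bind_rows(dplyr::filter(d, group == "G1"), dup),
                   "G1", "G3", tau_dcc = 1.05)
  expect_true(all(dcc0$delta == 0))
  expect_false(any(dcc0$significant))

  hits <- vapply(1:30, function(s) {
    cfg <- ionome_config(
      groups = c("A", "B"), timepoints_by_group = list(A = 4, B = 4),
      elements = c("Fe", "Mn", "Zn"),
      cell_cv = c(Fe = 0.2, Mn = 0.2, Zn = 0.2),
      planted_correlations = tibble::tibble(
        group = c("A", "B"), time_months = 4, element_a = "Fe",
        element_b = "Mn", rho = c(0.9, -0.9)),
      outlier_rate = 0)
    d <- generate_dataset(cfg, seed = 700 + s)
    dcc <- dcc_scan(d, "A", "B", tau_dcc = 1.05)
    dplyr::filter(dcc, element_a == "Fe", element_b == "Mn")$significant
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  expect_error(dcc_scan(generate_dataset(null_config(), seed = 1),
                        "G1", "missing", tau_dcc = 1), "share no time")
})

test_that("group-specific edges require significance in exactly one group", {
  base <- tibble::tibble(
    element_a = c("Zn", "Zn", "Fe", "Fe"),
    element_b = c("Se", "Se", "V", "V"),
    group = c("AD", "WT", "AD", "WT"),
    time_months = 4, n = 6,
    scc = c(0.9, 0.1, 0.9, 0.95),
    significant = c(TRUE, FALSE, TRUE, TRUE))
  gs <- group_specific_edges(base)
  expect_equal(nrow(gs), 1)
  expect_equal(gs$group, "AD")
  expect_equal(gs$element_a, "Zn")
  # per-time view keeps the shared Fe-V edge out as well
  gs_t <- group_specific_edges(base, by_time = TRUE)
  expect_false(any(gs_t$element_a == "Fe"))

  # planted AD-only Zn-Se correlation is reported AD-specific
  hits <- vapply(1:20, function(s) {
    cfg <- ionome_config(
      groups = c("WT", "AD"),
      timepoints_by_group = list(WT = 4, AD = 4),
      elements = c("Zn", "Se", "Fe"),
      cell_cv = c(Zn = 0.2, Se = 0.2, Fe = 0.2),
      planted_correlations = tibble::tibble(
        group = "AD", time_months = 4, element_a = "Zn", element_b = "Se",
        rho = 0.97),
      outlier_rate = 0)
    d <- generate_dataset(cfg, seed = 800 + s)
    edges <- dplyr::bind_rows(scc_matrix(d, "WT", 4, tau = 0.749),
                              scc_matrix(d, "AD", 4, tau = 0.749))
    gs <- group_specific_edges(edges)
    any(gs$group == "AD" & gs$element_a == "Zn" & gs$element_b == "Se")
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("overlap detection matches pairs on (pair, time) and calls
           strict sign flips reversed", {
  mk <- function(a, b, t, delta) {
    tibble::tibble(element_a = a, element_b = b, time_months = t,
                   delta = delta, significant = abs(delta) > 1.05)
  }
  ad_wt <- mk(c("Fe", "Zn"), c("Mn", "Cu"), 4, c(1.486, 1.2))
  se_ad <- mk(c("Fe", "Zn"), c("Mn", "Cu"), c(4, 6), c(-1.205, 1.3))
  res <- overlap_and_reversed_dccs(ad_wt, se_ad)
  expect_equal(nrow(res$shared), 1)  # Zn-Cu differs in time point
  expect_equal(res$shared$element_a, "Fe")
  expect_true(res$shared$reversed)
  expect_equal(nrow(res$reversed), 1)

  same_sign <- overlap_and_reversed_dccs(mk("Fe", "Mn", 4, 1.2),
                                         mk("Fe", "Mn", 4, 1.3))
  expect_equal(nrow(same_sign$shared), 1)
  expect_false(same_sign$shared$reversed)
  expect_equal(nrow(same_sign$reversed), 0)

  disjoint <- overlap_and_reversed_dccs(mk("Fe", "Mn", 4, 1.2),
                                        mk("Zn", "Cu", 4, 1.3))
  expect_equal(nrow(disjoint$shared), 0)
  expect_equal(nrow(disjoint$reversed), 0)
})

test_that("the planted Fe-Mn reversal propagates end to end", {
  hits <- vapply(1:40, function(s) {
    d <- generate_dataset(default_config(outlier_rate = 0), seed = 900 + s)
    ad_wt <- dcc_scan(d, "AD", "WT", tau_dcc = 1.05)
    se_ad <- dcc_scan(d, "Se", "AD", tau_dcc = 1.05)
    res <- overlap_and_reversed_dccs(ad_wt, se_ad)
    any(res$reversed$element_a == "Fe" & res$reversed$element_b == "Mn" &
          res$reversed$time_months == 4)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
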