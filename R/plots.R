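#' Plot element time courses
#'
#' Mean concentration with a normal-approximation 95% confidence band per
#' group over time, one panel per element -- the standard way to eyeball
#' group differences in an ionome study.
#'
#' @param dataset Long-format ionome tibble.
#' @param elements Elements to show (default all).
#' @return A ggplot.
#' @export
plot_element_profiles <- function(dataset, elements = NULL) {
  d <- as_tibble(dataset)
  if (!is.null(elements)) d <- filter(d, .data$element %in% elements)
  s <- d %>%
    group_by(.data$group, .data$time_months, .data$element) %>%
    summarise(mean = mean(.data$concentration),
              se = sd(.data$concentration) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(.data$time_months, .data$mean,
                                  colour = .data$group,
                                  fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                      ymax = .data$mean + 1.96 * .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~element, scales = "free_y") +
    ggplot2::labs(x = "Age (months)", y = "Concentration (a.u.)",
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}

#' @method autoplot ionome_dce
#' @export
autoplot.ionome_dce <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(effect = ifelse(.data$is_dce,
                           ifelse(.data$direction == "increased",
                                  "increased", "decreased"),
                           "ns"))
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$time_months), .data$element,
                                  fill = .data$effect)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c(increased = "#c0392b",
                                          decreased = "#27ae60",
                                          ns = "grey95")) +
    ggplot2::labs(x = "Age (months)", y = NULL, fill = NULL,
                  title = paste0("DCEs: ", d$comparison[1], " vs ",
                                 d$reference[1])) +
    ggplot2::theme_minimal()
}

#' @method autoplot threshold_estimate
#' @export
autoplot.threshold_estimate <- function(object, ...) {
  d <- tibble(quantile = object$quantiles)
  ggplot2::ggplot(d, ggplot2::aes(.data$quantile)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$point, linetype = 2) +
    ggplot2::labs(
      x = sprintf("empirical %g%% null quantile", 100 * (1 - object$alpha)),
      y = "inner runs",
      title = sprintf("%s threshold at n = %d: %.3f ± %.3f",
                      object$statistic, object$n, object$point,
                      object$ci_half_width)) +
    ggplot2::theme_minimal()
}

#' @method autoplot ionome_dcc
#' @export
autoplot.ionome_dcc <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(pair = paste(.data$element_a, .data$element_b, sep = "-"))
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$time_months), .data$pair,
                                  fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = filter(d, .data$significant), size = 0.6) +
    ggplot2::scale_fill_gradient2(low = "#27ae60", mid = "white",
                                  high = "#c0392b", limits = c(-2, 2)) +
    ggplot2::labs(x = "Age (months)", y = NULL,
                  fill = expression(Delta * "SCC"),
                  title = paste0(d$group1[1], " - ", d$group2[1],
                                 " (dots: significant DCCs)")) +
    ggplot2::theme_minimal()
}

#' @method autoplot ionome_clust
#' @export
autoplot.ionome_clust <- function(object, ...) {
  hc <- object$hclust
  # dendrogram as segments: x = leaf order, y = merge height
  n <- length(hc$labels)
  pos <- numeric(nrow(hc$merge))   # x position of each internal node
  hgt <- hc$height
  leaf_x <- setNames(seq_len(n), hc$order)
  segs <- list()
  node_x <- function(id) {
    if (id < 0) unname(leaf_x[as.character(-id)]) else pos[id]
  }
  node_y <- function(id) if (id < 0) 0 else hgt[id]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- node_x(a); xb <- node_x(b)
    pos[i] <- (xa + xb) / 2
    segs[[i]] <- tibble(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(node_y(a), hgt[i], node_y(b)), yend = c(hgt[i], hgt[i], hgt[i]))
  }
  labs <- tibble(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot(bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(.data$x, -0.02, label = .data$label),
                       vjust = 1, size = 3) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL,
                  y = sprintf("1 - %s correlation (%s linkage)",
                              object$cor_method, object$linkage)) +
    ggplot2::theme_minimal()
}
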