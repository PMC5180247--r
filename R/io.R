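#' Read a long-format ionome table
#'
#' Reads a delimited file with the canonical columns `sample_id`, `group`,
#' `time_months`, `element`, `concentration` and validates it: duplicate
#' (sample, element) rows and non-positive concentrations are rejected with
#' the offending row numbers; element symbols outside the canonical
#' 15-element panel are accepted with a warning.
#'
#' @param path File path (TSV by default; `delim` passes through).
#' @param delim Field delimiter.
#' @return A validated ionome tibble.
#' @export
read_ionome_table <- function(path, delim = "\t") {
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         comment = "#")
  required <- c("sample_id", "group", "time_months", "element",
                "concentration")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  d <- d[, required]
  validate_ionome(d)
}

validate_ionome <- function(d) {
  bad <- which(!is.finite(d$concentration) | d$concentration <= 0)
  if (length(bad)) {
    abort(paste0("non-positive or missing concentration at row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  dup <- which(duplicated(d[, c("sample_id", "element")]))
  if (length(dup)) {
    abort(paste0("duplicated (sample_id, element) at row(s): ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  multi <- d %>%
    distinct(.data$sample_id, .data$group, .data$time_months) %>%
    dplyr::count(.data$sample_id) %>%
    filter(n > 1)
  if (nrow(multi)) {
    abort(paste0("sample(s) mapped to more than one (group, time): ",
                 paste(head(multi$sample_id, 5), collapse = ", ")))
  }
  unknown <- setdiff(unique(d$element), ION_ELEMENTS)
  if (length(unknown)) {
    warn(paste0("element symbol(s) outside the canonical panel: ",
                paste(unknown, collapse = ", ")))
  }
  as_tibble(d)
}

#' Write a long-format ionome table
#'
#' @param dataset Ionome tibble.
#' @param path Output path.
#' @param delim Field delimiter (TSV by default).
#' @return `path`, invisibly.
#' @export
write_ionome_table <- function(dataset, path, delim = "\t") {
  readr::write_delim(dataset, path, delim = delim)
  invisible(path)
}

edges_to_igraph <- function(edges, significant_only = TRUE) {
  e <- as_tibble(edges)
  if (significant_only) e <- filter(e, .data$significant)
  g <- igraph::graph_from_data_frame(
    e[, c("element_a", "element_b")], directed = FALSE,
    vertices = unique(c(edges$element_a, edges$element_b)))
  if (nrow(e)) {
    igraph::E(g)$scc <- e$scc
    igraph::E(g)$sign <- ifelse(e$scc >= 0, "positive", "negative")
    igraph::E(g)$significant <- e$significant
  }
  g
}

#' Export a correlation network in SIF format
#'
#' Writes the significant edges of one edge table as Cytoscape simple
#' interaction format lines: `elementA corr elementB`.
#'
#' @param edges Edge tibble from [scc_matrix()].
#' @param path Output path.
#' @param significant_only Export only flagged edges (default TRUE).
#' @return `path`, invisibly.
#' @export
export_sif <- function(edges, path, significant_only = TRUE) {
  e <- as_tibble(edges)
  if (significant_only) e <- filter(e, .data$significant)
  writeLines(sprintf("%s corr %s", e$element_a, e$element_b), path)
  invisible(path)
}

#' Export a correlation network in GraphML format
#'
#' Writes the edges (with `scc`, `sign` and `significant` attributes) as
#' GraphML, loadable by Cytoscape.
#'
#' @inheritParams export_sif
#' @return `path`, invisibly.
#' @export
export_graphml <- function(edges, path, significant_only = TRUE) {
  g <- edges_to_igraph(edges, significant_only)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
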