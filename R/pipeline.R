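#' Run the full ionome analysis pipeline
#'
#' Composes the analysis stages in order -- QC (Dixon Q + normality screen),
#' differentially changed elements per group pair, element clustering and
#' group classification, per-(group, time) correlation networks,
#' simulation-derived thresholds, differentially changed correlations and
#' the overlap/reversal report -- and optionally writes the whole bundle to
#' an output directory (TSV tables, SIF/GraphML networks, Newick
#' dendrogram, JSON threshold report and run manifest).
#'
#' All randomness flows from `seed` through named per-stage substreams, so
#' re-running with the same inputs and seed reproduces the bundle.
#'
#' @param dataset Ionome tibble; if NULL, a synthetic dataset is generated
#'   from `config`.
#' @param config `ionome_config` used when `dataset` is NULL (default
#'   [default_config()]).
#' @param reference,disease,treated Group labels in the control / disease /
#'   treated roles (defaults WT, AD, Se).
#' @param alpha Significance level for DCE tests and threshold simulation.
#' @param tau_scc,tau_dcc Numeric threshold overrides (e.g. 0.749 and 1.05
#'   for exact replication of the study cutoffs); NULL simulates them.
#' @param inner_reps,outer_reps Threshold simulation settings used when no
#'   override is given.
#' @param classify_groups_pair Groups for the classification stage
#'   (default treated vs disease).
#' @param k Flat cluster count for the dendrogram cut.
#' @param outdir Output directory; NULL skips file output.
#' @param seed Top-level seed.
#' @return Object of class `ionome_pipeline`: list with `data`, `qc`,
#'   `dce` (list per pair), `dce_tables`, `clustering`, `classifier`,
#'   `edges`, `thresholds`, `dcc` (list per pair), `overlap`,
#'   `group_specific`, `manifest`.
#' @export
run_pipeline <- function(dataset = NULL, config = default_config(),
                         reference = "WT", disease = "AD", treated = "Se",
                         alpha = 0.05, tau_scc = NULL, tau_dcc = NULL,
                         inner_reps = 1000, outer_reps = 200,
                         classify_groups_pair = c(treated, disease),
                         k = 4, outdir = NULL, seed = 1L) {
  if (is.null(dataset)) {
    dataset <- generate_dataset(config, seed = substream_seed(seed, "simulate"))
  }
  dataset <- validate_ionome(dataset)

  qc <- qc_scan(dataset, alpha = alpha)
  clean <- qc$data

  pairs <- list(disease_vs_reference = c(reference, disease),
                treated_vs_disease = c(disease, treated))
  dce <- purrr::map(pairs, function(p) {
    dce_scan(clean, reference = p[1], comparison = p[2], alpha = alpha)
  })
  dce_tables <- purrr::map(dce, dce_table)

  clustering <- cluster_elements(clean, k = k)
  classifier <- classify_groups(clean, groups = classify_groups_pair,
                                algorithm = "decision_tree",
                                seed = substream_seed(seed, "classify"))

  n_cell <- clean %>%
    dplyr::count(.data$group, .data$time_months, .data$element) %>%
    pull(n) %>% min()
  thr_scc <- if (is.numeric(tau_scc)) NULL else
    simulate_scc_threshold(n_cell, alpha, inner_reps, outer_reps,
                           seed = substream_seed(seed, "tau_scc"))
  thr_dcc <- if (is.numeric(tau_dcc)) NULL else
    simulate_dcc_threshold(n_cell, alpha, inner_reps, outer_reps,
                           seed = substream_seed(seed, "tau_dcc"))
  tau_scc_val <- if (is.numeric(tau_scc)) tau_scc else thr_scc$point
  tau_dcc_val <- if (is.numeric(tau_dcc)) tau_dcc else thr_dcc$point

  cells <- clean %>% distinct(.data$group, .data$time_months)
  edges <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    scc_matrix(clean, cells$group[i], cells$time_months[i],
               tau = tau_scc_val)
  })

  dcc <- list(
    disease_vs_reference = dcc_scan(clean, disease, reference,
                                    tau_dcc = tau_dcc_val),
    treated_vs_disease = dcc_scan(clean, treated, disease,
                                  tau_dcc = tau_dcc_val))
  overlap <- overlap_and_reversed_dccs(dcc$disease_vs_reference,
                                       dcc$treated_vs_disease)
  specific <- group_specific_edges(edges)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ionomeNet")),
    seed = seed, alpha = alpha,
    n_per_cell = n_cell,
    tau_scc = tau_scc_val, tau_dcc = tau_dcc_val,
    tau_overridden = c(scc = is.numeric(tau_scc), dcc = is.numeric(tau_dcc)),
    n_samples = dplyr::n_distinct(dataset$sample_id),
    n_records = nrow(dataset),
    outliers_replaced = sum(!is.na(qc$report$outlier_index)),
    dce_counts = purrr::map_int(dce, ~ sum(.x$is_dce)),
    dcc_counts = purrr::map_int(dcc, ~ sum(.x$significant)),
    shared_dccs = nrow(overlap$shared),
    reversed_dccs = nrow(overlap$reversed))

  res <- structure(
    list(data = clean, qc = qc, dce = dce, dce_tables = dce_tables,
         clustering = clustering, classifier = classifier, edges = edges,
         thresholds = list(scc = thr_scc %||% tau_scc_val,
                           dcc = thr_dcc %||% tau_dcc_val),
         dcc = dcc, overlap = overlap, group_specific = specific,
         manifest = manifest),
    class = "ionome_pipeline")
  if (!is.null(outdir)) write_pipeline_bundle(res, outdir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_bundle <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  hdr <- sprintf("# ionomeNet seed=%d tau_scc=%.6g tau_dcc=%.6g",
                 res$manifest$seed, res$manifest$tau_scc,
                 res$manifest$tau_dcc)
  wtsv <- function(x, path) {
    writeLines(hdr, path)
    readr::write_delim(as_tibble(x), path, delim = "\t", append = TRUE,
                       col_names = TRUE)
  }
  wtsv(res$data, p("cleaned_ionome.tsv"))
  wtsv(res$qc$report, p("qc_report.tsv"))
  for (nm in names(res$dce)) {
    wtsv(res$dce[[nm]], p(paste0("dce_", nm, ".tsv")))
    wtsv(res$dce_tables[[nm]], p(paste0("dce_table_", nm, ".tsv")))
  }
  write_dendrogram_newick(res$clustering, p("element_dendrogram.nwk"))
  prof <- element_profile_matrix(res$data)
  wtsv(as_tibble(cbind(element = rownames(prof), as.data.frame(prof))),
       p("heatmap_matrix.tsv"))
  wtsv(tidy(res$classifier), p("classifier_importance.tsv"))
  wtsv(glance(res$classifier), p("classifier_accuracy.tsv"))
  wtsv(res$edges, p("edges.tsv"))
  cells <- distinct(as_tibble(res$edges), .data$group, .data$time_months)
  for (i in seq_len(nrow(cells))) {
    sub <- filter(as_tibble(res$edges), .data$group == cells$group[i],
                  .data$time_months == cells$time_months[i])
    base <- sprintf("network_%s_%02.0fm", cells$group[i],
                    cells$time_months[i])
    export_sif(sub, p(paste0(base, ".sif")))
    export_graphml(sub, p(paste0(base, ".graphml")))
  }
  for (nm in names(res$dcc)) wtsv(res$dcc[[nm]], p(paste0("dcc_", nm, ".tsv")))
  wtsv(res$overlap$shared, p("dcc_shared.tsv"))
  wtsv(res$overlap$reversed, p("dcc_reversed.tsv"))
  wtsv(res$group_specific, p("group_specific_edges.tsv"))
  thr <- purrr::map(res$thresholds, function(t) {
    if (inherits(t, "threshold_estimate")) {
      as.list(tidy(t)[1, ])
    } else {
      list(point = t, source = "override")
    }
  })
  jsonlite::write_json(thr, p("thresholds.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}

#' @export
print.ionome_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<ionome_pipeline>\n")
  cat("  samples:", m$n_samples, "| records:", m$n_records,
      "| outliers replaced:", m$outliers_replaced, "\n")
  cat(sprintf("  thresholds: |SCC| > %.3f, |dSCC| > %.3f (n = %d)\n",
              m$tau_scc, m$tau_dcc, m$n_per_cell))
  cat("  DCEs:", paste(names(m$dce_counts), m$dce_counts, sep = "=",
                       collapse = ", "), "\n")
  cat("  DCCs:", paste(names(m$dcc_counts), m$dcc_counts, sep = "=",
                       collapse = ", "),
      "| shared:", m$shared_dccs, "| reversed:", m$reversed_dccs, "\n")
  cat(sprintf("  classifier (%s): cv accuracy %.3f\n",
              x$classifier$algorithm, x$classifier$accuracy))
  invisible(x)
}
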