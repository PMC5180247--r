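#' Row-wise z-score standardisation
#'
#' Standardises each row (element) of a raw concentration matrix to mean 0
#' and sample sd 1 (denominator n - 1). Constant rows cannot be scaled;
#' they become all-zero and are flagged in the `constant_rows` attribute.
#'
#' @param m Numeric matrix, elements in rows, samples in columns (>= 2
#'   columns).
#' @return The standardised matrix with attribute `constant_rows` (logical
#'   vector per row).
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) abort("z-scoring needs at least 2 columns")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  constant <- s == 0
  z <- (m - mu) / ifelse(constant, 1, s)
  z[constant, ] <- 0
  attr(z, "constant_rows") <- setNames(constant, rownames(m))
  z
}

#' Element-by-sample profile matrix
#'
#' Reshapes a long-format ionome dataset into an elements x samples matrix
#' of z-scored concentrations (rows standardised via [zscore_rows()]),
#' with samples ordered by group, time, then sample id.
#'
#' @param dataset Long-format ionome tibble.
#' @return Z-scored matrix; row names are elements, column names sample
#'   ids, with `sample_info` attribute (tibble of sample_id, group,
#'   time_months).
#' @export
element_profile_matrix <- function(dataset) {
  info <- dataset %>%
    distinct(.data$sample_id, .data$group, .data$time_months) %>%
    arrange(.data$group, .data$time_months, .data$sample_id)
  elements <- unique(dataset$element)
  wide <- dataset %>%
    select("sample_id", "element", "concentration") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "concentration")
  m <- as.matrix(wide[, info$sample_id, drop = FALSE])
  rownames(m) <- wide$element
  z <- zscore_rows(m[elements, , drop = FALSE])
  attr(z, "sample_info") <- info
  z
}

#' Hierarchical clustering of element profiles
#'
#' Agglomerative clustering of elements using the correlation distance
#' 1 - rho between z-scored element profiles (Spearman by default, for
#' consistency with the network analysis). Elements are put in canonical
#' panel order before clustering so the dendrogram does not depend on the
#' input row order.
#'
#' @param x Long-format ionome tibble, or a profile matrix from
#'   [element_profile_matrix()] / [zscore_rows()].
#' @param linkage Agglomeration rule: `"ward"` (ward.D2, default),
#'   `"average"` or `"complete"`.
#' @param k Optional number of flat clusters to cut.
#' @param cor_method `"spearman"` (default) or `"pearson"`.
#' @return Object of class `ionome_clust`: list with `hclust`, `dist`,
#'   `linkage`, `cor_method` and (when `k` given) `clusters` (named
#'   membership vector).
#' @export
cluster_elements <- function(x, linkage = c("ward", "average", "complete"),
                             k = NULL, cor_method = c("spearman", "pearson")) {
  linkage <- match.arg(linkage)
  cor_method <- match.arg(cor_method)
  profiles <- if (is.matrix(x)) x else element_profile_matrix(x)
  if (nrow(profiles) < 3) abort("need at least 3 elements to cluster")
  ord <- intersect(ION_ELEMENTS, rownames(profiles))
  ord <- c(ord, setdiff(rownames(profiles), ord))
  profiles <- profiles[ord, , drop = FALSE]
  D <- as.dist(1 - cor(t(profiles), method = cor_method))
  hc <- hclust(D, method = switch(linkage, ward = "ward.D2", linkage))
  res <- list(hclust = hc, dist = D, linkage = linkage,
              cor_method = cor_method)
  if (!is.null(k)) res$clusters <- cutree(hc, k = k)
  structure(res, class = "ionome_clust")
}

#' @export
print.ionome_clust <- function(x, ...) {
  cat("<ionome_clust> ", length(x$hclust$labels), " elements, 1 - ",
      x$cor_method, " correlation distance, ", x$linkage, " linkage\n",
      sep = "")
  if (!is.null(x$clusters)) {
    cat("  k =", max(x$clusters), "clusters:",
        paste(vapply(split(names(x$clusters), x$clusters), paste,
                     character(1), collapse = "/"), collapse = " | "), "\n")
  }
  invisible(x)
}

#' @method tidy ionome_clust
#' @export
tidy.ionome_clust <- function(x, ...) {
  hc <- x$hclust
  tibble(merge_step = seq_along(hc$height), height = hc$height)
}

#' Export a dendrogram as Newick text
#'
#' @param clust An `ionome_clust`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clust, path) {
  ape::write.tree(ape::as.phylo(clust$hclust), file = path)
  invisible(path)
}

# Stratified fold assignment: within each class, cycle folds over a
# random permutation of the class members.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' Classify group membership from element profiles
#'
#' Pools samples across time points (time is dropped from the feature set)
#' and evaluates a classifier of group membership from the per-sample
#' element concentrations by stratified k-fold cross-validation. Feature
#' importances come from a fit on the full data: decision tree and random
#' forest use their native importance measures; the naive Bayes baseline
#' ranks features by the absolute standardised mean class difference.
#'
#' @param dataset Long-format ionome tibble.
#' @param groups Two group labels to separate.
#' @param algorithm `"decision_tree"` (rpart, depth <= 3, min leaf 3 --
#'   sized for ~60 samples), `"naive_bayes"` (e1071) or `"random_forest"`
#'   (randomForest, 500 trees).
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed Optional seed (fold assignment and forest randomness).
#' @return Object of class `ionome_classifier`: list with `accuracy`
#'   (cross-validated), `importance` (tibble, ranked), `algorithm`,
#'   `cv_folds`, `n`, `groups`, and `fit` (full-data model).
#' @export
classify_groups <- function(dataset, groups,
                            algorithm = c("decision_tree", "naive_bayes",
                                          "random_forest"),
                            cv_folds = 5, seed = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(length(groups) == 2)
  d <- filter(dataset, .data$group %in% groups)
  if (length(unique(d$group)) < 2) abort("need samples from both classes")
  elements <- unique(d$element)
  wide <- d %>%
    select("sample_id", "group", "element", "concentration") %>%
    tidyr::pivot_wider(names_from = "element", values_from = "concentration") %>%
    arrange(.data$sample_id)
  y <- factor(wide$group, levels = groups)
  if (min(table(y)) < 2) abort("need at least 2 samples per class")
  X <- as.data.frame(wide[, elements, drop = FALSE])

  fit_one <- function(Xtr, ytr) {
    df <- cbind(.class = ytr, Xtr)
    switch(algorithm,
      decision_tree = rpart::rpart(
        .class ~ ., data = df, method = "class",
        control = rpart::rpart.control(maxdepth = 3, minbucket = 3,
                                       cp = 0.01, xval = 0)),
      naive_bayes = e1071::naiveBayes(.class ~ ., data = df),
      random_forest = randomForest::randomForest(.class ~ ., data = df,
                                                 ntree = 500))
  }
  predict_one <- function(fit, Xte) {
    if (algorithm == "decision_tree") {
      predict(fit, Xte, type = "class")
    } else {
      predict(fit, Xte)
    }
  }

  res <- with_seed_opt(seed, {
    folds <- stratified_folds(y, cv_folds)
    correct <- logical(length(y))
    for (f in seq_len(cv_folds)) {
      te <- folds == f
      fit <- fit_one(X[!te, , drop = FALSE], y[!te])
      correct[te] <- predict_one(fit, X[te, , drop = FALSE]) == y[te]
    }
    full <- fit_one(X, y)
    list(acc = mean(correct), fit = full)
  })

  imp <- switch(algorithm,
    decision_tree = {
      vi <- res$fit$variable.importance
      if (is.null(vi)) vi <- setNames(numeric(0), character(0))
      tibble(element = names(vi), importance = unname(vi))
    },
    random_forest = {
      vi <- randomForest::importance(res$fit)[, 1]
      tibble(element = names(vi), importance = unname(vi))
    },
    naive_bayes = {
      sep <- vapply(elements, function(e) {
        a <- X[[e]][y == groups[1]]; b <- X[[e]][y == groups[2]]
        abs(mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
      }, numeric(1))
      tibble(element = elements, importance = unname(sep))
    })
  imp <- arrange(imp, dplyr::desc(.data$importance))

  structure(list(accuracy = res$acc, importance = imp,
                 algorithm = algorithm, cv_folds = cv_folds,
                 n = length(y), groups = groups, fit = res$fit),
            class = "ionome_classifier")
}

#' @export
print.ionome_classifier <- function(x, ...) {
  cat("<ionome_classifier> ", x$algorithm, ", ", x$cv_folds,
      "-fold stratified CV on ", x$n, " samples (",
      paste(x$groups, collapse = " vs "), ")\n", sep = "")
  cat(sprintf("  cv accuracy = %.3f; top features: %s\n", x$accuracy,
              paste(head(x$importance$element, 3), collapse = ", ")))
  invisible(x)
}

#' @method tidy ionome_classifier
#' @export
tidy.ionome_classifier <- function(x, ...) x$importance

#' @method glance ionome_classifier
#' @export
glance.ionome_classifier <- function(x, ...) {
  tibble(algorithm = x$algorithm, cv_accuracy = x$accuracy,
         cv_folds = x$cv_folds, n = x$n,
         top_feature = if (nrow(x$importance)) x$importance$element[1] else NA_character_)
}
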