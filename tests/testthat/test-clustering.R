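test_that("row z-scoring standardises, flags constants, and is affine
           invariant", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 8, 11))
  z <- zscore_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(attr(z, "constant_rows"), c(a = FALSE, b = TRUE, c = FALSE))
  expect_equal(unname(rowMeans(z)), c(0, 0, 0))
  expect_equal(unname(apply(z, 1, sd)), c(1, 0, 1))
  # row-wise affine rescaling of the raw data changes nothing
  m2 <- m * c(10, 3, 0.5) + c(100, -2, 7)
  expect_equal(zscore_rows(m2), z, ignore_attr = TRUE)
  expect_error(zscore_rows(matrix(1, 3, 1)), "2 columns")
})

test_that("element profiles are z-scored per element over all samples", {
  d <- generate_dataset(default_config(outlier_rate = 0), seed = 71)
  z <- element_profile_matrix(d)
  expect_equal(dim(z), c(15, 102))
  expect_equal(unname(rowMeans(z)), rep(0, 15))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 15))
  expect_setequal(rownames(z), unique(d$element))
})

test_that("clustering uses correlation distance with deterministic,
           order-invariant output", {
  # two identical profiles merge at height 0
  base <- rbind(A = c(1, 3, 2, 5, 4, 6, 8, 7),
                B = c(1, 3, 2, 5, 4, 6, 8, 7) * 2 + 1,  # same ranks
                C = c(8, 1, 6, 2, 7, 3, 5, 4))
  cl <- cluster_elements(zscore_rows(base), linkage = "average")
  expect_equal(min(cl$hclust$height), 0)

  # anti-correlated pair sits at the maximum distance 2 and merges last
  anti <- rbind(X = 1:8, Y = 8:1, Z = c(2, 1, 4, 3, 6, 5, 8, 7))
  cl2 <- cluster_elements(zscore_rows(anti), linkage = "complete")
  expect_equal(max(cl2$dist), 2)
  expect_equal(max(cl2$hclust$height), 2)
  merged_first <- cl2$hclust$merge[1, ]
  expect_true(all(merged_first %in% -c(1, 3)))  # X joins Z, not Y

  # input row order does not change the tree
  d <- generate_dataset(default_config(outlier_rate = 0), seed = 72)
  shuffled <- dplyr::arrange(d, dplyr::desc(element), sample_id)
  c1 <- cluster_elements(d, k = 4)
  c2 <- cluster_elements(shuffled, k = 4)
  expect_identical(c1$hclust$merge, c2$hclust$merge)
  expect_identical(c1$clusters, c2$clusters)
  expect_error(cluster_elements(zscore_rows(base[1:2, ])), "3 elements")
})

test_that("planted correlation blocks are recovered at k = 4 in most
           runs", {
  hits <- vapply(1:20, function(s) {
    d <- generate_dataset(block_config(rho = 0.8), seed = 1000 + s)
    cl <- cluster_elements(d, linkage = "ward", k = 4)
    ct <- cl$clusters
    intact <- function(m) length(unique(ct[m])) == 1
    intact(c("Zn", "Cu")) && intact(c("Fe", "V")) &&
      intact(c("Pb", "Cd", "Bi")) &&
      length(unique(ct[c("Zn", "Fe", "Pb")])) == 3
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("dendrogram exports as Newick with all elements as tips", {
  d <- generate_dataset(default_config(outlier_rate = 0), seed = 73)
  cl <- cluster_elements(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, unique(d$element))
})

test_that("classifier separates groups on a planted Fe/Se signature and
           ranks those elements on top", {
  res <- vapply(1:15, function(s) {
    d <- generate_dataset(default_config(outlier_rate = 0), seed = 1100 + s)
    fit <- classify_groups(d, c("Se", "AD"), algorithm = "decision_tree",
                           seed = s)
    c(acc = fit$accuracy,
      top2 = setequal(utils::head(fit$importance$element, 2),
                      c("Fe", "Se")))
  }, numeric(2))
  expect_gt(mean(res["acc", ] >= 0.85), 0.5)
  expect_gt(mean(res["top2", ]), 0.5)
})

test_that("classifier accuracy collapses to chance under label
           permutation and reaches 1 on separable toy data", {
  d <- generate_dataset(null_config(), seed = 74)
  accs <- vapply(1:10, function(s) {
    perm <- d
    ids <- unique(perm$sample_id)
    relab <- withr::with_seed(1200 + s,
                              setNames(sample(rep(c("P", "Q"), length.out =
                                                    length(ids))), ids))
    perm$group <- relab[perm$sample_id]
    classify_groups(perm, c("P", "Q"), seed = s)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)

  # one perfectly separating feature
  toy <- manual_dataset(list(
    A = list(Fe = 1:8, Zn = rnorm(8, 50, 1)),
    B = list(Fe = 101:108, Zn = rnorm(8, 50, 1))))
  fit <- classify_groups(toy, c("A", "B"), seed = 1)
  expect_equal(fit$accuracy, 1)
  expect_equal(fit$importance$element[1], "Fe")
  expect_error(classify_groups(dplyr::filter(toy, group == "A"),
                               c("A", "B")), "both classes")
})

test_that("importance ranking is stable under relabeling of
           non-informative elements", {
  d <- generate_dataset(default_config(outlier_rate = 0), seed = 75)
  fit1 <- classify_groups(d, c("Se", "AD"), seed = 5)
  swap <- c(Mg = "Co", Co = "Mg")
  d2 <- dplyr::mutate(d, element = dplyr::coalesce(swap[element], element))
  fit2 <- classify_groups(d2, c("Se", "AD"), seed = 5)
  expect_equal(fit1$accuracy, fit2$accuracy)
  expect_equal(utils::head(fit1$importance$element, 2),
               utils::head(fit2$importance$element, 2))
})

test_that("naive Bayes and random forest baselines run and report
           importances", {
  d <- generate_dataset(default_config(outlier_rate = 0), seed = 76)
  for (alg in c("naive_bayes", "random_forest")) {
    fit <- classify_groups(d, c("Se", "AD"), algorithm = alg, seed = 2)
    expect_gt(fit$accuracy, 0.7)
    expect_equal(nrow(fit$importance), 15)
    expect_true("Se" %in% utils::head(fit$importance$element, 3))
  }
})
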