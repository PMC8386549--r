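two_cluster_labels <- function(expr, frac_a = 0.5) {
  n <- ncol(expr)
  factor(setNames(rep(c("A", "B"), c(round(frac_a * n), n - round(frac_a * n))),
                  colnames(expr)), levels = c("A", "B"))
}

test_that("gene typing follows the sign of the cluster correlation", {
  expr <- toy_log2(30, 20, seed = 1)
  lab <- two_cluster_labels(expr)
  # a gene strictly higher in every cluster-A sample is type I
  up <- expr
  up["G001", lab == "A"] <- up["G001", lab == "A"] + 10
  up <- expression_matrix(unclass(up), "LOG2")
  ty <- assign_gene_types(up, c("G001", "G002"), lab)
  expect_equal(ty$type[ty$gene_id == "G001"], "I")
  expect_gt(ty$correlation[ty$gene_id == "G001"], 0)
  # negating a type-I gene's values flips it to type II
  dn <- up; dn["G001", ] <- -dn["G001", ]
  dn <- expression_matrix(unclass(dn), "LOG2")
  ty2 <- assign_gene_types(dn, "G001", lab)
  expect_equal(ty2$type, "II")
  expect_equal(ty2$correlation, -ty$correlation[ty$gene_id == "G001"])
})

test_that("label-independent genes split about evenly between types", {
  set.seed(2)
  expr <- expression_matrix(
    matrix(rnorm(500 * 40, 5), 500, 40,
           dimnames = list(sprintf("G%03d", 1:500), sprintf("S%02d", 1:40))),
    "LOG2")
  ty <- assign_gene_types(expr, rownames(expr), two_cluster_labels(expr))
  expect_gt(mean(ty$type == "I"), 0.4)
  expect_lt(mean(ty$type == "I"), 0.6)
})

test_that("constant genes fall to type II with a warning", {
  expr <- toy_log2(5, 10, seed = 3)
  expr["G002", ] <- 7
  expr <- expression_matrix(unclass(expr), "LOG2")
  expect_warning(ty <- assign_gene_types(expr, c("G001", "G002"),
                                         two_cluster_labels(expr)),
                 "constant")
  expect_equal(ty$type[ty$gene_id == "G002"], "II")
})

test_that("shadow-feature selection separates planted from noise genes", {
  set.seed(3)
  n <- 120
  lab <- factor(rep(c("A", "B"), each = n / 2))
  expr <- matrix(rnorm(40 * n), 40, n,
                 dimnames = list(sprintf("G%02d", 1:40), sprintf("S%03d", 1:n)))
  expr[1:6, lab == "A"] <- expr[1:6, lab == "A"] + 2
  res <- boruta_select(expr, lab, seed = 3)
  expect_gte(sum(res$decision[1:6] == "confirmed"), 5)
  expect_lte(sum(res$decision[7:40] == "confirmed"), 2)
  # decisions partition the gene set
  expect_equal(length(res$decision), 40)
  expect_true(all(res$decision %in% c("confirmed", "tentative", "rejected")))
  # determinism
  res2 <- boruta_select(expr, lab, seed = 3)
  expect_identical(res$decision, res2$decision)
  expect_error(boruta_select(expr, factor(rep("A", n))), "2 classes")
})

test_that("single-gene PCA score equals that gene's z-scores", {
  expr <- toy_log2(10, 15, seed = 4)
  sc <- pca_signature_score(expr, "G003")
  z <- (expr["G003", ] - mean(expr["G003", ])) / sd(expr["G003", ])
  expect_equal(unname(sc[names(z)]), unname(z), tolerance = 1e-10)
})

test_that("two perfectly correlated genes load equally on PC1", {
  base <- toy_log2(1, 12, seed = 5)
  expr <- expression_matrix(
    rbind(G1 = base[1, ], G2 = 2 * base[1, ] + 3), "LOG2")
  sc <- pca_signature_score(expr, c("G1", "G2"))
  v <- attr(sc, "rotation")
  expect_equal(abs(unname(v)), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  z <- (base[1, ] - mean(base[1, ])) / sd(base[1, ])
  expect_equal(as.numeric(sc), unname(sqrt(2) * z), tolerance = 1e-10)
})

test_that("the PC1 orientation always points toward high expression", {
  for (s in 1:100) {
    expr <- toy_log2(8, 10, seed = 100 + s)
    sc <- pca_signature_score(expr, rownames(expr)[1:5])
    z <- t(scale(t(expr[1:5, ])))
    expect_gte(cor(sc, colMeans(z)), 0)
  }
})

test_that("PCA scores are invariant to gene-wise affine rescaling", {
  expr <- toy_log2(12, 15, seed = 6)
  resc <- expr * rep(c(2, 5, 0.3), length.out = 12) + rep(1:12, 15)
  resc <- expression_matrix(unclass(resc), "LOG2")
  s1 <- pca_signature_score(expr, rownames(expr)[1:6])
  s2 <- pca_signature_score(resc, rownames(expr)[1:6])
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-8)
})

test_that("the ICI score is the antisymmetric difference of signature scores", {
  s1 <- setNames(c(2, 0.5, -1), c("a", "b", "c"))
  s2 <- setNames(c(0.5, 0.5, 1), c("a", "b", "c"))
  expect_equal(ici_score(s1, s2), setNames(c(1.5, 0, -2), c("a", "b", "c")))
  expect_equal(ici_score(s1, s1), setNames(rep(0, 3), names(s1)))
  expect_equal(ici_score(s1, s2) + ici_score(s2, s1),
               setNames(rep(0, 3), names(s1)))
  # sample alignment is by name, and mismatches are an error
  expect_equal(ici_score(s1, s2[c(3, 1, 2)]), ici_score(s1, s2))
  expect_error(ici_score(s1, setNames(1:3, c("a", "b", "z"))), "same samples")
})

test_that("the survival cutpoint recovers a planted hazard step", {
  set.seed(1)
  n <- 300
  sc <- setNames(rnorm(n), sprintf("S%03d", 1:n))
  rate <- ifelse(sc > 0, 3 / 1000, 1 / 1000)
  cl <- data.frame(sample_id = names(sc),
                   os_time = rexp(n, rate) + 1, os_event = 1)
  tab <- split_by_cutpoint(sc, cl)
  expect_lt(abs(tab$cutpoint[1]), 0.25)
  expect_true(all(tab$group == ifelse(tab$ici_score > tab$cutpoint, "high", "low")))
  # monotone transforms leave the grouping unchanged
  tab2 <- split_by_cutpoint(exp(sc), cl)
  expect_equal(tab2$group, tab$group)
  expect_error(split_by_cutpoint(setNames(rep(1, n), names(sc)), cl),
               "identical")
})
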