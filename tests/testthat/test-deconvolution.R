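# shared small signature: 4 cell types, 200 genes
sig4 <- make_reference_signature(
  simulation_config(n_genes = 200, n_cell_types = 4, seed = 5))

test_that("a pure cell-type mixture is recovered as fraction one", {
  mix <- expression_matrix(sig4[, 2, drop = FALSE], "TPM")
  colnames(mix) <- "M1"
  fr <- deconvolve(mix, sig4)
  expect_gt(fr$CT02, 0.99)
  expect_equal(sum(fr[, colnames(sig4)]), 1, tolerance = 1e-9)
  expect_gt(fr$pearson_r, 0.99)
})

test_that("an equal-parts mixture matches the nonnegative-least-squares oracle", {
  skip_if_not_installed("pracma")
  y <- 0.5 * sig4[, 1] + 0.5 * sig4[, 3]
  mix <- expression_matrix(matrix(y, ncol = 1,
                                  dimnames = list(rownames(sig4), "M")), "TPM")
  fr <- deconvolve(mix, sig4)
  est <- as.numeric(fr[1, colnames(sig4)])
  # independent oracle: NNLS on the same standardized inputs
  Xs <- (sig4 - mean(sig4)) / sd(as.vector(sig4))
  ys <- (y - mean(y)) / sd(y)
  nn <- pracma::lsqnonneg(Xs, ys)$x
  nn <- nn / sum(nn)
  expect_equal(est, nn, tolerance = 0.02)
  expect_equal(est, c(0.5, 0, 0.5, 0), tolerance = 0.02)
})

test_that("fractions lie on the simplex and are scale invariant", {
  set.seed(9)
  w <- t(apply(matrix(rgamma(3 * 4, 1), 3, 4), 1, function(x) x / sum(x)))
  mix <- sig4 %*% t(w) * matrix(rlnorm(200 * 3, 0, 0.1), 200, 3)
  colnames(mix) <- paste0("M", 1:3)
  mix <- expression_matrix(mix, "TPM")
  fr <- deconvolve(mix, sig4)
  f <- as.matrix(fr[, colnames(sig4)])
  expect_true(all(f >= 0))
  expect_equal(unname(rowSums(f)), rep(1, 3), tolerance = 1e-9)
  # multiplying a raw mixture column by a positive constant changes nothing
  mix10 <- expression_matrix(mix * 10, "TPM")
  fr10 <- deconvolve(mix10, sig4)
  expect_equal(as.matrix(fr10[, colnames(sig4)]), f, tolerance = 1e-6)
})

test_that("fraction recovery is accurate on a noisy synthetic cohort", {
  cfg <- simulation_config(n_genes = 400, n_samples = 30, n_cell_types = 8,
                           n_clusters = 1, deg_fraction = 0, noise_sd = 0.2,
                           seed = 11)
  sim <- simulate_cohort(cfg)
  fr <- deconvolve(sim$expression, sim$reference)
  est <- as.matrix(fr[, colnames(sim$reference)])
  expect_lt(mean(abs(est - sim$truth$true_fractions)), 0.05)
  expect_gt(cor(c(est), c(sim$truth$true_fractions)), 0.9)
})

test_that("deconvolution rejects inadequate inputs", {
  expect_error(deconvolve(toy_tpm(30, 2), sig4), "overlap")
  one <- sig4[, 1, drop = FALSE]
  expect_error(deconvolve(expression_matrix(sig4, "TPM"), one), "2 cell types")
  const <- sig4; const[, 2] <- 3
  expect_error(
    deconvolve(expression_matrix(sig4[, 1, drop = FALSE], "TPM"), const),
    "constant")
})

test_that("permutation p-value is exact for a perfect fit and never zero", {
  pp <- permutation_pvalue(sig4[, 1], sig4, n_perm = 1000, seed = 2)
  expect_equal(pp$p, 1 / 1001, tolerance = 1e-12)
  # observed r below every null draw gives the add-one upper bound 1
  set.seed(3)
  y <- setNames(rlnorm(200, 2, 1), rownames(sig4))
  pp2 <- permutation_pvalue(y, sig4, n_perm = 19, seed = 3)
  expect_gt(pp2$p, 0)
  expect_lte(pp2$p, 1)
  fake <- pp2
  expect_equal((1 + sum(pp2$null_r >= pp2$observed_r)) / 20, pp2$p)
})

test_that("permutation p is monotone nonincreasing in observed r", {
  set.seed(4)
  null_r <- runif(50, 0, 0.6)
  p_of <- function(r) (1 + sum(null_r >= r)) / 51
  rs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(vapply(rs, p_of, numeric(1))) <= 0))
})

test_that("deconvolve flags but keeps samples failing the screen", {
  set.seed(8)
  noise <- matrix(rlnorm(200 * 2, 2, 1), 200, 2,
                  dimnames = list(rownames(sig4), c("N1", "N2")))
  member <- sig4[, 3, drop = FALSE]; colnames(member) <- "M1"
  mix <- expression_matrix(cbind(member, noise), "TPM")
  fr <- deconvolve(mix, sig4, n_perm = 99, seed = 8)
  expect_equal(nrow(fr), 3)
  expect_false(fr$excluded[fr$sample_id == "M1"])
  expect_true(all(fr$perm_p > 0 & fr$perm_p <= 1))
})

test_that("rank enrichment scores behave at the extremes and in the null", {
  expr <- toy_log2(200, 4, seed = 6)
  genes <- rownames(expr)
  # a set occupying the top ranks of sample 1 scores the maximum for its size
  top <- genes[order(expr[, 1], decreasing = TRUE)[1:10]]
  others <- replicate(200, sample(genes, 10), simplify = FALSE)
  s_top <- enrichment_scores(expr, top, genes[1:10])$immune_score[1]
  s_others <- vapply(others, function(g)
    enrichment_scores(expr, g, genes[1:10])$immune_score[1], numeric(1))
  expect_gt(s_top, 0)
  expect_gte(s_top, max(s_others))
  # random sets have mean score near zero
  expect_lt(abs(mean(s_others)), 2 * sd(s_others))
  # combined = immune + stromal by definition
  es <- enrichment_scores(expr, genes[1:20], genes[21:40])
  expect_equal(es$combined_score, es$immune_score + es$stromal_score)
  expect_error(enrichment_scores(expr, genes[1:3], genes[1:20]), "fewer than 5")
})
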