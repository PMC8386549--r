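#' Estimate immune-cell fractions by linear nu-support-vector regression
#'
#' For each sample the mixture column and the reference signature are
#' restricted to shared genes and standardized jointly (the signature by its
#' global mean/sd, the mixture column by its own), a linear nu-SVR is fitted
#' for nu in {0.25, 0.5, 0.75}, and the fit whose reconstruction has the
#' smallest RMSE against the standardized mixture wins. Negative coefficients
#' are clamped to zero and the remainder normalized to sum to one, so each
#' sample's fractions lie on the simplex. Optionally a permutation p-value is
#' attached per sample (see [permutation_pvalue()]); samples with
#' `perm_p >= 0.05` are flagged `excluded` but retained in the table.
#'
#' @param mixture expression matrix (TPM) of bulk samples.
#' @param signature reference expression matrix, genes x cell types.
#' @param n_perm permutations for the significance screen; 0 skips it.
#' @param nu_grid nu values scanned.
#' @param seed seed for the permutation null.
#' @return data frame of class `cell_fractions`: one row per sample with one
#'   column per cell type plus `rmse`, `pearson_r`, `perm_p`, `excluded`.
#' @export
deconvolve <- function(mixture, signature, n_perm = 0, nu_grid = c(0.25, 0.5, 0.75),
                       seed = 1L) {
  if (ncol(signature) < 2) stop("signature must contain >= 2 cell types")
  genes <- intersect(rownames(mixture), rownames(signature))
  if (length(genes) < 50)
    stop("insufficient gene overlap between mixture and signature (",
         length(genes), " < 50)")
  X <- signature[genes, , drop = FALSE]
  if (any(apply(X, 2, stats::sd) == 0))
    stop("signature has a constant column")
  Xs <- (X - mean(X)) / stats::sd(as.vector(X))
  frac <- matrix(NA_real_, ncol(mixture), ncol(signature),
                 dimnames = list(colnames(mixture), colnames(signature)))
  rmse <- r <- pp <- rep(NA_real_, ncol(mixture))
  for (j in seq_len(ncol(mixture))) {
    fit <- .svr_fractions(mixture[genes, j], Xs, nu_grid)
    frac[j, ] <- fit$fractions
    rmse[j] <- fit$rmse
    r[j] <- fit$r
  }
  if (n_perm > 0) {
    set.seed(seed)
    for (j in seq_len(ncol(mixture)))
      pp[j] <- .perm_p(mixture[genes, j], Xs, n_perm, nu_grid, r[j])
  }
  out <- data.frame(sample_id = colnames(mixture), frac, rmse = rmse,
                    pearson_r = r, perm_p = pp,
                    excluded = !is.na(pp) & pp >= 0.05,
                    row.names = NULL, check.names = FALSE)
  class(out) <- c("cell_fractions", "data.frame")
  out
}

# Core single-sample fit on a pre-standardized signature.
.svr_fractions <- function(y_raw, Xs, nu_grid) {
  y <- (y_raw - mean(y_raw)) / stats::sd(y_raw)
  best <- NULL
  for (nu in nu_grid) {
    m <- e1071::svm(Xs, y, type = "nu-regression", kernel = "linear",
                    nu = nu, scale = FALSE)
    w <- drop(t(m$coefs) %*% m$SV)
    w[w < 0] <- 0
    f <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
    recon <- drop(Xs %*% f)
    e <- sqrt(mean((recon - y)^2))
    if (is.null(best) || e < best$rmse)
      best <- list(fractions = f, rmse = e, r = stats::cor(recon, y))
  }
  best
}

.perm_p <- function(y_raw, Xs, n_perm, nu_grid, r_obs) {
  null_r <- vapply(seq_len(n_perm), function(b) {
    .svr_fractions(sample(y_raw), Xs, nu_grid)$r
  }, numeric(1))
  (1 + sum(null_r >= r_obs)) / (n_perm + 1)
}

#' Permutation p-value for a deconvolution fit
#'
#' Builds a null distribution of fit correlations by deconvolving `n_perm`
#' gene-permuted versions of the mixture column against the same signature,
#' and reports the add-one estimator
#' `p = (1 + #\{null r >= observed r\}) / (n_perm + 1)`, which is never zero.
#'
#' @param mixture_column named numeric vector of one sample's expression over
#'   the signature's genes (or a superset).
#' @param signature reference expression matrix.
#' @param n_perm number of permutations (>= 1).
#' @param nu_grid nu values scanned per fit.
#' @param seed RNG seed for the permutations.
#' @return list with `p`, `observed_r`, `null_r`.
#' @export
permutation_pvalue <- function(mixture_column, signature, n_perm = 1000,
                               nu_grid = c(0.25, 0.5, 0.75), seed = 1L) {
  stopifnot(n_perm >= 1)
  genes <- intersect(names(mixture_column), rownames(signature))
  if (length(genes) < 50) stop("insufficient gene overlap")
  X <- signature[genes, , drop = FALSE]
  Xs <- (X - mean(X)) / stats::sd(as.vector(X))
  y <- mixture_column[genes]
  r_obs <- .svr_fractions(y, Xs, nu_grid)$r
  set.seed(seed)
  null_r <- vapply(seq_len(n_perm), function(b) {
    .svr_fractions(sample(y), Xs, nu_grid)$r
  }, numeric(1))
  list(p = (1 + sum(null_r >= r_obs)) / (n_perm + 1),
       observed_r = r_obs, null_r = null_r)
}

#' Rank-based immune / stromal enrichment scores
#'
#' Single-sample enrichment in the ssGSEA style: per sample, genes are ranked
#' by expression; the score is the sum over the ranked list of the difference
#' between the weighted in-set empirical CDF (absolute ranks raised to
#' `alpha`) and the out-of-set ECDF. The combined score is immune + stromal
#' by definition.
#'
#' @param expr expression matrix (any unit; ranks are scale-free per sample).
#' @param immune_set,stromal_set character vectors of gene ids.
#' @param alpha rank weight exponent (ssGSEA default 0.25).
#' @return data frame with `sample_id`, `immune_score`, `stromal_score`,
#'   `combined_score`.
#' @export
enrichment_scores <- function(expr, immune_set, stromal_set, alpha = 0.25) {
  imm <- vapply(seq_len(ncol(expr)), function(j)
    .ssgsea_one(expr[, j], rownames(expr), immune_set, alpha), numeric(1))
  str <- vapply(seq_len(ncol(expr)), function(j)
    .ssgsea_one(expr[, j], rownames(expr), stromal_set, alpha), numeric(1))
  data.frame(sample_id = colnames(expr), immune_score = imm,
             stromal_score = str, combined_score = imm + str)
}

.ssgsea_one <- function(values, genes, set, alpha) {
  inset <- genes %in% set
  if (sum(inset) < 5)
    stop("gene set has fewer than 5 members present in the expression matrix")
  ord <- order(values, decreasing = TRUE)
  inset <- inset[ord]
  n <- length(values)
  rnk <- rank(values, ties.method = "average")[ord] # absolute rank, high expr = high rank
  w <- abs(rnk)^alpha
  step_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
  step_out <- cumsum(!inset) / (n - sum(inset))
  sum(step_in - step_out)
}
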