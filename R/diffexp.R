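#' Moderated one-way F test for differential expression across clusters
#'
#' Per gene, fits group means on the log2 scale and shrinks the residual
#' variance toward a common prior in the empirical-Bayes style: a scaled
#' inverse-chi-square prior `(s0^2, d0)` is fitted by matching the first two
#' moments of `log(s_g^2)` across genes, and the posterior variance
#' `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)` replaces the per-gene variance in
#' the F denominator. P-values come from `F(k - 1, d_g + d0)` and are
#' BH-adjusted across genes. A gene is flagged `is_deg` when
#' `|log2fc| > lfc` and `fdr < fdr_cut`; `log2fc` is the largest absolute
#' pairwise difference of group means, so the threshold is well defined for
#' any number of clusters.
#'
#' @param expr LOG2 expression matrix, genes x samples.
#' @param labels cluster labels, one per sample (names ignored; order must
#'   match columns of `expr`).
#' @param lfc log2 fold-change threshold (default 1).
#' @param fdr_cut FDR threshold (default 0.05).
#' @param prior_df override for the prior degrees of freedom `d0`; `0` turns
#'   moderation off (ordinary one-way F), `NULL` estimates it from the data.
#' @return data frame of class `deg_result`: group means, `log2fc`,
#'   `moderated_F`, `p_value`, `fdr`, `is_deg`, plus attributes `d0`, `s0_2`.
#' @export
moderated_anova <- function(expr, labels, lfc = 1, fdr_cut = 0.05,
                            prior_df = NULL) {
  labels <- as.factor(labels)
  if (length(labels) != ncol(expr))
    stop("one label per expression column is required")
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  nj <- table(labels)
  if (any(nj < 2)) stop("every group needs >= 2 samples")
  n <- ncol(expr); k <- nlevels(labels)
  d_g <- n - k

  ## group means and within/between sums of squares, vectorized over genes
  gm <- sapply(levels(labels), function(l)
    rowMeans(expr[, labels == l, drop = FALSE]))
  grand <- rowMeans(expr)
  ss_between <- drop(gm^2 %*% nj) - n * grand^2
  tot <- rowSums(expr^2) - n * grand^2
  ss_within <- pmax(tot - ss_between, 0)
  ms_between <- ss_between / (k - 1)
  s2 <- ss_within / d_g

  pri <- if (is.null(prior_df)) .fit_variance_prior(s2, d_g) else
    list(d0 = prior_df,
         s0_2 = if (prior_df > 0) .fit_variance_prior(s2, d_g)$s0_2 else mean(s2))
  d0 <- pri$d0; s0_2 <- pri$s0_2
  post_var <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d_g * s2) / (d0 + d_g)
  modF <- ms_between / post_var
  df2 <- if (is.infinite(d0)) Inf else d_g + d0
  p <- stats::pf(modF, k - 1, df2, lower.tail = FALSE)
  fdr <- bh_adjust(p)

  ## max absolute pairwise group-mean difference
  pairs <- utils::combn(k, 2)
  log2fc <- apply(abs(gm[, pairs[1, ], drop = FALSE] -
                      gm[, pairs[2, ], drop = FALSE]), 1, max)

  out <- data.frame(gene_id = rownames(expr), gm, log2fc = log2fc,
                    moderated_F = modF, p_value = p, fdr = fdr,
                    is_deg = log2fc > lfc & fdr < fdr_cut,
                    row.names = NULL, check.names = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  class(out) <- c("deg_result", "data.frame")
  out
}

# Moment-matching fit of the scaled inverse-chi-square variance prior on the
# log scale: E[log s^2] and Var[log s^2] identify (s0^2, d0) through digamma
# and trigamma functions; trigamma is inverted by Newton iteration.
.fit_variance_prior <- function(s2, d_g) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  emean <- mean(e)
  evar <- stats::var(z) - trigamma(d_g / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s0_2 = exp(emean)))
  d0 <- 2 * .trigamma_inverse(evar)
  s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone after the cumulative
#' minimum pass; invariant to the input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Nonparametric group-difference tests
#'
#' Kruskal-Wallis H (with midrank tie correction) for any number of groups;
#' with exactly two groups the two-sided Wilcoxon rank-sum p is reported as
#' well.
#'
#' @param values numeric vector, one observation per sample.
#' @param labels group labels, same length.
#' @return list with `statistic` (H), `df`, `p` (Kruskal-Wallis), and for
#'   two groups also `wilcoxon_p`.
#' @export
group_difference_tests <- function(values, labels) {
  labels <- as.factor(droplevels(as.factor(labels)))
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  if (any(table(labels) == 0)) stop("every group needs >= 1 observation")
  kw <- stats::kruskal.test(values, labels)
  out <- list(statistic = unname(kw$statistic), df = unname(kw$parameter),
              p = kw$p.value)
  if (nlevels(labels) == 2) {
    sp <- split(values, labels)
    wt <- stats::wilcox.test(sp[[1]], sp[[2]], exact = length(values) < 50 &&
                               !any(duplicated(values)))
    out$wilcoxon_p <- wt$p.value
  }
  out
}
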