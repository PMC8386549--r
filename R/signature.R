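#' Assign DEGs to type I / type II by correlation with the gene clusters
#'
#' Each DEG's expression is correlated (Spearman) with the indicator of gene
#' cluster A (the better-prognosis cluster); a positive correlation makes it
#' type I, otherwise type II. A constant gene has undefined correlation and
#' is assigned type II with a warning.
#'
#' @param expr LOG2 expression matrix.
#' @param deg_genes character vector of DEG ids, all present in `expr`.
#' @param gene_cluster_labels factor of "A"/"B" per sample (names must cover
#'   the columns of `expr`).
#' @return data frame with `gene_id`, `correlation`, `type`.
#' @export
assign_gene_types <- function(expr, deg_genes, gene_cluster_labels) {
  miss <- setdiff(deg_genes, rownames(expr))
  if (length(miss)) stop("DEGs absent from expression matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  lab <- gene_cluster_labels[colnames(expr)]
  if (anyNA(lab)) stop("gene cluster labels missing for some samples")
  if (!all(lab %in% c("A", "B")) || length(unique(lab)) != 2)
    stop("gene clusters must be binary A/B")
  ind <- as.numeric(lab == "A")
  cors <- vapply(deg_genes, function(g) {
    v <- expr[g, ]
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(v, ind, method = "spearman")
  }, numeric(1))
  if (anyNA(cors))
    warning(sum(is.na(cors)), " constant gene(s) assigned type II")
  data.frame(gene_id = deg_genes, correlation = cors,
             type = ifelse(!is.na(cors) & cors > 0, "I", "II"))
}

#' Shadow-feature random-forest gene selection (Boruta-style)
#'
#' Iteratively appends a shuffled "shadow" copy of every candidate gene,
#' fits a random-forest classifier of the gene-cluster labels, and scores a
#' hit for each undecided gene whose permutation importance exceeds the
#' maximum shadow importance. The shadow pool always covers all original
#' candidates (not only those still undecided), so the max-shadow reference
#' keeps its extreme-value strength as genes are rejected. After each iteration, two-sided binomial tests
#' on the hit counts (Bonferroni-corrected at `alpha`) promote genes to
#' `confirmed` or `rejected`; rejected genes leave the model. The loop stops
#' when nothing is tentative or at `max_iter`.
#'
#' @param expr LOG2 expression matrix restricted to candidate DEGs.
#' @param target factor of gene-cluster labels per sample (>= 2 classes).
#' @param n_trees trees per forest (default 200).
#' @param max_iter iteration cap (default 100).
#' @param alpha significance level of the binomial decisions (default 0.01).
#' @param seed integer seed (forest fits and shadow shuffles).
#' @return list of class `boruta_result`: `decision` (named factor:
#'   confirmed / rejected / tentative), `hits`, `n_iterations`,
#'   `importance_history` (iterations x genes).
#' @export
boruta_select <- function(expr, target, n_trees = 200, max_iter = 100,
                          alpha = 0.01, seed = 1L) {
  target <- droplevels(as.factor(target))
  if (nlevels(target) < 2) stop("target must have >= 2 classes")
  if (nrow(expr) < 1) stop("need >= 1 candidate gene")
  genes <- rownames(expr)
  X <- t(expr)                              # samples x genes
  colnames(X) <- gid <- paste0("g", seq_along(genes)) # safe names
  decision <- stats::setNames(rep("tentative", length(genes)), genes)
  hits <- stats::setNames(rep(0L, length(genes)), genes)
  hist <- matrix(NA_real_, 0, length(genes), dimnames = list(NULL, genes))
  set.seed(seed)
  iter <- 0L
  while (any(decision == "tentative") && iter < max_iter) {
    iter <- iter + 1L
    active <- decision != "rejected"
    Xa <- X[, gid[active], drop = FALSE]
    ## shadows are shuffled copies of ALL original candidates, not just the
    ## remaining ones: a shadow pool that shrinks with rejections weakens the
    ## max-shadow reference exactly when the surviving, most chance-associated
    ## genes need the strongest null, and lets pure-noise genes be confirmed
    shadow <- apply(X, 2, sample)
    colnames(shadow) <- paste0("shadow_", seq_len(ncol(shadow)))
    d <- data.frame(.y = target, Xa, shadow, check.names = FALSE)
    rf <- ranger::ranger(dependent.variable.name = ".y", data = d,
                         num.trees = n_trees, importance = "permutation",
                         seed = seed + iter, num.threads = 1)
    imp <- rf$variable.importance
    shadow_max <- max(imp[startsWith(names(imp), "shadow_")])
    real_imp <- imp[colnames(Xa)]
    hit <- real_imp > shadow_max
    hits[genes[active]] <- hits[genes[active]] + as.integer(hit)
    row <- rep(NA_real_, length(genes))
    row[active] <- real_imp
    hist <- rbind(hist, row)
    ## binomial decisions on tentative genes, Bonferroni over candidates
    tent <- decision == "tentative"
    m <- sum(tent)
    for (g in genes[tent]) {
      p <- stats::binom.test(hits[[g]], iter, 0.5)$p.value
      if (p * m < alpha)
        decision[g] <- if (hits[[g]] > iter / 2) "confirmed" else "rejected"
    }
  }
  structure(list(decision = factor(decision,
                                   levels = c("confirmed", "tentative", "rejected")),
                 hits = hits, n_iterations = iter, importance_history = hist),
            class = "boruta_result")
}

#' PCA signature score
#'
#' Z-scores each gene of the set across samples and returns each sample's
#' coordinate on the first principal component of the samples x genes
#' submatrix. The sign of PC1 is not identifiable, so it is fixed so the
#' score correlates positively with the mean z-expression of the set: a high
#' score always means high expression of the signature.
#'
#' @param expr LOG2 expression matrix.
#' @param gene_set character vector of gene ids.
#' @return named numeric vector of per-sample scores, with the loadings in
#'   attribute `rotation` and per-gene centers/scales for projection.
#' @export
pca_signature_score <- function(expr, gene_set) {
  genes <- intersect(gene_set, rownames(expr))
  if (length(genes) == 0) stop("gene set has empty intersection with the matrix")
  sub <- expr[genes, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (sub - mu) / sdv                      # genes x samples, z per gene
  X <- t(z)                                  # samples x genes
  v <- stats::prcomp(X, center = FALSE, scale. = FALSE)$rotation[, 1]
  score <- drop(X %*% v)
  msig <- rowMeans(X)
  orient <- stats::cor(score, msig)
  if (!is.na(orient) && orient < 0) { v <- -v; score <- -score }
  names(score) <- colnames(expr)
  attr(score, "rotation") <- v
  attr(score, "center") <- mu
  attr(score, "scale") <- sdv
  score
}

#' The ICI score
#'
#' Per-sample difference of the type-I and type-II signature scores:
#' `ici = s1 - s2`. High values mean the immune-favorable (type I) program
#' dominates.
#'
#' @param s1,s2 named per-sample score vectors over the same samples.
#' @return named numeric vector.
#' @export
ici_score <- function(s1, s2) {
  if (is.null(names(s1)) || is.null(names(s2)) ||
      !setequal(names(s1), names(s2)))
    stop("s1 and s2 must be named over the same samples")
  out <- s1 - s2[names(s1)]
  attributes(out) <- list(names = names(s1))
  out
}

#' Split samples at the optimal survival cutpoint
#'
#' Finds the maximally selected log-rank cutpoint of the ICI score (see
#' [maxstat_cutpoint()]) and labels each sample high (`score > cutpoint`)
#' or low.
#'
#' @param scores named per-sample ICI scores.
#' @param clinical clinical data frame (`sample_id`, `os_time`, `os_event`);
#'   only samples with both a score and clinical data enter the scan.
#' @param minprop passed to [maxstat_cutpoint()].
#' @return data frame of class `ici_score_table`: `sample_id`, `ici_score`,
#'   `group` (high/low), `cutpoint`.
#' @export
split_by_cutpoint <- function(scores, clinical, minprop = 0.1) {
  clinical <- validate_clinical(clinical)
  ids <- intersect(names(scores), clinical$sample_id)
  if (length(ids) < 20) stop("need >= 20 samples with survival data")
  cl <- clinical[match(ids, clinical$sample_id), ]
  cp <- maxstat_cutpoint(scores[ids],
                         data.frame(time = cl$os_time, event = cl$os_event),
                         minprop = minprop)
  out <- data.frame(sample_id = names(scores),
                    ici_score = unname(scores),
                    group = ifelse(scores > cp$cutpoint, "high", "low"),
                    cutpoint = cp$cutpoint, row.names = NULL)
  attr(out, "cutpoint_result") <- cp
  class(out) <- c("ici_score_table", "data.frame")
  out
}
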