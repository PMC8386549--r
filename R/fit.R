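#' Fit the immune-cell-infiltration scoring pipeline
#'
#' Runs the full workflow on one cohort: nu-SVR deconvolution of immune-cell
#' fractions against a reference signature (with optional permutation
#' screen), consensus K-means ICI clusters on the fractions, moderated-F
#' differential expression among the ICI clusters, consensus gene clusters
#' on the DEGs, type I / type II gene assignment by correlation with the
#' better-prognosis gene cluster, shadow-feature random-forest selection of
#' characteristic genes, PCA signature scores `S_PCA I` and `S_PCA II`, the
#' ICI score `S_PCA I - S_PCA II`, and a high/low split at the maximally
#' selected log-rank cutpoint (after excluding follow-up shorter than
#' `min_followup` days). When a mutation table is supplied, tumor mutation
#' burden, TMB x ICI subgroups, their Spearman correlation and per-gene
#' mutation-frequency tests are added.
#'
#' @param expr expression matrix in TPM (or FPKM, converted on entry).
#' @param clinical clinical data frame (`sample_id`, `os_time`, `os_event`).
#' @param signature reference expression matrix, genes x cell types.
#' @param mutations optional mutation data frame.
#' @param n_perm permutations for the deconvolution screen (0 = skip).
#' @param ici_k ICI cluster count; `NULL` lets the delta-area rule choose.
#' @param gene_k gene cluster count (binary typing requires 2).
#' @param lfc,fdr_cut DEG thresholds (|log2FC| > `lfc`, FDR < `fdr_cut`).
#' @param min_followup minimum follow-up in days for survival analyses.
#' @param tmb_rule TMB split rule, `"median"` or `"maxstat"`.
#' @param reps consensus-clustering subsampling rounds.
#' @param seed integer seed for every stochastic stage.
#' @return an object of class `ici_fit`; see [summary.ici_fit()].
#' @seealso [deconvolve()], [ici_clusters()], [moderated_anova()],
#'   [boruta_select()], [pca_signature_score()], [split_by_cutpoint()]
#' @export
ici_fit <- function(expr, clinical, signature, mutations = NULL,
                    n_perm = 0, ici_k = NULL, gene_k = 2, lfc = 1,
                    fdr_cut = 0.05, min_followup = 30, tmb_rule = "median",
                    reps = 100, seed = 1L) {
  if (identical(expr_unit(expr), "FPKM")) expr <- fpkm_to_tpm(expr)
  .require_unit(expr, "TPM")
  clinical <- validate_clinical(clinical)

  fractions <- deconvolve(expr, signature, n_perm = n_perm, seed = seed)
  icl <- ici_clusters(fractions, k = ici_k, survival = clinical, reps = reps,
                      seed = seed)

  lexpr <- log2_transform(expr)
  kept <- names(icl)
  deg <- moderated_anova(lexpr[, kept, drop = FALSE], icl[kept],
                         lfc = lfc, fdr_cut = fdr_cut)
  deg_genes <- deg$gene_id[deg$is_deg]
  if (length(deg_genes) < 2)
    stop("fewer than 2 DEGs at |log2FC| > ", lfc, ", FDR < ", fdr_cut)

  gcl <- gene_clusters(lexpr[deg_genes, kept, drop = FALSE], k = gene_k,
                       survival = clinical, reps = reps, seed = seed)
  types <- assign_gene_types(lexpr[, kept, drop = FALSE], deg_genes, gcl)
  sel <- boruta_select(lexpr[deg_genes, kept, drop = FALSE], gcl[kept],
                       seed = seed)
  confirmed <- names(sel$decision)[sel$decision == "confirmed"]
  set1 <- intersect(confirmed, types$gene_id[types$type == "I"])
  set2 <- intersect(confirmed, types$gene_id[types$type == "II"])
  if (length(set1) == 0) {
    warning("no confirmed type I genes; falling back to all type I DEGs")
    set1 <- types$gene_id[types$type == "I"]
  }
  if (length(set2) == 0) {
    warning("no confirmed type II genes; falling back to all type II DEGs")
    set2 <- types$gene_id[types$type == "II"]
  }

  s1 <- pca_signature_score(lexpr, set1)
  s2 <- pca_signature_score(lexpr, set2)
  score <- ici_score(s1, s2)

  surv_clin <- clinical[clinical$os_time >= min_followup, ]
  scores_tab <- split_by_cutpoint(score, surv_clin)

  mut <- NULL
  if (!is.null(mutations)) {
    tmb <- compute_tmb(mutations, clinical$sample_id)
    tmb <- split_tmb(tmb, rule = tmb_rule, clinical = surv_clin)
    grp <- stats::setNames(scores_tab$group, scores_tab$sample_id)
    comb <- combined_subgroups(tmb, scores_tab)
    ids <- intersect(tmb$sample_id, names(score))
    corr <- tmb_ici_correlation(tmb$tmb[match(ids, tmb$sample_id)], score[ids])
    freq <- mutation_frequency_tests(mutations, grp)
    mut <- list(tmb = tmb, combined = comb, correlation = corr,
                frequency = freq)
  }

  structure(list(fractions = fractions, ici_clusters = icl, deg = deg,
                 deg_genes = deg_genes, gene_clusters = gcl,
                 gene_types = types, selection = sel,
                 signature_genes = list(type_I = set1, type_II = set2),
                 s_pca = list(s1 = s1, s2 = s2), scores = scores_tab,
                 mutation = mut, clinical = clinical,
                 min_followup = min_followup,
                 call = match.call(), seed = seed),
            class = "ici_fit")
}

#' @export
print.ici_fit <- function(x, ...) {
  cat("Immune cell infiltration scoring fit\n")
  cat(sprintf("  samples: %d   ICI clusters: %d   gene clusters: %d\n",
              nrow(x$fractions), nlevels(x$ici_clusters),
              nlevels(x$gene_clusters)))
  cat(sprintf("  DEGs: %d   signature genes: %d type I, %d type II\n",
              length(x$deg_genes), length(x$signature_genes$type_I),
              length(x$signature_genes$type_II)))
  cat(sprintf("  ICI score cutpoint: %.3f   high: %d   low: %d\n",
              x$scores$cutpoint[1], sum(x$scores$group == "high"),
              sum(x$scores$group == "low")))
  invisible(x)
}

#' Summarize an ICI scoring fit
#'
#' Adds the high-vs-low log-rank test (on samples passing the follow-up
#' filter) and, when present, the TMB correlation to the printed overview.
#'
#' @param object an `ici_fit`.
#' @param ... unused.
#' @return list with `logrank` (high vs low), `median_survival`, and the
#'   mutation correlation if available; printed compactly.
#' @export
summary.ici_fit <- function(object, ...) {
  cl <- object$clinical
  cl <- cl[cl$os_time >= object$min_followup, ]
  tab <- object$scores[match(cl$sample_id, object$scores$sample_id), ]
  lr <- logrank_test(data.frame(time = cl$os_time, event = cl$os_event),
                     tab$group)
  med <- vapply(c(high = "high", low = "low"), function(g) {
    km <- km_estimate(data.frame(time = cl$os_time, event = cl$os_event)
                      [tab$group == g, ])
    t_med <- km$time[km$survival <= 0.5]
    if (length(t_med)) min(t_med) else NA_real_
  }, numeric(1))
  out <- list(fit = object, logrank = lr, median_survival = med,
              tmb_correlation = object$mutation$correlation)
  class(out) <- "summary.ici_fit"
  out
}

#' @export
print.summary.ici_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  high vs low log-rank: chi2 = %.2f, p = %.3g\n",
              x$logrank$chi_square, x$logrank$p))
  cat(sprintf("  median OS (days): high = %s, low = %s\n",
              format(x$median_survival["high"]),
              format(x$median_survival["low"])))
  if (!is.null(x$tmb_correlation))
    cat(sprintf("  TMB vs ICI score: Spearman rho = %.3f, p = %.3g\n",
                x$tmb_correlation$rho, x$tmb_correlation$p))
  invisible(x)
}

#' Score new samples with a fitted ICI signature
#'
#' Projects new expression data onto the PCA loadings learned at fit time
#' (using the fit's per-gene centering and scaling) and applies the fitted
#' cutpoint.
#'
#' @param object an `ici_fit`.
#' @param newdata expression matrix in TPM or LOG2 containing the signature
#'   genes.
#' @param ... unused.
#' @return data frame with `sample_id`, `s_pca_1`, `s_pca_2`, `ici_score`,
#'   `group`.
#' @export
predict.ici_fit <- function(object, newdata, ...) {
  if (identical(expr_unit(newdata), "TPM")) newdata <- log2_transform(newdata)
  proj <- function(score_attr) {
    v <- attr(score_attr, "rotation")
    mu <- attr(score_attr, "center"); sdv <- attr(score_attr, "scale")
    genes <- names(v)
    miss <- setdiff(genes, rownames(newdata))
    if (length(miss)) stop("newdata lacks signature gene(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    z <- (newdata[genes, , drop = FALSE] - mu) / sdv
    drop(t(z) %*% v)
  }
  s1 <- proj(object$s_pca$s1)
  s2 <- proj(object$s_pca$s2)
  cut <- object$scores$cutpoint[1]
  data.frame(sample_id = colnames(newdata), s_pca_1 = s1, s_pca_2 = s2,
             ici_score = s1 - s2,
             group = ifelse(s1 - s2 > cut, "high", "low"), row.names = NULL)
}

#' Kaplan-Meier plot of the high / low ICI score groups
#'
#' @param x an `ici_fit`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the per-group KM curves.
#' @export
plot.ici_fit <- function(x, ...) {
  cl <- x$clinical[x$clinical$os_time >= x$min_followup, ]
  tab <- x$scores[match(cl$sample_id, x$scores$sample_id), ]
  cols <- c(high = "#D55E00", low = "#0072B2")
  curves <- lapply(c(high = "high", low = "low"), function(g) {
    km_estimate(data.frame(time = cl$os_time, event = cl$os_event)
                [tab$group == g, ])
  })
  graphics::plot(NA, xlim = c(0, max(cl$os_time)), ylim = c(0, 1),
                 xlab = "Time (days)", ylab = "Overall survival",
                 main = "ICI score groups", ...)
  for (g in names(curves)) {
    km <- curves[[g]]
    graphics::lines(stats::stepfun(km$time, c(1, km$survival)),
                    do.points = FALSE, col = cols[[g]], lwd = 2)
  }
  graphics::legend("topright", legend = names(curves), col = cols, lwd = 2,
                   bty = "n")
  invisible(curves)
}
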