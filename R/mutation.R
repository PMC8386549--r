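# Variant classes counted as nonsynonymous for tumor mutation burden.
NONSYNONYMOUS_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site")

#' Tumor mutation burden per sample
#'
#' TMB is the raw count of nonsynonymous records per sample (no per-megabase
#' normalization; no capture size is assumed). Samples in `samples` absent
#' from the mutation table get TMB 0. Records with a classification outside
#' the MAF vocabulary raise a warning and are excluded.
#'
#' @param muts mutation data frame (`sample_id`, `gene_symbol`,
#'   `variant_classification`).
#' @param samples character vector of sample ids to report.
#' @return data frame with `sample_id`, `tmb`.
#' @export
compute_tmb <- function(muts, samples) {
  muts <- validate_mutations(muts)
  unknown <- setdiff(unique(muts$variant_classification), MAF_VOCABULARY)
  if (length(unknown)) {
    warning("unknown variant classification(s) excluded: ",
            paste(unknown, collapse = ", "))
    muts <- muts[muts$variant_classification %in% MAF_VOCABULARY, ]
  }
  ns <- muts[muts$variant_classification %in% NONSYNONYMOUS_CLASSES, ]
  counts <- table(factor(ns$sample_id, levels = samples))
  data.frame(sample_id = samples, tmb = as.integer(counts), row.names = NULL)
}

#' Split samples into high / low TMB groups
#'
#' `median` rule: high iff `tmb > median(tmb)`. `maxstat` rule: cutpoint by
#' the maximally selected log-rank statistic against supplied survival data.
#'
#' @param tmb data frame from [compute_tmb()].
#' @param rule `"median"` or `"maxstat"`.
#' @param clinical clinical data frame, required for `rule = "maxstat"`.
#' @return the input with a `tmb_group` column (high/low).
#' @export
split_tmb <- function(tmb, rule = c("median", "maxstat"), clinical = NULL) {
  rule <- match.arg(rule)
  if (length(unique(tmb$tmb)) < 2) stop("all TMB values are identical")
  if (rule == "median") {
    cut <- stats::median(tmb$tmb)
    tmb$tmb_group <- ifelse(tmb$tmb > cut, "high", "low")
  } else {
    if (is.null(clinical)) stop("maxstat rule needs clinical data")
    clinical <- validate_clinical(clinical)
    cl <- clinical[match(tmb$sample_id, clinical$sample_id), ]
    cp <- maxstat_cutpoint(stats::setNames(as.numeric(tmb$tmb), tmb$sample_id),
                           data.frame(time = cl$os_time, event = cl$os_event))
    tmb$tmb_group <- ifelse(tmb$tmb > cp$cutpoint, "high", "low")
  }
  tmb
}

#' Combined TMB x ICI subgroups
#'
#' Crosses the binary TMB and ICI-score groupings into the four labels
#' `H-TMB+H-ICI`, `H-TMB+L-ICI`, `L-TMB+H-ICI`, `L-TMB+L-ICI`. Samples
#' missing either label are dropped (their count is reported in a message).
#'
#' @param tmb_groups named vector ("high"/"low") per sample, or the data
#'   frame from [split_tmb()].
#' @param ici_groups named vector ("high"/"low") per sample, or an
#'   `ici_score_table`.
#' @return named factor of combined labels.
#' @export
combined_subgroups <- function(tmb_groups, ici_groups) {
  if (is.data.frame(tmb_groups))
    tmb_groups <- stats::setNames(tmb_groups$tmb_group, tmb_groups$sample_id)
  if (is.data.frame(ici_groups))
    ici_groups <- stats::setNames(ici_groups$group, ici_groups$sample_id)
  ids <- intersect(names(tmb_groups), names(ici_groups))
  if (length(ids) == 0) stop("no samples carry both TMB and ICI labels")
  dropped <- length(union(names(tmb_groups), names(ici_groups))) - length(ids)
  if (dropped > 0) message(dropped, " sample(s) missing one label were dropped")
  lab <- paste0(ifelse(tmb_groups[ids] == "high", "H", "L"), "-TMB+",
                ifelse(ici_groups[ids] == "high", "H", "L"), "-ICI")
  factor(stats::setNames(lab, ids),
         levels = c("H-TMB+H-ICI", "H-TMB+L-ICI", "L-TMB+H-ICI", "L-TMB+L-ICI"))
}

#' Spearman correlation between TMB and ICI score
#'
#' Midrank-tied Spearman rho with the t approximation for the p-value.
#'
#' @param tmb numeric vector.
#' @param ici numeric vector, same length/order.
#' @return list with `rho` and `p`.
#' @export
tmb_ici_correlation <- function(tmb, ici) {
  if (length(tmb) != length(ici) || length(tmb) < 3)
    stop("need >= 3 paired observations")
  if (stats::sd(tmb) == 0 || stats::sd(ici) == 0)
    stop("constant vector: correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(tmb, ici, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Per-gene mutation-frequency comparison between ICI groups
#'
#' For each gene, a 2x2 table of (mutated, unmutated) x (high, low) ICI
#' group is tested with a two-sided Fisher exact test; BH adjustment across
#' tested genes. Genes are ranked by overall alteration frequency and the
#' top `top_k` reported, together with the per-sample x top-gene mutation
#' indicator matrix (the tabular equivalent of a waterfall plot). Gene
#' symbols are deduplicated; genes mutated in zero samples are skipped.
#'
#' @param muts mutation data frame.
#' @param ici_groups named vector ("high"/"low") per sample, or an
#'   `ici_score_table`.
#' @param top_k number of top genes to report (default 25).
#' @return list of class `mutfreq_result`: `tests` (data frame per gene:
#'   counts, frequencies, `p`, `fdr`), `top_genes`, `indicator`
#'   (samples x top genes 0/1 matrix).
#' @export
mutation_frequency_tests <- function(muts, ici_groups, top_k = 25) {
  muts <- validate_mutations(muts)
  if (is.data.frame(ici_groups))
    ici_groups <- stats::setNames(ici_groups$group, ici_groups$sample_id)
  ids <- names(ici_groups)
  hi <- ids[ici_groups == "high"]; lo <- ids[ici_groups == "low"]
  if (length(hi) == 0 || length(lo) == 0)
    stop("both ICI groups must be non-empty")
  muts <- muts[muts$sample_id %in% ids, ]
  genes <- unique(muts$gene_symbol)
  rows <- lapply(genes, function(g) {
    carriers <- unique(muts$sample_id[muts$gene_symbol == g])
    a <- sum(hi %in% carriers); b <- length(hi) - a
    c <- sum(lo %in% carriers); d <- length(lo) - c
    if (a + c == 0) return(NULL)
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
    data.frame(gene_symbol = g, mutated_high = a, unmutated_high = b,
               mutated_low = c, unmutated_low = d,
               freq_high = a / length(hi), freq_low = c / length(lo),
               freq_overall = (a + c) / length(ids), p = p)
  })
  tests <- do.call(rbind, rows)
  if (is.null(tests)) stop("no mutated genes among labeled samples")
  tests$fdr <- bh_adjust(tests$p)
  tests <- tests[order(-tests$freq_overall, tests$gene_symbol), ]
  rownames(tests) <- NULL
  top <- utils::head(tests$gene_symbol, top_k)
  ind <- matrix(0L, length(ids), length(top), dimnames = list(ids, top))
  for (g in top)
    ind[unique(muts$sample_id[muts$gene_symbol == g]), g] <- 1L
  structure(list(tests = tests, top_genes = top, indicator = ind),
            class = "mutfreq_result")
}
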