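#' Construct a tagged expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns) carrying a `unit` attribute, one of `"FPKM"`, `"TPM"` or `"LOG2"`
#' (log2(TPM + 1)). All downstream statistics in this package operate on the
#' LOG2 scale; deconvolution operates on TPM.
#'
#' @param values numeric matrix, genes x samples, with rownames (gene ids) and
#'   colnames (sample ids).
#' @param unit one of `"FPKM"`, `"TPM"`, `"LOG2"`.
#' @return the matrix with its `unit` attribute set.
#' @export
expression_matrix <- function(values, unit = c("TPM", "FPKM", "LOG2")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (anyNA(values))
    stop("expression matrix contains missing values")
  if (unit %in% c("FPKM", "TPM") && any(values < 0))
    stop("negative values are not allowed for unit ", unit)
  attr(values, "unit") <- unit
  values
}

#' Unit tag of an expression matrix
#' @param x an expression matrix.
#' @return the unit string, or `NA` if untagged.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) NA_character_ else u
}

.require_unit <- function(x, unit, arg = deparse(substitute(x))) {
  u <- expr_unit(x)
  if (is.na(u) || u != unit)
    stop(sprintf("`%s` must be an expression matrix in %s units (got %s)",
                 arg, unit, if (is.na(u)) "untagged" else u))
  invisible(x)
}

#' Convert FPKM to TPM
#'
#' TPM rescales each sample so abundances sum to one million:
#' `TPM_gj = FPKM_gj / sum_g(FPKM_gj) * 1e6`. The conversion puts cohorts
#' quantified on different pipelines on a common within-sample scale.
#'
#' @param expr expression matrix tagged FPKM.
#' @return expression matrix tagged TPM; every column sums to 1e6.
#' @export
fpkm_to_tpm <- function(expr) {
  .require_unit(expr, "FPKM")
  cs <- colSums(expr)
  if (any(cs <= 0)) {
    bad <- colnames(expr)[cs <= 0]
    stop("sample(s) with all-zero FPKM: ", paste(bad, collapse = ", "))
  }
  out <- sweep(expr, 2, cs, "/") * 1e6
  expression_matrix(out, "TPM")
}

#' Log2-transform a TPM matrix
#'
#' Applies `log2(x + 1)` with a pseudocount of 1, which keeps zeros at zero.
#'
#' @param expr expression matrix tagged TPM.
#' @return expression matrix tagged LOG2.
#' @export
log2_transform <- function(expr) {
  u <- expr_unit(expr)
  if (!is.na(u) && u == "LOG2")
    stop("expression matrix is already log2-transformed")
  .require_unit(expr, "TPM")
  out <- log2(expr + 1)
  expression_matrix(out, "LOG2")
}

#' Merge two expression cohorts
#'
#' Restricts to the intersection of gene sets and concatenates samples.
#' The cohort of origin is retained in the `cohort` attribute (a named
#' character vector over samples) so users can stratify downstream; no batch
#' correction is applied.
#'
#' @param a,b expression matrices with the same unit (both TPM or both LOG2).
#' @param names labels recorded as cohort of origin, length 2.
#' @return merged expression matrix with a `cohort` attribute.
#' @export
merge_cohorts <- function(a, b, names = c("cohort1", "cohort2")) {
  ua <- expr_unit(a); ub <- expr_unit(b)
  if (is.na(ua) || is.na(ub) || ua != ub)
    stop("cohorts must share a unit (both TPM or both LOG2)")
  if (!ua %in% c("TPM", "LOG2"))
    stop("merge operates on TPM or LOG2 matrices, not ", ua)
  genes <- intersect(rownames(a), rownames(b))
  if (length(genes) == 0L) stop("empty gene intersection between cohorts")
  dup <- intersect(colnames(a), colnames(b))
  if (length(dup) > 0L)
    stop("duplicate sample ids across cohorts: ", paste(utils::head(dup, 5), collapse = ", "))
  out <- cbind(a[genes, , drop = FALSE], b[genes, , drop = FALSE])
  out <- expression_matrix(out, ua)
  attr(out, "cohort") <- stats::setNames(
    rep(names, c(ncol(a), ncol(b))), colnames(out))
  out
}

#' Validate a clinical table
#'
#' Required columns: `sample_id` (unique), `os_time` (days, >= 0), `os_event`
#' (0/1). Optional columns such as age, sex and stage are passed through.
#'
#' @param clinical a data frame.
#' @return the validated data frame.
#' @export
validate_clinical <- function(clinical) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(clinical$sample_id)) stop("duplicate sample_id in clinical table")
  if (anyNA(clinical$os_time) || any(clinical$os_time < 0))
    stop("os_time must be nonnegative and non-missing")
  if (!all(clinical$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1")
  clinical
}

# MAF variant classes accepted in mutation tables.
MAF_VOCABULARY <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site",
  "Silent", "3'UTR", "5'UTR", "Intron", "RNA", "3'Flank", "5'Flank")

#' Validate a long-format mutation table
#'
#' @param muts data frame with columns `sample_id`, `gene_symbol`,
#'   `variant_classification`.
#' @return the validated data frame.
#' @export
validate_mutations <- function(muts) {
  need <- c("sample_id", "gene_symbol", "variant_classification")
  miss <- setdiff(need, names(muts))
  if (length(miss)) stop("mutation table missing column(s): ", paste(miss, collapse = ", "))
  for (col in need) {
    v <- muts[[col]]
    if (anyNA(v) || any(!nzchar(as.character(v))))
      stop("mutation table has empty values in column ", col)
  }
  muts
}

#' Read / write an expression TSV
#'
#' Dialect: first column gene id, header row of sample ids, tab-separated.
#' Non-numeric or missing cells are a parse error naming the offending
#' row and column.
#'
#' @param path file path.
#' @param unit unit tag to attach on read.
#' @return an expression matrix.
#' @export
read_expression_tsv <- function(path, unit = c("TPM", "FPKM", "LOG2")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("malformed expression TSV (need gene column + samples): ", path)
  genes <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression cell at gene '%s', sample '%s' (line %d)",
                 genes[idx[1]], colnames(mat)[idx[2]], idx[1] + 1L))
  }
  dimnames(num) <- list(genes, colnames(mat))
  expression_matrix(num, unit)
}

#' @rdname read_expression_tsv
#' @param expr expression matrix to write.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical TSV
#' @param path file path.
#' @return validated clinical data frame.
#' @export
read_clinical_tsv <- function(path) {
  validate_clinical(utils::read.delim(path, sep = "\t", check.names = FALSE))
}

#' @rdname read_clinical_tsv
#' @param clinical clinical data frame to write.
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(validate_clinical(clinical), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene sets
#'
#' Each GMT line is `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 member", i))
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional descriptions, recycled.
#' @export
write_gmt <- function(sets, path, descriptions = "") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a MAF-like mutation TSV
#'
#' Accepts standard MAF column names (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`) or this package's internal names, and returns
#' the internal long format.
#'
#' @param path file path.
#' @return validated mutation data frame with columns `sample_id`,
#'   `gene_symbol`, `variant_classification`.
#' @export
read_maf_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  alias <- c(Tumor_Sample_Barcode = "sample_id", Hugo_Symbol = "gene_symbol",
             Variant_Classification = "variant_classification")
  hit <- intersect(names(alias), names(df))
  names(df)[match(hit, names(df))] <- alias[hit]
  validate_mutations(df[, c("sample_id", "gene_symbol", "variant_classification")])
}

#' @rdname read_maf_tsv
#' @param muts mutation data frame to write (MAF column names are used).
#' @export
write_maf_tsv <- function(muts, path) {
  muts <- validate_mutations(muts)
  out <- data.frame(Tumor_Sample_Barcode = muts$sample_id,
                    Hugo_Symbol = muts$gene_symbol,
                    Variant_Classification = muts$variant_classification)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
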