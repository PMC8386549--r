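#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults describe a mid-sized bulk tumor cohort: a few hundred samples,
#' a 22-cell-type immune reference, three infiltration archetypes, a modest
#' fraction of cluster-informative genes and multiplicative log-normal
#' measurement noise.
#'
#' @param n_genes number of genes in the expression universe.
#' @param n_samples number of tumor samples.
#' @param n_cell_types number of immune cell types in the reference.
#' @param n_clusters number of planted sample clusters (infiltration
#'   archetypes with matched expression programs).
#' @param cluster_proportions probability vector over clusters (sums to 1).
#' @param deg_fraction proportion of genes that are cluster-informative
#'   (planted differentially expressed genes).
#' @param deg_log2_effect log2-scale shift magnitude of a planted DEG.
#' @param noise_sd standard deviation of the log2-scale Gaussian noise.
#' @param hazard_beta log-hazard decrease per unit of latent immune score
#'   (positive values make immune-rich samples survive longer).
#' @param censor_rate probability that a sample's survival time is censored.
#' @param mutation_rate_range bounds for per-sample mean nonsynonymous
#'   mutation counts.
#' @param seed integer seed; all randomness flows through it.
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 1000,
                              n_samples = 300,
                              n_cell_types = 8,
                              n_clusters = 3,
                              cluster_proportions = NULL,
                              deg_fraction = 0.1,
                              deg_log2_effect = 2,
                              noise_sd = 0.3,
                              hazard_beta = 1,
                              censor_rate = 0.3,
                              mutation_rate_range = c(20, 120),
                              seed = 1L) {
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_cell_types = as.integer(n_cell_types),
              n_clusters = as.integer(n_clusters),
              cluster_proportions = cluster_proportions,
              deg_fraction = deg_fraction, deg_log2_effect = deg_log2_effect,
              noise_sd = noise_sd, hazard_beta = hazard_beta,
              censor_rate = censor_rate,
              mutation_rate_range = mutation_rate_range,
              seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1 || n_samples < 1 || n_cell_types < 1 || n_clusters < 1)
      stop("all counts must be >= 1")
    if (length(cluster_proportions) != n_clusters ||
        any(cluster_proportions < 0) ||
        abs(sum(cluster_proportions) - 1) > 1e-8)
      stop("cluster_proportions must be a probability vector of length n_clusters")
    if (deg_fraction < 0 || deg_fraction > 1) stop("deg_fraction must lie in [0, 1]")
    if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must lie in [0, 1)")
    if (noise_sd < 0) stop("noise_sd must be nonnegative")
    if (length(mutation_rate_range) != 2 || any(mutation_rate_range < 0) ||
        mutation_rate_range[1] > mutation_rate_range[2])
      stop("mutation_rate_range must be nonnegative bounds (lo <= hi)")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a cell-type reference signature matrix
#'
#' Each cell type receives a disjoint block of marker genes whose mean
#' abundance is elevated `marker_fold`-fold over a shared log-normal
#' baseline, mimicking the structure of curated immune reference matrices
#' (distinct, identifiable expression profiles per cell type).
#'
#' @param config a [simulation_config()].
#' @param markers_per_type marker genes per cell type.
#' @param marker_fold fold elevation of marker genes in their own type.
#' @return expression matrix (genes x cell types), TPM-like nonnegative scale.
#' @export
make_reference_signature <- function(config, markers_per_type = 10,
                                     marker_fold = 8) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cell_types < 2)
    stop("need at least 2 cell types in the reference")
  if (config$n_genes < 10 * config$n_cell_types)
    stop("degenerate config: n_genes must be >= 10 * n_cell_types")
  set.seed(config$seed)
  g <- config$n_genes; k <- config$n_cell_types
  genes <- sprintf("G%04d", seq_len(g))
  types <- sprintf("CT%02d", seq_len(k))
  base <- matrix(rlnorm(g * k, meanlog = 2, sdlog = 0.5), g, k,
                 dimnames = list(genes, types))
  for (j in seq_len(k)) {
    idx <- ((j - 1) * markers_per_type + 1):(j * markers_per_type)
    base[idx, j] <- base[idx, j] * marker_fold
  }
  expression_matrix(base, "TPM")
}

# Dirichlet draw via independent gammas; rows on the simplex.
.rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Expression is built as a nonnegative mixture of cell-type reference
#' profiles (`reference %*% t(fractions)`, scaled per sample by a library-size
#' factor), with cluster-specific DEG shifts added on the log2 scale and
#' multiplicative log-normal noise. Per-sample fractions are Dirichlet draws
#' around cluster-specific archetypes, so sample clusters are visible both in
#' cell fractions and in DEG expression. The latent immune score is the mean
#' z-expression of positive-sign DEGs minus that of negative-sign DEGs;
#' survival is exponential with log-hazard `-hazard_beta * latent_score`
#' (higher score protective), censored with probability `censor_rate`.
#' Mutation counts per sample are Poisson with means drawn uniformly in
#' `mutation_rate_range`, expanded into MAF-like rows (~70% nonsynonymous).
#'
#' @param config a [simulation_config()].
#' @param reference optional reference signature; generated from `config`
#'   when omitted.
#' @return list with `expression` (TPM matrix), `clinical` (data frame),
#'   `mutations` (data frame), `reference`, and `truth` (list with
#'   `true_fractions`, `true_cluster`, `true_deg_genes`, `deg_sign`,
#'   `latent_score`, `true_mutcount`).
#' @export
simulate_cohort <- function(config, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(reference)) reference <- make_reference_signature(config)
  set.seed(config$seed + 1L)
  n <- config$n_samples; g <- config$n_genes; k <- config$n_cell_types
  K <- config$n_clusters
  genes <- rownames(reference)
  samples <- sprintf("S%04d", seq_len(n))

  ## planted clusters and per-cluster fraction archetypes
  cluster <- sample.int(K, n, replace = TRUE, prob = config$cluster_proportions)
  ## each phenotype elevates its own disjoint block of cell types, giving
  ## well-separated, mutually equidistant compositions by construction
  ## rather than by luck of a random draw
  blocks <- split(seq_len(k), rep(seq_len(min(K, k)), length.out = k))
  w <- matrix(1, K, k)
  for (kk in seq_len(K))
    w[kk, blocks[[(kk - 1L) %% length(blocks) + 1L]]] <- 8
  archetype <- w / rowSums(w)
  ## infiltration grade drives the DEG program and latent score per cluster
  grade <- if (K > 1) (seq_len(K) - 1) / (K - 1) else 1
  concentration <- 100                   # tightness of samples around archetype
  fractions <- matrix(NA_real_, n, k, dimnames = list(samples, colnames(reference)))
  for (i in seq_len(n))
    fractions[i, ] <- .rdirichlet(1, archetype[cluster[i], ] * concentration + 0.5)

  ## cluster-informative genes: disjoint from cell-type markers where possible
  n_deg <- round(config$deg_fraction * g)
  marker_span <- min(g, 10 * k)
  pool <- if (g - marker_span >= n_deg) (marker_span + 1):g else seq_len(g)
  deg_idx <- sort(sample(pool, n_deg))
  deg_sign <- sample(c(1, -1), n_deg, replace = TRUE)
  ## the same infiltration grade drives the cluster-specific DEG program

  ## expression: mixture, library size, log-scale DEG shift, log-normal noise
  mix <- reference %*% t(fractions)              # genes x samples, linear scale
  libsize <- rlnorm(n, meanlog = 0, sdlog = 0.15)
  mix <- sweep(mix, 2, libsize, "*")
  logex <- log2(mix)
  if (n_deg > 0) {
    shift <- outer(deg_sign * config$deg_log2_effect, grade[cluster])
    logex[deg_idx, ] <- logex[deg_idx, ] + shift
  }
  if (config$noise_sd > 0)
    logex <- logex + matrix(rnorm(g * n, 0, config$noise_sd), g, n)
  expr <- expression_matrix(2^logex, "TPM")

  ## latent score from realized expression (z per gene on log2 scale)
  z <- t(scale(t(log2(expr + 1))))
  z[is.nan(z)] <- 0
  latent <- if (n_deg > 0) {
    pos <- deg_idx[deg_sign > 0]; neg <- deg_idx[deg_sign < 0]
    mp <- if (length(pos)) colMeans(z[pos, , drop = FALSE]) else rep(0, n)
    mn <- if (length(neg)) colMeans(z[neg, , drop = FALSE]) else rep(0, n)
    mp - mn
  } else rep(0, n)
  names(latent) <- samples

  ## survival: exponential, higher latent score -> lower hazard
  base_rate <- 1 / 1000                      # median OS ~ 700 days at score 0
  rate <- base_rate * exp(-config$hazard_beta * latent)
  t_event <- rexp(n, rate)
  censored <- runif(n) < config$censor_rate
  os_time <- ifelse(censored, runif(n) * t_event, t_event)
  os_time <- pmax(os_time, 1)                # days, strictly positive
  clinical <- data.frame(
    sample_id = samples,
    os_time = round(os_time, 1),
    os_event = as.integer(!censored),
    age = round(runif(n, 40, 85)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE))

  ## mutations: per-sample Poisson counts over a frequency-skewed gene pool
  nonsyn_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                      "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                      "In_Frame_Ins", "Splice_Site", "Nonstop_Mutation",
                      "Translation_Start_Site")
  silent_classes <- c("Silent", "3'UTR", "5'UTR", "Intron", "RNA")
  mut_pool <- sprintf("MUT%03d", seq_len(60))
  pool_w <- 1 / seq_along(mut_pool)          # Zipf-like: few frequent drivers
  lambda <- runif(n, config$mutation_rate_range[1], config$mutation_rate_range[2])
  nonsyn_n <- rpois(n, lambda)
  silent_n <- rpois(n, lambda * 3 / 7)       # ~70% of records nonsynonymous
  total <- nonsyn_n + silent_n
  muts <- data.frame(
    sample_id = rep(samples, total),
    gene_symbol = sample(mut_pool, sum(total), replace = TRUE, prob = pool_w),
    variant_classification = unlist(lapply(seq_len(n), function(i) c(
      sample(nonsyn_classes, nonsyn_n[i], replace = TRUE),
      sample(silent_classes, silent_n[i], replace = TRUE)))))

  truth <- list(
    true_fractions = fractions,
    true_cluster = stats::setNames(cluster, samples),
    true_deg_genes = genes[deg_idx],
    deg_sign = stats::setNames(deg_sign, genes[deg_idx]),
    latent_score = latent,
    true_mutcount = stats::setNames(nonsyn_n, samples))
  stopifnot(max(abs(rowSums(fractions) - 1)) < 1e-9)
  list(expression = expr, clinical = clinical, mutations = muts,
       reference = reference, truth = truth)
}
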