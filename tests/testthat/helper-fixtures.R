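# Small fixtures shared across test files; everything is generated in code.

# tiny labeled expression matrix on the LOG2 scale
toy_log2 <- function(n_genes = 20, n_samples = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_genes * n_samples, 5, 1)), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  expression_matrix(m, "LOG2")
}

toy_tpm <- function(n_genes = 10, n_samples = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * n_samples, 3, 1), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  expression_matrix(m, "TPM")
}

toy_surv <- function(time, event) data.frame(time = time, event = event)

# brute-force two-group log-rank chi-square: direct O/E/V accumulation
oracle_logrank_chisq <- function(time, event, grp) {
  et <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  g1 <- grp == unique(grp)[1]
  for (t in et) {
    atrisk <- time >= t
    n <- sum(atrisk); n1 <- sum(atrisk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
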