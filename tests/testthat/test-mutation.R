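mut_row <- function(s, g, v) data.frame(sample_id = s, gene_symbol = g,
                                        variant_classification = v)

test_that("TMB counts only nonsynonymous records", {
  m <- mut_row(rep("s1", 4), paste0("g", 1:4),
               c("Missense_Mutation", "Missense_Mutation",
                 "Missense_Mutation", "Silent"))
  tmb <- compute_tmb(m, c("s1", "s2"))
  expect_equal(tmb$tmb, c(3L, 0L))
  # empty table: all zero
  expect_equal(compute_tmb(m[0, ], c("a", "b"))$tmb, c(0L, 0L))
  # unknown classifications warn and are excluded
  bad <- rbind(m, mut_row("s1", "g5", "Weird_Class"))
  expect_warning(tmb2 <- compute_tmb(bad, "s1"), "Weird_Class")
  expect_equal(tmb2$tmb, 3L)
})

test_that("TMB equals a brute-force record scan on random tables", {
  set.seed(1)
  samples <- sprintf("P%02d", 1:20)
  classes <- iciscore:::MAF_VOCABULARY
  m <- mut_row(sample(samples, 500, TRUE),
               sample(sprintf("g%02d", 1:30), 500, TRUE),
               sample(classes, 500, TRUE))
  tmb <- compute_tmb(m, samples)
  brute <- vapply(samples, function(s) {
    n <- 0L
    for (i in seq_len(nrow(m)))
      if (m$sample_id[i] == s &&
          m$variant_classification[i] %in% iciscore:::NONSYNONYMOUS_CLASSES)
        n <- n + 1L
    n
  }, integer(1))
  expect_equal(tmb$tmb, unname(brute))
})

test_that("the median TMB split is balanced up to ties", {
  tmb <- data.frame(sample_id = letters[1:4], tmb = 1:4)
  sp <- split_tmb(tmb)
  expect_equal(sp$tmb_group, c("low", "low", "high", "high"))
  expect_error(split_tmb(data.frame(sample_id = "a", tmb = c(2, 2))),
               "identical")
  set.seed(2)
  big <- data.frame(sample_id = sprintf("P%03d", 1:101),
                    tmb = rpois(101, 30))
  sp2 <- split_tmb(big)
  ties <- sum(big$tmb == stats::median(big$tmb))
  expect_lte(abs(sum(sp2$tmb_group == "high") - sum(sp2$tmb_group == "low")),
             ties)
})

test_that("combined subgroups cross the two binary labels exactly", {
  tg <- setNames(c("high", "high", "low", "low"), letters[1:4])
  ig <- setNames(c("high", "low", "high", "low"), letters[1:4])
  cs <- combined_subgroups(tg, ig)
  expect_equal(as.character(cs),
               c("H-TMB+H-ICI", "H-TMB+L-ICI", "L-TMB+H-ICI", "L-TMB+L-ICI"))
  expect_equal(levels(cs),
               c("H-TMB+H-ICI", "H-TMB+L-ICI", "L-TMB+H-ICI", "L-TMB+L-ICI"))
  # samples missing a label are dropped with a message; counts add up
  expect_message(cs2 <- combined_subgroups(tg, ig[1:3]), "dropped")
  expect_equal(length(cs2), 3)
  expect_error(combined_subgroups(tg[1:2], ig[3:4]), "both")
})

test_that("Spearman association behaves at the extremes and under the null", {
  expect_equal(tmb_ici_correlation(1:10, (1:10)^2)$rho, 1)
  expect_equal(tmb_ici_correlation(1:10, -(1:10))$rho, -1)
  expect_error(tmb_ici_correlation(rep(2, 5), 1:5), "constant")
  set.seed(3)
  rhos <- vapply(1:200, function(i)
    tmb_ici_correlation(rpois(300, 40), rnorm(300))$rho, numeric(1))
  expect_lt(abs(mean(rhos)), 0.02)
  expect_gte(mean(abs(rhos) < 0.15), 0.95)
})

test_that("Fisher frequency tests match the hypergeometric enumeration", {
  ici <- setNames(rep(c("high", "low"), each = 4), sprintf("P%d", 1:8))
  # gene mutated in 3/4 high and 1/4 low: two-sided p = 34/70 by enumerating
  # the support a = 0..4 of the margins (4,4)x(4,4)
  m <- mut_row(c("P1", "P2", "P3", "P5"), "GENE1", "Missense_Mutation")
  res <- mutation_frequency_tests(m, ici)
  expect_equal(res$tests$p, 34 / 70, tolerance = 1e-12)
  expect_equal(res$tests$mutated_high, 3)
  expect_equal(res$tests$freq_low, 0.25)
  # identical frequencies give p = 1
  m2 <- mut_row(c("P1", "P2", "P5", "P6"), "GENE2", "Nonsense_Mutation")
  expect_equal(mutation_frequency_tests(m2, ici)$tests$p, 1)
  # label swap and transposition leave the Fisher p unchanged
  swapped <- setNames(ifelse(ici == "high", "low", "high"), names(ici))
  expect_equal(mutation_frequency_tests(m, swapped)$tests$p, 34 / 70)
})

test_that("a strongly enriched gene is detected in a power simulation", {
  set.seed(4)
  ids <- sprintf("P%03d", 1:200)
  ici <- setNames(rep(c("high", "low"), each = 100), ids)
  carriers_low <- sample(ids[101:200], 60)
  carriers_high <- sample(ids[1:100], 10)
  m <- rbind(
    mut_row(c(carriers_low, carriers_high), "DRIVER", "Missense_Mutation"),
    mut_row(sample(ids, 50, TRUE), "PASSENGER", "Missense_Mutation"))
  res <- mutation_frequency_tests(m, ici)
  expect_lt(res$tests$fdr[res$tests$gene_symbol == "DRIVER"], 0.05)
  # ranked by overall frequency; indicator matrix consistent with the table
  expect_equal(res$tests$gene_symbol[1], "DRIVER")
  expect_equal(unname(colSums(res$indicator)[res$top_genes]),
               res$tests$mutated_high + res$tests$mutated_low)
})
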