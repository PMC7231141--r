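# Small random fixtures built in code.

random_genotype_matrix <- function(n_samples = 5, n_variants = 4,
                                   missing_rate = 0.1, seed = 1) {
  set.seed(seed)
  calls <- matrix(rbinom(n_samples * n_variants, 2, 0.4),
                  nrow = n_samples,
                  dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                  sprintf("rs%03d", seq_len(n_variants))))
  calls[runif(length(calls)) < missing_rate] <- NA
  r2 <- runif(n_variants, 0.2, 1)
  r2[sample(n_variants, 1)] <- NA  # one directly observed variant
  genotype_matrix(calls, data.frame(
    rsid = colnames(calls), chrom = "1",
    pos = sort(sample.int(1e6, n_variants)),
    ref = sample(c("A", "C"), n_variants, TRUE),
    alt = sample(c("G", "T"), n_variants, TRUE), r2 = r2))
}

random_survival_data <- function(n = 60, beta = 0.5, seed = 1,
                                 round_times = FALSE) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.1 * exp(beta * x1 - 0.3 * x2))
  t_c <- rexp(n, 0.05)
  tm <- pmin(t_ev, t_c)
  if (round_times) tm <- pmax(round(tm, 1), 0.1)  # induce ties
  data.frame(sample_id = sprintf("P%03d", seq_len(n)), time = tm,
             event = as.integer(t_ev <= t_c), x1 = x1, x2 = x2)
}

expect_genotypes_equal <- function(a, b, r2_tol = 1e-9) {
  expect_identical(a$sample_ids, b$sample_ids)
  expect_identical(unname(a$calls), unname(b$calls))
  expect_identical(a$variants$rsid, b$variants$rsid)
  expect_identical(a$variants$pos, b$variants$pos)
  expect_identical(a$variants$chrom, b$variants$chrom)
  expect_equal(a$variants$r2, b$variants$r2, tolerance = r2_tol)
}
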