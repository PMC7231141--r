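test_that("cis assignment reproduces the worked-example distances", {
  ex <- ovcca_example()
  pairs <- assign_cis_pairs(ex$snps, ex$genes, window = 5e5)
  znf <- pairs[pairs$rsid == "rs4873815" & pairs$gene_id == "ZNF707", ]
  expect_equal(znf$distance, 28310)
  # 660,571 bp pair appears only with the wider window
  expect_false(any(pairs$rsid == "rs11136002" &
                     pairs$gene_id == "TNFRSF10B"))
  pairs1m <- assign_cis_pairs(ex$snps, ex$genes, window = 1e6)
  tnf <- pairs1m[pairs1m$rsid == "rs11136002" &
                   pairs1m$gene_id == "TNFRSF10B", ]
  expect_equal(tnf$distance, 660571)
})

test_that("a SNP inside the gene body pairs at distance zero for any window", {
  snp <- data.frame(rsid = "rsIN", chrom = "2", pos = 5000)
  gene <- data.frame(gene_id = "G", chrom = "2", start = 4000, end = 6000)
  for (w in c(1, 1000, 1e6)) {
    pr <- assign_cis_pairs(snp, gene, window = w)
    expect_equal(pr$distance, 0)
  }
  # inclusive boundary: distance exactly equal to the window is kept
  snp2 <- data.frame(rsid = "rsEDGE", chrom = "2", pos = 4000 - 100)
  expect_equal(nrow(assign_cis_pairs(snp2, gene, window = 100)), 1)
  expect_equal(nrow(assign_cis_pairs(snp2, gene, window = 99)), 0)
})

test_that("chromosome label style mismatch is an explicit error", {
  snp <- data.frame(rsid = "rs1", chrom = "chr8", pos = 100)
  gene <- data.frame(gene_id = "G", chrom = "8", start = 50, end = 200)
  expect_error(assign_cis_pairs(snp, gene), "naming mismatch")
  # genuinely disjoint chromosomes give an empty result, not an error
  gene2 <- data.frame(gene_id = "G", chrom = "chr9", start = 50, end = 200)
  expect_equal(nrow(assign_cis_pairs(snp, gene2)), 0)
})

test_that("pair regression matches closed-form and lm on random data", {
  fit <- regress_pair(c(0, 1, 2, 0, 1, 2), c(0.1, 1.1, 2.1, -0.1, 0.9, 1.9))
  expect_equal(fit$beta, 1.0, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    x <- rbinom(n, 2, 0.4); if (var(x) == 0) next
    y <- 0.3 * x + rnorm(n)
    x[sample(n, 2)] <- NA  # pairwise-complete handling
    ours <- regress_pair(x, y)
    ref <- summary(lm(y ~ x))$coefficients
    expect_equal(ours$beta, ref["x", "Estimate"], tolerance = 1e-10)
    expect_equal(ours$se, ref["x", "Std. Error"], tolerance = 1e-10)
    expect_equal(ours$p, ref["x", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(ours$n, sum(!is.na(x)))
  }
})

test_that("degenerate regressions are flagged, not given p-values", {
  expect_equal(regress_pair(c(1, 1, 1, 1), rnorm(4))$status,
               "constant_dosage")
  expect_equal(regress_pair(c(0, 1, 2, 1), rep(2, 4))$status,
               "constant_expression")
  expect_equal(regress_pair(c(0, 1, NA), c(1, 2, 3))$status,
               "too_few_observations")
  # perfect fit: p collapses to the floor, never exactly zero
  fit <- regress_pair(c(0, 1, 2, 0, 1, 2), 2 * c(0, 1, 2, 0, 1, 2))
  expect_equal(fit$beta, 2)
  expect_lte(fit$p, .Machine$double.xmin)
  expect_gt(fit$p, 0)
})

test_that("regression p agrees with a permutation null", {
  set.seed(12)
  B <- 20000
  for (i in 1:3) {
    x <- rbinom(30, 2, 0.4)
    y <- rnorm(30)
    fit <- regress_pair(x, y)
    r_obs <- abs(cor(x, y))
    r_perm <- replicate(B, abs(cor(x, sample(y))))
    p_perm <- (1 + sum(r_perm >= r_obs - 1e-12)) / (B + 1)
    expect_lt(abs(fit$p - p_perm),
              3 * sqrt(p_perm * (1 - p_perm) / B) + 1e-3)
  }
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(0.03)$q, 0.03)
  # brute-force step-up oracle
  step_up <- function(p, alpha) {
    m <- length(p); s <- sort(p)
    k <- max(c(0, which(s <= seq_len(m) * alpha / m)))
    if (k == 0) rep(FALSE, m) else p <= s[k]
  }
  a <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(a$reject))
  expect_equal(a$reject, step_up(c(0.01, 0.02, 0.03, 0.04), 0.05))
  b <- bh_adjust(c(0.001, 0.8))
  expect_equal(b$q, c(0.002, 0.8))
  expect_equal(b$reject, c(TRUE, FALSE))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    res <- bh_adjust(p, alpha = 0.1)
    expect_equal(res$q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(res$reject, step_up(p, 0.1))
    # monotone: q ordering follows p ordering
    expect_true(all(diff(res$q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the funnel recovers a planted cis signal end to end", {
  cfg <- planted_funnel_config(seed = 42, n_snps = 300)
  sim <- simulate_genotypes(cfg)
  expr <- simulate_expression(sim$genotypes, cfg)
  res <- suppressWarnings(suppressMessages(
    run_funnel(sim$genotypes, sim$panel, expr, cfg$genome_map$genes,
               target_population = "JPT")))
  f <- res$funnel
  expect_lte(f$snps_passing_qc, f$snps_tested)
  expect_lte(f$differential_snps, f$snps_passing_qc)
  expect_gte(sum(sim$truth %in% res$selected_snps), 3)
  planted <- merge(cfg$eqtl_effects, res$associations,
                   by = c("rsid", "gene_id"))
  expect_gte(sum(planted$significant), 3)
  # q-values dominate p-values and respect the FDR flag definition
  ok <- res$associations$status == "ok"
  expect_true(all(res$associations$q[ok] >= res$associations$p[ok]))
  expect_identical(res$associations$significant[ok],
                   res$associations$q[ok] <= res$alpha)
})

test_that("an all-null run reports empty downstream stages with a warning", {
  cfg <- sim_config(n_snps = 150, samples_per_population = 60,
                    fst_background = 0.001, n_differentiated = 0,
                    genome_map = default_genome_map(150), seed = 3)
  sim <- simulate_genotypes(cfg)
  expr <- simulate_expression(sim$genotypes, cfg)
  expect_warning(
    res <- suppressMessages(
      run_funnel(sim$genotypes, sim$panel, expr, cfg$genome_map$genes,
                 target_population = "POP1")),
    "no ancestry-differentiated SNPs")
  expect_equal(res$funnel$differential_snps, 0)
  expect_equal(res$funnel$cis_pairs, 0)
  expect_equal(res$funnel$distinct_cis_genes, 0)
  expect_equal(nrow(res$associations), 0)
})

test_that("power increases with effect size and sample size", {
  pow <- function(beta, n, seeds = 1:30) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      x <- rbinom(n, 2, 0.3)
      if (var(x) == 0) return(NA_real_)
      y <- beta * x + rnorm(n)
      regress_pair(x, y)$p < 0.05
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lte(pow(0.1, 40), pow(0.35, 40) + 1e-9)
  expect_lte(pow(0.35, 40), pow(0.8, 40) + 1e-9)
  expect_lte(pow(0.2, 20), pow(0.2, 200) + 1e-9)
})
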