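test_that("quantile normalization maps columns to the rank-mean reference", {
  out <- quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))
  # identical columns are unchanged
  x <- cbind(s1 = c(2, 7, 1), s2 = c(2, 7, 1))
  expect_equal(quantile_normalize(x), x)
  # a tie group receives the mean of its tied reference values:
  # reference = rowMeans(sorted columns) = (1.5, 3.0, 7.0); the tied 2s of
  # column a occupy sorted positions 1-2, so both get (1.5 + 3.0) / 2
  xt <- cbind(a = c(2, 2, 9), b = c(1, 4, 5))
  qt <- quantile_normalize(xt)
  expect_equal(unname(qt[, "a"]), c(2.25, 2.25, 7.0))
  expect_equal(unname(qt[, "b"]), c(1.5, 3.0, 7.0))
  # untied input: every column shares one sorted multiset and moments
  set.seed(14)
  y <- matrix(rnorm(80), 20, 4)
  qn <- quantile_normalize(y)
  ref <- sort(qn[, 1])
  for (j in 2:4) expect_equal(sort(qn[, j]), ref, tolerance = 1e-12)
  expect_equal(unname(colMeans(qn)), rep(mean(qn[, 1]), 4), tolerance = 1e-12)
})

test_that("quantile normalization agrees with limma's implementation", {
  skip_if_not_installed("limma")
  set.seed(15)
  for (i in 1:5) {
    x <- matrix(rnorm(60), 15, 4)
    expect_equal(unname(quantile_normalize(x)),
                 unname(limma::normalizeQuantiles(x)), tolerance = 1e-10)
  }
})

test_that("rank-sum exact mode enumerates the permutation distribution", {
  ts <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ts$p, 0.1)
  expect_equal(ts$mode, "exact")
  # identical multisets cannot discriminate
  expect_equal(ranksum_test(c(1, 5, 9), c(9, 1, 5), mode = "normal")$p, 1)
  # exact p-values are achievable tail probabilities k / C(n, nx)
  set.seed(16)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(5)
    p <- ranksum_test(x, y, mode = "exact")$p
    expect_equal(p * choose(9, 4), round(p * choose(9, 4)), tolerance = 1e-9)
  }
})

test_that("rank-sum exact mode matches wilcox.test and the normal mode", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    pe <- ranksum_test(x, y, mode = "exact")$p
    ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(pe, ref, tolerance = 1e-12)
    pn <- ranksum_test(x, y, mode = "normal")$p
    expect_lt(abs(pe - pn), 0.01)
  }
  # ties force midranks + tie-corrected normal approximation
  xt <- c(1, 2, 2, 3, 7); yt <- c(2, 3, 3, 9, 9, 4)
  ours <- ranksum_test(xt, yt)
  expect_equal(ours$mode, "normal")
  ref <- suppressWarnings(wilcox.test(xt, yt, correct = TRUE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("median dichotomization sends ties low deterministically", {
  expect_equal(unname(dichotomize_by_median(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(unname(dichotomize_by_median(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  # odd n: the median sample itself is labeled low
  expect_equal(unname(dichotomize_by_median(c(5, 1, 9))),
               c("low", "low", "high"))
  expect_error(dichotomize_by_median(c(2, 2, 2)), "identical")
})

test_that("Kaplan-Meier estimator follows the product-limit closed form", {
  k <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(attr(k, "median_survival"), 2)
  # all censored: flat curve, median not reached
  k2 <- km_fit(c(5, 8, 10), c(0, 0, 0))
  expect_equal(nrow(k2), 0)
  expect_true(is.na(attr(k2, "median_survival")))
  # censoring after the last event leaves the curve unchanged
  k3 <- km_fit(c(1, 2, 3, 9), c(1, 1, 1, 0))
  expect_equal(k3$survival, c(3 / 4, 2 / 4, 1 / 4))
  expect_error(km_fit(-1, 1), ">= 0")
})

test_that("Kaplan-Meier curve matches survfit and the empirical survivor", {
  skip_if_not_installed("survival")
  set.seed(18)
  for (i in 1:5) {
    tt <- round(rexp(40, 0.1), 1); ev <- rbinom(40, 1, 0.6)
    if (sum(ev) == 0) next
    k <- km_fit(tt, ev)
    sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    ref <- summary(sf, times = k$time)
    expect_equal(k$survival, ref$surv, tolerance = 1e-12)
    expect_equal(k$n_risk, ref$n.risk, tolerance = 1e-12)
  }
  # no censoring: product-limit equals the empirical survivor function
  tt <- c(3, 1, 4, 1, 5, 9, 2, 6)
  k <- km_fit(tt, rep(1, 8))
  emp <- vapply(k$time, function(t) mean(tt > t), numeric(1))
  expect_equal(k$survival, emp)
  # survival bounded and non-increasing
  expect_true(all(k$survival >= 0 & k$survival <= 1))
  expect_true(all(diff(k$survival) <= 0))
})

test_that("log-rank test is symmetric, rank-invariant, and matches survdiff", {
  tt <- c(1, 2, 3, 4, 1, 2, 3, 4); ev <- rep(1, 8)
  gr <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(tt, ev, gr)
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)
  skip_if_not_installed("survival")
  set.seed(19)
  for (i in 1:5) {
    tt <- rexp(50, 0.1); ev <- rbinom(50, 1, 0.7)
    gr <- rep(c("a", "b"), 25)
    if (sum(ev) == 0) next
    ours <- logrank_test(tt, ev, gr)
    ref <- survival::survdiff(survival::Surv(tt, ev) ~ gr)
    expect_equal(ours$chi2, ref$chisq, tolerance = 1e-10)
    # label swap leaves the statistic unchanged
    expect_equal(logrank_test(tt, ev, rev(gr))$chi2, ours$chi2,
                 tolerance = 1e-10)
    # invariance under a strictly increasing time transform
    expect_equal(logrank_test(log1p(tt), ev, gr)$chi2, ours$chi2,
                 tolerance = 1e-10)
  }
})

test_that("log-rank type-I error is near nominal under the null", {
  set.seed(20)
  rej <- vapply(1:400, function(i) {
    tt <- rexp(60, 0.1); ev <- rbinom(60, 1, 0.7)
    gr <- rep(c("a", "b"), 30)
    logrank_test(tt, ev, gr)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("Cox fit agrees with survival::coxph under Breslow ties", {
  skip_if_not_installed("survival")
  for (s in 1:20) {
    d <- random_survival_data(n = 70, seed = s, round_times = s %% 2 == 0)
    fit <- suppressWarnings(cox_fit(d, c("x1", "x2")))
    ref <- survival::coxph(survival::Surv(time, event) ~ x1 + x2, data = d,
                           ties = "breslow")
    expect_true(fit$converged)
    expect_equal(fit$coefficients, coef(ref), tolerance = 1e-4)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-4)
    expect_equal(fit$hazard_ratios, exp(coef(ref)), tolerance = 1e-4)
  }
})

test_that("Cox null covariate is estimated near zero", {
  d <- random_survival_data(n = 500, beta = 0, seed = 77)
  fit <- cox_fit(d, "x1")
  expect_lt(abs(fit$coefficients["x1"]), 0.15)
})

test_that("Cox degenerate inputs are flagged, not silently returned", {
  d <- random_survival_data(n = 30, seed = 3)
  d$event <- 0
  expect_error(cox_fit(d, "x1"), "no events")
  # perfect separation: covariate orders events before all censorings
  d2 <- data.frame(time = c(1:5, 6:10),
                   event = c(rep(1, 5), rep(0, 5)),
                   x1 = c(rep(1, 5), rep(0, 5)))
  expect_warning(fit <- cox_fit(d2, "x1"), "converge")
  expect_false(fit$converged)
  d3 <- random_survival_data(n = 30, seed = 4)
  d3$x2 <- 2 * d3$x1
  expect_error(cox_fit(d3, c("x1", "x2")), "collinear")
})

test_that("differential expression table reuses BH adjustment", {
  set.seed(23)
  expr <- matrix(rnorm(200), 10, 20,
                 dimnames = list(paste0("g", 1:10), paste0("S", 1:20)))
  expr["g1", 1:10] <- expr["g1", 1:10] + 3
  res <- diff_expression(expr, paste0("S", 1:10), paste0("S", 11:20))
  expect_true(res$significant[res$gene_id == "g1"])
  expect_equal(res$q, bh_adjust(res$p)$q)
  expect_error(diff_expression(expr, "S1", "nope"), "nope")
})
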