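#' Quantile normalization of an expression matrix
#'
#' Each sample column's values are replaced by the mean of the
#' cross-sample order statistics at the same rank (the reference
#' distribution); tied values receive the mean of their tied reference
#' values via midranks. Afterwards every column shares an identical sorted
#' value multiset. Used to place arrays measured on different platforms on
#' a common scale before rank-based comparisons.
#'
#' @param x Numeric matrix, genes x samples (>= 2 samples), no missing
#'   values.
#' @return Matrix of the same shape and dimnames.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  if (anyNA(x)) stop("quantile normalization requires complete data")
  constant <- apply(x, 2, function(col) all(col == col[1]))
  if (any(constant))
    warning("column(s) with all-identical values normalized to the ",
            "reference distribution: ",
            paste(colnames(x)[constant], collapse = ", "))
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    o <- order(col)
    res <- numeric(length(col))
    # tie groups occupy contiguous sorted positions; every member gets the
    # mean of its group's reference values
    res[o] <- ave(ref, match(col[o], unique(col[o])))
    res
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test using midranks for ties. The exact null
#' distribution is enumerated when the combined sample size is at most 20
#' and there are no ties; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`.
#' @return List with `statistic` (rank sum of `x`), `p` (two-sided), and
#'   `mode` actually used.
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))$p # exact: 0.1
#' @export
ranksum_test <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  w <- sum(r[seq_len(nx)])
  ties <- any(duplicated(pooled))
  if (mode == "auto") mode <- if (n <= 20 && !ties) "exact" else "normal"
  mu <- nx * (n + 1) / 2
  if (mode == "exact") {
    if (ties) stop("exact mode is defined for untied data only")
    if (n > 20) stop("exact enumeration limited to n <= 20")
    # untied ranks are 1..n, so enumerate all rank subsets of size nx
    sums <- colSums(combn(n, nx))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
  } else {
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = w, p = p, mode = mode)
}

#' Dichotomize expression at the median
#'
#' Values strictly above the median are `"high"`, values at or below it
#' `"low"` (ties at the median, including the median sample itself for odd
#' n, go low so that group sizes are deterministic). All-identical values
#' cannot be split and are an error.
#'
#' @param values Numeric per-sample values (>= 2).
#' @return Character vector of `"high"`/`"low"` labels (named like
#'   `values`, if named).
#' @export
dichotomize_by_median <- function(values) {
  if (length(values) < 2) stop("need at least 2 samples to dichotomize")
  if (anyNA(values)) stop("missing values cannot be dichotomized")
  if (all(values == values[1]))
    stop("degenerate split: all values identical")
  med <- median(values)
  labels <- ifelse(values > med, "high", "low")
  if (!is.null(names(values))) names(labels) <- names(values)
  labels
}

#' Kaplan-Meier product-limit estimator
#'
#' Survival step function over the distinct event times; censored times
#' reduce the risk set but contribute no factor. The median survival is
#' the earliest event time at which the survival estimate drops to 0.5 or
#' below, and is undefined ("not reached") when the curve never does.
#'
#' @param time Numeric times (months, >= 0).
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Object of class `km_curve`: data-frame-backed list with
#'   `time` (distinct event times, ascending), `n_risk`, `n_event`,
#'   `survival`, plus attributes `median_survival` (`NA` = not reached)
#'   and `n`.
#' @examples
#' km_fit(c(1, 2, 3), c(1, 1, 1)) # S = 2/3, 1/3, 0
#' @export
km_fit <- function(time, event) {
  if (length(time) == 0) stop("at least one record required")
  if (any(time < 0) || anyNA(time)) stop("times must be >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  ev_times <- sort(unique(time[event == 1]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5)) ev_times[which(surv <= 0.5)[1]] else NA_real_
  structure(data.frame(time = ev_times, n_risk = n_risk,
                       n_event = n_event, survival = surv),
            median_survival = med, n = length(time), class = c("km_curve",
                                                               "data.frame"))
}

#' @export
print.km_curve <- function(x, ...) {
  med <- attr(x, "median_survival")
  cat("Kaplan-Meier curve:", attr(x, "n"), "subjects,",
      sum(x$n_event), "events\n")
  cat("  median survival:",
      if (is.na(med)) "not reached" else paste(signif(med, 4), "months"),
      "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Log-rank test for two survival curves
#'
#' Sums observed minus expected events for the first group over the
#' distinct pooled event times, with the hypergeometric variance at each
#' time; the statistic is chi-square with 1 degree of freedom.
#'
#' @param time Numeric times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Two-level group labels.
#' @return List with `chi2`, `df` (1), `p`, `observed` and `expected`
#'   (per-group event counts).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (any(table(group) == 0)) stop("both groups must be non-empty")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  ev_times <- sort(unique(time[event == 1]))
  g1 <- group == levels(group)[1]
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  d_tot <- sum(event == 1)
  list(chi2 = chi2, df = 1L,
       p = pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = c(o1, d_tot - o1), expected = c(e1, d_tot - e1))
}

#' Cox proportional hazards regression
#'
#' Maximizes the partial likelihood with Breslow handling of tied event
#' times by Newton-Raphson. Convergence is declared when the largest
#' absolute score component drops below `tol`; standard errors come from
#' the inverse observed information. Runs that fail to converge within
#' `max_iter` iterations, or whose coefficients diverge (as under perfect
#' separation), are flagged rather than silently returned.
#'
#' @param data Data frame with columns `time`, `event`, and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param tol Convergence tolerance on the score (default 1e-8).
#' @param max_iter Iteration cap (default 50).
#' @return Object of class `cox_fit`: list with `coefficients` (log hazard
#'   ratios), `se`, `hazard_ratios`, `loglik` (partial log-likelihood at
#'   the estimate), `converged`, `iterations`, `n`, `n_events`.
#' @export
cox_fit <- function(data, covariates, tol = 1e-8, max_iter = 50L) {
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  keep <- complete.cases(data[c("time", "event", covariates)])
  data <- data[keep, , drop = FALSE]
  time <- data$time; event <- data$event
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  if (sum(event) == 0) stop("no events observed; Cox model undefined")
  X <- as.matrix(data[covariates])
  storage.mode(X) <- "double"
  if (qr(cbind(X))$rank < ncol(X)) stop("covariates are collinear")
  p <- ncol(X); n <- nrow(X)
  beta <- rep(0, p)
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]

  partial <- function(beta) {
    eta <- drop(X %*% beta)
    wexp <- exp(eta)
    # cumulative risk-set sums, walking times from largest to smallest
    grad <- rep(0, p); info <- matrix(0, p, p); ll <- 0
    S0 <- 0; S1 <- rep(0, p); S2 <- matrix(0, p, p)
    i <- n
    for (t in rev(unique(time))) {
      while (i >= 1 && time[i] == t) {
        S0 <- S0 + wexp[i]
        S1 <- S1 + wexp[i] * X[i, ]
        S2 <- S2 + wexp[i] * tcrossprod(X[i, ])
        i <- i - 1
      }
      ev <- which(time == t & event == 1)
      d <- length(ev)
      if (d > 0) {
        xbar <- S1 / S0
        ll <- ll + sum(eta[ev]) - d * log(S0)
        grad <- grad + colSums(X[ev, , drop = FALSE]) - d * xbar
        info <- info + d * (S2 / S0 - tcrossprod(xbar))
      }
    }
    list(ll = ll, grad = grad, info = info)
  }

  converged <- FALSE; it <- 0L; pl <- partial(beta)
  while (it < max_iter) {
    it <- it + 1L
    step <- tryCatch(solve(pl$info, pl$grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    pl <- partial(beta)
    if (any(!is.finite(beta)) || any(abs(beta) > 20)) break
    if (max(abs(pl$grad)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Cox fit did not converge (possible separation or ",
            "insufficient events)")
  se <- tryCatch(sqrt(diag(solve(pl$info))),
                 error = function(e) rep(NA_real_, p))
  structure(list(coefficients = setNames(beta, covariates),
                 se = setNames(se, covariates),
                 hazard_ratios = setNames(exp(beta), covariates),
                 loglik = pl$ll, converged = converged, iterations = it,
                 n = n, n_events = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$n, " subjects, ", x$n_events,
      " events, ", x$iterations, " iterations",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = x$hazard_ratios,
                    se = x$se,
                    z = x$coefficients / x$se,
                    p = 2 * pnorm(-abs(x$coefficients / x$se)),
                    check.names = FALSE)
  print(tab, digits = 4)
  invisible(x)
}

#' Rank-based differential expression between two groups
#'
#' Per-gene Wilcoxon rank-sum comparison of two named sample groups with a
#' Benjamini-Hochberg adjusted q-value column (reusing [bh_adjust()]).
#'
#' @param expression Expression matrix (genes x samples).
#' @param group1,group2 Character vectors of sample ids.
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @return Data frame with `gene_id`, `statistic`, `p`, `q`, `significant`.
#' @export
diff_expression <- function(expression, group1, group2, alpha = 0.05) {
  missing <- setdiff(c(group1, group2), colnames(expression))
  if (length(missing))
    stop("sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  res <- lapply(rownames(expression), function(g) {
    ts <- ranksum_test(expression[g, group1], expression[g, group2])
    data.frame(gene_id = g, statistic = ts$statistic, p = ts$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  adj <- bh_adjust(out$p, alpha = alpha)
  out$q <- adj$q
  out$significant <- adj$reject
  out
}
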