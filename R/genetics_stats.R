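#' Exact binomial test of a proportion
#'
#' Two-sided exact test of `x` successes in `n` trials against a null
#' proportion `p0`, by direct enumeration of the binomial pmf: the p-value
#' sums the probabilities of all outcomes no more likely than the observed
#' one (the minimum-likelihood two-sided convention, with a small relative
#' tolerance for floating-point ties). One-sided alternatives sum the
#' corresponding tail. `method = "normal"` gives the chi-square/normal
#' approximation with continuity correction instead.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param p0 Null proportion (default the Mendelian double-knockout
#'   expectation 1/16).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param method `"exact"` (default) or `"normal"`.
#'
#' @return A one-row tibble: `x`, `n`, `estimate`, `p0`, `p_value`,
#'   `alternative`, `method`.
#' @examples
#' exact_binomial_test(3, 100, 1 / 16)
#' @export
exact_binomial_test <- function(x, n, p0 = 1 / 16,
                                alternative = c("two.sided", "less", "greater"),
                                method = c("exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(length(x) == 1L, length(n) == 1L, x >= 0, n >= 1, x <= n,
            p0 > 0, p0 < 1)
  if (method == "normal") {
    pv <- prop.test(x, n, p = p0, alternative = alternative,
                    correct = TRUE)$p.value
  } else {
    d <- dbinom(0:n, n, p0)
    pv <- switch(alternative,
      two.sided = sum(d[d <= d[x + 1L] * (1 + 1e-7)]),
      less = sum(d[seq_len(x + 1L)]),
      greater = sum(d[(x + 1L):(n + 1L)])
    )
    pv <- min(pv, 1)
  }
  tibble::tibble(x = x, n = n, estimate = x / n, p0 = p0, p_value = pv,
                 alternative = alternative, method = method)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval from Beta quantiles:
#' `low = qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `high = qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#' Vectorized over `x` and `n`.
#'
#' @param x Successes (vector).
#' @param n Trials (vector, recycled).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with `x`, `n`, `estimate`, `ci_low`, `ci_high`.
#' @export
clopper_pearson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(all(x >= 0), all(x <= n), conf_level > 0, conf_level < 1)
  alpha <- 1 - conf_level
  tibble::tibble(
    x = x, n = n, estimate = x / n,
    ci_low = ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1)),
    ci_high = ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  )
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests `m` and caps at 1.
#'
#' @param p Vector of p-values.
#' @param m Number of tests; must be at least `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) abort("m must be at least the number of tests")
  pmin(p * m, 1)
}

#' Test breeding frequencies against the Mendelian 1/16 expectation
#'
#' For each breed, tests whether the observed double-knockout fraction of
#' weaned pups differs from `p0` with the two-sided exact binomial test,
#' attaches the exact Clopper-Pearson interval, and Bonferroni-adjusts the
#' p-values across breeds. A breed whose adjusted p-value is below the
#' significance level with an interval entirely below `p0` shows
#' segregation distortion consistent with embryonic lethality.
#'
#' @param breeds Tibble with columns `breed`, `n_weaned`, `n_dko`.
#' @param p0 Null proportion (default 1/16).
#' @param conf_level Confidence level for the exact interval.
#' @param method Passed to [exact_binomial_test()].
#'
#' @return A tibble with one row per breed: observed proportion, exact CI,
#'   raw and Bonferroni-adjusted p-values.
#' @export
mendelian_breed_test <- function(breeds, p0 = 1 / 16, conf_level = 0.95,
                                 method = "exact") {
  stopifnot(all(c("breed", "n_weaned", "n_dko") %in% names(breeds)),
            all(breeds$n_dko >= 0), all(breeds$n_dko <= breeds$n_weaned))
  res <- purrr::map_dfr(seq_len(nrow(breeds)), function(i) {
    tst <- exact_binomial_test(breeds$n_dko[i], breeds$n_weaned[i], p0,
                               method = method)
    ci <- clopper_pearson_ci(breeds$n_dko[i], breeds$n_weaned[i], conf_level)
    tibble::tibble(breed = breeds$breed[i],
                   n_weaned = breeds$n_weaned[i], n_dko = breeds$n_dko[i],
                   proportion = tst$estimate, ci_low = ci$ci_low,
                   ci_high = ci$ci_high, p_value = tst$p_value)
  })
  res$p_adjusted <- bonferroni(res$p_value, nrow(res))
  res
}

#' Mendelian two-locus class probabilities
#'
#' The 9 genotype-class probabilities of a double-heterozygote intercross:
#' the outer product of (1/4, 1/2, 1/4) with itself, i.e. {1,2,1} x {1,2,1}
#' over 16. Classes are named `"<fancd2> <smad3>"`.
#'
#' @return Named numeric vector of length 9 summing to 1.
#' @export
mendelian_two_locus_probs <- function() {
  g <- c("+/+" = 1, "+/-" = 2, "-/-" = 1) / 4
  p <- as.vector(outer(g, g))
  names(p) <- as.vector(outer(names(g), names(g), function(a, b) paste(b, a)))
  p
}

#' Goodness of fit of litter genotype counts to Mendelian expectation
#'
#' Chi-square goodness of fit of observed genotype-class counts against
#' their Mendelian probabilities. When any expected count falls below
#' `min_expected` (common in small midgestation litters) the chi-square
#' approximation is unreliable, and a Monte-Carlo multinomial p-value is
#' reported instead (set the RNG seed beforehand for reproducibility); the
#' `method` field records which was used.
#'
#' @param counts Named or ordered numeric vector of class counts matching
#'   `probs`.
#' @param probs Expected class probabilities (default
#'   [mendelian_two_locus_probs()]).
#' @param min_expected Threshold triggering the Monte-Carlo fallback.
#' @param B Monte-Carlo replicates.
#'
#' @return An object of class `mendelian_gof`: list with `statistic`, `df`,
#'   `p_value`, `method`, and `residuals` (tibble of class, observed,
#'   expected, Pearson residual). `glance()` gives the one-row summary.
#' @export
mendelian_gof <- function(counts, probs = mendelian_two_locus_probs(),
                          min_expected = 5, B = 10000L) {
  if (length(counts) != length(probs)) {
    abort("counts and probabilities must have the same length")
  }
  if (sum(counts) <= 0) abort("total count must be positive")
  if (!is.null(names(counts)) && !is.null(names(probs))) {
    if (!setequal(names(counts), names(probs))) {
      abort("count classes do not match probability classes")
    }
    counts <- counts[names(probs)]
  }
  expected <- sum(counts) * probs
  use_mc <- any(expected < min_expected)
  ct <- suppressWarnings(
    chisq.test(counts, p = probs, simulate.p.value = use_mc, B = B)
  )
  residuals <- tibble::tibble(
    class = if (is.null(names(probs))) as.character(seq_along(probs)) else names(probs),
    observed = as.numeric(counts), expected = as.numeric(expected),
    residual = as.numeric(ct$residuals)
  )
  structure(
    list(statistic = unname(ct$statistic),
         df = length(probs) - 1L,
         p_value = ct$p.value,
         method = if (use_mc) "monte_carlo" else "chi_square",
         residuals = residuals),
    class = "mendelian_gof"
  )
}

#' @export
print.mendelian_gof <- function(x, ...) {
  cat("Mendelian goodness of fit (", x$method, "): X-squared = ",
      signif(x$statistic, 4), ", df = ", x$df,
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mendelian_gof <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 method = x$method)
}

#' @exportS3Method generics::tidy
tidy.mendelian_gof <- function(x, ...) x$residuals

# Binomial log-likelihood of a limiting-dilution assay under the
# single-hit model P(negative | dose) = exp(-f * dose).
single_hit_loglik <- function(log_f, assay) {
  f <- exp(log_f)
  p_neg <- exp(-f * assay$dose)
  n_pos <- assay$n_tested - assay$n_negative
  ll <- assay$n_negative * (-f * assay$dose) +
    n_pos * log1p(-p_neg + .Machine$double.xmin * (p_neg == 1))
  sum(ll)
}

validate_assay <- function(assay) {
  stopifnot(all(c("dose", "n_tested", "n_negative") %in% names(assay)))
  if (any(assay$dose < 0) || any(assay$n_negative < 0) ||
      any(assay$n_negative > assay$n_tested)) {
    abort("invalid limiting-dilution assay table")
  }
  if (any(assay$dose == 0 & assay$n_negative < assay$n_tested)) {
    warn("positive recipients at dose 0 are impossible under the single-hit model")
  }
  invisible(assay)
}

#' Fit the single-hit limiting-dilution model
#'
#' Under the single-hit (Poisson) model the probability that a recipient
#' shows no engraftment after receiving `dose` cells is `exp(-f * dose)`,
#' where `f` is the frequency of repopulating cells. The fit maximizes the
#' binomial log-likelihood over `log f` by one-dimensional optimization (a
#' direct MLE, equivalent to the complementary-log-log regression with a
#' single parameter), with a Wald confidence interval on the log scale.
#' With a single dose `d` and `k` of `n` negative recipients the MLE has
#' the closed form `-log(k/n) / d`, which the optimizer reproduces.
#'
#' @param assay Tibble with columns `dose` (cells injected), `n_tested`,
#'   `n_negative`.
#' @param conf_level Confidence level of the Wald interval.
#'
#' @return An object of class `single_hit_fit`: list with `frequency`
#'   (f-hat), `one_in` (1/f-hat), `log_f`, `se_log_f`, `ci_low`, `ci_high`,
#'   `log_lik`, `identifiable`, and the assay. All-negative or all-positive
#'   assays give a boundary estimate flagged `identifiable = FALSE`.
#'   `glance()` returns the one-row summary.
#' @export
fit_single_hit <- function(assay, conf_level = 0.95) {
  validate_assay(assay)
  inf <- assay[assay$dose > 0, ]
  if (nrow(inf) == 0L) abort("no informative (positive-dose) rows")
  all_neg <- sum(inf$n_negative) == sum(inf$n_tested)
  all_pos <- sum(inf$n_negative) == 0
  lo <- log(1e-9 / max(inf$dose))
  hi <- log(60 / min(inf$dose))
  opt <- optimize(function(lf) single_hit_loglik(lf, inf),
                  lower = lo, upper = hi, maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  log_f <- if (all_neg) lo else if (all_pos) hi else opt$maximum
  identifiable <- !(all_neg || all_pos)
  h <- 1e-5
  d2 <- (single_hit_loglik(log_f + h, inf) - 2 * single_hit_loglik(log_f, inf) +
           single_hit_loglik(log_f - h, inf)) / h^2
  se <- if (identifiable && d2 < 0) sqrt(-1 / d2) else NA_real_
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(frequency = exp(log_f), one_in = exp(-log_f),
         log_f = log_f, se_log_f = se,
         ci_low = if (is.na(se)) NA_real_ else exp(log_f - z * se),
         ci_high = if (is.na(se)) NA_real_ else exp(log_f + z * se),
         log_lik = single_hit_loglik(log_f, inf),
         identifiable = identifiable, assay = assay),
    class = "single_hit_fit"
  )
}

#' @export
print.single_hit_fit <- function(x, ...) {
  cat("Single-hit fit: frequency 1 in ", signif(x$one_in, 4),
      if (!x$identifiable) " (boundary, non-identifiable)", "\n", sep = "")
  if (!is.na(x$se_log_f)) {
    cat("  95% CI: 1 in ", signif(1 / x$ci_high, 4), " to 1 in ",
        signif(1 / x$ci_low, 4), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.single_hit_fit <- function(x, ...) {
  tibble::tibble(frequency = x$frequency, one_in = x$one_in,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 log_lik = x$log_lik, identifiable = x$identifiable)
}

#' Likelihood-ratio comparison of two limiting-dilution groups
#'
#' Fits the single-hit model to each group and to the pooled data, and
#' compares twice the log-likelihood gain to a chi-square with one degree
#' of freedom (the asymptotic approximation). When several pairwise
#' comparisons are made, adjust the resulting p-values with
#' [bonferroni()].
#'
#' @param assay_a,assay_b Limiting-dilution assay tibbles.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `freq_a`,
#'   `freq_b`, `identifiable`.
#' @export
lrt_compare <- function(assay_a, assay_b) {
  fa <- fit_single_hit(assay_a)
  fb <- fit_single_hit(assay_b)
  fs <- fit_single_hit(dplyr::bind_rows(assay_a, assay_b))
  stat <- max(0, 2 * (fa$log_lik + fb$log_lik - fs$log_lik))
  tibble::tibble(
    statistic = stat, df = 1L,
    p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
    freq_a = fa$frequency, freq_b = fb$frequency,
    identifiable = fa$identifiable && fb$identifiable && fs$identifiable
  )
}
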