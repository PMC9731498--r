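test_that("exact binomial p-values match enumeration and binom.test", {
  # x = 0 of 16 at p0 = 1/16: verify against direct pmf summation
  d <- dbinom(0:16, 16, 1 / 16)
  manual <- sum(d[d <= d[1]])
  expect_equal(exact_binomial_test(0, 16, 1 / 16)$p_value, manual)

  # binom.test implements the same minimum-likelihood convention and acts
  # as the independent cross-check over a grid
  for (n in c(7, 16, 50)) {
    for (x in c(0, 1, floor(n / 3), n)) {
      for (p0 in c(1 / 16, 0.3, 0.5)) {
        expect_equal(exact_binomial_test(x, n, p0)$p_value,
                     stats::binom.test(x, n, p0)$p.value,
                     tolerance = 1e-12)
      }
    }
  }

  # observing the modal outcome gives p = 1
  n <- 32
  x_mode <- which.max(dbinom(0:n, n, 1 / 16)) - 1L
  expect_equal(exact_binomial_test(x_mode, n, 1 / 16)$p_value, 1)

  expect_error(exact_binomial_test(5, 4), "x <= n")
})

test_that("exact p-values respect the success/failure relabeling symmetry", {
  for (n in c(10, 25)) {
    for (x in 0:n) {
      p1 <- exact_binomial_test(x, n, 0.3)$p_value
      p2 <- exact_binomial_test(n - x, n, 0.7)$p_value
      expect_equal(p1, p2, tolerance = 1e-12)
    }
  }
})

test_that("the exact test is conservative under the 1/16 null", {
  set.seed(201)
  n <- 200
  p_lookup <- vapply(0:n, function(x) exact_binomial_test(x, n, 1 / 16)$p_value,
                     numeric(1))
  draws <- rbinom(10000, n, 1 / 16)
  rejection <- mean(p_lookup[draws + 1L] < 0.05)
  expect_lte(rejection, 0.05)
})

test_that("the normal-approximation variant agrees with prop.test", {
  expect_equal(exact_binomial_test(9, 200, 1 / 16, method = "normal")$p_value,
               stats::prop.test(9, 200, 1 / 16)$p.value)
})

test_that("Clopper-Pearson intervals obey their closed forms and coverage", {
  n <- 30
  expect_equal(clopper_pearson_ci(0, n)$ci_low, 0)
  expect_equal(clopper_pearson_ci(0, n)$ci_high, 1 - 0.025^(1 / n))
  expect_equal(clopper_pearson_ci(n, n)$ci_high, 1)
  expect_equal(clopper_pearson_ci(n, n)$ci_low, 0.025^(1 / n))

  # the interval always contains the point estimate (exhaustive, n <= 50)
  for (nn in c(1, 2, 7, 23, 50)) {
    ci <- clopper_pearson_ci(0:nn, nn)
    expect_true(all(ci$ci_low <= ci$estimate + 1e-12))
    expect_true(all(ci$ci_high >= ci$estimate - 1e-12))
  }

  # simulated coverage at n = 100, p = 0.05 is at least nominal
  set.seed(202)
  x <- rbinom(10000, 100, 0.05)
  ci <- clopper_pearson_ci(x, 100)
  covered <- ci$ci_low <= 0.05 & 0.05 <= ci$ci_high
  expect_gte(mean(covered), 0.95)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(c(0.01, 0.2), 2), c(0.02, 0.4))
  expect_equal(bonferroni(0.9, 4), 1)
  set.seed(203)
  p <- runif(20)
  expect_true(all(bonferroni(p, 25) >= p))
  expect_equal(bonferroni(p, 20), stats::p.adjust(p, "bonferroni"))
  expect_error(bonferroni(p, 3), "at least")
})

test_that("breed tests run the full segregation-distortion workflow", {
  breeds <- tibble::tibble(
    breed = c("b1", "b2", "b3", "b4"),
    n_weaned = c(600, 300, 250, 200),
    n_dko = c(20, 9, 2, 3)
  )
  res <- mendelian_breed_test(breeds)
  expect_equal(nrow(res), 4L)
  expect_equal(res$p_adjusted, pmin(res$p_value * 4, 1))
  expect_true(all(res$ci_low <= res$proportion & res$proportion <= res$ci_high))
  # all these observed proportions sit below 1/16
  expect_true(all(res$proportion < 1 / 16))
})

test_that("Mendelian goodness of fit behaves at its extremes", {
  probs <- mendelian_two_locus_probs()
  expect_equal(sum(probs), 1)
  expect_equal(unname(probs[c("+/+ +/+", "-/- -/-")]), c(1 / 16, 1 / 16))

  counts <- probs * 160 # exactly proportional
  g <- mendelian_gof(counts)
  expect_equal(g$statistic, 0)
  expect_equal(g$p_value, 1)
  expect_equal(g$method, "chi_square")

  # all mass in one class: overwhelming rejection
  lump <- stats::setNames(c(141, rep(0, 8)), names(probs))
  set.seed(204)
  g2 <- mendelian_gof(lump)
  expect_lt(g2$p_value, 1e-3)

  # small litters trigger the Monte-Carlo method
  set.seed(205)
  g3 <- mendelian_gof(stats::setNames(c(2, 4, 2, 3, 6, 3, 1, 4, 2), names(probs)))
  expect_equal(g3$method, "monte_carlo")
  expect_error(mendelian_gof(c(1, 2, 3)), "length")
})

test_that("Mendelian litters of 141 embryos rarely reject the true null", {
  set.seed(206)
  probs <- mendelian_two_locus_probs()
  pvals <- replicate(1000, {
    counts <- as.numeric(stats::rmultinom(1, 141, probs))
    mendelian_gof(stats::setNames(counts, names(probs)))$p_value
  })
  expect_gte(mean(pvals > 0.05), 0.94)
})

test_that("the single-hit MLE matches the one-dose closed form", {
  for (k in c(2, 5, 8)) {
    assay <- tibble::tibble(dose = 1e5, n_tested = 10, n_negative = k)
    fit <- fit_single_hit(assay)
    expect_equal(fit$frequency, -log(k / 10) / 1e5, tolerance = 1e-6)
    expect_true(fit$identifiable)
  }
  # a dose-zero row predicts certain negativity and leaves the MLE alone
  assay <- tibble::tibble(dose = c(0, 1e5), n_tested = 10, n_negative = c(10, 5))
  fit0 <- fit_single_hit(assay)
  expect_equal(fit0$frequency, -log(0.5) / 1e5, tolerance = 1e-6)

  # boundary cases are flagged non-identifiable
  all_neg <- tibble::tibble(dose = c(1e4, 1e5), n_tested = 10, n_negative = c(10, 10))
  expect_false(fit_single_hit(all_neg)$identifiable)
  all_pos <- tibble::tibble(dose = c(1e4, 1e5), n_tested = 10, n_negative = c(0, 0))
  expect_false(fit_single_hit(all_pos)$identifiable)
})

test_that("the optimizer beats every grid point on random assays", {
  set.seed(207)
  for (rep in 1:20) {
    f_true <- 10^runif(1, -6, -4)
    doses <- 10^seq(4, 6, length.out = 4)
    assay <- tibble::tibble(
      dose = doses, n_tested = 10,
      n_negative = rbinom(4, 10, exp(-f_true * doses))
    )
    informative <- sum(assay$n_negative) > 0 &&
      sum(assay$n_negative) < sum(assay$n_tested)
    if (!informative) next
    fit <- fit_single_hit(assay)
    grid <- seq(log(1e-8), log(1e-3), length.out = 200)
    ll_grid <- vapply(grid, function(lf) hybridscar:::single_hit_loglik(lf, assay),
                      numeric(1))
    expect_gte(fit$log_lik + 1e-8, max(ll_grid))
  }
})

test_that("single-hit fits recover the true frequency across assays", {
  set.seed(208)
  f_true <- 1e-5
  doses <- c(1e4, 1e5, 3e5, 1e6)
  est <- replicate(500, {
    assay <- tibble::tibble(
      dose = doses, n_tested = 10,
      n_negative = rbinom(length(doses), 10, exp(-f_true * doses))
    )
    fit_single_hit(assay)$frequency
  })
  expect_lt(abs(median(est) / f_true - 1), 0.15)
})

test_that("likelihood-ratio comparison nests correctly", {
  assay <- tibble::tibble(dose = c(1e4, 1e5), n_tested = 10, n_negative = c(9, 4))
  same <- lrt_compare(assay, assay)
  expect_equal(same$statistic, 0, tolerance = 1e-6)
  expect_equal(same$p_value, 1, tolerance = 1e-4)

  set.seed(209)
  for (rep in 1:20) {
    mk <- function(f) {
      d <- c(1e4, 1e5, 5e5)
      tibble::tibble(dose = d, n_tested = 8,
                     n_negative = rbinom(3, 8, exp(-f * d)))
    }
    r <- lrt_compare(mk(1e-5), mk(10^runif(1, -5.5, -4.5)))
    expect_gte(r$statistic, 0)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
})

test_that("the LRT holds its size under equal frequencies", {
  set.seed(210)
  doses <- c(1e4, 1e5, 5e5)
  f <- 1e-5
  mk <- function() tibble::tibble(
    dose = doses, n_tested = 10,
    n_negative = rbinom(length(doses), 10, exp(-f * doses))
  )
  pvals <- replicate(2000, lrt_compare(mk(), mk())$p_value)
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
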