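test_that("mutation-rate arithmetic follows the diploid convention", {
  ## 59 autosomal DNMs over the median callable denominator
  expect_equal(signif(mutation_rate(59, 2582336232), 4), 1.142e-8)
  expect_equal(mutation_rate(0, 1e9), 0)
  ## doubling the callable denominator halves the rate
  expect_equal(mutation_rate(10, 2e9), mutation_rate(10, 1e9) / 2)
  expect_error(mutation_rate(10, 0), "positive")
})

test_that("rate adjustment reproduces the worked example and is monotone", {
  adj <- adjust_rate(1.143e-8, 0.045, 0.004)
  expect_equal(signif(adj, 3), 1.10e-8)
  expect_equal(round(adj * 6.4e9, 1), 70.1)
  ## identity when both error rates vanish
  expect_equal(adjust_rate(2e-8, 0, 0), 2e-8)
  ## monotone decreasing in fpr, increasing in mhr
  f <- seq(0, 0.5, 0.05)
  expect_true(all(diff(adjust_rate(1e-8, f, 0.1)) < 0))
  expect_true(all(diff(adjust_rate(1e-8, 0.1, f)) > 0))
  expect_error(adjust_rate(1e-8, 0.5, 1), "lie in")
  ## the full estimate object composes the pieces
  r <- rate_estimate(59, 2582336232, fpr = 0.045, mhr = 0.004)
  expect_equal(r$adj_mu, adjust_rate(r$mu, 0.045, 0.004))
  expect_equal(r$per_genome, r$adj_mu * 6.4e9)
})

test_that("identity-link fit is exact on noise-free linear counts", {
  d <- data.frame(age = 1:10, count = 2L * (1:10) + 3L)
  f <- fit_poisson_identity(count ~ age, d)
  expect_equal(unname(coef(f)), c(3, 2), tolerance = 1e-8)
  expect_lt(f$deviance, 1e-10)
  ## method surface behaves like a model object
  expect_equal(length(predict(f, newdata = data.frame(age = c(1, 2)))), 2L)
  expect_equal(dim(confint(f)), c(2L, 2L))
  expect_equal(nrow(simulate(f, nsim = 3, seed = 1)), 10L)
  expect_equal(length(residuals(f)), 10L)
  ## rank-deficient designs are refused
  d$age2 <- d$age * 2
  expect_error(fit_poisson_identity(count ~ age + age2, d),
               "rank deficient")
})

test_that("glm route agrees with a brute-force likelihood grid search", {
  set.seed(1)
  toy <- simulate_dnm_counts(10, 1.2, 5, c(20, 40))
  f <- fit_poisson_identity(count ~ age, toy)
  ll <- function(b0, b1) {
    mu <- b0 + b1 * toy$age
    if (any(mu <= 0)) return(-Inf)
    sum(stats::dpois(toy$count, mu, log = TRUE))
  }
  ## coarse grid, then refine (the likelihood ridge couples the two
  ## parameters, so the slope axis needs the finer resolution)
  g <- expand.grid(b0 = seq(-10, 20, 0.1), b1 = seq(0, 3, 0.01))
  g$ll <- mapply(ll, g$b0, g$b1)
  top <- g[which.max(g$ll), ]
  g2 <- expand.grid(b0 = seq(top$b0 - 0.2, top$b0 + 0.2, 0.001),
                    b1 = seq(top$b1 - 0.02, top$b1 + 0.02, 1e-4))
  g2$ll <- mapply(ll, g2$b0, g2$b1)
  best <- g2[which.max(g2$ll), ]
  expect_lt(abs(unname(coef(f))[2] - best$b1), 1e-3)
  expect_lt(abs(unname(coef(f))[1] - best$b0), 5e-3)
})

test_that("Wald CIs achieve nominal coverage across seeded replicates", {
  set.seed(2024)
  hits <- logical(1000)
  for (i in seq_along(hits)) {
    d <- simulate_dnm_counts(100, 1.44, 14.24, c(17, 45))
    f <- fit_poisson_identity(count ~ age, d)
    ci <- f$coefficients[f$coefficients$term == "age", c("ci_lo", "ci_hi")]
    hits[i] <- ci$ci_lo <= 1.44 && 1.44 <= ci$ci_hi
  }
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("nested deviance tests behave at the null and the boundary", {
  set.seed(11)
  d <- simulate_dnm_counts(300, 1.44, 14.24, c(17, 45))
  f1 <- fit_poisson_identity(count ~ age, d)
  f0 <- fit_poisson_identity(count ~ 1, d)
  cmp <- compare_nested_poisson(f0, f1)
  expect_gte(cmp$chi2, 0)
  expect_equal(cmp$df, 1L)
  ## identical models: chi2 = 0, p = 1
  same <- compare_nested_poisson(f1, f1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  ## reversed nesting (fewer parameters in the "full" model) is an error
  expect_error(compare_nested_poisson(f1, f0), "nested|parameters")
  ## different data is an error
  d2 <- d; d2$count <- rev(d2$count)
  f2 <- fit_poisson_identity(count ~ age, d2)
  expect_error(compare_nested_poisson(f0, f2), "same response")
})

test_that("the family-vs-pooled test holds its size under homogeneity", {
  set.seed(404)
  n_rej <- 0L
  n_rep <- 1000L
  for (r in seq_len(n_rep)) {
    fam <- rep(sprintf("f%02d", 1:8), each = 10)
    age <- stats::runif(80, 18, 45)
    d <- data.frame(count = stats::rpois(80, 1.72 * age + 15.12),
                    age = age, family_id = fam)
    f0 <- fit_poisson_identity(count ~ age, d)
    f1 <- fit_poisson_identity(count ~ age + family_id, d)
    p <- compare_nested_poisson(f0, f1)$p
    if (p < 0.05) n_rej <- n_rej + 1L
  }
  ## type-I error close to nominal 5% (3 binomial SEs over 1,000 runs)
  expect_gte(n_rej / n_rep, 0.029)
  expect_lte(n_rej / n_rep, 0.071)
})

test_that("family model suite separates homogeneous from heterogeneous", {
  ## heterogeneous: per-family slopes 0.2..3.2, recovered in rank order
  set.seed(88)
  slopes <- seq(0.2, 3.2, length.out = 16)
  rows <- lapply(seq_along(slopes), function(i) {
    age <- stats::runif(8, 18, 45)
    data.frame(family_id = sprintf("f%02d", i), dad_age = age,
               mom_age = age - 2,
               count = stats::rpois(8, slopes[i] * age + 20))
  })
  d <- do.call(rbind, rows)
  fm <- fit_family_models(d)
  ok <- !fm$per_family$skipped
  expect_gt(stats::cor(fm$per_family$slope[ok], slopes[ok],
                       method = "spearman"), 0.8)
  ## the interaction term is strongly supported here
  expect_lt(fm$test_interaction$p, 0.01)
  ## homogeneous: per-family slopes cluster near the shared slope
  set.seed(89)
  rows0 <- lapply(1:12, function(i) {
    age <- stats::runif(10, 18, 45)
    data.frame(family_id = sprintf("f%02d", i), dad_age = age,
               mom_age = age - 2,
               count = stats::rpois(10, 1.72 * age + 15))
  })
  d0 <- do.call(rbind, rows0)
  fm0 <- fit_family_models(d0)
  ok0 <- !fm0$per_family$skipped
  expect_lt(abs(median(fm0$per_family$slope[ok0]) - 1.72), 0.5)
  ## coverage-aware no-intercept model keeps the slope interpretable
  d0$callable_fraction <- stats::runif(nrow(d0), 0.85, 0.95)
  d0$count <- stats::rpois(nrow(d0),
                           (1.72 * d0$dad_age + 15) * d0$callable_fraction)
  fm2 <- fit_family_models(d0)
  expect_lt(abs(coef(fm2$scaled)[["dad_age_scaled"]] - 1.72), 0.35)
})

test_that("mosaic age models recover the pool model's signatures", {
  set.seed(505)
  n <- 2000
  age <- stats::runif(n, 18, 45)
  mosaic <- stats::rpois(n, 3)                       # age-independent pool
  total <- mosaic + stats::rpois(n, 1.44 * age + 14)
  tab <- data.frame(child_id = as.character(seq_len(n)),
                    mosaic_number = mosaic, total_dnms = total,
                    mosaic_fraction = mosaic / total,
                    dad_age = age,
                    n_siblings = sample(4:16, n, replace = TRUE))
  mm <- mosaic_age_models(tab)
  ## Poisson slope CI covers zero for the age-independent pool
  co <- mm$poisson_age$coefficients
  sl <- co[co$term == "dad_age", ]
  expect_true(sl$ci_lo <= 0 && 0 <= sl$ci_hi)
  ## but the log-fraction slope is negative: the germline denominator
  ## grows with age while the pool does not
  expect_lt(coef(mm$log_fraction_age)[["dad_age"]], 0)
  expect_lt(summary(mm$log_fraction_age)$coefficients["dad_age", 4], 1e-4)
  ## sibship size does not predict the mosaic fraction under the pool model
  expect_lt(abs(unname(mm$cor_fraction_sibs$estimate)), 0.1)
  ## all-zero mosaic counts skip the models
  tab0 <- tab; tab0$mosaic_number <- 0L
  expect_message(mm0 <- mosaic_age_models(tab0), "skipped")
  expect_null(mm0$poisson_age)
})

test_that("CI coverage of the identity-link fit under its own model", {
  set.seed(3030)
  covered <- logical(200)
  for (i in seq_along(covered)) {
    d <- simulate_dnm_counts(60, 0.9, 10, c(18, 45))
    f <- fit_poisson_identity(count ~ age, d)
    ci <- f$coefficients[f$coefficients$term == "age", ]
    covered[i] <- ci$ci_lo <= 0.9 && 0.9 <= ci$ci_hi
  }
  expect_gte(mean(covered), 0.9)
})

test_that("spectrum comparison flags match a hand-computed chi-squared", {
  cls <- mutation_classes()
  a <- setNames(c(30L, 25L, 80L, 50L, 20L, 85L, 10L, 20L), cls)
  b <- setNames(c(300L, 240L, 800L, 480L, 210L, 900L, 90L, 180L), cls)
  out <- compare_spectra(a, b)
  ## closed-form 2x2 chi-squared without continuity correction
  hand_chi2 <- function(x11, x12, x21, x22) {
    x11 <- as.numeric(x11); x12 <- as.numeric(x12)
    x21 <- as.numeric(x21); x22 <- as.numeric(x22)
    n <- x11 + x12 + x21 + x22
    (n * (x11 * x22 - x12 * x21)^2) /
      ((x11 + x12) * (x21 + x22) * (x11 + x21) * (x12 + x22))
  }
  ta <- sum(a); tb <- sum(b)
  for (k in cls) {
    expect_equal(out$chi2[out$class == k],
                 hand_chi2(a[[k]], ta - a[[k]], b[[k]], tb - b[[k]]),
                 tolerance = 1e-10)
  }
  ## identical spectra -> nothing significant
  same <- compare_spectra(a, a)
  expect_false(any(same$significant))
  ## zero-marginal classes are skipped with a flag
  a0 <- a; b0 <- b; a0[["indel"]] <- 0L; b0[["indel"]] <- 0L
  sk <- compare_spectra(a0, b0)
  expect_true(sk$skipped[sk$class == "indel"])
  ## flags are monotone in the adjusted p-values
  sig_p <- out$p_adj[out$significant]
  ns_p <- out$p_adj[!out$significant & !out$skipped]
  if (length(sig_p) && length(ns_p)) expect_lt(max(sig_p), min(ns_p))
  ## class order does not change the flag set
  perm <- sample(cls)
  out2 <- compare_spectra(a[perm], b[perm])
  expect_equal(out2$significant[match(cls, out2$class)], out$significant)
})

test_that("the mosaic CpG enrichment is detectable at study-like depth", {
  ## germline vs mosaic spectra at n ~ 22,000 vs ~ 300 (SNVs only)
  cfg <- sim_config()
  set.seed(61)
  gs <- cfg$spectrum_germline[setdiff(mutation_classes(), "indel")]
  ms <- cfg$spectrum_mosaic[setdiff(mutation_classes(), "indel")]
  germ <- stats::setNames(as.integer(stats::rmultinom(1, 22000,
                                                      gs / sum(gs))),
                          names(gs))
  mos <- stats::setNames(as.integer(stats::rmultinom(1, 300,
                                                     ms / sum(ms))),
                         names(ms))
  out <- compare_spectra(mos, germ)
  expect_true(out$significant[out$class == "CpG>TpG"])
})

test_that("error-rate constructors reduce to count ratios", {
  er <- error_rates(c(100, 25075), c(9, 202))
  expect_equal(round(100 * er$mhr, 1), 0.4)
  expect_equal(round(100 * er$fpr, 1), 4.5)
  expect_error(error_rates(c(1, 0), c(1, 2)))
})
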