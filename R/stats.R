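#' Germline mutation rate per base pair per generation
#'
#' The count of autosomal DNMs divided by the jointly callable autosomal
#' base pairs, divided by two (diploid convention).
#'
#' @param dnm_count autosomal DNM count.
#' @param callable_bp callable autosomal base pairs
#'   ([callable_autosomal_bp()]).
#' @return mutations per base pair per generation.
#' @export
mutation_rate <- function(dnm_count, callable_bp) {
  if (any(callable_bp <= 0)) stop("callable_bp must be positive")
  dnm_count / callable_bp / 2
}

#' Adjust a mutation rate for false positives and missed heterozygotes
#'
#' `adj_mu = mu * (1 - FPR) / (1 - MHR)`: false positives inflate the
#' observed rate, while missed parental heterozygotes remove true events
#' from the denominator's complement, so the two corrections pull in
#' opposite directions.
#'
#' @param mu unadjusted rate (per bp per generation).
#' @param fpr false-positive rate in \[0, 1).
#' @param mhr missed-heterozygote rate in \[0, 1).
#' @return adjusted rate.
#' @export
adjust_rate <- function(mu, fpr, mhr) {
  if (any(fpr < 0 | fpr >= 1) || any(mhr < 0 | mhr >= 1)) {
    stop("fpr and mhr must lie in [0, 1)")
  }
  mu * (1 - fpr) / (1 - mhr)
}

#' Full mutation-rate estimate with error adjustment
#'
#' @param dnm_count,callable_bp as in [mutation_rate()].
#' @param fpr,mhr error rates.
#' @param genome_size diploid genome size used to extrapolate the expected
#'   number of de novo mutations per genome (default ~6.4 Gbp).
#' @return a `dnm_rate` list: `mu`, `adj_mu`, `per_genome`, `components`.
#' @export
rate_estimate <- function(dnm_count, callable_bp, fpr = 0, mhr = 0,
                          genome_size = 6.4e9) {
  mu <- mutation_rate(dnm_count, callable_bp)
  adj <- adjust_rate(mu, fpr, mhr)
  structure(list(mu = mu, adj_mu = adj, per_genome = adj * genome_size,
                 components = list(dnm_count = dnm_count,
                                   callable_bp = callable_bp,
                                   fpr = fpr, mhr = mhr,
                                   genome_size = genome_size)),
            class = "dnm_rate")
}

#' @export
print.dnm_rate <- function(x, ...) {
  cat(sprintf("mu = %.4g, adjusted = %.4g per bp per generation\n",
              x$mu, x$adj_mu))
  cat(sprintf("expected %.1f de novo mutations per genome (%.2g bp)\n",
              x$per_genome, x$components$genome_size))
  invisible(x)
}

#' Error rates from raw counts
#'
#' @param mhr_counts `c(supported, total)` third-generation DNMs with and
#'   without grandparental support.
#' @param fpr_counts `c(flagged, total)` second-generation DNMs flagged by
#'   deep parental resequencing.
#' @return list with `mhr`, `fpr` and the counts.
#' @export
error_rates <- function(mhr_counts, fpr_counts) {
  stopifnot(length(mhr_counts) == 2, length(fpr_counts) == 2,
            mhr_counts[2] > 0, fpr_counts[2] > 0)
  list(mhr = mhr_counts[1] / mhr_counts[2],
       fpr = fpr_counts[1] / fpr_counts[2],
       mhr_counts = mhr_counts, fpr_counts = fpr_counts)
}

# ---------------------------------------------------------------------------
# identity-link Poisson regression

#' Fit an identity-link Poisson regression
#'
#' Counts are modelled as Poisson with mean *linear* in the covariates
#' (`E[y] = X b`), so coefficients read directly as additional mutations
#' per unit of the covariate (e.g. DNMs per year of paternal age). Fitting
#' goes through [stats::glm()] with `poisson(link = "identity")`,
#' initialized from an ordinary least-squares fit; if the converged fit has
#' nonpositive means at observed covariates, fitting fails loudly rather
#' than silently switching link.
#'
#' @param formula model formula.
#' @param data data frame.
#' @param start optional starting coefficients (defaults to OLS).
#' @return a `dnm_poisfit` object; methods: `print`, `summary`, `coef`,
#'   `confint` (Wald, +/- 1.96 SE), `predict`, `residuals`, `simulate`,
#'   `deviance`, `logLik`.
#' @export
fit_poisson_identity <- function(formula, data, start = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (is.null(start)) {
    start <- stats::lm.fit(X, y)$coefficients
    start[is.na(start)] <- 0
    mu0 <- drop(X %*% start)
    if (any(mu0 <= 0)) {
      ## shift toward the data mean until all starting means are positive
      start <- 0.9 * start
      start[1] <- start[1] + 0.1 * mean(y) + max(0, -min(mu0)) + 0.1
    }
  }
  fit <- tryCatch(
    stats::glm(formula, data = data,
               family = stats::poisson(link = "identity"), start = start),
    error = function(e) stop("identity-link fit failed: ",
                             conditionMessage(e), call. = FALSE))
  if (!fit$converged) stop("identity-link fit did not converge")
  if (any(stats::fitted(fit) <= 0)) {
    stop("identity-link fit produced nonpositive fitted means")
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    ci_lo = unname(est - 1.96 * se), ci_hi = unname(est + 1.96 * se),
    p = 2 * stats::pnorm(-abs(unname(est) / unname(se))),
    stringsAsFactors = FALSE)
  structure(list(glm = fit, coefficients = tab,
                 deviance = stats::deviance(fit),
                 n = length(y), formula = formula),
            class = "dnm_poisfit")
}

#' @export
print.dnm_poisfit <- function(x, digits = 4, ...) {
  cat("Identity-link Poisson regression:",
      deparse(x$formula), sprintf("(n = %d)\n", x$n))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("residual deviance %.2f on %d df\n", x$deviance,
              stats::df.residual(x$glm)))
  invisible(x)
}

#' @export
summary.dnm_poisfit <- function(object, ...) object$coefficients

#' @export
coef.dnm_poisfit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.dnm_poisfit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  tab <- object$coefficients
  ci <- cbind(tab$estimate - z * tab$se, tab$estimate + z * tab$se)
  rownames(ci) <- tab$term
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.dnm_poisfit <- function(object, newdata = NULL, ...) {
  stats::predict(object$glm, newdata = newdata, type = "response", ...)
}

#' @export
residuals.dnm_poisfit <- function(object, ...) {
  stats::residuals(object$glm, ...)
}

#' @export
deviance.dnm_poisfit <- function(object, ...) object$deviance

#' @export
logLik.dnm_poisfit <- function(object, ...) stats::logLik(object$glm)

#' @export
simulate.dnm_poisfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::fitted(object$glm)
  out <- as.data.frame(replicate(nsim, stats::rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Compare two nested identity-link Poisson fits
#'
#' Likelihood-ratio (analysis-of-deviance) test: the deviance drop from the
#' null to the full model is chi-squared with degrees of freedom equal to
#' the difference in parameter count.
#'
#' @param fit_null,fit_full [fit_poisson_identity()] objects fitted to the
#'   same data, with the null model's terms contained in the full model's.
#' @return list with `chi2`, `df`, `p`.
#' @export
compare_nested_poisson <- function(fit_null, fit_full) {
  g0 <- fit_null$glm; g1 <- fit_full$glm
  if (fit_null$n != fit_full$n ||
      !isTRUE(all.equal(unname(g0$y), unname(g1$y)))) {
    stop("models were not fitted to the same response")
  }
  p0 <- length(stats::coef(g0)); p1 <- length(stats::coef(g1))
  if (p1 < p0) stop("full model must have more parameters than the null")
  nm0 <- names(stats::coef(g0))
  if (!all(vapply(nm0, function(t)
    any(grepl(t, names(stats::coef(g1)), fixed = TRUE)), logical(1)))) {
    stop("models do not appear nested")
  }
  chi2 <- max(fit_null$deviance - fit_full$deviance, 0)
  df <- p1 - p0
  if (df == 0) {
    ## identical parameterizations: the test is vacuous
    if (chi2 > 1e-8) stop("models do not appear nested")
    return(list(chi2 = 0, df = 0L, p = 1))
  }
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Fit the family-aware parental-age model suite
#'
#' Fits, on a per-child table of DNM counts: (a) the pooled paternal-age
#' model `count ~ dad_age`; (b) family intercepts `count ~ dad_age +
#' family_id`; (c) the interaction model `count ~ dad_age * family_id`
#' (slopes free per family); (d) the coverage-aware no-intercept model
#' `count ~ dad_age_scaled + callable_fraction + 0` where `dad_age_scaled
#' = dad_age * callable_fraction` (the identity-link mean
#' `(Bp*Ap + B0) * callable_fraction` expands to exactly these two terms);
#' and (e) `count ~ dad_age + mom_age + family_id`. Separate per-family
#' fits (for families with >= 2 children) give per-family slopes with Wald
#' CIs.
#'
#' @param per_child data frame with `count`, `dad_age`, `mom_age`,
#'   `family_id`, and optionally `callable_fraction` (needed for (d)).
#' @return a `dnm_family_models` list with elements `pooled`, `family`,
#'   `interaction`, `scaled` (or NULL), `parental`, `per_family` (data
#'   frame of slopes), and the deviance tests `test_family`
#'   (a vs b) and `test_interaction` (b vs c).
#' @export
fit_family_models <- function(per_child) {
  stopifnot(all(c("count", "dad_age", "family_id") %in% names(per_child)))
  per_child$family_id <- factor(per_child$family_id)
  a <- fit_poisson_identity(count ~ dad_age, per_child)
  b <- fit_poisson_identity(count ~ dad_age + family_id, per_child)
  cc <- fit_poisson_identity(count ~ dad_age * family_id, per_child)
  d <- NULL
  if (!is.null(per_child$callable_fraction)) {
    per_child$dad_age_scaled <- per_child$dad_age *
      per_child$callable_fraction
    d <- fit_poisson_identity(
      count ~ dad_age_scaled + callable_fraction + 0, per_child)
  }
  e <- if (!is.null(per_child$mom_age)) {
    ## paternal and maternal ages can be nearly collinear within families;
    ## report NULL rather than a degenerate fit
    tryCatch(
      fit_poisson_identity(count ~ dad_age + mom_age + family_id,
                           per_child),
      error = function(err) NULL)
  }
  fams <- levels(per_child$family_id)
  pf <- lapply(fams, function(fm) {
    sub <- per_child[per_child$family_id == fm, , drop = FALSE]
    if (nrow(sub) < 2 || length(unique(sub$dad_age)) < 2) {
      return(data.frame(family_id = fm, n = nrow(sub), slope = NA_real_,
                        se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        skipped = TRUE))
    }
    ft <- tryCatch(fit_poisson_identity(count ~ dad_age, sub),
                   error = function(e) NULL)
    if (is.null(ft)) {
      return(data.frame(family_id = fm, n = nrow(sub), slope = NA_real_,
                        se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        skipped = TRUE))
    }
    co <- ft$coefficients[ft$coefficients$term == "dad_age", ]
    data.frame(family_id = fm, n = nrow(sub), slope = co$estimate,
               se = co$se, ci_lo = co$ci_lo, ci_hi = co$ci_hi,
               skipped = FALSE)
  })
  structure(list(
    pooled = a, family = b, interaction = cc, scaled = d, parental = e,
    per_family = do.call(rbind, pf),
    test_family = compare_nested_poisson(a, b),
    test_interaction = compare_nested_poisson(b, cc)),
    class = "dnm_family_models")
}

#' @export
print.dnm_family_models <- function(x, ...) {
  sl <- coef(x$pooled)[["dad_age"]]
  cat(sprintf("pooled paternal age effect: %.3f DNMs/year\n", sl))
  cat(sprintf("family term: chi2 = %.2f (df %d), p = %.3g\n",
              x$test_family$chi2, x$test_family$df, x$test_family$p))
  cat(sprintf("age x family interaction: chi2 = %.2f (df %d), p = %.3g\n",
              x$test_interaction$chi2, x$test_interaction$df,
              x$test_interaction$p))
  ok <- !x$per_family$skipped
  if (any(ok)) {
    cat(sprintf("per-family slopes: %.2f to %.2f across %d families\n",
                min(x$per_family$slope[ok]), max(x$per_family$slope[ok]),
                sum(ok)))
  }
  invisible(x)
}

#' Age and sibship models for shared (post-PGCS mosaic) DNM counts
#'
#' Fits: an identity-link Poisson regression of each child's shared-DNM
#' count on paternal age; a linear model of the log mosaic fraction on
#' paternal age (zero fractions excluded, count reported); and correlation
#' tests of the mosaic fraction (and count) against sibship size.
#'
#' @param per_child output of [per_child_mosaic_stats()].
#' @return list with `poisson_age`, `log_fraction_age` (an `lm`),
#'   `n_zero_excluded`, `cor_fraction_sibs`, `cor_number_sibs`.
#' @export
mosaic_age_models <- function(per_child) {
  if (all(per_child$mosaic_number == 0, na.rm = TRUE)) {
    message("all shared-DNM counts are zero; age models skipped")
    return(list(poisson_age = NULL, log_fraction_age = NULL,
                n_zero_excluded = NA_integer_,
                cor_fraction_sibs = NULL, cor_number_sibs = NULL))
  }
  pois <- fit_poisson_identity(mosaic_number ~ dad_age, per_child)
  pos <- !is.na(per_child$mosaic_fraction) & per_child$mosaic_fraction > 0
  loglm <- stats::lm(log(mosaic_fraction) ~ dad_age,
                     data = per_child[pos, , drop = FALSE])
  ok <- !is.na(per_child$mosaic_fraction)
  list(
    poisson_age = pois,
    log_fraction_age = loglm,
    n_zero_excluded = sum(!pos & ok),
    cor_fraction_sibs = stats::cor.test(per_child$mosaic_fraction[ok],
                                        per_child$n_siblings[ok]),
    cor_number_sibs = stats::cor.test(per_child$mosaic_number,
                                      per_child$n_siblings))
}

# ---------------------------------------------------------------------------
# mutation spectra

#' Tabulate mutation-class counts for a set of DNMs
#'
#' @param dnms data frame with `ref`, `alt`, `context`.
#' @return named integer vector over [mutation_classes()].
#' @export
spectrum_counts <- function(dnms) {
  cls <- classify_mutation(dnms$ref, dnms$alt, dnms$context)
  table(factor(cls, levels = mutation_classes()))
}

#' Compare two mutation spectra class by class
#'
#' For each mutation class, a 2x2 chi-squared test of independence (class
#' vs all other classes, group A vs group B), without continuity
#' correction by default; p-values are Benjamini-Hochberg adjusted across
#' the class set and flagged at the given FDR.
#'
#' @param counts_a,counts_b named per-class counts (same class sets).
#' @param fdr false-discovery-rate threshold for the significance flag.
#' @param correct continuity correction (passed to [stats::chisq.test()]).
#' @return a `dnm_spectrum_cmp` data frame: per-class counts, fractions,
#'   `chi2`, `p`, `p_adj`, `significant`, `skipped`.
#' @export
compare_spectra <- function(counts_a, counts_b, fdr = 0.05,
                            correct = FALSE) {
  if (!setequal(names(counts_a), names(counts_b))) {
    stop("class sets must be identical between groups")
  }
  cls <- names(counts_a)
  counts_b <- counts_b[cls]
  ta <- sum(counts_a); tb <- sum(counts_b)
  res <- lapply(cls, function(k) {
    m <- matrix(c(counts_a[[k]], ta - counts_a[[k]],
                  counts_b[[k]], tb - counts_b[[k]]), nrow = 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      return(data.frame(class = k, count_a = counts_a[[k]],
                        count_b = counts_b[[k]], frac_a = counts_a[[k]] / ta,
                        frac_b = counts_b[[k]] / tb, chi2 = NA_real_,
                        p = NA_real_, skipped = TRUE))
    }
    ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
    data.frame(class = k, count_a = counts_a[[k]], count_b = counts_b[[k]],
               frac_a = counts_a[[k]] / ta, frac_b = counts_b[[k]] / tb,
               chi2 = unname(ct$statistic), p = unname(ct$p.value),
               skipped = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  out$p_adj[!out$skipped] <- stats::p.adjust(out$p[!out$skipped],
                                             method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj <= fdr
  class(out) <- c("dnm_spectrum_cmp", "data.frame")
  out
}

#' @export
print.dnm_spectrum_cmp <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$frac_a <- round(y$frac_a, digits); y$frac_b <- round(y$frac_b, digits)
  y$chi2 <- signif(y$chi2, digits); y$p <- signif(y$p, digits)
  y$p_adj <- signif(y$p_adj, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Per-child DNM count table for age-effect regression
#'
#' Tabulates autosomal DNM counts per third-generation child (pass in the
#' DNM rows you want counted -- e.g. validated third-generation DNMs with
#' post-zygotic and shared-mosaic calls excluded) together with parental
#' ages, family-unit membership, sibship size and, when masks are given,
#' the trio callable fraction.
#'
#' @param dnms data frame of DNM rows with `child_id` (and `chrom` if
#'   `x_chrom` exclusion matters).
#' @param pedigree the pedigree.
#' @param family_units defaults to [split_family_units()].
#' @param masks optional named list of callable `GRanges` per sample.
#' @param lcr LCR exclusion intervals (used with `masks`).
#' @param genome data frame (`chrom`, `length`) (used with `masks`).
#' @param x_chrom X chromosome name; X-linked DNMs are excluded from counts.
#' @return data frame: `child_id`, `family_id`, `count`, `dad_age`,
#'   `mom_age`, `n_siblings`, and `callable_fraction` when computable.
#' @export
per_child_dnm_table <- function(dnms, pedigree,
                                family_units = split_family_units(pedigree),
                                masks = NULL, lcr = NULL, genome = NULL,
                                x_chrom = "chrX") {
  kids <- pedigree$id[pedigree$generation == "G3"]
  if (!is.null(dnms$chrom)) dnms <- dnms[dnms$chrom != x_chrom, , drop = FALSE]
  fu_id <- vapply(kids, function(kid) {
    hit <- vapply(family_units$children, function(ch) kid %in% ch,
                  logical(1))
    if (any(hit)) family_units$family_id[hit][1] else NA_character_
  }, character(1))
  out <- data.frame(
    child_id = kids,
    family_id = fu_id,
    count = vapply(kids, function(kid) sum(dnms$child_id == kid),
                   integer(1)),
    dad_age = pedigree$dad_age[match(kids, pedigree$id)],
    mom_age = pedigree$mom_age[match(kids, pedigree$id)],
    n_siblings = family_units$n_children[
      match(fu_id, family_units$family_id)] - 1L,
    stringsAsFactors = FALSE)
  if (!is.null(masks)) {
    out$callable_fraction <- vapply(kids, function(kid) {
      par <- stats::na.omit(unname(parents_of(pedigree, kid)))
      if (length(par) < 2 || !all(c(kid, par) %in% names(masks))) {
        return(NA_real_)
      }
      callable_fraction(masks[[kid]], masks[[par[1]]], masks[[par[2]]],
                        lcr, genome, x_chrom = x_chrom)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}
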