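#' Pooled bioassay mortality with binomial confidence limits
#'
#' Pools replicate tubes within each condition and reports the pooled
#' mortality proportion with a Wilson 95% interval (Clopper-Pearson via
#' `ci_method = "clopper-pearson"`).
#'
#' @param reps tibble with `n_exposed`, `n_dead` plus condition columns.
#' @param ... grouping columns defining a condition (e.g. `insecticide`,
#'   `season`, `pbo`); empty pools everything.
#' @param conf confidence level.
#' @param ci_method passed to [binom_ci()].
#' @return tibble per condition: `n_exposed`, `n_dead`, `mortality`,
#'   `lower`, `upper`.
#' @export
mortality_summary <- function(reps, ..., conf = 0.95, ci_method = "wilson") {
  check_columns(reps, c("n_exposed", "n_dead"), "`reps`")
  if (any(reps$n_dead < 0 | reps$n_dead > reps$n_exposed)) {
    abort("`n_dead` must lie in [0, n_exposed].")
  }
  pooled <- reps |>
    dplyr::group_by(...) |>
    dplyr::summarise(n_exposed = sum(n_exposed), n_dead = sum(n_dead),
                     .groups = "drop")
  if (any(pooled$n_exposed == 0)) abort("a condition has zero exposed.")
  ci <- binom_ci(pooled$n_dead, pooled$n_exposed, conf, ci_method)
  dplyr::bind_cols(pooled, mortality = ci$estimate, lower = ci$lower,
                   upper = ci$upper)
}

#' PBO synergism odds ratios and chi-square tests
#'
#' For each insecticide, pools replicates (and seasons) into a 2x2 table of
#' mortality with and without PBO pre-exposure and reports the odds of
#' mortality with PBO relative to insecticide alone (Woolf CI,
#' Haldane-corrected when a cell is zero) plus the Pearson chi-square test
#' (1 df, no continuity correction). The odds ratio exceeds 1 exactly when
#' pooled mortality is higher with PBO.
#'
#' @param reps tibble with `insecticide`, `pbo` (logical), `n_exposed`,
#'   `n_dead`; any `season` column is pooled over.
#' @param conf confidence level.
#' @return tibble per insecticide: mortalities with/without PBO, `or`,
#'   `or_lower`, `or_upper`, `chi2`, `p`, `haldane`.
#' @export
synergism_test <- function(reps, conf = 0.95) {
  check_columns(reps, c("insecticide", "pbo", "n_exposed", "n_dead"),
                "`reps`")
  pooled <- reps |>
    dplyr::group_by(insecticide, pbo) |>
    dplyr::summarise(n_exposed = sum(n_exposed), n_dead = sum(n_dead),
                     .groups = "drop")
  purrr::map_dfr(unique(pooled$insecticide), function(ins) {
    pp <- pooled[pooled$insecticide == ins, ]
    if (!all(c(TRUE, FALSE) %in% pp$pbo)) {
      abort(sprintf("'%s' needs both PBO and no-PBO exposures.", ins))
    }
    w <- pp[pp$pbo, ]; wo <- pp[!pp$pbo, ]
    tab <- matrix(c(w$n_dead, w$n_exposed - w$n_dead,
                    wo$n_dead, wo$n_exposed - wo$n_dead),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("pbo", "alone"), c("dead", "alive")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      abort(sprintf("'%s': zero margin, odds ratio undefined.", ins))
    }
    wr <- woolf_or(tab, conf)
    chi2 <- pearson_chi2_2x2(tab)
    tibble::tibble(
      insecticide = ins,
      mortality_pbo = w$n_dead / w$n_exposed,
      mortality_alone = wo$n_dead / wo$n_exposed,
      or = wr$or, or_lower = wr$lower, or_upper = wr$upper,
      chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE),
      haldane = wr$haldane
    )
  })
}

#' Fit an LC50 from survival on log10 dose
#'
#' Least-squares fit of per-vial survival proportion on log10 dose over the
#' partial-response range (observations at exactly 0 or 1 survival lie
#' outside the linear regime and are excluded). The LC50 is the inverse
#' prediction `10^((0.5 - intercept)/slope)` and its 95% confidence
#' interval comes from Fieller's theorem applied to the inverse prediction
#' on the log10-dose scale. Scaling every dose by a constant scales the
#' LC50 by exactly that constant.
#'
#' Dose-response profiles with a very sharp inflection (fewer than three
#' doses with partial response) cannot support the regression; the fit is
#' refused with advice to use [discriminating_dose_test()] instead.
#'
#' @param obs tibble with `dose` and either `survival` or `n` +
#'   `n_survived`; one line's data.
#' @param conf confidence level for the Fieller interval.
#' @return an object of class `lc50_fit` with [tidy()]/[glance()] methods;
#'   `$lc50`, `$ci`, `$slope` give the headline numbers.
#' @export
fit_lc50 <- function(obs, conf = 0.95) {
  check_columns(obs, "dose", "`obs`")
  if (!"survival" %in% names(obs)) {
    check_columns(obs, c("n", "n_survived"), "`obs`")
    obs$survival <- obs$n_survived / obs$n
  }
  if (any(obs$dose <= 0)) abort("doses must be > 0.")
  partial <- obs$survival > 0 & obs$survival < 1
  if (dplyr::n_distinct(obs$dose[partial]) < 3) {
    abort(paste(
      "fewer than 3 doses with partial response (sharp inflection):",
      "a dose-response line cannot be fit; use discriminating_dose_test()."
    ))
  }
  dat <- obs[partial, ]
  fit <- lm(survival ~ log10(dose), data = dat)
  a <- coef(fit)[[1]]; b <- coef(fit)[[2]]
  if (b == 0) abort("zero fitted slope; LC50 undefined.")
  ## a noise-free profile gives a perfect fit; the summary warning is moot
  vc <- suppressWarnings(stats::vcov(fit))
  theta <- (0.5 - a) / b          # log10 LC50
  tq <- qt(1 - (1 - conf) / 2, fit$df.residual)
  ## Fieller for the ratio m1/m2, m1 = 0.5 - a, m2 = b
  m1 <- 0.5 - a; m2 <- b
  v1 <- vc[1, 1]; v2 <- vc[2, 2]; cv <- -vc[1, 2]
  disc <- (m1 * m2 - tq^2 * cv)^2 - (m2^2 - tq^2 * v2) * (m1^2 - tq^2 * v1)
  ## a perfect (noise-free) fit collapses the interval onto the estimate;
  ## clear round-off before the sign checks
  if (disc < 0 && disc > -1e-12 * max((m1 * m2)^2, 1)) disc <- 0
  if (sum(stats::residuals(fit)^2) < 1e-18) {
    ci_log <- c(theta, theta)
  } else if (m2^2 - tq^2 * v2 <= 0 || disc < 0) {
    warn("Fieller interval unbounded; slope not distinguishable from zero.")
    ci_log <- c(-Inf, Inf)
  } else {
    roots <- ((m1 * m2 - tq^2 * cv) + c(-1, 1) * sqrt(disc)) /
      (m2^2 - tq^2 * v2)
    ci_log <- sort(roots)
  }
  structure(list(
    lc50 = 10^theta,
    ci = 10^ci_log,
    slope = -b,                   # mortality slope per log10 dose
    intercept = a,
    conf = conf,
    df = fit$df.residual,
    fit = fit,
    data = obs,
    n_used = nrow(dat)
  ), class = "lc50_fit")
}

#' @export
print.lc50_fit <- function(x, ...) {
  cat(sprintf("<lc50_fit> LC50 = %.4g (%.0f%% CI %.4g-%.4g), slope = %.3g, %d obs\n",
              x$lc50, 100 * x$conf, x$ci[[1]], x$ci[[2]], x$slope, x$n_used))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the regression terms of an LC50 fit
#' @param x an `lc50_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy lc50_fit
#' @export
tidy.lc50_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' One-row summary of an LC50 fit
#' @param x an `lc50_fit`.
#' @param ... unused.
#' @return tibble `lc50`, `lc50_lower`, `lc50_upper`, `slope`,
#'   `r.squared`, `df`, `n_used`.
#' @method glance lc50_fit
#' @export
glance.lc50_fit <- function(x, ...) {
  tibble::tibble(
    lc50 = x$lc50, lc50_lower = x$ci[[1]], lc50_upper = x$ci[[2]],
    slope = x$slope,
    r.squared = suppressWarnings(summary(x$fit))$r.squared,
    df = x$df, n_used = x$n_used
  )
}

#' Discriminating-dose resistance ratio and exact Mann-Whitney test
#'
#' When a sharp inflection blocks LC50 estimation, lines are compared at a
#' single diagnostic dose: the resistance ratio is the ratio of mean
#' per-vial survival of the test line to the control line, with an exact
#' two-sided Mann-Whitney p-value over the per-vial survival proportions
#' (see [mann_whitney_exact()]).
#'
#' @param test,control numeric vectors of per-vial survival proportions
#'   (>= 2 vials each).
#' @return one-row tibble `ratio`, `U`, `p`, `method`, `n_test`,
#'   `n_control`. The ratio is `NA` when control survival is 0; the p-value
#'   is still reported.
#' @export
discriminating_dose_test <- function(test, control) {
  if (length(test) < 2 || length(control) < 2) {
    abort("need >= 2 vials per group.")
  }
  mw <- mann_whitney_exact(test, control)
  ratio <- if (mean(control) == 0) NA_real_ else mean(test) / mean(control)
  tibble::tibble(ratio = ratio, U = mw$U, p = mw$p, method = mw$method,
                 n_test = length(test), n_control = length(control))
}

#' In-vitro substrate depletion from HPLC peak areas
#'
#' Percent substrate depletion of incubations with an NADPH regenerating
#' system relative to no-NADPH negative controls:
#' `100 * (1 - mean(test) / mean(control))`. The reported mean is clamped
#' at 0 (no depletion) with the raw value retained and flagged; the sd is
#' taken over per-replicate depletion values computed against the control
#' mean.
#'
#' @param test_areas peak areas with NADPH (>= 1 replicate).
#' @param control_areas peak areas without NADPH (>= 1 replicate).
#' @return one-row tibble `mean_depletion`, `sd`, `raw_mean`, `clamped`.
#' @export
substrate_depletion <- function(test_areas, control_areas) {
  if (!length(test_areas) || !length(control_areas)) {
    abort("need >= 1 replicate in each condition.")
  }
  cm <- mean(control_areas)
  if (cm <= 0) abort("control mean peak area must be positive.")
  per_rep <- 100 * (1 - test_areas / cm)
  raw <- 100 * (1 - mean(test_areas) / cm)
  tibble::tibble(
    mean_depletion = max(0, raw),
    sd = if (length(per_rep) > 1) sd(per_rep) else NA_real_,
    raw_mean = raw,
    clamped = raw < 0
  )
}
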