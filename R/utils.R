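#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson interval inverts the score test of `p = p0`; unlike the Wald
#' interval it is well behaved at the boundaries (0 or n successes) and keeps
#' nominal coverage at moderate n, which is why it is the package default for
#' the "95% binomial confidence limits" reported alongside bioassay
#' mortalities and genotype frequencies. Clopper-Pearson ("exact") limits are
#' available for sensitivity analysis.
#'
#' @param x number of successes (vectorised).
#' @param n number of trials.
#' @param conf confidence level, default 0.95.
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return A tibble with columns `estimate`, `lower`, `upper`.
#' @examples
#' binom_ci(80, 100)
#' @export
binom_ci <- function(x, n, conf = 0.95, method = c("wilson", "clopper-pearson")) {
  method <- arg_match(method)
  if (any(n <= 0)) abort("`n` must be positive.")
  if (any(x < 0 | x > n)) abort("`x` must lie in [0, n].")
  p_hat <- x / n
  if (method == "wilson") {
    z <- qnorm(1 - (1 - conf) / 2)
    denom <- 1 + z^2 / n
    centre <- (p_hat + z^2 / (2 * n)) / denom
    half <- (z / denom) * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2))
    lower <- pmax(0, centre - half)
    upper <- pmin(1, centre + half)
  } else {
    lower <- ifelse(x == 0, 0, stats::qbeta((1 - conf) / 2, x, n - x + 1))
    upper <- ifelse(x == n, 1, stats::qbeta(1 - (1 - conf) / 2, x + 1, n - x))
  }
  tibble::tibble(estimate = p_hat, lower = lower, upper = upper)
}

#' Geometric mean
#' @param x positive numeric vector.
#' @param na.rm drop missing values first.
#' @return scalar geometric mean.
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) abort("geometric mean requires strictly positive values.")
  exp(mean(log(x)))
}

## Pearson chi-square on a 2x2 table, no continuity correction.
## Closed form n(ad - bc)^2 / (r1 r2 c1 c2); equals
## chisq.test(tab, correct = FALSE)$statistic.
pearson_chi2_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(NA_real_)
  num / den
}

## Haldane-Anscombe correction: +0.5 to every cell when any cell is zero.
haldane_correct <- function(tab) {
  if (any(tab == 0)) list(tab = tab + 0.5, corrected = TRUE)
  else list(tab = tab, corrected = FALSE)
}

## Odds ratio with Woolf (log-scale normal) CI from a 2x2 table.
## Rows: exposure (e.g. PBO yes/no); columns: outcome (dead, alive).
woolf_or <- function(tab, conf = 0.95) {
  hc <- haldane_correct(tab)
  t2 <- hc$tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se_log <- sqrt(sum(1 / t2))
  z <- qnorm(1 - (1 - conf) / 2)
  list(
    or = or,
    lower = exp(log(or) - z * se_log),
    upper = exp(log(or) + z * se_log),
    haldane = hc$corrected
  )
}

## degrees <-> radians
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## stop unless all required columns are present
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
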