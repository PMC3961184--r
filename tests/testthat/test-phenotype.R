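test_that("pooled mortality carries Wilson limits with nominal behaviour", {
  reps <- tibble::tibble(insecticide = "bendiocarb", season = "dry",
                         pbo = FALSE, replicate = 1:4,
                         n_exposed = 25, n_dead = 20)
  out <- mortality_summary(reps, insecticide)
  expect_equal(out$mortality, 0.8)
  expect_equal(out$lower, 0.7112, tolerance = 1e-3)
  expect_equal(out$upper, 0.8666, tolerance = 1e-3)

  all_dead <- dplyr::mutate(reps, n_dead = 25)
  out1 <- mortality_summary(all_dead, insecticide)
  expect_equal(out1$mortality, 1)
  expect_equal(out1$upper, 1)
  none <- dplyr::mutate(reps, n_dead = 0)
  out0 <- mortality_summary(none, insecticide)
  expect_equal(out0$mortality, 0)
  expect_equal(out0$lower, 0)

  expect_error(mortality_summary(dplyr::mutate(reps, n_exposed = 0)),
               "zero exposed|\\[0, n_exposed\\]")
})

test_that("Wilson intervals contain the estimate and keep coverage", {
  set.seed(17)
  for (p in c(0.1, 0.5, 0.8)) {
    x <- rbinom(3000, 100, p)
    ci <- binom_ci(x, 100)
    expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
    cover <- mean(ci$lower <= p & p <= ci$upper)
    expect_gte(cover, 0.93)
    expect_lte(cover, 0.97)
  }
})

test_that("synergism odds ratios match hand arithmetic and pool seasons", {
  reps <- tibble::tibble(
    insecticide = "bendiocarb",
    season = rep(c("dry", "wet"), each = 2),
    pbo = rep(c(TRUE, FALSE), 2),
    n_exposed = 50,
    n_dead = c(40, 9, 40, 8)
  )
  res <- synergism_test(reps)
  ## pooled: 80/100 with PBO vs 17/100 without
  expect_equal(res$or, (80 * 83) / (20 * 17), tolerance = 1e-12)
  expect_equal(res$chi2, 79.45, tolerance = 0.01)
  expect_lt(res$p, 1e-10)
  expect_gt(res$or, 10)  # the strong bendiocarb synergism regime

  ## identical mortality: OR 1, chi2 0
  eq <- synergism_test(dplyr::mutate(reps, n_dead = 20))
  expect_equal(eq$or, 1)
  expect_equal(eq$chi2, 0, tolerance = 1e-12)

  ## a zero cell triggers the Haldane correction and the flag
  hz <- synergism_test(dplyr::mutate(reps, n_dead = c(50, 49, 50, 50)))
  expect_true(hz$haldane)
  expect_true(is.finite(hz$or))

  ## OR > 1 exactly when pooled mortality is higher with PBO
  set.seed(18)
  for (i in 1:25) {
    nd <- c(rbinom(2, 50, 0.6), rbinom(2, 50, 0.4))
    if (sum(nd) == 0 || sum(nd) == 200) next   # degenerate outcome margin
    r <- synergism_test(dplyr::mutate(reps, n_dead = nd[c(1, 3, 2, 4)]))
    expect_equal(r$or > 1, r$mortality_pbo > r$mortality_alone)
  }
})

test_that("LC50 fitting inverts the planted dose-response exactly", {
  ## symmetric textbook data centred on dose 1
  obs <- tibble::tibble(dose = c(0.25, 0.5, 1, 2, 4),
                        survival = c(0.9, 0.7, 0.5, 0.3, 0.1))
  f <- fit_lc50(obs)
  expect_equal(f$lc50, 1, tolerance = 1e-9)

  ## planted LC50 recovered to 1e-9 relative for arbitrary parameters
  for (L in c(0.11, 0.94, 13.74, 18.37)) {
    dr <- sim_dose_response(
      tibble::tibble(line_id = "L", lc50 = L, slope = 0.3),
      doses = L * 10^seq(-1.2, 1.2, length.out = 6), noise = "none"
    )
    f <- fit_lc50(dr)
    expect_lt(abs(f$lc50 - L) / L, 1e-9)
    expect_true(f$ci[1] <= f$lc50 && f$lc50 <= f$ci[2])
  }

  ## dose-scale equivariance: scaling doses scales the LC50
  dr <- sim_dose_response(tibble::tibble(line_id = "L", lc50 = 2, slope = 0.35),
                          doses = 2 * 10^seq(-1, 1, length.out = 5),
                          noise = "none")
  f1 <- fit_lc50(dr)
  f2 <- fit_lc50(dplyr::mutate(dr, dose = dose * 7))
  expect_equal(f2$lc50 / f1$lc50, 7, tolerance = 1e-9)

  ## sharp inflection (all-or-nothing survival) is refused with advice
  sharp <- tibble::tibble(dose = c(0.01, 0.02, 0.05, 0.2, 0.5, 1),
                          survival = c(1, 1, 1, 0, 0, 0))
  expect_error(fit_lc50(sharp), "discriminating_dose_test")
})

test_that("lc50 fits expose tidy and glance summaries", {
  dr <- sim_dose_response(
    tibble::tibble(line_id = "L", lc50 = 0.72, slope = 0.3),
    doses = 0.72 * 10^seq(-1.2, 1.2, length.out = 6),
    n_per_vial = 20, noise = "binomial", seed = 12
  )
  f <- fit_lc50(dr)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 2)
  gl <- glance(f)
  expect_true(gl$lc50_lower <= gl$lc50 & gl$lc50 <= gl$lc50_upper)
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
})

test_that("exact Mann-Whitney matches complete enumeration and is symmetric", {
  ## complete separation of 8 vs 8: the smallest achievable two-sided p
  res <- mann_whitney_exact(1:8, 9:16)
  expect_equal(res$p, 2 / choose(16, 8), tolerance = 1e-12)
  expect_equal(signif(res$p, 1), 2e-4)

  ## identical groups: p = 1
  expect_equal(mann_whitney_exact(rep(1, 4), rep(1, 4))$p, 1)

  ## equivalence with the brute-force oracle for all n1, n2 <= 6 (with ties)
  set.seed(40)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      x <- sample(1:4, n1, replace = TRUE) + stats::runif(n1, 0, 0.01)
      y <- sample(1:4, n2, replace = TRUE) + stats::runif(n2, 0, 0.01)
      expect_equal(mann_whitney_exact(x, y)$p, oracle_mw_p(x, y),
                   tolerance = 1e-12)
      ## symmetry in group order
      expect_equal(mann_whitney_exact(x, y)$p, mann_whitney_exact(y, x)$p,
                   tolerance = 1e-12)
    }
  }

  ## tie-free case agrees with the reference exact distribution
  x <- c(1.2, 3.4, 5.6, 7.1); y <- c(2.3, 4.5, 6.7, 8.9, 10.1)
  expect_equal(mann_whitney_exact(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)

  ## large samples switch to the tie-corrected normal approximation
  set.seed(41)
  big <- mann_whitney_exact(rnorm(15), rnorm(15))
  expect_equal(big$method, "normal-approximation")
  expect_true(big$p >= 0 && big$p <= 1)
})

test_that("discriminating-dose comparison reports ratio and exact p", {
  test <- c(0.9, 0.85, 0.95, 0.8, 0.9, 0.85, 0.9, 0.95)
  ctrl <- c(0.1, 0.15, 0.05, 0.2, 0.1, 0.15, 0.1, 0.05)
  res <- discriminating_dose_test(test, ctrl)
  expect_equal(res$p, 2 / choose(16, 8), tolerance = 1e-12)
  expect_equal(res$ratio, mean(test) / mean(ctrl))

  ## zero control survival: ratio undefined but p still reported
  res0 <- discriminating_dose_test(test, rep(0, 8))
  expect_true(is.na(res0$ratio))
  expect_false(is.na(res0$p))
  expect_error(discriminating_dose_test(0.5, ctrl), ">= 2")
})

test_that("substrate depletion reproduces the worked arithmetic and clamps", {
  ## constructed peak areas: 1 - 358/1000 = 64.2%
  res <- substrate_depletion(c(358, 358, 358), c(1000, 1000, 1000))
  expect_equal(res$mean_depletion, 64.2, tolerance = 1e-12)
  expect_false(res$clamped)

  expect_equal(substrate_depletion(c(500, 500), c(500, 500))$mean_depletion, 0)

  neg <- substrate_depletion(c(1100, 1050), c(1000, 1000))
  expect_equal(neg$mean_depletion, 0)
  expect_true(neg$clamped)
  expect_lt(neg$raw_mean, 0)
  expect_error(substrate_depletion(c(1, 2), c(0, 0)), "positive")
})
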