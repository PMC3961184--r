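test_that("relative expression matches the delta-delta-Ct closed forms", {
  ## identical Cts everywhere: fold exactly 1
  fx1 <- fixture_ct_fold(1)
  out1 <- relative_expression(fx1$ct, "tgt", "ref", fx1$groups, "ctl",
                              c(tgt = 1, ref = 1))
  expect_equal(out1$fold, c(1, 1), tolerance = 1e-12)

  ## target two cycles earlier at E = 1: fold 4 (the transgenic
  ## over-expression magnitude the pipeline is designed to detect)
  fx4 <- fixture_ct_fold(4)
  out4 <- relative_expression(fx4$ct, "tgt", "ref", fx4$groups, "ctl",
                              c(tgt = 1, ref = 1))
  expect_equal(out4$fold[out4$group == "exp"], 4, tolerance = 1e-12)

  ## E = 0.9, one cycle earlier: fold 1.9
  q <- tidyr::crossing(sample_id = c("e1", "e2", "c1", "c2"),
                       amplicon_id = c("tgt", "ref"))
  q$quantity <- ifelse(q$amplicon_id == "tgt" & grepl("^e", q$sample_id),
                       1.9, 1)
  ct <- sim_ct_table(q, c(tgt = 0.9, ref = 1), ct_noise_sd = 0)
  grp <- tibble::tibble(sample_id = c("e1", "e2", "c1", "c2"),
                        group = c("exp", "exp", "ctl", "ctl"))
  out <- relative_expression(ct, "tgt", "ref", grp, "ctl",
                             c(tgt = 0.9, ref = 1))
  expect_equal(out$fold[out$group == "exp"], 1.9, tolerance = 1e-12)
  ## and the planted Ct difference really is one cycle
  avg <- dplyr::summarise(
    dplyr::group_by(ct, sample_id, amplicon_id), ct = mean(ct),
    .groups = "drop"
  )
  expect_equal(avg$ct[avg$sample_id == "c1" & avg$amplicon_id == "tgt"] -
                 avg$ct[avg$sample_id == "e1" & avg$amplicon_id == "tgt"],
               1, tolerance = 1e-12)
})

test_that("with E = 1 everywhere the textbook 2^-ddCt form is reproduced", {
  set.seed(5)
  ids <- c(paste0("e", 1:3), paste0("c", 1:3))
  grp <- tibble::tibble(sample_id = ids,
                        group = rep(c("exp", "ctl"), each = 3))
  ct <- tidyr::crossing(sample_id = ids,
                        amplicon_id = c("tgt", "r1", "r2"),
                        replicate = 1:2) |>
    dplyr::mutate(ct = runif(dplyr::n(), 20, 30))
  eff <- c(tgt = 1, r1 = 1, r2 = 1)
  out <- relative_expression(ct, "tgt", c("r1", "r2"), grp, "ctl", eff)
  ## independent 2^-ddCt computation
  avg <- ct |>
    dplyr::group_by(sample_id, amplicon_id) |>
    dplyr::summarise(ct = mean(ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = amplicon_id, values_from = ct)
  dct <- avg$tgt - (avg$r1 + avg$r2) / 2
  rel <- 2^(-dct)
  fold_exp <- mean(rel[grep("^e", avg$sample_id)]) /
    mean(rel[grep("^c", avg$sample_id)])
  expect_equal(out$fold[out$group == "exp"], fold_exp, tolerance = 1e-12)
})

test_that("a constant Ct shift of one sample cancels at equal efficiencies", {
  fx <- fixture_ct_fold(2.5, eff = c(tgt = 1, ref = 1), seed = 6)
  shifted <- fx$ct |>
    dplyr::mutate(ct = ct + ifelse(sample_id == "exp1", 3.7, 0))
  eff <- c(tgt = 1, ref = 1)
  out0 <- relative_expression(fx$ct, "tgt", "ref", fx$groups, "ctl", eff)
  out1 <- relative_expression(shifted, "tgt", "ref", fx$groups, "ctl", eff)
  expect_equal(out0$fold, out1$fold, tolerance = 1e-9)
})

test_that("samples missing a reference amplicon are dropped with a warning", {
  fx <- fixture_ct_fold(2)
  broken <- dplyr::filter(fx$ct, !(sample_id == "exp1" &
                                     amplicon_id == "ref"))
  expect_warning(
    out <- relative_expression(broken, "tgt", "ref", fx$groups, "ctl",
                               c(tgt = 1, ref = 1)),
    "exp1"
  )
  expect_equal(out$n[out$group == "exp"], 2)
  ## every sample dropped: error
  no_ref <- dplyr::filter(fx$ct, amplicon_id != "ref")
  expect_error(
    suppressWarnings(relative_expression(no_ref, "tgt", "ref", fx$groups,
                                         "ctl", c(tgt = 1, ref = 1))),
    "absent|dropped"
  )
})

test_that("over-expression test selects pooled vs Welch via the F-test", {
  ## near-degenerate separation: 1,1,1 vs ~4,4,4 -> tiny p, pooled t
  q <- tidyr::crossing(sample_id = c(paste0("e", 1:3), paste0("c", 1:3)),
                       amplicon_id = c("tgt", "ref"))
  jit <- c(4.00, 4.01, 3.99, 1.00, 1.01, 0.99)
  q$quantity <- ifelse(q$amplicon_id == "tgt",
                       jit[match(q$sample_id,
                                 c("e1", "e2", "e3", "c1", "c2", "c3"))],
                       1)
  ct <- sim_ct_table(q, c(tgt = 1, ref = 1), ct_noise_sd = 0)
  grp <- tibble::tibble(sample_id = c(paste0("e", 1:3), paste0("c", 1:3)),
                        group = rep(c("exp", "ctl"), each = 3))
  res <- overexpression_test(ct, "tgt", "ref", grp, "ctl",
                             c(tgt = 1, ref = 1))
  expect_lt(res$p, 0.001)
  expect_equal(res$test_used, "pooled-t")
  expect_equal(res$fold, 4, tolerance = 0.01)

  ## identical replicate sets: p = 1
  fx <- fixture_ct_fold(1)
  res1 <- overexpression_test(fx$ct, "tgt", "ref", fx$groups, "ctl",
                              c(tgt = 1, ref = 1))
  expect_equal(res1$p, 1)

  ## variance ratio far beyond the F threshold selects Welch
  x <- c(0, 10, -10, 5, -5); y <- c(0, 0.1, -0.1, 0.05, -0.05)
  expect_equal(resistscope:::two_sample_t(x, y)$test_used, "welch-t")
})

test_that("copy-number ratios hit the planted values and the 1.5 boundary", {
  amps <- c("a1", "a2", "a3"); refs <- c("r1", "r2")
  eff <- setNames(rep(1, 5), c(amps, refs))
  build <- function(target_qty) {
    q <- tidyr::crossing(sample_id = c("s1", "cal1", "cal2"),
                         amplicon_id = c(amps, refs))
    q$quantity <- ifelse(q$amplicon_id %in% amps & q$sample_id == "s1",
                         target_qty, 1)
    sim_ct_table(q, eff, ct_noise_sd = 0)
  }
  ## identical to calibrator: ratio 1, no extra copy
  r1 <- copy_number_ratio(build(1), amps, refs, c("cal1", "cal2"), eff)
  expect_equal(r1$ratio, 1, tolerance = 1e-12)
  expect_false(r1$extra_copy)
  ## one cycle earlier at E = 1: ratio 2, extra copy
  r2 <- copy_number_ratio(build(2), amps, refs, c("cal1", "cal2"), eff)
  expect_equal(r2$ratio, 2, tolerance = 1e-12)
  expect_true(r2$extra_copy)
  ## planted 3 vs 2 copies: ratio exactly 1.5 sits below the strict threshold
  r15 <- copy_number_ratio(build(1.5), amps, refs, c("cal1", "cal2"), eff)
  expect_equal(r15$ratio, 1.5, tolerance = 1e-12)
  expect_false(r15$extra_copy)

  expect_error(
    copy_number_ratio(dplyr::filter(build(1), amplicon_id != "a2"),
                      amps, refs, c("cal1", "cal2"), eff),
    "a2"
  )
})

test_that("planted copy numbers are recovered under Ct noise", {
  set.seed(99)
  copies <- sample(2:4, 200, replace = TRUE)
  amps <- c("a1", "a2", "a3"); refs <- c("r1", "r2")
  eff <- setNames(rep(1, 5), c(amps, refs))
  ids <- sprintf("s%03d", seq_along(copies))
  q <- tidyr::crossing(sample_id = c(ids, "cal1", "cal2"),
                       amplicon_id = c(amps, refs))
  cop <- setNames(c(copies, 2, 2), c(ids, "cal1", "cal2"))
  q$quantity <- ifelse(q$amplicon_id %in% amps, cop[q$sample_id] / 2, 1)
  ct <- sim_ct_table(q, eff, replicates = 3, ct_noise_sd = 0.15, seed = 5)
  calls <- copy_number_ratio(ct, amps, refs, c("cal1", "cal2"), eff)
  est <- classify_copy_number(calls$ratio)
  acc <- mean(est == copies[match(calls$sample_id, ids)])
  expect_gte(acc, 0.95)
})

test_that("survivor/dead copy-number contrast behaves at its extremes", {
  expect_equal(copy_number_contrast(c(1, 1, 1), c(1, 1, 1))$p, 1)
  set.seed(8)
  surv <- rnorm(16, 2, 0.1); dead <- rnorm(16, 1, 0.1)
  res <- copy_number_contrast(surv, dead)
  expect_lt(res$p, 1e-10)
  expect_error(copy_number_contrast(1, c(1, 2)), ">= 2")
  ## null calibration over seeds: shared constant plus jitter
  set.seed(9)
  pv <- replicate(400, {
    copy_number_contrast(rnorm(8, 1.5, 0.1), rnorm(8, 1.5, 0.1))$p
  })
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})
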