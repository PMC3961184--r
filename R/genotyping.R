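#' Call G119S genotypes from TaqMan endpoint fluorescence
#'
#' Each well's position in the (VIC, FAM) plane is reduced to an angle
#' `atan2(FAM, VIC)` (degrees from the VIC axis) and a total signal
#' `FAM + VIC`. Cluster reference angles are anchored on the plate's
#' controls: the mean angle of the serine-homozygote (SS) controls, the
#' mean angle of the glycine-homozygote (GG) controls, and a fixed 45
#' degrees for heterozygotes (the 1:1 dye-balance line; the empirical
#' heterozygote cluster is not used as an anchor because gene duplication
#' skews it toward FAM). Every sample is assigned to the nearest reference
#' angle; it is excluded (no-call, `NC`) when its total signal falls below
#' `min_signal_frac` of the mean control signal or its angular distance to
#' the nearest reference exceeds `max_angle_dist` degrees. The caller is
#' scale-invariant: rescaling all fluorescence changes no call.
#'
#' @param records tibble with `sample_id`, `fam_dR`, `vic_dR`,
#'   `control_type` (`none`/`SS`/`GG`/`NTC`) and optionally `phenotype`.
#' @param min_signal_frac no-call floor as a fraction of mean control total
#'   signal (default 0.2).
#' @param max_angle_dist ambiguity guard in degrees (default 15).
#' @return tibble `sample_id`, `call` (`SS`/`GS`/`GG`/`NC`), `angle`,
#'   `total_signal`, `dye_ratio` (FAM/VIC), plus `phenotype` if present.
#' @export
call_genotypes <- function(records, min_signal_frac = 0.2,
                           max_angle_dist = 15) {
  check_columns(records, c("sample_id", "fam_dR", "vic_dR", "control_type"),
                "`records`")
  if (any(records$fam_dR < 0 | records$vic_dR < 0)) {
    abort("fluorescence must be non-negative.")
  }
  ctrl_ss <- records[records$control_type == "SS", ]
  ctrl_gg <- records[records$control_type == "GG", ]
  if (!nrow(ctrl_ss) || !nrow(ctrl_gg)) {
    abort("plate needs at least one SS and one GG control.")
  }
  angle_of <- function(fam, vic) rad2deg(atan2(fam, vic))
  refs <- c(
    SS = mean(angle_of(ctrl_ss$fam_dR, ctrl_ss$vic_dR)),
    GS = 45,
    GG = mean(angle_of(ctrl_gg$fam_dR, ctrl_gg$vic_dR))
  )
  ctrl_signal <- mean(c(ctrl_ss$fam_dR + ctrl_ss$vic_dR,
                        ctrl_gg$fam_dR + ctrl_gg$vic_dR))
  samples <- records[records$control_type == "none", ]
  angle <- angle_of(samples$fam_dR, samples$vic_dR)
  total <- samples$fam_dR + samples$vic_dR
  dist <- abs(outer(angle, refs, `-`))
  nearest <- names(refs)[max.col(-dist)]
  min_dist <- dist[cbind(seq_along(angle), max.col(-dist))]
  call <- ifelse(total < min_signal_frac * ctrl_signal | min_dist > max_angle_dist,
                 "NC", nearest)
  out <- tibble::tibble(
    sample_id = samples$sample_id,
    call = call,
    angle = angle,
    total_signal = total,
    dye_ratio = samples$fam_dR / samples$vic_dR
  )
  if ("phenotype" %in% names(samples)) out$phenotype <- samples$phenotype
  out
}

#' Heterozygote dye-balance contrast between survivors and dead
#'
#' Among wells called heterozygous, a duplicated resistant allele shows up
#' as a FAM:VIC (serine:glycine) dye ratio above the 1:1 heterozygote
#' expectation. This compares the dye ratios of surviving versus dead
#' heterozygotes with a Welch (unequal-variance) t-test on the raw ratios
#' (`log_ratio = TRUE` tests log ratios instead).
#'
#' @param calls output of [call_genotypes()] including `phenotype`.
#' @param log_ratio test on the log scale; default `FALSE`.
#' @return tibble `mean_alive`, `mean_dead`, `t`, `df`, `p`, `n_alive`,
#'   `n_dead`.
#' @export
het_dye_balance_contrast <- function(calls, log_ratio = FALSE) {
  check_columns(calls, c("call", "dye_ratio", "phenotype"), "`calls`")
  gs <- calls[calls$call == "GS", ]
  x <- gs$dye_ratio[gs$phenotype == "alive"]
  y <- gs$dye_ratio[gs$phenotype == "dead"]
  if (length(x) < 2 || length(y) < 2) {
    abort("need >= 2 alive and >= 2 dead heterozygote calls.")
  }
  tx <- if (log_ratio) log(x) else x
  ty <- if (log_ratio) log(y) else y
  if (var(tx) == 0 && var(ty) == 0 && isTRUE(all.equal(mean(tx), mean(ty)))) {
    return(tibble::tibble(mean_alive = mean(x), mean_dead = mean(y),
                          t = 0, df = NA_real_, p = 1,
                          n_alive = length(x), n_dead = length(y)))
  }
  tt <- t.test(tx, ty)
  tibble::tibble(
    mean_alive = mean(x), mean_dead = mean(y),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    n_alive = length(x), n_dead = length(y)
  )
}

#' Allele and heterozygote frequencies with Wilson confidence intervals
#'
#' The resistant-allele (serine) frequency is `(2 n_SS + n_GS) / (2N)` with
#' a Wilson 95% interval over the `2N` allele draws; the heterozygote
#' frequency `n_GS / N` gets a Wilson interval over individuals.
#'
#' @param n_SS,n_GS,n_GG genotype counts.
#' @param conf confidence level.
#' @return one-row tibble with `n`, `freq_S`, `freq_S_lower/upper`,
#'   `het_freq`, `het_lower/upper`.
#' @export
allele_frequency <- function(n_SS, n_GS, n_GG, conf = 0.95) {
  counts <- c(n_SS, n_GS, n_GG)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers.")
  }
  n <- sum(counts)
  if (n == 0) abort("no individuals.")
  s_alleles <- 2 * n_SS + n_GS
  ci_s <- binom_ci(s_alleles, 2 * n, conf)
  ci_h <- binom_ci(n_GS, n, conf)
  tibble::tibble(
    n = n,
    freq_S = ci_s$estimate, freq_S_lower = ci_s$lower,
    freq_S_upper = ci_s$upper,
    het_freq = ci_h$estimate, het_lower = ci_h$lower, het_upper = ci_h$upper
  )
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Expected genotype counts are computed from the observed allele
#' frequencies and compared with the observed counts by
#' `chi2 = sum (O - E)^2 / E` over the three genotype classes (1 df). When
#' only one allele is observed the statistic is 0 by convention.
#'
#' @inheritParams allele_frequency
#' @return one-row tibble `chi2`, `df`, `p`, and expected counts.
#' @export
hwe_test <- function(n_SS, n_GS, n_GG) {
  counts <- c(SS = n_SS, GS = n_GS, GG = n_GG)
  n <- sum(counts)
  if (n == 0) abort("no individuals.")
  p_s <- (2 * n_SS + n_GS) / (2 * n)
  if (p_s == 0 || p_s == 1) {
    return(tibble::tibble(chi2 = 0, df = 1, p = 1,
                          e_SS = n * p_s^2, e_GS = 2 * n * p_s * (1 - p_s),
                          e_GG = n * (1 - p_s)^2))
  }
  expected <- n * c(p_s^2, 2 * p_s * (1 - p_s), (1 - p_s)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  tibble::tibble(chi2 = chi2, df = 1, p = pchisq(chi2, 1, lower.tail = FALSE),
                 e_SS = expected[[1]], e_GS = expected[[2]],
                 e_GG = expected[[3]])
}

as_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("expected a 2x2 table.")
  if (any(tab < 0)) abort("counts must be non-negative.")
  tab
}

#' Genotype-outcome association on a 2x2 table
#'
#' Pearson chi-square (1 df, no continuity correction) plus the odds ratio
#' `ad/bc` with a Woolf log-scale confidence interval. When any cell is
#' zero the Haldane-Anscombe correction (+0.5 to every cell) is applied to
#' the odds ratio and its interval, and flagged.
#'
#' @param tab 2x2 matrix: rows = genotype classes, columns = outcome.
#' @param conf confidence level.
#' @return one-row tibble `or`, `or_lower`, `or_upper`, `chi2`, `p`,
#'   `haldane`.
#' @export
association_test <- function(tab, conf = 0.95) {
  tab <- as_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("a zero margin leaves the association undefined.")
  }
  w <- woolf_or(tab, conf)
  chi2 <- pearson_chi2_2x2(tab)
  tibble::tibble(
    or = w$or, or_lower = w$lower, or_upper = w$upper,
    chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE),
    haldane = w$haldane
  )
}

#' Woolf test of homogeneity of odds ratios across strata
#'
#' Tests whether stratum-specific odds ratios share a common value:
#' each stratum is weighted by the inverse variance of its log odds ratio
#' (`w = 1 / sum(1/cell)`, Haldane-corrected where a cell is zero) and
#' `chi2 = sum w (lnOR - pooled lnOR)^2` on `k - 1` df.
#'
#' @param strata list of 2x2 matrices (>= 2).
#' @return one-row tibble `chi2`, `df`, `p`, `pooled_or`, `n_strata`.
#' @export
homogeneity_test <- function(strata) {
  if (length(strata) < 2) abort("need >= 2 strata.")
  parts <- purrr::map_dfr(strata, function(tab) {
    tab <- as_2x2(tab)
    tab <- haldane_correct(tab)$tab
    tibble::tibble(
      log_or = log((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])),
      weight = 1 / sum(1 / tab)
    )
  })
  pooled <- sum(parts$weight * parts$log_or) / sum(parts$weight)
  chi2 <- sum(parts$weight * (parts$log_or - pooled)^2)
  df <- length(strata) - 1
  tibble::tibble(chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE),
                 pooled_or = exp(pooled), n_strata = length(strata))
}
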