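## average technical replicates on the Ct scale
average_ct <- function(ct) {
  check_columns(ct, c("sample_id", "amplicon_id", "ct"), "`ct`")
  if (any(ct$ct <= 0)) abort("Ct values must be positive.")
  ct |>
    dplyr::group_by(sample_id, amplicon_id) |>
    dplyr::summarise(ct = mean(ct), .groups = "drop")
}

## efficiency-corrected relative quantity; Ct on the exponential model
## quantity proportional to (1+E)^(-Ct)
ct_to_quantity <- function(ct, eff) (1 + eff)^(-ct)

#' Per-sample normalized expression from a Ct table
#'
#' Technical replicates are averaged on the Ct scale, each amplicon's Ct is
#' converted to a relative quantity `(1 + E)^(-Ct)` using its own PCR
#' efficiency, and the target quantity is divided by the geometric mean of
#' the reference-amplicon quantities (two stably-expressed genes in the
#' assay this models). Samples missing a reference amplicon are dropped
#' with a warning.
#'
#' @param ct tibble `sample_id`, `amplicon_id`, `replicate`, `ct`.
#' @param target target amplicon id.
#' @param references character vector of reference amplicon ids (>= 1).
#' @param efficiencies named numeric amplicon -> E, E in (0.5, 1.2].
#' @return tibble `sample_id`, `norm_expr`.
#' @export
normalized_expression <- function(ct, target, references, efficiencies) {
  if (!length(references)) abort("`references` must be non-empty.")
  need <- c(target, references)
  miss_e <- setdiff(need, names(efficiencies))
  if (length(miss_e)) {
    abort(sprintf("missing efficiency for: %s", paste(miss_e, collapse = ", ")))
  }
  if (any(efficiencies[need] <= 0.5 | efficiencies[need] > 1.2)) {
    abort("efficiencies must lie in (0.5, 1.2].")
  }
  avg <- average_ct(ct) |>
    dplyr::filter(amplicon_id %in% need) |>
    dplyr::mutate(qty = ct_to_quantity(ct, unname(efficiencies[amplicon_id])))
  wide <- tidyr::pivot_wider(avg, id_cols = sample_id,
                             names_from = amplicon_id, values_from = qty)
  miss_col <- setdiff(need, names(wide))
  if (length(miss_col)) {
    abort(sprintf("amplicon(s) absent from Ct table: %s",
                  paste(miss_col, collapse = ", ")))
  }
  complete <- complete.cases(wide[, need])
  if (any(!complete)) {
    warn(sprintf("dropping %d sample(s) with missing amplicons: %s",
                 sum(!complete),
                 paste(wide$sample_id[!complete], collapse = ", ")))
    wide <- wide[complete, ]
  }
  if (!nrow(wide)) abort("all samples dropped; no complete amplicon sets.")
  ref_gm <- apply(as.matrix(wide[, references, drop = FALSE]), 1,
                  geometric_mean)
  tibble::tibble(sample_id = wide$sample_id,
                 norm_expr = wide[[target]] / ref_gm)
}

#' Efficiency-corrected delta-delta-Ct relative expression by group
#'
#' Computes per-sample normalized expression (see
#' [normalized_expression()]), then reports each group's mean normalized
#' expression as a fold-change relative to the calibrator group's mean.
#' With all efficiencies equal to 1 this reduces exactly to the textbook
#' `2^-ddCt` quantification.
#'
#' @inheritParams normalized_expression
#' @param groups tibble `sample_id`, `group`.
#' @param calibrator_group group id used as the fold-change denominator
#'   (e.g. a susceptible reference population).
#' @return tibble `group`, `n`, `fold`, plus a `rel_expr` list-column of the
#'   per-sample normalized expressions divided by the calibrator mean.
#' @export
relative_expression <- function(ct, target, references, groups,
                                calibrator_group, efficiencies) {
  check_columns(groups, c("sample_id", "group"), "`groups`")
  ne <- normalized_expression(ct, target, references, efficiencies) |>
    dplyr::inner_join(groups, by = "sample_id")
  if (!calibrator_group %in% ne$group) {
    abort(sprintf("calibrator group '%s' has no usable samples.",
                  calibrator_group))
  }
  cal_mean <- mean(ne$norm_expr[ne$group == calibrator_group])
  ne |>
    dplyr::group_by(group) |>
    dplyr::summarise(
      n = dplyr::n(),
      fold = mean(norm_expr) / cal_mean,
      rel_expr = list(norm_expr / cal_mean),
      .groups = "drop"
    )
}

## Welch-or-pooled two-sample t on possibly degenerate data
two_sample_t <- function(x, y, var_alpha = 0.05) {
  if (length(x) < 2 || length(y) < 2) abort("need >= 2 replicates per group.")
  if (var(x) == 0 && var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(t = 0, p = 1, test_used = "degenerate-equal"))
    }
    return(list(t = Inf * sign(mean(x) - mean(y)), p = 0,
                test_used = "degenerate-separated"))
  }
  pooled <- var.test(x, y)$p.value >= var_alpha
  tt <- t.test(x, y, var.equal = pooled)
  list(t = unname(tt$statistic), p = tt$p.value,
       test_used = if (pooled) "pooled-t" else "welch-t")
}

#' Test group over-expression against the calibrator group
#'
#' A two-sided F-test of variance homogeneity at `var_alpha = 0.05` selects
#' between the pooled and the Welch (unequal-variance) two-sample t-test,
#' applied to log2 normalized expression of the test group versus the
#' calibrator group.
#'
#' @param ct,target,references,groups,calibrator_group,efficiencies as in
#'   [relative_expression()].
#' @param test_groups groups to test (default: all except the calibrator).
#' @param var_alpha significance level of the variance F-test.
#' @return tibble `group`, `fold`, `t`, `p`, `test_used`.
#' @export
overexpression_test <- function(ct, target, references, groups,
                                calibrator_group, efficiencies,
                                test_groups = NULL, var_alpha = 0.05) {
  ne <- normalized_expression(ct, target, references, efficiencies) |>
    dplyr::inner_join(groups, by = "sample_id")
  cal <- ne$norm_expr[ne$group == calibrator_group]
  if (length(cal) < 2) abort("calibrator group needs >= 2 replicates.")
  test_groups <- test_groups %||% setdiff(unique(ne$group), calibrator_group)
  purrr::map_dfr(test_groups, function(g) {
    x <- ne$norm_expr[ne$group == g]
    res <- two_sample_t(log2(x), log2(cal), var_alpha)
    tibble::tibble(group = g, fold = mean(x) / mean(cal),
                   t = res$t, p = res$p, test_used = res$test_used)
  })
}

#' Multi-amplicon qPCR copy-number ratio with extra-copy classification
#'
#' Estimates each sample's gene dose relative to a single-copy calibrator
#' strain from several target-gene amplicons (three exon fragments in the
#' assay this models) normalized against several single-copy reference
#' genes. For each (target amplicon, reference gene) pair the
#' delta-delta-Ct contribution is efficiency-corrected per amplicon:
#' `(1+E_t)^(Ct_t(cal) - Ct_t(s)) * (1+E_r)^(Ct_r(s) - Ct_r(cal))`,
#' which reduces to the single-base form `(1+E)^(dCt_s - dCt_cal)` when the
#' two efficiencies are equal. Contributions are then averaged across all
#' pairs, by default on the ratio scale (`average = "ddct"` averages on the
#' log/ddCt scale instead, i.e. a geometric mean). A sample is classified
#' as carrying an extra copy when its ratio strictly exceeds `threshold`
#' (default 1.5; a ratio of exactly 1.5 — e.g. a noise-free 3 vs 2 copies —
#' is at, not in excess of, the threshold and is classified below it).
#'
#' @param ct tibble `sample_id`, `amplicon_id`, `replicate`, `ct` covering
#'   test samples and calibrator pools.
#' @param target_amplicons character vector of target-gene amplicon ids.
#' @param reference_amplicons character vector of single-copy reference ids.
#' @param calibrator_samples sample ids of the calibrator pools.
#' @param efficiencies named numeric amplicon -> E; `scale = "two"` ignores
#'   them and uses base 2 throughout.
#' @param scale `"efficiency"` (default) or `"two"`.
#' @param average `"ratio"` (default) or `"ddct"`.
#' @param threshold extra-copy ratio threshold, default 1.5.
#' @return tibble `sample_id`, `ratio`, `extra_copy`, plus a `per_pair`
#'   list-column of the per-(amplicon x reference) contributions.
#' @export
copy_number_ratio <- function(ct, target_amplicons, reference_amplicons,
                              calibrator_samples, efficiencies = NULL,
                              scale = c("efficiency", "two"),
                              average = c("ratio", "ddct"),
                              threshold = 1.5) {
  scale <- arg_match(scale)
  average <- arg_match(average)
  need <- c(target_amplicons, reference_amplicons)
  if (scale == "two") {
    efficiencies <- setNames(rep(1, length(need)), need)
  }
  miss_e <- setdiff(need, names(efficiencies))
  if (length(miss_e)) {
    abort(sprintf("missing efficiency for: %s", paste(miss_e, collapse = ", ")))
  }
  avg <- average_ct(ct) |> dplyr::filter(amplicon_id %in% need)
  wide <- tidyr::pivot_wider(avg, id_cols = sample_id,
                             names_from = amplicon_id, values_from = ct)
  miss_col <- setdiff(need, names(wide))
  if (length(miss_col)) {
    abort(sprintf("amplicon assay(s) absent: %s",
                  paste(miss_col, collapse = ", ")))
  }
  miss_cal <- setdiff(calibrator_samples, wide$sample_id)
  if (length(miss_cal)) {
    abort(sprintf("calibrator pool(s) absent: %s",
                  paste(miss_cal, collapse = ", ")))
  }
  incomplete <- !complete.cases(wide[, need])
  if (any(incomplete)) {
    abort(sprintf("sample(s) missing amplicons: %s",
                  paste(wide$sample_id[incomplete], collapse = ", ")))
  }
  cal <- wide[wide$sample_id %in% calibrator_samples, ]
  cal_mean <- colMeans(as.matrix(cal[, need]))
  test <- wide[!wide$sample_id %in% calibrator_samples, ]
  pairs <- tidyr::crossing(tgt = target_amplicons, ref = reference_amplicons)
  per_sample <- purrr::map_dfr(seq_len(nrow(test)), function(i) {
    contrib <- purrr::pmap_dbl(pairs, function(tgt, ref) {
      (1 + efficiencies[[tgt]])^(cal_mean[[tgt]] - test[[tgt]][i]) *
        (1 + efficiencies[[ref]])^(test[[ref]][i] - cal_mean[[ref]])
    })
    ratio <- if (average == "ratio") mean(contrib) else geometric_mean(contrib)
    tibble::tibble(
      sample_id = test$sample_id[i], ratio = ratio,
      ## strict ">" with a relative guard so a planted boundary ratio
      ## (e.g. exactly 3 vs 2 copies) stays below threshold despite
      ## floating-point round-off
      extra_copy = ratio > threshold * (1 + 1e-9),
      per_pair = list(setNames(contrib, paste(pairs$tgt, pairs$ref, sep = ".")))
    )
  })
  per_sample
}

#' Integer copy-number classification from a qPCR ratio
#'
#' Converts a copy-number ratio against a calibrator of known copy number
#' into the nearest integer copy estimate: `round(ratio * calibrator_copies)`
#' (floored at 0). Against the usual diploid single-copy calibrator (2
#' copies) this places the class boundaries midway between consecutive
#' integer copy numbers (ratio 1.25 between 2 and 3 copies, 1.75 between 3
#' and 4).
#'
#' @param ratio numeric copy-number ratios from [copy_number_ratio()].
#' @param calibrator_copies copies carried by the calibrator (default 2).
#' @return integer vector of copy estimates.
#' @export
classify_copy_number <- function(ratio, calibrator_copies = 2) {
  if (any(ratio <= 0)) abort("ratios must be positive.")
  pmax(as.integer(round(ratio * calibrator_copies)), 0L)
}

#' Compare copy-number ratios between phenotype groups
#'
#' Welch (unequal-variance) two-sample t-test on copy-number ratios of
#' bioassay survivors versus dead individuals.
#'
#' @param survivors,dead numeric vectors of copy-number ratios (>= 2 each).
#' @return tibble `mean_survivors`, `mean_dead`, `t`, `df`, `p`.
#' @export
copy_number_contrast <- function(survivors, dead) {
  if (length(survivors) < 2 || length(dead) < 2) {
    abort("need >= 2 ratios per group.")
  }
  if (var(survivors) == 0 && var(dead) == 0) {
    eq <- isTRUE(all.equal(mean(survivors), mean(dead)))
    return(tibble::tibble(
      mean_survivors = mean(survivors), mean_dead = mean(dead),
      t = if (eq) 0 else Inf * sign(mean(survivors) - mean(dead)),
      df = NA_real_, p = if (eq) 1 else 0
    ))
  }
  tt <- t.test(survivors, dead)
  tibble::tibble(
    mean_survivors = mean(survivors), mean_dead = mean(dead),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
  )
}
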