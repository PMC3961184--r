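#' Normalize arrays on the M-value scale
#'
#' `"median"` subtracts each array's median M-value, removing global
#' array-level intensity imbalance (the array-effect term of the simulator);
#' `"none"` returns the input unchanged. No intensity-dependent (loess)
#' normalization is attempted.
#'
#' @param mvalues tibble with `probe_id`, `array_id`, `M`.
#' @param method `"median"` or `"none"`.
#' @return tibble of the same shape.
#' @export
normalize_arrays <- function(mvalues, method = c("median", "none")) {
  method <- arg_match(method)
  check_columns(mvalues, c("probe_id", "array_id", "M"), "`mvalues`")
  if (nrow(mvalues) == 0) abort("empty M-value table.")
  if (method == "none") return(tibble::as_tibble(mvalues))
  mvalues |>
    dplyr::group_by(array_id) |>
    dplyr::mutate(M = M - median(M, na.rm = TRUE)) |>
    dplyr::ungroup()
}

## group connectivity of a hybridization design (arrays are edges between
## the groups of their two samples); union-find
group_components <- function(scheme) {
  grp <- setNames(scheme$samples$group, scheme$samples$sample_id)
  groups <- unique(scheme$samples$group)
  parent <- setNames(seq_along(groups), groups)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  for (k in seq_len(nrow(scheme$arrays))) {
    a <- find(match(grp[[scheme$arrays$cy3_sample[[k]]]], groups))
    b <- find(match(grp[[scheme$arrays$cy5_sample[[k]]]], groups))
    if (a != b) parent[[a]] <- b
  }
  comp <- vapply(seq_along(groups), find, integer(1))
  split(groups, comp)
}

#' Fit per-probe group contrasts from a hybridization design
#'
#' Models every array measurement of a probe as the difference of true
#' group offsets of its two channels,
#' `M = offset[cy5 group] - offset[cy3 group] + error`, and solves the
#' resulting least-squares system per probe (one group's offset fixed at 0
#' as baseline; contrasts do not depend on that choice). Each requested
#' resistant-vs-susceptible comparison is reported as
#' `log2FC = offset[res] - offset[sus]` with its standard error and residual
#' degrees of freedom. Probes with missing arrays are fit on the equations
#' available; when the residual df is 0 the estimate is still returned but
#' `se`/`t` are `NA` (flagged, not dropped).
#'
#' @param mvalues tibble `probe_id`, `array_id`, `M`.
#' @param scheme the `hyb_scheme` the arrays were hybridized under.
#' @param comparisons comparisons to report: either a character vector
#'   `"res_group:sus_group"` or a tibble with columns `res_group`,
#'   `sus_group`.
#' @return tibble with one row per probe x comparison: `probe_id`,
#'   `comparison`, `res_group`, `sus_group`, `log2FC`, `se`, `t`, `df`,
#'   plus `s2` (residual variance) and `leverage` (unscaled contrast
#'   variance) consumed by [moderate_contrasts()].
#' @export
fit_contrasts <- function(mvalues, scheme, comparisons) {
  check_columns(mvalues, c("probe_id", "array_id", "M"), "`mvalues`")
  stopifnot(inherits(scheme, "hyb_scheme"))
  cmp <- parse_comparisons(comparisons)
  groups <- unique(scheme$samples$group)
  missing_groups <- setdiff(c(cmp$res_group, cmp$sus_group), groups)
  if (length(missing_groups)) {
    abort(sprintf("comparison group(s) not in scheme: %s",
                  paste(missing_groups, collapse = ", ")))
  }
  comps <- group_components(scheme)
  if (length(comps) > 1) {
    abort(sprintf(
      "design is disconnected; group components: %s",
      paste(vapply(comps, paste, "", collapse = "+"), collapse = " | ")
    ))
  }
  if (anyDuplicated(mvalues[, c("probe_id", "array_id")])) {
    abort("duplicate (probe_id, array_id) measurements.")
  }
  if (any(!is.finite(mvalues$M))) abort("non-finite M values.")

  grp <- setNames(scheme$samples$group, scheme$samples$sample_id)
  arr <- scheme$arrays
  keep_arrays <- intersect(arr$array_id, unique(mvalues$array_id))
  arr <- arr[arr$array_id %in% keep_arrays, ]
  if (nrow(arr) == 0) abort("no arrays in common between scheme and data.")
  baseline <- groups[[1]]
  coef_groups <- setdiff(groups, baseline)
  X <- matrix(0, nrow(arr), length(coef_groups),
              dimnames = list(arr$array_id, coef_groups))
  g5 <- grp[arr$cy5_sample]; g3 <- grp[arr$cy3_sample]
  for (j in seq_along(coef_groups)) {
    X[, j] <- (g5 == coef_groups[[j]]) - (g3 == coef_groups[[j]])
  }
  ## contrast matrix: one column per comparison on the coef scale
  L <- matrix(0, length(coef_groups), nrow(cmp),
              dimnames = list(coef_groups, cmp$comparison))
  for (k in seq_len(nrow(cmp))) {
    if (cmp$res_group[[k]] != baseline) L[cmp$res_group[[k]], k] <- 1
    if (cmp$sus_group[[k]] != baseline) L[cmp$sus_group[[k]], k] <- -1
  }

  wide <- tidyr::pivot_wider(mvalues, id_cols = probe_id,
                             names_from = array_id, values_from = M)
  probe_ids <- wide$probe_id
  Y <- as.matrix(wide[, arr$array_id, drop = FALSE])  # probes x arrays

  fit_one_design <- function(Xs, Ys) {
    ## Ys: arrays x probes (complete on this design)
    qrX <- qr(Xs)
    if (qrX$rank < ncol(Xs)) {
      abort("rank-deficient design after removing missing arrays.")
    }
    beta <- qr.coef(qrX, Ys)                       # p x probes
    res <- Ys - Xs %*% beta
    dfree <- nrow(Xs) - qrX$rank
    s2 <- if (dfree > 0) colSums(res^2) / dfree else rep(NA_real_, ncol(Ys))
    xtx_inv <- chol2inv(qr.R(qrX))
    lev <- unname(diag(t(L) %*% xtx_inv %*% L))    # per comparison
    est <- t(L) %*% beta                           # comparisons x probes
    list(est = est, s2 = s2, df = dfree, leverage = lev)
  }

  complete <- !apply(Y, 1, anyNA)
  out <- vector("list", 2)
  if (any(complete)) {
    f <- fit_one_design(X, t(Y[complete, , drop = FALSE]))
    out[[1]] <- tibble::tibble(
      probe_id = rep(probe_ids[complete], each = nrow(cmp)),
      comparison = rep(cmp$comparison, sum(complete)),
      log2FC = as.vector(f$est),
      s2 = rep(f$s2, each = nrow(cmp)),
      df = f$df,
      leverage = rep(f$leverage, sum(complete))
    )
  }
  if (any(!complete)) {
    ## probes with missing arrays: fit each on its available equations
    out[[2]] <- purrr::map_dfr(which(!complete), function(i) {
      ok <- !is.na(Y[i, ])
      Xs <- X[ok, , drop = FALSE]
      if (qr(Xs)$rank < ncol(Xs)) {
        return(tibble::tibble(
          probe_id = probe_ids[[i]], comparison = cmp$comparison,
          log2FC = NA_real_, s2 = NA_real_, df = 0L, leverage = NA_real_
        ))
      }
      f <- fit_one_design(Xs, cbind(Y[i, ok]))
      tibble::tibble(
        probe_id = probe_ids[[i]], comparison = cmp$comparison,
        log2FC = as.vector(f$est), s2 = f$s2[[1]], df = f$df,
        leverage = f$leverage
      )
    })
  }
  res <- dplyr::bind_rows(out) |>
    dplyr::left_join(cmp, by = "comparison") |>
    dplyr::mutate(
      se = ifelse(df > 0, sqrt(s2 * leverage), NA_real_),
      t = log2FC / se
    ) |>
    dplyr::select(probe_id, comparison, res_group, sus_group,
                  log2FC, se, t, df, s2, leverage)
  res
}

parse_comparisons <- function(comparisons) {
  if (is.character(comparisons)) {
    parts <- strsplit(comparisons, ":", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      abort('character comparisons must be "res_group:sus_group".')
    }
    comparisons <- tibble::tibble(
      res_group = vapply(parts, `[[`, "", 1),
      sus_group = vapply(parts, `[[`, "", 2)
    )
  }
  check_columns(comparisons, c("res_group", "sus_group"), "`comparisons`")
  dplyr::mutate(tibble::as_tibble(comparisons),
                comparison = paste(res_group, sus_group, sep = ":")) |>
    dplyr::select(comparison, res_group, sus_group)
}

## method-of-moments fit of the scaled-F model s2 ~ s0^2 * F(d, d0).
## Returns the prior df d0 and prior variance s0^2.
squeeze_mom <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (!length(s2)) abort("no positive residual variances to moderate.")
  m1 <- mean(s2)
  r <- var(s2) / m1^2
  if (!is.finite(r) || r * d <= 2) {
    return(list(d0 = Inf, s0_2 = m1))
  }
  d0 <- (4 * r * d + 2 * d - 4) / (r * d - 2)
  list(d0 = d0, s0_2 = m1 * (d0 - 2) / d0)
}

#' Moderated (or plain) per-contrast tests
#'
#' `"plain"` computes the ordinary t-test per contrast from the probe's own
#' residual variance. `"eb"` (default) shrinks each probe's residual
#' variance toward a common prior by method-of-moments empirical Bayes:
#' assuming `s2 ~ s0^2 F(d, d0)` across probes, the posterior variance is
#' `(d0 s0^2 + d s2) / (d0 + d)` and the moderated t has `d + d0` degrees of
#' freedom. In the `d0 -> Inf` limit every posterior variance equals `s0^2`.
#' P-values are two-sided; probes with residual df 0 keep `NA` p.
#'
#' @param contrasts output of [fit_contrasts()].
#' @param moderation `"eb"` or `"plain"`.
#' @return the input tibble with `se`, `t` updated (under `"eb"`) and
#'   columns `p` and `df_total` added.
#' @export
moderate_contrasts <- function(contrasts, moderation = c("eb", "plain")) {
  moderation <- arg_match(moderation)
  check_columns(contrasts, c("probe_id", "comparison", "log2FC", "s2", "df",
                             "leverage"), "`contrasts`")
  if (all(contrasts$df == 0, na.rm = TRUE)) {
    abort("all residual dfs are zero; no variance to test against.")
  }
  if (moderation == "plain") {
    return(dplyr::mutate(
      contrasts,
      se = ifelse(df > 0, sqrt(s2 * leverage), NA_real_),
      t = log2FC / se,
      df_total = as.numeric(df),
      p = ifelse(df > 0, 2 * pt(-abs(t), df), NA_real_)
    ))
  }
  per_probe <- dplyr::distinct(contrasts, probe_id, s2, df)
  d <- mean(per_probe$df[per_probe$df > 0])
  prior <- squeeze_mom(per_probe$s2[per_probe$df > 0], d)
  dplyr::mutate(
    contrasts,
    s2_post = ifelse(
      is.finite(prior$d0),
      (prior$d0 * prior$s0_2 + df * s2) / (prior$d0 + df),
      prior$s0_2
    ),
    se = sqrt(s2_post * leverage),
    t = log2FC / se,
    df_total = df + prior$d0,
    p = 2 * pt(-abs(t), df_total)
  ) |>
    dplyr::select(-s2_post)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted values, monotone-enforced and order-preserving with
#' the input (a thin, validated wrapper over `stats::p.adjust`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @examples
#' bh_qvalues(c(0.001, 0.01, 0.02, 0.8))
#' @export
bh_qvalues <- function(p) {
  if (any(is.na(p))) abort("p-values must not be NA/NaN.")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Add per-comparison q-values and direction to a contrast table
#'
#' Applies Benjamini-Hochberg correction within each comparison (each
#' resistant-vs-susceptible test is its own family, as when each pairwise
#' comparison is thresholded at q < 0.05) and records the direction of
#' change.
#'
#' @param contrasts tibble with `comparison` and `p` columns (see
#'   [moderate_contrasts()]); rows with `NA` p are left `NA` in `q`.
#' @return the input with `q` and `direction` (sign of `log2FC`) added.
#' @export
add_fdr <- function(contrasts, by = "comparison") {
  check_columns(contrasts, c("p", "log2FC", by), "`contrasts`")
  contrasts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(q = {
      ok <- !is.na(p)
      out <- rep(NA_real_, dplyr::n())
      if (any(ok)) out[ok] <- bh_qvalues(p[ok])
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(direction = sign(log2FC))
}
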