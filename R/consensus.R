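#' Define a consensus comparison plan
#'
#' A plan lists the resistant-vs-susceptible comparisons an experiment
#' contributes, the q-value threshold, and (for the selected-line design)
#' the pairs of comparisons that share a susceptible partner: one involving
#' the insecticide-selected resistant group and one the unexposed resistant
#' group. Those pairs drive the escalation criterion, which demands a more
#' extreme fold-change in the selected comparison.
#'
#' @param comparisons character `"res:sus"` vector or tibble with
#'   `res_group`, `sus_group`.
#' @param pairs optional tibble with columns `selected` and `unexposed`,
#'   each a comparison id present in `comparisons`; the two members of a
#'   pair must share their susceptible group.
#' @param alpha q-value threshold in (0, 1); default 0.05.
#' @return a `comparison_plan` object.
#' @export
comparison_plan <- function(comparisons, pairs = NULL, alpha = 0.05) {
  cmp <- parse_comparisons(comparisons)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (!is.null(pairs)) {
    check_columns(pairs, c("selected", "unexposed"), "`pairs`")
    pairs <- tibble::as_tibble(pairs)
    unknown <- setdiff(c(pairs$selected, pairs$unexposed), cmp$comparison)
    if (length(unknown)) {
      abort(sprintf("pair references unknown comparison(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    sus_of <- setNames(cmp$sus_group, cmp$comparison)
    if (any(sus_of[pairs$selected] != sus_of[pairs$unexposed])) {
      abort("paired comparisons must share their susceptible group.")
    }
  } else {
    pairs <- tibble::tibble(selected = character(), unexposed = character())
  }
  structure(list(comparisons = cmp, pairs = pairs, alpha = alpha),
            class = "comparison_plan")
}

#' @export
print.comparison_plan <- function(x, ...) {
  cat(sprintf("<comparison_plan> %d comparisons, %d escalation pairs, alpha = %g\n",
              nrow(x$comparisons), nrow(x$pairs), x$alpha))
  invisible(x)
}

#' Evaluate per-probe consensus significance criteria
#'
#' Applies the conjunctive significance rules to each probe:
#' \describe{
#'   \item{direction}{every plan comparison shows the same (non-zero) sign
#'     of log2 fold-change — over- and under-expression are treated
#'     symmetrically;}
#'   \item{q}{every plan comparison has `q < alpha` (strict; boundary ties
#'     fail);}
#'   \item{escalation}{(only when the plan has selected/unexposed pairs)
#'     within every pair sharing a susceptible partner the signs agree and
#'     the selected comparison's `|log2FC|` strictly exceeds the unexposed
#'     one's.}
#' }
#' A probe missing any plan comparison, or with an `NA` q in one, is flagged
#' `unevaluable` rather than failed.
#'
#' @param contrasts tibble from [add_fdr()] with `probe_id`, `comparison`,
#'   `log2FC`, `q`.
#' @param plan a [comparison_plan()].
#' @return tibble with one row per probe: criterion flags, `significant`
#'   (AND of applicable criteria), `unevaluable`, and `mean_log2FC` over the
#'   plan comparisons (retained evidence for gene summaries).
#' @export
evaluate_probes <- function(contrasts, plan) {
  stopifnot(inherits(plan, "comparison_plan"))
  check_columns(contrasts, c("probe_id", "comparison", "log2FC", "q"),
                "`contrasts`")
  cc <- dplyr::filter(contrasts, comparison %in% plan$comparisons$comparison)
  n_needed <- nrow(plan$comparisons)
  per_probe <- cc |>
    dplyr::group_by(probe_id) |>
    dplyr::summarise(
      n_present = dplyr::n_distinct(comparison),
      any_na = any(is.na(q) | is.na(log2FC)),
      crit_direction = !any_na &&
        (all(log2FC > 0) || all(log2FC < 0)),
      crit_q = !any_na && all(q < plan$alpha),
      mean_log2FC = mean(log2FC),
      .groups = "drop"
    ) |>
    dplyr::mutate(unevaluable = n_present < n_needed | any_na)

  if (nrow(plan$pairs)) {
    fc_wide <- cc |>
      dplyr::select(probe_id, comparison, log2FC) |>
      tidyr::pivot_wider(names_from = comparison, values_from = log2FC)
    na_col <- rep(NA_real_, nrow(fc_wide))
    esc <- purrr::pmap(plan$pairs, function(selected, unexposed) {
      s <- fc_wide[[selected]] %||% na_col
      u <- fc_wide[[unexposed]] %||% na_col
      (sign(s) == sign(u)) & (abs(s) > abs(u))
    })
    esc_all <- Reduce(`&`, esc)
    per_probe <- dplyr::left_join(
      per_probe,
      tibble::tibble(probe_id = fc_wide$probe_id,
                     crit_escalation = esc_all),
      by = "probe_id"
    )
  } else {
    per_probe$crit_escalation <- NA
  }
  per_probe |>
    dplyr::mutate(
      crit_escalation = ifelse(unevaluable, NA, crit_escalation),
      crit_direction = ifelse(unevaluable, NA, crit_direction),
      crit_q = ifelse(unevaluable, NA, crit_q),
      significant = !unevaluable & crit_direction & crit_q &
        (if (nrow(plan$pairs)) crit_escalation else TRUE),
      significant = ifelse(unevaluable, FALSE, significant)
    ) |>
    dplyr::select(probe_id, crit_direction, crit_q, crit_escalation,
                  significant, unevaluable, mean_log2FC)
}

#' @rdname evaluate_probes
#' @details `evaluate_exp1()` requires a plan with escalation pairs (the
#'   selected-line design); `evaluate_exp2()` requires one without (the
#'   loop design applies only the direction and q criteria).
#' @export
evaluate_exp1 <- function(contrasts, plan) {
  if (!nrow(plan$pairs)) {
    abort("the selected-line design needs escalation pairs in the plan.")
  }
  evaluate_probes(contrasts, plan)
}

#' @rdname evaluate_probes
#' @export
evaluate_exp2 <- function(contrasts, plan) {
  if (nrow(plan$pairs)) {
    abort("the loop design plan should not carry escalation pairs.")
  }
  evaluate_probes(contrasts, plan)
}

#' Combine experiments and aggregate probes to genes
#'
#' A probe is overall-significant only if significant in both experiments;
#' probes evaluated in one experiment only are reported with status
#' `"untested"` and excluded from overall significance. Genes are then
#' summarized with their significant/total probe counts and a
#' representative log2 fold-change (median over significant probes of the
#' first experiment's mean contrast).
#'
#' @param v1,v2 probe verdict tibbles from [evaluate_probes()].
#' @param probe_gene_map tibble `probe_id`, `gene_id` covering all probes.
#' @return list with `probes` (probe_id, status, overall_significant) and
#'   `genes` (gene_id, n_probes_significant, n_probes_total, `label`
#'   `"sig/total"`, median_log2FC) sorted by gene_id.
#' @export
combine_experiments <- function(v1, v2, probe_gene_map) {
  check_columns(probe_gene_map, c("probe_id", "gene_id"), "`probe_gene_map`")
  all_probes <- union(v1$probe_id, v2$probe_id)
  unmapped <- setdiff(all_probes, probe_gene_map$probe_id)
  if (length(unmapped)) {
    abort(sprintf("probe(s) missing from gene map: %s",
                  paste(head(unmapped, 5), collapse = ", ")))
  }
  probes <- tibble::tibble(probe_id = all_probes) |>
    dplyr::left_join(dplyr::select(v1, probe_id, sig1 = significant,
                                   mean_log2FC), by = "probe_id") |>
    dplyr::left_join(dplyr::select(v2, probe_id, sig2 = significant),
                     by = "probe_id") |>
    dplyr::mutate(
      status = dplyr::case_when(
        is.na(sig1) | is.na(sig2) ~ "untested",
        TRUE ~ "tested"
      ),
      overall_significant = !is.na(sig1) & !is.na(sig2) & sig1 & sig2
    )
  genes <- probes |>
    dplyr::left_join(probe_gene_map, by = "probe_id") |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(
      n_probes_significant = sum(overall_significant),
      n_probes_total = dplyr::n(),
      median_log2FC = if (any(overall_significant)) {
        median(mean_log2FC[overall_significant])
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(label = paste0(n_probes_significant, "/", n_probes_total)) |>
    dplyr::arrange(gene_id)
  list(probes = probes, genes = genes)
}
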