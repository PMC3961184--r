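## resolve a config entry that may be a path or an in-memory data frame
resolve_table <- function(x, schema_id) {
  if (is.null(x)) return(NULL)
  load_and_validate(x, schema_id)
}

resolve_scheme <- function(cfg) {
  hyb_scheme(resolve_table(cfg$arrays, "scheme_arrays"),
             resolve_table(cfg$samples, "samples"))
}

resolve_efficiencies <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  tab <- resolve_table(x, "efficiencies")
  setNames(tab$efficiency, tab$amplicon_id)
}

#' Run the full resistance-attribution pipeline
#'
#' Executes, in order, every stage the configuration provides inputs for:
#' differential expression and the cross-experiment consensus filter, qPCR
#' relative expression (with a check of the qualitative hypothesis that
#' fold-changes rank with the groups' resistance level), qPCR copy number
#' and its survivor/dead contrast, TaqMan genotyping with population and
#' association statistics, bioassay synergism, dose-response LC50 fits and
#' substrate depletion. Any stage failure halts with a stage-tagged error;
#' outputs of completed stages are retained in the partial report.
#'
#' @param config a named list (or path to a YAML file with the same
#'   structure). Recognised entries, all optional, each a list:
#'   \describe{
#'   \item{expression}{`exp1`/`exp2`, each with `mvalues`, `arrays`,
#'     `samples`, `comparisons` (character `"res:sus"`), optional `pairs`
#'     (data frame `selected`, `unexposed`); plus `probe2gene` and
#'     optional `alpha`, `normalize`, `moderation`.}
#'   \item{qpcr_expression}{`ct`, `efficiencies`, `groups`, `targets`
#'     (character), `references`, `calibrator_group`, optional
#'     `resistance_order` (groups from most to least resistant).}
#'   \item{copy_number}{`ct`, `efficiencies`, `target_amplicons`,
#'     `reference_amplicons`, `calibrator_samples`, optional `phenotypes`
#'     (data frame `sample_id`, `phenotype`).}
#'   \item{genotyping}{`taqman` (plate table).}
#'   \item{bioassay}{`bioassay` (replicate table).}
#'   \item{dose_response}{`dose` (observation table), optional
#'     `diagnostic_dose` (default 0.1) and `control_line`.}
#'   \item{depletion}{`hplc` (peak-area table).}
#'   }
#'   Tables may be file paths (TSV) or data frames. A `seed` entry seeds
#'   any stochastic step.
#' @return a `resist_report`: list of per-stage outputs plus a provenance
#'   block (config hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }

  if (!is.null(config$expression)) {
    report$expression <- stage("expression", run_expression_stage(config$expression))
  }
  if (!is.null(config$qpcr_expression)) {
    report$qpcr_expression <- stage("qpcr_expression",
                                    run_qpcr_stage(config$qpcr_expression))
  }
  if (!is.null(config$copy_number)) {
    report$copy_number <- stage("copy_number",
                                run_copy_number_stage(config$copy_number))
  }
  if (!is.null(config$genotyping)) {
    report$genotyping <- stage("genotyping",
                               run_genotyping_stage(config$genotyping))
  }
  if (!is.null(config$bioassay)) {
    report$bioassay <- stage("bioassay", {
      reps <- resolve_table(config$bioassay$bioassay, "bioassay")
      list(mortality = mortality_summary(reps, insecticide, season, pbo),
           synergism = synergism_test(reps))
    })
  }
  if (!is.null(config$dose_response)) {
    report$dose_response <- stage("dose_response",
                                  run_dose_stage(config$dose_response))
  }
  if (!is.null(config$depletion)) {
    report$depletion <- stage("depletion", {
      hplc <- resolve_table(config$depletion$hplc, "hplc")
      hplc |>
        dplyr::group_by(condition) |>
        dplyr::group_modify(function(d, key) {
          substrate_depletion(d$peak_area[d$nadph], d$peak_area[!d$nadph])
        }) |>
        dplyr::ungroup()
    })
  }
  if (!length(report)) abort("config provides no stage inputs.")
  report$provenance <- list(
    package = "resistscope",
    version = as.character(utils::packageVersion("resistscope")),
    config_hash = hash(config),
    seed = config$seed %||% NA,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(report, class = "resist_report")
}

run_expression_stage <- function(cfg) {
  eval_one <- function(ecfg) {
    scheme <- resolve_scheme(ecfg)
    mv <- resolve_table(ecfg$mvalues, "mvalues")
    mv <- normalize_arrays(mv, ecfg$normalize %||% "median")
    contrasts <- fit_contrasts(mv, scheme, ecfg$comparisons) |>
      moderate_contrasts(ecfg$moderation %||% "eb") |>
      add_fdr()
    plan <- comparison_plan(ecfg$comparisons, pairs = ecfg$pairs,
                            alpha = ecfg$alpha %||% 0.05)
    list(contrasts = contrasts, verdicts = evaluate_probes(contrasts, plan))
  }
  out <- list()
  if (!is.null(cfg$exp1)) out$exp1 <- eval_one(cfg$exp1)
  if (!is.null(cfg$exp2)) out$exp2 <- eval_one(cfg$exp2)
  if (!is.null(out$exp1) && !is.null(out$exp2)) {
    map <- resolve_table(cfg$probe2gene, "probe2gene")
    out$consensus <- combine_experiments(out$exp1$verdicts,
                                         out$exp2$verdicts, map)
  }
  out
}

run_qpcr_stage <- function(cfg) {
  ct <- resolve_table(cfg$ct, "ct")
  groups <- resolve_table(cfg$groups, "samples")
  eff <- resolve_efficiencies(cfg$efficiencies)
  folds <- purrr::map_dfr(cfg$targets, function(g) {
    dplyr::mutate(
      relative_expression(ct, g, cfg$references, groups,
                          cfg$calibrator_group, eff),
      gene = g, .before = 1
    )
  })
  tests <- purrr::map_dfr(cfg$targets, function(g) {
    dplyr::mutate(
      overexpression_test(ct, g, cfg$references, groups,
                          cfg$calibrator_group, eff),
      gene = g, .before = 1
    )
  })
  out <- list(folds = dplyr::select(folds, -rel_expr), tests = tests)
  if (!is.null(cfg$resistance_order)) {
    ## qualitative hypothesis: fold-changes rank with resistance level
    out$rank_order <- folds |>
      dplyr::group_by(gene) |>
      dplyr::summarise(rank_order_met = {
        f <- setNames(fold, group)[cfg$resistance_order]
        !anyNA(f) && all(diff(f) <= 0)
      }, .groups = "drop")
  }
  out
}

run_copy_number_stage <- function(cfg) {
  ct <- resolve_table(cfg$ct, "ct")
  eff <- resolve_efficiencies(cfg$efficiencies)
  calls <- copy_number_ratio(ct, cfg$target_amplicons,
                             cfg$reference_amplicons,
                             cfg$calibrator_samples, eff)
  out <- list(calls = dplyr::select(calls, -per_pair))
  if (!is.null(cfg$phenotypes)) {
    ph <- tibble::as_tibble(cfg$phenotypes)
    check_columns(ph, c("sample_id", "phenotype"), "`phenotypes`")
    joined <- dplyr::inner_join(calls, ph, by = "sample_id")
    out$contrast <- copy_number_contrast(
      joined$ratio[joined$phenotype == "alive"],
      joined$ratio[joined$phenotype == "dead"]
    )
    out$extra_copy_split <- joined |>
      dplyr::group_by(phenotype) |>
      dplyr::summarise(n = dplyr::n(), n_extra_copy = sum(extra_copy),
                       .groups = "drop")
  }
  out
}

run_genotyping_stage <- function(cfg) {
  plate <- resolve_table(cfg$taqman, "taqman")
  calls <- call_genotypes(plate,
                          min_signal_frac = cfg$min_signal_frac %||% 0.2,
                          max_angle_dist = cfg$max_angle_dist %||% 15)
  counts <- table(factor(calls$call, levels = c("SS", "GS", "GG", "NC")))
  out <- list(
    calls = calls,
    counts = tibble::tibble(call = names(counts), n = as.integer(counts)),
    allele = allele_frequency(counts[["SS"]], counts[["GS"]], counts[["GG"]]),
    hwe = hwe_test(counts[["SS"]], counts[["GS"]], counts[["GG"]])
  )
  ph <- calls$phenotype
  if (!is.null(ph) && sum(calls$call == "GS" & ph == "alive") >= 2 &&
      sum(calls$call == "GS" & ph == "dead") >= 2) {
    out$dye_balance <- het_dye_balance_contrast(calls)
  }
  called <- calls[calls$call != "NC" & calls$phenotype %in% c("alive", "dead"), ]
  if (nrow(called)) {
    tab <- rbind(
      serine = c(sum(called$call %in% c("SS", "GS") & called$phenotype == "alive"),
                 sum(called$call %in% c("SS", "GS") & called$phenotype == "dead")),
      no_serine = c(sum(called$call == "GG" & called$phenotype == "alive"),
                    sum(called$call == "GG" & called$phenotype == "dead"))
    )
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      out$association <- association_test(tab)
    }
  }
  out
}

run_dose_stage <- function(cfg) {
  obs <- resolve_table(cfg$dose, "dose")
  obs$survival <- obs$n_survived / obs$n
  fits <- purrr::map(split(obs, obs$line_id), function(d) {
    tryCatch(glance(fit_lc50(d)),
             error = function(e) tibble::tibble(error = conditionMessage(e)))
  })
  out <- list(lc50 = dplyr::bind_rows(fits, .id = "line_id"))
  ctrl <- cfg$control_line
  if (!is.null(ctrl)) {
    dd <- cfg$diagnostic_dose %||% 0.1
    at_dose <- obs[abs(log10(obs$dose) - log10(dd)) < 1e-9, ]
    ctrl_surv <- at_dose$survival[at_dose$line_id == ctrl]
    out$discriminating <- purrr::map_dfr(
      setdiff(unique(at_dose$line_id), ctrl),
      function(l) {
        dplyr::mutate(
          discriminating_dose_test(at_dose$survival[at_dose$line_id == l],
                                   ctrl_surv),
          line_id = l, .before = 1
        )
      }
    )
  }
  out
}

#' @export
print.resist_report <- function(x, ...) {
  stages <- setdiff(names(x), "provenance")
  cat(sprintf("<resist_report> stages: %s\n", paste(stages, collapse = ", ")))
  cat(sprintf("  config hash %s, seed %s\n",
              substr(x$provenance$config_hash, 1, 8),
              format(x$provenance$seed)))
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes every tabular stage output as TSV under `dir` and the whole
#' report (provenance block included, mandatory) as JSON. Gene-level
#' tables are written sorted by gene id; numbers keep full precision.
#'
#' @param report a `resist_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "resist_report")) abort("not a resist_report.")
  if (is.null(report$provenance)) abort("report has no provenance block.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(obj, prefix) {
    if (is.data.frame(obj)) {
      ## list-columns are not TSV-serializable; drop them
      obj <- obj[, !vapply(obj, is.list, logical(1)), drop = FALSE]
      f <- file.path(dir, paste0(prefix, ".tsv"))
      write_assay_table(obj, f)
      files <<- c(files, f)
    } else if (is.list(obj) && !inherits(obj, "lc50_fit")) {
      for (nm in names(obj)) emit(obj[[nm]], paste(prefix, nm, sep = "_"))
    }
  }
  for (nm in setdiff(names(report), "provenance")) emit(report[[nm]], nm)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_to_json(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, json_path)
  invisible(files)
}

report_to_json <- function(x) {
  if (is.data.frame(x)) {
    x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  } else if (inherits(x, "lc50_fit")) {
    glance(x)
  } else if (is.list(x)) {
    purrr::map(unclass(x), report_to_json)
  } else x
}
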