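#' Build a two-colour hybridization scheme
#'
#' A hybridization scheme ties each array to the two labelled samples it
#' carries (Cy3 and Cy5 channels) and each sample to its biological group.
#' All downstream contrast fitting is driven by this object.
#'
#' @param arrays tibble with columns `array_id`, `cy3_sample`, `cy5_sample`.
#' @param samples tibble with columns `sample_id`, `group`.
#' @return A validated `hyb_scheme` object (list of the two tibbles).
#' @export
hyb_scheme <- function(arrays, samples) {
  check_columns(arrays, c("array_id", "cy3_sample", "cy5_sample"), "`arrays`")
  check_columns(samples, c("sample_id", "group"), "`samples`")
  arrays <- tibble::as_tibble(arrays)
  samples <- tibble::as_tibble(samples)
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in `samples`.")
  if (anyDuplicated(arrays$array_id)) abort("duplicate array_id in `arrays`.")
  refs <- c(arrays$cy3_sample, arrays$cy5_sample)
  unknown <- setdiff(refs, samples$sample_id)
  if (length(unknown)) {
    abort(sprintf("arrays reference unknown sample(s): %s",
                  paste(unique(unknown), collapse = ", ")))
  }
  if (any(arrays$cy3_sample == arrays$cy5_sample)) {
    abort("an array must carry two distinct samples.")
  }
  structure(list(arrays = arrays, samples = samples), class = "hyb_scheme")
}

#' @export
print.hyb_scheme <- function(x, ...) {
  cat(sprintf(
    "<hyb_scheme> %d arrays, %d samples, %d groups\n",
    nrow(x$arrays), nrow(x$samples), dplyr::n_distinct(x$samples$group)
  ))
  invisible(x)
}

#' Pairwise full dye-swap design (Exp1-style)
#'
#' Every resistant group is compared directly with every susceptible group;
#' each replicate pairing is hybridized twice with the dye assignment
#' swapped, so gene-specific dye bias cancels in the contrast estimates.
#' Mirrors a design with two resistant groups (a bendiocarb-selected and an
#' unexposed population sample) against three susceptible populations, with
#' 2-3 biological replicates per group.
#'
#' @param res_groups character vector of resistant group ids.
#' @param sus_groups character vector of susceptible group ids.
#' @param n_reps biological replicates per group; scalar or named vector.
#' @return A `hyb_scheme`.
#' @examples
#' sim_scheme_dyeswap(c("Tia_sel", "Tia_unexp"), c("NG", "Mali", "Oky"))
#' @export
sim_scheme_dyeswap <- function(res_groups, sus_groups, n_reps = 3) {
  groups <- c(res_groups, sus_groups)
  reps <- rep_len(n_reps, length(groups))
  if (!is.null(names(n_reps))) reps <- unname(n_reps[groups])
  if (anyNA(reps)) abort("`n_reps` must name every group.")
  samples <- tibble::tibble(
    group = rep(groups, reps),
    sample_id = unlist(purrr::map2(groups, reps, function(g, r) {
      paste0(g, "_r", seq_len(r))
    }))
  )[, c("sample_id", "group")]
  arrays <- purrr::map_dfr(res_groups, function(rg) {
    purrr::map_dfr(sus_groups, function(sg) {
      k <- min(reps[match(rg, groups)], reps[match(sg, groups)])
      purrr::map_dfr(seq_len(k), function(i) {
        rs <- paste0(rg, "_r", i)
        ss <- paste0(sg, "_r", i)
        tibble::tibble(
          array_id = paste0(rg, ".vs.", sg, "_r", i, c("_fwd", "_rev")),
          cy3_sample = c(ss, rs),
          cy5_sample = c(rs, ss)
        )
      })
    })
  })
  hyb_scheme(arrays, samples)
}

#' Fully-interwoven loop design (Exp2-style)
#'
#' Samples are placed on a ring, interleaving the groups, and each array
#' connects two ring positions. Two passes are made: adjacent positions in
#' one dye orientation and next-but-one positions in the opposite
#' orientation. With three groups of three replicates this yields the
#' 18-array interwoven double loop over nine samples in which every sample
#' is hybridized four times, twice in each dye.
#'
#' @param groups character vector of group ids (order sets the interleave).
#' @param n_reps biological replicates per group (scalar).
#' @return A `hyb_scheme`.
#' @examples
#' sch <- sim_scheme_loop(c("Kovie", "Mal", "Oky"))
#' nrow(sch$arrays)  # 18
#' @export
sim_scheme_loop <- function(groups, n_reps = 3) {
  samples <- tibble::tibble(
    sample_id = as.vector(t(outer(groups, seq_len(n_reps),
                                  function(g, r) paste0(g, "_r", r)))),
    group = rep(groups, each = n_reps)
  )
  ## interleave groups around the ring: g1_r1, g2_r1, g3_r1, g1_r2, ...
  ring <- as.vector(t(matrix(samples$sample_id, nrow = n_reps, byrow = TRUE)))
  n <- length(ring)
  nxt <- function(i, k) ring[((i - 1 + k) %% n) + 1]
  arrays <- dplyr::bind_rows(
    tibble::tibble(
      array_id = paste0("loop1_", seq_len(n)),
      cy3_sample = ring,
      cy5_sample = vapply(seq_len(n), nxt, character(1), k = 1)
    ),
    tibble::tibble(
      array_id = paste0("loop2_", seq_len(n)),
      cy3_sample = vapply(seq_len(n), nxt, character(1), k = 2),
      cy5_sample = ring
    )
  )
  hyb_scheme(arrays, samples)
}

#' Plant per-gene expression truth
#'
#' Defines, for every gene, a true log2 expression offset per group
#' (baseline groups at 0) and flags the genes planted as
#' resistance-associated. Offsets for flagged genes should follow the rank
#' order implied by increasing resistance (e.g. selected >= unexposed >=
#' moderately-resistant >= susceptible); non-flagged genes carry zero offset
#' in every group.
#'
#' @param n_genes total genes.
#' @param probes_per_gene probes mapping to each gene.
#' @param n_resistance number of resistance-flagged genes (the first
#'   `n_resistance` gene ids).
#' @param group_offsets named numeric: true log2 offset of each non-baseline
#'   group for flagged genes. Groups not named have offset 0.
#' @param sign_flip optional fraction (0-1) of flagged genes whose offsets
#'   are negated, to plant under-expressed resistance genes. Default 0.
#' @return A `planted_truth` object: tibbles `genes` (gene_id, resistance,
#'   sign), `offsets` (gene_id, group, offset; flagged genes only) and
#'   `probes` (probe_id, gene_id).
#' @export
sim_truth <- function(n_genes, probes_per_gene = 1, n_resistance = 0,
                      group_offsets = numeric(), sign_flip = 0) {
  if (n_genes < 1 || probes_per_gene < 1) abort("counts must be >= 1.")
  if (n_resistance > n_genes) abort("more flagged genes than genes.")
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  flagged <- seq_len(n_genes) <= n_resistance
  sign <- rep(1, n_genes)
  if (sign_flip > 0 && n_resistance > 0) {
    k <- floor(sign_flip * n_resistance)
    if (k > 0) sign[seq_len(k)] <- -1
  }
  genes <- tibble::tibble(gene_id = gene_id, resistance = flagged, sign = sign)
  offsets <- if (n_resistance > 0 && length(group_offsets)) {
    tidyr::crossing(gene_id = gene_id[flagged],
                    group = names(group_offsets)) |>
      dplyr::mutate(offset = unname(group_offsets[group])) |>
      dplyr::left_join(genes[, c("gene_id", "sign")], by = "gene_id") |>
      dplyr::mutate(offset = offset * sign) |>
      dplyr::select(gene_id, group, offset)
  } else {
    tibble::tibble(gene_id = character(), group = character(),
                   offset = numeric())
  }
  probes <- tidyr::crossing(gene_id = gene_id, p = seq_len(probes_per_gene)) |>
    dplyr::mutate(probe_id = paste0(gene_id, "_p", p)) |>
    dplyr::select(probe_id, gene_id)
  structure(list(genes = genes, offsets = offsets, probes = probes),
            class = "planted_truth")
}

## look up the offset matrix genes x groups implied by a planted truth
truth_offset_matrix <- function(truth, groups) {
  m <- matrix(0, nrow = nrow(truth$genes), ncol = length(groups),
              dimnames = list(truth$genes$gene_id, groups))
  if (nrow(truth$offsets)) {
    keep <- truth$offsets$group %in% groups
    off <- truth$offsets[keep, ]
    m[cbind(off$gene_id, off$group)] <- off$offset
  }
  m
}

#' Simulate a two-colour expression experiment at the M-value level
#'
#' For each array and probe the simulated log2 ratio is
#' `M = offset[cy5 group] - offset[cy3 group] + array effect +
#' probe dye bias + N(0, array_noise_sd)`.
#' The array effect is drawn once per array (a global intensity imbalance
#' that per-array median normalization removes); the dye bias is drawn once
#' per probe and attaches to the Cy5 channel on every array, so dye-swap
#' averaging cancels it in contrast estimates. Arrays are simulated at the
#' normalized log-ratio level; raw two-channel intensities are not modelled.
#'
#' @param scheme a `hyb_scheme`.
#' @param truth a `planted_truth` covering all groups used in `scheme`.
#' @param array_noise_sd per-measurement noise sd in log2 units.
#' @param dye_bias_sd sd of the per-probe dye-bias term (default 0 = off).
#' @param array_effect_sd sd of the per-array effect (default 0 = off).
#' @param seed integer; fixed seed gives bit-identical output.
#' @return tibble `probe_id`, `array_id`, `M` (an M-value table).
#' @export
sim_mvalues <- function(scheme, truth, array_noise_sd = 0.25,
                        dye_bias_sd = 0, array_effect_sd = 0, seed = NULL) {
  stopifnot(inherits(scheme, "hyb_scheme"), inherits(truth, "planted_truth"))
  if (array_noise_sd < 0 || dye_bias_sd < 0 || array_effect_sd < 0) {
    abort("noise standard deviations must be >= 0.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  grp <- setNames(scheme$samples$group, scheme$samples$sample_id)
  groups <- unique(scheme$samples$group)
  bad <- setdiff(unique(truth$offsets$group), groups)
  ## offsets for groups absent from the scheme are simply unused
  offm <- truth_offset_matrix(truth, groups)
  probe_gene <- truth$probes
  n_probes <- nrow(probe_gene)
  n_arrays <- nrow(scheme$arrays)
  array_effect <- rnorm(n_arrays, 0, array_effect_sd)
  dye_bias <- rnorm(n_probes, 0, dye_bias_sd)
  g5 <- grp[scheme$arrays$cy5_sample]
  g3 <- grp[scheme$arrays$cy3_sample]
  ## per-gene group difference per array, expanded to probes
  delta <- offm[, g5, drop = FALSE] - offm[, g3, drop = FALSE] # genes x arrays
  rows <- match(probe_gene$gene_id, rownames(delta))
  signal <- delta[rows, , drop = FALSE]                        # probes x arrays
  noise <- matrix(rnorm(n_probes * n_arrays, 0, array_noise_sd),
                  n_probes, n_arrays)
  m <- signal + noise +
    matrix(array_effect, n_probes, n_arrays, byrow = TRUE) +
    matrix(dye_bias, n_probes, n_arrays)
  tibble::tibble(
    probe_id = rep(probe_gene$probe_id, times = n_arrays),
    array_id = rep(scheme$arrays$array_id, each = n_probes),
    M = as.vector(m)
  )
}

#' Simulate a TaqMan endpoint allelic-discrimination plate
#'
#' Each individual is a point in the (VIC, FAM) fluorescence plane: the FAM
#' dye labels the resistant serine (119S) allele, VIC the wild-type glycine
#' (119G) allele. A genotype class is a cluster at a characteristic angle
#' from the VIC axis: homozygotes hug an axis, balanced heterozygotes sit at
#' 45 degrees (1:1 dye balance), and duplication-carrying heterozygotes with
#' an extra serine allele are shifted toward FAM (e.g. 56.31 degrees, a 1.5:1
#' ratio). Signals are `FAM = r sin(theta)`, `VIC = r cos(theta)` with
#' `r ~ Normal(signal_mean, signal_sd)` truncated positive and
#' `theta ~ Normal(class angle, angular_sd)`.
#'
#' @param n_per_class named integer vector with (a subset of) names
#'   `SS`, `GS`, `GG`, `dup_GS`: individuals per planted class.
#' @param angles named numeric vector of class angles in degrees, strictly
#'   inside (0, 90).
#' @param angular_sd angular noise sd in degrees.
#' @param signal_mean,signal_sd total-signal distribution parameters;
#'   `signal_mean` must be positive.
#' @param survival named numeric: probability an individual of each class
#'   survives the bioassay (phenotype `alive` vs `dead`).
#' @param n_controls number of SS and of GG control wells.
#' @param n_ntc number of no-template control wells (near-zero signal).
#' @param seed integer seed.
#' @return tibble with `sample_id`, `fam_dR`, `vic_dR`, `control_type`
#'   (`none`, `SS`, `GG`, `NTC`), `phenotype` (`alive`, `dead`, `untested`)
#'   and the planted `class_truth`.
#' @export
sim_taqman_plate <- function(n_per_class = c(SS = 0, GS = 40, GG = 10, dup_GS = 0),
                             angles = c(SS = 80, GS = 45, GG = 10, dup_GS = 56.31),
                             angular_sd = 3,
                             signal_mean = 1, signal_sd = 0.1,
                             survival = c(SS = 0.9, GS = 0.5, GG = 0.05,
                                          dup_GS = 0.95),
                             n_controls = 3, n_ntc = 2, seed = NULL) {
  if (signal_mean <= 0) abort("`signal_mean` must be positive.")
  if (any(angles <= 0 | angles >= 90)) abort("angles must lie in (0, 90).")
  if (anyDuplicated(angles)) abort("class angles must be distinct.")
  if (!is.null(seed)) withr::local_seed(seed)
  rtrunc_pos <- function(n, mean, sd) {
    out <- rnorm(n, mean, sd)
    while (any(bad <- out <= 0)) out[bad] <- rnorm(sum(bad), mean, sd)
    out
  }
  draw <- function(n, class, control = "none", phenotype = NULL) {
    if (n == 0) return(NULL)
    ## clamp to the first quadrant so fluorescence stays non-negative
    theta <- deg2rad(pmin(pmax(rnorm(n, angles[[class]], angular_sd), 0), 90))
    r <- rtrunc_pos(n, signal_mean, signal_sd)
    ph <- phenotype %||%
      ifelse(stats::runif(n) < survival[[class]], "alive", "dead")
    tibble::tibble(
      fam_dR = r * sin(theta), vic_dR = r * cos(theta),
      control_type = control, phenotype = ph, class_truth = class
    )
  }
  recs <- dplyr::bind_rows(
    draw(n_controls, "SS", control = "SS", phenotype = "untested"),
    draw(n_controls, "GG", control = "GG", phenotype = "untested"),
    if (n_ntc > 0) tibble::tibble(
      fam_dR = abs(rnorm(n_ntc, 0, signal_sd / 10)),
      vic_dR = abs(rnorm(n_ntc, 0, signal_sd / 10)),
      control_type = "NTC", phenotype = "untested", class_truth = "NTC"
    ),
    purrr::map_dfr(names(n_per_class), function(cl) {
      draw(n_per_class[[cl]], cl)
    })
  )
  recs$sample_id <- sprintf("w%03d", seq_len(nrow(recs)))
  dplyr::select(recs, sample_id, fam_dR, vic_dR, control_type, phenotype,
                class_truth)
}

#' Simulate a qPCR Ct table from planted relative quantities
#'
#' Each cycle-threshold value follows the exponential amplification model
#' `Ct = base_ct - log(quantity) / log(1 + E)` plus Normal noise, so a
#' doubling of template at efficiency `E = 1` lowers Ct by exactly one
#' cycle. The table inverts exactly through the package's delta-delta-Ct
#' closed forms at zero noise.
#'
#' @param quantities tibble with `sample_id`, `amplicon_id`, `quantity`
#'   (relative template quantity, > 0).
#' @param efficiencies named numeric, amplicon_id -> E with E in (0.5, 1.2].
#' @param replicates technical replicates per (sample, amplicon).
#' @param ct_noise_sd Ct noise sd in cycles.
#' @param base_ct Ct of one quantity unit (default 24 cycles).
#' @param seed integer seed.
#' @return tibble `sample_id`, `amplicon_id`, `replicate`, `ct`.
#' @export
sim_ct_table <- function(quantities, efficiencies, replicates = 3,
                         ct_noise_sd = 0, base_ct = 24, seed = NULL) {
  check_columns(quantities, c("sample_id", "amplicon_id", "quantity"),
                "`quantities`")
  if (any(quantities$quantity <= 0)) abort("quantities must be > 0.")
  miss <- setdiff(unique(quantities$amplicon_id), names(efficiencies))
  if (length(miss)) {
    abort(sprintf("no efficiency for amplicon(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (any(efficiencies <= 0.5 | efficiencies > 1.2)) {
    abort("efficiencies must lie in (0.5, 1.2].")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  tidyr::crossing(quantities, replicate = seq_len(replicates)) |>
    dplyr::mutate(
      eff = unname(efficiencies[amplicon_id]),
      ct = base_ct - log(quantity) / log(1 + eff) +
        rnorm(dplyr::n(), 0, ct_noise_sd)
    ) |>
    dplyr::select(sample_id, amplicon_id, replicate, ct)
}

#' Simulate WHO-bioassay replicate mortality counts
#'
#' Deaths per replicate tube are Binomial(`n_per_replicate`,
#' `true_mortality`), the standard model for a WHO tube bioassay of batches
#' of adult females.
#'
#' @param conditions tibble with `insecticide`, `season`, `pbo` (logical),
#'   `mortality` (true probability in `[0,1]`) and optionally
#'   `n_replicates`, `n_per_replicate`.
#' @param n_replicates,n_per_replicate defaults used where the condition
#'   table does not override them (four replicate tubes of 25 females).
#' @param seed integer seed.
#' @return tibble, one row per replicate: condition columns plus
#'   `replicate`, `n_exposed`, `n_dead`.
#' @export
sim_bioassay <- function(conditions, n_replicates = 4, n_per_replicate = 25,
                         seed = NULL) {
  check_columns(conditions, c("insecticide", "season", "pbo", "mortality"),
                "`conditions`")
  if (any(conditions$mortality < 0 | conditions$mortality > 1)) {
    abort("`mortality` must lie in [0, 1].")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  conditions <- tibble::as_tibble(conditions)
  if (!"n_replicates" %in% names(conditions)) {
    conditions$n_replicates <- n_replicates
  }
  if (!"n_per_replicate" %in% names(conditions)) {
    conditions$n_per_replicate <- n_per_replicate
  }
  purrr::pmap_dfr(conditions, function(insecticide, season, pbo, mortality,
                                       n_replicates, n_per_replicate, ...) {
    tibble::tibble(
      insecticide = insecticide, season = season, pbo = pbo,
      replicate = seq_len(n_replicates),
      n_exposed = n_per_replicate,
      n_dead = rbinom(n_replicates, n_per_replicate, mortality)
    )
  })
}

#' Simulate dose-response survival data
#'
#' Expected survival follows the same linear-in-log10-dose model the LC50
#' fitter assumes: `p(d) = clamp(0.5 - slope * (log10 d - log10 lc50), 0, 1)`,
#' so at the LC50 survival is exactly 0.5 and noise-free recovery is exact.
#' A logistic alternative (`model = "logistic"`, matched slope at the LC50)
#' is provided for robustness checks of the fitter.
#'
#' @param lines tibble with `line_id`, `lc50` (> 0, micrograms per vial) and
#'   `slope` (per log10 dose, non-zero).
#' @param doses vector of doses (> 0), micrograms per vial.
#' @param n_per_vial flies per vial.
#' @param n_vials replicate vials per (line, dose).
#' @param noise `"binomial"` draws survivor counts; `"none"` returns the
#'   expected proportions exactly.
#' @param model `"linear"` (default) or `"logistic"`.
#' @param seed integer seed.
#' @return tibble `line_id`, `dose`, `vial`, `n`, `n_survived`, `survival`.
#' @export
sim_dose_response <- function(lines, doses, n_per_vial = 10, n_vials = 1,
                              noise = c("binomial", "none"),
                              model = c("linear", "logistic"), seed = NULL) {
  noise <- arg_match(noise)
  model <- arg_match(model)
  check_columns(lines, c("line_id", "lc50", "slope"), "`lines`")
  if (any(doses <= 0)) abort("doses must be > 0.")
  if (any(lines$lc50 <= 0)) abort("`lc50` must be > 0.")
  if (any(lines$slope == 0)) abort("`slope` must be non-zero (LC50 undefined).")
  if (!is.null(seed)) withr::local_seed(seed)
  grid <- tidyr::crossing(lines, dose = doses, vial = seq_len(n_vials))
  x <- log10(grid$dose) - log10(grid$lc50)
  p <- if (model == "linear") {
    pmin(pmax(0.5 - grid$slope * x, 0), 1)
  } else {
    stats::plogis(-4 * grid$slope * x)  # matched derivative at the LC50
  }
  n_surv <- if (noise == "binomial") {
    rbinom(nrow(grid), n_per_vial, p)
  } else {
    n_per_vial * p
  }
  tibble::tibble(
    line_id = grid$line_id, dose = grid$dose, vial = grid$vial,
    n = n_per_vial, n_survived = n_surv, survival = n_surv / n_per_vial
  )
}
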