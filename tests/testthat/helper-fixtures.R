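## shared fixture builders; everything is generated in code at test time

## the standard five-group selected-line design used across tests
fixture_exp1_scheme <- function(n_reps = 3) {
  sim_scheme_dyeswap(c("Tia_sel", "Tia_unexp"), c("NG", "Mali", "Oky"),
                     n_reps = n_reps)
}

fixture_exp1_comparisons <- function() {
  c("Tia_sel:NG", "Tia_sel:Mali", "Tia_sel:Oky",
    "Tia_unexp:NG", "Tia_unexp:Mali", "Tia_unexp:Oky")
}

fixture_exp1_pairs <- function() {
  tibble::tibble(
    selected = c("Tia_sel:NG", "Tia_sel:Mali", "Tia_sel:Oky"),
    unexposed = c("Tia_unexp:NG", "Tia_unexp:Mali", "Tia_unexp:Oky")
  )
}

## a small Ct-table fixture: target overexpressed `fold`-fold in group "exp"
fixture_ct_fold <- function(fold, eff = c(tgt = 1, ref = 1), n = 3,
                            noise = 0, seed = NULL) {
  ids <- c(paste0("exp", seq_len(n)), paste0("ctl", seq_len(n)))
  q <- tidyr::crossing(sample_id = ids, amplicon_id = names(eff))
  q$quantity <- ifelse(q$amplicon_id == "tgt" & grepl("^exp", q$sample_id),
                       fold, 1)
  list(
    ct = sim_ct_table(q, eff, replicates = 2, ct_noise_sd = noise,
                      seed = seed),
    groups = tibble::tibble(
      sample_id = ids,
      group = ifelse(grepl("^exp", ids), "exp", "ctl")
    )
  )
}

## brute-force consensus oracle: naive per-probe loops over the boolean rules
oracle_verdicts <- function(contrasts, plan) {
  probes <- unique(contrasts$probe_id)
  out <- lapply(probes, function(pr) {
    rows <- contrasts[contrasts$probe_id == pr &
                        contrasts$comparison %in% plan$comparisons$comparison, ]
    complete <- nrow(rows) == nrow(plan$comparisons) &&
      !any(is.na(rows$q)) && !any(is.na(rows$log2FC))
    if (!complete) {
      return(data.frame(probe_id = pr, significant = FALSE,
                        unevaluable = TRUE))
    }
    dir_ok <- all(rows$log2FC > 0) || all(rows$log2FC < 0)
    q_ok <- all(rows$q < plan$alpha)
    esc_ok <- TRUE
    if (nrow(plan$pairs)) {
      for (k in seq_len(nrow(plan$pairs))) {
        s <- rows$log2FC[rows$comparison == plan$pairs$selected[k]]
        u <- rows$log2FC[rows$comparison == plan$pairs$unexposed[k]]
        esc_ok <- esc_ok && sign(s) == sign(u) && abs(s) > abs(u)
      }
    }
    data.frame(probe_id = pr, significant = dir_ok && q_ok && esc_ok,
               unevaluable = FALSE)
  })
  do.call(rbind, out)
}

## brute-force HWE chi-square from first principles
oracle_hwe_chi2 <- function(n_ss, n_gs, n_gg) {
  n <- n_ss + n_gs + n_gg
  p <- (2 * n_ss + n_gs) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_ss, n_gs, n_gg)
  sum((o - e)^2 / e)
}

## brute-force exact Mann-Whitney by explicit assignment enumeration,
## written independently of the implementation (index-set loop, no ranks
## on the full vector reused)
oracle_mw_p <- function(x, y) {
  v <- c(x, y); n1 <- length(x); n <- length(v)
  u_of <- function(idx) {
    xs <- v[idx]; ys <- v[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}
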