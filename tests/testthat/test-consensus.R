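## build a contrast table directly from per-comparison (log2FC, q) specs
make_contrasts <- function(..., comparisons) {
  probes <- list(...)
  purrr::imap_dfr(probes, function(spec, pr) {
    tibble::tibble(probe_id = pr, comparison = comparisons,
                   log2FC = spec$fc, q = spec$q)
  })
}

exp1_plan <- function(alpha = 0.05) {
  comparison_plan(fixture_exp1_comparisons(), fixture_exp1_pairs(),
                  alpha = alpha)
}

test_that("selected-line criteria: direction, q, and escalation", {
  comparisons <- fixture_exp1_comparisons()
  ## selected FCs (2.0, 2.1, 1.9) vs unexposed (1.5, 1.6, 1.4), all q 0.01
  ## -> significant; one q at 0.06 -> fails criterion (ii); q 1 -> fails
  cc <- make_contrasts(
    good = list(fc = c(2.0, 2.1, 1.9, 1.5, 1.6, 1.4), q = rep(0.01, 6)),
    one_q_high = list(fc = c(2.0, 2.1, 1.9, 1.5, 1.6, 1.4),
                      q = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.06)),
    all_q_one = list(fc = c(2.0, 2.1, 1.9, 1.5, 1.6, 1.4), q = rep(1, 6)),
    no_escalation = list(fc = c(1.5, 1.6, 1.4, 2.0, 2.1, 1.9),
                         q = rep(0.01, 6)),
    discordant = list(fc = c(2.0, -2.1, 1.9, 1.5, -1.6, 1.4),
                      q = rep(0.01, 6)),
    down_regulated = list(fc = -c(2.0, 2.1, 1.9, 1.5, 1.6, 1.4),
                          q = rep(0.01, 6)),
    comparisons = comparisons
  )
  v <- evaluate_exp1(cc, exp1_plan())
  verdict <- setNames(v$significant, v$probe_id)
  expect_true(verdict[["good"]])
  expect_false(verdict[["one_q_high"]])   # five of six under 0.05 is not enough
  expect_false(verdict[["all_q_one"]])
  expect_false(verdict[["no_escalation"]])
  expect_false(verdict[["discordant"]])
  ## under-expression is symmetric: all-negative with escalation passes
  expect_true(verdict[["down_regulated"]])
})

test_that("loop-design criteria: direction and strict q only", {
  comparisons <- c("Kovie:Mal", "Kovie:Oky")
  cc <- make_contrasts(
    ok = list(fc = c(1, 1.2), q = c(0.03, 0.04)),
    discordant = list(fc = c(1, -1.2), q = c(1e-6, 1e-6)),
    boundary = list(fc = c(1, 1.2), q = c(0.049, 0.051)),
    at_alpha = list(fc = c(1, 1.2), q = c(0.05, 0.01)),
    comparisons = comparisons
  )
  v <- evaluate_exp2(cc, comparison_plan(comparisons))
  verdict <- setNames(v$significant, v$probe_id)
  expect_true(verdict[["ok"]])
  expect_false(verdict[["discordant"]])
  expect_false(verdict[["boundary"]])
  expect_false(verdict[["at_alpha"]])     # strict inequality at the threshold

  ## the two designs guard against the wrong plan shape
  expect_error(evaluate_exp1(cc, comparison_plan(comparisons)), "pairs")
  expect_error(evaluate_exp2(cc, exp1_plan()), "pairs")
})

test_that("probes missing a plan comparison are unevaluable, not failed", {
  comparisons <- c("Kovie:Mal", "Kovie:Oky")
  cc <- make_contrasts(
    complete = list(fc = c(1, 1), q = c(0.01, 0.01)),
    comparisons = comparisons
  )
  cc <- dplyr::bind_rows(
    cc,
    tibble::tibble(probe_id = "partial", comparison = "Kovie:Mal",
                   log2FC = 1, q = 0.01)
  )
  v <- evaluate_probes(cc, comparison_plan(comparisons))
  expect_true(v$unevaluable[v$probe_id == "partial"])
  expect_false(v$significant[v$probe_id == "partial"])
  expect_false(v$unevaluable[v$probe_id == "complete"])
})

test_that("verdicts equal the brute-force oracle on random tables", {
  set.seed(20)
  comparisons <- fixture_exp1_comparisons()
  plan <- exp1_plan()
  n <- 1000
  cc <- tidyr::crossing(probe_id = sprintf("p%04d", seq_len(n)),
                        comparison = comparisons) |>
    dplyr::mutate(
      log2FC = rnorm(dplyr::n(), 0, 1.5),
      q = stats::rbeta(dplyr::n(), 0.3, 1)   # many small q values
    )
  got <- evaluate_probes(cc, plan)
  want <- oracle_verdicts(cc, plan)
  m <- match(want$probe_id, got$probe_id)
  expect_equal(got$significant[m], want$significant)

  ## same exercise on the loop design (no escalation)
  plan2 <- comparison_plan(comparisons[1:2])
  cc2 <- dplyr::filter(cc, comparison %in% comparisons[1:2])
  got2 <- evaluate_probes(cc2, plan2)
  want2 <- oracle_verdicts(cc2, plan2)
  m2 <- match(want2$probe_id, got2$probe_id)
  expect_equal(got2$significant[m2], want2$significant)
})

test_that("criteria are conjunctive and monotone in alpha", {
  set.seed(21)
  comparisons <- fixture_exp1_comparisons()
  cc <- tidyr::crossing(probe_id = sprintf("p%03d", 1:200),
                        comparison = comparisons) |>
    dplyr::mutate(log2FC = rnorm(dplyr::n(), 0.5, 1),
                  q = stats::rbeta(dplyr::n(), 0.4, 1))
  ## adding a comparison can never rescue a probe
  plan_small <- comparison_plan(comparisons[c(1, 4)],
                                fixture_exp1_pairs()[1, ])
  plan_full <- exp1_plan()
  sig_small <- evaluate_probes(cc, plan_small)
  sig_full <- evaluate_probes(cc, plan_full)
  gained <- setdiff(sig_full$probe_id[sig_full$significant],
                    sig_small$probe_id[sig_small$significant])
  expect_length(gained, 0)

  ## stricter alpha shrinks the significant set
  sig_05 <- evaluate_probes(cc, exp1_plan(0.05))
  sig_01 <- evaluate_probes(cc, exp1_plan(0.01))
  expect_true(all(sig_01$probe_id[sig_01$significant] %in%
                    sig_05$probe_id[sig_05$significant]))
})

test_that("cross-experiment combination intersects and aggregates to genes", {
  v1 <- tibble::tibble(probe_id = c("p1", "p2", "p3", "p4"),
                       significant = c(TRUE, TRUE, FALSE, TRUE),
                       mean_log2FC = c(2, 1.8, 0.2, 1.2))
  v2 <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                       significant = c(TRUE, FALSE, FALSE),
                       mean_log2FC = c(1.5, 0.9, 0.1))
  map <- tibble::tibble(probe_id = c("p1", "p2", "p3", "p4"),
                        gene_id = c("gA", "gA", "gB", "gC"))
  out <- combine_experiments(v1, v2, map)
  ## p2 significant in one experiment only; p4 untested in the loop design
  expect_false(out$probes$overall_significant[out$probes$probe_id == "p2"])
  expect_equal(out$probes$status[out$probes$probe_id == "p4"], "untested")
  gA <- out$genes[out$genes$gene_id == "gA", ]
  expect_equal(gA$label, "1/2")
  expect_equal(gA$median_log2FC, 2)

  ## a gene with every probe significant carries the n/n annotation
  v1b <- tibble::tibble(probe_id = paste0("q", 1:4), significant = TRUE,
                        mean_log2FC = 1)
  v2b <- v1b
  mapb <- tibble::tibble(probe_id = paste0("q", 1:4), gene_id = "gX")
  outb <- combine_experiments(v1b, v2b, mapb)
  expect_equal(outb$genes$label, "4/4")
})

test_that("planted resistance genes are recovered end to end", {
  tr <- sim_truth(200, 2, 7, c(Tia_sel = 1.8, Tia_unexp = 1.2, Kovie = 1.2))
  sch1 <- fixture_exp1_scheme()
  sch2 <- sim_scheme_loop(c("Kovie", "Mal", "Oky"))
  mv1 <- sim_mvalues(sch1, tr, array_noise_sd = 0.2, seed = 31)
  mv2 <- sim_mvalues(sch2, tr, array_noise_sd = 0.2, seed = 32)
  c1 <- fit_contrasts(normalize_arrays(mv1), sch1,
                      fixture_exp1_comparisons()) |>
    moderate_contrasts() |> add_fdr()
  c2 <- fit_contrasts(normalize_arrays(mv2), sch2,
                      c("Kovie:Mal", "Kovie:Oky")) |>
    moderate_contrasts() |> add_fdr()
  v1 <- evaluate_probes(c1, exp1_plan())
  v2 <- evaluate_probes(c2, comparison_plan(c("Kovie:Mal", "Kovie:Oky")))
  genes <- combine_experiments(v1, v2, tr$probes)$genes
  hits <- genes$gene_id[genes$n_probes_significant > 0]
  planted <- tr$genes$gene_id[tr$genes$resistance]
  expect_setequal(hits, planted)
})
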