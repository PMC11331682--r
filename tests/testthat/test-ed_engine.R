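test_that("split_by_context applies the non-silent class rule", {
  models <- toy_models()
  cohort <- toy_cohort(list(
    list("S1", "GA", "missense"), list("S2", "GA", "nonsense"),
    list("S3", "GA", "synonymous"), list("S4", "GB", "missense")),
    roster = sprintf("S%d", 1:5))
  ctx <- split_by_context(cohort, "GA")
  expect_setequal(ctx$positive_samples, c("S1", "S2"))
  expect_setequal(ctx$negative_samples, c("S3", "S4", "S5"))

  none <- split_by_context(cohort, "GC")
  expect_length(none$positive_samples, 0)
  expect_true(attr(none, "empty_positive"))

  all_mut <- toy_cohort(list(list("S1", "GA", "missense"),
                             list("S2", "GA", "inframe_indel")),
                        roster = c("S1", "S2"))
  expect_length(split_by_context(all_mut, "GA")$negative_samples, 0)
})

test_that("cdns_score is the log2 ratio with antisymmetry and NA flags", {
  expect_equal(cdns_score(4, 1), 2)
  expect_equal(cdns_score(2.7, 2.7), 0)
  # antisymmetry over a grid
  for (wp in c(0.25, 1, 3.7)) for (wm in c(0.5, 2, 8)) {
    expect_equal(cdns_score(wp, wm), -cdns_score(wm, wp))
  }
  z <- cdns_score(0, 2)
  expect_true(is.na(z))
  expect_equal(attr(z, "reason"), "zero_plus")
  expect_equal(attr(cdns_score(0, 0), "reason"), "both_zero")
})

test_that("permutation p follows the add-one formula and is deterministic", {
  sim <- shared_neutral_sim()
  ws <- ed_workspace(sim$cohort, sim$gene_models, "trinuc96")
  # pick a context gene with a non-degenerate split
  g <- names(which(colSums(ws$nonsilent > 0) >= 5))[1]
  b <- setdiff(ws$panel, g)[1]
  p1 <- permutation_test(NULL, g, b, "missense", ws = ws, n_perm = 99,
                         seed = 5)
  p2 <- permutation_test(NULL, g, b, "missense", ws = ws, n_perm = 99,
                         seed = 5)
  expect_identical(p1$p_perm, p2$p_perm)
  expect_identical(p1$null, p2$null)
  # add-one correction: p = (1 + #extreme) / (n_perm + 1)
  obs <- p1$observed$cdns
  n_ext <- sum(if (obs >= 0) p1$null >= obs else p1$null <= obs, na.rm = TRUE)
  expect_equal(p1$p_perm, (1 + n_ext) / 100)
  expect_error(permutation_test(NULL, g, b, "missense", ws = ws, n_perm = 0),
               "n_perm")
})

test_that("permutation engine matches exhaustive enumeration on a toy", {
  # <= 8 samples: exact p by enumerating all context+ label assignments
  models <- toy_models()
  trip <- list(
    list("S1", "GA", "missense"), list("S2", "GA", "missense"),
    list("S1", "GB", "missense"), list("S1", "GB", "missense"),
    list("S2", "GB", "missense"), list("S3", "GB", "synonymous"),
    list("S4", "GB", "missense"), list("S5", "GB", "synonymous"),
    list("S6", "GA", "synonymous"), list("S4", "GC", "synonymous"),
    list("S1", "GC", "synonymous"), list("S2", "GA", "synonymous"),
    list("S7", "GB", "missense"))
  cohort <- toy_cohort(trip, roster = sprintf("S%d", 1:8))
  ws <- ed_workspace(cohort, models, "uniform")
  pt <- permutation_test(NULL, "GA", "GB", "missense", ws = ws,
                         n_perm = 4000, seed = 11)
  obs <- pt$observed

  # enumeration oracle: every subset of size n_pos as context+
  ids <- cohort$samples$sample_id
  nb <- sapply(ids, function(s) sum(cohort$records$sample_id == s &
                                      cohort$records$gene == "GB" &
                                      cohort$records$impact_class == "missense"))
  syn <- sapply(ids, function(s) sum(cohort$records$sample_id == s &
                                       cohort$records$impact_class == "synonymous"))
  tabs <- lapply(models, build_opportunity_table, granularity = "uniform")
  L_mis <- tabs$GB$counts["missense", "all"]
  L_syn <- sum(vapply(tabs, function(t) t$counts["synonymous", "all"], 1))
  omega <- function(idx) {
    e <- sum(syn[idx]) * L_mis / L_syn
    if (e <= 0) NA_real_ else sum(nb[idx]) / e
  }
  combos <- utils::combn(length(ids), obs$n_pos)
  null_exact <- apply(combos, 2, function(idx) {
    w_p <- omega(idx); w_m <- omega(setdiff(seq_along(ids), idx))
    as.numeric(cdns_score(w_p, w_m))
  })
  extreme <- if (obs$cdns >= 0) null_exact >= obs$cdns else
    null_exact <= obs$cdns
  extreme[is.na(extreme)] <- FALSE
  p_exact <- mean(extreme)
  expect_lt(abs(pt$p_perm - p_exact), 0.02)
})

test_that("sample size correction exposes the logistic mechanism", {
  # override limit: w = 1 recovers the uncorrected N
  c1 <- sample_size_correction(100, 900, w_override = 1)
  expect_equal(c1$corrected_N, 1000)
  # closed-form oracle at defaults
  c2 <- sample_size_correction(100, 9900)
  f <- 100 / 10000
  expect_equal(c2$w, 1 / (1 + exp(-50 * (f - 0.05))))
  expect_equal(c2$corrected_N, 100 + c2$w * 9900)
  # w non-increasing as the context-positive fraction decreases below m
  ws <- vapply(c(400, 200, 100, 50, 10),
               function(np) sample_size_correction(np, 10000 - np)$w,
               numeric(1))
  expect_true(all(diff(ws) <= 0))
  expect_error(sample_size_correction(0, 0), "positive")
})

test_that("corrected Fisher test matches the hypergeometric oracle", {
  # depletion table: no double mutants
  tab <- matrix(c(0, 100, 100, 800), 2, byrow = TRUE)
  got <- fisher_ant_test(tab)
  # direct hypergeometric tail: X = double mutants | margins
  oracle_p <- function(tb) {
    m <- tb[1, 1] + tb[2, 1]; n <- tb[1, 2] + tb[2, 2]; k <- sum(tb[1, ])
    sum(dhyper(0:tb[1, 1], m, n, k))
  }
  expect_equal(got$p_fisher, oracle_p(tab))
  expect_lt(got$p_fisher, 1e-4)

  indep <- matrix(c(10, 90, 90, 810), 2, byrow = TRUE)
  expect_equal(fisher_ant_test(indep)$p_fisher, oracle_p(indep))
  expect_gt(fisher_ant_test(indep)$p_fisher, 0.4)

  # w = 1 identical to plain fisher.test
  corr1 <- sample_size_correction(100, 900, w_override = 1)
  expect_equal(fisher_ant_test(indep, correction = corr1)$p_fisher,
               fisher.test(indep, alternative = "less")$p.value)
  # w < 1 shrinks the context-negative row
  corr <- sample_size_correction(10, 990)
  shrunk <- fisher_ant_test(indep, correction = corr)
  expect_equal(shrunk$table[2, ], round(corr$w * indep[2, ]))
  # zero margin flagged
  degen <- matrix(c(0, 0, 5, 5), 2, byrow = TRUE)
  expect_true(is.na(fisher_ant_test(degen)$p_fisher))
})

test_that("pair filters retain exactly the qualifying rows", {
  toy <- data.frame(
    gene_a = "A", gene_b = sprintf("B%02d", 1:10),
    cdns = c( 2.0,  1.0, -2.0, -1.9,  2.2, -2.5,  1.8,  2.0, NA,   -2.0),
    ed_ratio = c(4.0, 2.0, 0.25, 0.28, 4.5, 0.2, 3.5, 4.0, NA, 0.1),
    n_mut_plus = c(3,  5,   1,    0,    2,   4,   3,   3,  2,    1),
    p_perm = c(0.005, 0.001, 0.004, 0.002, 0.003, 0.5, 0.02, 0.009,
               0.001, 0.004),
    p_fisher = c(NA, NA, 0.003, 0.001, NA, 0.2, NA, NA, NA, 0.02))
  # tumor-type mode: permutation p throughout
  tt <- filter_pair_calls(toy, mode = "tumor_type")
  expect_equal(tt$call,
               c("SYN", "not_significant", "ANT", "not_significant",
                 "not_significant", "not_significant", "not_significant",
                 "SYN", "undefined", "ANT"))
  # pancancer mode: Fisher p for ANT rows changes the outcome of row 6/10
  pc <- filter_pair_calls(toy, mode = "pancancer")
  expect_equal(pc$call[3], "ANT")       # fisher p 0.003 < 0.01
  expect_equal(pc$call[10], "not_significant")  # fisher p 0.02
  expect_equal(pc$p_used[3], 0.003)
})

test_that("subsample_stability degenerates to the full estimate", {
  sim <- shared_neutral_sim()
  ws <- ed_workspace(sim$cohort, sim$gene_models, "trinuc96")
  g <- names(which(colSums(ws$nonsilent > 0) >= 8))[1]
  b <- setdiff(ws$panel, g)[2]
  full <- cdns_estimate(NULL, g, b, "missense", ws = ws)
  ss <- subsample_stability(NULL, g, b, "missense",
                            sizes = full$n_pos, reps = 5, seed = 3, ws = ws)
  expect_equal(unique(ss$cdns), full$cdns)
  expect_equal(unique(ss$n_mut), full$n_mut_plus)
  ss2 <- subsample_stability(NULL, g, b, "missense",
                             sizes = c(2, full$n_pos), reps = 4, seed = 9,
                             ws = ws)
  ss3 <- subsample_stability(NULL, g, b, "missense",
                             sizes = c(2, full$n_pos), reps = 4, seed = 9,
                             ws = ws)
  expect_identical(ss2, ss3)
  expect_error(subsample_stability(NULL, g, b, "missense",
                                   sizes = full$n_pos + 1, ws = ws),
               "exceeds")
})

test_that("both pair orientations are evaluated and reported separately", {
  sim <- shared_neutral_sim()
  res <- call_pairs(sim$cohort,
                    pairs = data.frame(gene_a = c("G001", "G002"),
                                       gene_b = c("G002", "G001")),
                    gene_models = sim$gene_models, classes = "missense",
                    mode = "tumor_type", n_perm = 49, seed = 4)
  expect_equal(nrow(res), 2L)
  expect_false(identical(res$dnds_plus[1], res$dnds_plus[2]))
})
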