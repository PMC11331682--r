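test_that("simulate_cds produces valid, deterministic gene models", {
  m1 <- simulate_cds(5, 40, seed = 3)
  m2 <- simulate_cds(5, 40, seed = 3)
  expect_identical(lapply(m1, `[[`, "cds"), lapply(m2, `[[`, "cds"))
  for (g in m1) {
    expect_equal(nchar(g$cds), 120L)
    expect_equal(substr(g$cds, 1, 3), "ATG")
    expect_true(g$has_terminal_stop)
    # gene_model() already rejects internal stops; re-parse as a check
    expect_silent(gene_model(g$gene, g$cds))
  }
  expect_error(simulate_cds(2, 5), ">= 10")
  # opportunity tables build and conserve across a larger panel
  panel <- simulate_cds(20, 30, seed = 8)
  for (g in panel) {
    ot <- build_opportunity_table(g)
    expect_equal(sum(opportunity_counts(ot)), 3 * ot$coding_length)
  }
})

test_that("simulated cohorts are deterministic and re-parse losslessly", {
  cfg <- sim_config(seed = 15, n_samples = 60, n_genes = 6,
                    gene_length_codons = 80, mut_rate = 1e-4,
                    indel_rate = 1e-5,
                    ed_pairs = data.frame(gene_a = "G001", gene_b = "G002",
                                          class = "missense", cdns_true = 1,
                                          prevalence = 0.3))
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  f1 <- withr::local_tempfile(fileext = ".maf")
  f2 <- withr::local_tempfile(fileext = ".maf")
  write_maf(s1$cohort, f1); write_maf(s2$cohort, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical

  # lossless round trip through the MAF reader (roster needs the explicit
  # sample list because some simulated samples may carry no mutations)
  back <- read_maf(f1, sample_list = s1$cohort$samples)
  expect_equal(back$N, s1$cohort$N)
  expect_equal(
    as.data.frame(back$records[order(sample_id, gene, position, alt_allele,
                                     t_alt_count)]),
    as.data.frame(s1$cohort$records[order(sample_id, gene, position,
                                          alt_allele, t_alt_count)]))
})

test_that("context status is realized as actual records at the programmed prevalence", {
  pairs <- data.frame(gene_a = c("G001", "G002"), gene_b = c("G003", "G004"),
                      class = "missense", cdns_true = c(2, -2),
                      prevalence = c(0.2, 0.4))
  cfg <- sim_config(seed = 44, n_samples = 800, n_genes = 6,
                    gene_length_codons = 150, mut_rate = 5e-5,
                    ed_pairs = pairs)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth$samples
  for (g in c("G001", "G002")) {
    ctx <- split_by_context(sim$cohort, g)
    # the MAF-derived split equals the generator's hidden status exactly
    expect_setequal(ctx$positive_samples,
                    truth$sample_id[truth[[paste0("ctx_", g)]]])
  }
  prev <- sim$truth$pairs$realized_prevalence
  expect_lt(abs(prev[1] - 0.2), 0.05)
  expect_lt(abs(prev[2] - 0.4), 0.05)
})

test_that("generated omegas are recovered by the estimator", {
  # per-gene regression of estimated log omega on true log omega
  om <- data.frame(gene = sprintf("G%03d", 1:10), class = "missense",
                   omega = c(0.5, 0.75, 1, 1, 1.5, 2, 3, 4, 6, 8))
  cfg <- sim_config(seed = 58, n_samples = 1000, n_genes = 14,
                    gene_length_codons = 400, mut_rate = 1e-4, omega = om)
  sim <- simulate_cohort(cfg)
  tabs <- lapply(sim$gene_models, build_opportunity_table,
                 granularity = "trinuc96")
  m <- fit_substitution_model(sim$cohort, sim$gene_models, "trinuc96",
                              tables = tabs)
  est <- vapply(om$gene, function(g)
    dnds(sim$cohort, sim$gene_models[[g]], m, tabs[[g]])$omega[1],
    numeric(1))
  fit <- lm(log(est) ~ log(om$omega))
  expect_gt(coef(fit)[2], 0.8)
  expect_lt(coef(fit)[2], 1.2)
})

test_that("hypermutators inflate per-sample burden as configured", {
  cfg <- sim_config(seed = 70, n_samples = 400, n_genes = 6,
                    gene_length_codons = 150, mut_rate = 1e-4,
                    hypermutator_fraction = 0.1, hypermutator_factor = 10)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth$samples
  tmb <- table(factor(sim$cohort$records$sample_id[
    sim$cohort$records$impact_class %in% nonsilent_classes()],
    levels = truth$sample_id))
  hyper <- truth$hypermutator
  expect_gt(sum(hyper), 10)
  expect_gt(mean(tmb[hyper]) / mean(tmb[!hyper]), 4)
})

test_that("write_simulation emits a complete, re-readable file set", {
  cfg <- sim_config(seed = 5, n_samples = 30, n_genes = 4,
                    gene_length_codons = 60, mut_rate = 1e-4,
                    ed_pairs = data.frame(gene_a = "G001", gene_b = "G002",
                                          class = "missense",
                                          cdns_true = 1, prevalence = 0.3))
  sim <- simulate_cohort(cfg)
  panel <- simulate_panel(
    data.frame(context_gene = "G001", target_gene = "G002",
               modality = "dependency", effect = 0.5),
    n_lines = 10, seed = 2)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, panel = panel)
  expect_setequal(
    list.files(dir),
    c("cohort.maf", "cds.fasta", "truth_genes.tsv", "truth_samples.tsv",
      "truth_pairs.tsv", "panel_mutations.tsv", "panel_viability.tsv",
      "panel_tumor_types.tsv", "truth_panel.tsv"))
  models <- read_cds_fasta(file.path(dir, "cds.fasta"))
  expect_equal(names(models), names(sim$gene_models))
  panel2 <- read_panel_tables(
    file.path(dir, "panel_mutations.tsv"),
    viability = file.path(dir, "panel_viability.tsv"),
    tumor_types = file.path(dir, "panel_tumor_types.tsv"))
  expect_equal(panel2$mutations, panel$panel$mutations)
})
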