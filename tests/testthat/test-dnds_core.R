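test_that("opportunity tables match the codon-enumeration oracle", {
  # hand-enumerable single codons behind a start codon are checked through
  # the oracle, not hard-coded beyond the two canonical examples
  for (codon in c("ATG", "TGG", "AAA", "CTT", "TAT")) {
    gm <- gene_model("X", paste0("ATG", codon, "TAA"))
    ot <- build_opportunity_table(gm, "uniform")
    got <- table(factor(ot$sites[pos > 3, class],
                        levels = c("synonymous", "missense", "nonsense")))
    expect_equal(as.numeric(got), as.numeric(oracle_codon_classes(codon)),
                 info = codon)
  }
  # canonical examples: ATG -> 9 missense; TGG -> 7 missense + 2 nonsense
  expect_equal(unname(oracle_codon_classes("ATG")), c(0, 9, 0))
  expect_equal(unname(oracle_codon_classes("TGG")), c(0, 7, 2))
})

test_that("class counts conserve 3 x coding length at every granularity", {
  models <- simulate_cds(10, 50, seed = 9)
  for (gran in c("uniform", "base6", "base12", "trinuc96", "trinuc192")) {
    for (m in models[1:3]) {
      ot <- build_opportunity_table(m, gran)
      oc <- opportunity_counts(ot)
      expect_equal(sum(oc), 3 * ot$coding_length + ot$splice_opportunity)
    }
  }
  # full-panel sweep at the default granularity
  for (m in models) {
    ot <- build_opportunity_table(m)
    expect_equal(sum(opportunity_counts(ot)), 3 * ot$coding_length)
  }
})

test_that("substitution-model fitting is the stated ML arithmetic", {
  # 1 synonymous mutation, uniform rate = n_syn / (L_syn * N)
  models <- toy_models()
  cohort <- toy_cohort(list(
    list("S1", "GA", "synonymous"), list("S1", "GA", "synonymous"),
    list("S2", "GB", "synonymous"), list("S2", "GA", "missense")),
    roster = sprintf("S%d", 1:10))
  m <- fit_substitution_model(cohort, models, "uniform")
  L_syn <- sum(vapply(models, function(g)
    opportunity_counts(build_opportunity_table(g, "uniform"))["synonymous"],
    numeric(1)))
  expect_equal(unname(m$rates["all"]), 3 / (L_syn * 10))
  expect_equal(m$total_exposure, 10L)

  empty <- toy_cohort(list(list("S1", "GA", "missense")),
                      roster = c("S1", "S2"))
  expect_error(fit_substitution_model(empty, models, "uniform"),
               "no synonymous")
})

test_that("uniform dnds equals the closed form and the site-level oracle", {
  sim <- shared_neutral_sim()
  cohort <- sim$cohort
  models <- sim$gene_models
  m <- fit_substitution_model(cohort, models, "uniform")
  cds_list <- setNames(lapply(models, `[[`, "cds"), names(models))
  for (g in names(models)[c(1, 5, 9)]) {
    d <- dnds(cohort, models[[g]], m)
    for (cls in c("missense", "truncating")) {
      want <- oracle_uniform_dnds(cds_list, as.data.frame(cohort$records),
                                  g, cls)
      got <- d$omega[d$class == cls]
      if (d$n_obs[d$class == cls] == 0) {
        expect_equal(got, 0)
      } else {
        expect_equal(got, want, tolerance = 1e-9)
      }
    }
  }
})

test_that("zero observed counts give omega 0, zero expectation is flagged", {
  models <- toy_models()
  cohort <- toy_cohort(list(list("S1", "GA", "synonymous")),
                       roster = sprintf("S%d", 1:5))
  m <- fit_substitution_model(cohort, models, "uniform")
  d <- dnds(cohort, models[["GB"]], m)
  expect_equal(d$omega[d$class == "truncating"], 0)
  expect_equal(d$n_obs[d$class == "truncating"], 0)
})

test_that("indel ratio is the stated per-length arithmetic", {
  # gene with 4 indels over its CDS; background 1 indel per equal length
  models <- simulate_cds(3, 100, seed = 2)   # 300 nt each
  trip <- c(rep(list(list("S1", "G001", "frameshift_indel")), 4),
            list(list("S2", "G002", "inframe_indel")))
  cohort <- toy_cohort(trip, models, roster = c("S1", "S2"))
  d <- dnds_indel(cohort, "G001", c("G002", "G003"), models)
  # (4 / 300) / (1 / 600) = 8
  expect_equal(d$omega, 8)
  expect_equal(d$class, "indel")

  none <- toy_cohort(list(list("S1", "G001", "frameshift_indel")), models,
                     roster = c("S1", "S2"))
  flagged <- dnds_indel(none, "G001", c("G002", "G003"), models)
  expect_true(is.na(flagged$omega))
  expect_match(flagged$flag, "undefined_background")

  zero <- toy_cohort(list(list("S1", "G002", "frameshift_indel")), models,
                     roster = c("S1", "S2"))
  expect_equal(dnds_indel(zero, "G001", c("G002", "G003"), models)$omega, 0)
})

test_that("adding a nonsynonymous observation never decreases omega", {
  sim <- shared_neutral_sim()
  m <- fit_substitution_model(sim$cohort, sim$gene_models, "uniform")
  g <- sim$gene_models[[3]]
  base <- dnds(sim$cohort, g, m)
  extra <- rbind(as.data.frame(sim$cohort$records),
                 data.frame(sample_id = sim$cohort$samples$sample_id[1],
                            gene = g$gene, impact_class = "missense",
                            ref_allele = "A", alt_allele = "C",
                            t_alt_count = 10L, t_ref_count = 90L,
                            tumor_type = NA_character_, position = 4L))
  bumped <- dnds(new_cohort(extra, sim$cohort$samples), g, m)
  expect_gte(bumped$omega[bumped$class == "missense"],
             base$omega[base$class == "missense"])
})

test_that("driver selection finds programmed positives and little else", {
  om <- data.frame(gene = rep(sprintf("G%03d", 1:5), each = 2),
                   class = rep(c("missense", "truncating"), 5), omega = 5)
  cfg <- sim_config(seed = 31, n_samples = 800, n_genes = 20,
                    gene_length_codons = 300, mut_rate = 5e-5, omega = om)
  sim <- simulate_cohort(cfg)
  m <- fit_substitution_model(sim$cohort, sim$gene_models, "trinuc96",
                              tables = NULL)
  sel <- select_driver_genes(sim$cohort, sim$gene_models, m)
  hits <- sel$gene[sel$selected]
  expect_gte(sum(sprintf("G%03d", 1:5) %in% hits), 4)
  expect_lte(sum(!hits %in% sprintf("G%03d", 1:5)), 2)
  expect_equal(nrow(select_driver_genes(sim$cohort, list(), m)), 0L)
})

test_that("granularity mismatch between tables and model is refused", {
  models <- toy_models()
  tabs <- lapply(models, build_opportunity_table, granularity = "uniform")
  cohort <- toy_cohort(list(list("S1", "GA", "synonymous")),
                       roster = c("S1", "S2"))
  expect_error(
    fit_substitution_model(cohort, models, "trinuc96", tables = tabs),
    "granularity")
})
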