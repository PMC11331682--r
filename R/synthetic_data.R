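# Synthetic cohorts and cell-line panels with known ground truth.
#
# The generative model is the estimand's mirror: per sample, context-gene
# mutation status is drawn Bernoulli(prevalence) and realized as an actual
# non-silent record, then per-gene per-class counts are Poisson with mean
# burden x rate x opportunity x omega_eff, where omega_eff multiplies the
# partner gene's class omega by 2^cdns_true in context-positive samples.
# Synonymous mutations always use omega = 1. By construction the programmed
# cdns_true equals the estimand.

#' Simulation configuration
#'
#' Defaults describe a 1,000-sample, 50-gene panel cohort at a typical
#' exome-wide somatic burden (`mut_rate` 2e-5 per opportunity per sample,
#' about 6 mutations/Mb across the panel after the lognormal burden
#' spread). High-burden fixtures (MSI/melanoma-grade) raise `mut_rate`.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_samples Cohort size.
#' @param tumor_types Named proportions of tumor-type labels.
#' @param n_genes,gene_length_codons Panel shape when `gene_models` is NULL.
#' @param gene_models Optional pre-built named list of gene models.
#' @param mut_rate Substitution rate per opportunity per sample (at burden
#'   multiplier 1).
#' @param indel_rate Indel rate per coding base per sample.
#' @param burden_sdlog Lognormal sd of the per-sample burden multiplier
#'   (mean fixed at 1).
#' @param hypermutator_fraction,hypermutator_factor Fraction of samples
#'   whose burden is multiplied by the factor.
#' @param spectrum Optional named category weights (see
#'   [sub_categories()]); default uniform.
#' @param granularity Category scheme used for sites and the spectrum.
#' @param omega Optional data.frame `(gene, class, omega)` overriding the
#'   neutral default of 1 (classes `missense`, `truncating`, `indel`).
#' @param ed_pairs Optional data.frame `(gene_a, gene_b, class, cdns_true,
#'   prevalence)` of programmed evolutionary dependencies. Context genes
#'   carry only synonymous background; their non-silent mutations are
#'   exactly the forced context records, so prevalence is exact.
#' @param depth_mean Mean sequencing depth (Poisson).
#' @param clonal_shape,subclonal_shape Beta shape pairs for clonal and
#'   subclonal VAF.
#' @param subclonal_genes Genes whose mutations are drawn subclonal
#'   (default: none — all genes clonal; list context genes here to emulate
#'   subclonal mutation contexts).
#' @param frameshift_fraction Fraction of indels that are 1-bp frameshifts
#'   (the rest are 3-bp in-frame deletions).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_samples = 1000,
                       tumor_types = c(TTA = 0.6, TTB = 0.4),
                       n_genes = 50, gene_length_codons = 500,
                       gene_models = NULL,
                       mut_rate = 2e-5, indel_rate = 2e-6,
                       burden_sdlog = 0.5,
                       hypermutator_fraction = 0, hypermutator_factor = 10,
                       spectrum = NULL, granularity = "uniform",
                       omega = NULL, ed_pairs = NULL,
                       depth_mean = 80,
                       clonal_shape = c(20, 20), subclonal_shape = c(4, 16),
                       subclonal_genes = character(),
                       frameshift_fraction = 0.8) {
  stopifnot(n_samples >= 1, mut_rate >= 0, indel_rate >= 0,
            abs(sum(tumor_types) - 1) < 1e-8)
  if (!is.null(ed_pairs)) {
    ed_pairs <- as.data.frame(ed_pairs)
    stopifnot(all(c("gene_a", "gene_b", "class", "cdns_true",
                    "prevalence") %in% names(ed_pairs)),
              all(is.finite(ed_pairs$cdns_true)),
              all(ed_pairs$prevalence > 0 & ed_pairs$prevalence < 1))
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate coding sequences
#'
#' Each gene starts with ATG, has no internal stop, and ends with a stop
#' codon. Deterministic per seed.
#'
#' @param n_genes Number of genes (named `G001`, ...).
#' @param length_codons Codons per gene including start and stop (>= 10).
#' @param seed Integer seed.
#' @return Named list of [gene_model()] objects.
#' @export
simulate_cds <- function(n_genes, length_codons, seed = 1) {
  if (length_codons < 10) stop("length_codons must be >= 10")
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  stops <- names(code)[code == "*"]
  withr::with_seed(seed, {
    models <- lapply(seq_len(n_genes), function(i) {
      body <- sample(sense, length_codons - 2L, replace = TRUE)
      cds <- paste(c("ATG", body, sample(stops, 1L)), collapse = "")
      gene_model(sprintf("G%03d", i), cds)
    })
  })
  names(models) <- vapply(models, `[[`, character(1), "gene")
  models
}

# Draw read counts for a set of records given clonality flags.
.draw_reads <- function(n, clonal, config) {
  vaf <- numeric(n)
  vaf[clonal] <- rbeta(sum(clonal), config$clonal_shape[1],
                       config$clonal_shape[2])
  vaf[!clonal] <- rbeta(sum(!clonal), config$subclonal_shape[1],
                        config$subclonal_shape[2])
  depth <- pmax(rpois(n, config$depth_mean), 2L)
  alt <- pmax(rbinom(n, depth, vaf), 1L)   # a called variant has >= 1 read
  list(alt = as.integer(alt), ref = as.integer(depth - alt))
}

#' Simulate a mutation cohort with known ground truth
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort`: `cohort` (a [new_cohort()]),
#'   `gene_models`, `tables` (opportunity tables), and `truth` with
#'   `genes` (per-gene per-class true omega), `pairs` (programmed pairs
#'   with realized prevalence), `samples` (burden, hypermutator and
#'   context-status columns).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(config) {
  models <- config$gene_models
  if (is.null(models))
    models <- simulate_cds(config$n_genes, config$gene_length_codons,
                           seed = sample.int(2^31 - 1, 1))
  panel <- names(models)
  tables <- lapply(models, build_opportunity_table,
                   granularity = config$granularity)
  cats <- sub_categories(config$granularity)

  # category rates normalized so the mean per-opportunity rate = mut_rate
  w <- if (is.null(config$spectrum)) setNames(rep(1, length(cats)), cats)
       else config$spectrum[cats]
  rate_cat <- config$mut_rate * length(cats) * w / sum(w)

  N <- config$n_samples
  ids <- sprintf("S%05d", seq_len(N))
  tt <- sample(names(config$tumor_types), N, replace = TRUE,
               prob = config$tumor_types)
  burden <- rlnorm(N, meanlog = -config$burden_sdlog^2 / 2,
                   sdlog = config$burden_sdlog)
  hyper <- runif(N) < config$hypermutator_fraction
  burden[hyper] <- burden[hyper] * config$hypermutator_factor

  # per-gene true omega lookup
  omega_of <- function(g, cls) {
    if (!is.null(config$omega)) {
      hit <- config$omega$gene == g & config$omega$class == cls
      if (any(hit)) return(config$omega$omega[hit][1])
    }
    1
  }

  ed <- config$ed_pairs
  context_genes <- if (is.null(ed)) character(0) else unique(ed$gene_a)
  ctx_status <- matrix(FALSE, nrow = N, ncol = length(context_genes),
                       dimnames = list(ids, context_genes))
  for (g in context_genes) {
    prev <- ed$prevalence[ed$gene_a == g][1]
    ctx_status[, g] <- runif(N) < prev
  }

  sub_classes <- c(synonymous = "synonymous", missense = "missense",
                   truncating = "nonsense")
  rec_list <- list()
  truth_genes <- list()

  for (g in panel) {
    tab <- tables[[g]]
    is_context <- g %in% context_genes
    # expected substitution counts per class per opportunity-category sum
    base_mu <- vapply(sub_classes, function(site_cls) {
      sum(rate_cat * tab$counts[site_cls, ])
    }, numeric(1))
    names(base_mu) <- names(sub_classes)

    for (cls in names(sub_classes)) {
      om <- if (cls == "synonymous") 1 else omega_of(g, cls)
      if (is_context && cls != "synonymous") next  # context genes: forced only
      mult <- rep(om, N)
      if (!is.null(ed) && cls != "synonymous") {
        for (k in which(ed$gene_b == g & ed$class == cls)) {
          on <- ctx_status[, ed$gene_a[k]]
          mult[on] <- mult[on] * 2^ed$cdns_true[k]
        }
      }
      counts <- rpois(N, burden * base_mu[cls] * mult)
      tot <- sum(counts)
      if (tot == 0L) next
      site_cls <- sub_classes[[cls]]
      pool <- tab$sites[class == site_cls]
      if (nrow(pool) == 0L)
        stop(sprintf("gene %s has no %s opportunity", g, site_cls))
      prob <- rate_cat[pool$category]
      pick <- pool[sample.int(nrow(pool), tot, replace = TRUE, prob = prob)]
      rec_list[[length(rec_list) + 1L]] <- data.table(
        sample_id = rep(ids, counts), gene = g,
        impact_class = if (cls == "truncating") "nonsense" else cls,
        ref_allele = pick$ref, alt_allele = pick$alt, position = pick$pos)
    }

    # indels
    om_ind <- if (is_context) 0 else omega_of(g, "indel")
    mult <- rep(om_ind, N)
    if (!is.null(ed)) {
      for (k in which(ed$gene_b == g & ed$class == "indel")) {
        on <- ctx_status[, ed$gene_a[k]]
        mult[on] <- mult[on] * 2^ed$cdns_true[k]
      }
    }
    L <- nchar(models[[g]]$cds)
    counts <- rpois(N, burden * config$indel_rate * L * mult)
    tot <- sum(counts)
    if (tot > 0L) {
      fs <- runif(tot) < config$frameshift_fraction
      pos <- sample.int(L - 3L, tot, replace = TRUE)
      s <- strsplit(models[[g]]$cds, "")[[1]]
      ref <- ifelse(fs, s[pos],
                    paste0(s[pos], s[pos + 1L], s[pos + 2L]))
      rec_list[[length(rec_list) + 1L]] <- data.table(
        sample_id = rep(ids, counts), gene = g,
        impact_class = ifelse(fs, "frameshift_indel", "inframe_indel"),
        ref_allele = ref, alt_allele = "-", position = pos)
    }

    truth_genes[[g]] <- data.table(
      gene = g, class = c("missense", "truncating", "indel"),
      omega_true = if (is_context) c(NA_real_, NA_real_, NA_real_)
                   else c(omega_of(g, "missense"), omega_of(g, "truncating"),
                          omega_of(g, "indel")))
  }

  # forced context mutations: one missense record per context-positive sample
  for (g in context_genes) {
    on <- which(ctx_status[, g])
    if (!length(on)) next
    pool <- tables[[g]]$sites[class == "missense"]
    pick <- pool[sample.int(nrow(pool), length(on), replace = TRUE)]
    rec_list[[length(rec_list) + 1L]] <- data.table(
      sample_id = ids[on], gene = g, impact_class = "missense",
      ref_allele = pick$ref, alt_allele = pick$alt, position = pick$pos)
  }

  records <- rbindlist(rec_list)
  if (nrow(records) == 0L)
    stop("simulation produced no mutations; raise mut_rate or n_samples")
  clonal <- !(records$gene %in% config$subclonal_genes)
  reads <- .draw_reads(nrow(records), clonal, config)
  records[, `:=`(t_alt_count = reads$alt, t_ref_count = reads$ref)]
  sample_tt <- setNames(tt, ids)
  records[, tumor_type := unname(sample_tt[sample_id])]
  setorder(records, sample_id, gene, position, alt_allele, impact_class)

  samples <- data.table(sample_id = ids, tumor_type = tt,
                        burden = burden, hypermutator = hyper)
  truth_pairs <- NULL
  if (!is.null(ed)) {
    truth_pairs <- as.data.table(ed)
    truth_pairs[, realized_prevalence :=
                  vapply(gene_a, function(g) mean(ctx_status[, g]),
                         numeric(1))]
    for (g in context_genes)
      samples[, (paste0("ctx_", g)) := ctx_status[, g]]
  }

  structure(list(
    cohort = new_cohort(records,
                        samples = samples[, .(sample_id, tumor_type)]),
    gene_models = models, tables = tables,
    truth = list(genes = as.data.frame(rbindlist(truth_genes)),
                 pairs = if (is.null(truth_pairs)) NULL
                         else as.data.frame(truth_pairs),
                 samples = as.data.frame(samples))),
    class = "sim_cohort")
}

#' Simulate a cell-line panel with programmed effect sizes
#'
#' Mutation status per gene is Bernoulli; viability of a knockout gene is
#' `baseline + effect x context_indicator + Normal(0, sd)`, IC50 likewise.
#' With `noise_sd = 0` the analysis functions recover the programmed
#' effects exactly.
#'
#' @param pairs data.frame with `context_gene`, `target_gene`, `modality`
#'   (`"dependency"` or `"drug"`), `effect`, and `drug` for drug rows.
#' @param n_lines Number of cell lines.
#' @param context_freq,target_freq Mutation frequencies of context and
#'   target genes.
#' @param viability_baseline,ic50_baseline Group baselines.
#' @param noise_sd Gaussian noise sd.
#' @param tumor_type Single label applied to all lines.
#' @param seed Integer seed.
#' @return List of class `sim_panel`: `panel` (a [cell_line_panel()]) and
#'   `truth` (the programmed pairs).
#' @export
simulate_panel <- function(pairs, n_lines = 40, context_freq = 0.5,
                           target_freq = 0.5, viability_baseline = -1,
                           ic50_baseline = 2, noise_sd = 0.2,
                           tumor_type = "SIM", seed = 1) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("context_gene", "target_gene", "modality", "effect") %in%
                  names(pairs)))
  withr::with_seed(seed, {
    lines <- sprintf("CL%03d", seq_len(n_lines))
    genes <- unique(c(pairs$context_gene, pairs$target_gene))
    mut <- vapply(genes, function(g) {
      freq <- if (g %in% pairs$context_gene) context_freq else target_freq
      as.integer(runif(n_lines) < freq)
    }, integer(n_lines))
    rownames(mut) <- lines
    # every target gene needs mutant lines in both context groups
    via <- NULL
    dep <- pairs[pairs$modality == "dependency", ]
    if (nrow(dep)) {
      via <- matrix(NA_real_, n_lines, length(unique(dep$target_gene)),
                    dimnames = list(lines, unique(dep$target_gene)))
      for (i in seq_len(nrow(dep))) {
        tg <- dep$target_gene[i]; cg <- dep$context_gene[i]
        via[, tg] <- viability_baseline + dep$effect[i] * mut[, cg] +
          rnorm(n_lines, 0, noise_sd)
      }
    }
    ic <- NULL
    dr <- pairs[pairs$modality == "drug", ]
    if (nrow(dr)) {
      if (!"drug" %in% names(dr)) stop("drug rows need a drug column")
      ic <- rbindlist(lapply(seq_len(nrow(dr)), function(i) {
        data.table(cell_line = lines, drug = dr$drug[i],
                   target_gene = dr$target_gene[i],
                   ic50 = ic50_baseline +
                     dr$effect[i] * mut[, dr$context_gene[i]] +
                     rnorm(n_lines, 0, noise_sd))
      }))
    }
    panel <- cell_line_panel(mut, via, ic,
                             tumor_type = setNames(rep(tumor_type, n_lines),
                                                   lines))
  })
  structure(list(panel = panel, truth = pairs), class = "sim_panel")
}

#' Write a simulated cohort (and optional panel) to plain-text files
#'
#' Produces `cohort.maf`, `cds.fasta`, `truth_genes.tsv`,
#' `truth_samples.tsv` (+ `truth_pairs.tsv` when pairs were programmed) in
#' `dir`, and panel tables when a `sim_panel` is supplied.
#'
#' @param sim A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @param panel Optional `sim_panel`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, panel = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_maf(sim$cohort, file.path(dir, "cohort.maf"))
  write_cds_fasta(sim$gene_models, file.path(dir, "cds.fasta"))
  write_results(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_results(sim$truth$samples, file.path(dir, "truth_samples.tsv"))
  if (!is.null(sim$truth$pairs))
    write_results(sim$truth$pairs, file.path(dir, "truth_pairs.tsv"))
  if (!is.null(panel)) {
    p <- panel$panel
    mut <- data.table(cell_line = rownames(p$mutations), p$mutations)
    write_results(mut, file.path(dir, "panel_mutations.tsv"))
    if (!is.null(p$viability)) {
      via <- data.table(cell_line = rownames(p$viability), p$viability)
      write_results(via, file.path(dir, "panel_viability.tsv"))
    }
    if (!is.null(p$ic50))
      write_results(p$ic50, file.path(dir, "panel_ic50.tsv"))
    if (!is.null(p$tumor_type))
      write_results(data.table(cell_line = names(p$tumor_type),
                               tumor_type = unname(p$tumor_type)),
                    file.path(dir, "panel_tumor_types.tsv"))
    write_results(panel$truth, file.path(dir, "truth_panel.tsv"))
  }
  invisible(dir)
}
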