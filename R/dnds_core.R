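# Per-gene, per-class dN/dS estimation with a synonymous-calibrated Poisson
# model. Replaces the covariate-regression machinery of full driver-discovery
# packages with an explicit opportunity-table construction: every possible
# single-nucleotide substitution in the CDS is enumerated and classified by
# translating the mutated codon.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")
.GRANULARITIES <- c("uniform", "base6", "base12", "trinuc96", "trinuc192")

# dN/dS classes reported by dnds(): truncating pools nonsense + splice_site.
.DNDS_CLASSES <- c("missense", "truncating", "indel")

#' Substitution-rate categories for a granularity
#'
#' @param granularity One of `"uniform"` (1 category), `"base12"` /
#'   `"base6"` (raw / strand-collapsed base substitutions) or
#'   `"trinuc192"` / `"trinuc96"` (raw / strand-collapsed trinucleotide
#'   context x substitution).
#' @return Character vector of category labels.
#' @export
sub_categories <- function(granularity = "trinuc96") {
  granularity <- match.arg(granularity, .GRANULARITIES)
  pyr <- c("C", "T")
  switch(granularity,
    uniform = "all",
    base12 = {
      g <- expand.grid(ref = .BASES, alt = .BASES, stringsAsFactors = FALSE)
      g <- g[g$ref != g$alt, ]
      sort(paste0(g$ref, ">", g$alt))
    },
    base6 = {
      g <- expand.grid(ref = pyr, alt = .BASES, stringsAsFactors = FALSE)
      g <- g[g$ref != g$alt, ]
      sort(paste0(g$ref, ">", g$alt))
    },
    trinuc192 = {
      g <- expand.grid(left = .BASES, ref = .BASES, alt = .BASES,
                       right = .BASES, stringsAsFactors = FALSE)
      g <- g[g$ref != g$alt, ]
      sort(paste0(g$left, "[", g$ref, ">", g$alt, "]", g$right))
    },
    trinuc96 = {
      g <- expand.grid(left = .BASES, ref = pyr, alt = .BASES,
                       right = .BASES, stringsAsFactors = FALSE)
      g <- g[g$ref != g$alt, ]
      sort(paste0(g$left, "[", g$ref, ">", g$alt, "]", g$right))
    })
}

# Vectorized category assignment. Purine references are strand-collapsed by
# reverse complement for base6/trinuc96.
.classify_category <- function(left, ref, alt, right, granularity) {
  switch(granularity,
    uniform = rep("all", length(ref)),
    base12 = paste0(ref, ">", alt),
    base6 = {
      flip <- ref %in% c("A", "G")
      ifelse(flip, paste0(.COMP[ref], ">", .COMP[alt]),
             paste0(ref, ">", alt))
    },
    trinuc192 = paste0(left, "[", ref, ">", alt, "]", right),
    trinuc96 = {
      flip <- ref %in% c("A", "G")
      ifelse(flip,
             paste0(.COMP[right], "[", .COMP[ref], ">", .COMP[alt], "]",
                    .COMP[left]),
             paste0(left, "[", ref, ">", alt, "]", right))
    })
}

#' Enumerate and classify every possible substitution in a gene
#'
#' All 3 possible single-nucleotide changes at each coding position are
#' classified by translating the mutated codon (same amino acid =
#' synonymous; to stop = nonsense; otherwise missense). A terminal stop
#' codon, when present, is excluded from counting, so the conservation law
#' is: class counts sum to 3 x coding length. Trinucleotide context at the
#' CDS boundaries is completed by padding with `A` (synthetic single-exon
#' genes carry no genomic flanks). Deterministic.
#'
#' @param gene A [gene_model()].
#' @param granularity See [sub_categories()]; default strand-collapsed
#'   trinucleotide (96 categories).
#' @return An object of class `opportunity_table`: list with `sites` (one
#'   row per possible substitution: `pos`, `ref`, `alt`, `class`,
#'   `category`), `counts` (class x category matrix), `coding_length`,
#'   `splice_opportunity`.
#' @export
build_opportunity_table <- function(gene, granularity = "trinuc96") {
  granularity <- match.arg(granularity, .GRANULARITIES)
  stopifnot(inherits(gene, "gene_model"))
  s <- strsplit(gene$cds, "")[[1]]
  L <- length(s)
  coding_len <- if (gene$has_terminal_stop) L - 3L else L
  if (coding_len < 3L) stop("gene model too short to enumerate")

  pos <- rep(seq_len(coding_len), each = 3L)
  ref <- s[pos]
  alt <- as.vector(vapply(s[seq_len(coding_len)],
                          function(b) .BASES[.BASES != b], character(3)))
  codon_start <- pos - (pos - 1L) %% 3L
  within <- (pos - 1L) %% 3L + 1L
  c1 <- s[codon_start]; c2 <- s[codon_start + 1L]; c3 <- s[codon_start + 2L]
  m1 <- ifelse(within == 1L, alt, c1)
  m2 <- ifelse(within == 2L, alt, c2)
  m3 <- ifelse(within == 3L, alt, c3)
  code <- Biostrings::GENETIC_CODE
  aa0 <- unname(code[paste0(c1, c2, c3)])
  aa1 <- unname(code[paste0(m1, m2, m3)])
  cls <- ifelse(aa1 == aa0, "synonymous",
                ifelse(aa1 == "*", "nonsense", "missense"))
  left <- ifelse(pos > 1L, s[pmax(pos - 1L, 1L)], "A")
  right <- ifelse(pos < L, s[pmin(pos + 1L, L)], "A")
  cat_lab <- .classify_category(left, ref, alt, right, granularity)

  sites <- data.table(pos = pos, ref = ref, alt = alt, class = cls,
                      category = cat_lab)
  cats <- sub_categories(granularity)
  counts <- table(factor(sites$class,
                         levels = c("synonymous", "missense", "nonsense")),
                  factor(sites$category, levels = cats))
  counts <- matrix(as.integer(counts), nrow = 3L,
                   dimnames = list(c("synonymous", "missense", "nonsense"),
                                   cats))
  structure(list(gene = gene$gene, granularity = granularity, sites = sites,
                 counts = counts, coding_length = coding_len,
                 splice_opportunity = gene$splice_opportunity,
                 cds_length = L),
            class = "opportunity_table")
}

#' Class totals of an opportunity table
#'
#' @param table An opportunity table.
#' @return Named numeric vector: synonymous, missense, nonsense,
#'   splice_site.
#' @export
opportunity_counts <- function(table) {
  c(rowSums(table$counts), splice_site = table$splice_opportunity)
}

.tables_for <- function(gene_models, granularity, tables = NULL) {
  if (!is.null(tables)) {
    gran <- unique(vapply(tables, `[[`, character(1), "granularity"))
    if (!identical(gran, granularity))
      stop(sprintf(
        "supplied opportunity tables use granularity '%s' but '%s' was requested",
        paste(gran, collapse = ","), granularity))
    return(tables)
  }
  out <- lapply(gene_models, build_opportunity_table,
                granularity = granularity)
  names(out) <- vapply(gene_models, `[[`, character(1), "gene")
  out
}

# Assign each substitution record of panel genes to its site category via a
# (gene, pos, alt) lookup in the opportunity tables. Returns the records
# with a `category` column; unmatched rows are dropped with a warning.
.site_categories <- function(records, tables) {
  per_gene <- rbindlist(lapply(names(tables), function(g) {
    s <- tables[[g]]$sites
    data.table(gene = g, pos = s$pos, alt = s$alt, category = s$category)
  }))
  setkey(per_gene, gene, pos, alt)
  rec <- copy(records)[, .(gene, pos = position, alt = alt_allele)]
  hit <- per_gene[rec, on = c("gene", "pos", "alt")]
  if (anyNA(hit$category)) {
    n <- sum(is.na(hit$category))
    warning(sprintf(
      "%d substitution record(s) did not match any site in the gene models; dropped from rate fitting",
      n))
  }
  hit$category
}

#' Fit a substitution-rate model from synonymous mutations
#'
#' Maximum-likelihood per-category rate = synonymous count in the category /
#' (synonymous opportunity in the category x subset size). Only synonymous
#' mutations inform the fit (the neutral proxy). Categories without
#' synonymous opportunity get an `NA` rate (never used in expectations).
#'
#' @param cohort Cohort subset to fit on.
#' @param gene_models Named list of gene models defining the panel.
#' @param granularity See [sub_categories()]. Granularities other than
#'   `"uniform"` require records with `position` and `alt_allele`.
#' @param tables Optional precomputed opportunity tables.
#' @return Object of class `substitution_model`: `granularity`, `rates`
#'   (per category, per opportunity per sample), `syn_counts`, `syn_opp`,
#'   `total_exposure` (the subset size).
#' @export
fit_substitution_model <- function(cohort, gene_models,
                                   granularity = "trinuc96", tables = NULL) {
  granularity <- match.arg(granularity, .GRANULARITIES)
  tables <- .tables_for(gene_models, granularity, tables)
  panel <- names(tables)
  syn <- cohort$records[impact_class == "synonymous" & gene %in% panel]
  if (nrow(syn) == 0L)
    stop(paste("no synonymous mutations in the cohort subset for this panel;",
               "use a coarser granularity or pool more genes/samples"))
  cats <- sub_categories(granularity)
  syn_opp <- Reduce(`+`, lapply(tables, function(t) t$counts["synonymous", ]))
  syn_opp <- setNames(as.numeric(syn_opp), cats)
  if (granularity == "uniform") {
    syn_counts <- setNames(nrow(syn), "all")
  } else {
    if (anyNA(syn$position) || anyNA(syn$alt_allele))
      stop("records lack position/alt_allele; use granularity = 'uniform'")
    cat_lab <- .site_categories(syn, tables)
    syn_counts <- table(factor(cat_lab, levels = cats))
    syn_counts <- setNames(as.numeric(syn_counts), cats)
  }
  N <- cohort$N
  rates <- setNames(ifelse(syn_opp > 0, syn_counts / (syn_opp * N),
                           NA_real_), cats)
  structure(list(granularity = granularity, rates = rates,
                 syn_counts = syn_counts, syn_opp = syn_opp,
                 total_exposure = N),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf(
    "<substitution_model> granularity=%s, %d categories, %d synonymous mutations over %d samples\n",
    x$granularity, length(x$rates), sum(x$syn_counts), x$total_exposure))
  invisible(x)
}

# Expected count of a substitution class for one gene under the rate model,
# for `n` samples. Splice opportunity enters via the uniform-equivalent mean
# synonymous rate.
.expected_count <- function(table, model, cls, n) {
  opp <- switch(cls,
    missense = table$counts["missense", ],
    truncating = table$counts["nonsense", ],
    synonymous = table$counts["synonymous", ])
  ok <- !is.na(model$rates) & opp > 0
  e <- n * sum(model$rates[ok] * opp[ok])
  if (cls == "truncating" && table$splice_opportunity > 0) {
    mean_rate <- sum(model$syn_counts) /
      (sum(model$syn_opp) * model$total_exposure)
    e <- e + n * mean_rate * table$splice_opportunity
  }
  e
}

#' Per-gene dN/dS for missense and truncating classes
#'
#' `omega = n_obs / n_exp` with `n_exp` from the synonymous-calibrated rate
#' model: `n_exp(class) = N x sum_categories rate(category) x
#' opportunity(gene, class, category)`. Truncating pools observed nonsense +
#' splice_site over nonsense + splice opportunity. Zero observed counts
#' yield omega = 0 (no pseudocount); `n_exp = 0` yields `NA` with
#' `flag = "undefined_exp"`.
#'
#' @param cohort Cohort subset to evaluate (the model should be fitted on
#'   this subset or be a declared global calibration).
#' @param gene A gene model, or a gene symbol when `table` is supplied.
#' @param model A fitted [fit_substitution_model()].
#' @param table Optional precomputed opportunity table for the gene.
#' @return data.frame with one row per class (`missense`, `truncating`):
#'   `gene`, `class`, `n_obs`, `n_exp`, `omega`, `subset_size`, `flag`.
#' @export
dnds <- function(cohort, gene, model, table = NULL) {
  if (is.null(table)) {
    stopifnot(inherits(gene, "gene_model"))
    table <- build_opportunity_table(gene, model$granularity)
  }
  g <- table$gene
  N <- cohort$N
  rec <- cohort$records[gene == g]
  n_mis <- sum(rec$impact_class == "missense")
  n_tru <- sum(rec$impact_class %in% c("nonsense", "splice_site"))
  out <- rbindlist(lapply(
    list(c("missense", n_mis), c("truncating", n_tru)),
    function(z) {
      cls <- z[[1]]; n_obs <- as.numeric(z[[2]])
      n_exp <- .expected_count(table, model, cls, N)
      flag <- ""
      omega <- if (n_exp > 0) n_obs / n_exp else { flag <- "undefined_exp"; NA_real_ }
      data.table(gene = g, class = cls, n_obs = n_obs, n_exp = n_exp,
                 omega = omega, subset_size = N, flag = flag)
    }))
  as.data.frame(out)
}

#' Indel rate ratio for one gene against a background panel
#'
#' `omega_ind = (gene indel count / gene CDS length) / (pooled background
#' indel count / pooled background CDS length)`, both in the same cohort
#' subset; frameshift and in-frame indels are pooled. The background panel
#' must exclude the tested gene (and any declared context genes).
#'
#' @param cohort Cohort subset.
#' @param gene Gene model (or symbol present in `gene_models`).
#' @param background_genes Character vector of background gene symbols.
#' @param gene_models Named list of gene models covering gene + background.
#' @return One-row data.frame (class `indel`); zero background indels give
#'   `NA` with `flag = "undefined_background"`.
#' @export
dnds_indel <- function(cohort, gene, background_genes, gene_models) {
  g <- if (inherits(gene, "gene_model")) gene$gene else gene
  background_genes <- setdiff(background_genes, g)
  if (!length(background_genes)) stop("empty background panel")
  indel_cls <- c("frameshift_indel", "inframe_indel")
  rec <- cohort$records[impact_class %in% indel_cls]
  n_g <- sum(rec$gene == g)
  n_bg <- sum(rec$gene %in% background_genes)
  L_g <- nchar(gene_models[[g]]$cds)
  L_bg <- sum(vapply(background_genes,
                     function(b) nchar(gene_models[[b]]$cds), numeric(1)))
  flag <- ""
  omega <- if (n_bg > 0) (n_g / L_g) / (n_bg / L_bg) else {
    flag <- "undefined_background"; NA_real_ }
  data.frame(gene = g, class = "indel", n_obs = n_g,
             n_exp = if (n_bg > 0) n_bg * L_g / L_bg else NA_real_,
             omega = omega, subset_size = cohort$N, flag = flag)
}

#' Select positively selected (driver) genes by global q-value
#'
#' One-sided Poisson test per gene of pooled non-silent substitution counts
#' (missense + nonsense + splice_site) against the neutral expectation,
#' Benjamini-Hochberg corrected across genes.
#'
#' @param cohort Cohort.
#' @param gene_models Named list of gene models.
#' @param model Fitted substitution model.
#' @param q_threshold FDR threshold for the `selected` flag (default 0.1).
#' @param tables Optional precomputed opportunity tables.
#' @return data.frame `gene`, `n_obs`, `n_exp`, `p`, `q`, `selected`,
#'   sorted by q.
#' @export
select_driver_genes <- function(cohort, gene_models, model,
                                q_threshold = 0.1, tables = NULL) {
  if (!length(gene_models))
    return(data.frame(gene = character(), n_obs = numeric(),
                      n_exp = numeric(), p = numeric(), q = numeric(),
                      selected = logical()))
  tables <- .tables_for(gene_models, model$granularity, tables)
  N <- cohort$N
  res <- rbindlist(lapply(names(tables), function(g) {
    rec <- cohort$records[gene == g]
    n_obs <- sum(rec$impact_class %in% c("missense", "nonsense", "splice_site"))
    n_exp <- .expected_count(tables[[g]], model, "missense", N) +
      .expected_count(tables[[g]], model, "truncating", N)
    p <- ppois(n_obs - 1, n_exp, lower.tail = FALSE)
    data.table(gene = g, n_obs = n_obs, n_exp = n_exp, p = p)
  }))
  res[, q := p.adjust(p, method = "BH")]
  res[, selected := q < q_threshold]
  as.data.frame(res[order(q, p)])
}
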