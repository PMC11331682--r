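# Mutation features contrasting SYN and ANT pairs: variant allele frequency
# differentials, tumor-mutation-burden differentials, their permuted
# baselines, and pathway co-membership z-scores.

#' Variant allele frequency of mutation records
#'
#' `VAF = t_alt_count / (t_alt_count + t_ref_count)`. Records with zero or
#' missing depth get `NA`; the number skipped is attached as attribute
#' `"n_skipped"`.
#'
#' @param records A cohort, or a data.frame with `t_alt_count` and
#'   `t_ref_count`.
#' @return Numeric vector of VAFs in `[0, 1]`.
#' @export
compute_vaf <- function(records) {
  if (inherits(records, "cohort")) records <- records$records
  depth <- records$t_alt_count + records$t_ref_count
  ok <- !is.na(depth) & depth > 0
  out <- rep(NA_real_, length(depth))
  out[ok] <- records$t_alt_count[ok] / depth[ok]
  attr(out, "n_skipped") <- sum(!ok)
  out
}

.gene_median_vaf <- function(cohort, g, include_other = FALSE) {
  rec <- cohort$records[gene == g &
                          impact_class %in% nonsilent_classes(include_other)]
  if (nrow(rec) == 0L) return(NA_real_)
  v <- compute_vaf(rec)
  if (all(is.na(v))) return(NA_real_)
  median(v, na.rm = TRUE)
}

#' VAF differential of a gene pair
#'
#' Median VAF over the partner gene's non-silent mutations minus the median
#' over the context gene's, in the (optionally tumor-type-restricted)
#' cohort. Negative values indicate a clonal context with a subclonal
#' partner.
#'
#' @param cohort A cohort.
#' @param gene_a Context gene.
#' @param gene_b Partner gene.
#' @param tumor_type Optional tumor-type restriction.
#' @return Scalar delta VAF in `[-1, 1]`, `NA` when a gene has no
#'   VAF-evaluable mutation.
#' @export
delta_vaf <- function(cohort, gene_a, gene_b, tumor_type = NULL) {
  if (!is.null(tumor_type))
    cohort <- suppressMessages(filter_cohort(cohort, tumor_types = tumor_type))
  .gene_median_vaf(cohort, gene_b) - .gene_median_vaf(cohort, gene_a)
}

.tmb_by_sample <- function(cohort, include_other = FALSE) {
  cls <- nonsilent_classes(include_other)
  rec <- cohort$records[impact_class %in% cls]
  tab <- table(factor(rec$sample_id, levels = cohort$samples$sample_id))
  setNames(as.numeric(tab), cohort$samples$sample_id)
}

#' TMB differential of a gene pair
#'
#' Tumor mutation burden (non-silent mutations per genome) is compared
#' between genomes mutated in both genes of the pair and genomes mutated in
#' exactly one (either one, pooled). The group summary is the median
#' (`mean` by flag) and the headline value is the log10 difference.
#'
#' @param cohort A cohort.
#' @param gene_a,gene_b The pair.
#' @param use_mean Summarize groups by the mean instead of the median.
#' @return List: `delta_log10` (log10 summary difference), `delta_raw`,
#'   `n_double`, `n_single`; `NA`s when a group is empty.
#' @export
delta_tmb <- function(cohort, gene_a, gene_b, use_mean = FALSE) {
  cls <- nonsilent_classes(FALSE)
  pos_a <- unique(cohort$records[gene == gene_a & impact_class %in% cls,
                                 sample_id])
  pos_b <- unique(cohort$records[gene == gene_b & impact_class %in% cls,
                                 sample_id])
  tmb <- .tmb_by_sample(cohort)
  ids <- names(tmb)
  double <- ids %in% pos_a & ids %in% pos_b
  single <- xor(ids %in% pos_a, ids %in% pos_b)
  if (!any(double) || !any(single))
    return(list(delta_log10 = NA_real_, delta_raw = NA_real_,
                n_double = sum(double), n_single = sum(single)))
  summ <- if (use_mean) mean else median
  td <- summ(tmb[double]); ts <- summ(tmb[single])
  list(delta_log10 = log10(td) - log10(ts), delta_raw = td - ts,
       n_double = sum(double), n_single = sum(single))
}

.pair_statistic <- function(pairs, cohort, statistic, tumor_type_specific) {
  vapply(seq_len(nrow(pairs)), function(i) {
    tt <- if (tumor_type_specific && "tumor_type" %in% names(pairs))
      pairs$tumor_type[i] else NULL
    if (statistic == "delta_vaf")
      delta_vaf(cohort, pairs$gene_a[i], pairs$gene_b[i], tumor_type = tt)
    else
      delta_tmb(cohort, pairs$gene_a[i], pairs$gene_b[i])$delta_log10
  }, numeric(1))
}

# Shuffle the gene multiset across the pair list; self-pairs trigger a
# redraw of the whole permutation.
.shuffle_pairs <- function(pairs, max_tries = 1000) {
  n <- nrow(pairs)
  pool <- c(pairs$gene_a, pairs$gene_b)
  for (t in seq_len(max_tries)) {
    perm <- sample(pool)
    a <- perm[seq_len(n)]; b <- perm[n + seq_len(n)]
    if (!any(a == b)) {
      out <- pairs
      out$gene_a <- a; out$gene_b <- b
      return(out)
    }
  }
  stop("could not draw a collision-free gene permutation")
}

#' Permuted baseline for pair-level features
#'
#' Reshuffles the genes across the pair list (preserving length and the
#' gene multiset, redrawing on self-pair collisions), recomputes the
#' statistic per permutation, and compares the observed SYN and ANT groups
#' against the pooled null with two-sample t-tests.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `call` (SYN/ANT) and
#'   optionally `tumor_type`.
#' @param cohort A cohort.
#' @param statistic `"delta_vaf"` or `"delta_tmb"`.
#' @param n_perm Number of permutations (default 100).
#' @param seed Optional integer seed.
#' @param tumor_type_specific Restrict each pair's statistic to its
#'   `tumor_type` column.
#' @return List: `observed` (pairs with a `value` column), `null` (pooled
#'   permuted per-pair values), `null_means` (one mean per permutation,
#'   the baseline for group-mean comparisons), `test_syn`, `test_ant`
#'   (t-tests of each group against the pooled null, `NULL` when the group
#'   is absent).
#' @export
permuted_baseline <- function(pairs, cohort,
                              statistic = c("delta_vaf", "delta_tmb"),
                              n_perm = 100, seed = NULL,
                              tumor_type_specific = FALSE) {
  statistic <- match.arg(statistic)
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 2L) stop("need at least 2 pairs")
  obs <- .pair_statistic(pairs, cohort, statistic, tumor_type_specific)
  run <- function() {
    lapply(seq_len(n_perm), function(p) {
      .pair_statistic(.shuffle_pairs(pairs), cohort, statistic,
                      tumor_type_specific)
    })
  }
  perms <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  null_means <- vapply(perms, mean, numeric(1), na.rm = TRUE)
  null <- unlist(perms)
  null <- null[!is.na(null)]
  observed <- pairs
  observed$value <- obs
  tt <- function(grp) {
    v <- obs[pairs$call == grp & !is.na(obs)]
    if (length(v) >= 2L && length(null) >= 2L) t.test(v, null) else NULL
  }
  list(observed = observed, null = null, null_means = null_means,
       test_syn = tt("SYN"), test_ant = tt("ANT"))
}

#' Pathway co-membership z-score of a gene pair
#'
#' Observed statistic: number of gene sets containing both genes. The null
#' preserves each set's size while reassigning genes uniformly without
#' replacement from the gene universe; `z = (obs - mean_perm) / sd_perm`.
#'
#' @param gene_a,gene_b The pair (both must be in the set universe).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param n_perm Number of permuted universes (default 1000).
#' @param seed Optional integer seed.
#' @return List: `z`, `obs`, `perm_mean`, `perm_sd`; `z` is `NA` with a
#'   `reason` when `sd_perm` is 0.
#' @export
pathway_concordance <- function(gene_a, gene_b, gene_sets, n_perm = 1000,
                                seed = NULL) {
  universe <- unique(unlist(gene_sets))
  if (!all(c(gene_a, gene_b) %in% universe))
    stop("both genes must be present in the gene-set universe")
  sizes <- lengths(gene_sets)
  obs <- sum(vapply(gene_sets,
                    function(s) gene_a %in% s && gene_b %in% s, logical(1)))
  run <- function() {
    vapply(seq_len(n_perm), function(p) {
      sum(vapply(sizes, function(sz) {
        s <- universe[sample.int(length(universe), sz)]
        gene_a %in% s && gene_b %in% s
      }, logical(1)))
    }, numeric(1))
  }
  nulls <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  m <- mean(nulls); s <- sd(nulls)
  if (is.na(s) || s == 0)
    return(list(z = NA_real_, obs = obs, perm_mean = m, perm_sd = s,
                reason = "zero permutation sd"))
  list(z = (obs - m) / s, obs = obs, perm_mean = m, perm_sd = s)
}
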