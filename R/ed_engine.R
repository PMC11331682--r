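# Context-stratified dN/dS, cdNS scores, permutation significance, the
# sample-size-corrected Fisher test for pan-cancer ANT pairs, and the SYN/ANT
# pair caller.
#
# Per-subset synonymous calibration makes the subset omega a ratio of two
# per-sample sums: with rate(category) fitted on the subset itself, the
# subset size cancels and
#   omega(subset) = sum_i nb[i] / sum_i e[i],  i in subset,
# where nb[i] is the sample's observed count of the class in gene B and
# e[i] = sum_cat S[i, cat] * opportunity_B(class, cat) / syn_opportunity(cat)
# built from the sample's synonymous counts S. Permutations of the context
# labels then only reshuffle which i enter each sum, which is what makes
# 1000-permutation tests cheap.

#' Precompute per-sample count structures for cdNS analyses
#'
#' Builds, once per cohort x gene panel, everything the cdNS estimator,
#' permutation test and pair caller need: per-sample synonymous counts by
#' rate category, per-sample class counts per gene, expected-count weights
#' and non-silent indicator matrix.
#'
#' @param cohort A cohort.
#' @param gene_models Named list of gene models (the evaluated panel; both
#'   context and partner genes must be in it).
#' @param granularity Rate-model granularity (see [sub_categories()]).
#' @param tables Optional precomputed opportunity tables.
#' @param include_other Count class `other` as non-silent for context
#'   splitting.
#' @return An object of class `ed_workspace`.
#' @export
ed_workspace <- function(cohort, gene_models, granularity = "trinuc96",
                         tables = NULL, include_other = FALSE) {
  granularity <- match.arg(granularity, .GRANULARITIES)
  tables <- .tables_for(gene_models, granularity, tables)
  panel <- names(tables)
  ids <- cohort$samples$sample_id
  N <- length(ids)
  cats <- sub_categories(granularity)

  rec <- cohort$records[gene %in% panel]
  # per-sample synonymous counts by category
  syn <- rec[impact_class == "synonymous"]
  if (granularity == "uniform") {
    syn_cat <- rep("all", nrow(syn))
  } else {
    if (nrow(syn) && (anyNA(syn$position) || anyNA(syn$alt_allele)))
      stop("records lack position/alt_allele; use granularity = 'uniform'")
    syn_cat <- if (nrow(syn)) .site_categories(syn, tables) else character(0)
  }
  S <- table(factor(syn$sample_id, levels = ids),
             factor(syn_cat, levels = cats))
  S <- matrix(as.numeric(S), nrow = N, dimnames = list(ids, cats))
  syn_opp <- Reduce(`+`, lapply(tables, function(t) t$counts["synonymous", ]))
  syn_opp <- setNames(as.numeric(syn_opp), cats)

  count_mat <- function(classes) {
    sub <- rec[impact_class %in% classes]
    m <- table(factor(sub$sample_id, levels = ids),
               factor(sub$gene, levels = panel))
    matrix(as.numeric(m), nrow = N, dimnames = list(ids, panel))
  }
  nb <- list(missense = count_mat("missense"),
             truncating = count_mat(c("nonsense", "splice_site")),
             indel = count_mat(c("frameshift_indel", "inframe_indel")))
  nonsil <- count_mat(nonsilent_classes(include_other))

  # expected-count weight per sample for substitution classes:
  # e[, g] = S %*% (opp_g(class, cat) / syn_opp(cat))
  ok <- syn_opp > 0
  e <- list()
  for (cls in c("missense", "truncating")) {
    W <- vapply(panel, function(g) {
      opp <- if (cls == "missense") tables[[g]]$counts["missense", ]
             else tables[[g]]$counts["nonsense", ]
      w <- numeric(length(cats))
      w[ok] <- opp[ok] / syn_opp[ok]
      w
    }, numeric(length(cats)))
    E <- S %*% W
    # splice opportunity enters via the uniform-equivalent mean rate
    spl <- vapply(panel, function(g) tables[[g]]$splice_opportunity,
                  numeric(1))
    if (cls == "truncating" && any(spl > 0))
      E <- E + rowSums(S) %o% (spl / sum(syn_opp))
    colnames(E) <- panel
    e[[cls]] <- E
  }
  L <- vapply(panel, function(g) nchar(gene_models[[g]]$cds), numeric(1))

  structure(list(sample_ids = ids, N = N, panel = panel, tables = tables,
                 granularity = granularity, S = S, syn_opp = syn_opp,
                 nb = nb, e = e, nonsilent = nonsil, L = L),
            class = "ed_workspace")
}

#' @export
print.ed_workspace <- function(x, ...) {
  cat(sprintf("<ed_workspace> %d samples x %d genes, granularity=%s\n",
              x$N, length(x$panel), x$granularity))
  invisible(x)
}

# nb / e vectors for one (gene_b, class); indel expectations are built
# against a background panel at call time.
.pair_vectors <- function(ws, gene_b, impact_class, background_genes = NULL) {
  stopifnot(gene_b %in% ws$panel)
  if (impact_class == "indel") {
    bg <- if (is.null(background_genes))
      setdiff(ws$panel, gene_b) else setdiff(background_genes, gene_b)
    if (!length(bg)) stop("empty indel background panel")
    nb <- ws$nb$indel[, gene_b]
    e <- rowSums(ws$nb$indel[, bg, drop = FALSE]) *
      (ws$L[gene_b] / sum(ws$L[bg]))
  } else {
    nb <- ws$nb[[impact_class]][, gene_b]
    e <- ws$e[[impact_class]][, gene_b]
  }
  list(nb = nb, e = e)
}

.omega_from_sums <- function(nb_sum, e_sum) {
  if (is.na(e_sum) || e_sum <= 0) return(NA_real_)
  nb_sum / e_sum
}

#' Split a cohort by mutation context
#'
#' Partitions the roster into samples with (context +) and without
#' (context -) at least one non-silent mutation in the context gene.
#'
#' @param cohort A cohort.
#' @param gene_a Context gene symbol.
#' @param include_other Count class `other` as non-silent.
#' @return Object of class `mutation_context`: `context_gene`,
#'   `positive_samples`, `negative_samples`. An empty positive set is valid
#'   and flagged via attribute `"empty_positive"`.
#' @export
split_by_context <- function(cohort, gene_a, include_other = FALSE) {
  cls <- nonsilent_classes(include_other)
  pos <- unique(cohort$records[gene == gene_a & impact_class %in% cls,
                               sample_id])
  neg <- setdiff(cohort$samples$sample_id, pos)
  out <- structure(list(context_gene = gene_a,
                        positive_samples = pos, negative_samples = neg),
                   class = "mutation_context")
  attr(out, "empty_positive") <- length(pos) == 0L
  out
}

#' The cdNS score
#'
#' `cdns = log2(dnds_plus / dnds_minus)`. Undefined (NA) when either ratio
#' is zero, non-finite or missing; the reason is attached as attribute
#' `"reason"` for scalar input.
#'
#' @param dnds_plus dN/dS in the context-positive subset.
#' @param dnds_minus dN/dS in the context-negative subset.
#' @return Numeric cdNS score (vectorized).
#' @export
cdns_score <- function(dnds_plus, dnds_minus) {
  out <- ifelse(is.na(dnds_plus) | is.na(dnds_minus) |
                  dnds_plus <= 0 | dnds_minus <= 0 |
                  !is.finite(dnds_plus) | !is.finite(dnds_minus),
                NA_real_, log2(dnds_plus / dnds_minus))
  if (length(out) == 1L && is.na(out)) {
    reason <- if (isTRUE(dnds_plus <= 0) && isTRUE(dnds_minus <= 0))
      "both_zero"
    else if (isTRUE(dnds_plus <= 0)) "zero_plus"
    else if (isTRUE(dnds_minus <= 0)) "zero_minus"
    else "missing"
    attr(out, "reason") <- reason
  }
  out
}

#' Context-stratified dN/dS and cdNS for one gene pair
#'
#' Computes `dnds(context+)`, `dnds(context-)` (each with its own
#' per-subset synonymous calibration), the cdNS score, the ED ratio and the
#' class mutation counts in each subset.
#'
#' @param cohort A cohort (ignored when `ws` is given).
#' @param gene_a Context gene.
#' @param gene_b Partner gene.
#' @param impact_class One of `"missense"`, `"truncating"`, `"indel"`.
#' @param gene_models Named list of gene models (ignored when `ws` given).
#' @param granularity Rate granularity (ignored when `ws` given).
#' @param ws Optional precomputed [ed_workspace()].
#' @param background_genes Indel background (default: panel minus the pair).
#' @return One-row data.frame: `gene_a`, `gene_b`, `impact_class`,
#'   `dnds_plus`, `dnds_minus`, `cdns`, `ed_ratio`, `n_mut_plus`,
#'   `n_mut_minus`, `n_pos`, `n_neg`.
#' @export
cdns_estimate <- function(cohort, gene_a, gene_b, impact_class,
                          gene_models = NULL, granularity = "trinuc96",
                          ws = NULL, background_genes = NULL) {
  impact_class <- match.arg(impact_class, .DNDS_CLASSES)
  if (is.null(ws))
    ws <- ed_workspace(cohort, gene_models, granularity)
  if (is.null(background_genes) && impact_class == "indel")
    background_genes <- setdiff(ws$panel, c(gene_a, gene_b))
  v <- .pair_vectors(ws, gene_b, impact_class, background_genes)
  pos <- ws$nonsilent[, gene_a] > 0
  dnds_plus <- .omega_from_sums(sum(v$nb[pos]), sum(v$e[pos]))
  dnds_minus <- .omega_from_sums(sum(v$nb[!pos]), sum(v$e[!pos]))
  cd <- cdns_score(dnds_plus, dnds_minus)
  data.frame(gene_a = gene_a, gene_b = gene_b, impact_class = impact_class,
             dnds_plus = dnds_plus, dnds_minus = dnds_minus,
             cdns = as.numeric(cd),
             ed_ratio = dnds_plus / dnds_minus,
             n_mut_plus = sum(v$nb[pos]), n_mut_minus = sum(v$nb[!pos]),
             n_pos = sum(pos), n_neg = sum(!pos))
}

# Core resampling engine shared by permutation_test and subsample_stability.
.perm_null <- function(nb, e, n_pos, N, n_perm) {
  nb_tot <- sum(nb); e_tot <- sum(e)
  null <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(N, n_pos)
    nbp <- sum(nb[idx]); ep <- sum(e[idx])
    wp <- .omega_from_sums(nbp, ep)
    wm <- .omega_from_sums(nb_tot - nbp, e_tot - ep)
    null[p] <- cdns_score(wp, wm)
  }
  null
}

#' Permutation test of a cdNS score
#'
#' Reassigns the context-positive label to a uniformly random sample subset
#' of the observed size, recomputes both per-subset-calibrated dN/dS ratios
#' and the cdNS score, and reports a one-sided p with add-one correction:
#' `p = (1 + #extreme) / (n_perm + 1)`. Permutations with undefined cdNS
#' are counted as non-exceeding and tallied. Deterministic given `seed`.
#'
#' With `alternative = "auto"` (the default used by the pair caller)
#' "extreme" means at least as extreme in the direction of the observed
#' score's sign; because the direction adapts to the data, this p is
#' bounded near 0.5 under the null and its nominal level doubles. The
#' fixed tails `"greater"` (the frequency with which permuted scores
#' exceed the observed, i.e. the SYN tail) and `"less"` are proper
#' one-sided p-values, approximately uniform under no dependence.
#'
#' @inheritParams cdns_estimate
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param alternative `"auto"`, `"greater"` or `"less"` (see Details).
#' @return List: `observed` (the [cdns_estimate()] row), `p_perm`, `null`
#'   (permuted cdNS scores, NA where undefined), `n_undefined`.
#' @export
permutation_test <- function(cohort, gene_a, gene_b, impact_class,
                             gene_models = NULL, n_perm = 1000, seed = NULL,
                             granularity = "trinuc96", ws = NULL,
                             background_genes = NULL,
                             alternative = c("auto", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(ws))
    ws <- ed_workspace(cohort, gene_models, granularity)
  obs <- cdns_estimate(NULL, gene_a, gene_b, impact_class, ws = ws,
                       background_genes = background_genes)
  if (is.na(obs$cdns))
    return(list(observed = obs, p_perm = NA_real_, null = NULL,
                n_undefined = NA_integer_,
                reason = "observed cdNS undefined"))
  v <- .pair_vectors(ws, gene_b, impact_class,
                     if (is.null(background_genes) && impact_class == "indel")
                       setdiff(ws$panel, c(gene_a, gene_b))
                     else background_genes)
  run <- function() .perm_null(v$nb, v$e, obs$n_pos, ws$N, n_perm)
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  dir_greater <- switch(alternative,
                        auto = obs$cdns >= 0, greater = TRUE, less = FALSE)
  extreme <- if (dir_greater) null >= obs$cdns else null <= obs$cdns
  extreme[is.na(extreme)] <- FALSE   # undefined permutations: non-exceeding
  p <- (1 + sum(extreme)) / (n_perm + 1)
  list(observed = obs, p_perm = p, null = null,
       n_undefined = sum(is.na(null)))
}

#' Sample-size correction factor for pan-cancer ANT testing
#'
#' Rescales the number of context-negative genomes by a logistic weight `w`
#' of the context-positive fraction `f = n_pos / (n_pos + n_neg)`:
#' `w = plogis(slope * (f - midpoint))`, `corrected_N = n_pos + w * n_neg`.
#' The published "recommended parameters" live in an external reference;
#' the defaults here (midpoint 0.05, slope 50) are package choices, fully
#' overridable, and `w_override = 1` recovers the uncorrected test.
#'
#' @param n_pos Context-positive genome count.
#' @param n_neg Context-negative genome count.
#' @param midpoint Logistic midpoint on the fraction scale.
#' @param slope Logistic slope.
#' @param w_override Optional fixed w in (0, 1].
#' @return Object of class `correction_params`: `w`, `corrected_N`, `f`,
#'   `midpoint`, `slope`.
#' @export
sample_size_correction <- function(n_pos, n_neg, midpoint = 0.05,
                                   slope = 50, w_override = NULL) {
  if (n_pos < 0 || n_neg < 0) stop("counts must be non-negative")
  if (n_pos + n_neg == 0) stop("n_pos + n_neg must be positive")
  f <- n_pos / (n_pos + n_neg)
  w <- if (!is.null(w_override)) w_override else plogis(slope * (f - midpoint))
  if (w <= 0 || w > 1) stop("w must be in (0, 1]")
  structure(list(w = w, corrected_N = n_pos + w * n_neg, f = f,
                 midpoint = midpoint, slope = slope),
            class = "correction_params")
}

#' Corrected Fisher's exact test for pan-cancer ANT pairs
#'
#' One-sided exact hypergeometric test for depletion of double mutants on a
#' 2x2 table (rows: context +/-; columns: partner mutated / wild type) whose
#' context-negative row is rescaled by the correction factor `w` and rounded
#' to the nearest integers. `w = 1` is the plain one-sided Fisher test.
#'
#' @param x Either a cohort or a 2x2 integer matrix (rows context +/-,
#'   columns partner mutant / wild type).
#' @param gene_a,gene_b Pair (when `x` is a cohort).
#' @param correction Optional [sample_size_correction()] result; default no
#'   correction.
#' @param include_other Count class `other` as non-silent.
#' @return List: `p_fisher`, `table` (corrected), `w`; `p_fisher` is `NA`
#'   with a `reason` when a table margin is zero.
#' @export
fisher_ant_test <- function(x, gene_a = NULL, gene_b = NULL,
                            correction = NULL, include_other = FALSE) {
  if (is.matrix(x)) {
    tab <- x
  } else {
    cls <- nonsilent_classes(include_other)
    pos_a <- unique(x$records[gene == gene_a & impact_class %in% cls,
                              sample_id])
    pos_b <- unique(x$records[gene == gene_b & impact_class %in% cls,
                              sample_id])
    ids <- x$samples$sample_id
    a_mut <- ids %in% pos_a; b_mut <- ids %in% pos_b
    tab <- matrix(c(sum(a_mut & b_mut), sum(a_mut & !b_mut),
                    sum(!a_mut & b_mut), sum(!a_mut & !b_mut)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("ctx_pos", "ctx_neg"),
                                  c("b_mut", "b_wt")))
  }
  w <- if (is.null(correction)) 1 else correction$w
  ctab <- tab
  ctab[2, ] <- round(w * ctab[2, ])
  if (any(rowSums(ctab) == 0) || any(colSums(ctab) == 0))
    return(list(p_fisher = NA_real_, table = ctab, w = w,
                reason = "zero margin"))
  p <- fisher.test(ctab, alternative = "less")$p.value
  list(p_fisher = p, table = ctab, w = w)
}

#' Apply the SYN/ANT pair filters to a results table
#'
#' The published filter set: p below the cutoff (`p_perm` for SYN and for
#' all tumor-type-specific pairs; corrected Fisher `p_fisher` for
#' pan-cancer ANT), minimum class mutations in the context-positive subset
#' (SYN >= 3, ANT >= 1), and ED ratio > `ratio_hi` or < `ratio_lo`.
#'
#' @param results data.frame with columns `cdns`, `ed_ratio`, `n_mut_plus`,
#'   `p_perm` and (for pan-cancer mode) `p_fisher`.
#' @param mode `"pancancer"` or `"tumor_type"`.
#' @param thresholds List with `p_cut` (0.01), `min_mut_syn` (3),
#'   `min_mut_ant` (1), `ratio_hi` (3), `ratio_lo` (0.3).
#' @return `results` with columns `p_used` and `call` (`SYN`, `ANT`,
#'   `not_significant`, or `undefined` when cdns is NA).
#' @export
filter_pair_calls <- function(results, mode = c("pancancer", "tumor_type"),
                              thresholds = list()) {
  mode <- match.arg(mode)
  th <- modifyList(list(p_cut = 0.01, min_mut_syn = 3, min_mut_ant = 1,
                        ratio_hi = 3, ratio_lo = 0.3), thresholds)
  results <- as.data.frame(results)
  syn_dir <- !is.na(results$cdns) & results$cdns > 0
  p_used <- results$p_perm
  if (mode == "pancancer" && "p_fisher" %in% names(results)) {
    ant <- !is.na(results$cdns) & results$cdns < 0
    p_used[ant] <- results$p_fisher[ant]
  }
  min_mut <- ifelse(syn_dir, th$min_mut_syn, th$min_mut_ant)
  pass <- !is.na(results$cdns) & !is.na(p_used) &
    p_used < th$p_cut &
    results$n_mut_plus >= min_mut &
    (results$ed_ratio > th$ratio_hi | results$ed_ratio < th$ratio_lo)
  call <- ifelse(is.na(results$cdns), "undefined",
                 ifelse(!pass, "not_significant",
                        ifelse(results$cdns > 0, "SYN", "ANT")))
  results$p_used <- p_used
  results$call <- call
  results
}

#' Evaluate and call SYN/ANT gene pairs
#'
#' Evaluates all ordered (context, partner) pairs and requested classes:
#' cdNS estimate, permutation p, corrected Fisher p for candidate
#' pan-cancer ANT pairs, then the published filters via
#' [filter_pair_calls()]. Both orientations of a pair are distinct rows
#' when both genes appear in both panels.
#'
#' @param cohort A cohort.
#' @param context_genes Context-gene symbols (gene A).
#' @param partner_genes Partner-gene symbols (gene B).
#' @param gene_models Named list of gene models covering the panel.
#' @param mode `"pancancer"` (Fisher p for ANT) or `"tumor_type"`
#'   (permutation p throughout).
#' @param classes Classes to evaluate.
#' @param n_perm Permutations per pair.
#' @param seed Integer seed; per-pair streams are derived from it.
#' @param granularity Rate granularity.
#' @param thresholds See [filter_pair_calls()].
#' @param correction List of [sample_size_correction()] parameters
#'   (`midpoint`, `slope`, optional `w_override`).
#' @param include_other Count class `other` as non-silent.
#' @param pairs Optional explicit data.frame of `(gene_a, gene_b)` rows
#'   (optionally with `impact_class`) to evaluate instead of the full
#'   ordered cross of `context_genes` x `partner_genes`.
#' @return data.frame of all evaluated (pair, class) rows with scores,
#'   p-values and the `call` column.
#' @export
call_pairs <- function(cohort, context_genes = NULL, partner_genes = NULL,
                       gene_models = NULL,
                       mode = c("pancancer", "tumor_type"),
                       classes = c("missense", "truncating", "indel"),
                       n_perm = 1000, seed = NULL, granularity = "trinuc96",
                       thresholds = list(),
                       correction = list(midpoint = 0.05, slope = 50),
                       include_other = FALSE, pairs = NULL) {
  mode <- match.arg(mode)
  classes <- match.arg(classes, .DNDS_CLASSES, several.ok = TRUE)
  ws <- ed_workspace(cohort, gene_models, granularity,
                     include_other = include_other)
  if (is.null(pairs)) {
    grid <- expand.grid(gene_a = context_genes, gene_b = partner_genes,
                        impact_class = classes, stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs)
    if (!"impact_class" %in% names(pairs))
      pairs <- merge(pairs, data.frame(impact_class = classes))
    grid <- pairs[, c("gene_a", "gene_b", "impact_class")]
  }
  grid <- grid[grid$gene_a != grid$gene_b, ]
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    a <- grid$gene_a[i]; b <- grid$gene_b[i]; cls <- grid$impact_class[i]
    pair_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    pt <- permutation_test(NULL, a, b, cls, ws = ws, n_perm = n_perm,
                           seed = pair_seed)
    row <- pt$observed
    row$p_perm <- pt$p_perm
    row$p_fisher <- NA_real_
    if (mode == "pancancer" && !is.na(row$cdns) && row$cdns < 0) {
      b_mut <- ws$nonsilent[, b] > 0
      a_mut <- ws$nonsilent[, a] > 0
      tab <- matrix(c(sum(a_mut & b_mut), sum(a_mut & !b_mut),
                      sum(!a_mut & b_mut), sum(!a_mut & !b_mut)),
                    nrow = 2, byrow = TRUE)
      corr <- sample_size_correction(
        row$n_pos, row$n_neg,
        midpoint = correction$midpoint %||% 0.05,
        slope = correction$slope %||% 50,
        w_override = correction$w_override)
      row$p_fisher <- fisher_ant_test(tab, correction = corr)$p_fisher
    }
    rows[[i]] <- row
  }
  res <- do.call(rbind, rows)
  filter_pair_calls(res, mode = mode, thresholds = thresholds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subsampling stability of a cdNS score
#'
#' Subsamples the context-positive genomes without replacement at the
#' requested sizes (100 draws per size by default), recomputing
#' `dnds(context+)` on the subsample against the full context-negative
#' estimate, and reports the cdNS distribution together with the number of
#' partner-gene class mutations carried by each subsample (the proxy used
#' to derive minimum-mutation thresholds).
#'
#' @inheritParams cdns_estimate
#' @param sizes Integer vector of context-positive subsample sizes.
#' @param reps Subsamples per size.
#' @param seed Optional integer seed.
#' @return data.frame: `size`, `rep`, `cdns`, `n_mut` (partner mutations in
#'   the subsample).
#' @export
subsample_stability <- function(cohort, gene_a, gene_b, impact_class,
                                sizes, reps = 100, seed = NULL,
                                gene_models = NULL, granularity = "trinuc96",
                                ws = NULL, background_genes = NULL) {
  if (is.null(ws))
    ws <- ed_workspace(cohort, gene_models, granularity)
  obs <- cdns_estimate(NULL, gene_a, gene_b, impact_class, ws = ws,
                       background_genes = background_genes)
  if (any(sizes > obs$n_pos))
    stop(sprintf("requested size exceeds available context+ genomes (%d)",
                 obs$n_pos))
  v <- .pair_vectors(ws, gene_b, impact_class,
                     if (is.null(background_genes) && impact_class == "indel")
                       setdiff(ws$panel, c(gene_a, gene_b))
                     else background_genes)
  pos_idx <- which(ws$nonsilent[, gene_a] > 0)
  neg_idx <- which(ws$nonsilent[, gene_a] == 0)
  w_minus <- .omega_from_sums(sum(v$nb[neg_idx]), sum(v$e[neg_idx]))
  run <- function() {
    out <- vector("list", length(sizes))
    for (k in seq_along(sizes)) {
      sz <- sizes[k]
      cd <- numeric(reps); nm <- numeric(reps)
      for (r in seq_len(reps)) {
        idx <- pos_idx[sample.int(length(pos_idx), sz)]
        nm[r] <- sum(v$nb[idx])
        cd[r] <- cdns_score(.omega_from_sums(nm[r], sum(v$e[idx])), w_minus)
      }
      out[[k]] <- data.table(size = sz, rep = seq_len(reps), cdns = cd,
                             n_mut = nm)
    }
    rbindlist(out)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  as.data.frame(res)
}
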