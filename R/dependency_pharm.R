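# Effect sizes linking evolutionary dependency to genetic dependency
# (knockout viability) and drug sensitivity (IC50), their
# rescuing/compromising classification and the fourfold SYN/ANT join.

.effect_label <- function(effect) {
  if (is.na(effect) || effect == 0) NA_character_
  else if (effect > 0) "rescuing" else "compromising"
}

#' Knockout-viability effect size of a mutation context
#'
#' Restricts the panel to cell lines mutated in the knockout gene with a
#' viability score for that gene, splits them by context-gene mutation
#' status, and reports `median(viability | context+) - median(viability |
#' context-)`. Positive effects (context mutation preserves viability under
#' the knockout) are labelled rescuing, negative compromising; exact ties
#' carry no label.
#'
#' @param panel A [cell_line_panel()].
#' @param knockout_gene Gene silenced/knocked out (must be a viability
#'   column).
#' @param context_gene Context gene (must be a mutation-matrix column).
#' @param min_group Minimum cell lines per group (default 2).
#' @return One-row data.frame: `gene_a` (context), `gene_b` (knockout),
#'   `modality`, `effect`, `n_pos`, `n_neg`, `label`; or zero rows with an
#'   `"omit_reason"` attribute when a group is too small.
#' @export
dependency_effect_size <- function(panel, knockout_gene, context_gene,
                                   min_group = 2) {
  if (is.null(panel$viability) || !knockout_gene %in% colnames(panel$viability))
    stop("no viability scores for gene ", knockout_gene)
  if (!context_gene %in% colnames(panel$mutations))
    stop("context gene absent from mutation matrix: ", context_gene)
  v <- panel$viability[, knockout_gene]
  lines <- rownames(panel$viability)[!is.na(v)]
  lines <- lines[panel$mutations[lines, knockout_gene] == 1]
  ctx <- panel$mutations[lines, context_gene] == 1
  .effect_rows(v[lines], ctx, context_gene, knockout_gene, "dependency",
               min_group)
}

.effect_rows <- function(values, ctx, gene_a, gene_b, modality, min_group) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      modality = character(), effect = numeric(),
                      n_pos = integer(), n_neg = integer(),
                      label = character())
  n_pos <- sum(ctx); n_neg <- sum(!ctx)
  if (n_pos < min_group || n_neg < min_group) {
    attr(empty, "omit_reason") <- sprintf(
      "group below minimum size (context+: %d, context-: %d, need >= %d)",
      n_pos, n_neg, min_group)
    return(empty)
  }
  eff <- median(values[ctx]) - median(values[!ctx])
  data.frame(gene_a = gene_a, gene_b = gene_b, modality = modality,
             effect = eff, n_pos = n_pos, n_neg = n_neg,
             label = .effect_label(eff))
}

#' IC50 effect size of a mutation context for a targeted agent
#'
#' Among tumor-type-matched cell lines mutated in the drug's target gene,
#' `effect = median(IC50 | context+) - median(IC50 | context-)`; a positive
#' effect means the context mutation confers resistance. IC50 values are
#' used on the scale recorded in the panel (`ic50_log_scale`), never
#' converted.
#'
#' @param panel A [cell_line_panel()] with an `ic50` table.
#' @param drug Drug name.
#' @param target_gene The drug's target (cell lines must be mutant).
#' @param context_gene Context gene.
#' @param tumor_type Optional tumor-type restriction (needs `tumor_type`
#'   in the panel).
#' @param min_group Minimum cell lines per group (default 2).
#' @return As [dependency_effect_size()], with `modality = "drug"` and a
#'   `drug` column.
#' @export
drug_effect_size <- function(panel, drug, target_gene, context_gene,
                             tumor_type = NULL, min_group = 2) {
  if (is.null(panel$ic50)) stop("panel has no ic50 table")
  d <- drug; tg <- target_gene
  ic <- panel$ic50[panel$ic50$drug == d & panel$ic50$target_gene == tg, ]
  lines <- ic$cell_line
  keep <- panel$mutations[lines, target_gene] == 1
  if (!is.null(tumor_type)) {
    if (is.null(panel$tumor_type)) stop("panel has no tumor_type labels")
    keep <- keep & panel$tumor_type[lines] %in% tumor_type
  }
  ic <- ic[keep, ]
  ctx <- panel$mutations[ic$cell_line, context_gene] == 1
  out <- .effect_rows(ic$ic50, ctx, context_gene, target_gene, "drug",
                      min_group)
  if (nrow(out)) out$drug <- drug
  out
}

#' Fourfold categorization of effect sizes against cdNS calls
#'
#' Joins effect-size rows to cdNS results on (gene_a, gene_b), averaging
#' effect sizes of pairs measured in more than one source, assigns the
#' fourfold category (Res-SYN / Res-ANT / Com-SYN / Com-ANT; exact-zero
#' effects are excluded), and reports the Pearson correlation between
#' effect size and cdNS.
#'
#' @param effects data.frame of effect-size rows (possibly from several
#'   databases).
#' @param cdns_results data.frame with `gene_a`, `gene_b`, `cdns`.
#' @return List: `pairs` (joined table with `category`), `correlation`
#'   (`cor.test` result or `NULL` when fewer than 3 joined pairs).
#' @export
categorize <- function(effects, cdns_results) {
  effects <- as.data.table(effects)
  cdns_results <- as.data.table(cdns_results)
  if (nrow(effects) == 0L || nrow(cdns_results) == 0L)
    return(list(pairs = data.frame(), correlation = NULL))
  avg <- effects[, .(effect = mean(effect), n_sources = .N),
                 by = .(gene_a, gene_b)]
  joined <- merge(avg, cdns_results[, .(gene_a, gene_b, cdns)],
                  by = c("gene_a", "gene_b"))
  if (nrow(joined) == 0L)
    return(list(pairs = data.frame(), correlation = NULL))
  joined[, category := ifelse(effect == 0 | is.na(cdns), NA_character_,
                        paste0(ifelse(effect > 0, "Res", "Com"), "-",
                               ifelse(cdns > 0, "SYN", "ANT")))]
  ct <- if (sum(complete.cases(joined[, .(effect, cdns)])) >= 3L)
    cor.test(joined$effect, joined$cdns, method = "pearson") else NULL
  list(pairs = as.data.frame(joined), correlation = ct)
}

#' Oncogene / tumor-suppressor composition of pair categories
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `category`.
#' @param annotation data.frame with `gene` and `role` in
#'   `{OG, TSG, both, unknown}` (e.g. from a cancer gene census export);
#'   unannotated genes fall into `unknown`.
#' @return Contingency table: category x pair role (`OG-OG`, `OG-TSG`,
#'   `TSG-TSG`, `unknown`).
#' @export
annotate_og_tsg <- function(pairs, annotation) {
  pairs <- as.data.frame(pairs)
  role <- setNames(annotation$role, annotation$gene)
  get_role <- function(g) {
    r <- role[g]
    r[is.na(r) | !r %in% c("OG", "TSG", "both")] <- "unknown"
    unname(r)
  }
  ra <- get_role(pairs$gene_a); rb <- get_role(pairs$gene_b)
  pair_role <- mapply(function(a, b) {
    if (a == "unknown" || b == "unknown") return("unknown")
    a <- if (a == "both") c("OG", "TSG") else a
    b <- if (b == "both") c("OG", "TSG") else b
    combos <- sort(c(a[1], b[1]))   # "both" counts once under its first role
    paste(combos, collapse = "-")
  }, ra, rb)
  pair_role[pair_role == "TSG-TSG"] <- "TSG-TSG"
  pair_role <- sub("^OG-TSG$|^TSG-OG$", "OG-TSG", pair_role)
  table(category = pairs$category,
        roles = factor(pair_role,
                       levels = c("OG-OG", "OG-TSG", "TSG-TSG", "unknown")))
}
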