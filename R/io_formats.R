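# MAF / FASTA / GMT / TSV interfaces and cohort assembly.

# Default MAF Variant_Classification -> internal impact class mapping
# (MC3 dialect). Overridable via the class_map argument of read_maf().
.DEFAULT_CLASS_MAP <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Splice_Site       = "splice_site",
  Silent            = "synonymous",
  Frame_Shift_Ins   = "frameshift_indel",
  Frame_Shift_Del   = "frameshift_indel",
  In_Frame_Ins      = "inframe_indel",
  In_Frame_Del      = "inframe_indel"
)

#' Construct a cohort of somatic mutation records
#'
#' A cohort couples a table of mutation records with a sample roster. The
#' roster, not the records, defines `N` (the total number of genomes), so
#' samples with zero mutations are representable when an explicit roster is
#' supplied.
#'
#' @param records data.frame with at least `sample_id`, `gene`,
#'   `impact_class`; optional columns `ref_allele`, `alt_allele`,
#'   `t_alt_count`, `t_ref_count`, `tumor_type`, `position` are filled with
#'   `NA` when absent.
#' @param samples Optional roster: character vector of sample ids or a
#'   data.frame with `sample_id` and optionally `tumor_type`, `subtype`.
#'   Defaults to the distinct `sample_id`s in `records`.
#' @return An object of class `cohort`: list with `records` (data.table),
#'   `samples` (data.table) and `N`.
#' @export
new_cohort <- function(records, samples = NULL) {
  records <- as.data.table(records)
  req <- c("sample_id", "gene", "impact_class")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("cohort records lack required column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(records$impact_class), .IMPACT_CLASSES)
  if (length(bad))
    stop("unknown impact_class value(s): ", paste(bad, collapse = ", "))
  opt <- c("ref_allele", "alt_allele", "t_alt_count", "t_ref_count",
           "tumor_type", "position")
  for (col in opt) if (!col %in% names(records))
    records[, (col) := if (col %in% c("t_alt_count", "t_ref_count", "position"))
      NA_integer_ else NA_character_]
  setcolorder(records, c(req, opt))
  if (any(!is.na(records$t_alt_count) & records$t_alt_count < 0) ||
      any(!is.na(records$t_ref_count) & records$t_ref_count < 0))
    stop("negative read counts in records")

  if (is.null(samples)) {
    samples <- unique(records[, .(sample_id, tumor_type)])
  } else if (is.character(samples)) {
    samples <- data.table(sample_id = samples, tumor_type = NA_character_)
  } else {
    samples <- as.data.table(samples)
    if (!"sample_id" %in% names(samples))
      stop("sample roster needs a sample_id column")
    if (!"tumor_type" %in% names(samples))
      samples[, tumor_type := NA_character_]
  }
  if (anyDuplicated(samples$sample_id))
    samples <- samples[!duplicated(sample_id)]
  if (nrow(samples) < 1L) stop("empty cohort: roster has no samples")
  orphan <- setdiff(records$sample_id, samples$sample_id)
  if (length(orphan))
    stop("records reference sample(s) absent from roster: ",
         paste(head(orphan, 5), collapse = ", "))
  structure(list(records = records, samples = samples, N = nrow(samples)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples, %d mutation records, %d genes\n",
              x$N, nrow(x$records), length(unique(x$records$gene))))
  tt <- x$samples$tumor_type
  if (!all(is.na(tt))) {
    tab <- sort(table(tt), decreasing = TRUE)
    cat("  tumor types:", paste(sprintf("%s=%d", names(tab), tab),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a MAF file into a cohort
#'
#' Accepts the MC3-style tab-separated dialect: required columns
#' `Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification`; optional
#' `t_alt_count`, `t_ref_count`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#' `Start_Position`, `tumor_type`. Unmappable Variant_Classification values
#' are kept with class `other` and counted in the parse report attached as
#' attribute `"parse_report"`.
#'
#' @param path MAF file path (plain TSV with a header row).
#' @param class_map Optional named character vector overriding/extending the
#'   default Variant_Classification mapping.
#' @param sample_list Optional explicit roster (character vector or
#'   data.frame with `sample_id`/`tumor_type`); lets zero-mutation samples
#'   enter the cohort. Defaults to the distinct barcodes in the file.
#' @return A [new_cohort()] object.
#' @export
read_maf <- function(path, class_map = NULL, sample_list = NULL) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = NULL,
              showProgress = FALSE)
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("MAF format error: missing required column(s): ",
         paste(miss, collapse = ", "))
  map <- .DEFAULT_CLASS_MAP
  if (!is.null(class_map)) map[names(class_map)] <- class_map
  cls <- unname(map[dt$Variant_Classification])
  unmapped <- is.na(cls)
  cls[unmapped] <- "other"

  grab_int <- function(col) if (col %in% names(dt))
    suppressWarnings(as.integer(dt[[col]])) else NA_integer_
  grab_chr <- function(col) if (col %in% names(dt))
    as.character(dt[[col]]) else NA_character_

  records <- data.table(
    sample_id    = as.character(dt$Tumor_Sample_Barcode),
    gene         = as.character(dt$Hugo_Symbol),
    impact_class = cls,
    ref_allele   = grab_chr("Reference_Allele"),
    alt_allele   = grab_chr("Tumor_Seq_Allele2"),
    t_alt_count  = grab_int("t_alt_count"),
    t_ref_count  = grab_int("t_ref_count"),
    tumor_type   = grab_chr("tumor_type"),
    position     = grab_int("Start_Position")
  )
  cohort <- new_cohort(records, samples = sample_list)
  attr(cohort, "parse_report") <- list(
    n_records = nrow(records),
    n_unmapped = sum(unmapped),
    unmapped_values = if (any(unmapped))
      table(dt$Variant_Classification[unmapped]) else NULL)
  cohort
}

#' Write a cohort back to MAF
#'
#' Inverse of [read_maf()]: `other` records are written with
#' Variant_Classification `Other` so that parse -> write -> parse is
#' idempotent. Indel direction (Ins vs Del) is recovered from the allele
#' lengths.
#'
#' @param cohort A cohort.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(cohort, path) {
  r <- cohort$records
  vc <- character(nrow(r))
  is_ins <- !is.na(r$ref_allele) & !is.na(r$alt_allele) &
    nchar(r$alt_allele) > nchar(r$ref_allele)
  vc[r$impact_class == "missense"]    <- "Missense_Mutation"
  vc[r$impact_class == "nonsense"]    <- "Nonsense_Mutation"
  vc[r$impact_class == "splice_site"] <- "Splice_Site"
  vc[r$impact_class == "synonymous"]  <- "Silent"
  vc[r$impact_class == "frameshift_indel"] <-
    ifelse(is_ins[r$impact_class == "frameshift_indel"],
           "Frame_Shift_Ins", "Frame_Shift_Del")
  vc[r$impact_class == "inframe_indel"] <-
    ifelse(is_ins[r$impact_class == "inframe_indel"],
           "In_Frame_Ins", "In_Frame_Del")
  vc[r$impact_class == "other"] <- "Other"
  out <- data.table(
    Hugo_Symbol = r$gene,
    Tumor_Sample_Barcode = r$sample_id,
    Variant_Classification = vc,
    Reference_Allele = r$ref_allele,
    Tumor_Seq_Allele2 = r$alt_allele,
    t_alt_count = r$t_alt_count,
    t_ref_count = r$t_ref_count,
    Start_Position = r$position,
    tumor_type = r$tumor_type)
  fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Filter a cohort by tumor type, subtype or minimum case count
#'
#' Restricts roster and records to matching samples; logs before/after N.
#'
#' @param cohort A cohort whose roster carries `tumor_type` labels when
#'   `tumor_types` or `min_cases` is used.
#' @param tumor_types Optional character set of tumor-type labels to keep.
#' @param subtype Optional predicate `function(samples) -> logical` applied
#'   to the roster (e.g. MSI status stored in a `subtype` column).
#' @param min_cases Optional integer: drop tumor types with fewer cases.
#' @param relabel Optional named character map applied to `tumor_type`
#'   before filtering (e.g. `c(COAD = "COADREAD", READ = "COADREAD")` to
#'   merge labels).
#' @return The filtered cohort (N updated).
#' @export
filter_cohort <- function(cohort, tumor_types = NULL, subtype = NULL,
                          min_cases = NULL, relabel = NULL) {
  samples <- copy(cohort$samples)
  n_before <- nrow(samples)
  if (!is.null(relabel)) {
    hit <- samples$tumor_type %in% names(relabel)
    samples[hit, tumor_type := unname(relabel[tumor_type])]
  }
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(tumor_types)) keep <- keep & samples$tumor_type %in% tumor_types
  if (!is.null(subtype)) keep <- keep & isTRUE_vec(subtype(samples))
  if (!is.null(min_cases)) {
    tab <- table(samples$tumor_type[keep])
    ok_types <- names(tab)[tab >= min_cases]
    keep <- keep & samples$tumor_type %in% ok_types
  }
  samples <- samples[keep]
  if (nrow(samples) == 0L)
    stop("filter removed all samples (empty cohort)")
  records <- cohort$records[sample_id %in% samples$sample_id]
  if (!is.null(relabel)) {
    hit <- records$tumor_type %in% names(relabel)
    records[hit, tumor_type := unname(relabel[tumor_type])]
  }
  message(sprintf("filter_cohort: %d -> %d samples, %d -> %d records",
                  n_before, nrow(samples), nrow(cohort$records),
                  nrow(records)))
  new_cohort(records, samples)
}

isTRUE_vec <- function(x) { x[is.na(x)] <- FALSE; as.logical(x) }

#' Gene model: a coding sequence with validation
#'
#' @param gene Gene symbol.
#' @param cds Coding sequence (A/C/G/T). Length must be divisible by 3 and
#'   there must be no internal stop codon; a terminal stop codon, when
#'   present, is excluded from opportunity counting.
#' @param splice_opportunity Number of essential-splice positions attributed
#'   to the gene (0 for synthetic single-exon genes).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, cds, splice_opportunity = 0) {
  cds <- toupper(as.character(cds))
  if (grepl("[^ACGT]", cds))
    stop(sprintf("gene model error (%s): CDS contains non-ACGT characters", gene))
  if (nchar(cds) %% 3L != 0L)
    stop(sprintf("gene model error (%s): CDS length %d not divisible by 3",
                 gene, nchar(cds)))
  codons <- substring(cds, seq(1, nchar(cds) - 2, by = 3),
                      seq(3, nchar(cds), by = 3))
  stops <- codons %in% c("TAA", "TAG", "TGA")
  if (any(stops[-length(stops)]))
    stop(sprintf("gene model error (%s): internal stop codon at codon %d",
                 gene, which(stops[-length(stops)])[1]))
  if (splice_opportunity < 0) stop("splice_opportunity must be >= 0")
  structure(list(gene = gene, cds = cds,
                 splice_opportunity = splice_opportunity,
                 has_terminal_stop = stops[length(stops)]),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d nt (%d codons)%s, splice_opportunity=%g\n",
              x$gene, nchar(x$cds), nchar(x$cds) / 3,
              if (x$has_terminal_stop) " + terminal stop" else "",
              x$splice_opportunity))
  invisible(x)
}

#' Read coding sequences from FASTA into gene models
#'
#' @param path FASTA path; sequence names are taken as the first word of each
#'   header line.
#' @param splice_opportunity Optional named numeric vector of per-gene splice
#'   opportunities (default 0).
#' @return Named list of [gene_model()] objects.
#' @export
read_cds_fasta <- function(path, splice_opportunity = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  out <- lapply(seq_along(seqs), function(i) {
    so <- if (!is.null(splice_opportunity) && nm[i] %in% names(splice_opportunity))
      splice_opportunity[[nm[i]]] else 0
    gene_model(nm[i], as.character(seqs[[i]]), splice_opportunity = so)
  })
  names(out) <- nm
  out
}

#' Write gene models to FASTA
#'
#' @param models Named list of gene models.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(models, path) {
  lines <- unlist(lapply(models, function(m) c(paste0(">", m$gene), m$cds)))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (`name<TAB>description<TAB>gene...` per line).
#' @return Named list of character vectors; set descriptions are kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("GMT format error: line(s) with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <- setNames(
    vapply(parts, `[`, character(1), 2), names(sets))
  sets
}

#' Write gene sets to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a cell-line panel from TSV tables
#'
#' @param mutations TSV with first column `cell_line` and one 0/1 column per
#'   gene (any non-silent mutation flag).
#' @param viability Optional TSV, same shape, of knockout viability scores
#'   (lower = less viable); may be sparse (NA).
#' @param ic50 Optional TSV with columns `cell_line`, `drug`, `target_gene`,
#'   `ic50`.
#' @param tumor_types Optional TSV with columns `cell_line`, `tumor_type`.
#' @param ic50_log_scale Whether IC50 values are on a (natural) log scale, as
#'   GDSC publishes them; recorded, never converted.
#' @return An object of class `cell_line_panel`.
#' @export
read_panel_tables <- function(mutations, viability = NULL, ic50 = NULL,
                              tumor_types = NULL, ic50_log_scale = TRUE) {
  to_matrix <- function(path) {
    dt <- fread(path, sep = "\t")
    m <- as.matrix(dt[, -1, with = FALSE])
    rownames(m) <- as.character(dt[[1]])
    m
  }
  mut <- to_matrix(mutations)
  via <- if (!is.null(viability)) to_matrix(viability) else NULL
  ic <- if (!is.null(ic50)) as.data.table(fread(ic50, sep = "\t")) else NULL
  tt <- if (!is.null(tumor_types)) {
    d <- fread(tumor_types, sep = "\t")
    setNames(as.character(d$tumor_type), as.character(d$cell_line))
  } else NULL
  cell_line_panel(mut, via, ic, tt, ic50_log_scale)
}

#' Construct a cell-line panel object
#'
#' @param mutations Binary cell line x gene matrix.
#' @param viability Optional cell line x knockout-gene score matrix.
#' @param ic50 Optional data.frame `(cell_line, drug, target_gene, ic50)`.
#' @param tumor_type Optional named character vector keyed by cell line.
#' @param ic50_log_scale Flag recording the IC50 scale.
#' @return An object of class `cell_line_panel`.
#' @export
cell_line_panel <- function(mutations, viability = NULL, ic50 = NULL,
                            tumor_type = NULL, ic50_log_scale = TRUE) {
  if (is.null(rownames(mutations)))
    stop("mutation matrix needs cell-line rownames")
  check_lines <- function(lines, what) {
    orphan <- setdiff(lines, rownames(mutations))
    if (length(orphan))
      stop(sprintf("%s references cell line(s) absent from mutation matrix: %s",
                   what, paste(head(orphan, 5), collapse = ", ")))
  }
  if (!is.null(viability)) check_lines(rownames(viability), "viability")
  if (!is.null(ic50)) {
    ic50 <- as.data.table(ic50)
    req <- c("cell_line", "drug", "target_gene", "ic50")
    if (!all(req %in% names(ic50)))
      stop("ic50 table needs columns: ", paste(req, collapse = ", "))
    check_lines(ic50$cell_line, "ic50 table")
  }
  if (!is.null(tumor_type)) check_lines(names(tumor_type), "tumor_type")
  structure(list(mutations = mutations, viability = viability, ic50 = ic50,
                 tumor_type = tumor_type, ic50_log_scale = ic50_log_scale),
            class = "cell_line_panel")
}

#' Write a results table to TSV
#'
#' Plain tab-separated output with a header row; [data.table::fread()] of
#' the result reproduces the table (round-trip fidelity).
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  fwrite(as.data.table(table), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
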