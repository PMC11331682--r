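# Shared fixtures and independent oracles. Everything is generated in code;
# no binary data.

# --- independent codon-enumeration oracle -----------------------------------
# Classifies all 9 possible substitutions of a single codon by brute force
# against Biostrings' genetic code, independently of the package's
# opportunity-table construction.
oracle_codon_classes <- function(codon) {
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  out <- c(synonymous = 0, missense = 0, nonsense = 0)
  for (i in 1:3) for (b in setdiff(bases, substr(codon, i, i))) {
    mut <- codon
    substr(mut, i, i) <- b
    cls <- if (code[[mut]] == code[[codon]]) "synonymous"
           else if (code[[mut]] == "*") "nonsense" else "missense"
    out[cls] <- out[cls] + 1
  }
  out
}

# Site-level brute-force dN/dS oracle (uniform rates): enumerates class
# opportunities directly from the CDS, then (n_N / L_N) / (n_S / L_S).
oracle_uniform_dnds <- function(cds_list, records, gene, cls) {
  opp <- sapply(cds_list, function(cds) {
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    if (codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
      codons <- codons[-length(codons)]
    Reduce(`+`, lapply(codons, oracle_codon_classes))
  })
  raw <- if (cls == "missense") "missense" else "nonsense"
  L_N <- opp[raw, gene]
  L_S <- sum(opp["synonymous", ])
  obs_cls <- if (cls == "missense") "missense" else c("nonsense", "splice_site")
  n_N <- sum(records$gene == gene & records$impact_class %in% obs_cls)
  n_S <- sum(records$impact_class == "synonymous" &
               records$gene %in% colnames(opp))
  (n_N / L_N) / (n_S / L_S)
}

# --- toy gene models --------------------------------------------------------
toy_models <- function() {
  list(
    GA = gene_model("GA", paste0("ATG", "AAACCCGGGTTTCTTAGAGAC", "TGA")),
    GB = gene_model("GB", paste0("ATG", "TGGCATGATCGATTTAAAGGA", "TAA")),
    GC = gene_model("GC", paste0("ATG", "CTTCGCACTGCTAGTGGTATT", "TAA"))
  )
}

# Build a cohort by hand from a compact spec: list of (sample, gene, class)
# plus optional explicit roster. Positions/alleles are filled from the gene
# model's first site of the class so trinucleotide fitting works.
toy_cohort <- function(triples, models = toy_models(), roster = NULL) {
  tabs <- lapply(models, build_opportunity_table, granularity = "trinuc96")
  rows <- lapply(triples, function(tr) {
    g <- tr[[2]]; cls <- tr[[3]]
    if (cls %in% c("frameshift_indel", "inframe_indel")) {
      data.frame(sample_id = tr[[1]], gene = g, impact_class = cls,
                 ref_allele = "A", alt_allele = "-",
                 t_alt_count = 30L, t_ref_count = 70L, position = 5L)
    } else {
      site <- tabs[[g]]$sites[class == cls][1]
      data.frame(sample_id = tr[[1]], gene = g, impact_class = cls,
                 ref_allele = site$ref, alt_allele = site$alt,
                 t_alt_count = 30L, t_ref_count = 70L,
                 position = site$pos)
    }
  })
  new_cohort(do.call(rbind, rows), samples = roster)
}

# --- shared small simulation (built once per test run) ----------------------
# A modest neutral cohort reused by several unit tests.
shared_neutral_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 424, n_samples = 400, n_genes = 12,
                        gene_length_codons = 200, mut_rate = 1e-4,
                        indel_rate = 2e-5)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

# Write a small MAF text file for io tests.
write_toy_maf <- function(path, extra_class = NULL) {
  lines <- c(
    paste(c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
            "Reference_Allele", "Tumor_Seq_Allele2", "t_alt_count",
            "t_ref_count", "Start_Position"), collapse = "\t"),
    "KRAS\tS1\tMissense_Mutation\tG\tA\t30\t70\t10",
    "TP53\tS1\tSilent\tC\tT\t20\t80\t33",
    "APC\tS2\tFrame_Shift_Del\tAG\tA\t15\t85\t101")
  if (!is.null(extra_class))
    lines <- c(lines, paste("EGFR", "S3", extra_class, "T", "C", 9, 91, 7,
                            sep = "\t"))
  writeLines(lines, path)
  path
}
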