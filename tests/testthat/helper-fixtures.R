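# Fixture builders shared across test files. Everything is generated in code;
# no data files.

tiny_spec <- function(...) {
  defaults <- list(n_cases = 60, n_controls = 40, n_genes = 6,
                   variants_per_gene_rate = 4, n_common_variants = 30,
                   planted_gene = "GENE001", planted_case_carriers = 5,
                   planted_control_carriers = 0, seed = 101)
  do.call(cohort_spec, utils::modifyList(defaults, list(...), keep.null = TRUE))
}

# a clean site row; override any field
make_sites <- function(n = 1, ...) {
  out <- data.frame(
    chrom = "X", pos = seq_len(n) * 100L,
    ref = "A", alt = "G", gene = "GENE001",
    consequence = "missense", pop_maf = 5e-5, male_maf = 5e-5,
    pop_call_rate = 0.99, pass_flag = TRUE, n_alleles = 2L,
    span_nt = 1L, in_decoy = FALSE, stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

make_samples <- function(n_cases = 3, n_controls = 2) {
  data.frame(
    sample_id = c(sprintf("CASE%03d", seq_len(n_cases)),
                  sprintf("CTRL%03d", seq_len(n_controls))),
    phenotype = rep(c("case", "control"), c(n_cases, n_controls)),
    age = 40, stratum = "S1", stringsAsFactors = FALSE
  )
}

# long genotype records for every sample x site; allele counts given as a
# samples x sites matrix (NA = missing); clean read metadata unless overridden
make_genotypes <- function(samples, sites, ac_matrix,
                           depth = 40L, gq = 90L) {
  vid <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  n_s <- nrow(samples); n_v <- nrow(sites)
  ac <- as.vector(ac_matrix)
  alt <- ifelse(!is.na(ac) & ac == 1L, depth %/% 2L, 0L)
  data.frame(
    sample_id = rep(samples$sample_id, times = n_v),
    variant_id = rep(vid, each = n_s),
    allele_count = as.integer(ac),
    depth = as.integer(ifelse(is.na(ac), 0L, depth)),
    gq = as.integer(ifelse(is.na(ac), 0L, gq)),
    ref_reads = as.integer(ifelse(is.na(ac), 0L, depth - alt)),
    alt_reads = as.integer(ifelse(is.na(ac), 0L, alt)),
    stringsAsFactors = FALSE
  )
}
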