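# Small shared fixtures, built in code.

# A compact simulation configuration for fast pipeline tests.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_scaffolds = 5, windows_per_scaffold = 20,
                   snps_per_window = 25, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Write a VCF from explicit per-sample GT strings; returns the path.
write_toy_vcf <- function(records, sample_ids, path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  writeLines(c(hdr, records), path)
  path
}

toy_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Genotype matrix built directly from a call matrix (sites x samples).
toy_genotype_matrix <- function(calls, groups = NULL, scaffold = "scaffold_1") {
  n_sites <- nrow(calls)
  n_samp <- ncol(calls)
  if (is.null(groups)) groups <- rep("control", n_samp)
  genotype_matrix(
    sites = tibble::tibble(scaffold = scaffold, pos = seq_len(n_sites) * 10L,
                           ref = "A", alt = "T"),
    calls = calls,
    samples = tibble::tibble(sample_id = sprintf("s%02d", seq_len(n_samp)),
                             group = groups)
  )
}
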