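#' Write a genotype matrix as VCFv4.2
#'
#' Minimal GT-only dialect: biallelic SNP records, unphased `0/0`, `0/1`,
#' `1/1` calls and `./.` for missing genotypes.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @param scaffold_length Optional single length used for the `##contig`
#'   header lines (omitted when `NULL`).
#' @return The path, invisibly.
#' @export
write_genotype_vcf <- function(gm, path, scaffold_length = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, open = "wb")  # binary mode: fixed LF line endings
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=larvascan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(scaffold_length)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          unique(gm$sites$scaffold), scaffold_length))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$samples$sample_id),
                      collapse = "\t"))
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  ok <- !is.na(gm$calls)
  gt[ok] <- gt_codes[gm$calls[ok] + 1L]
  body <- paste(
    gm$sites$scaffold, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
    ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Keeps biallelic SNP records only; multiallelic or non-SNP records are
#' skipped with a reported count. Phased separators are normalized to `/`
#' and half-missing diploid calls (e.g. `0/.`) are treated as missing.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param group_map Either a data frame with columns `sample_id` and
#'   `group`, or a named character vector mapping sample IDs to group
#'   labels. Every sample in the VCF must be present.
#' @return A [genotype_matrix()]; the number of skipped records is attached
#'   as attribute `n_skipped`.
#' @export
read_vcf <- function(path, group_map) {
  if (is.data.frame(group_map)) {
    stopifnot(all(c("sample_id", "group") %in% names(group_map)))
    gmap <- setNames(as.character(group_map$group),
                     as.character(group_map$sample_id))
  } else {
    gmap <- group_map
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    message(sprintf("read_vcf: skipped %d multiallelic/non-SNP record(s)",
                    n_skipped))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[snp, , drop = FALSE]
  samples <- colnames(gt)
  missing_samples <- setdiff(samples, names(gmap))
  if (length(missing_samples)) {
    stop("sample(s) absent from group map: ",
         paste(missing_samples, collapse = ", "))
  }
  gt <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  calls[gt == "0/0"] <- 0L
  calls[gt == "0/1" | gt == "1/0"] <- 1L
  calls[gt == "1/1"] <- 2L
  sites <- tibble::tibble(
    scaffold = fix[snp, "CHROM"],
    pos = as.integer(fix[snp, "POS"]),
    ref = ref[snp], alt = alt[snp]
  )
  out <- genotype_matrix(
    sites, calls,
    tibble::tibble(sample_id = samples, group = unname(gmap[samples]))
  )
  attr(out, "n_skipped") <- n_skipped
  out
}
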