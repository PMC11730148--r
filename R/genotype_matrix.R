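#' Construct a genotype matrix
#'
#' The central container of the pipeline: biallelic SNP calls coded as
#' derived/alt-allele counts (0/1/2, `NA` = missing) for sites in rows and
#' samples in columns, with scaffold coordinates and a condition label per
#' sample.
#'
#' @param sites Data frame with columns `scaffold`, `pos` (1-based),
#'   `ref`, `alt`; one row per biallelic SNP, unique on (scaffold, pos).
#' @param calls Integer matrix, `nrow(sites)` x `nrow(samples)`, entries in
#'   `{0, 1, 2, NA}`.
#' @param samples Data frame with columns `sample_id` and `group`
#'   (each group label typically `"control"` or `"heat"`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, calls, samples) {
  sites <- tibble::as_tibble(sites)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    all(c("scaffold", "pos", "ref", "alt") %in% names(sites)),
    all(c("sample_id", "group") %in% names(samples)),
    is.matrix(calls),
    nrow(calls) == nrow(sites),
    ncol(calls) == nrow(samples)
  )
  if (anyDuplicated(sites[, c("scaffold", "pos")])) {
    stop("sites must be unique on (scaffold, pos)")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("calls must be 0, 1, 2 or NA")
  }
  colnames(calls) <- samples$sample_id
  structure(
    list(sites = sites, calls = calls, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  grp <- table(x$samples$group)
  cat(sprintf(
    "<genotype_matrix> %d sites x %d samples (%s); %.1f%% missing\n",
    nrow(x$sites), nrow(x$samples),
    paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' Subset a genotype matrix by samples
#'
#' @param gm A [genotype_matrix()].
#' @param sample_ids Character vector of sample IDs to keep, or `NULL`.
#' @param group Optional group label; keeps all samples of that group
#'   (intersected with `sample_ids` when both are given).
#' @return A `genotype_matrix` with the selected samples; sites are kept
#'   as-is (no re-filtering).
#' @export
subset_samples <- function(gm, sample_ids = NULL, group = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- rep(TRUE, nrow(gm$samples))
  if (!is.null(group)) keep <- keep & gm$samples$group %in% group
  if (!is.null(sample_ids)) keep <- keep & gm$samples$sample_id %in% sample_ids
  if (!any(keep)) stop("no samples left after subsetting")
  genotype_matrix(gm$sites, gm$calls[, keep, drop = FALSE],
                  gm$samples[keep, , drop = FALSE])
}
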