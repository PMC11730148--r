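#' Classify windows into percentile tails
#'
#' Windows at or below the `lower_q` percentile of the chosen statistic are
#' called `positive-tail` (rare-allele excess, sweep-like) and windows at
#' or above the `upper_q` percentile `balancing-tail`
#' (intermediate-frequency excess); all others are `interior`. Cutoffs are
#' linear-interpolation percentiles (quantile type 7) over the valid
#' windows with a defined statistic; tail membership is closed (`<=` / `>=`).
#' If the two cutoffs coincide (degenerate, e.g. constant values), windows
#' that would fall in both tails are assigned `interior` with a warning.
#'
#' @param stats Output of [window_statistics()].
#' @param lower_q,upper_q Tail percentiles (defaults 5 and 95).
#' @param statistic Column to classify on, `"tajima_d"` (default) or
#'   `"pi"`.
#' @return Tibble with `scaffold`, `start`, `value`, `class`; cutoffs,
#'   percentiles, statistic and window size kept as attributes.
#' @export
classify_tails <- function(stats, lower_q = 5, upper_q = 95,
                           statistic = c("tajima_d", "pi")) {
  statistic <- match.arg(statistic)
  stopifnot(lower_q > 0, upper_q < 100, lower_q < upper_q)
  x <- stats[[statistic]]
  keep <- stats$valid & !is.na(x)
  df <- tibble::tibble(scaffold = stats$scaffold[keep],
                       start = stats$start[keep],
                       value = x[keep])
  if (nrow(df) < 20) {
    warning("fewer than 20 valid windows; percentile cutoffs are unstable")
  }
  lo <- unname(quantile(df$value, lower_q / 100, type = 7))
  hi <- unname(quantile(df$value, upper_q / 100, type = 7))
  cls <- rep("interior", nrow(df))
  in_lower <- df$value <= lo
  in_upper <- df$value >= hi
  both <- in_lower & in_upper
  if (any(both)) {
    warning("degenerate cutoffs: ", sum(both),
            " window(s) fell in both tails; assigned interior")
    in_lower[both] <- FALSE
    in_upper[both] <- FALSE
  }
  cls[in_lower] <- "positive-tail"
  cls[in_upper] <- "balancing-tail"
  df$class <- factor(cls, levels = c("positive-tail", "interior",
                                     "balancing-tail"))
  attr(df, "cutoffs") <- c(lower = lo, upper = hi)
  attr(df, "percentiles") <- c(lower = lower_q, upper = upper_q)
  attr(df, "statistic") <- statistic
  attr(df, "window_size") <- attr(stats, "window_size")
  df
}

#' Shared and unique outlier windows across conditions
#'
#' For each tail, counts the outlier windows of each condition, their
#' intersection (by window key) and the condition-unique remainders; the
#' inclusion-exclusion identity
#' `n_control + n_heat - n_shared = n_union` holds by construction.
#'
#' @param calls_control,calls_heat Outputs of [classify_tails()].
#' @return Tibble with one row per tail (`n_control`, `n_heat`, `n_shared`,
#'   `n_unique_control`, `n_unique_heat`, `n_union`); the shared window
#'   keys are attached as attribute `shared_windows` (a named list).
#' @export
contrast_conditions <- function(calls_control, calls_heat) {
  key <- function(df, cls) {
    d <- df[df$class == cls, , drop = FALSE]
    paste(d$scaffold, d$start, sep = ":")
  }
  tails <- c("positive-tail", "balancing-tail")
  shared_keys <- list()
  rows <- lapply(tails, function(tl) {
    kc <- key(calls_control, tl)
    kh <- key(calls_heat, tl)
    sh <- intersect(kc, kh)
    shared_keys[[tl]] <<- sh
    tibble::tibble(
      tail = tl,
      n_control = length(kc), n_heat = length(kh), n_shared = length(sh),
      n_unique_control = length(setdiff(kc, kh)),
      n_unique_heat = length(setdiff(kh, kc)),
      n_union = length(union(kc, kh))
    )
  })
  out <- dplyr::bind_rows(rows)
  stopifnot(all(out$n_control + out$n_heat - out$n_shared == out$n_union))
  attr(out, "shared_windows") <- shared_keys
  out
}

#' Map outlier windows to CDS annotations through flanking overlap
#'
#' A gene is linked to a called window when its CDS interval overlaps the
#' window extended by `flank` bp on both sides,
#' `[start - flank, end + flank)` in 0-based half-open coordinates — the
#' coordinate-space equivalent of searching the 1000-bp flanking sequence
#' around each outlier locus for nearby coding sequence. Strand is ignored.
#'
#' @param calls Output of [classify_tails()] (or any tibble with
#'   `scaffold`, `start`, `class`).
#' @param annotation Tibble with `gene_id`, `scaffold`, `start`, `end`
#'   (0-based half-open CDS intervals).
#' @param flank Flank width in bp (default 1000).
#' @param window_size Window length; defaults to the attribute carried by
#'   `calls`.
#' @param classes Window classes to map (defaults to both tails).
#' @param proteome Optional tibble with `gene_id`, `in_larva` used by
#'   `larva_only`.
#' @param larva_only If `TRUE`, restrict to genes with `in_larva == 1`
#'   (requires `proteome`), mirroring the restriction to CDS encoding
#'   larval proteins.
#' @return Tibble with `scaffold`, `start`, `class`, `gene_id`; one row per
#'   (window, gene) link.
#' @export
map_windows_to_genes <- function(calls, annotation, flank = 1000,
                                 window_size = attr(calls, "window_size"),
                                 classes = c("positive-tail",
                                             "balancing-tail"),
                                 proteome = NULL, larva_only = FALSE) {
  if (is.null(window_size)) stop("window_size is required")
  ann <- tibble::as_tibble(annotation)
  stopifnot(all(c("gene_id", "scaffold", "start", "end") %in% names(ann)),
            all(ann$end > ann$start), flank >= 0)
  if (larva_only) {
    if (is.null(proteome)) stop("larva_only = TRUE requires a proteome table")
    keep_genes <- proteome$gene_id[proteome$in_larva == 1]
    ann <- ann[ann$gene_id %in% keep_genes, , drop = FALSE]
  }
  w <- calls[calls$class %in% classes, , drop = FALSE]
  if (nrow(w) == 0 || nrow(ann) == 0) {
    return(tibble::tibble(scaffold = character(), start = integer(),
                          class = character(), gene_id = character()))
  }
  unknown <- !ann$scaffold %in% unique(w$scaffold)
  if (any(unknown)) {
    message(sprintf(
      "map_windows_to_genes: %d annotation(s) on scaffolds without called windows",
      sum(unknown)))
  }
  # 0-based half-open -> 1-based closed IRanges
  wr <- GenomicRanges::GRanges(
    w$scaffold,
    IRanges::IRanges(start = pmax(0L, w$start - flank) + 1L,
                     end = w$start + window_size + flank)
  )
  gr <- GenomicRanges::GRanges(
    ann$scaffold,
    IRanges::IRanges(start = ann$start + 1L, end = ann$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(wr, gr))
  tibble::tibble(
    scaffold = w$scaffold[S4Vectors::queryHits(hits)],
    start = w$start[S4Vectors::queryHits(hits)],
    class = as.character(w$class[S4Vectors::queryHits(hits)]),
    gene_id = ann$gene_id[S4Vectors::subjectHits(hits)]
  )
}

#' Build a binary gene score table for enrichment
#'
#' Genes mapped to outlier windows of the requested tail receive score 1,
#' all other background genes score 0. The background is the set of genes
#' detected in the larval proteome when a proteome table is supplied,
#' otherwise every annotated gene.
#'
#' @param mapping Output of [map_windows_to_genes()].
#' @param annotation Tibble with at least `gene_id` (the gene universe).
#' @param tail Which tail's genes score 1 (`"balancing-tail"` or
#'   `"positive-tail"`).
#' @param proteome Optional tibble with `gene_id`, `in_larva`.
#' @return Tibble with `gene_id`, `score` (0/1), `in_background` (logical).
#' @export
gene_score_table <- function(mapping, annotation,
                             tail = c("balancing-tail", "positive-tail"),
                             proteome = NULL) {
  tail <- match.arg(tail)
  scored <- unique(mapping$gene_id[mapping$class == tail])
  out <- tibble::tibble(
    gene_id = unique(annotation$gene_id),
    score = as.integer(unique(annotation$gene_id) %in% scored)
  )
  out$in_background <- if (is.null(proteome)) TRUE else
    out$gene_id %in% proteome$gene_id[proteome$in_larva == 1]
  out
}
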