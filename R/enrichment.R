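#' Mann-Whitney U test for category enrichment
#'
#' Rank-sum comparison of the scores of genes inside a category against
#' those outside, with midrank tie handling. The U statistic is
#' `sum(ranks of the category) - n1 (n1 + 1) / 2`. For combined sample
#' sizes up to `exact_max_n` the one-sided p-value is computed by exact
#' enumeration over all equally likely placements of the category; above
#' that, from the normal approximation with tie-corrected variance and a
#' continuity correction. If every score is identical across both groups
#' the p-value is 1.
#'
#' @param x_in Scores of the genes inside the category.
#' @param x_out Scores of the genes outside the category.
#' @param alternative `"greater"` (default; enrichment of high scores in
#'   the category), `"less"`, or `"two.sided"`.
#' @param exact_max_n Maximum combined size for exact enumeration.
#' @return A list with `U`, `p_value`, `method` (`"exact"`, `"normal"` or
#'   `"degenerate"`).
#' @examples
#' mann_whitney_u(c(1, 1, 1), rep(0, 7))  # exact p = 1/120
#' @export
mann_whitney_u <- function(x_in, x_out,
                           alternative = c("greater", "less", "two.sided"),
                           exact_max_n = 20) {
  alternative <- match.arg(alternative)
  n1 <- length(x_in)
  n2 <- length(x_out)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  pooled <- c(x_in, x_out)
  n <- n1 + n2
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (length(unique(pooled)) == 1L) {
    return(list(U = u, p_value = 1, method = "degenerate"))
  }

  if (n <= exact_max_n) {
    subsets <- utils::combn(n, n1)
    r_sub <- matrix(r[subsets], nrow = n1)
    u_all <- colSums(r_sub) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_ge <- mean(u_all >= u - eps)
    p_le <- mean(u_all <= u + eps)
    p <- switch(alternative,
      greater = p_ge, less = p_le,
      two.sided = min(1, 2 * min(p_ge, p_le))
    )
    return(list(U = u, p_value = p, method = "exact"))
  }

  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = u, p_value = 1, method = "degenerate"))
  mu <- n1 * n2 / 2
  sd <- sqrt(sigma2)
  p <- switch(alternative,
    greater = pnorm((u - mu - 0.5) / sd, lower.tail = FALSE),
    less = pnorm((u - mu + 0.5) / sd),
    two.sided = {
      z <- (u - mu - sign(u - mu) * 0.5) / sd
      min(1, 2 * pnorm(-abs(z)))
    }
  )
  list(U = u, p_value = min(1, max(p, .Machine$double.xmin)),
       method = "normal")
}

#' Rank-based GO enrichment over a gene score table
#'
#' One Mann-Whitney U test per qualifying GO term and namespace, comparing
#' the scores of the term's genes against the rest of the background
#' (genes flagged `in_background`, e.g. CDS encoding larval proteins).
#' Raw p-values are Benjamini-Hochberg adjusted within each namespace.
#' Terms smaller than `min_category` or larger than `max_category_frac`
#' of the background are skipped.
#'
#' @param scores Tibble with `gene_id`, `score` and optionally
#'   `in_background` (defaults to all `TRUE`); see [gene_score_table()].
#' @param go_map Tibble with `gene_id`, `go_id`, `namespace`.
#' @param min_category Minimum genes per tested term (default 5).
#' @param max_category_frac Maximum term size as a fraction of the
#'   background (default 0.5).
#' @param alternative Passed to [mann_whitney_u()].
#' @param exact_max_n Passed to [mann_whitney_u()].
#' @return Tibble sorted by raw p: `go_id`, `namespace`, `n_category`,
#'   `n_scored` (score-1 genes in the term), `U`, `p_value`, `p_adj`;
#'   the number of skipped terms is attached as attribute
#'   `n_skipped_terms`.
#' @export
run_enrichment <- function(scores, go_map, min_category = 5,
                           max_category_frac = 0.5,
                           alternative = "greater", exact_max_n = 20) {
  scores <- tibble::as_tibble(scores)
  if (!"in_background" %in% names(scores)) scores$in_background <- TRUE
  bg <- scores[scores$in_background, , drop = FALSE]
  if (nrow(bg) == 0) stop("background is empty")
  map <- go_map[go_map$gene_id %in% bg$gene_id, , drop = FALSE]
  if (nrow(map) == 0) {
    warning("GO map covers no background gene; empty result")
    return(empty_enrichment())
  }
  score_vec <- setNames(bg$score, bg$gene_id)
  max_size <- max_category_frac * nrow(bg)

  n_skipped <- 0L
  rows <- list()
  for (ns in sort(unique(map$namespace))) {
    sub <- map[map$namespace == ns, , drop = FALSE]
    terms <- split(sub$gene_id, sub$go_id)
    sizes <- lengths(lapply(terms, unique))
    qualify <- sizes >= min_category & sizes <= max_size
    n_skipped <- n_skipped + sum(!qualify)
    terms <- terms[qualify]
    if (!length(terms)) next
    res <- lapply(names(terms), function(tm) {
      members <- unique(terms[[tm]])
      inside <- score_vec[members]
      outside <- score_vec[setdiff(names(score_vec), members)]
      mw <- mann_whitney_u(inside, outside, alternative = alternative,
                           exact_max_n = exact_max_n)
      tibble::tibble(go_id = tm, namespace = ns,
                     n_category = length(members),
                     n_scored = sum(inside > 0),
                     U = mw$U, p_value = mw$p_value)
    })
    res <- dplyr::bind_rows(res)
    res$p_adj <- p.adjust(res$p_value, method = "BH")
    rows[[ns]] <- res
  }
  if (!length(rows)) {
    warning("no GO term qualified; empty result")
    out <- empty_enrichment()
  } else {
    out <- dplyr::arrange(dplyr::bind_rows(rows), .data$p_value)
  }
  attr(out, "n_skipped_terms") <- n_skipped
  out
}

empty_enrichment <- function() {
  tibble::tibble(go_id = character(), namespace = character(),
                 n_category = integer(), n_scored = integer(),
                 U = numeric(), p_value = numeric(), p_adj = numeric())
}

#' Overlap of enriched GO-term sets across analyses
#'
#' Pairwise and overall intersections of GO-term identifier sets from two
#' or more enrichment results (e.g. condition x tail), either over all
#' tested terms or restricted to terms with raw p below `alpha`.
#'
#' @param results Named list of [run_enrichment()] outputs.
#' @param alpha Optional raw-p inclusion threshold; `NULL` keeps all tested
#'   terms.
#' @return A list: `sets` (the term sets), `sizes`, `pairwise` (matrix of
#'   intersection counts), `n_common_all`.
#' @export
overlap_summary <- function(results, alpha = NULL) {
  stopifnot(is.list(results), length(results) >= 2,
            !is.null(names(results)), all(nzchar(names(results))))
  sets <- lapply(results, function(r) {
    ids <- if (is.null(alpha)) r$go_id else r$go_id[r$p_value < alpha]
    unique(ids)
  })
  k <- length(sets)
  pw <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  list(sets = sets, sizes = lengths(sets), pairwise = pw,
       n_common_all = length(Reduce(intersect, sets)))
}
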