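#' Mixed-model likelihood-ratio contrast of window statistics
#'
#' Fits, by maximum likelihood, a linear mixed model with a fixed condition
#' effect and a random intercept per window
#' (`value ~ condition + (1 | window)`) and the nested model without the
#' condition effect, and compares them with a likelihood-ratio test on
#' 1 degree of freedom. ML (not REML) is required for a likelihood-ratio
#' test on a fixed effect. Models are fitted with lme4.
#'
#' @param merged Output of [merge_conditions()].
#' @param statistic `"tajima_d"` (default) or `"pi"`.
#' @return An object of class `lmm_contrast`: `statistic`, `chisq`, `df`,
#'   `p_value`, `estimate` (heat minus control fixed effect), `aic_full`,
#'   `aic_reduced`, `loglik_full`, `loglik_reduced`, `n_windows`,
#'   `singular` and any fit `messages`.
#' @export
lmm_contrast <- function(merged, statistic = c("tajima_d", "pi")) {
  statistic <- match.arg(statistic)
  vc <- merged[[paste0(statistic, "_control")]]
  vh <- merged[[paste0(statistic, "_heat")]]
  if (is.null(vc) || is.null(vh)) {
    stop("merged table lacks the paired columns for ", statistic)
  }
  ok <- !is.na(vc) & !is.na(vh)
  n_windows <- sum(ok)
  if (n_windows < 2) stop("need at least 2 paired windows")
  if (n_windows < 30) {
    warning("fewer than 30 paired windows; the LRT may be unreliable")
  }
  window <- paste(merged$scaffold[ok], merged$start[ok], sep = ":")
  long <- data.frame(
    value = c(vc[ok], vh[ok]),
    condition = factor(rep(c("control", "heat"), each = n_windows),
                       levels = c("control", "heat")),
    window = factor(rep(window, 2))
  )
  msgs <- character(0)
  fit_ml <- function(formula, start = NULL) {
    withCallingHandlers(
      lme4::lmer(formula, data = long, REML = FALSE, start = start,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
      },
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      }
    )
  }
  full <- tryCatch(fit_ml(value ~ condition + (1 | window)),
                   error = function(e) e)
  reduced <- tryCatch(fit_ml(value ~ 1 + (1 | window)),
                      error = function(e) e)
  if (inherits(full, "error") || inherits(reduced, "error")) {
    bad <- if (inherits(full, "error")) full else reduced
    stop("mixed-model fit failed: ", conditionMessage(bad),
         if (length(msgs)) paste0(" [", paste(msgs, collapse = "; "), "]"))
  }
  # Each model's profiled deviance is also evaluated at the other model's
  # stopping point and the better value kept. For regular fits this changes
  # nothing; on a perfect-fit boundary (window intercepts explain the data
  # exactly, residual variance ~ 0) the profiled likelihood is unbounded in
  # theta and the two optimizers stop at arbitrary points, but the profiled
  # deviances coincide for all theta, so this pins the ratio at zero
  # instead of an optimizer artifact.
  dev_full <- lme4::lmer(value ~ condition + (1 | window), data = long,
                         REML = FALSE, devFunOnly = TRUE)
  dev_red <- lme4::lmer(value ~ 1 + (1 | window), data = long,
                        REML = FALSE, devFunOnly = TRUE)
  theta_f <- lme4::getME(full, "theta")
  theta_r <- lme4::getME(reduced, "theta")
  ll_full <- max(as.numeric(logLik(full)), -dev_full(theta_r) / 2)
  ll_red <- max(as.numeric(logLik(reduced)), -dev_red(theta_f) / 2)
  chisq <- 2 * (ll_full - ll_red)
  if (chisq < 0) {
    if (chisq > -1e-6) chisq <- 0 else {
      warning("negative likelihood-ratio statistic (", signif(chisq, 3),
              "); optimizer trouble")
      chisq <- max(0, chisq)
    }
  }
  structure(list(
    statistic = statistic,
    chisq = chisq, df = 1L,
    p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
    estimate = unname(lme4::fixef(full)["conditionheat"]),
    aic_full = AIC(full), aic_reduced = AIC(reduced),
    loglik_full = ll_full, loglik_reduced = ll_red,
    n_windows = n_windows,
    singular = lme4::isSingular(full) || lme4::isSingular(reduced),
    messages = unique(msgs)
  ), class = "lmm_contrast")
}

#' @export
print.lmm_contrast <- function(x, ...) {
  cat(sprintf(
    "<lmm_contrast> %s: Chisq = %.3g, df = %d, P = %.3g (n = %d windows)\n",
    x$statistic, x$chisq, x$df, x$p_value, x$n_windows))
  cat(sprintf("  full model: AIC = %.1f, logLik = %.1f; effect (heat - control) = %.4g\n",
              x$aic_full, x$loglik_full, x$estimate))
  if (x$singular) cat("  note: singular random-effect fit\n")
  invisible(x)
}

#' Subsampling robustness of the group contrast
#'
#' Repeatedly draws `k` control individuals without replacement (seed
#' `base_seed + iteration`, so every iteration is independently
#' reproducible), recomputes the control window statistics on the
#' subsample, and re-runs the mixed-model contrast of Tajima's D and pi
#' against the full heat group. This mirrors equalizing the control sample
#' size to the heat group (k = 10 of 16) with 100 repetitions.
#'
#' @param gm A [genotype_matrix()] containing both groups.
#' @param spec A [window_spec()].
#' @param k Control subsample size (default 10).
#' @param reps Number of iterations (default 100).
#' @param base_seed Base seed; iteration `i` uses `base_seed + i`.
#' @param n_mode Passed to [window_statistics()].
#' @return An object of class `subsample_robustness`: `results` (per-rep
#'   list with `iteration`, `seed`, `sample_ids`, `tajima_d` and `pi`
#'   [lmm_contrast()] objects) and `summary` (tibble with the fraction of
#'   significant reps and direction agreement per statistic).
#' @export
subsample_robustness <- function(gm, spec = window_spec(), k = 10,
                                 reps = 100, base_seed = 1L,
                                 n_mode = "median") {
  stopifnot(inherits(gm, "genotype_matrix"), reps >= 1)
  control_ids <- gm$samples$sample_id[gm$samples$group == "control"]
  if (k > length(control_ids)) {
    stop("k exceeds the control group size (", length(control_ids), ")")
  }
  stats_heat <- window_statistics(gm, spec, group = "heat", n_mode = n_mode)
  results <- vector("list", reps)
  for (r in seq_len(reps)) {
    seed <- base_seed + r
    set.seed(seed)
    ids <- sample(control_ids, k)
    gm_sub <- subset_samples(gm, sample_ids = c(
      ids, gm$samples$sample_id[gm$samples$group == "heat"]))
    stats_ctrl <- window_statistics(gm_sub, spec, group = "control",
                                    n_mode = n_mode)
    merged <- merge_conditions(stats_ctrl, stats_heat)
    results[[r]] <- list(
      iteration = r, seed = seed, sample_ids = sort(ids),
      tajima_d = lmm_contrast(merged, "tajima_d"),
      pi = lmm_contrast(merged, "pi")
    )
  }
  summarise_stat <- function(stat) {
    p <- vapply(results, function(x) x[[stat]]$p_value, numeric(1))
    est <- vapply(results, function(x) x[[stat]]$estimate, numeric(1))
    major <- sign(median(est))
    tibble::tibble(
      statistic = stat,
      frac_significant = mean(p < 0.05),
      frac_direction_agree = mean(sign(est) == major),
      median_estimate = median(est)
    )
  }
  structure(list(
    results = results,
    summary = dplyr::bind_rows(summarise_stat("tajima_d"),
                               summarise_stat("pi")),
    k = k, reps = reps, base_seed = base_seed
  ), class = "subsample_robustness")
}

#' @export
print.subsample_robustness <- function(x, ...) {
  cat(sprintf("<subsample_robustness> %d reps of %d control individuals (base seed %d)\n",
              x$reps, x$k, x$base_seed))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Compare per-tank survival between conditions
#'
#' Survival is treated as a proportion (alive / total per tank per day),
#' smoothed per condition with loess, and compared with a two-sided
#' Wilcoxon rank-sum test treating each tank as an independent replicate —
#' either on the final-day proportions (`mode = "endpoint"`, default; exact
#' p when there are no ties) or on all tank-day proportions pooled
#' (`mode = "per_day"`).
#'
#' @param tbl Tibble with columns `condition`, `tank`, `day`, `alive`,
#'   `total` (see [simulate_survival()]).
#' @param span Loess span, recorded in the output.
#' @param mode Aggregation feeding the rank test, see above.
#' @return A list: `curves` (tibble `condition`, `day`, `fitted`),
#'   `per_tank` (the proportions used by the test), `p_value`, `mode`,
#'   `span`.
#' @export
survival_compare <- function(tbl, span = 0.75,
                             mode = c("endpoint", "per_day")) {
  mode <- match.arg(mode)
  stopifnot(all(c("condition", "tank", "day", "alive", "total") %in%
                  names(tbl)))
  if (any(tbl$total <= 0)) stop("zero or negative tank totals")
  if (any(tbl$alive > tbl$total) || any(tbl$alive < 0)) {
    stop("alive counts must lie in [0, total]")
  }
  tbl <- tibble::as_tibble(tbl)
  tbl$prop <- tbl$alive / tbl$total
  n_tanks <- tapply(tbl$tank, tbl$condition, function(x) length(unique(x)))
  if (length(n_tanks) != 2 || any(n_tanks < 2)) {
    stop("need two conditions with >= 2 tanks each")
  }

  curves <- dplyr::bind_rows(lapply(split(tbl, tbl$condition), function(d) {
    days <- sort(unique(d$day))
    fit <- suppressWarnings(loess(prop ~ day, data = d, span = span,
                                  degree = 2))
    tibble::tibble(condition = d$condition[1], day = days,
                   fitted = as.numeric(predict(fit, newdata =
                                                 data.frame(day = days))))
  }))

  if (mode == "endpoint") {
    per_tank <- tbl |>
      dplyr::group_by(.data$condition, .data$tank) |>
      dplyr::slice_max(.data$day, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  } else {
    per_tank <- tbl
  }
  groups <- split(per_tank$prop, per_tank$condition)
  test <- suppressWarnings(
    wilcox.test(groups[[1]], groups[[2]], alternative = "two.sided",
                exact = mode == "endpoint")
  )
  list(curves = curves, per_tank = per_tank, p_value = test$p.value,
       mode = mode, span = span)
}
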