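#' Width of a confidence interval
#'
#' `upper - lower`, the efficiency measure used when comparing adjustment
#' models on bootstrap subsamples.
#'
#' @param estimate An `effect_estimate` (or any list with `lower`/`upper`).
#' @return Nonnegative scalar.
#' @export
ci_width <- function(estimate) {
  w <- estimate$upper - estimate$lower
  if (!is.finite(w) || w < 0) stop("invalid confidence bounds")
  w
}

#' Subsample bootstrap comparison of adjustment models
#'
#' The application-style evaluation against a reference model: each
#' iteration draws a random subsample (default 20% of the cohort, without
#' replacement), runs every adjustment model end to end (propensity fit,
#' caliper matching, effect estimate with inner bootstrap CI) for every
#' outcome, and records the point estimate and CI width. Models are then
#' compared with the reference (Model 4: measured confounders plus
#' embedding covariates) via the mean paired difference of estimates and of
#' CI widths over iterations, with percentile bootstrap CIs. The reference
#' compared with itself is identically zero.
#'
#' Iterations in which a model forms zero matched pairs are excluded and
#' counted.
#'
#' @param data Patient-level data frame (treatment, outcomes, covariates,
#'   embedding columns).
#' @param specs List of [model_spec()]s including the reference.
#' @param outcomes Named character vector of outcome columns (binary ->
#'   risk difference; continuous, e.g. length of stay -> mean difference).
#' @param treatment Treatment column name; default `"treatment"`.
#' @param n_boot Number of subsample iterations; default 1000.
#' @param fraction Subsample fraction in (0, 1]; default 0.2. The subsample
#'   size is `round(fraction * n)` exactly.
#' @param n_inner_boot Inner bootstrap replicates for each per-iteration
#'   CI; default 200.
#' @param caliper_fraction Matching caliper fraction; default 0.01.
#' @param reference `model_id` of the reference; default 4.
#' @param seed Master seed; default 1.
#' @return List of class `bootstrap_comparison`: `iterations` (one row per
#'   iteration x model x outcome), `comparison` (per outcome x model: mean
#'   estimate difference and mean CI-width difference vs the reference,
#'   each with percentile CIs), `n_excluded`.
#' @export
bootstrap_compare <- function(data, specs, outcomes,
                              treatment = "treatment", n_boot = 1000L,
                              fraction = 0.2, n_inner_boot = 200L,
                              caliper_fraction = 0.01, reference = 4L,
                              seed = 1L) {
  data <- as.data.frame(data)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (is.null(names(outcomes))) names(outcomes) <- outcomes
  ids <- vapply(specs, `[[`, 0L, "model_id")
  if (!reference %in% ids) stop("reference model ", reference, " not in specs")
  tr_all <- data[[treatment]]
  n <- nrow(data)
  m <- round(fraction * n)
  child <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_boot))
  rows <- list()
  n_excluded <- 0L
  for (b in seq_len(n_boot)) {
    res <- withr::with_seed(child[b], tryCatch({
      idx <- sample.int(n, m)
      dat <- data[idx, , drop = FALSE]
      tr <- tr_all[idx]
      iter_rows <- list()
      for (spec in specs) {
        mc <- NULL
        if (spec$model_id != 1L) {
          ps <- fit_propensity(dat, tr, spec)
          mc <- match_cohort(ps$ps, tr,
                             caliper_fraction = caliper_fraction)
        }
        for (oc in names(outcomes)) {
          est <- estimate_effect(dat[[outcomes[[oc]]]], tr, matched = mc,
                                 n_boot = n_inner_boot)
          iter_rows[[length(iter_rows) + 1L]] <- tibble::tibble(
            iteration = b, model = spec$model_id, outcome = oc,
            estimate = est$estimate, width = ci_width(est),
            n_pairs = if (is.null(mc)) NA_integer_ else nrow(mc))
        }
      }
      dplyr::bind_rows(iter_rows)
    }, error = function(e) {
      n_excluded <<- n_excluded + 1L
      message("iteration ", b, " excluded: ", conditionMessage(e))
      NULL
    }))
    rows[[b]] <- res
  }
  iterations <- dplyr::bind_rows(rows)
  if (nrow(iterations) == 0) stop("all bootstrap iterations failed")

  ref <- iterations[iterations$model == reference,
                    c("iteration", "outcome", "estimate", "width")]
  names(ref)[3:4] <- c("ref_estimate", "ref_width")
  paired <- dplyr::inner_join(iterations, ref,
                              by = c("iteration", "outcome"))
  paired$d_est <- paired$estimate - paired$ref_estimate
  paired$d_width <- paired$width - paired$ref_width
  pci <- function(x, q) quantile(x, q, names = FALSE, type = 7)
  comparison <- paired |>
    dplyr::group_by(.data$outcome, .data$model) |>
    dplyr::summarise(
      n_iter = dplyr::n(),
      mean_diff = mean(.data$d_est),
      diff_lo = pci(.data$d_est, 0.025),
      diff_hi = pci(.data$d_est, 0.975),
      mean_width_diff = mean(.data$d_width),
      width_lo = pci(.data$d_width, 0.025),
      width_hi = pci(.data$d_width, 0.975),
      .groups = "drop")
  structure(list(iterations = iterations, comparison = comparison,
                 n_excluded = n_excluded, reference = reference,
                 fraction = fraction, subsample_size = m),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat("<bootstrap_comparison> reference model ", x$reference,
      ", subsample ", x$subsample_size, " (fraction ", x$fraction, "), ",
      x$n_excluded, " iteration(s) excluded\n", sep = "")
  print(x$comparison, ...)
  invisible(x)
}
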