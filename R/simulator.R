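#' Random treatment assignment
#'
#' I.i.d. Bernoulli(p) treatment indicator, independent of everything else
#' by construction, so the true treatment-outcome risk difference is 0.
#' This is the first step of the bias-injection simulation: confounding is
#' introduced afterwards purely through outcome-dependent sampling.
#'
#' @param n Number of patients.
#' @param p Treatment probability in (0,1); default 0.5.
#' @param seed Seed; `NULL` uses the current RNG state.
#' @return Integer 0/1 vector of length `n`.
#' @export
assign_random_treatment <- function(n, p = 0.5, seed = NULL) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  draw <- function() rbinom(n, 1L, p)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Fit the prognostic model
#'
#' Main-effects logistic regression of the composite outcome (in-hospital
#' death or ADL dependency at discharge) on the measured-confounder
#' covariate set. Its predicted risks define the quartiles from which the
#' simulation samples treated patients, so confounding injected downstream
#' is, by construction, a function of exactly these covariates.
#'
#' @param data Data frame of covariates.
#' @param outcome Binary outcome vector (or column name in `data`).
#' @param covariates Covariate column names.
#' @return List of class `prognostic_fit`: `scores` (predicted risks),
#'   `auc` (apparent c-statistic), `coefficients`.
#' @export
fit_prognostic_model <- function(data, outcome, covariates) {
  if (is.character(outcome) && length(outcome) == 1) outcome <- data[[outcome]]
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(outcome)) < 2)
    stop("degenerate outcome: both classes must be present")
  X <- covariate_matrix(data, covariates)
  fit <- fit_logit(X, outcome)
  scores <- as.numeric(fit$fitted)
  structure(list(scores = scores, auc = cstat(scores, outcome),
                 coefficients = fit$coefficients, covariates = covariates),
            class = "prognostic_fit")
}

#' Quartile bins of predicted risk
#'
#' Cuts scores at their empirical 25/50/75 percentiles into labels
#' `Q1` (lowest risk) to `Q4` (highest risk); values equal to a cut point
#' fall in the lower bin. Degenerate score distributions collapse bins with
#' a warning (all-identical scores land in Q1).
#'
#' @param scores Finite numeric vector (e.g. `prognostic_fit$scores`).
#' @return Factor with levels `Q1..Q4`.
#' @export
quartile_bins <- function(scores) {
  if (!all(is.finite(scores))) stop("scores must be finite")
  qs <- quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  breaks <- unique(c(-Inf, qs, Inf))
  if (length(breaks) < 5)
    warning("tied score quantiles: quartile bins collapsed")
  bin <- .bincode(scores, breaks, right = TRUE, include.lowest = TRUE)
  factor(paste0("Q", bin), levels = paste0("Q", 1:4))
}

#' Scenario grid of quartile sampling weights
#'
#' Sampling scenarios interpolate linearly, component by component, between
#' the extreme favouring low-risk treated patients, `(0.4, 0.3, 0.2, 0.1)`
#' over quartiles Q1..Q4, and its mirror `(0.1, 0.2, 0.3, 0.4)` favouring
#' high-risk treated patients. Each weight vector sums to 1; the default
#' ten-scenario grid spans increasing injected-confounding intensity with
#' sign flipping at the uniform midpoint.
#'
#' @param n_scenarios Number of scenarios (>= 2); default 10.
#' @return Tibble with columns `scenario`, `w1..w4`.
#' @export
scenario_grid <- function(n_scenarios = 10L) {
  if (n_scenarios < 2) stop("n_scenarios must be >= 2")
  lo <- c(0.4, 0.3, 0.2, 0.1)
  hi <- c(0.1, 0.2, 0.3, 0.4)
  t <- (seq_len(n_scenarios) - 1) / (n_scenarios - 1)
  w <- t(vapply(t, function(tt) (1 - tt) * lo + tt * hi, numeric(4)))
  colnames(w) <- paste0("w", 1:4)
  dplyr::bind_cols(tibble::tibble(scenario = seq_len(n_scenarios)),
                   tibble::as_tibble(w))
}

#' Draw one simulation cohort under a sampling scenario
#'
#' Builds one replicate cohort: controls are sampled without replacement in
#' equal numbers per risk quartile from the untreated pool (until
#' `n_control` in total), while treated patients are sampled without
#' replacement from the treated pool with quartile proportions equal to the
#' scenario weights. Because outcome risk differs across quartiles, unequal
#' weights make the treated group systematically healthier or sicker than
#' the controls -- injected confounding of known direction -- even though
#' treatment was assigned at random.
#'
#' @param treatment Binary 0/1 vector over the source cohort.
#' @param bins Quartile factor from [quartile_bins()], same length.
#' @param weights Numeric length-4 quartile weights (nonnegative, summing
#'   to 1), e.g. one row of [scenario_grid()].
#' @param n_control Control cohort size; default 10000.
#' @param n_treated Treated cohort size; default `n_control`.
#' @param seed Seed; `NULL` uses the current RNG state.
#' @return List: `idx` (sampled row positions, treated first), `treatment`
#'   (0/1 for the sampled rows), `bookkeeping` (tibble of requested and
#'   realised counts per quartile and arm).
#' @export
sample_simulation_cohort <- function(treatment, bins, weights,
                                     n_control = 10000L,
                                     n_treated = n_control, seed = NULL) {
  weights <- as.numeric(weights)
  if (length(weights) != 4 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("weights must be 4 nonnegative values summing to 1")
  draw <- function() {
    q_lab <- paste0("Q", 1:4)
    # largest-remainder apportionment: treated counts hit n_treated exactly
    raw <- weights * n_treated
    n_t <- floor(raw)
    rem <- n_treated - sum(n_t)
    if (rem > 0) {
      top <- order(raw - n_t, decreasing = TRUE)[seq_len(rem)]
      n_t[top] <- n_t[top] + 1
    }
    n_c <- rep(n_control %/% 4L, 4L)
    extra <- n_control - sum(n_c)
    if (extra > 0) n_c[seq_len(extra)] <- n_c[seq_len(extra)] + 1L
    t_sel <- integer(0)
    c_sel <- integer(0)
    for (q in 1:4) {
      pool_t <- which(treatment == 1 & bins == q_lab[q])
      pool_c <- which(treatment == 0 & bins == q_lab[q])
      if (length(pool_t) < n_t[q])
        stop("quartile ", q_lab[q], " has ", length(pool_t),
             " eligible treated but ", n_t[q], " requested")
      if (length(pool_c) < n_c[q])
        stop("quartile ", q_lab[q], " has ", length(pool_c),
             " eligible controls but ", n_c[q], " requested")
      t_sel <- c(t_sel, sample(pool_t, n_t[q]))
      c_sel <- c(c_sel, sample(pool_c, n_c[q]))
    }
    list(idx = c(t_sel, c_sel),
         treatment = c(rep(1L, length(t_sel)), rep(0L, length(c_sel))),
         bookkeeping = tibble::tibble(
           quartile = rep(q_lab, 2),
           arm = rep(c("treated", "control"), each = 4),
           requested = c(n_t, n_c),
           realised = c(tabulate(bins[t_sel], 4), tabulate(bins[c_sel], 4))))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Run the bias-injection simulation study
#'
#' For each scenario and replicate: re-randomise treatment, draw a cohort
#' under the scenario's quartile weights (injecting confounding of known
#' intensity), then apply the requested adjustment models -- crude risk
#' difference for Model 1; propensity-score matching, matched risk
#' difference with percentile-bootstrap CI, matched c-statistic of the
#' reference specification, and median SMD over the prognostic covariates
#' for the others. The prognostic model is fit once on the full source
#' cohort before the replicate loop. Since the truth is a zero risk
#' difference, per-model bias and CI coverage are read off directly.
#'
#' A master seed spawns one child seed per (scenario, replicate), so any
#' single replicate can be reproduced in isolation.
#'
#' @param data Patient-level data frame (covariates and outcome).
#' @param specs List of [model_spec()]s to compare (e.g.
#'   [default_model_specs()] output).
#' @param outcome Composite outcome column name; default
#'   `"outcome_composite"`.
#' @param prognostic_covariates Covariates of the prognostic model; default:
#'   the Model-2 covariate set found in `specs`.
#' @param scenarios Tibble from [scenario_grid()] (or a subset of its rows).
#' @param n_reps Replicates per scenario; default 100.
#' @param n_control,n_treated Cohort sizes per replicate; default 10000.
#' @param p_treat Randomisation probability; default 0.5.
#' @param n_boot Bootstrap replicates for per-replicate CIs; default 200.
#' @param caliper_fraction Matching caliper fraction; default 0.01.
#' @param refit_spec Specification refit for matched c-statistics; default:
#'   the highest-numbered spec with covariates (Model 4). Its AUC on the
#'   unmatched replicate cohort is reported as Model 1's c-statistic.
#' @param seed Master seed; default 1.
#' @return List of class `simulation_result`: `replicates` (one row per
#'   scenario x replicate x model) and `summary` (per scenario x model:
#'   median estimate, percentile interval of estimates, coverage, mean
#'   c-statistic, mean median-SMD, replicates excluded).
#' @export
run_simulation <- function(data, specs, outcome = "outcome_composite",
                           prognostic_covariates = NULL,
                           scenarios = scenario_grid(), n_reps = 100L,
                           n_control = 10000L, n_treated = n_control,
                           p_treat = 0.5, n_boot = 200L,
                           caliper_fraction = 0.01, refit_spec = NULL,
                           seed = 1L) {
  data <- as.data.frame(data)
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  ids <- vapply(specs, `[[`, 0L, "model_id")
  if (is.null(prognostic_covariates)) {
    m2 <- specs[[which(ids == 2L)[1]]]
    if (is.null(m2)) stop("supply prognostic_covariates or a Model-2 spec")
    prognostic_covariates <- m2$covariates
  }
  if (is.null(refit_spec)) {
    with_cov <- which(ids != 1L)
    refit_spec <- specs[[with_cov[which.max(ids[with_cov])]]]
  }

  prog <- fit_prognostic_model(data, y, prognostic_covariates)
  bins <- quartile_bins(prog$scores)

  n_scen <- nrow(scenarios)
  child <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, n_scen * n_reps),
           nrow = n_scen))
  rows <- list()
  excluded <- 0L
  for (s in seq_len(n_scen)) {
    w <- as.numeric(scenarios[s, c("w1", "w2", "w3", "w4")])
    for (r in seq_len(n_reps)) {
      rows[[length(rows) + 1L]] <- withr::with_seed(child[s, r], tryCatch({
        tr_all <- assign_random_treatment(nrow(data), p_treat)
        samp <- sample_simulation_cohort(tr_all, bins, w,
                                         n_control = n_control,
                                         n_treated = n_treated)
        dat <- data[samp$idx, , drop = FALSE]
        tr <- samp$treatment
        yy <- y[samp$idx]
        simulate_one(dat, tr, yy, specs, refit_spec, n_boot,
                     caliper_fraction, prognostic_covariates,
                     scenario = scenarios$scenario[s], rep = r,
                     child_seed = child[s, r])
      }, error = function(e) {
        excluded <<- excluded + 1L
        message("replicate excluded (scenario ", scenarios$scenario[s],
                ", rep ", r, "): ", conditionMessage(e))
        NULL
      }))
    }
  }
  replicates <- dplyr::bind_rows(rows)
  if (nrow(replicates) == 0) stop("all replicates failed")
  summary <- replicates |>
    dplyr::group_by(.data$scenario, .data$model) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      median_estimate = median(.data$estimate),
      estimate_lo = quantile(.data$estimate, 0.025, names = FALSE),
      estimate_hi = quantile(.data$estimate, 0.975, names = FALSE),
      coverage = mean(.data$covered),
      mean_cstat = mean(.data$cstat),
      mean_smd = mean(.data$smd_median),
      .groups = "drop")
  structure(list(replicates = replicates, summary = summary,
                 excluded = excluded, prognostic = prog),
            class = "simulation_result")
}

# one replicate: apply every adjustment model to one sampled cohort
simulate_one <- function(dat, tr, yy, specs, refit_spec, n_boot,
                         caliper_fraction, prognostic_covariates,
                         scenario, rep, child_seed) {
  refit_fit <- fit_propensity(dat, tr, refit_spec)
  out <- list()
  for (spec in specs) {
    if (spec$model_id == 1L) {
      est <- estimate_effect(yy, tr, matched = NULL, n_boot = n_boot)
      cs <- cstat(refit_fit$ps, tr)
      smds <- vapply(prognostic_covariates,
                     function(v) smd(dat[[v]], tr), 0)
      n_pairs <- NA_integer_
    } else {
      ps <- if (identical(spec$covariates, refit_spec$covariates)) refit_fit
            else fit_propensity(dat, tr, spec)
      mc <- match_cohort(ps$ps, tr, caliper_fraction = caliper_fraction)
      est <- estimate_effect(yy, tr, matched = mc, n_boot = n_boot)
      cs <- matched_cstat(mc, dat, tr, refit_spec)
      smds <- vapply(prognostic_covariates,
                     function(v) smd(dat[[v]], tr, matched = mc), 0)
      n_pairs <- nrow(mc)
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      scenario = scenario, rep = rep, model = spec$model_id,
      estimate = est$estimate, lower = est$lower, upper = est$upper,
      covered = est$lower <= 0 & 0 <= est$upper,
      n_pairs = n_pairs, cstat = cs,
      smd_median = median(smds, na.rm = TRUE), seed = child_seed)
  }
  dplyr::bind_rows(out)
}

#' Coverage probability
#'
#' Fraction of replicates whose confidence interval contains the true
#' value (0 for the randomised-truth simulation).
#'
#' @param replicates Data frame with `lower` and `upper` columns (e.g. the
#'   `replicates` element of a [run_simulation()] result, possibly
#'   filtered by model).
#' @param truth True parameter value; default 0.
#' @return Proportion in `[0, 1]`.
#' @export
coverage <- function(replicates, truth = 0) {
  if (nrow(replicates) == 0) stop("no replicates supplied")
  mean(replicates$lower <= truth & truth <= replicates$upper)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", length(unique(x$replicates$scenario)),
      " scenario(s), ", length(unique(x$replicates$rep)), " replicate(s), ",
      x$excluded, " excluded\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}
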