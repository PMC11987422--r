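#' Risk-adjustment model specifications
#'
#' The four adjustment strategies compared throughout the package:
#' * Model 1 - no adjustment (crude group difference);
#' * Model 2 - propensity-score matching on the measured confounders
#'   (the "true" model in simulations where confounding is injected through
#'   a prognostic score built from these variables);
#' * Model 3 - propensity-score matching on age, sex and the k summed
#'   embedding components (the proxy-adjustment method);
#' * Model 4 - the union of Models 2 and 3.
#'
#' @param model_id Integer in 1..4.
#' @param covariates Character vector of covariate column names; must be
#'   empty for Model 1.
#' @return A `model_spec` object.
#' @export
model_spec <- function(model_id, covariates = character()) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:4) stop("model_id must be 1, 2, 3 or 4")
  if (model_id == 1 && length(covariates) > 0)
    stop("Model 1 takes no covariates")
  if (model_id != 1 && length(covariates) == 0)
    stop("Models 2-4 need at least one covariate")
  structure(list(model_id = model_id, covariates = unique(covariates)),
            class = "model_spec")
}

#' @rdname model_spec
#' @param measured Measured-confounder column names (Model 2 set, beyond
#'   demographics).
#' @param embedding Embedding covariate column names (see
#'   [embedding_cols()]).
#' @param demographics Demographic columns included in Models 2-4; default
#'   `c("age", "sex")`.
#' @return For `default_model_specs`, a named list `m1..m4`.
#' @export
default_model_specs <- function(measured, embedding,
                                demographics = c("age", "sex")) {
  m2 <- c(demographics, measured)
  m3 <- c(demographics, embedding)
  list(m1 = model_spec(1L),
       m2 = model_spec(2L, m2),
       m3 = model_spec(3L, m3),
       m4 = model_spec(4L, union(m2, m3)))
}

# main-effects logistic fit on a numeric matrix; IRLS via glm.fit, with an
# optional ridge penalty (penalised IRLS, intercept unpenalised) used as the
# separation fallback
fit_logit <- function(X, y, ridge = 0) {
  Xi <- cbind(`(Intercept)` = 1, X)
  if (ridge <= 0) {
    sep <- FALSE
    fit <- withCallingHandlers(
      glm.fit(Xi, y, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    # (quasi-)separation also shows as essentially degenerate fitted
    # probabilities before glm.fit's own warning threshold is reached
    if (!fit$converged ||
        any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
      sep <- TRUE
    beta <- coef(fit)
    beta[is.na(beta)] <- 0 # aliased (collinear) columns
    return(list(coefficients = beta, fitted = fit$fitted.values,
                separation = sep))
  }
  p <- ncol(Xi)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(50L)) {
    eta <- drop(Xi %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xi * w)
    beta_new <- drop(solve(XtW %*% Xi + pen, XtW %*% z))
    if (max(abs(beta_new - beta)) < 1e-8) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(coefficients = setNames(beta, colnames(Xi)),
       fitted = plogis(drop(Xi %*% beta)), separation = TRUE)
}

covariate_matrix <- function(data, covariates) {
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0)
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(data)[, covariates, drop = FALSE])
  if (!is.numeric(X)) stop("covariates must be numeric")
  if (anyNA(X)) stop("missing values in covariates")
  X
}

#' Fit a propensity-score model
#'
#' Main-effects logistic regression of treatment on the specified
#' covariates, fit by maximum likelihood (IRLS). Under (quasi-)separation
#' the fit is retried with a small L2 ridge penalty when `ridge_fallback`
#' is enabled, and the event is flagged.
#'
#' @param data Data frame holding the covariates.
#' @param treatment Binary 0/1 treatment vector (or column name in `data`).
#' @param spec A [model_spec()] with `model_id != 1`.
#' @param ridge_fallback Retry with ridge penalty on separation? Default
#'   `TRUE`.
#' @param ridge Penalty used by the fallback; default 1e-3.
#' @return List of class `ps_fit`: `ps` (scores in (0,1)), `coefficients`,
#'   `separation` flag, `spec`.
#' @export
fit_propensity <- function(data, treatment, spec, ridge_fallback = TRUE,
                           ridge = 1e-3) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$model_id == 1)
    stop("Model 1 has no propensity model (no adjustment)")
  if (is.character(treatment) && length(treatment) == 1)
    treatment <- data[[treatment]]
  if (!all(treatment %in% c(0, 1))) stop("treatment must be binary 0/1")
  if (length(unique(treatment)) < 2)
    stop("both treatment groups must be nonempty")
  X <- covariate_matrix(data, spec$covariates)
  fit <- fit_logit(X, treatment)
  if (fit$separation) {
    if (!ridge_fallback)
      stop("separation in propensity model and ridge_fallback = FALSE")
    message("separation detected; refitting with ridge penalty ", ridge)
    fit <- fit_logit(X, treatment, ridge = ridge)
  }
  structure(list(ps = as.numeric(fit$fitted),
                 coefficients = fit$coefficients,
                 separation = fit$separation, spec = spec),
            class = "ps_fit")
}

#' Greedy 1:1 nearest-neighbour caliper matching
#'
#' Matches each treated unit to the closest unmatched control on the
#' propensity score, without replacement, processing treated units in
#' random (seeded) order. The caliper is `caliper_fraction` times the
#' standard deviation of the score over all patients -- the "1% of the
#' standardised deviation" convention -- on the probability scale by
#' default; the common logit-scale alternative is available via `scale`.
#' Treated units with no unmatched control inside the caliper are dropped
#' and counted. Equidistant controls are resolved to the lowest patient id.
#'
#' @param ps Propensity scores (or a `ps_fit`).
#' @param treatment Binary 0/1 vector, same length as `ps`.
#' @param caliper_fraction Caliper as a fraction of SD(ps); default 0.01.
#' @param scale `"probability"` (default) or `"logit"`: scale on which
#'   distances and the caliper SD are computed.
#' @param seed Seed for the treated processing order; `NULL` uses the
#'   current RNG state.
#' @param ids Optional patient ids (used for tie-breaking and reporting);
#'   defaults to row position.
#' @return A `matched_cohort`: tibble with columns `treated`, `control`
#'   (positions into `ps`), `treated_id`, `control_id`, `ps_treated`,
#'   `ps_control`, plus attributes `caliper`, `scale`, `n_unmatched`.
#' @export
match_cohort <- function(ps, treatment, caliper_fraction = 0.01,
                         scale = c("probability", "logit"), seed = NULL,
                         ids = NULL) {
  scale <- match.arg(scale)
  if (inherits(ps, "ps_fit")) ps <- ps$ps
  if (!all(is.finite(ps))) stop("propensity scores must be finite")
  if (caliper_fraction <= 0) stop("caliper_fraction must be > 0")
  if (length(ps) != length(treatment)) stop("ps and treatment lengths differ")
  ids <- ids %||% seq_along(ps)
  x <- if (scale == "logit") stats::qlogis(pmin(pmax(ps, 1e-12), 1 - 1e-12))
       else ps
  caliper <- caliper_fraction * sd(x)
  t_idx <- which(treatment == 1)
  c_idx <- which(treatment == 0)
  if (length(t_idx) == 0 || length(c_idx) == 0)
    stop("both treatment groups must be nonempty")

  perm <- if (is.null(seed)) sample.int(length(t_idx))
          else withr::with_seed(seed, sample.int(length(t_idx)))
  t_ord <- t_idx[perm]
  c_ord <- c_idx[order(x[c_idx], ids[c_idx])]
  pref <- rank(ids[c_ord], ties.method = "first")
  m <- .greedy_match(x[t_ord], x[c_ord], as.integer(pref), caliper)
  hit <- !is.na(m)
  if (!any(hit)) stop("zero matched pairs: no control within the caliper")
  treated <- t_ord[hit]
  control <- c_ord[m[hit]]
  out <- tibble::tibble(
    treated = treated, control = control,
    treated_id = ids[treated], control_id = ids[control],
    ps_treated = ps[treated], ps_control = ps[control])
  ord <- order(out$treated)
  out <- out[ord, , drop = FALSE]
  attr(out, "caliper") <- caliper
  attr(out, "scale") <- scale
  attr(out, "n_unmatched") <- sum(!hit)
  class(out) <- c("matched_cohort", class(out))
  out
}

#' Standardised mean difference
#'
#' Balance diagnostic `|mean_t - mean_c| / sqrt((s_t^2 + s_c^2) / 2)`;
#' binary variables use the proportion variance `p(1-p)`. When a matched
#' cohort is supplied, the SMD is computed over matched units only. A value
#' below 0.1 is conventionally regarded as adequate balance. When both
#' groups are constant the SMD is 0 if the means agree and `NA` (with a
#' warning) otherwise.
#'
#' @param values Numeric or binary covariate vector.
#' @param treatment Binary 0/1 vector.
#' @param matched Optional [match_cohort()] result restricting the
#'   computation to matched units.
#' @return A scalar SMD (always >= 0).
#' @export
smd <- function(values, treatment, matched = NULL) {
  if (!is.null(matched)) {
    vt <- values[matched$treated]
    vc <- values[matched$control]
  } else {
    vt <- values[treatment == 1]
    vc <- values[treatment == 0]
  }
  if (length(vt) == 0 || length(vc) == 0)
    stop("both groups must be nonempty")
  binary <- all(values %in% c(0, 1))
  mt <- mean(vt); mc <- mean(vc)
  var_t <- if (binary) mt * (1 - mt) else stats::var(vt)
  var_c <- if (binary) mc * (1 - mc) else stats::var(vc)
  pooled <- sqrt((var_t + var_c) / 2)
  if (pooled == 0) {
    if (isTRUE(all.equal(mt, mc))) return(0)
    warning("zero pooled SD with unequal means; SMD undefined")
    return(NA_real_)
  }
  abs(mt - mc) / pooled
}

#' Concordance statistic (AUC)
#'
#' Rank-based area under the ROC curve of `scores` against binary `labels`,
#' with ties counted half (Mann-Whitney form).
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
cstat <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both label classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matched-cohort c-statistic
#'
#' Refits the given propensity specification on the matched subset only and
#' returns the AUC of the refit scores against treatment. Under complete
#' covariate balance the matched c-statistic is 0.5; residual imbalance
#' pushes it above 0.5, making this a one-number balance diagnostic.
#'
#' @param matched A [match_cohort()] result.
#' @param data Data frame holding the covariates (same row order as the
#'   vectors used for matching).
#' @param treatment Binary treatment vector (or column name in `data`).
#' @param spec [model_spec()] to refit (conventionally the reference,
#'   Model 4, specification).
#' @param ... Passed to [fit_propensity()].
#' @return AUC in `[0, 1]`.
#' @export
matched_cstat <- function(matched, data, treatment, spec, ...) {
  if (nrow(matched) == 0) stop("matched cohort is empty")
  if (is.character(treatment) && length(treatment) == 1)
    treatment <- data[[treatment]]
  rows <- c(matched$treated, matched$control)
  sub <- as.data.frame(data)[rows, , drop = FALSE]
  tr <- c(rep(1L, nrow(matched)), rep(0L, nrow(matched)))
  refit <- fit_propensity(sub, tr, spec, ...)
  cstat(refit$ps, tr)
}

#' Treatment-effect estimate with bootstrap confidence interval
#'
#' Point estimate is the difference in outcome means, treated minus control
#' (a risk difference for binary outcomes, a mean difference otherwise),
#' over matched pairs when a matched cohort is supplied. The 95% CI is a
#' percentile bootstrap: matched analyses resample pairs; unmatched
#' analyses resample patients within each treatment group.
#'
#' @param outcome Outcome vector (binary or continuous).
#' @param treatment Binary 0/1 vector.
#' @param matched Optional [match_cohort()] result.
#' @param n_boot Bootstrap replicates (>= 2); default 1000.
#' @param seed Seed; `NULL` uses the current RNG state.
#' @param conf Confidence level; default 0.95.
#' @return An `effect_estimate`: list with `estimand`, `estimate`, `lower`,
#'   `upper`, `n`, `n_boot`.
#' @export
estimate_effect <- function(outcome, treatment, matched = NULL,
                            n_boot = 1000L, seed = NULL, conf = 0.95) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  estimand <- if (all(outcome %in% c(0, 1))) "risk difference"
              else "mean difference"
  alpha <- (1 - conf) / 2
  run <- function() {
    if (!is.null(matched)) {
      d <- outcome[matched$treated] - outcome[matched$control]
      point <- mean(d)
      n <- length(d)
      boots <- vapply(seq_len(n_boot), function(b)
        mean(d[sample.int(n, n, replace = TRUE)]), 0)
    } else {
      yt <- outcome[treatment == 1]
      yc <- outcome[treatment == 0]
      if (length(yt) == 0 || length(yc) == 0)
        stop("both treatment groups must be nonempty")
      point <- mean(yt) - mean(yc)
      n <- length(outcome)
      boots <- vapply(seq_len(n_boot), function(b)
        mean(yt[sample.int(length(yt), replace = TRUE)]) -
          mean(yc[sample.int(length(yc), replace = TRUE)]), 0)
    }
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
    structure(list(estimand = estimand, estimate = point,
                   lower = ci[1], upper = ci[2],
                   n = n, n_boot = as.integer(n_boot)),
              class = "effect_estimate")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s: %.4f [%.4f, %.4f] (n = %d, %d bootstrap reps)\n",
              x$estimand, x$estimate, x$lower, x$upper, x$n, x$n_boot))
  invisible(x)
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("<matched_cohort> ", nrow(x), " pairs, caliper ",
      signif(attr(x, "caliper"), 4), " (", attr(x, "scale"), " scale), ",
      attr(x, "n_unmatched"), " treated unmatched\n", sep = "")
  NextMethod()
}
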