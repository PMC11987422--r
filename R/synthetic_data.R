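#' Specification of the synthetic claims generator
#'
#' Defines a cohort whose data-generating process is fully known, so every
#' pipeline stage is testable without access to restricted claims data. A
#' latent severity `s ~ N(0,1)` drives everything: code emission (through
#' severity-linked co-occurrence clusters), the measured confounders,
#' treatment assignment (slope `gamma`; `gamma = 0` gives a randomised
#' cohort), and the outcomes (in-hospital death, ADL dependency at
#' discharge, 90-day readmission, log-normal length of stay). Outcomes are
#' conditionally independent of the codes given severity, so severity is
#' the only confounder and the "true" adjustment model is well defined.
#'
#' Codes are emitted by first drawing, per code, a cluster with mixture
#' weights `exp(-(m_j - s)^2 / (2 * cluster_width^2))` over cluster
#' locations `m_j` equally spaced on `cluster_range`, then a token
#' uniformly within the cluster. Severity thus enters through cluster
#' *composition* -- a relational, co-occurrence signal rather than marginal
#' token frequencies -- which is the regime where embeddings can act as
#' severity proxies.
#'
#' @param n_patients Cohort size; default 20000.
#' @param vocab_size Number of distinct code tokens V; default 500.
#' @param n_clusters Number of severity-linked clusters c (>= 2, <= V);
#'   default 10.
#' @param codes_day1_mean Mean admission-day codes per patient (Poisson,
#'   floor 2); default 12.
#' @param codes_later_mean Mean later-day codes for stays >= 2 days;
#'   default 6.
#' @param cluster_width Kernel width of the severity-to-cluster mixture;
#'   default 0.4.
#' @param cluster_range Range of cluster locations; default `c(-2, 2)`.
#' @param gamma Severity slope of the treatment logit (confounding
#'   strength); default 1.
#' @param treatment_intercept Treatment logit intercept; default 0.
#' @param death_coef,adl_coef,readmit_coef Length-2 `(intercept, severity
#'   slope)` logit coefficients of in-hospital death, ADL dependency at
#'   discharge, and 90-day readmission.
#' @param los_meanlog,los_slope,los_sdlog Log-normal length-of-stay model
#'   `log LOS = meanlog + slope * s + N(0, sdlog)`, floored at 2 days.
#' @param day1_discharge_rate Fraction of planted same-day discharges
#'   (standard exclusion-rule violations, flagged in the truth record);
#'   default 0.02.
#' @param seed Master seed; default 1.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_patients = 20000L, vocab_size = 500L,
                           n_clusters = 10L, codes_day1_mean = 12,
                           codes_later_mean = 6, cluster_width = 0.4,
                           cluster_range = c(-2, 2), gamma = 1,
                           treatment_intercept = 0,
                           death_coef = c(-3.6, 1.6),
                           adl_coef = c(-1.7, 2.4),
                           readmit_coef = c(-1.9, 0.6),
                           los_meanlog = log(12), los_slope = 0.35,
                           los_sdlog = 0.45, day1_discharge_rate = 0.02,
                           seed = 1L) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (vocab_size < n_clusters)
    stop("infeasible: vocab_size (", vocab_size,
         ") smaller than n_clusters (", n_clusters, ")")
  if (codes_day1_mean <= 0 || codes_later_mean < 0)
    stop("code-count means must be positive")
  if (cluster_width <= 0) stop("cluster_width must be > 0")
  if (day1_discharge_rate < 0 || day1_discharge_rate >= 1)
    stop("day1_discharge_rate must lie in [0, 1)")
  if (los_sdlog <= 0) stop("los_sdlog must be > 0")
  structure(list(n_patients = as.integer(n_patients),
                 vocab_size = as.integer(vocab_size),
                 n_clusters = as.integer(n_clusters),
                 codes_day1_mean = codes_day1_mean,
                 codes_later_mean = codes_later_mean,
                 cluster_width = cluster_width,
                 cluster_range = cluster_range, gamma = gamma,
                 treatment_intercept = treatment_intercept,
                 death_coef = death_coef, adl_coef = adl_coef,
                 readmit_coef = readmit_coef, los_meanlog = los_meanlog,
                 los_slope = los_slope, los_sdlog = los_sdlog,
                 day1_discharge_rate = day1_discharge_rate,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# deterministic token table: cluster assignment, code family, token string
token_table <- function(spec) {
  V <- spec$vocab_size
  c <- spec$n_clusters
  bounds <- round(seq(0, V, length.out = c + 1))
  sizes <- diff(bounds)
  cluster <- rep(seq_len(c), sizes)
  within <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  # fixed family mix inside each cluster: diagnoses, drugs, procedures,
  # supplies in roughly 40/40/15/5 proportions
  frac <- within / rep(sizes, sizes)
  type <- ifelse(frac <= 0.40, "diagnosis",
          ifelse(frac <= 0.80, "medication",
          ifelse(frac <= 0.95, "procedure", "supply")))
  prefix <- c(diagnosis = "DX", medication = "RX",
              procedure = "PX", supply = "SP")[type]
  tibble::tibble(
    token = sprintf("%s:C%02dT%03d", prefix, cluster, within),
    cluster = cluster, code_type = unname(type))
}

#' Planted cluster labels
#'
#' Ground-truth cluster assignment of every token in a generator
#' specification, used to score embedding-structure recovery. The mapping
#' is a deterministic function of the spec (no simulation involved).
#'
#' @param spec A [generator_spec()].
#' @return Named integer vector: token -> cluster in `1..n_clusters`.
#' @export
planted_cluster_labels <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  tt <- token_table(spec)
  setNames(tt$cluster, tt$token)
}

#' Generate a synthetic claims cohort
#'
#' Draws a full cohort under the latent-severity model of
#' [generator_spec()]: long-format claims records, the patient-level table
#' (demographics, measured confounders, treatment, outcomes), and a truth
#' record carrying each patient's latent severity and true model
#' probabilities. With `gamma = 0` the true treatment-outcome risk
#' difference is 0 by construction. Identical spec and seed reproduce the
#' output exactly.
#'
#' The measured confounders (beyond age and sex) are noisy loadings on
#' severity styled after a heart-failure admission work-up: consciousness
#' level (`jcs`, 0-3), admission ADL score (`adl_admission`, 0-100,
#' Barthel-like), systolic blood pressure (`sbp`), hypertension diagnosis
#' (`htn`), and log natriuretic peptide (`bnp_log`);
#' [measured_confounder_names()] returns this set. A small planted fraction
#' of same-day discharges (flagged in `truth$excluded_day1`) exercises
#' cohort exclusion rules.
#'
#' @param spec A [generator_spec()].
#' @return List of class `claimvec_cohort`: `claims` (long-format records),
#'   `patients` (one row per patient), `truth`, and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  tt <- token_table(spec)
  c_n <- spec$n_clusters
  m <- seq(spec$cluster_range[1], spec$cluster_range[2], length.out = c_n)
  cl_start <- c(0L, cumsum(tabulate(tt$cluster, c_n)))
  cl_size <- tabulate(tt$cluster, c_n)

  withr::with_seed(spec$seed, {
    n <- spec$n_patients
    s <- rnorm(n)
    patient_id <- sprintf("P%06d", seq_len(n))

    age <- pmin(pmax(round(76 + 6 * s + rnorm(n, 0, 8)), 21), 105)
    sex <- rbinom(n, 1L, 0.45)
    jcs <- findInterval(0.8 * s + rnorm(n, 0, 0.8), c(0.3, 1.2, 2.0))
    adl_admission <- round(pmin(pmax(85 - 18 * s + rnorm(n, 0, 15), 0), 100))
    sbp <- round(130 - 10 * s + rnorm(n, 0, 18))
    htn <- rbinom(n, 1L, plogis(0.3 - 0.2 * s))
    bnp_log <- 5.5 + 0.8 * s + rnorm(n, 0, 0.7)

    p_treat <- plogis(spec$treatment_intercept + spec$gamma * s)
    treatment <- rbinom(n, 1L, p_treat)
    # exposure convention: rehabilitation begun within 2 days of admission
    rehab_start_day <- ifelse(treatment == 1, 2L,
                              ifelse(runif(n) < 0.2, NA_integer_,
                                     3L + rpois(n, 2)))

    p_death <- plogis(spec$death_coef[1] + spec$death_coef[2] * s)
    p_adl <- plogis(spec$adl_coef[1] + spec$adl_coef[2] * s)
    p_readmit <- plogis(spec$readmit_coef[1] + spec$readmit_coef[2] * s)
    outcome_death <- rbinom(n, 1L, p_death)
    outcome_adl_dependency <- rbinom(n, 1L, p_adl)
    outcome_composite <- as.integer(outcome_death | outcome_adl_dependency)
    outcome_readmit90 <- ifelse(outcome_death == 1L, 0L,
                                rbinom(n, 1L, p_readmit))

    los <- pmax(2, ceiling(exp(spec$los_meanlog + spec$los_slope * s +
                                 rnorm(n, 0, spec$los_sdlog))))
    excluded_day1 <- runif(n) < spec$day1_discharge_rate
    los[excluded_day1] <- 1

    # --- code emission ------------------------------------------------
    n1 <- 2L + rpois(n, max(spec$codes_day1_mean - 2, 0.01))
    n2 <- ifelse(los >= 2, rpois(n, spec$codes_later_mean), 0L)
    pat <- c(rep(seq_len(n), n1), rep(seq_len(n), n2))
    total <- length(pat)
    # per-code cluster via Gumbel-max over log mixture weights
    logw <- -outer(s[pat], m, `-`)^2 / (2 * spec$cluster_width^2)
    gum <- -log(-log(matrix(runif(total * c_n), total, c_n)))
    cl <- max.col(logw + gum, ties.method = "first")
    tok_idx <- cl_start[cl] + 1L + as.integer(floor(runif(total) * cl_size[cl]))
    day <- c(rep(1L, sum(n1)),
             2L + as.integer(floor(runif(sum(n2)) *
                                     (pmin(los, 7)[pat[-seq_len(sum(n1))]] - 1))))
    ord <- order(pat, day)
    rec_pid <- patient_id[pat[ord]]
    claims <- tibble::tibble(
      patient_id = rec_pid,
      admission_id = paste0(rec_pid, "-A1"),
      day_index = day[ord],
      code_type = tt$code_type[tok_idx[ord]],
      token = tt$token[tok_idx[ord]])

    patients <- tibble::tibble(
      patient_id = patient_id, age = as.numeric(age), sex = sex,
      jcs = as.numeric(jcs), adl_admission = as.numeric(adl_admission),
      sbp = as.numeric(sbp), htn = htn, bnp_log = bnp_log,
      treatment = treatment, rehab_start_day = rehab_start_day,
      admission_day_count = as.integer(los),
      length_of_stay = as.integer(los),
      outcome_death = outcome_death,
      outcome_adl_dependency = outcome_adl_dependency,
      outcome_composite = outcome_composite,
      outcome_readmit90 = outcome_readmit90)

    truth <- tibble::tibble(
      patient_id = patient_id, severity = s, p_treat = p_treat,
      p_death = p_death, p_adl = p_adl, p_readmit = p_readmit,
      excluded_day1 = excluded_day1)

    structure(list(claims = claims, patients = patients, truth = truth,
                   spec = spec),
              class = "claimvec_cohort")
  })
}

#' Measured-confounder column names
#'
#' The canonical measured-confounder set emitted by [generate_cohort()]
#' (beyond the age/sex demographics), i.e. the Model-2 covariates of the
#' synthetic study.
#'
#' @return Character vector of column names.
#' @export
measured_confounder_names <- function() {
  c("jcs", "adl_admission", "sbp", "htn", "bnp_log")
}

#' @export
print.claimvec_cohort <- function(x, ...) {
  cat("<claimvec_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$claims), " claim records, V = ", x$spec$vocab_size,
      ", clusters = ", x$spec$n_clusters, ", gamma = ", x$spec$gamma,
      ", seed = ", x$spec$seed, "\n", sep = "")
  invisible(x)
}
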