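#' Compress one patient's codes into a fixed-length vector
#'
#' Sums the embedding weight vectors of the patient's codes (with
#' multiplicity by default, since repeated codes are repeated signal), the
#' step that turns a variable-length code list into a k-dimensional
#' covariate. Tokens absent from the weight table contribute nothing and are
#' counted as missing; a patient with no matched token yields the zero
#' vector.
#'
#' @param tokens Character vector (multiset) of the patient's code tokens.
#' @param table An `embedding_table` (see [train_embeddings()],
#'   [load_weights()]).
#' @param dedupe Collapse repeated tokens before summing? Default `FALSE`.
#' @param mode `"sum"` (default) or `"mean"` over matched codes; the mean
#'   mode exists for sensitivity analyses only.
#' @return List with `v` (length-k numeric), `n_codes_used`,
#'   `n_codes_missing`; the two counts sum to `length(tokens)` (after
#'   deduplication when requested).
#' @export
vectorize_patient <- function(tokens, table, dedupe = FALSE,
                              mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (dedupe) tokens <- unique(tokens)
  w <- unclass_embedding(table)
  hit <- match(tokens, rownames(w))
  used <- sum(!is.na(hit))
  v <- if (used == 0) numeric(ncol(w))
       else colSums(w[hit[!is.na(hit)], , drop = FALSE])
  if (mode == "mean" && used > 0) v <- v / used
  list(v = as.numeric(v), n_codes_used = used,
       n_codes_missing = length(tokens) - used)
}

#' Vectorise a cohort from its claims records
#'
#' Builds the per-patient covariate vector from each patient's codes on the
#' selected admission days (default: day 1, the admission day, matching the
#' convention of adjusting on first-day diagnoses and treatments). One row
#' is returned per patient present in `records`; patients with no record on
#' the selected days get the zero vector with a warning.
#'
#' @param records Validated claims records.
#' @param table An `embedding_table`.
#' @param days Integer vector of day indices to include; default `1L`.
#' @param dedupe,mode Passed to [vectorize_patient()].
#' @return Tibble with `patient_id`, embedding columns `v1..vk`,
#'   `n_codes_used`, `n_codes_missing`.
#' @export
vectorize_cohort <- function(records, table, days = 1L, dedupe = FALSE,
                             mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  records <- validate_claims(records)
  ids <- sort(unique(records$patient_id))
  sel <- records[records$day_index %in% days, , drop = FALSE]
  by_patient <- split(sel$token, factor(sel$patient_id, levels = ids))
  rows <- lapply(by_patient, vectorize_patient, table = table,
                 dedupe = dedupe, mode = mode)
  k <- ncol(table)
  v <- do.call(rbind, lapply(rows, `[[`, "v"))
  colnames(v) <- paste0("v", seq_len(k))
  out <- tibble::tibble(patient_id = ids)
  out <- dplyr::bind_cols(out, tibble::as_tibble(v))
  out$n_codes_used <- vapply(rows, `[[`, 0L, "n_codes_used")
  out$n_codes_missing <- vapply(rows, `[[`, 0L, "n_codes_missing")
  n_empty <- sum(out$n_codes_used == 0)
  if (n_empty > 0)
    warning(n_empty, " patient(s) had no matched code on the selected days; ",
            "zero vectors assigned")
  out
}

#' Embedding covariate column names
#'
#' Convenience accessor for the `v1..vk` column names produced by
#' [vectorize_cohort()], as used in model covariate lists.
#'
#' @param k Embedding dimension.
#' @return Character vector `c("v1", ..., "vk")`.
#' @export
embedding_cols <- function(k) paste0("v", seq_len(k))
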