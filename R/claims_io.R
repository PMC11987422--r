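#' Read long-format claims records
#'
#' Reads a delimited text file of one code occurrence per row (one
#' patient-admission-day-code event) and validates it. The expected header is
#' `patient_id,admission_id,day_index,code_type,token`; the delimiter (comma
#' or tab) is auto-detected from the header line unless given.
#'
#' Day indexing is 1-based: `day_index == 1` is the admission day, the day
#' whose codes feed the patient-level covariate vectors.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter; `NULL` (default) auto-detects `","` vs `"\t"`
#'   from the header line.
#' @return A tibble of validated claims records, in file order.
#' @seealso [write_claims()], [validate_claims()]
#' @export
read_claims <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("claims file does not exist: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  rec <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    patient_id = readr::col_character(),
    admission_id = readr::col_character(),
    day_index = readr::col_integer(),
    code_type = readr::col_character(),
    token = readr::col_character()
  ), progress = FALSE)
  validate_claims(rec)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Validate claims records
#'
#' Checks the claims-record contract: all five columns present, `day_index`
#' a positive integer, `code_type` one of the recognised families
#' (`diagnosis`, `medication`, `procedure`, `supply`, `demographic`), and
#' non-empty tokens. Errors name the offending data line numbers (line 1 is
#' the header).
#'
#' @param records A data frame of claims records.
#' @return The records as a tibble, invisibly validated.
#' @export
validate_claims <- function(records) {
  missing_cols <- setdiff(CLAIMS_COLS, names(records))
  if (length(missing_cols) > 0)
    stop("claims records lack column(s): ", paste(missing_cols, collapse = ", "))
  records <- tibble::as_tibble(records)[, CLAIMS_COLS]
  line_of <- function(i) i + 1L # header occupies line 1
  bad <- which(is.na(records$day_index) | records$day_index < 1L)
  if (length(bad) > 0)
    stop("day_index must be >= 1; violated at line(s) ",
         paste(line_of(head(bad, 5L)), collapse = ", "))
  bad <- which(!(records$code_type %in% CODE_TYPES))
  if (length(bad) > 0)
    stop("unknown code_type at line(s) ",
         paste(line_of(head(bad, 5L)), collapse = ", "),
         " (expected one of ", paste(CODE_TYPES, collapse = ", "), ")")
  bad <- which(is.na(records$token) | !nzchar(records$token))
  if (length(bad) > 0)
    stop("empty token at line(s) ",
         paste(line_of(head(bad, 5L)), collapse = ", "))
  bad <- which(is.na(records$patient_id) | is.na(records$admission_id))
  if (length(bad) > 0)
    stop("missing patient_id/admission_id at line(s) ",
         paste(line_of(head(bad, 5L)), collapse = ", "))
  records$day_index <- as.integer(records$day_index)
  records
}

#' Write claims records
#'
#' Writes validated claims records as delimited text readable by
#' [read_claims()]; the round trip is lossless.
#'
#' @param records A data frame of claims records.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_claims <- function(records, path, delim = ",") {
  records <- validate_claims(records)
  readr::write_delim(records, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read / write the patient-level table
#'
#' The patient table holds one row per patient: demographics, measured
#' confounders, the treatment indicator, and outcomes (in-hospital death,
#' ADL dependency at discharge, 90-day readmission, length of stay).
#' Arbitrary additional measured-confounder columns are preserved.
#'
#' @param path File path.
#' @param delim Delimiter; auto-detected on read when `NULL`.
#' @return A tibble with one row per patient.
#' @export
read_patient_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("patient table does not exist: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    patient_id = readr::col_character(), .default = readr::col_guess()
  ), progress = FALSE)
  validate_patient_table(tab)
}

#' @rdname read_patient_table
#' @param patients A patient table.
#' @export
write_patient_table <- function(patients, path, delim = ",") {
  patients <- validate_patient_table(patients)
  readr::write_delim(patients, path, delim = delim, progress = FALSE)
  invisible(path)
}

validate_patient_table <- function(patients) {
  patients <- tibble::as_tibble(patients)
  if (!"patient_id" %in% names(patients)) stop("patient table needs patient_id")
  if (anyDuplicated(patients$patient_id))
    stop("patient table must have one row per patient_id")
  for (col in intersect(c("treatment", "sex", "outcome_death",
                          "outcome_adl_dependency", "outcome_readmit90"),
                        names(patients))) {
    v <- patients[[col]]
    if (!all(v %in% c(0L, 1L)))
      stop("column ", col, " must be binary 0/1")
  }
  if ("length_of_stay" %in% names(patients) &&
      any(patients$length_of_stay < 1))
    stop("length_of_stay must be >= 1")
  patients
}

#' Filter a patient cohort with declarative exclusion rules
#'
#' Applies named inclusion predicates in sequence; a row is removed when it
#' fails (or evaluates `NA` under) any predicate. This mirrors study-cohort
#' construction where e.g. same-day discharges are excluded with a rule like
#' `admission_day_count > 1`. The per-rule removal counts are attached as the
#' `"removed"` attribute. Applying the same rules twice removes nothing on
#' the second pass.
#'
#' @param patients A patient table.
#' @param rules Named character vector of predicate expressions over columns
#'   of `patients`; rows failing a predicate are removed.
#' @return The filtered table, with attribute `removed` (named integer
#'   vector of rows removed per rule).
#' @export
filter_cohort <- function(patients, rules = character()) {
  patients <- tibble::as_tibble(patients)
  removed <- setNames(integer(length(rules)), names(rules) %||% rules)
  if (length(rules) == 0) {
    attr(patients, "removed") <- removed
    return(patients)
  }
  if (is.null(names(rules)) || any(!nzchar(names(rules))))
    names(rules) <- ifelse(nzchar(names(rules) %||% ""), names(rules), rules)
  for (i in seq_along(rules)) {
    expr <- tryCatch(parse(text = rules[[i]])[[1]],
                     error = function(e) stop("unparseable rule: ", rules[[i]]))
    vars <- all.vars(expr)
    miss <- setdiff(vars, names(patients))
    if (length(miss) > 0)
      stop("rule '", names(rules)[i], "' references missing field(s): ",
           paste(miss, collapse = ", "))
    keep <- eval(expr, patients, parent.frame())
    keep <- !is.na(keep) & keep
    removed[i] <- sum(!keep)
    patients <- patients[keep, , drop = FALSE]
  }
  attr(patients, "removed") <- removed
  patients
}

#' Build a token vocabulary from claims records
#'
#' Counts token occurrences over the records and retains tokens seen at
#' least `min_count` times. Indices are dense `0..V-1`, assigned in
#' decreasing count order (ties broken lexicographically) as is conventional
#' for word-embedding vocabularies.
#'
#' @param records Validated claims records (or any data frame with a `token`
#'   column).
#' @param min_count Minimum corpus frequency to retain a token (>= 1).
#' @return An object of class `claimvec_vocab`: a tibble with columns
#'   `token`, `index`, `count`, and attribute `min_count`.
#' @export
build_vocabulary <- function(records, min_count = 1L) {
  if (min_count < 1) stop("min_count must be >= 1")
  if (nrow(records) == 0) stop("cannot build a vocabulary from zero records")
  counts <- table(records$token)
  tab <- tibble::tibble(token = names(counts), count = as.integer(counts))
  tab <- tab[tab$count >= min_count, , drop = FALSE]
  if (nrow(tab) == 0) stop("no token reaches min_count = ", min_count)
  tab <- tab[order(-tab$count, tab$token), , drop = FALSE]
  tab$index <- seq_len(nrow(tab)) - 1L
  tab <- tab[, c("token", "index", "count")]
  attr(tab, "min_count") <- as.integer(min_count)
  class(tab) <- c("claimvec_vocab", class(tab))
  tab
}

#' @export
print.claimvec_vocab <- function(x, ...) {
  cat("<claimvec_vocab> ", nrow(x), " tokens (min_count = ",
      attr(x, "min_count"), ")\n", sep = "")
  NextMethod()
}
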