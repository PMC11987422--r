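#' Convert claims records into code documents
#'
#' Groups code occurrences into unordered "documents" for embedding
#' training: by default all codes of one admission form one document (the
#' visit-as-context convention for medical concept embeddings), optionally
#' one document per admission-day. Tokens absent from the vocabulary are
#' dropped, and documents left with fewer than two tokens are discarded
#' since they carry no co-occurrence signal.
#'
#' @param records Validated claims records.
#' @param vocabulary A [build_vocabulary()] result; `NULL` keeps all tokens.
#' @param grouping `"admission"` (default) or `"admission_day"`.
#' @return Named list of character vectors (token multisets), one per
#'   document, ordered by document id.
#' @export
build_documents <- function(records, vocabulary = NULL,
                            grouping = c("admission", "admission_day")) {
  grouping <- match.arg(grouping)
  records <- validate_claims(records)
  if (!is.null(vocabulary)) {
    keep <- records$token %in% vocabulary$token
    records <- records[keep, , drop = FALSE]
  }
  key <- if (grouping == "admission") records$admission_id
         else paste0(records$admission_id, ":", records$day_index)
  docs <- split(records$token, key)
  docs <- docs[lengths(docs) >= 2L]
  if (length(docs) == 0)
    stop("empty corpus: no document retains >= 2 in-vocabulary tokens")
  docs[order(names(docs))]
}

#' Deterministically shuffle a corpus
#'
#' Permutes the document order and the token order within each document.
#' Claims codes have no natural sequence, so training epochs see randomised
#' neighbour sets; the same seed always yields the same permutation and the
#' per-document token multisets are conserved.
#'
#' @param docs A corpus as returned by [build_documents()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return The permuted corpus.
#' @export
shuffle_documents <- function(docs, seed = NULL) {
  do_shuffle <- function() {
    docs <- docs[sample.int(length(docs))]
    lapply(docs, function(d) d[sample.int(length(d))])
  }
  if (is.null(seed)) do_shuffle() else withr::with_seed(seed, do_shuffle())
}

#' Read / write a corpus as one document per line
#'
#' Serialises a corpus as space-separated tokens, one document per line
#' (document ids are not stored; on read, documents are named `doc1..docN`).
#'
#' @param docs Corpus (named list of character vectors).
#' @param path File path.
#' @return `path` invisibly for write; the corpus for read.
#' @export
write_corpus <- function(docs, path) {
  writeLines(vapply(docs, paste, "", collapse = " "), path)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file does not exist: ", path)
  lines <- readLines(path)
  docs <- strsplit(lines, " ", fixed = TRUE)
  names(docs) <- paste0("doc", seq_along(docs))
  docs
}
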