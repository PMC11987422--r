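#' Training configuration for code embeddings
#'
#' Hyperparameters for skip-gram-with-negative-sampling (SGNS) training.
#' The embedding dimension defaults to 200, the scale at which summed code
#' weights are used as patient-level covariates; the remaining defaults
#' follow common word2vec practice. The context window is the full document
#' length capped at `window`; codes within a document are unordered, so each
#' epoch reshuffles token order and the window sees random neighbours.
#'
#' @param dim Embedding dimension k (>= 2); default 200.
#' @param window Cap on the context window half-width; default 10.
#' @param negative Negative samples per observed pair (>= 1); default 5.
#' @param epochs Training epochs; default 5. `epochs = 0` returns the random
#'   initialisation, useful as an untrained baseline.
#' @param alpha Initial learning rate, decayed linearly; default 0.025.
#' @param min_count Vocabulary frequency threshold; default 1.
#' @param subsample Frequent-token subsampling threshold t; default 1e-4.
#' @param seed Integer seed for the trainer's own RNG (bit-reproducible in
#'   single-worker mode); default 1.
#' @return A list of class `sgns_config`.
#' @export
training_config <- function(dim = 200L, window = 10L, negative = 5L,
                            epochs = 5L, alpha = 0.025, min_count = 1L,
                            subsample = 1e-4, seed = 1L) {
  stopifnot(dim >= 2, window >= 1, negative >= 1, epochs >= 0,
            alpha > 0, min_count >= 1, subsample >= 0)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 negative = as.integer(negative), epochs = as.integer(epochs),
                 alpha = alpha, min_count = as.integer(min_count),
                 subsample = subsample, seed = as.integer(seed)),
            class = "sgns_config")
}

#' Train skip-gram code embeddings
#'
#' Learns a k-dimensional distributed representation for every vocabulary
#' token from code co-occurrence within documents, using skip-gram with
#' negative sampling: observed (code, neighbouring code) pairs are scored
#' against `negative` tokens drawn from the unigram^0.75 noise distribution.
#' Codes that tend to occur in the same admissions end up close in the
#' embedding space.
#'
#' Training is single-threaded and bit-reproducible for a fixed
#' `(corpus, config)`. The public weight per token is the input-matrix row;
#' the context matrix is returned only when `return_context = TRUE` (needed
#' e.g. to evaluate the training objective via [sgns_objective()]).
#'
#' @param docs Corpus from [build_documents()] (named list of token vectors).
#' @param config A [training_config()].
#' @param vocabulary Optional [build_vocabulary()] result; built from the
#'   corpus with `config$min_count` when `NULL`.
#' @param return_context Keep the output/context matrix as attribute
#'   `context`? Default `FALSE`.
#' @return An `embedding_table`: numeric matrix (V rows, k columns) with
#'   token rownames and the training metadata as attribute `config`.
#' @export
train_embeddings <- function(docs, config = training_config(),
                             vocabulary = NULL, return_context = FALSE) {
  stopifnot(inherits(config, "sgns_config"))
  if (length(docs) == 0) stop("corpus is empty")
  if (is.null(vocabulary)) {
    records <- tibble::tibble(token = unlist(docs, use.names = FALSE))
    vocabulary <- build_vocabulary(records, min_count = config$min_count)
  }
  if (nrow(vocabulary) < 2)
    stop("vocabulary must contain >= 2 tokens to draw negative samples")
  idx <- setNames(vocabulary$index, vocabulary$token)
  enc <- lapply(docs, function(d) {
    v <- unname(idx[d])
    as.integer(v[!is.na(v)])
  })
  enc <- enc[lengths(enc) >= 2L]
  if (length(enc) == 0) stop("empty corpus after vocabulary filtering")

  fit <- .sgns_train(enc, nrow(vocabulary), as.numeric(vocabulary$count),
                     config$dim, config$window, config$negative,
                     config$epochs, config$alpha, config$subsample,
                     config$seed)
  w <- fit$input
  rownames(w) <- vocabulary$token
  colnames(w) <- paste0("v", seq_len(config$dim))
  if (!all(is.finite(w))) stop("training produced non-finite weights")
  attr(w, "config") <- config
  if (return_context) {
    ctx <- fit$output
    dimnames(ctx) <- dimnames(w)
    attr(w, "context") <- ctx
  }
  class(w) <- c("embedding_table", class(w))
  w
}

#' Expected SGNS objective on a corpus
#'
#' Mean, over all ordered co-occurring token pairs within each document
#' (full-document window), of the negative-sampling log-likelihood
#' `log s(u_c . v_w) + negative * E_noise log s(-u_n . v_w)`, with the
#' expectation over the unigram^0.75 noise distribution taken exactly.
#' Used to verify that training improves the objective it optimises.
#'
#' @param docs Corpus (list of token vectors).
#' @param embedding An `embedding_table` trained with `return_context = TRUE`.
#' @param negative Number of negative samples (weight of the noise term).
#' @return A scalar; larger is better.
#' @export
sgns_objective <- function(docs, embedding, negative = 5L) {
  ctx <- attr(embedding, "context")
  if (is.null(ctx)) stop("embedding lacks a context matrix; train with return_context = TRUE")
  tokens <- rownames(embedding)
  counts <- table(factor(unlist(docs, use.names = FALSE), levels = tokens))
  noise <- as.numeric(counts)^0.75
  noise <- noise / sum(noise)
  logsig <- function(x) -log1p(exp(-pmin(pmax(x, -30), 30)))
  total <- 0
  n_pairs <- 0
  for (d in docs) {
    d <- d[d %in% tokens]
    if (length(d) < 2) next
    for (i in seq_along(d)) {
      w <- d[i]
      v_in <- embedding[w, , drop = TRUE]
      # noise expectation shared across contexts of this centre
      neg_term <- sum(noise * logsig(-as.numeric(ctx %*% v_in)))
      for (j in seq_along(d)[-i]) {
        u <- ctx[d[j], , drop = TRUE]
        total <- total + logsig(sum(u * v_in)) + negative * neg_term
        n_pairs <- n_pairs + 1
      }
    }
  }
  if (n_pairs == 0) stop("no co-occurring pairs in corpus")
  total / n_pairs
}

#' Save / load an embedding weight table
#'
#' The release format consumed by downstream users: delimited text with
#' header `token,v1,...,vk`, one row per token, full float precision
#' (lossless round trip).
#'
#' @param table An `embedding_table`.
#' @param path File path.
#' @param delim Delimiter (default comma).
#' @return `path` invisibly for save; an `embedding_table` for load.
#' @export
save_weights <- function(table, path, delim = ",") {
  df <- tibble::as_tibble(as.data.frame(unclass_embedding(table)))
  df <- tibble::add_column(df, token = rownames(table), .before = 1)
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

unclass_embedding <- function(table) {
  attr(table, "config") <- NULL
  attr(table, "context") <- NULL
  class(table) <- "matrix"
  table
}

#' @rdname save_weights
#' @export
load_weights <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("weights file does not exist: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  first <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  k <- length(first) - 1L
  lines <- readLines(path)[-1]
  parts <- strsplit(lines, delim, fixed = TRUE)
  ragged <- which(lengths(parts) != k + 1L)
  if (length(ragged) > 0) {
    bad_tok <- vapply(parts[ragged], `[[`, "", 1L)
    stop("ragged weight row(s) for token(s): ",
         paste(head(bad_tok, 5L), collapse = ", "))
  }
  tokens <- vapply(parts, `[[`, "", 1L)
  w <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L), use.names = FALSE)),
              nrow = length(parts), ncol = k, byrow = TRUE)
  if (!all(is.finite(w))) stop("non-finite weight values in ", path)
  rownames(w) <- tokens
  colnames(w) <- paste0("v", seq_len(k))
  class(w) <- c("embedding_table", class(w))
  w
}

#' Nearest codes by cosine similarity
#'
#' Ranks all other tokens by cosine similarity to the query token, the
#' standard qualitative check that related diagnoses, drugs and procedures
#' embed near one another. Ties are broken lexicographically; the query
#' token itself is excluded.
#'
#' @param table An `embedding_table`.
#' @param token Query token (must be in the table).
#' @param n Number of neighbours to return.
#' @return Tibble with columns `token` and `cosine`, in descending cosine
#'   order.
#' @export
nearest_codes <- function(table, token, n = 10L) {
  if (!token %in% rownames(table)) stop("unknown token: ", token)
  if (n < 1) stop("n must be >= 1")
  w <- unclass_embedding(table)
  q <- w[token, ]
  norms <- sqrt(rowSums(w^2))
  sims <- unname(as.numeric(w %*% q) / (norms * sqrt(sum(q^2))))
  sims[norms == 0] <- 0
  others <- setdiff(rownames(w), token)
  ord <- others[order(-sims[match(others, rownames(w))], others)]
  top <- head(ord, n)
  tibble::tibble(token = top, cosine = sims[match(top, rownames(w))])
}

#' @export
print.embedding_table <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<embedding_table> ", nrow(x), " tokens x ", ncol(x), " dims", sep = "")
  if (!is.null(cfg))
    cat(" (epochs = ", cfg$epochs, ", window <= ", cfg$window,
        ", negative = ", cfg$negative, ", seed = ", cfg$seed, ")", sep = "")
  cat("\n")
  invisible(x)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
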