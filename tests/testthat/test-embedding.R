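# small corpora with planted co-occurrence structure
pair_corpus <- function(n_docs = 300) {
  docs <- rep(list(c("A", "B")), n_docs)
  names(docs) <- paste0("d", seq_len(n_docs))
  docs
}

two_cluster_corpus <- function(n_docs = 400, seed = 1) {
  withr::with_seed(seed, {
    tok <- list(paste0("L", 1:10), paste0("R", 1:10))
    docs <- lapply(seq_len(n_docs), function(i)
      sample(tok[[(i %% 2) + 1]], 5))
    names(docs) <- paste0("d", seq_len(n_docs))
    docs
  })
}

cosine_of <- function(emb, a, b) {
  W <- matrix(as.numeric(emb), nrow(emb), dimnames = dimnames(emb))
  sum(W[a, ] * W[b, ]) / sqrt(sum(W[a, ]^2) * sum(W[b, ]^2))
}

unclass_mat <- function(e) {
  m <- unclass(e)
  attr(m, "config") <- NULL
  attr(m, "context") <- NULL
  m
}

test_that("codes that always co-occur embed with high cosine similarity", {
  # A and B always co-occur; filler tokens populate the noise distribution
  # so negatives for the pair are predominantly drawn outside it
  docs <- withr::with_seed(1, c(
    pair_corpus(),
    lapply(1:300, function(i) sample(paste0("F", 1:10), 3))))
  names(docs) <- paste0("d", seq_along(docs))
  emb <- train_embeddings(docs,
                          training_config(dim = 8, epochs = 120, window = 2,
                                          alpha = 0.05, subsample = 0,
                                          seed = 3))
  expect_gt(cosine_of(emb, "A", "B"), 0.5)
})

test_that("disjoint co-occurrence clusters are recovered in the embedding", {
  docs <- two_cluster_corpus()
  emb <- train_embeddings(docs, training_config(dim = 16, epochs = 10,
                                                subsample = 0, seed = 3))
  labels <- setNames(rep(1:2, each = 10), c(paste0("L", 1:10), paste0("R", 1:10)))
  expect_gt(cluster_cosine_gap(emb, labels), 0)
})

test_that("training is bit-reproducible for a fixed seed and differs across seeds", {
  docs <- two_cluster_corpus()
  e1 <- train_embeddings(docs, training_config(dim = 8, epochs = 2, seed = 42))
  e2 <- train_embeddings(docs, training_config(dim = 8, epochs = 2, seed = 42))
  expect_identical(unclass(e1)[, ], unclass(e2)[, ])
  e3 <- train_embeddings(docs, training_config(dim = 8, epochs = 2, seed = 43))
  expect_false(identical(unclass(e1)[, ], unclass(e3)[, ]))
})

test_that("the negative-sampling objective improves from initialisation", {
  docs <- two_cluster_corpus(n_docs = 200)
  cfg0 <- training_config(dim = 16, epochs = 0, subsample = 0, seed = 9)
  cfg5 <- training_config(dim = 16, epochs = 10, subsample = 0, seed = 9)
  e0 <- train_embeddings(docs, cfg0, return_context = TRUE)
  e5 <- train_embeddings(docs, cfg5, return_context = TRUE)
  expect_gt(sgns_objective(docs, e5), sgns_objective(docs, e0))
})

test_that("configuration and corpus preconditions are enforced", {
  expect_error(training_config(dim = 1), "dim")
  expect_error(training_config(negative = 0), "negative")
  expect_error(train_embeddings(list(), training_config(dim = 4)), "empty")
  # single-token vocabulary cannot support negative sampling
  docs <- list(a = c("A", "A"), b = c("A", "A"))
  expect_error(train_embeddings(docs, training_config(dim = 4)), ">= 2 tokens")
})

test_that("weight tables round-trip through the release format", {
  emb <- train_embeddings(two_cluster_corpus(),
                          training_config(dim = 8, epochs = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  save_weights(emb, path)
  back <- load_weights(path)
  expect_equal(rownames(back), rownames(emb))
  expect_equal(unclass(back)[, ], unclass_mat(emb), tolerance = 0)

  # one token, k = 3 -> header + 1 row
  tiny <- matrix(c(1, 2, 3), 1, 3,
                 dimnames = list("DX:A", paste0("v", 1:3)))
  class(tiny) <- c("embedding_table", class(tiny))
  save_weights(tiny, path)
  expect_length(readLines(path), 2L)

  writeLines(c("token,v1,v2", "DX:A,1,2", "DX:B,1"), path)
  expect_error(load_weights(path), "ragged.*DX:B")
})

test_that("nearest codes rank by cosine with deterministic tie handling", {
  W <- rbind(A = c(1, 0, 0), B = c(2, 0, 0), C = c(0, 1, 0),
             D = c(1, 1, 0) / sqrt(2))
  colnames(W) <- paste0("v", 1:3)
  class(W) <- c("embedding_table", class(W))
  nn <- nearest_codes(W, "A", n = 3)
  expect_equal(nn$token[1], "B") # scalar multiple: cosine exactly 1
  expect_equal(nn$cosine[1], 1)
  expect_equal(nn$cosine[nn$token == "C"], 0) # orthogonal
  expect_false("A" %in% nn$token)
  expect_error(nearest_codes(W, "Z"), "unknown token")

  # brute-force all-pairs oracle on a 50-token random table
  set.seed(8)
  W2 <- matrix(rnorm(50 * 6), 50, 6,
               dimnames = list(sprintf("T%02d", 1:50), paste0("v", 1:6)))
  class(W2) <- c("embedding_table", class(W2))
  got <- nearest_codes(W2, "T07", n = 10)
  want <- nearest_oracle(unclass(W2)[, ], "T07", 10)
  expect_equal(got$token, want$token)
  expect_equal(got$cosine, want$cosine, tolerance = 1e-12)
})

test_that("planted severity clusters from the generator are recovered", {
  fx <- small_fixture()
  labels <- planted_cluster_labels(fx$gen$spec)
  expect_gt(cluster_cosine_gap(fx$emb, labels), 0)
})
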