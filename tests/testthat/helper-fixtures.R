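# Shared fixtures, built once per test run and memoised. The small fixture
# backs the module tests; the full-scale fixture and grid simulation back
# the end-to-end acceptance properties.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small confounded cohort with 16-dim embeddings: fast enough for unit tests
small_fixture <- function() {
  memo("small", {
    spec <- generator_spec(n_patients = 2500, vocab_size = 80, n_clusters = 5,
                           gamma = 1, seed = 404)
    gen <- generate_cohort(spec)
    cohort <- filter_cohort(gen$patients,
                            c(multiday = "admission_day_count > 1"))
    vocab <- build_vocabulary(gen$claims)
    docs <- build_documents(gen$claims, vocab)
    emb <- train_embeddings(docs, training_config(dim = 16, seed = 7),
                            vocabulary = vocab)
    vectors <- suppressWarnings(vectorize_cohort(gen$claims, emb))
    features <- dplyr::inner_join(cohort, vectors, by = "patient_id")
    specs <- default_model_specs(measured_confounder_names(),
                                 embedding_cols(16))
    list(gen = gen, cohort = cohort, vocab = vocab, docs = docs, emb = emb,
         features = features, specs = specs)
  })
}

# study-scale cohort under confounded treatment (gamma = 1) with the full
# 200-dimensional embeddings
acceptance_fixture <- function() {
  memo("acceptance", {
    spec <- generator_spec(seed = 20240)
    gen <- generate_cohort(spec)
    cohort <- filter_cohort(gen$patients,
                            c(multiday = "admission_day_count > 1"))
    vocab <- build_vocabulary(gen$claims)
    docs <- build_documents(gen$claims, vocab)
    emb <- train_embeddings(docs, training_config(seed = 11),
                            vocabulary = vocab)
    vectors <- suppressWarnings(vectorize_cohort(gen$claims, emb))
    features <- dplyr::inner_join(cohort, vectors, by = "patient_id")
    specs <- default_model_specs(measured_confounder_names(),
                                 embedding_cols(200))
    list(spec = spec, gen = gen, cohort = cohort, emb = emb,
         features = features, specs = specs)
  })
}

# 5-point scenario grid, 20 replicates each, reduced cohort sizes
acceptance_grid_sim <- function() {
  memo("grid_sim", {
    fx <- acceptance_fixture()
    suppressMessages(run_simulation(
      fx$features, fx$specs, scenarios = scenario_grid(5), n_reps = 20,
      n_control = 2000, n_treated = 2000, n_boot = 200, seed = 331))
  })
}
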