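# Independent brute-force implementations used as oracles. These are kept
# deliberately naive and separate from the package's code paths.

# Newton-Raphson logistic regression (explicit score/Hessian), independent
# of glm.fit's IRLS/QR path
irls_oracle <- function(X, y, tol = 1e-10, max_iter = 100) {
  Xi <- cbind(1, X)
  beta <- numeric(ncol(Xi))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- crossprod(Xi, y - mu)
    hess <- crossprod(Xi * W, Xi)
    step <- solve(hess, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

# concordant-pair counting AUC, ties counted half
auc_pairs_oracle <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

# spreadsheet-style SMD
smd_oracle <- function(values, treatment) {
  vt <- values[treatment == 1]
  vc <- values[treatment == 0]
  if (all(values %in% c(0, 1))) {
    vart <- mean(vt) * (1 - mean(vt))
    varc <- mean(vc) * (1 - mean(vc))
  } else {
    vart <- sum((vt - mean(vt))^2) / (length(vt) - 1)
    varc <- sum((vc - mean(vc))^2) / (length(vc) - 1)
  }
  abs(mean(vt) - mean(vc)) / sqrt((vart + varc) / 2)
}

# greedy nearest-neighbour matching replayed with plain loops, using the
# same treated processing order and tie rule (lowest id) as the package
greedy_match_oracle <- function(ps, treatment, caliper_fraction, seed) {
  caliper <- caliper_fraction * sd(ps)
  t_idx <- which(treatment == 1)
  c_idx <- which(treatment == 0)
  t_ord <- t_idx[withr::with_seed(seed, sample.int(length(t_idx)))]
  alive <- rep(TRUE, length(c_idx))
  pairs <- list()
  for (t in t_ord) {
    if (!any(alive)) break
    cand <- c_idx[alive]
    d <- abs(ps[cand] - ps[t])
    best <- min(d)
    if (best > caliper) next
    pick <- min(cand[d == best]) # lowest id among equidistant
    pairs[[length(pairs) + 1]] <- c(treated = t, control = pick)
    alive[match(pick, c_idx)] <- FALSE
  }
  out <- do.call(rbind, pairs)
  out[order(out[, "treated"]), , drop = FALSE]
}

# all-pairs cosine ranking
nearest_oracle <- function(W, token, n) {
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  others <- setdiff(rownames(W), token)
  sims <- vapply(others, function(t) cos(W[token, ], W[t, ]), 0)
  ord <- order(-sims, others)
  data.frame(token = others[ord][seq_len(n)],
             cosine = unname(sims[ord][seq_len(n)]))
}

# mean within- minus between-cluster cosine over an embedding table
cluster_cosine_gap <- function(emb, labels) {
  W <- matrix(as.numeric(emb), nrow(emb), dimnames = dimnames(emb))
  W <- W / sqrt(rowSums(W^2))
  S <- W %*% t(W)
  diag(S) <- NA
  same <- outer(labels[rownames(W)], labels[rownames(W)], `==`)
  mean(S[same], na.rm = TRUE) - mean(S[!same], na.rm = TRUE)
}
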