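#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// xorshift64* generator: training must be bit-reproducible for a given seed
// in single-worker mode, independently of R's RNG state.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s * 2685821657736338717ULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over integer-coded documents.
// docs: list of integer vectors, 0-based token indices into a V-token
// vocabulary. counts: occurrence count per token (vocabulary order).
// Documents are unordered code sets: both document order and within-document
// token order are reshuffled every epoch so the sliding window sees random
// neighbours. Window per position is drawn uniformly in 1..window (word2vec
// dynamic window), with window capped at the document length.
// Returns the input ("word") matrix and the output ("context") matrix,
// both V x k.
// [[Rcpp::export(name = ".sgns_train")]]
List sgns_train(List docs, int vocab_size, NumericVector counts, int dim,
                int window, int negative, int epochs, double alpha,
                double subsample, int seed) {
  const int V = vocab_size, k = dim;
  const int n_docs = docs.size();
  if (V < 2) stop("vocabulary must contain at least 2 tokens");

  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);

  // negative-sampling distribution: unigram^0.75, sampled by binary search
  // over the cumulative mass
  std::vector<double> cum(V);
  double tot = 0.0;
  for (int i = 0; i < V; ++i) {
    tot += std::pow(counts[i], 0.75);
    cum[i] = tot;
  }
  if (tot <= 0) stop("token counts must be positive");
  for (int i = 0; i < V; ++i) cum[i] /= tot;

  // subsampling keep-probability per token (word2vec formula)
  double n_tokens = 0.0;
  for (int i = 0; i < V; ++i) n_tokens += counts[i];
  std::vector<double> keep(V, 1.0);
  if (subsample > 0) {
    for (int i = 0; i < V; ++i) {
      double f = counts[i] / n_tokens;
      if (f > subsample) {
        double p = (std::sqrt(f / subsample) + 1.0) * subsample / f;
        keep[i] = p < 1.0 ? p : 1.0;
      }
    }
  }

  // init: input weights uniform(-0.5/k, 0.5/k), context weights zero
  std::vector<double> syn0((size_t)V * k), syn1((size_t)V * k, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / k;

  // pre-decode documents once
  std::vector<std::vector<int>> dv(n_docs);
  double total_positions = 0.0;
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector doc = docs[d];
    dv[d].assign(doc.begin(), doc.end());
    total_positions += doc.size();
  }
  total_positions *= (double)epochs;
  if (total_positions <= 0) total_positions = 1;

  std::vector<int> doc_order(n_docs);
  for (int d = 0; d < n_docs; ++d) doc_order[d] = d;
  std::vector<double> neu1e(k);
  std::vector<int> sent;
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    // reshuffle document order and within-document token order
    for (int i = n_docs - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(doc_order[i], doc_order[j]);
    }
    for (int dd = 0; dd < n_docs; ++dd) {
      std::vector<int> &doc = dv[doc_order[dd]];
      for (int i = (int)doc.size() - 1; i > 0; --i) {
        int j = rng.below(i + 1);
        std::swap(doc[i], doc[j]);
      }
      // subsample occurrences
      sent.clear();
      for (size_t i = 0; i < doc.size(); ++i) {
        processed += 1.0;
        int w = doc[i];
        if (keep[w] < 1.0 && rng.unif() > keep[w]) continue;
        sent.push_back(w);
      }
      int len = (int)sent.size();
      if (len < 2) continue;

      double lr = alpha * (1.0 - processed / total_positions);
      if (lr < alpha * 1e-4) lr = alpha * 1e-4;

      int win = window < (len - 1) ? window : (len - 1);
      for (int pos = 0; pos < len; ++pos) {
        int center = sent[pos];
        int b = rng.below(win) + 1; // dynamic window in 1..win
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          int ctx = sent[cpos];
          double *v_in = &syn0[(size_t)ctx * k];
          for (int j = 0; j < k; ++j) neu1e[j] = 0.0;
          for (int s = 0; s <= negative; ++s) {
            int target;
            double label;
            if (s == 0) {
              target = center;
              label = 1.0;
            } else {
              double u = rng.unif();
              int lo = 0, hi = V - 1;
              while (lo < hi) {
                int mid = (lo + hi) / 2;
                if (cum[mid] < u) lo = mid + 1; else hi = mid;
              }
              target = lo;
              if (target == center) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * k];
            double dot = 0.0;
            for (int j = 0; j < k; ++j) dot += v_in[j] * v_out[j];
            double g = (label - sigmoid(dot)) * lr;
            for (int j = 0; j < k; ++j) {
              neu1e[j] += g * v_out[j];
              v_out[j] += g * v_in[j];
            }
          }
          for (int j = 0; j < k; ++j) v_in[j] += neu1e[j];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix w_in(V, k), w_out(V, k);
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < k; ++j) {
      w_in(i, j) = syn0[(size_t)i * k + j];
      w_out(i, j) = syn1[(size_t)i * k + j];
    }
  return List::create(_["input"] = w_in, _["output"] = w_out);
}

// Greedy 1:1 nearest-neighbour caliper matching without replacement.
// control_ps must be sorted ascending and control_rank carries, for ties,
// the preference order (lower = preferred, i.e. lowest patient id).
// treated_ps is traversed in the order given (caller randomises it).
// Returns, per treated unit, the 1-based index into the *sorted* control
// vector, or NA when no unmatched control lies within the caliper.
// [[Rcpp::export(name = ".greedy_match")]]
IntegerVector greedy_match(NumericVector treated_ps, NumericVector control_ps,
                           IntegerVector control_pref, double caliper) {
  const int nt = treated_ps.size(), nc = control_ps.size();
  IntegerVector out(nt, NA_INTEGER);
  if (nc == 0) return out;

  // union-find style "nearest alive" pointers with path compression
  std::vector<int> right(nc + 1), left(nc + 1);
  for (int i = 0; i <= nc; ++i) { right[i] = i; left[i] = i; }
  // left[] indexed 0..nc where slot i means control i-1 (slot 0 = none)

  auto find_right = [&](int i) -> int { // nc means none
    int r = i;
    while (r < nc && right[r] != r) r = right[r];
    while (i < nc && right[i] != i) { int nxt = right[i]; right[i] = r; i = nxt; }
    return r;
  };
  auto find_left = [&](int i) -> int { // 0 means none; slot i = control i-1
    int r = i;
    while (r > 0 && left[r] != r) r = left[r];
    while (i > 0 && left[i] != i) { int nxt = left[i]; left[i] = r; i = nxt; }
    return r;
  };

  for (int t = 0; t < nt; ++t) {
    double ps = treated_ps[t];
    // first sorted control with ps >= treated ps
    int lo = 0, hi = nc;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (control_ps[mid] < ps) lo = mid + 1; else hi = mid;
    }
    int r = find_right(lo);       // candidate at or above
    int l = find_left(lo);        // slot; control index l-1 below
    double dr = (r < nc) ? std::fabs(control_ps[r] - ps) : R_PosInf;
    double dl = (l > 0) ? std::fabs(ps - control_ps[l - 1]) : R_PosInf;
    int pick = -1;
    if (dr < dl) pick = r;
    else if (dl < dr) pick = l - 1;
    else if (l > 0 && r < nc) // exact tie: prefer lowest patient id
      pick = (control_pref[l - 1] < control_pref[r]) ? (l - 1) : r;
    else if (r < nc) pick = r;
    else if (l > 0) pick = l - 1;

    if (pick >= 0 && std::fabs(control_ps[pick] - ps) <= caliper) {
      out[t] = pick + 1;
      // retire control `pick`
      right[pick] = find_right(pick + 1);
      left[pick + 1] = find_left(pick);
    }
  }
  return out;
}
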