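#include <Rcpp.h>
using namespace Rcpp;

// Log-odds scores of every window of one encoded sequence (values 0..3,
// NA for ambiguity codes, which contribute 0) against a 4 x w score matrix
// and its reverse complement. Column 0: forward strand, column 1: reverse.
// [[Rcpp::export]]
NumericMatrix window_scores_cpp(IntegerVector seq, NumericMatrix fwd,
                                NumericMatrix rev) {
  const int w = fwd.ncol();
  const int n = seq.size();
  const int nw = n - w + 1;
  if (nw < 1) return NumericMatrix(0, 2);
  NumericMatrix out(nw, 2);
  for (int i = 0; i < nw; ++i) {
    double sf = 0.0, sr = 0.0;
    for (int j = 0; j < w; ++j) {
      const int b = seq[i + j];
      if (b == NA_INTEGER) continue; // ambiguous base: background, 0 log-odds
      sf += fwd(b, j);
      sr += rev(b, j);
    }
    out(i, 0) = sf;
    out(i, 1) = sr;
  }
  return out;
}

// Best window score per sequence over one or both strands; sequences
// shorter than the motif get -Inf.
// [[Rcpp::export]]
NumericVector max_scores_cpp(List seqs, NumericMatrix fwd, NumericMatrix rev,
                             bool both_strands) {
  const int w = fwd.ncol();
  const int ns = seqs.size();
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    IntegerVector seq = seqs[s];
    const int nw = seq.size() - w + 1;
    double best = R_NegInf;
    for (int i = 0; i < nw; ++i) {
      double sf = 0.0, sr = 0.0;
      for (int j = 0; j < w; ++j) {
        const int b = seq[i + j];
        if (b == NA_INTEGER) continue;
        sf += fwd(b, j);
        if (both_strands) sr += rev(b, j);
      }
      if (sf > best) best = sf;
      if (both_strands && sr > best) best = sr;
    }
    out[s] = best;
  }
  return out;
}

// log2 of the average odds (mean over all windows, both strands, of
// 2^window-log-odds) per sequence; -Inf for sequences shorter than w.
// [[Rcpp::export]]
NumericVector average_odds_cpp(List seqs, NumericMatrix fwd,
                               NumericMatrix rev, bool both_strands) {
  const int w = fwd.ncol();
  const int ns = seqs.size();
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    IntegerVector seq = seqs[s];
    const int nw = seq.size() - w + 1;
    if (nw < 1) { out[s] = R_NegInf; continue; }
    // two passes: max for stability, then sum of 2^(x - max)
    std::vector<double> scores;
    scores.reserve(both_strands ? 2 * nw : nw);
    for (int i = 0; i < nw; ++i) {
      double sf = 0.0, sr = 0.0;
      for (int j = 0; j < w; ++j) {
        const int b = seq[i + j];
        if (b == NA_INTEGER) continue;
        sf += fwd(b, j);
        if (both_strands) sr += rev(b, j);
      }
      scores.push_back(sf);
      if (both_strands) scores.push_back(sr);
    }
    double m = R_NegInf;
    for (double v : scores) if (v > m) m = v;
    double acc = 0.0;
    for (double v : scores) acc += std::pow(2.0, v - m);
    out[s] = m + std::log2(acc / scores.size());
  }
  return out;
}
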