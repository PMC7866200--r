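#include <Rcpp.h>
using namespace Rcpp;

// Window log-odds scores over an encoded, concatenated sequence corpus.
// codes: concatenated base codes (A=1, C=2, G=3, T=4, 0 = unknown, which
// scores 0 bits). lens: per-sequence lengths. lo: L x 4 log-odds matrix
// (columns A, C, G, T). Only windows lying fully inside one sequence are
// returned: their 1-based sequence index, 0-based start within the
// sequence, and forward- / reverse-strand scores.
// [[Rcpp::export]]
List scan_scores_cpp(IntegerVector codes, IntegerVector lens,
                     NumericMatrix lo) {
  const int L = lo.nrow();
  const int nseq = lens.size();

  // per-row lookup tables, index 0 = unknown base
  std::vector<double> f(L * 5), r(L * 5);
  for (int i = 0; i < L; ++i) {
    f[i * 5] = 0.0;
    r[i * 5] = 0.0;
    for (int b = 0; b < 4; ++b) {
      f[i * 5 + b + 1] = lo(i, b);
      // reverse strand: reversed positions, complemented bases
      r[i * 5 + b + 1] = lo(L - 1 - i, 3 - b);
    }
  }

  long total = 0;
  for (int s = 0; s < nseq; ++s)
    if (lens[s] >= L) total += lens[s] - L + 1;

  IntegerVector seq_idx(total), start(total);
  NumericVector fwd(total), rev(total);
  long k = 0;
  long offset = 0;
  for (int s = 0; s < nseq; ++s) {
    const int nw = lens[s] - L + 1;
    for (int p = 0; p < nw; ++p) {
      const int *c = &codes[offset + p];
      double sf = 0.0, sr = 0.0;
      for (int i = 0; i < L; ++i) {
        sf += f[i * 5 + c[i]];
        sr += r[i * 5 + c[i]];
      }
      seq_idx[k] = s + 1;
      start[k] = p;
      fwd[k] = sf;
      rev[k] = sr;
      ++k;
    }
    offset += lens[s];
  }
  return List::create(Named("seq_idx") = seq_idx, Named("start") = start,
                      Named("fwd") = fwd, Named("rev") = rev);
}
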