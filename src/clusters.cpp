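#include <Rcpp.h>
using namespace Rcpp;

// 4-connected component labelling of a logical (freq x time) grid stored
// column-major as a vector. Iterative flood fill (no recursion).
static void flood(const int* mask, int* labels, int nf, int nt,
                  int start, int lab, std::vector<int>& stack) {
  stack.clear();
  stack.push_back(start);
  labels[start] = lab;
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int r = idx % nf, c = idx / nf;
    const int nb[4][2] = {{r - 1, c}, {r + 1, c}, {r, c - 1}, {r, c + 1}};
    for (int k = 0; k < 4; ++k) {
      int rr = nb[k][0], cc = nb[k][1];
      if (rr < 0 || rr >= nf || cc < 0 || cc >= nt) continue;
      int j = cc * nf + rr;
      if (mask[j] && labels[j] == 0) {
        labels[j] = lab;
        stack.push_back(j);
      }
    }
  }
}

// [[Rcpp::export]]
IntegerVector cluster_label_cpp(LogicalVector mask, int nf, int nt) {
  IntegerVector labels(mask.size(), 0);
  std::vector<int> stack;
  int lab = 0;
  for (int i = 0; i < mask.size(); ++i) {
    if (mask[i] && labels[i] == 0) {
      ++lab;
      flood(INTEGER(mask), INTEGER(labels), nf, nt, i, lab, stack);
    }
  }
  labels.attr("n_clusters") = lab;
  return labels;
}

// For each row of `stats` (one permutation map, column-major freq x time),
// return the maximum cluster mass (sum of the statistic over a 4-connected
// supra-threshold cluster). If two_sided, the same is done on the negated
// map and the larger of the two maxima is returned.
// [[Rcpp::export]]
NumericVector max_cluster_masses_cpp(NumericMatrix stats, int nf, int nt,
                                     double thresh, bool two_sided) {
  int nperm = stats.nrow();
  int P = stats.ncol();
  if (P != nf * nt) stop("stat dimensions do not match nf * nt");
  NumericVector out(nperm);
  std::vector<int> mask(P), labels(P);
  std::vector<int> stack;
  for (int b = 0; b < nperm; ++b) {
    double best = 0.0;
    for (int side = 0; side < (two_sided ? 2 : 1); ++side) {
      double sign = side == 0 ? 1.0 : -1.0;
      std::fill(labels.begin(), labels.end(), 0);
      for (int i = 0; i < P; ++i) mask[i] = sign * stats(b, i) > thresh;
      int lab = 0;
      std::vector<double> mass;
      for (int i = 0; i < P; ++i) {
        if (mask[i] && labels[i] == 0) {
          ++lab;
          flood(mask.data(), labels.data(), nf, nt, i, lab, stack);
          mass.push_back(0.0);
        }
      }
      for (int i = 0; i < P; ++i) {
        if (labels[i] > 0) mass[labels[i] - 1] += sign * stats(b, i);
      }
      for (size_t m = 0; m < mass.size(); ++m) {
        if (mass[m] > best) best = mass[m];
      }
    }
    out[b] = best;
  }
  return out;
}
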