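#include <Rcpp.h>
using namespace Rcpp;

// Pathway Connectivity Index core.
//
// h:   genes x animals matrix of centered-sigmoid-transformed z-scores.
// members: list of 0-based integer row-index vectors, one per pathway
//          (only genes with expression data; possibly permuted).
// adj: list of dense pathway adjacency submatrices (a_ij in [0,1],
//      diagonal already set to 1 or 0 by the caller).
// divisor: per-pathway normalization constant (N, or the pair count).
//
// Returns a pathways x animals matrix with
//   PCI_p(s) = (1/divisor_p) * sum_{i<=j} sgn(h_i+h_j) sqrt|h_i| a_ij sqrt|h_j|.
// [[Rcpp::export(name = ".pci_core")]]
NumericMatrix pci_core(const NumericMatrix& h, const List& members,
                       const List& adj, const NumericVector& divisor) {
  const int n_path = members.size();
  const int n_anim = h.ncol();
  NumericMatrix out(n_path, n_anim);

  for (int p = 0; p < n_path; ++p) {
    IntegerVector idx = members[p];
    NumericMatrix A = adj[p];
    const int N = idx.size();
    const double inv = 1.0 / divisor[p];
    std::vector<double> hv(N), sq(N);
    for (int s = 0; s < n_anim; ++s) {
      for (int i = 0; i < N; ++i) {
        hv[i] = h(idx[i], s);
        sq[i] = std::sqrt(std::fabs(hv[i]));
      }
      double tot = 0.0;
      for (int i = 0; i < N; ++i) {
        const double hi = hv[i], si = sq[i];
        for (int j = i; j < N; ++j) {
          const double a = A(i, j);
          if (a == 0.0) continue;
          const double sum = hi + hv[j];
          if (sum == 0.0) continue;
          const double sgn = (sum > 0.0) ? 1.0 : -1.0;
          tot += sgn * si * a * sq[j];
        }
      }
      out(p, s) = tot * inv;
    }
  }
  return out;
}
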