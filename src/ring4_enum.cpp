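// Exhaustive enumeration of all valid 4-monomer ring configurations in a
// cubic box, used as the equilibrium oracle for the Monte-Carlo kernel.
// Deliberately self-contained: the bond rule is re-derived from the
// squared-length characterisation of the BFM bond set rather than shared
// with the simulation kernel.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

inline bool bond_ok(int dx, int dy, int dz) {
  int q = dx * dx + dy * dy + dz * dz;
  return q == 4 || q == 5 || q == 6 || q == 9 || q == 10;
}

inline bool cubes_overlap(int x1, int y1, int z1, int x2, int y2, int z2) {
  return std::abs(x1 - x2) < 2 && std::abs(y1 - y2) < 2 &&
         std::abs(z1 - z2) < 2;
}

// bond class by sorted absolute components:
// 0:(2,0,0) 1:(2,1,0) 2:(2,1,1) 3:(2,2,1) 4:(3,0,0) 5:(3,1,0)
inline int bond_class(int dx, int dy, int dz) {
  int a = std::abs(dx), b = std::abs(dy), c = std::abs(dz);
  if (a < b) std::swap(a, b);
  if (b < c) std::swap(b, c);
  if (a < b) std::swap(a, b);
  if (a == 2 && b == 0) return 0;
  if (a == 2 && b == 1 && c == 0) return 1;
  if (a == 2 && b == 1 && c == 1) return 2;
  if (a == 2 && b == 2) return 3;
  if (a == 3 && b == 0) return 4;
  if (a == 3 && b == 1) return 5;
  return -1;
}

}  // namespace

// Enumerates ordered 4-tuples (p0,p1,p2,p3) of monomer positions forming a
// valid self-avoiding ring in a box with positions 0..L-1 per axis.
// Returns the state count, the marginal count of p0 over the L^3 position
// cells, and the pooled bond-class counts (4 bonds per state).
// [[Rcpp::export(name = ".ring4_enumerate_cpp")]]
List ring4_enumerate_cpp(int L) {
  if (L < 3 || L > 8) stop("enumeration supported for L in 3..8");
  const int P = L * L * L;
  auto idx = [L](int x, int y, int z) { return (x * L + y) * L + z; };

  // neighbour lists under the bond rule
  std::vector<std::vector<int> > nb(P);
  std::vector<int> X(P), Y(P), Z(P);
  for (int x = 0; x < L; ++x)
    for (int y = 0; y < L; ++y)
      for (int z = 0; z < L; ++z) {
        int i = idx(x, y, z);
        X[i] = x; Y[i] = y; Z[i] = z;
      }
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < P; ++j)
      if (bond_ok(X[j] - X[i], Y[j] - Y[i], Z[j] - Z[i]))
        nb[i].push_back(j);

  double n_states = 0.0;
  std::vector<double> pos_counts(P, 0.0);
  std::vector<double> bond_counts(6, 0.0);

  std::vector<char> is_nb0(P, 0);
  for (int p0 = 0; p0 < P; ++p0) {
    for (int q : nb[p0]) is_nb0[q] = 1;
    for (int p1 : nb[p0]) {
      if (cubes_overlap(X[p0], Y[p0], Z[p0], X[p1], Y[p1], Z[p1])) continue;
      for (int p2 : nb[p1]) {
        if (cubes_overlap(X[p2], Y[p2], Z[p2], X[p0], Y[p0], Z[p0])) continue;
        if (cubes_overlap(X[p2], Y[p2], Z[p2], X[p1], Y[p1], Z[p1])) continue;
        for (int p3 : nb[p2]) {
          if (!is_nb0[p3]) continue;
          if (cubes_overlap(X[p3], Y[p3], Z[p3], X[p0], Y[p0], Z[p0])) continue;
          if (cubes_overlap(X[p3], Y[p3], Z[p3], X[p1], Y[p1], Z[p1])) continue;
          if (cubes_overlap(X[p3], Y[p3], Z[p3], X[p2], Y[p2], Z[p2])) continue;
          n_states += 1.0;
          pos_counts[p0] += 1.0;
          bond_counts[bond_class(X[p1] - X[p0], Y[p1] - Y[p0], Z[p1] - Z[p0])] += 1.0;
          bond_counts[bond_class(X[p2] - X[p1], Y[p2] - Y[p1], Z[p2] - Z[p1])] += 1.0;
          bond_counts[bond_class(X[p3] - X[p2], Y[p3] - Y[p2], Z[p3] - Z[p2])] += 1.0;
          bond_counts[bond_class(X[p0] - X[p3], Y[p0] - Y[p3], Z[p0] - Z[p3])] += 1.0;
        }
      }
    }
    for (int q : nb[p0]) is_nb0[q] = 0;
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["n_states"] = n_states,
                      _["pos_counts"] = NumericVector(pos_counts.begin(),
                                                      pos_counts.end()),
                      _["bond_counts"] = NumericVector(bond_counts.begin(),
                                                       bond_counts.end()),
                      _["L"] = L);
}
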