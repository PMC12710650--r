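#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving randomization of a binary matrix by checkerboard trades.
//
// A trade picks two 1-cells (r1,c1), (r2,c2) with r1 != r2, c1 != c2 and
// m[r1,c2] == m[r2,c1] == 0, then swaps the 2x2 checkerboard. Every trade
// preserves all row and column sums, and the chain is irreducible over the
// set of binary matrices with those margins. Attempted trades that fail the
// checkerboard condition leave the matrix unchanged (still counted as steps).
//
// Uses R's RNG so set.seed() in R makes the chain reproducible.

namespace {

struct EdgeList {
  std::vector<int> rows, cols;
  IntegerMatrix m;

  explicit EdgeList(IntegerMatrix mat) : m(mat) {
    int nr = m.nrow(), nc = m.ncol();
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        if (m(i, j) != 0) { rows.push_back(i); cols.push_back(j); }
  }

  int nnz() const { return static_cast<int>(rows.size()); }

  // one attempted trade; returns true if a swap happened
  bool attempt() {
    int n = nnz();
    if (n < 2) return false;
    int a = static_cast<int>(unif_rand() * n);
    int b = static_cast<int>(unif_rand() * n);
    if (a >= n) a = n - 1;
    if (b >= n) b = n - 1;
    if (a == b) return false;
    int r1 = rows[a], c1 = cols[a], r2 = rows[b], c2 = cols[b];
    if (r1 == r2 || c1 == c2) return false;
    if (m(r1, c2) != 0 || m(r2, c1) != 0) return false;
    m(r1, c1) = 0; m(r2, c2) = 0;
    m(r1, c2) = 1; m(r2, c1) = 1;
    cols[a] = c2; cols[b] = c1;
    return true;
  }

  void steps(int n_steps) {
    for (int s = 0; s < n_steps; ++s) attempt();
  }
};

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_checkerboard(IntegerMatrix m, int n_steps) {
  IntegerMatrix out = clone(m);
  EdgeList e(out);
  GetRNGstate();
  e.steps(n_steps);
  PutRNGstate();
  return out;
}

// Perform exactly `n_swaps` successful trades (bounded by `max_attempts`
// failed-or-successful picks) — used for small worked examples where the
// trade count, not the attempt count, is specified.
// [[Rcpp::export]]
IntegerMatrix cpp_checkerboard_swaps(IntegerMatrix m, int n_swaps,
                                     int max_attempts) {
  IntegerMatrix out = clone(m);
  EdgeList e(out);
  GetRNGstate();
  int done = 0;
  for (int a = 0; a < max_attempts && done < n_swaps; ++a)
    if (e.attempt()) ++done;
  PutRNGstate();
  return out;
}

// Permutation null for per-gene co-occurrence counts.
//
// Both matrices are randomized along independent chains. After a burn-in of
// `burn_in` attempted trades per matrix, one sample is taken every `step`
// attempts, for `n_perm` samples. For each sample the per-gene (column)
// count of samples carrying a 1 in both matrices is recorded. Column sums
// are invariant under the chain, so permuted proportions are these counts
// divided by the fixed per-gene mutation totals.
//
// [[Rcpp::export]]
IntegerMatrix cpp_perm_cooc_counts(IntegerMatrix mut, IntegerMatrix cnv,
                                   int n_perm, int burn_in, int step) {
  if (mut.nrow() != cnv.nrow() || mut.ncol() != cnv.ncol())
    stop("MUT and CNV matrices must have identical dimensions");
  int nr = mut.nrow(), nc = mut.ncol();
  IntegerMatrix m1 = clone(mut), m2 = clone(cnv);
  EdgeList e1(m1), e2(m2);
  IntegerMatrix counts(n_perm, nc);
  GetRNGstate();
  e1.steps(burn_in);
  e2.steps(burn_in);
  for (int p = 0; p < n_perm; ++p) {
    e1.steps(step);
    e2.steps(step);
    for (int j = 0; j < nc; ++j) {
      int cj = 0;
      for (int i = 0; i < nr; ++i)
        if (m1(i, j) != 0 && m2(i, j) != 0) ++cj;
      counts(p, j) = cj;
    }
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  return counts;
}

// Simpler null preserving row sums only: each permutation independently
// shuffles the gene labels within every sample (row) of both matrices.
// Kept as a sensitivity-analysis alternative to the both-margin chain.
//
// [[Rcpp::export]]
IntegerMatrix cpp_perm_cooc_counts_shuffle(IntegerMatrix mut, IntegerMatrix cnv,
                                           int n_perm) {
  if (mut.nrow() != cnv.nrow() || mut.ncol() != cnv.ncol())
    stop("MUT and CNV matrices must have identical dimensions");
  int nr = mut.nrow(), nc = mut.ncol();
  IntegerMatrix counts(n_perm, nc);
  std::vector<int> row1(nc), row2(nc);
  GetRNGstate();
  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) { row1[j] = mut(i, j); row2[j] = cnv(i, j); }
      for (int j = nc - 1; j > 0; --j) { // Fisher-Yates, R RNG
        int k1 = static_cast<int>(unif_rand() * (j + 1));
        int k2 = static_cast<int>(unif_rand() * (j + 1));
        if (k1 > j) k1 = j;
        if (k2 > j) k2 = j;
        std::swap(row1[j], row1[k1]);
        std::swap(row2[j], row2[k2]);
      }
      for (int j = 0; j < nc; ++j)
        if (row1[j] != 0 && row2[j] != 0) ++counts(p, j);
    }
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  return counts;
}
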