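// Rigid-body superposition and the multi-cutoff GDT superposition search.
//
// Coordinates are row-major n x 3 matrices.  The rotation convention is
// fitted = P %*% R + t  (row vectors), with R a proper rotation.

#include <RcppArmadillo.h>
#include <unordered_set>
#include <string>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Kabsch: least-squares fit of P onto Q, reflection-free.
static void kabsch_core(const arma::mat& P, const arma::mat& Q,
                        arma::mat& R, arma::rowvec& t, double& rmsd) {
  arma::rowvec cp = arma::mean(P, 0);
  arma::rowvec cq = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - cp;
  arma::mat Qc = Q.each_row() - cq;
  arma::mat H = Pc.t() * Qc;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed in Kabsch superposition");
  arma::mat D = arma::eye(3, 3);
  if (arma::det(U) * arma::det(V) < 0.0) D(2, 2) = -1.0;
  R = U * D * V.t();
  t = cq - cp * R;
  arma::mat diff = Pc * R - Qc;
  rmsd = std::sqrt(arma::accu(arma::square(diff)) / (double)P.n_rows);
}

// [[Rcpp::export]]
List kabsch_cpp(const arma::mat& P, const arma::mat& Q) {
  if (P.n_rows != Q.n_rows || P.n_cols != 3 || Q.n_cols != 3)
    Rcpp::stop("point sets must be n x 3 matrices of equal size");
  if (P.n_rows < 3) Rcpp::stop("need at least 3 points");
  arma::mat R;
  arma::rowvec t;
  double rmsd;
  kabsch_core(P, Q, R, t, rmsd);
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["rmsd"] = rmsd, _["n_points"] = (int)P.n_rows);
}

// Book-keeping for the best superposition per cutoff: the candidate pool
// is shared, so the per-cutoff maxima are non-decreasing in the cutoff
// by construction.
struct BestPerCutoff {
  std::vector<int> cnt;
  std::vector<double> rmsd;  // inlier RMSD at that cutoff, for ties
  explicit BestPerCutoff(size_t k) : cnt(k, 0), rmsd(k, 1e300) {}
  void update(const arma::vec& d2, const std::vector<double>& cut2) {
    for (size_t c = 0; c < cut2.size(); ++c) {
      int n_in = 0;
      double ss = 0.0;
      for (arma::uword i = 0; i < d2.n_elem; ++i) {
        if (d2[i] <= cut2[c]) {
          ++n_in;
          ss += d2[i];
        }
      }
      double r = n_in > 0 ? std::sqrt(ss / n_in) : 1e300;
      if (n_in > cnt[c] || (n_in == cnt[c] && r < rmsd[c])) {
        cnt[c] = n_in;
        rmsd[c] = r;
      }
    }
  }
};

// superpose on idx and return squared deviations for all points
static arma::vec eval_subset(const arma::mat& P, const arma::mat& Q,
                             const arma::uvec& idx) {
  arma::mat R;
  arma::rowvec t;
  double r;
  kabsch_core(P.rows(idx), Q.rows(idx), R, t, r);
  arma::mat F = P * R;
  F.each_row() += t;
  return arma::sum(arma::square(F - Q), 1);
}

static std::string set_key(const arma::uvec& idx) {
  std::string k;
  k.reserve(idx.n_elem * sizeof(arma::uword));
  for (arma::uword i = 0; i < idx.n_elem; ++i)
    k.append(reinterpret_cast<const char*>(&idx[i]), sizeof(arma::uword));
  return k;
}

// Best inlier counts at each cutoff over the superpositions visited by
// the search.  Every candidate superposition is scored against every
// cutoff, so the returned counts are non-decreasing in the cutoff.  For
// n <= exact_max_n the candidates are the fits on every subset of >= 3
// pairs (exhaustive seeding); otherwise contiguous windows (lengths 3,
// 5, 7 and n) seed an iterative refit driven separately at each cutoff:
// superpose on the current set, reselect the atoms within the cutoff,
// repeat to a fixed point or max_iter rounds.  Already-visited inlier
// sets are not refit again.
// [[Rcpp::export]]
IntegerVector gdt_counts_cpp(const arma::mat& P, const arma::mat& Q,
                             const NumericVector& cutoffs,
                             int exact_max_n = 12, int max_iter = 20) {
  const int n = (int)P.n_rows;
  if ((int)Q.n_rows != n || P.n_cols != 3 || Q.n_cols != 3)
    Rcpp::stop("point sets must be n x 3 matrices of equal size");
  if (n < 3) Rcpp::stop("need at least 3 paired residues");
  const size_t k = cutoffs.size();
  std::vector<double> cut2(k);
  for (size_t c = 0; c < k; ++c) {
    if (cutoffs[c] <= 0) Rcpp::stop("cutoffs must be positive");
    cut2[c] = cutoffs[c] * cutoffs[c];
  }
  BestPerCutoff best(k);

  if (n <= exact_max_n) {
    const unsigned long nmask = 1UL << n;
    std::vector<arma::uword> take;
    take.reserve(n);
    for (unsigned long mask = 0; mask < nmask; ++mask) {
      if (__builtin_popcountl(mask) < 3) continue;
      take.clear();
      for (int i = 0; i < n; ++i)
        if (mask & (1UL << i)) take.push_back((arma::uword)i);
      arma::uvec idx(take);
      best.update(eval_subset(P, Q, idx), cut2);
    }
  } else {
    // window seeds; their fits do not depend on the cutoff, so they are
    // evaluated once and only the refit trajectories run per cutoff
    const int lens[3] = {3, 5, 7};
    const int steps[3] = {2, 2, 3};
    std::vector<arma::uvec> seeds;
    for (int w = 0; w < 4; ++w) {
      int len = (w < 3) ? lens[w] : n;
      int step = (w < 3) ? steps[w] : 1;
      if (len > n) continue;
      for (int start = 0; start + len <= n; start += step) {
        seeds.push_back(arma::regspace<arma::uvec>(start, start + len - 1));
        if (len == n) break;  // global seed has a single placement
      }
    }
    std::vector<arma::vec> seed_d2(seeds.size());
    for (size_t i = 0; i < seeds.size(); ++i) {
      seed_d2[i] = eval_subset(P, Q, seeds[i]);
      best.update(seed_d2[i], cut2);
    }
    for (size_t c = 0; c < k; ++c) {
      if (best.cnt[c] == n) continue;  // nothing left to gain
      std::unordered_set<std::string> seen;
      for (size_t i = 0; i < seeds.size() && best.cnt[c] < n; ++i) {
        arma::uvec cur = arma::find(seed_d2[i] <= cut2[c]);
        for (int it = 0; it < max_iter; ++it) {
          if (cur.n_elem < 3) break;
          if (!seen.insert(set_key(cur)).second) break;
          arma::vec d2 = eval_subset(P, Q, cur);
          best.update(d2, cut2);
          arma::uvec inl = arma::find(d2 <= cut2[c]);
          if (inl.n_elem == cur.n_elem && arma::all(inl == cur)) break;
          cur = inl;
        }
      }
    }
  }
  return IntegerVector(best.cnt.begin(), best.cnt.end());
}

// Per-residue SphereGrinder fractions.  M and T hold the matched model
// and target atoms (same row order); idx_list gives, per sphere, the
// 0-based rows of the matched atoms inside that sphere; n_total is the
// full target-atom count of the sphere (matched or not).  Unmatched
// atoms count as outside the tolerance; spheres with fewer than 3
// matched atoms cannot be superposed and score 0.
// [[Rcpp::export]]
NumericVector sphere_fracs_cpp(const arma::mat& M, const arma::mat& T,
                               const List& idx_list,
                               const IntegerVector& n_total, double tol) {
  const double tol2 = tol * tol;
  const int ns = idx_list.size();
  NumericVector out(ns);
  for (int i = 0; i < ns; ++i) {
    IntegerVector iv = idx_list[i];
    if (iv.size() < 3) {
      out[i] = 0.0;
      continue;
    }
    arma::uvec idx(iv.size());
    for (int j = 0; j < iv.size(); ++j) idx[j] = (arma::uword)iv[j];
    arma::mat Ms = M.rows(idx), Ts = T.rows(idx);
    arma::mat R;
    arma::rowvec t;
    double r;
    kabsch_core(Ms, Ts, R, t, r);
    arma::mat F = Ms * R;
    F.each_row() += t;
    arma::vec d2 = arma::sum(arma::square(F - Ts), 1);
    out[i] = (double)arma::sum(d2 <= tol2) / (double)n_total[i];
  }
  return out;
}
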