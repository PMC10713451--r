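// Alternating Frank-Wolfe optimization of kernel archetypal analysis:
//   min_{A,B} ||M - M B A||_F^2,  A (s x n), B (n x s) column-stochastic.
//
// B is held dense (its FW support grows by at most one cell per pass);
// A is held as per-column sparse vectors, since each cell loads on few
// archetypes. The A-subproblem separates over cells, so every cell gets its
// own exact line search; the B step uses one global exact line search.
// All SRE bookkeeping uses the trace identity tr(M'M) - 2tr(A'C'M) + tr(A'HA)
// with C = M B, H = C'C, so the n x n reconstruction is never formed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <chrono>
#include <cstdlib>

using namespace arma;

typedef std::vector<std::pair<unsigned, double>> spcol;

// h * a_j for a sparse column (s * nnz ops)
static void h_times_col(const mat& h, const spcol& a, vec& out) {
  out.zeros();
  for (const auto& e : a) out += e.second * h.col(e.first);
}

static double dot_col(const spcol& a, const vec& v) {
  double r = 0.0;
  for (const auto& e : a) r += e.second * v(e.first);
  return r;
}

// drop near-zero entries, renormalize to unit column sum;
// returns whether the column changed
static bool prune_renorm(spcol& a) {
  double tot = 0.0;
  bool drop = false;
  for (const auto& e : a) {
    if (e.second > 1e-12) tot += e.second; else drop = true;
  }
  if (!drop && std::abs(tot - 1.0) < 1e-12) return false;
  if (tot <= 0) return false;            // caller guarantees a valid column
  spcol keep;
  keep.reserve(a.size());
  for (const auto& e : a) {
    if (e.second > 1e-12) keep.emplace_back(e.first, e.second / tot);
  }
  a.swap(keep);
  return true;
}

// Per-cell A update. The A-subproblem separates over cells into simplex
// QPs: min_a a'Ha - 2 tt_j'a. Each cell takes up to `steps` pairwise
// Frank-Wolfe steps (move weight from the worst active vertex to the best
// vertex, exact line search clipped at the available weight). The running
// product ha = H a_j is maintained incrementally, so a step costs O(s);
// pairwise steps keep the support small and converge linearly.
static double update_A(std::vector<spcol>& A, const mat& tt, const mat& h,
                       int steps, double normM2) {
  const unsigned n = A.size(), s = h.n_rows;
  vec ha(s), gd(s), tvec(s);
  double cross = 0.0, quad = 0.0;
  for (unsigned j = 0; j < n; ++j) {
    spcol& a = A[j];
    h_times_col(h, a, ha);
    tvec = tt.row(j).t();
    for (int t = 0; t < steps; ++t) {
      gd = tvec - ha;                        // -(1/2) gradient for this cell
      unsigned vto = gd.index_max();         // best vertex (lowest index on ties)
      // support cap: beyond kMaxSupport active archetypes, only exchange
      // weight within the active set (keeps every per-cell loop O(s * cap))
      const std::size_t kMaxSupport = 16;
      bool in_support = false;
      for (const auto& e : a) if (e.first == vto) { in_support = true; break; }
      if (!in_support && a.size() >= kMaxSupport) {
        double best = -datum::inf;
        for (const auto& e : a) {
          if (gd(e.first) > best) { best = gd(e.first); vto = e.first; }
        }
      }
      // worst active vertex
      unsigned aw_pos = 0;
      double aw_gd = datum::inf;
      for (unsigned q = 0; q < a.size(); ++q) {
        if (gd(a[q].first) < aw_gd) { aw_gd = gd(a[q].first); aw_pos = q; }
      }
      unsigned vaw = a[aw_pos].first;
      double num = gd(vto) - aw_gd;
      if (num <= 1e-14 * (1.0 + std::abs(aw_gd))) break;
      double den = h(vto, vto) - 2.0 * h(vto, vaw) + h(vaw, vaw);
      if (den <= 0) break;
      double g = std::min(num / den, a[aw_pos].second);
      if (g <= 0) break;
      // apply: shift g from vaw to vto, keep ha in sync
      a[aw_pos].second -= g;
      bool found = false;
      for (auto& e : a) {
        if (e.first == vto) { e.second += g; found = true; break; }
      }
      if (!found) a.emplace_back(vto, g);
      ha += g * (h.col(vto) - h.col(vaw));
      if (a[aw_pos].second <= 1e-12) a.erase(a.begin() + aw_pos);
    }
    // accumulate the SRE trace terms from the final state; ha is maintained
    // incrementally and only goes stale when pruning rescales the column
    if (prune_renorm(a)) h_times_col(h, a, ha);
    cross += dot_col(a, tvec);
    quad += dot_col(a, ha);
  }
  double v = normM2 - 2.0 * cross + quad;
  return v > 0 ? v : 0.0;
}

// dense n x s copy of selected kernel columns
static void gather_cols(const sp_mat& M, const uvec& idx, mat& out) {
  out.zeros();
  for (unsigned t = 0; t < idx.n_elem; ++t) {
    for (sp_mat::const_col_iterator it = M.begin_col(idx(t));
         it != M.end_col(idx(t)); ++it) {
      out(it.row(), t) = *it;
    }
  }
}

// A A' (s x s dense; s is small) and M A' (n x s)
static void a_outer_products(const std::vector<spcol>& A, const sp_mat& M,
                             mat& aa, mat& ma) {
  ma.zeros();
  aa.zeros();
  for (unsigned j = 0; j < A.size(); ++j) {
    const spcol& a = A[j];
    for (const auto& e1 : a) {
      for (const auto& e2 : a) {
        aa(e1.first, e2.first) += e1.second * e2.second;
      }
    }
    for (sp_mat::const_col_iterator it = M.begin_col(j);
         it != M.end_col(j); ++it) {
      for (const auto& e : a) ma(it.row(), e.first) += (*it) * e.second;
    }
  }
}

// Frank-Wolfe passes over B with per-column step sizes; cc (= M B) kept in
// sync. Each pass picks the FW vertex per archetype from the gradient,
// solves the small s x s system for the jointly optimal per-column steps
// gamma (the composite-direction quadratic is gamma' Q gamma - 2 c' gamma
// with Q = (mv'mv) o (A A') and c_t = -<mv_t, inner_t>), clips gamma to
// [0, 1], and finishes with one exact global line search along the scaled
// direction — so the step is always a descent step.
static void update_B(mat& B, mat& cc, const sp_mat& M,
                     const std::vector<spcol>& A, int passes,
                     mat& ma, mat& inner, mat& mv, mat& z,
                     double gain_floor) {
  const unsigned s = B.n_cols;
  mat aa(s, s);
  a_outer_products(A, M, aa, ma);
  inner = cc * aa - ma;                       // C A A' - M A'
  for (int p = 0; p < passes; ++p) {
    mat gneg = M * inner;                     // (1/2) gradient
    uvec vtx(s);
    for (unsigned t = 0; t < s; ++t) vtx(t) = gneg.col(t).index_min();
    gather_cols(M, vtx, mv);
    mv -= cc;                                 // mv_t = M(v_t - b_t)
    mat q = (mv.t() * mv) % aa;
    vec cvec(s);
    for (unsigned t = 0; t < s; ++t) cvec(t) = -dot(mv.col(t), inner.col(t));
    vec gamma;
    double ridge = 1e-10 * std::max(trace(q) / s, 1e-300);
    bool ok = solve(gamma, q + ridge * eye(s, s), cvec,
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) gamma = ones<vec>(s);
    gamma = clamp(gamma, 0.0, 1.0);
    double num = dot(gamma, cvec);
    if (num <= 0) { gamma = ones<vec>(s); num = accu(cvec); }
    if (num <= 0) break;
    double den = as_scalar(gamma.t() * q * gamma);
    if (den <= 0) break;
    double alpha = std::min(1.0, num / den);
    for (unsigned t = 0; t < s; ++t) {
      double g = alpha * gamma(t);
      B.col(t) *= (1.0 - g);
      B(vtx(t), t) += g;
      z.col(t) = g * mv.col(t);               // z reused as the scaled move
    }
    cc += z;
    inner += z * aa;
    // the exact-step SRE gain; stop once a pass buys practically nothing
    if (2.0 * alpha * num - alpha * alpha * den < gain_floor) break;
  }
}

// [[Rcpp::export(name = ".fw_fit_cpp")]]
Rcpp::List fw_fit_cpp(const arma::sp_mat& M, const arma::uvec& init,
                      int max_iter, double tol, int min_iter,
                      int a_passes, int b_passes, int init_a_passes) {
  const unsigned n = M.n_rows, s = init.n_elem;
  const double normM2 = accu(square(nonzeros(M)));

  mat B(n, s, fill::zeros);
  for (unsigned t = 0; t < s; ++t) B(init(t), t) = 1.0;

  mat cc = M * B;           // C = M B
  mat tt = M * cc;          // M C; row j is (C'M) column j
  mat h = cc.t() * cc;      // H = C'C

  // initialize A: each cell on its best single archetype, then FW passes
  std::vector<spcol> A(n);
  for (unsigned j = 0; j < n; ++j) {
    A[j].emplace_back(tt.row(j).index_max(), 1.0);
  }
  std::vector<double> trace;
  trace.push_back(update_A(A, tt, h, init_a_passes, normM2));

  mat ma(n, s), inner(n, s), mv(n, s), z(n, s);
  const double gain_floor = 1e-9 * normM2;
  const bool verbose = std::getenv("METACELLKIT_FW_VERBOSE") != nullptr;
  bool converged = false;
  int it = 0, hits = 0;
  while (it < max_iter) {
    ++it;
    std::chrono::steady_clock::time_point c0 = std::chrono::steady_clock::now();
    update_B(B, cc, M, A, b_passes, ma, inner, mv, z, gain_floor);
    std::chrono::steady_clock::time_point c1 = std::chrono::steady_clock::now();
    tt = M * cc;
    h = cc.t() * cc;
    std::chrono::steady_clock::time_point c2 = std::chrono::steady_clock::now();
    double sre = update_A(A, tt, h, a_passes, normM2);
    std::chrono::steady_clock::time_point c3 = std::chrono::steady_clock::now();
    if (verbose && it % 5 == 0) {
      std::size_t nnzA = 0;
      for (const auto& a : A) nnzA += a.size();
      Rcpp::Rcout << "iter " << it
        << " B=" << std::chrono::duration<double>(c1 - c0).count()
        << " tt/h=" << std::chrono::duration<double>(c2 - c1).count()
        << " A=" << std::chrono::duration<double>(c3 - c2).count()
        << " sre=" << sre << " nnzA/n=" << double(nnzA) / n << std::endl;
    }
    double prev = trace.back();
    trace.push_back(sre);
    double rel = (prev - sre) / std::max(prev, 1e-300);
    hits = (rel < tol) ? hits + 1 : 0;
    if (it >= min_iter && hits >= 3) { converged = true; break; }
  }

  // pack A as triplets
  std::size_t nnz = 0;
  for (const auto& a : A) nnz += a.size();
  Rcpp::IntegerVector ai(nnz), aj(nnz);
  Rcpp::NumericVector ax(nnz);
  std::size_t k = 0;
  for (unsigned j = 0; j < n; ++j) {
    for (const auto& e : A[j]) {
      ai[k] = e.first + 1; aj[k] = j + 1; ax[k] = e.second; ++k;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("ai") = ai, Rcpp::Named("aj") = aj, Rcpp::Named("ax") = ax,
      Rcpp::Named("B") = B,
      Rcpp::Named("sre_trace") = trace,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iter") = it);
}
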