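// Dynamic-programming cores for pairwise MML sequence comparison:
// scaled-linear and log-space forward passes over the three-state
// (match/insert/delete) alignment machine, Viterbi optimal alignment,
// the expected-alignment-distance recurrences, per-state backward pass,
// and stochastic traceback sampling.
//
// Conventions (shared with the R wrappers):
//  - state 0 = match (consumes one residue of each sequence),
//    state 1 = insert (consumes S, vertical move),
//    state 2 = delete (consumes T, horizontal move);
//  - cell (i, j) corresponds to prefixes S[1..i], T[1..j];
//  - trans(p, q) = Pr(q | p); rows sum to 1 - rho (rho = stop probability);
//  - phi = begin distribution over the three states;
//  - a path's joint probability is
//      phi[q1] * prod trans(q_k, q_{k+1}) * rho * prod emissions,
//    with match emission jm(s_i, t_j), insert emission gs[s_i],
//    delete emission gt[t_j].

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse3(double a, double b, double c) {
  double m = std::max(a, std::max(b, c));
  if (m == NEG_INF) return NEG_INF;
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

// Forward pass, linear space with per-row max rescaling. Returns the marginal
// message length in bits and (optionally) the scaled per-state matrices plus
// the cumulative log-scale of each row (natural log). Stored value * exp(rowlog)
// is the unnormalized joint mass of prefix alignments ending at the cell in
// that state.
// [[Rcpp::export]]
List fwd_scaled_cpp(IntegerVector sidx, IntegerVector tidx, NumericMatrix jm,
                    NumericVector gs, NumericVector gt, NumericMatrix trans,
                    NumericVector phi, double rho, bool keep) {
  const int m = sidx.size(), n = tidx.size();
  NumericMatrix Fm(m + 1, n + 1), Fi(m + 1, n + 1), Fd(m + 1, n + 1);
  NumericVector rowlog(m + 1);

  // row 0
  Fm(0, 0) = 1.0;
  for (int j = 1; j <= n; ++j) {
    double mass = (j == 1) ? Fm(0, 0) * phi[2] : Fd(0, j - 1) * trans(2, 2);
    Fd(0, j) = gt[tidx[j - 1]] * mass;
  }
  double mx = 1.0;
  for (int j = 1; j <= n; ++j) mx = std::max(mx, Fd(0, j));
  for (int j = 0; j <= n; ++j) { Fm(0, j) /= mx; Fd(0, j) /= mx; }
  rowlog[0] = std::log(mx);

  for (int i = 1; i <= m; ++i) {
    const int si = sidx[i - 1];
    // j = 0: insert only
    {
      double mass = (i == 1) ? Fm(0, 0) * phi[1]
                             : Fm(i - 1, 0) * trans(0, 1) + Fi(i - 1, 0) * trans(1, 1) +
                               Fd(i - 1, 0) * trans(2, 1);
      Fi(i, 0) = gs[si] * mass;
      Fm(i, 0) = 0.0; Fd(i, 0) = 0.0;
    }
    for (int j = 1; j <= n; ++j) {
      const int tj = tidx[j - 1];
      double massm = (i == 1 && j == 1)
        ? Fm(0, 0) * phi[0]
        : Fm(i - 1, j - 1) * trans(0, 0) + Fi(i - 1, j - 1) * trans(1, 0) +
          Fd(i - 1, j - 1) * trans(2, 0);
      double massi = Fm(i - 1, j) * trans(0, 1) + Fi(i - 1, j) * trans(1, 1) +
                     Fd(i - 1, j) * trans(2, 1);
      double massd = (i == 0) ? 0.0
        : Fm(i, j - 1) * trans(0, 2) + Fi(i, j - 1) * trans(1, 2) +
          Fd(i, j - 1) * trans(2, 2);
      Fm(i, j) = jm(si, tj) * massm;
      Fi(i, j) = gs[si] * massi;
      Fd(i, j) = gt[tj] * massd;
    }
    double mxi = 0.0;
    for (int j = 0; j <= n; ++j)
      mxi = std::max(mxi, std::max(Fm(i, j), std::max(Fi(i, j), Fd(i, j))));
    if (mxi <= 0.0) stop("forward pass lost all probability mass (degenerate model)");
    for (int j = 0; j <= n; ++j) { Fm(i, j) /= mxi; Fi(i, j) /= mxi; Fd(i, j) /= mxi; }
    rowlog[i] = rowlog[i - 1] + std::log(mxi);
  }

  double tot = Fm(m, n) + Fi(m, n) + Fd(m, n);
  double bits = R_PosInf;
  if (tot > 0.0)
    bits = -(std::log(tot * rho) + rowlog[m]) / M_LN2;
  if (keep)
    return List::create(_["bits"] = bits, _["Fm"] = Fm, _["Fi"] = Fi,
                        _["Fd"] = Fd, _["rowlog"] = rowlog);
  return List::create(_["bits"] = bits);
}

// Marginal message length only, rolling two-row buffers (used in time scans).
// [[Rcpp::export]]
double fwd_bits_cpp(IntegerVector sidx, IntegerVector tidx, NumericMatrix jm,
                    NumericVector gs, NumericVector gt, NumericMatrix trans,
                    NumericVector phi, double rho) {
  const int m = sidx.size(), n = tidx.size();
  std::vector<double> pm(n + 1), pi_(n + 1), pd(n + 1), cm(n + 1), ci(n + 1), cd(n + 1);
  double acc = 0.0;  // cumulative log scale of "previous" row

  pm[0] = 1.0; pi_[0] = 0.0; pd[0] = 0.0;
  for (int j = 1; j <= n; ++j) {
    double mass = (j == 1) ? pm[0] * phi[2] : pd[j - 1] * trans(2, 2);
    pd[j] = gt[tidx[j - 1]] * mass;
    pm[j] = 0.0; pi_[j] = 0.0;
  }
  double mx = 1.0;
  for (int j = 1; j <= n; ++j) mx = std::max(mx, pd[j]);
  for (int j = 0; j <= n; ++j) { pm[j] /= mx; pd[j] /= mx; }
  acc = std::log(mx);

  for (int i = 1; i <= m; ++i) {
    const int si = sidx[i - 1];
    {
      double mass = (i == 1) ? pm[0] * phi[1]
                             : pm[0] * trans(0, 1) + pi_[0] * trans(1, 1) + pd[0] * trans(2, 1);
      ci[0] = gs[si] * mass; cm[0] = 0.0; cd[0] = 0.0;
    }
    for (int j = 1; j <= n; ++j) {
      const int tj = tidx[j - 1];
      double massm = (i == 1 && j == 1)
        ? pm[0] * phi[0]
        : pm[j - 1] * trans(0, 0) + pi_[j - 1] * trans(1, 0) + pd[j - 1] * trans(2, 0);
      double massi = pm[j] * trans(0, 1) + pi_[j] * trans(1, 1) + pd[j] * trans(2, 1);
      double massd = cm[j - 1] * trans(0, 2) + ci[j - 1] * trans(1, 2) + cd[j - 1] * trans(2, 2);
      cm[j] = jm(si, tj) * massm;
      ci[j] = gs[si] * massi;
      cd[j] = gt[tj] * massd;
    }
    double mxi = 0.0;
    for (int j = 0; j <= n; ++j)
      mxi = std::max(mxi, std::max(cm[j], std::max(ci[j], cd[j])));
    if (mxi <= 0.0) stop("forward pass lost all probability mass (degenerate model)");
    for (int j = 0; j <= n; ++j) { pm[j] = cm[j] / mxi; pi_[j] = ci[j] / mxi; pd[j] = cd[j] / mxi; }
    acc += std::log(mxi);
  }
  double tot = pm[n] + pi_[n] + pd[n];
  if (tot <= 0.0) return R_PosInf;
  return -(std::log(tot * rho) + acc) / M_LN2;
}

// Full log-space forward pass (natural log). Exact per-cell values for the
// marginal landscape and for exposing the per-state forward matrices.
// [[Rcpp::export]]
List fwd_log_cpp(IntegerVector sidx, IntegerVector tidx, NumericMatrix jm,
                 NumericVector gs, NumericVector gt, NumericMatrix trans,
                 NumericVector phi, double rho) {
  const int m = sidx.size(), n = tidx.size();
  NumericMatrix Lm(m + 1, n + 1), Li(m + 1, n + 1), Ld(m + 1, n + 1);
  NumericMatrix lt(3, 3);
  for (int p = 0; p < 3; ++p) for (int q = 0; q < 3; ++q) lt(p, q) = std::log(trans(p, q));
  std::fill(Lm.begin(), Lm.end(), NEG_INF);
  std::fill(Li.begin(), Li.end(), NEG_INF);
  std::fill(Ld.begin(), Ld.end(), NEG_INF);

  Lm(0, 0) = 0.0;  // begin mass, kept in the match slot
  for (int j = 1; j <= n; ++j) {
    double mass = (j == 1) ? Lm(0, 0) + std::log(phi[2]) : Ld(0, j - 1) + lt(2, 2);
    Ld(0, j) = std::log(gt[tidx[j - 1]]) + mass;
  }
  for (int i = 1; i <= m; ++i) {
    const int si = sidx[i - 1];
    const double lgs = std::log(gs[si]);
    {
      double mass = (i == 1) ? Lm(0, 0) + std::log(phi[1])
                             : lse3(Lm(i - 1, 0) + lt(0, 1), Li(i - 1, 0) + lt(1, 1),
                                    Ld(i - 1, 0) + lt(2, 1));
      Li(i, 0) = lgs + mass;
    }
    for (int j = 1; j <= n; ++j) {
      const int tj = tidx[j - 1];
      double massm = (i == 1 && j == 1)
        ? Lm(0, 0) + std::log(phi[0])
        : lse3(Lm(i - 1, j - 1) + lt(0, 0), Li(i - 1, j - 1) + lt(1, 0),
               Ld(i - 1, j - 1) + lt(2, 0));
      double massi = lse3(Lm(i - 1, j) + lt(0, 1), Li(i - 1, j) + lt(1, 1),
                          Ld(i - 1, j) + lt(2, 1));
      double massd = lse3(Lm(i, j - 1) + lt(0, 2), Li(i, j - 1) + lt(1, 2),
                          Ld(i, j - 1) + lt(2, 2));
      Lm(i, j) = std::log(jm(si, tj)) + massm;
      Li(i, j) = lgs + massi;
      Ld(i, j) = std::log(gt[tj]) + massd;
    }
  }
  double tot = lse3(Lm(m, n), Li(m, n), Ld(m, n));
  double bits = -(tot + std::log(rho)) / M_LN2;
  return List::create(_["bits"] = bits, _["Lm"] = Lm, _["Li"] = Li, _["Ld"] = Ld);
}

// Per-state backward pass in log space. B_q(i, j) sums, over all suffix paths
// leaving state q at cell (i, j), the transitions, downstream emissions and the
// final stop probability (the emission at (i, j) itself is excluded; it lives
// in the forward matrices).
// [[Rcpp::export]]
List bwd_log_cpp(IntegerVector sidx, IntegerVector tidx, NumericMatrix jm,
                 NumericVector gs, NumericVector gt, NumericMatrix trans,
                 double rho) {
  const int m = sidx.size(), n = tidx.size();
  NumericMatrix Bm(m + 1, n + 1), Bi(m + 1, n + 1), Bd(m + 1, n + 1);
  NumericMatrix lt(3, 3);
  for (int p = 0; p < 3; ++p) for (int q = 0; q < 3; ++q) lt(p, q) = std::log(trans(p, q));
  const double lrho = std::log(rho);
  for (int i = m; i >= 0; --i) {
    for (int j = n; j >= 0; --j) {
      if (i == m && j == n) { Bm(i, j) = Bi(i, j) = Bd(i, j) = lrho; continue; }
      double em_m = (i < m && j < n) ? std::log(jm(sidx[i], tidx[j])) + Bm(i + 1, j + 1) : NEG_INF;
      double em_i = (i < m) ? std::log(gs[sidx[i]]) + Bi(i + 1, j) : NEG_INF;
      double em_d = (j < n) ? std::log(gt[tidx[j]]) + Bd(i, j + 1) : NEG_INF;
      for (int q = 0; q < 3; ++q) {
        double v = lse3(lt(q, 0) + em_m, lt(q, 1) + em_i, lt(q, 2) + em_d);
        if (q == 0) Bm(i, j) = v; else if (q == 1) Bi(i, j) = v; else Bd(i, j) = v;
      }
    }
  }
  return List::create(_["Bm"] = Bm, _["Bi"] = Bi, _["Bd"] = Bd);
}

// Optimal (minimum two-part message length) alignment by Viterbi in log space.
// Tie-break: match preferred over delete over insert.
// [[Rcpp::export]]
List viterbi_cpp(IntegerVector sidx, IntegerVector tidx, NumericMatrix jm,
                 NumericVector gs, NumericVector gt, NumericMatrix trans,
                 NumericVector phi, double rho) {
  const int m = sidx.size(), n = tidx.size();
  NumericMatrix Vm(m + 1, n + 1), Vi(m + 1, n + 1), Vd(m + 1, n + 1);
  IntegerMatrix Pm(m + 1, n + 1), Pi_(m + 1, n + 1), Pd(m + 1, n + 1);
  NumericMatrix lt(3, 3);
  for (int p = 0; p < 3; ++p) for (int q = 0; q < 3; ++q) lt(p, q) = std::log(trans(p, q));
  std::fill(Vm.begin(), Vm.end(), NEG_INF);
  std::fill(Vi.begin(), Vi.end(), NEG_INF);
  std::fill(Vd.begin(), Vd.end(), NEG_INF);
  const int pref[3] = {0, 2, 1};  // preference order m, d, i

  Vm(0, 0) = 0.0;
  // best predecessor for state q entering (i,j); returns score, sets *bp
  auto best = [&](int i, int j, int q, int pi0, int pj0, int *bp) -> double {
    if (pi0 == 0 && pj0 == 0) { *bp = -1; return Vm(0, 0) + std::log(phi[q]); }
    double sc = NEG_INF; int b = 0;
    for (int k = 0; k < 3; ++k) {
      int p = pref[k];
      double v = (p == 0 ? Vm(pi0, pj0) : p == 1 ? Vi(pi0, pj0) : Vd(pi0, pj0)) + lt(p, q);
      if (v > sc) { sc = v; b = p; }
    }
    *bp = b;
    return sc;
  };

  for (int j = 1; j <= n; ++j) {
    int bp; double sc = best(0, j, 2, 0, j - 1, &bp);
    Vd(0, j) = std::log(gt[tidx[j - 1]]) + sc; Pd(0, j) = bp;
  }
  for (int i = 1; i <= m; ++i) {
    const int si = sidx[i - 1];
    {
      int bp; double sc = best(i, 0, 1, i - 1, 0, &bp);
      Vi(i, 0) = std::log(gs[si]) + sc; Pi_(i, 0) = bp;
    }
    for (int j = 1; j <= n; ++j) {
      const int tj = tidx[j - 1];
      int bp;
      double sc = best(i, j, 0, i - 1, j - 1, &bp);
      Vm(i, j) = std::log(jm(si, tj)) + sc; Pm(i, j) = bp;
      sc = best(i, j, 1, i - 1, j, &bp);
      Vi(i, j) = std::log(gs[si]) + sc; Pi_(i, j) = bp;
      sc = best(i, j, 2, i, j - 1, &bp);
      Vd(i, j) = std::log(gt[tj]) + sc; Pd(i, j) = bp;
    }
  }
  // final state, preference m, d, i
  int q = 0; double vbest = Vm(m, n);
  if (Vd(m, n) > vbest) { vbest = Vd(m, n); q = 2; }
  if (Vi(m, n) > vbest) { vbest = Vi(m, n); q = 1; }
  double bits = -(vbest + std::log(rho)) / M_LN2;

  std::string states;
  int i = m, j = n;
  while (!(i == 0 && j == 0)) {
    int bp;
    if (q == 0) { bp = Pm(i, j); states.push_back('m'); --i; --j; }
    else if (q == 1) { bp = Pi_(i, j); states.push_back('i'); --i; }
    else { bp = Pd(i, j); states.push_back('d'); --j; }
    if (bp < 0) break;
    q = bp;
  }
  std::reverse(states.begin(), states.end());
  return List::create(_["bits"] = bits, _["states"] = states);
}

// Expected inter-alignment distance to a reference alignment, in the
// conditional-expectation form of the three-matrix recurrences: alongside the
// scaled forward masses we carry R_state(i, j) = EAD_state(i, j) / F_state(i, j),
// the expected distance-so-far conditional on ending at (i, j) in that state.
// Per-cell predecessor weights are scale-free, so no rescaling bookkeeping is
// needed. piref[k + 1] is the reference path's proper-diagonal index at skew
// diagonal k, k = 0..m+n.
// [[Rcpp::export]]
List ead_cpp(IntegerVector sidx, IntegerVector tidx, NumericMatrix jm,
             NumericVector gs, NumericVector gt, NumericMatrix trans,
             NumericVector phi, double rho, IntegerVector piref) {
  const int m = sidx.size(), n = tidx.size();
  if (piref.size() != m + n + 1) stop("reference profile has wrong length");
  NumericMatrix Fm(m + 1, n + 1), Fi(m + 1, n + 1), Fd(m + 1, n + 1);
  NumericMatrix Rm(m + 1, n + 1), Ri(m + 1, n + 1), Rd(m + 1, n + 1);

  Fm(0, 0) = 1.0;
  for (int j = 1; j <= n; ++j) {
    double mass = (j == 1) ? Fm(0, 0) * phi[2] : Fd(0, j - 1) * trans(2, 2);
    Fd(0, j) = gt[tidx[j - 1]] * mass;
    Rd(0, j) = (j == 1 ? 0.0 : Rd(0, j - 1)) + std::abs(j - piref[j]);
  }
  double mx = 1.0;
  for (int j = 1; j <= n; ++j) mx = std::max(mx, Fd(0, j));
  for (int j = 0; j <= n; ++j) { Fm(0, j) /= mx; Fd(0, j) /= mx; }

  for (int i = 1; i <= m; ++i) {
    const int si = sidx[i - 1];
    {
      double a0 = (i == 1) ? Fm(0, 0) * phi[1] : Fm(i - 1, 0) * trans(0, 1);
      double a1 = (i == 1) ? 0.0 : Fi(i - 1, 0) * trans(1, 1);
      double a2 = (i == 1) ? 0.0 : Fd(i - 1, 0) * trans(2, 1);
      double mass = a0 + a1 + a2;
      Fi(i, 0) = gs[si] * mass;
      double rprev = 0.0;
      if (mass > 0.0 && i > 1)
        rprev = (a0 * Rm(i - 1, 0) + a1 * Ri(i - 1, 0) + a2 * Rd(i - 1, 0)) / mass;
      Ri(i, 0) = rprev + std::abs(-i - piref[i]);
      Fm(i, 0) = 0.0; Fd(i, 0) = 0.0; Rm(i, 0) = 0.0; Rd(i, 0) = 0.0;
    }
    for (int j = 1; j <= n; ++j) {
      const int tj = tidx[j - 1];
      const int c = j - i, k = i + j;
      // match
      {
        double a0, a1, a2;
        if (i == 1 && j == 1) { a0 = Fm(0, 0) * phi[0]; a1 = a2 = 0.0; }
        else {
          a0 = Fm(i - 1, j - 1) * trans(0, 0);
          a1 = Fi(i - 1, j - 1) * trans(1, 0);
          a2 = Fd(i - 1, j - 1) * trans(2, 0);
        }
        double mass = a0 + a1 + a2;
        Fm(i, j) = jm(si, tj) * mass;
        double rprev = 0.0;
        if (mass > 0.0 && !(i == 1 && j == 1))
          rprev = (a0 * Rm(i - 1, j - 1) + a1 * Ri(i - 1, j - 1) + a2 * Rd(i - 1, j - 1)) / mass;
        Rm(i, j) = rprev + std::abs(c - piref[k - 1]) + std::abs(c - piref[k]);
      }
      // insert
      {
        double a0 = Fm(i - 1, j) * trans(0, 1);
        double a1 = Fi(i - 1, j) * trans(1, 1);
        double a2 = Fd(i - 1, j) * trans(2, 1);
        double mass = a0 + a1 + a2;
        Fi(i, j) = gs[si] * mass;
        double rprev = (mass > 0.0)
          ? (a0 * Rm(i - 1, j) + a1 * Ri(i - 1, j) + a2 * Rd(i - 1, j)) / mass : 0.0;
        Ri(i, j) = rprev + std::abs(c - piref[k]);
      }
      // delete
      {
        double a0 = Fm(i, j - 1) * trans(0, 2);
        double a1 = Fi(i, j - 1) * trans(1, 2);
        double a2 = Fd(i, j - 1) * trans(2, 2);
        double mass = a0 + a1 + a2;
        Fd(i, j) = gt[tj] * mass;
        double rprev = (mass > 0.0)
          ? (a0 * Rm(i, j - 1) + a1 * Ri(i, j - 1) + a2 * Rd(i, j - 1)) / mass : 0.0;
        Rd(i, j) = rprev + std::abs(c - piref[k]);
      }
    }
    double mxi = 0.0;
    for (int j = 0; j <= n; ++j)
      mxi = std::max(mxi, std::max(Fm(i, j), std::max(Fi(i, j), Fd(i, j))));
    if (mxi <= 0.0) stop("forward pass lost all probability mass (degenerate model)");
    for (int j = 0; j <= n; ++j) { Fm(i, j) /= mxi; Fi(i, j) /= mxi; Fd(i, j) /= mxi; }
  }

  double wm = Fm(m, n), wi = Fi(m, n), wd = Fd(m, n);
  double tot = wm + wi + wd;
  if (tot <= 0.0) stop("zero marginal probability; cannot form expectation");
  double expectation = (wm * Rm(m, n) + wi * Ri(m, n) + wd * Rd(m, n)) / tot;
  return List::create(_["expectation"] = expectation);
}

// Stochastic traceback sampling from the scaled forward matrices. Each draw is
// an exact sample from the posterior over alignments. Uses R's RNG.
// [[Rcpp::export]]
CharacterVector sample_paths_cpp(int nsamp, NumericMatrix Fm, NumericMatrix Fi,
                                 NumericMatrix Fd, NumericMatrix trans,
                                 NumericVector phi) {
  const int m = Fm.nrow() - 1, n = Fm.ncol() - 1;
  CharacterVector out(nsamp);
  const char letter[3] = {'m', 'i', 'd'};
  for (int s = 0; s < nsamp; ++s) {
    std::string states;
    int i = m, j = n;
    double w0 = Fm(m, n), w1 = Fi(m, n), w2 = Fd(m, n);
    double tot = w0 + w1 + w2;
    if (tot <= 0.0) stop("degenerate forward matrices: no mass at the sink");
    double u = unif_rand() * tot;
    int q = (u < w0) ? 0 : (u < w0 + w1) ? 1 : 2;
    while (!(i == 0 && j == 0)) {
      states.push_back(letter[q]);
      int pi0 = i, pj0 = j;
      if (q == 0) { --pi0; --pj0; } else if (q == 1) { --pi0; } else { --pj0; }
      if (pi0 == 0 && pj0 == 0) break;
      double a0 = Fm(pi0, pj0) * trans(0, q);
      double a1 = Fi(pi0, pj0) * trans(1, q);
      double a2 = Fd(pi0, pj0) * trans(2, q);
      double am = a0 + a1 + a2;
      if (am <= 0.0) stop("stochastic traceback reached a zero-mass cell");
      double v = unif_rand() * am;
      int p = (v < a0) ? 0 : (v < a0 + a1) ? 1 : 2;
      i = pi0; j = pj0; q = p;
    }
    std::reverse(states.begin(), states.end());
    out[s] = states;
  }
  return out;
}
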