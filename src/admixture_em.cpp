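// Block EM for the admixture likelihood
//   L(Q, F) = sum_ij [ g_ij log(sum_k q_ik f_kj)
//                    + (n_ij - g_ij) log(sum_k q_ik (1 - f_kj)) ]
// with g the alt-allele count and n the per-entry allele count (1 for a
// haploid monokaryon call, 2 for a dikaryon call, 0 for a missing call --
// masked entries contribute nothing because g = n = 0).
//
// The E/M sweep is a fused single pass over the genotype matrix (column
// major, K kept in registers), and convergence is accelerated with
// guarded SQUAREM extrapolation: each cycle runs two exact EM sweeps,
// extrapolates, stabilises with one more sweep, and falls back to the
// plain two-sweep result whenever the extrapolated point does not improve
// the likelihood. The recorded likelihood sequence is non-decreasing by
// construction.
//
// The R wrapper owns initialisation, multi-start and ploidy encoding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double EPS_P = 1e-9;   // clamp for mixture frequencies
static const double EPS_F = 1e-6;   // clamp for ancestral frequencies
static const int    KMAX  = 32;     // stack buffer bound for components

static double loglik(const mat& G, const mat& Nm, const mat& Q, const mat& F) {
  mat P = clamp(Q * F, EPS_P, 1.0 - EPS_P);
  return accu(G % log(P) + (Nm - G) % log(1.0 - P));
}

// One exact EM sweep (joint M-step for Q and F from the responsibilities
// of the current parameters), operating on Qt = Q^T (K x N) and F (K x J).
static void em_sweep(const mat& G, const mat& Nm, const vec& Ti,
                     mat& Qt, mat& F) {
  const uword N = G.n_rows, J = G.n_cols, K = F.n_rows;
  mat Qnum(K, N, fill::zeros);       // K x N accumulator for the Q update
  mat Fnum(K, J, fill::zeros), Fden(K, J, fill::zeros);
  double qi[KMAX], fj[KMAX];

  for (uword j = 0; j < J; ++j) {
    const double* Fj = F.colptr(j);
    const double* Gj = G.colptr(j);
    const double* Nj = Nm.colptr(j);
    double* fn = Fnum.colptr(j);
    double* fd = Fden.colptr(j);
    for (uword k = 0; k < K; ++k) fj[k] = Fj[k];
    for (uword i = 0; i < N; ++i) {
      const double n = Nj[i];
      if (n == 0.0) continue;        // masked / missing entry
      const double g = Gj[i];
      const double* Qi = Qt.colptr(i);
      double p = 0.0;
      for (uword k = 0; k < K; ++k) { qi[k] = Qi[k]; p += qi[k] * fj[k]; }
      if (p < EPS_P) p = EPS_P; else if (p > 1.0 - EPS_P) p = 1.0 - EPS_P;
      const double inv = 1.0 / (p * (1.0 - p));
      const double r1 = g * (1.0 - p) * inv;         // g / p
      const double r0 = (n - g) * p * inv;           // (n - g) / (1 - p)
      double* qn = Qnum.colptr(i);
      for (uword k = 0; k < K; ++k) {
        const double a1 = qi[k] * r1;                // responsibility mass
        const double a0 = qi[k] * r0;
        fn[k] += a1;
        fd[k] += a0;
        qn[k] += fj[k] * a1 + (1.0 - fj[k]) * a0;
      }
    }
  }
  // F update: f <- f A1 / (f A1 + (1 - f) A0)
  for (uword j = 0; j < J; ++j) {
    const double* fjc = F.colptr(j);
    double* fn = Fnum.colptr(j);
    const double* fd = Fden.colptr(j);
    for (uword k = 0; k < K; ++k) {
      const double num = fjc[k] * fn[k];
      const double den = num + (1.0 - fjc[k]) * fd[k];
      double f = den > 0.0 ? num / den : fjc[k];
      if (f < EPS_F) f = EPS_F; else if (f > 1.0 - EPS_F) f = 1.0 - EPS_F;
      fn[k] = f;                     // reuse Fnum as the new F
    }
  }
  F = Fnum;
  // Q update: q_ik <- sum_j (a + b) / T_i, renormalised per sample
  for (uword i = 0; i < N; ++i) {
    double* qn = Qnum.colptr(i);
    double s = 0.0;
    for (uword k = 0; k < K; ++k) { qn[k] /= Ti(i); s += qn[k]; }
    if (s <= 0.0) s = 1.0;
    for (uword k = 0; k < K; ++k) qn[k] /= s;
  }
  Qt = Qnum;
}

// project an extrapolated point back onto the feasible set
static void project(mat& Qt, mat& F) {
  F = clamp(F, EPS_F, 1.0 - EPS_F);
  Qt = clamp(Qt, 0.0, 1.0);
  for (uword i = 0; i < Qt.n_cols; ++i) {
    double s = accu(Qt.col(i));
    if (s <= 0.0) s = 1.0;
    Qt.col(i) /= s;
  }
}

// [[Rcpp::export(name = ".em_admixture_cpp")]]
Rcpp::List em_admixture_cpp(const arma::mat& G, const arma::mat& Nm,
                            const arma::mat& Q0in, const arma::mat& F0in,
                            double tol, int max_iter) {
  if (F0in.n_rows > (uword)KMAX)
    Rcpp::stop("K larger than the compiled component bound (32)");
  vec Ti = sum(Nm, 1);               // total alleles per sample
  Ti.replace(0.0, 1.0);              // guard fully-missing samples
  mat Qt = Q0in.t();                 // K x N working layout
  mat F = F0in;
  std::vector<double> ll_trace;
  double ll = loglik(G, Nm, Qt.t(), F);
  ll_trace.push_back(ll);

  int sweeps = 0;
  while (sweeps < max_iter) {
    mat Qt0 = Qt, F0 = F;
    mat Qt1 = Qt0, F1 = F0;
    em_sweep(G, Nm, Ti, Qt1, F1);
    mat Qt2 = Qt1, F2 = F1;
    em_sweep(G, Nm, Ti, Qt2, F2);
    sweeps += 2;

    // SQUAREM S3 step length
    mat rQ = Qt1 - Qt0, rF = F1 - F0;
    mat vQ = Qt2 - Qt1 - rQ, vF = F2 - F1 - rF;
    double rr = accu(rQ % rQ) + accu(rF % rF);
    double vv = accu(vQ % vQ) + accu(vF % vF);

    double ll_new;
    if (vv > 0 && rr > 0) {
      double alpha = -std::sqrt(rr / vv);
      if (alpha > -1.0) alpha = -1.0;
      mat Qs = Qt0 - 2.0 * alpha * rQ + (alpha * alpha) * vQ;
      mat Fs = F0 - 2.0 * alpha * rF + (alpha * alpha) * vF;
      project(Qs, Fs);
      em_sweep(G, Nm, Ti, Qs, Fs);   // stabilising sweep
      sweeps += 1;
      double lls = loglik(G, Nm, Qs.t(), Fs);
      if (lls >= ll) { Qt = Qs; F = Fs; ll_new = lls; }
      else {
        // fall back to the plain double sweep (monotone by EM theory)
        Qt = Qt2; F = F2; ll_new = loglik(G, Nm, Qt2.t(), F2);
      }
    } else {
      Qt = Qt2; F = F2;              // fixed point reached
      ll_new = loglik(G, Nm, Qt2.t(), F2);
    }
    ll_trace.push_back(ll_new);
    double delta = ll_new - ll;
    ll = ll_new;
    if (delta < tol) break;
  }
  return Rcpp::List::create(Rcpp::Named("Q") = Qt.t(),
                            Rcpp::Named("F") = F,
                            Rcpp::Named("loglik") = ll,
                            Rcpp::Named("loglik_trace") = ll_trace,
                            Rcpp::Named("iterations") = sweeps);
}
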