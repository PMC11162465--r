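#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Encoded reaction network (see encode_network() on the R side).
// A state is a vector of per-species indices (copy numbers for ordinary
// species, grid indices for parameter pseudo-species); the "value vector" w
// holds species values followed by theta entries, and compiled kinetics
// reference indices into w.
// ---------------------------------------------------------------------------

struct NetEnc {
  int n, r, ntheta;
  IntegerVector sizes;
  LogicalVector vdefault;
  std::vector<NumericVector> values;
  IntegerMatrix zeta;
  IntegerVector react_off, react_idx, react_nu;
  IntegerVector kind, c_ref, hill_reg, hill_act;
  NumericVector c_lit, hillK, hilln;
  IntegerVector lc_off, lc_aref, lc_sref;
  NumericVector lc_alit;

  explicit NetEnc(const List& e) {
    n = as<int>(e["n"]); r = as<int>(e["r"]); ntheta = as<int>(e["ntheta"]);
    sizes = e["sizes"]; vdefault = e["vdefault"];
    List vals = e["values"];
    for (int i = 0; i < n; i++) values.push_back(as<NumericVector>(vals[i]));
    zeta = as<IntegerMatrix>(e["zeta"]);
    react_off = e["react_off"]; react_idx = e["react_idx"]; react_nu = e["react_nu"];
    kind = e["kind"]; c_lit = e["c_lit"]; c_ref = e["c_ref"];
    hillK = e["hillK"]; hilln = e["hilln"]; hill_reg = e["hill_reg"]; hill_act = e["hill_act"];
    lc_off = e["lc_off"]; lc_alit = e["lc_alit"]; lc_aref = e["lc_aref"]; lc_sref = e["lc_sref"];
  }

  void wvec(const std::vector<int>& x, const NumericVector& theta,
            std::vector<double>& w) const {
    for (int i = 0; i < n; i++)
      w[i] = vdefault[i] ? (double)x[i] : values[i][x[i]];
    for (int k = 0; k < ntheta; k++) w[n + k] = theta[k];
  }

  double propensity(int j, const std::vector<double>& w) const {
    double c = c_ref[j] > 0 ? w[c_ref[j] - 1] : c_lit[j];
    if (kind[j] == 1) {            // mass action with falling factorials
      double lam = c;
      for (int k = react_off[j]; k < react_off[j + 1]; k++) {
        double xi = w[react_idx[k] - 1];
        int nu = react_nu[k];
        double f = xi;
        for (int d = 1; d < nu; d++) f *= (xi - d);
        if (f < 0) f = 0;
        lam *= f;
      }
      return lam;
    } else if (kind[j] == 2) {     // hill
      double x = w[hill_reg[j] - 1];
      double Kn = std::pow(hillK[j], hilln[j]);
      double xn = std::pow(x, hilln[j]);
      return c * (hill_act[j] == 1 ? xn : Kn) / (Kn + xn);
    } else {                       // linear combination
      double acc = 0.0;
      for (int k = lc_off[j]; k < lc_off[j + 1]; k++) {
        double a = lc_aref[k] > 0 ? w[lc_aref[k] - 1] : lc_alit[k];
        double s = lc_sref[k] > 0 ? w[lc_sref[k] - 1] : 1.0;
        acc += a * s;
      }
      return acc;
    }
  }
};

// ---------------------------------------------------------------------------
// Direct-method stochastic simulation (Gillespie).  Uses R's RNG so runs are
// reproducible under set.seed().
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ssa(List enc_, IntegerVector x0, NumericVector theta,
             double t0, double t_end, int max_events) {
  NetEnc enc(enc_);
  std::vector<int> x(x0.begin(), x0.end());
  std::vector<double> w(enc.n + enc.ntheta);
  std::vector<double> lam(enc.r);
  std::vector<double> times;
  std::vector<int> rxn;
  std::vector<int> states;   // flattened, row = event
  RNGScope rng;
  double t = t0;
  while (true) {
    enc.wvec(x, theta, w);
    double tot = 0.0;
    for (int j = 0; j < enc.r; j++) {
      double l = enc.propensity(j, w);
      if (!(l >= 0.0) || !R_finite(l))
        stop("propensity %d evaluated to a negative or non-finite value", j + 1);
      lam[j] = l; tot += l;
    }
    if (tot <= 0.0) break;
    t += R::exp_rand() / tot;
    if (t >= t_end) break;
    double u = unif_rand() * tot, cum = 0.0;
    int jsel = enc.r - 1;
    for (int j = 0; j < enc.r; j++) { cum += lam[j]; if (u <= cum) { jsel = j; break; } }
    for (int i = 0; i < enc.n; i++) x[i] += enc.zeta(i, jsel);
    times.push_back(t);
    rxn.push_back(jsel + 1);
    for (int i = 0; i < enc.n; i++) states.push_back(x[i]);
    if ((int)times.size() >= max_events)
      stop("SSA exceeded max_events = %d", max_events);
  }
  int k = times.size();
  IntegerMatrix S(k, enc.n);
  for (int e = 0; e < k; e++)
    for (int i = 0; i < enc.n; i++) S(e, i) = states[e * enc.n + i];
  IntegerVector xf(x.begin(), x.end());
  return List::create(_["times"] = wrap(times), _["rxn"] = wrap(rxn),
                      _["states"] = S, _["x_final"] = xf);
}

// Final states only, for Monte Carlo ensembles (one RNG stream, sequential).
// [[Rcpp::export]]
IntegerMatrix cpp_ssa_final(List enc_, IntegerMatrix X0, NumericVector theta,
                            double t0, double t_end, int max_events) {
  NetEnc enc(enc_);
  int N = X0.nrow();
  IntegerMatrix out(N, enc.n);
  std::vector<double> w(enc.n + enc.ntheta);
  std::vector<double> lam(enc.r);
  RNGScope rng;
  for (int s = 0; s < N; s++) {
    std::vector<int> x(enc.n);
    for (int i = 0; i < enc.n; i++) x[i] = X0(s, i);
    double t = t0;
    int ev = 0;
    while (true) {
      enc.wvec(x, theta, w);
      double tot = 0.0;
      for (int j = 0; j < enc.r; j++) {
        double l = enc.propensity(j, w);
        if (!(l >= 0.0) || !R_finite(l))
          stop("propensity %d evaluated to a negative or non-finite value", j + 1);
        lam[j] = l; tot += l;
      }
      if (tot <= 0.0) break;
      t += R::exp_rand() / tot;
      if (t >= t_end) break;
      double u = unif_rand() * tot, cum = 0.0;
      int jsel = enc.r - 1;
      for (int j = 0; j < enc.r; j++) { cum += lam[j]; if (u <= cum) { jsel = j; break; } }
      for (int i = 0; i < enc.n; i++) x[i] += enc.zeta(i, jsel);
      if (++ev >= max_events) stop("SSA exceeded max_events = %d", max_events);
    }
    for (int i = 0; i < enc.n; i++) out(s, i) = x[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Action of the matrix exponential exp(Q t) on a vector by uniformization.
// Q is a (sub)generator in compressed sparse column form: nonnegative
// off-diagonals, column sums <= 0.  The scheme is nonnegativity-preserving
// and, for proper generators, mass-conserving to the series tolerance.
// ---------------------------------------------------------------------------

struct SpMat {
  int m;
  const int *p, *i;
  const double *x;
  explicit SpMat(const S4& Q) {
    IntegerVector dim = Q.slot("Dim");
    m = dim[0];
    p = INTEGER(((SEXP)Q.slot("p")));
    i = INTEGER(((SEXP)Q.slot("i")));
    x = REAL(((SEXP)Q.slot("x")));
  }
  void mv(const std::vector<double>& v, std::vector<double>& out) const {
    std::fill(out.begin(), out.end(), 0.0);
    for (int j = 0; j < m; j++) {
      double vj = v[j];
      if (vj == 0.0) continue;
      for (int k = p[j]; k < p[j + 1]; k++) out[i[k]] += x[k] * vj;
    }
  }
  double max_neg_diag() const {
    double lam = 0.0;
    for (int j = 0; j < m; j++)
      for (int k = p[j]; k < p[j + 1]; k++)
        if (i[k] == j && -x[k] > lam) lam = -x[k];
    return lam;
  }
};

static void expatv_ws(const SpMat& Q, double lam, std::vector<double>& v,
                      double t, double tol, std::vector<double>& term,
                      std::vector<double>& tmp, std::vector<double>& acc) {
  if (t <= 0.0) return;
  int m = Q.m;
  if (lam <= 0.0) return;              // zero generator
  double amax = 40.0;
  int nstep = (int)std::ceil(lam * t / amax);
  if (nstep < 1) nstep = 1;
  double dt = t / nstep;
  double a = lam * dt;
  int K = (int)std::ceil(a + 8.0 * std::sqrt(a + 1.0) + 10.0);
  for (int s = 0; s < nstep; s++) {
    // u_0 = v; u_k = (P u_{k-1}) * a/k with P = I + Q/lam; result =
    // e^{-a} * sum_k u_k.  All u_k are nonnegative, so the series is stable.
    double e = std::exp(-a);
    for (int j = 0; j < m; j++) { term[j] = v[j]; acc[j] = v[j]; }
    for (int k = 1; k <= K; k++) {
      Q.mv(term, tmp);
      double nrm = 0.0;
      double fac = a / k;
      for (int j = 0; j < m; j++) {
        double u = (term[j] + tmp[j] / lam) * fac;
        if (u < 0.0) u = 0.0;           // guard rounding at hard zeros
        term[j] = u;
        acc[j] += u;
        nrm += u;
      }
      if (k > (int)a && nrm * e < tol) break;
    }
    for (int j = 0; j < m; j++) v[j] = acc[j] * e;
  }
}

static void expatv_inplace(const SpMat& Q, std::vector<double>& v,
                           double t, double tol) {
  int m = Q.m;
  std::vector<double> term(m), tmp(m), acc(m);
  expatv_ws(Q, Q.max_neg_diag(), v, t, tol, term, tmp, acc);
}

// Blocked variant: the matrix is block diagonal with contiguous blocks of
// equal size bs (subsystems whose trailing coordinates are static parameter
// pseudo-species), so each block is propagated with its own uniformization
// rate.  Low-rate blocks then need far fewer series terms than the global
// rate would force.
static void expatv_blocked(const SpMat& Q, const std::vector<double>& lamb,
                           int bs, std::vector<double>& v, double t,
                           double tol, std::vector<double>& term,
                           std::vector<double>& tmp) {
  if (t <= 0.0) return;
  int nb = Q.m / bs;
  std::vector<double> w(bs);
  for (int b = 0; b < nb; b++) {
    int lo = b * bs, hi = lo + bs;
    double lam = lamb[b];
    if (lam <= 0.0) continue;
    double vmass = 0.0;
    for (int j = lo; j < hi; j++) vmass += v[j];
    if (vmass <= 0.0) continue;
    double amax = 40.0;
    int nstep = (int)std::ceil(lam * t / amax);
    if (nstep < 1) nstep = 1;
    double dt = t / nstep;
    double a = lam * dt;
    int K = (int)std::ceil(a + 8.0 * std::sqrt(a + 1.0) + 10.0);
    double reltol = tol * (vmass < 1.0 ? vmass : 1.0);
    for (int s = 0; s < nstep; s++) {
      double e = std::exp(-a);
      for (int j = lo; j < hi; j++) { term[j] = v[j]; tmp[j] = v[j]; }
      // tmp accumulates the series for this block
      for (int k = 1; k <= K; k++) {
        // w = Q term (restricted to the block)
        double nrm = 0.0;
        double fac = a / k;
        {
          std::fill(w.begin(), w.end(), 0.0);
          for (int j = lo; j < hi; j++) {
            double vj = term[j];
            if (vj == 0.0) continue;
            for (int kk = Q.p[j]; kk < Q.p[j + 1]; kk++)
              w[Q.i[kk] - lo] += Q.x[kk] * vj;
          }
          for (int j = lo; j < hi; j++) {
            double u = (term[j] + w[j - lo] / lam) * fac;
            if (u < 0.0) u = 0.0;
            term[j] = u;
            tmp[j] += u;
            nrm += u;
          }
        }
        if (k > (int)a && nrm * e < reltol) break;
      }
      for (int j = lo; j < hi; j++) v[j] = tmp[j] * e;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_expatv(S4 Q, NumericVector v, double t, double tol) {
  SpMat M(Q);
  if ((int)v.size() != M.m) stop("dimension mismatch in cpp_expatv");
  std::vector<double> w(v.begin(), v.end());
  expatv_inplace(M, w, t, tol);
  return wrap(w);
}

// ---------------------------------------------------------------------------
// Walk a follower filter along a leader path: alternate exp(Q dt) propagation
// (with the no-leader-jump correction folded into Q's diagonal) and sparse
// jump updates, renormalizing after each step and accumulating the
// log-normalizer.
// ---------------------------------------------------------------------------

// per-block maxima of the negated diagonal (uniformization rates)
static std::vector<double> block_lams(const SpMat& Q, int bs) {
  int nb = Q.m / bs;
  std::vector<double> lamb(nb, 0.0);
  for (int j = 0; j < Q.m; j++)
    for (int k = Q.p[j]; k < Q.p[j + 1]; k++)
      if (Q.i[k] == j && -Q.x[k] > lamb[j / bs]) lamb[j / bs] = -Q.x[k];
  return lamb;
}

// [[Rcpp::export]]
List cpp_filter_path(NumericVector v0, List gens, IntegerVector gidx,
                     NumericVector dts, List jmats, IntegerVector jidx,
                     double tol, int block_size = 0) {
  int S = dts.size();
  std::vector<double> v(v0.begin(), v0.end());
  int m = v.size();
  std::vector<double> tmp(m), ws1(m), ws2(m), ws3(m);
  double logw = 0.0;
  std::vector<SpMat> G; G.reserve(gens.size());
  std::vector< std::vector<double> > Glam(gens.size());
  for (int k = 0; k < gens.size(); k++) G.push_back(SpMat(as<S4>(gens[k])));
  std::vector<SpMat> J; J.reserve(jmats.size());
  for (int k = 0; k < jmats.size(); k++) J.push_back(SpMat(as<S4>(jmats[k])));
  int bs = (block_size > 0 && block_size < m) ? block_size : m;
  for (int s = 0; s < S; s++) {
    if (dts[s] > 0.0) {
      int g = gidx[s] - 1;
      if (Glam[g].empty()) Glam[g] = block_lams(G[g], bs);
      if (bs < m)
        expatv_blocked(G[g], Glam[g], bs, v, dts[s], tol, ws1, ws2);
      else
        expatv_ws(G[g], Glam[g][0], v, dts[s], tol, ws1, ws2, ws3);
      double mass = 0.0;
      for (int j = 0; j < m; j++) { if (v[j] < 0) v[j] = 0; mass += v[j]; }
      if (!(mass > 1e-300))
        return List::create(_["v"] = wrap(v), _["logw"] = R_NegInf, _["ok"] = false);
      for (int j = 0; j < m; j++) v[j] /= mass;
      logw += std::log(mass);
    }
    if (jidx[s] > 0) {
      J[jidx[s] - 1].mv(v, tmp);
      double mass = 0.0;
      for (int j = 0; j < m; j++) { if (tmp[j] < 0) tmp[j] = 0; mass += tmp[j]; }
      if (!(mass > 1e-300))
        return List::create(_["v"] = wrap(v), _["logw"] = R_NegInf, _["ok"] = false);
      for (int j = 0; j < m; j++) v[j] = tmp[j] / mass;
      logw += std::log(mass);
    }
  }
  return List::create(_["v"] = wrap(v), _["logw"] = logw, _["ok"] = true);
}
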