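// Backend for the biogeographically constrained multi-species occupancy
// model: marginal negative log posterior, analytic gradient, and an adaptive
// Metropolis-within-Gibbs sampler. The marginal likelihood sums out the
// latent presence state per species-point pair; detection visit rows must be
// sorted by pair (pair_start gives the row ranges).
#include <Rcpp.h>
using namespace Rcpp;

static inline double soft_plus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline double log_inv_logit(double x) { return -soft_plus(-x); }
static inline double bern_ll(double eta, int y) {
  return y ? log_inv_logit(eta) : log_inv_logit(-eta);
}
static inline double pair_ll(double a, double logD, bool anyDet) {
  double lpsi = log_inv_logit(a), l1mpsi = log_inv_logit(-a);
  if (anyDet) return lpsi + logD;
  double x1 = lpsi + logD, x2 = l1mpsi;
  double m = std::max(x1, x2);
  return m + std::log(std::exp(x1 - m) + std::exp(x2 - m));
}

// Unpacked model data shared by all entry points.
struct OccData {
  int N, M, P, Q, K, npar;
  NumericMatrix Xocc, Wdet;
  IntegerVector kbin, y, pair_of, pair_start;
  NumericVector prior_sd_occ, prior_sd_det;
  double prior_sd_b;
  int i_beta_occ, i_b, i_uzeta, i_beta_det;
  int n_re;
  std::vector<IntegerVector> re_group;
  std::vector<NumericVector> re_x;
  std::vector<int> re_ng, re_val_off, re_sd_off;
  std::vector<double> re_sd_scale;
  std::vector<bool> re_is_det;
  std::vector<bool> anyDet;
};

static OccData unpack(List data) {
  OccData d;
  d.Xocc = as<NumericMatrix>(data["Xocc"]);
  d.Wdet = as<NumericMatrix>(data["Wdet"]);
  d.kbin = as<IntegerVector>(data["kbin"]);
  d.y = as<IntegerVector>(data["y"]);
  d.pair_of = as<IntegerVector>(data["pair_of"]);
  d.pair_start = as<IntegerVector>(data["pair_start"]);
  d.prior_sd_occ = as<NumericVector>(data["prior_sd_occ"]);
  d.prior_sd_det = as<NumericVector>(data["prior_sd_det"]);
  d.prior_sd_b = as<double>(data["prior_sd_b"]);
  d.N = d.Xocc.nrow(); d.P = d.Xocc.ncol();
  d.M = d.Wdet.nrow(); d.Q = d.Wdet.ncol();
  d.K = as<int>(data["K"]);
  List off = data["off"];
  d.i_beta_occ = as<int>(off["i_beta_occ"]);
  d.i_b = as<int>(off["i_b"]);
  d.i_uzeta = as<int>(off["i_uzeta"]);
  d.i_beta_det = as<int>(off["i_beta_det"]);
  d.npar = as<int>(off["npar"]);
  IntegerVector voff = off["re_val_off"], soff = off["re_sd_off"];
  List terms = data["re_terms"];
  d.n_re = terms.size();
  for (int t = 0; t < d.n_re; t++) {
    List tt = terms[t];
    d.re_group.push_back(as<IntegerVector>(tt["group"]));
    d.re_x.push_back(as<NumericVector>(tt["x"]));
    d.re_ng.push_back(as<int>(tt["n_groups"]));
    d.re_sd_scale.push_back(as<double>(tt["sd_scale"]));
    d.re_is_det.push_back(as<bool>(tt["is_det"]));
    d.re_val_off.push_back(voff[t]);
    d.re_sd_off.push_back(soff[t]);
  }
  d.anyDet.assign(d.N, false);
  for (int i = 0; i < d.N; i++)
    for (int v = d.pair_start[i]; v < d.pair_start[i + 1]; v++)
      if (d.y[v]) { d.anyDet[i] = true; break; }
  return d;
}

// zeta (length K) from K-1 free logits, last logit fixed at 0.
static void softmax_zeta(const double* u, int K, std::vector<double>& zeta,
                         std::vector<double>& Qc) {
  double mx = 0.0;
  for (int j = 0; j < K - 1; j++) mx = std::max(mx, u[j]);
  double s = std::exp(0.0 - mx);
  for (int j = 0; j < K - 1; j++) s += std::exp(u[j] - mx);
  zeta.resize(K); Qc.resize(K + 1); Qc[0] = 0.0;
  for (int j = 0; j < K; j++) {
    double uj = (j < K - 1) ? u[j] : 0.0;
    zeta[j] = std::exp(uj - mx) / s;
    Qc[j + 1] = Qc[j] + zeta[j];
  }
}

struct OccState {
  std::vector<double> eta_base, eta_d2r, eta_det, logD, ll;
  std::vector<double> zeta, Qc;
};

static void compute_state(const OccData& d, const NumericVector& par,
                          OccState& st) {
  st.eta_base.assign(d.N, 0.0);
  st.eta_d2r.assign(d.N, 0.0);
  st.eta_det.assign(d.M, 0.0);
  st.logD.assign(d.N, 0.0);
  st.ll.assign(d.N, 0.0);
  for (int j = 0; j < d.P; j++) {
    double b = par[d.i_beta_occ + j];
    if (b == 0.0) continue;
    for (int i = 0; i < d.N; i++) st.eta_base[i] += b * d.Xocc(i, j);
  }
  for (int j = 0; j < d.Q; j++) {
    double b = par[d.i_beta_det + j];
    if (b == 0.0) continue;
    for (int v = 0; v < d.M; v++) st.eta_det[v] += b * d.Wdet(v, j);
  }
  for (int t = 0; t < d.n_re; t++) {
    const IntegerVector& g = d.re_group[t];
    const NumericVector& x = d.re_x[t];
    const double* u = &par[d.re_val_off[t]];
    if (d.re_is_det[t]) {
      for (int v = 0; v < d.M; v++) st.eta_det[v] += u[g[v]] * x[v];
    } else {
      for (int i = 0; i < d.N; i++) st.eta_base[i] += u[g[i]] * x[i];
    }
  }
  if (d.K > 0) {
    softmax_zeta(&par[d.i_uzeta], d.K, st.zeta, st.Qc);
    double b = par[d.i_b];
    for (int i = 0; i < d.N; i++) st.eta_d2r[i] = b * st.Qc[d.kbin[i]];
  }
  for (int v = 0; v < d.M; v++) {
    st.logD[d.pair_of[v]] += bern_ll(st.eta_det[v], d.y[v]);
  }
  for (int i = 0; i < d.N; i++)
    st.ll[i] = pair_ll(st.eta_base[i] + st.eta_d2r[i], st.logD[i],
                       d.anyDet[i]);
}

static double log_prior(const OccData& d, const NumericVector& par,
                        const OccState& st) {
  double lp = 0.0;
  for (int j = 0; j < d.P; j++) {
    double s = d.prior_sd_occ[j], b = par[d.i_beta_occ + j];
    lp += -0.5 * b * b / (s * s) - std::log(s);
  }
  for (int j = 0; j < d.Q; j++) {
    double s = d.prior_sd_det[j], b = par[d.i_beta_det + j];
    lp += -0.5 * b * b / (s * s) - std::log(s);
  }
  if (d.K > 0) {
    double b = par[d.i_b], s = d.prior_sd_b;
    lp += -0.5 * b * b / (s * s);
    for (int j = 0; j < d.K; j++) lp += std::log(st.zeta[j]);
  }
  for (int t = 0; t < d.n_re; t++) {
    double lsd = par[d.re_sd_off[t]], sd = std::exp(lsd);
    double ssu = 0.0;
    const double* u = &par[d.re_val_off[t]];
    for (int g = 0; g < d.re_ng[t]; g++) ssu += u[g] * u[g];
    lp += -d.re_ng[t] * lsd - 0.5 * ssu / (sd * sd);
    double sc = d.re_sd_scale[t];
    lp += -0.5 * sd * sd / (sc * sc) + lsd;  // half-normal + log Jacobian
  }
  return lp;
}

// [[Rcpp::export]]
double occ_nlp(NumericVector par, List data) {
  OccData d = unpack(data);
  OccState st;
  compute_state(d, par, st);
  double ll = 0.0;
  for (int i = 0; i < d.N; i++) ll += st.ll[i];
  return -(ll + log_prior(d, par, st));
}

// [[Rcpp::export]]
List occ_eta(NumericVector par, List data) {
  OccData d = unpack(data);
  OccState st;
  compute_state(d, par, st);
  NumericVector eo(d.N), ed(d.M);
  for (int i = 0; i < d.N; i++) eo[i] = st.eta_base[i] + st.eta_d2r[i];
  for (int v = 0; v < d.M; v++) ed[v] = st.eta_det[v];
  return List::create(_["eta_occ"] = eo, _["eta_det"] = ed);
}

// [[Rcpp::export]]
NumericVector occ_nlp_grad(NumericVector par, List data) {
  OccData d = unpack(data);
  OccState st;
  compute_state(d, par, st);
  std::vector<double> docc(d.N), ddet(d.M);
  for (int i = 0; i < d.N; i++) {
    double a = st.eta_base[i] + st.eta_d2r[i];
    double psi = 1.0 / (1.0 + std::exp(-a));
    if (d.anyDet[i]) docc[i] = 1.0 - psi;
    else {
      double D = std::exp(st.logD[i]);
      double L = psi * D + (1.0 - psi);
      docc[i] = psi * (1.0 - psi) * (D - 1.0) / L;
    }
  }
  for (int v = 0; v < d.M; v++) {
    int i = d.pair_of[v];
    double p = 1.0 / (1.0 + std::exp(-st.eta_det[v]));
    if (d.anyDet[i]) ddet[v] = d.y[v] - p;
    else {
      double a = st.eta_base[i] + st.eta_d2r[i];
      double psi = 1.0 / (1.0 + std::exp(-a));
      double D = std::exp(st.logD[i]);
      double L = psi * D + (1.0 - psi);
      ddet[v] = -psi * D * p / L;
    }
  }
  NumericVector g(d.npar);
  for (int j = 0; j < d.P; j++) {
    double acc = 0.0;
    for (int i = 0; i < d.N; i++) acc += docc[i] * d.Xocc(i, j);
    double s = d.prior_sd_occ[j];
    g[d.i_beta_occ + j] = acc - par[d.i_beta_occ + j] / (s * s);
  }
  for (int j = 0; j < d.Q; j++) {
    double acc = 0.0;
    for (int v = 0; v < d.M; v++) acc += ddet[v] * d.Wdet(v, j);
    double s = d.prior_sd_det[j];
    g[d.i_beta_det + j] = acc - par[d.i_beta_det + j] / (s * s);
  }
  if (d.K > 0) {
    double b = par[d.i_b], acc = 0.0;
    for (int i = 0; i < d.N; i++) acc += docc[i] * st.Qc[d.kbin[i]];
    g[d.i_b] = acc - b / (d.prior_sd_b * d.prior_sd_b);
    for (int j = 0; j < d.K - 1; j++) {
      double a2 = 0.0;
      for (int i = 0; i < d.N; i++) {
        int k = d.kbin[i];
        if (k == 0) continue;
        double ind = (j < k) ? 1.0 : 0.0;
        a2 += docc[i] * b * st.zeta[j] * (ind - st.Qc[k]);
      }
      g[d.i_uzeta + j] = a2 + (1.0 - d.K * st.zeta[j]);
    }
  }
  for (int t = 0; t < d.n_re; t++) {
    const IntegerVector& gr = d.re_group[t];
    const NumericVector& x = d.re_x[t];
    double sd = std::exp(par[d.re_sd_off[t]]);
    double* gv = &g[d.re_val_off[t]];
    const double* u = &par[d.re_val_off[t]];
    if (d.re_is_det[t]) {
      for (int v = 0; v < d.M; v++) gv[gr[v]] += ddet[v] * x[v];
    } else {
      for (int i = 0; i < d.N; i++) gv[gr[i]] += docc[i] * x[i];
    }
    double ssu = 0.0;
    for (int k = 0; k < d.re_ng[t]; k++) {
      gv[k] -= u[k] / (sd * sd);
      ssu += u[k] * u[k];
    }
    double sc = d.re_sd_scale[t];
    g[d.re_sd_off[t]] = -d.re_ng[t] + ssu / (sd * sd)
      - sd * sd / (sc * sc) + 1.0;
  }
  for (int j = 0; j < d.npar; j++) g[j] = -g[j];
  return g;
}

// ---------------------------------------------------------------------------
// Adaptive Metropolis-within-Gibbs sampler.
// Scalar updates exploit the per-pair factorization of the likelihood;
// translation moves shift a fixed effect against its centred random-effect
// vector along the likelihood-invariant direction.
// ---------------------------------------------------------------------------

struct ParamPlan {
  int kind;  // 0 occ-linear, 1 det-linear, 2 d2r (b or uzeta), 3 log-sd
  std::vector<int> idx;    // affected pairs (occ) or visit rows (det)
  std::vector<double> x;   // covariate values aligned with idx
  int re_term;             // for kinds 0/1 from REs, and 3: term id (-1 else)
  double prior_sd;         // gaussian prior sd (kinds 0/1 for betas)
};

// [[Rcpp::export]]
List occ_mwg(NumericVector par0, List data, int n_warmup, int n_iter,
             IntegerVector save_idx, List trans_moves, double prop_init) {
  OccData d = unpack(data);
  NumericVector par = clone(par0);
  OccState st;
  compute_state(d, par, st);

  // build update plans for every scalar parameter
  std::vector<ParamPlan> plan(d.npar);
  for (int j = 0; j < d.P; j++) {
    ParamPlan& p = plan[d.i_beta_occ + j];
    p.kind = 0; p.re_term = -1; p.prior_sd = d.prior_sd_occ[j];
    for (int i = 0; i < d.N; i++)
      if (d.Xocc(i, j) != 0.0) { p.idx.push_back(i); p.x.push_back(d.Xocc(i, j)); }
  }
  for (int j = 0; j < d.Q; j++) {
    ParamPlan& p = plan[d.i_beta_det + j];
    p.kind = 1; p.re_term = -1; p.prior_sd = d.prior_sd_det[j];
    for (int v = 0; v < d.M; v++)
      if (d.Wdet(v, j) != 0.0) { p.idx.push_back(v); p.x.push_back(d.Wdet(v, j)); }
  }
  if (d.K > 0) {
    for (int j = 0; j < d.K; j++) {  // b then uzeta share the d2r plan kind
      int at = (j == 0) ? d.i_b : d.i_uzeta + (j - 1);
      ParamPlan& p = plan[at];
      p.kind = 2; p.re_term = -1; p.prior_sd = d.prior_sd_b;
      for (int i = 0; i < d.N; i++) if (d.kbin[i] > 0) p.idx.push_back(i);
    }
  }
  for (int t = 0; t < d.n_re; t++) {
    int G = d.re_ng[t];
    std::vector<std::vector<int> > by_g(G);
    std::vector<std::vector<double> > bx_g(G);
    const IntegerVector& gr = d.re_group[t];
    const NumericVector& x = d.re_x[t];
    int n = d.re_is_det[t] ? d.M : d.N;
    for (int i = 0; i < n; i++) {
      by_g[gr[i]].push_back(i);
      bx_g[gr[i]].push_back(x[i]);
    }
    for (int g = 0; g < G; g++) {
      ParamPlan& p = plan[d.re_val_off[t] + g];
      p.kind = d.re_is_det[t] ? 1 : 0;
      p.re_term = t; p.prior_sd = NA_REAL;
      p.idx = by_g[g]; p.x = bx_g[g];
    }
    ParamPlan& ps = plan[d.re_sd_off[t]];
    ps.kind = 3; ps.re_term = t; ps.prior_sd = NA_REAL;
  }

  int n_tm = trans_moves.size();
  std::vector<int> tm_beta(n_tm), tm_term(n_tm);
  std::vector<double> tm_prior(n_tm);
  for (int m = 0; m < n_tm; m++) {
    List mm = trans_moves[m];
    tm_beta[m] = as<int>(mm["beta_idx"]);
    tm_term[m] = as<int>(mm["re_term"]);
    tm_prior[m] = as<double>(mm["prior_sd"]);
  }

  std::vector<double> psd(d.npar, prop_init), psd_tm(n_tm, prop_init);
  std::vector<int> acc(d.npar, 0), acc_tm(n_tm, 0);
  std::vector<double> acc_tot(d.npar, 0.0);
  std::vector<double> dlogD_scratch(d.N, 0.0);
  std::vector<char> visited(d.N, 0);
  // caches: per-visit Bernoulli loglik, and proposed values reused on accept
  std::vector<double> logB(d.M);
  for (int v = 0; v < d.M; v++) logB[v] = bern_ll(st.eta_det[v], d.y[v]);
  std::vector<double> scratchL(d.N), scratchB(d.M), scratchD(d.N);

  NumericMatrix draws(n_iter, save_idx.size());
  GetRNGstate();
  int batch = 25;
  for (int it = 0; it < n_warmup + n_iter; it++) {
    for (int j = 0; j < d.npar; j++) {
      ParamPlan& p = plan[j];
      double old = par[j];
      double prop = old + norm_rand() * psd[j];
      double dlp = 0.0;
      bool ok = true;
      if (p.kind == 3) {  // log-sd of RE term t: prior-only
        int t = p.re_term;
        double sd_o = std::exp(old), sd_n = std::exp(prop);
        double ssu = 0.0;
        const double* u = &par[d.re_val_off[t]];
        for (int g = 0; g < d.re_ng[t]; g++) ssu += u[g] * u[g];
        double sc = d.re_sd_scale[t];
        double lp_n = -d.re_ng[t] * prop - 0.5 * ssu / (sd_n * sd_n)
          - 0.5 * sd_n * sd_n / (sc * sc) + prop;
        double lp_o = -d.re_ng[t] * old - 0.5 * ssu / (sd_o * sd_o)
          - 0.5 * sd_o * sd_o / (sc * sc) + old;
        dlp = lp_n - lp_o;
        if (std::log(unif_rand()) < dlp) { par[j] = prop; acc[j]++; }
        acc_tot[j] += 1.0;
        continue;
      }
      // prior difference
      if (p.re_term >= 0) {
        double sd = std::exp(par[d.re_sd_off[p.re_term]]);
        dlp += 0.5 * (old * old - prop * prop) / (sd * sd);
      } else if (p.kind == 2 && j != d.i_b) {
        // uzeta: flat-Dirichlet prior handled below via zeta recompute
      } else {
        double s = p.prior_sd;
        dlp += 0.5 * (old * old - prop * prop) / (s * s);
      }
      double delta = prop - old;
      double dll = 0.0;
      if (p.kind == 0) {  // occupancy-side linear
        for (size_t a = 0; a < p.idx.size(); a++) {
          int i = p.idx[a];
          double anew = st.eta_base[i] + delta * p.x[a] + st.eta_d2r[i];
          scratchL[i] = pair_ll(anew, st.logD[i], d.anyDet[i]);
          dll += scratchL[i] - st.ll[i];
        }
        if (std::log(unif_rand()) < dlp + dll) {
          for (size_t a = 0; a < p.idx.size(); a++) {
            int i = p.idx[a];
            st.eta_base[i] += delta * p.x[a];
            st.ll[i] = scratchL[i];
          }
          par[j] = prop; acc[j]++;
        }
      } else if (p.kind == 1) {  // detection-side linear
        // accumulate logD deltas over touched pairs
        std::vector<int> touched;
        for (size_t a = 0; a < p.idx.size(); a++) {
          int v = p.idx[a], i = d.pair_of[v];
          double bn = st.eta_det[v] + delta * p.x[a];
          scratchB[v] = bern_ll(bn, d.y[v]);
          if (!visited[i]) { visited[i] = 1; touched.push_back(i); }
          dlogD_scratch[i] += scratchB[v] - logB[v];
        }
        for (size_t a = 0; a < touched.size(); a++) {
          int i = touched[a];
          double anew = st.eta_base[i] + st.eta_d2r[i];
          scratchL[i] = pair_ll(anew, st.logD[i] + dlogD_scratch[i],
                                d.anyDet[i]);
          dll += scratchL[i] - st.ll[i];
        }
        if (std::log(unif_rand()) < dlp + dll) {
          for (size_t a = 0; a < p.idx.size(); a++) {
            int v = p.idx[a];
            st.eta_det[v] += delta * p.x[a];
            logB[v] = scratchB[v];
          }
          for (size_t a = 0; a < touched.size(); a++) {
            int i = touched[a];
            st.logD[i] += dlogD_scratch[i];
            st.ll[i] = scratchL[i];
          }
          par[j] = prop; acc[j]++;
        }
        for (size_t a = 0; a < touched.size(); a++) {
          dlogD_scratch[touched[a]] = 0.0;
          visited[touched[a]] = 0;
        }
      } else {  // kind 2: d2r scale or simplex logit
        NumericVector pnew = clone(par);
        pnew[j] = prop;
        std::vector<double> zeta_n, Qc_n;
        softmax_zeta(&pnew[d.i_uzeta], d.K, zeta_n, Qc_n);
        double bn = pnew[d.i_b];
        if (j != d.i_b) {
          for (int l = 0; l < d.K; l++)
            dlp += std::log(zeta_n[l]) - std::log(st.zeta[l]);
        }
        for (size_t a = 0; a < p.idx.size(); a++) {
          int i = p.idx[a];
          scratchD[i] = bn * Qc_n[d.kbin[i]];
          double anew = st.eta_base[i] + scratchD[i];
          scratchL[i] = pair_ll(anew, st.logD[i], d.anyDet[i]);
          dll += scratchL[i] - st.ll[i];
        }
        if (std::log(unif_rand()) < dlp + dll) {
          for (size_t a = 0; a < p.idx.size(); a++) {
            int i = p.idx[a];
            st.eta_d2r[i] = scratchD[i];
            st.ll[i] = scratchL[i];
          }
          st.zeta = zeta_n; st.Qc = Qc_n;
          par[j] = prop; acc[j]++;
        }
        ok = true;
      }
      (void)ok;
      acc_tot[j] += 1.0;
    }
    // translation moves (likelihood-invariant recentring)
    for (int m = 0; m < n_tm; m++) {
      int bi = tm_beta[m], t = tm_term[m];
      double sd = std::exp(par[d.re_sd_off[t]]);
      double delta = norm_rand() * psd_tm[m];
      double b_old = par[bi], b_new = b_old + delta;
      double s = tm_prior[m];
      double dlp = 0.5 * (b_old * b_old - b_new * b_new) / (s * s);
      double* u = &par[d.re_val_off[t]];
      for (int g = 0; g < d.re_ng[t]; g++) {
        double un = u[g] - delta;
        dlp += 0.5 * (u[g] * u[g] - un * un) / (sd * sd);
      }
      if (std::log(unif_rand()) < dlp) {
        par[bi] = b_new;
        for (int g = 0; g < d.re_ng[t]; g++) u[g] -= delta;
        acc_tm[m]++;
      }
    }
    // adapt proposal scales during warmup
    if (it < n_warmup && (it + 1) % batch == 0) {
      for (int j = 0; j < d.npar; j++) {
        double rate = acc[j] / (double)batch;
        psd[j] *= std::exp(1.2 * (rate - 0.44));
        psd[j] = std::min(std::max(psd[j], 1e-4), 10.0);
        acc[j] = 0;
      }
      for (int m = 0; m < n_tm; m++) {
        double rate = acc_tm[m] / (double)batch;
        psd_tm[m] *= std::exp(1.2 * (rate - 0.44));
        psd_tm[m] = std::min(std::max(psd_tm[m], 1e-4), 10.0);
        acc_tm[m] = 0;
      }
    }
    if (it >= n_warmup) {
      int row = it - n_warmup;
      for (int c = 0; c < save_idx.size(); c++)
        draws(row, c) = par[save_idx[c]];
    }
  }
  PutRNGstate();
  double ll = 0.0;
  for (int i = 0; i < d.N; i++) ll += st.ll[i];
  return List::create(_["draws"] = draws, _["final_par"] = par,
                      _["loglik"] = ll);
}
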