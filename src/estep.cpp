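#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Monte Carlo E-step for the joint model.
//
// For each subject, draws N antithetic samples of the random effects from the
// Gaussian posterior b | y (mean m_i, lower Cholesky C_i of the covariance:
// pairs m_i + C_i Omega and m_i - C_i Omega), weights them by the survival
// density f(T_i, delta_i | b; theta), and accumulates the survival-weighted
// conditional expectations needed by the M-step: E[b], E[bb'], and for every
// baseline-hazard atom t_j <= T_i the moments E[exp(eta_ij)],
// E[exp(eta_ij) w_ij] and E[exp(eta_ij) w_ij w_ij'], where
// eta_ij = v_i'gamma_v + gamma_y' w_ij and w_ij is the K-vector of
// random-effect trajectories at t_j. The random-effect design is affine in
// time, z_ik(t) = zc + zm t, so the K x r maps are G_i(t) = Gc_i + t Gm_i.
// Log-weights are shifted by their maximum before exponentiation.
//
// Draws use the R RNG (column-major N/2 x r standard normals per subject),
// so results are reproducible under set.seed() and identical to the R-level
// antithetic constructor.
//
// means:    n x r posterior means
// chols:    cube (r, r, n) of lower Cholesky factors
// N:        even number of draws
// vgam:     n-vector of v_i' gamma_v
// delta:    n-vector of event indicators
// loglamT:  n-vector of log lambda0(T_i) (used when delta = 1)
// hT:       n x r matrix mapping b -> W_2i(T_i, b) (used when delta = 1)
// Hc, Hm:   n x r matrices with rows Gc_i' gamma_y and Gm_i' gamma_y, so
//           W_2i(t, b) = b'(Hc_i + t Hm_i)
// Gc, Gm:   cubes (K, r, n) with the affine design maps
// ft:       J-vector of hazard atom times
// lambda0:  J-vector of hazard increments
// Ji:       n-vector of per-subject atom counts (t_j <= T_i)
// keep_draws: return the per-subject draw matrices
//
// [[Rcpp::export]]
List mjm_estep_cpp(arma::mat means, arma::cube chols, int N,
                   NumericVector vgam, IntegerVector delta,
                   NumericVector loglamT, arma::mat hT,
                   arma::mat Hc, arma::mat Hm,
                   arma::cube Gc, arma::cube Gm,
                   arma::vec ft, arma::vec lambda0, IntegerVector Ji,
                   int J, int K, bool keep_draws) {
  int n = means.n_rows;
  int r = means.n_cols;
  int Nh = N / 2;

  arma::vec logmeanw(n);
  arma::mat Eb(n, r, arma::fill::zeros);
  arma::cube Ebb(r, r, n, arma::fill::zeros);
  arma::mat Eexp(n, std::max(J, 1), arma::fill::zeros);
  arma::cube EexpW(std::max(J, 1), K, n, arma::fill::zeros);
  arma::cube EexpWW(std::max(J, 1), K * K, n, arma::fill::zeros);
  List draws_out(n);

  RNGScope rngScope;
  for (int i = 0; i < n; ++i) {
    // antithetic draws; Omega filled column-major to mirror matrix(rnorm(.))
    arma::mat Om(Nh, r);
    for (int c = 0; c < r; ++c)
      for (int m = 0; m < Nh; ++m)
        Om(m, c) = R::norm_rand();
    arma::mat shift = Om * chols.slice(i).t();
    arma::mat B(N, r);
    for (int m = 0; m < Nh; ++m) {
      B.row(2 * m) = means.row(i) + shift.row(m);
      B.row(2 * m + 1) = means.row(i) - shift.row(m);
    }

    int ji = Ji[i];
    arma::vec logw(N, arma::fill::zeros);
    arma::mat etaexp;
    if (ji > 0) {
      arma::vec w2c = B * Hc.row(i).t();
      arma::vec w2m = B * Hm.row(i).t();
      etaexp.set_size(N, ji);
      for (int j = 0; j < ji; ++j)
        etaexp.col(j) = arma::exp(w2c + ft[j] * w2m + vgam[i]);
      logw = -(etaexp * lambda0.head(ji));
    }
    if (delta[i] == 1)
      logw += loglamT[i] + vgam[i] + B * hT.row(i).t();

    double mx = logw.max();
    if (!std::isfinite(mx))
      stop("degenerate survival weights for subject %d", i + 1);
    arma::vec w = arma::exp(logw - mx);
    double sw = arma::accu(w);
    logmeanw[i] = mx + std::log(sw / N);
    arma::vec wn = w / sw;
    Eb.row(i) = (B.t() * wn).t();
    Ebb.slice(i) = B.t() * (B.each_col() % wn);

    if (ji > 0) {
      arma::mat Gci = Gc.slice(i);  // K x r
      arma::mat Gmi = Gm.slice(i);
      for (int j = 0; j < ji; ++j) {
        arma::vec wexp = wn % etaexp.col(j);
        Eexp(i, j) = arma::accu(wexp);
        arma::vec mj = B.t() * wexp;                   // r
        double tj = ft[j];
        EexpW.slice(i).row(j) = (Gci * mj + tj * (Gmi * mj)).t();
        arma::mat Mj = B.t() * (B.each_col() % wexp);  // r x r
        arma::mat Ecc = Gci * Mj * Gci.t();
        arma::mat Ecm = Gci * Mj * Gmi.t();
        arma::mat Emm = Gmi * Mj * Gmi.t();
        arma::mat WW = Ecc + tj * (Ecm + Ecm.t()) + tj * tj * Emm;
        EexpWW.slice(i).row(j) = arma::vectorise(WW).t();
      }
    }
    if (keep_draws) draws_out[i] = B;
  }
  return List::create(
    _["logmeanw"] = logmeanw, _["Eb"] = Eb, _["Ebb"] = Ebb,
    _["Eexp"] = Eexp, _["EexpW"] = EexpW, _["EexpWW"] = EexpWW,
    _["draws"] = draws_out);
}
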