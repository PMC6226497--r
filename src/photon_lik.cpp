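// Photon-by-photon likelihood engine for continuous-time Markov models of
// two-channel (donor/acceptor) photon streams.
//
// The likelihood of a trace is
//   L = p_fin^T  prod_{i=N..1} [ n_{c_i} exp(H tau_i) ]  p_ini ,
// with H = K - n_D - n_A, tau_1 = 0, later photons applied leftmost,
// optionally followed by a photon-free tail propagation exp(H * tail).
// Underflow is handled by renormalizing the propagated vector after every
// photon and accumulating the log scale.
//
// The generators used here (linear three-state chains and the
// association/dissociation/dark-state model) are tree-structured, hence
// symmetrizable by a diagonal similarity transform: we diagonalize the
// symmetrized H once and propagate in its eigenbasis (real arithmetic).
// A complex eig_gen fallback covers non-symmetrizable inputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Try to find diagonal d with diag(d) H diag(1/d) symmetric.
// Works when the off-diagonal sparsity pattern is symmetric, entries have
// matching signs, and the connectivity graph is consistent (always true for
// tree-structured rate matrices). Returns false on failure.
static bool symmetrizer(const mat& H, vec& d) {
  const uword n = H.n_rows;
  d.set_size(n);
  d.fill(datum::nan);
  d(0) = 1.0;
  std::vector<uword> stack{0};
  uvec visited(n, fill::zeros);
  visited(0) = 1;
  while (!stack.empty()) {
    uword i = stack.back();
    stack.pop_back();
    for (uword j = 0; j < n; ++j) {
      if (j == i) continue;
      double hij = H(i, j), hji = H(j, i);
      bool zi = std::abs(hij) < 1e-300, zj = std::abs(hji) < 1e-300;
      if (zi && zj) continue;
      if (zi != zj || hij * hji <= 0.0) return false;  // one-sided edge
      double dj = d(i) * std::sqrt(hji / hij);
      if (visited(j)) {
        if (std::abs(d(j) - dj) > 1e-8 * std::max(1.0, std::abs(dj)))
          return false;  // inconsistent cycle
      } else {
        d(j) = dj;
        visited(j) = 1;
        stack.push_back(j);
      }
    }
  }
  if (any(visited == 0)) {
    // disconnected states: give them unit scale (H block diagonal)
    for (uword j = 0; j < n; ++j) if (!visited(j)) d(j) = 1.0;
  }
  // verify
  for (uword i = 0; i < n; ++i)
    for (uword j = i + 1; j < n; ++j) {
      double a = d(i) * H(i, j) / d(j), b = d(j) * H(j, i) / d(i);
      if (std::abs(a - b) > 1e-7 * std::max(1.0, std::max(std::abs(a), std::abs(b))))
        return false;
    }
  return true;
}

// Core propagation in a real eigenbasis.
// lam: eigenvalues of H; AD, AA: channel rate matrices in the eigenbasis;
// w0: transformed p_ini; f: transformed p_fin.
static double propagate_real(const vec& lam, const mat& AD, const mat& AA,
                             const vec& w0, const vec& f,
                             const vec& tau, const ivec& chan, double tail) {
  vec w = w0;
  double acc = 0.0;
  const uword n = lam.n_elem, N = tau.n_elem;
  vec e(n);
  for (uword i = 0; i < N; ++i) {
    double t = tau(i);
    if (t > 0) {
      for (uword s = 0; s < n; ++s) e(s) = std::exp(lam(s) * t);
      w %= e;
    }
    w = (chan(i) == 0) ? AD * w : AA * w;
    double nrm = norm(w);
    if (!(nrm > 0)) return -datum::inf;
    w /= nrm;
    acc += std::log(nrm);
  }
  if (tail > 0) {
    for (uword s = 0; s < n; ++s) e(s) = std::exp(lam(s) * tail);
    w %= e;
    double nrm = norm(w);
    if (!(nrm > 0)) return -datum::inf;
    w /= nrm;
    acc += std::log(nrm);
  }
  double val = dot(f, w);
  if (!(val > 0)) return -datum::inf;
  return acc + std::log(val);
}

static double propagate_complex(const cx_vec& lam, const cx_mat& AD,
                                const cx_mat& AA, const cx_vec& w0,
                                const cx_vec& f, const vec& tau,
                                const ivec& chan, double tail) {
  cx_vec w = w0;
  double acc = 0.0;
  const uword n = lam.n_elem, N = tau.n_elem;
  cx_vec e(n);
  for (uword i = 0; i < N; ++i) {
    double t = tau(i);
    if (t > 0) {
      for (uword s = 0; s < n; ++s) e(s) = std::exp(lam(s) * t);
      w %= e;
    }
    w = (chan(i) == 0) ? AD * w : AA * w;
    double nrm = norm(w);
    if (!(nrm > 0)) return -datum::inf;
    w /= nrm;
    acc += std::log(nrm);
  }
  if (tail > 0) {
    for (uword s = 0; s < n; ++s) e(s) = std::exp(lam(s) * tail);
    w %= e;
    double nrm = norm(w);
    if (!(nrm > 0)) return -datum::inf;
    w /= nrm;
    acc += std::log(nrm);
  }
  double val = real(cdot(f, w));
  if (!(val > 0)) return -datum::inf;
  return acc + std::log(val);
}

// General log-likelihood for an arbitrary model.
// tau: inter-photon times (tau[0] conventionally 0); chan: 0 = donor,
// 1 = acceptor; tail: photon-free interval after the last photon.
// [[Rcpp::export]]
double cpp_trace_loglik(const arma::vec& tau, const arma::ivec& chan,
                        const arma::mat& K, const arma::vec& nD,
                        const arma::vec& nA, const arma::vec& pini,
                        const arma::vec& pfin, double tail) {
  const uword n = K.n_rows;
  mat H = K;
  H.diag() -= (nD + nA);
  vec d;
  if (symmetrizer(H, d)) {
    mat S = H;
    for (uword i = 0; i < n; ++i)
      for (uword j = 0; j < n; ++j) S(i, j) = d(i) * H(i, j) / d(j);
    S = 0.5 * (S + S.t());
    vec lam;
    mat V;
    eig_sym(lam, V, S);
    mat AD = V.t() * diagmat(nD) * V;
    mat AA = V.t() * diagmat(nA) * V;
    vec w0 = V.t() * (d % pini);
    vec f = V.t() * (pfin / d);
    return propagate_real(lam, AD, AA, w0, f, tau, chan, tail);
  }
  cx_vec lam;
  cx_mat V;
  eig_gen(lam, V, H);
  cx_mat Vi = inv(V);
  cx_mat AD = Vi * diagmat(conv_to<cx_vec>::from(nD)) * V;
  cx_mat AA = Vi * diagmat(conv_to<cx_vec>::from(nA)) * V;
  cx_vec w0 = Vi * conv_to<cx_vec>::from(pini);
  // L = pfin^T V (...) Vi pini = (V^T pfin)^T w; propagate_complex evaluates
  // cdot(f, w) = conj(f)^T w, so pass the conjugate of V^T pfin.
  cx_vec f = conj(V.st() * conv_to<cx_vec>::from(pfin));
  return propagate_complex(lam, AD, AA, w0, f, tau, chan, tail);
}

// Symmetrized eigendecomposition of the three-state chain
//   U <-> I <-> B with rates kon (U->I), kI (I->U and I->B), koff (B->I),
// minus the diagonal photon-rate matrix. Fills lam, V, and the diagonal
// symmetrizer d. H is tridiagonal with positive off-diagonals, so the
// symmetrizer always exists.
static void eig_chain3(double kon, double kI, double koff,
                       const vec& ntot, vec& lam, mat& V, vec& d) {
  // H = K - diag(ntot); K = [[-kon, kI, 0],[kon, -2 kI, koff],[0, kI, -koff]]
  d.set_size(3);
  d(0) = 1.0;
  d(1) = std::sqrt(kon / kI);
  d(2) = d(1) * std::sqrt(kI / koff);
  mat S(3, 3, fill::zeros);
  S(0, 0) = -kon - ntot(0);
  S(1, 1) = -2.0 * kI - ntot(1);
  S(2, 2) = -koff - ntot(2);
  S(0, 1) = S(1, 0) = std::sqrt(kon * kI);
  S(1, 2) = S(2, 1) = std::sqrt(koff * kI);
  eig_sym(lam, V, S);
}

// Delta lnL surface for one transition window (three-state minus two-state).
//
// tau/chan/tail: the window's photon stream; rates: (nDU, nAU, nDB, nAB) in
// photons/s; EB: mean bound-state transfer efficiency used to interpolate
// the intermediate photon rates; tauGrid: intermediate lifetimes (s);
// eGrid: intermediate transfer efficiencies; slow2/slow3: the fixed slow
// association/dissociation rate constants of the two- and three-state
// models (s^-1). Returns list(lnL2, delta) with delta[tau, E].
// [[Rcpp::export]]
Rcpp::List cpp_delta_surface(const arma::vec& tau, const arma::ivec& chan,
                             double tail, const arma::vec& rates, double EB,
                             const arma::vec& tauGrid, const arma::vec& eGrid,
                             double slow2, double slow3) {
  const double nDU = rates(0), nAU = rates(1), nDB = rates(2), nAB = rates(3);

  // two-state reference: K = [[-slow2, slow2],[slow2, -slow2]],
  // p_ini = (1,0), p_fin = (0,1)
  mat K2(2, 2);
  K2(0, 0) = -slow2; K2(0, 1) = slow2;
  K2(1, 0) = slow2;  K2(1, 1) = -slow2;
  vec nD2 = {nDU, nDB}, nA2 = {nAU, nAB};
  vec pini2 = {1.0, 0.0}, pfin2 = {0.0, 1.0};
  double lnL2 = cpp_trace_loglik(tau, chan, K2, nD2, nA2, pini2, pfin2, tail);

  const uword nT = tauGrid.n_elem, nE = eGrid.n_elem;
  mat delta(nT, nE);
  vec lam(3), d(3), ntot(3);
  mat V(3, 3);
  vec pini3 = {1.0, 0.0, 0.0}, pfin3 = {0.0, 0.0, 1.0};
  for (uword ie = 0; ie < nE; ++ie) {
    double frac = eGrid(ie) / EB;  // (E_I - <E_U>)/(<E_B> - <E_U>), <E_U> = 0
    double nDI = nDU + frac * (nDB - nDU);
    double nAI = nAU + frac * (nAB - nAU);
    if (nDI < 0) nDI = 0;
    if (nAI < 0) nAI = 0;
    vec nD3 = {nDU, nDI, nDB}, nA3 = {nAU, nAI, nAB};
    ntot(0) = nDU + nAU; ntot(1) = nDI + nAI; ntot(2) = nDB + nAB;
    for (uword it = 0; it < nT; ++it) {
      double kI = 1.0 / (2.0 * tauGrid(it));
      eig_chain3(slow3, kI, slow3, ntot, lam, V, d);
      mat AD = V.t() * diagmat(nD3) * V;
      mat AA = V.t() * diagmat(nA3) * V;
      vec w0 = V.t() * (d % pini3);
      vec f = V.t() * (pfin3 / d);
      double lnL3 = propagate_real(lam, AD, AA, w0, f, tau, chan, tail);
      delta(it, ie) = lnL3 - lnL2;
    }
  }
  return Rcpp::List::create(Rcpp::Named("lnL2") = lnL2,
                            Rcpp::Named("delta") = delta);
}
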