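// Blocked Gibbs sampler for (multi-response) Gaussian linear mixed models with
// an arbitrary set of random-effect blocks, each carrying a free within-block
// covariance matrix across (trait x effect) combinations.  Coefficients are
// stored trait-major: theta[t*P + j] is the coefficient of design column j for
// response t.  Random blocks may use a parameter-expanded (working-scale)
// update or a plain inverse-Wishart conditional.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

arma::mat safe_inv_sympd(const arma::mat& A) {
  arma::mat Ai;
  arma::mat As = arma::symmatu(A);
  if (!arma::inv_sympd(Ai, As)) {
    As.diag() += 1e-8 * (1.0 + arma::max(arma::abs(As.diag())));
    if (!arma::inv_sympd(Ai, As)) Rcpp::stop("failed to invert a covariance matrix");
  }
  return Ai;
}

// Inverse-Wishart draw via the Bartlett decomposition; uses R's RNG so that
// set.seed() on the R side fully determines the chain.
arma::mat riwish(double nu, const arma::mat& S) {
  const arma::uword d = S.n_rows;
  if (nu <= double(d) - 1.0)
    Rcpp::stop("inverse-Wishart degrees of freedom must exceed dimension - 1");
  arma::mat L = arma::chol(safe_inv_sympd(S), "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (arma::uword i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - double(i)));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return safe_inv_sympd(LA * LA.t());
}

struct Block {
  arma::umat cols;               // m x q design-column index per level/effect
  std::vector<arma::uvec> rows;  // observation rows per level
  int m, q, qT;
  double nu0, alphaV;
  bool px;
  arma::mat S0;                  // qT x qT prior scale
  arma::mat G;                   // current covariance
  arma::vec alpha;               // working scales (parameter expansion)
};

} // namespace

// [[Rcpp::export]]
List gibbs_lmm_cpp(const arma::mat& Y, const arma::mat& W, int p_fixed,
                   List block_list, double beta_var,
                   double nu_resid, const arma::mat& S_resid,
                   const arma::mat& R_init, bool update_resid,
                   int n_iter, int burn_in, int thin, bool save_u) {
  const int n = Y.n_rows;
  const int T = Y.n_cols;
  const int P = W.n_cols;
  const int PT = P * T;

  std::vector<Block> blocks;
  for (int b = 0; b < block_list.size(); ++b) {
    List bl = block_list[b];
    Block blk;
    arma::umat cols1 = as<arma::umat>(bl["cols"]);   // 1-based from R
    blk.cols = cols1 - 1;
    blk.m = blk.cols.n_rows;
    blk.q = blk.cols.n_cols;
    blk.qT = blk.q * T;
    List rws = bl["rows"];
    for (int j = 0; j < rws.size(); ++j)
      blk.rows.push_back(as<arma::uvec>(rws[j]) - 1);
    blk.nu0 = as<double>(bl["nu0"]);
    blk.S0 = as<arma::mat>(bl["S0"]);
    blk.px = as<bool>(bl["px"]);
    blk.alphaV = as<double>(bl["alphaV"]);
    blk.G = arma::eye(blk.qT, blk.qT);
    blk.alpha = arma::ones(blk.qT);
    blocks.push_back(blk);
  }

  // global coefficient index of level j, combined effect k = t*q + e
  auto gidx = [&](const Block& blk, int j, int k) -> arma::uword {
    int t = k / blk.q, e = k % blk.q;
    return arma::uword(t) * P + blk.cols(j, e);
  };

  const arma::mat WtW = W.t() * W;      // P x P
  const arma::mat WtY = W.t() * Y;      // P x T

  arma::vec theta(PT, arma::fill::zeros);
  arma::mat R = R_init;
  arma::mat E = Y;                      // residuals (theta = 0 initially)

  const int n_ret = (n_iter - burn_in) / thin;
  arma::mat beta_out(n_ret, p_fixed * T);
  arma::mat R_out(n_ret, T * T);
  std::vector<arma::mat> G_out, u_out;
  for (size_t b = 0; b < blocks.size(); ++b) {
    G_out.push_back(arma::mat(n_ret, blocks[b].qT * blocks[b].qT));
    u_out.push_back(arma::mat(save_u ? n_ret : 0,
                              save_u ? blocks[b].m * blocks[b].qT : 0));
  }
  arma::vec logpost(n_ret);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    arma::mat Rinv = safe_inv_sympd(R);

    // ---- joint location update (fixed + all random effects) ----
    arma::mat M;
    if (T == 1) M = Rinv(0, 0) * WtW; else M = arma::kron(Rinv, WtW);
    arma::vec bvec(PT, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      arma::vec bt(P, arma::fill::zeros);
      for (int s = 0; s < T; ++s) bt += Rinv(t, s) * WtY.col(s);
      bvec.subvec(t * P, t * P + P - 1) = bt;
      for (int j = 0; j < p_fixed; ++j) M(t * P + j, t * P + j) += 1.0 / beta_var;
    }
    for (size_t b = 0; b < blocks.size(); ++b) {
      Block& blk = blocks[b];
      if (blk.m == 0) continue;
      arma::mat Ginv = safe_inv_sympd(blk.G);
      for (int j = 0; j < blk.m; ++j)
        for (int k1 = 0; k1 < blk.qT; ++k1) {
          arma::uword i1 = gidx(blk, j, k1);
          for (int k2 = 0; k2 < blk.qT; ++k2)
            M(i1, gidx(blk, j, k2)) += Ginv(k1, k2);
        }
    }
    arma::mat Lm;
    if (!arma::chol(Lm, M, "lower")) {
      M.diag() += 1e-8 * (1.0 + arma::max(M.diag()));
      if (!arma::chol(Lm, M, "lower"))
        Rcpp::stop("location update: conditional precision not positive definite at iteration %d", it);
    }
    arma::vec mu = arma::solve(arma::trimatu(Lm.t()),
                               arma::solve(arma::trimatl(Lm), bvec));
    arma::vec z(PT);
    for (int i = 0; i < PT; ++i) z(i) = R::norm_rand();
    theta = mu + arma::solve(arma::trimatu(Lm.t()), z);

    arma::mat Theta(theta.memptr(), P, T, false, true);
    E = Y - W * Theta;

    // ---- residual covariance ----
    if (update_resid && n > 0) {
      R = riwish(nu_resid + n, S_resid + E.t() * E);
      Rinv = safe_inv_sympd(R);
    } else if (update_resid) {
      R = riwish(nu_resid, S_resid);
      Rinv = safe_inv_sympd(R);
    }

    // ---- random-effect covariances (per block) ----
    for (size_t b = 0; b < blocks.size(); ++b) {
      Block& blk = blocks[b];
      const int qT = blk.qT, q = blk.q;
      if (blk.m == 0) {
        if (blk.px) {
          arma::mat Psi = riwish(blk.nu0, blk.S0);
          for (int k = 0; k < qT; ++k) blk.alpha(k) = R::norm_rand() * std::sqrt(blk.alphaV);
          blk.G = arma::diagmat(blk.alpha) * Psi * arma::diagmat(blk.alpha);
        } else {
          blk.G = riwish(blk.nu0, blk.S0);
        }
        continue;
      }
      arma::mat U(blk.m, qT);
      for (int j = 0; j < blk.m; ++j)
        for (int k = 0; k < qT; ++k) U(j, k) = theta(gidx(blk, j, k));

      if (!blk.px) {
        blk.G = riwish(blk.nu0 + blk.m, blk.S0 + U.t() * U);
        continue;
      }

      // parameter expansion: U = V * diag(alpha)
      arma::mat V = U;
      for (int k = 0; k < qT; ++k) {
        double a = blk.alpha(k);
        if (std::abs(a) < 1e-12) a = (a < 0 ? -1e-12 : 1e-12);
        V.col(k) /= a;
      }
      arma::mat Psi = riwish(blk.nu0 + blk.m, blk.S0 + V.t() * V);

      // Gaussian conditional for the working scales alpha:
      // column k of D holds sum_j W[, cols(j, e_k)] * V(j, k), nonzero only on
      // the rows of level j; it predicts response t_k.
      arma::mat D(n, qT, arma::fill::zeros);
      for (int j = 0; j < blk.m; ++j) {
        const arma::uvec& rj = blk.rows[j];
        for (int e = 0; e < q; ++e) {
          arma::vec wcol = W.col(blk.cols(j, e));
          for (int t = 0; t < T; ++t) {
            int k = t * q + e;
            for (arma::uword ii = 0; ii < rj.n_elem; ++ii)
              D(rj(ii), k) += wcol(rj(ii)) * V(j, k);
          }
        }
      }
      arma::mat Ytil = E;
      for (int k = 0; k < qT; ++k) Ytil.col(k / q) += D.col(k) * blk.alpha(k);
      arma::mat DtD = D.t() * D;
      arma::mat DtYt = D.t() * Ytil;   // qT x T
      arma::mat Prec(qT, qT);
      for (int k1 = 0; k1 < qT; ++k1)
        for (int k2 = 0; k2 < qT; ++k2)
          Prec(k1, k2) = Rinv(k1 / q, k2 / q) * DtD(k1, k2);
      Prec.diag() += 1.0 / blk.alphaV;
      arma::vec rhs(qT, arma::fill::zeros);
      for (int k = 0; k < qT; ++k)
        for (int t = 0; t < T; ++t) rhs(k) += Rinv(k / q, t) * DtYt(k, t);
      arma::mat La;
      if (!arma::chol(La, Prec, "lower")) {
        Prec.diag() += 1e-8 * (1.0 + arma::max(Prec.diag()));
        if (!arma::chol(La, Prec, "lower"))
          Rcpp::stop("working-scale update: precision not positive definite at iteration %d", it);
      }
      arma::vec mua = arma::solve(arma::trimatu(La.t()),
                                  arma::solve(arma::trimatl(La), rhs));
      arma::vec za(qT);
      for (int k = 0; k < qT; ++k) za(k) = R::norm_rand();
      arma::vec anew = mua + arma::solve(arma::trimatu(La.t()), za);

      for (int j = 0; j < blk.m; ++j)
        for (int k = 0; k < qT; ++k) theta(gidx(blk, j, k)) = anew(k) * V(j, k);
      blk.G = arma::diagmat(anew) * Psi * arma::diagmat(anew);
      for (int k = 0; k < qT; ++k) Ytil.col(k / q) -= D.col(k) * anew(k);
      E = Ytil;
      blk.alpha = anew;
    }

    // ---- store retained draw ----
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_ret) {
      for (int t = 0; t < T; ++t)
        for (int j = 0; j < p_fixed; ++j)
          beta_out(kept, t * p_fixed + j) = theta(t * P + j);
      for (int t = 0; t < T; ++t)
        for (int s = 0; s < T; ++s) R_out(kept, t * T + s) = R(s, t);
      for (size_t b = 0; b < blocks.size(); ++b) {
        const Block& blk = blocks[b];
        for (int k1 = 0; k1 < blk.qT; ++k1)
          for (int k2 = 0; k2 < blk.qT; ++k2)
            G_out[b](kept, k1 * blk.qT + k2) = blk.G(k2, k1);
        if (save_u)
          for (int j = 0; j < blk.m; ++j)
            for (int k = 0; k < blk.qT; ++k)
              u_out[b](kept, k * blk.m + j) = theta(gidx(blk, j, k));
      }
      double ll = 0.0;
      if (n > 0) {
        double ldet, sgn;
        arma::log_det(ldet, sgn, R);
        arma::mat Rinv2 = safe_inv_sympd(R);
        ll = -0.5 * (n * T * std::log(2.0 * M_PI) + n * ldet +
                     arma::trace(Rinv2 * (E.t() * E)));
      }
      logpost(kept) = ll;
      ++kept;
    }
  }

  List Gl(G_out.size()), Ul(u_out.size());
  for (size_t b = 0; b < G_out.size(); ++b) { Gl[b] = G_out[b]; Ul[b] = u_out[b]; }
  return List::create(_["beta"] = beta_out, _["R"] = R_out, _["G"] = Gl,
                      _["u"] = Ul, _["loglik"] = logpost, _["retained"] = kept);
}
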