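// Batched objective for the full flux-temperature mortality model.
//
// The parameter vector theta (length 8 + n) is unconstrained:
//   [0]        log a_h
//   [1]        b_h
//   [2 .. n+1] log rho0_i
//   [n+2]      log kappa_e
//   [n+3]      log d0_e
//   [n+4]      logit mu
//   [n+5]      log a_beta
//   [n+6]      b_beta
//   [n+7]      log gamma
//
// Only {kappa_e, d0_e, a_beta, b_beta, gamma} enter the SIR pass, so the
// central-difference gradient re-runs the epidemics for 5 parameters only
// and reuses the cached R(30) for the rest.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

struct ModelData {
  vec pop, gdp;
  mat dist, commuters;     // n x n, entry [i][j] = flow j -> i
  mat temps, counts;       // n x B batch slices
  uvec i0;                 // 0-based patient-zero index per batch month
  double flux_lo, flux_hi, flux_stiffness, d0e_coeff;
  double upsilon;          // correlation-regularizer weight (0 => off)
  bool phase2;
  double dt;
  int n_steps_sir;
};

struct Unpacked {
  double a_h, b_h, kappa_e, d0_e, mu, a_beta, b_beta, gamma;
  vec rho0;
};

static Unpacked unpack(const vec &theta, int n) {
  Unpacked p;
  p.a_h = std::exp(theta(0));
  p.b_h = theta(1);
  p.rho0 = exp(theta.subvec(2, n + 1));
  p.kappa_e = std::exp(theta(n + 2));
  p.d0_e = std::exp(theta(n + 3));
  p.mu = 1.0 / (1.0 + std::exp(-theta(n + 4)));
  p.a_beta = std::exp(theta(n + 5));
  p.b_beta = theta(n + 6);
  p.gamma = std::exp(theta(n + 7));
  return p;
}

// total flux (commuter + episodic) for given episodic parameters
static mat total_flux_of(const Unpacked &p, const ModelData &d) {
  const int n = d.pop.n_elem;
  mat e = p.kappa_e * (d.gdp * d.pop.t()) % exp(-d.dist / p.d0_e);
  e.diag().zeros();
  mat f = d.commuters + e;
  f.diag().zeros();
  return f;
}

// Run the monthly-restarting SIR for every batch month; returns R(30) (n x B).
static mat run_sir_batch(const Unpacked &p, const ModelData &d, int &clamped) {
  const int n = d.pop.n_elem;
  const int B = d.temps.n_cols;
  mat f = total_flux_of(p, d);
  vec outflow = sum(f, 0).t() / d.pop;       // column sums / pop_j
  mat phi = f.each_row() / d.pop.t();
  phi.diag() = 1.0 - outflow;
  vec row_tot = sum(phi, 1);
  for (int i = 0; i < n; ++i) if (std::abs(row_tot(i)) < 1e-12) row_tot(i) = 1e-12;
  mat phi_hat = (phi.each_col() / row_tot).t();   // phi_hat[i][j] = phi[j][i]/rowsum_j

  const double beta_cap = (1.0 - 1e-9) / d.dt;
  mat beta = exp(-p.a_beta * d.temps + p.b_beta);
  beta.transform([beta_cap](double b) { return b > beta_cap ? beta_cap : b; });

  mat S(n, B), I(n, B, fill::zeros), R(n, B, fill::zeros);
  S.each_col() = d.pop;
  for (int b = 0; b < B; ++b) {
    S(d.i0(b), b) -= 1.0;
    I(d.i0(b), b) = 1.0;
  }
  for (int t = 0; t < d.n_steps_sir; ++t) {
    mat s_pool = phi * S;
    mat i_pool = phi * I;
    mat dI_pool = beta % s_pool % i_pool;
    dI_pool.each_col() /= d.pop;
    mat dI = phi_hat * dI_pool;
    S -= d.dt * dI;
    R += d.dt * p.gamma * I;
    I += d.dt * (dI - p.gamma * I);
    uvec negS = find(S < 0), negI = find(I < 0);
    clamped += negS.n_elem + negI.n_elem;
    S.elem(negS).zeros();
    I.elem(negI).zeros();
  }
  return R;
}

static mat lambda_of(const Unpacked &p, const ModelData &d, const mat &R30) {
  mat lam = exp(p.a_h * d.temps + p.b_h);
  lam.each_col() %= d.pop;
  lam.each_col() += p.rho0;
  lam += p.mu * R30;
  return lam;
}

// objective components given a cached R(30)
static Rcpp::List eval_components(const vec &theta, const ModelData &d,
                                  const mat &R30, const mat &corr0) {
  const int n = d.pop.n_elem;
  const int B = d.temps.n_cols;
  Unpacked p = unpack(theta, n);
  mat lam = lambda_of(p, d, R30);
  if (lam.min() <= 0 || !lam.is_finite())
    Rcpp::stop("non-positive or non-finite Poisson mean in objective");

  double ll = accu(d.counts % log(lam) - lam) / (double)(n * B);

  mat f = total_flux_of(p, d);
  vec outflow = sum(f, 0).t() / d.pop;
  double prior_flux = 0.0;
  for (int j = 0; j < n; ++j) {
    double ex = 0.0;
    if (outflow(j) > d.flux_hi) ex = outflow(j) - d.flux_hi;
    else if (outflow(j) < d.flux_lo) ex = d.flux_lo - outflow(j);
    prior_flux -= d.flux_stiffness * ex * ex;
  }
  double prior_d0e = -d.d0e_coeff * p.d0_e * p.d0_e;

  double corr_pen = 0.0;
  int skipped = 0;
  if (d.phase2 && d.upsilon > 0.0) {
    mat lam_c = lam.each_col() - mean(lam, 1);
    vec lam_sd = sqrt(sum(square(lam_c), 1));
    double n_pairs = n * (n - 1) / 2.0;
    for (int i = 1; i < n; ++i) {
      for (int j = 0; j < i; ++j) {
        if (lam_sd(i) <= 0 || lam_sd(j) <= 0 || !std::isfinite(corr0(i, j))) {
          ++skipped;
          continue;
        }
        double cm = dot(lam_c.row(i), lam_c.row(j)) / (lam_sd(i) * lam_sd(j));
        double diff = cm - corr0(i, j);
        corr_pen -= diff * diff;
      }
    }
    corr_pen *= d.upsilon / n_pairs;
  }

  double value = ll + prior_flux + prior_d0e + corr_pen;
  return Rcpp::List::create(
    Rcpp::Named("value") = value,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("prior_flux") = prior_flux,
    Rcpp::Named("prior_d0e") = prior_d0e,
    Rcpp::Named("corr_pen") = corr_pen,
    Rcpp::Named("skipped_pairs") = skipped);
}

static mat batch_corr(const mat &x) {
  // Pearson correlations between rows; NaN rows flagged with NaN entries
  const int n = x.n_rows;
  mat xc = x.each_col() - mean(x, 1);
  vec sd = sqrt(sum(square(xc), 1));
  mat out(n, n, fill::ones);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < i; ++j) {
      double v = (sd(i) > 0 && sd(j) > 0)
        ? dot(xc.row(i), xc.row(j)) / (sd(i) * sd(j))
        : datum::nan;
      out(i, j) = out(j, i) = v;
    }
  return out;
}

static ModelData build_data(const arma::vec &pop, const arma::vec &gdp,
                            const arma::mat &dist, const arma::mat &commuters,
                            const arma::mat &temps, const arma::mat &counts,
                            const arma::uvec &i0_1based, bool phase2,
                            double upsilon, double flux_lo, double flux_hi,
                            double flux_stiffness, double d0e_coeff,
                            double dt, int n_steps_sir) {
  ModelData d;
  d.pop = pop; d.gdp = gdp; d.dist = dist; d.commuters = commuters;
  d.temps = temps; d.counts = counts;
  d.i0 = i0_1based - 1;
  d.phase2 = phase2; d.upsilon = upsilon;
  d.flux_lo = flux_lo; d.flux_hi = flux_hi;
  d.flux_stiffness = flux_stiffness; d.d0e_coeff = d0e_coeff;
  d.dt = dt; d.n_steps_sir = n_steps_sir;
  return d;
}

// [[Rcpp::export]]
Rcpp::List cpp_batch_objective(const arma::vec &theta, const arma::vec &pop,
                               const arma::vec &gdp, const arma::mat &dist,
                               const arma::mat &commuters, const arma::mat &temps,
                               const arma::mat &counts, const arma::uvec &i0,
                               bool phase2, double upsilon, double flux_lo,
                               double flux_hi, double flux_stiffness,
                               double d0e_coeff, double dt = 1.0,
                               int n_steps_sir = 30) {
  ModelData d = build_data(pop, gdp, dist, commuters, temps, counts, i0,
                           phase2, upsilon, flux_lo, flux_hi, flux_stiffness,
                           d0e_coeff, dt, n_steps_sir);
  int clamped = 0;
  Unpacked p = unpack(theta, pop.n_elem);
  mat R30 = run_sir_batch(p, d, clamped);
  mat corr0 = batch_corr(d.counts);
  Rcpp::List out = eval_components(theta, d, R30, corr0);
  out["clamped"] = clamped;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_objective_grad(const arma::vec &theta, const arma::vec &pop,
                              const arma::vec &gdp, const arma::mat &dist,
                              const arma::mat &commuters, const arma::mat &temps,
                              const arma::mat &counts, const arma::uvec &i0,
                              bool phase2, double upsilon, double flux_lo,
                              double flux_hi, double flux_stiffness,
                              double d0e_coeff, double dt = 1.0,
                              int n_steps_sir = 30, double fd_h = 1e-5) {
  const int n = pop.n_elem;
  const int np = theta.n_elem;
  ModelData d = build_data(pop, gdp, dist, commuters, temps, counts, i0,
                           phase2, upsilon, flux_lo, flux_hi, flux_stiffness,
                           d0e_coeff, dt, n_steps_sir);
  mat corr0 = batch_corr(d.counts);

  int clamped = 0;
  Unpacked p0 = unpack(theta, n);
  mat R30 = run_sir_batch(p0, d, clamped);
  Rcpp::List base = eval_components(theta, d, R30, corr0);
  double f0 = base["value"];

  std::vector<bool> sir_par(np, false);
  sir_par[n + 2] = sir_par[n + 3] = sir_par[n + 5] = sir_par[n + 6] = sir_par[n + 7] = true;

  vec grad(np);
  for (int k = 0; k < np; ++k) {
    double h = fd_h * std::max(1.0, std::abs(theta(k)));
    vec tp = theta, tm = theta;
    tp(k) += h; tm(k) -= h;
    double fp, fm;
    if (sir_par[k]) {
      int c2 = 0;
      mat Rp = run_sir_batch(unpack(tp, n), d, c2);
      mat Rm = run_sir_batch(unpack(tm, n), d, c2);
      fp = Rcpp::as<double>(eval_components(tp, d, Rp, corr0)["value"]);
      fm = Rcpp::as<double>(eval_components(tm, d, Rm, corr0)["value"]);
    } else {
      fp = Rcpp::as<double>(eval_components(tp, d, R30, corr0)["value"]);
      fm = Rcpp::as<double>(eval_components(tm, d, R30, corr0)["value"]);
    }
    grad(k) = (fp - fm) / (2.0 * h);
  }
  if (!grad.is_finite() || !std::isfinite(f0))
    Rcpp::stop("non-finite objective or gradient");

  return Rcpp::List::create(
    Rcpp::Named("value") = f0,
    Rcpp::Named("loglik") = base["loglik"],
    Rcpp::Named("prior_flux") = base["prior_flux"],
    Rcpp::Named("prior_d0e") = base["prior_d0e"],
    Rcpp::Named("corr_pen") = base["corr_pen"],
    Rcpp::Named("grad") = grad,
    Rcpp::Named("clamped") = clamped);
}

// Final R(30) for a set of (month, patient-zero) pairs under given natural
// parameters; used for fast expectation-over-i0 predictions.
// [[Rcpp::export]]
arma::mat cpp_sir_r30(const arma::vec &pop, const arma::mat &flux_total,
                      const arma::mat &temps, const arma::uvec &i0,
                      double a_beta, double b_beta, double gamma,
                      double dt = 1.0, int n_steps_sir = 30) {
  ModelData d;
  d.pop = pop;
  d.commuters = flux_total;   // treat as the whole flux; episodic off
  d.dist = arma::mat(pop.n_elem, pop.n_elem, fill::ones);
  d.gdp = pop;
  d.temps = temps;
  d.i0 = i0 - 1;
  d.dt = dt; d.n_steps_sir = n_steps_sir;
  Unpacked p;
  p.kappa_e = 0.0; p.d0_e = 1.0;
  p.a_beta = a_beta; p.b_beta = b_beta; p.gamma = gamma;
  int clamped = 0;
  return run_sir_batch(p, d, clamped);
}
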