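#include <Rcpp.h>
using namespace Rcpp;

// Euler integration core for the category-cell network driven by
// stripe-cell path integration. All populations advance in lock-step;
// recurrent inhibition acts only within a population. Uses R's RNG so
// results are reproducible from set.seed().
//
// variant: 0 = base, 1 = v1 (gate on bottom-up + on-center, total weight 2),
//          2 = v2 (output/inhibitory signals gated by z).
// [[Rcpp::export]]
List run_trial_cpp(NumericVector speed, NumericVector heading, double dt,
                   NumericVector dir_rad, IntegerVector cell_dir,
                   NumericVector psi, NumericVector lambda,
                   NumericVector sigma, NumericVector omega,
                   NumericMatrix W_in, IntegerVector pop_id,
                   NumericVector beta, NumericVector eps,
                   double A, double B, double C, double D_inh,
                   double gamma, double Gamma, double lambda_w, double mu,
                   double sigma_noise, int variant, bool learn) {
  const int nt = speed.size();
  const int nd = dir_rad.size();
  const int ns = psi.size();
  const int nc = W_in.ncol();
  if (W_in.nrow() != ns) stop("weight matrix rows must match stripe cells");
  int npop = 0;
  for (int i = 0; i < nc; ++i) if (pop_id[i] + 1 > npop) npop = pop_id[i] + 1;

  NumericMatrix W = clone(W_in);
  NumericVector V(nc), z(nc, 1.0);
  NumericVector D(nd);                      // per-direction displacement
  NumericMatrix log(nt, nc);
  std::vector<double> S(ns), f(nc), out(nc), bu(nc), colsum(nc, 0.0);
  std::vector<double> Ftot(npop);
  const bool noisy = sigma_noise > 0;
  const double noise_sd = sigma_noise * std::sqrt(dt);
  RNGScope scope;

  if (variant == 1) {
    for (int i = 0; i < nc; ++i) {
      double cs = 0.0;
      for (int k = 0; k < ns; ++k) cs += W(k, i);
      colsum[i] = cs;
    }
  }

  for (int t = 0; t < nt; ++t) {
    // stripe activities at the current displacement
    for (int k = 0; k < ns; ++k) {
      double q = (D[cell_dir[k]] - psi[k]) / lambda[k];
      double r = (q - std::floor(q)) * lambda[k];   // in [0, lambda)
      if (r > lambda[k] / 2) r -= lambda[k];
      S[k] = omega[k] * std::exp(-r * r / (2 * sigma[k] * sigma[k]));
    }
    double Stot = 0.0;
    for (int k = 0; k < ns; ++k) Stot += S[k];

    // signals from the current state
    std::fill(Ftot.begin(), Ftot.end(), 0.0);
    for (int i = 0; i < nc; ++i) {
      f[i] = V[i] > Gamma ? V[i] - Gamma : 0.0;
      out[i] = (variant == 2) ? f[i] * z[i] : f[i];
      Ftot[pop_id[i]] += out[i];
      double b = 0.0;
      const double *w = &W(0, i);
      for (int k = 0; k < ns; ++k) b += w[k] * S[k];
      bu[i] = b;
    }

    // coupled Euler step of V and z
    for (int i = 0; i < nc; ++i) {
      double E, G;
      if (variant == 1) {
        E = z[i] * (bu[i] + gamma * f[i]);
        G = bu[i] + gamma * f[i];
      } else {
        E = bu[i] + gamma * f[i] * z[i];
        G = gamma * f[i];
      }
      double inh = Ftot[pop_id[i]] - out[i];
      double dV = beta[i] * (-A * V[i] + (B - V[i]) * E -
                             (C + V[i]) * D_inh * inh);
      double dz = eps[i] * ((1.0 - z[i]) - mu * z[i] * G * G);
      log(t, i) = out[i];
      V[i] += dt * dV;
      if (noisy) V[i] += R::rnorm(0.0, noise_sd);
      z[i] += dt * dz;
    }

    // instar learning, gated by the (possibly z-gated) output signal
    if (learn) {
      for (int i = 0; i < nc; ++i) {
        double g = out[i];
        if (g <= 0) continue;
        double *w = &W(0, i);
        double rate = lambda_w * g * dt;
        if (variant == 1) {
          double avail = 2.0 - colsum[i];
          double cs = 0.0;
          for (int k = 0; k < ns; ++k) {
            w[k] += rate * (S[k] * avail - w[k] * (Stot - S[k]));
            cs += w[k];
          }
          colsum[i] = cs;
        } else {
          for (int k = 0; k < ns; ++k)
            w[k] += rate * (S[k] - w[k] * Stot);
        }
      }
    }

    // path-integrate for the next sample
    for (int d = 0; d < nd; ++d)
      D[d] += speed[t] * std::cos(heading[t] - dir_rad[d]) * dt;
  }

  return List::create(_["W"] = W, _["V"] = V, _["z"] = z,
                      _["D"] = D, _["log"] = log);
}

// Single cell driven by an arbitrary bottom-up/current input vector, with
// self-excitatory feedback (gain gamma; 0 disables) that is habituatively
// gated unless `gated` is false (z then stays pinned at 1 in the feedback
// term while still being integrated). No recurrent inhibition.
// [[Rcpp::export]]
List inject_current_cpp(NumericVector input, double beta, double eps,
                        double A, double B, double gamma, double Gamma,
                        double mu, double sigma_noise, double dt,
                        bool gated) {
  const int nt = input.size();
  NumericVector V(nt), zout(nt);
  double v = 0.0, z = 1.0;
  const bool noisy = sigma_noise > 0;
  const double noise_sd = sigma_noise * std::sqrt(dt);
  RNGScope scope;
  for (int t = 0; t < nt; ++t) {
    V[t] = v; zout[t] = z;
    double f = v > Gamma ? v - Gamma : 0.0;
    double gate = gated ? z : 1.0;
    double E = input[t] + gamma * f * gate;
    double G = gamma * f;
    double dV = beta * (-A * v + (B - v) * E);
    double dz = eps * ((1.0 - z) - mu * z * G * G);
    v += dt * dV;
    if (noisy) v += R::rnorm(0.0, noise_sd);
    z += dt * dz;
  }
  return List::create(_["V"] = V, _["z"] = zout);
}
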