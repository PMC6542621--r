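#include <Rcpp.h>
using namespace Rcpp;

static inline double clip01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// Explicit-Euler integration of one stimulation phase of the plastic
// recurrent network.  The update is fully simultaneous: all derivatives are
// evaluated on the pre-step state.  Uses the R RNG, so runs are reproducible
// under set.seed().
//
// mode 0: every neuron receives iid tuning noise through n_pex input neurons
//         (each draw N(noise_mean, noise_sd) clipped to [0,1]).
// mode 1: population neurons receive Ornstein-Uhlenbeck input through their
//         input-layer block (Fex, length 2*n_pex); background neurons keep
//         the tuning-noise drive.
//
// Population-averaged samples (13 columns: t, F1, F2, FB, w11, w22, w21,
// w12, wB_mean, inh_11, inh_22, inh_12, inh_21) are recorded every
// sample_every steps.
// [[Rcpp::export]]
List simulate_phase_cpp(NumericVector F0, NumericMatrix W0, NumericMatrix Winh0,
                        NumericVector Fex0, IntegerVector pop_id,
                        int nsteps, double dt, double t0, int mode,
                        double noise_mean, double noise_sd,
                        NumericVector ou_means, double ou_delta,
                        double ou_sigma, double ou_h,
                        int n_pex, double w_ex,
                        double K, double beta_eps, double tau, double tau_w,
                        double F_T,
                        bool inh_plastic, double theta_u, double theta_d,
                        double theta_F, double delta_F,
                        double rho_u, double rho_d,
                        int sample_every) {
  const int n = F0.size();
  NumericVector F = clone(F0), Fex = clone(Fex0), Fnew(n), g(n), ext(n);
  NumericMatrix W = clone(W0), Winh = clone(Winh0);

  const double inv_tau = 1.0 / tau, inv_tw = 1.0 / tau_w;
  const double scale_fac = 1.0 / (1.0 - F_T);
  const int nsamp = nsteps / sample_every;
  NumericMatrix samples(nsamp, 13);
  int isamp = 0;

  // class index bounds (contiguous blocks: pop1, pop2, background)
  int n_P = 0;
  for (int i = 0; i < n; ++i) if (pop_id[i] == 1) ++n_P;
  const int b0 = 2 * n_P;              // first background index
  const int nB = n - b0;

  const double ou_drift = ou_delta * ou_h;
  const double ou_diff  = ou_sigma * std::sqrt(ou_h);

  for (int s = 0; s < nsteps; ++s) {
    // ---- external inputs ----
    if (mode == 1) {
      for (int k = 0; k < 2 * n_pex; ++k) {
        double target = (k < n_pex) ? ou_means[0] : ou_means[1];
        Fex[k] = clip01(Fex[k] + ou_drift * (target - Fex[k]) +
                        ou_diff * R::norm_rand());
      }
      double e1 = 0.0, e2 = 0.0;
      for (int k = 0; k < n_pex; ++k) e1 += Fex[k];
      for (int k = n_pex; k < 2 * n_pex; ++k) e2 += Fex[k];
      for (int i = 0; i < b0; ++i)
        ext[i] = w_ex * ((pop_id[i] == 1) ? e1 : e2);
      for (int i = b0; i < n; ++i) {
        double sum = 0.0;
        for (int k = 0; k < n_pex; ++k)
          sum += clip01(noise_mean + noise_sd * R::norm_rand());
        ext[i] = w_ex * sum;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        double sum = 0.0;
        for (int k = 0; k < n_pex; ++k)
          sum += clip01(noise_mean + noise_sd * R::norm_rand());
        ext[i] = w_ex * sum;
      }
    }

    // ---- drives (column-major traversal) ----
    {
      double *pg = REAL(g), *pW = REAL(W), *pWi = REAL(Winh), *pF = REAL(F);
      for (int i = 0; i < n; ++i) pg[i] = 0.0;
      if (inh_plastic) {
        for (int j = 0; j < n; ++j) {
          const double Fj = pF[j];
          const double *wc = pW + (size_t)j * n, *ic = pWi + (size_t)j * n;
          for (int i = 0; i < n; ++i) pg[i] += (wc[i] - ic[i]) * Fj;
        }
      } else {
        // static inhibition: Winh is constant, subtract theta * sum(F)
        double sF = 0.0;
        for (int j = 0; j < n; ++j) sF += pF[j];
        const double inh = pWi[0] * sF;
        for (int j = 0; j < n; ++j) {
          const double Fj = pF[j];
          const double *wc = pW + (size_t)j * n;
          for (int i = 0; i < n; ++i) pg[i] += wc[i] * Fj;
        }
        for (int i = 0; i < n; ++i) pg[i] -= inh;
      }
      for (int i = 0; i < n; ++i) pg[i] = K * (pg[i] + ext[i]);
    }

    // ---- activity update (from pre-step state) ----
    for (int i = 0; i < n; ++i) {
      double Fi = F[i];
      double dF = inv_tau * (1.0 - Fi) * Fi *
        (std::log(1.0 / Fi - 1.0) + g[i] - beta_eps);
      double x = Fi + dt * dF;
      if (x < 1e-6) x = 1e-6;
      if (x > 1.0 - 1e-6) x = 1.0 - 1e-6;
      Fnew[i] = x;
    }

    // ---- weight updates (from pre-step rates) ----
    if (inh_plastic) {
      double *pWi = REAL(Winh), *pF = REAL(F);
      const double c = dt * inv_tw;
      for (int j = 0; j < n; ++j) {
        const double Fj = pF[j];
        double *ic = pWi + (size_t)j * n;
        for (int i = 0; i < n; ++i) {
          const double Fi = pF[i];
          const double SF = Fi + Fj, DF = std::fabs(Fi - Fj);
          double drv = 0.0;
          if (DF > delta_F || SF < theta_F)
            drv = rho_u * (theta_u - ic[i]);
          else if (DF < delta_F && SF > theta_F)
            drv = rho_d * (theta_d - ic[i]);
          ic[i] += c * Fi * Fj * drv;
        }
      }
    }
    {
      double *pW = REAL(W), *pF = REAL(F);
      const double c = dt * inv_tw;
      for (int j = 0; j < n; ++j) {
        const double Fj = pF[j];
        double *wc = pW + (size_t)j * n;
        for (int i = 0; i < n; ++i) {
          const double Fi = pF[i];
          double w = wc[i];
          w += c * (Fi * Fj + (F_T - Fi) * scale_fac * w * w);
          wc[i] = (w > 0.0) ? w : 0.0;
        }
      }
    }
    for (int i = 0; i < n; ++i) F[i] = Fnew[i];

    if (!std::isfinite(F[0]) || !std::isfinite(W(0, 0)))
      stop("non-finite values during integration at t = %f",
           t0 + (s + 1) * dt);

    // ---- sampling ----
    if ((s + 1) % sample_every == 0 && isamp < nsamp) {
      double F1 = 0, F2 = 0, FB = 0;
      for (int i = 0; i < n_P; ++i) F1 += F[i];
      for (int i = n_P; i < b0; ++i) F2 += F[i];
      for (int i = b0; i < n; ++i) FB += F[i];
      double w11 = 0, w22 = 0, w21 = 0, w12 = 0, wB = 0;
      double i11 = 0, i22 = 0, i12 = 0, i21 = 0;
      for (int j = 0; j < n_P; ++j)
        for (int i = 0; i < n_P; ++i) {
          w11 += W(i, j); i11 += Winh(i, j);
        }
      for (int j = n_P; j < b0; ++j)
        for (int i = n_P; i < b0; ++i) {
          w22 += W(i, j); i22 += Winh(i, j);
        }
      for (int j = 0; j < n_P; ++j)       // pre in 1, post in 2
        for (int i = n_P; i < b0; ++i) {
          w21 += W(i, j); i21 += Winh(i, j);
        }
      for (int j = n_P; j < b0; ++j)      // pre in 2, post in 1
        for (int i = 0; i < n_P; ++i) {
          w12 += W(i, j); i12 += Winh(i, j);
        }
      for (int j = b0; j < n; ++j)        // pre in background, post in pops
        for (int i = 0; i < b0; ++i) wB += W(i, j);
      double nP2 = (double)n_P * n_P;
      samples(isamp, 0) = t0 + (s + 1) * dt;
      samples(isamp, 1) = F1 / n_P;
      samples(isamp, 2) = F2 / n_P;
      samples(isamp, 3) = nB > 0 ? FB / nB : NA_REAL;
      samples(isamp, 4) = w11 / nP2;
      samples(isamp, 5) = w22 / nP2;
      samples(isamp, 6) = w21 / nP2;
      samples(isamp, 7) = w12 / nP2;
      samples(isamp, 8) = nB > 0 ? wB / (2.0 * n_P * nB) : NA_REAL;
      samples(isamp, 9)  = i11 / nP2;
      samples(isamp, 10) = i22 / nP2;
      samples(isamp, 11) = i12 / nP2;
      samples(isamp, 12) = i21 / nP2;
      ++isamp;
    }
  }

  return List::create(_["F"] = F, _["W"] = W, _["W_inh"] = Winh,
                      _["F_ex"] = Fex, _["t"] = t0 + nsteps * dt,
                      _["samples"] = samples);
}
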