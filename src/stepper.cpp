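#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step integration of the compartmentalized Fenton / photo-Fenton model.
//
// State layout per compartment (columns of `state0`), all mol L^-1:
//   0 fe2, 1 fe3, 2 h2o2, 3 oh (HO*), 4..4+F organics (target, f1..fF),
//   5+F mineralized carbon (mol-C L^-1), 6+F inert sink (HO2* bookkeeping).
// Clamped species (H+, OH-, H2O, O2) are held outside the integrated state.
//
// Each step, per compartment: raw rates -> competitive normalization of the
// HO*-consuming set -> availability clamp (no consumption may exceed the
// current amount in one step) -> explicit update; then the oxidant feed and
// the cyclic advective exchange. This ordering is part of the scheme and is
// mirrored by the R reference implementation plant_step().

// [[Rcpp::export]]
List simulate_plant_cpp(NumericMatrix state0,
                        NumericVector volumes,
                        double flow,          // L s^-1
                        int irr_comp,         // 1-based; 0 = dark
                        double k0, double k1, double k2, double kelim,
                        double ktarget, double kfragment,
                        NumericVector fnc,    // F+1 fictitious carbon numbers
                        double mult,          // product multiplicity (2 or 1)
                        int feed_comp,        // 1-based
                        double feed_mol,      // total H2O2 fed, mol
                        double feed_dur,      // s
                        double dt,            // s
                        int n_steps,
                        IntegerVector rec_steps,  // 0-based step indices
                        int literal_norm) {
  const int ncomp = state0.nrow();
  const int nspec = state0.ncol();
  const int F = fnc.size() - 1;
  const int i_min = 5 + F, i_sink = 6 + F;
  if (nspec != 7 + F) stop("state has %d columns, mechanism needs %d", nspec, 7 + F);
  const int nrec = rec_steps.size();

  NumericMatrix S(clone(state0));
  NumericVector out(nrec * ncomp * nspec);
  std::vector<double> rb(F + 1), forg(F + 1);
  long clamped_steps = 0;
  int rec_ptr = 0;

  for (int s = 0; s <= n_steps; ++s) {
    while (rec_ptr < nrec && rec_steps[rec_ptr] == s) {
      for (int i = 0; i < ncomp; ++i)
        for (int j = 0; j < nspec; ++j)
          out[rec_ptr + nrec * (i + ncomp * j)] = S(i, j);
      ++rec_ptr;
    }
    if (s == n_steps) break;
    double t = s * dt;
    bool clamped = false;

    // reaction update (per compartment, from the common pre-step state)
    for (int i = 0; i < ncomp; ++i) {
      double fe2 = S(i, 0), fe3 = S(i, 1), h2o2 = S(i, 2), oh = S(i, 3);
      double r1 = k1 * fe3 * h2o2;
      double r2 = k2 * fe2 * h2o2;
      double r0 = (i + 1 == irr_comp) ? k0 * fe3 : 0.0;
      double relim = kelim * oh;
      double rbsum = 0.0;
      for (int b = 0; b <= F; ++b) {
        double kb = (b == 0) ? ktarget : kfragment;
        rb[b] = kb * S(i, 4 + b) * oh;
        rbsum += rb[b];
      }
      if (literal_norm) {
        double tot = relim + rbsum;
        if (tot > 0.0) {
          relim = relim * relim / tot;
          rbsum = 0.0;
          for (int b = 0; b <= F; ++b) { rb[b] = rb[b] * rb[b] / tot; rbsum += rb[b]; }
        }
      }
      // availability clamp: scale every reaction consuming species s by
      // min(1, c_s / (dt * total consumption of s))
      auto avail = [&](double c, double cons) {
        if (cons <= 0.0) return 1.0;
        double f = c / (dt * cons);
        if (f < 1.0) { clamped = true; return f; }
        return 1.0;
      };
      double f_fe3 = avail(fe3, r1 + r0);
      double f_fe2 = avail(fe2, r2);
      double f_h   = avail(h2o2, r1 + r2);
      double f_oh  = avail(oh, relim + rbsum);
      r1 *= std::min(f_fe3, f_h);
      r0 *= f_fe3;
      r2 *= std::min(f_fe2, f_h);
      relim *= f_oh;
      rbsum = 0.0;
      for (int b = 0; b <= F; ++b) {
        forg[b] = avail(S(i, 4 + b), rb[b]);
        rb[b] *= std::min(f_oh, forg[b]);
        rbsum += rb[b];
      }

      double d_fe3 = r2 - r1 - r0;
      S(i, 0) = fe2 - dt * d_fe3;
      S(i, 1) = fe3 + dt * d_fe3;
      S(i, 2) = h2o2 + dt * (-r1 - r2);
      S(i, 3) = oh + dt * (r2 + r0 - relim - rbsum);
      S(i, 4) -= dt * rb[0];
      for (int b = 1; b <= F; ++b) S(i, 4 + b) += dt * (mult * rb[b - 1] - rb[b]);
      S(i, i_min) += dt * fnc[F] * rb[F];
      S(i, i_sink) += dt * r1;   // HO2* routed to an inert cumulative sink
      for (int j = 0; j < nspec; ++j) if (S(i, j) < 0.0) S(i, j) = 0.0;
    }
    if (clamped) ++clamped_steps;

    // finite-time oxidant feed into the feed compartment
    if (feed_mol > 0.0 && t < feed_dur)
      S(feed_comp - 1, 2) += dt * (feed_mol / feed_dur) / volumes[feed_comp - 1];

    // cyclic advective exchange, computed from the post-reaction state
    {
      std::vector<double> col(ncomp);
      for (int j = 0; j < nspec; ++j) {
        for (int i = 0; i < ncomp; ++i) col[i] = S(i, j);
        for (int i = 0; i < ncomp; ++i) {
          int prev = (i == 0) ? ncomp - 1 : i - 1;
          S(i, j) = col[i] + flow * dt * (col[prev] - col[i]) / volumes[i];
        }
      }
    }
  }

  out.attr("dim") = IntegerVector::create(nrec, ncomp, nspec);
  return List::create(_["states"] = out,
                      _["clamped_steps"] = (double)clamped_steps,
                      _["n_steps"] = (double)n_steps);
}
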