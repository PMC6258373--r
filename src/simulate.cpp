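#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-step point-neuron network simulation with two synapse models.
//
// model 0 ("instantaneous"): per-cell activation m decays with tau_m; each
//   applied event adds its (signed) amount; spike when m >= 1, reset to 0.
// model 1 ("kinetic"): excitatory drive e follows a single exponential
//   (tau_e), inhibitory drive a difference of exponentials (rise tau_i1,
//   decay tau_i2, peak-normalized); the membrane v integrates the drives
//   with tau_m (exact linear propagation per step); spike when v >= 1.
//
// Both models share a 3 ms refractory period during which arriving events
// are discarded (counted in the audit) and the state is clamped at reset.
//
// Recurrent spikes are delivered after a constant delay through a ring
// buffer; external events (LGN, background, perturbation sources) arrive
// pre-binned at their arrival step, sorted ascending.
// [[Rcpp::export]]
List simulate_cpp(IntegerVector ei, NumericVector tau_m,
                  double t_stop, double dt, double refractory, double delay,
                  int model,
                  IntegerVector rec_ptr, IntegerVector rec_tgt, NumericVector rec_w,
                  IntegerVector ext_step, IntegerVector ext_tgt,
                  NumericVector ext_w, IntegerVector ext_lgn,
                  NumericVector kin_tau, // tau_e, tau_i1, tau_i2 for E then I targets
                  double analysis_start) {
  const int n = ei.size();
  const int nsteps = (int)std::ceil(t_stop / dt);
  const int dsteps = std::max(1, (int)std::lround(delay / dt));
  const int rsteps = (int)std::lround(refractory / dt);
  const int ring_n = dsteps + 1;

  std::vector<double> em(n), ke(n), ka(n), kb(n), de(n), da(n), db(n), fi(n);
  for (int c = 0; c < n; ++c) {
    em[c] = std::exp(-dt / tau_m[c]);
    if (model == 1) {
      const int cls = ei[c];
      const double te = kin_tau[3 * cls], t1 = kin_tau[3 * cls + 1], t2 = kin_tau[3 * cls + 2];
      const double Ee = std::exp(-dt / te), Ea = std::exp(-dt / t1), Eb = std::exp(-dt / t2);
      de[c] = Ee; da[c] = Ea; db[c] = Eb;
      ke[c] = (Ee - em[c]) / (1.0 / tau_m[c] - 1.0 / te);
      ka[c] = (Ea - em[c]) / (1.0 / tau_m[c] - 1.0 / t1);
      kb[c] = (Eb - em[c]) / (1.0 / tau_m[c] - 1.0 / t2);
      const double tp = std::log(t2 / t1) * t1 * t2 / (t2 - t1);
      fi[c] = 1.0 / (std::exp(-tp / t2) - std::exp(-tp / t1));
    }
  }

  std::vector<double> v(n, 0.0), e(n, 0.0), a(n, 0.0), b(n, 0.0);
  std::vector<int> ref_until(n, -1);
  std::vector<double> ring_exc((size_t)ring_n * n, 0.0), ring_inh((size_t)ring_n * n, 0.0);
  std::vector<int> ring_cnt((size_t)ring_n * n, 0);
  std::vector<double> lgn_exc(n, 0.0), tot_exc(n, 0.0);
  long long applied = 0, discarded = 0, delivered = 0, scheduled = 0;
  std::vector<int> sp_cell;
  std::vector<double> sp_time;

  int ext_i = 0;
  const int n_ext = ext_step.size();

  for (int s = 0; s < nsteps; ++s) {
    const double t = s * dt;
    const bool record = t >= analysis_start;
    // state propagation over [t, t+dt)
    if (model == 0) {
      for (int c = 0; c < n; ++c) v[c] *= em[c];
    } else {
      for (int c = 0; c < n; ++c) {
        if (s >= ref_until[c])
          v[c] = v[c] * em[c] + e[c] * ke[c] + b[c] * kb[c] - a[c] * ka[c];
        else
          v[c] = 0.0;
        e[c] *= de[c]; a[c] *= da[c]; b[c] *= db[c];
      }
    }
    // external events arriving at this step
    while (ext_i < n_ext && ext_step[ext_i] == s) {
      const int c = ext_tgt[ext_i];
      const double w = ext_w[ext_i];
      ++delivered;
      if (s < ref_until[c]) {
        ++discarded;
      } else {
        ++applied;
        if (model == 0) {
          v[c] += w;
        } else if (w >= 0) {
          e[c] += w;
        } else {
          a[c] += fi[c] * w; b[c] += fi[c] * w;
        }
        if (record && w > 0) {
          tot_exc[c] += w;
          if (ext_lgn[ext_i]) lgn_exc[c] += w;
        }
      }
      ++ext_i;
    }
    // recurrent events due at this step
    const int slot = s % ring_n;
    {
      double *rx = &ring_exc[(size_t)slot * n];
      double *ri = &ring_inh[(size_t)slot * n];
      int *rc = &ring_cnt[(size_t)slot * n];
      for (int c = 0; c < n; ++c) {
        const int cnt = rc[c];
        if (cnt == 0) continue;
        delivered += cnt;
        if (s < ref_until[c]) {
          discarded += cnt;
        } else {
          applied += cnt;
          const double wx = rx[c], wi = ri[c];
          if (model == 0) {
            v[c] += wx + wi;
          } else {
            e[c] += wx;
            a[c] += fi[c] * wi; b[c] += fi[c] * wi;
          }
          if (record && wx > 0) tot_exc[c] += wx;
        }
        rx[c] = 0.0; ri[c] = 0.0; rc[c] = 0;
      }
    }
    // threshold crossings
    const int dslot = (s + dsteps) % ring_n;
    double *dx = &ring_exc[(size_t)dslot * n];
    double *di = &ring_inh[(size_t)dslot * n];
    int *dc = &ring_cnt[(size_t)dslot * n];
    for (int c = 0; c < n; ++c) {
      if (s < ref_until[c]) continue;
      if (v[c] >= 1.0) {
        if (!std::isfinite(v[c])) stop("simulation state diverged (non-finite activation)");
        sp_cell.push_back(c);
        sp_time.push_back(t);
        v[c] = 0.0;
        ref_until[c] = s + rsteps;
        scheduled += rec_ptr[c + 1] - rec_ptr[c];
        for (int q = rec_ptr[c]; q < rec_ptr[c + 1]; ++q) {
          const int tg = rec_tgt[q];
          const double w = rec_w[q];
          if (w >= 0) dx[tg] += w; else di[tg] += w;
          dc[tg] += 1;
        }
      }
    }
  }

  return List::create(
    _["cell"] = IntegerVector(sp_cell.begin(), sp_cell.end()),
    _["time"] = NumericVector(sp_time.begin(), sp_time.end()),
    _["lgn_exc"] = NumericVector(lgn_exc.begin(), lgn_exc.end()),
    _["tot_exc"] = NumericVector(tot_exc.begin(), tot_exc.end()),
    _["n_applied"] = (double)applied,
    _["n_discarded"] = (double)discarded,
    _["n_delivered"] = (double)delivered,
    _["n_scheduled_recurrent"] = (double)scheduled,
    _["n_external_processed"] = (double)ext_i,
    _["state_v"] = NumericVector(v.begin(), v.end()),
    _["state_e"] = NumericVector(e.begin(), e.end()),
    _["state_a"] = NumericVector(a.begin(), a.end()),
    _["state_b"] = NumericVector(b.begin(), b.end()),
    _["state_time"] = (nsteps - 1) * dt);
}
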