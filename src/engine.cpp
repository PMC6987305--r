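#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Synchronous per-bin update loop of the coupled neuron-astrocyte model.
//
// Within each 5 ms bin the order is fixed:
//   1. firing intensities from previous-bin spikes/weights and previous-bin
//      astrocyte activity (rectified at zero),
//   2. Bernoulli spike draws (one uniform per neuron),
//   3. Tsodyks-Markram resource update + weight recomputation, with the
//      release increment taken from the previous-bin bound-receptor fraction,
//   4. local IP3 / calcium / gliotransmitter updates (IP3 forced to 1 while
//      the owning astrocyte is active),
//   5. astrocyte network: propagation efficiencies, propensities and UAR
//      transitions (one uniform per astrocyte).
//
// The R reference engine consumes the RNG in the identical order, so both
// engines produce bit-identical trajectories for the same seed.

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(int n_neurons, int n_steps, NumericVector c_noise,
                IntegerVector pre, IntegerVector post,
                NumericVector ymax_signed, NumericVector ustar_base,
                IntegerVector syn_astro,
                IntegerVector neigh_ptr, IntegerVector neigh_idx,
                NumericVector theta, IntegerVector n_syn,
                List pars, bool use_local, bool use_network,
                IntegerVector monitor, bool astro_trace) {
  const int m = pre.size();
  const int n_astro = theta.size();

  const double e_f    = pars["e_f"];     // exp(-omega_f * dt)
  const double rec_d  = pars["rec_d"];   // 1 - exp(-omega_d * dt)
  const double alpha  = pars["alpha"];
  const double e_ip3  = pars["e_ip3"];   // exp(-omega_ip3 * dt)
  const double o_acc  = pars["omega_acc"];
  const double ca_th  = pars["ca_th"];
  const double g_r    = pars["g_r"];
  const double e_g    = pars["e_g"];     // exp(-omega_g * dt)
  const double p_UA   = pars["p_UA"];    // dt / tau_A
  const double p_AR   = pars["p_AR"];    // dt / tau_R
  const double p_RU   = pars["p_RU"];    // dt / tau_U
  const double y_astro = pars["y_astro"];
  const double Mfac   = pars["M"];

  // state
  std::vector<int> s_prev(n_neurons, 0), s_cur(n_neurons, 0);
  std::vector<double> x(m, 1.0), u(m, 0.0), y(m, 0.0), g(m, 0.0),
      ip3(m, 0.0), ca(m, 0.0);
  std::vector<int> state(n_astro, 0);  // 0 = U, 1 = A, 2 = R
  std::vector<double> lam(n_neurons), sum_ca(n_astro);

  std::vector<int> spike_bin, spike_neuron;
  spike_bin.reserve(1024);
  spike_neuron.reserve(1024);
  IntegerVector pooled(n_steps);
  IntegerVector neuron_counts(n_neurons);
  IntegerVector active_count(n_steps);

  IntegerMatrix states_out =
      astro_trace ? IntegerMatrix(n_astro, n_steps) : IntegerMatrix(0, 0);
  const int n_mon = monitor.size();
  NumericMatrix mon_out =
      n_mon > 0 ? NumericMatrix(n_steps, 7 * n_mon) : NumericMatrix(0, 0);

  RNGScope scope;

  for (int k = 0; k < n_steps; ++k) {
    // 1. firing intensities
    for (int i = 0; i < n_neurons; ++i) lam[i] = c_noise[i];
    for (int s = 0; s < m; ++s) {
      if (s_prev[pre[s]]) lam[post[s]] += y[s];
      if (y_astro > 0.0) {
        const int a = syn_astro[s];
        if (a >= 0 && state[a] == 1) lam[post[s]] -= y_astro;
      }
    }
    // 2. spike draws (one uniform per neuron, fixed order)
    for (int i = 0; i < n_neurons; ++i) {
      double li = lam[i] > 0.0 ? lam[i] : 0.0;
      double P = std::exp(-li) * li;
      double ui = unif_rand();
      s_cur[i] = (ui < P) ? 1 : 0;
      if (s_cur[i]) {
        spike_bin.push_back(k + 1);
        spike_neuron.push_back(i + 1);
        ++neuron_counts[i];
        ++pooled[k];
      }
    }
    // 3. TM update + weights; 4. local astrocytic dynamics
    if (n_astro > 0) std::fill(sum_ca.begin(), sum_ca.end(), 0.0);
    for (int s = 0; s < m; ++s) {
      const int a = syn_astro[s];
      const bool local = use_local && a >= 0;
      double ustar = ustar_base[s];
      if (local) ustar = ustar_base[s] * (1.0 - g[s]) + alpha * g[s];
      const int sj = s_cur[pre[s]];
      double u_plus = (1.0 - u[s]) * ustar * sj + u[s];
      double RR = x[s] * u_plus * sj;
      u[s] = u_plus * e_f;
      double x_rem = x[s] - RR;
      x[s] = x_rem + (1.0 - x_rem) * rec_d;
      y[s] = ymax_signed[s] * RR;
      if (local) {
        const bool forced = state[a] == 1;
        double ip3_new;
        if (forced) {
          ip3_new = 1.0;
        } else {
          double dec = ip3[s] * e_ip3;
          ip3_new = dec + (1.0 - dec) * RR;
        }
        double ca_new = ca[s] + o_acc * (ip3_new - ca[s]);
        bool crossing = (ca[s] < ca_th) && (ca_th < ca_new);
        double base = crossing ? g[s] + (1.0 - g[s]) * g_r : g[s];
        g[s] = base * e_g;
        ip3[s] = ip3_new;
        ca[s] = ca_new;
        sum_ca[a] += ca_new;
      }
      if (n_mon > 0) {
        for (int j = 0; j < n_mon; ++j) {
          if (monitor[j] == s) {
            mon_out(k, 7 * j + 0) = x[s];
            mon_out(k, 7 * j + 1) = u[s];
            mon_out(k, 7 * j + 2) = RR;
            mon_out(k, 7 * j + 3) = ustar;
            mon_out(k, 7 * j + 4) = g[s];
            mon_out(k, 7 * j + 5) = ip3[s];
            mon_out(k, 7 * j + 6) = ca[s];
          }
        }
      }
    }
    // 5. astrocyte UAR dynamics: propensities from the start-of-bin states
    //    for every cell, then synchronous probabilistic transitions
    if (n_astro > 0) {
      std::vector<double> gamma(n_astro, 0.0);
      for (int a = 0; a < n_astro; ++a) {
        if (use_network) {
          double sum_beta = 0.0;
          for (int p = neigh_ptr[a]; p < neigh_ptr[a + 1]; ++p) {
            const int b = neigh_idx[p];
            if (state[b] == 1) {
              // propagation efficiency of active neighbour b
              int I_b = 0;
              for (int q = neigh_ptr[b]; q < neigh_ptr[b + 1]; ++q)
                if (state[neigh_idx[q]] != 1) ++I_b;
              if (I_b > 0) sum_beta += 1.0 / I_b;
            }
          }
          gamma[a] += theta[a] * sum_beta;
        }
        if (use_local && n_syn[a] > 0)
          gamma[a] += Mfac * sum_ca[a] / n_syn[a];
      }
      int n_active_now = 0;
      for (int a = 0; a < n_astro; ++a) {
        double ua = unif_rand();
        if (state[a] == 0) {
          if (gamma[a] > theta[a] && ua < p_UA) state[a] = 1;
        } else if (state[a] == 1) {
          if (ua < p_AR) state[a] = 2;
        } else {
          if (ua < p_RU) state[a] = 0;
        }
        if (state[a] == 1) ++n_active_now;
        if (astro_trace) states_out(a, k) = state[a];
      }
      active_count[k] = n_active_now;
    }
    std::swap(s_prev, s_cur);
  }

  List out = List::create(
      _["spike_bin"] = wrap(spike_bin),
      _["spike_neuron"] = wrap(spike_neuron),
      _["pooled"] = pooled,
      _["neuron_counts"] = neuron_counts,
      _["active_count"] = active_count);
  if (astro_trace) out["astro_states"] = states_out;
  if (n_mon > 0) out["monitor"] = mon_out;
  return out;
}
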