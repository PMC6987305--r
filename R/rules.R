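# Elementary per-bin update rules of the model. These vectorized R versions
# define the reference semantics; the compiled engine in src/ applies the same
# rules in the same order and is cross-checked against them in the tests.

#' Instantaneous firing intensity of a neuron
#'
#' Combines the basal noise intensity with the signed synaptic input from
#' presynaptic spikes of the previous bin and the astrocytic depression, and
#' rectifies at zero:
#' `lambda_i = max(0, c_i + sum_j y_ij s_j - y_astro * n_active_enwrapped)`.
#'
#' All intensities are expected spike counts per time bin (dimensionless);
#' with the astrocytic term absent this reduces to the classic noise-plus-
#' synaptic-drive rate of the stochastic spiking model.
#'
#' @param c_i basal noise intensity of the neuron.
#' @param presyn_spikes 0/1 vector, previous-bin spike indicators of the
#'   presynaptic neurons (one entry per incoming synapse).
#' @param weights signed synaptic weights `y_ij` (same length).
#' @param active_enwrapped number of incoming synapses enwrapped by currently
#'   active astrocytes.
#' @param y_astro per-synapse astrocytic depression strength.
#' @return Non-negative firing intensity (per bin).
#' @export
#' @examples
#' firing_rate(0.01, c(1, 1), c(0.3, 0.5), active_enwrapped = 3,
#'             y_astro = 0.01)  # 0.78
firing_rate <- function(c_i, presyn_spikes = numeric(0),
                        weights = numeric(0), active_enwrapped = 0,
                        y_astro = 0) {
  stopifnot(length(presyn_spikes) == length(weights),
            active_enwrapped >= 0, y_astro >= 0)
  max(0, c_i + sum(weights * presyn_spikes) - y_astro * active_enwrapped)
}

#' Probability of emitting one spike in a bin
#'
#' A neuron with intensity `lambda` emits at most one spike per bin; the
#' probability of exactly one event of a Poisson process with mean
#' `lambda * dt` is `P = exp(-lambda dt) * lambda dt`. The probability is
#' maximal (`exp(-1)`) when `lambda * dt = 1`.
#'
#' @param lambda firing intensity (vectorized, non-negative).
#' @param dt bin width in the same units, so that `lambda * dt` is the
#'   expected spike count per bin. The simulation engine works directly with
#'   per-bin intensities (`dt = 1`).
#' @return Spike probability per bin.
#' @export
#' @examples
#' spike_probability(10, 0.005)   # exp(-0.05) * 0.05
spike_probability <- function(lambda, dt = 1) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  mu <- lambda * dt
  exp(-mu) * mu
}

#' Draw spikes from per-neuron probabilities
#'
#' Independent Bernoulli draws from the current RNG state; reproducible after
#' [set.seed()].
#'
#' @param P vector of per-neuron spike probabilities in \[0, 1\].
#' @return Integer 0/1 spike vector.
#' @export
sample_spikes <- function(P) {
  if (any(P < 0 | P > 1)) stop("probabilities must lie in [0, 1]")
  as.integer(runif(length(P)) < P)
}

#' One Tsodyks-Markram synapse update
#'
#' Discrete-time update of the available resource fraction `x`, the ready-for-
#' release fraction `u` and the per-bin released fraction `RR`, assuming the
#' presynaptic spike (if any) arrives at the start of the bin:
#' \itemize{
#'   \item `RR = x_prev * ((1 - u_prev) U* s + u_prev) * s`
#'   \item `u = ((1 - u_prev) U* s + u_prev) * exp(-omega_f dt)`
#'   \item `x = (x_prev - RR) + (1 - (x_prev - RR)) * (1 - exp(-omega_d dt))`
#' }
#' All quantities stay in \[0, 1\] for any spike train and any release
#' increment `U*` in \[0, 1\].
#'
#' @param x_prev,u_prev previous-bin state (vectorized).
#' @param U_star release increment recruited by a spike, in \[0, 1\].
#' @param s presynaptic spike indicator, 0 or 1.
#' @param params a [tm_params()].
#' @param dt bin width (s).
#' @return List with vectors `x`, `u`, `RR`.
#' @export
#' @examples
#' update_tm(1, 0, U_star = 0.5, s = 1, tm_params(), dt = 0.005)
update_tm <- function(x_prev, u_prev, U_star, s, params = tm_params(),
                      dt = 0.005) {
  stopifnot(all(x_prev >= 0 & x_prev <= 1), all(u_prev >= 0 & u_prev <= 1),
            all(U_star >= 0 & U_star <= 1), all(s %in% c(0, 1)))
  u_plus <- (1 - u_prev) * U_star * s + u_prev
  RR <- x_prev * u_plus * s
  u <- u_plus * exp(-params$omega_f * dt)
  x_rem <- x_prev - RR
  x <- x_rem + (1 - x_rem) * (1 - exp(-params$omega_d * dt))
  list(x = x, u = u, RR = RR)
}

#' Synaptic weight from released resources
#'
#' The effective weight is directly proportional to the fraction of resources
#' released in the bin: `y = Y_max * RR`, with `Y_max` positive for
#' excitatory and negative for inhibitory presynaptic neurons.
#'
#' @param RR released fraction in \[0, 1\] (vectorized).
#' @param Y_max signed weight bound.
#' @return Signed synaptic weight.
#' @export
synaptic_weight <- function(RR, Y_max) {
  stopifnot(all(RR >= 0 & RR <= 1))
  Y_max * RR
}

#' Release increment under gliotransmission
#'
#' The spike-triggered release increment interpolates between the basal value
#' `y_base / Y_max` (no bound gliotransmitter receptors) and the
#' gliotransmission effect parameter `alpha` (all receptors bound):
#' `U* = (y_base / Y_max) * (1 - g) + alpha * g`. Naked synapses have
#' `g = 0` at all times, so their `U*` is constant.
#'
#' @param y_base basal weight magnitude.
#' @param Y_max weight bound magnitude (non-zero).
#' @param g bound-receptor fraction in \[0, 1\] (vectorized).
#' @param alpha gliotransmission effect parameter.
#' @return Release increment in \[0, 1\].
#' @export
#' @examples
#' release_increment(0.35, 0.7, g = c(0, 0.5, 1), alpha = 0.7)
release_increment <- function(y_base, Y_max, g, alpha = 0.7) {
  if (any(Y_max == 0)) stop("Y_max must be non-zero")
  stopifnot(all(g >= 0 & g <= 1))
  (y_base / abs(Y_max)) * (1 - g) + alpha * g
}

#' Local astrocytic IP3 update
#'
#' Exponential degradation plus spike-driven production saturated at 1:
#' `ip3 = ip3_prev e^{-omega_ip3 dt} + (1 - ip3_prev e^{-omega_ip3 dt}) RR`.
#' While the owning astrocyte is in the active state, the local IP3 is forced
#' to its maximum value 1.
#'
#' @param ip3_prev previous-bin IP3 (vectorized, in \[0, 1\]).
#' @param RR released resource fraction this bin.
#' @param params a [local_params()].
#' @param dt bin width (s).
#' @param forced logical; TRUE while the owning astrocyte is active.
#' @return Updated IP3 in \[0, 1\].
#' @export
update_ip3 <- function(ip3_prev, RR, params = local_params(), dt = 0.005,
                       forced = FALSE) {
  stopifnot(all(ip3_prev >= 0 & ip3_prev <= 1), all(RR >= 0 & RR <= 1))
  decayed <- ip3_prev * exp(-params$omega_ip3 * dt)
  out <- decayed + (1 - decayed) * RR
  out[forced] <- 1
  out
}

#' Local astrocytic calcium update
#'
#' First-order relaxation of the local calcium toward the local IP3 with the
#' dimensionless per-bin gain `omega_acc`, capturing the slow time scale of
#' the calcium-release machinery:
#' `ca = ca_prev + omega_acc * (ip3 - ca_prev)`.
#'
#' @param ca_prev previous-bin calcium (vectorized, in \[0, 1\]).
#' @param ip3 current-bin IP3.
#' @param omega_acc per-bin relaxation gain.
#' @return Updated calcium in \[0, 1\].
#' @export
update_calcium <- function(ca_prev, ip3, omega_acc = 0.05) {
  stopifnot(all(ca_prev >= 0 & ca_prev <= 1), all(ip3 >= 0 & ip3 <= 1))
  ca_prev + omega_acc * (ip3 - ca_prev)
}

#' Gliotransmitter receptor binding update
#'
#' A gliotransmission event occurs on an upward crossing of the calcium
#' threshold (`ca_prev < ca_th < ca`, strict on both sides): a fraction `g_r`
#' of the unbound receptors is recruited before the exponential unbinding
#' decay. While the calcium stays above threshold no new event occurs, which
#' latches release during sustained astrocyte activation:
#' `g = (g_prev + (1 - g_prev) g_r) e^{-omega_g dt}` on a crossing,
#' `g = g_prev e^{-omega_g dt}` otherwise.
#'
#' @param g_prev previous-bin bound fraction (vectorized, in \[0, 1\]).
#' @param ca_prev,ca previous- and current-bin local calcium.
#' @param params a [local_params()].
#' @param dt bin width (s).
#' @return Updated bound-receptor fraction in \[0, 1\].
#' @export
update_gliotransmitter <- function(g_prev, ca_prev, ca,
                                   params = local_params(), dt = 0.005) {
  stopifnot(all(g_prev >= 0 & g_prev <= 1))
  crossing <- (ca_prev < params$ca_th) & (params$ca_th < ca)
  base <- ifelse(crossing, g_prev + (1 - g_prev) * params$g_r, g_prev)
  base * exp(-params$omega_g * dt)
}

#' Propagation efficiency of an active astrocyte
#'
#' An active astrocyte spreads its activation drive equally over its
#' gap-junction neighbours that are not themselves active:
#' `beta = 1 / I_a` with `I_a` the number of non-active neighbours; inactive
#' and refractory astrocytes (and active ones with no non-active neighbour)
#' have `beta = 0`.
#'
#' @param state astrocyte state, one of `"U"`, `"A"`, `"R"`.
#' @param neighbor_states character vector of neighbour states.
#' @return Propagation efficiency in \[0, 1\].
#' @export
propagation_efficiency <- function(state, neighbor_states = character(0)) {
  stopifnot(state %in% c("U", "A", "R"),
            all(neighbor_states %in% c("U", "A", "R")))
  if (state != "A") return(0)
  I_a <- sum(neighbor_states != "A")
  if (I_a == 0) 0 else 1 / I_a
}

#' Astrocyte activation threshold
#'
#' Linear in the gap-junction neighbour count: `theta = b0 * n_a + b1`.
#'
#' @param n_a neighbour count (vectorized, non-negative).
#' @param b0,b1 slope and intercept.
#' @return Activation threshold.
#' @export
activation_threshold <- function(n_a, b0 = 0.02, b1 = 0.205) {
  stopifnot(all(n_a >= 0))
  b0 * n_a + b1
}

#' Astrocyte activation propensity
#'
#' Combines the gap-junction input from active neighbours with the
#' synapse-averaged local calcium of the cell:
#' `gamma = theta * sum(beta_b) + M * sum(ca_local) / N_syn`, where the sum of
#' `beta_b` runs over the gap-coupled neighbours and `N_syn` is the number of
#' excitatory synapses enwrapped by the astrocyte (the calcium term is zero
#' for an astrocyte with no enwrapped synapse).
#'
#' @param theta the astrocyte's own activation threshold.
#' @param neighbor_betas propagation efficiencies of the neighbours.
#' @param sum_local_ca sum of the local calcium over the cell's enwrapped
#'   synapses.
#' @param N_syn number of enwrapped excitatory synapses.
#' @param M whole-cell scaling of the averaged local calcium.
#' @return Activation propensity (non-negative).
#' @export
activation_propensity <- function(theta, neighbor_betas = numeric(0),
                                  sum_local_ca = 0, N_syn = 0, M = 5) {
  stopifnot(N_syn >= 0)
  ca_term <- if (N_syn > 0) M * sum_local_ca / N_syn else 0
  theta * sum(neighbor_betas) + ca_term
}

#' One step of the three-state astrocyte dynamics
#'
#' Per-bin probabilistic transitions of the UAR states: an inactive astrocyte
#' whose propensity exceeds its threshold activates with probability
#' `dt / tau_A`; active cells become refractory with probability `dt / tau_R`
#' and refractory cells recover with probability `dt / tau_U`. At most one
#' transition happens per bin (a freshly activated cell cannot turn
#' refractory in the same bin). One uniform draw is consumed per astrocyte
#' per call, so trajectories are reproducible after [set.seed()].
#'
#' @param states character vector of `"U"`, `"A"`, `"R"`.
#' @param gammas activation propensities.
#' @param thetas activation thresholds.
#' @param params a [uar_params()].
#' @param dt bin width (s).
#' @return Updated state vector.
#' @export
update_astrocyte_states <- function(states, gammas, thetas,
                                    params = uar_params(), dt = 0.005) {
  n <- length(states)
  stopifnot(all(states %in% c("U", "A", "R")), length(gammas) == n,
            length(thetas) == n)
  if (n == 0) return(states)
  u <- runif(n)
  out <- states
  act <- states == "U" & gammas > thetas & u < dt / params$tau_A
  out[act] <- "A"
  ref <- states == "A" & u < dt / params$tau_R
  out[ref] <- "R"
  rec <- states == "R" & u < dt / params$tau_U
  rec[ref] <- FALSE
  out[rec] <- "U"
  out
}

#' Astrocytic depression applied to one neuron
#'
#' The adenosine-like depression subtracted from a neuron's firing intensity:
#' `y_astro` times the number of its incoming synapses that are enwrapped by
#' an astrocyte active in the previous bin (regardless of presynaptic
#' spiking).
#'
#' @param synapse_astro astrocyte id per incoming synapse (NA for naked).
#' @param active logical vector over astrocytes, TRUE if active.
#' @param y_astro per-synapse depression strength.
#' @return Non-negative intensity deduction.
#' @export
depression_term <- function(synapse_astro, active, y_astro = 0.01) {
  enwrapped <- !is.na(synapse_astro)
  y_astro * sum(active[synapse_astro[enwrapped]])
}
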