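#' Culture geometry for the virtual MEA
#'
#' Spatial parameters of the simulated culture: the extent of the plated area,
#' minimum inter-soma distances enforced during random cell placement, the
#' width of the Gaussian distance-dependent connection probabilities, the hard
#' cutoff for astrocyte-synapse enwrapping and the gap-junction connection
#' distance. All lengths are in micrometers.
#'
#' The culture is quasi-two-dimensional: cells are placed uniformly in a thin
#' box (default 750 x 750 x 10 um) and all distances are 3D Euclidean.
#'
#' @param extent numeric length-3, culture dimensions in um.
#' @param min_neuron_dist minimum inter-soma distance between neurons (um).
#' @param min_astro_dist minimum inter-soma distance between astrocytes (um).
#' @param sigma_N standard deviation of the neuron-neuron Gaussian connection
#'   probability (um).
#' @param sigma_A standard deviation of the astrocyte-synapse Gaussian
#'   connection probability (um).
#' @param d_A hard cutoff beyond which a synapse cannot be enwrapped (um).
#' @param gap_cutoff maximum inter-soma distance for a gap junction (um).
#' @return An object of class `culture_geometry` (a validated list).
#' @export
#' @examples
#' geom <- culture_geometry()
#' geom$sigma_N
culture_geometry <- function(extent = c(750, 750, 10),
                             min_neuron_dist = 10,
                             min_astro_dist = 30,
                             sigma_N = 200,
                             sigma_A = 150,
                             d_A = 70,
                             gap_cutoff = 100) {
  stopifnot(length(extent) == 3, all(extent > 0),
            min_neuron_dist > 0, min_astro_dist > 0,
            sigma_N > 0, sigma_A > 0, d_A > 0, gap_cutoff > 0)
  if (d_A > gap_cutoff)
    stop("d_A must not exceed the gap-junction cutoff")
  if (max(min_neuron_dist, min_astro_dist) >= min(extent[1:2]))
    stop("minimum cell distances must be smaller than the culture extent")
  structure(list(extent = as.numeric(extent),
                 min_neuron_dist = min_neuron_dist,
                 min_astro_dist = min_astro_dist,
                 sigma_N = sigma_N, sigma_A = sigma_A,
                 d_A = d_A, gap_cutoff = gap_cutoff),
            class = "culture_geometry")
}

#' Tsodyks-Markram synapse parameters
#'
#' @param omega_d recovery rate of synaptic vesicles (1/s).
#' @param omega_f decay rate of the ready-for-release fraction (facilitation
#'   variable u) (1/s).
#' @param Y_max_plus upper bound of excitatory synaptic weights.
#' @param Y_max_minus lower bound of inhibitory synaptic weights (negative).
#' @param alpha gliotransmission effect parameter: the release increment U*
#'   interpolates from `y_base / Y_max` (no bound receptors) to `alpha`
#'   (all receptors bound). With the default 0.7 gliotransmission is
#'   potentiating for every synapse with `y_base / Y_max < 0.7`.
#' @return List of class `tm_params`.
#' @export
tm_params <- function(omega_d = 4.0405, omega_f = 2.0,
                      Y_max_plus = 0.7, Y_max_minus = -0.7, alpha = 0.7) {
  stopifnot(omega_d > 0, omega_f > 0, Y_max_plus > 0, Y_max_minus < 0,
            alpha > 0, alpha <= 1)
  structure(list(omega_d = omega_d, omega_f = omega_f,
                 Y_max_plus = Y_max_plus, Y_max_minus = Y_max_minus,
                 alpha = alpha),
            class = "tm_params")
}

#' Local astrocytic process parameters
#'
#' Parameters of the per-synapse astrocytic microdomain: IP3 degradation,
#' the IP3-to-calcium accumulation gain, the calcium threshold for
#' gliotransmitter release, the recruited receptor fraction per release and
#' the receptor recovery (unbinding) rate.
#'
#' @param omega_ip3 IP3 degradation rate (1/s).
#' @param omega_acc dimensionless per-bin relaxation gain of calcium toward
#'   IP3 (no unit; applied once per 5 ms step).
#' @param ca_th calcium threshold for gliotransmitter release (normalized).
#' @param g_r fraction of unbound receptors recruited per release event.
#' @param omega_g recovery rate of gliotransmitter receptors (1/s).
#' @return List of class `local_params`.
#' @export
local_params <- function(omega_ip3 = 152.3, omega_acc = 0.05,
                         ca_th = 0.1, g_r = 0.3, omega_g = 0.077) {
  stopifnot(omega_ip3 > 0, omega_acc > 0, omega_acc <= 1,
            ca_th > 0, ca_th < 1, g_r > 0, g_r < 1, omega_g > 0)
  structure(list(omega_ip3 = omega_ip3, omega_acc = omega_acc,
                 ca_th = ca_th, g_r = g_r, omega_g = omega_g),
            class = "local_params")
}

#' Whole-cell astrocyte (UAR) network parameters
#'
#' Parameters of the three-state astrocyte dynamics (U inactive, A active,
#' R refractory) and of the astrocyte-to-neuron depression.
#'
#' @param b0 slope of the activation threshold in the neighbour count.
#' @param b1 intercept of the activation threshold.
#' @param tau_A time scale of the U to A activation transition (s): once the
#'   activation propensity exceeds the threshold, activation occurs with
#'   probability `dt / tau_A` per step.
#' @param tau_R time scale of the spontaneous A to R transition (s); the mean
#'   dwell time in the active state.
#' @param tau_U time scale of the spontaneous R to U transition (s); the mean
#'   refractory dwell time.
#' @param M scaling between the synapse-averaged local calcium and the
#'   whole-cell self-induced activation drive.
#' @param y_astro per-synapse depressing signal applied by an active astrocyte
#'   to the postsynaptic neuron (same per-bin intensity units as the synaptic
#'   weights).
#' @return List of class `uar_params`.
#' @export
uar_params <- function(b0 = 0.02, b1 = 0.205, tau_A = 1.5, tau_R = 7.0,
                       tau_U = 5.0, M = 5, y_astro = 0.01) {
  stopifnot(b0 >= 0, b1 > 0, tau_A > 0, tau_R > 0, tau_U > 0,
            M > 0, y_astro >= 0)
  structure(list(b0 = b0, b1 = b1, tau_A = tau_A, tau_R = tau_R,
                 tau_U = tau_U, M = M, y_astro = y_astro),
            class = "uar_params")
}

#' Full default parameter set
#'
#' Bundles the geometry, synapse, local-astrocyte and astrocyte-network
#' parameter groups with the time grid defaults (5 ms step, 300 s horizon).
#'
#' @param dt simulation time step (s).
#' @param T_total total simulated time (s).
#' @param geometry a [culture_geometry()].
#' @param tm a [tm_params()].
#' @param local a [local_params()].
#' @param uar a [uar_params()].
#' @return Named list with elements `dt`, `T_total`, `geometry`, `tm`,
#'   `local`, `uar`.
#' @export
inexa_params <- function(dt = 0.005, T_total = 300,
                         geometry = culture_geometry(),
                         tm = tm_params(),
                         local = local_params(),
                         uar = uar_params()) {
  stopifnot(dt > 0, T_total > 0)
  n_steps <- T_total / dt
  if (abs(n_steps - round(n_steps)) > 1e-8)
    stop("T_total must be an integer multiple of dt")
  stopifnot(inherits(geometry, "culture_geometry"), inherits(tm, "tm_params"),
            inherits(local, "local_params"), inherits(uar, "uar_params"))
  if (dt / min(uar$tau_A, uar$tau_R, uar$tau_U) > 1)
    stop("dt must not exceed the smallest astrocyte time constant")
  list(dt = dt, T_total = T_total, n_steps = as.integer(round(n_steps)),
       geometry = geometry, tm = tm, local = local, uar = uar)
}

# Symmetric triangular distribution on [0, upper], mode at upper/2.
# Used for the per-neuron noise intensities and the basal synaptic weights.
rtri <- function(n, upper) {
  upper * (runif(n) + runif(n)) / 2
}
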