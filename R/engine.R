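#' Build a simulation scenario configuration
#'
#' The model is exercised through a ladder of four scenarios that add
#' astrocytic signalling in stages:
#' \describe{
#'   \item{`noise_only`}{independent Poisson neurons: all synaptic weights and
#'     the astrocytic depression are zero; no astrocytes.}
#'   \item{`nn_only`}{the plain neuronal network with Tsodyks-Markram
#'     synapses; no astrocytes (`g = 0` everywhere, `y_astro = 0`).}
#'   \item{`nn_psa`}{presynaptic astrocyte processes: excitatory synapses are
#'     enwrapped and local IP3/calcium/gliotransmission dynamics run, but the
#'     astrocytes do not form a network (propagation efficiency identically
#'     zero) and release no depressing transmitter (`y_astro = 0`).}
#'   \item{`nn_a`}{the full model: gap-junction network propagation and
#'     astrocytic depression enabled.}
#' }
#' Three noise ceilings crossed with `noise_only`, `nn_only`, `nn_psa` and
#' three astrocyte counts for `nn_a` give the 18 standard scenarios (see
#' [enumerate_scenarios()]).
#'
#' @param scenario one of `"noise_only"`, `"nn_only"`, `"nn_psa"`, `"nn_a"`.
#' @param C_max upper bound of the triangular per-neuron noise intensity
#'   distribution (per-bin units), typically 0.01, 0.02 or 0.03.
#' @param n_astrocytes astrocyte count; defaults to 0 for the astrocyte-free
#'   scenarios and 107 otherwise (the 30% ratio for 250 neurons; 28 and 63
#'   correspond to 10% and 20%).
#' @param n_runs number of repeated runs in [run_experiment()].
#' @param params an [inexa_params()] bundle.
#' @return Object of class `inexa_config`.
#' @export
#' @examples
#' build_scenario("nn_a", C_max = 0.02, n_astrocytes = 107)
build_scenario <- function(scenario = c("nn_a", "noise_only", "nn_only",
                                        "nn_psa"),
                           C_max = 0.02,
                           n_astrocytes = NULL,
                           n_runs = 5,
                           params = inexa_params()) {
  scenario <- match.arg(scenario)
  stopifnot(C_max >= 0, n_runs >= 1)
  if (is.null(n_astrocytes))
    n_astrocytes <- if (scenario %in% c("noise_only", "nn_only")) 0L else 107L
  if (scenario %in% c("noise_only", "nn_only") && n_astrocytes != 0)
    stop(scenario, " uses no astrocytes")
  if (scenario %in% c("nn_psa", "nn_a") && n_astrocytes <= 0)
    stop(scenario, " requires astrocytes")
  structure(list(
    scenario = scenario,
    C_max = C_max,
    n_astrocytes = as.integer(n_astrocytes),
    n_runs = as.integer(n_runs),
    params = params,
    weights_on = scenario != "noise_only",
    local_on = scenario %in% c("nn_psa", "nn_a"),
    network_on = scenario == "nn_a",
    y_astro = if (scenario == "nn_a") params$uar$y_astro else 0
  ), class = "inexa_config")
}

#' Enumerate the standard scenario ladder
#'
#' Crosses the three noise ceilings with the four model stages (the full model
#' at three astrocyte ratios), yielding the 18 standard configurations.
#'
#' @param C_max_values noise ceilings.
#' @param astro_counts astrocyte counts for the full-model stage.
#' @param ... passed to [build_scenario()].
#' @return List of 18 `inexa_config` objects.
#' @export
enumerate_scenarios <- function(C_max_values = c(0.01, 0.02, 0.03),
                                astro_counts = c(28L, 63L, 107L), ...) {
  out <- list()
  for (C_max in C_max_values) {
    out <- c(out,
             list(build_scenario("noise_only", C_max, 0L, ...),
                  build_scenario("nn_only", C_max, 0L, ...),
                  build_scenario("nn_psa", C_max, ...)),
             lapply(astro_counts, function(a)
               build_scenario("nn_a", C_max, a, ...)))
  }
  out
}

#' @export
print.inexa_config <- function(x, ...) {
  cat(sprintf("inexa scenario '%s': C_max = %g, %d astrocytes, %d run(s)\n",
              x$scenario, x$C_max, x$n_astrocytes, x$n_runs))
  cat(sprintf("  T = %g s, dt = %g s (%d bins); y_astro = %g\n",
              x$params$T_total, x$params$dt, x$params$n_steps, x$y_astro))
  invisible(x)
}

# Pack topology + config into the flat arrays the engines consume.
prepare_engine_inputs <- function(topology, config) {
  params <- config$params
  syn <- topology$synapses
  n_astro_top <- if (is.null(topology$astro_positions)) 0L
                 else nrow(topology$astro_positions)
  if (config$n_astrocytes != n_astro_top)
    stop("topology carries ", n_astro_top, " astrocytes but the scenario ",
         "expects ", config$n_astrocytes,
         "; use resample_astrocytes() first")
  Ymax <- ifelse(syn$sign > 0, params$tm$Y_max_plus,
                 abs(params$tm$Y_max_minus))
  astro <- if (config$local_on) syn$astrocyte else rep(NA_integer_,
                                                       nrow(syn))
  n_syn_per_astro <- if (n_astro_top > 0) {
    tabulate(astro[!is.na(astro)], nbins = n_astro_top)
  } else integer(0)
  neigh <- topology$gap$neighbors
  neigh_ptr <- cumsum(c(0L, vapply(neigh, length, integer(1))))
  dt <- params$dt
  list(
    n_neurons = nrow(topology$neuron_positions),
    n_steps = params$n_steps,
    c_noise = topology$c_unit * config$C_max,
    pre = syn$pre - 1L,
    post = syn$post - 1L,
    ymax_signed = if (config$weights_on) syn$sign * Ymax else
                    rep(0, nrow(syn)),
    ustar_base = syn$y_base / Ymax,
    syn_astro = ifelse(is.na(astro), -1L, astro - 1L),
    neigh_ptr = as.integer(neigh_ptr),
    neigh_idx = as.integer(unlist(neigh, use.names = FALSE) - 1L),
    theta = activation_threshold(topology$gap$degree,
                                 params$uar$b0, params$uar$b1),
    n_syn = as.integer(n_syn_per_astro),
    pars = list(e_f = exp(-params$tm$omega_f * dt),
                rec_d = 1 - exp(-params$tm$omega_d * dt),
                alpha = params$tm$alpha,
                e_ip3 = exp(-params$local$omega_ip3 * dt),
                omega_acc = params$local$omega_acc,
                ca_th = params$local$ca_th,
                g_r = params$local$g_r,
                e_g = exp(-params$local$omega_g * dt),
                p_UA = dt / params$uar$tau_A,
                p_AR = dt / params$uar$tau_R,
                p_RU = dt / params$uar$tau_U,
                y_astro = config$y_astro,
                M = params$uar$M),
    use_local = config$local_on,
    use_network = config$network_on
  )
}

#' Simulate one run of the coupled network
#'
#' Advances the synchronous per-bin update loop over the whole time horizon:
#' firing intensities from previous-bin spikes and astrocyte activity, spike
#' draws, Tsodyks-Markram synapse updates with gliotransmission-modulated
#' release increments, local IP3/calcium/receptor dynamics, and the
#' three-state astrocyte network transitions.
#'
#' @param topology a `culture_topology` whose astrocyte count matches the
#'   scenario.
#' @param config an `inexa_config` from [build_scenario()].
#' @param seed integer seed for the dynamics RNG (spike and state-transition
#'   draws).
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation; identical trajectories, much slower).
#' @param monitor_synapses optional integer vector of synapse row indices
#'   whose state (x, u, RR, U*, g, IP3, Ca) is recorded every bin.
#' @param astro_trace logical; record the full per-astrocyte state matrix.
#' @return Object of class `inexa_result`: `raster` (data.frame with `bin`,
#'   `neuron`, `time`), `pooled` (per-bin network spike count),
#'   `astro_active` (per-bin active-astrocyte count), `neuron_counts`,
#'   `dt`, `T_total`, `config`, `seed`, and optional `astro_states` /
#'   `monitor` traces.
#' @export
#' @examples
#' top <- build_culture_topology(30, 24, 0, seed = 1)
#' cfg <- build_scenario("nn_only", 0.02,
#'                       params = inexa_params(T_total = 5))
#' res <- simulate_culture(top, cfg, seed = 1)
#' sum(res$pooled)
simulate_culture <- function(topology, config, seed = 1,
                             engine = c("cpp", "r"),
                             monitor_synapses = NULL,
                             astro_trace = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(topology, "culture_topology"),
            inherits(config, "inexa_config"))
  inp <- prepare_engine_inputs(topology, config)
  monitor <- if (is.null(monitor_synapses)) integer(0)
             else as.integer(monitor_synapses - 1L)
  set.seed(seed)
  raw <- if (engine == "cpp") {
    .engine_run(inp$n_neurons, inp$n_steps, inp$c_noise, inp$pre, inp$post,
                inp$ymax_signed, inp$ustar_base, inp$syn_astro,
                inp$neigh_ptr, inp$neigh_idx, inp$theta, inp$n_syn,
                inp$pars, inp$use_local, inp$use_network, monitor,
                astro_trace)
  } else {
    engine_run_r(inp, monitor, astro_trace)
  }
  dt <- config$params$dt
  res <- list(
    raster = data.frame(bin = raw$spike_bin, neuron = raw$spike_neuron,
                        time = (raw$spike_bin - 1L) * dt),
    pooled = as.integer(raw$pooled),
    astro_active = as.integer(raw$active_count),
    neuron_counts = as.integer(raw$neuron_counts),
    n_neurons = inp$n_neurons,
    n_astrocytes = config$n_astrocytes,
    astro_positions = topology$astro_positions,
    dt = dt,
    T_total = config$params$T_total,
    config = config,
    seed = seed,
    engine = engine)
  if (astro_trace) res$astro_states <- raw$astro_states
  if (length(monitor) > 0) {
    res$monitor <- lapply(seq_along(monitor), function(j) {
      tr <- raw$monitor[, (7 * (j - 1) + 1):(7 * j), drop = FALSE]
      colnames(tr) <- c("x", "u", "RR", "U_star", "g", "ip3", "ca")
      tr
    })
    names(res$monitor) <- as.character(monitor_synapses)
  }
  structure(res, class = "inexa_result")
}

#' @export
print.inexa_result <- function(x, ...) {
  cat(sprintf("inexa result: '%s', %d neurons, %d astrocytes, T = %g s\n",
              x$config$scenario, x$n_neurons, x$n_astrocytes, x$T_total))
  cat(sprintf("  %d spikes (%.2f spikes/min/neuron)",
              nrow(x$raster), mean_spike_rate(x)))
  if (x$n_astrocytes > 0)
    cat(sprintf("; mean active astrocytes %.2f", mean(x$astro_active)))
  cat("\n")
  invisible(x)
}

# Pure-R reference engine: mirrors src/engine.cpp bin for bin and draw for
# draw (one uniform per neuron, then one per astrocyte). Used for small
# cross-validation runs; O(n_steps * m) in interpreted code.
engine_run_r <- function(inp, monitor = integer(0), astro_trace = FALSE) {
  n <- inp$n_neurons; n_steps <- inp$n_steps
  m <- length(inp$pre); n_astro <- length(inp$theta)
  pre <- inp$pre + 1L; post <- inp$post + 1L
  syn_astro <- ifelse(inp$syn_astro < 0L, NA_integer_, inp$syn_astro + 1L)
  p <- inp$pars
  neigh <- if (n_astro > 0) {
    lapply(seq_len(n_astro), function(a) {
      len <- inp$neigh_ptr[a + 1L] - inp$neigh_ptr[a]
      inp$neigh_idx[inp$neigh_ptr[a] + seq_len(len)] + 1L
    })
  } else list()
  s_prev <- integer(n)
  x <- rep(1, m); u <- numeric(m); y <- numeric(m)
  g <- numeric(m); ip3 <- numeric(m); ca <- numeric(m)
  state <- integer(n_astro)                # 0 = U, 1 = A, 2 = R
  enwrapped <- !is.na(syn_astro) & inp$use_local
  pooled <- integer(n_steps); active_count <- integer(n_steps)
  neuron_counts <- integer(n)
  spike_bin <- list(); spike_neuron <- list()
  states_out <- if (astro_trace) matrix(0L, n_astro, n_steps) else NULL
  mon_out <- if (length(monitor)) matrix(0, n_steps, 7 * length(monitor))
             else NULL

  for (k in seq_len(n_steps)) {
    lam <- inp$c_noise
    fired <- which(s_prev[pre] == 1L)
    if (length(fired))
      lam <- lam + unname(tapply_sum(y[fired], post[fired], n))
    if (p$y_astro > 0 && n_astro > 0) {
      depressed <- which(!is.na(syn_astro) & state[syn_astro] == 1L)
      if (length(depressed))
        lam <- lam - p$y_astro *
          unname(tapply_sum(rep(1, length(depressed)),
                            post[depressed], n))
    }
    lam <- pmax(0, lam)
    P <- exp(-lam) * lam
    s_cur <- as.integer(runif(n) < P)
    sp <- which(s_cur == 1L)
    if (length(sp)) {
      spike_bin[[length(spike_bin) + 1L]] <- rep(k, length(sp))
      spike_neuron[[length(spike_neuron) + 1L]] <- sp
      neuron_counts[sp] <- neuron_counts[sp] + 1L
      pooled[k] <- length(sp)
    }
    ustar <- inp$ustar_base
    ustar[enwrapped] <- inp$ustar_base[enwrapped] * (1 - g[enwrapped]) +
      p$alpha * g[enwrapped]
    sj <- s_cur[pre]
    u_plus <- (1 - u) * ustar * sj + u
    RR <- x * u_plus * sj
    u <- u_plus * p$e_f
    x_rem <- x - RR
    x <- x_rem + (1 - x_rem) * p$rec_d
    y <- inp$ymax_signed * RR
    if (any(enwrapped)) {
      e <- enwrapped
      forced <- state[syn_astro[e]] == 1L
      dec <- ip3[e] * p$e_ip3
      ip3_new <- ifelse(forced, 1, dec + (1 - dec) * RR[e])
      ca_new <- ca[e] + p$omega_acc * (ip3_new - ca[e])
      crossing <- (ca[e] < p$ca_th) & (p$ca_th < ca_new)
      g[e] <- ifelse(crossing, g[e] + (1 - g[e]) * p$g_r, g[e]) * p$e_g
      ip3[e] <- ip3_new
      ca[e] <- ca_new
    }
    if (length(monitor)) {
      for (j in seq_along(monitor)) {
        s <- monitor[j] + 1L
        mon_out[k, (7 * (j - 1) + 1):(7 * j)] <-
          c(x[s], u[s], RR[s], ustar[s], g[s], ip3[s], ca[s])
      }
    }
    if (n_astro > 0) {
      gamma <- numeric(n_astro)
      if (inp$use_network) {
        I <- vapply(seq_len(n_astro), function(a)
          sum(state[neigh[[a]]] != 1L), numeric(1))
        beta <- ifelse(state == 1L & I > 0, 1 / pmax(I, 1), 0)
        gamma <- inp$theta * vapply(seq_len(n_astro), function(a)
          sum(beta[neigh[[a]]]), numeric(1))
      }
      if (inp$use_local && any(enwrapped)) {
        sum_ca <- tapply_sum(ca[enwrapped], syn_astro[enwrapped], n_astro)
        has_syn <- inp$n_syn > 0
        gamma[has_syn] <- gamma[has_syn] +
          p$M * sum_ca[has_syn] / inp$n_syn[has_syn]
      }
      ua <- runif(n_astro)
      new_state <- state
      new_state[state == 0L & gamma > inp$theta & ua < p$p_UA] <- 1L
      new_state[state == 1L & ua < p$p_AR] <- 2L
      new_state[state == 2L & ua < p$p_RU] <- 0L
      state <- new_state
      active_count[k] <- sum(state == 1L)
      if (astro_trace) states_out[, k] <- state
    }
    s_prev <- s_cur
  }
  list(spike_bin = unlist(spike_bin, use.names = FALSE) %||% integer(0),
       spike_neuron = unlist(spike_neuron, use.names = FALSE) %||%
         integer(0),
       pooled = pooled, neuron_counts = neuron_counts,
       active_count = active_count,
       astro_states = states_out, monitor = mon_out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sum `values` into `n` groups given 1-based group indices.
tapply_sum <- function(values, groups, n) {
  out <- numeric(n)
  agg <- rowsum(values, groups)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Run a multi-run experiment for one scenario
#'
#' Builds one neuronal network (positions, synapse table, basal weights and
#' noise quantiles) that is shared by all runs, then for each run resamples
#' the astrocytic network (placement, synapse assignment, gap junctions) and
#' simulates the dynamics with a run-specific seed. This mirrors the standard
#' protocol: the same neuronal network in all simulations, the astrocytic
#' network resampled at each run.
#'
#' @param config an `inexa_config`.
#' @param seed master integer seed; the topology seed and the per-run
#'   astrocyte-placement and dynamics seeds are derived from it.
#' @param topology optional pre-built `culture_topology` (astrocytes, if any,
#'   are resampled per run regardless).
#' @param engine passed to [simulate_culture()].
#' @return Object of class `inexa_experiment`: list with `results` (one
#'   `inexa_result` per run), `topology` (the shared neuronal network),
#'   `config`, `seed`.
#' @export
run_experiment <- function(config, seed = 1, topology = NULL,
                           engine = "cpp") {
  stopifnot(inherits(config, "inexa_config"))
  sub <- derive_seeds(seed, 1L + 2L * config$n_runs)
  if (is.null(topology)) {
    topology <- build_culture_topology(
      n_neurons = 250, n_excitatory = 200, n_astrocytes = 0,
      geometry = config$params$geometry, seed = sub[1L])
  }
  results <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    top_r <- if (config$n_astrocytes > 0) {
      resample_astrocytes(topology, config$n_astrocytes,
                          seed = sub[2L * r])
    } else {
      resample_astrocytes(topology, 0L)
    }
    results[[r]] <- simulate_culture(top_r, config, seed = sub[2L * r + 1L],
                                     engine = engine)
  }
  structure(list(results = results, topology = topology, config = config,
                 seed = seed),
            class = "inexa_experiment")
}

# Independent sub-seeds derived from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Mean spike rate of a result or experiment
#'
#' @param x an `inexa_result` or `inexa_experiment`.
#' @return Mean firing rate over neurons (and runs), in spikes per minute.
#' @export
mean_spike_rate <- function(x) {
  if (inherits(x, "inexa_experiment"))
    return(mean(vapply(x$results, mean_spike_rate, numeric(1))))
  stopifnot(inherits(x, "inexa_result"))
  60 * mean(x$neuron_counts) / x$T_total
}

#' Per-neuron spike time vectors
#'
#' @param result an `inexa_result`.
#' @return List of numeric spike-time vectors (s), one per neuron.
#' @export
spike_trains <- function(result) {
  stopifnot(inherits(result, "inexa_result"))
  out <- rep(list(numeric(0)), result$n_neurons)
  if (nrow(result$raster)) {
    sp <- split(result$raster$time, result$raster$neuron)
    out[as.integer(names(sp))] <- sp
  }
  out
}

#' Sweep astrocyte activation time and receptor recovery rate
#'
#' Runs the full model (`nn_a`) on a grid of the astrocyte activation time
#' constant `tau_A` and the gliotransmitter receptor recovery rate `omega_g`,
#' recording the mean spike rate over all neurons for each cell of the grid.
#' All grid cells share one topology and one dynamics seed (common random
#' numbers), so differences across the grid reflect the parameters rather
#' than sampling noise.
#'
#' @param tau_A_values activation time constants (s).
#' @param omega_g_values receptor recovery rates (1/s).
#' @param C_max noise ceiling (the sweep is defined at 0.02).
#' @param n_astrocytes astrocyte count (default the 30% ratio).
#' @param params base [inexa_params()]; `tau_A`/`omega_g` are overridden per
#'   cell.
#' @param seed master seed (topology, astrocyte placement, dynamics).
#' @return Matrix of mean spike rates (spikes/min per neuron) with one row
#'   per `tau_A` and one column per `omega_g`, with dimnames.
#' @export
parameter_sweep <- function(tau_A_values = c(1.0, 1.5, 2.5, 3.5, 4.5),
                            omega_g_values = c(0.077, 0.31, 1.24, 4.96,
                                               51.29),
                            C_max = 0.02, n_astrocytes = 107L,
                            params = inexa_params(), seed = 1) {
  sub <- derive_seeds(seed, 3L)
  topology <- build_culture_topology(250, 200, 0,
                                     geometry = params$geometry,
                                     seed = sub[1L])
  topology <- resample_astrocytes(topology, n_astrocytes, seed = sub[2L])
  rates <- matrix(NA_real_, length(tau_A_values), length(omega_g_values),
                  dimnames = list(tau_A = tau_A_values,
                                  omega_g = omega_g_values))
  for (i in seq_along(tau_A_values)) {
    for (j in seq_along(omega_g_values)) {
      p <- inexa_params(
        dt = params$dt, T_total = params$T_total,
        geometry = params$geometry,
        tm = params$tm,
        local = local_params(omega_ip3 = params$local$omega_ip3,
                             omega_acc = params$local$omega_acc,
                             ca_th = params$local$ca_th,
                             g_r = params$local$g_r,
                             omega_g = omega_g_values[j]),
        uar = uar_params(b0 = params$uar$b0, b1 = params$uar$b1,
                         tau_A = tau_A_values[i], tau_R = params$uar$tau_R,
                         tau_U = params$uar$tau_U, M = params$uar$M,
                         y_astro = params$uar$y_astro))
      cfg <- build_scenario("nn_a", C_max, n_astrocytes, n_runs = 1,
                            params = p)
      res <- simulate_culture(topology, cfg, seed = sub[3L])
      rates[i, j] <- mean_spike_rate(res)
    }
  }
  rates
}

#' Write a spike raster as CSV
#'
#' @param result an `inexa_result`.
#' @param path output path; columns `time_s`, `neuron_id`.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(result, path) {
  write.csv(data.frame(time_s = result$raster$time,
                       neuron_id = result$raster$neuron),
            path, row.names = FALSE)
  invisible(path)
}

#' Write the astrocyte state trace as CSV
#'
#' Requires a result simulated with `astro_trace = TRUE`; rows are
#' (time_s, astrocyte_id, state) with state in U/A/R.
#'
#' @param result an `inexa_result` carrying `astro_states`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_astro_trace_csv <- function(result, path) {
  if (is.null(result$astro_states))
    stop("result has no astrocyte state trace; simulate with ",
         "astro_trace = TRUE")
  st <- result$astro_states
  lab <- c("U", "A", "R")
  df <- data.frame(
    time_s = rep((seq_len(ncol(st)) - 1L) * result$dt, each = nrow(st)),
    astrocyte_id = rep(seq_len(nrow(st)), ncol(st)),
    state = lab[as.vector(st) + 1L])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
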