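#' Randomly place cells with a minimum inter-soma distance
#'
#' Cells are placed uniformly at random in the culture box; any cell closer
#' than `min_dist` to an already-placed cell is relocated until all pairwise
#' inter-soma distances satisfy the constraint (rejection sampling with a
#' bounded number of attempts). Uses the current R random number generator
#' state, so results are reproducible after [set.seed()].
#'
#' @param n number of cells to place.
#' @param extent numeric length-3 culture box (um).
#' @param min_dist minimum pairwise inter-soma distance (um).
#' @param max_attempts total relocation budget before an infeasible packing is
#'   signalled.
#' @return An `n` x 3 matrix of positions (um).
#' @export
#' @examples
#' set.seed(1)
#' pos <- place_cells(50, c(750, 750, 10), 30)
#' min(dist(pos)) >= 30
place_cells <- function(n, extent = c(750, 750, 10), min_dist,
                        max_attempts = 1e5) {
  stopifnot(n >= 0, length(extent) == 3, min_dist > 0)
  pos <- matrix(numeric(0), ncol = 3)
  if (n == 0) return(pos)
  pos <- matrix(NA_real_, nrow = n, ncol = 3)
  attempts <- 0L
  for (k in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("place_cells: could not satisfy the minimum-distance ",
             "constraint; packing appears infeasible")
      cand <- runif(3) * extent
      if (k == 1L) { pos[1L, ] <- cand; break }
      d2 <- (pos[seq_len(k - 1L), 1L] - cand[1L])^2 +
            (pos[seq_len(k - 1L), 2L] - cand[2L])^2 +
            (pos[seq_len(k - 1L), 3L] - cand[3L])^2
      if (min(d2) >= min_dist^2) { pos[k, ] <- cand; break }
    }
  }
  pos
}

#' Neuron-neuron connection probability
#'
#' Gaussian fall-off of the probability that a directed synapse forms between
#' two neurons at inter-soma distance `d`:
#' `P_NN(d) = exp(-d^2 / (2 sigma_N^2))`.
#'
#' @param d inter-soma distance (um), non-negative; vectorized.
#' @param sigma_N Gaussian width (um).
#' @return Connection probability in (0, 1].
#' @export
#' @examples
#' neuron_connection_probability(200, 200)  # exp(-0.5)
neuron_connection_probability <- function(d, sigma_N = 200) {
  stopifnot(sigma_N > 0)
  if (any(d < 0)) stop("distances must be non-negative")
  exp(-d^2 / (2 * sigma_N^2))
}

#' Astrocyte-synapse enwrapping probability
#'
#' Gaussian fall-off with a hard cutoff: a synapse at distance `d` from an
#' astrocyte soma is enwrapped with probability
#' `P_AN(d) = exp(-d^2 / (2 sigma_A^2)) * H(d_A - d)` where `H(x) = 1` for
#' `x > 0` and 0 otherwise, so the probability is exactly zero at and beyond
#' the cutoff `d_A`.
#'
#' @param d synapse-to-soma distance (um), non-negative; vectorized.
#' @param sigma_A Gaussian width (um).
#' @param d_A hard cutoff distance (um).
#' @return Enwrapping probability in \[0, 1\].
#' @export
#' @examples
#' astrocyte_synapse_probability(c(0, 50, 70), 150, 70)
astrocyte_synapse_probability <- function(d, sigma_A = 150, d_A = 70) {
  stopifnot(sigma_A > 0, d_A > 0)
  if (any(d < 0)) stop("distances must be non-negative")
  exp(-d^2 / (2 * sigma_A^2)) * as.numeric(d < d_A)
}

#' Build the directed neuronal synapse table
#'
#' Every ordered pair of distinct neurons is connected independently with the
#' Gaussian distance-dependent probability [neuron_connection_probability()].
#' Each realized synapse draws a basal weight magnitude `y_base` from a
#' symmetric triangular distribution on \[0, 0.7\] and inherits its sign from
#' the presynaptic neuron type (+1 excitatory, -1 inhibitory). Autapses are
#' excluded.
#'
#' @param positions `n x 3` matrix of neuron positions (um).
#' @param is_excitatory logical vector of length `n`.
#' @param geometry a [culture_geometry()].
#' @param y_base_max upper bound of the triangular basal-weight distribution.
#' @return A `data.frame` with columns `pre`, `post` (1-based neuron ids),
#'   `y_base` (weight magnitude), `sign` (+1/-1), `distance` (um) and
#'   `astrocyte` (NA until assigned).
#' @export
build_neuron_network <- function(positions, is_excitatory,
                                 geometry = culture_geometry(),
                                 y_base_max = 0.7) {
  n <- nrow(positions)
  stopifnot(length(is_excitatory) == n, is.logical(is_excitatory))
  if (n < 2) {
    return(data.frame(pre = integer(0), post = integer(0),
                      y_base = numeric(0), sign = numeric(0),
                      distance = numeric(0), astrocyte = integer(0)))
  }
  D <- as.matrix(dist(positions))
  P <- neuron_connection_probability(D, geometry$sigma_N)
  diag(P) <- 0
  A <- matrix(runif(n * n), n, n) < P
  idx <- which(A, arr.ind = TRUE)      # row = pre, col = post
  ord <- order(idx[, 2L], idx[, 1L])   # stable post-major ordering
  idx <- idx[ord, , drop = FALSE]
  m <- nrow(idx)
  data.frame(pre = as.integer(idx[, 1L]),
             post = as.integer(idx[, 2L]),
             y_base = rtri(m, y_base_max),
             sign = ifelse(is_excitatory[idx[, 1L]], 1, -1),
             distance = D[idx],
             astrocyte = rep(NA_integer_, m))
}

#' Assign excitatory synapses to astrocytes
#'
#' For each excitatory synapse, astrocytes are tried in order of increasing
#' distance between the astrocyte soma and the synapse site; each candidate
#' within the cutoff `d_A` succeeds with probability
#' [astrocyte_synapse_probability()]. The first success enwraps the synapse;
#' if every candidate fails (or none is within the cutoff) the synapse stays
#' "naked". Inhibitory synapses are never enwrapped.
#'
#' The synapse site defaults to the postsynaptic soma; the presynaptic soma or
#' the midpoint can be selected instead.
#'
#' @param synapses synapse table from [build_neuron_network()].
#' @param neuron_positions `n x 3` neuron position matrix (um).
#' @param astro_positions `n_A x 3` astrocyte position matrix (um).
#' @param geometry a [culture_geometry()].
#' @param synapse_site one of `"post"`, `"pre"`, `"midpoint"`.
#' @return The synapse table with the `astrocyte` column filled (1-based
#'   astrocyte id, or NA for naked synapses).
#' @export
assign_synapses_to_astrocytes <- function(synapses, neuron_positions,
                                          astro_positions,
                                          geometry = culture_geometry(),
                                          synapse_site = c("post", "pre",
                                                           "midpoint")) {
  synapse_site <- match.arg(synapse_site)
  synapses$astrocyte <- NA_integer_
  n_astro <- if (is.null(astro_positions)) 0L else nrow(astro_positions)
  if (n_astro == 0L || nrow(synapses) == 0L) return(synapses)

  site <- switch(synapse_site,
    post = neuron_positions[synapses$post, , drop = FALSE],
    pre = neuron_positions[synapses$pre, , drop = FALSE],
    midpoint = (neuron_positions[synapses$post, , drop = FALSE] +
                neuron_positions[synapses$pre, , drop = FALSE]) / 2)

  excit <- which(synapses$sign > 0)
  if (length(excit) == 0L) return(synapses)

  # Synapses sharing a site have identical candidate lists; group them so the
  # sorted-distance work is done once per site.
  key <- interaction(round(site[excit, 1L], 9), round(site[excit, 2L], 9),
                     round(site[excit, 3L], 9), drop = TRUE)
  for (grp in split(excit, key)) {
    s <- site[grp[1L], ]
    d <- sqrt((astro_positions[, 1L] - s[1L])^2 +
              (astro_positions[, 2L] - s[2L])^2 +
              (astro_positions[, 3L] - s[3L])^2)
    cand <- which(d < geometry$d_A)
    if (length(cand) == 0L) next
    cand <- cand[order(d[cand])]
    p <- astrocyte_synapse_probability(d[cand], geometry$sigma_A,
                                       geometry$d_A)
    # first Bernoulli success along the distance-ordered candidates
    U <- matrix(runif(length(grp) * length(cand)), nrow = length(grp))
    hit <- U < matrix(p, nrow = length(grp), ncol = length(cand),
                      byrow = TRUE)
    first <- apply(hit, 1L, function(row) {
      w <- which(row)
      if (length(w)) w[1L] else NA_integer_
    })
    synapses$astrocyte[grp] <- ifelse(is.na(first), NA_integer_,
                                      cand[first])
  }
  synapses
}

#' Build the astrocytic gap-junction graph
#'
#' Two astrocytes are coupled by a gap junction iff their inter-soma distance
#' is strictly smaller than the connection cutoff. The graph is undirected and
#' has no self-edges; construction is deterministic given the positions.
#'
#' @param astro_positions `n_A x 3` astrocyte position matrix (um).
#' @param gap_cutoff connection distance cutoff (um).
#' @return List with `edges` (data.frame `a`, `b`, `distance`, with `a < b`),
#'   `degree` (per-astrocyte neighbour count `n_a`) and `neighbors` (list of
#'   neighbour id vectors).
#' @export
build_gap_junctions <- function(astro_positions, gap_cutoff = 100) {
  n_astro <- if (is.null(astro_positions)) 0L else nrow(astro_positions)
  if (n_astro <= 1L) {
    return(list(edges = data.frame(a = integer(0), b = integer(0),
                                   distance = numeric(0)),
                degree = rep(0L, n_astro),
                neighbors = rep(list(integer(0)), n_astro)))
  }
  D <- as.matrix(dist(astro_positions))
  A <- D < gap_cutoff
  diag(A) <- FALSE
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  edges <- data.frame(a = as.integer(idx[, 1L]), b = as.integer(idx[, 2L]),
                      distance = D[idx])
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  degree <- as.integer(rowSums(A))
  neighbors <- lapply(seq_len(n_astro), function(a) which(A[a, ]))
  list(edges = edges, degree = degree, neighbors = neighbors)
}

#' Generate a complete culture topology
#'
#' Places neurons and astrocytes on the virtual MEA, wires the directed
#' neuronal synapse table, assigns excitatory synapses to astrocytes and
#' builds the gap-junction graph. Per-neuron unit noise quantiles (scaled by
#' the scenario noise ceiling `C_max` at simulation time) are drawn here so
#' that the same neuronal network keeps the same noise structure across
#' scenarios.
#'
#' @param n_neurons total number of neurons.
#' @param n_excitatory number of excitatory neurons (the first
#'   `n_excitatory` ids; the rest are inhibitory).
#' @param n_astrocytes number of astrocytes (0 for purely neuronal networks).
#' @param geometry a [culture_geometry()].
#' @param seed optional integer; when given, the whole construction is
#'   seeded and reproducible.
#' @param synapse_site synapse location convention, see
#'   [assign_synapses_to_astrocytes()].
#' @return Object of class `culture_topology`: a list with `neuron_positions`,
#'   `is_excitatory`, `c_unit` (unit triangular noise quantiles),
#'   `synapses`, `astro_positions`, `gap`, `geometry`, `synapse_site`.
#' @export
#' @examples
#' top <- build_culture_topology(n_neurons = 40, n_excitatory = 32,
#'                               n_astrocytes = 8, seed = 1)
#' topology_statistics(top)
build_culture_topology <- function(n_neurons = 250, n_excitatory = 200,
                                   n_astrocytes = 0,
                                   geometry = culture_geometry(),
                                   seed = NULL,
                                   synapse_site = "post") {
  stopifnot(n_excitatory >= 0, n_excitatory <= n_neurons, n_astrocytes >= 0)
  if (!is.null(seed)) set.seed(seed)
  neuron_positions <- place_cells(n_neurons, geometry$extent,
                                  geometry$min_neuron_dist)
  is_excitatory <- seq_len(n_neurons) <= n_excitatory
  c_unit <- rtri(n_neurons, 1)
  synapses <- build_neuron_network(neuron_positions, is_excitatory, geometry)
  top <- structure(list(neuron_positions = neuron_positions,
                        is_excitatory = is_excitatory,
                        c_unit = c_unit,
                        synapses = synapses,
                        astro_positions = NULL,
                        gap = build_gap_junctions(NULL, geometry$gap_cutoff),
                        geometry = geometry,
                        synapse_site = synapse_site),
                   class = "culture_topology")
  if (n_astrocytes > 0) top <- resample_astrocytes(top, n_astrocytes)
  top
}

#' Resample the astrocytic network on an existing neuronal network
#'
#' Re-places the astrocytes, re-assigns excitatory synapses and rebuilds the
#' gap-junction graph while keeping the neuronal network (positions, synapse
#' table, basal weights, noise quantiles) untouched. This is the per-run
#' resampling used by [run_experiment()].
#'
#' @param topology a `culture_topology`.
#' @param n_astrocytes number of astrocytes to place.
#' @param seed optional integer seed for the resampling.
#' @return The topology with new `astro_positions`, `gap` and synapse
#'   `astrocyte` assignments.
#' @export
resample_astrocytes <- function(topology, n_astrocytes, seed = NULL) {
  stopifnot(inherits(topology, "culture_topology"), n_astrocytes >= 0)
  if (!is.null(seed)) set.seed(seed)
  geometry <- topology$geometry
  if (n_astrocytes == 0) {
    topology$astro_positions <- NULL
    topology$gap <- build_gap_junctions(NULL, geometry$gap_cutoff)
    topology$synapses$astrocyte <- NA_integer_
    return(topology)
  }
  astro_positions <- place_cells(n_astrocytes, geometry$extent,
                                 geometry$min_astro_dist)
  topology$astro_positions <- astro_positions
  topology$synapses <- assign_synapses_to_astrocytes(
    topology$synapses, topology$neuron_positions, astro_positions,
    geometry, topology$synapse_site)
  topology$gap <- build_gap_junctions(astro_positions, geometry$gap_cutoff)
  topology
}

#' @export
print.culture_topology <- function(x, ...) {
  n <- nrow(x$neuron_positions)
  n_astro <- if (is.null(x$astro_positions)) 0L else nrow(x$astro_positions)
  cat("Culture topology:", n, "neurons (", sum(x$is_excitatory),
      "excitatory ),", n_astro, "astrocytes\n")
  cat("  synapses:", nrow(x$synapses),
      sprintf("(%.2f%% of %d possible)", 100 * nrow(x$synapses) /
                (n * (n - 1)), n * (n - 1)), "\n")
  if (n_astro > 0)
    cat("  gap junctions:", nrow(x$gap$edges), "edges\n")
  invisible(x)
}

#' Topology summary statistics
#'
#' Computes the standard summary measures of a generated culture: possible and
#' realized directed connection counts, connectivity percentage, mean
#' out-degree, mean connection length, bidirectionally connected pair count,
#' mean enwrapped synapses and gap junctions per astrocyte, the percentage of
#' naked (astrocyte-free) excitatory synapses and the mean gap-junction
#' distance.
#'
#' @param topology a `culture_topology`.
#' @return Object of class `topology_stats` (a named list of scalars).
#' @export
topology_statistics <- function(topology) {
  stopifnot(inherits(topology, "culture_topology"))
  n <- nrow(topology$neuron_positions)
  syn <- topology$synapses
  realized <- nrow(syn)
  max_connections <- n * (n - 1)
  key_fwd <- paste(syn$pre, syn$post)
  key_rev <- paste(syn$post, syn$pre)
  bidirectional_pairs <- sum(key_rev %in% key_fwd) / 2
  n_astro <- if (is.null(topology$astro_positions)) 0L
             else nrow(topology$astro_positions)
  excit <- syn$sign > 0
  n_excit <- sum(excit)
  assigned <- sum(!is.na(syn$astrocyte[excit]))
  structure(list(
    n_neurons = n,
    n_astrocytes = n_astro,
    max_connections = max_connections,
    realized_connections = realized,
    connectivity_pct = 100 * realized / max_connections,
    mean_connections_per_neuron = realized / n,
    mean_connection_length = if (realized) mean(syn$distance) else NA_real_,
    bidirectional_pairs = bidirectional_pairs,
    n_excitatory_synapses = n_excit,
    synapses_per_astrocyte = if (n_astro) assigned / n_astro else NA_real_,
    gap_junctions_per_astrocyte = if (n_astro) mean(topology$gap$degree)
                                  else NA_real_,
    naked_synapse_pct = if (n_excit) 100 * (n_excit - assigned) / n_excit
                        else NA_real_,
    mean_gap_distance = if (nrow(topology$gap$edges))
                          mean(topology$gap$edges$distance) else NA_real_
  ), class = "topology_stats")
}

#' @export
print.topology_stats <- function(x, ...) {
  cat("Topology statistics\n")
  fmt <- function(v) if (is.na(v)) "-" else format(round(v, 2))
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, fmt(x[[nm]])))
  invisible(x)
}

#' Serialize a topology to JSON
#'
#' Writes positions, the synapse table and the gap-junction edges to a JSON
#' file that [read_topology_json()] round-trips.
#'
#' @param topology a `culture_topology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  stopifnot(inherits(topology, "culture_topology"))
  obj <- list(
    geometry = unclass(topology$geometry),
    synapse_site = topology$synapse_site,
    neuron_positions = topology$neuron_positions,
    is_excitatory = topology$is_excitatory,
    c_unit = topology$c_unit,
    synapses = topology$synapses,
    astro_positions = topology$astro_positions,
    gap_edges = topology$gap$edges)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a topology from JSON
#'
#' @param path file written by [write_topology_json()].
#' @return A `culture_topology`.
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geometry <- do.call(culture_geometry, as.list(obj$geometry))
  syn <- as.data.frame(obj$synapses)
  syn$astrocyte <- as.integer(syn$astrocyte)
  astro <- if (is.null(obj$astro_positions)) NULL
           else as.matrix(obj$astro_positions)
  structure(list(neuron_positions = as.matrix(obj$neuron_positions),
                 is_excitatory = as.logical(obj$is_excitatory),
                 c_unit = as.numeric(obj$c_unit),
                 synapses = syn,
                 astro_positions = astro,
                 gap = build_gap_junctions(astro, geometry$gap_cutoff),
                 geometry = geometry,
                 synapse_site = obj$synapse_site),
            class = "culture_topology")
}

#' Write the synapse table as CSV
#'
#' @param topology a `culture_topology`.
#' @param path output CSV path; columns `pre_id`, `post_id`, `y_base`,
#'   `sign`, `astrocyte_id`.
#' @return `path`, invisibly.
#' @export
write_synapse_csv <- function(topology, path) {
  syn <- topology$synapses
  out <- data.frame(pre_id = syn$pre, post_id = syn$post,
                    y_base = syn$y_base, sign = syn$sign,
                    astrocyte_id = syn$astrocyte)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
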