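# Spatial placement, wiring rules and topology statistics.

test_that("place_cells enforces the minimum inter-soma distance", {
  expect_equal(nrow(place_cells(0, min_dist = 10)), 0)
  set.seed(11)
  pos <- place_cells(250, c(750, 750, 10), 10)
  expect_equal(dim(pos), c(250, 3))
  expect_true(all(pos >= 0 & pos <= rep(c(750, 750, 10), each = 250)))
  expect_gte(min(dist(pos)), 10)
  pos_a <- place_cells(107, c(750, 750, 10), 30)
  expect_gte(min(dist(pos_a)), 30)
  # reproducible given the seed
  set.seed(11)
  expect_identical(place_cells(250, c(750, 750, 10), 10), pos)
  # infeasible packing is signalled, not looped forever
  expect_error(place_cells(100, c(20, 20, 1), 19, max_attempts = 2000),
               "infeasible")
})

test_that("connection probabilities follow the Gaussian forms", {
  expect_equal(neuron_connection_probability(0, 200), 1)
  expect_equal(neuron_connection_probability(200, 200), exp(-0.5),
               tolerance = 1e-9)
  expect_equal(neuron_connection_probability(600, 200), exp(-4.5),
               tolerance = 1e-9)
  expect_error(neuron_connection_probability(-1), "non-negative")
  expect_equal(astrocyte_synapse_probability(0, 150, 70), 1)
  expect_equal(astrocyte_synapse_probability(70, 150, 70), 0)  # H(0) = 0
  expect_equal(astrocyte_synapse_probability(50, 150, 70),
               exp(-2500 / 45000), tolerance = 1e-9)
  expect_equal(astrocyte_synapse_probability(120, 150, 70), 0)
})

test_that("neuron network realizes edges at the Gaussian frequency", {
  set.seed(5)
  # one neuron: no pairs
  empty <- build_neuron_network(matrix(c(1, 1, 1), 1), TRUE)
  expect_equal(nrow(empty), 0)
  # two neurons at fixed distance: per-direction frequency over many draws
  pos <- rbind(c(0, 0, 0), c(200, 0, 0))
  n_rep <- 4000
  hits <- replicate(n_rep, {
    syn <- build_neuron_network(pos, c(TRUE, FALSE))
    nrow(syn)
  })
  p <- exp(-0.5)
  expect_lt(abs(mean(hits) / 2 - p), 4 * sqrt(p * (1 - p) / (2 * n_rep)))
  # properties of one realized table
  set.seed(6)
  top <- build_culture_topology(60, 48, 0, seed = 6)
  syn <- top$synapses
  expect_true(all(syn$pre != syn$post))                       # no autapses
  expect_true(all(syn$y_base >= 0 & syn$y_base <= 0.7))
  expect_true(all(syn$sign == ifelse(top$is_excitatory[syn$pre], 1, -1)))
})

test_that("bidirectional pairs are consistent with independent directions", {
  # over seeds, E[#bidirectional] = sum over pairs of P(d)^2
  counts <- numeric(12); expected <- numeric(12)
  for (s in 1:12) {
    top <- build_culture_topology(80, 64, 0, seed = 100 + s)
    st <- topology_statistics(top)
    counts[s] <- st$bidirectional_pairs
    D <- as.matrix(dist(top$neuron_positions))
    P2 <- neuron_connection_probability(D[upper.tri(D)], 200)^2
    expected[s] <- sum(P2)
  }
  se <- sd(counts - expected) / sqrt(12)
  expect_lt(abs(mean(counts - expected)), 3 * se + 1e-9)
})

test_that("astrocyte assignment respects the cutoff and nearest-first rule", {
  set.seed(21)
  top <- build_culture_topology(50, 40, 10, seed = 21)
  syn <- top$synapses
  assigned <- which(!is.na(syn$astrocyte))
  expect_gt(length(assigned), 0)
  # never linked beyond the cutoff, measured at the postsynaptic soma
  d_assigned <- sqrt(rowSums((top$neuron_positions[syn$post[assigned], ,
                                                   drop = FALSE] -
    top$astro_positions[syn$astrocyte[assigned], , drop = FALSE])^2))
  expect_true(all(d_assigned < top$geometry$d_A))
  # inhibitory synapses are always naked
  expect_true(all(is.na(syn$astrocyte[syn$sign < 0])))
  # no astrocytes: all naked
  top0 <- resample_astrocytes(top, 0L)
  expect_true(all(is.na(top0$synapses$astrocyte)))
  expect_equal(topology_statistics(top0)$naked_synapse_pct, 100)
  # a single astrocyte beyond the cutoff from every synapse: all naked
  far <- top
  far$astro_positions <- matrix(c(5000, 5000, 5), 1)
  far$synapses$astrocyte <- NA_integer_
  far$synapses <- assign_synapses_to_astrocytes(
    far$synapses, far$neuron_positions, far$astro_positions, far$geometry)
  expect_true(all(is.na(far$synapses$astrocyte)))
})

test_that("more astrocytes mean fewer naked synapses and fewer per cell", {
  top <- build_culture_topology(100, 80, 0, seed = 31)
  stats <- lapply(c(10L, 30L, 60L), function(na) {
    topology_statistics(resample_astrocytes(top, na, seed = 32))
  })
  naked <- vapply(stats, `[[`, numeric(1), "naked_synapse_pct")
  per_astro <- vapply(stats, `[[`, numeric(1), "synapses_per_astrocyte")
  expect_true(all(diff(naked) < 0))
  expect_true(all(diff(per_astro) < 0))
})

test_that("gap junctions form strictly below the cutoff", {
  one <- build_gap_junctions(matrix(c(0, 0, 0), 1), 100)
  expect_equal(nrow(one$edges), 0)
  near <- build_gap_junctions(rbind(c(0, 0, 0), c(99, 0, 0)), 100)
  expect_equal(nrow(near$edges), 1)
  expect_equal(near$degree, c(1L, 1L))
  far <- build_gap_junctions(rbind(c(0, 0, 0), c(101, 0, 0)), 100)
  expect_equal(nrow(far$edges), 0)
  # symmetry of the neighbour lists
  set.seed(8)
  gap <- build_gap_junctions(place_cells(30, min_dist = 30), 100)
  for (a in seq_along(gap$neighbors)) {
    for (b in gap$neighbors[[a]]) {
      expect_true(a %in% gap$neighbors[[b]])
    }
  }
})

test_that("topology statistics match hand-computed values on a fixture", {
  # five neurons on a line, hand-placed; wiring replaced by a known table
  top <- build_culture_topology(5, 4, 0, seed = 41)
  top$neuron_positions <- cbind(c(0, 100, 200, 300, 400), 0, 0)
  top$synapses <- data.frame(
    pre = c(1L, 2L, 2L, 4L), post = c(2L, 1L, 3L, 5L),
    y_base = 0.3, sign = c(1, 1, 1, -1),
    distance = c(100, 100, 100, 100), astrocyte = NA_integer_)
  st <- topology_statistics(top)
  expect_equal(st$max_connections, 20)
  expect_equal(st$realized_connections, 4)
  expect_equal(st$connectivity_pct, 100 * 4 / 20)
  expect_equal(st$mean_connections_per_neuron, 4 / 5)
  expect_equal(st$mean_connection_length, 100)
  expect_equal(st$bidirectional_pairs, 1)   # 1<->2 only
  expect_equal(st$naked_synapse_pct, 100)
  # 250-neuron contract for the possible-connection count
  expect_equal(250 * 249, 62250)
})

test_that("topology serialization round-trips through JSON and CSV", {
  top <- build_culture_topology(25, 20, 6, seed = 51)
  path <- tempfile(fileext = ".json")
  write_topology_json(top, path)
  back <- read_topology_json(path)
  expect_equal(back$neuron_positions, top$neuron_positions,
               ignore_attr = TRUE)
  expect_equal(back$synapses$y_base, top$synapses$y_base)
  expect_equal(back$synapses$astrocyte, top$synapses$astrocyte)
  expect_equal(back$gap$edges$distance, top$gap$edges$distance)
  expect_equal(unclass(back$geometry), unclass(top$geometry))
  csv <- tempfile(fileext = ".csv")
  write_synapse_csv(top, csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), nrow(top$synapses))
  expect_named(tab, c("pre_id", "post_id", "y_base", "sign", "astrocyte_id"))
})
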