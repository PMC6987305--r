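# Closed-form checks of the elementary update rules, each against values
# computed independently from the model equations, plus the basic invariants
# of each rule.

tol <- testthat_tolerance()

test_that("firing intensity combines noise, synaptic drive and depression", {
  expect_equal(firing_rate(0.02), 0.02)
  expect_equal(firing_rate(0.01, c(1, 1), c(0.3, 0.5),
                           active_enwrapped = 3, y_astro = 0.01),
               0.01 + 0.8 - 0.03)
  # rectification at zero for dominant inhibition
  expect_equal(firing_rate(0.01, 1, -0.7), 0)
  # non-spiking inputs contribute nothing
  expect_equal(firing_rate(0.05, c(0, 0), c(0.7, -0.7)), 0.05)
})

test_that("spike probability is the one-event Poisson mass", {
  expect_equal(spike_probability(0), 0)
  expect_equal(spike_probability(10, 0.005), exp(-0.05) * 0.05,
               tolerance = 1e-9)
  # global maximum exp(-1) at lambda * dt = 1
  expect_equal(spike_probability(200, 0.005), exp(-1), tolerance = 1e-9)
  mu <- seq(0, 1, by = 0.01)
  expect_true(all(diff(spike_probability(mu)) > 0))
  expect_true(all(spike_probability(seq(0, 50, by = 0.1)) <= exp(-1) + tol))
  expect_error(spike_probability(-1), "non-negative")
})

test_that("spike sampling matches its probabilities", {
  set.seed(1)
  expect_identical(sample_spikes(rep(0, 5)), integer(5))
  expect_identical(sample_spikes(rep(1, 5)), rep(1L, 5))
  s <- sample_spikes(rep(0.5, 1e4))
  # binomial 3-sigma band around 0.5
  expect_lt(abs(mean(s) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("TM update matches the discretized closed forms", {
  p <- tm_params()
  dt <- 0.005
  # rest is a fixed point without spikes
  rest <- update_tm(1, 0, 0.5, s = 0, p, dt)
  expect_equal(rest$x, 1)
  expect_equal(rest$u, 0)
  expect_equal(rest$RR, 0)
  # spike from rest: independent arithmetic for RR, u, x
  st <- update_tm(1, 0, U_star = 0.5, s = 1, p, dt)
  expect_equal(st$RR, 0.5, tolerance = 1e-9)
  expect_equal(st$u, 0.5 * exp(-2.0 * dt), tolerance = 1e-9)
  expect_equal(st$x, 0.5 + 0.5 * (1 - exp(-4.0405 * dt)), tolerance = 1e-9)
  # silent decay step
  st2 <- update_tm(0.5, 0.2, 0.5, s = 0, p, dt)
  expect_equal(st2$RR, 0)
  expect_equal(st2$u, 0.2 * exp(-0.01), tolerance = 1e-9)
  expect_equal(st2$x, 0.5 + 0.5 * (1 - exp(-0.0202025)), tolerance = 1e-9)
})

test_that("TM state stays in [0,1] under random spike trains and recovers", {
  p <- tm_params()
  set.seed(42)
  x <- runif(2000); u <- runif(2000)
  for (k in 1:50) {
    st <- update_tm(x, u, U_star = runif(2000), s = rbinom(1, 1, 0.5),
                    p, dt = 0.005)
    x <- st$x; u <- st$u
    expect_true(all(st$x >= 0 & st$x <= 1))
    expect_true(all(st$u >= 0 & st$u <= 1))
    expect_true(all(st$RR >= 0 & st$RR <= 1))
  }
  # geometric relaxation to rest at the stated rates
  x <- 0.2; u <- 0.9
  for (k in 1:3) {
    st <- update_tm(x, u, 0.5, s = 0, p, dt = 0.005)
    expect_equal(1 - st$x, (1 - x) * exp(-p$omega_d * 0.005),
                 tolerance = 1e-9)
    expect_equal(st$u, u * exp(-p$omega_f * 0.005), tolerance = 1e-9)
    x <- st$x; u <- st$u
  }
})

test_that("short-term depression emerges under high-frequency drive", {
  p <- tm_params()
  x <- 1; u <- 0; rr <- numeric(20)
  for (k in 1:20) {    # a spike every bin (200 Hz)
    st <- update_tm(x, u, U_star = 0.5, s = 1, p, dt = 0.005)
    x <- st$x; u <- st$u; rr[k] <- st$RR
  }
  expect_lt(mean(rr[11:20]), mean(rr[1:2]))
})

test_that("synaptic weight is proportional to released resources", {
  expect_equal(synaptic_weight(0, 0.7), 0)
  expect_equal(synaptic_weight(0.5, 0.7), 0.35)
  expect_equal(synaptic_weight(0.5, -0.7), -0.35)
})

test_that("release increment interpolates basal to alpha with g", {
  expect_equal(release_increment(0.35, 0.7, g = 0), 0.5)
  expect_equal(release_increment(0.35, 0.7, g = 1), 0.7)
  expect_equal(release_increment(0.35, 0.7, g = 0.5), 0.6)
  # monotone increasing in g in the potentiating regime
  g <- seq(0, 1, by = 0.05)
  expect_true(all(diff(release_increment(0.2, 0.7, g, alpha = 0.7)) > 0))
  expect_error(release_increment(0.35, 0, 0.5), "non-zero")
})

test_that("IP3 update follows degradation plus saturating production", {
  lp <- local_params()
  expect_equal(update_ip3(0, 0, lp), 0)
  expect_equal(update_ip3(1, 0, lp), exp(-0.7615), tolerance = 1e-9)
  e <- 0.5 * exp(-0.7615)
  expect_equal(update_ip3(0.5, 0.2, lp), e + (1 - e) * 0.2,
               tolerance = 1e-9)
  # forcing during astrocyte activation pins IP3 at its maximum
  expect_equal(update_ip3(0.3, 0.1, lp, forced = TRUE), 1)
})

test_that("calcium relaxes toward IP3 with the per-bin gain", {
  expect_equal(update_calcium(0.4, 0.4), 0.4)
  expect_equal(update_calcium(0, 1, 0.05), 0.05)
  expect_equal(update_calcium(0.2, 0.1, 0.05), 0.195)
})

test_that("gliotransmitter release triggers on upward threshold crossings", {
  lp <- local_params()
  e_g <- exp(-0.077 * 0.005)
  expect_equal(update_gliotransmitter(0, 0.05, 0.06, lp), 0)
  expect_equal(update_gliotransmitter(0, 0.09, 0.12, lp), 0.3 * e_g,
               tolerance = 1e-9)
  expect_equal(update_gliotransmitter(0.3, 0.5, 0.6, lp), 0.3 * e_g,
               tolerance = 1e-9)
  # staying above threshold does not re-trigger (latching)
  expect_equal(update_gliotransmitter(0.3, 0.15, 0.2, lp), 0.3 * e_g)
  # repeated crossings compound toward saturation: g' = g + (1-g) g_r
  g <- 0
  for (k in 1:50) g <- update_gliotransmitter(g, 0.09, 0.12, lp)
  expect_true(g < 1 && g > 0.9)
})

test_that("propagation efficiency splits over non-active neighbours", {
  expect_equal(propagation_efficiency("U", c("A", "U")), 0)
  expect_equal(propagation_efficiency("R", c("A", "U")), 0)
  expect_equal(propagation_efficiency("A", c("A", "U", "U", "R")), 1 / 3)
  expect_equal(propagation_efficiency("A", c("A", "A")), 0)
  expect_equal(propagation_efficiency("A", character(0)), 0)
})

test_that("activation threshold is linear in the neighbour count", {
  expect_equal(activation_threshold(0), 0.205)
  expect_equal(activation_threshold(5), 0.305)
  n <- 0:12
  th <- activation_threshold(n, b0 = 0.02, b1 = 0.205)
  expect_equal(th, 0.02 * n + 0.205)
})

test_that("activation propensity combines neighbour input and calcium", {
  expect_equal(activation_propensity(0.305), 0)
  expect_equal(activation_propensity(0.305, neighbor_betas = c(0.5, 0.5)),
               0.305)
  expect_equal(activation_propensity(0.305, sum_local_ca = 2, N_syn = 100,
                                     M = 5), 0.1)
  # no enwrapped synapse: the calcium term vanishes instead of dividing by 0
  expect_equal(activation_propensity(0.205, sum_local_ca = 3, N_syn = 0), 0)
})

test_that("UAR transitions use the stated per-bin probabilities", {
  up <- uar_params()
  dt <- 0.005
  expect_equal(dt / up$tau_A, 0.005 / 1.5, tolerance = 1e-12)
  expect_equal(dt / up$tau_R, 0.005 / 7, tolerance = 1e-12)
  expect_equal(dt / up$tau_U, 0.001, tolerance = 1e-12)
  # subthreshold propensity: U is absorbing
  set.seed(7)
  s <- rep("U", 1000)
  s2 <- update_astrocyte_states(s, gammas = rep(0, 1000),
                                thetas = rep(0.205, 1000), up, dt)
  expect_identical(s2, s)
  # empirical transition frequencies within 4-sigma binomial bands
  freq <- function(from, gamma, p_expect, n = 2e5) {
    out <- update_astrocyte_states(rep(from, n), rep(gamma, n),
                                   rep(0.205, n), up, dt)
    c(mean(out != from), p_expect, 4 * sqrt(p_expect / n))
  }
  for (case in list(freq("U", 1, dt / up$tau_A),
                    freq("A", 0, dt / up$tau_R),
                    freq("R", 0, dt / up$tau_U))) {
    expect_lt(abs(case[1] - case[2]), case[3])
  }
})

test_that("astrocytic depression counts enwrapped active presynapses", {
  expect_equal(depression_term(c(NA, NA), active = c(TRUE, TRUE)), 0)
  expect_equal(depression_term(c(1L, 1L, 2L, NA), c(TRUE, TRUE)), 0.03)
  expect_equal(depression_term(c(1L, 2L), c(FALSE, FALSE)), 0)
})
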