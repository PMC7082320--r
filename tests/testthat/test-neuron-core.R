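test_that("psp_kernel is causal, non-negative, and vanishes at the origin", {
  p <- neuron_params()
  expect_identical(psp_kernel(-1, 5, p), 0)
  expect_identical(psp_kernel(5, -1, p), 0)
  expect_equal(psp_kernel(0, 0, p), 0)
  set.seed(11)
  s <- runif(500, -10, 60)
  t <- runif(500, -10, 60)
  expect_true(all(psp_kernel(s, t, p) >= 0))
  expect_true(all(psp_kernel(s, t, p)[s < 0 | t < 0] == 0))
})

test_that("psp_kernel matches numerical quadrature of the defining integral", {
  p <- neuron_params(tau_m = 16, tau_s = 4)
  grid <- expand.grid(s = seq(0.5, 40, length.out = 20),
                      t = seq(0.5, 40, length.out = 20))
  v_closed <- psp_kernel(grid$s, grid$t, p)
  v_quad <- mapply(psp_kernel_quadrature, grid$s, grid$t,
                   MoreArgs = list(tau_m = 16, tau_s = 4))
  expect_lt(max(abs(v_closed - v_quad) / v_quad), 1e-3)
  # spot value from the spec's example point
  expect_equal(psp_kernel(8, 3, p), psp_kernel_quadrature(8, 3), tolerance = 1e-9)
})

test_that("degenerate time constants are rejected", {
  expect_error(neuron_params(tau_m = 4, tau_s = 4), "tau_m > tau_s")
  expect_error(neuron_params(tau_m = 2, tau_s = 4), "tau_m > tau_s")
  expect_error(neuron_params(threshold = 0), "threshold")
})

test_that("lif_step decays, integrates, fires at threshold and resets", {
  p <- neuron_params()
  st <- layer_state_init(2)
  # zero input, zero state: stays zero
  st0 <- lif_step(st, c(0, 0), p)
  expect_equal(st0$u, c(0, 0))
  expect_equal(st0$fired, c(0L, 0L))

  # constant current with an unreachable threshold converges monotonically
  # to the closed-form steady state of the linear recurrence:
  # alpha* = c, u* = tau_m * alpha*
  p_inf <- neuron_params(threshold = 1e12)
  c0 <- 0.3
  st <- layer_state_init(1)
  us <- numeric(400)
  for (i in 1:400) {
    st <- lif_step(st, c0, p_inf)
    us[i] <- st$u
  }
  expect_true(all(diff(us) >= -1e-12))
  expect_equal(st$u, p_inf$tau_m * c0, tolerance = 1e-3)

  # a neuron just below threshold plus a strong pulse fires and resets
  st <- list(u = 0.99, alpha = 0, fired = 0L)
  out <- lif_step(st, 10, p)
  expect_equal(out$fired, 1L)
  expect_equal(out$u, p$reset)
})

test_that("forward_pass propagates silence and validates inputs", {
  net <- snn_network(c(4, 5, 2), seed = 1)
  fw <- forward_pass(net, matrix(0L, 4, 30))
  expect_true(all(vapply(fw$counts[-1], sum, numeric(1)) == 0))
  expect_true(all(vapply(fw$e, sum, numeric(1)) == 0))
  expect_error(forward_pass(net, matrix(0L, 3, 30)), "input neurons")
  expect_error(forward_pass(net, matrix(0L, 4, 0)), "horizon")
})

test_that("a single strong synapse transmits a spike and accrues S-PSP", {
  net <- snn_network(c(1, 1), seed = 1)
  net$weights[[1]][1, 1] <- 50
  x <- matrix(0L, 1, 40)
  x[1, 5] <- 1L
  fw <- forward_pass(net, x)
  expect_gte(fw$counts[[2]], 1)
  expect_gt(fw$e[[1]][1, 1], 0)
})

test_that("compiled trial simulation equals the single-step operation path", {
  p <- neuron_params()
  set.seed(21)
  for (rep in 1:5) {
    n_pre <- sample(3:8, 1)
    n_post <- sample(2:6, 1)
    T <- 80
    net <- snn_network(c(n_pre, n_post), params = p, seed = rep)
    x <- matrix(rbinom(n_pre * T, 1L, runif(1, 0.05, 0.3)), n_pre, T)
    fw <- forward_pass(net, x)
    ref <- layer_forward_stepwise(net$weights[[1]], x, p)
    expect_identical(fw$spikes[[2]], ref$spikes)
    expect_identical(fw$e[[1]], ref$e)
  }
})

test_that("forward pass is deterministic for identical inputs", {
  net <- snn_network(c(6, 8, 3), seed = 4)
  set.seed(5)
  x <- matrix(rbinom(6 * 100, 1L, 0.2), 6, 100)
  f1 <- forward_pass(net, x)
  f2 <- forward_pass(net, x)
  expect_identical(f1, f2)
})

test_that("firing counts track the threshold-scaled total PSP", {
  # o ~ a / nu with a = sum_j w_ij e_{i|j}; each firing consumes at least nu
  # of accumulated potential, with bounded overshoot, so a/nu >= o and the
  # two stay close in rate-driven regimes.
  set.seed(9)
  net <- snn_network(c(10, 6), seed = 5, init_scale = 3)
  x <- matrix(rbinom(10 * 200, 1L, 0.25), 10, 200)
  fw <- forward_pass(net, x)
  o <- fw$counts[[2]]
  a <- rowSums(net$weights[[1]] * fw$e[[1]])
  nu <- net$params$threshold
  expect_true(all(a / nu >= o - 1e-9))
  active <- o > 5
  expect_true(any(active))
  expect_true(all(a[active] / nu <= 1.6 * o[active] + 1))
})

test_that("spike trains convert losslessly between representations", {
  tr <- spike_train(c(0, 7, 19), horizon = 20)
  expect_identical(as_spike_train(spike_indicator(tr)), tr)
  expect_error(spike_train(c(3, 3), 10), "strictly increasing")
  expect_error(spike_train(c(3, 25), 10), "horizon")

  m <- matrix(rbinom(40, 1L, 0.3), 4, 10)
  storage.mode(m) <- "integer"
  tab <- spikes_to_table(m)
  expect_identical(table_to_spikes(tab, 4, 10), m)
})
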