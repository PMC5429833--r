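test_that("dense long sampling reproduces the universal semicircle", {
  ax <- sampled_axis(seq(0, 100 * 50, length.out = 4096), "echo_time")
  loc <- build_reference_locus(ax, tau_min = 5, tau_max = 50, n_grid = 64)
  dev <- abs(sqrt((loc$re - 0.5)^2 + loc$im^2) - 0.5)
  expect_lt(max(dev), 1e-3)
  # closed-form continuous limit, verified independently (absolute error)
  for (tt in c(5, 20, 50)) {
    g <- oracle_continuous(tt, 100 * 50)
    s <- exp(-ax$values / tt)
    p <- compute_phasor(s)
    expect_lt(abs(p$re - Re(g)), 1e-3)
    expect_lt(abs(p$im - Im(g)), 1e-3)
  }
})

test_that("the 4-echo subset locus deviates from the semicircle", {
  ax4 <- sampled_axis(7.23 * c(4, 20, 36, 52), "echo_time")
  loc <- build_reference_locus(ax4)
  dev <- abs(sqrt((loc$re - 0.5)^2 + loc$im^2) - 0.5)
  expect_gt(max(dev), 0.01)
  # fast-decay end of the grid approaches (1, 0)
  expect_gt(loc$re[1], 0.999)
  expect_lt(abs(loc$im[1]), 1e-3)
  expect_true(all(diff(loc$phase) > 0))
})

test_that("phase inversion round-trips mono-exponential decays", {
  ax <- axis64()
  loc <- build_reference_locus(ax)
  p <- compute_phasor(exp(-(ax$values - ax$values[1]) / 105))
  tau <- invert_phasor_to_tau(p, loc)
  expect_equal(as.numeric(tau), 105, tolerance = 1e-3)
  expect_identical(attr(tau, "flag"), "ok")
  # undersampled scheme through the deviated locus
  ax4 <- sampled_axis(7.23 * c(4, 20, 36, 52), "echo_time")
  loc4 <- build_reference_locus(ax4)
  p4 <- compute_phasor(exp(-(ax4$values - ax4$values[1]) / 105))
  expect_equal(as.numeric(invert_phasor_to_tau(p4, loc4)), 105,
               tolerance = 5e-3)
  # origin = slow-decay limit
  tinf <- invert_phasor_to_tau(phasor_point(0, 0), loc)
  expect_identical(attr(tinf, "flag"), "slow_limit")
  expect_identical(as.numeric(tinf), Inf)
  # phase outside the represented range is clipped and flagged
  expect_warning(tlo <- invert_phasor_to_tau(phasor_point(1, -1e-4), loc),
                 "clipped")
  expect_identical(attr(tlo, "flag"), "below_range")
})

test_that("round-trip recovery holds across random taus and axes", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(4:48, 1)
    dx <- stats::runif(1, 1, 20)
    ax <- sampled_axis(dx * seq_len(n), "echo_time")
    loc <- build_reference_locus(ax)
    tau <- stats::runif(1, 0.5 * dx, 20 * dx * n)
    p <- compute_phasor(exp(-(ax$values - ax$values[1]) / tau))
    expect_equal(as.numeric(invert_phasor_to_tau(p, loc)), tau,
                 tolerance = 1e-3)
  }
})

test_that("continuous-limit inversion agrees with tau = tan(phase)/omega", {
  # dense AND long: step << tau << duration so both discretization and
  # truncation are negligible
  ax <- sampled_axis(seq(0, 16384, length.out = 16384), "echo_time")
  loc <- build_reference_locus(ax, tau_min = 100, tau_max = 5000,
                               n_grid = 256)
  omega <- 2 * pi / 16384
  for (tt in c(1000, 1500, 2000)) {
    p <- compute_phasor(exp(-ax$values / tt))
    tau_closed <- tan(phasor_phase(p)) / omega
    expect_equal(as.numeric(invert_phasor_to_tau(p, loc)), tau_closed,
                 tolerance = 1e-3)
  }
})

test_that("tau_map reproduces homogeneous and mixed phantoms", {
  ax <- axis64()
  spec <- phantom_spec(c(8, 8), ax, list(
    phantom_region("a", "rect", xlim = c(1, 8), ylim = c(1, 4),
                   components = list(list(tau = 130, fraction = 1))),
    phantom_region("b", "rect", xlim = c(1, 8), ylim = c(5, 8),
                   components = list(list(tau = 40, fraction = 0.5),
                                     list(tau = 80, fraction = 0.5)))))
  gen <- generate_stack(spec)
  f <- compute_phasor_field(gen$stack, threshold = 0)
  m <- tau_map(f, build_reference_locus(ax))
  a <- m$value[gen$truth$labels == 1]
  b <- m$value[gen$truth$labels == 2]
  expect_equal(a, rep(130, length(a)), tolerance = 1e-3)
  # phase of a convex phasor combination lies between the component phases
  expect_true(all(b > 40 & b < 80))
})

test_that("diffusion tau maps convert to ADC units", {
  gen <- generate_stack(phantom_diffusion(dim = c(24L, 24L)))
  f <- compute_phasor_field(gen$stack)
  m <- tau_map(f, build_reference_locus(gen$stack$axis))
  expect_identical(m$units, "1e-9 m^2/s")
  tissue <- m$value[gen$truth$labels == 1 & m$valid]
  csf <- m$value[gen$truth$labels == 2 & m$valid]
  expect_equal(stats::median(tissue), 0.65, tolerance = 0.01)
  expect_equal(stats::median(csf), 3.1, tolerance = 0.01)
  # fixed unit conversion: 1e-3 mm^2/s = 1e-9 m^2/s
  expect_equal(tau_to_adc(1000), 1)
  expect_equal(adc_to_tau(tau_to_adc(322.58)), 322.58)
})

test_that("mixture average tau is bounded by the component taus", {
  ax <- axis64()
  loc <- build_reference_locus(ax)
  set.seed(11)
  for (i in 1:50) {
    taus <- sort(stats::runif(2, 15, 600))
    f1 <- stats::runif(1, 0.05, 0.95)
    s <- f1 * mono_profile(ax, taus[1]) + (1 - f1) * mono_profile(ax, taus[2])
    tau <- as.numeric(invert_phasor_to_tau(compute_phasor(s), loc))
    expect_gte(tau, taus[1])
    expect_lte(tau, taus[2])
  }
})

test_that("locus construction validates its inputs", {
  ax <- axis64()
  expect_error(build_reference_locus(ax, tau_min = 10, tau_max = 5), "tau_min")
  expect_error(build_reference_locus(ax, n_grid = 10), "n_grid")
  expect_error(tau_map(compute_phasor_field(generate_stack(
    phantom_stem(dim = c(8L, 8L)))$stack),
    build_reference_locus(sampled_axis(1:10, "echo_time"))),
    "different sampling axis")
})
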