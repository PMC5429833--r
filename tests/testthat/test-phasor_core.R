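test_that("fast- and slow-decay limits hit the semicircle endpoints", {
  # all signal in the first sample -> (1, 0)
  p <- compute_phasor(c(5, rep(0, 63)))
  expect_equal(p$re, 1)
  expect_equal(p$im, 0)
  # constant signal -> origin
  q <- compute_phasor(rep(3, 64))
  expect_equal(phasor_modulus(q), 0, tolerance = 1e-14)
})

test_that("phasor of a 105 ms decay matches the frozen brute-force value", {
  # frozen from oracle_phasor on exp(-t/105), t = 7.23*(0:63) ms
  s <- exp(-7.23 * (0:63) / 105)
  p <- compute_phasor(s)
  expect_equal(p$re, 0.352280806578, tolerance = 1e-10)
  expect_equal(p$im, 0.453748608977, tolerance = 1e-10)
  g <- oracle_phasor(s)
  expect_equal(p$re, Re(g), tolerance = 1e-12)
  expect_equal(p$im, Im(g), tolerance = 1e-12)
})

test_that("compute_phasor agrees with the naive summation oracle", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(3:96, 1)
    s <- stats::runif(n)
    h <- if (n >= 7) sample(1:floor((n - 1) / 2), 1) else 1L
    p <- compute_phasor(s, h)
    g <- oracle_phasor(s, h)
    expect_lt(Mod(complex(real = p$re, imaginary = p$im) - g), 1e-12)
  }
})

test_that("phasor is scale-invariant and bounded for non-negative signals", {
  set.seed(1)
  for (i in 1:200) {
    s <- stats::runif(32)
    p <- compute_phasor(s)
    for (c in c(1e-6, 0.5, 3, 1e7)) {
      q <- compute_phasor(c * s)
      expect_lt(abs(q$re - p$re) + abs(q$im - p$im), 1e-13)
    }
    expect_lte(phasor_modulus(p), 1 + 1e-12)
  }
})

test_that("mixing is linear with integral weights", {
  ax <- axis64()
  set.seed(7)
  for (i in 1:200) {
    taus <- stats::runif(3, 10, 600)
    a <- stats::runif(3, 0.1, 2)
    comps <- lapply(taus, function(tt) exp(-ax$values / tt))
    s <- a[1] * comps[[1]] + a[2] * comps[[2]] + a[3] * comps[[3]]
    w <- vapply(1:3, function(j) a[j] * sum(comps[[j]]) / sum(s), numeric(1))
    gm <- compute_phasor(s)
    gs <- lapply(comps, compute_phasor)
    expect_equal(gm$re, sum(w * vapply(gs, `[[`, numeric(1), "re")),
                 tolerance = 1e-12)
    expect_equal(gm$im, sum(w * vapply(gs, `[[`, numeric(1), "im")),
                 tolerance = 1e-12)
  }
})

test_that("compute_phasor validates its input", {
  expect_error(compute_phasor(c(1, 2)), "3 samples")
  expect_error(compute_phasor(rep(0, 8)), "positive")
  expect_error(compute_phasor(c(-2, 1, 0.5)), "positive")
  expect_error(compute_phasor(c(1, NA, 2)), "non-finite")
  expect_error(compute_phasor(1:8, harmonic = 4), "harmonic")
  expect_error(compute_phasor(1:8, harmonic = 0), "harmonic")
})

test_that("phasor field of a homogeneous phantom is uniform and filter-stable", {
  ax <- sampled_axis(7.23 * (1:16), "echo_time")
  prof <- exp(-ax$values / 90)
  data <- array(rep(prof, each = 12 * 10), c(12, 10, 16))
  stack <- signal_stack(data, ax)
  ref <- compute_phasor(prof)
  f0 <- compute_phasor_field(stack, mean_filter_radius = 0)
  expect_true(all(f0$valid))
  expect_equal(as.vector(f0$re), rep(ref$re, 120), tolerance = 1e-12)
  expect_equal(as.vector(f0$im), rep(ref$im, 120), tolerance = 1e-12)
  # mean filter of a spatially constant field is the identity, borders included
  f1 <- compute_phasor_field(stack, mean_filter_radius = 1)
  expect_equal(f1$re, f0$re, tolerance = 1e-12)
  expect_equal(f1$im, f0$im, tolerance = 1e-12)
})

test_that("two-component pixels equal the intensity-weighted mix of pure phasors", {
  ax <- sampled_axis(7.23 * (1:32), "echo_time")
  spec <- phantom_spec(c(8, 8), ax, list(
    phantom_region("mix", "rect", xlim = c(1, 8), ylim = c(1, 8),
                   components = list(list(tau = 50, fraction = 0.5),
                                     list(tau = 200, fraction = 0.5)))))
  gen <- generate_stack(spec)
  f <- compute_phasor_field(gen$stack)
  g1 <- compute_phasor(mono_profile(ax, 50))
  g2 <- compute_phasor(mono_profile(ax, 200))
  expect_equal(as.vector(f$re), rep(0.5 * g1$re + 0.5 * g2$re, 64),
               tolerance = 1e-12)
  expect_equal(as.vector(f$im), rep(0.5 * g1$im + 0.5 * g2$im, 64),
               tolerance = 1e-12)
})

test_that("intensity thresholding invalidates dim pixels", {
  ax <- sampled_axis(1:8, "echo_time")
  data <- array(1, c(4, 4, 8))
  data[1, 1, ] <- 1e-4        # dim pixel
  f <- compute_phasor_field(signal_stack(data, ax), threshold = 0.05)
  expect_false(f$valid[1, 1])
  expect_true(all(f$valid[-1]))
  expect_true(is.na(f$re[1, 1]))
  expect_warning(
    compute_phasor_field(signal_stack(data, ax), threshold = 10,
                         threshold_type = "absolute"),
    "no pixels")
})

test_that("subsample_axis extracts the printed echo subsets", {
  gen <- generate_stack(phantom_stem(dim = c(16L, 16L)))
  s16 <- subsample_axis(gen$stack, seq(2, 62, by = 4))
  expect_equal(s16$axis$n, 16L)
  expect_equal(s16$axis$values, 7.23 * seq(2, 62, by = 4))
  s4 <- subsample_axis(gen$stack, c(4, 20, 36, 52))
  expect_equal(s4$axis$n, 4L)
  expect_equal(s4$data[3, 3, ], gen$stack$data[3, 3, c(4, 20, 36, 52)])
  # identity subset
  sid <- subsample_axis(gen$stack, 1:64)
  expect_equal(sid$data, gen$stack$data)
  expect_error(subsample_axis(gen$stack, c(4, 20)), "at least 3")
  expect_error(subsample_axis(gen$stack, c(4, 4, 20)), "strictly increasing")
  expect_error(subsample_axis(gen$stack, c(4, 20, 99)), "out of range")
})

test_that("sampled_axis enforces its invariants", {
  expect_error(sampled_axis(c(1, 2, 2)), "strictly increasing")
  expect_error(sampled_axis(c(1, NA, 3)), "finite")
  expect_error(sampled_axis(5), "at least 2")
  expect_equal(axis_unit(sampled_axis(1:4, "b_value")), "s/mm^2")
})
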