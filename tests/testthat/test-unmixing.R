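make_refs <- function(ax = axis64(), taus = c(40, 80, 500)) {
  component_set_from_taus(ax, taus)
}

test_that("barycentric unmixing reproduces vertices, centroid and weights", {
  refs <- make_refs()
  m <- refs$coords
  expect_equal(unname(unmix_three(phasor_point(m[1, 1], m[1, 2]), refs)),
               c(1, 0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  ctr <- colMeans(m)
  expect_equal(unname(unmix_three(phasor_point(ctr[1], ctr[2]), refs)),
               rep(1 / 3, 3), tolerance = 1e-12, ignore_attr = TRUE)
  set.seed(5)
  for (i in 1:100) {
    w <- stats::rexp(3); w <- w / sum(w)
    q <- as.vector(w %*% m)
    f <- unmix_three(phasor_point(q[1], q[2]), refs)
    expect_equal(unname(f), w, tolerance = 1e-12, ignore_attr = TRUE)
    # independent linear-solve oracle
    expect_equal(unname(f), oracle_barycentric(q, m), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
})

test_that("points outside the triangle get negative, unclamped fractions", {
  refs <- make_refs()
  q <- 1.4 * refs$coords[1, ] - 0.4 * colMeans(refs$coords)
  f <- unmix_three(phasor_point(q[1], q[2]), refs)
  expect_true(any(f < 0))
  expect_false(attr(f, "inside"))
  expect_equal(sum(f), 1, tolerance = 1e-12)
})

test_that("two-component unmixing projects onto the reference chord", {
  ax <- axis64()
  refs <- component_set_from_taus(ax, c(80, 500))
  mid <- colMeans(refs$coords)
  expect_equal(unname(unmix_two(phasor_point(mid[1], mid[2]), refs)),
               c(0.5, 0.5), tolerance = 1e-12, ignore_attr = TRUE)
  r2 <- refs$coords[2, ]
  expect_equal(unname(unmix_two(phasor_point(r2[1], r2[2]), refs)),
               c(0, 1), tolerance = 1e-12, ignore_attr = TRUE)
  # noiseless 70/30 integral mixture of 80 and 500 ms decays
  s <- 0.7 * mono_profile(ax, 80) + 0.3 * mono_profile(ax, 500)
  p <- compute_phasor(s)
  expect_equal(unname(unmix_two(p, refs)), c(0.7, 0.3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("unmixing is equivariant under reference permutation", {
  refs <- make_refs()
  set.seed(9)
  perms <- list(c(2, 1, 3), c(3, 1, 2), c(1, 3, 2))
  for (i in 1:20) {
    w <- stats::rexp(3); w <- w / sum(w)
    q <- as.vector(w %*% refs$coords)
    f <- unmix_three(phasor_point(q[1], q[2]), refs)
    for (pm in perms) {
      refs_p <- component_set(refs$coords[pm, ], refs$labels[pm])
      f_p <- unmix_three(phasor_point(q[1], q[2]), refs_p)
      expect_equal(unname(f_p), unname(f)[pm], tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("fraction_maps lifts per-pixel unmixing over a field", {
  gen <- generate_stack(phantom_brain(dim = c(24L, 24L),
                                      random_fractions = TRUE, seed = 2))
  f <- compute_phasor_field(gen$stack, threshold = 0)
  refs <- make_refs(gen$stack$axis)
  fm <- fraction_maps(f, refs)
  idx <- which(gen$truth$labels == 1)
  fr <- matrix(fm$fractions, ncol = 3)
  tru <- gen$truth$fractions[["brain"]]
  expect_equal(fr[idx, ], unname(tru), tolerance = 1e-9)
  # spot-check against the scalar API
  i <- idx[17]
  expect_equal(fr[i, ],
               unname(unmix_three(phasor_point(f$re[i], f$im[i]), refs)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # partition of unity everywhere valid
  expect_equal(rowSums(fr[as.vector(f$valid), ]),
               rep(1, sum(f$valid)), tolerance = 1e-12)
  # rgb composite is clamped to [0, 1]
  rgb <- fractions_rgb(fm)
  expect_true(all(rgb >= 0 & rgb <= 1))
  expect_equal(dim(rgb), c(24L, 24L, 3L))
})

test_that("degenerate reference sets are rejected", {
  expect_error(component_set(rbind(c(0.2, 0.3), c(0.2, 0.3)), c("a", "b")),
               "distinct")
  expect_error(component_set(rbind(c(0, 0), c(0.5, 0.5), c(0.25, 0.25))),
               "collinear")
  refs2 <- component_set(rbind(c(0.1, 0.2), c(0.6, 0.4)))
  expect_error(unmix_three(phasor_point(0.3, 0.3), refs2), "3 references")
})

test_that("cloud extrapolation recovers T2 endmembers from a noiseless cloud", {
  ax <- axis64()
  loc <- build_reference_locus(ax)
  fr <- seq(0.1, 0.9, length.out = 40)
  pts <- t(vapply(fr, function(f1) {
    p <- compute_phasor(f1 * mono_profile(ax, 80) +
                          (1 - f1) * mono_profile(ax, 500))
    c(p$re, p$im)
  }, numeric(2)))
  ex <- extrapolate_cloud_to_locus(pts, loc)
  expect_equal(ex$tau, c(80, 500), tolerance = 0.02)
  expect_identical(ex$flags, c("intersect", "intersect"))
})

test_that("cloud extrapolation recovers ADC endmembers", {
  gen <- generate_stack(phantom_diffusion(dim = c(32L, 32L)))
  f <- compute_phasor_field(gen$stack, threshold = 0)
  loc <- build_reference_locus(gen$stack$axis)
  sel <- gen$truth$labels == 3 & f$valid
  ex <- extrapolate_cloud_to_locus(cbind(f$re[sel], f$im[sel]), loc)
  expect_equal(sort(tau_to_adc(ex$tau)), c(0.65, 3.1), tolerance = 0.02)
})

test_that("degenerate clouds are rejected with informative errors", {
  loc <- build_reference_locus(axis64())
  same <- matrix(rep(c(0.4, 0.3), each = 20), ncol = 2)
  expect_error(extrapolate_cloud_to_locus(same, loc), "degenerate")
  set.seed(1)
  blob <- cbind(0.4 + stats::rnorm(50, sd = 0.01),
                0.3 + stats::rnorm(50, sd = 0.01))
  expect_error(extrapolate_cloud_to_locus(blob, loc), "not elongated")
  expect_error(extrapolate_cloud_to_locus(same[1:5, ], loc), "at least 10")
})
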