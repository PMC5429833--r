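# two well-separated mono-exponential tissues on a 16x16 grid
two_cluster_field <- function() {
  ax <- sampled_axis(7.23 * (1:32), "echo_time")
  spec <- phantom_spec(c(16, 16), ax, list(
    phantom_region("short", "rect", xlim = c(1, 16), ylim = c(1, 8),
                   components = list(list(tau = 40, fraction = 1))),
    phantom_region("long", "rect", xlim = c(1, 16), ylim = c(9, 16),
                   components = list(list(tau = 400, fraction = 1)))))
  gen <- generate_stack(spec)
  list(gen = gen, field = compute_phasor_field(gen$stack, threshold = 0))
}

test_that("ROIs covering / missing the cloud select all / no pixels", {
  tc <- two_cluster_field()
  f <- tc$field
  pts <- valid_phasors(f)
  box <- phasor_roi(rbind(c(min(pts[, 1]) - 0.01, min(pts[, 2]) - 0.01),
                          c(max(pts[, 1]) + 0.01, min(pts[, 2]) - 0.01),
                          c(max(pts[, 1]) + 0.01, max(pts[, 2]) + 0.01),
                          c(min(pts[, 1]) - 0.01, max(pts[, 2]) + 0.01)),
                    "all")
  seg <- segment_phasors(f, list(box))
  expect_equal(sum(seg$labels > 0), sum(f$valid))
  far <- phasor_roi(rbind(c(-1, -1), c(-0.9, -1), c(-0.9, -0.9)), "none")
  seg0 <- segment_phasors(f, list(far))
  expect_equal(sum(seg0$labels > 0), 0L)
})

test_that("disjoint phasor clusters segment exactly to the tissue masks", {
  tc <- two_cluster_field()
  f <- tc$field
  g40 <- compute_phasor(mono_profile(tc$gen$stack$axis, 40))
  g400 <- compute_phasor(mono_profile(tc$gen$stack$axis, 400))
  roi_around <- function(g, label) {
    phasor_roi(rbind(c(g$re - 0.05, g$im - 0.05), c(g$re + 0.05, g$im - 0.05),
                     c(g$re + 0.05, g$im + 0.05), c(g$re - 0.05, g$im + 0.05)),
               label)
  }
  seg <- segment_phasors(f, list(roi_around(g40, "short"),
                                 roi_around(g400, "long")))
  expect_equal(seg$labels, tc$gen$truth$labels, ignore_attr = TRUE)
  # partition: each valid pixel in exactly 0 or 1 segment; counts consistent
  expect_equal(sum(seg$legend$n), sum(seg$labels > 0))
  # pure function of phasor coordinates: permuting pixels permutes labels
  perm <- sample(length(f$re))
  fp <- f
  fp$re[] <- f$re[perm]; fp$im[] <- f$im[perm]
  fp$valid[] <- f$valid[perm]; fp$intensity[] <- f$intensity[perm]
  segp <- segment_phasors(fp, list(roi_around(g40, "short"),
                                   roi_around(g400, "long")))
  expect_equal(as.vector(segp$labels), as.vector(seg$labels)[perm])
})

test_that("overlapping ROIs warn and resolve by first match", {
  tc <- two_cluster_field()
  big <- phasor_roi(rbind(c(-1, -1), c(2, -1), c(2, 2), c(-1, 2)), "big")
  expect_warning(seg <- segment_phasors(tc$field, list(big, big)), "overlap")
  expect_true(all(seg$labels[tc$field$valid] == 1L))
})

test_that("polygon containment is boundary-inclusive and even-odd", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_true(phasorMRI:::points_in_polygon(0.5, 0.5, sq))
  expect_true(phasorMRI:::points_in_polygon(0, 0.5, sq))    # edge
  expect_true(phasorMRI:::points_in_polygon(1, 1, sq))      # vertex
  expect_false(phasorMRI:::points_in_polygon(1.0001, 0.5, sq))
})

test_that("ROI validation rejects malformed polygons", {
  expect_error(phasor_roi(rbind(c(0, 0), c(1, 1)), "x"), "3")
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(phasor_roi(bow, "x"), "self-intersecting")
})

test_that("mean signals per segment average the raw decays", {
  tc <- two_cluster_field()
  gen <- tc$gen
  ax <- gen$stack$axis
  g40 <- compute_phasor(mono_profile(ax, 40))
  rois <- list(
    phasor_roi(rbind(c(g40$re - 0.05, g40$im - 0.05),
                     c(g40$re + 0.05, g40$im - 0.05),
                     c(g40$re + 0.05, g40$im + 0.05),
                     c(g40$re - 0.05, g40$im + 0.05)), "short"),
    phasor_roi(rbind(c(-1, -1), c(-0.9, -1), c(-0.9, -0.9)), "empty"))
  seg <- segment_phasors(tc$field, rois)
  tab <- mean_signal_per_segment(gen$stack, seg)
  short <- tab[tab$name == "short", ]
  expect_equal(short$mean_signal, mono_profile(ax, 40), tolerance = 1e-12)
  expect_equal(unique(short$n_pixels), 128L)
  empty <- tab[tab$name == "empty", ]
  expect_true(all(is.nan(empty$mean_signal)))
  expect_equal(unique(empty$n_pixels), 0L)
})

test_that("back-projection composites segment colors over the background", {
  tc <- two_cluster_field()
  seg <- segment_phasors(tc$field, list(
    phasor_roi(rbind(c(-1, -1), c(2, -1), c(2, 2), c(-1, 2)), "all",
               color = "red")))
  rgb <- backproject(seg, background = NULL, alpha = 1)
  expect_equal(dim(rgb), c(16L, 16L, 3L))
  expect_true(all(rgb[, , 1][seg$labels == 1L] == 1))
  expect_true(all(rgb[, , 2][seg$labels == 1L] == 0))
  # unassigned pixels show the background
  seg0 <- segment_phasors(tc$field, list(
    phasor_roi(rbind(c(-1, -1), c(-0.9, -1), c(-0.9, -0.9)), "none")))
  bg <- matrix(seq(0, 1, length.out = 256), 16, 16)
  rgb0 <- backproject(seg0, background = bg)
  expect_equal(rgb0[, , 1], bg, tolerance = 1e-12)
  expect_equal(rgb0[, , 2], rgb0[, , 3], tolerance = 1e-12)
})

test_that("ROIs round-trip through JSON", {
  rois <- list(phasor_roi(rbind(c(0.1, 0.1), c(0.4, 0.15), c(0.2, 0.5)),
                          "a", color = "blue"),
               roi_sector(0.2, 0.9, label = "wedge", color = "green"))
  path <- tempfile(fileext = ".json")
  write_rois(rois, path)
  back <- read_rois(path)
  expect_equal(back[[1]]$vertices, rois[[1]]$vertices, ignore_attr = TRUE)
  expect_equal(back[[2]]$vertices, rois[[2]]$vertices, ignore_attr = TRUE)
  expect_identical(back[[1]]$label, "a")
  expect_identical(back[[2]]$color, "green")
})
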