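# Axis fitting and pair descriptors: exactness, equivariance, recovery.

test_that("axis fit is exact on ideal helices and equivariant", {
  h <- make_ideal_helix(20)
  ca <- ca_matrix(select_segment(h, helix_segment("A", 1, 20), "CA"))
  ax <- fit_helix_axis(ca)
  expect_lt(max(abs(ax$direction - c(0, 0, 1))), 1e-6)
  expect_lt(ax$rms_deviation, 1e-6)
  expect_equal(unname(diff(ax$residue_projections)), rep(1.5, 19))

  R <- tmhelix:::rotation_about(c(1, 0, 0), 30)
  ax2 <- fit_helix_axis(ca %*% t(R))
  expect_lt(max(abs(ax2$direction - as.numeric(R %*% c(0, 0, 1)))), 1e-6)

  set.seed(7)
  noisy <- ca + matrix(rnorm(length(ca), sd = 0.3), ncol = 3)
  axn <- fit_helix_axis(noisy)
  ang <- acos(sum(axn$direction * c(0, 0, 1))) * 180 / pi
  expect_lt(ang, 2)

  expect_error(fit_helix_axis(ca[1:5, ]), ">= 8")
  line <- cbind(0, 0, 1:10)
  expect_error(fit_helix_axis(line), "collinear")
})

test_that("closest approach reproduces analytic skew-line geometry", {
  mk_axis <- function(p, d, n = 10) {
    # synthetic helix_axis for pure line tests
    structure(list(point = p, direction = tmhelix:::unitv(d),
                   residue_projections = setNames(seq_len(n) - 1,
                                                  seq_len(n)),
                   radius = 2.3, rms_deviation = 0), class = "helix_axis")
  }
  a <- mk_axis(c(0, 0, 0), c(0, 0, 1))
  b <- mk_axis(c(8, 0, 0), c(0, 1, 1))
  ca <- closest_approach(a, b)
  expect_equal(ca$distance, 8)
  expect_equal(ca$vector, c(1, 0, 0))
  swapped <- closest_approach(b, a)
  expect_equal(swapped$distance, 8)
  expect_equal(swapped$vector, -ca$vector)
  # parallel tie-break drops the perpendicular from A's first residue
  b2 <- mk_axis(c(0, 6, -3), c(0, 0, 1))
  cap <- closest_approach(a, b2)
  expect_equal(cap$distance, 6)
  expect_equal(cap$point_a, c(0, 0, 0))
  expect_error(closest_approach(a, mk_axis(c(0, 0, 5), c(0, 0, 1))),
               "coincident")
  expect_equal(crossing_angle(a, b2), 0)
})

test_that("rotation angle is measured from the approach vector", {
  h <- make_ideal_helix(20)
  ca <- ca_matrix(select_segment(h, helix_segment("A", 1, 20), "CA"))
  ax <- fit_helix_axis(ca)
  # radial direction of residue 4 is at azimuth 300 deg; an approach vector
  # pointing along it gives zero
  a4 <- c(cos(300 * pi / 180), sin(300 * pi / 180), 0)
  expect_equal(rotation_angle(ca, ax, 4, a4), 0, tolerance = 1e-6)
  # pre-rotating the helix about its own axis shifts the angle identically
  ca90 <- tmhelix:::rotate_coords(ca, c(0, 0, 1), 90)
  rownames(ca90) <- rownames(ca)
  ax90 <- fit_helix_axis(ca90)
  r0 <- rotation_angle(ca, ax, 4, c(1, 0, 0))
  r90 <- rotation_angle(ca90, ax90, 4, c(1, 0, 0))
  expect_equal(circular_diff(r90, r0), 90, tolerance = 1e-6)
  # residues 4 and 11 are 7 residues = 700 deg of twist apart, i.e. -20 deg
  # once wrapped into (-180, 180]
  r4 <- rotation_angle(ca, ax, 4, c(1, 0, 0))
  r11 <- rotation_angle(ca, ax, 11, c(1, 0, 0))
  expect_equal(circular_diff(r11, r4), circular_diff(7 * 100, 0),
               tolerance = 2)
  expect_equal(circular_diff(7 * 100, 0), -20)
  expect_error(rotation_angle(ca, ax, 99, c(1, 0, 0)), "reference residue")
})

test_that("register shift recovers the construction and is antisymmetric", {
  g0 <- dimer_geometry(tiny_dimer(0))
  expect_equal(g0$register_shift, 0, tolerance = 0.1)
  d54 <- make_dimer(dimer_spec(24, crossing_angle = -30,
                               register_shift = 5.4, sequence = B1_SEQ))
  axs <- segment_axes(d54)
  expect_equal(register_shift(axs[[1]], axs[[2]], 11), 5.4,
               tolerance = 0.2)
  expect_equal(register_shift(axs[[2]], axs[[1]], 11), -5.4,
               tolerance = 0.2)
  flipped <- axs[[2]]
  flipped$direction <- -flipped$direction
  expect_error(register_shift(axs[[1]], flipped, 11), "anti-aligned")
})

test_that("tilt angle is the analytic axis-normal angle", {
  mk <- function(d) structure(list(point = c(0, 0, 0),
                                   direction = tmhelix:::unitv(d),
                                   residue_projections = c(`1` = 0),
                                   radius = 2.3, rms_deviation = 0),
                              class = "helix_axis")
  expect_equal(tilt_angle(mk(c(0, 0, 1))), 0)
  expect_equal(tilt_angle(mk(c(1, 0, 1))), 45)
  expect_equal(tilt_angle(mk(c(0, 0, -1))), 0)  # orientation-independent
  # invariant under rotation about the membrane normal
  expect_equal(tilt_angle(mk(c(1, 1, 2))),
               tilt_angle(mk(as.numeric(
                 tmhelix:::rotation_about(c(0, 0, 1), 73) %*% c(1, 1, 2)))))
})

test_that("descriptors are equivariant under rigid motion and flip under reflection", {
  base <- tiny_dimer(-40)
  g0 <- dimer_geometry(base)
  gm <- dimer_geometry(rigid_move(base))
  expect_equal(gm$crossing_angle, g0$crossing_angle, tolerance = 1e-6)
  expect_equal(gm$inter_axial_distance, g0$inter_axial_distance,
               tolerance = 1e-6)
  expect_equal(gm$register_shift, g0$register_shift, tolerance = 1e-6)
  expect_equal(gm$rotation_angles, g0$rotation_angles, tolerance = 1e-5)
  gr <- dimer_geometry(mirror_x(base))
  expect_equal(gr$crossing_angle, -g0$crossing_angle, tolerance = 1e-6)
})

test_that("generator parameters are recovered across a crossing/distance grid", {
  specs <- expand.grid(crossing = c(0, -25, 25, 55, -55, 60),
                       dist = c(8, 12), register = c(0, 2.7))
  for (i in seq_len(nrow(specs))) {
    sp <- dimer_spec(24, inter_axial_distance = specs$dist[i],
                     crossing_angle = specs$crossing[i],
                     rotation_a = 35, rotation_b = -120,
                     register_shift = specs$register[i], sequence = B1_SEQ)
    g <- dimer_geometry(make_dimer(sp))
    expect_equal(g$crossing_angle, specs$crossing[i], tolerance = 1)
    expect_equal(g$inter_axial_distance, specs$dist[i], tolerance = 0.1)
    expect_equal(g$register_shift, specs$register[i], tolerance = 0.2)
    truth <- function(rot, ref) circular_diff((ref - 1) * 100 + rot, 0)
    for (ref in c(4, 11)) {
      expect_lt(abs(circular_diff(g$rotation_angles["A", as.character(ref)],
                                  truth(35, ref))), 2)
      expect_lt(abs(circular_diff(g$rotation_angles["B", as.character(ref)],
                                  truth(-120, ref))), 2)
    }
  }
})
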