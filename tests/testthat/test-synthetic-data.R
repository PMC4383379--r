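# Generators: ideal helices, oligomers, trajectories, membrane, coiled coil.

test_that("ideal helix obeys its construction parameters exactly", {
  h <- make_ideal_helix(20)
  ca <- ca_matrix(select_segment(h, helix_segment("A", 1, 20), "CA"))
  expect_equal(diff(range(ca[, 3])), 28.5)                 # (20-1) x 1.5
  expect_equal(unname(sqrt(ca[, 1]^2 + ca[, 2]^2)), rep(2.3, 20))  # on-cylinder
  # azimuth advances 100 deg per residue: residue 18 of an 18-mer sits at
  # 17 x 100 deg from residue 1
  h18 <- make_ideal_helix(18)
  ca18 <- ca_matrix(select_segment(h18, helix_segment("A", 1, 18), "CA"))
  az <- atan2(ca18[, 2], ca18[, 1]) * 180 / pi
  expect_equal(unname(circular_diff(az[18], az[1])),
               circular_diff(17 * 100, 0), tolerance = 1e-9)
  ax <- fit_helix_axis(ca)
  expect_lt(max(abs(ax$direction - c(0, 0, 1))), 1e-6)
  expect_lt(ax$rms_deviation, 1e-6)
  expect_error(make_ideal_helix(5), "n_residues")
  expect_error(make_ideal_helix(10, rise_per_residue = -1), "positive")
})

test_that("backbone decoration has sane peptide geometry", {
  h <- make_ideal_helix(12, sequence = "LSTGLLLLLLLL")
  at <- h$atoms
  get <- function(rn, el) unlist(at[at$resno == rn & at$elety == el,
                                    c("x", "y", "z")])
  expect_equal(sqrt(sum((get(5, "H") - get(5, "N"))^2)), 1.01,
               tolerance = 1e-6)
  expect_equal(sqrt(sum((get(5, "O") - get(5, "C"))^2)), 1.231,
               tolerance = 1e-6)
  expect_equal(sqrt(sum((get(5, "CB") - get(5, "CA"))^2)), 1.53,
               tolerance = 1e-6)
  expect_true("OG" %in% at$elety[at$resno == 2])   # Ser
  expect_true("OG1" %in% at$elety[at$resno == 3])  # Thr
  expect_true("CB" %in% at$elety[at$resno == 3])
  expect_false("CB" %in% at$elety[at$resno == 4])  # Gly
})

test_that("dimer generator ground truth is recovered by analysis", {
  for (om in c(0, -40, 60)) {
    g <- dimer_geometry(tiny_dimer(om))
    expect_equal(g$crossing_angle, om, tolerance = 0.5)
    expect_equal(g$inter_axial_distance, 10, tolerance = 0.1)
  }
  # mirroring flips the crossing handedness
  g40 <- dimer_geometry(mirror_x(tiny_dimer(-40)))
  expect_equal(g40$crossing_angle, 40, tolerance = 1)
  expect_error(dimer_spec(crossing_angle = 100), "90")
  expect_error(dimer_spec(inter_axial_distance = 0), "inter_axial")
})

test_that("trimer is symmetric with the requested chain order", {
  sp <- dimer_spec(24, inter_axial_distance = 9.5, crossing_angle = -20,
                   sequence = B1_SEQ)
  tm <- make_trimer(sp, "clockwise")
  axs <- segment_axes(tm)
  cr <- c(crossing_angle(axs[[1]], axs[[2]]),
          crossing_angle(axs[[2]], axs[[3]]),
          crossing_angle(axs[[1]], axs[[3]]))
  expect_lt(max(cr) - min(cr), 1)
  expect_equal(mean(cr), -20, tolerance = 1)
  dd <- c(closest_approach(axs[[1]], axs[[2]])$distance,
          closest_approach(axs[[2]], axs[[3]])$distance,
          closest_approach(axs[[1]], axs[[3]])$distance)
  expect_lt(max(dd) - min(dd), 0.1)
  # chain order: A -> B azimuthal step is +120 deg (clockwise viewed from
  # the N-terminal side) for the clockwise arrangement, -120 anticlockwise
  step_ab <- function(model) {
    ctr <- vapply(c("A", "B"), function(ch) {
      colMeans(as.matrix(model$atoms[model$atoms$chain == ch &
                                       model$atoms$elety == "CA",
                                     c("x", "y", "z")]))
    }, numeric(3))
    circular_diff(atan2(ctr[2, 2], ctr[1, 2]) * 180 / pi,
                  atan2(ctr[2, 1], ctr[1, 1]) * 180 / pi)
  }
  expect_equal(step_ab(tm), 120, tolerance = 1)
  expect_equal(step_ab(make_trimer(sp, "anticlockwise")), -120,
               tolerance = 1)
})

test_that("trajectory generator: zero noise, determinism, jitter, drift", {
  dm <- tiny_dimer()
  tr <- make_trajectory(dm, noise_spec(sigma_atom = 0, n_frames = 4))
  expect_equal(tr$xyz[, , 1], tr$xyz[, , 4])
  expect_equal(tr$xyz[, 1, 1], dm$atoms$x)

  n1 <- noise_spec(sigma_atom = 0.3, n_frames = 3, seed = 42)
  expect_identical(make_trajectory(dm, n1)$xyz,
                   make_trajectory(dm, n1)$xyz)
  n2 <- noise_spec(sigma_atom = 0.3, n_frames = 3, seed = 43)
  expect_false(identical(make_trajectory(dm, n1)$xyz,
                         make_trajectory(dm, n2)$xyz))

  trd <- make_trajectory(dm, noise_spec(
    sigma_atom = 0, n_frames = 11,
    drift = list(parameter = "crossing_angle", delta = 30)))
  cr <- geometry_timeseries(trd)$crossing$values
  expect_equal(cr[11] - cr[1], 30, tolerance = 0.1)
  expect_error(make_trajectory(make_ideal_helix(10), noise_spec(
    n_frames = 3, drift = list(parameter = "crossing_angle", delta = 1))),
    "dimer_spec")
  expect_error(noise_spec(jitter = list(bogus = 1)), "jitter")
})

test_that("per-residue RMSF of isotropic noise matches sigma * sqrt(3)", {
  dm <- tiny_dimer()
  tr <- make_trajectory(dm, noise_spec(sigma_atom = 0.5, n_frames = 2000,
                                       dt_ns = 0.1, seed = 11))
  rf <- rmsf(tr, "mainchain")
  expect_equal(mean(rf$rmsf), 0.5 * sqrt(3), tolerance = 0.05 * 0.866)
})

test_that("cone NH probe matches the closed-form order parameter", {
  expect_equal(order_parameters(make_cone_nh_trajectory(0, 500),
                                block_ns = 1, align = FALSE)$s2, 1)
  s30 <- order_parameters(make_cone_nh_trajectory(30, 2e4, seed = 5),
                          block_ns = 50, align = FALSE)$s2
  expect_equal(s30, cone_s2(30), tolerance = 0.03)
  expect_equal(cone_s2(90), 0)
})

test_that("membrane slab geometry", {
  slab <- make_membrane_slab(z_upper = 20, z_lower = -20)
  expect_equal(slab$spacing, sqrt(64.3), tolerance = 0.01)
  expect_equal(nrow(slab$lower), 72)
  expect_equal(nrow(slab$upper), 72)
  p <- c(slab$lower[5, 1], slab$lower[5, 2], slab$lower[5, 3] - 10)
  expect_equal(distance_to_leaflet(p, slab, "lower"), 10)
  expect_error(make_membrane_slab(z_upper = -1, z_lower = 1), "z_upper")
})

test_that("coiled-coil generator limits", {
  st <- make_coiled_coil(2, pitch = Inf, superhelix_radius = 4.9)
  axs <- segment_axes(st)
  expect_equal(crossing_angle(axs[[1]], axs[[2]]), 0)
  expect_equal(closest_approach(axs[[1]], axs[[2]])$distance, 9.8,
               tolerance = 0.3)
  expect_equal(coiling_handedness(make_coiled_coil(2, pitch = 140)),
               "anticlockwise", ignore_attr = TRUE)
  # a/d positions carry the hydrophobic register
  cc <- make_coiled_coil(2, pitch = 140)
  a_res <- cc$atoms[cc$atoms$chain == "A" & cc$atoms$elety == "CA", ]
  expect_true(all(a_res$resid[c(1, 4, 8, 11)] == "LEU"))
  expect_true(all(a_res$resid[c(2, 3, 5)] == "ALA"))
})
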