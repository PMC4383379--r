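# Time-resolved metrics: series definitions, equilibration logic, RMSF,
# order parameters, contacts, membrane distances.

stationary_traj <- function(seed = 4, n_frames = 60) {
  make_trajectory(tiny_dimer(-30), noise_spec(
    sigma_atom = 0.05, n_frames = n_frames, dt_ns = 5,
    jitter = list(crossing_angle = 3, rotation = 6, register_shift = 0.2),
    seed = seed))
}

drift_traj <- function(delta = 40, seed = 4, n_frames = 60) {
  make_trajectory(tiny_dimer(-30), noise_spec(
    sigma_atom = 0.05, n_frames = n_frames, dt_ns = 5,
    drift = list(parameter = "crossing_angle", delta = delta), seed = seed))
}

test_that("geometry time series start at the defined origin", {
  tr <- make_trajectory(tiny_dimer(-30),
                        noise_spec(sigma_atom = 0, n_frames = 5))
  ts <- geometry_timeseries(tr)
  expect_equal(ts$rmsd$values[1], 0, tolerance = 1e-9)
  expect_equal(ts$rotation_A_4$values[1], 0)
  expect_equal(ts$rotation_B_11$values[1], 0)
  # static trajectory: every series is constant
  for (s in ts) expect_lt(diff(range(s$values)), 1e-9)
  expect_equal(ts$crossing$values[1], -30, tolerance = 0.5)
})

test_that("crossing drift is tracked across the series", {
  ts <- geometry_timeseries(drift_traj(delta = 30, seed = 9))
  v <- ts$crossing$values
  expect_equal(v[length(v)] - v[1], 30, tolerance = 2)
})

test_that("equilibration criteria pass stationary series and fail drift", {
  eq <- equilibration_report(geometry_timeseries(stationary_traj()),
                             window_ns = 250)
  expect_true(eq$pass)
  expect_true(all(eq$table$sd[grepl("crossing", eq$table$metric)] < 10))

  eqd <- equilibration_report(geometry_timeseries(drift_traj(40)),
                              window_ns = 250)
  expect_false(eqd$pass)
  expect_false(eqd$table$pass[eqd$table$metric == "crossing"])

  # tightening any threshold never converts fail into pass
  loose <- equilibration_report(
    geometry_timeseries(drift_traj(40)), window_ns = 250,
    thresholds = list(rmsd_sd = 0.5, crossing_range = 10,
                      rotation_range = 25))
  tight <- equilibration_report(
    geometry_timeseries(drift_traj(40)), window_ns = 250,
    thresholds = list(rmsd_sd = 0.25, crossing_range = 5,
                      rotation_range = 12.5))
  expect_true(all(!loose$table$pass | tight$table$pass == FALSE |
                    loose$table$pass >= tight$table$pass))
  expect_true(sum(tight$table$pass) <= sum(loose$table$pass))

  expect_error(equilibration_report(geometry_timeseries(
    stationary_traj(n_frames = 10)), window_ns = 2000), "window")
})

test_that("RMSF: zero for static input, scales linearly with noise", {
  static <- make_trajectory(tiny_dimer(), noise_spec(sigma_atom = 0,
                                                     n_frames = 3))
  expect_lt(max(rmsf(static, "mainchain")$rmsf), 1e-9)
  tr1 <- make_trajectory(tiny_dimer(), noise_spec(sigma_atom = 0.25,
                                                  n_frames = 400,
                                                  dt_ns = 0.1, seed = 2))
  tr2 <- make_trajectory(tiny_dimer(), noise_spec(sigma_atom = 0.5,
                                                  n_frames = 400,
                                                  dt_ns = 0.1, seed = 2))
  m1 <- mean(rmsf(tr1, "mainchain")$rmsf)
  m2 <- mean(rmsf(tr2, "mainchain")$rmsf)
  expect_equal(m2 / m1, 2, tolerance = 0.1)
})

test_that("order parameters: rigid limit, isotropic limit, cross-method", {
  rigid <- make_trajectory(make_ideal_helix(12),
                           noise_spec(sigma_atom = 0, n_frames = 20))
  s2r <- order_parameters(rigid, block_ns = 10)
  expect_true(all(abs(s2r$s2 - 1) < 1e-6))

  iso <- make_cone_nh_trajectory(180, 2e4, seed = 8)
  s2i <- order_parameters(iso, block_ns = 50, align = FALSE)$s2
  expect_lt(abs(s2i), 0.03)

  cone <- make_cone_nh_trajectory(45, 2e4, seed = 3)
  sm <- order_parameters(cone, block_ns = 50, align = FALSE)$s2
  sp <- order_parameters(cone, block_ns = 50, align = FALSE,
                         method = "p2")$s2
  expect_equal(sm, cone_s2(45), tolerance = 0.03)
  expect_lt(abs(sm - sp), 0.05)

  expect_error(order_parameters(rigid, block_ns = 1000), "span")
  # prolines are omitted with a notice
  hp <- make_ideal_helix(10, sequence = "LLLPLLLLLL")
  trp <- make_trajectory(hp, noise_spec(sigma_atom = 0, n_frames = 3,
                                        dt_ns = 10))
  expect_message(s2p <- order_parameters(trp, block_ns = 10), "omitted")
  expect_false(4 %in% s2p$resno)
})

test_that("floppy residues show higher RMSF and lower S2 than rigid ones", {
  h <- make_ideal_helix(16)
  at <- h$atoms
  floppy_rows <- at$resno >= 9
  set.seed(21)
  frames <- lapply(1:150, function(k) {
    a <- at
    a[floppy_rows, c("x", "y", "z")] <- a[floppy_rows, c("x", "y", "z")] +
      matrix(rnorm(sum(floppy_rows) * 3, sd = 0.6), ncol = 3)
    a[!floppy_rows, c("x", "y", "z")] <- a[!floppy_rows, c("x", "y", "z")] +
      matrix(rnorm(sum(!floppy_rows) * 3, sd = 0.03), ncol = 3)
    structure_model(a)
  })
  tr <- trajectory(frames, times_ns = (1:150) * 0.5)
  rf <- rmsf(tr, "mainchain",
             align_on = helix_segment("A", 1, 8))
  s2 <- order_parameters(tr, block_ns = 25,
                         align_on = helix_segment("A", 1, 8))
  rigid_res <- 2:8; floppy_res <- 10:16
  expect_gt(mean(rf$rmsf[rf$resno %in% floppy_res]),
            2 * mean(rf$rmsf[rf$resno %in% rigid_res]))
  expect_lt(mean(s2$s2[s2$resno %in% floppy_res]),
            mean(s2$s2[s2$resno %in% rigid_res]) - 0.2)
})

test_that("Ser/Thr hydroxyl contact fractions and minimum distances", {
  # two serines on facing helices: hydroxyls at a fixed, known separation
  sq <- paste(c(rep("L", 11), "S", rep("L", 12)), collapse = "")
  dm <- make_dimer(dimer_spec(24, inter_axial_distance = 10,
                              crossing_angle = 0, sequence = sq,
                              rotation_a = -20, rotation_b = -20))
  tr <- make_trajectory(dm, noise_spec(sigma_atom = 0, n_frames = 4))
  ct <- min_contact_distance(tr)
  expect_length(ct, 1)
  d <- ct[["A|B"]]$series$values
  expect_lt(diff(range(d)), 1e-9)  # constant series
  d0 <- d[1]
  expect_equal(unname(ct[["A|B"]]$fractions),
               c(mean(d < 3.5), mean(d < 5)))
  # hydroxyls sit ~3.8 A apart by construction: inside the 5.0 A contact
  # class but outside the close 3.5 A class
  expect_gt(d0, 3.5); expect_lt(d0, 5)
  expect_equal(unname(ct[["A|B"]]$fractions), c(0, 1))
  # brute-force recount on noisy frames
  trn <- make_trajectory(dm, noise_spec(sigma_atom = 0.4, n_frames = 20,
                                        seed = 6))
  ctn <- min_contact_distance(trn)
  og_rows <- which(trn$atoms$elety == "OG")
  brute <- vapply(seq_len(20), function(k) {
    xa <- trn$xyz[og_rows[1], , k]; xb <- trn$xyz[og_rows[2], , k]
    sqrt(sum((xa - xb)^2))
  }, 1)
  expect_equal(ctn[["A|B"]]$series$values, brute, tolerance = 1e-9)
  # absence of Ser/Thr yields an empty result with a notice
  polyL <- make_dimer(dimer_spec(24, crossing_angle = 0,
                                 sequence = "L"))
  expect_message(empty <- min_contact_distance(make_trajectory(
    polyL, noise_spec(n_frames = 2))), "no Ser/Thr")
  expect_length(empty, 0)
})

test_that("membrane distance matches analytic placement and is rigid-invariant", {
  slab <- make_membrane_slab(z_upper = 20, z_lower = -20)
  h <- make_ideal_helix(10)
  # put the tail COM 10 A below a lower-leaflet grid atom
  gx <- slab$lower[4, 1]; gy <- slab$lower[4, 2]
  tail_rows <- h$atoms$resno >= 8 & !grepl("^H", h$atoms$elety)
  com <- colMeans(as.matrix(h$atoms[tail_rows, c("x", "y", "z")]))
  shift <- c(gx, gy, -30) - com
  h$atoms[, c("x", "y", "z")] <- sweep(as.matrix(
    h$atoms[, c("x", "y", "z")]), 2, shift, "+")
  tr <- make_trajectory(structure_model(h$atoms),
                        noise_spec(sigma_atom = 0, n_frames = 3))
  md <- membrane_distance(tr, helix_segment("A", 1, 10), slab, "lower")
  expect_equal(md$values, rep(10, 3), tolerance = 1e-9)
  # rigid in-plane translation by one grid period leaves the series intact
  h2 <- h
  h2$atoms$x <- h2$atoms$x + slab$spacing
  tr2 <- make_trajectory(structure_model(h2$atoms),
                         noise_spec(sigma_atom = 0, n_frames = 3))
  md2 <- membrane_distance(tr2, helix_segment("A", 1, 10), slab, "lower")
  expect_equal(md2$values, md$values, tolerance = 1e-6)
  # brute-force nearest-atom scan agrees on random placements
  set.seed(12)
  h3 <- h
  h3$atoms[, c("x", "y", "z")] <- as.matrix(h3$atoms[, c("x", "y", "z")]) +
    matrix(rnorm(nrow(h3$atoms) * 3, sd = 3), ncol = 3)
  tr3 <- make_trajectory(structure_model(h3$atoms),
                         noise_spec(sigma_atom = 0, n_frames = 2))
  md3 <- membrane_distance(tr3, helix_segment("A", 1, 10), slab, "lower")
  rows <- which(tr3$atoms$resno >= 8 & !grepl("^H", tr3$atoms$elety))
  com3 <- colMeans(tr3$xyz[rows, , 1])
  expect_equal(md3$values[1],
               sqrt(min(rowSums(sweep(slab$lower, 2, com3)^2))))
})
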