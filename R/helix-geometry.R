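# Helix axis fitting and helix-pair descriptors: signed crossing angle,
# per-residue rotation angle, register shift, tilt, inter-axial distance.

coords_to_ca <- function(x) {
  if (is.data.frame(x)) return(ca_matrix(x))
  m <- as.matrix(x)
  stopifnot(ncol(m) == 3)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  m
}

# initial axis estimate: bisector directions + circle fit.
# For each interior residue the bisector (CA[i-1]-CA[i]) + (CA[i+1]-CA[i])
# points exactly at the axis of a regular helix; the direction is the null
# eigenvector of the summed unit-bisector outer products, the point the
# least-squares circle center of the CA projections in the normal plane.
.axis_init <- function(ca) {
  n <- nrow(ca)
  bis <- matrix(NA_real_, n - 2, 3)
  for (i in 2:(n - 1)) {
    b <- (ca[i - 1, ] - ca[i, ]) + (ca[i + 1, ] - ca[i, ])
    nb <- vnorm(b)
    bis[i - 1, ] <- if (nb > 1e-9) b / nb else NA_real_
  }
  bis <- bis[stats::complete.cases(bis), , drop = FALSE]
  if (nrow(bis) < 3) {
    stop("geometry error: degenerate (collinear) CA input", call. = FALSE)
  }
  ev <- eigen(crossprod(bis), symmetric = TRUE)
  d <- ev$vectors[, 3]
  if (sum(d * (ca[n, ] - ca[1, ])) < 0) d <- -d
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(vcross(d, ref)); e2 <- vcross(d, e1)
  P <- cbind(ca %*% e1, ca %*% e2)
  A <- cbind(2 * P, 1)
  sol <- tryCatch(qr.solve(A, rowSums(P^2)),
                  error = function(e) stop("geometry error: circle fit failed",
                                           call. = FALSE))
  list(d = d, e1 = e1, e2 = e2, point = as.numeric(sol[1] * e1 + sol[2] * e2))
}

#' Fit a helix axis from CA coordinates
#'
#' Least-squares fit of a full parametric regular helix (axis direction and
#' position, radius, phase, twist and rise per residue) to the CA
#' positions, by Levenberg-Marquardt refinement of a closed-form initial
#' estimate (per-residue bisector directions, which point exactly at the
#' axis of a regular helix, plus a circle fit in the normal plane). The
#' fit is exact (zero residual) on an ideal helix and is the
#' maximum-likelihood axis under isotropic coordinate noise; local
#' distortions (kinks, bulges) are absorbed into `rms_deviation`, which
#' flags irregularity, rather than producing discrete kink calls. The
#' direction is oriented N to C.
#'
#' @param ca_coords residue-indexed CA coordinate table: either the output
#'   of [select_segment()] or an `n x 3` matrix with residue indices as
#'   rownames.
#' @return An object of class `helix_axis`: `point`, unit `direction`
#'   (N to C), `residue_projections` (named axial coordinates, A),
#'   `radius`, `twist`, `rise` and `rms_deviation` (CA spread about the
#'   mean radius, A).
#' @export
fit_helix_axis <- function(ca_coords) {
  ca <- coords_to_ca(ca_coords)
  n <- nrow(ca)
  if (n < 8) {
    stop("geometry error: axis fitting needs >= 8 CA positions", call. = FALSE)
  }
  init <- .axis_init(ca)
  d0 <- init$d; e1 <- init$e1; e2 <- init$e2; p0 <- init$point
  # initial cylinder coordinates about the first-pass axis
  t0 <- as.numeric(sweep(ca, 2, p0) %*% d0)
  rad0 <- sweep(ca, 2, p0) - outer(t0, d0)
  phi_raw <- atan2(rad0 %*% e2, rad0 %*% e1)
  phi <- as.numeric(phi_raw)
  phi <- phi[1] + cumsum(c(0, wrap180(rad2deg(diff(phi))))) * pi / 180
  idx <- seq_len(n) - 1
  tau0 <- if (n > 1) stats::coef(stats::lm(phi ~ idx))[2] else 0
  phi0 <- phi[1]
  h0 <- mean(diff(t0)); z0 <- t0[1]
  r0 <- mean(sqrt(rowSums(rad0^2)))

  model_xyz <- function(p) {
    d <- unitv(d0 + p[1] * e1 + p[2] * e2)
    u1 <- unitv(e1 - sum(e1 * d) * d)
    u2 <- vcross(d, u1)
    q <- p0 + p[3] * e1 + p[4] * e2
    tt <- p[5] + idx * p[6]
    ph <- p[8] + idx * p[9]
    sweep(outer(tt, d) + p[7] * (outer(cos(ph), u1) + outer(sin(ph), u2)),
          2, q, "+")
  }
  resid_fn <- function(p) as.numeric(ca - model_xyz(p))
  start <- c(0, 0, 0, 0, z0, h0, r0, phi0, tau0)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  p <- if (!is.null(fit)) fit$par else start
  d <- unitv(d0 + p[1] * e1 + p[2] * e2)
  if (sum(d * (ca[n, ] - ca[1, ])) < 0) d <- -d
  point <- p0 + p[3] * e1 + p[4] * e2
  # report the foot of the axis, coordinates along it, and radial spread
  t <- as.numeric(sweep(ca, 2, point) %*% d)
  radial <- sweep(ca, 2, point) - outer(t, d)
  r <- sqrt(rowSums(radial^2))
  proj <- stats::setNames(t, rownames(ca))
  structure(list(point = as.numeric(point), direction = as.numeric(d),
                 residue_projections = proj,
                 radius = mean(r),
                 twist = rad2deg(p[9]), rise = p[6],
                 rms_deviation = sqrt(mean((r - mean(r))^2))),
            class = "helix_axis")
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf("helix_axis: dir (%.3f, %.3f, %.3f), %d residues, radius %.2f A, rmsd %.3f A\n",
              x$direction[1], x$direction[2], x$direction[3],
              length(x$residue_projections), x$radius, x$rms_deviation))
  invisible(x)
}

# closest approach between two lines (point + unit direction); no
# parallel handling here - callers decide the tie-break
.line_closest_approach <- function(p1, d1, p2, d2) {
  b <- sum(d1 * d2)
  r <- p1 - p2
  denom <- 1 - b^2
  t <- (-sum(r * d1) + b * sum(r * d2)) / denom
  s <- (sum(r * d2) - b * sum(r * d1)) / denom
  qa <- p1 + t * d1
  qb <- p2 + s * d2
  list(point_a = qa, point_b = qb, distance = vnorm(qb - qa),
       t_a = t, t_b = s)
}

# signed crossing between two oriented lines, folded into (-90, 90];
# positive = left-handed, negative = right-handed
.signed_crossing <- function(p1, d1, p2, d2) {
  cr <- vcross(d1, d2)
  if (vnorm(cr) < 1e-9) return(0)
  ca <- .line_closest_approach(p1, d1, p2, d2)
  if (ca$distance < 1e-8) {
    stop("geometry error: axes intersect; crossing handedness undefined",
         call. = FALSE)
  }
  u <- (ca$point_b - ca$point_a) / ca$distance
  ang <- rad2deg(atan2(sum(cr * u), sum(d1 * d2)))
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Closest approach between two helix axes
#'
#' Standard mutual-perpendicular segment between the two axis lines. For
#' parallel axes the foot of the perpendicular dropped from axis A's
#' first-residue projection is used (the continuous limit of the skew
#' case).
#'
#' @param axis_a,axis_b [fit_helix_axis()] results.
#' @return list with `point_a`, `point_b`, unit `vector` (A to B) and
#'   `distance` (A).
#' @export
closest_approach <- function(axis_a, axis_b) {
  stopifnot(inherits(axis_a, "helix_axis"), inherits(axis_b, "helix_axis"))
  p1 <- axis_a$point; d1 <- axis_a$direction
  p2 <- axis_b$point; d2 <- axis_b$direction
  # below ~0.06 deg the mutual-perpendicular direction of two fitted lines
  # is numerically degenerate; use the parallel-limit tie-break there
  if (vnorm(vcross(d1, d2)) < 1e-3) {
    qa <- p1 + axis_a$residue_projections[1] * d1
    w <- qa - p2
    qb <- p2 + sum(w * d2) * d2
    dist <- vnorm(qa - qb)
    if (dist < 1e-8) {
      stop("geometry error: coincident axes", call. = FALSE)
    }
    return(list(point_a = qa, point_b = qb,
                vector = (qb - qa) / dist, distance = dist))
  }
  ca <- .line_closest_approach(p1, d1, p2, d2)
  if (ca$distance < 1e-8) {
    stop("geometry error: intersecting axes; approach vector undefined",
         call. = FALSE)
  }
  list(point_a = ca$point_a, point_b = ca$point_b,
       vector = (ca$point_b - ca$point_a) / ca$distance,
       distance = ca$distance)
}

#' Signed helix crossing angle
#'
#' Magnitude is the acute angle between the axis directions; the sign is
#' the handedness of the crossing, read from the signed dihedral
#' a -> closest-approach -> b: negative for right-handed crossings,
#' positive for left-handed (the convention in which published right-handed
#' TM dimers such as GpA-like packings carry negative angles). Values are
#' reported in (-90, 90]; the result is invariant under swapping the two
#' axes and flips sign under reflection.
#'
#' @param axis_a,axis_b [fit_helix_axis()] results.
#' @return signed crossing angle in degrees.
#' @export
crossing_angle <- function(axis_a, axis_b) {
  stopifnot(inherits(axis_a, "helix_axis"), inherits(axis_b, "helix_axis"))
  cr <- vcross(axis_a$direction, axis_b$direction)
  if (vnorm(cr) < 1e-3) {
    # (near-)parallel axes: the residual angle is reported with the sign
    # read from the parallel-limit approach vector (zero separation is an
    # error raised by the tie-break)
    ca <- closest_approach(axis_a, axis_b)
    ang <- rad2deg(atan2(sum(cr * ca$vector),
                         sum(axis_a$direction * axis_b$direction)))
    if (ang > 90) ang <- ang - 180
    if (ang <= -90) ang <- ang + 180
    return(ang)
  }
  .signed_crossing(axis_a$point, axis_a$direction,
                   axis_b$point, axis_b$direction)
}

#' Rotation angle of a reference residue about its helix axis
#'
#' The azimuthal position of the reference residue's CA about the helix
#' axis, measured from the interhelix approach vector: both the radial
#' vector (axis to CA) and the approach vector are projected onto the plane
#' normal to the axis and the signed angle between them is returned in
#' (-180, 180], positive clockwise when viewed from the N-terminal side.
#' This reports which helix face points at the partner.
#'
#' @param helix_cas residue-indexed CA table ([select_segment()] output or
#'   matrix with residue rownames).
#' @param axis the helix's [fit_helix_axis()].
#' @param reference_residue renumbered residue index (typically 4, one turn
#'   into the membrane, or 11, near the TM center).
#' @param approach_vector 3-vector from this helix towards its partner
#'   (for time series, the initial-frame approach vector held fixed).
#' @return rotation angle in degrees.
#' @export
rotation_angle <- function(helix_cas, axis, reference_residue,
                           approach_vector) {
  stopifnot(inherits(axis, "helix_axis"))
  ca <- coords_to_ca(helix_cas)
  row <- match(as.character(reference_residue), rownames(ca))
  if (is.na(row)) {
    stop("geometry error: reference residue ", reference_residue,
         " not in the supplied CA table", call. = FALSE)
  }
  d <- axis$direction
  p <- ca[row, ] - axis$point
  radial <- p - sum(p * d) * d
  if (vnorm(radial) < 1e-6) {
    stop("geometry error: reference CA lies on the helix axis", call. = FALSE)
  }
  a <- approach_vector - sum(approach_vector * d) * d
  if (vnorm(a) < 1e-9) {
    stop("geometry error: approach vector parallel to the helix axis",
         call. = FALSE)
  }
  wrap180(rad2deg(atan2(sum(d * vcross(a, radial)), sum(a * radial))))
}

#' Register (piston) shift between two helices
#'
#' Axial offset of helix B relative to helix A at an equivalent residue:
#' each residue's axial coordinate is measured along its own axis from the
#' closest-approach foot point, and the difference (B minus A) is returned.
#' Measuring from the mutual-perpendicular feet makes the value invariant
#' under the crossing angle; one canonical helical turn corresponds to
#' 5.4 A. The sign flips when the helices are swapped.
#'
#' @param axis_a,axis_b [fit_helix_axis()] results (must be co-oriented:
#'   an inter-axis angle beyond 90 degrees is an error).
#' @param equivalent_residue renumbered residue index present in both
#'   helices' projections.
#' @return register shift in A (positive: B displaced towards its
#'   C-terminus relative to A).
#' @export
register_shift <- function(axis_a, axis_b, equivalent_residue) {
  stopifnot(inherits(axis_a, "helix_axis"), inherits(axis_b, "helix_axis"))
  if (sum(axis_a$direction * axis_b$direction) < 0) {
    stop("geometry error: axes are anti-aligned (angle > 90 degrees); ",
         "orient both N-to-C before comparing register", call. = FALSE)
  }
  key <- as.character(equivalent_residue)
  if (!key %in% names(axis_a$residue_projections) ||
      !key %in% names(axis_b$residue_projections)) {
    stop("geometry error: residue ", equivalent_residue,
         " absent from one of the axes", call. = FALSE)
  }
  ca <- closest_approach(axis_a, axis_b)
  foot_a <- sum((ca$point_a - axis_a$point) * axis_a$direction)
  foot_b <- sum((ca$point_b - axis_b$point) * axis_b$direction)
  (axis_b$residue_projections[[key]] - foot_b) -
    (axis_a$residue_projections[[key]] - foot_a)
}

#' Helix tilt relative to the membrane normal
#'
#' Orientation-independent angle in [0, 90] between the helix axis and the
#' membrane normal (+z by the package's frame convention: right-handed
#' coordinates, extracellular side +z).
#'
#' @param axis a [fit_helix_axis()] result.
#' @param membrane_normal membrane normal vector (default +z).
#' @return tilt angle in degrees.
#' @export
tilt_angle <- function(axis, membrane_normal = c(0, 0, 1)) {
  stopifnot(inherits(axis, "helix_axis"))
  ct <- abs(sum(unitv(axis$direction) * unitv(membrane_normal)))
  rad2deg(acos(min(1, ct)))
}

#' Full helix-pair geometry of a two-chain model
#'
#' Convenience wrapper computing every pair descriptor for two helix
#' segments of one model: fitted axes, signed crossing angle,
#' closest-approach vector and inter-axial distance, rotation angles of the
#' reference residues on both helices (helix A measured from the A-to-B
#' approach vector, helix B from B-to-A), register shift and per-helix
#' tilt.
#'
#' @param model a [structure_model()] with at least two chains.
#' @param segments list of two [helix_segment()]; by default the full
#'   residue range of the first two chains.
#' @param reference_residues renumbered residues for rotation angles
#'   (default 4 and 11).
#' @param register_residue renumbered residue for the register shift
#'   (default: central residue of the common range).
#' @param approach_vectors optional list `(a, b)` of fixed approach vectors
#'   (time-series mode); defaults to this structure's own closest approach.
#' @return An object of class `dimer_geometry`.
#' @export
dimer_geometry <- function(model, segments = NULL,
                           reference_residues = c(4, 11),
                           register_residue = NULL,
                           approach_vectors = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(segments)) segments <- default_segments(model)[1:2]
  stopifnot(length(segments) == 2)
  cas <- lapply(segments, function(s) select_segment(model, s, "CA"))
  axes <- lapply(cas, fit_helix_axis)
  ca <- closest_approach(axes[[1]], axes[[2]])
  crossing <- crossing_angle(axes[[1]], axes[[2]])
  if (is.null(approach_vectors)) {
    approach_vectors <- list(a = ca$vector, b = -ca$vector)
  }
  rot <- matrix(NA_real_, nrow = 2, ncol = length(reference_residues),
                dimnames = list(c("A", "B"), reference_residues))
  for (j in seq_along(reference_residues)) {
    rot["A", j] <- rotation_angle(cas[[1]], axes[[1]],
                                  reference_residues[j], approach_vectors$a)
    rot["B", j] <- rotation_angle(cas[[2]], axes[[2]],
                                  reference_residues[j], approach_vectors$b)
  }
  common <- intersect(names(axes[[1]]$residue_projections),
                      names(axes[[2]]$residue_projections))
  if (is.null(register_residue)) {
    register_residue <- as.integer(common[ceiling(length(common) / 2)])
  }
  structure(list(
    crossing_angle = crossing,
    closest_approach_vector = ca$vector,
    inter_axial_distance = ca$distance,
    rotation_angles = rot,
    register_shift = register_shift(axes[[1]], axes[[2]], register_residue),
    register_residue = register_residue,
    tilt_a = tilt_angle(axes[[1]]), tilt_b = tilt_angle(axes[[2]]),
    axes = axes, segments = segments),
    class = "dimer_geometry")
}

#' @export
print.dimer_geometry <- function(x, ...) {
  cat(sprintf("dimer_geometry: crossing %.1f deg, inter-axial %.2f A, register %.2f A\n",
              x$crossing_angle, x$inter_axial_distance, x$register_shift))
  cat("rotation angles (deg):\n")
  print(round(x$rotation_angles, 1))
  cat(sprintf("tilt: A %.1f deg, B %.1f deg\n", x$tilt_a, x$tilt_b))
  invisible(x)
}

# one full-range segment per chain
default_segments <- function(model) {
  lapply(unique(model$atoms$chain), function(ch) {
    rs <- range(model$atoms$resno[model$atoms$chain == ch])
    helix_segment(ch, rs[1], rs[2])
  })
}
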