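# Internal vector/rigid-body helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# wrap an angle in degrees into (-180, 180]
wrap180 <- function(x) {
  y <- ((x + 180) %% 360) - 180
  ifelse(y == -180, 180, y)
}

# rotation matrix about arbitrary unit axis (Rodrigues), angle in degrees
rotation_about <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# rotate n x 3 coordinate matrix about an axis through a point
rotate_coords <- function(xyz, axis, angle_deg, center = c(0, 0, 0)) {
  R <- rotation_about(axis, angle_deg)
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+")
}

# NeRF atom placement: position D from reference atoms A-B-C with
# bond |C-D|, angle B-C-D and dihedral A-B-C-D (degrees).
place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- deg2rad(angle); dih <- deg2rad(dihedral)
  bc <- unitv(C - B)
  n <- unitv(vcross(B - A, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Kabsch superposition of mobile onto fixed (both n x 3); returns list with
# the transformed mobile coordinates and the applied rotation/translation.
kabsch_fit <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), ncol(mobile) == 3)
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- sweep(P %*% t(R), 2, cf, "+")
  list(xyz = fitted, rotation = R, center_mobile = cm, center_fixed = cf)
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# restore RNG state on exit; all generator randomness goes through this
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
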