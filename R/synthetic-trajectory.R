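# Synthetic trajectories: stationary Gaussian noise around a base
# structure, optional linear parameter drift, and a one-residue NH cone
# probe used as the order-parameter oracle.

#' Noise/drift specification for synthetic trajectories
#'
#' @param sigma_atom isotropic Gaussian noise, standard deviation per
#'   coordinate (A), >= 0.
#' @param n_frames number of frames (>= 2).
#' @param dt_ns frame spacing (ns).
#' @param drift optional `list(parameter = "crossing_angle" or
#'   "register_shift", delta = total change over the trajectory)`; the
#'   ground-truth parameter then varies linearly from its base value to
#'   base + delta.
#' @param jitter optional stationary geometric fluctuation: a named list
#'   of per-frame standard deviations for `crossing_angle` (deg),
#'   `rotation` (deg, applied to both helices independently) and
#'   `register_shift` (A); each frame is rebuilt from the base
#'   [dimer_spec()] with parameters drawn around their base values,
#'   emulating the collective fluctuations of an equilibrated simulation
#'   rather than independent per-atom noise.
#' @param seed integer seed; identical seeds give bit-identical
#'   trajectories.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_atom = 0, n_frames = 2, dt_ns = 1,
                       drift = NULL, jitter = NULL, seed = 1L) {
  if (sigma_atom < 0) stop("sigma_atom must be >= 0", call. = FALSE)
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (!is.null(drift)) {
    stopifnot(is.list(drift), !is.null(drift$parameter),
              !is.null(drift$delta))
    if (!drift$parameter %in% c("crossing_angle", "register_shift")) {
      stop("drift parameter must be 'crossing_angle' or 'register_shift'",
           call. = FALSE)
    }
  }
  if (!is.null(jitter)) {
    bad <- setdiff(names(jitter),
                   c("crossing_angle", "rotation", "register_shift"))
    if (length(bad) > 0) {
      stop("unknown jitter parameter(s): ", paste(bad, collapse = ","),
           call. = FALSE)
    }
  }
  structure(list(sigma_atom = sigma_atom, n_frames = as.integer(n_frames),
                 dt_ns = dt_ns, drift = drift, jitter = jitter,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a synthetic trajectory around a base structure
#'
#' Frames are copies of the base structure with independent isotropic
#' Gaussian noise added to every coordinate. With a drift specification the
#' base itself is rebuilt per frame from its generating [dimer_spec()]
#' (which [make_dimer()] stores in the model metadata) so that the drifting
#' parameter's ground truth varies linearly from its base value to
#' base + delta across the trajectory. Without noise or drift all frames
#' equal the base.
#'
#' @param base a [structure_model()]; for drift it must carry
#'   `metadata$dimer_spec`.
#' @param noise a [noise_spec()].
#' @return A [trajectory()].
#' @export
make_trajectory <- function(base, noise) {
  stopifnot(inherits(base, "structure_model"), inherits(noise, "noise_spec"))
  nf <- noise$n_frames
  needs_rebuild <- !is.null(noise$drift) || !is.null(noise$jitter)
  spec <- base$metadata$dimer_spec
  if (needs_rebuild && is.null(spec)) {
    stop("drift/jitter require a base built by make_dimer() ",
         "(dimer_spec metadata)", call. = FALSE)
  }
  frames <- with_seed(noise$seed, {
    lapply(seq_len(nf), function(k) {
      b <- base
      if (needs_rebuild) {
        sp <- spec
        if (!is.null(noise$drift)) {
          frac <- (k - 1) / (nf - 1)
          sp[[noise$drift$parameter]] <-
            sp[[noise$drift$parameter]] + noise$drift$delta * frac
        }
        jt <- noise$jitter
        if (!is.null(jt)) {
          if (!is.null(jt$crossing_angle)) {
            sp$crossing_angle <- sp$crossing_angle +
              stats::rnorm(1, sd = jt$crossing_angle)
          }
          if (!is.null(jt$rotation)) {
            sp$rotation_a <- sp$rotation_a + stats::rnorm(1, sd = jt$rotation)
            sp$rotation_b <- sp$rotation_b + stats::rnorm(1, sd = jt$rotation)
          }
          if (!is.null(jt$register_shift)) {
            sp$register_shift <- sp$register_shift +
              stats::rnorm(1, sd = jt$register_shift)
          }
        }
        b <- make_dimer(sp)
      }
      at <- b$atoms
      if (noise$sigma_atom > 0) {
        at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
          matrix(stats::rnorm(nrow(at) * 3, sd = noise$sigma_atom),
                 ncol = 3)
      }
      structure_model(at, metadata = b$metadata)
    })
  })
  trajectory(frames, times_ns = (seq_len(nf) - 1) * noise$dt_ns)
}

#' One-residue NH cone-probe trajectory
#'
#' Generates a trajectory of a single glycine whose amide NH unit vector is
#' drawn uniformly from within a cone of the given half-angle about +z (the
#' N position and the rest of the residue are fixed). This is the analytic
#' oracle for the S2 order parameter: uniform sampling within a cone of
#' half-angle theta gives S2 = [cos(theta) (1 + cos(theta)) / 2]^2, i.e. 1
#' in the rigid limit (half-angle 0) and 0 for the full hemisphere.
#'
#' @param half_angle cone half-angle in degrees, in [0, 180].
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param dt_ns frame spacing (ns), default 0.01.
#' @return A [trajectory()] with atoms N, H, CA of one residue.
#' @export
make_cone_nh_trajectory <- function(half_angle, n_frames, seed = 1L,
                                    dt_ns = 0.01) {
  stopifnot(half_angle >= 0, half_angle <= 180, n_frames >= 2)
  cmin <- cos(deg2rad(half_angle))
  u <- with_seed(seed, {
    ct <- stats::runif(n_frames, min = cmin, max = 1)
    phi <- stats::runif(n_frames, 0, 2 * pi)
    st <- sqrt(pmax(0, 1 - ct^2))
    cbind(st * cos(phi), st * sin(phi), ct)
  })
  lab <- data.frame(chain = "A", resno = 1L, resid = "GLY",
                    elety = c("N", "H", "CA"), stringsAsFactors = FALSE)
  frames <- lapply(seq_len(n_frames), function(k) {
    xyz <- rbind(c(0, 0, 0), 1.01 * u[k, ], c(1.458, 0, 0))
    structure_model(cbind(lab, data.frame(x = xyz[, 1], y = xyz[, 2],
                                          z = xyz[, 3])))
  })
  trajectory(frames, times_ns = (seq_len(n_frames) - 1) * dt_ns)
}

#' Closed-form cone S2 order parameter
#'
#' S2 for an NH vector uniformly distributed within a cone of the given
#' half-angle: `[cos(theta) (1 + cos(theta)) / 2]^2`.
#'
#' @param half_angle cone half-angle in degrees.
#' @return the order parameter in [0, 1].
#' @export
cone_s2 <- function(half_angle) {
  ct <- cos(deg2rad(half_angle))
  (ct * (1 + ct) / 2)^2
}
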