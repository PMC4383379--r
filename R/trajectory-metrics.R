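# Time-resolved analysis: geometry time series, equilibration assessment,
# RMSF, NH S2 order parameters, Ser/Thr hydroxyl contacts and
# JM-tail-to-membrane distances.

#' Construct a labeled time series
#'
#' @param metric metric name.
#' @param times_ns strictly increasing times (ns).
#' @param values numeric values (NA marks flagged gaps).
#' @param units unit string.
#' @return An object of class `time_series`.
#' @export
time_series <- function(metric, times_ns, values, units = "") {
  stopifnot(length(times_ns) == length(values))
  if (length(times_ns) > 1 && any(diff(times_ns) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(metric = metric, times_ns = as.numeric(times_ns),
                 values = as.numeric(values), units = units),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  ok <- x$values[!is.na(x$values)]
  cat(sprintf("time_series '%s': %d points, mean %.3f %s (%d gaps)\n",
              x$metric, length(x$values), mean(ok), x$units,
              sum(is.na(x$values))))
  invisible(x)
}

# centered 14-residue window (the always-membrane-embedded core), or the
# full segment when shorter
central_region <- function(segment, width = 14) {
  n <- segment$last_residue - segment$first_residue + 1L
  if (n <= width) return(c(1L, n))
  lo <- floor((n - width) / 2) + 1L
  c(lo, lo + width - 1L)
}

frame_xyz_of <- function(traj, rows, k) {
  traj$xyz[rows, , k, drop = FALSE][, , 1, drop = TRUE]
}

#' Geometry time series of a two-helix trajectory
#'
#' Computes, per frame: RMSD of the central-region backbone to the starting
#' structure (after best-fit superposition), the signed crossing angle from
#' per-frame fitted axes, and per-helix rotation angles of the reference
#' residues measured against the *initial-frame* closest-approach vector
#' held fixed and offset so that the starting structure's rotation is zero.
#' Frames where the axis fit fails are flagged as gaps (NA) and the series
#' continues.
#'
#' @param traj a [trajectory()].
#' @param segments list of two [helix_segment()]; default: full chains.
#' @param reference_residues renumbered rotation reference residues
#'   (default 4 and 11).
#' @param region renumbered residue range for the RMSD central region;
#'   default: centered 14-residue core of segment 1.
#' @return named list of [time_series()]: `rmsd`, `crossing`, and
#'   `rotation_<helix>_<residue>` entries.
#' @export
geometry_timeseries <- function(traj, segments = NULL,
                                reference_residues = c(4, 11),
                                region = NULL) {
  stopifnot(inherits(traj, "trajectory"), n_frames(traj) >= 2)
  m0 <- frame_model(traj, 1)
  if (is.null(segments)) segments <- default_segments(m0)[1:2]
  stopifnot(length(segments) == 2)
  if (is.null(region)) region <- central_region(segments[[1]])

  # row indices once: labeling is shared across frames
  seg_rows <- function(seg, filter) {
    at <- traj$atoms
    keep <- at$chain == seg$chain_id &
      at$resno >= seg$first_residue & at$resno <= seg$last_residue
    if (identical(filter, "CA")) keep <- keep & at$elety == "CA"
    if (identical(filter, "backbone")) {
      keep <- keep & at$elety %in% c("N", "CA", "C", "O")
    }
    which(keep)
  }
  ca_rows <- lapply(segments, seg_rows, filter = "CA")
  ca_resno <- lapply(seq_along(segments), function(i) {
    traj$atoms$resno[ca_rows[[i]]] - segments[[i]]$first_residue + 1L
  })
  bb_rows <- unlist(lapply(segments, function(seg) {
    r <- seg_rows(seg, "backbone")
    ren <- traj$atoms$resno[r] - seg$first_residue + 1L
    r[ren >= region[1] & ren <= region[2]]
  }))

  fit_frame <- function(k) {
    axes <- lapply(seq_along(segments), function(i) {
      m <- frame_xyz_of(traj, ca_rows[[i]], k)
      rownames(m) <- ca_resno[[i]]
      fit_helix_axis(m)
    })
    list(axes = axes,
         cas = lapply(seq_along(segments), function(i) {
           m <- frame_xyz_of(traj, ca_rows[[i]], k)
           rownames(m) <- ca_resno[[i]]
           m
         }))
  }

  f0 <- fit_frame(1)
  ca0 <- closest_approach(f0$axes[[1]], f0$axes[[2]])
  u0 <- list(ca0$vector, -ca0$vector)
  bb0 <- frame_xyz_of(traj, bb_rows, 1)
  rot0 <- matrix(NA_real_, 2, length(reference_residues))
  for (h in 1:2) {
    for (j in seq_along(reference_residues)) {
      rot0[h, j] <- rotation_angle(f0$cas[[h]], f0$axes[[h]],
                                   reference_residues[j], u0[[h]])
    }
  }

  nf <- n_frames(traj)
  rmsd_v <- cross_v <- rep(NA_real_, nf)
  rot_v <- array(NA_real_, c(2, length(reference_residues), nf))
  for (k in seq_len(nf)) {
    bbk <- frame_xyz_of(traj, bb_rows, k)
    rmsd_v[k] <- rmsd_xyz(kabsch_fit(bbk, bb0)$xyz, bb0)
    fk <- tryCatch(fit_frame(k), error = function(e) NULL)
    if (is.null(fk)) next  # flagged gap
    cross_v[k] <- tryCatch(crossing_angle(fk$axes[[1]], fk$axes[[2]]),
                           error = function(e) NA_real_)
    for (h in 1:2) {
      for (j in seq_along(reference_residues)) {
        v <- tryCatch(rotation_angle(fk$cas[[h]], fk$axes[[h]],
                                     reference_residues[j], u0[[h]]),
                      error = function(e) NA_real_)
        rot_v[h, j, k] <- wrap180(v - rot0[h, j])
      }
    }
  }
  out <- list(
    rmsd = time_series("rmsd_to_start", traj$times_ns, rmsd_v, "A"),
    crossing = time_series("crossing", traj$times_ns, cross_v, "deg"))
  hl <- c("A", "B")
  for (h in 1:2) {
    for (j in seq_along(reference_residues)) {
      nm <- paste0("rotation_", hl[h], "_", reference_residues[j])
      out[[nm]] <- time_series(nm, traj$times_ns, rot_v[h, j, ], "deg")
    }
  }
  out
}

#' Equilibration assessment over a trailing window
#'
#' Computes means and standard deviations of each series over the last
#' `window_ns` of the trajectory and applies the equilibration criteria:
#' the RMSD series must have a standard deviation below `rmsd_sd`,
#' crossing-angle series must stay within `crossing_range` of their window
#' mean, and rotation series within `rotation_range` (ranges interpreted as
#' max |value - mean|; set `mode = "sd"` to compare standard deviations
#' against the same thresholds instead). A trajectory passes only if every
#' criterion passes; injected drift inside the window fails.
#'
#' @param series_set named list of [time_series()] (e.g. from
#'   [geometry_timeseries()]); metric names starting `rmsd`, `crossing` or
#'   `rotation` select the criterion applied.
#' @param window_ns trailing window length (ns), default 250.
#' @param thresholds list with `rmsd_sd` (A), `crossing_range` (deg),
#'   `rotation_range` (deg).
#' @param mode `"range"` (default) or `"sd"` fluctuation measure for
#'   angle series.
#' @return An object of class `equilibration_report` with a per-series
#'   statistics table and overall `pass`.
#' @export
equilibration_report <- function(series_set, window_ns = 250,
                                 thresholds = list(rmsd_sd = 0.5,
                                                   crossing_range = 10,
                                                   rotation_range = 25),
                                 mode = c("range", "sd")) {
  mode <- match.arg(mode)
  stopifnot(is.list(series_set), length(series_set) >= 1)
  t_all <- series_set[[1]]$times_ns
  span <- diff(range(t_all))
  if (window_ns > span) {
    stop("input error: window (", window_ns,
         " ns) exceeds the trajectory span (", span, " ns)", call. = FALSE)
  }
  t_hi <- max(t_all)
  rows <- lapply(series_set, function(s) {
    keep <- s$times_ns >= t_hi - window_ns & !is.na(s$values)
    v <- s$values[keep]
    mu <- mean(v); sdv <- stats::sd(v); rng <- max(abs(v - mu))
    crit <- if (grepl("^rmsd", s$metric)) "rmsd_sd"
      else if (grepl("^crossing", s$metric)) "crossing_range"
      else if (grepl("^rotation", s$metric)) "rotation_range"
      else NA_character_
    measure <- if (identical(crit, "rmsd_sd") || mode == "sd") sdv else rng
    pass <- if (is.na(crit)) NA else measure < thresholds[[crit]]
    data.frame(metric = s$metric, mean = mu, sd = sdv, range = rng,
               criterion = crit,
               threshold = ifelse(is.na(crit), NA_real_,
                                  thresholds[[crit]]),
               measure = measure, pass = pass, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(window_ns = c(t_hi - window_ns, t_hi), table = tab,
                 thresholds = thresholds, mode = mode,
                 pass = all(tab$pass, na.rm = TRUE)),
            class = "equilibration_report")
}

#' @export
print.equilibration_report <- function(x, ...) {
  cat(sprintf("equilibration_report: window %.1f-%.1f ns, %s\n",
              x$window_ns[1], x$window_ns[2],
              if (x$pass) "PASS" else "FAIL"))
  print(cbind(x$table[, c("metric", "criterion")],
              round(x$table[, c("mean", "sd", "range", "threshold")], 3),
              pass = x$table$pass))
  invisible(x)
}

# indices of selected atoms by selection keyword
.selection_rows <- function(atoms, selection) {
  switch(selection,
         mainchain = which(atoms$elety %in% c("N", "CA", "C", "O")),
         heavy = which(!grepl("^[0-9]*H", atoms$elety)),
         `mainchain+sidechain` = which(!grepl("^[0-9]*H", atoms$elety)),
         stop("unknown selection '", selection, "'", call. = FALSE))
}

# superpose every frame of an xyz array onto reference coordinates using
# the rows in align_rows; returns the transformed array
.align_frames <- function(xyz, align_rows, ref = NULL) {
  nf <- dim(xyz)[3]
  if (is.null(ref)) ref <- xyz[align_rows, , 1, drop = FALSE][, , 1]
  for (k in seq_len(nf)) {
    mob <- xyz[align_rows, , k]
    fit <- kabsch_fit(mob, ref)
    xyz[, , k] <- sweep(sweep(xyz[, , k], 2, fit$center_mobile) %*%
                          t(fit$rotation), 2, fit$center_fixed, "+")
  }
  xyz
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of the selected atoms about the trajectory-average structure, after
#' superposing every frame on the CA atoms of `align_on` (all CA atoms by
#' default). Frames are first aligned to frame 1, the average structure is
#' formed, frames are re-aligned to that average and the residue value is
#' the RMS over its selected atoms of the per-atom fluctuations.
#'
#' @param traj a [trajectory()].
#' @param selection `"mainchain"` (N, CA, C, O), `"heavy"`, or
#'   `"mainchain+sidechain"`.
#' @param align_on optional [helix_segment()] whose CA atoms drive the
#'   superposition.
#' @return data.frame with `chain`, `resno`, `resid`, `rmsf` (A).
#' @export
rmsf <- function(traj, selection = c("mainchain", "heavy",
                                     "mainchain+sidechain"),
                 align_on = NULL) {
  selection <- match.arg(selection)
  stopifnot(inherits(traj, "trajectory"), n_frames(traj) >= 2)
  at <- traj$atoms
  sel <- .selection_rows(at, selection)
  if (length(sel) == 0) stop("input error: empty selection", call. = FALSE)
  align_rows <- if (is.null(align_on)) {
    which(at$elety == "CA")
  } else {
    which(at$elety == "CA" & at$chain == align_on$chain_id &
            at$resno >= align_on$first_residue &
            at$resno <= align_on$last_residue)
  }
  if (length(align_rows) < 3) {
    stop("input error: fewer than 3 CA atoms to align on", call. = FALSE)
  }
  xyz <- .align_frames(traj$xyz, align_rows)
  avg <- apply(xyz, c(1, 2), mean)
  xyz <- .align_frames(xyz, align_rows, ref = avg[align_rows, ])
  avg <- apply(xyz, c(1, 2), mean)
  msf <- rowMeans(apply(xyz, 3, function(f) rowSums((f - avg)^2)))
  key <- paste(at$chain, at$resno)
  res_rows <- split(sel, key[sel])
  out <- do.call(rbind, lapply(res_rows, function(r) {
    data.frame(chain = at$chain[r[1]], resno = at$resno[r[1]],
               resid = at$resid[r[1]], rmsf = sqrt(mean(msf[r])),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  out
}

#' NH order parameters (S2) from a trajectory
#'
#' Generalized order parameters of mainchain NH bond vectors, estimated
#' per non-overlapping time block and averaged over blocks, so that
#' motions slower than the block length do not depress S2 (the block
#' length plays the role of an effective correlation-time cutoff for
#' comparison with solution NMR). Within each block, after optional
#' superposition of every frame on the alignment CA set, the unit NH
#' vectors u enter the second-moment estimator
#' `S2 = 3/2 (<x^2>^2 + <y^2>^2 + <z^2>^2 + 2<xy>^2 + 2<xz>^2 + 2<yz>^2) - 1/2`.
#' `method = "p2"` instead estimates the plateau of the P2 autocorrelation
#' from frame pairs separated by at least half the block (an independent
#' route that should agree with the moment estimator). Amide hydrogens
#' missing from the input are reconstructed per frame as in
#' [reconstruct_amide_h()]; prolines and chain-initial residues are
#' omitted with a message.
#'
#' @param traj a [trajectory()].
#' @param block_ns block length in ns (default 10); the trajectory span
#'   must be at least one block.
#' @param align superpose frames on CA atoms before analysis (default
#'   TRUE; disable for probes analyzed in a fixed frame).
#' @param align_on optional [helix_segment()] restricting the alignment CA
#'   set (typically the central TM region).
#' @param method `"moments"` (default) or `"p2"`.
#' @return data.frame with `chain`, `resno`, `resid`, `s2`; block length
#'   and method in attributes.
#' @export
order_parameters <- function(traj, block_ns = 10, align = TRUE,
                             align_on = NULL,
                             method = c("moments", "p2")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "trajectory"))
  t <- traj$times_ns
  span <- t[length(t)] - t[1]
  if (span < block_ns) {
    stop("input error: trajectory span (", span,
         " ns) is shorter than one block (", block_ns, " ns)",
         call. = FALSE)
  }
  at <- traj$atoms
  xyz <- traj$xyz
  if (align) {
    align_rows <- if (is.null(align_on)) which(at$elety == "CA") else {
      which(at$elety == "CA" & at$chain == align_on$chain_id &
              at$resno >= align_on$first_residue &
              at$resno <= align_on$last_residue)
    }
    if (length(align_rows) >= 3) xyz <- .align_frames(xyz, align_rows)
  }
  # NH vectors per residue: use stored H or reconstruct from Cprev, N, CA
  key <- paste(at$chain, at$resno)
  residues <- unique(at[, c("chain", "resno", "resid")])
  residues <- residues[order(residues$chain, residues$resno), ]
  omitted <- character(0)
  nh <- list()
  for (i in seq_len(nrow(residues))) {
    ch <- residues$chain[i]; rn <- residues$resno[i]
    rk <- paste(ch, rn)
    if (residues$resid[i] == "PRO") {
      omitted <- c(omitted, rk); next
    }
    nrow_i <- which(key == rk & at$elety == "N")
    hrow_i <- which(key == rk & at$elety == "H")
    if (length(nrow_i) != 1) { omitted <- c(omitted, rk); next }
    if (length(hrow_i) == 1) {
      u <- xyz[hrow_i, , ] - xyz[nrow_i, , ]
    } else {
      carow <- which(key == rk & at$elety == "CA")
      cprev <- which(paste(at$chain, at$resno) == paste(ch, rn - 1) &
                       at$elety == "C")
      if (length(carow) != 1 || length(cprev) != 1) {
        omitted <- c(omitted, rk); next
      }
      vn <- xyz[nrow_i, , ] - xyz[cprev, , ]
      vc <- xyz[nrow_i, , ] - xyz[carow, , ]
      vn <- vn / rep(sqrt(colSums(vn^2)), each = 3)
      vc <- vc / rep(sqrt(colSums(vc^2)), each = 3)
      u <- vn + vc
    }
    u <- u / rep(sqrt(colSums(u^2)), each = 3)  # 3 x nframes unit vectors
    nh[[rk]] <- u
  }
  if (length(omitted) > 0) {
    message("order_parameters: omitted residues without NH: ",
            paste(omitted, collapse = ", "))
  }
  nb <- max(1L, floor(span / block_ns))
  blocks <- split(seq_along(t),
                  pmin(floor((t - t[1]) / block_ns), nb - 1L))
  blocks <- blocks[vapply(blocks, length, 1L) >= 2]
  s2_of_block <- function(u, idx) {
    x <- u[1, idx]; y <- u[2, idx]; z <- u[3, idx]
    if (method == "moments") {
      1.5 * (mean(x^2)^2 + mean(y^2)^2 + mean(z^2)^2 +
               2 * mean(x * y)^2 + 2 * mean(x * z)^2 +
               2 * mean(y * z)^2) - 0.5
    } else {
      # P2 autocorrelation plateau: average C(tau) at a few long,
      # deterministic lags over all available origins
      n <- length(idx)
      lags <- unique(pmax(1L, floor(n * c(1 / 2, 2 / 3, 3 / 4))))
      lags <- lags[lags < n]
      mean(vapply(lags, function(l) {
        i1 <- seq_len(n - l); i2 <- i1 + l
        d <- x[i1] * x[i2] + y[i1] * y[i2] + z[i1] * z[i2]
        mean(1.5 * d^2 - 0.5)
      }, 1))
    }
  }
  vals <- vapply(names(nh), function(rk) {
    mean(vapply(blocks, function(idx) s2_of_block(nh[[rk]], idx), 1))
  }, 1)
  keep <- match(names(nh), paste(residues$chain, residues$resno))
  out <- data.frame(chain = residues$chain[keep],
                    resno = residues$resno[keep],
                    resid = residues$resid[keep],
                    s2 = unname(vals), stringsAsFactors = FALSE)
  attr(out, "block_ns") <- block_ns
  attr(out, "method") <- method
  attr(out, "n_blocks") <- length(blocks)
  out
}

#' Cross-chain Ser/Thr hydroxyl minimum-distance series
#'
#' For every pair of chains, tracks the per-frame minimum distance over all
#' cross-chain Ser OG / Thr OG1 atom pairs (auto-detected, or restricted to
#' `pairs`), together with the fraction of frames below the contact cutoffs
#' (3.5 A: close hydrogen-bond-like contact; 5.0 A: persistent sidechain
#' contact).
#'
#' @param traj a [trajectory()].
#' @param pairs optional data.frame with columns `chain_a`, `resno_a`,
#'   `chain_b`, `resno_b` restricting the hydroxyl pairs.
#' @param cutoffs contact cutoffs (A).
#' @return named list (one entry per chain pair `"A|B"`), each with the
#'   minimum-distance [time_series()], `fractions`, and the contributing
#'   atom pairs; empty (with a message) when no Ser/Thr hydroxyls exist.
#' @export
min_contact_distance <- function(traj, pairs = NULL, cutoffs = c(3.5, 5.0)) {
  stopifnot(inherits(traj, "trajectory"))
  at <- traj$atoms
  hyd <- which(at$elety %in% c("OG", "OG1") & at$resid %in% c("SER", "THR"))
  if (length(hyd) == 0) {
    message("min_contact_distance: no Ser/Thr hydroxyl atoms in trajectory")
    return(structure(list(), class = "contact_series_set"))
  }
  chains <- sort(unique(at$chain[hyd]))
  out <- list()
  for (i in seq_along(chains)) {
    for (j in seq_along(chains)) {
      if (j <= i) next
      rows_a <- hyd[at$chain[hyd] == chains[i]]
      rows_b <- hyd[at$chain[hyd] == chains[j]]
      if (!is.null(pairs)) {
        keep_a <- at$resno[rows_a] %in%
          pairs$resno_a[pairs$chain_a == chains[i]]
        keep_b <- at$resno[rows_b] %in%
          pairs$resno_b[pairs$chain_b == chains[j]]
        rows_a <- rows_a[keep_a]; rows_b <- rows_b[keep_b]
      }
      if (length(rows_a) == 0 || length(rows_b) == 0) next
      nf <- n_frames(traj)
      mind <- vapply(seq_len(nf), function(k) {
        xa <- frame_xyz_of(traj, rows_a, k)
        xb <- frame_xyz_of(traj, rows_b, k)
        if (length(rows_a) == 1) xa <- matrix(xa, ncol = 3)
        if (length(rows_b) == 1) xb <- matrix(xb, ncol = 3)
        min(sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                   2 * xa %*% t(xb)))
      }, 1)
      fr <- vapply(cutoffs, function(ct) mean(mind < ct), 1)
      names(fr) <- format(cutoffs)
      key <- paste0(chains[i], "|", chains[j])
      out[[key]] <- list(
        series = time_series(paste0("min_OG_dist_", key), traj$times_ns,
                             mind, "A"),
        fractions = fr,
        atoms_a = at[rows_a, c("chain", "resno", "resid", "elety")],
        atoms_b = at[rows_b, c("chain", "resno", "resid", "elety")])
    }
  }
  structure(out, class = "contact_series_set")
}

#' JM-tail-to-membrane distance series
#'
#' Per frame, the Euclidean distance from the center of mass (heavy atoms)
#' of the last three residues of the juxtamembrane tail segment to the
#' nearest headgroup heavy atom of the chosen leaflet.
#'
#' @param traj a [trajectory()].
#' @param tail_segment [helix_segment()] covering the JM helix; its last 3
#'   residues define the tail.
#' @param slab a [make_membrane_slab()] (static leaflets).
#' @param leaflet `"lower"` (inner, default) or `"upper"`.
#' @return A [time_series()] in A.
#' @export
membrane_distance <- function(traj, tail_segment, slab,
                              leaflet = c("lower", "upper")) {
  leaflet <- match.arg(leaflet)
  stopifnot(inherits(traj, "trajectory"), inherits(slab, "membrane_slab"))
  at <- traj$atoms
  tail_res <- (tail_segment$last_residue - 2L):tail_segment$last_residue
  rows <- which(at$chain == tail_segment$chain_id &
                  at$resno %in% tail_res & !grepl("^[0-9]*H", at$elety))
  if (length(rows) == 0) {
    stop("input error: no heavy tail atoms found", call. = FALSE)
  }
  leaf <- if (leaflet == "lower") slab$lower else slab$upper
  if (nrow(leaf) == 0) stop("input error: empty leaflet", call. = FALSE)
  d <- vapply(seq_len(n_frames(traj)), function(k) {
    com <- colMeans(matrix(frame_xyz_of(traj, rows, k), ncol = 3))
    sqrt(min(rowSums(sweep(leaf, 2, com)^2)))
  }, 1)
  time_series(paste0("jm_tail_to_", leaflet, "_leaflet"), traj$times_ns,
              d, "A")
}
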