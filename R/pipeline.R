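# End-to-end orchestration: parse models -> pair geometry -> pairwise
# normalized-RMSD matrix -> threshold grouping -> optional trajectory
# metrics -> report bundle on disk.

default_config <- function() {
  list(
    central_region = c(11, 25),
    reference_residues = c(4, 11),
    group_threshold = 3.5,
    equilibration = list(window_ns = 250, rmsd_sd = 0.5,
                         crossing_range = 10, rotation_range = 25),
    kih_cutoff = 7.0,
    seed = 1L)
}

#' Run the full candidate-model analysis workflow
#'
#' For every input model: helix-pair geometry (crossing angle, rotation
#' angles at the reference residues, inter-axial distance, register,
#' tilt); then the pairwise normalized-RMSD matrix over all models and its
#' threshold grouping; optionally trajectory metrics (geometry time
#' series, equilibration report) for a supplied trajectory. Results are
#' written as TSV/JSON under `output_dir` together with a summary that
#' echoes every threshold and convention used. A model that fails a stage
#' is logged and skipped; remaining models are still processed and the
#' failure is recorded in the summary (`n_errors > 0`).
#'
#' @param config named list or path to a YAML file. Recognized fields:
#'   `models` (list of `path`/`label` entries, or a named list of
#'   [structure_model()] objects), `segments` (list of
#'   `chain`/`first`/`last`), `central_region`, `reference_residues`,
#'   `group_threshold`, `equilibration` (window_ns, rmsd_sd,
#'   crossing_range, rotation_range), `trajectory` (`path`, `dt_ns`),
#'   `output_dir`, `seed`.
#' @return invisibly, a list with `geometry` (data.frame),
#'   `rmsd_matrix`, `grouping`, `equilibration` (or NULL), `errors`
#'   (character vector) and `output_dir`.
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_config(), config)
  out_dir <- cfg$output_dir
  if (is.null(out_dir)) stop("config must name an output_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(cfg$seed))
  errors <- character(0)
  note <- function(label, e) {
    msg <- paste0(label, ": ", conditionMessage(e))
    errors <<- c(errors, msg)
    message("run_analysis error - ", msg)
    NULL
  }

  # ---- load models -------------------------------------------------------
  models <- list()
  if (!is.null(cfg$models) && length(cfg$models) > 0 &&
      inherits(cfg$models[[1]], "structure_model")) {
    models <- cfg$models
  } else {
    for (m in cfg$models) {
      label <- if (!is.null(m$label)) m$label else basename(m$path)
      got <- tryCatch(read_structure(m$path)[[1]],
                      error = function(e) note(label, e))
      if (!is.null(got)) models[[label]] <- got
    }
  }
  if (length(models) == 0) {
    stop("no readable models in config", call. = FALSE)
  }

  segments_of <- function(model) {
    if (is.null(cfg$segments)) return(default_segments(model))
    lapply(cfg$segments, function(s) {
      helix_segment(s$chain, s$first, s$last, s$label)
    })
  }

  # ---- per-model geometry ------------------------------------------------
  ref <- cfg$reference_residues
  geo_rows <- list()
  for (label in names(models)) {
    g <- tryCatch(
      dimer_geometry(models[[label]], segments_of(models[[label]])[1:2],
                     reference_residues = ref),
      error = function(e) note(label, e))
    if (is.null(g)) next
    row <- data.frame(label = label, crossing = g$crossing_angle,
                      stringsAsFactors = FALSE)
    for (h in c("A", "B")) {
      for (r in ref) {
        row[[paste0("rotation_", h, "_", r)]] <- g$rotation_angles[h,
                                                                   as.character(r)]
      }
    }
    row$inter_axial_distance <- g$inter_axial_distance
    row$register_shift <- g$register_shift
    row$tilt_A <- g$tilt_a; row$tilt_B <- g$tilt_b
    geo_rows[[label]] <- row
  }
  geometry <- do.call(rbind, geo_rows)
  rownames(geometry) <- NULL
  utils::write.table(geometry, file.path(out_dir, "geometry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- pairwise matrix + grouping ---------------------------------------
  mat <- grouping <- NULL
  if (length(models) >= 2) {
    mat <- tryCatch(pairwise_matrix(models, region = cfg$central_region),
                    error = function(e) note("pairwise_matrix", e))
    if (!is.null(mat)) {
      utils::write.table(round(mat$values, 4),
                         file.path(out_dir, "rmsd_matrix.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      grouping <- group_structures(mat, threshold = cfg$group_threshold)
      jsonlite::write_json(
        list(threshold = cfg$group_threshold, groups = grouping$groups,
             representatives = as.list(grouping$representatives)),
        file.path(out_dir, "grouping.json"), auto_unbox = TRUE,
        pretty = TRUE)
    }
  }

  # ---- optional trajectory metrics --------------------------------------
  equil <- NULL
  if (!is.null(cfg$trajectory)) {
    equil <- tryCatch({
      traj <- if (inherits(cfg$trajectory, "trajectory")) cfg$trajectory
        else read_trajectory(cfg$trajectory$path,
                             dt_ns = if (!is.null(cfg$trajectory$dt_ns))
                               cfg$trajectory$dt_ns else 1)
      segs <- segments_of(frame_model(traj, 1))[1:2]
      ts <- geometry_timeseries(traj, segs, reference_residues = ref)
      eq <- equilibration_report(
        ts, window_ns = cfg$equilibration$window_ns,
        thresholds = list(rmsd_sd = cfg$equilibration$rmsd_sd,
                          crossing_range = cfg$equilibration$crossing_range,
                          rotation_range = cfg$equilibration$rotation_range))
      tst <- data.frame(time_ns = ts[[1]]$times_ns)
      for (nm in names(ts)) tst[[nm]] <- ts[[nm]]$values
      utils::write.table(tst, file.path(out_dir, "timeseries.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(window_ns = eq$window_ns, pass = eq$pass, table = eq$table),
        file.path(out_dir, "equilibration.json"), auto_unbox = TRUE,
        pretty = TRUE, digits = 6)
      eq
    }, error = function(e) note("trajectory", e))
  }

  # ---- summary with provenance ------------------------------------------
  summary <- list(
    n_models = length(models),
    n_errors = length(errors),
    errors = errors,
    settings = list(
      central_region = cfg$central_region,
      reference_residues = cfg$reference_residues,
      group_threshold = cfg$group_threshold,
      equilibration = cfg$equilibration,
      kih_cutoff = cfg$kih_cutoff,
      seed = cfg$seed),
    conventions = list(
      crossing_sign = "negative = right-handed crossing",
      rotation_sense = "positive = clockwise viewed from the N-terminal side",
      renumbering = "segment residues renumbered to start at 1",
      register = "axial offset from closest-approach feet; 5.4 A per turn"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(geometry = geometry, rmsd_matrix = mat,
                 grouping = grouping, equilibration = equil,
                 errors = errors, output_dir = out_dir))
}
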