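#' Run the full measurement pipeline
#'
#' Executes the stages phantom (optional) -> split -> measure -> tensile
#' -> summarise from a single structured YAML configuration, writing every
#' stage output plus a run manifest under `out_dir`. Reruns with the same
#' configuration and seed produce identical result files (the manifest
#' timestamp aside). No stage mutates its inputs.
#'
#' The configuration holds the blocks:
#' \describe{
#'   \item{`seed`}{top-level integer seed; per-stage seeds are derived
#'     deterministically from it.}
#'   \item{`pipeline`}{fields of [pipeline_config()].}
#'   \item{`phantom`}{optional: `truth` (arguments to [phantom_truth()],
#'     empty for the defaults), `mesh_resolution`, `pose`.}
#'   \item{`inputs`}{alternative to `phantom`: paths `radius`, `ulna`,
#'     `membrane` (STL), `landmarks` (JSON), plus `distal_hints` with 3D
#'     points `radius`/`ulna`, and optionally `clip_half_width` (mm).}
#'   \item{`tensile`}{optional: `curves` (list of CSV paths) and/or
#'     `synthetic` (list of [tensile_truth()] argument sets).}
#' }
#'
#' @param config path to a YAML file or an equivalent named list.
#' @param out_dir output directory; created if absent.
#' @param seed optional override of the configured seed.
#' @return invisibly, a list with `status` (0 on success), the stage
#'   `results`, and the written `paths`. Errors abort with the failing
#'   stage named; outputs of completed stages are preserved.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg_snapshot <- if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    yaml::read_yaml(config)
  } else config
  seed <- as.integer(seed %||% cfg_snapshot$seed %||% 1L)
  pl <- do.call(pipeline_config, cfg_snapshot$pipeline %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  input_files <- character(0)
  stage <- "setup"
  on_fail <- function(e) stopf("pipeline stage '%s' failed: %s", stage,
                               conditionMessage(e))

  tryCatch({
    ## ---- stage: phantom or input loading -------------------------------
    clip_half_width <- cfg_snapshot$inputs$clip_half_width %||% NULL
    if (!is.null(cfg_snapshot$phantom)) {
      stage <- "phantom"
      message("[phantom] generating synthetic forearm")
      pb <- cfg_snapshot$phantom
      truth <- do.call(phantom_truth, normalise_truth_args(pb$truth %||% list()))
      ph <- make_phantom(truth,
                         mesh_resolution = pb$mesh_resolution %||% 1,
                         pose = pb$pose %||% "canonical",
                         seed = seed + 1L)
      pdir <- file.path(out_dir, "phantom")
      dir.create(pdir, showWarnings = FALSE)
      paths <- c(paths,
                 write_mesh(ph$radius, file.path(pdir, "radius.stl")),
                 write_mesh(ph$ulna, file.path(pdir, "ulna.stl")),
                 write_mesh(ph$membrane, file.path(pdir, "membrane.stl")),
                 write_landmarks(ph$landmarks, file.path(pdir, "landmarks.json")))
      truth_path <- file.path(pdir, "truth.json")
      jsonlite::write_json(truth_echo_json(truth), truth_path,
                           auto_unbox = TRUE, digits = NA)
      paths <- c(paths, truth_path)
      radius <- ph$radius; ulna <- ph$ulna; membrane <- ph$membrane
      landmarks <- ph$landmarks
      distal_hints <- list(radius = ph$axes$radius$distal_point,
                           ulna = ph$axes$ulna$distal_point)
      doac <- truth$ligaments$DOAC
      if (!is.null(doac)) clip_half_width <- doac$clip_half_width
    } else if (!is.null(cfg_snapshot$inputs)) {
      stage <- "inputs"
      ins <- cfg_snapshot$inputs
      for (field in c("radius", "ulna", "membrane", "landmarks")) {
        if (is.null(ins[[field]]))
          stopf("config field 'inputs.%s' is missing", field)
        if (!file.exists(ins[[field]]))
          stopf("file for 'inputs.%s' not found: %s", field, ins[[field]])
      }
      input_files <- unlist(ins[c("radius", "ulna", "membrane", "landmarks")])
      radius <- read_mesh(ins$radius, "radius")
      ulna <- read_mesh(ins$ulna, "ulna")
      membrane <- read_mesh(ins$membrane, "membrane")
      landmarks <- read_landmarks(ins$landmarks)
      if (is.null(ins$distal_hints))
        stopf("config field 'inputs.distal_hints' is required to orient the bone axes")
      distal_hints <- lapply(ins$distal_hints, unlist)
    } else stopf("config needs either a 'phantom' or an 'inputs' block")

    ## ---- stage: split + measure ---------------------------------------
    stage <- "measure"
    message("[measure] bone axes, separation, morphometry (slab ",
            pl$slab_width, " mm, step ", pl$station_step, " mm, width mode ",
            pl$attachment_width_mode, ")")
    recs <- measure_iom(radius, ulna, membrane, landmarks, distal_hints,
                        pl, clip_half_width = clip_half_width)
    sdir <- file.path(out_dir, "split")
    mdir <- file.path(out_dir, "morphometry")
    dir.create(sdir, showWarnings = FALSE)
    dir.create(mdir, showWarnings = FALSE)
    morpho_df <- do.call(rbind, lapply(recs, as.data.frame))
    rownames(morpho_df) <- NULL
    for (r in recs) {
      paths <- c(paths,
                 write_mesh(r$mesh, file.path(sdir, paste0(r$ligament_id, ".stl"))))
      for (pr in r$profiles) {
        pf <- file.path(mdir, sprintf("profile_%s_%s.csv", r$ligament_id,
                                      pr$position))
        utils::write.csv(data.frame(station = pr$stations,
                                    thickness = pr$thickness),
                         pf, row.names = FALSE)
        paths <- c(paths, pf)
      }
    }
    mj <- file.path(mdir, "morphometry.json")
    jsonlite::write_json(morpho_df, mj, auto_unbox = TRUE, digits = NA,
                         na = "null")
    paths <- c(paths, mj)

    ## ---- stage: tensile -------------------------------------------------
    tens_df <- NULL
    if (!is.null(cfg_snapshot$tensile)) {
      stage <- "tensile"
      message("[tensile] curve analysis (preload ", pl$preload,
              " N, stop fraction ", pl$failure_stop_fraction,
              ", first-peak drop ", pl$first_peak_drop, ")")
      tdir <- file.path(out_dir, "tensile")
      dir.create(tdir, showWarnings = FALSE)
      curves <- list()
      for (p in cfg_snapshot$tensile$curves %||% list()) {
        if (!file.exists(p)) stopf("tensile curve file not found: %s", p)
        input_files <- c(input_files, p)
        curves[[length(curves) + 1L]] <- read_curve(p)
      }
      syn <- cfg_snapshot$tensile$synthetic %||% list()
      for (i in seq_along(syn)) {
        args <- syn[[i]]
        args$seed <- args$seed %||% (seed + 100L + i)
        tr <- do.call(tensile_truth, args)
        cu <- make_tensile_curve(tr)
        cp <- file.path(tdir, sprintf("curve_%02d.csv", i))
        paths <- c(paths, write_curve(cu, cp))
        curves[[length(curves) + 1L]] <- cu
      }
      if (length(curves)) {
        tens_df <- do.call(rbind, lapply(curves, analyse_tensile_curve,
                                         cfg = pl))
        tj <- file.path(tdir, "tensile_results.json")
        jsonlite::write_json(tens_df, tj, auto_unbox = TRUE, digits = NA,
                             na = "null")
        utils::write.csv(tens_df, file.path(tdir, "tensile_results.csv"),
                         row.names = FALSE)
        paths <- c(paths, tj, file.path(tdir, "tensile_results.csv"))
      }
    }

    ## ---- stage: summarise -----------------------------------------------
    stage <- "summarise"
    message("[summarise] Mean/SD/Range tables (population SD)")
    udir <- file.path(out_dir, "summary")
    dir.create(udir, showWarnings = FALSE)
    msum <- make_table(morpho_df,
                       values = c("radial_pct", "ulnar_pct", "fan_out_deg",
                                  "width_radial", "width_ulnar",
                                  "thickness_mean"))
    utils::write.csv(msum, file.path(udir, "morphometry_summary.csv"),
                     row.names = FALSE)
    paths <- c(paths, file.path(udir, "morphometry_summary.csv"))
    tsum <- NULL
    if (!is.null(tens_df)) {
      tsum <- make_table(tens_df,
                         values = c("csa", "first_peak_force",
                                    "ultimate_force", "stiffness",
                                    "ultimate_strain"))
      utils::write.csv(tsum, file.path(udir, "tensile_summary.csv"),
                       row.names = FALSE)
      paths <- c(paths, file.path(udir, "tensile_summary.csv"))
    }

    ## ---- manifest --------------------------------------------------------
    stage <- "manifest"
    manifest <- list(
      tool = "iomorph",
      version = as.character(utils::packageVersion("iomorph")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      config = cfg_snapshot,
      parameters = unclass(pl),
      input_digests = as.list(tools::md5sum(input_files)))
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         null = "null")
    paths <- c(paths, mpath)

    invisible(list(status = 0L,
                   results = list(morphometry = morpho_df,
                                  morphometry_summary = msum,
                                  tensile = tens_df,
                                  tensile_summary = tsum),
                   paths = paths))
  }, error = on_fail)
}

## YAML deserialises vectors as lists; coerce the truth block back to the
## shapes phantom_truth() expects.
normalise_truth_args <- function(tr) {
  num <- function(x) if (is.list(x)) unlist(x) else x
  for (f in c("bone_lengths", "bone_radii"))
    if (!is.null(tr[[f]])) tr[[f]] <- num(tr[[f]])
  if (!is.null(tr$ligaments))
    tr$ligaments <- lapply(tr$ligaments, function(sp) {
      for (f in c("radial_span", "ulnar_span", "thickness", "fan_out"))
        if (!is.null(sp[[f]])) sp[[f]] <- num(sp[[f]])
      sp
    })
  tr
}

## JSON-friendly echo of a phantom_truth (landmark objects flattened).
truth_echo_json <- function(truth) {
  t2 <- unclass(truth)
  t2$ligaments <- lapply(t2$ligaments, function(l) {
    l$landmarks <- lapply(l$landmarks$points, as.numeric)
    l
  })
  t2
}
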