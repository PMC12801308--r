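#' Default pipeline configuration
#'
#' Fully-defaulted configuration for the end-to-end chain: synthetic
#' two-helix trajectory -> descriptors/clustering -> CV extraction ->
#' WT-MetaD on a two-well model potential -> FES -> basins -> MFEP ->
#' kinetics.  WT-MetaD parameters default to the production values (width
#' 0.2 nm, hill 1.2 kJ/mol, stride 1 ps, bias factor 8); run lengths are
#' desk-scale.
#'
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "fespath_run",
    stages = list(generate = TRUE, cluster = TRUE, cvs = TRUE, metad = TRUE,
                  fes = TRUE, paths = TRUE, report = TRUE),
    toy = list(
      angles = c(150, 130, 110, 90, 70, 50, 30),
      frames_per_angle = 30L,
      noise_sd = 0.03,
      frame_dt = 1,
      potential = list(
        centers = list(c(0.6, 1.0), c(2.0, 1.0)),
        depths = c(18.7, 18.7),
        widths = c(0.3, 0.3),
        conf_k = 5,
        conf_center = c(1.3, 1.0))),
    clustering = list(n_components = 2L, k = 7L),
    metad = list(height = 1.2, sigma = 0.2, stride = 1, biasfactor = 8,
                 temperature = 310.15, friction = 1.0, timestep = 5e-4,
                 n_steps = 6e5),
    grid = list(npoints = 128L, pad = NULL),
    # basin threshold defaults to kB*T at 310.15 K: dips shallower than
    # thermal energy are not metastable states, and a single stray hill in a
    # rarely-visited region already carves W0*gamma/(gamma-1) ~ 1.4 kJ/mol
    minima = list(min_depth = 2.58),
    neb = list(n_images = 32L, spring_k = 100, step = 1e-4, tol = 0.5,
               max_iter = 5000L),
    kinetics = list(temperature = 300, transmission = 1))
}

# recursive unknown-key / constraint checking; returns character vector of
# violations (empty when valid)
.config_violations <- function(cfg, ref = default_config(), path = "") {
  errs <- character(0)
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    errs <- c(errs, sprintf("unknown key: %s%s", path, unknown))
  for (nm in intersect(names(cfg), names(ref))) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
        nm != "potential") {
      if (!is.list(cfg[[nm]])) {
        errs <- c(errs, sprintf("%s%s must be a mapping", path, nm))
      } else {
        errs <- c(errs, .config_violations(cfg[[nm]], ref[[nm]],
                                           sprintf("%s%s.", path, nm)))
      }
    }
  }
  errs
}

.config_constraints <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$metad$biasfactor > 1, "metad.biasfactor must exceed 1")
  chk(all(cfg$metad$sigma > 0), "metad.sigma (nm) must be positive")
  chk(cfg$metad$height > 0, "metad.height (kJ/mol) must be positive")
  chk(cfg$metad$stride > 0, "metad.stride (ps) must be positive")
  chk(cfg$metad$temperature > 0, "metad.temperature (K) must be positive")
  chk(cfg$metad$friction > 0, "metad.friction (1/ps) must be positive")
  chk(cfg$metad$timestep > 0, "metad.timestep (ps) must be positive")
  chk(cfg$toy$noise_sd >= 0, "toy.noise_sd (nm) must be >= 0")
  chk(all(cfg$toy$angles >= 0 & cfg$toy$angles <= 180),
      "toy.angles must lie in [0, 180] degrees")
  chk(all(unlist(cfg$toy$potential$widths) > 0),
      "toy.potential.widths (nm) must be positive")
  chk(all(unlist(cfg$toy$potential$depths) > 0),
      "toy.potential.depths (kJ/mol) must be positive")
  chk(cfg$kinetics$temperature > 0, "kinetics.temperature (K) must be positive")
  chk(cfg$clustering$k >= 1, "clustering.k must be >= 1")
  chk(cfg$neb$n_images >= 3, "neb.n_images must be >= 3")
  errs
}

# fill defaults recursively (user values win)
.config_merge <- function(cfg, ref) {
  for (nm in names(ref)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- ref[[nm]]
    } else if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
               is.list(cfg[[nm]]) && nm != "potential") {
      cfg[[nm]] <- .config_merge(cfg[[nm]], ref[[nm]])
    }
  }
  cfg[names(ref)]
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a JSON mapping (or takes a list), rejects unknown keys, fills
#' defaults, and checks unit constraints; all violations are reported
#' together.  An empty file or list yields the full default configuration.
#'
#' @param config path to a JSON file, or a (possibly partial) config list.
#' @return a normalized `pipeline_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (nzchar(trimws(txt)))
      jsonlite::fromJSON(txt, simplifyDataFrame = FALSE) else list()
  }
  stopifnot(is.list(config))
  errs <- .config_violations(config)
  if (!length(errs)) {
    config <- .config_merge(config, default_config())
    errs <- .config_constraints(config)
  }
  if (length(errs))
    stop(paste(c("invalid configuration:", paste(" -", errs)),
               collapse = "\n"))
  structure(config, class = c("pipeline_config", "list"))
}

.toy_potential <- function(p) {
  centers <- p$centers
  if (is.list(centers)) centers <- do.call(rbind, centers)
  make_gaussian_wells(centers, depths = unlist(p$depths),
                      widths = unlist(p$widths), conf_k = p$conf_k %||% 0,
                      conf_center = if (!is.null(p$conf_center))
                        unlist(p$conf_center))
}

.stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%OS2"), stage,
                    sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing every intermediate
#' artifact under `outdir` and a manifest (JSON) recording package version,
#' seeds, parameters and per-stage outputs.  With identical configuration
#' and seeds the artifacts are byte-identical across reruns.  A stage
#' failure aborts with the stage name; artifacts of completed stages are
#' preserved.
#'
#' @param config a [validate_config()] result, config list, or JSON path.
#' @param outdir overrides `config$outdir`.
#' @param verbose log stage progress.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), outdir = NULL, verbose = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  outdir <- outdir %||% cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "fespath",
                   version = as.character(packageVersion("fespath")),
                   seed = cfg$seed, config = unclass(cfg),
                   stages = list())
  artifacts <- function(...) file.path(outdir, c(...))
  run_stage <- function(name, enabled, fun) {
    if (!isTRUE(enabled)) return(invisible(NULL))
    .stage_log(verbose, name, "start")
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- out
    .stage_log(verbose, name, "done: %s", paste(out$outputs, collapse = ", "))
    out
  }
  env <- new.env()

  run_stage("generate", cfg$stages$generate, function() {
    schedule <- rep(unlist(cfg$toy$angles), each = cfg$toy$frames_per_angle)
    env$traj <- generate_helix_pair_trajectory(
      schedule, noise_sd = cfg$toy$noise_sd, seed = cfg$seed,
      frame_dt = cfg$toy$frame_dt)
    env$regimes <- rep(seq_along(unlist(cfg$toy$angles)),
                       each = cfg$toy$frames_per_angle)
    f <- artifacts("trajectory.pdb")
    write_pdb(env$traj, f)
    list(outputs = basename(f), frames = n_frames(env$traj),
         seed = cfg$seed)
  })

  # stages communicate via files: later stages reload what an earlier run
  # wrote when rerun in isolation
  need_traj <- function() {
    if (is.null(env$traj)) env$traj <- read_pdb(artifacts("trajectory.pdb"),
                                                frame_dt = cfg$toy$frame_dt)
    env$traj
  }
  need_hills <- function() {
    if (is.null(env$hills)) env$hills <- read_hills(artifacts("HILLS"))
    env$hills
  }

  run_stage("cluster", cfg$stages$cluster, function() {
    D <- build_descriptors(need_traj())
    env$model <- cluster_conformations(D, cfg$clustering$n_components,
                                       cfg$clustering$k, seed = cfg$seed)
    f <- artifacts("clusters.json")
    write_cluster_summary(env$model, f)
    tl <- transition_timeline(env$model, env$traj$times)
    f2 <- artifacts("timeline.csv")
    write_series_csv(tl, f2)
    list(outputs = c(basename(f), "clusters_labels.csv", basename(f2)),
         explained_variance_ratio = env$model$explained_variance_ratio,
         density = env$model$density)
  })

  run_stage("cvs", cfg$stages$cvs, function() {
    need_traj()
    cv <- compute_cvs(env$traj)
    cv$interhelical_angle <- interhelical_angle(env$traj)
    f <- artifacts("cv_series.csv")
    write_series_csv(cv, f)
    rp <- rmsd_profile(env$traj)
    f2 <- artifacts("rmsd.csv")
    write_series_csv(rp, f2)
    list(outputs = c(basename(f), basename(f2)))
  })

  run_stage("metad", cfg$stages$metad, function() {
    env$pot <- .toy_potential(cfg$toy$potential)
    mp <- cfg$metad
    run <- run_wtmetad(
      env$pot,
      params = wtmetad_params(mp$height, mp$sigma, mp$stride, mp$biasfactor,
                              mp$temperature, seed = cfg$seed),
      langevin = langevin_params(mp$friction, mp$temperature, mp$timestep,
                                 mp$n_steps, seed = cfg$seed))
    env$hills <- run$hills
    f <- artifacts("HILLS")
    write_hills(run$hills, f)
    f2 <- artifacts("metad_cv.csv")
    write_series_csv(run$cv, f2)
    list(outputs = c(basename(f), basename(f2)), n_hills = nrow(run$hills),
         params = mp, seed = cfg$seed)
  })

  run_stage("fes", cfg$stages$fes, function() {
    env$fes <- bias_sum_fes(need_hills(), npoints = cfg$grid$npoints,
                            pad = cfg$grid$pad,
                            temperature = cfg$metad$temperature)
    f <- artifacts("fes.dat")
    write_fes(env$fes, f)
    env$minima <- find_minima(env$fes, min_depth = cfg$minima$min_depth)
    f2 <- artifacts("basins.csv")
    utils::write.csv(as.data.frame(env$minima)[, c("label", env$fes$cv_names,
                                                   "free_energy")],
                     f2, row.names = FALSE, quote = FALSE)
    list(outputs = c(basename(f), paste0(basename(f), ".json"), basename(f2)),
         n_basins = nrow(env$minima))
  })

  run_stage("paths", cfg$stages$paths, function() {
    if (is.null(env$fes)) {
      env$fes <- bias_sum_fes(need_hills(), npoints = cfg$grid$npoints,
                              pad = cfg$grid$pad,
                              temperature = cfg$metad$temperature)
      env$minima <- find_minima(env$fes, min_depth = cfg$minima$min_depth)
    }
    tt <- transition_table(env$fes, env$minima,
                           temperature = cfg$kinetics$temperature,
                           transmission = cfg$kinetics$transmission,
                           n_images = cfg$neb$n_images,
                           spring_k = cfg$neb$spring_k, step = cfg$neb$step,
                           tol = cfg$neb$tol, max_iter = cfg$neb$max_iter)
    env$transitions <- tt
    f <- artifacts("transitions.csv")
    write_transition_table(tt, f)
    list(outputs = basename(f), n_transitions = nrow(tt))
  })

  run_stage("report", cfg$stages$report, function() {
    f <- artifacts("manifest.json")
    list(outputs = basename(f))
  })

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
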