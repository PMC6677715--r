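default_config <- function() {
  list(
    mode = "wellmixed",
    pathway = list(beta_n = 100, beta_d = 500, beta_r = 3e5,
                   k_t = 2, k_c = 0.5, k_rs = 1e7, m = 2, s = 2,
                   omega = 400, w_a = 1, w_b = 1, q_a = 1, q_b = 1,
                   chunk_safety = 0.05, dtau_min = 1e-6, dtau_max = 0.5,
                   collier_const = 1),
    protrusion = list(length = 3.5, directions = NULL, width = 2 * pi),
    lattice = list(nx = 10, ny = 10, periodic = FALSE, type = "hex"),
    growth = list(kappa = 0.02, mu = 1, c_thr = 0.5, c_b = 1,
                  d_move = 1, target_size = 1000, keep_connected = TRUE),
    mesh = list(n_voxels = 40),
    seed = 1,
    t_end = 200,
    times = c(4, 20, 40, 200),
    events = NULL
  )
}

merge_section <- function(base, user, section) {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("load_config: unknown key(s) in '", section, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  base[names(user)] <- user
  base
}

#' Load and validate an experiment configuration
#'
#' Reads a structured experiment description from a YAML file or an inline
#' list, fills in the documented defaults (the static-pattern baseline:
#' system volume 400, production strengths [100, 500, 3e5], saturation
#' constants [2, 0.5, 1e7], unit weights, isotropic protrusions of length
#' 3.5 cell radii), validates every field through the corresponding
#' parameter constructors, and rejects unknown keys by name.
#'
#' @param x a file path to a YAML config, a list, or \code{NULL} for pure
#'   defaults.
#' @return An object of class \code{"experiment_config"}.
#' @examples
#' cfg <- load_config(list(pathway = list(omega = 800)))
#' cfg$pathway$omega
#' @export
load_config <- function(x = NULL) {
  user <- if (is.null(x)) list()
          else if (is.character(x)) yaml::read_yaml(x)
          else if (is.list(x)) x
          else stop("load_config: expected a path or a list", call. = FALSE)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- base
  for (sec in c("pathway", "protrusion", "lattice", "growth", "mesh"))
    cfg[[sec]] <- merge_section(base[[sec]], user[[sec]], sec)
  for (key in c("mode", "seed", "t_end", "times", "events"))
    if (!is.null(user[[key]])) cfg[[key]] <- user[[key]]
  if (!cfg$mode %in% c("wellmixed", "growth", "coupled"))
    stop("load_config: mode must be wellmixed, growth or coupled",
         call. = FALSE)
  if (!cfg$lattice$type %in% c("hex", "square"))
    stop("load_config: lattice type must be hex or square", call. = FALSE)
  # constructors perform the range validation and name offending fields
  cfg$params <- do.call(pathway_params, cfg$pathway)
  cfg$spec <- protrusion_spec(cfg$protrusion$length,
                              cfg$protrusion$directions,
                              cfg$protrusion$width)
  cfg$gparams <- do.call(growth_params, cfg$growth)
  if (cfg$mesh$n_voxels < 1)
    stop("load_config: mesh n_voxels must be >= 1", call. = FALSE)
  structure(cfg, class = "experiment_config")
}

#' Shipped experiment presets
#'
#' Named configurations for the package's standard experiments:
#' \describe{
#'   \item{\code{"static-pattern"}}{stochastic lateral inhibition on a
#'     static 10 x 10 hexagonal grid, isotropic protrusions of length 3.5,
#'     unit weights, snapshots at t = 4, 20, 40, 200.}
#'   \item{\code{"growth"}}{nutrient-limited growth from one founder cell
#'     to 1000 cells.}
#'   \item{\code{"coupled-baseline"}}{the full two-layer model: static
#'     pathway parameters over a replayed growth log.}
#'   \item{\code{"spots"}}{differential signal weighting
#'     [w_a, q_a, w_b, q_b] = [1, 0.001, 0.06, 0.06], producing sparse
#'     spot patterns.}
#'   \item{\code{"polarized"}}{horizontally polarized protrusions
#'     (directions 0 and pi, width pi/20, length 5) with weights
#'     [1, 0.001, 0.2, 0.15], producing stripe-like patterns.}
#' }
#'
#' @param name preset name.
#' @return An \code{"experiment_config"}.
#' @examples
#' config_preset("spots")$pathway$q_a
#' @export
config_preset <- function(name = c("static-pattern", "growth",
                                   "coupled-baseline", "spots",
                                   "polarized")) {
  name <- match.arg(name)
  overrides <- switch(name,
    "static-pattern" = list(mode = "wellmixed"),
    "growth" = list(mode = "growth"),
    "coupled-baseline" = list(mode = "coupled"),
    "spots" = list(mode = "coupled",
                   pathway = list(w_a = 1, q_a = 0.001, w_b = 0.06,
                                  q_b = 0.06)),
    "polarized" = list(mode = "coupled",
                       pathway = list(w_a = 1, q_a = 0.001, w_b = 0.2,
                                      q_b = 0.15),
                       protrusion = list(length = 5,
                                         directions = c(0, pi),
                                         width = pi / 20)))
  load_config(overrides)
}

center_voxel <- function(lattice) {
  mid <- colMeans(lattice$coords)
  which.min((lattice$coords[, 1] - mid[1])^2 +
              (lattice$coords[, 2] - mid[2])^2)
}

build_config_lattice <- function(cfg) {
  if (cfg$lattice$type == "hex")
    build_hex_lattice(cfg$lattice$nx, cfg$lattice$ny, cfg$lattice$periodic)
  else
    build_square_lattice(cfg$lattice$nx, cfg$lattice$ny,
                         cfg$lattice$periodic)
}

#' Run a configured experiment
#'
#' Executes one experiment end to end and writes its artifacts (trajectory
#' CSV, snapshot CSVs, event log, a YAML echo of the configuration, and a
#' plain-text run log including the seed) into \code{out_dir}, so that the
#' run directory suffices to reproduce the run exactly.
#'
#' @param cfg an \code{"experiment_config"} (see \code{\link{load_config}}).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the main result object (trajectory data frame or
#'   event log).
#' @export
run_experiment <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  echo <- unclass(cfg)
  echo$params <- echo$spec <- echo$gparams <- NULL
  yaml::write_yaml(echo, file.path(out_dir, "config.yaml"))
  logfile <- file.path(out_dir, "run.log")
  logline <- function(...)
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...), "\n",
        sep = "", file = logfile, append = TRUE)
  logline("mode=%s seed=%d", cfg$mode, as.integer(cfg$seed))
  set.seed(cfg$seed)
  lat <- build_config_lattice(cfg)
  result <- switch(cfg$mode,
    wellmixed = {
      graph <- contact_graph(lat, cfg$spec, cfg$params)
      init <- random_initial_counts(nrow(lat$coords), cfg$params)
      traj <- ssa_population(init, graph, cfg$params, t_end = cfg$t_end,
                             times = cfg$times)
      write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
      for (tt in unique(traj$time)) {
        snap <- traj[traj$time == tt, ]
        snap$x <- lat$coords[snap$cell, 1]
        snap$y <- lat$coords[snap$cell, 2]
        utils::write.csv(snap, file.path(out_dir,
                                         sprintf("snapshot_t%g.csv", tt)),
                         row.names = FALSE)
      }
      logline("wellmixed: %d cells, %d output times", nrow(lat$coords),
              length(unique(traj$time)))
      traj
    },
    growth = {
      grid <- population_grid(lat, occupied = center_voxel(lat))
      log <- simulate_population(grid, cfg$gparams, t_end = cfg$t_end)
      write_event_log(log, file.path(out_dir, "events.jsonl"))
      final <- attr(log, "final_grid")
      utils::write.csv(grid_snapshot(final),
                       file.path(out_dir, "final_grid.csv"),
                       row.names = FALSE)
      logline("growth: %d events, final population %d", nrow(log),
              sum(final$u))
      log
    },
    coupled = {
      if (is.null(cfg$events))
        stop("coupled mode needs an 'events' log path in the config",
             call. = FALSE)
      events <- read_event_log(cfg$events)
      grid <- population_grid(lat, occupied = center_voxel(lat))
      mesh <- cell_mesh_fixture(cfg$mesh$n_voxels, cfg$params$omega)
      tissue <- tissue_state(grid, mesh, cfg$params, cfg$spec)
      traj <- run_coupled(tissue, events, t_end = cfg$t_end,
                          times = cfg$times)
      write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
      final <- attr(traj, "tissue")
      utils::write.csv(grid_snapshot(final$grid),
                       file.path(out_dir, "final_grid.csv"),
                       row.names = FALSE)
      logline("coupled: replayed %d events, %d cells at t_end",
              nrow(events), length(final$cell_ids))
      traj
    })
  invisible(result)
}

cli_usage <- function() {
  paste(
    "usage: tissuessa <wellmixed|growth|coupled> [--config FILE]",
    "                [--seed INT] [--out DIR] [--t-end NUM]",
    "                [--snapshots t1,t2,...] [--events FILE]",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (!key %in% c("config", "seed", "out", "t-end", "snapshots", "events"))
      stop("unknown flag: --", key, call. = FALSE)
    if (i + 1L > length(args)) stop("missing value for --", key,
                                    call. = FALSE)
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Thin shell interface over \code{\link{run_experiment}}: the subcommands
#' \code{wellmixed}, \code{growth} and \code{coupled} run the
#' corresponding experiment mode, overriding the config with the given
#' seed, horizon and snapshot times, and write all artifacts into the
#' output directory. Installed alongside the package as the executable
#' \code{exec/tissuessa}.
#'
#' @param argv character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Integer exit status, invisibly: 0 on success, non-zero on usage
#'   errors.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  fail <- function(msg) {
    message(msg)
    message(cli_usage())
    invisible(2L)
  }
  if (!length(argv)) return(fail("no subcommand given"))
  mode <- argv[1]
  if (!mode %in% c("wellmixed", "growth", "coupled"))
    return(fail(paste0("unknown subcommand: ", mode)))
  flags <- tryCatch(parse_flags(argv[-1]), error = function(e) e)
  if (inherits(flags, "error")) return(fail(conditionMessage(flags)))
  user <- if (!is.null(flags$config)) yaml::read_yaml(flags$config)
          else list()
  user$mode <- mode
  if (!is.null(flags$seed)) user$seed <- as.integer(flags$seed)
  if (!is.null(flags[["t-end"]])) user$t_end <- as.numeric(flags[["t-end"]])
  if (!is.null(flags$snapshots))
    user$times <- as.numeric(strsplit(flags$snapshots, ",")[[1]])
  if (!is.null(flags$events)) user$events <- flags$events
  if (mode == "coupled" && is.null(user$events))
    return(fail("coupled mode requires --events (a recorded event log)"))
  if (mode == "coupled" && is.null(user$t_end) && is.null(flags[["t-end"]]) &&
      is.null(flags$config))
    return(fail("coupled mode requires --t-end"))
  cfg <- tryCatch(load_config(user), error = function(e) e)
  if (inherits(cfg, "error")) return(fail(conditionMessage(cfg)))
  out_dir <- if (!is.null(flags$out)) flags$out else "."
  run_experiment(cfg, out_dir)
  invisible(0L)
}
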