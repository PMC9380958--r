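#' Validate and normalise an experiment configuration
#'
#' Experiments are described by a YAML mapping (or an equivalent named
#' list). Physical quantities carry explicit units in their key names
#' (`v_swim_um_per_s`, `B_s`, `dt_s`, ...) to prevent unit bugs. Missing
#' optional fields are filled with the standard defaults (`dt_s = 0.01`,
#' `f = 0.01`, the standard depth regions, output every 0.1 s). All
#' violations are collected and reported together with their field paths.
#'
#' The motility grid must contain exactly one non-motile entry (the Q
#' baseline) and at least one motile entry.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A normalised `gp_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML mapping (named list)")
  errs <- character()
  need <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  gv <- function(x, path, default = NULL) {
    v <- x
    for (k in strsplit(path, ".", fixed = TRUE)[[1]]) v <- v[[k]]
    if (is.null(v)) default else v
  }

  dom_l <- gv(config, "domain", list())
  domain <- flow_domain(Lx = gv(dom_l, "Lx_m", 0.6), Ly = gv(dom_l, "Ly_m", 0.6),
                        Lz = gv(dom_l, "Lz_m", 0.3))

  flow <- gv(config, "flow", list())
  flow_type <- gv(flow, "type", "kinematic")
  need(flow_type %in% c("kinematic", "taylor_green", "uniform", "gridded"),
       "flow.type: must be one of kinematic, taylor_green, uniform, gridded")
  if (flow_type == "gridded")
    need(is.character(gv(flow, "path", "")) && nzchar(gv(flow, "path", "")),
         "flow.path: required for gridded flow")

  sim <- gv(config, "simulation", list())
  n_microbes <- gv(sim, "n_microbes", 1000L)
  dt <- gv(sim, "dt_s", 0.01)
  total_time <- gv(sim, "total_time_s", 60)
  output_interval <- gv(sim, "output_interval_s", 0.1)
  seed_z <- unlist(gv(sim, "seed_z_range_m", c(0.15, 0.3)))
  need(n_microbes >= 1, "simulation.n_microbes: must be >= 1")
  need(dt > 0, "simulation.dt_s: must be > 0")
  need(total_time > 0, "simulation.total_time_s: must be > 0")
  need(length(seed_z) == 2 && seed_z[2] > seed_z[1],
       "simulation.seed_z_range_m: must be an increasing pair")

  mots <- gv(config, "motility", list())
  need(length(mots) >= 1, "motility: at least one entry required")
  parsed_mot <- list()
  n_nonmotile <- 0L
  for (i in seq_along(mots)) {
    m <- mots[[i]]
    mode <- gv(m, "mode", NA_character_)
    pre <- sprintf("motility[%d]", i)
    if (!mode %in% c("gyrotactic", "non_gyrotactic_motile", "non_motile")) {
      need(FALSE, sprintf("%s.mode: unknown mode `%s`", pre, mode))
      next
    }
    v_um <- gv(m, "v_swim_um_per_s", if (mode == "non_motile") 0 else NULL)
    B <- gv(m, "B_s", NULL)
    if (mode == "gyrotactic" && is.null(B)) {
      need(FALSE, sprintf("%s.B_s: required for gyrotactic mode", pre))
      next
    }
    if (mode != "gyrotactic" && !is.null(B)) {
      need(FALSE, sprintf("%s.B_s: only valid for gyrotactic mode", pre))
      next
    }
    if (is.null(v_um)) {
      need(FALSE, sprintf("%s.v_swim_um_per_s: required for motile modes", pre))
      next
    }
    if (mode == "non_motile") n_nonmotile <- n_nonmotile + 1L
    parsed_mot[[length(parsed_mot) + 1L]] <-
      motility_params(mode, B = B, v_swim = v_um * 1e-6)
  }
  need(n_nonmotile == 1L, "motility: exactly one non_motile entry (the Q baseline) is required")
  need(length(parsed_mot) - n_nonmotile >= 1L, "motility: at least one motile entry is required")

  ana <- gv(config, "analysis", list())
  f <- gv(ana, "f", 0.01)
  need(f > 0 && f <= 1, "analysis.f: must be in (0, 1]")
  cadence <- gv(ana, "q_cadence_s", 1)
  regions_spec <- gv(ana, "regions", "default")
  regions <- if (identical(regions_spec, "default")) depth_regions()
             else depth_regions(lapply(regions_spec, unlist))

  sc <- gv(config, "scales", list())

  if (length(errs))
    abort(paste0("invalid experiment config:\n", paste0("  - ", errs, collapse = "\n")))

  structure(list(
    experiment = gv(config, "experiment", "experiment"),
    master_seed = as.integer(gv(config, "master_seed", 1L)),
    domain = domain,
    flow = utils::modifyList(list(type = flow_type), flow),
    simulation = list(n_microbes = as.integer(n_microbes), dt_s = dt,
                      total_time_s = total_time,
                      output_interval_s = output_interval,
                      seed_z_range_m = seed_z),
    motility = parsed_mot,
    analysis = list(f = f, q_cadence_s = cadence, regions = regions,
                    effvel_window_s = unlist(gv(ana, "effvel_window_s",
                                                c(0, total_time)))),
    scales = list(nu_m2_per_s = gv(sc, "nu_m2_per_s", 5e-6),
                  F_b_m2_per_s3 = gv(sc, "F_b_m2_per_s3", 5e-4),
                  h0_m = gv(sc, "h0_m", 0.15)),
    output_dir = gv(config, "output_dir", "gyropatch-output")
  ), class = "gp_config")
}

build_flow <- function(cfg) {
  fl <- cfg$flow
  switch(fl$type,
    kinematic = make_kinematic_turbulence(
      n_modes = fl$n_modes %||% 64L,
      k_min = fl$k_min_rad_per_m %||% (2 * pi / 0.3),
      k_max = fl$k_max_rad_per_m %||% (2 * pi / 0.02),
      u_rms = fl$u_rms_m_per_s %||% 0.04,
      unsteadiness = fl$unsteadiness %||% 0.5,
      seed = fl$seed %||% (cfg$master_seed * 1000L + 7L),
      domain = cfg$domain),
    taylor_green = make_taylor_green(
      U = fl$U_m_per_s %||% 0.01,
      kappa = (fl$kappa_cells %||% 10) * 2 * pi / cfg$domain$Lx,
      domain = cfg$domain),
    uniform = make_uniform_flow(unlist(fl$U_m_per_s %||% c(0, 0, 0)), cfg$domain),
    gridded = load_gridded_field(fl$path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mot_label <- function(m) {
  if (m$mode == "non_motile") return("non_motile")
  sprintf("%s_B%s_v%g", m$mode, if (is.null(m$B)) "NA" else format(m$B),
          m$v_swim * 1e6)
}

#' Run an end-to-end patchiness experiment
#'
#' Orchestrates the full procedure from one config: builds the flow,
#' simulates the non-motile baseline and every motile population from
#' seed-derived initial conditions, then computes the Q series for each
#' motile/non-motile pair, the scale report, and effective-velocity and
#' polar-angle summaries. All artifacts, a machine-readable manifest with
#' every seed, and a log file are written to the output directory. A stage
#' failure aborts with the stage name; artifacts completed before the
#' failure are retained.
#'
#' @param config A `gp_config` from [validate_config()], a path to a YAML
#'   config, or a named list.
#' @param out_dir Output directory (default from the config).
#' @return Invisibly, a list of written file paths.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "gp_config")) config else validate_config(config)
  out_dir <- out_dir %||% cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "experiment.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logmsg <- function(...) writeLines(sprintf(...), log_con)
  paths <- list(log = log_path)

  stage <- function(name, expr) {
    logmsg("[%s] start", name)
    t0 <- proc.time()[[3]]
    res <- tryCatch(expr, error = function(e)
      abort(sprintf("experiment stage `%s` failed: %s", name, conditionMessage(e))))
    logmsg("[%s] done in %.1f s", name, proc.time()[[3]] - t0)
    res
  }

  field <- stage("flow", build_flow(cfg))

  sim <- cfg$simulation
  entries <- cfg$motility
  seeds <- cfg$master_seed + seq_along(entries)
  trajs <- list()
  for (i in seq_along(entries)) {
    lab <- mot_label(entries[[i]])
    trajs[[lab]] <- stage(paste0("simulate:", lab), {
      sc <- simulation_config(n_microbes = sim$n_microbes, dt = sim$dt_s,
                              total_time = sim$total_time_s,
                              output_interval = sim$output_interval_s,
                              seed_z_range = sim$seed_z_range_m,
                              seed = seeds[i], domain = cfg$domain)
      tr <- run_simulation(sc, field, entries[[i]])
      p <- file.path(out_dir, paste0("trajectory_", lab, ".nc"))
      write_trajectory(tr, p)
      paths[[paste0("trajectory_", lab)]] <- p
      tr
    })
  }

  baseline_lab <- vapply(entries, function(m) m$mode, "") == "non_motile"
  baseline <- trajs[[mot_label(entries[[which(baseline_lab)]])]]

  qfiles <- list()
  for (lab in names(trajs)) {
    if (trajs[[lab]]$motility$mode == "non_motile") next
    qs <- stage(paste0("q_series:", lab),
      q_timeseries_by_region(trajs[[lab]], baseline,
                             regions = cfg$analysis$regions,
                             f = cfg$analysis$f,
                             cadence = cfg$analysis$q_cadence_s))
    p <- file.path(out_dir, paste0("qseries_", lab, ".csv"))
    write_qseries_csv(qs, p)
    qfiles[[lab]] <- p
    paths[[paste0("qseries_", lab)]] <- p
  }

  stage("diagnostics", {
    prof <- turbulence_profile(field,
                               z_levels = seq(0.05, cfg$domain$Lz, length.out = 11),
                               nu = cfg$scales$nu_m2_per_s,
                               n_samples = 1000L,
                               t_window = c(0, min(5, sim$total_time_s)),
                               seed = cfg$master_seed)
    utils::write.csv(as_tibble(prof), file.path(out_dir, "depth_profile.csv"),
                     row.names = FALSE)
    eps_peak <- max(prof$epsilon)
    reps <- bind_rows(lapply(entries, function(m) {
      r <- scale_report(nu = cfg$scales$nu_m2_per_s, epsilon = eps_peak,
                        B = m$B, v_swim = if (m$v_swim > 0) m$v_swim else NULL,
                        F_b = cfg$scales$F_b_m2_per_s3, h0 = cfg$scales$h0_m)
      r$motility <- mot_label(m)
      r
    }))
    utils::write.csv(reps, file.path(out_dir, "scale_report.csv"), row.names = FALSE)
    paths$scale_report <- file.path(out_dir, "scale_report.csv")

    ev_summ <- bind_rows(lapply(names(trajs), function(lab) {
      tr <- trajs[[lab]]
      ev <- effective_velocity(tr, field, cadence = cfg$analysis$q_cadence_s,
                               window = cfg$analysis$effvel_window_s,
                               regions = cfg$analysis$regions)
      ev %>% filter(!is.na(.data$region)) %>%
        group_by(.data$region) %>%
        summarise(mean_speed = mean(.data$speed),
                  mean_theta = mean(.data$theta_eff, na.rm = TRUE),
                  .groups = "drop") %>%
        mutate(motility = lab)
    }))
    utils::write.csv(ev_summ, file.path(out_dir, "effective_velocity.csv"),
                     row.names = FALSE)
    paths$effective_velocity <- file.path(out_dir, "effective_velocity.csv")

    pa <- bind_rows(lapply(names(trajs), function(lab) {
      tr <- trajs[[lab]]
      if (tr$motility$mode == "non_motile") return(NULL)
      st <- polar_angle_stats(tr, window = cfg$analysis$effvel_window_s)
      st$means$motility <- lab
      st$means
    }))
    utils::write.csv(pa, file.path(out_dir, "polar_angles.csv"), row.names = FALSE)
    paths$polar_angles <- file.path(out_dir, "polar_angles.csv")
  })

  manifest <- list(
    experiment = cfg$experiment,
    package_version = as.character(utils::packageVersion("gyropatch")),
    master_seed = cfg$master_seed,
    simulation_seeds = as.list(setNames(seeds, vapply(entries, mot_label, ""))),
    flow = cfg$flow,
    n_microbes = sim$n_microbes,
    total_time_s = sim$total_time_s,
    dt_s = sim$dt_s,
    f = cfg$analysis$f)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- file.path(out_dir, "manifest.json")
  logmsg("experiment complete")
  invisible(paths)
}

#' Built-in desk-scale demo configuration
#'
#' A small kinematic-turbulence experiment (2000 microbes, 30 s, one
#' gyrotactic population against the non-motile baseline) that runs in a
#' few minutes on one CPU.
#'
#' @param out_dir Output directory.
#' @param master_seed Integer master seed.
#' @return A `gp_config`.
#' @export
demo_experiment_config <- function(out_dir = "gyropatch-demo", master_seed = 1L) {
  validate_config(list(
    experiment = "desk-scale demo",
    master_seed = master_seed,
    flow = list(type = "kinematic", n_modes = 32L),
    simulation = list(n_microbes = 2000L, total_time_s = 30,
                      output_interval_s = 0.5),
    motility = list(
      list(mode = "non_motile"),
      list(mode = "gyrotactic", B_s = 1.0, v_swim_um_per_s = 500)),
    analysis = list(f = 0.01, q_cadence_s = 1,
                    effvel_window_s = c(10, 30)),
    output_dir = out_dir))
}
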