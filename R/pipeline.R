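# Configuration-driven orchestration: validate a config, run the enabled
# analysis stages in the canonical order (structure -> hydrogen bonds ->
# energetics/stability -> viscosity -> orientation -> VACF -> diffusion),
# write per-stage CSV/JSON artifacts plus a summary and manifest.

.known_stage_params <- list(
  rdf = c("group_a", "group_b", "r_max", "dr", "exclude_same_molecule"),
  hbond = c("preset", "d_min", "d_max", "angle_min", "angle_max",
            "distance_definition", "donors", "hydrogens", "acceptors"),
  energy = c("cutoff"),
  stability = c("from_table", "threshold"),
  visc = c("volume", "t_upper"),
  vrd = c("site_a_name", "site_b_name", "species"),
  vacf = c("group"),
  msd = c("group", "max_lag_fraction", "beta_tolerance", "unwrap")
)
.known_top_keys <- c("trajectory", "topology", "stress_series", "outdir",
                     "seed", "temperature", "stages")

#' Validate and normalize an analysis configuration
#'
#' Accepts a YAML file path or an R list. Unknown top-level or stage keys
#' are errors that name the accepted keys; defaults (seed 1, temperature
#' 353.15 K, outdir "deswater-run") are injected. Normalization is
#' idempotent.
#'
#' @param config Path to a YAML config or a named list.
#' @return Normalized config list of class `analysis_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  unknown <- setdiff(names(config), .known_top_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(.known_top_keys, collapse = ", "))
  }
  if (is.null(config$stages) || !length(config$stages)) {
    stop("validation error: config enables no stages")
  }
  stages <- config$stages
  for (nm in names(stages)) {
    if (!nm %in% names(.known_stage_params)) {
      stop("unknown stage '", nm, "'; accepted: ",
           paste(names(.known_stage_params), collapse = ", "))
    }
    bad <- setdiff(names(stages[[nm]] %||% list()), .known_stage_params[[nm]])
    if (length(bad)) {
      stop("unknown key(s) in stage '", nm, "': ",
           paste(bad, collapse = ", "), "; accepted: ",
           paste(.known_stage_params[[nm]], collapse = ", "))
    }
  }
  out <- list(
    trajectory = config$trajectory,
    topology = config$topology,
    stress_series = config$stress_series,
    outdir = config$outdir %||% "deswater-run",
    seed = as.integer(config$seed %||% 1L),
    temperature = as.numeric(config$temperature %||% 353.15),
    stages = stages[order(match(names(stages),
                                names(.known_stage_params)))]
  )
  structure(out, class = "analysis_config")
}

#' Run the configured analysis pipeline
#'
#' Executes every enabled stage against the input trajectory (and/or
#' literal-table input for the stability stage), writing one CSV or JSON
#' artifact per stage, a structured run log, a MANIFEST, and a consolidated
#' `summary.json`. Deterministic for a given config and seed. A stage
#' failure aborts with the stage name; artifacts of completed stages are
#' retained and the MANIFEST marks the run incomplete.
#'
#' @param config An `analysis_config` (or anything [validate_config()]
#'   accepts).
#' @param trajectory Optionally, an in-memory [trajectory()] overriding the
#'   config's file inputs.
#' @return Invisibly, the summary list (also written to
#'   `<outdir>/summary.json`).
#' @export
run_pipeline <- function(config, trajectory = NULL) {
  config <- validate_config(unclass(config))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_lines <- c(sprintf("deswater pipeline | seed %d | temperature %.2f K",
                         config$seed, config$temperature))
  manifest <- character(0)
  summary <- list(seed = config$seed, temperature = config$temperature,
                  stages = names(config$stages))
  traj <- trajectory
  needs_traj <- setdiff(names(config$stages), "stability")
  if (is.null(traj) && length(needs_traj)) {
    if (is.null(config$trajectory) || is.null(config$topology)) {
      stop("config error: stages ", paste(needs_traj, collapse = ", "),
           " need trajectory and topology inputs")
    }
    top <- read_topology(config$topology)
    traj <- read_extended_xyz(config$trajectory, top)
  }
  write_artifact <- function(df, name) {
    path <- file.path(config$outdir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    manifest <<- c(manifest, name)
    path
  }
  for (stage in names(config$stages)) {
    p <- config$stages[[stage]] %||% list()
    res <- tryCatch(switch(
      stage,
      rdf = {
        r <- compute_rdf(traj, p$group_a, p$group_b,
                         r_max = p$r_max, dr = p$dr %||% 0.05,
                         exclude_same_molecule =
                           p$exclude_same_molecule %||% TRUE)
        write_artifact(r, "rdf.csv")
        ext <- tryCatch(find_first_extrema(r), error = function(e) NULL)
        cn <- if (!is.null(ext) && !is.na(ext$r_first_min)) {
          coordination_number(r, ext$r_first_min)
        } else NA_real_
        list(first_max = ext$r_first_max %||% NA_real_,
             first_min = ext$r_first_min %||% NA_real_,
             coordination_number = cn)
      },
      hbond = {
        crit <- hbond_criteria(p$preset, p$d_min, p$d_max, p$angle_min,
                               p$angle_max,
                               p$distance_definition %||% "donor_acceptor")
        dmap <- donor_hydrogen_map(
          traj$topology,
          select_atoms(traj$topology, name = p$donors %||% NULL,
                       role = if (is.null(p$donors)) "HBD" else NULL,
                       element = if (is.null(p$donors)) c("O", "N") else NULL),
          select_atoms(traj$topology, name = p$hydrogens %||% NULL,
                       role = if (is.null(p$hydrogens)) "HBD" else NULL,
                       element = if (is.null(p$hydrogens)) "H" else NULL))
        acc <- if (is.null(p$acceptors)) "HBA" else p$acceptors
        series <- hbond_count_series(traj, dmap, acc, crit)
        occ <- hbond_occupancy(traj, dmap, acc, crit)
        write_artifact(series, "hbond_series.csv")
        write_artifact(occ, "hbond_occupancy.csv")
        gf <- tryCatch(fit_gaussian_histogram(series),
                       error = function(e) NULL)
        list(preset = crit$preset,
             mean_bonds = mean(series$n_bonds),
             gaussian_mean = gf$mean %||% NA_real_,
             gaussian_sigma = gf$sigma %||% NA_real_,
             top_occupancy = if (nrow(occ)) occ$occupancy[1] else NA_real_)
      },
      energy = {
        cutoff <- min(p$cutoff %||% 12, cell_half_min(traj$cell))
        dec <- bind_decompositions(
          "system",
          group_interaction_energy(traj, "HBA", "HBD", cutoff,
                                   label = "hba-hbd"),
          group_interaction_energy(traj, "HBA", "water", cutoff,
                                   label = "hba-water"),
          group_interaction_energy(traj, "HBD", "water", cutoff,
                                   label = "hbd-water"))
        write_artifact(dec, "energy_decomposition.csv")
        assign("last_energy", dec, envir = stage_env)
        list(e_totals = stats::setNames(dec$e_total, dec$pair))
      },
      stability = {
        energies <- if (!is.null(p$from_table)) {
          if (!file.exists(p$from_table)) {
            stop("stability table not found: ", p$from_table)
          }
          tibble::as_tibble(utils::read.csv(p$from_table))
        } else if (exists("last_energy", envir = stage_env)) {
          get("last_energy", envir = stage_env)
        } else {
          stop("stability stage needs 'from_table' or a prior energy stage")
        }
        rep <- stability_report(energies, p$threshold %||% 3.30)
        write_artifact(rep, "stability.csv")
        list(S = stats::setNames(rep$S, rep$system),
             classification = stats::setNames(rep$classification,
                                              rep$system))
      },
      visc = {
        stress <- read_stress_series(config$stress_series)
        vol <- p$volume %||% cell_volume(traj$cell)
        v <- green_kubo_viscosity(stress, vol, config$temperature,
                                  t_upper = p$t_upper)
        write_artifact(v$acf, "viscosity_running.csv")
        list(eta = v$eta, t_upper = v$t_upper,
             plateau_drift = v$plateau_drift)
      },
      vrd = {
        sp <- p$species %||% traj$topology$atoms$species[1]
        sa <- select_atoms(traj$topology, species = sp,
                           name = p$site_a_name)
        sb <- select_atoms(traj$topology, species = sp,
                           name = p$site_b_name)
        v <- compute_vrd(traj, sa, sb)
        write_artifact(v, "vrd.csv")
        list(vrd_final = v$value[nrow(v)])
      },
      vacf = {
        v <- compute_vacf(traj, p$group %||% NULL)
        write_artifact(v, "vacf.csv")
        z <- vacf_zero_times(v)
        list(mean_collision_time = z$mean_collision_time,
             velocity_randomization_time = z$velocity_randomization_time)
      },
      msd = {
        m <- compute_msd(traj, p$group %||% NULL,
                         p$max_lag_fraction %||% 0.5,
                         unwrap = p$unwrap %||% FALSE)
        write_artifact(m, "msd.csv")
        fit <- fit_diffusion(m, p$beta_tolerance %||% 0.1)
        if (fit$fallback) {
          log_lines <- c(log_lines,
                         "warning: msd stage used fallback fit window")
        }
        list(D_s_A2_per_ns = fit$D_s, beta_window = fit$beta_window,
             fallback = fit$fallback)
      }),
      error = function(e) {
        writeLines(c(manifest, "INCOMPLETE"),
                   file.path(config$outdir, "MANIFEST"))
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    summary[[stage]] <- res
    log_lines <- c(log_lines, sprintf("stage %s: done", stage))
  }
  writeLines(manifest, file.path(config$outdir, "MANIFEST"))
  writeLines(log_lines, file.path(config$outdir, "run.log"))
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

stage_env <- new.env(parent = emptyenv())
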