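#' Run the solubilization-analysis pipeline from a config
#'
#' Orchestrates seeded end-to-end runs: `simulate` writes synthetic inputs
#' (trajectories, titration table, FCS count trace, QCM-D trace) under
#' `<out_dir>/data`; the analysis stages (`kinetics`, `titration`, `fcs`,
#' `qcmd`) read them back and write fit results as JSON/CSV under
#' `<out_dir>/results`; `report` renders a Markdown summary. A manifest
#' records the package version, seed, config and the MD5 of every output, so
#' identical config + seed reproduce identical manifests for deterministic
#' stages.
#'
#' The config is a JSON file or an equivalent nested list with optional
#' blocks `simulate$trajectories` (`n`, `params` for [solub_params()]),
#' `simulate$titration` (`hill`, `noise_sd`, `replicates`,
#' `concentrations`), `simulate$fcs` (params for [fcs_sim_params()]),
#' `simulate$qcmd` (params for [qcmd_sim_params()]), and per-analysis
#' options (`kinetics$form`, `fcs$fix_Omega`, `qcmd$injection_time`, ...).
#'
#' @param config Path to a JSON config or a list.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed; per-generator seeds are derived from it.
#' @param stages Stages to run, in dependency order; default: every stage
#'   with a config block, plus any analysis whose input exists on disk.
#' @return The manifest (list), invisibly; also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1,
                         stages = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
  }
  dir.create(file.path(out_dir, "data"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "results"), showWarnings = FALSE)
  all_stages <- c("simulate", "kinetics", "titration", "fcs", "qcmd", "report")
  stages <- stages %||% config$stages %||%
    intersect(all_stages, c(names(config), "report"))
  stages <- intersect(all_stages, stages)  # dependency order
  outputs <- character(0)
  status <- list()
  add <- function(paths) outputs <<- c(outputs, paths)

  data_path <- function(...) file.path(out_dir, "data", ...)
  res_path <- function(...) file.path(out_dir, "results", ...)
  write_result <- function(x, name) {
    p <- res_path(name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    add(p)
  }

  run_stage <- function(name, fun) {
    status[[name]] <<- tryCatch({
      fun()
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    sc <- config$simulate %||% list()
    if (!is.null(sc$trajectories)) {
      n <- sc$trajectories$n %||% 10
      p <- do.call(solub_params, sc$trajectories$params %||% list())
      for (i in seq_len(n)) {
        tr <- generate_trajectory(p, seed = seed * 1000 + i,
                                  vesicle_id = sprintf("v%03d", i))
        f <- data_path(sprintf("trajectory_%03d.csv", i))
        write_trajectory(tr, f)
        add(c(f, paste0(f, ".json")))
      }
    }
    if (!is.null(sc$titration)) {
      h <- do.call(hill_params, sc$titration$hill %||% list())
      tt <- generate_titration(
        h, concentrations = unlist(sc$titration$concentrations) %||%
          default_titration_grid(),
        noise_sd = sc$titration$noise_sd %||% 0.01,
        replicates = sc$titration$replicates %||% 1,
        seed = seed + 7)
      f <- data_path("titration.csv")
      write.csv(tt, f, row.names = FALSE)
      add(f)
    }
    if (!is.null(sc$fcs)) {
      p <- do.call(fcs_sim_params, sc$fcs)
      tr <- generate_fcs_trace(p, seed = seed + 13)
      f <- data_path("fcs_trace.csv")
      write_fcs_trace(tr, f)
      add(c(f, paste0(f, ".json")))
    }
    if (!is.null(sc$qcmd)) {
      p <- do.call(qcmd_sim_params, sc$qcmd)
      tr <- generate_qcmd_trace(p, seed = seed + 19)
      f <- data_path("qcmd_trace.csv")
      write_qcmd_trace(tr, f)
      add(f)
    }
  })

  if ("kinetics" %in% stages) run_stage("kinetics", function() {
    files <- sort(list.files(data_path(), "^trajectory_.*\\.csv$",
                             full.names = TRUE))
    if (!length(files)) stop_invalid("kinetics stage: no trajectory CSVs found")
    fits <- lapply(files, function(f) {
      fit_biphasic(read_trajectory(f),
                   form = config$kinetics$form %||% "mechanistic")
    })
    write_result(lapply(fits, function(f) f[setdiff(names(f), "stderr")]),
                 "biphasic_fits.json")
    summ <- summarize_condition(fits, config$kinetics$label %||% "condition")
    f <- res_path("condition_summary.csv")
    write.csv(as.data.frame(summ), f, row.names = FALSE)
    add(f)
    trajs <- lapply(files, read_trajectory)
    ct <- build_fret_contour(trajs,
                             time_bin_s = config$kinetics$time_bin_s %||% 10,
                             e_bin_width = config$kinetics$e_bin_width %||% 0.02)
    f <- res_path("fret_contour.csv")
    write.csv(as.data.frame(unclass(ct)), f)
    add(f)
  })

  if ("titration" %in% stages) run_stage("titration", function() {
    f_in <- data_path("titration.csv")
    if (!file.exists(f_in)) stop_invalid("titration stage: no titration.csv")
    tt <- read.csv(f_in)
    fit <- fit_hill(tt$conc_mM, tt$E)
    write_result(fit[c("A", "B", "k", "n", "chi2", "converged", "flags")],
                 "hill_fit.json")
    grid <- seq(0, max(tt$conc_mM), length.out = 100)
    f <- res_path("hill_curve.csv")
    write.csv(data.frame(conc_mM = grid, E = hill_eval(grid, fit)), f,
              row.names = FALSE)
    add(f)
  })

  if ("fcs" %in% stages) run_stage("fcs", function() {
    f_in <- data_path("fcs_trace.csv")
    if (!file.exists(f_in)) stop_invalid("fcs stage: no fcs_trace.csv")
    tr <- read_fcs_trace(f_in)
    curve <- multitau_correlate(tr$counts, tr$bin_dt)
    f <- res_path("fcs_correlation.csv")
    write.csv(as.data.frame(curve), f, row.names = FALSE)
    add(f)
    fix_om <- config$fcs$fix_Omega %||% tr$params$Omega
    fit <- fit_fcs(curve, fix_Omega = fix_om)
    omega <- config$fcs$omega_xy %||% tr$params$omega_xy
    D <- diffusion_coefficient(fit$tau_D, omega)
    Rh <- hydrodynamic_radius(D)
    write_result(list(N = fit$N, tau_D_s = fit$tau_D, Omega = fit$Omega,
                      chi2_reduced = fit$chi2_reduced,
                      converged = fit$converged,
                      D_m2s = D, R_h_m = Rh, diameter_nm = 2 * Rh * 1e9),
                 "fcs_fit.json")
  })

  if ("qcmd" %in% stages) run_stage("qcmd", function() {
    f_in <- data_path("qcmd_trace.csv")
    if (!file.exists(f_in)) stop_invalid("qcmd stage: no qcmd_trace.csv")
    tr <- read_qcmd_trace(f_in)
    inj <- config$qcmd$injection_time %||% 120
    res <- detect_mass_phases(tr, injection_time = inj)
    write_result(res[c("m_vesicle", "m_peak", "m_final", "gain_pct",
                       "loss_pct", "t_peak", "t_settle", "flags")],
                 "mass_phases.json")
    mass <- data.frame(time_s = tr$time_s,
                       mass_ngcm2 = sauerbrey_mass(tr$delta_f_hz,
                                                   attr(tr, "overtone")))
    f <- res_path("qcmd_mass.csv")
    write.csv(mass, f, row.names = FALSE)
    add(f)
    f <- res_path("qcmd_df.csv")
    write.csv(df_plot_data(tr), f, row.names = FALSE)
    add(f)
  })

  manifest <- list(
    package = "vesolv",
    version = as.character(utils::packageVersion("vesolv")),
    seed = seed,
    stages = stages,
    status = status,
    config = config,
    out_dir = normalizePath(out_dir),
    files = {
      o <- sort(unique(outputs))
      data.frame(path = sub(paste0("^", normalizePath(out_dir), "/?"), "",
                            normalizePath(o)),
                 md5 = unname(tools::md5sum(o)), row.names = NULL)
    }
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)

  if ("report" %in% stages) {
    status$report <- tryCatch({
      render_report(mpath)
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    manifest$status <- status
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
  }
  failed <- vapply(status, function(s) !identical(s, "ok"), logical(1))
  if (any(failed)) {
    warning("stage failure(s): ",
            paste(names(status)[failed], unlist(status[failed]),
                  collapse = "; "), call. = FALSE)
  }
  invisible(manifest)
}

#' Render a Markdown report from a run manifest
#'
#' Collects whatever result files the run produced (biphasic condition
#' summary, Hill fit, FCS fit and sizing, QCM-D mass phases) into a single
#' human-readable `report.md` next to the manifest. Regeneration from the
#' same manifest is idempotent.
#'
#' @param manifest Path to a `manifest.json` written by [run_pipeline()]
#'   (or the manifest list with an `out_dir` entry).
#' @return Path of the report, invisibly.
#' @export
render_report <- function(manifest) {
  if (is.character(manifest)) {
    out_dir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE,
                                    simplifyDataFrame = TRUE)
  } else {
    out_dir <- manifest$out_dir
  }
  res <- function(name) file.path(out_dir, "results", name)
  lines <- c("# Vesicle solubilization analysis report", "",
             sprintf("- package: vesolv %s", manifest$version %||% "?"),
             sprintf("- seed: %s", manifest$seed %||% "?"),
             sprintf("- stages: %s", paste(manifest$stages, collapse = ", ")),
             "")
  if (file.exists(res("condition_summary.csv"))) {
    cs <- read.csv(res("condition_summary.csv"))
    lines <- c(lines, "## Biphasic kinetics", "",
               sprintf("- condition: %s (n = %d vesicles)", cs$label, cs$n),
               sprintf("- swelling half-life t_E = %.3g +/- %.2g s (SEM)",
                       cs$mean_t_E, cs$sem_t_E),
               sprintf("- lysis half-life t_L = %.3g +/- %.2g s (SEM)",
                       cs$mean_t_L, cs$sem_t_L),
               sprintf("- t_L / t_E = %.3g", cs$ratio_L_over_E), "")
  }
  if (file.exists(res("hill_fit.json"))) {
    h <- jsonlite::read_json(res("hill_fit.json"), simplifyVector = TRUE)
    lines <- c(lines, "## Hill titration", "",
               sprintf("- A = %.3g, B = %.3g, k = %.3g mM, n = %.3g",
                       h$A, h$B, h$k, h$n), "")
  }
  if (file.exists(res("fcs_fit.json"))) {
    f <- jsonlite::read_json(res("fcs_fit.json"), simplifyVector = TRUE)
    lines <- c(lines, "## FCS", "",
               sprintf("- N = %.3g, tau_D = %.3g ms", f$N, f$tau_D_s * 1e3),
               sprintf("- D = %.3g m^2/s -> hydrodynamic diameter %.3g nm",
                       f$D_m2s, f$diameter_nm), "")
  }
  if (file.exists(res("mass_phases.json"))) {
    q <- jsonlite::read_json(res("mass_phases.json"), simplifyVector = TRUE)
    lines <- c(lines, "## QCM-D mass phases", "",
               sprintf("- mass gain: %.3g%%, mass loss: %.3g%%",
                       q$gain_pct, q$loss_pct),
               sprintf("- vesicle layer %.4g ng/cm^2, peak %.4g, final %.4g",
                       q$m_vesicle, q$m_peak, q$m_final), "")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
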