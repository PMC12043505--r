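# Reproducible end-to-end analyses: site chronology, regional
# Mesolithic-to-Neolithic transition, and the age-depth re-analysis.
# Each command takes a config (an R list or a YAML file), requires a seed,
# and writes seeded, byte-identically rerunnable summary tables plus a
# manifest (config hash, seed, package version).

load_run_config <- function(cfg) {
  if (is.character(cfg)) {
    if (!file.exists(cfg)) {
      stop_bc(sprintf("config file not found: %s", cfg), "baychron_config_error")
    }
    cfg <- yaml::read_yaml(cfg)
  }
  if (!is.list(cfg)) stop_bc("config must be a list or a YAML path",
                             "baychron_config_error")
  if (is.null(cfg$seed)) stop_bc("config must set a seed", "baychron_config_error")
  cfg
}

resolve_curve <- function(x, kind) {
  if (inherits(x, "cal_curve")) return(x)
  if (is.null(x) || !is.character(x) || !file.exists(x)) {
    stop_bc(sprintf("missing %s curve (path does not exist)", kind),
            "baychron_config_error")
  }
  read_cal_curve(x, kind = kind)
}

resolve_dates <- function(x) {
  if (inherits(x, "date_table")) return(x)
  if (is.data.frame(x)) return(date_table(x))
  if (is.null(x) || !is.character(x) || !file.exists(x)) {
    stop_bc("missing date table (path does not exist)", "baychron_config_error")
  }
  read_date_table(x)
}

cfg_mcmc <- function(cfg) {
  m <- cfg$mcmc %||% list()
  mcmc_control(chains = m$chains %||% 4,
               iterations = m$iterations %||% 20000,
               burn_in = m$burn_in %||% floor((m$iterations %||% 20000) / 2),
               thin = m$thin %||% 10,
               seed = cfg$seed)
}

write_manifest <- function(cfg, out_dir, command) {
  cfg$output <- NULL # the hash identifies the analysis, not its destination
  cfg$seed <- as.integer(cfg$seed)
  cfg_txt <- yaml::as.yaml(cfg[order(names(cfg))])
  tmp <- tempfile(); writeLines(cfg_txt, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  manifest <- list(command = command, seed = cfg$seed, config_md5 = hash,
                   package = "baychron",
                   version = as.character(utils::packageVersion("baychron")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
}

log_stage <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}

#' Run the site-chronology analysis
#'
#' Fits the phase model to the terrestrial (charcoal/bone) dates,
#' independently calibrates the marine shells with the supplied Delta-R,
#' and emits a consistency statement: do the pooled shell calibrated ages
#' fall within the 95% HPD span of the charcoal phase model?
#'
#' @param cfg Config list or YAML path. Blocks: `curves` (`terrestrial`,
#'   optionally `marine`: paths or `cal_curve`s), `dates` (path or
#'   [date_table]; phase membership from the `phase_id` column), `model`
#'   (`boundary_type`, `contiguous`, `tau_scale`, `delta_r` = c(mean, sd),
#'   `outlier` = TRUE/FALSE, `phase_order`: phase ids, older first), `mcmc`
#'   (`chains`, `iterations`, `burn_in`, `thin`), `seed` (mandatory),
#'   `output` (optional directory).
#' @param verbose Emit one log line per MCMC stage with diagnostics.
#' @return An object of class `site_chronology_report`.
#' @export
run_site_chronology <- function(cfg, verbose = FALSE) {
  cfg <- load_run_config(cfg)
  model_cfg <- cfg$model %||% list()
  curve <- resolve_curve(cfg$curves$terrestrial, "terrestrial")
  dates <- resolve_dates(cfg$dates)
  terr <- dates[dates$material == "terrestrial", , drop = FALSE]
  mar <- dates[dates$material == "marine", , drop = FALSE]
  if (!nrow(terr)) stop_bc("no terrestrial dates for the phase model",
                           "baychron_config_error")
  if (!"phase_id" %in% names(terr) || any(is.na(terr$phase_id))) {
    stop_bc("every terrestrial date needs a phase_id", "baychron_config_error")
  }
  marine_curve <- if (nrow(mar)) resolve_curve(cfg$curves$marine, "marine")
  dr <- model_cfg$delta_r
  if (nrow(mar) && is.null(dr)) {
    stop_bc("marine dates present: model$delta_r = c(mean, sd) required",
            "baychron_config_error")
  }

  order_ids <- model_cfg$phase_order %||% unique(terr$phase_id)
  btype <- model_cfg$boundary_type %||% "sigma"
  phases <- lapply(order_ids, function(id) {
    phase_spec(id, terr$lab_code[terr$phase_id == id], btype)
  })
  outl <- if (isFALSE(model_cfg$outlier)) NULL else outlier_spec()

  log_stage(verbose, "phase model: %d phases, %d dates, seed %d",
            length(phases), nrow(terr), cfg$seed)
  fit <- phase_model(date_table(terr), phases, curve,
                     outlier = outl,
                     contiguous = model_cfg$contiguous %||% TRUE,
                     tau_scale = model_cfg$tau_scale %||% 100,
                     mcmc = cfg_mcmc(cfg))
  log_stage(verbose, "phase model: max R-hat %.3f%s",
            max(fit$diagnostics$rhat, na.rm = TRUE),
            if (fit$flagged) " [FLAGGED]" else "")

  est <- boundary_estimates(fit)
  shells <- NULL; consistency <- NA_character_
  if (nrow(mar)) {
    rng <- curve_range(marine_curve)
    grid <- cal_grid(rng[["oldest"]], rng[["youngest"]], step_yr = 5)
    shells <- apply_delta_r(date_table(mar), marine_curve,
                            list(mean = dr[1], sd = dr[2]), grid)
    start_old <- est$hpd95_older[1]
    end_young <- est$hpd95_younger[nrow(est)]
    ok <- shells$pooled_range[["oldest"]] <= start_old &&
      shells$pooled_range[["youngest"]] >= end_young
    consistency <- if (ok) "consistent" else "inconsistent"
    log_stage(verbose, "shells: pooled range %.1f-%.1f ka (%s)",
              as_ka(shells$pooled_range[["oldest"]]),
              as_ka(shells$pooled_range[["youngest"]]), consistency)
  }

  report <- structure(list(fit = fit, boundaries = est,
                           outliers = if (!is.null(outl)) outlier_report(fit),
                           shells = shells, consistency = consistency,
                           seed = cfg$seed),
                      class = "site_chronology_report")
  if (!is.null(cfg$output)) {
    dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
    write_summary_table(est, file.path(cfg$output, "boundaries.csv"))
    if (!is.null(report$outliers)) {
      write_summary_table(report$outliers, file.path(cfg$output, "outliers.csv"))
    }
    if (!is.null(shells)) {
      write_summary_table(
        data.frame(lab_code = names(shells$means), mean_calbp = shells$means,
                   mean_ka = as_ka(shells$means)),
        file.path(cfg$output, "shells.csv"))
    }
    write_summary_table(fit$diagnostics, file.path(cfg$output, "diagnostics.csv"))
    write_manifest(cfg, cfg$output, "site_chronology")
  }
  report
}

#' @export
print.site_chronology_report <- function(x, ...) {
  cat("Site chronology report\n")
  print(x$boundaries[, c("boundary", "mean", "ka")], row.names = FALSE)
  if (!is.null(x$shells)) {
    cat(sprintf("Shells: %.1f-%.1f ka; charcoal model %s with shell series\n",
                as_ka(x$shells$pooled_range[["oldest"]]),
                as_ka(x$shells$pooled_range[["youngest"]]), x$consistency))
  }
  invisible(x)
}

#' Run the regional Mesolithic-to-Neolithic transition model
#'
#' For each region, fits a two-phase model (Mesolithic older, Neolithic
#' younger) per requested boundary treatment and reports the
#' end-Mesolithic and start-Neolithic boundaries. `"both"` fits the sigma
#' and uniform variants, parameterising the most likely range of
#' scenarios. Regions missing a culture group are skipped with a warning.
#'
#' @param cfg Config list or YAML path. `dates` must carry `region` and
#'   `culture` ("Mesolithic"/"Neolithic") columns; `curves$terrestrial` as
#'   in [run_site_chronology]; `model$boundary_type` one of `"sigma"`,
#'   `"uniform"`, `"both"`; `seed`; optional `output`.
#' @param verbose Emit per-region log lines.
#' @return An object of class `transition_report` with `table` (one row
#'   per region x boundary type) and `skipped`.
#' @export
run_transition_model <- function(cfg, verbose = FALSE) {
  cfg <- load_run_config(cfg)
  curve <- resolve_curve(cfg$curves$terrestrial, "terrestrial")
  dates <- resolve_dates(cfg$dates)
  if (!all(c("region", "culture") %in% names(dates))) {
    stop_bc("transition model needs region and culture columns",
            "baychron_config_error")
  }
  btype <- (cfg$model %||% list())$boundary_type %||% "both"
  types <- if (btype == "both") c("sigma", "uniform") else btype
  regions <- unique(dates$region)
  rows <- list(); skipped <- character()
  for (r in regions) {
    d <- dates[dates$region == r, , drop = FALSE]
    meso <- d[d$culture == "Mesolithic", , drop = FALSE]
    neo <- d[d$culture == "Neolithic", , drop = FALSE]
    if (!nrow(meso) || !nrow(neo)) {
      warning(sprintf("region %s missing a culture group; skipped", r),
              call. = FALSE)
      skipped <- c(skipped, r)
      next
    }
    for (ty in types) {
      log_stage(verbose, "region %s, %s boundaries (%d + %d dates)",
                r, ty, nrow(meso), nrow(neo))
      fit <- phase_model(
        date_table(d), list(phase_spec("Mesolithic", meso$lab_code, ty),
                            phase_spec("Neolithic", neo$lab_code, ty)),
        curve, outlier = NULL, contiguous = FALSE,
        mcmc = cfg_mcmc(cfg))
      est <- boundary_estimates(fit)
      em <- est[est$boundary == "end_Mesolithic", ]
      sn <- est[est$boundary == "start_Neolithic", ]
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, boundary_type = ty,
        end_meso_calbp = em$mean, end_meso_ka = em$ka,
        start_neo_calbp = sn$mean, start_neo_ka = sn$ka,
        start_neo_hpd95_older = sn$hpd95_older,
        start_neo_hpd95_younger = sn$hpd95_younger,
        rhat_max = max(fit$diagnostics$rhat, na.rm = TRUE))
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  report <- structure(list(table = tab, skipped = skipped, seed = cfg$seed),
                      class = "transition_report")
  if (!is.null(cfg$output) && !is.null(tab)) {
    dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
    write_summary_table(tab, file.path(cfg$output, "transition.csv"))
    write_manifest(cfg, cfg$output, "transition_model")
  }
  report
}

#' @export
print.transition_report <- function(x, ...) {
  cat("Mesolithic-to-Neolithic transition boundaries\n")
  if (!is.null(x$table)) {
    print(x$table[, c("region", "boundary_type", "end_meso_ka", "start_neo_ka")],
          row.names = FALSE)
  }
  if (length(x$skipped)) cat("Skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Run the age-depth re-analysis
#'
#' Fits the non-monotonic Bayesian age-depth regression, imputes ages at
#' the requested undated depths, and heads the report with the age
#' reversal count that motivates the non-monotone treatment.
#'
#' @param cfg Config list or YAML path. Blocks: `curves$terrestrial`,
#'   `core` (path or data.frame), `impute_depths` (numeric), `priors`
#'   (optional [age_depth_priors] fields), `mcmc`, `seed`, `output`.
#' @param verbose Emit log lines.
#' @return An object of class `agedepth_report`.
#' @export
run_agedepth <- function(cfg, verbose = FALSE) {
  cfg <- load_run_config(cfg)
  curve <- resolve_curve(cfg$curves$terrestrial, "terrestrial")
  core <- if (is.data.frame(cfg$core)) cfg$core else {
    if (is.null(cfg$core) || !file.exists(cfg$core)) {
      stop_bc("missing core table (path does not exist)", "baychron_config_error")
    }
    utils::read.csv(cfg$core)
  }
  pri_cfg <- cfg$priors %||% list()
  priors <- age_depth_priors(
    beta0_mean = pri_cfg$beta0_mean, beta0_sd = pri_cfg$beta0_sd %||% 10000,
    beta1_mean = pri_cfg$beta1_mean %||% 0,
    beta1_sd = pri_cfg$beta1_sd %||% 10000,
    sigma_eps_scale = pri_cfg$sigma_eps_scale %||% 1000)

  reversals <- count_reversals(core, curve)
  log_stage(verbose, "core: %d samples, %d age reversals, seed %d",
            nrow(core), reversals, cfg$seed)
  fit <- age_depth(core, curve, priors, cfg_mcmc(cfg))
  log_stage(verbose, "age-depth: max R-hat %.3f%s",
            max(fit$diagnostics$rhat, na.rm = TRUE),
            if (!fit$converged) " [FLAGGED]" else "")
  imput <- if (length(cfg$impute_depths)) {
    impute_depth_ages(fit, as.numeric(cfg$impute_depths), force = TRUE)
  }
  report <- structure(list(reversals = reversals, fit = fit,
                           imputation = imput, seed = cfg$seed),
                      class = "agedepth_report")
  if (!is.null(cfg$output)) {
    dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
    write_summary_table(summary(fit)$estimates,
                        file.path(cfg$output, "agedepth.csv"))
    if (!is.null(imput)) {
      write_summary_table(imput$summary, file.path(cfg$output, "imputed.csv"))
    }
    write_summary_table(data.frame(reversals = reversals),
                        file.path(cfg$output, "reversals.csv"))
    write_manifest(cfg, cfg$output, "agedepth")
  }
  report
}

#' @export
print.agedepth_report <- function(x, ...) {
  cat(sprintf("Age-depth re-analysis: %d age reversals in the dated series\n",
              x$reversals))
  print(x$fit)
  if (!is.null(x$imputation)) print(x$imputation)
  invisible(x)
}
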