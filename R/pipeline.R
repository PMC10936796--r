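# End-to-end pipeline: simulate or read tables, validate, run the
# requested analyses, and write a structured report bundle.

#' Pipeline run configuration
#'
#' A plain list, readable from YAML with [read_run_config()]. Recognised
#' fields:
#' \describe{
#'   \item{seed}{integer; drives every stochastic stage.}
#'   \item{output}{output directory for the report bundle (optional; no
#'     files are written when absent).}
#'   \item{simulate}{list of [generator_config()] overrides, plus
#'     `n_stomachs`; mutually exclusive with `inputs`.}
#'   \item{inputs}{list of file paths `stations`, `samples`, `stomachs`.}
#'   \item{analyses}{character vector from `validate`, `niche`, `ogive`,
#'     `lw`, `diet`, `envelope`, `abundance` (default: all).}
#'   \item{niche}{`variables`, `probs`, `season`.}
#'   \item{ogive}{`sex`, `mature_stages`, `n_boot`, `level`.}
#'   \item{envelope}{`juvenile_max_tl`, `mature_stages`.}
#'   \item{abundance}{`trend`.}
#' }
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  tn_assert(file.exists(path), sprintf("config file not found: %s", path),
            "tn_input_error")
  yaml::read_yaml(path)
}

resolve_config <- function(config) {
  defaults <- list(
    seed = 1L,
    analyses = c("validate", "niche", "ogive", "lw", "diet", "envelope",
                 "abundance"),
    niche = list(variables = c("temperature", "depth"),
                 probs = c(0.05, 0.95), season = "both"),
    ogive = list(sex = "female", mature_stages = 3:7, n_boot = 200L,
                 level = 0.95),
    envelope = list(juvenile_max_tl = 20, mature_stages = c(5, 6)),
    abundance = list(trend = TRUE)
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]]))
        config[[k]][[kk]] <- config[[k]][[kk]] %||% defaults[[k]][[kk]]
    }
  }
  config
}

load_pipeline_data <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    n_stomachs <- sim$n_stomachs %||% 27
    sim$n_stomachs <- NULL
    # YAML-sourced vectors arrive as lists; coerce the structured fields
    if (!is.null(sim$n_stations)) sim$n_stations <- unlist(sim$n_stations)
    if (!is.null(sim$years)) sim$years <- unlist(sim$years)
    gcfg <- do.call(generator_config, sim)
    generate_survey(gcfg, seed = config$seed, n_stomachs = n_stomachs)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    tn_assert(!is.null(inp$stations), "inputs$stations path is required",
              "tn_config_error")
    need_samples <- any(c("ogive", "lw", "envelope") %in% config$analyses)
    tn_assert(!need_samples || !is.null(inp$samples),
              "requested analyses need a specimen table (inputs$samples)",
              "tn_config_error")
    tn_assert(!("diet" %in% config$analyses) || !is.null(inp$stomachs),
              "diet analysis needs a stomach table (inputs$stomachs)",
              "tn_config_error")
    list(
      stations = read_stations(inp$stations),
      samples = if (!is.null(inp$samples)) read_biosamples(inp$samples)
                else NULL,
      stomachs = if (!is.null(inp$stomachs)) read_stomachs(inp$stomachs)
                 else NULL,
      config = NULL
    )
  } else {
    tn_stop("config must provide either 'simulate' or 'inputs'",
            "tn_config_error")
  }
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order over simulated or
#' file-based inputs and assembles a structured report in which every
#' numeric result carries the parameters that produced it. With an output
#' directory set, writes the three input tables, the report (JSON) and the
#' resolved configuration (YAML) beside each other, so the bundle alone
#' suffices to re-run the analysis. Deterministic for a fixed seed and
#' configuration.
#'
#' @param config a run-configuration list (see [read_run_config()]) or a
#'   YAML file path.
#' @return the report, invisibly a list; elements per requested analysis
#'   plus `meta` (seed, record counts) and `config_echo`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- resolve_config(config)
  data <- load_pipeline_data(config)
  stations <- data$stations
  samples <- data$samples
  stomachs <- data$stomachs
  report <- list(meta = list(
    seed = config$seed,
    n_stations = nrow(stations),
    n_samples = if (is.null(samples)) 0L else nrow(samples),
    n_stomachs = if (is.null(stomachs)) 0L else nrow(stomachs)
  ))

  run <- function(stage, expr) {
    tryCatch(expr, tn_error = function(e) {
      tn_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
              "tn_stage_error")
    })
  }

  if ("validate" %in% config$analyses) {
    report$validate <- run("validate", {
      v <- validate_dataset(stations, samples %||% stations[0, ], stomachs)
      list(worst = v$worst, violations = as.list(v$violations),
           warnings = as.list(v$warnings))
    })
  }
  if ("niche" %in% config$analyses) {
    np <- config$niche
    report$niche <- run("niche", {
      out <- list()
      for (v in np$variables) {
        s <- niche_summary(stations, v, probs = unlist(np$probs),
                           season = np$season)
        out[[v]] <- list(
          tb = s$tb, steno = s$steno,
          interval = unname(s$interval),
          interval_unweighted = unname(s$interval_unweighted),
          interval_width = interval_width(s$interval),
          probs = s$probs, n_stations = s$n_stations,
          n_missing = s$n_missing, total_catch = s$total_catch,
          season = s$season
        )
      }
      out
    })
  }
  if ("ogive" %in% config$analyses) {
    op <- config$ogive
    report$ogive <- run("ogive", {
      sub <- samples[!is.na(samples$maturity_stage) &
                       samples$sex == op$sex, , drop = FALSE]
      tn_assert(nrow(sub) > 0, "no staged specimens for the requested sex",
                "tn_insufficient_data_error")
      mat <- binarize_maturity(sub$maturity_stage,
                               mature_stages = unlist(op$mature_stages))
      fit <- fit_maturity_ogive(sub$total_length, mat)
      ci <- if (op$n_boot > 0)
        l50_ci_bootstrap(sub$total_length, mat, n_boot = op$n_boot,
                         level = op$level, seed = config$seed)
      else NULL
      list(sex = op$sex, beta0 = fit$beta0, beta1 = fit$beta1,
           l50 = fit$l50, l95 = fit$l95, converged = fit$converged,
           n_used = fit$n_used, n_mature = fit$n_mature,
           l50_ci = if (!is.null(ci)) c(ci$lo, ci$hi) else NULL,
           ci_level = if (!is.null(ci)) ci$level else NULL,
           n_boot = op$n_boot)
    })
  }
  if ("lw" %in% config$analyses) {
    report$lw <- run("lw", {
      sub <- samples[!is.na(samples$weight), , drop = FALSE]
      fit <- fit_length_weight(sub$total_length, sub$weight)
      list(log_a = fit$log_a, b = fit$b, r2 = fit$r2, n_used = fit$n_used,
           residual_sd = fit$residual_sd)
    })
  }
  if ("diet" %in% config$analyses && !is.null(stomachs)) {
    report$diet <- run("diet", {
      d <- diet_summary(stomachs)
      list(n_stomachs = d$n_stomachs, vacuity = d$vacuity,
           occurrence = as.list(d$occurrence),
           weight_pct = as.list(d$weight_pct))
    })
  }
  if ("envelope" %in% config$analyses) {
    ep <- config$envelope
    report$envelope <- run("envelope", {
      juv <- subgroup_envelope(
        stations, samples,
        function(s) s$total_length <= ep$juvenile_max_tl,
        label = sprintf("juveniles (TL <= %g cm)", ep$juvenile_max_tl))
      mf <- subgroup_envelope(
        stations, samples,
        function(s) s$sex == "female" &
          s$maturity_stage %in% unlist(ep$mature_stages),
        label = sprintf("late-stage females (stages %s)",
                        paste(unlist(ep$mature_stages), collapse = ",")))
      ov <- envelope_overlap(juv, mf)
      list(
        juveniles = list(n = juv$n, depth = as.list(juv$depth),
                         temperature = as.list(juv$temperature)),
        mature_females = list(n = mf$n, depth = as.list(mf$depth),
                              temperature = as.list(mf$temperature)),
        critical_habitat = list(
          depth = if (!is.null(ov$depth)) unname(ov$depth) else NULL,
          temperature = if (!is.null(ov$temperature))
            unname(ov$temperature) else NULL,
          disjoint = as.list(ov$disjoint))
      )
    })
  }
  if ("abundance" %in% config$analyses) {
    ap <- config$abundance
    report$abundance <- run("abundance", {
      ser <- annual_abundance_index(stations, trend = isTRUE(ap$trend))
      tr <- attr(ser, "trend")
      list(series = lapply(seq_len(nrow(ser)), function(i) as.list(ser[i, ])),
           trend = if (!is.null(tr))
             list(slope = tr$slope, ci = unname(tr$ci),
                  p_value = tr$p_value) else NULL)
    })
  }

  report$config_echo <- config[setdiff(names(config), "output")]

  if (!is.null(config$output)) {
    dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
    write_table(stations, file.path(config$output, "stations.csv"))
    if (!is.null(samples))
      write_table(samples, file.path(config$output, "samples.csv"))
    if (!is.null(stomachs))
      write_table(stomachs, file.path(config$output, "stomachs.csv"))
    jsonlite::write_json(report, file.path(config$output, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    yaml::write_yaml(config, file.path(config$output, "config.yaml"))
  }
  invisible(report)
}
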