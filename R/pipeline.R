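#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages end-to-end on simulated or file-based inputs:
#' selectivity scoring, dose-response fitting, ZIP synergy, mediation,
#' paralog preference, and PK summaries, each seeded from the
#' configuration. Stages not configured are skipped; a stage failure is
#' recorded in the report and its dependents are not attempted.
#'
#' The configuration is a named list (or a YAML file path, read with the
#' \pkg{yaml} package when installed) with optional entries:
#' \describe{
#'   \item{seed}{master seed; per-stage seeds default to it.}
#'   \item{selectivity}{`list(screen =, annotations =, target_lineage =,
#'     min_target =)` where `screen`/`annotations` are data frames or CSV
#'     paths; or `list(simulate = list(...))` with [simulate_screen()]
#'     arguments.}
#'   \item{synergy}{`list(simulate = list(...))` ([simulate_combination_plate()]
#'     arguments) plus optional `fc_threshold`, `p_threshold`, `mode`.}
#'   \item{mediation}{`list(simulate = list(...))`
#'     ([simulate_expression_chain()] arguments).}
#'   \item{paralog}{`list(simulate = list(...))` or `list(decat = )` plus
#'     `n_sim`, `mask`.}
#'   \item{pk}{`list(simulate = list(...))` or `list(profiles = )` plus
#'     `interval_h`, `threshold`.}
#'   \item{out_dir}{directory for the JSON + text report (optional).}
#' }
#'
#' @param config named list or YAML path.
#' @return list of class `run_report`: per-stage `status`
#'   (`"ok"`/`"failed"`/`"skipped"`), key outputs, warnings, `config`
#'   echo, and the package version.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  report <- list(stages = list(), warnings = character(),
                 config = config,
                 version = as.character(utils::packageVersion("drugselect")))

  resolve_table <- function(x, reader) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("input file not found: ", x)
      reader(x)
    } else x
  }
  run_stage <- function(name, fn) {
    out <- tryCatch(fn(), error = function(e)
      structure(conditionMessage(e), class = "stage_error"))
    if (inherits(out, "stage_error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = unclass(out))
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), out)
    }
  }

  if (!is.null(config$selectivity)) {
    run_stage("selectivity", function() {
      cfg <- config$selectivity
      if (!is.null(cfg$simulate)) {
        sim <- do.call(simulate_screen,
                       utils::modifyList(list(seed = seed), cfg$simulate))
        screen <- sim$screen; ann <- sim$annotations
        target <- cfg$target_lineage %||% "neuroblastoma"
      } else {
        screen <- resolve_table(cfg$screen, read_screen_csv)
        ann <- resolve_table(cfg$annotations, read_annotations_csv)
        target <- cfg$target_lineage
      }
      rk <- rank_drugs(screen, ann, target,
                       min_target = cfg$min_target %||% 3)
      list(top = utils::head(rk$results, 10),
           n_scored = nrow(rk$results), n_skipped = nrow(rk$skipped))
    })
  }
  if (!is.null(config$synergy)) {
    run_stage("synergy", function() {
      cfg <- config$synergy
      sim <- do.call(simulate_combination_plate,
                     utils::modifyList(list(seed = seed), cfg$simulate %||% list()))
      dm <- normalize_plate(sim$plate)
      surf <- zip_delta_surface(dm, mode = cfg$mode %||% "zip")
      call <- call_combination(dm, surf,
                               fc_threshold = cfg$fc_threshold %||% 1.5,
                               p_threshold = cfg$p_threshold %||% 0.01)
      list(delta_max = surf$delta_max, delta_min = surf$delta_min,
           classification = call$classification,
           log2_fc_at_max = call$log2_fc_at_max, p_max = call$p_max)
    })
  }
  if (!is.null(config$mediation)) {
    run_stage("mediation", function() {
      cfg <- config$mediation
      sim <- do.call(simulate_expression_chain,
                     utils::modifyList(list(seed = seed), cfg$simulate %||% list()))
      med <- mediation(sim$sensitivity, sim$exposure, sim$mediator)
      list(marginal_exposure_p = med$marginal$exposure_p,
           conditional_exposure_p = med$conditional$exposure_p,
           conditional_mediator_p = med$conditional$mediator_p)
    })
  }
  if (!is.null(config$paralog)) {
    run_stage("paralog", function() {
      cfg <- config$paralog
      decat <- if (!is.null(cfg$decat)) {
        resolve_table(cfg$decat, read_decat_csv)
      } else {
        do.call(simulate_decatenation,
                utils::modifyList(list(seed = seed), cfg$simulate %||% list()))$decat
      }
      st <- simulation_test(decat, n_sim = cfg$n_sim %||% 2000,
                            seed = seed, mask = cfg$mask)
      list(fold_preference = st$preference$fold_preference,
           ci = st$preference$ci, p_value = st$p_value)
    })
  }
  if (!is.null(config$pk)) {
    run_stage("pk", function() {
      cfg <- config$pk
      prof <- if (!is.null(cfg$profiles)) {
        resolve_table(cfg$profiles, read_pk_csv)
      } else {
        do.call(simulate_pk,
                utils::modifyList(list(seed = seed), cfg$simulate %||% list()))$profiles
      }
      per <- lapply(split(prof, prof$subject), function(p) {
        p <- p[order(p$time_h), ]
        pk_nca(p$time_h, p$conc_ugL,
               interval_h = cfg$interval_h %||% NULL,
               threshold = cfg$threshold %||% 100)
      })
      list(t_half = vapply(per, `[[`, numeric(1), "t_half"),
           auc_0_t = vapply(per, `[[`, numeric(1), "auc_0_t"),
           c_avg = vapply(per, `[[`, numeric(1), "c_avg"),
           mean_t_half = mean(vapply(per, `[[`, numeric(1), "t_half")))
    })
  }

  class(report) <- "run_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(utils::capture.output(print(report)),
               file.path(config$out_dir, "report.txt"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("drugselect pipeline report (version ", x$version, ")\n", sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat("- ", nm, ": ", st$status, "\n", sep = "")
    if (st$status == "failed") cat("    error: ", st$error, "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
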