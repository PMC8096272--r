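#' @include AllClasses.R synthetic.R fluctuation.R steepness.R energetics.R
NULL

.CONFIG_KEYS <- c("seed", "window", "conditions", "grid", "detect", "sim",
                  "eDuplex", "perG4Gain")
.CONDITION_KEYS <- c("construct", "ion", "turns", "nRamps", "pFold")
.GRID_KEYS <- c("from", "to", "by")
.DETECT_KEYS <- c("smoothSd", "minProminenceFrac", "minSeparation")
.SIM_KEYS <- c("fC1", "fC2", "turnsPerG4", "plectonemeSlope",
               "transitionWidth", "hopRateScale", "relaxTime", "beadNoiseSd",
               "trackingNoiseSd", "sampleRate", "dwell")

.checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
  invisible(x)
}

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (readable from YAML) with keys
#' `seed`, `window`, `conditions` (list of lists with `construct`, `ion`,
#' `turns`, `nRamps` and optional `pFold`), and optional `grid`
#' (`from`/`to`/`by`), `detect` (peak-detection options), `sim`
#' ([SimParams] overrides), `eDuplex` and `perG4Gain`. Unknown keys are
#' rejected.
#'
#' @param config Named list.
#' @return The validated config with defaults filled in.
#' @export
validateRunConfig <- function(config) {
  stopifnot(is.list(config))
  .checkKeys(config, .CONFIG_KEYS, "config")
  if (is.null(config$conditions) || !length(config$conditions))
    stop("config must define at least one condition")
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$window <- if (is.null(config$window)) 4 else config$window
  config$eDuplex <- if (is.null(config$eDuplex)) 120 else config$eDuplex
  config$perG4Gain <- if (is.null(config$perG4Gain)) 10 else config$perG4Gain
  config$grid <- utils::modifyList(list(from = 0.05, to = 3, by = 0.01),
                                   .checkKeys(config$grid %||% list(),
                                              .GRID_KEYS, "grid"))
  config$detect <- utils::modifyList(
    list(smoothSd = 0.03, minProminenceFrac = 0.10, minSeparation = 0.10),
    .checkKeys(config$detect %||% list(), .DETECT_KEYS, "detect"))
  .checkKeys(config$sim %||% list(), .SIM_KEYS, "sim")
  config$conditions <- lapply(config$conditions, function(cond) {
    .checkKeys(cond, .CONDITION_KEYS, "condition")
    if (is.null(cond$construct) || is.null(cond$ion) ||
        is.null(cond$turns) || is.null(cond$nRamps))
      stop("each condition needs construct, ion, turns and nRamps")
    cond
  })
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulate-analyze-report pipeline
#'
#' For every configured (construct, ion, turns) condition: simulate an
#' ensemble of force ramps, profile the extension variance, classify each
#' ramp (single/double/no peak), fit the logistic steepness to each ramp's
#' mean curve, and summarise. Across conditions the pipeline then fits the
#' S0 mixture on the first condition's samples (when >= 30 fits converge),
#' computes the work area between the double-peak and single-peak cohort
#' mean curves of the first condition, and assembles the energy ledger from
#' the ensemble's mean characteristic forces. Per-ramp failures are
#' recorded and do not abort the run.
#'
#' All randomness derives from `config$seed`; with `writeDir` set, the
#' outputs (classifications.tsv, summary.tsv, s0.tsv, report.json,
#' resolved_config.yaml, pipeline.log) are byte-identical across runs with
#' the same config.
#'
#' @param config Run configuration (see [validateRunConfig()]).
#' @param writeDir Optional output directory.
#' @param verbose Log one line per ramp (`FALSE` keeps the log in the
#'   returned object / log file only).
#' @return List with `classifications` (data.frame), `summaries`
#'   (data.frame, one row per condition), `s0` (data.frame), `mixture`,
#'   `ledger` ([G4EnergyLedger] or `NULL`), `workArea`, `failures`, `log`.
#' @export
runPipeline <- function(config, writeDir = NULL, verbose = FALSE) {
  config <- validateRunConfig(config)
  grid <- defaultForceGrid(config$grid$from, config$grid$to, config$grid$by)
  det <- config$detect
  logLines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logLines <<- c(logLines, line)
    if (verbose) message(line)
  }
  cls <- list()
  s0rows <- list()
  sumRows <- list()
  failures <- list()
  firstProfiles <- NULL
  firstLabels <- NULL
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[[ci]]
    cfg <- TetherConfig(construct = cond$construct, ion = cond$ion,
                        pFold = cond$pFold %||% NA_real_)
    prm <- do.call(SimParams, config$sim %||% list())
    ens <- simulateEnsembleProfiles(cond$nRamps, cond$turns, cfg, prm,
                                    window = config$window, forceGrid = grid,
                                    seed = config$seed + ci)
    labels <- character(cond$nRamps)
    for (r in seq_len(cond$nRamps)) {
      pc <- tryCatch(
        detectCharacteristicForces(ens$profiles[[r]],
                                   smoothSd = det$smoothSd,
                                   minProminenceFrac = det$minProminenceFrac,
                                   minSeparation = det$minSeparation),
        error = function(e) e)
      lf <- tryCatch(
        fitLogistic(data.frame(force_pN = grid,
                               ext_mean_nm = ens$profiles[[r]]@meanExtension)),
        error = function(e) e)
      if (inherits(pc, "error")) {
        failures <- c(failures, list(list(condition = ci, ramp = r,
                                          stage = "detect",
                                          message = conditionMessage(pc))))
        labels[r] <- NA_character_
        say("cond %d ramp %d: DETECT FAILED (%s)", ci, r,
            conditionMessage(pc))
        next
      }
      labels[r] <- peakLabel(pc)
      fcs <- characteristicForces(pc)
      cls <- c(cls, list(data.frame(
        condition = ci, construct = cond$construct, ion = cond$ion,
        turns = cond$turns, ramp = r, g4_available = ens$g4Available[r],
        label = peakLabel(pc),
        fC = if (peakLabel(pc) == "single") fcs[["fC"]] else NA_real_,
        fC1 = if (peakLabel(pc) == "double") fcs[["fC1"]] else NA_real_,
        fC2 = if (peakLabel(pc) == "double") fcs[["fC2"]] else NA_real_)))
      if (!inherits(lf, "error") && lf$converged)
        s0rows <- c(s0rows, list(data.frame(
          condition = ci, construct = cond$construct, ion = cond$ion,
          turns = cond$turns, ramp = r, label = peakLabel(pc),
          S0 = lf$S0, F1 = lf$F1)))
      say("cond %d ramp %d: %s%s", ci, r, peakLabel(pc),
          if (length(fcs)) paste0(" [", paste(sprintf("%.2f", fcs),
                                              collapse = ", "), " pN]")
          else "")
    }
    ok <- !is.na(labels)
    summ <- classifyEnsemble(ens$profiles[ok], smoothSd = det$smoothSd,
                             minProminenceFrac = det$minProminenceFrac,
                             minSeparation = det$minSeparation)
    sumRows <- c(sumRows, list(data.frame(
      condition = ci, construct = cond$construct, ion = cond$ion,
      turns = cond$turns, n = summ@n, n_double = summ@nDouble,
      n_single = summ@nSingle, n_none = summ@nNone,
      pct_double = summ@pctDouble, se_pct = summ@sePct,
      fC1_mean = summ@fcStats$mean[summ@fcStats$which == "fC1_double"],
      fC2_mean = summ@fcStats$mean[summ@fcStats$which == "fC2_double"],
      fC_single_mean = summ@fcStats$mean[summ@fcStats$which == "fC_single"])))
    if (ci == 1L) {
      firstProfiles <- ens$profiles
      firstLabels <- labels
    }
  }
  classifications <- do.call(rbind, cls)
  summaries <- do.call(rbind, sumRows)
  s0 <- if (length(s0rows)) do.call(rbind, s0rows) else
    data.frame(condition = integer(0), S0 = numeric(0))
  # mixture on the first condition's S0 samples
  mixture <- NULL
  s0First <- s0$S0[s0$condition == 1L]
  if (length(s0First) >= 30)
    mixture <- tryCatch(selectS0Mixture(s0First), error = function(e) NULL)
  # work area between double- and single-peak cohorts of condition 1
  wa <- NA_real_
  if (!is.null(firstProfiles)) {
    dbl <- which(firstLabels == "double")
    sgl <- which(firstLabels == "single")
    if (length(dbl) >= 3 && length(sgl) >= 3) {
      hi <- ensembleMeanCurve(firstProfiles[dbl])
      lo <- ensembleMeanCurve(firstProfiles[sgl])
      wa <- suppressWarnings(as.numeric(workArea(hi, lo)))
    }
  }
  # ledger from the ensemble's mean characteristic forces
  ledger <- NULL
  f1 <- summaries$fC1_mean[1]
  f2 <- summaries$fC2_mean[1]
  if (is.finite(f1) && is.finite(f2))
    ledger <- energyLedger(fC1 = f1, fC2 = f2, eDuplex = config$eDuplex,
                           perG4Gain = config$perG4Gain, workArea = wa)
  out <- list(classifications = classifications, summaries = summaries,
              s0 = s0, mixture = mixture, ledger = ledger, workArea = wa,
              failures = failures, log = logLines, config = config)
  if (!is.null(writeDir)) .writePipelineReport(out, writeDir)
  out
}

.writePipelineReport <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wtsv(res$classifications, "classifications.tsv")
  wtsv(res$summaries, "summary.tsv")
  wtsv(res$s0, "s0.tsv")
  report <- list(
    summaries = res$summaries,
    mixture = if (!is.null(res$mixture)) list(
      k = res$mixture$k,
      k2_weights = if (!is.null(res$mixture$k2)) res$mixture$k2$weights,
      k2_means = if (!is.null(res$mixture$k2)) res$mixture$k2$means,
      bic_k1 = res$mixture$k1$bic,
      bic_k2 = if (!is.null(res$mixture$k2)) res$mixture$k2$bic),
    work_area_kcalmol = res$workArea,
    ledger = if (!is.null(res$ledger)) list(
      fC1 = res$ledger@fC1, fC2 = res$ledger@fC2, ratio = res$ledger@ratio,
      e_duplex = res$ledger@eDuplex, e_g4_path = res$ledger@eG4Path,
      net_gain = res$ledger@netGain),
    n_failures = length(res$failures),
    seed = res$config$seed)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", na = "null")
  yaml::write_yaml(res$config, file.path(dir, "resolved_config.yaml"),
                   precision = 12)
  writeLines(res$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}
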