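#' @include AllClasses.R
NULL

# Plain-text exchange formats: traces as headered TSV, ramps as a directory
# with a YAML manifest, mean curves as TSV. All formats round-trip.

.TRACE_HEADER_KEYS <- c("force_pN", "turns", "construct", "ion", "seed")

#' Write a trace to a tab-separated text file
#'
#' Format: comment header lines `# key=value` (force_pN, turns, construct,
#' ion, seed), a column header, then `time_s  extension_nm` rows.
#'
#' @param trace A [Trace].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "Trace"))
  meta <- trace@meta
  cfg <- meta$config
  hdr <- c(
    sprintf("# force_pN=%.*g", 15, trace@force),
    sprintf("# turns=%g", trace@turns),
    sprintf("# construct=%s", if (!is.null(cfg)) cfg@construct else "NA"),
    sprintf("# ion=%s", if (!is.null(cfg)) cfg@ion else "NA"),
    sprintf("# seed=%s", if (!is.null(meta$seed)) meta$seed else "NA"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s\textension_nm", con)
  # 17 significant digits so numeric arrays round-trip exactly
  utils::write.table(
    data.frame(time_s = sprintf("%.17g", trace@time),
               extension_nm = sprintf("%.17g", trace@extension)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trace written by [writeTrace()]
#'
#' @param path File path.
#' @return A [Trace] (metadata restored into the `meta` list).
#' @export
readTrace <- function(path) {
  lines <- readLines(path)
  hdrIdx <- grep("^#", lines)
  hdr <- lines[hdrIdx]
  kv <- regmatches(hdr, regexec("^#\\s*([^=]+)=(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3) trimws(m[2]) else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3) trimws(m[3]) else NA_character_,
                 character(1))
  meta <- stats::setNames(as.list(vals), keys)
  missing <- setdiff(c("force_pN", "turns", "construct", "ion"), keys)
  if (length(missing))
    stop("trace header incomplete, missing: ", paste(missing, collapse = ", "))
  body <- lines[-c(hdrIdx, hdrIdx[length(hdrIdx)] + 1L)]  # drop column header
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 2L)
  if (length(bad))
    stop(sprintf("malformed trace row at line %d of %s",
                 bad[1] + length(hdrIdx) + 1L, path))
  tm <- as.numeric(vapply(fields, `[`, character(1), 1L))
  ex <- as.numeric(vapply(fields, `[`, character(1), 2L))
  if (anyNA(tm) || anyNA(ex)) {
    bad <- which(is.na(tm) | is.na(ex))[1]
    stop(sprintf("non-numeric trace row at line %d of %s",
                 bad + length(hdrIdx) + 1L, path))
  }
  new("Trace", force = as.numeric(meta$force_pN),
      turns = as.numeric(meta$turns), time = tm, extension = ex,
      meta = list(construct = meta$construct, ion = meta$ion,
                  seed = suppressWarnings(as.integer(meta$seed))))
}

#' Write a force ramp as a directory with a manifest
#'
#' One trace file per grid force plus `manifest.yaml` recording turns,
#' construct, ion, G4 availability, the force grid and the file list.
#'
#' @param ramp A [ForceRamp].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRamp <- function(ramp, dir) {
  stopifnot(is(ramp, "ForceRamp"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("trace_%04d.tsv", seq_along(ramp@traces))
  for (i in seq_along(ramp@traces)) {
    tr <- ramp@traces[[i]]
    tr@meta$config <- ramp@config
    writeTrace(tr, file.path(dir, files[i]))
  }
  manifest <- list(turns = ramp@turns, construct = ramp@config@construct,
                   ion = ramp@config@ion, g4_available = ramp@g4Available,
                   force_grid = as.numeric(ramp@forceGrid), files = files)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"),
                   precision = 12)
  invisible(dir)
}

#' Read a force ramp directory written by [writeRamp()]
#'
#' @param dir Ramp directory containing `manifest.yaml`.
#' @param cfg Optional [TetherConfig] to attach (defaults to one built from
#'   the manifest's construct/ion).
#' @param prm Optional [SimParams] to attach.
#' @return A [ForceRamp].
#' @export
readRamp <- function(dir, cfg = NULL, prm = SimParams()) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop("no manifest.yaml in ", dir)
  manifest <- yaml::read_yaml(mf)
  if (is.null(cfg))
    cfg <- TetherConfig(construct = manifest$construct, ion = manifest$ion)
  trs <- lapply(manifest$files, function(f) readTrace(file.path(dir, f)))
  new("ForceRamp", traces = trs,
      forceGrid = as.numeric(manifest$force_grid),
      turns = as.numeric(manifest$turns),
      g4Available = isTRUE(manifest$g4_available), config = cfg, params = prm)
}

#' Write / read a mean force-extension curve as TSV
#'
#' Columns `force_pN`, `ext_mean_nm`, `ext_sd_nm`, `n`.
#'
#' @param curve Mean-curve data.frame.
#' @param path File path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeMeanCurve <- function(curve, path) {
  .checkMeanCurve(curve)
  utils::write.table(curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeanCurve
#' @export
readMeanCurve <- function(path) {
  curve <- utils::read.table(path, header = TRUE, sep = "\t")
  .checkMeanCurve(curve)
  curve
}
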