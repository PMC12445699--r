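#' Write a trace to a columnar text file
#'
#' Plain-text serialization of a trace: `#`-prefixed `key=value` header
#' lines (molecule id, cycle, preset, sampling rate, schema version,
#' optional constant force) followed by a tab-separated table with
#' columns `time_s`, `magnet_mm`, `force_pN`, `ext_nm`. Numeric values
#' are written at full precision (17 significant digits) so the
#' write-read round trip is lossless to better than 1e-9 relative.
#'
#' @param trace An `mt_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  m <- trace$meta
  hdr <- c(
    paste0("# schema_version=", m$schema_version),
    paste0("# molecule_id=", m$molecule_id),
    paste0("# cycle=", m$cycle),
    paste0("# preset=", m$preset),
    paste0("# trace_rate=", format(m$trace_rate, digits = 17)),
    if (!is.null(m$constant_force))
      paste0("# constant_force=", format(m$constant_force, digits = 17))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(trace$data), collapse = "\t"), con)
  d <- trace$data
  lines <- do.call(paste, c(lapply(d, function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- "NA"
    out
  }), list(sep = "\t")))
  writeLines(lines, con)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' The schema version is checked; malformed rows are reported with their
#' line number.
#'
#' @param path Input path.
#' @return An `mt_trace`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^# *", "", lines[is_hdr])
  kv <- strsplit(hdr, "=", fixed = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(p) paste(p[-1], collapse = "=")),
    vapply(kv, `[[`, "", 1))
  if (is.null(meta$schema_version))
    stop("missing schema_version header in ", path)
  if (meta$schema_version != "1.0")
    stop("schema version mismatch: file has '", meta$schema_version,
         "', reader supports '1.0'")
  body <- lines[!is_hdr]
  if (length(body) < 2) stop("truncated trace file: no data rows in ", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nc <- length(cols)
  bad <- which(vapply(rows, length, 0L) != nc)
  if (length(bad) > 0)
    stop("malformed row at line ",
         which(!is_hdr)[1 + bad[1]], " of ", path)
  vals <- trimws(unlist(rows))
  mat <- matrix(suppressWarnings(as.numeric(vals)), ncol = nc,
                byrow = TRUE)
  nn <- which(is.na(mat) & !matrix(vals == "NA", ncol = nc,
                                   byrow = TRUE), arr.ind = TRUE)
  if (nrow(nn) > 0)
    stop("non-numeric value at line ", which(!is_hdr)[1 + nn[1, 1]],
         " of ", path)
  d <- as.data.frame(mat)
  colnames(d) <- cols
  tm <- d$time_s
  if (is.unsorted(tm, strictly = TRUE))
    stop("time column must be strictly increasing in ", path)
  meta_out <- list(
    molecule_id = meta$molecule_id,
    cycle = as.integer(meta$cycle),
    preset = meta$preset,
    trace_rate = as.numeric(meta$trace_rate),
    schema_version = meta$schema_version)
  if (!is.null(meta$constant_force))
    meta_out$constant_force <- as.numeric(meta$constant_force)
  structure(list(data = d, meta = meta_out), class = "mt_trace")
}

#' Write a trace set to a directory
#'
#' One trace file per molecule-cycle, a `manifest.tsv` listing them, and
#' a `truth.tsv` sidecar with ground-truth events when present. The
#' directory is written atomically: content goes to a temporary sibling
#' directory that is renamed into place on success, so a partial trace
#' set is never left behind.
#'
#' @param traceset An `mt_traceset`.
#' @param dir Output directory (must not exist or be empty).
#' @return `dir`, invisibly.
#' @export
write_traceset <- function(traceset, dir) {
  if (dir.exists(dir) && length(list.files(dir)) > 0)
    stop("refusing to write into non-empty directory ", dir)
  tmp <- paste0(dir, ".tmp-", Sys.getpid())
  dir.create(tmp, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  rows <- lapply(traceset$traces, function(tr) {
    fn <- sprintf("%s_cycle%d.tsv", tr$meta$molecule_id, tr$meta$cycle)
    write_trace(tr, file.path(tmp, fn))
    data.frame(filename = fn, molecule_id = tr$meta$molecule_id,
               cycle = tr$meta$cycle, preset = tr$meta$preset,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  truth_path <- if (!is.null(traceset$truth) && nrow(traceset$truth) > 0) {
    utils::write.table(traceset$truth, file.path(tmp, "truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    "truth.tsv"
  } else NA_character_
  manifest$truth <- truth_path
  utils::write.table(manifest, file.path(tmp, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (dir.exists(dir)) unlink(dir, recursive = TRUE)
  if (!file.rename(tmp, dir))
    stop("could not finalize trace set directory ", dir)
  ok <- TRUE
  invisible(dir)
}

#' Read a trace set directory
#'
#' @param dir Directory written by [write_traceset()].
#' @return An `mt_traceset`.
#' @export
read_traceset <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv in ", dir)
  manifest <- utils::read.table(mf, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  missing <- !file.exists(file.path(dir, manifest$filename))
  if (any(missing))
    stop("manifest lists missing file(s): ",
         paste(manifest$filename[missing], collapse = ", "))
  traces <- lapply(file.path(dir, manifest$filename), read_trace)
  truth <- NULL
  tp <- file.path(dir, "truth.tsv")
  if (file.exists(tp))
    truth <- utils::read.table(tp, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  ids <- unique(manifest$molecule_id)
  structure(
    list(traces = traces, truth = truth,
         meta = list(preset = manifest$preset[1],
                     n_molecules = length(ids),
                     n_cycles = max(manifest$cycle),
                     trace_rate = traces[[1]]$meta$trace_rate,
                     schema_version = traces[[1]]$meta$schema_version)),
    class = "mt_traceset"
  )
}

config_builders <- function() {
  list(mechanics = polymer_params, geometry = tether_geometry,
       instrument = magnet_map, bead = bead_params,
       acquisition = acquisition_config, protocol = protocol_config,
       analysis = analysis_config)
}

#' Load and validate a configuration file
#'
#' YAML configuration with sections `mechanics`, `geometry`,
#' `instrument`, `bead`, `acquisition`, `protocol` and `analysis`
#' mirroring the package constructors; every field defaults to the
#' constructor default, unknown sections or keys are rejected, and all
#' constructor invariants are enforced at load time. An empty file
#' yields the full defaults. A `presets` section may override preset
#' fields (`target_mean`, `target_sd`, `p_maintain`,
#' `assembled_fraction`) per transition of a named registry preset.
#'
#' @param path Path to a YAML file; `NULL` gives defaults.
#' @return Named list of validated configuration objects plus `presets`
#'   (the possibly overridden registry).
#' @examples
#' cfg <- load_config(system.file("extdata", "example_config.yml",
#'                                package = "nucpull"))
#' cfg$protocol$n_cycles
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  builders <- config_builders()
  known <- c(names(builders), "presets")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  out <- lapply(names(builders), function(sec) {
    args <- raw[[sec]]
    if (is.null(args)) args <- list()
    fn <- builders[[sec]]
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad) > 0)
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    do.call(fn, args)
  })
  names(out) <- names(builders)
  presets <- preset_registry()
  if (!is.null(raw$presets)) {
    for (pn in names(raw$presets)) {
      if (!pn %in% names(presets))
        stop("unknown preset '", pn, "' in config; available: ",
             paste(names(presets), collapse = ", "))
      ov <- raw$presets[[pn]]
      p <- presets[[pn]]
      allowed <- c("p_maintain", "assembled_fraction", "transitions")
      bad <- setdiff(names(ov), allowed)
      if (length(bad) > 0)
        stop("unknown key(s) in preset override '", pn, "': ",
             paste(bad, collapse = ", "))
      if (!is.null(ov$p_maintain)) p$p_maintain <- ov$p_maintain
      if (!is.null(ov$assembled_fraction))
        p$assembled_fraction <- ov$assembled_fraction
      if (!is.null(ov$transitions)) {
        for (i in seq_along(ov$transitions)) {
          tv <- ov$transitions[[i]]
          bad <- setdiff(names(tv), c("target_mean", "target_sd", "dx"))
          if (length(bad) > 0)
            stop("unknown transition key(s) in preset override '", pn,
                 "': ", paste(bad, collapse = ", "))
          p$transitions[[i]][names(tv)] <- tv
        }
      }
      # re-validate invariants through the constructor
      presets[[pn]] <- condition_preset(p$name, p$transitions,
                                        p$p_maintain,
                                        p$assembled_fraction,
                                        p$sequential)
    }
  }
  out$presets <- presets
  out
}
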