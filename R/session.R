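# Session file format: a directory holding a YAML manifest plus one
# delimited-text table per channel. Delimited-text-first storage keeps
# fixtures reviewable; timestamps are seconds from session start.

.SESSION_FORMAT_VERSION <- "1.0"

#' Write a session directory
#'
#' Writes `manifest.yaml` (session id, kind, seed, protocol parameters,
#' format version, and a channel registry mapping each channel to its
#' file, units and cadence) plus one CSV per channel. Every value column
#' must have declared units, channel names must be unique, and
#' timestamps must be strictly increasing within a channel; round trips
#' through [read_session()] are value-exact.
#'
#' @param dir directory to create (must not already contain a manifest).
#' @param manifest list with at least `session_id` and `kind`; `seed`,
#'   `created` and `protocol` are carried through.
#' @param channels named list; each element a list with `data` (a
#'   data.frame whose first column is `timestamp` in seconds), `units`
#'   (named character covering every column), and optional `cadence`.
#' @return `dir`, invisibly.
#' @export
write_session <- function(dir, manifest, channels) {
  stopifnot(is.list(manifest), !is.null(manifest$session_id),
            !is.null(manifest$kind))
  if (anyDuplicated(names(channels))) {
    stop("duplicate channel names", call. = FALSE)
  }
  if (is.null(names(channels)) || any(names(channels) == "")) {
    stop("channels must be named", call. = FALSE)
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (is.null(ch$data) || !is.data.frame(ch$data)) {
      stop(sprintf("channel '%s' has no data table", nm), call. = FALSE)
    }
    covered <- names(ch$data) %in% names(ch$units) |
      (grepl("^bin_[0-9]+$", names(ch$data)) & "bins" %in% names(ch$units))
    missing_units <- names(ch$data)[!covered]
    if (length(missing_units)) {
      stop(sprintf("channel '%s' lacks units for: %s", nm,
                   paste(missing_units, collapse = ", ")), call. = FALSE)
    }
    ts <- ch$data$timestamp
    if (!is.null(ts) && length(ts) > 1 && any(diff(ts) <= 0)) {
      stop(sprintf("channel '%s': timestamps not strictly increasing", nm),
           call. = FALSE)
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  registry <- lapply(names(channels), function(nm) {
    ch <- channels[[nm]]
    list(file = paste0(nm, ".csv"),
         units = as.list(ch$units),
         cadence = if (is.null(ch$cadence) || is.na(ch$cadence)) NULL
                   else ch$cadence)
  })
  names(registry) <- names(channels)
  man <- list(format_version = .SESSION_FORMAT_VERSION,
              session_id = manifest$session_id, kind = manifest$kind,
              seed = manifest$seed, created = manifest$created,
              protocol = manifest$protocol, channels = registry)
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"), precision = 15)
  for (nm in names(channels)) {
    utils::write.csv(channels[[nm]]$data,
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a session directory
#'
#' Parses the manifest, rejects newer major format versions, loads every
#' registered channel table (erroring with the file name and row on a
#' corrupted table), and warns about unregistered files found on disk.
#'
#' @param dir session directory.
#' @return list with `manifest` and `channels` (named list of
#'   data.frames, each carrying a `units` attribute).
#' @export
read_session <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) {
    stop(sprintf("no manifest in '%s'", dir), call. = FALSE)
  }
  man <- yaml::read_yaml(mf)
  major <- as.integer(strsplit(as.character(man$format_version),
                               ".", fixed = TRUE)[[1]][1])
  if (is.na(major) || major >
      as.integer(strsplit(.SESSION_FORMAT_VERSION, ".",
                          fixed = TRUE)[[1]][1])) {
    stop(sprintf("session format version %s is newer than this reader",
                 man$format_version), call. = FALSE)
  }
  channels <- list()
  for (nm in names(man$channels)) {
    reg <- man$channels[[nm]]
    path <- file.path(dir, reg$file)
    if (!file.exists(path)) {
      stop(sprintf("registered channel file missing: %s", reg$file),
           call. = FALSE)
    }
    tab <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE),
      error = function(e) stop(sprintf("corrupted table '%s': %s",
                                       reg$file, conditionMessage(e)),
                               call. = FALSE),
      warning = function(w) stop(sprintf("corrupted table '%s': %s",
                                         reg$file, conditionMessage(w)),
                                 call. = FALSE))
    expected <- setdiff(names(reg$units), "bins")
    if (!all(expected %in% names(tab))) {
      stop(sprintf("corrupted table '%s': missing columns", reg$file),
           call. = FALSE)
    }
    numeric_cols <- names(tab)[vapply(tab, is.numeric, TRUE)]
    bad <- which(!stats::complete.cases(tab[numeric_cols]))
    if (length(bad)) {
      stop(sprintf("corrupted table '%s' at row %d", reg$file, bad[1]),
           call. = FALSE)
    }
    attr(tab, "units") <- unlist(reg$units)
    channels[[nm]] <- tab
  }
  on_disk <- setdiff(list.files(dir), "manifest.yaml")
  extra <- setdiff(on_disk,
                   vapply(man$channels, `[[`, "", "file"))
  if (length(extra)) {
    warning(sprintf("unregistered file(s) in session: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  list(manifest = man, channels = channels)
}

#' Rebuild DTOF/IRF objects from a phantom session
#'
#' Convenience accessor turning the wide `dtof_<wavelength>` and
#' `irf_<wavelength>` channel tables of a phantom or IRF session back
#' into `dtof_histogram` / `irf_record` objects on the session's time
#' grid.
#'
#' @param session result of [read_session()].
#' @param wavelength 685 or 828.
#' @param spec [forward_model_spec()] matching the simulation grid.
#' @return list with `irf` and `dtofs` (possibly empty list).
#' @export
session_histograms <- function(session, wavelength,
                               spec = forward_model_spec()) {
  getbins <- function(row) {
    as.numeric(row[grep("^bin_", names(row))])
  }
  irf_tab <- session$channels[[paste0("irf_", wavelength)]]
  irf <- if (!is.null(irf_tab)) {
    new_irf_record(spec$time_edges, getbins(irf_tab[1, ]), wavelength)
  }
  dt_tab <- session$channels[[paste0("dtof_", wavelength)]]
  dtofs <- if (!is.null(dt_tab)) {
    lapply(seq_len(nrow(dt_tab)), function(i) {
      new_dtof_histogram(spec$time_edges, getbins(dt_tab[i, ]),
                         wavelength, timestamp = dt_tab$timestamp[i])
    })
  } else list()
  list(irf = irf, dtofs = dtofs)
}
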