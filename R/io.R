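# Readers/writers: study manifest, time-series TSV (plain and gzipped with
# JSON sidecar, BIDS physiological-recording dialect), study directories,
# and results tables.

#' Read a study manifest
#'
#' Tab-separated manifest with columns `run_id`, `session_date` (ISO-8601),
#' `egg_path`, `rsn_path`, `included`, `exclusion_reason`. Dates are parsed
#' strictly; duplicate run ids, malformed dates, and excluded runs without a
#' reason are schema errors naming the offending record.
#'
#' @param path manifest file path.
#' @param check_paths verify that linked files exist (default TRUE).
#' @return manifest data.frame (dates as `Date`).
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("read_manifest: no such file: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("run_id", "session_date", "egg_path", "rsn_path", "included",
           "exclusion_reason")
  if (!all(req %in% names(m))) {
    stop("read_manifest: missing columns: ",
         paste(setdiff(req, names(m)), collapse = ", "))
  }
  if (anyDuplicated(m$run_id)) {
    stop("read_manifest: duplicated run_id: ",
         paste(unique(m$run_id[duplicated(m$run_id)]), collapse = ", "))
  }
  dates <- as.Date(m$session_date, format = "%Y-%m-%d")
  bad <- is.na(dates) | format(dates, "%Y-%m-%d") != m$session_date
  if (any(bad)) {
    stop("read_manifest: malformed session_date for run ",
         paste(m$run_id[bad], collapse = ", "))
  }
  m$session_date <- dates
  m$included <- as.logical(m$included)
  if (any(is.na(m$included))) stop("read_manifest: included must be TRUE/FALSE")
  noreason <- !m$included & (is.na(m$exclusion_reason) | m$exclusion_reason == "")
  if (any(noreason)) {
    stop("read_manifest: excluded run without a reason: ",
         paste(m$run_id[noreason], collapse = ", "))
  }
  m$exclusion_reason[is.na(m$exclusion_reason)] <- ""
  if (check_paths) {
    base <- dirname(path)
    for (col in c("egg_path", "rsn_path")) {
      p <- ifelse(file.exists(m[[col]]), m[[col]], file.path(base, m[[col]]))
      missing <- !file.exists(p)
      if (any(missing)) {
        stop("read_manifest: unresolvable ", col, " for run ",
             paste(m$run_id[missing], collapse = ", "))
      }
    }
  }
  m
}

#' Write a study manifest
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest
  m$session_date <- format(as.Date(m$session_date), "%Y-%m-%d")
  if (!"egg_path" %in% names(m)) m$egg_path <- ""
  if (!"rsn_path" %in% names(m)) m$rsn_path <- ""
  cols <- c("run_id", "session_date", "egg_path", "rsn_path", "included",
            "exclusion_reason")
  utils::write.table(m[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a time-series file
#'
#' Plain TSV with a header row, or gzipped TSV with a JSON sidecar carrying
#' `SamplingFrequency`, `StartTime`, and `Columns` (the BIDS physiological
#' recording dialect). The sampling rate must come from the sidecar or the
#' `rate` argument; it is never guessed.
#'
#' @param path `.tsv` or `.tsv.gz` file.
#' @param rate sampling rate in Hz; required for plain TSV without sidecar.
#' @param sidecar JSON sidecar path (default: `path` with `.tsv[.gz]`
#'   replaced by `.json`, used if it exists).
#' @return list with `values` (time-by-column matrix), `rate`, `labels`.
#' @export
read_timeseries <- function(path, rate = NULL, sidecar = NULL) {
  if (!file.exists(path)) stop("read_timeseries: no such file: ", path)
  if (is.null(sidecar)) {
    sidecar <- sub("\\.tsv(\\.gz)?$", ".json", path)
  }
  labels <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$SamplingFrequency)) rate <- meta$SamplingFrequency
    if (!is.null(meta$Columns)) labels <- meta$Columns
  }
  if (is.null(rate)) {
    stop("read_timeseries: sampling rate missing (no sidecar and no rate ",
         "argument); refusing to guess")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  has_header <- is.null(labels)
  tab <- utils::read.table(con, header = has_header, sep = "\t")
  values <- as.matrix(tab)
  if (has_header) labels <- colnames(tab) else colnames(values) <- labels
  list(values = values, rate = rate, labels = labels)
}

#' Write a time-series file
#'
#' Values are written with 15 significant digits so a write-read round trip
#' preserves them to better than 1e-9. A `.tsv.gz` path also writes the
#' JSON sidecar (`SamplingFrequency`, `StartTime`, `Columns`) and omits the
#' header row, per the BIDS physiological-recording dialect; a plain `.tsv`
#' gets a header row.
#'
#' @param values numeric matrix (time in rows) or vector.
#' @param path output `.tsv` or `.tsv.gz` path.
#' @param rate sampling rate in Hz (required for `.tsv.gz`).
#' @param labels column labels (default from `colnames`).
#' @param start_time recording start time in seconds (sidecar only).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(values, path, rate = NULL, labels = NULL,
                             start_time = 0) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  if (is.null(labels)) {
    labels <- colnames(values)
    if (is.null(labels)) labels <- sprintf("col%02d", seq_len(ncol(values)))
  }
  txt <- apply(values, 2L, function(col) formatC(col, digits = 15, format = "g"))
  if (is.null(dim(txt))) txt <- matrix(txt, ncol = ncol(values))
  gz <- grepl("\\.gz$", path)
  if (gz) {
    if (is.null(rate)) stop("write_timeseries: rate required for .tsv.gz output")
    con <- gzfile(path, "w")
    utils::write.table(txt, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    sidecar <- sub("\\.tsv\\.gz$", ".json", path)
    jsonlite::write_json(
      list(SamplingFrequency = rate, StartTime = start_time,
           Columns = as.list(labels)),
      sidecar, auto_unbox = TRUE, pretty = TRUE)
  } else {
    colnames(txt) <- labels
    utils::write.table(txt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Write a synthetic study to a directory
#'
#' Creates `manifest.tsv`, per-run raw EGG (`<run>_physio.tsv.gz` +
#' `<run>_physio.json`), RSN time courses (`<run>_rsn.tsv`), and ground
#' truth (`<run>_truth.json`).
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- bundle$manifest
  m$egg_path <- sprintf("%s_physio.tsv.gz", m$run_id)
  m$rsn_path <- sprintf("%s_rsn.tsv", m$run_id)
  for (id in m$run_id) {
    run <- bundle$runs[[id]]
    write_timeseries(run$egg$samples, file.path(dir, sprintf("%s_physio.tsv.gz", id)),
                     rate = run$egg$rate,
                     labels = sprintf("egg%d", seq_len(ncol(run$egg$samples))))
    write_timeseries(run$rsn$values, file.path(dir, sprintf("%s_rsn.tsv", id)))
    jsonlite::write_json(
      list(base_frequency = run$truth$base_frequency,
           mean_frequency = run$truth$mean_frequency,
           phase_bold = run$truth$phase_bold,
           coupling = run$truth$coupling),
      file.path(dir, sprintf("%s_truth.json", id)),
      auto_unbox = TRUE, digits = NA)
  }
  write_manifest(m, file.path(dir, "manifest.tsv"))
  jsonlite::write_json(unclass(bundle$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir study directory.
#' @param bold_rate RSN sampling rate in Hz (default 0.5; RSN TSVs carry no
#'   sidecar).
#' @return list with `manifest`, `egg` (named list of [egg_recording()]),
#'   `rsn` (named list of `rsn_set`), and `truth` (named list or NULL).
#' @export
read_study <- function(dir, bold_rate = 0.5) {
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  egg <- list()
  rsn <- list()
  truth <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$run_id[i]
    e <- read_timeseries(file.path(dir, manifest$egg_path[i]))
    egg[[id]] <- egg_recording(e$values, e$rate, id, manifest$session_date[i])
    r <- read_timeseries(file.path(dir, manifest$rsn_path[i]), rate = bold_rate)
    rsn[[id]] <- structure(list(values = r$values, rate = bold_rate,
                                labels = r$labels, run_id = id),
                           class = "rsn_set")
    tp <- file.path(dir, sprintf("%s_truth.json", id))
    if (file.exists(tp)) truth[[id]] <- jsonlite::read_json(tp, simplifyVector = TRUE)
  }
  list(manifest = manifest, egg = egg, rsn = rsn,
       truth = if (length(truth)) truth else NULL)
}

#' Reported per-network synchronization table of a densely sampled subject
#'
#' Ships the published per-network results of a highly sampled
#' single-subject concurrent EGG-fMRI study (19 sessions, two 15-minute
#' runs each): matched and mismatched PLV means and standard deviations,
#' uncorrected and FDR-adjusted p-values, and the fractional gastric
#' variance of each of the 18 networks. Useful as reference input for the
#' multiple-testing routines and as a magnitude benchmark for simulations.
#'
#' @return data.frame with one row per network.
#' @export
example_sync_table <- function() {
  utils::read.delim(system.file("extdata", "single_subject_sync_table.tsv",
                                package = "gastrosync"),
                    stringsAsFactors = FALSE)
}

#' Write the per-network results table
#'
#' @param analysis a `sync_analysis` from [run_full_analysis()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(analysis, path) {
  stopifnot(inherits(analysis, "sync_analysis"))
  tab <- analysis$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(col) formatC(col, digits = 6, format = "g"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
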