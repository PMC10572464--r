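# Delimited-text readers and writers. Every writer has a reader and
# write o read o write is idempotent; numbers are serialized at full
# precision (%.17g) so round-trips are exact.

write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(apply(m, 2, function(col) sprintf("%.17g", col)),
                      stringsAsFactors = FALSE)
  names(df) <- colnames(m)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  m <- vapply(df, as.numeric, numeric(nrow(df)))
  if (nrow(df) == 1) m <- matrix(m, 1, dimnames = list(NULL, names(df)))
  colnames(m) <- names(df)
  m
}

#' Write / read an ROI time series as tab-delimited text
#'
#' Header row = ROI labels; one row per timepoint.
#'
#' @param timeseries a [roi_timeseries()].
#' @param path file path.
#' @return `path` invisibly (writer); a `roi_timeseries` (reader).
#' @export
write_timeseries <- function(timeseries, path) {
  stopifnot(inherits(timeseries, "roi_timeseries"))
  write_matrix_tsv(timeseries$data, path)
}

#' @rdname write_timeseries
#' @param subject_id subject id for the reader (default: file base name).
#' @param tr_seconds repetition time for the reader.
#' @export
read_timeseries <- function(path, subject_id = NULL, tr_seconds = 3) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]+$", "", basename(path))
  m <- read_matrix_tsv(path)
  roi_timeseries(subject_id, m, colnames(m), tr_seconds)
}

#' Write / read a connectivity matrix as tab-delimited text
#'
#' Two square files (header = ROI labels): one for Pearson r, one for
#' Fisher z.
#'
#' @param conn a `connectivity_matrix` (with `z`).
#' @param path_r,path_z file paths for the r and z matrices.
#' @return paths invisibly (writer); a `connectivity_matrix` (reader).
#' @export
write_connectivity <- function(conn, path_r, path_z) {
  stopifnot(inherits(conn, "connectivity_matrix"), !is.null(conn$z))
  write_matrix_tsv(conn$r, path_r)
  write_matrix_tsv(conn$z, path_z)
  invisible(c(path_r, path_z))
}

#' @rdname write_connectivity
#' @param subject_id subject id for the reader.
#' @param n_timepoints_used timepoint count to record.
#' @export
read_connectivity <- function(path_r, path_z, subject_id = NULL,
                              n_timepoints_used = NA_integer_) {
  if (is.null(subject_id))
    subject_id <- sub("_r$", "", sub("\\.[^.]+$", "", basename(path_r)))
  r <- read_matrix_tsv(path_r)
  z <- read_matrix_tsv(path_z)
  labs <- colnames(r)
  rownames(r) <- colnames(r)
  rownames(z) <- colnames(z)
  structure(list(subject_id = subject_id, r = r, z = z, roi_labels = labs,
                 n_timepoints_used = n_timepoints_used),
            class = "connectivity_matrix")
}

#' Write / read a subject table as tab-delimited text
#'
#' Columns: `subject_id`, `group`, `cdr`, `mmse`.
#'
#' @param design a [study_design()].
#' @param path file path.
#' @param seed seed to record when reading back (default 1).
#' @return `path` invisibly (writer); a `study_design` (reader).
#' @export
write_subject_table <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  df <- data.frame(subject_id = design$subject_ids,
                   group = unname(design$group_of[design$subject_ids]),
                   cdr = sprintf("%.17g", design$cdr[design$subject_ids]),
                   mmse = sprintf("%.17g", design$mmse[design$subject_ids]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path, seed = 1L) {
  if (!file.exists(path)) stopf("subject table not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  study_design(df$subject_id,
               stats::setNames(df$group, df$subject_id),
               cdr = if ("cdr" %in% names(df))
                 stats::setNames(as.numeric(df$cdr), df$subject_id),
               mmse = if ("mmse" %in% names(df))
                 stats::setNames(as.numeric(df$mmse), df$subject_id),
               seed = seed)
}

#' Write / read nuisance traces as tab-delimited text
#'
#' Columns `fd` (framewise displacement, mm) and `global_signal`.
#'
#' @param nuisance data.frame with columns `fd`, `global_signal`.
#' @param path file path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_nuisance <- function(nuisance, path) {
  df <- data.frame(fd = sprintf("%.17g", nuisance$fd),
                   global_signal = sprintf("%.17g", nuisance$global_signal))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nuisance
#' @export
read_nuisance <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  data.frame(fd = as.numeric(df$fd), global_signal = as.numeric(df$global_signal))
}

#' Write / read a simulation scenario as JSON
#'
#' @param scenario a [simulation_scenario()].
#' @param path file path.
#' @return `path` invisibly (writer); a `simulation_scenario` (reader).
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  x <- unclass(scenario)
  x$n_per_group <- as.list(x$n_per_group)  # keep group names in JSON
  jsonlite::write_json(x, path, pretty = TRUE,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stopf("scenario file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pe <- x$planted_edges
  if (!is.null(pe) && (is.data.frame(pe) && nrow(pe) == 0)) pe <- NULL
  simulation_scenario(
    n_per_group = unlist(x$n_per_group),
    n_timepoints = x$n_timepoints, tr_seconds = x$tr_seconds,
    within_network_loading = x$within_network_loading,
    ar1_coefficient = x$ar1_coefficient,
    planted_edges = pe,
    affected_group = x$affected_group,
    cdr_model = as.list(x$cdr_model), mmse_model = as.list(x$mmse_model),
    cdr_realistic = isTRUE(x$cdr_realistic),
    spike_fraction = x$spike_fraction, seed = x$seed)
}

#' Write an edge-stat map with its JSON sidecar
#'
#' The matrix goes to `<path>.tsv`, the metadata (contrast, stat kind,
#' df) to `<path>.json`.
#'
#' @param stat_map an `edge_stat_map`.
#' @param path path stem (without extension).
#' @return the two paths, invisibly.
#' @export
write_stat_map <- function(stat_map, path) {
  stopifnot(inherits(stat_map, "edge_stat_map"))
  write_matrix_tsv(stat_map$stat, paste0(path, ".tsv"))
  jsonlite::write_json(list(stat_kind = stat_map$stat_kind, df = stat_map$df,
                            contrast = stat_map$contrast),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, c(".tsv", ".json")))
}

#' @rdname write_stat_map
#' @export
read_stat_map <- function(path) {
  m <- read_matrix_tsv(paste0(path, ".tsv"))
  rownames(m) <- colnames(m)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(stat = m, stat_kind = meta$stat_kind, df = meta$df,
                 contrast = meta$contrast, roi_labels = colnames(m)),
            class = "edge_stat_map")
}
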