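#' @section Kinetic CSV dialect:
#' One file per plate run. Leading metadata lines are \code{key,value} pairs
#' (project, species, strain, plate, replicate, temperature), followed by a
#' header row whose first column is \code{Time(min)} (or \code{Hour}) and
#' whose remaining 96 columns are the well identifiers A01..H12, then one row
#' per time point. Times are stored in minutes internally; an \code{Hour}
#' column is converted on read.
#' @name kinetic-csv
#' @keywords internal
NULL

KINETIC_META_KEYS <- c("project", "species", "strain", "plate", "replicate",
                       "temperature")

fmt_full <- function(x) {
  # full-precision decimal rendering that survives as.numeric round trips
  out <- character(length(x))
  na <- is.na(x)
  out[na] <- "NA"
  if (any(!na)) {
    v <- x[!na]
    s17 <- sprintf("%.17g", v)
    s15 <- sprintf("%.15g", v)
    out[!na] <- ifelse(as.numeric(s15) == v, s15, s17)
  }
  out
}

#' Parse an OmniLog-style kinetic CSV export
#'
#' Reads one plate run (96 well columns) into a \code{\link{record_set}} of
#' 96 \code{\link{well_record}}s, one per well, each carrying the full time
#' series. Metadata come from the file's header lines and can be overridden
#' by \code{metadata}; phenotype labels come from the phenotype map, keyed by
#' (plate, well).
#'
#' @param path Path to the kinetic CSV file (see the dialect description in
#'   \code{\link{kinetic-csv}}).
#' @param phenotype_map Optional data frame with columns \code{plate},
#'   \code{well}, \code{phenotype} (see \code{\link{read_phenotype_map}}).
#' @param metadata Named list overriding header metadata (project, species,
#'   strain, plate, replicate, temperature).
#' @param default_phenotype If \code{TRUE} (default), wells absent from the
#'   phenotype map are labelled \code{"<plate>_<well>"}; if \code{FALSE},
#'   an unmapped well is an error.
#' @param partial If \code{FALSE} (default), a file must carry all 96 well
#'   columns, as instrument exports do; set \code{TRUE} to accept files
#'   holding a subset of wells (e.g. re-written filtered selections).
#' @return A \code{record_set} with one record per well column.
#' @export
parse_kinetic_csv <- function(path, phenotype_map = NULL,
                              metadata = list(), default_phenotype = TRUE,
                              partial = FALSE) {
  lines <- readLines(path)
  hdr_idx <- grep("^(Time\\(min\\)|Hour),", lines)[1]
  if (is.na(hdr_idx))
    stop("no 'Time(min)' or 'Hour' header row found in ", path)
  meta <- list()
  if (hdr_idx > 1L) {
    for (ln in lines[seq_len(hdr_idx - 1L)]) {
      kv <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (length(kv) >= 2L && kv[1] %in% KINETIC_META_KEYS)
        meta[[kv[1]]] <- paste(kv[-1], collapse = ",")
    }
  }
  for (k in names(metadata)) meta[[k]] <- metadata[[k]]
  missing_meta <- setdiff(KINETIC_META_KEYS, names(meta))
  if (length(missing_meta) > 0L)
    stop("missing metadata: ", paste(missing_meta, collapse = ", "))

  tab <- utils::read.csv(text = lines[hdr_idx:length(lines)],
                         check.names = FALSE, colClasses = "character")
  time_col <- names(tab)[1]
  wells <- names(tab)[-1]
  expected <- plate_wells()
  invalid <- setdiff(wells, expected)
  if (length(invalid) > 0L)
    stop("invalid well column(s): ", paste(invalid, collapse = ", "))
  absent <- setdiff(expected, wells)
  if (!partial && length(absent) > 0L)
    stop("missing well column(s): ", paste(absent, collapse = ", "))
  if (length(wells) == 0L) stop("no well columns found")
  if (anyDuplicated(wells))
    stop("duplicate well column(s): ",
         paste(unique(wells[duplicated(wells)]), collapse = ", "))

  num <- suppressWarnings(lapply(tab, as.numeric))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(tab[[j]]))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value '%s' at data row %d, column %s",
                   tab[[j]][bad[1]], bad[1], names(tab)[j]))
  }
  times <- num[[1]]
  if (time_col == "Hour") times <- times * 60
  nondec <- which(diff(times) <= 0)
  if (length(nondec) > 0L)
    stop("time column not strictly increasing at data row ", nondec[1] + 1L)

  recs <- lapply(wells, function(w) {
    phen <- lookup_phenotype(phenotype_map, meta$plate, w, default_phenotype)
    well_record(meta$project, meta$species, meta$strain, phen, meta$plate, w,
                as.integer(meta$replicate), as.numeric(meta$temperature),
                kinetic_curve(times, num[[w]]))
  })
  record_set(recs)
}

lookup_phenotype <- function(map, plate, well, default_ok) {
  if (!is.null(map)) {
    hit <- map$phenotype[map$plate == plate & map$well == well]
    if (length(hit) >= 1L) return(hit[1])
  }
  if (!default_ok)
    stop("no phenotype mapping for ", plate, "/", well,
         " and default labelling is disabled")
  paste(plate, well, sep = "_")
}

#' Parse a directory (or vector) of kinetic CSV files
#'
#' @param paths A directory containing \code{*.csv} plate files, or a
#'   character vector of file paths. A \code{phenotype_map.csv} sidecar in
#'   the directory is used automatically unless \code{phenotype_map} is
#'   given.
#' @param phenotype_map Optional phenotype map data frame (see
#'   \code{\link{read_phenotype_map}}).
#' @param ... Passed on to \code{\link{parse_kinetic_csv}}.
#' @return A combined \code{record_set}.
#' @export
parse_kinetic_dir <- function(paths, phenotype_map = NULL, ...) {
  if (length(paths) == 1L && dir.exists(paths)) {
    sidecar <- file.path(paths, "phenotype_map.csv")
    if (is.null(phenotype_map) && file.exists(sidecar))
      phenotype_map <- read_phenotype_map(sidecar)
    paths <- sort(list.files(paths, pattern = "\\.csv$", full.names = TRUE))
  }
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths) > 0L)
    stop("no such file or directory: ",
         paste(missing_paths, collapse = ", "))
  paths <- paths[!grepl("(phenotype_map|truth)\\.csv$", basename(paths))]
  if (length(paths) == 0L) stop("no kinetic CSV files found")
  do.call(bind_records,
          lapply(paths, parse_kinetic_csv, phenotype_map = phenotype_map,
                 ...))
}

#' Write a record set as a kinetic CSV export
#'
#' Serialises one plate run in the dialect that \code{\link{parse_kinetic_csv}}
#' reads back exactly (numeric values at full precision, wells in record
#' order). All records must share the same plate, strain, replicate and
#' temperature, and all curves the same time points.
#'
#' @param rs A non-empty \code{\link{record_set}} (one plate run).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_kinetic_csv <- function(rs, path) {
  stopifnot(inherits(rs, "record_set"))
  if (length(rs) == 0L) stop("cannot write an empty record set")
  conflict <- KINETIC_META_KEYS[vapply(KINETIC_META_KEYS, function(f)
    length(unique(rs$meta[[f]])) > 1L, logical(1))]
  if (length(conflict) > 0L)
    stop("record set mixes metadata; one file holds one plate run ",
         "(conflicting keys: ", paste(conflict, collapse = ", "), ")")
  times <- rs$curves[[1]]$times
  same <- vapply(rs$curves, function(k) identical(k$times, times), logical(1))
  if (!all(same))
    stop("all wells in a plate file must share the same time points")
  meta_lines <- vapply(KINETIC_META_KEYS, function(f)
    paste(f, rs$meta[[f]][1], sep = ","), character(1))
  header <- paste(c("Time(min)", rs$meta$well), collapse = ",")
  vals <- vapply(rs$curves, function(k) fmt_full(k$values),
                 character(length(times)))
  rows <- apply(cbind(fmt_full(times), vals), 1, paste, collapse = ",")
  writeLines(c(meta_lines, header, rows), path)
  invisible(path)
}

#' Read a phenotype map
#'
#' A phenotype map links each (plate, well) position to its substrate or
#' compound label, optionally with a mode-of-action annotation.
#'
#' @param path CSV file with columns \code{plate}, \code{well},
#'   \code{phenotype} and optionally \code{mode_of_action}.
#' @return A data frame.
#' @export
read_phenotype_map <- function(path) {
  map <- utils::read.csv(path, colClasses = "character")
  need <- c("plate", "well", "phenotype")
  if (!all(need %in% names(map)))
    stop("phenotype map must have columns ", paste(need, collapse = ", "))
  map
}

#' Write a tabular report as CSV
#'
#' All report outputs (outlier tables, correlation matrices, cluster
#' memberships, comparison tables) funnel through this writer: header row
#' mandatory, numeric cells at full precision, openable by any spreadsheet.
#'
#' @param rows A data frame, or a list of equal-length row vectors.
#' @param path Output file path.
#' @param columns Column names (required when \code{rows} is a list; taken
#'   from the data frame otherwise).
#' @return \code{path}, invisibly.
#' @export
write_report_table <- function(rows, path, columns = NULL) {
  if (is.data.frame(rows)) {
    df <- rows
    if (!is.null(columns)) names(df) <- columns
  } else {
    stopifnot(is.list(rows))
    if (is.null(columns)) stop("columns are required for list input")
    lens <- vapply(rows, length, integer(1))
    if (any(lens != length(columns)))
      stop("ragged rows: row(s) ",
           paste(which(lens != length(columns)), collapse = ", "),
           " do not match the ", length(columns), " columns")
    if (length(rows) == 0L) {
      df <- stats::setNames(as.data.frame(
        rep(list(character(0)), length(columns))), columns)
    } else {
      df <- as.data.frame(do.call(rbind, lapply(rows, as.list)))
      names(df) <- columns
    }
  }
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- fmt_full(df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
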