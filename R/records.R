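#' Construct a kinetic curve
#'
#' The atomic measurement of a phenotype microarray run: one well's intensity
#' time series. Times are minutes since the start of incubation; values are
#' instrument intensity units (arbitrary optical-density-derived units).
#'
#' @param times Numeric vector of time points in minutes, strictly increasing,
#'   non-negative, length >= 2.
#' @param values Numeric vector of intensity readings, same length as
#'   \code{times}, finite and >= 0 (z-score scaled curves relax the
#'   non-negativity; see \code{\link{zscore_scale}}).
#' @param .validate_nonneg Internal: set \code{FALSE} for derived curves
#'   (z-scored) that may be negative.
#' @return An object of class \code{kinetic_curve}: a list with elements
#'   \code{times} and \code{values}.
#' @examples
#' kc <- kinetic_curve(times = c(0, 15, 30), values = c(10, 12, 20))
#' @export
kinetic_curve <- function(times, values, .validate_nonneg = TRUE) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length (", length(times), " vs ",
         length(values), ")")
  if (length(times) < 2L)
    stop("a kinetic curve needs at least 2 time points")
  if (anyNA(times) || any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite")
  if (.validate_nonneg && any(values < 0))
    stop("intensity values must be non-negative")
  structure(list(times = times, values = values), class = "kinetic_curve")
}

#' @export
print.kinetic_curve <- function(x, ...) {
  cat(sprintf("<kinetic_curve> %d points, t = [%g, %g] min, v = [%g, %g]\n",
              length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.kinetic_curve <- function(x) length(x$times)

well_id_ok <- function(well) grepl("^[A-H](0[1-9]|1[0-2])$", well)

#' All 96 well identifiers of a plate
#'
#' Row letters A-H crossed with zero-padded columns 01-12, in row-major order
#' (A01, A02, ..., H12).
#' @return Character vector of length 96.
#' @export
plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
}

#' Construct a well record
#'
#' A kinetic curve together with its full metadata coordinate. The coordinate
#' (project, strain, phenotype, plate, well, replicate, temperature) must be
#' unique within a \code{\link{record_set}}.
#'
#' @param project,species,strain,phenotype,plate Character labels. Plates are
#'   conventionally PM01..PM20 but any non-empty label is accepted.
#' @param well Well identifier: row letter A-H plus zero-padded column 01-12.
#' @param replicate Positive integer replicate index, or \code{NA} for an
#'   averaged record (see \code{\link{average_replicates}}).
#' @param temperature Incubation temperature, degrees Celsius.
#' @param curve A \code{\link{kinetic_curve}}.
#' @return An object of class \code{well_record}.
#' @export
well_record <- function(project, species, strain, phenotype, plate, well,
                        replicate, temperature, curve) {
  if (!inherits(curve, "kinetic_curve")) stop("curve must be a kinetic_curve")
  if (!nzchar(plate)) stop("plate label must be non-empty")
  if (!well_id_ok(well))
    stop("invalid well identifier '", well, "' (expected A01..H12)")
  replicate <- as.integer(replicate)
  if (!is.na(replicate) && replicate < 1L)
    stop("replicate must be a positive integer")
  structure(list(project = as.character(project),
                 species = as.character(species),
                 strain = as.character(strain),
                 phenotype = as.character(phenotype),
                 plate = as.character(plate), well = as.character(well),
                 replicate = replicate, temperature = as.numeric(temperature),
                 curve = curve),
            class = "well_record")
}

#' @export
print.well_record <- function(x, ...) {
  cat(sprintf("<well_record> %s/%s %s %s rep %s @ %g C, %d points\n",
              x$plate, x$well, x$strain, x$phenotype,
              ifelse(is.na(x$replicate), "avg", x$replicate),
              x$temperature, length(x$curve)))
  invisible(x)
}

META_FIELDS <- c("project", "species", "strain", "phenotype", "plate",
                 "well", "replicate", "temperature")
KEY_FIELDS <- c("project", "strain", "phenotype", "plate", "well",
                "replicate", "temperature")

new_record_set <- function(meta, curves) {
  rownames(meta) <- NULL
  structure(list(meta = meta, curves = curves), class = "record_set")
}

#' Construct a record set
#'
#' An ordered collection of \code{\link{well_record}}s. Internally the
#' metadata live in a data frame (one row per record) and the curves in a
#' parallel list, so filtering and grouping are vectorised. Iteration order is
#' insertion order. The metadata coordinate of every record must be unique.
#'
#' @param records A list of \code{well_record} objects (may be empty).
#' @return An object of class \code{record_set}.
#' @seealso \code{\link{filter_records}}, \code{\link{group_replicates}}
#' @export
record_set <- function(records = list()) {
  if (inherits(records, "well_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "well_record")))
  if (length(records) == 0L) {
    meta <- data.frame(project = character(), species = character(),
                       strain = character(), phenotype = character(),
                       plate = character(), well = character(),
                       replicate = integer(), temperature = numeric(),
                       stringsAsFactors = FALSE)
    return(new_record_set(meta, list()))
  }
  meta <- do.call(rbind, lapply(records, function(r)
    data.frame(r[META_FIELDS], stringsAsFactors = FALSE)))
  rs <- new_record_set(meta, lapply(records, `[[`, "curve"))
  assert_unique_keys(rs)
  rs
}

assert_unique_keys <- function(rs) {
  key <- do.call(paste, c(rs$meta[KEY_FIELDS], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate record coordinate(s): ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "))
  invisible(rs)
}

#' @export
length.record_set <- function(x) nrow(x$meta)

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("<record_set> %d records", length(x)))
  if (length(x) > 0L)
    cat(sprintf(": %d strain(s), %d plate(s), %d phenotype(s)",
                length(unique(x$meta$strain)), length(unique(x$meta$plate)),
                length(unique(x$meta$phenotype))))
  cat("\n")
  invisible(x)
}

#' @export
`[.record_set` <- function(x, i, ...) {
  new_record_set(x$meta[i, , drop = FALSE], x$curves[i])
}

#' @export
`[[.record_set` <- function(x, i, ...) {
  if (is.character(i)) return(.subset2(x, i))  # plain list element access
  m <- x$meta[i, , drop = FALSE]
  well_record(m$project, m$species, m$strain, m$phenotype, m$plate, m$well,
              m$replicate, m$temperature, x$curves[[i]])
}

#' @export
as.data.frame.record_set <- function(x, ...) x$meta

#' Combine record sets
#'
#' @param ... \code{record_set} objects.
#' @return A single \code{record_set}; the uniqueness invariant is re-checked.
#' @export
bind_records <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "record_set")))
  rs <- new_record_set(do.call(rbind, lapply(sets, function(s) s$meta)),
                       do.call(c, lapply(sets, function(s) s$curves)))
  assert_unique_keys(rs)
  rs
}

#' Record selection criteria
#'
#' Each argument is an optional set of accepted values for the corresponding
#' metadata field; \code{NULL} means no constraint. Criteria combine
#' conjunctively across fields and disjunctively within a field's value set,
#' mirroring a hierarchical drill-down (project, strain, phenotype, plate,
#' well, replicate, temperature) as composed filters.
#'
#' @param project,strain,phenotype,plate,well,replicate,temperature Optional
#'   vectors of accepted values.
#' @return An object of class \code{filter_criteria}.
#' @export
filter_criteria <- function(project = NULL, strain = NULL, phenotype = NULL,
                            plate = NULL, well = NULL, replicate = NULL,
                            temperature = NULL) {
  structure(list(project = project, strain = strain, phenotype = phenotype,
                 plate = plate, well = well, replicate = replicate,
                 temperature = temperature),
            class = "filter_criteria")
}

#' Filter a record set hierarchically
#'
#' Returns exactly the records matching every provided constraint, in their
#' original order; the input is unmodified. A criterion value absent from the
#' catalog is not an error -- the matching subset (possibly empty) is
#' returned. Filtering is idempotent and composing two filters equals
#' filtering with their conjunction.
#'
#' @param rs A \code{\link{record_set}}.
#' @param criteria A \code{\link{filter_criteria}}; alternatively pass the
#'   fields directly via \code{...}.
#' @param ... Field constraints forwarded to \code{filter_criteria} when
#'   \code{criteria} is not given.
#' @return The matching \code{record_set}.
#' @examples
#' # rs <- generate_experiment(seed = 1)$records
#' # filter_records(rs, strain = "WT", plate = "PM01")
#' @export
filter_records <- function(rs, criteria = NULL, ...) {
  stopifnot(inherits(rs, "record_set"))
  if (is.null(criteria)) criteria <- filter_criteria(...)
  stopifnot(inherits(criteria, "filter_criteria"))
  keep <- rep(TRUE, length(rs))
  for (f in names(criteria)) {
    if (!is.null(criteria[[f]]))
      keep <- keep & (rs$meta[[f]] %in% criteria[[f]])
  }
  rs[keep]
}

#' Group records into replicate sets
#'
#' Splits a record set by the replicate-group key (strain, phenotype, plate,
#' well, temperature): members of a group differ only in replicate index.
#' Records at different temperatures are never grouped together. Every record
#' lands in exactly one group and the union of all groups reconstitutes the
#' input; singleton groups are allowed.
#'
#' @param rs A \code{\link{record_set}}.
#' @return A named list of \code{record_set} groups, keyed by
#'   \code{strain|phenotype|plate|well|temperature}, in order of first
#'   appearance.
#' @export
group_replicates <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  key <- with(rs$meta, paste(strain, phenotype, plate, well, temperature,
                             sep = "|"))
  idx <- split(seq_len(length(rs)), factor(key, levels = unique(key)))
  lapply(idx, function(i) rs[i])
}
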