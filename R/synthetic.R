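default_experiment_config <- function() {
  list(
    project = "synthetic_pm",
    species = "synthetic organism",
    strains = c("WT", "MUT"),      # first strain is the parent
    plates = sprintf("PM%02d", 1:20),
    wells_per_plate = 96L,
    replicates = 2L,
    temperature = 37,
    cycle_min = 15,                # instrument reading interval, minutes
    duration_h = 72,               # incubation course, hours
    baseline = 15,                 # pre-growth intensity, instrument units
    amplitude_range = c(150, 250), # logistic amplitude A, instrument units
    rate_range = c(0.005, 0.02),   # logistic rate r, per minute
    midpoint_range_min = c(600, 1800), # logistic midpoint t_m, minutes
    noise_frac = 0.01,             # noise_sd = noise_frac * A, per time point
    decay_wells = character(0),    # "plate|well" keys with decaying profiles
    planted_outliers = NULL,       # data.frame: strain, plate, well,
                                   #   replicate, type ("reversed" | "flat")
    planted_ratios = NULL          # data.frame: plate, well, ratio (> 0);
                                   #   applied to every non-parent strain
  )
}

validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, key) if (!ok) bad <<- c(bad, key)
  chk(length(cfg$strains) >= 1L && !anyDuplicated(cfg$strains), "strains")
  chk(length(cfg$plates) >= 1L && !anyDuplicated(cfg$plates), "plates")
  chk(cfg$wells_per_plate >= 1L && cfg$wells_per_plate <= 96L,
      "wells_per_plate")
  chk(cfg$replicates >= 1L, "replicates")
  chk(cfg$cycle_min > 0, "cycle_min")
  chk(cfg$duration_h > 0, "duration_h")
  chk(cfg$baseline >= 0, "baseline")
  chk(all(cfg$amplitude_range >= 0) && diff(cfg$amplitude_range) >= 0,
      "amplitude_range")
  chk(all(cfg$rate_range > 0) && diff(cfg$rate_range) >= 0, "rate_range")
  chk(diff(cfg$midpoint_range_min) >= 0, "midpoint_range_min")
  chk(cfg$noise_frac >= 0, "noise_frac")
  if (!is.null(cfg$planted_ratios))
    chk(all(cfg$planted_ratios$ratio > 0), "planted_ratios")
  if (!is.null(cfg$planted_outliers))
    chk(all(cfg$planted_outliers$type %in% c("reversed", "flat")),
        "planted_outliers")
  if (length(bad) > 0L)
    stop("invalid experiment config value(s): ", paste(bad, collapse = ", "))
  cfg
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

logistic_mean <- function(times, baseline, A, r, tm, decay = FALSE) {
  s <- if (decay) -1 else 1
  baseline + A * stats::plogis(s * r * (times - tm))
}

#' Generate a synthetic phenotype microarray experiment
#'
#' Emulates a standard OmniLog-style run: by default 2 strains (a wild-type
#' parent and a mutant) x 20 plates x 96 wells x 2 replicates, read every 15
#' minutes over 72 hours (289 time points per curve). Each (plate, well)
#' position gets a logistic growth model
#' \eqn{v(t) = baseline + A / (1 + e^{-r (t - t_m)})} shared across strains
#' and replicates, plus independent Gaussian noise per reading (sd =
#' \code{noise_frac} x A), clipped at zero. Ground truth for every planted
#' feature is returned alongside the records.
#'
#' Planted features, all optional via \code{config}:
#' \itemize{
#'   \item \code{decay_wells}: wells whose profile decreases sigmoidally
#'     instead of growing (a second shape family, for clustering tests);
#'   \item \code{planted_outliers}: individual replicate curves replaced by a
#'     time-reversed copy of the well's mean curve, or by a flat baseline;
#'   \item \code{planted_ratios}: wells where every non-parent strain's
#'     noise-free curve is scaled by \code{ratio}, so the planted AUC-summary
#'     ratio equals \code{ratio} exactly in the noise-free limit.
#' }
#'
#' @param config Named list overriding \code{default_experiment_config()};
#'   see that function's source for keys, defaults and units.
#' @param seed Integer random seed (mandatory for reproducibility).
#' @return List with \code{records} (a \code{\link{record_set}}),
#'   \code{truth} (data frame, one row per record: model parameters, shape
#'   family, outlier type, planted ratio), \code{phenotype_map} (data frame
#'   plate/well/phenotype), and the resolved \code{config}.
#' @export
generate_experiment <- function(config = list(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- utils::modifyList(default_experiment_config(), config)
  validate_config(cfg)
  times <- seq(0, cfg$duration_h * 60, by = cfg$cycle_min)
  wells <- plate_wells()[seq_len(cfg$wells_per_plate)]
  parent <- cfg$strains[1]

  with_seed(seed, {
    # per-(plate, well) growth model, shared across strains and replicates
    wt <- expand.grid(well = wells, plate = cfg$plates,
                      stringsAsFactors = FALSE)[, c("plate", "well")]
    nw <- nrow(wt)
    wt$amplitude <- stats::runif(nw, cfg$amplitude_range[1],
                                 cfg$amplitude_range[2])
    wt$rate <- stats::runif(nw, cfg$rate_range[1], cfg$rate_range[2])
    wt$midpoint <- stats::runif(nw, cfg$midpoint_range_min[1],
                                cfg$midpoint_range_min[2])
    wt$noise_sd <- cfg$noise_frac * wt$amplitude
    wt$family <- ifelse(paste(wt$plate, wt$well, sep = "|") %in%
                          cfg$decay_wells, "decay", "growth")
    wt$phenotype <- paste0("phen_", wt$plate, "_", wt$well)
    ratios <- rep(1, nw)
    if (!is.null(cfg$planted_ratios)) {
      pk <- paste(cfg$planted_ratios$plate, cfg$planted_ratios$well,
                  sep = "|")
      m <- match(paste(wt$plate, wt$well, sep = "|"), pk)
      ratios[!is.na(m)] <- cfg$planted_ratios$ratio[m[!is.na(m)]]
    }
    wt$planted_ratio <- ratios

    design <- expand.grid(replicate = seq_len(cfg$replicates),
                          widx = seq_len(nw),
                          strain = cfg$strains,
                          stringsAsFactors = FALSE)
    # deterministic record order: strain, then plate/well, then replicate
    design <- design[order(match(design$strain, cfg$strains), design$widx,
                           design$replicate), ]
    n <- nrow(design)

    ok <- rep(NA_character_, n)
    if (!is.null(cfg$planted_outliers)) {
      po <- cfg$planted_outliers
      pk <- paste(po$strain, po$plate, po$well, po$replicate, sep = "|")
      dk <- paste(design$strain, wt$plate[design$widx],
                  wt$well[design$widx], design$replicate, sep = "|")
      m <- match(dk, pk)
      ok[!is.na(m)] <- po$type[m[!is.na(m)]]
    }

    meta <- data.frame(
      project = cfg$project, species = cfg$species,
      strain = design$strain,
      phenotype = wt$phenotype[design$widx],
      plate = wt$plate[design$widx], well = wt$well[design$widx],
      replicate = as.integer(design$replicate),
      temperature = cfg$temperature, stringsAsFactors = FALSE)

    curves <- vector("list", n)
    truth_rows <- wt[design$widx, c("plate", "well", "phenotype",
                                    "amplitude", "rate", "midpoint",
                                    "noise_sd", "family", "planted_ratio")]
    truth_rows$strain <- design$strain
    truth_rows$replicate <- as.integer(design$replicate)
    truth_rows$outlier_type <- ok
    truth_rows$baseline <- cfg$baseline
    scale_i <- ifelse(design$strain == parent, 1,
                      wt$planted_ratio[design$widx])
    for (i in seq_len(n)) {
      w <- design$widx[i]
      mu <- logistic_mean(times, cfg$baseline, wt$amplitude[w], wt$rate[w],
                          wt$midpoint[w], decay = wt$family[w] == "decay")
      mu <- mu * scale_i[i]
      if (!is.na(ok[i])) {
        mu <- if (ok[i] == "reversed") rev(mu)
              else rep(cfg$baseline, length(times))
      }
      v <- mu + stats::rnorm(length(times), 0, wt$noise_sd[w])
      curves[[i]] <- kinetic_curve(times, pmax(v, 0))
    }

    rs <- new_record_set(meta, curves)
    assert_unique_keys(rs)
    truth <- truth_rows[, c("strain", "plate", "well", "replicate",
                            "phenotype", "family", "baseline", "amplitude",
                            "rate", "midpoint", "noise_sd", "outlier_type",
                            "planted_ratio")]
    rownames(truth) <- NULL
    truth$seed <- seed
    pmap <- unique(wt[, c("plate", "well", "phenotype")])
    pmap$mode_of_action <- "synthetic substrate"
    rownames(pmap) <- NULL
    list(records = rs, truth = truth, phenotype_map = pmap, config = cfg)
  })
}

#' Generate synthetic negative-control wells
#'
#' Flat curves (zero growth amplitude) with additive Gaussian noise, clipped
#' at zero, labelled with the reserved phenotype \code{"negative_control"}.
#' Controls fill wells A01..H12 on plates NC01, NC02, ... as needed.
#'
#' @param n Number of control wells (>= 1).
#' @param baseline Mean intensity, instrument units (default 15).
#' @param noise_sd Gaussian noise sd per reading (default 1.5).
#' @param cycle_min,duration_h Reading interval and course, as in
#'   \code{\link{generate_experiment}}.
#' @param strain,project,species,temperature Metadata labels.
#' @param seed Integer random seed (mandatory).
#' @return A \code{\link{record_set}} of \code{n} flat control records.
#' @export
generate_negative_controls <- function(n, baseline = 15, noise_sd = 1.5,
                                       cycle_min = 15, duration_h = 72,
                                       strain = "WT",
                                       project = "synthetic_pm",
                                       species = "synthetic organism",
                                       temperature = 37, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n < 1L) stop("need at least 1 negative control")
  if (noise_sd < 0 || baseline < 0)
    stop("invalid experiment config value(s): ",
         paste(c("noise_sd", "baseline")[c(noise_sd < 0, baseline < 0)],
               collapse = ", "))
  times <- seq(0, duration_h * 60, by = cycle_min)
  wells <- plate_wells()
  with_seed(seed, {
    idx <- seq_len(n) - 1L
    meta <- data.frame(
      project = project, species = species, strain = strain,
      phenotype = "negative_control",
      plate = sprintf("NC%02d", idx %/% 96L + 1L),
      well = wells[idx %% 96L + 1L],
      replicate = 1L, temperature = temperature, stringsAsFactors = FALSE)
    curves <- lapply(seq_len(n), function(i)
      kinetic_curve(times, pmax(baseline +
        stats::rnorm(length(times), 0, noise_sd), 0)))
    rs <- new_record_set(meta, curves)
    assert_unique_keys(rs)
    rs
  })
}

#' Write a synthetic experiment to a directory of kinetic CSV files
#'
#' One file per (strain, plate, replicate) run, named
#' \code{<strain>_<plate>_rep<k>.csv}, plus \code{phenotype_map.csv} and
#' \code{truth.csv}. The files round-trip exactly through
#' \code{\link{parse_kinetic_dir}}.
#'
#' @param exp A \code{\link{generate_experiment}} result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  stopifnot(is.list(exp), inherits(exp$records, "record_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rs <- exp$records
  key <- with(rs$meta, paste(strain, plate, replicate, sep = "_"))
  for (k in unique(key))
    write_kinetic_csv(rs[key == k], file.path(dir, paste0(k, ".csv")))
  write_report_table(exp$phenotype_map, file.path(dir, "phenotype_map.csv"))
  write_report_table(exp$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
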