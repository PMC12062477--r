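#' One cultivated sample: per-timepoint (optionally per-tile) adhesion counts
#'
#' Represents the image-derived counting data for one well: the number of
#' adhesion cells counted at each imaging timepoint, optionally resolved into
#' the 64 tiles (8 x 8 tiling) of the imaged culture area.
#'
#' @param sample_id sample label.
#' @param operator operator label.
#' @param X_seed seeding density (cells/cm^2).
#' @param times imaging times in hours since seeding, strictly ascending; the
#'   observation nearest 24 h is the Day 1 frame the parameter definitions use.
#' @param tile_counts integer matrix `[n_timepoints x 64]` of adhesion cells
#'   per tile image, or `NULL` when tiles are unavailable.
#' @param total_counts integer vector of per-timepoint totals; derived from
#'   `tile_counts` when those are given.
#' @param S imaged culture area in cm^2. The default is the 15.3 mm x 15.3 mm
#'   square tiling area (2.3409 cm^2); `S = pi * (1.53 / 2)^2` selects the
#'   circle-of-diameter-15.3 mm reading (1.8385 cm^2) instead.
#' @return an object of class `tiled_observation`.
#' @export
tiled_observation <- function(sample_id, operator, X_seed, times,
                              tile_counts = NULL, total_counts = NULL,
                              S = 2.3409) {
  stopifnot(is.numeric(X_seed), length(X_seed) == 1L, X_seed > 0,
            is.numeric(times), length(times) >= 1L,
            is.numeric(S), length(S) == 1L, S > 0)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly ascending")
  if (is.null(tile_counts) && is.null(total_counts))
    stop("one of tile_counts or total_counts is required")
  if (!is.null(tile_counts)) {
    tile_counts <- as.matrix(tile_counts)
    if (ncol(tile_counts) != 64L)
      stop("tile_counts must have 64 columns (8 x 8 tiling)")
    if (nrow(tile_counts) != length(times))
      stop("tile_counts must have one row per timepoint")
    if (any(tile_counts < 0) || any(!is.finite(tile_counts)))
      stop("tile counts must be finite and >= 0")
    total_counts <- rowSums(tile_counts)
  } else {
    total_counts <- as.numeric(total_counts)
    if (length(total_counts) != length(times))
      stop("total_counts must have one entry per timepoint")
    if (any(total_counts < 0) || any(!is.finite(total_counts)))
      stop("total counts must be finite and >= 0")
  }
  structure(
    list(sample_id = as.character(sample_id),
         operator = as.character(operator),
         X_seed = X_seed, S = S, times = as.numeric(times),
         tile_counts = tile_counts, total_counts = total_counts),
    class = "tiled_observation")
}

#' @export
print.tiled_observation <- function(x, ...) {
  cat(sprintf("Tiled observation '%s' (operator %s)\n", x$sample_id, x$operator))
  cat(sprintf("  X_seed = %g cells/cm^2, S = %g cm^2, %d timepoints (%g-%g h)%s\n",
              x$X_seed, x$S, length(x$times), min(x$times), max(x$times),
              if (is.null(x$tile_counts)) ", totals only" else ", 64 tiles"))
  invisible(x)
}

# Index of the Day 1 frame: the observation closest to 24 h post seeding,
# required to fall within +/- tol hours of it.
day1_index <- function(obs, tol = 3) {
  i <- which.min(abs(obs$times - 24))
  if (abs(obs$times[i] - 24) > tol)
    stop(sprintf("sample '%s' has no observation within %g h of the 24 h Day 1 frame",
                 obs$sample_id, tol))
  i
}

#' Adhesion ratio of a sample
#'
#' The fraction of seeded cells counted as attached on Day 1: the sum of the
#' Day 1 counts over all tiles divided by the number of seeded cells
#' `S * X_seed`.
#'
#' @param obs a [tiled_observation()].
#' @return the adhesion ratio (dimensionless).
#' @export
adhesion_ratio <- function(obs) {
  stopifnot(inherits(obs, "tiled_observation"))
  seeded <- obs$S * obs$X_seed
  if (!(seeded > 0)) stop("S * X_seed must be > 0")
  obs$total_counts[day1_index(obs)] / seeded
}

#' Seeding heterogeneity of a sample
#'
#' The population standard deviation of the normalized per-tile Day 1 counts:
#' `sqrt(mean((N_i / sum(N) - 1/64)^2))` over the 64 tiles. Zero for perfectly
#' uniform seeding; the maximum, `sqrt(63)/64` (~0.124), when every cell lands
#' in a single tile. Undefined without tile resolution or when no cells
#' attached on Day 1.
#'
#' @param obs a [tiled_observation()] with tile-resolved counts.
#' @return the seeding heterogeneity (dimensionless).
#' @export
seeding_heterogeneity <- function(obs) {
  stopifnot(inherits(obs, "tiled_observation"))
  if (is.null(obs$tile_counts))
    stop("seeding heterogeneity requires tile-resolved counts")
  n1 <- obs$tile_counts[day1_index(obs), ]
  tot <- sum(n1)
  if (tot <= 0) stop("seeding heterogeneity undefined: Day 1 tile sum is 0")
  sqrt(mean((n1 / tot - 1 / 64)^2))
}

#' Maximum cell density of a sample
#'
#' The saturation density estimate from imaging: 64 times the maximum
#' per-tile count observed over all tiles and timepoints, divided by the
#' imaged area. The single densest tile is taken to reflect the locally
#' saturated state.
#'
#' @param obs a [tiled_observation()]. Without tile resolution the totals are
#'   used under a uniformity assumption (`max(total) / S`), which requires
#'   `assume_uniform = TRUE`.
#' @param assume_uniform allow the totals-only fallback.
#' @return maximum cell density (cells/cm^2).
#' @export
max_cell_density <- function(obs, assume_uniform = FALSE) {
  stopifnot(inherits(obs, "tiled_observation"))
  if (is.null(obs$tile_counts)) {
    if (!assume_uniform)
      stop("max_cell_density without tiles requires assume_uniform = TRUE")
    return(max(obs$total_counts) / obs$S)
  }
  64 * max(obs$tile_counts) / obs$S
}

#' Extract the per-sample model input parameters
#'
#' Computes the adhesion ratio, seeding heterogeneity, and maximum cell
#' density of one sample from its tiled counts.
#'
#' @param obs a [tiled_observation()] with tile-resolved counts.
#' @return an object of class `sample_parameters`: a one-row data.frame with
#'   columns `sample_id`, `operator`, `X_seed`, `alpha`, `epsilon`, `X_m`.
#' @export
extract_parameters <- function(obs) {
  stopifnot(inherits(obs, "tiled_observation"))
  out <- data.frame(sample_id = obs$sample_id, operator = obs$operator,
                    X_seed = obs$X_seed,
                    alpha = adhesion_ratio(obs),
                    epsilon = seeding_heterogeneity(obs),
                    X_m = max_cell_density(obs),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_parameters", "data.frame")
  out
}

#' Extract parameters for a list of samples
#'
#' @param obs_list a list of [tiled_observation()] objects.
#' @return a `sample_parameters` data.frame with one row per sample.
#' @export
extract_parameters_all <- function(obs_list) {
  stopifnot(length(obs_list) >= 1L)
  out <- do.call(rbind, lapply(obs_list, extract_parameters))
  class(out) <- c("sample_parameters", "data.frame")
  out
}

#' Read tiled observations from long-format CSV
#'
#' The dialect has columns `sample_id`, `operator`, `X_seed_cells_per_cm2`,
#' `time_h`, `tile_index` (0-63, or blank for totals-only rows), `count`, with
#' a header row. Returns one [tiled_observation()] per sample.
#'
#' @param path CSV file path.
#' @param S imaged area (cm^2) to attach to each observation.
#' @return a named list of `tiled_observation` objects.
#' @export
read_observations <- function(path, S = 2.3409) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "operator", "X_seed_cells_per_cm2", "time_h",
            "tile_index", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  out <- lapply(split(df, df$sample_id), function(d) {
    times <- sort(unique(d$time_h))
    tiled <- !all(is.na(d$tile_index))
    if (tiled) {
      if (any(is.na(d$tile_index)))
        stop("sample '", d$sample_id[1L], "': mixed tiled and totals-only rows")
      if (any(d$tile_index < 0 | d$tile_index > 63))
        stop("tile_index must be in 0-63")
      m <- matrix(0, nrow = length(times), ncol = 64L)
      m[cbind(match(d$time_h, times), d$tile_index + 1L)] <- d$count
      tiled_observation(d$sample_id[1L], d$operator[1L],
                        d$X_seed_cells_per_cm2[1L], times,
                        tile_counts = m, S = S)
    } else {
      d <- d[order(d$time_h), ]
      tiled_observation(d$sample_id[1L], d$operator[1L],
                        d$X_seed_cells_per_cm2[1L], d$time_h,
                        total_counts = d$count, S = S)
    }
  })
  out[order(names(out))]
}

#' Write tiled observations to long-format CSV
#'
#' Inverse of [read_observations()]; numeric values round-trip losslessly.
#'
#' @param obs_list list of [tiled_observation()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs_list, path) {
  rows <- lapply(obs_list, function(o) {
    if (!is.null(o$tile_counts)) {
      data.frame(sample_id = o$sample_id, operator = o$operator,
                 X_seed_cells_per_cm2 = o$X_seed,
                 time_h = rep(o$times, each = 64L),
                 tile_index = rep(0:63, times = length(o$times)),
                 count = as.vector(t(o$tile_counts)))
    } else {
      data.frame(sample_id = o$sample_id, operator = o$operator,
                 X_seed_cells_per_cm2 = o$X_seed, time_h = o$times,
                 tile_index = NA_integer_, count = o$total_counts)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
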