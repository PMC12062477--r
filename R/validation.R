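#' Experimental probability of meeting the quality specification
#'
#' The fraction (in percent) of the validation samples at one condition whose
#' measured cell number and confluency satisfy the specification.
#'
#' @param N_exp measured numbers of adhesion cells, one per sample.
#' @param P_exp measured confluency levels, same length.
#' @param spec a [quality_spec()].
#' @return probability in percent.
#' @export
experimental_probability <- function(N_exp, P_exp, spec = quality_spec()) {
  stopifnot(is.numeric(N_exp), is.numeric(P_exp),
            length(N_exp) == length(P_exp))
  if (length(N_exp) < 1L) stop("at least one sample is required")
  100 * mean(satisfies_spec(N_exp, P_exp, spec))
}

#' Categorize a condition by crossing predicted and experimental probability
#'
#' Both probabilities are compared against the minimum acceptable risk `pi`
#' (inclusive at `pi` on both sides):
#' * `CDS`     - correctly identified feasible:   `h >= pi` and `h_exp >= pi`
#' * `C_notDS` - correctly identified infeasible: `h <  pi` and `h_exp <  pi`
#' * `IDS`     - incorrectly identified feasible:   `h >= pi`, `h_exp < pi`
#' * `I_notDS` - incorrectly identified infeasible: `h < pi`, `h_exp >= pi`
#'
#' @param h predicted probability (percent); vectorized.
#' @param h_exp experimental probability (percent).
#' @param pi minimum acceptable risk (percent).
#' @return factor with levels `CDS`, `C_notDS`, `IDS`, `I_notDS`.
#' @export
categorize_condition <- function(h, h_exp, pi) {
  stopifnot(is.numeric(h), is.numeric(h_exp), is.numeric(pi))
  if (any(h < 0 | h > 100) || any(h_exp < 0 | h_exp > 100))
    stop("h and h_exp must be in [0, 100]")
  in_ds <- h >= pi
  feas <- h_exp >= pi
  out <- ifelse(in_ds & feas, "CDS",
         ifelse(!in_ds & !feas, "C_notDS",
         ifelse(in_ds & !feas, "IDS", "I_notDS")))
  factor(out, levels = c("CDS", "C_notDS", "IDS", "I_notDS"))
}

#' Design-space validation metrics
#'
#' Counts the four condition categories and computes the three summary
#' ratios:
#' * `R1 = nCDS / (nCDS + nIDS)` - precision-like: of the conditions the DS
#'   proposes, how many were experimentally feasible.
#' * `R2 = nCDS / (nCDS + nI_notDS)` - recall-like: of the experimentally
#'   feasible conditions, how many the DS captured.
#' * `R3 = nC_notDS / (nC_notDS + nIDS)` - specificity-like: of the
#'   experimentally infeasible conditions, how many the DS excluded.
#'
#' A ratio with a zero denominator is reported as `NA` with a warning, never
#' as 0 or 1.
#'
#' @param categories factor from [categorize_condition()].
#' @return an object of class `validation_metrics`: list with the four counts
#'   and `R1`, `R2`, `R3`.
#' @export
compute_metrics <- function(categories) {
  stopifnot(length(categories) >= 1L)
  categories <- factor(categories, levels = c("CDS", "C_notDS", "IDS", "I_notDS"))
  n <- as.list(table(categories))
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning("denominator of ", name, " is 0; reported as NA")
      return(NA_real_)
    }
    num / den
  }
  structure(
    list(nCDS = n$CDS, nC_notDS = n$C_notDS, nIDS = n$IDS,
         nI_notDS = n$I_notDS,
         R1 = ratio(n$CDS, n$CDS + n$IDS, "R1"),
         R2 = ratio(n$CDS, n$CDS + n$I_notDS, "R2"),
         R3 = ratio(n$C_notDS, n$C_notDS + n$IDS, "R3")),
    class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("Validation: CDS %d, C-notDS %d, IDS %d, I-notDS %d\n",
              x$nCDS, x$nC_notDS, x$nIDS, x$nI_notDS))
  cat(sprintf("  R1 = %s  R2 = %s  R3 = %s\n",
              format(x$R1, digits = 3), format(x$R2, digits = 3),
              format(x$R3, digits = 3)))
  invisible(x)
}

#' Per-sample validation measurements from tiled observations
#'
#' Converts validation-experiment observations into the long table the DS
#' validation consumes: one row per (sample, harvest time) with the measured
#' cell number and confluency. The confluency of each sample uses that
#' sample's own measured maximum cell density (`P_exp = N_exp / (S * X_m)`);
#' `X_m_mode = "global"` divides by the mean `X_m` over all samples instead.
#'
#' @param obs_list list of [tiled_observation()] objects.
#' @param t_h_days harvest times (days) to extract; must match observation
#'   times exactly (no snapping).
#' @param X_m_mode `"per_sample"` (default) or `"global"`.
#' @return data.frame with columns `sample_id`, `operator`, `X_seed`,
#'   `t_h_days`, `N_exp`, `P_exp`.
#' @export
observations_to_conditions <- function(obs_list, t_h_days,
                                       X_m_mode = c("per_sample", "global")) {
  X_m_mode <- match.arg(X_m_mode)
  X_ms <- vapply(obs_list, max_cell_density, numeric(1L))
  X_m_global <- mean(X_ms)
  rows <- Map(function(o, xm) {
    t_h <- 24 * t_h_days
    idx <- match(t_h, o$times)
    if (anyNA(idx))
      stop("sample '", o$sample_id, "' lacks observations at t_h (days): ",
           paste(t_h_days[is.na(idx)], collapse = ", "))
    N <- o$total_counts[idx]
    denom <- if (X_m_mode == "per_sample") xm else X_m_global
    data.frame(sample_id = o$sample_id, operator = o$operator,
               X_seed = o$X_seed, t_h_days = t_h_days,
               N_exp = N, P_exp = N / (o$S * denom))
  }, obs_list, X_ms)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Validate a design space against experimental measurements
#'
#' Matches validation measurements to grid cells exactly on
#' (`X_seed`, `t_h_days`), computes the experimental probability per
#' condition, categorizes every condition, and summarizes with R1/R2/R3.
#' Conditions whose (`X_seed`, `t_h_days`) do not appear in the probability
#' map raise an error listing the offending rows; no nearest-neighbour
#' snapping is performed.
#'
#' @param ds a [determine_design_space()] result.
#' @param conditions data.frame with columns `X_seed`, `t_h_days`, `N_exp`,
#'   `P_exp` (one row per sample; [observations_to_conditions()] produces
#'   this).
#' @param spec a [quality_spec()]; defaults to the one stored in the map.
#' @return an object of class `validation_report`: list with `conditions`
#'   (per-condition data.frame: `X_seed`, `t_h_days`, `n`, `h`, `h_exp`,
#'   `category`) and `metrics` ([compute_metrics()]).
#' @export
validate_design_space <- function(ds, conditions, spec = NULL) {
  stopifnot(inherits(ds, "design_space"), is.data.frame(conditions))
  need <- c("X_seed", "t_h_days", "N_exp", "P_exp")
  if (length(setdiff(need, names(conditions))))
    stop("conditions must have columns ", paste(need, collapse = ", "))
  map <- ds$map
  if (is.null(spec)) spec <- map$spec
  g <- map$grid
  ix <- match(conditions$X_seed, g$X_seed_values)
  it <- match(conditions$t_h_days, g$t_h_days)
  bad <- is.na(ix) | is.na(it)
  if (any(bad))
    stop("conditions not on the grid (no snapping): ",
         paste(sprintf("(%g, %g d)", conditions$X_seed[bad],
                       conditions$t_h_days[bad])[seq_len(min(5L, sum(bad)))],
               collapse = ", "))
  key <- interaction(conditions$X_seed, conditions$t_h_days, drop = TRUE)
  per <- lapply(split(seq_len(nrow(conditions)), key), function(i) {
    d <- conditions[i, ]
    data.frame(X_seed = d$X_seed[1L], t_h_days = d$t_h_days[1L],
               n = nrow(d),
               h = map$h[match(d$X_seed[1L], g$X_seed_values),
                         match(d$t_h_days[1L], g$t_h_days)],
               h_exp = experimental_probability(d$N_exp, d$P_exp, spec))
  })
  per <- do.call(rbind, c(per, make.row.names = FALSE))
  per <- per[order(per$X_seed, per$t_h_days), ]
  rownames(per) <- NULL
  per$category <- categorize_condition(per$h, per$h_exp, ds$pi)
  structure(list(conditions = per, metrics = compute_metrics(per$category),
                 pi = ds$pi),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Design-space validation at pi = %g%% over %d conditions\n",
              x$pi, nrow(x$conditions)))
  print(x$metrics)
  invisible(x)
}

#' Permutation study over pre-/validation-experiment assignments
#'
#' For each labelled experiment group in turn: use that group as the
#' pre-experiment (growth-rate re-estimation, prediction interval, parameter
#' pool, probability map) and pool the remaining groups as the validation
#' experiment, then validate the design space at each requested risk level.
#' An empty design space (all probabilities below `pi`) is reported with a
#' zero-condition DS and `NA` metrics where denominators vanish.
#'
#' @param experiments named list (>= 2 entries) of lists of
#'   [tiled_observation()] objects, e.g. `list(A = ..., B = ..., C = ...)`.
#' @param pis risk levels in percent, default `c(50, 70, 90)`.
#' @param grid a [condition_grid()] for the maps (validation conditions use
#'   the observation densities).
#' @param spec a [quality_spec()].
#' @param M Monte-Carlo iterations.
#' @param seed integer seed for the parameter draws (one per permutation,
#'   derived deterministically).
#' @param level prediction-interval level.
#' @param ... passed to [fit_experiment()].
#' @return a data.frame with one row per (pre-experiment, pi): columns
#'   `pre`, `pi`, `ds_size`, `nCDS`, `nC_notDS`, `nIDS`, `nI_notDS`, `R1`,
#'   `R2`, `R3`; the full per-permutation objects are attached as attribute
#'   `"runs"`.
#' @export
permutation_study <- function(experiments, pis = c(50, 70, 90),
                              grid = condition_grid(), spec = quality_spec(),
                              M = 1000, seed = NULL, level = 0.95, ...) {
  stopifnot(is.list(experiments), length(experiments) >= 2L,
            !is.null(names(experiments)))
  runs <- list()
  rows <- list()
  for (j in seq_along(experiments)) {
    pre_name <- names(experiments)[j]
    pre <- experiments[[j]]
    val <- do.call(c, experiments[-j])
    est <- fit_experiment(pre, ...)
    bounds <- mu_m_prediction_interval(est, level = level)
    pool <- as_parameter_pool(est$parameters)
    run_seed <- if (is.null(seed)) NULL else seed + j
    map <- probability_map(grid, pool, bounds, spec = spec, M = M,
                           seed = run_seed)
    t_h <- grid$t_h_days
    conditions <- observations_to_conditions(val, t_h)
    per_pi <- lapply(pis, function(p) {
      ds <- determine_design_space(map, pi = p)
      rep_ <- validate_design_space(ds, conditions, spec = spec)
      list(ds = ds, report = rep_)
    })
    names(per_pi) <- pis
    runs[[pre_name]] <- list(estimation = est, interval = bounds, map = map,
                             per_pi = per_pi)
    rows[[pre_name]] <- do.call(rbind, lapply(seq_along(pis), function(k) {
      m <- per_pi[[k]]$report$metrics
      data.frame(pre = pre_name, pi = pis[k],
                 ds_size = sum(per_pi[[k]]$ds$mask),
                 nCDS = m$nCDS, nC_notDS = m$nC_notDS, nIDS = m$nIDS,
                 nI_notDS = m$nI_notDS, R1 = m$R1, R2 = m$R2, R3 = m$R3)
    }))
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "runs") <- runs
  out
}
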