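# Relative plasmid copy number from colony qPCR. The estimator follows the
# standard efficiency-corrected delta-Ct model:
#
#   CN          = 2^-(Ct_plasmid - Ct_gDNA)
#   CN_adjusted = CN * (A_gDNA / A_plasmid)
#
# where A is the per-cycle amplification factor of a primer pair (perfect
# doubling A = 2), estimated per well by log-linear regression over the
# exponential phase of the fluorescence curve. The factor interpretation of
# "efficiency" keeps the correction dimensionally coherent with the base-2
# delta-Ct term.

.check_curve <- function(fluorescence, cycles) {
  if (is.data.frame(fluorescence)) {
    cycles <- fluorescence$cycle
    fluorescence <- fluorescence$value
  }
  if (is.null(cycles)) cycles <- seq_along(fluorescence)
  if (length(cycles) != length(fluorescence))
    .stopf("cycles and fluorescence must have equal length")
  if (any(diff(cycles) <= 0)) .stopf("cycles must be strictly increasing")
  list(cycles = as.numeric(cycles), values = as.numeric(fluorescence))
}

#' Quantification cycle (Ct) of an amplification curve
#'
#' The fractional cycle at which fluorescence first crosses `threshold`,
#' by linear interpolation between the bracketing cycles.
#'
#' @param fluorescence Numeric vector of fluorescence values, or a
#'   `data.frame` with columns `cycle` and `value`.
#' @param threshold Fluorescence threshold; must lie above the baseline
#'   (the first value) and be reached by the curve.
#' @param cycles Cycle numbers (defaults to `seq_along(fluorescence)`).
#' @param log_scale If `TRUE`, interpolate between the bracketing cycles on
#'   the log-fluorescence scale instead of linearly. Log interpolation is
#'   exact for exponential growth and is what [estimate_copy_number()] uses
#'   on baseline-subtracted curves; the default is plain linear
#'   interpolation.
#' @return Ct as a numeric scalar.
#' @export
#' @examples
#' compute_ct(2^(1:20), threshold = 1024)   # 10
compute_ct <- function(fluorescence, threshold, cycles = NULL,
                       log_scale = FALSE) {
  cv <- .check_curve(fluorescence, cycles)
  if (!is.finite(threshold)) .stopf("threshold must be finite")
  if (threshold <= cv$values[1])
    .stopf("invalid threshold: %.4g is at or below the first-cycle baseline %.4g",
           threshold, cv$values[1])
  above <- which(cv$values >= threshold)
  if (length(above) == 0)
    .stopf("no amplification: curve never reaches threshold %.4g", threshold)
  i <- above[1]
  if (log_scale && cv$values[i - 1] > 0) {
    cv$cycles[i - 1] + (log(threshold) - log(cv$values[i - 1])) /
      (log(cv$values[i]) - log(cv$values[i - 1])) * (cv$cycles[i] - cv$cycles[i - 1])
  } else {
    cv$cycles[i - 1] + (threshold - cv$values[i - 1]) /
      (cv$values[i] - cv$values[i - 1]) * (cv$cycles[i] - cv$cycles[i - 1])
  }
}

# Baseline level of a curve: mean of the first nb cycles when that stretch
# is flat (CV < 0.2), else 0 (no resolvable flat baseline).
.curve_baseline <- function(values, nb = 5L) {
  nb <- min(nb, length(values))
  m <- mean(values[1:nb]); s <- stats::sd(values[1:nb])
  if (is.finite(m) && m > 0 && is.finite(s) && s / m < 0.2) m else 0
}

#' Per-well amplification factor from the exponential phase
#'
#' Estimates the per-cycle amplification factor A of one well by a
#' log-linear regression over the exponential phase of the fluorescence
#' curve; the factor is `exp(slope)` of the fitted natural-log slope
#' (equivalently `10^slope` on a log10 fit).
#'
#' Window and fitting rules (config-exposed; window and fit quality are
#' returned for auditability):
#' \itemize{
#'   \item A baseline level and its noise SD come from the first
#'     `baseline_cycles` cycles when that stretch is flat (coefficient of
#'     variation below 0.2); otherwise the curve is treated as
#'     baseline-free.
#'   \item The window is the first run of at least `window_min` consecutive
#'     baseline-subtracted points exceeding `start_sd_mult` baseline SDs
#'     above baseline, capped at `window_max` points and at `plateau_frac`
#'     of the curve maximum. Isolated noise spikes above the detection
#'     floor are skipped; no qualifying run is an error.
#'   \item When the curve has resolved its plateau (flat final cycles), the
#'     saturating dynamic is removed exactly by the logistic linearization
#'     `log(y / (K - y))`, which is linear in cycle with slope `log(A)` for
#'     logistic growth to plateau K; otherwise plain `log(y)` is fitted,
#'     which is exact for unsaturated exponential growth.
#'   \item The fit is weighted by the delta-method precision of each log
#'     point under additive fluorescence noise (weight proportional to
#'     `y^2`, or `(y(K-y)/K)^2` under the logistic transform), so
#'     barely-detectable early points do not dominate the slope.
#' }
#' A fit with weighted R-squared below 0.98 is flagged low confidence.
#'
#' @inheritParams compute_ct
#' @param baseline_cycles,start_sd_mult,plateau_frac,window_min,window_max
#'   Window-rule parameters (see Details).
#' @return A list with `A` (amplification factor per cycle), `window`
#'   (cycles used), `r_squared`, `baseline`, `plateau` (`NA` when the curve
#'   never flattens) and `low_confidence`.
#' @export
estimate_efficiency <- function(fluorescence, cycles = NULL,
                                baseline_cycles = 5L, start_sd_mult = 3,
                                plateau_frac = 0.5, window_min = 4L,
                                window_max = 10L) {
  cv <- .check_curve(fluorescence, cycles)
  n <- length(cv$values)
  if (n < 10)
    .stopf("curve-based efficiency estimation needs at least 10 cycles")
  nb <- min(baseline_cycles, n)
  b_mean <- mean(cv$values[1:nb]); b_sd <- stats::sd(cv$values[1:nb])
  flat <- is.finite(b_mean) && b_mean > 0 && b_sd / b_mean < 0.2
  baseline <- if (flat) b_mean else 0
  floor_level <- if (flat) b_mean + start_sd_mult * b_sd else -Inf

  y <- cv$values - baseline
  tail5 <- y[max(1, n - 4):n]
  plateau_resolved <- mean(tail5) > 0 && stats::sd(tail5) / mean(tail5) < 0.02 &&
    max(y) <= mean(tail5) * 1.05
  K <- if (plateau_resolved) mean(tail5) else Inf

  eligible <- which(cv$values > floor_level & y > 0 &
                      y <= plateau_frac * max(y) & y < K)
  if (!length(eligible)) .stopf("insufficient exponential phase: no eligible points")
  runs <- split(eligible, cumsum(c(1L, diff(eligible) != 1L)))
  win <- NULL
  for (r in runs) {
    if (length(r) >= window_min) {
      win <- r[seq_len(min(length(r), window_max))]
      break
    }
  }
  if (is.null(win))
    .stopf("insufficient exponential phase: longest eligible run has %d points (need %d)",
           max(lengths(runs)), window_min)
  yy <- y[win]
  if (is.finite(K)) {
    z <- yy / (K - yy); wts <- (yy * (K - yy) / K)^2
  } else {
    z <- yy; wts <- yy^2
  }
  fit <- stats::lm(log(z) ~ cv$cycles[win], weights = wts)
  r2 <- summary(fit)$r.squared
  list(A = exp(unname(stats::coef(fit)[2])), window = cv$cycles[win],
       r_squared = r2, baseline = baseline,
       plateau = if (is.finite(K)) K else NA_real_,
       low_confidence = is.finite(r2) && r2 < 0.98)
}

#' Raw relative copy number from a Ct pair
#'
#' `CN = 2^-(Ct_plasmid - Ct_gDNA)`: plasmid copies per genome copy under
#' perfect doubling.
#'
#' @param ct_plasmid,ct_gdna Quantification cycles (finite, > 0).
#' @return Numeric copy number (vectorised).
#' @export
#' @examples
#' copy_number_raw(20, 25)  # 32
copy_number_raw <- function(ct_plasmid, ct_gdna) {
  if (any(!is.finite(ct_plasmid)) || any(!is.finite(ct_gdna)))
    .stopf("Ct values must be finite")
  2^(-(ct_plasmid - ct_gdna))
}

#' Efficiency-corrected copy number
#'
#' `CN_adjusted = CN * (A_gDNA / A_plasmid)` where A is the per-cycle
#' amplification factor of each primer pair (perfect doubling A = 2).
#'
#' @param cn Raw copy number from [copy_number_raw()].
#' @param a_gdna,a_plasmid Amplification factors, each in (1, 2.2].
#' @return Numeric adjusted copy number (vectorised).
#' @export
#' @examples
#' copy_number_adjusted(32, 1.9, 2.0)  # 30.4
copy_number_adjusted <- function(cn, a_gdna, a_plasmid) {
  for (a in list(a_gdna, a_plasmid))
    if (any(!is.finite(a) | a <= 1 | a > 2.2))
      .stopf("amplification factors must lie in (1, 2.2]")
  cn * (a_gdna / a_plasmid)
}

#' Aggregate per-pairing copy numbers for one sample
#'
#' Summarizes the adjusted copy-number values from all replicate x dilution
#' pairings of a sample: median, quartiles (linear-interpolation
#' convention), mean, sample SD and the nearest-integer rounding of the
#' mean (the headline "relative copy number").
#'
#' @param values Numeric vector of per-pairing `CN_adjusted` values (> 0).
#' @param sample Optional sample label.
#' @param by_replicate Optional factor (e.g. biological replicate) of the
#'   same length; when given, a second SD across replicate means is also
#'   reported (`sd_replicates`), since spread can be quoted either across
#'   all pairings or across biological replicates.
#' @return An object of class `cn_estimate`.
#' @export
aggregate_copy_number <- function(values, sample = NULL, by_replicate = NULL) {
  values <- values[!is.na(values)]
  if (length(values) == 0) .stopf("no copy-number values to aggregate")
  if (any(values <= 0)) .stopf("copy-number values must be positive")
  single <- length(values) == 1
  sdv <- if (single) 0 else stats::sd(values)
  sd_rep <- NA_real_
  if (!is.null(by_replicate)) {
    mr <- tapply(values, by_replicate, mean)
    sd_rep <- if (length(mr) > 1) stats::sd(mr) else 0
  }
  structure(list(
    sample = sample %||% NA_character_, values = values,
    median = stats::median(values),
    q1 = stats::quantile(values, 0.25, names = FALSE, type = 7),
    q3 = stats::quantile(values, 0.75, names = FALSE, type = 7),
    mean = mean(values), sd = sdv, sd_replicates = sd_rep,
    rounded = round_half_up(mean(values)),
    n = length(values), degenerate = single), class = "cn_estimate")
}

#' @export
print.cn_estimate <- function(x, ...) {
  cat(sprintf("Relative plasmid copy number%s: %d (mean %.2f +/- %.2f, median %.2f [%.2f-%.2f], n=%d%s)\n",
              if (is.na(x$sample)) "" else paste0(" [", x$sample, "]"),
              x$rounded, x$mean, x$sd, x$median, x$q1, x$q3, x$n,
              if (x$degenerate) "; single value, SD reported as 0" else ""))
  invisible(x)
}

#' Estimate relative copy numbers from a colony-qPCR well table
#'
#' The full estimation path behind a copy-number experiment: technical
#' triplicate Cts are averaged within each (sample, target, replicate,
#' dilution) stratum; plasmid and gDNA strata sharing (sample, replicate,
#' dilution) are paired (dilutions act as independent estimates of the same
#' ratio, since delta-Ct is dilution-invariant in expectation); each pairing
#' yields an efficiency-corrected copy number; pairings are aggregated per
#' sample with [aggregate_copy_number()].
#'
#' Wells either carry instrument-exported `Ct` and `efficiency` columns, or
#' raw per-cycle fluorescence is supplied via `curves`, in which case Ct
#' (common auto threshold) and per-well efficiency are computed with
#' [compute_ct()] and [estimate_efficiency()].
#'
#' @param wells `data.frame` with columns `well_id`, `target` (`"gDNA"` or
#'   `"plasmid"`), `sample`, `replicate`, `dilution`, and (unless `curves`
#'   is given) `Ct` and `efficiency`.
#' @param curves Optional long `data.frame` of raw fluorescence (`well_id`,
#'   `cycle`, `value`).
#' @param threshold `"auto"` (default: `threshold_frac` of the smallest
#'   per-well maximum, a common threshold in every well's exponential
#'   region) or a number.
#' @param threshold_frac Fraction used by the auto threshold.
#' @param efficiency_pooling `"target_mean"` (default; the amplification
#'   factor is a property of the primer pair, so per-well estimates are
#'   averaged per sample x target before correction) or `"per_well"`.
#' @return A list of class `cn_estimates`: per-sample `cn_estimate` objects
#'   (`$estimates`), plus a per-pairing audit table (`$pairings`) and the
#'   per-well table with the Ct/efficiency values used (`$wells`).
#' @export
estimate_copy_number <- function(wells, curves = NULL, threshold = "auto",
                                 threshold_frac = 0.05,
                                 efficiency_pooling = c("target_mean", "per_well")) {
  efficiency_pooling <- match.arg(efficiency_pooling)
  req <- c("well_id", "target", "sample", "replicate", "dilution")
  if (!is.data.frame(wells) || !all(req %in% names(wells)))
    .stopf("wells must be a data.frame with columns %s", paste(req, collapse = ", "))
  if (!all(wells$target %in% c("gDNA", "plasmid")))
    .stopf("target must be 'gDNA' or 'plasmid'")

  if (!is.null(curves)) {
    if (!all(c("well_id", "cycle", "value") %in% names(curves)))
      .stopf("curves must have columns well_id, cycle, value")
    split_curves <- split(curves[c("cycle", "value")], curves$well_id)
    missing <- setdiff(wells$well_id, names(split_curves))
    if (length(missing))
      .stopf("no curve data for well(s): %s", paste(missing, collapse = ", "))
    # Work on baseline-subtracted signal; Ct by log-scale interpolation at a
    # common threshold in every well's exponential region (a fraction of the
    # smallest per-well maximum).
    signal <- lapply(split_curves[unique(wells$well_id)], function(d) {
      v <- d$value[order(d$cycle)]
      list(cycles = sort(d$cycle), values = v - .curve_baseline(v))
    })
    thr <- if (identical(threshold, "auto")) {
      threshold_frac * min(vapply(signal[wells$well_id],
                                  function(d) max(d$values), numeric(1)))
    } else as.numeric(threshold)
    wells$Ct <- vapply(wells$well_id, function(w) {
      d <- signal[[w]]
      compute_ct(d$values, thr, cycles = d$cycles, log_scale = TRUE)
    }, numeric(1))
    wells$efficiency <- vapply(wells$well_id, function(w) {
      d <- split_curves[[w]]
      estimate_efficiency(d$value[order(d$cycle)], cycles = sort(d$cycle))$A
    }, numeric(1))
  }
  if (!all(c("Ct", "efficiency") %in% names(wells)))
    .stopf("wells must carry Ct and efficiency (or supply curves)")
  if (any(wells$Ct <= 0)) .stopf("Ct values must be positive")

  if (efficiency_pooling == "target_mean") {
    key <- paste(wells$sample, wells$target)
    pooled <- tapply(wells$efficiency, key, mean)
    wells$eff_used <- as.numeric(pooled[key])
  } else {
    wells$eff_used <- wells$efficiency
  }

  # Average technical replicates within (sample, target, replicate, dilution).
  strata <- stats::aggregate(wells[c("Ct", "eff_used")],
                             wells[c("sample", "target", "replicate", "dilution")],
                             mean)
  gd <- strata[strata$target == "gDNA", , drop = FALSE]
  pl <- strata[strata$target == "plasmid", , drop = FALSE]
  pairs <- merge(gd, pl, by = c("sample", "replicate", "dilution"),
                 suffixes = c("_gdna", "_plasmid"))
  unpaired <- nrow(gd) + nrow(pl) - 2L * nrow(pairs)
  if (unpaired > 0)
    .warnf("%d unpaired (sample, replicate, dilution) strata excluded", unpaired)
  if (nrow(pairs) == 0) .stopf("no plasmid/gDNA pairings found")

  pairs$cn_raw <- copy_number_raw(pairs$Ct_plasmid, pairs$Ct_gdna)
  pairs$cn_adjusted <- copy_number_adjusted(pairs$cn_raw, pairs$eff_used_gdna,
                                            pairs$eff_used_plasmid)
  pairs <- pairs[order(pairs$sample, pairs$replicate, pairs$dilution), ]
  rownames(pairs) <- NULL

  estimates <- lapply(split(pairs, pairs$sample), function(ps) {
    aggregate_copy_number(ps$cn_adjusted, sample = ps$sample[1],
                          by_replicate = ps$replicate)
  })
  structure(list(estimates = estimates, pairings = pairs, wells = wells),
            class = "cn_estimates")
}

#' @export
print.cn_estimates <- function(x, ...) {
  for (e in x$estimates) print(e)
  invisible(x)
}

#' Read a wells CSV / raw curves CSV
#'
#' `read_wells_csv()` expects columns `well_id`, `target`, `sample`,
#' `replicate`, `dilution` and optionally `Ct`, `efficiency`;
#' `read_curves_csv()` expects `well_id`, `cycle`, `value`.
#'
#' @param path CSV file path.
#' @export
read_wells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("well_id", "target", "sample", "replicate", "dilution")
  if (!all(req %in% names(df)))
    .stopf("wells CSV '%s' must have columns %s", path, paste(req, collapse = ", "))
  df
}

#' @rdname read_wells_csv
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("well_id", "cycle", "value") %in% names(df)))
    .stopf("curves CSV '%s' must have columns well_id, cycle, value", path)
  df
}
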