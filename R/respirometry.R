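#' Construct / validate an oxygen trace
#'
#' An oxygen trace is the raw intermittent-flow respirometry record: a
#' time-stamped series of chamber PO2 with phase labels (`"flush"` or
#' `"closed"`) and integer cycle indices.
#'
#' @param time_min Numeric, strictly increasing time in minutes.
#' @param po2_mmHg Numeric, non-negative PO2 in mmHg.
#' @param phase Character, `"flush"` or `"closed"`.
#' @param cycle Integer cycle index (shared by the flush and closed phase of
#'   one measurement cycle).
#' @return A `data.frame` of class `o2_trace`.
#' @export
o2_trace <- function(time_min, po2_mmHg, phase, cycle) {
  stopifnot(is.numeric(time_min), is.numeric(po2_mmHg),
            length(time_min) == length(po2_mmHg),
            length(phase) == length(time_min),
            length(cycle) == length(time_min))
  if (any(diff(time_min) <= 0))
    stop("time_min must be strictly increasing", call. = FALSE)
  if (any(po2_mmHg < 0)) stop("po2_mmHg must be >= 0", call. = FALSE)
  if (!all(phase %in% c("flush", "closed")))
    stop("phase must be 'flush' or 'closed'", call. = FALSE)
  out <- data.frame(time_min = time_min, po2_mmHg = po2_mmHg,
                    phase = as.character(phase), cycle = as.integer(cycle))
  class(out) <- c("o2_trace", "data.frame")
  out
}

#' Respirometer chamber setup
#'
#' @param v_chamber_L Respirometer volume in litres.
#' @param m_fish_kg Fish mass in kg; must be smaller than the chamber volume
#'   (water displacement makes the effective volume `v_chamber_L - m_fish_kg`,
#'   which must be positive).
#' @param conditions A [water_conditions()] object.
#' @return An object of class `chamber_setup`.
#' @examples
#' chamber_setup(2.5, 0.091, water_conditions(24, 35))
#' @export
chamber_setup <- function(v_chamber_L, m_fish_kg, conditions) {
  stopifnot(inherits(conditions, "water_conditions"),
            is.numeric(v_chamber_L), is.numeric(m_fish_kg))
  if (!(v_chamber_L > m_fish_kg && m_fish_kg > 0))
    stop("need v_chamber_L > m_fish_kg > 0", call. = FALSE)
  structure(list(v_chamber_L = v_chamber_L, m_fish_kg = m_fish_kg,
                 conditions = conditions),
            class = "chamber_setup")
}

#' Per-cycle linear regression of the PO2 decline
#'
#' Fits an ordinary least-squares line to the PO2 decline of each closed
#' phase over its final window (default the last 2 min). Cycles are flagged
#' not-retained when the regression R^2 falls below `r2_threshold`
#' (default 0.95) or the fit is degenerate (fewer than 3 points, or a
#' zero-variance PO2 record, whose R^2 carries no slope information).
#'
#' @param trace An [o2_trace()].
#' @param window_min Length of the fitting window at the end of each closed
#'   phase, minutes (default 2).
#' @param r2_threshold Minimum R^2 for a cycle to be retained (default 0.95).
#' @return A `data.frame` with one row per closed cycle: `cycle`, `slope`
#'   (mmHg/min), `intercept`, `r_squared`, `n_points`, `window_start`,
#'   `window_end`, `mean_po2`, `retained` and `flag`.
#' @export
fit_cycle_slopes <- function(trace, window_min = 2, r2_threshold = 0.95) {
  stopifnot(inherits(trace, "o2_trace"), window_min > 0)
  closed <- trace[trace$phase == "closed", , drop = FALSE]
  if (nrow(closed) == 0L) stop("trace has no closed phase", call. = FALSE)
  cycles <- sort(unique(closed$cycle))
  rows <- lapply(cycles, function(cy) {
    seg <- closed[closed$cycle == cy, , drop = FALSE]
    t_end <- max(seg$time_min)
    win <- seg[seg$time_min >= t_end - window_min, , drop = FALSE]
    base <- data.frame(cycle = cy, slope = NA_real_, intercept = NA_real_,
                       r_squared = NA_real_, n_points = nrow(win),
                       window_start = min(win$time_min),
                       window_end = t_end,
                       mean_po2 = mean(win$po2_mmHg),
                       retained = FALSE, flag = "")
    if (nrow(win) < 3L) {
      base$flag <- "too_few_points"
      return(base)
    }
    if (stats::var(win$po2_mmHg) == 0) {
      base$slope <- 0
      base$intercept <- win$po2_mmHg[1L]
      base$flag <- "constant_po2"
      return(base)
    }
    fit <- stats::lm(po2_mmHg ~ time_min, data = win)
    # R^2 computed directly (summary.lm warns on numerically perfect fits)
    r2 <- 1 - sum(stats::residuals(fit)^2) /
      sum((win$po2_mmHg - mean(win$po2_mmHg))^2)
    base$slope <- unname(stats::coef(fit)[2L])
    base$intercept <- unname(stats::coef(fit)[1L])
    base$r_squared <- r2
    base$retained <- isTRUE(r2 >= r2_threshold)
    if (!base$retained) base$flag <- "low_r_squared"
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "window_min") <- window_min
  attr(out, "r2_threshold") <- r2_threshold
  out
}

#' Oxygen uptake from a PO2 decline slope
#'
#' The closed-respirometer chamber equation: MO2 = -slope * alpha *
#' (V_chamber - M_fish) / M_fish, yielding mass-specific oxygen uptake in
#' umol kg^-1 min^-1 from a decline slope in mmHg min^-1, the oxygen
#' solubility of the water (umol L^-1 mmHg^-1) and the effective
#' respirometer volume.
#'
#' @param slope PO2 decline slope(s) in mmHg min^-1 (negative for a decline).
#' @param setup A [chamber_setup()].
#' @return MO2 in umol kg^-1 min^-1.
#' @examples
#' # slope -1 mmHg/min, alpha 1.5, V 2 L, fish 0.1 kg -> 28.5 umol/kg/min
#' @export
mo2_from_slope <- function(slope, setup) {
  stopifnot(inherits(setup, "chamber_setup"), is.numeric(slope))
  alpha <- o2_solubility(setup$conditions)
  -slope * alpha * (setup$v_chamber_L - setup$m_fish_kg) / setup$m_fish_kg
}

#' Build an MO2 series from per-cycle regressions
#'
#' Applies the chamber equation to each cycle regression, carrying over the
#' retention flags from the R^2 filter.
#'
#' @param regressions Output of [fit_cycle_slopes()].
#' @param setup A [chamber_setup()].
#' @return A `data.frame` of class `mo2_series`: `cycle`, `time_min` (window
#'   midpoint), `mo2` (umol kg^-1 min^-1), `mean_po2`, `r_squared`,
#'   `retained`, `background_corrected`, `flag`.
#' @export
mo2_series <- function(regressions, setup) {
  stopifnot(is.data.frame(regressions), inherits(setup, "chamber_setup"))
  out <- data.frame(
    cycle = regressions$cycle,
    time_min = (regressions$window_start + regressions$window_end) / 2,
    mo2 = mo2_from_slope(regressions$slope, setup),
    mean_po2 = regressions$mean_po2,
    r_squared = regressions$r_squared,
    retained = regressions$retained,
    background_corrected = FALSE,
    flag = regressions$flag)
  class(out) <- c("mo2_series", "data.frame")
  out
}

#' Subtract background (microbial) respiration
#'
#' Background oxygen consumption is measured in the empty chamber before and
#' after the trial; the correction assumes a linear increase in background
#' rate over the measurement interval and subtracts the time-interpolated
#' rate from every record. Records driven negative by the correction are
#' flagged (`"negative_after_background"`) but kept.
#'
#' @param series An [mo2_series()].
#' @param pre_rate,post_rate Background rates in the same mass-specific units
#'   as the series (umol kg^-1 min^-1), measured at `t_start` and `t_end`.
#' @param t_start,t_end Times (min) bracketing the series at which the pre
#'   and post background rates apply.
#' @return The corrected `mo2_series` with `background_corrected = TRUE`.
#' @export
background_correct <- function(series, pre_rate, post_rate, t_start, t_end) {
  stopifnot(inherits(series, "mo2_series"), t_end > t_start)
  if (any(series$time_min < t_start - 1e-9) ||
      any(series$time_min > t_end + 1e-9))
    stop("background rates must bracket the series in time", call. = FALSE)
  if (post_rate < pre_rate)
    message("background_correct: declining background rate (unusual)")
  frac <- (series$time_min - t_start) / (t_end - t_start)
  bg <- pre_rate + frac * (post_rate - pre_rate)
  series$mo2 <- series$mo2 - bg
  series$background_corrected <- TRUE
  neg <- series$mo2 < 0 & series$retained
  series$flag[neg] <- "negative_after_background"
  series
}

#' Construct an SMR estimate directly from a known value
#'
#' Used when the standard metabolic rate is known a priori (e.g. the ground
#' truth of a simulation) rather than estimated from a trace.
#'
#' @param value SMR in umol kg^-1 min^-1.
#' @param units Unit label (default `"umol_kg_min"`).
#' @return An object of class `smr_estimate`.
#' @export
smr_estimate <- function(value, units = "umol_kg_min") {
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  structure(list(value = value, quantile_fraction = NA_real_,
                 n_used = NA_integer_, units = units),
            class = "smr_estimate")
}

#' @export
print.smr_estimate <- function(x, ...) {
  cat(sprintf("<smr_estimate> %.3f %s", x$value, x$units))
  if (!is.na(x$n_used))
    cat(sprintf(" (mean of lowest %d%% = %d records)",
                round(100 * x$quantile_fraction), x$n_used))
  cat("\n")
  invisible(x)
}

#' Standard metabolic rate as the lowest-decile mean
#'
#' SMR is the mean of the lowest `quantile_fraction` (default 10%) of the
#' retained, background-corrected MO2 records; the count is
#' `ceiling(fraction * n)` so at least one record is always used.
#'
#' @param series An [mo2_series()].
#' @param quantile_fraction Fraction of lowest records averaged (default 0.10).
#' @return An `smr_estimate` with `value` (umol kg^-1 min^-1),
#'   `quantile_fraction`, `n_used` and `units`.
#' @export
estimate_smr <- function(series, quantile_fraction = 0.10) {
  stopifnot(inherits(series, "mo2_series"),
            quantile_fraction > 0, quantile_fraction <= 1)
  vals <- series$mo2[series$retained]
  if (length(vals) < 10L)
    stop(sprintf("estimate_smr needs >= 10 retained records, got %d",
                 length(vals)), call. = FALSE)
  k <- ceiling(quantile_fraction * length(vals))
  lowest <- sort(vals)[seq_len(k)]
  structure(list(value = mean(lowest), quantile_fraction = quantile_fraction,
                 n_used = k, units = "umol_kg_min"),
            class = "smr_estimate")
}

#' Critical oxygen tension from a closed Pcrit run
#'
#' Partitions an uninterrupted closed run into consecutive, non-overlapping
#' bins of `bin_minutes` (default 2), computes each bin's MO2 from its OLS
#' decline slope via the chamber equation, and locates the PO2 at which MO2
#' is first reduced below the SMR.
#'
#' The reported `value` interpolates MO2 linearly between the last bin at or
#' above SMR and the first below (the crossing of the longest below-SMR run
#' when noise induces several). When the upstream bin lies on the regulation
#' plateau (MO2 equal to SMR within numerical tolerance) the crossing is
#' unidentifiable within the bracketing segment and the first below-SMR
#' bin's mean PO2 is taken instead. The conservative first-bin-below value
#' is always reported alongside (`value_first_below`). If MO2 never drops
#' below SMR the estimate is censored at the minimum observed PO2.
#'
#' @param closed_run An [o2_trace()] consisting of a single closed run.
#' @param smr An `smr_estimate` in umol kg^-1 min^-1 (the SMR measured for
#'   the same individual immediately prior).
#' @param setup A [chamber_setup()].
#' @param bin_minutes Bin length in minutes (default 2).
#' @param r2_threshold R^2 retention threshold for the per-bin fits.
#' @return An object of class `pcrit_estimate`: `value` (mmHg), `method`,
#'   `value_first_below`, `censored`, `bin_minutes` and a `diagnostics`
#'   data.frame of per-bin MO2 and PO2.
#' @export
estimate_pcrit <- function(closed_run, smr, setup, bin_minutes = 2,
                           r2_threshold = 0.95) {
  stopifnot(inherits(closed_run, "o2_trace"),
            inherits(smr, "smr_estimate"),
            inherits(setup, "chamber_setup"), bin_minutes > 0)
  if (!identical(smr$units, "umol_kg_min"))
    stop("smr must be in umol_kg_min units", call. = FALSE)
  seg <- closed_run[closed_run$phase == "closed", , drop = FALSE]
  if (nrow(seg) < 6L) stop("closed run too short", call. = FALSE)
  t0 <- min(seg$time_min)
  bin_idx <- floor((seg$time_min - t0) / bin_minutes)
  # drop a trailing fragment shorter than half a bin
  last <- max(bin_idx)
  keep <- bin_idx < last |
    (sum(bin_idx == last) * stats::median(diff(seg$time_min)) >= bin_minutes / 2)
  seg <- seg[keep, , drop = FALSE]
  bin_idx <- bin_idx[keep]
  pseudo <- o2_trace(seg$time_min, seg$po2_mmHg,
                     rep("closed", nrow(seg)), bin_idx)
  regs <- fit_cycle_slopes(pseudo, window_min = bin_minutes,
                           r2_threshold = r2_threshold)
  bins <- mo2_series(regs, setup)
  usable <- bins[!is.na(bins$mo2), , drop = FALSE]
  smr_val <- smr$value
  # plateau tie tolerance: bins whose MO2 equals SMR to rounding count as above
  tol <- 1e-6 * smr_val
  below <- usable$mo2 < smr_val - tol
  diag <- data.frame(bin = usable$cycle, time_min = usable$time_min,
                     mo2 = usable$mo2, mean_po2 = usable$mean_po2,
                     r_squared = usable$r_squared, below_smr = below)
  res <- list(value = NA_real_, method = "first-crossing-interpolated",
              value_first_below = NA_real_, censored = FALSE,
              smr = smr_val, bin_minutes = bin_minutes, diagnostics = diag)
  if (!any(below)) {
    res$value <- min(closed_run$po2_mmHg)
    res$value_first_below <- res$value
    res$censored <- TRUE
    class(res) <- "pcrit_estimate"
    return(res)
  }
  # maximal runs of consecutive below-SMR bins; crossing of the longest run
  # (ties resolved to the latest), robust to isolated noisy bins
  r <- rle(below)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  cand <- which(r$values & run_start > 1L)
  if (length(cand) == 0L) {
    # series starts below SMR: pure conformer from the first bin
    first_lo <- 1L
    res$value <- usable$mean_po2[first_lo]
    res$value_first_below <- res$value
    class(res) <- "pcrit_estimate"
    return(res)
  }
  best <- cand[which.max(r$lengths[cand] + seq_along(r$lengths)[cand] * 1e-9)]
  i_lo <- run_start[best]
  i_hi <- i_lo - 1L
  mo2_hi <- usable$mo2[i_hi]; mo2_lo <- usable$mo2[i_lo]
  po2_hi <- usable$mean_po2[i_hi]; po2_lo <- usable$mean_po2[i_lo]
  res$value_first_below <- po2_lo
  if (mo2_hi <= smr_val + tol) {
    # upstream bin on the regulation plateau: crossing unidentifiable within
    # the segment; take the point where conformity is first observed
    res$value <- po2_lo
  } else {
    lambda <- (mo2_hi - smr_val) / (mo2_hi - mo2_lo)
    res$value <- po2_hi + lambda * (po2_lo - po2_hi)
  }
  class(res) <- "pcrit_estimate"
  res
}

#' @export
print.pcrit_estimate <- function(x, ...) {
  cat(sprintf("<pcrit_estimate> %.2f mmHg (%s%s; first-bin-below %.2f; %g-min bins)\n",
              x$value, x$method, if (x$censored) ", censored" else "",
              x$value_first_below, x$bin_minutes))
  invisible(x)
}
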