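# Run code with a locally-set RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Fish model for trace simulation
#'
#' The ground-truth animal behind a simulated respirometry trace: an
#' oxyregulator above its critical tension and a linear (through-the-origin)
#' oxyconformer below it, with optional spontaneous-activity bursts.
#'
#' @param smr_true True standard metabolic rate, umol kg^-1 min^-1.
#' @param pcrit_true True critical oxygen tension, mmHg.
#' @param mass_kg Fish mass, kg.
#' @param activity_rate Spontaneous activity bursts per hour (Poisson rate;
#'   default 0).
#' @param activity_magnitude Burst size as a multiple of SMR added on top of
#'   it (>= 0); bursts only ever raise MO2, so the lowest-decile SMR
#'   estimator stays unbiased.
#' @param burst_min Duration of one activity burst, minutes (default 1).
#' @return An object of class `fish_model`.
#' @export
fish_model <- function(smr_true, pcrit_true, mass_kg,
                       activity_rate = 0, activity_magnitude = 0,
                       burst_min = 1) {
  stopifnot(smr_true > 0, pcrit_true > 0, mass_kg > 0,
            activity_rate >= 0, activity_magnitude >= 0, burst_min > 0)
  structure(list(smr_true = smr_true, pcrit_true = pcrit_true,
                 mass_kg = mass_kg, activity_rate = activity_rate,
                 activity_magnitude = activity_magnitude,
                 burst_min = burst_min),
            class = "fish_model")
}

#' Trace simulation configuration
#'
#' @param chamber_volume_L Respirometer volume, L.
#' @param flush_min,closed_min Flush and closed phase lengths, minutes
#'   (defaults 3 and 3, one 6-min measurement cycle).
#' @param duration_h Total trace duration, hours.
#' @param ambient_po2 Ambient (fully flushed) PO2, mmHg (default 150).
#' @param background_rate_start,background_rate_end Chamber-level background
#'   (microbial) O2 consumption at the start and end of the trace,
#'   umol min^-1; interpolated linearly in time between them (defaults 0).
#' @param noise_sd Gaussian measurement noise added to sampled PO2, mmHg.
#' @param conditions A [water_conditions()] object (default 24 degC, 35 psu).
#' @param dt_s Integration and sampling step, seconds (default 1).
#' @param seed Integer seed; a fixed seed makes the output bit-reproducible.
#' @return An object of class `trace_sim_config`.
#' @export
trace_sim_config <- function(chamber_volume_L, flush_min = 3, closed_min = 3,
                             duration_h = 20, ambient_po2 = 150,
                             background_rate_start = 0,
                             background_rate_end = 0,
                             noise_sd = 0.2,
                             conditions = water_conditions(24, 35),
                             dt_s = 1, seed = NULL) {
  stopifnot(chamber_volume_L > 0, flush_min > 0, closed_min > 0,
            duration_h > 0, ambient_po2 > 0, noise_sd >= 0,
            dt_s > 0, dt_s <= 1,
            inherits(conditions, "water_conditions"))
  structure(list(chamber_volume_L = chamber_volume_L, flush_min = flush_min,
                 closed_min = closed_min, duration_h = duration_h,
                 ambient_po2 = ambient_po2,
                 background_rate_start = background_rate_start,
                 background_rate_end = background_rate_end,
                 noise_sd = noise_sd, conditions = conditions,
                 dt_s = dt_s, seed = seed),
            class = "trace_sim_config")
}

# Instantaneous mass-specific MO2 (umol/kg/min) of the regulator/conformer
# model: SMR (x activity factor) at or above pcrit, proportional to PO2 below.
.fish_mo2 <- function(po2, fish, act_factor) {
  fish$smr_true * act_factor * min(1, po2 / fish$pcrit_true)
}

# Per-step activity factor vector (1 outside bursts, 1 + magnitude inside).
.activity_factors <- function(fish, n_steps, dt_min) {
  act <- rep(1, n_steps)
  if (fish$activity_rate > 0 && fish$activity_magnitude > 0) {
    total_min <- n_steps * dt_min
    n_bursts <- stats::rpois(1, fish$activity_rate * total_min / 60)
    if (n_bursts > 0) {
      starts <- sort(stats::runif(n_bursts, 0, total_min))
      for (s in starts) {
        i0 <- max(1L, ceiling(s / dt_min))
        i1 <- min(n_steps, ceiling((s + fish$burst_min) / dt_min))
        act[i0:i1] <- 1 + fish$activity_magnitude
      }
    }
  }
  act
}

# Shared Euler integrator. phase_fun(t_min) -> "flush" | "closed".
.integrate_trace <- function(fish, cfg, n_steps, phase_fun, cycle_fun,
                             stop_po2 = NULL) {
  dt_min <- cfg$dt_s / 60
  alpha <- o2_solubility(cfg$conditions)
  eff_vol <- cfg$chamber_volume_L - fish$mass_kg
  if (eff_vol <= 0)
    stop("chamber volume must exceed fish volume (mass in kg ~ L)",
         call. = FALSE)
  denom <- alpha * eff_vol
  tau_flush <- cfg$flush_min / 4   # flush relaxation time constant
  total_min <- n_steps * dt_min
  act <- .activity_factors(fish, n_steps, dt_min)
  bg0 <- cfg$background_rate_start
  bg_slope <- (cfg$background_rate_end - bg0) / total_min

  time_min <- numeric(n_steps)
  po2 <- numeric(n_steps)
  phase <- character(n_steps)
  cycle <- integer(n_steps)
  consumed <- numeric(n_steps)  # umol removed by fish+background this step
  p <- cfg$ambient_po2
  clipped <- FALSE
  n_used <- n_steps
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt_min
    ph <- phase_fun(t)
    time_min[i] <- t
    po2[i] <- p
    phase[i] <- ph
    cycle[i] <- cycle_fun(t)
    if (ph == "closed") {
      mo2 <- .fish_mo2(p, fish, act[i])
      bg <- bg0 + bg_slope * t
      cons <- (mo2 * fish$mass_kg + bg) * dt_min
      consumed[i] <- cons
      p <- p - cons / denom
      if (p < 0) { p <- 0; clipped <- TRUE }
    } else {
      p <- p + (cfg$ambient_po2 - p) * (1 - exp(-dt_min / tau_flush))
    }
    if (!is.null(stop_po2) && p < stop_po2) { n_used <- i; break }
  }
  reached_stop <- is.null(stop_po2) || n_used < n_steps
  idx <- seq_len(n_used)
  noise <- if (cfg$noise_sd > 0)
    stats::rnorm(n_used, 0, cfg$noise_sd) else numeric(n_used)
  tr <- o2_trace(time_min[idx], pmax(0, po2[idx] + noise),
                 phase[idx], cycle[idx])
  attr(tr, "clipped") <- clipped
  # per-cycle closed-phase oxygen budget (noiseless state, for conservation
  # checks): umol removed vs. effective-volume PO2 drop
  cl <- phase[idx] == "closed"
  if (any(cl)) {
    budgets <- lapply(split(which(cl), cycle[idx][cl]), function(ii) {
      i0 <- min(ii); i1 <- max(ii)
      p_end <- if (i1 < n_used) po2[i1 + 1L] else
        po2[i1] - consumed[i1] / denom
      data.frame(cycle = cycle[i0],
                 o2_removed_umol = sum(consumed[ii]),
                 po2_drop_umol = denom * (po2[i0] - p_end))
    })
    attr(tr, "o2_budget") <- do.call(rbind, c(budgets,
                                              make.row.names = FALSE))
  }
  attr(tr, "alpha") <- alpha
  attr(tr, "reached_stop") <- reached_stop
  tr
}

#' Simulate an intermittent-flow respirometry trace
#'
#' Integrates chamber PO2 through alternating flush and closed phases with a
#' forward-Euler scheme at `dt_s` (default 1 s) steps. During closed phases
#' `dPO2/dt = -(MO2 * M_f + background(t)) / (alpha * (V - M_f))`, with the
#' fish an oxyregulator at `smr_true` (plus activity bursts) above
#' `pcrit_true` and a linear oxyconformer below it; flush phases relax PO2
#' exponentially back toward ambient. Gaussian noise of sd `noise_sd` is
#' added to the sampled PO2 only (not the state). PO2 is clipped at zero and
#' the trace flagged (attribute `"clipped"`) if a step would go negative.
#'
#' @param fish A [fish_model()].
#' @param cfg A [trace_sim_config()].
#' @return An [o2_trace()] with attributes `o2_budget` (per-cycle oxygen
#'   bookkeeping), `alpha` and `clipped`.
#' @export
simulate_trace <- function(fish, cfg) {
  stopifnot(inherits(fish, "fish_model"), inherits(cfg, "trace_sim_config"))
  with_seed(cfg$seed, {
    dt_min <- cfg$dt_s / 60
    n_steps <- floor(cfg$duration_h * 60 / dt_min)
    cyc_len <- cfg$flush_min + cfg$closed_min
    phase_fun <- function(t) if ((t %% cyc_len) < cfg$flush_min)
      "flush" else "closed"
    cycle_fun <- function(t) as.integer(t %/% cyc_len) + 1L
    .integrate_trace(fish, cfg, n_steps, phase_fun, cycle_fun)
  })
}

#' Simulate a closed-circuit Pcrit run
#'
#' A single uninterrupted closed phase from ambient PO2 down past
#' `stop_po2`, under the same regulator/conformer fish model as
#' [simulate_trace()].
#'
#' @param fish A [fish_model()].
#' @param cfg A [trace_sim_config()]; `duration_h` caps the run length.
#' @param stop_po2 PO2 (mmHg) below which the run stops; must be below
#'   ambient.
#' @return An [o2_trace()] consisting of one closed phase.
#' @export
simulate_closed_pcrit_run <- function(fish, cfg, stop_po2) {
  stopifnot(inherits(fish, "fish_model"), inherits(cfg, "trace_sim_config"))
  if (stop_po2 >= cfg$ambient_po2)
    stop("stop_po2 must be below ambient_po2", call. = FALSE)
  with_seed(cfg$seed, {
    dt_min <- cfg$dt_s / 60
    n_steps <- floor(cfg$duration_h * 60 / dt_min)
    tr <- .integrate_trace(fish, cfg, n_steps,
                           phase_fun = function(t) "closed",
                           cycle_fun = function(t) 1L,
                           stop_po2 = stop_po2)
    if (!isTRUE(attr(tr, "reached_stop")))
      warning("run ended before reaching stop_po2; increase duration_h")
    tr
  })
}
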