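# Synthetic nitrite time series from ammonia-oxidizer batch cultures.
#
# The control culture accumulates nitrite along a logistic curve toward a
# carrying concentration K (the simplest saturating form; its rate constant is
# parameterized so the peak production rate equals `max_rate`). An inhibitor
# added at `addition_time` multiplies the instantaneous production rate by
#   1 - f * 2^(-(t - t_add)/t_half),
# i.e. an initial fractional suppression f that relaxes back with half-time
# t_half (t_half = Inf encodes persistent inhibition; finite values mimic the
# transient inhibition seen for recoverable compounds). Replicates differ only
# by Gaussian observation noise.

#' Parameters for the culture simulator
#'
#' @param baseline_nitrite initial nitrite concentration (uM); must be > 0
#'   for the logistic curve to grow.
#' @param max_rate peak nitrite production rate (uM/h).
#' @param carrying_nitrite saturation nitrite concentration K (uM).
#' @param addition_time time of inhibitor addition (h); must fall inside
#'   the observation window.
#' @param inhibition_fraction initial fractional rate suppression f in [0, 1].
#' @param recovery_halftime half-time of inhibition decay (h); Inf =
#'   persistent inhibition.
#' @param noise_sd observation noise standard deviation (uM).
#' @param n_replicates replicate cultures per treatment.
#' @param timepoints sampling times (h), strictly increasing.
#' @param seed integer seed for the observation noise.
#' @param strain strain identifier; prefix "AOA"/"AOB" tags the domain.
#' @param compound treated-culture compound identifier.
#' @param dose applied dose (mg/L), recorded in the output.
#' @param control control treatment name (solvent control by default).
#' @return validated parameter list of class \code{culture_sim_params}.
#' @export
cultureSimParams <- function(baseline_nitrite = 5,
                             max_rate = 5,
                             carrying_nitrite = 500,
                             addition_time = 48,
                             inhibition_fraction = 0.9,
                             recovery_halftime = Inf,
                             noise_sd = 5,
                             n_replicates = 3L,
                             timepoints = seq(0, 240, by = 12),
                             seed = 1L,
                             strain = "AOA_Nsp1",
                             compound = "cpd_001",
                             dose = 20,
                             control = "DMSO") {
  p <- list(baseline_nitrite = baseline_nitrite, max_rate = max_rate,
            carrying_nitrite = carrying_nitrite, addition_time = addition_time,
            inhibition_fraction = inhibition_fraction,
            recovery_halftime = recovery_halftime, noise_sd = noise_sd,
            n_replicates = as.integer(n_replicates), timepoints = timepoints,
            seed = as.integer(seed), strain = strain, compound = compound,
            dose = dose, control = control)
  validate_culture_params(p)
  class(p) <- "culture_sim_params"
  p
}

validate_culture_params <- function(p) {
  if (any(diff(p$timepoints) <= 0)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  if (p$inhibition_fraction < 0 || p$inhibition_fraction > 1) {
    stop("inhibition_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p$baseline_nitrite <= 0) stop("baseline_nitrite must be > 0", call. = FALSE)
  if (p$carrying_nitrite <= p$baseline_nitrite) {
    stop("carrying_nitrite must exceed baseline_nitrite", call. = FALSE)
  }
  if (p$max_rate <= 0) stop("max_rate must be > 0", call. = FALSE)
  if (p$addition_time < min(p$timepoints) || p$addition_time >= max(p$timepoints)) {
    stop("addition_time must lie within [min(timepoints), max(timepoints))",
         call. = FALSE)
  }
  if (p$recovery_halftime <= 0) stop("recovery_halftime must be > 0", call. = FALSE)
  if (p$n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  invisible(TRUE)
}

# Deterministic (noise-free) trajectories, integrated with deSolve.
culture_trajectory <- function(p, treated) {
  r <- 4 * p$max_rate / p$carrying_nitrite
  K <- p$carrying_nitrite
  f <- if (treated) p$inhibition_fraction else 0
  mult <- function(t) {
    if (f == 0 || t < p$addition_time) return(1)
    1 - f * 2^(-(t - p$addition_time) / p$recovery_halftime)
  }
  deriv <- function(t, y, parms) list(mult(t) * r * y[1] * (1 - y[1] / K))
  times <- sort(unique(c(p$timepoints, p$addition_time)))
  out <- deSolve::ode(y = c(N = p$baseline_nitrite), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-9)
  out[match(p$timepoints, out[, "time"]), "N"]
}

#' Simulate a culture inhibition assay
#'
#' Generates nitrite time series for a solvent-control culture and a treated
#' culture sharing the same growth parameters, in the long assay format used
#' throughout the package (one row per strain x treatment x replicate x
#' timepoint). Treated and control trajectories are identical up to the
#' addition time; afterwards the treated production rate is suppressed by the
#' configured inhibition fraction with optional exponential recovery. The
#' output is deterministic under the parameter seed.
#'
#' @param params a \code{culture_sim_params} object from
#'   \code{\link{cultureSimParams}}.
#' @return data.frame with columns \code{strain}, \code{treatment},
#'   \code{dose_mg_per_L}, \code{replicate}, \code{time_h},
#'   \code{nitrite_uM}, \code{addition_time_h}.
#' @examples
#' head(simulateCulture(cultureSimParams(noise_sd = 0)))
#' @export
simulateCulture <- function(params) {
  stopifnot(inherits(params, "culture_sim_params"))
  p <- params
  ctl <- culture_trajectory(p, treated = FALSE)
  trt <- culture_trajectory(p, treated = TRUE)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(p$seed)

  one_arm <- function(traj, treatment) {
    do.call(rbind, lapply(seq_len(p$n_replicates), function(rep) {
      noise <- if (p$noise_sd > 0) stats::rnorm(length(traj), 0, p$noise_sd) else 0
      data.frame(
        strain = p$strain,
        treatment = treatment,
        dose_mg_per_L = if (treatment == p$control) 0 else p$dose,
        replicate = rep,
        time_h = p$timepoints,
        nitrite_uM = pmax(0, traj + noise),
        addition_time_h = p$addition_time,
        stringsAsFactors = FALSE
      )
    }))
  }
  out <- rbind(one_arm(ctl, p$control), one_arm(trt, p$compound))
  rownames(out) <- NULL
  out
}
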