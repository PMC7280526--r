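## Tortuosity / free-diffusivity arithmetic, DTI-based prediction of the
## tracer ADC, percent differences and the relative-l2 misfit metric.

#' Free diffusion coefficient of gadobutrol
#'
#' Literature approximation for the free (unhindered) diffusion coefficient
#' of gadobutrol (604 Da) in solution, in mm^2/s.
#' @export
D_FREE_GADOBUTROL <- 3.8e-4

#' Tortuosity and apparent diffusivity conversions
#'
#' Tortuosity relates the free and apparent diffusion coefficients of a
#' solute in tissue: `lambda = sqrt(D_free / D_ADC)`. The two functions are
#' mutual inverses.
#'
#' @param D_free free diffusion coefficient (> 0), any unit.
#' @param D_ADC apparent diffusion coefficient (> 0), same unit.
#' @param lambda tortuosity (> 0, dimensionless).
#' @return `tortuosity`: lambda; `adc_from_tortuosity`: D_ADC in the unit of
#'   `D_free`.
#' @export
#' @examples
#' tortuosity(3.8e-4, 1.28e-4)            # about 1.72
#' adc_from_tortuosity(3.8e-4, 1.72)      # about 1.3e-4 mm^2/s
tortuosity <- function(D_free, D_ADC) {
  if (any(D_free <= 0) || any(D_ADC <= 0)) stop("diffusivities must be positive")
  sqrt(D_free / D_ADC)
}

#' @rdname tortuosity
#' @export
adc_from_tortuosity <- function(D_free, lambda) {
  if (any(D_free <= 0) || any(lambda <= 0)) stop("inputs must be positive")
  D_free / lambda^2
}

#' Predict the tracer ADC from a water (DTI) ADC
#'
#' DTI measures the ADC of water, not of the contrast agent. Assuming the
#' tortuosity of the extracellular space is the same for both species (valid
#' for molecules below about 1 kDa), the tracer ADC is predicted as
#' `lambda = sqrt(D_free_water / water_ADC)` and then
#' `D_free_tracer / lambda^2`.
#'
#' @param water_ADC ADC of water from DTI (mm^2/s).
#' @param D_free_water free diffusion coefficient of water (mm^2/s); supply
#'   from configuration (temperature dependent, about 3e-3 at body
#'   temperature).
#' @param D_free_tracer free diffusion coefficient of the tracer (mm^2/s);
#'   defaults to [D_FREE_GADOBUTROL].
#' @return predicted tracer ADC in mm^2/s.
#' @export
gadobutrol_adc_from_water <- function(water_ADC, D_free_water,
                                      D_free_tracer = D_FREE_GADOBUTROL) {
  if (any(water_ADC <= 0) || any(D_free_water <= 0) || any(D_free_tracer <= 0))
    stop("inputs must be positive")
  lam <- tortuosity(D_free_water, water_ADC)
  adc_from_tortuosity(D_free_tracer, lam)
}

#' Percent difference of a simulated ADC against a reference
#'
#' @param sim_ADC simulated/estimated value.
#' @param ref_ADC reference value (> 0), e.g. DTI-derived.
#' @return `100 * (sim - ref) / ref`.
#' @export
percent_difference <- function(sim_ADC, ref_ADC) {
  if (any(ref_ADC <= 0)) stop("reference must be positive")
  100 * (sim_ADC - ref_ADC) / ref_ADC
}

#' Convert ADC values between mm^2/h and mm^2/s
#'
#' @param value positive value(s).
#' @param from,to `"mm2_h"` or `"mm2_s"`.
#' @return converted value.
#' @export
#' @examples
#' convert_adc_units(0.57, "mm2_h", "mm2_s")  # 1.58e-4, printed as 1.6e-4
convert_adc_units <- function(value, from = c("mm2_h", "mm2_s"),
                              to = c("mm2_s", "mm2_h")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (any(value <= 0)) stop("value must be positive")
  if (from == to) return(value)
  if (from == "mm2_h" && to == "mm2_s") value / 3600
  else value * 3600
}

#' Relative l2 norm of the difference between simulation and observation
#'
#' For each common observation time computes
#' `||u(t_i) - u_obs(t_i)|| / ||u_obs(t_i)||` over vertex values and returns
#' both the sum over times (the literal printed formula) and their mean (the
#' headline value when several observations are pooled).
#'
#' @param states a [state_series()] restricted to the observation times.
#' @param obs an [observation_series()] with matching times and vertex count.
#' @return list: `per_time`, `sum`, `mean`.
#' @export
rl2nd <- function(states, obs) {
  if (length(states$times) != length(obs$times) ||
      any(abs(states$times - obs$times) > 1e-9))
    stop("time sets differ")
  if (nrow(states$values) != nrow(obs$values))
    stop("vertex counts differ")
  denom <- sqrt(colSums(obs$values^2))
  if (any(denom == 0)) stop("zero-norm observation")
  num <- sqrt(colSums((states$values - obs$values)^2))
  r <- num / denom
  list(per_time = r, sum = sum(r), mean = mean(r))
}
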