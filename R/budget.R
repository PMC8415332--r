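# Droplet sample-consumption arithmetic and Poisson occupancy modelling.

#' Drop volume from diameter
#'
#' Spherical drops: `V = pi/6 d^3`. An 80 um drop holds 268.1 pl (often
#' quoted as "about 250 pl").
#'
#' @param diameter_um Drop diameter in um.
#' @return Volume in pl.
#' @examples
#' drop_volume_from_diameter(80)
#' @export
drop_volume_from_diameter <- function(diameter_um) {
  if (any(diameter_um <= 0)) stop("diameter must be > 0")
  pi / 6 * diameter_um^3 * 1e-3  # 1 um^3 = 1 fl = 1e-3 pl
}

#' Volumetric consumption rate
#'
#' @param drop_volume_pl Volume per drop, pl.
#' @param frequency_hz Dispense frequency, Hz.
#' @return Consumption in ul/min (`volume * frequency * 60 / 1e6`).
#' @examples
#' volumetric_rate(250, 60)   # 0.9 ul/min
#' volumetric_rate(250, 1200) # 18 ul/min at the recycling frequency
#' @export
volumetric_rate <- function(drop_volume_pl, frequency_hz) {
  if (any(drop_volume_pl < 0) || any(frequency_hz < 0)) {
    stop("volume and frequency must be >= 0")
  }
  drop_volume_pl * frequency_hz * 60 / 1e6
}

#' Poisson hit probability
#'
#' Probability that a probed volume holds at least one crystal:
#' `1 - exp(-lambda)` with `lambda = concentration * probed_volume`.
#'
#' @param concentration_per_nl Crystal number density, crystals/nl.
#' @param probed_volume_nl Probed volume, nl.
#' @return Probability in `[0, 1)`.
#' @export
hit_probability <- function(concentration_per_nl, probed_volume_nl) {
  if (any(concentration_per_nl < 0) || any(probed_volume_nl < 0)) {
    stop("concentration and volume must be >= 0")
  }
  1 - exp(-concentration_per_nl * probed_volume_nl)
}

#' Multi-crystal probability given a hit
#'
#' `P(N >= 2 | N >= 1)` for Poisson occupancy:
#' `(1 - exp(-l) - l exp(-l)) / (1 - exp(-l))`.
#'
#' @param lambda Poisson mean crystal count.
#' @return Conditional probability.
#' @export
multi_crystal_probability <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  p1 <- 1 - exp(-lambda)
  ifelse(p1 == 0, 0, (1 - exp(-lambda) - lambda * exp(-lambda)) / p1)
}

#' Concentration from an observed hit rate
#'
#' Inverts [hit_probability()]: `-log(1 - rate/100) / probed_volume`.
#' Assumes every probed drop is hit by the beam; a known blank-drop (miss)
#' probability can be divided out first via `miss_probability`.
#'
#' @param observed_hit_rate_pct Observed hit rate, percent, in (0, 100).
#' @param probed_volume_nl Probed volume per event, nl.
#' @param miss_probability Fraction of probed pulses that miss the drop;
#'   the hit rate is corrected to drops actually probed.
#' @return Estimated concentration, crystals/nl.
#' @export
estimate_concentration <- function(observed_hit_rate_pct, probed_volume_nl,
                                   miss_probability = 0) {
  if (probed_volume_nl <= 0) stop("probed volume must be > 0")
  if (miss_probability < 0 || miss_probability >= 1) {
    stop("miss_probability must lie in [0, 1)")
  }
  p <- observed_hit_rate_pct / 100 / (1 - miss_probability)
  if (any(observed_hit_rate_pct <= 0) || any(p >= 1)) {
    stop("hit rate must lie strictly between 0 and 100*(1-miss) percent")
  }
  -log(1 - p) / probed_volume_nl
}

#' Consumption and occupancy report
#'
#' One JSON-ready summary of the droplet budget: drop volume, volumetric
#' consumption, Poisson occupancy in the probed sub-volume, hit and
#' multi-crystal probabilities, and the concentration the observed hit
#' rate implies (when one is given).
#'
#' @param drop A [drop_model()].
#' @param concentration_per_nl Slurry concentration, crystals/nl.
#' @param observed_hit_rate_pct Optional observed hit rate for the inverse
#'   estimate.
#' @param path Optional path; when given the report is written as JSON.
#' @return A named list.
#' @export
consumption_report <- function(drop, concentration_per_nl,
                               observed_hit_rate_pct = NULL,
                               path = NULL) {
  stopifnot(inherits(drop, "drop_model"))
  vol_pl <- drop_volume_from_diameter(drop$diameter_um)
  probed_nl <- vol_pl * 1e-3 * drop$interaction_fraction
  lambda <- concentration_per_nl * probed_nl
  rep <- list(
    drop_volume_pl = vol_pl,
    rate_ul_per_min = volumetric_rate(vol_pl, drop$dispense_rate_hz),
    probed_volume_nl = probed_nl,
    lambda = lambda,
    p_hit = hit_probability(concentration_per_nl, probed_nl),
    p_multi_given_hit = multi_crystal_probability(lambda),
    estimated_concentration_per_nl =
      if (is.null(observed_hit_rate_pct)) NA_real_ else
        estimate_concentration(observed_hit_rate_pct, probed_nl,
                               drop$miss_probability))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  rep
}
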