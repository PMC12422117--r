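# Class-conditional effect profiles: the deconvolution statistics reported for
# adult and pediatric asthmatic (A) vs non-asthmatic (NA) groups, used both as
# the ground truth of the cohort simulator and as reference values for the
# group-comparison arithmetic.

# Published per-order component statistics. `order_label` is kept exactly as
# printed (the pediatric table labels its third block "3"); `order_index` is
# the 0-based component index actually used by the code.
published_deconv_table <- function(age_group = c("adult", "pediatric")) {
  age_group <- match.arg(age_group)
  if (age_group == "adult") {
    df <- data.frame(
      order_label = rep(c("0", "1", "2"), each = 2),
      order_index = rep(0:2, each = 2),
      class = rep(c("asthmatic", "control"), 3),
      amplitude = c(0.00258, 0.00084, 327.86, 0.0027, 343.15, 173.91),
      mean      = c(0.026, 0.0085, 17.04, 0.088, 27.61, 24.18),
      sd        = c(1.022, 1.0075, 4.51, 1.34, 8.97, 7.82),
      fwhm      = c(2.41, 2.37, 10.61, 3.15, 21.12, 18.42),
      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      order_label = rep(c("0", "1", "3"), each = 2),
      order_index = rep(0:2, each = 2),
      class = rep(c("asthmatic", "control"), 3),
      amplitude = c(643.18, 0.000774, 6.02e-10, 150.33, 612.02, 497.99),
      mean      = c(15.52, 0.13, 5.08e-09, 21.56, 27.85, 16.56),
      sd        = c(3.51, 1.31, 4.96, 0.99, 42.11, 9.26),
      fwhm      = c(8.26, 3.17, 11.68, 2.35, 21.81, 19.18),
      stringsAsFactors = FALSE)
  }
  df$age_group <- age_group
  df
}

#' Default effect profile for an age group
#'
#' Builds the [effect profile][validate_profile] whose per-order Gaussian
#' component statistics (amplitude, mean, SD per class) equal the published
#' adult or pediatric deconvolution values, together with capnogram shape
#' parameters (square/trapezoid for controls, "shark-fin" for asthmatics),
#' per-channel additive noise levels, and the class-conditional airway
#' temperature (+0.5 degC) and humidity (-3 %RH) offsets of asthmatics.
#'
#' @param age_group `"adult"` or `"pediatric"`.
#' @param noise_frac additive Gaussian noise SD per channel, expressed as a
#'   fraction of that channel's dynamic range. 0 disables noise.
#' @param retention_span length of the VOC retention-time axis, in retention
#'   units; component means/SDs live on this axis.
#' @return an object of class `breathdx_profile`.
#' @export
#' @examples
#' p <- table_profile("adult")
#' p$components[p$components$class == "asthmatic" & p$components$order == 2, ]
table_profile <- function(age_group = c("adult", "pediatric"),
                          noise_frac = 0.05, retention_span = 60) {
  age_group <- match.arg(age_group)
  assert_that(is.numeric(noise_frac) && noise_frac >= 0,
              "noise_frac must be a nonnegative number")
  tab <- published_deconv_table(age_group)
  comp <- data.frame(class = tab$class, order = tab$order_index,
                     amplitude = tab$amplitude, mean = tab$mean, sd = tab$sd,
                     stringsAsFactors = FALSE)
  peak <- max(vapply(c("asthmatic", "control"), function(cl)
    sum(comp$amplitude[comp$class == cl]), numeric(1)))
  profile <- structure(list(
    age_group = age_group,
    components = comp,
    capnogram = list(
      end_tidal = 5.0,          # end-tidal CO2 level, %
      upstroke_frac = 0.2,      # control: fraction of exhalation in upstroke
      sharkfin_tau = 0.35,      # asthmatic: exponential rise constant
      sharkfin_linear = 0.15),  # asthmatic: linear admixture keeping slope > 0
    flow_peak = 6.0,            # peak exhaled flow, L/min (control)
    flow_asthma_factor = 0.7,   # airway-obstruction flow reduction
    temperature_base = 34.0,    # exhaled air temperature, degC
    temperature_offset = 0.5,   # asthmatic increment, degC
    humidity_base = 95.0,       # exhaled humidity, %RH
    humidity_offset = -3.0,     # asthmatic decrement, %RH
    pressure_base = 101.3,      # kPa
    subject_sd = 0.10,          # between-subject lognormal-ish spread
    retention_span = retention_span,
    noise_frac = noise_frac,
    noise_sd = c(co2 = 5.0, voc = peak, flow = 6.0, temperature = 1.0,
                 humidity = 5.0, pressure = 0.5) * noise_frac
  ), class = "breathdx_profile")
  validate_profile(profile)
  profile
}

#' Validate an effect profile
#'
#' Checks the structural invariants of a `breathdx_profile`: three component
#' orders per class, strictly positive SDs, nonnegative amplitudes, and
#' nonnegative noise levels.
#'
#' @param profile a `breathdx_profile`.
#' @return the profile, invisibly; errors describe the first violation.
#' @export
validate_profile <- function(profile) {
  assert_that(inherits(profile, "breathdx_profile"),
              "not a breathdx_profile object")
  comp <- profile$components
  for (cl in c("asthmatic", "control")) {
    sub <- comp[comp$class == cl, ]
    assert_that(nrow(sub) == 3L && setequal(sub$order, 0:2),
                sprintf("class '%s' must have component orders 0,1,2", cl))
  }
  assert_that(all(comp$sd > 0), "component SDs must be > 0")
  assert_that(all(comp$amplitude >= 0), "component amplitudes must be >= 0")
  assert_that(all(is.finite(unlist(comp[c("amplitude", "mean", "sd")]))),
              "component parameters must be finite")
  assert_that(all(profile$noise_sd >= 0), "noise SDs must be >= 0")
  invisible(profile)
}

#' Scale the asthmatic-control effect size of a profile
#'
#' Interpolates every class-conditional difference (VOC component parameters,
#' capnogram shape, flow reduction, temperature/humidity offsets) between the
#' control value (`factor = 0`) and the full asthmatic value (`factor = 1`).
#' At `factor = 0` the two classes are statistically identical, which is the
#' null condition used to calibrate chance-level classifier performance.
#'
#' @param profile a `breathdx_profile`.
#' @param factor effect-size multiplier in `[0, 1]` (values above 1 extrapolate).
#' @return a modified `breathdx_profile`.
#' @export
scale_effect <- function(profile, factor) {
  validate_profile(profile)
  assert_that(is.numeric(factor) && length(factor) == 1L && factor >= 0,
              "factor must be a single nonnegative number")
  comp <- profile$components
  for (o in 0:2) {
    ia <- which(comp$class == "asthmatic" & comp$order == o)
    ic <- which(comp$class == "control" & comp$order == o)
    for (fld in c("amplitude", "mean", "sd"))
      comp[ia, fld] <- comp[ic, fld] + factor * (comp[ia, fld] - comp[ic, fld])
  }
  comp$sd <- pmax(comp$sd, 1e-6)
  comp$amplitude <- pmax(comp$amplitude, 0)
  profile$components <- comp
  profile$temperature_offset <- profile$temperature_offset * factor
  profile$humidity_offset <- profile$humidity_offset * factor
  profile$flow_asthma_factor <- 1 + factor * (profile$flow_asthma_factor - 1)
  profile$sharkfin_blend <- factor   # capnogram shape morph weight
  validate_profile(profile)
  profile
}
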