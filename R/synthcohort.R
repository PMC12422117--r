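# Synthetic exhalation cohort generator. One record = one exhalation session:
# 13 named waveform channels, a binary asthma label and an age-group tag;
# every subject contributes three replicate sessions.

CHANNELS <- c("co2", "voc_total", "isoprene", "acetone", "ethanol",
              "nox_proxy", "flow", "temperature", "humidity", "pressure",
              "voc_aux1", "voc_aux2", "voc_aux3")

# fixed scale of each named/auxiliary VOC channel relative to the total
VOC_SCALES <- c(isoprene = 0.5, acetone = 0.35, ethanol = 0.25,
                nox_proxy = 0.10, voc_aux1 = 0.15, voc_aux2 = 0.08,
                voc_aux3 = 0.05)

sum_of_gaussians <- function(x, amplitude, mean, sd) {
  y <- numeric(length(x))
  for (i in seq_along(amplitude))
    y <- y + amplitude[i] * exp(-(x - mean[i])^2 / (2 * sd[i]^2))
  y
}

#' Generate a VOC sensor channel
#'
#' Produces a composite VOC profile as the sum of the profile's three
#' class-conditional Gaussian components, plus a constant baseline and
#' additive i.i.d. Gaussian sensor noise. The series is sampled on the
#' retention axis `seq(0, retention_span, length.out = n_samples)`. The same
#' seed always yields an identical series.
#'
#' @param class `"asthmatic"` or `"control"`.
#' @param profile a `breathdx_profile` (see [table_profile()]).
#' @param n_samples number of samples, at least 50.
#' @param seed integer RNG seed for the noise draw.
#' @param baseline constant offset added to the series (default 0).
#' @return numeric vector of length `n_samples` with attribute `"retention"`
#'   holding the retention-time grid.
#' @export
generate_voc_channel <- function(class = c("asthmatic", "control"), profile,
                                 n_samples, seed = 1L, baseline = 0) {
  class <- match.arg(class)
  validate_profile(profile)
  assert_that(is_count(n_samples) && n_samples >= 50,
              "n_samples must be an integer >= 50")
  comp <- profile$components[profile$components$class == class, ]
  comp <- comp[order(comp$order), ]
  x <- seq(0, profile$retention_span, length.out = n_samples)
  y <- sum_of_gaussians(x, comp$amplitude, comp$mean, comp$sd) + baseline
  nsd <- unname(profile$noise_sd["voc"])
  if (nsd > 0) y <- y + with_seed(seed, stats::rnorm(n_samples, 0, nsd))
  attr(y, "retention") <- x
  y
}

# expiratory limb shapes on u in [0,1], normalised to end at 1
capno_square_shape <- function(u, upstroke_frac) {
  pmin(u / upstroke_frac, 1)
}

capno_sharkfin_shape <- function(u, tau, linear) {
  expo <- (1 - exp(-u / tau)) / (1 - exp(-1 / tau))
  (1 - linear) * expo + linear * u
}

#' Generate a CO2 capnogram for one exhalation
#'
#' Controls get the square/trapezoid waveform of a healthy breath: a fast
#' upstroke followed by a near-flat alveolar plateau at the end-tidal level.
#' Asthmatics get the obstructive "shark-fin": a monotonically rising
#' expiratory limb with no flat plateau, still reaching the configured
#' end-tidal level at end-expiration. Additive Gaussian noise as configured.
#'
#' @inheritParams generate_voc_channel
#' @return numeric vector of length `n_samples` (CO2 in %).
#' @export
generate_capnogram <- function(class = c("asthmatic", "control"), profile,
                               n_samples, seed = 1L) {
  class <- match.arg(class)
  validate_profile(profile)
  assert_that(is_count(n_samples) && n_samples >= 50,
              "n_samples must be an integer >= 50")
  cp <- profile$capnogram
  u <- seq(0, 1, length.out = n_samples)
  square <- capno_square_shape(u, cp$upstroke_frac)
  if (class == "control") {
    shape <- square
  } else {
    fin <- capno_sharkfin_shape(u, cp$sharkfin_tau, cp$sharkfin_linear)
    blend <- profile$sharkfin_blend %||% 1
    shape <- (1 - blend) * square + blend * fin
  }
  y <- cp$end_tidal * shape
  nsd <- unname(profile$noise_sd["co2"])
  if (nsd > 0) y <- y + with_seed(seed, stats::rnorm(n_samples, 0, nsd))
  y
}

# smooth auxiliary physiology channels, class-shifted per the profile
generate_physio_channels <- function(class, profile, n_samples, seeds) {
  u <- seq(0, 1, length.out = n_samples)
  asth <- class == "asthmatic"
  flow_peak <- profile$flow_peak * if (asth) profile$flow_asthma_factor else 1
  out <- list(
    flow = flow_peak * sin(pi * u)^2,
    temperature = profile$temperature_base +
      (if (asth) profile$temperature_offset else 0) + 0.2 * sin(2 * pi * u),
    humidity = profile$humidity_base +
      (if (asth) profile$humidity_offset else 0) - 1.5 * cos(pi * u),
    pressure = profile$pressure_base + 0.2 * sin(2 * pi * u)
  )
  nsd <- profile$noise_sd
  keys <- c(flow = "flow", temperature = "temperature",
            humidity = "humidity", pressure = "pressure")
  for (i in seq_along(out)) {
    ch <- names(out)[i]
    s <- unname(nsd[keys[ch]])
    if (s > 0)
      out[[i]] <- out[[i]] + with_seed(seeds[i], stats::rnorm(n_samples, 0, s))
  }
  out
}

#' Cohort specification
#'
#' @param n_asthmatic,n_control subject counts per class (each at least 1).
#' @param age_group `"adult"` or `"pediatric"`.
#' @param profile effect profile; defaults to [table_profile()] for the age
#'   group.
#' @param n_replicates sessions per subject (default 3, triplicate testing).
#' @param n_samples samples per channel (default 250).
#' @param sampling_rate samples per second (default 25).
#' @param seed integer master seed; a fixed spec reproduces the cohort exactly.
#' @return an object of class `breathdx_cohort_spec`.
#' @export
cohort_spec <- function(n_asthmatic, n_control,
                        age_group = c("adult", "pediatric"), profile = NULL,
                        n_replicates = 3L, n_samples = 250L,
                        sampling_rate = 25, seed = 1L) {
  age_group <- match.arg(age_group)
  assert_that(is_count(n_asthmatic) && is_count(n_control),
              "subject counts must be positive integers")
  assert_that(is_count(n_replicates), "n_replicates must be a positive integer")
  assert_that(is_count(n_samples) && n_samples >= 50,
              "n_samples must be an integer >= 50")
  profile <- profile %||% table_profile(age_group)
  validate_profile(profile)
  structure(list(n_asthmatic = as.integer(n_asthmatic),
                 n_control = as.integer(n_control), age_group = age_group,
                 profile = profile, n_replicates = as.integer(n_replicates),
                 n_samples = as.integer(n_samples),
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "breathdx_cohort_spec")
}

# perturb component parameters by a subject-level multiplicative effect
subject_profile <- function(profile, seed) {
  ssd <- profile$subject_sd
  if (ssd <= 0) return(profile)
  comp <- profile$components
  mult <- with_seed(seed, exp(stats::rnorm(nrow(comp) * 3, 0, ssd)))
  m <- matrix(mult, nrow(comp), 3)
  comp$amplitude <- comp$amplitude * m[, 1]
  comp$mean <- comp$mean * m[, 2]
  comp$sd <- comp$sd * m[, 3]
  profile$components <- comp
  profile
}

#' Generate a labelled synthetic cohort
#'
#' Simulates `n_asthmatic + n_control` subjects with `n_replicates` exhalation
#' records each. All 13 channels are populated: the capnogram and the VOC
#' channels come from the class-conditional generators, flow, temperature,
#' humidity and pressure are class-shifted smooth curves plus noise. Subjects
#' vary around the profile values by a lognormal between-subject effect.
#'
#' @param spec a [cohort_spec()].
#' @return a list of `breath_record` objects of length
#'   `(n_asthmatic + n_control) * n_replicates`, with class
#'   `breathdx_cohort`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(2, 2, "adult", seed = 7))
#' length(cohort)  # 4 subjects x 3 replicates
generate_cohort <- function(spec) {
  assert_that(inherits(spec, "breathdx_cohort_spec"),
              "spec must come from cohort_spec()")
  n_sub <- spec$n_asthmatic + spec$n_control
  labels <- rep(c(1L, 0L), c(spec$n_asthmatic, spec$n_control))
  subject_ids <- sprintf("S%03d", seq_len(n_sub))
  seeds <- derive_seeds(spec$seed, n_sub * (spec$n_replicates * 8L + 1L))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }
  records <- vector("list", n_sub * spec$n_replicates)
  idx <- 0L
  for (s in seq_len(n_sub)) {
    cls <- if (labels[s] == 1L) "asthmatic" else "control"
    prof_s <- subject_profile(spec$profile, nxt())
    for (r in seq_len(spec$n_replicates)) {
      voc <- generate_voc_channel(cls, prof_s, spec$n_samples, nxt())
      retention <- attr(voc, "retention")
      voc <- as.numeric(voc)
      co2 <- generate_capnogram(cls, prof_s, spec$n_samples, nxt())
      physio <- generate_physio_channels(cls, prof_s, spec$n_samples,
                                         c(nxt(), nxt(), nxt(), nxt()))
      chans <- list(co2 = co2, voc_total = voc)
      sub_seeds <- derive_seeds(nxt(), length(VOC_SCALES))
      nsd <- unname(prof_s$noise_sd["voc"])
      base_voc <- voc
      if (nsd > 0) {
        # named VOC channels share the mixture shape, not the noise draw
        comp <- prof_s$components[prof_s$components$class == cls, ]
        base_voc <- sum_of_gaussians(retention, comp$amplitude, comp$mean,
                                     comp$sd)
      }
      for (j in seq_along(VOC_SCALES)) {
        ch <- names(VOC_SCALES)[j]
        y <- VOC_SCALES[[j]] * base_voc
        s_ch <- nsd * VOC_SCALES[[j]]
        if (s_ch > 0)
          y <- y + with_seed(sub_seeds[j],
                             stats::rnorm(spec$n_samples, 0, s_ch))
        chans[[ch]] <- y
      }
      chans <- c(chans, physio)[CHANNELS]
      idx <- idx + 1L
      records[[idx]] <- structure(list(
        subject_id = subject_ids[s], age_group = spec$age_group,
        label = labels[s], replicate_index = r,
        sampling_rate = spec$sampling_rate,
        retention_span = spec$profile$retention_span,
        channels = chans), class = "breath_record")
    }
  }
  structure(records, class = "breathdx_cohort", spec = spec)
}

#' Validate a breath record
#'
#' Asserts the record invariants: exactly 13 named channels, all series of
#' equal length (at least 50 samples), all values finite, a 0/1 label and a
#' positive replicate index.
#'
#' @param record a `breath_record`.
#' @return the record, invisibly.
#' @export
validate_record <- function(record) {
  assert_that(inherits(record, "breath_record"), "not a breath_record")
  ch <- record$channels
  missing <- setdiff(CHANNELS, names(ch))
  assert_that(length(missing) == 0,
              paste("record is missing channel(s):",
                    paste(missing, collapse = ", ")))
  assert_that(length(ch) == 13L,
              sprintf("record must have the 13 canonical channels; got %d",
                      length(ch)))
  lens <- vapply(ch, length, integer(1))
  assert_that(length(unique(lens)) == 1L && lens[1] >= 50,
              "all channels must share one length >= 50")
  assert_that(all(vapply(ch, function(x) all(is.finite(x)), logical(1))),
              "all channel values must be finite")
  assert_that(record$label %in% c(0L, 1L), "label must be 0 or 1")
  assert_that(is_count(record$replicate_index), "bad replicate_index")
  invisible(record)
}

#' Write a cohort to disk
#'
#' Writes the waveforms as one long-format CSV (`subject_id`, `replicate`,
#' `channel`, `t_seconds`, `value`) and a JSON sidecar with labels, age group,
#' seed and the generating spec echo. The round trip through
#' [read_cohort()] is lossless to ~1e-15 relative precision.
#'
#' @param cohort a `breathdx_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- attr(cohort, "spec")
  rows <- lapply(cohort, function(rec) {
    n <- length(rec$channels[[1]])
    t_sec <- (seq_len(n) - 1) / rec$sampling_rate
    data.frame(subject_id = rec$subject_id, replicate = rec$replicate_index,
               channel = rep(names(rec$channels), each = n),
               t_seconds = rep(t_sec, length(rec$channels)),
               value = unlist(rec$channels, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  long$value <- format(long$value, digits = 17, trim = TRUE, scientific = TRUE)
  long$t_seconds <- format(long$t_seconds, digits = 17, trim = TRUE)
  csv_path <- file.path(dir, "waveforms.csv")
  utils::write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
  subj <- unique(data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    label = vapply(cohort, `[[`, 0L, "label"),
    age_group = vapply(cohort, `[[`, "", "age_group"),
    stringsAsFactors = FALSE))
  meta <- list(subjects = subj, seed = spec$seed, age_group = spec$age_group,
               sampling_rate = spec$sampling_rate,
               retention_span = spec$profile$retention_span,
               n_samples = spec$n_samples,
               n_replicates = spec$n_replicates,
               n_asthmatic = spec$n_asthmatic, n_control = spec$n_control)
  json_path <- file.path(dir, "cohort.json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(waveforms = csv_path, metadata = json_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `waveforms.csv` and `cohort.json`.
#' @return a `breathdx_cohort` (spec echo reduced to the sidecar fields).
#' @export
read_cohort <- function(dir) {
  csv_path <- file.path(dir, "waveforms.csv")
  json_path <- file.path(dir, "cohort.json")
  assert_that(file.exists(csv_path) && file.exists(json_path),
              "dir must contain waveforms.csv and cohort.json")
  long <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  labels <- stats::setNames(meta$subjects$label, meta$subjects$subject_id)
  key <- interaction(long$subject_id, long$replicate, drop = TRUE)
  records <- lapply(split(long, key), function(df) {
    chans <- lapply(split(df$value, df$channel), as.numeric)
    chans <- chans[CHANNELS]
    structure(list(subject_id = df$subject_id[1], age_group = meta$age_group,
                   label = as.integer(labels[[df$subject_id[1]]]),
                   replicate_index = as.integer(df$replicate[1]),
                   sampling_rate = meta$sampling_rate,
                   retention_span = meta$retention_span,
                   channels = chans), class = "breath_record")
  })
  ord <- order(vapply(records, `[[`, "", "subject_id"),
               vapply(records, `[[`, 0L, "replicate_index"))
  structure(unname(records[ord]), class = "breathdx_cohort", meta = meta)
}
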