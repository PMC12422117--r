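# Waveform preprocessing: feature standardization, end-tidal plateau
# detection on the capnogram, scalar breath-feature extraction, and PCA.

#' Standardize a sample-by-feature matrix
#'
#' Centers every feature column to mean 0 and scales it to SD 1. Constant
#' columns cannot be scaled; they are mapped to all-zeros and reported via a
#' warning and the `"constant_features"` attribute.
#'
#' @param x numeric matrix or data frame, samples in rows (at least 2).
#' @return matrix of the same shape, with attributes `"center"`, `"scale"`
#'   and `"constant_features"`.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  assert_that(length(x) > 0 && nrow(x) >= 2,
              "standardize needs a nonempty matrix with >= 2 samples")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  const <- !is.finite(sds) | sds < 1e-12
  sds[const] <- 1
  out <- sweep(sweep(x, 2, ctr), 2, sds, "/")
  if (any(const)) {
    out[, const] <- 0
    warning("constant feature(s) mapped to zero: ",
            paste(colnames(x)[const] %||% which(const), collapse = ", "))
  }
  attr(out, "center") <- ctr
  attr(out, "scale") <- sds
  attr(out, "constant_features") <- which(const)
  out
}

#' Detect the end-tidal plateau of a capnogram
#'
#' Smooths the series with a centered moving average, takes first
#' differences, and finds maximal runs where the absolute smoothed slope is
#' at most `slope_tol`. Candidate runs must be at least `min_length` samples
#' long and sit in the upper half of the signal range (the end-tidal plateau
#' is the alveolar, high-CO2 segment, which excludes the pre-upstroke
#' baseline). The longest candidate wins; ties go to the latest run.
#'
#' @param capnogram numeric series (CO2, %).
#' @param min_length minimum plateau length in samples.
#' @param slope_tol maximum absolute slope, in signal units per sample.
#' @param smooth_window moving-average window (samples, default 5).
#' @return a list with `start_index`, `end_index`, `mean_level`, `slope`
#'   (class `plateau_interval`), or `NULL` when no qualifying run exists.
#' @export
detect_end_tidal_plateau <- function(capnogram, min_length = 25L,
                                     slope_tol = 0.004, smooth_window = 5L) {
  assert_that(is.numeric(capnogram) && length(capnogram) >= 2,
              "capnogram must be a numeric series")
  assert_that(is_count(min_length) && min_length <= length(capnogram),
              "min_length must be a positive integer <= series length")
  sm <- moving_average(capnogram, smooth_window)
  slope <- diff(sm)
  flat <- abs(slope) <= slope_tol
  if (!any(flat)) return(NULL)
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lo <- min(sm); hi <- max(sm)
  best <- NULL
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i] + 1L   # slope k covers samples k..k+1
    if (e - s + 1L < min_length) next
    lvl <- mean(capnogram[s:e])
    if (hi > lo && lvl < lo + 0.5 * (hi - lo)) next
    if (is.null(best) || (e - s) >= (best$end_index - best$start_index))
      best <- list(start_index = s, end_index = e, mean_level = lvl,
                   slope = unname(stats::coef(
                     stats::lm(y ~ t, data.frame(y = capnogram[s:e],
                                                 t = s:e)))[2]))
  }
  if (!is.null(best)) class(best) <- "plateau_interval"
  best
}

#' Extract scalar breath features from one record
#'
#' Computes the VOC summary features (`voc_max`, the maximum of the total-VOC
#' channel, and `voc_plateau_width`, the time in seconds the channel spends
#' at or above `plateau_fraction` of its maximum), capnogram features from
#' [detect_end_tidal_plateau()] (`co2_plateau_slope` in %/s,
#' `co2_end_tidal` in %, `upstroke_angle` in degrees), and mean/max summaries
#' of every remaining channel.
#'
#' @param record a validated `breath_record`.
#' @param plateau_fraction fraction of `voc_max` defining the VOC plateau
#'   (default 0.5, i.e. the full width at half maximum).
#' @param plateau_args list of arguments forwarded to
#'   [detect_end_tidal_plateau()].
#' @return named numeric feature vector.
#' @export
extract_features <- function(record, plateau_fraction = 0.5,
                             plateau_args = list()) {
  validate_record(record)
  assert_that(plateau_fraction > 0 && plateau_fraction <= 1,
              "plateau_fraction must be in (0, 1]")
  fs <- record$sampling_rate
  voc <- record$channels$voc_total
  voc_max <- max(voc)
  width <- if (voc_max <= 0) 0 else
    sum(voc >= plateau_fraction * voc_max) / fs
  co2 <- record$channels$co2
  pl <- do.call(detect_end_tidal_plateau, c(list(co2), plateau_args))
  if (is.null(pl)) {
    slope_s <- max(diff(moving_average(co2, 5L))) * fs
    end_tidal <- co2[length(co2)]
  } else {
    slope_s <- pl$slope * fs
    end_tidal <- pl$mean_level
  }
  upstroke <- atan(max(diff(moving_average(co2, 5L))) * fs) * 180 / pi
  out <- c(voc_max = voc_max, voc_plateau_width = width,
           co2_plateau_slope = slope_s, co2_end_tidal = end_tidal,
           upstroke_angle = upstroke)
  rest <- setdiff(CHANNELS, c("co2", "voc_total"))
  for (ch in rest) {
    y <- record$channels[[ch]]
    out[paste0(ch, "_mean")] <- mean(y)
    out[paste0(ch, "_max")] <- max(y)
  }
  assert_that(all(is.finite(out)), "non-finite feature value")
  out
}

#' Per-subject feature table for a cohort
#'
#' Extracts features for every record and aggregates the replicate sessions
#' of each subject by the median, one row per subject.
#'
#' @param cohort a `breathdx_cohort` (or list of `breath_record`s).
#' @inheritParams extract_features
#' @return data frame: `subject_id`, `label`, `age_group`, then one column
#'   per feature.
#' @export
extract_feature_table <- function(cohort, plateau_fraction = 0.5,
                                  plateau_args = list()) {
  feats <- t(vapply(cohort, extract_features, numeric(27),
                    plateau_fraction = plateau_fraction,
                    plateau_args = plateau_args))
  ids <- vapply(cohort, `[[`, "", "subject_id")
  labels <- vapply(cohort, `[[`, 0L, "label")
  ages <- vapply(cohort, `[[`, "", "age_group")
  uid <- unique(ids)
  med <- t(vapply(uid, function(s)
    apply(feats[ids == s, , drop = FALSE], 2, stats::median), feats[1, ]))
  out <- data.frame(subject_id = uid,
                    label = labels[match(uid, ids)],
                    age_group = ages[match(uid, ids)],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(med))
}

#' Principal component analysis of a feature matrix
#'
#' Eigen-decomposes the feature covariance (via [stats::prcomp()]) and keeps
#' the smallest number of components whose cumulative explained variance
#' reaches `variance_target`, unless a fixed `n_components` is requested.
#'
#' @param x numeric sample-by-feature matrix (ideally standardized; at least
#'   2 samples).
#' @param variance_target cumulative explained-variance threshold in (0, 1].
#' @param n_components optional fixed component count overriding the
#'   threshold.
#' @return list of class `breathdx_pca`: `loadings` (component x feature),
#'   `explained_variance_ratio` (all components, non-increasing),
#'   `scores` (sample x kept component), `center`, `n_components_kept`.
#' @export
fit_pca <- function(x, variance_target = 0.95, n_components = NULL) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 2, "fit_pca needs >= 2 samples")
  assert_that(variance_target > 0 && variance_target <= 1,
              "variance_target must be in (0, 1]")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  k <- if (!is.null(n_components)) {
    assert_that(is_count(n_components) && n_components <= length(evr),
                "n_components out of range")
    as.integer(n_components)
  } else which(cumsum(evr) >= variance_target - 1e-12)[1]
  structure(list(loadings = t(pr$rotation[, seq_len(k), drop = FALSE]),
                 explained_variance_ratio = evr,
                 scores = pr$x[, seq_len(k), drop = FALSE],
                 center = pr$center,
                 n_components_kept = k), class = "breathdx_pca")
}

#' Project new samples onto a fitted PCA basis
#'
#' @param pca a `breathdx_pca` from [fit_pca()].
#' @param x sample-by-feature matrix with the training feature count.
#' @return sample-by-component score matrix.
#' @export
project <- function(pca, x) {
  x <- as.matrix(x)
  assert_that(inherits(pca, "breathdx_pca"), "pca must come from fit_pca()")
  assert_that(ncol(x) == ncol(pca$loadings),
              sprintf("feature count mismatch: got %d, expected %d",
                      ncol(x), ncol(pca$loadings)))
  sweep(x, 2, pca$center) %*% t(pca$loadings)
}

#' Variance-weighted PCA scores for the classifier
#'
#' Scales each kept component's scores by its explained-variance ratio, so
#' that more informative components enter the downstream model with
#' proportionally higher weight.
#'
#' @inheritParams project
#' @return weighted score matrix.
#' @export
pca_weighted_scores <- function(pca, x) {
  s <- project(pca, x)
  sweep(s, 2, pca$explained_variance_ratio[seq_len(ncol(s))], "*")
}

#' Serialize / load a PCA model as JSON
#' @param pca a `breathdx_pca`.
#' @param path file path.
#' @return `write_pca`: the path, invisibly; `read_pca`: a `breathdx_pca`.
#' @export
write_pca <- function(pca, path) {
  jsonlite::write_json(list(loadings = pca$loadings,
                            explained_variance_ratio =
                              pca$explained_variance_ratio,
                            center = as.list(pca$center),
                            n_components_kept = pca$n_components_kept),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_pca
#' @export
read_pca <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(loadings = m$loadings,
                 explained_variance_ratio = m$explained_variance_ratio,
                 scores = NULL, center = unlist(m$center),
                 n_components_kept = m$n_components_kept),
            class = "breathdx_pca")
}

#' Write a per-subject feature table as CSV
#' @param features data frame from [extract_feature_table()].
#' @param path file path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
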