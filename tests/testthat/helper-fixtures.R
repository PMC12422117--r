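# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small adult cohort with the full effect, 5% noise
small_cohort <- function() cached("small_cohort", function()
  generate_cohort(cohort_spec(10, 10, "adult", seed = 101)))

small_features <- function() cached("small_features", function()
  extract_feature_table(small_cohort()))

# larger cohort: enough training subjects per fold for every reference
# classifier's defaults (tree models need ~20 rows to split)
medium_features <- function() cached("medium_features", function()
  extract_feature_table(generate_cohort(
    cohort_spec(30, 30, "adult", seed = 202, n_samples = 120L))))

# single-component profile: one clean Gaussian on the voc channels
single_peak_profile <- function(amplitude = 1, mean = 30, sd = 4,
                                noise_frac = 0) {
  p <- table_profile("adult", noise_frac = noise_frac)
  comp <- p$components
  for (cl in c("asthmatic", "control")) {
    idx <- comp$class == cl
    comp$amplitude[idx] <- c(amplitude, 0, 0)
    comp$mean[idx] <- c(mean, mean + 10, mean + 20)
    comp$sd[idx] <- c(sd, sd, sd)
  }
  p$components <- comp
  p$subject_sd <- 0
  validate_profile(p)
  p
}

# tiny ADENA configuration for fast exact tests
tiny_config <- function(...) adena_config(
  conv_filters = c(4L, 8L), kernel_size = 3L, se_reduction = 2L,
  capsule_count = 3L, capsule_dim = 4L, routing_iterations = 3L,
  head_hidden_units = 5L, ...)

# brute-force AUC over all positive-negative pairs (independent oracle)
pairwise_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# numeric gradient of f at x by central differences
numeric_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
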