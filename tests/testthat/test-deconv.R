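test_that("FWHM follows the Gaussian relation on published rows", {
  expect_equal(round(fwhm_from_sd(8.97), 2), 21.12)
  expect_equal(round(fwhm_from_sd(1.022), 2), 2.41)
  expect_equal(fwhm_from_sd(1), 2 * sqrt(2 * log(2)), tolerance = 1e-12)
  expect_equal(fwhm_from_sd(1), 2.354820, tolerance = 1e-6)
  expect_error(fwhm_from_sd(0))
  expect_error(fwhm_from_sd(-3))
})

test_that("gaussian components are self-consistent", {
  g <- gaussian_component(2, 10, 1.5)
  expect_lte(abs(g$fwhm - 2 * sqrt(2 * log(2)) * g$sd), 1e-6 * g$fwhm)
  expect_error(gaussian_component(2, 10, -1))
  expect_error(gaussian_component(-2, 10, 1))
  expect_error(gaussian_component(1, 0, 1, fwhm = 10))  # way off the relation
})

test_that("deconvolve recovers exact and noisy mixtures", {
  x <- seq(0, 40, length.out = 300)

  # exact single Gaussian, self-fit to machine-level accuracy
  y1 <- 2 * exp(-(x - 10)^2 / (2 * 1.5^2))
  f1 <- deconvolve(y1, n_components = 1, x = x)
  expect_true(f1$converged)
  cmp <- f1$components[[1]]
  expect_equal(cmp$amplitude, 2, tolerance = 1e-6)
  expect_equal(cmp$mean, 10, tolerance = 1e-6)
  expect_equal(cmp$sd, 1.5, tolerance = 1e-6)
  expect_lte(f1$residual_rms, 1e-6 * max(y1))

  # three well-separated Gaussians + 1% noise: all parameters within 5%
  truth <- data.frame(amplitude = c(3, 5, 2), mean = c(8, 20, 32),
                      sd = c(1.5, 2, 1.8))
  gmix <- function(x, tab) Reduce(`+`, lapply(seq_len(nrow(tab)), function(i)
    tab$amplitude[i] * exp(-(x - tab$mean[i])^2 / (2 * tab$sd[i]^2))))
  set.seed(4)
  y3 <- gmix(x, truth) + rnorm(length(x), 0, 0.05)
  f3 <- deconvolve(y3, n_components = 3, x = x)
  perm <- match_components(f3, truth)
  for (i in 1:3) {
    c3 <- f3$components[[perm[i]]]
    expect_lt(abs(c3$amplitude - truth$amplitude[i]) / truth$amplitude[i],
              0.05)
    expect_lt(abs(c3$mean - truth$mean[i]) / truth$mean[i], 0.05)
    expect_lt(abs(c3$sd - truth$sd[i]) / truth$sd[i], 0.05)
  }

  # over-specification: the spurious component collapses
  f2 <- deconvolve(y1, n_components = 2, x = x)
  amps <- sort(vapply(f2$components, `[[`, 0, "amplitude"))
  expect_lte(amps[1], 0.01 * amps[2])

  # components come back sorted by mean
  means <- vapply(f3$components, `[[`, 0, "mean")
  expect_true(all(diff(means) >= 0))

  expect_error(deconvolve(y1[1:10], n_components = 3))
})

test_that("percent difference and fold ratio match the published arithmetic", {
  expect_equal(round(percent_difference(0.00258, 0.00084), 2), 207.14)
  expect_equal(round(percent_difference(15.52, 0.13), 2), 11838.46)
  expect_equal(percent_difference(7.3, 7.3), 0)
  expect_error(percent_difference(1, 0))

  r <- fold_ratio(643.18, 0.000774)
  expect_gt(r, 83000)
  expect_equal(r, 643.18 / 0.000774, tolerance = 1e-12)
  expect_equal(fold_ratio(5, 5), 1)
  expect_equal(fold_ratio(0, 1), 0)
  expect_error(fold_ratio(1, 0))
  expect_error(fold_ratio(1, -2))
})

test_that("compare_groups reproduces the published adult comparisons", {
  res <- published_table_results("adult")
  cmp <- compare_groups(res)

  cell <- function(o, m) cmp$percent_difference[cmp$order == o &
                                                  cmp$metric == m]
  expect_equal(round(cell(0, "amplitude"), 2), 207.14)
  expect_equal(round(cell(0, "mean"), 2), 205.88)
  expect_equal(round(cell(0, "sd"), 2), 1.44)
  expect_equal(round(cell(0, "fwhm"), 2), 1.69)
  expect_equal(round(cell(1, "sd"), 2), 236.57)

  # identical classes: all percent differences vanish
  same <- list(asthmatic = res$control, control = res$control)
  cmp0 <- compare_groups(same)
  expect_true(all(abs(cmp0$percent_difference) < 1e-12))

  expect_error(compare_groups(list(asthmatic = res$asthmatic)))
})

test_that("compare_groups flags undefined control cells", {
  zero_control <- published_table_results("adult")
  zero_control$control[[1]]$components[[1]]$amplitude <- 0
  cmp <- compare_groups(zero_control)
  row <- cmp[cmp$order == 0 & cmp$metric == "amplitude", ]
  expect_true(row$undefined)
  expect_true(is.na(row$percent_difference))
})

test_that("the FWHM audit reports exactly the anomalous published cells", {
  audit <- audit_fwhm_tables(tol = 0.01)
  flagged <- audit[audit$flagged, ]

  # no adult row violates the Gaussian relation
  expect_false(any(flagged$age_group == "adult"))

  # the two pediatric cells known to be inconsistent are flagged ...
  expect_true(any(flagged$age_group == "pediatric" &
                    flagged$order_label == "0" & flagged$class == "control"))
  expect_true(any(flagged$age_group == "pediatric" &
                    flagged$order_label == "3" &
                    flagged$class == "asthmatic"))
  # ... and so is the third true anomaly: the order-"3" control row, whose
  # printed FWHM (19.18) matches neither its own SD (9.26 -> 21.81) nor any
  # other in the block; the two order-"3" FWHM cells appear swapped.
  expect_true(any(flagged$age_group == "pediatric" &
                    flagged$order_label == "3" & flagged$class == "control"))
  expect_equal(nrow(flagged), 3)
})

test_that("match_components resolves permuted and spurious components", {
  truth <- data.frame(amplitude = c(300, 0.003, 200), mean = c(15, 0.03, 28),
                      sd = c(4, 1, 8))
  comps <- list(gaussian_component(198, 27.8, 7.9),
                gaussian_component(5, 45, 0.4),      # spurious
                gaussian_component(301, 15.1, 4.1))
  fake <- structure(list(components = comps), class = "deconvolution")
  perm <- match_components(fake, truth)
  expect_equal(perm[1], 3L)  # dominant 300-amplitude peak pairs with 15.1
  expect_equal(perm[3], 1L)  # 200-amplitude peak pairs with 27.8
  expect_equal(perm[2], 2L)  # spurious component lands on the tiny slot
})
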