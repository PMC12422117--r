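test_that("conv_block matches the brute-force cross-correlation", {
  # identity kernel passes the input through ReLU
  w_id <- array(c(0, 1, 0), c(3, 1, 1))
  x <- c(-2, 1, 3, -1, 5)
  expect_equal(as.numeric(conv_block(x, w_id, 0)), pmax(x, 0))

  # all-negative pre-activation floors at zero
  expect_equal(as.numeric(conv_block(x, w_id, -100)), rep(0, 5))

  # random 8-sample input against a direct double loop
  set.seed(1)
  x8 <- matrix(rnorm(16), 2, 8)           # 2 channels x 8 positions
  w <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  b <- rnorm(4)
  out <- conv_block(x8, w, b)
  xp <- cbind(0, x8, 0)                   # same padding, k = 3
  for (co in 1:4) for (p in 1:8) {
    acc <- b[co]
    for (ci in 1:2) for (o in 1:3) acc <- acc + w[o, ci, co] * xp[ci, p + o - 1]
    expect_equal(out[co, p], max(acc, 0), tolerance = 1e-12)
  }

  expect_error(conv_block(x8, array(rnorm(9), c(3, 3, 1)), 0), "channels")
})

test_that("squeeze is the per-channel mean and is linear", {
  expect_equal(squeeze(matrix(7, 3, 5)), rep(7, 3))
  expect_equal(squeeze(matrix(1:4, 1)), 2.5)
  set.seed(2)
  for (i in 1:20) {
    X <- matrix(rnorm(12), 3); Y <- matrix(rnorm(12), 3)
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(squeeze(a * X + b * Y), a * squeeze(X) + b * squeeze(Y),
                 tolerance = 1e-12)
  }
})

test_that("excitation gates behave under both activation orders", {
  C <- 4; R <- 2
  z <- rnorm(C)
  expect_equal(excite(z, matrix(0, R, C), matrix(0, C, R)), rep(0.5, C))

  set.seed(3)
  for (i in 1:200) {
    g <- excite(rnorm(C), matrix(rnorm(R * C), R, C),
                matrix(rnorm(C * R), C, R))
    expect_true(all(g > 0 & g < 1))
  }

  # r = 1, identity weights: gates increase monotonically in z
  zs <- seq(-3, 6, by = 1)
  gs <- vapply(zs, function(v) excite(v, matrix(1), matrix(1))[1], numeric(1))
  expect_true(all(diff(gs) >= 0))
  expect_gt(gs[length(gs)], 0.99)

  # paper-literal order: ReLU outermost, gates only bounded below
  gl <- excite(c(5, 5), diag(2), diag(2), activation_order = "paper_literal")
  expect_true(all(gl >= 0))
  expect_error(excite(rnorm(3), matrix(0, 2, 4), matrix(0, 4, 2)))
})

test_that("residual attention variants are distinguished by their extremes", {
  e <- matrix(rnorm(12), 3)
  ones <- matrix(1, 3, 4); zeros <- matrix(0, 3, 4)
  expect_equal(residual_attention(e, ones, "mask_product"), e)
  expect_equal(residual_attention(e, zeros, "mask_product"), zeros)
  expect_equal(residual_attention(e, zeros, "residual_mask"), e)
  expect_equal(residual_attention(e, ones, "residual_mask"), 2 * e)

  m <- matrix(runif(12), 3)
  expect_true(all(abs(residual_attention(e, m, "mask_product")) <= abs(e)))
  expect_error(residual_attention(e, matrix(1, 2, 2)))
})

test_that("squash and dynamic routing honour the capsule contracts", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  set.seed(4)
  for (i in 1:50) {
    v <- squash(rnorm(4) * 10^runif(1, -2, 2))
    expect_lt(sqrt(sum(v^2)), 1)
  }

  # one output capsule: softmax over a single class is identically 1
  u1 <- array(rnorm(5 * 1 * 3), c(5, 1, 3))
  for (iters in c(1L, 4L)) {
    r <- dynamic_routing(u1, iters)
    expect_equal(as.numeric(r$coupling), rep(1, 5))
  }

  # agreement: a coherent input cluster wins coupling mass that grows
  # with iterations
  set.seed(5)
  agree <- matrix(rep(c(3, 0, 0, 0), each = 6), 6, 4)  # all point the same way
  u2 <- array(0, c(6, 2, 4))
  u2[, 1, ] <- agree + matrix(rnorm(24, 0, 0.05), 6, 4)
  u2[, 2, ] <- matrix(rnorm(24, 0, 1), 6, 4)           # incoherent
  mass <- vapply(c(2L, 3L, 5L), function(it)
    mean(dynamic_routing(u2, it)$coupling[, 1]), numeric(1))
  expect_true(all(mass > 0.5))
  expect_true(all(diff(mass) > 0))

  u_bad <- u1; u_bad[1] <- NA
  expect_error(dynamic_routing(u_bad, 2L), "finite")
})

test_that("the full forward pass is deterministic in eval mode and bounded", {
  cfg <- tiny_config()
  model <- adena_init(cfg, 7L, seed = 9)
  set.seed(10)
  x <- matrix(rnorm(7), 1)
  p <- replicate(10, adena_forward(model, x)$probability)
  expect_equal(length(unique(p)), 1L)

  # probabilities stay strictly inside (0, 1) across many random draws
  for (s in 1:5) {
    m <- adena_init(cfg, 7L, seed = s)
    X <- matrix(rnorm(200 * 7), 200)
    out <- adena_forward(m, X)
    expect_true(all(out$probability > 0 & out$probability < 1))
    expect_equal(out$probability, 1 / (1 + exp(-out$logit)),
                 tolerance = 1e-9)
  }

  # zeroed sigmoid head answers 0.5
  m0 <- adena_init(cfg, 7L, seed = 1)
  m0$weights$Wo[] <- 0
  m0$weights$bo <- 0
  expect_equal(adena_forward(m0, x)$probability, 0.5)
})

test_that("focal and combined losses obey their limit identities", {
  # perfect prediction costs (numerically) nothing
  expect_lt(focal_loss(1, 1, gamma = 2), 1e-6)
  expect_lt(focal_loss(0, 0, gamma = 2), 1e-6)

  # gamma = 0 reduces focal to plain cross-entropy
  p <- c(0.1, 0.45, 0.8, 0.99)
  y <- c(0, 1, 1, 0)
  expect_equal(focal_loss(y, p, gamma = 0),
               -ifelse(y == 1, log(p), log(1 - p)), tolerance = 1e-12)

  # direct evaluation at y = 1, p = 0.5, gamma = 2
  expect_equal(focal_loss(1, 0.5, gamma = 2), 0.25 * log(2),
               tolerance = 1e-12)

  # combined loss at gamma = 0 is exactly twice the mean BCE
  bce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(combined_loss(y, p, gamma = 0), 2 * bce, tolerance = 1e-12)

  # strictly decreasing in p for a positive label
  ps <- seq(0.01, 0.99, by = 0.01)
  ls <- vapply(ps, function(q) combined_loss(1, q, gamma = 2), numeric(1))
  expect_true(all(diff(ls) < 0))

  expect_error(focal_loss(c(1, 0), 0.5))
  expect_error(combined_loss(1, 0.5, gamma = -1))
})

test_that("analytic gradients match numeric differentiation", {
  cfg <- tiny_config()
  L <- 6L; B <- 3L
  model <- adena_init(cfg, L, seed = 11)
  set.seed(5)
  X <- matrix(rnorm(B * L), B, L)
  y <- c(1, 0, 1)
  w0 <- breathdx:::flatten_weights(model$weights)

  lossfun <- function(wvec) {
    m <- model
    m$weights <- breathdx:::unflatten_weights(wvec, model$weights)
    combined_loss(y, adena_forward(m, X)$probability, gamma = 2)
  }

  fw <- breathdx:::nn_forward(model, X, train = FALSE, keep_cache = TRUE)
  p <- fw$probability
  dlogit <- breathdx:::combined_loss_grad_p(y, p, 2) * p * (1 - p) / B
  gr <- breathdx:::nn_backward(model, fw$cache, dlogit)
  ga <- unlist(gr[names(model$weights)], use.names = FALSE)

  idx <- sort(sample(length(w0), 120))
  gn <- vapply(idx, function(i) {
    wp <- w0; wp[i] <- wp[i] + 1e-6
    wm <- w0; wm[i] <- wm[i] - 1e-6
    (lossfun(wp) - lossfun(wm)) / 2e-6
  }, numeric(1))
  rel <- abs(ga[idx] - gn) / pmax(abs(gn), 1e-8)
  expect_lt(max(rel), 1e-4)

  # loss gradient in p itself
  for (yy in c(0, 1)) for (gam in c(0, 2)) for (q in c(0.2, 0.5, 0.9)) {
    gnum <- numeric_gradient(function(v) combined_loss(yy, v, gam), q)
    gan <- breathdx:::combined_loss_grad_p(yy, q, gam)
    expect_lt(abs(gnum - gan) / max(abs(gnum), 1e-8), 1e-4)
  }
})

test_that("the network overfits a small separable toy set", {
  set.seed(12)
  X <- rbind(matrix(rnorm(4 * 6, mean = 2), 4, 6),
             matrix(rnorm(4 * 6, mean = -2), 4, 6))
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  cfg <- tiny_config(spatial_dropout_rate = 0, stochastic_depth_survival = 1)
  fit <- adena_train(X, y, model_config = cfg,
                     config = train_config(5e-4, 500L, 8L, seed = 2))
  final <- combined_loss(y, adena_predict(fit, X), gamma = cfg$gamma)
  expect_lt(final, 0.05)
  # descent sanity
  expect_lt(fit$history$train_loss[500], fit$history$train_loss[1])
})
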