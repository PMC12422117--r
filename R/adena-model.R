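# Full ADENA network: conv blocks -> squeeze/excitation gating -> residual
# attention -> capsule dynamic routing -> stochastic-depth dense block ->
# spatial dropout -> average pooling -> sigmoid head. Forward and backward
# passes are vectorized over the batch; gradients are derived analytically
# (the routing loop is unrolled in the backward pass).

#' ADENA model configuration
#'
#' @param conv_filters filter counts of the two convolution blocks.
#' @param kernel_size convolution kernel length (odd).
#' @param se_reduction squeeze-excitation bottleneck ratio `r`.
#' @param activation_order excitation activation order, `"standard"`
#'   (sigmoid outermost, bounded gates) or `"paper_literal"` (ReLU
#'   outermost).
#' @param attention_variant `"mask_product"` (`M(E) * E`) or
#'   `"residual_mask"` (`(1 + M(E)) * E`).
#' @param capsule_count number of output capsules `J`.
#' @param capsule_dim capsule dimension `D` (must divide the last conv
#'   filter count).
#' @param routing_iterations routing rounds, at least 1.
#' @param stochastic_depth_survival survival probability of the dense
#'   residual block.
#' @param spatial_dropout_rate probability of zeroing a whole capsule map in
#'   training.
#' @param gamma focal-loss focusing parameter (default 2).
#' @param head_hidden_units bottleneck width of the dense residual block.
#' @return list of class `adena_config`.
#' @export
adena_config <- function(conv_filters = c(16L, 32L), kernel_size = 5L,
                         se_reduction = 4L,
                         activation_order = c("standard", "paper_literal"),
                         attention_variant = c("mask_product",
                                               "residual_mask"),
                         capsule_count = 8L, capsule_dim = 8L,
                         routing_iterations = 3L,
                         stochastic_depth_survival = 0.8,
                         spatial_dropout_rate = 0.2, gamma = 2,
                         head_hidden_units = 32L) {
  activation_order <- match.arg(activation_order)
  attention_variant <- match.arg(attention_variant)
  assert_that(length(conv_filters) == 2 && all(conv_filters >= 1),
              "conv_filters must give two positive counts")
  assert_that(is_count(kernel_size) && kernel_size %% 2 == 1,
              "kernel_size must be a positive odd integer")
  assert_that(conv_filters[2] %% se_reduction == 0,
              "se_reduction must divide the last filter count")
  assert_that(conv_filters[2] %% capsule_dim == 0,
              "capsule_dim must divide the last filter count")
  assert_that(is_count(routing_iterations), "routing_iterations must be >= 1")
  assert_that(stochastic_depth_survival >= 0 &&
                stochastic_depth_survival <= 1 &&
                spatial_dropout_rate >= 0 && spatial_dropout_rate < 1,
              "probabilities must lie in [0, 1]")
  assert_that(gamma >= 0, "gamma must be >= 0")
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 se_reduction = as.integer(se_reduction),
                 activation_order = activation_order,
                 attention_variant = attention_variant,
                 capsule_count = as.integer(capsule_count),
                 capsule_dim = as.integer(capsule_dim),
                 routing_iterations = as.integer(routing_iterations),
                 stochastic_depth_survival = stochastic_depth_survival,
                 spatial_dropout_rate = spatial_dropout_rate,
                 gamma = gamma,
                 head_hidden_units = as.integer(head_hidden_units[1])),
            class = "adena_config")
}

#' Initialise ADENA weights
#'
#' He-style scaled Gaussian initialisation for all kernels and matrices,
#' zero biases.
#'
#' @param config an [adena_config()].
#' @param input_length length of the input feature vector.
#' @param seed integer RNG seed.
#' @return list of class `adena_model` with elements `config`,
#'   `input_length`, `weights`.
#' @export
adena_init <- function(config, input_length, seed = 1L) {
  assert_that(inherits(config, "adena_config"), "config must be adena_config")
  assert_that(is_count(input_length), "input_length must be a positive count")
  k <- config$kernel_size
  C1 <- config$conv_filters[1]; C2 <- config$conv_filters[2]
  R <- C2 %/% config$se_reduction
  J <- config$capsule_count; D <- config$capsule_dim
  nt <- C2 %/% D
  h <- config$head_hidden_units
  gauss <- function(n, fan_in) stats::rnorm(n, 0, sqrt(2 / fan_in))
  weights <- with_seed(seed, list(
    W1m = matrix(gauss(k * C1, k), k, C1), b1 = numeric(C1),
    W2m = matrix(gauss(k * C1 * C2, k * C1), k * C1, C2), b2 = numeric(C2),
    Wse1 = matrix(gauss(R * C2, C2), R, C2),
    Wse2 = matrix(gauss(C2 * R, R), C2, R),
    Wm1 = matrix(gauss(C2 * R, C2), C2, R),
    Wm2 = matrix(gauss(R * C2, R), R, C2), bm = numeric(C2),
    Wcap = array(gauss(nt * J * D * D, D), c(nt, J, D, D)),
    Wh1 = matrix(gauss(h * J * D, J * D), h, J * D), bh1 = numeric(h),
    Wh2 = matrix(gauss(J * D * h, h), J * D, h), bh2 = numeric(J * D),
    Wo = matrix(gauss(J, J), J, 1), bo = 0))
  structure(list(config = config, input_length = as.integer(input_length),
                 weights = weights), class = "adena_model")
}

# mean over the middle (position) axis of a (B, L, C) array -> (B, C)
pool_positions <- function(arr) {
  d <- dim(arr)
  m <- colSums(aperm(arr, c(2, 1, 3)))
  matrix(m, d[1], d[3]) / d[2]
}

# broadcast a (B, C) matrix over positions -> (B, L, C)
spread_positions <- function(m, L) {
  B <- nrow(m); C <- ncol(m)
  aperm(array(m, c(B, C, L)), c(1, 3, 2))
}

im2col <- function(Xarr, k) {
  # Xarr: (B, L, C) zero-padded convolution input; returns (B*L) x (k*C)
  d <- dim(Xarr); B <- d[1]; L <- d[2] - k + 1L; C <- d[3]
  out <- matrix(0, B * L, k * C)
  for (o in seq_len(k))
    out[, ((o - 1) * C + 1):(o * C)] <-
      matrix(Xarr[, (seq_len(L)) + (o - 1), , drop = FALSE], B * L, C)
  out
}

col2im <- function(dcol, B, L, C, k) {
  # adjoint of im2col: (B*L) x (k*C) -> padded (B, L + k - 1, C)
  acc <- array(0, c(B, L + k - 1L, C))
  for (o in seq_len(k))
    acc[, (seq_len(L)) + (o - 1), ] <-
      acc[, (seq_len(L)) + (o - 1), , drop = FALSE] +
      array(dcol[, ((o - 1) * C + 1):(o * C)], c(B, L, C))
  acc
}

pad_positions <- function(Xarr, k) {
  d <- dim(Xarr); half <- (k - 1L) %/% 2L
  out <- array(0, c(d[1], d[2] + k - 1L, d[3]))
  out[, (half + 1L):(half + d[2]), ] <- Xarr
  out
}

# ---- routing: batched, matricized, with per-iteration cache ----
# Prediction vectors are carried as a (B*N) x (J*D) matrix `Um`: row index
# (b, n) with b fastest, column index (j, d) with j fastest. All routing
# algebra then reduces to elementwise products, row/column regroupings and
# rowsum() calls -- no per-capsule loops.
routing_forward <- function(Um, B, N, J, D, iterations) {
  colJ <- rep(seq_len(J), D)
  rowB <- rep_len(seq_len(B), B * N)
  sum_d <- function(m)                 # (rows) x (J*D) -> rows x J over d
    matrix(rowSums(matrix(m, nrow(m) * J, D)), nrow(m), J)
  bmat <- matrix(0, B * N, J)
  c_list <- s_list <- v_list <- vector("list", iterations)
  vmat <- NULL
  for (it in seq_len(iterations)) {
    eb <- exp(bmat - bmat[cbind(seq_len(B * N), max.col(bmat, "first"))])
    cmat <- eb / rowSums(eb)
    smat <- rowsum(cmat[, colJ, drop = FALSE] * Um, rowB)   # B x (J*D)
    n2 <- sum_d(smat^2)
    beta <- sqrt(n2) / (1 + n2)          # squash: v = beta(||s||) * s
    beta[n2 == 0] <- 0
    vmat <- smat * beta[, colJ, drop = FALSE]
    c_list[[it]] <- cmat; s_list[[it]] <- smat; v_list[[it]] <- vmat
    if (it < iterations)                 # agreement update of the logits
      bmat <- bmat + sum_d(Um * vmat[rowB, , drop = FALSE])
  }
  list(v = array(vmat, c(B, J, D)), vmat = vmat,
       c_list = c_list, s_list = s_list, v_list = v_list)
}

# backward through the unrolled routing; returns the gradient in Um layout
routing_backward <- function(Um, B, N, J, D, cache, dv_mat) {
  iterations <- length(cache$c_list)
  colJ <- rep(seq_len(J), D)
  rowB <- rep_len(seq_len(B), B * N)
  sum_d <- function(m)
    matrix(rowSums(matrix(m, nrow(m) * J, D)), nrow(m), J)
  dUm <- matrix(0, B * N, J * D)
  db_next <- NULL  # dL/db^{it} flowing from later iterations
  for (it in rev(seq_len(iterations))) {
    cmat <- cache$c_list[[it]]
    smat <- cache$s_list[[it]]
    vmat <- cache$v_list[[it]]
    if (it == iterations) {
      dv <- dv_mat
    } else {
      # v^{it} fed the agreement update b^{it} = b^{it-1} + u.v
      Dexp <- db_next[, colJ, drop = FALSE]
      dv <- rowsum(Dexp * Um, rowB)
      dUm <- dUm + Dexp * vmat[rowB, , drop = FALSE]
    }
    # squash backward: ds = beta*dv + (beta'(n)/n) (s.dv) s
    n2 <- sum_d(smat^2)
    n <- sqrt(n2)
    beta <- n / (1 + n2); beta[n == 0] <- 0
    betap <- (1 - n2) / (1 + n2)^2
    coef <- ifelse(n > 0, betap / n, 0) * sum_d(smat * dv)
    ds <- dv * beta[, colJ, drop = FALSE] + smat * coef[, colJ, drop = FALSE]
    # s_j = sum_i c_ij u_ij
    DSbig <- ds[rowB, , drop = FALSE]
    dc <- sum_d(Um * DSbig)
    dUm <- dUm + cmat[, colJ, drop = FALSE] * DSbig
    # softmax over J backward (rowSums recycles down the columns)
    db <- cmat * (dc - rowSums(cmat * dc))
    if (it < iterations) db <- db + db_next  # identity path of the update
    db_next <- db
  }
  dUm
}

# ---- full network ----
nn_forward <- function(model, X, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config; w <- model$weights
  X <- as.matrix(X)
  assert_that(ncol(X) == model$input_length,
              sprintf("input length %d, model expects %d",
                      ncol(X), model$input_length))
  B <- nrow(X); L <- ncol(X); k <- cfg$kernel_size
  C1 <- cfg$conv_filters[1]; C2 <- cfg$conv_filters[2]
  J <- cfg$capsule_count; D <- cfg$capsule_dim; nt <- C2 %/% D
  # conv block 1 (input = one channel)
  X0 <- array(X, c(B, L, 1L))
  X1c <- im2col(pad_positions(X0, k), k)
  A1 <- sweep(X1c %*% w$W1m, 2, w$b1, "+")
  H1 <- relu(A1)
  H1arr <- array(H1, c(B, L, C1))
  # conv block 2
  X2c <- im2col(pad_positions(H1arr, k), k)
  A2 <- sweep(X2c %*% w$W2m, 2, w$b2, "+")
  H2 <- relu(A2)
  H2arr <- array(H2, c(B, L, C2))
  # squeeze / excite
  z <- pool_positions(H2arr)
  s1 <- z %*% t(w$Wse1)
  if (cfg$activation_order == "standard") {
    h1 <- relu(s1)
    q <- h1 %*% t(w$Wse2)
    g <- sigmoid(q)
  } else {
    h1 <- sigmoid(s1)
    q <- h1 %*% t(w$Wse2)
    g <- relu(q)
  }
  Earr <- H2arr * spread_positions(g, L)
  # residual attention (learned sigmoid bottleneck mask)
  Em <- matrix(Earr, B * L, C2)
  mpre <- Em %*% w$Wm1
  mh <- relu(mpre)
  Mq <- sweep(mh %*% w$Wm2, 2, w$bm, "+")
  Mm <- sigmoid(Mq)
  RAm <- if (cfg$attention_variant == "mask_product") Em * Mm else
    Em * (1 + Mm)
  RAarr <- array(RAm, c(B, L, C2))
  # capsule predictions: one matmul per channel group, filling the routing
  # matrix Um (rows (b, l, t), columns (j, d))
  N <- L * nt
  Um <- matrix(0, B * N, J * D)
  Ut_list <- vector("list", nt)
  for (t in seq_len(nt)) {
    Ut <- matrix(RAarr[, , ((t - 1) * D + 1):(t * D)], B * L, D)
    Ut_list[[t]] <- Ut
    Wt_big <- matrix(aperm(array(w$Wcap[t, , , ], c(J, D, D)), c(3, 1, 2)),
                     D, J * D)
    Um[((t - 1) * B * L + 1):(t * B * L), ] <- Ut %*% Wt_big
  }
  rt <- routing_forward(Um, B, N, J, D, cfg$routing_iterations)
  F0 <- rt$vmat
  # stochastic-depth dense residual block
  hpre <- sweep(F0 %*% t(w$Wh1), 2, w$bh1, "+")
  hh <- relu(hpre)
  f2 <- sweep(hh %*% t(w$Wh2), 2, w$bh2, "+")
  gs <- if (train) stats::rbinom(B, 1, cfg$stochastic_depth_survival)
        else rep(cfg$stochastic_depth_survival, B)
  F1 <- F0 + f2 * gs
  # spatial dropout over whole capsules
  if (train && cfg$spatial_dropout_rate > 0) {
    keep <- matrix(stats::rbinom(B * J, 1, 1 - cfg$spatial_dropout_rate),
                   B, J) / (1 - cfg$spatial_dropout_rate)
  } else keep <- matrix(1, B, J)
  F1arr <- array(F1, c(B, J, D))
  F2arr <- F1arr * array(keep, c(B, J, D))
  # spatial average pooling and sigmoid head
  P <- matrix(rowMeans(matrix(F2arr, B * J, D)), B, J)
  logit <- as.numeric(P %*% w$Wo + w$bo)
  prob <- sigmoid(logit)
  out <- list(probability = prob, logit = logit)
  if (keep_cache)
    out$cache <- list(X = X, X1c = X1c, A1 = A1, H1arr = H1arr, X2c = X2c,
                      A2 = A2, H2arr = H2arr, z = z, s1 = s1, h1 = h1, q = q,
                      g = g, Earr = Earr, Em = Em, mpre = mpre, mh = mh,
                      Mm = Mm, RAarr = RAarr, Ut_list = Ut_list, Um = Um,
                      rt = rt, F0 = F0, hpre = hpre, hh = hh, f2 = f2,
                      gs = gs, keep = keep, F1arr = F1arr, P = P,
                      prob = prob, logit = logit)
  out
}

nn_backward <- function(model, cache, dlogit) {
  cfg <- model$config; w <- model$weights
  B <- length(dlogit); L <- model$input_length
  k <- cfg$kernel_size
  C1 <- cfg$conv_filters[1]; C2 <- cfg$conv_filters[2]
  J <- cfg$capsule_count; D <- cfg$capsule_dim; nt <- C2 %/% D
  gr <- list()
  # head
  gr$Wo <- t(cache$P) %*% matrix(dlogit, B, 1)
  gr$bo <- sum(dlogit)
  dP <- matrix(dlogit, B, 1) %*% t(w$Wo)              # (B, J)
  dF2 <- array(array(dP, c(B, J, D)) / D, c(B, J, D)) # pooling spread
  # spatial dropout
  dF1arr <- dF2 * array(cache$keep, c(B, J, D))
  dF1 <- matrix(dF1arr, B, J * D)
  # stochastic-depth residual block
  dF0 <- dF1
  df2 <- dF1 * cache$gs
  gr$bh2 <- colSums(df2)
  gr$Wh2 <- t(df2) %*% cache$hh
  dhh <- df2 %*% w$Wh2
  dhpre <- dhh * (cache$hpre > 0)
  gr$bh1 <- colSums(dhpre)
  gr$Wh1 <- t(dhpre) %*% cache$F0
  dF0 <- dF0 + dhpre %*% w$Wh1
  # routing
  N <- L * nt
  dUm <- routing_backward(cache$Um, B, N, J, D, cache$rt,
                          matrix(dF0, B, J * D))
  # capsule transforms
  dRAm <- matrix(0, B * L, C2)
  gr$Wcap <- array(0, dim(w$Wcap))
  for (t in seq_len(nt)) {
    Ut <- cache$Ut_list[[t]]
    rows_t <- ((t - 1) * B * L + 1):(t * B * L)
    Wt_big <- matrix(aperm(array(w$Wcap[t, , , ], c(J, D, D)), c(3, 1, 2)),
                     D, J * D)
    dUm_t <- dUm[rows_t, , drop = FALSE]
    dRAm[, ((t - 1) * D + 1):(t * D)] <- dUm_t %*% t(Wt_big)
    dWt_big <- t(Ut) %*% dUm_t
    gr$Wcap[t, , , ] <- aperm(array(dWt_big, c(D, J, D)), c(2, 3, 1))
  }
  # residual attention
  Em <- cache$Em; Mm <- cache$Mm
  if (cfg$attention_variant == "mask_product") {
    dEm <- dRAm * Mm
    dM <- dRAm * Em
  } else {
    dEm <- dRAm * (1 + Mm)
    dM <- dRAm * Em
  }
  dMq <- dM * Mm * (1 - Mm)
  gr$bm <- colSums(dMq)
  gr$Wm2 <- t(cache$mh) %*% dMq
  dmh <- dMq %*% t(w$Wm2)
  dmpre <- dmh * (cache$mpre > 0)
  gr$Wm1 <- t(Em) %*% dmpre
  dEm <- dEm + dmpre %*% t(w$Wm1)
  dEarr <- array(dEm, c(B, L, C2))
  # squeeze / excite
  dH2arr <- dEarr * spread_positions(cache$g, L)
  dg <- matrix(colSums(aperm(cache$H2arr * dEarr, c(2, 1, 3))), B, C2)
  if (cfg$activation_order == "standard") {
    dq <- dg * cache$g * (1 - cache$g)
    gr$Wse2 <- t(dq) %*% cache$h1
    dh1 <- dq %*% w$Wse2
    ds1 <- dh1 * (cache$s1 > 0)
  } else {
    dq <- dg * (cache$q > 0)
    gr$Wse2 <- t(dq) %*% cache$h1
    dh1 <- dq %*% w$Wse2
    ds1 <- dh1 * cache$h1 * (1 - cache$h1)
  }
  gr$Wse1 <- t(ds1) %*% cache$z
  dz <- ds1 %*% w$Wse1
  dH2arr <- dH2arr + spread_positions(dz, L) / L
  # conv block 2
  dH2 <- matrix(dH2arr, B * L, C2)
  dA2 <- dH2 * (cache$A2 > 0)
  gr$b2 <- colSums(dA2)
  gr$W2m <- t(cache$X2c) %*% dA2
  dX2c <- dA2 %*% t(w$W2m)
  half <- (k - 1L) %/% 2L
  dH1p <- col2im(dX2c, B, L, C1, k)
  dH1arr <- dH1p[, (half + 1L):(half + L), , drop = FALSE]
  # conv block 1
  dH1 <- matrix(dH1arr, B * L, C1)
  dA1 <- dH1 * (cache$A1 > 0)
  gr$b1 <- colSums(dA1)
  gr$W1m <- t(cache$X1c) %*% dA1
  gr
}

#' Forward pass of the ADENA network
#'
#' Runs the full pipeline on a batch of input feature vectors. Eval mode is
#' deterministic: dropout is off and the stochastic-depth block is always
#' active, rescaled by its survival probability. Train mode draws the
#' stochastic-depth and spatial-dropout gates from the current RNG stream
#' (seed it, or pass `seed`).
#'
#' @param model an [adena_init()] model.
#' @param x numeric matrix (batch x input_length) or single feature vector.
#' @param mode `"eval"` (default) or `"train"`.
#' @param seed optional seed for the training-mode stochastic gates.
#' @return list with `probability` and `logit` vectors
#'   (`probability = sigmoid(logit)`).
#' @export
adena_forward <- function(model, x, mode = c("eval", "train"), seed = NULL) {
  mode <- match.arg(mode)
  assert_that(inherits(model, "adena_model"), "model must be an adena_model")
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!is.null(seed)) return(with_seed(seed, nn_forward(model, x,
                                                        mode == "train")))
  nn_forward(model, x, train = (mode == "train"))
}

# flatten/unflatten weight lists for the optimizer and gradient checks
flatten_weights <- function(w) unlist(w, use.names = FALSE)

unflatten_weights <- function(vec, template) {
  out <- template
  pos <- 1L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    out[[nm]] <- template[[nm]]
    out[[nm]][] <- vec[pos:(pos + n - 1L)]
    pos <- pos + n
  }
  out
}
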