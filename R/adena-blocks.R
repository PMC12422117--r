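# Building blocks of the ADENA classifier: 1-D convolution with ReLU,
# squeeze-and-excitation channel gating, residual attention masking, capsule
# dynamic routing, and the combined focal + binary cross-entropy loss.
# Feature maps are channel x position matrices (the 2-D H x W formulation
# collapses to 1 x L for breath signals).

#' Convolution block: cross-correlation, bias, ReLU
#'
#' Computes `relu(w * x + b)` where `*` is "same"-padded cross-correlation
#' along the position axis.
#'
#' @param x input feature map, `C_in x L` matrix (a plain vector is treated
#'   as one channel).
#' @param weights kernel array `k x C_in x C_out`.
#' @param bias numeric vector of length `C_out`.
#' @return `C_out x L` feature map.
#' @export
conv_block <- function(x, weights, bias) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  dw <- dim(weights)
  assert_that(length(dw) == 3L, "weights must be a k x C_in x C_out array")
  assert_that(dw[2] == nrow(x),
              sprintf("input has %d channels, kernel expects %d",
                      nrow(x), dw[2]))
  assert_that(length(bias) == dw[3], "bias length must equal C_out")
  k <- dw[1]; L <- ncol(x)
  half <- (k - 1) %/% 2
  xp <- cbind(matrix(0, nrow(x), half), x, matrix(0, nrow(x), k - 1 - half))
  out <- matrix(0, dw[3], L)
  for (co in seq_len(dw[3])) {
    acc <- rep(bias[co], L)
    for (ci in seq_len(dw[2]))
      for (o in seq_len(k))
        acc <- acc + weights[o, ci, co] * xp[ci, (seq_len(L)) + (o - 1)]
    out[co, ] <- acc
  }
  relu(out)
}

#' Squeeze: per-channel global average
#'
#' @param x feature map, `C x L` matrix (channels in rows).
#' @return numeric vector `z` with `z[c] = mean(x[c, ])`.
#' @export
squeeze <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  assert_that(length(x) > 0, "empty feature map")
  rowMeans(x)
}

#' Excitation: channel gates from the squeezed descriptor
#'
#' Default (`"standard"`) computes `sigmoid(W2 %*% relu(W1 %*% z))`, giving
#' gates strictly inside (0, 1) as required for multiplicative channel
#' gating. `"paper_literal"` applies the activations in the reverse order,
#' `relu(W2 %*% sigmoid(W1 %*% z))`, and its gates are only bounded below.
#'
#' @param z squeezed channel vector, length `C`.
#' @param W1 bottleneck matrix `(C/r) x C`.
#' @param W2 expansion matrix `C x (C/r)`.
#' @param activation_order `"standard"` or `"paper_literal"`.
#' @return gate vector of length `C`.
#' @export
excite <- function(z, W1, W2, activation_order = c("standard",
                                                   "paper_literal")) {
  activation_order <- match.arg(activation_order)
  assert_that(ncol(W1) == length(z), "W1 columns must match length(z)")
  assert_that(ncol(W2) == nrow(W1) && nrow(W2) == length(z),
              "W2 must be C x (C/r) with W1 (C/r) x C")
  if (activation_order == "standard")
    as.numeric(sigmoid(W2 %*% relu(W1 %*% z)))
  else
    as.numeric(relu(W2 %*% sigmoid(W1 %*% z)))
}

#' Residual attention: mask-modulated feature map
#'
#' Applies an attention mask to the excitation output `e`:
#' `mask_product` returns `M * e` (the literal reading of the architecture),
#' `residual_mask` returns `(1 + M) * e` (the residual-attention-literature
#' form). The mask is supplied explicitly here; inside the full network it
#' is a learned sigmoid bottleneck over `e` (see [adena_forward()]).
#'
#' @param e feature map matrix.
#' @param mask matrix of the same shape with entries in `[0, 1]`.
#' @param variant `"mask_product"` (default) or `"residual_mask"`.
#' @return modulated feature map.
#' @export
residual_attention <- function(e, mask,
                               variant = c("mask_product", "residual_mask")) {
  variant <- match.arg(variant)
  assert_that(identical(dim(e) %||% length(e), dim(mask) %||% length(mask)),
              "mask shape must equal feature shape")
  if (variant == "mask_product") mask * e else (1 + mask) * e
}

#' Squash nonlinearity
#'
#' `squash(s) = (||s||^2 / (1 + ||s||^2)) * s / ||s||`; output norm is
#' always `< 1` and the zero vector maps to itself.
#'
#' @param s numeric vector.
#' @return squashed vector.
#' @export
squash <- function(s) {
  n2 <- sum(s^2)
  if (n2 == 0) return(s)
  (n2 / (1 + n2)) * s / sqrt(n2)
}

#' Dynamic routing by agreement
#'
#' Capsule routing: coupling logits start at zero; each iteration computes
#' coupling coefficients as a softmax over output capsules, forms weighted
#' prediction sums, squashes them, and (between iterations) reinforces the
#' logits by the scalar agreement between predictions and outputs.
#'
#' @param u_hat prediction-vector array `N_in x J x D` (input capsule x
#'   output capsule x dimension).
#' @param iterations number of routing rounds, at least 1.
#' @return list: `v` (`J x D` output capsule matrix), `coupling`
#'   (`N_in x J` final coefficients).
#' @export
dynamic_routing <- function(u_hat, iterations = 3L) {
  assert_that(is.array(u_hat) && length(dim(u_hat)) == 3L,
              "u_hat must be an N x J x D array")
  assert_that(all(is.finite(u_hat)), "u_hat must be finite")
  assert_that(is_count(iterations), "iterations must be >= 1")
  d <- dim(u_hat)  # (N, J, D); rows (b=1, n), columns (j, d)
  Um <- matrix(u_hat, d[1], d[2] * d[3])
  out <- routing_forward(Um, 1L, d[1], d[2], d[3], as.integer(iterations))
  list(v = matrix(out$vmat, d[2], d[3]),
       coupling = matrix(out$c_list[[length(out$c_list)]], d[1], d[2]))
}

PROB_EPS <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

#' Focal loss
#'
#' `-(1 - p_t)^gamma * log(p_t)` with `p_t = p` for positives and `1 - p`
#' for negatives; probabilities are clamped at `1e-7`. `gamma = 0` reduces
#' exactly to cross-entropy.
#'
#' @param y 0/1 labels.
#' @param p predicted probabilities.
#' @param gamma focusing parameter, `>= 0` (default 2).
#' @return per-element focal loss vector.
#' @export
focal_loss <- function(y, p, gamma = 2) {
  assert_that(length(y) == length(p), "label/probability length mismatch")
  assert_that(gamma >= 0, "gamma must be >= 0")
  p <- clamp_prob(p)
  pt <- ifelse(y == 1, p, 1 - p)
  -(1 - pt)^gamma * log(pt)
}

bce_loss <- function(y, p) {
  p <- clamp_prob(p)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Combined focal + binary cross-entropy loss
#'
#' Mean over the batch of `focal_loss + BCE`. With `gamma = 0` this equals
#' exactly twice the mean binary cross-entropy.
#'
#' @inheritParams focal_loss
#' @return scalar loss.
#' @export
combined_loss <- function(y, p, gamma = 2) {
  assert_that(length(y) == length(p), "label/probability length mismatch")
  mean(focal_loss(y, p, gamma) + bce_loss(y, p))
}

# d(combined)/dp, elementwise (batch mean applied by caller)
combined_loss_grad_p <- function(y, p, gamma = 2) {
  p <- clamp_prob(p)
  gfoc <- if (gamma == 0) ifelse(y == 1, -1 / p, 1 / (1 - p)) else ifelse(
    y == 1,
    gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p,
    -gamma * p^(gamma - 1) * log(1 - p) + p^gamma / (1 - p))
  gbce <- ifelse(y == 1, -1 / p, 1 / (1 - p))
  gfoc + gbce
}
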