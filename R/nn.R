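# Minimal dense-network engine: fully connected layers with batch
# normalization and LeakyReLU, trained full-batch with Adam via hand-written
# backpropagation. All heavy operations are BLAS matrix products; elementwise
# work uses fused column-broadcast idioms. Hidden layers carry no bias term:
# batch normalization centers each column, so a pre-BN bias is exactly
# redundant (its gradient is identically zero); BN's beta plays that role.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# broadcast a length-h vector across the n rows of an n x h matrix
# (rep.int is several times faster than rep(v, each = n))
.rows <- function(v, n) rep.int(v, rep.int(n, length(v)))

.cmeans <- function(X) .colMeans(X, nrow(X), ncol(X))
.csums <- function(X) .colSums(X, nrow(X), ncol(X))

#' @noRd
nn_init_mlp <- function(input_dim, hidden, out_dim = NULL, slope = 0.01) {
  stopifnot(input_dim >= 1, all(hidden >= 1))
  layers <- vector("list", length(hidden))
  fan_in <- input_dim
  # Kaiming fan-in scaling adapted for LeakyReLU
  for (l in seq_along(hidden)) {
    h <- hidden[l]
    sd <- sqrt(2 / ((1 + slope^2) * fan_in))
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * h, sd = sd), fan_in, h),
      gamma = rep(1, h), beta = numeric(h),
      r_mean = numeric(h), r_var = rep(1, h)
    )
    fan_in <- h
  }
  final <- NULL
  if (!is.null(out_dim)) {
    sd <- sqrt(1 / fan_in)
    final <- list(W = matrix(stats::rnorm(fan_in * out_dim, sd = sd), fan_in, out_dim),
                  b = numeric(out_dim))
  }
  structure(list(input_dim = input_dim, hidden = hidden, out_dim = out_dim,
                 slope = slope, layers = layers, final = final),
            class = "nn_mlp")
}

# Forward pass. training = TRUE uses batch statistics and updates running
# statistics; training = FALSE uses running statistics (deterministic).
# Returns list(out, cache, net); cache is NULL unless keep_cache.
#' @noRd
nn_forward <- function(net, X, training = FALSE, keep_cache = FALSE) {
  if (!is.matrix(X) || ncol(X) != net$input_dim)
    stop(sprintf("input must be a matrix with %d columns", net$input_dim))
  n <- nrow(X)
  slope <- net$slope
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  H <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    A <- H %*% ly$W
    if (training) {
      mv <- col_mean_var(A)
      mu <- mv$mean; v <- mv$var
      inv <- 1 / sqrt(v + BN_EPS)
      net$layers[[l]]$r_mean <- (1 - BN_MOMENTUM) * ly$r_mean + BN_MOMENTUM * mu
      net$layers[[l]]$r_var <- (1 - BN_MOMENTUM) * ly$r_var + BN_MOMENTUM * v
    } else {
      mu <- ly$r_mean
      inv <- 1 / sqrt(ly$r_var + BN_EPS)
    }
    Hn <- if (keep_cache) bn_act_forward(A, mu, inv, ly$gamma, ly$beta, slope)
          else bn_act_eval(A, mu, inv, ly$gamma, ly$beta, slope)
    if (keep_cache) {
      # H doubles as the LeakyReLU derivative record (fac = 1 where H > 0);
      # Ahat is recomputed in backward from A, mu, inv
      caches[[l]] <- list(X = H, A = A, mu = mu, inv = inv, H = Hn)
    }
    H <- Hn
  }
  out <- H
  final_cache <- NULL
  if (!is.null(net$final)) {
    if (keep_cache) final_cache <- H
    out <- H %*% net$final$W + .rows(net$final$b, n)
  }
  cache <- if (keep_cache) list(layers = caches, final_in = final_cache, n = n) else NULL
  list(out = out, cache = cache, net = net)
}

# Backpropagation from d_out (gradient w.r.t. nn_forward output) to parameter
# gradients, optionally also the gradient w.r.t. the network input.
#' @noRd
nn_backward <- function(net, cache, d_out, input_grad = TRUE) {
  n <- cache$n
  grads <- list(layers = vector("list", length(net$layers)), final = NULL)
  dH <- d_out
  if (!is.null(net$final)) {
    Hin <- cache$final_in
    grads$final <- list(W = crossprod(Hin, d_out), b = .csums(d_out))
    dH <- tcrossprod(d_out, net$final$W)
  }
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    cc <- cache$layers[[l]]
    bw <- bn_act_backward(dH, cc$H, cc$A, cc$mu, ly$gamma, cc$inv, net$slope)
    grads$layers[[l]] <- list(W = crossprod(cc$X, bw$dA),
                              gamma = bw$dgamma, beta = bw$dbeta)
    if (l > 1L || input_grad) dH <- tcrossprod(bw$dA, ly$W) else dH <- NULL
  }
  list(grads = grads, d_input = dH)
}

#' @noRd
nn_n_params <- function(net) {
  tot <- 0L
  for (ly in net$layers) tot <- tot + length(ly$W) +
      length(ly$gamma) + length(ly$beta)
  if (!is.null(net$final)) tot <- tot + length(net$final$W) + length(net$final$b)
  tot
}

# ---- Adam ----------------------------------------------------------------

#' @noRd
adam_new <- function() list(t = 0L, m = NULL, v = NULL)

# Applies one Adam step to `net` given `grads` from nn_backward.
# Returns list(net, state). beta1/beta2/eps are the usual defaults.
#' @noRd
adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  # adam_fused mutates the moment buffers m and v in place (they are owned
  # exclusively by this state) and returns the fresh parameter vector
  upd <- function(p, g, m, v) {
    if (is.null(m)) m <- p * 0
    if (is.null(v)) v <- p * 0
    list(p = adam_fused(p, g, m, v, beta1, beta2, bc1, bc2, lr, eps),
         m = m, v = v)
  }
  if (is.null(state$m)) {
    state$m <- list(layers = vector("list", length(net$layers)), final = NULL)
    state$v <- state$m
  }
  for (l in seq_along(net$layers)) {
    for (nm in c("W", "gamma", "beta")) {
      r <- upd(net$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               state$m$layers[[l]][[nm]], state$v$layers[[l]][[nm]])
      net$layers[[l]][[nm]] <- r$p
      state$m$layers[[l]][[nm]] <- r$m
      state$v$layers[[l]][[nm]] <- r$v
    }
  }
  if (!is.null(net$final)) {
    for (nm in c("W", "b")) {
      r <- upd(net$final[[nm]], grads$final[[nm]],
               state$m$final[[nm]], state$v$final[[nm]])
      net$final[[nm]] <- r$p
      state$m$final[[nm]] <- r$m
      state$v$final[[nm]] <- r$v
    }
  }
  list(net = net, state = state)
}

# ---- shared numeric helpers ----------------------------------------------

#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a logit matrix.
#'
#' @param logits numeric matrix of unnormalized scores.
#' @return matrix of the same shape with rows summing to 1.
#' @export
softmax <- function(logits) {
  stopifnot(is.matrix(logits))
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
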