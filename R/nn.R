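## Minimal fully-connected network with manual backpropagation, used by the
## conditional GAN trainers. Rows are samples. Hidden activation is leaky
## ReLU (slope 0.2); the output activation is per-network ("linear", "tanh"
## or "sigmoid"). Everything runs on base-R matrix ops.

LRELU_SLOPE <- 0.2

mlp_init <- function(sizes) {
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    n_in <- sizes[l]; n_out <- sizes[l + 1L]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
      b = numeric(n_out))
  }
  layers
}

act_fun <- function(Z, act) {
  switch(act,
         lrelu = ifelse(Z > 0, Z, LRELU_SLOPE * Z),
         tanh = tanh(Z),
         sigmoid = 1 / (1 + exp(-Z)),
         linear = Z)
}

act_grad <- function(Z, A, act) {
  switch(act,
         lrelu = ifelse(Z > 0, 1, LRELU_SLOPE),
         tanh = 1 - A^2,
         sigmoid = A * (1 - A),
         linear = matrix(1, nrow(Z), ncol(Z)))
}

mlp_forward <- function(net, X, out_act = "linear") {
  L <- length(net)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net[[l]]$W, 2, net[[l]]$b, "+")
    A[[l + 1L]] <- act_fun(Z[[l]], if (l < L) "lrelu" else out_act)
  }
  list(out = A[[L + 1L]], A = A, Z = Z, out_act = out_act)
}

## dOut is dLoss/d(output activation); returns per-layer gradients and the
## gradient w.r.t. the network input (needed to push generator updates
## through the critic).
mlp_backward <- function(net, cache, dOut) {
  L <- length(net)
  grads <- vector("list", L)
  dZ <- dOut * act_grad(cache$Z[[L]], cache$A[[L + 1L]], cache$out_act)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(cache$A[[l]], dZ), b = colSums(dZ))
    dA <- dZ %*% t(net[[l]]$W)
    if (l > 1L) dZ <- dA * act_grad(cache$Z[[l - 1L]], cache$A[[l]], "lrelu")
  }
  list(grads = grads, dInput = dA)
}

opt_init <- function(net, method, lr) {
  state <- list(method = method, lr = lr, t = 0L,
                m = lapply(net, function(l) list(W = l$W * 0, b = l$b * 0)),
                v = lapply(net, function(l) list(W = l$W * 0, b = l$b * 0)))
  state
}

## One minimizing step; returns updated net and state.
opt_step <- function(net, grads, state) {
  lr <- state$lr
  if (state$method == "rmsprop") {
    rho <- 0.9; eps <- 1e-8
    for (l in seq_along(net)) {
      for (par in c("W", "b")) {
        g <- grads[[l]][[par]]
        state$v[[l]][[par]] <- rho * state$v[[l]][[par]] + (1 - rho) * g^2
        net[[l]][[par]] <- net[[l]][[par]] -
          lr * g / sqrt(state$v[[l]][[par]] + eps)
      }
    }
  } else {  # adam
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
    for (l in seq_along(net)) {
      for (par in c("W", "b")) {
        g <- grads[[l]][[par]]
        state$m[[l]][[par]] <- b1 * state$m[[l]][[par]] + (1 - b1) * g
        state$v[[l]][[par]] <- b2 * state$v[[l]][[par]] + (1 - b2) * g^2
        net[[l]][[par]] <- net[[l]][[par]] -
          lr * (state$m[[l]][[par]] / corr1) /
            (sqrt(state$v[[l]][[par]] / corr2) + eps)
      }
    }
  }
  list(net = net, state = state)
}

clip_net <- function(net, bound) {
  lapply(net, function(l) list(W = pmin(pmax(l$W, -bound), bound),
                               b = pmin(pmax(l$b, -bound), bound)))
}

net_max_abs <- function(net) {
  max(vapply(net, function(l) max(abs(l$W), abs(l$b)), numeric(1)))
}
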