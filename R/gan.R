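#' Configuration for the conditional GAN trainers
#'
#' Defaults follow standard practice for tabular conditional (W)GANs:
#' a 100-dimensional Gaussian noise prior, fully-connected generator
#' noise+labels -> 256 -> 512 -> features with tanh output over
#' min-max-scaled features, critic features+labels -> 512 -> 256 -> 1 with
#' leaky-ReLU hidden units, weight-clip bound 0.01, 5 critic steps per
#' generator step and RMSProp at 5e-5 for the Wasserstein variant (Adam at
#' 2e-4 for the plain conditional GAN). Production runs use tens of
#' thousands of iterations; scale `iterations` down for quick experiments.
#'
#' @param noise_dim dimension of the Gaussian noise prior.
#' @param gen_hidden,critic_hidden hidden-layer widths.
#' @param lr learning rate; `NULL` picks the per-method default.
#' @param clip critic weight-clip bound c (> 0, Wasserstein only).
#' @param n_critic critic updates per generator update (Wasserstein only).
#' @param iterations number of generator iterations.
#' @param batch_size minibatch size.
#' @param per_class train one model per class instead of a single
#'   label-conditioned model (non-default).
#' @param seed RNG seed for training.
#' @return a `gan_config` list.
#' @export
gan_config <- function(noise_dim = 100, gen_hidden = c(256, 512),
                       critic_hidden = c(512, 256), lr = NULL, clip = 0.01,
                       n_critic = 5, iterations = 50000, batch_size = 64,
                       per_class = FALSE, seed = 1L) {
  stopifnot(clip > 0, iterations >= 1, batch_size >= 1, n_critic >= 1)
  structure(list(noise_dim = noise_dim, gen_hidden = gen_hidden,
                 critic_hidden = critic_hidden, lr = lr, clip = clip,
                 n_critic = n_critic, iterations = iterations,
                 batch_size = batch_size, per_class = per_class,
                 seed = seed),
            class = "gan_config")
}

## Min-max scaler to [-1, 1], fitted on real rows only; constant columns
## map to 0 and invert to their constant.
fit_minmax <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  list(lo = lo, hi = hi, span = ifelse(hi > lo, hi - lo, 1))
}
apply_minmax <- function(scaler, X) {
  Xs <- sweep(sweep(X, 2, scaler$lo), 2, scaler$span, "/") * 2 - 1
  Xs[, scaler$hi == scaler$lo] <- 0
  Xs
}
invert_minmax <- function(scaler, Xs) {
  X <- sweep(sweep((Xs + 1) / 2, 2, scaler$span, "*"), 2, scaler$lo, "+")
  for (j in which(scaler$hi == scaler$lo)) X[, j] <- scaler$lo[j]
  X
}

onehot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  Y
}

#' Per-class synthetic-sample deficits for balancing
#'
#' Deficit of a class is the majority-class count minus its own count; the
#' reference (largest) class has deficit 0.
#'
#' @param class_counts named or plain integer vector of per-class counts.
#' @return integer vector of deficits, same order and names.
#' @export
compute_deficits <- function(class_counts) {
  stopifnot(all(class_counts >= 1))
  as.integer(max(class_counts) - class_counts) |>
    stats::setNames(names(class_counts))
}

gan_new <- function(method, p, classes, config) {
  K <- length(classes)
  gen <- mlp_init(c(config$noise_dim + K, config$gen_hidden, p))
  critic <- mlp_init(c(p + K, config$critic_hidden, 1))
  structure(list(method = method, generator = gen, critic = critic,
                 classes = classes, p = p, config = config, scaler = NULL,
                 trace = NULL),
            class = "gan_model")
}

gan_sample_fake <- function(model, Y) {
  z <- matrix(stats::rnorm(nrow(Y) * model$config$noise_dim), nrow(Y))
  mlp_forward(model$generator, cbind(z, Y), out_act = "tanh")
}

## Shared training loop for both conditional variants. `Xs` is scaled to
## [-1, 1]; Y one-hot labels.
gan_train_loop <- function(model, Xs, Y) {
  cfg <- model$config
  wasserstein <- model$method == "cwgan"
  lr <- if (!is.null(cfg$lr)) cfg$lr else if (wasserstein) 5e-5 else 2e-4
  opt_method <- if (wasserstein) "rmsprop" else "adam"
  g_state <- opt_init(model$generator, opt_method, lr)
  d_state <- opt_init(model$critic, opt_method, lr)
  n <- nrow(Xs)
  gloss <- dloss <- numeric(cfg$iterations)
  n_d_steps <- if (wasserstein) cfg$n_critic else 1L
  clip_trace <- numeric(cfg$iterations * n_d_steps)
  step <- 0L
  for (it in seq_len(cfg$iterations)) {
    for (d_it in seq_len(n_d_steps)) {
      idx <- sample.int(n, cfg$batch_size, replace = cfg$batch_size > n)
      xb <- Xs[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
      fake <- gan_sample_fake(model, yb)
      cr <- mlp_forward(model$critic, cbind(xb, yb), "linear")
      cf <- mlp_forward(model$critic, cbind(fake$out, yb), "linear")
      m <- cfg$batch_size
      if (wasserstein) {
        # minimize -(E[D(x|y)] - E[D(G(z|y))]); no sigmoid, no logs
        d_val <- mean(cr$out) - mean(cf$out)
        d_real <- matrix(-1 / m, m, 1)
        d_fake <- matrix(1 / m, m, 1)
      } else {
        sr <- 1 / (1 + exp(-cr$out)); sf <- 1 / (1 + exp(-cf$out))
        d_val <- -(mean(log(pmax(sr, 1e-12))) + mean(log(pmax(1 - sf, 1e-12))))
        d_real <- -(1 - sr) / m
        d_fake <- sf / m
      }
      if (!is.finite(d_val)) stop("non-finite discriminator loss at iteration ", it)
      br <- mlp_backward(model$critic, cr, if (wasserstein) d_real else d_real)
      bf <- mlp_backward(model$critic, cf, d_fake)
      grads <- lapply(seq_along(br$grads), function(l) list(
        W = br$grads[[l]]$W + bf$grads[[l]]$W,
        b = br$grads[[l]]$b + bf$grads[[l]]$b))
      upd <- opt_step(model$critic, grads, d_state)
      model$critic <- upd$net; d_state <- upd$state
      if (wasserstein) model$critic <- clip_net(model$critic, cfg$clip)
      step <- step + 1L
      clip_trace[step] <- net_max_abs(model$critic)
    }
    dloss[it] <- d_val
    # generator step
    idx <- sample.int(n, cfg$batch_size, replace = cfg$batch_size > n)
    yb <- Y[idx, , drop = FALSE]
    fake <- gan_sample_fake(model, yb)
    cf <- mlp_forward(model$critic, cbind(fake$out, yb), "linear")
    m <- cfg$batch_size
    if (wasserstein) {
      g_val <- -mean(cf$out)
      d_out <- matrix(-1 / m, m, 1)
    } else {
      sf <- 1 / (1 + exp(-cf$out))
      g_val <- mean(log(pmax(1 - sf, 1e-12)))
      d_out <- -sf / m
    }
    if (!is.finite(g_val)) stop("non-finite generator loss at iteration ", it)
    bc <- mlp_backward(model$critic, cf, d_out)
    d_gen_out <- bc$dInput[, seq_len(model$p), drop = FALSE]
    bg <- mlp_backward(model$generator, fake, d_gen_out)
    upd <- opt_step(model$generator, bg$grads, g_state)
    model$generator <- upd$net; g_state <- upd$state
    gloss[it] <- g_val
  }
  model$trace <- data.frame(iteration = seq_len(cfg$iterations),
                            gloss = gloss, dloss = dloss)
  model$critic_step_max <- clip_trace
  model
}

gan_train <- function(X, labels, config, method) {
  labels <- factor(labels)
  classes <- levels(labels)
  if (!is.null(config$seed)) set.seed(config$seed)
  scaler <- fit_minmax(X)
  Xs <- apply_minmax(scaler, X)
  if (config$per_class) {
    models <- lapply(classes, function(cl) {
      sub <- labels == cl
      m <- gan_new(method, ncol(X), cl, config)
      m$scaler <- scaler
      gan_train_loop(m, Xs[sub, , drop = FALSE],
                     matrix(1, sum(sub), 1))
    })
    names(models) <- classes
    return(structure(list(method = method, models = models, classes = classes,
                          p = ncol(X), config = config, scaler = scaler,
                          trace = models[[1]]$trace),
                     class = c("gan_model_set", "gan_model")))
  }
  model <- gan_new(method, ncol(X), classes, config)
  model$scaler <- scaler
  gan_train_loop(model, Xs, onehot(labels, classes))
}

#' Train a conditional GAN on a labelled feature matrix
#'
#' Alternating updates of a sigmoid discriminator (maximising
#' `log D(x|y) + log(1 - D(G(z|y)))`) and the generator (minimising
#' `log(1 - D(G(z|y)))`), with Adam. Both networks are conditioned on the
#' one-hot class label. Features are min-max scaled to \[-1, 1\]
#' internally; per-iteration generator and discriminator losses are
#' recorded in `$trace`.
#'
#' @param X samples x features numeric matrix (real rows only).
#' @param labels class factor for `X`'s rows.
#' @param config a [gan_config()].
#' @return a `gan_model` with elements `generator`, `critic`, `classes`,
#'   `scaler`, `config` and `trace` (iteration, gloss, dloss).
#' @export
train_cgan <- function(X, labels, config = gan_config()) {
  gan_train(X, labels, config, "cgan")
}

#' Train a conditional Wasserstein GAN (weight clipping)
#'
#' The critic has no output sigmoid and no logarithms in the loss: it
#' maximises `E[D(x|y)] - E[D(G(z|y))]`, with every critic parameter
#' clipped to `[-c, c]` after each of the `n_critic` critic updates per
#' generator step, and RMSProp as optimizer.
#'
#' @inheritParams train_cgan
#' @return a `gan_model`; `$critic_step_max` records the maximum absolute
#'   critic parameter after every critic update.
#' @export
train_cwgan <- function(X, labels, config = gan_config()) {
  gan_train(X, labels, config, "cwgan")
}

#' Sample synthetic rows of one class from a trained model
#'
#' @param model a trained `gan_model`.
#' @param class_label class name (or index into `model$classes`).
#' @param n number of rows (0 gives an empty batch).
#' @param seed optional RNG seed for reproducible sampling.
#' @return a matrix `n x p` in original feature space, with attributes
#'   `class_label` and `synthetic = TRUE`.
#' @export
gan_generate <- function(model, class_label, n, seed = NULL) {
  stopifnot(n >= 0)
  if (is.numeric(class_label)) class_label <- model$classes[class_label]
  if (is.na(class_label) || !(class_label %in% model$classes))
    stop("unknown class: ", class_label)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(model, "gan_model_set")) {
    sub <- model$models[[class_label]]
    Y <- matrix(1, n, 1)
    gen <- sub
  } else {
    Y <- onehot(rep(class_label, n), model$classes)
    gen <- model
  }
  if (n == 0) {
    out <- matrix(numeric(0), 0, model$p)
  } else {
    out <- invert_minmax(model$scaler, gan_sample_fake(gen, Y)$out)
  }
  attr(out, "class_label") <- class_label
  attr(out, "synthetic") <- TRUE
  out
}

#' Balance a labelled feature matrix by synthetic oversampling
#'
#' Adds per-class synthetic rows sized by [compute_deficits()] so every
#' class reaches the majority count. Real rows are never modified.
#' `"smote"` interpolates between within-class nearest neighbours;
#' `"none"` returns the input unchanged.
#'
#' @param X samples x features numeric matrix.
#' @param labels class factor for `X`'s rows.
#' @param method `"cwgan"` (default), `"cgan"`, `"smote"` or `"none"`.
#' @param config a [gan_config()] (GAN methods; its seed also drives SMOTE).
#' @param smote_k neighbours for SMOTE interpolation.
#' @return a list with `X`, `labels`, `synthetic` (logical row flags),
#'   `model` (trained GAN or `NULL`) and `deficits`.
#' @export
augment_dataset <- function(X, labels,
                            method = c("cwgan", "cgan", "smote", "none"),
                            config = gan_config(), smote_k = 5) {
  method <- match.arg(method)
  labels <- factor(labels)
  stopifnot(nlevels(labels) >= 2)
  counts <- table(labels)
  deficits <- compute_deficits(as.integer(counts)) |>
    stats::setNames(names(counts))
  if (method == "none" || all(deficits == 0)) {
    return(list(X = X, labels = labels,
                synthetic = rep(FALSE, nrow(X)), model = NULL,
                deficits = deficits))
  }
  model <- NULL
  new_rows <- list(); new_labels <- list()
  if (method %in% c("cgan", "cwgan")) {
    model <- gan_train(X, labels, config, method)
    for (cl in names(deficits)) {
      d <- deficits[[cl]]
      if (d > 0) {
        new_rows[[cl]] <- gan_generate(model, cl, d)
        new_labels[[cl]] <- rep(cl, d)
      }
    }
  } else {  # smote
    if (!is.null(config$seed)) set.seed(config$seed)
    for (cl in names(deficits)) {
      d <- deficits[[cl]]
      if (d > 0) {
        new_rows[[cl]] <- smote_rows(X[labels == cl, , drop = FALSE], d, smote_k)
        new_labels[[cl]] <- rep(cl, d)
      }
    }
  }
  Xa <- rbind(X, do.call(rbind, new_rows))
  la <- factor(c(as.character(labels), unlist(new_labels)),
               levels = levels(labels))
  list(X = Xa, labels = la,
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(Xa) - nrow(X))),
       model = model, deficits = deficits)
}

## k-NN interpolation oversampling within one class (SMOTE-style baseline).
smote_rows <- function(Xc, n_new, k = 5) {
  n <- nrow(Xc)
  if (n == 1) return(Xc[rep(1, n_new), , drop = FALSE])
  k <- min(k, n - 1)
  D <- as.matrix(stats::dist(Xc))
  nn <- apply(D, 1, function(d) order(d)[2:(k + 1)])
  if (is.null(dim(nn))) nn <- matrix(nn, nrow = 1)
  i <- sample.int(n, n_new, replace = TRUE)
  j <- vapply(i, function(ii) nn[sample.int(k, 1), ii], integer(1))
  gap <- stats::runif(n_new)
  Xc[i, , drop = FALSE] + gap * (Xc[j, , drop = FALSE] - Xc[i, , drop = FALSE])
}

#' Euclidean distance between class means of real and synthetic rows
#'
#' The generative diagnostic: the norm of the difference between the
#' column-mean of the real rows and of the synthetic rows of one class.
#'
#' @param real,synthetic non-empty matrices of equal width.
#' @return a non-negative scalar.
#' @export
mean_distance <- function(real, synthetic) {
  if (nrow(real) == 0 || nrow(synthetic) == 0) stop("empty row set")
  if (ncol(real) != ncol(synthetic)) stop("feature widths differ")
  sqrt(sum((colMeans(real) - colMeans(synthetic))^2))
}

#' Write a per-iteration loss trace as CSV
#' @param model a trained `gan_model`.
#' @param path CSV path (columns iteration, gloss, dloss).
#' @export
write_loss_trace <- function(model, path) {
  utils::write.csv(model$trace, path, row.names = FALSE)
  invisible(path)
}
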