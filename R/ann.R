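# A small feed-forward binary classifier written directly in R matrix
# algebra: ReLU hidden layers, sigmoid output, binary cross-entropy loss,
# inverted dropout, L2 weight decay, Adam updates, optional early stopping,
# and per-layer freezing for the transfer phase. Freezing is implemented by
# skipping the parameter update of the frozen dense layers entirely, so
# frozen weights stay bitwise identical through fine-tuning.

#' ANN configuration
#'
#' Defaults follow a funnel-shaped architecture with dropout after the two
#' widest hidden layers and mild L2 decay; all values are configurable and
#' smaller architectures are appropriate for the few dozen features of the
#' synthetic data.
#'
#' @param layer_widths widths of the hidden dense layers (the 1-unit sigmoid
#'   output layer is implicit).
#' @param dropout_rates dropout probability after each hidden layer (recycled
#'   to `length(layer_widths)`).
#' @param l2_strength L2 penalty on weights.
#' @param epochs maximum training epochs.
#' @param optimizer_name only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience (epochs without validation
#'   improvement) when a validation set is supplied.
#' @param frozen_layers indices of dense layers (1 = first hidden, up to the
#'   output layer) whose parameters are not updated; used in the transfer
#'   phase only.
#' @param rng_seed integer seed for initialization, shuffling and dropout.
#' @export
ann_config <- function(layer_widths = c(256L, 128L, 64L, 32L),
                       dropout_rates = c(0.3, 0.3, 0, 0),
                       l2_strength = 1e-4, epochs = 200L,
                       optimizer_name = "adam", learning_rate = 1e-3,
                       batch_size = 64L, patience = 20L,
                       frozen_layers = integer(0), rng_seed = 1L) {
  stopifnot(all(layer_widths >= 1L), l2_strength >= 0, epochs >= 1L,
            learning_rate > 0, all(dropout_rates >= 0), all(dropout_rates < 1))
  if (optimizer_name != "adam") stopf("optimizer '%s' not implemented", optimizer_name)
  dropout_rates <- rep_len(dropout_rates, length(layer_widths))
  structure(list(layer_widths = as.integer(layer_widths),
                 dropout_rates = dropout_rates, l2_strength = l2_strength,
                 epochs = as.integer(epochs), optimizer_name = optimizer_name,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 frozen_layers = as.integer(frozen_layers),
                 rng_seed = as.integer(rng_seed)),
            class = "ann_config")
}

ann_init <- function(n_in, cfg) {
  widths <- c(n_in, cfg$layer_widths, 1L)
  L <- length(widths) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialization for ReLU layers
    W[[l]] <- matrix(rnorm(widths[l] * widths[l + 1L], 0,
                           sqrt(2 / widths[l])), widths[l], widths[l + 1L])
    b[[l]] <- rep(0, widths[l + 1L])
  }
  list(W = W, b = b, n_layers = L)
}

ann_forward <- function(net, X, dropout = NULL) {
  L <- net$n_layers
  a <- X
  zs <- vector("list", L)
  as <- vector("list", L + 1L)
  masks <- vector("list", L)
  as[[1L]] <- a
  for (l in seq_len(L)) {
    z <- sweep(a %*% net$W[[l]], 2L, net$b[[l]], `+`)
    zs[[l]] <- z
    if (l < L) {
      a <- pmax(z, 0)
      if (!is.null(dropout) && dropout[l] > 0) {
        keep <- matrix(runif(length(a)) >= dropout[l], nrow(a), ncol(a))
        a <- a * keep / (1 - dropout[l])
        masks[[l]] <- keep / (1 - dropout[l])
      }
    } else {
      a <- 1 / (1 + exp(-z))
    }
    as[[l + 1L]] <- a
  }
  list(zs = zs, as = as, masks = masks, out = drop(a))
}

ann_bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# One Adam minibatch step; returns updated net and optimizer state.
ann_step <- function(net, opt, X, y, cfg) {
  L <- net$n_layers
  fw <- ann_forward(net, X, dropout = cfg$dropout_rates)
  p <- fw$as[[L + 1L]]
  n <- nrow(X)
  delta <- (p - y) / n # d(BCE)/dz at the sigmoid output
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$as[[l]], delta) + 2 * cfg$l2_strength * net$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- tcrossprod(delta, net$W[[l]])
      if (!is.null(fw$masks[[l - 1L]])) delta <- delta * fw$masks[[l - 1L]]
      delta <- delta * (fw$zs[[l - 1L]] > 0)
    }
  }
  opt$t <- opt$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr_t <- cfg$learning_rate * sqrt(1 - b2^opt$t) / (1 - b1^opt$t)
  for (l in seq_len(L)) {
    if (l %in% cfg$frozen_layers) next
    opt$mW[[l]] <- b1 * opt$mW[[l]] + (1 - b1) * gW[[l]]
    opt$vW[[l]] <- b2 * opt$vW[[l]] + (1 - b2) * gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr_t * opt$mW[[l]] / (sqrt(opt$vW[[l]]) + eps)
    opt$mb[[l]] <- b1 * opt$mb[[l]] + (1 - b1) * gb[[l]]
    opt$vb[[l]] <- b2 * opt$vb[[l]] + (1 - b2) * gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr_t * opt$mb[[l]] / (sqrt(opt$vb[[l]]) + eps)
  }
  list(net = net, opt = opt)
}

ann_fit <- function(X, y, cfg, net = NULL, X_val = NULL, y_val = NULL) {
  if (length(unique(y)) < 2L) {
    stopf("degenerate training set: all labels identical")
  }
  if (length(cfg$frozen_layers) &&
      all(seq_len(length(cfg$layer_widths) + 1L) %in% cfg$frozen_layers)) {
    stopf("all layers are frozen: nothing to train")
  }
  with_local_seed(cfg$rng_seed, {
    if (is.null(net)) net <- ann_init(ncol(X), cfg)
    L <- net$n_layers
    zero_like <- function(x) lapply(x, function(m) m * 0)
    opt <- list(mW = zero_like(net$W), vW = zero_like(net$W),
                mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
    n <- nrow(X)
    best_val <- Inf
    best_net <- net
    stall <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s in starts) {
        batch <- idx[s:min(s + cfg$batch_size - 1L, n)]
        step <- ann_step(net, opt, X[batch, , drop = FALSE], y[batch], cfg)
        net <- step$net
        opt <- step$opt
      }
      if (!is.null(X_val)) {
        val_loss <- ann_bce(ann_forward(net, X_val)$out, y_val)
        if (!is.finite(val_loss)) {
          stopf("non-finite validation loss at epoch %d (lr=%g)", epoch,
                cfg$learning_rate)
        }
        if (val_loss < best_val - 1e-6) {
          best_val <- val_loss
          best_net <- net
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= cfg$patience) break
        }
      }
    }
    final <- if (!is.null(X_val)) best_net else net
    train_loss <- ann_bce(ann_forward(final, X)$out, y)
    if (!is.finite(train_loss)) {
      stopf("non-finite training loss (lr=%g, l2=%g)", cfg$learning_rate,
            cfg$l2_strength)
    }
    final
  })
}

ann_predict <- function(net, X) ann_forward(net, X)$out
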