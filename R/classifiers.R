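#' Base-classifier specification
#'
#' Two interchangeable backends share one fit/predict contract:
#' `fast_baseline` is a deterministic ridge-penalized logistic regression
#' (fitted by glmnet's convex coordinate-descent solver) suited to
#' desk-scale testing and benchmarking; `deep_reference` is a stacked gated
#' network (three LSTM-style layers of 64/32/16 units applied to each
#' sample as a length-1 sequence, dropout 0.2 after each layer, sigmoid
#' output) trained with the focal loss by Adam, with early stopping on a
#' stratified validation split.
#'
#' @param kind `"fast_baseline"` or `"deep_reference"`
#' @param gamma focal focusing parameter (default 2.0)
#' @param alpha focal class-balance weight on the positive class (default
#'   0.25; the negative class receives `1 - alpha`)
#' @param learning_rate Adam step size (default 0.001)
#' @param epochs maximum training epochs (default 100)
#' @param batch_size minibatch size (default 16)
#' @param dropout dropout rate after each gated layer (default 0.2)
#' @param layer_units hidden units per gated layer (default `c(64, 32, 16)`)
#' @param early_stopping list with `validation_fraction` (default 0.10),
#'   `patience` (default 10) and `restore_best` (default TRUE)
#' @param threshold decision cut on the predicted probability; labels are 1
#'   when the probability is `>= threshold` (inclusive; default 0.5)
#' @param lambda ridge penalty for `fast_baseline` (default 1e-3)
#' @return object of class `classifier_spec`
#' @export
classifier_spec <- function(kind = c("fast_baseline", "deep_reference"),
                            gamma = 2.0, alpha = 0.25,
                            learning_rate = 0.001, epochs = 100L,
                            batch_size = 16L, dropout = 0.2,
                            layer_units = c(64L, 32L, 16L),
                            early_stopping = list(validation_fraction = 0.10,
                                                  patience = 10L,
                                                  restore_best = TRUE),
                            threshold = 0.5, lambda = 1e-3) {
  kind <- match.arg(kind)
  if (gamma < 0) stop("gamma must be >= 0")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  structure(
    list(kind = kind, gamma = gamma, alpha = alpha,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), dropout = dropout,
         layer_units = as.integer(layer_units),
         early_stopping = early_stopping, threshold = threshold,
         lambda = lambda),
    class = "classifier_spec")
}

#' Focal loss for binary classification
#'
#' `FL = -alpha_t * (1 - p_t)^gamma * log(p_t)` with `p_t = p` for positive
#' labels and `1 - p` otherwise, and `alpha_t = alpha` on the positive
#' class, `1 - alpha` on the negative. Down-weights easy examples so
#' training emphasizes hard, minority-class samples. Probabilities are
#' clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p predicted probability (vector) of class 1
#' @param y true 0/1 label (vector)
#' @param gamma focusing parameter, `>= 0`
#' @param alpha class-balance weight in (0, 1)
#' @return non-negative loss, element-wise
#' @examples
#' focal_loss(0.5, 1)                    # 0.25 * 0.25 * log(2)
#' focal_loss(0.9, 1, gamma = 0, alpha = 0.5) / 0.5  # plain cross-entropy
#' @export
focal_loss <- function(p, y, gamma = 2.0, alpha = 0.25) {
  eps <- 1e-7
  n <- max(length(p), length(y))
  p <- rep_len(p, n); y <- rep_len(y, n)
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  -at * (1 - pt)^gamma * log(pt)
}

# gradient of the mean focal loss w.r.t. the output logit
focal_grad_logit <- function(p, y, gamma, alpha) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  dl_dpt <- at * (gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) -
                    (1 - pt)^gamma / pt)
  s <- ifelse(y == 1, 1, -1)
  dl_dpt * s * pt * (1 - pt)
}

#' Train a classifier on a fully observed feature matrix
#'
#' @param X numeric matrix, fully observed and min-max normalized, with
#'   feature ids as column names
#' @param y 0/1 labels
#' @param spec a [classifier_spec()]
#' @param seed integer seed; identical `(X, y, spec, seed)` give identical
#'   fitted parameters and predictions
#' @return object of class `trained_model` carrying the spec snapshot, the
#'   feature scope and the fitted parameters
#' @details Single-class training labels yield a constant-probability
#'   predictor (the observed class-1 rate, clipped away from 0/1) with a
#'   warning, so ensembles over sparse profile subsets degrade gracefully.
#' @export
train_classifier <- function(X, y, spec = classifier_spec(), seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  if (anyNA(X)) stop("X must be fully observed on its feature scope")
  model <- list(spec = spec, feature_scope = colnames(X),
                n_train = nrow(X))
  if (length(unique(y)) < 2L) {
    warning("single-class training labels; fitting a constant predictor")
    eps <- 1e-7
    model$kind <- "constant"
    model$constant_p <- min(max(mean(y), eps), 1 - eps)
    return(structure(model, class = "trained_model"))
  }
  if (spec$kind == "fast_baseline") {
    Xf <- X
    if (ncol(Xf) == 1L) {
      Xf <- cbind(Xf, .pad = 0)  # glmnet requires >= 2 columns
    }
    fit <- glmnet::glmnet(Xf, y, family = "binomial", alpha = 0,
                          lambda = spec$lambda, standardize = FALSE)
    model$kind <- "fast_baseline"
    model$fit <- fit
  } else {
    model$kind <- "deep_reference"
    model$fit <- fit_gated_net(X, y, spec, seed)
  }
  structure(model, class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model (%s): %d features, n_train = %d\n",
              x$kind, length(x$feature_scope), x$n_train))
  invisible(x)
}

#' Predict class-1 probabilities / labels
#'
#' @param model a [train_classifier()] result
#' @param X matrix matching the model's feature scope
#' @param threshold decision cut; defaults to the model spec's threshold.
#'   Labels are 1 when the probability is `>= threshold` (inclusive).
#' @return `predict_proba`: numeric vector in `[0, 1]`; `predict_label`:
#'   integer 0/1 vector
#' @export
predict_proba <- function(model, X) {
  X <- rbind(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$feature_scope)) {
      stop("feature-scope mismatch: model expects ",
           length(model$feature_scope), " features, got ", ncol(X))
    }
  } else {
    if (!all(model$feature_scope %in% colnames(X))) {
      stop("feature-scope mismatch: missing features ",
           paste(head(setdiff(model$feature_scope, colnames(X)), 5),
                 collapse = ", "))
    }
    X <- X[, model$feature_scope, drop = FALSE]
  }
  switch(model$kind,
    constant = rep(model$constant_p, nrow(X)),
    fast_baseline = {
      if (ncol(X) == 1L) X <- cbind(X, .pad = 0)
      as.numeric(predict(model$fit, newx = X, type = "response"))
    },
    deep_reference = as.numeric(gated_net_forward(model$fit, X)$p),
    stop("unknown model kind"))
}

#' @rdname predict_proba
#' @export
predict_label <- function(model, X, threshold = model$spec$threshold) {
  as.integer(predict_proba(model, X) >= threshold)
}

## ---- gated deep reference backend -------------------------------------
## Each sample is treated as a length-1 sequence whose single step is the
## full feature vector; with a zero initial state the LSTM recurrence
## reduces to input-driven gates: i = sig(X Wi + bi), g = tanh(X Wg + bg),
## o = sig(X Wo + bo), c = i * g, h = o * tanh(c). The forget gate acts on
## the zero initial cell state and therefore drops out of the computation.

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_gated_net <- function(d_in, units) {
  layers <- list()
  for (u in units) {
    layers[[length(layers) + 1L]] <- list(
      Wi = glorot(d_in, u), bi = numeric(u),
      Wg = glorot(d_in, u), bg = numeric(u),
      Wo = glorot(d_in, u), bo = numeric(u))
    d_in <- u
  }
  list(layers = layers,
       W_out = glorot(d_in, 1L), b_out = 0)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

gated_layer_forward <- function(layer, X) {
  i <- sigmoid(sweep(X %*% layer$Wi, 2, layer$bi, "+"))
  g <- tanh(sweep(X %*% layer$Wg, 2, layer$bg, "+"))
  o <- sigmoid(sweep(X %*% layer$Wo, 2, layer$bo, "+"))
  cc <- i * g
  t <- tanh(cc)
  list(h = o * t, i = i, g = g, o = o, t = t, X = X)
}

gated_net_forward <- function(net, X, dropout = 0, drop_masks = NULL) {
  caches <- list()
  h <- X
  for (l in seq_along(net$layers)) {
    cache <- gated_layer_forward(net$layers[[l]], h)
    h <- cache$h
    if (dropout > 0) {
      mask <- drop_masks[[l]]
      h <- h * mask
      cache$drop_mask <- mask
    }
    caches[[l]] <- cache
  }
  z <- as.numeric(h %*% net$W_out + net$b_out)
  list(p = sigmoid(z), z = z, h = h, caches = caches)
}

gated_net_backward <- function(net, fwd, dz) {
  n <- length(dz)
  grads <- list(W_out = crossprod(fwd$h, dz) / n,
                b_out = mean(dz), layers = list())
  dh <- outer(dz, as.numeric(net$W_out))
  for (l in rev(seq_along(net$layers))) {
    cache <- fwd$caches[[l]]
    if (!is.null(cache$drop_mask)) dh <- dh * cache$drop_mask
    o <- cache$o; t <- cache$t; i <- cache$i; g <- cache$g
    do_pre <- dh * t * o * (1 - o)
    dc <- dh * o * (1 - t^2)
    di_pre <- dc * g * i * (1 - i)
    dg_pre <- dc * i * (1 - g^2)
    X <- cache$X
    grads$layers[[l]] <- list(
      Wi = crossprod(X, di_pre) / n, bi = colMeans(di_pre),
      Wg = crossprod(X, dg_pre) / n, bg = colMeans(dg_pre),
      Wo = crossprod(X, do_pre) / n, bo = colMeans(do_pre))
    layer <- net$layers[[l]]
    dh <- di_pre %*% t(layer$Wi) + dg_pre %*% t(layer$Wg) +
      do_pre %*% t(layer$Wo)
  }
  grads
}

# flat parameter walk for the Adam update
net_param_names <- function(net) {
  c("W_out", "b_out",
    unlist(lapply(seq_along(net$layers), function(l)
      paste0("layers.", l, ".", c("Wi", "bi", "Wg", "bg", "Wo", "bo")))))
}

net_get <- function(net, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "layers") net$layers[[as.integer(parts[2])]][[parts[3]]]
  else net[[name]]
}

net_set <- function(net, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "layers") net$layers[[as.integer(parts[2])]][[parts[3]]] <- value
  else net[[name]] <- value
  net
}

fit_gated_net <- function(X, y, spec, seed) {
  es <- spec$early_stopping
  withr::with_seed(derive_seed(seed, "gated_net"), {
    # stratified validation split for early stopping
    val_idx <- integer(0)
    for (cl in unique(y)) {
      members <- which(y == cl)
      n_val <- max(1L, floor(length(members) * es$validation_fraction))
      if (length(members) > n_val) {
        val_idx <- c(val_idx, sample(members, n_val))
      }
    }
    tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
    if (length(val_idx) == 0L || length(unique(y[tr_idx])) < 2L) {
      tr_idx <- seq_len(nrow(X)); val_idx <- seq_len(nrow(X))
    }
    Xt <- X[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
    Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]

    net <- init_gated_net(ncol(X), spec$layer_units)
    pnames <- net_param_names(net)
    mom <- lapply(pnames, function(nm) net_get(net, nm) * 0)
    vel <- mom
    names(mom) <- names(vel) <- pnames
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
    step <- 0L
    best_val <- Inf; best_net <- net; wait <- 0L

    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(nrow(Xt))
      for (start in seq(1L, nrow(Xt), by = spec$batch_size)) {
        rows <- ord[start:min(start + spec$batch_size - 1L, nrow(Xt))]
        Xb <- Xt[rows, , drop = FALSE]; yb <- yt[rows]
        drop_masks <- NULL
        if (spec$dropout > 0) {
          drop_masks <- lapply(spec$layer_units, function(u)
            matrix(rbinom(length(rows) * u, 1L, 1 - spec$dropout),
                   length(rows), u) / (1 - spec$dropout))
        }
        fwd <- gated_net_forward(net, Xb, spec$dropout, drop_masks)
        dz <- focal_grad_logit(fwd$p, yb, spec$gamma, spec$alpha)
        grads <- gated_net_backward(net, fwd, dz)
        step <- step + 1L
        for (nm in pnames) {
          g <- net_get(grads, nm)
          mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g
          vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g^2
          mhat <- mom[[nm]] / (1 - beta1^step)
          vhat <- vel[[nm]] / (1 - beta2^step)
          net <- net_set(net, nm,
                         net_get(net, nm) -
                           spec$learning_rate * mhat / (sqrt(vhat) + adam_eps))
        }
      }
      val_loss <- mean(focal_loss(gated_net_forward(net, Xv)$p, yv,
                                  spec$gamma, spec$alpha))
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss; best_net <- net; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= es$patience) break
      }
    }
    if (isTRUE(es$restore_best)) best_net else net
  })
}
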