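#' Specification of the two-block feedforward network
#'
#' The network takes drug and target feature vectors as two separate input
#' blocks. The drug block (and, for expression-based GEP target features,
#' the target block) passes through 1-3 fully connected hidden layers; for
#' embedding-based target features (PPI/PM) the target block is empty and
#' the embedding is fed forward unchanged. Block outputs are concatenated
#' and connected to 1-2 further hidden layers and a single sigmoid output
#' unit. Training minimizes binary cross-entropy with Adam, dropout on each
#' fully connected hidden layer, and early stopping on validation loss.
#'
#' @param drug_block_layers widths of the drug-block hidden layers (1-3).
#' @param target_block_layers widths of the target-block hidden layers
#'   (0-3; empty means the target features are used directly).
#' @param joint_layers widths of the post-concatenation hidden layers (1-2).
#' @param activation `"relu"` or `"tanh"`.
#' @param dropout_rate dropout probability on each hidden layer, in \[0, 1).
#'   Default 0.5.
#' @param learning_rate Adam step size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 20); best-validation parameters are restored.
#' @param batch_size minibatch size.
#' @param seed seed for initialization, shuffling and dropout.
#' @return An object of class `dnn_spec`.
#' @export
dnn_spec <- function(drug_block_layers = c(64L), target_block_layers = integer(0),
                     joint_layers = c(32L), activation = c("relu", "tanh"),
                     dropout_rate = 0.5, learning_rate = 1e-3,
                     max_epochs = 200L, early_stop_patience = 20L,
                     batch_size = 128L, seed = 1L) {
  activation <- match.arg(activation)
  drug_block_layers <- as.integer(drug_block_layers)
  target_block_layers <- as.integer(target_block_layers)
  joint_layers <- as.integer(joint_layers)
  if (!length(drug_block_layers) %in% 1:3)
    stop("drug_block_layers must have 1-3 layers", call. = FALSE)
  if (!length(target_block_layers) %in% 0:3)
    stop("target_block_layers must have 0-3 layers", call. = FALSE)
  if (!length(joint_layers) %in% 1:2)
    stop("joint_layers must have 1-2 layers", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  structure(list(drug_block_layers = drug_block_layers,
                 target_block_layers = target_block_layers,
                 joint_layers = joint_layers, activation = activation,
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "dnn_spec")
}

act_fun <- function(x, activation) {
  switch(activation, relu = pmax(x, 0), tanh = tanh(x))
}
act_grad <- function(z, activation) {
  switch(activation, relu = (z > 0) * 1, tanh = 1 - tanh(z)^2)
}

init_layer <- function(nin, nout, activation) {
  sd <- if (activation == "relu") sqrt(2 / nin) else sqrt(2 / (nin + nout))
  list(W = matrix(rnorm(nin * nout, sd = sd), nin, nout), b = rep(0, nout))
}

#' Build an (untrained) two-block network
#'
#' Parameters are initialized from `spec$seed` (He initialization for relu,
#' Glorot for tanh; zero biases).
#'
#' @param spec a [dnn_spec()].
#' @param drug_dim drug feature dimension.
#' @param target_dim target feature dimension.
#' @return An object of class `dti_dnn` (also `dti_model`).
#' @export
build_dnn <- function(spec, drug_dim, target_dim) {
  stopifnot(inherits(spec, "dnn_spec"))
  if (drug_dim < 1L || target_dim < 1L)
    stop("feature dimensions must be >= 1", call. = FALSE)
  set.seed(spec$seed)
  params <- list()
  nin <- drug_dim
  for (i in seq_along(spec$drug_block_layers)) {
    params[[paste0("drug", i)]] <- init_layer(nin, spec$drug_block_layers[i],
                                              spec$activation)
    nin <- spec$drug_block_layers[i]
  }
  drug_out <- nin
  nin <- target_dim
  for (i in seq_along(spec$target_block_layers)) {
    params[[paste0("target", i)]] <- init_layer(nin, spec$target_block_layers[i],
                                                spec$activation)
    nin <- spec$target_block_layers[i]
  }
  target_out <- nin
  nin <- drug_out + target_out
  for (i in seq_along(spec$joint_layers)) {
    params[[paste0("joint", i)]] <- init_layer(nin, spec$joint_layers[i],
                                               spec$activation)
    nin <- spec$joint_layers[i]
  }
  params[["out"]] <- init_layer(nin, 1L, spec$activation)
  structure(list(kind = "dnn", spec = spec, params = params,
                 drug_dim = drug_dim, target_dim = target_dim,
                 drug_out = drug_out, target_out = target_out,
                 trained = FALSE, training_log = NULL),
            class = c("dti_dnn", "dti_model"))
}

sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

# Forward pass. With dropout = TRUE, inverted-dropout masks are drawn from
# the current RNG state and recorded in the cache for backprop.
dnn_forward <- function(model, drug_x, target_x, dropout = FALSE,
                        keep_cache = FALSE) {
  spec <- model$spec
  p <- model$params
  rate <- if (dropout) spec$dropout_rate else 0
  cache <- list(layers = list())
  run_block <- function(a, prefix, nlayers, cache_env) {
    for (i in seq_len(nlayers)) {
      key <- paste0(prefix, i)
      z <- sweep(a %*% p[[key]]$W, 2, p[[key]]$b, "+")
      h <- act_fun(z, spec$activation)
      mask <- NULL
      if (rate > 0) {
        mask <- matrix(rbinom(length(h), 1, 1 - rate) / (1 - rate),
                       nrow(h), ncol(h))
        h <- h * mask
      }
      cache_env$layers[[key]] <- list(input = a, z = z, mask = mask)
      a <- h
    }
    a
  }
  env <- new.env()
  env$layers <- list()
  hd <- run_block(drug_x, "drug", length(spec$drug_block_layers), env)
  ht <- run_block(target_x, "target", length(spec$target_block_layers), env)
  a <- cbind(hd, ht)
  a <- run_block(a, "joint", length(spec$joint_layers), env)
  z_out <- sweep(a %*% p$out$W, 2, p$out$b, "+")
  prob <- as.vector(sigmoid(z_out))
  if (!keep_cache) return(prob)
  list(prob = prob, joint_in_drug = ncol(hd), a_out = a, layers = env$layers)
}

bce_loss <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(pmax(prob, eps)) + (1 - y) * log(pmax(1 - prob, eps)))
}

# Combined forward/backward pass returning the mean binary cross-entropy and
# its gradient with respect to every parameter (same named-list layout).
dnn_backprop <- function(model, drug_x, target_x, y, dropout = FALSE) {
  spec <- model$spec
  p <- model$params
  fw <- dnn_forward(model, drug_x, target_x, dropout = dropout,
                    keep_cache = TRUE)
  n <- length(y)
  grads <- list()
  # output layer: d(loss)/d(z_out) = (prob - y)/n
  dz <- matrix((fw$prob - y) / n, ncol = 1)
  grads$out <- list(W = t(fw$a_out) %*% dz, b = sum(dz))
  da <- dz %*% t(p$out$W)
  back_block <- function(da, prefix, nlayers) {
    for (i in rev(seq_len(nlayers))) {
      key <- paste0(prefix, i)
      cc <- fw$layers[[key]]
      if (!is.null(cc$mask)) da <- da * cc$mask
      dzl <- da * act_grad(cc$z, spec$activation)
      grads[[key]] <<- list(W = t(cc$input) %*% dzl, b = colSums(dzl))
      da <- dzl %*% t(p[[key]]$W)
    }
    da
  }
  da <- back_block(da, "joint", length(spec$joint_layers))
  nd <- fw$joint_in_drug
  back_block(da[, seq_len(nd), drop = FALSE], "drug",
             length(spec$drug_block_layers))
  if (length(spec$target_block_layers) > 0)
    back_block(da[, -seq_len(nd), drop = FALSE], "target",
               length(spec$target_block_layers))
  list(loss = bce_loss(fw$prob, y), grads = grads)
}

# One Adam update for a single parameter array.
adam_step <- function(theta, grad, m, v, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad^2
  m_hat <- m / (1 - beta1^t)
  v_hat <- v / (1 - beta2^t)
  list(theta = theta - lr * m_hat / (sqrt(v_hat) + eps), m = m, v = v)
}

#' Train a two-block network
#'
#' Minimizes binary cross-entropy with Adam over shuffled minibatches, with
#' dropout active during training only. A stratified fraction of the data is
#' held out for validation; training stops when the validation loss has not
#' improved for `early_stop_patience` epochs (or at `max_epochs`) and the
#' best-validation parameters are restored.
#'
#' @param model a [build_dnn()] result.
#' @param drug_x,target_x feature matrices (rows = pairs).
#' @param labels 0/1 interaction labels; both classes must be present.
#' @param validation_fraction fraction held out for early stopping; with 0,
#'   training runs to `max_epochs` monitoring the training loss.
#' @return The trained `dti_dnn`, with a `training_log` data.frame
#'   (epoch, train_loss, val_loss).
#' @export
train_dnn <- function(model, drug_x, target_x, labels,
                      validation_fraction = 0.1) {
  stopifnot(inherits(model, "dti_dnn"))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (ncol(drug_x) != model$drug_dim || ncol(target_x) != model$target_dim)
    stop("feature dimensions do not match the built model", call. = FALSE)
  spec <- model$spec
  set.seed(derive_seed(spec$seed, 11L))
  n <- length(labels)

  val_idx <- integer(0)
  if (validation_fraction > 0) {
    for (cl in c(0, 1)) {
      cls <- which(labels == cl)
      nv <- max(1L, round(validation_fraction * length(cls)))
      val_idx <- c(val_idx, sample(cls, nv))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xd_tr <- drug_x[tr_idx, , drop = FALSE]
  Xt_tr <- target_x[tr_idx, , drop = FALSE]
  y_tr <- labels[tr_idx]

  state <- lapply(model$params, function(l)
    list(W = list(m = l$W * 0, v = l$W * 0), b = list(m = l$b * 0, v = l$b * 0)))
  t_step <- 0L
  best_loss <- Inf
  best_params <- model$params
  wait <- 0L
  log <- vector("list", spec$max_epochs)

  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample(length(tr_idx))
    batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
    for (b in batches) {
      bp <- dnn_backprop(model, Xd_tr[b, , drop = FALSE],
                         Xt_tr[b, , drop = FALSE], y_tr[b], dropout = TRUE)
      t_step <- t_step + 1L
      for (key in names(bp$grads)) {
        for (part in c("W", "b")) {
          st <- adam_step(model$params[[key]][[part]], bp$grads[[key]][[part]],
                          state[[key]][[part]]$m, state[[key]][[part]]$v,
                          t_step, spec$learning_rate)
          model$params[[key]][[part]] <- st$theta
          state[[key]][[part]]$m <- st$m
          state[[key]][[part]]$v <- st$v
        }
      }
    }
    train_loss <- bce_loss(dnn_forward(model, Xd_tr, Xt_tr), y_tr)
    val_loss <- if (length(val_idx) > 0) {
      bce_loss(dnn_forward(model, drug_x[val_idx, , drop = FALSE],
                           target_x[val_idx, , drop = FALSE]),
               labels[val_idx])
    } else train_loss
    log[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                               val_loss = val_loss)
    if (val_loss < best_loss - 1e-9) {
      best_loss <- val_loss
      best_params <- model$params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$early_stop_patience) break
    }
  }
  model$params <- best_params
  model$training_log <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
  model$trained <- TRUE
  model
}

#' Predict interaction probabilities from a trained two-block network
#'
#' @param object a `dti_dnn`.
#' @param drug_x,target_x feature matrices with the training dimensionality.
#' @param ... unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.dti_dnn <- function(object, drug_x, target_x, ...) {
  drug_x <- as.matrix(drug_x)
  target_x <- as.matrix(target_x)
  if (ncol(drug_x) != object$drug_dim || ncol(target_x) != object$target_dim)
    stop("feature dimensions do not match the trained model", call. = FALSE)
  dnn_forward(object, drug_x, target_x, dropout = FALSE)
}

#' @export
print.dti_dnn <- function(x, ...) {
  s <- x$spec
  cat("<dti_dnn>", if (x$trained) "trained" else "untrained", "\n")
  cat(sprintf("  drug block %d -> [%s]; target block %d -> [%s]; joint [%s] -> 1\n",
              x$drug_dim, paste(s$drug_block_layers, collapse = ","),
              x$target_dim,
              if (length(s$target_block_layers)) paste(s$target_block_layers, collapse = ",") else "pass-through",
              paste(s$joint_layers, collapse = ",")))
  cat(sprintf("  activation %s, dropout %.2f, lr %g, batch %d, patience %d\n",
              s$activation, s$dropout_rate, s$learning_rate, s$batch_size,
              s$early_stop_patience))
  if (x$trained)
    cat(sprintf("  stopped after %d epochs; best val loss %.4f\n",
                max(x$training_log$epoch), min(x$training_log$val_loss)))
  invisible(x)
}
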