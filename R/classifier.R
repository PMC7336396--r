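#' Train the fully-connected interaction classifier
#'
#' A small multilayer perceptron mapping an embedding vector through three
#' rectified (ReLU) hidden layers of 32, 32 and 16 units to a 2-way softmax
#' that estimates the interaction probability. Training minimises
#' cross-entropy with Adam on shuffled minibatches; when enough data is
#' available a seeded validation split drives early stopping (best weights
#' are restored). All randomness (initialisation, shuffling, split) is
#' governed by `seed`, so training is reproducible.
#'
#' @param x numeric feature matrix (rows = samples), entries expected in
#'   `[0, 1]` (no further scaling is applied), or a tibble from
#'   [embed_pairs()] containing a `label` column.
#' @param y labels (`"positive"`/`"negative"`, factor or character, or
#'   0/1); ignored when `x` is an embedding tibble.
#' @param hidden integer vector of hidden-layer sizes.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction fraction of samples held out for early stopping;
#'   splits smaller than 5 samples disable early stopping.
#' @param class_weights if `TRUE`, weight the loss inversely to class
#'   frequency. Off by default: imbalanced regimes are evaluated as-is.
#' @param seed integer seed.
#' @return An object of class `dti_mlp`.
#' @export
mlp_train <- function(x, y = NULL, hidden = c(32L, 32L, 16L),
                      epochs = 100L, batch_size = 32L, learning_rate = 1e-3,
                      patience = 10L, val_fraction = 0.1,
                      class_weights = FALSE, seed = 1L) {
  if (is.data.frame(x)) {
    em <- embedding_matrix(x)
    if (is.null(y)) y <- em$y
    x <- em$x
  }
  x <- as.matrix(x)
  if (is.null(y)) stop("labels are required")
  y <- normalize_labels(y)
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  if (length(y) != nrow(x)) stop("x and y sizes differ")
  if (any(hidden < 1) || learning_rate <= 0) stop("invalid classifier configuration")

  n <- nrow(x); p <- ncol(x)
  sizes <- c(p, as.integer(hidden), 2L)
  w_cls <- if (class_weights) {
    cw <- n / (2 * tabulate(y + 1L, nbins = 2L))
    cw[y + 1L]
  } else {
    rep(1, n)
  }

  withr::with_seed(seed, {
    params <- init_mlp(sizes)
    n_val <- floor(val_fraction * n)
    use_val <- n_val >= 5
    if (use_val) {
      val_idx <- sample.int(n, n_val)
      if (length(unique(y[val_idx])) < 2) use_val <- FALSE
    }
    tr_idx <- if (use_val) setdiff(seq_len(n), val_idx) else seq_len(n)

    opt <- adam_state(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    history <- vector("list", epochs)
    step <- 0L
    for (epoch in seq_len(epochs)) {
      perm <- sample(tr_idx)
      batches <- split(perm, ceiling(seq_along(perm) / batch_size))
      for (b in batches) {
        step <- step + 1L
        gr <- mlp_gradients(params, x[b, , drop = FALSE], y[b], w_cls[b])
        upd <- adam_update(params, gr$grads, opt, learning_rate, step)
        params <- upd$params; opt <- upd$opt
      }
      train_loss <- mlp_loss(params, x[tr_idx, , drop = FALSE], y[tr_idx],
                             w_cls[tr_idx])
      val_loss <- if (use_val) {
        mlp_loss(params, x[val_idx, , drop = FALSE], y[val_idx], w_cls[val_idx])
      } else {
        NA_real_
      }
      history[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                            val_loss = val_loss)
      monitor <- if (use_val) val_loss else train_loss
      if (monitor < best$loss - 1e-8) {
        best <- list(loss = monitor, params = params, epoch = epoch)
        wait <- 0L
      } else if (use_val) {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    params <- if (use_val) best$params else params
    history <- tibble::as_tibble(do.call(rbind, history[!vapply(history, is.null, TRUE)]))
    structure(
      list(params = params, sizes = sizes,
           levels = c("negative", "positive"),
           history = history,
           config = list(hidden = hidden, epochs = epochs,
                         batch_size = batch_size,
                         learning_rate = learning_rate, patience = patience,
                         val_fraction = val_fraction,
                         class_weights = class_weights, seed = seed),
           best_epoch = if (use_val) best$epoch else nrow(history),
           used_validation = use_val),
      class = "dti_mlp"
    )
  })
}

# Map assorted label encodings onto integer 0 (negative) / 1 (positive).
normalize_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("positive", "negative"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    return(as.integer(y == "positive"))
  }
  if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
  as.integer(y)
}

init_mlp <- function(sizes) {
  L <- length(sizes) - 1L
  lapply(seq_len(L), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

mlp_forward <- function(params, x) {
  L <- length(params)
  acts <- vector("list", L + 1L)
  acts[[1]] <- x
  a <- x
  for (l in seq_len(L)) {
    z <- sweep(a %*% params[[l]]$W, 2, params[[l]]$b, "+")
    a <- if (l < L) pmax(z, 0) else z
    acts[[l + 1]] <- a
  }
  # numerically stable softmax over the two output units
  z <- acts[[L + 1]]
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  list(prob = ez / rowSums(ez), acts = acts)
}

mlp_loss <- function(params, x, y, w = rep(1, length(y))) {
  pr <- mlp_forward(params, x)$prob
  p_true <- pr[cbind(seq_along(y), y + 1L)]
  -sum(w * log(pmax(p_true, 1e-12))) / sum(w)
}

mlp_gradients <- function(params, x, y, w = rep(1, length(y))) {
  L <- length(params)
  fwd <- mlp_forward(params, x)
  nb <- nrow(x)
  target <- matrix(0, nb, 2)
  target[cbind(seq_len(nb), y + 1L)] <- 1
  delta <- (fwd$prob - target) * (w / sum(w))
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    a_prev <- fwd$acts[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(params[[l]]$W)) * (fwd$acts[[l]] > 0)
    }
  }
  list(grads = grads, loss = mlp_loss(params, x, y, w))
}

adam_state <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0
  ))
}

adam_update <- function(params, grads, opt, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    o <- opt[[l]]; g <- grads[[l]]
    o$mW <- beta1 * o$mW + (1 - beta1) * g$W
    o$vW <- beta2 * o$vW + (1 - beta2) * g$W^2
    o$mb <- beta1 * o$mb + (1 - beta1) * g$b
    o$vb <- beta2 * o$vb + (1 - beta2) * g$b^2
    mW_hat <- o$mW / (1 - beta1^step); vW_hat <- o$vW / (1 - beta2^step)
    mb_hat <- o$mb / (1 - beta1^step); vb_hat <- o$vb / (1 - beta2^step)
    params[[l]]$W <- params[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    params[[l]]$b <- params[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    opt[[l]] <- o
  }
  list(params = params, opt = opt)
}

#' Predict interaction probabilities
#'
#' @param object a `dti_mlp`.
#' @param newdata feature matrix or embedding tibble with `f*` columns.
#' @param type `"prob"` for the two-class probability tibble, `"positive"`
#'   for the positive-class probability vector.
#' @param ... unused.
#' @return A tibble with columns `p_negative`, `p_positive` (rows sum to
#'   1), or a numeric vector for `type = "positive"`.
#' @export
predict.dti_mlp <- function(object, newdata, type = c("prob", "positive"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- embedding_matrix(newdata)$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$sizes[1]) {
    stop("feature length ", ncol(newdata), " does not match the ",
         object$sizes[1], " the model was trained on")
  }
  pr <- mlp_forward(object$params, newdata)$prob
  if (type == "positive") return(pr[, 2])
  tibble::tibble(p_negative = pr[, 1], p_positive = pr[, 2])
}

#' Score drug-target pairs with a trained classifier
#'
#' @param model a `dti_mlp`.
#' @param embeddings embedding tibble from [embed_pairs()].
#' @return The pair identifier columns plus `probability`, the estimated
#'   interaction likelihood.
#' @export
predict_pairs <- function(model, embeddings) {
  keep <- intersect(c("drug_id", "target_id", "drug", "target", "label"),
                    names(embeddings))
  out <- embeddings[, keep]
  out$probability <- predict(model, embeddings, type = "positive")
  out
}

#' @export
print.dti_mlp <- function(x, ...) {
  cat("<dti_mlp> layers ", paste(x$sizes, collapse = "-"),
      ", trained ", nrow(x$history), " epochs",
      if (x$used_validation) paste0(" (best at ", x$best_epoch, ")"),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a classifier
#'
#' @param x a `dti_mlp`.
#' @param ... unused.
#' @return A tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`.
#' @export
tidy.dti_mlp <- function(x, ...) x$history

#' One-row summary of a trained classifier
#'
#' @param x a `dti_mlp`.
#' @param ... unused.
#' @return A tibble with `n_parameters`, `epochs_trained`, `best_epoch`,
#'   `final_train_loss`, `final_val_loss`.
#' @export
glance.dti_mlp <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  h <- x$history
  tibble::tibble(
    n_parameters = np,
    epochs_trained = nrow(h),
    best_epoch = x$best_epoch,
    final_train_loss = h$train_loss[nrow(h)],
    final_val_loss = h$val_loss[nrow(h)]
  )
}
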