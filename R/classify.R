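#' Training configuration for scalogram-image classifiers
#'
#' Defaults follow the study regime: Adam, learning rate 1e-4, batch size
#' 30, 15 epochs.  (Batch size 30 is the primary reported value; 20 also
#' appears once in the source material's discussion -- it is configurable
#' here.)
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate Positive step size. Default 1e-4.
#' @param batch_size Minibatch size, `>= 1`. Default 30.
#' @param max_epochs Number of passes over the training data, `>= 0`.
#'   Default 15.  Zero returns the classifier untouched.
#' @param validation_frequency History-recording period in iterations;
#'   `NULL` (default) records once per epoch.
#' @param seed Integer seed controlling shuffling (and any optimizer
#'   randomness).
#' @param class_order Optional ordered character vector of class labels;
#'   defaults to the sorted unique training labels.
#'
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 1e-4,
                         batch_size = 30, max_epochs = 15,
                         validation_frequency = NULL, seed = 1,
                         class_order = NULL) {
  optimizer <- match.arg(optimizer)
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("`learning_rate` must be > 0")
  }
  stopifnot(is.numeric(batch_size), batch_size >= 1,
            batch_size == round(batch_size),
            is.numeric(max_epochs), max_epochs >= 0,
            max_epochs == round(max_epochs))
  if (!is.null(validation_frequency)) {
    stopifnot(is.numeric(validation_frequency), validation_frequency >= 1)
  }
  structure(
    list(optimizer = optimizer, learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         validation_frequency = validation_frequency,
         seed = as.integer(seed), class_order = class_order),
    class = "train_config"
  )
}

#' Stack RGB images into a 4-D tensor
#'
#' @param images A list of `ecg_rgb_image` objects (or of H x W x 3
#'   arrays), or an already-stacked `H x W x 3 x N` array.
#' @return A numeric array `H x W x 3 x N` with values in `[0, 1]`.
#' @export
image_tensor <- function(images) {
  if (is.array(images) && length(dim(images)) == 4L) {
    return(if (max(images) > 1) images / 255 else images)
  }
  if (inherits(images, "ecg_rgb_image")) images <- list(images)
  stopifnot(is.list(images), length(images) >= 1)
  mats <- lapply(images, function(im) {
    px <- if (inherits(im, "ecg_rgb_image")) im$pixels else im
    stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
    px / 255
  })
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d), logical(1)))) {
    stop("all images must share the same dimensions")
  }
  array(unlist(mats, use.names = FALSE), dim = c(d, length(mats)))
}

# ---- internal CNN engine ---------------------------------------------------
# Activations are stored channel-first (C, H, W, N); convolutions are 3x3,
# stride 1, zero padding 1 ("same"), computed as im2col gathers followed by
# one BLAS matrix multiply.

# gather indices: rows ordered (channel, kernel-row, kernel-col), columns
# ordered (h, w, image); indices address the zero-padded (C, H+2, W+2, N)
# array's underlying vector
conv_gather_idx <- function(C, H, W, N) {
  dh <- rep(0:2, each = C, times = 3)
  dw <- rep(0:2, each = 3L * C)
  cc <- rep(seq_len(C), times = 9)
  rowbase <- cc + C * dh + C * (H + 2L) * dw
  h <- rep(seq_len(H), times = W * N)
  w <- rep(rep(seq_len(W), each = H), times = N)
  n <- rep(seq_len(N), each = H * W)
  colbase <- C * (h - 1L) + C * (H + 2L) * (w - 1L) +
    C * (H + 2L) * (W + 2L) * (n - 1L)
  m <- outer(as.integer(rowbase), as.integer(colbase), `+`)
  storage.mode(m) <- "integer"
  m
}

conv_forward <- function(x, Wm, b, idx) {
  d <- dim(x)                                  # (C, H, W, N)
  xp <- array(0, c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  xp[, 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- x
  cols <- matrix(xp[c(idx)], nrow = nrow(idx))
  out <- Wm %*% cols + b                       # (OC, H*W*N)
  list(out = array(out, c(nrow(Wm), d[2], d[3], d[4])), cols = cols)
}

conv_backward <- function(dout, cols, Wm, idx, in_dim, need_dx = TRUE) {
  # dout: (OC, H, W, N) array; in_dim: c(C, H, W, N) of the layer input
  dmat <- matrix(dout, nrow = dim(dout)[1])
  dW <- tcrossprod(dmat, cols)
  db <- rowSums(dmat)
  dx <- NULL
  if (need_dx) {
    dcols <- crossprod(Wm, dmat)               # (9C, H*W*N)
    dxp <- numeric(in_dim[1] * (in_dim[2] + 2L) * (in_dim[3] + 2L) * in_dim[4])
    for (r in seq_len(nrow(idx))) {
      ii <- idx[r, ]
      dxp[ii] <- dxp[ii] + dcols[r, ]
    }
    dxp <- array(dxp, c(in_dim[1], in_dim[2] + 2L, in_dim[3] + 2L, in_dim[4]))
    dx <- dxp[, 2:(in_dim[2] + 1L), 2:(in_dim[3] + 1L), , drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

pool_forward <- function(x) {
  d <- dim(x)
  ho <- d[2] %/% 2L
  wo <- d[3] %/% 2L
  ih <- seq_len(ho) * 2L - 1L
  iw <- seq_len(wo) * 2L - 1L
  a11 <- x[, ih, iw, , drop = FALSE]
  a21 <- x[, ih + 1L, iw, , drop = FALSE]
  a12 <- x[, ih, iw + 1L, , drop = FALSE]
  a22 <- x[, ih + 1L, iw + 1L, , drop = FALSE]
  m <- pmax(a11, a21, a12, a22)
  k11 <- a11 == m
  k21 <- (a21 == m) & !k11
  k12 <- (a12 == m) & !(k11 | k21)
  k22 <- !(k11 | k21 | k12)
  list(out = m, masks = list(k11, k21, k12, k22), in_dim = d)
}

pool_backward <- function(dy, pf) {
  d <- pf$in_dim
  ho <- d[2] %/% 2L
  wo <- d[3] %/% 2L
  ih <- seq_len(ho) * 2L - 1L
  iw <- seq_len(wo) * 2L - 1L
  dx <- array(0, d)
  dx[, ih, iw, ] <- dy * pf$masks[[1]]
  dx[, ih + 1L, iw, ] <- dy * pf$masks[[2]]
  dx[, ih, iw + 1L, ] <- dy * pf$masks[[3]]
  dx[, ih + 1L, iw + 1L, ] <- dy * pf$masks[[4]]
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  colSums(aperm(array(x, c(d[1], d[2] * d[3], d[4])), c(2, 1, 3)), dims = 1)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

cnn_forward <- function(weights, x, keep_cache = FALSE) {
  cache <- if (keep_cache) list(x1 = x) else NULL
  idx <- attr(x, "gather_idx")                 # optional precomputed indices
  d <- dim(x)
  get_idx <- function(C, H, W, N, layer) {
    if (!is.null(idx)) idx[[layer]] else conv_gather_idx(C, H, W, N)
  }
  a <- x
  pools <- list()
  convs <- list()
  relus <- list()
  for (l in 1:3) {
    dl <- dim(a)
    cf <- conv_forward(a, weights[[paste0("W", l)]], weights[[paste0("b", l)]],
                       get_idx(dl[1], dl[2], dl[3], dl[4], l))
    r <- cf$out
    mask <- r > 0
    r[!mask] <- 0
    pf <- pool_forward(r)
    if (keep_cache) {
      convs[[l]] <- cf
      relus[[l]] <- mask
      pools[[l]] <- pf
      cache[[paste0("in_dim", l)]] <- dl
    }
    a <- pf$out
  }
  feats <- gap_forward(a)                       # (C3, N)
  if (is.null(dim(feats))) feats <- matrix(feats, ncol = dim(a)[4])
  logits <- weights$V %*% feats + weights$c0
  probs <- softmax_cols(logits)
  if (keep_cache) {
    cache$convs <- convs
    cache$relus <- relus
    cache$pools <- pools
    cache$feats <- feats
    cache$gap_dim <- dim(a)
  }
  list(probs = probs, logits = logits, feats = feats, cache = cache)
}

cnn_backward <- function(weights, fwd, y_onehot, idx = NULL) {
  cache <- fwd$cache
  n <- ncol(y_onehot)
  dlogits <- (fwd$probs - y_onehot) / n
  grads <- list(
    V = tcrossprod(dlogits, cache$feats),
    c0 = rowSums(dlogits)
  )
  dfeats <- crossprod(weights$V, dlogits)       # (C3, N)
  gd <- cache$gap_dim                           # (C3, Ho, Wo, N)
  hw <- gd[2] * gd[3]
  dmat <- dfeats[, rep(seq_len(gd[4]), each = hw), drop = FALSE] / hw
  da <- array(dmat, gd)
  for (l in 3:1) {
    dr <- pool_backward(da, cache$pools[[l]])
    dr <- dr * cache$relus[[l]]
    dl <- cache[[paste0("in_dim", l)]]
    this_idx <- if (!is.null(idx)) idx[[l]] else
      conv_gather_idx(dl[1], dl[2], dl[3], dl[4])
    cb <- conv_backward(dr, cache$convs[[l]]$cols,
                        weights[[paste0("W", l)]], this_idx, dl,
                        need_dx = l > 1)
    grads[[paste0("W", l)]] <- cb$dW
    grads[[paste0("b", l)]] <- cb$db
    if (l > 1) da <- cb$dx
  }
  grads
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

optim_step <- function(weights, grads, state, config,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  lr <- config$learning_rate
  if (config$optimizer == "sgd") {
    for (nm in names(grads)) weights[[nm]] <- weights[[nm]] - lr * grads[[nm]]
    return(list(weights = weights, state = state))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

# ---- public classifier surface ---------------------------------------------

#' Build the reference convolutional network
#'
#' A small, fully seeded convolutional classifier used as the desk-scale
#' test vehicle for the scalogram-image pipeline: three blocks of (3x3
#' convolution, rectified-linear activation, 2x2 max pooling) with 8, 16
#' and 32 channels, global average pooling, and one dense layer to
#' `n_classes` with softmax output.  Convolution weights are
#' He-initialized from the seeded generator; the dense head starts at
#' zero, so the untrained network predicts exact ties (broken toward the
#' first class).
#'
#' This network is the offline stand-in for externally supplied pretrained
#' backbones (see [attach_backbone()]): large fine-tuned image networks
#' need downloaded weights and are out of scope for self-contained tests.
#'
#' @param input_size `c(height, width)` of the input images; both `>= 32`.
#' @param n_classes Number of output classes, `>= 2`.
#' @param seed Integer seed for weight initialization.
#'
#' @return An untrained `ecg_classifier` handle.
#' @examples
#' clf <- reference_cnn(c(64, 64), 3, seed = 1)
#' @export
reference_cnn <- function(input_size, n_classes, seed = 1) {
  stopifnot(length(input_size) == 2L, is.numeric(input_size))
  if (any(input_size < 32)) {
    stop("`input_size` must be at least 32 x 32 pixels")
  }
  if (!is.numeric(n_classes) || n_classes < 2) {
    stop("`n_classes` must be >= 2")
  }
  input_size <- as.integer(input_size)
  n_classes <- as.integer(n_classes)
  channels <- c(3L, 8L, 16L, 32L)
  weights <- with_private_seed(seed, {
    w <- list()
    for (l in 1:3) {
      fan_in <- 9L * channels[l]
      w[[paste0("W", l)]] <- matrix(
        rnorm(channels[l + 1] * fan_in, 0, sqrt(2 / fan_in)),
        nrow = channels[l + 1])
      w[[paste0("b", l)]] <- numeric(channels[l + 1])
    }
    w$V <- matrix(0, nrow = n_classes, ncol = channels[4])
    w$c0 <- numeric(n_classes)
    w
  })
  structure(
    list(kind = "reference_cnn", input_size = input_size,
         n_classes = n_classes, class_order = NULL, weights = weights,
         channels = channels, seed = as.integer(seed), trained_epochs = 0L,
         history = NULL),
    class = "ecg_classifier"
  )
}

#' Attach an externally supplied feature-extracting backbone
#'
#' Wraps an image-in / features-out component (for example a pretrained
#' network exported from another framework) behind the classifier
#' contract: the backbone's classification layer is replaced by a fresh
#' zero-initialized dense layer with `n_classes` outputs, which is what
#' [train_classifier()] then optimizes (the backbone itself is frozen).
#' Calling this again on the same extractor simply installs another fresh
#' head of the same output dimension.
#'
#' @param feature_extractor A function taking an `H x W x 3 x N` array in
#'   `[0, 1]` and returning an `n_features x N` numeric matrix (or a
#'   vector for a single image).
#' @param n_classes Number of output classes, `>= 2`.
#' @param input_size `c(height, width)` the extractor accepts; probed at
#'   attach time, so an incompatible extractor fails here, not at predict
#'   time.
#'
#' @return An `ecg_classifier` handle of kind `"backbone"`.
#' @export
attach_backbone <- function(feature_extractor, n_classes, input_size) {
  stopifnot(is.function(feature_extractor), length(input_size) == 2L)
  if (!is.numeric(n_classes) || n_classes < 2) stop("`n_classes` must be >= 2")
  input_size <- as.integer(input_size)
  probe <- tryCatch(
    feature_extractor(array(0, c(input_size, 3L, 1L))),
    error = function(e) {
      stop("feature extractor is incompatible with input size ",
           input_size[1], " x ", input_size[2], ": ", conditionMessage(e))
    })
  probe <- as.matrix(probe)
  n_features <- nrow(probe)
  if (n_features < 1) stop("feature extractor returned no features")
  structure(
    list(kind = "backbone", input_size = input_size,
         n_classes = as.integer(n_classes), class_order = NULL,
         weights = list(V = matrix(0, n_classes, n_features),
                        c0 = numeric(n_classes)),
         extractor = feature_extractor, n_features = n_features,
         trained_epochs = 0L, history = NULL),
    class = "ecg_classifier"
  )
}

#' @export
print.ecg_classifier <- function(x, ...) {
  cat(sprintf("ECG scalogram-image classifier (%s), input %d x %d, %d classes\n",
              x$kind, x$input_size[1], x$input_size[2], x$n_classes))
  if (!is.null(x$class_order)) {
    cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  }
  cat(sprintf("  trained epochs: %d\n", x$trained_epochs))
  invisible(x)
}

classifier_probs <- function(object, x, chunk = 256L) {
  # x: (H, W, 3, N) in [0, 1]
  n <- dim(x)[4]
  out <- matrix(NA_real_, object$n_classes, n)
  if (object$kind == "backbone") {
    feats <- as.matrix(object$extractor(x))
    out[] <- softmax_cols(object$weights$V %*% feats + object$weights$c0)
    return(out)
  }
  xc <- aperm(x, c(3, 1, 2, 4))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[, s:e] <- cnn_forward(object$weights,
                              xc[, , , s:e, drop = FALSE])$probs
  }
  out
}

check_image_dims <- function(object, x) {
  d <- dim(x)
  if (d[1] != object$input_size[1] || d[2] != object$input_size[2]) {
    stop("images are ", d[1], " x ", d[2],
         " but the classifier expects ", object$input_size[1], " x ",
         object$input_size[2])
  }
}

#' Predict rhythm classes for scalogram images
#'
#' The predicted label is the argmax class probability; exact ties break
#' toward the earliest class in the class order, deterministically.
#'
#' @param object A trained (or untrained) `ecg_classifier`.
#' @param images Images accepted by [image_tensor()].
#' @param ... Unused.
#' @return A tibble with `.pred_class` (factor in class order) and one
#'   `.prob_<class>` column per class.
#' @export
predict.ecg_classifier <- function(object, images, ...) {
  x <- image_tensor(images)
  check_image_dims(object, x)
  probs <- classifier_probs(object, x)
  classes <- object$class_order %||% paste0("class", seq_len(object$n_classes))
  pred <- classes[apply(probs, 2, which.max)]   # which.max: first maximum
  out <- tibble::tibble(.pred_class = factor(pred, levels = classes))
  for (k in seq_along(classes)) {
    out[[paste0(".prob_", classes[k])]] <- probs[k, ]
  }
  out
}

#' Train a scalogram-image classifier
#'
#' Minimizes categorical cross-entropy with the configured optimizer,
#' epochs, batch size and learning rate.  Shuffling and initialization are
#' fully seeded, so training is deterministic given (inputs, config).  For
#' backbone handles only the attached dense head is optimized.
#'
#' @param object An `ecg_classifier` from [reference_cnn()] or
#'   [attach_backbone()].
#' @param images,labels Training images (see [image_tensor()]) and their
#'   class labels.
#' @param val_images,val_labels Optional validation set, evaluated whenever
#'   history is recorded.
#' @param config A [train_config()].
#'
#' @return A list with `classifier` (the trained handle, carrying the
#'   history) and `history` (a tibble with one row per recording point:
#'   `iteration`, `epoch`, `train_loss`, `train_accuracy`, `val_loss`,
#'   `val_accuracy`; accuracies in percent).
#' @export
train_classifier <- function(object, images, labels,
                             val_images = NULL, val_labels = NULL,
                             config = train_config()) {
  stopifnot(inherits(object, "ecg_classifier"), inherits(config, "train_config"))
  x <- image_tensor(images)
  check_image_dims(object, x)
  n <- dim(x)[4]
  if (n < 1) stop("empty training set")
  labels <- as.character(labels)
  if (length(labels) != n) stop("length(labels) must match the image count")
  classes <- config$class_order %||% object$class_order %||% sort(unique(labels))
  if (length(classes) != object$n_classes) {
    stop("classifier has ", object$n_classes, " outputs but ",
         length(classes), " classes were supplied")
  }
  bad <- setdiff(unique(labels), classes)
  if (length(bad)) {
    stop("label(s) outside the class order: ", paste(bad, collapse = ", "))
  }
  y <- match(labels, classes)
  object$class_order <- classes

  history <- tibble::tibble(
    iteration = integer(), epoch = integer(),
    train_loss = numeric(), train_accuracy = numeric(),
    val_loss = numeric(), val_accuracy = numeric())
  if (config$max_epochs == 0L) {
    object$history <- history
    return(list(classifier = object, history = history))
  }

  has_val <- !is.null(val_images)
  if (has_val) {
    xv <- image_tensor(val_images)
    check_image_dims(object, xv)
    yv <- match(as.character(val_labels), classes)
    if (anyNA(yv)) stop("validation label outside the class order")
  }

  eval_set <- function(w, xs, ys) {
    obj2 <- object
    obj2$weights <- w
    p <- classifier_probs(obj2, xs)
    eps <- 1e-12
    ll <- -mean(log(pmax(p[cbind(ys, seq_along(ys))], eps)))
    acc <- 100 * mean(apply(p, 2, which.max) == ys)
    c(ll, acc)
  }

  is_cnn <- object$kind == "reference_cnn"
  if (is_cnn) xc <- aperm(x, c(3, 1, 2, 4))
  if (!is_cnn) feats_all <- as.matrix(object$extractor(x))

  weights <- object$weights
  state <- adam_init(weights)
  n_batches <- ceiling(n / config$batch_size)
  record_every <- config$validation_frequency %||% n_batches
  idx_cache <- new.env(parent = emptyenv())
  iter <- 0L

  with_private_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      for (bi in seq_len(n_batches)) {
        rows <- ord[((bi - 1L) * config$batch_size + 1L):
                      min(bi * config$batch_size, n)]
        yb <- y[rows]
        onehot <- matrix(0, object$n_classes, length(rows))
        onehot[cbind(yb, seq_along(rows))] <- 1

        if (is_cnn) {
          xb <- xc[, , , rows, drop = FALSE]
          key <- as.character(length(rows))
          if (is.null(idx_cache[[key]])) {
            d <- dim(xb)
            ch <- object$channels
            h <- d[2]; w2 <- d[3]
            lst <- list()
            for (l in 1:3) {
              lst[[l]] <- conv_gather_idx(ch[l], h, w2, d[4])
              h <- h %/% 2L; w2 <- w2 %/% 2L
            }
            idx_cache[[key]] <- lst
          }
          attr(xb, "gather_idx") <- idx_cache[[key]]
          fwd <- cnn_forward(weights, xb, keep_cache = TRUE)
          grads <- cnn_backward(weights, fwd, onehot,
                                idx = idx_cache[[key]])
        } else {
          fb <- feats_all[, rows, drop = FALSE]
          logits <- weights$V %*% fb + weights$c0
          fwd <- list(probs = softmax_cols(logits))
          dlogits <- (fwd$probs - onehot) / length(rows)
          grads <- list(V = tcrossprod(dlogits, fb), c0 = rowSums(dlogits))
        }

        step <- optim_step(weights, grads, state, config)
        weights <- step$weights
        state <- step$state
        iter <- iter + 1L

        if (iter %% record_every == 0L) {
          eps <- 1e-12
          bl <- -mean(log(pmax(fwd$probs[cbind(yb, seq_along(yb))], eps)))
          ba <- 100 * mean(apply(fwd$probs, 2, which.max) == yb)
          if (has_val) {
            vm <- eval_set(weights, xv, yv)
          } else {
            vm <- c(NA_real_, NA_real_)
          }
          history <- dplyr::bind_rows(history, tibble::tibble(
            iteration = iter, epoch = epoch,
            train_loss = bl, train_accuracy = ba,
            val_loss = vm[1], val_accuracy = vm[2]))
        }
      }
    }
  })

  object$weights <- weights
  object$trained_epochs <- object$trained_epochs + config$max_epochs
  object$history <- history
  list(classifier = object, history = history)
}

#' Tidy a classifier's training history
#'
#' @param x A trained `ecg_classifier`.
#' @param ... Unused.
#' @return The training-history tibble (empty if never trained).
#' @method tidy ecg_classifier
#' @export
tidy.ecg_classifier <- function(x, ...) {
  x$history %||% tibble::tibble(
    iteration = integer(), epoch = integer(),
    train_loss = numeric(), train_accuracy = numeric(),
    val_loss = numeric(), val_accuracy = numeric())
}

#' One-row summary of a classifier
#'
#' @param x An `ecg_classifier`.
#' @param ... Unused.
#' @return A one-row tibble: kind, input size, classes, trained epochs,
#'   and final recorded training/validation metrics (NA if untrained).
#' @method glance ecg_classifier
#' @export
glance.ecg_classifier <- function(x, ...) {
  h <- tidy(x)
  last <- if (nrow(h)) h[nrow(h), ] else
    tibble::tibble(train_loss = NA_real_, train_accuracy = NA_real_,
                   val_loss = NA_real_, val_accuracy = NA_real_)
  tibble::tibble(
    kind = x$kind, input_height = x$input_size[1],
    input_width = x$input_size[2], n_classes = x$n_classes,
    trained_epochs = x$trained_epochs,
    train_loss = last$train_loss, train_accuracy = last$train_accuracy,
    val_loss = last$val_loss, val_accuracy = last$val_accuracy)
}

#' Plot a training history
#'
#' @param object An `ecg_classifier` with recorded history, or the history
#'   tibble itself.
#' @param ... Unused.
#' @return A ggplot of accuracy (%) against iteration, one line per split.
#' @method autoplot ecg_classifier
#' @export
autoplot.ecg_classifier <- function(object, ...) {
  h <- if (is.data.frame(object)) object else tidy(object)
  df <- tidyr::pivot_longer(
    h, c("train_accuracy", "val_accuracy"),
    names_to = "split", values_to = "accuracy")
  df$split <- sub("_accuracy$", "", df$split)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$accuracy,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Accuracy (%)", colour = NULL)
}

#' Save / load a classifier checkpoint
#'
#' Checkpoints are JSON (text) documents holding the weights, class order
#' and architecture metadata of a reference CNN.  Backbone handles hold an
#' arbitrary function and cannot be checkpointed this way.
#'
#' @param object A `reference_cnn`-kind `ecg_classifier`.
#' @param path Output path.
#' @return Invisibly, `path` (for `save_classifier`); the restored
#'   `ecg_classifier` (for `load_classifier`).
#' @export
save_classifier <- function(object, path) {
  stopifnot(inherits(object, "ecg_classifier"))
  if (object$kind != "reference_cnn") {
    stop("only reference CNN handles can be checkpointed to JSON")
  }
  payload <- list(
    kind = object$kind, input_size = object$input_size,
    n_classes = object$n_classes, class_order = object$class_order,
    channels = object$channels, seed = object$seed,
    trained_epochs = object$trained_epochs,
    weights = lapply(object$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.vector(w))
      else list(dim = length(w), data = as.vector(w))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(p$weights, function(w) {
    if (length(w$dim) == 2L) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  structure(
    list(kind = p$kind, input_size = as.integer(p$input_size),
         n_classes = as.integer(p$n_classes),
         class_order = if (length(p$class_order)) p$class_order else NULL,
         weights = weights, channels = as.integer(p$channels),
         seed = as.integer(p$seed),
         trained_epochs = as.integer(p$trained_epochs),
         history = NULL),
    class = "ecg_classifier"
  )
}
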