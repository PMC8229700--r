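#' Small residual CNN architecture specification
#'
#' Builds the 27-layer small residual network used for single-heartbeat
#' recognition: a 7x7x32 convolution stem with max pooling, one
#' identity-shortcut residual stage at 32 channels, two projection-shortcut
#' residual stages at 64 and 128 channels (each shortcut is a strided 1x1
#' convolution followed by a 2x2 max pooling), global max pooling and a fully
#' connected softmax classifier. The three addition layers merge: (9) the
#' stage-1 batch norm output with its input, (16) and (23) each stage's main
#' branch batch norm with its max-pooled 1x1 projection.
#'
#' The default 224 x 224 x 3 input can be replaced by any odd-sized square
#' input for which the stage arithmetic stays consistent (e.g. 32 or 64);
#' the parameter count is independent of the input size because the
#' classifier head sits behind global max pooling.
#'
#' @param num_classes Number of identities (>= 2).
#' @param input_size Input image side length (default 224).
#' @return A `small_cnn_spec`: a tibble with one row per layer (columns
#'   `index`, `kind`, `n_filters`, `filter_size`, `stride`, `padding`,
#'   `channels_in`) with attributes `num_classes`, `input_size` and
#'   `skip_wiring`.
#' @export
build_small_cnn <- function(num_classes, input_size = 224) {
  if (!is.numeric(num_classes) || num_classes < 2) {
    abort("`num_classes` must be >= 2.")
  }
  num_classes <- as.integer(num_classes)
  L <- function(index, kind, n_filters = NA, filter_size = NA, stride = NA,
                padding = NA, channels_in = NA) {
    tibble::tibble(index = index, kind = kind, n_filters = n_filters,
                   filter_size = filter_size, stride = stride,
                   padding = padding, channels_in = channels_in)
  }
  spec <- dplyr::bind_rows(
    L(1, "image_input"),
    L(2, "convolution", 32, 7, 1, 3, 3),
    L(3, "max_pooling", NA, 2, 2, 1),
    L(4, "relu"),
    L(5, "batch_norm", channels_in = 32),
    L(6, "convolution", 32, 3, 1, 1, 32),
    L(7, "convolution", 32, 3, 1, 1, 32),
    L(8, "batch_norm", channels_in = 32),
    L(9, "addition"),
    L(10, "relu"),
    L(11, "convolution", 64, 3, 2, 1, 32),
    L(12, "convolution", 64, 3, 2, 1, 64),
    L(13, "batch_norm", channels_in = 64),
    L(14, "convolution", 64, 1, 2, 0, 32),
    L(15, "max_pooling", NA, 2, 2, 1),
    L(16, "addition"),
    L(17, "batch_norm", channels_in = 64),
    L(18, "convolution", 128, 3, 2, 1, 64),
    L(19, "convolution", 128, 3, 2, 1, 128),
    L(20, "batch_norm", channels_in = 128),
    L(21, "convolution", 128, 1, 2, 0, 64),
    L(22, "max_pooling", NA, 2, 2, 1),
    L(23, "addition"),
    L(24, "global_max_pooling"),
    L(25, "fully_connected", n_filters = num_classes, channels_in = 128),
    L(26, "softmax"),
    L(27, "classification_output")
  )
  attr(spec, "num_classes") <- num_classes
  attr(spec, "input_size") <- as.integer(input_size)
  attr(spec, "skip_wiring") <- list(
    `9` = c(5L, 8L), `16` = c(15L, 13L), `23` = c(22L, 20L)
  )
  class(spec) <- c("small_cnn_spec", class(spec))
  spec
}

#' Count learnable parameters of a network spec
#'
#' Convolutions contribute `k^2 * c_in * c_out + c_out`, batch norms `2 * c`,
#' the fully connected head `c_in * num_classes + num_classes`. Strides and
#' pooling carry no parameters, so the count is independent of the input
#' size.
#'
#' @param spec A `small_cnn_spec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  total <- 0L
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    total <- total + switch(
      row$kind,
      convolution = row$filter_size^2 * row$channels_in * row$n_filters +
        row$n_filters,
      batch_norm = 2L * row$channels_in,
      fully_connected = row$channels_in * row$n_filters + row$n_filters,
      0L
    )
  }
  as.integer(total)
}

#' @export
print.small_cnn_spec <- function(x, ...) {
  cat(sprintf("<small_cnn_spec> %d layers, %d classes, %s learnable parameters\n",
              nrow(x), attr(x, "num_classes"),
              format(count_parameters(x), big.mark = ",")))
  NextMethod()
}

#' Training configuration for the small CNN
#'
#' Defaults mirror the reference recipe: stochastic gradient descent with
#' momentum 0.9, mini-batches of 150, learning rate 0.001, 80 epochs.
#'
#' @param batch_size,learning_rate,epochs,momentum,seed Scalars.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 150, learning_rate = 0.001, epochs = 80,
                         momentum = 0.9, seed = 1) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1,
            momentum >= 0, momentum < 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 momentum = momentum, seed = as.integer(seed)),
            class = "train_config")
}

# ---- internal: parameter initialisation and the forward/backward graph ----

init_params <- function(spec) {
  conv_ids <- c(2, 6, 7, 11, 12, 14, 18, 19, 21)
  bn_ids <- c(5, 8, 13, 17, 20)
  pars <- list()
  for (i in conv_ids) {
    row <- spec[spec$index == i, ]
    fanin <- row$filter_size^2 * row$channels_in
    pars[[paste0("W", i)]] <- matrix(
      rnorm(fanin * row$n_filters, 0, sqrt(2 / fanin)), fanin, row$n_filters)
    pars[[paste0("b", i)]] <- numeric(row$n_filters)
  }
  for (i in bn_ids) {
    c_ <- spec$channels_in[spec$index == i]
    pars[[paste0("g", i)]] <- rep(1, c_)
    pars[[paste0("be", i)]] <- numeric(c_)
  }
  nc <- attr(spec, "num_classes")
  pars$W25 <- matrix(rnorm(128 * nc, 0, sqrt(2 / 128)), nc, 128)
  pars$b25 <- numeric(nc)
  pars
}

init_bn_state <- function(spec) {
  s <- list()
  for (i in c(5, 8, 13, 17, 20)) {
    c_ <- spec$channels_in[spec$index == i]
    s[[paste0("m", i)]] <- numeric(c_)
    s[[paste0("v", i)]] <- rep(1, c_)
  }
  s
}

build_plans <- function(spec, input_size) {
  s <- input_size
  p <- list()
  dims <- list()
  conv_out <- function(n, k, st, pd) (n + 2L * pd - k) %/% st + 1L
  p$c2 <- conv_plan(s, s, 3L, 7L, 1L, 3L); s2 <- conv_out(s, 7L, 1L, 3L)
  p$p3 <- pool_plan(s2, s2, 32L, 2L, 2L, 1L); s3 <- p$p3$ho
  dims$stage1 <- s3
  p$c6 <- conv_plan(s3, s3, 32L, 3L, 1L, 1L)
  p$c7 <- conv_plan(s3, s3, 32L, 3L, 1L, 1L)
  p$c11 <- conv_plan(s3, s3, 32L, 3L, 2L, 1L); s11 <- p$c11$ho
  p$c12 <- conv_plan(s11, s11, 64L, 3L, 2L, 1L); s12 <- p$c12$ho
  p$c14 <- conv_plan(s3, s3, 32L, 1L, 2L, 0L); s14 <- p$c14$ho
  p$p15 <- pool_plan(s14, s14, 64L, 2L, 2L, 1L); s15 <- p$p15$ho
  if (s15 != s12) {
    abort(sprintf(
      "Input size %d is incompatible with the stage arithmetic (stage-2 %d vs %d).",
      input_size, s12, s15))
  }
  dims$stage2 <- s12
  p$c18 <- conv_plan(s12, s12, 64L, 3L, 2L, 1L); s18 <- p$c18$ho
  p$c19 <- conv_plan(s18, s18, 128L, 3L, 2L, 1L); s19 <- p$c19$ho
  p$c21 <- conv_plan(s12, s12, 64L, 1L, 2L, 0L); s21 <- p$c21$ho
  p$p22 <- pool_plan(s21, s21, 128L, 2L, 2L, 1L); s22 <- p$p22$ho
  if (s22 != s19) {
    abort(sprintf(
      "Input size %d is incompatible with the stage arithmetic (stage-3 %d vs %d).",
      input_size, s19, s22))
  }
  dims$stage3 <- s19
  list(plans = p, dims = dims)
}

cnn_forward <- function(X, pars, bn_state, plans, training = TRUE) {
  p <- plans$plans
  d1 <- plans$dims$stage1; d2 <- plans$dims$stage2; d3 <- plans$dims$stage3
  cc <- list()
  f2 <- conv_forward(X, p$c2, pars$W2, pars$b2, 32L); cc$f2 <- f2
  f3 <- pool_forward(f2$out, p$p3); cc$f3 <- f3
  x4 <- pmax(f3$out, 0); cc$m4 <- f3$out > 0
  f5 <- bn_forward(x4, d1^2, 32L, pars$g5, pars$be5, bn_state$m5, bn_state$v5,
                   training); cc$f5 <- f5
  f6 <- conv_forward(f5$out, p$c6, pars$W6, pars$b6, 32L); cc$f6 <- f6
  f7 <- conv_forward(f6$out, p$c7, pars$W7, pars$b7, 32L); cc$f7 <- f7
  f8 <- bn_forward(f7$out, d1^2, 32L, pars$g8, pars$be8, bn_state$m8,
                   bn_state$v8, training); cc$f8 <- f8
  x9 <- f5$out + f8$out
  x10 <- pmax(x9, 0); cc$m10 <- x9 > 0
  f11 <- conv_forward(x10, p$c11, pars$W11, pars$b11, 64L); cc$f11 <- f11
  f12 <- conv_forward(f11$out, p$c12, pars$W12, pars$b12, 64L); cc$f12 <- f12
  f13 <- bn_forward(f12$out, d2^2, 64L, pars$g13, pars$be13, bn_state$m13,
                    bn_state$v13, training); cc$f13 <- f13
  f14 <- conv_forward(x10, p$c14, pars$W14, pars$b14, 64L); cc$f14 <- f14
  f15 <- pool_forward(f14$out, p$p15); cc$f15 <- f15
  x16 <- f13$out + f15$out
  f17 <- bn_forward(x16, d2^2, 64L, pars$g17, pars$be17, bn_state$m17,
                    bn_state$v17, training); cc$f17 <- f17
  f18 <- conv_forward(f17$out, p$c18, pars$W18, pars$b18, 128L); cc$f18 <- f18
  f19 <- conv_forward(f18$out, p$c19, pars$W19, pars$b19, 128L); cc$f19 <- f19
  f20 <- bn_forward(f19$out, d3^2, 128L, pars$g20, pars$be20, bn_state$m20,
                    bn_state$v20, training); cc$f20 <- f20
  f21 <- conv_forward(f17$out, p$c21, pars$W21, pars$b21, 128L); cc$f21 <- f21
  f22 <- pool_forward(f21$out, p$p22); cc$f22 <- f22
  x23 <- f20$out + f22$out
  f24 <- gmp_forward(x23, d3^2, 128L); cc$f24 <- f24
  logits <- pars$W25 %*% f24$out + pars$b25
  probs <- softmax_probs(logits)
  bn_new <- bn_state
  if (training) {
    bn_new$m5 <- f5$run_mean; bn_new$v5 <- f5$run_var
    bn_new$m8 <- f8$run_mean; bn_new$v8 <- f8$run_var
    bn_new$m13 <- f13$run_mean; bn_new$v13 <- f13$run_var
    bn_new$m17 <- f17$run_mean; bn_new$v17 <- f17$run_var
    bn_new$m20 <- f20$run_mean; bn_new$v20 <- f20$run_var
  }
  list(probs = probs, x24 = f24$out, cache = cc, bn_state = bn_new)
}

cnn_backward <- function(fwd, X, y_idx, pars, plans) {
  p <- plans$plans
  d1 <- plans$dims$stage1; d2 <- plans$dims$stage2; d3 <- plans$dims$stage3
  cc <- fwd$cache
  N <- ncol(X)
  g <- list()
  dlogits <- fwd$probs
  dlogits[cbind(y_idx, seq_len(N))] <- dlogits[cbind(y_idx, seq_len(N))] - 1
  dlogits <- dlogits / N
  g$W25 <- tcrossprod(dlogits, fwd$x24)
  g$b25 <- rowSums(dlogits)
  d24 <- crossprod(pars$W25, dlogits)
  d23 <- gmp_backward(d24, cc$f24, d3^2, 128L)
  b20 <- bn_backward(d23, cc$f20, d3^2, 128L, pars$g20)
  g$g20 <- b20$dgamma; g$be20 <- b20$dbeta
  d22 <- pool_backward(d23, cc$f22, p$p22)
  b21 <- conv_backward(d22, cc$f21, p$c21, pars$W21, 128L)
  g$W21 <- b21$dW; g$b21 <- b21$db
  b19 <- conv_backward(b20$dX, cc$f19, p$c19, pars$W19, 128L)
  g$W19 <- b19$dW; g$b19 <- b19$db
  b18 <- conv_backward(b19$dX, cc$f18, p$c18, pars$W18, 128L)
  g$W18 <- b18$dW; g$b18 <- b18$db
  d17 <- b18$dX + b21$dX
  b17 <- bn_backward(d17, cc$f17, d2^2, 64L, pars$g17)
  g$g17 <- b17$dgamma; g$be17 <- b17$dbeta
  d16 <- b17$dX
  b13 <- bn_backward(d16, cc$f13, d2^2, 64L, pars$g13)
  g$g13 <- b13$dgamma; g$be13 <- b13$dbeta
  d15 <- pool_backward(d16, cc$f15, p$p15)
  b14 <- conv_backward(d15, cc$f14, p$c14, pars$W14, 64L)
  g$W14 <- b14$dW; g$b14 <- b14$db
  b12 <- conv_backward(b13$dX, cc$f12, p$c12, pars$W12, 64L)
  g$W12 <- b12$dW; g$b12 <- b12$db
  b11 <- conv_backward(b12$dX, cc$f11, p$c11, pars$W11, 64L)
  g$W11 <- b11$dW; g$b11 <- b11$db
  d10 <- b11$dX + b14$dX
  d9 <- d10 * cc$m10
  b8 <- bn_backward(d9, cc$f8, d1^2, 32L, pars$g8)
  g$g8 <- b8$dgamma; g$be8 <- b8$dbeta
  b7 <- conv_backward(b8$dX, cc$f7, p$c7, pars$W7, 32L)
  g$W7 <- b7$dW; g$b7 <- b7$db
  b6 <- conv_backward(b7$dX, cc$f6, p$c6, pars$W6, 32L)
  g$W6 <- b6$dW; g$b6 <- b6$db
  d5 <- d9 + b6$dX   # addition-9 passes the gradient to both branches
  b5 <- bn_backward(d5, cc$f5, d1^2, 32L, pars$g5)
  g$g5 <- b5$dgamma; g$be5 <- b5$dbeta
  d4 <- b5$dX * cc$m4
  d3_ <- pool_backward(d4, cc$f3, p$p3)
  b2 <- conv_backward(d3_, cc$f2, p$c2, pars$W2, 32L)
  g$W2 <- b2$dW; g$b2 <- b2$db
  g
}

images_to_matrix <- function(images) {
  d <- dim(images[[1]])
  X <- matrix(0, prod(d), length(images))
  for (i in seq_along(images)) X[, i] <- as.numeric(images[[i]]) / 255
  list(X = X, size = d[1])
}

#' Train the small CNN on labelled scalogram images
#'
#' Mini-batch stochastic gradient descent with momentum on the softmax
#' cross-entropy loss. Shuffling, initialisation and therefore the entire run
#' are deterministic given `config$seed`.
#'
#' @param images Tibble with a list-column `image` (`S x S x 3` arrays,
#'   values 0-255) and a `subject_id` label column.
#' @param config A [train_config()].
#' @param spec Optional `small_cnn_spec`; built automatically from the number
#'   of distinct labels and the image size when omitted.
#' @param classes Optional full label set; labels absent from the training
#'   data raise an error naming them.
#' @return A `small_cnn_fit` with elements `spec`, `pars`, `bn_state`,
#'   `classes`, `log` (per-epoch loss/accuracy tibble).
#' @export
train_small_cnn <- function(images, config = train_config(), spec = NULL,
                            classes = NULL) {
  labels <- as.character(images$subject_id)
  observed <- sort(unique(labels))
  classes <- if (is.null(classes)) observed else sort(as.character(classes))
  absent <- setdiff(classes, observed)
  if (length(absent)) {
    abort(sprintf("Classes absent from the training data: %s",
                  paste(absent, collapse = ", ")))
  }
  if (length(classes) < 2) abort("Need at least 2 classes in the training data.")
  dat <- images_to_matrix(images$image)
  spec <- spec %||% build_small_cnn(length(classes), input_size = dat$size)
  if (attr(spec, "num_classes") != length(classes)) {
    abort(sprintf("Spec expects %d classes but the data has %d.",
                  attr(spec, "num_classes"), length(classes)))
  }
  y <- match(labels, classes)
  set.seed(config$seed)
  pars <- init_params(spec)
  bn_state <- init_bn_state(spec)
  plans <- build_plans(spec, dat$size)
  vel <- lapply(pars, function(p) p * 0)
  N <- ncol(dat$X)
  log_rows <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; ep_correct <- 0
    for (bs in seq(1, N, by = config$batch_size)) {
      idx <- ord[bs:min(N, bs + config$batch_size - 1L)]
      Xb <- dat$X[, idx, drop = FALSE]
      yb <- y[idx]
      fwd <- cnn_forward(Xb, pars, bn_state, plans, training = TRUE)
      bn_state <- fwd$bn_state
      loss <- cross_entropy_loss(fwd$probs, yb)
      grads <- cnn_backward(fwd, Xb, yb, pars, plans)
      for (nm in names(grads)) {
        vel[[nm]] <- config$momentum * vel[[nm]] - config$learning_rate * grads[[nm]]
        pars[[nm]] <- pars[[nm]] + vel[[nm]]
      }
      ep_loss <- ep_loss + loss * length(idx)
      ep_correct <- ep_correct + sum(apply(fwd$probs, 2, which.max) == yb)
    }
    log_rows[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / N,
                                     accuracy = ep_correct / N)
  }
  structure(
    list(spec = spec, pars = pars, bn_state = bn_state, classes = classes,
         input_size = dat$size, config = config,
         log = dplyr::bind_rows(log_rows)),
    class = "small_cnn_fit"
  )
}

#' @export
print.small_cnn_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf(
    "<small_cnn_fit> %d classes, input %dx%dx3, %d epochs (final loss %.4f, training accuracy %.3f)\n",
    length(x$classes), x$input_size, x$input_size, nrow(x$log), last$loss,
    last$accuracy))
  invisible(x)
}

#' Predict identities for scalogram images
#'
#' @param object A `small_cnn_fit`.
#' @param images Tibble with an `image` list-column (same size as training).
#' @param ... Unused.
#' @return A tibble with `pred` (label, argmax with ties to the lowest class
#'   index) and a `probs` list-column (named probability vectors summing
#'   to 1).
#' @export
predict.small_cnn_fit <- function(object, images, ...) {
  dat <- images_to_matrix(images$image)
  if (dat$size != object$input_size) {
    abort(sprintf("Image size %d does not match the model's input size %d.",
                  dat$size, object$input_size))
  }
  plans <- build_plans(object$spec, dat$size)
  # batch inference to bound memory
  N <- ncol(dat$X)
  preds <- character(N)
  probs <- vector("list", N)
  for (bs in seq(1, N, by = 256)) {
    idx <- bs:min(N, bs + 255)
    fwd <- cnn_forward(dat$X[, idx, drop = FALSE], object$pars,
                       object$bn_state, plans, training = FALSE)
    for (k in seq_along(idx)) {
      pv <- fwd$probs[, k]
      names(pv) <- object$classes
      probs[[idx[k]]] <- pv
      preds[idx[k]] <- object$classes[which.max(pv)]
    }
  }
  tibble::tibble(pred = preds, probs = probs)
}

#' @export
tidy.small_cnn_fit <- function(x, ...) x$log

#' @export
glance.small_cnn_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(
    n_classes = length(x$classes),
    n_layers = nrow(x$spec),
    n_parameters = count_parameters(x$spec),
    epochs = nrow(x$log),
    final_loss = last$loss,
    final_training_accuracy = last$accuracy
  )
}

#' @export
autoplot.small_cnn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("loss", "accuracy"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
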