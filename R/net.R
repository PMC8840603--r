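# Toy-scale multi-branch reconstruction network, implemented natively: three
# parallel downsampling feature extractors carrying the signature mechanisms
# of the migrated backbones (residual skips, channel-attention weighting,
# dense connectivity), cascade feature fusion by channel concatenation, and a
# pre-upsampling head that restores full resolution with convolution +
# pixel-recombination stages. Forward and backward passes are hand-derived;
# convolution uses im2col + BLAS matrix products. Tensors are H x W x C
# arrays.

## ---- low-level layers -----------------------------------------------------

conv_init <- function(c_in, c_out, ksize = 3L) {
  fan_in <- ksize * ksize * c_in
  list(w = matrix(stats::rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)),
                  fan_in, c_out),
       b = numeric(c_out), k = as.integer(ksize))
}

im2col <- function(x, k, stride = 1L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * pad, W + 2L * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  Ho <- length(seq.int(1L, H, by = stride))
  Wo <- length(seq.int(1L, W, by = stride))
  r0 <- (seq_len(Ho) - 1L) * stride
  c0 <- (seq_len(Wo) - 1L) * stride
  M <- matrix(0, Ho * Wo, k * k * C)
  col <- 0L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    M[, col + seq_len(C)] <- matrix(xp[r0 + dy + 1L, c0 + dx + 1L, ,
                                       drop = FALSE], Ho * Wo, C)
    col <- col + C
  }
  list(M = M, Ho = Ho, Wo = Wo, dims = d, pad = pad, r0 = r0, c0 = c0)
}

col2im <- function(dM, ic, k) {
  H <- ic$dims[1]; W <- ic$dims[2]; C <- ic$dims[3]
  dxp <- array(0, c(H + 2L * ic$pad, W + 2L * ic$pad, C))
  col <- 0L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    slab <- array(dM[, col + seq_len(C)], c(ic$Ho, ic$Wo, C))
    dxp[ic$r0 + dy + 1L, ic$c0 + dx + 1L, ] <-
      dxp[ic$r0 + dy + 1L, ic$c0 + dx + 1L, , drop = FALSE] + slab
    col <- col + C
  }
  dxp[ic$pad + seq_len(H), ic$pad + seq_len(W), , drop = FALSE]
}

conv_fwd <- function(x, p, stride = 1L) {
  ic <- im2col(x, p$k, stride)
  out_mat <- ic$M %*% p$w
  out_mat <- sweep(out_mat, 2L, p$b, "+")
  list(out = array(out_mat, c(ic$Ho, ic$Wo, ncol(p$w))),
       cache = list(ic = ic, p = p, stride = stride))
}

conv_bwd <- function(dout, cache) {
  ic <- cache$ic; p <- cache$p
  dmat <- matrix(dout, ic$Ho * ic$Wo, ncol(p$w))
  list(dx = col2im(dmat %*% t(p$w), ic, p$k),
       dw = crossprod(ic$M, dmat),
       db = colSums(dmat))
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dout, cache) dout * cache

# Squeeze-and-excitation channel attention: global average pool -> two dense
# layers -> sigmoid per-channel gains.
se_init <- function(c_in, reduce = 2L) {
  h <- max(1L, c_in %/% reduce)
  # positive squeeze bias keeps the hidden ReLU live at initialization
  list(w1 = matrix(stats::rnorm(h * c_in, 0, sqrt(2 / c_in)), h, c_in),
       b1 = rep(1, h),
       w2 = matrix(stats::rnorm(c_in * h, 0, sqrt(2 / h)), c_in, h),
       b2 = numeric(c_in))
}

se_fwd <- function(x, p) {
  d <- dim(x)
  z <- apply(x, 3L, mean)
  h_pre <- drop(p$w1 %*% z) + p$b1
  h <- pmax(h_pre, 0)
  s_pre <- drop(p$w2 %*% h) + p$b2
  s <- 1 / (1 + exp(-s_pre))
  out <- x * rep(s, each = d[1] * d[2])
  list(out = out, cache = list(x = x, z = z, h = h, h_pre = h_pre, s = s, p = p))
}

se_bwd <- function(dout, cache) {
  x <- cache$x; d <- dim(x); hw <- d[1] * d[2]
  s <- cache$s; p <- cache$p
  dx <- dout * rep(s, each = hw)
  ds <- vapply(seq_len(d[3]), function(c) sum(dout[, , c] * x[, , c]),
               numeric(1))
  ds_pre <- ds * s * (1 - s)
  dw2 <- ds_pre %o% cache$h
  db2 <- ds_pre
  dh <- drop(crossprod(p$w2, ds_pre)) * (cache$h_pre > 0)
  dw1 <- dh %o% cache$z
  db1 <- dh
  dz <- drop(crossprod(p$w1, dh))
  dx <- dx + rep(dz / hw, each = hw)
  list(dx = dx, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

## ---- exported structural operations --------------------------------------

#' Cascade feature fusion by channel concatenation
#'
#' Merges the feature maps of the three extractor branches into one map whose
#' channel count is the sum of the branch channel counts; every input value
#' appears exactly once in the output (order a, b, c).
#'
#' @param x_a,x_b,x_c H x W x C arrays with identical spatial size (any of
#'   them may have zero channels)
#' @return an H x W x (C_a + C_b + C_c) array
#' @export
fuse_features <- function(x_a, x_b, x_c) {
  maps <- list(x_a, x_b, x_c)
  for (m in maps)
    if (length(dim(m)) != 3L) stop("feature maps must be H x W x C arrays",
                                   call. = FALSE)
  hw <- lapply(maps, function(m) dim(m)[1:2])
  if (!all(vapply(hw, identical, logical(1), hw[[1]])))
    stop("feature maps must share spatial size", call. = FALSE)
  d <- dim(maps[[1]])[1:2]
  array(c(x_a, x_b, x_c),
        c(d, dim(x_a)[3] + dim(x_b)[3] + dim(x_c)[3]))
}

#' Pixel recombination (sub-pixel rearrangement) by a factor of 2
#'
#' Each consecutive group of 4 input channels becomes one output channel at
#' doubled spatial size: channel `4(c-1) + 2 dy + dx + 1` of the input fills
#' the output pixels at row offset `dy`, column offset `dx` (dy, dx in {0, 1})
#' of output channel `c`. Element count is conserved exactly.
#'
#' @param x H x W x C array with C divisible by 4
#' @return a 2H x 2W x C/4 array
#' @export
pixel_shuffle <- function(x) {
  d <- dim(x)
  if (length(d) != 3L || d[3] %% 4L != 0L)
    stop("pixel recombination needs an H x W x C array with C divisible by 4",
         call. = FALSE)
  c4 <- d[3] %/% 4L
  out <- array(0, c(2L * d[1], 2L * d[2], c4))
  for (dy in 0:1) for (dx in 0:1) {
    out[seq.int(1L, 2L * d[1], 2L) + dy,
        seq.int(1L, 2L * d[2], 2L) + dx, ] <-
      x[, , (seq_len(c4) - 1L) * 4L + 2L * dy + dx + 1L, drop = FALSE]
  }
  out
}

pixel_shuffle_bwd <- function(dout) {
  d <- dim(dout)
  x <- array(0, c(d[1] %/% 2L, d[2] %/% 2L, d[3] * 4L))
  for (dy in 0:1) for (dx in 0:1) {
    x[, , (seq_len(d[3]) - 1L) * 4L + 2L * dy + dx + 1L] <-
      dout[seq.int(1L, d[1], 2L) + dy, seq.int(1L, d[2], 2L) + dx, ,
           drop = FALSE]
  }
  x
}

#' One upsampling stage: convolution + pixel recombination, doubling size
#'
#' Applies a 3x3 convolution (identity mapping when `weights` is `NULL`, in
#' which case the input channel count itself must be divisible by 4) followed
#' by [pixel_shuffle()]. Output height and width are exactly twice the input.
#'
#' @param features H x W x C array
#' @param weights optional conv parameter list from the network; its output
#'   channels must be divisible by 4
#' @export
upsample_stage <- function(features, weights = NULL) {
  if (is.null(weights)) {
    pixel_shuffle(features)
  } else {
    if (ncol(weights$w) %% 4L != 0L)
      stop("stage convolution must produce a channel count divisible by 4",
           call. = FALSE)
    pixel_shuffle(conv_fwd(features, weights)$out)
  }
}

## ---- model ----------------------------------------------------------------

#' Assemble the multi-branch fusion reconstruction network
#'
#' Maps a 2-channel S x S dual-channel image to a 2-channel S x S output. The
#' `"standin"` branches are shallow convolutional stacks carrying the three
#' signature mechanisms of the migrated backbones — a residual skip, a
#' channel-attention gate, and dense connectivity — each after a stride-2
#' downsampling convolution; the fused 3C-channel map is restored to full
#' resolution by one convolution + pixel-recombination stage (log2 of the
#' extractor downsampling factor) and projected to 2 channels, with a global
#' input skip. Requesting a named pretrained backbone raises a capability
#' error: no deep-learning backend is installed, and the branches are
#' deliberately pluggable stand-ins.
#'
#' @param branch_kind `"standin"`, or one of `"resnet50"`, `"xception"`,
#'   `"densenet121"` (which require an external deep-learning backend)
#' @param channels trunk width C of each branch
#' @param growth dense-branch growth rate
#' @param seed seed for weight initialization
#' @return an object of class `fpm_network`
#' @export
fpm_network <- function(branch_kind = c("standin", "resnet50", "xception",
                                        "densenet121"),
                        channels = 8L, growth = 4L, seed = 1L) {
  branch_kind <- match.arg(branch_kind)
  if (branch_kind != "standin")
    stop("backbone '", branch_kind, "' requires a deep-learning backend, ",
         "which is not available; use branch_kind = \"standin\"",
         call. = FALSE)
  C <- as.integer(channels); G <- as.integer(growth)
  stopifnot(C >= 2, G >= 1)
  params <- with_seed(seed, list(
    stem = conv_init(2L, C),
    a_down = conv_init(C, C), a1 = conv_init(C, C), a2 = conv_init(C, C),
    b_down = conv_init(C, C), b1 = conv_init(C, C), b_se = se_init(C),
    c_down = conv_init(C, C), c1 = conv_init(C, G), c2 = conv_init(C + G, G),
    c_proj = conv_init(C + 2L * G, C, 1L),
    head1 = conv_init(3L * C, 4L * C),
    head2 = conv_init(2L * C, C),
    out = conv_init(C, 2L)))
  # zero-initialized projection: with the global input skip the untrained
  # network is exactly the identity map, which stabilizes early training
  params$out$w[] <- 0
  structure(list(params = params, channels = C, growth = G,
                 branch_kind = branch_kind, seed = as.integer(seed)),
            class = "fpm_network")
}

#' @export
print.fpm_network <- function(x, ...) {
  cat("FPM fusion network (", x$branch_kind, " branches, C =", x$channels,
      ", growth =", x$growth, "):", n_parameters(x), "parameters\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param model an `fpm_network`
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p)
    sum(vapply(p[names(p) != "k"], length, integer(1))), integer(1)))
}

net_forward <- function(model, x, keep_cache = TRUE) {
  p <- model$params
  cc <- list()
  st <- conv_fwd(x, p$stem); s_r <- relu_fwd(st$out)
  # residual branch
  ad <- conv_fwd(s_r$out, p$a_down, 2L); ad_r <- relu_fwd(ad$out)
  a1 <- conv_fwd(ad_r$out, p$a1); a1_r <- relu_fwd(a1$out)
  a2 <- conv_fwd(a1_r$out, p$a2)
  a_sum <- a2$out + ad_r$out
  a_out <- relu_fwd(a_sum)
  # attention branch
  bd <- conv_fwd(s_r$out, p$b_down, 2L); bd_r <- relu_fwd(bd$out)
  b1 <- conv_fwd(bd_r$out, p$b1); b1_r <- relu_fwd(b1$out)
  b_se <- se_fwd(b1_r$out, p$b_se)
  # dense branch
  cd <- conv_fwd(s_r$out, p$c_down, 2L); cd_r <- relu_fwd(cd$out)
  c1 <- conv_fwd(cd_r$out, p$c1); c1_r <- relu_fwd(c1$out)
  cat1 <- fuse_features(cd_r$out, c1_r$out,
                        array(0, c(dim(cd_r$out)[1:2], 0L)))
  c2 <- conv_fwd(cat1, p$c2); c2_r <- relu_fwd(c2$out)
  cat2 <- fuse_features(cat1, c2_r$out,
                        array(0, c(dim(cat1)[1:2], 0L)))
  cp <- conv_fwd(cat2, p$c_proj); cp_r <- relu_fwd(cp$out)
  # fusion + pre-upsampling head
  fused <- fuse_features(a_out$out, b_se$out, cp_r$out)
  h1 <- conv_fwd(fused, p$head1); h1_r <- relu_fwd(h1$out)
  up <- pixel_shuffle(h1_r$out)
  # full-resolution stem skip rejoins the upsampled features
  upcat <- fuse_features(up, s_r$out, array(0, c(dim(up)[1:2], 0L)))
  h2 <- conv_fwd(upcat, p$head2); h2_r <- relu_fwd(h2$out)
  o <- conv_fwd(h2_r$out, p$out)
  out <- o$out + x           # global input skip
  if (!keep_cache) return(list(out = out))
  list(out = out,
       cache = list(st = st, s_r = s_r, ad = ad, ad_r = ad_r, a1 = a1,
                    a1_r = a1_r, a2 = a2, a_out = a_out, bd = bd,
                    bd_r = bd_r, b1 = b1, b1_r = b1_r, b_se = b_se,
                    cd = cd, cd_r = cd_r, c1 = c1, c1_r = c1_r, c2 = c2,
                    c2_r = c2_r, cp = cp, cp_r = cp_r, h1 = h1,
                    h1_r = h1_r, h2 = h2, h2_r = h2_r, o = o,
                    dims = list(C = model$channels, G = model$growth)))
}

net_backward <- function(model, cache, dout) {
  C <- cache$dims$C; G <- cache$dims$G
  g <- list()
  bo <- conv_bwd(dout, cache$o$cache)
  g$out <- bo[c("dw", "db")]
  d_h2r <- relu_bwd(bo$dx, cache$h2_r$cache)
  bh2 <- conv_bwd(d_h2r, cache$h2$cache)
  g$head2 <- bh2[c("dw", "db")]
  d_up <- bh2$dx[, , seq_len(C), drop = FALSE]
  d_sr_skip <- bh2$dx[, , C + seq_len(C), drop = FALSE]
  d_h1r <- relu_bwd(pixel_shuffle_bwd(d_up), cache$h1_r$cache)
  bh1 <- conv_bwd(d_h1r, cache$h1$cache)
  g$head1 <- bh1[c("dw", "db")]
  d_fused <- bh1$dx
  d_a <- d_fused[, , seq_len(C), drop = FALSE]
  d_b <- d_fused[, , C + seq_len(C), drop = FALSE]
  d_c <- d_fused[, , 2L * C + seq_len(C), drop = FALSE]
  # dense branch backward
  d_cpr <- relu_bwd(d_c, cache$cp_r$cache)
  bcp <- conv_bwd(d_cpr, cache$cp$cache)
  g$c_proj <- bcp[c("dw", "db")]
  d_cat2 <- bcp$dx
  d_cat1 <- d_cat2[, , seq_len(C + G), drop = FALSE]
  d_c2r <- relu_bwd(d_cat2[, , C + G + seq_len(G), drop = FALSE],
                    cache$c2_r$cache)
  bc2 <- conv_bwd(d_c2r, cache$c2$cache)
  g$c2 <- bc2[c("dw", "db")]
  d_cat1 <- d_cat1 + bc2$dx
  d_cdr <- d_cat1[, , seq_len(C), drop = FALSE]
  d_c1r <- relu_bwd(d_cat1[, , C + seq_len(G), drop = FALSE],
                    cache$c1_r$cache)
  bc1 <- conv_bwd(d_c1r, cache$c1$cache)
  g$c1 <- bc1[c("dw", "db")]
  d_cdr <- d_cdr + bc1$dx
  d_cdr <- relu_bwd(d_cdr, cache$cd_r$cache)
  bcd <- conv_bwd(d_cdr, cache$cd$cache)
  g$c_down <- bcd[c("dw", "db")]
  # attention branch backward
  bse <- se_bwd(d_b, cache$b_se$cache)
  g$b_se <- bse[c("dw1", "db1", "dw2", "db2")]
  d_b1r <- relu_bwd(bse$dx, cache$b1_r$cache)
  bb1 <- conv_bwd(d_b1r, cache$b1$cache)
  g$b1 <- bb1[c("dw", "db")]
  d_bdr <- relu_bwd(bb1$dx, cache$bd_r$cache)
  bbd <- conv_bwd(d_bdr, cache$bd$cache)
  g$b_down <- bbd[c("dw", "db")]
  # residual branch backward
  d_asum <- relu_bwd(d_a, cache$a_out$cache)
  ba2 <- conv_bwd(d_asum, cache$a2$cache)
  g$a2 <- ba2[c("dw", "db")]
  d_a1r <- relu_bwd(ba2$dx, cache$a1_r$cache)
  ba1 <- conv_bwd(d_a1r, cache$a1$cache)
  g$a1 <- ba1[c("dw", "db")]
  d_adr <- relu_bwd(ba1$dx + d_asum, cache$ad_r$cache)  # skip path
  bad <- conv_bwd(d_adr, cache$ad$cache)
  g$a_down <- bad[c("dw", "db")]
  # stem backward
  d_sr <- bad$dx + bbd$dx + bcd$dx + d_sr_skip
  d_sr <- relu_bwd(d_sr, cache$s_r$cache)
  bst <- conv_bwd(d_sr, cache$st$cache)
  g$stem <- bst[c("dw", "db")]
  g
}

# Map gradient-name pairs onto the parameter structure for the optimizer.
grad_names <- list(conv = c(dw = "w", db = "b"),
                   se = c(dw1 = "w1", db1 = "b1", dw2 = "w2", db2 = "b2"))

## ---- training -------------------------------------------------------------

#' Training hyperparameters
#'
#' Defaults follow the training recipe the package targets: Adam at learning
#' rate 4e-5 with batches of 4, mean-squared-error loss. Toy runs typically
#' raise the learning rate.
#'
#' @param learning_rate Adam step size (> 0)
#' @param batch_size examples per gradient step (>= 1)
#' @param epochs full passes over the training set
#' @param loss loss token; only `"mse"` is supported
#' @param seed seed controlling initial shuffling and batch order
#' @export
train_config <- function(learning_rate = 4e-5, batch_size = 4L, epochs = 10L,
                         loss = "mse", seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            identical(loss, "mse"))
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 seed = as.integer(seed)),
            class = "train_config")
}

as_example_array <- function(x) {
  if (inherits(x, "fpm_input")) as_input_array(x) else x
}

#' Train the network by Adam on mean-squared error
#'
#' Minimizes the per-pixel MSE between predicted and true dual-channel
#' images. Returns the trained model and the per-epoch loss history (train
#' and, when a validation set is supplied, validation). A non-finite loss
#' aborts with a training-divergence error carrying the last finite model in
#' its `model` field.
#'
#' @param model an `fpm_network`
#' @param data list of examples, each a list with `input` and `truth`
#'   (`fpm_input` objects or H x W x 2 arrays)
#' @param cfg a `train_config`
#' @param validation optional list of examples in the same form
#' @return a list with `model` (trained) and `history` (data frame with
#'   `epoch`, `train_loss`, and `val_loss` when validation is given)
#' @export
fpm_train <- function(model, data, cfg = train_config(), validation = NULL) {
  stopifnot(inherits(model, "fpm_network"), inherits(cfg, "train_config"))
  if (length(data) == 0) stop("empty training set", call. = FALSE)
  xs <- lapply(data, function(e) as_example_array(e$input))
  ys <- lapply(data, function(e) as_example_array(e$truth))
  vx <- lapply(validation, function(e) as_example_array(e$input))
  vy <- lapply(validation, function(e) as_example_array(e$truth))
  adam <- list(m = rapply(model$params, function(z) z * 0, how = "replace"),
               v = rapply(model$params, function(z) z * 0, how = "replace"),
               t = 0L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = integer(0), train_loss = numeric(0))
  if (!is.null(validation)) history$val_loss <- numeric(0)
  last_good <- model
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample(length(xs))
      batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
      epoch_losses <- numeric(0)
      for (bi in batches) {
        grads <- NULL
        loss <- 0
        for (i in bi) {
          fwd <- net_forward(model, xs[[i]])
          diff <- fwd$out - ys[[i]]
          loss <- loss + mean(diff^2)
          dout <- 2 * diff / (length(diff) * length(bi))
          gi <- net_backward(model, fwd$cache, dout)
          grads <- if (is.null(grads)) gi else
            Map(function(a, b) Map(`+`, a, b), grads, gi)
        }
        loss <- loss / length(bi)
        if (!is.finite(loss)) {
          cond <- structure(
            class = c("fpm_training_divergence", "error", "condition"),
            list(message = sprintf("training diverged at epoch %d", epoch),
                 call = NULL, model = last_good))
          stop(cond)
        }
        epoch_losses <- c(epoch_losses, loss)
        adam$t <- adam$t + 1L
        for (layer in names(grads)) {
          kind <- if ("dw1" %in% names(grads[[layer]])) "se" else "conv"
          for (gn in names(grad_names[[kind]])) {
            pn <- grad_names[[kind]][[gn]]
            gval <- grads[[layer]][[gn]]
            adam$m[[layer]][[pn]] <- b1 * adam$m[[layer]][[pn]] + (1 - b1) * gval
            adam$v[[layer]][[pn]] <- b2 * adam$v[[layer]][[pn]] + (1 - b2) * gval^2
            mhat <- adam$m[[layer]][[pn]] / (1 - b1^adam$t)
            vhat <- adam$v[[layer]][[pn]] / (1 - b2^adam$t)
            model$params[[layer]][[pn]] <- model$params[[layer]][[pn]] -
              cfg$learning_rate * mhat / (sqrt(vhat) + eps)
          }
        }
        last_good <- model
      }
      row <- data.frame(epoch = epoch, train_loss = mean(epoch_losses))
      if (!is.null(validation)) {
        row$val_loss <- mean(vapply(seq_along(vx), function(i) {
          mean((net_forward(model, vx[[i]], keep_cache = FALSE)$out -
                  vy[[i]])^2)
        }, numeric(1)))
      }
      history <- rbind(history, row)
    }
  })
  list(model = model, history = history)
}

#' Predict a dual-channel reconstruction
#'
#' A deterministic evaluation-mode forward pass. With `raw = TRUE` the
#' unclamped H x W x 2 output array is returned; otherwise the output is
#' wrapped into a valid `fpm_input` (intensity clipped at 0, phase wrapped).
#'
#' @param object an `fpm_network` (possibly trained)
#' @param newdata an `fpm_input` or H x W x 2 array
#' @param raw return the raw output array instead of an `fpm_input`
#' @param ... unused
#' @export
predict.fpm_network <- function(object, newdata, raw = FALSE, ...) {
  x <- as_example_array(newdata)
  if (length(dim(x)) != 3L || dim(x)[3] != 2L)
    stop("network input must be an H x W x 2 dual-channel image",
         call. = FALSE)
  out <- net_forward(object, x, keep_cache = FALSE)$out
  if (raw) out else input_from_array(out)
}
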