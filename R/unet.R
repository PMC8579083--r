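# Compact trainable encoder-decoder (U-Net style) segmenter, 2D or 3D.
#
# The network is a standard U-Net topology: per resolution level two 3x3(x3)
# convolutions with ReLU, 2x max-pooling between levels, nearest-neighbor
# upsampling with skip concatenation on the way up (a 1x1 convolution
# reduces the concatenated channels before the level's convolutions), and a
# final 1x1 convolution with a sigmoid.  Training minimizes the Dice loss
# with Adam at batch size 1.  Everything is seeded and deterministic.
#
# Weights are K x Cout matrices (K = Cin * prod(kernel)); feature maps are
# N x C matrices over the voxel grid.  2D networks are 3D networks with a
# flat z axis (kernel and pooling of extent 1 along z).

#' Soft Dice loss
#'
#' `1 - 2*sum(p*t) / (sum(p) + sum(t) + eps)`, in `[0, 1]`; 0 for perfect
#' overlap, 1 for disjoint masks.
#'
#' @param pred probability grid in `[0, 1]`.
#' @param truth binary grid of the same shape.
#' @param eps numerical stabilizer.
#' @return Scalar loss.
#' @export
dice_loss <- function(pred, truth, eps = 1e-6) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("dice_loss: shape mismatch")
  den <- sum(pred) + sum(truth) + eps
  1 - 2 * sum(pred * truth) / den
}

dice_loss_grad <- function(pred, truth, eps = 1e-6) {
  den <- sum(pred) + sum(truth) + eps
  num <- 2 * sum(pred * truth)
  (num / den^2) - (2 * truth / den)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam at batch size 1,
#' initial learning rate 1e-3 dropped to 1e-4 after epoch 100 and to 1e-5
#' after epoch 250, with a 90:10 training:validation split.
#'
#' @param epochs number of epochs (>= 1).
#' @param batch_size volumes per gradient step (the recipe uses 1).
#' @param optimizer currently `"adam"`.
#' @param learning_rate initial learning rate.
#' @param milestones epochs after which the rate is multiplied by
#'   `lr_decay` (cumulatively).
#' @param lr_decay per-milestone decay factor.
#' @param validation_fraction fraction of cases held out for validation
#'   monitoring, in `[0, 0.5]`.
#' @param augment apply data augmentation (flip / rotation / translation /
#'   scale combinations) during training.
#' @param seed RNG seed controlling initialization, shuffling and
#'   augmentation.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 1L, optimizer = "adam",
                         learning_rate = 1e-3, milestones = c(100L, 250L),
                         lr_decay = 0.1, validation_fraction = 0.1,
                         augment = FALSE, seed = 1L) {
  stopifnot(epochs >= 1L, learning_rate > 0,
            validation_fraction >= 0, validation_fraction <= 0.5,
            optimizer == "adam")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 learning_rate = learning_rate,
                 milestones = as.integer(milestones), lr_decay = lr_decay,
                 validation_fraction = validation_fraction,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

schedule_lr <- function(cfg, epoch) {
  cfg$learning_rate * cfg$lr_decay^sum(epoch > cfg$milestones)
}

#' Construct an untrained U-Net segmenter
#'
#' @param dimensionality 2 or 3.
#' @param depth number of pooling steps (resolution levels minus one).
#' @param base_channels channels at the finest level; doubled per level.
#' @param in_channels input channels.
#' @param seed seed for the (He) weight initialization.
#' @return An object of class `unet_segmenter`.
#' @export
unet_segmenter <- function(dimensionality = 3L, depth = 1L,
                           base_channels = 4L, in_channels = 1L, seed = 1L) {
  stopifnot(dimensionality %in% c(2L, 3L), depth >= 0L, base_channels >= 1L)
  ksz <- if (dimensionality == 3L) c(3L, 3L, 3L) else c(3L, 3L, 1L)
  pf <- if (dimensionality == 3L) c(2L, 2L, 2L) else c(2L, 2L, 1L)
  set.seed(seed)
  he_conv <- function(cin, cout, k) {
    K <- cin * prod(k)
    list(W = matrix(rnorm(K * cout, sd = sqrt(2 / K)), K, cout),
         b = numeric(cout))
  }
  ch <- function(l) base_channels * 2L^l
  params <- list()
  for (l in 0:depth) {
    cin <- if (l == 0L) in_channels else ch(l - 1L)
    params[[paste0("enc", l, "a")]] <- he_conv(cin, ch(l), ksz)
    params[[paste0("enc", l, "b")]] <- he_conv(ch(l), ch(l), ksz)
  }
  if (depth > 0L) for (l in (depth - 1L):0) {
    params[[paste0("dec", l, "r")]] <- he_conv(ch(l) + ch(l + 1L), ch(l),
                                               c(1L, 1L, 1L))
    params[[paste0("dec", l, "a")]] <- he_conv(ch(l), ch(l), ksz)
    params[[paste0("dec", l, "b")]] <- he_conv(ch(l), ch(l), ksz)
  }
  params[["out"]] <- he_conv(base_channels, 1L, c(1L, 1L, 1L))
  # start the output probabilities low: with foreground a small minority,
  # a negative prior bias makes the Dice loss informative from epoch 1
  params[["out"]]$b[] <- -2
  structure(list(dimensionality = dimensionality, depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 kernel = ksz, pool = pf, seed = as.integer(seed),
                 params = params, history = NULL),
            class = "unet_segmenter")
}

#' @export
print.unet_segmenter <- function(x, ...) {
  npar <- sum(vapply(x$params, function(p) length(p$W) + length(p$b),
                     numeric(1)))
  cat(sprintf("<unet_segmenter> %dD, depth %d, base %d channels, %d params%s\n",
              x$dimensionality, x$depth, x$base_channels, npar,
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

relu <- function(x) x * (x > 0)

unet_forward <- function(model, x, dims, cache = FALSE) {
  p <- model$params
  ksz <- model$kernel; pf <- model$pool; D <- model$depth
  cv <- function(a, nm, d, k = ksz)
    cpp_conv_fw(a, p[[nm]]$W, p[[nm]]$b, d, k)
  cc <- list(enc_in = list(), enc_h1 = list(), enc_h2 = list(),
             pools = list(), dims = list(), dec = list())
  a <- x; d <- dims
  for (l in 0:D) {
    if (l > 0) {
      pl <- cpp_maxpool_fw(a, d, pf)
      cc$pools[[l]] <- list(idx = pl$idx, n_in = nrow(a))
      a <- pl$Y; d <- pl$dims_out
    }
    cc$enc_in[[l + 1]] <- a
    h1 <- relu(cv(a, paste0("enc", l, "a"), d))
    h2 <- relu(cv(h1, paste0("enc", l, "b"), d))
    cc$enc_h1[[l + 1]] <- h1
    cc$enc_h2[[l + 1]] <- h2
    cc$dims[[l + 1]] <- d
    a <- h2
  }
  u <- a; du <- d
  if (D > 0) for (l in (D - 1):0) {
    dl <- cc$dims[[l + 1]]
    up <- cpp_upsample_fw(u, du, pf, dl)
    cat_ <- cbind(up, cc$enc_h2[[l + 1]])
    r <- relu(cv(cat_, paste0("dec", l, "r"), dl, c(1L, 1L, 1L)))
    h1 <- relu(cv(r, paste0("dec", l, "a"), dl))
    h2 <- relu(cv(h1, paste0("dec", l, "b"), dl))
    cc$dec[[as.character(l)]] <- list(cat = cat_, r = r, h1 = h1, h2 = h2,
                                      du = du)
    u <- h2; du <- dl
  }
  logits <- cv(u, "out", du, c(1L, 1L, 1L))
  prob <- 1 / (1 + exp(-logits))
  if (cache) list(prob = prob, logits = logits, u = u, du = du, cache = cc)
  else prob
}

unet_backward <- function(model, fw, dlogits, dims) {
  p <- model$params
  ksz <- model$kernel; pf <- model$pool; D <- model$depth
  g <- list()
  cc <- fw$cache
  bw <- function(xin, nm, dY, d, k = ksz) {
    r <- cpp_conv_bw(xin, p[[nm]]$W, dY, d, k)
    g[[nm]] <<- list(W = r$dW, b = r$db)
    r$dX
  }
  du <- fw$du
  dU <- bw(fw$u, "out", dlogits, du, c(1L, 1L, 1L))
  if (D > 0) for (l in 0:(D - 1)) {
    dc <- cc$dec[[as.character(l)]]
    dl <- cc$dims[[l + 1]]
    dU <- dU * (dc$h2 > 0)
    dU <- bw(dc$h1, paste0("dec", l, "b"), dU, dl)
    dU <- dU * (dc$h1 > 0)
    dU <- bw(dc$r, paste0("dec", l, "a"), dU, dl)
    dU <- dU * (dc$r > 0)
    dCat <- bw(dc$cat, paste0("dec", l, "r"), dU, dl, c(1L, 1L, 1L))
    cup <- ncol(dCat) - ncol(cc$enc_h2[[l + 1]])
    dSkip <- dCat[, (cup + 1):ncol(dCat), drop = FALSE]
    dUp <- dCat[, 1:cup, drop = FALSE]
    dU <- cpp_upsample_bw(dUp, dc$du, pf, dl)
    # stash skip gradient for the encoder pass
    cc$dec[[as.character(l)]]$dskip <- dSkip
  }
  # encoder, from the bottom level up
  for (l in D:0) {
    d <- cc$dims[[l + 1]]
    dH2 <- dU
    if (l < D) dH2 <- dH2 + cc$dec[[as.character(l)]]$dskip
    dH2 <- dH2 * (cc$enc_h2[[l + 1]] > 0)
    dH1 <- bw(cc$enc_h1[[l + 1]], paste0("enc", l, "b"), dH2, d)
    dH1 <- dH1 * (cc$enc_h1[[l + 1]] > 0)
    dIn <- bw(cc$enc_in[[l + 1]], paste0("enc", l, "a"), dH1, d)
    if (l > 0) dU <- cpp_maxpool_bw(dIn, cc$pools[[l]]$idx,
                                    cc$pools[[l]]$n_in)
  }
  g
}

adam_init <- function(params)
  lapply(params, function(pp) list(mW = pp$W * 0, vW = pp$W * 0,
                                   mb = pp$b * 0, vb = pp$b * 0))

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    st <- state[[nm]]; gr <- grads[[nm]]
    st$mW <- beta1 * st$mW + (1 - beta1) * gr$W
    st$vW <- beta2 * st$vW + (1 - beta2) * gr$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * gr$b
    st$vb <- beta2 * st$vb + (1 - beta2) * gr$b^2
    params[[nm]]$W <- params[[nm]]$W -
      lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b -
      lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# random flip/translation augmentation of paired (input, target) arrays
augment_pair <- function(x, t) {
  if (runif(1) < 0.5) { x <- x[dim(x)[1]:1, , , drop = FALSE]
                        t <- t[dim(t)[1]:1, , , drop = FALSE] }
  if (runif(1) < 0.5) { x <- x[, dim(x)[2]:1, , drop = FALSE]
                        t <- t[, dim(t)[2]:1, , drop = FALSE] }
  sh <- sample(-2:2, 2, replace = TRUE)
  if (any(sh != 0)) {
    shift1 <- function(a) {
      out <- array(0, dim(a))
      d <- dim(a)
      xs <- seq_len(d[1]) - sh[1]; ys <- seq_len(d[2]) - sh[2]
      okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
      out[which(okx), which(oky), ] <- a[xs[okx], ys[oky], , drop = FALSE]
      out
    }
    x <- shift1(x); t <- shift1(t)
  }
  list(x = x, t = t)
}

# the 16 deterministic flip/rotation/scale combinations used for patch
# augmentation: 2 horizontal flips x 2 vertical flips x 2 rotations (0/90
# degrees) x 2 scales (1.0 / 0.9)
augment_16 <- function(x) {
  stopifnot(length(dim(x)) == 2L, dim(x)[1] == dim(x)[2])
  out <- list()
  n <- dim(x)[1]
  for (fh in 0:1) for (fv in 0:1) for (rot in 0:1) for (sc in 0:1) {
    a <- x
    if (fh) a <- a[n:1, , drop = FALSE]
    if (fv) a <- a[, n:1, drop = FALSE]
    if (rot) a <- t(a)[, , drop = FALSE]
    if (sc) {
      s <- 1 / 0.9  # zoom in by 10% about the patch center
      A <- cbind(diag(c(s, s, 1)),
                 c((1 - s) * (n - 1) / 2, (1 - s) * (n - 1) / 2, 0))
      a3 <- cpp_resample_affine(as.numeric(a), c(n, n, 1L), A,
                                c(n, n, 1L), FALSE, 0)
      a <- matrix(a3, n, n)
    }
    out[[length(out) + 1L]] <- a
  }
  out
}

fit_segmenter <- function(model, inputs, targets, cfg) {
  stopifnot(inherits(model, "unet_segmenter"), inherits(cfg, "train_config"))
  if (length(inputs) < 2L) stop("need at least 2 training cases")
  if (length(inputs) != length(targets)) stop("inputs/targets length mismatch")
  as3d <- function(a) { if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L); a }
  inputs <- lapply(inputs, as3d)
  targets <- lapply(targets, as3d)
  if (all(vapply(targets, function(t) all(t == 0), logical(1))))
    warning("all training labels are background")
  set.seed(cfg$seed)
  n <- length(inputs)
  n_val <- floor(cfg$validation_fraction * n)
  idx <- sample.int(n)
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer()
  train_idx <- setdiff(idx, val_idx)
  state <- adam_init(model$params)
  t_step <- 0L
  history <- data.frame()
  case_loss <- function(i) {
    d <- dim(inputs[[i]])
    pr <- unet_forward(model, matrix(as.numeric(inputs[[i]]), ncol = 1), d)
    dice_loss(as.numeric(pr), as.numeric(targets[[i]]))
  }
  for (epoch in seq_len(cfg$epochs)) {
    lr <- schedule_lr(cfg, epoch)
    ord <- sample(train_idx)
    ep_loss <- 0
    for (i in ord) {
      xarr <- inputs[[i]]; tarr <- targets[[i]]
      if (isTRUE(cfg$augment)) {
        au <- augment_pair(xarr, tarr)
        xarr <- au$x; tarr <- au$t
      }
      d <- dim(xarr)
      x <- matrix(as.numeric(xarr), ncol = 1)
      tv <- as.numeric(tarr)
      fw <- unet_forward(model, x, d, cache = TRUE)
      pvec <- as.numeric(fw$prob)
      ep_loss <- ep_loss + dice_loss(pvec, tv)
      dp <- dice_loss_grad(pvec, tv)
      dlogits <- matrix(dp * pvec * (1 - pvec), ncol = 1)
      grads <- unet_backward(model, fw, dlogits, d)
      t_step <- t_step + 1L
      upd <- adam_step(model$params, grads, state, lr, t_step)
      model$params <- upd$params
      state <- upd$state
    }
    val_loss <- if (length(val_idx))
      mean(vapply(val_idx, case_loss, numeric(1))) else NA_real_
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / length(ord),
      val_loss = val_loss))
  }
  model$history <- history
  model
}

#' Predict voxelwise probabilities
#'
#' @param model a trained segmenter (or an [oracle_segmenter()]).
#' @param x input array (2D patch or 3D volume) of normalized intensities.
#' @param ... unused.
#' @return Array of probabilities, same shape as `x`.
#' @export
predict_probabilities <- function(model, x, ...)
  UseMethod("predict_probabilities")

#' @export
predict_probabilities.unet_segmenter <- function(model, x, ...) {
  d <- dim(x)
  if (length(d) == 3L && model$dimensionality == 2L && d[3] > 1L) {
    # 2D model on a slice stack: predict slice by slice
    out <- array(0, d)
    for (k in seq_len(d[3]))
      out[, , k] <- predict_probabilities(model, x[, , k])
    return(out)
  }
  if (length(d) == 2L) d <- c(d, 1L)
  pr <- unet_forward(model, matrix(as.numeric(x), ncol = 1), d)
  array(as.numeric(pr), dim(x))
}

#' Oracle segmenter carrying known truth probabilities
#'
#' Used to run the pipeline with ground truth injected in place of a trained
#' model, isolating the plumbing from the learning.
#'
#' @param prob array of probabilities (typically a binarized truth mask).
#' @return An object of class `oracle_segmenter`.
#' @export
oracle_segmenter <- function(prob) {
  structure(list(prob = prob), class = "oracle_segmenter")
}

#' @export
predict_probabilities.oracle_segmenter <- function(model, x, ...) {
  if (!identical(dim(model$prob), dim(x)))
    stop("oracle probability shape does not match input")
  model$prob
}

#' Save / load a segmenter checkpoint
#'
#' Checkpoints are plain JSON (architecture descriptor, parameters, seed,
#' loss history), portable across platforms.
#'
#' @param model a `unet_segmenter`.
#' @param path file path.
#' @return `path` (writer) or the model (reader).
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "unet_segmenter"))
  obj <- unclass(model)
  obj$params <- lapply(obj$params, function(pp)
    list(W = as.numeric(pp$W), dims = dim(pp$W), b = pp$b))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(pp)
    list(W = matrix(pp$W, pp$dims[1], pp$dims[2]), b = as.numeric(pp$b)))
  structure(list(dimensionality = obj$dimensionality, depth = obj$depth,
                 base_channels = obj$base_channels,
                 in_channels = obj$in_channels, kernel = obj$kernel,
                 pool = obj$pool, seed = obj$seed, params = params,
                 history = obj$history),
            class = "unet_segmenter")
}
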