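#' UNet model configuration
#'
#' Architecture of the fully convolutional 3D detection network. `depth`
#' encoder levels of two 3x3x3 convolutions each (instance norm + leaky ReLU),
#' with 2x max pooling between levels and channel widths
#' `base_channels * 2^level`. The decoder upsamples (nearest neighbor, with
#' skip concatenation) only until the output resolution equals one cell per
#' `stride` input voxels, where a 1x1x1 head emits the 10 prediction
#' channels; with 2 Angstrom voxels and the default `stride = 4` the output
#' cells are 8 Angstrom, matching the pose-codec grid.
#'
#' @param depth Number of encoder levels (default 4).
#' @param base_channels Feature width at the first level (default 16).
#' @param stride Input voxels per output cell; a power of 2, at most
#'   `2^(depth-1)` (default 4).
#' @param norm Use instance normalization (default TRUE).
#' @param lrelu_alpha Negative slope of the leaky ReLU (default 0.1).
#' @return A `unet_config` list.
#' @export
unet_config <- function(depth = 4, base_channels = 16, stride = 4,
                        norm = TRUE, lrelu_alpha = 0.1) {
  stopifnot(depth >= 1, base_channels >= 1, stride >= 1)
  k <- log2(stride)
  if (abs(k - round(k)) > 1e-9 || k > depth - 1)
    stop("`stride` must be a power of 2 no larger than 2^(depth-1)")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 stride = as.integer(stride),
                 n_up = as.integer(depth - 1 - round(k)),
                 norm = isTRUE(norm),
                 lrelu_alpha = lrelu_alpha,
                 out_channels = 10L),
            class = "unet_config")
}

#' Create a detection model with randomly initialized weights
#'
#' @param cfg A [unet_config()].
#' @param seed Integer seed for the He-style weight initialization.
#' @return A `unet_model` (list with `params` and `cfg`).
#' @export
new_detector <- function(cfg = unet_config(), seed = 0) {
  set.seed(seed)
  D <- cfg$depth
  ch <- cfg$base_channels * 2^(0:(D - 1))
  he <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
  conv_pair <- function(cin, cout) list(
    w1 = he(c(3, 3, 3, cin, cout), 27 * cin), b1 = numeric(cout),
    g1 = rep(1, cout), be1 = numeric(cout),
    w2 = he(c(3, 3, 3, cout, cout), 27 * cout), b2 = numeric(cout),
    g2 = rep(1, cout), be2 = numeric(cout))
  enc <- vector("list", D)
  cin <- 1L
  for (d in seq_len(D)) {
    enc[[d]] <- conv_pair(cin, ch[d])
    cin <- ch[d]
  }
  dec <- vector("list", cfg$n_up)
  for (u in seq_len(cfg$n_up)) {
    lvl <- D - u                 # resolution level after this step (1-based)
    cin_u <- ch[lvl + 1] + ch[lvl]
    dec[[u]] <- conv_pair(cin_u, ch[lvl])
  }
  c_last <- if (cfg$n_up > 0) ch[D - cfg$n_up] else ch[D]
  head <- list(w = matrix(stats::rnorm(c_last * cfg$out_channels, 0,
                                       sqrt(1 / c_last)),
                          c_last, cfg$out_channels),
               b = numeric(cfg$out_channels))
  structure(list(params = list(enc = enc, dec = dec, head = head), cfg = cfg),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<unet_model> depth %d, base %d, stride %d, %d parameters\n",
              x$cfg$depth, x$cfg$base_channels, x$cfg$stride, np))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

instnorm_fwd <- function(x, g, be) {
  d <- dim(x)
  n <- prod(d[1:3])
  xm <- matrix(x, n, d[4])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  va <- colMeans(xc^2)
  inv <- 1 / sqrt(va + 1e-5)
  xhat <- sweep(xc, 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, g, `*`), 2, be, `+`)
  list(y = array(y, d), cache = list(xhat = xhat, inv = inv, g = g, d = d))
}

instnorm_bwd <- function(dy, cache) {
  d <- cache$d
  n <- prod(d[1:3])
  dym <- matrix(dy, n, d[4])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$g, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(dxhat - rep(m1, each = n) - cache$xhat * rep(m2, each = n),
              2, cache$inv, `*`)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x, alpha) {
  neg <- x < 0
  y <- x
  y[neg] <- alpha * x[neg]
  list(y = y, neg = neg)
}

lrelu_bwd <- function(dy, neg, alpha) {
  dx <- dy
  dx[neg] <- alpha * dy[neg]
  dx
}

block_fwd <- function(x, pr, cfg, keep = TRUE) {
  a <- cfg$lrelu_alpha
  c1 <- conv3_fwd(x, dim(x), pr$w1, pr$b1)
  if (cfg$norm) { n1 <- instnorm_fwd(c1, pr$g1, pr$be1) } else {
    n1 <- list(y = c1, cache = NULL) }
  r1 <- lrelu_fwd(n1$y, a)
  c2 <- conv3_fwd(r1$y, dim(r1$y), pr$w2, pr$b2)
  if (cfg$norm) { n2 <- instnorm_fwd(c2, pr$g2, pr$be2) } else {
    n2 <- list(y = c2, cache = NULL) }
  r2 <- lrelu_fwd(n2$y, a)
  cache <- if (keep) list(x = x, in1 = n1$cache, neg1 = r1$neg, a1 = r1$y,
                          in2 = n2$cache, neg2 = r2$neg) else NULL
  list(y = r2$y, cache = cache)
}

block_bwd <- function(dy, cache, pr, cfg) {
  a <- cfg$lrelu_alpha
  g <- list()
  d2 <- lrelu_bwd(dy, cache$neg2, a)
  if (cfg$norm) {
    nb <- instnorm_bwd(d2, cache$in2)
    g$g2 <- nb$dgamma; g$be2 <- nb$dbeta
    d2 <- nb$dx
  } else { g$g2 <- 0 * pr$g2; g$be2 <- 0 * pr$be2 }
  cb <- conv3_bwd(cache$a1, dim(cache$a1), pr$w2, d2, length(pr$b2))
  g$w2 <- cb$gw; g$b2 <- cb$gb
  d1 <- lrelu_bwd(cb$gx, cache$neg1, a)
  if (cfg$norm) {
    nb <- instnorm_bwd(d1, cache$in1)
    g$g1 <- nb$dgamma; g$be1 <- nb$dbeta
    d1 <- nb$dx
  } else { g$g1 <- 0 * pr$g1; g$be1 <- 0 * pr$be1 }
  cb <- conv3_bwd(cache$x, dim(cache$x), pr$w1, d1, length(pr$b1))
  g$w1 <- cb$gw; g$b1 <- cb$gb
  list(dx = cb$gx, grads = g)
}

concat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# Full forward pass on an (X, Y, Z, 1) array whose spatial dims are multiples
# of 2^(depth-1). Returns the raw (pre-sigmoid) output and, optionally, the
# caches needed for the backward pass.
unet_forward <- function(params, x, cfg, keep = TRUE) {
  D <- cfg$depth
  skips <- vector("list", D)
  enc_caches <- vector("list", D)
  pool_idx <- vector("list", D)
  h <- x
  for (d in seq_len(D)) {
    bf <- block_fwd(h, params$enc[[d]], cfg, keep)
    skips[[d]] <- bf$y
    enc_caches[[d]] <- bf$cache
    if (d < D) {
      mp <- maxpool3_fwd(bf$y, dim(bf$y))
      h <- mp$y
      pool_idx[[d]] <- if (keep) mp$idx else NULL
    }
  }
  h <- skips[[D]]
  dec_caches <- vector("list", cfg$n_up)
  up_dims <- vector("list", cfg$n_up)
  for (u in seq_len(cfg$n_up)) {
    up_dims[[u]] <- dim(h)
    up <- upsample3_fwd(h, dim(h))
    cat_ <- concat4(up, skips[[D - u]])
    bf <- block_fwd(cat_, params$dec[[u]], cfg, keep)
    h <- bf$y
    dec_caches[[u]] <- bf$cache
  }
  dh <- dim(h)
  n <- prod(dh[1:3])
  hm <- matrix(h, n, dh[4])
  out <- sweep(hm %*% params$head$w, 2, params$head$b, `+`)
  out <- array(out, c(dh[1:3], cfg$out_channels))
  cache <- if (keep) list(skips = skips, enc = enc_caches, pool = pool_idx,
                          dec = dec_caches, up_dims = up_dims, h_last = h)
           else NULL
  list(out = out, cache = cache)
}

# Backward pass: gradient of a scalar loss with respect to all parameters,
# given d loss / d raw output.
unet_backward <- function(params, cfg, cache, dout) {
  D <- cfg$depth
  h <- cache$h_last
  dh <- dim(h)
  n <- prod(dh[1:3])
  dom <- matrix(dout, n, cfg$out_channels)
  hm <- matrix(h, n, dh[4])
  g_head <- list(w = t(hm) %*% dom, b = colSums(dom))
  dhm <- dom %*% t(params$head$w)
  dcur <- array(dhm, dh)

  g_dec <- vector("list", cfg$n_up)
  g_skip <- vector("list", D)
  for (u in rev(seq_len(cfg$n_up))) {
    bb <- block_bwd(dcur, cache$dec[[u]], params$dec[[u]], cfg)
    g_dec[[u]] <- bb$grads
    dcat <- bb$dx
    cu <- dim(dcat)[4] - dim(cache$skips[[D - u]])[4]
    dup <- dcat[, , , seq_len(cu), drop = FALSE]
    dskip <- dcat[, , , cu + seq_len(dim(dcat)[4] - cu), drop = FALSE]
    g_skip[[D - u]] <- dskip
    dcur <- upsample3_bwd(dup, cache$up_dims[[u]])
  }
  if (is.null(g_skip[[D]])) g_skip[[D]] <- dcur else
    g_skip[[D]] <- g_skip[[D]] + dcur

  g_enc <- vector("list", D)
  for (d in rev(seq_len(D))) {
    dy <- g_skip[[d]]
    bb <- block_bwd(dy, cache$enc[[d]], params$enc[[d]], cfg)
    g_enc[[d]] <- bb$grads
    if (d > 1) {
      below <- maxpool3_bwd(cache$pool[[d - 1]], bb$dx,
                            dim(cache$skips[[d - 1]]))
      if (is.null(g_skip[[d - 1]])) g_skip[[d - 1]] <- below
      else g_skip[[d - 1]] <- g_skip[[d - 1]] + below
    }
  }
  list(enc = g_enc, dec = g_dec, head = g_head)
}

#' Predict the 10-channel pose grid for a density map
#'
#' Runs the fully convolutional network on a (normalized) density grid of
#' arbitrary size. The input is zero-padded on the high side to a multiple of
#' `2^depth` voxels, passed through the network, and the prediction is
#' cropped back to `ceiling(extent / stride)` cells per axis. Channels 1
#' (occupancy) and 10 (VHH probability) pass through a sigmoid; the pose
#' channels stay unconstrained.
#'
#' @param model A `unet_model` (see [new_detector()], [train_detector()]).
#' @param grid A [density_grid()] with isotropic voxels, values in `[0, 1]`.
#' @return A prediction [pose_grid()] carrying `cell_size = stride * voxel`
#'   and the input origin.
#' @export
predict_grid <- function(model, grid) {
  stopifnot(inherits(model, "unet_model"), inherits(grid, "density_grid"))
  cfg <- model$cfg
  if (max(grid$voxel) - min(grid$voxel) > 1e-6)
    stop("predict_grid requires isotropic voxels (resample first)")
  d <- dim(grid$values)
  m <- 2^cfg$depth
  if (any(d < m))
    stop(sprintf("input grid too small: need at least %d voxels per axis", m))
  pd <- as.integer(ceiling(d / m) * m)
  x <- array(0, c(pd, 1L))
  x[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), 1] <- grid$values
  fw <- unet_forward(model$params, x, cfg, keep = FALSE)
  out <- fw$out
  nc <- as.integer(ceiling(d / cfg$stride))
  out <- out[seq_len(nc[1]), seq_len(nc[2]), seq_len(nc[3]), , drop = FALSE]
  out[, , , 1] <- sigmoid(out[, , , 1])
  out[, , , 10] <- sigmoid(out[, , , 10])
  geom <- grid_geometry(nc, cell_size = cfg$stride * grid$voxel[1],
                        origin = grid$origin)
  pose_grid(out, geom, kind = "prediction")
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the weights and the architecture
#' configuration, so a trained detector can be reloaded for prediction.
#'
#' @param model A `unet_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `unet_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(list(format = "cryoab_checkpoint_v1",
               params = model$params, cfg = unclass(model$cfg),
               history = model$history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cryoab_checkpoint_v1"))
    stop("not a cryoab checkpoint: ", path)
  m <- structure(list(params = obj$params,
                      cfg = structure(obj$cfg, class = "unet_config")),
                 class = "unet_model")
  m$history <- obj$history
  m
}
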