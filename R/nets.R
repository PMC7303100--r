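#' Architecture hyperparameters
#'
#' Collects the hyperparameters the architecture family leaves open. The
#' structural constants of the densenet trunk (three blocks of two layers,
#' growth rate 10, average pooling between blocks, GAP, linear 3-output
#' regression head) are the defaults; widths, kernels and the path-block
#' downsampling are configurable.
#'
#' @param spatial_kernel odd spatial kernel size in voxels.
#' @param temporal_kernel temporal kernel size for the 4D convolutions
#'   (causal padding keeps the sequence length).
#' @param initial_channels integer 3-vector (c1, c2, c3), output channels of
#'   the three initial (path) convolution layers.
#' @param growth_rate feature maps added by each densely connected layer.
#' @param layers_per_block layers per densenet block.
#' @param n_blocks number of densenet blocks in the trunk.
#' @param pool_factor average-pooling factor between blocks (spatial axes;
#'   the temporal axis is pooled too in 4D trunks while longer than one).
#' @param activation only `"relu"` is implemented.
#' @param use_norm normalization layers; not implemented, must be FALSE.
#' @param aux_outputs add two auxiliary linear heads predicting the two
#'   preceding shifts (used by the temporally regularized loss).
#' @param path_pool number of 2x average-poolings inserted after the first
#'   `path_pool` path-block layers (0 = full-resolution trunk; the desk
#'   profile uses 2 so the trunk runs at 8^3).
#' @param input_norm input preprocessing: `"sequence"` standardizes all
#'   five volumes of a sequence jointly to zero mean and unit variance
#'   (removes absolute-brightness shortcuts while preserving the
#'   between-frame brightness differences that carry axial information),
#'   `"volume"` standardizes each volume separately, `"global"` applies the
#'   fixed affine (x - 0.2) / 0.2, `"none"` feeds raw intensities.
#' @return A `model_config` list.
#' @export
model_config <- function(spatial_kernel = 3L, temporal_kernel = 2L,
                         initial_channels = c(8L, 16L, 32L),
                         growth_rate = 10L, layers_per_block = 2L,
                         n_blocks = 3L, pool_factor = 2L,
                         activation = "relu", use_norm = FALSE,
                         aux_outputs = FALSE, path_pool = 0L,
                         input_norm = c("sequence", "volume", "global", "none")) {
  input_norm <- match.arg(input_norm)
  if (spatial_kernel %% 2 == 0) stop("spatial_kernel must be odd")
  if (length(initial_channels) != 3) stop("initial_channels must have length 3")
  if (activation != "relu") stop("only the 'relu' activation is implemented")
  if (isTRUE(use_norm)) stop("normalization layers are not implemented")
  structure(list(spatial_kernel = as.integer(spatial_kernel),
                 temporal_kernel = as.integer(temporal_kernel),
                 initial_channels = as.integer(initial_channels),
                 growth_rate = as.integer(growth_rate),
                 layers_per_block = as.integer(layers_per_block),
                 n_blocks = as.integer(n_blocks),
                 pool_factor = as.integer(pool_factor),
                 activation = activation, use_norm = FALSE,
                 aux_outputs = isTRUE(aux_outputs),
                 path_pool = as.integer(path_pool),
                 input_norm = input_norm),
            class = "model_config")
}

#' @rdname model_config
#' @details `desk_model_config()` is the reduced-width profile used by the
#'   desk-scale benchmark: narrower paths, growth rate 8, and a trunk running
#'   at 8^3 resolution (`path_pool = 2`), sized so that a full training run
#'   completes in minutes on one CPU core.
#' @export
desk_model_config <- function(aux_outputs = FALSE) {
  model_config(initial_channels = c(4L, 8L, 12L), growth_rate = 8L,
               path_pool = 2L, aux_outputs = aux_outputs)
}

arch_names <- function() {
  c("two_path_3d", "s_two_path_3d", "five_path_3d", "dense4d", "five_path_4d")
}

# frames fed to the path stage, in path order (pairs contiguous for s_two_path)
path_frames <- function(arch) {
  switch(arch,
         two_path_3d   = c(1L, 5L),
         s_two_path_3d = c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L),
         five_path_3d  = 1:5,
         five_path_4d  = 1:5,
         stop("unknown architecture: ", arch))
}

# channels entering the densenet trunk
trunk_in_channels <- function(arch, cfg) {
  c3 <- cfg$initial_channels[3]
  switch(arch,
         two_path_3d   = 2L * c3,
         s_two_path_3d = 2L * c3,
         five_path_3d  = 5L * c3,
         dense4d       = c3,
         five_path_4d  = c3)
}

trunk_is_4d <- function(arch) arch %in% c("dense4d", "five_path_4d")

#' Build one of the five motion-estimation architectures
#'
#' All five models share the same densenet trunk (blocks of densely
#' concatenated conv+ReLU layers joined by average pooling, global average
#' pooling, linear regression head) and differ in the initial processing:
#' \describe{
#'   \item{two_path_3d}{two weight-shared 3D conv paths on the first and last
#'     volume, outputs stacked into the channel dimension.}
#'   \item{s_two_path_3d}{the identical network applied to the four
#'     consecutive volume pairs; the four pairwise predictions are summed.}
#'   \item{five_path_3d}{five weight-shared 3D paths, channel concatenation.}
#'   \item{dense4d}{three initial 4D convolutions on the full
#'     (5, 32, 32, 32) tensor, 4D densenet trunk.}
#'   \item{five_path_4d}{five weight-shared 3D paths whose outputs are
#'     reassembled into a temporal dimension, then a 4D densenet trunk.}
#' }
#' Path weights are shared across paths by construction (one parameter set,
#' applied batch-wise), so mutating a path parameter changes every path.
#'
#' @param arch one of `"two_path_3d"`, `"s_two_path_3d"`, `"five_path_3d"`,
#'   `"dense4d"`, `"five_path_4d"`.
#' @param config a [model_config()].
#' @param seed seed for the (Glorot-uniform) weight initialization.
#' @param precision `"single"` (training default) or `"double"`.
#' @return An object of class `oct_model`.
#' @export
build_model <- function(arch = arch_names(), config = model_config(),
                        seed = 1L, precision = c("single", "double")) {
  arch <- match.arg(arch)
  precision <- match.arg(precision)
  cfg <- config
  k <- cfg$spatial_kernel
  kt_path <- if (arch == "dense4d") cfg$temporal_kernel else 1L
  kt_trunk <- if (trunk_is_4d(arch)) cfg$temporal_kernel else 1L
  ic <- cfg$initial_channels

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  params <- list()
  ch <- c(1L, ic)
  for (l in 1:3) {
    params[[paste0("path", l, "_w")]] <-
      glorot_conv(k, kt_path, ch[l], ch[l + 1])
    params[[paste0("path", l, "_b")]] <- numeric(ch[l + 1])
  }
  c0 <- trunk_in_channels(arch, cfg)
  cur <- c0
  for (bl in seq_len(cfg$n_blocks)) for (ly in seq_len(cfg$layers_per_block)) {
    params[[sprintf("block%d_layer%d_w", bl, ly)]] <-
      glorot_conv(k, kt_trunk, cur, cfg$growth_rate)
    params[[sprintf("block%d_layer%d_b", bl, ly)]] <- numeric(cfg$growth_rate)
    cur <- cur + cfg$growth_rate
  }
  nf <- cur   # GAP feature length
  params$head_w <- glorot_mat(3L, nf)
  params$head_b <- numeric(3)
  if (cfg$aux_outputs) {
    params$head_n1_w <- glorot_mat(3L, nf)
    params$head_n1_b <- numeric(3)
    params$head_n2_w <- glorot_mat(3L, nf)
    params$head_n2_b <- numeric(3)
  }
  structure(list(arch = arch, config = cfg, params = params,
                 n_features = nf, precision = precision,
                 init_seed = as.integer(seed)),
            class = "oct_model")
}

# He-style fan-in scaling, appropriate for the ReLU stacks used throughout
glorot_conv <- function(k, kt, ci, co) {
  n <- k^3 * kt
  sd <- sqrt(2 / (n * ci))
  array(stats::rnorm(n * ci * co, 0, sd), c(k, k, k, kt, ci, co))
}

glorot_mat <- function(nout, nin) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
}

#' @export
print.oct_model <- function(x, ...) {
  cat(sprintf("<oct_model> %s: %d parameters, %d GAP features%s\n",
              x$arch, count_parameters(x), x$n_features,
              if (x$config$aux_outputs) ", auxiliary heads" else ""))
  invisible(x)
}

#' Count independent trainable parameters
#'
#' Weight-shared paths are stored once and therefore counted once.
#'
#' @param model an `oct_model`, or any list of numeric parameter arrays.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "oct_model")) model$params else model
  if (length(params) == 0) return(0L)
  sum(vapply(params, length, integer(1)))
}

# ---------------------------------------------------------------------------
# forward / backward
# ---------------------------------------------------------------------------

# path stage: three conv+ReLU layers, optional 2x pooling after the first
# cfg$path_pool layers. x: (X,Y,Z,T,C,B). Returns output and (optionally)
# the cache needed by the backward pass.
path_stage_fwd <- function(prm, x, cfg, single, keep = FALSE) {
  caches <- vector("list", 3)
  for (l in 1:3) {
    w <- prm[[paste0("path", l, "_w")]]
    b <- prm[[paste0("path", l, "_b")]]
    y <- conv_fwd_(x, w, b, TRUE, single)
    a <- relu_fwd_(y)
    pooled <- l <= cfg$path_pool
    if (keep) caches[[l]] <- list(x = x, a = a,
                                  adim = dim(a), pooled = pooled)
    x <- if (pooled) pool_fwd_(a, cfg$pool_factor, FALSE) else a
  }
  list(out = x, caches = caches)
}

path_stage_bwd <- function(prm, caches, d, cfg, single, grads) {
  for (l in 3:1) {
    cc <- caches[[l]]
    if (cc$pooled) d <- pool_bwd_(d, cc$adim, cfg$pool_factor, FALSE)
    d <- relu_bwd_(d, cc$a)
    g <- conv_bwd_(cc$x, prm[[paste0("path", l, "_w")]], d,
                   need_dx = l > 1, TRUE, single)
    grads[[paste0("path", l, "_w")]] <- grads[[paste0("path", l, "_w")]] + g$dw
    grads[[paste0("path", l, "_b")]] <- grads[[paste0("path", l, "_b")]] + g$db
    if (l > 1) d <- g$dx
  }
  grads
}

dense_block_fwd <- function(prm, x, bl, cfg, single, keep = FALSE) {
  caches <- vector("list", cfg$layers_per_block)
  for (ly in seq_len(cfg$layers_per_block)) {
    w <- prm[[sprintf("block%d_layer%d_w", bl, ly)]]
    b <- prm[[sprintf("block%d_layer%d_b", bl, ly)]]
    y <- conv_fwd_(x, w, b, TRUE, single)
    a <- relu_fwd_(y)
    if (keep) caches[[ly]] <- list(x = x, a = a)
    x <- concat_c_(x, a)
  }
  list(out = x, caches = caches)
}

dense_block_bwd <- function(prm, caches, d, bl, cfg, single, grads) {
  for (ly in rev(seq_len(cfg$layers_per_block))) {
    cc <- caches[[ly]]
    cin <- dim(cc$x)[5]
    g_ch <- dim(cc$a)[5]
    dh <- d[, , , , cin + seq_len(g_ch), , drop = FALSE]
    d  <- d[, , , , seq_len(cin), , drop = FALSE]
    dh <- relu_bwd_(dh, cc$a)
    key <- sprintf("block%d_layer%d", bl, ly)
    g <- conv_bwd_(cc$x, prm[[paste0(key, "_w")]], dh, TRUE, TRUE, single)
    grads[[paste0(key, "_w")]] <- grads[[paste0(key, "_w")]] + g$dw
    grads[[paste0(key, "_b")]] <- grads[[paste0(key, "_b")]] + g$db
    d <- d + g$dx
  }
  list(d = d, grads = grads)
}

trunk_fwd <- function(prm, x, cfg, dim4d, single, keep = FALSE) {
  blocks <- vector("list", cfg$n_blocks)
  pools <- vector("list", cfg$n_blocks)
  for (bl in seq_len(cfg$n_blocks)) {
    db <- dense_block_fwd(prm, x, bl, cfg, single, keep)
    x <- db$out
    blocks[[bl]] <- db$caches
    if (bl < cfg$n_blocks) {
      pt <- dim4d && dim(x)[4] > 1
      if (keep) pools[[bl]] <- list(xdim = dim(x), pool_time = pt)
      x <- pool_fwd_(x, cfg$pool_factor, pt)
    }
  }
  feats <- gap_fwd_(x)
  list(features = feats, gap_dim = dim(x), blocks = blocks, pools = pools)
}

trunk_bwd <- function(prm, tc, dF, cfg, single, grads) {
  d <- gap_bwd_(dF, tc$gap_dim)
  for (bl in rev(seq_len(cfg$n_blocks))) {
    if (bl < cfg$n_blocks) {
      pc <- tc$pools[[bl]]
      d <- pool_bwd_(d, pc$xdim, cfg$pool_factor, pc$pool_time)
    }
    res <- dense_block_bwd(prm, tc$blocks[[bl]], d, bl, cfg, single, grads)
    d <- res$d
    grads <- res$grads
  }
  list(d = d, grads = grads)
}

zero_grads <- function(params) lapply(params, function(p) p * 0)

# full forward on a batch tensor X: (32,32,32,5,1,B)
net_forward <- function(model, X, keep = FALSE) {
  cfg <- model$config
  prm <- model$params
  arch <- model$arch
  single <- model$precision == "single"
  dX <- dim(X)
  B <- dX[6]

  if (identical(cfg$input_norm, "global")) {
    X <- (X - 0.2) / 0.2
  } else if (cfg$input_norm %in% c("volume", "sequence")) {
    # "volume": standardize each time step independently;
    # "sequence": joint statistics over a sample's five volumes, preserving
    # relative brightness between frames
    ncol_ <- if (cfg$input_norm == "volume") prod(dX[4:6]) else prod(dX[5:6])
    m <- matrix(X, length(X) / ncol_, ncol_)
    mu <- colMeans(m)
    sdv <- sqrt(pmax(colMeans(m^2) - mu^2, 1e-12))
    X <- array(sweep(sweep(m, 2, mu, `-`), 2, sdv, `/`), dX)
  }

  if (arch == "dense4d") {
    ps <- path_stage_fwd(prm, X, cfg, single, keep)
    tin <- ps$out
    reass <- NULL
  } else {
    idx <- path_frames(arch)
    P <- length(idx)
    Xp <- X[, , , idx, , , drop = FALSE]
    dim(Xp) <- c(dX[1:3], 1L, 1L, P * B)
    ps <- path_stage_fwd(prm, Xp, cfg, single, keep)
    po <- ps$out                       # (xs, ys, zs, 1, c3, P*B)
    dp <- dim(po)
    c3 <- dp[5]
    if (arch == "five_path_4d") {
      dim(po) <- c(dp[1:3], c3, 5L, B)
      po <- aperm(po, c(1, 2, 3, 5, 4, 6))   # -> (xs, ys, zs, 5, c3, B)
      tin <- po
      reass <- list(P = P, c3 = c3, dp = dp)
    } else if (arch == "s_two_path_3d") {
      tin <- po
      dim(tin) <- c(dp[1:3], 1L, 2L * c3, 4L * B)
      reass <- list(P = P, c3 = c3, dp = dp)
    } else {
      tin <- po
      dim(tin) <- c(dp[1:3], 1L, P * c3, B)
      reass <- list(P = P, c3 = c3, dp = dp)
    }
  }

  tr <- trunk_fwd(prm, tin, cfg, trunk_is_4d(arch), single, keep)
  feats <- tr$features                 # nf x (B or 4B)

  lin <- function(wk, bk) prm[[wk]] %*% feats + as.vector(prm[[bk]])
  y <- lin("head_w", "head_b")
  if (arch == "s_two_path_3d") {
    y4 <- array(y, c(3, 4, B))
    y <- apply(y4, c(1, 3), sum)       # sum of pairwise estimates
    dim(y) <- c(3, B)
  }
  pred <- list(y_tn = y)
  if (cfg$aux_outputs) {
    y1 <- lin("head_n1_w", "head_n1_b")
    y2 <- lin("head_n2_w", "head_n2_b")
    if (arch == "s_two_path_3d") {
      y1 <- matrix(apply(array(y1, c(3, 4, B)), c(1, 3), sum), 3, B)
      y2 <- matrix(apply(array(y2, c(3, 4, B)), c(1, 3), sum), 3, B)
    }
    pred$y_tn1 <- y1
    pred$y_tn2 <- y2
  }
  cache <- if (keep) list(ps = ps, tr = tr, feats = feats, reass = reass,
                          B = B, tin_dim = dim(tin)) else NULL
  list(pred = pred, cache = cache)
}

# backward from prediction gradients (same shapes as pred entries)
net_backward <- function(model, cache, dpred) {
  cfg <- model$config
  prm <- model$params
  arch <- model$arch
  single <- model$precision == "single"
  B <- cache$B
  feats <- cache$feats
  nb <- ncol(feats)                    # B, or 4B for s_two_path_3d

  expand_ <- function(dy) {            # sample gradient -> per-pair columns
    if (arch == "s_two_path_3d") {
      matrix(dy[, rep(seq_len(B), each = 4)], 3, nb)
    } else dy
  }

  grads <- zero_grads(prm)
  heads <- list(c("head_w", "head_b", "y_tn"))
  if (cfg$aux_outputs)
    heads <- c(heads, list(c("head_n1_w", "head_n1_b", "y_tn1")),
               list(c("head_n2_w", "head_n2_b", "y_tn2")))
  dF <- matrix(0, nrow(feats), nb)
  for (h in heads) {
    dy <- dpred[[h[3]]]
    if (is.null(dy)) next
    dy <- expand_(dy)
    grads[[h[1]]] <- grads[[h[1]]] + dy %*% t(feats)
    grads[[h[2]]] <- grads[[h[2]]] + rowSums(dy)
    dF <- dF + t(prm[[h[1]]]) %*% dy
  }

  tb <- trunk_bwd(prm, cache$tr, dF, cfg, single, grads)
  d <- tb$d
  grads <- tb$grads

  if (arch == "dense4d") {
    grads <- path_stage_bwd(prm, cache$ps$caches, d, cfg, single, grads)
  } else {
    re <- cache$reass
    dp <- re$dp
    if (arch == "five_path_4d") {
      d <- aperm(d, c(1, 2, 3, 5, 4, 6))       # back to (xs,ys,zs,c3,5,B)
      dim(d) <- dp
    } else {
      dim(d) <- dp
    }
    grads <- path_stage_bwd(prm, cache$ps$caches, d, cfg, single, grads)
  }
  grads
}

#' Predict the relative translation for a motion sequence
#'
#' Runs a model on one sequence and returns the predicted relative
#' translation between the initial and the final volume, in mm. The
#' two-path model consumes the first and last volume; all other
#' architectures consume all five. Auxiliary predictions of the two
#' preceding shifts are populated iff the model was built with
#' `aux_outputs = TRUE`.
#'
#' @param model an `oct_model`.
#' @param seq an `oct_sequence`, or a 32 x 32 x 32 x 5 array.
#' @return An `oct_prediction`: `y_tn` (3-vector, mm), and `y_tn1`, `y_tn2`
#'   when auxiliary outputs are enabled.
#' @export
forward <- function(model, seq) {
  vols <- if (inherits(seq, "oct_sequence")) seq$volumes else seq
  d <- dim(vols)
  if (is.null(d) || length(d) != 4 || !all(d == c(fov_voxels(), 5)))
    stop("input must be a 32 x 32 x 32 x 5 volume sequence (x, y, z, time)")
  X <- vols
  dim(X) <- c(d[1:3], 5L, 1L, 1L)
  out <- net_forward(model, X, keep = FALSE)$pred
  pred <- list(y_tn = as.numeric(out$y_tn))
  if (model$config$aux_outputs) {
    pred$y_tn1 <- as.numeric(out$y_tn1)
    pred$y_tn2 <- as.numeric(out$y_tn2)
  }
  structure(pred, class = "oct_prediction")
}

#' @export
print.oct_prediction <- function(x, ...) {
  cat(sprintf("<oct_prediction> y_tn = (%.4f, %.4f, %.4f) mm\n",
              x$y_tn[1], x$y_tn[2], x$y_tn[3]))
  invisible(x)
}

# batched prediction over dataset indices; returns n x 3 matrix (mm)
predict_batch <- function(model, dataset, idx = seq_along(dataset$sequences),
                          microbatch = 25L, augment = NULL) {
  n <- length(idx)
  out <- matrix(0, n, 3)
  pos <- 1L
  while (pos <= n) {
    rows <- pos:min(n, pos + microbatch - 1L)
    X <- assemble_batch(dataset, idx[rows], augment)
    out[rows, ] <- t(net_forward(model, X, keep = FALSE)$pred$y_tn)
    pos <- pos + microbatch
  }
  out
}

# stack sequences into the engine batch tensor (32,32,32,5,1,B)
assemble_batch <- function(dataset, idx, augment = NULL) {
  B <- length(idx)
  X <- array(0, c(fov_voxels(), 5L, 1L, B))
  for (j in seq_len(B)) {
    s <- dataset$sequences[[idx[j]]]
    if (!is.null(augment)) s <- augment(s)
    X[, , , , 1L, j] <- s$volumes
  }
  X
}
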