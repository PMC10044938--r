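#' Network configuration
#'
#' Architecture hyperparameters of the scoring network. The defaults give a
#' 39-convolution network: 3 feature-extraction BCMs condensing the
#' 146-channel input to \code{feature_channels} maps, \code{num_levels}
#' encoder levels (a dense block plus a transition down each), a bottleneck
#' dense block, \code{num_levels} decoder levels (transition up, residual
#' skip-add from the encoder, dense block), and a 1x1 projection head
#' followed by symmetrization.
#'
#' @param feature_channels channels of the condensed feature map (default 16)
#' @param dcm_layers BCM layers per dense block
#' @param growth channels added by each dense-block layer
#' @param num_levels encoder/decoder pyramid depth
#' @param kernel_size convolution kernel (odd)
#' @param downsample_factor spatial shrink per level (2 = 2x2 max pool)
#' @param max_length longest admissible sequence; longer inputs are refused
#' @return list of class \code{network_config}; \code{pad_multiple} is
#'   \code{downsample_factor^num_levels}
#' @export
network_config <- function(feature_channels = 16L, dcm_layers = 3L,
                           growth = 16L, num_levels = 4L, kernel_size = 3L,
                           downsample_factor = 2L, max_length = 720L) {
  stopifnot(feature_channels >= 1L, dcm_layers >= 1L, growth >= 1L,
            num_levels >= 1L, kernel_size >= 1L, kernel_size %% 2L == 1L,
            downsample_factor >= 2L, max_length >= 1L)
  structure(list(feature_channels = as.integer(feature_channels),
                 dcm_layers = as.integer(dcm_layers),
                 growth = as.integer(growth),
                 num_levels = as.integer(num_levels),
                 kernel_size = as.integer(kernel_size),
                 downsample_factor = as.integer(downsample_factor),
                 max_length = as.integer(max_length),
                 pad_multiple = as.integer(downsample_factor^num_levels)),
            class = "network_config")
}

#' Read / write a network configuration file
#'
#' YAML file whose keys mirror \code{\link{network_config}} fields exactly.
#'
#' @param path YAML file
#' @return a \code{network_config}
#' @export
read_network_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[names(vals) != "pad_multiple"]
  do.call(network_config, vals)
}

#' @rdname read_network_config
#' @param cfg a \code{network_config}
#' @export
write_network_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ---- block parameter constructors -----------------------------------------

#' Basic convolution module (BCM) parameters
#'
#' Convolution + batch normalization + ReLU, the basic processing unit of
#' the network.
#'
#' @param in_channels,out_channels feature-map depths
#' @param kernel_size odd kernel size (1 gives a pointwise conv)
#' @return BCM parameter list
#' @export
bcm_init <- function(in_channels, out_channels, kernel_size = 3L) {
  list(conv = .conv_init(kernel_size, in_channels, out_channels),
       bn = .bn_init(out_channels))
}

#' Run a BCM forward
#'
#' Spatial size is preserved (same padding); all outputs are non-negative
#' (ReLU); output depth equals the BCM's configured out-channels.
#'
#' @param x input array (H, W, C)
#' @param params from \code{\link{bcm_init}}
#' @param training use batch statistics (and update running statistics)
#'   instead of running statistics
#' @return output array (H, W, out_channels)
#' @export
bcm_forward <- function(x, params, training = FALSE) {
  .bcm_fwd(params, x, training, keep = FALSE)$out
}

.bcm_fwd <- function(p, x, training, keep) {
  co <- .conv_forward(x, p$conv)
  bn <- .bn_forward(co, p$bn, training, keep)
  out <- pmax(bn$out, 0)
  cache <- if (keep) list(x = x, bn_cache = bn$cache, mask = bn$out > 0) else NULL
  list(out = out, p = list(conv = p$conv, bn = bn$p), cache = cache)
}

.bcm_bwd <- function(p, cache, dout) {
  dbn <- dout * cache$mask
  bnb <- .bn_backward(p$bn, cache$bn_cache, dbn)
  cb <- .conv_backward(cache$x, p$conv, bnb$dx)
  list(dx = cb$dx,
       g = list(conv = list(w = cb$dw, b = cb$db),
                bn = list(gamma = bnb$dgamma, beta = bnb$dbeta)))
}

#' Dense connected module (DCM) parameters
#'
#' A stack of BCMs where each layer receives the concatenation of the block
#' input and all preceding layer outputs.
#'
#' @param in_channels block input depth
#' @param n_layers number of BCM layers
#' @param growth channels produced by each layer
#' @param kernel_size convolution kernel
#' @return DCM parameter list
#' @export
dcm_init <- function(in_channels, n_layers, growth, kernel_size = 3L) {
  layers <- lapply(seq_len(n_layers), function(l)
    bcm_init(in_channels + (l - 1L) * growth, growth, kernel_size))
  names(layers) <- paste0("l", seq_len(n_layers))
  list(layers = layers, in_channels = as.integer(in_channels),
       growth = as.integer(growth))
}

#' Run a DCM forward
#'
#' With \code{include_input} (the encoder side) the output concatenates the
#' block input with every layer's new feature maps, so output depth is
#' \code{in + n_layers * growth}; without it (decoder side) only the new
#' maps are returned, depth \code{n_layers * growth}.
#'
#' @param x input array (H, W, in_channels)
#' @param params from \code{\link{dcm_init}}
#' @param include_input concatenate the input into the output
#' @param training batch-statistics mode
#' @return output array
#' @export
dcm_forward <- function(x, params, include_input = TRUE, training = FALSE) {
  .dcm_fwd(params, x, include_input, training, keep = FALSE)$out
}

.dcm_fwd <- function(p, x, include_input, training, keep) {
  cur <- x
  np <- p
  caches <- vector("list", length(p$layers))
  for (l in seq_along(p$layers)) {
    r <- .bcm_fwd(p$layers[[l]], cur, training, keep)
    np$layers[[l]] <- r$p
    caches[[l]] <- r$cache
    cur <- .cat3(cur, r$out)
  }
  cin <- dim(x)[3]
  out <- if (include_input) cur
         else .slice_channels(cur, cin + 1L, dim(cur)[3])
  list(out = out, p = np,
       cache = if (keep) list(layers = caches, cin = cin) else NULL)
}

.dcm_bwd <- function(p, cache, dout, include_input) {
  n <- length(p$layers)
  g <- p$growth
  cin <- cache$cin
  if (include_input) {
    dx_acc <- .slice_channels(dout, 1L, cin)
    douts <- lapply(seq_len(n), function(l)
      .slice_channels(dout, cin + (l - 1L) * g + 1L, cin + l * g))
  } else {
    dims <- dim(cache$layers[[1]]$x)
    dx_acc <- array(0, c(dims[1], dims[2], cin))
    douts <- lapply(seq_len(n), function(l)
      .slice_channels(dout, (l - 1L) * g + 1L, l * g))
  }
  grads <- list(layers = vector("list", n))
  names(grads$layers) <- names(p$layers)
  for (l in rev(seq_len(n))) {
    r <- .bcm_bwd(p$layers[[l]], cache$layers[[l]], douts[[l]])
    grads$layers[[l]] <- r$g
    dx_acc <- dx_acc + .slice_channels(r$dx, 1L, cin)
    if (l > 1L) for (m in seq_len(l - 1L)) {
      douts[[m]] <- douts[[m]] +
        .slice_channels(r$dx, cin + (m - 1L) * g + 1L, cin + m * g)
    }
  }
  list(dx = dx_acc, g = grads)
}

#' Transition down: pointwise BCM then 2x2 max pooling
#'
#' Halves the spatial size; depth is preserved by the 1x1 BCM (the
#' following dense block deepens the pathway).
#'
#' @param x input array with even spatial size
#' @param params a \code{\link{bcm_init}} with kernel 1
#' @param training batch-statistics mode
#' @return array of half spatial size
#' @export
transition_down <- function(x, params, training = FALSE) {
  .td_fwd(params, x, training, keep = FALSE)$out
}

.td_fwd <- function(p, x, training, keep) {
  r <- .bcm_fwd(p, x, training, keep)
  mp <- .maxpool_forward(r$out, keep)
  list(out = mp$out, p = r$p,
       cache = if (keep) list(bcm = r$cache, mp = mp$cache) else NULL)
}

.td_bwd <- function(p, cache, dout) {
  dup <- .maxpool_backward(cache$mp, dout)
  .bcm_bwd(p, cache$bcm, dup)
}

#' Transition up: nearest-neighbour 2x upsampling then BCM
#'
#' Doubles the spatial size and sets the depth to the BCM's out-channels
#' (chosen to match the encoder map it is added to).
#'
#' @param x input array
#' @param params a \code{\link{bcm_init}}
#' @param training batch-statistics mode
#' @return array of doubled spatial size
#' @export
transition_up <- function(x, params, training = FALSE) {
  .tu_fwd(params, x, training, keep = FALSE)$out
}

.tu_fwd <- function(p, x, training, keep) {
  up <- .upsample_forward(x)
  r <- .bcm_fwd(p, up, training, keep)
  list(out = r$out, p = r$p, cache = r$cache)
}

.tu_bwd <- function(p, cache, dout) {
  r <- .bcm_bwd(p, cache, dout)
  list(dx = .upsample_backward(r$dx), g = r$g)
}

#' Residual skip-add of decoder and encoder maps
#'
#' Elementwise sum; both maps must agree in spatial size and depth, anything
#' else is an architecture wiring error.
#'
#' @param decoder_map,encoder_map arrays of identical shape
#' @return their elementwise sum
#' @export
residual_skip_add <- function(decoder_map, encoder_map) {
  if (!identical(dim(decoder_map), dim(encoder_map)))
    stop(sprintf("skip-add wiring error: decoder map %s vs encoder map %s",
                 paste(dim(decoder_map), collapse = "x"),
                 paste(dim(encoder_map), collapse = "x")))
  decoder_map + encoder_map
}

#' Symmetrize a raw map into a score map
#'
#' The raw L x L map is added to its transpose and batch-normalized; since
#' the normalization is elementwise-uniform, the result stays symmetric.
#' With the default (fresh) normalization parameters in inference mode the
#' output is exactly \code{raw + t(raw)} up to the unit-variance scaling.
#'
#' @param raw square matrix (or (L, L, 1) array)
#' @param params single-channel batch-norm parameters (default fresh)
#' @param training batch-statistics mode
#' @return symmetric L x L score matrix
#' @export
symmetrize <- function(raw, params = NULL, training = FALSE) {
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  if (dim(raw)[1] != dim(raw)[2]) stop("raw map must be square")
  if (is.null(params)) params <- .bn_init(1L)
  y <- raw + aperm(raw, c(2L, 1L, 3L))
  bn <- .bn_forward(y, params, training, keep = FALSE)
  matrix(bn$out, dim(raw)[1], dim(raw)[2])
}

# ---- full network ---------------------------------------------------------

#' Initialize a scoring network
#'
#' He-initialized weights; deterministic in the seed. The returned model
#' carries its \code{\link{network_config}} so checkpoints are
#' self-describing.
#'
#' @param cfg a \code{\link{network_config}}
#' @param seed integer seed for weight initialization
#' @return object of class \code{rna_score_network}
#' @export
init_network <- function(cfg = network_config(), seed = 1L) {
  .with_local_seed(seed, {
    f <- cfg$feature_channels; g <- cfg$growth; n <- cfg$dcm_layers
    k <- cfg$kernel_size; nl <- cfg$num_levels
    params <- list()
    params$fe <- list(b1 = bcm_init(146L, f, k),
                      b2 = bcm_init(f, f, k),
                      b3 = bcm_init(f, f, k))
    enc <- list(); td <- list(); depths <- integer(nl)
    d <- f
    for (l in seq_len(nl)) {
      enc[[l]] <- dcm_init(d, n, g, k)
      depths[l] <- d + n * g
      td[[l]] <- bcm_init(depths[l], depths[l], 1L)
      d <- depths[l]
    }
    names(enc) <- names(td) <- paste0("lev", seq_len(nl))
    params$enc <- enc
    params$td <- td
    params$bottleneck <- dcm_init(d, n, g, k)
    tu <- list(); dec <- list()
    prev <- n * g
    for (l in rev(seq_len(nl))) {
      tu[[paste0("lev", l)]] <- bcm_init(prev, depths[l], k)
      dec[[paste0("lev", l)]] <- dcm_init(depths[l], n, g, k)
      prev <- n * g
    }
    params$tu <- tu
    params$dec <- dec
    params$head <- list(conv = .conv_init(1L, n * g, 1L), bn = .bn_init(1L))
    structure(list(cfg = cfg, params = params, enc_depths = depths),
              class = "rna_score_network")
  })
}

#' @export
print.rna_score_network <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<rna_score_network> %d feature channels, %d levels, ",
                     "%d-layer DCMs, growth %d, max length %d\n"),
              cfg$feature_channels, cfg$num_levels, cfg$dcm_layers,
              cfg$growth, cfg$max_length))
  invisible(x)
}

# full forward pass; keep=TRUE retains every cache needed for backprop and
# returns the (possibly updated) model alongside the padded score map
.net_apply <- function(model, conf, training = FALSE, keep = FALSE) {
  cfg <- model$cfg
  L <- dim(conf)[1]
  if (L > cfg$max_length)
    stop(sprintf("sequence length %d exceeds the configured maximum %d; over-length sequences are not scored",
                 L, cfg$max_length))
  pm <- cfg$pad_multiple
  Lp <- as.integer(ceiling(L / pm) * pm)
  if (Lp != L) {
    xp <- array(0, c(Lp, Lp, dim(conf)[3]))
    xp[seq_len(L), seq_len(L), ] <- conf
  } else xp <- conf
  p <- model$params
  caches <- list()
  # feature extraction
  x <- xp
  caches$fe <- vector("list", 3L)
  for (b in 1:3) {
    r <- .bcm_fwd(p$fe[[b]], x, training, keep)
    p$fe[[b]] <- r$p
    caches$fe[[b]] <- r$cache
    x <- r$out
  }
  # encoder
  nl <- cfg$num_levels
  skips <- vector("list", nl)
  caches$enc <- caches$td <- vector("list", nl)
  for (l in seq_len(nl)) {
    r <- .dcm_fwd(p$enc[[l]], x, include_input = TRUE, training, keep)
    p$enc[[l]] <- r$p
    caches$enc[[l]] <- r$cache
    skips[[l]] <- r$out
    r2 <- .td_fwd(p$td[[l]], r$out, training, keep)
    p$td[[l]] <- r2$p
    caches$td[[l]] <- r2$cache
    x <- r2$out
  }
  r <- .dcm_fwd(p$bottleneck, x, include_input = FALSE, training, keep)
  p$bottleneck <- r$p
  caches$bottleneck <- r$cache
  x <- r$out
  # decoder
  caches$tu <- caches$dec <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    key <- paste0("lev", l)
    r <- .tu_fwd(p$tu[[key]], x, training, keep)
    p$tu[[key]] <- r$p
    caches$tu[[l]] <- r$cache
    x <- residual_skip_add(r$out, skips[[l]])
    skips[[l]] <- NULL
    r2 <- .dcm_fwd(p$dec[[key]], x, include_input = FALSE, training, keep)
    p$dec[[key]] <- r2$p
    caches$dec[[l]] <- r2$cache
    x <- r2$out
  }
  # head: pointwise projection, add transpose, batch-normalize
  raw <- .conv_forward(x, p$head$conv)
  if (keep) caches$head_in <- x
  y <- raw + aperm(raw, c(2L, 1L, 3L))
  bn <- .bn_forward(y, p$head$bn, training, keep)
  p$head$bn <- bn$p
  caches$head_bn <- bn$cache
  S <- matrix(bn$out, Lp, Lp)[seq_len(L), seq_len(L), drop = FALSE]
  model$params <- p
  list(S = S, model = model, caches = if (keep) caches else NULL,
       L = L, Lp = Lp)
}

# backward pass mirroring .net_apply; dS is the gradient on the CROPPED
# L x L score map; returns a gradient tree shaped like model$params
.net_backward <- function(model, fw, dS) {
  p <- model$params
  cfg <- model$cfg
  caches <- fw$caches
  L <- fw$L; Lp <- fw$Lp
  dSp <- matrix(0, Lp, Lp)
  dSp[seq_len(L), seq_len(L)] <- dS
  g <- list()
  dy <- array(dSp, c(Lp, Lp, 1L))
  bnb <- .bn_backward(p$head$bn, caches$head_bn, dy)
  draw <- bnb$dx + aperm(bnb$dx, c(2L, 1L, 3L))
  cb <- .conv_backward(caches$head_in, p$head$conv, draw)
  g$head <- list(conv = list(w = cb$dw, b = cb$db),
                 bn = list(gamma = bnb$dgamma, beta = bnb$dbeta))
  dx <- cb$dx
  nl <- cfg$num_levels
  g$dec <- g$tu <- list()
  g$enc <- g$td <- vector("list", nl)
  dskips <- vector("list", nl)
  for (l in seq_len(nl)) {
    key <- paste0("lev", l)
    r <- .dcm_bwd(p$dec[[key]], caches$dec[[l]], dx, include_input = FALSE)
    g$dec[[key]] <- r$g
    # skip-add: gradient flows unchanged to both the transition-up output
    # and the stored encoder map
    dskips[[l]] <- r$dx
    r2 <- .tu_bwd(p$tu[[key]], caches$tu[[l]], r$dx)
    g$tu[[key]] <- r2$g
    dx <- r2$dx
  }
  r <- .dcm_bwd(p$bottleneck, caches$bottleneck, dx, include_input = FALSE)
  g$bottleneck <- r$g
  dx <- r$dx
  for (l in rev(seq_len(nl))) {
    r2 <- .td_bwd(p$td[[l]], caches$td[[l]], dx)
    dskip <- r2$dx + dskips[[l]]
    r <- .dcm_bwd(p$enc[[l]], caches$enc[[l]], dskip, include_input = TRUE)
    g$enc[[l]] <- r$g
    g$td[[l]] <- r2$g
    dx <- r$dx
  }
  names(g$enc) <- names(g$td) <- paste0("lev", seq_len(nl))
  g$fe <- vector("list", 3L)
  for (b in 3:1) {
    r <- .bcm_bwd(p$fe[[b]], caches$fe[[b]], dx)
    g$fe[[b]] <- r$g
    dx <- r$dx
  }
  names(g$fe) <- c("b1", "b2", "b3")
  attr(g, "d_input") <- dx
  g
}

#' Full network forward pass
#'
#' Pads the input conformation to a multiple of the pyramid's pad multiple,
#' runs feature extraction, encoder, bottleneck, decoder and the
#' symmetrizing head, and crops back to L x L. The output is symmetric
#' within floating tolerance for any weights.
#'
#' @param model an \code{\link{init_network}} model
#' @param conf input conformation from
#'   \code{\link{build_input_conformation}}
#' @param training batch-statistics mode (used by the training harness)
#' @return symmetric L x L score matrix
#' @export
network_forward <- function(model, conf, training = FALSE) {
  .net_apply(model, conf, training = training, keep = FALSE)$S
}

#' Score a sequence
#'
#' Encodes the sequence and runs the network in inference mode.
#'
#' @param model an \code{\link{init_network}} model
#' @param seq an \code{\link{rna_sequence}}
#' @return symmetric L x L score matrix
#' @export
predict_scores <- function(model, seq) {
  network_forward(model, build_input_conformation(seq))
}

#' Predict the structure of a sequence end-to-end
#'
#' \code{\link{predict_scores}} followed by \code{\link{predict_structure}}.
#'
#' @param model an \code{\link{init_network}} model
#' @param seq an \code{\link{rna_sequence}}
#' @param solver_cfg a \code{\link{solver_config}}
#' @return a \code{\link{structure_record}} of the prediction
#' @export
predict_record <- function(model, seq, solver_cfg = solver_config()) {
  S <- predict_scores(model, seq)
  P <- predict_structure(seq, S, solver_cfg)
  structure_record(seq, contact_pairs(P), id = seq$id)
}

#' Save / load a model checkpoint
#'
#' Weights and configuration are serialized together with a format version
#' tag so checkpoints are portable across sessions.
#'
#' @param model an \code{rna_score_network}
#' @param path checkpoint file (RDS)
#' @return invisibly, the path
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "rnafoldnet-checkpoint", version = 1L,
               cfg = unclass(model$cfg), params = model$params,
               enc_depths = model$enc_depths), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return \code{load_checkpoint}: the restored model
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "rnafoldnet-checkpoint"))
    stop(sprintf("'%s' is not a checkpoint file", path))
  cfg <- do.call(network_config,
                 x$cfg[setdiff(names(x$cfg), "pad_multiple")])
  structure(list(cfg = cfg, params = x$params, enc_depths = x$enc_depths),
            class = "rna_score_network")
}
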