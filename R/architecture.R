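# Model assembly: ResNet-style bottleneck backbone, optional SE attention,
# second-order pooling head and adaptive gates, plus reference builders
# (canonical ResNet50 and VGG16) used for exact parameter counting.

# ---- bottleneck residual block ----------------------------------------------

nn_bottleneck <- function(c_in, c_mid, c_out, stride = 1) {
  needs_proj <- (c_in != c_out) || (stride != 1)
  mods <- list(
    conv1 = nn_conv(c_in, c_mid, 1, 1, 0),
    bn1 = nn_batchnorm(c_mid), relu1 = nn_relu(),
    conv2 = nn_conv(c_mid, c_mid, 3, stride, 1),
    bn2 = nn_batchnorm(c_mid), relu2 = nn_relu(),
    conv3 = nn_conv(c_mid, c_out, 1, 1, 0),
    bn3 = nn_batchnorm(c_out),
    relu_out = nn_relu()
  )
  if (needs_proj) {
    mods$proj <- nn_conv(c_in, c_out, 1, stride, 0)
    mods$proj_bn <- nn_batchnorm(c_out)
  }
  new_nn_layer("nn_bottleneck", list(modules = mods, needs_proj = needs_proj))
}

#' @export
nn_forward.nn_bottleneck <- function(layer, x, training = FALSE) {
  m <- layer$modules
  f <- nn_forward(m$conv1, x, training)
  f <- nn_forward(m$bn1, f, training)
  f <- nn_forward(m$relu1, f, training)
  f <- nn_forward(m$conv2, f, training)
  f <- nn_forward(m$bn2, f, training)
  f <- nn_forward(m$relu2, f, training)
  f <- nn_forward(m$conv3, f, training)
  f <- nn_forward(m$bn3, f, training)
  sc <- if (layer$needs_proj) {
    nn_forward(m$proj_bn, nn_forward(m$proj, x, training), training)
  } else {
    x
  }
  nn_forward(m$relu_out, f + sc, training)
}

#' @export
nn_backward.nn_bottleneck <- function(layer, dout) {
  m <- layer$modules
  d <- nn_backward(m$relu_out, dout)
  df <- nn_backward(m$bn3, d)
  df <- nn_backward(m$conv3, df)
  df <- nn_backward(m$relu2, df)
  df <- nn_backward(m$bn2, df)
  df <- nn_backward(m$conv2, df)
  df <- nn_backward(m$relu1, df)
  df <- nn_backward(m$bn1, df)
  df <- nn_backward(m$conv1, df)
  dsc <- if (layer$needs_proj) {
    nn_backward(m$proj, nn_backward(m$proj_bn, d))
  } else {
    d
  }
  df + dsc
}

#' Apply a residual bottleneck block to a single feature map
#'
#' Standard bottleneck composition `y = F(x, W) + x` (projection shortcut
#' when shapes change), exposed for direct use and testing. The block must be
#' materialized (see [make_bottleneck()]).
#'
#' @param x `[C, H, W]` feature map array
#' @param block a materialized bottleneck module
#' @return `[C', H', W']` output feature map
#' @export
residual_block <- function(x, block) {
  stopifnot(inherits(block, "nn_bottleneck"))
  if (!is.array(x) || length(dim(x)) != 3) {
    stop_lungsop("lungsop_shape_mismatch", "input must be a [C, H, W] array")
  }
  xin <- array(x, dim = c(dim(x), 1))
  out <- nn_forward(block, xin, training = FALSE)
  array(out, dim = dim(out)[1:3])
}

#' Construct and initialize a bottleneck residual block
#'
#' @param c_in,c_mid,c_out input, bottleneck and output channel counts
#' @param stride stride of the 3x3 convolution (2 at stage transitions)
#' @param seed initialization seed
#' @param zero_init initialize all transform weights to zero, making the
#'   block an exact identity (testing aid)
#' @return a materialized bottleneck module
#' @export
make_bottleneck <- function(c_in, c_mid, c_out, stride = 1, seed = 1,
                            zero_init = FALSE) {
  b <- nn_bottleneck(c_in, c_mid, c_out, stride)
  with_seed(seed, nn_materialize(b))
  # batch norms start from identity transform but running stats are fresh;
  # put them in a deterministic state for stand-alone (eval-mode) use
  if (zero_init) {
    for (l in nn_collect(b)) {
      if (inherits(l, "nn_conv")) l$params$W[] <- 0
    }
  }
  b
}

# ---- model configuration ----------------------------------------------------

#' Model configuration for the gated second-order pooling classifier
#'
#' @param n_classes number of output classes (default 3)
#' @param input_size expected square input size in pixels (default 224)
#' @param in_channels input channels (default 3; grayscale inputs are
#'   replicated)
#' @param se_reduction SE bottleneck reduction ratio r (default 16)
#' @param ns_iterations Newton-Schulz iterations (default 5)
#' @param cov_power_exponent covariance power exponent (fixed at 0.5; the
#'   eigendecomposition oracle honours other values)
#' @param width_multiplier uniform channel-width scale in (0, 1]; 1 is the
#'   full-size network, smaller values give CPU-scale models
#' @param use_se,use_sop,use_dfe ablation flags (all TRUE for the full model)
#' @param three_stage use the literal three-stage (3, 4, 6) backbone instead
#'   of the canonical four-stage (3, 4, 6, 3) ResNet50 geometry
#' @param sop_dim channel width of the 1x1 reduction feeding the head SOP;
#'   default `max(16, round(256 * width_multiplier))`
#' @param dfe_tau,dfe_mode,dfe_reg_weight gate threshold, mode
#'   (`"hard"`/`"soft"`) for the intermediate gates, and balance-regularizer
#'   weight lambda
#' @param head_mode fusion mode at the classification head (default
#'   `"soft"`, the convex-combination form)
#' @param pretrained_backbone optional path to a checkpoint supplying
#'   backbone weights (never downloaded)
#' @return object of class `model_config`
#' @export
model_config <- function(n_classes = 3, input_size = 224, in_channels = 3,
                         se_reduction = 16, ns_iterations = 5,
                         cov_power_exponent = 0.5, width_multiplier = 1,
                         use_se = TRUE, use_sop = TRUE, use_dfe = TRUE,
                         three_stage = FALSE, sop_dim = NULL,
                         dfe_tau = 0.5, dfe_mode = "hard",
                         dfe_reg_weight = 0.01, head_mode = "soft",
                         pretrained_backbone = NULL) {
  if (n_classes < 2 || input_size < 8 || width_multiplier <= 0 ||
      width_multiplier > 1 || ns_iterations < 0) {
    stop_lungsop("lungsop_config_error", "invalid model configuration")
  }
  if (use_dfe && !(use_se && use_sop)) {
    stop_lungsop("lungsop_config_error",
                 "the adaptive gate requires both SE and SOP branches")
  }
  w <- width_multiplier
  if (is.null(sop_dim)) sop_dim <- max(16L, round(256 * w))
  structure(list(
    n_classes = n_classes, input_size = input_size, in_channels = in_channels,
    se_reduction = se_reduction, ns_iterations = ns_iterations,
    cov_power_exponent = cov_power_exponent, width_multiplier = w,
    use_se = use_se, use_sop = use_sop, use_dfe = use_dfe,
    three_stage = three_stage, sop_dim = sop_dim,
    dfe_tau = dfe_tau, dfe_mode = dfe_mode, dfe_reg_weight = dfe_reg_weight,
    head_mode = head_mode, pretrained_backbone = pretrained_backbone
  ), class = "model_config")
}

wch <- function(c, w) max(1L, as.integer(round(c * w)))

build_backbone <- function(cfg) {
  w <- cfg$width_multiplier
  stem_out <- wch(64, w)
  stem <- nn_sequential(
    nn_conv(cfg$in_channels, stem_out, 7, 2, 3),
    nn_batchnorm(stem_out), nn_relu(),
    nn_maxpool(3, 2, 1)
  )
  depths <- if (cfg$three_stage) c(3, 4, 6) else c(3, 4, 6, 3)
  mids <- vapply(c(64, 128, 256, 512)[seq_along(depths)], wch, integer(1), w = w)
  outs <- 4L * mids
  blocks <- list()
  c_in <- stem_out
  for (s in seq_along(depths)) {
    for (b in seq_len(depths[s])) {
      stride <- if (s > 1 && b == 1) 2 else 1
      blocks[[length(blocks) + 1]] <- nn_bottleneck(c_in, mids[s], outs[s], stride)
      c_in <- outs[s]
    }
  }
  list(stem = stem, stages = nn_sequential(blocks), out_channels = c_in,
       stem_channels = stem_out)
}

#' Build the gated second-order pooling classifier
#'
#' Assembles: 7x7 stem convolution + max pooling, an adaptive gate at the
#' stem output (intermediate placement), the bottleneck stages, a second
#' adaptive gate, an SE attention block, and the classification head where a
#' final second-order pooling branch is fused with the excitation-weighted
#' global descriptor before the fully connected softmax classifier. Ablation
#' flags in the config produce the plain backbone and the +SE / +SOP /
#' +SE+SOP / +SE+SOP+DFE variants.
#'
#' @param cfg a [model_config()]
#' @param seed initialization seed; construction is deterministic given the
#'   seed
#' @param materialize allocate and initialize weights (default TRUE; FALSE
#'   builds shape descriptors only, enough for parameter counting)
#' @return object of class `lungsop_model`
#' @export
build_lung_se_sop <- function(cfg = model_config(), seed = 1,
                              materialize = TRUE) {
  stopifnot(inherits(cfg, "model_config"))
  bb <- build_backbone(cfg)
  ch <- bb$out_channels
  parts <- list(stem = bb$stem)
  if (cfg$use_dfe) {
    parts$dfe1 <- nn_dfe_intermediate(bb$stem_channels, tau = cfg$dfe_tau,
                                      mode = cfg$dfe_mode,
                                      se_reduction = cfg$se_reduction,
                                      n_iter = cfg$ns_iterations)
  }
  parts$stages <- bb$stages
  if (cfg$use_dfe) {
    parts$dfe2 <- nn_dfe_intermediate(ch, tau = cfg$dfe_tau,
                                      mode = cfg$dfe_mode,
                                      se_reduction = cfg$se_reduction,
                                      n_iter = cfg$ns_iterations)
  }
  if (cfg$use_se) {
    parts$se <- nn_se_module(ch, cfg$se_reduction)
  }
  if (cfg$use_dfe) {
    parts$head <- nn_head(ch, cfg$sop_dim, cfg$se_reduction,
                          tau = cfg$dfe_tau, mode = cfg$head_mode,
                          n_iter = cfg$ns_iterations)
    feature_width <- cfg$sop_dim^2
  } else if (cfg$use_sop) {
    parts$head <- nn_sequential(
      nn_conv(ch, cfg$sop_dim, 1, 1, 0),
      nn_batchnorm(cfg$sop_dim), nn_relu(),
      nn_sop_vec(cfg$ns_iterations)
    )
    feature_width <- cfg$sop_dim^2
  } else {
    parts$head <- nn_gap()
    feature_width <- ch
  }
  parts$classifier <- nn_linear(feature_width, cfg$n_classes, bias = TRUE)
  model <- structure(list(parts = parts, cfg = cfg, seed = seed,
                          feature_width = feature_width),
                     class = "lungsop_model")
  if (materialize) with_seed(seed, nn_materialize(parts))
  if (!is.null(cfg$pretrained_backbone)) {
    load_backbone_weights(model, cfg$pretrained_backbone)
  }
  model
}

#' Canonical ResNet50 reference builder
#'
#' Stages of 3, 4, 6 and 3 bottlenecks with global average pooling and a
#' fully connected head. With `n_classes = 1000` this is the reference
#' architecture whose trainable parameter count is 25.6 M.
#'
#' @param n_classes classifier width (default 1000)
#' @param pretrained optional checkpoint path for externally supplied
#'   weights; nothing is ever downloaded
#' @param width_multiplier channel scale (1 = canonical); non-unit widths
#'   are for desk-scale forward tests only
#' @param materialize allocate weight arrays (needed for a forward pass;
#'   parameter counting works without)
#' @param seed initialization seed
#' @return `lungsop_model`
#' @export
build_resnet50_baseline <- function(n_classes = 1000, pretrained = NULL,
                                    width_multiplier = 1, materialize = FALSE,
                                    seed = 1) {
  cfg <- model_config(n_classes = n_classes, use_se = FALSE, use_sop = FALSE,
                      use_dfe = FALSE, width_multiplier = width_multiplier,
                      pretrained_backbone = pretrained)
  bb <- build_backbone(cfg)
  parts <- list(stem = bb$stem, stages = bb$stages, head = nn_gap(),
                classifier = nn_linear(bb$out_channels, n_classes, bias = TRUE))
  model <- structure(list(parts = parts, cfg = cfg, seed = seed,
                          feature_width = bb$out_channels),
                     class = "lungsop_model")
  if (materialize) with_seed(seed, nn_materialize(parts))
  if (!is.null(pretrained)) load_backbone_weights(model, pretrained)
  model
}

#' Canonical VGG16 reference builder (configuration D)
#'
#' Thirteen 3x3 convolutions (64-64, 128-128, 256-256-256, 512-512-512,
#' 512-512-512) with 2x2 max pooling and the 4096/4096/`n_classes` fully
#' connected head. Used for parameter-count verification; with 1000 classes
#' the trainable count is 138.4 M.
#'
#' @param n_classes classifier width (default 1000)
#' @param materialize allocate weights (default FALSE: counting only)
#' @param seed initialization seed
#' @return `lungsop_model`
#' @export
build_vgg16_reference <- function(n_classes = 1000, materialize = FALSE,
                                  seed = 1) {
  widths <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                 c(512, 512, 512), c(512, 512, 512))
  layers <- list()
  c_in <- 3L
  for (grp in widths) {
    for (cw in grp) {
      layers[[length(layers) + 1]] <- nn_conv(c_in, cw, 3, 1, 1, bias = TRUE)
      layers[[length(layers) + 1]] <- nn_relu()
      c_in <- cw
    }
    layers[[length(layers) + 1]] <- nn_maxpool(2, 2, 0)
  }
  parts <- list(
    stem = nn_sequential(layers),
    head = new_nn_layer("nn_flatten", list()),
    classifier = nn_sequential(
      nn_linear(512 * 7 * 7, 4096, bias = TRUE), nn_relu(),
      nn_linear(4096, 4096, bias = TRUE), nn_relu(),
      nn_linear(4096, n_classes, bias = TRUE)
    )
  )
  model <- structure(list(parts = parts,
                          cfg = list(n_classes = n_classes, input_size = 224,
                                     in_channels = 3),
                          seed = seed, feature_width = 512 * 7 * 7),
                     class = "lungsop_model")
  if (materialize) with_seed(seed, nn_materialize(parts))
  model
}

#' @export
nn_forward.nn_flatten <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (training) layer$cache <- d
  matrix(x, nrow = prod(d[1:3]), ncol = d[4])
}

#' @export
nn_backward.nn_flatten <- function(layer, dout) {
  d <- layer$cache
  layer$cache <- NULL
  array(dout, dim = d)
}

# ---- forward / classify ------------------------------------------------------

# x: [C, H, W, N] array in model layout; returns list(logits, alphas)
model_forward <- function(model, x, training = FALSE) {
  p <- model$parts
  alphas <- list()
  h <- nn_forward(p$stem, x, training)
  if (!is.null(p$dfe1)) {
    h <- nn_forward(p$dfe1, h, training)
    alphas$dfe1 <- p$dfe1$last_alpha
  }
  h <- nn_forward(p$stages, h, training)
  if (!is.null(p$dfe2)) {
    h <- nn_forward(p$dfe2, h, training)
    alphas$dfe2 <- p$dfe2$last_alpha
  }
  if (!is.null(p$se)) h <- nn_forward(p$se, h, training)
  feats <- nn_forward(p$head, h, training)
  if (inherits(p$head, "nn_head")) alphas$head <- p$head$last_alpha
  logits <- nn_forward(p$classifier, feats, training)
  list(logits = logits, alphas = alphas)
}

model_backward <- function(model, dlogits) {
  p <- model$parts
  d <- nn_backward(p$classifier, dlogits)
  d <- nn_backward(p$head, d)
  if (!is.null(p$se)) d <- nn_backward(p$se, d)
  if (!is.null(p$dfe2)) d <- nn_backward(p$dfe2, d)
  d <- nn_backward(p$stages, d)
  if (!is.null(p$dfe1)) d <- nn_backward(p$dfe1, d)
  nn_backward(p$stem, d)
}

# number of gate instances in the model (for the regularizer mean)
model_gates <- function(model) {
  p <- model$parts
  Filter(Negate(is.null),
         list(p$dfe1, p$dfe2, if (inherits(p$head, "nn_head")) p$head))
}

# Convert images to the model input layout [C, H, W, N]; accepts a single
# [H, W] matrix, an [H, W, N] array, a list of labeled images, or an
# already-shaped [C, H, W, N] array.
as_model_input <- function(x, model) {
  cin <- model$cfg$in_channels
  size <- model$cfg$input_size
  if (is.list(x) && !is.array(x)) {
    x <- simplify2array(lapply(x, function(im) {
      if (inherits(im, "labeled_image")) im$pixels else im
    }))
  }
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  d <- dim(x)
  if (length(d) == 3) {
    if (d[1] != size || d[2] != size) {
      stop_lungsop("lungsop_shape_mismatch",
                   sprintf("input is %dx%d but the model expects %dx%d",
                           d[1], d[2], size, size))
    }
    arr <- array(0, dim = c(cin, d[1], d[2], d[3]))
    for (ci in seq_len(cin)) arr[ci, , , ] <- x
    return(arr)
  }
  if (length(d) == 4) {
    if (d[1] != cin || d[2] != size || d[3] != size) {
      stop_lungsop("lungsop_shape_mismatch", "input layout must be [C, H, W, N]")
    }
    return(x)
  }
  stop_lungsop("lungsop_shape_mismatch", "unrecognized input shape")
}

#' Classify images with a built model
#'
#' Runs a deterministic (evaluation-mode) forward pass and returns class
#' probabilities; rows sum to one within 1e-6.
#'
#' @param model a `lungsop_model`
#' @param x an `[H, W]` matrix, `[H, W, N]` stack, list of `labeled_image`
#'   objects, or a pre-shaped `[C, H, W, N]` array matching the model input
#'   size
#' @return an `N x K` matrix of class probabilities (single input: still a
#'   1 x K matrix)
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "lungsop_model"))
  xin <- as_model_input(x, model)
  out <- model_forward(model, xin, training = FALSE)
  t(softmax_cols(out$logits))
}

# ---- parameter counting ------------------------------------------------------

#' Count trainable parameters
#'
#' Counts every trainable parameter (convolution and linear weights and
#' biases, batch-norm scale and shift; running statistics are buffers, not
#' parameters) from the layer shape descriptors, so unmaterialized reference
#' models are counted without allocating weights.
#'
#' @param model a `lungsop_model` or any layer/module (list)
#' @return list with `exact` (integer count) and `millions` (rounded
#'   half-up to one decimal)
#' @export
count_parameters <- function(model) {
  target <- if (inherits(model, "lungsop_model")) model$parts else model
  exact <- nn_param_count(target)
  list(exact = exact, millions = round_half_up(exact / 1e6, 1))
}

# ---- checkpoints -------------------------------------------------------------

model_state <- function(model) {
  layers <- nn_collect(model$parts)
  lapply(layers, function(l) {
    st <- list(params = l$params)
    if (inherits(l, "nn_batchnorm")) {
      st$running_mean <- l$running_mean
      st$running_var <- l$running_var
    }
    st
  })
}

restore_model_state <- function(model, state) {
  layers <- nn_collect(model$parts)
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    layers[[i]]$params <- state[[i]]$params
    layers[[i]]$materialized <- TRUE
    if (inherits(layers[[i]], "nn_batchnorm")) {
      layers[[i]]$running_mean <- state[[i]]$running_mean
      layers[[i]]$running_var <- state[[i]]$running_var
    }
  }
  invisible(model)
}

#' Save a model checkpoint
#'
#' Single-file checkpoint with a versioned header echoing the model
#' configuration, the construction seed, and all parameter/buffer arrays.
#'
#' @param model a `lungsop_model`
#' @param path output file path
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "lungsop-checkpoint", version = 1L,
               cfg = model$cfg, seed = model$seed,
               state = model_state(model)), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()]
#' @return a rebuilt `lungsop_model` with restored weights
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "lungsop-checkpoint")) {
    stop_lungsop("lungsop_config_error", "not a model checkpoint")
  }
  cfg <- ck$cfg
  cfg$pretrained_backbone <- NULL
  model <- build_lung_se_sop(cfg, seed = ck$seed)
  restore_model_state(model, ck$state)
  model
}

load_backbone_weights <- function(model, path) {
  ck <- readRDS(path)
  restore_model_state(model, ck$state)
  invisible(model)
}
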