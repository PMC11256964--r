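#' Network architecture options
#'
#' A fully convolutional dilated residual network in the trRosetta style:
#' an input convolution followed by residual blocks, each
#' conv - instance norm - ELU - (dropout) - conv - instance norm with an
#' additive skip and a trailing ELU, with dilation rates cycling through
#' \code{dilation_cycle} to widen the receptive field. A final 1x1
#' convolution produces one logit per residue pair; the logit map is added
#' to its transpose before the sigmoid, so the output is symmetric by
#' construction. No layer depends on L: one weight set serves inputs of any
#' size.
#'
#' @param n_blocks number of residual blocks (full-scale default 31).
#' @param n_filters filters per convolution (full-scale default 32).
#' @param kernel convolution kernel size (3).
#' @param dilation_cycle dilation rates, repeated across blocks.
#' @param dropout dropout rate inside blocks during training (default 0).
#' @return A list of class \code{network_config}.
#' @export
network_config <- function(n_blocks = 31, n_filters = 32, kernel = 3,
                           dilation_cycle = c(1, 2, 4, 8, 16), dropout = 0) {
  stopifnot(n_blocks >= 1, n_filters >= 1, kernel %in% c(1, 3, 5),
            all(dilation_cycle >= 1), dropout >= 0, dropout < 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 n_filters = as.integer(n_filters),
                 kernel = as.integer(kernel),
                 dilation_cycle = as.integer(dilation_cycle),
                 dropout = dropout),
            class = "network_config")
}

#' Training options
#'
#' @param p_multi probability of drawing a multi-domain example at each
#'   training step (0.65, with single-domain examples drawn at 0.35).
#' @param p_single probability for single-domain examples; must sum to 1
#'   with \code{p_multi}.
#' @param learning_rate Adam step size.
#' @param epochs passes over the dataset (one epoch = one step per chain).
#' @param batch_size fixed at 1: chains have variable length, so each step
#'   processes one chain.
#' @param seed integer seed fixing sampling and initialization.
#' @return A list of class \code{training_config}.
#' @export
training_config <- function(p_multi = 0.65, p_single = 1 - p_multi,
                            learning_rate = 1e-3, epochs = 10,
                            batch_size = 1, seed = 1) {
  if (abs(p_multi + p_single - 1) > 1e-9) {
    stop("p_multi + p_single must equal 1", call. = FALSE)
  }
  stopifnot(p_multi >= 0, p_multi <= 1, learning_rate > 0, epochs >= 1,
            batch_size == 1)
  structure(list(p_multi = p_multi, p_single = p_single,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = 1L, seed = as.integer(seed)),
            class = "training_config")
}

#' Build an untrained segmentation network
#'
#' Initializes weights (He initialization for convolutions; the output
#' layer starts near zero so the initial prediction is close to 0.5
#' everywhere) and returns the model handle used by
#' \code{\link{train_segmenter}} and \code{\link{predict_soft_adjacency}}.
#'
#' @param config a \code{\link{network_config}}.
#' @param seed optional integer seed for the weight draw.
#' @return An object of class \code{domain_cnn}.
#' @export
build_model <- function(config = network_config(), seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  structure(list(params = init_params(config), config = config,
                 trained = FALSE, history = NULL, training = NULL),
            class = "domain_cnn")
}

init_params <- function(cfg) {
  k <- cfg$kernel
  nf <- cfg$n_filters
  he <- function(fan_in, n_out) {
    matrix(rnorm(n_out * fan_in, 0, sqrt(2 / fan_in)), n_out, fan_in)
  }
  p <- list(in_W = he(5 * k * k, nf), in_b = numeric(nf),
            in_g = rep(1, nf), in_be = numeric(nf))
  for (i in seq_len(cfg$n_blocks)) {
    pre <- sprintf("blk%02d_", i)
    p[[paste0(pre, "W1")]] <- he(nf * k * k, nf)
    p[[paste0(pre, "b1")]] <- numeric(nf)
    p[[paste0(pre, "g1")]] <- rep(1, nf)
    p[[paste0(pre, "be1")]] <- numeric(nf)
    p[[paste0(pre, "W2")]] <- he(nf * k * k, nf)
    p[[paste0(pre, "b2")]] <- numeric(nf)
    p[[paste0(pre, "g2")]] <- rep(1, nf)
    p[[paste0(pre, "be2")]] <- numeric(nf)
  }
  p$out_W <- matrix(rnorm(nf, 0, 0.01), 1, nf)
  p$out_b <- 0
  p
}

block_dilation <- function(cfg, i) {
  cfg$dilation_cycle[(i - 1L) %% length(cfg$dilation_cycle) + 1L]
}

# ---- layer primitives (forward caches feed the hand-written backward) ----
# thin wrappers over the compiled kernels; arrays are reshaped to
# (L*L) x C matrices without copying the data

inorm_fwd <- function(x, g, be, eps = 1e-5) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  res <- inorm_fwd_cpp(x, g, be, eps)
  y <- res$y
  dim(y) <- d
  list(y = y, xhat = res$xhat, sd = res$sd)
}

inorm_bwd <- function(gy, cache, g) {
  d <- dim(gy)
  dim(gy) <- c(d[1] * d[2], d[3])
  res <- inorm_bwd_cpp(gy, cache$xhat, cache$sd, g)
  gx <- res$gx
  dim(gx) <- d
  list(gx = gx, gg = as.numeric(res$gg), gbe = as.numeric(res$gbe))
}

elu_fwd <- function(x) list(y = elu_cpp(x))

elu_bwd <- function(gy, cache) elu_grad_cpp(gy, cache$y)

# forward pass; keep_cache = TRUE stores per-layer activations and im2col
# patch matrices for backprop
net_forward <- function(params, x, cfg, keep_cache = FALSE,
                        dropout_train = FALSE) {
  p <- params
  k <- cfg$kernel
  conv <- if (keep_cache) {
    function(x, W, b, k, d) conv2d_fwd_cache(x, W, b, k, d)
  } else {
    function(x, W, b, k, d) list(y = conv2d_fwd(x, W, b, k, d))
  }
  c0 <- conv(x, p$in_W, p$in_b, k, 1L)
  n0 <- inorm_fwd(c0$y, p$in_g, p$in_be)
  e0 <- elu_fwd(n0$y)
  h <- e0$y
  blocks <- if (keep_cache) vector("list", cfg$n_blocks) else NULL
  for (i in seq_len(cfg$n_blocks)) {
    pre <- sprintf("blk%02d_", i)
    d <- block_dilation(cfg, i)
    t1 <- conv(h, p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]], k, d)
    n1 <- inorm_fwd(t1$y, p[[paste0(pre, "g1")]], p[[paste0(pre, "be1")]])
    a1 <- elu_fwd(n1$y)
    a1y <- a1$y
    mask <- NULL
    if (dropout_train && cfg$dropout > 0) {
      mask <- array(runif(length(a1y)) >= cfg$dropout,
                    dim = dim(a1y)) / (1 - cfg$dropout)
      a1y <- a1y * mask
    }
    t2 <- conv(a1y, p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]], k, d)
    n2 <- inorm_fwd(t2$y, p[[paste0(pre, "g2")]], p[[paste0(pre, "be2")]])
    pre_act <- h + n2$y
    eo <- elu_fwd(pre_act)
    if (keep_cache) {
      blocks[[i]] <- list(col1 = t1$col, col2 = t2$col, n1 = n1, a1 = a1,
                          mask = mask, n2 = n2, eo = eo, dilation = d)
    }
    h <- eo$y
  }
  z <- conv(h, p$out_W, p$out_b, 1L, 1L)
  Z <- matrix(z$y[, , 1], dim(z$y)[1], dim(z$y)[2])
  logits <- Z + t(Z)  # exact symmetry: a_ij and a_ji sum identical terms
  cache <- if (keep_cache) list(col0 = c0$col, n0 = n0, e0 = e0,
                                col_top = z$col, dims = dim(x),
                                blocks = blocks) else NULL
  list(logits = logits, cache = cache)
}

# backward pass; g_logits is dLoss/dlogits on the symmetrized L x L map
net_backward <- function(params, cfg, cache, g_logits) {
  p <- params
  k <- cfg$kernel
  nf <- cfg$n_filters
  grads <- list()
  gZ <- g_logits + t(g_logits)
  dims <- cache$dims
  gz_cube <- array(gZ, dim = c(dims[1], dims[2], 1))
  bo <- conv2d_bwd_cached(cache$col_top, p$out_W, gz_cube, 1L, 1L, nf)
  grads$out_W <- bo$gW
  grads$out_b <- as.numeric(bo$gb)
  gh <- bo$gx
  for (i in rev(seq_len(cfg$n_blocks))) {
    pre <- sprintf("blk%02d_", i)
    bc <- cache$blocks[[i]]
    g_pre <- elu_bwd(gh, bc$eo)
    nb2 <- inorm_bwd(g_pre, bc$n2, p[[paste0(pre, "g2")]])
    grads[[paste0(pre, "g2")]] <- nb2$gg
    grads[[paste0(pre, "be2")]] <- nb2$gbe
    cb2 <- conv2d_bwd_cached(bc$col2, p[[paste0(pre, "W2")]], nb2$gx, k,
                             bc$dilation, nf)
    grads[[paste0(pre, "W2")]] <- cb2$gW
    grads[[paste0(pre, "b2")]] <- as.numeric(cb2$gb)
    g_a1 <- cb2$gx
    if (!is.null(bc$mask)) g_a1 <- g_a1 * bc$mask
    g_n1y <- elu_bwd(g_a1, bc$a1)
    nb1 <- inorm_bwd(g_n1y, bc$n1, p[[paste0(pre, "g1")]])
    grads[[paste0(pre, "g1")]] <- nb1$gg
    grads[[paste0(pre, "be1")]] <- nb1$gbe
    cb1 <- conv2d_bwd_cached(bc$col1, p[[paste0(pre, "W1")]], nb1$gx, k,
                             bc$dilation, nf)
    grads[[paste0(pre, "W1")]] <- cb1$gW
    grads[[paste0(pre, "b1")]] <- as.numeric(cb1$gb)
    gh <- cb1$gx + g_pre  # conv path + skip connection
  }
  g_n0y <- elu_bwd(gh, cache$e0)
  nb0 <- inorm_bwd(g_n0y, cache$n0, p$in_g)
  grads$in_g <- nb0$gg
  grads$in_be <- nb0$gbe
  cb0 <- conv2d_bwd_cached(cache$col0, p$in_W, nb0$gx, k, 1L, 5L)
  grads$in_W <- cb0$gW
  grads$in_b <- as.numeric(cb0$gb)
  grads
}

#' Predict the soft adjacency matrix for a feature stack
#'
#' Runs the network forward and returns the sigmoid of the symmetrized
#' logits, clipped to \[eps, 1 - eps\]. The output inherits the exact
#' SE(3)/reflection invariance of the features.
#'
#' @param model a \code{domain_cnn}.
#' @param features an L x L x 5 array from \code{\link{featurize}}.
#' @param eps probability clip.
#' @return Symmetric L x L matrix of co-membership probabilities.
#' @export
predict_soft_adjacency <- function(model, features, eps = 1e-4) {
  stopifnot(inherits(model, "domain_cnn"))
  features <- unclass(features)
  if (length(dim(features)) != 3 || dim(features)[3] != 5) {
    stop("features must be an L x L x 5 array", call. = FALSE)
  }
  fwd <- net_forward(model$params, features, model$config)
  clip_prob(plogis(fwd$logits), eps)
}

#' Binary cross-entropy between a soft and a binary adjacency
#'
#' Mean over the L(L-1)/2 residue pairs i < j of
#' -\[a log p + (1 - a) log(1 - p)\], with predictions clipped to
#' \[eps, 1 - eps\]. Diagonal terms are excluded.
#'
#' @param pred L x L matrix of probabilities.
#' @param target binary L x L adjacency label.
#' @param eps probability clip.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(pred, target, eps = 1e-4) {
  if (!all(dim(pred) == dim(target))) {
    stop("prediction and target shapes differ", call. = FALSE)
  }
  p <- clip_prob(pred, eps)
  ut <- upper.tri(p)
  -mean(target[ut] * log(p[ut]) + (1 - target[ut]) * log1p(-p[ut]))
}

# numerically stable BCE from logits, averaged over off-diagonal entries
bce_from_logits <- function(logits, target) {
  L <- nrow(logits)
  ut <- upper.tri(logits)
  z <- logits[ut]
  a <- target[ut]
  mean(pmax(z, 0) - z * a + log1p(exp(-abs(z))))
}

#' Train the segmentation network
#'
#' Stochastic training with Adam, one chain per step. At every step a
#' multi-domain example is drawn with probability \code{p_multi} and a
#' single-domain example otherwise (uniformly within the class), and the
#' binary cross-entropy between the predicted and true pairwise
#' co-membership matrices is minimized. Fully deterministic given the
#' config seed.
#'
#' @param model a \code{domain_cnn} from \code{\link{build_model}}, or NULL
#'   to build one from \code{net_config} (seeded by the training seed).
#' @param dataset a list of items with elements \code{features},
#'   \code{label} and \code{flag}, as built by \code{\link{make_dataset}}.
#' @param config a \code{\link{training_config}}.
#' @param net_config a \code{\link{network_config}}, used when \code{model}
#'   is NULL.
#' @param verbose print a line per epoch.
#' @return The trained \code{domain_cnn}; \code{$history} holds a data
#'   frame of per-step losses.
#' @export
train_segmenter <- function(model = NULL, dataset, config = training_config(),
                            net_config = network_config(), verbose = FALSE) {
  stopifnot(inherits(config, "training_config"))
  if (length(dataset) == 0) stop("dataset is empty", call. = FALSE)
  set.seed(config$seed)
  if (is.null(model)) model <- build_model(net_config)
  stopifnot(inherits(model, "domain_cnn"))
  cfg <- model$config
  params <- model$params
  flags <- vapply(dataset, function(it) it$flag, character(1))
  idx_single <- which(flags == "single")
  idx_multi <- which(flags == "multi")
  state <- lapply(params, function(w) list(m = w * 0, v = w * 0))
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  lr <- config$learning_rate
  steps <- length(dataset)
  hist_loss <- numeric(config$epochs * steps)
  hist_epoch <- integer(config$epochs * steps)
  t <- 0L
  for (ep in seq_len(config$epochs)) {
    for (s in seq_len(steps)) {
      pool <- if (runif(1) < config$p_multi) idx_multi else idx_single
      if (length(pool) == 0) pool <- seq_len(steps)
      i <- pool[sample.int(length(pool), 1)]
      item <- dataset[[i]]
      fwd <- net_forward(params, unclass(item$features), cfg,
                         keep_cache = TRUE, dropout_train = TRUE)
      A <- item$label
      L <- nrow(A)
      loss <- bce_from_logits(fwd$logits, A)
      G <- (plogis(fwd$logits) - A)
      diag(G) <- 0
      G <- G / (L * (L - 1))
      grads <- net_backward(params, cfg, fwd$cache, G)
      t <- t + 1L
      corr1 <- 1 - b1^t
      corr2 <- 1 - b2^t
      for (nm in names(params)) {
        g <- grads[[nm]]
        st <- state[[nm]]
        st$m <- b1 * st$m + (1 - b1) * g
        st$v <- b2 * st$v + (1 - b2) * g * g
        state[[nm]] <- st
        params[[nm]] <- params[[nm]] -
          lr * (st$m / corr1) / (sqrt(st$v / corr2) + aeps)
      }
      hist_loss[t] <- loss
      hist_epoch[t] <- ep
    }
    if (verbose) {
      message(sprintf("epoch %d/%d mean BCE %.4f", ep, config$epochs,
                      mean(hist_loss[hist_epoch == ep])))
    }
  }
  model$params <- params
  model$trained <- TRUE
  model$training <- config
  model$history <- data.frame(step = seq_len(t), epoch = hist_epoch,
                              loss = hist_loss)
  model
}

#' Save / load a trained model
#'
#' Checkpoints are written with R's native serialization.
#'
#' @param model a \code{domain_cnn}.
#' @param path checkpoint file path.
#' @return \code{save_model}: \code{path}, invisibly. \code{load_model}:
#'   the \code{domain_cnn}.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "domain_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "domain_cnn")) {
    stop("not a domain_cnn checkpoint: ", path, call. = FALSE)
  }
  model
}

#' @export
print.domain_cnn <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<domain_cnn> %d residual blocks, %d filters, %s (%s parameters)\n",
    x$config$n_blocks, x$config$n_filters,
    if (x$trained) "trained" else "untrained", format(np, big.mark = ",")))
  invisible(x)
}

#' @export
summary.domain_cnn <- function(object, ...) {
  print(object)
  cat(sprintf("dilation cycle: %s; kernel %d; dropout %.2f\n",
              paste(object$config$dilation_cycle, collapse = ","),
              object$config$kernel, object$config$dropout))
  if (!is.null(object$history)) {
    h <- object$history
    first <- mean(h$loss[h$epoch == min(h$epoch)])
    last <- mean(h$loss[h$epoch == max(h$epoch)])
    cat(sprintf("training: %d steps over %d epochs; mean BCE %.4f -> %.4f\n",
                nrow(h), max(h$epoch), first, last))
  }
  invisible(object)
}

#' @export
plot.domain_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    stop("model has no training history to plot", call. = FALSE)
  }
  h <- x$history
  graphics::plot(h$step, h$loss, type = "l", col = "grey60",
                 xlab = "training step", ylab = "binary cross-entropy", ...)
  by_ep <- tapply(h$loss, h$epoch, mean)
  steps_ep <- tapply(h$step, h$epoch, stats::median)
  graphics::lines(steps_ep, by_ep, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Predict domain assignments with a trained model
#'
#' Convenience method running the full pipeline on a chain (featurize,
#' predict pairwise co-membership, resolve domains, score confidence).
#'
#' @param object a trained \code{domain_cnn}.
#' @param newdata a \code{\link{protein_chain}} or a precomputed
#'   L x L x 5 feature array.
#' @param type "assignment" for the full segmentation, "adjacency" for the
#'   raw soft adjacency matrix.
#' @param ss optional \code{secondary_structure} for featurization.
#' @param assigner an \code{\link{assigner_config}}.
#' @param features_config a \code{\link{feature_config}}.
#' @param ... unused.
#' @return For type "assignment", a list of class
#'   \code{domain_segmentation}: \code{assignment}, \code{n_domains},
#'   \code{chopping} (when a chain was supplied), \code{confidence},
#'   \code{soft}. For type "adjacency", the soft adjacency matrix.
#' @export
predict.domain_cnn <- function(object, newdata, type = c("assignment",
                                                         "adjacency"),
                               ss = NULL, assigner = assigner_config(),
                               features_config = feature_config(), ...) {
  type <- match.arg(type)
  is_chain <- inherits(newdata, "protein_chain")
  feats <- if (is_chain) featurize(newdata, ss, config = features_config)
           else newdata
  soft <- predict_soft_adjacency(object, feats, eps = assigner$eps)
  if (type == "adjacency") return(soft)
  labels <- assign_domains(soft, config = assigner)
  conf <- confidence_score(labels, soft, eps = assigner$eps)
  structure(list(
    assignment = labels,
    n_domains = length(setdiff(unique(as.integer(labels)), 0L)),
    chopping = if (is_chain) format_chopping(labels, newdata) else NULL,
    confidence = conf,
    soft = soft), class = "domain_segmentation")
}

#' @export
print.domain_segmentation <- function(x, ...) {
  cat(sprintf("<domain_segmentation> %d domain(s), confidence %.3f\n",
              x$n_domains, x$confidence))
  if (!is.null(x$chopping)) cat("chopping:", x$chopping, "\n")
  invisible(x)
}
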