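# Non-uniformity Field Detector (NFD).
#
# A small discriminator-style convolutional classifier (strided 4x4
# convolutions, leaky-ReLU activations, no pooling; a linear logit head
# over the final feature grid) that flags shimmed magnitude maps
# containing voids or artifacts.  Labels are generated programmatically: the
# uniform class consists of well-shimmed magnitude maps, the
# non-uniform class of the same maps with smooth multiplicative voids
# injected, so the ground truth is objective and reproducible.

#' NFD configuration
#'
#' @param widths channel widths of the strided convolution stack.
#' @param head `"flatten"` (default) keeps the final feature grid and
#'   feeds it whole to the logit layer, preserving where a void sits;
#'   `"gap"` global-average-pools first (fewer parameters, but spatial
#'   evidence is diluted).
#' @param local_contrast if `TRUE` (default) the input has a second
#'   plane: the map minus its 9x9 box-blurred version (scaled by
#'   `residual_gain`, zero outside the map support).  Small shallow
#'   voids barely move the raw magnitude but stand out in this
#'   high-pass plane.
#' @param residual_gain multiplier on the local-contrast plane.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param threshold decision threshold on the uniform-confidence score.
#' @param val_fraction fraction of the training set held out for
#'   validation-based checkpointing.
#' @param seed seed controlling initialization, split and batch order.
#' @return an `nfd_config` list.
#' @export
nfd_config <- function(widths = c(32L, 64L, 128L, 256L),
                       head = c("flatten", "gap"), local_contrast = TRUE,
                       residual_gain = 5, learning_rate = 2e-4,
                       epochs = 10L, batch_size = 16L,
                       threshold = 0.5, val_fraction = 0.1, seed = 1L) {
  head <- match.arg(head)
  structure(list(widths = as.integer(widths), head = head,
                 local_contrast = isTRUE(local_contrast),
                 residual_gain = residual_gain,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), threshold = threshold,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "nfd_config")
}

#' Build an (untrained) non-uniformity detector
#'
#' Discriminator-style stack: a strided 4x4 convolution per width
#' (stride 2, doubling widths), leaky-ReLU (slope 0.2) activations,
#' batch normalization after all but the first convolution, then a
#' single-logit linear head over either the flattened feature grid or
#' its global average (see `head` in [nfd_config()]).  The sigmoid of
#' the logit is the confidence that a map is uniform.
#'
#' @param config an [nfd_config()].
#' @param input_shape `(rows, cols)` of the magnitude maps the model
#'   will see; fixes the logit-layer width for the flatten head.
#' @return an object of class `nfd_model`.
#' @export
build_nfd <- function(config = nfd_config(), input_shape = c(101L, 101L)) {
  stopifnot(inherits(config, "nfd_config"))
  layers <- list()
  c_in <- if (config$local_contrast) 2L else 1L
  hw <- as.integer(input_shape)
  with_seed(config$seed, {
    for (i in seq_along(config$widths)) {
      w <- config$widths[i]
      layers[[sprintf("conv%d", i)]] <-
        c(conv_layer(c_in, w, 4L, stride = 2L, pad = 1L), list(type = "conv"))
      if (i > 1L)
        layers[[sprintf("bn%d", i)]] <- c(bn_layer(w), list(type = "bn"))
      layers[[sprintf("act%d", i)]] <- list(type = "lrelu")
      c_in <- w
      hw <- (hw + 2L - 4L) %/% 2L + 1L
    }
    if (config$head == "gap") {
      layers[["gap"]] <- list(type = "gap")
      n_feat <- c_in
    } else {
      layers[["flatten"]] <- list(type = "flatten")
      n_feat <- c_in * prod(hw)
    }
    layers[["fc"]] <- c(fc_layer(n_feat, 1L, w_scale = sqrt(1 / n_feat)),
                        list(type = "fc"))
  })
  n_par <- sum(vapply(flatten_pars(list(layers = layers)), length,
                      integer(1)))
  structure(list(layers = layers, config = config, n_parameters = n_par,
                 trained = FALSE, input_shape = as.integer(input_shape)),
            class = "nfd_model")
}

#' @export
print.nfd_model <- function(x, ...) {
  cat(sprintf("<nfd_model> widths %s, %d parameters, %s\n",
              paste(x$config$widths, collapse = "/"), x$n_parameters,
              if (x$trained) sprintf("trained (val accuracy %.3f)",
                                     x$best_val_acc)
              else "untrained"))
  invisible(x)
}

nfd_fwd <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  names(caches) <- names(layers)
  h <- x
  for (nm in names(layers)) {
    ly <- layers[[nm]]
    res <- switch(ly$type,
      conv = conv_fwd(ly, h),
      bn = { r <- bn_fwd(ly, h, training); layers[[nm]] <- r$layer; r },
      lrelu = lrelu_fwd(h),
      gap = gap_fwd(h),
      flatten = {
        d <- dim(h)
        list(out = matrix(h, prod(d[1:3]), d[4]), cache = d)
      },
      fc = fc_fwd(ly, h))
    caches[[nm]] <- res$cache
    h <- res$out
  }
  list(out = h, layers = layers, caches = caches)
}

nfd_bwd <- function(layers, caches, dout) {
  grads <- new.env(parent = emptyenv())
  dh <- dout
  for (nm in rev(names(layers))) {
    ly <- layers[[nm]]
    prefix <- paste0(".layers.", nm)
    dh <- switch(ly$type,
      conv = conv_bwd(ly, caches[[nm]], dh, grads, prefix),
      bn = bn_bwd(ly, caches[[nm]], dh, grads, prefix),
      lrelu = lrelu_bwd(caches[[nm]], dh),
      gap = gap_bwd(caches[[nm]], dh),
      flatten = array(dh, caches[[nm]]),
      fc = fc_bwd(ly, caches[[nm]], dh, grads, prefix))
  }
  as.list(grads, all.names = TRUE)
}

#' Build a labeled NFD dataset from shimmed slices
#'
#' The uniform class consists of well-shimmed combined-magnitude maps
#' (slice RMSE below `rmse_cut`, zeroed outside the mask); the
#' non-uniform class repeats the same maps with randomly placed smooth
#' voids injected via [inject_nonuniformity()].  Classes are exactly
#' balanced at `n_per_class` each.
#'
#' @param volume a `field_volume`, or a list of them (slices are pooled
#'   across volumes, which gives the detector more phantom diversity).
#' @param shim_table a [shim_volume()] table over `volume` carrying its
#'   `results` attribute (any method), or a list of tables parallel to
#'   the volume list.
#' @param n_per_class examples per class.
#' @param rmse_cut maximum slice RMSE (in percent) for the uniform class.
#' @param radius_frac void radius range as a fraction of the smaller
#'   grid dimension.
#' @param depth_range void depth range (each void's depth is uniform in
#'   this interval).
#' @param seed seed for slice sampling and void placement.
#' @return list of examples `list(map, mask, label, volume, slice)`,
#'   uniform first, with attribute `n_per_class`.
#' @export
make_nfd_dataset <- function(volume, shim_table, n_per_class = 100L,
                             rmse_cut = 20, radius_frac = c(0.08, 0.2),
                             depth_range = c(0.5, 1), seed = 1L) {
  volumes <- if (inherits(volume, "field_volume")) list(volume) else volume
  tables <- if (is.data.frame(shim_table)) list(shim_table) else shim_table
  stopifnot(all(vapply(volumes, inherits, TRUE, "field_volume")),
            length(volumes) == length(tables))
  pool <- do.call(rbind, lapply(seq_along(volumes), function(v) {
    tab <- tables[[v]]
    if (is.null(attr(tab, "results")))
      stopf("shim table %d must carry its 'results' attribute", v)
    ok <- which(tab$ok & tab$rmse_percent <= rmse_cut)
    if (length(ok) == 0L) return(NULL)
    data.frame(volume = v, slice = ok)
  }))
  if (is.null(pool) || nrow(pool) < n_per_class)
    stopf("only %d slices below the RMSE cut; need %d per class",
          if (is.null(pool)) 0L else nrow(pool), n_per_class)
  gs <- dim(volumes[[1]]$mask)[1:2]
  rad_range <- radius_frac * min(gs)
  with_seed(seed, {
    pick <- pool[sample(nrow(pool), n_per_class), , drop = FALSE]
    uniform <- lapply(seq_len(n_per_class), function(j) {
      v <- pick$volume[j]; i <- pick$slice[j]
      map <- attr(tables[[v]], "results")[[i]]$combined_magnitude
      map[!volumes[[v]]$mask[, , i]] <- 0
      list(map = map, mask = volumes[[v]]$mask[, , i], label = "uniform",
           volume = v, slice = i)
    })
    nonuniform <- lapply(uniform, function(ex) {
      nv <- sample(1:2, 1)
      map <- inject_nonuniformity(ex$map, ex$mask,
                                  radius = runif(nv, rad_range[1], rad_range[2]),
                                  depth = runif(nv, depth_range[1], depth_range[2]),
                                  n_voids = nv)
      list(map = map, mask = ex$mask, label = "nonuniform",
           volume = ex$volume, slice = ex$slice)
    })
    structure(c(uniform, nonuniform), n_per_class = n_per_class)
  })
}

# Input featurization: the raw magnitude plane, plus (optionally) its
# local-contrast residual against a 9x9 box blur, scaled by the gain
# and restricted to the map support.
nfd_features <- function(map, config) {
  if (!config$local_contrast) return(array(map, c(1L, dim(map))))
  res <- (map - box_blur(map)) * (map > 0)
  out <- array(0, c(2L, dim(map)))
  out[1, , ] <- map
  out[2, , ] <- config$residual_gain * res
  out
}

stack_maps <- function(examples, idx, config) {
  d <- dim(examples[[idx[1]]]$map)
  P <- if (config$local_contrast) 2L else 1L
  x <- array(0, c(P, d, length(idx)))
  for (j in seq_along(idx))
    x[, , , j] <- nfd_features(examples[[idx[j]]]$map, config)
  x
}

#' Train the non-uniformity detector
#'
#' Binary cross-entropy training with the Adam update rule on a
#' balanced labeled set; a seeded validation split is used to
#' checkpoint the best-accuracy parameters.  Aborts (with the last
#' good checkpoint) if the loss becomes non-finite.
#'
#' @param examples labeled examples from [make_nfd_dataset()].
#' @param config an [nfd_config()].
#' @return a trained `nfd_model` with `$history` (per-epoch loss and
#'   validation accuracy).
#' @export
train_nfd <- function(examples, config = nfd_config()) {
  labels <- vapply(examples, function(e) e$label, character(1))
  if (length(unique(labels)) < 2L)
    stopf("training set must contain both classes")
  y <- as.numeric(labels == "uniform")
  model <- build_nfd(config, input_shape = dim(examples[[1]]$map))
  layers <- model$layers
  flat <- flatten_pars(list(layers = layers))
  state <- adam_state_init(flat)

  n <- length(examples)
  n_val <- max(2L, round(config$val_fraction * n))
  perm <- with_seed(derive_seed(config$seed, 7L), sample(n))
  val_idx <- perm[seq_len(n_val)]
  train_idx <- perm[-seq_len(n_val)]

  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_acc = numeric())
  best <- list(layers = layers, acc = -Inf, epoch = 0L)
  aborted <- FALSE
  for (epoch in seq_len(config$epochs)) {
    n_batches <- ceiling(length(train_idx) / config$batch_size)
    epoch_rng <- with_seed(derive_seed(config$seed, 200L + epoch),
                           list(order = sample(train_idx),
                                flips = matrix(runif(2L * n_batches) < 0.5,
                                               n_batches)))
    order <- epoch_rng$order
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      idx <- order[((bi - 1L) * config$batch_size + 1L):
                     min(bi * config$batch_size, length(order))]
      x <- stack_maps(examples, idx, config)
      # label-preserving augmentation: random row/column flips per batch
      if (epoch_rng$flips[bi, 1L]) x <- x[, dim(x)[2]:1, , , drop = FALSE]
      if (epoch_rng$flips[bi, 2L]) x <- x[, , dim(x)[3]:1, , drop = FALSE]
      fw <- nfd_fwd(layers, x, training = TRUE)
      layers <- fw$layers
      p <- 1 / (1 + exp(-fw$out))
      yb <- y[idx]
      eps <- 1e-12
      loss <- -mean(yb * log(p + eps) + (1 - yb) * log(1 - p + eps))
      if (!is.finite(loss)) { aborted <- TRUE; break }
      dlogit <- matrix((p - yb) / length(idx), 1L)
      grads <- nfd_bwd(layers, fw$caches, dlogit)
      upd <- adam_apply(flat, grads, state, config$learning_rate)
      flat <- upd$flat
      state <- upd$state
      layers <- set_pars(list(layers = layers), flat)$layers
      epoch_loss <- epoch_loss + loss / n_batches
    }
    if (aborted) {
      warning("non-finite NFD loss; returning last good checkpoint",
              call. = FALSE)
      break
    }
    val_p <- nfd_confidences(layers, examples, val_idx, config)
    vy <- y[val_idx] == 1
    # balanced validation accuracy so neither class dominates the checkpoint
    val_acc <- if (any(vy) && any(!vy))
      (mean(val_p[vy] >= config$threshold) +
         mean(val_p[!vy] < config$threshold)) / 2
    else mean((val_p >= config$threshold) == vy)
    history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss,
                                         val_acc = val_acc))
    if (val_acc > best$acc)
      best <- list(layers = layers, acc = val_acc, epoch = epoch)
  }
  model$layers <- if (best$epoch > 0L) best$layers else layers
  model$trained <- TRUE
  model$history <- history
  model$best_val_acc <- best$acc
  model$best_epoch <- best$epoch
  model
}

nfd_confidences <- function(layers, examples, idx, config,
                            batch_size = 64L) {
  out <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = batch_size)) {
    take <- idx[start:min(start + batch_size - 1L, length(idx))]
    x <- stack_maps(examples, take, config)
    fw <- nfd_fwd(layers, x, training = FALSE)
    out[start:(start + length(take) - 1L)] <- 1 / (1 + exp(-fw$out))
  }
  out
}

#' Classify a magnitude map as uniform or non-uniform
#'
#' Deterministic forward pass; the confidence is the probability that
#' the map is uniform, and the label is `uniform` iff the confidence
#' reaches the threshold.
#'
#' @param model a trained `nfd_model`.
#' @param magnitude_map numeric matrix matching the training shape.
#' @param threshold decision threshold; default from the model config.
#' @return an `nfd_result`: `confidence`, `predicted_label`,
#'   `threshold`.
#' @export
nfd_classify <- function(model, magnitude_map,
                         threshold = model$config$threshold) {
  if (!model$trained) stopf("NFD has not been trained")
  if (!identical(as.integer(dim(magnitude_map)),
                 as.integer(model$input_shape)))
    stopf("map shape (%s) does not match training shape (%s)",
          paste(dim(magnitude_map), collapse = "x"),
          paste(model$input_shape, collapse = "x"))
  x <- array(nfd_features(magnitude_map, model$config),
             c(if (model$config$local_contrast) 2L else 1L,
               dim(magnitude_map), 1L))
  fw <- nfd_fwd(model$layers, x, training = FALSE)
  conf <- 1 / (1 + exp(-fw$out[1, 1]))
  structure(list(confidence = conf,
                 predicted_label = if (conf >= threshold) "uniform"
                                   else "nonuniform",
                 threshold = threshold),
            class = "nfd_result")
}

#' @export
print.nfd_result <- function(x, ...) {
  cat(sprintf("<nfd_result> %s (confidence of uniform %.4f, threshold %.2f)\n",
              x$predicted_label, x$confidence, x$threshold))
  invisible(x)
}

#' Evaluate the detector on a labeled test set
#'
#' @param model a trained `nfd_model`.
#' @param examples labeled test examples (disjoint from training).
#' @param threshold decision threshold; default from the model config.
#' @return list with the 2x2 `confusion` matrix (rows = true class,
#'   columns = predicted), `accuracy` per class, `balanced_accuracy`,
#'   and `mean_confidence` (of uniform) per class.
#' @export
evaluate_nfd <- function(model, examples,
                         threshold = model$config$threshold) {
  labels <- vapply(examples, function(e) e$label, character(1))
  if (!all(c("uniform", "nonuniform") %in% labels))
    stopf("test set must contain both classes")
  conf <- nfd_confidences(model$layers, examples, seq_along(examples),
                          model$config)
  pred <- ifelse(conf >= threshold, "uniform", "nonuniform")
  classes <- c("uniform", "nonuniform")
  confusion <- table(factor(labels, classes), factor(pred, classes),
                     dnn = c("true", "predicted"))
  acc <- diag(confusion) / rowSums(confusion)
  mean_conf <- vapply(classes, function(cl) mean(conf[labels == cl]),
                      numeric(1))
  list(confusion = confusion, accuracy = acc,
       balanced_accuracy = mean(acc), mean_confidence = mean_conf)
}
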