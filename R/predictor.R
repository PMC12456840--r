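# Residual-network shim-weight regressor with a physics-informed loss.
#
# The network maps an encoded multi-channel B1+ slice to the real and
# imaginary parts of the per-channel shim weights.  Training does not
# regress the reference weights directly (they are only defined up to a
# global phase); instead the loss compares the excitation RMSE achieved
# by the predicted weights with the RMSE of the Adam-derived reference
# weights, differentiating through the field combination.

#' Encode a multi-channel complex slice as real input planes
#'
#' `realimag16` stacks the real parts of all channels followed by the
#' imaginary parts (2C planes; lossless).  `magphase32` additionally
#' stacks magnitude and phase planes (4C planes; phase in radians,
#' wrapped to (-pi, pi]).
#'
#' @param fields complex array `(channels, rows, cols)`.
#' @param mode `"realimag16"` or `"magphase32"`.
#' @return numeric array `(planes, rows, cols)` with attribute
#'   `encoding_mode`.
#' @export
encode_input <- function(fields, mode = c("realimag16", "magphase32")) {
  mode <- match.arg(mode)
  d <- dim(fields)
  if (length(d) != 3L) stopf("fields must be a (channels, rows, cols) array")
  C <- d[1]
  planes <- if (mode == "realimag16") 2L * C else 4L * C
  out <- array(0, c(planes, d[2], d[3]))
  out[seq_len(C), , ] <- Re(fields)
  out[C + seq_len(C), , ] <- Im(fields)
  if (mode == "magphase32") {
    out[2L * C + seq_len(C), , ] <- Mod(fields)
    out[3L * C + seq_len(C), , ] <- Arg(fields)
  }
  attr(out, "encoding_mode") <- mode
  out
}

#' Decode a network output vector into complex shim weights
#'
#' Pairs entries `(2c-1, 2c)` as the real and imaginary parts of
#' channel c, using the first `2 * n_channels` entries; surplus entries
#' (e.g. of a 32-wide head driving 8 channels) are ignored.
#'
#' @param output numeric vector (or one column of a batch matrix).
#' @param n_channels number of channels to decode.
#' @return complex weight vector of length `n_channels`.
#' @export
decode_weights <- function(output, n_channels = 8L) {
  if (length(output) < 2L * n_channels)
    stopf("output length %d cannot decode %d complex weights",
          length(output), n_channels)
  idx <- seq_len(n_channels)
  complex(real = output[2L * idx - 1L], imaginary = output[2L * idx])
}

#' Predictor configuration
#'
#' Defaults follow a ResNet18-style recipe: four stages of two basic
#' blocks with widths 64/128/256/512, Adam at an initial learning rate
#' of 1e-3 halved every 50 epochs over 200 epochs, batch size 16, and
#' an 8:1:1 train/validation/test split.  Reduced widths/epochs are
#' appropriate for CPU-scale experiments.
#'
#' @param stage_widths feature-map widths of the four stages.
#' @param blocks_per_stage residual blocks per stage.
#' @param n_channels transmit channels of the input slices.
#' @param output_dim head width; at least `2 * n_channels` (surplus
#'   entries are ignored by [decode_weights()]).
#' @param encoding_mode input encoding, see [encode_input()].
#' @param loss_form `"eq3_plain"` (mean of RMSE differences) or
#'   `"mse"` (mean squared RMSE difference).
#' @param learning_rate,lr_decay,lr_period,epochs Adam schedule: the
#'   rate is `learning_rate * lr_decay^floor((epoch-1)/lr_period)`.
#' @param batch_size minibatch size.
#' @param split_ratios train/validation/test fractions (must sum to 1).
#' @param seed seed controlling initialization, the split and batch
#'   order.
#' @return a `predictor_config` list.
#' @export
predictor_config <- function(stage_widths = c(64L, 128L, 256L, 512L),
                             blocks_per_stage = 2L, n_channels = 8L,
                             output_dim = 2L * n_channels,
                             encoding_mode = c("realimag16", "magphase32"),
                             loss_form = c("eq3_plain", "mse"),
                             learning_rate = 1e-3, lr_decay = 0.5,
                             lr_period = 50L, epochs = 200L,
                             batch_size = 16L,
                             split_ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  encoding_mode <- match.arg(encoding_mode)
  loss_form <- match.arg(loss_form)
  if (abs(sum(split_ratios) - 1) > 1e-8)
    stopf("split_ratios must sum to 1")
  if (output_dim < 2L * n_channels)
    stopf("output_dim must be at least 2 * n_channels")
  if (output_dim %% 2L != 0L) stopf("output_dim must be even")
  structure(list(stage_widths = as.integer(stage_widths),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 n_channels = as.integer(n_channels),
                 output_dim = as.integer(output_dim),
                 encoding_mode = encoding_mode, loss_form = loss_form,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 lr_period = as.integer(lr_period),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 split_ratios = split_ratios, seed = as.integer(seed)),
            class = "predictor_config")
}

#' Build an (untrained) shim-weight regression network
#'
#' @param config a [predictor_config()].
#' @return an object of class `shim_net` with the network, its
#'   configuration and a parameter count.
#' @export
build_predictor <- function(config = predictor_config()) {
  stopifnot(inherits(config, "predictor_config"))
  input_planes <- if (config$encoding_mode == "realimag16")
    2L * config$n_channels else 4L * config$n_channels
  net <- with_seed(config$seed,
                   resnet_build(input_planes, config$stage_widths,
                                config$blocks_per_stage, config$output_dim))
  # physics-informed head initialization: the untrained network starts
  # at the quadrature (CP) mode and learns the residual from there
  qb <- quadrature_weights(config$n_channels)
  bias <- rep(0, config$output_dim)
  cidx <- seq_len(config$n_channels)
  bias[2L * cidx - 1L] <- Re(qb)
  bias[2L * cidx] <- Im(qb)
  net$fc$par$b <- bias
  n_par <- sum(vapply(flatten_pars(net), length, integer(1)))
  structure(list(net = net, config = config, input_planes = input_planes,
                 n_parameters = n_par, trained = FALSE, history = NULL),
            class = "shim_net")
}

#' @export
print.shim_net <- function(x, ...) {
  cat(sprintf("<shim_net> widths %s, %d block(s)/stage, %d parameters\n",
              paste(x$config$stage_widths, collapse = "/"),
              x$config$blocks_per_stage, x$n_parameters))
  cat(sprintf("  encoding %s, output dim %d, %s\n", x$config$encoding_mode,
              x$config$output_dim,
              if (x$trained) sprintf("trained (best epoch %d, val RMSE %.3f %%)",
                                     x$best_epoch, x$best_val_rmse)
              else "untrained"))
  invisible(x)
}

#' Assemble training examples from volumes and reference shims
#'
#' Pairs each slice's encoded input with the in-mask field matrix,
#' target, and the reference (Adam upper-bound) weights and RMSE used
#' by the physics loss.
#'
#' @param volumes list of `field_volume` objects (or a single one).
#' @param references list (parallel to `volumes`) of [shim_volume()]
#'   tables carrying their `results` attribute, or of lists of
#'   `shim_result` objects.
#' @param mode input encoding, see [encode_input()].
#' @param m target magnitude; default 1.
#' @return list of training examples; each has `input`, `A`, `m`,
#'   `mbar`, `mask`, `rmse_ref`, `weights_ref`, `volume`, `slice` and a
#'   `source_id` grouping rotated copies of one source slice.
#' @export
build_examples <- function(volumes, references, mode = "realimag16", m = 1) {
  if (inherits(volumes, "field_volume")) volumes <- list(volumes)
  if (!is.list(references[[1]]) && !is.data.frame(references[[1]]))
    references <- list(references)
  examples <- list()
  for (v in seq_along(volumes)) {
    vol <- volumes[[v]]
    ref <- references[[v]]
    results <- if (is.data.frame(ref)) attr(ref, "results") else ref
    vol_id <- vol$metadata$volume_id %||% v
    for (i in seq_len(n_slices(vol))) {
      sl <- get_slice(vol, i)
      res <- results[[i]]
      if (is.null(res)) next  # flagged slice: no reference available
      A <- field_matrix(sl$fields, sl$mask)
      mv <- target_vector(m, sl$mask)
      examples[[length(examples) + 1L]] <-
        list(input = encode_input(sl$fields, mode),
             A = A, m = mv, mbar = mean(mv), mask = sl$mask,
             rmse_ref = res$rmse_percent, weights_ref = res$weights,
             volume = vol_id, slice = i,
             source_id = sprintf("v%d:s%d", vol_id, sl$source_slice))
    }
  }
  examples
}

#' Split examples into train/validation/test sets
#'
#' Splitting operates on source slices, so all rotated copies of one
#' slice land in the same subset and rotation augmentation cannot leak
#' between training and testing.
#'
#' @param examples list of examples from [build_examples()].
#' @param ratios train/validation/test fractions summing to 1.
#' @param seed split seed.
#' @return list of integer index vectors `train`, `val`, `test`;
#'   disjoint and exhaustive.
#' @export
split_dataset <- function(examples, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8) stopf("split ratios must sum to 1")
  if (length(examples) < 10L) stopf("dataset too small to split (need >= 10 slices)")
  src <- vapply(examples, function(e) e$source_id, character(1))
  ids <- unique(src)
  n <- length(ids)
  counts <- diff(c(0L, round(cumsum(ratios) * n)))
  perm <- with_seed(seed, sample(ids))
  groups <- rep(c("train", "val", "test"), counts)
  assign <- stats::setNames(groups, perm)
  list(train = unname(which(assign[src] == "train")),
       val = unname(which(assign[src] == "val")),
       test = unname(which(assign[src] == "test")))
}

stack_inputs <- function(examples, idx) {
  d <- dim(examples[[idx[1]]]$input)
  x <- array(0, c(d, length(idx)))
  for (j in seq_along(idx)) x[, , , j] <- examples[[idx[j]]]$input
  x
}

# RMSE (as % of target FA) of predicted weights plus its gradient with
# respect to the raw network outputs; vectorized over a batch.
physics_terms <- function(out_mat, batch, n_channels, want_grad = TRUE) {
  B <- length(batch)
  D <- nrow(out_mat)
  rmse <- numeric(B)
  dout <- if (want_grad) matrix(0, D, B) else NULL
  for (i in seq_len(B)) {
    ex <- batch[[i]]
    b <- decode_weights(out_mat[, i], n_channels)
    f <- as.vector(ex$A %*% b)
    mag <- Mod(f)
    r <- mag - ex$m
    N <- length(r)
    S <- sum(r * r)
    rmse[i] <- 100 * sqrt(S / N) / ex$mbar
    if (want_grad) {
      if (S > 0) {
        phase <- ifelse(mag > 0, f / mag, 0 + 0i)
        g <- 2 * as.vector(Conj(t(ex$A)) %*% (r * phase))
        dS <- 100 / (2 * ex$mbar * sqrt(S * N))
        idx <- seq_len(n_channels)
        dout[2L * idx - 1L, i] <- dS * Re(g)
        dout[2L * idx, i] <- dS * Im(g)
      }
    }
  }
  list(rmse = rmse, dout = dout)
}

#' Physics-informed training loss
#'
#' Compares the excitation RMSE achieved by predicted weights with the
#' reference RMSE, slice by slice.  The default `eq3_plain` form is the
#' mean over the batch of `RMSE_pred(i) - RMSE_ref(i)`; the `mse` form
#' is the mean of squared differences.  Both are differentiable through
#' the field combination.  Examples with an empty mask are excluded
#' with a warning.
#'
#' @param predicted_weights complex matrix `(channels, batch)` or a
#'   list of weight vectors.
#' @param batch list of examples from [build_examples()].
#' @param form `"eq3_plain"` or `"mse"`.
#' @return scalar loss.
#' @export
physics_loss <- function(predicted_weights, batch,
                         form = c("eq3_plain", "mse")) {
  form <- match.arg(form)
  if (is.list(predicted_weights))
    predicted_weights <- do.call(cbind, predicted_weights)
  if (length(batch) == 0L) stopf("batch must be non-empty")
  keep <- vapply(batch, function(e) nrow(e$A) > 0L, logical(1))
  if (!all(keep)) {
    warning(sprintf("%d example(s) with empty mask excluded", sum(!keep)),
            call. = FALSE)
    batch <- batch[keep]
    predicted_weights <- predicted_weights[, keep, drop = FALSE]
  }
  C <- nrow(predicted_weights)
  out_mat <- matrix(0, 2L * C, ncol(predicted_weights))
  idx <- seq_len(C)
  out_mat[2L * idx - 1L, ] <- Re(predicted_weights)
  out_mat[2L * idx, ] <- Im(predicted_weights)
  terms <- physics_terms(out_mat, batch, C, want_grad = FALSE)
  ref <- vapply(batch, function(e) e$rmse_ref, numeric(1))
  diffs <- terms$rmse - ref
  if (form == "eq3_plain") mean(diffs) else mean(diffs^2)
}

#' Train the shim-weight regressor
#'
#' Minimizes the physics-informed loss with Adam under the configured
#' step-decay schedule, tracking validation mean RMSE per epoch and
#' checkpointing the best-validation parameters.  Fully seeded: the
#' split, initialization and batch order all derive from
#' `config$seed`.  A non-finite training loss aborts with the last
#' good checkpoint.
#'
#' @param examples list of examples from [build_examples()].
#' @param config a [predictor_config()].
#' @param splits optional list (`train`, `val`, `test`) of example
#'   indices; default [split_dataset()] under the config ratios/seed.
#' @return a trained `shim_net`; `$history` holds per-epoch training
#'   loss, validation mean RMSE and learning rate, `$splits` the index
#'   sets used.
#' @export
train_predictor <- function(examples, config = predictor_config(),
                            splits = NULL) {
  if (is.null(splits))
    splits <- split_dataset(examples, config$split_ratios, config$seed)
  model <- build_predictor(config)
  net <- model$net
  flat <- flatten_pars(net)
  state <- adam_state_init(flat)
  Cch <- config$n_channels
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_rmse = numeric(), lr = numeric())
  best <- list(net = net, val = Inf, epoch = 0L)
  aborted <- FALSE

  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      config$lr_decay^((epoch - 1L) %/% config$lr_period)
    order <- with_seed(derive_seed(config$seed, 100L + epoch),
                       sample(splits$train))
    n_batches <- ceiling(length(order) / config$batch_size)
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      idx <- order[((bi - 1L) * config$batch_size + 1L):
                     min(bi * config$batch_size, length(order))]
      x <- stack_inputs(examples, idx)
      fw <- resnet_fwd(net, x, training = TRUE)
      net <- fw$net
      batch <- examples[idx]
      terms <- physics_terms(fw$out, batch, Cch)
      ref <- vapply(batch, function(e) e$rmse_ref, numeric(1))
      diffs <- terms$rmse - ref
      if (config$loss_form == "eq3_plain") {
        loss <- mean(diffs)
        dloss <- rep(1 / length(idx), length(idx))
      } else {
        loss <- mean(diffs^2)
        dloss <- 2 * diffs / length(idx)
      }
      if (!is.finite(loss)) { aborted <- TRUE; break }
      dout <- sweep(terms$dout, 2, dloss, `*`)
      grads <- resnet_bwd(net, fw$cache, dout)
      upd <- adam_apply(flat, grads, state, lr)
      flat <- upd$flat
      state <- upd$state
      net <- set_pars(net, flat)
      epoch_loss <- epoch_loss + loss / n_batches
    }
    if (aborted) {
      warning("non-finite training loss; returning last good checkpoint",
              call. = FALSE)
      break
    }
    val_rmse <- if (length(splits$val) > 0)
      mean(predict_rmse(net, examples, splits$val, Cch)) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss,
                                         val_rmse = val_rmse, lr = lr))
    if (is.finite(val_rmse) && val_rmse < best$val)
      best <- list(net = net, val = val_rmse, epoch = epoch)
  }

  if (!is.finite(best$val) || best$epoch == 0L)
    best <- list(net = net, val = NA_real_, epoch = nrow(history))
  model$net <- best$net
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best$epoch
  model$best_val_rmse <- best$val
  model$splits <- splits
  model
}

# Mean predicted RMSE over example indices (evaluation mode, batched).
predict_rmse <- function(net, examples, idx, n_channels, batch_size = 32L) {
  out <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = batch_size)) {
    take <- idx[start:min(start + batch_size - 1L, length(idx))]
    x <- stack_inputs(examples, take)
    fw <- resnet_fwd(net, x, training = FALSE)
    terms <- physics_terms(fw$out, examples[take], n_channels,
                           want_grad = FALSE)
    out[(start:(start + length(take) - 1L)) - 0L] <- terms$rmse
  }
  out
}

#' Predict shim weights for one slice
#'
#' Single forward pass through the trained network; the returned
#' `shim_result` carries the RMSE recomputed from the predicted
#' weights by the shimming core.
#'
#' @param object a trained `shim_net`.
#' @param fields complex array `(channels, rows, cols)`.
#' @param mask logical region-of-interest mask.
#' @param m target magnitude; default 1.
#' @param ... unused.
#' @return a `shim_result` with method `"resnet"`.
#' @export
predict.shim_net <- function(object, fields, mask, m = 1, ...) {
  if (!object$trained) stopf("model has not been trained")
  d <- dim(fields)
  if (d[1] != object$config$n_channels)
    stopf("field has %d channels; model expects %d", d[1],
          object$config$n_channels)
  t0 <- proc.time()[["elapsed"]]
  x <- encode_input(fields, object$config$encoding_mode)
  x <- array(x, c(dim(x), 1L))
  fw <- resnet_fwd(object$net, x, training = FALSE)
  b <- decode_weights(fw$out[, 1], object$config$n_channels)
  check_mask(mask)
  lam <- resolve_lambda(NULL, sum(mask), d[1])
  make_shim_result(fields, mask, m, b, lam, "resnet",
                   seconds = proc.time()[["elapsed"]] - t0)
}

#' Evaluate a trained predictor against baselines
#'
#' Computes the per-slice RMSE of the network on the given examples and
#' aligns it with the stored reference (Adam upper-bound) RMSE and any
#' additional per-slice baseline tables, reporting means, quartiles and
#' paired differences.
#'
#' @param model a trained `shim_net`.
#' @param examples list of examples from [build_examples()].
#' @param idx indices to evaluate (e.g. `model$splits$test`).
#' @param baselines optional named list of per-slice RMSE vectors
#'   aligned with `examples` (e.g. quadrature and variable-exchange
#'   results).
#' @return list with `table` (per-slice RMSEs), `summary` (per-method
#'   mean and quartiles) and `paired` (mean paired differences vs the
#'   network).
#' @export
evaluate_predictor <- function(model, examples, idx = NULL,
                               baselines = NULL) {
  if (is.null(idx)) idx <- model$splits$test
  rmse_net <- predict_rmse(model$net, examples, idx,
                           model$config$n_channels)
  tab <- data.frame(example = idx,
                    volume = vapply(examples[idx],
                                    function(e) as.numeric(e$volume),
                                    numeric(1)),
                    slice = vapply(examples[idx],
                                   function(e) as.numeric(e$slice),
                                   numeric(1)),
                    resnet = rmse_net,
                    reference = vapply(examples[idx],
                                       function(e) as.numeric(e$rmse_ref),
                                       numeric(1)))
  if (!is.null(baselines))
    for (nm in names(baselines)) tab[[nm]] <- baselines[[nm]][idx]
  methods <- setdiff(names(tab), c("example", "volume", "slice"))
  summ <- do.call(rbind, lapply(methods, function(mth) {
    q <- stats::quantile(tab[[mth]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(method = mth, mean = mean(tab[[mth]]), q25 = q[1],
               median = q[2], q75 = q[3])
  }))
  paired <- vapply(setdiff(methods, "resnet"),
                   function(mth) mean(tab$resnet - tab[[mth]]), numeric(1))
  list(table = tab, summary = summ, paired = paired)
}
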