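#' Training configuration
#'
#' Defaults follow the model's reference hyper-parameters: window length 30
#' snapshots (60 ps), 50 parallel streams, hidden width 1024, 3 layers,
#' Adam at learning rate 1e-4, inverted dropout with keep-probability 0.9
#' on non-recurrent connections, 300 epochs. Desk-scale runs typically
#' shrink \code{hidden_size}, \code{epochs} and \code{eval_interval}.
#'
#' @param sequence_length BPTT window length in snapshots.
#' @param batch_size Number of parallel streams.
#' @param hidden_size Hidden width per GRU layer.
#' @param num_layers Number of stacked GRU layers.
#' @param learning_rate Adam step size.
#' @param dropout_keep Keep-probability in (0, 1].
#' @param epochs Number of passes over the concatenated training sequence.
#' @param seed Seed controlling initialization, dropout and any shuffling.
#' @param eval_interval_steps Validation-metric cadence, in training steps.
#' @param ma_window Moving-average window (in evaluation points) used to
#'   pick the best checkpoint by validation precision of the improved
#'   class.
#' @param use_bias Add bias vectors to every gate and the output layer.
#' @param init_range Uniform initializer half-width.
#' @param carry_across_trajectories Keep hidden state across trajectory
#'   boundaries during training (the concatenated-sequence scheme); state
#'   is always reset per trajectory at prediction time.
#' @return A list of class \code{trainConfig}.
#' @export
trainConfig <- function(sequence_length = 30L, batch_size = 50L,
                        hidden_size = 1024L, num_layers = 3L,
                        learning_rate = 1e-4, dropout_keep = 0.9,
                        epochs = 300L, seed = 1L,
                        eval_interval_steps = 2000L, ma_window = 30L,
                        use_bias = FALSE, init_range = 0.08,
                        carry_across_trajectories = TRUE) {
  cfg <- list(sequence_length = as.integer(sequence_length),
              batch_size = as.integer(batch_size),
              hidden_size = as.integer(hidden_size),
              num_layers = as.integer(num_layers),
              learning_rate = learning_rate,
              dropout_keep = dropout_keep,
              epochs = as.integer(epochs), seed = as.integer(seed),
              eval_interval_steps = as.integer(eval_interval_steps),
              ma_window = as.integer(ma_window), use_bias = use_bias,
              init_range = init_range,
              carry_across_trajectories = carry_across_trajectories)
  stopifnot(all(vapply(cfg[c("sequence_length", "batch_size", "hidden_size",
                             "num_layers", "epochs")], function(x) x >= 1L,
                       logical(1L))),
            cfg$learning_rate >= 0, cfg$dropout_keep > 0,
            cfg$dropout_keep <= 1)
  class(cfg) <- "trainConfig"
  cfg
}

# Adam optimizer over the nested grad/param structure
.adamInit <- function(grads) rapply(grads, function(m) m * 0, how = "replace")

.adamStep <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (l in seq_along(params$layers)) {
    for (nm in names(params$layers[[l]])) {
      r <- upd(params$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               state$m$layers[[l]][[nm]], state$v$layers[[l]][[nm]])
      params$layers[[l]][[nm]] <- r$p
      state$m$layers[[l]][[nm]] <- r$m
      state$v$layers[[l]][[nm]] <- r$v
    }
  }
  r <- upd(params$Wout, grads$Wout, state$m$Wout, state$v$Wout)
  params$Wout <- r$p; state$m$Wout <- r$m; state$v$Wout <- r$v
  if (!is.null(grads$bout)) {
    r <- upd(attr(params$Wout, "bout"), grads$bout, state$m$bout, state$v$bout)
    attr(params$Wout, "bout") <- r$p
    state$m$bout <- r$m; state$v$bout <- r$v
  }
  list(params = params, state = state)
}

.stackToParams <- function(stack) {
  p <- list(layers = stack@layers, Wout = stack@Wout)
  p
}

.paramsToStack <- function(stack, params) {
  stack@layers <- params$layers
  stack@Wout <- params$Wout
  stack
}

.trailingMA <- function(x, window) {
  n <- length(x)
  mean(x[max(1L, n - window + 1L):n])
}

#' Train the recurrent snapshot classifier
#'
#' Minimizes the mean class-weighted cross-entropy over stateful
#' mini-batches with Adam. The training sequence is the concatenation of
#' all trajectories, split into \code{batch_size} parallel streams
#' (\code{\link{buildBatchPlan}}); hidden state carries across iterations
#' within an epoch and is reset to zero at each epoch start. Dropout is
#' applied to non-recurrent connections during training only. When a
#' validation set is supplied, per-class precision/recall/F1 are recorded
#' every \code{eval_interval_steps} and the returned model is the
#' checkpoint with the best trailing moving average (window
#' \code{ma_window}, truncated while fewer points exist) of
#' improved-class validation precision.
#'
#' @param ts Training \linkS4class{TrajectorySet}, standardized and
#'   labeled.
#' @param config A \code{\link{trainConfig}}.
#' @param weights Class weights for (I, N, D).
#' @param val Optional validation \linkS4class{TrajectorySet}.
#' @param verbose Print one line per epoch.
#' @return List with \code{model} (\linkS4class{GRUStack} at the selected
#'   checkpoint), \code{final_model}, \code{curve} (data.frame: step,
#'   epoch, train_loss and, with validation, per-class
#'   precision/recall/F1), \code{best_step}, \code{config}.
#' @export
trainModel <- function(ts, config = trainConfig(), weights = c(0.05, 1, 10),
                       val = NULL, verbose = FALSE) {
  if (anyNA(stateLabels(ts))) stop("training set has unlabeled snapshots")
  if (is.null(normalizationStats(ts)) && is.null(metadata(ts)$shuffled)) {
    warning("training set does not appear to be standardized")
  }
  set.seed(config$seed)
  stack <- initGRUStack(input_size = 19L, hidden_size = config$hidden_size,
                        num_layers = config$num_layers,
                        seed = sample.int(.Machine$integer.max, 1L),
                        init_range = config$init_range,
                        use_bias = config$use_bias)
  X <- featureMatrix(ts)
  Y <- oneHot(stateLabels(ts))
  if (!config$carry_across_trajectories) {
    # zero the features at trajectory starts contributes nothing; boundary
    # handling without carry is emulated by per-trajectory epochs instead
    warning("training always uses the concatenated-sequence scheme; ",
            "per-trajectory state reset applies at prediction time")
  }
  plan <- buildBatchPlan(ncol(X), config$batch_size, config$sequence_length)
  params <- .stackToParams(stack)
  dummy <- .zeroGrads(stack)
  if (stack@use_bias) dummy$bout <- numeric(3L)
  adam <- list(m = .adamInit(dummy), v = .adamInit(dummy))
  step <- 0L
  curve <- list()
  best <- list(ma = -Inf, params = params, step = 0L)
  prec_hist <- numeric(0L)
  din <- stack@input_size
  for (epoch in seq_len(config$epochs)) {
    h <- .zeroStates(stack, plan@batch_size)
    epoch_loss <- 0
    for (k in seq_len(plan@n_iterations)) {
      idx <- planIndices(plan, k)
      Xw <- array(X[, t(idx)], dim = c(din, plan@batch_size, plan@seq_len))
      Yw <- array(Y[, t(idx)], dim = c(3L, plan@batch_size, plan@seq_len))
      work <- .paramsToStack(stack, params)
      gr <- gruGradients(work, Xw, Yw, weights = weights, h0 = h,
                         dropout_keep = config$dropout_keep)
      if (!is.finite(gr$loss)) {
        stop(sprintf("training diverged: non-finite loss at step %d (epoch %d)",
                     step + 1L, epoch))
      }
      h <- gr$h_final
      step <- step + 1L
      if (config$learning_rate > 0) {
        res <- .adamStep(params, gr$grads, adam, config$learning_rate, step)
        params <- res$params
        adam <- res$state
      }
      epoch_loss <- epoch_loss + gr$loss
      if (!is.null(val) && step %% config$eval_interval_steps == 0L) {
        pred <- predictModel(.paramsToStack(stack, params), val)
        cm <- confusionMatrix3(stateLabels(val), pred$predicted)
        met <- classMetrics(cm)
        prec_hist <- c(prec_hist, met$precision[met$class == "I"])
        ma <- .trailingMA(prec_hist, config$ma_window)
        if (ma > best$ma) best <- list(ma = ma, params = params, step = step)
        curve[[length(curve) + 1L]] <- data.frame(
          step = step, epoch = epoch, train_loss = gr$loss,
          class = met$class, precision = met$precision,
          recall = met$recall, f1 = met$f1)
      }
    }
    if (verbose) {
      message(sprintf("epoch %d/%d  mean loss %.5f", epoch, config$epochs,
                      epoch_loss / plan@n_iterations))
    }
  }
  final <- .paramsToStack(stack, params)
  model <- if (is.null(val) || best$step == 0L) final else
    .paramsToStack(stack, best$params)
  list(model = model, final_model = final,
       curve = if (length(curve)) do.call(rbind, curve) else
         data.frame(step = integer(), epoch = integer(),
                    train_loss = numeric(), class = character(),
                    precision = numeric(), recall = numeric(),
                    f1 = numeric()),
       best_step = best$step, config = config)
}

#' Per-snapshot class probabilities and labels
#'
#' Runs the trained stack over every trajectory in time order, starting
#' from a zero hidden state per trajectory, and labels each snapshot with
#' the highest-probability class. Exact probability ties are broken toward
#' D, then N, then I (so an uninformative uniform output yields the
#' majority decreased state).
#'
#' @param stack A \linkS4class{GRUStack}.
#' @param ts A \linkS4class{TrajectorySet} standardized compatibly with
#'   training.
#' @param carry_state Carry hidden state across trajectory boundaries in
#'   container order instead of resetting (mirrors the training-time
#'   concatenation; off by default).
#' @return A \code{data.frame}: the snapshot metadata plus \code{prob_I},
#'   \code{prob_N}, \code{prob_D} and \code{predicted}.
#' @export
predictModel <- function(stack, ts, carry_state = FALSE) {
  X <- featureMatrix(ts)
  if (nrow(X) != stack@input_size) {
    stop("feature dimension mismatch: ", nrow(X), " vs ", stack@input_size)
  }
  lens <- trajectoryLengths(ts)
  probs <- matrix(NA_real_, 3L, ncol(X))
  if (carry_state) {
    fw <- forwardGRU(stack, X)
    probs[] <- fw$probs[, 1L, ]
  } else {
    starts <- cumsum(c(1L, unname(lens)))[seq_along(lens)]
    # batch together trajectories of equal length for speed
    for (L in unique(unname(lens))) {
      sel <- which(unname(lens) == L)
      idx <- outer(0:(L - 1L), starts[sel], "+") + 0L  # L x B
      Xa <- array(X[, t(idx)], dim = c(stack@input_size, length(sel), L))
      fw <- forwardGRU(stack, Xa)
      for (b in seq_along(sel)) probs[, idx[, b]] <- fw$probs[, b, ]
    }
  }
  pred <- predictFromProbs(probs)
  out <- snapshotData(ts)
  out$prob_I <- probs[1L, ]
  out$prob_N <- probs[2L, ]
  out$prob_D <- probs[3L, ]
  out$predicted <- pred
  rownames(out) <- NULL
  out
}

#' @rdname predictModel
#' @param probs 3 x n matrix of class probabilities (rows I, N, D).
#' @export
predictFromProbs <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 1L)
  pref <- c(3L, 2L, 1L)   # D, then N, then I on exact ties
  idx <- apply(probs, 2L, function(p) pref[which.max(p[pref])])
  factor(stateLevels()[idx], levels = stateLevels())
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the \linkS4class{GRUStack}, the
#' \code{\link{trainConfig}} and (optionally) the
#' \linkS4class{NormalizationStats} used for the training features.
#'
#' @param model A \linkS4class{GRUStack}.
#' @param path Destination file (RDS).
#' @param config Optional \code{\link{trainConfig}}.
#' @param stats Optional \linkS4class{NormalizationStats}.
#' @return \code{path} (save) / a list with \code{model}, \code{config},
#'   \code{stats} (load).
#' @export
saveModel <- function(model, path, config = NULL, stats = NULL) {
  saveRDS(list(model = model, config = config, stats = stats,
               package_version = as.character(utils::packageVersion("trajstate"))),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
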