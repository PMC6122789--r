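#' GRUStack: parameters of the stacked GRU classifier
#'
#' Each layer holds six weight matrices: \code{W}, \code{U} for the
#' candidate state, \code{Wr}, \code{Ur} for the reset gate and \code{Wz},
#' \code{Uz} for the update gate (shapes hidden x input and hidden x
#' hidden). \code{Wout} (3 x hidden) maps the last hidden layer to class
#' logits, normalized by a softmax. Biases are off by default; when
#' \code{use_bias} is set, \code{bc}, \code{br}, \code{bz} per layer and
#' \code{bout} are added.
#'
#' @aliases GRUStack
#' @export
setClass("GRUStack",
         representation(layers = "list", Wout = "matrix",
                        input_size = "integer", hidden_size = "integer",
                        num_layers = "integer", use_bias = "logical"))

setValidity("GRUStack", function(object) {
  if (length(object@layers) != object@num_layers) return("layer count mismatch")
  h <- object@hidden_size
  for (l in seq_along(object@layers)) {
    p <- object@layers[[l]]
    din <- if (l == 1L) object@input_size else h
    for (nm in c("W", "Wr", "Wz")) {
      if (!identical(dim(p[[nm]]), c(h, din))) {
        return(sprintf("layer %d: %s must be %d x %d", l, nm, h, din))
      }
    }
    for (nm in c("U", "Ur", "Uz")) {
      if (!identical(dim(p[[nm]]), c(h, h))) {
        return(sprintf("layer %d: %s must be %d x %d", l, nm, h, h))
      }
    }
    if (!all(vapply(p, function(m) all(is.finite(m)), logical(1L)))) {
      return(sprintf("layer %d has non-finite entries", l))
    }
  }
  if (nrow(object@Wout) != 3L) return("Wout must have 3 class rows")
  if (ncol(object@Wout) != h) return("Wout column count mismatch")
  TRUE
})

setMethod("show", "GRUStack", function(object) {
  cat("GRUStack:", object@num_layers, "layer(s), hidden", object@hidden_size,
      ", input", object@input_size,
      if (object@use_bias) ", with biases" else ", no biases", "\n")
})

#' Initialize a GRU stack
#'
#' Weights are drawn i.i.d. uniform on \code{[-init_range, init_range]}.
#'
#' @param input_size Number of input features (19 for snapshot tables).
#' @param hidden_size Hidden state width per layer.
#' @param num_layers Number of stacked GRU layers.
#' @param seed Integer seed for the initialization draw.
#' @param init_range Half-width of the uniform initializer.
#' @param use_bias Add bias vectors (off by default: the model as defined
#'   carries none).
#' @param zero Set all weights to zero (for closed-form checks).
#' @return A \linkS4class{GRUStack}.
#' @export
initGRUStack <- function(input_size = 19L, hidden_size = 64L, num_layers = 3L,
                         seed = 1L, init_range = 0.08, use_bias = FALSE,
                         zero = FALSE) {
  set.seed(seed)
  rmat <- function(r, c) {
    if (zero) matrix(0, r, c) else
      matrix(stats::runif(r * c, -init_range, init_range), r, c)
  }
  layers <- vector("list", num_layers)
  for (l in seq_len(num_layers)) {
    din <- if (l == 1L) input_size else hidden_size
    layers[[l]] <- list(W = rmat(hidden_size, din), U = rmat(hidden_size, hidden_size),
                        Wr = rmat(hidden_size, din), Ur = rmat(hidden_size, hidden_size),
                        Wz = rmat(hidden_size, din), Uz = rmat(hidden_size, hidden_size))
    if (use_bias) {
      layers[[l]]$bc <- numeric(hidden_size)
      layers[[l]]$br <- numeric(hidden_size)
      layers[[l]]$bz <- numeric(hidden_size)
    }
  }
  obj <- new("GRUStack", layers = layers, Wout = rmat(3L, hidden_size),
             input_size = as.integer(input_size),
             hidden_size = as.integer(hidden_size),
             num_layers = as.integer(num_layers), use_bias = use_bias)
  if (use_bias) attr(obj@Wout, "bout") <- numeric(3L)
  obj
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Column-wise softmax
#'
#' @param logits Numeric matrix (classes x batch) or vector.
#' @return Matrix of the same shape; every column sums to 1.
#' @export
softmaxCols <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, ncol = 1L)
  e <- exp(sweep(logits, 2L, apply(logits, 2L, max)))
  sweep(e, 2L, colSums(e), "/")
}

# one GRU cell step; x (din x B), h_prev (h x B); returns gates for backprop
.gruCellFull <- function(x, h_prev, p, use_bias = FALSE) {
  az <- p$Wz %*% x + p$Uz %*% h_prev
  ar <- p$Wr %*% x + p$Ur %*% h_prev
  if (use_bias) { az <- az + p$bz; ar <- ar + p$br }
  z <- .sigmoid(az)
  r <- .sigmoid(ar)
  ac <- p$W %*% x + p$U %*% (r * h_prev)
  if (use_bias) ac <- ac + p$bc
  htilde <- tanh(ac)
  list(h = z * h_prev + (1 - z) * htilde, z = z, r = r, htilde = htilde)
}

#' One GRU cell update
#'
#' Computes the update gate \code{z = sigma(Wz x + Uz h)}, reset gate
#' \code{r = sigma(Wr x + Ur h)}, candidate \code{htilde = tanh(W x +
#' U (r * h))} and the new state \code{z * h + (1 - z) * htilde}.
#'
#' @param x Input vector (or matrix, columns = batch).
#' @param h_prev Previous hidden state (same batch layout).
#' @param params A single layer's parameter list (see
#'   \linkS4class{GRUStack}).
#' @param use_bias Whether the layer carries bias vectors.
#' @return The new hidden state, same shape as \code{h_prev}.
#' @export
gruCell <- function(x, h_prev, params, use_bias = FALSE) {
  vec <- is.null(dim(h_prev))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (is.null(dim(h_prev))) h_prev <- matrix(h_prev, ncol = 1L)
  if (nrow(x) != ncol(params$W)) {
    stop("dimension mismatch: input length ", nrow(x), ", expected ",
         ncol(params$W))
  }
  h <- .gruCellFull(x, h_prev, params, use_bias)$h
  if (vec) as.numeric(h) else h
}

.zeroStates <- function(stack, batch) {
  lapply(seq_len(stack@num_layers),
         function(l) matrix(0, stack@hidden_size, batch))
}

# X: input_size x B x T array (or matrix input_size x T => B = 1)
.asInputArray <- function(X, input_size) {
  if (length(dim(X)) == 3L) return(X)
  if (is.null(dim(X))) X <- matrix(X, nrow = input_size)
  array(X, dim = c(nrow(X), 1L, ncol(X)))
}

#' Forward pass through the GRU stack
#'
#' Runs the stacked GRU over a sequence; layer l at time t consumes the
#' state of layer l - 1 (layer 1 consumes the input features) and the
#' softmax output layer turns the last layer's state into a probability
#' vector per snapshot. Final per-layer states are returned so a sequence
#' can be processed in stateful chunks.
#'
#' @param stack A \linkS4class{GRUStack}.
#' @param X Inputs: a features x time matrix, or a features x batch x time
#'   array.
#' @param h0 Optional list of per-layer initial states (hidden x batch);
#'   zeros when omitted.
#' @param dropout_keep Keep-probability for inverted dropout on the
#'   non-recurrent connections (layer inputs and the pre-softmax state);
#'   1 disables it. Masks are resampled every timestep. Training-time
#'   only; prediction uses 1.
#' @param masks Optional list of pre-sampled per-timestep mask sets
#'   (internal use; recycled over time).
#' @param cache Keep intermediate activations for backpropagation
#'   (internal use).
#' @return List with \code{probs} (3 x batch x time array; each column
#'   sums to 1), \code{h_final} (list of per-layer states), and
#'   \code{cache} when requested.
#' @export
forwardGRU <- function(stack, X, h0 = NULL, dropout_keep = 1,
                       masks = NULL, cache = FALSE) {
  X <- .asInputArray(X, stack@input_size)
  B <- dim(X)[2L]; Tn <- dim(X)[3L]
  if (dim(X)[1L] != stack@input_size) {
    stop("dimension mismatch: ", dim(X)[1L], " features, expected ",
         stack@input_size)
  }
  h <- if (is.null(h0)) .zeroStates(stack, B) else lapply(h0, function(m) {
    if (is.null(dim(m))) matrix(m, ncol = B) else m
  })
  nl <- stack@num_layers
  use_dropout <- dropout_keep < 1
  probs <- array(0, dim = c(3L, B, Tn))
  cc <- if (cache) list(layers = vector("list", Tn), out = vector("list", Tn),
                        masks = vector("list", Tn), X = X) else NULL
  for (t in seq_len(Tn)) {
    xin <- X[, , t, drop = FALSE]; dim(xin) <- c(dim(X)[1L], B)
    # dropout masks are resampled every timestep (non-recurrent
    # connections only); pre-supplied masks are reused in order
    mt <- if (!use_dropout) NULL else if (is.null(masks)) {
      sampleDropoutMasks(stack, B, dropout_keep)
    } else {
      masks[[((t - 1L) %% length(masks)) + 1L]]
    }
    step_cache <- if (cache) vector("list", nl) else NULL
    for (l in seq_len(nl)) {
      xl <- if (use_dropout) xin * mt$input[[l]] else xin
      st <- .gruCellFull(xl, h[[l]], stack@layers[[l]], stack@use_bias)
      if (cache) {
        step_cache[[l]] <- list(x = xl, h_prev = h[[l]], z = st$z, r = st$r,
                                htilde = st$htilde)
      }
      h[[l]] <- st$h
      xin <- st$h
    }
    o <- if (use_dropout) xin * mt$out else xin
    logits <- stack@Wout %*% o
    if (stack@use_bias) logits <- logits + attr(stack@Wout, "bout")
    probs[, , t] <- softmaxCols(logits)
    if (cache) {
      cc$layers[[t]] <- step_cache; cc$out[[t]] <- o; cc$masks[[t]] <- mt
    }
  }
  dimnames(probs) <- list(stateLevels(), NULL, NULL)
  out <- list(probs = probs, h_final = h)
  if (cache) out$cache <- cc
  out
}

#' @rdname forwardGRU
#' @param B Batch width for which to sample masks.
#' @export
sampleDropoutMasks <- function(stack, B, dropout_keep) {
  mk <- function(r) matrix(stats::rbinom(r * B, 1L, dropout_keep), r, B) / dropout_keep
  list(input = lapply(seq_len(stack@num_layers), function(l) {
    mk(if (l == 1L) stack@input_size else stack@hidden_size)
  }), out = mk(stack@hidden_size))
}

#' Class-weighted cross-entropy loss
#'
#' \eqn{L = -\sum_j \omega_j y'_j \log y_j} for one-hot truth \eqn{y'} and
#' predicted probabilities \eqn{y}. The default weights
#' \code{c(0.05, 1, 10)} for (I, N, D) push the classifier toward high
#' precision on improved states and high recall on decreased states.
#' Probabilities are clipped to \code{[1e-12, 1]}.
#'
#' @param y_true One-hot vector, or a 3 x n matrix of one-hot columns, or a
#'   label factor/character vector.
#' @param y_pred Probability vector or 3 x n matrix of probability columns.
#' @param weights Positive class weights for (I, N, D).
#' @return Per-sample loss values (scalar for a single sample).
#' @export
weightedCrossEntropy <- function(y_true, y_pred, weights = c(0.05, 1, 10)) {
  if (any(weights <= 0)) stop("class weights must be positive")
  if (is.character(y_true) || is.factor(y_true)) y_true <- oneHot(y_true)
  if (is.null(dim(y_true))) y_true <- matrix(y_true, ncol = 1L)
  if (is.null(dim(y_pred))) y_pred <- matrix(y_pred, ncol = 1L)
  y_pred <- pmin(pmax(y_pred, 1e-12), 1)
  out <- -colSums(weights * y_true * log(y_pred))
  if (length(out) == 1L) out[[1L]] else out
}

# ---- backward pass ---------------------------------------------------------

.zeroGrads <- function(stack) {
  g <- list(layers = lapply(stack@layers, function(p) {
    lapply(p, function(m) if (is.matrix(m)) matrix(0, nrow(m), ncol(m)) else numeric(length(m)))
  }), Wout = matrix(0, nrow(stack@Wout), ncol(stack@Wout)))
  if (stack@use_bias) g$bout <- numeric(3L)
  g
}

#' Gradients of the weighted cross-entropy through the GRU stack
#'
#' Truncated backpropagation through time over one window: the state the
#' window starts from is treated as a constant.
#'
#' @param stack A \linkS4class{GRUStack}.
#' @param X Inputs (see \code{\link{forwardGRU}}).
#' @param Y One-hot targets, 3 x time matrix or 3 x batch x time array.
#' @param weights Class weights (see \code{\link{weightedCrossEntropy}}).
#' @param h0 Optional initial states.
#' @param dropout_keep,masks Dropout configuration, as in
#'   \code{\link{forwardGRU}}.
#' @return List with \code{grads} (same shapes as the stack parameters),
#'   \code{loss} (mean weighted cross-entropy over the window),
#'   \code{h_final}.
#' @export
gruGradients <- function(stack, X, Y, weights = c(0.05, 1, 10), h0 = NULL,
                         dropout_keep = 1, masks = NULL) {
  X <- .asInputArray(X, stack@input_size)
  B <- dim(X)[2L]; Tn <- dim(X)[3L]
  Y <- .asInputArray(Y, 3L)
  fw <- forwardGRU(stack, X, h0 = h0, dropout_keep = dropout_keep,
                   masks = masks, cache = TRUE)
  cc <- fw$cache
  nl <- stack@num_layers
  nsamp <- B * Tn
  use_dropout <- dropout_keep < 1
  g <- .zeroGrads(stack)
  dh_next <- .zeroStates(stack, B)   # gradient wrt h_t^l flowing from t+1
  loss <- 0
  for (t in rev(seq_len(Tn))) {
    mt <- if (use_dropout) cc$masks[[t]] else NULL
    yt <- Y[, , t, drop = FALSE]; dim(yt) <- c(3L, B)
    pt <- fw$probs[, , t, drop = FALSE]; dim(pt) <- c(3L, B)
    wsel <- colSums(weights * yt)     # omega of the true class, per column
    loss <- loss + sum(-wsel * log(pmax(colSums(yt * pt), 1e-12)))
    # d L / d logits for weighted CE with one-hot truth
    dlog <- sweep(pt, 2L, wsel, "*") - weights * yt
    dlog <- dlog / nsamp
    o <- cc$out[[t]]
    g$Wout <- g$Wout + dlog %*% t(o)
    if (stack@use_bias) g$bout <- g$bout + rowSums(dlog)
    dtop <- t(stack@Wout) %*% dlog
    if (use_dropout) dtop <- dtop * mt$out
    for (l in rev(seq_len(nl))) {
      s <- cc$layers[[t]][[l]]
      p <- stack@layers[[l]]
      # dtop holds the gradient arriving at h_t^l from the layer above
      # (or the output layer when l is the top layer)
      dh <- dh_next[[l]] + dtop
      dz <- dh * (s$h_prev - s$htilde)
      dht <- dh * (1 - s$z)
      dh_prev <- dh * s$z
      dac <- dht * (1 - s$htilde^2)
      gl <- g$layers[[l]]
      gl$W <- gl$W + dac %*% t(s$x)
      rh <- s$r * s$h_prev
      gl$U <- gl$U + dac %*% t(rh)
      drh <- t(p$U) %*% dac
      dr <- drh * s$h_prev
      dh_prev <- dh_prev + drh * s$r
      daz <- dz * s$z * (1 - s$z)
      dar <- dr * s$r * (1 - s$r)
      gl$Wz <- gl$Wz + daz %*% t(s$x)
      gl$Uz <- gl$Uz + daz %*% t(s$h_prev)
      gl$Wr <- gl$Wr + dar %*% t(s$x)
      gl$Ur <- gl$Ur + dar %*% t(s$h_prev)
      if (stack@use_bias) {
        gl$bc <- gl$bc + rowSums(dac)
        gl$bz <- gl$bz + rowSums(daz)
        gl$br <- gl$br + rowSums(dar)
      }
      g$layers[[l]] <- gl
      dh_prev <- dh_prev + t(p$Uz) %*% daz + t(p$Ur) %*% dar
      dh_next[[l]] <- dh_prev
      dx <- t(p$W) %*% dac + t(p$Wz) %*% daz + t(p$Wr) %*% dar
      if (use_dropout) dx <- dx * mt$input[[l]]
      dtop <- dx                       # flows to layer l - 1 as its dh at t
    }
  }
  list(grads = g, loss = loss / nsamp, h_final = fw$h_final)
}

# ---- batch plan ------------------------------------------------------------

#' BatchPlan: stateful mini-batch layout over concatenated trajectories
#'
#' All trajectories are concatenated (in container order) into one sequence
#' of length T, split into \code{batch_size} contiguous equal-length
#' streams (tail remainder dropped), and each training iteration k
#' processes window k (length \code{seq_len}) of every stream, so windows
#' are contiguous, non-overlapping, and hidden state carries across
#' iterations.
#'
#' @aliases BatchPlan
#' @export
setClass("BatchPlan",
         representation(total = "integer", batch_size = "integer",
                        seq_len = "integer", stream_length = "integer",
                        n_iterations = "integer", offsets = "integer",
                        dropped = "integer"))

setValidity("BatchPlan", function(object) {
  if (object@n_iterations < 1L) return("plan has no iterations")
  if (object@stream_length < object@seq_len) return("streams shorter than one window")
  TRUE
})

setMethod("show", "BatchPlan", function(object) {
  cat("BatchPlan: T =", object@total, "->", object@batch_size,
      "streams of", object@stream_length, "steps;",
      object@n_iterations, "iterations/epoch of length", object@seq_len,
      ";", object@dropped, "steps dropped\n")
})

#' Build the stateful mini-batch plan
#'
#' @param n_total Concatenated sequence length (or a
#'   \linkS4class{TrajectorySet}, whose snapshot count is used).
#' @param batch_size Number of parallel streams.
#' @param seq_len Window length per iteration (truncation horizon of BPTT).
#' @return A \linkS4class{BatchPlan}.
#' @export
buildBatchPlan <- function(n_total, batch_size = 50L, seq_len = 30L) {
  if (is(n_total, "TrajectorySet")) n_total <- nSnapshots(n_total)
  n_total <- as.integer(n_total)
  batch_size <- as.integer(batch_size); seq_len <- as.integer(seq_len)
  if (n_total < batch_size * seq_len) {
    stop("dataset shorter than one batch: ", n_total, " < ",
         batch_size * seq_len)
  }
  S <- n_total %/% batch_size
  iters <- S %/% seq_len
  dropped <- (n_total - batch_size * S) + batch_size * (S - iters * seq_len)
  new("BatchPlan", total = n_total, batch_size = batch_size,
      seq_len = seq_len, stream_length = S, n_iterations = iters,
      offsets = as.integer((seq_len(batch_size) - 1L) * S),
      dropped = as.integer(dropped))
}

#' Snapshot indices of one training iteration
#'
#' @param plan A \linkS4class{BatchPlan}.
#' @param k Iteration number in \code{1..n_iterations}.
#' @return A \code{seq_len} x \code{batch_size} matrix of 1-based indices
#'   into the concatenated sequence; row t gives the batch columns at
#'   window position t.
#' @export
planIndices <- function(plan, k) {
  if (k < 1L || k > plan@n_iterations) stop("iteration out of range")
  within_stream <- (k - 1L) * plan@seq_len + seq_len(plan@seq_len)
  outer(within_stream, plan@offsets, "+")
}
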