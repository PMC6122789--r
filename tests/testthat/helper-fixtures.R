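# Small in-code fixtures shared across the suite.

# a tiny labeled TrajectorySet with hand-set delta values
tinyTrajectorySet <- function() {
  feat <- matrix(seq_len(19 * 6) / 10, nrow = 6, ncol = 19,
                 dimnames = list(NULL, canonicalFeatures()))
  makeTrajectorySet(feat,
                    target_id = rep(c("T1", "T2"), each = 3),
                    trajectory_id = rep(c("T1_r1", "T2_r1"), each = 3),
                    time_ps = rep(c(0L, 2L, 4L), 2L),
                    gdtts_ref = c(0.5, 0.52, 0.45, 0.7, 0.7, 0.69),
                    delta_gdtts = c(0, 0.02, -0.05, 0, 0.003, -0.011))
}

# scalar-loop GRU reference: computes one cell step element by element,
# independent of the vectorized implementation
scalarGRUCell <- function(x, h_prev, p) {
  H <- length(h_prev)
  z <- r <- htilde <- h <- numeric(H)
  sig <- function(v) 1 / (1 + exp(-v))
  for (i in seq_len(H)) {
    z[i] <- sig(sum(p$Wz[i, ] * x) + sum(p$Uz[i, ] * h_prev))
    r[i] <- sig(sum(p$Wr[i, ] * x) + sum(p$Ur[i, ] * h_prev))
  }
  for (i in seq_len(H)) {
    htilde[i] <- tanh(sum(p$W[i, ] * x) + sum(p$U[i, ] * (r * h_prev)))
    h[i] <- z[i] * h_prev[i] + (1 - z[i]) * htilde[i]
  }
  h
}

# scalar-loop forward pass over a stack and sequence, with softmax output
scalarGRUForward <- function(stack, X) {
  Tn <- ncol(X)
  nl <- stack@num_layers
  h <- lapply(seq_len(nl), function(l) numeric(stack@hidden_size))
  probs <- matrix(0, 3L, Tn)
  for (t in seq_len(Tn)) {
    xin <- X[, t]
    for (l in seq_len(nl)) {
      h[[l]] <- scalarGRUCell(xin, h[[l]], stack@layers[[l]])
      xin <- h[[l]]
    }
    logit <- as.numeric(stack@Wout %*% xin)
    e <- exp(logit - max(logit))
    probs[, t] <- e / sum(e)
  }
  probs
}

# numeric central-difference gradient of the mean weighted CE wrt one
# parameter matrix of a stack
numericGrad <- function(stack, X, Y, weights, layer, name, eps = 1e-6) {
  lossOf <- function(st) {
    f <- forwardGRU(st, X)
    mean(weightedCrossEntropy(Y, matrix(f$probs[, 1L, ], 3L), weights))
  }
  p <- if (is.null(layer)) stack@Wout else stack@layers[[layer]][[name]]
  g <- p * 0
  for (i in seq_along(p)) {
    st1 <- stack; st2 <- stack
    if (is.null(layer)) {
      st1@Wout[i] <- st1@Wout[i] + eps
      st2@Wout[i] <- st2@Wout[i] - eps
    } else {
      st1@layers[[layer]][[name]][i] <- st1@layers[[layer]][[name]][i] + eps
      st2@layers[[layer]][[name]][i] <- st2@layers[[layer]][[name]][i] - eps
    }
    g[i] <- (lossOf(st1) - lossOf(st2)) / (2 * eps)
  }
  g
}

# toy structure helpers: CA-only chain with given coordinates
caStructure <- function(xyz, resno = seq_len(nrow(xyz)), id = "toy") {
  structureModel(resno = resno, atom = rep("CA", nrow(xyz)), xyz = xyz,
                 id = id)
}

rotationZ <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}
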