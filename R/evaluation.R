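#' Confusion matrix over the three states
#'
#' @param actual,predicted Label vectors (factor or character, values in
#'   I/N/D) of equal length.
#' @return 3 x 3 integer matrix; rows = actual, columns = predicted, both
#'   ordered I, N, D.
#' @export
#' @examples
#' confusionMatrix3(c("I", "I", "D"), c("I", "D", "D"))
confusionMatrix3 <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("length mismatch: ", length(actual), " vs ", length(predicted))
  }
  a <- factor(as.character(actual), levels = stateLevels())
  p <- factor(as.character(predicted), levels = stateLevels())
  m <- table(actual = a, predicted = p)
  matrix(as.integer(m), 3L, 3L, dimnames = list(actual = stateLevels(),
                                                predicted = stateLevels()))
}

#' Per-class precision, recall and F1
#'
#' For class c: TP = cm[c, c], FP = column sum minus TP, FN = row sum minus
#' TP; precision = TP / (TP + FP), recall = TP / (TP + FN), F1 their
#' harmonic mean. Undefined 0/0 ratios are reported as 0 (so a classifier
#' that never predicts a class scores precision 0.000 for it).
#'
#' @param cm A 3 x 3 confusion matrix (rows actual, columns predicted).
#' @return \code{data.frame} with columns \code{class}, \code{tp},
#'   \code{fp}, \code{fn}, \code{precision}, \code{recall}, \code{f1}.
#' @export
classMetrics <- function(cm) {
  stopifnot(identical(dim(cm), c(3L, 3L)))
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- safe(2 * precision * recall, precision + recall)
  data.frame(class = stateLevels(), tp = as.integer(tp), fp = as.integer(fp),
             fn = as.integer(fn), precision = precision, recall = recall,
             f1 = f1, row.names = NULL)
}

#' Class-balanced grouped cross-validation folds
#'
#' Assigns whole targets to k folds at random (all trajectories of a
#' target share its fold) and re-draws until, for every fold and every
#' class, the class percentage in the training split differs from the
#' validation split by at most \code{max_diff_pct} percentage points.
#'
#' @param ts A labeled \linkS4class{TrajectorySet}.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param max_diff_pct Allowed |train% - val%| per class, in percentage
#'   points.
#' @param max_tries Rejection-sampling budget.
#' @return \code{data.frame} with columns \code{target_id} and
#'   \code{fold} (0-based, matching the k folds); attribute
#'   \code{"balance"} holds the per-fold class percentages.
#' @export
buildFolds <- function(ts, k = 7L, seed = 1L, max_diff_pct = 6,
                       max_tries = 1000L) {
  cd <- snapshotData(ts)
  if (anyNA(cd$label)) stop("fold construction needs labeled snapshots")
  tgts <- unique(cd$target_id)
  if (length(tgts) < k) stop("fewer targets than folds")
  counts <- table(cd$target_id, cd$label)  # targets x classes
  counts <- counts[tgts, stateLevels(), drop = FALSE]
  set.seed(seed)
  sizes <- rep(length(tgts) %/% k, k)
  sizes[seq_len(length(tgts) %% k)] <- sizes[seq_len(length(tgts) %% k)] + 1L
  best_imbalance <- Inf
  for (try in seq_len(max_tries)) {
    fold <- sample(rep(seq_len(k) - 1L, times = sizes))
    tot <- colSums(counts)
    bal <- t(vapply(seq_len(k) - 1L, function(f) {
      val <- colSums(counts[fold == f, , drop = FALSE])
      tr <- tot - val
      c(100 * tr / sum(tr), 100 * val / sum(val))
    }, numeric(6L)))
    diffs <- abs(bal[, 1:3] - bal[, 4:6])
    worst <- max(diffs)
    if (worst <= max_diff_pct) {
      out <- data.frame(target_id = tgts, fold = fold)
      colnames(bal) <- c(paste0("train_", stateLevels()),
                         paste0("val_", stateLevels()))
      attr(out, "balance") <- as.data.frame(bal)
      attr(out, "tries") <- try
      return(out)
    }
    best_imbalance <- min(best_imbalance, worst)
  }
  stop(sprintf(paste("could not satisfy the %.1f percentage-point class",
                     "balance in %d tries (best achieved %.2f)"),
               max_diff_pct, max_tries, best_imbalance))
}

#' Select the best step of a learning curve by trailing moving average
#'
#' @param values Metric values at successive evaluation points.
#' @param steps Step numbers (defaults to 1..n).
#' @param window Moving-average window size.
#' @return The step whose trailing window mean is maximal (first maximum
#'   on ties); attribute \code{"ma"} carries the averaged curve.
#' @export
learningCurveSelect <- function(values, steps = seq_along(values),
                                window = 30L) {
  n <- length(values)
  if (n < window) stop("need at least ", window, " evaluation points")
  ma <- vapply(seq_len(n), function(i) {
    if (i < window) NA_real_ else mean(values[(i - window + 1L):i])
  }, numeric(1L))
  best <- which.max(ma)          # NA-safe: which.max ignores NA
  out <- steps[best]
  attr(out, "ma") <- ma
  out
}

#' Cumulative distribution of prediction outcomes along a quality axis
#'
#' Restricts the predictions to TP, FN or FP snapshots of one class and
#' returns the right-continuous empirical CDF of the chosen axis variable.
#'
#' @param predictions A prediction \code{data.frame} (as returned by
#'   \code{\link{predictModel}} or \code{\link{predictBaseline}}) with
#'   columns \code{label}, \code{predicted} and the axis variable.
#' @param axis \code{"delta_gdtts"} or \code{"gdtts_ref"}.
#' @param outcome \code{"TP"}, \code{"FN"} or \code{"FP"}.
#' @param class One of \code{"I"}, \code{"N"}, \code{"D"}.
#' @return \code{data.frame} with sorted unique \code{x} and \code{cdf};
#'   zero rows (with attribute \code{"empty"}) when no snapshot has the
#'   outcome.
#' @export
cumulativeBy <- function(predictions, axis = c("delta_gdtts", "gdtts_ref"),
                         outcome = c("TP", "FN", "FP"), class = "I") {
  axis <- match.arg(axis)
  outcome <- match.arg(outcome)
  stopifnot(class %in% stateLevels())
  a <- as.character(predictions$label)
  p <- as.character(predictions$predicted)
  sel <- switch(outcome,
                TP = a == class & p == class,
                FN = a == class & p != class,
                FP = a != class & p == class)
  x <- predictions[[axis]][sel]
  if (!length(x)) {
    out <- data.frame(x = numeric(), cdf = numeric())
    attr(out, "empty") <- TRUE
    warning("no ", outcome, " snapshots for class ", class)
    return(out)
  }
  fn <- stats::ecdf(x)
  xs <- sort(unique(x))
  data.frame(x = xs, cdf = fn(xs))
}

#' Density of assigned probabilities for one predicted class
#'
#' Histogram density (default bin width 0.05 on [0, 1]) of the winning
#' class probability among snapshots predicted as the class.
#'
#' @param predictions Prediction \code{data.frame} with \code{prob_I},
#'   \code{prob_N}, \code{prob_D} and \code{predicted} columns.
#' @param class One of \code{"I"}, \code{"N"}, \code{"D"}.
#' @param binwidth Histogram bin width.
#' @return \code{data.frame} with \code{mid} (bin midpoints),
#'   \code{density} and \code{count}.
#' @export
probabilityDensity <- function(predictions, class = "I", binwidth = 0.05) {
  stopifnot(class %in% stateLevels())
  sel <- as.character(predictions$predicted) == class
  pm <- pmax(predictions$prob_I, predictions$prob_N, predictions$prob_D)[sel]
  breaks <- unique(c(round(seq(0, 1, by = binwidth), 10), 1))
  h <- graphics::hist(pm, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, density = h$density, count = h$counts)
}

#' Maximum-likelihood Markov chain over the state labels
#'
#' Counts consecutive label pairs and row-normalizes. By default
#' transitions never span trajectory boundaries; \code{mode =
#' "concatenated"} counts over the raw concatenation instead. A state that
#' is never left yields its identity-like observed row; a state never
#' visited yields a uniform row and is reported in the \code{"flagged"}
#' attribute.
#'
#' @param ts A labeled \linkS4class{TrajectorySet} (or a list of label
#'   vectors).
#' @param mode \code{"within"} (default) or \code{"concatenated"}.
#' @return 3 x 3 row-stochastic matrix (rows/cols I, N, D); attribute
#'   \code{"counts"} holds the transition counts.
#' @export
estimateMarkov <- function(ts, mode = c("within", "concatenated")) {
  mode <- match.arg(mode)
  if (is(ts, "TrajectorySet")) {
    lab <- as.character(stateLabels(ts))
    tid <- as.character(colData(ts)$trajectory_id)
    seqs <- split(lab, factor(tid, levels = unique(tid)))
  } else {
    seqs <- lapply(ts, as.character)
  }
  if (mode == "concatenated") seqs <- list(unlist(seqs, use.names = FALSE))
  counts <- matrix(0L, 3L, 3L, dimnames = list(stateLevels(), stateLevels()))
  for (s in seqs) {
    if (length(s) < 2L) next
    from <- factor(s[-length(s)], levels = stateLevels())
    to <- factor(s[-1L], levels = stateLevels())
    counts <- counts + table(from, to)
  }
  P <- counts / pmax(rowSums(counts), 1L)
  flagged <- stateLevels()[rowSums(counts) == 0L]
  P[rowSums(counts) == 0L, ] <- 1 / 3
  P <- matrix(as.numeric(P), 3L, 3L,
              dimnames = list(stateLevels(), stateLevels()))
  attr(P, "counts") <- counts
  if (length(flagged)) attr(P, "flagged") <- flagged
  P
}

#' Run lengths of constant-label segments per state
#'
#' Run-length encodes the label sequence of each trajectory and pools the
#' segment lengths by state.
#'
#' @param ts A labeled \linkS4class{TrajectorySet}.
#' @return Named list (\code{I}, \code{N}, \code{D}) of integer segment
#'   lengths, in order of occurrence.
#' @export
segmentLengths <- function(ts) {
  lab <- as.character(stateLabels(ts))
  tid <- as.character(colData(ts)$trajectory_id)
  out <- list(I = integer(), N = integer(), D = integer())
  for (s in split(lab, factor(tid, levels = unique(tid)))) {
    r <- rle(s)
    for (st in stateLevels()) {
      out[[st]] <- c(out[[st]], r$lengths[r$values == st])
    }
  }
  out
}

#' Tabulate segment-length histograms
#'
#' @param segments Output of \code{\link{segmentLengths}}.
#' @return \code{data.frame} with \code{class}, \code{length},
#'   \code{count} and \code{cumulative} (cumulative count from short to
#'   long segments).
#' @export
segmentHistogram <- function(segments) {
  do.call(rbind, lapply(stateLevels(), function(st) {
    x <- segments[[st]]
    if (!length(x)) {
      return(data.frame(class = character(), length = integer(),
                        count = integer(), cumulative = integer()))
    }
    tab <- table(x)
    data.frame(class = st, length = as.integer(names(tab)),
               count = as.integer(tab), cumulative = cumsum(as.integer(tab)))
  }))
}
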