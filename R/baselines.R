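#' Non-temporal baseline classifiers
#'
#' Per-snapshot classifiers trained on the same standardized features,
#' labels and folds as the recurrent model:
#' \describe{
#'   \item{\code{"rf"}}{Random forest: 500 bootstrapped trees, gini split
#'     criterion, no depth limit, minimum internal-node size 31, all 19
#'     features available to every tree (no feature subsampling). Backed
#'     by \pkg{ranger}.}
#'   \item{\code{"knn"}}{k-nearest neighbours: k = 5, uniform weights,
#'     Euclidean distance. Backed by \pkg{class}.}
#'   \item{\code{"lr"}}{Logistic regression: one-vs-rest binary ridge
#'     (L2) fits with regularization strength 1.0, argmax over the
#'     per-class probabilities. Backed by \pkg{glmnet} with
#'     \code{lambda = 1/n}, which matches an L2 strength (C) of 1.0 on
#'     the summed-loss scale.}
#' }
#' No class weights are applied.
#'
#' @param ts A labeled, standardized \linkS4class{TrajectorySet}.
#' @param kind One of \code{"rf"}, \code{"knn"}, \code{"lr"}.
#' @param seed Integer seed (bootstrap draws, tie-breaking).
#' @return An object of class \code{baselineModel}.
#' @export
fitBaseline <- function(ts, kind = c("rf", "knn", "lr"), seed = 1L) {
  kind <- match.arg(kind)
  y <- stateLabels(ts)
  if (anyNA(y)) stop("baseline training needs labeled snapshots")
  y <- droplevels(factor(as.character(y), levels = stateLevels()))
  if (nlevels(y) < 2L) stop("single-class training data")
  X <- t(featureMatrix(ts))
  obj <- list(kind = kind, seed = as.integer(seed),
              classes = levels(y))
  set.seed(seed)
  if (kind == "rf") {
    df <- data.frame(label = y, X, check.names = FALSE)
    obj$fit <- ranger::ranger(
      dependent.variable.name = "label", data = df,
      num.trees = 500L, mtry = 19L, min.node.size = 31L,
      splitrule = "gini", replace = TRUE, probability = TRUE,
      num.threads = 1L, seed = seed)
  } else if (kind == "knn") {
    if (nrow(X) < 5L) stop("fewer than k = 5 training points")
    obj$X <- X
    obj$y <- y
    obj$k <- 5L
  } else {
    n <- nrow(X)
    obj$fit <- lapply(stateLevels(), function(cl) {
      yy <- as.integer(as.character(y) == cl)
      if (length(unique(yy)) < 2L) return(NULL)   # class absent: score 0
      glmnet::glmnet(X, yy, family = "binomial", alpha = 0,
                     lambda = 1 / n, standardize = FALSE,
                     thresh = 1e-10, maxit = 1e5)
    })
    names(obj$fit) <- stateLevels()
  }
  class(obj) <- "baselineModel"
  obj
}

#' @export
print.baselineModel <- function(x, ...) {
  cat("baselineModel:", toupper(x$kind), "\n")
  invisible(x)
}

#' Predict with a baseline classifier
#'
#' @param model A \code{baselineModel} from \code{\link{fitBaseline}}.
#' @param ts A \linkS4class{TrajectorySet} (standardized like the training
#'   data).
#' @return A \code{data.frame}: snapshot metadata plus \code{prob_I},
#'   \code{prob_N}, \code{prob_D} (KNN reports neighbour vote fractions)
#'   and \code{predicted}.
#' @export
predictBaseline <- function(model, ts) {
  X <- t(featureMatrix(ts))
  out <- snapshotData(ts)
  rownames(out) <- NULL
  probs <- matrix(0, nrow(X), 3L, dimnames = list(NULL, stateLevels()))
  if (model$kind == "rf") {
    p <- stats::predict(model$fit, data.frame(X, check.names = FALSE),
                        num.threads = 1L, seed = model$seed)$predictions
    probs[, colnames(p)] <- p
    pred <- predictFromProbs(t(probs))
  } else if (model$kind == "knn") {
    set.seed(model$seed)
    kn <- class::knn(model$X, X, model$y, k = model$k, prob = TRUE)
    pred <- factor(as.character(kn), levels = stateLevels())
    win <- attr(kn, "prob")
    probs[cbind(seq_len(nrow(X)), as.integer(pred))] <- win
  } else {
    scores <- vapply(stateLevels(), function(cl) {
      f <- model$fit[[cl]]
      if (is.null(f)) return(rep(0, nrow(X)))
      as.numeric(stats::predict(f, X, type = "response"))
    }, numeric(nrow(X)))
    probs[] <- scores
    # argmax of unnormalized one-vs-rest scores; exact ties favour D, N, I
    pred <- predictFromProbs(t(scores))
  }
  out$prob_I <- probs[, "I"]
  out$prob_N <- probs[, "N"]
  out$prob_D <- probs[, "D"]
  out$predicted <- pred
  out
}
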