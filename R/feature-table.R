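#' @importFrom data.table fread fwrite as.data.table
NULL

.requiredIdCols <- c("target_id", "trajectory_id", "time_ps")

#' Read a snapshot feature table (CSV)
#'
#' Reads the canonical comma-separated snapshot table: mandatory header with
#' \code{target_id}, \code{trajectory_id}, \code{time_ps}, the 19
#' \code{\link{canonicalFeatures}} columns, and optionally
#' \code{gdtts_ref}, \code{delta_gdtts} and \code{label}. Unknown extra
#' columns are ignored. When \code{label} is absent but \code{delta_gdtts}
#' is present, labels are derived with \code{\link{assignLabel}}. Rows are
#' ordered by time within each trajectory; duplicate
#' \code{(trajectory, time)} rows are an error.
#'
#' @param path Path to a CSV file.
#' @param strict Passed to \code{\link{assignLabel}} for derived labels.
#' @return A \linkS4class{TrajectorySet}.
#' @export
readFeatureTable <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  miss <- setdiff(.requiredIdCols, colnames(dt))
  if (length(miss)) stop("missing column ", paste(miss, collapse = ", "))
  missf <- setdiff(canonicalFeatures(), colnames(dt))
  if (length(missf)) stop("missing feature ", paste(missf, collapse = ", "))
  key <- paste(dt$trajectory_id, dt$time_ps)
  if (anyDuplicated(key)) {
    stop("duplicate (trajectory, time) row at line ",
         which(duplicated(key))[1L] + 1L, ": ", key[duplicated(key)][1L])
  }
  makeTrajectorySet(
    features = as.matrix(dt[, canonicalFeatures(), drop = FALSE]),
    target_id = dt$target_id,
    trajectory_id = dt$trajectory_id,
    time_ps = dt$time_ps,
    gdtts_ref = if ("gdtts_ref" %in% colnames(dt)) dt$gdtts_ref else NULL,
    delta_gdtts = if ("delta_gdtts" %in% colnames(dt)) dt$delta_gdtts else NULL,
    label = if ("label" %in% colnames(dt)) dt$label else NULL,
    strict = strict)
}

#' Write a snapshot feature table (CSV)
#'
#' @param ts A \linkS4class{TrajectorySet}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(ts, path) {
  cd <- snapshotData(ts)
  out <- cbind(cd[, c("target_id", "trajectory_id", "time_ps",
                      "gdtts_ref", "delta_gdtts", "label")],
               as.data.frame(t(featureMatrix(ts))))
  rownames(out) <- NULL
  data.table::fwrite(out, path)
  invisible(path)
}

#' NormalizationStats: per-target feature means and standard deviations
#'
#' Slots \code{mean} and \code{sd} are targets x 19 matrices (rownames =
#' target ids, colnames = \code{\link{canonicalFeatures}}). Population
#' (1/n) standard deviations are stored; degenerate columns (sd below
#' 1e-12) are recorded with sd 1 so that the transform round-trips.
#'
#' @aliases NormalizationStats
#' @export
setClass("NormalizationStats",
         representation(mean = "matrix", sd = "matrix"))

setValidity("NormalizationStats", function(object) {
  if (!identical(dim(object@mean), dim(object@sd)))
    return("mean and sd dimensions differ")
  if (ncol(object@mean) != 19L) return("expected 19 feature columns")
  if (any(object@sd <= 0)) return("sd entries must be positive")
  TRUE
})

setMethod("show", "NormalizationStats", function(object) {
  cat("NormalizationStats for", nrow(object@mean), "target(s), 19 features\n")
})

.popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardize features per target
#'
#' Transforms every feature column to zero mean and unit standard deviation
#' within each target, using population (1/n) standard deviations over all
#' of that target's snapshots. Train and validation folds never share a
#' target, so per-target standardization introduces no leakage. Degenerate
#' (constant) columns become zeros and are recorded with sd 1.
#'
#' @param ts A \linkS4class{TrajectorySet}.
#' @return The standardized \linkS4class{TrajectorySet}; the
#'   \linkS4class{NormalizationStats} are stored in
#'   \code{metadata(.)$normalization}.
#' @export
standardize <- function(ts) {
  feat <- featureMatrix(ts)
  tgt <- as.character(colData(ts)$target_id)
  utgt <- unique(tgt)
  mu <- matrix(0, length(utgt), 19L, dimnames = list(utgt, canonicalFeatures()))
  sg <- mu
  for (g in utgt) {
    sel <- tgt == g
    m <- rowMeans(feat[, sel, drop = FALSE])
    s <- apply(feat[, sel, drop = FALSE], 1L, .popSd)
    deg <- s < 1e-12
    s[deg] <- 1
    feat[, sel] <- (feat[, sel, drop = FALSE] - m) / s
    mu[g, ] <- m
    sg[g, ] <- s
  }
  out <- ts
  SummarizedExperiment::assay(out, "features") <- feat
  metadata(out)$normalization <- new("NormalizationStats", mean = mu, sd = sg)
  out
}

#' @rdname standardize
#' @param ts A \linkS4class{TrajectorySet}.
#' @export
normalizationStats <- function(ts) metadata(ts)$normalization

#' Invert or re-apply a stored standardization
#'
#' @param ts A \linkS4class{TrajectorySet}.
#' @param stats A \linkS4class{NormalizationStats}.
#' @return A \linkS4class{TrajectorySet} with features mapped back to the
#'   original scale.
#' @export
unstandardize <- function(ts, stats = normalizationStats(ts)) {
  if (is.null(stats)) stop("no normalization stats available")
  feat <- featureMatrix(ts)
  tgt <- as.character(colData(ts)$target_id)
  for (g in unique(tgt)) {
    sel <- tgt == g
    feat[, sel] <- feat[, sel, drop = FALSE] * stats@sd[g, ] + stats@mean[g, ]
  }
  out <- ts
  SummarizedExperiment::assay(out, "features") <- feat
  metadata(out)$normalization <- NULL
  out
}

#' Export / import normalization statistics as JSON
#'
#' @param stats A \linkS4class{NormalizationStats}.
#' @param path JSON file path.
#' @return \code{path} (write) or a \linkS4class{NormalizationStats} (read).
#' @export
writeNormalizationStats <- function(stats, path) {
  jsonlite::write_json(
    list(features = canonicalFeatures(),
         targets = rownames(stats@mean),
         mean = unname(apply(stats@mean, 1L, as.numeric, simplify = FALSE)),
         sd = unname(apply(stats@sd, 1L, as.numeric, simplify = FALSE))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeNormalizationStats
#' @export
readNormalizationStats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(m) {
    m <- do.call(rbind, lapply(seq_along(x$targets), function(i) as.numeric(m[i, ])))
    dimnames(m) <- list(x$targets, x$features)
    m
  }
  new("NormalizationStats", mean = mk(x$mean), sd = mk(x$sd))
}
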