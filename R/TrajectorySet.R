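#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' TrajectorySet: snapshots of refinement trajectories
#'
#' An S4 container (extending \linkS4class{SummarizedExperiment}) holding
#' refinement-trajectory snapshots. The single assay \code{"features"} is a
#' 19 x n matrix (rows = \code{\link{canonicalFeatures}}, columns =
#' snapshots). Per-snapshot metadata live in \code{colData}:
#' \code{target_id}, \code{trajectory_id}, \code{time_ps},
#' \code{gdtts_ref}, \code{delta_gdtts} and \code{label}.
#'
#' Validity requires: 19 canonical feature rows; strictly increasing
#' \code{time_ps} with a constant step within each trajectory; each
#' trajectory belonging to exactly one target; and, where
#' \code{delta_gdtts} is present, the time-0 snapshot of a trajectory
#' having \code{delta_gdtts = 0} (and hence label \code{N}).
#'
#' @aliases TrajectorySet
#' @export
setClass("TrajectorySet", contains = "SummarizedExperiment")

.validTrajectorySet <- function(object) {
  msgs <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'features' is missing")
  }
  feat <- assay(object, "features")
  if (!identical(rownames(feat), canonicalFeatures())) {
    msgs <- c(msgs, "feature rows must equal canonicalFeatures() in order")
  }
  cd <- colData(object)
  need <- c("target_id", "trajectory_id", "time_ps", "label")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    return(c(msgs, paste("missing colData column(s):",
                         paste(miss, collapse = ", "))))
  }
  if (ncol(object) > 0L) {
    tid <- as.character(cd$trajectory_id)
    tgt <- as.character(cd$target_id)
    if (anyNA(tid) || anyNA(tgt)) msgs <- c(msgs, "NA trajectory/target ids")
    for (tr in unique(tid)) {
      sel <- tid == tr
      tp <- cd$time_ps[sel]
      if (any(diff(tp) <= 0)) {
        msgs <- c(msgs, sprintf("time_ps not strictly increasing in trajectory '%s'", tr))
      } else if (length(tp) > 2L && length(unique(diff(tp))) != 1L) {
        msgs <- c(msgs, sprintf("non-constant time step in trajectory '%s'", tr))
      }
      if (length(unique(tgt[sel])) != 1L) {
        msgs <- c(msgs, sprintf("trajectory '%s' maps to several targets", tr))
      }
      if ("delta_gdtts" %in% colnames(cd)) {
        d0 <- cd$delta_gdtts[sel][tp == 0]
        if (length(d0) && all(!is.na(d0)) && any(abs(d0) > 1e-9)) {
          msgs <- c(msgs, sprintf("trajectory '%s': delta_gdtts at time 0 is not 0", tr))
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("TrajectorySet", .validTrajectorySet)

#' Construct a TrajectorySet
#'
#' @param features Numeric matrix, either 19 x n (rows named as
#'   \code{\link{canonicalFeatures}}) or n x 19 (columns so named).
#' @param target_id,trajectory_id Character vectors, one entry per snapshot.
#' @param time_ps Integer-valued snapshot times in picoseconds.
#' @param gdtts_ref Optional GDT_TS of each snapshot versus the reference
#'   structure (fraction in [0, 1]).
#' @param delta_gdtts Optional GDT_TS change versus the starting model.
#' @param label Optional labels; derived from \code{delta_gdtts} via
#'   \code{\link{assignLabel}} when omitted.
#' @param strict Passed to \code{\link{assignLabel}} when labels are derived.
#' @return A \linkS4class{TrajectorySet}. Snapshots are ordered by
#'   trajectory (first appearance) and time.
#' @export
#' @examples
#' x <- matrix(rnorm(19 * 3), 3, 19, dimnames = list(NULL, canonicalFeatures()))
#' makeTrajectorySet(x, "T1", "T1_r1", c(0L, 2L, 4L),
#'                   delta_gdtts = c(0, 0.02, -0.05))
makeTrajectorySet <- function(features, target_id, trajectory_id, time_ps,
                              gdtts_ref = NULL, delta_gdtts = NULL,
                              label = NULL, strict = FALSE) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.null(colnames(features)) &&
      all(canonicalFeatures() %in% colnames(features)) &&
      ncol(features) >= 19L) {
    features <- t(features[, canonicalFeatures(), drop = FALSE])
  }
  if (nrow(features) != 19L) {
    stop("'features' must have the 19 canonical features as rows or columns")
  }
  rownames(features) <- canonicalFeatures()
  n <- ncol(features)
  target_id <- rep_len(as.character(target_id), n)
  trajectory_id <- rep_len(as.character(trajectory_id), n)
  time_ps <- as.integer(time_ps)
  if (is.null(label)) {
    label <- if (is.null(delta_gdtts)) {
      factor(rep(NA_character_, n), levels = stateLevels())
    } else {
      assignLabel(delta_gdtts, strict = strict)
    }
  } else {
    label <- factor(as.character(label), levels = stateLevels())
  }
  cd <- DataFrame(target_id = target_id, trajectory_id = trajectory_id,
                  time_ps = time_ps,
                  gdtts_ref = if (is.null(gdtts_ref)) NA_real_ else gdtts_ref,
                  delta_gdtts = if (is.null(delta_gdtts)) NA_real_ else delta_gdtts,
                  label = label)
  ord <- order(match(trajectory_id, unique(trajectory_id)), time_ps)
  se <- SummarizedExperiment(
    assays = list(features = features[, ord, drop = FALSE]),
    colData = cd[ord, , drop = FALSE])
  new("TrajectorySet", se)
}

#' @describeIn makeTrajectorySet Feature matrix (19 x n snapshots).
#' @param ts A \linkS4class{TrajectorySet}.
#' @export
featureMatrix <- function(ts) assay(ts, "features")

#' Per-snapshot metadata of a TrajectorySet
#'
#' @param ts A \linkS4class{TrajectorySet}.
#' @return A \code{data.frame} with one row per snapshot.
#' @export
snapshotData <- function(ts) as.data.frame(colData(ts))

#' @rdname snapshotData
#' @export
targetIds <- function(ts) unique(as.character(colData(ts)$target_id))

#' @rdname snapshotData
#' @export
trajectoryIds <- function(ts) unique(as.character(colData(ts)$trajectory_id))

#' @rdname snapshotData
#' @export
stateLabels <- function(ts) colData(ts)$label

#' @rdname snapshotData
#' @export
nSnapshots <- function(ts) ncol(ts)

#' Lengths of the trajectories in snapshot order
#' @param ts A \linkS4class{TrajectorySet}.
#' @return Named integer vector (names = trajectory ids, in column order).
#' @export
trajectoryLengths <- function(ts) {
  tid <- as.character(colData(ts)$trajectory_id)
  out <- rle(tid)
  stats::setNames(out$lengths, out$values)
}

setMethod("show", "TrajectorySet", function(object) {
  cd <- colData(object)
  cat("TrajectorySet with", ncol(object), "snapshots |",
      length(unique(cd$target_id)), "targets |",
      length(unique(cd$trajectory_id)), "trajectories\n")
  if (ncol(object)) {
    tab <- table(cd$label, useNA = "ifany")
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  if (!is.null(metadata(object)$normalization)) {
    cat("  standardized per target (stats in metadata(.)$normalization)\n")
  }
})

#' Subset a TrajectorySet to a set of targets
#'
#' @param ts A \linkS4class{TrajectorySet}.
#' @param targets Character vector of target ids to keep.
#' @return A \linkS4class{TrajectorySet}.
#' @export
subsetTargets <- function(ts, targets) {
  keep <- as.character(colData(ts)$target_id) %in% targets
  out <- ts[, keep]
  methods::validObject(out)
  out
}

#' Randomly permute snapshot order within each trajectory
#'
#' Used for the temporal-ablation experiment: features, quality scores and
#' labels are shuffled jointly within each trajectory while the time grid is
#' kept, destroying temporal structure but not the marginal distribution.
#'
#' @param ts A \linkS4class{TrajectorySet}.
#' @param seed Integer seed.
#' @return A \linkS4class{TrajectorySet} of the same dimensions.
#' @export
shuffleSnapshots <- function(ts, seed = 1L) {
  set.seed(seed)
  cd <- colData(ts)
  tid <- as.character(cd$trajectory_id)
  feat <- featureMatrix(ts)
  gd <- cd$gdtts_ref
  dd <- cd$delta_gdtts
  lab <- as.character(cd$label)
  for (tr in unique(tid)) {
    sel <- which(tid == tr)
    p <- sample(seq_along(sel))
    feat[, sel] <- feat[, sel[p], drop = FALSE]
    gd[sel] <- gd[sel[p]]
    dd[sel] <- dd[sel[p]]
    lab[sel] <- lab[sel[p]]
  }
  # the time-0 snapshot need no longer carry delta 0, so drop the walk values
  se <- SummarizedExperiment(
    assays = list(features = feat),
    colData = DataFrame(target_id = cd$target_id, trajectory_id = cd$trajectory_id,
                        time_ps = cd$time_ps, gdtts_ref = gd,
                        delta_gdtts = NA_real_,
                        label = factor(lab, levels = stateLevels())))
  out <- new("TrajectorySet", se)
  metadata(out) <- list(shuffled = TRUE)
  out
}
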