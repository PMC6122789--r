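#' Canonical snapshot feature names
#'
#' The 19 per-snapshot descriptors in their canonical column order: 17
#' potential-energy / scoring-function terms (DFIRE sum and terms 1-4, DOPE
#' and high-resolution DOPE, DOOP, calRW, calRWplus, GOAP and its
#' angular component, and the Modeller bond/angle/dihedral/improper/molpdf
#' terms) plus the two distance metrics to the starting model
#' (\code{N_RMSD_SM}, \code{N_GDTTS_SM}).
#'
#' @return Character vector of length 19.
#' @export
#' @examples
#' canonicalFeatures()
canonicalFeatures <- function() {
  c("N_DDFIRESUM", "N_DDFIRETERM1", "N_DDFIRETERM2", "N_DDFIRETERM3",
    "N_DDFIRETERM4", "N_DOPE", "N_DOPE_HR", "N_RMSD_SM", "N_GDTTS_SM",
    "N_DOOP", "N_CALRW", "N_CALRWP", "N_GOAP", "N_GOAPAG", "N_BOND",
    "N_ANGLE", "N_DIHEDRAL", "N_IMPROPER", "N_MOLPDF")
}

#' State labels used throughout the package
#'
#' @return Character vector \code{c("I","N","D")}: improved, no-change,
#'   decreased model quality relative to the starting model.
#' @export
stateLevels <- function() c("I", "N", "D")

#' Assign a conformational-state label from a GDT_TS change
#'
#' A snapshot is labeled improved (\code{I}) when its GDT_TS gain over the
#' starting model is at least 0.01, decreased (\code{D}) when the loss
#' exceeds 0.01, and no-change (\code{N}) in between. By default the
#' boundary value -0.01 belongs to \code{N}; with \code{strict = TRUE} it
#' belongs to \code{D} (an alternative reading of the band in which
#' \code{N} is the open interval (-0.01, 0.01)).
#'
#' @param delta_gdtts Numeric vector of GDT_TS differences (snapshot minus
#'   starting model, both scored against the reference structure), on the
#'   0-1 fraction scale.
#' @param strict Logical; if \code{TRUE}, \code{delta_gdtts == -0.01} is
#'   labeled \code{D} instead of \code{N}.
#' @return Factor with levels \code{I}, \code{N}, \code{D}.
#' @export
#' @examples
#' assignLabel(c(0.02, 0, -0.01, -0.0101))
assignLabel <- function(delta_gdtts, strict = FALSE) {
  if (!is.numeric(delta_gdtts)) {
    stop("labeling error: 'delta_gdtts' must be numeric")
  }
  if (any(!is.finite(delta_gdtts))) {
    stop("labeling error: non-finite delta_gdtts at position ",
         which(!is.finite(delta_gdtts))[1L])
  }
  lab <- ifelse(delta_gdtts >= 0.01, "I",
                ifelse(if (strict) delta_gdtts > -0.01 else delta_gdtts >= -0.01,
                       "N", "D"))
  factor(lab, levels = stateLevels())
}

#' One-hot encode state labels
#'
#' @param labels Factor or character vector of labels in \code{I}, \code{N},
#'   \code{D}.
#' @return A 3 x n numeric matrix; rows named \code{I}, \code{N}, \code{D},
#'   each column a one-hot probability vector.
#' @export
oneHot <- function(labels) {
  labels <- factor(as.character(labels), levels = stateLevels())
  if (any(is.na(labels))) stop("unknown label among I/N/D")
  m <- matrix(0, nrow = 3L, ncol = length(labels),
              dimnames = list(stateLevels(), NULL))
  m[cbind(as.integer(labels), seq_along(labels))] <- 1
  m
}
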