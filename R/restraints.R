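#' Filter an ensemble of models against a starting structure
#'
#' Removes physically implausible models: members whose CA-RMSD to the
#' starting model (after optimal superposition) exceeds the cutoff.
#'
#' @param models List of \linkS4class{StructureModel}s.
#' @param start Starting \linkS4class{StructureModel}.
#' @param cutoff RMSD cutoff in Angstrom (default 10).
#' @return The retained sublist; attribute \code{"rmsd"} holds all RMSDs.
#' @export
filterModels <- function(models, start, cutoff = 10) {
  r <- vapply(models, rmsdStructures, numeric(1L), w = start)
  keep <- r <= cutoff
  if (!any(keep)) {
    stop("no model within ", cutoff,
         " Angstrom CA-RMSD of the start; review the cutoff")
  }
  out <- models[keep]
  attr(out, "rmsd") <- r
  out
}

#' Residues eligible for position restraints
#'
#' Structurally conserved residues: those whose per-residue CA-RMSF over
#' the (filtered) ensemble is below the cutoff.
#'
#' @param ensemble List of \linkS4class{StructureModel}s (>= 2).
#' @param rmsf_cutoff RMSF cutoff in Angstrom (default 3).
#' @return Integer vector of residue indices; attribute \code{"rmsf"}
#'   holds the per-residue values.
#' @export
positionRestraints <- function(ensemble, rmsf_cutoff = 3) {
  r <- rmsfEnsemble(ensemble)
  out <- as.integer(names(r)[r < rmsf_cutoff])
  attr(out, "rmsf") <- r
  out
}

.caDistMatrix <- function(s) {
  as.matrix(stats::dist(.atomCoords(s, "CA")))
}

#' Conserved residue-residue distance restraints
#'
#' All CA-CA pairs at least \code{min_sep} residues apart whose
#' ensemble-mean distance is below \code{max_dist} and whose distance
#' standard deviation is below \code{max_sd}; the restraint reference
#' distance is the ensemble mean.
#'
#' @param ensemble List of \linkS4class{StructureModel}s (>= 2) with
#'   consistent numbering.
#' @param min_sep Minimum sequence separation |i - j| (default 5).
#' @param max_dist Mean-distance cutoff in Angstrom (default 9).
#' @param max_sd Distance standard-deviation cutoff in Angstrom (default 1).
#' @return \code{data.frame} with \code{res_i}, \code{res_j},
#'   \code{distance} (mean, Angstrom), \code{sd}.
#' @export
distanceRestraints <- function(ensemble, min_sep = 5L, max_dist = 9,
                               max_sd = 1) {
  if (length(ensemble) < 2L) stop("need at least 2 models")
  cas <- lapply(ensemble, .atomCoords, atom = "CA")
  shared <- Reduce(intersect, lapply(cas, rownames))
  res <- as.integer(shared)
  dists <- simplify2array(lapply(cas, function(m) {
    as.matrix(stats::dist(m[shared, , drop = FALSE]))
  }))                                             # n x n x models
  mu <- apply(dists, c(1L, 2L), mean)
  sg <- sqrt(apply(dists, c(1L, 2L), function(x) mean((x - mean(x))^2)))
  pairs <- which(upper.tri(mu), arr.ind = TRUE)
  sep <- abs(res[pairs[, 1L]] - res[pairs[, 2L]])
  sel <- sep >= min_sep & mu[pairs] < max_dist & sg[pairs] < max_sd
  data.frame(res_i = pmin(res[pairs[sel, 1L]], res[pairs[sel, 2L]]),
             res_j = pmax(res[pairs[sel, 1L]], res[pairs[sel, 2L]]),
             distance = mu[pairs][sel], sd = sg[pairs][sel])
}

# contacts of one model: pairs with CA or CB distance < cutoff, skipping
# direct neighbours; the shorter qualifying distance fixes the atom choice
.modelContacts <- function(s, cutoff = 8, neighbor_excl = 1L) {
  ca <- .atomCoords(s, "CA")
  cb <- .atomCoords(s, "CB")
  res <- as.integer(rownames(ca))
  dca <- as.matrix(stats::dist(ca))
  # CB distance where both residues have a CB; CA substitutes otherwise
  mix <- ca
  if (nrow(cb)) mix[rownames(cb), ] <- cb
  dcb <- as.matrix(stats::dist(mix))
  pairs <- which(upper.tri(dca), arr.ind = TRUE)
  sep <- abs(res[pairs[, 1L]] - res[pairs[, 2L]])
  d1 <- dca[pairs]; d2 <- dcb[pairs]
  dmin <- pmin(d1, d2)
  atom <- ifelse(d1 <= d2, "CA", "CB")
  sel <- sep > neighbor_excl & dmin < cutoff
  data.frame(res_i = res[pairs[sel, 1L]], res_j = res[pairs[sel, 2L]],
             atom = atom[sel], distance = dmin[sel],
             stringsAsFactors = FALSE)
}

#' ContactMap: residue contacts with reference distances
#'
#' \code{kind} is \code{"CM_exl"} (contacts observed in exactly one model
#' of the ensemble, reference distance from that model) or
#' \code{"CM_min"} (every observed contact, reference distance = minimum
#' across the ensemble). Contacts are unordered residue pairs at sequence
#' separation >= 2 with a CA or CB distance under 8 Angstrom; the contact
#' identity includes the atom choice, and the shorter of the qualifying
#' CA/CB distances defines it.
#'
#' @aliases ContactMap
#' @export
setClass("ContactMap",
         representation(kind = "character", contacts = "data.frame"))

setValidity("ContactMap", function(object) {
  if (!object@kind %in% c("CM_exl", "CM_min")) return("unknown kind")
  ct <- object@contacts
  need <- c("res_i", "res_j", "atom", "r0", "source")
  if (!all(need %in% colnames(ct))) {
    return(paste("contacts needs", paste(need, collapse = "/")))
  }
  if (nrow(ct) && any(abs(ct$res_i - ct$res_j) < 2L)) {
    return("direct-neighbour contact present")
  }
  if (nrow(ct) && any(ct$r0 >= 8)) return("r0 must be < 8 Angstrom")
  TRUE
})

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap", object@kind, "with", nrow(object@contacts),
      "contact(s)\n")
})

#' Build the exclusive and minimum-distance contact maps
#'
#' @param ensemble List of \linkS4class{StructureModel}s (already
#'   filtered).
#' @param cutoff Contact distance cutoff in Angstrom (default 8).
#' @return List with elements \code{CM_exl} and \code{CM_min}, both
#'   \linkS4class{ContactMap}s whose \code{source} column names the model
#'   providing each reference distance.
#' @export
buildContactMaps <- function(ensemble, cutoff = 8) {
  ids <- vapply(seq_along(ensemble), function(i) {
    id <- ensemble[[i]]@id
    if (is.na(id) || !nzchar(id)) paste0("model", i) else id
  }, character(1L))
  percontact <- do.call(rbind, lapply(seq_along(ensemble), function(i) {
    ct <- .modelContacts(ensemble[[i]], cutoff = cutoff)
    if (nrow(ct)) ct$source <- ids[i]
    ct
  }))
  if (is.null(percontact) || !nrow(percontact)) {
    empty <- data.frame(res_i = integer(), res_j = integer(),
                        atom = character(), r0 = numeric(),
                        source = character())
    return(list(CM_exl = new("ContactMap", kind = "CM_exl", contacts = empty),
                CM_min = new("ContactMap", kind = "CM_min", contacts = empty)))
  }
  key <- paste(percontact$res_i, percontact$res_j, percontact$atom)
  nmodels <- vapply(split(percontact$source, key),
                    function(s) length(unique(s)), integer(1L))
  mk <- function(df) {
    data.frame(res_i = df$res_i, res_j = df$res_j, atom = df$atom,
               r0 = df$distance, source = df$source)
  }
  exl <- percontact[key %in% names(nmodels)[nmodels == 1L], , drop = FALSE]
  # minimum across the ensemble; ties go to the first model id
  ord <- order(key, percontact$distance, match(percontact$source, ids))
  sorted <- percontact[ord, , drop = FALSE]
  minc <- sorted[!duplicated(key[ord]), , drop = FALSE]
  list(CM_exl = new("ContactMap", kind = "CM_exl", contacts = mk(exl)),
       CM_min = new("ContactMap", kind = "CM_min", contacts = mk(minc)))
}

#' Rational switching function for contact formation
#'
#' \eqn{D(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)} with n = 6, m = 10: 1 for
#' a fully formed contact (r = 0), the removable-singularity limit
#' n/m = 0.6 at r = r0, and 0 as r grows. Continuous and strictly
#' decreasing for r > 0 when n < m.
#'
#' @param r Distance(s), Angstrom.
#' @param r0 Reference distance, Angstrom (> 0).
#' @param n,m Exponents, n < m.
#' @return Numeric vector of switching-function values.
#' @export
contactFunction <- function(r, r0, n = 6L, m = 10L) {
  if (any(r0 <= 0)) stop("r0 must be positive")
  if (any(r < 0)) stop("r must be non-negative")
  stopifnot(n < m, n > 0, m > 0)
  x <- r / r0
  out <- ifelse(abs(x - 1) < 1e-9, n / m, (1 - x^n) / (1 - x^m))
  as.numeric(out)
}

.contactDistance <- function(s, res_i, res_j, atom) {
  ca <- .atomCoords(s, "CA")
  cb <- .atomCoords(s, "CB")
  get1 <- function(res, at) {
    m <- if (at == "CB" && as.character(res) %in% rownames(cb)) cb else ca
    key <- as.character(res)
    if (!key %in% rownames(m)) return(rep(NA_real_, 3L))
    m[key, ]
  }
  vapply(seq_along(res_i), function(i) {
    a <- get1(res_i[i], atom[i]); b <- get1(res_j[i], atom[i])
    sqrt(sum((a - b)^2))
  }, numeric(1L))
}

#' Contact-map collective variables
#'
#' For a structure R and a contact map, the CV is the mean over contacts
#' of the squared difference between the switching-function value in R and
#' in the contact's own reference model: CV1 uses the exclusive map,
#' CV2 the minimum-distance map. N is the contact count of the respective
#' map. Contacts whose atoms cannot be resolved in R are excluded with a
#' warning.
#'
#' @param R A \linkS4class{StructureModel} to evaluate.
#' @param cm A \linkS4class{ContactMap}.
#' @param ref_structures Named list of \linkS4class{StructureModel}s
#'   covering the \code{source} ids of the map; when omitted, the
#'   reference switching value is taken at \code{r = r0} (its value in
#'   the source model by construction).
#' @param n,m Switching-function exponents.
#' @return The CV value (>= 0); attribute \code{"n_contacts"} gives the
#'   contacts used.
#' @export
collectiveVariable <- function(R, cm, ref_structures = NULL, n = 6L,
                               m = 10L) {
  ct <- cm@contacts
  if (!nrow(ct)) return(structure(0, n_contacts = 0L))
  dR <- .contactDistance(R, ct$res_i, ct$res_j, ct$atom)
  bad <- !is.finite(dR)
  if (any(bad)) {
    warning(sum(bad), " contact(s) with unresolvable atoms excluded: ",
            paste(utils::head(paste0(ct$res_i[bad], "-", ct$res_j[bad]), 5L),
                  collapse = ", "))
    ct <- ct[!bad, , drop = FALSE]
    dR <- dR[!bad]
    if (!nrow(ct)) return(structure(0, n_contacts = 0L))
  }
  DR <- contactFunction(dR, ct$r0, n, m)
  Dref <- if (is.null(ref_structures)) {
    contactFunction(ct$r0, ct$r0, n, m)
  } else {
    vapply(seq_len(nrow(ct)), function(i) {
      contactFunction(
        .contactDistance(ref_structures[[ct$source[i]]],
                         ct$res_i[i], ct$res_j[i], ct$atom[i]),
        ct$r0[i], n, m)
    }, numeric(1L))
  }
  structure(mean((DR - Dref)^2), n_contacts = nrow(ct))
}

#' @rdname collectiveVariable
#' @param cm_exl,cm_min The two \linkS4class{ContactMap}s from
#'   \code{\link{buildContactMaps}}.
#' @export
collectiveVariables <- function(R, cm_exl, cm_min, ref_structures = NULL,
                                n = 6L, m = 10L) {
  c(CV1 = as.numeric(collectiveVariable(R, cm_exl, ref_structures, n, m)),
    CV2 = as.numeric(collectiveVariable(R, cm_min, ref_structures, n, m)))
}

#' Write restraints as GROMACS-style text blocks
#'
#' Plain-text dialect: a \code{[ position_restraints ]} block listing the
#' restrained residue indices (function type 1, default force constants)
#' and a \code{[ distance_restraints ]} block with one line per pair and
#' its reference distance in nm.
#'
#' @param position Integer residue indices (from
#'   \code{\link{positionRestraints}}).
#' @param distance \code{data.frame} from
#'   \code{\link{distanceRestraints}}.
#' @param path Output file.
#' @param fc Force constant written for position restraints
#'   (kJ mol^-1 nm^-2).
#' @return \code{path}, invisibly.
#' @export
writeRestraints <- function(position, distance, path, fc = 1000) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[ position_restraints ]", con)
  writeLines("; residue  funct  fx fy fz (kJ mol^-1 nm^-2)", con)
  for (r in position) {
    writeLines(sprintf("%6d  1  %g %g %g", r, fc, fc, fc), con)
  }
  writeLines("", con)
  writeLines("[ distance_restraints ]", con)
  writeLines("; res_i res_j  funct  low up1 (nm)", con)
  if (nrow(distance)) {
    for (i in seq_len(nrow(distance))) {
      writeLines(sprintf("%6d %6d  1  %.4f %.4f", distance$res_i[i],
                         distance$res_j[i], distance$distance[i] / 10,
                         distance$distance[i] / 10), con)
    }
  }
  invisible(path)
}

#' Export a contact map as JSON
#'
#' @param cm A \linkS4class{ContactMap}.
#' @param path JSON output file.
#' @return \code{path}, invisibly.
#' @export
writeContactMapJSON <- function(cm, path) {
  jsonlite::write_json(list(kind = cm@kind, contacts = cm@contacts),
                       path, digits = NA, dataframe = "rows")
  invisible(path)
}
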