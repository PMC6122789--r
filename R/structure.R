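#' StructureModel: minimal protein coordinate container
#'
#' Holds the atom records needed by the distance metrics and restraint
#' generators: residue index, atom name and Cartesian coordinates in
#' Angstroms. Parsed PDB files keep only the first model, altloc " "/"A",
#' and drop hydrogens.
#'
#' @aliases StructureModel
#' @export
setClass("StructureModel",
         representation(atoms = "data.frame", chain = "character",
                        id = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("resno", "atom", "x", "y", "z")
  if (!all(need %in% colnames(a))) return("atoms needs resno/atom/x/y/z")
  ca <- a$resno[a$atom == "CA"]
  if (anyDuplicated(ca)) return("a residue has more than one CA atom")
  if (any(!is.finite(as.matrix(a[, c("x", "y", "z")])))) {
    return("non-finite coordinates")
  }
  TRUE
})

#' Construct a StructureModel from raw vectors
#'
#' @param resno Integer residue indices, one per atom.
#' @param atom Atom names (\code{"CA"}, \code{"CB"}, ...).
#' @param xyz n x 3 numeric matrix of coordinates (Angstrom).
#' @param chain Chain identifier.
#' @param id Model identifier.
#' @return A \linkS4class{StructureModel}.
#' @export
structureModel <- function(resno, atom, xyz, chain = "A", id = "model") {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  new("StructureModel",
      atoms = data.frame(resno = as.integer(resno),
                         atom = as.character(atom),
                         x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]),
      chain = chain, id = id)
}

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel '", object@id, "': ", nrow(object@atoms), " atoms, ",
      length(unique(object@atoms$resno)), " residues\n", sep = "")
})

#' Read a PDB file into a StructureModel
#'
#' Uses \pkg{bio3d} to parse ATOM records; keeps the first model of
#' multi-model files, altloc blank or "A", and discards hydrogens.
#'
#' @param path PDB file path.
#' @param id Model identifier (defaults to the file name).
#' @return A \linkS4class{StructureModel}.
#' @export
readStructurePDB <- function(path, id = basename(path)) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[is.na(a$alt) | a$alt %in% c("", " ", "A"), , drop = FALSE]
  elesym <- sub("^[0-9]*", "", a$elety)
  a <- a[!grepl("^H", elesym), , drop = FALSE]
  structureModel(a$resno, a$elety, cbind(a$x, a$y, a$z),
                 chain = as.character(a$chain[1L]), id = id)
}

#' Write a StructureModel to a PDB file
#'
#' @param s A \linkS4class{StructureModel}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeStructurePDB <- function(s, path) {
  a <- s@atoms
  n <- nrow(a)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", n), resno = a$resno,
                   resid = rep("ALA", n), eleno = seq_len(n),
                   elety = a$atom, chain = rep(s@chain[1L], n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

# coordinates of one atom type, rownames = residue numbers
.atomCoords <- function(s, atom = "CA") {
  a <- s@atoms[s@atoms$atom == atom, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

# paired coordinate sets over the shared residues (by residue index)
.pairedCa <- function(v, w) {
  cv <- .atomCoords(v, "CA")
  cw <- .atomCoords(w, "CA")
  shared <- intersect(rownames(cv), rownames(cw))
  if (!length(shared)) stop("zero paired CA atoms between structures")
  list(v = cv[shared, , drop = FALSE], w = cw[shared, , drop = FALSE],
       resno = as.integer(shared))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of the mobile structure's selected atoms onto the
#' target's, returning the proper rotation (det +1), translation and the
#' attained RMSD, which is the global minimum over rigid motions.
#'
#' @param mobile,target \linkS4class{StructureModel}s with residue-paired
#'   CA atoms (pairing is by residue index).
#' @return A list with \code{rotation} (3 x 3), \code{translation}
#'   (length 3), and \code{rmsd_after} (Angstrom). The fitted mobile
#'   coordinates are \code{coords \%*\% t(rotation) + translation}.
#' @export
superpose <- function(mobile, target) {
  p <- .pairedCa(mobile, target)
  fit <- kabsch(p$v, p$w)
  fit
}

#' @rdname superpose
#' @param mobileCoords,targetCoords n x 3 coordinate matrices of paired
#'   atoms (n >= 3, non-collinear).
#' @export
kabsch <- function(mobileCoords, targetCoords) {
  if (nrow(mobileCoords) != nrow(targetCoords)) {
    stop("mismatched atom counts: ", nrow(mobileCoords), " vs ",
         nrow(targetCoords))
  }
  n <- nrow(mobileCoords)
  if (n < 3L) stop("need at least 3 paired atoms")
  cm <- colMeans(mobileCoords)
  ct <- colMeans(targetCoords)
  A <- sweep(mobileCoords, 2L, cm)
  B <- sweep(targetCoords, 2L, ct)
  if (qr(A)$rank < 2L) stop("degenerate (collinear) atom selection")
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps mobile -> target frame
  fitted <- A %*% t(R)
  rmsd_after <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(ct - (R %*% cm)),
       rmsd_after = rmsd_after)
}

.applyFit <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2L, fit$translation, "+")
}

#' Root-mean-square deviation between two structures
#'
#' \eqn{RMSD(v,w) = \sqrt{ (1/n) \sum_i \| v_i - w_i \|^2 }} over paired CA
#' atoms, optionally after an optimal rigid-body superposition.
#'
#' @param v,w \linkS4class{StructureModel}s.
#' @param superpose_first Superpose \code{v} onto \code{w} first
#'   (default \code{TRUE}).
#' @return RMSD in Angstrom.
#' @export
rmsdStructures <- function(v, w, superpose_first = TRUE) {
  p <- .pairedCa(v, w)
  if (superpose_first) {
    kabsch(p$v, p$w)$rmsd_after
  } else {
    sqrt(mean(rowSums((p$v - p$w)^2)))
  }
}

#' Global distance test total score (GDT_TS)
#'
#' Mean over the 1, 2, 4 and 8 Angstrom cutoffs of the fraction of paired
#' residues whose CA deviation is at or below the cutoff. The default
#' policy uses a single global Kabsch superposition on all paired CA atoms;
#' \code{mode = "iterative"} refines the fit on the residues under each
#' cutoff (at most 5 iterations), approximating search-based GDT
#' implementations.
#'
#' @param model,reference \linkS4class{StructureModel}s.
#' @param mode \code{"single"} (default) or \code{"iterative"}.
#' @return GDT_TS as a fraction in [0, 1].
#' @export
gdtts <- function(model, reference, mode = c("single", "iterative")) {
  mode <- match.arg(mode)
  p <- .pairedCa(model, reference)
  cutoffs <- c(1, 2, 4, 8)
  devGlobal <- function(mv, mw) {
    fit <- kabsch(mv, mw)
    sqrt(rowSums((.applyFit(mv, fit) - mw)^2))
  }
  dev0 <- devGlobal(p$v, p$w)
  frac <- vapply(cutoffs, function(cut) {
    if (mode == "single") return(mean(dev0 <= cut))
    dev <- dev0
    for (it in seq_len(5L)) {
      keep <- dev <= cut
      if (sum(keep) < 3L) break
      fit <- kabsch(p$v[keep, , drop = FALSE], p$w[keep, , drop = FALSE])
      newdev <- sqrt(rowSums((.applyFit(p$v, fit) - p$w)^2))
      if (identical(newdev <= cut, keep)) { dev <- newdev; break }
      dev <- newdev
    }
    mean(dev <= cut)
  }, numeric(1L))
  mean(frac)
}

#' Per-residue CA root-mean-square fluctuation of an ensemble
#'
#' Structures are first superposed onto the first member over the shared CA
#' atoms (disable with \code{fit = FALSE} if the ensemble is already in a
#' common frame); RMSF of residue j is the root mean square distance of its
#' CA from the ensemble-mean position.
#'
#' @param ensemble List of \linkS4class{StructureModel}s (>= 2) with
#'   consistent residue numbering.
#' @param fit Superpose members onto the first before measuring.
#' @return Named numeric vector (names = residue numbers), Angstrom.
#' @export
rmsfEnsemble <- function(ensemble, fit = TRUE) {
  if (length(ensemble) < 2L) stop("need at least 2 structures")
  coords <- lapply(ensemble, .atomCoords, atom = "CA")
  shared <- Reduce(intersect, lapply(coords, rownames))
  if (!length(shared)) stop("inconsistent residue sets: no shared residues")
  coords <- lapply(coords, function(m) m[shared, , drop = FALSE])
  if (fit) {
    ref <- coords[[1L]]
    coords <- lapply(coords, function(m) .applyFit(m, kabsch(m, ref)))
  }
  arr <- simplify2array(coords)              # residues x 3 x models
  mean_pos <- apply(arr, c(1L, 2L), mean)
  sq <- sweep(arr, c(1L, 2L), mean_pos)^2
  out <- sqrt(apply(sq, 1L, sum) / length(ensemble))
  stats::setNames(out, shared)
}

#' Score trajectory snapshots against start and reference structures
#'
#' Computes, for each snapshot model, the two distance-metric features
#' (CA-RMSD and GDT_TS to the starting model) plus the labeling inputs:
#' GDT_TS to the reference structure and its change against the starting
#' model's score, with the derived state label.
#'
#' @param snapshots List of \linkS4class{StructureModel}s in time order.
#' @param start Starting \linkS4class{StructureModel} (time 0).
#' @param reference Reference (crystal) \linkS4class{StructureModel};
#'   optional. Without it only the two starting-model metrics are
#'   returned.
#' @param strict Passed to \code{\link{assignLabel}}.
#' @return \code{data.frame} with one row per snapshot: \code{rmsd_sm},
#'   \code{gdtts_sm}, and when a reference is given \code{gdtts_ref},
#'   \code{delta_gdtts}, \code{label}.
#' @export
scoreSnapshots <- function(snapshots, start, reference = NULL,
                           strict = FALSE) {
  out <- data.frame(
    rmsd_sm = vapply(snapshots, rmsdStructures, numeric(1L), w = start),
    gdtts_sm = vapply(snapshots, gdtts, numeric(1L), reference = start))
  if (!is.null(reference)) {
    g0 <- gdtts(start, reference)
    out$gdtts_ref <- vapply(snapshots, gdtts, numeric(1L),
                            reference = reference)
    out$delta_gdtts <- out$gdtts_ref - g0
    out$label <- assignLabel(out$delta_gdtts, strict = strict)
  }
  out
}

#' Write per-snapshot structure metrics or per-residue RMSF as TSV
#'
#' @param x A \code{data.frame} from \code{\link{scoreSnapshots}}, or the
#'   named vector from \code{\link{rmsfEnsemble}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsTSV <- function(x, path) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- data.frame(resno = as.integer(names(x)), rmsf = as.numeric(x))
  }
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
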