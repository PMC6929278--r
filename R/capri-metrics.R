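#' @title CAPRI-style pose evaluation
#' @name capri-metrics
#' @description Evaluation of a predicted pose against the native complex:
#'   fraction of native contacts recovered (F_nat), fraction of non-native
#'   contacts in the prediction (F_non-nat), interface backbone RMSD after
#'   optimal superposition (I_rmsd), and the derived quality class.
NULL

contact_keys <- function(contacts) paste(contacts$rec_uid, contacts$lig_uid,
                                         sep = "\r")

#' Fraction of native contacts
#'
#' Number of predicted residue-residue contacts that are also native,
#' divided by the number of native contacts. Intersection is by residue
#' pair identity.
#'
#' @param predicted,native `"contact_set"` objects from [contact_pairs()];
#'   `native` must be non-empty.
#' @return Fraction in \[0, 1\].
#' @export
fnat <- function(predicted, native) {
  if (!nrow(native)) stop("native contact set is empty: fnat undefined")
  sum(contact_keys(predicted) %in% contact_keys(native)) / nrow(native)
}

#' Fraction of non-native contacts
#'
#' Number of predicted contacts absent from the native set, divided by the
#' total number of predicted contacts. A pose with no contacts has no
#' defined value: `NA` is returned (and should be excluded from averages,
#' not coerced to 0 or 1).
#'
#' @param predicted,native `"contact_set"` objects.
#' @return Fraction in \[0, 1\], or `NA` when `predicted` is empty.
#' @export
fnonnat <- function(predicted, native) {
  if (!nrow(predicted)) return(NA_real_)
  sum(!(contact_keys(predicted) %in% contact_keys(native))) / nrow(predicted)
}

#' Interface backbone RMSD
#'
#' Interface residues are determined on the native complex at the contact
#' cutoff; the backbone atoms (N, CA, C, O) of those residues are collected
#' from both structures in identical residue/atom order (atoms missing from
#' either structure are dropped pairwise); the pose's interface is then
#' optimally superposed onto the native interface and the residual RMSD
#' returned.
#'
#' @param pose,native [hexa_structure] objects sharing chain ids and residue
#'   numbering.
#' @param contact_cutoff interface contact cutoff in Angstrom (default 6.0).
#' @return RMSD in Angstrom (>= 0).
#' @export
irmsd <- function(pose, native, contact_cutoff = 6.0) {
  nc <- contact_pairs(native, cutoff = contact_cutoff)
  if (!nrow(nc)) stop("native complex has no interface at ", contact_cutoff,
                      " A")
  iface <- interface_residues(nc)
  uids <- c(iface$receptor, iface$ligand)
  backbone <- c("N", "CA", "C", "O")
  pose_xyz <- list(); nat_xyz <- list()
  for (u in uids) {
    pa <- residue_atoms(pose, u); na_ <- residue_atoms(native, u)
    if (!nrow(pa))
      stop("pose lacks native interface residue ", u,
           ": residue numbering mismatch")
    for (b in backbone) {
      cp <- atom_coord(pa, b); cn <- atom_coord(na_, b)
      if (!is.null(cp) && !is.null(cn)) {   # pairwise drop of missing atoms
        pose_xyz[[length(pose_xyz) + 1L]] <- cp
        nat_xyz[[length(nat_xyz) + 1L]] <- cn
      }
    }
  }
  P <- do.call(rbind, pose_xyz); Q <- do.call(rbind, nat_xyz)
  superpose(P, Q)$rmsd
}

#' CAPRI quality class from F_nat and I_rmsd
#'
#' A pose is Incorrect when F_nat < 10% or I_rmsd > 4 A. Otherwise, under
#' the default (`strict = FALSE`) semantics the F_nat thresholds act as
#' lower bounds and the class is the best one whose F_nat lower bound and
#' I_rmsd band are both met: High (F_nat >= 50% and I_rmsd <= 1),
#' Medium (F_nat >= 30% and 1 < I_rmsd <= 2), Acceptable (F_nat >= 10% and
#' 2 < I_rmsd <= 4) — with any pose surviving the Incorrect test classified
#' at the best band its I_rmsd admits. This makes the map total and
#' monotone. `strict = TRUE` reproduces the verbatim mutually-exclusive
#' bands (both measures two-sided) and returns `"Unclassified"` for the
#' gaps they leave.
#'
#' @param fnat fraction in \[0, 1\].
#' @param irmsd Angstrom, >= 0.
#' @param strict logical; use the verbatim band definition.
#' @return One of `"Incorrect"`, `"Acceptable"`, `"Medium"`, `"High"` (or
#'   `"Unclassified"` in strict mode).
#' @export
quality_class <- function(fnat, irmsd, strict = FALSE) {
  stopifnot(fnat >= 0, fnat <= 1, irmsd >= 0)
  if (strict) {
    if (fnat < 0.10 || irmsd > 4.0) return("Incorrect")
    if (fnat >= 0.50 && irmsd <= 1.0) return("High")
    if (fnat >= 0.30 && fnat < 0.50 && irmsd > 1.0 && irmsd <= 2.0)
      return("Medium")
    if (fnat >= 0.10 && fnat < 0.30 && irmsd > 2.0 && irmsd <= 4.0)
      return("Acceptable")
    return("Unclassified")
  }
  if (fnat < 0.10 || irmsd > 4.0) return("Incorrect")
  if (fnat >= 0.50 && irmsd <= 1.0) return("High")
  if (fnat >= 0.30 && irmsd <= 2.0) return("Medium")
  "Acceptable"
}

#' Full CAPRI score of a pose against the native complex
#'
#' @param pose,native [hexa_structure] objects.
#' @param contact_cutoff contact cutoff in Angstrom (default 6.0).
#' @param strict passed to [quality_class()].
#' @return A list of class `"capri_score"`: `fnat`, `fnonnat` (`NA` when the
#'   pose has no contacts), `irmsd`, `quality`.
#' @export
capri_score <- function(pose, native, contact_cutoff = 6.0, strict = FALSE) {
  nc <- contact_pairs(native, cutoff = contact_cutoff)
  pc <- contact_pairs(pose, cutoff = contact_cutoff)
  fn <- fnat(pc, nc)
  ir <- irmsd(pose, native, contact_cutoff = contact_cutoff)
  base::structure(list(fnat = fn, fnonnat = fnonnat(pc, nc), irmsd = ir,
                       quality = quality_class(fn, ir, strict = strict)),
                  class = "capri_score")
}

#' @export
print.capri_score <- function(x, ...) {
  cat(sprintf("CAPRI score: fnat %.3f, fnonnat %s, irmsd %.3f A, %s\n",
              x$fnat,
              if (is.na(x$fnonnat)) "NA" else sprintf("%.3f", x$fnonnat),
              x$irmsd, x$quality))
  invisible(x)
}
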