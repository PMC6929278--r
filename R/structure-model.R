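#' @title Two-unit structure model
#' @name hexa_structure
#' @description A `hexa_structure` is a light S3 container for a two-unit
#'   (receptor/ligand) protein complex: an atom table (chain, residue number,
#'   insertion code, residue type, atom name, coordinates) plus the two
#'   disjoint chain-id sets partitioning the chains into receptor and ligand
#'   units. Residues are addressed by a uid string `"chain.resno"` (with the
#'   insertion code appended when present).
NULL

residue_uid <- function(chain, resno, icode = "") {
  ic <- ifelse(is.na(icode) | icode == "" | icode == " ", "", icode)
  paste0(chain, ".", resno, ic)
}

new_structure <- function(atoms, receptor_ids, ligand_ids) {
  atoms$uid <- residue_uid(atoms$chain, atoms$resno, atoms$icode)
  chains <- unique(atoms$chain)
  if (!all(receptor_ids %in% chains))
    stop("receptor chain id(s) not in structure: ",
         paste(setdiff(receptor_ids, chains), collapse = ", "))
  if (!all(ligand_ids %in% chains))
    stop("ligand chain id(s) not in structure: ",
         paste(setdiff(ligand_ids, chains), collapse = ", "))
  if (length(intersect(receptor_ids, ligand_ids)))
    stop("receptor and ligand chain sets must be disjoint")
  if (!length(receptor_ids) || !length(ligand_ids))
    stop("both units must contain at least one chain")
  extra <- setdiff(chains, c(receptor_ids, ligand_ids))
  if (length(extra))
    stop("chain(s) not assigned to a unit: ", paste(extra, collapse = ", "))
  atoms$unit <- ifelse(atoms$chain %in% receptor_ids, "receptor", "ligand")
  structure(list(atoms = atoms,
                 receptor_ids = receptor_ids,
                 ligand_ids = ligand_ids),
            class = "hexa_structure")
}

#' @export
print.hexa_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("hexa_structure: ", nrow(x$atoms), " atoms, ", nrow(rt), " residues\n",
      "  receptor chains: ", paste(x$receptor_ids, collapse = ","),
      " (", sum(rt$unit == "receptor"), " residues)\n",
      "  ligand chains:   ", paste(x$ligand_ids, collapse = ","),
      " (", sum(rt$unit == "ligand"), " residues)\n", sep = "")
  invisible(x)
}

#' Build a structure from an atom table
#'
#' Programmatic constructor for a [hexa_structure] from a data.frame of
#' atoms, for synthetic structures and tests. Missing optional columns get
#' defaults (`icode = ""`, `resid = "ALA"`, `o = 1`).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `elety`, `x`,
#'   `y`, `z` and optionally `icode`, `resid`, `o`.
#' @param receptor_ids,ligand_ids chain-id sets of the two units.
#' @return A [hexa_structure].
#' @export
as_structure <- function(atoms, receptor_ids, ligand_ids) {
  need <- c("chain", "resno", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  if (is.null(atoms$o)) atoms$o <- 1
  new_structure(atoms[, c("chain", "resno", "icode", "resid", "elety",
                          "x", "y", "z", "o")],
                receptor_ids, ligand_ids)
}

#' Read a PDB file into a two-unit structure
#'
#' Parses ATOM records through bio3d, drops HETATM/water records, resolves
#' alternate locations to the highest-occupancy copy (ties broken by altLoc
#' label order), and partitions chains into receptor and ligand units.
#'
#' @param file path to a PDB file, or a character scalar of PDB text
#'   (detected by embedded newlines).
#' @param receptor_ids,ligand_ids character vectors of chain ids forming the
#'   two units. Every chain in the file must belong to exactly one unit.
#' @return A [hexa_structure] object; residues keep file order.
#' @export
read_pdb <- function(file, receptor_ids, ligand_ids) {
  if (length(file) == 1L && grepl("\n", file)) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(strsplit(file, "\n")[[1]], tmp)
    file <- tmp
  }
  pdb <- tryCatch(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (!nrow(at)) stop("no ATOM records found")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  ## altloc resolution: within (chain, resno, icode, atom name) keep the
  ## highest-occupancy record; ties by altLoc label order.
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "\r"),
                       unique(paste(at$chain, at$resno, at$insert,
                                    sep = "\r")))), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno, icode = at$insert,
                      resid = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z, o = at$o,
                      stringsAsFactors = FALSE)
  new_structure(atoms, receptor_ids, ligand_ids)
}

#' Write a structure to a PDB file
#'
#' @param structure a [hexa_structure].
#' @param file output path.
#' @return Invisibly, the path written.
#' @export
write_pdb <- function(structure, file) {
  a <- structure$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz, resno = a$resno, chain = a$chain,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   resid = a$resid, elety = a$elety, o = a$o)
  invisible(file)
}

#' Residue-level summary table of a structure
#'
#' @param structure a [hexa_structure].
#' @return A data.frame with one row per residue in file order: `uid`,
#'   `chain`, `resno`, `icode`, `resid` (3-letter), `aa` (1-letter, NA for
#'   unknown types), `unit`, and `seqpos` (1-based rank within its chain,
#'   insertion codes ordered after their base index by file order).
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  first <- !duplicated(a$uid)
  rt <- a[first, c("uid", "chain", "resno", "icode", "resid", "unit")]
  rt$aa <- unname(AA_ONE[rt$resid])
  rt$seqpos <- stats::ave(seq_len(nrow(rt)), rt$chain,
                          FUN = seq_along)
  rownames(rt) <- NULL
  rt
}

#' Chain sequences of a structure
#'
#' @param structure a [hexa_structure].
#' @return Named character vector of one-letter sequences, one per chain
#'   (unknown residue types become `X`).
#' @export
chain_sequences <- function(structure) {
  rt <- residue_table(structure)
  rt$aa[is.na(rt$aa)] <- "X"
  vapply(split(rt$aa, rt$chain), paste, character(1), collapse = "")[
    unique(rt$chain)]
}

residue_atoms <- function(structure, uid) {
  a <- structure$atoms
  a[a$uid == uid, , drop = FALSE]
}

atom_coord <- function(res_atoms, name) {
  i <- which(res_atoms$elety == name)
  if (!length(i)) return(NULL)
  as.numeric(res_atoms[i[1], c("x", "y", "z")])
}

## ---- contacts ----------------------------------------------------------

#' Inter-unit residue contacts
#'
#' A receptor residue and a ligand residue are in contact when the minimum
#' distance over all their atom pairs is strictly below the cutoff (the 6-A
#' interface rule by default). Candidate residue pairs are pre-filtered by
#' centroid distance before exact atom-pair minimization.
#'
#' @param structure a [hexa_structure]; both units must contain atoms.
#' @param cutoff contact cutoff in Angstrom (default 6.0, strict `<`).
#' @return A data.frame of class `"contact_set"` with columns `rec_uid`,
#'   `lig_uid`, `dist` (minimum inter-atomic distance), one row per residue
#'   pair, and attribute `cutoff`.
#' @export
contact_pairs <- function(structure, cutoff = 6.0) {
  a <- structure$atoms
  rec <- a[a$unit == "receptor", , drop = FALSE]
  lig <- a[a$unit == "ligand", , drop = FALSE]
  if (!nrow(rec) || !nrow(lig)) stop("both units must contain atoms")

  split_unit <- function(u) {
    uids <- unique(u$uid)
    coords <- lapply(uids, function(id)
      as.matrix(u[u$uid == id, c("x", "y", "z"), drop = FALSE]))
    cent <- t(vapply(coords, colMeans, numeric(3)))
    rad <- vapply(seq_along(coords), function(i)
      sqrt(max(rowSums(sweep(coords[[i]], 2, cent[i, ])^2))), numeric(1))
    list(uids = uids, coords = coords, cent = cent, rad = rad)
  }
  R <- split_unit(rec); L <- split_unit(lig)

  ## centroid-distance prefilter: a pair can only contact if centroids are
  ## within cutoff + both residue radii
  cd <- sqrt(outer(rowSums(R$cent^2), rowSums(L$cent^2), "+") -
               2 * R$cent %*% t(L$cent))
  bound <- outer(R$rad, L$rad, "+") + cutoff
  cand <- which(cd < bound, arr.ind = TRUE)

  out <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    ca <- R$coords[[i]]; cb <- L$coords[[j]]
    d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
    dmin <- sqrt(max(0, min(d2)))
    if (dmin < cutoff)
      out[[length(out) + 1L]] <- data.frame(rec_uid = R$uids[i],
                                            lig_uid = L$uids[j],
                                            dist = dmin,
                                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(rec_uid = character(0), lig_uid = character(0),
               dist = numeric(0), stringsAsFactors = FALSE)
  res <- res[order(res$rec_uid, res$lig_uid), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "cutoff") <- cutoff
  class(res) <- c("contact_set", class(res))
  res
}

#' Interface residues of a contact set
#'
#' @param contacts a `"contact_set"` from [contact_pairs()].
#' @return A list with `receptor` and `ligand`: sorted character vectors of
#'   residue uids appearing in at least one contact pair.
#' @export
interface_residues <- function(contacts) {
  list(receptor = sort(unique(contacts$rec_uid)),
       ligand = sort(unique(contacts$lig_uid)))
}

## ---- residue-local frames ----------------------------------------------

cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-8) stop("degenerate geometry: zero-length axis vector")
  v / n
}

## Tetrahedral virtual C-beta from backbone N, CA, C: bond length 1.53 A,
## both angles N-CA-CB and C-CA-CB equal to 110.5 degrees, on the side of
## the N-CA-C plane given by the right-handed cross product (the L-amino-acid
## side for standard backbone chirality).
virtual_cbeta <- function(n, ca, c) {
  a <- unit3(n - ca); b <- unit3(c - ca)
  s <- a + b
  if (sqrt(sum(s^2)) < 1e-8 || sqrt(sum(cross3(a, b)^2)) < 1e-8)
    stop("degenerate geometry: N, CA, C collinear, cannot place virtual CB")
  p <- unit3(s)                    # in-plane bisector of N and C directions
  q <- unit3(cross3(a, b))         # normal to the N-CA-C plane
  cos_t <- cos(110.5 * pi / 180)
  u <- -cos_t / sqrt((1 + sum(a * b)) / 2)   # component along -p
  if (u > 1) u <- 1
  v <- sqrt(max(0, 1 - u^2))
  ca + 1.53 * (-u * p + v * q)
}

#' Residue-local coordinate frame
#'
#' Builds the canonical frame of a residue: the C-alpha atom at the origin,
#' the C-beta direction along the positive y-axis, and the backbone N in the
#' x-y plane with positive x. Glycine (or any residue lacking C-beta) gets a
#' virtual C-beta placed by the tetrahedral rule from N, CA, C (bond 1.53 A,
#' angles 110.5 degrees).
#'
#' @param structure a [hexa_structure].
#' @param uid residue uid (see [residue_table()]).
#' @return A list of class `"residue_frame"` with `origin` (C-alpha, length-3)
#'   and `axes` (3 x 3 orthonormal matrix whose columns are the world-space
#'   x, y, z frame axes; `det = +1`). World coordinates `p` map into the
#'   frame as `t(axes) %*% (p - origin)`.
#' @export
residue_frame <- function(structure, uid) {
  ra <- residue_atoms(structure, uid)
  if (!nrow(ra)) stop("no such residue: ", uid)
  ca <- atom_coord(ra, "CA"); n <- atom_coord(ra, "N")
  if (is.null(ca) || is.null(n))
    stop("residue ", uid, " lacks CA or N; frame undefined")
  cb <- atom_coord(ra, "CB")
  if (is.null(cb)) {
    c_at <- atom_coord(ra, "C")
    if (is.null(c_at))
      stop("residue ", uid, " lacks CB and C; cannot construct virtual CB")
    cb <- virtual_cbeta(n, ca, c_at)
  }
  y <- unit3(cb - ca)
  nv <- n - ca
  xr <- nv - sum(nv * y) * y
  if (sqrt(sum(xr^2)) < 1e-6)
    stop("degenerate geometry: CA, CB, N collinear for residue ", uid)
  x <- unit3(xr)
  z <- cross3(x, y)
  base::structure(list(origin = ca, axes = cbind(x = x, y = y, z = z),
                       uid = uid),
                  class = "residue_frame")
}

#' Map world coordinates into a residue frame
#'
#' @param frame a `"residue_frame"` from [residue_frame()].
#' @param coords n x 3 matrix (or length-3 vector) of world coordinates.
#' @return n x 3 matrix of frame coordinates.
#' @export
frame_coords <- function(frame, coords) {
  m <- if (is.null(dim(coords))) matrix(coords, 1) else as.matrix(coords)
  sweep(m, 2, frame$origin) %*% frame$axes
}

## ---- hexagon spatial neighbors -----------------------------------------

## Azimuthal sector about the frame y-axis: angle in the x-z plane measured
## from +x toward +z; sector s covers [60(s-1), 60s) degrees, half-open.
hexagon_sector <- function(fc) {
  phi <- atan2(fc[, 3], fc[, 1]) * 180 / pi
  phi <- phi %% 360
  pmin(floor(phi / 60) + 1L, 6L)
}

#' Hexagon spatial neighbors of a residue
#'
#' Partitions space around a residue into six 60-degree azimuthal sectors
#' about its frame y-axis and, per sector, selects the non-local residue
#' whose C-alpha is nearest to the target C-alpha and strictly within the
#' cutoff. A residue is non-local when it lies on another chain, or on the
#' same chain at sequence separation `|delta seqpos| >= min_sep` (default 4,
#' i.e. at least three residues strictly between).
#'
#' @param structure a [hexa_structure].
#' @param uid target residue uid.
#' @param cutoff C-alpha distance cutoff in Angstrom (default 10).
#' @param min_sep minimum same-chain sequence separation (default 4; set 3
#'   for the looser non-locality reading).
#' @param cross_chain logical; whether residues of other chains are eligible
#'   (default TRUE).
#' @return Character vector of length 6 (sectors 1..6) of neighbor uids,
#'   `NA` where a sector is empty; attribute `dist` holds the six C-alpha
#'   distances.
#' @export
hexagon_neighbors <- function(structure, uid, cutoff = 10.0, min_sep = 4L,
                              cross_chain = TRUE) {
  fr <- residue_frame(structure, uid)
  rt <- residue_table(structure)
  tgt <- rt[rt$uid == uid, ]
  a <- structure$atoms
  ca <- a[a$elety == "CA", , drop = FALSE]
  ca <- ca[ca$uid != uid, , drop = FALSE]
  pos <- rt$seqpos[match(ca$uid, rt$uid)]
  chain <- rt$chain[match(ca$uid, rt$uid)]
  same <- chain == tgt$chain
  eligible <- (same & abs(pos - tgt$seqpos) >= min_sep) |
    (!same & cross_chain)
  ca <- ca[eligible, , drop = FALSE]
  out <- rep(NA_character_, 6)
  dists <- rep(NA_real_, 6)
  if (nrow(ca)) {
    fc <- frame_coords(fr, as.matrix(ca[, c("x", "y", "z")]))
    d <- sqrt(rowSums(fc^2))
    keep <- d < cutoff
    if (any(keep)) {
      fc <- fc[keep, , drop = FALSE]; d <- d[keep]; uids <- ca$uid[keep]
      sec <- hexagon_sector(fc)
      for (s in 1:6) {
        in_s <- which(sec == s)
        if (length(in_s)) {
          best <- in_s[order(d[in_s], uids[in_s])][1]  # ties: uid order
          out[s] <- uids[best]
          dists[s] <- d[best]
        }
      }
    }
  }
  attr(out, "dist") <- dists
  out
}

## ---- rigid transforms and superposition --------------------------------

#' Rigid transform constructor
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 translation vector (Angstrom).
#' @return A list of class `"rigid_transform"`. Applied to row-vector
#'   coordinates as `x %*% t(rotation) + translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation determinant must be +1 (no reflections)")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param t a `"rigid_transform"`.
#' @return The inverse `"rigid_transform"`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation),
                  -as.numeric(t$translation %*% t$rotation))
}

#' Compose two rigid transforms
#' @param t2,t1 `"rigid_transform"` objects; the result applies `t1` first.
#' @return The composite `"rigid_transform"`.
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t1$translation %*% t(t2$rotation)) +
                    t2$translation)
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param t a `"rigid_transform"`.
#' @return n x 3 transformed matrix.
#' @export
transform_coords <- function(coords, t) {
  m <- if (is.null(dim(coords))) matrix(coords, 1) else as.matrix(coords)
  sweep(m %*% t(t$rotation), 2, t$translation, "+")
}

#' Apply a rigid transform to one unit of a structure
#'
#' @param structure a [hexa_structure].
#' @param t a `"rigid_transform"`.
#' @param unit `"ligand"` (default) or `"receptor"`: the unit whose
#'   coordinates move; the other unit is untouched.
#' @return A new [hexa_structure].
#' @export
apply_transform <- function(structure, t, unit = c("ligand", "receptor")) {
  unit <- match.arg(unit)
  a <- structure$atoms
  sel <- a$unit == unit
  a[sel, c("x", "y", "z")] <-
    transform_coords(as.matrix(a[sel, c("x", "y", "z")]), t)
  out <- structure
  out$atoms <- a
  out
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of one point set onto another: returns the
#' proper rotation (no reflection) and translation minimizing the RMSD, via
#' the SVD of the 3 x 3 covariance matrix.
#'
#' @param moving,fixed n x 3 coordinate matrices, n >= 3, matched row order.
#' @return A list with `transform` (a `"rigid_transform"` mapping `moving`
#'   onto `fixed`) and `rmsd` (Angstrom, after superposition).
#' @export
superpose <- function(moving, fixed) {
  P <- as.matrix(moving); Q <- as.matrix(fixed)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3)
    stop("moving and fixed must be matching n x 3 matrices")
  n <- nrow(P)
  if (n < 3) stop("superposition needs at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate point cloud: points are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rmsd <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  tr <- rigid_transform(R, cq - as.numeric(cp %*% t(R)))
  list(transform = tr, rmsd = rmsd)
}
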