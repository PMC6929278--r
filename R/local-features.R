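#' @title Multi-scale local block features
#' @name hexablock-features
#' @description Per-residue feature extractors. The sequential extractor
#'   (MLAB) averages profile rows over six overlapping blocks of an
#'   11-residue window centered on the target (global zone A, bisection B/C,
#'   trichotomy D/E/F). The spatial extractor does the same over the hexagon
#'   window: the target residue plus its six azimuthal-sector neighbors.
#'   Both return fixed-length block-major vectors (6 blocks x profile
#'   columns), with empty blocks zero-filled and flagged.
NULL

#' Default sequential block scheme
#'
#' Slots 1..11 are window positions R-5 .. R .. R+5 (target at slot 6).
#' A = all 11 slots; B = slots up to and including the target, C = target
#' onward (overlapping at the target); D/E/F = a 4/4/3 trichotomy.
#'
#' @return Named list of integer slot-index vectors (A..F) with attribute
#'   `n_slots = 11`.
#' @export
default_mlab_scheme <- function() {
  s <- list(A = 1:11, B = 1:6, C = 6:11, D = 1:4, E = 5:8, F = 9:11)
  attr(s, "n_slots") <- 11L
  s
}

#' Default hexagon block scheme
#'
#' Slots 1..7 hold the target residue (slot 1) then sector neighbors 1..6
#' (slots 2..7). A = all; B = target + sectors 1-3, C = target + sectors
#' 4-6; D/E/F = sector pairs (1,2), (3,4), (5,6).
#'
#' @return Named list of integer slot-index vectors (A..F) with attribute
#'   `n_slots = 7`.
#' @export
default_hexagon_scheme <- function() {
  s <- list(A = 1:7, B = 1:4, C = c(1L, 5:7), D = 2:3, E = 4:5, F = 6:7)
  attr(s, "n_slots") <- 7L
  s
}

validate_scheme <- function(scheme, n_slots) {
  stopifnot(identical(sort(names(scheme)), sort(c("A", "B", "C", "D", "E", "F"))))
  for (b in names(scheme))
    if (any(scheme[[b]] < 1 | scheme[[b]] > n_slots))
      stop("block ", b, " indexes slots outside 1..", n_slots)
  invisible(TRUE)
}

## Fingerprint a scheme for model persistence checks.
scheme_fingerprint <- function(scheme) {
  paste(vapply(c("A", "B", "C", "D", "E", "F"), function(b)
    paste0(b, ":", paste(scheme[[b]], collapse = ",")), character(1)),
    collapse = ";")
}

#' Sequential profile window around a residue
#'
#' @param profile L x p numeric matrix (one profile row per chain position;
#'   typically a normalized PSSM, p = 20).
#' @param i 1-based target position, 1 <= i <= L.
#' @param half_width window half-width (default 5, the 11-slot window).
#' @return A list of class `"seq_window"`: `rows` ((2*half_width+1) x p
#'   matrix, absent slots zero), `present` (logical per slot), `center`
#'   (target slot index).
#' @export
sequential_window <- function(profile, i, half_width = 5L) {
  m <- as.matrix(unclass(profile))
  L <- nrow(m)
  if (i < 1 || i > L) stop("position ", i, " outside 1..", L)
  n_slots <- 2L * half_width + 1L
  rows <- matrix(0, n_slots, ncol(m), dimnames = list(NULL, colnames(m)))
  present <- logical(n_slots)
  for (s in seq_len(n_slots)) {
    pos <- i + (s - half_width - 1L)
    if (pos >= 1 && pos <= L) {
      rows[s, ] <- m[pos, ]
      present[s] <- TRUE
    }
  }
  base::structure(list(rows = rows, present = present,
                       center = half_width + 1L),
                  class = "seq_window")
}

## Shared block-mean core for both extractors: mean of PRESENT rows per
## block; empty blocks -> zeros + flag. Returns block-major flat vector.
block_means <- function(rows, present, scheme) {
  validate_scheme(scheme, nrow(rows))
  blocks <- c("A", "B", "C", "D", "E", "F")
  p <- ncol(rows)
  vals <- numeric(0)
  counts <- integer(6); names(counts) <- blocks
  empty <- logical(6); names(empty) <- blocks
  cn <- colnames(rows)
  if (is.null(cn)) cn <- seq_len(p)
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    sl <- scheme[[b]][present[scheme[[b]]]]
    counts[bi] <- length(sl)
    if (length(sl)) {
      v <- colMeans(rows[sl, , drop = FALSE])
    } else {
      v <- numeric(p)
      empty[bi] <- TRUE
    }
    names(v) <- paste0(b, ".", cn)
    vals <- c(vals, v)
  }
  attr(vals, "counts") <- counts
  attr(vals, "empty") <- empty
  vals
}

#' MLAB features of a sequential window
#'
#' Block-wise means of the window's profile rows: for block k and profile
#' column j, the mean over the block's present rows (count `B_k`); blocks
#' with no present rows yield zeros and an emptiness flag.
#'
#' @param window a `"seq_window"` from [sequential_window()].
#' @param scheme block scheme (default [default_mlab_scheme()]).
#' @return Numeric vector of length `6 * p` (block-major; 120 for a PSSM
#'   profile), with attributes `counts` (present rows per block) and `empty`
#'   (logical per block).
#' @export
mlab_features <- function(window, scheme = default_mlab_scheme()) {
  if (!window$present[window$center]) stop("window center row is absent")
  block_means(window$rows, window$present, scheme)
}

#' Hexagon profile window of a residue
#'
#' Slot 1 carries the target residue's profile row; slots 2..7 carry the
#' rows of the six sector neighbors from [hexagon_neighbors()], absent
#' where a sector is empty. Each neighbor's row is looked up by its chain
#' and 1-based chain position.
#'
#' @param structure a [hexa_structure].
#' @param profiles named list, one L x p profile matrix per chain id.
#' @param uid target residue uid.
#' @param cutoff,min_sep,cross_chain passed to [hexagon_neighbors()].
#' @return A list of class `"hexagon_window"`: `rows` (7 x p), `present`
#'   (logical 7), `neighbors` (uids, NA when absent), `ok` (FALSE when the
#'   target frame could not be built, in which case only the target row is
#'   present and all sectors are empty).
#' @export
hexagon_window <- function(structure, profiles, uid, cutoff = 10.0,
                           min_sep = 4L, cross_chain = TRUE) {
  rt <- residue_table(structure)
  row_of <- function(u) {
    r <- rt[rt$uid == u, ]
    prof <- profiles[[r$chain]]
    if (is.null(prof)) stop("no profile supplied for chain ", r$chain)
    as.matrix(unclass(prof))[r$seqpos, ]
  }
  tgt_row <- row_of(uid)
  p <- length(tgt_row)
  rows <- matrix(0, 7, p, dimnames = list(NULL, names(tgt_row)))
  present <- logical(7)
  rows[1, ] <- tgt_row
  present[1] <- TRUE
  nb <- rep(NA_character_, 6)
  ok <- TRUE
  res <- tryCatch(hexagon_neighbors(structure, uid, cutoff = cutoff,
                                    min_sep = min_sep,
                                    cross_chain = cross_chain),
                  error = function(e) e)
  if (inherits(res, "error")) {
    ok <- FALSE                       # chain break / missing backbone: no
  } else {                            # spatial context, target row only
    nb <- res
    for (s in 1:6) {
      if (!is.na(nb[s])) {
        rows[s + 1L, ] <- row_of(nb[s])
        present[s + 1L] <- TRUE
      }
    }
  }
  base::structure(list(rows = rows, present = present,
                       neighbors = as.character(nb), ok = ok),
                  class = "hexagon_window")
}

#' Hexagon features of a spatial window
#'
#' Block-wise means over the hexagon window's present rows, exactly as
#' [mlab_features()] but over the 7 spatial slots (target + 6 sectors).
#'
#' @param window a `"hexagon_window"` from [hexagon_window()].
#' @param scheme block scheme (default [default_hexagon_scheme()]).
#' @return Numeric vector of length `6 * p` (120 for a PSSM profile) with
#'   `counts` and `empty` attributes.
#' @export
hexagon_features <- function(window, scheme = default_hexagon_scheme()) {
  if (!window$present[1]) stop("hexagon window lacks its target row")
  block_means(window$rows, window$present, scheme)
}

#' Per-residue MLAB + hexagon feature map for a whole structure
#'
#' Convenience wrapper computing, for every residue, the 120-component MLAB
#' vector from its chain profile and the 120-component hexagon vector from
#' the structure geometry.
#'
#' @param structure a [hexa_structure].
#' @param profiles named list of L x 20 chain profiles (normalized PSSMs).
#' @param hex_cutoff,min_sep,cross_chain hexagon parameters.
#' @param mlab_scheme,hexagon_scheme block schemes.
#' @return Numeric matrix, one row per residue (rownames = uids), 240
#'   columns (`mlab.*` then `hex.*`).
#' @export
residue_feature_map <- function(structure, profiles, hex_cutoff = 10.0,
                                min_sep = 4L, cross_chain = TRUE,
                                mlab_scheme = default_mlab_scheme(),
                                hexagon_scheme = default_hexagon_scheme()) {
  rt <- residue_table(structure)
  out <- NULL
  for (i in seq_len(nrow(rt))) {
    prof <- profiles[[rt$chain[i]]]
    if (is.null(prof)) stop("no profile supplied for chain ", rt$chain[i])
    mv <- mlab_features(sequential_window(prof, rt$seqpos[i]), mlab_scheme)
    hw <- hexagon_window(structure, profiles, rt$uid[i], cutoff = hex_cutoff,
                         min_sep = min_sep, cross_chain = cross_chain)
    hv <- hexagon_features(hw, hexagon_scheme)
    v <- c(mv, hv)
    if (is.null(out))
      out <- matrix(0, nrow(rt), length(v),
                    dimnames = list(rt$uid, c(paste0("mlab.", names(mv)),
                                              paste0("hex.", names(hv)))))
    out[i, ] <- v
  }
  out
}
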