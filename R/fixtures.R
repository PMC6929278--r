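#' @title Deterministic synthetic fixtures
#' @name synthetic-fixtures
#' @description Seeded generators for idealized chains, two-chain toy
#'   complexes, rigid-body decoy ladders with computed CAPRI labels, and
#'   synthetic evolutionary profiles. Every generator is a pure function of
#'   its arguments and seed; independent random streams are derived by
#'   stable hashing of (seed, generator name, call index) so adding one
#'   generator never shifts another's draws.
NULL

#' Derive a per-generator stream seed
#'
#' @param seed global integer seed.
#' @param name generator name.
#' @param index call index (default 0).
#' @return An integer in \[0, 2^31), a stable hash of the three arguments.
#' @export
stream_seed <- function(seed, name, index = 0L) {
  h <- as.numeric(seed) %% 2147483629
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483629
  as.integer((h * 7919 + as.numeric(index) * 104729) %% 2147483629)
}

## Ideal-geometry parameters of the chain generator. CA atoms sit on a
## regular helix (radius r, twist per residue, rise per residue); backbone
## N and C are placed at +/-55.5 degrees from the local axis-normal in the
## tangent/normal plane (so the N-CA-C angle is 111 degrees), O off the
## carbonyl, CB radially outward.
CHAIN_GEOMETRY <- list(
  helix  = list(radius = 2.3, twist = 100 * pi / 180, rise = 1.5),
  strand = list(radius = 1.0, twist = 165 * pi / 180, rise = 3.2))

#' Ideal C-alpha geometry parameters
#'
#' Exposes the generator's internal helix parameters so tests can derive
#' expected geometry (e.g. the consecutive C-alpha distance
#' `sqrt((2 r sin(twist/2))^2 + rise^2)`) in closed form.
#'
#' @param geometry `"helix"` or `"strand"`.
#' @return List with `radius` (A), `twist` (radians per residue), `rise`
#'   (A per residue).
#' @export
chain_geometry <- function(geometry = c("helix", "strand")) {
  CHAIN_GEOMETRY[[match.arg(geometry)]]
}

#' Generate an ideal-geometry chain
#'
#' Places a deterministic poly-residue chain with complete N, CA, C, O, CB
#' backbones on an ideal helical (or extended-strand) curve along the
#' z-axis. No randomness: two calls with the same arguments are
#' bit-identical.
#'
#' @param n residue count (>= 1).
#' @param geometry `"helix"` (default) or `"strand"`.
#' @param chain_id single-letter chain id.
#' @param sequence optional one-letter sequence of length `n`; defaults to
#'   cycling through the 20-type alphabet.
#' @return Atom data.frame (columns chain, resno, icode, resid, elety,
#'   x, y, z, o) suitable for assembly into a [hexa_structure].
#' @export
make_ideal_chain <- function(n, geometry = c("helix", "strand"),
                             chain_id = "A", sequence = NULL) {
  if (n < 1) stop("chain length must be >= 1")
  g <- chain_geometry(match.arg(geometry))
  if (is.null(sequence))
    sequence <- paste(rep(AA_ALPHABET, length.out = n), collapse = "")
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != n) stop("sequence length must equal n")

  half <- 55.5 * pi / 180              # half of the 111-degree N-CA-C angle
  rows <- list()
  for (i in seq_len(n)) {
    th <- (i - 1) * g$twist
    ca <- c(g$radius * cos(th), g$radius * sin(th), (i - 1) * g$rise)
    u <- c(cos(th), sin(th), 0)                       # radial outward
    tv <- c(-g$radius * g$twist * sin(th),
            g$radius * g$twist * cos(th), g$rise)
    tv <- tv / sqrt(sum(tv^2))                        # curve tangent
    w <- cross3(tv, u); w <- w / sqrt(sum(w^2))
    nd <- -sin(half) * tv + cos(half) * w
    cd <- sin(half) * tv + cos(half) * w
    xyz <- rbind(N = ca + 1.46 * nd,
                 CA = ca,
                 C = ca + 1.52 * cd,
                 O = ca + 1.52 * cd + 1.23 * u,
                 CB = ca + 1.53 * u)
    res3 <- AA_THREE[aa[i]]
    keep <- if (aa[i] == "G") c("N", "CA", "C", "O") else rownames(xyz)
    rows[[i]] <- data.frame(chain = chain_id, resno = i, icode = "",
                            resid = unname(res3), elety = keep,
                            x = xyz[keep, 1], y = xyz[keep, 2],
                            z = xyz[keep, 3], o = 1,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a two-chain toy complex with a controlled interface
#'
#' Assembles a receptor chain and a ligand chain (both ideal geometry,
#' parallel axes) and slides the ligand along the x-axis until the minimum
#' inter-unit atom distance equals `contact_distance` (within 0.01 A), so
#' the 6-A interface is non-empty exactly when `contact_distance < 6`.
#'
#' @param n_receptor,n_ligand chain lengths (default 25 each).
#' @param contact_distance target closest-approach distance in Angstrom
#'   (default 4.5).
#' @param geometry chain geometry for both chains.
#' @param receptor_id,ligand_id chain ids (default A and B).
#' @param seed recorded in the result's `seed` attribute (the construction
#'   itself is deterministic).
#' @return A [hexa_structure] with attribute `seed`.
#' @export
make_toy_complex <- function(n_receptor = 25L, n_ligand = 25L,
                             contact_distance = 4.5,
                             geometry = "helix",
                             receptor_id = "A", ligand_id = "B",
                             seed = 1L) {
  ra <- make_ideal_chain(n_receptor, geometry, receptor_id)
  la <- make_ideal_chain(n_ligand, geometry, ligand_id)
  rxyz <- as.matrix(ra[, c("x", "y", "z")])
  lxyz0 <- as.matrix(la[, c("x", "y", "z")])
  mind <- function(s) {
    lx <- sweep(lxyz0, 2, c(s, 0, 0), "+")
    d2 <- outer(rowSums(rxyz^2), rowSums(lx^2), "+") - 2 * rxyz %*% t(lx)
    sqrt(max(0, min(d2)))
  }
  lo <- 0; hi <- 10 + contact_distance
  while (mind(hi) < contact_distance) hi <- hi + 10
  for (it in 1:60) {                       # bisection on the x-offset
    mid <- (lo + hi) / 2
    if (mind(mid) < contact_distance) lo <- mid else hi <- mid
  }
  s <- hi
  if (abs(mind(s) - contact_distance) > 0.1)
    stop("could not place ligand at the requested contact distance")
  la[, c("x", "y", "z")] <- sweep(lxyz0, 2, c(s, 0, 0), "+")
  out <- new_structure(rbind(ra, la), receptor_id, ligand_id)
  attr(out, "seed") <- seed
  out
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

rotation_about_axis <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Random rigid perturbation of a unit about its centroid
#'
#' Rotation by `rot_deg` about a uniformly random axis through the unit
#' centroid, followed by translation of norm `trans_ang` in a uniformly
#' random direction. Draws from the current RNG state.
#'
#' @param structure a [hexa_structure].
#' @param trans_ang translation magnitude in Angstrom.
#' @param rot_deg rotation magnitude in degrees.
#' @param unit which unit the transform will be applied to (its centroid is
#'   the rotation center).
#' @return A `"rigid_transform"`.
#' @export
random_perturbation <- function(structure, trans_ang, rot_deg,
                                unit = "ligand") {
  a <- structure$atoms
  cen <- colMeans(as.matrix(a[a$unit == unit, c("x", "y", "z")]))
  R <- if (rot_deg > 0)
    rotation_about_axis(random_unit_vector(), rot_deg * pi / 180)
  else diag(3)
  tv <- if (trans_ang > 0) trans_ang * random_unit_vector() else c(0, 0, 0)
  ## rotate about the centroid, then translate
  rigid_transform(R, cen - as.numeric(cen %*% t(R)) + tv)
}

#' Generate a decoy ladder with computed CAPRI labels
#'
#' Perturbs the native ligand unit by seeded random rigid transforms at a
#' ladder of magnitudes and labels every decoy with its true CAPRI score
#' against the native. The default ladder (translations 0.5/1/2/3/4 A,
#' rotations of `rot_deg_per_ang = 5` degrees per Angstrom) spans
#' High-quality to Incorrect poses.
#'
#' @param native a [hexa_structure] with a non-empty interface.
#' @param magnitudes translation magnitudes in Angstrom, one ladder rung
#'   each.
#' @param n_per_magnitude decoys per rung (default 20).
#' @param seed global seed; the ladder uses the `"decoy_ladder"` stream.
#' @param rot_deg_per_ang rotation magnitude per Angstrom of translation.
#' @param contact_cutoff CAPRI contact cutoff (default 6.0).
#' @return A data.frame of class `"decoy_ladder"`: `pose_id`, `magnitude`,
#'   `fnat`, `fnonnat`, `irmsd`, `quality`; attribute `poses` holds the
#'   corresponding list of [hexa_structure] decoys, attribute `seed` the
#'   seed.
#' @export
make_decoy_ladder <- function(native, magnitudes = c(0.5, 1, 2, 3, 4),
                              n_per_magnitude = 20L, seed = 1L,
                              rot_deg_per_ang = 5, contact_cutoff = 6.0) {
  if (any(magnitudes < 0)) stop("magnitudes must be >= 0")
  nc <- contact_pairs(native, cutoff = contact_cutoff)
  if (!nrow(nc)) stop("native complex has no interface")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stream_seed(seed, "decoy_ladder"))
  poses <- list(); rows <- list(); id <- 0L
  for (m in magnitudes) {
    for (j in seq_len(n_per_magnitude)) {
      id <- id + 1L
      tr <- random_perturbation(native, trans_ang = m,
                                rot_deg = m * rot_deg_per_ang)
      pose <- apply_transform(native, tr, unit = "ligand")
      sc <- capri_score(pose, native, contact_cutoff = contact_cutoff)
      pid <- sprintf("decoy_%03d", id)
      poses[[pid]] <- pose
      rows[[id]] <- data.frame(pose_id = pid, magnitude = m,
                               fnat = sc$fnat, fnonnat = sc$fnonnat,
                               irmsd = sc$irmsd, quality = sc$quality,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "poses") <- poses
  attr(out, "seed") <- seed
  class(out) <- c("decoy_ladder", class(out))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic evolutionary profile
#'
#' Draws per-position amino-acid frequency rows from a symmetric
#' Dirichlet-style scheme (normalized Gamma draws with shape =
#' `sharpness`), then derives the substitution-projected profile and its
#' min-max normalized form. Lower `sharpness` concentrates each row on few
#' residue types (sharper profiles).
#'
#' @param L sequence length (>= 1).
#' @param seed global seed; uses the `"synthetic_profile"` stream with
#'   `index`.
#' @param sharpness Dirichlet concentration (default 0.5).
#' @param index call index distinguishing multiple profiles under one seed.
#' @return A list: `omega` (L x 20 frequency profile), `pssm` (L x 20,
#'   via [build_pssm()] with the packaged Dayhoff matrix), `npssm`
#'   (min-max normalized), `seed`.
#' @export
make_synthetic_profile <- function(L, seed = 1L, sharpness = 0.5,
                                   index = 0L) {
  if (L < 1) stop("L must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stream_seed(seed, "synthetic_profile", index))
  g <- matrix(stats::rgamma(L * 20, shape = sharpness) + 1e-12, L, 20)
  omega <- g / rowSums(g)
  colnames(omega) <- AA_ALPHABET
  pssm <- build_pssm(omega)
  list(omega = omega, pssm = pssm, npssm = minmax_normalize(pssm),
       seed = seed)
}
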