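# Shared fixtures and independent oracles used across the suite.

# Minimal structure from per-residue single/multi atom specs:
# res list entries: list(chain, resno, elety vector, xyz matrix, resid)
tiny_structure <- function(res, receptor_ids = "A", ligand_ids = "B") {
  rows <- lapply(res, function(r) {
    xyz <- if (is.null(dim(r$xyz))) matrix(r$xyz, 1) else r$xyz
    data.frame(chain = r$chain, resno = r$resno,
               resid = if (is.null(r$resid)) "ALA" else r$resid,
               elety = r$elety, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  })
  as_structure(do.call(rbind, rows), receptor_ids, ligand_ids)
}

# Brute-force contact oracle: loop over every atom pair of every
# receptor/ligand residue pair, no prefilters.
oracle_contacts <- function(structure, cutoff = 6.0) {
  a <- structure$atoms
  rec <- a[a$unit == "receptor", ]
  lig <- a[a$unit == "ligand", ]
  out <- list()
  for (ru in unique(rec$uid)) for (lu in unique(lig$uid)) {
    ra <- rec[rec$uid == ru, c("x", "y", "z")]
    la <- lig[lig$uid == lu, c("x", "y", "z")]
    dmin <- Inf
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(la)))
      dmin <- min(dmin, sqrt(sum((as.numeric(ra[i, ]) -
                                    as.numeric(la[j, ]))^2)))
    if (dmin < cutoff)
      out[[length(out) + 1]] <- data.frame(rec_uid = ru, lig_uid = lu,
                                           dist = dmin,
                                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(rec_uid = character(0), lig_uid = character(0),
               dist = numeric(0))
  res[order(res$rec_uid, res$lig_uid), , drop = FALSE]
}

# Quaternion-method optimal superposition RMSD (Horn 1987): independent of
# the package's SVD/Kabsch path.
oracle_quaternion_rmsd <- function(moving, fixed) {
  P <- sweep(as.matrix(moving), 2, colMeans(as.matrix(moving)))
  Q <- sweep(as.matrix(fixed), 2, colMeans(as.matrix(fixed)))
  S <- t(P) %*% Q
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# Brute-force hexagon sector assignment: recompute every candidate's frame
# azimuth directly and scan sectors by definition.
oracle_hexagon <- function(structure, uid, cutoff = 10, min_sep = 4,
                           cross_chain = TRUE) {
  fr <- residue_frame(structure, uid)
  rt <- residue_table(structure)
  tgt <- rt[rt$uid == uid, ]
  best_uid <- rep(NA_character_, 6)
  best_d <- rep(Inf, 6)
  for (i in seq_len(nrow(rt))) {
    if (rt$uid[i] == uid) next
    same <- rt$chain[i] == tgt$chain
    if (same && abs(rt$seqpos[i] - tgt$seqpos) < min_sep) next
    if (!same && !cross_chain) next
    ra <- structure$atoms[structure$atoms$uid == rt$uid[i] &
                            structure$atoms$elety == "CA", ]
    if (!nrow(ra)) next
    fc <- frame_coords(fr, as.numeric(ra[1, c("x", "y", "z")]))
    d <- sqrt(sum(fc^2))
    if (d >= cutoff) next
    phi <- (atan2(fc[3], fc[1]) * 180 / pi) %% 360
    s <- min(floor(phi / 60) + 1, 6)
    if (d < best_d[s] ||
        (d == best_d[s] && !is.na(best_uid[s]) && rt$uid[i] < best_uid[s])) {
      best_d[s] <- d
      best_uid[s] <- rt$uid[i]
    }
  }
  best_uid
}

# A rigid transform drawn from the current RNG state.
random_rigid <- function(max_trans = 20) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  rigid_transform(R, stats::runif(3, -max_trans, max_trans))
}

# Small PSI-BLAST ASCII fixture (3 residues, standard 44-column layout),
# written in code at test time.
psiblast_fixture_lines <- function() {
  pb <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")
  set.seed(7)
  sc <- matrix(sample(-8:11, 60, replace = TRUE), 3, 20)
  fq <- matrix(0, 3, 20)
  for (i in 1:3) { v <- sample(0:20, 20, replace = TRUE); fq[i, ] <- round(v / sum(v) * 100) }
  hdr <- paste0("            ", paste(sprintf("%3s", pb), collapse = " "),
                "  ", paste(sprintf("%3s", pb), collapse = " "))
  rows <- vapply(1:3, function(i)
    paste0(sprintf("%5d %s  ", i, c("M", "K", "V")[i]),
           paste(sprintf("%3d", sc[i, ]), collapse = " "), "  ",
           paste(sprintf("%3d", fq[i, ]), collapse = " "),
           "  0.30     0.08"), character(1))
  list(lines = c("", "Last position-specific scoring matrix computed",
                 hdr, rows, "", "                      K         Lambda",
                 "Standard Ungapped    0.1337     0.3179"),
       scores = sc, freqs = fq, pb_order = pb, sequence = "MKV")
}
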