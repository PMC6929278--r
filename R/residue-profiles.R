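#' Normalize the physicochemical table to zero mean and unit SD
#'
#' Z-scores each property column over the 20 amino-acid types. The 20 types
#' are the whole population, so the population standard deviation
#' (denominator 20) is used by default; a flag switches to the sample SD
#' (denominator 19).
#'
#' @param table 20 x 6 numeric matrix as returned by [physchem_table()].
#' @param sample_sd logical; use the sample SD instead of the population SD.
#' @return A 20 x 6 matrix of class `"physchem_norm"`; each column has mean 0
#'   and SD 1 (under the chosen convention).
#' @export
#' @examples
#' colMeans(normalize_physchem(physchem_table()))
normalize_physchem <- function(table = physchem_table(), sample_sd = FALSE) {
  stopifnot(is.matrix(table), ncol(table) >= 1)
  if (any(!is.finite(table))) stop("physicochemical table has non-finite cells")
  n <- nrow(table)
  mu <- colMeans(table)
  dev <- sweep(table, 2, mu)
  denom <- if (sample_sd) n - 1 else n
  sd <- sqrt(colSums(dev^2) / denom)
  if (any(sd < .Machine$double.eps))
    stop("constant property column: SD is zero, cannot normalize")
  out <- sweep(dev, 2, sd, "/")
  class(out) <- c("physchem_norm", class(out))
  out
}

#' Encode a sequence with normalized physicochemical properties
#'
#' @param sequence character; an amino-acid string or a vector of one-letter
#'   codes.
#' @param table normalized table from [normalize_physchem()].
#' @param strict logical; reject non-standard codes instead of remapping
#'   (B to N, Z to Q, U to C, O to K, X to the column means).
#' @return An L x 6 numeric matrix; row i encodes residue i.
#' @export
encode_physchem <- function(sequence, table = normalize_physchem(),
                            strict = FALSE) {
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  idx <- aa_index(aa, strict = strict)
  out <- matrix(NA_real_, length(aa), ncol(table),
                dimnames = list(NULL, colnames(table)))
  known <- !is.na(idx)
  out[known, ] <- table[idx[known], , drop = FALSE]
  if (any(!known))  # X and anything unmapped: column means (zero after Eq.-1 z-scoring)
    out[!known, ] <- matrix(colMeans(table), sum(!known), ncol(table),
                            byrow = TRUE)
  rownames(out) <- aa
  out
}

#' Build a PSSM from a frequency profile and a substitution matrix
#'
#' Projects per-position amino-acid frequencies through a 20 x 20
#' substitution matrix: `PSSM[i, j] = sum_k omega[i, k] * D[k, j]`,
#' i.e. the matrix product `omega %*% D`.
#'
#' @param profile L x 20 matrix of per-position frequencies; rows must sum
#'   to 1 (tolerance 1e-6) with entries in \[0, 1\].
#' @param subst 20 x 20 substitution matrix (default [dayhoff_matrix()]).
#' @return An L x 20 numeric matrix of class `"pssm"`.
#' @export
build_pssm <- function(profile, subst = dayhoff_matrix()) {
  profile <- as.matrix(profile)
  if (ncol(profile) != 20L) stop("profile must have 20 columns")
  if (!all(dim(subst) == c(20L, 20L))) stop("substitution matrix must be 20 x 20")
  if (any(profile < -1e-9 | profile > 1 + 1e-9))
    stop("profile entries must lie in [0, 1]")
  if (any(abs(rowSums(profile) - 1) > 1e-6))
    stop("profile rows must sum to 1")
  out <- profile %*% subst
  dimnames(out) <- list(rownames(profile), AA_ALPHABET)
  class(out) <- c("pssm", class(out))
  out
}

#' Min-max normalize a PSSM to \[0, 1\]
#'
#' Applies `(x - min) / (max - min)` with the single global minimum and
#' maximum of the whole L x 20 matrix (not per column), so the output has
#' matrix-wide minimum exactly 0 and maximum exactly 1.
#'
#' @param pssm L x 20 numeric matrix.
#' @return Matrix of the same shape, class `"pssm_norm"`, entries in \[0, 1\].
#' @export
minmax_normalize <- function(pssm) {
  m <- as.matrix(unclass(pssm))
  if (any(!is.finite(m))) stop("PSSM has non-finite entries")
  lo <- min(m); hi <- max(m)
  if (hi - lo < .Machine$double.eps)
    stop("constant PSSM: min-max normalization undefined")
  out <- (m - lo) / (hi - lo)
  class(out) <- c("pssm_norm", class(out))
  out
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the classic 44-column ASCII profile that `psiblast
#' -out_ascii_pssm` writes: a header naming 40 amino-acid columns, then one
#' row per query position holding the position index, the query residue, 20
#' integer log-odds scores and 20 percent frequencies, followed by trailing
#' statistics lines (ignored). Columns are remapped from PSI-BLAST's
#' A R N D C ... order to the package alphabet order.
#'
#' @param file path to the PSSM file, or a character vector of its lines.
#' @param block `"logodds"` (default) returns the 20 log-odds columns as the
#'   PSSM; `"frequencies"` returns the percent-frequency block divided by
#'   100 (rows renormalized to sum to 1) as a frequency profile.
#' @return A list with `scores` (L x 20 matrix, class `"pssm"` or a
#'   frequency profile), `sequence` (one-letter query string) and `block`.
#' @export
parse_psiblast_pssm <- function(file, block = c("logodds", "frequencies")) {
  block <- match.arg(block)
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n"))
  ## header: the line whose tokens are 40 (or 20) single letters
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  is_header <- vapply(toks, function(tk)
    length(tk) %in% c(20L, 40L) && all(nchar(tk) == 1L) &&
      all(tk %in% AA_ALPHABET), logical(1))
  hi <- which(is_header)
  if (!length(hi)) stop("no PSSM header line with amino-acid columns found")
  hi <- hi[1]
  header <- toks[[hi]]
  n_aa_cols <- length(header)
  col_order <- match(AA_ALPHABET, header[1:20])

  scores <- list(); freqs <- list(); seq_chars <- character(0)
  for (li in seq(hi + 1, length(lines))) {
    tk <- toks[[li]]
    if (!length(tk)) break                      # blank line ends the table
    if (is.na(suppressWarnings(as.integer(tk[1])))) break  # statistics block
    vals <- suppressWarnings(as.numeric(tk[-(1:2)]))
    if (length(vals) < n_aa_cols || any(is.na(vals[1:n_aa_cols])))
      stop("malformed PSSM row at line ", li, ": expected ", n_aa_cols,
           " numeric columns")
    seq_chars <- c(seq_chars, tk[2])
    scores[[length(scores) + 1L]] <- vals[1:20]
    if (n_aa_cols == 40L) freqs[[length(freqs) + 1L]] <- vals[21:40]
  }
  if (!length(scores)) stop("PSSM table has no data rows")

  logodds <- do.call(rbind, scores)[, col_order, drop = FALSE]
  colnames(logodds) <- AA_ALPHABET
  if (block == "frequencies") {
    if (!length(freqs))
      stop("file has no percent-frequency block (20-column layout)")
    fr <- do.call(rbind, freqs)[, col_order, drop = FALSE] / 100
    rs <- rowSums(fr)
    rs[rs == 0] <- 1
    fr <- fr / rs
    colnames(fr) <- AA_ALPHABET
    return(list(scores = fr, sequence = paste(seq_chars, collapse = ""),
                block = block))
  }
  class(logodds) <- c("pssm", class(logodds))
  list(scores = logodds, sequence = paste(seq_chars, collapse = ""),
       block = block)
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Inverse of [parse_psiblast_pssm()] for round-tripping: writes the header,
#' one row per position with log-odds and percent-frequency blocks, and a
#' minimal trailing statistics stanza.
#'
#' @param pssm L x 20 matrix (package alphabet column order).
#' @param sequence one-letter query sequence of length L.
#' @param file output path.
#' @param freqs optional L x 20 frequency matrix (fractions); defaults to a
#'   uniform profile.
#' @return Invisibly, the path written.
#' @export
write_psiblast_pssm <- function(pssm, sequence, file, freqs = NULL) {
  m <- as.matrix(unclass(pssm))
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(nrow(m) == length(aa), ncol(m) == 20L)
  ## PSI-BLAST column order
  pb_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")
  perm <- match(pb_order, AA_ALPHABET)
  if (is.null(freqs)) freqs <- matrix(1 / 20, nrow(m), 20L)
  fpct <- round(as.matrix(unclass(freqs))[, perm, drop = FALSE] * 100)
  sm <- m[, perm, drop = FALSE]
  hdr <- paste0("\nLast position-specific scoring matrix computed, weighted ",
                "observed percentages rounded down, information per position, ",
                "and relative weight of gapless real matches to pseudocounts\n",
                "            ", paste(sprintf("%3s", pb_order), collapse = " "),
                "  ", paste(sprintf("%3s", pb_order), collapse = " "))
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste0(sprintf("%5d %s  ", i, aa[i]),
           paste(sprintf("%3d", round(sm[i, ])), collapse = " "), "  ",
           paste(sprintf("%3d", fpct[i, ]), collapse = " "),
           sprintf("  %4.2f %8.2f", 0, 0))
  }, character(1))
  tail <- c("", "                      K         Lambda",
            "Standard Ungapped    0.1337     0.3179")
  writeLines(c(hdr, rows, tail), file)
  invisible(file)
}
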