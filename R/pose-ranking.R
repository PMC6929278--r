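#' @title SVR-based pose re-ranking
#' @name pose-ranking
#' @description Per-pose feature assembly from pluggable energy terms,
#'   support vector regression against interface RMSD, decoy ranking with
#'   top-k selection, and consensus binding-residue extraction. The two
#'   in-package terms are the MLAB (group 6) and hexagon (group 7) feature
#'   groups, pooled over the pose's interface residues; classical contact
#'   energies (groups 1-5) enter through the same plug-in contract, with a
#'   simplified contact-propensity reference term provided.
NULL

#' Pool per-residue features over a pose's interface
#'
#' Element-wise mean (or sum/max, by `pooling`) of the per-residue feature
#' vectors of all interface residues of the pose, both sides pooled
#' together. A pose with no contacts yields a zero vector flagged empty.
#'
#' @param pose a [hexa_structure].
#' @param per_residue numeric matrix, one row per residue, rownames = uids;
#'   must cover every interface residue.
#' @param cutoff interface contact cutoff in Angstrom (default 6.0).
#' @param pooling `"mean"` (default), `"sum"` or `"max"`.
#' @param contacts optional precomputed `"contact_set"` for `pose`.
#' @return Numeric vector (length `ncol(per_residue)`), attribute `empty`
#'   TRUE when the pose has no interface.
#' @export
pool_interface_features <- function(pose, per_residue, cutoff = 6.0,
                                    pooling = c("mean", "sum", "max"),
                                    contacts = NULL) {
  pooling <- match.arg(pooling)
  if (is.null(contacts)) contacts <- contact_pairs(pose, cutoff = cutoff)
  iface <- interface_residues(contacts)
  uids <- c(iface$receptor, iface$ligand)
  if (!length(uids)) {
    v <- numeric(ncol(per_residue))
    names(v) <- colnames(per_residue)
    attr(v, "empty") <- TRUE
    return(v)
  }
  miss <- setdiff(uids, rownames(per_residue))
  if (length(miss))
    stop("per-residue feature map misses interface residue(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  m <- per_residue[uids, , drop = FALSE]
  v <- switch(pooling,
              mean = colMeans(m),
              sum = colSums(m),
              max = apply(m, 2, max))
  attr(v, "empty") <- FALSE
  v
}

#' Energy-term plug-in constructor
#'
#' An energy term is a named feature group: a function mapping a pose to a
#' fixed-length numeric sub-vector. Groups 1..5 are reserved for classical
#' contact/structure energies supplied by the user (see
#' [contact_propensity_term()] for a simplified reference term); groups 6
#' and 7 are the in-package MLAB and hexagon groups ([mlab_term()],
#' [hexagon_term()]).
#'
#' @param name term label.
#' @param group_id integer 1..7.
#' @param fn function of one argument (a pose [hexa_structure]) returning a
#'   numeric vector of constant length across poses of one complex.
#' @return A list of class `"energy_term"`.
#' @export
energy_term <- function(name, group_id, fn) {
  stopifnot(is.character(name), group_id %in% 1:7, is.function(fn))
  base::structure(list(name = name, group_id = as.integer(group_id),
                       fn = fn),
                  class = "energy_term")
}

#' MLAB energy term (group 6)
#'
#' Sequence features are pose-independent, so the per-residue MLAB vectors
#' are precomputed once from the chain profiles; per pose, the term pools
#' them over the pose's interface residues.
#'
#' @param reference a [hexa_structure] giving the complex's residues.
#' @param profiles named list of per-chain L x 20 profiles.
#' @param scheme block scheme (default [default_mlab_scheme()]).
#' @param cutoff,pooling pooling parameters (see
#'   [pool_interface_features()]).
#' @return An `"energy_term"` of group 6 (120 components).
#' @export
mlab_term <- function(reference, profiles, scheme = default_mlab_scheme(),
                      cutoff = 6.0, pooling = "mean") {
  rt <- residue_table(reference)
  fm <- NULL
  for (i in seq_len(nrow(rt))) {
    prof <- profiles[[rt$chain[i]]]
    if (is.null(prof)) stop("no profile supplied for chain ", rt$chain[i])
    v <- mlab_features(sequential_window(prof, rt$seqpos[i]), scheme)
    if (is.null(fm)) fm <- matrix(0, nrow(rt), length(v),
                                  dimnames = list(rt$uid, names(v)))
    fm[i, ] <- v
  }
  energy_term("mlab", 6L, function(pose)
    pool_interface_features(pose, fm, cutoff = cutoff, pooling = pooling))
}

#' Hexagon energy term (group 7)
#'
#' Spatial features depend on the pose geometry: per pose, hexagon windows
#' are computed on the pose for its interface residues and their block-mean
#' vectors pooled.
#'
#' @param profiles named list of per-chain L x 20 profiles.
#' @param scheme block scheme (default [default_hexagon_scheme()]).
#' @param hex_cutoff hexagon neighbor cutoff in Angstrom (default 10).
#' @param min_sep,cross_chain non-locality parameters (see
#'   [hexagon_neighbors()]).
#' @param cutoff,pooling pooling parameters.
#' @return An `"energy_term"` of group 7 (120 components).
#' @export
hexagon_term <- function(profiles, scheme = default_hexagon_scheme(),
                         hex_cutoff = 10.0, min_sep = 4L, cross_chain = TRUE,
                         cutoff = 6.0, pooling = "mean") {
  force(profiles); force(scheme)
  energy_term("hexagon", 7L, function(pose) {
    contacts <- contact_pairs(pose, cutoff = cutoff)
    iface <- interface_residues(contacts)
    uids <- c(iface$receptor, iface$ligand)
    ncols <- ncol(as.matrix(unclass(profiles[[1]]))) * 6L
    if (!length(uids)) {
      v <- numeric(ncols)
      attr(v, "empty") <- TRUE
      return(v)
    }
    fm <- NULL
    for (u in uids) {
      hw <- hexagon_window(pose, profiles, u, cutoff = hex_cutoff,
                           min_sep = min_sep, cross_chain = cross_chain)
      v <- hexagon_features(hw, scheme)
      if (is.null(fm)) fm <- matrix(0, length(uids), length(v),
                                    dimnames = list(uids, names(v)))
      fm[u, ] <- v
    }
    pool_interface_features(pose, fm, cutoff = cutoff, pooling = "mean",
                            contacts = contacts)
  })
}

#' Simplified contact-propensity energy term (group 1)
#'
#' A reference implementation of the classical amino-acid contact energy
#' group, reduced to its simplest statistical-potential form: the sum over
#' interface residue pairs of a 20 x 20 pair-propensity table, plus the
#' contact count, as a 2-component sub-vector. Shipped as a stand-in for
#' user-supplied classical terms; disabled unless explicitly included.
#'
#' @param propensity 20 x 20 numeric matrix indexed by the package alphabet.
#' @param cutoff contact cutoff in Angstrom (default 6.0).
#' @return An `"energy_term"` of group 1 (2 components: propensity sum,
#'   contact count).
#' @export
contact_propensity_term <- function(propensity, cutoff = 6.0) {
  propensity <- as.matrix(propensity)
  stopifnot(all(dim(propensity) == c(20, 20)), all(is.finite(propensity)))
  energy_term("contact_propensity", 1L, function(pose) {
    contacts <- contact_pairs(pose, cutoff = cutoff)
    if (!nrow(contacts)) return(c(propensity_sum = 0, contact_count = 0))
    rt <- residue_table(pose)
    ra <- aa_index(rt$aa[match(contacts$rec_uid, rt$uid)])
    la <- aa_index(rt$aa[match(contacts$lig_uid, rt$uid)])
    keep <- !is.na(ra) & !is.na(la)
    c(propensity_sum = sum(propensity[cbind(ra[keep], la[keep])]),
      contact_count = nrow(contacts))
  })
}

#' Assemble the grouped feature vector of a pose
#'
#' Evaluates each energy term on the pose and concatenates the sub-vectors
#' in the declared term order, recording the group layout (offsets and
#' lengths) needed for model fingerprinting and group-subset ablation.
#'
#' @param pose a [hexa_structure].
#' @param terms list of `"energy_term"` objects (non-empty).
#' @return Numeric vector with attribute `layout`: a data.frame of `name`,
#'   `group_id`, `offset` (0-based), `length` per term.
#' @export
assemble_features <- function(pose, terms) {
  if (!length(terms)) stop("no energy terms supplied")
  vals <- list(); lay <- list(); off <- 0L
  for (tm in terms) {
    stopifnot(inherits(tm, "energy_term"))
    v <- tm$fn(pose)
    if (any(!is.finite(v)))
      stop("energy term '", tm$name, "' produced non-finite values")
    vals[[length(vals) + 1L]] <- as.numeric(v)
    lay[[length(lay) + 1L]] <- data.frame(name = tm$name,
                                          group_id = tm$group_id,
                                          offset = off, length = length(v),
                                          stringsAsFactors = FALSE)
    off <- off + length(v)
  }
  out <- unlist(vals)
  attr(out, "layout") <- do.call(rbind, lay)
  out
}

layout_fingerprint <- function(layout) {
  paste(sprintf("%s[g%d:%d+%d]", layout$name, layout$group_id,
                layout$offset, layout$length), collapse = "|")
}

#' SVR configuration
#'
#' Defaults: radial-basis kernel, regularization cost 1, epsilon-tube 0.1,
#' kernel width gamma = 1/feature-dimension (the e1071 convention, applied
#' at fit time), features standardized to zero mean and unit variance using
#' training-set statistics.
#'
#' @param kernel `"radial"`, `"linear"`, `"polynomial"` or `"sigmoid"`.
#' @param cost positive regularization weight.
#' @param epsilon epsilon-tube width.
#' @param gamma kernel width; `NULL` uses 1/ncol(x).
#' @param standardize logical; standardize features with training stats.
#' @param seed integer seed recorded for any subsampling (the exact fit
#'   itself is deterministic).
#' @return A list of class `"svr_config"`.
#' @export
svr_config <- function(kernel = "radial", cost = 1, epsilon = 0.1,
                       gamma = NULL, standardize = TRUE, seed = 1L) {
  stopifnot(cost > 0, epsilon > 0, is.null(gamma) || gamma > 0)
  base::structure(list(kernel = kernel, cost = cost, epsilon = epsilon,
                       gamma = gamma, standardize = standardize,
                       seed = as.integer(seed)),
                  class = "svr_config")
}

#' Train the pose-scoring SVR
#'
#' Fits an epsilon-regression support vector machine of the per-pose
#' feature vectors against the interface-RMSD responses. The model record
#' stores the training standardization parameters, the configuration, and
#' a layout/scheme fingerprint so a mismatched feature layout at prediction
#' time is an error rather than a silent re-map.
#'
#' @param x numeric matrix, one row per pose.
#' @param y interface RMSD responses (Angstrom, >= 0), one per row.
#' @param config an [svr_config()].
#' @param layout optional layout data.frame (from [assemble_features()]).
#' @param scheme_id optional block-scheme fingerprint string.
#' @return A list of class `"hexa_svr"`.
#' @export
train_svr <- function(x, y, config = svr_config(), layout = NULL,
                      scheme_id = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("one response per feature row required")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("features and responses must be finite")
  if (length(unique(y)) < 2) stop("constant responses: regression degenerate")
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  if (config$standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale < 1e-12] <- 1          # constant columns carry no signal
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
  fit <- e1071::svm(x = xs, y = y, type = "eps-regression",
                    kernel = config$kernel, cost = config$cost,
                    epsilon = config$epsilon, gamma = gamma, scale = FALSE)
  base::structure(list(fit = fit, center = center, scale = scale,
                       config = config, gamma = gamma,
                       n_features = ncol(x),
                       fingerprint = if (is.null(layout)) NULL else
                         layout_fingerprint(layout),
                       scheme_id = scheme_id),
                  class = "hexa_svr")
}

#' Predict pose responses from a trained SVR
#'
#' @param object a `"hexa_svr"` model.
#' @param newdata numeric matrix of pose features (same layout as training).
#' @param layout optional layout of `newdata`; checked against the model
#'   fingerprint when both are present.
#' @param ... unused.
#' @return Numeric vector of predicted interface RMSD (energy proxy).
#' @export
predict.hexa_svr <- function(object, newdata, layout = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature dimension ", ncol(newdata), " does not match the model (",
         object$n_features, ")")
  if (!is.null(layout) && !is.null(object$fingerprint)) {
    fp <- layout_fingerprint(layout)
    if (!identical(fp, object$fingerprint)) {
      tl <- strsplit(fp, "|", fixed = TRUE)[[1]]
      ml <- strsplit(object$fingerprint, "|", fixed = TRUE)[[1]]
      bad <- tl[tl != c(ml, rep("", max(0, length(tl) - length(ml))))[
        seq_along(tl)]][1]
      stop("feature layout mismatch at group ", bad)
    }
  }
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  as.numeric(stats::predict(object$fit, xs))
}

#' Rank poses and select the top k
#'
#' Orders poses by predicted response ascending (lowest predicted interface
#' RMSD first), ties broken by pose id, and marks the top-k selection
#' (k = 10 by default).
#'
#' @param model a `"hexa_svr"`.
#' @param x numeric matrix of pose features; rownames (or `pose_ids`) name
#'   the poses.
#' @param k number of poses to select (default 10).
#' @param pose_ids optional character vector of pose ids.
#' @param layout optional feature layout for fingerprint checking.
#' @return A data.frame of class `"ranked_poses"`: `pose_id`, `predicted`,
#'   `rank`, `selected`, in rank order.
#' @export
rank_and_select <- function(model, x, k = 10L, pose_ids = NULL,
                            layout = NULL) {
  x <- as.matrix(x)
  if (is.null(pose_ids)) pose_ids <- rownames(x)
  if (is.null(pose_ids)) pose_ids <- as.character(seq_len(nrow(x)))
  pred <- predict(model, x, layout = layout)
  ord <- order(pred, pose_ids)
  if (k > nrow(x))
    warning("k = ", k, " exceeds the ", nrow(x), " available poses; ",
            "selecting all")
  out <- data.frame(pose_id = pose_ids[ord], predicted = pred[ord],
                    rank = seq_along(ord),
                    selected = seq_along(ord) <= min(k, nrow(x)),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_poses", class(out))
  out
}

#' Consensus binding residues over top-ranked poses
#'
#' Votes each residue by the number of top poses in whose interface it
#' appears and keeps residues reaching `min_votes` (majority of the poses
#' by default).
#'
#' @param top_poses non-empty list of [hexa_structure] poses.
#' @param cutoff interface contact cutoff in Angstrom (default 6.0).
#' @param min_votes minimum number of poses a residue must appear in
#'   (default `ceiling(n/2)`).
#' @return A list with `receptor` and `ligand` uid vectors, plus a `votes`
#'   attribute (named integer vector over all voted residues).
#' @export
consensus_binding_residues <- function(top_poses, cutoff = 6.0,
                                       min_votes = NULL) {
  if (!length(top_poses)) stop("no poses supplied")
  if (is.null(min_votes)) min_votes <- ceiling(length(top_poses) / 2)
  rec <- character(0); lig <- character(0)
  for (p in top_poses) {
    iface <- interface_residues(contact_pairs(p, cutoff = cutoff))
    rec <- c(rec, iface$receptor)
    lig <- c(lig, iface$ligand)
  }
  rv <- table(rec); lv <- table(lig)
  out <- list(receptor = sort(names(rv)[rv >= min_votes]),
              ligand = sort(names(lv)[lv >= min_votes]))
  votes <- c(as.integer(rv), as.integer(lv))
  names(votes) <- c(names(rv), names(lv))
  attr(out, "votes") <- votes
  out
}

#' Feature-group ablation experiment
#'
#' Re-runs the train/rank pipeline restricted to subsets of the feature
#' groups (e.g. classical contact energies vs the two local-feature groups
#' vs all), on a fixed train/held-out split, and tabulates for each subset
#' the held-out rank correlation and the mean true response of its top-k
#' selection.
#'
#' @param x pose feature matrix; `groups` maps each column to a group id.
#' @param y true interface RMSD responses.
#' @param groups integer vector, `length(groups) == ncol(x)`.
#' @param subsets named list of group-id vectors to ablate over.
#' @param config an [svr_config()].
#' @param train_frac fraction of poses used for training (default 0.6).
#' @param k top-k selection size (default 10).
#' @param seed split seed.
#' @return A data.frame: `subset`, `n_features`, `spearman` (held-out),
#'   `mean_irmsd_topk`, `mean_irmsd_all` (held-out baseline).
#' @export
run_ablation <- function(x, y, groups,
                         subsets = list(`6` = 6L, `7` = 7L,
                                        `6+7` = c(6L, 7L)),
                         config = svr_config(), train_frac = 0.6, k = 10L,
                         seed = 1L) {
  x <- as.matrix(x)
  stopifnot(length(groups) == ncol(x), length(y) == nrow(x))
  set.seed(seed)
  n <- nrow(x)
  tr <- sort(sample.int(n, max(2L, round(train_frac * n))))
  te <- setdiff(seq_len(n), tr)
  rows <- list()
  for (nm in names(subsets)) {
    cols <- which(groups %in% subsets[[nm]])
    if (!length(cols)) stop("subset '", nm, "' selects no feature columns")
    model <- train_svr(x[tr, cols, drop = FALSE], y[tr], config = config)
    pred <- predict(model, x[te, cols, drop = FALSE])
    sel <- order(pred)[seq_len(min(k, length(te)))]
    rows[[nm]] <- data.frame(
      subset = nm, n_features = length(cols),
      spearman = stats::cor(pred, y[te], method = "spearman"),
      mean_irmsd_topk = mean(y[te][sel]),
      mean_irmsd_all = mean(y[te]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
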