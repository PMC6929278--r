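#' @title End-to-end synthetic experiments
#' @name hexablock-experiments
#' @description Seeded, self-contained experiments that exercise the whole
#'   pipeline on synthetic data: decoy-ladder ranking recovery (can the SVR
#'   trained on the two local-feature groups re-rank decoys by interface
#'   RMSD?) and the feature-group ablation design. Both build their own toy
#'   complex, profiles and decoys, so they run without any external data.
NULL

#' Default hydrophobicity-product contact propensity
#'
#' A simplified 20 x 20 pair-propensity table for the reference contact
#' energy term: the outer product of the z-scored hydrophobicity column, so
#' hydrophobic-hydrophobic pairs score high and mixed pairs low. A crude
#' stand-in for statistically derived contact potentials, adequate as a
#' reference feature group.
#'
#' @return 20 x 20 numeric matrix in alphabet order.
#' @export
hydrophobicity_propensity <- function() {
  h <- normalize_physchem()[, "H"]
  outer(h, h)
}

## Shared experiment setup: toy complex + per-chain profiles + decoy ladder
## + per-pose features for the requested energy terms.
experiment_setup <- function(seed, n_residues = 25L,
                             magnitudes = c(0.5, 1, 2, 3, 4),
                             n_per_magnitude = 100L,
                             with_propensity = FALSE) {
  s <- make_toy_complex(n_receptor = n_residues, n_ligand = n_residues)
  profs <- list(
    A = make_synthetic_profile(n_residues, seed = seed, index = 1)$npssm,
    B = make_synthetic_profile(n_residues, seed = seed, index = 2)$npssm)
  ladder <- make_decoy_ladder(s, magnitudes = magnitudes,
                              n_per_magnitude = n_per_magnitude,
                              seed = seed)
  terms <- list()
  if (with_propensity)
    terms <- c(terms, list(contact_propensity_term(
      hydrophobicity_propensity())))
  terms <- c(terms, list(mlab_term(s, profs), hexagon_term(profs)))
  poses <- attr(ladder, "poses")
  feats <- lapply(poses, assemble_features, terms = terms)
  X <- do.call(rbind, lapply(feats, as.numeric))
  rownames(X) <- names(poses)
  layout <- attr(feats[[1]], "layout")
  groups <- rep(layout$group_id, layout$length)
  list(native = s, profiles = profs, ladder = ladder, x = X,
       y = ladder$irmsd, groups = groups, layout = layout)
}

#' Decoy-ranking recovery experiment
#'
#' Generates a seeded decoy ladder for a toy complex, extracts the MLAB and
#' hexagon feature groups per pose, and over `n_replicates` random
#' train/held-out splits fits the SVR with interface-RMSD response, ranks
#' the held-out poses and records (i) the Spearman correlation between
#' predicted and true interface RMSD, (ii) whether the top-1 selected pose
#' beats the expected interface RMSD of a random selection from the same
#' pool, and (iii) the mean true interface RMSD of the top-k selection.
#'
#' @param seed global experiment seed.
#' @param magnitudes,n_per_magnitude decoy-ladder design (defaults: 5
#'   magnitudes x 100 decoys).
#' @param n_replicates number of train/held-out resampling replicates.
#' @param train_frac training fraction per replicate (default 0.6).
#' @param k top-k selection size (default 10).
#' @param config an [svr_config()].
#' @param n_residues chain length of the toy complex.
#' @return A list: `spearman` (vector over replicates), `spearman_mean`,
#'   `top1_beats_random` (logical vector), `top1_success_rate`,
#'   `mean_irmsd_top1`, `mean_irmsd_topk`, `mean_irmsd_random` (held-out
#'   pool average), `n_poses`, `replicates` (per-replicate data.frame).
#' @export
ranking_recovery_experiment <- function(seed = 1L,
                                        magnitudes = c(0.5, 1, 2, 3, 4),
                                        n_per_magnitude = 100L,
                                        n_replicates = 100L,
                                        train_frac = 0.6, k = 10L,
                                        config = svr_config(),
                                        n_residues = 25L) {
  setup <- experiment_setup(seed, n_residues = n_residues,
                            magnitudes = magnitudes,
                            n_per_magnitude = n_per_magnitude)
  X <- setup$x; y <- setup$y
  n <- nrow(X)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    old <- .Random.seed_save()
    set.seed(stream_seed(seed, "ranking_split", r))
    tr <- sort(sample.int(n, round(train_frac * n)))
    .Random.seed_restore(old)
    te <- setdiff(seq_len(n), tr)
    model <- train_svr(X[tr, , drop = FALSE], y[tr], config = config)
    ranked <- rank_and_select(model, X[te, , drop = FALSE], k = k)
    true_te <- y[te]
    names(true_te) <- rownames(X)[te]
    top1 <- true_te[ranked$pose_id[1]]
    topk <- mean(true_te[ranked$pose_id[ranked$selected]])
    rows[[r]] <- data.frame(
      replicate = r,
      spearman = stats::cor(ranked$predicted[order(ranked$pose_id)],
                            true_te[sort(names(true_te))],
                            method = "spearman"),
      irmsd_top1 = unname(top1), irmsd_topk = topk,
      irmsd_random = mean(true_te),
      stringsAsFactors = FALSE)
  }
  rep_tab <- do.call(rbind, rows)
  list(spearman = rep_tab$spearman,
       spearman_mean = mean(rep_tab$spearman),
       top1_beats_random = rep_tab$irmsd_top1 < rep_tab$irmsd_random,
       top1_success_rate = mean(rep_tab$irmsd_top1 < rep_tab$irmsd_random),
       mean_irmsd_top1 = mean(rep_tab$irmsd_top1),
       mean_irmsd_topk = mean(rep_tab$irmsd_topk),
       mean_irmsd_random = mean(rep_tab$irmsd_random),
       n_poses = n, replicates = rep_tab)
}

#' Feature-group ablation experiment
#'
#' Runs the group-subset comparison design end to end on synthetic data:
#' poses featurized with the reference contact-propensity group (1) plus
#' the MLAB (6) and hexagon (7) groups, then [run_ablation()] over the
#' classical-group subset, the local-feature subset and all groups.
#'
#' @param seed global experiment seed.
#' @param magnitudes,n_per_magnitude decoy-ladder design.
#' @param config an [svr_config()].
#' @param train_frac,k ablation split and selection parameters.
#' @param n_residues chain length of the toy complex.
#' @return The comparison data.frame from [run_ablation()] (one row per
#'   subset: held-out Spearman, mean interface RMSD of the top-k selection,
#'   held-out average), with attribute `n_poses`.
#' @export
ablation_experiment <- function(seed = 1L, magnitudes = c(0.5, 1, 2, 3, 4),
                                n_per_magnitude = 40L,
                                config = svr_config(), train_frac = 0.6,
                                k = 10L, n_residues = 25L) {
  setup <- experiment_setup(seed, n_residues = n_residues,
                            magnitudes = magnitudes,
                            n_per_magnitude = n_per_magnitude,
                            with_propensity = TRUE)
  tab <- run_ablation(setup$x, setup$y, setup$groups,
                      subsets = list(contact = 1L, local = c(6L, 7L),
                                     all = c(1L, 6L, 7L)),
                      config = config, train_frac = train_frac, k = k,
                      seed = stream_seed(seed, "ablation_split"))
  attr(tab, "n_poses") <- nrow(setup$x)
  tab
}
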