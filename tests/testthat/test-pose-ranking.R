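# small shared complex + profiles for the ranking tests
ranking_fixture <- function(n = 15L, seed = 31L) {
  s <- make_toy_complex(n_receptor = n, n_ligand = n)
  profs <- list(A = make_synthetic_profile(n, seed = seed, index = 1)$npssm,
                B = make_synthetic_profile(n, seed = seed, index = 2)$npssm)
  list(s = s, profs = profs)
}

test_that("interface pooling averages per-residue vectors", {
  fx <- ranking_fixture()
  iface <- interface_residues(contact_pairs(fx$s))
  uids <- c(iface$receptor, iface$ligand)
  rt <- residue_table(fx$s)
  fm <- matrix(seq_len(nrow(rt) * 4), nrow(rt), 4,
               dimnames = list(rt$uid, NULL))
  v <- pool_interface_features(fx$s, fm)
  expect_equal(as.numeric(v), unname(colMeans(fm[uids, , drop = FALSE])))
  expect_false(attr(v, "empty"))
  # sum pooling
  vs <- pool_interface_features(fx$s, fm, pooling = "sum")
  expect_equal(as.numeric(vs), unname(colSums(fm[uids, , drop = FALSE])))
  # a pose with no contacts pools to a flagged zero vector
  far <- apply_transform(fx$s, rigid_transform(diag(3), c(50, 0, 0)),
                         "ligand")
  vf <- pool_interface_features(far, fm)
  expect_true(all(vf == 0))
  expect_true(attr(vf, "empty"))
  # single interface residue: pooled vector equals its row
  one <- tiny_structure(list(
    list(chain = "A", resno = 1, elety = "CA", xyz = c(0, 0, 0)),
    list(chain = "B", resno = 1, elety = "CA", xyz = c(4, 0, 0)),
    list(chain = "B", resno = 2, elety = "CA", xyz = c(40, 0, 0))))
  fm1 <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
                dimnames = list(c("A.1", "B.1", "B.2"), NULL))
  expect_equal(as.numeric(pool_interface_features(one, fm1)),
               unname(colMeans(fm1[c("A.1", "B.1"), ])))
})

test_that("feature assembly concatenates groups with a recorded layout", {
  fx <- ranking_fixture()
  tm <- mlab_term(fx$s, fx$profs)
  th <- hexagon_term(fx$profs)
  v1 <- assemble_features(fx$s, list(tm))
  expect_equal(length(v1), 120)
  v2 <- assemble_features(fx$s, list(tm, th))
  expect_equal(length(v2), 240)
  lay <- attr(v2, "layout")
  expect_equal(lay$offset, c(0, 120))
  expect_equal(lay$group_id, c(6L, 7L))
  # determinism: identical pose evaluated twice is bit-identical
  expect_identical(v2, assemble_features(fx$s, list(tm, th)))
  expect_error(assemble_features(fx$s, list()), "no energy terms")
})

test_that("the contact-propensity reference term sums pair propensities", {
  set.seed(13)
  prop <- matrix(rnorm(400), 20, 20,
                 dimnames = list(rownames(physchem_table()),
                                 rownames(physchem_table())))
  tm <- contact_propensity_term(prop)
  # no contacts -> (0, 0)
  far <- tiny_structure(list(
    list(chain = "A", resno = 1, elety = "CA", xyz = c(0, 0, 0)),
    list(chain = "B", resno = 1, elety = "CA", xyz = c(50, 0, 0))))
  expect_equal(unname(tm$fn(far)), c(0, 0))
  # one A-C contact reads the single table cell
  ac <- tiny_structure(list(
    list(chain = "A", resno = 1, resid = "ALA", elety = "CA",
         xyz = c(0, 0, 0)),
    list(chain = "B", resno = 1, resid = "CYS", elety = "CA",
         xyz = c(3, 0, 0))))
  expect_equal(unname(tm$fn(ac)), c(prop["A", "C"], 1))
  # toy complex: sum matches brute-force pair enumeration
  fx <- ranking_fixture()
  cc <- contact_pairs(fx$s)
  rt <- residue_table(fx$s)
  want <- sum(vapply(seq_len(nrow(cc)), function(i)
    prop[rt$aa[match(cc$rec_uid[i], rt$uid)],
         rt$aa[match(cc$lig_uid[i], rt$uid)]], numeric(1)))
  expect_equal(unname(tm$fn(fx$s)), c(want, nrow(cc)))
})

test_that("the SVR recovers a linear signal and refits deterministically", {
  set.seed(17)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6)
  beta <- c(2, -1, 0.5, 0, 0, 1)
  y <- as.numeric(X %*% beta) + 10 + rnorm(n, sd = 0.1)
  tr <- 1:140; te <- 141:200
  m <- train_svr(X[tr, ], y[tr])
  pred <- predict(m, X[te, ])
  expect_gte(cor(pred, y[te], method = "spearman"), 0.9)
  # identical input -> identical predictions
  m2 <- train_svr(X[tr, ], y[tr])
  expect_equal(predict(m2, X[te, ]), pred, tolerance = 1e-12)
  # duplicating every training row doubles the loss term, i.e. acts as
  # doubled cost: with cost halved to compensate the fit is unchanged up to
  # the quadratic-programming solver's convergence tolerance
  cfg1 <- svr_config(cost = 1, standardize = FALSE)
  cfg2 <- svr_config(cost = 0.5, standardize = FALSE)
  mA <- train_svr(X[tr, ], y[tr], config = cfg1)
  mB <- train_svr(X[c(tr, tr), ], y[c(tr, tr)], config = cfg2)
  expect_equal(predict(mB, X[te, ]), predict(mA, X[te, ]),
               tolerance = 1e-4)
  # degenerate responses are an error
  expect_error(train_svr(X[tr, ], rep(1, 140)), "constant")
  # training pose prediction is finite
  expect_true(all(is.finite(predict(m, X[tr, ]))))
})

test_that("ranking orders by prediction with stable ties and top-k capping", {
  set.seed(23)
  X <- matrix(rnorm(60), 20, 3)
  y <- abs(X[, 1]) + 0.01 * rnorm(20)
  m <- train_svr(X, y)
  rownames(X) <- sprintf("p%02d", 1:20)
  rk <- rank_and_select(m, X, k = 5)
  expect_equal(rk$rank, 1:20)
  expect_true(all(diff(rk$predicted) >= -1e-12))  # non-decreasing
  expect_equal(sum(rk$selected), 5)
  expect_equal(rk$pose_id[order(rk$predicted, rk$pose_id)], rk$pose_id)
  # k exceeding n selects all with a warning
  expect_warning(rk2 <- rank_and_select(m, X[1:3, ], k = 10), "exceeds")
  expect_equal(sum(rk2$selected), 3)
  # invariance of the order under monotone transforms of the prediction is
  # inherent to rank-based selection: check against a direct sort
  pred <- predict(m, X)
  expect_equal(rk$pose_id, rownames(X)[order(pred, rownames(X))])
  # feature-dimension mismatch is caught
  expect_error(predict(m, X[, 1:2]), "dimension")
})

test_that("layout fingerprints block mismatched feature layouts", {
  fx <- ranking_fixture()
  tm <- mlab_term(fx$s, fx$profs); th <- hexagon_term(fx$profs)
  v <- assemble_features(fx$s, list(tm, th))
  lay <- attr(v, "layout")
  X <- rbind(v, v + 0.01, v - 0.01, v * 1.1)
  m <- train_svr(X, c(1, 2, 3, 4), layout = lay)
  expect_silent(predict(m, X, layout = lay))
  lay2 <- lay; lay2$name[2] <- "other"; lay2$group_id[2] <- 3L
  expect_error(predict(m, X, layout = lay2), "layout mismatch")
})

test_that("consensus binding residues follow the voting rule", {
  fx <- ranking_fixture()
  iface <- interface_residues(contact_pairs(fx$s))
  # single pose, one vote required: exactly its interface
  one <- consensus_binding_residues(list(fx$s), min_votes = 1)
  expect_equal(one$receptor, iface$receptor)
  expect_equal(one$ligand, iface$ligand)
  # a residue present in 2 of 3 poses passes min_votes = 2, fails 3
  far <- apply_transform(fx$s, rigid_transform(diag(3), c(50, 0, 0)),
                         "ligand")
  poses <- list(fx$s, fx$s, far)
  two <- consensus_binding_residues(poses, min_votes = 2)
  expect_equal(two$receptor, iface$receptor)
  none <- consensus_binding_residues(poses, min_votes = 3)
  expect_equal(none$receptor, character(0))
  # min_votes above n empties the set
  over <- consensus_binding_residues(list(fx$s), min_votes = 5)
  expect_equal(over$receptor, character(0))
  expect_equal(over$ligand, character(0))
  # default majority: ceiling(n/2)
  dflt <- consensus_binding_residues(poses)
  expect_equal(dflt$receptor, two$receptor)
})

test_that("the ablation harness tabulates group subsets end to end", {
  set.seed(29)
  n <- 80
  X <- cbind(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 3), n, 3))
  groups <- c(6L, 6L, 7L, 7L, 7L)
  y <- abs(X[, 1] + X[, 3] + rnorm(n, sd = 0.2))
  tab <- run_ablation(X, y, groups,
                      subsets = list(mlab = 6L, hexagon = 7L,
                                     all = c(6L, 7L)),
                      k = 5L, seed = 3L)
  expect_equal(tab$subset, c("mlab", "hexagon", "all"))
  expect_equal(tab$n_features, c(2L, 3L, 5L))
  expect_true(all(is.finite(tab$spearman)))
  expect_true(all(tab$mean_irmsd_topk >= 0))
  # top-k selection should not be worse than the held-out average for the
  # informative full model
  expect_lte(tab$mean_irmsd_topk[3], tab$mean_irmsd_all[3])
  expect_error(run_ablation(X, y, groups, subsets = list(bad = 4L)),
               "no feature columns")
})
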