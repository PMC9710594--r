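test_that("fnat counts reproduced native contacts only", {
  native <- make_cm(sprintf("A:%d:", 1:10), sprintf("B:%d:", 1:10))
  # all 10 reproduced plus 7 extras: extras ignored
  model <- make_cm(c(sprintf("A:%d:", 1:10), sprintf("A:%d:", 21:27)),
                   c(sprintf("B:%d:", 1:10), sprintf("B:%d:", 21:27)))
  expect_equal(fnat(native, model), 1.0)
  expect_equal(fnat(native, make_cm(sprintf("A:%d:", 1:3),
                                    sprintf("B:%d:", 1:3))), 0.3)
  expect_equal(fnat(native, make_cm("A:99:", "B:99:")), 0.0)
  empty <- make_cm(character(0), character(0))
  expect_error(fnat(empty, model), "undefined-native")
})

test_that("ligand_rmsd isolates the ligand displacement", {
  nat <- make_native(synthetic_spec(seed = 21), 1)
  expect_lt(ligand_rmsd(nat, nat), 1e-8)

  # rigid ligand translation with the receptor untouched survives the fit
  d8 <- nat
  is_lig <- d8$atoms$chain == "B"
  d8$atoms$x[is_lig] <- d8$atoms$x[is_lig] + 8 / sqrt(2)
  d8$atoms$y[is_lig] <- d8$atoms$y[is_lig] + 8 / sqrt(2)
  expect_equal(ligand_rmsd(nat, d8), 8.0, tolerance = 1e-6)

  # ligand rotated 30 degrees about its centroid: the receptor fit is the
  # identity, so L-rms equals the direct displacement RMSD of the ligand
  # backbone, computed here analytically
  rot <- nat
  lig_bb <- rot$atoms$chain == "B" & rot$atoms$name %in% c("N", "CA", "C", "O")
  xyz <- as.matrix(rot$atoms[rot$atoms$chain == "B", c("x", "y", "z")])
  ctr <- colMeans(xyz)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  moved <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, `+`)
  rot$atoms[rot$atoms$chain == "B", c("x", "y", "z")] <- moved
  bb_old <- as.matrix(nat$atoms[lig_bb, c("x", "y", "z")])
  bb_new <- as.matrix(rot$atoms[lig_bb, c("x", "y", "z")])
  expected <- sqrt(mean(rowSums((bb_new - bb_old)^2)))
  expect_equal(ligand_rmsd(nat, rot), expected, tolerance = 1e-8)
})

test_that("interface_rmsd is fit-invariant and matches the quaternion oracle", {
  nat <- make_native(synthetic_spec(seed = 22), 1)
  expect_lt(interface_rmsd(nat, nat), 1e-8)
  set.seed(1)
  expect_lt(interface_rmsd(nat, random_rigid(nat)), 1e-8)

  # small hinge perturbation of the ligand: compare to an independent
  # quaternion fit over the same (native-defined) interface selection
  hinge <- decoyforest:::.perturb_ligand(nat, 0.8, 5)
  iface <- interface_residues(nat, 10)
  bb_nat <- backbone_coords(nat, iface)
  bb_dec <- backbone_coords(hinge, iface)
  expect_identical(rownames(bb_nat), rownames(bb_dec))
  expect_equal(interface_rmsd(nat, hinge),
               quaternion_fit(bb_dec, bb_nat)$rmsd, tolerance = 1e-8)
})

test_that("classify_quality implements the ranked criteria table", {
  expect_equal(classify_quality(0.05, 2.0, 1.0), "incorrect")
  expect_equal(classify_quality(0.6, 0.8, 0.7), "high")
  expect_equal(classify_quality(0.2, 8.0, 3.5), "acceptable")
  expect_equal(classify_quality(0.5, 3.0, 1.5), "medium")
  expect_equal(classify_quality(0.4, 12, 5), "incorrect")
  # vectorized
  expect_equal(classify_quality(c(0.05, 0.6), c(2, 0.8), c(1, 0.7)),
               c("incorrect", "high"))
})

test_that("classify_quality is monotone in each parameter", {
  rank <- function(q) match(q, QUALITY_LEVELS)
  set.seed(17)
  for (i in 1:200) {
    f <- runif(1); l <- runif(1, 0, 15); r <- runif(1, 0, 6)
    base <- rank(classify_quality(f, l, r))
    expect_gte(rank(classify_quality(min(1, f + runif(1, 0, 0.3)), l, r)),
               base)
    expect_gte(rank(classify_quality(f, max(0, l - runif(1, 0, 4)), r)),
               base)
    expect_gte(rank(classify_quality(f, l, max(0, r - runif(1, 0, 2)))),
               base)
  }
})

test_that("screen_clashes applies the mean + 2 sd rule strictly", {
  x <- setNames(c(rep(0, 100), 50), sprintf("m%03d", 1:101))
  scr <- screen_clashes(x)
  expect_equal(scr$threshold, mean(x) + 2 * sd(x))
  expect_equal(scr$discarded_ids, "m101")
  expect_length(scr$kept_ids, 100L)

  # zero variance: nothing exceeds the threshold (strict >)
  all7 <- setNames(rep(7, 5), letters[1:5])
  expect_length(screen_clashes(all7)$discarded_ids, 0L)

  # {2,2,2,2,3}: threshold ~ 3.094, none discarded
  v <- setNames(c(2, 2, 2, 2, 3), letters[1:5])
  scr2 <- screen_clashes(v)
  expect_equal(scr2$threshold, 2.2 + 2 * sd(v))
  expect_length(scr2$discarded_ids, 0L)

  expect_error(screen_clashes(setNames(3, "only")), "degenerate-statistics")
})

test_that("assess_target labels decoys per-decoy and order-preserving", {
  spec <- synthetic_spec(seed = 23, tier_counts = c(incorrect = 4,
                                                    acceptable = 3,
                                                    medium = 3, high = 3))
  nat <- make_native(spec, 1)

  res_self <- assess_target(nat, list(nat))
  expect_equal(res_self$quality, "high")
  expect_equal(res_self$fnat, 1)
  expect_lt(res_self$lrms, 1e-8)
  expect_lt(res_self$irms, 1e-8)

  far <- nat
  far$atoms$x[far$atoms$chain == "B"] <-
    far$atoms$x[far$atoms$chain == "B"] + 100
  far$model_id <- "far"
  res <- assess_target(nat, list(nat, far))
  expect_equal(res$model_id, c("native", "far"))
  expect_equal(res$quality[2], "incorrect")
  expect_equal(res$fnat[2], 0)

  # planted tiers recovered distributionally (median per tier)
  dec <- make_decoys(nat, spec)
  a <- assess_target(nat, dec$decoys)
  keep <- !dec$clash_outlier
  rank <- function(q) match(q, QUALITY_LEVELS)
  med <- tapply(rank(a$quality[keep]), dec$planted[keep], median)
  expect_equal(as.vector(med[c("incorrect", "acceptable", "medium", "high")]),
               c(1, 2, 3, 4))
})

test_that("shrinking the perturbation drives the metrics to perfection", {
  nat <- make_native(synthetic_spec(seed = 24), 1)
  set.seed(24)
  mags <- c(8, 2, 0.5, 0.05)
  prev_l <- Inf; prev_f <- -1
  for (k in seq_along(mags)) {
    d <- decoyforest:::.perturb_ligand(nat, mags[k], mags[k] * 4)
    l <- ligand_rmsd(nat, d)
    f <- fnat(residue_contacts(nat), residue_contacts(d))
    expect_lt(l, prev_l)
    expect_gte(f, prev_f)
    prev_l <- l; prev_f <- f
  }
  expect_lt(prev_l, 0.3)
  expect_equal(prev_f, 1)
})
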