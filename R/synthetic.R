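# Seeded synthetic test surface: idealized two-helix complexes, rigid-body
# perturbed decoy ensembles with planted CAPRI tiers, and feature tables with
# stated class-conditional distributions. Stands in for docking-engine decoy
# sets so every other module can be exercised fully offline.

.AA20 <- names(.AA3TO1)

#' Specification of the synthetic world
#'
#' Defaults state the world the tests run in: two packed idealized helices
#' (receptor 40 residues, ligand 25), 300 decoys per target split
#' 255/20/15/10 across incorrect/acceptable/medium/high, per-tier rigid
#' perturbation magnitudes chosen so each tier's decoys assess (by
#' construction, see the methods vignette) into the intended CAPRI class,
#' a 5% clash-outlier fraction, and a feature block of 3 informative
#' (class-conditional mean shift 2 sd) plus 5 noise features with 2%
#' missingness.
#'
#' @param n_targets number of targets.
#' @param n_rec,n_lig residues per body (receptor >= ligand).
#' @param tier_counts named integer vector over
#'   `c("incorrect", "acceptable", "medium", "high")`: decoys per tier.
#' @param tier_translation,tier_rotation named numeric vectors (same names):
#'   rigid translation (Angstrom) and rotation (degrees) magnitude per tier;
#'   must strictly increase from high to incorrect.
#' @param clash_fraction fraction of decoys turned into deliberate
#'   interpenetration clash outliers (drawn from the incorrect tier).
#' @param features data.frame `name`, `mu_incorrect`, `mu_correct`, `sd`,
#'   `missing_rate` describing class-conditional feature distributions.
#' @param seed integer seed (mandatory).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    n_targets = 8, n_rec = 40, n_lig = 25,
    tier_counts = c(incorrect = 255, acceptable = 20, medium = 15, high = 10),
    tier_translation = c(incorrect = 40, acceptable = 4.5, medium = 1.8,
                         high = 0.2),
    tier_rotation = c(incorrect = 120, acceptable = 40, medium = 16,
                      high = 1),
    clash_fraction = 0.05,
    features = default_feature_spec(),
    seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_rec >= n_lig, all(tier_counts >= 0),
            clash_fraction >= 0, clash_fraction <= 1)
  tiers <- c("high", "medium", "acceptable", "incorrect")
  stopifnot(all(tiers %in% names(tier_counts)))
  if (!all(diff(tier_translation[tiers]) > 0) ||
      !all(diff(tier_rotation[tiers]) > 0))
    stop("perturbation magnitudes must strictly increase high -> incorrect")
  structure(list(n_targets = n_targets, n_rec = n_rec, n_lig = n_lig,
                 tier_counts = tier_counts,
                 tier_translation = tier_translation,
                 tier_rotation = tier_rotation,
                 clash_fraction = clash_fraction,
                 features = features, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default class-conditional feature specification
#'
#' Three informative features (incorrect-class mean 0, correct-class mean 2,
#' sd 1: a 2-sigma shift) and five pure-noise features, all with 2%
#' missingness.
#'
#' @param n_informative,n_noise counts.
#' @param delta class mean shift in sd units for informative features.
#' @param missing_rate per-cell missingness probability.
#' @return data.frame as accepted by [synthetic_spec()].
#' @export
default_feature_spec <- function(n_informative = 3, n_noise = 5, delta = 2,
                                 missing_rate = 0.02) {
  rbind(
    data.frame(name = sprintf("informative_%d", seq_len(n_informative)),
               mu_incorrect = 0, mu_correct = delta, sd = 1,
               missing_rate = missing_rate),
    data.frame(name = sprintf("noise_%d", seq_len(n_noise)),
               mu_incorrect = 0, mu_correct = 0, sd = 1,
               missing_rate = missing_rate))
}

# Idealized alpha-helix backbone for one chain along +z.
# radius/rise/twist are the canonical helix parameters; N and C sit on the
# helix curve slightly behind/ahead of CA, O radially outside C.
.helix_chain <- function(n_res, chain, serial0 = 1L, aa_offset = 0L) {
  twist <- 100 * pi / 180; rise <- 1.5; radius <- 2.3
  rows <- lapply(seq_len(n_res), function(i) {
    t0 <- (i - 1) * twist
    pos <- function(dt, r, dz) c(r * cos(t0 + dt), r * sin(t0 + dt),
                                 (i - 1) * rise + dz)
    ca <- pos(0, radius, 0)
    nn <- pos(-0.50, 1.8, -0.6)
    cc <- pos(0.55, 1.9, 0.55)
    oo <- pos(0.55, 3.1, 0.65)
    resname <- .AA20[((i - 1 + aa_offset) %% 20L) + 1L]
    data.frame(name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               resname = resname, chain = chain, resseq = i, icode = "",
               x = c(nn[1], ca[1], cc[1], oo[1]),
               y = c(nn[2], ca[2], cc[2], oo[2]),
               z = c(nn[3], ca[3], cc[3], oo[3]),
               stringsAsFactors = FALSE)
  })
  a <- do.call(rbind, rows)
  a$serial <- serial0 + seq_len(nrow(a)) - 1L
  a$is_hydrogen <- FALSE
  a[, c("serial", "name", "element", "resname", "chain", "resseq", "icode",
        "x", "y", "z", "is_hydrogen")]
}

.rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th); C <- 1 - c_
  matrix(c(c_ + a[1]^2 * C, a[1] * a[2] * C - a[3] * s_,
           a[1] * a[3] * C + a[2] * s_,
           a[2] * a[1] * C + a[3] * s_, c_ + a[2]^2 * C,
           a[2] * a[3] * C - a[1] * s_,
           a[3] * a[1] * C - a[2] * s_, a[3] * a[2] * C + a[1] * s_,
           c_ + a[3]^2 * C), 3, 3, byrow = TRUE)
}

.random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

.apply_rigid <- function(atoms, R, t, center = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center + t, `+`)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Generate a synthetic native complex
#'
#' Two idealized backbone helices packed side by side (axis separation
#' 9.4 Angstrom) so a genuine 5-Angstrom contact interface exists (>= 5
#' contacts, no clashes), with residue names assigned round-robin over the
#' 20 amino acids (offset per target so composition features vary), a small
#' coordinate jitter, and a random global rigid placement. Deterministic per
#' (spec seed, target index).
#'
#' @param spec a [synthetic_spec()].
#' @param index 1-based target index.
#' @return a [complex_model()] with `target_id` `"T<index>"`.
#' @export
make_native <- function(spec, index) {
  .with_seed(.target_seed(spec$seed, paste0("native", index)), {
    rec <- .helix_chain(spec$n_rec, "A", 1L, aa_offset = index)
    lig <- .helix_chain(spec$n_lig, "B", nrow(rec) + 1L,
                        aa_offset = 7L * index)
    # face the ligand helix toward the receptor across x, centred along z
    lig <- .apply_rigid(lig, .rotation_matrix(c(0, 0, 1), 180),
                        c(9.4, 0, (spec$n_rec - spec$n_lig) * 1.5 / 2))
    atoms <- rbind(rec, lig)
    jitter <- matrix(rnorm(3L * nrow(atoms), sd = 0.05), ncol = 3)
    atoms$x <- atoms$x + jitter[, 1]
    atoms$y <- atoms$y + jitter[, 2]
    atoms$z <- atoms$z + jitter[, 3]
    atoms <- .apply_rigid(atoms, .rotation_matrix(.random_unit(),
                                                  runif(1, 0, 360)),
                          runif(3, -10, 10))
    complex_model(atoms, "A", "B", model_id = "native",
                  target_id = paste0("T", index))
  })
}

# Perturb the ligand body rigidly: rotation about an axis through the ligand
# centroid (axis biased perpendicular to the helix axis so displacement
# scales with the lever arm) plus a translation.
.perturb_ligand <- function(native, magnitude_t, magnitude_r) {
  a <- native$atoms
  is_lig <- a$chain %in% native$ligand_chains
  lig <- a[is_lig, , drop = FALSE]
  centroid <- colMeans(as.matrix(lig[, c("x", "y", "z")]))
  # principal (helix) axis of the ligand
  xyz <- sweep(as.matrix(lig[, c("x", "y", "z")]), 2, centroid)
  ax <- svd(xyz)$v[, 1]
  perp <- .random_unit()
  perp <- perp - sum(perp * ax) * ax
  perp <- perp / sqrt(sum(perp^2))
  R <- .rotation_matrix(perp, magnitude_r)
  t <- .random_unit() * magnitude_t
  lig <- .apply_rigid(lig, R, t, center = centroid)
  a[is_lig, c("x", "y", "z")] <- lig[, c("x", "y", "z")]
  m <- native
  m$atoms <- a
  m
}

#' Generate a decoy ensemble with planted quality tiers
#'
#' The ligand is rigidly perturbed with tier-specific translation/rotation
#' magnitudes (translation drawn in \[0.5, 1\] x magnitude for spread;
#' incorrect-tier decoys additionally get a fully random orientation). A
#' `clash_fraction` of the incorrect-tier decoys is instead driven into the
#' receptor to create clash-count outliers. Planted tiers are recorded;
#' boundary decoys may assess into an adjacent tier (tests assert
#' distributional, not per-decoy, agreement).
#'
#' @param native from [make_native()].
#' @param spec a [synthetic_spec()].
#' @return list with `decoys` (list of [complex_model()]) and `planted`
#'   (character vector of tiers), plus `clash_outlier` (logical).
#' @export
make_decoys <- function(native, spec) {
  .with_seed(.target_seed(spec$seed, paste0("decoys", native$target_id)), {
    tiers <- rep(names(spec$tier_counts), spec$tier_counts)
    n_clash <- round(spec$clash_fraction * length(tiers))
    clash_idx <- which(tiers == "incorrect")
    clash_idx <- head(clash_idx, n_clash)
    decoys <- vector("list", length(tiers))
    clash_outlier <- logical(length(tiers))
    rec_centroid <- colMeans(as.matrix(
      .body_atoms(native, "receptor")[, c("x", "y", "z")]))
    for (i in seq_along(tiers)) {
      tier <- tiers[i]
      if (i %in% clash_idx) {
        # interpenetration outlier: ligand centroid dropped onto the
        # receptor centroid
        m <- native
        a <- m$atoms
        is_lig <- a$chain %in% m$ligand_chains
        lig_centroid <- colMeans(as.matrix(a[is_lig, c("x", "y", "z")]))
        shift <- rec_centroid - lig_centroid + runif(3, -1, 1)
        a[is_lig, c("x", "y", "z")] <-
          sweep(as.matrix(a[is_lig, c("x", "y", "z")]), 2, -shift)
        m$atoms <- a
        clash_outlier[i] <- TRUE
        tiers[i] <- "incorrect"
      } else {
        tmax <- spec$tier_translation[[tier]]
        rmax <- spec$tier_rotation[[tier]]
        m <- .perturb_ligand(native, runif(1, 0.5, 1) * tmax,
                             runif(1, 0.5, 1) * rmax)
      }
      m$model_id <- sprintf("%s_d%04d", native$target_id, i)
      decoys[[i]] <- m
    }
    list(decoys = decoys, planted = tiers, clash_outlier = clash_outlier)
  })
}

#' Generate a feature table with stated class-conditional distributions
#'
#' Informative features are Gaussian with class-dependent means; noise
#' features are class-independent; cells go missing independently at each
#' feature's stated rate. Deterministic given the spec seed.
#'
#' @param labels binary vector (0 incorrect / 1 correct), one per decoy row.
#' @param spec a [synthetic_spec()]; `spec$features` states the
#'   distributions.
#' @param target_id,model_ids row keys; defaults enumerate one target.
#' @param seed optional override of `spec$seed`.
#' @return a [feature_table()].
#' @export
make_feature_table <- function(labels, spec,
                               target_id = "T1",
                               model_ids = sprintf("m%05d",
                                                   seq_along(labels)),
                               seed = NULL) {
  fs <- spec$features
  stopifnot(nrow(fs) >= 2L)
  .with_seed(.target_seed(seed %||% spec$seed,
                          paste0("features", target_id)), {
    df <- data.frame(target_id = target_id, model_id = model_ids,
                     stringsAsFactors = FALSE)
    for (k in seq_len(nrow(fs))) {
      mu <- ifelse(labels == 1L, fs$mu_correct[k], fs$mu_incorrect[k])
      x <- rnorm(length(labels), mean = mu, sd = fs$sd[k])
      x[runif(length(x)) < fs$missing_rate[k]] <- NA_real_
      df[[fs$name[k]]] <- x
    }
    feature_table(df)
  })
}
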