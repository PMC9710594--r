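# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no binary fixtures.

# --- model builders --------------------------------------------------------

# A complex from explicit atom coordinates: one atom per row of `coords`,
# residue/chain/name metadata supplied in parallel vectors.
make_model <- function(coords, chain, resseq, name = "CA", element = "C",
                       resname = "ALA", receptor = "A", ligand = "B",
                       icode = "", model_id = "m", target_id = "t") {
  n <- nrow(coords)
  atoms <- data.frame(serial = seq_len(n),
                      name = rep_len(name, n),
                      element = rep_len(element, n),
                      resname = rep_len(resname, n),
                      chain = rep_len(chain, n),
                      resseq = rep_len(resseq, n),
                      icode = rep_len(icode, n),
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      is_hydrogen = rep_len(element, n) %in% c("H", "D"),
                      stringsAsFactors = FALSE)
  complex_model(atoms, receptor, ligand, model_id = model_id,
                target_id = target_id)
}

# Two single-residue bodies, one atom each, a set distance apart on x.
two_atom_model <- function(d, element = "C") {
  make_model(rbind(c(0, 0, 0), c(d, 0, 0)), chain = c("A", "B"),
             resseq = c(1L, 1L), element = element, resname = "GLY")
}

# A contact map object from explicit residue-pair keys.
make_cm <- function(rec_res, lig_res, target = "t", model = "m") {
  structure(data.frame(rec_res = rec_res, lig_res = lig_res,
                       stringsAsFactors = FALSE),
            cutoff = 5, target_id = target, model_id = model,
            class = c("contact_map", "data.frame"))
}

# Random rigid transform applied to a complex model.
random_rigid <- function(model) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  t <- runif(3, -20, 20)
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]; a$y <- xyz[, 2] + t[2]; a$z <- xyz[, 3] + t[3]
  model$atoms <- a
  model
}

# --- independent oracles ---------------------------------------------------

# O(N^2) brute-force cutoff oracles over heavy atoms, written against the
# raw atom tables (no shared code with the package kernels).
brute_force_geometry <- function(model, contact_cutoff = 5,
                                 interface_cutoff = 10, clash_cutoff = 3) {
  a <- model$atoms[!model$atoms$is_hydrogen, ]
  rec <- a[a$chain %in% model$receptor_chains, ]
  lig <- a[a$chain %in% model$ligand_chains, ]
  key <- function(df) sprintf("%s:%d:%s", df$chain, df$resseq, df$icode)
  contacts <- character(0); iface <- character(0); clashes <- 0L
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                  (rec$z[i] - lig$z[j])^2)
      if (d < contact_cutoff)
        contacts <- c(contacts, paste(key(rec[i, ]), key(lig[j, ]),
                                      sep = "|"))
      if (d < interface_cutoff) iface <- c(iface, key(rec[i, ]),
                                           key(lig[j, ]))
      if (d < clash_cutoff) clashes <- clashes + 1L
    }
  }
  list(contacts = sort(unique(contacts)), interface = sort(unique(iface)),
       clashes = clashes)
}

# Quaternion (Horn) absolute-orientation oracle, independent of the Kabsch
# implementation: returns the optimal proper rotation and post-fit RMSD.
quaternion_fit <- function(mobile, reference) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  S <- t(P) %*% Q
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fitted <- P %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

# Analytic buried area of two intersecting solvent spheres (radius r+probe)
# at centre distance d: each sphere loses a spherical cap 2*pi*R*h.
two_sphere_bsa <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(0)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  2 * pi * R1 * h1 + 2 * pi * R2 * h2
}

# Direct-formula metrics oracle (independent re-derivation of the closed
# forms from the confusion counts).
metrics_oracle <- function(tp, tn, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  acc <- (tp + tn) / (tp + tn + fp + fn)
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
  else 0
  list(P = p, R = r, Acc = acc, F1 = f1, MCC = mcc)
}

# Rank-sum empirical AUC oracle.
empirical_auc <- function(x_neg, x_pos) {
  r <- rank(c(x_neg, x_pos))
  rp <- sum(r[(length(x_neg) + 1):(length(x_neg) + length(x_pos))])
  (rp - length(x_pos) * (length(x_pos) + 1) / 2) /
    (length(x_neg) * length(x_pos))
}

# Small labeled decoy set purely as data (for dataset-module tests):
# `per_target` is a named list target -> c(correct = , incorrect = ).
fake_labeled <- function(per_target) {
  rows <- lapply(names(per_target), function(t) {
    nc <- per_target[[t]][["correct"]]; ni <- per_target[[t]][["incorrect"]]
    data.frame(target_id = t,
               model_id = sprintf("%s_m%05d", t, seq_len(nc + ni)),
               quality = c(rep("acceptable", nc), rep("incorrect", ni)),
               label = c(rep(1L, nc), rep(0L, ni)),
               clash_kept = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
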