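test_that("contact_frequencies equals a dictionary tally", {
  set.seed(41)
  # 20 synthetic maps over a small contact universe
  universe <- expand.grid(r = sprintf("A:%d:", 1:5), l = sprintf("B:%d:", 1:4))
  maps <- lapply(1:20, function(i) {
    pick <- runif(nrow(universe)) < 0.3
    make_cm(as.character(universe$r[pick]), as.character(universe$l[pick]))
  })
  fr <- contact_frequencies(maps)
  # oracle: count every key directly
  tally <- table(unlist(lapply(maps, function(m)
    paste(m$rec_res, m$lig_res, sep = "|"))))
  expect_equal(sort(names(fr)), sort(names(tally)))
  expect_equal(unname(fr[names(tally)]), unname(as.numeric(tally)) / 20)

  one <- make_cm("A:1:", "B:1:")
  prior <- if ("A:1:|B:1:" %in% names(tally)) tally[["A:1:|B:1:"]] else 0
  expect_equal(unname(contact_frequencies(c(maps, list(one)))["A:1:|B:1:"]),
               (prior + 1) / 21)
  expect_error(contact_frequencies(list()), "empty")
})

test_that("consrank_score has the stated closed forms and bounds", {
  cmx <- make_cm(sprintf("A:%d:", 1:6), sprintf("B:%d:", 1:6))
  # identical ensemble: every member scores 1
  ens <- rep(list(cmx), 7)
  fr <- contact_frequencies(ens)
  expect_equal(consrank_score(cmx, fr), 1.0)

  # a decoy whose contacts are unique in an ensemble of M scores 1/M
  M <- 5
  maps <- lapply(1:M, function(i)
    make_cm(sprintf("A:%d:", i * 10 + 1:3), sprintf("B:%d:", i * 10 + 1:3)))
  fr2 <- contact_frequencies(maps)
  expect_equal(consrank_score(maps[[1]], fr2), 1 / M)

  # hand tally on a mixed small ensemble
  m1 <- make_cm(c("A:1:", "A:2:"), c("B:1:", "B:2:"))
  m2 <- make_cm(c("A:1:", "A:3:"), c("B:1:", "B:3:"))
  m3 <- make_cm("A:1:", "B:1:")
  fr3 <- contact_frequencies(list(m1, m2, m3))
  expect_equal(consrank_score(m1, fr3), mean(c(3 / 3, 1 / 3)))
  expect_equal(consrank_score(m3, fr3), 1.0)
  expect_equal(consrank_score(m1, fr3, normalize = "sum"), 3 / 3 + 1 / 3)

  # contactless model scores 0; scores always within [0, 1]
  expect_equal(consrank_score(make_cm(character(0), character(0)), fr3), 0)
  for (m in list(m1, m2, m3))
    expect_true(consrank_score(m, fr3) >= 0 && consrank_score(m, fr3) <= 1)

  # duplicating a decoy never decreases its score
  fr4 <- contact_frequencies(list(m1, m2, m3, m1))
  expect_gte(consrank_score(m1, fr4), consrank_score(m1, fr3))
})

test_that("contact_class_counts follows the overlapping class table", {
  pair_model <- function(res_a, res_b)
    make_model(rbind(c(0, 0, 0), c(4, 0, 0)), chain = c("A", "B"),
               resseq = c(1L, 1L), resname = c(res_a, res_b))
  kd <- contact_class_counts(pair_model("LYS", "ASP"))
  expect_equal(unname(kd["NC_charged_charged"]), 1)
  expect_equal(unname(kd["NC_total"]), 1)
  expect_equal(unname(kd["NC_apolar_apolar"]), 0)

  ff <- contact_class_counts(pair_model("PHE", "PHE"))
  expect_equal(unname(ff["NC_aromatic_aromatic"]), 1)
  expect_equal(unname(ff["NC_apolar_apolar"]), 1)   # PHE is in both classes
  expect_equal(unname(ff["NC_apolar_aromatic"]), 1)
  expect_equal(unname(ff["NC_total"]), 1)

  none <- contact_class_counts(two_atom_model(50))
  expect_true(all(none == 0))
  expect_length(none, 21L)

  expect_warning(contact_class_counts(pair_model("UNK", "ALA")), "unknown")
})

test_that("buried_surface_area matches the two-sphere analytic form", {
  for (d in c(3, 4.5, 5.5)) {
    m <- two_atom_model(d)
    bsa <- buried_surface_area(m, n_points = 960)
    expect_equal(unname(bsa["BSA_total"]), two_sphere_bsa(1.7, 1.7, d),
                 tolerance = 0.03)
    expect_equal(unname(bsa["BSA_total"]),
                 unname(bsa["BSA_polar"] + bsa["BSA_apolar"]),
                 tolerance = 1e-6)
    expect_equal(unname(bsa["BSA_polar"]), 0)  # carbon atoms only
  }
  # fully separated bodies bury nothing
  expect_equal(unname(buried_surface_area(two_atom_model(100))["BSA_total"]),
               0, tolerance = 1e-6)
  # partition property holds on a realistic complex too
  nat <- make_native(synthetic_spec(seed = 44), 1)
  b <- buried_surface_area(nat, n_points = 240)
  expect_gt(unname(b["BSA_total"]), 0)
  expect_equal(unname(b["BSA_total"]),
               unname(b["BSA_polar"] + b["BSA_apolar"]), tolerance = 1e-6)
})

test_that("nis reports planted exposed non-interface composition", {
  # 5 SER + 4 LEU receptor atoms and 1 ASN ligand atom, ligand far away:
  # no interface, everything exposed -> 6 polar / 4 apolar = (60, 40)
  coords <- rbind(cbind(seq(0, 80, by = 10), 0, 0), c(300, 0, 0))
  m <- make_model(coords, chain = c(rep("A", 9), "B"), resseq = c(1:9, 1L),
                  resname = c(rep("SER", 5), rep("LEU", 4), "ASN"))
  v <- nis(m, n_points = 960)
  expect_equal(unname(v["NIS_polar"]), 60)
  expect_equal(unname(v["NIS_apolar"]), 40)

  # every residue at the interface -> no eligible residue -> missing
  close_m <- two_atom_model(5)
  expect_true(all(is.na(nis(close_m))))
})

test_that("geometric features are invariant under rigid motion", {
  nat <- make_native(synthetic_spec(seed = 45), 1)
  set.seed(45)
  moved <- random_rigid(nat)
  expect_equal(contact_class_counts(moved), contact_class_counts(nat))
  expect_equal(buried_surface_area(moved, n_points = 240),
               buried_surface_area(nat, n_points = 240), tolerance = 0.02)
  expect_equal(nis(moved, n_points = 240), nis(nat, n_points = 240),
               tolerance = 0.02)
})

test_that("load_external_features merges tables with explicit missing cells", {
  d1 <- data.frame(target_id = "T1", model_id = c("m1", "m2"),
                   scoreA = c(1.5, 2.5))
  d2 <- data.frame(target_id = "T1", model_id = c("m1", "m3"),
                   scoreB = c(9, 10))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.table(d1, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(d2, p2, sep = ",", row.names = FALSE, quote = FALSE)

  ft <- load_external_features(c(p1, p2))
  expect_setequal(registry_names(ft), c("scoreA", "scoreB"))
  expect_true(all(attr(ft, "provenance") == "external"))
  df <- as.data.frame(ft)
  expect_equal(nrow(df), 3L)
  expect_true(is.na(df$scoreB[df$model_id == "m2"]))
  expect_true(is.na(df$scoreA[df$model_id == "m3"]))

  # duplicate keys inside one file
  dup <- rbind(d1, d1[1, ])
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(dup, p3, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_external_features(p3), "key-collision")

  # conflicting values across files
  d1b <- data.frame(target_id = "T1", model_id = "m1", scoreA = 99)
  p4 <- withr::local_tempfile(fileext = ".tsv")
  write.table(d1b, p4, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_external_features(c(p1, p4)), "key-collision")

  # unknown columns dropped with warning when a registry is declared
  expect_warning(ft2 <- load_external_features(p1, registry = "scoreB"),
                 "unknown")
})

test_that("clean_and_impute drops >30%-missing features and fills by target mean", {
  df <- data.frame(
    target_id = rep(c("T1", "T2"), each = 5),
    model_id = sprintf("m%d", 1:10),
    mostly_missing = c(rep(NA, 4), 1:6),          # 40% missing -> dropped
    sparse = c(1, 2, 3, NA, 4, 10, NA, 20, 30, 40),
    full = 1:10)
  ft <- feature_table(df)
  expect_warning(clean <- clean_and_impute(ft), "dropping")
  expect_setequal(registry_names(clean), c("sparse", "full"))
  out <- as.data.frame(clean)
  expect_false(anyNA(out))
  expect_equal(out$sparse[4], mean(c(1, 2, 3, 4)))     # T1 mean
  expect_equal(out$sparse[7], mean(c(10, 20, 30, 40))) # T2 mean
  # idempotent
  expect_equal(as.data.frame(clean_and_impute(clean)), out)

  # a target with zero observations falls back to the global mean
  df2 <- data.frame(target_id = rep(c("T1", "T2"), each = 2),
                    model_id = sprintf("m%d", 1:4),
                    f = c(2, 4, NA, NA))
  out2 <- as.data.frame(clean_and_impute(feature_table(df2), max_missing = 0.5))
  expect_equal(out2$f[3:4], c(3, 3))
})

test_that("zscore with training-fit stats standardizes the training rows", {
  set.seed(46)
  df <- data.frame(target_id = rep(c("T1", "T2"), each = 10),
                   model_id = sprintf("m%d", 1:20),
                   a = rnorm(20, 5, 3), b = runif(20), const = 1)
  ft <- feature_table(df)
  train <- df$target_id == "T1"
  expect_warning(stats <- fit_normalization(ft, rows = train), "constant")
  z <- zscore(ft, stats)
  zm <- as.matrix(as.data.frame(z)[train, c("a", "b")])
  expect_equal(unname(colMeans(zm)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(zm, 2, sd)), c(1, 1), tolerance = 1e-8)
  expect_false("const" %in% registry_names(z))

  # closed forms: x = mu -> 0, x = mu + sigma -> 1
  one <- feature_table(data.frame(target_id = "T", model_id = c("p", "q"),
                                  a = c(stats$mu[["a"]],
                                        stats$mu[["a"]] + stats$sigma[["a"]]),
                                  b = stats$mu[["b"]]))
  zo <- as.data.frame(zscore(one, stats))
  expect_equal(zo$a, c(0, 1))
  expect_equal(zo$b, c(0, 0))
})
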