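# Feature computation for docking decoys: consensus contact-frequency
# (CONSRANK-style) score, inter-residue contact counts per amino-acid class,
# buried surface area (total/polar/apolar), non-interacting surface
# composition, plus ingestion/cleaning/normalization of externally computed
# per-decoy scoring-function tables.

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Amino-acid class table
#'
#' Overlapping membership is intentional (e.g. PHE is both apolar and
#' aromatic, HIS is polar, aromatic and charged).
#' @return named list of 1-letter residue codes per class.
#' @export
residue_classes <- function() {
  list(apolar    = c("A", "V", "L", "I", "M", "P", "G", "F", "W"),
       polar     = c("S", "T", "N", "Q", "C", "Y", "H"),
       aliphatic = c("A", "V", "L", "I"),
       aromatic  = c("F", "W", "Y", "H"),
       charged   = c("D", "E", "K", "R", "H"))
}

# Theoretical maximum accessible surface area per residue (Angstrom^2),
# used for relative solvent exposure.
.MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
              G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
              P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

# Van der Waals radii by element for SASA.
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.vdw_radius <- function(element) {
  r <- .VDW[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Ensemble contact frequencies
#'
#' Frequency ("conservation") of every inter-residue contact over a decoy
#' ensemble: the fraction of ensemble members featuring that contact.
#'
#' @param ensemble list of contact maps ([residue_contacts()]) of the same
#'   target.
#' @return named numeric vector, names `"rec_res|lig_res"`, values in (0, 1].
#' @export
contact_frequencies <- function(ensemble) {
  if (length(ensemble) == 0L) stop("empty ensemble")
  tallies <- table(unlist(lapply(ensemble, contact_keys)))
  setNames(as.numeric(tallies) / length(ensemble), names(tallies))
}

#' Consensus (CONSRANK-style) score of one decoy
#'
#' Mean ensemble frequency of the decoy's inter-residue contacts. A decoy
#' with no contacts scores 0. `normalize = "sum"` returns the unnormalized
#' sum of frequencies instead.
#'
#' @param model_contacts contact map of the decoy.
#' @param frequencies from [contact_frequencies()] on the ensemble containing
#'   the decoy.
#' @param normalize `"mean"` (default) or `"sum"`.
#' @return a single number; in \[0, 1\] for `"mean"`.
#' @export
consrank_score <- function(model_contacts, frequencies,
                           normalize = c("mean", "sum")) {
  normalize <- match.arg(normalize)
  keys <- contact_keys(model_contacts)
  if (length(keys) == 0L) return(0)
  fr <- frequencies[keys]
  fr[is.na(fr)] <- 0
  if (normalize == "mean") mean(fr) else sum(fr)
}

#' Contact counts per amino-acid class
#'
#' For each unordered pair of classes over \{apolar, polar, aliphatic,
#' aromatic, charged\} (15 features), the number of 5-Angstrom residue
#' contacts whose receptor member belongs to one class and ligand member to
#' the other; plus 5 per-class totals (contacts with at least one member in
#' the class) and the overall contact count (21 features). Residues with
#' overlapping class membership count in every applicable class. Unknown
#' residue types count under no class (with a warning) but do enter the
#' overall total.
#'
#' @param model a [complex_model()].
#' @param cutoff contact cutoff, Angstrom.
#' @param classes see [residue_classes()].
#' @return named numeric vector of length 21 (`NC_*`).
#' @export
contact_class_counts <- function(model, cutoff = 5.0,
                                 classes = residue_classes()) {
  cm <- residue_contacts(model, cutoff)
  cls_names <- names(classes)
  pair_names <- character(0)
  for (i in seq_along(cls_names))
    for (j in i:length(cls_names))
      pair_names <- c(pair_names,
                      paste0("NC_", cls_names[i], "_", cls_names[j]))
  counts <- setNames(numeric(length(pair_names) + length(cls_names) + 1L),
                     c(pair_names, paste0("NC_", cls_names), "NC_total"))
  counts["NC_total"] <- nrow(cm)
  if (nrow(cm) == 0L) return(counts)

  res1 <- function(keys) {
    chain_res <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
    a <- model$atoms
    rk <- .res_key(a)
    unname(.AA3TO1[a$resname[match(keys, rk)]])
  }
  aa_r <- res1(cm$rec_res)
  aa_l <- res1(cm$lig_res)
  if (anyNA(aa_r) || anyNA(aa_l))
    warning("contacts with unknown residue type counted under no class")
  member <- function(aa, cl) !is.na(aa) & aa %in% classes[[cl]]
  for (i in seq_along(cls_names)) {
    ci <- cls_names[i]
    in_ri <- member(aa_r, ci); in_li <- member(aa_l, ci)
    counts[paste0("NC_", ci)] <- sum(in_ri | in_li)
    for (j in i:length(cls_names)) {
      cj <- cls_names[j]
      in_rj <- member(aa_r, cj); in_lj <- member(aa_l, cj)
      counts[paste0("NC_", ci, "_", cj)] <-
        sum((in_ri & in_lj) | (in_rj & in_li))
    }
  }
  counts
}

# Per-atom SASA of a heavy-atom table.
.atom_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  sasa_shrake_rupley(as.matrix(atoms[, c("x", "y", "z")]),
                     .vdw_radius(atoms$element), probe, n_points)
}

#' Buried surface area of the interface
#'
#' BSA = SASA(receptor alone) + SASA(ligand alone) - SASA(complex),
#' Shrake-Rupley with a 1.4-Angstrom probe on heavy atoms. The polar part is
#' the contribution of N/O atoms, the apolar part that of all other heavy
#' atoms (C, S, ...); total = polar + apolar exactly.
#'
#' @param model a [complex_model()].
#' @param probe probe radius, Angstrom.
#' @param n_points test points per atom (surface discretization).
#' @return named numeric vector `c(BSA_total=, BSA_polar=, BSA_apolar=)` in
#'   Angstrom^2.
#' @export
buried_surface_area <- function(model, probe = 1.4, n_points = 960) {
  rec <- .body_atoms(model, "receptor")
  lig <- .body_atoms(model, "ligand")
  alone <- c(.atom_sasa(rec, probe, n_points),
             .atom_sasa(lig, probe, n_points))
  both <- rbind(rec, lig)
  incplx <- .atom_sasa(both, probe, n_points)
  db <- alone - incplx
  polar <- both$element %in% c("N", "O")
  c(BSA_total = sum(db), BSA_polar = sum(db[polar]),
    BSA_apolar = sum(db[!polar]))
}

# BSA + NIS sharing one complex SASA evaluation (the featurize hot path).
.surface_features <- function(model, interface_cutoff = 10.0,
                              exposure_threshold = 0.05, probe = 1.4,
                              n_points = 960) {
  rec <- .body_atoms(model, "receptor")
  lig <- .body_atoms(model, "ligand")
  both <- rbind(rec, lig)
  alone <- c(.atom_sasa(rec, probe, n_points),
             .atom_sasa(lig, probe, n_points))
  incplx <- .atom_sasa(both, probe, n_points)
  db <- alone - incplx
  polar <- both$element %in% c("N", "O")
  bsa <- c(BSA_total = sum(db), BSA_polar = sum(db[polar]),
           BSA_apolar = sum(db[!polar]))
  keys <- .res_key(both)
  res_sasa <- tapply(incplx, keys, sum)
  res_aa <- .AA3TO1[both$resname[match(names(res_sasa), keys)]]
  rel <- as.numeric(res_sasa) / as.numeric(.MAX_ASA[res_aa])
  exposed <- !is.na(rel) & rel > exposure_threshold
  pick <- exposed & !(names(res_sasa) %in%
                        interface_residues(model, interface_cutoff))
  nis_v <- if (!any(pick)) c(NIS_polar = NA_real_, NIS_apolar = NA_real_)
  else {
    aa <- res_aa[pick]
    cl <- residue_classes()
    c(NIS_polar = 100 * mean(aa %in% cl$polar),
      NIS_apolar = 100 * mean(aa %in% cl$apolar))
  }
  c(bsa, nis_v)
}

#' Non-interacting surface composition
#'
#' Among residues that are solvent-exposed in the complex (relative SASA
#' above `exposure_threshold` of the residue's theoretical maximum) and NOT
#' part of the 10-Angstrom interface, the percentages that are polar and
#' apolar by the residue class table. Charged-only residues (D, E, K, R)
#' count in the denominator but in neither percentage.
#'
#' @param model a [complex_model()].
#' @param interface_cutoff Angstrom; defines the excluded interface.
#' @param exposure_threshold relative SASA above which a residue is exposed.
#' @param probe,n_points SASA parameters.
#' @return `c(NIS_polar=, NIS_apolar=)` percentages, or both `NA` when no
#'   exposed non-interface residue exists.
#' @export
nis <- function(model, interface_cutoff = 10.0, exposure_threshold = 0.05,
                probe = 1.4, n_points = 960) {
  atoms <- rbind(.body_atoms(model, "receptor"), .body_atoms(model, "ligand"))
  s <- .atom_sasa(atoms, probe, n_points)
  keys <- .res_key(atoms)
  res_sasa <- tapply(s, keys, sum)
  res_aa <- .AA3TO1[atoms$resname[match(names(res_sasa), keys)]]
  max_asa <- .MAX_ASA[res_aa]
  rel <- as.numeric(res_sasa) / as.numeric(max_asa)
  exposed <- !is.na(rel) & rel > exposure_threshold
  iface <- interface_residues(model, interface_cutoff)
  pick <- exposed & !(names(res_sasa) %in% iface)
  if (!any(pick)) return(c(NIS_polar = NA_real_, NIS_apolar = NA_real_))
  aa <- res_aa[pick]
  cl <- residue_classes()
  c(NIS_polar = 100 * mean(aa %in% cl$polar),
    NIS_apolar = 100 * mean(aa %in% cl$apolar))
}

# ---------------------------------------------------------------------------
# Feature tables

#' Construct a feature table
#'
#' A per-decoy feature matrix keyed by (target_id, model_id), with an ordered
#' feature registry and per-feature provenance (`"internal"` or
#' `"external"`). Missing values are `NA`.
#'
#' @param df data.frame with character columns `target_id`, `model_id` and
#'   one numeric column per feature.
#' @param provenance named character vector over the feature columns;
#'   defaults to `"internal"` for all.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(df, provenance = NULL) {
  stopifnot(all(c("target_id", "model_id") %in% names(df)))
  registry <- setdiff(names(df), c("target_id", "model_id"))
  if (anyDuplicated(paste(df$target_id, df$model_id)))
    stop("key-collision error: duplicate (target_id, model_id) rows")
  if (is.null(provenance))
    provenance <- setNames(rep("internal", length(registry)), registry)
  rownames(df) <- NULL
  structure(df, registry = registry,
            provenance = provenance[registry],
            class = c("feature_table", "data.frame"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d rows, %d features (%d internal, %d external)>\n",
              nrow(x), length(attr(x, "registry")),
              sum(attr(x, "provenance") == "internal"),
              sum(attr(x, "provenance") == "external")))
  invisible(x)
}

#' Feature names of a feature table
#' @param table a [feature_table()].
#' @return character vector, in registry order.
#' @export
registry_names <- function(table) attr(table, "registry")

# Numeric feature matrix of a feature table.
feature_matrix <- function(table, features = registry_names(table)) {
  m <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- paste(table$target_id, table$model_id, sep = "/")
  m
}

#' Compute the internal feature set for one target's decoy ensemble
#'
#' CONSRANK score over the ensemble, the 21 contact-class counts, buried
#' surface area (3) and non-interacting surface (2): 27 internal features.
#'
#' @param decoys list of [complex_model()]s of one target (the ensemble the
#'   consensus is computed on).
#' @param contact_cutoff Angstrom for contacts.
#' @param surface logical; set `FALSE` to skip the (costlier) BSA/NIS terms.
#' @param n_points SASA discretization.
#' @return a [feature_table()].
#' @export
featurize_target <- function(decoys, contact_cutoff = 5.0, surface = TRUE,
                             n_points = 960) {
  stopifnot(length(decoys) >= 1L)
  maps <- lapply(decoys, residue_contacts, cutoff = contact_cutoff)
  freqs <- contact_frequencies(maps)
  rows <- lapply(seq_along(decoys), function(i) {
    d <- decoys[[i]]
    v <- c(CONSRANK_score = consrank_score(maps[[i]], freqs),
           contact_class_counts(d, contact_cutoff))
    if (surface)
      v <- c(v, tryCatch(.surface_features(d, n_points = n_points),
                         error = function(e)
                           setNames(rep(NA_real_, 5),
                                    c("BSA_total", "BSA_polar", "BSA_apolar",
                                      "NIS_polar", "NIS_apolar"))))
    cbind(data.frame(target_id = d$target_id, model_id = d$model_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  feature_table(do.call(rbind, rows))
}

#' Load and merge external per-decoy feature tables
#'
#' Reads CSV/TSV files keyed by `target_id` and `model_id` (CCharPPI-style
#' exports) and outer-merges them. Unknown columns (not in `registry`, when
#' given) are dropped with a warning; cells absent from every file stay
#' missing. A (target, model) key carrying conflicting non-missing values
#' for the same feature is an error.
#'
#' @param paths character vector of file paths (`.csv` comma-separated,
#'   anything else tab-separated).
#' @param registry optional expected feature names.
#' @return a [feature_table()] with provenance `"external"`.
#' @export
load_external_features <- function(paths, registry = NULL) {
  merged <- NULL
  for (p in paths) {
    sep <- if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
    df <- read.delim(p, sep = sep, stringsAsFactors = FALSE,
                     check.names = FALSE)
    if (!all(c("target_id", "model_id") %in% names(df)))
      stop("file lacks target_id/model_id columns: ", p)
    if (!is.null(registry)) {
      unknown <- setdiff(names(df), c("target_id", "model_id", registry))
      if (length(unknown) > 0L) {
        warning("ignoring unknown feature column(s): ",
                paste(unknown, collapse = ", "))
        df <- df[, setdiff(names(df), unknown), drop = FALSE]
      }
    }
    if (anyDuplicated(paste(df$target_id, df$model_id)))
      stop("key-collision error: duplicate keys in ", p)
    if (is.null(merged)) { merged <- df; next }
    shared <- setdiff(intersect(names(merged), names(df)),
                      c("target_id", "model_id"))
    both <- merge(merged, df, by = c("target_id", "model_id"), all = TRUE,
                  suffixes = c("", ".NEW"))
    for (f in shared) {
      a <- both[[f]]; b <- both[[paste0(f, ".NEW")]]
      conflict <- !is.na(a) & !is.na(b) & a != b
      if (any(conflict))
        stop("key-collision error: conflicting values for feature ", f)
      a[is.na(a)] <- b[is.na(a)]
      both[[f]] <- a
      both[[paste0(f, ".NEW")]] <- NULL
    }
    merged <- both
  }
  feats <- setdiff(names(merged), c("target_id", "model_id"))
  for (f in feats) merged[[f]] <- as.numeric(merged[[f]])
  feature_table(merged,
                provenance = setNames(rep("external", length(feats)), feats))
}

#' Merge two feature tables (e.g. internal + external)
#'
#' @param a,b [feature_table()]s with disjoint registries.
#' @return merged [feature_table()] (outer join on keys).
#' @export
merge_features <- function(a, b) {
  overlap <- intersect(registry_names(a), registry_names(b))
  if (length(overlap) > 0L)
    stop("feature registries overlap: ", paste(overlap, collapse = ", "))
  m <- merge(as.data.frame(a), as.data.frame(b),
             by = c("target_id", "model_id"), all = TRUE)
  feature_table(m, provenance = c(attr(a, "provenance"),
                                  attr(b, "provenance")))
}

#' Drop over-missing features and impute the rest
#'
#' Features missing in more than `max_missing` (default 30%) of all rows are
#' dropped. Remaining missing cells are imputed with the per-target mean of
#' that feature, falling back to the global (all-target) mean when a target
#' has no observed value. Idempotent.
#'
#' @param table a [feature_table()].
#' @param max_missing maximum tolerated missing fraction per feature.
#' @return imputed [feature_table()] with no missing values.
#' @export
clean_and_impute <- function(table, max_missing = 0.3) {
  df <- as.data.frame(table)
  feats <- registry_names(table)
  frac <- vapply(feats, function(f) mean(is.na(df[[f]])), numeric(1))
  drop <- feats[frac > max_missing]
  if (length(drop) > 0L) {
    warning("dropping ", length(drop), " feature(s) missing in >",
            round(100 * max_missing), "% of rows: ",
            paste(drop, collapse = ", "))
    df <- df[, setdiff(names(df), drop), drop = FALSE]
    feats <- setdiff(feats, drop)
  }
  for (f in feats) {
    x <- df[[f]]
    if (!anyNA(x)) next
    gmean <- mean(x, na.rm = TRUE)
    tmeans <- tapply(x, df$target_id, function(v) mean(v, na.rm = TRUE))
    fill <- as.numeric(tmeans[df$target_id])
    fill[is.nan(fill)] <- gmean
    x[is.na(x)] <- fill[is.na(x)]
    df[[f]] <- x
  }
  feature_table(df, provenance = attr(table, "provenance")[feats])
}

#' Fit Z-score normalization statistics on training rows
#'
#' Per-feature mean and standard deviation, fit on the given rows only
#' (typically the training targets). Constant features (sd = 0) are dropped
#' with a warning.
#'
#' @param table a [feature_table()] without missing values.
#' @param rows optional logical/integer row subset to fit on (default: all).
#' @return list with `mu`, `sigma` (named numeric vectors) and `features`.
#' @export
fit_normalization <- function(table, rows = NULL) {
  m <- feature_matrix(table)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  mu <- colMeans(m)
  sigma <- apply(m, 2, sd)
  keep <- sigma > 0
  if (any(!keep))
    warning("dropping constant feature(s): ",
            paste(names(sigma)[!keep], collapse = ", "))
  list(mu = mu[keep], sigma = sigma[keep], features = names(mu)[keep])
}

#' Apply Z-score normalization
#'
#' Every cell becomes (x - mu) / sigma with the supplied (training-fit)
#' statistics; features without statistics (e.g. constant ones) are dropped.
#'
#' @param table a [feature_table()].
#' @param stats from [fit_normalization()].
#' @return normalized [feature_table()].
#' @export
zscore <- function(table, stats) {
  df <- as.data.frame(table)[, c("target_id", "model_id", stats$features)]
  for (f in stats$features)
    df[[f]] <- (df[[f]] - stats$mu[[f]]) / stats$sigma[[f]]
  feature_table(df, provenance = attr(table, "provenance")[stats$features])
}
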