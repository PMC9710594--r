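# CAPRI-style quality assessment of docking decoys against the native
# complex: fraction of native contacts (fnat), ligand RMSD after receptor
# superposition (L-rms), interface RMSD (I-rms), the four-level quality
# label, and the per-target clash outlier screen.

#' Default CAPRI quality criteria
#'
#' The ranked classification table. `high`: fnat >= 0.5 and (L-rms <= 1 or
#' I-rms <= 1); `medium`: fnat >= 0.3 and (L-rms <= 5 or I-rms <= 2);
#' `acceptable`: fnat >= 0.1 and (L-rms <= 10 or I-rms <= 4); everything
#' else (in particular fnat < 0.1) is `incorrect`. Evaluated top-down, so a
#' decoy gets the best tier whose conditions it meets.
#'
#' @return a named list of per-tier thresholds, editable and passable to
#'   [classify_quality()]; can also be loaded from JSON via
#'   [jsonlite::read_json()] with the same shape.
#' @export
capri_criteria <- function() {
  list(
    high       = list(fnat_min = 0.5, lrms_max = 1,  irms_max = 1),
    medium     = list(fnat_min = 0.3, lrms_max = 5,  irms_max = 2),
    acceptable = list(fnat_min = 0.1, lrms_max = 10, irms_max = 4)
  )
}

#' Quality tiers, worst to best
#' @export
QUALITY_LEVELS <- c("incorrect", "acceptable", "medium", "high")

#' Fraction of native contacts reproduced by a decoy
#'
#' @param native_contacts,model_contacts contact maps from
#'   [residue_contacts()] with consistent residue keying.
#' @return fraction in \[0, 1\]: |native AND model| / |native|. Contacts
#'   present only in the model are ignored.
#' @export
fnat <- function(native_contacts, model_contacts) {
  nk <- contact_keys(native_contacts)
  if (length(nk) == 0L)
    stop("undefined-native error: native contact map is empty")
  mean(nk %in% contact_keys(model_contacts))
}

# Backbone coordinate matrices of decoy/native matched by
# (residue key, atom name); unmatched atoms are dropped with a logged count.
.matched_backbone <- function(native, decoy, chains, residue_subset = NULL) {
  sel <- function(m) {
    a <- m$atoms[m$atoms$chain %in% chains & !m$atoms$is_hydrogen &
                   m$atoms$name %in% .BACKBONE, , drop = FALSE]
    if (!is.null(residue_subset))
      a <- a[.res_key(a) %in% residue_subset, , drop = FALSE]
    key <- paste0(.res_key(a), "|", a$name)
    a <- a[!duplicated(key), , drop = FALSE]
    rownames(a) <- NULL
    list(a = a, key = paste0(.res_key(a), "|", a$name))
  }
  nn <- sel(native); dd <- sel(decoy)
  common <- intersect(nn$key, dd$key)
  dropped <- length(union(nn$key, dd$key)) - length(common)
  if (dropped > 0L)
    message(sprintf("dropped %d unmatched backbone atom(s)", dropped))
  list(native = as.matrix(nn$a[match(common, nn$key), c("x", "y", "z")]),
       decoy = as.matrix(dd$a[match(common, dd$key), c("x", "y", "z")]),
       n = length(common))
}

#' Ligand RMSD (L-rms)
#'
#' Backbone RMSD of the decoy ligand against the native ligand after optimal
#' superposition of the decoy receptor backbone onto the native receptor
#' backbone. Residues are matched by (chain, resseq, icode).
#'
#' @param native,decoy [complex_model()]s sharing residue numbering.
#' @return L-rms in Angstrom.
#' @export
ligand_rmsd <- function(native, decoy) {
  rec <- .matched_backbone(native, decoy, native$receptor_chains)
  if (rec$n < 3L)
    stop("correspondence error: <3 matched receptor backbone atoms")
  fit <- superpose(rec$decoy, rec$native)
  lig <- .matched_backbone(native, decoy, native$ligand_chains)
  if (lig$n < 1L) stop("correspondence error: no matched ligand atoms")
  rmsd_coords(fit$transform(lig$decoy), lig$native)
}

#' Interface RMSD (I-rms)
#'
#' Backbone RMSD over the NATIVE interface residues (both bodies, 10 Angstrom
#' heavy-atom criterion on the native) after optimally superposing the
#' decoy's matching interface backbone onto the native's.
#'
#' @inheritParams ligand_rmsd
#' @param interface_cutoff Angstrom cutoff defining the native interface.
#' @return I-rms in Angstrom (post-fit RMSD).
#' @export
interface_rmsd <- function(native, decoy, interface_cutoff = 10.0) {
  iface <- interface_residues(native, interface_cutoff)
  m <- .matched_backbone(native, decoy,
                         c(native$receptor_chains, native$ligand_chains),
                         residue_subset = iface)
  if (m$n < 3L)
    stop("correspondence error: <3 matched interface backbone atoms")
  superpose(m$decoy, m$native)$rmsd
}

#' Assign the CAPRI quality label
#'
#' @param fnat,lrms,irms the three assessment parameters (vectorized).
#' @param criteria threshold table, see [capri_criteria()].
#' @return character vector of labels in
#'   `c("incorrect", "acceptable", "medium", "high")`.
#' @export
classify_quality <- function(fnat, lrms, irms, criteria = capri_criteria()) {
  tier <- function(cr) fnat >= cr$fnat_min &
    (lrms <= cr$lrms_max | irms <= cr$irms_max)
  out <- rep("incorrect", length(fnat))
  out[tier(criteria$acceptable)] <- "acceptable"
  out[tier(criteria$medium)] <- "medium"
  out[tier(criteria$high)] <- "high"
  out
}

#' Per-target clash outlier screen
#'
#' Discards decoys whose clash count strictly exceeds mean + 2 standard
#' deviations (sample sd, n-1 denominator) over the target's decoys.
#'
#' @param clashes named integer vector (names = model ids) or data.frame with
#'   columns `model_id`, `clashes`.
#' @param n_sd number of standard deviations above the mean.
#' @return list with `mean_clashes`, `sd_clashes`, `threshold`, `kept_ids`,
#'   `discarded_ids`.
#' @export
screen_clashes <- function(clashes, n_sd = 2) {
  if (is.data.frame(clashes))
    clashes <- setNames(clashes$clashes, clashes$model_id)
  if (length(clashes) < 2L)
    stop("degenerate-statistics error: need >= 2 models")
  mu <- mean(clashes); s <- sd(clashes)
  thr <- mu + n_sd * s
  list(mean_clashes = mu, sd_clashes = s, threshold = thr,
       kept_ids = names(clashes)[clashes <= thr],
       discarded_ids = names(clashes)[clashes > thr])
}

#' Assess a target's decoys against the native
#'
#' Computes fnat, L-rms, I-rms, clash count and quality label for each decoy.
#' Per-decoy failures are flagged in the `error` column rather than aborting
#' the batch; output preserves input order.
#'
#' @param native the native [complex_model()].
#' @param decoys list of decoy [complex_model()]s.
#' @param criteria see [capri_criteria()].
#' @param contact_cutoff,interface_cutoff,clash_cutoff Angstrom.
#' @return data.frame: `model_id`, `fnat`, `lrms`, `irms`, `clashes`,
#'   `quality`, `error`.
#' @export
assess_target <- function(native, decoys, criteria = capri_criteria(),
                          contact_cutoff = 5.0, interface_cutoff = 10.0,
                          clash_cutoff = 3.0) {
  native_cm <- residue_contacts(native, contact_cutoff)
  rows <- lapply(decoys, function(d) {
    out <- data.frame(model_id = d$model_id, fnat = NA_real_,
                      lrms = NA_real_, irms = NA_real_,
                      clashes = NA_integer_, quality = NA_character_,
                      error = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      out$fnat <- fnat(native_cm, residue_contacts(d, contact_cutoff))
      out$lrms <- suppressMessages(ligand_rmsd(native, d))
      out$irms <- suppressMessages(
        interface_rmsd(native, d, interface_cutoff))
      out$clashes <- count_clashes(d, clash_cutoff)
      out$quality <- classify_quality(out$fnat, out$lrms, out$irms, criteria)
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
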