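# Geometric kernel: inter-body contacts, interface residues, clashes, and
# optimal rigid superposition. All cutoffs use a strict "<" comparison and
# heavy atoms only.

# Cross-body pairs of heavy atoms with distance < cutoff.
# Returns list(ri, li, d): indices into the receptor/ligand atom tables.
.cross_pairs <- function(rec, lig, cutoff) {
  if (nrow(rec) == 0L || nrow(lig) == 0L)
    return(list(ri = integer(0), li = integer(0)))
  hits <- cross_pairs_within(as.matrix(rec[, c("x", "y", "z")]),
                             as.matrix(lig[, c("x", "y", "z")]),
                             cutoff)
  list(ri = hits[, 1L], li = hits[, 2L])
}

#' Inter-body residue contact map
#'
#' A contact is any receptor/ligand heavy-atom pair closer than `cutoff`
#' (default 5 Angstrom), recorded as the unordered-in-atoms but role-ordered
#' pair (receptor residue, ligand residue).
#'
#' @param model a [complex_model()].
#' @param cutoff Angstrom; strict `<`.
#' @return object of class `contact_map`: data.frame with columns `rec_res`,
#'   `lig_res` (residue keys), plus attributes `cutoff`, `target_id`,
#'   `model_id`.
#' @export
residue_contacts <- function(model, cutoff = 5.0) {
  rec <- .body_atoms(model, "receptor")
  lig <- .body_atoms(model, "ligand")
  p <- .cross_pairs(rec, lig, cutoff)
  pairs <- unique(data.frame(rec_res = .res_key(rec)[p$ri],
                             lig_res = .res_key(lig)[p$li],
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  structure(pairs[order(pairs$rec_res, pairs$lig_res), , drop = FALSE],
            cutoff = cutoff, target_id = model$target_id,
            model_id = model$model_id, class = c("contact_map", "data.frame"))
}

# Canonical "rec|lig" contact keys of a contact map.
contact_keys <- function(cm) {
  if (nrow(cm) == 0L) character(0) else paste(cm$rec_res, cm$lig_res, sep = "|")
}

#' Interface residues at a heavy-atom distance cutoff
#'
#' Union over both bodies of residues having at least one heavy atom closer
#' than `cutoff` (default 10 Angstrom) to any heavy atom of the partner body.
#'
#' @inheritParams residue_contacts
#' @return character vector of residue keys (`"chain:resseq:icode"`), sorted.
#' @export
interface_residues <- function(model, cutoff = 10.0) {
  rec <- .body_atoms(model, "receptor")
  lig <- .body_atoms(model, "ligand")
  p <- .cross_pairs(rec, lig, cutoff)
  sort(unique(c(.res_key(rec)[p$ri], .res_key(lig)[p$li])))
}

#' Count inter-body atomic clashes
#'
#' Clashes are receptor/ligand heavy-atom pairs closer than `cutoff`
#' (default 3 Angstrom).
#'
#' @inheritParams residue_contacts
#' @return non-negative integer count of atom pairs.
#' @export
count_clashes <- function(model, cutoff = 3.0) {
  rec <- .body_atoms(model, "receptor")
  lig <- .body_atoms(model, "ligand")
  length(.cross_pairs(rec, lig, cutoff)$ri)
}

#' Unfitted RMSD between two coordinate sets
#'
#' @param a,b numeric n x 3 matrices in atom correspondence.
#' @return RMSD in Angstrom.
#' @export
rmsd_coords <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("correspondence error: coordinate sets differ in length")
  if (nrow(a) < 1L) stop("correspondence error: empty coordinate sets")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` with a proper rotation
#' (reflection corrected by flipping the smallest singular vector when the
#' determinant is negative).
#'
#' @param mobile,reference numeric n x 3 matrices (n >= 3) in correspondence.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (post-fit), and `transform(x)` applying the fit to new n x 3
#'   coordinates.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("correspondence error: point sets differ in length")
  if (nrow(mobile) < 3L)
    stop("underdetermined error: need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)                       # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)                  # x_ref ~ R %*% x_mob
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  translation <- as.numeric(cr - R %*% cm)
  list(rotation = R, translation = translation, rmsd = rmsd,
       transform = function(x) sweep(as.matrix(x) %*% t(R), 2,
                                     translation, `+`))
}
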