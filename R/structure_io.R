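#' @useDynLib decoyforest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd setNames predict rnorm runif
#' @importFrom utils read.delim write.table head
NULL

# Water residue names excluded from all geometry.
.WATERS <- c("HOH", "WAT", "DOD", "H2O")

#' Two-body complex model
#'
#' Container for the atoms of a protein-protein complex with an explicit
#' receptor/ligand chain partition. The receptor is, by convention, the larger
#' body (more residues) and the ligand the smaller one; an explicit partition
#' overrides that convention.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`, `is_hydrogen`.
#' @param receptor_chains,ligand_chains character vectors of chain ids; must
#'   be disjoint and jointly cover every atom's chain.
#' @param model_id,target_id identifier strings.
#' @return An object of class `complex_model`.
#' @export
complex_model <- function(atoms, receptor_chains, ligand_chains,
                          model_id = "model", target_id = "target") {
  receptor_chains <- unique(as.character(receptor_chains))
  ligand_chains <- unique(as.character(ligand_chains))
  if (length(intersect(receptor_chains, ligand_chains)) > 0L)
    stop("receptor and ligand chain sets overlap: ",
         paste(intersect(receptor_chains, ligand_chains), collapse = ","))
  extra <- setdiff(unique(atoms$chain), c(receptor_chains, ligand_chains))
  if (length(extra) > 0L)
    stop("chains not assigned to either body: ", paste(extra, collapse = ","))
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  structure(list(model_id = model_id, target_id = target_id,
                 atoms = atoms, receptor_chains = receptor_chains,
                 ligand_chains = ligand_chains),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("<complex_model %s/%s: %d atoms, receptor {%s}, ligand {%s}>\n",
              x$target_id, x$model_id, nrow(x$atoms),
              paste(x$receptor_chains, collapse = ","),
              paste(x$ligand_chains, collapse = ",")))
  invisible(x)
}

.guess_element <- function(name, resname) {
  # PDB atom-name heuristics when columns 77-78 are blank: names are
  # right-justified in a 4-char field; element is the first alphabetic
  # character unless the name starts with a digit (e.g. "1HB2").
  nm <- gsub("[0-9' ]", "", name)
  if (nchar(nm) == 0L) return("X")
  first <- substr(nm, 1L, 1L)
  if (first == "H") return("H")
  if (first == "D") return("D")
  first
}

#' Read a PDB file into a complex model
#'
#' Parses ATOM records (fixed columns). HETATM records and waters are dropped;
#' for alternate locations, the highest-occupancy conformer is kept (first on
#' tie). Hydrogens are retained in the model but excluded from contact, clash
#' and surface geometry downstream. If no chain partition is supplied, chains
#' are split so the body with more residues becomes the receptor.
#'
#' @param path PDB file path.
#' @param receptor_chains,ligand_chains optional explicit chain partition.
#' @param model_id,target_id identifiers; default to the file base name.
#' @return A [complex_model()].
#' @export
read_pdb <- function(path, receptor_chains = NULL, ligand_chains = NULL,
                     model_id = NULL, target_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_lines <- lines[rec == "ATOM  "]
  if (length(atom_lines) == 0L)
    stop("format error: no ATOM records in ", path)
  f <- function(a, b) substr(atom_lines, a, b)
  serial <- suppressWarnings(as.integer(f(7, 11)))
  name <- trimws(f(13, 16))
  altloc <- f(17, 17)
  resname <- trimws(f(18, 20))
  chain <- trimws(f(22, 22))
  resseq <- suppressWarnings(as.integer(f(23, 26)))
  icode <- trimws(f(27, 27))
  x <- suppressWarnings(as.numeric(f(31, 38)))
  y <- suppressWarnings(as.numeric(f(39, 46)))
  z <- suppressWarnings(as.numeric(f(47, 54)))
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  elem <- toupper(trimws(substr(atom_lines, 77, 78)))
  if (any(!is.finite(x) | !is.finite(y) | !is.finite(z)))
    stop("format error: unparseable coordinates in ", path)
  blank <- elem == ""
  if (any(blank))
    elem[blank] <- mapply(.guess_element, name[blank], resname[blank])
  keep <- !(resname %in% .WATERS)
  atoms <- data.frame(serial = serial, name = name, element = elem,
                      resname = resname, chain = chain, resseq = resseq,
                      icode = icode, x = x, y = y, z = z,
                      altloc = altloc, occ = occ,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # first on tie (stable order).
  has_alt <- atoms$altloc != " " & atoms$altloc != ""
  if (any(has_alt)) {
    key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name)
    ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resseq,
                                     atoms$icode, atoms$name)), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  atoms$altloc <- NULL
  atoms$occ <- NULL
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  rownames(atoms) <- NULL

  base <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  chains <- unique(atoms$chain)
  if (is.null(receptor_chains) || is.null(ligand_chains)) {
    if (length(chains) < 2L)
      stop("partition error: single-chain file and no explicit partition")
    nres <- vapply(chains, function(ch) {
      a <- atoms[atoms$chain == ch, ]
      length(unique(paste(a$resseq, a$icode)))
    }, integer(1))
    # larger body = receptor; deterministic: sort chains, assign the single
    # largest chain... with >2 chains, greedily assign chains (largest first)
    # to the smaller-so-far body so sizes balance, then call the bigger side
    # the receptor.  For the common 2-chain case this is just larger=receptor.
    ord <- order(-nres, chains)
    side_a <- character(0); side_b <- character(0); na <- 0L; nb <- 0L
    for (i in ord) {
      if (na <= nb) { side_a <- c(side_a, chains[i]); na <- na + nres[i] }
      else { side_b <- c(side_b, chains[i]); nb <- nb + nres[i] }
    }
    if (na >= nb) { receptor_chains <- side_a; ligand_chains <- side_b }
    else { receptor_chains <- side_b; ligand_chains <- side_a }
  }
  complex_model(atoms, receptor_chains, ligand_chains,
                model_id = model_id %||% base,
                target_id = target_id %||% base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a complex model as a PDB file
#'
#' @param model a [complex_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L,
    ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name),
    a$resname, a$chain, a$resseq %% 10000L,
    ifelse(a$icode == "", " ", a$icode),
    a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Residue keys "chain:resseq:icode" in atom order (stable).
.res_key <- function(atoms) sprintf("%s:%d:%s", atoms$chain, atoms$resseq,
                                    atoms$icode)

.body_atoms <- function(model, body = c("receptor", "ligand"),
                        heavy_only = TRUE) {
  body <- match.arg(body)
  ch <- if (body == "receptor") model$receptor_chains else model$ligand_chains
  a <- model$atoms[model$atoms$chain %in% ch, , drop = FALSE]
  if (heavy_only) a <- a[!a$is_hydrogen, , drop = FALSE]
  a
}

.BACKBONE <- c("N", "CA", "C", "O")

#' Backbone coordinates in stable residue order
#'
#' Backbone = N, CA, C, O. Residues missing some backbone atoms contribute the
#' atoms they have, with a warning. Order: atoms sorted by (chain, resseq,
#' icode, backbone position).
#'
#' @param model a [complex_model()].
#' @param residue_subset optional character vector of residue keys
#'   (`"chain:resseq:icode"`); `NULL` means all residues.
#' @return numeric matrix (n x 3) with rownames `"<residue key>|<atom name>"`.
#' @export
backbone_coords <- function(model, residue_subset = NULL) {
  a <- model$atoms[!model$atoms$is_hydrogen & model$atoms$name %in% .BACKBONE,
                   , drop = FALSE]
  keys <- .res_key(a)
  if (!is.null(residue_subset)) {
    if (length(residue_subset) == 0L)
      stop("empty-selection error: residue_subset is empty")
    a <- a[keys %in% residue_subset, , drop = FALSE]
    keys <- .res_key(a)
  }
  if (nrow(a) == 0L) stop("empty-selection error: no backbone atoms selected")
  ord <- order(a$chain, a$resseq, a$icode, match(a$name, .BACKBONE))
  a <- a[ord, , drop = FALSE]
  keys <- keys[ord]
  n_partial <- sum(table(keys) < 4L)
  if (n_partial > 0L)
    warning(sprintf("%d residue(s) with incomplete backbone", n_partial))
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste0(keys, "|", a$name)
  m
}
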