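# Structure input/output and basic structural operations.
#
# A `protein_structure` holds heavy atoms of the polymer only, ordered as in
# the source file; hetero groups are carried separately as `ligand_instance`
# objects. All coordinates are in Angstrom.

#' Residue-key strings
#'
#' A residue is identified by `chain:resno:icode` (insertion code usually
#' empty). Keys are unique within a structure and stable across re-reads.
#'
#' @param chain chain identifiers
#' @param resno residue sequence numbers
#' @param icode insertion codes (default empty)
#' @return character vector of keys
#' @export
residue_key <- function(chain, resno, icode = "") {
  icode[is.na(icode)] <- ""
  paste(chain, resno, icode, sep = ":")
}

#' Construct a protein structure from an atom table
#'
#' @param atom data.frame with columns `chain`, `resno`, `icode`, `resid`
#'   (3-letter residue name), `elety` (atom name), `elesy` (element),
#'   `x`, `y`, `z`
#' @param source provenance string
#' @return an object of class `protein_structure` with fields `atom`,
#'   `residue_keys` (ordered, unique), `residue_names`, `chains`, `source`
#' @export
protein_structure <- function(atom, source = "<memory>") {
  stopifnot(is.data.frame(atom), nrow(atom) >= 1)
  needed <- c("chain", "resno", "icode", "resid", "elety", "elesy",
              "x", "y", "z")
  missing_cols <- setdiff(needed, names(atom))
  if (length(missing_cols))
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("non-finite atom coordinates")
  key <- residue_key(atom$chain, atom$resno, atom$icode)
  ukeys <- unique(key)
  res_index <- match(key, ukeys)
  first <- !duplicated(key)
  structure(
    list(atom = atom,
         residue_keys = ukeys,
         residue_names = atom$resid[first],
         residue_index = res_index,
         chains = unique(atom$chain),
         source = source),
    class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d residues, %d atoms, chain(s) %s [%s]\n",
              length(x$residue_keys), nrow(x$atom),
              paste(x$chains, collapse = ","), x$source))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `protein_structure`
#' @return integer
#' @export
n_residues <- function(structure) length(structure$residue_keys)

#' Heavy-atom coordinate matrix
#' @param structure a `protein_structure` or `ligand_instance`
#' @return numeric matrix with one row per atom and columns x, y, z
#' @export
atom_coords <- function(structure) {
  if (inherits(structure, "ligand_instance")) return(structure$coords)
  as.matrix(structure$atom[, c("x", "y", "z")])
}

#' Construct a ligand instance
#'
#' @param resid het code (e.g. "LIG")
#' @param chain,resno,icode residue identifiers of the hetero group
#' @param coords heavy-atom coordinate matrix (n x 3)
#' @param elety atom names
#' @param elesy element symbols
#' @return object of class `ligand_instance`
#' @export
ligand_instance <- function(resid, chain, resno, coords, elety = NULL,
                            elesy = NULL, icode = "") {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("ligand must have at least one heavy atom")
  if (!all(is.finite(coords))) stop("non-finite ligand coordinates")
  if (is.null(elety)) elety <- sprintf("C%d", seq_len(nrow(coords)))
  if (is.null(elesy)) elesy <- rep("C", nrow(coords))
  structure(
    list(id = paste0(resid, ":", residue_key(chain, resno, icode)),
         resid = resid, chain = chain, resno = resno, icode = icode,
         coords = coords, elety = elety, elesy = elesy),
    class = "ligand_instance")
}

# Hetero residue names treated as solvent, never as ligands.
WATER_CODES <- c("HOH", "WAT", "DOD")

#' Default monoatomic-ion het codes excluded from ligand extraction
#' @return character vector
#' @export
default_ion_codes <- function() {
  c("NA", "CL", "MG", "ZN", "CA", "K", "MN", "FE", "CU", "NI", "CO", "CD",
    "HG", "BR", "IOD", "F", "LI", "RB", "CS", "SR", "BA", "SO4", "PO4")
}

#' Read a protein structure and its ligands from a PDB file
#'
#' Polymer residues come from ATOM records and hetero groups from HETATM
#' records. Hydrogens are discarded (all distance rules in the pipeline are
#' heavy-atom conventions); waters and monoatomic ions are excluded from the
#' ligand list; only the first alternate location is kept.
#'
#' @param path file path
#' @param format "pdb" (default) or "cif"
#' @param ion_codes het codes excluded as ions
#' @return list with elements `structure` (a [protein_structure()]) and
#'   `ligands` (list of [ligand_instance()])
#' @export
read_structure <- function(path, format = c("pdb", "cif"),
                           ion_codes = default_ion_codes()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
         else bio3d::read.cif(path, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  elesy <- at$elesy
  bad <- is.na(elesy) | elesy == ""
  if (any(bad)) elesy[bad] <- substr(gsub("[0-9 ]", "", at$elety[bad]), 1, 1)
  elesy <- toupper(elesy)
  at$elesy <- elesy
  keep <- elesy != "H" & elesy != "D" & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  poly <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(poly) == 0) stop("no polymer (ATOM) heavy atoms in ", path)
  struct <- protein_structure(
    data.frame(chain = poly$chain, resno = poly$resno, icode = poly$insert,
               resid = poly$resid, elety = poly$elety, elesy = poly$elesy,
               x = poly$x, y = poly$y, z = poly$z,
               stringsAsFactors = FALSE),
    source = path)
  het <- at[at$type == "HETATM", , drop = FALSE]
  het <- het[!(het$resid %in% c(WATER_CODES, ion_codes)), , drop = FALSE]
  ligands <- list()
  if (nrow(het)) {
    grp <- paste(het$resid, het$chain, het$resno, het$insert, sep = "|")
    for (g in unique(grp)) {
      sub <- het[grp == g, , drop = FALSE]
      ligands[[length(ligands) + 1L]] <- ligand_instance(
        resid = sub$resid[1], chain = sub$chain[1], resno = sub$resno[1],
        coords = cbind(sub$x, sub$y, sub$z),
        elety = sub$elety, elesy = sub$elesy, icode = sub$insert[1])
    }
  }
  list(structure = struct, ligands = ligands)
}

#' Write a structure (and optional ligands) to a PDB file
#'
#' Emits standard ATOM/HETATM records with %8.3f coordinates; ligand groups
#' are appended after the polymer.
#'
#' @param structure a `protein_structure`
#' @param path output path
#' @param ligands optional list of `ligand_instance`
#' @return `path`, invisibly
#' @export
write_structure_pdb <- function(structure, path, ligands = list()) {
  at <- structure$atom
  n_poly <- nrow(at)
  lig_rows <- if (length(ligands))
    do.call(rbind, lapply(ligands, function(l)
      data.frame(chain = l$chain, resno = l$resno, icode = l$icode,
                 resid = l$resid, elety = l$elety, elesy = l$elesy,
                 x = l$coords[, 1], y = l$coords[, 2], z = l$coords[, 3],
                 stringsAsFactors = FALSE)))
  else NULL
  all_rows <- rbind(at, lig_rows)
  n <- nrow(all_rows)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(all_rows[, c("x", "y", "z")]))),
    type = c(rep("ATOM", n_poly), rep("HETATM", n - n_poly)),
    resno = all_rows$resno,
    resid = all_rows$resid,
    eleno = seq_len(n),
    elety = all_rows$elety,
    chain = all_rows$chain,
    insert = all_rows$icode,
    elesy = all_rows$elesy)
  invisible(path)
}

#' Restrict a structure to a single chain
#'
#' @param structure a `protein_structure`
#' @param chain_id chain identifier
#' @return a `protein_structure` with exactly the residues of that chain,
#'   in the original order
#' @export
select_chain <- function(structure, chain_id) {
  if (!chain_id %in% structure$chains)
    stop("chain '", chain_id, "' not present (chains: ",
         paste(structure$chains, collapse = ","), ")")
  keep <- structure$atom$chain == chain_id
  protein_structure(structure$atom[keep, , drop = FALSE],
                    source = structure$source)
}

# Maximum accessible surface areas (A^2) per residue type, theoretical
# Gly-X-Gly values (Tien et al. 2013), used to normalise ASA to RSA.
MAX_ASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174)
GENERIC_MAX_ASA <- 197

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
GENERIC_VDW <- 1.70

#' Per-residue relative solvent accessibility
#'
#' Shrake-Rupley accessible surface area (probe 1.4 A, deterministic
#' golden-spiral test points) summed per residue and divided by the residue
#' type's reference maximum ASA. Values are dimensionless, typically in
#' `[0, ~1.2]`; residues with RSA at or below 0.02 are treated as buried by
#' the labelling rules.
#'
#' @param structure a `protein_structure`
#' @param n_sphere_points test points per atom (default 960)
#' @param probe probe radius in Angstrom (default 1.4)
#' @return named numeric vector, one entry per residue key
#' @export
relative_surface_accessibility <- function(structure, n_sphere_points = 960,
                                           probe = 1.4) {
  if (n_residues(structure) < 1) stop("empty structure")
  radii <- VDW_RADII[structure$atom$elesy]
  radii[is.na(radii)] <- GENERIC_VDW
  asa_atom <- cpp_sasa(atom_coords(structure), radii, n_sphere_points, probe)
  asa_res <- as.numeric(tapply(asa_atom, structure$residue_index, sum))
  ref <- MAX_ASA[structure$residue_names]
  if (anyNA(ref)) {
    warning("residue type(s) missing from the max-ASA table: ",
            paste(unique(structure$residue_names[is.na(ref)]), collapse = ","),
            "; using the generic maximum")
    ref[is.na(ref)] <- GENERIC_MAX_ASA
  }
  setNames(asa_res / ref, structure$residue_keys)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Matched coordinate pair for two structures: atoms are matched by
# (residue key, atom name); unmatched atoms/residues are dropped.
matched_coords <- function(a, b, selection = c("backbone", "all")) {
  selection <- match.arg(selection)
  tag <- function(s) paste(residue_key(s$atom$chain, s$atom$resno,
                                       s$atom$icode), s$atom$elety)
  ta <- tag(a); tb <- tag(b)
  if (selection == "backbone") {
    ka <- a$atom$elety %in% BACKBONE_ATOMS
    kb <- b$atom$elety %in% BACKBONE_ATOMS
  } else {
    ka <- rep(TRUE, length(ta)); kb <- rep(TRUE, length(tb))
  }
  common <- intersect(ta[ka], tb[kb])
  if (length(common) < 3)
    stop("fewer than 3 matched atoms for selection '", selection, "'")
  ia <- match(common, ta); ib <- match(common, tb)
  list(a = atom_coords(a)[ia, , drop = FALSE],
       b = atom_coords(b)[ib, , drop = FALSE],
       n_dropped = (sum(ka) - length(common)) + (sum(kb) - length(common)))
}

# Kabsch least-squares rotation: returns R such that
# mobile_centred %*% t(R) best fits reference_centred.
kabsch_rotation <- function(mobile_c, ref_c) {
  s <- svd(crossprod(mobile_c, ref_c))       # X^T Y = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Rigid-body superposition of two structures
#'
#' Least-squares (Kabsch) fit of `mobile` onto `reference` over atoms matched
#' by residue key and atom name, with the proper-rotation determinant
#' correction. The returned transform maps mobile coordinates as
#' `x %*% t(rotation) + translation`.
#'
#' @param mobile,reference `protein_structure` objects
#' @param selection "backbone" (N, CA, C, O) or "all"
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (post-fit, Angstrom) and `n_atoms` matched
#' @export
superpose <- function(mobile, reference, selection = c("backbone", "all")) {
  m <- matched_coords(mobile, reference, selection)
  cm <- colMeans(m$a); cr <- colMeans(m$b)
  R <- kabsch_rotation(sweep(m$a, 2, cm), sweep(m$b, 2, cr))
  tr <- as.numeric(cr - R %*% cm)
  fitted <- sweep(m$a, 2, cm) %*% t(R)
  dev <- fitted - sweep(m$b, 2, cr)
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums(dev^2))), n_atoms = nrow(m$a))
}

#' Apply a rigid transform to a structure
#' @param structure a `protein_structure`
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 vector
#' @return transformed `protein_structure`
#' @export
transform_structure <- function(structure, rotation, translation) {
  xyz <- atom_coords(structure) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  at <- structure$atom
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  protein_structure(at, source = structure$source)
}

#' Root-mean-square deviation between two structures
#'
#' @param a,b `protein_structure` objects with matchable residue keys
#' @param selection "backbone" or "all"
#' @param superpose_first least-squares fit before measuring (default TRUE)
#' @return RMSD in Angstrom
#' @export
structure_rmsd <- function(a, b, selection = c("backbone", "all"),
                           superpose_first = TRUE) {
  selection <- match.arg(selection)
  if (superpose_first) return(superpose(a, b, selection)$rmsd)
  m <- matched_coords(a, b, selection)
  sqrt(mean(rowSums((m$a - m$b)^2)))
}
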