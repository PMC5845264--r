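# Reading protein-ligand complexes from PDB text and deriving typed
# ligand-protein contact profiles.  Pocket residues are defined by a
# distance criterion: any ligand-heavy-atom / residue-heavy-atom pair at or
# below `contact_cutoff` (4.5 A by default) is a contact, and a binding
# residue is a residue with at least one contact.

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# modified polymer residues mapped to their parent amino acid for sequence
# and residue-group purposes (selenomethionine and friends)
.residue_aliases <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", CSO = "CYS", CSD = "CYS",
  OCS = "CYS", SEP = "SER", TPO = "THR", PTR = "TYR", HYP = "PRO",
  MLY = "LYS", KCX = "LYS", CME = "CYS", CSX = "CYS", ALY = "LYS",
  M3L = "LYS", FME = "MET", PCA = "GLU", LLP = "LYS"
)

# physico-chemical residue groups used to type protein-ligand contacts:
# I aliphatic/thioether, II small, III hydroxyl, IV proline, V aromatic,
# VI acid/amide, VII basic, VIII histidine
.residue_group_table <- c(
  LEU = "I", VAL = "I", ILE = "I", MET = "I", CYS = "I",
  ALA = "II", GLY = "II",
  SER = "III", THR = "III",
  PRO = "IV",
  PHE = "V", TYR = "V", TRP = "V",
  GLU = "VI", ASP = "VI", ASN = "VI", GLN = "VI",
  LYS = "VII", ARG = "VII",
  HIS = "VIII"
)

#' Residue group of an amino acid
#'
#' Maps a 3-letter residue code to its contact-typing group (I-VIII):
#' I (LVIMC), II (AG), III (ST), IV (P), V (FYW), VI (EDNQ), VII (KR),
#' VIII (H).  Modified residues in the shipped alias table (e.g. MSE) are
#' mapped to their parent amino acid first; anything else returns `NA`.
#'
#' @param res_name character vector of 3-letter residue codes.
#' @return character vector of groups, `NA` where the residue has no group.
#' @examples
#' residue_group(c("LEU", "MSE", "HIS", "UNK"))
#' @export
residue_group <- function(res_name) {
  res_name <- toupper(res_name)
  alias <- .residue_aliases[res_name]
  res_name <- ifelse(is.na(alias), res_name, alias)
  unname(.residue_group_table[res_name])
}

#' Default HET-code exclusion list
#'
#' Solvent, common ions, buffer components and cryoprotectants that must
#' never be treated as a bound small-molecule ligand, plus modified amino
#' acids that belong to the polymer.
#'
#' @return character vector of 3-letter HET codes.
#' @export
default_het_exclusions <- function() {
  c(
    # waters
    "HOH", "DOD", "WAT",
    # ions
    "NA", "K", "MG", "CA", "ZN", "CL", "MN", "FE", "FE2", "CU", "CU1",
    "NI", "CO", "CD", "HG", "BR", "IOD", "F", "CS", "LI", "SR", "BA",
    "AL", "NH4", "SO4", "PO4", "NO3", "CO3", "BCT", "SCN", "AZI",
    # cryoprotectants, buffers, additives
    "GOL", "EDO", "PEG", "PG4", "PGE", "1PE", "MPD", "DMS", "BME",
    "EOH", "MOH", "IPA", "TRS", "EPE", "MES", "FMT", "ACT", "ACY",
    "CIT", "TLA", "SIN", "URE",
    # modified amino acids (polymer side)
    names(.residue_aliases)
  )
}

.fmt_coord_ok <- function(line) {
  coords <- c(substr(line, 31, 38), substr(line, 39, 46), substr(line, 47, 54))
  !anyNA(suppressWarnings(as.numeric(coords)))
}

#' Parse PDB-format text
#'
#' Reads ATOM/HETATM records from PDB text.  Only the first MODEL is kept;
#' within each alternate-location group the highest-occupancy conformer is
#' retained (ties broken by the lowest altloc character).  Hydrogens are
#' dropped.  Residues are keyed by (chain, residue number, insertion code)
#' in author numbering.
#'
#' @param pdb_text a single string or character vector of PDB lines.
#' @return an object of class `pdb_structure`: a list with element `atoms`,
#'   a data frame with columns serial, name, element, x, y, z, occupancy,
#'   altloc, chain, resno, icode, resname, is_hetero.
#' @seealso [chain_residues()], [hetero_groups()], [extract_complexes()]
#' @export
parse_pdb <- function(pdb_text) {
  if (length(pdb_text) == 1) pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  if (length(pdb_text) == 0 || all(!nzchar(pdb_text))) {
    .stopf("empty PDB input")
  }
  # first MODEL only
  endmdl <- grep("^ENDMDL", pdb_text)
  if (length(endmdl) > 0) pdb_text <- pdb_text[seq_len(endmdl[1] - 1)]

  is_atom <- grepl("^(ATOM  |HETATM)", pdb_text)
  if (!any(is_atom)) .stopf("no ATOM/HETATM records found")
  bad <- which(is_atom & !vapply(pdb_text, .fmt_coord_ok, logical(1)))
  if (length(bad) > 0) {
    .stopf("malformed coordinate field at line %d: %s", bad[1],
           trimws(pdb_text[bad[1]]))
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(pdb_text, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  element <- toupper(trimws(at$elesy))
  # fall back to the first alphabetic character of the atom name
  miss <- is.na(element) | element == ""
  if (any(miss)) {
    element[miss] <- substr(gsub("[^A-Za-z].*$", "",
                                 gsub("^[0-9 ]*", "", at$elety[miss])), 1, 1)
  }
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    resname = trimws(at$resid),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]

  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # ties -> lowest altloc character
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname,
               atoms$name, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL

  structure(list(atoms = atoms), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  res <- chain_residues(x)
  het <- hetero_groups(x)
  cat(sprintf("pdb_structure: %d atoms, %d chain(s) [%s], %d hetero group(s)\n",
              nrow(x$atoms), length(res),
              paste(names(res), collapse = ","), length(het)))
  invisible(x)
}

#' Polymer residues per chain
#'
#' @param parsed a `pdb_structure` from [parse_pdb()].
#' @return named list (by chain id) of data frames with one row per polymer
#'   residue (chain, resno, icode, resname), in file order.
#' @export
chain_residues <- function(parsed) {
  at <- parsed$atoms
  # modified residues (MSE etc.) are deposited as HETATM but belong to the
  # polymer, hence the alias-table escape hatch
  poly <- at[(!at$is_hetero & at$resname %in% .standard_aa) |
               at$resname %in% names(.residue_aliases), , drop = FALSE]
  if (nrow(poly) == 0) return(list())
  key <- paste(poly$chain, poly$resno, poly$icode, sep = "|")
  first <- poly[!duplicated(key), c("chain", "resno", "icode", "resname")]
  split(first, first$chain)
}

#' Hetero groups (candidate ligands, solvent, ions)
#'
#' @param parsed a `pdb_structure` from [parse_pdb()].
#' @return list of data frames of atoms, one per HETATM group keyed by
#'   (chain, resno, icode, resname).
#' @export
hetero_groups <- function(parsed) {
  at <- parsed$atoms
  het <- at[at$is_hetero & !(at$resname %in% names(.residue_aliases)), ,
            drop = FALSE]
  if (nrow(het) == 0) return(list())
  key <- paste(het$chain, het$resno, het$icode, het$resname, sep = "|")
  split(het, factor(key, levels = unique(key)))
}

.residue_key <- function(chain, resno, icode) paste(chain, resno, icode, sep = "|")

.one_letter <- function(res_name) {
  alias <- .residue_aliases[res_name]
  res_name <- ifelse(is.na(alias), res_name, alias)
  out <- bio3d::aa321(res_name)
  out[is.na(out)] <- "X"
  out
}

#' Extract protein-ligand complex records
#'
#' Builds one `complex_record` per (protein chain, bound ligand) pair.
#' Chains must have between `min_len` and `max_len` polymer residues
#' (counted over residues with at least one atom, author numbering).
#' Hetero groups on the exclusion list, with fewer than `min_ligand_atoms`
#' heavy atoms, with no contact to the chain, or covalently linked to it
#' (any heavy-atom distance below `covalent_cutoff`) are not ligands.
#'
#' @param parsed a `pdb_structure` from [parse_pdb()].
#' @param pdb_id identifier recorded on each output record.
#' @param exclusion_list HET codes never treated as ligands.
#' @param min_len,max_len chain length bounds (residues).
#' @param min_ligand_atoms minimum ligand heavy-atom count.
#' @param covalent_cutoff distance (A) below which a ligand-protein atom
#'   pair is considered covalent and the ligand discarded.
#' @param contact_cutoff contact distance (A) defining binding residues.
#' @return list of `complex_record` objects (possibly empty).
#' @export
extract_complexes <- function(parsed, pdb_id = "XXXX",
                              exclusion_list = default_het_exclusions(),
                              min_len = 50, max_len = 999,
                              min_ligand_atoms = 6,
                              covalent_cutoff = 1.9,
                              contact_cutoff = 4.5) {
  chains <- chain_residues(parsed)
  hets <- hetero_groups(parsed)
  at <- parsed$atoms
  out <- list()
  for (chain_id in names(chains)) {
    res <- chains[[chain_id]]
    if (nrow(res) < min_len || nrow(res) > max_len) next
    chain_atoms <- at[at$chain == chain_id &
                        .residue_key(at$chain, at$resno, at$icode) %in%
                          .residue_key(res$chain, res$resno, res$icode), ,
                      drop = FALSE]
    for (h in hets) {
      lig_name <- h$resname[1]
      if (lig_name %in% exclusion_list) next
      if (nrow(h) < min_ligand_atoms) next
      d <- .cross_dist(h[, c("x", "y", "z")], chain_atoms[, c("x", "y", "z")])
      if (min(d) < covalent_cutoff) next   # covalently linked
      if (min(d) > contact_cutoff) next    # not bound to this chain
      rec <- structure(list(
        id = sprintf("%s_%s_%s%d", pdb_id, chain_id, lig_name, h$resno[1]),
        pdb_id = pdb_id,
        chain_id = chain_id,
        residues = res,
        chain_atoms = chain_atoms,
        sequence = paste(.one_letter(res$resname), collapse = ""),
        ligand = list(res_name = lig_name, atoms = h, parent_chain = chain_id),
        pocket_source = "ligand-derived"
      ), class = "complex_record")
      rec$contacts <- contact_profile(rec, cutoff = contact_cutoff)
      bk <- unique(rec$contacts[, c("chain", "resno", "icode", "resname")])
      rec$binding_residues <- bk[order(match(
        .residue_key(bk$chain, bk$resno, bk$icode),
        .residue_key(res$chain, res$resno, res$icode))), , drop = FALSE]
      rownames(rec$binding_residues) <- NULL
      out[[rec$id]] <- rec
    }
  }
  out
}

#' @export
print.complex_record <- function(x, ...) {
  cat(sprintf(
    "complex_record %s: chain %s (%d aa), ligand %s (%d atoms), %d binding residues, %d contacts\n",
    x$id, x$chain_id, nrow(x$residues), x$ligand$res_name,
    nrow(x$ligand$atoms), nrow(x$binding_residues), nrow(x$contacts)))
  invisible(x)
}

#' Typed ligand-protein contact profile
#'
#' One contact per (ligand heavy atom, residue) pair whose minimum
#' heavy-atom distance is at or below `cutoff`.  Each contact is typed by
#' the residue group (I-VIII); residues without a group (non-standard,
#' unaliased) are skipped with a message.
#'
#' @param record a `complex_record`.
#' @param cutoff contact distance in Angstrom.
#' @param verbose message skipped residues.
#' @return data frame: ligand_atom (index), ligand_atom_name, chain, resno,
#'   icode, resname, group, distance.
#' @export
contact_profile <- function(record, cutoff = 4.5, verbose = FALSE) {
  lig <- record$ligand$atoms
  if (is.null(lig) || nrow(lig) == 0) .stopf("empty ligand")
  ca <- record$chain_atoms
  d <- .cross_dist(lig[, c("x", "y", "z")], ca[, c("x", "y", "z")])
  rkey <- .residue_key(ca$chain, ca$resno, ca$icode)
  ukeys <- unique(rkey)
  rows <- list()
  skipped <- character(0)
  for (k in ukeys) {
    idx <- which(rkey == k)
    resname <- ca$resname[idx[1]]
    grp <- residue_group(resname)
    dmin <- apply(d[, idx, drop = FALSE], 1, min)
    hit <- which(dmin <= cutoff)
    if (length(hit) == 0) next
    if (is.na(grp)) {
      skipped <- c(skipped, resname)
      next
    }
    rows[[k]] <- data.frame(
      ligand_atom = hit,
      ligand_atom_name = lig$name[hit],
      chain = ca$chain[idx[1]],
      resno = ca$resno[idx[1]],
      icode = ca$icode[idx[1]],
      resname = resname,
      group = grp,
      distance = dmin[hit],
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped) > 0) {
    .msgf(verbose, "skipped %d contact residue(s) without a group: %s",
          length(skipped), paste(unique(skipped), collapse = ","))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ligand_atom = integer(0), ligand_atom_name = character(0),
                      chain = character(0), resno = integer(0),
                      icode = character(0), resname = character(0),
                      group = character(0), distance = numeric(0))
  }
  rownames(out) <- NULL
  out
}

.fmt_atom_name <- function(name, element) {
  # PDB columns 13-16: element-aligned for 1-letter elements
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         ifelse(nchar(element) == 1, sprintf(" %-3s", name), sprintf("%-4s", name)))
}

.pdb_atom_line <- function(type, serial, name, resname, chain, resno, icode,
                           x, y, z, occ = 1, element = "") {
  sprintf("%-6s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, .fmt_atom_name(name, element), resname, chain, resno,
          ifelse(nzchar(icode), icode, " "), x, y, z, occ, 0, element)
}

#' Write a pocket-only PDB file
#'
#' Emits ATOM records for the binding residues and HETATM records for the
#' ligand of a complex record; residue identifiers (chain, author residue
#' number, insertion code) are preserved so re-parsing round-trips exactly.
#'
#' @param record a `complex_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(record, path) {
  ca <- record$chain_atoms
  bkey <- .residue_key(record$binding_residues$chain,
                       record$binding_residues$resno,
                       record$binding_residues$icode)
  sel <- ca[.residue_key(ca$chain, ca$resno, ca$icode) %in% bkey, , drop = FALSE]
  lines <- character(0)
  serial <- 0
  for (i in seq_len(nrow(sel))) {
    serial <- serial + 1
    lines <- c(lines, .pdb_atom_line("ATOM", serial, sel$name[i], sel$resname[i],
                                     sel$chain[i], sel$resno[i], sel$icode[i],
                                     sel$x[i], sel$y[i], sel$z[i],
                                     element = sel$element[i]))
  }
  lig <- record$ligand$atoms
  for (i in seq_len(nrow(lig))) {
    serial <- serial + 1
    lines <- c(lines, .pdb_atom_line("HETATM", serial, lig$name[i], lig$resname[i],
                                     lig$chain[i], lig$resno[i], lig$icode[i],
                                     lig$x[i], lig$y[i], lig$z[i],
                                     element = lig$element[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a contact profile as TSV
#'
#' @param contacts data frame from [contact_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(contacts, path) {
  out <- data.frame(
    ligand_atom_name = contacts$ligand_atom_name,
    chain = contacts$chain,
    seq_num = contacts$resno,
    icode = contacts$icode,
    res_name = contacts$resname,
    group = contacts$group,
    distance = round(contacts$distance, 3)
  )
  write_tsv(out, path)
}
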