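#' @title PDB input/output restricted to what moment calculations need
#' @name structure_io
#' @description
#' Reading is deliberately minimal: alpha-carbon traces of protein chains
#' (side chains ignored), all heavy atoms when contact counting requires
#' them, and ribonucleotide chain detection. Only the first MODEL of an
#' entry is used; HETATM records (waters, metals, ligands) are always
#' excluded. Writing produces minimal single-atom-per-residue PDB files
#' for synthetic fixtures.
NULL

RIBONUCLEOTIDES   <- c("A", "C", "G", "U", "I")
DEOXYNUCLEOTIDES  <- c("DA", "DC", "DG", "DT", "DI", "T")
NUCLEOTIDE_NAMES  <- c(RIBONUCLEOTIDES, DEOXYNUCLEOTIDES)

# Read PDB source into lines. Accepts a file path, a single string with
# newlines, a character vector of lines, or a connection.
pdb_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (!is.character(source)) {
    stop_rbp("PDB source must be a file path, text, or connection",
             "rbp_parse_error")
  }
  if (length(source) == 1L && !grepl("\n", source, fixed = TRUE)) {
    if (!file.exists(source)) {
      stop_rbp(sprintf("PDB file not found: %s", source),
               "rbp_missing_file_error")
    }
    return(readLines(source, warn = FALSE))
  }
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

pdb_source_name <- function(source) {
  if (is.character(source) && length(source) == 1L &&
      !grepl("\n", source, fixed = TRUE) && file.exists(source)) {
    sub("\\.(pdb|ent)$", "", basename(source), ignore.case = TRUE)
  } else {
    "structure"
  }
}

# Fixed-column parse of ATOM records in the first MODEL.
# Columns (1-based, inclusive): record 1-6, serial 7-11, name 13-16,
# altloc 17, resname 18-20, chain 22, resseq 23-26, icode 27,
# x 31-38, y 39-46, z 47-54, occupancy 55-60, element 77-78.
parse_pdb_atoms <- function(source, include_hetatm = FALSE) {
  lines <- pdb_lines(source)
  end <- grep("^ENDMDL", lines)
  if (length(end)) lines_use <- lines[seq_len(end[1] - 1L)] else lines_use <- lines
  rec <- substr(lines_use, 1, 6)
  keep <- rec == "ATOM  " | (include_hetatm & rec == "HETATM")
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(record = character(), name = character(),
                      altloc = character(), resname = character(),
                      chain = character(), resseq = integer(),
                      icode = character(), x = double(), y = double(),
                      z = double(), occ = double(), element = character(),
                      line = integer(), stringsAsFactors = FALSE))
  }
  ln <- lines_use[idx]
  num_field <- function(str, lo, hi, what) {
    raw <- substr(str, lo, hi)
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & trimws(raw) != ""
    bad <- bad | is.na(val)
    if (any(bad)) {
      stop_rbp(sprintf("malformed %s field at line %d: '%s'",
                       what, idx[which(bad)[1]], raw[which(bad)[1]]),
               "rbp_parse_error")
    }
    val
  }
  occ_raw <- trimws(substr(ln, 55, 60))
  occ <- suppressWarnings(as.numeric(occ_raw))
  occ[is.na(occ)] <- 1.0
  data.frame(
    record  = trimws(rec[idx]),
    name    = trimws(substr(ln, 13, 16)),
    altloc  = substr(ln, 17, 17),
    resname = trimws(substr(ln, 18, 20)),
    chain   = substr(ln, 22, 22),
    resseq  = as.integer(num_field(ln, 23, 26, "residue number")),
    icode   = substr(ln, 27, 27),
    x       = num_field(ln, 31, 38, "x coordinate"),
    y       = num_field(ln, 39, 46, "y coordinate"),
    z       = num_field(ln, 47, 54, "z coordinate"),
    occ     = occ,
    element = trimws(substr(ln, 77, 78)),
    line    = idx,
    stringsAsFactors = FALSE
  )
}

residue_key <- function(atoms) paste(atoms$chain, atoms$resseq, atoms$icode, sep = "\r")

#' Read alpha-carbon traces of protein chains from a PDB file
#'
#' Parses ATOM records of the first MODEL only, drops HETATM (waters,
#' metals, ligands), nucleic-acid residues and side-chain atoms, and
#' returns one ordered Calpha record per amino-acid residue. Alternate
#' locations keep the highest-occupancy copy (ties: first in file order).
#' Residues lacking a Calpha are skipped and counted in a warning.
#'
#' @param source Path to a PDB file, PDB text, or a connection.
#' @param chains Optional character vector of chain identifiers to keep.
#' @param residue_range Optional inclusive author-number interval
#'   `c(start, end)`; only valid together with a single-chain `chains`.
#'   Compared on author residue numbers, ignoring insertion codes.
#' @return A list of `chain_structure` objects, one per selected protein
#'   chain in file order. Each is a data frame with columns `chain`,
#'   `resseq`, `icode`, `resname`, `x`, `y`, `z` and attributes
#'   `source_id` (e.g. `"1jo0_A"`) and `n_missing_ca`.
#' @examples
#' pdb <- write_minimal_pdb(list(A = data.frame(
#'   resname = c("LYS", "GLU", "GLY"),
#'   x = c(0, 4, 8), y = 0, z = 0)))
#' read_pdb_calpha(pdb)[[1]]
#' @export
read_pdb_calpha <- function(source, chains = NULL, residue_range = NULL) {
  if (!is.null(residue_range)) {
    if (is.null(chains) || length(chains) != 1L) {
      stop_rbp("residue_range requires selecting exactly one chain",
               "rbp_parse_error")
    }
    stopifnot(length(residue_range) == 2L, residue_range[1] <= residue_range[2])
  }
  atoms <- parse_pdb_atoms(source, include_hetatm = FALSE)
  if (!nrow(atoms)) stop_rbp("no ATOM records found", "rbp_parse_error")
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  if (!is.null(residue_range)) {
    atoms <- atoms[atoms$resseq >= residue_range[1] &
                   atoms$resseq <= residue_range[2], , drop = FALSE]
  }
  # amino-acid residues: polymer ATOM residues that are not nucleotides
  atoms <- atoms[!(atoms$resname %in% NUCLEOTIDE_NAMES), , drop = FALSE]
  if (!nrow(atoms)) {
    stop_rbp("no protein residues in selection", "rbp_parse_error")
  }
  key <- residue_key(atoms)
  res_first <- !duplicated(key)
  res_keys <- key[res_first]
  ca <- atoms[atoms$name == "CA", , drop = FALSE]
  # altloc policy: highest occupancy, tie broken by file order
  if (nrow(ca)) {
    ord <- order(residue_key(ca), -ca$occ, ca$line)
    ca <- ca[ord, , drop = FALSE]
    ca <- ca[!duplicated(residue_key(ca)), , drop = FALSE]
    ca <- ca[order(ca$line), , drop = FALSE]
  }
  ca_keys <- residue_key(ca)
  missing_total <- sum(!(res_keys %in% ca_keys))
  if (missing_total > 0) {
    warning(sprintf("%d residue(s) lacking a C-alpha atom were skipped",
                    missing_total), call. = FALSE)
  }
  src <- pdb_source_name(source)
  out <- list()
  for (ch in unique(ca$chain)) {
    cc <- ca[ca$chain == ch, , drop = FALSE]
    st <- data.frame(chain = cc$chain, resseq = cc$resseq, icode = cc$icode,
                     resname = cc$resname, x = cc$x, y = cc$y, z = cc$z,
                     stringsAsFactors = FALSE)
    miss_ch <- sum(startsWith(res_keys, paste0(ch, "\r")) &
                   !(res_keys %in% ca_keys))
    attr(st, "source_id") <- paste0(src, "_", ch)
    attr(st, "n_missing_ca") <- miss_ch
    class(st) <- c("chain_structure", "data.frame")
    out[[ch]] <- st
  }
  if (!length(out)) {
    stop_rbp("no protein residues with C-alpha atoms in selection",
             "rbp_parse_error")
  }
  out
}

#' Detect RNA chains in a PDB file
#'
#' A chain is labelled RNA when more than half of its polymer (ATOM)
#' residues carry single-letter ribonucleotide names (A, C, G, U, I).
#' Deoxyribonucleotide names (DA, DC, DG, DT) never count as RNA.
#'
#' @inheritParams read_pdb_calpha
#' @return Character vector of RNA chain identifiers (possibly empty).
#' @export
detect_rna_chains <- function(source) {
  atoms <- parse_pdb_atoms(source, include_hetatm = FALSE)
  if (!nrow(atoms)) return(character())
  res <- atoms[!duplicated(residue_key(atoms)), , drop = FALSE]
  out <- character()
  for (ch in unique(res$chain)) {
    rn <- res$resname[res$chain == ch]
    if (mean(rn %in% RIBONUCLEOTIDES) > 0.5) out <- c(out, ch)
  }
  out
}

#' Read all heavy atoms of a PDB file, grouped for contact counting
#'
#' Returns every non-hydrogen ATOM-record atom of the first MODEL with
#' its residue identity, as required by [count_contact_residues()].
#'
#' @inheritParams read_pdb_calpha
#' @return Data frame with columns `chain`, `resseq`, `icode`, `resname`,
#'   `name`, `x`, `y`, `z`.
#' @export
read_pdb_heavy_atoms <- function(source, chains = NULL) {
  atoms <- parse_pdb_atoms(source, include_hetatm = FALSE)
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  is_h <- atoms$element %in% c("H", "D") |
    (atoms$element == "" & grepl("^[0-9]*H", atoms$name))
  atoms <- atoms[!is_h, , drop = FALSE]
  atoms[, c("chain", "resseq", "icode", "resname", "name", "x", "y", "z")]
}

#' Count protein residues in contact with RNA
#'
#' A protein residue is in contact when any of its heavy atoms lies
#' within `cutoff` of any RNA heavy atom; each residue is counted at
#' most once. The selection rule used for complex curation keeps
#' proteins with at least 3 such residues.
#'
#' @param protein_atoms Heavy atoms of one protein chain, as returned by
#'   [read_pdb_heavy_atoms()] (needs `resseq`, `icode`, `x`, `y`, `z`).
#' @param rna_atoms Heavy atoms of all RNA chains (needs `x`, `y`, `z`).
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @return Integer count of contacting protein residues.
#' @export
count_contact_residues <- function(protein_atoms, rna_atoms, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  if (is.null(protein_atoms) || !NROW(protein_atoms)) {
    stop_rbp("no protein heavy atoms: read the structure with read_pdb_heavy_atoms()",
             "rbp_parse_error")
  }
  if (is.null(rna_atoms) || !NROW(rna_atoms)) {
    stop_rbp("no RNA heavy atoms: read the structure with read_pdb_heavy_atoms()",
             "rbp_parse_error")
  }
  p <- as.matrix(protein_atoms[, c("x", "y", "z")])
  r <- as.matrix(rna_atoms[, c("x", "y", "z")])
  # squared-distance matrix via the expansion |p-r|^2 = |p|^2 + |r|^2 - 2 p.r
  d2 <- outer(rowSums(p^2), rowSums(r^2), "+") - 2 * tcrossprod(p, r)
  hit <- apply(d2 <= cutoff^2 + 1e-12, 1L, any)
  length(unique(residue_key(protein_atoms)[hit]))
}

#' Write a minimal Calpha-only PDB file
#'
#' Emits one `ATOM` record (atom name `CA`) per residue with fixed PDB
#' columns, a `TER` after each chain and a final `END`. Output
#' round-trips through [read_pdb_calpha()] to 1e-3 Angstrom (the PDB
#' column precision).
#'
#' @param chains Named (or unnamed, then chains are `A`, `B`, ...) list;
#'   each element a data frame with columns `resname`, `x`, `y`, `z`.
#' @param path Optional file path; when given, the text is also written
#'   there.
#' @return PDB text as a single string (invisibly when `path` is given).
#' @export
write_minimal_pdb <- function(chains, path = NULL) {
  if (!is.list(chains) || !length(chains)) {
    stop_rbp("chains must be a non-empty list", "rbp_parse_error")
  }
  ids <- names(chains)
  if (is.null(ids) || any(ids == "")) ids <- LETTERS[seq_along(chains)]
  serial <- 0L
  lines <- character()
  for (k in seq_along(chains)) {
    ch <- as.data.frame(chains[[k]])
    if (!nrow(ch)) stop_rbp("empty chain in write_minimal_pdb", "rbp_parse_error")
    xyz <- as.matrix(ch[, c("x", "y", "z")])
    if (any(!is.finite(xyz))) {
      stop_rbp("non-finite coordinate in write_minimal_pdb", "rbp_parse_error")
    }
    if (any(xyz > 9999.999) || any(xyz < -999.999)) {
      stop_rbp("coordinate exceeds PDB fixed-column width (%8.3f)",
               "rbp_parse_error")
    }
    for (i in seq_len(nrow(ch))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, substr(ch$resname[i], 1, 3), ids[k], i,
        xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, 0.0))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %s%4d",
                              serial, substr(ch$resname[nrow(ch)], 1, 3),
                              ids[k], nrow(ch)))
  }
  txt <- paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
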