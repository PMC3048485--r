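#' Unit-charge scheme for residues
#'
#' The low-resolution charge model places one point charge per residue
#' at its Calpha: Lys and Arg +1, Asp and Glu -1, everything else 0.
#' Histidine is neutral by default; `mode = "his_positive"` is the other
#' protonation extreme (all His +1) used to check sensitivity to the
#' His protonation state.
#'
#' @param mode `"his_neutral"` (default) or `"his_positive"`.
#' @param table Optional named numeric vector overriding the charge
#'   table entirely (residue name -> charge in elementary-charge units).
#' @return A `charge_scheme` object.
#' @export
charge_scheme <- function(mode = c("his_neutral", "his_positive"), table = NULL) {
  mode <- match.arg(mode)
  if (is.null(table)) {
    table <- c(LYS = 1, ARG = 1, ASP = -1, GLU = -1)
    if (mode == "his_positive") table <- c(table, HIS = 1)
  } else {
    stopifnot(is.numeric(table), !is.null(names(table)))
  }
  structure(list(mode = mode, table = table), class = "charge_scheme")
}

#' Read a custom charge table from a two-column TSV
#'
#' Columns: residue name (3-letter), charge in elementary-charge units.
#' No header expected.
#'
#' @param path TSV file path.
#' @return Named numeric vector usable as the `table` of [charge_scheme()].
#' @export
read_charge_table <- function(path) {
  if (!file.exists(path)) {
    stop_rbp(sprintf("charge table not found: %s", path),
             "rbp_missing_file_error")
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("resname", "charge"))
  stats::setNames(as.numeric(df$charge), toupper(df$resname))
}

#' Assign point charges to a chain structure
#'
#' Every residue with a Calpha contributes one point (possibly zero
#' charge); the residue count N used for normalisation is the number of
#' points. Residue names absent from the scheme table get charge 0; the
#' distinct unknown names are recorded in the `unknown_residues`
#' attribute.
#'
#' @param chain A `chain_structure` from [read_pdb_calpha()].
#' @param scheme A [charge_scheme()].
#' @return A `charged_point_set`: list with `xyz` (N x 3 matrix,
#'   Angstrom), `charge` (length N, elementary charges), `n_residues`,
#'   `source_id`.
#' @export
assign_charges <- function(chain, scheme = charge_scheme()) {
  stopifnot(inherits(scheme, "charge_scheme"))
  ch <- as.data.frame(chain)
  if (!nrow(ch)) stop_rbp("empty chain", "rbp_parse_error")
  q <- unname(scheme$table[ch$resname])
  q[is.na(q)] <- 0
  standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")
  unknown <- setdiff(unique(ch$resname), c(names(scheme$table), standard_aa))
  if (length(unknown) && isTRUE(getOption("rbpmoments.verbose", FALSE))) {
    message("residues treated as neutral (not in charge table): ",
            paste(unknown, collapse = ", "))
  }
  structure(list(
    xyz = unname(as.matrix(ch[, c("x", "y", "z")])),
    charge = q,
    n_residues = nrow(ch),
    source_id = attr(chain, "source_id", exact = TRUE) %||% "points",
    unknown_residues = unknown
  ), class = "charged_point_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a charged_point_set directly from coordinates and charges
# (used by the synthetic-fixture generator and tests).
charged_point_set <- function(xyz, charge, source_id = "points") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(nrow(xyz) >= 1, length(charge) == nrow(xyz), all(is.finite(xyz)))
  structure(list(xyz = xyz, charge = as.numeric(charge),
                 n_residues = nrow(xyz), source_id = source_id,
                 unknown_residues = character()),
            class = "charged_point_set")
}

#' Net charge per residue
#'
#' Signed total charge divided by the residue count N. Reported signed
#' (control proteins average slightly negative), unlike the dipole and
#' quadrupole magnitudes which are reported as absolute values.
#'
#' @param cps A `charged_point_set` from [assign_charges()].
#' @return Signed scalar, elementary charges per residue.
#' @export
net_charge_per_residue <- function(cps) {
  stopifnot(inherits(cps, "charged_point_set"), cps$n_residues >= 1)
  sum(cps$charge) / cps$n_residues
}
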