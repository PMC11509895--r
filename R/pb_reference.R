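## The 16 Protein Blocks and their reference dihedral windows.

the <- new.env(parent = emptyenv())

#' Protein Block labels
#'
#' The 16 Protein Blocks of the structural alphabet, labelled `a` to `p`.
#' `m` and `d` are the prototypes of the alpha-helix core and the central
#' beta-strand; `a`-`c` are mostly strand N-caps, `e`-`f` strand C-caps,
#' `k`-`l` helix N-caps and `n`-`p` helix C-caps.
#'
#' @return Character vector of the 16 labels in alphabetical order.
#' @export
pb_labels <- function() letters[1:16]

#' Symbol used for unassignable positions
#'
#' Positions whose 8-angle window contains an undefined dihedral (the two
#' residues at each chain end, chain breaks, missing backbone atoms) carry
#' this symbol instead of a Protein Block.
#'
#' @return The character `"Z"`.
#' @export
pb_unassigned <- function() "Z"

#' Protein Blocks reference angle table
#'
#' The canonical 16 x 8 table of reference dihedral angles defining the
#' Protein Blocks structural alphabet.  Each block is described by the
#' window (psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1),
#' psi(i+1), phi(i+2)) over five consecutive residues, centred on residue
#' i; all angles in degrees.  The table ships as versioned plain-text
#' package data and is guarded by a checksum test.
#'
#' @return A tibble with columns `label`, `psi_m2`, `phi_m1`, `psi_m1`,
#'   `phi_0`, `psi_0`, `phi_p1`, `psi_p1`, `phi_p2`.
#' @examples
#' pb_reference()
#' @export
pb_reference <- function() {
  if (is.null(the$pb_reference)) {
    path <- system.file("extdata", "pb_reference_angles.csv",
                        package = "pbflex", mustWork = TRUE)
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot(identical(tab$label, pb_labels()), ncol(tab) == 9L)
    the$pb_reference <- tab
  }
  the$pb_reference
}

## Reference angles as a plain 16 x 8 matrix, rows named a..p.
pb_reference_matrix <- function(table = pb_reference()) {
  m <- as.matrix(table[, -1])
  rownames(m) <- table$label
  m
}

#' Flexibility interpretation band for an Neq value
#'
#' Descriptive labels for per-position Neq values as used when reading
#' flexibility profiles: 1 means total rigidity, around 4 flexible, around
#' 6 highly flexible, and 8 or more a disordered region.  The bands are
#' labels for interpretation, not statistical thresholds.
#'
#' @param neq Numeric vector of Neq values in `[1, 16]`.
#' @return Character vector: `"rigid"` (< 4), `"flexible"` (4 to < 6),
#'   `"highly flexible"` (6 to < 8) or `"disordered"` (>= 8); `NA` stays
#'   `NA`.
#' @export
neq_band <- function(neq) {
  cut(neq,
      breaks = c(-Inf, 4, 6, 8, Inf),
      labels = c("rigid", "flexible", "highly flexible", "disordered"),
      right = FALSE) |> as.character()
}
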