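## Backbone torsion geometry.

#' Torsion (dihedral) angle of four points
#'
#' Signed dihedral about the p2-p3 axis in the usual convention for
#' backbone phi/psi (positive clockwise looking from p2 towards p3).
#' Vectorized: the four arguments may be n x 3 matrices.
#'
#' @param p1,p2,p3,p4 Length-3 vectors or n x 3 matrices of coordinates
#'   in Angstrom.
#' @return Angle(s) in degrees in `(-180, 180]`; `NA` where a triple of
#'   consecutive points is (near-)collinear or any coordinate is missing.
#' @examples
#' torsion_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))  # 180
#' torsion_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))  # 0
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  as_mat <- function(p) if (is.null(dim(p))) matrix(p, ncol = 3) else p
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3); p4 <- as_mat(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  b2n <- row_norm(b2)
  m1 <- cross3(n1, b2 / b2n)
  x <- row_dot(n1, n2)
  y <- row_dot(m1, n2)
  ang <- wrap_angle(-atan2(y, x) * 180 / pi)
  degenerate <- row_norm(n1) < 1e-9 | row_norm(n2) < 1e-9 | b2n < 1e-9
  ang[degenerate] <- NA_real_
  drop(ang)
}

#' Extract backbone phi/psi dihedrals from an ensemble
#'
#' phi(i) is the torsion C(i-1)-N(i)-CA(i)-C(i) and psi(i) the torsion
#' N(i)-CA(i)-C(i)-N(i+1).  phi is undefined at the first residue and psi
#' at the last.  A CA(i)-CA(i+1) distance above `break_threshold` is
#' treated as a chain break: the dihedrals spanning that peptide bond
#' (psi(i) and phi(i+1)) become undefined.  Missing backbone atoms make
#' the affected dihedrals undefined and are reported once.
#'
#' @param ensemble A [conf_ensemble()].
#' @param break_threshold CA-CA distance (Angstrom) above which two
#'   consecutive residues are considered disconnected; the default 4.5 is
#'   a generous bound on peptide-bond geometry.
#' @return A `dihedral_series`: list with `phi` and `psi` (F x R matrices,
#'   degrees, `NA` = undefined) and `resno`.
#' @export
extract_phi_psi <- function(ensemble, break_threshold = 4.5) {
  res <- residues(ensemble)
  R <- nrow(res)
  F_ <- n_frames(ensemble)
  N <- atom_coords(ensemble, "N")
  CA <- atom_coords(ensemble, "CA")
  C <- atom_coords(ensemble, "C")
  if (anyNA(N[, 1, 1]) || anyNA(CA[, 1, 1]) || anyNA(C[, 1, 1])) {
    missing <- res$resno[is.na(N[, 1, 1]) | is.na(CA[, 1, 1]) | is.na(C[, 1, 1])]
    inform(sprintf(
      "backbone atoms missing at position(s) %s; affected dihedrals undefined",
      paste(missing, collapse = ", ")))
  }
  phi <- matrix(NA_real_, F_, R)
  psi <- matrix(NA_real_, F_, R)
  for (f in seq_len(F_)) {
    n <- N[, , f]; ca <- CA[, , f]; cc <- C[, , f]
    if (R > 1) {
      brk <- row_norm(ca[-1, , drop = FALSE] - ca[-R, , drop = FALSE]) >
        break_threshold
      brk[is.na(brk)] <- TRUE
      ## phi(i), i = 2..R: C(i-1) N(i) CA(i) C(i)
      phi[f, -1] <- torsion_angle(cc[-R, , drop = FALSE], n[-1, , drop = FALSE],
                                  ca[-1, , drop = FALSE], cc[-1, , drop = FALSE])
      phi[f, -1][brk] <- NA_real_
      ## psi(i), i = 1..R-1: N(i) CA(i) C(i) N(i+1)
      psi[f, -R] <- torsion_angle(n[-R, , drop = FALSE], ca[-R, , drop = FALSE],
                                  cc[-R, , drop = FALSE], n[-1, , drop = FALSE])
      psi[f, -R][brk] <- NA_real_
    }
  }
  dihedral_series(phi, psi, resno = res$resno,
                  system_label = ensemble$system_label)
}

#' Construct a dihedral series
#'
#' Container for per-frame, per-residue backbone phi/psi angles in
#' degrees, wrapped into `(-180, 180]`; `NA` marks undefined angles.  By
#' construction phi is undefined at the first residue and psi at the
#' last; these are enforced.
#'
#' @param phi,psi F x R numeric matrices (degrees).
#' @param resno Author sequence numbers, length R.
#' @param system_label Label carried into downstream profiles.
#' @param labels Optional F x R character matrix of generating conformer
#'   labels (attached by the synthetic generator for recovery tests).
#' @return An object of class `dihedral_series`.
#' @export
dihedral_series <- function(phi, psi, resno = seq_len(ncol(phi)),
                            system_label = "system", labels = NULL) {
  stopifnot(is.matrix(phi), is.matrix(psi), all(dim(phi) == dim(psi)),
            length(resno) == ncol(phi))
  phi[] <- wrap_angle(phi)
  psi[] <- wrap_angle(psi)
  phi[, 1] <- NA_real_
  psi[, ncol(psi)] <- NA_real_
  structure(
    list(phi = phi, psi = psi, resno = as.integer(resno),
         system_label = system_label, labels = labels),
    class = "dihedral_series"
  )
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("<dihedral_series> '%s': %d frame(s) x %d residue(s)\n",
              x$system_label, nrow(x$phi), ncol(x$phi)))
  invisible(x)
}

#' @export
tidy.dihedral_series <- function(x, ...) {
  F_ <- nrow(x$phi); R <- ncol(x$phi)
  tibble::tibble(
    frame = rep(seq_len(F_), times = R),
    position = rep(x$resno, each = F_),
    phi = as.vector(x$phi),
    psi = as.vector(x$psi)
  )
}
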