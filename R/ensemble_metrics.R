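## Coordinate-space flexibility: Kabsch superposition, RMSD, RMSF.
## All fits and measures use C-alpha atoms only, unweighted.

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping `mobile` onto
#' `target` in the least-squares sense (SVD of the cross-covariance;
#' reflections are excluded by forcing determinant +1).
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3, same n.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length
#'   3) and `rmsd` (Angstrom).  Row-vector convention: the superposed
#'   mobile set is `mobile %*% rotation + translation` (translation
#'   recycled per row).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L) {
    abort("mobile and target must be n x 3 matrices of equal size")
  }
  n <- nrow(mobile)
  if (n < 3L) abort("superposition needs at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  X <- sweep(mobile, 2, cm); Y <- sweep(target, 2, ct)
  H <- crossprod(X, Y)
  s <- svd(H)
  if (min(s$d) < 1e-12 && sum(s$d > 1e-12) < 2) {
    abort("degenerate (rank-deficient) point set; cannot superpose")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)  # x' = x R (row vectors)
  fitted <- X %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(rotation = R, translation = ct - drop(cm %*% R), rmsd = rmsd)
}

## C-alpha coordinate array (R x 3 x F) with a check that all CA exist.
ca_array <- function(ensemble) {
  ca <- atom_coords(ensemble, "CA")
  if (anyNA(ca[, 1, 1])) {
    abort(sprintf("missing CA atoms at position(s) %s",
                  paste(residues(ensemble)$resno[is.na(ca[, 1, 1])],
                        collapse = ", ")))
  }
  ca
}

#' Per-frame RMSD against a reference frame
#'
#' Each frame is superposed onto the reference frame by [kabsch_superpose()]
#' on C-alpha atoms, and the post-fit root-mean-square deviation is
#' reported.  The reference defaults to the first saved frame.
#'
#' @param ensemble A [conf_ensemble()].
#' @param reference Reference frame index (default 1).
#' @return Tibble `frame`, `time_ps` (NA unless the ensemble records a
#'   frame spacing), `rmsd` (Angstrom); the value at the reference frame
#'   is 0.
#' @export
rmsd_series <- function(ensemble, reference = 1L) {
  F_ <- n_frames(ensemble)
  if (reference < 1 || reference > F_) {
    abort(sprintf("reference frame %d outside 1..%d", reference, F_))
  }
  ca <- ca_array(ensemble)
  ref <- ca[, , reference]
  rmsd <- vapply(seq_len(F_), function(f)
    kabsch_superpose(ca[, , f], ref)$rmsd, numeric(1))
  rmsd[reference] <- 0
  sp <- ensemble$frame_spacing
  tibble::tibble(
    frame = seq_len(F_),
    time_ps = if (is.na(sp)) NA_real_ else (seq_len(F_) - 1) * sp,
    rmsd = rmsd
  )
}

## Superpose every frame's CA set onto `ref` (R x 3); returns R x 3 x F.
fit_all_frames <- function(ca, ref) {
  out <- ca
  for (f in seq_len(dim(ca)[3])) {
    k <- kabsch_superpose(ca[, , f], ref)
    out[, , f] <- ca[, , f] %*% k$rotation +
      matrix(k$translation, nrow(ref), 3, byrow = TRUE)
  }
  out
}

#' Per-residue RMSF about the mean structure
#'
#' Root-mean-square fluctuation of each C-alpha about its average
#' position.  The average structure is refined iteratively: frames are
#' superposed onto the first frame, a mean structure is computed, all
#' frames are re-superposed onto that mean and the mean recomputed (two
#' passes), then `RMSF(i) = sqrt(mean_t |r_i(t) - <r_i>|^2)`.
#'
#' @param ensemble A [conf_ensemble()] with at least 2 frames.
#' @param passes Number of mean-structure refinement passes (default 2).
#' @return Tibble `position`, `rmsf` (Angstrom).
#' @export
rmsf <- function(ensemble, passes = 2L) {
  if (n_frames(ensemble) < 2L) abort("RMSF needs at least 2 frames")
  ca <- ca_array(ensemble)
  ref <- ca[, , 1]
  fitted <- ca
  for (p in seq_len(passes)) {
    fitted <- fit_all_frames(ca, ref)
    ref <- apply(fitted, c(1, 2), mean)
  }
  dev2 <- apply(fitted, 3, function(x) rowSums((x - ref)^2))  # R x F
  tibble::tibble(
    position = residues(ensemble)$resno,
    rmsf = sqrt(rowMeans(dev2))
  )
}
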