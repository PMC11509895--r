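## ConformationalEnsemble: frames x residues x atoms coordinate container.
##
## Internal representation: an atom table (one row per atom, residues in
## author-numbering order) plus a coordinate array of dim (n_atoms, 3,
## n_frames) in Angstrom.  The long-tibble view is available via tidy().

#' Construct a conformational ensemble
#'
#' Low-level constructor for the per-frame, per-residue coordinate
#' container used throughout the package.  Most users obtain ensembles
#' from [read_multimodel_pdb()] or from the synthetic generators
#' ([build_ideal_conformation()], [perturb_coordinates()]).
#'
#' @param atoms Tibble with one row per atom and columns `resno` (author
#'   sequence number, integer), `resname` (3-letter code), `elety` (atom
#'   name, e.g. `"CA"`).  Residues must appear as contiguous blocks.
#' @param xyz Numeric array of dim `(n_atoms, 3, n_frames)`, coordinates
#'   in Angstrom; all values finite.
#' @param system_label Character label for the system (e.g. `"WT"`).
#' @param frame_spacing Time between consecutive frames in picoseconds
#'   (metadata only), or `NA`.
#' @return An object of class `conf_ensemble`.
#' @export
conf_ensemble <- function(atoms, xyz, system_label = "system",
                          frame_spacing = NA_real_) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("resno", "resname", "elety") %in% names(atoms)))
  if (length(dim(xyz)) == 2L) dim(xyz) <- c(dim(xyz), 1L)
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[1] == nrow(atoms),
            dim(xyz)[2] == 3L)
  if (!all(is.finite(xyz))) abort("ensemble coordinates must all be finite")
  atoms$resno <- as.integer(atoms$resno)
  ## residues must be contiguous blocks in author order
  blocks <- rle(atoms$resno)$values
  if (anyDuplicated(blocks)) {
    abort("atom table interleaves residues; atoms of one residue must be contiguous")
  }
  structure(
    list(atoms = atoms, xyz = xyz,
         system_label = system_label,
         frame_spacing = frame_spacing),
    class = "conf_ensemble"
  )
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conf_ensemble> '%s': %d frame(s), %d residue(s), %d atoms/frame\n",
    x$system_label, n_frames(x), n_residues(x), nrow(x$atoms)))
  if (!is.na(x$frame_spacing)) {
    cat(sprintf("  frame spacing: %g ps\n", x$frame_spacing))
  }
  invisible(x)
}

#' Number of frames / residues in an ensemble
#'
#' @param ensemble A `conf_ensemble`.
#' @return Integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$xyz)[3]

#' @rdname n_frames
#' @export
n_residues <- function(ensemble) length(unique(ensemble$atoms$resno))

#' Residue table of an ensemble
#'
#' @param ensemble A `conf_ensemble`.
#' @return Tibble with one row per residue: `resno`, `resname`.
#' @export
residues <- function(ensemble) {
  dplyr::distinct(ensemble$atoms, .data$resno, .data$resname)
}

## Row indices of one atom type per residue (NA where absent), in residue
## order.  Used for backbone/CA lookups.
atom_indices <- function(ensemble, elety) {
  res <- residues(ensemble)$resno
  idx <- match(paste(res, elety), paste(ensemble$atoms$resno, ensemble$atoms$elety))
  idx
}

## n_res x 3 x F array of one atom type (rows NA where the atom is absent).
atom_coords <- function(ensemble, elety = "CA") {
  idx <- atom_indices(ensemble, elety)
  out <- ensemble$xyz[ifelse(is.na(idx), 1L, idx), , , drop = FALSE]
  if (anyNA(idx)) out[is.na(idx), , ] <- NA_real_
  out
}

#' @export
tidy.conf_ensemble <- function(x, ...) {
  nf <- n_frames(x)
  na <- nrow(x$atoms)
  tibble::tibble(
    frame = rep(seq_len(nf), each = na),
    resno = rep(x$atoms$resno, times = nf),
    resname = rep(x$atoms$resname, times = nf),
    elety = rep(x$atoms$elety, times = nf),
    x = as.vector(x$xyz[, 1, ]),
    y = as.vector(x$xyz[, 2, ]),
    z = as.vector(x$xyz[, 3, ])
  )
}

#' Restrict an ensemble to a subset of frames
#'
#' @param ensemble A `conf_ensemble`.
#' @param frames Integer vector of frame indices to keep, in order.
#' @return A `conf_ensemble` with the selected frames.
#' @export
subset_frames <- function(ensemble, frames) {
  stopifnot(all(frames >= 1), all(frames <= n_frames(ensemble)))
  conf_ensemble(ensemble$atoms,
                ensemble$xyz[, , frames, drop = FALSE],
                system_label = ensemble$system_label,
                frame_spacing = ensemble$frame_spacing)
}

## Apply a rigid transform (row-vector convention: x' = x R + t) to every
## frame, or to one frame if `frame` given.
transform_frames <- function(ensemble, rotation, translation, frame = NULL) {
  fr <- frame %||% seq_len(n_frames(ensemble))
  for (f in fr) {
    ensemble$xyz[, , f] <- ensemble$xyz[, , f] %*% rotation +
      matrix(translation, nrow(ensemble$atoms), 3, byrow = TRUE)
  }
  ensemble
}
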