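## Protein Block assignment: nearest prototype in angular space.
##
## A residue's local conformation is the 8-angle window
## (psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1),
## phi(i+2)) over five consecutive residues; it is compared with the 16
## reference windows by the sum of squared wrapped angular differences
## (RMSDA up to a constant factor: the sum, not the mean, is used -- the
## argmin is identical and the identity/zero properties are preserved).

#' Angular dissimilarity between an 8-angle window and a prototype
#'
#' Sum over the 8 angle pairs of the squared differences, each difference
#' wrapped into `(-180, 180]`.  Symmetric, non-negative, zero iff all
#' angles agree modulo 360, and invariant to adding multiples of 360 to
#' any angle.
#'
#' @param window,prototype Numeric vectors of 8 angles in degrees.
#' @return Non-negative scalar (degrees squared); `NA` if any window
#'   angle is undefined.
#' @examples
#' rmsda(rep(0, 8), c(10, rep(0, 7)))  # 100
#' @export
rmsda <- function(window, prototype) {
  stopifnot(length(window) == 8L, length(prototype) == 8L)
  if (anyNA(window) || anyNA(prototype)) return(NA_real_)
  sum(sq_ang_diff(window, prototype))
}

#' Assign one 8-angle window to a Protein Block
#'
#' Label of the reference prototype with minimal [rmsda()]; ties are
#' broken alphabetically.  Windows containing an undefined angle get the
#' unassignable symbol `"Z"`.
#'
#' @param window Numeric vector of 8 angles in degrees (`NA` = undefined).
#' @param table Reference table, see [pb_reference()].
#' @return A single Protein Block label (`"a"`..`"p"`) or `"Z"`.
#' @export
assign_pb <- function(window, table = pb_reference()) {
  if (anyNA(window)) return(pb_unassigned())
  proto <- pb_reference_matrix(table)
  d <- rowSums(sq_ang_diff(matrix(window, 16, 8, byrow = TRUE), proto))
  rownames(proto)[which.min(d)]  # which.min takes the first = alphabetical
}

## Build the n x 8 window matrix for interior positions 3..R-2 of one
## dihedral series; rows ordered frame-major within position.
pb_windows <- function(dihedrals) {
  phi <- dihedrals$phi; psi <- dihedrals$psi
  R <- ncol(phi)
  if (R < 5) abort("Protein Block assignment needs at least 5 residues")
  pos <- 3:(R - 2)
  cbind(
    psi = as.vector(psi[, pos - 2]),
    phi = as.vector(phi[, pos - 1]),
    psi = as.vector(psi[, pos - 1]),
    phi = as.vector(phi[, pos]),
    psi = as.vector(psi[, pos]),
    phi = as.vector(phi[, pos + 1]),
    psi = as.vector(psi[, pos + 1]),
    phi = as.vector(phi[, pos + 2])
  )
}

#' Assign every residue of every frame to a Protein Block
#'
#' Applies nearest-prototype assignment per residue and frame.  The first
#' two and last two positions are always `"Z"` (their 5-residue window is
#' incomplete); interior positions are `"Z"` exactly when a window
#' dihedral is undefined.
#'
#' @param dihedrals A `dihedral_series` from [extract_phi_psi()] or
#'   [sample_dihedral_ensemble()].
#' @param table Reference table, see [pb_reference()].
#' @return A `pb_sequences` object: F x R character matrix of symbols
#'   over `a`..`p` and `Z`, plus `resno`.
#' @export
assign_ensemble <- function(dihedrals, table = pb_reference()) {
  phi <- dihedrals$phi
  F_ <- nrow(phi); R <- ncol(phi)
  W <- pb_windows(dihedrals)
  proto <- pb_reference_matrix(table)
  ok <- rowSums(is.na(W)) == 0L
  lab <- rep(pb_unassigned(), nrow(W))
  if (any(ok)) {
    D <- matrix(Inf, sum(ok), 16L)
    Wok <- W[ok, , drop = FALSE]
    for (j in seq_len(16L)) {
      D[, j] <- rowSums(sq_ang_diff(Wok,
                                    matrix(proto[j, ], nrow(Wok), 8, byrow = TRUE)))
    }
    lab[ok] <- rownames(proto)[max.col(-D, ties.method = "first")]
  }
  pbs <- matrix(pb_unassigned(), F_, R)
  pbs[, 3:(R - 2)] <- lab
  structure(
    list(pbs = pbs, resno = dihedrals$resno,
         system_label = dihedrals$system_label),
    class = "pb_sequences"
  )
}

#' @export
print.pb_sequences <- function(x, ...) {
  cat(sprintf("<pb_sequences> '%s': %d frame(s) x %d residue(s), Z-rate %.3f\n",
              x$system_label, nrow(x$pbs), ncol(x$pbs),
              mean(x$pbs == pb_unassigned())))
  invisible(x)
}

#' @export
tidy.pb_sequences <- function(x, ...) {
  tibble::tibble(
    frame = rep(seq_len(nrow(x$pbs)), times = ncol(x$pbs)),
    position = rep(x$resno, each = nrow(x$pbs)),
    pb = as.vector(x$pbs)
  )
}

#' Per-position Protein Block frequency profile
#'
#' Counts, per position, how often each of the 16 blocks occurs across
#' frames; frequencies are counts divided by the number of assignable
#' (non-`Z`) frames at that position, so observed rows sum to 1.
#' Positions with no assignable frame are flagged unobserved (`n_obs` 0,
#' frequencies `NA`).
#'
#' @param pbs A `pb_sequences` object, or a list of them whose counts are
#'   pooled (e.g. simulation replicates pooled before normalization).
#' @return A `pb_profile` tibble: `position`, `n_obs`, and one frequency
#'   column per block `a`..`p`.
#' @export
pb_frequency_profile <- function(pbs) {
  if (inherits(pbs, "pb_sequences")) pbs <- list(pbs)
  stopifnot(length(pbs) >= 1, all(purrr::map_lgl(pbs, inherits, "pb_sequences")))
  resno <- pbs[[1]]$resno
  for (p in pbs) {
    if (!identical(p$resno, resno)) abort("pooled pb_sequences have different positions")
  }
  mat <- do.call(rbind, purrr::map(pbs, "pbs"))
  counts <- apply(mat, 2, function(col)
    table(factor(col, levels = pb_labels())))  # 16 x R
  n_obs <- colSums(counts)
  freq <- t(counts) / ifelse(n_obs == 0, NA_real_, n_obs)
  out <- tibble::as_tibble(as.data.frame(freq))
  names(out) <- pb_labels()
  out <- dplyr::bind_cols(
    tibble::tibble(position = resno, n_obs = as.integer(n_obs)), out)
  class(out) <- c("pb_profile", class(out))
  attr(out, "system_label") <- pbs[[1]]$system_label
  out
}

## 16-column frequency matrix of a pb_profile (rows = positions).
profile_freq_matrix <- function(profile) {
  as.matrix(profile[, pb_labels()])
}

#' Export Protein Block sequences as FASTA-like text
#'
#' One record per frame, sequence = the frame's PB string (symbols
#' `a`..`p` and `Z`), for interoperability with existing PB tooling.
#'
#' @param pbs A `pb_sequences` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pb_fasta <- function(pbs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(pbs$pbs))) {
    writeLines(c(sprintf(">%s | frame %d", pbs$system_label, f),
                 paste(pbs$pbs[f, ], collapse = "")), con)
  }
  invisible(path)
}
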