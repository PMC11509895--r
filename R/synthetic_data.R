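## Synthetic ensembles with known statistical structure.
##
## Two independent generators: a dihedral-space sampler for testing PB
## assignment and the entropy statistics (no 3D rebuild needed), and a
## coordinate-space perturber for testing RMSD/RMSF.  Both are
## bit-reproducible given a seed.

#' Analytic Neq of a conformer distribution
#'
#' Ground truth for recovery tests: the exponential Shannon entropy
#' `exp(-sum p ln p)` of a generating distribution over Protein Blocks.
#'
#' @param distribution Named numeric vector, names in `a`..`p`,
#'   probabilities summing to 1.
#' @return Scalar in `[1, 16]`.
#' @examples
#' analytic_neq(c(m = 1))            # 1
#' analytic_neq(c(m = 0.5, d = 0.5)) # 2
#' @export
analytic_neq <- function(distribution) {
  check_distribution(distribution)
  p <- distribution[distribution > 0]
  exp(-sum(p * log(p)))
}

check_distribution <- function(distribution) {
  if (is.null(names(distribution)) || !all(names(distribution) %in% pb_labels())) {
    abort("conformer distribution must be named with Protein Block labels a..p")
  }
  check_normalized(unname(distribution), "conformer distribution")
  invisible(distribution)
}

#' Sample a dihedral-space ensemble from per-position PB mixtures
#'
#' Generates an F x R phi/psi series with known conformer statistics.
#' Per frame, one conformer label is drawn at each position from that
#' position's distribution; the position's (phi, psi) is the label's
#' central reference pair plus wrapped Gaussian noise of standard
#' deviation `sigma`.
#'
#' Draws are coupled within a frame (a single uniform variate per frame
#' drives every position's inverse-CDF draw), so a frame is
#' conformer-coherent wherever neighbouring positions share the same
#' distribution.  This matters because a Protein Block is assigned from
#' a 5-residue window: with independently drawn neighbours the window
#' mixes conformations and the nearest prototype is usually a transition
#' block, not the sampled label.  Per-position marginal distributions
#' are exact either way.  Faithful label recovery through
#' [assign_ensemble()] additionally requires mixtures over blocks whose
#' repeated central angles re-assign to themselves -- the regular
#' prototypes `m` (helix) and `d` (strand); transition blocks cannot be
#' embedded in a homogeneous chain by construction.
#'
#' @param n_residues Number of residues (>= 5).
#' @param n_frames Number of frames.
#' @param distribution Named probability vector over PB labels applied
#'   at every position, or a list of length `n_residues` of such vectors.
#'   Probabilities on labels outside `a`..`p` are an error.
#' @param sigma Angular noise standard deviation in degrees (default 10;
#'   small enough that the `m`/`d` basins stay separated, large enough
#'   to exercise wrapping).
#' @param seed Optional integer; fixing it makes the output
#'   bit-reproducible without disturbing the caller's RNG stream.
#' @param table PB reference table.
#' @return A `dihedral_series` whose `labels` field records the F x R
#'   generating labels (ground truth for recovery tests).
#' @export
sample_dihedral_ensemble <- function(n_residues, n_frames, distribution,
                                     sigma = 10, seed = NULL,
                                     table = pb_reference()) {
  stopifnot(n_residues >= 5, n_frames >= 1, sigma >= 0)
  dists <- if (is.list(distribution)) distribution else
    rep(list(distribution), n_residues)
  if (length(dists) != n_residues) {
    abort("need one distribution, or one per residue")
  }
  purrr::walk(dists, check_distribution)
  ## alphabetical inverse-CDF per position
  cdfs <- purrr::map(dists, function(d) {
    d <- d[order(names(d))]
    cum <- cumsum(unname(d))
    cum[length(cum)] <- 1  # guard the last bin against rounding
    list(labels = names(d), cum = cum)
  })
  proto <- pb_reference_matrix(table)

  with_optional_seed(seed, {
    u <- runif(n_frames)  # one variate per frame: conformer-coherent frames
    labels <- matrix(NA_character_, n_frames, n_residues)
    for (i in seq_len(n_residues)) {
      ci <- cdfs[[i]]
      labels[, i] <- ci$labels[findInterval(u, ci$cum, left.open = TRUE) + 1L]
    }
    phi <- matrix(proto[labels, "phi_0"], n_frames, n_residues)
    psi <- matrix(proto[labels, "psi_0"], n_frames, n_residues)
    if (sigma > 0) {
      phi <- phi + rnorm(length(phi), 0, sigma)
      psi <- psi + rnorm(length(psi), 0, sigma)
    }
    dihedral_series(phi, psi, resno = seq_len(n_residues),
                    system_label = "synthetic", labels = labels)
  })
}

## ---- ideal backbone geometry ---------------------------------------------

## Standard backbone internal coordinates (Angstrom / degrees).
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180
)

## Place atom D given A, B, C and internal coordinates (NeRF).  The
## torsion convention matches torsion_angle(A, B, C, D) == tors.
place_atom <- function(a, b, c, bond, angle, tors) {
  ang <- angle * pi / 180
  tor <- tors * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- drop(n) / sqrt(sum(n^2))
  m <- drop(cross3(n, bc))
  ## signs chosen so that torsion_angle(a, b, c, d) == tors
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d[1] * drop(bc) + d[2] * m + d[3] * n
}

#' Build an ideal single-conformation backbone
#'
#' Constructs an N/CA/C/O backbone with uniform (phi, psi) by standard
#' internal-coordinate geometry: (-57, -47) degrees for an alpha helix,
#' (-120, +135) for a beta strand.  [extract_phi_psi()] recovers the
#' targets to well under 0.5 degrees, and the interior Protein Blocks
#' are all `m` (helix) or all `d` (strand).
#'
#' @param kind `"helix"` or `"strand"`.
#' @param n_residues Number of residues (>= 5).
#' @param resname Residue name used for every position (default ALA).
#' @return A [conf_ensemble()] with one frame.
#' @export
build_ideal_conformation <- function(kind = c("helix", "strand"),
                                     n_residues, resname = "ALA") {
  kind <- match.arg(kind)
  if (n_residues < 5) abort("need at least 5 residues")
  tgt <- switch(kind, helix = c(phi = -57, psi = -47),
                strand = c(phi = -120, psi = 135))
  build_backbone(rep(tgt["phi"], n_residues), rep(tgt["psi"], n_residues),
                 resname = resname,
                 system_label = paste0("ideal_", kind))
}

## Backbone from per-residue (phi, psi); phi[1] and psi[n] are unused
## except for carbonyl placement.
build_backbone <- function(phi, psi, resname = "ALA",
                           system_label = "built") {
  n <- length(phi)
  stopifnot(length(psi) == n)
  g <- .bb
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                             g$b_c_n, g$a_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                              g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                             g$b_ca_c, g$a_n_ca_c, phi[i + 1])
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, wrap_angle(psi[i] + 180))
  }
  O[n, ] <- place_atom(N[n, ], CA[n, ], C[n, ],
                       g$b_c_o, g$a_ca_c_o, wrap_angle(psi[n] + 180))
  atoms <- tibble::tibble(
    resno = rep(seq_len(n), each = 4L),
    resname = resname,
    elety = rep(c("N", "CA", "C", "O"), n)
  )
  xyz <- array(NA_real_, c(4L * n, 3L, 1L))
  xyz[seq(1, 4 * n, 4), , 1] <- N
  xyz[seq(2, 4 * n, 4), , 1] <- CA
  xyz[seq(3, 4 * n, 4), , 1] <- C
  xyz[seq(4, 4 * n, 4), , 1] <- O
  conf_ensemble(atoms, xyz, system_label = system_label)
}

#' Harmonic coordinate-space ensemble around a reference conformation
#'
#' Emulates per-residue thermal fluctuation: every frame displaces each
#' residue rigidly by an isotropic Gaussian vector (per-axis standard
#' deviation = that residue's amplitude) and then applies a random
#' global rigid-body motion (uniform rotation, Gaussian translation).
#' With per-axis amplitude `s` the expected post-superposition RMSF of an
#' otherwise rigid scaffold residue is `s * sqrt(3)`.
#'
#' @param reference A single-frame [conf_ensemble()].
#' @param amplitudes Per-residue displacement amplitude in Angstrom
#'   (length = number of residues, or scalar recycled); must be >= 0.
#' @param n_frames Number of frames to generate.
#' @param seed Optional integer for bit-reproducibility.
#' @param translation_sd Standard deviation (Angstrom) of the random
#'   global translation (default 5).
#' @return A [conf_ensemble()] with `n_frames` frames.
#' @export
perturb_coordinates <- function(reference, amplitudes, n_frames, seed = NULL,
                                translation_sd = 5) {
  stopifnot(inherits(reference, "conf_ensemble"))
  if (n_frames(reference) != 1L) abort("reference must have exactly one frame")
  R <- n_residues(reference)
  if (length(amplitudes) == 1L) amplitudes <- rep(amplitudes, R)
  if (length(amplitudes) != R) abort("need one amplitude per residue")
  if (any(amplitudes < 0)) abort("amplitudes must be non-negative")
  atoms_per_res <- ensemble_res_index(reference)
  ref <- reference$xyz[, , 1]
  na <- nrow(ref)
  with_optional_seed(seed, {
    xyz <- array(NA_real_, c(na, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      disp <- matrix(rnorm(3L * R, 0, amplitudes), R, 3)  # recycled per column
      frame <- ref + disp[atoms_per_res, ]
      rot <- random_rotation()
      tr <- rnorm(3, 0, translation_sd)
      xyz[, , f] <- frame %*% rot + matrix(tr, na, 3, byrow = TRUE)
    }
    conf_ensemble(reference$atoms, xyz,
                  system_label = paste0(reference$system_label, "_harmonic"),
                  frame_spacing = reference$frame_spacing)
  })
}

## residue index (1..R) of each atom row
ensemble_res_index <- function(ensemble) {
  match(ensemble$atoms$resno, residues(ensemble)$resno)
}

## Uniform random rotation from a normalized Gaussian quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
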