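## Comparison statistics over Protein Block frequency profiles:
## Neq (equivalent number of blocks), Delta-Neq, Delta-PB, Delta-RMSF,
## logo-ready matrices, and the two-system comparison table.

#' Equivalent number of Protein Blocks (Neq)
#'
#' Exponential of the Shannon entropy (natural log) of a position's PB
#' frequency vector: `Neq = exp(-sum f_x ln f_x)` with `0 ln 0 := 0`.
#' 1 means a single block is ever observed (total rigidity); 16 means a
#' uniform, random-like distribution over the whole alphabet.
#'
#' @param frequencies Normalized, non-negative frequency vector (one
#'   entry per Protein Block).  Unnormalized input is an error.
#' @return Scalar in `[1, 16]` for a 16-block alphabet.
#' @examples
#' neq(c(1, rep(0, 15)))        # 1
#' neq(rep(1 / 16, 16))         # 16
#' neq(c(0.5, 0.5, rep(0, 14))) # 2
#' @export
neq <- function(frequencies) {
  check_normalized(frequencies, "PB frequency vector")
  f <- frequencies[frequencies > 0]
  exp(-sum(f * log(f)))
}

#' Absolute Neq difference between two systems
#'
#' @param neq1,neq2 Neq values (vectors allowed, matched elementwise).
#' @return `abs(neq1 - neq2)`, non-negative and symmetric.
#' @export
delta_neq <- function(neq1, neq2) abs(neq1 - neq2)

#' Delta-PB: L1 distance between two PB frequency vectors
#'
#' `sum_x |f_x(1) - f_x(2)|` over the 16 blocks.  0 means identical PB
#' usage at the position, 2 means completely disjoint usage.  Because it
#' compares full distributions it separates systems that an identical
#' Neq would conflate.
#'
#' @param f1,f2 Normalized frequency vectors of equal length.
#' @return Scalar in `[0, 2]`.
#' @examples
#' delta_pb(c(1, rep(0, 15)), c(0, 1, rep(0, 14)))  # 2
#' @export
delta_pb <- function(f1, f2) {
  stopifnot(length(f1) == length(f2))
  check_normalized(f1, "first PB frequency vector")
  check_normalized(f2, "second PB frequency vector")
  sum(abs(f1 - f2))
}

#' Signed RMSF difference between two systems
#'
#' Convention: variant minus wild-type, per aligned position.
#'
#' @param mutant,wildtype Equal-length numeric vectors, or tibbles with
#'   columns `position` and `rmsf` (as returned by [rmsf()]), aligned by
#'   position.
#' @return Numeric vector (or tibble `position`, `delta_rmsf` when both
#'   inputs are tibbles).
#' @export
delta_rmsf <- function(mutant, wildtype) {
  if (is.data.frame(mutant) && is.data.frame(wildtype)) {
    if (!identical(mutant$position, wildtype$position)) {
      abort("RMSF profiles have different positions; align them first")
    }
    return(tibble::tibble(position = mutant$position,
                          delta_rmsf = mutant$rmsf - wildtype$rmsf))
  }
  if (length(mutant) != length(wildtype)) {
    abort("RMSF vectors have different lengths")
  }
  mutant - wildtype
}

#' Slice a PB frequency profile into a logo-ready matrix
#'
#' Returns the positions x 16 frequency table for an inclusive position
#' range, suitable for any sequence-logo renderer (rows sum to 1).
#' Unobserved positions inside the range are dropped with a warning.
#'
#' @param profile A `pb_profile` from [pb_frequency_profile()].
#' @param start,end Inclusive author-numbered position range.
#' @return Numeric matrix, rownames = positions, colnames = `a`..`p`.
#' @export
logo_matrix <- function(profile, start = min(profile$position),
                        end = max(profile$position)) {
  sel <- profile$position >= start & profile$position <= end
  if (!any(sel)) abort(sprintf("no profile positions in range %d..%d", start, end))
  sub <- profile[sel, ]
  if (any(sub$n_obs == 0)) {
    warn(sprintf("dropping %d unobserved position(s) from logo matrix",
                 sum(sub$n_obs == 0)))
    sub <- sub[sub$n_obs > 0, ]
  }
  m <- profile_freq_matrix(sub)
  rownames(m) <- sub$position
  m
}

## Per-position Neq of a pb_profile (NA at unobserved positions).
profile_neq <- function(profile) {
  fm <- profile_freq_matrix(profile)
  vapply(seq_len(nrow(fm)), function(i) {
    if (profile$n_obs[i] == 0) NA_real_ else neq(fm[i, ])
  }, numeric(1))
}

#' Per-system flexibility profile
#'
#' Bundles, for one system, the per-position PB frequency profile with
#' the flexibility measures: Neq (with its interpretation band) and,
#' when coordinates are available, the C-alpha RMSF.  This is the input
#' to [compare_systems()].
#'
#' @param x A [conf_ensemble()] (full profile: PBs, Neq and RMSF) or a
#'   `dihedral_series` (PBs and Neq only; RMSF is `NA`).
#' @param region_map Region annotation tibble (default
#'   [default_region_map()]).
#' @param table PB reference table.
#' @param label System label; defaults to the object's.
#' @return A `system_profile`: list with `label`, `pb` (the
#'   `pb_profile`) and `flex` (tibble `position`, `region`, `rmsf`,
#'   `neq`, `band`, `n_obs`).
#' @export
system_profile <- function(x, region_map = default_region_map(),
                           table = pb_reference(), label = NULL) {
  UseMethod("system_profile")
}

#' @export
system_profile.conf_ensemble <- function(x, region_map = default_region_map(),
                                         table = pb_reference(), label = NULL) {
  dih <- extract_phi_psi(x)
  rmsf_tbl <- if (n_frames(x) >= 2) rmsf(x) else
    tibble::tibble(position = residues(x)$resno, rmsf = NA_real_)
  build_system_profile(dih, rmsf_tbl, region_map, table,
                       label %||% x$system_label)
}

#' @export
system_profile.dihedral_series <- function(x, region_map = default_region_map(),
                                           table = pb_reference(), label = NULL) {
  rmsf_tbl <- tibble::tibble(position = x$resno, rmsf = NA_real_)
  build_system_profile(x, rmsf_tbl, region_map, table,
                       label %||% x$system_label)
}

build_system_profile <- function(dihedrals, rmsf_tbl, region_map, table, label) {
  pbs <- assign_ensemble(dihedrals, table)
  profile <- pb_frequency_profile(pbs)
  nq <- profile_neq(profile)
  flex <- tibble::tibble(
    position = profile$position,
    region = annotate_regions(region_map, profile$position),
    rmsf = rmsf_tbl$rmsf[match(profile$position, rmsf_tbl$position)],
    neq = nq,
    band = neq_band(nq),
    n_obs = profile$n_obs
  )
  structure(list(label = label, pb = profile, flex = flex,
                 z_rate = mean(pbs$pbs == pb_unassigned())),
            class = "system_profile")
}

#' @export
print.system_profile <- function(x, ...) {
  cat(sprintf("<system_profile> '%s': %d position(s), Z-rate %.3f\n",
              x$label, nrow(x$flex), x$z_rate))
  print(utils::head(x$flex, 5))
  invisible(x)
}

#' @export
tidy.system_profile <- function(x, ...) x$flex

#' @export
glance.system_profile <- function(x, ...) {
  obs <- x$flex[x$flex$n_obs > 0, ]
  tibble::tibble(
    label = x$label,
    n_positions = nrow(x$flex),
    n_observed = nrow(obs),
    z_rate = x$z_rate,
    mean_neq = mean(obs$neq),
    max_neq = max(obs$neq),
    mean_rmsf = mean(obs$rmsf)
  )
}

#' Compare two systems position by position
#'
#' The central comparison of the package: for two systems profiled over
#' the same positions, computes per position the absolute Neq difference
#' (Delta-Neq), the L1 distance between PB frequency vectors (Delta-PB)
#' and the signed RMSF difference (system 1 minus system 2, i.e. variant
#' minus wild-type when called as `compare_systems(variant, wildtype)`).
#' Positions unobserved in either system get `NA` deltas, never 0.
#'
#' @param system1,system2 `system_profile` objects over identical
#'   position sets (system 1 = variant, system 2 = reference/wild-type
#'   for the Delta-RMSF sign convention).
#' @return A `pb_comparison` tibble: `position`, `region`, `rmsf1`,
#'   `rmsf2`, `delta_rmsf`, `neq1`, `neq2`, `delta_neq`, `delta_pb`.
#'   Per-region maxima are available via [region_summary()].
#' @export
compare_systems <- function(system1, system2) {
  stopifnot(inherits(system1, "system_profile"),
            inherits(system2, "system_profile"))
  p1 <- system1$flex$position
  p2 <- system2$flex$position
  if (!identical(p1, p2)) {
    bad <- union(setdiff(p1, p2), setdiff(p2, p1))
    if (!length(bad)) bad <- p1[p1 != p2]
    abort(sprintf("systems are not aligned; misaligned position(s): %s",
                  paste(sort(bad), collapse = ", ")))
  }
  fm1 <- profile_freq_matrix(system1$pb)
  fm2 <- profile_freq_matrix(system2$pb)
  observed <- system1$flex$n_obs > 0 & system2$flex$n_obs > 0
  dpb <- rep(NA_real_, length(p1))
  dpb[observed] <- rowSums(abs(fm1[observed, , drop = FALSE] -
                               fm2[observed, , drop = FALSE]))
  out <- tibble::tibble(
    position = p1,
    region = system1$flex$region,
    rmsf1 = system1$flex$rmsf,
    rmsf2 = system2$flex$rmsf,
    delta_rmsf = system1$flex$rmsf - system2$flex$rmsf,
    neq1 = system1$flex$neq,
    neq2 = system2$flex$neq,
    delta_neq = ifelse(observed, delta_neq(system1$flex$neq, system2$flex$neq),
                       NA_real_),
    delta_pb = dpb
  )
  class(out) <- c("pb_comparison", class(out))
  attr(out, "labels") <- c(system1$label, system2$label)
  out
}

#' Per-region maxima of the comparison measures
#'
#' Summarizes a [compare_systems()] table into, per annotated region, the
#' maximal Delta-PB, maximal Delta-Neq and maximal `|Delta-RMSF|`.
#'
#' @param comparison A `pb_comparison` tibble.
#' @return Tibble `region`, `n_positions`, `max_delta_pb`,
#'   `max_delta_neq`, `max_abs_delta_rmsf`.
#' @export
region_summary <- function(comparison) {
  max_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  comparison |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_positions = dplyr::n(),
      max_delta_pb = max_na(.data$delta_pb),
      max_delta_neq = max_na(.data$delta_neq),
      max_abs_delta_rmsf = max_na(abs(.data$delta_rmsf)),
      .groups = "drop"
    )
}

#' @export
glance.pb_comparison <- function(x, ...) {
  max_na <- function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  labs <- attr(x, "labels") %||% c(NA_character_, NA_character_)
  tibble::tibble(
    system1 = labs[1], system2 = labs[2],
    n_positions = nrow(x),
    max_delta_pb = max_na(x$delta_pb),
    max_delta_neq = max_na(x$delta_neq),
    max_abs_delta_rmsf = max_na(abs(x$delta_rmsf))
  )
}
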