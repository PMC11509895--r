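## Workflow orchestration: mutate -> assign -> profile -> compare, with
## fixed, versioned output schemas.  The CLI in inst/exec/pbflex is a
## thin wrapper over these functions.

schema_version <- "pbflex-schema-v1"

write_tsv_with_schema <- function(df, path, what) {
  writeLines(sprintf("# %s %s", schema_version, what), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a pbflex TSV output
#'
#' Reads tables written by [run_profile()]/[run_compare()] (one leading
#' `#` schema comment line, then a header).
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_pbflex_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

resolve_ensemble <- function(input, chain = NULL, label = NULL) {
  if (inherits(input, "conf_ensemble")) {
    if (!is.null(label)) input$system_label <- label
    return(input)
  }
  read_multimodel_pdb(input, chain = chain, system_label = label)
}

#' Apply truncation mutations to a structure file
#'
#' Reads a (multi-model) PDB, applies Cys truncation mutations and
#' writes the mutated structure.  Nothing is written if validation
#' fails.
#'
#' @param input Input PDB path (or a [conf_ensemble()]).
#' @param spec Mutation spec: a compact string like `"C32A,C99G"` or a
#'   tibble from [mutation_spec()].
#' @param output Output PDB path.
#' @param chain Chain to read (see [read_multimodel_pdb()]).
#' @return The mutated ensemble, invisibly.
#' @export
run_mutate <- function(input, spec, output, chain = NULL) {
  ens <- resolve_ensemble(input, chain)
  specs <- if (is.character(spec)) parse_mutation_spec(spec) else spec
  mut <- mutate_side_chain_truncation(ens, specs)
  write_multimodel_pdb(mut, output)
  inform(sprintf("wrote %s (%d mutation(s))", output, nrow(specs)))
  invisible(mut)
}

#' Profile one system
#'
#' Runs the full single-system analysis -- RMSD series, RMSF, PB
#' assignment, per-position frequencies and Neq -- and writes four TSVs
#' (`rmsd.tsv`, `rmsf.tsv`, `neq.tsv`, `pb_frequencies.tsv`) into
#' `out_dir`.  Frame count, residue count and Z-rate are logged.
#'
#' @param input Input multi-model PDB path or [conf_ensemble()].
#' @param out_dir Output directory (created if needed).
#' @param chain Chain to read.
#' @param region_map Region annotation (default [default_region_map()]).
#' @param label System label.
#' @param replicates Optional integer vector of replicate ids, one per
#'   frame; when given, per-replicate PB profiles are also written
#'   (`pb_frequencies_rep<k>.tsv`) for dispersion checks, while the main
#'   outputs pool counts across all frames.
#' @return List with `profile` (the [system_profile()]), `rmsd`
#'   (tibble) and the output paths, invisibly.
#' @export
run_profile <- function(input, out_dir, chain = NULL,
                        region_map = default_region_map(), label = NULL,
                        replicates = NULL) {
  ens <- resolve_ensemble(input, chain, label)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- system_profile(ens, region_map = region_map)
  rmsd_tbl <- if (n_frames(ens) >= 2) rmsd_series(ens) else
    tibble::tibble(frame = 1L, time_ps = NA_real_, rmsd = 0)
  inform(sprintf("profiled '%s': %d frame(s), %d residue(s), Z-rate %.3f",
                 sp$label, n_frames(ens), n_residues(ens), sp$z_rate))

  paths <- c(
    rmsd = file.path(out_dir, "rmsd.tsv"),
    rmsf = file.path(out_dir, "rmsf.tsv"),
    neq = file.path(out_dir, "neq.tsv"),
    pb = file.path(out_dir, "pb_frequencies.tsv")
  )
  write_tsv_with_schema(rmsd_tbl, paths["rmsd"], "rmsd: frame time_ps rmsd_A")
  write_tsv_with_schema(
    dplyr::select(sp$flex, "position", "region", "rmsf"),
    paths["rmsf"], "rmsf: position region rmsf_A")
  write_tsv_with_schema(
    dplyr::select(sp$flex, "position", "region", "neq", "band", "n_obs"),
    paths["neq"], "neq: position region neq band n_obs")
  write_tsv_with_schema(tibble::as_tibble(sp$pb), paths["pb"],
                        "pb_frequencies: position n_obs a..p")
  if (!is.null(replicates)) {
    stopifnot(length(replicates) == n_frames(ens))
    dih <- extract_phi_psi(ens)
    pbs <- assign_ensemble(dih)
    for (r in unique(replicates)) {
      sub <- structure(list(pbs = pbs$pbs[replicates == r, , drop = FALSE],
                            resno = pbs$resno, system_label = sp$label),
                       class = "pb_sequences")
      write_tsv_with_schema(
        tibble::as_tibble(pb_frequency_profile(sub)),
        file.path(out_dir, sprintf("pb_frequencies_rep%s.tsv", r)),
        "pb_frequencies (one replicate): position n_obs a..p")
    }
  }
  invisible(list(profile = sp, rmsd = rmsd_tbl, paths = paths))
}

#' Compare two systems end to end
#'
#' Profiles two systems over aligned positions and writes the
#' per-position comparison table (`comparison.tsv`) and a JSON summary
#' of per-region maxima (`region_summary.json`).
#'
#' @param input1,input2 Input PDB paths or [conf_ensemble()] objects;
#'   system 1 is the variant in the Delta-RMSF sign convention.
#' @param out_dir Output directory.
#' @param chain Chain to read from file inputs.
#' @param region_map Region annotation.
#' @param labels Optional length-2 character vector of system labels.
#' @return List with `comparison` (the [compare_systems()] tibble),
#'   `summary` (the [region_summary()] tibble) and output paths,
#'   invisibly.
#' @export
run_compare <- function(input1, input2, out_dir, chain = NULL,
                        region_map = default_region_map(), labels = NULL) {
  e1 <- resolve_ensemble(input1, chain, labels[1])
  e2 <- resolve_ensemble(input2, chain, if (length(labels) > 1) labels[2])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s1 <- system_profile(e1, region_map = region_map)
  s2 <- system_profile(e2, region_map = region_map)
  cmp <- compare_systems(s1, s2)
  summ <- region_summary(cmp)
  paths <- c(comparison = file.path(out_dir, "comparison.tsv"),
             summary = file.path(out_dir, "region_summary.json"))
  write_tsv_with_schema(
    tibble::as_tibble(cmp), paths["comparison"],
    "comparison: position region rmsf1 rmsf2 delta_rmsf neq1 neq2 delta_neq delta_pb")
  jsonlite::write_json(
    list(schema = schema_version,
         systems = list(system1 = s1$label, system2 = s2$label),
         regions = summ),
    paths["summary"], auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  inform(sprintf("compared '%s' vs '%s' over %d positions",
                 s1$label, s2$label, nrow(cmp)))
  invisible(list(comparison = cmp, summary = summ, paths = paths))
}

#' Generate a synthetic coordinate ensemble and write it as PDB
#'
#' Builds an ideal backbone, applies harmonic per-residue fluctuation
#' plus random rigid-body motion, and writes a multi-model PDB so the
#' full file-to-report pipeline can be exercised end to end.
#'
#' @param output Output PDB path.
#' @param kind `"helix"` or `"strand"`.
#' @param n_residues,n_frames Ensemble dimensions.
#' @param amplitudes Per-residue (or scalar) fluctuation amplitude in
#'   Angstrom.
#' @param seed Integer seed (bit-reproducible output).
#' @return The generated ensemble, invisibly.
#' @export
run_simulate <- function(output, kind = "helix", n_residues = 20,
                         n_frames = 50, amplitudes = 0.5, seed = 1) {
  ref <- build_ideal_conformation(kind, n_residues)
  ens <- perturb_coordinates(ref, amplitudes, n_frames, seed = seed)
  write_multimodel_pdb(ens, output)
  inform(sprintf("wrote %s: %d frames x %d residues (%s, seed %d)",
                 output, n_frames, n_residues, kind, seed))
  invisible(ens)
}
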