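## Multi-model PDB input/output, in-silico truncation mutants, and
## FR/CDR region annotation.
##
## Parsing and record formatting are delegated to bio3d; this file adds a
## light pre-validation of the MODEL blocks because bio3d assumes every
## model carries the same atoms and silently mis-reads files where that
## fails.

## ---- multi-model pre-scan -------------------------------------------------

## Fixed-column fields of ATOM records needed for identity/occupancy checks.
atom_line_fields <- function(lines) {
  tibble::tibble(
    elety = trimws(substr(lines, 13, 16)),
    alt = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resno = suppressWarnings(as.integer(substr(lines, 23, 26))),
    insert = trimws(substr(lines, 27, 27)),
    occ = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    elesy = trimws(substr(lines, 77, 78))
  )
}

is_hydrogen <- function(fields) {
  bare <- sub("^[0-9]+", "", fields$elety)
  ifelse(fields$elesy != "", fields$elesy %in% c("H", "D"),
         substr(bare, 1, 1) %in% c("H", "D"))
}

backbone_atoms <- c("N", "CA", "C", "O")

#' Read a multi-model PDB file into a conformational ensemble
#'
#' Reads a (possibly multi-MODEL) PDB file, keeping one chain, and returns
#' the frames-by-residues-by-atoms coordinate container the rest of the
#' package operates on.  A single-structure file counts as one frame.
#'
#' Hydrogens are ignored.  For alternate locations the highest-occupancy
#' conformer is kept (ties resolved in favour of altloc `A`).  Atoms that
#' are not present in every model are dropped with a warning, except
#' backbone atoms (N, CA, C, O): a model lacking a backbone atom of a
#' residue present elsewhere is an error naming that residue, as is any
#' difference in residue composition between models.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier to keep.  May be omitted when the file
#'   contains a single chain; otherwise missing or absent chains are an
#'   error naming the chains available.
#' @param system_label Label stored on the ensemble; defaults to the file
#'   name without extension.
#' @param frame_spacing Optional time between models in picoseconds
#'   (metadata only).
#' @return A [conf_ensemble()] with frames ordered by MODEL number.
#' @export
read_multimodel_pdb <- function(path, chain = NULL, system_label = NULL,
                                frame_spacing = NA_real_) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)

  model_starts <- grep("^MODEL", lines)
  atom_mask <- startsWith(lines, "ATOM")
  if (!any(atom_mask)) abort(sprintf("no ATOM records in %s", path))

  ## assign each ATOM line to a model block (0 = no MODEL records)
  if (length(model_starts)) {
    model_no <- as.integer(sub("^MODEL\\s+", "", lines[model_starts]))
    block <- findInterval(which(atom_mask), model_starts)
    if (any(block == 0)) abort("ATOM records found before the first MODEL record")
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts)) {
      abort("unbalanced MODEL/ENDMDL records")
    }
  } else {
    model_no <- 1L
    block <- rep(1L, sum(atom_mask))
  }

  atom_idx <- which(atom_mask)
  fields <- atom_line_fields(lines[atom_idx])

  ## chain selection
  chains <- sort(unique(fields$chain))
  if (is.null(chain)) {
    if (length(chains) > 1) {
      abort(sprintf("file has chains %s; supply `chain`",
                    paste(chains, collapse = ", ")))
    }
    chain <- chains
  }
  if (!chain %in% chains) {
    abort(sprintf("chain '%s' not present; available chains: %s",
                  chain, paste(chains, collapse = ", ")))
  }
  keep <- fields$chain == chain & !is_hydrogen(fields)

  ## altloc: keep highest occupancy per (model, residue, atom); tie -> 'A'
  fields$line <- atom_idx
  fields$model <- block
  f <- fields[keep, ]
  f <- f |>
    dplyr::group_by(.data$model, .data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(dplyr::coalesce(.data$occ, 1)),
                   .data$alt != "A", .data$alt, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$line)

  ## atom identity across models
  f$key <- paste(f$resno, f$insert, f$resname, f$elety, sep = "|")
  models <- sort(unique(f$model))
  key_sets <- split(f$key, f$model)
  common <- Reduce(intersect, key_sets)
  if (length(models) > 1L) {
    all_keys <- unique(unlist(key_sets))
    extra <- setdiff(all_keys, common)
    if (length(extra)) {
      parts <- do.call(rbind, strsplit(extra, "|", fixed = TRUE))
      res_ids <- paste0(parts[, 3], parts[, 1])
      bb <- parts[, 4] %in% backbone_atoms
      ## residue completely absent from some model?
      res_common <- unique(sub("\\|[^|]*$", "", common))
      res_all <- unique(sub("\\|[^|]*$", "", all_keys))
      res_extra <- setdiff(res_all, res_common)
      if (length(res_extra)) {
        p <- strsplit(res_extra[1], "|", fixed = TRUE)[[1]]
        lacking <- models[!vapply(models, function(m)
          any(startsWith(key_sets[[as.character(m)]], res_extra[1])), logical(1))]
        abort(sprintf(
          "inconsistent residue composition across models: residue %s%s missing from MODEL %s",
          p[3], p[1], paste(lacking, collapse = ",")))
      }
      if (any(bb)) {
        i <- which(bb)[1]
        key <- extra[i]
        lacking <- models[!vapply(models, function(m)
          key %in% key_sets[[as.character(m)]], logical(1))]
        abort(sprintf(
          "backbone atom %s of residue %s missing from MODEL %s",
          parts[i, 4], res_ids[i], paste(lacking, collapse = ",")))
      }
      warn(sprintf(
        "dropping %d atom(s) not present in all models: %s",
        length(extra),
        paste(unique(paste0(res_ids, ":", parts[, 4])), collapse = ", ")))
      f <- f[f$key %in% common, ]
    }
  }

  ## hand the filtered records to bio3d, wrapped back into MODEL blocks
  parts <- split(lines[f$line], f$model)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(tmp, "w")
  ord <- order(model_no[models])  # frames ordered by MODEL number
  for (j in seq_along(ord)) {
    chunk <- parts[[ord[j]]]
    ## renumber serials: input files may repeat them after filtering
    substr(chunk, 7, 11) <- sprintf("%5d", seq_along(chunk))
    writeLines(sprintf("MODEL %8d", j), con)
    writeLines(chunk, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)

  pdb <- bio3d::read.pdb(tmp, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  nf <- nrow(pdb$xyz)
  natom <- nrow(pdb$atom)
  xyz <- aperm(array(t(as.matrix(pdb$xyz)), dim = c(3, natom, nf)), c(2, 1, 3))

  conf_ensemble(
    atoms = tibble::tibble(resno = pdb$atom$resno,
                           resname = pdb$atom$resid,
                           elety = pdb$atom$elety),
    xyz = xyz,
    system_label = system_label %||% sub("\\.[^.]*$", "", basename(path)),
    frame_spacing = frame_spacing
  )
}

#' Write a conformational ensemble as a multi-model PDB file
#'
#' Each frame becomes one sequentially numbered MODEL/ENDMDL block; record
#' formatting is done by bio3d, so coordinates round-trip at the PDB
#' format's 3-decimal precision.
#'
#' @param ensemble A [conf_ensemble()].
#' @param path Output path.
#' @param chain Chain identifier written on every atom record.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ensemble, path, chain = "A") {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("directory does not exist: %s", dir))
  nf <- n_frames(ensemble)
  na <- nrow(ensemble$atoms)
  xyz <- t(matrix(aperm(ensemble$xyz, c(2, 1, 3)), nrow = 3L * na))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = ensemble$atoms$resno,
    resid = ensemble$atoms$resname,
    elety = ensemble$atoms$elety,
    chain = rep(chain, na),
    eleno = seq_len(na)
  )
  invisible(path)
}

## ---- mutants --------------------------------------------------------------

#' Specify a side-chain truncation mutation
#'
#' @param position Author sequence number of the residue to mutate.
#' @param from_residue 3-letter code the residue must currently have
#'   (default `"CYS"`).
#' @param to_residue Target residue, `"ALA"` or `"GLY"`.
#' @return A one-row tibble (`position`, `from_residue`, `to_residue`).
#' @export
mutation_spec <- function(position, from_residue = "CYS",
                          to_residue = c("ALA", "GLY")) {
  to_residue <- match.arg(to_residue)
  tibble::tibble(position = as.integer(position),
                 from_residue = toupper(from_residue),
                 to_residue = to_residue)
}

#' Parse a compact mutation string
#'
#' Accepts comma-separated one-letter specs like `"C32A,C99G"` (wild-type
#' one-letter code, author position, target `A` or `G`).
#'
#' @param spec Character scalar.
#' @return Tibble of mutation specs, one row per mutation.
#' @export
parse_mutation_spec <- function(spec) {
  one <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  parts <- trimws(strsplit(spec, ",")[[1]])
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([AG])$", parts))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    abort(sprintf("cannot parse mutation spec '%s' (expected e.g. C32A)",
                  parts[bad][1]))
  }
  purrr::map_dfr(m, function(g) {
    mutation_spec(as.integer(g[3]), from_residue = one[[g[2]]],
                  to_residue = one[[g[4]]])
  })
}

## Atoms retained after truncation to the target residue.
truncation_atom_set <- function(to_residue) {
  switch(to_residue,
         ALA = c(backbone_atoms, "CB"),
         GLY = backbone_atoms,
         abort(sprintf("unsupported target residue '%s'", to_residue)))
}

#' Build side-chain truncation mutants
#'
#' Disrupts a disulfide bridge in silico by truncating cysteines: Cys to
#' Ala keeps exactly N, CA, C, O, CB; Cys to Gly keeps N, CA, C, O.  Kept
#' atoms retain their coordinates in every frame, so backbone dihedrals,
#' Protein Block assignments and C-alpha metrics are bit-identical before
#' and after mutation; no other residue is touched.  No minimization or
#' rotamer placement is performed.
#'
#' @param ensemble A [conf_ensemble()].
#' @param specs Tibble of mutation specs ([mutation_spec()],
#'   [parse_mutation_spec()]) with columns `position`, `from_residue`,
#'   `to_residue`.
#' @return The mutated `conf_ensemble`; its label gains a `+spec` suffix.
#' @export
mutate_side_chain_truncation <- function(ensemble, specs) {
  specs <- tibble::as_tibble(specs)
  res <- residues(ensemble)
  for (k in seq_len(nrow(specs))) {
    pos <- specs$position[k]
    i <- match(pos, res$resno)
    if (is.na(i)) abort(sprintf("no residue at position %d", pos))
    if (res$resname[i] != specs$from_residue[k]) {
      abort(sprintf("residue at position %d is %s, not %s",
                    pos, res$resname[i], specs$from_residue[k]))
    }
  }
  keep <- rep(TRUE, nrow(ensemble$atoms))
  resname <- ensemble$atoms$resname
  for (k in seq_len(nrow(specs))) {
    pos <- specs$position[k]
    sel <- ensemble$atoms$resno == pos
    keep[sel] <- ensemble$atoms$elety[sel] %in%
      truncation_atom_set(specs$to_residue[k])
    resname[sel] <- specs$to_residue[k]
  }
  atoms <- ensemble$atoms
  atoms$resname <- resname
  conf_ensemble(atoms[keep, ], ensemble$xyz[keep, , , drop = FALSE],
                system_label = paste0(ensemble$system_label, "+",
                                      paste(specs$position, specs$to_residue,
                                            sep = "", collapse = ",")),
                frame_spacing = ensemble$frame_spacing)
}

## ---- region annotation ----------------------------------------------------

#' Default VHH region map
#'
#' CDR bounds in author numbering: CDR1 23-37, CDR2 50-63, CDR3 99-105,
#' with the framework regions FR1-FR4 filling the complement.  The bounds
#' are approximate by nature and overridable via [read_region_map()] or a
#' hand-built tibble.
#'
#' @param n_residues Upper bound of FR4 (default 128 covers typical VHH
#'   domains).
#' @return Tibble with columns `region`, `start`, `end` (inclusive).
#' @export
default_region_map <- function(n_residues = 128L) {
  tibble::tibble(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
    start = c(1L, 23L, 38L, 50L, 64L, 99L, 106L),
    end = c(22L, 37L, 49L, 63L, 98L, 105L, as.integer(n_residues))
  )
}

#' Read a region map from YAML or JSON
#'
#' The file maps region names to inclusive `[start, end]` author-numbering
#' ranges, e.g. `CDR1: [23, 37]`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Tibble with columns `region`, `start`, `end`.
#' @export
read_region_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                abort(sprintf("unsupported region map format '.%s'", ext)))
  map <- tibble::tibble(
    region = names(raw),
    start = vapply(raw, function(r) as.integer(r[[1]]), integer(1)),
    end = vapply(raw, function(r) as.integer(r[[2]]), integer(1))
  )
  validate_region_map(map)
}

validate_region_map <- function(map) {
  stopifnot(all(c("region", "start", "end") %in% names(map)))
  if (any(map$end < map$start)) abort("region map has end < start")
  map <- dplyr::arrange(map, .data$start)
  if (nrow(map) > 1 && any(map$start[-1] <= map$end[-nrow(map)])) {
    abort("region map ranges overlap")
  }
  map
}

#' Annotate positions with their region
#'
#' Deterministic lookup of each author-numbered position in a region map;
#' positions outside every range are `"unassigned"`.
#'
#' @param region_map Tibble with columns `region`, `start`, `end`.
#' @param position Integer vector of author sequence numbers.
#' @return Character vector of region names, same length as `position`.
#' @examples
#' annotate_regions(default_region_map(), c(30, 101, 45))
#' @export
annotate_regions <- function(region_map, position) {
  region_map <- validate_region_map(region_map)
  out <- rep("unassigned", length(position))
  for (k in seq_len(nrow(region_map))) {
    hit <- position >= region_map$start[k] & position <= region_map$end[k]
    out[hit] <- region_map$region[k]
  }
  out
}
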