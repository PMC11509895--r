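# Fixtures are generated in code; no binary data ships with the tests.

# PDB ATOM line with correct fixed columns (for hand-built malformed files)
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          occ = 1, alt = " ", elesy = NULL) {
  elesy <- if (is.null(elesy)) substr(sub("^[0-9]+", "", trimws(name)), 1, 1) else elesy
  fmt_name <- if (nchar(name) >= 4) name else sprintf(" %-3s", name)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, fmt_name, alt, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0, elesy)
}

# two-residue, hand-positioned backbone used by the malformed-file tests
toy_residue_lines <- function(resno, shift = 0, chain = "A") {
  base <- list(N = c(0, 0, 0), CA = c(1.458, 0, 0),
               C = c(2.009, 1.42, 0), O = c(1.251, 2.39, 0))
  offs <- c(3.8 * (resno - 1) + shift, 0, 0)
  vapply(names(base), function(el) {
    pdb_atom_line(1L, el, "ALA", chain, resno, base[[el]] + offs)
  }, character(1))
}

toy_multimodel_lines <- function(n_models = 2, n_res = 2, chain = "A") {
  unlist(lapply(seq_len(n_models), function(m) {
    c(sprintf("MODEL %8d", m),
      unlist(lapply(seq_len(n_res), toy_residue_lines,
                    shift = 0.1 * (m - 1), chain = chain)),
      "ENDMDL")
  }))
}

# helix-based ensemble with CYS (CB + SG side chain stubs) at `positions`
make_cys_ensemble <- function(n_residues, positions, n_frames = 1, seed = 1) {
  ref <- build_ideal_conformation("helix", n_residues)
  atoms <- ref$atoms
  frame1 <- ref$xyz[, , 1]
  rows <- list()
  coords <- list()
  for (r in unique(atoms$resno)) {
    sel <- which(atoms$resno == r)
    a <- atoms[sel, ]
    x <- frame1[sel, , drop = FALSE]
    if (r %in% positions) {
      a$resname <- "CYS"
      ca <- x[a$elety == "CA", ]
      a <- dplyr::bind_rows(a, tibble::tibble(resno = r, resname = "CYS",
                                              elety = c("CB", "SG")))
      x <- rbind(x, ca + c(1.0, 1.0, 0.5), ca + c(1.8, 2.2, 1.0))
    }
    rows[[length(rows) + 1]] <- a
    coords[[length(coords) + 1]] <- x
  }
  xyz1 <- do.call(rbind, coords)
  ens <- conf_ensemble(dplyr::bind_rows(rows),
                       array(xyz1, dim = c(nrow(xyz1), 3, 1)),
                       system_label = "cys_toy")
  if (n_frames > 1) perturb_coordinates(ens, 0.2, n_frames, seed = seed) else ens
}

# uniform random point on the 16-simplex (for Neq / Delta-PB properties)
random_simplex <- function(k = 16) {
  e <- -log(runif(k))
  e / sum(e)
}
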