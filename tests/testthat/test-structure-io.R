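test_that("multi-model files read into ensembles with frames ordered by MODEL", {
  f <- withr::local_tempfile(fileext = ".pdb")
  ref <- build_ideal_conformation("helix", 6)
  ens <- perturb_coordinates(ref, 0.1, 2, seed = 11)
  write_multimodel_pdb(ens, f)
  back <- read_multimodel_pdb(f, chain = "A")
  expect_equal(n_frames(back), 2)
  expect_equal(n_residues(back), 6)
  expect_identical(back$atoms$elety, ens$atoms$elety)

  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ref, f1)
  expect_equal(n_frames(read_multimodel_pdb(f1, chain = "A")), 1)
})

test_that("write/read round trip preserves coordinates at format precision", {
  f <- withr::local_tempfile(fileext = ".pdb")
  ens <- perturb_coordinates(build_ideal_conformation("strand", 5), 0.3, 3,
                             seed = 2)
  write_multimodel_pdb(ens, f)
  back <- read_multimodel_pdb(f, chain = "A")
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3 + 1e-9)
  expect_identical(residues(back), residues(ens))
})

test_that("MODEL records are numbered sequentially past 999", {
  f <- withr::local_tempfile(fileext = ".pdb")
  ens <- perturb_coordinates(build_ideal_conformation("helix", 5), 0.05, 1005,
                             seed = 5)
  write_multimodel_pdb(ens, f)
  models <- grep("^MODEL", readLines(f), value = TRUE)
  expect_length(models, 1005)
  expect_identical(as.integer(sub("MODEL\\s+", "", models)), 1:1005)
  expect_equal(n_frames(read_multimodel_pdb(f, chain = "A")), 1005)
})

test_that("missing chains are reported with the available alternatives", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_multimodel_lines(chain = "B"), f)
  expect_error(read_multimodel_pdb(f, chain = "A"), "available chains: B")
  ## single-chain files do not need an explicit chain
  expect_equal(n_frames(read_multimodel_pdb(f)), 2)
})

test_that("a model lacking a backbone atom is an error naming the residue", {
  lines <- toy_multimodel_lines(n_models = 2, n_res = 2)
  drop <- intersect(grep(" CA ", lines), which(cumsum(grepl("^MODEL", lines)) == 2))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-drop[1]], f)
  expect_error(read_multimodel_pdb(f, chain = "A"),
               "backbone atom CA of residue ALA1 missing from MODEL 2")
})

test_that("non-backbone atoms absent from some model are dropped with a warning", {
  lines <- toy_multimodel_lines(n_models = 2, n_res = 2)
  cb <- pdb_atom_line(99L, "CB", "ALA", "A", 1, c(1.5, -1, 0.8))
  ## CB present only in model 1
  lines <- append(lines, cb, after = grep("^MODEL", lines)[1] + 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_warning(ens <- read_multimodel_pdb(f, chain = "A"), "dropping 1 atom")
  expect_false("CB" %in% ens$atoms$elety)
  expect_equal(n_frames(ens), 2)
})

test_that("altloc keeps the highest occupancy, ties resolved to A", {
  res <- toy_residue_lines(1)
  ca_a <- pdb_atom_line(10L, "CA", "ALA", "A", 1, c(1.458, 0, 0), occ = 0.4, alt = "A")
  ca_b <- pdb_atom_line(11L, "CA", "ALA", "A", 1, c(9.999, 0, 0), occ = 0.6, alt = "B")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(res[c("N")], ca_a, ca_b, res[c("C", "O")]), f)
  ens <- read_multimodel_pdb(f, chain = "A")
  expect_equal(ens$xyz[ens$atoms$elety == "CA", 1, 1], 9.999)

  ca_b2 <- pdb_atom_line(11L, "CA", "ALA", "A", 1, c(9.999, 0, 0), occ = 0.4, alt = "B")
  writeLines(c(res[c("N")], ca_a, ca_b2, res[c("C", "O")]), f)
  ens <- read_multimodel_pdb(f, chain = "A")
  expect_equal(ens$xyz[ens$atoms$elety == "CA", 1, 1], 1.458)
})

test_that("hydrogens are ignored on read", {
  res <- toy_residue_lines(1)
  h <- pdb_atom_line(20L, "HA", "ALA", "A", 1, c(1.5, -1, 0), elesy = "H")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(res, h), f)
  ens <- read_multimodel_pdb(f, chain = "A")
  expect_false("HA" %in% ens$atoms$elety)
  expect_equal(nrow(ens$atoms), 4)
})

test_that("Cys truncation keeps the defined atom sets and nothing else changes", {
  ens <- make_cys_ensemble(12, positions = c(5, 9))
  ala <- mutate_side_chain_truncation(ens, mutation_spec(5, to_residue = "ALA"))
  expect_setequal(ala$atoms$elety[ala$atoms$resno == 5], c("N", "CA", "C", "O", "CB"))
  expect_identical(unique(ala$atoms$resname[ala$atoms$resno == 5]), "ALA")

  gly <- mutate_side_chain_truncation(ens, mutation_spec(9, to_residue = "GLY"))
  expect_setequal(gly$atoms$elety[gly$atoms$resno == 9], c("N", "CA", "C", "O"))

  both <- mutate_side_chain_truncation(
    ens, dplyr::bind_rows(mutation_spec(5, to_residue = "ALA"),
                          mutation_spec(9, to_residue = "GLY")))
  ## all other residues bit-identical
  untouched <- !both$atoms$resno %in% c(5, 9)
  orig_untouched <- !ens$atoms$resno %in% c(5, 9)
  expect_identical(both$xyz[untouched, , ], ens$xyz[orig_untouched, , ])
  ## kept atoms of mutated residues keep their exact coordinates
  keep5 <- ens$atoms$resno == 5 & ens$atoms$elety %in% c("N", "CA", "C", "O", "CB")
  expect_identical(both$xyz[both$atoms$resno == 5, , ], ens$xyz[keep5, , ])
})

test_that("mutation order does not matter and mutation is idempotent per spec", {
  ens <- make_cys_ensemble(12, positions = c(5, 9))
  ab <- mutate_side_chain_truncation(
    mutate_side_chain_truncation(ens, mutation_spec(5, to_residue = "ALA")),
    mutation_spec(9, to_residue = "GLY"))
  ba <- mutate_side_chain_truncation(
    mutate_side_chain_truncation(ens, mutation_spec(9, to_residue = "GLY")),
    mutation_spec(5, to_residue = "ALA"))
  expect_identical(ab$atoms[, c("resno", "resname", "elety")],
                   ba$atoms[, c("resno", "resname", "elety")])
  expect_identical(ab$xyz, ba$xyz)
})

test_that("mutation validation rejects mismatched or absent residues", {
  ens <- make_cys_ensemble(12, positions = 5)
  expect_error(mutate_side_chain_truncation(ens, mutation_spec(6)),
               "is ALA, not CYS")
  expect_error(mutate_side_chain_truncation(ens, mutation_spec(99)),
               "no residue at position 99")
})

test_that("compact mutation strings parse to specs", {
  sp <- parse_mutation_spec("C32A,C99G")
  expect_equal(sp$position, c(32L, 99L))
  expect_equal(sp$from_residue, c("CYS", "CYS"))
  expect_equal(sp$to_residue, c("ALA", "GLY"))
  expect_error(parse_mutation_spec("C32Q"), "cannot parse")
})

test_that("region annotation follows the CDR/FR map with unassigned fallback", {
  map <- default_region_map()
  expect_identical(annotate_regions(map, c(30L, 101L, 45L)),
                   c("CDR1", "CDR3", "FR2"))
  expect_identical(annotate_regions(map, 999L), "unassigned")
  expect_error(annotate_regions(
    tibble::tibble(region = c("A", "B"), start = c(1L, 5L), end = c(10L, 8L)),
    3L),
    "overlap")
})

test_that("region maps round trip through YAML and JSON", {
  map <- list(CDR1 = c(23, 37), CDR2 = c(50, 63), CDR3 = c(99, 105))
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(map, fy)
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(map, fj)
  my <- read_region_map(fy)
  mj <- read_region_map(fj)
  expect_identical(my, mj)
  expect_identical(annotate_regions(my, 30L), "CDR1")
  expect_identical(annotate_regions(my, 45L), "unassigned")
})
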