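test_that("Neq hits its closed-form values and bounds", {
  expect_equal(neq(c(1, rep(0, 15))), 1)
  expect_equal(neq(rep(1 / 16, 16)), 16)
  expect_equal(neq(c(0.5, 0.5, rep(0, 14))), 2)
  expect_equal(neq(c(0.5, 0.25, 0.25, rep(0, 13))), 2^1.5)
  withr::with_seed(53, {
    for (i in 1:100) {
      f <- random_simplex()
      v <- neq(f)
      expect_gte(v, 1)
      expect_lte(v, 16 + 1e-12)
      expect_equal(neq(sample(f)), v)  # label-permutation invariance
    }
  })
})

test_that("unnormalized frequency input is rejected, not silently rescaled", {
  expect_error(neq(rep(0.1, 16)), "not normalized")
  expect_error(neq(c(-0.1, 1.1, rep(0, 14))), "negative")
  expect_error(delta_pb(rep(0.2, 16), rep(1 / 16, 16)), "not normalized")
})

test_that("Delta-Neq is the absolute symmetric difference", {
  expect_equal(delta_neq(3, 6), 3)
  expect_equal(delta_neq(4.2, 4.2), 0)
  expect_equal(delta_neq(2, 7), delta_neq(7, 2))
})

test_that("Delta-PB endpoints and halfway case", {
  f1 <- c(1, rep(0, 15))
  f2 <- c(0, 1, rep(0, 14))
  f3 <- c(0.5, 0.5, rep(0, 14))
  expect_equal(delta_pb(f1, f1), 0)
  expect_equal(delta_pb(f1, f2), 2)
  expect_equal(delta_pb(f1, f3), 1)
})

test_that("Delta-PB is a metric on the frequency simplex", {
  withr::with_seed(59, {
    for (i in 1:100) {
      a <- random_simplex(); b <- random_simplex(); c <- random_simplex()
      expect_equal(delta_pb(a, b), delta_pb(b, a))
      expect_lte(delta_pb(a, c), delta_pb(a, b) + delta_pb(b, c) + 1e-12)
      expect_gte(delta_pb(a, b), 0)
      expect_lte(delta_pb(a, b), 2 + 1e-12)
    }
    expect_equal(delta_pb(c(0.3, 0.7, rep(0, 14)), c(0.3, 0.7, rep(0, 14))), 0)
  })
})

test_that("Delta-RMSF is the signed variant-minus-reference difference", {
  a <- c(1.0, 1.5, 2.0)
  expect_equal(delta_rmsf(a, a), c(0, 0, 0))
  expect_equal(delta_rmsf(a + 1, a), c(1, 1, 1))
  expect_equal(delta_rmsf(a, a + 1), -delta_rmsf(a + 1, a))
  expect_error(delta_rmsf(a, a[1:2]), "different lengths")
  t1 <- tibble::tibble(position = 1:3, rmsf = a)
  t2 <- tibble::tibble(position = 1:3, rmsf = a + 0.5)
  expect_equal(delta_rmsf(t2, t1)$delta_rmsf, rep(0.5, 3))
  expect_error(delta_rmsf(t1, tibble::tibble(position = 2:4, rmsf = a)),
               "different positions")
})

test_that("logo matrices slice frequency profiles with rows summing to one", {
  dih <- sample_dihedral_ensemble(20, 100, c(m = 0.7, d = 0.3), seed = 61)
  prof <- pb_frequency_profile(assign_ensemble(dih))
  expect_warning(full <- logo_matrix(prof), "unobserved")
  obs <- prof[prof$n_obs > 0, ]
  expect_equal(nrow(full), nrow(obs))
  expect_equal(unname(full), unname(as.matrix(obs[, pb_labels()])))
  sub <- logo_matrix(prof, 5, 15)
  expect_equal(nrow(sub), 11)
  expect_identical(rownames(sub), as.character(5:15))
  expect_true(all(abs(rowSums(sub) - 1) < 1e-12))
  expect_error(logo_matrix(prof, 50, 60), "no profile positions")
  ## single-conformer position: one column 1.0, rest 0
  pure <- pb_frequency_profile(assign_ensemble(
    sample_dihedral_ensemble(7, 10, c(m = 1), sigma = 0, seed = 1)))
  lm <- logo_matrix(pure, 3, 3)
  expect_equal(unname(lm[1, "m"]), 1)
  expect_equal(sum(lm), 1)
})

test_that("a system compared with itself has all-zero deltas", {
  ens <- perturb_coordinates(build_ideal_conformation("helix", 15), 0.2, 30,
                             seed = 67)
  sp <- system_profile(ens, region_map = default_region_map())
  cmp <- compare_systems(sp, sp)
  obs <- cmp[!is.na(cmp$delta_pb), ]
  expect_gt(nrow(obs), 0)
  expect_true(all(obs$delta_pb == 0))
  expect_true(all(obs$delta_neq == 0))
  expect_true(all(cmp$delta_rmsf == 0))
})

test_that("swapping system order negates Delta-RMSF, preserves Delta-PB and Delta-Neq", {
  e1 <- perturb_coordinates(build_ideal_conformation("helix", 12), 0.15, 25,
                            seed = 71)
  e2 <- perturb_coordinates(build_ideal_conformation("helix", 12), 0.35, 25,
                            seed = 73)
  s1 <- system_profile(e1, label = "sys1")
  s2 <- system_profile(e2, label = "sys2")
  ab <- compare_systems(s1, s2)
  ba <- compare_systems(s2, s1)
  expect_equal(ba$delta_rmsf, -ab$delta_rmsf)
  expect_equal(ba$delta_pb, ab$delta_pb)
  expect_equal(ba$delta_neq, ab$delta_neq)
})

test_that("misaligned systems are rejected with the offending positions", {
  d1 <- sample_dihedral_ensemble(8, 5, c(m = 1), seed = 1)
  d2 <- sample_dihedral_ensemble(8, 5, c(m = 1), seed = 1)
  d2$resno <- d2$resno + 100L
  s1 <- system_profile(d1)
  s2 <- system_profile(d2)
  expect_error(compare_systems(s1, s2), "misaligned position")
})

test_that("positions unobserved in either system get NA deltas, never zero", {
  mk <- function(sym) structure(list(
    pbs = matrix(c(sym, sym, "Z", "Z", sym, sym), nrow = 2),
    resno = 1:3, system_label = "x"), class = "pb_sequences")
  prof1 <- pb_frequency_profile(mk("m"))
  prof2 <- pb_frequency_profile(mk("d"))
  flex <- function(p) tibble::tibble(
    position = p$position, region = "FR1", rmsf = NA_real_,
    neq = c(1, NA, 1), band = NA_character_, n_obs = p$n_obs)
  s1 <- structure(list(label = "a", pb = prof1, flex = flex(prof1), z_rate = 0),
                  class = "system_profile")
  s2 <- structure(list(label = "b", pb = prof2, flex = flex(prof2), z_rate = 0),
                  class = "system_profile")
  cmp <- compare_systems(s1, s2)
  expect_true(is.na(cmp$delta_pb[2]))
  expect_true(is.na(cmp$delta_neq[2]))
  expect_equal(cmp$delta_pb[c(1, 3)], c(2, 2))
})

test_that("region summary reports per-region maxima of the three measures", {
  cmp <- tibble::tibble(
    position = 1:4,
    region = c("CDR1", "CDR1", "FR1", "FR1"),
    rmsf1 = 1, rmsf2 = 1,
    delta_rmsf = c(0.2, -0.9, 0.1, 0),
    neq1 = 1, neq2 = 1,
    delta_neq = c(1, 3, 0.5, NA),
    delta_pb = c(0.25, 1.25, 0.1, NA))
  class(cmp) <- c("pb_comparison", class(cmp))
  s <- region_summary(cmp)
  expect_equal(s$max_delta_pb[s$region == "CDR1"], 1.25)
  expect_equal(s$max_delta_neq[s$region == "CDR1"], 3)
  expect_equal(s$max_abs_delta_rmsf[s$region == "CDR1"], 0.9)
  expect_equal(s$max_delta_pb[s$region == "FR1"], 0.1)
})

test_that("Neq interpretation bands label the stated ranges", {
  expect_identical(neq_band(c(1, 3.9, 4, 5.9, 6, 7.9, 8, 16)),
                   c("rigid", "rigid", "flexible", "flexible",
                     "highly flexible", "highly flexible",
                     "disordered", "disordered"))
  expect_true(is.na(neq_band(NA_real_)))
})
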