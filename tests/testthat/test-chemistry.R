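# Mass engine: modification deltas, propionylation rules, precursor and
# fragment m/z.

test_that("modification deltas match their atomic compositions", {
  d <- mod_deltas()
  expect_equal(unname(d["unmod"]), 0)
  expect_equal(unname(d["me1"]), 14.015650, tolerance = 1e-6)
  expect_equal(unname(d["me2"]), 28.031300, tolerance = 1e-6)
  expect_equal(unname(d["me3"]), 42.046950, tolerance = 1e-6)
  expect_equal(unname(d["ac"]),  42.010565, tolerance = 1e-6)
  expect_equal(unname(d["ph"]),  79.966331, tolerance = 1e-6)
  expect_equal(unname(d["prop"]), 56.026215, tolerance = 1e-6)
  # trimethyl and acetyl are near-isobaric but not equal
  expect_equal(unname(d["me3"] - d["ac"]), 0.036385, tolerance = 1e-6)
})

test_that("propionylation hits the N-terminus and unmod/me1 lysines only", {
  cases <- list(
    # sequence, mods, start, expected propionyl count, expected K sites
    list("KSTGGKAPR", NULL, 9L, 3L, c(9L, 14L)),
    list("KSTGGKAPR", "K9me2", 9L, 2L, 14L),
    list("KSAPASGGVKKPHR", "K27me1K36ac", 27L, 3L, c(27L, 37L))
  )
  for (cs in cases) {
    dp <- derivatize(cs[[1]], cs[[2]], start = cs[[3]])
    expect_true(dp$nterm_prop)
    expect_equal(n_propionyl(dp), cs[[4]])
    expect_equal(dp$prop_sites, cs[[5]])
  }
})

test_that("derivatization is idempotent and validates residue compatibility", {
  dp <- derivatize("KSTGGKAPR", "K9me1S10ph", start = 9)
  expect_equal(derivatize(dp), dp)
  expect_error(derivatize("KSTGGKAPR", "R17ac", start = 9), "cannot sit")
  expect_error(derivatize("KSTGGKAPR", "K9me1K9ac", start = 9), "duplicate")
  expect_error(derivatize("KSTGGKAPR", "K20me1", start = 9), "outside")
  expect_error(derivatize("KSTGGKXPR"), "unknown residue")
})

test_that("precursor m/z reproduces targeted-list values", {
  dp <- derivatize("KQLATKAAR", "K18me1", start = 18)
  expect_equal(round(precursor_mz(dp, 2), 4), 584.8561)
  dp <- derivatize("GKGGKGLGKGGAKR", "K5ac", start = 4)
  expect_equal(round(precursor_mz(dp, 2), 4), 768.9465)
})

test_that("charge algebra holds for any peptide", {
  set.seed(1)
  forms <- the_catalog$forms[sample(nrow(the_catalog$forms), 20), ]
  for (i in seq_len(nrow(forms))) {
    dp <- derivatize(forms$sequence[i], forms$form[i], start = forms$start[i])
    expect_equal(precursor_mz(dp, 1), 2 * precursor_mz(dp, 2) - proton_mass(),
                 tolerance = 1e-9)
    expect_equal(precursor_mz(dp, 3) * 3 - 3 * proton_mass(),
                 precursor_mz(dp, 1) - proton_mass(), tolerance = 1e-9)
  }
})

test_that("fragment m/z matches independent hand sums", {
  # b2 of K9ac form: prop + K + ac + S + proton
  dp9 <- derivatize("KSTGGKAPR", "K9ac", start = 9)
  b2_expect <- 56.026215 + 128.094963 + 42.010565 + 87.032028 + 1.00727646
  expect_equal(fragment_mz(dp9, "b", 2), b2_expect, tolerance = 1e-6)
  expect_equal(round(fragment_mz(dp9, "b", 2), 4), 314.1710)
  # K14ac form differs by ac <-> prop on K9
  dp14 <- derivatize("KSTGGKAPR", "K14ac", start = 9)
  expect_equal(round(fragment_mz(dp14, "b", 2), 4), 328.1867)
  expect_equal(fragment_mz(dp14, "b", 2) - fragment_mz(dp9, "b", 2),
               56.026215 - 42.010565, tolerance = 1e-6)
  # y1 of any ...R peptide is arginine + water + proton
  expect_equal(round(fragment_mz(dp9, "y", 1), 4), 175.1190)
  expect_error(fragment_mz(dp9, "b", 9), "index")
  expect_error(fragment_mz(dp9, "y", 0), "index")
})

test_that("precursor neutral mass equals b_i + y_(n-i) neutral for all i", {
  set.seed(2)
  forms <- the_catalog$forms[sample(nrow(the_catalog$forms), 15), ]
  for (i in seq_len(nrow(forms))) {
    dp <- derivatize(forms$sequence[i], forms$form[i], start = forms$start[i])
    n <- nchar(dp$sequence)
    M <- neutral_mass(dp)
    for (j in seq_len(n - 1)) {
      b <- fragment_mz(dp, "b", j) - proton_mass()
      y <- fragment_mz(dp, "y", n - j) - proton_mass()
      expect_equal(b + y, M, tolerance = 1e-8)
    }
  }
})

test_that("me3/ac resolvability is computed from m/z, charge and tolerance", {
  # brute force over all same-backbone form pairs: a pair is grouped at
  # 10 ppm iff its computed delta-ppm is below tolerance
  f <- the_catalog$forms
  grp <- detect_isobaric_groups(the_catalog, ppm_tol = 10)
  for (bb in unique(f$backbone)) {
    b <- grp[grp$backbone == bb, ]
    for (i in seq_len(nrow(b) - 1)) {
      for (j in (i + 1):nrow(b)) {
        dppm <- abs(b$mz[i] - b$mz[j]) / b$mz[i] * 1e6
        same <- b$group[i] == b$group[j]
        if (dppm <= 10) expect_true(same) else
          if (!same) expect_gt(dppm, 10)
      }
    }
  }
  # me3-only vs ac-only forms are never grouped at 10 ppm for 2+ backbones
  # under m/z 1800 (0.036385 Da / 2 at those m/z always exceeds 10 ppm)
  me3 <- grp[grepl("me3", grp$form) & !grepl("ac", grp$form) &
             grp$charge == 2 & grp$mz < 1800, ]
  for (i in seq_len(nrow(me3))) {
    ac_twin <- grp[grp$backbone == me3$backbone[i] &
                   grp$form == sub("me3", "ac", me3$form[i]), ]
    if (nrow(ac_twin) == 1L) {
      expect_false(me3$group[i] == ac_twin$group)
    }
  }
})
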