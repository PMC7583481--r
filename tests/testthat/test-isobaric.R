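# Fragment signatures and MS2-based area splitting.

test_that("K9ac/K14ac signatures contain the hand-verified b2 ions", {
  members <- list(K9ac = derivatize("KSTGGKAPR", "K9ac", start = 9),
                  K14ac = derivatize("KSTGGKAPR", "K14ac", start = 9))
  sig <- discriminating_fragments(members, ppm = 20)
  b2_9 <- sig$K9ac[sig$K9ac$series == "b" & sig$K9ac$index == 2, "mz"]
  b2_14 <- sig$K14ac[sig$K14ac$series == "b" & sig$K14ac$index == 2, "mz"]
  expect_equal(round(b2_9, 4), 314.1710)
  expect_equal(round(b2_14, 4), 328.1867)
  # signatures are pairwise disjoint
  expect_true(all(vapply(sig$K9ac$mz, function(m)
    all(abs(sig$K14ac$mz - m) / m * 1e6 > 20), logical(1))))
  expect_length(attr(sig, "indistinguishable"), 0L)
})

test_that("a group of one is trivially split", {
  members <- list(K9ac = derivatize("KSTGGKAPR", "K9ac", start = 9))
  sig <- discriminating_fragments(members)
  sp <- split_area(100, NULL, sig)
  expect_equal(unname(sp$areas), 100)
  expect_equal(sp$flag, "ok")
})

test_that("the 4-member triacetyl groups are separable via position subgroups", {
  # middle members of these groups retain no unique singly charged b/y ion,
  # but every member is separated from every other at some cleavage position
  grp <- detect_isobaric_groups(the_catalog, ppm_tol = 10)
  g3 <- grp[grp$backbone == "H2AV_1_21_AGGKGKAGKDSGKSKSKVVSR" &
            grp$form == "K9acK13acK17ac", ]
  members_df <- grp[grp$group_id == g3$group_id, ]
  expect_equal(nrow(members_df), 4L)
  members <- lapply(seq_len(nrow(members_df)), function(i)
    derivatize(members_df$sequence[i], members_df$form[i],
               start = members_df$start[i]))
  names(members) <- members_df$form
  sig <- discriminating_fragments(members, ppm = 20)
  expect_length(attr(sig, "indistinguishable"), 0L)
  n_unique <- vapply(sig, nrow, integer(1))
  expect_true(any(n_unique == 0L))    # the middle members
  expect_true(any(n_unique > 0L))     # the edge members
  expect_gt(nrow(attr(sig, "positions")), 0L)
})

test_that("split recovers a 70/30 pair exactly from noiseless MS2", {
  truth <- sample_ground_truth(the_catalog, seed = 9,
                               backbones = "H3_9_17_KSTGGKAPR",
                               coelution_spread = 0)
  i9 <- which(truth$forms$form == "K9ac")
  i14 <- which(truth$forms$form == "K14ac")
  truth$forms$fraction[] <- 0
  truth$forms$fraction[i9] <- 0.7
  truth$forms$fraction[i14] <- 0.3
  truth$forms$total <- 1e9
  run <- simulate_run(the_catalog, truth, seed = 9)
  q <- quantify_run(run, the_catalog)
  r <- q$ratios[q$ratios$backbone == "H3_9_17_KSTGGKAPR", ]
  expect_lt(abs(r$ratio[r$form == "K9ac"] - 0.7), 0.03)
  expect_lt(abs(r$ratio[r$form == "K14ac"] - 0.3), 0.03)
})

test_that("split areas are conserved exactly and permutation-equivariant", {
  members <- list(K9ac = derivatize("KSTGGKAPR", "K9ac", start = 9),
                  K14ac = derivatize("KSTGGKAPR", "K14ac", start = 9))
  sig <- discriminating_fragments(members, ppm = 20)
  set.seed(31)
  for (rep in 1:20) {
    w_true <- stats::runif(1)
    ms2 <- do.call(rbind, lapply(1:5, function(s) {
      eff <- stats::runif(nrow(sig$K9ac), 0.3, 1)
      rbind(data.frame(scan = s, mz = sig$K9ac$mz,
                       intensity = w_true * eff),
            data.frame(scan = s, mz = sig$K14ac$mz,
                       intensity = (1 - w_true) * eff))
    }))
    area <- stats::runif(1, 1e6, 1e9)
    sp <- split_area(area, ms2, sig)
    expect_equal(sum(sp$areas), area, tolerance = 1e-14)  # conservation
    # permuting member labels permutes the outputs identically
    sig_rev <- discriminating_fragments(rev(members), ppm = 20)
    sp_rev <- split_area(area, ms2, sig_rev)
    expect_equal(sp_rev$areas[names(sp$areas)], sp$areas)
  }
})

test_that("only one member's fragments observed gives it all the area", {
  members <- list(K9ac = derivatize("KSTGGKAPR", "K9ac", start = 9),
                  K14ac = derivatize("KSTGGKAPR", "K14ac", start = 9))
  sig <- discriminating_fragments(members, ppm = 20)
  ms2 <- data.frame(scan = 1L, mz = sig$K9ac$mz, intensity = 1)
  sp <- split_area(50, ms2, sig)
  expect_equal(unname(sp$areas["K9ac"]), 50)
  expect_equal(unname(sp$areas["K14ac"]), 0)
  # equal unique-ion intensities every scan split 50/50
  ms2b <- rbind(ms2, data.frame(scan = 1L, mz = sig$K14ac$mz, intensity = 1))
  ms2b$intensity <- 1
  # use equal numbers of matched ions per member for exact symmetry
  n <- min(nrow(sig$K9ac), nrow(sig$K14ac))
  ms2c <- data.frame(scan = 1L,
                     mz = c(sig$K9ac$mz[seq_len(n)],
                            sig$K14ac$mz[seq_len(n)]),
                     intensity = 1)
  sp <- split_area(80, ms2c, sig)
  expect_equal(unname(sp$areas), c(40, 40))
})

test_that("no qualifying MS2 yields an unresolved aggregate; negatives error", {
  members <- list(K9ac = derivatize("KSTGGKAPR", "K9ac", start = 9),
                  K14ac = derivatize("KSTGGKAPR", "K14ac", start = 9))
  sig <- discriminating_fragments(members, ppm = 20)
  sp <- split_area(10, NULL, sig)
  expect_equal(sp$flag, "unresolved")
  expect_equal(unname(sp$areas["aggregate"]), 10)
  expect_true(all(is.na(sp$areas[c("K9ac", "K14ac")])))
  bad <- data.frame(scan = 1L, mz = sig$K9ac$mz[1], intensity = -1)
  expect_error(split_area(10, bad, sig), "negative")
})

test_that("median split error stays below 5% under log-normal MS2 noise", {
  members <- list(K9ac = derivatize("KSTGGKAPR", "K9ac", start = 9),
                  K14ac = derivatize("KSTGGKAPR", "K14ac", start = 9))
  sig <- discriminating_fragments(members, ppm = 20)
  errs <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    w_true <- stats::runif(1, 0.1, 0.9)
    eff <- stats::runif(nrow(sig$K9ac), 0.3, 1)
    ms2 <- do.call(rbind, lapply(1:10, function(sc) {
      noise <- exp(stats::rnorm(2 * length(eff), 0, 0.2))
      rbind(data.frame(scan = sc, mz = sig$K9ac$mz,
                       intensity = w_true * eff *
                         noise[seq_along(eff)]),
            data.frame(scan = sc, mz = sig$K14ac$mz,
                       intensity = (1 - w_true) * eff *
                         noise[-seq_along(eff)]))
    }))
    sp <- split_area(1, ms2, sig)
    abs(unname(sp$areas["K9ac"]) - w_true)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})
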