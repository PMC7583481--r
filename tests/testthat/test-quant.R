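# Ratio tables, single-PTM summation, variant abundance.

test_that("backbone ratios normalize over the full catalog denominator", {
  areas <- data.frame(backbone = "H3_9_17_KSTGGKAPR",
                      form = c("unmod", "K9me1"), area = c(3, 1))
  rt <- backbone_ratios(areas, the_catalog)
  expect_equal(nrow(rt), 20L)  # both published rows of the backbone
  expect_equal(rt$ratio[rt$form == "unmod"], 0.75)
  expect_equal(rt$ratio[rt$form == "K9me1"], 0.25)
  expect_equal(rt$ratio[rt$form == "S10ph"], 0)      # kept, not dropped
  expect_equal(sum(rt$ratio), 1)
  # single nonzero form gets ratio 1
  one <- backbone_ratios(data.frame(backbone = "H3_3_8_TKQTAR",
                                    form = "K4me2", area = 5), the_catalog)
  expect_equal(one$ratio[one$form == "K4me2"], 1)
  # all-zero block is flagged
  zero <- backbone_ratios(data.frame(backbone = "H3_3_8_TKQTAR",
                                     form = "K4me2", area = 0), the_catalog)
  expect_true(all(is.na(zero$ratio)))
  expect_true(all(zero$flag == "no_signal"))
})

test_that("ratios are invariant to rescaling all areas", {
  set.seed(21)
  areas <- data.frame(backbone = "H3_27_40_KSAPASGGVKKPHR",
                      form = the_catalog$forms$form[
                        the_catalog$forms$backbone ==
                          "H3_27_40_KSAPASGGVKKPHR"],
                      area = stats::runif(25, 0, 1e9))
  r1 <- backbone_ratios(areas, the_catalog)
  areas$area <- areas$area * 17.3
  r2 <- backbone_ratios(areas, the_catalog)
  expect_equal(r1$ratio, r2$ratio)
})

test_that("single-PTM ratios sum all forms carrying the mark", {
  # uniform ratios over the 25 forms of H3 27-40: K27me1 appears in 5 forms
  areas <- data.frame(backbone = "H3_27_40_KSAPASGGVKKPHR",
                      form = the_catalog$forms$form[
                        the_catalog$forms$backbone ==
                          "H3_27_40_KSAPASGGVKKPHR"],
                      area = 1)
  sp <- single_ptm_ratios(backbone_ratios(areas, the_catalog))
  expect_equal(sp$ratio[sp$mark == "H3K27me1"], 5 / 25)
  expect_equal(sp$ratio[sp$mark == "H3K36ac"], 5 / 25)
  # H3K14ac sums across the unphosphorylated and phosphorylated series
  areas2 <- data.frame(backbone = "H3_9_17_KSTGGKAPR",
                       form = c("K14ac", "S10phK14ac", "unmod"),
                       area = c(1, 1, 2))
  sp2 <- single_ptm_ratios(backbone_ratios(areas2, the_catalog))
  expect_equal(sp2$ratio[sp2$mark == "H3K14ac"], 0.5)
  expect_equal(sp2$ratio[sp2$mark == "H3S10ph"], 0.25)
  # a backbone with only unmod detected has zero for every mark
  areas3 <- data.frame(backbone = "H3_3_8_TKQTAR", form = "unmod", area = 9)
  sp3 <- single_ptm_ratios(backbone_ratios(areas3, the_catalog))
  expect_true(all(sp3$ratio == 0))
  expect_true(all(sp3$ratio >= 0 & sp3$ratio <= 1))
})

test_that("variant fractions per pair and pooled behave as ratios of areas", {
  areas <- data.frame(
    sequence = c("YRPGTVALR", "FRPGTVALR", "VTIMPKDIQLAR", "VTIMPKDMQLAR",
                 "HLQLAVR", "HLHLAIR"),
    area = c(80, 20, 50, 50, 100, 0))
  va <- variant_abundance(areas, the_catalog)
  p <- va$pairs
  expect_equal(p$fraction[p$variant_seq == "FRPGTVALR"], 0.2)
  expect_equal(p$fraction[p$variant_seq == "VTIMPKDMQLAR"], 0.5)
  expect_equal(p$fraction[p$variant_seq == "HLHLAIR"], 0)
  # pooled H3.3V estimate is the area-weighted mean over its two pairs
  pooled <- va$pooled$fraction[va$pooled$variant_label == "H3.3V"]
  expect_equal(pooled, (0.2 * 100 + 0.5 * 100) / 200)
  # both areas zero flags the pair as missing
  va2 <- variant_abundance(data.frame(sequence = "YRPGTVALR", area = 0),
                           the_catalog)
  expect_true("missing" %in% va2$pairs$flag)
})

test_that("a simulated variant spike is recovered by the full pipeline", {
  truth <- sample_ground_truth(
    the_catalog, seed = 13,
    backbones = c("H3_54_63_YQKSTELLIR", "H2A_37_43_KGNYAQR"),
    variant_fraction = c("H3.3V" = 0.2, "H2AV" = 0.15, "H1.0" = 0.1))
  run <- simulate_run(the_catalog, truth, seed = 13)
  q <- quantify_run(run, the_catalog)
  pooled <- q$variants$pooled
  expect_lt(abs(pooled$fraction[pooled$variant_label == "H3.3V"] - 0.2),
            0.02)
  expect_lt(abs(pooled$fraction[pooled$variant_label == "H2AV"] - 0.15),
            0.02)
})
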