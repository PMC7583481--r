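# Shared fixtures: the shipped catalog, a mid-size backbone panel used for
# closed-loop simulations, and small hand-built runs.

the_catalog <- suppressMessages(load_catalog())

# panel of backbones whose isobaric groups are all fully identifiable from
# singly charged b/y ions (2- and 4-member groups; no degenerate 6-member
# double-acetyl group) and which avoids the H3 73-83 / H2B 31-40 m/z
# near-collision
recovery_panel <- c(
  "H3_3_8_TKQTAR", "H3_9_17_KSTGGKAPR", "H3_18_26_KQLATKAAR",
  "H3_27_40_KSAPASGGVKKPHR", "H3_54_63_YQKSTELLIR", "H4_20_23_KVLR",
  "H2B_31_40_KESYSVYIYR"
)

# a minimal ms_run built directly from scan tables
make_run <- function(ms1, ms2 = NULL, scan_times = NULL) {
  if (is.null(scan_times)) scan_times <- sort(unique(ms1$rt))
  if (is.null(ms2)) {
    ms2 <- data.frame(scan = integer(), rt = numeric(),
                      precursor_mz = numeric(), mz = numeric(),
                      intensity = numeric())
  }
  structure(list(ms1 = ms1, ms2 = ms2, scan_times = scan_times,
                 meta = list(seed = NA_integer_)),
            class = "ms_run")
}

# a run containing one Gaussian peak at a single m/z
gaussian_run <- function(mz, apex, sigma = 0.05, area = 1e9,
                         rt_max = 10, dt = 0.02) {
  times <- seq(0, rt_max, by = dt)
  amp <- area / (sigma * sqrt(2 * pi))
  ms1 <- data.frame(scan = seq_along(times), rt = times, mz = mz,
                    intensity = amp * exp(-(times - apex)^2 / (2 * sigma^2)))
  ms1 <- ms1[ms1$intensity > 0, ]
  make_run(ms1, scan_times = times)
}
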