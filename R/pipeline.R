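# End-to-end orchestration: simulate runs, quantify runs against the catalog
# (extraction -> isobaric splitting -> ratio tables), and run the
# differential statistics; TSV outputs with provenance headers.

#' Pipeline configuration
#'
#' @param ms1_ppm MS1 extraction and isobaric-grouping tolerance in ppm.
#' @param ms2_ppm MS2 fragment match tolerance in ppm (independent of MS1).
#' @param pseudo_ratio Floor applied to ratios before log2 in the statistics
#'   stage.
#' @param baseline_frac Peak-detection threshold as a fraction of the window
#'   maximum.
#' @param envelope_correction Divide each monoisotopic XIC area by the
#'   modeled isotopologue-0 envelope share, so areas estimate total species
#'   abundance rather than the monoisotopic slice.
#' @param seed Seed recorded in output headers (and used by
#'   [run_simulate()]).
#' @param sim [sim_params()] used by the simulator stage.
#' @param contrasts Default contrast list for the statistics stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ms1_ppm = 10, ms2_ppm = 20, pseudo_ratio = 1e-6,
                            baseline_frac = 0.01,
                            envelope_correction = TRUE, seed = 1L,
                            sim = sim_params(), contrasts = NULL) {
  stopifnot(ms1_ppm > 0, ms2_ppm > 0)
  structure(list(ms1_ppm = ms1_ppm, ms2_ppm = ms2_ppm,
                 pseudo_ratio = pseudo_ratio,
                 baseline_frac = baseline_frac,
                 envelope_correction = envelope_correction,
                 seed = as.integer(seed), sim = sim, contrasts = contrasts),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "seed")]), tmp)
  unname(tools::md5sum(tmp))
}

.provenance_header <- function(catalog, config) {
  c(sprintf("# histoneptm %s", as.character(utils::packageVersion("histoneptm"))),
    sprintf("# catalog %s", catalog$version),
    sprintf("# config %s", .config_hash(config)),
    sprintf("# seed %d", config$seed))
}

#' Quantify one run against the catalog
#'
#' For every backbone, forms are grouped into isobaric clusters at the MS1
#' tolerance and the backbone's quantification charge; each cluster's XIC is
#' extracted and its main peak integrated. Multi-member clusters are split
#' among members using unique b/y fragment ions from MS2 scans whose
#' precursor matches the cluster and whose RT falls inside the integrated
#' MS1 peak; clusters with no usable MS2 evidence are reported as an
#' `aggregate` pseudo-form flagged `unresolved`. Variant-marker peptides are
#' quantified from their own XICs. Areas are envelope-corrected by default.
#'
#' @param run An `ms_run`.
#' @param catalog A `histone_catalog`.
#' @param config A [pipeline_config()].
#' @return A list of class `quant_result`: `peaks` (per-form RT/area/flag),
#'   `ratios` (per-backbone [backbone_ratios()] table), `single_ptms`,
#'   `variants` (from [variant_abundance()]), `splits` (per-group audit of
#'   isobaric splits).
#' @export
quantify_run <- function(run, catalog, config = pipeline_config()) {
  stopifnot(inherits(run, "ms_run"), inherits(catalog, "histone_catalog"))
  if (nrow(run$ms1) == 0L) stop("run has no MS1 centroids")
  grp <- detect_isobaric_groups(catalog, ppm_tol = config$ms1_ppm)

  # candidate peaks in decreasing height; reject any whose XIC one isotope
  # spacing below carries > half the apex intensity (such a "peak" is the
  # +1 isotopologue of a lighter species, not a monoisotopic peak)
  accepted_peaks <- function(mz, charge) {
    trace <- extract_xic(run, mz, ppm = config$ms1_ppm)
    pks <- find_peaks(trace, baseline_frac = config$baseline_frac)
    if (length(pks) == 0L) return(list())
    left <- extract_xic(run, mz - .C13_DELTA / charge, ppm = config$ms1_ppm)
    Filter(function(pk) {
      at_apex <- left$intensity[which.min(abs(left$rt - pk$apex_rt))]
      at_apex <= 0.5 * pk$apex_intensity
    }, pks)
  }
  pick_peak <- function(mz, charge) {
    pks <- accepted_peaks(mz, charge)
    if (length(pks)) return(pks[[1]])
    structure(list(area = 0, apex_rt = NA_real_,
                   bounds = c(NA_real_, NA_real_), flag = "not_detected"),
              class = "peak_result")
  }

  peak_rows <- list(); split_rows <- list(); k <- 0L; ks <- 0L
  for (gid in sort(unique(grp$group_id))) {
    g <- grp[grp$group_id == gid, , drop = FALSE]
    mz <- mean(g$mz)
    pks <- accepted_peaks(mz, g$charge[1])
    env0 <- isotope_envelope(mz * g$charge[1] - g$charge[1] * .PROTON, 1)
    corr <- if (config$envelope_correction) env0 else 1
    if (length(pks) == 0L) {
      for (m in seq_len(nrow(g))) {
        k <- k + 1L
        peak_rows[[k]] <- data.frame(
          backbone = g$backbone[m], form = g$form[m], mz = g$mz[m],
          rt = NA_real_, area = 0, flag = "not_detected",
          stringsAsFactors = FALSE)
      }
      next
    }
    if (nrow(g) == 1L) {
      pk <- pks[[1]]
      k <- k + 1L
      peak_rows[[k]] <- data.frame(
        backbone = g$backbone, form = g$form, mz = g$mz, rt = pk$apex_rt,
        area = pk$area / corr, flag = "ok", stringsAsFactors = FALSE)
      next
    }
    # isobaric cluster: split every accepted MS1 peak by the MS2 scans that
    # fall inside it, then sum each member's shares across peaks
    members <- lapply(seq_len(nrow(g)), function(m)
      derivatize(g$sequence[m], g$form[m], start = g$start[m]))
    names(members) <- g$form
    sig <- discriminating_fragments(members, ppm = config$ms2_ppm)
    tol <- mz * config$ms1_ppm * 1e-6
    m_area <- stats::setNames(numeric(nrow(g)), g$form)
    m_best <- stats::setNames(rep(NA_real_, nrow(g)), g$form)
    m_share <- stats::setNames(numeric(nrow(g)), g$form)
    agg_area <- 0; agg_rt <- NA_real_
    any_resolved <- FALSE; n_scans <- 0L
    for (pk in pks) {
      area <- pk$area / corr
      ms2 <- run$ms2[abs(run$ms2$precursor_mz - mz) <= tol &
                     run$ms2$rt >= pk$bounds[1] &
                     run$ms2$rt <= pk$bounds[2], , drop = FALSE]
      sp <- split_area(area, ms2, sig, ppm = config$ms2_ppm)
      if (sp$flag == "unresolved") {
        agg_area <- agg_area + area
        if (is.na(agg_rt)) agg_rt <- pk$apex_rt
      } else {
        any_resolved <- TRUE
        n_scans <- n_scans + if (is.null(sp$scan_weights)) 0L else
          nrow(sp$scan_weights)
        for (m in g$form) {
          m_area[m] <- m_area[m] + sp$areas[m]
          if (sp$areas[m] > m_share[m]) {
            m_share[m] <- sp$areas[m]
            m_best[m] <- pk$apex_rt
          }
        }
      }
    }
    if (any_resolved) {
      for (m in seq_len(nrow(g))) {
        k <- k + 1L
        peak_rows[[k]] <- data.frame(
          backbone = g$backbone[m], form = g$form[m], mz = g$mz[m],
          rt = m_best[g$form[m]], area = unname(m_area[g$form[m]]),
          flag = "isobaric_split", stringsAsFactors = FALSE)
      }
    } else {
      for (m in seq_len(nrow(g))) {
        k <- k + 1L
        peak_rows[[k]] <- data.frame(
          backbone = g$backbone[m], form = g$form[m], mz = g$mz[m],
          rt = agg_rt, area = NA_real_, flag = "unresolved",
          stringsAsFactors = FALSE)
      }
    }
    if (agg_area > 0) {
      k <- k + 1L
      peak_rows[[k]] <- data.frame(
        backbone = g$backbone[1],
        form = paste0("aggregate(", paste(g$form, collapse = "/"), ")"),
        mz = mz, rt = agg_rt, area = agg_area, flag = "unresolved",
        stringsAsFactors = FALSE)
    }
    ks <- ks + 1L
    split_rows[[ks]] <- data.frame(
      group_id = gid, mz = mz, n_members = nrow(g), n_peaks = length(pks),
      n_ms2_scans = n_scans,
      flag = if (any_resolved) "ok" else "unresolved",
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peak_rows)
  ratios <- backbone_ratios(peaks, catalog)
  sptm <- single_ptm_ratios(ratios)

  vr <- catalog$variants
  v_area <- vapply(seq_len(nrow(vr)), function(i) {
    pk <- pick_peak(vr$mz[i], vr$charge[i])
    if (pk$flag == "not_detected") return(0)
    corr <- if (config$envelope_correction)
      isotope_envelope(vr$neutral_mass[i], 1) else 1
    pk$area / corr
  }, numeric(1))
  variants <- variant_abundance(
    data.frame(sequence = vr$sequence, area = v_area,
               stringsAsFactors = FALSE), catalog)

  structure(list(peaks = peaks, ratios = ratios, single_ptms = sptm,
                 variants = variants,
                 splits = if (ks) do.call(rbind, split_rows) else NULL),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant result: %d forms, %d marks, %d variant pairs>\n",
              nrow(x$ratios), nrow(x$single_ptms),
              nrow(x$variants$pairs)))
  invisible(x)
}

.write_table_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Simulate runs and write them with their ground truth
#'
#' Draws a ground truth per run (seeds `seed`, `seed + 1`, ...) and writes
#' each run plus a `ground_truth_<i>.tsv` of the true form fractions,
#' enabling closed-loop recovery tests.
#'
#' @param out_dir Output directory.
#' @param catalog A `histone_catalog`.
#' @param config A [pipeline_config()]; `config$sim` controls the simulator
#'   and `config$seed` the first run's seed.
#' @param n_runs Number of runs.
#' @param format Run file format (`"mzML"` or `"internal"`).
#' @param ... Passed to [sample_ground_truth()] (e.g. `backbones`,
#'   `concentration`).
#' @return Invisibly, a data frame listing the files written.
#' @export
run_simulate <- function(out_dir, catalog = load_catalog(),
                         config = pipeline_config(), n_runs = 1L,
                         format = c("internal", "mzML"), ...) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "mzML") ".mzML" else ".tsv"
  files <- lapply(seq_len(n_runs), function(i) {
    seed_i <- config$seed + i - 1L
    truth <- sample_ground_truth(catalog, seed = seed_i, ...)
    run <- simulate_run(catalog, truth, params = config$sim, seed = seed_i)
    run_path <- file.path(out_dir, sprintf("run_%03d%s", i, ext))
    write_run(run, run_path, format = format)
    gt_path <- file.path(out_dir, sprintf("ground_truth_%03d.tsv", i))
    gt <- truth$forms[, c("backbone", "form", "fraction", "apex_rt",
                          "sigma", "total")]
    cfg_i <- config; cfg_i$seed <- seed_i
    .write_table_with_header(gt, gt_path,
                             .provenance_header(catalog, cfg_i))
    data.frame(run = run_path, ground_truth = gt_path, seed = seed_i,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, files))
}

#' Quantify run files and write the output tables
#'
#' For each readable run file, writes `histone_ratios.tsv` (per-form RT,
#' area, ratio per backbone), `histone_ratios_single_PTMs.tsv` and
#' `variant_ratios.tsv`, each with a provenance header (tool version,
#' catalog version, config hash, seed), plus a `peak_decisions.tsv` log of
#' every peak and isobaric split.
#'
#' @param files Character vector of run files (mzML or internal format).
#' @param catalog A `histone_catalog`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; one subdirectory per run.
#' @return Invisibly, a list of `quant_result`s named by run file.
#' @export
run_quantify <- function(files, catalog = load_catalog(),
                         config = pipeline_config(), out_dir = ".") {
  stopifnot(length(files) >= 1L)
  hdr <- .provenance_header(catalog, config)
  res <- lapply(files, function(f) {
    run <- read_run(f)
    q <- quantify_run(run, catalog, config)
    sub <- file.path(out_dir, sub("\\.[^.]+$", "", basename(f)))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    rat <- q$ratios
    out <- data.frame(Histone = rat$histone,
                      Peptide = sprintf("%s(%s_%d_%d)", rat$form,
                                        rat$histone, rat$start, rat$end),
                      `RT (min)` = round(rat$rt, 2),
                      Area = signif(rat$area, 6),
                      Ratio = round(rat$ratio, 6),
                      Flag = rat$flag,
                      check.names = FALSE, stringsAsFactors = FALSE)
    .write_table_with_header(out, file.path(sub, "histone_ratios.tsv"), hdr)
    sp <- q$single_ptms
    sp$ratio <- round(sp$ratio, 6)
    .write_table_with_header(
      sp[, c("mark", "ratio")],
      file.path(sub, "histone_ratios_single_PTMs.tsv"), hdr)
    vp <- q$variants$pairs
    vp$fraction <- round(vp$fraction, 6)
    .write_table_with_header(vp, file.path(sub, "variant_ratios.tsv"), hdr)
    .write_table_with_header(q$peaks, file.path(sub, "peak_decisions.tsv"),
                             hdr)
    if (!is.null(q$splits)) {
      .write_table_with_header(q$splits,
                               file.path(sub, "isobaric_splits.tsv"), hdr)
    }
    q
  })
  names(res) <- files
  invisible(res)
}

#' Differential statistics over quantified samples
#'
#' Assembles the per-sample single-PTM tables into the long format expected
#' by [fit_mark_model()], fits the batch-aware model, and (optionally)
#' writes the per-contrast results plus a heatmap-ready log2 fold-change
#' matrix with hierarchically clustered row order.
#'
#' @param single_ptms Named list of per-sample single-PTM data frames
#'   (columns `mark`, `ratio`), names matching `sheet$sample`.
#' @param sheet Sample sheet (`sample`, `condition`, `batch`).
#' @param contrasts List of contrasts `c(A, B)`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param catalog Catalog used only for output provenance headers.
#' @return A list with `results` (per mark x contrast) and `fc_matrix`
#'   (marks x contrasts, rows in clustered order when >= 2 marks).
#' @export
run_stats <- function(single_ptms, sheet, contrasts,
                      config = pipeline_config(), out_dir = NULL,
                      catalog = NULL) {
  long <- do.call(rbind, lapply(names(single_ptms), function(s) {
    d <- single_ptms[[s]]
    data.frame(sample = s, mark = d$mark, ratio = d$ratio,
               stringsAsFactors = FALSE)
  }))
  res <- fit_mark_model(long, sheet, contrasts,
                        pseudo_ratio = config$pseudo_ratio)
  fc <- stats::xtabs(log2fc ~ mark + contrast, data = res)
  fc <- matrix(fc, nrow = nrow(fc), dimnames = dimnames(fc))
  if (nrow(fc) >= 2L) {
    cl <- cluster_marks(fc)
    fc <- fc[cl$order, , drop = FALSE]
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- if (!is.null(catalog)) .provenance_header(catalog, config) else
      sprintf("# histoneptm %s",
              as.character(utils::packageVersion("histoneptm")))
    .write_table_with_header(res, file.path(out_dir, "mark_contrasts.tsv"),
                             hdr)
    fc_df <- data.frame(mark = rownames(fc), fc, check.names = FALSE)
    .write_table_with_header(fc_df, file.path(out_dir, "heatmap_matrix.tsv"),
                             hdr)
  }
  list(results = res, fc_matrix = fc)
}
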