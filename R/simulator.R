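# Synthetic-run generator: centroided MS1 scans and targeted MS2 scans for
# catalog peptides with known ground-truth form fractions, so extraction,
# isobaric splitting and quantification are testable end to end.

#' Simulation parameters
#'
#' Defaults emulate the acquisition design the pipeline was built for: a
#' 70-minute gradient, MS1 scans every 0.02 min (>= 10 points across a peak of
#' sigma 0.05 min), an isotope envelope of depth 3, and targeted MS2 scans
#' inside each isobaric group's elution window. Noise is off by default;
#' `noise_sd` adds multiplicative log-normal noise per centroid and
#' `ppm_jitter` adds uniform m/z jitter.
#'
#' @param scan_interval MS1 scan spacing in minutes.
#' @param rt_max Gradient length in minutes.
#' @param envelope_depth Number of isotopologues simulated per species.
#' @param noise_sd Log-normal sigma of multiplicative intensity noise.
#' @param ppm_jitter Half-width (ppm) of uniform m/z jitter.
#' @param ms2_every Emit one targeted MS2 scan per this many MS1 scans inside
#'   a group's elution window.
#' @param ms2_scale Overall MS2 intensity scale relative to MS1.
#' @param frag_eff_range Range of the per-fragment-position fragmentation
#'   efficiency, drawn uniformly once per backbone per run.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(scan_interval = 0.02, rt_max = 70,
                       envelope_depth = 3, noise_sd = 0, ppm_jitter = 0,
                       ms2_every = 3, ms2_scale = 0.5,
                       frag_eff_range = c(0.3, 1)) {
  structure(list(scan_interval = scan_interval, rt_max = rt_max,
                 envelope_depth = envelope_depth, noise_sd = noise_sd,
                 ppm_jitter = ppm_jitter, ms2_every = ms2_every,
                 ms2_scale = ms2_scale, frag_eff_range = frag_eff_range),
            class = "sim_params")
}

#' Isotope envelope model
#'
#' Binomial averagine-style envelope: the number of carbons is estimated from
#' the peptide mass (4.9384 C per 111.1254 Da of averagine), and isotopologue
#' abundances follow `dbinom(k, nC, p13C)` with the natural 13C abundance.
#' Only the first `depth` isotopologues are modeled; their shares deliberately
#' do not sum to 1, so that the monoisotopic share is the true fraction of
#' the full envelope carried by isotopologue 0.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param depth Number of isotopologues.
#' @return Numeric vector of envelope shares for isotopologues `0:(depth-1)`.
#' @export
isotope_envelope <- function(mass, depth = 3) {
  n_c <- round(mass * 4.9384 / 111.1254)
  stats::dbinom(seq_len(depth) - 1L, n_c, 0.0107)
}

#' Draw a ground truth for a simulated run
#'
#' Per backbone, form fractions are drawn from a symmetric Dirichlet with
#' concentration `concentration`, and a total abundance (arbitrary area
#' units) is drawn log-uniformly from `total_range`. All members of an
#' isobaric group (detected at `ms1_ppm` and the backbone's quantification
#' charge) co-elute at one apex; groups matching a targeted-list entry elute
#' inside that entry's retention-time window, all other species anywhere in
#' the mid-gradient. Apexes of same-m/z species from *different* backbones
#' are pushed apart so that accidental cross-backbone interference does not
#' occur (the intended interference -- within-backbone isobars -- remains).
#' Variant-marker abundances are split between canonical and variant peptides
#' according to `variant_fraction`.
#'
#' @param catalog A `histone_catalog`.
#' @param concentration Symmetric Dirichlet concentration parameter (> 0).
#' @param seed Integer seed; the draw is deterministic per seed.
#' @param backbones Optional character vector of backbone ids to restrict to.
#' @param sigma Chromatographic peak sigma in minutes.
#' @param total_range Range of per-backbone total abundance (log-uniform).
#' @param variant_fraction Named vector of variant fractions per variant
#'   label (fraction of a marker pair's abundance carried by the variant).
#' @param ms1_ppm Tolerance used to decide which forms co-elute as isobars.
#' @param coelution_spread Width (min) of the uniform spread of isobaric
#'   members around their cluster apex; positional isomers co-elute only
#'   approximately on a real gradient, and this partial separation is what
#'   per-peak MS2 splitting exploits.
#' @return An object of class `ground_truth` with data frames `forms`
#'   (fraction, apex RT, sigma, cluster id per form), `backbones` (totals)
#'   and `variants`.
#' @export
sample_ground_truth <- function(catalog, concentration = 1, seed = 1,
                                backbones = NULL, sigma = 0.05,
                                total_range = c(5e8, 5e9),
                                variant_fraction = c("H3.3V" = 0.2,
                                                     "H2AV" = 0.15,
                                                     "H1.0" = 0.10),
                                ms1_ppm = 10, coelution_spread = 2) {
  stopifnot(concentration > 0, sigma > 0)
  set.seed(as.integer(seed))
  grp <- detect_isobaric_groups(catalog, ppm_tol = ms1_ppm)
  if (!is.null(backbones)) grp <- grp[grp$backbone %in% backbones, ]
  if (nrow(grp) == 0L) stop("no catalog forms selected")

  bb_ids <- unique(grp$backbone)
  totals <- data.frame(
    backbone = bb_ids,
    total = 10 ^ stats::runif(length(bb_ids), log10(total_range[1]),
                              log10(total_range[2])),
    stringsAsFactors = FALSE
  )

  forms <- do.call(rbind, lapply(bb_ids, function(bb) {
    b <- grp[grp$backbone == bb, , drop = FALSE]
    x <- stats::rgamma(nrow(b), shape = concentration)
    b$fraction <- x / sum(x)
    b
  }))

  # one apex per isobaric cluster; targeted clusters elute in their window
  tg <- catalog$targeted
  clus <- unique(forms[, c("backbone", "group", "group_id")])
  clus$apex_rt <- NA_real_
  for (i in seq_len(nrow(clus))) {
    members <- forms$form[forms$group_id == clus$group_id[i]]
    win <- c(5, 65)
    hit <- which(tg$backbone == clus$backbone[i] &
                 vapply(tg$member_list, function(m) all(m %in% members),
                        logical(1)))
    if (length(hit)) {
      win <- c(tg$t_start[hit[1]] + 1, tg$t_stop[hit[1]] - 1)
    }
    clus$apex_rt[i] <- stats::runif(1, win[1], win[2])
  }
  forms$apex_rt <- clus$apex_rt[match(forms$group_id, clus$group_id)]
  forms$sigma <- sigma
  forms$total <- totals$total[match(forms$backbone, totals$backbone)]

  vr <- catalog$variants
  pair_tot <- 10 ^ stats::runif(nrow(vr), log10(total_range[1]),
                                log10(total_range[2]))
  # members of a marker pair share one abundance, split by variant fraction
  for (p in setdiff(unique(vr$pair), 0)) {
    pair_tot[vr$pair == p] <- pair_tot[vr$pair == p][1]
  }
  vfrac_of <- function(label) {
    v <- variant_fraction[label]
    if (is.na(v)) 0.15 else unname(v)
  }
  vr$fraction <- vapply(seq_len(nrow(vr)), function(i) {
    if (vr$role[i] == "variant") return(vfrac_of(vr$variant_label[i]))
    if (vr$pair[i] > 0) {
      partner <- vr$variant_label[vr$pair == vr$pair[i] &
                                  vr$role == "variant"][1]
      return(1 - vfrac_of(partner))
    }
    1
  }, numeric(1))
  vr$abundance <- pair_tot * vr$fraction
  vr$apex_rt <- stats::runif(nrow(vr), 5, 65)
  vr$sigma <- sigma
  # a canonical marker that coincides with a simulated backbone's unmodified
  # form (e.g. VTIMPKDIQLAR) is the same physical species: alias it to that
  # form's abundance and apex, and rescale its paired variant so the pair's
  # true variant fraction stays at the requested value
  vr$alias <- FALSE
  for (i in which(vr$role == "canonical")) {
    hit <- which(forms$sequence == vr$sequence[i] & forms$form == "unmod")
    if (!length(hit)) next
    vr$alias[i] <- TRUE
    vr$abundance[i] <- forms$total[hit[1]] * forms$fraction[hit[1]]
    vr$apex_rt[i] <- forms$apex_rt[hit[1]]
    if (vr$pair[i] > 0) {
      j <- which(vr$pair == vr$pair[i] & vr$role == "variant")
      f <- vfrac_of(vr$variant_label[j[1]])
      vr$abundance[j] <- vr$abundance[i] * f / (1 - f)
    }
  }

  # keep near-isobaric species from different backbones apart in time;
  # isotopologues are compared too, so that e.g. the +1 isotopologue of a
  # me1 pair cannot co-elute with another backbone's monoisotopic peak
  base_sp <- rbind(
    data.frame(id = forms$group_id, backbone = forms$backbone, mz = forms$mz,
               charge = forms$charge, stringsAsFactors = FALSE),
    data.frame(id = paste0("vr#", vr$sequence[!vr$alias]),
               backbone = "variant_markers",
               mz = vr$mz[!vr$alias], charge = vr$charge[!vr$alias],
               stringsAsFactors = FALSE)
  )
  base_sp <- unique(base_sp)
  all_sp <- do.call(rbind, lapply(0:2, function(k) {
    s <- base_sp
    s$mz <- s$mz + k * 1.0033548 / s$charge
    s
  }))
  apex_of <- c(stats::setNames(clus$apex_rt, clus$group_id),
               stats::setNames(vr$apex_rt, paste0("vr#", vr$sequence)))
  for (pass in 1:5) {
    moved <- FALSE
    o <- order(all_sp$mz)
    s <- all_sp[o, ]
    for (i in seq_len(nrow(s) - 1L)) {
      for (j in (i + 1L):nrow(s)) {
        if ((s$mz[j] - s$mz[i]) / s$mz[i] * 1e6 > 3 * ms1_ppm) break
        if (s$backbone[i] == s$backbone[j]) next
        if (abs(apex_of[s$id[i]] - apex_of[s$id[j]]) < 1.5) {
          apex_of[s$id[j]] <- 5 + (apex_of[s$id[j]] - 5 + 2.5) %% 60
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  forms$apex_rt <- unname(apex_of[forms$group_id])
  # positional isomers co-elute only approximately: members of a
  # multi-member cluster spread around the cluster apex, as on a real
  # gradient; this partial separation is what lets per-peak MS2 splitting
  # resolve large acetyl-isomer groups
  if (coelution_spread > 0) {
    sz <- stats::ave(forms$fraction, forms$group_id, FUN = length)
    jit <- stats::runif(nrow(forms), -coelution_spread / 2,
                        coelution_spread / 2)
    forms$apex_rt <- forms$apex_rt + ifelse(sz > 1, jit, 0)
  }
  moved <- !vr$alias
  vr$apex_rt[moved] <- unname(apex_of[paste0("vr#", vr$sequence[moved])])
  for (i in which(vr$alias)) {
    hit <- which(forms$sequence == vr$sequence[i] & forms$form == "unmod")
    vr$apex_rt[i] <- forms$apex_rt[hit[1]]
  }

  structure(list(forms = forms, backbones = totals, variants = vr,
                 seed = as.integer(seed), concentration = concentration),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground truth: %d forms over %d backbones, %d variant markers, seed %d>\n",
              nrow(x$forms), nrow(x$backbones), nrow(x$variants), x$seed))
  invisible(x)
}

# Gaussian elution profile sampled on the scan grid, area = total abundance
.profile_rows <- function(times, apex, sigma, area) {
  amp <- area / (sigma * sqrt(2 * pi))
  sel <- which(abs(times - apex) <= 4 * sigma)
  if (!length(sel)) return(NULL)
  list(scan = sel,
       intensity = amp * exp(-(times[sel] - apex)^2 / (2 * sigma^2)))
}

#' Simulate a centroided LC-MS/MS run
#'
#' Each ground-truth species contributes a Gaussian elution profile sampled at
#' the MS1 scan times on its lowest isotopologues (area = total abundance x
#' form fraction x envelope share). Inside each multi-member isobaric
#' cluster's elution window, targeted MS2 scans at the cluster m/z contain
#' singly charged b/y fragments of every member with intensity proportional
#' to the member's instantaneous MS1 contribution times a per-fragment-position
#' efficiency drawn once per backbone per run. Optional multiplicative
#' log-normal noise and uniform ppm jitter are applied per centroid.
#'
#' @param catalog A `histone_catalog`.
#' @param truth A `ground_truth` from [sample_ground_truth()].
#' @param params A [sim_params()] list.
#' @param seed Integer seed; identical seed and parameters give an identical
#'   run.
#' @return An object of class `ms_run`: a list with data frames `ms1`
#'   (`scan`, `rt`, `mz`, `intensity`) and `ms2` (`scan`, `rt`,
#'   `precursor_mz`, `mz`, `intensity`), plus `meta`.
#' @export
simulate_run <- function(catalog, truth, params = sim_params(), seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  missing <- !paste(truth$forms$backbone, truth$forms$form) %in%
    paste(catalog$forms$backbone, catalog$forms$form)
  if (any(missing)) {
    stop("ground truth references form(s) absent from catalog: ",
         paste(truth$forms$form[missing], collapse = ", "))
  }
  set.seed(as.integer(seed))
  times <- seq(0, params$rt_max, by = params$scan_interval)

  f <- truth$forms
  f$area <- f$total * f$fraction
  species <- rbind(
    data.frame(mz0 = f$mz, charge = f$charge,
               mass = catalog$forms$neutral_mass[
                 match(paste(f$backbone, f$form),
                       paste(catalog$forms$backbone, catalog$forms$form))],
               area = f$area, apex = f$apex_rt, sigma = f$sigma,
               stringsAsFactors = FALSE),
    with(truth$variants[!truth$variants$alias, , drop = FALSE],
         data.frame(mz0 = mz, charge = charge, mass = neutral_mass,
                    area = abundance, apex = apex_rt, sigma = sigma,
                    stringsAsFactors = FALSE))
  )

  scan_l <- list(); mz_l <- list(); int_l <- list(); k_i <- 0L
  for (i in seq_len(nrow(species))) {
    if (species$area[i] <= 0) next
    env <- isotope_envelope(species$mass[i], params$envelope_depth)
    prof <- .profile_rows(times, species$apex[i], species$sigma[i],
                          species$area[i])
    if (is.null(prof)) next
    for (k in seq_along(env)) {
      k_i <- k_i + 1L
      scan_l[[k_i]] <- prof$scan
      mz_l[[k_i]] <- rep(species$mz0[i] + (k - 1L) * .C13_DELTA /
                           species$charge[i], length(prof$scan))
      int_l[[k_i]] <- prof$intensity * env[k]
    }
  }
  ms1 <- data.frame(scan = unlist(scan_l), mz = unlist(mz_l),
                    intensity = unlist(int_l))
  # merge coincident theoretical centroids (e.g. coeluting isobars)
  key <- paste(ms1$scan, sprintf("%.6f", ms1$mz))
  ms1 <- data.frame(scan = ms1$scan[!duplicated(key)],
                    mz = ms1$mz[!duplicated(key)],
                    intensity = as.numeric(
                      rowsum(ms1$intensity, key, reorder = FALSE)))
  ms1 <- ms1[order(ms1$scan, ms1$mz), ]
  ms1$rt <- times[ms1$scan]

  # targeted MS2 over every multi-member isobaric cluster
  multi <- split(f, f$group_id)
  multi <- multi[vapply(multi, nrow, integer(1)) >= 2L]
  eff_env <- new.env(parent = emptyenv())
  frag_eff <- function(backbone, n_res) {
    if (is.null(eff_env[[backbone]])) {
      eff_env[[backbone]] <- matrix(
        stats::runif(2L * (n_res - 1L), params$frag_eff_range[1],
                     params$frag_eff_range[2]),
        nrow = 2L, dimnames = list(c("b", "y"), NULL))
    }
    eff_env[[backbone]]
  }
  m2_scan <- list(); m2_rt <- list(); m2_prec <- list()
  m2_mz <- list(); m2_int <- list(); k_i <- 0L
  # deterministic order independent of list hashing
  for (gid in sort(names(multi))) {
    g <- multi[[gid]]
    n_res <- nchar(g$sequence[1])
    eff <- frag_eff(g$backbone[1], n_res)
    prec <- mean(g$mz)
    sg <- g$sigma[1]
    sel <- which(times >= min(g$apex_rt) - 4 * sg &
                 times <= max(g$apex_rt) + 4 * sg)
    if (length(sel) == 0L) next
    sel <- sel[seq(1, length(sel), by = params$ms2_every)]
    frags <- lapply(seq_len(nrow(g)), function(m) {
      dp <- derivatize(g$sequence[m], g$form[m], start = g$start[m])
      fr <- fragment_ions(dp)
      fr$eff <- eff[cbind(match(fr$series, c("b", "y")), fr$index)]
      fr
    })
    env0 <- isotope_envelope(mean(catalog$forms$neutral_mass[
      match(paste(g$backbone, g$form),
            paste(catalog$forms$backbone, catalog$forms$form))]), 1)
    for (s in sel) {
      t <- times[s]
      contrib <- g$total * g$fraction * env0 / (sg * sqrt(2 * pi)) *
        exp(-(t - g$apex_rt)^2 / (2 * sg^2))
      if (sum(contrib) <= 0) next
      mzv <- numeric(0); intv <- numeric(0)
      for (m in seq_len(nrow(g))) {
        mzv <- c(mzv, frags[[m]]$mz)
        intv <- c(intv, frags[[m]]$eff * contrib[m] * params$ms2_scale)
      }
      key <- sprintf("%.6f", mzv)
      mzv2 <- mzv[!duplicated(key)]
      intv2 <- as.numeric(rowsum(intv, key, reorder = FALSE))
      o <- order(mzv2)
      k_i <- k_i + 1L
      m2_scan[[k_i]] <- s; m2_rt[[k_i]] <- t + params$scan_interval / 2
      m2_prec[[k_i]] <- prec
      m2_mz[[k_i]] <- mzv2[o]; m2_int[[k_i]] <- intv2[o]
    }
  }
  n_per <- vapply(m2_mz, length, integer(1))
  ms2 <- data.frame(
    scan = rep(unlist(m2_scan), n_per),
    rt = rep(unlist(m2_rt), n_per),
    precursor_mz = rep(unlist(m2_prec), n_per),
    mz = unlist(m2_mz), intensity = unlist(m2_int)
  )
  if (nrow(ms2) == 0L) {
    ms2 <- data.frame(scan = integer(), rt = numeric(),
                      precursor_mz = numeric(), mz = numeric(),
                      intensity = numeric())
  }

  if (params$ppm_jitter > 0) {
    ms1$mz <- ms1$mz * (1 + stats::runif(nrow(ms1), -params$ppm_jitter,
                                         params$ppm_jitter) * 1e-6)
    ms2$mz <- ms2$mz * (1 + stats::runif(nrow(ms2), -params$ppm_jitter,
                                         params$ppm_jitter) * 1e-6)
  }
  if (params$noise_sd > 0) {
    ms1$intensity <- ms1$intensity *
      exp(stats::rnorm(nrow(ms1), 0, params$noise_sd))
    ms2$intensity <- ms2$intensity *
      exp(stats::rnorm(nrow(ms2), 0, params$noise_sd))
  }

  structure(list(
    ms1 = ms1[, c("scan", "rt", "mz", "intensity")],
    ms2 = ms2,
    scan_times = times,
    meta = list(seed = as.integer(seed), params = params,
                catalog_version = catalog$version)
  ), class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  cat(sprintf("<ms run: %d MS1 centroids over %d scans, %d MS2 centroids, seed %s>\n",
              nrow(x$ms1), length(x$scan_times), nrow(x$ms2),
              format(x$meta$seed)))
  invisible(x)
}
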