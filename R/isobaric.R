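# Splitting a shared MS1 XIC area among coeluting isobaric forms using
# discriminating fragment ions from targeted MS2 scans.

#' Discriminating fragment ions of an isobaric group
#'
#' Computes all singly charged b/y ions per member and removes every ion that
#' lies within `ppm` of any other member's ions; what remains is each
#' member's unique fragment signature (pairwise disjoint by construction).
#' Members can also be discriminated without unique ions: at a given
#' backbone cleavage position the members' fragment masses partition them
#' into subgroups (e.g. a b-ion mass shared by two of four members), and the
#' relative intensities of those mass variants carry the subgroup
#' abundances. The signature therefore also records, per cleavage position,
#' the member partition induced by fragment mass. A member is only truly
#' indistinguishable when it falls in the same subgroup as some other member
#' at every position.
#'
#' @param members A list of `derivatized_peptide`s (the group members),
#'   named by form.
#' @param ppm MS2 match tolerance in ppm (default 20).
#' @return A list of class `fragment_signature`: per member a data frame of
#'   unique ions (`series`, `index`, `mz`); attributes `positions` (the
#'   per-position subgroup table), `indistinguishable` (members that cannot
#'   be separated from some other member even via subgroups) and `ppm`.
#' @export
discriminating_fragments <- function(members, ppm = 20) {
  stopifnot(is.list(members), length(members) >= 1L)
  frag <- lapply(members, fragment_ions)
  n <- length(members)

  uniq <- lapply(seq_len(n), function(i) {
    others <- unlist(lapply(frag[-i], function(f) f$mz))
    f <- frag[[i]]
    if (length(others)) {
      keep <- vapply(f$mz, function(m)
        all(abs(others - m) / m * 1e6 > ppm), logical(1))
      f <- f[keep, , drop = FALSE]
    }
    rownames(f) <- NULL
    f
  })
  names(uniq) <- names(members)

  # per cleavage position, partition members by fragment mass
  pos_rows <- list(); k <- 0L
  if (n >= 2L) {
    all_pos <- unique(frag[[1]][, c("series", "index")])
    all_mz <- unlist(lapply(frag, function(f) f$mz))
    pos_key <- unlist(lapply(frag, function(f) paste(f$series, f$index)))
    for (p in seq_len(nrow(all_pos))) {
      key <- paste(all_pos$series[p], all_pos$index[p])
      mzs <- vapply(frag, function(f)
        f$mz[f$series == all_pos$series[p] & f$index == all_pos$index[p]],
        numeric(1))
      o <- order(mzs)
      gap <- diff(mzs[o]) / mzs[o][-n] * 1e6
      grp_sorted <- cumsum(c(1L, as.integer(gap > ppm)))
      grp <- integer(n); grp[o] <- grp_sorted
      if (max(grp) < 2L) next
      for (v in seq_len(max(grp))) {
        mem <- which(grp == v)
        mu <- mean(mzs[mem])
        # the variant's m/z must not collide with ions of other positions
        foreign <- all_mz[pos_key != key]
        if (any(abs(foreign - mu) / mu * 1e6 <= ppm)) next
        k <- k + 1L
        pos_rows[[k]] <- data.frame(
          series = all_pos$series[p], index = all_pos$index[p],
          variant = v, mz = mu,
          members = paste(names(members)[mem], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  positions <- if (k) do.call(rbind, pos_rows) else NULL

  # a member is separable iff the subgroup partitions distinguish it from
  # every other member at some position
  indist <- character(0)
  if (n >= 2L) {
    sep <- matrix(FALSE, n, n)
    if (!is.null(positions)) {
      for (key in unique(paste(positions$series, positions$index))) {
        rows <- positions[paste(positions$series, positions$index) == key, ]
        mem_sets <- strsplit(rows$members, ";")
        for (ms in mem_sets) {
          a <- match(ms, names(members))
          b <- setdiff(seq_len(n), a)
          sep[a, b] <- TRUE; sep[b, a] <- TRUE
        }
      }
    }
    indist <- names(members)[vapply(seq_len(n), function(i)
      any(!sep[i, -i]), logical(1))]
  }
  structure(uniq, positions = positions, indistinguishable = indist,
            ppm = ppm, class = c("fragment_signature", "list"))
}

# pooled intensity at target m/z values over a set of MS2 centroids
.pooled_intensity <- function(ms2, mzs, ppm) {
  vapply(mzs, function(mu)
    sum(ms2$intensity[abs(ms2$mz - mu) / mu * 1e6 <= ppm]), numeric(1))
}

#' Split a group MS1 area among isobaric members by MS2 evidence
#'
#' When every member retains unique fragment ions, each member's weight is
#' its pooled unique-ion intensity share across the qualifying MS2 scans
#' (per-scan weights averaged with scan-total weighting collapse to this
#' pooled share). When some members lack unique ions, weights are instead
#' solved from position-wise subgroup shares: at each cleavage position the
#' observed intensities of the fragment mass variants estimate the summed
#' weight of each member subgroup, and a least-squares fit on the simplex
#' recovers the member weights. Member areas are the group area times the
#' weights and sum to the group area exactly. With no qualifying MS2 scan or
#' a genuinely inseparable member, the whole area is assigned to an
#' `"aggregate"` pseudo-form and flagged `"unresolved"`.
#'
#' @param group_area Non-negative MS1 peak area to distribute.
#' @param ms2_scans Data frame of MS2 centroids (`scan`, `mz`, `intensity`)
#'   restricted to scans whose precursor matches the group and whose RT lies
#'   within the integrated MS1 peak.
#' @param signature A `fragment_signature` for the members.
#' @param ppm MS2 match tolerance in ppm; defaults to the signature's.
#' @return A list of class `area_split`: `areas` (named, summing exactly to
#'   `group_area`), `weights`, `method` (`"unique_ions"`, `"subgroups"` or
#'   `"none"`), `flag` (`"ok"` or `"unresolved"`), and `scan_weights`
#'   (per-scan audit table, unique-ion path only).
#' @export
split_area <- function(group_area, ms2_scans, signature, ppm = NULL) {
  stopifnot(group_area >= 0, inherits(signature, "fragment_signature"))
  if (is.null(ppm)) ppm <- attr(signature, "ppm")
  members <- names(signature)
  n <- length(members)
  if (n == 1L) {
    return(structure(list(areas = stats::setNames(group_area, members),
                          weights = stats::setNames(1, members),
                          method = "unique_ions", flag = "ok",
                          scan_weights = NULL), class = "area_split"))
  }
  unresolved <- function() {
    structure(list(
      areas = c(stats::setNames(rep(NA_real_, n), members),
                aggregate = group_area),
      weights = stats::setNames(rep(NA_real_, n), members),
      method = "none", flag = "unresolved", scan_weights = NULL),
      class = "area_split")
  }
  if (length(attr(signature, "indistinguishable")) > 0L ||
      is.null(ms2_scans) || nrow(ms2_scans) == 0L) {
    return(unresolved())
  }
  if (any(ms2_scans$intensity < 0)) stop("negative MS2 intensities")

  finish <- function(w, method, scan_weights = NULL) {
    areas <- group_area * w
    i <- which.max(areas)
    areas[i] <- areas[i] + (group_area - sum(areas))  # exact conservation
    structure(list(areas = areas, weights = w, method = method, flag = "ok",
                   scan_weights = scan_weights), class = "area_split")
  }

  all_unique <- all(vapply(signature, nrow, integer(1)) > 0L)
  if (all_unique) {
    scans <- split(ms2_scans, ms2_scans$scan)
    per_scan <- do.call(rbind, lapply(scans, function(sc) {
      I <- vapply(members, function(m)
        sum(.pooled_intensity(sc, signature[[m]]$mz, ppm)), numeric(1))
      c(total = sum(I), I)
    }))
    per_scan <- per_scan[per_scan[, "total"] > 0, , drop = FALSE]
    if (nrow(per_scan) == 0L) return(unresolved())
    pooled <- colSums(per_scan[, members, drop = FALSE])
    w <- pooled / sum(pooled)
    sw <- data.frame(scan = as.integer(rownames(per_scan)),
                     total = per_scan[, "total"],
                     sweep(per_scan[, members, drop = FALSE], 1,
                           per_scan[, "total"], "/"),
                     check.names = FALSE)
    rownames(sw) <- NULL
    return(finish(w, "unique_ions", sw))
  }

  # subgroup-share least squares
  pos <- attr(signature, "positions")
  if (is.null(pos)) return(unresolved())
  pos$I <- .pooled_intensity(ms2_scans, pos$mz, ppm)
  rows <- list(); s_obs <- numeric(0); k <- 0L
  for (key in unique(paste(pos$series, pos$index))) {
    pr <- pos[paste(pos$series, pos$index) == key, , drop = FALSE]
    tot <- sum(pr$I)
    if (tot <= 0) next
    for (r in seq_len(nrow(pr))) {
      mem <- strsplit(pr$members[r], ";")[[1]]
      k <- k + 1L
      rows[[k]] <- as.numeric(members %in% mem)
      s_obs[k] <- pr$I[r] / tot
    }
  }
  if (k == 0L) return(unresolved())
  A <- do.call(rbind, rows)
  # nonnegative least squares with sum-to-one as a heavily weighted row;
  # nonnegativity resolves the rank deficiency of purely cumulative
  # prefix/suffix evidence in large positional-isomer groups
  A <- rbind(A, rep(1e3, n))
  s_obs <- c(s_obs, 1e3)
  w <- tryCatch(pracma::lsqnonneg(A, s_obs)$x, error = function(e) NULL)
  if (is.null(w) || sum(w) == 0) return(unresolved())
  w <- stats::setNames(w / sum(w), members)
  finish(w, "subgroups")
}

#' @export
print.area_split <- function(x, ...) {
  cat(sprintf("<area split (%s, %s): %s>\n", x$flag, x$method,
              paste(names(x$areas), signif(x$areas, 4),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
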