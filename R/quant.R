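# Ratio tables: per-backbone form ratios, single-PTM relative abundances,
# and variant-vs-canonical abundance from marker peptides.

#' Per-backbone form ratios
#'
#' A form's ratio is its area divided by the sum of areas over *all* catalog
#' forms sharing the same backbone (histone, coordinates, sequence) --
#' including, e.g., the phosphorylated series of the same peptide. Undetected
#' forms contribute area 0 (they are kept, not dropped), so ratios are
#' comparable across samples. A backbone with zero total area is flagged and
#' its ratios are `NA`.
#'
#' @param areas Data frame with columns `backbone`, `form`, `area` and
#'   optionally `rt`, `flag` (as produced by [quantify_run()]).
#' @param catalog A `histone_catalog`; defines the full denominator per
#'   backbone.
#' @return A data frame (`ratio_table`) with one row per catalog form (plus
#'   any aggregate pseudo-forms): `histone`, `start`, `end`, `sequence`,
#'   `backbone`, `form`, `rt`, `area`, `ratio`, `flag`.
#' @export
backbone_ratios <- function(areas, catalog) {
  stopifnot(all(c("backbone", "form", "area") %in% names(areas)))
  if (!"rt" %in% names(areas)) areas$rt <- NA_real_
  if (!"flag" %in% names(areas)) areas$flag <- "ok"
  if (any(stats::na.omit(areas$area) < 0)) stop("negative areas")
  full <- catalog$forms[, c("histone", "start", "end", "sequence",
                            "backbone", "form")]
  full <- full[full$backbone %in% unique(areas$backbone), , drop = FALSE]
  m <- match(paste(full$backbone, full$form),
             paste(areas$backbone, areas$form))
  full$rt <- areas$rt[m]
  full$area <- areas$area[m]
  full$flag <- areas$flag[m]
  full$area[is.na(full$area) & !(full$flag %in% "unresolved")] <- 0
  full$flag[is.na(full$flag)] <- "not_detected"
  # carry aggregate pseudo-forms (unresolved isobaric groups) into the block
  extra <- areas[!paste(areas$backbone, areas$form) %in%
                   paste(full$backbone, full$form), , drop = FALSE]
  if (nrow(extra)) {
    bb <- catalog$backbones[match(extra$backbone,
                                  catalog$backbones$backbone), ]
    extra2 <- data.frame(histone = bb$histone, start = bb$start,
                         end = bb$end, sequence = bb$sequence,
                         backbone = extra$backbone, form = extra$form,
                         rt = extra$rt, area = extra$area, flag = extra$flag,
                         stringsAsFactors = FALSE)
    full <- rbind(full, extra2)
  }
  out <- do.call(rbind, lapply(split(full, full$backbone), function(b) {
    tot <- sum(b$area, na.rm = TRUE)
    if (tot > 0) {
      b$ratio <- ifelse(is.na(b$area), NA_real_, b$area / tot)
    } else {
      b$ratio <- NA_real_
      b$flag <- "no_signal"
    }
    b
  }))
  rownames(out) <- NULL
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Single-PTM relative abundances
#'
#' The relative abundance of an individual mark (e.g. H3K14ac) is the sum of
#' the ratios of all forms of that mark's backbone that contain the mark --
#' e.g. H3K14ac = r(K14ac) + r(K9me1K14ac) + ... + r(S10phK14ac) + ... .
#' Mark names are prefixed with the catalog's histone label.
#'
#' @param ratio_table Output of [backbone_ratios()].
#' @return A data frame with columns `mark`, `histone`, `backbone`, `ratio`.
#' @export
single_ptm_ratios <- function(ratio_table) {
  rt <- ratio_table[!is.na(ratio_table$ratio) | TRUE, , drop = FALSE]
  out <- do.call(rbind, lapply(split(rt, rt$backbone), function(b) {
    parsed <- lapply(b$form, function(f) {
      if (f == "aggregate" || grepl("^aggregate", f)) return(NULL)
      parse_form(f)
    })
    marks <- unique(do.call(rbind, parsed))
    if (is.null(marks) || nrow(marks) == 0L) return(NULL)
    marks <- marks[order(marks$site, marks$kind), , drop = FALSE]
    ratio <- vapply(seq_len(nrow(marks)), function(i) {
      has <- vapply(parsed, function(p)
        !is.null(p) && any(p$site == marks$site[i] &
                           p$kind == marks$kind[i]), logical(1))
      if (!any(has)) return(0)
      sum(b$ratio[has], na.rm = FALSE)
    }, numeric(1))
    data.frame(mark = paste0(b$histone[1], marks$residue, marks$site,
                             marks$kind),
               histone = b$histone[1], backbone = b$backbone[1],
               ratio = ratio, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Variant-vs-canonical abundance from marker peptides
#'
#' For each aligned canonical/variant marker-peptide pair covering the same
#' protein region, the variant fraction is
#' `area_variant / (area_variant + area_canonical)`; the pooled per-label
#' estimate is the area-weighted mean over its pairs.
#'
#' @param areas Data frame with columns `sequence` and `area` for the
#'   quantified marker peptides.
#' @param catalog A `histone_catalog` (defines the pairs).
#' @return A list with data frames `pairs` (per-pair fractions) and `pooled`
#'   (per variant label); pairs where both areas are zero are flagged
#'   `missing`.
#' @export
variant_abundance <- function(areas, catalog) {
  vr <- catalog$variants
  vr$area <- areas$area[match(vr$sequence, areas$sequence)]
  vr$area[is.na(vr$area)] <- 0
  pair_ids <- setdiff(unique(vr$pair), 0)
  pairs <- do.call(rbind, lapply(pair_ids, function(p) {
    canon <- vr[vr$pair == p & vr$role == "canonical", ]
    varnt <- vr[vr$pair == p & vr$role == "variant", ]
    tot <- canon$area[1] + varnt$area[1]
    data.frame(family = canon$family[1], variant_label = varnt$variant_label[1],
               canonical_seq = canon$sequence[1],
               variant_seq = varnt$sequence[1],
               canonical_area = canon$area[1], variant_area = varnt$area[1],
               fraction = if (tot > 0) varnt$area[1] / tot else NA_real_,
               flag = if (tot > 0) "ok" else "missing",
               stringsAsFactors = FALSE)
  }))
  ok <- pairs[pairs$flag == "ok", , drop = FALSE]
  pooled <- do.call(rbind, lapply(split(ok, ok$variant_label), function(g) {
    w <- g$canonical_area + g$variant_area
    data.frame(variant_label = g$variant_label[1],
               fraction = sum(g$fraction * w) / sum(w),
               n_pairs = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- rownames(pooled) <- NULL
  list(pairs = pairs, pooled = pooled)
}
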