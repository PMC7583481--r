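# Machine-readable peptide/PTM catalog: backbone peptides with their
# enumerated (un)modified forms, targeted isobaric groups with retention-time
# windows, and variant-marker peptides; plus in-silico digestion and
# isobaric-group detection.

.backbone_id <- function(histone, start, end, sequence) {
  paste(histone, start, end, sequence, sep = "_")
}

#' Load the histone peptide/PTM catalog
#'
#' Reads the catalog shipped with the package (or user-supplied replacements
#' in the same format): one TSV of backbone peptides with their combinatorial
#' PTM forms, one TSV of targeted isobaric groups (label, member forms, m/z,
#' charge, retention-time window), and one TSV of variant-marker peptides used
#' to compare canonical histones against their variants.
#'
#' On load, every form name is parsed and validated against its backbone
#' sequence, targeted groups are resolved against catalog forms, and each
#' targeted group's printed m/z is recomputed from the derivatization rules;
#' groups whose printed value deviates by more than `flag_ppm` are flagged
#' `printed_mz_discrepant` (and the computed value is carried alongside).
#'
#' @param peptides,targeted,variants Paths to the three TSV files; defaults
#'   are the catalog shipped in `extdata`.
#' @param flag_ppm Tolerance (ppm) beyond which a printed targeted m/z is
#'   flagged as discrepant with the recomputed value (default 5).
#' @return An object of class `histone_catalog`: a list with data frames
#'   `entries` (one row per catalog line), `forms` (one row per backbone
#'   form, with computed neutral mass, quantification charge and m/z),
#'   `backbones` (one row per unique backbone), `targeted` and `variants`.
#' @export
#' @examples
#' cat <- load_catalog()
#' subset(cat$backbones, sequence == "KSTGGKAPR")$n_forms  # 20
load_catalog <- function(peptides = catalog_file("ce_histone_peptides.tsv"),
                         targeted = catalog_file("ce_targeted_groups.tsv"),
                         variants = catalog_file("ce_variant_markers.tsv"),
                         flag_ppm = 5) {
  entries <- utils::read.delim(peptides, stringsAsFactors = FALSE,
                               check.names = FALSE)
  need <- c("histone", "start", "end", "sequence", "forms")
  if (!all(need %in% names(entries))) {
    stop("peptide catalog must have columns: ", paste(need, collapse = ", "))
  }
  bad_len <- which(nchar(entries$sequence) != entries$end - entries$start + 1L)
  if (length(bad_len)) {
    stop("catalog row ", bad_len[1], " (", entries$sequence[bad_len[1]],
         "): sequence length does not match start/end coordinates")
  }

  forms <- do.call(rbind, lapply(seq_len(nrow(entries)), function(i) {
    fs <- trimws(strsplit(entries$forms[i], ";")[[1]])
    fs <- fs[nzchar(fs)]
    data.frame(histone = entries$histone[i], start = entries$start[i],
               end = entries$end[i], sequence = entries$sequence[i],
               form = fs, entry = i, stringsAsFactors = FALSE)
  }))
  forms$backbone <- .backbone_id(forms$histone, forms$start, forms$end,
                                 forms$sequence)
  dup <- duplicated(forms[, c("backbone", "form")])
  if (any(dup)) {
    stop("duplicate form '", forms$form[dup][1], "' for backbone ",
         forms$backbone[dup][1])
  }
  # validate each form against its sequence and compute masses
  forms$neutral_mass <- vapply(seq_len(nrow(forms)), function(i) {
    dp <- tryCatch(
      derivatize(forms$sequence[i], forms$form[i], start = forms$start[i]),
      error = function(e) stop("catalog row for backbone ", forms$backbone[i],
                               ", form '", forms$form[i], "': ",
                               conditionMessage(e)))
    neutral_mass(dp)
  }, numeric(1))

  backbones <- unique(forms[, c("histone", "start", "end", "sequence",
                                "backbone")])
  backbones$n_forms <- as.integer(table(forms$backbone)[backbones$backbone])
  # one quantification charge per backbone: 2+ except for heavy peptides
  backbones$charge <- ifelse(
    vapply(backbones$sequence, function(s)
      sum(.RESIDUE_MASS[strsplit(s, "")[[1]]]), numeric(1)) > 1900, 3L, 2L)
  rownames(backbones) <- NULL

  forms$charge <- backbones$charge[match(forms$backbone, backbones$backbone)]
  forms$mz <- (forms$neutral_mass + forms$charge * .PROTON) / forms$charge
  rownames(forms) <- NULL

  tg <- utils::read.delim(targeted, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("label", "histone", "start", "end", "members", "mz", "z",
            "t_start", "t_stop")
  if (!all(need %in% names(tg))) {
    stop("targeted-group catalog must have columns: ",
         paste(need, collapse = ", "))
  }
  if (any(tg$t_start >= tg$t_stop)) {
    stop("targeted group '", tg$label[tg$t_start >= tg$t_stop][1],
         "': t_start must be < t_stop")
  }
  tg$backbone <- NA_character_
  tg$computed_mz <- NA_real_
  tg$ppm_offset <- NA_real_
  member_list <- vector("list", nrow(tg))
  for (i in seq_len(nrow(tg))) {
    bb <- backbones[backbones$histone == tg$histone[i] &
                    backbones$start == tg$start[i] &
                    backbones$end == tg$end[i], , drop = FALSE]
    if (nrow(bb) != 1L) {
      stop("targeted group '", tg$label[i], "': no unique backbone ",
           tg$histone[i], " ", tg$start[i], "-", tg$end[i], " in catalog")
    }
    mem <- trimws(strsplit(tg$members[i], ";")[[1]])
    known <- forms$form[forms$backbone == bb$backbone]
    missing <- setdiff(mem, known)
    if (length(missing)) {
      stop("targeted group '", tg$label[i], "': member form(s) not in ",
           "catalog: ", paste(missing, collapse = ", "))
    }
    tg$backbone[i] <- bb$backbone
    member_list[[i]] <- mem
    masses <- forms$neutral_mass[forms$backbone == bb$backbone &
                                 forms$form %in% mem]
    if (diff(range(masses)) > 1e-4) {
      stop("targeted group '", tg$label[i],
           "': member forms are not isobaric")
    }
    tg$computed_mz[i] <- (mean(masses) + tg$z[i] * .PROTON) / tg$z[i]
  }
  tg$member_list <- member_list
  tg$ppm_offset <- (tg$mz - tg$computed_mz) / tg$computed_mz * 1e6
  tg$printed_mz_discrepant <- abs(tg$ppm_offset) > flag_ppm

  vr <- utils::read.delim(variants, stringsAsFactors = FALSE,
                          check.names = FALSE)
  vr$neutral_mass <- vapply(vr$sequence, function(s)
    neutral_mass(derivatize(s)), numeric(1))
  vr$charge <- 2L
  vr$mz <- (vr$neutral_mass + vr$charge * .PROTON) / vr$charge
  short <- vr$sequence[nchar(vr$sequence) < 6]
  if (length(short)) {
    message("catalog: short (<6 residue) variant-marker peptide(s) with low ",
            "specificity retained: ", paste(short, collapse = ", "))
  }

  structure(list(entries = entries, forms = forms, backbones = backbones,
                 targeted = tg, variants = vr,
                 version = "ce-tables-1"),
            class = "histone_catalog")
}

#' @export
print.histone_catalog <- function(x, ...) {
  cat(sprintf(paste0("<histone catalog '%s': %d backbones, %d forms, ",
                     "%d targeted groups, %d variant markers>\n"),
              x$version, nrow(x$backbones), nrow(x$forms),
              nrow(x$targeted), nrow(x$variants)))
  invisible(x)
}

#' Path to a shipped catalog file
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path.
#' @export
catalog_file <- function(file) {
  p <- system.file("extdata", file, package = "histoneptm")
  if (!nzchar(p)) stop("catalog file not found: ", file)
  p
}

#' Serialize a catalog back to its three TSV files
#'
#' Writes the `entries`, `targeted` and `variants` tables in the same format
#' [load_catalog()] reads, so that a written catalog re-loads identically
#' (bit-stable form names).
#'
#' @param catalog A `histone_catalog`.
#' @param dir Output directory.
#' @return Invisibly, the three file paths.
#' @export
write_catalog <- function(catalog, dir) {
  stopifnot(inherits(catalog, "histone_catalog"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "ce_histone_peptides.tsv")
  p2 <- file.path(dir, "ce_targeted_groups.tsv")
  p3 <- file.path(dir, "ce_variant_markers.tsv")
  utils::write.table(catalog$entries, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tg <- catalog$targeted[, c("label", "histone", "start", "end", "members",
                             "mz", "z", "t_start", "t_stop")]
  utils::write.table(tg, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  vr_cols <- c("family", "sequence", "role", "variant_label", "genes", "pair")
  utils::write.table(catalog$variants[, vr_cols], p3, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Build the derivatized peptide for one catalog form
#' @param catalog A `histone_catalog`.
#' @param backbone Backbone id (see `catalog$forms$backbone`).
#' @param form Form name.
#' @return A `derivatized_peptide`.
#' @export
catalog_peptide <- function(catalog, backbone, form) {
  row <- catalog$forms[catalog$forms$backbone == backbone &
                       catalog$forms$form == form, , drop = FALSE]
  if (nrow(row) != 1L) stop("no form '", form, "' for backbone ", backbone)
  derivatize(row$sequence, row$form, start = row$start)
}

#' Detect isobaric groups among catalog forms
#'
#' Forms of one backbone whose precursor m/z (at the given charge) agree
#' within `ppm_tol` are grouped by single-linkage chaining of sorted m/z.
#' Whether a near-isobaric pair (e.g. trimethyl vs acetyl, 0.036385 Da apart)
#' lands in one group is therefore computed from m/z, charge and tolerance,
#' never assumed.
#'
#' @param catalog A `histone_catalog`.
#' @param ppm_tol Grouping tolerance in ppm (default 10).
#' @param charge Optional charge; default is each backbone's quantification
#'   charge from the catalog.
#' @return Data frame of catalog forms with columns `backbone`, `form`,
#'   `charge`, `mz` and an integer `group` (unique within backbone); a
#'   `group_id` string identifies the group globally.
#' @export
detect_isobaric_groups <- function(catalog, ppm_tol = 10, charge = NULL) {
  stopifnot(ppm_tol > 0)
  f <- catalog$forms
  if (!is.null(charge)) {
    f$charge <- as.integer(charge)
    f$mz <- (f$neutral_mass + f$charge * .PROTON) / f$charge
  }
  out <- do.call(rbind, lapply(split(f, f$backbone), function(b) {
    b <- b[order(b$mz), , drop = FALSE]
    gap <- diff(b$mz) / b$mz[-nrow(b)] * 1e6
    b$group <- cumsum(c(1L, as.integer(gap > ppm_tol)))
    b
  }))
  rownames(out) <- NULL
  out$group_id <- paste(out$backbone, out$group, sep = "#")
  out[, c("histone", "start", "end", "sequence", "backbone", "form",
          "charge", "mz", "group", "group_id")]
}

#' In-silico tryptic digestion of fully propionylated protein sequence
#'
#' After derivatization every lysine is either propionylated or biologically
#' modified, so trypsin cleaves C-terminal to arginine only; no cleavage
#' occurs when the next residue is proline (ArgC-like specificity).
#'
#' @param sequence Protein or region sequence (one-letter residues).
#' @return Data frame with columns `start`, `end`, `peptide` (coordinates
#'   relative to the input sequence, 1-based inclusive).
#' @export
#' @examples
#' insilico_digest("TKQTARKSTGGKAPR")$peptide
insilico_digest <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut_after <- which(res == "R")
  cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  bounds <- unique(bounds)
  data.frame(
    start = bounds[-length(bounds)] + 1L,
    end = bounds[-1],
    peptide = vapply(seq_len(length(bounds) - 1L), function(i)
      substr(sequence, bounds[i] + 1L, bounds[i + 1L]), character(1)),
    stringsAsFactors = FALSE
  )
}
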