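# Monoisotopic mass engine: residue masses, PTM deltas, propionylation rules,
# precursor and b/y fragment m/z.

#' Monoisotopic residue masses
#'
#' Monoisotopic masses (Da) of amino-acid residues as they occur in a peptide
#' chain (i.e. minus one water relative to the free amino acid), from standard
#' atomic compositions.
#'
#' @return Named numeric vector of residue masses in Da.
#' @export
#' @examples
#' residue_masses()[["K"]]
residue_masses <- function() .RESIDUE_MASS

.RESIDUE_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Monoisotopic modification mass deltas
#'
#' Mass deltas (Da) for the biological modifications handled by the pipeline
#' (mono-, di-, tri-methylation, acetylation, phosphorylation) plus the
#' propionyl group introduced by chemical derivatization. Note that
#' trimethylation (42.046950) and acetylation (42.010565) are near-isobaric:
#' they differ by 0.036385 Da, resolvable or not depending on m/z, charge and
#' the configured tolerance.
#'
#' @return Named numeric vector of mass deltas in Da.
#' @export
mod_deltas <- function() .MOD_DELTA

.MOD_DELTA <- c(
  unmod = 0,
  me1 = 14.015650, me2 = 28.031300, me3 = 42.046950,
  ac = 42.010565, ph = 79.966331,
  prop = 56.026215
)

# physical constants (Da)
.PROTON <- 1.00727646
.WATER  <- 18.010565
.C13_DELTA <- 1.0033548

#' @rdname mod_deltas
#' @export
proton_mass <- function() .PROTON

#' @rdname mod_deltas
#' @export
water_mass <- function() .WATER

# residues each mod kind may sit on
.MOD_TARGETS <- list(
  me1 = "K", me2 = "K", me3 = "K", ac = "K", ph = c("S", "T", "Y")
)

# lysine states that keep the epsilon-amine reactive toward propionylation
.PROP_RETAINING <- c("unmod", "me1")

#' Parse a combinatorial PTM form name
#'
#' Form names follow the `K9me2S10phK14ac` convention: a concatenation of
#' residue letter, protein coordinate and modification kind. `"unmod"` (or an
#' empty string) denotes the unmodified form.
#'
#' @param form Character scalar form name.
#' @return A data frame with columns `site` (1-based protein coordinate),
#'   `residue` and `kind`; zero rows for the unmodified form.
#' @export
#' @examples
#' parse_form("K9me1K14ac")
parse_form <- function(form) {
  stopifnot(is.character(form), length(form) == 1L)
  empty <- data.frame(site = integer(), residue = character(),
                      kind = character(), stringsAsFactors = FALSE)
  if (form %in% c("unmod", "")) return(empty)
  rx <- "([A-Z])([0-9]+)(me1|me2|me3|ac|ph)"
  m <- gregexpr(rx, form)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(form)) {
    stop("cannot parse form name: '", form, "'")
  }
  toks <- regmatches(form, gregexpr(rx, form))[[1]]
  out <- data.frame(
    site = as.integer(sub(rx, "\\2", toks)),
    residue = sub(rx, "\\1", toks),
    kind = sub(rx, "\\3", toks),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$site)) {
    stop("duplicate modification site in form '", form, "'")
  }
  out
}

#' Compose a form name from a site table
#'
#' Inverse of [parse_form()]; sites are emitted in ascending coordinate order,
#' which is the convention used throughout the catalog.
#'
#' @param mods Data frame with columns `site`, `residue`, `kind`.
#' @return Character form name (`"unmod"` when no modification is present).
#' @export
format_form <- function(mods) {
  if (nrow(mods) == 0L) return("unmod")
  mods <- mods[order(mods$site), , drop = FALSE]
  paste0(mods$residue, mods$site, mods$kind, collapse = "")
}

#' Apply the two-round propionylation rules to a peptide
#'
#' Propionic-anhydride derivatization, done once before and once after tryptic
#' digestion, places a propionyl group (i) on the peptide N-terminus and (ii)
#' on the epsilon-amine of every lysine that is unmodified or monomethylated.
#' Lysines carrying me2, me3 or ac have no reactive amine and receive no
#' propionyl. Derivatization is modeled as complete (no under-propionylation).
#'
#' @param sequence Peptide sequence (one-letter residues).
#' @param mods Biological modifications: either a form name string (see
#'   [parse_form()]) or a data frame with columns `site` and `kind` (`residue`
#'   optional), with `site` in the protein coordinates implied by `start`.
#'   Passing an existing `derivatized_peptide` re-derivatizes it (a no-op).
#' @param start 1-based protein coordinate of the first residue, so that
#'   modification sites can be given in protein numbering (e.g. K9 within the
#'   peptide spanning residues 9-17).
#' @return An object of class `derivatized_peptide`: a list with elements
#'   `sequence`, `start`, `mods` (site table), `nterm_prop` (always `TRUE`)
#'   and `prop_sites` (protein coordinates of propionylated lysines).
#' @export
#' @examples
#' dp <- derivatize("KSTGGKAPR", "K9me2", start = 9)
#' dp$prop_sites   # K14 only: me2 blocks propionylation of K9
derivatize <- function(sequence, mods = NULL, start = 1L) {
  if (inherits(sequence, "derivatized_peptide")) {
    dp <- sequence
    return(derivatize(dp$sequence, dp$mods, start = dp$start))
  }
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% names(.RESIDUE_MASS))) {
    stop("unknown residue symbol in '", sequence, "': ",
         paste(setdiff(res, names(.RESIDUE_MASS)), collapse = ", "))
  }
  start <- as.integer(start)
  if (is.null(mods)) {
    mods <- parse_form("unmod")
  } else if (is.character(mods)) {
    mods <- parse_form(mods)
  }
  stopifnot(is.data.frame(mods), all(c("site", "kind") %in% names(mods)))
  mods <- mods[mods$kind != "unmod", , drop = FALSE]
  n <- length(res)
  local <- as.integer(mods$site) - start + 1L
  if (any(local < 1L | local > n)) {
    stop("modification site outside peptide ", start, "-", start + n - 1L)
  }
  if (anyDuplicated(mods$site)) stop("more than one modification on a residue")
  mods$residue <- res[local]
  for (i in seq_len(nrow(mods))) {
    ok <- .MOD_TARGETS[[mods$kind[i]]]
    if (is.null(ok) || !(mods$residue[i] %in% ok)) {
      stop("modification '", mods$kind[i], "' cannot sit on residue '",
           mods$residue[i], "' at position ", mods$site[i])
    }
  }
  mods <- mods[order(mods$site), c("site", "residue", "kind"), drop = FALSE]
  rownames(mods) <- NULL

  k_coord <- which(res == "K") + start - 1L
  k_state <- rep("unmod", length(k_coord))
  hit <- match(k_coord, mods$site)
  k_state[!is.na(hit)] <- mods$kind[hit[!is.na(hit)]]
  structure(
    list(sequence = sequence, start = start, mods = mods,
         nterm_prop = TRUE,
         prop_sites = k_coord[k_state %in% .PROP_RETAINING]),
    class = "derivatized_peptide"
  )
}

#' @export
print.derivatized_peptide <- function(x, ...) {
  cat(sprintf("<derivatized peptide %s (%d-%d), %s, %d propionyl>\n",
              x$sequence, x$start, x$start + nchar(x$sequence) - 1L,
              format_form(x$mods), n_propionyl(x)))
  invisible(x)
}

#' Number of propionyl groups on a derivatized peptide
#' @param dp A `derivatized_peptide`.
#' @return Integer count (N-terminal propionyl plus propionylated lysines).
#' @export
n_propionyl <- function(dp) {
  stopifnot(inherits(dp, "derivatized_peptide"))
  as.integer(dp$nterm_prop) + length(dp$prop_sites)
}

#' Monoisotopic neutral mass of a derivatized peptide
#' @param dp A `derivatized_peptide`.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(dp) {
  stopifnot(inherits(dp, "derivatized_peptide"))
  res <- strsplit(dp$sequence, "")[[1]]
  sum(.RESIDUE_MASS[res]) + .WATER +
    sum(.MOD_DELTA[dp$mods$kind]) +
    .MOD_DELTA[["prop"]] * n_propionyl(dp)
}

#' Precursor m/z of a derivatized peptide
#'
#' `(M + z * proton) / z` with the proton mass 1.00727646 Da.
#'
#' @param dp A `derivatized_peptide`.
#' @param charge Positive integer charge state.
#' @return Precursor m/z.
#' @export
#' @examples
#' dp <- derivatize("KQLATKAAR", "K18me1", start = 18)
#' precursor_mz(dp, 2)  # 584.8561
precursor_mz <- function(dp, charge = 2L) {
  charge <- as.integer(charge)
  stopifnot(charge >= 1L)
  (neutral_mass(dp) + charge * .PROTON) / charge
}

#' Singly or multiply charged b/y fragment m/z
#'
#' b_i carries the first `index` residues plus the N-terminal propionyl and
#' any side-chain modifications on those residues; y_i carries the last
#' `index` residues, their modifications, and the C-terminal water.
#'
#' @param dp A `derivatized_peptide`.
#' @param series `"b"` or `"y"`.
#' @param index Fragment index, `1 <= index < nchar(sequence)`.
#' @param charge Fragment charge (default 1).
#' @return Fragment m/z.
#' @export
fragment_mz <- function(dp, series = c("b", "y"), index, charge = 1L) {
  series <- match.arg(series)
  stopifnot(inherits(dp, "derivatized_peptide"))
  res <- strsplit(dp$sequence, "")[[1]]
  n <- length(res)
  index <- as.integer(index)
  if (index < 1L || index >= n) {
    stop("fragment index must be in [1, ", n - 1L, "], got ", index)
  }
  local_mods <- dp$mods$site - dp$start + 1L
  local_props <- dp$prop_sites - dp$start + 1L
  if (series == "b") {
    keep <- seq_len(index)
    mass <- sum(.RESIDUE_MASS[res[keep]]) +
      sum(.MOD_DELTA[dp$mods$kind[local_mods <= index]]) +
      .MOD_DELTA[["prop"]] * (as.integer(dp$nterm_prop) + sum(local_props <= index))
  } else {
    keep <- seq.int(n - index + 1L, n)
    mass <- sum(.RESIDUE_MASS[res[keep]]) + .WATER +
      sum(.MOD_DELTA[dp$mods$kind[local_mods > n - index]]) +
      .MOD_DELTA[["prop"]] * sum(local_props > n - index)
  }
  (mass + charge * .PROTON) / charge
}

#' All b/y fragment ions of a derivatized peptide
#'
#' @param dp A `derivatized_peptide`.
#' @param charges Fragment charge states to enumerate (default singly charged,
#'   sufficient for splitting isobaric precursors of charge <= 3).
#' @return Data frame with columns `series`, `index`, `charge`, `mz`.
#' @export
fragment_ions <- function(dp, charges = 1L) {
  n <- nchar(dp$sequence)
  grid <- expand.grid(index = seq_len(n - 1L), series = c("b", "y"),
                      charge = as.integer(charges),
                      stringsAsFactors = FALSE)
  grid$mz <- vapply(seq_len(nrow(grid)), function(i) {
    fragment_mz(dp, grid$series[i], grid$index[i], grid$charge[i])
  }, numeric(1))
  grid[, c("series", "index", "charge", "mz")]
}
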