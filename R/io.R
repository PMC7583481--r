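# Reading and writing runs: a documented tab-separated scan table (internal
# format) and centroided mzML (64-bit, uncompressed binary arrays).

#' Write a run to disk
#'
#' `format = "internal"` writes one tab-separated table of centroids with
#' columns `scan`, `ms_level`, `rt`, `precursor_mz`, `mz`, `intensity`
#' (empty `precursor_mz` for MS1 rows), preceded by `#`-prefixed header
#' lines carrying scan-grid metadata. `format = "mzML"` writes a centroided
#' mzML document with 64-bit little-endian uncompressed binary arrays.
#' Either round-trips through [read_run()] (m/z to 1e-5, intensity to 1e-3
#' relative).
#'
#' @param run An `ms_run`.
#' @param path Output file path.
#' @param format `"internal"` or `"mzML"`; default from the file extension.
#' @return Invisibly, `path`.
#' @export
write_run <- function(run, path, format = c("auto", "internal", "mzML")) {
  stopifnot(inherits(run, "ms_run"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE))
      "mzML" else "internal"
  }
  if (format == "internal") .write_run_tsv(run, path) else
    .write_run_mzml(run, path)
  invisible(path)
}

.write_run_tsv <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# histoneptm run table v1",
    sprintf("# scan_times\t%s", paste(sprintf("%.6g", run$scan_times),
                                      collapse = ",")),
    sprintf("# seed\t%s", format(run$meta$seed)),
    "scan\tms_level\trt\tprecursor_mz\tmz\tintensity"), con)
  fmt <- function(df, level, prec) {
    if (nrow(df) == 0L) return(character())
    sprintf("%d\t%d\t%.6f\t%s\t%.6f\t%.6e",
            df$scan, level, df$rt, prec, df$mz, df$intensity)
  }
  writeLines(fmt(run$ms1, 1L, ""), con)
  writeLines(fmt(run$ms2, 2L, sprintf("%.6f", run$ms2$precursor_mz)), con)
}

.read_run_tsv <- function(path) {
  hdr <- readLines(path, n = 10)
  st_line <- grep("^# scan_times\t", hdr, value = TRUE)
  seed_line <- grep("^# seed\t", hdr, value = TRUE)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  ms1 <- d[d$ms_level == 1L, c("scan", "rt", "mz", "intensity")]
  ms2 <- d[d$ms_level == 2L,
           c("scan", "rt", "precursor_mz", "mz", "intensity")]
  rownames(ms1) <- rownames(ms2) <- NULL
  scan_times <- if (length(st_line)) {
    as.numeric(strsplit(sub("^# scan_times\t", "", st_line), ",")[[1]])
  } else sort(unique(ms1$rt))
  seed <- if (length(seed_line))
    suppressWarnings(as.integer(sub("^# seed\t", "", seed_line))) else NA
  structure(list(ms1 = ms1, ms2 = ms2, scan_times = scan_times,
                 meta = list(seed = seed, source = path)),
            class = "ms_run")
}

.b64_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

.doubles_b64 <- function(s, n) {
  readBin(jsonlite::base64_dec(s), what = "numeric", n = n, size = 8L,
          endian = "little")
}

.mzml_spectrum <- function(index, id, ms_level, rt, mz, intensity,
                           precursor_mz = NA) {
  cv <- function(acc, name, value = NULL, unit = NULL) {
    paste0('<cvParam cvRef="MS" accession="', acc, '" name="', name, '"',
           if (!is.null(value)) paste0(' value="', value, '"'),
           if (!is.null(unit))
             paste0(' unitCvRef="UO" unitAccession="UO:0000031"',
                    ' unitName="minute"'),
           '/>')
  }
  arr <- function(data, acc, name) {
    b64 <- .b64_doubles(data)
    paste0('<binaryDataArray encodedLength="', nchar(b64), '">',
           cv("MS:1000523", "64-bit float"),
           cv("MS:1000576", "no compression"),
           cv(acc, name),
           '<binary>', b64, '</binary></binaryDataArray>')
  }
  paste0(
    '<spectrum index="', index, '" id="', id, '" defaultArrayLength="',
    length(mz), '">',
    cv("MS:1000511", "ms level", ms_level),
    cv("MS:1000127", "centroid spectrum"),
    '<scanList count="1">',
    cv("MS:1000795", "no combination"),
    '<scan>', cv("MS:1000016", "scan start time", sprintf("%.6f", rt),
                 unit = TRUE),
    '</scan></scanList>',
    if (!is.na(precursor_mz)) paste0(
      '<precursorList count="1"><precursor><selectedIonList count="1">',
      '<selectedIon>',
      cv("MS:1000744", "selected ion m/z", sprintf("%.6f", precursor_mz)),
      '</selectedIon></selectedIonList></precursor></precursorList>') else "",
    '<binaryDataArrayList count="2">',
    arr(mz, "MS:1000514", "m/z array"),
    arr(intensity, "MS:1000515", "intensity array"),
    '</binaryDataArrayList></spectrum>'
  )
}

.write_run_mzml <- function(run, path) {
  ms1_by <- split(run$ms1, run$ms1$scan)
  ms2_rows <- run$ms2
  ms2_key <- if (nrow(ms2_rows))
    paste(ms2_rows$scan, sprintf("%.6f", ms2_rows$precursor_mz)) else
      character()
  ms2_by <- split(ms2_rows, ms2_key)
  ms2_scan_of <- vapply(ms2_by, function(b) b$scan[1], integer(1))
  ms2_groups_at <- split(names(ms2_by), ms2_scan_of)

  specs <- vector("list", length(run$scan_times) + length(ms2_by))
  n_s <- 0L
  idx <- 0L
  for (s in seq_along(run$scan_times)) {
    b <- ms1_by[[as.character(s)]]
    mzv <- if (is.null(b)) numeric() else b$mz
    intv <- if (is.null(b)) numeric() else b$intensity
    n_s <- n_s + 1L
    specs[[n_s]] <- .mzml_spectrum(
      idx, paste0("scan=", idx + 1L), 1L, run$scan_times[s], mzv, intv)
    idx <- idx + 1L
    for (k in ms2_groups_at[[as.character(s)]]) {
      b2 <- ms2_by[[k]]
      n_s <- n_s + 1L
      specs[[n_s]] <- .mzml_spectrum(
        idx, paste0("scan=", idx + 1L), 2L, b2$rt[1], b2$mz, b2$intensity,
        precursor_mz = b2$precursor_mz[1])
      idx <- idx + 1L
    }
  }
  specs <- unlist(specs[seq_len(n_s)])
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum"/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="histoneptm" version="',
    as.character(utils::packageVersion("histoneptm")), '"/></softwareList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="simulation">',
    '<processingMethod order="1" softwareRef="histoneptm"/>',
    '</dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    '<spectrumList count="', idx, '" defaultDataProcessingRef="simulation">',
    paste(specs, collapse = ""),
    '</spectrumList></run></mzML>\n'
  )
  writeLines(doc, path, sep = "")
}

.read_run_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  specs <- xml2::xml_find_all(doc, ".//spectrum")
  n_spec <- length(specs)
  # vectorized attribute extraction over the spectrum nodeset
  level <- as.integer(xml2::xml_attr(xml2::xml_find_first(
    specs, "cvParam[@accession='MS:1000511']"), "value"))
  rt <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
    specs, ".//scan/cvParam[@accession='MS:1000016']"), "value"))
  prec <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
    specs, ".//cvParam[@accession='MS:1000744']"), "value"))
  n_pts <- as.integer(xml2::xml_attr(specs, "defaultArrayLength"))

  arrs <- xml2::xml_find_all(doc, ".//binaryDataArray")
  arr_is_mz <- !is.na(xml2::xml_attr(xml2::xml_find_first(
    arrs, "cvParam[@accession='MS:1000514']"), "accession"))
  arr_b64 <- xml2::xml_text(xml2::xml_find_all(arrs, "binary"))
  # two arrays per spectrum, in document order
  if (length(arrs) != 2L * n_spec) {
    stop("malformed mzML: expected 2 binary arrays per spectrum in ", path)
  }
  arr_spec <- rep(seq_len(n_spec), each = 2L)
  mz_list <- vector("list", n_spec)
  int_list <- vector("list", n_spec)
  for (a in seq_along(arrs)) {
    s <- arr_spec[a]
    if (n_pts[s] == 0L) next
    vals <- .doubles_b64(arr_b64[a], n_pts[s])
    if (arr_is_mz[a]) mz_list[[s]] <- vals else int_list[[s]] <- vals
  }

  is1 <- level == 1L
  scan_no <- cumsum(is1)
  scan_times <- rt[is1]
  per <- ifelse(is1, n_pts, 0L)
  ms1 <- data.frame(
    scan = rep(scan_no, per), rt = rep(rt, per),
    mz = unlist(mz_list[is1 & n_pts > 0]),
    intensity = unlist(int_list[is1 & n_pts > 0]))
  per2 <- ifelse(!is1, n_pts, 0L)
  ms2 <- data.frame(
    scan = rep(scan_no, per2), rt = rep(rt, per2),
    precursor_mz = rep(prec, per2),
    mz = unlist(mz_list[!is1 & n_pts > 0]),
    intensity = unlist(int_list[!is1 & n_pts > 0]))
  if (nrow(ms1) == 0L) {
    ms1 <- data.frame(scan = integer(), rt = numeric(), mz = numeric(),
                      intensity = numeric())
  }
  if (nrow(ms2) == 0L) {
    ms2 <- data.frame(scan = integer(), rt = numeric(),
                      precursor_mz = numeric(), mz = numeric(),
                      intensity = numeric())
  }
  structure(list(ms1 = ms1, ms2 = ms2, scan_times = scan_times,
                 meta = list(source = path)), class = "ms_run")
}

#' Read a run from disk
#'
#' Accepts the internal tab-separated scan table or centroided mzML; the
#' format is inferred from the extension unless given.
#'
#' @param path Input file.
#' @param format `"auto"`, `"internal"` or `"mzML"`.
#' @return An `ms_run`.
#' @export
read_run <- function(path, format = c("auto", "internal", "mzML")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read run file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE))
      "mzML" else "internal"
  }
  if (format == "internal") .read_run_tsv(path) else .read_run_mzml(path)
}
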