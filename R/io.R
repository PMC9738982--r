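# Plain-text spectrum I/O: spectrometer-style two-column exports and wide CSV
# tables with one column per cuvette. Both formats round-trip through
# write_spectra()/read_spectra().

VALUE_KINDS <- c("absorption_percent", "transmittance_fraction")

meta_to_string <- function(meta) {
  keys <- c(species = "species", counter_concentration = "concentration",
            set_id = "set", time_h = "time", cuvette_id = "cuvette",
            true_concentration = "true_concentration")
  parts <- character(0)
  for (field in names(keys)) {
    v <- meta[[field]]
    if (!is.null(v) && !is.na(v))
      parts <- c(parts, paste0(keys[[field]], "=",
                               if (is.numeric(v)) format(v, digits = 17) else v))
  }
  paste(parts, collapse = ";")
}

string_to_meta <- function(s) {
  meta <- list()
  if (!nzchar(s)) return(meta)
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (!nzchar(kv)) next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stopf("malformed metadata token '%s' (expected key=value)", kv)
    key <- substr(kv, 1, eq - 1); val <- substr(kv, eq + 1, nchar(kv))
    meta[[key]] <- val
  }
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  chr <- function(x) if (is.null(x)) NA_character_ else x
  list(species = chr(meta$species),
       counter_concentration = num(meta$concentration),
       time_h = num(meta$time), set_id = chr(meta$set),
       cuvette_id = chr(meta$cuvette),
       true_concentration = num(meta$true_concentration))
}

make_spectrum_from_meta <- function(w, v, value_kind, meta) {
  spectrum(w, v, value_kind = value_kind,
           species = meta$species %||% NA_character_,
           counter_concentration = meta$counter_concentration %||% NA_real_,
           time_h = meta$time_h %||% NA_real_,
           set_id = meta$set_id %||% NA_character_,
           cuvette_id = meta$cuvette_id %||% NA_character_,
           true_concentration = meta$true_concentration %||% NA_real_)
}

#' Read spectra from plain-text files
#'
#' Two formats are supported. `two_column_text`: one spectrum per file, with
#' `# key: value` header lines (the `value_kind` key is required) followed by
#' whitespace- or comma-separated (wavelength, value) rows; `path` may name
#' several files. `wide_csv`: first column holds the wavelength grid, each
#' further column one spectrum; metadata is embedded in the column headers as
#' `id;key=value;...` tokens and the first header cell carries
#' `wavelength;value_kind=...`. A sidecar JSON file `<path>.json` (fields
#' `value_kind` and per-column `columns`) overrides header metadata when
#' present.
#'
#' @param path file path (or vector of paths for `two_column_text`).
#' @param format `"wide_csv"` or `"two_column_text"`.
#' @return a [spectrum_set()].
#' @export
read_spectra <- function(path, format = c("wide_csv", "two_column_text")) {
  format <- match.arg(format)
  if (format == "two_column_text") {
    return(spectrum_set(lapply(path, read_two_column_one)))
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("wide CSV needs a wavelength column plus >= 1 spectrum")
  headers <- names(df)
  first <- strsplit(headers[1], ";", fixed = TRUE)[[1]]
  kind <- NA_character_
  for (tok in first[-1]) {
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] == "value_kind") kind <- kv[2]
  }
  sidecar <- paste0(path, ".json")
  side <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar, simplifyVector = FALSE) else NULL
  if (!is.null(side$value_kind)) kind <- side$value_kind
  if (is.na(kind)) stopf("value_kind missing from header and sidecar of %s", path)
  if (!kind %in% VALUE_KINDS) stopf("unknown value_kind '%s'", kind)
  w <- suppressWarnings(as.numeric(df[[1]]))
  if (any(is.na(w)))
    stopf("malformed wavelength at data row %d of %s", which(is.na(w))[1], path)
  spectra <- lapply(seq_along(headers)[-1], function(j) {
    h <- headers[j]
    semi <- regexpr(";", h, fixed = TRUE)
    id <- if (semi > 0) substr(h, 1, semi - 1) else h
    meta <- if (semi > 0) string_to_meta(substr(h, semi + 1, nchar(h))) else list()
    sc <- side$columns[[id]]
    if (!is.null(sc)) {
      for (f in names(sc)) meta[[f]] <- sc[[f]]
    }
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (any(is.na(v)))
      stopf("malformed value at data row %d, column '%s' of %s",
            which(is.na(v))[1], id, path)
    make_spectrum_from_meta(w, v, kind, meta)
  })
  spectrum_set(spectra)
}

read_two_column_one <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  hdr <- grepl("^\\s*#", lines)
  meta <- list(); kind <- NA_character_
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2]); val <- trimws(m[3])
      if (key == "value_kind") kind <- val else meta[[key]] <- val
    }
  }
  if (is.na(kind)) stopf("value_kind header missing in %s", path)
  if (!kind %in% VALUE_KINDS) stopf("unknown value_kind '%s' in %s", kind, path)
  data_lines <- which(!hdr & nzchar(trimws(lines)))
  if (length(data_lines) == 0) stopf("no data rows in %s", path)
  w <- numeric(length(data_lines)); v <- numeric(length(data_lines))
  for (i in seq_along(data_lines)) {
    ln <- data_lines[i]
    toks <- strsplit(trimws(lines[ln]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) != 2 || any(is.na(vals)))
      stopf("malformed row at line %d of %s: '%s'", ln, path, lines[ln])
    w[i] <- vals[1]; v[i] <- vals[2]
  }
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  chr <- function(x) if (is.null(x)) NA_character_ else x
  make_spectrum_from_meta(w, v, kind, list(
    species = chr(meta$species),
    counter_concentration = num(meta$concentration),
    time_h = num(meta$time), set_id = chr(meta$set),
    cuvette_id = chr(meta$cuvette),
    true_concentration = num(meta$true_concentration)))
}

#' Write spectra to plain-text files
#'
#' Inverse of [read_spectra()]; writes round-trip bit-exactly (values are
#' serialized with 17 significant digits).
#'
#' @param set a [spectrum_set()].
#' @param path output file (`wide_csv`) or vector of one path per spectrum
#'   (`two_column_text`).
#' @param format `"wide_csv"` or `"two_column_text"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path, format = c("wide_csv", "two_column_text")) {
  format <- match.arg(format)
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  if (format == "two_column_text") {
    if (length(path) != length(set$spectra))
      stopf("need one path per spectrum (%d given, %d spectra)",
            length(path), length(set$spectra))
    for (i in seq_along(path)) {
      s <- set$spectra[[i]]
      hdr <- c(sprintf("# value_kind: %s", s$value_kind))
      keys <- c(species = "species", counter_concentration = "concentration",
                set_id = "set", time_h = "time", cuvette_id = "cuvette",
                true_concentration = "true_concentration")
      for (field in names(keys)) {
        v <- s$meta[[field]]
        if (!is.null(v) && !is.na(v))
          hdr <- c(hdr, sprintf("# %s: %s", keys[[field]],
                                if (is.numeric(v)) fmt(v) else v))
      }
      writeLines(c(hdr, paste(fmt(s$wavelengths_nm), fmt(s$values))), path[i])
    }
    return(invisible(path))
  }
  if (!set$common_grid) stopf("wide CSV requires a common wavelength grid")
  if (length(set$spectra) == 0) stopf("empty spectrum set")
  kind <- unique(vapply(set$spectra, `[[`, character(1), "value_kind"))
  if (length(kind) != 1) stopf("mixed value kinds in one wide CSV")
  w <- set$spectra[[1]]$wavelengths_nm
  headers <- c(sprintf("wavelength;value_kind=%s", kind))
  cols <- list()
  for (i in seq_along(set$spectra)) {
    s <- set$spectra[[i]]
    id <- s$meta$cuvette_id
    if (is.null(id) || is.na(id)) id <- sprintf("s%d", i)
    ms <- meta_to_string(s$meta)
    headers <- c(headers, if (nzchar(ms)) paste0(id, ";", ms) else id)
    cols[[i]] <- s$values
  }
  quote_cell <- function(x) paste0('"', gsub('"', '""', x), '"')
  lines <- c(paste(vapply(headers, quote_cell, character(1)), collapse = ","),
             vapply(seq_along(w), function(r)
               paste(c(fmt(w[r]),
                       vapply(cols, function(cc) fmt(cc[r]), character(1))),
                     collapse = ","), character(1)))
  writeLines(lines, path)
  invisible(path)
}
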