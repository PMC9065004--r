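#' Read a Mascot Generic Format (mgf) file
#'
#' Parses BEGIN IONS / END IONS blocks. `PEPMASS` (first token) is the
#' precursor m/z; `CHARGE=2-` gives magnitude 2, negative polarity;
#' `RTINSECONDS` and `TITLE` are kept when present. Spectra with an empty
#' peak list are skipped with a warning; a block without PEPMASS is an
#' error naming the scan.
#'
#' @param path mgf file path.
#' @return List of `spectrum` objects: `scan` (title or running index),
#'   `pepmass`, `charge` (magnitude), `polarity`, `rt`, `peaks` (two-column
#'   matrix `mz`, `intensity`, sorted by m/z).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed mgf: unbalanced BEGIN/END IONS", call. = FALSE)
  }
  spectra <- list()
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(block)]
    is_kv <- grepl("^[A-Z]+=", block)
    kv <- block[is_kv]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[A-Z]+=", "", kv)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pep <- get("PEPMASS")
    if (is.na(pep)) {
      stop("mgf scan ", b, ": missing PEPMASS", call. = FALSE)
    }
    chg <- get("CHARGE")
    charge <- NA_integer_
    polarity <- "-"
    if (!is.na(chg)) {
      polarity <- if (grepl("-", chg, fixed = TRUE)) "-" else "+"
      charge <- as.integer(gsub("[^0-9]", "", chg))
    }
    peak_lines <- block[!is_kv]
    peaks <- matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("mz", "intensity")))
    if (length(peak_lines) > 0L) {
      fields <- strsplit(trimws(peak_lines), "[ \t]+")
      mzv <- as.numeric(vapply(fields, `[`, character(1), 1L))
      iv <- as.numeric(vapply(fields, `[`, character(1), 2L))
      if (anyNA(mzv) || anyNA(iv)) {
        stop("mgf scan ", b, ": malformed peak line", call. = FALSE)
      }
      o <- order(mzv)
      peaks <- cbind(mz = mzv[o], intensity = iv[o])
    }
    if (nrow(peaks) == 0L) {
      warning("mgf scan ", b, ": empty peak list, skipped")
      next
    }
    title <- get("TITLE")
    rt <- suppressWarnings(as.numeric(get("RTINSECONDS")))
    spectra[[length(spectra) + 1L]] <- structure(
      list(scan = if (is.na(title)) paste0("scan_", b) else title,
           pepmass = as.numeric(strsplit(pep, "[ \t]+")[[1]][1L]),
           charge = charge, polarity = polarity, rt = rt, peaks = peaks),
      class = "spectrum")
  }
  spectra
}

#' Write spectra to an mgf file
#'
#' Standard dialect: BEGIN IONS / TITLE / PEPMASS / CHARGE (with trailing
#' `-` for negative polarity) / RTINSECONDS / peak lines / END IONS.
#' Numeric formatting is fixed so the output is byte-stable.
#'
#' @param spectra List of `spectrum` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$scan), con)
    writeLines(paste0("PEPMASS=", formatC(sp$pepmass, format = "f",
                                          digits = 6)), con)
    if (!is.na(sp$charge)) {
      writeLines(paste0("CHARGE=", sp$charge,
                        if (identical(sp$polarity, "-")) "-" else "+"), con)
    }
    if (!is.null(sp$rt) && !is.na(sp$rt)) {
      writeLines(paste0("RTINSECONDS=", formatC(sp$rt, format = "f",
                                                digits = 3)), con)
    }
    apply(sp$peaks, 1, function(p) {
      writeLines(paste(formatC(p[1], format = "f", digits = 6),
                       formatC(p[2], format = "f", digits = 2)), con)
    })
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s  m/z %.4f  z=%s%s  %d peaks\n", x$scan,
              x$pepmass, x$charge, x$polarity, nrow(x$peaks)))
  invisible(x)
}
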