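#' Filter ranked OSMs into a final report
#'
#' Removes decoys and low-confidence identifications. All thresholds are
#' optional; tightening any of them can only shrink the report.
#'
#' @param osms Ranked OSM table from [search_spectra()].
#' @param sp_min Minimum S_p of the top match.
#' @param dsp2_min Minimum dSp2: matches whose runner-up target is within
#'   this relative distance of the top score are considered low-specificity
#'   and removed (rows with no runner-up pass).
#' @param fdr Desired FDR level; converted to a uniform S_p cutoff via
#'   [sp_cutoff_for_fdr()] on the rank-1 OSMs.
#' @param unique_only Keep one row per distinct (sequence, channel); light
#'   and heavy identifications are counted separately.
#' @param modified_only Keep only sequences containing a non-canonical
#'   residue code.
#' @param require_decoy Restrict the FDR computation to targets with at
#'   least one competing decoy (see [rank1_for_stats()]).
#' @param alphabet Residue alphabet (to recognize modification codes).
#' @return Filtered data.frame of rank-1 target identifications.
#' @export
filter_report <- function(osms, sp_min = 0, dsp2_min = 0, fdr = NULL,
                          unique_only = FALSE, modified_only = FALSE,
                          require_decoy = TRUE,
                          alphabet = default_alphabet()) {
  rec <- osms[osms$rank == 1L & !osms$is_decoy, , drop = FALSE]
  rec <- rec[rec$Sp >= sp_min, , drop = FALSE]
  if (dsp2_min > 0) {
    rec <- rec[is.na(rec$dSp2) | rec$dSp2 >= dsp2_min, , drop = FALSE]
  }
  if (!is.null(fdr)) {
    cutoff <- sp_cutoff_for_fdr(rank1_for_stats(osms, require_decoy), fdr)
    rec <- rec[rec$Sp >= cutoff, , drop = FALSE]
  }
  if (modified_only) {
    canon <- c("A", "C", "G", "U")
    has_mod <- vapply(strsplit(rec$seq, ""), function(cs) {
      any(!cs %in% canon)
    }, logical(1))
    rec <- rec[has_mod, , drop = FALSE]
  }
  if (unique_only) {
    rec <- rec[order(-rec$Sp), , drop = FALSE]
    rec <- rec[!duplicated(paste(rec$seq, rec$channel)), , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Map identifications onto reference sequences
#'
#' Marks every reference position covered by at least one identified
#' fragment and reports percent coverage, plus the stricter coverage by
#' fragments whose sequence occurs at exactly one position in the reference
#' (unique placement).
#'
#' @param records Filtered report rows carrying `parent_id`, `start`, `end`,
#'   `seq`.
#' @param references Named character vector of (modified) parent sequences.
#' @return List of per-reference coverage maps: `reference`, `length`,
#'   `hits` (per-position counts), `percent`, `unique_percent`.
#' @export
map_coverage <- function(records, references) {
  lapply(names(references), function(id) {
    ref <- references[[id]]
    len <- nchar(ref)
    hits <- integer(len)
    uniq <- integer(len)
    rows <- records[records$parent_id == id & !is.na(records$start), ,
                    drop = FALSE]
    if (nrow(rows) > 0L && any(rows$end > len)) {
      stop("record positions exceed reference length for ", id,
           call. = FALSE)
    }
    for (i in seq_len(nrow(rows))) {
      span <- rows$start[i]:rows$end[i]
      hits[span] <- hits[span] + 1L
      occ <- gregexpr(rows$seq[i], ref, fixed = TRUE)[[1L]]
      n_occ <- if (occ[1L] == -1L) 0L else length(occ)
      if (n_occ == 1L) uniq[span] <- uniq[span] + 1L
    }
    structure(list(reference = id, length = len, hits = hits,
                   percent = 100 * sum(hits > 0L) / len,
                   unique_percent = 100 * sum(uniq > 0L) / len),
              class = "coverage_map")
  })
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf("<coverage_map> %s: %.1f%% covered (%.1f%% unique placement)\n",
              x$reference, x$percent, x$unique_percent))
  invisible(x)
}

#' Coverage intervals as a BED-like table
#'
#' @param coverage List from [map_coverage()].
#' @return data.frame `reference`, `start`, `end` (1-based inclusive runs of
#'   covered positions).
#' @export
coverage_intervals <- function(coverage) {
  rows <- lapply(coverage, function(cm) {
    r <- rle(cm$hits > 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(reference = cm$reference, start = starts[keep],
               end = ends[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(reference = character(0), start = integer(0),
                      end = integer(0))
  }
  out
}

#' Per-ion annotation of one OSM
#'
#' Recomputes the peak assignment for a spectrum/entry pair and returns the
#' full predicted-ion table (one row per theoretical ion: series, index,
#' charge, theoretical m/z, matched peak m/z and normalized intensity, ppm
#' error, matched flag) for manual curation, plus the precursor-loss
#' annotation.
#'
#' @param spectrum A `spectrum`.
#' @param entry A `library_entry`.
#' @param params [score_params()].
#' @return List of class `osm_annotation`: `scan`, `display`, `table`,
#'   `losses`, `n`, `L`, `Sp`.
#' @export
annotate_spectrum <- function(spectrum, entry, params = score_params()) {
  m <- match_fragments(spectrum, entry, params)
  structure(list(scan = spectrum$scan, display = entry$display,
                 table = m$assignments, losses = m$excluded,
                 n = m$n, L = m$L, Sp = score_sp(m, params)),
            class = "osm_annotation")
}

#' Write an annotation as TSV and simple static HTML
#'
#' @param annotation An `osm_annotation`.
#' @param path Output path without extension; writes `<path>.tsv` and
#'   `<path>.html`.
#' @return Paths, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  tsv <- paste0(path, ".tsv")
  utils::write.table(annotation$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tab <- annotation$table
  cell <- function(v) ifelse(is.na(v), "", format(v, digits = 8))
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    cls <- if (tab$matched[i]) " class='matched'" else ""
    paste0("<tr", cls, "><td>", tab$series[i], "</td><td>", tab$index[i],
           "</td><td>", tab$charge[i], "</td><td>",
           cell(tab$mz[i]), "</td><td>", cell(tab$peak_mz[i]),
           "</td><td>", cell(tab$ppm[i]), "</td></tr>")
  }, character(1))
  html <- c(
    "<html><head><style>",
    "table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px}",
    ".matched{background:#cfe8cf}",
    "</style></head><body>",
    sprintf("<h3>%s &mdash; %s</h3>", annotation$scan, annotation$display),
    sprintf("<p>n = %d of L = %d, S<sub>p</sub> = %.4f</p>",
            annotation$n, annotation$L, annotation$Sp),
    "<table><tr><th>series</th><th>i</th><th>z</th><th>theoretical m/z</th>",
    "<th>matched peak</th><th>ppm</th></tr>",
    rows, "</table></body></html>")
  writeLines(html, paste0(path, ".html"))
  invisible(c(tsv = tsv, html = paste0(path, ".html")))
}
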