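# Coordinate parsing and TSV report rendering. User-facing coordinates are
# 1-based inclusive in the UCSC style "contig:start-end"; everything
# internal is 0-based half-open.

#' Parse a genomic region string
#'
#' Accepts `"contig:start-end"` with either an ASCII hyphen or a Unicode
#' en-dash (as coordinates are often pasted from genome browsers). Thousands
#' separators are rejected.
#'
#' @param text a single region string, 1-based inclusive.
#' @return an object of class `region_spec`: list with `contig`, `start` and
#'   `end` (1-based inclusive, as typed) and `start0`/`end0` (0-based
#'   half-open).
#' @examples
#' parse_region("chr17:7671806-7671856")$end0 - parse_region("chr17:7671806-7671856")$start0
#' @export
parse_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^(\\S+):([0-9]+)[-–]([0-9]+)$", text))[[1]]
  if (length(m) != 4L)
    fk_stop("parse_error", "cannot parse region '%s' (expected contig:start-end)", text)
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  if (start < 1)
    fk_stop("parse_error", "region start must be >= 1 in '%s'", text)
  if (start > end)
    fk_stop("inverted_interval", "region start %s exceeds end %s", m[3], m[4])
  structure(list(contig = m[2], start = start, end = end,
                 start0 = start - 1, end0 = end),
            class = "region_spec")
}

#' Render a 0-based location as a 1-based inclusive region string
#'
#' @param contig contig name(s).
#' @param offset 0-based window start(s).
#' @param k window length.
#' @param strand `"+"` or `"-"` (omitted from the string when `NULL`).
#' @return character vector like `"c1:1-4:+"`.
#' @export
render_location <- function(contig, offset, k, strand = NULL) {
  base <- sprintf("%s:%.0f-%.0f", contig, offset + 1, offset + k)
  if (is.null(strand)) base else paste0(base, ":", strand)
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region> %s:%.0f-%.0f (%.0f bp)\n", x$contig, x$start, x$end,
              x$end - x$start + 1))
  invisible(x)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}

#' Write summary and detail query reports as TSV
#'
#' The summary table (one row per query window, counts grouped by mismatch
#' distance) is always written in full. The detail table is truncated to the
#' first `max_detail_rows` rows; any remainder goes to a sidecar overflow
#' file next to the detail file, with a notice logged to standard error.
#' Truncation never alters the summary, which is computed before it.
#'
#' @param summary a [summarize_windows()] data.frame (or `NULL` to skip).
#' @param detail a [detail_windows()] data.frame (or `NULL` to skip).
#' @param summary_path,detail_path output TSV paths.
#' @param max_detail_rows detail rows kept in the main file (default 1000).
#' @param overflow_path sidecar path for truncated rows.
#' @return invisible list of the paths written and the number of truncated
#'   rows.
#' @export
write_report_tables <- function(summary = NULL, detail = NULL,
                                summary_path = NULL, detail_path = NULL,
                                max_detail_rows = 1000L,
                                overflow_path = if (!is.null(detail_path))
                                  paste0(detail_path, ".overflow.tsv") else NULL) {
  if (!is.null(max_detail_rows) && max_detail_rows < 1L)
    fk_stop("range_error", "max_detail_rows must be >= 1")
  written <- list(truncated = 0L)
  if (!is.null(summary) && !is.null(summary_path)) {
    s <- summary
    s$flag <- ifelse(s$ambiguous, "ambiguous", "ok")
    s <- s[, c("window_index", "kmer", "n_exact", "n_mm1", "n_mm2", "flag")]
    .write_tsv(s, summary_path)
    written$summary <- summary_path
  }
  if (!is.null(detail) && !is.null(detail_path)) {
    d <- detail[, c("window_index", "query_kmer", "distance", "match_rendered",
                    "count", "locations", "mismatch_positions")]
    keep <- seq_len(min(nrow(d), max_detail_rows))
    .write_tsv(d[keep, , drop = FALSE], detail_path)
    written$detail <- detail_path
    extra <- nrow(d) - length(keep)
    if (extra > 0L) {
      .write_tsv(d[-keep, , drop = FALSE], overflow_path)
      written$overflow <- overflow_path
      written$truncated <- extra
      message(sprintf("detail output truncated to %d rows; %d overflow rows written to %s",
                      max_detail_rows, extra, overflow_path))
    }
  }
  invisible(written)
}
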