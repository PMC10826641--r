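#' Merged interval set on one scaffold
#'
#' Intervals are stored 0-based half-open, sorted, with overlapping or
#' abutting intervals merged on construction.
#'
#' @param scaffold scaffold name.
#' @param starts,ends integer vectors, 0-based half-open.
#' @param feature_type label (default "CDS").
#' @return an `interval_set`.
#' @export
interval_set <- function(scaffold, starts, ends, feature_type = "CDS") {
  stop_if(length(starts) != length(ends), "starts/ends length mismatch")
  stop_if(any(starts < 0), "negative interval start")
  stop_if(any(ends <= starts), "interval with end <= start")
  m <- merge_intervals(starts, ends)
  structure(list(scaffold = scaffold, starts = m$starts, ends = m$ends,
                 feature_type = feature_type),
            class = "interval_set")
}

# merge sorted/unsorted 0-based half-open intervals; abutting merged too
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0) return(list(starts = integer(), ends = integer()))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- starts[i]; me <- ends[i] }
  }
  list(starts = c(out_s, ms), ends = c(out_e, me))
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set:", length(x$starts), x$feature_type, "interval(s) on",
      x$scaffold, "spanning", sum(x$ends - x$starts), "bp\n")
  invisible(x)
}

#' Read CDS (or other) intervals from GFF3 or BED
#'
#' GFF3 1-based closed coordinates are converted to the internal 0-based
#' half-open convention; BED is used as-is. Intervals are merged per
#' scaffold.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param feature_type GFF3 feature type to keep (default "CDS"; ignored
#'   for BED).
#' @return named list of [interval_set()], keyed by scaffold.
#' @export
read_intervals <- function(path, dialect = c("auto", "gff3", "bed"),
                           feature_type = "CDS") {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
    dialect <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (dialect == "gff3") {
    f <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(f, function(x) length(x) >= 5 && x[3] == feature_type,
                   logical(1))
    f <- f[keep]
    scaf <- vapply(f, `[`, "", 1)
    start <- as.integer(vapply(f, `[`, "", 4)) - 1L   # to 0-based
    end <- as.integer(vapply(f, `[`, "", 5))          # closed -> half-open
  } else {
    f <- strsplit(lines, "[\t ]+")
    scaf <- vapply(f, `[`, "", 1)
    start <- as.integer(vapply(f, `[`, "", 2))
    end <- as.integer(vapply(f, `[`, "", 3))
  }
  bad <- which(end <= start)
  stop_if(length(bad) > 0, "interval with end <= start at row ", bad[1],
          " (", scaf[bad[1]], ":", start[bad[1]], "-", end[bad[1]], ")")
  out <- lapply(split(seq_along(scaf), scaf), function(i)
    interval_set(scaf[i[1]], start[i], end[i], feature_type))
  out
}

#' Total overlap between a [start, end) range and an interval set
#' @param iv an `interval_set`.
#' @param start,end 0-based half-open query range.
#' @return overlap length in bp.
#' @export
interval_overlap <- function(iv, start, end) {
  sum(pmax(0, pmin(iv$ends, end) - pmax(iv$starts, start)))
}
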