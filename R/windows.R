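#' Fixed-width genomic windows
#'
#' Tiles each scaffold with windows of `size` bp every `step` bp
#' (nonoverlapping when `step == size`). A terminal window shorter than
#' `size` is kept and flagged `partial` so downstream statistics can
#' exclude it explicitly.
#'
#' @param scaffold_lengths named integer vector of scaffold lengths (bp).
#' @param size window size in bp (> 0).
#' @param step step between window starts in bp (default `size`).
#' @return data.frame: scaffold, start, end (0-based half-open), partial.
#' @export
bp_windows <- function(scaffold_lengths, size, step = size) {
  stop_if(size <= 0 || step <= 0, "size and step must be > 0")
  out <- lapply(names(scaffold_lengths), function(s) {
    len <- scaffold_lengths[[s]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + size, len)
    data.frame(scaffold = s, start = starts, end = ends,
               partial = ends - starts < size, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' SNP-count sliding windows
#'
#' Windows over consecutive SNP indices per scaffold; only complete
#' windows of `size` SNPs are emitted and windows never span scaffolds.
#' The bp span used to pair a SNP window with bp-based annotation is
#' `[first SNP position, last SNP position + 1)`.
#'
#' @param gm a [genotype_matrix()].
#' @param size SNPs per window (> 0).
#' @param slide SNPs between successive window starts (> 0).
#' @return data.frame: scaffold, start, end (bp span, 0-based half-open),
#'   snp_from, snp_to (row indices into `gm`, inclusive), n_snps.
#' @export
snp_windows <- function(gm, size, slide) {
  stop_if(size <= 0 || slide <= 0, "size and slide must be > 0")
  snp_idx <- snp_sites(gm)
  out <- list()
  for (s in unique(gm$scaffold)) {
    idx <- snp_idx[gm$scaffold[snp_idx] == s]
    n <- length(idx)
    if (n < size) next
    starts <- seq(1L, n - size + 1L, by = slide)
    out[[s]] <- data.frame(
      scaffold = s,
      start = gm$pos[idx[starts]] - 1L,
      end = gm$pos[idx[starts + size - 1L]],
      snp_from = idx[starts], snp_to = idx[starts + size - 1L],
      n_snps = size, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    warning("no scaffold holds ", size, " SNPs; empty window set")
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), snp_from = integer(),
                      snp_to = integer(), n_snps = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genic fraction of windows
#'
#' Fraction of each window's bp span covered by (merged) CDS intervals.
#'
#' @param windows data.frame with scaffold, start, end columns.
#' @param cds named list of [interval_set()] keyed by scaffold (as from
#'   [read_intervals()]).
#' @return numeric vector of fractions in [0, 1], one per window.
#' @export
genic_fraction <- function(windows, cds) {
  vapply(seq_len(nrow(windows)), function(i) {
    iv <- cds[[windows$scaffold[i]]]
    if (is.null(iv)) return(0)
    interval_overlap(iv, windows$start[i], windows$end[i]) /
      (windows$end[i] - windows$start[i])
  }, numeric(1))
}

#' Missing-data filter for window alignments
#'
#' A window alignment is dropped when any sample's fraction of Ns (or
#' gaps) exceeds `max_missing` -- the whole-window profile used before
#' tree estimation.
#'
#' @param aln named character vector of equal-length sequences.
#' @param max_missing maximum tolerated N fraction per sample
#'   (default 0.75).
#' @return TRUE to keep the window, FALSE to drop it.
#' @export
alignment_window_filter <- function(aln, max_missing = 0.75) {
  stop_if(length(unique(nchar(aln))) > 1, "sequences of unequal length")
  frac <- vapply(aln, function(s) {
    n <- nchar(s)
    (n - nchar(gsub("[Nn?-]", "", s))) / n
  }, numeric(1))
  all(frac <= max_missing)
}

#' Per-individual missing-data filter for CDS alignments
#'
#' The per-gene profile: individuals whose N fraction exceeds
#' `max_missing` are removed from the alignment rather than dropping the
#' alignment itself.
#'
#' @param aln named character vector of equal-length sequences.
#' @param max_missing threshold (default 0.5).
#' @return the alignment with offending individuals removed.
#' @export
filter_cds_individuals <- function(aln, max_missing = 0.5) {
  stop_if(length(unique(nchar(aln))) > 1, "sequences of unequal length")
  frac <- vapply(aln, function(s) {
    n <- nchar(s)
    (n - nchar(gsub("[Nn?-]", "", s))) / n
  }, numeric(1))
  aln[frac <= max_missing]
}
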