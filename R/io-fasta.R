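#' Build a per-sample consensus sequence from a genotype matrix
#'
#' Applies one sample's genotypes to a reference: homozygous alternate
#' sites get the alternate base, heterozygous sites the IUPAC ambiguity
#' code for the ref/alt pair, and missing genotypes become N. Sites absent
#' from the matrix are left at the reference base.
#'
#' @param gm a [genotype_matrix()].
#' @param reference named character vector of scaffold sequences (names =
#'   scaffold ids), or a `Biostrings::DNAStringSet`.
#' @param sample sample id.
#' @param path optional FASTA output path (one record per scaffold).
#' @return named character vector of consensus scaffold sequences.
#' @export
write_consensus_fasta <- function(gm, reference, sample, path = NULL) {
  if (inherits(reference, "DNAStringSet"))
    reference <- stats::setNames(as.character(reference), names(reference))
  stop_if(!sample %in% gm$samples, "unknown sample: ", sample)
  scafs <- unique(gm$scaffold)
  miss <- setdiff(scafs, names(reference))
  stop_if(length(miss) > 0,
          "reference lacks scaffold(s): ", paste(miss, collapse = ", "))
  g <- gm$geno[, sample]
  out <- reference
  for (s in scafs) {
    idx <- which(gm$scaffold == s)
    stop_if(max(gm$pos[idx]) > nchar(reference[[s]]),
            "position beyond reference length on scaffold ", s)
    seqv <- strsplit(out[[s]], "")[[1]]
    gi <- g[idx]
    p <- gm$pos[idx]
    ref <- gm$ref[idx]
    alt <- gm$alt[idx]
    seqv[p[is.na(gi)]] <- "N"
    hom <- which(!is.na(gi) & gi == 2L & !is.na(alt))
    seqv[p[hom]] <- alt[hom]
    het <- which(!is.na(gi) & gi == 1L & !is.na(alt))
    seqv[p[het]] <- iupac_code(ref[het], alt[het])
    out[[s]] <- paste(seqv, collapse = "")
  }
  if (!is.null(path)) write_fasta(out, path)
  out
}

#' Write named sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file path.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), sub(" .*", "", names(x)))
}
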