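# CDS fixture generator: builds aligned CDS copies carrying injected
# loss-of-function mutations with known truth, for validating the scanner.

#' Loss-of-function mutation specification
#'
#' @param kind one of `large_deletion`, `frameshift_insertion`,
#'   `frameshift_deletion`, `premature_stop_substitution`,
#'   `domain_substitution`.
#' @param position 1-based CDS coordinate where the mutation starts.
#' @param length event length in bp (indels only); frameshift indels must
#'   not be a multiple of 3.
#' @param zygosity `hom` or `het` (substitutions only; het sites are
#'   encoded as IUPAC codes).
#' @param bases optional explicit inserted bases for
#'   `frameshift_insertion` (length must match `length`); random bases
#'   are drawn when omitted.
#' @return a `lof_spec`.
#' @export
lof_spec <- function(kind = c("large_deletion", "frameshift_insertion",
                              "frameshift_deletion",
                              "premature_stop_substitution",
                              "domain_substitution"),
                     position, length = 0, zygosity = c("hom", "het"),
                     bases = NULL) {
  kind <- match.arg(kind)
  zygosity <- match.arg(zygosity)
  if (kind %in% c("frameshift_insertion", "frameshift_deletion"))
    stop_if(length %% 3 == 0, "frameshift indel length must not be 0 mod 3")
  if (kind == "large_deletion")
    stop_if(length < 1, "large_deletion needs a positive length")
  if (!is.null(bases))
    stop_if(nchar(bases) != length, "bases must match the indel length")
  structure(list(kind = kind, position = as.integer(position),
                 length = as.integer(length), zygosity = zygosity,
                 bases = bases),
            class = "lof_spec")
}

#' Random functional CDS sequence
#'
#' Uniform non-stop codons with a terminal TAA; translates without
#' internal stops by construction.
#'
#' @param n_codons codon count including the terminal stop.
#' @param seed RNG seed.
#' @return CDS string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, seed = 1) {
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste0(paste(sample_int(sense, n_codons - 1, replace = TRUE),
               collapse = ""), "TAA")
}

# single-base substitution at `pos` creating the target property
mutate_base_het <- function(ref_base, new_base, zygosity) {
  if (zygosity == "het") iupac_code(ref_base, new_base) else new_base
}

#' Build an aligned CDS fixture with injected mutations
#'
#' One aligned copy per specification (each carrying exactly its
#' mutation), plus unmutated clean copies. Insertions add alignment
#' columns where all other rows are gapped; heterozygous substitutions
#' are encoded as IUPAC codes.
#'
#' @param reference_cds functional CDS string (see [random_cds()]).
#' @param exons data.frame start/end in 1-based CDS coordinates
#'   (default: one exon spanning the CDS).
#' @param domains data.frame name/aa_start/aa_end (default none).
#' @param specs list of [lof_spec()].
#' @param seed RNG seed (inserted bases, substitution choices).
#' @param n_clean number of unmutated copies (default 1).
#' @return a [cds_alignment_set()] whose copies are named
#'   `mut<i>_<kind>` and `clean_<j>`; attribute `truth` records the
#'   injected events.
#' @export
make_cds_fixture <- function(reference_cds, exons = NULL, domains = NULL,
                             specs = list(), seed = 1, n_clean = 1) {
  set.seed(seed)
  L <- nchar(reference_cds)
  ref <- strsplit(reference_cds, "")[[1]]
  code <- Biostrings::GENETIC_CODE
  for (sp in specs)
    stop_if(sp$position < 1 || sp$position > L,
            "spec position outside CDS: ", sp$position)

  # insertion slots: after which reference position, how many columns
  ins_idx <- which(vapply(specs, function(s)
    s$kind == "frameshift_insertion", logical(1)))
  ins_specs <- specs[ins_idx]
  ins_after <- vapply(ins_specs, function(s) s$position, 1L)
  # column layout: ref positions 1..L with insertion blocks interleaved
  col_ref <- integer(0)   # reference coordinate per column; NA = insertion
  ins_block_cols <- vector("list", length(ins_specs))
  for (p in seq_len(L)) {
    col_ref <- c(col_ref, p)
    hit <- which(ins_after == p)
    for (h in hit) {
      ins_block_cols[[h]] <- length(col_ref) + seq_len(ins_specs[[h]]$length)
      col_ref <- c(col_ref, rep(NA_integer_, ins_specs[[h]]$length))
    }
  }
  n_col <- length(col_ref)
  base_row <- rep("-", n_col)
  base_row[!is.na(col_ref)] <- ref[col_ref[!is.na(col_ref)]]

  rows <- list(reference = base_row)
  truth <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    row <- base_row
    nm <- paste0("mut", i, "_", sp$kind)
    if (sp$kind %in% c("large_deletion", "frameshift_deletion")) {
      stop_if(sp$position + sp$length - 1L > L, "deletion runs past CDS")
      row[which(col_ref %in% seq(sp$position, sp$position + sp$length - 1L))] <-
        "-"
    } else if (sp$kind == "frameshift_insertion") {
      idx <- match(i, ins_idx)
      row[ins_block_cols[[idx]]] <- if (!is.null(sp$bases))
        strsplit(sp$bases, "")[[1]]
      else sample_int(c("A", "C", "G", "T"), sp$length, replace = TRUE)
    } else if (sp$kind == "premature_stop_substitution") {
      codon_i <- (sp$position - 1L) %/% 3L
      cds <- codon_i * 3L + 1:3
      stop_if(cds[3] >= L, "stop substitution too close to CDS end")
      for (k in 1:3) {
        col <- which(col_ref == cds[k])
        row[col] <- mutate_base_het(ref[cds[k]], c("T", "A", "A")[k],
                                    sp$zygosity)
      }
    } else if (sp$kind == "domain_substitution") {
      codon_i <- (sp$position - 1L) %/% 3L
      cds <- codon_i * 3L + 1:3
      ref_codon <- paste(ref[cds], collapse = "")
      ref_aa <- unname(code[ref_codon])
      done <- FALSE
      for (k in 1:3) {
        for (b in setdiff(c("A", "C", "G", "T"), ref[cds[k]])) {
          cand <- ref_codon
          substr(cand, k, k) <- b
          if (code[cand] != ref_aa && code[cand] != "*") {
            col <- which(col_ref == cds[k])
            row[col] <- mutate_base_het(ref[cds[k]], b, sp$zygosity)
            done <- TRUE; break
          }
        }
        if (done) break
      }
      stop_if(!done, "no nonsynonymous substitution available at codon ",
              codon_i + 1)
    }
    rows[[nm]] <- row
    truth[[length(truth) + 1L]] <-
      data.frame(sample = nm, kind = sp$kind, position = sp$position,
                 length = sp$length, zygosity = sp$zygosity,
                 stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_clean)) rows[[paste0("clean_", j)]] <- base_row
  aln <- vapply(rows, paste, "", collapse = "")
  set <- cds_alignment_set(aln, reference = "reference", exons = exons,
                           domains = domains)
  attr(set, "truth") <- if (length(truth)) do.call(rbind, truth)
                        else data.frame()
  set
}
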