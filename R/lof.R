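# Loss-of-function scan of aligned CDS copies against a functional
# reference. Alignments are haploid consensus rows; heterozygous
# substitution sites are encoded as IUPAC ambiguity codes and both
# resolutions are evaluated.

#' Aligned CDS copies with exon and domain annotation
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (gaps "-"); must include the reference row.
#' @param reference name of the functional reference row (default
#'   "reference").
#' @param exons data.frame with columns start, end: exon intervals in
#'   1-based closed CDS (reference, gap-free) coordinates, contiguous.
#' @param domains data.frame with columns name, aa_start, aa_end:
#'   amino-acid intervals of conserved domains (e.g. SRS1..SRS6,
#'   heme-binding).
#' @return a `cds_alignment_set`.
#' @export
cds_alignment_set <- function(aln, reference = "reference",
                              exons = NULL, domains = NULL) {
  stop_if(!reference %in% names(aln), "reference row missing: ", reference)
  stop_if(length(unique(nchar(aln))) > 1, "alignment rows of unequal length")
  ref_seq <- gsub("-", "", aln[[reference]])
  stop_if(nchar(ref_seq) %% 3 != 0,
          "reference CDS length must be a multiple of 3")
  aa <- translate_cds(ref_seq)
  stop_if(any(aa$first_stop < length(aa$codons)),
          "reference contains an internal stop codon")
  if (is.null(exons))
    exons <- data.frame(start = 1L, end = nchar(ref_seq))
  if (!is.null(domains) && nrow(domains) > 0)
    stop_if(any(domains$aa_end > nchar(ref_seq) / 3),
            "domain interval beyond protein length")
  structure(list(aln = aln, reference = reference, exons = exons,
                 domains = domains %||%
                   data.frame(name = character(), aa_start = integer(),
                              aa_end = integer())),
            class = "cds_alignment_set")
}

#' @export
print.cds_alignment_set <- function(x, ...) {
  cat("cds_alignment_set:", length(x$aln) - 1, "copies vs", x$reference,
      "|", nchar(x$aln[[1]]), "columns,", nrow(x$exons), "exon(s),",
      nrow(x$domains), "domain(s)\n")
  invisible(x)
}

# amino-acid resolutions of one codon given IUPAC bases; "*" = stop
codon_aas <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  if (codon %in% names(code)) return(unname(code[codon]))
  sets <- lapply(strsplit(codon, "")[[1]], iupac_bases)
  combos <- expand.grid(sets, stringsAsFactors = FALSE)
  unique(unname(code[paste0(combos[, 1], combos[, 2], combos[, 3])]))
}

# translate an unaligned CDS; returns codons, aa resolution list and the
# index of the first codon with a possible stop (Inf if none)
translate_cds <- function(seq) {
  n <- nchar(seq) %/% 3
  stop_if(n < 1, "realized CDS shorter than one codon")
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  code <- Biostrings::GENETIC_CODE
  plain <- codons %in% names(code)
  aas <- vector("list", n)
  aas[plain] <- as.list(unname(code[codons[plain]]))
  for (i in which(!plain)) aas[[i]] <- codon_aas(codons[i])
  stops <- which(vapply(aas, function(a) "*" %in% a, logical(1)))
  list(codons = codons, aas = aas,
       first_stop = if (length(stops)) stops[1] else Inf)
}

# reference CDS coordinate of every alignment column (NA at insertion
# columns, i.e. where the reference row has a gap)
ref_column_coords <- function(set) {
  ref <- strsplit(set$aln[[set$reference]], "")[[1]]
  coord <- cumsum(ref != "-")
  coord[ref == "-"] <- NA_integer_
  coord
}

empty_events <- function() {
  data.frame(kind = character(), cds_pos = integer(), length = integer(),
             zygosity = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' Detect indels of a CDS copy against the reference
#'
#' Maximal gap runs are classified: deletions of at least
#' `large_deletion_min` bp become `large_deletion` events (with the
#' overlapped exons listed); any indel whose length is not a multiple of
#' 3 additionally produces a `frameshift` event; in-frame indels are
#' reported as `inframe_indel` and never contribute to a LOF verdict.
#'
#' @param set a [cds_alignment_set()].
#' @param sample copy name.
#' @param large_deletion_min minimum deletion size in bp (default 100).
#' @return data.frame of events: kind, cds_pos (1-based reference CDS
#'   coordinate), length, zygosity, detail.
#' @export
detect_indels <- function(set, sample, large_deletion_min = 100) {
  stop_if(!sample %in% names(set$aln), "unknown sample: ", sample)
  ref <- strsplit(set$aln[[set$reference]], "")[[1]]
  smp <- strsplit(set$aln[[sample]], "")[[1]]
  coord <- ref_column_coords(set)
  ev <- empty_events()
  add <- function(kind, pos, len, detail = "")
    ev <<- rbind(ev, data.frame(kind = kind, cds_pos = pos, length = len,
                                zygosity = "hom", detail = detail,
                                stringsAsFactors = FALSE))
  # deletions: sample gap where reference has a base
  del <- ref != "-" & smp == "-"
  r <- rle(del)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    cols <- starts[i]:ends[i]
    len <- sum(ref[cols] != "-")
    pos <- coord[cols[1]]
    if (len >= large_deletion_min) {
      hit <- which(set$exons$start <= coord[cols[length(cols)]] &
                     set$exons$end >= pos)
      add("large_deletion", pos, len,
          paste0("exons:", paste(hit, collapse = "+")))
    }
    if (len %% 3 != 0) add("frameshift", pos, len, "deletion")
    else if (len < large_deletion_min) add("inframe_indel", pos, len,
                                           "deletion")
  }
  # insertions: reference gap where sample has a base
  ins <- ref == "-" & smp != "-"
  r <- rle(ins)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    cols <- starts[i]:ends[i]
    len <- length(cols)
    prior <- coord[seq_len(cols[1] - 1)]
    pos <- if (any(!is.na(prior))) max(prior, na.rm = TRUE) else 0L
    if (len %% 3 != 0) add("frameshift", pos, len, "insertion")
    else add("inframe_indel", pos, len, "insertion")
  }
  ev
}

#' Detect premature stop codons in a CDS copy
#'
#' The copy's realized CDS (its aligned row with gaps removed, so
#' insertions shift the reading frame) is translated from the reference
#' start; the first stop codon strictly upstream of the realized
#' terminal codon is reported. At heterozygous IUPAC sites both
#' resolutions are evaluated: zygosity is `het` when only one allele
#' creates the stop.
#'
#' @inheritParams detect_indels
#' @return data.frame of `premature_stop` events (possibly empty);
#'   cds_pos is the codon start in realized-CDS coordinates.
#' @export
detect_premature_stop <- function(set, sample) {
  stop_if(!sample %in% names(set$aln), "unknown sample: ", sample)
  realized <- gsub("-", "", set$aln[[sample]])
  tr <- translate_cds(realized)
  n_codons <- length(tr$codons)
  i <- tr$first_stop
  if (!is.finite(i) || i >= n_codons) return(empty_events())
  all_stop <- identical(tr$aas[[i]], "*")
  data.frame(kind = "premature_stop", cds_pos = 3L * (i - 1L) + 1L,
             length = 0L, zygosity = if (all_stop) "hom" else "het",
             detail = paste0("codon:", i), stringsAsFactors = FALSE)
}

#' Detect amino-acid substitutions inside conserved domains
#'
#' Reports nonsynonymous differences from the reference protein whose
#' amino-acid position falls inside a named domain interval. Domains
#' downstream of a frameshift are flagged as not scanned (the reading
#' frame there is ambiguous). Zygosity comes from the IUPAC state of the
#' codon.
#'
#' @inheritParams detect_indels
#' @return data.frame of `domain_substitution` events; attribute
#'   `skipped_domains` lists domains not scanned due to upstream
#'   frameshifts.
#' @export
detect_domain_substitutions <- function(set, sample) {
  stop_if(!sample %in% names(set$aln), "unknown sample: ", sample)
  ev <- empty_events()
  if (nrow(set$domains) == 0) { attr(ev, "skipped_domains") <- character(0)
                                return(ev) }
  indels <- detect_indels(set, sample, large_deletion_min = Inf)
  fs_pos <- indels$cds_pos[indels$kind == "frameshift"]
  smp <- strsplit(set$aln[[sample]], "")[[1]]
  coord <- ref_column_coords(set)
  ref_seq <- gsub("-", "", set$aln[[set$reference]])
  ref_aa <- vapply(translate_cds(ref_seq)$codons,
                   function(cd) codon_aas(cd)[1], "")
  skipped <- character(0)
  for (d in seq_len(nrow(set$domains))) {
    dom <- set$domains[d, ]
    dom_cds_start <- 3L * (dom$aa_start - 1L) + 1L
    if (any(fs_pos < dom_cds_start)) {
      skipped <- c(skipped, dom$name)
      next
    }
    for (aa_pos in dom$aa_start:dom$aa_end) {
      cds <- 3L * (aa_pos - 1L) + 1:3
      cols <- match(cds, coord)
      if (anyNA(cols)) next
      bases <- smp[cols]
      if (any(bases == "-")) next   # deletion; handled by indel scan
      aas <- codon_aas(paste(bases, collapse = ""))
      alt <- setdiff(aas, c(ref_aa[aa_pos], "*"))
      if (length(alt) == 0) next
      het <- ref_aa[aa_pos] %in% aas ||
        any(!bases %in% c("A", "C", "G", "T"))
      ev <- rbind(ev, data.frame(
        kind = "domain_substitution", cds_pos = cds[1], length = 3L,
        zygosity = if (het) "het" else "hom",
        detail = paste0(dom$name, ":", ref_aa[aa_pos], aa_pos,
                        paste(alt, collapse = "/")),
        stringsAsFactors = FALSE))
    }
  }
  attr(ev, "skipped_domains") <- skipped
  ev
}

#' Classify all CDS copies for loss of function
#'
#' Aggregates indel, premature-stop and domain-substitution events per
#' copy. Verdicts: `LOF` when any large deletion, frameshift or
#' premature stop is present; `putative_reduced_function` when only
#' domain substitutions are found; `intact` otherwise. Copies sharing an
#' identical event (same kind, position and length) are grouped into
#' shared-mutation clusters.
#'
#' @param set a [cds_alignment_set()].
#' @param large_deletion_min minimum large-deletion size (default 100).
#' @return list: `reports` (sample, verdict, n_events), `events` (per
#'   sample), `clusters` (shared events carried by >= 2 samples).
#' @export
classify_lof <- function(set, large_deletion_min = 100) {
  samples <- setdiff(names(set$aln), set$reference)
  lof_kinds <- c("large_deletion", "frameshift", "premature_stop")
  all_ev <- list(); verdicts <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    ev <- rbind(detect_indels(set, s, large_deletion_min),
                detect_premature_stop(set, s),
                detect_domain_substitutions(set, s))
    scored <- ev[ev$kind %in% c(lof_kinds, "domain_substitution"), ,
                 drop = FALSE]
    verdicts[i] <-
      if (any(scored$kind %in% lof_kinds)) "LOF"
      else if (nrow(scored) > 0) "putative_reduced_function"
      else "intact"
    if (nrow(ev) > 0) { ev$sample <- s
                        all_ev[[length(all_ev) + 1L]] <- ev }
  }
  events <- if (length(all_ev)) do.call(rbind, all_ev) else {
    e <- empty_events(); e$sample <- character(0); e
  }
  shared <- events[events$kind %in% lof_kinds, , drop = FALSE]
  clusters <- if (nrow(shared) > 0) {
    key <- paste(shared$kind, shared$cds_pos, shared$length)
    agg <- split(shared$sample, key)
    agg <- agg[lengths(agg) >= 2]
    if (length(agg) > 0)
      data.frame(event = names(agg),
                 n_samples = lengths(agg),
                 samples = vapply(agg, function(x)
                   paste(sort(unique(x)), collapse = ","), ""),
                 row.names = NULL, stringsAsFactors = FALSE)
    else NULL
  } else NULL
  list(reports = data.frame(sample = samples, verdict = verdicts,
                            stringsAsFactors = FALSE),
       events = events,
       clusters = clusters %||% data.frame(event = character(),
                                           n_samples = integer(),
                                           samples = character()))
}
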