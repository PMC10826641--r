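# Config-driven orchestration: simulation writers, landscape regressions,
# and the end-to-end pipeline over files in standard formats.

#' Default six-taxon guide tree
#'
#' An ultrametric species tree (branch lengths in coalescent units) for a
#' small montane radiation: two hummingbird-pollinated species that are
#' not sister (newberryi, rupicola), their blue-flowered relatives, and
#' montanus as outgroup.
#' @return a rooted `phylo`.
#' @export
default_guide_tree <- function() {
  ape::read.tree(text = paste0(
    "((((newberryi:0.5,cardwellii:0.5):0.25,rupicola:0.75):0.75,",
    "(davidsonii:1,fruticosus:1):0.5):1.5,montanus:3);"))
}

#' Ordinary least-squares landscape regression
#'
#' Regresses a per-window statistic (fdM, dxy, FST, RF distance or a
#' topology weight) on a covariate, by default the window's genic
#' fraction. Windows with NA in either variable are excluded and counted.
#'
#' @param windows data.frame of windows carrying both columns.
#' @param response response column name.
#' @param covariate covariate column name (default "genic_fraction").
#' @return a `landscape_regression`: slope, intercept, r_squared,
#'   p_value (two-tailed slope t-test), n_windows, n_dropped.
#' @export
landscape_regression <- function(windows, response,
                                 covariate = "genic_fraction") {
  y <- windows[[response]]; x <- windows[[covariate]]
  stop_if(is.null(y) || is.null(x), "missing response/covariate column")
  ok <- !is.na(y) & !is.na(x)
  stop_if(sum(ok) < 3, "need >= 3 windows with data")
  stop_if(stats::var(x[ok]) == 0, "covariate has zero variance")
  fit <- stats::lm(y[ok] ~ x[ok])
  sm <- summary(fit)
  structure(list(response = response, covariate = covariate,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n_windows = sum(ok), n_dropped = sum(!ok)),
            class = "landscape_regression")
}

#' @export
print.landscape_regression <- function(x, ...) {
  cat(sprintf(
    "landscape regression %s ~ %s: slope %.4g (p = %.3g), R^2 = %.3f, n = %d\n",
    x$response, x$covariate, x$slope, x$p_value, x$r_squared, x$n_windows))
  invisible(x)
}

#' Simulate a complete analysis-ready dataset on disk
#'
#' Runs the coalescent simulator and writes every input the pipeline
#' consumes: a VCF, a sample-to-population map, a BED of CDS intervals
#' with tunable density, the per-tree gene trees (Newick, one per line)
#' and the guide tree.
#'
#' @param out_dir output directory (created if needed).
#' @param model a [species_tree_model()]; default: [default_guide_tree()]
#'   with 2 diploid samples per ingroup taxon and 1 outgroup sample.
#' @param n_trees gene trees / genomic blocks (default 100).
#' @param snps_per_tree expected SNPs per block (default 40).
#' @param block_bp block width (default 10000).
#' @param cds_density fraction of each block covered by CDS intervals
#'   (default 0.25).
#' @param cds_mean_len mean CDS interval length in bp (default 1500).
#' @param seed RNG seed.
#' @return named list of written file paths plus the `genotype_matrix`.
#' @export
simulate_dataset <- function(out_dir, model = NULL, n_trees = 100,
                             snps_per_tree = 40, block_bp = 10000,
                             cds_density = 0.25, cds_mean_len = 1500,
                             seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(model)) {
    spt <- default_guide_tree()
    k <- stats::setNames(rep(2L, 6), spt$tip.label)
    k["montanus"] <- 1L
    model <- species_tree_model(spt, k)
  }
  layout <- scaffold_layout(n_trees, block_bp = block_bp)
  trees <- simulate_gene_trees(model, n_trees, seed = seed)
  gm <- sprinkle_mutations(trees, mutation_model(snps_per_tree), layout,
                           seed = seed + 1, ploidy = model$ploidy)
  # CDS intervals: one interval per block, density-controlled
  set.seed(seed + 2)
  cds <- lapply(seq_len(nrow(layout)), function(i) {
    total <- round(cds_density * block_bp)
    if (total < 1) return(NULL)
    n_iv <- max(1L, round(total / cds_mean_len))
    width <- rep(total %/% n_iv, n_iv)
    starts <- sort(sample_int(seq(0, block_bp - max(width)), n_iv))
    data.frame(scaffold = layout$scaffold[i],
               start = layout$start[i] + starts,
               end = layout$start[i] + starts + width)
  })
  cds <- do.call(rbind, cds)
  paths <- list(
    vcf = file.path(out_dir, "simulated.vcf"),
    popmap = file.path(out_dir, "popmap.tsv"),
    bed = file.path(out_dir, "cds.bed"),
    gene_trees = file.path(out_dir, "gene_trees.nwk"),
    guide_tree = file.path(out_dir, "guide_tree.nwk"))
  write_vcf(gm, paths$vcf)
  pm <- model_popmap(model)
  utils::write.table(data.frame(names(pm), unname(pm)), paths$popmap,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cds, paths$bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_trees(trees, paths$gene_trees)
  ape::write.tree(model$tree, paths$guide_tree)
  c(paths, list(gm = gm, layout = layout))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline over files
#'
#' filter -> windows -> diversity -> introgression -> discordance ->
#' loss-of-function, each stage skipped when its inputs are absent. All
#' outputs are TSV/Newick files in `out_dir` plus a manifest recording
#' inputs, seeds and per-stage record counts. Re-running an identical
#' config reproduces identical tables.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `vcf`, `popmap`, `guide_tree`, `outgroup` (required); `bed` or
#'   `gff`, `gene_trees`, `cds_fasta` (aligned, with reference row
#'   "reference"), `domains_tsv`, `exons_tsv` (optional);
#'   `bp_window_size` (default 10000), `snp_window_size` (default 500),
#'   `snp_window_slide` (default 125), `filters` (list passed to
#'   [filter_config()]), `seed` (default 1), `n_jackknife_blocks`
#'   (default 20).
#' @param out_dir output directory.
#' @return manifest list (also written to `manifest.tsv`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    stop_if(!requireNamespace("yaml", quietly = TRUE),
            "reading a config file requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  for (req in c("vcf", "popmap", "guide_tree", "outgroup"))
    stop_if(is.null(config[[req]]), "config missing required field: ", req)
  for (f in c("vcf", "popmap", "guide_tree", "bed", "gff", "gene_trees",
              "cds_fasta"))
    if (!is.null(config[[f]]))
      stop_if(!file.exists(config[[f]]), "input does not exist: ",
              config[[f]], " (field ", f, ")")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  manifest <- list(seed = seed)

  filt <- do.call(filter_config, config$filters %||% list())
  gm <- read_vcf(config$vcf, filt)
  manifest$filter_log <- attr(gm, "filter_log")
  popmap <- read_popmap(config$popmap)
  guide <- ape::read.tree(config$guide_tree)
  outgroup <- config$outgroup

  # windows
  scaf_len <- tapply(gm$pos, gm$scaffold, max)
  bpw <- bp_windows(scaf_len, config$bp_window_size %||% 10000)
  snw <- snp_windows(gm, config$snp_window_size %||% 500,
                     config$snp_window_slide %||% 125)
  cds <- NULL
  if (!is.null(config$bed)) cds <- read_intervals(config$bed, "bed")
  if (!is.null(config$gff)) cds <- read_intervals(config$gff, "gff3")
  if (!is.null(cds)) {
    bpw$genic_fraction <- genic_fraction(bpw, cds)
    if (nrow(snw) > 0) snw$genic_fraction <- genic_fraction(snw, cds)
  }
  write_tsv(bpw, file.path(out_dir, "windows_bp.tsv"))
  write_tsv(snw, file.path(out_dir, "windows_snp.tsv"))

  # diversity
  div <- windowed_diversity(gm, bpw, popmap)
  write_tsv(div, file.path(out_dir, "diversity_bp.tsv"))
  manifest$n_diversity_rows <- nrow(div)

  # genome-wide D for all trios + Bonferroni
  trios <- d_all_trios(gm, popmap, guide, outgroup,
                       n_blocks = config$n_jackknife_blocks %||% 20)
  write_tsv(trios, file.path(out_dir, "trios_d.tsv"))
  manifest$n_trios <- nrow(trios)
  manifest$n_trios_significant <- sum(trios$significant)

  # windowed fdM for each trio, plus landscape regression if CDS known
  if (nrow(snw) > 0) {
    fdm_all <- list()
    for (i in seq_len(nrow(trios))) {
      pops <- c(trios$P1[i], trios$P2[i], trios$P3[i], outgroup)
      fw <- fdm_windows(gm, popmap, pops, snw)
      fw$trio <- paste(pops[1:3], collapse = "-")
      fdm_all[[i]] <- fw
    }
    fdm_all <- do.call(rbind, fdm_all)
    write_tsv(fdm_all, file.path(out_dir, "fdm_windows.tsv"))
    if (!is.null(cds)) {
      regs <- lapply(split(fdm_all, fdm_all$trio), function(d)
        tryCatch(landscape_regression(d, "fdm"), error = function(e) NULL))
      regs <- Filter(Negate(is.null), regs)
      if (length(regs) > 0)
        write_tsv(data.frame(
          trio = names(regs),
          slope = vapply(regs, `[[`, 0, "slope"),
          r_squared = vapply(regs, `[[`, 0, "r_squared"),
          p_value = vapply(regs, `[[`, 0, "p_value"),
          n_windows = vapply(regs, `[[`, 0, "n_windows")),
          file.path(out_dir, "fdm_landscape_regression.tsv"))
    }
  }

  # discordance against window/gene trees
  if (!is.null(config$gene_trees)) {
    gtrees <- read_trees(config$gene_trees)
    # tips of simulated gene trees are haploid lineages sample.1/.2
    tipmap <- NULL
    tips1 <- gtrees[[1]]$tip.label
    if (all(tips1 %in% names(popmap))) {
      tipmap <- popmap
    } else {
      base <- sub("\\.[12]$", "", tips1)
      if (all(base %in% names(popmap)))
        tipmap <- stats::setNames(unname(popmap[base]), tips1)
    }
    rf <- vapply(gtrees, function(gt) {
      gt2 <- gt
      if (!is.null(tipmap)) {
        # one tip per taxon for the species-tree comparison
        keep <- !duplicated(unname(tipmap[gt$tip.label]))
        gt2 <- ape::keep.tip(gt, gt$tip.label[keep])
        gt2$tip.label <- unname(tipmap[gt2$tip.label])
      }
      suppressWarnings(rf_normalized(gt2, guide))
    }, numeric(1))
    gcf <- gene_concordance(gtrees, guide, taxon_map = tipmap)
    write_tsv(data.frame(tree = seq_along(gtrees), rf = rf),
              file.path(out_dir, "rf_windows.tsv"))
    write_tsv(gcf, file.path(out_dir, "gene_concordance.tsv"))
    manifest$mean_rf <- mean(rf)
  }

  # LOF scan
  if (!is.null(config$cds_fasta)) {
    aln <- read_fasta(config$cds_fasta)
    exons <- if (!is.null(config$exons_tsv))
      utils::read.table(config$exons_tsv, header = TRUE) else NULL
    domains <- if (!is.null(config$domains_tsv))
      utils::read.table(config$domains_tsv, header = TRUE,
                        stringsAsFactors = FALSE) else NULL
    set <- cds_alignment_set(aln, exons = exons, domains = domains)
    res <- classify_lof(set)
    write_tsv(res$reports, file.path(out_dir, "lof_reports.tsv"))
    write_tsv(res$events, file.path(out_dir, "lof_events.tsv"))
    write_tsv(res$clusters, file.path(out_dir, "lof_clusters.tsv"))
    manifest$n_lof <- sum(res$reports$verdict == "LOF")
  }

  manifest$outputs <- list.files(out_dir)
  mf <- data.frame(key = c("seed", names(manifest$filter_log)),
                   value = c(seed, unname(manifest$filter_log)))
  write_tsv(mf, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
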