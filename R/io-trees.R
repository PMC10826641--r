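#' Read a file of Newick trees, one per line
#'
#' @param path file path; blank lines ignored.
#' @return list of `phylo` objects, in file order.
#' @export
read_trees <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    tr <- tryCatch(ape::read.tree(text = lines[i]),
                   error = function(e) NULL, warning = function(w) NULL)
    stop_if(is.null(tr) || !inherits(tr, "phylo"),
            "cannot parse Newick at line ", i, " of ", path)
    out[[j]] <- tr
  }
  out
}

#' Write a list of trees as one Newick string per line
#' @param trees list of `phylo` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  writeLines(vapply(trees, ape::write.tree, ""), path)
  invisible(path)
}
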