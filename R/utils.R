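# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
iupac_code <- function(a, b) {
  key <- paste(pmin(a, b), pmax(a, b), sep = "")
  map <- c(AA = "A", CC = "C", GG = "G", TT = "T",
           AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  out <- unname(map[key])
  out[is.na(out)] <- "N"
  out
}

# bases encoded by an IUPAC letter
iupac_bases <- function(x) {
  map <- list(A = "A", C = "C", G = "G", T = "T",
              M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
              S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  map[[toupper(x)]] %||% "N"
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# sample() without the length-1 surprise
sample_int <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# split 1..n into k contiguous blocks of near-equal size
contiguous_blocks <- function(n, k) {
  stop_if(k < 1 || n < k, "cannot split ", n, " items into ", k, " blocks")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}
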