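#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbinom rgeom rpois runif setNames cor.test pt
#' @importFrom utils head
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")

# random DNA string of length n (uses the current RNG stream)
.rdna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# k random codons avoiding stop codons, concatenated
.rcodons_nostop <- function(k) {
  if (k <= 0) return("")
  all_codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste, collapse = "")
  ok <- setdiff(all_codons, STOP_CODONS)
  paste(sample(ok, k, replace = TRUE), collapse = "")
}

# translate an in-frame nucleotide string via the standard genetic code;
# returns "" for empty input ("*" marks stops)
.CODON_TABLE <- Biostrings::GENETIC_CODE
.translate_nt <- function(nt) {
  if (!nzchar(nt)) return("")
  stopifnot(nchar(nt) %% 3 == 0)
  starts <- seq.int(1L, nchar(nt), 3L)
  paste(.CODON_TABLE[substring(nt, starts, starts + 2L)], collapse = "")
}

.is_simplex <- function(w, tol = 1e-9) {
  all(w >= 0) && abs(sum(w) - 1) <= tol
}

# deterministic 32-bit sub-seed derivation (kept < 2^31 - 1)
.sub_seed <- function(master, index, salt = 0L) {
  m <- 2147483647
  x <- (as.numeric(master) %% m)
  x <- (x * 1000003 + as.numeric(index) * 7919 + as.numeric(salt) * 104729) %% m
  as.integer(x)
}

# weighted single draw returning the name
.draw1 <- function(weights) {
  stopifnot(!is.null(names(weights)))
  names(weights)[sample.int(length(weights), 1L, prob = weights)]
}
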