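# Low-level sequence helpers shared by the generator and the scanners.
# All sequences are plain uppercase DNA character strings (U is mapped to T
# on input); RNA motifs such as the C box RUGAUGA are matched with T == U.

.BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## TRUE iff a (on the guide/plus side) can pair with b, Watson-Crick only.
.wc_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

## TRUE iff a:b is a G:U (G:T in DNA alphabet) wobble.
.gu_pair <- function(a, b) {
  (a == "G" & b == "T") | (a == "T" & b == "G")
}

.can_pair <- function(a, b, allow_gu = TRUE) {
  if (allow_gu) .wc_pair(a, b) | .gu_pair(a, b) else .wc_pair(a, b)
}

.comp1 <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Split a sequence into a character vector of single bases.
.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

## Random DNA string of length n drawn from the supplied RNG stream.
.random_dna <- function(n, prob = NULL) {
  if (n <= 0) return("")
  paste(sample(.BASES, n, replace = TRUE, prob = prob), collapse = "")
}

## Positions (1-based) where `pattern` (IUPAC, e.g. "RTGATGA") matches
## `chars` with at most max_mm mismatches.  Returns a data.frame with
## columns start and mm.  Vectorized over candidate start positions.
.iupac_tab <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), N = c("A", "C", "G", "T")
)

.match_box <- function(chars, pattern, max_mm = 0L, from = 1L, to = NA) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  k <- length(pat)
  n <- length(chars)
  if (is.na(to)) to <- n - k + 1L
  to <- min(to, n - k + 1L)
  if (from > to) return(data.frame(start = integer(0), mm = integer(0)))
  starts <- from:to
  mm <- integer(length(starts))
  for (i in seq_len(k)) {
    ok <- chars[starts + i - 1L] %in% .iupac_tab[[pat[i]]]
    mm <- mm + !ok
  }
  keep <- mm <= max_mm
  data.frame(start = starts[keep], mm = mm[keep])
}

## Count mismatches of chars[start..] against an IUPAC pattern.
.box_mm <- function(chars, start, pattern) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sum(vapply(seq_along(pat), function(i) {
    !(chars[start + i - 1L] %in% .iupac_tab[[pat[i]]])
  }, logical(1)))
}
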