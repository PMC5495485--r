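## Internal helpers shared across modules.
##
## Coordinate convention: every interval in this package is 0-based,
## half-open [start, end), matching the convention stated in all exported
## documentation. `subseq0()` is the only place that translates to R's
## 1-based substr().

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' @importFrom data.table data.table := .N .SD setkey setkeyv rleid fifelse
NULL

## Extract [start, end) from a sequence string (0-based, half-open).
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

## Vectorised: extract many windows of a single sequence.
subseq0_many <- function(seq, start, end) {
  substring(seq, start + 1L, end)
}

check_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    offending <- regmatches(seq[bad][1], regexpr("[^ACGTN]", seq[bad][1]))
    stop(sprintf("%s contains illegal character '%s' (alphabet is A,C,G,T,N)",
                 what, offending), call. = FALSE)
  }
  invisible(TRUE)
}

## Random DNA of length n at a given GC fraction, using the supplied RNG state.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## All k-mers of a sequence as a character vector (position i, 0-based start i-1).
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

## Sequence as integer codes (utf8), for vectorised mismatch counting.
seq_ints <- function(seq) utf8ToInt(seq)

## Wilson score interval (95%) via prop.test without continuity correction.
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  ## prop.test's chi-square-approximation warning concerns its test
  ## statistic, not the score interval used here
  as.numeric(suppressWarnings(
    stats::prop.test(x, n, conf.level = conf, correct = FALSE)$conf.int))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
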