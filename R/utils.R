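# Internal helpers shared across modules.

#' @keywords internal
geomean <- function(x) {
  stopifnot(all(x >= 0))
  exp(mean(log(pmax(x, 1e-12))))
}

#' Run code with a locally seeded RNG, restoring the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stage-specific child seed from a master seed so independent
# stages do not share RNG streams. Kept below 2^31 - 1.
#' @keywords internal
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L)
}

# DNA <-> integer codes (A=1, C=2, G=3, T=4); other letters -> NA.
#' @keywords internal
dna_to_int <- function(seq) {
  v <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T"))
  v
}

#' @keywords internal
int_to_dna <- function(v) paste(c("A", "C", "G", "T")[v], collapse = "")

#' @keywords internal
revcomp_int <- function(v) rev(5L - v)

#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# All k-mer integer codes (base-4, in 0..4^k-1) along an integer-coded
# sequence; windows containing NA (ambiguous bases) get NA.
#' @keywords internal
kmer_codes <- function(v, k) {
  n <- length(v) - k + 1L
  if (n < 1L) return(integer(0))
  code <- numeric(n)
  for (j in seq_len(k)) {
    code <- code + (v[j:(j + n - 1L)] - 1L) * 4^(k - j)
  }
  code
}

#' @keywords internal
fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}
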