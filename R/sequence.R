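#' Normalize an RNA (or DNA) sequence string
#'
#' Upper-cases, converts T to U, and validates the alphabet. `N` is retained
#' (it is never allowed to pair); any other character is rejected.
#'
#' @param x character scalar (or a `Biostrings` XString, which is coerced).
#' @return normalized character scalar over `{A,C,G,U,N}`.
#' @export
as_rna <- function(x) {
  x <- as.character(x)
  if (length(x) != 1L) stop("expected a single sequence string")
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  if (!nzchar(x)) stop("empty sequence")
  bad <- gsub("[ACGUN]", "", x)
  if (nzchar(bad))
    stop("invalid residue(s) in sequence: ", paste(unique(strsplit(bad, "")[[1]]),
                                                   collapse = ", "))
  x
}

# integer encoding used by the compiled engine: A=0 C=1 G=2 U=3 N=4
encode_seq <- function(x) {
  m <- c(A = 0L, C = 1L, G = 2L, U = 3L, N = 4L)
  unname(m[strsplit(x, "")[[1]]])
}

#' Reverse complement of an RNA string (Watson-Crick; N maps to N)
#' @param x normalized RNA string.
#' @return character scalar.
#' @export
revcomp_rna <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

base_frequencies <- function(x) {
  ch <- strsplit(x, "")[[1]]
  n <- length(ch)
  c(freq_a = sum(ch == "A") / n, freq_g = sum(ch == "G") / n,
    freq_c = sum(ch == "C") / n, freq_u = sum(ch == "U") / n)
}

# Run code with a private, restored RNG state (all generators in the package
# are pure functions of their seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
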