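#' Parse dot-bracket notation into a base-pair matrix
#'
#' @param db dot-bracket string using `(`, `)` and `.`.
#' @return integer matrix with columns `i`, `j` (1-based, `i < j`), ordered by
#'   `i`; zero rows for an unpaired structure.
#' @export
db_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (length(ch) && any(!ch %in% c("(", ")", ".")))
    stop("malformed dot-bracket string: unexpected character")
  stack <- integer(0)
  out <- list()
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (!length(stack)) stop("malformed dot-bracket string: unmatched ')'")
      out[[length(out) + 1L]] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("malformed dot-bracket string: unmatched '('")
  pairs <- if (length(out)) do.call(rbind, out) else matrix(integer(0), 0, 2)
  colnames(pairs) <- c("i", "j")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Serialize a base-pair matrix to dot-bracket notation
#'
#' @param pairs two-column matrix/data.frame of pairs (1-based, `i < j`).
#' @param n sequence length.
#' @return dot-bracket string of length `n`.
#' @export
pairs_to_db <- function(pairs, n) {
  ch <- rep(".", n)
  pairs <- as.matrix(pairs)
  if (nrow(pairs)) {
    ch[pairs[, 1]] <- "("
    ch[pairs[, 2]] <- ")"
  }
  paste(ch, collapse = "")
}

#' Validate a nested secondary structure
#'
#' Checks 1-based coordinates, one partner per index, minimum hairpin loop,
#' and the non-crossing (nested) property.
#'
#' @param pairs two-column matrix of pairs.
#' @param n sequence length.
#' @param min_hairpin minimum unpaired loop length enclosed by a pair.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_structure <- function(pairs, n, min_hairpin = 3L) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) return(invisible(TRUE))
  if (any(pairs < 1) || any(pairs > n)) stop("pair index out of range")
  if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j")
  idx <- c(pairs[, 1], pairs[, 2])
  if (anyDuplicated(idx)) stop("an index appears in more than one pair")
  if (any(pairs[, 2] - pairs[, 1] - 1L < min_hairpin))
    stop("pair encloses a loop shorter than the minimum hairpin length")
  if (pairs_cross(pairs)) stop("crossing (pseudoknotted) pairs are not allowed")
  invisible(TRUE)
}

# TRUE if any two pairs in the set cross
pairs_cross <- function(pairs) {
  pairs <- as.matrix(pairs)
  m <- nrow(pairs)
  if (m < 2) return(FALSE)
  o <- order(pairs[, 1])
  pi <- pairs[o, 1]; pj <- pairs[o, 2]
  for (a in seq_len(m - 1)) {
    b <- (a + 1):m
    if (any(pi[b] < pj[a] & pj[b] > pj[a])) return(TRUE)
  }
  FALSE
}
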