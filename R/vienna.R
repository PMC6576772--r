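# Optional external folding backend: delegates MFE prediction to an
# installed ViennaRNA `RNAfold` binary (full Turner 2004 parameterization)
# for fidelity runs. The bundled engine remains the default and the only
# backend the test oracles certify.

#' Is an RNAfold binary available on the PATH?
#' @export
vienna_available <- function() nzchar(Sys.which("RNAfold"))

#' MFE fold via the ViennaRNA RNAfold binary
#'
#' Supports `max_span` (via `--maxBPspan`) and forced-unpaired constraints;
#' forced pairs are not passed through and raise an error.
#'
#' @inheritParams mfe_fold
#' @return same shape as [mfe_fold()].
#' @export
vienna_mfe_fold <- function(seq, constraints = NULL, params = fold_params()) {
  if (!vienna_available()) stop("RNAfold binary not found on PATH")
  seq <- as_rna(seq)
  args <- c("--noPS", paste0("-T", params$temperature))
  input <- seq
  if (!is.null(constraints)) {
    if (!is.null(constraints$forced_pairs) && nrow(constraints$forced_pairs))
      stop("forced pairs are not supported by the vienna backend wrapper")
    if (!is.null(constraints$max_span))
      args <- c(args, paste0("--maxBPspan=", constraints$max_span))
    if (length(constraints$forced_unpaired)) {
      cstr <- rep(".", nchar(seq))
      cstr[constraints$forced_unpaired] <- "x"
      args <- c(args, "-C")
      input <- c(seq, paste(cstr, collapse = ""))
    }
  }
  out <- system2("RNAfold", args, input = input, stdout = TRUE, stderr = FALSE)
  line <- out[grepl("[().]+\\s+\\(\\s*-?[0-9.]+\\)", out)][1]
  if (is.na(line)) stop("could not parse RNAfold output")
  db <- sub("\\s.*$", "", line)
  e <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
  pairs <- db_to_pairs(db)
  list(pairs = pairs, db = db, delta_g = e, n = nchar(seq))
}
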