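# Structural conservation of motif base pairs against a multiple sequence
# alignment: conserved / consistent / compensatory / disruptive / gapped,
# plus chemical-probing consistency counting.

#' Gap-aware coordinate map between a reference and its alignment
#'
#' @param aln named character vector of equal-length aligned rows (gap `-`),
#'   e.g. from [read_alignment()].
#' @param reference_id name of the reference row.
#' @return list with `reference_id`, `pos_to_col` (reference position ->
#'   alignment column), `col_to_pos` (inverse, `NA` at gap columns),
#'   `reference_seq` (ungapped) and `aln`.
#' @export
map_reference_to_alignment <- function(aln, reference_id) {
  if (!reference_id %in% names(aln))
    stop("reference '", reference_id, "' not found in alignment")
  widths <- nchar(aln)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: row '", names(aln)[which(widths != widths[1])[1]],
         "' has a different length")
  ref <- strsplit(aln[[reference_id]], "")[[1]]
  pos_to_col <- which(ref != "-")
  col_to_pos <- rep(NA_integer_, length(ref))
  col_to_pos[pos_to_col] <- seq_along(pos_to_col)
  list(reference_id = reference_id, pos_to_col = pos_to_col,
       col_to_pos = col_to_pos,
       reference_seq = paste(ref[ref != "-"], collapse = ""), aln = aln)
}

#' Classify one base pair across homologs
#'
#' Per homolog: `gapped` if either position is a gap; `disruptive` if the
#' homolog pair is non-canonical; `conserved` if both residues are identical
#' to the (canonical) reference pair; `consistent` if exactly one residue
#' changed with pairing kept canonical (incl. GU); `compensatory` if both
#' changed with pairing kept. The conservation fraction is
#' (conserved + consistent + compensatory) / (non-gapped homologs).
#'
#' @param pair length-2 vector `(i, j)` in reference coordinates.
#' @param map a [map_reference_to_alignment()] result.
#' @return list with `i`, `j`, `ref_pair`, `categories` (named character per
#'   homolog), `conservation_fraction`, `n_gapped`, `ref_noncanonical` flag.
#' @export
classify_pair <- function(pair, map) {
  i <- pair[[1]]; j <- pair[[2]]
  if (i > length(map$pos_to_col) || j > length(map$pos_to_col))
    stop("pair position outside the reference")
  ci <- map$pos_to_col[i]; cj <- map$pos_to_col[j]
  ref_i <- toupper(substr(map$aln[[map$reference_id]], ci, ci))
  ref_j <- toupper(substr(map$aln[[map$reference_id]], cj, cj))
  ref_canonical <- !is.na(pair_type(ref_i, ref_j))
  homologs <- setdiff(names(map$aln), map$reference_id)
  cats <- vapply(homologs, function(h) {
    a <- toupper(chartr("T", "U", substr(map$aln[[h]], ci, ci)))
    b <- toupper(chartr("T", "U", substr(map$aln[[h]], cj, cj)))
    if (a == "-" || b == "-") return("gapped")
    canonical <- !is.na(pair_type(a, b))
    if (!canonical) return("disruptive")
    if (a == ref_i && b == ref_j) return("conserved")
    if (a != ref_i && b != ref_j) return("compensatory")
    "consistent"
  }, character(1))
  non_gap <- cats != "gapped"
  list(i = i, j = j, ref_pair = paste0(ref_i, ref_j), categories = cats,
       conservation_fraction = if (any(non_gap))
         mean(cats[non_gap] %in% c("conserved", "consistent", "compensatory"))
       else NA_real_,
       n_gapped = sum(!non_gap), ref_noncanonical = !ref_canonical)
}

#' Conservation summary over a motif's pairs
#'
#' @param classifications list of [classify_pair()] results covering the
#'   motif's pairs.
#' @param aggregate `"per_pair"` (default): percent = mean over pairs of
#'   each pair's conservation fraction x 100; `"per_homolog"`: percent =
#'   mean over homologs of the fraction of pairs kept canonical.
#' @return list with `percent_canonical`, `n_consistent`, `n_compensatory`,
#'   `n_disruptive` (pairs exhibiting >= 1 homolog in that category) and
#'   `n_pairs`.
#' @export
summarize_motif_conservation <- function(classifications,
                                         aggregate = c("per_pair", "per_homolog")) {
  aggregate <- match.arg(aggregate)
  has <- function(cl, cat) any(cl$categories == cat)
  pct <- if (aggregate == "per_pair") {
    100 * mean(vapply(classifications, `[[`, numeric(1),
                      "conservation_fraction"), na.rm = TRUE)
  } else {
    cats <- do.call(rbind, lapply(classifications, `[[`, "categories"))
    ok <- cats %in% c("conserved", "consistent", "compensatory")
    dim(ok) <- dim(cats)
    100 * mean(colMeans(ok[, colSums(cats != "gapped") > 0, drop = FALSE]))
  }
  list(percent_canonical = pct,
       n_consistent = sum(vapply(classifications, has, logical(1), "consistent")),
       n_compensatory = sum(vapply(classifications, has, logical(1), "compensatory")),
       n_disruptive = sum(vapply(classifications, has, logical(1), "disruptive")),
       n_pairs = length(classifications))
}

#' Chemical-probing consistency of a structure model
#'
#' A chemically modified nucleotide (single-strand-sensitive reagents,
#' reactivity `strong` or `weak`) is inconsistent with the model iff it is
#' Watson-Crick paired (AU/UA/GC/CG; a GU wobble does not count) within the
#' structure.
#'
#' @param pairs two-column pair matrix of the structure model.
#' @param seq the sequence the model refers to.
#' @param overlay data.frame with columns `pos` and `reactivity`
#'   (`strong`/`weak`/`none`); optional logical column `pausing`.
#' @return list with `n_modified`, `n_inconsistent`, `verdicts` data.frame.
#' @export
probing_consistency <- function(pairs, seq, overlay) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  if (any(overlay$pos < 1 | overlay$pos > n))
    stop("overlay position outside the structure")
  pairs <- as.matrix(pairs)
  partner <- integer(n)
  if (nrow(pairs)) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  mod <- overlay[overlay$reactivity %in% c("strong", "weak"), , drop = FALSE]
  wc <- c("AU", "UA", "GC", "CG")
  inconsistent <- vapply(mod$pos, function(p) {
    q <- partner[p]
    if (q == 0L) return(FALSE)
    pt <- pair_type(substr(seq, min(p, q), min(p, q)),
                    substr(seq, max(p, q), max(p, q)))
    !is.na(pt) && pt %in% wc
  }, logical(1))
  list(n_modified = nrow(mod), n_inconsistent = sum(inconsistent),
       verdicts = data.frame(pos = mod$pos, reactivity = mod$reactivity,
                             inconsistent = inconsistent,
                             stringsAsFactors = FALSE))
}
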