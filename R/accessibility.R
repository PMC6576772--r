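# miRNA target-site accessibility: ddG = dG(duplex) - dG(open), where
# dG(open) is the ensemble free-energy cost of holding the target site
# single-stranded within a fixed-flank local context.

SEED_DEFS <- list("6mer" = c(2L, 7L), "7mer" = c(2L, 8L), "8mer" = c(2L, 8L))

#' Find miRNA seed-complement sites in a transcript
#'
#' Exact Watson-Crick complements (GU disallowed in the seed match by
#' default) of the miRNA seed: positions 2-7 (`6mer`), 2-8 (`7mer`), or 2-8
#' plus a target-side A opposite position 1 (`8mer`).
#'
#' @param transcript RNA sequence searched (mRNA sense).
#' @param mirna miRNA sequence, 5' to 3', length >= 8.
#' @param seed_def `"6mer"`, `"7mer"` or `"8mer"`.
#' @return data.frame of sites: `start`, `end` (1-based transcript
#'   coordinates), `seed_def`, `seed_end` (miRNA position of the seed's 3'
#'   end), `site_seq`.
#' @export
find_seed_sites <- function(transcript, mirna, seed_def = c("7mer", "6mer", "8mer")) {
  seed_def <- match.arg(seed_def)
  transcript <- as_rna(transcript)
  mirna <- as_rna(mirna)
  if (nchar(mirna) < 8) stop("miRNA must be at least 8 nt")
  rng <- SEED_DEFS[[seed_def]]
  seed <- substr(mirna, rng[1], rng[2])
  pat <- revcomp_rna(seed)
  if (seed_def == "8mer") pat <- paste0(pat, "A")
  hits <- gregexpr(pat, transcript, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    return(data.frame(start = integer(0), end = integer(0),
                      seed_def = character(0), seed_end = integer(0),
                      site_seq = character(0), stringsAsFactors = FALSE))
  starts <- as.integer(hits)
  ends <- starts + nchar(pat) - 1L
  data.frame(start = starts, end = ends, seed_def = seed_def,
             seed_end = rng[2],
             site_seq = substring(transcript, starts, ends),
             stringsAsFactors = FALSE)
}

#' PITA-style site accessibility ddG
#'
#' ddG = dG(duplex) - dG(open). The duplex term is the minimum hybridization
#' energy of the full miRNA against the site's footprint (the seed site
#' extended upstream by the miRNA length beyond the seed and one nt
#' downstream, truncated at transcript ends). The opening term is
#' dG(open) = G(ensemble of footprint +/- flank) - G(same region with every
#' footprint nt forced unpaired) <= 0, computed from partition-function free
#' energies; more negative ddG means a more accessible, more favorable site.
#'
#' @param transcript full transcript sequence.
#' @param site one row of [find_seed_sites()] output, or a list/row with
#'   `start` and `end` (an explicit interval is treated as the whole
#'   footprint).
#' @param mirna miRNA sequence.
#' @param flank nt of context on each side of the footprint (default 70,
#'   truncated at transcript ends).
#' @param params [fold_params()].
#' @param dg_open_method `"ensemble"` (default) or `"mfe"` free energies for
#'   the opening cost.
#' @return list with `dg_duplex`, `dg_open`, `ddg`, `flank`, `footprint`
#'   (start, end) and `region` (start, end of the folded context).
#' @export
compute_ddg <- function(transcript, site, mirna, flank = 70L,
                        params = fold_params(),
                        dg_open_method = c("ensemble", "mfe")) {
  dg_open_method <- match.arg(dg_open_method)
  transcript <- as_rna(transcript)
  mirna <- as_rna(mirna)
  L <- nchar(transcript)
  start <- as.integer(site$start); end <- as.integer(site$end)
  if (is.na(start) || is.na(end) || start < 1 || end > L || start > end)
    stop("site outside the transcript")
  if (!is.null(site$seed_end) && length(site$seed_end) && !is.na(site$seed_end)) {
    fp_start <- max(1L, start - (nchar(mirna) - as.integer(site$seed_end)))
    fp_end <- min(L, end + 1L)
  } else {
    fp_start <- start; fp_end <- end
  }
  reg_start <- max(1L, fp_start - flank)
  reg_end <- min(L, fp_end + flank)
  region <- substr(transcript, reg_start, reg_end)
  open_idx <- (fp_start:fp_end) - reg_start + 1L
  if (dg_open_method == "ensemble") {
    g_free <- ensemble_free_energy(region, params = params)
    g_open <- ensemble_free_energy(region, forced_unpaired = open_idx,
                                   params = params)
  } else {
    g_free <- mfe_fold(region, params = params)$delta_g
    g_open <- mfe_fold(region, fold_constraints(forced_unpaired = open_idx),
                       params = params)$delta_g
  }
  dg_open <- g_free - g_open  # <= 0: cost of opening enters ddg as -dg_open
  dg_duplex <- duplex_energy(mirna, substr(transcript, fp_start, fp_end),
                             params = params)
  list(dg_duplex = dg_duplex, dg_open = dg_open, ddg = dg_duplex - dg_open,
       flank = as.integer(flank), footprint = c(fp_start, fp_end),
       region = c(reg_start, reg_end))
}
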