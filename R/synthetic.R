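# Seeded generators with known truth, so every pipeline stage can be scored
# offline. Every generator is a pure function of its seed.

#' Random RNA background of given composition
#'
#' @param length sequence length (nt).
#' @param composition named probabilities for A, C, G, U (must sum to 1).
#' @param seed integer seed.
#' @return character sequence.
#' @export
random_background <- function(length,
                              composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                              seed = 1L) {
  if (abs(sum(composition) - 1) > 1e-9) stop("composition must sum to 1")
  bases <- c("A", "C", "G", "U")
  comp <- composition[bases]
  with_seed(seed, paste(sample(bases, length, replace = TRUE, prob = comp),
                        collapse = ""))
}

#' Specification for a background with embedded hairpins
#'
#' @param length background length (nt).
#' @param composition background base composition.
#' @param inserts list of inserts, each a list with `position` (1-based start
#'   of the insert), `stem` (bp), `loop` (loop sequence, >= 3 nt).
#' @param stem_composition base composition used to draw stem sequences
#'   (GC-rich by default, so embedded stems are thermodynamically stable).
#' @param seed integer seed.
#' @export
synthetic_motif_spec <- function(length = 300L,
                                 composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                                 inserts = list(list(position = 140L, stem = 12L,
                                                     loop = "GAAA")),
                                 stem_composition = c(A = 0.1, C = 0.4, G = 0.4, U = 0.1),
                                 seed = 1L) {
  structure(list(length = as.integer(length), composition = composition,
                 inserts = inserts, stem_composition = stem_composition,
                 seed = as.integer(seed)),
            class = "synthetic_motif_spec")
}

#' Embed designed hairpins in a random background
#'
#' Each insert is a perfect stem-loop (stem, loop, reverse-complement stem)
#' written over the background at its position; the returned truth pairs are
#' exactly the designed stems at absolute coordinates.
#'
#' @param spec a [synthetic_motif_spec()].
#' @return list with `seq`, `truth_pairs` (data.frame `i`, `j`, `insert`) and
#'   `inserts` (start/end of each written insert).
#' @export
embed_motif <- function(spec) {
  bases <- c("A", "C", "G", "U")
  out <- with_seed(spec$seed, {
    bg <- strsplit(paste(sample(bases, spec$length, replace = TRUE,
                                prob = spec$composition[bases]), collapse = ""),
                   "")[[1]]
    truth <- list(); meta <- list()
    occupied <- rep(FALSE, spec$length)
    for (k in seq_along(spec$inserts)) {
      ins <- spec$inserts[[k]]
      loop <- as_rna(ins$loop)
      if (nchar(loop) < 3) stop("loop must be at least 3 nt")
      stem5 <- paste(sample(bases, ins$stem, replace = TRUE,
                            prob = spec$stem_composition[bases]), collapse = "")
      insert <- paste0(stem5, loop, revcomp_rna(stem5))
      len <- nchar(insert)
      p0 <- ins$position
      if (p0 < 1 || p0 + len - 1 > spec$length)
        stop("insert ", k, " does not fit in the background")
      if (any(occupied[p0:(p0 + len - 1)])) stop("overlapping inserts")
      occupied[p0:(p0 + len - 1)] <- TRUE
      bg[p0:(p0 + len - 1)] <- strsplit(insert, "")[[1]]
      truth[[k]] <- data.frame(i = p0 + seq_len(ins$stem) - 1L,
                               j = p0 + len - seq_len(ins$stem), insert = k)
      meta[[k]] <- c(start = p0, end = p0 + len - 1L)
    }
    list(seq = paste(bg, collapse = ""),
         truth_pairs = if (length(truth)) do.call(rbind, truth)
           else data.frame(i = integer(0), j = integer(0), insert = integer(0)),
         inserts = meta)
  })
  out
}

#' Specification for a synthetic alignment with programmed covariation
#'
#' @param reference reference sequence.
#' @param truth_pairs two-column matrix/data.frame of reference pairs.
#' @param n_homologs number of non-reference rows.
#' @param rates named vector `c(consistent=, compensatory=, disruptive=)` of
#'   per-pair, per-homolog mutation probabilities (sum <= 1; the remainder is
#'   conserved).
#' @param background_rate substitution rate at positions outside all pairs.
#' @param seed integer seed.
#' @export
synthetic_alignment_spec <- function(reference, truth_pairs, n_homologs = 15L,
                                     rates = c(consistent = 0.1,
                                               compensatory = 0.05,
                                               disruptive = 0.05),
                                     background_rate = 0.1, seed = 1L) {
  if (any(rates < 0) || sum(rates) > 1) stop("rates must be in [0,1], sum <= 1")
  structure(list(reference = as_rna(reference),
                 truth_pairs = as.matrix(truth_pairs)[, 1:2, drop = FALSE],
                 n_homologs = as.integer(n_homologs), rates = rates,
                 background_rate = background_rate, seed = as.integer(seed)),
            class = "synthetic_alignment_spec")
}

# canonical pairs reachable from a reference pair by changing one/both sides
.one_change_canonical <- function(a, b) {
  cand <- list()
  for (p in list(c("A","U"), c("U","A"), c("G","C"), c("C","G"), c("G","U"), c("U","G"))) {
    if ((p[1] == a) + (p[2] == b) == 1) cand[[length(cand) + 1L]] <- p
  }
  cand
}
.two_change_canonical <- function(a, b) {
  cand <- list()
  for (p in list(c("A","U"), c("U","A"), c("G","C"), c("C","G"), c("G","U"), c("U","G"))) {
    if (p[1] != a && p[2] != b) cand[[length(cand) + 1L]] <- p
  }
  cand
}

#' Generate an ungapped alignment with programmed pair mutations
#'
#' For each homolog and truth pair a category is drawn at the programmed
#' rates and an appropriate double/single substitution is applied (consistent
#' keeps canonical pairing with one side changed, compensatory with both
#' changed, disruptive breaks canonicity). Background substitutions touch
#' only positions outside all pairs. The emitted truth table records the
#' mutations actually applied.
#'
#' @param spec a [synthetic_alignment_spec()].
#' @return list with `aln` (named character vector, reference first, id
#'   `ref`) and `truth` (data.frame `homolog`, `i`, `j`, `category`).
#' @export
synth_alignment <- function(spec) {
  ref <- strsplit(spec$reference, "")[[1]]
  tp <- spec$truth_pairs
  in_pair <- unique(as.vector(tp))
  bases <- c("A", "C", "G", "U")
  with_seed(spec$seed, {
    aln <- list(ref = paste(ref, collapse = ""))
    truth <- list()
    cats <- c("consistent", "compensatory", "disruptive", "conserved")
    probs <- c(spec$rates[["consistent"]], spec$rates[["compensatory"]],
               spec$rates[["disruptive"]], 1 - sum(spec$rates))
    for (h in seq_len(spec$n_homologs)) {
      hom <- ref
      for (r in seq_len(nrow(tp))) {
        i <- tp[r, 1]; j <- tp[r, 2]
        cat_r <- sample(cats, 1, prob = probs)
        if (cat_r == "consistent") {
          pick <- .one_change_canonical(ref[i], ref[j])
          p <- pick[[sample.int(length(pick), 1)]]
          hom[i] <- p[1]; hom[j] <- p[2]
        } else if (cat_r == "compensatory") {
          pick <- .two_change_canonical(ref[i], ref[j])
          p <- pick[[sample.int(length(pick), 1)]]
          hom[i] <- p[1]; hom[j] <- p[2]
        } else if (cat_r == "disruptive") {
          ok <- bases[vapply(bases, function(x)
            is.na(pair_type(x, ref[j])), logical(1))]
          hom[i] <- sample(ok, 1)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          homolog = sprintf("hom%02d", h), i = i, j = j, category = cat_r,
          stringsAsFactors = FALSE)
      }
      bg_pos <- setdiff(seq_along(ref), in_pair)
      mut <- bg_pos[runif(length(bg_pos)) < spec$background_rate]
      for (m in mut) hom[m] <- sample(setdiff(bases, ref[m]), 1)
      aln[[sprintf("hom%02d", h)]] <- paste(hom, collapse = "")
    }
    list(aln = unlist(aln), truth = do.call(rbind, truth))
  })
}

#' Generate a synthetic dual-luciferase assay table with known TE effects
#'
#' The first element of `fold_effects` names the control construct (effect
#' 1). Relative transcript abundance and plate factors vary sample-to-sample
#' (log-normal / Ct noise controlled by `noise_sd`); RRR is constructed so
#' the sample's true TE is the programmed effect, which the ddCt chain then
#' recovers. With `noise_sd = 0` the recovery is exact.
#'
#' @param n_per_construct replicates per construct.
#' @param fold_effects named positive numerics (control first, typically 1).
#' @param noise_sd noise SD (applied to log-RRR and to Ct values).
#' @param seed integer seed.
#' @return data.frame in [compute_te()] input format; attribute `truth`
#'   holds the programmed effects, attribute `control` the control name.
#' @export
synth_reporter <- function(n_per_construct = 3L,
                           fold_effects = c(pIS2 = 1, M17 = 0.42),
                           noise_sd = 0, seed = 1L) {
  if (any(fold_effects <= 0)) stop("effects must be positive")
  with_seed(seed, {
    rows <- list()
    for (cstr in names(fold_effects)) {
      for (rep_i in seq_len(n_per_construct)) {
        ct_ff <- 20 + rnorm(1, 0, noise_sd)
        ddct <- rnorm(1, 0, noise_sd)          # sample-level abundance shift
        ct_rl <- ct_ff + 2 + ddct              # baseline dCt of 2 cycles
        ff <- 1e6 * exp(rnorm(1, 0, noise_sd)) # plate factor
        rrr <- fold_effects[[cstr]] * 2^(-ddct) * exp(rnorm(1, 0, noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          construct = cstr, replicate = rep_i, rl_rlu = rrr * ff, ff_rlu = ff,
          ct_rl = ct_rl, ct_ff = ct_ff, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- fold_effects
    attr(out, "control") <- names(fold_effects)[1]
    out
  })
}
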