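#' Scan parameters
#'
#' @param window window size in nt (>= 10).
#' @param step step size in nt (>= 1).
#' @param n_randomizations number of mononucleotide shuffles per window
#'   (>= 2).
#' @param temperature folding temperature (C).
#' @param rng_seed integer seed; one generator is seeded per scan and
#'   consumed window-by-window in order, so a scan is a pure function of its
#'   seed.
#' @param sigma_mode `"all"` (default): the z-score denominator is the
#'   population standard deviation over the native plus all randomized
#'   energies; `"randoms"`: over the randomized energies only (sensitivity
#'   analysis).
#' @param ensemble compute partition-function metrics (ED, fMFE, centroid)
#'   per window; can be disabled when only MFE structures and z-scores are
#'   needed.
#' @return object of class `scan_params`.
#' @export
scan_params <- function(window = 70L, step = 1L, n_randomizations = 100L,
                        temperature = 37, rng_seed = 1L,
                        sigma_mode = c("all", "randoms"), ensemble = TRUE) {
  window <- as.integer(window); step <- as.integer(step)
  n_randomizations <- as.integer(n_randomizations)
  if (window < 10) stop("window must be at least 10 nt")
  if (step < 1) stop("step must be at least 1")
  if (n_randomizations < 2) stop("n_randomizations must be at least 2")
  structure(list(window = window, step = step,
                 n_randomizations = n_randomizations,
                 shuffle_kind = "mononucleotide",
                 temperature = temperature, rng_seed = as.integer(rng_seed),
                 sigma_mode = match.arg(sigma_mode), ensemble = ensemble),
            class = "scan_params")
}

#' Window coordinates for a sliding scan
#'
#' Windows start at 1 and advance by `step`; only full windows are emitted
#' (no partial tail), so the count is `floor((L - window)/step) + 1` and
#' metrics are attributed to the window's first nucleotide.
#'
#' @param seq RNA sequence.
#' @param window,step window and step sizes (nt).
#' @return data.frame with columns `i`, `j`, `subseq`.
#' @export
iter_windows <- function(seq, window = 70L, step = 1L) {
  seq <- as_rna(seq)
  L <- nchar(seq)
  if (L < window)
    stop("sequence (", L, " nt) is shorter than the window (", window,
         " nt); shorten the window or supply a longer sequence")
  starts <- seq.int(1L, L - window + 1L, by = step)
  data.frame(i = starts, j = starts + window - 1L,
             subseq = substring(seq, starts, starts + window - 1L),
             stringsAsFactors = FALSE)
}

#' Mononucleotide shuffle
#'
#' Uniform-random permutation of the residues; base composition is conserved
#' exactly. Consumes the current RNG stream.
#'
#' @param seq sequence string.
#' @return shuffled string.
#' @export
shuffle_mononucleotide <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (!length(ch)) stop("cannot shuffle an empty sequence")
  paste(sample(ch), collapse = "")
}

#' Summary of a shuffle null for one window
#'
#' @param native native MFE (kcal/mol).
#' @param random_energies MFEs of the randomized sequences.
#' @param sigma_mode see [scan_params()].
#' @return list with `mean_random`, `sigma` (population SD), `n`,
#'   `random_energies`, `sigma_mode`.
#' @export
null_summary <- function(native, random_energies,
                         sigma_mode = c("all", "randoms")) {
  sigma_mode <- match.arg(sigma_mode)
  if (length(random_energies) < 2) stop("need at least 2 randomized energies")
  pool <- if (sigma_mode == "all") c(native, random_energies) else random_energies
  list(mean_random = mean(random_energies),
       sigma = sqrt(mean((pool - mean(pool))^2)),
       n = length(random_energies), random_energies = random_energies,
       sigma_mode = sigma_mode)
}

#' Thermodynamic z-score
#'
#' z = (dG_native - mean(dG_random)) / sigma, with sigma the population
#' standard deviation over the native plus randomized energies (or randoms
#' only, per the null's `sigma_mode`). Negative z means more stable than
#' composition-matched random sequence. When sigma = 0 (all energies
#' identical) z is defined as 0 and flagged via attribute `flagged`.
#'
#' @param native native MFE.
#' @param null a [null_summary()].
#' @return numeric z (attribute `flagged` TRUE when sigma was 0).
#' @export
compute_zscore <- function(native, null) {
  if (null$sigma == 0)
    return(structure(0, flagged = TRUE))
  structure((native - null$mean_random) / null$sigma, flagged = FALSE)
}

#' Empirical P-value of the native energy
#'
#' Fraction of randomized sequences strictly more stable than native (ties
#' count as not more stable).
#'
#' @inheritParams compute_zscore
#' @return fraction in \[0, 1\].
#' @export
compute_pvalue <- function(native, null) {
  sum(null$random_energies < native) / null$n
}

#' Sliding-window thermodynamic scan
#'
#' For every window: the native MFE fold, `n_randomizations` mononucleotide
#' shuffles folded for their energies, the z-score and empirical P-value,
#' ensemble metrics (ED, fMFE, centroid), base frequencies and GC%. Every
#' shuffle is asserted to conserve the window's base composition.
#'
#' @param seq RNA sequence (a character scalar; T normalized to U).
#' @param params [scan_params()].
#' @param fold_parameters [fold_params()]; its temperature is taken from
#'   `params`.
#' @return data.frame of per-window records (one row per window), with the
#'   scan parameters attached as attribute `scan_params`.
#' @export
scan_sequence <- function(seq, params = scan_params(),
                          fold_parameters = fold_params(params$temperature)) {
  seq <- as_rna(seq)
  win <- iter_windows(seq, params$window, params$step)
  nw <- nrow(win)
  out <- vector("list", nw)
  with_seed(params$rng_seed, {
    for (w in seq_len(nw)) {
      sub <- win$subseq[w]
      native <- mfe_fold(sub, params = fold_parameters)
      sorted_native <- sort(strsplit(sub, "")[[1]])
      rand_e <- numeric(params$n_randomizations)
      for (r in seq_len(params$n_randomizations)) {
        sh <- shuffle_mononucleotide(sub)
        if (!identical(sort(strsplit(sh, "")[[1]]), sorted_native))
          stop("internal error: shuffle altered base composition")
        rand_e[r] <- mfe_energy(sh, fold_parameters)
      }
      null <- null_summary(native$delta_g, rand_e, params$sigma_mode)
      z <- compute_zscore(native$delta_g, null)
      pv <- compute_pvalue(native$delta_g, null)
      if (params$ensemble) {
        em <- ensemble_metrics(sub, params = fold_parameters)
        ed <- em$ed; fmfe <- em$fmfe; cdb <- em$centroid_db
      } else {
        ed <- NA_real_; fmfe <- NA_real_; cdb <- NA_character_
      }
      fr <- base_frequencies(sub)
      out[[w]] <- data.frame(
        i = win$i[w], j = win$j[w], delta_g = native$delta_g,
        zscore = as.numeric(z), pvalue = pv, ed = ed, fmfe = fmfe,
        window_seq = sub, mfe_db = native$db, centroid_db = cdb,
        freq_a = fr[["freq_a"]], freq_g = fr[["freq_g"]],
        freq_c = fr[["freq_c"]], freq_u = fr[["freq_u"]],
        gc_pct = 100 * (fr[["freq_g"]] + fr[["freq_c"]]),
        sigma = null$sigma, mean_random = null$mean_random,
        z_flagged = attr(z, "flagged"), stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "scan_params") <- params
  res
}

#' Region specification for scan summaries
#'
#' @param name region labels.
#' @param start,end inclusive window-index ranges (must be non-overlapping
#'   and within the scan).
#' @export
region_spec <- function(name, start, end) {
  d <- data.frame(name = as.character(name), start = as.integer(start),
                  end = as.integer(end), stringsAsFactors = FALSE)
  if (any(d$start > d$end)) stop("region start must not exceed end")
  o <- order(d$start)
  if (nrow(d) > 1 && any(d$start[o][-1] <= d$end[o][-nrow(d)]))
    stop("regions overlap")
  d
}

#' Per-region metric summaries, Welch t-tests and metric correlations
#'
#' Means of dG, z and ED per region; pairwise two-tailed Welch t-tests
#' between regions for each metric (the p-values carry the caveat that
#' overlapping scan windows are not independent, so they are descriptive
#' only); Pearson correlations between metric columns over all windows.
#'
#' @param scan a [scan_sequence()] table.
#' @param regions a [region_spec()] data.frame of window-index ranges.
#' @return list with `means`, `ttests` (list of p-value matrices per metric),
#'   `correlations`, `flags`, `caveat`.
#' @export
summarize_regions <- function(scan, regions) {
  if (any(regions$end > nrow(scan))) stop("region range outside the scan table")
  metrics <- c("delta_g", "zscore", "ed")
  groups <- lapply(seq_len(nrow(regions)),
                   function(r) scan[regions$start[r]:regions$end[r], , drop = FALSE])
  names(groups) <- regions$name
  means <- do.call(rbind, lapply(groups, function(g)
    vapply(metrics, function(m) mean(g[[m]]), numeric(1))))
  means <- data.frame(name = regions$name, n_windows = regions$end - regions$start + 1L,
                      means, row.names = NULL, stringsAsFactors = FALSE)
  flags <- character(0)
  ttests <- lapply(metrics, function(m) {
    k <- length(groups)
    pm <- matrix(NA_real_, k, k, dimnames = list(regions$name, regions$name))
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a >= b) next
      xa <- groups[[a]][[m]]; xb <- groups[[b]][[m]]
      if (length(xa) < 2 || length(xb) < 2) {
        flags <<- c(flags, paste0("t-test skipped (", m, "): region with < 2 windows"))
        next
      }
      if (sd(xa) == 0 && sd(xb) == 0) {
        flags <<- c(flags, paste0("t-test skipped (", m, "): zero variance"))
        next
      }
      pm[a, b] <- pm[b, a] <- welch_t_test(xa, xb)$p
    }
    pm
  })
  names(ttests) <- metrics
  num_cols <- c("delta_g", "zscore", "pvalue", "ed", "fmfe", "gc_pct")
  num_cols <- num_cols[vapply(num_cols, function(cn) !all(is.na(scan[[cn]])), logical(1))]
  constant <- vapply(num_cols, function(cn) sd(scan[[cn]]) == 0, logical(1))
  if (any(constant))
    flags <- c(flags, paste0("correlation undefined for constant column(s): ",
                             paste(num_cols[constant], collapse = ", ")))
  correlations <- suppressWarnings(cor(scan[num_cols]))
  list(means = means, ttests = ttests, correlations = correlations,
       flags = unique(flags),
       caveat = paste("Welch t-test p-values are descriptive only:",
                      "overlapping scan windows violate independence"))
}
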