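# Bundled simplified nearest-neighbor energy model (37 C reference values).
# Watson-Crick/Watson-Crick stack free energies are the published Turner 2004
# dinucleotide values; stacks involving GU wobble pairs are approximated by
# class (one wobble, wobble next to GC, tandem wobble). Loop penalties are
# length-only initiation terms with Jacobson-Stockmayer extrapolation; there
# are no terminal-mismatch, dangling-end or coaxial terms. The same parameter
# object drives the compiled DP engine and the pure-R enumeration oracle.

PAIR_LEVELS <- c("CG", "GC", "GU", "UG", "AU", "UA")

#' Pair type of two bases
#'
#' Returns the canonical pair class ("CG", "GC", "GU", "UG", "AU", "UA") or
#' `NA` for a non-canonical combination. `N` never pairs.
#'
#' @param a,b single upper-case RNA bases.
#' @return character scalar or `NA_character_`.
#' @export
pair_type <- function(a, b) {
  key <- paste0(a, b)
  ifelse(key %in% PAIR_LEVELS, key, NA_character_)
}

# 6x6 stack table builder: rows = closing (outer) pair (i,j),
# cols = stacked (inner) pair (i+1, j-1). Values in kcal/mol at 37 C.
.build_stack_table <- function() {
  wc <- c("AU", "UA", "GC", "CG")
  # Turner 2004 WC/WC nearest-neighbor dG37, addressed as outer/inner
  wc_tab <- matrix(NA_real_, 4, 4, dimnames = list(wc, wc))
  wc_tab["AU", ] <- c(AU = -0.93, UA = -1.10, GC = -2.08, CG = -2.24)
  wc_tab["UA", ] <- c(AU = -1.33, UA = -0.93, GC = -2.11, CG = -2.35)
  wc_tab["GC", ] <- c(AU = -2.35, UA = -2.24, GC = -3.26, CG = -3.42)
  wc_tab["CG", ] <- c(AU = -2.11, UA = -2.08, GC = -2.36, CG = -3.26)
  st <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))
  is_gu <- function(p) p %in% c("GU", "UG")
  for (p in PAIR_LEVELS) {
    for (q in PAIR_LEVELS) {
      if (!is_gu(p) && !is_gu(q)) {
        st[p, q] <- wc_tab[p, q]
      } else if (is_gu(p) && is_gu(q)) {
        st[p, q] <- -0.5
      } else {
        other <- if (is_gu(p)) q else p
        st[p, q] <- if (other %in% c("GC", "CG")) -2.1 else -1.4
      }
    }
  }
  st
}

#' Energy-model parameters for the bundled folding engine
#'
#' @param temperature folding temperature in degrees Celsius; enters through
#'   RT in Boltzmann weighting (the free-energy tables themselves are 37 C
#'   values, so temperatures far from 37 C are not physically meaningful).
#' @param max_interior largest allowed total unpaired length of a bulge or
#'   internal loop (standard convention, 30 nt).
#' @param min_hairpin minimum hairpin loop length in nt.
#' @param duplex_max_gap largest bulge/internal gap per strand in the
#'   intermolecular duplex model.
#' @return an object of class `fold_params`.
#' @export
fold_params <- function(temperature = 37, max_interior = 30L,
                        min_hairpin = 3L, duplex_max_gap = 10L) {
  stopifnot(min_hairpin >= 1, max_interior >= 2)
  rt <- 0.0019872 * (273.15 + temperature)
  p <- list(
    stack = .build_stack_table(),
    hairpin_init = c(3, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4),  # first entry = min size
    bulge_init = c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4),            # sizes 1..6
    internal_init = c(1.5, 1.6, 1.7, 1.8, 2.0),              # sizes 2..6
    ml_closing = 3.4, ml_branch = 0.4, ml_unpaired = 0.4,
    temperature = temperature, rt = rt,
    min_hairpin = as.integer(min_hairpin),
    max_interior = as.integer(max_interior),
    duplex_max_gap = as.integer(duplex_max_gap),
    lxc = 1.75 * rt  # Jacobson-Stockmayer coefficient for long loops
  )
  class(p) <- "fold_params"
  p
}

# Loop-penalty lookup tables extended to length n (Inf marks impossible sizes).
loop_tables <- function(params, n) {
  n <- max(n, 31L)
  hp <- rep(Inf, n)
  base <- params$hairpin_init[-1]
  sizes <- seq_along(base) + params$min_hairpin - 1L
  hp[sizes] <- base
  top <- max(sizes)
  if (n > top)
    hp[(top + 1):n] <- hp[top] + params$lxc * log((top + 1):n / top)
  bu <- rep(Inf, n)
  bu[seq_along(params$bulge_init)] <- params$bulge_init
  tb <- length(params$bulge_init)
  if (n > tb) bu[(tb + 1):n] <- bu[tb] + params$lxc * log((tb + 1):n / tb)
  il <- rep(Inf, n)
  il[2:6] <- params$internal_init
  if (n > 6) il[7:n] <- il[6] + params$lxc * log((7:n) / 6)
  list(hairpin = hp, bulge = bu, internal = il)
}

# Hairpin penalty for a loop of L unpaired nt (vectorised, used by the oracle).
hairpin_energy <- function(L, params, tabs = NULL) {
  if (is.null(tabs)) tabs <- loop_tables(params, max(L, 3L))
  ifelse(L >= params$min_hairpin, tabs$hairpin[L], Inf)
}
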