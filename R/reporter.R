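# Dual-luciferase reporter statistics: relative response ratio, ddCt
# relative abundance, translational efficiency, Welch t-tests.

#' Translational efficiency from dual-luciferase + qPCR data
#'
#' Per sample: RRR = RL/FF relative light units; dCt = Ct_RL - Ct_FF; ddCt is
#' taken against the control construct's mean dCt; relative abundance =
#' 2^(-ddCt); TE = RRR / 2^(-ddCt); `te_norm` rescales so the control
#' construct's mean TE is 1.
#'
#' @param samples data.frame with columns `construct`, `replicate`, `rl_rlu`,
#'   `ff_rlu`, `ct_rl`, `ct_ff`.
#' @param control name of the control (unregulated) construct.
#' @return list with `samples` (input plus `rrr`, `dct`, `ddct`,
#'   `rel_abundance`, `te`, `te_norm`) and `constructs` (per-construct mean
#'   and SD of `te_norm`).
#' @export
compute_te <- function(samples, control) {
  need <- c("construct", "replicate", "rl_rlu", "ff_rlu", "ct_rl", "ct_ff")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  if (!control %in% samples$construct)
    stop("control construct '", control, "' not present")
  if (any(samples$rl_rlu <= 0 | samples$ff_rlu <= 0))
    stop("luminescence readings must be positive")
  if (any(!is.finite(samples$ct_rl) | !is.finite(samples$ct_ff)))
    stop("Ct values must be finite")
  s <- samples
  s$rrr <- s$rl_rlu / s$ff_rlu
  s$dct <- s$ct_rl - s$ct_ff
  ref_dct <- mean(s$dct[s$construct == control])
  s$ddct <- s$dct - ref_dct
  s$rel_abundance <- 2^(-s$ddct)
  s$te <- s$rrr / s$rel_abundance
  s$te_norm <- s$te / mean(s$te[s$construct == control])
  agg <- split(s$te_norm, s$construct)
  constructs <- data.frame(
    construct = names(agg),
    n = vapply(agg, length, integer(1)),
    te_norm_mean = vapply(agg, mean, numeric(1)),
    te_norm_sd = vapply(agg, function(x) if (length(x) > 1) sd(x) else NA_real_,
                        numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(samples = s, constructs = constructs, control = control)
}

#' Two-sample unpaired Welch t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-tailed p-value (delegates to [stats::t.test()]). Significance markers
#' follow the convention `*` p < 0.05, `**` p < 0.005.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return list with `t`, `df`, `p`, `stars`, `flagged` (TRUE when both
#'   groups had zero variance, in which case `t`/`p` are `NA`).
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, stars = "",
                flagged = TRUE))
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  p <- unname(ht$p.value)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = p,
       stars = if (p < 0.005) "**" else if (p < 0.05) "*" else "",
       flagged = FALSE)
}

#' Pairwise Welch t-tests of TE between constructs
#'
#' @param te a [compute_te()] result.
#' @return data.frame of pairwise comparisons on `te_norm`.
#' @export
te_comparisons <- function(te) {
  s <- te$samples
  cs <- unique(s$construct)
  out <- list()
  for (a in seq_along(cs)) for (b in seq_along(cs)) {
    if (a >= b) next
    w <- welch_t_test(s$te_norm[s$construct == cs[a]],
                      s$te_norm[s$construct == cs[b]])
    out[[length(out) + 1L]] <- data.frame(
      group_a = cs[a], group_b = cs[b], t = w$t, df = w$df, p = w$p,
      stars = w$stars, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
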