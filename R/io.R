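# Readers/writers and pipeline orchestration. Standard formats go through
# Biostrings; TSVs are tab-delimited UTF-8 with '.' decimal and a commented
# header carrying the tool version, config checksum and seed, so reruns are
# byte-comparable.

#' Read a (multi-)FASTA file of RNA/DNA sequences
#'
#' T is normalized to U; characters outside `{A,C,G,U,N}` are rejected;
#' duplicate or empty identifiers are errors.
#'
#' @param path FASTA file.
#' @return named character vector of normalized sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("empty sequence identifier in ", path)
  if (anyDuplicated(ids))
    stop("duplicate identifier(s): ", paste(unique(ids[duplicated(ids)]),
                                            collapse = ", "))
  out <- vapply(seq_along(x), function(k) as_rna(as.character(x[[k]])),
                character(1))
  names(out) <- ids
  out
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' All rows must have equal length; the gap character `-` is preserved; T is
#' normalized to U.
#'
#' @param path aligned FASTA file.
#' @return named character vector of aligned rows.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1)
    stop("ragged alignment: record '", ids[which(w != w[1])[1]],
         "' has length ", w[which(w != w[1])[1]], ", expected ", w[1])
  out <- toupper(chartr("Tt", "Uu", as.character(x)))
  bad <- gsub("[ACGUN-]", "", paste(out, collapse = ""))
  if (nzchar(bad))
    stop("invalid residue(s) in alignment: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  names(out) <- ids
  out
}

# Cheap deterministic checksum of a configuration (hex string).
config_checksum <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2^31)
}

.tsv_header <- function(config = NULL, seed = NULL) {
  c(paste0("# foldscan ", as.character(packageVersion("foldscan"))),
    if (!is.null(config)) paste0("# config ", config_checksum(config)),
    if (!is.null(seed)) paste0("# seed ", seed))
}

#' Write a scan table as TSV
#'
#' Emits exactly the documented column set and order (i, j, dG, z, P, ED,
#' fMFE, sequence, MFE dot-bracket, centroid dot-bracket, A/G/C/U
#' frequencies, GC%) after commented header lines.
#'
#' @param scan [scan_sequence()] table.
#' @param path output path.
#' @param config,seed recorded in the header.
#' @export
write_scan_tsv <- function(scan, path, config = NULL, seed = NULL) {
  cols <- c("i", "j", "delta_g", "zscore", "pvalue", "ed", "fmfe",
            "window_seq", "mfe_db", "centroid_db",
            "freq_a", "freq_g", "freq_c", "freq_u", "gc_pct")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.tsv_header(config, seed), con)
  write.table(scan[, cols], con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv_with_header <- function(df, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.tsv_header(config, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by this package (skips '#' header lines)
#' @param path file path.
#' @export
read_foldscan_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Pipeline configuration
#'
#' Defaults follow the method's standard settings: 70-nt window, 1-nt step,
#' 100 shuffles, average-z cutoffs -1 and -2, 300-nt maximum pair span for
#' the constrained refold, 10-nt motif merge gap, 70-nt accessibility flanks.
#'
#' @param window,step,n_randomizations scan settings.
#' @param cutoffs average-z cutoffs (most permissive first is conventional).
#' @param max_span refold maximum base-pair distance (nt).
#' @param merge_gap motif merge gap (nt).
#' @param flank accessibility flank (nt).
#' @param seed integer seed for the scan.
#' @param backend `"bundled"` or `"vienna"`.
#' @param out_dir output directory.
#' @param ensemble compute per-window ensemble metrics.
#' @export
pipeline_config <- function(window = 70L, step = 1L, n_randomizations = 100L,
                            cutoffs = c(-1, -2), max_span = 300L,
                            merge_gap = 10L, flank = 70L, seed = 1L,
                            backend = c("bundled", "vienna"),
                            out_dir = tempfile("foldscan_run_"),
                            ensemble = TRUE) {
  structure(list(window = as.integer(window), step = as.integer(step),
                 n_randomizations = as.integer(n_randomizations),
                 cutoffs = cutoffs, max_span = as.integer(max_span),
                 merge_gap = as.integer(merge_gap), flank = as.integer(flank),
                 seed = as.integer(seed), backend = match.arg(backend),
                 out_dir = out_dir, ensemble = ensemble),
            class = "pipeline_config")
}

#' Run the scan -> consensus -> motif pipeline on one sequence
#'
#' Executes the sliding-window scan, tallies partners, calls the weighted
#' consensus pairs, filters at each configured cutoff, fills in helices by
#' constrained refolding at the most permissive cutoff, extracts motifs,
#' compares them to the unconstrained global fold, and annotates tetraloops.
#' Every output file is stamped with the tool version, a config checksum and
#' the seed.
#'
#' @param seq RNA sequence (character) or path to a single-record FASTA.
#' @param config [pipeline_config()].
#' @return list with the scan table, tally, pairs per cutoff, fill-in pairs,
#'   motifs, overlap report, tetraloops, and `files` (paths written).
#' @export
run_pipeline <- function(seq, config = pipeline_config()) {
  if (nchar(seq) < 500 && file.exists(seq)) {
    fa <- read_fasta(seq)
    if (length(fa) != 1) stop("expected a single-record FASTA")
    seq <- fa[[1]]
  }
  seq <- as_rna(seq)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  msg <- function(stage, t)
    message(sprintf("[foldscan] %-12s %6.1f s", stage,
                    as.numeric(difftime(Sys.time(), t, units = "secs"))))
  sp <- scan_params(window = config$window, step = config$step,
                    n_randomizations = config$n_randomizations,
                    rng_seed = config$seed, ensemble = config$ensemble)
  scan <- scan_sequence(seq, sp)
  msg("scan", t0)

  t1 <- Sys.time()
  tally <- tally_partners(scan)
  winners <- call_winning_pairs(tally)
  by_cutoff <- lapply(config$cutoffs, function(cf) filter_by_zavg(winners, cf))
  names(by_cutoff) <- paste0("cutoff_", config$cutoffs)
  base_pairs <- by_cutoff[[1]]
  fill <- if (nrow(base_pairs))
    refold_fill_in(seq, base_pairs, max_span = config$max_span,
                   merge_gap = config$merge_gap)
  else base_pairs
  final_pairs <- rbind(base_pairs, fill)
  motifs <- extract_motifs(final_pairs, merge_gap = config$merge_gap)
  global <- mfe_fold(seq)
  overlap <- global_overlap(motifs, global)
  tetra <- annotate_tetraloops(motifs, seq)
  msg("consensus", t1)

  files <- c(
    scan = write_scan_tsv(scan, file.path(config$out_dir, "scan.tsv"),
                          config, config$seed),
    partners = write_tsv_with_header(tally, file.path(config$out_dir, "partners.tsv"),
                                     config, config$seed),
    pairs = write_tsv_with_header(final_pairs, file.path(config$out_dir, "pairs.tsv"),
                                  config, config$seed),
    overlap = if (!is.null(overlap$per_motif))
      write_tsv_with_header(overlap$per_motif,
                            file.path(config$out_dir, "overlap.tsv"),
                            config, config$seed) else NULL,
    tetraloops = write_tsv_with_header(tetra,
                                       file.path(config$out_dir, "tetraloops.tsv"),
                                       config, config$seed))
  # motif models as dot-bracket blocks: header, sequence, structure
  db_path <- file.path(config$out_dir, "motifs.db.txt")
  con <- file(db_path, "w")
  for (m in motifs) {
    sub <- substr(seq, m$start, m$end)
    loc <- cbind(m$pairs$i - m$start + 1L, m$pairs$j - m$start + 1L)
    writeLines(c(sprintf(">motif_%d %d-%d mean_zavg=%.3f", m$index, m$start,
                         m$end, m$mean_zavg),
                 sub, pairs_to_db(loc, nchar(sub))), con)
  }
  close(con)
  files <- c(files, motifs = db_path)

  list(scan = scan, tally = tally, winners = winners, by_cutoff = by_cutoff,
       fill_in = fill, final_pairs = final_pairs, motifs = motifs,
       overlap = overlap, tetraloops = tetra, global = global,
       config = config, files = files)
}
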