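# Window-based GC profiling, composition summaries and intergenic-region
# detection. N bases are excluded from both numerator and denominator of
# every GC fraction; windows never wrap, whatever the recorded topology.

.get_seq <- function(genomes, genome = NULL) {
  if (is.character(genomes) && is.null(names(genomes)) && length(genomes) == 1L)
    return(toupper(genomes))
  seqs <- if (is.character(genomes)) genomes else as.character(genomes)
  if (is.null(genome)) {
    if (length(seqs) > 1L) stop("Multiple genomes; pass `genome`")
    genome <- names(seqs)[1]
  }
  if (!genome %in% names(seqs)) stop("Genome '", genome, "' not found")
  toupper(seqs[[genome]])
}

.base_counts <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  c(A = sum(v == "A"), C = sum(v == "C"), G = sum(v == "G"),
    T = sum(v == "T"), N = sum(v == "N"))
}

#' GC fraction of windows tiling a genome
#'
#' Windows of `window` bp are laid every `step` bp from position 0
#' (non-overlapping when `step == window`, the default). A trailing partial
#' window is included and flagged. Windows consisting entirely of `N` get
#' `NA`.
#'
#' @param genomes Genome collection or single sequence string.
#' @param genome Genome id when `genomes` holds several.
#' @param window Window size in bp (default 100).
#' @param step Step between window starts (default `window`).
#' @return `data.table` with columns `start`, `end` (0-based half-open),
#'   `gc_fraction`, `partial`.
#' @export
gc_windows <- function(genomes, genome = NULL, window = 100, step = window) {
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  seq <- .get_seq(genomes, genome)
  len <- nchar(seq)
  if (window > len) {
    warning("Window (", window, " bp) exceeds genome length (", len,
            " bp); using a single whole-genome window")
    window <- len
  }
  starts <- seq.int(0L, len - 1L, by = step)
  starts <- starts[starts < len]
  ends <- pmin(starts + window, len)
  v <- strsplit(seq, "")[[1]]
  is_gc <- v %in% c("G", "C")
  is_n <- v == "N"
  cum_gc <- c(0L, cumsum(is_gc))
  cum_n <- c(0L, cumsum(is_n))
  gc <- (cum_gc[ends + 1L] - cum_gc[starts + 1L])
  nn <- (cum_n[ends + 1L] - cum_n[starts + 1L])
  denom <- (ends - starts) - nn
  frac <- ifelse(denom > 0L, gc / denom, NA_real_)
  data.table(start = starts, end = ends, gc_fraction = frac,
             partial = (ends - starts) < window)
}

#' Base composition of a genome or region
#'
#' Per-base fractions over non-`N` positions and the GC fraction.
#'
#' @inheritParams gc_windows
#' @param start,end Optional 0-based half-open region bounds (default: whole
#'   sequence).
#' @return List with `start`, `end`, `length_bp`, `n_excluded` (N count),
#'   `fraction` (named numeric A/C/G/T), `gc_fraction`.
#' @export
base_composition <- function(genomes, genome = NULL, start = NULL, end = NULL) {
  seq <- .get_seq(genomes, genome)
  len <- nchar(seq)
  if (is.null(start)) start <- 0L
  if (is.null(end)) end <- len
  if (start < 0L || end > len || start >= end)
    stop("Empty or out-of-bounds region [", start, ",", end, ")")
  sub <- substr(seq, start + 1L, end)
  bc <- .base_counts(sub)
  tot <- sum(bc[c("A", "C", "G", "T")])
  if (tot == 0L) stop("Region contains no determinate bases")
  frac <- bc[c("A", "C", "G", "T")] / tot
  list(start = start, end = end, length_bp = end - start,
       n_excluded = unname(bc["N"]),
       fraction = frac,
       gc_fraction = unname(frac["G"] + frac["C"]))
}

#' Intergenic (non-coding) regions of a genome
#'
#' Maximal gaps in the union of all annotated gene intervals (every feature
#' kind counts as covered), clipped to `[0, length)` and filtered by a
#' minimum length. Each region is returned with its base composition and the
#' deviation of its GC and per-base fractions from the whole genome.
#'
#' @inheritParams gc_windows
#' @param features Feature table for the genome.
#' @param min_len Minimum region length in bp (default 200, so sub-gene
#'   micro-gaps are suppressed while genuine non-coding islands pass).
#' @return `data.table`: `start`, `end`, `length_bp`, `a`, `c`, `g`, `t`,
#'   `gc_fraction`, `gc_genome`, `delta_gc`, `delta_t`.
#' @export
intergenic_regions <- function(genomes, features, genome = NULL,
                               min_len = 200) {
  seq <- .get_seq(genomes, genome)
  len <- nchar(seq)
  feats <- as.data.table(features)
  if (!is.null(genome)) feats <- feats[genome_id == genome]
  if (nrow(feats) > 0L) {
    ir <- IRanges::reduce(IRanges::IRanges(start = pmax(feats$start, 0L) + 1L,
                                           end = pmin(feats$end, len)))
    gaps <- IRanges::gaps(ir, start = 1L, end = len)
  } else {
    gaps <- IRanges::IRanges(start = 1L, end = len)
  }
  gs <- IRanges::start(gaps) - 1L
  ge <- IRanges::end(gaps)
  keep <- (ge - gs) >= min_len
  gs <- gs[keep]; ge <- ge[keep]
  whole <- base_composition(seq)
  rows <- lapply(seq_along(gs), function(i) {
    comp <- base_composition(seq, start = gs[i], end = ge[i])
    data.table(start = gs[i], end = ge[i], length_bp = ge[i] - gs[i],
               a = comp$fraction[["A"]], c = comp$fraction[["C"]],
               g = comp$fraction[["G"]], t = comp$fraction[["T"]],
               gc_fraction = comp$gc_fraction,
               gc_genome = whole$gc_fraction,
               delta_gc = comp$gc_fraction - whole$gc_fraction,
               delta_t = comp$fraction[["T"]] - whole$fraction[["T"]])
  })
  if (length(rows) == 0L)
    return(data.table(start = integer(), end = integer(),
                      length_bp = integer(), a = numeric(), c = numeric(),
                      g = numeric(), t = numeric(), gc_fraction = numeric(),
                      gc_genome = numeric(), delta_gc = numeric(),
                      delta_t = numeric()))
  rbindlist(rows)
}

#' Genomic feature summary
#'
#' Length, integer-rounded GC percentage, number of CDS and of tRNA genes —
#' the per-genome overview row.
#'
#' @inheritParams intergenic_regions
#' @return List with `genome_id`, `length_bp`, `gc_percent` (integer),
#'   `gc_fraction` (raw), `n_genes`, `n_trna`.
#' @export
genome_summary <- function(genomes, features, genome = NULL) {
  seq <- .get_seq(genomes, genome)
  feats <- as.data.table(features)
  if (!is.null(genome)) feats <- feats[genome_id == genome]
  comp <- base_composition(seq)
  gid <- if (!is.null(genome)) genome
         else if (nrow(feats)) unique(feats$genome_id)[1]
         else NA_character_
  list(genome_id = gid,
       length_bp = nchar(seq),
       gc_percent = as.integer(round(100 * comp$gc_fraction)),
       gc_fraction = comp$gc_fraction,
       n_genes = sum(feats$kind == "CDS"),
       n_trna = sum(feats$kind == "tRNA"))
}

#' Write GC-scan outputs
#'
#' Window profile as BED-like TSV (0-based half-open), genome summary TSV
#' and intergenic-region TSV.
#'
#' @param genomes Genome collection.
#' @param features Feature table.
#' @param dir Output directory.
#' @param window,min_len Passed through to [gc_windows()] and
#'   [intergenic_regions()].
#' @return Named vector of files written, invisibly.
#' @export
write_gc_report <- function(genomes, features, dir, window = 100,
                            min_len = 200) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(genome_lengths(genomes))
  win <- rbindlist(lapply(ids, function(g) {
    w <- gc_windows(genomes, genome = g, window = window)
    data.table(chrom = g, w)
  }))
  f1 <- file.path(dir, "gc_windows.tsv")
  fwrite(win, f1, sep = "\t")
  summ <- rbindlist(lapply(ids, function(g) {
    s <- genome_summary(genomes, features, genome = g)
    as.data.table(s[c("genome_id", "length_bp", "gc_percent", "n_genes",
                      "n_trna")])
  }))
  f2 <- file.path(dir, "genome_summary.tsv")
  fwrite(summ, f2, sep = "\t")
  reg <- rbindlist(lapply(ids, function(g) {
    r <- intergenic_regions(genomes, features, genome = g, min_len = min_len)
    if (nrow(r)) data.table(chrom = g, r) else NULL
  }))
  f3 <- file.path(dir, "intergenic_regions.tsv")
  if (is.null(reg) || nrow(reg) == 0L) reg <- data.table(chrom = character())
  fwrite(reg, f3, sep = "\t")
  invisible(c(windows = f1, summary = f2, regions = f3))
}
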