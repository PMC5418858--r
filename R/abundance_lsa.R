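# Genome-size-normalized relative abundance and local similarity analysis
# (LSA): rank → normal-score transform, delay-bounded dynamic programming
# for the maximal local co-variation, permutation significance.

#' Read a per-sample read-count table
#'
#' TSV with header `sample_id`, `time_index`, `total_reads`, `target_id`,
#' `mapped_reads` (long format; one row per sample × target).
#'
#' @param path Path to the TSV.
#' @return A validated `data.table`.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("Counts table not found: ", path)
  tab <- fread(path, sep = "\t", header = TRUE)
  need <- c("sample_id", "time_index", "total_reads", "target_id",
            "mapped_reads")
  if (!all(need %in% names(tab)))
    stop("Counts table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$mapped_reads < 0) || any(tab$mapped_reads > tab$total_reads))
    stop("mapped_reads must satisfy 0 <= m <= total_reads")
  tab
}

#' Genome-size-normalized relative abundance (percent)
#'
#' `RA% = 100 * (m / T) / (L / 1000)` — the percentage of sample reads
#' mapped to the target, per kilobase of target genome. Dividing by genome
#' length makes phage and host abundances comparable despite their ~100-fold
#' size difference; any common monotone convention serves the downstream
#' rank-based analysis.
#'
#' @param m Mapped read count(s).
#' @param total Total reads in the sample (> 0).
#' @param length_bp Target genome length in bp (> 0).
#' @return Relative abundance in percent (vectorized).
#' @export
relative_abundance <- function(m, total, length_bp) {
  if (any(total <= 0)) stop("total reads must be > 0")
  if (any(length_bp <= 0)) stop("genome length must be > 0")
  if (any(m < 0) || any(m > total)) stop("need 0 <= m <= total")
  100 * (m / total) / (length_bp / 1000)
}

#' Relative-abundance series for each target
#'
#' @param counts Count table ([read_counts_table()]).
#' @param genome_lengths Named vector of genome lengths in bp, one per
#'   target id present in `counts`.
#' @return `data.table` with `target_id`, `time_index`, `sample_id`,
#'   `abundance` (percent), ordered by target then time.
#' @export
abundance_series <- function(counts, genome_lengths) {
  tabs <- as.data.table(counts)
  miss <- setdiff(unique(tabs$target_id), names(genome_lengths))
  if (length(miss))
    stop("No genome length for target(s): ", paste(miss, collapse = ", "))
  out <- tabs[, .(sample_id, time_index, target_id,
                  abundance = relative_abundance(
                    mapped_reads, total_reads,
                    as.numeric(genome_lengths[target_id])))]
  setorder(out, target_id, time_index)
  out
}

.normal_scores <- function(x) {
  n <- length(x)
  stats::qnorm(rank(x, ties.method = "average") / (n + 1))
}

# Maximal positive and maximal negative local alignment score over lags
# |d| <= D: for each lag, the maximum-magnitude contiguous partial sum of
# pointwise products (prefix-sum formulation of Kadane's algorithm).
.ls_core <- function(zx, zy, max_delay) {
  n <- length(zx)
  best <- -Inf; best_delay <- 0L; best_sign <- 1
  for (d in -max_delay:max_delay) {
    if (d >= 0) { p <- zx[seq_len(n - d)] * zy[seq_len(n - d) + d] }
    else        { p <- zx[seq_len(n + d) - d] * zy[seq_len(n + d)] }
    cs <- cumsum(p)
    lo <- cummin(c(0, cs[-length(cs)]))
    hi <- cummax(c(0, cs[-length(cs)]))
    mp <- max(cs - lo)           # best positive association on this lag
    mn <- min(cs - hi)           # best negative association
    if (mp > best) { best <- mp; best_delay <- d; best_sign <- 1 }
    if (-mn > best) { best <- -mn; best_delay <- d; best_sign <- -1 }
  }
  list(score = max(best, 0) / n, delay = best_delay, sign = best_sign)
}

.ls_score_only <- function(zx, zy, max_delay) {
  n <- length(zx)
  best <- 0
  for (d in -max_delay:max_delay) {
    if (d >= 0) { p <- zx[seq_len(n - d)] * zy[seq_len(n - d) + d] }
    else        { p <- zx[seq_len(n + d) - d] * zy[seq_len(n + d)] }
    cs <- cumsum(p)
    lo <- cummin(c(0, cs[-length(cs)]))
    hi <- cummax(c(0, cs[-length(cs)]))
    best <- max(best, cs - lo, hi - cs)
  }
  best / n
}

.prepare_series <- function(x, label) {
  if (mean(is.na(x)) > 0.25)
    stop("Series '", label, "' has more than 25% missing values")
  if (anyNA(x)) {
    warning("Series '", label, "' has missing values; linear interpolation applied")
    idx <- seq_along(x)
    x <- stats::approx(idx[!is.na(x)], x[!is.na(x)], xout = idx,
                       rule = 2)$y
  }
  if (length(unique(x)) == 1L)
    stop("Series '", label, "' is constant; ranks undefined")
  x
}

#' Local similarity analysis of two time series
#'
#' Both series are rank-transformed to normal scores
#' (`qnorm(rank/(n+1))`). For every lag `d` with `|d| <= max_delay`, dynamic
#' programming finds the contiguous stretch of aligned points with the
#' largest (positive association) or most negative (negative association)
#' sum of score products; the local similarity score is that maximum divided
#' by the series length. Significance is assessed by permuting one series
#' `n_perm` times; the p-value uses the add-one estimator
#' `(1 + #[LS_perm >= LS_obs]) / (1 + n_perm)`, so it is never zero.
#'
#' Positive `delay` means `y` lags behind `x` by `delay` steps (x at time
#' `t` aligns with y at `t + delay`).
#'
#' @param x,y Numeric series of equal length `n >= 4`, sampled on the same
#'   time grid. Up to 25% missing values are linearly interpolated (with a
#'   warning); constant series are an error.
#' @param max_delay Maximum |lag| scanned (default 3).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation null (required).
#' @return Object of class `lsa_result`: list with `ls_score`, `sign`
#'   (`"+"`/`"-"`), `delay`, `p_value`, `n_perm`, `seed`, `n`.
#' @export
local_similarity <- function(x, y, max_delay = 3, n_perm = 1000, seed) {
  if (length(x) != length(y)) stop("Series must have equal length")
  n <- length(x)
  if (n < 4L) stop("Need series length >= 4")
  if (missing(seed) || is.null(seed)) stop("A permutation seed is required")
  max_delay <- as.integer(max_delay)
  if (max_delay < 0L || max_delay >= n) stop("max_delay must be in [0, n)")
  x <- .prepare_series(x, "x")
  y <- .prepare_series(y, "y")
  zx <- .normal_scores(x)
  zy <- .normal_scores(y)
  obs <- .ls_core(zx, zy, max_delay)
  # permute a canonically chosen member of the pair so that the p-value is
  # identical whichever way the arguments are ordered
  d <- zx - zy
  first_diff <- which(d != 0)[1]
  if (!is.na(first_diff) && d[first_diff] > 0) {
    fixed <- zy; permuted <- zx
  } else {
    fixed <- zx; permuted <- zy
  }
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (.ls_score_only(fixed, sample(permuted), max_delay) >= obs$score)
      exceed <- exceed + 1L
  }
  structure(list(ls_score = obs$score,
                 sign = if (obs$sign >= 0) "+" else "-",
                 delay = obs$delay,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, seed = seed, n = n),
            class = "lsa_result")
}

#' @export
print.lsa_result <- function(x, ...) {
  cat(sprintf("LS = %.3f (%s), delay = %d, p = %.4g (%d permutations, n = %d)\n",
              x$ls_score, x$sign, x$delay, x$p_value, x$n_perm, x$n))
  invisible(x)
}

#' Phage–host local similarity report
#'
#' Runs [local_similarity()] between the host abundance series and each
#' phage abundance series over an identical time grid.
#'
#' @param abund Abundance table ([abundance_series()]).
#' @param phage_ids Character vector of phage target ids.
#' @param host_id Host target id.
#' @param max_delay,n_perm,seed Passed to [local_similarity()]; each pair
#'   uses a sub-seed derived deterministically from `seed`.
#' @return `data.table`: `phage_id`, `host_id`, `ls_score`, `sign`, `delay`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
phage_host_report <- function(abund, phage_ids, host_id, max_delay = 3,
                              n_perm = 1000, seed) {
  ab <- as.data.table(abund)
  grid <- function(id) ab[target_id == id][order(time_index)]
  host <- grid(host_id)
  if (nrow(host) == 0L) stop("Host series '", host_id, "' not found")
  rows <- lapply(seq_along(phage_ids), function(i) {
    ph <- grid(phage_ids[i])
    if (!identical(ph$time_index, host$time_index))
      stop("Time grids differ between '", host_id, "' and '", phage_ids[i], "'")
    sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
    r <- local_similarity(host$abundance, ph$abundance,
                          max_delay = max_delay, n_perm = n_perm,
                          seed = sub_seed)
    data.table(phage_id = phage_ids[i], host_id = host_id,
               ls_score = r$ls_score, sign = r$sign, delay = r$delay,
               p_value = r$p_value, n_perm = r$n_perm, seed = r$seed)
  })
  rbindlist(rows)
}

#' Per-sample functional-category percentages
#'
#' Distributes each sample's per-gene transcript counts over functional
#' categories and reports percentages of the total assigned to genes of
#' known function; the `"unknown"` category is excluded from the
#' denominator. Samples where every counted gene is of unknown function (or
#' all counts are zero) get `NA` for all categories, with a warning.
#'
#' @param gene_counts `data.table` with `gene_id`, `sample_id`, `count`.
#' @param categories `data.table` with `gene_id`, `category` (label
#'   `"unknown"` for unannotated genes).
#' @return `data.table`: `sample_id`, `category`, `percent`.
#' @export
functional_profile <- function(gene_counts, categories) {
  gc_ <- merge(as.data.table(gene_counts), as.data.table(categories),
               by = "gene_id", all.x = TRUE)
  if (anyNA(gc_$category))
    stop("Every gene needs a category (use 'unknown' for unannotated genes)")
  known <- gc_[category != "unknown"]
  cats <- sort(unique(known$category))
  samples <- unique(gc_$sample_id)
  rows <- lapply(samples, function(s) {
    sub <- known[sample_id == s]
    tot <- sum(sub$count)
    if (tot == 0) {
      warning("Sample '", s, "' has no known-function counts; NA profile")
      return(data.table(sample_id = s, category = cats,
                        percent = NA_real_))
    }
    agg <- sub[, .(count = sum(count)), by = category]
    pct <- stats::setNames(rep(0, length(cats)), cats)
    pct[agg$category] <- 100 * agg$count / tot
    data.table(sample_id = s, category = cats, percent = unname(pct))
  })
  rbindlist(rows)
}
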