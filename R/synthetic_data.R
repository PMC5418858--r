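# Seeded generators emitting exactly the formats the pipeline consumes
# (FASTA, GFF3, ortholog TSV, counts TSV) plus machine-readable truth
# files, so every stage is testable without external downloads.

.rand_cds <- function(n_codons) {
  sense <- names(genetic_code()$code)[genetic_code()$code != "*" &
                                      genetic_code()$code != "M"]
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         "TAA")
}

#' Generate a genome set with planted ortholog-sharing structure
#'
#' Builds `n_clusters` disjoint clusters of genomes. Every genome of a
#' cluster carries one gene for each of the cluster's core ortholog groups
#' plus its own private accessory OGs; `shared_fraction_within` is the
#' fraction of a genome's assigned OGs that are core, which fixes the
#' within-cluster pairwise Jaccard at roughly `s / (2 - s)`. Clusters share
#' no OGs, so between-cluster Jaccard is 0. The first two genomes of each
#' cluster additionally share one planted pair-exclusive OG, and each
#' genome carries `noise_singletons` genes absent from the ortholog table.
#'
#' @param out_dir Directory to write `genomes.fasta`, `annotations.gff3`,
#'   `orthologs.tsv` and `truth.json` (created if missing).
#' @param n_clusters,genomes_per_cluster Cluster layout (defaults 2 × 5).
#' @param core_ogs_per_cluster Core OGs per cluster (default 15, the size
#'   of a typical phage-cluster core genome).
#' @param shared_fraction_within Fraction of each genome's assigned OGs
#'   that are core (default 0.6 → within-cluster J ≈ 0.43, comfortably
#'   above the 0.1 clustering cutoff).
#' @param noise_singletons Unassigned genes per genome (default 2).
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical files.
#' @param gene_codons Codons per generated gene body (default 60).
#' @return List with the paths written plus the in-memory `genomes`,
#'   `features`, `og_table` and `truth` objects.
#' @export
gen_genome_set <- function(out_dir, n_clusters = 2, genomes_per_cluster = 5,
                           core_ogs_per_cluster = 15,
                           shared_fraction_within = 0.6,
                           noise_singletons = 2, seed, gene_codons = 60) {
  if (missing(seed)) stop("seed is required")
  if (n_clusters < 1 || genomes_per_cluster < 1 || core_ogs_per_cluster < 1)
    stop("Cluster layout parameters must be positive")
  s <- shared_fraction_within
  if (s <= 0 || s > 1)
    stop("Infeasible sharing bounds: shared_fraction_within must be in (0, 1]")
  set.seed(seed)
  n_unique <- max(0L, as.integer(round(core_ogs_per_cluster * (1 - s) / s)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  feats <- list(); ortho <- list(); seqs <- character()
  membership <- list(); core_truth <- list(); excl_truth <- list()
  for (ci in seq_len(n_clusters)) {
    core_ids <- sprintf("og_c%d_core%02d", ci, seq_len(core_ogs_per_cluster))
    excl_id <- sprintf("og_c%d_excl_pair", ci)
    gids <- sprintf("cluster%d_genome%d", ci, seq_len(genomes_per_cluster))
    membership[[ci]] <- gids
    core_truth[[ci]] <- core_ids
    excl_truth[ci] <- list(if (genomes_per_cluster >= 2)
      list(genomes = gids[1:2], ogs = excl_id) else NULL)
    for (gi in seq_len(genomes_per_cluster)) {
      g <- gids[gi]
      uniq_ids <- if (n_unique > 0)
        sprintf("og_c%d_g%d_acc%02d", ci, gi, seq_len(n_unique)) else character()
      gene_ogs <- c(core_ids, uniq_ids,
                    if (gi <= 2 && genomes_per_cluster >= 2) excl_id)
      n_assigned <- length(gene_ogs)
      n_genes <- n_assigned + noise_singletons
      gene_ids <- sprintf("%s_gene%03d", g, seq_len(n_genes))
      gene_seqs <- vapply(seq_len(n_genes),
                          function(i) .rand_cds(gene_codons), character(1))
      spacer <- function() paste(sample(c("A", "C", "G", "T"), 50,
                                        replace = TRUE), collapse = "")
      parts <- character(2 * n_genes + 1)
      starts <- integer(n_genes); ends <- integer(n_genes)
      pos <- 0L
      parts[1] <- spacer(); pos <- pos + 50L
      for (i in seq_len(n_genes)) {
        starts[i] <- pos
        parts[2 * i] <- gene_seqs[i]
        pos <- pos + nchar(gene_seqs[i])
        ends[i] <- pos
        parts[2 * i + 1] <- spacer()
        pos <- pos + 50L
      }
      seqs[[g]] <- paste(parts, collapse = "")
      feats[[g]] <- data.table(
        gene_id = gene_ids, genome_id = g, start = starts, end = ends,
        strand = rep(c("+", "-"), length.out = n_genes), kind = "CDS",
        product = NA_character_, category = NA_character_,
        anticodon = NA_character_)
      ortho[[g]] <- data.table(gene_id = gene_ids[seq_len(n_assigned)],
                               genome_id = g, og_id = gene_ogs)
    }
  }
  features <- rbindlist(feats)
  og_table <- rbindlist(ortho)
  genomes <- Biostrings::DNAStringSet(unlist(seqs))

  f_fa <- file.path(out_dir, "genomes.fasta")
  write_fasta(genomes, f_fa)
  f_gff <- file.path(out_dir, "annotations.gff3")
  write_annotations(features, f_gff)
  f_og <- file.path(out_dir, "orthologs.tsv")
  write_ortholog_table(og_table, f_og)

  sets <- og_sets(features, og_table)
  within_j <- c(); between_j <- c()
  for (ci in seq_len(n_clusters)) {
    g <- membership[[ci]]
    if (length(g) >= 2)
      for (i in seq_len(length(g) - 1)) for (j in (i + 1):length(g))
        within_j <- c(within_j, jaccard(sets[[g[i]]], sets[[g[j]]]))
    if (ci < n_clusters)
      for (cj in (ci + 1):n_clusters)
        for (a in membership[[ci]]) for (b in membership[[cj]])
          between_j <- c(between_j, jaccard(sets[[a]], sets[[b]]))
  }
  truth <- list(
    seed = seed,
    clusters = lapply(seq_len(n_clusters), function(ci) list(
      reference = membership[[ci]][1],
      members = membership[[ci]],
      core_ogs = core_truth[[ci]],
      exclusive = excl_truth[[ci]])),
    min_within_jaccard = if (length(within_j)) min(within_j) else NA,
    max_between_jaccard = if (length(between_j)) max(between_j) else 0)
  f_truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(fasta = f_fa, gff3 = f_gff, orthologs = f_og, truth_file = f_truth,
       genomes = genomes, features = features, og_table = og_table,
       truth = truth)
}

#' Generate coding sequences with a prescribed synonymous usage profile
#'
#' Amino acids are drawn uniformly; each amino acid's codon is drawn from
#' the target synonymous-usage profile. An initiator `ATG` and a single
#' terminal stop (`TAA`) are appended to every gene.
#'
#' @param target_usage Named numeric over sense codons (DNA or RNA names):
#'   synonymous usage per codon, summing to 1 within each amino-acid
#'   family. A family whose codons sum to 0 is an error.
#' @param n_genes Number of CDS to emit.
#' @param mean_length_codons Mean gene-body length in codons (Poisson,
#'   minimum 10).
#' @param seed Integer seed.
#' @param out_fasta,out_gff3 Optional paths; if given, a single-contig
#'   genome (genes concatenated with 30 bp spacers) and its GFF3 are
#'   written.
#' @return List with `cds` (named character vector), and `genomes` /
#'   `features` plus file paths when outputs were requested.
#' @export
gen_cds_biased <- function(target_usage, n_genes, mean_length_codons, seed,
                           out_fasta = NULL, out_gff3 = NULL) {
  if (missing(seed)) stop("seed is required")
  gc <- genetic_code()
  names(target_usage) <- as_dna(toupper(names(target_usage)))
  sense <- names(gc$code)[gc$code != "*"]
  usage <- stats::setNames(rep(0, length(sense)), sense)
  usage[intersect(names(target_usage), sense)] <-
    target_usage[intersect(names(target_usage), sense)]
  aas <- setdiff(unique(gc$code), "*")
  fam <- split(sense, gc$code[sense])
  for (a in aas) {
    tot <- sum(usage[fam[[a]]])
    if (tot <= 0) stop("Zero-sum synonymous family for amino acid ", a)
    if (abs(tot - 1) > 1e-6)
      stop("Usage for amino acid ", a, " sums to ", tot, ", not 1")
  }
  set.seed(seed)
  cds <- character(n_genes)
  for (i in seq_len(n_genes)) {
    len <- max(10L, stats::rpois(1, mean_length_codons))
    aa_seq <- sample(aas, len, replace = TRUE)
    codons <- character(len)
    for (a in unique(aa_seq)) {
      idx <- which(aa_seq == a)
      f <- fam[[a]]
      codons[idx] <- if (length(f) == 1L) f
                     else sample(f, length(idx), replace = TRUE,
                                 prob = usage[f])
    }
    cds[i] <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  }
  names(cds) <- sprintf("synth_gene%04d", seq_len(n_genes))
  out <- list(cds = cds)
  if (!is.null(out_fasta)) {
    spacer <- function() paste(sample(c("A", "C", "G", "T"), 30,
                                      replace = TRUE), collapse = "")
    pos <- 0L; parts <- character(0)
    starts <- integer(n_genes); ends <- integer(n_genes)
    parts <- c(parts, spacer()); pos <- pos + 30L
    for (i in seq_len(n_genes)) {
      starts[i] <- pos
      parts <- c(parts, cds[i]); pos <- pos + nchar(cds[i]); ends[i] <- pos
      parts <- c(parts, spacer()); pos <- pos + 30L
    }
    genome <- Biostrings::DNAStringSet(paste(parts, collapse = ""))
    names(genome) <- "synth_contig"
    write_fasta(genome, out_fasta)
    features <- data.table(
      gene_id = names(cds), genome_id = "synth_contig",
      start = starts, end = ends, strand = "+", kind = "CDS",
      product = NA_character_, category = NA_character_,
      anticodon = NA_character_)
    if (!is.null(out_gff3)) write_annotations(features, out_gff3)
    out$genomes <- genome
    out$features <- features
    out$fasta <- out_fasta
    out$gff3 <- out_gff3
  }
  out
}

#' Generate a coupled host/phage abundance time series
#'
#' The host fluctuates smoothly around its baseline as a mean-reverting
#' AR(1) process (autoregression 0.7, innovation s.d. `0.5 * baseline`),
#' reflected at zero so the series stays positive without tied, clipped
#' stretches — an ecologically sensible stand-in for a population
#' fluctuating about a carrying capacity, and one whose extremes are not
#' concentrated at the series ends (a drifting random walk makes a planted
#' lag nearly unidentifiable, because the lagged alignment must drop an
#' endpoint while the unlagged one keeps every point at high
#' autocorrelation). The phage tracks the host with a time lag:
#' `phage[t] = coupling * host[t - lag] + noise`, likewise reflected at
#' zero. Both latent series are rescaled into a realistic
#' relative-abundance range and converted to integer mapped-read counts
#' under the stated per-sample totals and genome lengths (counts are
#' simulated at the count-table level; read mapping is out of scope).
#'
#' @param out_dir Directory for `counts.tsv` and `timeseries_truth.json`.
#' @param n_points Number of time points (default 20).
#' @param lag Phage delay in steps (default 1); needs `n_points >= lag + 4`.
#' @param coupling Coupling coefficient (default 0.9); 0 gives an
#'   uncoupled pair.
#' @param noise_sd Gaussian noise s.d. on the latent (unit) scale
#'   (default 0.1).
#' @param baseline Latent host baseline (default 1).
#' @param seed Integer seed.
#' @param total_reads Per-sample sequencing depth (default 1e6).
#' @param host_length,phage_length Genome lengths in bp (defaults: a
#'   6.5 Mbp host, a 70 kbp phage).
#' @param max_host_ra Maximum host relative abundance in percent after
#'   rescaling (default 0.01, keeping counts well below the total).
#' @return List with `counts` (`data.table`), `truth`, and the files
#'   written.
#' @export
gen_timeseries <- function(out_dir, n_points = 20, lag = 1, coupling = 0.9,
                           noise_sd = 0.1, baseline = 1, seed,
                           total_reads = 1e6, host_length = 6537648,
                           phage_length = 70000, max_host_ra = 0.01) {
  if (missing(seed)) stop("seed is required")
  if (lag >= n_points) stop("lag must be smaller than n_points")
  if (n_points < lag + 4) stop("Need n_points >= lag + 4")
  set.seed(seed)
  ar_coef <- 0.7
  innov_sd <- 0.5 * baseline
  u <- numeric(n_points)
  u[1] <- stats::rnorm(1, sd = innov_sd / sqrt(1 - ar_coef^2))
  for (t in seq_len(n_points)[-1])
    u[t] <- ar_coef * u[t - 1] + stats::rnorm(1, sd = innov_sd)
  host <- abs(baseline + u)
  lagged <- if (lag > 0)
    c(rep(host[1], lag), host[seq_len(n_points - lag)]) else host
  phage <- abs(coupling * lagged + stats::rnorm(n_points, sd = noise_sd))
  scale <- max_host_ra / max(host)
  ra_host <- host * scale
  ra_phage <- phage * scale
  ra_to_m <- function(ra, L) {
    m <- round(ra / 100 * total_reads * L / 1000)
    pmin(pmax(m, 0), total_reads)
  }
  counts <- rbindlist(list(
    data.table(sample_id = sprintf("S%02d", seq_len(n_points)),
               time_index = seq_len(n_points), total_reads = total_reads,
               target_id = "host",
               mapped_reads = ra_to_m(ra_host, host_length)),
    data.table(sample_id = sprintf("S%02d", seq_len(n_points)),
               time_index = seq_len(n_points), total_reads = total_reads,
               target_id = "phage",
               mapped_reads = ra_to_m(ra_phage, phage_length))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f_counts <- file.path(out_dir, "counts.tsv")
  fwrite(counts, f_counts, sep = "\t")
  truth <- list(seed = seed, lag = lag, coupling = coupling,
                noise_sd = noise_sd, n_points = n_points,
                host_length = host_length, phage_length = phage_length,
                total_reads = total_reads,
                latent_host = host, latent_phage = phage)
  f_truth <- file.path(out_dir, "timeseries_truth.json")
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(counts = counts, truth = truth, counts_file = f_counts,
       truth_file = f_truth)
}
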