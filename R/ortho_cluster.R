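# Gene-sharing similarity and reference-anchored clustering over
# ortholog-group sets, with conservation / core / exclusive queries.

#' Ortholog-group set of one genome
#'
#' Collapses a genome's genes to the set of ortholog-group identifiers they
#' belong to. Paralogs (several genes in one OG) contribute a single set
#' element. Genes absent from the ortholog table are, by default, given
#' unique `singleton:<gene_id>` identifiers so that unshared gene content
#' still inflates the union of the Jaccard index.
#'
#' @param features Feature table of the genome (only `kind == "CDS"` rows are
#'   used).
#' @param og_table Ortholog assignment table ([read_ortholog_table()]).
#' @param genome Genome id; defaults to the single genome present in
#'   `features`.
#' @param include_singletons Give unassigned genes singleton OG ids
#'   (default `TRUE`).
#' @return Character vector of OG identifiers (a set).
#' @export
og_set <- function(features, og_table, genome = NULL,
                   include_singletons = TRUE) {
  feats <- as.data.table(features)[kind == "CDS"]
  if (is.null(genome)) {
    gids <- unique(feats$genome_id)
    if (length(gids) > 1L)
      stop("Multiple genomes in features; pass `genome`")
    genome <- gids
  }
  feats <- feats[genome_id == genome]
  if (nrow(feats) == 0L) {
    warning("Genome '", genome, "' has no CDS features; empty OG set")
    return(character())
  }
  assigned <- og_table[gene_id %in% feats$gene_id]
  ogs <- unique(assigned$og_id)
  if (include_singletons) {
    missing <- setdiff(feats$gene_id, assigned$gene_id)
    ogs <- c(ogs, paste0("singleton:", missing, recycle0 = TRUE))
  }
  ogs
}

#' Ortholog-group sets for every genome in a feature table
#'
#' @inheritParams og_set
#' @return Named list of character vectors, one per genome.
#' @export
og_sets <- function(features, og_table, include_singletons = TRUE) {
  gids <- unique(as.data.table(features)$genome_id)
  stats::setNames(
    lapply(gids, function(g) og_set(features, og_table, genome = g,
                                    include_singletons = include_singletons)),
    gids)
}

#' Jaccard index of two sets
#'
#' `J(A,B) = |A ∩ B| / |A ∪ B|`, the gene-sharing similarity of two genomes
#' when applied to their ortholog-group sets. Defined as 0 when both sets
#' are empty.
#'
#' @param a,b Character vectors treated as sets.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(a) + length(b) - length(intersect(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Full pairwise Jaccard matrix
#'
#' @param sets Named list of OG sets ([og_sets()]).
#' @return Symmetric numeric matrix of Jaccard indices.
#' @export
pairwise_jaccard <- function(sets) {
  n <- length(sets)
  m <- matrix(1, n, n, dimnames = list(names(sets), names(sets)))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- jaccard(sets[[i]], sets[[j]])
  }
  diag(m) <- vapply(sets, function(s) if (length(s)) 1 else 0, numeric(1))
  m
}

#' Reference-anchored gene-sharing cluster
#'
#' Groups genomes whose Jaccard similarity to a chosen reference genome is at
#' least `cutoff` (boundary included). No transitive closure is applied: the
#' cluster is exactly the reference's neighbourhood.
#'
#' @param reference_id Genome id of the reference; must be in `sets`.
#' @param sets Named list of OG sets ([og_sets()]).
#' @param cutoff Minimum `J(ref, X)` for membership (default 0.1).
#' @return An object of class `phage_cluster`: list with `reference_id`,
#'   `cutoff`, and `members`, a `data.table` (`genome_id`, `jaccard_index`)
#'   sorted by similarity descending then genome id.
#' @export
build_cluster <- function(reference_id, sets, cutoff = 0.1) {
  if (!reference_id %in% names(sets))
    stop("Reference genome '", reference_id, "' not among candidates")
  ref <- sets[[reference_id]]
  j <- vapply(sets, function(s) jaccard(ref, s), numeric(1))
  members <- data.table(genome_id = names(sets), jaccard_index = j)
  members <- members[jaccard_index >= cutoff]
  setorder(members, -jaccard_index, genome_id)
  structure(list(reference_id = reference_id, cutoff = cutoff,
                 members = members),
            class = "phage_cluster")
}

#' @export
print.phage_cluster <- function(x, ...) {
  cat(sprintf("Gene-sharing cluster anchored at '%s' (J >= %g): %d member(s)\n",
              x$reference_id, x$cutoff, nrow(x$members)))
  print(x$members)
  invisible(x)
}

.cluster_gene_og <- function(cluster, features, og_table,
                             include_singletons = TRUE) {
  feats <- as.data.table(features)[kind == "CDS" &
                                   genome_id %in% cluster$members$genome_id]
  tab <- merge(feats[, .(gene_id, genome_id)],
               og_table[, .(gene_id, og_id)],
               by = "gene_id", all.x = TRUE)
  if (include_singletons) {
    tab[is.na(og_id), og_id := paste0("singleton:", gene_id)]
  } else {
    tab <- tab[!is.na(og_id)]
  }
  tab
}

#' Ortholog-group conservation across a cluster
#'
#' For each ortholog group found in the cluster, counts member genes
#' (`n_genes`) and distinct member genomes containing at least one gene
#' (`n_genomes`). Sorted by `n_genomes` then `n_genes` descending, ties by
#' OG id — the "most conserved ortholog groups" ranking.
#'
#' @param cluster A `phage_cluster` ([build_cluster()]).
#' @param features Feature table covering the cluster members.
#' @param og_table Ortholog assignment table.
#' @param include_singletons Count unassigned genes as singleton OGs
#'   (default `TRUE`, so gene totals are conserved).
#' @return `data.table` with columns `og_id`, `n_genes`, `n_genomes`.
#' @export
conservation_table <- function(cluster, features, og_table,
                               include_singletons = TRUE) {
  tab <- .cluster_gene_og(cluster, features, og_table, include_singletons)
  out <- tab[, .(n_genes = .N,
                 n_genomes = data.table::uniqueN(genome_id)), by = og_id]
  setorder(out, -n_genomes, -n_genes, og_id)
  out
}

#' Core ortholog groups of a cluster
#'
#' Ortholog groups present in every member genome of the cluster.
#'
#' @inheritParams conservation_table
#' @return Character vector of OG ids.
#' @export
core_ogs <- function(cluster, features, og_table) {
  if (nrow(cluster$members) == 0L) stop("Cluster has no members")
  cons <- conservation_table(cluster, features, og_table,
                             include_singletons = TRUE)
  cons[n_genomes == nrow(cluster$members), og_id]
}

#' Ortholog groups exclusive to a genome subset
#'
#' Groups present in every genome of `subset` and in no other cluster
#' member. With `subset` equal to the whole cluster this is the core.
#'
#' @param subset Character vector of genome ids, all cluster members.
#' @inheritParams conservation_table
#' @return Character vector of OG ids.
#' @export
exclusive_ogs <- function(subset, cluster, features, og_table) {
  members <- cluster$members$genome_id
  if (!all(subset %in% members))
    stop("Subset genomes not all in cluster: ",
         paste(setdiff(subset, members), collapse = ", "))
  tab <- .cluster_gene_og(cluster, features, og_table,
                          include_singletons = TRUE)
  per_og <- tab[, .(genomes = list(unique(genome_id))), by = og_id]
  keep <- vapply(per_og$genomes, function(g) {
    all(subset %in% g) && length(setdiff(g, subset)) == 0L
  }, logical(1))
  sort(per_og$og_id[keep])
}

#' Write cluster reports to TSV
#'
#' Writes the member list (`genome_id`, `jaccard_index`) and the
#' conservation table (`og_id`, `n_genes`, `n_genomes`).
#'
#' @param cluster A `phage_cluster`.
#' @param features,og_table As in [conservation_table()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cluster_report <- function(cluster, features, og_table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, "cluster_members.tsv")
  fwrite(cluster$members, f1, sep = "\t")
  f2 <- file.path(dir, "og_conservation.tsv")
  fwrite(conservation_table(cluster, features, og_table), f2, sep = "\t")
  f3 <- file.path(dir, "core_ogs.tsv")
  fwrite(data.table(og_id = core_ogs(cluster, features, og_table)), f3,
         sep = "\t")
  invisible(c(members = f1, conservation = f2, core = f3))
}
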