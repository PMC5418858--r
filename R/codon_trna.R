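# Synonymous codon-usage statistics, the random-usage baseline, tRNA
# anticodon complements and target-codon gene ranking. Codons are held
# internally in the DNA alphabet and displayed in RNA (UUA etc.).

#' The genetic code used for codon-usage analysis
#'
#' Bacterial/archaeal code (translation table 11); identical in codon→amino
#' acid assignments to the standard code, so AUG is methionine with a
#' synonymous family of size 1. No special handling of initiator codons.
#'
#' @return List with `code` (named character: DNA codon → one-letter amino
#'   acid, `*` for stop) and `family_size` (named integer per amino acid,
#'   stops excluded).
#' @export
genetic_code <- function() {
  code <- Biostrings::getGeneticCode("11")
  fam <- table(code[code != "*"])
  list(code = code,
       family_size = stats::setNames(as.integer(fam), names(fam)))
}

#' Convert codons between DNA and RNA alphabets
#' @param x Character vector of codons.
#' @return `as_rna`: RNA form (T→U); `as_dna`: DNA form (U→T).
#' @export
as_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("Uu", "Tt", x)

#' Truncate values to a number of decimals (no rounding)
#'
#' Tabular codon-usage reports truncate fractions, so 1/6 prints as 0.166.
#'
#' @param x Numeric vector.
#' @param digits Decimals kept (default 3).
#' @return Truncated numeric vector.
#' @export
truncate_digits <- function(x, digits = 3) {
  f <- 10^digits
  trunc(x * f) / f
}

#' Aggregate codon counts over a set of coding sequences
#'
#' CDS whose length is not a multiple of 3 are skipped with a warning. A
#' terminal stop codon is excluded from the counts; internal stop codons are
#' counted but flagged (pseudogenes and annotation slips occur).
#'
#' @param cds Character vector of CDS nucleotide strings (DNA or RNA
#'   alphabet), optionally named by gene id.
#' @param source_id Label for the profile (e.g. a genome id).
#' @return Object of class `codon_profile`: list with `source_id`, `counts`
#'   (named integer over the 64 DNA codons), `n_cds`, `n_skipped`,
#'   `n_internal_stops`.
#' @export
codon_counts <- function(cds, source_id = "cds_set") {
  if (length(cds) == 0L) stop("Empty CDS set")
  cds <- as_dna(toupper(cds))
  code <- genetic_code()$code
  all_codons <- names(code)
  counts <- stats::setNames(integer(64), all_codons)
  n_skipped <- 0L
  n_internal <- 0L
  n_used <- 0L
  for (s in cds) {
    if (nchar(s) %% 3 != 0L || nchar(s) == 0L) { n_skipped <- n_skipped + 1L; next }
    cod <- .split_codons(s)
    last <- cod[length(cod)]
    if (last %in% all_codons && code[last] == "*") cod <- cod[-length(cod)]
    cod <- cod[cod %in% all_codons]          # codons containing N are ignored
    n_internal <- n_internal + sum(code[cod] == "*")
    tb <- table(cod)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    n_used <- n_used + 1L
  }
  if (n_skipped > 0L)
    warning(n_skipped, " CDS with length not divisible by 3 were skipped")
  if (n_internal > 0L)
    warning(n_internal, " internal stop codon(s) found (counted, flagged)")
  structure(list(source_id = source_id, counts = counts, n_cds = n_used,
                 n_skipped = n_skipped, n_internal_stops = n_internal),
            class = "codon_profile")
}

.split_codons <- function(s) {
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

#' Per-gene codon counts
#'
#' @inheritParams codon_counts
#' @return Named list of `codon_profile` objects, one per input CDS.
#' @export
codon_counts_by_gene <- function(cds) {
  if (is.null(names(cds))) names(cds) <- paste0("gene", seq_along(cds))
  stats::setNames(
    lapply(seq_along(cds), function(i)
      suppressWarnings(codon_counts(cds[i], source_id = names(cds)[i]))),
    names(cds))
}

#' Synonymous codon usage
#'
#' For each sense codon, the fraction its count contributes among all codons
#' of the same amino acid. Families with zero total count get `NA` (usage
#' undefined). Stop codons are excluded.
#'
#' @param profile A `codon_profile` ([codon_counts()]) or a named count
#'   vector over DNA codons.
#' @return Named numeric vector over the 61 sense codons (DNA names).
#' @export
synonymous_usage <- function(profile) {
  counts <- if (inherits(profile, "codon_profile")) profile$counts else profile
  gc <- genetic_code()
  sense <- names(gc$code)[gc$code != "*"]
  aa <- gc$code[sense]
  fam_tot <- tapply(as.numeric(counts[sense]), aa, sum)
  usage <- as.numeric(counts[sense]) / as.numeric(fam_tot[aa])
  usage[fam_tot[aa] == 0] <- NA_real_
  stats::setNames(usage, sense)
}

#' Random-usage baseline
#'
#' The synonymous usage expected with no bias: `1/k` for an amino acid with
#' `k` synonymous codons (1 for Met/Trp, 0.5 for two-codon families, 0.25
#' for four, 1/6 for Leu/Ser/Arg).
#'
#' @return Named numeric vector over the 61 sense codons (DNA names).
#' @export
random_usage <- function() {
  gc <- genetic_code()
  sense <- names(gc$code)[gc$code != "*"]
  stats::setNames(1 / gc$family_size[gc$code[sense]], sense)
}

#' tRNA anticodon complement of a genome
#'
#' Collects the anticodons of annotated tRNA genes and the codon each one
#' decodes under strict Watson–Crick pairing (the reverse complement of the
#' anticodon; wobble is not modelled). Anticodons are taken from the
#' feature's `anticodon` attribute or parsed from product text such as
#' `"tRNA-Pro(ugg)"`; features with neither are reported as undetermined —
#' the pseudo-tRNA case.
#'
#' @param features Feature table; only `kind == "tRNA"` rows are used.
#' @param source_id Label (defaults to the genome id of the tRNAs).
#' @return Object of class `trna_complement`: list with `source_id`, `table`
#'   (`data.table`: `gene_id`, `anticodon` RNA, `decoded_codon` RNA,
#'   `amino_acid`), `n_undetermined`, `n_amino_acids`.
#' @export
trna_complement <- function(features, source_id = NULL) {
  tr <- as.data.table(features)[kind == "tRNA"]
  if (is.null(source_id))
    source_id <- if (nrow(tr)) unique(tr$genome_id)[1] else "trna_set"
  code <- genetic_code()$code
  ac <- toupper(tr$anticodon)
  from_prod <- toupper(sub(".*\\(([ACGUTacgut]{3})\\).*", "\\1",
                           ifelse(is.na(tr$product), "", tr$product)))
  from_prod[!grepl("^[ACGUT]{3}$", from_prod)] <- NA_character_
  ac[is.na(ac) | !grepl("^[ACGUT]{3}$", ac)] <-
    from_prod[is.na(ac) | !grepl("^[ACGUT]{3}$", ac)]
  det <- !is.na(ac)
  tab <- data.table(gene_id = tr$gene_id[det],
                    anticodon = as_rna(ac[det]))
  if (nrow(tab)) {
    dec_dna <- vapply(as_dna(tab$anticodon), revcomp, character(1))
    tab[, decoded_codon := as_rna(dec_dna)]
    tab[, amino_acid := unname(code[dec_dna])]
  } else {
    tab[, `:=`(decoded_codon = character(), amino_acid = character())]
  }
  structure(list(source_id = source_id, table = tab,
                 n_undetermined = sum(!det),
                 n_amino_acids = length(unique(tab$amino_acid))),
            class = "trna_complement")
}

#' @export
print.trna_complement <- function(x, ...) {
  cat(sprintf("tRNA complement of '%s': %d determined (%d amino acids), %d undetermined\n",
              x$source_id, nrow(x$table), x$n_amino_acids, x$n_undetermined))
  print(x$table)
  invisible(x)
}

#' Rarity report for codons decoded by phage tRNAs
#'
#' For every codon decoded by a tRNA carried on the phage genome, compares
#' the host's synonymous usage with the random baseline. A codon is flagged
#' `rare_host` when host usage is strictly below the baseline — the pattern
#' of phages recruiting tRNAs for codons their host rarely uses. Codons not
#' rare in the host (e.g. asparagine/methionine exceptions) appear with
#' `rare_host = FALSE`. If the host tRNA complement is supplied, codons with
#' no host tRNA decoding them are flagged `host_trna_absent`.
#'
#' @param phage_profile,host_profile `codon_profile` objects.
#' @param phage_trnas `trna_complement` of the phage.
#' @param host_trnas Optional `trna_complement` of the host.
#' @return `data.table`: `codon` (RNA), `amino_acid`, `n_phage_trnas`,
#'   `n_host_trnas` (NA if unknown), `random_usage`, `phage_usage`,
#'   `host_usage`, `rare_host`, `host_trna_absent`.
#' @export
rare_codon_report <- function(phage_profile, host_profile, phage_trnas,
                              host_trnas = NULL) {
  code <- genetic_code()$code
  pu <- synonymous_usage(phage_profile)
  hu <- synonymous_usage(host_profile)
  ru <- random_usage()
  dec <- phage_trnas$table
  if (nrow(dec) == 0L) stop("Phage tRNA complement has no determined anticodons")
  per <- dec[, .(n_phage_trnas = .N), by = decoded_codon]
  dna <- as_dna(per$decoded_codon)
  n_host <- rep(NA_integer_, nrow(per))
  if (!is.null(host_trnas)) {
    hc <- host_trnas$table[, .N, by = decoded_codon]
    n_host <- hc$N[match(per$decoded_codon, hc$decoded_codon)]
    n_host[is.na(n_host)] <- 0L
  }
  out <- data.table(
    codon = per$decoded_codon,
    amino_acid = unname(code[dna]),
    n_phage_trnas = per$n_phage_trnas,
    n_host_trnas = n_host,
    random_usage = unname(ru[dna]),
    phage_usage = unname(pu[dna]),
    host_usage = unname(hu[dna]),
    rare_host = unname(hu[dna] < ru[dna]))
  out[, host_trna_absent := if (is.null(host_trnas)) NA else n_host_trnas == 0L]
  setorder(out, codon)
  out
}

#' Codon-usage comparison table
#'
#' The tabular report comparing, for each sense codon, phage and host tRNA
#' counts, the random baseline, and phage/host synonymous usage. Usage
#' columns are truncated (not rounded) to 3 decimals, matching the field's
#' reporting convention (1/6 prints as 0.166).
#'
#' @inheritParams rare_codon_report
#' @param codons Optional RNA codon subset to report (default: codons
#'   decoded by phage tRNAs).
#' @return `data.table` with one row per codon.
#' @export
codon_usage_table <- function(phage_profile, host_profile, phage_trnas,
                              host_trnas = NULL, codons = NULL) {
  rep0 <- rare_codon_report(phage_profile, host_profile, phage_trnas,
                            host_trnas)
  if (!is.null(codons)) rep0 <- rep0[codon %in% as_rna(toupper(codons))]
  rep0[, `:=`(random_usage = truncate_digits(random_usage),
              phage_usage = truncate_digits(phage_usage),
              host_usage = truncate_digits(host_usage))]
  rep0
}

#' Rank genes by their content of target codons
#'
#' Scores each gene by the fraction of its codons that fall in a target set
#' (e.g. the codons decoded by phage-encoded tRNAs) and ranks genes by that
#' score — the logic behind finding proteins enriched in phage-tRNA codons.
#' Genes with fewer than `min_codons` codons are excluded (short genes give
#' unstable fractions).
#'
#' @param gene_profiles Named list of `codon_profile` objects
#'   ([codon_counts_by_gene()]).
#' @param target_codons Character vector of codons (RNA or DNA alphabet).
#' @param min_codons Minimum codon count for inclusion (default 30).
#' @return `data.table`: `gene_id`, `n_codons`, `n_target`, `score`, sorted
#'   by score descending, ties broken by gene length then gene id.
#' @export
rank_genes_by_target_codons <- function(gene_profiles, target_codons,
                                        min_codons = 30) {
  if (length(target_codons) == 0L) stop("Empty target codon set")
  tgt <- unique(as_dna(toupper(target_codons)))
  rows <- lapply(names(gene_profiles), function(g) {
    cnt <- gene_profiles[[g]]$counts
    data.table(gene_id = g, n_codons = sum(cnt),
               n_target = sum(cnt[tgt], na.rm = TRUE))
  })
  out <- rbindlist(rows)
  out <- out[n_codons >= min_codons]
  out[, score := n_target / n_codons]
  setorder(out, -score, -n_codons, gene_id)
  out
}
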