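test_that("codon_counts skips bad lengths, drops terminal stops, flags internal stops", {
  p <- codon_counts("ATGAAATAG")
  expect_equal(unname(p$counts[c("ATG", "AAA")]), c(1L, 1L))
  expect_equal(sum(p$counts), 2L)          # stop excluded

  expect_warning(p2 <- codon_counts(c("ATGAAATAG", "ATGAAATA")), "skipped")
  expect_equal(p2$n_cds, 1L)

  p3 <- codon_counts(c("ATGTTATAA", "ATGTTATAA"))
  expect_equal(unname(p3$counts[c("ATG", "TTA")]), c(2L, 2L))

  expect_warning(p4 <- codon_counts("ATGTAAAAATAA"), "internal stop")
  expect_equal(p4$n_internal_stops, 1L)
  expect_error(codon_counts(character()), "Empty")
})

test_that("codon counts are additive over CDS sets", {
  set.seed(3)
  s1 <- replicate(5, paste0("ATG", random_dna(30), "TAA"))
  s2 <- replicate(4, paste0("ATG", random_dna(45), "TAA"))
  c1 <- suppressWarnings(codon_counts(s1))
  c2 <- suppressWarnings(codon_counts(s2))
  c12 <- suppressWarnings(codon_counts(c(s1, s2)))
  expect_equal(c12$counts, c1$counts + c2$counts)
})

test_that("synonymous usage normalizes within amino-acid families", {
  p <- codon_counts("ATGAAATAG")
  u <- synonymous_usage(p)
  expect_equal(unname(u["ATG"]), 1)        # single-codon family
  expect_true(is.na(u["CCA"]))             # zero-count family undefined

  counts <- setNames(integer(64), names(genetic_code()$code))
  counts["TTA"] <- 1L; counts["CTG"] <- 3L
  expect_equal(unname(synonymous_usage(counts)["TTA"]), 0.25)

  # usage sums to 1 within every family that has counts
  set.seed(9)
  prof <- suppressWarnings(
    codon_counts(replicate(30, paste0("ATG", random_dna(90), "TAA"))))
  u2 <- synonymous_usage(prof)
  code <- genetic_code()$code
  for (aa in unique(code[code != "*"])) {
    fam <- names(code)[code == aa]
    if (all(!is.na(u2[fam]))) expect_equal(sum(u2[fam]), 1, tolerance = 1e-9)
  }
})

test_that("random usage is 1/family-size, truncated for display", {
  ru <- random_usage()
  expect_equal(unname(truncate_digits(ru["TTA"])), 0.166)  # Leu, 6 codons
  expect_equal(unname(ru["CCA"]), 0.25)                    # Pro, 4
  expect_equal(unname(ru["AAC"]), 0.5)                     # Asn, 2
  expect_equal(unname(ru["ATG"]), 1)                       # Met, 1
  code <- genetic_code()$code
  for (aa in unique(code[code != "*"])) {
    fam <- names(code)[code == aa]
    expect_equal(sum(ru[fam]), 1)
  }
  expect_equal(truncate_digits(0.9999), 0.999)             # truncation, not rounding
})

test_that("trna_complement decodes anticodons and reports undetermined", {
  expect_identical(as_rna(revcomp(as_dna("UAA"))), "UUA")
  acs <- c("UAA", "UAG", "CAU", "GUU", "UGG", "UGG", "UCU", "UGA", "UGU",
           "UAC")
  feats <- make_features(paste0("t", seq_along(acs)), "phage",
                         start = 100 * (seq_along(acs) - 1),
                         end = 100 * seq_along(acs) - 30,
                         kind = "tRNA", anticodon = acs)
  tc <- trna_complement(feats)
  expect_equal(nrow(tc$table), 10L)
  expect_equal(tc$n_undetermined, 0L)
  expect_identical(tc$table[anticodon == "UAA", decoded_codon], "UUA")

  # anticodon parsed from product text; missing both -> undetermined
  feats2 <- make_features(c("t1", "t2"), "phage", c(0, 100), c(70, 170),
                          kind = "tRNA",
                          product = c("tRNA-Leu(uaa)", "putative tRNA"))
  tc2 <- trna_complement(feats2)
  expect_equal(nrow(tc2$table), 1L)
  expect_equal(tc2$n_undetermined, 1L)
  expect_identical(tc2$table$decoded_codon, "UUA")
})

test_that("rare_codon_report flags host-rare codons with strict inequality", {
  # host built to the usage pattern a biased host genome shows: UUA very
  # rare among Leu codons, AAC dominant among Asn codons
  counts <- setNames(integer(64), names(genetic_code()$code))
  counts[c("TTA", "CTG", "CTC", "CTT", "CTA", "TTG")] <-
    c(3L, 700L, 200L, 50L, 27L, 20L)                     # Leu: UUA 0.003
  counts[c("AAC", "AAT")] <- c(850L, 150L)               # Asn: AAC 0.85
  counts[c("CCA", "CCG", "CCC", "CCT")] <- c(47L, 700L, 200L, 53L)
  counts["ATG"] <- 500L
  host <- structure(list(source_id = "host", counts = counts, n_cds = 1L,
                         n_skipped = 0L, n_internal_stops = 0L),
                    class = "codon_profile")
  phage <- suppressWarnings(
    codon_counts(replicate(20, paste0("ATG", random_dna(60), "TAA")), "phage"))
  acs <- c("UAA", "UGG", "GUU", "CAU")    # decode UUA, CCA, AAC, AUG
  trnas <- trna_complement(
    make_features(paste0("t", 1:4), "phage", 100 * (0:3), 100 * (1:4) - 30,
                  kind = "tRNA", anticodon = acs))
  rep <- rare_codon_report(phage, host, trnas)
  expect_true(rep[codon == "UUA", rare_host])             # 0.003 < 0.166
  expect_true(rep[codon == "CCA", rare_host])             # 0.047 < 0.25
  expect_false(rep[codon == "AAC", rare_host])            # 0.85 >= 0.5
  expect_false(rep[codon == "AUG", rare_host])            # 1 is never < 1

  # exact tie with the baseline is not rare (strict <)
  counts2 <- counts
  counts2[c("AAC", "AAT")] <- c(100L, 100L)
  host2 <- host; host2$counts <- counts2
  rep2 <- rare_codon_report(phage, host2, trnas)
  expect_false(rep2[codon == "AAC", rare_host])

  # host tRNA absence flag
  host_trnas <- trna_complement(
    make_features("h1", "host", 0, 70, kind = "tRNA", anticodon = "GUU"))
  rep3 <- rare_codon_report(phage, host, trnas, host_trnas)
  expect_true(rep3[codon == "UUA", host_trna_absent])
  expect_false(rep3[codon == "AAC", host_trna_absent])
})

test_that("codon_usage_table truncates displayed fractions", {
  phage <- suppressWarnings(codon_counts("ATGTTATTGCTACTCCTGCTTTAA"))
  host <- phage
  trnas <- trna_complement(
    make_features("t1", "p", 0, 70, kind = "tRNA", anticodon = "UAA"))
  tab <- codon_usage_table(phage, host, trnas)
  expect_equal(tab$random_usage, 0.166)
  expect_equal(tab$phage_usage, 0.166)    # 1/6 truncated
})

test_that("rank_genes_by_target_codons scores, filters and orders", {
  profs <- codon_counts_by_gene(c(
    big = paste0("ATG", strrep("TTA", 4), strrep("GGC", 5), "TAA"),
    small = paste0("ATG", strrep("GGC", 9), "TAA")))
  r <- rank_genes_by_target_codons(profs, "UUA", min_codons = 5)
  expect_equal(r[gene_id == "big", score], 4 / 10)
  expect_identical(r$gene_id, c("big", "small"))
  expect_error(rank_genes_by_target_codons(profs, character()), "Empty")
  r2 <- rank_genes_by_target_codons(profs, "UUA", min_codons = 30)
  expect_equal(nrow(r2), 0L)
})

test_that("a gene enriched in target codons ranks first among simulated genes", {
  set.seed(77)
  genes <- replicate(50, paste0("ATG", random_dna(300), "TAA"))
  names(genes) <- paste0("bg", 1:50)
  # plant one gene with ~3x the background frequency of the target codons
  target <- c("TTA", "CCA")
  planted <- paste0("ATG",
                    paste(sample(c(rep(target, 15), replicate(70, random_dna(3))),
                                 100, replace = TRUE), collapse = ""), "TAA")
  profs <- codon_counts_by_gene(c(genes, planted = planted))
  r <- suppressWarnings(
    rank_genes_by_target_codons(profs, as_rna(target), min_codons = 30))
  expect_identical(r$gene_id[1], "planted")
})
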