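# Shared fixture builders; everything is generated in code at test time.

make_features <- function(gene_id, genome_id, start, end,
                          strand = "+", kind = "CDS",
                          product = NA_character_,
                          category = NA_character_,
                          anticodon = NA_character_) {
  data.table::data.table(gene_id = gene_id, genome_id = genome_id,
                         start = as.integer(start), end = as.integer(end),
                         strand = strand, kind = kind, product = product,
                         category = category, anticodon = anticodon)
}

make_og_table <- function(gene_id, genome_id, og_id) {
  data.table::data.table(gene_id = gene_id, genome_id = genome_id,
                         og_id = og_id)
}

write_tmp_fasta <- function(records, file = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), file)
  file
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Independent brute-force Jaccard on subsets of 1:u encoded as index vectors
jaccard_oracle <- function(a, b) {
  inter <- sum(a %in% b)
  uni <- length(unique(c(a, b)))
  if (uni == 0) 0 else inter / uni
}

# Independent brute-force local-similarity oracle (D = 0): exhaustive search
# over all contiguous intervals of the normal-score product series.
lsa_oracle_d0 <- function(x, y) {
  n <- length(x)
  zx <- qnorm(rank(x) / (n + 1))
  zy <- qnorm(rank(y) / (n + 1))
  p <- zx * zy
  best <- 0
  for (i in seq_len(n)) for (j in i:n) best <- max(best, abs(sum(p[i:j])))
  best / n
}
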