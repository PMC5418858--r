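# Genome, annotation and ortholog-table I/O. Internal coordinates are
# 0-based half-open; GFF3/GenBank readers convert from 1-based inclusive.

.VALID_BASES <- c("A", "C", "G", "T", "N")

#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercased and RNA-style `U` is mapped to `T`. Any other
#' character outside `A,C,G,T,N` raises a format error naming the offending
#' record.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param topology Either a single value recycled to all records or a vector,
#'   one of `"linear"` or `"circular"`. Windows and regions never wrap, so
#'   topology is carried as metadata only.
#' @return A [Biostrings::DNAStringSet] named by genome id, with a
#'   `topology` character vector in its `metadata()`.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), .VALID_BASES)
    if (length(bad) > 0L) {
      stop("Record '", ids[i], "' contains invalid characters: ",
           paste(bad, collapse = ", "))
    }
    if (nchar(seqs[[i]]) == 0L) stop("Record '", ids[i], "' has empty sequence")
  }
  if (anyDuplicated(ids)) stop("Duplicate genome ids in FASTA: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  topology <- rep_len(match.arg(topology, c("linear", "circular"),
                                several.ok = TRUE), length(ids))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::metadata(out)$topology <- stats::setNames(topology, ids)
  out
}

#' Write genome sequences to FASTA
#'
#' @param genomes A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (is.character(genomes)) genomes <- Biostrings::DNAStringSet(genomes)
  Biostrings::writeXStringSet(genomes, path)
  invisible(path)
}

.empty_features <- function() {
  data.table(gene_id = character(), genome_id = character(),
             start = integer(), end = integer(), strand = character(),
             kind = character(), product = character(),
             category = character(), anticodon = character())
}

.validate_features <- function(feat, genomes = NULL) {
  if (nrow(feat) == 0L) return(feat)
  if (any(feat$start < 0L) || any(feat$start >= feat$end))
    stop("Invalid feature coordinates: need 0 <= start < end")
  if (!all(feat$strand %in% c("+", "-")))
    stop("Unknown strand symbol: ",
         paste(unique(setdiff(feat$strand, c("+", "-"))), collapse = ", "))
  dup <- feat[, .N, by = .(genome_id, gene_id)][N > 1L]
  if (nrow(dup) > 0L)
    stop("Duplicate gene_id within genome: ",
         paste(dup$gene_id, collapse = ", "))
  if (!is.null(genomes)) {
    lens <- genome_lengths(genomes)
    for (g in unique(feat$genome_id)) {
      if (!g %in% names(lens)) next
      if (any(feat[genome_id == g, end] > lens[[g]]))
        stop("Feature extends beyond sequence length of genome '", g, "'")
    }
  }
  feat
}

#' Lengths of a genome collection
#'
#' @param genomes Named [Biostrings::DNAStringSet] or named character vector.
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genomes) {
  if (is.character(genomes)) return(stats::setNames(nchar(genomes), names(genomes)))
  stats::setNames(Biostrings::width(genomes), names(genomes))
}

#' Read gene annotations (GFF3 or GenBank flat file)
#'
#' Coordinates in the file (1-based inclusive) are converted to the internal
#' 0-based half-open convention. CDS and tRNA features are retained with
#' their kind; all other feature types are kept with `kind = "other"`.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"genbank"`.
#' @param genomes Optional genome collection used to validate that no feature
#'   extends beyond its sequence.
#' @return A `data.table` of gene features with columns `gene_id`,
#'   `genome_id`, `start`, `end` (0-based half-open), `strand`, `kind`
#'   (`CDS`/`tRNA`/`other`), `product`, `category`, `anticodon`.
#' @export
read_annotations <- function(path, format = c("gff3", "genbank"),
                             genomes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("Annotation file not found: ", path)
  feat <- switch(format,
                 gff3 = .read_gff3(path),
                 genbank = .read_genbank(path))
  if (!any(feat$kind == "CDS"))
    warning("No CDS features found in ", path)
  .validate_features(feat, genomes)
}

.read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(.empty_features())
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% names(mc)) as.character(mc[[col]]) else rep(NA_character_, length(gr))
  type <- as.character(mc$type)
  kind <- ifelse(type == "CDS", "CDS", ifelse(type == "tRNA", "tRNA", "other"))
  gene_id <- pick("ID")
  lt <- pick("locus_tag")
  gene_id <- ifelse(is.na(gene_id), lt, gene_id)
  auto <- paste0(as.character(GenomicRanges::seqnames(gr)), "_feat",
                 seq_along(gr))
  gene_id <- ifelse(is.na(gene_id), auto, gene_id)
  strand <- as.character(BiocGenerics::strand(gr))
  feat <- data.table(
    gene_id = gene_id,
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    kind = kind,
    product = pick("product"),
    category = pick("category"),
    anticodon = pick("anticodon"))
  feat
}

# Minimal read-only GenBank flat-file parser: single-interval CDS/tRNA
# locations, optionally complement(); join()/order() locations are rejected.
.read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  genome_id <- NA_character_
  n_auto <- 0L
  i <- 1L
  in_features <- FALSE
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("^LOCUS", line)) {
      genome_id <- strsplit(trimws(sub("^LOCUS", "", line)), "\\s+")[[1]][1]
      in_features <- FALSE
    } else if (grepl("^VERSION", line)) {
      v <- strsplit(trimws(sub("^VERSION", "", line)), "\\s+")[[1]][1]
      if (nzchar(v)) genome_id <- v
    } else if (grepl("^FEATURES", line)) {
      in_features <- TRUE
    } else if (grepl("^(ORIGIN|CONTIG|//)", line)) {
      in_features <- FALSE
    } else if (in_features && grepl("^ {5}\\S", line)) {
      key <- sub("^ {5}(\\S+).*$", "\\1", line)
      loc <- trimws(sub("^ {5}\\S+\\s+", "", line))
      quals <- character()
      j <- i + 1L
      while (j <= length(lines) && grepl("^ {21}", lines[j])) {
        quals <- c(quals, trimws(lines[j])); j <- j + 1L
      }
      # continuation lines of the location itself have no leading "/"
      while (length(quals) > 0L && !startsWith(quals[1], "/")) {
        loc <- paste0(loc, quals[1]); quals <- quals[-1]
      }
      qual_get <- function(name) {
        hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (length(hit) == 0L) return(NA_character_)
        gsub('^"|"$', "", sub(paste0("^/", name, "="), "", hit[1]))
      }
      if (grepl("join|order", loc))
        stop("Multi-interval GenBank locations are not supported: ", loc)
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      m <- regmatches(loc, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", loc))[[1]]
      if (length(m) == 3L) {
        s1 <- as.integer(m[2]); e1 <- as.integer(m[3])
        kind <- if (key == "CDS") "CDS" else if (key == "tRNA") "tRNA" else "other"
        gid <- qual_get("locus_tag")
        if (is.na(gid)) gid <- qual_get("gene")
        if (is.na(gid)) { n_auto <- n_auto + 1L; gid <- paste0(genome_id, "_feat", n_auto) }
        rows[[length(rows) + 1L]] <- data.table(
          gene_id = gid, genome_id = genome_id,
          start = s1 - 1L, end = e1, strand = strand, kind = kind,
          product = qual_get("product"), category = qual_get("category"),
          anticodon = qual_get("anticodon"))
      }
      i <- j - 1L
    }
    i <- i + 1L
  }
  if (length(rows) == 0L) return(.empty_features())
  rbindlist(rows)
}

#' Write gene features as GFF3
#'
#' Converts the internal 0-based half-open coordinates back to 1-based
#' inclusive GFF3.
#'
#' @param features Feature table as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0L) {
    attrs <- paste0("ID=", features$gene_id)
    has_prod <- !is.na(features$product)
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=", features$product[has_prod])
    has_cat <- !is.na(features$category)
    attrs[has_cat] <- paste0(attrs[has_cat], ";category=", features$category[has_cat])
    has_ac <- !is.na(features$anticodon)
    attrs[has_ac] <- paste0(attrs[has_ac], ";anticodon=", features$anticodon[has_ac])
    type <- ifelse(features$kind == "other", "region", features$kind)
    writeLines(paste(features$genome_id, "phagecomp", type,
                     features$start + 1L, features$end, ".",
                     features$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Extract the coding sequence of a feature
#'
#' Returns the substring `[start, end)` of the genome; for minus-strand
#' features the reverse complement is returned.
#'
#' @param genomes Genome collection ([Biostrings::DNAStringSet] or named
#'   character vector), or a single unnamed sequence.
#' @param feature One-row feature table (or list) with `genome_id`, `start`,
#'   `end`, `strand`.
#' @return The nucleotide string of the gene, 5'→3'.
#' @export
extract_cds <- function(genomes, feature) {
  if (is.character(genomes) && is.null(names(genomes)) && length(genomes) == 1L) {
    seq <- genomes
  } else {
    seqs <- if (is.character(genomes)) genomes else as.character(genomes)
    if (!feature$genome_id %in% names(seqs))
      stop("Genome '", feature$genome_id, "' not found")
    seq <- seqs[[feature$genome_id]]
  }
  s <- as.integer(feature$start); e <- as.integer(feature$end)
  if (s < 0L || e > nchar(seq) || s >= e)
    stop("Feature out of genome bounds: [", s, ",", e, ") vs length ", nchar(seq))
  sub <- substr(seq, s + 1L, e)
  if (feature$strand == "-") sub <- revcomp(sub)
  sub
}

#' Reverse complement of a DNA string
#'
#' @param x A character string over `A,C,G,T,N` (lowercase accepted).
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

#' Read a gene → ortholog-group assignment table
#'
#' A TSV with header columns `gene_id`, `genome_id`, `og_id` (POG-style).
#' A gene listed under two different ortholog groups is an error; exact
#' duplicate rows are collapsed.
#'
#' @param path Path to the TSV.
#' @return A `data.table` with columns `gene_id`, `genome_id`, `og_id`.
#' @export
read_ortholog_table <- function(path) {
  if (!file.exists(path)) stop("Ortholog table not found: ", path)
  tab <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (nrow(tab) == 0L) {
    warning("Ortholog table is empty: ", path)
    return(data.table(gene_id = character(), genome_id = character(),
                      og_id = character()))
  }
  need <- c("gene_id", "genome_id", "og_id")
  if (!all(need %in% names(tab)))
    stop("Ortholog table must have columns: ", paste(need, collapse = ", "))
  tab <- unique(tab[, .(gene_id, genome_id, og_id)])
  conflict <- tab[, .(n_og = data.table::uniqueN(og_id)), by = gene_id][n_og > 1L]
  if (nrow(conflict) > 0L)
    stop("Gene(s) assigned to multiple ortholog groups: ",
         paste(conflict$gene_id, collapse = ", "))
  tab
}

#' Write an ortholog table to TSV
#' @param table Ortholog assignment `data.table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(table, path) {
  fwrite(table[, .(gene_id, genome_id, og_id)], path, sep = "\t")
  invisible(path)
}
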