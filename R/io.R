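# File-format interfaces: FASTA, GFF3, FASTQ, TSV.

#' Write species genomes to FASTA and GFF3
#'
#' One `<species>.fasta` and `<species>.gff3` per genome.  GFF3 rows are
#' 1-based inclusive exon records carrying a `gene_id` attribute.  Output is
#' deterministic: the same genomes produce byte-identical files.
#'
#' @param genomes list of `species_genome` objects.
#' @param dir output directory (created if needed).
#' @return invisibly, a data.frame of written paths.
#' @export
write_genomes <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- lapply(genomes, function(g) {
    fa <- file.path(dir, paste0(g$species_id, ".fasta"))
    gff <- file.path(dir, paste0(g$species_id, ".gff3"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(g$contigs), fa, width = 80L)
    gm <- g$gene_models
    lines <- c("##gff-version 3",
               sprintf("%s\tcocultureseq\texon\t%d\t%d\t.\t%s\t.\tgene_id=%s",
                       gm$contig, gm$start, gm$end, gm$strand, gm$gene_id))
    writeLines(lines, gff)
    data.frame(species = g$species_id, fasta = fa, gff3 = gff,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, paths))
}

#' Read gene models from a GFF3 file
#'
#' Accepts exon records with a `gene_id` (or `Parent`/`ID`) attribute;
#' coordinates are 1-based inclusive.
#'
#' @param path GFF3 file.
#' @return data.frame `gene_id`, `contig`, `strand`, `start`, `end` (one row
#'   per exon, sorted by gene then start).
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "exon", TRUE)
  f <- f[keep]
  if (!length(f)) stop("no exon records in ", path)
  attr_id <- vapply(f, function(x) {
    m <- regmatches(x[9], regexec("(?:gene_id|Parent|ID)=([^;]+)", x[9]))[[1]]
    if (length(m) < 2) stop("exon record without gene_id attribute")
    m[2]
  }, "")
  out <- data.frame(
    gene_id = attr_id,
    contig = vapply(f, `[`, "", 1),
    strand = vapply(f, `[`, "", 7),
    start = as.integer(vapply(f, `[`, "", 4)),
    end = as.integer(vapply(f, `[`, "", 5)),
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id, out$start), , drop = FALSE]
}

#' Write a read-pair set to paired FASTQ files
#'
#' Quality strings are constant Q30 (the assignment stage does not use
#' qualities).
#'
#' @param reads a `read_pairs` object (or data.frame with `fragment_id`,
#'   `seq1`, `seq2`).
#' @param prefix output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` (`.gz` appended when `gzip = TRUE`).
#' @param gzip compress output.
#' @return invisibly, the two paths.
#' @export
write_fastq_pair <- function(reads, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_1", "_2"), ext)
  for (m in 1:2) {
    seqs <- if (m == 1) reads$seq1 else reads$seq2
    qual <- strrep("?", nchar(seqs))  # phred+33 Q30
    con <- if (gzip) gzfile(paths[m], "w") else file(paths[m], "w")
    writeLines(paste0("@", reads$fragment_id, "/", m, "\n", seqs,
                      "\n+\n", qual), con, sep = "\n")
    close(con)
  }
  invisible(paths)
}

#' Read paired FASTQ files into a read-pair set
#'
#' @param path1,path2 FASTQ files for mates 1 and 2 (optionally gzipped).
#' @return a `read_pairs` data.table (`fragment_id`, `seq1`, `seq2`).
#' @export
read_fastq_pair <- function(path1, path2) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    list(id = sub("/[12]$", "", sub(" .*", "", names(x))),
         seq = as.character(x))
  }
  a <- rd(path1); b <- rd(path2)
  if (!identical(a$id, b$id)) stop("mate files are not in matching order")
  reads <- data.table::data.table(fragment_id = a$id, seq1 = a$seq,
                                  seq2 = b$seq)
  data.table::setattr(reads, "class", c("read_pairs", class(reads)))
  reads
}

#' Write a table as TSV
#'
#' @param x data.frame or matrix (matrices keep row names in a first
#'   `gene_id` column).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
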