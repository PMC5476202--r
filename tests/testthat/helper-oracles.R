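# Independent oracles used by the test suite.  Each re-derives the checked
# quantity by direct search, enumeration or closed form, sharing no code
# with the implementation under test.

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), "",
                USE.NAMES = FALSE))
}

random_read <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force species assignment by all-substring search: a query k-mer
# hits a species when it occurs verbatim in any contig (either strand).
brute_force_assign <- function(reads, genomes, k, min_hits, margin) {
  seqs <- lapply(genomes, function(g) {
    c(unname(g$contigs), unname(revcomp_chr(g$contigs)))
  })
  names(seqs) <- vapply(genomes, function(g) g$species_id, "")
  verdicts <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    kmers <- character(0)
    for (s in c(reads$seq1[i], reads$seq2[i])) {
      n <- nchar(s)
      kmers <- c(kmers, substring(s, 1:(n - k + 1), k:n))
    }
    hits <- vapply(seqs, function(ctgs) {
      sum(vapply(kmers,
                 function(km) any(grepl(km, ctgs, fixed = TRUE)), TRUE))
    }, 0L)
    b <- which.max(hits)
    second <- if (length(hits) > 1) max(hits[-b]) else 0L
    verdicts[i] <- if (hits[b] < min_hits) "unmapped"
      else if (second <= margin * hits[b]) "unique" else "ambiguous"
  }
  verdicts
}

# Brute-force complete linkage: at each step recompute every inter-cluster
# distance as the max over the *original* matrix, merge the closest pair.
brute_force_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < bd) { bd <- dij; best <- c(i, j) }
      }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Exhaustive hypergeometric upper tail by enumerating all draws of size n
# from N background genes of which the first K carry the term.
enumerate_hypergeom_p <- function(N, K, n, k) {
  if (K == 0) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Closed-form least squares on (x, y) via the normal equations.
normal_equations_fit <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# Shared small study config for pipeline-level tests (kept light).
tiny_cfg <- function(...) {
  sim_config(n_species = 2, genome_length_bp = 20000, n_genes = 30,
             gene_length_range = c(250, 400), rrna_copies = 5,
             depth_mono = 400, depth_mixed = 1200, n_replicates = 2,
             seed = 42, ...)
}

# Hand-built two-species genomes with known sequences for exact assignment
# and counting tests.  Gene A sits at 101..400 on '+', gene B at 601..900
# on '-'; species differ by the substitutions in `diverge_at`.
handmade_genomes <- function(len = 1200, seed = 99, diverge_at = integer(0)) {
  set.seed(seed)
  base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
  ch <- strsplit(base, "")[[1]]
  ch2 <- ch
  for (p in diverge_at) {
    ch2[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  mk <- function(sp, chars) {
    gm <- data.frame(
      gene_id = paste0(sp, c("_gA", "_gB")), contig = "chr1",
      strand = c("+", "-"), start = c(101L, 601L), end = c(400L, 900L),
      stringsAsFactors = FALSE)
    structure(list(
      species_id = sp, contigs = c(chr1 = paste(chars, collapse = "")),
      gene_models = gm,
      annotations = data.frame(gene_id = gm$gene_id,
                               cazy_family = c("GH7", NA),
                               cazy_class = c("GH", NA),
                               stringsAsFactors = FALSE),
      term_map = data.frame(gene_id = gm$gene_id[1], term = "T_GH",
                            stringsAsFactors = FALSE)
    ), class = "species_genome")
  }
  list(spX = mk("spX", ch), spY = mk("spY", ch2))
}

# A read pair taken noiselessly from a gene of a handmade genome
# (dUTP orientation: mate 1 antisense, mate 2 sense).
pair_from_gene <- function(genome, gene_id, offset = 1, frag_len = 150,
                           read_len = 75) {
  gm <- genome$gene_models
  row <- gm[gm$gene_id == gene_id, ]
  if (row$strand == "+") {
    gstart <- row$start + offset - 1
    frag <- substr(genome$contigs[[row$contig]], gstart,
                   gstart + frag_len - 1)
  } else {
    gend <- row$end - offset + 1
    frag <- revcomp_chr(substr(genome$contigs[[row$contig]],
                               gend - frag_len + 1, gend))
  }
  dt <- data.table::data.table(
    fragment_id = paste0(gene_id, ".o", offset),
    seq1 = revcomp_chr(substr(frag, frag_len - read_len + 1, frag_len)),
    seq2 = substr(frag, 1, read_len))
  data.table::setattr(dt, "class", c("read_pairs", class(dt)))
  dt
}
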