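#' Generate synthetic multi-species genomes
#'
#' Builds one random ancestral genome, lays out non-overlapping single-exon
#' gene models plus two marker loci (a multi-copy rRNA-analogue and a
#' single-copy locus), then derives each species by independent per-site
#' substitution from the ancestor.  The per-site rate is solved so that the
#' expected *pairwise* mismatch fraction between any two species equals
#' `cfg$divergence`.  All copies of the rRNA marker are identical within a
#' species, and every species pair is forced to differ at the marker's
#' discriminating positions (the positions a species-specific hydrolysis
#' probe would target), even at zero background divergence.
#'
#' Gene coordinates are shared across species (substitution-only evolution,
#' no indels), so each gene has a positional ortholog in every genome.  A
#' configurable fraction of genes receives a CAZy family label spanning the
#' degradative classes (GH, CE, PL, AA) and at least one non-degradative GT
#' family; genes also receive flat annotation terms usable for enrichment.
#'
#' @param cfg a [sim_config()] object.
#' @return a list of `species_genome` objects, one per species, each with
#'   elements `species_id`, `contigs` (named character), `gene_models`
#'   (data.frame: `gene_id`, `contig`, `strand`, `start`, `end`, one row per
#'   exon), `marker_rrna` and `marker_single_copy` (`marker_locus` objects),
#'   `annotations` (`gene_id`, `cazy_family`, `cazy_class`) and `term_map`
#'   (`gene_id`, `term`).
#' @export
generate_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    L <- cfg$genome_length_bp
    ml <- cfg$marker_length

    gene_len <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                       cfg$n_genes, replace = TRUE)
    block_len <- c(gene_len, rep(ml, cfg$rrna_copies), ml)
    block_type <- c(rep("gene", cfg$n_genes),
                    rep("rrna", cfg$rrna_copies), "single")
    spare <- L - sum(block_len)
    if (spare < 0) {
      stop("genome_length_bp too small to host ", cfg$n_genes,
           " genes plus marker loci (need >= ", sum(block_len), " bp)")
    }
    ord <- sample(length(block_len))
    block_len <- block_len[ord]; block_type <- block_type[ord]
    gaps <- as.vector(stats::rmultinom(1, spare, rep(1, length(block_len) + 1)))
    starts <- cumsum(gaps[-length(gaps)] + c(0, head(block_len, -1))) + 1L
    ends <- starts + block_len - 1L

    gene_rows <- which(block_type == "gene")
    rrna_rows <- which(block_type == "rrna")
    single_row <- which(block_type == "single")

    ancestral <- random_dna(L)
    # all rRNA copies carry one common ancestral marker sequence
    anc_rrna <- random_dna(ml)
    anc_chars <- strsplit(ancestral, "", fixed = TRUE)[[1]]
    for (i in rrna_rows) {
      anc_chars[starts[i]:ends[i]] <- strsplit(anc_rrna, "", fixed = TRUE)[[1]]
    }
    ancestral <- paste(anc_chars, collapse = "")
    anc_single <- substr(ancestral, starts[single_row], ends[single_row])

    # per-site rate q such that E[pairwise mismatch] = divergence:
    # p = 2q(1-q) + (2/3)q^2  =>  q = (3 - sqrt(9 - 12 p)) / 4
    q <- (3 - sqrt(9 - 12 * cfg$divergence)) / 4

    disc_pos <- sort(sample(ml, cfg$n_discriminating))
    disc_base <- function(s, j) DNA_BASES[((s - 1L) + j) %% 4L + 1L]
    for (s1 in seq_len(cfg$n_species - 1L)) {
      for (s2 in (s1 + 1L):cfg$n_species) {
        if (!any(vapply(seq_along(disc_pos),
                        function(j) disc_base(s1, j) != disc_base(s2, j),
                        TRUE))) {
          stop("cannot make rRNA markers of all species pairs distinct; ",
               "increase n_discriminating or reduce n_species")
        }
      }
    }

    strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)

    # annotations are ancestral (shared across positional orthologs)
    fam_pool <- data.frame(
      family = c("GH5", "GH7", "GH10", "GH11", "GH3", "CE1", "CE5",
                 "PL1", "AA9", "GT2", "GT35"),
      class = c("GH", "GH", "GH", "GH", "GH", "CE", "CE",
                "PL", "AA", "GT", "GT"),
      stringsAsFactors = FALSE
    )
    n_cazy <- round(cfg$cazy_fraction * cfg$n_genes)
    cazy_idx <- sort(sample(cfg$n_genes, n_cazy))
    fam_draw <- sample(nrow(fam_pool), n_cazy, replace = TRUE)
    if (n_cazy > 0 && !any(fam_pool$class[fam_draw] == "GT")) {
      fam_draw[length(fam_draw)] <- which(fam_pool$family == "GT2")
    }
    cazy_family <- rep(NA_character_, cfg$n_genes)
    cazy_family[cazy_idx] <- fam_pool$family[fam_draw]
    cazy_class <- rep(NA_character_, cfg$n_genes)
    cazy_class[cazy_idx] <- fam_pool$class[fam_draw]

    generic_terms <- sprintf("T_G%02d", 1:10)
    term_list <- lapply(seq_len(cfg$n_genes), function(i) {
      t <- sample(generic_terms, sample(0:2, 1))
      if (!is.na(cazy_class[i])) t <- c(paste0("T_", cazy_class[i]), t)
      t
    })

    genomes <- vector("list", cfg$n_species)
    for (s in seq_len(cfg$n_species)) {
      sp <- cfg$species_ids[s]
      n_mut <- rbinom(1, L, q)
      mut_idx <- if (n_mut > 0) sample.int(L, n_mut) else integer(0)
      gseq <- mutate_positions(ancestral, mut_idx)

      # species marker sequences: background divergence + forced
      # discriminating bases (shared verbatim across all copies)
      sp_rrna <- mutate_positions(anc_rrna,
                                  which(runif(ml) < q))
      sp_single <- mutate_positions(anc_single, which(runif(ml) < q))
      rch <- strsplit(sp_rrna, "", fixed = TRUE)[[1]]
      sch <- strsplit(sp_single, "", fixed = TRUE)[[1]]
      for (j in seq_along(disc_pos)) {
        rch[disc_pos[j]] <- disc_base(s, j)
        sch[disc_pos[j]] <- disc_base(s, j)
      }
      sp_rrna <- paste(rch, collapse = "")
      sp_single <- paste(sch, collapse = "")

      gch <- strsplit(gseq, "", fixed = TRUE)[[1]]
      for (i in rrna_rows) gch[starts[i]:ends[i]] <- rch
      gch[starts[single_row]:ends[single_row]] <- sch
      gseq <- paste(gch, collapse = "")

      gene_ids <- sprintf("%s_g%04d", sp, seq_len(cfg$n_genes))
      gm <- data.frame(
        gene_id = gene_ids, contig = "chr1", strand = strands,
        start = starts[gene_rows], end = ends[gene_rows],
        stringsAsFactors = FALSE
      )
      marker_rrna <- structure(list(
        locus_id = paste0(sp, "_rrna58S"), contig = "chr1",
        intervals = data.frame(start = starts[rrna_rows],
                               end = ends[rrna_rows]),
        copy_number = cfg$rrna_copies,
        discriminating_positions = disc_pos, sequence = sp_rrna
      ), class = "marker_locus")
      marker_single <- structure(list(
        locus_id = paste0(sp, "_scl"), contig = "chr1",
        intervals = data.frame(start = starts[single_row],
                               end = ends[single_row]),
        copy_number = 1L,
        discriminating_positions = disc_pos, sequence = sp_single
      ), class = "marker_locus")

      genomes[[s]] <- structure(list(
        species_id = sp, contigs = c(chr1 = gseq), gene_models = gm,
        marker_rrna = marker_rrna, marker_single_copy = marker_single,
        annotations = data.frame(gene_id = gene_ids,
                                 cazy_family = cazy_family,
                                 cazy_class = cazy_class,
                                 stringsAsFactors = FALSE),
        term_map = data.frame(
          gene_id = rep(gene_ids, lengths(term_list)),
          term = unlist(term_list), stringsAsFactors = FALSE
        )
      ), class = "species_genome")
    }
    names(genomes) <- cfg$species_ids
    genomes
  })
}

#' @export
print.species_genome <- function(x, ...) {
  cat("species_genome:", x$species_id, "-",
      sum(nchar(x$contigs)), "bp in", length(x$contigs), "contig(s),",
      length(unique(x$gene_models$gene_id)), "genes,",
      x$marker_rrna$copy_number, "rRNA marker copies\n")
  invisible(x)
}

#' Gene lengths from gene models
#'
#' Sums exon widths per gene (`L_g`), the length used in FPKM.
#'
#' @param gene_models data.frame with `gene_id`, `start`, `end` (one row per
#'   exon; exons assumed non-overlapping within a gene).
#' @return named numeric vector of summed exon bp.
#' @export
gene_lengths <- function(gene_models) {
  w <- gene_models$end - gene_models$start + 1
  if (any(w < 1)) stop("gene model with exon of width < 1")
  tot <- tapply(w, gene_models$gene_id, sum)[unique(gene_models$gene_id)]
  setNames(as.numeric(tot), names(tot))
}

#' Observed pairwise divergence between two equal-length genomes
#'
#' @param g1,g2 `species_genome` objects with identical contig layout.
#' @return fraction of mismatching sites.
#' @export
pairwise_divergence <- function(g1, g2) {
  stopifnot(identical(names(g1$contigs), names(g2$contigs)))
  mism <- 0; tot <- 0
  for (ct in names(g1$contigs)) {
    a <- strsplit(g1$contigs[[ct]], "", fixed = TRUE)[[1]]
    b <- strsplit(g2$contigs[[ct]], "", fixed = TRUE)[[1]]
    stopifnot(length(a) == length(b))
    mism <- mism + sum(a != b); tot <- tot + length(a)
  }
  mism / tot
}
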