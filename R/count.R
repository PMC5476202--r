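#' Count uniquely assigned fragments onto gene models
#'
#' Union-rule counting of one sample's assignments: a unique fragment is
#' counted once for gene `g` if its inferred interval overlaps exons of `g`
#' and of no other gene (fragments touching two genes are discarded as
#' gene-ambiguous; fragments touching no exon are left uncounted).  Strand
#' compatibility follows the library type: with `stranded_mode = "reverse"`
#' (directional dUTP kit, the default) a fragment is compatible with a gene
#' on the opposite strand of its reported (mate-1) strand; `"forward"`
#' requires equality; `"none"` ignores strand.
#'
#' @param assignments a [assign_reads()] result for one sample.
#' @param genomes list of `species_genome` objects (their `gene_models`
#'   define the exons; contigs must cover every assigned contig).
#' @param stranded_mode `"reverse"` (default), `"forward"`, or `"none"`.
#' @return list of class `sample_counts`, one element per species:
#'   `counts` (named integer over all genes), `n_unique` (fragments uniquely
#'   assigned to the species), `n_counted` (fragments counted into genes).
#' @export
count_fragments <- function(assignments, genomes,
                            stranded_mode = c("reverse", "forward", "none")) {
  stranded_mode <- match.arg(stranded_mode)
  uniq <- assignments[assignments$verdict == "unique", ]
  known <- unlist(lapply(genomes, function(g) {
    paste0(g$species_id, ":", unique(g$gene_models$contig))
  }))
  if (nrow(uniq) &&
      !all(paste0(uniq$species, ":", uniq$contig) %in% known)) {
    stop("assignment refers to a contig absent from the gene models")
  }
  out <- lapply(genomes, function(g) {
    gm <- g$gene_models
    ids <- unique(gm$gene_id)
    sel <- uniq[uniq$species == g$species_id, ]
    counts <- setNames(integer(length(ids)), ids)
    n_counted <- 0L
    if (nrow(sel)) {
      exons <- GenomicRanges::GRanges(
        gm$contig, IRanges::IRanges(gm$start, gm$end), strand = gm$strand,
        gene_id = gm$gene_id)
      frags <- GenomicRanges::GRanges(
        sel$contig, IRanges::IRanges(sel$start, sel$end))
      ov <- GenomicRanges::findOverlaps(frags, exons,
                                        ignore.strand = TRUE)
      if (length(ov)) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        gene <- gm$gene_id[sh]
        gstrand <- gm$strand[sh]
        ok <- switch(stranded_mode,
                     none = rep(TRUE, length(ov)),
                     forward = sel$strand[qh] == gstrand,
                     reverse = sel$strand[qh] != gstrand)
        qh <- qh[ok]; gene <- gene[ok]
        if (length(qh)) {
          dt <- unique(data.table::data.table(frag = qh, gene = gene))
          ngene <- dt[, .N, by = frag]
          keep <- ngene$frag[ngene$N == 1L]
          hit <- dt[dt$frag %in% keep, ]
          tab <- table(hit$gene)
          counts[names(tab)] <- as.integer(tab)
          n_counted <- nrow(hit)
        }
      }
    }
    list(counts = counts, n_unique = nrow(sel), n_counted = n_counted)
  })
  names(out) <- vapply(genomes, function(g) g$species_id, "")
  class(out) <- "sample_counts"
  out
}

#' Per-species gene-by-sample count matrices over a set of samples
#'
#' Runs [count_fragments()] on each sample's assignments and binds the
#' results into one integer matrix per species, with per-sample totals.
#'
#' @param assignment_list named list (by sample id) of [assign_reads()]
#'   results.
#' @param genomes list of `species_genome` objects.
#' @param stranded_mode passed to [count_fragments()].
#' @return object of class `gene_counts`: per species a list with `counts`
#'   (gene x sample integer matrix), `n_unique` and `n_counted` (named
#'   per-sample totals).  `counts >= 0` and `n_counted <= n_unique` always.
#' @export
gene_counts <- function(assignment_list, genomes,
                        stranded_mode = "reverse") {
  if (is.null(names(assignment_list))) {
    names(assignment_list) <- paste0("s", seq_along(assignment_list))
  }
  per_sample <- lapply(assignment_list, count_fragments, genomes = genomes,
                       stranded_mode = stranded_mode)
  sp_ids <- vapply(genomes, function(g) g$species_id, "")
  out <- lapply(sp_ids, function(sp) {
    mats <- lapply(per_sample, function(s) s[[sp]]$counts)
    counts <- do.call(cbind, mats)
    colnames(counts) <- names(assignment_list)
    list(counts = counts,
         n_unique = vapply(per_sample, function(s) s[[sp]]$n_unique, 0L),
         n_counted = vapply(per_sample, function(s) s[[sp]]$n_counted, 0L))
  })
  names(out) <- sp_ids
  class(out) <- "gene_counts"
  out
}

#' @export
print.gene_counts <- function(x, ...) {
  for (sp in names(x)) {
    cat(sprintf("%s: %d genes x %d samples, %s counted fragments\n",
                sp, nrow(x[[sp]]$counts), ncol(x[[sp]]$counts),
                format(sum(x[[sp]]$n_counted), big.mark = ",")))
  }
  invisible(x)
}
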