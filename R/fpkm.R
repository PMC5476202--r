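#' Species-specific FPKM
#'
#' FPKM of gene `g` in sample `s` for one species is
#' `C_gs * 1e9 / (L_g * M_s)` where `C_gs` is the number of uniquely
#' assigned fragments counted onto the gene, `L_g` the summed exon length in
#' bp, and `M_s` that species' own gene-model-counted fragment total in the
#' sample — never the whole-sample total.  Consequently the identity
#' `sum_g FPKM_gs * (L_g / 1e3) = 1e6` holds exactly for every
#' species-sample with `M_s > 0`.
#'
#' @param counts a [gene_counts()] object (or, for a single species, a list
#'   with a `counts` matrix).
#' @param genomes list of `species_genome` objects supplying gene models, or
#'   a single data.frame of gene models when `counts` is single-species.
#' @return object of class `expression_matrix`: per species a list with
#'   `fpkm` (gene x sample), `lengths` (`L_g`), and `M` (per-sample
#'   denominators).  Samples with `M_s = 0` get all-`NA` columns with a
#'   warning.
#' @export
compute_fpkm <- function(counts, genomes) {
  if (inherits(counts, "gene_counts")) {
    sp_ids <- names(counts)
    gm_list <- lapply(genomes, function(g) g$gene_models)
    names(gm_list) <- vapply(genomes, function(g) g$species_id, "")
  } else {
    sp_ids <- "species"
    counts <- list(species = counts)
    gm_list <- list(species = genomes)
  }
  out <- lapply(sp_ids, function(sp) {
    C <- counts[[sp]]$counts
    L <- gene_lengths(gm_list[[sp]])
    if (!all(rownames(C) %in% names(L))) {
      stop("genes without a model length in species ", sp)
    }
    L <- L[rownames(C)]
    M <- colSums(C)
    fpkm <- sweep(C * 1e9 / L, 2, M, "/")
    if (any(M == 0)) {
      warning("species ", sp, ": zero counted fragments in sample(s) ",
              paste(colnames(C)[M == 0], collapse = ", "),
              "; FPKM set to NA")
      fpkm[, M == 0] <- NA_real_
    }
    list(fpkm = fpkm, lengths = L, M = M)
  })
  names(out) <- sp_ids
  class(out) <- "expression_matrix"
  out
}

#' @export
print.expression_matrix <- function(x, ...) {
  for (sp in names(x)) {
    cat(sprintf("%s: FPKM %d genes x %d samples (M_s: %s)\n", sp,
                nrow(x[[sp]]$fpkm), ncol(x[[sp]]$fpkm),
                paste(format(x[[sp]]$M), collapse = " ")))
  }
  invisible(x)
}

#' Mean and standard error over replicates
#'
#' @param values numeric vector of per-replicate values (n >= 2).
#' @return list with `mean`, `se` (sample sd / sqrt(n)) and `n`.
#' @export
replicate_summary <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least two replicates")
  list(mean = mean(values), se = sd(values) / sqrt(n), n = n)
}

#' Total FPKM over an annotation-defined gene set
#'
#' Sums FPKM per sample over the genes whose CAZy class is in
#' `include_classes` and not in `exclude_classes`.  The defaults implement
#' the lignocellulose-degradation convention: degradative classes GH, CE,
#' PL, AA included, glycosyltransferases (GT) excluded as they do not
#' degrade plant biomass.  When replicate grouping is supplied, per-group
#' mean and standard error (n = replicates) are reported.
#'
#' @param fpkm gene x sample FPKM matrix for one species (or one element of
#'   [compute_fpkm()] output).
#' @param annotations data.frame `gene_id`, `cazy_class`.
#' @param include_classes,exclude_classes CAZy class filters.
#' @param groups optional factor/character of length `ncol(fpkm)` mapping
#'   samples to conditions for the replicate summary.
#' @return object of class `aggregate_series`: `total` (named per-sample
#'   totals), `genes` (gene ids summed), and when `groups` is given a
#'   `summary` data.frame (`group`, `mean`, `se`, `n`).
#' @export
aggregate_set_fpkm <- function(fpkm, annotations,
                               include_classes = c("GH", "CE", "PL", "AA"),
                               exclude_classes = "GT",
                               groups = NULL) {
  if (is.list(fpkm) && !is.null(fpkm$fpkm)) fpkm <- fpkm$fpkm
  if (!all(rownames(fpkm) %in% annotations$gene_id)) {
    stop("annotation table does not cover all genes")
  }
  cls <- annotations$cazy_class[match(rownames(fpkm), annotations$gene_id)]
  keep <- !is.na(cls) & cls %in% include_classes & !(cls %in% exclude_classes)
  if (!any(keep)) {
    warning("no genes match the annotation filter; totals are 0")
    total <- setNames(numeric(ncol(fpkm)), colnames(fpkm))
  } else {
    total <- colSums(fpkm[keep, , drop = FALSE])
  }
  out <- list(total = total, genes = rownames(fpkm)[keep])
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(total))
    sm <- lapply(split(total, groups), function(v) {
      s <- replicate_summary(v)
      data.frame(mean = s$mean, se = s$se, n = s$n)
    })
    out$summary <- data.frame(group = names(sm),
                              do.call(rbind, sm), row.names = NULL)
  }
  class(out) <- "aggregate_series"
  out
}

#' @export
print.aggregate_series <- function(x, ...) {
  cat("aggregate FPKM over", length(x$genes), "genes\n")
  print(x$total)
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
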