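#' Select genes for expression clustering
#'
#' Implements the published heatmap gene-selection rule: keep genes with a
#' significant change from their glucose control (`p_adj < max_padj` in at
#' least one straw-vs-glucose comparison) and FPKM >= `min_fpkm` in at least
#' one straw condition, optionally restricted to an annotation-defined set
#' (e.g. CAZy genes only).  The glucose control column is retained in the
#' returned matrix for display.
#'
#' @param fpkm_by_condition gene x condition matrix of condition-mean FPKM.
#' @param padj gene x comparison matrix (or named vector) of adjusted
#'   p-values from the straw-vs-glucose tests.
#' @param straw_conditions,glucose_condition column names of
#'   `fpkm_by_condition`.
#' @param genes_allowed optional character vector restricting the result
#'   (annotation filter).
#' @param max_padj,min_fpkm selection thresholds (defaults 0.05 and 1).
#' @return numeric matrix (selected genes x `c(glucose, straw...)`); empty
#'   with a warning when nothing passes.
#' @export
select_cluster_genes <- function(fpkm_by_condition, padj, straw_conditions,
                                 glucose_condition, genes_allowed = NULL,
                                 max_padj = 0.05, min_fpkm = 1) {
  genes <- rownames(fpkm_by_condition)
  if (is.null(dim(padj))) padj <- cbind(padj)
  if (is.null(rownames(padj))) rownames(padj) <- genes
  if (!all(genes %in% rownames(padj))) {
    stop("padj must cover all genes in fpkm_by_condition")
  }
  padj <- padj[genes, , drop = FALSE]
  sig <- apply(padj, 1, min) < max_padj
  expressed <- apply(fpkm_by_condition[, straw_conditions, drop = FALSE],
                     1, max) >= min_fpkm
  keep <- sig & expressed
  if (!is.null(genes_allowed)) keep <- keep & genes %in% genes_allowed
  if (!any(keep)) {
    warning("no genes pass the clustering selection rule")
    return(fpkm_by_condition[FALSE, c(glucose_condition, straw_conditions),
                             drop = FALSE])
  }
  fpkm_by_condition[keep, c(glucose_condition, straw_conditions),
                    drop = FALSE]
}

#' Log-transform an expression matrix
#'
#' `x -> log2(x + offset)`; the default offset 1 preserves zeros.
#'
#' @param x non-negative numeric matrix or vector.
#' @param offset added before the log (default 1).
#' @return transformed object of the same shape.
#' @export
log_transform <- function(x, offset = 1) {
  if (any(x < 0, na.rm = TRUE)) stop("negative values cannot be log-transformed")
  log2(x + offset)
}

#' Uncentered-correlation distance between matrix rows
#'
#' The uncentered correlation `r_u(x, y) = sum(x*y) /
#' sqrt(sum(x^2) * sum(y^2))` is a cosine-type similarity that does not
#' subtract row means, so — unlike Pearson — it is sensitive to the
#' magnitude of the profiles.  The distance is `d = 1 - r_u`; rows that are
#' positive scalar multiples of each other are at distance 0, and
#' anti-correlated rows can reach d up to 2.
#'
#' @param x numeric matrix (rows = genes, columns = conditions).
#' @return symmetric distance matrix with zero diagonal.
#' @export
uncentered_correlation_distance <- function(x) {
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    stop("all-zero row(s): ",
         paste(rownames(x)[nrm == 0] %||% which(nrm == 0), collapse = ", "))
  }
  r <- (x %*% t(x)) / outer(nrm, nrm)
  d <- 1 - r
  d[d < 0 & d > -1e-12] <- 0  # numerical guard on the diagonal
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Complete-linkage agglomerative clustering
#'
#' Standard agglomeration with inter-cluster distance equal to the maximum
#' pairwise member distance.  At each step the closest active pair is
#' merged; ties are broken by the lexicographically smallest pair of active
#' cluster indices (original leaves first, then merge order).  The result is
#' an `hclust`-compatible object, so [stats::cutree()], `plot()` and
#' [dendrogram_newick()] all apply.
#'
#' @param d distance matrix (square symmetric) or `dist` object.
#' @return object of classes `complete_linkage` and `hclust` with `merge`,
#'   `height` (non-decreasing), `order`, and `labels`.
#' @export
complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two observations")
  labels <- rownames(d) %||% as.character(seq_len(n))
  # active cluster bookkeeping: id < 0 => leaf -id, id > 0 => merge row id
  active_ids <- -seq_len(n)     # hclust convention
  dm <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    m <- nrow(dm)
    best <- c(NA_integer_, NA_integer_); bd <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (dm[i, j] < bd - 1e-15) { bd <- dm[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(active_ids[i], active_ids[j]))
    height[step] <- bd
    # complete linkage update: max of the two merged rows
    newrow <- pmax(dm[i, ], dm[j, ])[-c(i, j)]
    keep <- setdiff(seq_len(m), c(i, j))
    dm <- dm[keep, keep, drop = FALSE]
    dm <- rbind(cbind(dm, newrow), c(newrow, 0))
    members[[length(members) + 1L]] <- c(members[[i]], members[[j]])
    members <- members[c(keep, length(members))]
    active_ids <- c(active_ids[keep], step)
  }
  order <- leaf_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "complete",
                 dist.method = "uncentered correlation"),
            class = c("complete_linkage", "hclust"))
}

leaf_order <- function(merge) {
  expand <- function(id) {
    if (id < 0) return(-id)
    c(expand(merge[id, 1]), expand(merge[id, 2]))
  }
  expand(nrow(merge))
}

#' Cut a dendrogram into flat clusters
#'
#' @param dend a [complete_linkage()] (or any `hclust`) object.
#' @param k desired number of clusters, or
#' @param h height to cut at (provide exactly one of `k`, `h`).
#' @return named integer vector of cluster labels.
#' @export
cut_dendrogram <- function(dend, k = NULL, h = NULL) {
  stats::cutree(dend, k = k, h = h)
}

#' Export a dendrogram in Newick format
#'
#' @param dend a [complete_linkage()] (or any `hclust`) object.
#' @param path optional file to write to.
#' @return the Newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Hypergeometric term enrichment of a gene list
#'
#' For each term, tests over-representation in `gene_list` against
#' `background` with the upper-tail hypergeometric probability
#' `P(X >= k)` where `N` = background size, `K` = background genes carrying
#' the term, `n` = list size, `k` = list genes carrying the term; BH
#' adjustment across terms.  Terms mapped only to genes outside the
#' background are skipped with a warning.
#'
#' @param gene_list character vector (must be a subset of `background`).
#' @param background character vector of all assayable genes.
#' @param term_map data.frame `gene_id`, `term` (flat map, no hierarchy).
#' @return data.frame of class `enrichment_result`: `term`, `N`, `K`, `n`,
#'   `k`, `p`, `p_adj`, ordered by `p`.
#' @export
hypergeom_enrich <- function(gene_list, background, term_map) {
  background <- unique(background)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% background)) {
    stop("gene_list must be a subset of background")
  }
  tm <- unique(term_map[, c("gene_id", "term")])
  orphan_terms <- setdiff(tm$term[!tm$gene_id %in% background],
                          tm$term[tm$gene_id %in% background])
  if (length(orphan_terms)) {
    warning("term(s) absent from background skipped: ",
            paste(orphan_terms, collapse = ", "))
  }
  tm <- tm[tm$gene_id %in% background, , drop = FALSE]
  if (!nrow(tm)) {
    return(structure(data.frame(term = character(0), N = integer(0),
                                K = integer(0), n = integer(0),
                                k = integer(0), p = numeric(0),
                                p_adj = numeric(0)),
                     class = c("enrichment_result", "data.frame")))
  }
  N <- length(background); n <- length(gene_list)
  K <- table(tm$term)
  in_list <- tm$gene_id %in% gene_list
  k <- table(factor(tm$term[in_list], levels = names(K)))
  p <- phyper(as.integer(k) - 1L, as.integer(K), N - as.integer(K), n,
              lower.tail = FALSE)
  out <- data.frame(term = names(K), N = N, K = as.integer(K), n = n,
                    k = as.integer(k), p = p, p_adj = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
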