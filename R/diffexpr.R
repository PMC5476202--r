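#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with nonzero counts in every sample) of the ratio of the gene's
#' count to its across-sample geometric mean.
#'
#' @param counts gene x sample count matrix.
#' @return named numeric vector of size factors `s_j`.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    stop("no gene has nonzero counts in every sample; consider a ",
         "pseudo-reference (e.g. add genes or pool samples)")
  }
  lg <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(lg)  # log geometric mean
  s <- apply(exp(lg - ref), 2, median)
  setNames(s, colnames(counts))
}

#' Moderated negative-binomial Wald test for two groups
#'
#' Counts are normalised by size factors (`q_gj = C_gj / s_j`).  A per-gene
#' dispersion is estimated by method of moments from the pooled within-group
#' variance of the normalised counts, floored at `1e-8`, then moderated
#' toward the across-gene median dispersion with prior weight `prior_df`
#' (information sharing across genes, in the spirit of count-based DE
#' tools, which keeps the test calibrated at 3-vs-3 replication without
#' sacrificing power).  The Wald statistic on the log2 difference of group
#' means uses the NB variance `mu + alpha * mu^2` propagated by the delta
#' method and is referred to a t distribution with
#' `prior_df + n1 + n2 - 2` degrees of freedom.  The reported fold change is
#' `log2((mean2 + eps) / (mean1 + eps))` with pseudo-mean `eps = 0.5`.
#'
#' @param counts gene x sample count matrix.
#' @param groups length-`ncol(counts)` vector with exactly two levels; the
#'   first level (factor order) is the reference/control group.
#' @param s size factors; default [size_factors()] of `counts`.
#' @param prior_df prior degrees of freedom for dispersion moderation.
#' @param eps pseudo-mean added before taking log2 fold changes.
#' @return data.frame: `gene`, `mean_ref`, `mean_test` (normalised group
#'   means), `log2fc`, `dispersion`, `stat`, `p`.
#' @export
nb_test <- function(counts, groups, s = size_factors(counts),
                    prior_df = 20, eps = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("need at least two samples per group")
  }
  q <- sweep(counts, 2, s, "/")
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(q[, g1, drop = FALSE])
  m2 <- rowMeans(q[, g2, drop = FALSE])
  v1 <- apply(q[, g1, drop = FALSE], 1, var)
  v2 <- apply(q[, g2, drop = FALSE], 1, var)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  mu <- (m1 + m2) / 2
  a_raw <- ifelse(mu > 0, pmax((sp2 - mu) / mu^2, 1e-8), 1e-8)
  a0 <- median(a_raw[mu > 0])
  if (!is.finite(a0)) a0 <- 1e-8
  alpha <- (prior_df * a0 + df * a_raw) / (prior_df + df)
  log2fc <- log2((m2 + eps) / (m1 + eps))
  vlog <- function(m, n) (m + alpha * m^2) / n / ((m + eps) * log(2))^2
  se <- sqrt(vlog(m1, n1) + vlog(m2, n2))
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pt(-abs(stat), df = prior_df + df)
  # degenerate genes: zero variance in both groups and equal means
  degen <- v1 == 0 & v2 == 0 & m1 == m2
  p[degen] <- 1; stat[degen] <- 0
  data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
             mean_ref = m1, mean_test = m2, log2fc = log2fc,
             dispersion = alpha, stat = stat, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj_(i) = min_{j >= i} ( n * p_(j) / j )`, capped at 1; ties are
#' handled stably.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Call differentially expressed genes under the study's filters
#'
#' A gene is called \emph{up} when its normalised-count fold change
#' (test / control, with pseudo-mean) is at least `min_fold`, `p_adj <
#' max_padj`, and its mean FPKM in the \emph{test} condition is at least
#' `min_fpkm`; \emph{down} requires fold `<= 1/min_fold`, the same `p_adj`
#' rule, and FPKM `>= min_fpkm` in the \emph{control} condition.  Defaults
#' are the published cut-offs: >= 2-fold on normalised counts (not FPKM),
#' `p_adj < 0.05`, and FPKM >= 1 in the relevant condition.
#'
#' @param stats output of [nb_test()] (control = `mean_ref`,
#'   test = `mean_test`).
#' @param fpkm_ref,fpkm_test per-gene FPKM in the control / test condition,
#'   either a vector (condition mean) or a gene x replicate matrix (its row
#'   means are used); names or row names must cover `stats$gene`.
#' @param min_fold,max_padj,min_fpkm the three thresholds.
#' @return object of class `de_result`: `table` (per-gene `gene`,
#'   `mean_ref`, `mean_test`, `log2fc`, `fold`, `p`, `p_adj`, `fold_pass`,
#'   `p_pass`, `fpkm_pass`, `call`) and the thresholds.  `call != "none"`
#'   implies all three flags are `TRUE`.
#' @export
call_de <- function(stats, fpkm_ref, fpkm_test, min_fold = 2,
                    max_padj = 0.05, min_fpkm = 1) {
  cond_mean <- function(x) {
    if (is.matrix(x)) setNames(rowMeans(x), rownames(x)) else x
  }
  fr <- cond_mean(fpkm_ref); ft <- cond_mean(fpkm_test)
  if (!all(stats$gene %in% names(fr)) || !all(stats$gene %in% names(ft))) {
    stop("FPKM vectors must cover all tested genes")
  }
  fr <- fr[stats$gene]; ft <- ft[stats$gene]
  p_adj <- bh_adjust(stats$p)
  fold <- 2^stats$log2fc
  up_fold <- fold >= min_fold
  down_fold <- fold <= 1 / min_fold
  p_pass <- p_adj < max_padj
  up_fpkm <- ft >= min_fpkm
  down_fpkm <- fr >= min_fpkm
  call <- ifelse(up_fold & p_pass & up_fpkm, "up",
                 ifelse(down_fold & p_pass & down_fpkm, "down", "none"))
  tab <- data.frame(
    gene = stats$gene, mean_ref = stats$mean_ref,
    mean_test = stats$mean_test, log2fc = stats$log2fc, fold = fold,
    p = stats$p, p_adj = p_adj,
    fold_pass = up_fold | down_fold, p_pass = p_pass,
    fpkm_pass = ifelse(call == "up", up_fpkm,
                       ifelse(call == "down", down_fpkm,
                              up_fpkm | down_fpkm)),
    call = call, row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, min_fold = min_fold, max_padj = max_padj,
                 min_fpkm = min_fpkm),
            class = "de_result")
}

#' Two-group differential expression pipeline for one species
#'
#' Convenience wrapper: size factors, moderated NB Wald test, BH adjustment
#' and threshold calling in one step.
#'
#' @param counts gene x sample counts for the two groups.
#' @param groups two-level grouping (first level = control).
#' @param fpkm gene x sample FPKM matrix aligned with `counts` (used only
#'   for the FPKM >= `min_fpkm` filter).
#' @param ... passed to [call_de()] (thresholds) and [nb_test()] is run with
#'   defaults.
#' @return a [call_de()] result with `size_factors` attached.
#' @export
de_test <- function(counts, groups, fpkm, ...) {
  groups <- as.factor(groups)
  s <- size_factors(counts)
  stats <- nb_test(counts, groups, s = s)
  g1 <- groups == levels(groups)[1]
  res <- call_de(stats, fpkm_ref = fpkm[, g1, drop = FALSE],
                 fpkm_test = fpkm[, !g1, drop = FALSE], ...)
  res$size_factors <- s
  res$groups <- groups
  res
}

#' @export
print.de_result <- function(x, ...) {
  tab <- table(x$table$call)
  cat(sprintf("de_result: %d genes tested; up %d, down %d (fold >= %g, p_adj < %g, FPKM >= %g)\n",
              nrow(x$table), sum(x$table$call == "up"),
              sum(x$table$call == "down"), x$min_fold, x$max_padj,
              x$min_fpkm))
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  t <- object$table
  out <- list(
    n = nrow(t), up = sum(t$call == "up"), down = sum(t$call == "down"),
    up_genes = t$gene[t$call == "up"], down_genes = t$gene[t$call == "down"]
  )
  class(out) <- "summary.de_result"
  out
}

#' @export
print.summary.de_result <- function(x, ...) {
  cat(sprintf("%d genes: %d up, %d down\n", x$n, x$up, x$down))
  invisible(x)
}
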