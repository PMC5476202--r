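#' Quantify a simulated study end to end
#'
#' Builds the composite reference from the study's genomes, assigns every
#' sample's read pairs, counts fragments per gene, and computes per-species
#' FPKM.
#'
#' @param study a [simulate_study()] object.
#' @param k k-mer size for the composite reference.
#' @param params an [assign_params()]; defaults to `assign_params(k)`.
#' @param stranded_mode passed to [gene_counts()].
#' @return list of class `quantified_study`: `ref`, `assignments` (named
#'   list per sample), `counts` ([gene_counts()]), `fpkm`
#'   ([compute_fpkm()]), `sheet`.
#' @export
quantify_study <- function(study, k = 31L, params = assign_params(k = k),
                           stranded_mode = "reverse") {
  stopifnot(inherits(study, "study"))
  ref <- build_composite_reference(study$genomes, k = k)
  assignments <- lapply(study$samples, function(s) {
    assign_reads(s$reads, ref, params)
  })
  counts <- gene_counts(assignments, study$genomes,
                        stranded_mode = stranded_mode)
  fpkm <- compute_fpkm(counts, study$genomes)
  structure(list(ref = ref, assignments = assignments, counts = counts,
                 fpkm = fpkm, sheet = study$sheet),
            class = "quantified_study")
}

#' @export
print.quantified_study <- function(x, ...) {
  cat("quantified_study:", length(x$assignments), "samples\n")
  print(x$counts)
  invisible(x)
}

#' Samples belonging to a condition
#'
#' @param sheet a [sample_sheet()] data.frame.
#' @param condition condition name.
#' @return character vector of sample ids.
#' @export
condition_samples <- function(sheet, condition) {
  sheet$sample_id[sheet$condition == condition]
}

#' Two-condition differential expression for one species of a study
#'
#' Subsets the species' counts and FPKM to the two conditions' samples and
#' runs [de_test()] with the study's DE filters (control = `cond_ref`).
#'
#' @param qs a [quantify_study()] result.
#' @param species species id.
#' @param cond_ref,cond_test condition names (control and test).
#' @param ... thresholds passed to [call_de()].
#' @return a `de_result`.
#' @export
study_de <- function(qs, species, cond_ref, cond_test, ...) {
  s_ref <- condition_samples(qs$sheet, cond_ref)
  s_test <- condition_samples(qs$sheet, cond_test)
  samples <- c(s_ref, s_test)
  counts <- qs$counts[[species]]$counts[, samples, drop = FALSE]
  fpkm <- qs$fpkm[[species]]$fpkm[, samples, drop = FALSE]
  groups <- factor(rep(c("ref", "test"), c(length(s_ref), length(s_test))),
                   levels = c("ref", "test"))
  de_test(counts, groups, fpkm, ...)
}
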