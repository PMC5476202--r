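#' Simulate condition-dependent true expression with planted effects
#'
#' Draws a heavy-tailed (log-normal) baseline transcript fraction per gene
#' and species, plants three disjoint effect classes, and produces expected
#' transcript fractions for every condition and replicate of the configured
#' study:
#' \itemize{
#'   \item \emph{straw-induced} genes (a fraction of the degradative CAZy
#'     genes, classes GH/CE/PL/AA) are multiplied by
#'     `cfg$straw_induction_fold` in any straw medium;
#'   \item \emph{mixed-down} genes are divided by `cfg$mixed_down_fold` in
#'     mixed cultures.  They are drawn from the straw-induced set (the
#'     biomass-degrading genes repressed by co-cultivation are the
#'     substrate-induced ones), so the straw induction applies to them too;
#'     their label is `mixed_down`;
#'   \item \emph{mixed-up} genes (a fraction of the non-CAZy genes) are
#'     multiplied by `cfg$mixed_up_fold` in mixed cultures.
#' }
#' After applying effects, fractions are renormalised to sum to 1 per
#' species-sample; per-replicate biological noise (log-normal,
#' `cfg$replicate_sdlog`) is multiplied in before renormalisation.
#'
#' @param cfg a [sim_config()] object.
#' @param genomes output of [generate_genomes()].
#' @param seed RNG seed; defaults to `cfg$seed + 1`.
#' @return object of class `true_expression`: list with
#'   `fractions[[condition]][[species]]` (genes x replicates matrix, columns
#'   summing to 1), `labels` (data.frame `species`, `gene_id`, `effect` in
#'   none/straw_induced/mixed_down/mixed_up), and `conditions` (data.frame
#'   `condition`, `medium`, `community` with list-column `species`).
#' @export
simulate_expression <- function(cfg, genomes, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(c(cfg$straw_induction_fold, cfg$mixed_down_fold,
            cfg$mixed_up_fold) <= 0)) {
    stop("effect folds must be > 0")
  }
  sheet <- sample_sheet(cfg)
  conds <- unique(sheet[, c("condition", "medium", "community")])
  conds$species <- lapply(conds$condition, function(cc) {
    names(sheet$proportions[[match(cc, sheet$condition)]])
  })
  rownames(conds) <- NULL

  with_seed(seed, {
    labels <- list(); fractions <- list()
    base_by_sp <- list(); lab_by_sp <- list()
    for (sp in cfg$species_ids) {
      g <- genomes[[sp]]
      ids <- g$annotations$gene_id
      n <- length(ids)
      base <- rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
      eff <- rep("none", n)
      degr <- which(g$annotations$cazy_class %in% c("GH", "CE", "PL", "AA"))
      n_ind <- round(cfg$frac_straw_induced * length(degr))
      ind_all <- if (n_ind > 0) sample(degr, n_ind) else integer(0)
      # mixed-repressed genes are a subset of the straw-induced ones
      n_down <- min(round(cfg$frac_mixed_down * length(degr)),
                    length(ind_all))
      down <- if (n_down > 0) sample(ind_all, n_down) else integer(0)
      ind <- setdiff(ind_all, down)
      noncazy <- which(is.na(g$annotations$cazy_class))
      n_up <- round(cfg$frac_mixed_up * length(noncazy))
      up <- if (n_up > 0) sample(noncazy, n_up) else integer(0)
      eff[down] <- "mixed_down"; eff[ind] <- "straw_induced"
      eff[up] <- "mixed_up"
      base_by_sp[[sp]] <- setNames(base, ids)
      lab_by_sp[[sp]] <- eff
      labels[[sp]] <- data.frame(species = sp, gene_id = ids, effect = eff,
                                 stringsAsFactors = FALSE)
    }
    for (ci in seq_len(nrow(conds))) {
      cc <- conds$condition[ci]
      fractions[[cc]] <- list()
      for (sp in conds$species[[ci]]) {
        b <- base_by_sp[[sp]]
        eff <- lab_by_sp[[sp]]
        if (conds$medium[ci] == "straw") {
          straw_set <- eff %in% c("straw_induced", "mixed_down")
          b[straw_set] <- b[straw_set] * cfg$straw_induction_fold
        }
        if (conds$community[ci] == "mixed") {
          b[eff == "mixed_down"] <- b[eff == "mixed_down"] / cfg$mixed_down_fold
          b[eff == "mixed_up"] <- b[eff == "mixed_up"] * cfg$mixed_up_fold
        }
        m <- matrix(NA_real_, length(b), cfg$n_replicates,
                    dimnames = list(names(b),
                                    paste0("r", seq_len(cfg$n_replicates))))
        for (r in seq_len(cfg$n_replicates)) {
          noisy <- b * rlnorm(length(b), 0, cfg$replicate_sdlog)
          m[, r] <- noisy / sum(noisy)
        }
        fractions[[cc]][[sp]] <- m
      }
    }
    structure(list(fractions = fractions,
                   labels = do.call(rbind, labels),
                   conditions = conds),
              class = "true_expression")
  })
}

#' @export
print.true_expression <- function(x, ...) {
  tab <- table(x$labels$effect)
  cat("true_expression:", nrow(x$conditions), "conditions,",
      length(unique(x$labels$species)), "species\n")
  cat("  planted effects:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
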