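#' Configuration for a synthetic mixed-culture study
#'
#' Collects every tunable of the synthetic-data generator.  Defaults emulate
#' the design of a three-species fungal co-culture experiment on wheat straw:
#' glucose and straw monocultures for each species plus mixed straw cultures,
#' three biological replicates, paired 2 x 75 bp reads, and sequencing depth
#' in a 30:100 mono-to-mixed ratio (scaled down from ~30 M and ~100 M
#' fragments per sample to desk scale by a factor of 10^3).
#'
#' @param n_species number of species in the community.
#' @param species_ids character ids; defaults to `"spA"`, `"spB"`, ...
#' @param genome_length_bp length of each (single-contig) genome.
#' @param n_genes protein-coding genes per species.
#' @param gene_length_range min/max gene length in bp (single-exon models).
#' @param divergence target *pairwise* substitution fraction between any two
#'   species, in `[0, 1)`.  Each species is mutated independently from a
#'   common ancestor at the per-site rate that yields this expected pairwise
#'   mismatch fraction.
#' @param read_length read length in bp (paired-end, both mates).
#' @param fragment_length_mean,fragment_length_sd fragment-size distribution.
#' @param error_rate per-base sequencing substitution error rate.
#' @param depth_mono,depth_mixed fragments per monoculture / mixed-culture
#'   sample (the study design sequenced mixtures ~3.3x deeper).
#' @param mixtures list of character vectors of species ids grown together on
#'   straw; default is the single community of all species.
#' @param mix_proportions optional named list: for each mixture (named by
#'   `paste(sort(ids), collapse="_")`) a vector of fractions summing to 1.
#'   Default: equal shares.
#' @param n_replicates biological replicates per condition.
#' @param cazy_fraction fraction of genes carrying a CAZy family label.
#' @param straw_induction_fold expression multiplier applied to
#'   straw-induced genes in straw media (monoculture or mixed).
#' @param mixed_down_fold,mixed_up_fold fold applied to the planted
#'   mixed-culture-repressed / -induced gene subsets in mixed cultures.
#' @param frac_straw_induced,frac_mixed_down,frac_mixed_up fractions of the
#'   degradative CAZy (induced/repressed) and non-CAZy (up) gene sets
#'   carrying planted effects; the mixed-repressed genes are drawn from the
#'   straw-induced set (use `frac_mixed_down <= frac_straw_induced`).
#' @param expr_meanlog,expr_sdlog log-normal baseline expression parameters
#'   (heavy-tailed transcript fractions, as observed in fungal transcriptomes).
#' @param replicate_sdlog log-normal biological noise multiplied into each
#'   replicate's expected fractions before renormalisation.
#' @param rrna_copies true copy number of the multi-copy 5.8S-analogue rRNA
#'   marker per genome (rDNA repeats).
#' @param marker_length length in bp of each marker locus.
#' @param n_discriminating number of species-discriminating positions forced
#'   into the rRNA marker.
#' @param seed integer seed governing all generator randomness.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 3L,
                       species_ids = NULL,
                       genome_length_bp = 100000L,
                       n_genes = 200L,
                       gene_length_range = c(300L, 600L),
                       divergence = 0.10,
                       read_length = 75L,
                       fragment_length_mean = 180,
                       fragment_length_sd = 20,
                       error_rate = 0.001,
                       depth_mono = 30000L,
                       depth_mixed = 100000L,
                       mixtures = NULL,
                       mix_proportions = NULL,
                       n_replicates = 3L,
                       cazy_fraction = 0.3,
                       straw_induction_fold = 5,
                       mixed_down_fold = 4,
                       mixed_up_fold = 3,
                       frac_straw_induced = 0.5,
                       frac_mixed_down = 0.3,
                       frac_mixed_up = 0.05,
                       expr_meanlog = 0,
                       expr_sdlog = 1.2,
                       replicate_sdlog = 0.1,
                       rrna_copies = 50L,
                       marker_length = 160L,
                       n_discriminating = 8L,
                       seed = 1L) {
  if (is.null(species_ids)) {
    species_ids <- paste0("sp", LETTERS[seq_len(n_species)])
  }
  if (length(species_ids) != n_species || anyDuplicated(species_ids)) {
    stop("species_ids must be ", n_species, " unique ids")
  }
  if (!is.numeric(divergence) || divergence < 0 || divergence >= 1) {
    stop("divergence must lie in [0, 1)")
  }
  if (depth_mono <= 0 || depth_mixed <= 0) stop("depth must be > 0")
  if (any(c(straw_induction_fold, mixed_down_fold, mixed_up_fold) <= 0)) {
    stop("effect folds must be > 0")
  }
  if (is.null(mixtures)) mixtures <- list(species_ids)
  mixtures <- lapply(mixtures, function(m) {
    if (!all(m %in% species_ids)) stop("mixture names unknown species")
    sort(m)
  })
  if (!is.null(mix_proportions)) {
    for (nm in names(mix_proportions)) {
      p <- mix_proportions[[nm]]
      if (abs(sum(p) - 1) > 1e-9) {
        stop("mix proportions for '", nm, "' must sum to 1 (tol 1e-9)")
      }
    }
  }
  cfg <- list(
    n_species = as.integer(n_species), species_ids = species_ids,
    genome_length_bp = as.integer(genome_length_bp),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    divergence = divergence, read_length = as.integer(read_length),
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd, error_rate = error_rate,
    depth_mono = as.integer(depth_mono),
    depth_mixed = as.integer(depth_mixed),
    mixtures = mixtures, mix_proportions = mix_proportions,
    n_replicates = as.integer(n_replicates),
    cazy_fraction = cazy_fraction,
    straw_induction_fold = straw_induction_fold,
    mixed_down_fold = mixed_down_fold, mixed_up_fold = mixed_up_fold,
    frac_straw_induced = frac_straw_induced,
    frac_mixed_down = frac_mixed_down, frac_mixed_up = frac_mixed_up,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    replicate_sdlog = replicate_sdlog,
    rrna_copies = as.integer(rrna_copies),
    marker_length = as.integer(marker_length),
    n_discriminating = as.integer(n_discriminating),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Any field of [sim_config()] may appear in the file; missing fields take
#' their defaults.
#'
#' @param path path to a YAML file.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic mixed-culture study configuration\n")
  cat("  species:      ", paste(x$species_ids, collapse = ", "), "\n")
  cat("  genome:       ", x$genome_length_bp, "bp,", x$n_genes, "genes\n")
  cat("  divergence:   ", x$divergence, "(pairwise)\n")
  cat("  reads:        2 x", x$read_length, "bp, error", x$error_rate, "\n")
  cat("  depth:        ", x$depth_mono, "(mono) /", x$depth_mixed,
      "(mixed) fragments\n")
  cat("  replicates:   ", x$n_replicates, "\n")
  cat("  mixtures:     ",
      paste(vapply(x$mixtures, paste, "", collapse = "+"), collapse = "; "),
      "\n")
  invisible(x)
}

#' Sample sheet for a configured study
#'
#' Expands the configured conditions into one row per sequenced sample:
#' a glucose and a straw monoculture for every species plus each configured
#' straw mixture, all with `n_replicates` replicates.
#'
#' @param cfg a [sim_config()] object.
#' @return data.frame with columns `sample_id`, `condition`, `medium`,
#'   `community`, `replicate`, `depth`, and a list-column `proportions`
#'   (named species fractions summing to 1).
#' @export
sample_sheet <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- list()
  add <- function(condition, medium, community, sp, props, depth) {
    for (r in seq_len(cfg$n_replicates)) {
      rows[[length(rows) + 1L]] <<- list(
        sample_id = sprintf("%s.r%d", condition, r),
        condition = condition, medium = medium, community = community,
        replicate = r, depth = depth, proportions = list(setNames(props, sp))
      )
    }
  }
  for (sp in cfg$species_ids) {
    add(paste0("glucose.", sp), "glucose", "mono", sp, 1, cfg$depth_mono)
    add(paste0("straw.", sp), "straw", "mono", sp, 1, cfg$depth_mono)
  }
  for (mix in cfg$mixtures) {
    nm <- paste(mix, collapse = "_")
    props <- if (!is.null(cfg$mix_proportions) &&
                 nm %in% names(cfg$mix_proportions)) {
      cfg$mix_proportions[[nm]]
    } else rep(1 / length(mix), length(mix))
    add(paste0("mix.", nm), "straw", "mixed", mix, props, cfg$depth_mixed)
  }
  out <- data.frame(
    sample_id = vapply(rows, `[[`, "", "sample_id"),
    condition = vapply(rows, `[[`, "", "condition"),
    medium = vapply(rows, `[[`, "", "medium"),
    community = vapply(rows, `[[`, "", "community"),
    replicate = vapply(rows, `[[`, 0L, "replicate"),
    depth = vapply(rows, `[[`, 0L, "depth"),
    stringsAsFactors = FALSE
  )
  out$proportions <- lapply(rows, function(r) r$proportions[[1]])
  out
}
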