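#' Simulate truth-labelled paired reads for one sample
#'
#' Emulates a directional (dUTP-style) paired-end library: for each fragment
#' the species is drawn from the sample's mix proportions, the gene from the
#' species' expected transcript fractions, and the fragment is placed
#' uniformly within the (spliced) transcript.  Mate 2 is the sense strand of
#' the fragment start, mate 1 the reverse complement of the fragment end
#' (read 1 antisense to the transcript, as in Illumina directional kits).
#' A fixed per-base substitution error rate is applied.  Fragments longer
#' than their transcript are resampled (with a summary warning).
#'
#' @param genomes output of [generate_genomes()].
#' @param expr a [simulate_expression()] object.
#' @param sample_spec list with `sample_id`, `condition`, `replicate`,
#'   `proportions` (named fractions summing to 1), `depth`, and optionally
#'   `read_length` (75), `fragment_length_mean` (180), `fragment_length_sd`
#'   (20), `error_rate` (0.001).
#' @param seed RNG seed.
#' @return list of class `read_sim` with `reads` (class `read_pairs`:
#'   data.table `fragment_id`, `seq1`, `seq2`) and `truth` (data.table
#'   `fragment_id`, `species`, `gene_id`, `contig`, `start`, `end`,
#'   `strand`), one truth record per simulated fragment.
#' @export
simulate_read_pairs <- function(genomes, expr, sample_spec, seed = 1L) {
  props <- sample_spec$proportions
  if (abs(sum(props) - 1) > 1e-9) stop("mix proportions must sum to 1")
  depth <- sample_spec$depth
  if (is.null(depth) || depth <= 0) stop("depth must be > 0")
  rl <- sample_spec$read_length %||% 75L
  fl_mean <- sample_spec$fragment_length_mean %||% 180
  fl_sd <- sample_spec$fragment_length_sd %||% 20
  err <- sample_spec$error_rate %||% 0.001
  cond <- sample_spec$condition
  repl <- sample_spec$replicate %||% 1L
  sid <- sample_spec$sample_id %||% cond

  with_seed(seed, {
    sp_draw <- if (length(props) == 1L) rep(names(props), depth) else
      sample(names(props), depth, replace = TRUE, prob = props)
    frag_sp <- character(depth); frag_gene <- character(depth)
    frag_ct <- character(depth); frag_start <- integer(depth)
    frag_end <- integer(depth); frag_strand <- character(depth)
    frag_seq <- character(depth)
    n_resampled <- 0L

    for (sp in unique(sp_draw)) {
      idx <- which(sp_draw == sp)
      g <- genomes[[sp]]
      fr <- expr$fractions[[cond]][[sp]][, repl]
      gm <- g$gene_models
      # simulation uses single-exon transcripts (one row per gene)
      stopifnot(!anyDuplicated(gm$gene_id))
      gi <- sample.int(nrow(gm), length(idx), replace = TRUE,
                       prob = fr[gm$gene_id])
      glen <- gm$end[gi] - gm$start[gi] + 1L
      flen <- pmax(rl, as.integer(round(rnorm(length(idx), fl_mean, fl_sd))))
      for (it in 1:100) {
        bad <- which(flen > glen)
        if (!length(bad)) break
        n_resampled <- n_resampled + length(bad)
        flen[bad] <- pmax(rl, as.integer(round(rnorm(length(bad),
                                                     fl_mean, fl_sd))))
        if (it == 100L) flen[flen > glen] <- glen[flen > glen]
      }
      pos <- floor(runif(length(idx)) * (glen - flen + 1)) + 1L
      plus <- gm$strand[gi] == "+"
      gstart <- ifelse(plus, gm$start[gi] + pos - 1L,
                       gm$end[gi] - pos - flen + 2L)
      gend <- gstart + flen - 1L
      ctg <- gm$contig[gi]
      raw <- substring(g$contigs[ctg], gstart, gend)
      if (any(!plus)) raw[!plus] <- revcomp(raw[!plus])
      frag_sp[idx] <- sp; frag_gene[idx] <- gm$gene_id[gi]
      frag_ct[idx] <- ctg; frag_start[idx] <- gstart
      frag_end[idx] <- gend; frag_strand[idx] <- gm$strand[gi]
      frag_seq[idx] <- raw
    }
    if (n_resampled > 0) {
      warning(n_resampled,
              " fragment draws exceeded their transcript and were resampled")
    }
    flen_all <- nchar(frag_seq)
    seq2 <- substr(frag_seq, 1L, rl)
    seq1 <- revcomp(substring(frag_seq, flen_all - rl + 1L, flen_all))

    # sequencing errors: substitute random different bases
    n_bases <- 2L * depth * rl
    n_err <- rbinom(1, n_bases, err)
    if (n_err > 0) {
      hit <- sort(sample.int(n_bases, n_err))
      mate <- ifelse(hit <= depth * rl, 1L, 2L)
      within <- ifelse(mate == 1L, hit, hit - depth * rl) - 1L
      ridx <- within %/% rl + 1L
      bpos <- within %% rl + 1L
      for (m in 1:2) {
        sel <- which(mate == m)
        if (!length(sel)) next
        tgt <- if (m == 1L) seq1 else seq2
        for (rid in unique(ridx[sel])) {
          pp <- bpos[sel][ridx[sel] == rid]
          tgt[rid] <- mutate_positions(tgt[rid], pp)
        }
        if (m == 1L) seq1 <- tgt else seq2 <- tgt
      }
    }
    fid <- sprintf("%s.f%07d", sid, seq_len(depth))
    reads <- data.table::data.table(fragment_id = fid, seq1 = seq1,
                                    seq2 = seq2)
    data.table::setattr(reads, "read_length", rl)
    data.table::setattr(reads, "class",
                        c("read_pairs", class(reads)))
    truth <- data.table::data.table(
      fragment_id = fid, species = frag_sp, gene_id = frag_gene,
      contig = frag_ct, start = frag_start, end = frag_end,
      strand = frag_strand
    )
    structure(list(reads = reads, truth = truth, sample_id = sid),
              class = "read_sim")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete study: genomes, expression and all samples
#'
#' Convenience wrapper running [generate_genomes()],
#' [simulate_expression()], and [simulate_read_pairs()] for every row of the
#' study's [sample_sheet()].  Per-sample seeds are derived deterministically
#' from `cfg$seed`.
#'
#' @param cfg a [sim_config()] object.
#' @return list of class `study`: `cfg`, `genomes`, `expr`, `sheet`,
#'   `samples` (named list of `read_sim` objects).
#' @export
simulate_study <- function(cfg) {
  genomes <- generate_genomes(cfg)
  expr <- simulate_expression(cfg, genomes)
  sheet <- sample_sheet(cfg)
  samples <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    spec <- list(
      sample_id = sheet$sample_id[i], condition = sheet$condition[i],
      replicate = sheet$replicate[i], proportions = sheet$proportions[[i]],
      depth = sheet$depth[i], read_length = cfg$read_length,
      fragment_length_mean = cfg$fragment_length_mean,
      fragment_length_sd = cfg$fragment_length_sd,
      error_rate = cfg$error_rate
    )
    samples[[i]] <- simulate_read_pairs(genomes, expr, spec,
                                        seed = cfg$seed + 1000L + i)
  }
  names(samples) <- sheet$sample_id
  structure(list(cfg = cfg, genomes = genomes, expr = expr, sheet = sheet,
                 samples = samples), class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat("Synthetic study:", length(x$genomes), "species,",
      nrow(x$sheet), "samples,",
      sum(x$sheet$depth), "fragments total\n")
  invisible(x)
}
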