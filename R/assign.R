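#' Build a composite multi-species k-mer reference
#'
#' Concatenates all member genomes into one reference, tagging each contig as
#' `<species>|<contig>`, and indexes every k-mer of both strands.  This is
#' the data structure behind unique-read species attribution: a read pair is
#' attributed to a species only when its k-mer support is unique to that
#' species, mirroring the exclusion of non-uniquely-mapping reads on a
#' concatenated reference genome.
#'
#' Minus-strand entries store the reverse complement of the forward k-mer at
#' the same forward-coordinate start, so a read matching the reverse strand
#' is located without re-complementing the reference.  An optional mask
#' removes k-mers overlapping given intervals (parity with repeat-masked
#' references); by default no masking is applied.
#'
#' @param genomes list of `species_genome` objects (>= 2, unique ids).
#' @param k k-mer size (default 31).
#' @param mask optional data.frame `species`, `contig`, `start`, `end`:
#'   k-mers overlapping any masked interval are excluded from the index.
#' @return object of class `composite_reference`: list with `index` (keyed
#'   data.table `kmer`, `species`, `contig`, `pos`, `strand`), `contigs`
#'   (named character, tagged ids), `contig_species` (named character),
#'   `k`, and `species` (ids).
#' @export
build_composite_reference <- function(genomes, k = 31L, mask = NULL) {
  if (length(genomes) < 2L) stop("need at least two genomes")
  ids <- vapply(genomes, function(g) g$species_id, "")
  if (anyDuplicated(ids)) stop("duplicate species id in genomes")
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive")

  parts <- list(); comp <- character(0); comp_sp <- character(0)
  for (g in genomes) {
    for (ct in names(g$contigs)) {
      seq <- g$contigs[[ct]]
      tagged <- paste0(g$species_id, "|", ct)
      comp[tagged] <- seq
      comp_sp[tagged] <- g$species_id
      n <- nchar(seq)
      if (n < k) next
      pos <- seq_len(n - k + 1L)
      fwd <- substring(seq, pos, pos + k - 1L)
      if (!is.null(mask)) {
        mi <- mask[mask$species == g$species_id & mask$contig == ct, ,
                   drop = FALSE]
        if (nrow(mi)) {
          bad <- rep(FALSE, length(pos))
          for (j in seq_len(nrow(mi))) {
            bad <- bad | (pos <= mi$end[j] & pos + k - 1L >= mi$start[j])
          }
          pos <- pos[!bad]; fwd <- fwd[!bad]
          if (!length(pos)) next
        }
      }
      rev <- revcomp(fwd)
      parts[[length(parts) + 1L]] <- data.table::data.table(
        kmer = c(fwd, rev), species = g$species_id, contig = ct,
        pos = c(pos, pos), strand = rep(c("+", "-"), each = length(pos))
      )
    }
  }
  index <- data.table::rbindlist(parts)
  data.table::setkey(index, kmer)
  structure(list(index = index, contigs = comp, contig_species = comp_sp,
                 k = k, species = unname(ids)),
            class = "composite_reference")
}

#' @export
print.composite_reference <- function(x, ...) {
  cat("composite_reference:", length(x$species), "species,",
      length(x$contigs), "contigs,", sum(nchar(x$contigs)), "bp, k =",
      x$k, "(", nrow(x$index), "indexed k-mer positions )\n")
  invisible(x)
}

#' Write the composite reference to a single FASTA file
#'
#' @param ref a `composite_reference`.
#' @param path output FASTA; contigs appear as `<species>|<contig>`.
#' @return invisibly, `path`.
#' @export
write_composite_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$contigs), path,
                              width = 80L)
  invisible(path)
}

#' Assignment parameters
#'
#' @param k k-mer size (must match the reference).
#' @param min_hits minimum supporting k-mer hits for the best species; pairs
#'   below this in every species are `unmapped`.
#' @param margin maximum allowed ratio of second-best to best species hits
#'   for a `unique` verdict.  The default 0 is zero-tolerance: any hit in a
#'   second species voids uniqueness (the strictest reading of "unique to a
#'   particular species").
#' @return a list of class `assign_params`.
#' @export
assign_params <- function(k = 31L, min_hits = 2L, margin = 0) {
  if (margin < 0 || margin > 1) stop("margin must be in [0, 1]")
  if (min_hits < 1L) stop("min_hits must be >= 1")
  structure(list(k = as.integer(k), min_hits = as.integer(min_hits),
                 margin = margin), class = "assign_params")
}

#' Assign read pairs to species by exact k-mer voting
#'
#' For each pair, every k-mer of both mates is looked up in the composite
#' index; a query k-mer contributes at most one hit per species.  The pair
#' is `unique(s)` iff `hits(s) >= min_hits` and `hits(s') <= margin *
#' hits(s)` for every other species, `unmapped` iff all species fall below
#' `min_hits`, otherwise `ambiguous`.  For unique pairs the locus is
#' inferred from the matches of the winning species on its modal contig;
#' the reported strand is the reference strand that mate 1 matches (under a
#' directional dUTP library mate 1 is antisense, so a fragment from a `+`
#' gene reports strand `-`).
#'
#' @param reads a `read_pairs` object (columns `fragment_id`, `seq1`,
#'   `seq2`), e.g. from [simulate_read_pairs()] or [read_fastq_pair()].
#' @param ref a [build_composite_reference()] object.
#' @param params an [assign_params()] object; `params$k` must equal `ref$k`.
#' @param chunk_size pairs processed per index join (memory control).
#' @return data.table of class `read_assignments`: `fragment_id`, `verdict`
#'   (`unique`/`ambiguous`/`unmapped`), `species` (`NA` unless unique),
#'   `contig`, `start`, `end`, `strand` (inferred locus, `NA` unless
#'   unique), plus `hits_<species>` columns.
#' @export
assign_reads <- function(reads, ref, params = assign_params(k = ref$k),
                         chunk_size = 20000L) {
  stopifnot(inherits(ref, "composite_reference"))
  if (params$k != ref$k) stop("params$k must match ref$k")
  k <- ref$k
  n <- nrow(reads)
  if (n == 0L) {
    warning("empty read set")
    return(empty_assignments(ref$species))
  }
  if (any(nchar(reads$seq1) < k) || any(nchar(reads$seq2) < k)) {
    stop("reads shorter than k")
  }
  out <- vector("list", ceiling(n / chunk_size))
  for (ci in seq_along(out)) {
    rows <- ((ci - 1L) * chunk_size + 1L):min(ci * chunk_size, n)
    out[[ci]] <- assign_chunk(reads[rows, ], ref, params)
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "class",
                      c("read_assignments", class(res)))
  data.table::setattr(res, "species", ref$species)
  res
}

empty_assignments <- function(species) {
  res <- data.table::data.table(
    fragment_id = character(0), verdict = character(0),
    species = character(0), contig = character(0),
    start = integer(0), end = integer(0), strand = character(0)
  )
  for (sp in species) res[, paste0("hits_", sp) := integer(0)]
  data.table::setattr(res, "class", c("read_assignments", class(res)))
  data.table::setattr(res, "species", species)
  res
}

# Core per-chunk work: query-k-mer table, index join, vote, locus inference.
assign_chunk <- function(reads, ref, params) {
  k <- ref$k
  qparts <- list()
  for (m in 1:2) {
    seqs <- if (m == 1) reads$seq1 else reads$seq2
    len <- nchar(seqs)
    nk <- len - k + 1L
    fid <- rep.int(seq_len(nrow(reads)), nk)
    off <- sequence(nk)
    qparts[[m]] <- data.table::data.table(
      fid = fid, mate = m, off = off, len = len[fid],
      kmer = substring(seqs[fid], off, off + k - 1L)
    )
  }
  q <- data.table::rbindlist(qparts)
  hitsm <- ref$index[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]

  nsp <- length(ref$species)
  hitmat <- matrix(0L, nrow(reads), nsp,
                   dimnames = list(NULL, ref$species))
  if (nrow(hitsm)) {
    # one vote per distinct query k-mer per species
    votes <- unique(hitsm, by = c("fid", "mate", "off", "species"))
    cnt <- votes[, .N, by = .(fid, species)]
    hitmat[cbind(cnt$fid, match(cnt$species, ref$species))] <- cnt$N
  }
  best <- max.col(hitmat, ties.method = "first")
  best_hits <- hitmat[cbind(seq_len(nrow(reads)), best)]
  second <- if (nsp == 1L) {
    integer(nrow(reads))
  } else {
    hm2 <- hitmat
    hm2[cbind(seq_len(nrow(reads)), best)] <- -1L
    do.call(pmax, as.data.frame(hm2))
  }
  verdict <- ifelse(
    best_hits < params$min_hits, "unmapped",
    ifelse(second <= params$margin * best_hits, "unique", "ambiguous")
  )
  win_sp <- ifelse(verdict == "unique", ref$species[best], NA_character_)

  res <- data.table::data.table(
    fragment_id = reads$fragment_id, verdict = verdict, species = win_sp,
    contig = NA_character_, start = NA_integer_, end = NA_integer_,
    strand = NA_character_
  )
  uniq <- which(verdict == "unique")
  if (length(uniq) && nrow(hitsm)) {
    hw <- hitsm[data.table::data.table(fid = uniq,
                                       species = win_sp[uniq]),
                on = c("fid", "species"), nomatch = NULL]
    # modal contig per fragment
    cct <- hw[, .N, by = .(fid, contig)]
    data.table::setorder(cct, fid, -N, contig)
    mct <- cct[!duplicated(fid)]
    hw <- hw[mct[, .(fid, contig)], on = c("fid", "contig")]
    # genomic span: '-' entries store the revcomp k-mer at the forward
    # coordinate, so both strands use pos directly
    span <- hw[, .(start = min(pos), end = max(pos) + k - 1L), by = fid]
    # reported strand = modal strand of mate-1 matches (flip mate-2's when
    # mate 1 has no hits on the modal contig)
    sct <- hw[, .N, by = .(fid, mate, strand)]
    data.table::setorder(sct, fid, mate, -N, strand)
    sct <- sct[!duplicated(data.table::data.table(sct$fid, sct$mate))]
    s1 <- sct[mate == 1L]; s2 <- sct[mate == 2L]
    st <- setNames(rep(NA_character_, length(uniq)), uniq)
    st[as.character(s2$fid)] <- ifelse(s2$strand == "+", "-", "+")
    st[as.character(s1$fid)] <- s1$strand
    res[span$fid, `:=`(contig = mct$contig[match(span$fid, mct$fid)],
                       start = span$start, end = span$end,
                       strand = unname(st[as.character(span$fid)]))]
  }
  for (j in seq_len(nsp)) {
    res[, paste0("hits_", ref$species[j]) := hitmat[, j]]
  }
  res
}

#' Confusion matrix of species assignment against simulation truth
#'
#' @param truth truth table from [simulate_read_pairs()] (`fragment_id`,
#'   `species`).
#' @param assignments a [assign_reads()] result covering the same fragments.
#' @return list of class `assignment_confusion`: `counts` (true species x
#'   assigned category), `rates` (rows normalised to 1), `misassignment`
#'   (fraction of all fragments uniquely assigned to a wrong species),
#'   `unique_fraction`, `ambiguous_fraction`, `unmapped_fraction`, and
#'   `unique_correct_fraction`.
#' @export
assignment_confusion <- function(truth, assignments) {
  if (!setequal(truth$fragment_id, assignments$fragment_id)) {
    stop("truth and assignments cover different fragment ids")
  }
  m <- merge(as.data.frame(truth[, c("fragment_id", "species")]),
             as.data.frame(assignments[, c("fragment_id", "verdict",
                                           "species")]),
             by = "fragment_id", suffixes = c("_true", "_called"))
  cat_called <- ifelse(m$verdict == "unique", m$species_called, m$verdict)
  all_sp <- sort(unique(m$species_true))
  lev <- c(all_sp, "ambiguous", "unmapped")
  counts <- table(factor(m$species_true, all_sp),
                  factor(cat_called, lev))
  rates <- counts / rowSums(counts)
  uniq <- m$verdict == "unique"
  structure(list(
    counts = unclass(counts), rates = unclass(rates),
    misassignment = mean(uniq & m$species_called != m$species_true),
    unique_fraction = mean(uniq),
    ambiguous_fraction = mean(m$verdict == "ambiguous"),
    unmapped_fraction = mean(m$verdict == "unmapped"),
    unique_correct_fraction = mean(uniq & m$species_called == m$species_true)
  ), class = "assignment_confusion")
}

#' @export
print.assignment_confusion <- function(x, ...) {
  cat("assignment confusion (true species x assigned):\n")
  print(x$counts)
  cat(sprintf("unique %.3f (correct %.3f), ambiguous %.3f, unmapped %.3f, misassignment %.4f\n",
              x$unique_fraction, x$unique_correct_fraction,
              x$ambiguous_fraction, x$unmapped_fraction, x$misassignment))
  invisible(x)
}
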