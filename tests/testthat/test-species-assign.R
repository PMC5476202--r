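test_that("composite reference concatenates and tags all contigs", {
  cfg <- sim_config(n_species = 2, genome_length_bp = 10000, n_genes = 10,
                    rrna_copies = 3, seed = 2)
  g <- generate_genomes(cfg)
  ref <- build_composite_reference(g, k = 31)
  expect_identical(sum(nchar(ref$contigs)), 20000L)
  expect_setequal(names(ref$contigs), c("spA|chr1", "spB|chr1"))
  expect_identical(unname(ref$contig_species["spA|chr1"]), "spA")
  # every indexed k-mer occurs verbatim at its recorded position/strand
  idx <- ref$index[sample(nrow(ref$index), 50)]
  for (i in seq_len(nrow(idx))) {
    seq <- g[[idx$species[i]]]$contigs[[idx$contig[i]]]
    fwd <- substr(seq, idx$pos[i], idx$pos[i] + ref$k - 1)
    expect_identical(idx$kmer[i],
                     if (idx$strand[i] == "+") fwd else revcomp_chr(fwd))
  }
})

test_that("duplicate species ids are rejected", {
  g <- handmade_genomes()
  g2 <- g; g2$spY$species_id <- "spX"
  expect_error(build_composite_reference(g2), "duplicate species id")
})

test_that("a k-mer unique to one genome has a single forward index entry", {
  g <- handmade_genomes(diverge_at = 150)
  ref <- build_composite_reference(g, k = 31)
  km <- substr(g$spX$contigs[["chr1"]], 135, 165)  # spans the divergent site
  hits <- ref$index[ref$index$kmer == km & ref$index$strand == "+", ]
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$species, "spX")
  expect_identical(hits$pos, 135L)
})

test_that("masked intervals are excluded from the index", {
  g <- handmade_genomes()
  mask <- data.frame(species = "spX", contig = "chr1",
                     start = 1L, end = 600L)
  ref <- build_composite_reference(g, k = 31, mask = mask)
  expect_identical(nrow(ref$index[species == "spX" & pos <= 570]), 0L)
  refu <- build_composite_reference(g, k = 31)
  expect_gt(nrow(refu$index[species == "spX" & pos <= 570]), 0L)
})

test_that("reads over a divergent site are unique; identical regions tie", {
  g <- handmade_genomes(diverge_at = seq(105, 895, by = 20))
  ref <- build_composite_reference(g, k = 31)
  par <- assign_params(k = 31, min_hits = 2, margin = 0)
  # gene gA (101..400, '+'): every read k-mer spans a divergent site
  rX <- pair_from_gene(g$spX, "spX_gA", offset = 50)
  aX <- assign_reads(rX, ref, par)
  expect_identical(aX$verdict, "unique")
  expect_identical(aX$species, "spX")
  rY <- pair_from_gene(g$spY, "spY_gA", offset = 50)
  expect_identical(assign_reads(rY, ref, par)$species, "spY")
  # a fragment avoiding both divergent sites is a perfect tie
  g0 <- handmade_genomes(diverge_at = integer(0))
  ref0 <- build_composite_reference(g0, k = 31)
  a0 <- assign_reads(pair_from_gene(g0$spX, "spX_gA", offset = 50),
                     ref0, par)
  expect_identical(a0$verdict, "ambiguous")
})

test_that("inferred locus covers the true fragment and reports mate-1 strand", {
  g <- handmade_genomes(diverge_at = seq(105, 895, by = 20))
  ref <- build_composite_reference(g, k = 31)
  par <- assign_params(k = 31)
  # '+' gene: fragment at 150..299; mate 1 is antisense => strand '-'
  a <- assign_reads(pair_from_gene(g$spX, "spX_gA", offset = 50), ref, par)
  expect_identical(a$verdict, "unique")
  expect_identical(a$contig, "chr1")
  expect_identical(a$strand, "-")
  expect_gte(a$start, 150L); expect_lte(a$end, 299L)
  expect_gt(a$end - a$start, 100L)
  # '-' gene gB (601..900): mate 1 matches the forward strand
  b <- assign_reads(pair_from_gene(g$spX, "spX_gB", offset = 50), ref, par)
  expect_identical(b$strand, "+")
  expect_gte(b$start, 601L); expect_lte(b$end, 851L)
})

test_that("an empty read set yields an empty table with a warning", {
  g <- handmade_genomes()
  ref <- build_composite_reference(g, k = 31)
  empty <- data.table::data.table(fragment_id = character(0),
                                  seq1 = character(0), seq2 = character(0))
  expect_warning(res <- assign_reads(empty, ref), "empty")
  expect_identical(nrow(res), 0L)
  expect_true(all(c("hits_spX", "hits_spY") %in% names(res)))
})

test_that("verdicts partition fragments and match the brute-force oracle", {
  set.seed(31)
  for (k in c(31L, 15L)) {
    cfg <- sim_config(n_species = 2, genome_length_bp = 1500, n_genes = 2,
                      gene_length_range = c(300, 400), rrna_copies = 2,
                      marker_length = 60, divergence = 0.08, seed = k)
    g <- generate_genomes(cfg)
    ref <- build_composite_reference(g, k = k)
    par <- assign_params(k = k, min_hits = 2, margin = 0)
    n <- 250L
    rl <- 40L
    src <- sample(names(g), n, replace = TRUE)
    mk_read <- function(i) {
      if (i %% 10 == 0) return(random_read(rl))  # unplaced read
      seq <- g[[src[i]]]$contigs[["chr1"]]
      st <- sample(nchar(seq) - rl + 1, 1)
      r <- substr(seq, st, st + rl - 1)
      if (runif(1) < 0.5) r <- revcomp_chr(r)
      if (runif(1) < 0.3) {  # sprinkle an error
        p <- sample(rl, 1)
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      r
    }
    reads <- data.table::data.table(
      fragment_id = paste0("r", 1:n),
      seq1 = vapply(1:n, mk_read, ""),
      seq2 = vapply(1:n, mk_read, ""))
    data.table::setattr(reads, "class", c("read_pairs", class(reads)))
    got <- assign_reads(reads, ref, par)
    expect_identical(sum(got$verdict %in%
                           c("unique", "ambiguous", "unmapped")), n)
    want <- brute_force_assign(reads, g, k = k, min_hits = 2, margin = 0)
    expect_identical(got$verdict, want)
  }
})

test_that("ambiguity falls and uniqueness rises with divergence", {
  rates <- vapply(c(0, 0.10), function(dv) {
    cfg <- sim_config(n_species = 2, genome_length_bp = 20000, n_genes = 25,
                      rrna_copies = 4, divergence = dv, seed = 17)
    g <- generate_genomes(cfg)
    expr <- simulate_expression(cfg, g)
    spec <- list(sample_id = "t", condition = "straw.spA", replicate = 1,
                 proportions = c(spA = 1), depth = 1500L)
    rs <- simulate_read_pairs(g, expr, spec, seed = 18)
    ref <- build_composite_reference(g, k = 31)
    conf <- assignment_confusion(rs$truth, assign_reads(rs$reads, ref))
    c(conf$ambiguous_fraction, conf$unique_correct_fraction,
      conf$misassignment)
  }, numeric(3))
  expect_gte(rates[1, 1], 0.99)   # shared regions at zero divergence
  expect_lt(rates[2, 1], 0.01)    # essentially nothing unique at 0%
  expect_gt(rates[2, 2], 0.3)     # divergence frees unique assignment
  expect_lte(rates[3, 2], 0.01)   # misassignment stays rare
})

test_that("a generous vote margin recovers most reads uniquely at 10% divergence", {
  cfg <- sim_config(n_species = 2, genome_length_bp = 30000, n_genes = 40,
                    rrna_copies = 4, divergence = 0.10, seed = 23)
  g <- generate_genomes(cfg)
  expr <- simulate_expression(cfg, g)
  spec <- list(sample_id = "t", condition = "straw.spA", replicate = 1,
               proportions = c(spA = 1), depth = 3000L)
  rs <- simulate_read_pairs(g, expr, spec, seed = 24)
  ref <- build_composite_reference(g, k = 31)
  conf <- assignment_confusion(
    rs$truth, assign_reads(rs$reads, ref, assign_params(k = 31,
                                                        margin = 0.3)))
  expect_gte(conf$unique_correct_fraction, 0.95)
  expect_lte(conf$misassignment, 0.01)
})

test_that("union-rule counting handles exons, strands and ambiguity", {
  g <- handmade_genomes(diverge_at = seq(105, 895, by = 20))
  # fragment fully inside gene gA with correct (reverse) orientation
  mk_asg <- function(start, end, strand, sp = "spX") {
    dt <- data.table::data.table(
      fragment_id = "f1", verdict = "unique", species = sp,
      contig = "chr1", start = start, end = end, strand = strand,
      hits_spX = 10L, hits_spY = 0L)
    data.table::setattr(dt, "class", c("read_assignments", class(dt)))
    dt
  }
  cnt <- count_fragments(mk_asg(150L, 299L, "-"), g, "reverse")
  expect_identical(unname(cnt$spX$counts["spX_gA"]), 1L)
  expect_identical(cnt$spX$n_counted, 1L)
  # wrong orientation is not counted under a stranded library
  cnt2 <- count_fragments(mk_asg(150L, 299L, "+"), g, "reverse")
  expect_identical(sum(cnt2$spX$counts), 0L)
  cnt2f <- count_fragments(mk_asg(150L, 299L, "+"), g, "forward")
  expect_identical(unname(cnt2f$spX$counts["spX_gA"]), 1L)
  # intergenic fragment leaves totals unchanged
  cnt3 <- count_fragments(mk_asg(450L, 550L, "-"), g, "none")
  expect_identical(cnt3$spX$n_counted, 0L)
  expect_identical(cnt3$spX$n_unique, 1L)
  # unknown contig errors
  expect_error(count_fragments(mk_asg(150L, 299L, "-", sp = "spZ"), g),
               "contig")
})

test_that("fragments overlapping two genes are discarded as gene-ambiguous", {
  g <- handmade_genomes()
  # add an overlapping second gene on spX covering 350..500 (+)
  g$spX$gene_models <- rbind(
    g$spX$gene_models,
    data.frame(gene_id = "spX_gC", contig = "chr1", strand = "+",
               start = 350L, end = 500L, stringsAsFactors = FALSE))
  dt <- data.table::data.table(
    fragment_id = "f1", verdict = "unique", species = "spX",
    contig = "chr1", start = 340L, end = 420L, strand = "-",
    hits_spX = 10L, hits_spY = 0L)
  data.table::setattr(dt, "class", c("read_assignments", class(dt)))
  cnt <- count_fragments(dt, g, "reverse")
  expect_identical(sum(cnt$spX$counts), 0L)
  expect_identical(cnt$spX$n_counted, 0L)
})

test_that("multi-exon models count a fragment once per gene", {
  g <- handmade_genomes()
  # replace gA by a two-exon model
  g$spX$gene_models <- data.frame(
    gene_id = c("spX_gA", "spX_gA", "spX_gB"), contig = "chr1",
    strand = c("+", "+", "-"),
    start = c(101L, 301L, 601L), end = c(200L, 400L, 900L),
    stringsAsFactors = FALSE)
  dt <- data.table::data.table(
    fragment_id = "f1", verdict = "unique", species = "spX",
    contig = "chr1", start = 150L, end = 350L, strand = "-",
    hits_spX = 10L, hits_spY = 0L)
  data.table::setattr(dt, "class", c("read_assignments", class(dt)))
  cnt <- count_fragments(dt, g, "reverse")
  expect_identical(unname(cnt$spX$counts["spX_gA"]), 1L)
  expect_identical(unname(gene_lengths(g$spX$gene_models)["spX_gA"]), 200)
})

test_that("assignment confusion partitions and detects perfection", {
  truth <- data.table::data.table(
    fragment_id = c("a", "b", "c", "d"),
    species = c("spX", "spX", "spY", "spY"))
  asg <- data.table::data.table(
    fragment_id = c("a", "b", "c", "d"),
    verdict = c("unique", "unique", "unique", "ambiguous"),
    species = c("spX", "spX", "spY", NA))
  conf <- assignment_confusion(truth, asg)
  expect_identical(conf$misassignment, 0)
  expect_equal(rowSums(conf$rates), c(spX = 1, spY = 1))
  off <- conf$counts[cbind(c("spX", "spY"), c("spY", "spX"))]
  expect_true(all(off == 0))
  # all-ambiguous: zero misassignment and zero unique fraction
  asg$verdict <- "ambiguous"; asg$species <- NA
  conf2 <- assignment_confusion(truth, asg)
  expect_identical(conf2$misassignment, 0)
  expect_identical(conf2$unique_fraction, 0)
  expect_error(assignment_confusion(truth[1:3], asg), "different fragment")
})
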