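test_that("zero divergence yields identical genomes outside marker loci", {
  cfg <- sim_config(n_species = 2, genome_length_bp = 20000, n_genes = 20,
                    divergence = 0, rrna_copies = 5, seed = 3)
  g <- generate_genomes(cfg)
  a <- strsplit(g$spA$contigs[["chr1"]], "")[[1]]
  b <- strsplit(g$spB$contigs[["chr1"]], "")[[1]]
  marker_sites <- unlist(lapply(
    list(g$spA$marker_rrna, g$spA$marker_single_copy),
    function(m) unlist(Map(seq, m$intervals$start, m$intervals$end))))
  outside <- setdiff(seq_along(a), marker_sites)
  expect_identical(a[outside], b[outside])
  # markers still discriminate every species pair
  expect_true(g$spA$marker_rrna$sequence != g$spB$marker_rrna$sequence)
})

test_that("same config and seed reproduce byte-identical FASTA/GFF3", {
  cfg <- tiny_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genomes(generate_genomes(cfg), d1)
  write_genomes(generate_genomes(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("configured pairwise divergence is realised on a 100 kb genome", {
  cfg <- sim_config(n_species = 3, genome_length_bp = 1e5, n_genes = 100,
                    divergence = 0.10, seed = 5)
  g <- generate_genomes(cfg)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    obs <- pairwise_divergence(g[[pair[1]]], g[[pair[2]]])
    expect_lt(abs(obs - 0.10), 0.01)
    expect_lt(abs(obs - 0.10) / 0.10, 0.10)  # +-10% relative at >= 50 kb
  }
})

test_that("genome too small for the requested genes raises a sizing error", {
  cfg <- sim_config(n_species = 2, genome_length_bp = 5000, n_genes = 50,
                    seed = 1)
  expect_error(generate_genomes(cfg), "too small")
})

test_that("gene models lie within contigs and markers do not overlap", {
  g <- generate_genomes(tiny_cfg())
  for (sp in names(g)) {
    gm <- g[[sp]]$gene_models
    expect_true(all(gm$start >= 1 &
                      gm$end <= nchar(g[[sp]]$contigs[gm$contig])))
    iv <- rbind(g[[sp]]$marker_rrna$intervals,
                g[[sp]]$marker_single_copy$intervals)
    iv <- iv[order(iv$start), ]
    expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
    expect_identical(g[[sp]]$marker_single_copy$copy_number, 1L)
  }
})

test_that("unit folds give condition-independent expression", {
  cfg <- tiny_cfg(straw_induction_fold = 1, mixed_down_fold = 1,
                  mixed_up_fold = 1, replicate_sdlog = 0)
  g <- generate_genomes(cfg)
  expr <- simulate_expression(cfg, g)
  fr <- lapply(expr$fractions, function(co) co$spA[, 1])
  fr <- fr[!vapply(fr, is.null, TRUE)]
  for (i in seq_along(fr)[-1]) expect_equal(fr[[i]], fr[[1]])
})

test_that("planted mixed-down genes carry the configured fold before renormalisation", {
  cfg <- tiny_cfg(mixed_down_fold = 4, replicate_sdlog = 0)
  g <- generate_genomes(cfg)
  expr <- simulate_expression(cfg, g)
  lab <- expr$labels[expr$labels$species == "spA", ]
  down <- lab$gene_id[lab$effect == "mixed_down"]
  none <- lab$gene_id[lab$effect == "none"][1]
  expect_gt(length(down), 0)
  mono <- expr$fractions[["straw.spA"]]$spA[, 1]
  mix <- expr$fractions[["mix.spA_spB"]]$spA[, 1]
  # double ratio cancels the renormalisation constant
  dr <- (mono[down] / mono[none]) / (mix[down] / mix[none])
  expect_equal(unname(dr), rep(4, length(down)))
})

test_that("expected transcript fractions sum to one per species-sample", {
  cfg <- tiny_cfg()
  expr <- simulate_expression(cfg, generate_genomes(cfg))
  for (co in expr$fractions) {
    for (m in co) expect_equal(unname(colSums(m)), rep(1, ncol(m)))
  }
})

test_that("read simulation conserves depth and respects the mixture", {
  cfg <- tiny_cfg()
  g <- generate_genomes(cfg)
  expr <- simulate_expression(cfg, g)
  spec <- list(sample_id = "t", condition = "straw.spA", replicate = 1,
               proportions = c(spA = 1), depth = 1000L)
  rs <- simulate_read_pairs(g, expr, spec, seed = 8)
  expect_identical(nrow(rs$reads), 1000L)
  expect_identical(nrow(rs$truth), 1000L)
  expect_true(all(rs$truth$species == "spA"))
  expect_true(all(nchar(rs$reads$seq1) == 75L))

  # two-species mixture: species fraction within 3 binomial SDs
  spec2 <- list(sample_id = "m", condition = "mix.spA_spB", replicate = 1,
                proportions = c(spA = 0.8, spB = 0.2), depth = 50000L)
  # over-long fragment draws are resampled with a summary warning
  rs2 <- suppressWarnings(simulate_read_pairs(g, expr, spec2, seed = 9))
  frac <- mean(rs2$truth$species == "spA")
  tol <- 3 * sqrt(0.8 * 0.2 / 50000)
  expect_lt(abs(frac - 0.8), tol)
})

test_that("read pairs are error-free copies of the genome at error rate 0", {
  cfg <- tiny_cfg(error_rate = 0)
  g <- generate_genomes(cfg)
  expr <- simulate_expression(cfg, g)
  spec <- list(sample_id = "t", condition = "glucose.spA", replicate = 1,
               proportions = c(spA = 1), depth = 50L, error_rate = 0)
  rs <- simulate_read_pairs(g, expr, spec, seed = 4)
  for (i in 1:10) {
    tr <- rs$truth[i]
    frag <- substr(g$spA$contigs[[tr$contig]], tr$start, tr$end)
    if (tr$strand == "-") frag <- revcomp_chr(frag)
    expect_identical(rs$reads$seq2[i], substr(frag, 1, 75))
    expect_identical(rs$reads$seq1[i],
                     revcomp_chr(substr(frag, nchar(frag) - 74,
                                        nchar(frag))))
  }
})

test_that("seeded study simulation is bit-reproducible", {
  cfg <- sim_config(n_species = 2, genome_length_bp = 12000, n_genes = 15,
                    rrna_copies = 3, depth_mono = 100, depth_mixed = 200,
                    n_replicates = 2, seed = 21)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genomes$spA$contigs, s2$genomes$spA$contigs)
  expect_identical(s1$samples[[1]]$reads$seq1, s2$samples[[1]]$reads$seq1)
  expect_identical(s1$samples[[5]]$truth, s2$samples[[5]]$truth)
})

test_that("qPCR plate follows the log-linear Ct model", {
  # copies = 1 at the intercept
  p <- simulate_qpcr_plate(c(t1 = 1), curve = c(-3.5, 40), noise_sd = 0)
  expect_equal(p$Ct, 40)
  # a 10x copy step moves Ct by one slope unit
  p2 <- simulate_qpcr_plate(matrix(c(100, 1000), 1),
                            curve = c(-3.321928, 40), noise_sd = 0)
  expect_equal(p2$Ct[1] - p2$Ct[2], 3.321928, tolerance = 1e-9)
  # zero copies never amplify
  p3 <- simulate_qpcr_plate(c(t1 = 0))
  expect_true(is.na(p3$Ct))
})

test_that("default standard series is 10 five-fold dilutions from 5e7", {
  s <- qpcr_standard_series()
  expect_length(s, 10)
  expect_equal(s, 5e7 * 5^-(0:9))
  sim <- simulate_standard_series(noise_sd = 0)
  expect_identical(nrow(sim), 10L)
  expect_equal(sim$copies, 5e7 * 5^-(0:9))
})

test_that("gDNA biomass simulation scales with dry weight and spans 2-50 mg", {
  sim <- simulate_gdna_biomass(c(a = 10, b = 20, z = 0), noise_sd = 0)
  expect_equal(sim$samples$copies_well[2], 2 * sim$samples$copies_well[1])
  expect_true(is.na(sim$samples$Ct[sim$samples$sample == "z"]))
  expect_equal(range(sim$standards$weight_mg), c(2, 50))
  expect_equal(sim$samples$flask_weight_mg, sim$samples$aliquot_weight_mg)
  sim2 <- simulate_gdna_biomass(c(a = 10), aliquot_fraction = 0.25)
  expect_equal(sim2$samples$flask_weight_mg, 40)
})

test_that("YAML config round-trips through read_sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_species: 2", "genome_length_bp: 15000", "n_genes: 10",
               "divergence: 0.05", "seed: 12"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$n_species, 2L)
  expect_equal(cfg$divergence, 0.05)
  expect_identical(cfg$n_replicates, 3L)  # default preserved
  writeLines("not_a_field: 1", path)
  expect_error(read_sim_config(path), "unknown config fields")
})
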