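test_that("population and community specs validate their parameters", {
  expect_error(population_spec("X", 1e5, 1.2, relative_abundance = 1),
               "gc_fraction")
  expect_error(population_spec("X", 5000, 0.5, relative_abundance = 1),
               "genome_length")
  p1 <- population_spec("A", 1e5, 0.5, relative_abundance = 0.7)
  p2 <- population_spec("B", 1e5, 0.5, relative_abundance = 0.2)
  expect_error(community_spec(list(p1, p2)), "sum to 1")
  expect_error(community_spec(list(p1)), "at least 2")
  expect_error(
    community_spec(list(p1, population_spec("B", 1e5, 0.5,
                                            relative_abundance = 0.3)),
                   contig_length_law = list(dist = "fixed", length = 400)),
    ">= 500")
})

test_that("generated genomes hit the target G+C and are seed-deterministic", {
  spec <- population_spec("X", 50000, 0.50, signature_bias = 0,
                          relative_abundance = 1)
  g <- generate_genome(spec, 11)
  expect_equal(nchar(g), 50000)
  expect_lt(abs(gc_per_contig(g) - 0.50), 0.02)
  expect_identical(g, generate_genome(spec, 11))
  # biased chains are recalibrated to the target G+C too
  spec_b <- population_spec("Y", 50000, 0.62, signature_bias = 0.3,
                            relative_abundance = 1)
  gb <- generate_genome(spec_b, 12)
  expect_lt(abs(gc_per_contig(gb) - 0.62), 0.02)
})

test_that("populations with distinct G+C separate in CLR signature space", {
  mk <- function(gc, id, seed) {
    spec <- population_spec(id, 1e5, gc, relative_abundance = 1)
    g <- generate_genome(spec, seed)
    ctg <- fragment_into_contigs(g, list(dist = "fixed", length = 5000),
                                 seed = seed, prefix = id)
    signature_table(setNames(ctg$seq, ctg$contig_id))$clr
  }
  a <- mk(0.40, "lo", 21)
  b <- mk(0.65, "hi", 22)
  between <- mean_cross_dist(a, b)
  within <- (mean_within_dist(a) + mean_within_dist(b)) / 2
  expect_gt(between, within)
})

test_that("fragmentation tiles the genome exactly and respects the minimum", {
  g <- paste(rep("ACGT", 2500), collapse = "")  # 10 kb
  ctg <- fragment_into_contigs(g, list(dist = "fixed", length = 1000),
                               seed = 1)
  expect_equal(nrow(ctg), 10)
  expect_equal(sum(ctg$length), nchar(g))
  expect_identical(paste(ctg$seq, collapse = ""), g)
  set.seed(5)
  ctg2 <- fragment_into_contigs(generate_genome(
    population_spec("Z", 60000, 0.5, relative_abundance = 1), 5),
    list(dist = "loguniform", min = 1000, max = 8000), seed = 2)
  expect_true(all(ctg2$length >= 500))
  expect_equal(sum(ctg2$length), 60000)
  expect_error(fragment_into_contigs("ACGTACGT",
                                     list(dist = "fixed", length = 1000)),
               "shorter")
})

test_that("simulated counts conserve library sizes and expression structure", {
  spec <- small_community_spec()
  comm <- simulate_community(spec)
  expect_equal(sum(comm$metag$count), spec$total_metag_reads)
  expect_equal(sum(comm$metat$count), spec$total_metat_reads)
  # non-expressed genes have exactly zero metaT counts
  zero <- comm$gene_truth$gene_id[!comm$gene_truth$expressed]
  expect_true(all(comm$metat$count[match(zero, comm$metat$id)] == 0))
  # a population with expressed_fraction 0 transcribes nothing
  pops0 <- list(
    population_spec("A", 5e4, 0.45, relative_abundance = 0.5,
                    expressed_fraction = 0),
    population_spec("B", 5e4, 0.55, relative_abundance = 0.5,
                    expressed_fraction = 0.9))
  c0 <- simulate_community(community_spec(pops0, 1e5, 1e5, rng_seed = 2),
                           variant_region = "genome")
  a_genes <- c0$genes$gene_id[c0$genes$pop_id == "A"]
  expect_true(all(c0$metat$count[match(a_genes, c0$metat$id)] == 0))
})

test_that("metagenomic read share tracks abundance within binomial bounds", {
  pops <- list(
    population_spec("A", 1e5, 0.45, relative_abundance = 0.8),
    population_spec("B", 1e5, 0.55, relative_abundance = 0.2))
  spec <- community_spec(pops, total_metag_reads = 1e6,
                         total_metat_reads = 1e5, rng_seed = 13)
  comm <- simulate_community(spec, variant_region = "genome")
  share <- sum(comm$metag$count[comm$contigs$pop_id == "A"]) / 1e6
  se <- sqrt(0.8 * 0.2 / 1e6)
  expect_lt(abs(share - 0.8), 3 * se)
})

test_that("variant injection counts, collisions and caller noise behave", {
  spec0 <- population_spec("A", 5e4, 0.5, relative_abundance = 1,
                           snp_per_kb = 0)
  g <- generate_genome(spec0, 3)
  ctg <- fragment_into_contigs(g, list(dist = "fixed", length = 5000),
                               seed = 3, prefix = "A")
  ctg$pop_id <- "A"
  v0 <- inject_variants(ctg, spec0, seed = 1, region = "genome",
                        callers = default_callers(0, 0))
  expect_equal(nrow(v0$truth), 0)
  expect_true(all(vapply(v0$callsets, nrow, integer(1)) == 0))

  spec2 <- population_spec("A", 5e4, 0.5, relative_abundance = 1,
                           snp_per_kb = 2)
  v2 <- inject_variants(ctg, spec2, seed = 1, region = "genome",
                        callers = default_callers(0, 0))
  expect_equal(nrow(v2$truth), 100)  # 2 per kb on a 50 kb genome
  expect_false(anyDuplicated(paste(v2$truth$contig, v2$truth$pos)) > 0)
  # reference alleles match the genome sequence
  seqs <- setNames(ctg$seq, ctg$contig_id)
  expect_identical(unname(substring(seqs[v2$truth$contig], v2$truth$pos,
                                    v2$truth$pos)),
                   unname(v2$truth$ref))
  expect_true(all(v2$truth$ref != v2$truth$alt))
  # zero noise: every caller reports exactly the truth
  tk <- paste(v2$truth$contig, v2$truth$pos, v2$truth$ref, v2$truth$alt)
  for (cs in v2$callsets)
    expect_setequal(paste(cs$contig, cs$pos, cs$ref, cs$alt), tk)
  # impossible collision-free placement errors out
  dense <- population_spec("A", 5e4, 0.5, relative_abundance = 1,
                           snp_per_kb = 1100)
  expect_error(inject_variants(ctg, dense, seed = 1, region = "genome"),
               "collision")
})

test_that("spectral evidence is emitted for the configured protein subset", {
  spec <- small_community_spec()
  comm <- simulate_community(spec)
  expect_true(all(comm$evidence$intensity > 0))
  p0 <- population_spec("A", 5e4, 0.5, relative_abundance = 0.5,
                        proteome_detect_fraction = 0)
  truth <- data.frame(gene_id = paste0("g", 1:50), pop_id = "A",
                      expressed = TRUE, level = 1)
  genes <- data.frame(gene_id = truth$gene_id, length_aa = 299)
  expect_equal(nrow(simulate_spectra(truth, genes, p0, 1)), 0)
  p1 <- population_spec("A", 5e4, 0.5, relative_abundance = 0.5,
                        proteome_detect_fraction = 1)
  ev <- simulate_spectra(truth, genes, p1, 1)
  expect_length(unique(ev$protein_id), 50)
  expect_true(all(ev$intensity > 0))
})

test_that("the generator is byte-deterministic for a fixed spec and seed", {
  c1 <- simulate_community(small_community_spec(seed = 9))
  c2 <- simulate_community(small_community_spec(seed = 9))
  expect_identical(c1$contigs, c2$contigs)
  expect_identical(c1$metag, c2$metag)
  expect_identical(c1$metat, c2$metat)
  expect_identical(c1$variant_truth, c2$variant_truth)
  expect_identical(c1$callsets, c2$callsets)
  expect_identical(c1$evidence, c2$evidence)
  expect_identical(c1$abundance, c2$abundance)
})

test_that("every contig, gene and variant appears exactly once in the truth", {
  comm <- simulate_community(small_community_spec())
  expect_equal(sort(names(comm$contig_to_pop)),
               sort(comm$contigs$contig_id))
  expect_equal(sort(comm$gene_truth$gene_id), sort(comm$genes$gene_id))
  expect_false(anyDuplicated(paste(comm$variant_truth$contig,
                                   comm$variant_truth$pos)) > 0)
})
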