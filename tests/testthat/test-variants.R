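mkset <- function(keys, dg = 50, dt = 50, caller = "x") {
  parts <- strsplit(keys, ":")
  popomics:::new_callset(data.frame(
    contig = vapply(parts, `[`, character(1), 1),
    pos = as.integer(vapply(parts, `[`, character(1), 2)),
    ref = vapply(parts, `[`, character(1), 3),
    alt = vapply(parts, `[`, character(1), 4),
    depth_g = dg, depth_t = dt, stringsAsFactors = FALSE), caller)
}

test_that("VCF round trip preserves SNPs and depths", {
  df <- data.frame(contig = c("c1", "c1", "c2"), pos = c(5L, 9L, 3L),
                   ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                   depth_g = c(12, 30, 8), depth_t = c(15, 11, 40),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(df, path)
  cs <- parse_vcf(path, caller = "test")
  expect_s3_class(cs, "callset")
  expect_equal(nrow(cs), 3)
  expect_equal(popomics:::variant_keys(cs), popomics:::variant_keys(df))
  expect_equal(cs$depth_g, df$depth_g)
  expect_equal(cs$depth_t, df$depth_t)
  expect_identical(attr(cs, "caller"), "test")
})

test_that("multiallelic records decompose and indels are skipped with a count", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DPG,Number=1,Type=Integer,Description=\"g\">",
    "##INFO=<ID=DPT,Number=1,Type=Integer,Description=\"t\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "c1\t10\t.\tA\tC,T\t.\tPASS\tDPG=20;DPT=25",
    "c1\t40\t.\tAT\tA\t.\tPASS\tDPG=9;DPT=9",
    "c2\t7\t.\tG\tGA\t.\tPASS\tDPG=11;DPT=11",
    "c2\t9\t.\tT\tA\t.\tPASS\tDPG=13;DPT=14"), path)
  cs <- parse_vcf(path)
  expect_equal(nrow(cs), 3)  # A>C, A>T, T>A
  expect_equal(sum(cs$contig == "c1" & cs$pos == 10), 2)
  expect_equal(attr(cs, "n_skipped"), 2)
})

test_that("call-set intersection matches brute-force set algebra", {
  a <- mkset(c("c1:1:A:T", "c1:2:C:G", "c1:3:G:A"))
  b <- mkset(c("c1:2:C:G", "c1:3:G:A", "c1:4:T:C"))
  cc <- mkset(c("c1:3:G:A", "c1:5:A:G"))
  got <- intersect_callsets(list(a, b, cc))
  expect_equal(popomics:::variant_keys(got), "c1:3:G:A")
  expect_equal(popomics:::variant_keys(intersect_callsets(list(a, a))),
               popomics:::variant_keys(a))
  disj <- intersect_callsets(list(mkset("c1:1:A:T"), mkset("c2:1:A:T")))
  expect_equal(nrow(disj), 0)
  expect_error(intersect_callsets(list(a)), "at least two")
  # randomized equivalence against an independent set oracle,
  # plus order invariance
  set.seed(8)
  universe <- sprintf("c%d:%d:A:G", sample(1:3, 300, TRUE), sample(1:500, 300, TRUE))
  universe <- unique(universe)
  for (i in 1:100) {
    sets <- lapply(1:3, function(j) sample(universe, sample(5:40, 1)))
    callsets <- lapply(sets, mkset)
    got <- sort(popomics:::variant_keys(intersect_callsets(callsets)))
    expect_equal(got, sort(oracle_intersect(sets)))
    perm <- sample(3)
    got_perm <- sort(popomics:::variant_keys(
      intersect_callsets(callsets[perm])))
    expect_equal(got_perm, got)
  }
})

test_that("intersection takes the minimum depth per library across callers", {
  a <- mkset("c1:1:A:T", dg = 30, dt = 12)
  b <- mkset("c1:1:A:T", dg = 14, dt = 44)
  got <- intersect_callsets(list(a, b))
  expect_equal(got$depth_g, 14)
  expect_equal(got$depth_t, 12)
})

test_that("the joint depth filter is boundary-inclusive and monotone", {
  v <- data.frame(contig = "c", pos = 1:4, ref = "A", alt = "G",
                  depth_g = c(10, 9, 100, 15), depth_t = c(10, 100, 9, 50))
  kept <- depth_filter(v, 10)
  expect_equal(kept$pos, c(1, 4))
  set.seed(9)
  v2 <- data.frame(contig = "c", pos = 1:200, ref = "A", alt = "G",
                   depth_g = rpois(200, 15), depth_t = rpois(200, 15))
  sizes <- vapply(5:30, function(md) nrow(depth_filter(v2, md)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("variant density normalizes per kb and by population size", {
  d <- variant_density(0, 1e6, 0.5)
  expect_equal(d$snp_per_kb, 0)
  expect_equal(d$normalized_density, 0)
  d2 <- variant_density(100, 1e6, 0.5)
  expect_equal(d2$snp_per_kb, 0.1)
  expect_equal(d2$normalized_density, 0.2)
  expect_equal(variant_density(100, 1e6, 1.0)$normalized_density,
               d2$normalized_density / 2)
  expect_error(variant_density(1, 1e6, 0), "N_i")
})

test_that("per-gene variant counting is inclusive and conserves totals", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      contig_id = c("c1", "c1", "c2"),
                      start = c(10L, 100L, 1L), end = c(50L, 200L, 99L))
  v <- data.frame(contig = c("c1", "c1", "c1", "c2", "c2"),
                  pos = c(10L, 50L, 60L, 99L, 100L))
  got <- per_gene_variant_counts(v, genes)
  expect_equal(got$per_gene$n_variants, c(2, 0, 1))  # boundaries inclusive
  expect_equal(got$intergenic, 2)
  # overlapping genes both count a shared position
  ov <- data.frame(gene_id = c("a", "b"), contig_id = "c1",
                   start = c(1L, 5L), end = c(10L, 15L))
  both <- per_gene_variant_counts(data.frame(contig = "c1", pos = 7L), ov)
  expect_equal(both$per_gene$n_variants, c(1, 1))
  # conservation on non-overlapping fixtures
  set.seed(10)
  for (i in 1:20) {
    ng <- sample(3:8, 1)
    starts <- cumsum(sample(50:100, ng))
    genes_i <- data.frame(gene_id = paste0("g", 1:ng), contig_id = "c1",
                          start = starts, end = starts + 30L)
    vpos <- sample(1:max(genes_i$end + 50), 40)
    res <- per_gene_variant_counts(data.frame(contig = "c1", pos = vpos),
                                   genes_i)
    expect_equal(sum(res$per_gene$n_variants) + res$intergenic, 40)
  }
  expect_error(per_gene_variant_counts(
    v, data.frame(gene_id = "g", contig_id = "c1", start = 10L, end = 5L)),
    "end < start")
})

test_that("filter-then-intersect equals intersect-then-filter at shared depths", {
  set.seed(11)
  universe <- sprintf("c1:%d:A:G", 1:80)
  dg <- rpois(80, 12); dt <- rpois(80, 12)
  pick <- function() sort(sample(80, 50))
  idx <- list(pick(), pick())
  sets <- lapply(idx, function(i) mkset(universe[i], dg = dg[i], dt = dt[i]))
  a <- depth_filter(intersect_callsets(sets), 10)
  b <- intersect_callsets(lapply(sets, depth_filter, min_depth = 10))
  expect_equal(popomics:::variant_keys(a), popomics:::variant_keys(b))
})
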