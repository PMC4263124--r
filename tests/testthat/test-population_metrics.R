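test_that("relative population sizes follow the length-normalized read share", {
  one <- population_size(data.frame(cg_id = "CG1", l_i = 1e6, c_i = 500))
  expect_equal(one$N_i, 1.0)
  two <- population_size(data.frame(cg_id = c("A", "B"),
                                    l_i = c(1000, 2000), c_i = c(100, 100)))
  expect_equal(two$N_i, c(2 / 3, 1 / 3))  # (0.1, 0.05) / 0.15
  expect_equal(sum(two$N_i), 1, tolerance = 1e-9)
  # scale invariance of the relative mode
  two10 <- population_size(data.frame(cg_id = c("A", "B"),
                                      l_i = c(1000, 2000),
                                      c_i = c(1000, 1000)))
  expect_equal(two10$N_i, two$N_i)
  # rpkm_like is proportional to relative within a sample
  rk <- population_size(data.frame(cg_id = c("A", "B"), l_i = c(1000, 2000),
                                   c_i = c(100, 100)), mode = "rpkm_like")
  expect_equal(sd(rk$N_i / two$N_i) / mean(rk$N_i / two$N_i), 0,
               tolerance = 1e-12)
  expect_identical(attr(rk, "mode"), "rpkm_like")
  expect_error(population_size(data.frame(cg_id = "A", l_i = 10, c_i = 0)),
               "zero total")
})

test_that("FPKM matches its definition and conservation identity", {
  expect_equal(fpkm(0, 1000, 1e6), 0)
  expect_equal(fpkm(10, 1000, 1e6), 10)
  set.seed(3)
  for (i in 1:100) {
    cnt <- rpois(1, 500); len <- sample(200:3000, 1); tot <- 10^sample(5:7, 1)
    expect_equal(fpkm(cnt, len, tot), oracle_fpkm(cnt, len, tot))
  }
  # if all fragments land in genes, sum FPKM_g * length_g = 1e9
  counts <- c(120, 30, 850); lens <- c(900, 1500, 600)
  f <- fpkm(counts, lens, sum(counts))
  expect_equal(sum(f * lens), 1e9)
  # halving the library doubles FPKM
  expect_equal(fpkm(10, 1000, 5e5), 2 * fpkm(10, 1000, 1e6))
  expect_error(fpkm(1, 0, 100), "gene_length")
  expect_error(fpkm(1, 100, 0), "total_mapped")
})

test_that("expression calls use the inclusive 50 x N_i threshold", {
  expect_true(call_expressed(50 * 0.3, 0.3))       # boundary equality
  expect_false(call_expressed(0, 0.3))
  expect_false(call_expressed(50 * 0.3 - 1e-9, 0.3))
  # raising the factor never grows the expressed set
  set.seed(4)
  fp <- runif(200, 0, 30); ni <- 0.25
  for (f in c(10, 25, 50, 100)) {
    lo <- call_expressed(fp, ni, factor = f)
    hi <- call_expressed(fp, ni, factor = f * 2)
    expect_true(all(lo | !hi))
  }
  expect_equal(expressed_fraction(c(rep(TRUE, 9), rep(FALSE, 11))), 45)
  expect_equal(expressed_fraction(rep(TRUE, 5)), 100)
  expect_equal(expressed_fraction(rep(FALSE, 5)), 0)
  expect_error(expressed_fraction(logical(0)), "zero genes")
})

test_that("expression-calling recovers generating expressed fractions", {
  comm <- simulate_community(small_community_spec())
  asg <- data.frame(contig_id = comm$contigs$contig_id,
                    cg_id = comm$contigs$pop_id, posterior = 1)
  prof <- profile_from_assignments(asg, comm$metag)
  expr <- expression_table(comm$genes[, c("gene_id", "contig_id", "length")],
                           asg,
                           data.frame(id = comm$metat$id,
                                      count = comm$metat$count), prof)
  frac <- tapply(expr$expressed, expr$cg_id, expressed_fraction)
  expect_lt(abs(frac[["A"]] - 80), 2)
  expect_lt(abs(frac[["B"]] - 90), 2)
})

test_that("COG profiles collapse multi-category genes and close to 1", {
  p <- cog_profile(rep("I", 10))
  expect_equal(unname(p$normalized[["I"]]), 1.0)
  p2 <- cog_profile(c("E", "EI", "KL", "", "I"))
  expect_equal(unname(p2$counts[["Multi+I"]]), 1)  # "EI"
  expect_equal(unname(p2$counts[["Multi-I"]]), 1)  # "KL"
  expect_equal(unname(p2$counts[["No"]]), 1)
  expect_equal(sum(p2$normalized), 1, tolerance = 1e-9)
  expect_error(cog_profile(c("E", "X9")), "unknown COG")
})

test_that("completeness is the detected fraction of the 40-marker panel", {
  panel <- uscg_panel()
  expect_length(panel, 40)
  expect_equal(completeness(panel), 100)
  expect_equal(completeness(character(0)), 0)
  expect_equal(completeness(panel[-1]), 97.5)  # 39 of 40
  expect_equal(completeness(c(panel[1], panel[1], "junk")), 2.5)
  expect_error(completeness("x", panel = character(0)), "empty")
})

test_that("AAI finds reciprocal best hits and is order-invariant", {
  set.seed(6)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  proteome <- setNames(vapply(1:6, function(i)
    paste(sample(aas, 100, replace = TRUE), collapse = ""), character(1)),
    paste0("p", 1:6))
  self <- aai(proteome, proteome)
  expect_equal(self$n_orthologs, 6)
  expect_equal(self$median_identity, 100)
  # one substituted residue in a 100-residue protein: 99% identity
  mutated <- proteome
  substr(mutated["p1"], 50, 50) <- if (substr(proteome["p1"], 50, 50) == "A")
    "V" else "A"
  res <- aai(proteome["p1"], mutated["p1"])
  expect_equal(res$pairs$identity, 99.0)
  # shuffling input order changes nothing
  shuf <- aai(proteome[sample(6)], mutated[sample(6)])
  ref <- aai(proteome, mutated)
  expect_equal(sort(shuf$pairs$identity), sort(ref$pairs$identity))
  expect_equal(shuf$median_identity, ref$median_identity)
  expect_error(aai(character(0), proteome), "non-empty")
})
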