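# small helper: CLR signatures of fragmented genomes from n populations
sig_fixture <- function(gcs, seed0 = 31, genome = 1e5, frag = 2000) {
  parts <- lapply(seq_along(gcs), function(i) {
    spec <- population_spec(paste0("P", i), genome, gcs[i],
                            relative_abundance = 1)
    g <- generate_genome(spec, seed0 + i)
    ctg <- fragment_into_contigs(g, list(dist = "fixed", length = frag),
                                 seed = seed0 + i, prefix = paste0("P", i))
    setNames(ctg$seq, ctg$contig_id)
  })
  seqs <- unlist(parts)
  labels <- rep(seq_along(gcs), vapply(parts, length, integer(1)))
  list(sig = signature_table(seqs), labels = labels)
}

test_that("the embedding is seed-deterministic and separates populations", {
  fx <- sig_fixture(c(0.38, 0.62))
  e1 <- embed_signatures(fx$sig, perplexity = 10, seed = 4)
  e2 <- embed_signatures(fx$sig, perplexity = 10, seed = 4)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1$x)) && all(is.finite(e1$y)))
  Y <- as.matrix(e1[, c("x", "y")])
  a <- Y[fx$labels == 1, ]; b <- Y[fx$labels == 2, ]
  expect_gt(mean_cross_dist(a, b),
            (mean_within_dist(a) + mean_within_dist(b)) / 2)
  expect_error(embed_signatures(fx$sig, perplexity = 1000), "too few")
})

test_that("three well-separated populations embed with a high silhouette", {
  skip_if_not_installed("cluster")
  fx <- sig_fixture(c(0.35, 0.50, 0.65))
  emb <- embed_signatures(fx$sig, perplexity = 10, seed = 2)
  sil <- cluster::silhouette(fx$labels,
                             stats::dist(as.matrix(emb[, c("x", "y")])))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("EM mixture fitting obeys its closed forms and monotonicity", {
  set.seed(10)
  X <- cbind(rnorm(200), rnorm(200))
  f1 <- fit_gmm(X, n_components = 1)
  expect_equal(as.vector(f1$means), colMeans(X), tolerance = 1e-9)
  # widely separated clusters: hard assignment equals nearest initial mean
  X2 <- rbind(cbind(rnorm(100, 0, 0.5), rnorm(100, 0, 0.5)),
              cbind(rnorm(80, 30, 0.5), rnorm(80, 30, 0.5)))
  init <- rbind(c(0, 0), c(30, 30))
  f2 <- fit_gmm(X2, init_means = init)
  hard <- max.col(f2$responsibilities)
  nearest <- apply(X2, 1, function(p)
    which.min(colSums((t(init) - p)^2)))
  expect_equal(hard, unname(nearest))
  tr <- f2$log_likelihood_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  expect_true(all(abs(rowSums(f2$responsibilities) - 1) < 1e-9))
  expect_equal(sum(f2$weights), 1, tolerance = 1e-9)
  expect_error(fit_gmm(X2[1:2, ], n_components = 5), "degenerate")
})

test_that("EM mixture agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC  # Mclust looks it up unqualified
  set.seed(11)
  X <- rbind(cbind(rnorm(150, 0), rnorm(150, 0)),
             cbind(rnorm(150, 6), rnorm(150, 6)))
  f <- fit_gmm(X, n_components = 2, seed = 1)
  m <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  ours <- f$means[order(f$means[, 1]), ]
  theirs <- t(m$parameters$mean)[order(t(m$parameters$mean)[, 1]), ]
  expect_equal(unname(ours), unname(theirs), tolerance = 0.05)
})

test_that("bin assignment respects the posterior threshold", {
  set.seed(12)
  X <- rbind(cbind(rnorm(100, 0, 0.3), rnorm(100, 0, 0.3)),
             cbind(rnorm(100, 10, 0.3), rnorm(100, 10, 0.3)))
  pts <- data.frame(contig_id = paste0("c", 1:200), x = X[, 1], y = X[, 2])
  f <- fit_gmm(pts, init_means = rbind(c(0, 0), c(10, 10)))
  a <- assign_bins(f, pts)
  centre <- data.frame(contig_id = "mu", x = f$means[1, 1],
                       y = f$means[1, 2])
  at_mean <- assign_bins(f, centre)
  expect_gt(at_mean$posterior, 0.99)
  expect_equal(at_mean$cg_id, "CG1")
  a0 <- assign_bins(f, pts, min_posterior = 0)
  expect_false(any(a0$cg_id == "unbinned"))
})

test_that("read recruitment conserves totals exactly", {
  asg <- data.frame(contig_id = c("c1", "c2", "c3"),
                    cg_id = c("CG1", "CG1", "CG2"), posterior = 1)
  counts <- data.frame(id = c("c1", "c2", "c3"), count = c(100, 200, 300))
  rec <- recruit_reads(asg, counts)
  expect_equal(unname(rec$c_i[c("CG1", "CG2")]), c(300, 300))
  expect_equal(rec$residual, 0)
  expect_error(recruit_reads(asg, data.frame(id = "c9", count = 5)),
               "unknown")
  set.seed(20)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    asg <- data.frame(
      contig_id = paste0("c", 1:n),
      cg_id = sample(c("CG1", "CG2", "CG3", "unbinned"), n, replace = TRUE),
      posterior = runif(n))
    counts <- data.frame(id = paste0("c", 1:n), count = rpois(n, 50))
    rec <- recruit_reads(asg, counts)
    expect_equal(sum(rec$c_i) + rec$residual, sum(counts$count))
  }
})

test_that("second-round refinement is idempotent on clean bins and passes through short groups", {
  fx2 <- sig_fixture(c(0.38, 0.62), frag = 2000)
  emb <- embed_signatures(fx2$sig, perplexity = 10, seed = 2)
  f <- fit_gmm(emb, n_components = 2, seed = 2)
  asg <- assign_bins(f, emb)
  # groups of 50 contigs are below the re-embedding size for perplexity 30
  expect_message(
    out <- iterate_binning(structure(
      rep("ACGTACGTACGT", nrow(asg)), names = asg$contig_id), asg,
      perplexity = 30),
    "passed through")
  expect_identical(out, asg)
})

test_that("coverage splitting detects a 10x bimodal bin and spares unimodal ones", {
  # merged bin built from two generator populations at ~10x depth ratio
  pops <- list(
    population_spec("LO", 1.5e5, 0.48, relative_abundance = 1 / 11,
                    expressed_fraction = 0.9),
    population_spec("HI", 1.5e5, 0.52, relative_abundance = 10 / 11,
                    expressed_fraction = 0.9))
  spec <- community_spec(pops, total_metag_reads = 6e5,
                         total_metat_reads = 2e5, rng_seed = 17)
  comm <- simulate_community(spec, variant_region = "genome")
  dep <- setNames(comm$metag$depth, comm$metag$id)
  sp <- split_by_coverage(dep, cg_id = "CG8")
  expect_true(attr(sp, "split"))
  truth_sub <- ifelse(comm$contig_to_pop[sp$contig_id] == "LO", "CG8a",
                      "CG8b")
  expect_gte(mean(sp$cg_id == truth_sub), 0.95)
  # label ordering contract: "a" is the lower-depth mode
  expect_lt(mean(dep[sp$contig_id[sp$cg_id == "CG8a"]]),
            mean(dep[sp$contig_id[sp$cg_id == "CG8b"]]))
  # single-population depths are never split across seeds
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 150
    lens <- round(exp(runif(n, log(1000), log(20000))))
    counts <- rmultinom(1, 3e5, lens / sum(lens))[, 1]
    d1 <- setNames(counts * 100 / lens, paste0("c", 1:n))
    expect_false(attr(split_by_coverage(d1, seed = s), "split"))
  }
  expect_warning(split_by_coverage(c(a = 1, b = 2, c = 3)), "fewer than 4")
  expect_error(split_by_coverage(c(a = 0, b = 2, c = 3, d = 4)), "positive")
})
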