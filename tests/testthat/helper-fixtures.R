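# Small, fast community used by unit tests (two clearly separated
# populations, ~150 contigs).
small_community_spec <- function(seed = 3L) {
  pops <- list(
    population_spec("A", 2.5e5, 0.40, relative_abundance = 0.6,
                    expressed_fraction = 0.8, snp_per_kb = 1),
    population_spec("B", 2.5e5, 0.62, relative_abundance = 0.4,
                    expressed_fraction = 0.9, snp_per_kb = 1)
  )
  community_spec(pops, total_metag_reads = 4e5, total_metat_reads = 4e5,
                 rng_seed = seed)
}

# Independent brute-force oracles -------------------------------------------

# reverse complement without Biostrings
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# straight-line CLR
oracle_clr <- function(counts, pseudocount = 1) {
  v <- counts + pseudocount
  p <- v / sum(v)
  log(p) - mean(log(p))
}

# rank-and-Pearson Spearman with average ties
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"), method = "pearson")
}

# key-string set intersection
oracle_intersect <- function(key_sets) Reduce(intersect, key_sets)

# FPKM from first principles
oracle_fpkm <- function(count, len, total) (count / (len / 1000)) / (total / 1e6)

# mean pairwise Euclidean distance between two row sets of a matrix
mean_cross_dist <- function(A, B) {
  s <- 0
  for (i in seq_len(nrow(A))) s <- s + sum(sqrt(rowSums((B - A[rep(i, nrow(B)), , drop = FALSE])^2)))
  s / (nrow(A) * nrow(B))
}
mean_within_dist <- function(A) {
  n <- nrow(A)
  d <- as.matrix(stats::dist(A))
  sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
}

# The default benchmark community and its full binning run are expensive;
# they are computed once per test session and shared.
.acceptance_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (!is.null(.acceptance_cache$run)) return(.acceptance_cache$run)
  spec <- default_community_spec(rng_seed = 1L)
  comm <- simulate_community(spec)
  seqs <- setNames(comm$contigs$seq, comm$contigs$contig_id)
  bins <- bin_contigs(
    seqs, k = length(spec$populations),
    counts = data.frame(id = comm$metag$id, count = comm$metag$count),
    depths = setNames(comm$metag$depth, comm$metag$id), seed = 1L)
  .acceptance_cache$run <- list(spec = spec, comm = comm, bins = bins)
  .acceptance_cache$run
}

# population profile (l_i, c_i, N_i) from an assignment table
profile_from_assignments <- function(assignments, metag) {
  counts <- data.frame(id = metag$id, count = metag$count,
                       length = metag$length)
  rec <- recruit_reads(assignments, counts)
  binned <- assignments[assignments$cg_id != "unbinned", , drop = FALSE]
  l_i <- tapply(counts$length[match(binned$contig_id, counts$id)],
                binned$cg_id, sum)
  population_size(data.frame(cg_id = names(rec$c_i),
                             l_i = as.numeric(l_i[names(rec$c_i)]),
                             c_i = as.numeric(rec$c_i),
                             stringsAsFactors = FALSE))
}
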