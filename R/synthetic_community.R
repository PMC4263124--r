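#' Describe one population of a synthetic community
#'
#' A population is a genome-scale sequence model plus the multi-omic
#' parameters the downstream analysis is supposed to recover: its relative
#' abundance (DNA fraction per unit genome), the fraction of its genes that
#' are transcribed, per-gene transcript overdispersion, SNP density, and the
#' fraction of expressed proteins with spectral evidence.
#'
#' @param pop_id Population label.
#' @param genome_length Genome length in bases (>= 10,000).
#' @param gc_fraction Target G+C fraction, in (0, 1).
#' @param signature_bias Concentration of the population-specific perturbation
#'   of the order-2 Markov transition matrix away from the G+C-implied
#'   baseline. 0 gives a composition-only signature; the default 0.3 gives
#'   clearly distinct expected pentamer profiles between populations.
#' @param relative_abundance Relative population size; across a community
#'   these must sum to 1.
#' @param expressed_fraction Fraction of the population's genes that are
#'   transcribed (0 to 1).
#' @param expression_dispersion Gamma overdispersion of per-gene transcript
#'   levels (variance/mean^2 of the level distribution); 0 gives equal levels.
#' @param snp_per_kb True variants per kilobase of genome.
#' @param proteome_detect_fraction Fraction of expressed genes with at least
#'   one identified spectrum.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(pop_id, genome_length, gc_fraction,
                            signature_bias = 0.3, relative_abundance,
                            expressed_fraction = 0.9,
                            expression_dispersion = 0.5,
                            snp_per_kb = 1, proteome_detect_fraction = 0.1) {
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must lie strictly between 0 and 1")
  if (genome_length < 10000) stop("genome_length must be >= 10,000 bases")
  if (expressed_fraction < 0 || expressed_fraction > 1)
    stop("expressed_fraction must be in [0, 1]")
  if (proteome_detect_fraction < 0 || proteome_detect_fraction > 1)
    stop("proteome_detect_fraction must be in [0, 1]")
  if (snp_per_kb < 0) stop("snp_per_kb must be >= 0")
  if (relative_abundance <= 0) stop("relative_abundance must be positive")
  structure(list(
    pop_id = as.character(pop_id), genome_length = as.integer(genome_length),
    gc_fraction = gc_fraction, signature_bias = signature_bias,
    relative_abundance = relative_abundance,
    expressed_fraction = expressed_fraction,
    expression_dispersion = expression_dispersion,
    snp_per_kb = snp_per_kb,
    proteome_detect_fraction = proteome_detect_fraction
  ), class = "population_spec")
}

#' Describe a synthetic community
#'
#' @param populations List of [population_spec()] objects (>= 2); their
#'   `relative_abundance` values must sum to 1 (tolerance 1e-9).
#' @param total_metag_reads,total_metat_reads Library sizes (single-end read
#'   equivalents) for the metagenomic and metatranscriptomic libraries.
#' @param read_length Read length in bases, used to convert counts to depth.
#' @param contig_length_law Contig length distribution: a list with `dist`
#'   ("loguniform" or "fixed") and parameters (`min`, `max`, or `length`).
#'   The minimum must be >= 500 bases.
#' @param rng_seed Root seed; every stage draws from a substream derived
#'   from it.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(populations, total_metag_reads = 2e6,
                           total_metat_reads = 2e6, read_length = 100,
                           contig_length_law = list(dist = "loguniform",
                                                    min = 1000, max = 20000),
                           rng_seed = 1L) {
  if (length(populations) < 2) stop("a community needs at least 2 populations")
  if (!all(vapply(populations, inherits, logical(1), "population_spec")))
    stop("populations must be population_spec objects")
  ab <- vapply(populations, `[[`, numeric(1), "relative_abundance")
  if (abs(sum(ab) - 1) > 1e-9)
    stop("relative abundances must sum to 1 (got ", format(sum(ab)), ")")
  ids <- vapply(populations, `[[`, character(1), "pop_id")
  if (anyDuplicated(ids)) stop("duplicate population ids")
  if (total_metag_reads <= 0 || total_metat_reads <= 0)
    stop("library sizes must be positive")
  law_min <- contig_length_law$min %||% contig_length_law$length
  if (is.null(law_min) || law_min < 500)
    stop("contig length law minimum must be >= 500 bases")
  structure(list(
    populations = setNames(populations, ids),
    total_metag_reads = total_metag_reads,
    total_metat_reads = total_metat_reads,
    read_length = read_length, contig_length_law = contig_length_law,
    rng_seed = as.integer(rng_seed)
  ), class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat("Synthetic community:", length(x$populations), "populations\n")
  for (p in x$populations)
    cat(sprintf("  %-6s %7.2f kb  GC %.2f  abundance %.3f  expressed %.2f  SNP/kb %.2f\n",
                p$pop_id, p$genome_length / 1000, p$gc_fraction,
                p$relative_abundance, p$expressed_fraction, p$snp_per_kb))
  cat(sprintf("  metaG %g reads, metaT %g reads, read length %d, seed %d\n",
              x$total_metag_reads, x$total_metat_reads,
              as.integer(x$read_length), x$rng_seed))
  invisible(x)
}

#' Default five-population benchmark community
#'
#' Five populations spanning G+C 0.35-0.65 with skewed abundances, a dominant
#' "generalist" transcribing 45% of its genes at low SNP density, and a
#' "specialist" transcribing 93% at ten-fold higher SNP density. Yields about
#' 1,500 contigs of at least 1 kb.
#'
#' @param rng_seed Root seed.
#' @return A `community_spec`.
#' @export
default_community_spec <- function(rng_seed = 1L) {
  pops <- list(
    population_spec("P1", 2.0e6, 0.650, relative_abundance = 0.40,
                    expressed_fraction = 0.45, snp_per_kb = 0.2,
                    proteome_detect_fraction = 0.10),
    population_spec("P2", 1.8e6, 0.425, relative_abundance = 0.25,
                    expressed_fraction = 0.93, snp_per_kb = 2.0,
                    proteome_detect_fraction = 0.10),
    population_spec("P3", 2.1e6, 0.500, relative_abundance = 0.15,
                    expressed_fraction = 0.85, snp_per_kb = 1.0,
                    proteome_detect_fraction = 0.10),
    population_spec("P4", 1.9e6, 0.575, relative_abundance = 0.12,
                    expressed_fraction = 0.90, snp_per_kb = 1.5,
                    proteome_detect_fraction = 0.10),
    population_spec("P5", 1.7e6, 0.350, relative_abundance = 0.08,
                    expressed_fraction = 0.88, snp_per_kb = 1.0,
                    proteome_detect_fraction = 0.10)
  )
  community_spec(pops, total_metag_reads = 4e6, total_metat_reads = 4e6,
                 rng_seed = rng_seed)
}

# --- genome model -----------------------------------------------------------

# Stationary G+C of an order-2 chain, via power iteration on the
# 16-state dinucleotide chain.
markov_stationary <- function(trans) {
  T16 <- matrix(0, 16, 16)
  for (a in 0:3) for (b in 0:3) for (cc in 0:3)
    T16[4 * a + b + 1, 4 * b + cc + 1] <- trans[4 * a + b + 1, cc + 1]
  pi0 <- rep(1 / 16, 16)
  for (i in 1:200) pi0 <- as.vector(pi0 %*% T16)
  pi0 / sum(pi0)
}

markov_gc <- function(trans) {
  st <- markov_stationary(trans)
  base <- vapply(0:3, function(b) sum(st[seq(b + 1, 16, by = 4)]), numeric(1))
  base[2] + base[3]  # C + G
}

# Rescale the C/G columns (bisection on a single multiplier) so the chain's
# stationary composition hits the target G+C exactly in expectation.
calibrate_gc <- function(trans, target) {
  scale_cols <- function(f) {
    tr <- trans
    tr[, c(2, 3)] <- tr[, c(2, 3)] * f
    tr / rowSums(tr)
  }
  lo <- 1e-3; hi <- 1e3
  for (i in 1:80) {
    mid <- sqrt(lo * hi)
    if (markov_gc(scale_cols(mid)) < target) lo <- mid else hi <- mid
  }
  scale_cols(sqrt(lo * hi))
}

#' Generate a population genome from a perturbed order-2 Markov chain
#'
#' The transition matrix starts from the i.i.d. composition implied by
#' `gc_fraction`, is perturbed per (dinucleotide state, base) by
#' `exp(signature_bias * z)` with population-specific standard normal draws
#' `z`, and is then recalibrated so the stationary G+C matches the target.
#' Distinct populations therefore carry distinct expected pentamer profiles
#' even at equal G+C.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @return A single character string over A/C/G/T of length
#'   `spec$genome_length`.
#' @export
generate_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  gc <- spec$gc_fraction
  base <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  z <- matrix(rnorm(64), 16, 4)
  trans <- matrix(base, 16, 4, byrow = TRUE) * exp(spec$signature_bias * z)
  trans <- trans / rowSums(trans)
  if (spec$signature_bias != 0) trans <- calibrate_gc(trans, gc)
  st <- markov_stationary(trans)
  init_pair <- sample.int(16, 1, prob = st) - 1L
  init <- c(init_pair %/% 4L, init_pair %% 4L)
  codes <- cpp_markov_seq(spec$genome_length, trans, as.integer(init))
  intToUtf8(c(65L, 67L, 71L, 84L)[codes + 1L])
}

#' Fragment a genome into non-overlapping contigs
#'
#' Tiles the genome left to right with fragment lengths drawn from the
#' contig length law; the concatenation of the fragments reconstructs the
#' genome exactly and every fragment respects the law's minimum (a short
#' terminal remainder is merged into the previous fragment).
#'
#' @param genome Character string (one sequence).
#' @param law List: `dist` "loguniform" (`min`, `max`) or "fixed" (`length`).
#' @param seed Integer seed.
#' @param prefix Contig id prefix.
#' @return A data.frame with contig_id, start, end, length, seq.
#' @export
fragment_into_contigs <- function(genome, law = list(dist = "loguniform",
                                                     min = 1000, max = 20000),
                                  seed = 1L, prefix = "ctg") {
  n <- nchar(genome)
  law_min <- law$min %||% law$length
  if (law_min < 500) stop("contig length law minimum must be >= 500")
  if (n < law_min) stop("genome shorter than the minimum contig length")
  set.seed(seed)
  lens <- integer(0)
  total <- 0L
  repeat {
    l <- switch(law$dist,
      loguniform = as.integer(round(exp(runif(1, log(law$min), log(law$max))))),
      fixed = as.integer(law$length),
      stop("unknown contig length law: ", law$dist))
    if (total + l >= n) {
      rem <- n - total
      if (rem >= law_min && length(lens) >= 0) {
        lens <- c(lens, rem)
      } else if (length(lens) > 0) {
        lens[length(lens)] <- lens[length(lens)] + rem
      } else {
        lens <- n
      }
      break
    }
    lens <- c(lens, l)
    total <- total + l
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  data.frame(
    contig_id = sprintf("%s_%04d", prefix, seq_along(lens)),
    start = starts, end = ends, length = lens,
    seq = substring(genome, starts, ends),
    stringsAsFactors = FALSE
  )
}

#' Lay out non-overlapping gene models on contigs
#'
#' Deterministic tiling: genes of fixed nucleotide length separated by fixed
#' intergenic gaps, alternating strand, never spanning contig ends.
#'
#' @param contigs Contig data.frame (from [fragment_into_contigs()]), with a
#'   `pop_id` column.
#' @param gene_length Gene length in bases (multiple of 3).
#' @param gap Intergenic gap in bases.
#' @return Data.frame gene_id, contig_id, pop_id, start, end, strand, length,
#'   length_aa.
#' @export
place_genes <- function(contigs, gene_length = 900, gap = 100) {
  if (gene_length %% 3 != 0) stop("gene_length must be a multiple of 3")
  out <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    L <- contigs$length[i]
    ng <- (L - gap) %/% (gene_length + gap)
    if (ng < 1) next
    starts <- gap + (seq_len(ng) - 1L) * (gene_length + gap) + 1L
    out[[i]] <- data.frame(
      gene_id = sprintf("%s_g%03d", contigs$contig_id[i], seq_len(ng)),
      contig_id = contigs$contig_id[i],
      pop_id = contigs$pop_id[i],
      start = starts, end = starts + gene_length - 1L,
      strand = rep_len(c("+", "-"), ng),
      length = gene_length, length_aa = gene_length / 3L - 1L,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate metagenomic and metatranscriptomic count tables
#'
#' MetaG counts are multinomial across contigs with probability proportional
#' to population abundance x contig length. Per population, an exact rounded
#' fraction of genes is selected as expressed; expressed genes receive
#' gamma-distributed relative levels (mean 1, squared coefficient of
#' variation = `expression_dispersion`) and metaT counts are multinomial with
#' probability proportional to level x abundance x gene length. Non-expressed
#' genes get exactly zero metaT counts. Depth = count x read_length / length.
#'
#' @param community A [community_spec()].
#' @param contigs Contig data.frame with pop_id and length.
#' @param genes Gene data.frame from [place_genes()].
#' @param seed Integer seed (defaults to the community's counts substream).
#' @return List: `metag` (contig counts/depth), `metat` (gene counts/depth),
#'   `gene_truth` (gene_id, pop_id, expressed, level).
#' @export
simulate_counts <- function(community, contigs, genes,
                            seed = stage_seed(community$rng_seed, "counts")) {
  set.seed(seed)
  ab <- vapply(community$populations, `[[`, numeric(1), "relative_abundance")
  for (p in community$populations) {
    if (p$expressed_fraction > 0 && !any(genes$pop_id == p$pop_id))
      stop("population ", p$pop_id,
           " has expressed_fraction > 0 but no genes")
  }
  # metaG: multinomial over contigs
  pg <- ab[contigs$pop_id] * contigs$length
  metag_counts <- as.vector(rmultinom(1, community$total_metag_reads,
                                      pg / sum(pg)))
  metag <- data.frame(
    id = contigs$contig_id, length = contigs$length, count = metag_counts,
    depth = metag_counts * community$read_length / contigs$length,
    stringsAsFactors = FALSE
  )
  # expressed gene selection: exact rounded fraction per population
  expressed <- logical(nrow(genes))
  level <- numeric(nrow(genes))
  for (p in community$populations) {
    idx <- which(genes$pop_id == p$pop_id)
    n_exp <- round(p$expressed_fraction * length(idx))
    if (n_exp > 0) {
      sel <- sample(idx, n_exp)
      expressed[sel] <- TRUE
      disp <- p$expression_dispersion
      level[sel] <- if (disp > 0) rgamma(n_exp, shape = 1 / disp, rate = 1 / disp)
                    else 1
    }
  }
  pt <- ifelse(expressed, level * ab[genes$pop_id] * genes$length, 0)
  metat_counts <- integer(nrow(genes))
  if (any(pt > 0))
    metat_counts[pt > 0] <- as.vector(
      rmultinom(1, community$total_metat_reads, pt[pt > 0] / sum(pt)))
  metat <- data.frame(
    id = genes$gene_id, length = genes$length, count = metat_counts,
    depth = metat_counts * community$read_length / genes$length,
    stringsAsFactors = FALSE
  )
  list(
    metag = metag, metat = metat,
    gene_truth = data.frame(
      gene_id = genes$gene_id, pop_id = genes$pop_id,
      expressed = expressed, level = level, stringsAsFactors = FALSE
    )
  )
}

#' Default synthetic caller noise configuration
#'
#' Three synthetic callers emulating a multi-caller consensus. Per caller,
#' `fp_rate` is the number of uniformly placed false positives as a fraction
#' of the true variant count and `fn_rate` the Bernoulli dropout probability
#' per true variant. Rates of 0 make every caller report exactly the truth.
#'
#' @param fp_rate False-positive fraction (default 0.05).
#' @param fn_rate Dropout probability (default 0.02).
#' @return Named list of per-caller noise settings.
#' @export
default_callers <- function(fp_rate = 0.05, fn_rate = 0.02) {
  list(mpileup = list(fp_rate = fp_rate, fn_rate = fn_rate),
       gatk = list(fp_rate = fp_rate, fn_rate = fn_rate),
       freebayes = list(fp_rate = fp_rate, fn_rate = fn_rate))
}

offsets_to_coords <- function(offsets, iv) {
  cum <- cumsum(iv$len)
  idx <- findInterval(offsets - 1L, c(0L, cum), rightmost.closed = FALSE)
  pos <- iv$start[idx] + (offsets - c(0L, cum)[idx]) - 1L
  data.frame(contig = iv$contig[idx], pos = as.integer(pos),
             gene_id = iv$gene_id[idx], stringsAsFactors = FALSE)
}

#' Inject true variants and emit noisy per-caller call sets
#'
#' Places `round(snp_per_kb x genome_length / 1000)` true SNPs uniformly
#' without collision. By default variants land inside expressed genes, where
#' both metagenomic and metatranscriptomic coverage exists (a variant outside
#' transcribed sequence cannot carry metaT depth and could never survive a
#' joint depth filter); `region = "genome"` places them anywhere. Each
#' synthetic caller reports truth minus Bernoulli dropouts plus uniformly
#' placed false positives.
#'
#' When depths are supplied, placement is further restricted to genes whose
#' rounded metaT depth and whose contig's rounded metaG depth reach
#' `min_depth_placement`: a synthetic "true" variant in sequence without
#' adequate coverage in both libraries would be unobservable by construction
#' and is not meaningful ground truth.
#'
#' @param contigs Contig data.frame (one population) with seq.
#' @param spec The population's [population_spec()].
#' @param seed Integer seed.
#' @param genes,expressed_ids Gene table and expressed gene ids (required for
#'   `region = "expressed"`).
#' @param depth_g Named per-contig metaG depth (defaults to 50).
#' @param depth_t Named per-gene metaT depth (defaults to 50 inside genes,
#'   0 elsewhere).
#' @param callers Named list of per-caller noise rates (`fp_rate`, `fn_rate`);
#'   see `default_callers()`.
#' @param region "expressed" or "genome".
#' @param min_depth_placement Coverage floor for placement when depths are
#'   supplied (default 10).
#' @return List: `truth` data.frame (contig, pos, ref, alt, pop_id, depth_g,
#'   depth_t) and `callsets`, a named list of caller data.frames of the same
#'   shape.
#' @export
inject_variants <- function(contigs, spec, seed, genes = NULL,
                            expressed_ids = NULL, depth_g = NULL,
                            depth_t = NULL, callers = default_callers(),
                            region = c("expressed", "genome"),
                            min_depth_placement = 10) {
  region <- match.arg(region)
  set.seed(seed)
  glen <- sum(contigs$length)
  n_true <- round(spec$snp_per_kb * glen / 1000)
  if (region == "expressed") {
    if (is.null(genes)) stop("region = 'expressed' needs a gene table")
    gsub_ <- genes[genes$gene_id %in% expressed_ids &
                     genes$contig_id %in% contigs$contig_id, , drop = FALSE]
    if (!is.null(depth_t))
      gsub_ <- gsub_[round(depth_t[gsub_$gene_id]) >= min_depth_placement, ,
                     drop = FALSE]
    if (!is.null(depth_g))
      gsub_ <- gsub_[round(depth_g[gsub_$contig_id]) >= min_depth_placement, ,
                     drop = FALSE]
    iv <- data.frame(contig = gsub_$contig_id, start = gsub_$start,
                     len = gsub_$end - gsub_$start + 1L,
                     gene_id = gsub_$gene_id, stringsAsFactors = FALSE)
  } else {
    keep <- if (!is.null(depth_g))
      round(depth_g[contigs$contig_id]) >= min_depth_placement
    else rep(TRUE, nrow(contigs))
    iv <- data.frame(contig = contigs$contig_id[keep], start = 1L,
                     len = contigs$length[keep], gene_id = NA_character_,
                     stringsAsFactors = FALSE)
  }
  space <- sum(iv$len)
  if (n_true > space)
    stop("cannot place ", n_true, " variants without collision in ",
         space, " available bases")
  seqs <- setNames(contigs$seq, contigs$contig_id)
  draw_variants <- function(offsets) {
    if (length(offsets) == 0)
      return(data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        pop_id = character(0), depth_g = numeric(0),
                        depth_t = numeric(0), stringsAsFactors = FALSE))
    co <- offsets_to_coords(offsets, iv)
    ref <- substring(seqs[co$contig], co$pos, co$pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1), USE.NAMES = FALSE)
    dg <- if (is.null(depth_g)) rep(50, nrow(co)) else unname(depth_g[co$contig])
    dt <- if (is.null(depth_t)) {
      ifelse(is.na(co$gene_id), 0, 50)
    } else {
      ifelse(is.na(co$gene_id), 0, unname(depth_t[co$gene_id]))
    }
    data.frame(contig = co$contig, pos = co$pos, ref = unname(ref), alt = alt,
               pop_id = spec$pop_id, depth_g = round(dg), depth_t = round(dt),
               stringsAsFactors = FALSE)
  }
  true_off <- if (n_true > 0) sort(sample.int(space, n_true)) else integer(0)
  truth <- draw_variants(true_off)
  callsets <- lapply(names(callers), function(cl) {
    rates <- callers[[cl]]
    keep <- if (nrow(truth) > 0) runif(nrow(truth)) >= rates$fn_rate else logical(0)
    cs <- truth[keep, , drop = FALSE]
    n_fp <- round(rates$fp_rate * n_true)
    if (n_fp > 0) {
      free <- setdiff(seq_len(space), true_off)
      fp <- draw_variants(sort(sample(free, min(n_fp, length(free)))))
      cs <- rbind(cs, fp)
    }
    cs <- cs[order(cs$contig, cs$pos), , drop = FALSE]
    rownames(cs) <- NULL
    cs
  })
  names(callsets) <- names(callers)
  rownames(truth) <- NULL
  list(truth = truth, callsets = callsets)
}

#' Simulate sparse protein-level spectral evidence
#'
#' For an exact rounded `proteome_detect_fraction` subset of the expressed
#' genes, emits one or more peptides each with one or more spectra carrying
#' positive summed fragment-ion intensities; undetected proteins are absent
#' from the table.
#'
#' @param gene_truth Gene truth table (gene_id, expressed, level).
#' @param genes Gene table with length_aa.
#' @param spec The population's [population_spec()].
#' @param seed Integer seed.
#' @return Data.frame protein_id, length_aa, peptide_id, spectrum_id,
#'   intensity.
#' @export
simulate_spectra <- function(gene_truth, genes, spec, seed) {
  set.seed(seed)
  expr <- gene_truth[gene_truth$expressed & gene_truth$pop_id == spec$pop_id, ,
                     drop = FALSE]
  n_det <- round(spec$proteome_detect_fraction * nrow(expr))
  empty <- data.frame(protein_id = character(0), length_aa = integer(0),
                      peptide_id = character(0), spectrum_id = character(0),
                      intensity = numeric(0), stringsAsFactors = FALSE)
  if (n_det == 0) return(empty)
  det <- expr[sample.int(nrow(expr), n_det), , drop = FALSE]
  aa <- setNames(genes$length_aa, genes$gene_id)
  rows <- lapply(seq_len(nrow(det)), function(i) {
    g <- det$gene_id[i]
    n_pep <- 1 + rpois(1, 2)
    do.call(rbind, lapply(seq_len(n_pep), function(p) {
      n_spec <- 1 + rpois(1, 1)
      data.frame(
        protein_id = g, length_aa = unname(aa[g]),
        peptide_id = sprintf("%s_p%02d", g, p),
        spectrum_id = sprintf("%s_p%02d_s%02d", g, p, seq_len(n_spec)),
        intensity = rlnorm(n_spec, meanlog = log(1e5 * max(det$level[i], 1e-3)),
                           sdlog = 1),
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# COG letters used for synthetic annotations (single-letter categories plus
# the multi/none classes handled by cog_profile()).
cog_alphabet <- function() {
  c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L", "M", "N",
    "O", "P", "Q", "R", "S", "T", "U", "V", "Z")
}

simulate_annotations <- function(genes, seed) {
  set.seed(seed)
  letters_ <- cog_alphabet()
  kind <- sample(c("single", "multi", "none"), nrow(genes), replace = TRUE,
                 prob = c(0.80, 0.15, 0.05))
  cog <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    cog[i] <- switch(kind[i],
      single = sample(letters_, 1),
      multi = paste(sample(letters_, 2), collapse = ""),
      none = "")
  }
  data.frame(gene_id = genes$gene_id, cog = cog, stringsAsFactors = FALSE)
}

#' The 40-marker universal single-copy gene panel identifiers
#'
#' Synthetic identifiers for a 40-gene universal single-copy marker panel
#' used for completeness estimation.
#' @return Character vector of length 40.
#' @export
uscg_panel <- function() sprintf("USCG_%02d", 1:40)

simulate_markers <- function(community, seed) {
  set.seed(seed)
  panel <- uscg_panel()
  do.call(rbind, lapply(community$populations, function(p) {
    # most populations near-complete; drop a few markers at random
    n_miss <- sample(0:3, 1, prob = c(0.55, 0.25, 0.12, 0.08))
    present <- if (n_miss > 0) sample(panel, 40 - n_miss) else panel
    data.frame(pop_id = p$pop_id, marker = sort(present),
               stringsAsFactors = FALSE)
  }))
}

simulate_abundance_matrix <- function(community, seed, n_samples = 8,
                                      depth = 12000) {
  set.seed(seed)
  ab <- vapply(community$populations, `[[`, numeric(1), "relative_abundance")
  n_extra <- 4
  taxa <- c(names(ab), sprintf("rare_%02d", seq_len(n_extra)))
  base <- c(ab * 0.9, rep(0.1 / n_extra, n_extra))
  counts <- sapply(seq_len(n_samples), function(s) {
    p <- base * rlnorm(length(base), 0, 0.4)
    as.vector(rmultinom(1, depth, p / sum(p)))
  })
  dimnames(counts) <- list(taxa, sprintf("S%02d", seq_len(n_samples)))
  counts
}

simulate_lipids <- function(community, abundance, seed) {
  set.seed(seed)
  compounds <- c("hexanoic", "octanoic", "decanoic", "dodecanoic",
                 "tetradecanoic", "palmitoleic", "hexadecanoic", "linoleic",
                 "oleic", "linolenic", "octadecanoic", "eicosanoic",
                 "docosanoic", "tetracosanoic")
  samples <- colnames(abundance)
  p1 <- abundance[1, ] / colSums(abundance)  # dominant lipid accumulator
  rows <- lapply(compounds, function(cmp) {
    extra <- rlnorm(length(samples), log(10), 0.3)
    base_ratio <- rlnorm(1, log(2), 0.4)
    # the two monounsaturated compounds track the dominant population
    coupled <- cmp %in% c("palmitoleic", "oleic")
    ratio <- if (coupled) base_ratio * (p1 / mean(p1))^2
             else base_ratio * rlnorm(length(samples), 0, 0.25)
    data.frame(compound = cmp, sample = samples,
               intracellular = extra * ratio, extracellular = extra,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete ground-truthed synthetic community
#'
#' Runs every generator stage from a single root seed: genomes, contig
#' fragmentation, gene models, metaG/metaT count tables, variant truth plus
#' noisy caller sets, protein spectral evidence, COG annotations, marker
#' presence, a taxon abundance matrix and a lipid quantification table.
#'
#' @param spec A [community_spec()].
#' @param callers Caller noise configuration (see `default_callers()`);
#'   set rates to 0 for noise-free call sets.
#' @param variant_region "expressed" (default) or "genome".
#' @return A list of class `community` with elements contigs, genes, counts
#'   (metag/metat), variants (truth + callsets), evidence, annotations,
#'   markers, abundance, lipids, and truth tables.
#' @export
simulate_community <- function(spec, callers = default_callers(),
                               variant_region = "expressed") {
  stopifnot(inherits(spec, "community_spec"))
  root <- spec$rng_seed
  contigs <- do.call(rbind, lapply(seq_along(spec$populations), function(i) {
    p <- spec$populations[[i]]
    genome <- generate_genome(p, stage_seed(root, "genome") + i)
    ctg <- fragment_into_contigs(genome, spec$contig_length_law,
                                 seed = stage_seed(root, "fragment") + i,
                                 prefix = p$pop_id)
    ctg$pop_id <- p$pop_id
    ctg
  }))
  rownames(contigs) <- NULL
  genes <- place_genes(contigs)
  counts <- simulate_counts(spec, contigs, genes)
  depth_g <- setNames(counts$metag$depth, counts$metag$id)
  depth_t <- setNames(counts$metat$depth, counts$metat$id)
  expressed_ids <- counts$gene_truth$gene_id[counts$gene_truth$expressed]
  var_parts <- lapply(seq_along(spec$populations), function(i) {
    p <- spec$populations[[i]]
    inject_variants(contigs[contigs$pop_id == p$pop_id, , drop = FALSE], p,
                    seed = stage_seed(root, "variants") + i, genes = genes,
                    expressed_ids = expressed_ids, depth_g = depth_g,
                    depth_t = depth_t, callers = callers,
                    region = variant_region)
  })
  truth <- do.call(rbind, lapply(var_parts, `[[`, "truth"))
  rownames(truth) <- NULL
  caller_names <- names(callers)
  callsets <- setNames(lapply(caller_names, function(cl) {
    cs <- do.call(rbind, lapply(var_parts, function(v) v$callsets[[cl]]))
    rownames(cs) <- NULL
    cs
  }), caller_names)
  evidence <- do.call(rbind, lapply(seq_along(spec$populations), function(i) {
    simulate_spectra(counts$gene_truth, genes, spec$populations[[i]],
                     seed = stage_seed(root, "spectra") + i)
  }))
  rownames(evidence) <- NULL
  annotations <- simulate_annotations(genes, stage_seed(root, "abundance") + 7L)
  markers <- simulate_markers(spec, stage_seed(root, "abundance") + 13L)
  abundance <- simulate_abundance_matrix(spec, stage_seed(root, "abundance"))
  lipids <- simulate_lipids(spec, abundance, stage_seed(root, "lipids"))
  structure(list(
    spec = spec, contigs = contigs, genes = genes,
    metag = counts$metag, metat = counts$metat,
    gene_truth = counts$gene_truth,
    variant_truth = truth, callsets = callsets,
    evidence = evidence, annotations = annotations, markers = markers,
    abundance = abundance, lipids = lipids,
    contig_to_pop = setNames(contigs$pop_id, contigs$contig_id),
    abundance_truth = vapply(spec$populations, `[[`, numeric(1),
                             "relative_abundance")
  ), class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat("Synthetic community realisation:\n")
  cat(sprintf("  %d contigs (%.1f Mb), %d genes, %d true variants, %d proteins with evidence\n",
              nrow(x$contigs), sum(x$contigs$length) / 1e6, nrow(x$genes),
              nrow(x$variant_truth), length(unique(x$evidence$protein_id))))
  invisible(x)
}
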