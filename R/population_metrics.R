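#' Relative population sizes of composite genomes
#'
#' Length-normalized relative abundance of each composite genome from its
#' mapped metagenomic read count `c_i` and length `l_i`. The default
#' "relative" mode returns `N_i = (c_i/l_i) / sum_j(c_j/l_j)`, a
#' dimensionless relative size summing to 1 across CGs; "rpkm_like" returns
#' `N_i = 1e9 * c_i / (C * l_i)` with `C` the total reads mappable to all
#' CGs. The two modes are proportional within a sample; the mode used is
#' recorded as an attribute.
#'
#' @param profiles Data.frame with columns cg_id, l_i (bases) and c_i
#'   (mapped reads).
#' @param mode "relative" (default) or "rpkm_like".
#' @return The input data.frame with an `N_i` column and a `mode` attribute.
#' @export
population_size <- function(profiles, mode = c("relative", "rpkm_like")) {
  mode <- match.arg(mode)
  stopifnot(all(c("cg_id", "l_i", "c_i") %in% names(profiles)))
  if (any(profiles$l_i <= 0)) stop("composite genome lengths must be positive")
  C <- sum(profiles$c_i)
  if (C <= 0) stop("zero total mappable reads")
  rate <- profiles$c_i / profiles$l_i
  profiles$N_i <- switch(mode,
    relative = rate / sum(rate),
    rpkm_like = 1e9 * profiles$c_i / (C * profiles$l_i))
  attr(profiles, "mode") <- mode
  profiles
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count * 1e9 / (gene_length * total_mapped)`.
#'
#' @param count Mapped fragment count(s).
#' @param gene_length Gene length(s) in bases.
#' @param total_mapped Total mapped fragments in the library.
#' @return Numeric FPKM value(s).
#' @export
fpkm <- function(count, gene_length, total_mapped) {
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  count * 1e9 / (gene_length * total_mapped)
}

#' Population-normalized expression call
#'
#' A gene is called expressed when its metatranscriptomic FPKM is at least
#' `factor` times the relative population size of its composite genome
#' (boundary equality counts as expressed). The threshold scales with
#' population size so that expression calls are comparable between abundant
#' and rare populations.
#'
#' @param metat_fpkm Metatranscriptomic FPKM value(s).
#' @param n_i Relative population size(s) `N_i` of the gene's CG.
#' @param factor Threshold multiplier (default 50).
#' @return Logical vector of expression calls.
#' @export
call_expressed <- function(metat_fpkm, n_i, factor = 50) {
  metat_fpkm >= factor * n_i
}

#' Percentage of genes expressed in a composite genome
#'
#' @param calls Logical expression calls for every gene of the CG.
#' @return Percent expressed (0-100).
#' @export
expressed_fraction <- function(calls) {
  if (length(calls) == 0) stop("composite genome has zero genes")
  100 * sum(calls) / length(calls)
}

#' Build the per-gene expression table for a community sample
#'
#' Joins gene counts to bin assignments, computes metaG/metaT FPKM, relative
#' population sizes and the population-normalized expression call.
#'
#' @param genes Data.frame gene_id, contig_id, length.
#' @param assignments Contig-to-CG assignments (contig_id, cg_id).
#' @param metag_gene_counts,metat_counts Data.frames (id, count) of per-gene
#'   metaG and metaT fragment counts; metaG gene counts may be NULL.
#' @param profiles Output of [population_size()] for the same sample.
#' @param factor Expression threshold multiplier (default 50).
#' @return Data.frame gene_id, cg_id, length, metag_fpkm, metat_fpkm, N_i,
#'   expressed.
#' @export
expression_table <- function(genes, assignments, metat_counts, profiles,
                             metag_gene_counts = NULL, factor = 50) {
  cg <- assignments$cg_id[match(genes$contig_id, assignments$contig_id)]
  n_i <- setNames(profiles$N_i, profiles$cg_id)
  tc <- metat_counts$count[match(genes$gene_id, metat_counts$id)]
  tc[is.na(tc)] <- 0
  total_t <- sum(metat_counts$count)
  out <- data.frame(
    gene_id = genes$gene_id, cg_id = cg, length = genes$length,
    metat_fpkm = fpkm(tc, genes$length, total_t),
    stringsAsFactors = FALSE
  )
  if (!is.null(metag_gene_counts)) {
    gcnt <- metag_gene_counts$count[match(genes$gene_id, metag_gene_counts$id)]
    gcnt[is.na(gcnt)] <- 0
    out$metag_fpkm <- fpkm(gcnt, genes$length, sum(metag_gene_counts$count))
  }
  out$N_i <- unname(n_i[out$cg_id])
  out$expressed <- call_expressed(out$metat_fpkm, out$N_i, factor)
  attr(out, "factor") <- factor
  out
}

# COG category alphabet of the functional profile (single letters plus the
# multi-membership and unassigned classes)
cog_categories <- function() c(cog_alphabet(), "Multi-I", "Multi+I", "No")

#' Functional COG profile of a composite genome
#'
#' Counts genes per COG category. Genes annotated with several categories
#' collapse to "Multi+I" when lipid transport and metabolism (I) is among
#' them and to "Multi-I" otherwise; unannotated genes count as "No". Counts
#' are normalized by the total number of genes, so the normalized profile
#' sums to 1.
#'
#' @param cogs Character vector of per-gene COG letters ("E", "EI", "", ...).
#' @param cg_id Optional label stored on the result.
#' @return List of class `cog_profile`: cg_id, counts, normalized.
#' @export
cog_profile <- function(cogs, cg_id = NA_character_) {
  cogs[is.na(cogs)] <- ""
  letters_seen <- unique(unlist(strsplit(cogs, "")))
  bad <- setdiff(letters_seen, cog_alphabet())
  if (length(bad))
    stop("unknown COG category symbol(s): ", paste(bad, collapse = ", "))
  collapse1 <- function(s) {
    if (nchar(s) == 0) return("No")
    if (nchar(s) == 1) return(s)
    if (grepl("I", s, fixed = TRUE)) "Multi+I" else "Multi-I"
  }
  cls <- vapply(cogs, collapse1, character(1), USE.NAMES = FALSE)
  counts <- table(factor(cls, levels = cog_categories()))
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(cg_id = cg_id, counts = counts,
                 normalized = counts / length(cogs)),
            class = "cog_profile")
}

#' @export
print.cog_profile <- function(x, ...) {
  cat("COG profile", if (!is.na(x$cg_id)) paste0("(", x$cg_id, ")"),
      "- top categories:\n")
  top <- sort(x$normalized[x$counts > 0], decreasing = TRUE)
  print(round(utils::head(top, 8), 3))
  invisible(x)
}

#' Genome completeness from universal single-copy genes
#'
#' Percentage of a universal single-copy marker panel detected at least once
#' in a composite genome's annotations.
#'
#' @param found Character vector of marker identifiers detected in the CG.
#' @param panel The marker panel (default the 40-gene panel of
#'   [uscg_panel()]).
#' @return Percent complete (0-100).
#' @export
completeness <- function(found, panel = uscg_panel()) {
  if (length(panel) == 0) stop("empty marker panel")
  100 * length(intersect(unique(found), panel)) / length(panel)
}

#' Average amino-acid identity between two proteomes
#'
#' Identifies putative orthologues as reciprocal best hits under global
#' (Needleman-Wunsch) alignment with the BLOSUM62 substitution matrix, and
#' summarises their percent identities (matches over alignment columns).
#'
#' @param proteome_a,proteome_b Named character vectors or `AAStringSet`s.
#' @param gap_opening,gap_extension Gap penalties (defaults 10 and 0.5).
#' @return List of class `aai_result`: n_orthologs, median_identity,
#'   sd_identity, pairs (data.frame a, b, identity). When no reciprocal pair
#'   exists, n_orthologs is 0 and the summaries are NA.
#' @export
aai <- function(proteome_a, proteome_b, gap_opening = 10,
                gap_extension = 0.5) {
  pa <- if (inherits(proteome_a, "AAStringSet")) proteome_a
        else Biostrings::AAStringSet(proteome_a)
  pb <- if (inherits(proteome_b, "AAStringSet")) proteome_b
        else Biostrings::AAStringSet(proteome_b)
  if (length(pa) == 0 || length(pb) == 0) stop("both proteomes must be non-empty")
  if (is.null(names(pa))) names(pa) <- paste0("a", seq_along(pa))
  if (is.null(names(pb))) names(pb) <- paste0("b", seq_along(pb))
  score <- matrix(NA_real_, length(pa), length(pb),
                  dimnames = list(names(pa), names(pb)))
  ident <- score
  for (i in seq_along(pa)) {
    aln <- Biostrings::pairwiseAlignment(
      rep(pa[i], length(pb)), pb, type = "global",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension)
    score[i, ] <- Biostrings::score(aln)
    ident[i, ] <- Biostrings::pid(aln, type = "PID1")
  }
  best_ab <- max.col(score, ties.method = "first")
  best_ba <- max.col(t(score), ties.method = "first")
  rbh <- which(best_ba[best_ab] == seq_along(best_ab))
  pairs <- data.frame(
    a = names(pa)[rbh], b = names(pb)[best_ab[rbh]],
    identity = ident[cbind(rbh, best_ab[rbh])],
    stringsAsFactors = FALSE
  )
  structure(list(
    n_orthologs = nrow(pairs),
    median_identity = if (nrow(pairs)) median(pairs$identity) else NA_real_,
    sd_identity = if (nrow(pairs) > 1) sd(pairs$identity) else NA_real_,
    pairs = pairs
  ), class = "aai_result")
}

#' @export
print.aai_result <- function(x, ...) {
  if (x$n_orthologs == 0) {
    cat("AAI: no reciprocal best-hit orthologue pairs\n")
  } else {
    cat(sprintf("AAI: median %.1f%% +/- %.1f (n = %d orthologue pairs)\n",
                x$median_identity, x$sd_identity %||% NA, x$n_orthologs))
  }
  invisible(x)
}
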