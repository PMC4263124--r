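new_callset <- function(df, caller, n_skipped = 0L) {
  stopifnot(all(c("contig", "pos", "ref", "alt", "depth_g", "depth_t") %in%
                  names(df)))
  df <- df[order(df$contig, df$pos, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, caller = caller, n_skipped = n_skipped,
            class = c("callset", "data.frame"))
}

variant_keys <- function(df) paste(df$contig, df$pos, df$ref, df$alt, sep = ":")

#' Read a SNP call set from a VCF file
#'
#' Parses a VCF 4.2 file into a normalized call set of biallelic SNPs.
#' Multiallelic records are decomposed into one variant per alternate
#' allele; indels and other non-SNP alleles are skipped and counted.
#' Per-variant metagenomic and metatranscriptomic depths are read from INFO
#' fields (default `DPG` and `DPT`).
#'
#' @param path VCF file path.
#' @param caller Caller label (default: file name without extension).
#' @param depth_fields Length-2 named character vector: INFO keys for the
#'   metaG and metaT depths.
#' @param missing_depth "zero" (default) records depth 0 when the field is
#'   absent; "skip" drops the record.
#' @return A `callset` data.frame (contig, pos, ref, alt, depth_g, depth_t)
#'   with attributes `caller` and `n_skipped`.
#' @export
parse_vcf <- function(path, caller = NULL,
                      depth_fields = c(g = "DPG", t = "DPT"),
                      missing_depth = c("zero", "skip")) {
  missing_depth <- match.arg(missing_depth)
  caller <- caller %||% sub("\\.vcf$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(new_callset(data.frame(contig = character(0), pos = integer(0),
                                  ref = character(0), alt = character(0),
                                  depth_g = numeric(0), depth_t = numeric(0),
                                  stringsAsFactors = FALSE), caller))
  dg <- suppressWarnings(as.numeric(vcfR::extract.info(v, depth_fields[["g"]])))
  dt <- suppressWarnings(as.numeric(vcfR::extract.info(v, depth_fields[["t"]])))
  rows <- vector("list", nrow(fix))
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    if (is.na(pos)) stop("malformed VCF record at data line ", i)
    ref <- toupper(fix$REF[i])
    alts <- toupper(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    snp <- nchar(ref) == 1 & nchar(alts) == 1 &
      ref %in% c("A", "C", "G", "T") & alts %in% c("A", "C", "G", "T") &
      alts != ref
    n_skipped <- n_skipped + sum(!snp)
    if (!any(snp)) next
    gi <- dg[i]; ti <- dt[i]
    if (is.na(gi) || is.na(ti)) {
      if (missing_depth == "skip") { n_skipped <- n_skipped + sum(snp); next }
      gi <- if (is.na(gi)) 0 else gi
      ti <- if (is.na(ti)) 0 else ti
    }
    rows[[i]] <- data.frame(contig = fix$CHROM[i], pos = pos, ref = ref,
                            alt = alts[snp], depth_g = gi, depth_t = ti,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df))
    df <- data.frame(contig = character(0), pos = integer(0),
                     ref = character(0), alt = character(0),
                     depth_g = numeric(0), depth_t = numeric(0),
                     stringsAsFactors = FALSE)
  new_callset(df, caller, n_skipped)
}

#' Write a call set as a minimal VCF 4.2 file
#'
#' SNP-only records; per-variant metaG/metaT depths go to the INFO fields
#' `DPG` and `DPT`.
#'
#' @param df Data.frame with contig, pos, ref, alt, depth_g, depth_t.
#' @param path Output path.
#' @param source Value of the `##source` header line.
#' @return Invisibly, the path.
#' @export
write_vcf <- function(df, path, source = "popomics") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source),
    "##INFO=<ID=DPG,Number=1,Type=Integer,Description=\"Metagenomic read depth\">",
    "##INFO=<ID=DPT,Number=1,Type=Integer,Description=\"Metatranscriptomic read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  df <- df[order(df$contig, df$pos, df$alt), , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDPG=%d;DPT=%d",
                  df$contig, as.integer(df$pos), df$ref, df$alt,
                  as.integer(round(df$depth_g)),
                  as.integer(round(df$depth_t)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Intersect SNP call sets from multiple callers
#'
#' Keeps variants identified (same contig, position, reference and alternate
#' allele) by every caller. Depths are taken as the per-library minimum
#' across callers (conservative).
#'
#' @param callsets List of at least two call sets (from [parse_vcf()] or of
#'   the same shape).
#' @return A `callset` data.frame of the consensus variants.
#' @export
intersect_callsets <- function(callsets) {
  if (length(callsets) < 2)
    stop("need at least two call sets to intersect")
  keys <- lapply(callsets, variant_keys)
  common <- Reduce(intersect, keys)
  first <- callsets[[1]]
  out <- first[match(common, keys[[1]]), , drop = FALSE]
  if (nrow(out)) {
    for (i in seq_along(callsets)[-1]) {
      m <- match(common, keys[[i]])
      out$depth_g <- pmin(out$depth_g, callsets[[i]]$depth_g[m])
      out$depth_t <- pmin(out$depth_t, callsets[[i]]$depth_t[m])
    }
  }
  new_callset(as.data.frame(out), caller = "intersection")
}

#' Joint metagenomic/metatranscriptomic depth filter
#'
#' Keeps variants whose read depth is at least `min_depth` in both the
#' metagenomic and the metatranscriptomic library (boundary inclusive).
#'
#' @param variants Call set data.frame with depth_g and depth_t.
#' @param min_depth Minimum depth in each library (default 10).
#' @return The filtered call set.
#' @export
depth_filter <- function(variants, min_depth = 10) {
  keep <- variants$depth_g >= min_depth & variants$depth_t >= min_depth
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Population-normalized variant density
#'
#' SNP density per kilobase of composite genome, and that density divided by
#' the relative population size `N_i`, which makes densities comparable
#' between abundant and rare populations.
#'
#' @param v_i Variant count(s) per CG.
#' @param l_i CG length(s) in bases.
#' @param n_i Relative population size(s).
#' @param cg_id Optional CG labels.
#' @return Data.frame cg_id, v_i, snp_per_kb, normalized_density.
#' @export
variant_density <- function(v_i, l_i, n_i, cg_id = NULL) {
  if (any(l_i <= 0)) stop("l_i must be positive")
  if (any(n_i <= 0)) stop("N_i must be positive")
  snp_per_kb <- v_i / (l_i / 1000)
  data.frame(
    cg_id = cg_id %||% paste0("CG", seq_along(v_i)),
    v_i = v_i, snp_per_kb = snp_per_kb,
    normalized_density = snp_per_kb / n_i,
    stringsAsFactors = FALSE
  )
}

#' Count variants per gene
#'
#' A variant counts toward every gene whose interval (1-based inclusive)
#' contains its position; overlapping genes are each incremented. Variants
#' falling in no gene are reported as the intergenic count.
#'
#' @param variants Call set data.frame (contig, pos).
#' @param genes Data.frame gene_id, contig_id, start, end.
#' @return List: `per_gene` (data.frame gene_id, n_variants) and
#'   `intergenic` (count).
#' @export
per_gene_variant_counts <- function(variants, genes) {
  if (any(genes$end < genes$start))
    stop("gene interval with end < start: ",
         genes$gene_id[which(genes$end < genes$start)[1]])
  gr_genes <- GenomicRanges::GRanges(
    genes$contig_id, IRanges::IRanges(genes$start, genes$end))
  gr_var <- GenomicRanges::GRanges(
    variants$contig, IRanges::IRanges(variants$pos, width = 1))
  hits <- GenomicRanges::countOverlaps(gr_genes, gr_var)
  in_gene <- GenomicRanges::countOverlaps(gr_var, gr_genes) > 0
  list(
    per_gene = data.frame(gene_id = genes$gene_id, n_variants = hits,
                          stringsAsFactors = FALSE),
    intergenic = sum(!in_gene)
  )
}

#' Variant summary per composite genome
#'
#' Maps a filtered consensus call set onto contig-to-CG assignments and
#' computes per-CG counts and population-normalized densities.
#'
#' @param variants Filtered call set (contig, pos, ...).
#' @param assignments Contig assignments (contig_id, cg_id).
#' @param profiles Output of [population_size()] (cg_id, l_i, N_i).
#' @return Data.frame from [variant_density()], one row per CG in
#'   `profiles`.
#' @export
variant_summary <- function(variants, assignments, profiles) {
  cg <- assignments$cg_id[match(variants$contig, assignments$contig_id)]
  counts <- table(factor(cg, levels = profiles$cg_id))
  variant_density(as.integer(counts), profiles$l_i, profiles$N_i,
                  cg_id = profiles$cg_id)
}
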