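#' Read a FASTA file of contigs
#'
#' Bases are upper-cased; record ids are the first whitespace-delimited token
#' of each header, with full descriptions retained as an attribute.
#'
#' @param path FASTA file.
#' @return A named `DNAStringSet` with a `descriptions` attribute.
#' @export
read_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA file: ", path)
  desc <- names(raw)
  ids <- vapply(strsplit(desc, "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         ids[duplicated(ids)][1])
  out <- Biostrings::DNAStringSet(toupper(as.character(raw)))
  names(out) <- ids
  attr(out, "descriptions") <- setNames(desc, ids)
  out
}

#' Write sequences as wrapped FASTA
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- if (inherits(seqs, "XStringSet")) seqs
        else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Returns the gene/CDS features with 1-based inclusive coordinates.
#'
#' @param path GFF3 file.
#' @param types Feature types to keep (default gene and CDS).
#' @return Data.frame gene_id, contig_id, start, end, strand, length.
#' @export
read_gff3 <- function(path, types = c("gene", "CDS")) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 in ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% types]
  id <- gr$ID %||% as.character(seq_along(gr))
  data.frame(
    gene_id = id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length = GenomicRanges::width(gr),
    stringsAsFactors = FALSE
  )
}

#' Write gene models as GFF3
#' @param genes Data.frame gene_id, contig_id, start, end, strand.
#' @param path Output path.
#' @param type Feature type (default CDS).
#' @return Invisibly, the path.
#' @export
write_gff3 <- function(genes, path, type = "CDS") {
  lines <- sprintf("%s\tpopomics\t%s\t%d\t%d\t.\t%s\t0\tID=%s",
                   genes$contig_id, type, as.integer(genes$start),
                   as.integer(genes$end), genes$strand, genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# TSV conventions: tab-separated, UTF-8, '.' decimal, '#'-prefixed metadata
# header naming units/modes.
write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", unlist(meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Write a simulated community bundle to disk
#'
#' Emits the standard input files of the analysis pipeline (contigs.fasta,
#' genes.gff3, count and depth TSVs, per-caller VCFs, protein evidence,
#' annotations, marker table, abundance and lipid tables) plus ground-truth
#' tables under `truth/`.
#'
#' @param bundle A `community` from [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_community <- function(bundle, dir) {
  stopifnot(inherits(bundle, "community"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_fasta(setNames(bundle$contigs$seq, bundle$contigs$contig_id),
              p("contigs.fasta"))
  write_gff3(bundle$genes, p("genes.gff3"))
  write_tsv(bundle$metag[, c("id", "length", "count")], p("metag_counts.tsv"),
            meta = list(library = "metagenomic", units = "fragment counts"))
  write_tsv(bundle$metat[, c("id", "length", "count")], p("metat_counts.tsv"),
            meta = list(library = "metatranscriptomic",
                        units = "fragment counts"))
  write_tsv(data.frame(id = bundle$metag$id,
                       depth_g = bundle$metag$depth,
                       stringsAsFactors = FALSE),
            p("depth.tsv"), meta = list(units = "fold coverage"))
  for (cl in names(bundle$callsets))
    write_vcf(bundle$callsets[[cl]], p(paste0("caller_", cl, ".vcf")),
              source = paste0("popomics-synthetic-", cl))
  write_tsv(bundle$evidence, p("protein_evidence.tsv"),
            meta = list(units = "summed fragment-ion intensity"))
  write_tsv(bundle$annotations, p("annotations.tsv"))
  write_tsv(bundle$markers, p("markers.tsv"))
  writeLines(uscg_panel(), p("uscg_panel.txt"))
  ab <- data.frame(taxon = rownames(bundle$abundance), bundle$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(ab, p("abundance.tsv"), meta = list(units = "read counts"))
  write_tsv(bundle$lipids, p("lipids.tsv"),
            meta = list(units = "concentration, arbitrary"))
  write_tsv(data.frame(contig_id = names(bundle$contig_to_pop),
                       pop_id = unname(bundle$contig_to_pop),
                       stringsAsFactors = FALSE),
            p("truth", "contig_to_pop.tsv"))
  write_tsv(bundle$gene_truth, p("truth", "gene_truth.tsv"))
  write_tsv(bundle$variant_truth, p("truth", "variant_truth.tsv"))
  write_tsv(data.frame(pop_id = names(bundle$abundance_truth),
                       abundance = unname(bundle$abundance_truth),
                       stringsAsFactors = FALSE),
            p("truth", "abundance_truth.tsv"))
  invisible(dir)
}
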