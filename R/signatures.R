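#' Canonical k-mers under reverse-complement collapsing
#'
#' Each k-mer over A/C/G/T is represented by the lexicographically smaller of
#' itself and its reverse complement. For odd k no k-mer is its own reverse
#' complement, so the canonical set has exactly 4^k / 2 members (512
#' pentamers).
#'
#' @param k Word size (default 5).
#' @return Sorted character vector of canonical k-mers.
#' @export
canonical_pentamers <- function(k = 5) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), stringsAsFactors = FALSE))
  kmers <- do.call(paste0, grid[, k:1, drop = FALSE])
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  sort(unique(ifelse(kmers <= rc, kmers, rc)))
}

#' Canonicalize a single k-mer
#' @param kmer A k-mer over A/C/G/T.
#' @return The lexicographically smaller of the k-mer and its reverse
#'   complement.
#' @export
canonicalize_kmer <- function(kmer) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  if (kmer <= rc) kmer else rc
}

# cached canonical collapse matrix: 4^k x (4^k / 2) indicator
kmer_cache <- new.env(parent = emptyenv())

canonical_collapse_matrix <- function(k = 5) {
  key <- paste0("k", k)
  if (!is.null(kmer_cache[[key]])) return(kmer_cache[[key]])
  all_k <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(all_k)))
  canon <- ifelse(all_k <= rc, all_k, rc)
  canon_set <- canonical_pentamers(k)
  M <- matrix(0, length(all_k), length(canon_set),
              dimnames = list(all_k, canon_set))
  M[cbind(seq_along(all_k), match(canon, canon_set))] <- 1
  kmer_cache[[key]] <- M
  M
}

#' Canonical k-mer signature of one sequence
#'
#' Slides a width-k window with step 1; windows containing any non-A/C/G/T
#' symbol match no k-mer and are skipped; each valid window increments its
#' canonical k-mer.
#'
#' @param sequence Character string or `DNAString`.
#' @param k Word size (default 5).
#' @return Named integer vector over the canonical k-mer set.
#' @export
count_signature <- function(sequence, k = 5) {
  s <- if (inherits(sequence, "DNAString")) sequence
       else Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(s) < k)
    stop("sequence shorter than ", k, " bases: empty signature")
  raw <- Biostrings::oligonucleotideFrequency(s, width = k)
  counts <- as.vector(raw %*% canonical_collapse_matrix(k))
  names(counts) <- colnames(canonical_collapse_matrix(k))
  if (sum(counts) == 0)
    stop("no valid ", k, "-mer window (all windows contain ambiguous bases)")
  counts
}

#' Centred log-ratio transform of count compositions
#'
#' Adds a pseudocount, closes to proportions and subtracts the mean log:
#' `clr_j = log p_j - mean(log p)`. Rows of a matrix are transformed
#' independently; every output row sums to zero.
#'
#' @param counts Non-negative numeric vector or matrix (rows = observations).
#' @param pseudocount Added to every count before closure (default 1).
#' @return Numeric vector or matrix of the same shape.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  x <- as.matrix(counts)
  vec_in <- is.null(dim(counts))
  if (vec_in) x <- matrix(counts, nrow = 1)
  if (any(x < 0)) stop("counts must be non-negative")
  v <- x + pseudocount
  if (any(v <= 0))
    stop("all-zero composition with zero pseudocount is outside the CLR domain")
  lp <- log(v / rowSums(v))
  out <- lp - rowMeans(lp)
  if (vec_in) as.vector(out) else out
}

#' G+C fraction of a sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); ambiguous bases are excluded from the
#' denominator.
#'
#' @param sequence Character string or `DNAString`.
#' @return Fraction in \[0, 1\].
#' @export
gc_per_contig <- function(sequence) {
  s <- if (inherits(sequence, "DNAString")) sequence
       else Biostrings::DNAString(toupper(as.character(sequence)))
  f <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) stop("sequence contains no unambiguous A/C/G/T base")
  unname((f[["C"]] + f[["G"]]) / tot)
}

#' Signature table for a set of contigs
#'
#' Computes canonical pentamer counts, CLR-transformed signatures, G+C and
#' length for every contig.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param k Word size (default 5).
#' @param pseudocount CLR pseudocount (default 1).
#' @return List with `contig_id`, `length`, `gc`, `counts` (n x 4^k/2) and
#'   `clr` (same shape).
#' @export
signature_table <- function(seqs, k = 5, pseudocount = 1) {
  ss <- as_dna(seqs)
  if (is.null(names(ss))) stop("sequences must be named")
  if (any(Biostrings::width(ss) < k))
    stop("all sequences must be at least ", k, " bases long")
  raw <- Biostrings::oligonucleotideFrequency(ss, width = k)
  counts <- raw %*% canonical_collapse_matrix(k)
  gc_counts <- Biostrings::letterFrequency(ss, letters = c("A", "C", "G", "T"))
  list(
    contig_id = names(ss),
    length = Biostrings::width(ss),
    gc = unname((gc_counts[, "C"] + gc_counts[, "G"]) / rowSums(gc_counts)),
    counts = counts,
    clr = clr_transform(counts, pseudocount)
  )
}
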