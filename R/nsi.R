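#' Raw spectral index of one protein
#'
#' Sum of the summed fragment-ion intensities over all spectra of all
#' peptides of the protein. Peptide and spectral counts enter implicitly as
#' summation multiplicities, so a protein with more identified peptides or
#' spectra accumulates a larger index at equal per-spectrum intensity.
#'
#' @param intensities Numeric vector of per-spectrum summed fragment-ion
#'   intensities (one element per spectrum, across all peptides).
#' @return The raw spectral index (sum of intensities).
#' @export
spectral_index <- function(intensities) {
  if (length(intensities) == 0)
    stop("no spectral evidence: protein is not quantified")
  if (any(intensities <= 0)) stop("spectrum intensities must be positive")
  sum(intensities)
}

#' Normalized spectral index table
#'
#' Length- and total-signal-normalized label-free protein quantification:
#' `nsi_p = si_p / (length_p * sum_q si_q)` with `si_p` the protein's raw
#' spectral index. The closure identity `sum_p nsi_p * length_p = 1` holds on
#' every run; NSI values are reported log2-transformed alongside. Proteins
#' without spectral evidence are absent from the table (undetected, not
#' zero).
#'
#' @param evidence Data.frame with columns protein_id, length_aa and
#'   intensity (one row per spectrum).
#' @return Data.frame protein_id, length_aa, n_peptides, n_spectra, si_raw,
#'   nsi, log2_nsi, sorted by decreasing nsi.
#' @export
nsi_table <- function(evidence) {
  stopifnot(all(c("protein_id", "length_aa", "intensity") %in% names(evidence)))
  if (nrow(evidence) == 0) stop("no detected proteins")
  if (any(evidence$intensity <= 0)) stop("spectrum intensities must be positive")
  if (any(evidence$length_aa <= 0)) stop("protein lengths must be positive")
  si <- tapply(evidence$intensity, evidence$protein_id, sum)
  len <- tapply(evidence$length_aa, evidence$protein_id,
                function(x) x[1])
  n_spec <- tapply(evidence$intensity, evidence$protein_id, length)
  n_pep <- if ("peptide_id" %in% names(evidence)) {
    tapply(evidence$peptide_id, evidence$protein_id,
           function(x) length(unique(x)))
  } else {
    rep(NA_integer_, length(si))
  }
  total <- sum(si)
  if (total <= 0) stop("zero total intensity")
  nsi <- as.numeric(si) / (as.numeric(len) * total)
  out <- data.frame(
    protein_id = names(si), length_aa = as.numeric(len),
    n_peptides = as.integer(n_pep), n_spectra = as.integer(n_spec),
    si_raw = as.numeric(si), nsi = nsi, log2_nsi = log2(nsi),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$nsi), , drop = FALSE]
  rownames(out) <- NULL
  out
}
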