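#' Rarefy a count vector to fixed depth
#'
#' Draws `reps` replicate subsamples of exactly `depth` reads without
#' replacement (classical rarefaction).
#'
#' @param counts Non-negative integer vector of taxon counts.
#' @param depth Subsampling depth (default 6359).
#' @param reps Number of replicates (default 10).
#' @param seed Integer seed.
#' @return Integer matrix (reps x taxa); each row sums to `depth` exactly.
#' @export
rarefy_counts <- function(counts, depth = 6359, reps = 10, seed = 1L) {
  counts <- round(counts)
  if (sum(counts) < depth)
    stop("sample total (", sum(counts), ") is shallower than depth ", depth)
  set.seed(seed)
  # vegan warns whenever no count equals 1 ("should be used for observed
  # counts"); these are genuine counts, so that heuristic is muffled
  out <- withCallingHandlers(
    vegan::rrarefy(matrix(rep(counts, reps), nrow = reps, byrow = TRUE),
                   depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  colnames(out) <- names(counts)
  out
}

#' Simpson diversity index
#'
#' Gini-Simpson form by default: `D = 1 - sum(p_i^2)`, the probability that
#' two random reads belong to different taxa. The `"dominance"` form returns
#' `sum(p_i^2)` and `"inverse"` returns `1 / sum(p_i^2)`; the form used is
#' recorded as an attribute.
#'
#' @param x Proportions (summing to 1) or counts (normalized internally).
#' @param form "gini_simpson" (default), "dominance" or "inverse".
#' @return The index value with attribute `form`.
#' @export
simpson_index <- function(x, form = c("gini_simpson", "dominance", "inverse")) {
  form <- match.arg(form)
  if (length(x) == 0 || sum(x) <= 0) stop("empty or all-zero abundance vector")
  p <- x / sum(x)
  s2 <- sum(p^2)
  val <- switch(form, gini_simpson = 1 - s2, dominance = s2, inverse = 1 / s2)
  structure(val, form = form)
}

#' Pielou evenness index
#'
#' `J = H / ln(S)` with `H` the Shannon entropy (natural log) and `S` the
#' number of taxa with non-zero abundance; zero-count taxa do not affect the
#' index. `J` lies in (0, 1] and is undefined (NA with a warning) for a
#' single-taxon sample.
#'
#' @param x Proportions or counts.
#' @return The evenness value, or NA when only one taxon is present.
#' @export
pielou_evenness <- function(x) {
  if (length(x) == 0 || sum(x) <= 0) stop("empty or all-zero abundance vector")
  p <- x[x > 0] / sum(x)
  s <- length(p)
  if (s == 1) {
    warning("evenness is undefined for a single-taxon sample")
    return(NA_real_)
  }
  -sum(p * log(p)) / log(s)
}

#' Rarefied diversity and evenness per sample
#'
#' For each sample deep enough, draws rarefaction replicates and reports the
#' mean and standard deviation of the Simpson diversity and Pielou evenness
#' across replicates. Shallower samples are skipped with a warning (or raise
#' an error with `shallow = "error"`).
#'
#' @param abundance Taxa x samples count matrix.
#' @param depth Rarefaction depth (default 6359).
#' @param reps Replicates per sample (default 10).
#' @param seed Integer seed.
#' @param shallow "skip" (default) or "error".
#' @return Data.frame sample, simpson_mean, simpson_sd, pielou_mean,
#'   pielou_sd; attribute `simpson_form` records the index form.
#' @export
diversity_indices <- function(abundance, depth = 6359, reps = 10, seed = 1L,
                              shallow = c("skip", "error")) {
  shallow <- match.arg(shallow)
  samples <- colnames(abundance) %||% as.character(seq_len(ncol(abundance)))
  rows <- lapply(seq_len(ncol(abundance)), function(j) {
    x <- abundance[, j]
    if (sum(x) < depth) {
      msg <- paste0("sample ", samples[j], " (", sum(x),
                    " reads) is shallower than depth ", depth)
      if (shallow == "error") stop(msg)
      warning(msg, "; skipped", call. = FALSE)
      return(NULL)
    }
    reps_mat <- rarefy_counts(x, depth = depth, reps = reps,
                              seed = stage_seed(seed, "rarefy") + j)
    simp <- apply(reps_mat, 1, function(r) as.numeric(simpson_index(r)))
    piel <- apply(reps_mat, 1, pielou_evenness)
    data.frame(sample = samples[j],
               simpson_mean = mean(simp), simpson_sd = sd(simp),
               pielou_mean = mean(piel), pielou_sd = sd(piel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "simpson_form") <- "gini_simpson"
  attr(out, "depth") <- depth
  out
}

#' Intracellular/extracellular lipid accumulation ratios
#'
#' Ratio of quantified intracellular to extracellular abundance per compound
#' and sample; the ratio is undefined (NA, with a warning) where the
#' extracellular concentration is zero.
#'
#' @param lipids Data.frame with compound, sample, intracellular,
#'   extracellular.
#' @return The input with a `ratio` column.
#' @export
accumulation_ratio <- function(lipids) {
  stopifnot(all(c("intracellular", "extracellular") %in% names(lipids)))
  if (any(lipids$intracellular < 0) || any(lipids$extracellular < 0))
    stop("concentrations must be non-negative")
  undef <- lipids$extracellular == 0
  if (any(undef))
    warning(sum(undef), " ratio(s) undefined: extracellular concentration 0")
  lipids$ratio <- ifelse(undef, NA_real_,
                         lipids$intracellular / lipids$extracellular)
  lipids
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks; returns NA with a warning when
#' either vector is constant (rank correlation undefined).
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return rho in \[-1, 1\], or NA.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("rank correlation undefined for a constant vector")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Taxon-lipid rank correlations
#'
#' Spearman correlation between each taxon's relative abundance and each
#' lipid compound's accumulation ratio across the shared samples.
#'
#' @param abundance Taxa x samples count matrix.
#' @param lipids Lipid table with `ratio` (see [accumulation_ratio()]).
#' @return Data.frame taxon, compound, rho, sorted by decreasing rho.
#' @export
taxon_lipid_correlations <- function(abundance, lipids) {
  if (!"ratio" %in% names(lipids)) lipids <- accumulation_ratio(lipids)
  props <- sweep(abundance, 2, colSums(abundance), "/")
  compounds <- unique(lipids$compound)
  rows <- list()
  for (cmp in compounds) {
    sub <- lipids[lipids$compound == cmp, , drop = FALSE]
    common <- intersect(colnames(props), sub$sample)
    if (length(common) < 3) next
    r <- sub$ratio[match(common, sub$sample)]
    if (any(is.na(r))) next
    for (tx in rownames(props)) {
      rho <- suppressWarnings(spearman_rho(props[tx, common], r))
      rows[[length(rows) + 1]] <- data.frame(
        taxon = tx, compound = cmp, rho = rho, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$rho), , drop = FALSE]
  rownames(out) <- NULL
  out
}
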