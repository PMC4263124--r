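#' Two-dimensional stochastic neighbour embedding of contig signatures
#'
#' Projects CLR-transformed signatures to 2-D with t-distributed stochastic
#' neighbour embedding (exact O(n^2) gradient, early exaggeration), after an
#' initial PCA reduction. Deterministic for a fixed seed.
#'
#' @param clr Numeric matrix (contigs x signature dimensions), rownames =
#'   contig ids, or the list returned by [signature_table()].
#' @param perplexity Effective neighbourhood size (default 30); needs at
#'   least `3 * perplexity + 1` points.
#' @param seed Integer seed.
#' @param max_iter Gradient iterations (default 750).
#' @param eta Learning rate (default 200).
#' @param initial_dims PCA dimensions retained before the embedding
#'   (default 50).
#' @return Data.frame contig_id, x, y.
#' @export
embed_signatures <- function(clr, perplexity = 30, seed = 1L, max_iter = 750,
                             eta = 200, initial_dims = 50) {
  if (is.list(clr) && !is.null(clr$clr)) {
    ids <- clr$contig_id
    X <- clr$clr
  } else {
    X <- as.matrix(clr)
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  }
  n <- nrow(X)
  if (n - 1 < 3 * perplexity)
    stop("too few points (", n, ") for perplexity ", perplexity)
  d <- min(initial_dims, ncol(X), n - 1)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = d)
  set.seed(seed)
  Y <- cpp_tsne(pc$x, perplexity, as.integer(max_iter), eta,
                12, 250L, 250L)
  data.frame(contig_id = ids, x = Y[, 1], y = Y[, 2],
             stringsAsFactors = FALSE)
}

# Gaussian log-density for one component (full covariance, via Cholesky)
mvn_logdens <- function(X, mu, sigma) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * ncol(X) * log(2 * pi)
}

#' Fit a Gaussian mixture by expectation-maximisation
#'
#' Means are either supplied (one component per expected cluster) or seeded
#' by k-means for a requested component count. Covariances are initialized as
#' diagonal matrices with small positive entries and floored at `cov_floor`
#' throughout to prevent singularities. Iterates until the relative
#' log-likelihood change falls below `tol`.
#'
#' @param points Numeric matrix (n x d) or data.frame with columns x, y.
#' @param init_means Optional K x d matrix of initial component means.
#' @param n_components Number of components (ignored if `init_means` given).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @param seed Seed for the k-means initialization.
#' @param cov_floor Variance floor added to covariance diagonals.
#' @return Object of class `popomics_gmm`: means, covariances, weights,
#'   responsibilities, log_likelihood_trace, bic.
#' @export
fit_gmm <- function(points, init_means = NULL, n_components = NULL,
                    tol = 1e-6, max_iter = 500, seed = 1L,
                    cov_floor = 1e-6) {
  X <- if (is.data.frame(points)) as.matrix(points[, c("x", "y")])
       else as.matrix(points)
  n <- nrow(X); d <- ncol(X)
  if (is.null(init_means)) {
    if (is.null(n_components)) stop("give init_means or n_components")
    K <- as.integer(n_components)
    if (K < 1) stop("n_components must be >= 1")
    if (n < K) stop("degenerate mixture: fewer points (", n,
                    ") than components (", K, ")")
    if (K == 1) {
      mu <- matrix(colMeans(X), 1, d)
    } else {
      set.seed(seed)
      km <- stats::kmeans(X, centers = K, nstart = 10, iter.max = 100)
      mu <- km$centers
    }
  } else {
    mu <- as.matrix(init_means)
    K <- nrow(mu)
    if (n < K) stop("degenerate mixture: fewer points (", n,
                    ") than components (", K, ")")
  }
  # "small positive entries": a fixed small fraction of the total variance
  var0 <- max(0.01 * mean(apply(X, 2, var)), cov_floor)
  sigma <- rep(list(diag(var0, d)), K)
  w <- rep(1 / K, K)
  trace <- numeric(0)
  ll_old <- -Inf
  R <- matrix(0, n, K)
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(K),
                   function(k) log(w[k]) + mvn_logdens(X, mu[k, ], sigma[[k]]),
                   numeric(n))
    logd <- matrix(logd, n, K)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    R <- exp(logd - lse)
    Nk <- colSums(R)
    bad <- which(Nk < 1e-8)
    if (length(bad))
      stop("degenerate mixture: component ", bad[1], " lost all support")
    w <- Nk / n
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(R[, k] * X) / Nk[k]
      Xc <- sweep(X, 2, mu[k, ])
      sigma[[k]] <- crossprod(Xc * sqrt(R[, k])) / Nk[k] + diag(cov_floor, d)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
  }
  n_par <- (K - 1) + K * d + K * d * (d + 1) / 2
  structure(list(
    n_components = K, means = mu, covariances = sigma, weights = w,
    responsibilities = R, log_likelihood_trace = trace,
    bic = -2 * trace[length(trace)] + n_par * log(n),
    n = n, d = d
  ), class = "popomics_gmm")
}

#' @export
print.popomics_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: %d components in %d-D, n = %d, logLik = %.2f, BIC = %.2f\n",
              x$n_components, x$d, x$n,
              x$log_likelihood_trace[length(x$log_likelihood_trace)], x$bic))
  invisible(x)
}

# BIC scan over component counts; returns the best fit
select_gmm_k <- function(points, k_range = 1:10, seed = 1L, ...) {
  fits <- lapply(k_range, function(k) {
    tryCatch(fit_gmm(points, n_components = k, seed = seed, ...),
             error = function(e) NULL)
  })
  bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic, numeric(1))
  fits[[which.min(bics)]]
}

#' Assign contigs to composite genomes from a fitted mixture
#'
#' Each point is labelled with its maximum-responsibility component; points
#' whose maximum posterior falls below `min_posterior` are labelled
#' `"unbinned"`.
#'
#' @param model A fitted [fit_gmm()] object.
#' @param points The embedded points the model was fitted to (data.frame with
#'   contig_id, x, y).
#' @param min_posterior Posterior threshold below which a contig stays
#'   unbinned (default 0.5).
#' @param labels Optional component labels (default CG1..CGK).
#' @return Data.frame contig_id, cg_id, posterior.
#' @export
assign_bins <- function(model, points, min_posterior = 0.5, labels = NULL) {
  stopifnot(inherits(model, "popomics_gmm"))
  K <- model$n_components
  labels <- labels %||% paste0("CG", seq_len(K))
  X <- if (is.data.frame(points)) as.matrix(points[, c("x", "y")])
       else as.matrix(points)
  logd <- vapply(seq_len(K),
                 function(k) log(model$weights[k]) +
                   mvn_logdens(X, model$means[k, ], model$covariances[[k]]),
                 numeric(nrow(X)))
  logd <- matrix(logd, nrow(X), K)
  m <- apply(logd, 1, max)
  R <- exp(logd - (m + log(rowSums(exp(logd - m)))))
  comp <- max.col(R, ties.method = "first")
  post <- R[cbind(seq_len(nrow(R)), comp)]
  cg <- ifelse(post < min_posterior, "unbinned", labels[comp])
  ids <- if (is.data.frame(points) && !is.null(points$contig_id))
    points$contig_id else rownames(X) %||% as.character(seq_len(nrow(X)))
  data.frame(contig_id = ids, cg_id = cg, posterior = post,
             stringsAsFactors = FALSE)
}

#' Recruit mapped reads to composite genomes
#'
#' Sums per-contig read counts over each composite genome; counts on
#' unbinned contigs form the residual pool. Conserves the table total
#' exactly.
#'
#' @param assignments Data.frame contig_id, cg_id (from [assign_bins()]).
#' @param counts Data.frame with columns id and count.
#' @return List: `c_i` (named per-CG totals), `residual`, `total`.
#' @export
recruit_reads <- function(assignments, counts) {
  unknown <- setdiff(counts$id, assignments$contig_id)
  if (length(unknown))
    stop("contigs present in counts but unknown to assignments: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  cg <- assignments$cg_id[match(counts$id, assignments$contig_id)]
  binned <- cg != "unbinned"
  c_i <- tapply(counts$count[binned], cg[binned], sum)
  c_i <- setNames(as.numeric(c_i), names(c_i))
  list(c_i = c_i, residual = sum(counts$count[!binned]),
       total = sum(counts$count))
}

#' Second-round refinement of contig bins
#'
#' Within each first-round composite genome, recomputes signatures and the
#' 2-D embedding on contigs of at least `round2_min_length` bases and
#' re-clusters them with a BIC-scanned Gaussian mixture. A group is split
#' only when the best multi-component model beats the single component by
#' more than `delta_bic`. Contigs below the length threshold (or groups too
#' small to embed) keep their first-round label; when a group splits, its
#' short contigs join the largest sub-bin.
#'
#' @param seqs Named character vector or DNAStringSet of all contigs.
#' @param assignments First-round assignments (contig_id, cg_id, posterior).
#' @param round2_min_length Minimum contig length for re-profiling
#'   (default 1000).
#' @param perplexity,seed,pseudocount Passed to the embedding.
#' @param max_k Maximum sub-components per group (default 3).
#' @param delta_bic BIC margin required to accept a split (default 10).
#' @return Refined assignments data.frame (contig_id, cg_id, posterior).
#' @export
iterate_binning <- function(seqs, assignments, round2_min_length = 1000,
                            perplexity = 30, seed = 1L, pseudocount = 1,
                            max_k = 3, delta_bic = 10) {
  ss <- as_dna(seqs)
  widths <- setNames(Biostrings::width(ss), names(ss))
  out <- assignments
  for (cg in setdiff(unique(assignments$cg_id), "unbinned")) {
    members <- assignments$contig_id[assignments$cg_id == cg]
    eligible <- members[widths[members] >= round2_min_length]
    if (length(eligible) < 3 * perplexity + 2) {
      message("group ", cg, ": too few contigs >= ", round2_min_length,
              " bp for re-embedding; passed through unchanged")
      next
    }
    sig <- signature_table(ss[eligible], pseudocount = pseudocount)
    emb <- embed_signatures(sig, perplexity = perplexity, seed = seed)
    fit1 <- fit_gmm(emb, n_components = 1, seed = seed)
    fits <- lapply(2:max_k, function(k) {
      tryCatch(fit_gmm(emb, n_components = k, seed = seed),
               error = function(e) NULL)
    })
    bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic,
                   numeric(1))
    best <- which.min(bics)
    if (bics[best] + delta_bic < fit1$bic) {
      sub <- assign_bins(fits[[best]], emb,
                         labels = paste0(cg, "_", seq_len(best + 1)))
      idx <- match(sub$contig_id, out$contig_id)
      out$cg_id[idx] <- sub$cg_id
      out$posterior[idx] <- sub$posterior
      # short contigs join the largest sub-bin of their former group
      short <- setdiff(members, eligible)
      if (length(short)) {
        tab <- table(sub$cg_id[sub$cg_id != "unbinned"])
        out$cg_id[match(short, out$contig_id)] <- names(tab)[which.max(tab)]
      }
    }
  }
  out
}

# 1-D Gaussian mixture with a shared variance, K = 1 or 2. The shared
# variance matters: per-contig depth noise shrinks with contig length, so an
# unequal-variance two-component fit can model that scale mixture and "win"
# on a single population; a common variance restricts the second component
# to describing a genuine second depth mode.
em1d_shared_var <- function(x, K, seed = 1L, tol = 1e-8, max_iter = 500,
                            var_floor = 1e-6) {
  n <- length(x)
  if (K == 1) {
    mu <- mean(x)
    v <- max(var(x) * (n - 1) / n, var_floor)
    ll <- sum(stats::dnorm(x, mu, sqrt(v), log = TRUE))
    return(list(mu = mu, var = v, w = 1, ll = ll,
                bic = -2 * ll + 2 * log(n), resp = matrix(1, n, 1)))
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2, nstart = 10)
  mu <- as.vector(km$centers)
  v <- max(var(x) / 4, var_floor)
  w <- rep(0.5, 2)
  ll_old <- -Inf
  R <- matrix(0, n, 2)
  for (it in seq_len(max_iter)) {
    logd <- vapply(1:2, function(k)
      log(w[k]) + stats::dnorm(x, mu[k], sqrt(v), log = TRUE), numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    R <- exp(logd - lse)
    Nk <- colSums(R)
    if (any(Nk < 1e-8)) return(NULL)
    w <- Nk / n
    mu <- colSums(R * x) / Nk
    v <- max(sum(R * (x - rep(mu, each = n))^2) / n, var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(mu = mu, var = v, w = w, ll = ll,
       bic = -2 * ll + 4 * log(n), resp = R)
}

#' Split a composite genome by read-depth bimodality
#'
#' Fits one- and two-component shared-variance Gaussian mixtures on log10
#' per-contig depth. The bin is split only when the two-component model
#' improves BIC by more than `delta_bic` *and* the two depth modes differ by
#' at least a factor of `min_fold` (two coexisting populations merged into
#' one bin differ substantially in coverage; smaller contrasts are
#' indistinguishable from depth noise). Sub-bins are labelled `"<id>a"`
#' (lower mean depth) and `"<id>b"` (higher).
#'
#' @param depths Named positive per-contig depths of one composite genome.
#' @param cg_id The bin label.
#' @param delta_bic BIC margin required to split (default 10).
#' @param min_fold Minimum ratio between the two depth modes (default 2).
#' @param seed Seed for mixture initialization.
#' @return Data.frame contig_id, cg_id (possibly with a/b suffixes),
#'   plus attribute `split` (logical).
#' @export
split_by_coverage <- function(depths, cg_id = "CG", delta_bic = 10,
                              min_fold = 2, seed = 1L) {
  if (any(depths <= 0)) stop("depths must be positive")
  ids <- names(depths) %||% as.character(seq_along(depths))
  no_split <- function(warn = NULL) {
    if (!is.null(warn)) warning(warn, call. = FALSE)
    structure(data.frame(contig_id = ids, cg_id = cg_id,
                         stringsAsFactors = FALSE), split = FALSE)
  }
  if (length(depths) < 4)
    return(no_split(paste0(cg_id, ": fewer than 4 contigs; not split")))
  x <- log10(depths)
  fit1 <- em1d_shared_var(x, 1)
  fit2 <- em1d_shared_var(x, 2, seed = seed)
  if (is.null(fit2) || fit2$bic + delta_bic >= fit1$bic ||
      abs(diff(fit2$mu)) < log10(min_fold))
    return(no_split())
  comp <- max.col(fit2$resp, ties.method = "first")
  ord <- order(fit2$mu)  # low depth first
  lab <- setNames(paste0(cg_id, c("a", "b")), ord)
  structure(data.frame(contig_id = ids,
                       cg_id = unname(lab[as.character(comp)]),
                       stringsAsFactors = FALSE), split = TRUE)
}

#' Bin contigs into composite genomes
#'
#' The full signature-based binning pipeline: canonical pentamer signatures
#' with CLR transform, 2-D stochastic neighbour embedding, EM Gaussian
#' mixture clustering (user-initialized means, fixed K, or BIC scan),
#' optional second-round re-profiling of each group restricted to contigs of
#' at least `round2_min_length` bases, and optional coverage-based bin
#' splitting from per-contig depths.
#'
#' @param seqs Named character vector or `DNAStringSet` of contigs.
#' @param k Number of composite genomes; `NULL` with `init_means = NULL`
#'   triggers a BIC scan over `2:k_max`.
#' @param init_means Optional K x 2 matrix of mixture means in the embedding
#'   (the interactive workflow's user-picked cluster centres).
#' @param counts Optional per-contig read count data.frame (id, count) for
#'   read recruitment.
#' @param depths Optional named per-contig depths for coverage splitting.
#' @param min_length Contigs below this length are excluded from binning
#'   (default 500).
#' @param round2_min_length Second-round length threshold (default 1000).
#' @param iterate Run the second refinement round (default TRUE).
#' @param perplexity,seed,pseudocount,min_posterior,k_max,delta_bic Tuning
#'   parameters, see the individual stage functions.
#' @return Object of class `cg_binning`: signatures, embedding, model,
#'   assignments (final), recruitment (if counts given).
#' @export
bin_contigs <- function(seqs, k = NULL, init_means = NULL, counts = NULL,
                        depths = NULL, min_length = 500,
                        round2_min_length = 1000, iterate = TRUE,
                        perplexity = 30, seed = 1L, pseudocount = 1,
                        min_posterior = 0.5, k_max = 10, delta_bic = 10) {
  ss <- as_dna(seqs)
  if (is.null(names(ss))) stop("contigs must be named")
  keep <- Biostrings::width(ss) >= min_length
  if (sum(keep) < 3 * perplexity + 2)
    stop("too few contigs of at least ", min_length, " bases")
  short_ids <- names(ss)[!keep]
  ss_b <- ss[keep]
  sig <- signature_table(ss_b, pseudocount = pseudocount)
  emb <- embed_signatures(sig, perplexity = perplexity,
                          seed = stage_seed(seed, "embed"))
  model <- if (!is.null(init_means)) {
    fit_gmm(emb, init_means = init_means)
  } else if (!is.null(k)) {
    fit_gmm(emb, n_components = k, seed = stage_seed(seed, "gmm"))
  } else {
    select_gmm_k(emb, k_range = 2:k_max, seed = stage_seed(seed, "gmm"))
  }
  assignments <- assign_bins(model, emb, min_posterior = min_posterior)
  if (iterate)
    assignments <- iterate_binning(ss_b, assignments,
                                   round2_min_length = round2_min_length,
                                   perplexity = perplexity,
                                   seed = stage_seed(seed, "gmm") + 1L,
                                   pseudocount = pseudocount,
                                   delta_bic = delta_bic)
  if (!is.null(depths)) {
    refined <- assignments
    for (cg in setdiff(unique(assignments$cg_id), "unbinned")) {
      members <- assignments$contig_id[assignments$cg_id == cg]
      dd <- depths[members]
      dd <- dd[!is.na(dd) & dd > 0]
      if (length(dd) < 4) next
      sp <- split_by_coverage(dd, cg_id = cg, delta_bic = delta_bic,
                              seed = stage_seed(seed, "gmm") + 2L)
      refined$cg_id[match(sp$contig_id, refined$contig_id)] <- sp$cg_id
    }
    assignments <- refined
  }
  if (length(short_ids))
    assignments <- rbind(assignments,
                         data.frame(contig_id = short_ids, cg_id = "unbinned",
                                    posterior = NA_real_,
                                    stringsAsFactors = FALSE))
  res <- structure(list(
    signatures = sig, embedding = emb, model = model,
    assignments = assignments,
    params = list(min_length = min_length, perplexity = perplexity,
                  pseudocount = pseudocount, min_posterior = min_posterior,
                  seed = seed)
  ), class = "cg_binning")
  if (!is.null(counts)) {
    cc <- counts[counts$id %in% assignments$contig_id, , drop = FALSE]
    res$recruitment <- recruit_reads(assignments, cc)
  }
  res
}

#' @export
print.cg_binning <- function(x, ...) {
  tab <- table(x$assignments$cg_id)
  cat("Composite-genome binning of", nrow(x$assignments), "contigs:\n")
  print(tab)
  invisible(x)
}
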