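#' Counts per million
#'
#' @param dataset a [count_dataset()].
#' @param factors optional per-sample TMM scaling factors; when supplied, cpm
#'   is computed against effective library sizes (raw size x factor).
#' @return genes x samples matrix of cpm values.
#' @export
compute_cpm <- function(dataset, factors = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  lib <- colSums(dataset$counts)
  if (any(lib <= 0)) stop("zero library size in sample(s): ",
                          paste(colnames(dataset$counts)[lib <= 0], collapse = ", "))
  if (!is.null(factors)) {
    stopifnot(length(factors) == ncol(dataset$counts), all(factors > 0))
    lib <- lib * factors
  }
  sweep(dataset$counts, 2, lib / 1e6, "/")
}

#' Expression filter: minimum number of samples above a cpm threshold
#'
#' Keeps a gene iff strictly more than `cpm_threshold` cpm (on raw library
#' sizes, single pass: library sizes are not recomputed after dropping genes)
#' is observed in at least `min_samples` samples. The default reproduces the
#' "at least three samples over 2 cpm" rule.
#'
#' @param dataset a [count_dataset()].
#' @param min_samples minimum number of qualifying samples (default 3).
#' @param cpm_threshold strict cpm cutoff (default 2).
#' @return filtered [count_dataset()].
#' @export
filter_genes <- function(dataset, min_samples = 3, cpm_threshold = 2) {
  cpm <- compute_cpm(dataset)
  keep <- rowSums(cpm > cpm_threshold) >= min_samples
  subset_dataset(dataset, genes = keep)
}

# weighted trimmed mean of M-values between one sample and the reference;
# obs/ref are raw counts, nO/nR their library sizes
tmm_pair <- function(obs, ref, nO, nR, logratio_trim = 0.3, sum_trim = 0.05) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) return(NA_real_)
  obs <- obs[pos]; ref <- ref[pos]
  M <- log2((obs / nO) / (ref / nR))
  A <- 0.5 * log2((obs / nO) * (ref / nR))
  # delta-method binomial variance of M, used as precision weights
  w <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  fin <- is.finite(M) & is.finite(A) & is.finite(w) & w > 0
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1;      hiS <- n + 1 - loS
  keep <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
  if (!any(keep)) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' TMM scaling factors
#'
#' Standard trimmed mean of M-values between-sample normalization: the
#' reference is the sample whose 75th-percentile cpm is closest to the mean
#' 75th percentile; per sample, M (log ratio) and A (log abundance) values are
#' computed over genes positive in both sample and reference, the extreme 30%
#' of M and 5% of A are trimmed, and the factor is 2 to the precision-weighted
#' mean of the remaining M values. Factors are rescaled to geometric mean 1.
#'
#' @param dataset a [count_dataset()] with >= 2 samples.
#' @param logratio_trim,sum_trim trim fractions for M and A (defaults 0.30 and
#'   0.05).
#' @return named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_factors <- function(dataset, logratio_trim = 0.3, sum_trim = 0.05) {
  stopifnot(inherits(dataset, "count_dataset"))
  x <- dataset$counts
  if (ncol(x) < 2) stop("TMM needs at least two samples")
  lib <- colSums(x)
  if (any(lib <= 0)) stop("zero library size")
  # per-sample 75th percentile of count proportions picks the reference
  f75 <- vapply(seq_len(ncol(x)),
                function(j) unname(stats::quantile(x[, j] / lib[j], 0.75)),
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(x)), function(j) {
    if (j == ref) return(1)
    tmm_pair(x[, j], x[, ref], lib[j], lib[ref],
             logratio_trim = logratio_trim, sum_trim = sum_trim)
  }, numeric(1))
  if (anyNA(f))
    stop("sample(s) share no positive genes with the reference: ",
         paste(colnames(x)[is.na(f)], collapse = ", "))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(x))
}

#' Normalized log2-cpm matrix
#'
#' Computes log2 cpm against effective library sizes with a prior count
#' proportional to each effective library size, expressed per million reads:
#' prior_s = prior_count * efflib_s / 1e6, and
#' \deqn{log2((count + prior_s) / (efflib_s + 2 prior_s) \cdot 10^6)}
#' The absolute proportionality makes the transform exactly invariant to
#' jointly rescaling counts and library sizes (sequencing depth), at the cost
#' of a slightly stronger prior than a fixed half-count on deep libraries.
#'
#' @param dataset a [count_dataset()].
#' @param factors per-sample TMM factors (default: computed via
#'   [tmm_factors()]).
#' @param prior_count positive prior per million reads (default 0.5).
#' @return object of class `normalized_dataset`: list with `gene_ids`,
#'   `sample_ids`, `factors`, `eff_libsize`, `logcpm` (genes x samples,
#'   finite everywhere) and the sample `design`.
#' @export
logcpm_matrix <- function(dataset, factors = NULL, prior_count = 0.5) {
  stopifnot(inherits(dataset, "count_dataset"))
  if (prior_count <= 0) stop("prior_count must be > 0")
  if (is.null(factors)) factors <- tmm_factors(dataset)
  stopifnot(length(factors) == ncol(dataset$counts), all(factors > 0))
  lib <- colSums(dataset$counts)
  eff <- lib * factors
  pr <- prior_count * eff / 1e6
  logcpm <- log2(sweep(sweep(dataset$counts, 2, pr, "+"), 2, eff + 2 * pr, "/") * 1e6)
  structure(list(gene_ids = rownames(dataset$counts),
                 sample_ids = colnames(dataset$counts),
                 factors = stats::setNames(factors, colnames(dataset$counts)),
                 eff_libsize = stats::setNames(eff, colnames(dataset$counts)),
                 logcpm = logcpm,
                 design = dataset$design),
            class = "normalized_dataset")
}
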