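#' Construct an ordination object from sample scores
#'
#' Mostly used internally by [ordinate_pca()]; exposed so score-space
#' geometries can be built directly (e.g. for worked examples).
#'
#' @param scores samples x k numeric matrix with sample ids as rownames.
#' @param groups data.frame with columns sample, regime, sex, tissue matching
#'   the score rows.
#' @param explained optional non-increasing explained-variance fractions.
#' @return object of class `ordination`: scores, explained, groups, and the
#'   regime x sex x tissue centroids.
#' @export
ordination <- function(scores, groups, explained = NULL) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == nrow(groups),
            all(c("sample", "regime", "sex", "tissue") %in% names(groups)))
  if (is.null(rownames(scores))) rownames(scores) <- groups$sample
  key <- paste(groups$regime, groups$sex, groups$tissue, sep = ".")
  cents <- do.call(rbind, lapply(split(seq_len(nrow(scores)), key), function(i) {
    colMeans(scores[i, , drop = FALSE])
  }))
  structure(list(scores = scores, explained = explained,
                 groups = groups, centroids = cents, group_key = key),
            class = "ordination")
}

#' PCA ordination of normalized expression
#'
#' Principal component analysis of the samples x genes log2-cpm matrix based
#' on the covariance matrix (genes centered, not scaled). Group centroids are
#' the arithmetic means of member sample scores in the retained k-dimensional
#' space; one joint ordination is fitted for all samples.
#'
#' @param norm a `normalized_dataset` from [logcpm_matrix()].
#' @param k number of retained components (default 16; must be <=
#'   min(samples - 1, genes)).
#' @return an [ordination()] with `explained` variance fractions.
#' @export
ordinate_pca <- function(norm, k = 16) {
  stopifnot(inherits(norm, "normalized_dataset"))
  X <- t(norm$logcpm)   # samples x genes
  kmax <- min(nrow(X) - 1, ncol(X))
  if (k > kmax) stop(sprintf("k = %d exceeds min(samples - 1, genes) = %d", k, kmax))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  expl <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  ordination(pc$x[, seq_len(k), drop = FALSE],
             data.frame(sample = norm$sample_ids,
                        regime = norm$design$regime,
                        sex = norm$design$sex,
                        tissue = norm$design$tissue,
                        stringsAsFactors = FALSE),
             explained = expl[seq_len(k)])
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

#' Multivariate repeatability of expression divergence for one group
#'
#' For the regime x sex x tissue group, computes D = the Euclidean distance
#' between the E and L centroids of that sex x tissue stratum, d = the mean
#' Euclidean distance of the group's replicate-line samples to their own
#' centroid, and the repeatability R = D / (D + d). R = 1 means replicate
#' lines sit exactly on their centroid (perfectly repeatable divergence);
#' R = 0 means no E-L divergence. When both D and d are zero, R is defined
#' as 0.
#'
#' @param ord an [ordination()].
#' @param regime "E" or "L".
#' @param sex "F" or "M".
#' @param tissue "abdomen" or "head_thorax".
#' @return list of class `repeatability_estimate`: regime, sex, tissue, R, D,
#'   d, ci_low, ci_high (NA without bootstrap), n_boot.
#' @export
repeatability_R <- function(ord, regime, sex, tissue) {
  stopifnot(inherits(ord, "ordination"))
  g <- ord$groups
  stratum <- g$sex == sex & g$tissue == tissue
  for (r in c("E", "L")) {
    if (!any(stratum & g$regime == r))
      stop(sprintf("stratum %s/%s has no %s samples", sex, tissue, r))
  }
  centE <- colMeans(ord$scores[stratum & g$regime == "E", , drop = FALSE])
  centL <- colMeans(ord$scores[stratum & g$regime == "L", , drop = FALSE])
  D <- euclid(centE, centL)
  own <- stratum & g$regime == regime
  if (sum(own) < 2)
    stop(sprintf("group %s/%s/%s has fewer than 2 replicate samples",
                 regime, sex, tissue))
  cent <- if (regime == "E") centE else centL
  d <- mean(apply(ord$scores[own, , drop = FALSE], 1, euclid, b = cent))
  R <- if (D == 0) 0 else D / (D + d)
  structure(list(regime = regime, sex = sex, tissue = tissue,
                 R = R, D = D, d = d,
                 ci_low = NA_real_, ci_high = NA_real_, n_boot = 0L),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("repeatability %s/%s/%s: R = %.4f (D = %.4g, d = %.4g)",
              x$regime, x$sex, x$tissue, x$R, x$D, x$d))
  if (!is.na(x$ci_low))
    cat(sprintf("  95%% bootstrap CI [%.4f, %.4f] (%d replicates)",
                x$ci_low, x$ci_high, x$n_boot))
  cat("\n")
  invisible(x)
}

#' Repeatability with a gene-bootstrap confidence interval
#'
#' Resamples genes with replacement, refits the PCA (by default) and
#' recomputes R per replicate; the CI is the percentile 2.5/97.5 interval,
#' clamped to contain the point estimate and the [0, 1] range. Deterministic
#' under a fixed seed.
#'
#' @param norm a `normalized_dataset`.
#' @param regime,sex,tissue group selector as in [repeatability_R()].
#' @param k retained components (capped at min(samples - 1, genes)).
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @param refit_pca refit the ordination per replicate (default TRUE); when
#'   FALSE, distances are computed directly in the resampled gene space.
#' @param boot_unit "genes" (default) resamples genes with replacement;
#'   "samples" resamples replicate samples within each regime x sex x tissue
#'   group (degenerate with few replicate lines, provided for comparison).
#' @return a `repeatability_estimate` with ci_low/ci_high/n_boot filled in.
#' @export
bootstrap_ci <- function(norm, regime, sex, tissue, k = 16, n_boot = 1000,
                         seed = 1, refit_pca = TRUE,
                         boot_unit = c("genes", "samples")) {
  stopifnot(inherits(norm, "normalized_dataset"))
  boot_unit <- match.arg(boot_unit)
  if (n_boot < 100) stop("n_boot must be >= 100")
  G <- nrow(norm$logcpm)
  k <- min(k, length(norm$sample_ids) - 1, G)
  est <- repeatability_R(ordinate_pca(norm, k), regime, sex, tissue)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  groups <- data.frame(sample = norm$sample_ids, regime = norm$design$regime,
                       sex = norm$design$sex, tissue = norm$design$tissue,
                       stringsAsFactors = FALSE)
  gkey <- paste(groups$regime, groups$sex, groups$tissue, sep = ".")
  reps <- vapply(seq_len(n_boot), function(b) {
    sub <- norm
    grp <- groups
    if (boot_unit == "genes") {
      idx <- sample.int(G, G, replace = TRUE)
      sub$logcpm <- norm$logcpm[idx, , drop = FALSE]
      sub$gene_ids <- norm$gene_ids[idx]
    } else {
      cols <- unlist(lapply(split(seq_along(gkey), gkey), function(i)
        sample(i, length(i), replace = TRUE)), use.names = FALSE)
      sub$logcpm <- norm$logcpm[, cols, drop = FALSE]
      sub$sample_ids <- paste0(norm$sample_ids[cols], "_b", seq_along(cols))
      colnames(sub$logcpm) <- sub$sample_ids
      sub$design <- norm$design[cols, , drop = FALSE]
      grp <- groups[cols, , drop = FALSE]
      grp$sample <- sub$sample_ids
    }
    ordb <- if (refit_pca) ordinate_pca(sub, k)
            else ordination(t(sub$logcpm), grp)
    repeatability_R(ordb, regime, sex, tissue)$R
  }, numeric(1))
  ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  est$ci_low <- max(0, min(ci[1], est$R))
  est$ci_high <- min(1, max(ci[2], est$R))
  est$n_boot <- as.integer(n_boot)
  est
}

#' Repeatability estimates for every regime x sex x tissue group
#'
#' @param norm a `normalized_dataset`.
#' @param k retained components (capped at min(samples - 1, genes)).
#' @param n_boot optional bootstrap replicates (0 = no CI).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with one row per group: regime, sex, tissue, R, D, d,
#'   ci_low, ci_high.
#' @export
repeatability_all <- function(norm, k = 16, n_boot = 0, seed = 1) {
  k <- min(k, length(norm$sample_ids) - 1, nrow(norm$logcpm))
  ord <- ordinate_pca(norm, k)
  g <- unique(ord$groups[, c("regime", "sex", "tissue")])
  rows <- lapply(seq_len(nrow(g)), function(i) {
    est <- if (n_boot > 0) {
      bootstrap_ci(norm, g$regime[i], g$sex[i], g$tissue[i], k = k,
                   n_boot = n_boot, seed = seed)
    } else repeatability_R(ord, g$regime[i], g$sex[i], g$tissue[i])
    data.frame(regime = est$regime, sex = est$sex, tissue = est$tissue,
               R = est$R, D = est$D, d = est$d,
               ci_low = est$ci_low, ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
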