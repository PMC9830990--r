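#' Negative-binomial deviance
#'
#' @param y observed counts.
#' @param mu fitted means (> 0).
#' @param phi NB dispersion; 0 gives the Poisson deviance.
#' @return total deviance (scalar).
#' @keywords internal
nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-12)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi == 0) {
    2 * sum(t1 - (y - mu))
  } else {
    2 * sum(t1 - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  }
}

#' Fit a log-link negative-binomial GLM to one gene
#'
#' Iteratively reweighted least squares with working weights mu/(1 + phi mu);
#' convergence when the relative deviance change drops below `tol` (default
#' 1e-8) or after `maxit` (default 50) iterations. Coefficients are on the
#' natural-log scale.
#'
#' @param y counts for one gene (length n).
#' @param design n x p full-rank model matrix.
#' @param offset log effective library sizes (length n).
#' @param phi NB dispersion (scalar, >= 0).
#' @param tol,maxit convergence controls.
#' @return list(coefficients, fitted, deviance, converged, iterations,
#'   df_residual).
#' @export
fit_nbglm <- function(y, design, offset = rep(0, length(y)), phi = 0,
                      tol = 1e-8, maxit = 50L) {
  X <- as.matrix(design)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("design rows must match length(y)")
  if (qr(X)$rank < p) stop("design matrix is not full rank")
  beta <- qr.coef(qr(X), log(pmax(y, 0.125)) - offset)
  beta[is.na(beta)] <- 0
  dev <- Inf; converged <- FALSE; it <- 0L
  repeat {
    it <- it + 1L
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -700), 700)
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    dev_new <- nb_deviance(y, pmax(exp(pmin(drop(X %*% beta_new) + offset, 700)), 1e-10), phi)
    if (!is.finite(dev_new)) { converged <- FALSE; break }
    if (abs(dev - dev_new) < tol * (abs(dev_new) + 0.1)) {
      beta <- beta_new; dev <- dev_new; converged <- TRUE; break
    }
    beta <- beta_new; dev <- dev_new
    if (it >= maxit) break
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -700), 700)
  list(coefficients = beta, fitted = exp(eta), deviance = dev,
       converged = converged, iterations = it, df_residual = n - p)
}

# fit every gene of a count matrix against one design; returns coefficient
# matrix (genes x p), deviances and convergence flags
fit_nbglm_matrix <- function(counts, design, offset, phi) {
  G <- nrow(counts)
  p <- ncol(design)
  coefs <- matrix(NA_real_, G, p, dimnames = list(rownames(counts), colnames(design)))
  dev <- numeric(G); conv <- logical(G)
  for (g in seq_len(G)) {
    f <- fit_nbglm(counts[g, ], design, offset, if (length(phi) > 1) phi[g] else phi)
    coefs[g, ] <- f$coefficients
    dev[g] <- f$deviance
    conv[g] <- f$converged
  }
  list(coefficients = coefs, deviance = dev, converged = conv)
}

#' Common and tagwise NB dispersion via Cox-Reid adjusted profile likelihood
#'
#' The common dispersion maximizes the summed Cox-Reid adjusted profile
#' likelihood over genes; tagwise dispersions maximize the per-gene APL plus a
#' fixed prior-weight penalty anchored at the common value (no abundance
#' trend). Estimation is delegated to edgeR's Cox-Reid routines.
#'
#' @param dataset a filtered [count_dataset()].
#' @param design model matrix (>= 2 residual df).
#' @param offset log effective library sizes (default: log raw library
#'   sizes).
#' @param prior_weight shrinkage weight in genes-equivalent prior degrees of
#'   freedom (default 10); 0 gives unshrunk tagwise estimates, large values
#'   collapse every gene to the common dispersion.
#' @return list of class `dispersion_estimates`: common (scalar), tagwise
#'   (per-gene vector), prior_weight.
#' @export
estimate_dispersions <- function(dataset, design, offset = NULL, prior_weight = 10) {
  stopifnot(inherits(dataset, "count_dataset"))
  counts <- dataset$counts
  if (any(rowSums(counts) == 0))
    stop("all-zero gene rows must be filtered before dispersion estimation")
  if (nrow(design) - qr(design)$rank < 1)
    stop("design leaves no residual degrees of freedom")
  if (is.null(offset)) offset <- log(colSums(counts))
  common <- edgeR::estimateGLMCommonDisp(counts, design, offset = offset)
  pw <- min(prior_weight, 1e8)
  tagwise <- edgeR::estimateGLMTagwiseDisp(counts, design, offset = offset,
                                           dispersion = common,
                                           prior.df = pw, trend = FALSE)
  structure(list(common = common,
                 tagwise = stats::setNames(tagwise, rownames(counts)),
                 prior_weight = prior_weight),
            class = "dispersion_estimates")
}

#' Likelihood-ratio test between nested NB GLM fits
#'
#' @param full,reduced results of [fit_nbglm()] (or per-gene lists from the
#'   matrix fitter) under the same dispersion.
#' @param design_full,design_reduced the two model matrices; the reduced
#'   column space must be nested in the full one.
#' @return list(statistic, df, p) with statistic = deviance_reduced -
#'   deviance_full clamped at zero and p from the chi-square reference.
#' @export
lrt_contrast <- function(full, reduced, design_full, design_reduced) {
  rf <- qr(design_full)$rank
  rr <- qr(design_reduced)$rank
  if (qr(cbind(design_full, design_reduced))$rank > rf)
    stop("designs are not nested: reduced model is not a submodel of the full model")
  df <- rf - rr
  if (df < 1) stop("designs are not nested: no rank difference")
  stat <- pmax(reduced$deviance - full$deviance, 0)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q[order(o)]
}

#' Apply the DE call rule
#'
#' up when q < alpha and log2FC > fc_threshold; down when q < alpha and
#' log2FC < -fc_threshold; ns otherwise. All inequalities are strict.
#'
#' @param logFC log2 fold changes.
#' @param q BH-adjusted p-values.
#' @param alpha FDR level in (0, 1) (default 0.05).
#' @param fc_threshold |log2FC| cutoff (default 1).
#' @return character vector in {"up", "down", "ns"}.
#' @export
call_de <- function(logFC, q, alpha = 0.05, fc_threshold = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  ifelse(q < alpha & logFC > fc_threshold, "up",
         ifelse(q < alpha & logFC < -fc_threshold, "down", "ns"))
}

de_contrasts <- c("regime_in_F", "regime_in_M", "sex_in_E", "sex_in_L",
                  "interaction")

# group-mean model matrix for the 4 regime x sex cells, and the reduced
# design for a given contrast (merging the two contrasted cells, or the
# additive model for the interaction test)
contrast_designs <- function(design, contrast) {
  grp <- factor(paste(design$regime, design$sex, sep = "."),
                levels = c("E.F", "L.F", "E.M", "L.M"))
  grp <- droplevels(grp)  # separate fits carry only the contrasted cells
  full <- stats::model.matrix(~ 0 + grp)
  colnames(full) <- levels(grp)
  merge_cells <- function(a, b) {
    keep <- setdiff(levels(grp), c(a, b))
    red <- cbind(full[, a] + full[, b], full[, keep, drop = FALSE])
    colnames(red) <- c(paste(a, b, sep = "+"), keep)
    red
  }
  cells <- switch(contrast,                       # (reference, comparison)
    regime_in_F = c("E.F", "L.F"),                # L - E in females
    regime_in_M = c("E.M", "L.M"),
    sex_in_E    = c("E.F", "E.M"),                # M - F in E
    sex_in_L    = c("L.F", "L.M"),
    interaction = NULL,
    stop("unknown contrast '", contrast, "'; expected one of: ",
         paste(de_contrasts, collapse = ", ")))
  if (is.null(cells)) {
    red <- stats::model.matrix(~ regime + sex, data = design)
    cvec <- NULL
  } else {
    if (!all(cells %in% levels(grp)))
      stop("contrast cells ", paste(cells, collapse = ", "),
           " not all present in the design")
    red <- merge_cells(cells[1], cells[2])
    cvec <- as.numeric(levels(grp) == cells[2]) -
            as.numeric(levels(grp) == cells[1])
  }
  list(full = full, reduced = red, cvec = cvec, group = grp)
}

#' Differential expression for one tissue and one contrast
#'
#' Subsets the dataset to one tissue, applies the expression filter, TMM
#' normalization, Cox-Reid dispersion estimation on the 4-cell regime x sex
#' group-means model, and a likelihood-ratio test of the requested contrast.
#' Regime contrasts are L minus E; sex contrasts are M minus F (so negative
#' log2FC means female-biased). log2FC is computed from a prior-count
#' stabilized refit so zero-count groups yield finite values; the
#' `interaction` contrast compares the 4-cell model against the additive
#' regime + sex model and reports the female-vs-male difference in regime
#' response as its log2FC.
#'
#' @param dataset a [count_dataset()] (any mix of tissues; will be subset).
#' @param tissue "abdomen" or "head_thorax".
#' @param contrast one of regime_in_F, regime_in_M, sex_in_E, sex_in_L,
#'   interaction.
#' @param alpha FDR level (default 0.05).
#' @param fc_threshold |log2FC| call cutoff (default 1).
#' @param prior_weight dispersion shrinkage weight (default 10).
#' @param filter apply [filter_genes()] first (default TRUE).
#' @param prior_count prior count for the stabilized log2FC (default 0.5).
#' @param separate_fits for the four pairwise contrasts, drop the other two
#'   regime x sex cells and fit a plain two-group model on the contrasted
#'   cells only (default FALSE: one joint 4-cell model per tissue).
#' @return data.frame of class `de_result` with columns gene, logFC, logCPM,
#'   LR, p, q, call, converged; attributes contrast/tissue/alpha/fc_threshold
#'   and n_samples.
#' @export
run_de <- function(dataset, tissue, contrast, alpha = 0.05, fc_threshold = 1,
                   prior_weight = 10, filter = TRUE, prior_count = 0.5,
                   separate_fits = FALSE) {
  stopifnot(inherits(dataset, "count_dataset"))
  contrast <- match.arg(contrast, de_contrasts)
  sub <- subset_dataset(dataset, samples = dataset$design$tissue == tissue)
  if (separate_fits && contrast != "interaction") {
    keep_cells <- switch(contrast,
      regime_in_F = sub$design$sex == "F",
      regime_in_M = sub$design$sex == "M",
      sex_in_E    = sub$design$regime == "E",
      sex_in_L    = sub$design$regime == "L")
    sub <- subset_dataset(sub, samples = keep_cells)
  }
  if (ncol(sub$counts) == 0) stop("no samples for tissue '", tissue, "'")
  if (filter) sub <- filter_genes(sub)
  if (nrow(sub$counts) == 0) stop("no genes pass the expression filter")
  fac <- tmm_factors(sub)
  eff <- colSums(sub$counts) * fac
  offset <- log(eff)
  dz <- contrast_designs(sub$design, contrast)
  disp <- estimate_dispersions(sub, dz$full, offset = offset,
                               prior_weight = prior_weight)
  phi <- disp$tagwise
  full <- fit_nbglm_matrix(sub$counts, dz$full, offset, phi)
  redu <- fit_nbglm_matrix(sub$counts, dz$reduced, offset, phi)
  lrt <- lrt_contrast(full, redu, dz$full, dz$reduced)
  # prior-count stabilized logFC: refit the cell-means model on augmented
  # counts so empty cells stay finite
  pr <- prior_count * eff / mean(eff)
  aug_counts <- sweep(sub$counts, 2, pr, "+")
  aug_offset <- log(eff + 2 * pr)
  aug <- fit_nbglm_matrix(aug_counts, dz$full, aug_offset, phi)
  if (is.null(dz$cvec)) {
    # interaction effect: (L-E in M) minus (L-E in F)
    cvec <- c(1, -1, -1, 1)
  } else cvec <- dz$cvec
  logFC <- drop(aug$coefficients %*% cvec) / log(2)
  norm <- logcpm_matrix(sub, factors = fac, prior_count = prior_count)
  p <- lrt$p
  conv <- full$converged & redu$converged
  if (!all(conv))
    warning(sum(!conv), " gene(s) did not converge and are excluded from calls")
  q <- bh_adjust(p)
  call <- call_de(logFC, q, alpha = alpha, fc_threshold = fc_threshold)
  call[!conv] <- NA_character_
  out <- data.frame(gene = rownames(sub$counts), logFC = logFC,
                    logCPM = rowMeans(norm$logcpm), LR = lrt$statistic,
                    p = p, q = q, call = call, converged = conv,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- contrast
  attr(out, "tissue") <- tissue
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "dispersion") <- disp
  class(out) <- c("de_result", "data.frame")
  out
}

#' Genes called DE in a result
#'
#' @param de a `de_result`.
#' @return character vector of gene ids with call != ns.
#' @export
de_genes <- function(de) de$gene[!is.na(de$call) & de$call != "ns"]
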