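#' Classify genes as female-biased, male-biased or unbiased per regime
#'
#' Uses the male-minus-female sign convention: FB when q < alpha and
#' log2FC < -fc_threshold, MB when q < alpha and log2FC > fc_threshold, UB
#' otherwise. A gene is flagged `biased_either` when biased in at least one
#' regime.
#'
#' @param de_sex_E,de_sex_L `de_result`s for the M-vs-F contrast within the E
#'   and L regimes, over the same gene set.
#' @param alpha FDR level (default 0.05).
#' @param fc_threshold |log2FC| cutoff (default 1).
#' @return data.frame of class `sexbias_table`: gene, class_E, class_L,
#'   lfc_E, lfc_L, biased_either.
#' @export
classify_sex_bias <- function(de_sex_E, de_sex_L, alpha = 0.05, fc_threshold = 1) {
  if (!identical(sort(de_sex_E$gene), sort(de_sex_L$gene)))
    stop("E and L sex-contrast results cover different gene sets")
  de_sex_L <- de_sex_L[match(de_sex_E$gene, de_sex_L$gene), ]
  cls <- function(de) {
    call <- call_de(de$logFC, de$q, alpha = alpha, fc_threshold = fc_threshold)
    ifelse(call == "down", "FB", ifelse(call == "up", "MB", "UB"))
  }
  out <- data.frame(gene = de_sex_E$gene,
                    class_E = cls(de_sex_E), class_L = cls(de_sex_L),
                    lfc_E = de_sex_E$logFC, lfc_L = de_sex_L$logFC,
                    stringsAsFactors = FALSE)
  out$biased_either <- out$class_E != "UB" | out$class_L != "UB"
  class(out) <- c("sexbias_table", "data.frame")
  out
}

#' Cross-classification of DE calls between the sexes
#'
#' @param de_F,de_M `de_result`s for the regime contrast in females and males
#'   over the same gene universe.
#' @param restrict_to optional gene set; the table is computed on the subset
#'   (used e.g. for tissue-exclusive gene sets).
#' @return list of class `overlap_table`: female_only, male_only, both,
#'   neither, union; always satisfies female_only + male_only + both = union.
#' @export
overlap_table <- function(de_F, de_M, restrict_to = NULL) {
  if (!identical(sort(de_F$gene), sort(de_M$gene)))
    stop("female and male results cover different gene universes")
  de_M <- de_M[match(de_F$gene, de_M$gene), ]
  keep <- if (is.null(restrict_to)) rep(TRUE, nrow(de_F)) else de_F$gene %in% restrict_to
  inF <- !is.na(de_F$call[keep]) & de_F$call[keep] != "ns"
  inM <- !is.na(de_M$call[keep]) & de_M$call[keep] != "ns"
  structure(list(female_only = sum(inF & !inM), male_only = sum(!inF & inM),
                 both = sum(inF & inM), neither = sum(!inF & !inM),
                 union = sum(inF | inM)),
            class = "overlap_table")
}

pearson_chisq_2x2 <- function(tab, correction = FALSE) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table: empty margin")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  d <- abs(tab - E)
  if (correction) d <- pmax(d - 0.5, 0)
  sum(d^2 / E)
}

#' Two-proportion Pearson chi-square test
#'
#' Pearson chi-square on the 2x2 table (x1, n1-x1; x2, n2-x2) with 1 df;
#' Yates continuity correction only when `correction = TRUE` (default off).
#'
#' @param x1,n1 successes and total of group 1.
#' @param x2,n2 successes and total of group 2.
#' @param correction apply Yates correction.
#' @return list(statistic, df = 1, p).
#' @export
proportion_test <- function(x1, n1, x2, n2, correction = FALSE) {
  if (n1 <= 0 || n2 <= 0 || x1 > n1 || x2 > n2 || x1 < 0 || x2 < 0)
    stop("need 0 <= x <= n with n > 0")
  tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  stat <- pearson_chisq_2x2(tab, correction)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Enrichment of a sex-bias class among DE genes
#'
#' 2x2 chi-square of sex-bias class membership (union over regimes) against
#' DE membership, over the gene universe.
#'
#' @param sexbias a `sexbias_table`.
#' @param de_union gene set DE between regimes (in either sex).
#' @param universe background gene set (all analyzed genes); de_union must be
#'   a subset.
#' @param class "FB" or "MB".
#' @return list of class `enrichment_result`: overlap, class_size,
#'   selected_size, universe_size, odds_ratio, statistic, p.
#' @export
sexbias_de_enrichment <- function(sexbias, de_union, universe, class = c("FB", "MB")) {
  class <- match.arg(class)
  if (!all(de_union %in% universe)) stop("de_union must be a subset of universe")
  sb <- sexbias[sexbias$gene %in% universe, ]
  in_class <- sb$gene[sb$class_E == class | sb$class_L == class]
  a <- sum(universe %in% in_class & universe %in% de_union)
  b <- sum(universe %in% in_class & !(universe %in% de_union))
  c_ <- sum(!(universe %in% in_class) & universe %in% de_union)
  d <- sum(!(universe %in% in_class) & !(universe %in% de_union))
  tab <- rbind(c(a, b), c(c_, d))
  if (length(in_class) == 0)
    stop("degenerate enrichment: no genes in class ", class)
  stat <- pearson_chisq_2x2(tab)
  structure(list(overlap = a, class_size = length(in_class),
                 selected_size = length(de_union),
                 universe_size = length(universe),
                 odds_ratio = (a * d) / max(b * c_, .Machine$double.eps),
                 statistic = stat,
                 p = stats::pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "enrichment_result")
}

#' Median-difference test with a bootstrap CI of the median difference
#'
#' Default is the Brown-Mood two-sample median test: count, per group, the
#' values above the pooled median and form a signed normal-approximation Z
#' from the hypergeometric null (positive when the first group's median
#' exceeds the second's). `method = "wilcoxon"` substitutes the rank-sum
#' normal approximation; `paired = TRUE` (equal lengths required) runs a
#' sign test on the per-gene differences. The CI is a percentile bootstrap
#' (resampling genes, or gene pairs when paired) of median(x) - median(y).
#'
#' @param x,y numeric vectors (e.g. mean log2-cpm of a gene class in E and L).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @param method "brown_mood" (default) or "wilcoxon".
#' @param paired treat x and y as per-gene pairs (default FALSE).
#' @return list(Z, p, ci_low, ci_high, median_diff).
#' @export
median_difference_test <- function(x, y, n_boot = 10000, seed = 1,
                                   method = c("brown_mood", "wilcoxon"),
                                   paired = FALSE) {
  stopifnot(length(x) > 0, length(y) > 0)
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (paired && n1 != n2) stop("paired test needs equal-length vectors")
  degenerate <- function() {
    warning("degenerate median test: no information about a location difference")
    list(Z = 0, p = 1)
  }
  zt <- if (paired) {
    d <- x - y; d <- d[d != 0]
    if (length(d) == 0) degenerate() else {
      np <- sum(d > 0); n <- length(d)
      Z <- (np - n / 2) / sqrt(n / 4)
      list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
    }
  } else if (method == "brown_mood") {
    pooled <- stats::median(c(x, y))
    M <- sum(c(x, y) > pooled)
    m1 <- sum(x > pooled)
    if (M == 0 || M == N) degenerate() else {
      mu <- n1 * M / N
      v <- n1 * (M / N) * (1 - M / N) * (N - n1) / (N - 1)
      list(Z = (m1 - mu) / sqrt(v),
           p = 2 * stats::pnorm(-abs((m1 - mu) / sqrt(v))))
    }
  } else {
    r <- rank(c(x, y))
    W <- sum(r[seq_len(n1)])
    tie <- table(r)
    v <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (v <= 0) degenerate() else {
      Z <- (W - n1 * (N + 1) / 2) / sqrt(v)
      list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  diffs <- vapply(seq_len(n_boot), function(b) {
    if (paired) {
      i <- sample.int(n1, n1, replace = TRUE)
      stats::median(x[i] - y[i])
    } else {
      stats::median(x[sample.int(n1, n1, replace = TRUE)]) -
        stats::median(y[sample.int(n2, n2, replace = TRUE)])
    }
  }, numeric(1))
  ci <- unname(stats::quantile(diffs, c(0.025, 0.975)))
  list(Z = zt$Z, p = min(zt$p, 1), ci_low = ci[1], ci_high = ci[2],
       median_diff = stats::median(x) - stats::median(y))
}

#' Correlation of sex-bias log2FC between regimes
#'
#' Pearson correlation of the E and L sex-bias log2FC over the union of genes
#' sex-biased in either regime, with a Fisher-z 95% CI and a t-test on
#' df = n - 2.
#'
#' @param sexbias a `sexbias_table`.
#' @return list(r, df, ci_low, ci_high, t, p, n).
#' @export
sexbias_correlation <- function(sexbias) {
  sb <- sexbias[sexbias$biased_either, ]
  n <- nrow(sb)
  if (n < 3) stop("fewer than 3 genes sex-biased in either regime")
  r <- stats::cor(sb$lfc_E, sb$lfc_L)
  z <- atanh(r); se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, df = n - 2L, ci_low = ci[1], ci_high = ci[2],
       t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Best homology hit per query
#'
#' Minimal e-value per query; ties broken by maximal bit score, remaining
#' ties by first occurrence (stable).
#'
#' @param hits a `homology_hits` table from [read_homology_hits()].
#' @return data.frame with one row per query, original columns retained.
#' @export
best_hit_selection <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$query_id, hits$e_value, -hits$bit_score,
               seq_len(nrow(hits)))
  h <- hits[ord, ]
  out <- h[!duplicated(h$query_id), ]
  out <- out[match(unique(hits$query_id), out$query_id), ]
  rownames(out) <- NULL
  out
}

#' Candidate-gene enrichment among DE genes
#'
#' 2x2 chi-square of candidate membership against DE membership over the
#' gene universe.
#'
#' @param candidates candidate gene set (non-empty, subset of universe).
#' @param de_union DE gene set (subset of universe).
#' @param universe background gene set.
#' @return list(statistic, df = 1, p, overlap, n_candidates).
#' @export
candidate_enrichment <- function(candidates, de_union, universe) {
  candidates <- intersect(candidates, universe)
  if (length(candidates) == 0) stop("empty candidate set (after universe intersection)")
  if (!all(de_union %in% universe)) stop("de_union must be a subset of universe")
  inC <- universe %in% candidates
  inD <- universe %in% de_union
  tab <- rbind(c(sum(inC & inD), sum(inC & !inD)),
               c(sum(!inC & inD), sum(!inC & !inD)))
  stat <- pearson_chisq_2x2(tab)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       overlap = sum(inC & inD), n_candidates = length(candidates))
}

#' Gene-set (term) over-representation by hypergeometric test
#'
#' One-sided upper-tail hypergeometric p per term, P[X >= overlap], with
#' terms first intersected with the universe; BH adjustment across tested
#' terms. Terms with an empty universe intersection are skipped (recorded in
#' the `skipped` attribute).
#'
#' @param selected selected gene set (subset of universe).
#' @param universe background gene set.
#' @param terms a `gene_set_map` from [read_gmt()] (or any named list of gene
#'   id vectors).
#' @return data.frame: term, overlap, term_size, selected_size,
#'   universe_size, odds_ratio, p, q.
#' @export
term_enrichment <- function(selected, universe, terms) {
  if (!all(selected %in% universe)) stop("selected must be a subset of universe")
  N <- length(universe); s <- length(selected)
  rows <- list(); skipped <- character(0)
  for (term in names(terms)) {
    tg <- intersect(terms[[term]], universe)
    K <- length(tg)
    if (K == 0) { skipped <- c(skipped, term); next }
    k <- length(intersect(tg, selected))
    p <- stats::phyper(k - 1, K, N - K, s, lower.tail = FALSE)
    expct <- K * s / N
    rows[[term]] <- data.frame(term = term, overlap = k, term_size = K,
                               selected_size = s, universe_size = N,
                               odds_ratio = (k * (N - K - s + k)) /
                                 max((K - k) * (s - k), .Machine$double.eps),
                               expected = expct, p = p,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), selected_size = integer(0),
                      universe_size = integer(0), odds_ratio = numeric(0),
                      expected = numeric(0), p = numeric(0), q = numeric(0))
  } else {
    out$q <- bh_adjust(out$p)
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}
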