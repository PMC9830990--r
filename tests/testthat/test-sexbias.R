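mk_de <- function(genes, logFC, q) {
  data.frame(gene = genes, logFC = logFC, q = q, stringsAsFactors = FALSE)
}

test_that("classify_sex_bias applies the FB/MB/UB rule per regime", {
  genes <- c("g1", "g2", "g3", "g4")
  deE <- mk_de(genes, logFC = c(-2, 0.5, 3, 0.2), q = c(0.01, 0.01, 0.04, 0.8))
  deL <- mk_de(genes, logFC = c(-0.2, 0.5, 3, 0.1), q = c(0.9, 0.01, 0.04, 0.9))
  sb <- classify_sex_bias(deE, deL)
  expect_equal(sb$class_E, c("FB", "UB", "MB", "UB"))  # g2 fails fc threshold
  expect_equal(sb$class_L, c("UB", "UB", "MB", "UB"))
  expect_equal(sb$biased_either, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(classify_sex_bias(deE, deL[1:3, ]), "different gene sets")
})

test_that("classify_sex_bias agrees with call_de under the sign convention", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:200)
  deE <- mk_de(genes, rnorm(200, 0, 2), runif(200))
  deL <- mk_de(genes, rnorm(200, 0, 2), runif(200))
  sb <- classify_sex_bias(deE, deL)
  callE <- call_de(deE$logFC, deE$q)
  expect_equal(sb$class_E == "FB", callE == "down")
  expect_equal(sb$class_E == "MB", callE == "up")
})

test_that("overlap_table set arithmetic and additivity", {
  genes <- letters[1:10]
  deF <- fake_de(genes, c("a", "b", "c"))
  deM <- fake_de(genes, c("b", "c", "d"))
  ov <- overlap_table(deF, deM)
  expect_equal(ov$female_only, 1); expect_equal(ov$male_only, 1)
  expect_equal(ov$both, 2); expect_equal(ov$union, 4)
  expect_equal(ov$neither, 6)

  ov2 <- overlap_table(fake_de(genes, c("a", "b", "c")),
                       fake_de(genes, c("d", "e")))
  expect_equal(ov2$both, 0); expect_equal(ov2$union, 5)

  # additivity holds under restriction too
  ov3 <- overlap_table(deF, deM, restrict_to = c("a", "b", "d"))
  expect_equal(ov3$female_only + ov3$male_only + ov3$both, ov3$union)
  expect_equal(ov3$union, 3)
})

test_that("proportion_test is Pearson chi-square (z^2 identity, hand value)", {
  null <- proportion_test(10, 100, 10, 100)
  expect_equal(null$statistic, 0); expect_equal(null$p, 1)

  # hand-derived Pearson chi-square for (30/100 vs 10/100):
  # expected = 20, statistic = sum((obs - exp)^2 / exp) over the 2x2 = 12.5
  expect_equal(proportion_test(30, 100, 10, 100)$statistic, 12.5,
               tolerance = 1e-12)

  edge <- proportion_test(5, 5, 0, 7)
  expect_true(is.finite(edge$statistic) && edge$p >= 0 && edge$p <= 1)
  expect_error(proportion_test(0, 10, 0, 10), "empty margin")

  # oracle identity: chi-square equals the squared two-proportion z statistic
  set.seed(4)
  for (i in 1:100) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    p1 <- x1 / n1; p2 <- x2 / n2; pp <- (x1 + x2) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(proportion_test(x1, n1, x2, n2)$statistic, z^2,
                 tolerance = 1e-9)
  }
})

test_that("sexbias_de_enrichment behaves at the extremes and under the null", {
  genes <- sprintf("g%04d", 1:2000)
  sb <- data.frame(gene = genes, class_E = "UB", class_L = "UB",
                   lfc_E = 0, lfc_L = 0, biased_either = FALSE,
                   stringsAsFactors = FALSE)
  sb$class_E[1:200] <- "FB"; sb$biased_either[1:200] <- TRUE
  # all DE genes FB, no other FB overlap -> huge enrichment
  e <- sexbias_de_enrichment(sb, de_union = genes[1:100], universe = genes,
                             class = "FB")
  expect_lt(e$p, 1e-3)
  expect_equal(e$overlap, 100)
  sb0 <- sb; sb0$class_E[] <- "UB"
  expect_error(sexbias_de_enrichment(sb0, genes[1:100], genes, "FB"),
               "degenerate")

  # null: p approximately uniform (KS sanity over 200 simulated tables)
  set.seed(9)
  ps <- replicate(200, {
    sbn <- sb
    sbn$class_E[] <- "UB"
    sbn$class_E[sample(2000, 300)] <- "FB"
    sexbias_de_enrichment(sbn, sample(genes, 200), genes, "FB")$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("median_difference_test: identity, shift, determinism", {
  set.seed(5)
  x <- rnorm(100)
  same <- median_difference_test(x, x, n_boot = 500, seed = 1)
  expect_equal(same$Z, 0); expect_equal(same$p, 1)
  expect_true(same$ci_low <= 0 && same$ci_high >= 0)

  y <- rnorm(200)
  sh <- median_difference_test(y + 5, y, n_boot = 2000, seed = 2)
  expect_gt(sh$Z, 0); expect_lt(sh$p, 1e-6)
  expect_equal(sh$ci_low, 5, tolerance = 0.5)
  expect_equal(sh$ci_high, 5, tolerance = 0.5)

  a <- median_difference_test(y + 0.1, y, n_boot = 300, seed = 7)
  b <- median_difference_test(y + 0.1, y, n_boot = 300, seed = 7)
  expect_identical(a, b)

  expect_warning(median_difference_test(rep(1, 5), rep(1, 5), n_boot = 100),
                 "degenerate")
})

test_that("sexbias_correlation: identity, null size, df bookkeeping", {
  genes <- sprintf("g%03d", 1:50)
  lfc <- seq(-3, 3, length.out = 50)
  sb <- data.frame(gene = genes, class_E = "FB", class_L = "FB",
                   lfc_E = lfc, lfc_L = lfc, biased_either = TRUE,
                   stringsAsFactors = FALSE)
  res <- sexbias_correlation(sb)
  expect_equal(res$r, 1)
  expect_equal(res$df, 48)

  set.seed(10)
  hits <- 0
  for (s in 1:20) {
    sbn <- sb[rep(1, 1000), ]
    sbn$gene <- sprintf("h%04d", 1:1000)
    sbn$lfc_E <- rnorm(1000); sbn$lfc_L <- rnorm(1000)
    r <- sexbias_correlation(sbn)$r
    hits <- hits + (abs(r) < 0.1)
  }
  expect_gte(hits, 19)
  expect_error(sexbias_correlation(sb[1:2, ]), "fewer than 3")
})

test_that("best_hit_selection: e-value first, bit score tie-break, stable", {
  h <- data.frame(query_id = c("q1", "q1", "q2", "q2", "q2"),
                  subject_id = c("s1", "s2", "s3", "s4", "s5"),
                  e_value = c(1e-5, 1e-10, 1e-10, 1e-10, 1e-10),
                  bit_score = c(100, 90, 200, 554, 554),
                  stringsAsFactors = FALSE)
  best <- best_hit_selection(h)
  expect_equal(best$subject_id[best$query_id == "q1"], "s2")
  expect_equal(best$subject_id[best$query_id == "q2"], "s4")  # first of ties
  empty <- h[0, ]
  expect_equal(nrow(best_hit_selection(empty)), 0)
})

test_that("candidate_enrichment: extremes, depletion and null uniformity", {
  genes <- sprintf("g%04d", 1:2000)
  de <- genes[1:100]
  ex <- candidate_enrichment(de, de, genes)
  expect_lt(ex$p, 1e-10)
  dep <- candidate_enrichment(genes[101:200], de, genes)
  expect_true(is.finite(dep$statistic) && dep$p <= 1)
  expect_error(candidate_enrichment(character(0), de, genes), "empty")

  # expected overlap must be large enough for the chi-square approximation,
  # otherwise discreteness shows up in the KS comparison
  de_big <- genes[1:800]
  set.seed(11)
  ps <- replicate(200, candidate_enrichment(sample(genes, 600), de_big, genes)$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("term_enrichment: closed form, brute force, degenerate cases", {
  # universe 10, term 5, selected 5, overlap 5 -> p = 1/C(10,5)
  uni <- letters[1:10]
  terms <- list(T1 = letters[1:5])
  res <- term_enrichment(letters[1:5], uni, terms)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)

  # brute-force hypergeometric tail on all small configurations
  tail_brute <- function(k, K, N, s) {
    sum(sapply(k:min(K, s), function(j)
      choose(K, j) * choose(N - K, s - j) / choose(N, s)))
  }
  set.seed(13)
  for (i in 1:50) {
    N <- sample(5:15, 1)
    uni <- sprintf("u%02d", 1:N)
    K <- sample(1:N, 1); s <- sample(1:N, 1)
    term <- list(T = sample(uni, K))
    sel <- sample(uni, s)
    k <- length(intersect(term$T, sel))
    expect_equal(term_enrichment(sel, uni, term)$p, tail_brute(k, K, N, s),
                 tolerance = 1e-12)
  }

  # selected = universe -> p = 1 for every term
  res2 <- term_enrichment(uni, uni, list(A = uni[1:3], B = uni[2:9]))
  expect_true(all(res2$p == 1))

  # term disjoint from universe is skipped, not an error
  res3 <- term_enrichment(uni[1:2], uni, list(A = uni[1:3], Z = c("x", "y")))
  expect_equal(res3$term, "A")
  expect_equal(attr(res3, "skipped"), "Z")
  expect_error(term_enrichment(c(uni, "zz"), uni, list(A = uni[1:3])),
               "subset")
})

test_that("median test variants: wilcoxon and paired", {
  set.seed(17)
  y <- rnorm(150)
  w <- median_difference_test(y + 2, y, n_boot = 300, seed = 1,
                              method = "wilcoxon")
  expect_gt(w$Z, 0); expect_lt(w$p, 1e-6)
  pr <- median_difference_test(y + 1, y, n_boot = 300, seed = 1, paired = TRUE)
  expect_gt(pr$Z, 0); expect_lt(pr$p, 1e-6)
  expect_equal(pr$ci_low, 1, tolerance = 1e-6)  # constant paired shift
  expect_error(median_difference_test(1:3, 1:4, paired = TRUE), "equal-length")
})
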