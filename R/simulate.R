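#' Configuration for the synthetic experimental-evolution count generator
#'
#' The generator emulates the study layout: two selection regimes (E/L), a set
#' of replicate lines per regime, two sexes, and one pooled RNA-seq library
#' per line x sex x tissue. Counts are negative-binomial around library-size
#' scaled expected proportions
#' \deqn{count_{g,s} \sim NB(\mu = L_s 2^{\eta_{g,s}} / \sum_g 2^{\eta_{g,s}},\ \phi_g)}
#' with
#' \deqn{\eta = baseline_g + tissue_g + sex_g I[male] + regime_{g,sex} I[L] + line_{g,line}.}
#'
#' @param n_genes number of genes (default 17000, the filtered-gene scale of
#'   the study).
#' @param n_lines_per_regime replicate lines per regime (default 4).
#' @param tissues character subset of c("abdomen", "head_thorax").
#' @param library_size_range log-uniform sampling range for library sizes.
#' @param baseline_log2_mean,baseline_log2_sd normal distribution of baseline
#'   log2 expression scores.
#' @param tissue_shift_sd sd of the per-gene head_thorax shift (log2).
#' @param dispersion list(kind = "lognormal", median, log_sd) or
#'   list(kind = "fixed", value); per-gene NB dispersion phi.
#' @param frac_sex_biased named fractions of sex-biased genes per tissue
#'   (defaults: abdomen 0.35, head_thorax 0.05, mirroring the reproductive vs
#'   somatic contrast).
#' @param frac_regime_de fraction of genes with a regime (E vs L) effect.
#' @param frac_interaction fraction with sex-specific (interaction) regime
#'   effects.
#' @param effect_size list(kind = "one_plus_exp", rate) giving |log2FC| =
#'   1 + Exp(rate), or list(kind = "fixed", value).
#' @param sigma_line sd of per gene x line log2 random effects; scalar or
#'   named c(E = , L = ).
#' @param rng_seed integer seed; identical seeds give bit-identical datasets.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 17000,
                       n_lines_per_regime = 4,
                       tissues = c("abdomen", "head_thorax"),
                       library_size_range = c(5e6, 2e7),
                       baseline_log2_mean = 5,
                       baseline_log2_sd = 2,
                       tissue_shift_sd = 1,
                       dispersion = list(kind = "lognormal", median = 0.05, log_sd = 0.5),
                       frac_sex_biased = c(abdomen = 0.35, head_thorax = 0.05),
                       frac_regime_de = 0.06,
                       frac_interaction = 0.005,
                       effect_size = list(kind = "one_plus_exp", rate = 1),
                       sigma_line = 0.15,
                       rng_seed = 1) {
  tissues <- match.arg(tissues, c("abdomen", "head_thorax"), several.ok = TRUE)
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_lines_per_regime < 1) stop("need at least one line per regime")
  if (any(library_size_range <= 0)) stop("degenerate config: zero library size")
  fr <- c(frac_sex_biased, frac_regime_de, frac_interaction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (length(sigma_line) == 1) sigma_line <- c(E = unname(sigma_line), L = unname(sigma_line))
  if (any(sigma_line < 0)) stop("sigma_line must be >= 0")
  if (!all(c("E", "L") %in% names(sigma_line))) stop("sigma_line needs E and L entries")
  miss <- setdiff(tissues, names(frac_sex_biased))
  if (length(miss) > 0) stop("frac_sex_biased missing tissue(s): ", paste(miss, collapse = ", "))
  structure(list(
    n_genes = as.integer(n_genes), n_lines_per_regime = as.integer(n_lines_per_regime),
    tissues = tissues, library_size_range = library_size_range,
    baseline_log2_mean = baseline_log2_mean, baseline_log2_sd = baseline_log2_sd,
    tissue_shift_sd = tissue_shift_sd, dispersion = dispersion,
    frac_sex_biased = frac_sex_biased, frac_regime_de = frac_regime_de,
    frac_interaction = frac_interaction, effect_size = effect_size,
    sigma_line = sigma_line, rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

draw_effect_sizes <- function(n, dist) {
  if (n == 0) return(numeric(0))
  switch(dist$kind,
         one_plus_exp = 1 + stats::rexp(n, rate = dist$rate),
         fixed = rep(dist$value, n),
         stop("unknown effect_size kind: ", dist$kind))
}

draw_dispersions <- function(n, dist) {
  switch(dist$kind,
         lognormal = exp(stats::rnorm(n, mean = log(dist$median), sd = dist$log_sd)),
         fixed = rep(dist$value, n),
         stop("unknown dispersion kind: ", dist$kind))
}

rnb <- function(mu, phi) {
  # phi = 0 is the Poisson limit
  out <- numeric(length(mu))
  pois <- phi == 0
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois), size = 1 / phi[!pois],
                                               mu = mu[!pois])
  out
}

simulate_core <- function(config, null_effects = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$rng_seed)

  G <- config$n_genes
  nl <- config$n_lines_per_regime
  genes <- sprintf("g%05d", seq_len(G))

  baseline <- stats::rnorm(G, config$baseline_log2_mean, config$baseline_log2_sd)
  tissue_shift <- stats::rnorm(G, 0, config$tissue_shift_sd)  # head_thorax minus abdomen
  phi <- draw_dispersions(G, config$dispersion)

  # per-tissue gene-level effects (log2, male - female / L - E conventions)
  eff <- list()
  for (t in config$tissues) {
    sexb <- stats::runif(G) < config$frac_sex_biased[[t]]
    sex_lfc <- numeric(G)
    sex_lfc[sexb] <- sample(c(-1, 1), sum(sexb), replace = TRUE) *
      draw_effect_sizes(sum(sexb), config$effect_size)
    inter <- stats::runif(G) < config$frac_interaction
    rde <- stats::runif(G) < config$frac_regime_de
    reg_F <- reg_M <- numeric(G)
    shared <- rde & !inter
    sgn <- sample(c(-1, 1), sum(shared), replace = TRUE)
    mag <- draw_effect_sizes(sum(shared), config$effect_size)
    reg_F[shared] <- sgn * mag
    reg_M[shared] <- sgn * mag
    # interaction genes: independent regime response per sex
    reg_F[inter] <- sample(c(-1, 1), sum(inter), replace = TRUE) *
      draw_effect_sizes(sum(inter), config$effect_size)
    reg_M[inter] <- sample(c(-1, 1), sum(inter), replace = TRUE) *
      draw_effect_sizes(sum(inter), config$effect_size)
    if (null_effects) {
      sex_lfc[] <- 0; reg_F[] <- 0; reg_M[] <- 0; inter[] <- FALSE
    }
    eff[[t]] <- list(sex = sex_lfc, reg_F = reg_F, reg_M = reg_M, interaction = inter)
  }

  # line random effects, gene x line, per-regime sd
  lines_tab <- expand.grid(line = seq_len(nl), regime = c("E", "L"),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  line_eff <- matrix(0, G, nrow(lines_tab))
  for (j in seq_len(nrow(lines_tab))) {
    s <- config$sigma_line[[lines_tab$regime[j]]]
    if (s > 0) line_eff[, j] <- stats::rnorm(G, 0, s)
  }

  design <- expand.grid(line = seq_len(nl), regime = c("E", "L"),
                        sex = c("F", "M"), tissue = config$tissues,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample <- sprintf("%s%d_%s_%s", design$regime, design$line, design$sex,
                           ifelse(design$tissue == "abdomen", "abd", "ht"))
  design <- design[, c("sample", "regime", "line", "sex", "tissue")]
  S <- nrow(design)
  lsr <- log(config$library_size_range)
  libsize <- round(exp(stats::runif(S, lsr[1], lsr[2])))

  counts <- matrix(0, G, S, dimnames = list(genes, design$sample))
  for (s in seq_len(S)) {
    t <- design$tissue[s]
    e <- eff[[t]]
    eta <- baseline +
      tissue_shift * (t == "head_thorax") +
      e$sex * (design$sex[s] == "M") +
      (if (design$sex[s] == "F") e$reg_F else e$reg_M) * (design$regime[s] == "L") +
      line_eff[, which(lines_tab$line == design$line[s] &
                         lines_tab$regime == design$regime[s])]
    w <- 2^eta
    mu <- libsize[s] * w / sum(w)
    counts[, s] <- rnb(mu, phi)
  }

  truth <- data.frame(gene = genes, phi = phi, stringsAsFactors = FALSE)
  for (t in config$tissues) {
    e <- eff[[t]]
    sex_E <- e$sex
    sex_L <- e$sex + (e$reg_M - e$reg_F)  # interaction shifts dimorphism in L
    cls <- function(x) ifelse(x < 0, "FB", ifelse(x > 0, "MB", "UB"))
    w0 <- 2^(baseline + tissue_shift * (t == "head_thorax"))
    truth[[paste0("class_E_", t)]] <- cls(sex_E)
    truth[[paste0("class_L_", t)]] <- cls(sex_L)
    truth[[paste0("sexbias_lfc_E_", t)]] <- sex_E
    truth[[paste0("sexbias_lfc_L_", t)]] <- sex_L
    truth[[paste0("regime_lfc_F_", t)]] <- e$reg_F
    truth[[paste0("regime_lfc_M_", t)]] <- e$reg_M
    truth[[paste0("interaction_", t)]] <- e$interaction
    truth[[paste0("baseline_cpm_", t)]] <- w0 / sum(w0) * 1e6
  }

  list(dataset = count_dataset(counts, design), truth = truth,
       lib_sizes = stats::setNames(libsize, design$sample))
}

#' Simulate a replicated experimental-evolution count dataset
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (a [count_dataset()]), `truth`
#'   (data.frame, one row per gene, holding true dispersions, per-tissue true
#'   sex-bias log2FC and FB/MB/UB class per regime, true regime log2FC per
#'   sex, interaction flags and baseline cpm) and `lib_sizes` (the requested
#'   per-sample library sizes).
#' @export
simulate_dataset <- function(config) simulate_core(config, null_effects = FALSE)

#' Simulate a global-null dataset
#'
#' As [simulate_dataset()] but with every sex, regime and interaction effect
#' forced to zero; line random effects and gene dispersions are retained.
#'
#' @param config a [sim_config()].
#' @return list(dataset, truth); all truth classes are UB and all true log2FC
#'   are zero.
#' @export
simulate_null <- function(config) simulate_core(config, null_effects = TRUE)
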