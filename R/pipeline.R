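pipeline_defaults <- function() {
  list(mode = "simulate",
       counts = NULL, design = NULL,      # input TSVs when mode = "counts"
       gmt = NULL, candidates = NULL, hits = NULL, curve = NULL,
       alpha = 0.05, fc_threshold = 1,
       pca_components = 16, n_boot = 0,
       prior_weight = 10, seed = 1,
       outdir = ".",
       sim = list(),                      # overrides passed to sim_config()
       stages = list(repeatability = TRUE, de = TRUE, sexbias = TRUE,
                     enrich = FALSE, candidates = FALSE, curvefit = FALSE))
}

#' Build and validate a pipeline configuration
#'
#' @param ... named overrides of the defaults: mode ("simulate" or "counts"),
#'   counts/design/gmt/candidates/hits/curve paths, alpha, fc_threshold,
#'   pca_components, n_boot, prior_weight, seed, outdir, sim (list of
#'   [sim_config()] overrides) and stages (named logical list).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(over)) {
    if (k %in% c("sim", "stages")) {
      sub <- over[[k]]
      bad <- setdiff(names(sub), names(if (k == "sim") formals(sim_config) else cfg$stages))
      if (length(bad) > 0)
        stop("unknown ", k, " key(s): ", paste(bad, collapse = ", "))
      cfg[[k]][names(sub)] <- sub
    } else cfg[[k]] <- over[[k]]
  }
  if (!cfg$mode %in% c("simulate", "counts"))
    stop("mode must be 'simulate' or 'counts'")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$fc_threshold < 0) stop("fc_threshold must be >= 0")
  if (cfg$pca_components < 1) stop("pca_components must be >= 1")
  if (cfg$n_boot < 0) stop("n_boot must be >= 0")
  if (cfg$mode == "counts" && (is.null(cfg$counts) || is.null(cfg$design)))
    stop("mode 'counts' needs counts and design paths")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Absent keys take their defaults; unknown keys are rejected by name.
#'
#' @param path YAML file; an empty file yields the full default
#'   configuration.
#' @return a [pipeline_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a YAML mapping")
  do.call(pipeline_config, raw)
}

read_divergence_series <- function(path) {
  series <- read_tsv_checked(path, "divergence series")
  names(series) <- sub("^time$", "X", sub("^divergence$", "Y", names(series)))
  # an all-female series would type-convert "F" to logical on read
  if (is.logical(series$sex)) series$sex <- ifelse(series$sex, "T", "F")
  series
}

log_stage <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Orchestrates: data acquisition (synthetic generation or TSV input), global
#' filtering/normalization, multivariate repeatability per regime x sex x
#' tissue group, per-tissue differential expression for all five contrasts,
#' sex-bias classification with overlap/proportion/median-shift/correlation
#' summaries, optional term and candidate enrichment, and the optional
#' divergence-curve fit. Writes per-stage TSVs, a MANIFEST of completed
#' stages, and a machine-readable `summary.json` into `outdir`. Reruns with
#' an identical configuration produce identical summaries.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress with timestamps (default FALSE).
#' @return the summary (invisibly), as written to summary.json.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  completed <- character(0)
  manifest <- function() writeLines(completed, file.path(outdir, "MANIFEST"))
  stage <- function(name, expr) {
    log_stage(verbose, "stage %s", name)
    res <- tryCatch(expr, error = function(e) {
      manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    completed <<- c(completed, name)
    res
  }
  summary <- list(parameters = list(alpha = config$alpha,
                                    fc_threshold = config$fc_threshold,
                                    pca_components = config$pca_components,
                                    n_boot = config$n_boot,
                                    prior_weight = config$prior_weight,
                                    seed = config$seed, mode = config$mode))

  dat <- stage("data", {
    if (config$mode == "simulate") {
      sim_args <- config$sim
      if (is.null(sim_args$rng_seed)) sim_args$rng_seed <- config$seed
      sim <- simulate_dataset(do.call(sim_config, sim_args))
      write_counts(sim$dataset, file.path(outdir, "counts.tsv"),
                   file.path(outdir, "design.tsv"))
      write_table(sim$truth, file.path(outdir, "truth.tsv"))
      sim$dataset
    } else {
      read_counts(config$counts, config$design)
    }
  })
  summary$n_genes_input <- nrow(dat$counts)
  summary$n_samples <- ncol(dat$counts)

  if (isTRUE(config$stages$repeatability)) {
    summary$repeatability <- stage("repeatability", {
      filt <- filter_genes(dat)
      norm <- logcpm_matrix(filt)
      k <- min(config$pca_components, ncol(filt$counts) - 1, nrow(filt$counts))
      reps <- repeatability_all(norm, k = k, n_boot = config$n_boot,
                                seed = config$seed)
      write_table(reps, file.path(outdir, "repeatability.tsv"))
      reps
    })
  }

  tissues <- as.character(unique(dat$design$tissue))
  de <- list()
  if (isTRUE(config$stages$de)) {
    summary$de_counts <- stage("de", {
      counts <- list()
      for (t in tissues) {
        de[[t]] <- list()
        for (ctr in de_contrasts) {
          res <- run_de(dat, tissue = t, contrast = ctr,
                        alpha = config$alpha, fc_threshold = config$fc_threshold,
                        prior_weight = config$prior_weight)
          de[[t]][[ctr]] <- res
          write_table(res[, setdiff(names(res), "converged")],
                      file.path(outdir, sprintf("de_%s_%s.tsv", t, ctr)))
          counts[[t]][[ctr]] <- list(up = sum(res$call == "up", na.rm = TRUE),
                                     down = sum(res$call == "down", na.rm = TRUE),
                                     n_universe = nrow(res))
        }
      }
      counts
    })
  }

  if (isTRUE(config$stages$sexbias) && isTRUE(config$stages$de)) {
    summary$sexbias <- stage("sexbias", {
      out <- list()
      for (t in tissues) {
        sb <- classify_sex_bias(de[[t]]$sex_in_E, de[[t]]$sex_in_L,
                                alpha = config$alpha,
                                fc_threshold = config$fc_threshold)
        write_table(sb, file.path(outdir, sprintf("sexbias_%s.tsv", t)))
        ov <- overlap_table(de[[t]]$regime_in_F, de[[t]]$regime_in_M)
        n <- nrow(sb)
        counts <- list(
          E = list(FB = sum(sb$class_E == "FB"), MB = sum(sb$class_E == "MB"),
                   UB = sum(sb$class_E == "UB")),
          L = list(FB = sum(sb$class_L == "FB"), MB = sum(sb$class_L == "MB"),
                   UB = sum(sb$class_L == "UB")))
        props <- lapply(counts, function(x) lapply(x, function(v) v / n))
        ptests <- list(
          FB = proportion_test(counts$E$FB, n, counts$L$FB, n),
          MB = proportion_test(counts$E$MB, n, counts$L$MB, n))
        de_union <- union(de_genes(de[[t]]$regime_in_F),
                          de_genes(de[[t]]$regime_in_M))
        enr <- lapply(c(FB = "FB", MB = "MB"), function(cl) {
          tryCatch({
            e <- sexbias_de_enrichment(sb, de_union, sb$gene, cl)
            list(statistic = e$statistic, p = e$p, overlap = e$overlap,
                 class_size = e$class_size)
          }, error = function(e) list(error = conditionMessage(e)))
        })
        corr <- tryCatch(sexbias_correlation(sb), error = function(e)
          list(error = conditionMessage(e)))
        out[[t]] <- list(overlap = unclass(ov), counts = counts,
                         proportions = props, proportion_tests = ptests,
                         de_enrichment = enr,
                         correlation = corr,
                         n_biased_either = sum(sb$biased_either))
      }
      out
    })
  }

  if (isTRUE(config$stages$enrich) && !is.null(config$gmt) && length(de) > 0) {
    summary$term_enrichment <- stage("enrich", {
      terms <- read_gmt(config$gmt)
      out <- list()
      for (t in tissues) {
        universe <- de[[t]]$regime_in_F$gene
        sel <- union(de_genes(de[[t]]$regime_in_F), de_genes(de[[t]]$regime_in_M))
        te <- term_enrichment(sel, universe, terms)
        if (nrow(te) > 0)
          write_table(te, file.path(outdir, sprintf("enrichment_%s.tsv", t)))
        out[[t]] <- list(n_terms = nrow(te),
                         n_significant = sum(te$q < config$alpha))
      }
      out
    })
  }

  if (isTRUE(config$stages$candidates) && !is.null(config$hits) &&
      !is.null(config$candidates) && length(de) > 0) {
    summary$candidates <- stage("candidates", {
      hits <- read_homology_hits(config$hits)
      best <- best_hit_selection(hits)
      if (nrow(best) > 0) write_table(best, file.path(outdir, "best_hits.tsv"))
      cand_queries <- readLines(config$candidates, warn = FALSE)
      cand_genes <- unique(best$subject_id[best$query_id %in% cand_queries])
      out <- list(n_candidate_genes = length(cand_genes))
      for (t in tissues) {
        universe <- de[[t]]$regime_in_F$gene
        sel <- union(de_genes(de[[t]]$regime_in_F), de_genes(de[[t]]$regime_in_M))
        out[[t]] <- tryCatch(
          candidate_enrichment(cand_genes, sel, universe),
          error = function(e) list(error = conditionMessage(e)))
      }
      out
    })
  }

  if (isTRUE(config$stages$curvefit) && !is.null(config$curve)) {
    summary$divergence_curve <- stage("curvefit", {
      series <- read_divergence_series(config$curve)
      fits <- lapply(c(F = "F", M = "M"), function(sx)
        fit_divergence_curve(series, sex = sx))
      cmp <- compare_parameters(fits$F, fits$M)
      list(F = unclass(fits$F)[c("a", "b", "se_a", "se_b", "df", "n")],
           M = unclass(fits$M)[c("a", "b", "se_a", "se_b", "df", "n")],
           comparison = cmp)
    })
  }

  manifest()
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, file.path(outdir, "summary.json"))
  log_stage(verbose, "pipeline complete: %s", file.path(outdir, "summary.json"))
  invisible(summary)
}
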