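# shared fixture builders; everything is generated in code at test time

make_design <- function(n_lines = 4, tissues = "abdomen", sexes = c("F", "M"),
                        regimes = c("E", "L")) {
  d <- expand.grid(line = seq_len(n_lines), regime = regimes, sex = sexes,
                   tissue = tissues, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$sample <- sprintf("%s%d_%s_%s", d$regime, d$line, d$sex,
                      ifelse(d$tissue == "abdomen", "abd", "ht"))
  d[, c("sample", "regime", "line", "sex", "tissue")]
}

random_dataset <- function(n_genes = 50, n_lines = 2, seed = 1,
                           tissues = "abdomen", mu = 50, size = 5) {
  set.seed(seed)
  design <- make_design(n_lines, tissues)
  counts <- matrix(rnbinom(n_genes * nrow(design), mu = mu, size = size),
                   n_genes, nrow(design),
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   design$sample))
  count_dataset(counts, design)
}

# normalized_dataset wrapper around an explicit genes x samples matrix
as_norm <- function(logcpm, design) {
  structure(list(gene_ids = rownames(logcpm), sample_ids = colnames(logcpm),
                 factors = setNames(rep(1, ncol(logcpm)), colnames(logcpm)),
                 eff_libsize = setNames(rep(1e6, ncol(logcpm)), colnames(logcpm)),
                 logcpm = logcpm, design = design),
            class = "normalized_dataset")
}

# score-space geometry with between-centroid distance D = 1 and mean
# within-group disparity d = 0.5 for every group (the half-disparity worked
# configuration): E samples at (0, +-0.5), L samples at (1, +-0.5)
half_disparity_norm <- function() {
  design <- make_design(n_lines = 4, tissues = "abdomen", sexes = "F")
  coords <- rbind(cbind(0, c(0.5, -0.5, 0.5, -0.5)),   # E1..E4
                  cbind(1, c(0.5, -0.5, 0.5, -0.5)))   # L1..L4
  logcpm <- t(coords)
  rownames(logcpm) <- c("gA", "gB")
  colnames(logcpm) <- design$sample
  as_norm(logcpm, design)
}

# minimal de_result-like table from a named call vector
fake_de <- function(genes, called, direction = "up") {
  data.frame(gene = genes,
             call = ifelse(genes %in% called, direction, "ns"),
             stringsAsFactors = FALSE)
}

trunc2 <- function(x) floor(x * 100) / 100
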