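#' Count dataset bound to an experimental-evolution sample design
#'
#' A `count_dataset` couples a genes x samples matrix of non-negative integer
#' read counts to a per-sample design with the four factors of the study
#' layout: selection regime (E = early reproduction, L = late reproduction),
#' replicate line (1..4 within regime), sex (F/M) and tissue pool
#' (abdomen = reproductive, head_thorax = somatic).
#'
#' @param counts integer matrix, genes in rows, samples in columns; must have
#'   row and column names (gene ids / sample ids).
#' @param design data.frame with columns `sample`, `regime`, `line`, `sex`,
#'   `tissue`; one row per sample. Factor levels are canonicalized
#'   case-insensitively to E/L, F/M, abdomen/head_thorax.
#' @return object of class `count_dataset`: list with elements `counts`
#'   (numeric matrix of whole numbers), `design` (data.frame, row order
#'   matching the count columns).
#' @export
count_dataset <- function(counts, design) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids")
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count at gene '%s', sample '%s': must be a non-negative integer",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  design <- validate_design(design, colnames(counts))
  structure(list(counts = counts, design = design), class = "count_dataset")
}

canon_factor <- function(x, levels, what) {
  m <- match(tolower(as.character(x)), tolower(levels))
  if (anyNA(m))
    stop(sprintf("unknown %s level(s): %s", what,
                 paste(unique(as.character(x)[is.na(m)]), collapse = ", ")))
  factor(levels[m], levels = levels)
}

validate_design <- function(design, sample_ids) {
  need <- c("sample", "regime", "line", "sex", "tissue")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0)
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  design <- as.data.frame(design)[, need]
  design$sample <- as.character(design$sample)
  extra <- setdiff(design$sample, sample_ids)
  if (length(extra) > 0)
    stop("design has sample(s) absent from counts: ", paste(extra, collapse = ", "))
  absent <- setdiff(sample_ids, design$sample)
  if (length(absent) > 0)
    stop("counts have sample(s) absent from design: ", paste(absent, collapse = ", "))
  design <- design[match(sample_ids, design$sample), , drop = FALSE]
  design$regime <- canon_factor(design$regime, c("E", "L"), "regime")
  design$sex    <- canon_factor(design$sex, c("F", "M"), "sex")
  design$tissue <- canon_factor(design$tissue, c("abdomen", "head_thorax"), "tissue")
  line <- suppressWarnings(as.integer(as.character(design$line)))
  if (anyNA(line) || any(line < 1))
    stop("unknown line level(s): ",
         paste(unique(design$line[is.na(line) | line < 1]), collapse = ", "))
  design$line <- line
  key <- interaction(design$regime, design$line, design$sex, design$tissue, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated (regime, line, sex, tissue) combination in design: ",
         as.character(key[duplicated(key)][1]))
  if (anyNA(design))
    stop("design contains missing values")
  rownames(design) <- NULL
  design
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(regime = x$design$regime, sex = x$design$sex, tissue = x$design$tissue))
  invisible(x)
}

#' Subset a count dataset by gene and/or sample
#'
#' @param dataset a `count_dataset`.
#' @param genes character or logical/integer index over genes (optional).
#' @param samples character or logical/integer index over samples (optional).
#' @return a `count_dataset` restricted to the selection.
#' @export
subset_dataset <- function(dataset, genes = NULL, samples = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  counts <- dataset$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  design <- dataset$design[match(colnames(counts), dataset$design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "count_dataset")
}

read_tsv_checked <- function(path, what, colClasses = NA) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  nf <- tryCatch(utils::count.fields(path, sep = "\t", quote = "", comment.char = ""),
                 error = function(e) stop(sprintf("cannot parse %s '%s': %s", what, path,
                                                  conditionMessage(e))))
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0) stop(sprintf("%s file '%s' is empty", what, path))
  if (length(unique(nf)) != 1)
    stop(sprintf("malformed TSV '%s': line %d has %d fields, expected %d",
                 path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    colClasses = colClasses, stringsAsFactors = FALSE)
}

#' Read a counts TSV plus a design TSV into a validated count dataset
#'
#' The counts file is tab-separated with a header row of sample ids and gene
#' ids in the first column (genes in rows, samples in columns). The design
#' file is tab-separated with columns sample, regime, line, sex, tissue.
#'
#' @param path counts TSV path.
#' @param design_path design TSV path.
#' @return a validated [count_dataset()].
#' @export
read_counts <- function(path, design_path) {
  tab <- read_tsv_checked(path, "counts")
  if (ncol(tab) < 2) stop("counts TSV needs a gene-id column plus >= 1 sample column")
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  rownames(mat) <- genes
  # design columns stay character: "F" must not type-convert to logical
  design <- read_tsv_checked(design_path, "design", colClasses = "character")
  count_dataset(mat, design)
}

#' Write a tabular result as TSV
#'
#' Writes a header plus rows; numeric columns are rendered with 15 significant
#' digits so a re-read reproduces values to float round-trip precision.
#'
#' @param rows non-empty data.frame (or coercible) with consistent columns.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  if (is.null(rows)) stop("rows must be a non-empty table")
  if (is.list(rows) && !is.data.frame(rows)) {
    len <- vapply(rows, length, integer(1))
    if (length(len) == 0 || length(unique(len)) != 1)
      stop("columns have inconsistent lengths")
    rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  }
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0 || ncol(rows) == 0) stop("refusing to write an empty table")
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write table to '", path, "': ", conditionMessage(e)))
  invisible(ok)
}

#' Read a GMT gene-set file
#'
#' Tab-separated; each line is term id, description, then member gene ids.
#' Members are de-duplicated per term.
#'
#' @param path GMT path.
#' @return object of class `gene_set_map`: named list of unique gene-id
#'   vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields", i))
    sets[[f[1]]] <- unique(f[-(1:2)])
    descs[f[1]] <- f[2]
  }
  structure(sets, descriptions = descs, class = "gene_set_map")
}

#' Read a 12-column tabular homology-search hit table
#'
#' Standard tabular format: query, subject, percent identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, e-value,
#' bit score. Row order is preserved; an empty file yields an empty table.
#'
#' @param path hits path.
#' @return data.frame of class `homology_hits`.
#' @export
read_homology_hits <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path)
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "e_value", "bit_score")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 2), cols[1:2]))
    for (nm in cols[3:12]) out[[nm]] <- numeric(0)
    class(out) <- c("homology_hits", "data.frame")
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 12))
    stop(sprintf("homology hits parse error at line %d: %d columns, expected 12",
                 which(nf != 12)[1], nf[nf != 12][1]))
  m <- do.call(rbind, f)
  out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop(sprintf("homology hits parse error: non-numeric value '%s' in column %d",
                   m[which(is.na(v))[1], j], j))
    out[[cols[j]]] <- v
  }
  if (any(out$e_value < 0)) stop("negative e-value in homology hits")
  if (any(!is.finite(out$bit_score))) stop("non-finite bit score in homology hits")
  class(out) <- c("homology_hits", "data.frame")
  out
}

#' Write a count dataset as a counts TSV plus a design TSV
#'
#' @param dataset a `count_dataset`.
#' @param path counts TSV path.
#' @param design_path design TSV path.
#' @export
write_counts <- function(dataset, path, design_path) {
  stopifnot(inherits(dataset, "count_dataset"))
  tab <- data.frame(gene_id = rownames(dataset$counts), dataset$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(TRUE)
}
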