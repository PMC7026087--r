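#' Write a table as TSV
#'
#' @param x data.frame or matrix.
#' @param path Output path.
#' @param rownames_as Optional column name under which to store rownames
#'   (used for gene x sample matrices).
#' @export
write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(setNames(list(rownames(x)), rownames_as),
                    as.data.frame(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count matrix as TSV (gene_id + one column per sample)
#' @param counts Gene x sample matrix.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  write_tsv(counts, path, rownames_as = "gene_id")
}

#' Read a count matrix written by [write_counts_tsv()]
#' @param path TSV path.
#' @return Integer gene x sample matrix.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read a sample design table
#' @param path TSV path with columns sample_id, genotype, gonadal_sex,
#'   genetic_sex, stress, region.
#' @return data.frame.
#' @export
read_design_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "genotype", "gonadal_sex", "genetic_sex",
              "stress", "region")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop("design is missing column(s): ", paste(missing, collapse = ", "))
  }
  d
}

#' Write a count matrix in sparse MatrixMarket triplet format
#'
#' @param counts Gene x sample matrix.
#' @param path Output `.mtx` path; gene and sample names are written
#'   alongside as `<path>.genes` / `<path>.samples`.
#' @export
write_counts_mtx <- function(counts, path) {
  nz <- which(counts != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(counts), ncol(counts), nrow(nz)), con)
  writeLines(sprintf("%d %d %d", nz[, 1], nz[, 2], counts[nz]), con)
  writeLines(rownames(counts), paste0(path, ".genes"))
  writeLines(colnames(counts), paste0(path, ".samples"))
  invisible(path)
}

#' Write the simulation ground truth as plain-text sidecars
#'
#' @param truth A `sim_truth` object.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_truth_sidecar <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  paths <- character(0)
  att <- data.frame(gene = names(truth$attribution),
                    attribution = unname(truth$attribution),
                    stringsAsFactors = FALSE)
  p <- file.path(dir, "truth_attribution.tsv"); write_tsv(att, p)
  paths <- c(paths, p)
  mod <- truth$module_assignment
  moddf <- data.frame(gene = names(mod), module = unname(mod),
                      stringsAsFactors = FALSE)
  moddf <- moddf[!is.na(moddf$module), ]
  p <- file.path(dir, "truth_modules.tsv"); write_tsv(moddf, p)
  paths <- c(paths, p)
  sdf <- do.call(rbind, lapply(names(truth$stress_de), function(k) {
    cbind(contrast = k, truth$stress_de[[k]])
  }))
  if (is.null(sdf)) {
    sdf <- data.frame(contrast = character(), gene = character(),
                      effect = numeric())
  }
  p <- file.path(dir, "truth_stress_effects.tsv"); write_tsv(sdf, p)
  invisible(c(paths, p))
}
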