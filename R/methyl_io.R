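#' Construct a methylation beta-value matrix
#'
#' A \code{methyl_matrix} is a numeric samples x sites matrix of methylation
#' fractions (beta values). Row names are sample identifiers, column names are
#' CpG site identifiers (e.g. \code{"cg16732616"}). All non-missing values
#' must lie in \[0, 1\]; missing values are \code{NA}, never zero.
#'
#' @param betas numeric matrix, samples in rows, CpG sites in columns, with
#'   unique row and column names.
#' @return A validated \code{methyl_matrix}.
#' @export
methyl_matrix <- function(betas) {
  if (!is.matrix(betas) || !is.numeric(betas))
    stop("betas must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(betas)) || is.null(colnames(betas)))
    stop("betas must have sample row names and site column names",
         call. = FALSE)
  validate_methyl_matrix(structure(betas, class = c("methyl_matrix", "matrix")))
}

#' @rdname methyl_matrix
#' @param x object to validate.
#' @export
validate_methyl_matrix <- function(x) {
  sids <- rownames(x)
  cids <- colnames(x)
  if (anyDuplicated(sids))
    stop("duplicate sample id: ", sids[duplicated(sids)][1L], call. = FALSE)
  if (anyDuplicated(cids))
    stop("duplicate site id: ", cids[duplicated(cids)][1L], call. = FALSE)
  bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "beta value out of [0,1]: sample '%s', site '%s', value %g",
      sids[i], cids[j], x[i, j]), call. = FALSE)
  }
  x
}

#' @export
`[.methyl_matrix` <- function(x, i, j, ..., drop = FALSE) {
  y <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(y)) class(y) <- c("methyl_matrix", "matrix")
  y
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("methyl_matrix: %d samples x %d CpG sites (%d missing values)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Read a beta-value matrix from delimited text
#'
#' The default layout is samples in rows and sites in columns (first header
#' row holds site ids, first column sample ids). GEO series-matrix exports
#' are usually the transpose; pass \code{orientation = "sites_by_samples"}
#' to transpose on load. Empty cells and \code{"NA"} are treated as missing.
#'
#' @param path file path.
#' @param sep field delimiter, \code{"\t"} (default) or \code{","}.
#' @param orientation \code{"samples_by_sites"} (default) or
#'   \code{"sites_by_samples"}.
#' @return A \code{\link{methyl_matrix}}.
#' @examples
#' f <- system.file("extdata", "synthetic_demo_betas.tsv",
#'                  package = "methyldx")
#' m <- read_beta_matrix(f)
#' m
#' @export
read_beta_matrix <- function(path, sep = "\t",
                             orientation = c("samples_by_sites",
                                             "sites_by_samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          na.strings = c("NA", ""), check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("malformed header in ", path,
         ": expected an id column plus at least one data column (line 1)",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  dat <- df[, -1L, drop = FALSE]
  notnum <- which(!vapply(dat, is.numeric, logical(1)))
  if (length(notnum) > 0) {
    col <- names(dat)[notnum[1L]]
    val <- dat[[notnum[1L]]]
    row <- which(is.na(suppressWarnings(as.numeric(val))) & !is.na(val))[1L]
    stop(sprintf("non-numeric beta value in column '%s' (data line %d)",
                 col, if (is.na(row)) 1L else row), call. = FALSE)
  }
  m <- as.matrix(dat)
  rownames(m) <- ids
  if (orientation == "sites_by_samples") m <- t(m)
  methyl_matrix(m)
}

#' Write a beta-value matrix to delimited text
#'
#' Inverse of \code{\link{read_beta_matrix}} (samples-by-sites layout):
#' reading the written file reproduces the matrix to at least 10 significant
#' digits. Missing values are written as \code{NA}.
#'
#' @param x a \code{methyl_matrix}.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_beta_matrix <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "methyl_matrix"))
  df <- data.frame(sample_id = rownames(x),
                   format(unclass(x), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a sample metadata table
#'
#' The file must carry columns \code{sample_id}, \code{tissue} and
#' \code{status} (plus an optional \code{dataset_id}). Status may be coded
#' \code{0}/\code{1} or \code{"healthy"}/\code{"disease"} (case-insensitive)
#' and is normalised to integer 0 = healthy, 1 = disease.
#'
#' @param path file path.
#' @param tissue_vocabulary allowed tissue labels; defaults to the six
#'   tissues of the multi-tissue cohort design.
#' @param sep field delimiter.
#' @return data.frame with columns sample_id, tissue, status (and dataset_id
#'   when present), one row per sample.
#' @export
read_sample_metadata <- function(path, tissue_vocabulary = default_tissues(),
                                 sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "tissue", "status")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$tissue <- as.character(df$tissue)
  sample_metadata(df, tissue_vocabulary = tissue_vocabulary)
}

#' Validate a sample metadata data.frame
#'
#' @param df data.frame with sample_id, tissue, status columns.
#' @param tissue_vocabulary allowed tissue labels.
#' @return the normalised data.frame.
#' @export
sample_metadata <- function(df, tissue_vocabulary = default_tissues()) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1L], call. = FALSE)
  unknown <- setdiff(unique(df$tissue), tissue_vocabulary)
  if (length(unknown) > 0)
    stop("unknown tissue label: ", unknown[1L],
         " (vocabulary: ", paste(tissue_vocabulary, collapse = ", "), ")",
         call. = FALSE)
  df$status <- normalize_status(df$status)
  rownames(df) <- NULL
  df
}

normalize_status <- function(status) {
  s <- tolower(trimws(as.character(status)))
  out <- ifelse(s %in% c("0", "healthy", "control", "normal"), 0L,
                ifelse(s %in% c("1", "disease", "case"), 1L, NA_integer_))
  if (anyNA(out))
    stop("uninterpretable status value: ", status[is.na(out)][1L],
         call. = FALSE)
  out
}

#' Default tissue vocabulary
#'
#' The six tissues of the multi-tissue disease-diagnosis design: brain,
#' saliva, whole_blood, kidney, lung, breast.
#' @return character vector of labels.
#' @export
default_tissues <- function() {
  c("brain", "saliva", "whole_blood", "kidney", "lung", "breast")
}

#' Write a result table to delimited text
#'
#' Writes any data.frame of pipeline results (chi-square screen tables,
#' disease-site rankings, per-site summaries, ...) with a header row and a
#' deterministic column order, so that \code{\link{read_result_table}}
#' reproduces the records.
#'
#' @param rows data.frame of result records.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_result_table <- function(rows, path, sep = "\t") {
  stopifnot(is.data.frame(rows))
  out <- rows
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), NA, format(v, digits = 15, trim = TRUE, scientific = FALSE)))
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write result table to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}

#' Read an optional CpG-to-gene lookup table
#'
#' Two-column delimited file (cpg_id, gene). Passed through into summary
#' outputs; no annotation is computed.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return named character vector, names = CpG ids.
#' @export
read_gene_lookup <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("gene lookup needs two columns", call. = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
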