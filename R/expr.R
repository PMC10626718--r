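#' Construct a validated expression matrix
#'
#' The container used throughout the package: a numeric genes x samples
#' matrix of abundances with a scale tag recording whether values are raw
#' FPKM or log2-transformed. Row names are gene identifiers, column names
#' sample labels; both must be unique.
#'
#' @param values Numeric matrix with gene row names and sample column names.
#' @param scale_tag `"fpkm"` (raw, non-negative) or `"log2"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `scale_tag`.
#' @examples
#' m <- expression_matrix(matrix(1:12, 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4))))
#' dim(m)
#' @export
expression_matrix <- function(values, scale_tag = c("fpkm", "log2")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop("`values` must carry gene row names and sample column names", call. = FALSE)
  }
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g)) {
    stop("duplicate gene_ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    stop("duplicate sample_ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 genes[bad[1]], samples[bad[2]]), call. = FALSE)
  }
  if (scale_tag == "fpkm" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative FPKM at gene '%s', sample '%s'",
                 genes[bad[1]], samples[bad[2]]), call. = FALSE)
  }
  structure(list(values = values, scale_tag = scale_tag),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of identifiers, in matrix order.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a UTF-8, tab-delimited file whose first row is the sample header
#' (first field `gene_id` or similar) and whose first column holds gene
#' identifiers. Values are parsed as FPKM.
#'
#' @param path Path to the TSV file.
#' @return An [expression_matrix()] with `scale_tag = "fpkm"`, preserving the
#'   file's row and column order.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (ncol(raw) < 2L) stop("expected gene_id column plus >= 1 sample column", call. = FALSE)
  genes <- raw[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicate gene_ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  samples <- colnames(raw)[-1]
  vals <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(genes, samples))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 genes[bad[1]], samples[bad[2]]), call. = FALSE)
  }
  expression_matrix(vals, "fpkm")
}

#' Write an expression matrix to TSV
#'
#' Emits `gene_id` plus one column per sample, values with 6 significant
#' digits.
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene_id = gene_ids(m),
                   apply(m$values, 2, format_sig6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove non-expressed and constitutively expressed genes
#'
#' Applies the two pre-correlation filters on raw FPKM rows: genes with mean
#' FPKM below `min_mean` are treated as non-expressed, and genes with a
#' coefficient of variation (CV = sd/mean, sample standard deviation with
#' denominator n-1) below `min_cv` as constitutively expressed. Removal uses
#' strict inequality, so boundary values are retained.
#'
#' @param m An `ExpressionMatrix` with `scale_tag = "fpkm"`.
#' @param min_mean Mean-FPKM threshold (default 0.1).
#' @param min_cv CV threshold (default 0.5).
#' @return List with elements `matrix` (the filtered `ExpressionMatrix`) and
#'   `removed`, a data frame with columns `gene_id`, `mean_fpkm`, `cv`, and
#'   `reasons` (semicolon-joined among `low_mean`, `low_cv`).
#' @export
filter_expression <- function(m, min_mean = 0.1, min_cv = 0.5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale_tag != "fpkm") {
    stop("filter_expression operates on raw FPKM (scale_tag = 'fpkm')", call. = FALSE)
  }
  if (ncol(m$values) < 2L) {
    stop("CV undefined: at least 2 samples required", call. = FALSE)
  }
  mu <- rowMeans(m$values)
  sdv <- apply(m$values, 1, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  low_mean <- mu < min_mean
  low_cv <- !is.na(cv) & cv < min_cv
  drop <- low_mean | low_cv
  reasons <- character(sum(drop))
  if (any(drop)) {
    reasons <- mapply(function(lm, lc) {
      paste(c(if (lm) "low_mean", if (lc) "low_cv"), collapse = ";")
    }, low_mean[drop], low_cv[drop])
  }
  removed <- data.frame(
    gene_id = gene_ids(m)[drop],
    mean_fpkm = unname(mu[drop]),
    cv = unname(cv[drop]),
    reasons = unname(reasons),
    stringsAsFactors = FALSE
  )
  kept <- m$values[!drop, , drop = FALSE]
  list(matrix = expression_matrix(kept, "fpkm"), removed = removed)
}

#' Write a removal report produced by [filter_expression()]
#' @param report The `removed` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_removal_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' log2-transform an FPKM matrix
#'
#' Maps every value x to log2(x + 1). The pseudocount keeps zero-FPKM cells
#' finite (0 maps to 0) so they can enter correlations. Guards against double
#' transformation via the scale tag.
#'
#' @param m An `ExpressionMatrix` with `scale_tag = "fpkm"`.
#' @return An `ExpressionMatrix` with `scale_tag = "log2"`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale_tag == "log2") {
    stop("matrix is already log2-transformed", call. = FALSE)
  }
  expression_matrix(log2(m$values + 1), "log2")
}

#' Average replicate columns into one column per tissue/condition
#'
#' @param m An `ExpressionMatrix`.
#' @param groups Named character vector mapping every sample id to its group
#'   label.
#' @return An `ExpressionMatrix` with one column per group (arithmetic mean of
#'   member columns), groups ordered by first appearance in `m`.
#' @export
average_replicates <- function(m, groups) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  samples <- sample_ids(m)
  missing <- setdiff(samples, names(groups))
  if (length(missing)) {
    stop("samples not assigned to a group: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- as.character(groups[samples])
  levels <- unique(g)
  out <- vapply(levels, function(lv) {
    rowMeans(m$values[, g == lv, drop = FALSE])
  }, numeric(nrow(m$values)))
  out <- matrix(out, nrow = nrow(m$values),
                dimnames = list(gene_ids(m), levels))
  expression_matrix(out, m$scale_tag)
}
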