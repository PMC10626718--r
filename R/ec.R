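#' Pearson correlation matrix between gene expression profiles
#'
#' Rows are genes (ortholog-pair members in one species), columns profiled
#' conditions. The result is the n x n matrix of Pearson correlation
#' coefficients between gene profiles within that species.
#'
#' @param x Numeric matrix, genes x conditions, >= 3 conditions.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix", call. = FALSE)
  if (ncol(x) < 3L) stop("need at least 3 conditions", call. = FALSE)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance gene profiles (drop upstream): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(t(x))
  diag(R) <- 1
  R
}

#' Initial expression-conservation scores
#'
#' EC_0(i) is the Pearson correlation between row i of the species-A
#' correlation matrix and row i of the species-B correlation matrix,
#' computed over the n-1 off-diagonal positions (the self entry, identically
#' 1 in both, is excluded so it cannot inflate the score). It measures how
#' similarly ortholog pair i correlates with all other pairs in the two
#' species.
#'
#' @param Ra,Rb n x n correlation matrices (same pair ordering), n >= 4.
#' @return Numeric vector of EC_0 values in `[-1, 1]`; NA where a row is
#'   degenerate (zero variance across off-diagonal entries).
#' @export
ec_initial <- function(Ra, Rb) {
  check_ec_inputs(Ra, Rb)
  n <- nrow(Ra)
  vapply(seq_len(n), function(i) {
    x <- Ra[i, -i]
    y <- Rb[i, -i]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    snap_unit(stats::cor(x, y))
  }, numeric(1))
}

check_ec_inputs <- function(Ra, Rb) {
  if (!is.matrix(Ra) || !is.matrix(Rb)) stop("correlation matrices required", call. = FALSE)
  if (!all(dim(Ra) == dim(Rb))) stop("Ra and Rb must have identical dimensions", call. = FALSE)
  if (nrow(Ra) != ncol(Ra)) stop("correlation matrices must be square", call. = FALSE)
  if (nrow(Ra) < 4L) stop("need at least 4 ortholog pairs", call. = FALSE)
  invisible(TRUE)
}

#' Weighted Pearson correlation
#'
#' Computes the weighted correlation
#' `sum(w (x - xbar)(y - ybar)) / (sqrt(sum(w (x - xbar)^2)) * sqrt(sum(w (y - ybar)^2)))`
#' with weighted means `xbar = sum(w x)/sum(w)` (likewise `ybar`). The
#' symmetric denominator is the only form bounded in `[-1, 1]`, and the
#' weighted means make the statistic invariant to positive affine transforms
#' of either argument.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param w Non-negative weights; at least 3 must be strictly positive.
#' @return Weighted correlation in `[-1, 1]`.
#' @export
weighted_pcc <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w)) {
    stop("x, y, w must have equal lengths", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(w > 0) < 3L) stop("insufficient support: fewer than 3 positive weights", call. = FALSE)
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  num <- sum(w * (x - xbar) * (y - ybar))
  den <- sqrt(sum(w * (x - xbar)^2)) * sqrt(sum(w * (y - ybar)^2))
  if (den == 0) {
    stop("degenerate input: zero weighted variance", call. = FALSE)
  }
  snap_unit(num / den)
}

# clamp to [-1, 1] and absorb sub-1e-12 rounding at the boundaries, so that
# exactly collinear inputs report exactly +/-1
snap_unit <- function(r) {
  r <- min(1, max(-1, r))
  if (abs(r) >= 1 - 1e-12) r <- sign(r)
  r
}

#' Iterative expression-conservation estimate
#'
#' Starting from [ec_initial()], each iteration recomputes every pair's EC as
#' a weighted Pearson correlation of the two matrix rows, restricted to the
#' positions g' of pairs whose previous EC was strictly positive and
#' weighted by those previous EC values. Pairs with non-positive previous EC
#' are excluded as weights only: their own EC is still recomputed every
#' iteration. Iteration stops when the summed squared change
#' `sum_i (EC_k(i) - EC_(k-1)(i))^2` drops below `tolerance`, or at
#' `max_iter`.
#'
#' Pairs with undefined EC_0 (degenerate rows) are dropped from the pair set
#' with a warning before iteration begins.
#'
#' @inheritParams ec_initial
#' @param tolerance Convergence threshold on the summed squared EC change
#'   (default 0.1).
#' @param max_iter Iteration cap (default 100); hitting it leaves
#'   `converged = FALSE`.
#' @return An `ECResult`: list with `ec` (final scores, named by rownames of
#'   `Ra` if present), `ec_initial`, `trace` (iterations x pairs matrix,
#'   first row EC_0), `delta_history`, `converged`, `n_iterations`, and
#'   `dropped` (pair names/indices removed for degeneracy).
#' @export
ec_iterate <- function(Ra, Rb, tolerance = 0.1, max_iter = 100L) {
  check_ec_inputs(Ra, Rb)
  ids <- rownames(Ra)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Ra)))
  ec0_full <- ec_initial(Ra, Rb)
  bad <- is.na(ec0_full)
  dropped <- ids[bad]
  if (any(bad)) {
    warning("dropping ", sum(bad), " pair(s) with undefined EC_0: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    keep <- which(!bad)
    if (length(keep) < 4L) stop("fewer than 4 pairs remain after dropping degenerate rows",
                                call. = FALSE)
    Ra <- Ra[keep, keep, drop = FALSE]
    Rb <- Rb[keep, keep, drop = FALSE]
    ids <- ids[keep]
    ec0 <- ec0_full[keep]
  } else {
    ec0 <- ec0_full
  }
  n <- length(ec0)
  trace <- list(ec0)
  delta_history <- numeric(0)
  ec_prev <- ec0
  converged <- FALSE
  k <- 0L
  while (k < max_iter) {
    k <- k + 1L
    pos <- which(ec_prev > 0)
    ec_k <- vapply(seq_len(n), function(i) {
      idx <- setdiff(pos, i)
      if (length(idx) < 3L) {
        stop("weight support collapsed at iteration ", k,
             " (fewer than 3 positively weighted pairs)", call. = FALSE)
      }
      weighted_pcc(Ra[i, idx], Rb[i, idx], ec_prev[idx])
    }, numeric(1))
    delta <- sum((ec_k - ec_prev)^2)
    trace[[k + 1L]] <- ec_k
    delta_history <- c(delta_history, delta)
    ec_prev <- ec_k
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  trace <- do.call(rbind, trace)
  rownames(trace) <- paste0("iter", seq_len(nrow(trace)) - 1L)
  colnames(trace) <- ids
  structure(list(
    ec = stats::setNames(ec_prev, ids),
    ec_initial = stats::setNames(ec0, ids),
    trace = trace,
    delta_history = delta_history,
    converged = converged,
    n_iterations = k,
    dropped = dropped,
    tolerance = tolerance
  ), class = "ECResult")
}

#' @export
print.ECResult <- function(x, ...) {
  cat(sprintf("ECResult: %d pairs, %d iteration(s), %s (median EC %.3f)\n",
              length(x$ec), x$n_iterations,
              if (x$converged) "converged" else "not converged",
              stats::median(x$ec)))
  invisible(x)
}

#' Compare two EC distributions with the Mann-Whitney U test
#'
#' Two-sided test using the normal approximation with tie correction, as
#' implemented by [stats::wilcox.test()]. The reported U is the number of
#' (ec1, ec2) pairs where ec1 ranks higher.
#'
#' @param ec1,ec2 Non-empty numeric EC vectors.
#' @return List with `u`, `p_value`, `median1`, `median2`, `n1`, `n2`.
#' @export
compare_ec_distributions <- function(ec1, ec2) {
  ec1 <- ec1[is.finite(ec1)]
  ec2 <- ec2[is.finite(ec2)]
  if (!length(ec1) || !length(ec2)) stop("both EC vectors must be non-empty", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(ec1, ec2, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)
  )
  list(u = unname(wt$statistic), p_value = wt$p.value,
       median1 = stats::median(ec1), median2 = stats::median(ec2),
       n1 = length(ec1), n2 = length(ec2))
}

#' Placement of a gene subset in the genome-wide EC distribution
#'
#' Fraction of the subset's EC values at or above the empirical q-quantile
#' (nearest-rank) of the genome-wide EC distribution — e.g. how many focal
#' ortholog pairs fall in the genome-wide top 5% when `q = 0.95`.
#'
#' @param genome_ec Genome-wide EC values (>= 20 required).
#' @param subset_ec EC values of the gene subset (non-empty).
#' @param q Quantile level (default 0.95).
#' @return Fraction in `[0, 1]`.
#' @export
ec_quantile_placement <- function(genome_ec, subset_ec, q = 0.95) {
  genome_ec <- genome_ec[is.finite(genome_ec)]
  if (length(genome_ec) < 20L) stop("genome-wide EC vector must have >= 20 values", call. = FALSE)
  if (!length(subset_ec)) stop("empty subset", call. = FALSE)
  srt <- sort(genome_ec)
  idx <- max(1L, ceiling(q * length(srt)))
  threshold <- srt[idx]
  mean(subset_ec >= threshold)
}

#' Write an EC report to TSV
#'
#' One row per ortholog pair: gene ids, final and initial EC, iteration count
#' and convergence flag.
#'
#' @param result An `ECResult`.
#' @param pairs `OrthologPairSet` data frame aligned with the EC result rows
#'   (columns `gene_a`, `gene_b`); optional.
#' @param path Output path.
#' @return The report data frame, invisibly.
#' @export
write_ec_report <- function(result, pairs = NULL, path) {
  stopifnot(inherits(result, "ECResult"))
  ids <- names(result$ec)
  if (is.null(pairs)) {
    df <- data.frame(pair = ids, stringsAsFactors = FALSE)
  } else {
    idx <- match(ids, paste(pairs$gene_a, pairs$gene_b, sep = "|"))
    if (any(is.na(idx))) idx <- seq_along(ids)
    df <- data.frame(gene_a = pairs$gene_a[idx], gene_b = pairs$gene_b[idx],
                     stringsAsFactors = FALSE)
  }
  df$ec_final <- unname(result$ec)
  df$ec_initial <- unname(result$ec_initial)
  df$n_iterations <- result$n_iterations
  df$converged <- result$converged
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
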