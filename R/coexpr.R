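#' Two-sided p-value for a Spearman correlation
#'
#' Default is the t approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2
#' degrees of freedom; `|rho| = 1` gives p = 0. An exact permutation option
#' (full enumeration of rank permutations) is available for n <= 9, where
#' enumeration is tractable.
#'
#' @param rho Spearman correlation(s).
#' @param n Number of samples the correlation was computed over.
#' @param method `"t"` (default) or `"exact"`.
#' @return p-value(s) in `[0, 1]`; NA propagates.
#' @export
spearman_pvalue <- function(rho, n, method = c("t", "exact")) {
  method <- match.arg(method)
  if (n < 4L) stop("need at least 4 samples for a p-value", call. = FALSE)
  if (method == "t") {
    p <- rep(NA_real_, length(rho))
    ok <- is.finite(rho)
    r <- pmin(pmax(rho[ok], -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    p[ok] <- ifelse(abs(r) >= 1, 0,
                    2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE))
    return(p)
  }
  if (n > 9L) stop("exact permutation p-value supported for n <= 9 only", call. = FALSE)
  vapply(rho, function(r) {
    if (!is.finite(r)) return(NA_real_)
    perms <- permutations_of(seq_len(n))
    base <- seq_len(n)
    rho_null <- apply(perms, 1, function(p) stats::cor(base, p))
    mean(abs(rho_null) >= abs(r) - 1e-12)
  }, numeric(1))
}

# All permutations of a vector, one per row. Only used for small n.
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(x[i], permutations_of(x[-i]))
  }))
}

#' Spearman correlation of query genes against all other genes
#'
#' Rank-transforms each gene's profile (average ranks on ties) and computes
#' Pearson correlations of the ranks, which equals Spearman's rho. Partners
#' with zero variance get `rho = NA` and are excluded from edge calling and
#' ranking downstream.
#'
#' @param m A log2-scale `ExpressionMatrix` with >= 4 samples.
#' @param queries Character vector of query gene ids (must be in `m`).
#' @param p_method p-value method passed to [spearman_pvalue()].
#' @return Data frame with columns `query`, `partner`, `rho`, `pvalue`; one
#'   row per (query, partner != query).
#' @export
spearman_query_vs_all <- function(m, queries, p_method = "t") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale_tag != "log2") {
    stop("correlations are computed on the log2 scale; call log_transform() first",
         call. = FALSE)
  }
  n <- ncol(m$values)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  absent <- setdiff(queries, gene_ids(m))
  if (length(absent)) {
    stop("query genes absent from matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  rk <- t(apply(m$values, 1, rank))
  sds <- apply(rk, 1, stats::sd)
  C <- suppressWarnings(stats::cor(t(rk[queries, , drop = FALSE]), t(rk)))
  C[, sds == 0] <- NA_real_
  C[sds[queries] == 0, ] <- NA_real_
  genes <- gene_ids(m)
  out <- do.call(rbind, lapply(queries, function(q) {
    partners <- setdiff(genes, q)
    data.frame(query = q, partner = partners,
               rho = unname(C[q, partners]),
               stringsAsFactors = FALSE)
  }))
  out$pvalue <- spearman_pvalue(out$rho, n, method = p_method)
  rownames(out) <- NULL
  out
}

#' Call signed coexpression edges from a correlation table
#'
#' Retains pairs with `|rho| > rho_threshold` and `pvalue < p_threshold`
#' (both strict), assigning the edge sign from the sign of rho. Undefined
#' correlations never yield edges.
#'
#' @param corr Output of [spearman_query_vs_all()].
#' @param rho_threshold Correlation magnitude gate (default 0.95).
#' @param p_threshold Significance gate (default 1e-5).
#' @return Edge data frame: `query`, `partner`, `rho`, `pvalue`, `sign`
#'   (`"positive"`/`"negative"`), `mr` (NA until scored), `reliable` (NA).
#' @export
call_edges <- function(corr, rho_threshold = 0.95, p_threshold = 1e-5) {
  keep <- is.finite(corr$rho) & is.finite(corr$pvalue) &
    abs(corr$rho) > rho_threshold & corr$pvalue < p_threshold
  edges <- corr[keep, c("query", "partner", "rho", "pvalue"), drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  edges$mr <- NA_real_
  edges$reliable <- NA
  rownames(edges) <- NULL
  edges
}

#' Rank a query's partners by correlation strength
#'
#' Partners are ordered by descending `|rho|` (or signed rho when
#' `use_abs = FALSE`); rank 1 is the strongest partner and ties receive the
#' fractional average rank. Undefined correlations are excluded before
#' ranking.
#'
#' @param corr Correlation table from [spearman_query_vs_all()].
#' @param query The query gene id.
#' @param use_abs Rank by `|rho|` (default) or signed rho.
#' @return Named numeric vector of ranks, one per scored partner.
#' @export
rank_partners <- function(corr, query, use_abs = TRUE) {
  rows <- corr[corr$query == query & is.finite(corr$rho), , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no scored partners for query '", query, "'", call. = FALSE)
  }
  key <- if (use_abs) abs(rows$rho) else rows$rho
  stats::setNames(rank(-key), rows$partner)
}

#' Mutual rank of a gene pair
#'
#' Geometric mean of the two directed correlation ranks,
#' `MR(ab) = sqrt(Rank(a->b) * Rank(b->a))`. Smaller MR means stronger mutual
#' coexpression; MR >= 1 with equality iff both directed ranks are 1.
#'
#' @param rank_ab,rank_ba Directed ranks (each >= 1); vectorized.
#' @return Numeric MR value(s).
#' @export
mutual_rank <- function(rank_ab, rank_ba) {
  if (any(rank_ab < 1 | rank_ba < 1)) {
    stop("ranks must be >= 1", call. = FALSE)
  }
  sqrt(rank_ab * rank_ba)
}

#' Mutual ranks for every scored (query, partner) pair
#'
#' Computes the full gene-gene Spearman matrix, ranks each gene's partners
#' over the whole gene universe (descending `|rho|`, average ranks on ties,
#' undefined correlations excluded), and returns `Rank(q->p)`, `Rank(p->q)`
#' and their geometric-mean MR for every query-partner pair.
#'
#' @inheritParams spearman_query_vs_all
#' @param use_abs Rank by `|rho|` (default) or signed rho.
#' @return Data frame: `query`, `partner`, `rank_qp`, `rank_pq`, `mr`.
#' @export
mutual_rank_table <- function(m, queries, use_abs = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  absent <- setdiff(queries, gene_ids(m))
  if (length(absent)) {
    stop("query genes absent from matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  rk <- t(apply(m$values, 1, rank))
  sds <- apply(rk, 1, stats::sd)
  scored <- gene_ids(m)[sds > 0]
  C <- suppressWarnings(stats::cor(t(rk[scored, , drop = FALSE])))
  key <- if (use_abs) abs(C) else C
  # rank of every partner from every scored gene's point of view
  rank_from <- matrix(NA_real_, nrow(C), ncol(C), dimnames = dimnames(C))
  for (g in scored) {
    others <- setdiff(scored, g)
    rank_from[g, others] <- rank(-key[g, others])
  }
  out <- do.call(rbind, lapply(intersect(queries, scored), function(q) {
    partners <- setdiff(scored, q)
    data.frame(query = q, partner = partners,
               rank_qp = unname(rank_from[q, partners]),
               rank_pq = unname(rank_from[cbind(partners, q)]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    stop("no scored query genes (all queries have zero variance)", call. = FALSE)
  }
  out$mr <- mutual_rank(out$rank_qp, out$rank_pq)
  rownames(out) <- NULL
  out
}

#' Flag reliable edges by the top-percentile mutual-rank rule
#'
#' An edge is reliable iff its MR is among the `k = ceiling(top_fraction * N)`
#' smallest MR values over the N scored pairs; ties at the cutoff MR are all
#' included.
#'
#' @param edges Edge data frame from [call_edges()].
#' @param all_pairs_mr MR table from [mutual_rank_table()] covering every
#'   scored (query, partner) pair.
#' @param top_fraction Fraction of pairs considered reliable (default 0.01).
#' @return `edges` with `mr` filled in and `reliable` set.
#' @export
apply_mr_reliability <- function(edges, all_pairs_mr, top_fraction = 0.01) {
  if (is.null(all_pairs_mr) || nrow(all_pairs_mr) == 0L) {
    stop("empty MR table", call. = FALSE)
  }
  n_pairs <- nrow(all_pairs_mr)
  k <- ceiling(top_fraction * n_pairs)
  cutoff <- sort(all_pairs_mr$mr, partial = k)[k]
  if (nrow(edges) == 0L) return(edges)
  idx <- match(paste(edges$query, edges$partner, sep = "\r"),
               paste(all_pairs_mr$query, all_pairs_mr$partner, sep = "\r"))
  if (any(is.na(idx))) {
    bad <- edges[is.na(idx), , drop = FALSE]
    stop("edges missing from the MR table: ",
         paste(bad$query, bad$partner, sep = "-", collapse = ", "),
         call. = FALSE)
  }
  edges$mr <- all_pairs_mr$mr[idx]
  edges$reliable <- edges$mr <= cutoff
  edges
}

#' Assemble a query-gene coexpression network
#'
#' Runs correlation, edge calling, mutual-rank scoring and the reliability
#' rule in one call.
#'
#' @inheritParams spearman_query_vs_all
#' @inheritParams call_edges
#' @param mr_top Top MR fraction for [apply_mr_reliability()].
#' @param annotations Optional data frame (`gene_id`, `tf_family`,
#'   `lncrna_flag`) attached as node annotations.
#' @param use_abs Rank MR partners by `|rho|` (default) or signed rho.
#' @return A `CoexpressionNetwork`: list with `edges`, `query_genes`,
#'   `annotations`.
#' @export
build_coexpression_network <- function(m, queries, rho_threshold = 0.95,
                                       p_threshold = 1e-5, mr_top = 0.01,
                                       annotations = NULL, use_abs = TRUE) {
  corr <- spearman_query_vs_all(m, queries)
  edges <- call_edges(corr, rho_threshold, p_threshold)
  mr_tab <- mutual_rank_table(m, queries, use_abs = use_abs)
  edges <- apply_mr_reliability(edges, mr_tab, top_fraction = mr_top)
  coexpression_network(edges, queries, annotations)
}

#' @rdname build_coexpression_network
#' @param edges Edge data frame.
#' @param query_genes The seed gene set.
#' @export
coexpression_network <- function(edges, query_genes, annotations = NULL) {
  stray <- setdiff(unique(edges$query), query_genes)
  if (length(stray)) {
    stop("edges reference non-query genes: ", paste(stray, collapse = ", "),
         call. = FALSE)
  }
  if (any(edges$query == edges$partner)) stop("self-edges not allowed", call. = FALSE)
  structure(list(edges = edges, query_genes = query_genes,
                 annotations = annotations),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf("CoexpressionNetwork: %d queries, %d edges (%d reliable)\n",
              length(x$query_genes), nrow(x$edges),
              sum(x$edges$reliable, na.rm = TRUE)))
  invisible(x)
}

#' Shared coexpression partners between query genes
#'
#' For every unordered pair of query genes, counts partners coexpressed with
#' both; also reports each partner's breadth (how many queries it connects
#' to), distinguishing partners tied to a single query from shared hubs.
#'
#' @param net A `CoexpressionNetwork`.
#' @return List with `query_pairs` (data frame `query1`, `query2`, `shared`)
#'   and `partner_breadth` (data frame `partner`, `n_queries`).
#' @export
shared_partners <- function(net) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  sets <- split(net$edges$partner, net$edges$query)
  qs <- sort(net$query_genes)
  pairs <- if (length(qs) >= 2L) {
    combs <- utils::combn(qs, 2L)
    data.frame(
      query1 = combs[1, ], query2 = combs[2, ],
      shared = apply(combs, 2, function(p) {
        length(intersect(sets[[p[1]]], sets[[p[2]]]))
      }),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(query1 = character(), query2 = character(), shared = integer(),
               stringsAsFactors = FALSE)
  }
  breadth <- as.data.frame(table(partner = unique(net$edges[c("query", "partner")])$partner),
                           stringsAsFactors = FALSE)
  names(breadth) <- c("partner", "n_queries")
  list(query_pairs = pairs, partner_breadth = breadth)
}

#' Cross-species conserved coexpression edges
#'
#' Maps species-A network edges through an ortholog pairing and returns those
#' whose mapped (query, partner) pair is also an edge of the species-B
#' network with the same sign. Genes without an ortholog are unmatched by
#' definition.
#'
#' @param netA,netB `CoexpressionNetwork` objects for the two species.
#' @param pairs `OrthologPairSet` data frame with `gene_a`, `gene_b` columns
#'   mapping species-A ids to species-B ids.
#' @return The subset of `netA$edges` conserved in `netB`.
#' @export
cross_species_network_overlap <- function(netA, netB, pairs) {
  stopifnot(inherits(netA, "CoexpressionNetwork"),
            inherits(netB, "CoexpressionNetwork"))
  map <- stats::setNames(pairs$gene_b, pairs$gene_a)
  ea <- netA$edges
  if (nrow(ea) == 0L || nrow(netB$edges) == 0L) return(ea[0, , drop = FALSE])
  qb <- unname(map[ea$query])
  pb <- unname(map[ea$partner])
  # B edges as an unordered signed pair set
  eb <- netB$edges
  keyset <- c(paste(eb$query, eb$partner, eb$sign, sep = "\r"),
              paste(eb$partner, eb$query, eb$sign, sep = "\r"))
  hit <- !is.na(qb) & !is.na(pb) &
    paste(qb, pb, ea$sign, sep = "\r") %in% keyset
  out <- ea[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a network edge list to TSV
#' @param net A `CoexpressionNetwork`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
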