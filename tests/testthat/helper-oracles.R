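# Independent brute-force oracles. These deliberately avoid the package's
# code paths: correlations go through cor(method = "spearman") pair by pair,
# ranks are computed by counting, and set operations are double loops.

oracle_spearman <- function(values, q, p) {
  stats::cor(values[q, ], values[p, ], method = "spearman")
}

# full MR table for query genes over a log2 matrix, by enumeration
oracle_mr_table <- function(values, queries) {
  genes <- rownames(values)
  sds <- apply(values, 1, stats::sd)
  scored <- genes[sds > 0]
  rho <- matrix(NA_real_, length(scored), length(scored),
                dimnames = list(scored, scored))
  for (a in scored) for (b in scored) {
    rho[a, b] <- stats::cor(values[a, ], values[b, ], method = "spearman")
  }
  rank_dir <- function(from, to) {
    key <- abs(rho[from, setdiff(scored, from)])
    v <- abs(rho[from, to])
    sum(key > v) + (sum(key == v) + 1) / 2
  }
  out <- NULL
  for (q in intersect(queries, scored)) {
    for (p in setdiff(scored, q)) {
      r1 <- rank_dir(q, p)
      r2 <- rank_dir(p, q)
      out <- rbind(out, data.frame(query = q, partner = p,
                                   rank_qp = r1, rank_pq = r2,
                                   mr = sqrt(r1 * r2),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# top-fraction reliability flags by sort-and-count
oracle_top_flags <- function(mr_values, top_fraction) {
  k <- ceiling(top_fraction * length(mr_values))
  cutoff <- sort(mr_values)[k]
  mr_values <= cutoff
}

# weighted Pearson correlation straight from the definition
oracle_wpcc <- function(x, y, w) {
  xbar <- sum(w * x) / sum(w)
  ybar <- sum(w * y) / sum(w)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * (x[i] - xbar) * (y[i] - ybar)
    dx <- dx + w[i] * (x[i] - xbar)^2
    dy <- dy + w[i] * (y[i] - ybar)^2
  }
  num / (sqrt(dx) * sqrt(dy))
}

# reciprocal best hits by double loop over gene universes
oracle_rbh <- function(ab, ba, emax = 1e-5) {
  best_of <- function(hits, q) {
    rows <- hits[hits$query == q & hits$evalue < emax, , drop = FALSE]
    if (nrow(rows) == 0) return(NA_character_)
    rows <- rows[order(rows$evalue, -rows$bitscore, rows$subject), , drop = FALSE]
    rows$subject[1]
  }
  pairs <- NULL
  for (a in unique(ab$query)) {
    b <- best_of(ab, a)
    if (is.na(b)) next
    if (identical(best_of(ba, b), a)) {
      pairs <- rbind(pairs, data.frame(gene_a = a, gene_b = b,
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(pairs)) pairs <- data.frame(gene_a = character(),
                                          gene_b = character(),
                                          stringsAsFactors = FALSE)
  pairs[order(pairs$gene_a), , drop = FALSE]
}

# exact two-sided Mann-Whitney p by enumeration of group assignments
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# area under the ranking (probability a conserved pair outranks a scrambled)
auc_ranking <- function(score, label) {
  r <- rank(score)
  (sum(r[label]) - sum(label) * (sum(label) + 1) / 2) /
    (sum(label) * sum(!label))
}

# small random log2 expression matrix with distinct ranks almost surely
random_log2_matrix <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  structure(list(values = v, scale_tag = "log2"), class = "ExpressionMatrix")
}
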