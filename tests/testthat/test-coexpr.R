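log2_matrix <- function(vals, genes, samples = NULL) {
  m <- matrix(vals, nrow = length(genes), byrow = TRUE)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  structure(list(values = m, scale_tag = "log2"), class = "ExpressionMatrix")
}

test_that("perfect monotone agreement and reversal give rho of +1 and -1", {
  m <- log2_matrix(c(1, 2, 3, 4, 5,
                     2, 4, 6, 8, 10,
                     5, 4, 3, 2, 1), c("q", "up", "down"))
  ct <- spearman_query_vs_all(m, "q")
  expect_equal(ct$rho[ct$partner == "up"], 1)
  expect_equal(ct$rho[ct$partner == "down"], -1)
  expect_equal(ct$pvalue[ct$partner == "up"], 0)
})

test_that("Spearman rho matches a rank-then-Pearson reference to 1e-12", {
  m <- random_log2_matrix(20, 10, seed = 101)
  queries <- gene_ids(m)[1:5]
  ct <- spearman_query_vs_all(m, queries)
  for (i in sample.int(nrow(ct), 25)) {
    expect_equal(ct$rho[i], oracle_spearman(m$values, ct$query[i], ct$partner[i]),
                 tolerance = 1e-12)
  }
})

test_that("rho is invariant under strictly monotone per-gene transforms", {
  m <- random_log2_matrix(10, 8, seed = 77)
  m$values <- m$values - min(m$values) + 0.5  # positive before cubing
  m3 <- m
  m3$values <- m3$values^3
  r1 <- spearman_query_vs_all(m, gene_ids(m)[1])
  r2 <- spearman_query_vs_all(m3, gene_ids(m3)[1])
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
})

test_that("zero-variance partners are excluded from edges and missing queries error", {
  m <- random_log2_matrix(6, 6, seed = 5)
  m$values[3, ] <- 2  # constant profile
  ct <- spearman_query_vs_all(m, gene_ids(m)[1])
  expect_true(is.na(ct$rho[ct$partner == gene_ids(m)[3]]))
  expect_equal(nrow(call_edges(ct, 0, 1)), 4L)  # 5 partners minus the NA one
  expect_error(spearman_query_vs_all(m, "nope"), "absent.*nope")
})

test_that("edge calling applies both strict gates and assigns signs", {
  corr <- data.frame(query = "q", partner = c("a", "b", "c", "d"),
                     rho = c(0.96, -0.96, 0.99, 0.95),
                     pvalue = c(1e-7, 1e-7, 2e-5, 1e-9))
  edges <- call_edges(corr)
  expect_setequal(edges$partner, c("a", "b"))  # c fails p, d fails |rho| > .95
  expect_identical(edges$sign[edges$partner == "a"], "positive")
  expect_identical(edges$sign[edges$partner == "b"], "negative")
})

test_that("partner ranking orders by |rho| with average ranks on ties", {
  corr <- data.frame(query = "q", partner = c("b", "c", "d"),
                     rho = c(-0.9, 0.8, 0.7), pvalue = 0)
  expect_equal(rank_partners(corr, "q"), c(b = 1, c = 2, d = 3))
  corr$rho <- c(0.9, -0.9, 0.7)
  expect_equal(rank_partners(corr, "q"), c(b = 1.5, c = 1.5, d = 3))
  expect_error(rank_partners(corr, "zz"), "no scored partners")
})

test_that("mutual rank is the geometric mean, symmetric, and >= 1", {
  expect_equal(mutual_rank(1, 1), 1)
  expect_equal(mutual_rank(4, 9), 6)
  expect_equal(mutual_rank(2, 3), sqrt(6))
  expect_equal(mutual_rank(5, 2), mutual_rank(2, 5))
  expect_error(mutual_rank(0.5, 2), ">= 1")
  set.seed(1)
  r1 <- sample(1:50, 20); r2 <- sample(1:50, 20)
  expect_true(all(mutual_rank(r1, r2) >= 1))
})

test_that("MR table and reliability flags match the brute-force oracle", {
  m <- random_log2_matrix(15, 8, seed = 303)
  queries <- gene_ids(m)[1:3]
  mine <- mutual_rank_table(m, queries)
  ref <- oracle_mr_table(m$values, queries)
  key <- function(d) d[order(d$query, d$partner), ]
  mine <- key(mine); ref <- key(ref)
  expect_equal(mine$rank_qp, ref$rank_qp)
  expect_equal(mine$rank_pq, ref$rank_pq)
  expect_equal(mine$mr, ref$mr, tolerance = 1e-12)
  ct <- spearman_query_vs_all(m, queries)
  edges <- call_edges(ct, 0.3, 0.5)
  flagged <- apply_mr_reliability(edges, mine, top_fraction = 0.1)
  idx <- match(paste(flagged$query, flagged$partner),
               paste(ref$query, ref$partner))
  expect_identical(flagged$reliable,
                   unname(oracle_top_flags(ref$mr, 0.1)[idx]))
})

test_that("reliability keeps k smallest MRs with cutoff ties included", {
  mr_tab <- data.frame(query = "q", partner = sprintf("p%03d", 1:200),
                       mr = as.numeric(1:200))
  edges <- data.frame(query = "q", partner = c("p001", "p002", "p003"),
                      rho = 0.99, pvalue = 0, sign = "positive",
                      mr = NA_real_, reliable = NA)
  out <- apply_mr_reliability(edges, mr_tab, top_fraction = 0.01)  # k = 2
  expect_identical(out$reliable, c(TRUE, TRUE, FALSE))
  expect_error(apply_mr_reliability(edges, mr_tab[0, ], 0.01), "empty")
  # never adds edges
  expect_equal(nrow(out), nrow(edges))
})

test_that("shared partner counts and breadth follow set intersection", {
  edges <- data.frame(
    query = c("q1", "q1", "q1", "q2", "q2", "q2"),
    partner = c("a", "b", "c", "b", "c", "d"),
    rho = 0.99, pvalue = 0, sign = "positive", mr = 1, reliable = TRUE)
  net <- coexpression_network(edges, c("q1", "q2"))
  sp <- shared_partners(net)
  expect_equal(sp$query_pairs$shared, 2L)
  expect_equal(sp$partner_breadth$n_queries[sp$partner_breadth$partner == "b"], 2L)
  expect_equal(sp$partner_breadth$n_queries[sp$partner_breadth$partner == "a"], 1L)
  # disjoint partner sets share nothing
  edges2 <- edges
  edges2$partner <- c("a", "b", "c", "x", "y", "z")
  expect_equal(shared_partners(coexpression_network(edges2, c("q1", "q2")))$query_pairs$shared, 0L)
})

test_that("same-module queries share more partners than cross-module queries", {
  wins <- 0L
  n_runs <- 25L
  for (s in seq_len(n_runs)) {
    cfg <- simulation_config(n_genes = 60, n_modules = 2, n_conditions_a = 6,
                             replicates_per_condition = 2, noise_sd = 0.15,
                             flat_fraction = 0, neg_loading_prob = 0,
                             n_queries_per_module = 2, seed = 4000 + s)
    sim <- simulate_expression(cfg)
    lg <- log_transform(sim$matrix)
    qs <- sim$truth$query_genes
    net <- build_coexpression_network(lg, qs, rho_threshold = 0.9,
                                      p_threshold = 1e-4)
    sp <- shared_partners(net)$query_pairs
    mod <- sim$truth$module_of_gene
    same <- mod[sp$query1] == mod[sp$query2]
    if (mean(sp$shared[same]) > mean(sp$shared[!same])) wins <- wins + 1L
  }
  expect_gte(wins / n_runs, 0.95)
})

test_that("cross-species overlap maps edges through orthologs and respects sign", {
  edges <- data.frame(query = c("q1", "q1"), partner = c("a", "b"),
                      rho = c(0.99, -0.99), pvalue = 0,
                      sign = c("positive", "negative"), mr = 1, reliable = TRUE)
  netA <- coexpression_network(edges, "q1")
  # identity-like mapping: same topology in B with one sign flipped
  edgesB <- data.frame(query = c("Q1", "Q1"), partner = c("A", "B"),
                       rho = c(0.99, 0.99), pvalue = 0,
                       sign = c("positive", "positive"), mr = 1, reliable = TRUE)
  netB <- coexpression_network(edgesB, "Q1")
  pairs <- data.frame(gene_a = c("q1", "a", "b"), gene_b = c("Q1", "A", "B"))
  ov <- cross_species_network_overlap(netA, netB, pairs)
  expect_identical(ov$partner, "a")  # the sign-flipped edge is not conserved
  # identical networks under the identity mapping are fully conserved
  idp <- data.frame(gene_a = c("q1", "a", "b"), gene_b = c("q1", "a", "b"))
  expect_equal(nrow(cross_species_network_overlap(netA, netA, idp)), 2L)
  # empty partner network yields empty overlap
  empty <- coexpression_network(edges[0, ], character(0))
  expect_equal(nrow(cross_species_network_overlap(netA, empty, pairs)), 0L)
})

test_that("exact permutation p-values agree with the t approximation in rank order", {
  set.seed(9)
  x <- rnorm(6); y <- rnorm(6)
  rho <- cor(x, y, method = "spearman")
  p_exact <- spearman_pvalue(rho, 6, method = "exact")
  expect_gte(p_exact, 0)
  expect_lte(p_exact, 1)
  # perfect correlation is the most extreme achievable: p = 2/6! * ... >= minimum
  p_perfect <- spearman_pvalue(1, 6, method = "exact")
  expect_lt(p_perfect, p_exact + 1e-12)
})
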