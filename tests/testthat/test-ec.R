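rand_corr_pair <- function(n, n_cond, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n_cond), n, n_cond,
              dimnames = list(sprintf("p%03d", 1:n), NULL))
  b <- matrix(rnorm(n * n_cond), n, n_cond, dimnames = dimnames(a))
  list(Ra = correlation_matrix(a), Rb = correlation_matrix(b))
}

# a pair with genuinely shared correlation structure, so EC values are
# mostly positive and the iteration has weight support
related_corr_pair <- function(n, n_cond, seed, noise = 0.4) {
  set.seed(seed)
  base <- matrix(rnorm(n * n_cond), n, n_cond,
                 dimnames = list(sprintf("p%03d", 1:n), NULL))
  a <- base + matrix(rnorm(n * n_cond, sd = noise), n, n_cond)
  b <- base + matrix(rnorm(n * n_cond, sd = noise), n, n_cond)
  list(Ra = correlation_matrix(a), Rb = correlation_matrix(b))
}

test_that("correlation matrix is symmetric with unit diagonal and matches cov-based oracle", {
  set.seed(12)
  x <- matrix(rnorm(60), 10, 6, dimnames = list(sprintf("g%02d", 1:10), NULL))
  R <- correlation_matrix(x)
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 10))
  # independent covariance-based computation
  cx <- x - rowMeans(x)
  ref <- (cx %*% t(cx)) / sqrt(outer(rowSums(cx^2), rowSums(cx^2)))
  diag(ref) <- 1
  expect_equal(R, ref, tolerance = 1e-12, ignore_attr = TRUE)
  # identical and sign-flipped rows
  x2 <- rbind(a = x[1, ], b = x[1, ], c = -x[1, ], d = x[2, ])
  R2 <- correlation_matrix(x2)
  expect_equal(R2["a", "b"], 1)
  expect_equal(R2["a", "c"], -1)
  x[3, ] <- 5
  expect_error(correlation_matrix(x), "zero-variance.*g03")
})

test_that("EC_0 is 1 for identical matrices and -1 for off-diagonal sign flips", {
  cp <- rand_corr_pair(8, 10, seed = 42)
  expect_equal(ec_initial(cp$Ra, cp$Ra), rep(1, 8))
  flipped <- -cp$Ra
  diag(flipped) <- 1
  expect_equal(ec_initial(cp$Ra, flipped), rep(-1, 8))
})

test_that("EC_0 compares off-diagonal row entries only", {
  cp <- rand_corr_pair(6, 8, seed = 43)
  ec <- ec_initial(cp$Ra, cp$Rb)
  ref <- sapply(1:6, function(i) cor(cp$Ra[i, -i], cp$Rb[i, -i]))
  expect_equal(ec, ref, tolerance = 1e-12)
})

test_that("EC_0 of independent random data centres on zero", {
  means <- sapply(1:100, function(s) {
    cp <- rand_corr_pair(50, 12, seed = 9000 + s)
    mean(ec_initial(cp$Ra, cp$Rb))
  })
  expect_lt(abs(mean(means)), 0.05)
})

test_that("weighted PCC reduces to PCC under uniform weights and is affine-invariant", {
  set.seed(33)
  for (s in 1:100) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(weighted_pcc(x, y, rep(1, 12)), cor(x, y), tolerance = 1e-12)
  }
  x <- rnorm(10); w <- runif(10, 0.1, 2)
  expect_equal(weighted_pcc(x, 2 * x + 3, w), 1, tolerance = 1e-12)
  expect_equal(weighted_pcc(x, -0.5 * x + 1, w), -1, tolerance = 1e-12)
})

test_that("weighted PCC matches the from-definition oracle and validates input", {
  set.seed(34)
  for (s in 1:20) {
    x <- rnorm(15); y <- rnorm(15); w <- runif(15)
    expect_equal(weighted_pcc(x, y, w), oracle_wpcc(x, y, w),
                 tolerance = 1e-12)
  }
  expect_error(weighted_pcc(1:5, 1:5, c(1, 1, 0, 0, 0)), "insufficient support")
  expect_error(weighted_pcc(1:5, 1:5, c(-1, 1, 1, 1, 1)), "non-negative")
})

test_that("identical correlation matrices are an immediate EC fixed point", {
  cp <- rand_corr_pair(10, 8, seed = 55)
  res <- ec_iterate(cp$Ra, cp$Ra)
  expect_equal(unname(res$ec), rep(1, 10))
  expect_equal(res$delta_history, 0)
  expect_true(res$converged)
  expect_equal(res$n_iterations, 1L)
})

test_that("one weighted step under uniform positive weights equals EC_0 on the support", {
  cp <- rand_corr_pair(12, 10, seed = 66)
  # manual single iteration with uniform weights over all positions
  ec0 <- ec_initial(cp$Ra, cp$Rb)
  manual <- sapply(1:12, function(i) {
    idx <- setdiff(1:12, i)
    weighted_pcc(cp$Ra[i, idx], cp$Rb[i, idx], rep(1, 11))
  })
  expect_equal(manual, ec0, tolerance = 1e-12)
})

test_that("EC stays within [-1, 1] at every iteration and is permutation-equivariant", {
  cfg <- simulation_config(n_genes = 40, n_conditions_a = 8, n_conditions_b = 8,
                           conserved_fraction = 0.5, seed = 77)
  sp <- simulate_species_pair(cfg)
  Ra <- correlation_matrix(sp$matrix_a)
  Rb <- correlation_matrix(sp$matrix_b)
  res <- ec_iterate(Ra, Rb)
  expect_true(all(res$trace >= -1 & res$trace <= 1))
  set.seed(1)
  perm <- sample(40)
  res_p <- ec_iterate(Ra[perm, perm], Rb[perm, perm])
  expect_equal(res_p$ec, res$ec[perm], tolerance = 1e-10)
  expect_equal(res_p$n_iterations, res$n_iterations)
})

test_that("weights exclude non-positive EC pairs but their own EC is recomputed", {
  cp <- related_corr_pair(10, 8, seed = 88, noise = 1.2)
  ec0 <- ec_initial(cp$Ra, cp$Rb)
  res <- ec_iterate(cp$Ra, cp$Rb, tolerance = 1e-9, max_iter = 1)
  pos <- which(ec0 > 0)
  manual <- sapply(1:10, function(i) {
    idx <- setdiff(pos, i)
    weighted_pcc(cp$Ra[i, idx], cp$Rb[i, idx], ec0[idx])
  })
  expect_equal(unname(res$trace[2, ]), manual, tolerance = 1e-12)
  expect_equal(length(res$trace[2, ]), 10L)  # non-positive pairs still scored
})

test_that("degenerate rows are dropped with a warning before iteration", {
  cp <- related_corr_pair(8, 10, seed = 99)
  Ra <- cp$Ra; Rb <- cp$Rb
  Ra[2, -2] <- 0.5; Ra[-2, 2] <- 0.5  # constant off-diagonal row
  expect_warning(res <- ec_iterate(Ra, Rb), "undefined EC_0.*p002")
  expect_false("p002" %in% names(res$ec))
  expect_equal(length(res$ec), 7L)
})

test_that("iteration sharpens the conserved/scrambled contrast on planted data", {
  grew <- 0L
  for (s in 1:20) {
    cfg <- simulation_config(n_genes = 80, n_conditions_a = 10,
                             n_conditions_b = 10, conserved_fraction = 0.8,
                             noise_sd = 0.25, seed = 300 + s)
    sp <- simulate_species_pair(cfg)
    res <- ec_iterate(correlation_matrix(sp$matrix_a),
                      correlation_matrix(sp$matrix_b))
    cons <- sp$truth$conserved
    expect_gt(mean(res$ec[cons]), mean(res$ec[!cons]))
    gap0 <- mean(res$ec_initial[cons]) - mean(res$ec_initial[!cons])
    gapf <- mean(res$ec[cons]) - mean(res$ec[!cons])
    if (gapf > gap0) grew <- grew + 1L
  }
  expect_gte(grew, 18L)  # ~90% of runs
})

test_that("Mann-Whitney comparison handles identity and complete separation", {
  set.seed(11)
  ec1 <- rnorm(30)
  same <- compare_ec_distributions(ec1, ec1)
  expect_gt(same$p_value, 0.9)
  ec_hi <- runif(20, 2, 3)
  ec_lo <- runif(20, -1, 0)
  sep <- compare_ec_distributions(ec_hi, ec_lo)
  expect_equal(sep$u, 400)
  expect_lt(sep$p_value, 0.01)
})

test_that("Mann-Whitney approximation tracks the exact enumeration at small n", {
  set.seed(13)
  for (s in 1:5) {
    x <- rnorm(7, mean = 0.5)
    y <- rnorm(7)
    approx_p <- compare_ec_distributions(x, y)$p_value
    exact_p <- oracle_mw_exact(x, y)
    expect_lt(abs(approx_p - exact_p), 0.05)
  }
})

test_that("quantile placement fractions behave at the extremes and under resampling", {
  set.seed(17)
  genome <- rnorm(200, 0, 0.1)
  top <- sort(genome, decreasing = TRUE)[1:10]
  expect_equal(ec_quantile_placement(genome, top), 1)
  below <- genome[genome < median(genome)][1:20]
  expect_equal(ec_quantile_placement(genome, below), 0)
  fracs <- replicate(200, ec_quantile_placement(genome, sample(genome, 50)))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
  expect_error(ec_quantile_placement(genome, numeric(0)), "empty subset")
  expect_error(ec_quantile_placement(rnorm(10), 1), ">= 20")
})
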