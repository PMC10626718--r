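#' Simulation configuration
#'
#' Parameters of the latent-factor expression generator. Gene expression on
#' the log2 scale is `baseline + loading * activity(module, condition) +
#' noise`, where module activities are standard-normal per condition;
#' replicate columns share the condition activity and differ only in noise.
#' FPKM is recovered as `2^signal - 1`, floored at 0. A fraction of genes is
#' "flat" (no module loading) to exercise the CV filter, and a small
#' fraction of module loadings is negative so that negative coexpression
#' arises.
#'
#' @param n_genes Number of genes (or ortholog pairs).
#' @param n_modules Number of latent coexpression modules.
#' @param n_conditions_a,n_conditions_b Conditions profiled in species A / B.
#' @param replicates_per_condition Biological replicates per species-A
#'   condition (species B is profiled without replication).
#' @param conserved_fraction Fraction of ortholog pairs whose module
#'   membership (expression program) is conserved between species.
#' @param noise_sd Per-gene log2-scale noise standard deviation.
#' @param loading_scale Magnitude of module loadings on the log2 scale.
#' @param baseline_log2_mean Baseline log2 expression level.
#' @param flat_fraction Fraction of genes without a module loading.
#' @param neg_loading_prob Probability that a gene's loading is negative.
#' @param n_queries_per_module Planted query genes per module.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 200L, n_modules = 4L,
                              n_conditions_a = 5L, n_conditions_b = 6L,
                              replicates_per_condition = 2L,
                              conserved_fraction = 0.5, noise_sd = 0.25,
                              loading_scale = 2, baseline_log2_mean = 3,
                              flat_fraction = 0.1, neg_loading_prob = 0.3,
                              n_queries_per_module = 2L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              n_conditions_a = as.integer(n_conditions_a),
              n_conditions_b = as.integer(n_conditions_b),
              replicates_per_condition = as.integer(replicates_per_condition),
              conserved_fraction = conserved_fraction, noise_sd = noise_sd,
              loading_scale = loading_scale,
              baseline_log2_mean = baseline_log2_mean,
              flat_fraction = flat_fraction,
              neg_loading_prob = neg_loading_prob,
              n_queries_per_module = as.integer(n_queries_per_module),
              seed = as.integer(seed))
  if (cfg$n_modules < 1L || cfg$n_genes < cfg$n_modules) {
    stop("need n_genes >= n_modules >= 1", call. = FALSE)
  }
  if (cfg$conserved_fraction < 0 || cfg$conserved_fraction > 1) {
    stop("conserved_fraction must be in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$loading_scale <= 0) stop("loading_scale must be > 0", call. = FALSE)
  if (cfg$replicates_per_condition < 1L) stop("need >= 1 replicate", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a single-species FPKM expression matrix with planted modules
#'
#' @param cfg A [simulation_config()].
#' @return List with `matrix` (an FPKM `ExpressionMatrix`, conditions x
#'   replicates columns), `groups` (sample -> condition map for
#'   [average_replicates()]), and `truth` (a `SimulationTruth` list:
#'   `module_of_gene` with NA for flat genes, `flat`, `query_genes`,
#'   `config`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    k <- cfg$n_modules
    genes <- sprintf("g%04d", seq_len(n))
    n_flat <- round(cfg$flat_fraction * n)
    flat <- rep(FALSE, n)
    if (n_flat > 0) flat[sample.int(n, n_flat)] <- TRUE
    module <- rep(NA_integer_, n)
    module[!flat] <- rep_len(seq_len(k), sum(!flat))
    loading <- ifelse(flat, 0,
                      cfg$loading_scale *
                        ifelse(stats::runif(n) < cfg$neg_loading_prob, -1, 1))
    conds <- sprintf("cond%02d", seq_len(cfg$n_conditions_a))
    reps <- cfg$replicates_per_condition
    samples <- as.vector(t(outer(conds, seq_len(reps),
                                 function(cn, r) paste0(cn, "_rep", r))))
    groups <- stats::setNames(rep(conds, each = reps), samples)
    activity <- matrix(stats::rnorm(k * length(conds)), nrow = k,
                       dimnames = list(NULL, conds))
    signal <- matrix(cfg$baseline_log2_mean, n, length(samples),
                     dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      act <- ifelse(is.na(module), 0, activity[cbind(module, match(groups[j], conds))])
      act[is.na(act)] <- 0
      signal[, j] <- cfg$baseline_log2_mean + loading * act +
        stats::rnorm(n, sd = cfg$noise_sd)
    }
    fpkm <- pmax(2^signal - 1, 0)
    # planted query genes: the first genes of each module
    query_genes <- unlist(lapply(seq_len(k), function(mm) {
      utils::head(genes[!flat & module == mm], cfg$n_queries_per_module)
    }))
    truth <- structure(list(module_of_gene = stats::setNames(module, genes),
                            flat = stats::setNames(flat, genes),
                            loading = stats::setNames(loading, genes),
                            query_genes = query_genes,
                            config = cfg),
                       class = "SimulationTruth")
    list(matrix = expression_matrix(fpkm, "fpkm"), groups = groups,
         truth = truth)
  })
}

#' Simulate paired two-species expression for ortholog pairs
#'
#' Each gene's log2 profile follows a mixed-membership program: a primary
#' module plus a secondary module with mixing weight drawn uniformly from
#' `[0.2, 0.8]`, scaled to unit variance, and a loading sign (negative =
#' repressed module member, probability `neg_loading_prob`). The mixture
#' gives the within-species correlation structure a continuum of values,
#' and negative loadings extend it over `[-1, 1]` — both needed for the
#' correlation rows that the EC statistic compares to carry gene-level
#' information rather than a handful of module-level values.
#'
#' A `conserved_fraction` of ortholog pairs shares its complete program
#' (primary, secondary, mixing weight, sign) between the species; each
#' remaining ("scrambled") pair is driven in species B by its own private
#' latent program mixed with a random shared module, emulating diverged,
#' gene-specific regulation. Private programs keep the planted labels
#' identifiable: two diverged pairs never share a conserved neighbourhood
#' by construction. Conditions are
#' independently per species — the tissue panels deliberately do not match,
#' which is the situation the EC statistic is designed to handle. Matrices
#' are returned on the log2 scale, ready for [correlation_matrix()].
#'
#' @param cfg A [simulation_config()].
#' @return A `PairedExpression` list: `pairs` (data frame `gene_a`,
#'   `gene_b`), `matrix_a`, `matrix_b` (log2-scale, rows aligned to pairs),
#'   and `truth` (`conserved` logical vector, `module_a`, `module_b`,
#'   `config`).
#' @export
simulate_species_pair <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    k <- cfg$n_modules
    gene_a <- sprintf("A%04d", seq_len(n))
    gene_b <- sprintf("B%04d", seq_len(n))
    draw_secondary <- function(primary) {
      vapply(primary, function(m) {
        if (m <= k && k > 1L) {
          others <- seq_len(k)[-m]
          others[sample.int(k - 1L, 1L)]
        } else sample.int(k, 1L)
      }, integer(1))
    }
    m1_a <- sample(rep_len(seq_len(k), n))
    m2_a <- draw_secondary(m1_a)
    mix_a <- stats::runif(n, 0.2, 0.8)
    sign_a <- ifelse(stats::runif(n) < cfg$neg_loading_prob, -1, 1)
    n_cons <- round(cfg$conserved_fraction * n)
    conserved <- rep(FALSE, n)
    if (n_cons > 0) conserved[sample.int(n, n_cons)] <- TRUE
    # conserved pairs inherit the full program; scrambled pairs get a
    # private primary program (index k + i) so diverged pairs never share
    # planted structure, mixed with a random shared module
    scram <- which(!conserved)
    m1_b <- m1_a; m2_b <- m2_a; mix_b <- mix_a; sign_b <- sign_a
    if (length(scram)) {
      m1_b[scram] <- k + seq_along(scram)
      m2_b[scram] <- sample.int(k, length(scram), replace = TRUE)
      mix_b[scram] <- stats::runif(length(scram), 0.2, 0.8)
      sign_b[scram] <- ifelse(stats::runif(length(scram)) < cfg$neg_loading_prob,
                              -1, 1)
    }
    sim_matrix <- function(m1, m2, mix, sgn, n_cond, reps, prefix) {
      conds <- sprintf("%s_cond%02d", prefix, seq_len(n_cond))
      samples <- as.vector(t(outer(conds, seq_len(reps),
                                   function(cn, r) paste0(cn, "_rep", r))))
      n_prog <- max(c(m1, m2))
      activity <- matrix(stats::rnorm(n_prog * n_cond), nrow = n_prog,
                         dimnames = list(NULL, conds))
      cond_of <- rep(seq_len(n_cond), each = reps)
      sig <- matrix(0, n, length(samples))
      base <- (activity[m1, , drop = FALSE] + mix * activity[m2, , drop = FALSE]) /
        sqrt(1 + mix^2)
      for (j in seq_along(samples)) {
        sig[, j] <- cfg$baseline_log2_mean +
          cfg$loading_scale * sgn * base[, cond_of[j]] +
          stats::rnorm(n, sd = cfg$noise_sd)
      }
      colnames(sig) <- samples
      sig
    }
    ma <- sim_matrix(m1_a, m2_a, mix_a, sign_a, cfg$n_conditions_a,
                     cfg$replicates_per_condition, "A")
    mb <- sim_matrix(m1_b, m2_b, mix_b, sign_b, cfg$n_conditions_b, 1L, "B")
    rownames(ma) <- gene_a
    rownames(mb) <- gene_b
    truth <- structure(list(conserved = stats::setNames(conserved, gene_a),
                            module_a = stats::setNames(m1_a, gene_a),
                            module_b = stats::setNames(
                              ifelse(conserved, m1_b, NA_integer_), gene_b),
                            config = cfg),
                       class = "SimulationTruth")
    structure(list(pairs = data.frame(gene_a = gene_a, gene_b = gene_b,
                                      stringsAsFactors = FALSE),
                   matrix_a = ma, matrix_b = mb, scale_tag = "log2",
                   truth = truth),
              class = "PairedExpression")
  })
}

#' Simulate BLAST hit, orthogroup and domain tables with known truth
#'
#' Builds tabular orthology inputs around the true one-to-one map of a
#' [simulate_species_pair()] truth. True pairs get mutual hits with e-values
#' log-uniform in `[1e-50, 1e-10]`. Decoys, added per gene at `decoy_rate`,
#' are either gate-failing hits (e-value in `[1e-4, 1e-2]`) or passing but
#' sub-best one-directional hits (e-value in `[1e-9, 1e-6]`), so recovery
#' must rely on the e-value gate and reciprocity. A handful of extra decoy
#' gene pairs form reciprocal best hits across *different* orthogroups, so
#' the orthogroup constraint is also load-bearing. A domain table plants the
#' expansin-defining domains (DPBB_1, Expansin_C) on a designated family
#' subset, with some candidates missing the second domain.
#'
#' @param truth `SimulationTruth` from [simulate_species_pair()]; used to
#'   reconstruct the true map when `pairs` is not given.
#' @param pairs Data frame `gene_a`, `gene_b` of the true map; defaults to
#'   the pairing recorded in `truth`.
#' @param decoy_rate Expected decoy hits per true gene (default 0.3).
#' @param seed Integer seed.
#' @return List: `hits_ab`, `hits_ba` (hit tables), `orthogroups` (long
#'   data frame `orthogroup`, `species`, `gene`), `domains` (data frame
#'   `gene`, `domain`, `evalue`), `truth_map` (the planted pairing),
#'   `family_candidates`, `family_true` (candidates carrying both domains).
#' @export
simulate_orthology_tables <- function(truth, pairs = NULL, decoy_rate = 0.3,
                                      seed = 1L) {
  if (is.null(pairs)) {
    pairs <- data.frame(gene_a = names(truth$conserved),
                        gene_b = names(truth$module_b),
                        stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    n <- nrow(pairs)
    rle_ev <- function(m) 10^stats::runif(m, -50, -10)
    hits_ab <- data.frame(query = pairs$gene_a, subject = pairs$gene_b,
                          evalue = rle_ev(n),
                          bitscore = stats::runif(n, 200, 500),
                          stringsAsFactors = FALSE)
    hits_ba <- data.frame(query = pairs$gene_b, subject = pairs$gene_a,
                          evalue = rle_ev(n),
                          bitscore = stats::runif(n, 200, 500),
                          stringsAsFactors = FALSE)
    # per-gene decoys: gate-failing or sub-best passing, never displacing
    # the true best hit and never reciprocal
    add_decoys <- function(hits, subjects) {
      n_decoy <- stats::rbinom(1, nrow(hits), min(decoy_rate, 1))
      if (n_decoy == 0) return(hits)
      qi <- sample.int(nrow(hits), n_decoy)
      wrong <- vapply(qi, function(i) {
        sample(setdiff(subjects, hits$subject[i]), 1)
      }, character(1))
      gate_fail <- stats::runif(n_decoy) < 0.5
      ev <- ifelse(gate_fail, 10^stats::runif(n_decoy, -4, -2),
                   10^stats::runif(n_decoy, -9, -6))
      rbind(hits, data.frame(query = hits$query[qi], subject = wrong,
                             evalue = ev,
                             bitscore = stats::runif(n_decoy, 50, 199),
                             stringsAsFactors = FALSE))
    }
    hits_ab <- add_decoys(hits_ab, pairs$gene_b)
    hits_ba <- add_decoys(hits_ba, pairs$gene_a)
    # one orthogroup per true pair
    ogs <- sprintf("OG%06d", seq_len(n))
    orthogroups <- rbind(
      data.frame(orthogroup = ogs, species = "species_a", gene = pairs$gene_a,
                 stringsAsFactors = FALSE),
      data.frame(orthogroup = ogs, species = "species_b", gene = pairs$gene_b,
                 stringsAsFactors = FALSE)
    )
    # cross-orthogroup RBH decoys: reciprocal, passing, but split across
    # two different orthogroups -> must be rejected by pair_orthologs
    n_extra <- max(1L, round(decoy_rate * n / 10))
    if (decoy_rate > 0) {
      xa <- sprintf("Xa%04d", seq_len(n_extra))
      xb <- sprintf("Xb%04d", seq_len(n_extra))
      hits_ab <- rbind(hits_ab, data.frame(
        query = xa, subject = xb, evalue = rle_ev(n_extra),
        bitscore = stats::runif(n_extra, 200, 500), stringsAsFactors = FALSE))
      hits_ba <- rbind(hits_ba, data.frame(
        query = xb, subject = xa, evalue = rle_ev(n_extra),
        bitscore = stats::runif(n_extra, 200, 500), stringsAsFactors = FALSE))
      host_a <- sample(ogs, n_extra, replace = FALSE)
      host_b <- vapply(host_a, function(h) sample(setdiff(ogs, h), 1), character(1))
      orthogroups <- rbind(orthogroups,
        data.frame(orthogroup = host_a, species = "species_a", gene = xa,
                   stringsAsFactors = FALSE),
        data.frame(orthogroup = host_b, species = "species_b", gene = xb,
                   stringsAsFactors = FALSE))
    }
    # domain table: plant family domains on a candidate subset of A genes
    n_cand <- min(8L, n)
    cand <- sample(pairs$gene_a, n_cand)
    has_second <- rep(TRUE, n_cand)
    if (n_cand > 2) has_second[sample.int(n_cand, max(1L, round(n_cand / 4)))] <- FALSE
    domains <- rbind(
      data.frame(gene = cand, domain = "DPBB_1",
                 evalue = 10^stats::runif(n_cand, -30, -10),
                 stringsAsFactors = FALSE),
      data.frame(gene = cand[has_second], domain = "Expansin_C",
                 evalue = 10^stats::runif(sum(has_second), -30, -10),
                 stringsAsFactors = FALSE)
    )
    list(hits_ab = validate_hit_table(collapse_hsps(hits_ab)),
         hits_ba = validate_hit_table(collapse_hsps(hits_ba)),
         orthogroups = orthogroups, domains = domains,
         truth_map = pairs,
         family_candidates = cand, family_true = cand[has_second])
  })
}
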