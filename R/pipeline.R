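#' Pipeline run configuration
#'
#' Collects every stage threshold with defaults equal to the published
#' analysis constants: mean-FPKM filter 0.1, CV filter 0.5, Spearman
#' |rho| > 0.95 with p < 1e-5, top-1% mutual-rank reliability, BLASTP
#' e-value < 1e-5, EC convergence tolerance 0.1 with a 100-iteration cap.
#'
#' @param min_mean,min_cv Expression filter thresholds.
#' @param rho,pmax Edge-calling thresholds.
#' @param mr_top Top MR fraction for reliability.
#' @param evalue Ortholog best-hit e-value gate.
#' @param tol,max_iter EC iteration controls.
#' @param decoy_rate Decoy rate for simulated orthology tables.
#' @param seed Run seed (propagated to the simulator).
#' @param sim A [simulation_config()]; defaults to the study-scale preset
#'   (200 genes, 4 modules, 5 conditions x 2 replicates vs 6 conditions)
#'   with this run's seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(min_mean = 0.1, min_cv = 0.5, rho = 0.95,
                       pmax = 1e-5, mr_top = 0.01, evalue = 1e-5,
                       tol = 0.1, max_iter = 100L, decoy_rate = 0.3,
                       seed = 1L, sim = NULL) {
  if (is.null(sim)) sim <- simulation_config(seed = seed)
  cfg <- list(min_mean = min_mean, min_cv = min_cv, rho = rho, pmax = pmax,
              mr_top = mr_top, evalue = evalue, tol = tol,
              max_iter = as.integer(max_iter), decoy_rate = decoy_rate,
              seed = as.integer(seed), sim = sim)
  stopifnot(min_mean >= 0, min_cv >= 0, rho > 0, rho <= 1,
            pmax > 0, pmax <= 1, mr_top > 0, mr_top <= 1,
            evalue > 0, tol > 0, max_iter >= 1, decoy_rate >= 0)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  flat <- unlist(cfg, use.names = TRUE)
  fnv1a_hash(paste(names(flat), format(flat, digits = 15), sep = "=",
                   collapse = ";"))
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Build per-group query coexpression networks
#'
#' Filters and log-transforms the FPKM matrix, then assembles one network
#' per query group (e.g. phylogenetic groups of a gene family). Groups whose
#' queries were all removed by the expression filter yield an empty network
#' with a warning. The summary counts, per group, surviving queries, edges,
#' distinct partners, partners coexpressed with exactly one vs multiple
#' queries, and annotated TF / lncRNA partners when annotations are given.
#'
#' @param cfg A [run_config()].
#' @param m FPKM `ExpressionMatrix`.
#' @param queries Data frame with columns `gene`, `group`.
#' @param annotations Optional node annotation data frame (`gene_id`,
#'   `tf_family`, `lncrna_flag`).
#' @return List with `networks` (named by group), `summary` (data frame),
#'   `filtered` (the filtered log2 matrix), `removal_report`.
#' @export
run_coexpression_stage <- function(cfg, m, queries, annotations = NULL) {
  stopifnot(inherits(cfg, "run_config"), inherits(m, "ExpressionMatrix"))
  filt <- filter_expression(m, cfg$min_mean, cfg$min_cv)
  log_stage("filter", "%d/%d genes retained", nrow(filt$matrix$values),
            nrow(m$values))
  lg <- log_transform(filt$matrix)
  groups <- unique(queries$group)
  networks <- list()
  rows <- list()
  for (g in groups) {
    qs <- queries$gene[queries$group == g]
    surviving <- intersect(qs, gene_ids(lg))
    if (length(surviving) == 0L) {
      warning("group '", g, "': no query gene survived filtering; empty network",
              call. = FALSE)
      net <- coexpression_network(
        data.frame(query = character(), partner = character(),
                   rho = numeric(), pvalue = numeric(), sign = character(),
                   mr = numeric(), reliable = logical(),
                   stringsAsFactors = FALSE),
        character(0), annotations)
    } else {
      net <- build_coexpression_network(lg, surviving, cfg$rho, cfg$pmax,
                                        cfg$mr_top, annotations)
    }
    networks[[as.character(g)]] <- net
    breadth <- shared_partners_safe(net)
    ann_counts <- annotation_counts(net, annotations)
    rows[[as.character(g)]] <- data.frame(
      group = as.character(g), n_queries = length(qs),
      n_queries_surviving = length(surviving),
      n_edges = nrow(net$edges),
      n_reliable = sum(net$edges$reliable, na.rm = TRUE),
      n_partners = length(unique(net$edges$partner)),
      partners_one_query = breadth$one, partners_multi_query = breadth$multi,
      tf_partners = ann_counts$tf, lncrna_partners = ann_counts$lnc,
      stringsAsFactors = FALSE)
    log_stage("coexpress", "group %s: %d queries -> %d edges", g,
              length(surviving), nrow(net$edges))
  }
  list(networks = networks, summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       filtered = lg, removal_report = filt$removed)
}

shared_partners_safe <- function(net) {
  if (nrow(net$edges) == 0L) return(list(one = 0L, multi = 0L))
  breadth <- shared_partners(net)$partner_breadth
  list(one = sum(breadth$n_queries == 1L), multi = sum(breadth$n_queries > 1L))
}

annotation_counts <- function(net, annotations) {
  if (is.null(annotations) || nrow(net$edges) == 0L) {
    return(list(tf = 0L, lnc = 0L))
  }
  partners <- unique(net$edges$partner)
  ann <- annotations[annotations$gene_id %in% partners, , drop = FALSE]
  tf <- if ("tf_family" %in% names(ann)) sum(!is.na(ann$tf_family) & nzchar(ann$tf_family)) else 0L
  lnc <- if ("lncrna_flag" %in% names(ann)) sum(isTRUE(ann$lncrna_flag) | ann$lncrna_flag %in% c(TRUE, "TRUE", "1")) else 0L
  list(tf = tf, lnc = lnc)
}

#' Run the expression-conservation stage on a paired data set
#'
#' Computes within-species correlation matrices, iterates the EC statistic,
#' and (when a focal gene subset is supplied) compares the subset's EC
#' distribution against the genome-wide one with the Mann-Whitney U test and
#' reports its placement relative to the genome-wide 95th percentile.
#'
#' @param cfg A [run_config()].
#' @param paired A `PairedExpression` (see [simulate_species_pair()]), or a
#'   list with `pairs`, `matrix_a`, `matrix_b` rows aligned to pairs.
#' @param subset Optional character vector of `gene_a` ids forming the focal
#'   subset.
#' @return List with `ec` (an `ECResult`), `report` (per-pair data frame),
#'   and `comparison` (NULL, or list with the Mann-Whitney summary and
#'   `frac_top5`).
#' @export
run_conservation_stage <- function(cfg, paired, subset = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (nrow(paired$pairs) < 4L) stop("ortholog pair set smaller than 4", call. = FALSE)
  Ra <- correlation_matrix(paired$matrix_a)
  Rb <- correlation_matrix(paired$matrix_b)
  res <- ec_iterate(Ra, Rb, tolerance = cfg$tol, max_iter = cfg$max_iter)
  log_stage("ec", "%d pairs, %d iteration(s), converged=%s",
            length(res$ec), res$n_iterations, res$converged)
  report <- data.frame(gene_a = paired$pairs$gene_a,
                       gene_b = paired$pairs$gene_b,
                       stringsAsFactors = FALSE)
  report <- report[report$gene_a %in% names(res$ec), , drop = FALSE]
  report$ec_final <- unname(res$ec[report$gene_a])
  report$ec_initial <- unname(res$ec_initial[report$gene_a])
  report$n_iterations <- res$n_iterations
  report$converged <- res$converged
  comparison <- NULL
  if (!is.null(subset)) {
    in_sub <- report$gene_a %in% subset
    if (any(in_sub)) {
      mw <- compare_ec_distributions(report$ec_final[in_sub], report$ec_final)
      frac <- ec_quantile_placement(report$ec_final, report$ec_final[in_sub],
                                    q = 0.95)
      comparison <- c(mw, list(frac_top5 = frac))
    }
  }
  list(ec = res, report = report, comparison = comparison)
}

#' Run the full synthetic-analysis pipeline and write its outputs
#'
#' Reproduces the analysis shape end-to-end on the simulated preset:
#' generate FPKM data with planted modules, filter and log-transform, build
#' per-module query networks with mutual-rank reliability, generate a
#' two-species ortholog scenario, recover ortholog pairs from simulated
#' hit/orthogroup tables, run the EC iteration, and compare the conserved
#' subset's EC placement. All output files are deterministic functions of
#' (config, seed) and carry a provenance header (tool version, config hash,
#' seed).
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results and the written file
#'   paths.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  seed <- cfg$seed
  wtsv <- function(df, name) {
    write_tsv_provenance(df, file.path(out_dir, name), hash, seed)
  }

  # --- coexpression side -------------------------------------------------
  sim <- simulate_expression(cfg$sim)
  queries <- data.frame(
    gene = sim$truth$query_genes,
    group = paste0("group", sim$truth$module_of_gene[sim$truth$query_genes]),
    stringsAsFactors = FALSE)
  coex <- run_coexpression_stage(cfg, sim$matrix, queries)
  wtsv(expr_to_df(sim$matrix), "expression_fpkm.tsv")
  wtsv(coex$removal_report, "removal_report.tsv")
  wtsv(coex$summary, "network_summary.tsv")
  for (g in names(coex$networks)) {
    wtsv(coex$networks[[g]]$edges, sprintf("edges_%s.tsv", g))
  }

  # --- conservation side -------------------------------------------------
  paired <- simulate_species_pair(cfg$sim)
  tabs <- simulate_orthology_tables(paired$truth, paired$pairs,
                                    decoy_rate = cfg$decoy_rate, seed = seed)
  rbh <- reciprocal_best_hits(tabs$hits_ab, tabs$hits_ba, cfg$evalue)
  pairset <- pair_orthologs(rbh, tabs$orthogroups)
  log_stage("orthologs", "%d RBH candidates -> %d orthogroup-consistent pairs",
            nrow(rbh), nrow(pairset))
  aligned <- list(
    pairs = pairset,
    matrix_a = paired$matrix_a[pairset$gene_a, , drop = FALSE],
    matrix_b = paired$matrix_b[pairset$gene_b, , drop = FALSE])
  cons_subset <- names(paired$truth$conserved)[paired$truth$conserved]
  cons <- run_conservation_stage(cfg, aligned, subset = cons_subset)
  wtsv(pairset, "ortholog_pairs.tsv")
  wtsv(cons$report, "ec_report.tsv")
  ec_summary <- data.frame(
    species_pair = "species_a|species_b",
    gene_set = "conserved_truth",
    n = if (is.null(cons$comparison)) 0L else cons$comparison$n1,
    median_ec = if (is.null(cons$comparison)) NA_real_ else cons$comparison$median1,
    mw_u = if (is.null(cons$comparison)) NA_real_ else cons$comparison$u,
    p_value = if (is.null(cons$comparison)) NA_real_ else cons$comparison$p_value,
    frac_top5 = if (is.null(cons$comparison)) NA_real_ else cons$comparison$frac_top5,
    stringsAsFactors = FALSE)
  wtsv(ec_summary, "ec_summary.tsv")

  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(version = coexcons_version(), config_hash = hash, seed = seed,
         module_of_gene = as.list(sim$truth$module_of_gene),
         query_genes = sim$truth$query_genes,
         conserved_pairs = cons_subset,
         ortholog_map = paired$pairs),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  invisible(list(coexpression = coex, conservation = cons,
                 ortholog_pairs = pairset,
                 files = list.files(out_dir, full.names = TRUE)))
}

expr_to_df <- function(m) {
  data.frame(gene_id = gene_ids(m),
             apply(m$values, 2, format_sig6),
             check.names = FALSE, stringsAsFactors = FALSE)
}
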