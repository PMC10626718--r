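#' Read a BLAST tabular hit table
#'
#' Reads outfmt-6-style tab-delimited hits and collapses multiple HSPs per
#' (query, subject) pair to the minimal e-value (ties: maximal bitscore).
#' Column positions are configurable for non-default outfmt layouts.
#'
#' @param path Path to the tabular file (no header).
#' @param cols Named integer vector giving the 1-based positions of
#'   `query`, `subject`, `evalue`, `bitscore`.
#' @return Data frame `query`, `subject`, `evalue`, `bitscore`, one row per
#'   (query, subject) pair.
#' @export
read_hit_table <- function(path,
                           cols = c(query = 1L, subject = 2L,
                                    evalue = 11L, bitscore = 12L)) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  hits <- data.frame(
    query = as.character(raw[[cols[["query"]]]]),
    subject = as.character(raw[[cols[["subject"]]]]),
    evalue = as.numeric(raw[[cols[["evalue"]]]]),
    bitscore = as.numeric(raw[[cols[["bitscore"]]]]),
    stringsAsFactors = FALSE
  )
  validate_hit_table(collapse_hsps(hits))
}

# Best HSP per (query, subject): minimal e-value, then maximal bitscore.
collapse_hsps <- function(hits) {
  o <- order(hits$query, hits$subject, hits$evalue, -hits$bitscore)
  hits <- hits[o, , drop = FALSE]
  keep <- !duplicated(hits[c("query", "subject")])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_hit_table <- function(hits) {
  stopifnot(all(c("query", "subject", "evalue", "bitscore") %in% names(hits)))
  if (any(!is.finite(hits$evalue) | hits$evalue < 0)) {
    stop("e-values must be finite and non-negative", call. = FALSE)
  }
  if (anyDuplicated(hits[c("query", "subject")])) {
    stop("duplicate (query, subject) rows; collapse HSPs first", call. = FALSE)
  }
  hits
}

#' Best hit per query under the e-value gate
#'
#' Hits with e-value >= `emax` are discarded before selection, so a query
#' whose best raw hit fails the gate gets no subject at all. Among passing
#' hits the minimal e-value wins; ties broken by maximal bitscore, then by
#' lexicographically smallest subject id.
#'
#' @param hits Hit table (`query`, `subject`, `evalue`, `bitscore`).
#' @param emax Strict e-value gate (default 1e-5).
#' @return Data frame `query`, `subject`, `evalue` with one row per query
#'   that has a passing hit.
#' @export
best_hits <- function(hits, emax = 1e-5) {
  if (nrow(hits) == 0L) stop("empty hit table", call. = FALSE)
  hits <- validate_hit_table(hits)
  hits <- hits[hits$evalue < emax, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  o <- order(hits$query, hits$evalue, -hits$bitscore, hits$subject)
  hits <- hits[o, , drop = FALSE]
  out <- hits[!duplicated(hits$query), c("query", "subject", "evalue")]
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two species
#'
#' Emits pair (a, b) iff b is a's best hit in the A-vs-B table and a is b's
#' best hit in the B-vs-A table, with the e-value gate enforced in both
#' directions. One-to-one by construction.
#'
#' @param ab Hit table of species-A queries against species-B subjects.
#' @param ba Hit table of species-B queries against species-A subjects.
#' @param emax Strict e-value gate applied in both directions.
#' @return Data frame `gene_a`, `gene_b`, `evalue_ab`, `evalue_ba`.
#' @export
reciprocal_best_hits <- function(ab, ba, emax = 1e-5) {
  best_ab <- best_hits(ab, emax)
  best_ba <- best_hits(ba, emax)
  back <- stats::setNames(best_ba$subject, best_ba$query)
  keep <- !is.na(back[best_ab$subject]) & back[best_ab$subject] == best_ab$query
  keep[is.na(keep)] <- FALSE
  ev_ba <- stats::setNames(best_ba$evalue, best_ba$query)
  out <- data.frame(
    gene_a = best_ab$query[keep],
    gene_b = best_ab$subject[keep],
    evalue_ab = best_ab$evalue[keep],
    evalue_ba = unname(ev_ba[best_ab$subject[keep]]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read an Orthofinder-style orthogroups table
#'
#' Tab-delimited: first column the orthogroup id, remaining columns one per
#' species holding comma-separated gene lists; header row gives species
#' names.
#'
#' @param path Path to the table.
#' @return Long data frame `orthogroup`, `species`, `gene`.
#' @export
read_orthogroups <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected orthogroup id plus species columns", call. = FALSE)
  species <- colnames(raw)[-1]
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    og <- raw[i, 1]
    do.call(rbind, lapply(species, function(sp) {
      genes <- strsplit(raw[i, sp], ",[ ]*")[[1]]
      genes <- genes[nzchar(genes)]
      if (!length(genes)) return(NULL)
      data.frame(orthogroup = og, species = sp, gene = genes,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  validate_orthogroups(out)
}

validate_orthogroups <- function(og) {
  dup <- unique(og$gene[duplicated(og$gene)])
  if (length(dup)) {
    stop("genes assigned to multiple orthogroups: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  rownames(og) <- NULL
  og
}

#' Constrain reciprocal best hits to shared orthogroups
#'
#' Retains RBH candidate pairs whose two genes belong to the same
#' orthogroup; pairs with either gene absent from every orthogroup are
#' dropped. These are the "highly similar ortholog" pairs used for the
#' expression-conservation comparison.
#'
#' @param rbh Candidate pairs from [reciprocal_best_hits()].
#' @param og Long orthogroup table (`orthogroup`, `gene`), e.g. from
#'   [read_orthogroups()].
#' @return `OrthologPairSet` data frame: `gene_a`, `gene_b`, `orthogroup`,
#'   `evalue_ab`, `evalue_ba`.
#' @export
pair_orthologs <- function(rbh, og) {
  og_of <- stats::setNames(og$orthogroup, og$gene)
  og_a <- unname(og_of[rbh$gene_a])
  og_b <- unname(og_of[rbh$gene_b])
  keep <- !is.na(og_a) & !is.na(og_b) & og_a == og_b
  out <- data.frame(
    gene_a = rbh$gene_a[keep],
    gene_b = rbh$gene_b[keep],
    orthogroup = og_a[keep],
    evalue_ab = rbh$evalue_ab[keep],
    evalue_ba = rbh$evalue_ba[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a protein-domain annotation table
#' @param path TSV with columns gene, domain, evalue (header optional but
#'   expected as `gene`, `domain`, `evalue`).
#' @return Data frame `gene`, `domain`, `evalue`.
#' @export
read_domain_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(raw)[1:3] <- c("gene", "domain", "evalue")
  raw$evalue <- as.numeric(raw$evalue)
  if (any(!nzchar(raw$domain))) stop("empty domain names", call. = FALSE)
  raw
}

# Case-insensitive, with "-" and "_" treated as equivalent.
normalize_domain <- function(x) gsub("-", "_", tolower(x), fixed = TRUE)

#' Screen gene-family candidates by required conserved domains
#'
#' Retains candidates that carry at least one annotation row for every
#' required domain. Domain names are matched case-insensitively with "-" and
#' "_" interchangeable. The default domains (DPBB_1 and Expansin_C) define
#' expansin-family membership.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param domains Domain table (`gene`, `domain`).
#' @param required Domain names that must all be present.
#' @return The retained subset of `candidates`, in input order.
#' @export
screen_family_candidates <- function(candidates, domains,
                                     required = c("DPBB_1", "Expansin_C")) {
  req <- normalize_domain(required)
  dom_by_gene <- split(normalize_domain(domains$domain), domains$gene)
  keep <- vapply(candidates, function(g) {
    all(req %in% dom_by_gene[[g]])
  }, logical(1))
  candidates[keep]
}
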