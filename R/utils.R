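#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their seed and never
#' perturb user code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# FNV-1a over a string; used to stamp a config fingerprint into output
# headers without a cryptographic dependency.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256), keeping h a double in [0, 2^32)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit FNV prime multiplication; split h to stay within double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' @keywords internal
coexcons_version <- function() {
  as.character(utils::packageVersion("coexcons"))
}

# Writes a data frame as TSV with a deterministic provenance header.
write_tsv_provenance <- function(df, path, config_hash = NULL, seed = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# coexcons %s", coexcons_version()), con)
  if (!is.null(config_hash)) writeLines(sprintf("# config_hash=%s", config_hash), con)
  if (!is.null(seed)) writeLines(sprintf("# seed=%s", format(seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Format numbers with 6 significant digits for TSV export.
format_sig6 <- function(x) formatC(x, digits = 6L, format = "g")
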