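#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median rnorm runif setNames aggregate cutree dist
#' @importFrom utils read.delim write.table head tail
NULL

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit sub-seed from a master seed and a stage label.
# Keeps every derived seed in [0, 2^31 - 1].
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# TSV writers with fixed formatting so re-runs are byte-identical.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
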