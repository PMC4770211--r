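# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a local RNG seed without disturbing the caller's
## random number stream. A NULL seed uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## Derive a reproducible child seed from a master seed and a stage label,
## kept below 2^31 so it is a valid R integer.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629) + 1L
}

KINGDOMS <- c("metazoa", "plantae", "fungi", "other")

check_kingdom <- function(kingdom) {
  match.arg(kingdom, KINGDOMS)
}

## Maximal runs of TRUE in a logical vector as a start/end table.
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
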