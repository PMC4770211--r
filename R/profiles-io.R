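#' Per-residue disorder profiles
#'
#' A disorder profile holds one organism's copy of one Mediator subunit:
#' its amino-acid sequence and the per-residue disorder propensity in
#' `[0, 1]` produced upstream by a disorder predictor (IUPred-style).
#' Scores are consumed, never computed from sequence.
#'
#' @param organism_id Single string identifying the organism.
#' @param subunit_id Single string identifying the subunit (e.g. `"Med19"`).
#' @param kingdom One of `"metazoa"`, `"plantae"`, `"fungi"`, `"other"`.
#' @param sequence Amino-acid string of length `L >= 1`. Non-canonical
#'   letters (X, B, Z, U, ...) are accepted; predictors score them too.
#' @param scores Numeric vector of length `L`, each value in `[0, 1]`.
#'   Out-of-range scores are an error, never clipped: they indicate an
#'   upstream parsing problem that must surface.
#'
#' @return An object of class `disorder_profile`.
#' @export
disorder_profile <- function(organism_id, subunit_id, kingdom, sequence, scores) {
  stopifnot(is.character(organism_id), length(organism_id) == 1L,
            is.character(subunit_id), length(subunit_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  kingdom <- check_kingdom(kingdom)
  scores <- as.numeric(scores)
  L <- nchar(sequence)
  if (L < 1L)
    stop("sequence must have length >= 1", call. = FALSE)
  if (length(scores) != L)
    stop(sprintf("length(scores) [%d] != nchar(sequence) [%d]",
                 length(scores), L), call. = FALSE)
  if (anyNA(scores) || any(scores < 0) || any(scores > 1))
    stop("all scores must lie in [0, 1]", call. = FALSE)
  structure(
    list(organism_id = organism_id, subunit_id = subunit_id,
         kingdom = kingdom, sequence = sequence, scores = scores),
    class = "disorder_profile")
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat(sprintf("<disorder_profile> %s | %s | %s  (L = %d, mean disorder = %.3f)\n",
              x$organism_id, x$subunit_id, x$kingdom,
              nchar(x$sequence), mean(x$scores)))
  invisible(x)
}

#' @export
length.disorder_profile <- function(x) nchar(x$sequence)

#' Read an IUPred-style per-residue score table
#'
#' Parses a whitespace- or tab-separated table with at least three columns
#' per data line: 1-based position, one-letter residue, disorder score.
#' Lines starting with `#` are comments; extra columns are ignored. The
#' sequence is reconstructed from the residue column.
#'
#' @param path Path to the score table.
#' @inheritParams disorder_profile
#' @return A [disorder_profile()].
#' @details Positions must form a contiguous `1..L` run (any order in the
#'   file); duplicated or missing positions are a format error. Scores
#'   outside `[0, 1]` are a value error.
#' @export
read_score_table <- function(path, organism_id, subunit_id, kingdom = "other") {
  if (!file.exists(path))
    stop(sprintf("score table not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L)
    stop(sprintf("no data lines in %s", path), call. = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("line %d of %s has fewer than 3 fields",
                 which(nf < 3L)[1L], path), call. = FALSE)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  res <- vapply(fields, `[[`, "", 2L)
  sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(pos))
    stop(sprintf("non-integer position in %s", path), call. = FALSE)
  if (anyNA(sc))
    stop(sprintf("non-numeric score in %s", path), call. = FALSE)
  o <- order(pos)
  pos <- pos[o]; res <- res[o]; sc <- sc[o]
  if (anyDuplicated(pos))
    stop(sprintf("duplicated position %d in %s",
                 pos[duplicated(pos)][1L], path), call. = FALSE)
  if (!identical(pos, seq_along(pos)))
    stop(sprintf("positions in %s are not a contiguous 1..L run", path),
         call. = FALSE)
  if (any(nchar(res) != 1L))
    stop(sprintf("residue column in %s must be single letters", path),
         call. = FALSE)
  disorder_profile(organism_id, subunit_id, kingdom,
                   paste(res, collapse = ""), sc)
}

#' Write a disorder profile as a canonical score table
#'
#' Emits the same dialect [read_score_table()] reads: a `#` metadata header
#' (organism, subunit, kingdom) followed by tab-separated
#' position/residue/score lines. `read_score_table(write_score_table(p))`
#' round-trips exactly (scores serialised at full precision).
#'
#' @param profile A [disorder_profile()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_score_table <- function(profile, path) {
  stopifnot(inherits(profile, "disorder_profile"))
  hdr <- c(sprintf("# organism_id=%s", profile$organism_id),
           sprintf("# subunit_id=%s", profile$subunit_id),
           sprintf("# kingdom=%s", profile$kingdom))
  L <- nchar(profile$sequence)
  body <- sprintf("%d\t%s\t%.17g", seq_len(L),
                  strsplit(profile$sequence, "")[[1L]], profile$scores)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Average disorder of a subunit
#'
#' The arithmetic mean of the per-residue disorder scores over the whole
#' sequence; the per-protein summary underlying the organisms-by-subunits
#' matrix and all kingdom comparisons.
#'
#' @param profile A [disorder_profile()] or a bare numeric score vector.
#' @return A single number in `[0, 1]`.
#' @export
average_disorder <- function(profile) {
  scores <- if (inherits(profile, "disorder_profile")) profile$scores
            else as.numeric(profile)
  if (length(scores) == 0L)
    stop("cannot average an empty profile", call. = FALSE)
  mean(scores)
}

#' Binarize a disorder profile
#'
#' Residues with score greater than *or equal to* the threshold (default
#' 0.5) are disordered; the boundary is inclusive.
#'
#' @inheritParams average_disorder
#' @param threshold Disorder cut-off, strictly inside `(0, 1)`.
#' @return A logical vector of class `binary_disorder_track` with a
#'   `threshold` attribute; `TRUE` marks disordered residues.
#' @export
binarize <- function(profile, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  scores <- if (inherits(profile, "disorder_profile")) profile$scores
            else as.numeric(profile)
  if (length(scores) == 0L)
    stop("cannot binarize an empty profile", call. = FALSE)
  structure(scores >= threshold, threshold = threshold,
            class = "binary_disorder_track")
}

#' Read profile sequences from FASTA
#'
#' Headers are parsed as `organism_id|subunit_id|kingdom`.
#'
#' @param path FASTA file.
#' @return A data frame with columns `organism_id`, `subunit_id`,
#'   `kingdom`, `sequence`.
#' @export
read_profile_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L)
    stop(sprintf("FASTA header %d is not 'org|subunit|kingdom'", bad[1L]),
         call. = FALSE)
  data.frame(
    organism_id = vapply(parts, `[[`, "", 1L),
    subunit_id = vapply(parts, `[[`, "", 2L),
    kingdom = vapply(parts, `[[`, "", 3L),
    sequence = as.character(aa),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write profile sequences to FASTA
#'
#' @param profiles List of [disorder_profile()] objects.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_profile_fasta <- function(profiles, path) {
  seqs <- vapply(profiles, function(p) p$sequence, "")
  names(seqs) <- vapply(profiles, function(p)
    paste(p$organism_id, p$subunit_id, p$kingdom, sep = "|"), "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
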