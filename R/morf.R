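#' Call MoRF segments from a per-residue score track
#'
#' A molecular recognition feature (MoRF) is a stretch of at least
#' `min_len` residues (default 5) whose predictor score is greater than or
#' equal to `threshold` (default 0.5). Runs are maximal and no gaps are
#' tolerated: a single sub-threshold residue splits a run.
#'
#' @param scores Numeric vector of per-residue MoRF propensities.
#' @param min_len Minimum segment length.
#' @param threshold Inclusive score cut-off.
#' @return Data frame with `start`, `end`, `length`.
#' @export
call_morfs <- function(scores, min_len = 5L, threshold = 0.5) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L)
    stop("empty MoRF score track", call. = FALSE)
  stopifnot(min_len >= 1L)
  runs <- true_runs(scores >= threshold)
  runs$length <- runs$end - runs$start + 1L
  runs <- runs[runs$length >= min_len, , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

#' Map residue coordinates onto alignment columns
#'
#' Residue `i` of the ungapped sequence maps to the column of its i-th
#' non-gap character in the aligned row.
#'
#' @param start,end 1-based inclusive residue coordinates of a segment.
#' @param aligned_row Aligned sequence string (gaps as `-`).
#' @return Integer vector of covered alignment columns.
#' @export
map_segment_to_columns <- function(start, end, aligned_row) {
  stopifnot(length(aligned_row) == 1L, start >= 1L, start <= end)
  chars <- strsplit(aligned_row, "")[[1L]]
  non_gap <- which(chars != "-")
  if (end > length(non_gap))
    stop(sprintf("segment end %d beyond ungapped length %d",
                 end, length(non_gap)), call. = FALSE)
  non_gap[start:end]
}

#' Conserved MoRF regions on a multiple sequence alignment
#'
#' A MoRF region is conserved when it is aligned across organisms: every
#' column of the region is MoRF-covered in at least `min_organisms`
#' organisms (default 4). Regions shorter than `min_run` columns (default
#' 5, mirroring the MoRF minimum length) are discarded to avoid
#' single-column artifacts.
#'
#' @param coverage Named list: organism -> integer vector of MoRF-covered
#'   alignment columns (from [map_segment_to_columns()]).
#' @param width Alignment width (defaults to the maximum covered column).
#' @param min_organisms Minimum supporting organisms per column.
#' @param min_run Minimum region width in columns.
#' @return Data frame with `column_start`, `column_end`, `n_organisms`,
#'   and a list column `supporting` of organism ids covering at least one
#'   column of the region.
#' @export
conserved_morf_regions <- function(coverage, width = NULL,
                                   min_organisms = 4L, min_run = 5L) {
  if (length(coverage) < min_organisms)
    stop(sprintf("need at least %d organisms, got %d",
                 min_organisms, length(coverage)), call. = FALSE)
  cols <- unlist(coverage, use.names = FALSE)
  empty <- data.frame(column_start = integer(0), column_end = integer(0),
                      n_organisms = integer(0))
  empty$supporting <- list()
  if (length(cols) == 0L) return(empty)
  width <- width %||% max(cols)
  counts <- integer(width)
  for (v in coverage) {
    v <- unique(as.integer(v))
    counts[v] <- counts[v] + 1L
  }
  runs <- true_runs(counts >= min_organisms)
  runs <- runs[runs$end - runs$start + 1L >= min_run, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)
  sup <- lapply(seq_len(nrow(runs)), function(i) {
    rng <- runs$start[i]:runs$end[i]
    names(coverage)[vapply(coverage, function(v) any(v %in% rng), NA)]
  })
  out <- data.frame(column_start = runs$start, column_end = runs$end,
                    n_organisms = vapply(sup, length, 0L))
  out$supporting <- sup
  rownames(out) <- NULL
  out
}

#' Flag junction-MoRFs
#'
#' A junction-MoRF sits at the boundary between a disordered region and
#' well-defined secondary structure. Operationally a MoRF is flagged when
#' it overlaps the window `[p - w, p + w]` around an IDR boundary `p` and
#' straddles that IDR (covers at least one residue inside and one
#' outside), or, when `domains` are supplied, when one of its own boundary
#' windows intersects a domain boundary window.
#'
#' @param morfs Data frame of MoRF segments (`start`, `end`).
#' @param idrs Data frame of IDR segments (`start`, `end`); may be empty.
#' @param domains Optional data frame of structured-domain intervals
#'   (`start`, `end`).
#' @param w Boundary window half-width in residues (default 10).
#' @return `morfs` with an added logical column `is_junction`.
#' @export
junction_morfs <- function(morfs, idrs, domains = NULL, w = 10L) {
  if (w < 0L)
    stop("w must be >= 0", call. = FALSE)
  flag <- rep(FALSE, nrow(morfs))
  if (!is.null(idrs) && nrow(idrs) > 0L) {
    for (i in seq_len(nrow(idrs))) {
      s <- idrs$start[i]; e <- idrs$end[i]
      near <- (morfs$start <= s + w & morfs$end >= s - w) |
              (morfs$start <= e + w & morfs$end >= e - w)
      inside <- morfs$start <= e & morfs$end >= s
      outside <- morfs$start < s | morfs$end > e
      flag <- flag | (near & inside & outside)
    }
  }
  if (!is.null(domains) && nrow(domains) > 0L) {
    dom_b <- c(domains$start, domains$end)
    morf_b <- cbind(morfs$start, morfs$end)
    for (p in dom_b) {
      hit <- (abs(morf_b[, 1L] - p) <= 2L * w) |
             (abs(morf_b[, 2L] - p) <= 2L * w)
      flag <- flag | hit
    }
  }
  morfs$is_junction <- flag
  morfs
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path Aligned FASTA (all rows equal width; gaps as `-`).
#' @return Named character vector of aligned rows.
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  rows <- as.character(aa)
  if (length(unique(nchar(rows))) > 1L)
    stop("alignment rows differ in width; not an aligned FASTA",
         call. = FALSE)
  rows
}
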