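#' Call intrinsically disordered regions from a binary track
#'
#' An IDR is a continuous stretch of at least `min_len` residues (default
#' 30) predicted disordered at the 0.5 threshold, tolerating ordered gaps
#' of at most `max_gap` residues (default 3). Any number of gaps is
#' allowed, each individually at most `max_gap` long; the minimum length
#' counts the full span including tolerated gap residues. Segments start
#' and end on disordered residues, are maximal, non-overlapping, and
#' sorted by start.
#'
#' @param track Logical vector (`TRUE` = disordered), e.g. from
#'   [binarize()].
#' @param min_len Minimum segment span, in residues.
#' @param max_gap Maximum tolerated ordered gap inside a segment.
#' @return Data frame with columns `start`, `end`, `span` (1-based,
#'   inclusive coordinates).
#' @export
call_idrs <- function(track, min_len = 30L, max_gap = 3L) {
  bits <- as.logical(track)
  if (length(bits) == 0L)
    stop("empty disorder track", call. = FALSE)
  if (anyNA(bits))
    stop("disorder track contains NA", call. = FALSE)
  stopifnot(min_len >= 1L, max_gap >= 0L)
  d <- which(bits)
  if (length(d) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      span = integer(0)))
  ## chain consecutive disordered positions whose ordered gap <= max_gap
  brk <- c(TRUE, diff(d) - 1L > max_gap)
  grp <- cumsum(brk)
  start <- as.integer(tapply(d, grp, min))
  end <- as.integer(tapply(d, grp, max))
  span <- end - start + 1L
  keep <- span >= min_len
  data.frame(start = start[keep], end = end[keep], span = span[keep],
             row.names = NULL)
}

#' Assign an IDR to the N-terminal, middle, or C-terminal third
#'
#' The protein is split into thirds: N = `[1, floor(L/3)]`, middle =
#' `(floor(L/3), floor(2L/3)]`, C = `(floor(2L/3), L]` (the remainder when
#' `L` is not divisible by 3 accrues to the C region). A segment belongs
#' to the region holding more than half of its span; when no region does
#' (long IDRs), the termini take precedence over the middle: the segment
#' goes to whichever of N or C overlaps it more, ties to N.
#'
#' @param start,end Integer vectors of 1-based inclusive segment bounds.
#' @param L Protein length (must be >= 3 so the thirds are non-degenerate).
#' @return Character vector over `c("N", "middle", "C")`.
#' @export
assign_region <- function(start, end, L) {
  if (L < 3L)
    stop("protein too short to split into thirds (L < 3)", call. = FALSE)
  if (any(start < 1L) || any(end > L) || any(start > end))
    stop("segment outside [1, L]", call. = FALSE)
  nb <- floor(L / 3)
  mb <- floor(2 * L / 3)
  span <- end - start + 1L
  ov_n <- pmax(0L, pmin(end, nb) - start + 1L)
  ov_m <- pmax(0L, pmin(end, mb) - pmax(start, nb + 1L) + 1L)
  ov_c <- pmax(0L, end - pmax(start, mb + 1L) + 1L)
  region <- ifelse(ov_n * 2L > span, "N",
            ifelse(ov_m * 2L > span, "middle",
            ifelse(ov_c * 2L > span, "C",
            ifelse(ov_n >= ov_c, "N", "C"))))
  region
}

#' Call and place IDRs for one profile
#'
#' Convenience wrapper: binarize, call IDRs, and assign each to a region.
#'
#' @param profile A [disorder_profile()].
#' @param threshold Disorder threshold passed to [binarize()].
#' @inheritParams call_idrs
#' @return Data frame with `organism_id`, `subunit_id`, `start`, `end`,
#'   `span`, `region`.
#' @export
idr_segments <- function(profile, threshold = 0.5, min_len = 30L, max_gap = 3L) {
  stopifnot(inherits(profile, "disorder_profile"))
  seg <- call_idrs(binarize(profile, threshold), min_len, max_gap)
  L <- nchar(profile$sequence)
  seg$region <- if (nrow(seg) > 0L) assign_region(seg$start, seg$end, L)
                else character(0)
  cbind(data.frame(organism_id = rep(profile$organism_id, nrow(seg)),
                   subunit_id = rep(profile$subunit_id, nrow(seg)),
                   stringsAsFactors = FALSE),
        seg)
}

#' Classify per-kingdom IDR conservation of a subunit region
#'
#' A region of a subunit is *highly conserved* in a kingdom when at least
#' 70% of the kingdom's organisms (that possess the subunit) have an IDR
#' assigned to that region, *moderately conserved* at 50-70%, otherwise
#' not conserved. One organism can count toward several regions via
#' several IDRs.
#'
#' @param presence Named list: organism id -> character vector of regions
#'   (subset of `c("N", "middle", "C")`) holding at least one IDR.
#' @param kingdom,subunit_id Labels carried into the output.
#' @param high,moderate Percentage thresholds (defaults 70 and 50).
#' @return Data frame with one row per region: `subunit_id`, `kingdom`,
#'   `region`, `n_with_idr`, `n_organisms`, `pct`, `class`.
#' @export
classify_conservation <- function(presence, kingdom = "other",
                                  subunit_id = NA_character_,
                                  high = 70, moderate = 50) {
  if (length(presence) == 0L)
    stop("empty presence table", call. = FALSE)
  stopifnot(moderate <= high)
  regions <- c("N", "middle", "C")
  n_org <- length(presence)
  n_with <- vapply(regions, function(r)
    sum(vapply(presence, function(x) r %in% x, NA)), 0L)
  pct <- 100 * n_with / n_org
  cls <- ifelse(pct >= high, "highly_conserved",
         ifelse(pct >= moderate, "moderately_conserved", "not_conserved"))
  data.frame(subunit_id = subunit_id, kingdom = kingdom, region = regions,
             n_with_idr = as.integer(n_with), n_organisms = n_org,
             pct = pct, class = cls, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Report region conservation restricted to an organism subset
#'
#' A *restricted* IDR is one conserved only within a particular organism
#' group: kingdom-wide presence below `moderate` percent but at least
#' `high` percent within the supplied subset.
#'
#' @inheritParams classify_conservation
#' @param subset_ids Organism ids defining the restricted group (must be a
#'   subset of `names(presence)`).
#' @return Data frame per region with `pct_all`, `pct_subset`,
#'   `restricted` (logical).
#' @export
restricted_idrs <- function(presence, subset_ids, high = 70, moderate = 50) {
  if (!all(subset_ids %in% names(presence)))
    stop("subset_ids must be organisms in the presence table", call. = FALSE)
  if (length(subset_ids) == 0L)
    stop("empty organism subset", call. = FALSE)
  all_tab <- classify_conservation(presence, high = high, moderate = moderate)
  sub_tab <- classify_conservation(presence[subset_ids],
                                   high = high, moderate = moderate)
  data.frame(region = all_tab$region,
             pct_all = all_tab$pct,
             pct_subset = sub_tab$pct,
             restricted = all_tab$pct < moderate & sub_tab$pct >= high,
             stringsAsFactors = FALSE)
}

#' Export IDR segments as BED intervals
#'
#' 0-based half-open coordinates, one line per segment, name column
#' `organism|subunit|region`.
#'
#' @param segments Data frame from [idr_segments()].
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
write_idr_bed <- function(segments, path) {
  bed <- data.frame(chrom = paste(segments$organism_id,
                                  segments$subunit_id, sep = "|"),
                    start = segments$start - 1L,
                    end = segments$end,
                    name = segments$region)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
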