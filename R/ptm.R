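#' PTM site tracks
#'
#' A PTM track lists predicted post-translational modification sites on
#' one profile: 1-based positions with a type from the seven classes the
#' analysis distinguishes (Ser/Thr/Tyr phosphorylation, Lys acetylation,
#' Lys/Arg methylation, N- and O-linked glycosylation).
#'
#' @param positions Integer vector of 1-based site positions.
#' @param types Character vector of PTM types (recycled if length 1).
#' @param L Protein length; all positions must lie in `[1, L]`.
#' @param organism_id,subunit_id Optional labels.
#' @return Data frame of class `ptm_track` with columns `position`,
#'   `ptm_type` and attribute `L`.
#' @export
ptm_track <- function(positions, types, L,
                      organism_id = NA_character_,
                      subunit_id = NA_character_) {
  positions <- as.integer(positions)
  types <- rep_len(as.character(types), length(positions))
  if (length(positions) > 0L) {
    ok <- types %in% PTM_TYPES
    if (!all(ok))
      stop(sprintf("unknown ptm_type: %s", types[!ok][1L]), call. = FALSE)
    if (any(positions < 1L) || any(positions > L))
      stop("PTM positions must lie in [1, L]", call. = FALSE)
    if (anyDuplicated(paste(positions, types)))
      stop("duplicated (position, type) pair", call. = FALSE)
  }
  out <- data.frame(position = positions, ptm_type = types,
                    stringsAsFactors = FALSE)
  attr(out, "L") <- as.integer(L)
  attr(out, "organism_id") <- organism_id
  attr(out, "subunit_id") <- subunit_id
  class(out) <- c("ptm_track", "data.frame")
  out
}

#' @rdname ptm_track
#' @format NULL
#' @export
PTM_TYPES <- c("phosphoS", "phosphoT", "phosphoY", "acetylK",
               "methylKR", "glycN", "glycO")

#' Fraction of PTM sites falling inside IDRs
#'
#' Positions are compared against IDR intervals inclusively; a site
#' carrying several PTM types still counts per type row supplied. With no
#' IDRs the fraction is 0; with no sites of the filtered type the
#' fraction is undefined and an error is raised.
#'
#' @param track A [ptm_track()] (or data frame with `position`,
#'   `ptm_type`).
#' @param idrs Data frame of IDR intervals with `start`, `end`.
#' @param ptm_type Optional type filter (character vector); default all.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_in_idr <- function(track, idrs, ptm_type = NULL) {
  pos <- track$position
  if (!is.null(ptm_type)) pos <- pos[track$ptm_type %in% ptm_type]
  if (length(pos) == 0L)
    stop("no PTM sites of the requested type: fraction undefined",
         call. = FALSE)
  if (is.null(idrs) || nrow(idrs) == 0L) return(0)
  inside <- vapply(pos, function(p)
    any(p >= idrs$start & p <= idrs$end), NA)
  mean(inside)
}

#' Mean disorder at PTM versus non-PTM positions
#'
#' @param profile A [disorder_profile()] or numeric score vector.
#' @param track A [ptm_track()] (positions on the same profile).
#' @return List with `mean_ptm` and `mean_non_ptm`.
#' @export
disorder_at_sites <- function(profile, track) {
  scores <- if (inherits(profile, "disorder_profile")) profile$scores
            else as.numeric(profile)
  pos <- unique(track$position)
  if (length(pos) == 0L)
    stop("track has no PTM sites", call. = FALSE)
  if (any(pos > length(scores)))
    stop("PTM position beyond profile length", call. = FALSE)
  non <- setdiff(seq_along(scores), pos)
  if (length(non) == 0L)
    stop("all positions are PTM sites: non-PTM mean undefined",
         call. = FALSE)
  list(mean_ptm = mean(scores[pos]), mean_non_ptm = mean(scores[non]))
}

#' Detect PTM hotspots by sliding-window density
#'
#' A 30-residue stretch qualifies as a PTM hotspot when the fraction of
#' its positions carrying at least one predicted PTM site lies between
#' 0.1 and 0.3, both bounds inclusive. Windows slide with step `step`
#' (default 1, fully overlapping); overlapping qualifying windows are
#' merged into maximal regions whose density is the maximum window
#' density inside them. Regions are banded `"low"` (density in
#' `[0.1, 0.2)`) or `"high"` (`[0.2, 0.3]`; the 0.2 boundary goes to
#' high). Two PTM types at one position count once: density is positional
#' occupancy. Windows denser than the upper bound are excluded per the
#' literal rule; set `max_density = 1` to lift the cap.
#'
#' @param track A [ptm_track()] or integer vector of site positions.
#' @param L Protein length (defaults to the track's `L` attribute).
#' @param window Window width in residues (default 30).
#' @param min_density,max_density Inclusive density bounds.
#' @param step Window step (1 = overlapping; `window` = tiled).
#' @return Data frame with `start`, `end`, `density`, `band`.
#' @export
find_hotspots <- function(track, L = NULL, window = 30L,
                          min_density = 0.1, max_density = 0.3,
                          step = 1L) {
  pos <- if (is.data.frame(track)) track$position else as.integer(track)
  L <- L %||% attr(track, "L")
  if (is.null(L))
    stop("protein length L is required", call. = FALSE)
  if (L < window)
    stop(sprintf("protein shorter than the window (L = %d < %d)", L, window),
         call. = FALSE)
  stopifnot(step >= 1L)
  empty <- data.frame(start = integer(0), end = integer(0),
                      density = numeric(0), band = character(0))
  if (length(pos) == 0L) return(empty)
  occupied <- integer(L)
  occupied[unique(pos)] <- 1L
  cs <- c(0L, cumsum(occupied))
  starts <- seq.int(1L, L - window + 1L, by = step)
  counts <- cs[starts + window] - cs[starts]
  dens <- counts / window
  tol <- 1e-9
  qual <- dens >= min_density - tol & dens <= max_density + tol
  if (!any(qual)) return(empty)
  qs <- starts[qual]; qd <- dens[qual]
  ## merge windows that overlap or touch into maximal regions
  brk <- c(TRUE, diff(qs) >= window)
  grp <- cumsum(brk)
  out <- do.call(rbind, lapply(split(seq_along(qs), grp), function(ii) {
    data.frame(start = qs[ii[1L]],
               end = qs[ii[length(ii)]] + window - 1L,
               density = max(qd[ii]))
  }))
  out$band <- ifelse(out$density >= 0.2 - tol, "high", "low")
  rownames(out) <- NULL
  out
}

#' Read a PTM site table
#'
#' TSV with columns `organism_id`, `subunit_id`, `position`, `ptm_type`.
#'
#' @param path Input TSV.
#' @return Data frame (one row per site).
#' @export
read_ptm_table <- function(path) {
  df <- read_tsv(path)
  need <- c("organism_id", "subunit_id", "position", "ptm_type")
  if (!all(need %in% names(df)))
    stop("PTM table must have columns organism_id, subunit_id, position, ptm_type",
         call. = FALSE)
  df$position <- as.integer(df$position)
  df
}
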