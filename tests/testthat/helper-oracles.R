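# Independent oracles used to cross-check the package implementations.
# These deliberately use different mechanisms (regex engine, quadratic
# interval enumeration, per-window rescans) from the production code.

## Maximal gap-tolerant disordered intervals via a greedy PCRE match:
## a leftmost-greedy match of 1(0{1,g}1|1)* is exactly a maximal interval
## that starts/ends disordered and contains no ordered run longer than g.
idr_oracle_regex <- function(bits, min_len = 30L, max_gap = 3L) {
  s <- paste(as.integer(bits), collapse = "")
  pat <- if (max_gap == 0L) "1+" else sprintf("1(?:0{1,%d}1|1)*", max_gap)
  m <- gregexpr(pat, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(0), end = integer(0),
                      span = integer(0)))
  start <- as.integer(m)
  span <- attr(m, "match.length")
  out <- data.frame(start = start, end = start + span - 1L, span = span)
  out[out$span >= min_len, , drop = FALSE]
}

## Quadratic brute force: enumerate every valid interval, keep maximal
## ones, filter on span. Only for short tracks.
idr_oracle_brute <- function(bits, min_len = 30L, max_gap = 3L) {
  L <- length(bits)
  valid <- list()
  for (i in seq_len(L)) {
    if (!bits[i]) next
    run0 <- 0L
    for (j in i:L) {
      if (bits[j]) {
        run0 <- 0L
        valid[[length(valid) + 1L]] <- c(i, j)
      } else {
        run0 <- run0 + 1L
        if (run0 > max_gap) break
      }
    }
  }
  if (length(valid) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      span = integer(0)))
  iv <- do.call(rbind, valid)
  maximal <- vapply(seq_len(nrow(iv)), function(r) {
    !any(iv[, 1L] <= iv[r, 1L] & iv[, 2L] >= iv[r, 2L] &
           (iv[, 1L] < iv[r, 1L] | iv[, 2L] > iv[r, 2L]))
  }, NA)
  iv <- iv[maximal, , drop = FALSE]
  out <- data.frame(start = iv[, 1L], end = iv[, 2L],
                    span = iv[, 2L] - iv[, 1L] + 1L)
  out <- out[out$span >= min_len, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

## Hotspot oracle: examine every window independently, then union
## overlapping qualifying windows as intervals.
hotspot_oracle <- function(positions, L, window = 30L,
                           lo = 0.1, hi = 0.3) {
  occupied <- seq_len(L) %in% positions
  regions <- list()
  cur <- NULL
  for (s in seq_len(L - window + 1L)) {
    dens <- sum(occupied[s:(s + window - 1L)]) / window
    ok <- dens >= lo - 1e-9 && dens <= hi + 1e-9
    if (ok) {
      if (!is.null(cur) && s < cur$next_free) {
        cur$end <- s + window - 1L
        cur$density <- max(cur$density, dens)
        cur$next_free <- s + window
      } else {
        if (!is.null(cur)) regions[[length(regions) + 1L]] <- cur
        cur <- list(start = s, end = s + window - 1L, density = dens,
                    next_free = s + window)
      }
    }
  }
  if (!is.null(cur)) regions[[length(regions) + 1L]] <- cur
  if (length(regions) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      density = numeric(0), band = character(0)))
  out <- do.call(rbind, lapply(regions, function(r)
    data.frame(start = r$start, end = r$end, density = r$density)))
  out$band <- ifelse(out$density >= 0.2 - 1e-9, "high", "low")
  out
}

## MoRF oracle: explicit left-to-right scan.
morf_oracle <- function(scores, min_len = 5L, threshold = 0.5) {
  segs <- list()
  i <- 1L
  L <- length(scores)
  while (i <= L) {
    if (scores[i] >= threshold) {
      j <- i
      while (j < L && scores[j + 1L] >= threshold) j <- j + 1L
      if (j - i + 1L >= min_len)
        segs[[length(segs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(segs) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  m <- do.call(rbind, segs)
  data.frame(start = m[, 1L], end = m[, 2L],
             length = m[, 2L] - m[, 1L] + 1L)
}

## Random unrooted tree with strictly positive branch lengths and its
## additive (path-length) distance matrix.
random_additive_matrix <- function(n_tips) {
  tr <- ape::rtree(n_tips, br = function(n) stats::runif(n, 0.1, 2))
  tr <- ape::unroot(tr)
  dm <- ape::cophenetic.phylo(tr)
  list(tree = tr, d = dm[tr$tip.label, tr$tip.label])
}

## A small, fast simulation config for pipeline-level tests.
small_sim_config <- function(seed = 1L) {
  panel <- data.frame(
    subunit_id = c("Med6", "Med8", "Med19", "Med4", "Med31", "Med15"),
    length = c(150L, 160L, 170L, 180L, 130L, 220L),
    absent_in = c("", "", "", "", "", "fungi"),
    stringsAsFactors = FALSE)
  ## sd 0.01 keeps the reduced 6-subunit panel inside the recovery
  ## precondition (between-group separation >= 3x within-group spread)
  mk <- function(x) stats::setNames(x, panel$subunit_id)
  groups <- list(
    list(name = "metazoa_main", composition = c(metazoa = 8L),
         means = mk(c(0.38, 0.50, 0.67, 0.51, 0.21, 0.59)), sd = 0.01),
    list(name = "plantae_main", composition = c(plantae = 6L),
         means = mk(c(0.39, 0.58, 0.67, 0.56, 0.33, 0.61)), sd = 0.01),
    list(name = "fungi_main", composition = c(fungi = 6L),
         means = mk(c(0.41, 0.45, 0.61, 0.52, 0.27, NA)), sd = 0.01),
    list(name = "basal", composition = c(metazoa = 2L, fungi = 2L),
         means = mk(c(0.22, 0.25, 0.30, 0.28, 0.15, 0.30)), sd = 0.01))
  simulation_config(groups = groups, subunits = panel, seed = seed)
}

expect_same_segments <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  if (nrow(want) > 0L) {
    expect_equal(got$start, want$start, ignore_attr = TRUE)
    expect_equal(got$end, want$end, ignore_attr = TRUE)
  }
}
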