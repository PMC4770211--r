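#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test with midranks for ties. `method = "exact"` enumerates all
#' label assignments of the pooled sample (feasible for small samples,
#' undefined bias from ties avoided by refusing tied exact requests in
#' `"auto"`); `"normal_approx"` uses the tie-corrected normal
#' approximation with a 0.5 continuity correction. `"auto"` picks exact
#' when `min(n) <= 8` and there are no ties, otherwise the approximation.
#'
#' @param a,b Numeric samples (non-empty).
#' @param method `"auto"`, `"exact"`, or `"normal_approx"`.
#' @return List with `U` (statistic of the first sample), `p_value`
#'   (two-sided, capped at 1), and `method` actually used.
#' @export
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("samples must not contain NA", call. = FALSE)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (method == "auto")
    method <- if (min(n1, n2) <= 8L && !ties) "exact" else "normal_approx"
  mu <- n1 * n2 / 2
  if (method == "exact") {
    if (choose(N, n1) > 5e6)
      stop("sample sizes too large for exact enumeration", call. = FALSE)
    idx <- utils::combn(N, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    tie_tab <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(U - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  list(U = U, p_value = p, method = method)
}

#' Table-style rank-order string for three kingdoms
#'
#' Summarises per-subunit kingdom comparisons the way the disorder
#' comparison table prints them: kingdoms ordered by decreasing mean
#' average disorder, adjacent pairs joined by `">"` when their pairwise
#' Mann-Whitney p-value is below `alpha` and by `"="` otherwise. Within a
#' maximal run of `"="`-connected kingdoms the letters are printed in the
#' fixed display order P, M, F (the convention the published table
#' follows, e.g. "P=M=F" even when the P/M/F means differ slightly).
#' Only the simple linear form is produced; non-adjacent significance is
#' available from the full p-value triple.
#'
#' @param means Named numeric vector with entries `M`, `P`, `F`.
#' @param pvals Named numeric vector with entries `MP`, `MF`, `PF`.
#' @param alpha Significance level (default 0.05).
#' @return A string such as `"P>M>F"` or `"P=M=F"`.
#' @export
rank_order_string <- function(means, pvals, alpha = 0.05) {
  need_m <- c("M", "P", "F"); need_p <- c("MP", "MF", "PF")
  if (!all(need_m %in% names(means)) || anyNA(means[need_m]))
    stop("means must be named M, P, F and non-missing", call. = FALSE)
  if (!all(need_p %in% names(pvals)) || anyNA(pvals[need_p]))
    stop("pvals must be named MP, MF, PF and non-missing", call. = FALSE)
  means <- means[need_m]
  display <- c("P", "M", "F")
  ord <- order(-means, match(names(means), display))
  chain <- names(means)[ord]
  pair_p <- function(x, y) {
    key <- paste(sort(c(x, y), method = "radix"), collapse = "")
    if (key %in% names(pvals)) return(pvals[[key]])
    key2 <- paste0(substr(key, 2, 2), substr(key, 1, 1))
    pvals[[key2]]
  }
  rel <- vapply(seq_len(2L), function(i) {
    p <- pair_p(chain[i], chain[i + 1L])
    if (p < alpha && means[chain[i]] != means[chain[i + 1L]]) ">" else "="
  }, "")
  grp <- cumsum(c(1L, as.integer(rel == ">")))
  parts <- vapply(split(chain, grp), function(ks)
    paste(ks[order(match(ks, display))], collapse = "="), "")
  paste(parts, collapse = ">")
}

#' Kingdom comparison table for subunit average disorder
#'
#' Builds the per-subunit summary comparing metazoa (M), plantae (P) and
#' fungi (F): per-kingdom mean and sd of average disorder, the three
#' pairwise two-sided Mann-Whitney p-values, significance flags at
#' `alpha`, and the rank-order string. Raw p-values are reported; no
#' multiple-testing correction is applied.
#'
#' @param averages Data frame with columns `organism_id`, `kingdom`,
#'   `subunit_id`, `avg_disorder` (one row per organism/subunit).
#' @param alpha Significance level.
#' @param method Mann-Whitney method, see [mann_whitney_u()].
#' @return Data frame with one row per subunit.
#' @export
kingdom_comparison <- function(averages, alpha = 0.05, method = "auto") {
  need <- c("organism_id", "kingdom", "subunit_id", "avg_disorder")
  if (!all(need %in% names(averages)))
    stop("averages must have columns organism_id, kingdom, subunit_id, avg_disorder",
         call. = FALSE)
  letters3 <- c(metazoa = "M", plantae = "P", fungi = "F")
  averages <- averages[averages$kingdom %in% names(letters3), , drop = FALSE]
  out <- lapply(split(averages, averages$subunit_id), function(df) {
    smp <- lapply(names(letters3), function(k)
      df$avg_disorder[df$kingdom == k])
    names(smp) <- letters3
    mns <- vapply(smp, function(x) if (length(x)) mean(x) else NA_real_, 0)
    sds <- vapply(smp, function(x) if (length(x) > 1L) stats::sd(x) else NA_real_, 0)
    pv <- c(MP = NA_real_, MF = NA_real_, PF = NA_real_)
    for (pr in list(c("M", "P"), c("M", "F"), c("P", "F"))) {
      key <- paste0(pr[1L], pr[2L])
      if (length(smp[[pr[1L]]]) > 0L && length(smp[[pr[2L]]]) > 0L)
        pv[key] <- mann_whitney_u(smp[[pr[1L]]], smp[[pr[2L]]],
                                  method = method)$p_value
    }
    ro <- if (!anyNA(mns) && !anyNA(pv))
      rank_order_string(mns, pv, alpha = alpha)
    else NA_character_
    data.frame(subunit_id = df$subunit_id[1L],
               n_M = length(smp$M), n_P = length(smp$P), n_F = length(smp$F),
               mean_M = mns[["M"]], sd_M = sds[["M"]],
               mean_P = mns[["P"]], sd_P = sds[["P"]],
               mean_F = mns[["F"]], sd_F = sds[["F"]],
               p_MP = pv[["MP"]], p_MF = pv[["MF"]], p_PF = pv[["PF"]],
               sig_MP = !is.na(pv[["MP"]]) & pv[["MP"]] < alpha,
               sig_MF = !is.na(pv[["MF"]]) & pv[["MF"]] < alpha,
               sig_PF = !is.na(pv[["PF"]]) & pv[["PF"]] < alpha,
               rank_order = ro,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
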