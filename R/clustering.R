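#' Organisms-by-subunits average disorder matrix
#'
#' Aggregates [average_disorder()] over a profile set into a numeric grid
#' (rows = organisms, columns = subunits) with a presence mask marking
#' which subunits were found in which organisms (e.g. Med1 is absent in
#' plants, Med26 in fungi).
#'
#' @param profiles List of [disorder_profile()] objects with unique
#'   (organism, subunit) pairs.
#' @return An object of class `subunit_disorder_matrix`: a list with
#'   `values` (numeric matrix, `NA` where absent), `present` (logical
#'   matrix), and `kingdoms` (named by organism).
#' @export
build_disorder_matrix <- function(profiles) {
  stopifnot(length(profiles) > 0L)
  orgs <- vapply(profiles, function(p) p$organism_id, "")
  subs <- vapply(profiles, function(p) p$subunit_id, "")
  key <- paste(orgs, subs, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("duplicate (organism, subunit) pair: %s",
                 sub("\r", " / ", key[duplicated(key)][1L])), call. = FALSE)
  u_org <- unique(orgs)
  u_sub <- unique(subs)
  values <- matrix(NA_real_, length(u_org), length(u_sub),
                   dimnames = list(u_org, u_sub))
  for (p in profiles)
    values[p$organism_id, p$subunit_id] <- average_disorder(p)
  kingdoms <- vapply(profiles, function(p) p$kingdom, "")[match(u_org, orgs)]
  names(kingdoms) <- u_org
  structure(list(values = values, present = !is.na(values),
                 kingdoms = kingdoms),
            class = "subunit_disorder_matrix")
}

#' @export
print.subunit_disorder_matrix <- function(x, ...) {
  cat(sprintf("<subunit_disorder_matrix> %d organisms x %d subunits (%.1f%% present)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$present)))
  invisible(x)
}

#' Euclidean disorder distance between two organisms
#'
#' Distance between organisms X and Y is the root of the sum of squared
#' differences in average disorder over corresponding subunits. Subunits
#' absent in either organism are handled by `policy`: `"shared_only"`
#' (default) sums over the shared subunits only; `"shared_rescaled"`
#' multiplies that value by `sqrt(n_total / n_shared)` so organisms with
#' few shared subunits are not artificially close.
#'
#' @param x,y Numeric rows of average disorder (may contain `NA`).
#' @param policy Missing-subunit policy.
#' @param n_total Panel size used by `"shared_rescaled"` (defaults to
#'   `length(x)`).
#' @return A non-negative number.
#' @export
euclidean_disorder_distance <- function(x, y,
                                        policy = c("shared_only",
                                                   "shared_rescaled"),
                                        n_total = length(x)) {
  policy <- match.arg(policy)
  shared <- !is.na(x) & !is.na(y)
  n_shared <- sum(shared)
  if (n_shared == 0L)
    stop("no shared subunits between the two organisms", call. = FALSE)
  d <- sqrt(sum((x[shared] - y[shared])^2))
  if (policy == "shared_rescaled") d <- d * sqrt(n_total / n_shared)
  d
}

#' All-pairs disorder distance matrix
#'
#' @param m A `subunit_disorder_matrix` from [build_disorder_matrix()].
#' @inheritParams euclidean_disorder_distance
#' @return Symmetric numeric matrix with zero diagonal, organism labels as
#'   dimnames.
#' @export
disorder_distance_matrix <- function(m, policy = c("shared_only",
                                                   "shared_rescaled")) {
  stopifnot(inherits(m, "subunit_disorder_matrix"))
  policy <- match.arg(policy)
  v <- m$values
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- euclidean_disorder_distance(
        v[i, ], v[j, ], policy = policy, n_total = ncol(v))
    }
  }
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Symmetric matrix with dimnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_phylip <- function(d, path) {
  labs <- rownames(d)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(formatC(labs[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining: at each step the pair minimising
#' `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)` is joined,
#' with limb lengths from the usual three-point formulas and distances to
#' the new node `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`. Q ties are
#' broken by the lowest (row, column) index. Negative limb lengths are
#' clamped to zero with the deficit transferred to the sister branch so
#' the joined pair's path length is preserved. The last three lineages
#' meet at a trifurcation; a two-taxon input yields a single edge split at
#' its midpoint. On an additive matrix the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param d Symmetric non-negative matrix with zero diagonal and organism
#'   labels as dimnames.
#' @return An unrooted `ape::phylo` tree with the organisms as tips.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d) %||% colnames(d)
  if (is.null(labs))
    stop("distance matrix must carry labels as dimnames", call. = FALSE)
  n <- length(labs)
  if (n < 2L)
    stop("need at least 2 labels", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0) || any(d < 0))
    stop("invalid distance matrix (asymmetric, negative, or non-zero diagonal)",
         call. = FALSE)
  fmt <- function(x) sprintf("%.17g", x)
  if (n == 2L) {
    txt <- sprintf("(%s:%s,%s:%s);", labs[1L], fmt(d[1L, 2L] / 2),
                   labs[2L], fmt(d[1L, 2L] / 2))
    return(ape::read.tree(text = txt))
  }
  rep_nwk <- labs
  D <- d
  while (length(rep_nwk) > 3L) {
    m <- nrow(D)
    Tsum <- rowSums(D)
    Q <- (m - 2) * D - outer(Tsum, Tsum, `+`)
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- D[i, j] / 2 + (Tsum[i] - Tsum[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_rep <- sprintf("(%s:%s,%s:%s)", rep_nwk[i], fmt(li),
                       rep_nwk[j], fmt(lj))
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    rep_nwk <- c(rep_nwk[keep], new_rep)
  }
  la <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  lb <- D[1L, 2L] - la
  lc <- D[1L, 3L] - la
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 rep_nwk[1L], fmt(la), rep_nwk[2L], fmt(lb),
                 rep_nwk[3L], fmt(lc))
  ape::read.tree(text = txt)
}

#' Cut a tree into organism groups
#'
#' Operationalizes reading "major groups" off an NJ dendrogram. Two modes:
#' `"k_groups"` removes the `k - 1` longest internal edges (ties broken by
#' edge order in the tree) and returns the leaf sets of the resulting
#' components; `"length_threshold"` removes every internal edge longer
#' than `tau` times the median internal edge length. Components containing
#' no leaves are dropped.
#'
#' @param tree An `ape::phylo` tree.
#' @param mode Cutting mode.
#' @param k Number of groups (`k_groups` mode).
#' @param tau Multiple of the median internal edge length
#'   (`length_threshold` mode); default 8.
#' @return A list of character vectors of tip labels, ordered by each
#'   group's smallest tip index.
#' @export
cut_groups <- function(tree, mode = c("k_groups", "length_threshold"),
                       k = NULL, tau = 8) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  internal <- tree$edge[, 2L] > ntip
  lens <- tree$edge.length
  drop_edge <- rep(FALSE, nrow(tree$edge))
  if (mode == "k_groups") {
    if (is.null(k) || k < 1L)
      stop("k must be a positive integer", call. = FALSE)
    if (k - 1L > sum(internal))
      stop(sprintf("k = %d exceeds internal edge count + 1 (%d)",
                   k, sum(internal) + 1L), call. = FALSE)
    if (k > 1L) {
      idx <- which(internal)
      idx <- idx[order(-lens[idx])][seq_len(k - 1L)]
      drop_edge[idx] <- TRUE
    }
  } else {
    if (!is.numeric(tau) || tau <= 0)
      stop("tau must be > 0", call. = FALSE)
    if (any(internal)) {
      med <- stats::median(lens[internal])
      drop_edge <- internal & lens > tau * med
    }
  }
  edges <- tree$edge[!drop_edge, , drop = FALSE]
  n_nodes <- max(tree$edge)
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2L),
                                   directed = FALSE)
  g <- igraph::add_vertices(
    g, length(setdiff(as.character(seq_len(n_nodes)),
                      igraph::V(g)$name)),
    name = setdiff(as.character(seq_len(n_nodes)), igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  tip_comp <- comp[as.character(seq_len(ntip))]
  groups <- split(tree$tip.label, tip_comp)
  ord <- order(vapply(groups, function(tips)
    min(match(tips, tree$tip.label)), 0L))
  groups <- groups[ord]
  names(groups) <- paste0("group", seq_along(groups))
  groups
}

#' Flatten groups into an organism/group table
#'
#' @param groups List from [cut_groups()].
#' @return Data frame with columns `organism_id`, `group`.
#' @export
groups_table <- function(groups) {
  data.frame(organism_id = unlist(groups, use.names = FALSE),
             group = rep(names(groups), lengths(groups)),
             stringsAsFactors = FALSE)
}
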