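mk_profile <- function(org, sub, kng, mu, L = 40L) {
  disorder_profile(org, sub, kng, strrep("A", L), rep(mu, L))
}

test_that("the disorder matrix aggregates averages with a presence mask", {
  ps <- list(mk_profile("o1", "s1", "metazoa", 0.2),
             mk_profile("o1", "s2", "metazoa", 0.4),
             mk_profile("o2", "s1", "fungi", 0.5),
             mk_profile("o2", "s2", "fungi", 0.8))
  m <- build_disorder_matrix(ps)
  expect_equal(dim(m$values), c(2L, 2L))
  expect_true(all(m$present))
  expect_equal(m$values["o1", "s2"], 0.4)

  m2 <- build_disorder_matrix(ps[-4L])
  expect_equal(sum(!m2$present), 1L)
  expect_false(m2$present["o2", "s2"])

  expect_error(build_disorder_matrix(c(ps, ps[1L])), "duplicate")
})

test_that("euclidean distance follows the shared-subunit policies", {
  expect_equal(euclidean_disorder_distance(c(0.3, 0.3), c(0.3, 0.3)), 0)
  expect_equal(euclidean_disorder_distance(c(0.2, 0.4), c(0.5, 0.8)), 0.5)
  ## subunit missing in one organism is skipped under shared_only
  expect_equal(euclidean_disorder_distance(c(0.2, 0.4, 0.9),
                                           c(0.5, 0.8, NA)), 0.5)
  expect_equal(euclidean_disorder_distance(c(0.2, 0.4, 0.9),
                                           c(0.5, 0.8, NA),
                                           policy = "shared_rescaled"),
               0.5 * sqrt(3 / 2))
  expect_error(euclidean_disorder_distance(c(NA, 0.4), c(0.5, NA)),
               "no shared")
})

test_that("distance matrices are symmetric, zero-diagonal, and metric under full presence", {
  set.seed(11)
  ps <- list()
  for (o in 1:6) for (s in 1:4)
    ps[[length(ps) + 1L]] <- mk_profile(paste0("o", o), paste0("s", s),
                                        "metazoa", runif(1))
  d <- disorder_distance_matrix(build_disorder_matrix(ps))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_true(all(d >= 0))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("two- and three-taxon neighbor joining give the closed-form limbs", {
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(sort(t2$edge.length), c(0.4, 0.4))

  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  lab <- t3$tip.label[t3$edge[, 2L][t3$edge[, 2L] <= 3L]]
  limb <- t3$edge.length[t3$edge[, 2L] <= 3L]
  expect_equal(limb[match(c("A", "B", "C"), lab)], c(1, 2, 3))
})

test_that("NJ recovers additive matrices exactly and agrees with an independent NJ", {
  set.seed(2024)
  for (i in 1:40) {
    ra <- random_additive_matrix(sample(4:12, 1))
    est <- nj_tree(ra$d)
    d_back <- ape::cophenetic.phylo(est)[rownames(ra$d), colnames(ra$d)]
    expect_lt(max(abs(d_back - ra$d)), 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(est), ra$tree), 0,
                 ignore_attr = TRUE)
    ## independent implementation agrees on the topology
    ref <- ape::nj(ra$d)
    expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("a 4-taxon additive matrix yields the AB|CD split with exact lengths", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  expect_lt(max(abs(ape::cophenetic.phylo(tr)[labs, labs] - d)), 1e-12)
  g <- cut_groups(tr, "k_groups", k = 2)
  expect_equal(sort(unname(vapply(g, paste, "", collapse = ""))),
               c("AB", "CD"))
})

test_that("Newick output round-trips topology and branch lengths", {
  set.seed(77)
  ra <- random_additive_matrix(10)
  tr <- nj_tree(ra$d)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f, digits = 14)
  tr2 <- ape::read.tree(f)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  d1 <- ape::cophenetic.phylo(tr); d2 <- ape::cophenetic.phylo(tr2)
  expect_lt(max(abs(d1 - d2[rownames(d1), colnames(d1)])), 1e-9)
})

test_that("negative limb estimates are clamped without losing path length", {
  ## non-additive matrix known to produce a negative NJ limb
  labs <- paste0("t", 1:4)
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, dimnames = list(labs, labs))
  d["t1", "t2"] <- d["t2", "t1"] <- 8  # forces Q tie-breaks / negatives
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_tree(d), "invalid distance matrix")
  expect_error(nj_tree(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "at least 2")
})

test_that("cut_groups handles k bounds and degenerate star trees", {
  set.seed(5)
  ra <- random_additive_matrix(8)
  tr <- nj_tree(ra$d)
  expect_equal(length(cut_groups(tr, "k_groups", k = 1)), 1L)
  expect_setequal(cut_groups(tr, "k_groups", k = 1)[[1L]], tr$tip.label)
  n_internal <- sum(tr$edge[, 2L] > length(tr$tip.label))
  expect_error(cut_groups(tr, "k_groups", k = n_internal + 2L), "exceeds")
  ## star-like tree: tiny equal internal edges, nothing exceeds tau x median
  star <- ape::read.tree(text = "((A:1,B:1):1e-12,(C:1,D:1):1e-12,E:1);")
  expect_equal(length(cut_groups(star, "length_threshold", tau = 5)), 1L)
})

test_that("four planted disorder groups are recovered from seeded simulations", {
  hits <- 0L
  for (rep in 1:20) {
    cfg <- small_sim_config(seed = 1000L + rep)
    sim <- simulate_profiles(cfg)
    d <- disorder_distance_matrix(build_disorder_matrix(sim$profiles))
    gr <- cut_groups(nj_tree(d), "k_groups", k = 4)
    truth <- split(sim$organisms$organism_id, sim$organisms$group)
    match_all <- length(gr) == length(truth) &&
      all(vapply(gr, function(g)
        any(vapply(truth, function(t) setequal(g, t), NA)), NA))
    hits <- hits + as.integer(match_all)
  }
  expect_gte(hits, 19L)
})

test_that("PHYLIP distance matrix export is well-formed", {
  labs <- c("A", "B", "C")
  d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(labs, labs))
  f <- withr::local_tempfile()
  write_phylip(d, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1L])), 3L)
  expect_equal(length(lines), 4L)
  row2 <- strsplit(trimws(lines[3L]), "\\s+")[[1L]]
  expect_equal(row2[1L], "B")
  expect_equal(as.numeric(row2[-1L]), c(1, 0, 3))
})
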