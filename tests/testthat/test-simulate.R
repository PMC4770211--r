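test_that("profile simulation is a pure function of (config, seed)", {
  cfg <- small_sim_config(seed = 7L)
  s1 <- simulate_profiles(cfg)
  s2 <- simulate_profiles(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_profiles(small_sim_config(seed = 8L))
  k <- names(s1$profiles)[1L]
  expect_false(identical(s1$profiles[[k]]$scores, s3$profiles[[k]]$scores))
  ## simulation restores the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_profiles(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("default study composition matches the designed 146-organism panel", {
  cfg <- simulation_config(seed = 1L)
  n <- vapply(cfg$groups, function(g) sum(g$composition), 0L)
  expect_equal(sum(n), 146L)
  expect_equal(sort(unname(n)), c(15L, 21L, 21L, 89L))
  ## Med1 absent in plants, Med26 in fungi
  sim <- simulate_profiles(cfg)
  mat <- build_disorder_matrix(sim$profiles)
  plants <- names(mat$kingdoms)[mat$kingdoms == "plantae"]
  fungi <- names(mat$kingdoms)[mat$kingdoms == "fungi"]
  expect_false(any(mat$present[plants, "Med1"]))
  expect_false(any(mat$present[fungi, "Med26"]))
  expect_true(all(mat$present[plants, "Med8"]))
})

test_that("planted IDR blocks are recovered by the caller within 2 residues", {
  panel <- data.frame(subunit_id = "MedX", length = 200L, absent_in = "",
                      stringsAsFactors = FALSE)
  ## target mean 0.26 with laws 0.9/0.1 plants a single 40-residue block
  groups <- list(list(name = "g", composition = c(metazoa = 200L),
                      means = c(MedX = 0.26), sd = 0))
  cfg <- simulation_config(groups = groups, subunits = panel,
                           mu_disordered = 0.9, mu_ordered = 0.1,
                           concentration = 30, seed = 42L)
  sim <- simulate_profiles(cfg)
  ok <- 0L; n <- 0L
  for (key in names(sim$profiles)) {
    n <- n + 1L
    truth <- sim$truth$blocks[[key]]
    expect_equal(truth$end - truth$start + 1L, 40L)
    called <- call_idrs(binarize(sim$profiles[[key]]$scores))
    hit <- nrow(called) == 1L &&
      abs(called$start - truth$start) <= 2L &&
      abs(called$end - truth$end) <= 2L
    ok <- ok + as.integer(hit)
  }
  expect_gte(ok / n, 0.95)
})

test_that("group-level sample means land on the configured targets", {
  panel <- data.frame(subunit_id = "MedY", length = 400L, absent_in = "",
                      stringsAsFactors = FALSE)
  targets <- c(0.30, 0.45, 0.60, 0.20)
  groups <- lapply(seq_along(targets), function(i)
    list(name = paste0("g", i), composition = c(metazoa = 30L),
         means = c(MedY = targets[i]), sd = 0.05))
  cfg <- simulation_config(groups = groups, subunits = panel, seed = 3L)
  sim <- simulate_profiles(cfg)
  av <- vapply(sim$profiles, average_disorder, 0)
  grp <- sim$truth$meta$group[match(names(av),
                                    paste(sim$truth$meta$organism_id,
                                          sim$truth$meta$subunit_id,
                                          sep = "|"))]
  got <- tapply(av, grp, mean)[paste0("g", seq_along(targets))]
  expect_true(all(abs(got - targets) < 0.02))
})

test_that("PTM placement is uniform at odds 1 and IDR-enriched at odds > 1", {
  p <- disorder_profile("o", "s", "metazoa", strrep("A", 20000),
                        rep(0.5, 20000))
  blocks <- data.frame(start = c(2001L, 12001L), end = c(6000L, 16000L))
  idr_frac <- 8000 / 20000
  tr <- simulate_ptm_track(p, blocks, rate = 10, idr_odds = 1, seed = 5L)
  expect_gt(nrow(tr), 1500L)
  expect_lt(abs(fraction_in_idr(tr, blocks) - idr_frac), 0.05)

  wins <- 0L
  p2 <- disorder_profile("o", "s", "metazoa", strrep("A", 2000),
                         rep(0.5, 2000))
  b2 <- data.frame(start = 501L, end = 1000L)
  for (i in 1:100) {
    tri <- simulate_ptm_track(p2, b2, rate = 5, idr_odds = 5, seed = i)
    wins <- wins + as.integer(fraction_in_idr(tri, b2) > 0.25)
  }
  expect_gte(wins, 99L)

  empty <- simulate_ptm_track(p2, b2, rate = 0, seed = 1L)
  expect_equal(nrow(empty), 0L)
})

test_that("planted MoRFs are conserved exactly when >= 4 organisms carry them", {
  ms <- simulate_msa_and_morfs(n_organisms = 5L, width = 200L,
                               indel_rate = 0,
                               morf_blocks = data.frame(start = 50L,
                                                        end = 61L),
                               morf_organisms = paste0("org0", 1:4),
                               seed = 9L)
  cov <- lapply(names(ms$alignment), function(o) {
    segs <- call_morfs(ms$morf_scores[[o]])
    unlist(lapply(seq_len(nrow(segs)), function(i)
      map_segment_to_columns(segs$start[i], segs$end[i],
                             ms$alignment[[o]])))
  })
  names(cov) <- names(ms$alignment)
  out <- conserved_morf_regions(cov, width = 200L)
  expect_equal(nrow(out), 1L)
  expect_lte(abs(out$column_start - 50L), 1L)
  expect_lte(abs(out$column_end - 61L), 1L)

  ms3 <- simulate_msa_and_morfs(n_organisms = 5L, width = 200L,
                                indel_rate = 0,
                                morf_blocks = data.frame(start = 50L,
                                                         end = 61L),
                                morf_organisms = paste0("org0", 1:3),
                                seed = 9L)
  cov3 <- lapply(names(ms3$alignment), function(o) {
    segs <- call_morfs(ms3$morf_scores[[o]])
    unlist(lapply(seq_len(nrow(segs)), function(i)
      map_segment_to_columns(segs$start[i], segs$end[i],
                             ms3$alignment[[o]])))
  })
  names(cov3) <- names(ms3$alignment)
  expect_equal(nrow(conserved_morf_regions(cov3, width = 200L)), 0L)
})

test_that("zero indel rate gives an ungapped alignment of full width", {
  ms <- simulate_msa_and_morfs(n_organisms = 4L, width = 120L,
                               indel_rate = 0, seed = 2L)
  expect_true(all(nchar(ms$alignment) == 120L))
  expect_false(any(grepl("-", ms$alignment, fixed = TRUE)))
  expect_error(simulate_msa_and_morfs(n_organisms = 3L), ">= 4")
})

test_that("network simulation plants exactly the requested hubs", {
  net <- simulate_network(n_subunits = 8L, n_external = 120L, n_hubs = 3L,
                          hub_degree = c(12L, 20L),
                          nonhub_degree = c(1L, 6L),
                          p_subunit_edge = 0, seed = 13L)
  tab <- classify_hubs(net$graph)
  hubs <- tab$node[tab$is_hub & tab$is_subunit]
  expect_setequal(hubs, net$truth$hubs)
  expect_equal(length(hubs), 3L)

  ## degree capped at 9 for everyone: no hubs anywhere
  net0 <- simulate_network(n_subunits = 8L, n_external = 50L, n_hubs = 0L,
                           nonhub_degree = c(1L, 9L),
                           p_subunit_edge = 0, seed = 13L)
  expect_equal(sum(classify_hubs(net0$graph)$is_hub), 0L)

  ## determinism: identical seed, identical edge bytes
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_edges(simulate_network(seed = 4L)$graph, f1)
  write_edges(simulate_network(seed = 4L)$graph, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("invalid simulation configs are rejected with named violations", {
  expect_error(simulation_config(mu_disordered = 1.2), "mu_disordered")
  expect_error(simulation_config(mu_disordered = 0.2, mu_ordered = 0.5),
               "exceed")
  expect_error(simulation_config(ptm_idr_odds = 0.5), "ptm_idr_odds")
  panel <- data.frame(subunit_id = "A", length = 100L, absent_in = "")
  expect_error(simulation_config(
    groups = list(list(name = "g", composition = c(metazoa = 0L),
                       means = c(A = 0.5), sd = 0.1)),
    subunits = panel), ">= 1 organism")
})
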