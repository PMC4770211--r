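test_that("exact Mann-Whitney matches full enumeration on the textbook case", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)  # 2 of the 20 assignments as extreme
  expect_equal(res$method, "exact")
})

test_that("identical samples give p = 1", {
  x <- c(1.2, 3.4, 3.4, 5)
  expect_equal(mann_whitney_u(x, x)$p_value, 1)
  expect_equal(mann_whitney_u(rep(2, 5), rep(2, 7))$p_value, 1)
})

test_that("U statistics of the two orientations sum to n1*n2 with equal p", {
  set.seed(31)
  for (i in 1:25) {
    a <- runif(sample(2:10, 1)); b <- runif(sample(2:10, 1))
    r1 <- mann_whitney_u(a, b); r2 <- mann_whitney_u(b, a)
    expect_equal(r1$U + r2$U, length(a) * length(b))
    expect_equal(r1$p_value, r2$p_value)
  }
})

test_that("exact p agrees with the reference implementation when min(n) <= 8", {
  set.seed(67)
  for (i in 1:30) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- rnorm(na); b <- rnorm(nb)
    mine <- mann_whitney_u(a, b, method = "exact")
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE,
                                               correct = FALSE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p for small untied samples", {
  ## Exhaustive over all achievable U: the 0.02 band holds from
  ## min(n) >= 5; for the tiniest samples the true worst-case gap is
  ## larger (0.088 at n = 2,2) and is pinned here instead.
  worst_by_min_n <- c(`2` = 0.089, `3` = 0.038, `4` = 0.031)
  for (na in 2:8) {
    for (nb in na:10) {
      N <- na + nb
      comb <- utils::combn(N, na)
      Us <- colSums(matrix(seq_len(N)[comb], nrow = na)) -
        na * (na + 1) / 2
      band <- if (na >= 5L) 0.02 else worst_by_min_n[[as.character(na)]]
      u_idx <- match(unique(Us), Us)
      if (length(u_idx) > 20L)  # thin the grid for the largest pairs
        u_idx <- u_idx[round(seq(1L, length(u_idx), length.out = 15L))]
      for (hit in u_idx) {
        x <- comb[, hit]; y <- setdiff(seq_len(N), x)
        pe <- mann_whitney_u(x, y, method = "exact")$p_value
        pn <- mann_whitney_u(x, y, method = "normal_approx")$p_value
        expect_lte(abs(pe - pn), band)
      }
    }
  }
})

test_that("ties are handled with midranks and a tie-corrected variance", {
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  mine <- mann_whitney_u(a, b, method = "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  ## auto must not attempt exact enumeration in the presence of ties
  expect_equal(mann_whitney_u(a, b)$method, "normal_approx")
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("rank order strings reproduce the published subunit rows", {
  ## Med8: plants above metazoans above fungi, all pairs significant
  expect_equal(rank_order_string(
    c(M = 0.50, P = 0.58, F = 0.45),
    c(MP = 7.211e-07, MF = 0.016, PF = 1.810e-05)), "P>M>F")
  ## Med9: no significant pair; printed in fixed display order
  expect_equal(rank_order_string(
    c(M = 0.50, P = 0.56, F = 0.51),
    c(MP = 0.145, MF = 0.650, PF = 0.484)), "P=M=F")
  ## all equal means / p = 1 collapses to one equality group
  expect_equal(rank_order_string(c(M = 0.4, P = 0.4, F = 0.4),
                                 c(MP = 1, MF = 1, PF = 1)), "P=M=F")
  ## mixed: one significant adjacent pair
  expect_equal(rank_order_string(c(M = 0.50, P = 0.58, F = 0.49),
                                 c(MP = 0.01, MF = 0.6, PF = 0.02)),
               "P>M=F")
  expect_error(rank_order_string(c(M = 1, P = 1), c(MP = 1, MF = 1, PF = 1)),
               "named M, P, F")
})

test_that("kingdom comparison table carries means, p-values and flags", {
  set.seed(12)
  av <- rbind(
    data.frame(organism_id = paste0("m", 1:12), kingdom = "metazoa",
               subunit_id = "Med8", avg_disorder = rnorm(12, 0.50, 0.03)),
    data.frame(organism_id = paste0("p", 1:12), kingdom = "plantae",
               subunit_id = "Med8", avg_disorder = rnorm(12, 0.70, 0.03)),
    data.frame(organism_id = paste0("f", 1:12), kingdom = "fungi",
               subunit_id = "Med8", avg_disorder = rnorm(12, 0.30, 0.03)))
  tab <- kingdom_comparison(av)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$rank_order, "P>M>F")
  expect_true(tab$sig_MP && tab$sig_MF && tab$sig_PF)
  expect_equal(tab$n_M, 12L)
  expect_lt(abs(tab$mean_P - 0.70), 0.05)
  ## a subunit absent from one kingdom yields NA p-values, no rank order
  av2 <- av[av$kingdom != "plantae", ]
  av2$subunit_id <- "Med26"
  tab2 <- kingdom_comparison(rbind(av, av2))
  expect_true(is.na(tab2$p_MP[tab2$subunit_id == "Med26"]))
  expect_true(is.na(tab2$rank_order[tab2$subunit_id == "Med26"]))
})

test_that("type-I error of the test is calibrated near alpha", {
  set.seed(88)
  rej <- 0L
  n_rep <- 400L
  for (i in seq_len(n_rep)) {
    p <- mann_whitney_u(rnorm(20), rnorm(20))$p_value
    rej <- rej + as.integer(p < 0.05)
  }
  expect_gte(rej / n_rep, 0.025)
  expect_lte(rej / n_rep, 0.075)
})
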