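test_that("Fisher exact test reproduces known tables and degenerate cases", {
  expect_equal(round(fisher_exact_2x2(8, 3, 5, 13), 3), 0.027)
  expect_equal(round(fisher_exact_2x2(6, 25, 6, 9), 3), 0.165)
  expect_equal(round(fisher_exact_2x2(11, 20, 10, 5), 3), 0.063)
  expect_equal(fisher_exact_2x2(0, 5, 0, 7), 1.0)  # degenerate column
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "empty")
})

test_that("Fisher exact agrees with stats::fisher.test across random tables", {
  set.seed(31)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  }
})

test_that("Fisher exact is invariant under simultaneous row and column swaps", {
  set.seed(32)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(fisher_exact_2x2(tab),
                 fisher_exact_2x2(tab[2:1, 2:1]), tolerance = 1e-12)
  }
})

test_that("hypergeometric point probabilities sum to one", {
  # spot normalization here; the full margins-to-60 sweep is an
  # acceptance-level check
  for (m in list(c(5, 7, 4), c(10, 3, 6), c(20, 20, 13))) {
    h <- alsmet:::hyper2x2_logprob(m[1], m[2], m[3])
    expect_equal(sum(exp(h$logp)), 1, tolerance = 1e-14)
  }
})

test_that("Mann-Whitney exact p matches enumeration and printed examples", {
  r1 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p.value, 2 / 6)
  expect_equal(r1$method, "exact")

  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$p.value, 0.1)  # 2 / choose(6, 3)

  set.seed(33)
  for (rep in 1:25) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    expect_equal(mann_whitney_u(x, y)$p.value, oracle_mwu_exact_p(x, y))
  }
})

test_that("Mann-Whitney approximation handles ties like the platform default", {
  x <- c(1, 1, 2, 2, 3, 5, 5, 8)
  y <- c(2, 3, 3, 4, 5, 6, 6, 9, 9)
  mine <- mann_whitney_u(x, y)
  expect_equal(mine$method, "normal approximation")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                             exact = FALSE))
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)

  # identical multisets: U at its null mean, p = 1
  same <- mann_whitney_u(c(3, 3, 7, 9), c(3, 3, 7, 9))
  expect_equal(same$p.value, 1)

  # large samples switch to the approximation even without ties
  big <- mann_whitney_u(seq(0.5, 11, by = 1), seq(1, 12, by = 1.01))
  expect_equal(big$method, "normal approximation")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Spearman correlation matches the rank definition", {
  expect_equal(spearman_rank(1:6, (1:6)^3)$statistic, 1)
  expect_equal(spearman_rank(1:6, -(1:6))$statistic, -1)
  r <- spearman_rank(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(r$statistic, 0.8)  # 1 - 6*4 / (5*24)

  # equals Pearson on ranks for tie-free data; p matches cor.test t approx
  set.seed(34)
  x <- rnorm(20); y <- x + rnorm(20)
  mine <- spearman_rank(x, y)
  expect_equal(mine$statistic, stats::cor(rank(x), rank(y)))
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)

  expect_error(spearman_rank(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rank(1:3, 1:3), "4 complete pairs")
})

test_that("median [IQR] uses type-7 interpolation", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)), c(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(c(1, 2, 3, 4)),
               c(median = 2.5, q1 = 1.75, q3 = 3.25))
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  expect_true(all(is.na(median_iqr(c(NA_real_, NA_real_)))))
})

test_that("compare_groups reproduces its per-variable tests exactly", {
  set.seed(35)
  n1 <- 11; n2 <- 18
  df <- data.frame(
    grp = rep(c(TRUE, FALSE), c(n1, n2)),
    peg = c(rep(c(TRUE, FALSE), c(8, 3)), rep(c(TRUE, FALSE), c(5, 13))),
    age = c(rnorm(n1, 72, 5), rnorm(n2, 69, 6)),
    gone = NA_real_,
    flat = 1.0
  )
  df$gone[df$grp] <- rnorm(n1)  # fully missing in one group
  tab <- compare_groups(df, "grp", c("peg", "age", "gone", "flat"))

  expect_equal(round(tab$p[tab$variable == "peg"], 3), 0.027)
  expect_equal(tab$p[tab$variable == "age"],
               mann_whitney_u(df$age[df$grp], df$age[!df$grp])$p.value)
  expect_true(is.na(tab$p[tab$variable == "gone"]))
  expect_equal(tab$n_FALSE[tab$variable == "gone"], 0)
  expect_equal(tab$p[tab$variable == "flat"], 1)  # identical across groups
  expect_error(compare_groups(df, "grp", "nope"), "unknown variable")
  expect_error(compare_groups(df, "flat", "age"), "two observed levels")
})
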