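test_that("Kruskal-Wallis matches hand computation and naive-rank oracle", {
  # no ties: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1) = 27/7
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$H, 27 / 7, tolerance = 1e-12)
  expect_equal(res$p, stats::pchisq(27 / 7, 1, lower.tail = FALSE))
  # randomized small cases with ties vs the pairwise-counting oracle
  withr::with_seed(21, {
    for (rep in 1:25) {
      k <- sample(2:4, 1)
      groups <- lapply(seq_len(k), function(i)
        sample(1:4, sample(2:4, 1), replace = TRUE))
      if (length(unique(unlist(groups))) == 1) next
      expect_equal(kruskal_wallis(groups)$H, naive_kw_H(groups),
                   tolerance = 1e-10)
    }
  })
})

test_that("Kruskal-Wallis degenerate and invariance conventions", {
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2))), list(H = 0, p = 1))
  g1 <- c(3, 1, 4, 1, 5)
  g2 <- c(9, 2, 6)
  a <- kruskal_wallis(list(g1, g2))
  b <- kruskal_wallis(list(sample(g1), sample(g2)))
  expect_equal(a, b)
  expect_error(kruskal_wallis(list(c(1, 2))), "2")
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))), "non-empty")
})

test_that("Dunn z matches the hand formula, oracle, and antisymmetry", {
  res <- dunn_vs_reference(1:6, rep(c("A", "B"), each = 3), "A")
  expect_equal(res$z, 3 / sqrt(3.5 * 2 / 3), tolerance = 1e-12)
  expect_equal(res$p_raw, 2 * stats::pnorm(-res$z))
  # swap group and reference: z negated, p unchanged
  swp <- dunn_vs_reference(1:6, rep(c("A", "B"), each = 3), "B")
  expect_equal(swp$z, -res$z)
  expect_equal(swp$p_raw, res$p_raw)
  # naive-rank oracle on small tied samples, three groups
  withr::with_seed(22, {
    for (rep in 1:25) {
      v <- sample(1:5, 8, replace = TRUE)
      g <- sample(c("A", "A", "A", "B", "B", "B", "C", "C"))
      got <- dunn_vs_reference(v, g, "C")
      for (i in seq_len(nrow(got)))
        expect_equal(got$z[i], naive_dunn_z(v, g, got$group[i], "C"),
                     tolerance = 1e-10)
    }
  })
})

test_that("two-group Dunn equals the rank-sum normal approximation", {
  withr::with_seed(23, {
    for (rep in 1:50) {
      n1 <- sample(3:8, 1)
      n2 <- sample(3:8, 1)
      v <- sample(seq_len(n1 + n2))  # no ties
      g <- rep(c("A", "B"), c(n1, n2))
      z <- dunn_vs_reference(v, g, "A")$z
      # Wilcoxon rank-sum normal approximation (no continuity correction)
      W <- sum(naive_ranks(v)[g == "B"])
      z_rs <- (W - n2 * (n1 + n2 + 1) / 2) /
        sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
      expect_equal(z, z_rs, tolerance = 1e-10)
    }
  })
})

test_that("null Dunn z is standard normal over Monte-Carlo replicates", {
  zs <- vapply(1:1000, function(seed) {
    withr::with_seed(3000 + seed, {
      v <- rnorm(60)
      g <- rep(c("A", "B"), each = 30)
      dunn_vs_reference(v, g, "A")$z
    })
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.1)
  expect_lt(abs(stats::sd(zs) - 1), 0.1)
})

test_that("Holm adjustment matches step-down enumeration and p.adjust", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.30)), c(0.03, 0.04, 0.30))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  withr::with_seed(24, {
    for (rep in 1:20) {
      p <- round(runif(sample(1:5, 1)), 3)
      expect_equal(holm_adjust(p), naive_holm(p), tolerance = 1e-12)
    }
  })
})

test_that("Holm adjustment dominates raw p and preserves their order", {
  withr::with_seed(25, {
    p <- runif(12)
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # monotone
  })
})

test_that("screen_panel recovers a planted shift with the right sign", {
  cfg <- default_cohort_config(effect_size = 0, seed = 7)
  cfg$groups$n <- rep(40L, nrow(cfg$groups))
  cfg$effects["TRAP1", "LC"] <- 2
  co <- generate_cohort(cfg)
  st <- screen_panel(co$matrix, co$groups)
  rec <- st[st$protein == "TRAP1" & st$contrast == "LC", ]
  expect_gt(rec$dunn_z, 0)
  expect_lt(rec$p_adj, 0.05)
  expect_gt(rec$kw_H, 0)
})

test_that("screening table has the six CTL contrasts and coherent p-values", {
  co <- generate_cohort(default_cohort_config(seed = 10))
  st <- screen_panel(co$matrix, co$groups)
  expect_equal(nrow(st), ncol(co$matrix) * 6)
  expect_setequal(unique(st$contrast),
                  c("GC", "EC", "LC", "BC", "CCA", "CRC"))
  expect_true(all(st$p_adj >= st$p_raw))
  expect_true(all(st$p_raw >= 0 & st$p_adj <= 1))
  # signed statistic agrees with the rank-mean direction
  keep7 <- co$groups %in% c("CTL", "GC", "EC", "LC", "BC", "CCA", "CRC")
  r <- rank(co$matrix[keep7, "TRAP1"])
  g7 <- co$groups[keep7]
  dir <- sign(as.vector(tapply(r, g7, mean)[unique(st$contrast)]) -
                mean(r[g7 == "CTL"]))
  z_tr <- st$dunn_z[st$protein == "TRAP1"][match(
    unique(st$contrast), st$contrast[st$protein == "TRAP1"])]
  expect_equal(sign(z_tr), dir)
  wide <- screening_wide(st)
  expect_equal(nrow(wide), 6)
  expect_equal(ncol(wide), 1 + 2 * ncol(co$matrix))
  # missing required group errors
  keep <- co$groups != "CTL"
  expect_error(screen_panel(co$matrix[keep, ], co$groups[keep]), "CTL")
})

test_that("global Holm family is at least as conservative as per-protein", {
  co <- generate_cohort(default_cohort_config(seed = 13))
  per <- screen_panel(co$matrix, co$groups, family = "protein")
  glob <- screen_panel(co$matrix, co$groups, family = "global")
  expect_true(all(glob$p_adj >= per$p_adj - 1e-12))
})

test_that("constant matrix yields all-zero z statistics", {
  co <- generate_cohort(default_cohort_config(seed = 1))
  m <- co$matrix
  m[] <- 1
  st <- screen_panel(m, co$groups)
  expect_true(all(st$dunn_z == 0))
  expect_true(all(st$kw_H == 0))
  expect_true(all(st$p_adj == 1))
})
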