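# independent enumeration oracles ----------------------------------------

# exact binomial tail by direct summation of the mass function
binom_tail_oracle <- function(k, n, p, direction) {
  probs <- vapply(0:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), numeric(1))
  switch(direction,
         greater = sum(probs[(k + 1):(n + 1)]),
         less = sum(probs[1:(k + 1)]),
         two.sided = sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
}

# two-sided Fisher p by enumerating all tables with the observed margins
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(a) dhyper(a, r1, r2, c1), numeric(1))
  obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("exact binomial test and CI reproduce the enumeration oracle and edge cases", {
  expect_equal(exact_binomial_test(1, 1, 0.5, "greater"), 0.5)
  for (n in c(3, 7, 12)) {
    for (k in 0:n) {
      for (dir in c("greater", "less", "two.sided")) {
        expect_equal(exact_binomial_test(k, n, 0.4, dir),
                     binom_tail_oracle(k, n, 0.4, dir), tolerance = 1e-12,
                     info = sprintf("k=%d n=%d %s", k, n, dir))
      }
    }
  }
  expect_error(exact_binomial_test(5, 4), class = "adaptbias_domain_error")

  expect_equal(unname(clopper_pearson_ci(0, 20)[1]), 0)
  expect_equal(unname(clopper_pearson_ci(20, 20)[2]), 1)
  # beta-quantile representation against the search-based definition
  ci <- clopper_pearson_ci(13, 20)
  expect_equal(exact_binomial_test(13, 20, ci[["lower"]], "greater"), 0.025,
               tolerance = 1e-9)
  expect_equal(exact_binomial_test(13, 20, ci[["upper"]], "less"), 0.025,
               tolerance = 1e-9)
})

test_that("Fisher's exact test matches brute-force enumeration for small tables", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  set.seed(12)
  checked <- 0
  for (total in 8:14) {
    for (rep in 1:20) {
      cells <- as.numeric(stats::rmultinom(1, total, rep(0.25, 4)))
      tab <- matrix(cells, 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab), fisher_oracle(tab), tolerance = 1e-12)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
  # invariant to swapping both rows and both columns
  tab <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(fisher_exact(tab), fisher_exact(tab[2:1, 2:1]))
  expect_error(fisher_exact(matrix(c(0, 0, 3, 9), 2, byrow = TRUE)),
               class = "adaptbias_domain_error")
})

test_that("exact binomial power reproduces the design value and is monotone", {
  pw <- exact_binomial_power(130, 0.5, 0.65, 0.025)
  expect_equal(pw$power, 0.928, tolerance = 0.001 / 0.928)
  expect_lte(pw$achieved_size, 0.025)

  # p1 = p0: power equals the achieved size
  pw0 <- exact_binomial_power(130, 0.5, 0.5, 0.025)
  expect_equal(pw0$power, pw0$achieved_size)
  expect_lte(pw0$power, 0.025)

  # Monte-Carlo oracle at the design point
  set.seed(401)
  mc <- mean(rbinom(1e5, 130, 0.65) >= pw$critical_k)
  expect_equal(pw$power, mc, tolerance = 0.005 / pw$power)

  # monotone in p1 and in n
  p_grid <- seq(0.55, 0.8, by = 0.05)
  pows <- vapply(p_grid, function(p) exact_binomial_power(130, 0.5, p)$power, numeric(1))
  expect_true(all(diff(pows) > 0))
  n_grid <- c(50, 80, 130, 200)
  pows_n <- vapply(n_grid, function(n) exact_binomial_power(n)$power, numeric(1))
  expect_true(all(diff(pows_n) > 0))

  # alpha unreachable at tiny n
  pw_small <- exact_binomial_power(3, 0.5, 0.65, 0.025)
  expect_false(pw_small$alpha_reachable)
  expect_equal(pw_small$power, 0)
})

test_that("Clopper-Pearson intervals reach nominal coverage at the study design point", {
  set.seed(88)
  k <- rbinom(3000, 169, 0.65)
  ci <- vapply(k, function(kk) clopper_pearson_ci(kk, 169), numeric(2))
  covered <- ci[1, ] <= 0.65 & 0.65 <= ci[2, ]
  expect_gte(mean(covered), 0.95)
})

test_that("the location-adjusted scale test behaves under null, scale shift, and permutation oracle", {
  # mirror-symmetric groups with identical spread: no evidence
  g1 <- c(-2, -1, 0, 1, 2) + 10
  g2 <- c(-2, -1, 0, 1, 2) - 5
  r <- ansari_bradley_scale_test(c(g1, g2), rep(c("a", "b"), each = 5), exact = FALSE)
  expect_equal(r$statistic, 0, tolerance = 1e-9)
  expect_gte(r$p_value, 0.99)

  # power against a 3x scale ratio (the two-sided AB test rejects at the
  # package's 0.05 reporting level in the large majority of draws)
  set.seed(19)
  pvals <- vapply(1:100, function(i) {
    x <- rnorm(20); y <- rnorm(20, sd = 3)
    ansari_bradley_scale_test(c(x, y), rep(c("a", "b"), each = 20),
                              exact = FALSE)$p_value
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.8)

  # two-sample scores agree with the canonical Ansari-Bradley implementation
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(7, sd = 2)
    mine <- ansari_bradley_scale_test(c(x, y), rep(c("a", "b"), c(8, 7)),
                                      exact = FALSE)
    ref <- suppressWarnings(stats::ansari.test(x - median(x), y - median(y),
                                               exact = FALSE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  }

  # chi-square approximation tracks the exact permutation p at pooled n <= 12
  set.seed(23)
  gaps <- vapply(1:10, function(i) {
    x <- rnorm(6); y <- rnorm(6, sd = 2)
    approx_p <- ansari_bradley_scale_test(c(x, y), rep(c("a", "b"), each = 6),
                                          exact = FALSE)$p_value
    exact_p <- ansari_bradley_scale_test(c(x, y), rep(c("a", "b"), each = 6),
                                         exact = TRUE)$p_value
    abs(approx_p - exact_p)
  }, numeric(1))
  expect_lt(max(gaps), 0.15)
  expect_lt(median(gaps), 0.05)

  # constant group after centring is flagged but still computes
  rc <- ansari_bradley_scale_test(c(1, 1, 1, rnorm(5)), rep(c("a", "b"), c(3, 5)),
                                  exact = FALSE)
  expect_true(rc$degenerate)
  expect_error(ansari_bradley_scale_test(1:5, rep("a", 5)),
               class = "adaptbias_domain_error")
})

test_that("cross-over schedules satisfy the design constraints with balanced carryover", {
  s <- generate_crossover(seed = 7)
  expect_equal(nrow(s), 390)
  trip <- dplyr::count(s, physician_id, case_id, algorithm)
  expect_true(all(trip$n == 1))
  expect_equal(nrow(trip), 390)
  per <- dplyr::count(s, physician_id, session)
  expect_true(all(per$n == 10))
  # within a session every case appears exactly once
  cs <- dplyr::count(s, physician_id, session, case_id)
  expect_true(all(cs$n == 1))
  # preceding algorithm matches the same case in the previous session
  prev <- s |>
    dplyr::group_by(physician_id, case_id) |>
    dplyr::arrange(session, .by_group = TRUE) |>
    dplyr::mutate(chk = dplyr::lag(algorithm)) |>
    dplyr::ungroup()
  expect_identical(prev$chk, prev$preceding_algorithm)

  # 13 physicians: off-diagonal carryover counts within 1 of each other
  m <- carryover_matrix(s)
  off <- m[row(m) != col(m)]
  expect_lte(diff(range(off)), 1)
  expect_equal(sum(off), 13 * 10 * 2)

  # 12 physicians divide the 6 Williams-type sequences exactly
  m12 <- carryover_matrix(generate_crossover(n_physicians = 12, seed = 3))
  off12 <- m12[row(m12) != col(m12)]
  expect_equal(diff(range(off12)), 0)

  # determinism and the degenerate single-pair design
  expect_identical(generate_crossover(seed = 5), generate_crossover(seed = 5))
  s1 <- generate_crossover(n_physicians = 1, n_cases = 1, seed = 2)
  expect_equal(sort(s1$algorithm), sort(algorithm_labels()))
  expect_error(generate_crossover(sessions = 2), class = "adaptbias_domain_error")
})
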