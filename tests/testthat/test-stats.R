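test_that("Friedman statistic matches hand ranking and trivial cases", {
  same <- matrix(rep(c(1, 2, 3), each = 3), 3, 3)
  r0 <- friedman_rank(t(same) * 0 + 5)  # all columns identical
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  ordered <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), 3, 3)
  r1 <- friedman_rank(ordered)
  expect_equal(r1$statistic, 6.0)
  expect_equal(r1$df, 2)

  expect_error(friedman_rank(matrix(1, 1, 3)), "at least 2")
})

test_that("Friedman chi-square p is close to the exact permutation law", {
  tb <- matrix(c(1.2, 0.8, 2.0, 1.9,
                 2.1, 1.1, 2.5, 2.4,
                 3.3, 0.9, 2.6, 3.0), 4, 3)
  got <- friedman_rank(tb)
  # exact oracle: enumerate all (3!)^4 within-row permutation assignments
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  stat_of <- function(m) {
    r <- t(apply(m, 1, rank))
    n <- nrow(m); k <- ncol(m)
    12 / (n * k * (k + 1)) * sum((colSums(r) - n * (k + 1) / 2)^2)
  }
  obs <- stat_of(tb)
  cnt <- 0L; tot <- 0L
  for (p1 in 1:6) for (p2 in 1:6) for (p3 in 1:6) for (p4 in 1:6) {
    m <- rbind(tb[1, perms[[p1]]], tb[2, perms[[p2]]],
               tb[3, perms[[p3]]], tb[4, perms[[p4]]])
    tot <- tot + 1L
    if (stat_of(m) >= obs - 1e-12) cnt <- cnt + 1L
  }
  p_exact <- cnt / tot
  # chi-square approximation documented accuracy at n = 4
  expect_lt(abs(got$p_value - p_exact), 0.1)
})

test_that("Wilcoxon signed-rank exact p matches full sign enumeration", {
  x <- c(5.1, 4.2, 6.3, 3.0, 7.7, 5.9)
  y <- c(4.0, 4.9, 5.1, 3.4, 6.1, 5.9)  # one zero difference -> dropped
  got <- wilcoxon_signed_rank(x, y)
  d <- (x - y)[x - y != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  # oracle: enumerate all 2^n sign assignments of the ranked magnitudes
  vs <- vapply(0:(2^n - 1), function(bits) {
    signs <- as.integer(intToBits(bits))[1:n]
    sum(r[signs == 1])
  }, 1.0)
  p_exact <- min(1, 2 * min(mean(vs <= v_obs + 1e-12),
                            mean(vs >= v_obs - 1e-12)))
  expect_true(got$exact)
  expect_equal(got$n, n)
  expect_equal(got$statistic, v_obs)
  expect_equal(got$p_value, p_exact, tolerance = 1e-12)
})

test_that("Wilcoxon handles degenerate and large-sample cases", {
  x <- c(1, 2, 3, 4, 5)
  deg <- wilcoxon_signed_rank(x, x)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  # exact vs normal approximation agree within 0.01 at n = 20
  withr::with_seed(16, {
    a <- rnorm(20, 0.3); b <- rnorm(20)
  })
  p_exact <- wilcoxon_signed_rank(a, b, exact_max = 25)$p_value
  p_approx <- wilcoxon_signed_rank(a, b, exact_max = 5)$p_value
  expect_lt(abs(p_exact - p_approx), 0.01)

  # mid-ranked ties still give an exact, valid distribution
  tied <- wilcoxon_signed_rank(c(3, 3, 5, 5, 8, 1), c(1, 1, 3, 3, 5, 2))
  expect_true(tied$exact)
  expect_gte(tied$p_value, 0)
  expect_lte(tied$p_value, 1)
})

test_that("Bonferroni bookkeeping follows alpha / C(k, 2)", {
  b5 <- bonferroni_threshold(0.05, 5)
  expect_equal(b5$m, 10)
  expect_equal(b5$threshold, 0.005)
  b2 <- bonferroni_threshold(0.05, 2)
  expect_equal(b2$m, 1)
  expect_equal(b2$threshold, 0.05)
  b4 <- bonferroni_threshold(0.10, 4)
  expect_equal(b4$m, 6)
  expect_equal(b4$threshold, 0.1 / 6, tolerance = 1e-12)
  expect_error(bonferroni_threshold(0.05, 1), ">= 2")
})

test_that("Kruskal-Wallis agrees with a small permutation oracle", {
  same <- list(c(2, 2), c(2, 2), c(2, 2))
  r0 <- kruskal_wallis(same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  groups <- list(c(1.1, 2.3, 2.8), c(3.5, 4.1, 1.9), c(0.4, 5.2, 6.0))
  got <- kruskal_wallis(groups)
  # oracle: all 9! / (3! 3! 3!) = 1680 assignments of the pooled sample
  pooled <- unlist(groups)
  h_of <- function(g1, g2, g3) {
    kruskal.test(list(pooled[g1], pooled[g2], pooled[g3]))$statistic
  }
  obs <- unname(got$statistic)
  idx <- combn(9, 3)
  cnt <- 0L; tot <- 0L
  for (i in seq_len(ncol(idx))) {
    rest <- setdiff(1:9, idx[, i])
    jdx <- combn(rest, 3)
    for (j in seq_len(ncol(jdx))) {
      g1 <- idx[, i]; g2 <- jdx[, j]; g3 <- setdiff(rest, g2)
      tot <- tot + 1L
      if (unname(h_of(g1, g2, g3)) >= obs - 1e-12) cnt <- cnt + 1L
    }
  }
  expect_lt(abs(got$p_value - cnt / tot), 0.1)
  # rank invariance under strictly monotone transforms
  expect_equal(kruskal_wallis(lapply(groups, exp))$statistic,
               got$statistic, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Mann-Whitney U exact p matches enumeration on tiny samples", {
  got <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(got$statistic), 0)
  expect_equal(got$p_value, 2 / 6, tolerance = 1e-12)
  expect_true(got$exact)

  # same multiset: p = 1 up to the approximation
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.9)

  # exact vs approximation within 0.02 at n = 10 per group
  withr::with_seed(17, {
    a <- rnorm(10, 0.5); b <- rnorm(10)
  })
  p_exact <- mann_whitney_u(a, b, exact_max = 10)$p_value
  p_approx <- mann_whitney_u(a, b, exact_max = 0)$p_value
  expect_lt(abs(p_exact - p_approx), 0.02)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("image sets are ranked by descending mean score with ties flagged", {
  scores <- reader_score_summary()
  rk <- rank_by_mean(scores, reader = 1, category = "noise")
  expect_identical(rk$image_set,
                   c("1.5 min CNN", "4 min", "1 min CNN", "1.5 min",
                     "1 min"))
  expect_false(any(rk$tied))

  tied <- tibble::tibble(image_set = c("A", "B", "C"), reader = 1,
                         category = "noise", mean = c(2, 2, 2))
  rkt <- rank_by_mean(tied, 1, "noise")
  expect_true(all(rkt$tied))

  dec <- tibble::tibble(image_set = c("4 min", "1.5 min", "1 min"),
                        reader = 9, category = "contrast",
                        mean = c(5, 4, 3))
  expect_identical(rank_by_mean(dec, 9, "contrast")$image_set,
                   c("4 min", "1.5 min", "1 min"))
})

test_that("comparison suite emits 10 pairwise rows per metric", {
  withr::with_seed(18, {
    subjects <- sprintf("p%02d", 1:8)
    grid <- tidyr::expand_grid(subject = subjects,
                               image_set = IMAGE_SETS,
                               lesion = c("lesion_1", "lesion_2"))
    grid$suv_max <- rnorm(nrow(grid), 5)
    grid$suv_peak <- grid$suv_max - abs(rnorm(nrow(grid), 0.5))
    cov_map <- tidyr::expand_grid(subject = subjects,
                                  image_set = IMAGE_SETS)
    cov_map$cov <- runif(nrow(cov_map), 0.05, 0.2)
    metrics <- dplyr::left_join(grid, cov_map,
                                by = c("subject", "image_set"))
  })
  cmp <- run_comparison_suite(metrics)
  expect_equal(nrow(cmp$pairwise), 30)  # 10 pairs x 3 metrics
  expect_equal(as.integer(table(cmp$pairwise$metric)), rep(10L, 3))
  expect_equal(cmp$threshold, 0.005)
  expect_equal(nrow(glance(cmp)), 3)
  expect_equal(nrow(tidy(cmp)), 30)

  # identical metric values across image sets: nothing is significant
  flat <- metrics
  flat <- dplyr::group_by(flat, subject, lesion)
  flat <- dplyr::mutate(flat, suv_max = suv_max[1], suv_peak = suv_peak[1],
                        cov = cov[1])
  flat <- dplyr::ungroup(flat)
  cflat <- run_comparison_suite(flat)
  expect_false(any(cflat$pairwise$significant))

  # incomplete coverage is a validation error naming the missing cells
  expect_error(run_comparison_suite(metrics[metrics$image_set != "4 min" |
                                              metrics$subject != "p01", ]),
               "incomplete.*p01", ignore.case = TRUE)
})

test_that("reader-score suite runs KW omnibus plus 10 pairwise MWU tests", {
  withr::with_seed(19, {
    scores <- tidyr::expand_grid(reader = 1:2, category = "noise",
                                 image_set = IMAGE_SETS,
                                 exam = 1:12)
    shift <- match(scores$image_set, IMAGE_SETS) / 2
    scores$score <- pmin(5, pmax(1, round(3 + shift - 1.5 +
                                            rnorm(nrow(scores), 0, 0.7))))
  })
  sc <- score_comparison_suite(scores)
  expect_equal(nrow(sc$omnibus), 2)
  expect_equal(nrow(sc$pairwise), 20)
  expect_equal(sc$threshold, 0.005)
})
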