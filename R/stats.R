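#' Friedman omnibus test for related samples
#'
#' Rank-based comparison of k related measurement columns (image sets)
#' across n subjects/lesions, with mid-rank tie handling within rows; the
#' p-value comes from the chi-square approximation with k - 1 degrees of
#' freedom (via [stats::friedman.test()]).
#'
#' @param table numeric matrix or data frame: rows = subjects/lesions,
#'   columns = image-set labels. No missing cells.
#' @return one-row tibble: `method`, `statistic`, `df`, `p_value`, `n`.
#' @export
friedman_rank <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  if (anyNA(m)) stop("missing cells are not allowed", call. = FALSE)
  ft <- stats::friedman.test(m)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) {  # every row fully tied: no evidence at all
    stat <- 0; p <- 1
  }
  tibble::tibble(method = "Friedman",
                 statistic = stat,
                 df = unname(ft$parameter),
                 p_value = p,
                 n = nrow(m))
}

#' Wilcoxon signed-rank test (exact with ties)
#'
#' Paired two-sided test. Zero differences are dropped; absolute differences
#' are mid-ranked. For n <= 25 retained pairs the null distribution of the
#' positive-rank sum is computed exactly by a generating-function recursion
#' over the doubled ranks (so mid-ranks stay integral), and the two-sided
#' p-value doubles the smaller tail (capped at 1). For larger n a normal
#' approximation with continuity and tie corrections is used.
#'
#' @param x,y paired measurements of equal length.
#' @param exact_max largest n for which the exact null is enumerated.
#' @return one-row tibble: `method`, `statistic` (positive-rank sum V),
#'   `p_value`, `n` (pairs retained), `exact`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  out <- function(stat, p, exact, degenerate = FALSE) {
    tibble::tibble(method = "Wilcoxon signed-rank", statistic = stat,
                   p_value = p, n = n, exact = exact,
                   degenerate = degenerate)
  }
  if (n == 0L) return(out(0, 1, TRUE, degenerate = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1L)
    f[1] <- 1
    for (ri in r2) {
      g <- f / 2
      g[(ri + 1L):(tot + 1L)] <- g[(ri + 1L):(tot + 1L)] +
        f[1L:(tot + 1L - ri)] / 2
      f <- g
    }
    obs <- as.integer(round(2 * v))
    p_lo <- sum(f[1L:(obs + 1L)])
    p_hi <- sum(f[(obs + 1L):(tot + 1L)])
    p <- min(1, 2 * min(p_lo, p_hi))
    return(out(v, p, TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sig2)
  out(v, min(1, 2 * stats::pnorm(-abs(z))), FALSE)
}

#' Bonferroni bookkeeping for all pairwise comparisons
#'
#' With k groups there are `m = k (k - 1) / 2` pairwise comparisons and the
#' corrected significance threshold is `alpha / m` (5 image sets: m = 10,
#' threshold 0.005 at alpha = 0.05).
#'
#' @param alpha family-wise error rate.
#' @param n_groups number of groups (>= 2).
#' @return list with `m` (comparison count) and `threshold`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_groups = 5L) {
  if (n_groups < 2L) stop("`n_groups` must be >= 2", call. = FALSE)
  m <- n_groups * (n_groups - 1) / 2
  list(m = m, threshold = alpha / m)
}

#' Kruskal-Wallis omnibus test for independent groups
#'
#' H statistic with tie correction; chi-square p-value with k - 1 degrees of
#' freedom (via [stats::kruskal.test()]).
#'
#' @param groups list of numeric samples (>= 2 groups, each non-empty).
#' @return one-row tibble: `method`, `statistic`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop("every group must be non-empty", call. = FALSE)
  }
  kt <- stats::kruskal.test(groups)
  stat <- unname(kt$statistic)
  p <- kt$p.value
  if (!is.finite(stat)) {  # all observations tied across all groups
    stat <- 0; p <- 1
  }
  tibble::tibble(method = "Kruskal-Wallis",
                 statistic = stat,
                 df = unname(kt$parameter),
                 p_value = p,
                 n = sum(lengths(groups)))
}

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided, mid-rank ties. The p-value is exact (full enumeration via the
#' exact null of the rank-sum statistic) when the smaller sample has at most
#' `exact_max` observations and there are no ties; otherwise a tie-corrected
#' normal approximation with continuity correction is used (via
#' [stats::wilcox.test()]).
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_max exact-enumeration cutoff on `min(length(a), length(b))`.
#' @return one-row tibble: `method`, `statistic` (U for `a`), `p_value`,
#'   `n`, `exact`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8L) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  tibble::tibble(method = "Mann-Whitney U",
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n = length(a) + length(b),
                 exact = exact)
}

# canonical image-set display order (gold standard first)
image_set_order <- function(labels) {
  canon <- c("4 min", "1.5 min", "1.5 min CNN", "1 min", "1 min CNN")
  c(intersect(canon, labels), setdiff(unique(labels), canon))
}

#' Rank image sets by mean reader score
#'
#' Orders the image-set labels by descending mean score (1 = best). Ties are
#' broken by the canonical label order and flagged.
#'
#' @param scores tibble with columns `image_set`, `reader`, `category` and
#'   `mean` (per-set mean score), e.g. [reader_score_summary()].
#' @param reader,category the score vector to rank.
#' @return tibble: `rank`, `image_set`, `mean_score`, `tied`.
#' @export
rank_by_mean <- function(scores, reader, category) {
  sel <- scores[scores$reader == reader & scores$category == category, ]
  if (nrow(sel) == 0L) {
    stop("no scores for reader ", reader, " / ", category, call. = FALSE)
  }
  expected <- image_set_order(sel$image_set)
  if (anyNA(sel$mean) || length(unique(sel$image_set)) != nrow(sel)) {
    stop("need exactly one mean per image set", call. = FALSE)
  }
  sel$image_set <- factor(sel$image_set, levels = expected)
  ord <- order(-sel$mean, sel$image_set)
  tied <- duplicated(sel$mean[ord]) | duplicated(sel$mean[ord],
                                                 fromLast = TRUE)
  tibble::tibble(rank = seq_len(nrow(sel)),
                 image_set = as.character(sel$image_set[ord]),
                 mean_score = sel$mean[ord],
                 tied = tied)
}

#' Bundled reader-score summary
#'
#' Example per-reader, per-category score descriptives (n, min, max, mean,
#' SD on a 5-point scale) for the five whole-body image sets, from a
#' three-reader clinical image-quality evaluation; used to demonstrate the
#' ranking and reporting operations.
#'
#' @return a tibble with columns `image_set`, `reader`, `category`, `n`,
#'   `min`, `max`, `mean`, `sd`.
#' @export
reader_score_summary <- function() {
  path <- system.file("extdata", "reader_scores.csv",
                      package = "petdenoise", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Omnibus and post-hoc comparison of the five image sets
#'
#' Reproduces the standard reporting layout for quantitative PET image-set
#' comparisons: per metric (SUVpeak, SUVmax, COV) a Friedman omnibus test
#' over the related samples, then all pairwise Wilcoxon signed-rank tests
#' with the Bonferroni-corrected threshold `alpha / C(k, 2)`.
#'
#' @param metrics tibble from [evaluate_image_sets()] (stacked over
#'   subjects): columns `subject`, `image_set`, `lesion`, `suv_max`,
#'   `suv_peak`, `cov`.
#' @param alpha family-wise error rate (default 0.05).
#' @return an `image_set_comparison` object: `omnibus` and `pairwise`
#'   tibbles plus the threshold bookkeeping. `tidy()` returns the pairwise
#'   table, `glance()` the omnibus table.
#' @export
run_comparison_suite <- function(metrics, alpha = 0.05) {
  req <- c("subject", "image_set", "lesion", "suv_max", "suv_peak", "cov")
  stopifnot(all(req %in% names(metrics)))
  sets <- image_set_order(metrics$image_set)
  k <- length(sets)
  bf <- bonferroni_threshold(alpha, k)

  # validate complete image-set coverage
  cover <- tidyr::expand_grid(subject = unique(metrics$subject),
                              image_set = sets)
  have <- dplyr::distinct(metrics, .data$subject, .data$image_set)
  missing <- dplyr::anti_join(cover, have, by = c("subject", "image_set"))
  if (nrow(missing) > 0L) {
    stop("incomplete image-set coverage: missing ",
         paste(missing$subject, missing$image_set, sep = "/",
               collapse = ", "), call. = FALSE)
  }

  wide_tbl <- function(value_col, unit_cols) {
    w <- tidyr::pivot_wider(
      dplyr::distinct(metrics[, c(unit_cols, "image_set", value_col)]),
      names_from = "image_set", values_from = dplyr::all_of(value_col))
    as.matrix(w[, sets])
  }
  tables <- list(
    suv_peak = wide_tbl("suv_peak", c("subject", "lesion")),
    suv_max = wide_tbl("suv_max", c("subject", "lesion")),
    cov = wide_tbl("cov", "subject"))

  omnibus <- purrr::imap_dfr(tables, function(tb, metric) {
    dplyr::mutate(friedman_rank(tb), metric = metric, .before = 1)
  })
  pair_idx <- utils::combn(k, 2)
  pairwise <- purrr::imap_dfr(tables, function(tb, metric) {
    purrr::map_dfr(seq_len(ncol(pair_idx)), function(j) {
      i1 <- pair_idx[1, j]; i2 <- pair_idx[2, j]
      res <- wilcoxon_signed_rank(tb[, i1], tb[, i2])
      dplyr::mutate(res, metric = metric,
                    pair = paste(sets[i1], sets[i2], sep = "–"),
                    set_a = sets[i1], set_b = sets[i2], .before = 1)
    })
  })
  pairwise$significant <- pairwise$p_value < bf$threshold
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 alpha = alpha, m = bf$m, threshold = bf$threshold,
                 image_sets = sets),
            class = "image_set_comparison")
}

#' Reader-score comparison across image sets
#'
#' Per reader and category: Kruskal-Wallis omnibus over the image sets, then
#' all pairwise Mann-Whitney U tests with the Bonferroni-corrected
#' threshold.
#'
#' @param scores per-examination score tibble: columns `reader`, `category`,
#'   `image_set`, `score`.
#' @inheritParams run_comparison_suite
#' @return an `image_set_comparison` object.
#' @export
score_comparison_suite <- function(scores, alpha = 0.05) {
  req <- c("reader", "category", "image_set", "score")
  stopifnot(all(req %in% names(scores)))
  sets <- image_set_order(scores$image_set)
  k <- length(sets)
  bf <- bonferroni_threshold(alpha, k)
  pair_idx <- utils::combn(k, 2)
  by_rc <- dplyr::group_split(dplyr::group_by(scores, .data$reader,
                                              .data$category))
  omnibus <- purrr::map_dfr(by_rc, function(g) {
    grp <- lapply(sets, function(s) g$score[g$image_set == s])
    dplyr::mutate(kruskal_wallis(grp), reader = g$reader[1],
                  category = g$category[1], .before = 1)
  })
  pairwise <- purrr::map_dfr(by_rc, function(g) {
    purrr::map_dfr(seq_len(ncol(pair_idx)), function(j) {
      s1 <- sets[pair_idx[1, j]]; s2 <- sets[pair_idx[2, j]]
      res <- mann_whitney_u(g$score[g$image_set == s1],
                            g$score[g$image_set == s2])
      dplyr::mutate(res, reader = g$reader[1], category = g$category[1],
                    pair = paste(s1, s2, sep = "–"),
                    set_a = s1, set_b = s2, .before = 1)
    })
  })
  pairwise$significant <- pairwise$p_value < bf$threshold
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 alpha = alpha, m = bf$m, threshold = bf$threshold,
                 image_sets = sets),
            class = "image_set_comparison")
}

#' @rdname run_comparison_suite
#' @param x an `image_set_comparison`.
#' @param ... unused.
#' @export
tidy.image_set_comparison <- function(x, ...) x$pairwise

#' @rdname run_comparison_suite
#' @export
glance.image_set_comparison <- function(x, ...) x$omnibus

#' @export
print.image_set_comparison <- function(x, ...) {
  cat(sprintf(
    "<image_set_comparison> %d image sets, %d pairwise tests per family, Bonferroni threshold %.4g\n",
    length(x$image_sets), x$m, x$threshold))
  print(x$omnibus)
  invisible(x)
}
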