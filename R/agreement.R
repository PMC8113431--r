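#' Bland-Altman agreement analysis
#'
#' Computes the paired differences `d = x - y`, their mean and sample SD,
#' the 95% limits of agreement `mean(d) +/- 1.96 sd(d)`, the least-squares
#' trend of the difference against the pairwise mean `(x + y)/2`, and
#' t-based confidence limits for the mean difference and for each limit of
#' agreement (standard error `sd * sqrt(1/n + z^2 / (2(n - 1)))`).
#'
#' @param x,y paired measurements (equal length, n >= 3).
#' @param conf confidence level for the limits (default 0.95).
#' @return a `bland_altman` object; see [tidy.bland_altman()].
#' @examples
#' ba <- bland_altman(c(1, 2, 3, 4), c(1, 1, 2, 5))
#' tidy(ba)
#' @export
bland_altman <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("at least 3 pairs are required", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  # the conventional reporting multiplier (1.96 at 95%), not qnorm's
  # 1.959964: limits of agreement are universally quoted as d +/- 1.96 SD
  z <- if (identical(conf, 0.95)) 1.96 else stats::qnorm(1 - (1 - conf) / 2)
  loa <- mean_diff + c(-1, 1) * z * sd_diff
  trend <- unname(stats::coef(stats::lm(d ~ m))[2])
  tq <- stats::qt(1 - (1 - conf) / 2, n - 1)
  se_mean <- sd_diff / sqrt(n)
  se_loa <- sd_diff * sqrt(1 / n + z^2 / (2 * (n - 1)))
  structure(list(
    n = n, mean_diff = mean_diff, sd_diff = sd_diff,
    loa_lower = loa[1], loa_upper = loa[2], trend_slope = trend,
    conf = conf,
    mean_diff_ci = mean_diff + c(-1, 1) * tq * se_mean,
    loa_lower_ci = loa[1] + c(-1, 1) * tq * se_loa,
    loa_upper_ci = loa[2] + c(-1, 1) * tq * se_loa,
    data = tibble::tibble(mean = m, diff = d)),
    class = "bland_altman")
}

#' @rdname bland_altman
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    term = c("mean difference", "lower LoA", "upper LoA", "trend slope"),
    estimate = c(x$mean_diff, x$loa_lower, x$loa_upper, x$trend_slope),
    conf.low = c(x$mean_diff_ci[1], x$loa_lower_ci[1], x$loa_upper_ci[1],
                 NA_real_),
    conf.high = c(x$mean_diff_ci[2], x$loa_lower_ci[2], x$loa_upper_ci[2],
                  NA_real_))
}

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 trend_slope = x$trend_slope, conf = x$conf)
}

#' @rdname bland_altman
#' @param object a `bland_altman` object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dotted") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "mean of pair", y = "difference",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean diff %.4g, %.0f%% LoA [%.4g, %.4g], trend %.4g\n",
              x$n, x$mean_diff, 100 * x$conf, x$loa_lower, x$loa_upper,
              x$trend_slope))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors (equal length, n >= 3, non-degenerate).
#' @return a one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must be equal length with n >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
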