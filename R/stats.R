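#' Two-sample Kolmogorov-Smirnov comparison of distance distributions
#'
#' Two-sided KS test: D is the supremum over the pooled sample points of the
#' absolute ECDF difference; the p value comes from the asymptotic Kolmogorov
#' distribution at effective sample size n1*n2/(n1+n2) (delegated to
#' [stats::ks.test()]).
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return object of class `mm_ks` with `statistic` (D), `p_value`, `n1`,
#'   `n2`. Supports [tidy()] and [glance()].
#' @export
ks_two_sample <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_validation("both samples need at least 2 finite values.")
  }
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(
    list(
      statistic = unname(ht$statistic),
      p_value = max(unname(ht$p.value), .Machine$double.xmin),
      n1 = length(a), n2 = length(b),
      method = "two-sided two-sample Kolmogorov-Smirnov (asymptotic)"
    ),
    class = "mm_ks"
  )
}

#' @export
print.mm_ks <- function(x, ...) {
  cat(sprintf("KS two-sample: D = %.4f, p = %.3g (n1 = %d, n2 = %d)\n",
              x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' @rdname ks_two_sample
#' @param x an `mm_ks` object.
#' @param ... unused.
#' @export
tidy.mm_ks <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n1 = x$n1, n2 = x$n2, method = x$method)
}

#' @rdname ks_two_sample
#' @export
glance.mm_ks <- function(x, ...) tidy.mm_ks(x)

#' Two-tailed unpaired t test on per-volume means
#'
#' Student's pooled-variance test by default (the unpaired t test on
#' per-mouse/volume group means), with Welch's unequal-variance variant by
#' flag. Degenerate zero-variance-in-both-groups inputs are handled by
#' convention: p = 1 when the means are equal, p = 0 (infinite t) otherwise,
#' both flagged.
#'
#' @param a,b numeric group values (per-volume means; each length >= 2).
#' @param variant `"student"` (default) or `"welch"`.
#' @return object of class `mm_ttest` with `statistic`, `df`, `p_value`,
#'   `variant`, `degenerate`. Supports [tidy()] and [glance()].
#' @export
t_test_unpaired <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) {
    stop_validation("both groups need at least 2 values.")
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(statistic = 0, df = length(a) + length(b) - 2, p_value = 1)
    } else {
      res <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p_value = 0)
    }
    return(structure(c(res, list(variant = variant, degenerate = TRUE,
                                 mean_a = mean(a), mean_b = mean(b))),
                     class = "mm_ttest"))
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"),
                      alternative = "two.sided")
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value), variant = variant, degenerate = FALSE,
         mean_a = mean(a), mean_b = mean(b)),
    class = "mm_ttest"
  )
}

#' @export
print.mm_ttest <- function(x, ...) {
  cat(sprintf("unpaired t test (%s): t = %.4f, df = %.2f, p = %.3g%s\n",
              x$variant, x$statistic, x$df, x$p_value,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' @rdname t_test_unpaired
#' @param x an `mm_ttest` object.
#' @param ... unused.
#' @export
tidy.mm_ttest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 estimate1 = x$mean_a, estimate2 = x$mean_b,
                 variant = x$variant, degenerate = x$degenerate)
}

#' @rdname t_test_unpaired
#' @export
glance.mm_ttest <- function(x, ...) tidy.mm_ttest(x)
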