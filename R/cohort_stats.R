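# Exact mutation-frequency estimation and 2x2 categorical comparison.

#' Mutation frequency with an exact (Clopper-Pearson) confidence interval
#'
#' The interval inverts the exact binomial tails: the lower bound solves
#' P(X >= n_carriers) = (1 - level)/2 and the upper bound solves
#' P(X <= n_carriers) = (1 - level)/2, computed via the beta-quantile form of
#' those tail equations. Degenerate bounds are exact: ci_low = 0 when
#' n_carriers = 0, ci_high = 1 when n_carriers = n_total.
#'
#' @param n_carriers number of mutation carriers
#' @param n_total cohort size
#' @param level confidence level, default 0.95
#' @return list of class `frequency_estimate`: n_carriers, n_total, point,
#'   ci_low, ci_high, level (all proportions on \[0,1\])
#' @export
frequency_with_ci <- function(n_carriers, n_total, level = 0.95) {
  stopifnot(n_total >= 1, level > 0, level < 1)
  if (n_carriers < 0 || n_carriers > n_total) {
    stop("n_carriers must lie in [0, n_total]", call. = FALSE)
  }
  alpha <- 1 - level
  lo <- if (n_carriers == 0) 0 else
    stats::qbeta(alpha / 2, n_carriers, n_total - n_carriers + 1)
  hi <- if (n_carriers == n_total) 1 else
    stats::qbeta(1 - alpha / 2, n_carriers + 1, n_total - n_carriers)
  structure(list(n_carriers = n_carriers, n_total = n_total,
                 point = n_carriers / n_total, ci_low = lo, ci_high = hi,
                 level = level),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("Mutation frequency: %d/%d = %.1f%% (%.0f%% CI %.1f-%.1f%%)\n",
              x$n_carriers, x$n_total, 100 * x$point, 100 * x$level,
              100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' 2x2 categorical comparison: chi-square and Fisher's exact test
#'
#' The chi-square statistic is the closed form
#' N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), with the Yates continuity-corrected
#' variant when `correction = TRUE`. When any margin is zero the chi-square is
#' undefined (reported NA) and only Fisher's exact test (two-sided by the
#' point-probability convention) is returned.
#'
#' @param a,b,c,d cell counts, rows = groups, columns = outcome
#' @param correction apply Yates continuity correction to the chi-square
#' @return list of class `two_by_two`: table, chi2, p_chi2, p_fisher,
#'   continuity_corrected
#' @export
two_by_two <- function(a, b, c, d, correction = FALSE) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0))
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(group = c("g1", "g2"),
                                outcome = c("yes", "no")))
  N <- sum(counts)
  margins_ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  if (margins_ok) {
    num <- abs(a * d - b * c)
    if (correction) num <- max(0, num - N / 2)
    chi2 <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
    p_chi2 <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    p_chi2 <- NA_real_
  }
  p_fisher <- stats::fisher.test(tab)$p.value
  structure(list(table = tab, chi2 = chi2, p_chi2 = p_chi2,
                 p_fisher = p_fisher, continuity_corrected = correction),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  print(x$table)
  if (is.na(x$chi2)) {
    cat("chi-square undefined (zero margin); ")
  } else {
    cat(sprintf("chi2 = %.4f%s, p = %.4g; ",
                x$chi2, if (x$continuity_corrected) " (Yates)" else "",
                x$p_chi2))
  }
  cat(sprintf("Fisher two-sided p = %.4g\n", x$p_fisher))
  invisible(x)
}
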