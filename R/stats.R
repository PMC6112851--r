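## Nonparametric and parametric test wrappers with the small-sample exact
## behaviour and degenerate-case handling the pipeline relies on.

#' Run a statistical test
#'
#' Thin, uniform wrapper over the base tests used throughout the
#' pipeline. Rank tests use the exact small-sample null distribution when
#' the sample is small and untied (the base implementation switches to a
#' tie-corrected normal approximation otherwise). A paired signed-rank
#' test on identical samples (all-zero differences) returns p = 1 with a
#' warning instead of erroring, so that null pharmacology comparisons are
#' reported rather than dropped. The two-sample t-test uses pooled
#' variance.
#'
#' @param x Numeric vector, or a list of group vectors for
#'   `kruskal_wallis`.
#' @param y Second sample (ignored for `kruskal_wallis`).
#' @param kind One of `"wilcoxon_paired"`, `"wilcoxon_ranksum"`,
#'   `"kruskal_wallis"`, `"t_two_sample"`.
#' @return A one-row data frame: `test`, `statistic`, `p_value`, `n`,
#'   `direction` (sign of `median(x) - median(y)` where applicable).
#' @export
run_test <- function(x, y = NULL,
                     kind = c("wilcoxon_paired", "wilcoxon_ranksum",
                              "kruskal_wallis", "t_two_sample")) {
  kind <- match.arg(kind)
  direction <- NA_real_
  if (kind == "kruskal_wallis") {
    abort_if(!is.list(x), "kruskal_wallis expects a list of groups")
    abort_if(length(x) < 2L, "need at least two groups")
    kt <- kruskal.test(x)
    return(data.frame(test = kind, statistic = unname(kt$statistic),
                      p_value = kt$p.value,
                      n = sum(lengths(x)), direction = direction))
  }
  abort_if(is.null(y), kind, " requires two samples")
  if (kind == "wilcoxon_paired") {
    abort_if(length(x) != length(y), "paired samples must match in length")
    abort_if(length(x) < 2L, "need at least two pairs")
    d <- x - y
    direction <- sign(median(d))
    if (all(d == 0)) {
      warning("all paired differences are zero; p = 1", call. = FALSE)
      return(data.frame(test = kind, statistic = 0, p_value = 1,
                        n = length(x), direction = 0))
    }
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
  } else if (kind == "wilcoxon_ranksum") {
    abort_if(length(x) < 2L || length(y) < 2L,
             "need at least two values per group")
    direction <- sign(median(x) - median(y))
    wt <- suppressWarnings(wilcox.test(x, y))
  } else { # t_two_sample
    abort_if(length(x) < 2L || length(y) < 2L,
             "need at least two values per group")
    direction <- sign(mean(x) - mean(y))
    wt <- t.test(x, y, var.equal = TRUE)
  }
  data.frame(test = kind, statistic = unname(wt$statistic),
             p_value = wt$p.value, n = length(x) + length(y),
             direction = direction)
}

#' Holm adjustment across a declared test family
#'
#' Applies the Holm step-down correction to the `p_value` column of a
#' stack of [run_test()] / [lesion_size_correlation()] results. Adjusted
#' p-values are monotone and never smaller than the raw ones.
#'
#' @param results Data frame with a `p_value` column (one row per test of
#'   the family).
#' @return `results` with a `p_adjusted` column added.
#' @export
holm_adjust <- function(results) {
  abort_if(!"p_value" %in% names(results),
           "`results` needs a p_value column")
  results$p_adjusted <- p.adjust(results$p_value, method = "holm")
  results
}
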