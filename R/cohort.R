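#' Compare biallelic-expression burden between two cohorts
#'
#' Tests whether per-sample heterozygous-site burdens differ between two
#' cohorts (e.g. case vs control), with two complementary tests reported
#' together:
#' \itemize{
#'   \item a two-sided permutation test on the difference in mean per-sample
#'     het-site count. All \eqn{\binom{n}{n_1}} cohort labelings are
#'     enumerated exhaustively when there are at most `exhaustive_limit` of
#'     them; otherwise `n_perm` random relabelings are drawn and
#'     \eqn{p = (1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(n_{perm}+1)}
#'     (the +1 convention keeps p away from 0);
#'   \item Fisher's exact test on the 2×2 table of cohort × "any het site"
#'     (at least one non-flagged heterozygous position).
#' }
#' When the counts tibble carries a `sex` column (or one is supplied via
#' `samples`), non-male samples are excluded by default: in a male-silencing
#' design females are legitimately heterozygous and belong in the positive
#' controls, not the test.
#'
#' @param counts Tibble with one row per sample: columns `sample`, `n_het`
#'   and either a `cohort` column or a `samples` sheet to join.
#' @param samples Optional sample sheet (`sample`, `cohort`, and optionally
#'   `sex`) joined onto `counts`.
#' @param n_perm Number of random permutations when exhaustive enumeration is
#'   not feasible (default 9999; must be >= 1).
#' @param seed Optional RNG seed for the sampled permutations.
#' @param alpha Nominal significance level recorded in the result.
#' @param male_only Drop samples whose `sex` is not `"male"` when a sex
#'   column is available (default `TRUE`).
#' @param exhaustive_limit Enumerate all labelings when
#'   `choose(n, n1) <= exhaustive_limit` (default `1e5`).
#' @return An object of class `cohort_result`; see [tidy.cohort_result()] and
#'   [glance.cohort_result()].
#' @examples
#' counts <- tibble::tibble(
#'   sample = paste0("S", 1:6),
#'   cohort = rep(c("case", "control"), each = 3),
#'   n_het = c(0, 0, 3, 0, 0, 0)
#' )
#' compare_groups(counts, seed = 1)
#' @export
compare_groups <- function(counts, samples = NULL, n_perm = 9999, seed = NULL,
                           alpha = 0.05, male_only = TRUE,
                           exhaustive_limit = 1e5) {
  counts <- as_tibble(counts)
  if (!is.null(samples)) {
    counts <- dplyr::inner_join(
      counts, as_tibble(samples)[intersect(names(samples), c("sample", "cohort", "sex"))],
      by = "sample"
    )
  }
  if (!all(c("sample", "cohort", "n_het") %in% names(counts))) {
    abort("`counts` must provide columns sample, cohort and n_het")
  }
  if (male_only && "sex" %in% names(counts)) {
    counts <- dplyr::filter(counts, .data$sex == "male")
  }
  if (any(is.na(counts$n_het)) || any(counts$n_het < 0)) {
    abort("het counts must be non-negative")
  }
  if (!is.numeric(n_perm) || n_perm < 1) {
    abort("`n_perm` must be >= 1")
  }
  cohorts <- sort(unique(counts$cohort))
  if (length(cohorts) != 2) {
    abort(sprintf("exactly two cohorts required, got %d", length(cohorts)),
      class = "biallele_cohort_error"
    )
  }
  x <- counts$n_het
  g1 <- counts$cohort == cohorts[1]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) {
    abort("each cohort needs at least two samples",
      class = "biallele_cohort_error"
    )
  }
  delta_obs <- mean(x[g1]) - mean(x[!g1])
  n <- n1 + n2

  n_labelings <- choose(n, n1)
  if (n_labelings <= exhaustive_limit) {
    # Exhaustive: all distinct assignments of samples to cohort 1. |delta|
    # compared with a tiny tolerance so ties are not lost to rounding.
    idx <- combn(n, n1)
    sum_all <- sum(x)
    deltas <- colSums(matrix(x[idx], nrow = n1)) / n1 -
      (sum_all - colSums(matrix(x[idx], nrow = n1))) / n2
    p_perm <- mean(abs(deltas) >= abs(delta_obs) - 1e-12)
    perm_method <- "exhaustive"
    n_perm_used <- ncol(idx)
  } else {
    draw <- function() {
      perm <- sample.int(n, n1)
      s1 <- sum(x[perm])
      s1 / n1 - (sum(x) - s1) / n2
    }
    deltas <- withr::with_seed(
      seed %||% sample.int(.Machine$integer.max, 1),
      vapply(seq_len(n_perm), function(i) draw(), numeric(1))
    )
    p_perm <- (1 + sum(abs(deltas) >= abs(delta_obs) - 1e-12)) / (n_perm + 1)
    perm_method <- "sampled"
    n_perm_used <- n_perm
  }

  any_het <- x > 0
  tab <- table(
    factor(counts$cohort, levels = cohorts),
    factor(any_het, levels = c(FALSE, TRUE))
  )
  p_fisher <- fisher.test(tab)$p.value

  structure(
    list(
      counts = counts,
      cohorts = cohorts,
      n = setNames(c(n1, n2), cohorts),
      mean_het = setNames(c(mean(x[g1]), mean(x[!g1])), cohorts),
      n_biallelic = setNames(
        c(sum(any_het & g1), sum(any_het & !g1)), cohorts
      ),
      delta_mean = delta_obs,
      p_perm = p_perm,
      perm_method = perm_method,
      n_perm = n_perm_used,
      p_fisher = p_fisher,
      alpha = alpha,
      seed = seed
    ),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cohort_result> %s (n=%d) vs %s (n=%d)\n",
      "  mean het sites: %.3g vs %.3g (delta = %.3g)\n",
      "  samples with >= 1 het site: %d vs %d\n",
      "  permutation p = %.4g (%s, %d labelings/draws)\n",
      "  Fisher exact p = %.4g  [alpha = %g]\n"
    ),
    x$cohorts[1], x$n[1], x$cohorts[2], x$n[2],
    x$mean_het[1], x$mean_het[2], x$delta_mean,
    x$n_biallelic[1], x$n_biallelic[2],
    x$p_perm, x$perm_method, x$n_perm, x$p_fisher, x$alpha
  ))
  invisible(x)
}

#' Tidy a cohort comparison
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @return One row per cohort: `cohort`, `n`, `mean_het`, `n_biallelic`.
#' @export
tidy.cohort_result <- function(x, ...) {
  tibble(
    cohort = x$cohorts,
    n = as.integer(x$n),
    mean_het = as.numeric(x$mean_het),
    n_biallelic = as.integer(x$n_biallelic)
  )
}

#' One-row summary of a cohort comparison
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @return A one-row tibble with the statistic and both p-values.
#' @export
glance.cohort_result <- function(x, ...) {
  tibble(
    delta_mean = x$delta_mean,
    p_perm = x$p_perm,
    perm_method = x$perm_method,
    n_perm = as.integer(x$n_perm),
    p_fisher = x$p_fisher,
    alpha = x$alpha
  )
}
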