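#' Calibrate the per-base miscall rate on a hemizygous negative control
#'
#' A hemizygous (or otherwise guaranteed monoallelic) gene such as X-linked
#' TMLHE in males carries no true heterozygosity, so every non-reference read
#' measures technical noise: sequencing error, library-preparation
#' substitutions and residual misalignment. The estimator pools reads across
#' all columns whose per-column non-reference fraction is at most
#' `outlier_fraction` (columns above it are plausible true variants, RNA
#' edits or systematic artifacts and are excluded, then reported) and returns
#' \deqn{\hat\epsilon = \frac{\sum \text{non-reference reads}}{\sum \text{depth}}.}
#'
#' @param pileup A pileup tibble for the negative-control gene (columns as
#'   returned by [read_counts_tsv()] / [simulate_pileup()]); may span many
#'   samples, which are pooled.
#' @param outlier_fraction Columns with non-reference fraction above this
#'   value are excluded from pooling (default 0.2).
#' @return An object of class `noise_estimate` with fields `epsilon`,
#'   `pooled_depth`, `n_positions_used`, `n_positions_excluded`, and
#'   `excluded` (a tibble of the excluded columns). `tidy()` returns it as a
#'   one-row tibble.
#' @examples
#' sim <- simulate_pileup(sim_scenario(200, error_rate = 0.01, depth = 100,
#'                                     n_samples = 5, seed = 3))
#' estimate_error_rate(sim$pileup)
#' @export
estimate_error_rate <- function(pileup, outlier_fraction = 0.2) {
  pileup <- validate_pileup(as_tibble(pileup))
  pileup <- dplyr::filter(pileup, .data$depth > 0)
  if (nrow(pileup) == 0) {
    abort("no pileup columns with positive depth; cannot estimate error rate",
      class = "biallele_noise_error"
    )
  }
  nonref <- pileup$depth - ref_counts(pileup)
  frac <- nonref / pileup$depth
  keep <- frac <= outlier_fraction
  if (!any(keep)) {
    abort("all columns exceed `outlier_fraction`; no usable columns",
      class = "biallele_noise_error"
    )
  }
  pooled_depth <- sum(pileup$depth[keep])
  epsilon <- sum(nonref[keep]) / pooled_depth
  if (epsilon >= 0.75) {
    abort("estimated error rate >= 0.75: genotype model is degenerate",
      class = "biallele_noise_error"
    )
  }
  structure(
    list(
      epsilon = epsilon,
      pooled_depth = pooled_depth,
      n_positions_used = sum(keep),
      n_positions_excluded = sum(!keep),
      outlier_fraction = outlier_fraction,
      excluded = dplyr::mutate(
        pileup[!keep, c("sample", "gene", "pos", "depth")],
        nonref_fraction = frac[!keep]
      )
    ),
    class = "noise_estimate"
  )
}

# Count of reads matching the reference base, per row.
ref_counts <- function(pileup) {
  counts <- as.matrix(pileup[BASE_COLS])
  counts[cbind(seq_len(nrow(pileup)), match(pileup$ref_base, BASES))]
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<noise_estimate> eps = %.3g over pooled depth %d\n",
      "  %d columns used, %d excluded (non-ref fraction > %g)\n"
    ),
    x$epsilon, x$pooled_depth, x$n_positions_used, x$n_positions_excluded,
    x$outlier_fraction
  ))
  invisible(x)
}

#' @export
tidy.noise_estimate <- function(x, ...) {
  tibble(
    epsilon = x$epsilon, pooled_depth = x$pooled_depth,
    n_positions_used = x$n_positions_used,
    n_positions_excluded = x$n_positions_excluded
  )
}

#' Configure the genotype-likelihood classifier
#'
#' @param priors Positive genotype priors `(hom_ref, het, hom_alt)`;
#'   normalised to sum to 1. Default uniform.
#' @param d_min Minimum used depth for a call (default 20); shallower columns
#'   are `no_call`. This gate stands in for read-quality filtering.
#' @param tau Posterior threshold in `(0.5, 1]` (default 0.95): the winning
#'   genotype's posterior must reach `tau`, otherwise `no_call`.
#' @param epsilon Either the string `"estimate"` (caller must supply a rate,
#'   e.g. from [estimate_error_rate()]) or a numeric override in `[0, 0.75)`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(priors = c(1, 1, 1) / 3, d_min = 20, tau = 0.95,
                         epsilon = "estimate") {
  if (length(priors) != 3 || any(!is.finite(priors)) || any(priors <= 0)) {
    abort("`priors` must be three positive values")
  }
  priors <- priors / sum(priors)
  if (!is.numeric(d_min) || length(d_min) != 1 || d_min < 1) {
    abort("`d_min` must be a single integer >= 1")
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0.5 || tau > 1) {
    abort("`tau` must lie in (0.5, 1]")
  }
  if (!identical(epsilon, "estimate")) {
    check_epsilon(epsilon)
  }
  structure(
    list(priors = setNames(priors, GT_CLASSES), d_min = as.integer(d_min),
         tau = tau, epsilon = epsilon),
    class = "model_config"
  )
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || is.na(epsilon) ||
    epsilon < 0 || epsilon >= 0.75) {
    abort("`epsilon` must be a single value in [0, 0.75)",
      class = "biallele_noise_error"
    )
  }
  invisible(epsilon)
}

# Reference-match probabilities for the three genotype classes at error rate
# eps. With eps = 0 these reduce to the idealised 1 / 0.5 / 0 model: a read
# matches the reference with probability 0.5 at an expressed heterozygous
# site and 0 or 1 at homozygous sites.
genotype_ref_probs <- function(epsilon) {
  p_rr <- 1 - epsilon
  p_aa <- epsilon / 3
  p_ra <- 0.5 * p_rr + 0.5 * p_aa
  if (p_rr <= p_ra) {
    abort("error rate leaves genotype classes unordered (p_RR <= p_RA)",
      class = "biallele_noise_error"
    )
  }
  c(hom_ref = p_rr, het = p_ra, hom_alt = p_aa)
}

#' Classify per-site genotypes from reference-base counts
#'
#' The pipeline's core statistic. For each pileup column the non-reference
#' bases are collapsed and the reference-base count `k` out of used depth `d`
#' is scored under three binomial models, one per genotype class, whose
#' reference-match probabilities embed the miscall rate `eps`:
#' \deqn{p_{RR} = 1-\epsilon,\quad
#'       p_{RA} = \tfrac12(1-\epsilon) + \tfrac12\,\epsilon/3,\quad
#'       p_{AA} = \epsilon/3.}
#' Log-likelihoods `log Binom(k; d, p_g)` are combined with the configured
#' priors into posteriors (log-space with max subtraction); the maximum a
#' posteriori class is called when `d >= d_min` and the winning posterior
#' reaches `tau`, otherwise the column is `no_call`.
#'
#' @param pileup A pileup tibble (see [read_counts_tsv()]).
#' @param epsilon Per-base miscall probability in `[0, 0.75)`; typically the
#'   `epsilon` of a [estimate_error_rate()] fit, or a `noise_estimate` object
#'   itself. Overridden by a numeric `config$epsilon`.
#' @param config A [model_config()].
#' @return A tibble with one row per column: `sample`, `gene`, `pos`,
#'   `depth_used`, `ref_fraction`, log-likelihoods `ll_hom_ref`, `ll_het`,
#'   `ll_hom_alt`, posteriors `q_hom_ref`, `q_het`, `q_hom_alt`, and `call`.
#' @examples
#' sim <- simulate_pileup(sim_scenario(40, divergent_sites = c(10, 20),
#'                                     y_fraction = 0.5, depth = 100,
#'                                     n_samples = 2, seed = 5))
#' calls <- classify_sites(sim$pileup, epsilon = 0)
#' dplyr::count(calls, call)
#' @export
classify_sites <- function(pileup, epsilon, config = model_config()) {
  if (inherits(epsilon, "noise_estimate")) epsilon <- epsilon$epsilon
  if (is.numeric(config$epsilon)) epsilon <- config$epsilon
  check_epsilon(epsilon)
  pileup <- validate_pileup(as_tibble(pileup))
  p_g <- genotype_ref_probs(epsilon)
  k <- ref_counts(pileup)
  d <- pileup$depth
  if (any(k > d)) {
    abort("reference count exceeds depth") # unreachable on validated input
  }
  ll <- vapply(p_g, function(p) dbinom(k, d, p, log = TRUE),
               numeric(length(k)))
  ll <- matrix(ll, ncol = 3, dimnames = list(NULL, GT_CLASSES))
  lp <- sweep(ll, 2, log(config$priors), "+")
  m <- apply(lp, 1, max)
  q <- exp(lp - m)
  q <- q / rowSums(q)
  best <- max.col(q, ties.method = "first")
  q_max <- q[cbind(seq_along(best), best)]
  call <- ifelse(d >= config$d_min & q_max >= config$tau,
                 GT_CLASSES[best], "no_call")
  tibble(
    sample = pileup$sample, gene = pileup$gene, pos = pileup$pos,
    ref_base = pileup$ref_base,
    depth_used = d,
    ref_fraction = ifelse(d > 0, k / d, NA_real_),
    ll_hom_ref = unname(ll[, "hom_ref"]), ll_het = unname(ll[, "het"]),
    ll_hom_alt = unname(ll[, "hom_alt"]),
    q_hom_ref = unname(q[, "hom_ref"]), q_het = unname(q[, "het"]),
    q_hom_alt = unname(q[, "hom_alt"]),
    call = unname(call)
  )
}

#' Per-position variant-frequency table
#'
#' The descriptive layer beneath the genotype calls: for every pileup column
#' the fraction of reads matching the reference base, the pooled
#' non-reference fraction, and the per-base fractions. This is the
#' variant-frequency-per-coordinate summary that a heterozygosity map plots.
#'
#' @param pileup A pileup tibble.
#' @return A tibble with columns `sample`, `gene`, `pos`, `ref_base`,
#'   `depth`, `ref_fraction`, `nonref_fraction`, `fA`, `fC`, `fG`, `fT`.
#' @export
site_frequency_table <- function(pileup) {
  pileup <- validate_pileup(as_tibble(pileup))
  if (nrow(pileup) == 0) {
    abort("empty pileup", class = "biallele_invalid_pileup")
  }
  k <- ref_counts(pileup)
  d <- pileup$depth
  frac <- function(n) ifelse(d > 0, n / d, NA_real_)
  tibble(
    sample = pileup$sample, gene = pileup$gene, pos = pileup$pos,
    ref_base = pileup$ref_base, depth = d,
    ref_fraction = frac(k),
    nonref_fraction = frac(d - k),
    fA = frac(pileup$nA), fC = frac(pileup$nC),
    fG = frac(pileup$nG), fT = frac(pileup$nT)
  )
}
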