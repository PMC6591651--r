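# Independent oracles, deliberately built from first principles rather than
# through the code paths they check.

# Binomial log-pmf from explicit factorial sums (no dbinom, no lchoose).
log_binom_pmf_oracle <- function(k, d, p) {
  if (k < 0 || k > d) {
    return(-Inf)
  }
  if (p == 0) {
    return(if (k == 0) 0 else -Inf)
  }
  if (p == 1) {
    return(if (k == d) 0 else -Inf)
  }
  lfact <- function(n) sum(log(seq_len(n)))
  lfact(d) - lfact(k) - lfact(d - k) + k * log(p) + (d - k) * log(1 - p)
}

# Exhaustive two-group permutation p-value for the |difference in means|
# statistic, by explicit enumeration of every assignment of n1 samples to
# group 1.
perm_p_oracle <- function(x, n1) {
  n <- length(x)
  combos <- utils::combn(n, n1)
  obs <- mean(x[seq_len(n1)]) - mean(x[-seq_len(n1)])
  deltas <- apply(combos, 2, function(ix) mean(x[ix]) - mean(x[-ix]))
  mean(abs(deltas) >= abs(obs) - 1e-12)
}

# Direct per-site call probability: P(classifier emits `target` | true
# reference-read probability p_true), by enumerating every k in 0..d.
call_prob_oracle <- function(d, p_true, epsilon, target,
                             config = model_config()) {
  pileup <- tibble::tibble(
    sample = "S", gene = "g", pos = seq_len(d + 1), ref_base = "A",
    depth = d, nA = 0:d, nC = d - (0:d), nG = 0L, nT = 0L
  )
  calls <- classify_sites(pileup, epsilon = epsilon, config = config)
  sum(stats::dbinom(0:d, d, p_true)[calls$call == target])
}

# A minimal hand-built pileup tibble.
make_pileup <- function(nA = 0, nC = 0, nG = 0, nT = 0, ref_base = "A",
                        pos = 1L, sample = "S1", gene = "g") {
  tibble::tibble(
    sample = sample, gene = gene, pos = as.integer(pos), ref_base = ref_base,
    depth = as.integer(nA + nC + nG + nT),
    nA = as.integer(nA), nC = as.integer(nC),
    nG = as.integer(nG), nT = as.integer(nT)
  )
}
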