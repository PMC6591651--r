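#' Simulate per-sample transcript pileups under an allelic-mixture model
#'
#' Generates per-position A/C/G/T read counts for every sample of a scenario,
#' together with the ground truth that produced them. Each read originates
#' from the reference-bearing allele with probability `1 - f` and from the
#' alternative allele with probability `f` (where `f` is the scenario's
#' `y_fraction`, or 0.5 for female samples, which are true heterozygotes), and
#' is miscalled with probability `eps`, substituting uniformly among the three
#' other bases. The reference-base count at each column is therefore a
#' binomial draw with success probability
#' \deqn{p_{ref} = (1-f)(1-\epsilon) + f\,\epsilon/3}
#' at a divergent site and \eqn{1-\epsilon} elsewhere; the remaining reads
#' fall on the alternative base and the two unrelated bases in proportion to
#' their model probabilities.
#'
#' @param scenario A [sim_scenario()].
#' @return A list of class `biallele_sim` with elements
#'   \describe{
#'     \item{pileup}{tibble with columns `sample`, `gene`, `pos`, `ref_base`,
#'       `depth`, `nA`, `nC`, `nG`, `nT`; `depth` always equals the base-count
#'       sum.}
#'     \item{truth}{tibble with columns `sample`, `gene`, `pos`, `class`
#'       (`hom_ref`/`het`/`hom_alt`) and the generating `p_ref`.}
#'     \item{read_totals}{per-sample realized total mapped read count (`NA`
#'       under the fixed-depth law).}
#'     \item{scenario}{the scenario, for provenance.}
#'   }
#' @examples
#' sim <- simulate_pileup(sim_scenario(
#'   transcript_length = 50, divergent_sites = 25,
#'   y_fraction = 0.5, depth = 100, n_samples = 3, seed = 7
#' ))
#' sim$pileup
#' @export
simulate_pileup <- function(scenario) {
  if (!inherits(scenario, "sim_scenario")) {
    abort("`scenario` must be created with sim_scenario()")
  }
  withr::with_seed(scenario$seed, simulate_pileup_impl(scenario))
}

simulate_pileup_impl <- function(scenario) {
  L <- scenario$transcript_length
  ns <- scenario$n_samples
  eps <- scenario$error_rate
  ref <- reference_bases(L)
  is_div <- seq_len(L) %in% scenario$divergent_sites
  alt <- ref # placeholder at non-divergent sites (never receives counts)
  alt[scenario$divergent_sites] <- unname(scenario$alt_bases)

  # Female samples carry two expressed alleles (true PAR/autosomal
  # heterozygosity): effective alt-allele transcript fraction 0.5.
  f_eff <- ifelse(scenario$sex == "female", 0.5, scenario$y_fraction)

  depths <- realized_depths(scenario, L, ns)

  # Long vectors over the sample x position grid (samples vary slowest).
  smp <- rep(seq_len(ns), each = L)
  pos <- rep(seq_len(L), times = ns)
  d <- as.integer(t(depths$depth))
  f <- f_eff[smp]
  div <- is_div[pos]
  eps3 <- eps / 3

  p_ref <- ifelse(div, (1 - f) * (1 - eps) + f * eps3, 1 - eps)
  p_alt <- ifelse(div, f * (1 - eps) + (1 - f) * eps3, 0)

  n_ref <- rbinom(length(d), d, p_ref)
  rem <- d - n_ref

  counts <- matrix(0L, nrow = length(d), ncol = 4L,
                   dimnames = list(NULL, BASES))
  ref_col <- match(ref[pos], BASES)
  # The three non-reference base columns, in A<C<G<T order.
  nonref_lookup <- t(vapply(1:4, function(r) setdiff(1:4, r), integer(3)))
  nr <- nonref_lookup[ref_col, , drop = FALSE]
  # First non-reference slot: the alternative base at divergent sites, else
  # just the first of the three (which then takes a uniform 1/3 share).
  alt_col <- ifelse(div, match(alt[pos], BASES), nr[, 1L])
  o1 <- ifelse(nr[, 1L] != alt_col, nr[, 1L], nr[, 2L])
  o2 <- ifelse(nr[, 3L] != alt_col, nr[, 3L], nr[, 2L])
  # Conditional split of the non-reference reads: alt base vs the two
  # unrelated bases, proportional to p_alt : eps/3 : eps/3 at divergent
  # sites and uniform 1/3 each elsewhere.
  denom <- p_alt + 2 * eps3
  p_alt_cond <- ifelse(div, ifelse(denom > 0, p_alt / denom, 0), 1 / 3)
  n_alt <- rbinom(length(d), rem, p_alt_cond)
  rem2 <- rem - n_alt
  n_o1 <- rbinom(length(d), rem2, 0.5)
  n_o2 <- rem2 - n_o1

  idx <- seq_along(d)
  counts[cbind(idx, ref_col)] <- n_ref
  counts[cbind(idx, alt_col)] <- n_alt
  counts[cbind(idx, o1)] <- counts[cbind(idx, o1)] + n_o1
  counts[cbind(idx, o2)] <- counts[cbind(idx, o2)] + n_o2

  sample_ids <- sample_names(ns)
  pileup <- tibble(
    sample = sample_ids[smp],
    gene = scenario$gene,
    pos = pos,
    ref_base = ref[pos],
    depth = d,
    nA = counts[, "A"], nC = counts[, "C"],
    nG = counts[, "G"], nT = counts[, "T"]
  )
  truth <- tibble(
    sample = sample_ids[smp],
    gene = scenario$gene,
    pos = pos,
    class = ifelse(!div, "hom_ref",
      ifelse(f == 0, "hom_ref", ifelse(f == 1, "hom_alt", "het"))
    ),
    p_ref = p_ref
  )
  structure(
    list(
      pileup = pileup, truth = truth,
      read_totals = tibble(
        sample = sample_ids, sex = scenario$sex,
        total_reads = depths$total_reads
      ),
      scenario = scenario
    ),
    class = "biallele_sim"
  )
}

# Per-position depths, ns x L, plus the realized per-transcript mapped-read
# totals. Under the range law each sample draws a total read count uniformly
# from the configured range; every read starts uniformly over the feasible
# start positions and covers `read_length` consecutive positions (truncated
# at the transcript end), so per-position depth is the read coverage.
realized_depths <- function(scenario, L, ns) {
  if (!is.null(scenario$depth)) {
    return(list(
      depth = matrix(scenario$depth, nrow = ns, ncol = L),
      total_reads = rep(NA_integer_, ns)
    ))
  }
  rng <- scenario$total_read_range
  len <- min(scenario$read_length, L)
  totals <- sample(seq.int(rng[1], rng[2]), ns, replace = TRUE)
  n_starts <- L - len + 1L
  depth <- t(vapply(totals, function(tt) {
    starts <- sample.int(n_starts, tt, replace = TRUE)
    # coverage by difference array: +1 at start, -1 after the read's end
    delta <- tabulate(starts, nbins = L) -
      tabulate(pmin(starts + len, L + 1L), nbins = L + 1L)[seq_len(L)]
    as.integer(cumsum(delta))
  }, integer(L)))
  list(depth = depth, total_reads = totals)
}

sample_names <- function(ns, prefix = "S") {
  sprintf("%s%0*d", prefix, nchar(ns), seq_len(ns))
}

#' @export
print.biallele_sim <- function(x, ...) {
  cat(sprintf(
    "<biallele_sim> %d samples x %d positions of %s (%d pileup rows)\n",
    x$scenario$n_samples, x$scenario$transcript_length, x$scenario$gene,
    nrow(x$pileup)
  ))
  invisible(x)
}

#' Simulate a labelled two-cohort allelic-expression study
#'
#' Runs [simulate_pileup()] for a case and a control scenario over the same
#' transcript and returns the combined pileups, a sample sheet with cohort and
#' sex labels, and the combined ground truth. Sample identifiers are prefixed
#' with the cohort name. Female samples (if any are declared in a scenario's
#' `sex`) are simulated as true heterozygotes, mirroring the use of a female
#' sample as the positive heterozygosity reference in a male-silencing study.
#'
#' @param scenario_case,scenario_control [sim_scenario()] objects sharing
#'   `transcript_length`, `divergent_sites`, `alt_bases` and `gene`.
#' @param cohort_names Length-2 character: labels for the case and control
#'   cohorts.
#' @return A list of class `biallele_cohort_sim` with elements `pileup`,
#'   `samples` (tibble `sample`, `cohort`, `sex`), `truth`, and `scenarios`.
#' @examples
#' case <- sim_scenario(60, divergent_sites = c(10, 30), y_fraction = 0.3,
#'                      depth = 200, n_samples = 5, seed = 11)
#' ctrl <- sim_scenario(60, divergent_sites = c(10, 30), y_fraction = 0,
#'                      depth = 200, n_samples = 5, seed = 12)
#' cs <- simulate_cohort(case, ctrl)
#' cs$samples
#' @export
simulate_cohort <- function(scenario_case, scenario_control,
                            cohort_names = c("case", "control")) {
  for (sc in list(scenario_case, scenario_control)) {
    if (!inherits(sc, "sim_scenario")) {
      abort("both scenarios must be created with sim_scenario()")
    }
  }
  same <- identical(scenario_case$transcript_length,
                    scenario_control$transcript_length) &&
    identical(scenario_case$divergent_sites, scenario_control$divergent_sites) &&
    identical(scenario_case$alt_bases, scenario_control$alt_bases) &&
    identical(scenario_case$gene, scenario_control$gene)
  if (!same) {
    abort(
      "case and control scenarios describe different transcripts",
      class = "biallele_mismatched_transcripts"
    )
  }
  cohort_names <- as.character(cohort_names)
  if (length(cohort_names) != 2 || anyDuplicated(cohort_names)) {
    abort("`cohort_names` must be two distinct labels")
  }
  sims <- list(simulate_pileup(scenario_case), simulate_pileup(scenario_control))
  parts <- purrr::map2(sims, cohort_names, function(sim, cohort) {
    relabel <- function(tb) {
      dplyr::mutate(tb, sample = paste(cohort, .data$sample, sep = "_"))
    }
    list(
      pileup = relabel(sim$pileup),
      truth = relabel(sim$truth),
      samples = tibble(
        sample = paste(cohort, sample_names(sim$scenario$n_samples), sep = "_"),
        cohort = cohort,
        sex = sim$scenario$sex
      )
    )
  })
  structure(
    list(
      pileup = dplyr::bind_rows(purrr::map(parts, "pileup")),
      samples = dplyr::bind_rows(purrr::map(parts, "samples")),
      truth = dplyr::bind_rows(purrr::map(parts, "truth")),
      scenarios = setNames(
        list(scenario_case, scenario_control), cohort_names
      )
    ),
    class = "biallele_cohort_sim"
  )
}

#' @export
print.biallele_cohort_sim <- function(x, ...) {
  tab <- table(x$samples$cohort)
  cat(sprintf(
    "<biallele_cohort_sim> %s over %d positions of %s\n",
    paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = " vs "),
    x$scenarios[[1]]$transcript_length, x$scenarios[[1]]$gene
  ))
  invisible(x)
}
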