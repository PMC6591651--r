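#' Detection power for reactivation of a silenced allele
#'
#' Monte-Carlo power surface for the whole pipeline: for every grid cell a
#' two-cohort study is simulated `n_replicates` times (cases expressing the
#' silenced allele at fraction `y_fraction`, controls fully silenced), each
#' replicate is pushed through classification, artifact flagging, burden
#' counting and the cohort comparison, and three detection probabilities are
#' recorded:
#' \describe{
#'   \item{`p_detect_sample`}{probability that a single case sample shows at
#'     least one non-flagged site whose call evidences the silenced allele
#'     (`het` or `hom_alt` at a divergent site; under the silencing design
#'     the active allele carries the reference base, so any alternative-
#'     allele call is evidence).}
#'   \item{`p_detect_any`}{probability that a replicate contains at least one
#'     such case sample.}
#'   \item{`p_reject`}{probability that the cohort permutation test on the
#'     evidence-site burden rejects at level `alpha`.}
#' }
#' Replicates classify with the cell's generating error rate; calibrating
#' `eps` from a negative control is a separate, separately tested stage.
#'
#' @param grid Tibble of scenario cells with columns `y_fraction`, `n_sites`,
#'   `depth`, `n_per_cohort`, `error_rate` (missing columns are filled with
#'   defaults `n_sites = 5`, `depth = 100`, `n_per_cohort = 10`,
#'   `error_rate = 0`).
#' @param n_replicates Replicates per cell (default 50).
#' @param seed Integer seed; every replicate derives its own sub-seed.
#' @param config A [model_config()] used for classification.
#' @param transcript_length Length of the simulated transcript (default 60);
#'   divergent sites are spread evenly along it.
#' @param n_perm Permutations per cohort test (default 199).
#' @param alpha Significance level for `p_reject` (default 0.05).
#' @return A tibble of class `power_result`: the grid plus detection
#'   probabilities, their binomial standard errors, and `n_replicates`.
#' @seealso [autoplot.power_result()]
#' @examples
#' \donttest{
#' pr <- power_analysis(
#'   tibble::tibble(y_fraction = c(0, 0.5), depth = 100, n_per_cohort = 5),
#'   n_replicates = 10, seed = 1
#' )
#' pr
#' }
#' @export
power_analysis <- function(grid, n_replicates = 50, seed = 1,
                           config = model_config(),
                           transcript_length = 60, n_perm = 199,
                           alpha = 0.05) {
  grid <- as_tibble(grid)
  defaults <- list(
    y_fraction = 0, n_sites = 5L, depth = 100L, n_per_cohort = 10L,
    error_rate = 0
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(grid)) grid[[nm]] <- defaults[[nm]]
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    abort("`n_replicates` must be >= 1")
  }
  # Validate every cell up front so a bad cell fails before any simulation.
  purrr::pwalk(grid, function(y_fraction, n_sites, depth, n_per_cohort,
                              error_rate, ...) {
    sim_scenario(
      transcript_length = transcript_length,
      divergent_sites = divergent_positions(transcript_length, n_sites),
      y_fraction = y_fraction, error_rate = error_rate,
      depth = depth, n_samples = n_per_cohort, seed = 1L
    )
  })

  counter <- 0L
  cells <- purrr::pmap(grid, function(y_fraction, n_sites, depth,
                                      n_per_cohort, error_rate, ...) {
    sites <- divergent_positions(transcript_length, n_sites)
    det_sample <- det_any <- reject <- logical(n_replicates)
    frac_detected <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      counter <<- counter + 1L
      rep_seed <- (as.integer(seed) * 2971L + counter * 7919L) %% 2147483629L
      case <- sim_scenario(
        transcript_length, sites,
        y_fraction = y_fraction,
        error_rate = error_rate, depth = depth,
        n_samples = n_per_cohort, seed = rep_seed
      )
      ctrl <- sim_scenario(
        transcript_length, sites,
        y_fraction = 0,
        error_rate = error_rate, depth = depth,
        n_samples = n_per_cohort, seed = rep_seed + 1L
      )
      cs <- simulate_cohort(case, ctrl)
      calls <- classify_sites(cs$pileup, epsilon = error_rate, config = config)
      arts <- flag_artifacts(calls, cs$samples)
      burden <- count_het_sites(calls, arts, classes = c("het", "hom_alt"))
      burden <- dplyr::left_join(cs$samples, burden, by = "sample") |>
        dplyr::mutate(n_het = dplyr::coalesce(.data$n_het, 0L))
      case_hits <- burden$n_het[burden$cohort == "case"] > 0
      frac_detected[r] <- mean(case_hits)
      det_any[r] <- any(case_hits)
      res <- compare_groups(burden,
        n_perm = n_perm, seed = rep_seed + 2L,
        alpha = alpha
      )
      reject[r] <- res$p_perm < alpha
    }
    tibble(
      y_fraction = y_fraction, n_sites = n_sites, depth = depth,
      n_per_cohort = n_per_cohort, error_rate = error_rate,
      p_detect_sample = mean(frac_detected),
      se_detect_sample = sqrt(
        mean(frac_detected) * (1 - mean(frac_detected)) /
          (n_replicates * n_per_cohort)
      ),
      p_detect_any = mean(det_any),
      se_detect_any = sqrt(mean(det_any) * (1 - mean(det_any)) / n_replicates),
      p_reject = mean(reject),
      se_reject = sqrt(mean(reject) * (1 - mean(reject)) / n_replicates),
      n_replicates = as.integer(n_replicates)
    )
  })
  out <- dplyr::bind_rows(cells)
  class(out) <- c("power_result", class(out))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "alpha") <- alpha
  out
}

# m divergent sites spread evenly along the transcript interior.
divergent_positions <- function(transcript_length, n_sites) {
  if (n_sites == 0) {
    return(integer())
  }
  unique(as.integer(round(seq(
    from = max(2, transcript_length / (n_sites + 1)),
    to = transcript_length - 1,
    length.out = n_sites
  ))))
}
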