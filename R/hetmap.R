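#' Assemble a per-sample heterozygosity map
#'
#' Joins one sample's pileup with its genotype calls into the per-position
#' profile (reference fraction, call, used depth) that summarises allelic
#' expression of one transcript in one sample — the object a per-gene
#' "heterozygosity map" figure plots across a cohort. Positions absent from
#' the sample's pileup are absent from the map (uncovered positions are not
#' imputed); positions present but refused by the classifier carry
#' `no_call`.
#'
#' @param pileup Pileup tibble for one sample and one gene.
#' @param calls Output of [classify_sites()] on that same pileup.
#' @return A tibble of class `het_map` with columns `sample`, `gene`, `pos`,
#'   `ref_fraction`, `depth_used`, `call`, ordered by position.
#' @export
build_het_map <- function(pileup, calls) {
  pileup <- as_tibble(pileup)
  calls <- as_tibble(calls)
  if (nrow(pileup) == 0) {
    out <- tibble(
      sample = character(), gene = character(), pos = integer(),
      ref_fraction = numeric(), depth_used = integer(), call = character()
    )
    return(structure(out, class = c("het_map", class(out))))
  }
  if (!identical(sort(unique(pileup$sample)), sort(unique(calls$sample))) ||
    !identical(sort(unique(pileup$gene)), sort(unique(calls$gene)))) {
    abort("pileup and calls describe different samples or genes",
      class = "biallele_mismatch"
    )
  }
  key_p <- paste(pileup$sample, pileup$gene, pileup$pos)
  key_c <- paste(calls$sample, calls$gene, calls$pos)
  if (!setequal(key_p, key_c) || length(key_p) != length(key_c)) {
    abort("calls do not align 1:1 with the pileup's positions",
      class = "biallele_mismatch"
    )
  }
  out <- dplyr::arrange(
    calls[c("sample", "gene", "pos", "ref_fraction", "depth_used", "call")],
    .data$sample, .data$gene, .data$pos
  )
  structure(out, class = c("het_map", class(out)))
}

#' Flag recurrent-artifact positions across a cohort
#'
#' A position that yields every possible genotype class across the samples of
#' *both* cohorts is far more plausibly a recurrent sequencing/alignment
#' artifact than a real polymorphism, and is excluded from heterozygote
#' counting. Two operationalisations of "the majority of control and case
#' samples produce all possible genotypes" are provided:
#' \describe{
#'   \item{`"all_classes"` (default)}{flag a position when, within each
#'     cohort separately, the non-missing calls contain all three classes
#'     `hom_ref`, `het`, `hom_alt`.}
#'   \item{`"majority"`}{flag when, within each cohort, at least
#'     `majority_frac` of the called samples disagree with that cohort's
#'     modal call.}
#' }
#'
#' @param calls Genotype calls (or a [build_het_map()] result) for all
#'   samples, all cohorts, one or more genes.
#' @param samples Sample sheet tibble with columns `sample` and `cohort`.
#' @param rule `"all_classes"` or `"majority"`.
#' @param majority_frac Disagreement threshold for the `"majority"` rule
#'   (default 0.5).
#' @return An object of class `artifact_set`: list with `flagged` (tibble
#'   `gene`, `pos`), `evidence` (per gene, pos, cohort call counts), `rule`
#'   and `majority_frac`.
#' @export
flag_artifacts <- function(calls, samples, rule = c("all_classes", "majority"),
                           majority_frac = 0.5) {
  rule <- match.arg(rule)
  calls <- as_tibble(calls)
  samples <- as_tibble(samples)
  calls <- dplyr::inner_join(calls, samples[c("sample", "cohort")],
    by = "sample"
  )
  cohorts <- unique(calls$cohort)
  if (length(cohorts) < 2) {
    abort(
      paste(
        "artifact flagging needs >= 2 cohorts; for a single cohort run the",
        "pipeline without artifact flagging (empty_artifact_set())"
      ),
      class = "biallele_single_cohort"
    )
  }
  called <- dplyr::filter(calls, .data$call != "no_call")
  evidence <- dplyr::count(called, .data$gene, .data$pos, .data$cohort,
    .data$call,
    name = "n"
  )
  if (nrow(evidence) == 0) {
    out <- empty_artifact_set()
    out$rule <- rule
    out$majority_frac <- majority_frac
    out$cohorts <- cohorts
    return(out)
  }
  per_cohort <- evidence |>
    dplyr::group_by(.data$gene, .data$pos, .data$cohort) |>
    dplyr::summarise(
      n_classes = dplyr::n_distinct(.data$call),
      n_called = sum(.data$n),
      n_modal = max(.data$n),
      .groups = "drop"
    )
  flagged <- per_cohort |>
    dplyr::group_by(.data$gene, .data$pos) |>
    dplyr::summarise(
      flagged = if (rule == "all_classes") {
        dplyr::n() == length(cohorts) && all(.data$n_classes == 3L)
      } else {
        dplyr::n() == length(cohorts) &&
          all((.data$n_called - .data$n_modal) / .data$n_called >= majority_frac)
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$flagged) |>
    dplyr::select("gene", "pos")
  structure(
    list(
      flagged = flagged, evidence = evidence,
      rule = rule, majority_frac = majority_frac, cohorts = cohorts
    ),
    class = "artifact_set"
  )
}

#' An empty artifact set (single-cohort mode)
#'
#' @return An `artifact_set` flagging nothing, for pipelines where artifact
#'   flagging is not applicable (a single cohort).
#' @export
empty_artifact_set <- function() {
  structure(
    list(
      flagged = tibble(gene = character(), pos = integer()),
      evidence = tibble(
        gene = character(), pos = integer(),
        cohort = character(), call = character(), n = integer()
      ),
      rule = "none", majority_frac = NA_real_, cohorts = character()
    ),
    class = "artifact_set"
  )
}

#' @export
print.artifact_set <- function(x, ...) {
  cat(sprintf(
    "<artifact_set> rule \"%s\": %d flagged position(s) across %d cohort(s)\n",
    x$rule, nrow(x$flagged), length(x$cohorts)
  ))
  if (nrow(x$flagged) > 0) {
    cat(
      " ",
      paste(sprintf("%s:%d", x$flagged$gene, x$flagged$pos), collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}

#' Count heterozygous (biallelic-evidence) sites per sample
#'
#' Counts, for every sample and gene, the positions whose call is in
#' `classes` and which are not flagged as recurrent artifacts — flagged
#' positions are never counted as heterozygotes. The default counts `het`
#' calls only, the direct read-out of biallelic expression; passing
#' `classes = c("het", "hom_alt")` additionally counts positions where only
#' the alternative allele is seen, which under a silencing design (the
#' reference-bearing allele is the active copy) also evidences expression of
#' the normally silenced allele.
#'
#' @param map A [build_het_map()] result or any calls tibble covering the
#'   samples to count.
#' @param artifacts An `artifact_set` from [flag_artifacts()] (or
#'   [empty_artifact_set()]).
#' @param classes Calls that count toward the burden (default `"het"`).
#' @return A tibble `sample`, `gene`, `n_het` with one row per sample × gene
#'   present in `map` (zero counts included).
#' @export
count_het_sites <- function(map, artifacts = empty_artifact_set(),
                            classes = "het") {
  map <- as_tibble(map)
  if (!inherits(artifacts, "artifact_set")) {
    abort("`artifacts` must be an artifact_set")
  }
  if (nrow(map) == 0) {
    return(tibble(sample = character(), gene = character(), n_het = integer()))
  }
  flagged_key <- paste(artifacts$flagged$gene, artifacts$flagged$pos)
  map |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::summarise(
      n_het = sum(.data$call %in% classes &
        !(paste(.data$gene, .data$pos) %in% flagged_key)),
      .groups = "drop"
    )
}
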