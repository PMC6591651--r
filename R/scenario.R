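#' Define a synthetic allelic-expression scenario
#'
#' A scenario describes one cohort's worth of samples expressing a single
#' transcript from a mixture of two alleles: a reference-bearing allele
#' (by convention the active X-linked copy) contributing a fraction
#' `1 - y_fraction` of transcripts, and a second allele (e.g. a normally
#' silenced Y-linked copy) carrying the alternative base at each divergent
#' site and contributing `y_fraction`. Per-base miscalls occur with
#' probability `error_rate`, substituting uniformly among the three other
#' bases. The reference sequence is a deterministic A/C/G/T cycle over
#' positions, so two scenarios over the same transcript length automatically
#' share reference and alternative bases.
#'
#' @param transcript_length Transcript length in positions (1-based
#'   coordinates `1..transcript_length`).
#' @param divergent_sites Integer vector of 1-based positions where the two
#'   alleles differ. May be empty (a hemizygous-control-like transcript).
#' @param y_fraction Fraction `f` in `[0, 1]` of transcripts originating from
#'   the second (alternative-base) allele. `f = 0` is complete silencing,
#'   `f = 0.5` balanced biallelic expression.
#' @param error_rate Per-base miscall probability `eps` in `[0, 0.75)`.
#' @param depth Fixed per-position read depth; if `NULL` (default) the total
#'   mapped read count per transcript is drawn uniformly from
#'   `total_read_range` and spread multinomially over positions.
#' @param total_read_range Length-2 integer range for the per-transcript
#'   total mapped read count; the default 653--4033 matches the depth range
#'   observed for a SPRY3-length transcript in cerebellar RNA-seq libraries.
#' @param read_length Number of consecutive positions each mapped read
#'   covers under the `total_read_range` depth law (default 100, a typical
#'   short-read length); per-position depth is the read coverage. Ignored
#'   when `depth` is fixed.
#' @param n_samples Number of samples to simulate (>= 1).
#' @param sex Sample sex labels, `"male"` or `"female"`, recycled to
#'   `n_samples`. Female samples are simulated as true heterozygotes at
#'   divergent sites (both alleles expressed 50:50, as in pseudoautosomal or
#'   autosomal heterozygosity) regardless of `y_fraction`.
#' @param alt_bases Optional named character vector mapping divergent
#'   positions to their alternative base; defaults to the next base in the
#'   A/C/G/T cycle after the reference base. Must differ from the reference
#'   base at every site.
#' @param gene Gene/transcript identifier used in outputs.
#' @param seed Integer RNG seed. The same scenario and seed give bit-identical
#'   simulations.
#'
#' @return An object of class `sim_scenario` (a validated list).
#' @seealso [simulate_pileup()], [simulate_cohort()]
#' @examples
#' sc <- sim_scenario(
#'   transcript_length = 100, divergent_sites = c(20, 60),
#'   y_fraction = 0.5, error_rate = 0.005, depth = 80,
#'   n_samples = 4, seed = 1
#' )
#' sc
#' @export
sim_scenario <- function(transcript_length,
                         divergent_sites = integer(),
                         y_fraction = 0,
                         error_rate = 0,
                         depth = NULL,
                         total_read_range = c(653L, 4033L),
                         read_length = 100L,
                         n_samples = 1,
                         sex = "male",
                         alt_bases = NULL,
                         gene = "geneA",
                         seed = 1L) {
  stop_field <- function(field, msg) {
    abort(sprintf("Invalid scenario field `%s`: %s", field, msg),
      class = "biallele_invalid_scenario"
    )
  }
  if (!is.numeric(transcript_length) || length(transcript_length) != 1 ||
    is.na(transcript_length) || transcript_length < 1) {
    stop_field("transcript_length", "must be a single integer >= 1")
  }
  transcript_length <- as.integer(transcript_length)
  divergent_sites <- as.integer(divergent_sites)
  if (anyNA(divergent_sites) || anyDuplicated(divergent_sites) ||
    any(divergent_sites < 1L) || any(divergent_sites > transcript_length)) {
    stop_field(
      "divergent_sites",
      "must be distinct positions within [1, transcript_length]"
    )
  }
  divergent_sites <- sort(divergent_sites)
  if (!is.numeric(y_fraction) || length(y_fraction) != 1 ||
    is.na(y_fraction) || y_fraction < 0 || y_fraction > 1) {
    stop_field("y_fraction", "must be a single value in [0, 1]")
  }
  if (!is.numeric(error_rate) || length(error_rate) != 1 ||
    is.na(error_rate) || error_rate < 0 || error_rate >= 0.75) {
    stop_field("error_rate", "must be a single value in [0, 0.75)")
  }
  if (!is.null(depth)) {
    if (!is.numeric(depth) || length(depth) != 1 || is.na(depth) ||
      depth < 1) {
      stop_field("depth", "must be NULL or a single integer >= 1")
    }
    depth <- as.integer(depth)
  } else {
    total_read_range <- as.integer(total_read_range)
    if (length(total_read_range) != 2 || anyNA(total_read_range) ||
      total_read_range[1] < 1 ||
      total_read_range[1] > total_read_range[2]) {
      stop_field("total_read_range", "must be an increasing positive range")
    }
    if (!is.numeric(read_length) || length(read_length) != 1 ||
      is.na(read_length) || read_length < 1) {
      stop_field("read_length", "must be a single integer >= 1")
    }
    read_length <- as.integer(read_length)
  }
  if (!is.numeric(n_samples) || length(n_samples) != 1 || is.na(n_samples) ||
    n_samples < 1) {
    stop_field("n_samples", "must be a single integer >= 1")
  }
  n_samples <- as.integer(n_samples)
  sex <- rep_len(as.character(sex), n_samples)
  if (!all(sex %in% c("male", "female"))) {
    stop_field("sex", "labels must be \"male\" or \"female\"")
  }
  ref <- reference_bases(transcript_length)
  if (is.null(alt_bases)) {
    alt_bases <- setNames(
      default_alt_bases(ref[divergent_sites]),
      as.character(divergent_sites)
    )
  } else {
    alt_bases <- alt_bases[as.character(divergent_sites)]
    if (anyNA(alt_bases) || !all(alt_bases %in% BASES)) {
      stop_field("alt_bases", "must name a valid base for every divergent site")
    }
    if (any(alt_bases == ref[divergent_sites])) {
      stop_field("alt_bases", "alternative base equals reference base")
    }
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_field("seed", "must be a single integer")
  }
  structure(
    list(
      transcript_length = transcript_length,
      divergent_sites = divergent_sites,
      alt_bases = alt_bases,
      y_fraction = y_fraction,
      error_rate = error_rate,
      depth = depth,
      total_read_range = if (is.null(depth)) total_read_range else NULL,
      read_length = if (is.null(depth)) read_length else NULL,
      n_samples = n_samples,
      sex = sex,
      gene = gene,
      seed = as.integer(seed)
    ),
    class = "sim_scenario"
  )
}

# Reference base at each position: a deterministic A/C/G/T cycle, so any two
# scenarios over the same coordinates agree on ref (and default alt) bases.
reference_bases <- function(transcript_length) {
  BASES[(seq_len(transcript_length) - 1L) %% 4L + 1L]
}

default_alt_bases <- function(ref) {
  BASES[match(ref, BASES) %% 4L + 1L]
}

#' @export
print.sim_scenario <- function(x, ...) {
  depth_law <- if (is.null(x$depth)) {
    sprintf(
      "total reads ~ U[%d, %d], read length %d",
      x$total_read_range[1], x$total_read_range[2], x$read_length
    )
  } else {
    sprintf("fixed depth %d per position", x$depth)
  }
  cat(sprintf(
    paste0(
      "<sim_scenario> gene %s: %d positions, %d divergent site(s)\n",
      "  y_fraction f = %g, error_rate eps = %g\n",
      "  %s\n  %d sample(s) (%d male, %d female), seed %d\n"
    ),
    x$gene, x$transcript_length, length(x$divergent_sites),
    x$y_fraction, x$error_rate, depth_law, x$n_samples,
    sum(x$sex == "male"), sum(x$sex == "female"), x$seed
  ))
  invisible(x)
}
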