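#' Read a samtools mpileup text file into a base-count table
#'
#' Consumes the standard 6-column mpileup text format (chrom/gene, 1-based
#' position, reference base, depth, read bases, base qualities) and decodes
#' the read-bases string into per-base counts:
#' * `.` and `,` count toward the reference base (strands are merged);
#' * `A C G T a c g t` count toward the named base, case-insensitively;
#' * `^` consumes the following mapping-quality character, `$` is consumed;
#' * `+n...`/`-n...` indel runs are consumed and ignored;
#' * `*`, `#`, `N`, `n`, `<`, `>` are excluded from the used depth.
#'
#' The decoded A+C+G+T total defines `depth` in the returned table (the
#' "depth used"); if the file's depth field disagrees with the decoded reads
#' after accounting for the excluded symbols, a warning is raised and the
#' decoded counts win.
#'
#' @param file Path to an mpileup text file (one sample per file).
#' @param sample Sample identifier; defaults to the file name without its
#'   `.mpileup`/`.pileup` extension.
#' @return A tibble with columns `sample`, `gene`, `pos`, `ref_base`,
#'   `depth`, `nA`, `nC`, `nG`, `nT`, sorted by position, one row per covered
#'   position.
#' @seealso [read_counts_tsv()], [write_fixture()]
#' @export
read_mpileup <- function(file, sample = NULL) {
  if (is.null(sample)) {
    sample <- sub("\\.(m?pileup|txt)$", "", basename(file))
  }
  lines <- readr::read_lines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_pileup())
  }
  rows <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 5) {
      abort(sprintf("malformed mpileup line %d: expected >= 5 tab-separated fields", i),
        class = "biallele_parse_error"
      )
    }
    pos <- suppressWarnings(as.integer(fields[2]))
    ref_base <- toupper(fields[3])
    if (is.na(pos) || pos < 1 || !(ref_base %in% c(BASES, "N"))) {
      abort(sprintf("malformed mpileup line %d: bad position or reference base", i),
        class = "biallele_parse_error"
      )
    }
    decoded <- decode_read_bases(fields[5], ref_base, i)
    claimed <- suppressWarnings(as.integer(fields[4]))
    if (!is.na(claimed) && claimed != decoded$n_reads) {
      warn(sprintf(
        "mpileup line %d: depth field %d disagrees with %d decoded reads; using decoded counts",
        i, claimed, decoded$n_reads
      ))
    }
    tibble(
      sample = sample, gene = fields[1], pos = pos, ref_base = ref_base,
      depth = sum(decoded$counts),
      nA = decoded$counts[["A"]], nC = decoded$counts[["C"]],
      nG = decoded$counts[["G"]], nT = decoded$counts[["T"]]
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$gene, .data$pos)
  validate_pileup(out)
}

# Decode one mpileup read-bases string into A/C/G/T counts.
# Returns the counts and the number of reads the string represents
# (including excluded symbols such as '*' and 'N', for depth checking).
decode_read_bases <- function(s, ref_base, line_no = NA) {
  # '^' starts a read segment; the following character is a mapping quality
  # and may be any byte, so strip the pair before anything else.
  s <- gsub("\\^.", "", s, perl = TRUE)
  s <- gsub("$", "", s, fixed = TRUE)
  # Indel runs: [+-]<len><len bases>; length digits may be multi-digit.
  repeat {
    m <- regexpr("[+-][0-9]+", s, perl = TRUE)
    if (m == -1) break
    len <- as.integer(substr(s, m + 1L, m + attr(m, "match.length") - 1L))
    drop_to <- m + attr(m, "match.length") + len - 1L
    if (drop_to > nchar(s)) {
      abort(sprintf("malformed mpileup line %s: truncated indel run", line_no),
        class = "biallele_parse_error"
      )
    }
    s <- paste0(substr(s, 1L, m - 1L), substr(s, drop_to + 1L, nchar(s)))
  }
  if (s == "*" || s == "") {
    # samtools prints a lone '*' placeholder for zero-depth columns
    return(list(counts = setNames(rep(0L, 4L), BASES), n_reads = 0L))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  up <- toupper(chars)
  up[chars %in% c(".", ",")] <- ref_base
  known <- up %in% BASES
  skipped <- up %in% c("*", "#", "N", "<", ">")
  if (any(!known & !skipped)) {
    bad <- chars[!known & !skipped][1]
    abort(
      sprintf("malformed mpileup line %s: unexpected symbol '%s' in read bases", line_no, bad),
      class = "biallele_parse_error"
    )
  }
  counts <- vapply(BASES, function(b) sum(up == b), integer(1))
  list(counts = counts, n_reads = length(chars))
}

#' Read a per-position base-count TSV
#'
#' Reads the package's tab-separated counts format with the exact header
#' `sample gene pos ref_base depth nA nC nG nT` and validates every row:
#' counts must be non-negative, `nA+nC+nG+nT` must equal `depth`, and
#' `(sample, gene, pos)` must be unique.
#'
#' @param file Path to a counts TSV (as written by [write_fixture()]).
#' @return A validated pileup tibble (see [read_mpileup()] for columns).
#' @export
read_counts_tsv <- function(file) {
  hdr <- strsplit(readr::read_lines(file, n_max = 1), "\t", fixed = TRUE)[[1]]
  expected <- c("sample", "gene", "pos", "ref_base", "depth", BASE_COLS)
  missing <- setdiff(expected, hdr)
  if (length(missing) > 0) {
    abort(sprintf("counts TSV is missing column(s): %s",
                  paste(missing, collapse = ", ")),
      class = "biallele_parse_error"
    )
  }
  tb <- readr::read_tsv(file,
    col_types = readr::cols(
      sample = readr::col_character(), gene = readr::col_character(),
      pos = readr::col_integer(), ref_base = readr::col_character(),
      depth = readr::col_integer(), nA = readr::col_integer(),
      nC = readr::col_integer(), nG = readr::col_integer(),
      nT = readr::col_integer()
    ),
    progress = FALSE
  )
  if (nrow(tb) == 0) {
    return(empty_pileup())
  }
  validate_pileup(tb[expected])
}

#' Read a sample sheet TSV
#'
#' @param file Path to a tab-separated sample sheet with header
#'   `sample cohort sex`.
#' @return A tibble with those three character columns.
#' @export
read_sample_sheet <- function(file) {
  tb <- readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(c("sample", "cohort", "sex"), names(tb))
  if (length(missing) > 0) {
    abort(sprintf("sample sheet is missing column(s): %s",
                  paste(missing, collapse = ", ")),
      class = "biallele_parse_error"
    )
  }
  tb[c("sample", "cohort", "sex")]
}

BASE_COLS <- c("nA", "nC", "nG", "nT")

empty_pileup <- function() {
  tibble(
    sample = character(), gene = character(), pos = integer(),
    ref_base = character(), depth = integer(),
    nA = integer(), nC = integer(), nG = integer(), nT = integer()
  )
}

# Shared invariant checks for any pileup tibble entering the pipeline.
validate_pileup <- function(tb) {
  counts <- as.matrix(tb[BASE_COLS])
  if (any(is.na(counts)) || any(counts < 0)) {
    bad <- which(rowSums(is.na(counts) | counts < 0) > 0)[1]
    abort(sprintf("negative or missing base count in row %d", bad),
      class = "biallele_invalid_pileup"
    )
  }
  mismatch <- which(rowSums(counts) != tb$depth)
  if (length(mismatch) > 0) {
    r <- tb[mismatch[1], ]
    abort(
      sprintf(
        "base counts do not sum to depth for sample %s, %s pos %d (row %d)",
        r$sample, r$gene, r$pos, mismatch[1]
      ),
      class = "biallele_invalid_pileup"
    )
  }
  if (any(tb$pos < 1)) {
    abort("positions must be >= 1 (1-based coordinates)",
      class = "biallele_invalid_pileup"
    )
  }
  if (!all(tb$ref_base %in% c(BASES, "N"))) {
    abort("reference base must be one of A, C, G, T",
      class = "biallele_invalid_pileup"
    )
  }
  key <- paste(tb$sample, tb$gene, tb$pos)
  if (anyDuplicated(key)) {
    r <- tb[which(duplicated(key))[1], ]
    abort(
      sprintf("duplicate entry for sample %s, %s pos %d", r$sample, r$gene, r$pos),
      class = "biallele_invalid_pileup"
    )
  }
  tb
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Emits a simulation (from [simulate_pileup()] or [simulate_cohort()]) as
#' the pipeline's on-disk interchange formats: one samtools-style mpileup
#' text file per sample (`<sample>.mpileup`, base qualities written as a
#' constant high-quality `I`), a combined counts TSV (`counts.tsv`), a sample
#' sheet (`samples.tsv`), the ground truth (`truth.tsv`), and the scenario
#' parameters as `key = value` lines (`scenario.txt`). Reading the files back
#' with [read_mpileup()] / [read_counts_tsv()] reproduces the simulated
#' counts exactly.
#'
#' @param sim A `biallele_sim` or `biallele_cohort_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(sim, dir) {
  if (!inherits(sim, c("biallele_sim", "biallele_cohort_sim"))) {
    abort("`sim` must come from simulate_pileup() or simulate_cohort()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot create output directory '%s'", dir))
  }
  pileup <- sim$pileup
  samples <- if (!is.null(sim$samples)) {
    sim$samples
  } else {
    tibble(
      sample = sample_names(sim$scenario$n_samples),
      cohort = "cohort1", sex = sim$scenario$sex
    )
  }
  files <- c()
  for (s in unique(pileup$sample)) {
    f <- file.path(dir, paste0(s, ".mpileup"))
    write_mpileup_file(dplyr::filter(pileup, .data$sample == s), f)
    files <- c(files, setNames(f, paste0("mpileup_", s)))
  }
  counts_f <- file.path(dir, "counts.tsv")
  readr::write_tsv(pileup, counts_f, progress = FALSE)
  sheet_f <- file.path(dir, "samples.tsv")
  readr::write_tsv(samples, sheet_f, progress = FALSE)
  files <- c(files, counts = counts_f, samples = sheet_f)
  if (!is.null(sim$truth)) {
    truth_f <- file.path(dir, "truth.tsv")
    readr::write_tsv(sim$truth, truth_f, progress = FALSE)
    files <- c(files, truth = truth_f)
  }
  scen <- sim$scenario %||% sim$scenarios
  cfg_f <- file.path(dir, "scenario.txt")
  readr::write_lines(scenario_config_lines(scen), cfg_f)
  files <- c(files, scenario = cfg_f)
  invisible(files)
}

# One sample's pileup as mpileup text. Read bases alternate '.' and ',' for
# reference reads and upper/lower case for non-reference reads, exercising
# the strand-merging path of the decoder; a '^]' prefix and '$' suffix mark
# the first and last read. All coordinates 1-based inclusive.
write_mpileup_file <- function(pileup, file) {
  lines <- purrr::pmap_chr(
    pileup[c("gene", "pos", "ref_base", "depth", BASE_COLS)],
    function(gene, pos, ref_base, depth, nA, nC, nG, nT) {
      counts <- c(A = nA, C = nC, G = nG, T = nT)
      bases <- character(0)
      nref <- counts[[ref_base]]
      bases <- c(bases, rep_len(c(".", ","), nref))
      for (b in setdiff(BASES, ref_base)) {
        bases <- c(bases, rep_len(c(b, tolower(b)), counts[[b]]))
      }
      if (length(bases) == 0) {
        return(paste(gene, pos, ref_base, 0L, "*", "*", sep = "\t"))
      }
      bases[1] <- paste0("^]", bases[1])
      bases[length(bases)] <- paste0(bases[length(bases)], "$")
      paste(gene, pos, ref_base, depth,
        paste(bases, collapse = ""),
        strrep("I", depth),
        sep = "\t"
      )
    }
  )
  readr::write_lines(lines, file)
}

scenario_config_lines <- function(scen) {
  if (inherits(scen, "sim_scenario")) scen <- list(scenario = scen)
  unlist(purrr::imap(scen, function(sc, nm) {
    kv <- function(k, v) sprintf("%s.%s = %s", nm, k, paste(v, collapse = ","))
    c(
      kv("gene", sc$gene),
      kv("transcript_length", sc$transcript_length),
      kv("divergent_sites", if (length(sc$divergent_sites)) sc$divergent_sites else "none"),
      kv("alt_bases", if (length(sc$alt_bases)) unname(sc$alt_bases) else "none"),
      kv("y_fraction", sc$y_fraction),
      kv("error_rate", sc$error_rate),
      kv("depth", if (is.null(sc$depth)) {
        sprintf(
          "reads~uniform[%d,%d] x length %d",
          sc$total_read_range[1], sc$total_read_range[2], sc$read_length
        )
      } else {
        sc$depth
      }),
      kv("n_samples", sc$n_samples),
      kv("seed", sc$seed)
    )
  }), use.names = FALSE)
}
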