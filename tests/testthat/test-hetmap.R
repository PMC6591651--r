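# Build a calls tibble directly (one gene, one position per row spec).
make_calls <- function(sample, call, pos = 1L, gene = "g") {
  tibble::tibble(
    sample = sample, gene = gene, pos = as.integer(pos),
    ref_fraction = NA_real_, depth_used = 100L, call = call
  )
}

test_that("heterozygosity maps align 1:1 with the classified pileup", {
  sim <- simulate_pileup(sim_scenario(40,
    divergent_sites = c(10, 20),
    y_fraction = 0, error_rate = 0, depth = 60, n_samples = 1, seed = 2
  ))
  calls <- classify_sites(sim$pileup, epsilon = 0)
  map <- build_het_map(sim$pileup, calls)
  expect_s3_class(map, "het_map")
  expect_identical(nrow(map), nrow(sim$pileup))
  expect_true(all(map$ref_fraction == 1))
  expect_false(any(map$call == "het"))
  expect_identical(map$pos, sort(map$pos))

  # empty pileup -> empty map
  empty <- build_het_map(sim$pileup[0, ], calls[0, ])
  expect_identical(nrow(empty), 0L)

  # mismatched inputs refused
  other <- dplyr::mutate(calls, sample = "other")
  expect_error(build_het_map(sim$pileup, other), class = "biallele_mismatch")
  expect_error(build_het_map(sim$pileup, calls[-1, ]),
    class = "biallele_mismatch"
  )
})

test_that("a female (true heterozygous) sample yields het calls at divergent sites", {
  sim <- simulate_pileup(sim_scenario(30,
    divergent_sites = c(5, 15),
    y_fraction = 0, error_rate = 0.005, depth = 200, n_samples = 1,
    sex = "female", seed = 6
  ))
  calls <- classify_sites(sim$pileup, epsilon = 0.005)
  map <- build_het_map(sim$pileup, calls)
  expect_identical(map$call[map$pos %in% c(5, 15)], c("het", "het"))
  truth_het <- dplyr::filter(sim$truth, class == "het")
  expect_setequal(truth_het$pos, c(5, 15))
})

test_that("artifact flagging implements the all-three-classes-per-cohort rule", {
  sheet <- tibble::tibble(
    sample = c("a1", "a2", "a3", "c1", "c2", "c3"),
    cohort = rep(c("case", "control"), each = 3),
    sex = "male"
  )
  # position 1: all classes in both cohorts -> flagged
  # position 2: all hom_ref -> kept
  # position 3: all classes in case only -> kept
  calls <- dplyr::bind_rows(
    make_calls(sheet$sample, rep(c("hom_ref", "het", "hom_alt"), 2), pos = 1),
    make_calls(sheet$sample, rep("hom_ref", 6), pos = 2),
    make_calls(sheet$sample, c("hom_ref", "het", "hom_alt", rep("hom_ref", 3)), pos = 3)
  )
  arts <- flag_artifacts(calls, sheet)
  expect_identical(arts$flagged$pos, 1L)
  expect_identical(arts$rule, "all_classes")

  # no_call never contributes evidence
  calls4 <- dplyr::bind_rows(
    make_calls(sheet$sample[1:3], c("hom_ref", "het", "no_call"), pos = 4),
    make_calls(sheet$sample[4:6], c("hom_ref", "het", "hom_alt"), pos = 4)
  )
  expect_identical(nrow(flag_artifacts(calls4, sheet)$flagged), 0L)

  expect_error(flag_artifacts(calls, sheet[1:3, ]),
    class = "biallele_single_cohort"
  )
})

test_that("sex-linked true heterozygosity is not mistaken for an artifact", {
  # females het, males hom_ref, in both cohorts: only two classes ever seen
  sheet <- tibble::tibble(
    sample = paste0("s", 1:8),
    cohort = rep(c("case", "control"), each = 4),
    sex = rep(c("male", "male", "female", "female"), 2)
  )
  calls <- make_calls(
    sheet$sample,
    ifelse(sheet$sex == "female", "het", "hom_ref"),
    pos = 1
  )
  arts <- flag_artifacts(calls, sheet)
  expect_identical(nrow(arts$flagged), 0L)
})

test_that("the stricter majority-disagreement mode flags split positions", {
  sheet <- tibble::tibble(
    sample = paste0("s", 1:8),
    cohort = rep(c("case", "control"), each = 4), sex = "male"
  )
  # half of each cohort disagrees with the modal call
  calls <- make_calls(
    sheet$sample,
    rep(c("hom_ref", "hom_ref", "het", "hom_alt"), 2),
    pos = 1
  )
  expect_identical(nrow(flag_artifacts(calls, sheet, rule = "majority")$flagged), 1L)
  expect_identical(
    nrow(flag_artifacts(calls, sheet, rule = "majority", majority_frac = 0.6)$flagged),
    0L
  )
  # same position under the default rule is also flagged (all three classes)
  expect_identical(nrow(flag_artifacts(calls, sheet)$flagged), 1L)
})

test_that("removing a sample never adds a flagged position (monotonicity)", {
  sheet <- tibble::tibble(
    sample = paste0("s", 1:10),
    cohort = rep(c("case", "control"), each = 5), sex = "male"
  )
  withr::with_seed(99, {
    for (rep in 1:20) {
      calls <- dplyr::bind_rows(lapply(1:4, function(p) {
        make_calls(sheet$sample,
          sample(c("hom_ref", "het", "hom_alt", "no_call"), 10, replace = TRUE),
          pos = p
        )
      }))
      full <- flag_artifacts(calls, sheet)$flagged
      drop <- sample(sheet$sample[-c(5, 10)], 1) # keep both cohorts alive
      reduced <- flag_artifacts(
        dplyr::filter(calls, sample != drop), sheet
      )$flagged
      expect_true(all(paste(reduced$gene, reduced$pos) %in%
        paste(full$gene, full$pos)))
    }
  })
})

test_that("het-site counting excludes flagged positions and respects subset ordering", {
  map <- make_calls("s1", c("het", "het", "het", "hom_ref"), pos = 1:4)
  none <- empty_artifact_set()
  expect_identical(count_het_sites(map, none)$n_het, 3L)

  all_flagged <- none
  all_flagged$flagged <- tibble::tibble(gene = "g", pos = 1:3)
  expect_identical(count_het_sites(map, all_flagged)$n_het, 0L)

  some <- none
  some$flagged <- tibble::tibble(gene = "g", pos = 1L)
  # A1 subset of A2 implies count(A1) >= count(A2)
  expect_gte(
    count_het_sites(map, some)$n_het,
    count_het_sites(map, all_flagged)$n_het
  )
  expect_identical(count_het_sites(map, some)$n_het, 2L)

  # zero het calls and empty maps count zero
  hom <- make_calls("s1", rep("hom_ref", 3), pos = 1:3)
  expect_identical(count_het_sites(hom, none)$n_het, 0L)
  expect_identical(nrow(count_het_sites(map[0, ], none)), 0L)
})

test_that("null false-het rate matches the direct per-site call probability", {
  # f = 0 males with moderate error: predicted per-sample het count is
  # L * P(het call | hom_ref), computed by enumerating every k directly
  d <- 50
  eps <- 0.05
  L <- 200
  cfg <- model_config(d_min = 20, tau = 0.7)
  p_het <- call_prob_oracle(d, p_true = 1 - eps, epsilon = eps,
                            target = "het", config = cfg)
  n <- 40
  sim <- simulate_pileup(sim_scenario(L,
    y_fraction = 0, error_rate = eps,
    depth = d, n_samples = n, seed = 44
  ))
  calls <- classify_sites(sim$pileup, epsilon = eps, config = cfg)
  counts <- count_het_sites(calls, empty_artifact_set())
  expected <- L * p_het
  mc_se <- sqrt(L * p_het * (1 - p_het) / n)
  expect_lt(abs(mean(counts$n_het) - expected), 3 * mc_se + 1e-9)
  # and the false-call rate vanishes at strict settings with small error
  strict <- classify_sites(sim$pileup,
    epsilon = eps,
    config = model_config(d_min = 20, tau = 0.999)
  )
  expect_lte(
    mean(count_het_sites(strict, empty_artifact_set())$n_het),
    mean(counts$n_het)
  )
})
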