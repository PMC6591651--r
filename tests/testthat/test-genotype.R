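test_that("error-rate calibration is the pooled non-reference fraction", {
  # no mismatches at all
  clean <- make_pileup(nA = 50, ref_base = "A")
  expect_identical(estimate_error_rate(clean)$epsilon, 0)

  # 100 mismatches in 10,000 pooled reads spread over 100 columns
  pu <- dplyr::bind_rows(lapply(1:100, function(i) {
    make_pileup(nA = 99, nG = 1, ref_base = "A", pos = i)
  }))
  ne <- estimate_error_rate(pu)
  expect_equal(ne$epsilon, 0.01)
  expect_identical(ne$pooled_depth, 10000L)
  expect_identical(ne$n_positions_excluded, 0L)
})

test_that("outlier columns are excluded and the ratio recomputed without them", {
  pu <- dplyr::bind_rows(
    lapply(1:100, function(i) make_pileup(nA = 99, nG = 1, ref_base = "A", pos = i)),
    make_pileup(nA = 50, nC = 50, ref_base = "A", pos = 101)
  )
  ne <- estimate_error_rate(pu, outlier_fraction = 0.2)
  # recomputed by hand over the 100 clean columns only
  expect_equal(ne$epsilon, 100 / 10000)
  expect_identical(ne$n_positions_excluded, 1L)
  expect_identical(ne$excluded$pos, 101L)
  expect_equal(ne$excluded$nonref_fraction, 0.5)
  expect_equal(tidy(ne)$epsilon, ne$epsilon)
})

test_that("degenerate noise inputs raise errors", {
  expect_error(estimate_error_rate(make_pileup()),
    class = "biallele_noise_error"
  ) # zero depth only
  hot <- make_pileup(nA = 10, nC = 90, ref_base = "A")
  expect_error(estimate_error_rate(hot, outlier_fraction = 0.2),
    "usable",
    class = "biallele_noise_error"
  )
  # pooled rate above the identifiable range
  expect_error(estimate_error_rate(hot, outlier_fraction = 0.95),
    "0.75",
    class = "biallele_noise_error"
  )
})

test_that("classifier reproduces the idealised 1 / 0.5 / 0 model at eps = 0", {
  calls <- classify_sites(make_pileup(nA = 100, ref_base = "A"), epsilon = 0)
  expect_identical(calls$call, "hom_ref")
  expect_identical(calls$ll_hom_ref, 0) # log Binom(100; 100, 1)
  expect_equal(calls$ll_het, 100 * log(0.5))
  expect_identical(calls$ll_hom_alt, -Inf)
  expect_equal(calls$q_hom_ref, 1)
})

test_that("a balanced column is called heterozygous with oracle-checked posteriors", {
  eps <- 0.01
  calls <- classify_sites(make_pileup(nA = 50, nC = 50, ref_base = "A"),
    epsilon = eps, config = model_config(tau = 0.95)
  )
  expect_identical(calls$call, "het")
  # brute-force posterior from the independent factorial-sum pmf
  p <- c(1 - eps, 0.5 * (1 - eps) + 0.5 * eps / 3, eps / 3)
  ll <- vapply(p, function(pp) log_binom_pmf_oracle(50, 100, pp), numeric(1))
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  expect_equal(
    c(calls$q_hom_ref, calls$q_het, calls$q_hom_alt),
    post,
    tolerance = 1e-12
  )
  expect_gt(calls$q_het, 0.95)
})

test_that("the depth gate forces no_call regardless of counts", {
  calls <- classify_sites(make_pileup(nA = 5, nC = 5, ref_base = "A"),
    epsilon = 0.01, config = model_config(d_min = 20)
  )
  expect_identical(calls$call, "no_call")
  # posteriors still normalised and reported
  expect_equal(calls$q_hom_ref + calls$q_het + calls$q_hom_alt, 1,
    tolerance = 1e-12
  )
})

test_that("log-likelihoods match the factorial-sum oracle for all small columns", {
  for (eps in c(0, 0.01, 0.05)) {
    p <- biallele:::genotype_ref_probs(eps)
    for (d in c(1, 2, 5, 13, 20)) {
      pu <- dplyr::bind_rows(lapply(0:d, function(k) {
        make_pileup(nA = k, nC = d - k, ref_base = "A", pos = k + 1)
      }))
      calls <- classify_sites(pu, epsilon = eps)
      for (k in 0:d) {
        expect_equal(
          c(calls$ll_hom_ref[k + 1], calls$ll_het[k + 1], calls$ll_hom_alt[k + 1]),
          unname(vapply(p, function(pp) log_binom_pmf_oracle(k, d, pp), numeric(1))),
          tolerance = 1e-9
        )
      }
    }
  }
})

test_that("posteriors are normalised and ref/alt label symmetry holds at eps = 0", {
  d <- 40
  pu <- dplyr::bind_rows(lapply(0:d, function(k) {
    make_pileup(nA = k, nC = d - k, ref_base = "A", pos = k + 1)
  }))
  pri <- c(0.5, 0.3, 0.2)
  fwd <- classify_sites(pu, epsilon = 0, config = model_config(priors = pri))
  expect_true(all(abs(fwd$q_hom_ref + fwd$q_het + fwd$q_hom_alt - 1) < 1e-12))
  # swap k -> d - k and the hom priors
  rev <- classify_sites(pu, epsilon = 0,
    config = model_config(priors = pri[c(3, 2, 1)])
  )
  expect_equal(fwd$q_hom_ref, base::rev(rev$q_hom_alt), tolerance = 1e-12)
  expect_equal(fwd$q_het, base::rev(rev$q_het), tolerance = 1e-12)
})

test_that("calls partition the count range into contiguous genotype bands", {
  for (eps in c(0, 0.01, 0.05)) {
    d <- 60
    pu <- dplyr::bind_rows(lapply(0:d, function(k) {
      make_pileup(nA = k, nC = d - k, ref_base = "A", pos = k + 1)
    }))
    calls <- classify_sites(pu, epsilon = eps,
      config = model_config(d_min = 20, tau = 0.95)
    )
    named <- calls$call[calls$call != "no_call"]
    runs <- rle(named)$values
    # increasing k can only move hom_alt -> het -> hom_ref
    expect_identical(runs, runs[order(match(runs, c("hom_alt", "het", "hom_ref")))])
    expect_identical(anyDuplicated(runs), 0L)
  }
})

test_that("error-rate recovery on hemizygous simulations is within Monte-Carlo error", {
  eps <- 0.01
  sim <- simulate_pileup(sim_scenario(400,
    y_fraction = 0, error_rate = eps,
    depth = 100, n_samples = 10, seed = 31
  ))
  ne <- estimate_error_rate(sim$pileup)
  expect_lt(abs(ne$epsilon - eps), 3 * sqrt(eps * (1 - eps) / ne$pooled_depth))
})

test_that("site frequency table reports per-base fractions", {
  sf <- site_frequency_table(make_pileup(nA = 5, ref_base = "A"))
  expect_identical(sf$nonref_fraction, 0)
  sf2 <- site_frequency_table(make_pileup(nC = 3, nG = 3, ref_base = "C"))
  expect_equal(sf2$ref_fraction, 0.5)
  expect_equal(sf2$fG, 0.5)
  expect_error(site_frequency_table(make_pileup()[0, ]),
    class = "biallele_invalid_pileup"
  )

  # simulated balanced site matches the recorded truth within MC error
  n <- 2000
  sim <- simulate_pileup(sim_scenario(1,
    divergent_sites = 1, y_fraction = 0.5,
    error_rate = 0.01, depth = 100, n_samples = n, seed = 12
  ))
  sf3 <- site_frequency_table(sim$pileup)
  p_ref <- unique(sim$truth$p_ref)
  expect_lt(
    abs(mean(sf3$ref_fraction) - p_ref),
    3 * sqrt(p_ref * (1 - p_ref) / 100 / n)
  )
})
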