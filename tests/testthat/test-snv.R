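test_that("posterior matches an independent log-space oracle to 1e-6", {
  grid <- default_maf_grid()
  set.seed(101)
  for (i in 1:1000) {
    depth <- sample(c(30, 100, 300, 1000, 5000), 1)
    n_other <- sample(0:2, 1)
    n_alt <- sample(0:min(depth - n_other, 50), 1)
    n_ref <- depth - n_alt - n_other
    fwd <- c(n_other, n_ref, 0, n_alt)  # A other, C ref, T alt
    pu <- manual_pileup(fwd, c(0, 0, 0, 0), ref = "C")
    p0 <- sample(c(0.9, 0.99, 0.999), 1)
    e <- sample(c(0.0005, 0.001, 0.005), 1)
    res <- mutation_posterior(pu, p0, e, grid)
    counts <- c(A = n_other, C = n_ref, G = 0, T = n_alt)
    ora <- oracle_posterior(counts, "C", res$alt, p0, e, grid)
    expect_lt(abs(res$posterior - ora), 1e-6)
  }
})

test_that("posterior is monotone in alt count and in the no-mutation prior", {
  grid <- default_maf_grid()
  post_at <- function(n_alt, p0) {
    pu <- manual_pileup(c(0, 500 - n_alt, 0, n_alt), c(0, 0, 0, 0))
    mutation_posterior(pu, p0, 0.001, grid)$posterior
  }
  ps <- vapply(c(0, 1, 2, 4, 8, 16, 32), post_at, numeric(1), p0 = 0.999)
  expect_true(all(diff(ps) >= -1e-12))
  expect_true(all(ps >= 0 & ps <= 1))

  # hotspot prior (smaller P(F=0)) raises the posterior, strictly with alt reads
  expect_gt(post_at(5, 0.9), post_at(5, 0.999))
  expect_gte(post_at(0, 0.9), post_at(0, 0.999) - 1e-12)
})

test_that("clean reference pileups stay below the call threshold", {
  pu <- manual_pileup(c(0, 100, 0, 0), c(0, 0, 0, 0))
  res <- mutation_posterior(pu, 0.999, 0.001)
  expect_lt(res$posterior, 0.99)
  expect_equal(res$maf_estimate, 0)
})

test_that("strand-bias filter fails only one-stranded significant variants", {
  balanced <- manual_pileup(c(0, 250, 0, 20), c(0, 250, 0, 20))
  expect_true(strand_bias_filter(balanced, "T")$pass)

  one_sided <- manual_pileup(c(0, 500, 0, 40), c(0, 500, 0, 0))
  expect_false(strand_bias_filter(one_sided, "T")$pass)

  tiny <- manual_pileup(c(0, 2, 0, 2), c(0, 0, 0, 0))
  expect_true(strand_bias_filter(tiny, "T")$pass)
})

test_that("position-bias filter flags end-clustered variants and missing summaries", {
  centered <- manual_pileup(c(0, 100, 0, 20), c(0, 0, 0, 0),
                            offset_mean = 0.5, offset_disp = 0.08)
  expect_true(position_bias_filter(centered)$pass)

  end_clustered <- manual_pileup(c(0, 100, 0, 20), c(0, 0, 0, 0),
                                 offset_mean = 0.02, offset_disp = 0.0001)
  expect_false(position_bias_filter(end_clustered)$pass)

  missing <- manual_pileup(c(0, 100, 0, 0), c(0, 0, 0, 0),
                           offset_mean = NA_real_, offset_disp = NA_real_)
  res <- position_bias_filter(missing)
  expect_true(res$pass)
  expect_true(res$warning)
})

test_that("somatic annotation precedence: known somatic beats germline", {
  dbs <- site_databases(
    germline_sites = tibble::tibble(contig = "chr17", pos = 100L, alt = "T"),
    somatic_sites = tibble::tibble(contig = "chr17", pos = 100L, alt = "T",
                                   hotspot = FALSE))
  expect_equal(classify_somatic("chr17", 100L, "T", dbs), "known_somatic")

  dbs2 <- site_databases(
    germline_sites = tibble::tibble(contig = "chr17", pos = 100L, alt = "T"))
  expect_equal(classify_somatic("chr17", 100L, "T", dbs2), "filtered_germline")
  expect_equal(classify_somatic("chr1", 5L, "A", dbs2), "unknown")
  expect_equal(classify_somatic("chr1", 5L, "A", dbs2, truncating = TRUE),
               "likely_somatic_or_functional")
})

test_that("call_variants finds a clonal variant, honours blacklists, stays empty on empty input", {
  expect_equal(nrow(call_variants(simulate_pileup(0, 0, 0)[0, ])), 0)

  pus <- dplyr::bind_rows(
    simulate_pileup(300, 0.3, 0.001, seed = 1, contig = "chr17", pos = 100L),
    simulate_pileup(300, 0, 0.001, seed = 2, contig = "chr17", pos = 200L))
  calls <- call_variants(pus)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 100L)
  expect_equal(calls$alt, "T")
  expect_lt(abs(calls$maf_estimate - 0.3), 0.05)

  dbs <- site_databases(
    artifact_sites = tibble::tibble(contig = "chr17", pos = 100L, alt = "T"))
  calls2 <- call_variants(pus, dbs, keep_filtered = TRUE)
  expect_true("artifact" %in% unlist(strsplit(calls2$filter[calls2$pos == 100L], ";")))
  expect_equal(nrow(call_variants(pus, dbs)), 0)
})

test_that("caller detects all clonal variants at depth 250+ and emits no error-only calls", {
  # sensitivity
  hits <- vapply(1:20, function(s) {
    pu <- simulate_pileup(250, 0.2, 0.001, seed = s)
    nrow(call_variants(pu)) == 1
  }, logical(1))
  expect_true(all(hits))

  # specificity on 5,000 error-only sites
  pus <- purrr::list_rbind(purrr::map(1:5000, function(s)
    simulate_pileup(400, 0, 0.001, seed = 10000 + s, pos = s)))
  expect_equal(nrow(call_variants(pus)), 0)
})
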