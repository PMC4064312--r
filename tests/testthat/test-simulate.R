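test_that("pileup counts respect depth, purity of signal, and degenerate inputs", {
  pu <- simulate_pileup(100, true_maf = 0, base_error = 0, seed = 1)
  counts <- sapply(c("A", "G", "T"), function(b) pu[[paste0(b, "_fwd")]] + pu[[paste0(b, "_rev")]])
  expect_equal(unname(counts), c(0, 0, 0))
  expect_equal(pu$C_fwd + pu$C_rev, 100)

  pu0 <- simulate_pileup(0, 0.3, 0.001, seed = 2)
  expect_equal(pu0$depth, 0)
  expect_equal(pu0$A_fwd + pu0$A_rev + pu0$C_fwd + pu0$C_rev +
                 pu0$G_fwd + pu0$G_rev + pu0$T_fwd + pu0$T_rev, 0)

  expect_error(simulate_pileup(-5, 0.3, 0.001), "non-negative")
  expect_error(simulate_pileup(10, 1.3, 0.001), "0, 1")
})

test_that("pileup alt fraction converges to the error-mixed expectation", {
  depth <- 1e6
  e <- 0.001
  maf <- 0.3
  pu <- simulate_pileup(depth, maf, e, seed = 42)
  p_alt <- maf * (1 - e) + (1 - maf) * e / 3
  obs <- (pu$T_fwd + pu$T_rev) / depth
  sd3 <- 3 * sqrt(p_alt * (1 - p_alt) / depth)
  expect_lt(abs(obs - p_alt), sd3)
})

test_that("simulators are byte-identical under a fixed seed", {
  expect_identical(simulate_pileup(500, 0.2, 0.001, seed = 7),
                   simulate_pileup(500, 0.2, 0.001, seed = 7))
  expect_identical(simulate_logratio_profile(c(2, 2, 6, 6), 0.6, 2, 0.1, seed = 7),
                   simulate_logratio_profile(c(2, 2, 6, 6), 0.6, 2, 0.1, seed = 7))
  ref <- random_sequence(200, 5)
  expect_identical(simulate_exon_reads(ref, NULL, 30, 49, 0.01, seed = 3),
                   simulate_exon_reads(ref, NULL, 30, 49, 0.01, seed = 3))
})

test_that("log-ratio forward model matches the mixture equation", {
  prof <- simulate_logratio_profile(rep(2, 20), 0.8, 2, 0, seed = 1)
  expect_equal(prof$lr, rep(0, 20))
  prof2 <- simulate_logratio_profile(rep(6, 10), 0.5, 2, 0, seed = 1)
  expect_equal(prof2$lr, rep(1, 10))  # log2((0.5*6+1)/(0.5*2+1)) = 1
})

test_that("SNP BAFs follow the purity-weighted copy-state expectation", {
  b <- simulate_snp_bafs(2, 1, purity = 0.7, n_snps = 200, depth = 100, seed = 1)
  expect_lt(abs(mean(b$baf) - 0.5), 3 * sqrt(0.25 / (200 * 100)) * 10)

  b2 <- simulate_snp_bafs(2, 0, purity = 1, n_snps = 50, depth = 100, seed = 2)
  expect_equal(mean(b2$baf), 0)

  n <- 500; depth <- 200
  b3 <- simulate_snp_bafs(4, 1, purity = 0.5, n_snps = n, depth = depth, seed = 3)
  e_baf <- 1 / 3  # (0.5*1 + 0.5) / (0.5*4 + 1)
  expect_lt(abs(mean(b3$baf) - e_baf),
            3 * sqrt(e_baf * (1 - e_baf) / (n * depth)))

  expect_error(simulate_snp_bafs(2, 3, 0.5, 10, 50), "exceed")
})

test_that("exon reads tile the window and carry the variant at its fraction", {
  ref <- random_sequence(260, 11)
  rd <- simulate_exon_reads(ref, NULL, depth = 20, read_length = 49,
                            base_error = 0, seed = 4)
  expect_true(all(vapply(rd$seq, function(s) grepl(s, ref, fixed = TRUE),
                         logical(1))))

  v <- list(type = "deletion", at = 120, len = 3, fraction = 0.5)
  rd2 <- simulate_exon_reads(ref, v, depth = 50, read_length = 49,
                             base_error = 0, seed = 5)
  frac <- mean(rd2$hap == "alt")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(rd2)))
  alt_win <- paste0(substr(ref, 1, 119), substr(ref, 123, 260))
  alt_reads <- rd2$seq[rd2$hap == "alt"]
  expect_true(all(vapply(alt_reads, function(s) grepl(s, alt_win, fixed = TRUE),
                         logical(1))))

  expect_error(simulate_exon_reads(substr(ref, 1, 30), NULL, 10, 49, 0),
               "shorter")
})

test_that("cohort simulation respects prevalences and links every signal to truth", {
  panel <- synthetic_panel(20, 90)
  prev <- tibble::tribble(
    ~gene, ~prev_a, ~prev_b, ~kind,
    "TP53", 0, 1, "mutation",
    "CCND1", 0, 0.5, "amplification")
  spec <- cohort_spec(n_group_a = 3, n_group_b = 5, gene_prevalence = prev,
                      n_null_sites = 5, seed = 21)
  sim <- simulate_cohort(spec, panel)

  truth_b <- dplyr::filter(sim$truth, group == "HPV-")
  expect_true(all(vapply(truth_b$variants,
                         function(v) "TP53" %in% v$gene, logical(1))))
  truth_a <- dplyr::filter(sim$truth, group == "HPV+")
  expect_true(all(vapply(truth_a$variants,
                         function(v) !"TP53" %in% v$gene, logical(1))))

  # every truth variant has a matching pileup row and vice versa
  for (i in seq_len(nrow(sim$samples))) {
    tv <- sim$truth$variants[[i]]
    pu <- sim$samples$pileups[[i]]
    expect_true(all(tv$pos %in% pu$pos))
  }

  sim2 <- simulate_cohort(spec, panel)
  expect_identical(sim$truth, sim2$truth)
})

test_that("empirical cohort prevalence sits inside the binomial interval", {
  panel <- synthetic_panel(20, 90)
  prev <- tibble::tibble(gene = "PIK3CA", prev_a = 0.4, prev_b = 0.1,
                         kind = "mutation")
  spec <- cohort_spec(n_group_a = 20, n_group_b = 20, gene_prevalence = prev,
                      n_null_sites = 0, seed = 33)
  sim <- simulate_cohort(spec, panel)
  hit_a <- mean(vapply(sim$truth$variants[sim$truth$group == "HPV+"],
                       function(v) "PIK3CA" %in% v$gene, logical(1)))
  expect_lt(abs(hit_a - 0.4), 3 * sqrt(0.4 * 0.6 / 20))
})
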