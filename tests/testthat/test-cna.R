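test_that("log-ratio computation centres, filters and joins correctly", {
  panel <- synthetic_panel(20, 90)
  tum <- tibble::tibble(exon = panel$exon, gene = panel$gene, coverage = 400)
  nor <- tibble::tibble(exon = panel$exon, coverage = 400)
  expect_equal(compute_logratios(tum, nor)$lr, rep(0, nrow(panel)))

  tum2 <- dplyr::mutate(tum, coverage = 800)  # global 2x scaling
  expect_equal(compute_logratios(tum2, nor)$lr, rep(0, nrow(panel)))

  tum3 <- dplyr::mutate(tum, coverage = ifelse(gene == "TP53", 1600, 400))
  lr3 <- compute_logratios(tum3, nor)
  up <- lr3$lr[lr3$gene == "TP53"]
  expect_true(all(abs(up - 2) < 1e-9))  # median centre is the diploid mass

  expect_error(compute_logratios(dplyr::mutate(tum, exon = paste0(exon, "_x")),
                                 nor), "share no exons")
})

test_that("expected log-ratio follows the purity/ploidy mixture exactly", {
  expect_equal(expected_logratio(2, 0.37, 2), 0)
  expect_equal(expected_logratio(6, 0.5, 2), 1)   # log2(4/2)
  expect_equal(expected_logratio(4, 1, 2), 1)
  for (p in c(0.2, 0.5, 0.9)) {
    lr <- expected_logratio(0:8, p, 2.4)
    expect_true(all(diff(lr) > 0))
    expect_equal(expected_logratio(2.4, p, 2.4), 0)
  }
})

test_that("expected BAF follows the allele-weighted mixture", {
  expect_equal(expected_baf(2, 1, 0.33), 0.5)
  expect_equal(expected_baf(2, 0, 1), 0)
  expect_equal(expected_baf(3, 1, 0.6), (0.6 + 0.4) / (1.8 + 0.8))
})

test_that("segmentation finds clean steps, leaves flat noise whole, localises breakpoints", {
  step <- tibble::tibble(lr = rep(c(0, 1), each = 30))
  seg <- segment_profile(step)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$end_index[1], 30)
  expect_equal(seg$lr_seg, c(0, 1))

  flat <- tibble::tibble(lr = withr::with_seed(5, rnorm(3230, 0, 0.1)))
  expect_equal(nrow(segment_profile(flat)), 1)

  truth_bounds <- cumsum(c(40, 25, 30, 25, 40))
  lr <- withr::with_seed(8, rep(c(0, 0.8, -0.2, 1.4, 0), c(40, 25, 30, 25, 40)) +
                           rnorm(160, 0, 0.15))
  segs <- segment_profile(tibble::tibble(lr = lr))
  found <- segs$end_index[-nrow(segs)]
  expect_equal(length(found), 4)
  expect_true(all(abs(found - truth_bounds[1:4]) <= 2))
})

test_that("purity/ploidy fit recovers simulated truth and flags flat profiles", {
  copies <- rep(c(2, 1, 3, 0, 4, 6, 2), c(40, 25, 25, 15, 25, 20, 40))
  prof <- simulate_logratio_profile(copies, 0.7, mean(copies), 0.1, seed = 10)
  segs <- segment_profile(prof)
  fit <- fit_purity_ploidy(segs)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$purity - 0.7), 0.05)
  expect_lt(abs(fit$ploidy - mean(copies)), 0.2)
  # fitted integer copies match truth on every segment (by majority exon state)
  for (s in seq_len(nrow(fit$segments))) {
    idx <- fit$segments$start_index[s]:fit$segments$end_index[s]
    true_c <- as.integer(names(sort(-table(copies[idx])))[1])
    expect_equal(fit$segments$C_seg[s], true_c)
  }

  flat_fit <- fit_purity_ploidy(segment_profile(
    simulate_logratio_profile(rep(2, 100), 0.6, 2, 0.05, seed = 11)))
  expect_false(flat_fit$identifiable)
  expect_true(is.na(flat_fit$purity))

  # a coarser grid still containing the truth finds the same optimum
  fit2 <- fit_purity_ploidy(segs, purity_grid = seq(0.1, 1, 0.05),
                            ploidy_grid = seq(1.5, 4, 0.25))
  expect_lt(abs(fit2$purity - 0.7), 0.051)
})

test_that("round-trip simulate -> segment -> fit recovers purity across 20 replicates", {
  copies <- rep(c(2, 1, 3, 0, 4, 6, 2), c(40, 25, 25, 15, 25, 20, 40))
  res <- purrr::map_dbl(1:20, function(s) {
    p <- withr::with_seed(s, runif(1, 0.3, 0.9))
    prof <- simulate_logratio_profile(copies, p, mean(copies), 0.1,
                                      seed = 500 + s)
    fit <- fit_purity_ploidy(segment_profile(prof))
    abs(fit$purity - p)
  })
  expect_true(all(res <= 0.05))
})

make_fit <- function(panel, gene_copies, purity = 0.6) {
  # fit object with one segment per run of constant copy state
  copies <- rep(2L, nrow(panel))
  for (g in names(gene_copies)) copies[panel$gene == g] <- gene_copies[[g]]
  seg_id <- cumsum(c(1L, diff(copies) != 0))
  starts <- which(!duplicated(seg_id))
  ends <- c(starts[-1] - 1L, length(copies))
  ploidy <- mean(copies)
  segs <- tibble::tibble(
    segment = seq_along(starts), start_index = starts, end_index = ends,
    n_exons = ends - starts + 1L,
    lr_seg = expected_logratio(copies[starts], purity, ploidy),
    C_seg = copies[starts])
  fit <- structure(list(purity = purity, ploidy = ploidy, segments = segs,
                        loglik = 0, identifiable = TRUE),
                   class = "purity_ploidy_fit")
  list(fit = fit, profile = tibble::tibble(gene = panel$gene, lr = NA_real_))
}

test_that("focal calls obey the copy thresholds and the purity gate", {
  panel <- synthetic_panel(20, 90)
  amp <- make_fit(panel, c(CCND1 = 6L, CDKN2A = 0L), purity = 0.6)
  calls <- call_focal_cnas(amp$fit, amp$profile)
  expect_equal(sort(calls$gene), c("CCND1", "CDKN2A"))
  expect_equal(calls$type[calls$gene == "CCND1"], "amplification")
  expect_equal(calls$type[calls$gene == "CDKN2A"], "homozygous_deletion")
  expect_equal(calls$copies[calls$gene == "CDKN2A"], 0)

  # five copies is below the amplification threshold
  five <- make_fit(panel, c(CCND1 = 5L), purity = 0.6)
  expect_equal(nrow(call_focal_cnas(five$fit, five$profile)), 0)

  # purity gate: no calls at or below 20% purity, calls just above
  for (p_gate in c(0.05, 0.10, 0.15, 0.20)) {
    gated <- make_fit(panel, c(CCND1 = 7L), purity = p_gate)
    expect_equal(nrow(suppressMessages(call_focal_cnas(gated$fit, gated$profile))), 0)
  }
  open <- make_fit(panel, c(CCND1 = 7L), purity = 0.21)
  expect_gt(nrow(call_focal_cnas(open$fit, open$profile)), 0)

  # unidentifiable fits never emit calls
  flat <- make_fit(panel, list(), purity = 0.6)
  flat$fit$identifiable <- FALSE
  expect_equal(nrow(suppressMessages(call_focal_cnas(flat$fit, flat$profile))), 0)
})

test_that("amplification and deletion recover end-to-end on a multi-event profile", {
  panel <- synthetic_panel(20, 90)
  copies <- rep(2L, nrow(panel))
  copies[panel$gene == "CCND1"] <- 7L
  copies[panel$gene == "CDKN2A"] <- 0L
  prof <- simulate_logratio_profile(copies, 0.6, mean(copies), 0.05,
                                    seed = 4, panel = panel)
  segs <- segment_profile(prof)
  bafs <- purrr::list_rbind(purrr::map(seq_len(nrow(segs)), function(s) {
    C <- copies[segs$start_index[s]]
    simulate_snp_bafs(C, min(1L, C), 0.6, n_snps = 2 * segs$n_exons[s],
                      depth = 100, seed = 40 + s) |>
      dplyr::mutate(segment = s)
  }))
  fit <- fit_purity_ploidy(segs, bafs)
  calls <- call_focal_cnas(fit, prof)
  expect_true("CCND1" %in% calls$gene[calls$type == "amplification"])
  expect_true("CDKN2A" %in% calls$gene[calls$type == "homozygous_deletion"])
  expect_lt(abs(fit$purity - 0.6), 0.1)
})
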