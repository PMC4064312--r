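exact_tiling_reads <- function(ref, read_length = 40) {
  n <- nchar(ref) - read_length + 1
  substring(ref, 1:n, read_length:(read_length + n - 1))
}

test_that("reference-tiling reads yield a single anchored path equal to the window", {
  ref <- random_sequence(150, 1)
  g <- build_graph(exact_tiling_reads(ref), ref, k = 21, anchor_min_support = 1)
  expect_true(g$anchored)
  haps <- enumerate_haplotypes(g)
  expect_equal(nrow(haps), 1)
  expect_equal(haps$sequence, ref)
})

test_that("a het deletion forms a two-path bubble with ranked supports", {
  ref <- random_sequence(150, 2)
  alt <- paste0(substr(ref, 1, 69), substr(ref, 73, 150))
  reads <- c(rep(exact_tiling_reads(ref), 2), exact_tiling_reads(alt))
  g <- build_graph(reads, ref, k = 21, anchor_min_support = 1)
  haps <- enumerate_haplotypes(g)
  expect_equal(nrow(haps), 2)
  expect_equal(haps$sequence[1], ref)         # better-covered branch first
  expect_gte(haps$support[1], haps$support[2])
  expect_equal(haps$sequence[2], alt)
})

test_that("empty read sets and anchor-disconnecting pruning are flagged unanchored", {
  ref <- random_sequence(100, 3)
  g <- build_graph(character(), ref, k = 21)
  expect_false(g$anchored)
  expect_equal(nrow(enumerate_haplotypes(g)), 0)

  # middle covered once: pruning at 2 disconnects the anchors
  reads <- c(rep(substr(ref, 1, 40), 3), substr(ref, 15, 85),
             rep(substr(ref, 61, 100), 3))
  g2 <- build_graph(reads, ref, k = 21, anchor_min_support = 2)
  expect_true(g2$anchored)
  expect_false(prune_graph(g2, 2)$anchored)
})

test_that("pruning at support 1 is the identity and at 2 removes singleton error k-mers", {
  ref <- random_sequence(120, 4)
  reads <- rep(exact_tiling_reads(ref), 3)
  err_read <- paste0("T", substr(ref, 52, 80), "A")  # chimeric junk
  g <- build_graph(c(reads, err_read), ref, k = 21, anchor_min_support = 1)
  g1 <- prune_graph(g, 1)
  expect_equal(length(g1$nodes), length(g$nodes))
  g2 <- prune_graph(g, 2)
  expect_lt(length(g2$nodes), length(g$nodes))
  expect_true(g2$anchored)
  expect_equal(enumerate_haplotypes(g2)$sequence[1], ref)
})

test_that("repeat-induced cycles terminate and return acyclic paths only", {
  unit <- "ACGTGTCA"
  ref <- paste0(random_sequence(60, 5), strrep(unit, 6), random_sequence(60, 6))
  reads <- exact_tiling_reads(ref, 30)
  g <- build_graph(reads, ref, k = 11, anchor_min_support = 1)
  haps <- enumerate_haplotypes(g, max_paths = 8)
  expect_true(nrow(haps) >= 0)  # termination is the property under test
})

test_that("alignment score equals the affine DP oracle on random pairs", {
  withr::with_seed(77, {
    for (i in 1:40) {
      a <- random_sequence(sample(30:70, 1), 1000 + i)
      b <- random_sequence(sample(30:70, 1), 2000 + i)
      al <- align_haplotype(a, b)
      expect_equal(al$score, oracle_affine_score(a, b))
    }
  })
})

test_that("identical sequences align gap-free; known deletions appear as one gap", {
  ref <- random_sequence(80, 7)
  al <- align_haplotype(ref, ref)
  expect_equal(al$score, nchar(ref))
  expect_false(grepl("-", al$aligned_pattern, fixed = TRUE))

  alt <- paste0(substr(ref, 1, 39), substr(ref, 43, 80))
  al2 <- align_haplotype(alt, ref)
  expect_equal(sum(strsplit(al2$aligned_pattern, "")[[1]] == "-"), 3)
})

test_that("indel left-normalisation is leftmost and idempotent", {
  #        1234567890123
  ref <- "GGCAAAAATTTTC"
  # deleting AA at pos 6-7 is ambiguous within the A-run; leftmost anchor is 3
  nz <- left_align_indel(5L, "deletion", "AA", ref)
  expect_equal(nz$pos, 3L)
  expect_equal(nz$seq, "AA")
  nz2 <- left_align_indel(nz$pos, "deletion", nz$seq, ref)
  expect_identical(nz2, nz)

  # insertion of A after the run start normalises to the run's left edge
  ni <- left_align_indel(7L, "insertion", "A", ref)
  expect_equal(ni$pos, 3L)
})

test_that("call_indels is quiet on reference reads and exact on simulated indels", {
  ref <- random_sequence(260, 8)
  clean <- simulate_exon_reads(ref, NULL, depth = 60, read_length = 49,
                               base_error = 0, seed = 1)
  expect_equal(nrow(suppressWarnings(call_indels(clean, ref))), 0)

  v <- list(type = "deletion", at = 120, len = 3, fraction = 0.3)
  rd <- simulate_exon_reads(ref, v, depth = 100, read_length = 49,
                            base_error = 0.005, seed = 2)
  calls <- call_indels(rd, ref)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "deletion")
  expect_equal(calls$len, 3)
  # left-aligned anchor must sit at or left of the simulated offset
  expect_lte(calls$pos, 120L)
  expect_gt(calls$support_fraction, 0.15)
})

test_that("two indels on distinct haplotypes are both called", {
  ref <- random_sequence(300, 9)
  alt1 <- paste0(substr(ref, 1, 79), substr(ref, 84, 300))          # 4-bp del
  alt2 <- paste0(substr(ref, 1, 200), "TTACG", substr(ref, 201, 300)) # 5-bp ins
  reads <- c(exact_tiling_reads(alt1, 49), exact_tiling_reads(alt2, 49),
             exact_tiling_reads(ref, 49))
  calls <- call_indels(reads, ref, min_fraction = 0.1)
  expect_equal(sort(calls$type), c("deletion", "insertion"))
})

test_that("indels of length 1-15 are recovered at fraction 0.3, coverage 100x", {
  ref <- random_sequence(260, 10)
  cases <- expand.grid(len = c(1, 2, 4, 7, 11, 15), seed = 1:3)
  hits <- purrr::map2_lgl(cases$len, cases$seed, function(len, s) {
    v <- list(type = "deletion", at = 110, len = len, fraction = 0.3)
    rd <- simulate_exon_reads(ref, v, depth = 100, read_length = 49,
                              base_error = 0.01, seed = 7000 + 100 * len + s)
    cc <- suppressWarnings(call_indels(rd, ref))
    any(cc$type == "deletion" & cc$len == len)
  })
  expect_gte(mean(hits), 0.95)
})
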