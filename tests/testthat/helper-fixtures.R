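# Shared fixtures and independent oracles, all built in code.

random_sequence <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# one-row pileup built directly from strand counts (A,C,G,T) x (fwd,rev)
manual_pileup <- function(fwd, rev, ref = "C", offset_mean = 0.5,
                          offset_disp = 0.08, contig = "chr1", pos = 100L) {
  stopifnot(length(fwd) == 4, length(rev) == 4)
  out <- tibble::tibble(contig = contig, pos = pos, ref = ref)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(bases)) {
    out[[paste0(bases[i], "_fwd")]] <- fwd[i]
    out[[paste0(bases[i], "_rev")]] <- rev[i]
  }
  out$depth <- sum(fwd) + sum(rev)
  out$offset_mean <- offset_mean
  out$offset_disp <- offset_disp
  out
}

# Independent posterior oracle: same model, evaluated through
# stats::dmultinom in log space with a different normalisation path.
oracle_posterior <- function(counts, ref, alt, p0, e, grid) {
  probs_at <- function(f) {
    p <- rep(e / 3, 4)
    names(p) <- c("A", "C", "G", "T")
    p[ref] <- (1 - f) * (1 - e) + f * e / 3
    p[alt] <- f * (1 - e) + (1 - f) * e / 3
    p
  }
  ll <- function(f) stats::dmultinom(counts, prob = probs_at(f), log = TRUE)
  l0 <- ll(0) + log(p0)
  lg <- vapply(grid, ll, numeric(1)) + log(1 - p0) - log(length(grid))
  all_l <- c(l0, lg)
  m <- max(all_l)
  z <- m + log(sum(exp(all_l - m)))
  1 - exp(l0 - z)
}

# Brute-force affine-gap global alignment score (Gotoh), independent of the
# package's alignment route.
oracle_affine_score <- function(a, b, match = 1, mismatch = -2,
                                gap_open = 5, gap_extend = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  gp <- function(k) -(gap_open + gap_extend * k)  # Biostrings-style affine
  for (i in 2:(n + 1)) { Ix[i, 1] <- gp(i - 1); }
  for (j in 2:(m + 1)) { Iy[1, j] <- gp(j - 1); }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (x[i - 1] == y[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                    Ix[i - 1, j] - gap_extend)
    Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                    Iy[i, j - 1] - gap_extend)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Exhaustive two-sided Fisher p over all tables with the observed margins.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    stats::dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# alteration matrix drawn straight from group prevalences (truth level)
random_alteration_matrix <- function(prev, n_a, n_b, seed,
                                     extra_genes = character()) {
  withr::with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_a + n_b))
    groups <- c(rep("HPV+", n_a), rep("HPV-", n_b))
    rows <- list()
    for (i in seq_along(samples)) {
      pcol <- if (groups[i] == "HPV+") prev$prev_a else prev$prev_b
      hit <- stats::runif(nrow(prev)) < pcol
      alt <- ifelse(hit, ifelse(prev$kind == "mutation", "mutation",
                                ifelse(prev$kind == "amplification",
                                       "amplification", "deletion")), "none")
      rows[[i]] <- tibble::tibble(sample = samples[i], group = groups[i],
                                  gene = prev$gene, alteration = alt)
      if (length(extra_genes)) {
        rows[[i]] <- dplyr::bind_rows(rows[[i]],
          tibble::tibble(sample = samples[i], group = groups[i],
                         gene = extra_genes, alteration = "none"))
      }
    }
    dplyr::bind_rows(rows)
  })
}
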