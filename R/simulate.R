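#' Simulate an allele pileup at one site
#'
#' Draws per-read alleles from the same generative model the substitution
#' caller inverts: a read carries the mutant allele with probability
#' `true_maf`; sequencing error then substitutes any other base uniformly at
#' `base_error` per base. Strand is Bernoulli(`strand_balance`) independent
#' of allele, and the offset of the variant within its read is uniform, so
#' the strand-bias and position-bias filters see null behaviour unless
#' `offset_bias` is set.
#'
#' @param depth Total read count at the site (>= 0).
#' @param true_maf True mutant allele fraction in [0, 1].
#' @param base_error Per-base sequencing error rate in [0, 0.25).
#' @param strand_balance Probability a read is on the forward strand.
#' @param seed Optional integer seed.
#' @param contig,pos,ref,alt Site coordinates and alleles.
#' @param offset_bias Optional fraction in (0, 0.5); when set, variant-read
#'   offsets cluster at a read end (artifact signature) instead of uniform.
#' @return A one-row pileup tibble: `contig`, `pos`, `ref`, the eight
#'   per-allele per-strand counts (`A_fwd` ... `T_rev`), `depth`,
#'   `offset_mean`, `offset_disp`.
#' @export
simulate_pileup <- function(depth, true_maf, base_error,
                            strand_balance = 0.5, seed = NULL,
                            contig = "chr17", pos = 7578406L,
                            ref = "C", alt = "T", offset_bias = NULL) {
  assert_that(is.numeric(depth) && length(depth) == 1 && depth >= 0,
              "`depth` must be a single non-negative count")
  assert_fraction(true_maf, "true_maf")
  assert_that(base_error >= 0 && base_error < 0.25,
              "`base_error` must lie in [0, 0.25)")
  assert_that(ref %in% BASES && alt %in% BASES && ref != alt,
              "`ref`/`alt` must be distinct bases in ACGT")
  depth <- as.integer(depth)

  with_seed_or_not(seed, {
    probs <- allele_probs(true_maf, base_error, ref, alt)
    counts <- if (depth > 0) as.integer(rmultinom(1, depth, probs)) else integer(4)
    names(counts) <- BASES
    fwd <- vapply(counts, function(nc) rbinom(1, nc, strand_balance), integer(1))
    rev <- counts - fwd
    n_var <- counts[[alt]]
    if (n_var > 0) {
      off <- if (is.null(offset_bias)) runif(n_var)
             else runif(n_var, 0, offset_bias)
      offset_mean <- mean(off)
      offset_disp <- if (n_var > 1) stats::var(off) else 0
    } else {
      offset_mean <- NA_real_
      offset_disp <- NA_real_
    }
    out <- tibble(contig = contig, pos = as.integer(pos), ref = ref)
    for (b in BASES) {
      out[[paste0(b, "_fwd")]] <- fwd[[b]]
      out[[paste0(b, "_rev")]] <- rev[[b]]
    }
    out$depth <- depth
    out$offset_mean <- offset_mean
    out$offset_disp <- offset_disp
    out
  })
}

# P(observed base) for a site with mutant fraction f: the true allele is alt
# with probability f, ref otherwise; error e moves a base to each of the
# other three alleles with probability e/3.
allele_probs <- function(f, e, ref, alt) {
  p <- rep(e / 3, 4)
  names(p) <- BASES
  p[ref] <- (1 - f) * (1 - e) + f * e / 3
  p[alt] <- f * (1 - e) + (1 - f) * e / 3
  p
}

#' Simulate an exon log-ratio profile
#'
#' Forward model of the copy-number mixture: each exon's log2 tumor/normal
#' ratio is `expected_logratio(C, purity, ploidy)` plus Gaussian noise.
#'
#' @param copies Integer vector of true exon copy numbers (>= 0).
#' @param purity Tumor purity in (0, 1].
#' @param ploidy Average tumor copy number (> 0).
#' @param noise_sd Gaussian noise standard deviation in log2 units.
#' @param seed Optional integer seed.
#' @param panel Optional target panel; when given, its exon coordinates are
#'   carried on the output rows.
#' @return A tibble with one row per exon: `exon_index`, `copies`, `lr`, plus
#'   panel columns when supplied.
#' @export
simulate_logratio_profile <- function(copies, purity, ploidy, noise_sd,
                                      seed = NULL, panel = NULL) {
  assert_that(all(copies >= 0), "`copies` must be >= 0")
  assert_fraction(purity, "purity", open_left = TRUE)
  assert_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  with_seed_or_not(seed, {
    mu <- expected_logratio(copies, purity, ploidy)
    lr <- mu + rnorm(length(copies), 0, noise_sd)
    out <- tibble(exon_index = seq_along(copies),
                  copies = as.integer(copies), lr = lr)
    if (!is.null(panel)) {
      assert_that(nrow(panel) == length(copies),
                  "`panel` must have one row per element of `copies`")
      out <- dplyr::bind_cols(panel[, c("contig", "start", "end", "gene", "exon")], out)
    }
    out
  })
}

#' Simulate heterozygous-SNP allele fractions
#'
#' Alt-allele read fractions at heterozygous germline SNPs under a copy
#' state: expected BAF is `(p*m + (1-p)) / (p*C + 2*(1-p))` for total copies
#' `C`, minor copies `m` and purity `p`; observed counts are binomial at the
#' given depth.
#'
#' @param copies,minor Integer vectors (recycled pairwise) of total and
#'   minor-allele copy number per segment; `minor <= copies` required.
#' @param purity Tumor purity in (0, 1].
#' @param n_snps Number of SNPs simulated per segment.
#' @param depth Read depth per SNP.
#' @param seed Optional integer seed.
#' @return A tibble: `segment`, `copies`, `minor`, `depth`, `alt_count`,
#'   `baf`.
#' @export
simulate_snp_bafs <- function(copies, minor, purity, n_snps, depth,
                              seed = NULL) {
  assert_that(length(copies) == length(minor), "`copies` and `minor` must align")
  assert_that(all(minor <= copies), "`minor` copies cannot exceed total copies")
  assert_fraction(purity, "purity", open_left = TRUE)
  with_seed_or_not(seed, {
    purrr::map(seq_along(copies), function(i) {
      e_baf <- expected_baf(copies[i], minor[i], purity)
      alt <- rbinom(n_snps, depth, e_baf)
      tibble(segment = i, copies = copies[i], minor = minor[i],
             depth = depth, alt_count = alt, baf = alt / depth)
    }) |> list_rbind()
  })
}

#' Simulate reads tiling an exon window
#'
#' Uniformly tiles a reference window with fixed-length reads, optionally
#' injecting a substitution or indel carried by a stated fraction of reads,
#' with independent per-base errors.
#'
#' @param reference_window Character scalar reference sequence (ACGT).
#' @param variant `NULL` or a list with `type` ("substitution", "insertion",
#'   "deletion"), `at` (1-based offset of the variant in the window; for an
#'   insertion the inserted bases go after `at`), `seq` (alt base or inserted
#'   bases) or `len` (deletion length), and `fraction` (variant-carrying read
#'   fraction).
#' @param depth Target mean per-base coverage; the number of reads drawn is
#'   `ceiling(depth * window_length / read_length)`.
#' @param read_length Read length; must be shorter than the window.
#' @param base_error Per-base error rate.
#' @param seed Optional integer seed.
#' @return A tibble: `read_id`, `seq`, `hap` ("ref"/"alt"), `start` (1-based
#'   start of the read on its haplotype).
#' @export
simulate_exon_reads <- function(reference_window, variant = NULL, depth = 100,
                                read_length = 49, base_error = 0.001,
                                seed = NULL) {
  L <- nchar(reference_window)
  assert_that(read_length < L, "window shorter than a read")
  haps <- c(ref = reference_window)
  frac <- 0
  if (!is.null(variant)) {
    haps["alt"] <- apply_window_variant(reference_window, variant)
    frac <- variant$fraction %||% 0.5
    if (!is.null(variant$len) && variant$type != "substitution") {
      assert_that((variant$len %||% nchar(variant$seq %||% "")) < read_length / 2,
                  "indel length must be < read_length / 2")
    }
  }
  n_reads <- as.integer(ceiling(depth * L / read_length))
  with_seed_or_not(seed, {
    hap <- ifelse(runif(n_reads) < frac, "alt", "ref")
    seqs <- character(n_reads)
    starts <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      h <- haps[[hap[i]]]
      s <- sample.int(nchar(h) - read_length + 1L, 1)
      r <- substr(h, s, s + read_length - 1L)
      if (base_error > 0) r <- mutate_bases(r, base_error)
      seqs[i] <- r
      starts[i] <- s
    }
    tibble(read_id = sprintf("read%04d", seq_len(n_reads)),
           seq = seqs, hap = hap, start = starts)
  })
}

apply_window_variant <- function(ref, variant) {
  at <- variant$at
  switch(variant$type,
    substitution = paste0(substr(ref, 1, at - 1), variant$seq,
                          substr(ref, at + 1, nchar(ref))),
    insertion = paste0(substr(ref, 1, at), variant$seq,
                       substr(ref, at + 1, nchar(ref))),
    deletion = paste0(substr(ref, 1, at - 1),
                      substr(ref, at + variant$len, nchar(ref))),
    abort("unknown variant type", call = NULL)
  )
}

mutate_bases <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1)
  paste(chars, collapse = "")
}

#' Cohort simulation specification
#'
#' Defaults emulate the study design this package targets: two groups of 20
#' oropharyngeal tumors stratified by HPV status, with the recurrent
#' alterations concentrated as reported for that cohort (TP53 mutation in
#' every HPV- tumor; CCND1 amplification and CDKN2A/B deletion only in HPV-;
#' PIK3CA/PTEN alterations enriched in HPV+).
#'
#' @param n_group_a,n_group_b Samples per group (group A = HPV+,
#'   group B = HPV-).
#' @param gene_prevalence Tibble with columns `gene`, `prev_a`, `prev_b`,
#'   `kind` (one of "mutation", "amplification", "deletion").
#' @param purity_range,ploidy_range Sampling intervals for tumor purity and
#'   background ploidy.
#' @param depth_mean Mean sequencing depth at variant sites.
#' @param base_error_rate Per-base error rate.
#' @param lr_noise_sd Exon log-ratio noise standard deviation (log2 units).
#' @param n_null_sites Error-only pileup sites added per sample (specificity
#'   probes for the caller).
#' @param baf_depth,snps_per_exon Heterozygous-SNP read depth and density.
#' @param seed Integer seed for the whole cohort draw.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_group_a = 20, n_group_b = 20,
                        gene_prevalence = default_gene_prevalence(),
                        purity_range = c(0.3, 0.9),
                        ploidy_range = c(1.8, 3.6),
                        depth_mean = 500,
                        base_error_rate = 0.001,
                        lr_noise_sd = 0.15,
                        n_null_sites = 50,
                        baf_depth = 100,
                        snps_per_exon = 0.5,
                        seed = 1L) {
  assert_fraction(gene_prevalence$prev_a, "prev_a")
  assert_fraction(gene_prevalence$prev_b, "prev_b")
  assert_that(depth_mean > 0, "`depth_mean` must be positive")
  assert_fraction(purity_range, "purity_range", open_left = TRUE)
  spec <- list(n_group_a = n_group_a, n_group_b = n_group_b,
               gene_prevalence = gene_prevalence,
               purity_range = purity_range, ploidy_range = ploidy_range,
               depth_mean = depth_mean, base_error_rate = base_error_rate,
               lr_noise_sd = lr_noise_sd, n_null_sites = n_null_sites,
               baf_depth = baf_depth, snps_per_exon = snps_per_exon,
               seed = as.integer(seed))
  structure(spec, class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_gene_prevalence <- function() {
  tibble::tribble(
    ~gene,     ~prev_a, ~prev_b, ~kind,
    "TP53",       0.05,    1.00, "mutation",
    "CCND1",      0.00,    0.55, "amplification",
    "CDKN2A",     0.00,    0.40, "deletion",
    "CDKN2B",     0.00,    0.40, "deletion",
    "PIK3CA",     0.35,    0.10, "mutation",
    "PTEN",       0.25,    0.10, "deletion",
    "FBXW7",      0.15,    0.15, "mutation",
    "SOX2",       0.12,    0.12, "amplification"
  )
}

#' Simulate a two-group tumor cohort with full ground truth
#'
#' Draws per-sample purity, ploidy, gene alterations (Bernoulli at the
#' group-specific prevalence), then generates every downstream input
#' consistent with that truth: variant-site and error-only pileups, an exon
#' log-ratio profile, heterozygous-SNP BAFs per copy segment, and HPV-16
#' read tallies.
#'
#' Mutant allele fractions follow the same mixture as the copy-number model:
#' a clonal heterozygous substitution on local copy state `C` in a tumor of
#' purity `p` is observed at `p * 1 / (p*C + 2*(1-p))`.
#'
#' @param spec A [cohort_spec()].
#' @param panel A target panel tibble; defaults to [synthetic_panel()].
#' @return A list with `samples` (nested tibble: one row per sample with
#'   list-columns `pileups`, `lr_profile`, `bafs` and scalar viral columns)
#'   and `truth` (tibble of all true per-sample alterations and parameters).
#' @export
simulate_cohort <- function(spec, panel = synthetic_panel()) {
  assert_that(inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  withr::with_seed(spec$seed, {
    n <- spec$n_group_a + spec$n_group_b
    ids <- sprintf("S%02d", seq_len(n))
    groups <- c(rep("HPV+", spec$n_group_a), rep("HPV-", spec$n_group_b))
    samples <- vector("list", n)
    truths <- vector("list", n)
    for (i in seq_len(n)) {
      sim <- simulate_one_sample(ids[i], groups[i], spec, panel)
      samples[[i]] <- sim$bundle
      truths[[i]] <- sim$truth
    }
    list(samples = list_rbind(samples), truth = list_rbind(truths))
  })
}

simulate_one_sample <- function(id, group, spec, panel) {
  purity <- runif(1, spec$purity_range[1], spec$purity_range[2])
  prev_col <- if (group == "HPV+") "prev_a" else "prev_b"
  gp <- spec$gene_prevalence
  altered <- gp[runif(nrow(gp)) < gp[[prev_col]], , drop = FALSE]

  # exon copy states: diploid background, amplified genes at 7, deletions at 0
  copies <- rep(2L, nrow(panel))
  for (j in seq_len(nrow(altered))) {
    idx <- which(panel$gene == altered$gene[j])
    if (altered$kind[j] == "amplification") copies[idx] <- 7L
    if (altered$kind[j] == "deletion") copies[idx] <- 0L
  }
  ploidy <- mean(copies)

  # variant pileups at the first exon of each mutated gene
  mut <- altered[altered$kind == "mutation", , drop = FALSE]
  variants <- purrr::map(seq_len(nrow(mut)), function(j) {
    ex <- panel[panel$gene == mut$gene[j], ][1, ]
    c_local <- copies[which(panel$exon == ex$exon)]
    maf <- purity * 1 / (purity * c_local + 2 * (1 - purity))
    depth <- max(1L, stats::rpois(1, spec$depth_mean))
    pu <- simulate_pileup(depth, maf, spec$base_error_rate,
                          contig = ex$contig, pos = as.integer(ex$start + 11L),
                          ref = "C", alt = "T")
    list(pileup = pu,
         truth = tibble(gene = mut$gene[j], contig = ex$contig,
                        pos = as.integer(ex$start + 11L), ref = "C", alt = "T",
                        true_maf = maf))
  })
  var_pileups <- list_rbind(purrr::map(variants, "pileup"))
  var_truth <- list_rbind(purrr::map(variants, "truth"))

  # error-only probe sites on filler genes
  null_panel <- panel[!panel$gene %in% gp$gene, ]
  null_idx <- seq_len(min(spec$n_null_sites, nrow(null_panel)))
  null_pileups <- list_rbind(purrr::map(null_idx, function(j) {
    ex <- null_panel[j, ]
    depth <- max(1L, stats::rpois(1, spec$depth_mean))
    simulate_pileup(depth, 0, spec$base_error_rate, contig = ex$contig,
                    pos = as.integer(ex$start + 11L), ref = "C", alt = "T")
  }))
  pileups <- bind_rows(var_pileups, null_pileups)

  lr <- simulate_logratio_profile(copies, purity, ploidy, spec$lr_noise_sd,
                                  panel = panel)

  # BAFs per run of constant copy state
  seg_id <- cumsum(c(1L, diff(copies) != 0))
  seg_c <- as.integer(tapply(copies, seg_id, function(x) x[1]))
  seg_len <- as.integer(table(seg_id))
  minor <- ifelse(seg_c == 0, 0L, 1L)
  n_snps <- pmax(1L, as.integer(round(seg_len * spec$snps_per_exon)))
  bafs <- list_rbind(purrr::map(seq_along(seg_c), function(s) {
    simulate_snp_bafs(seg_c[s], minor[s], purity, n_snps[s], spec$baf_depth) |>
      mutate(segment = s)
  }))

  total_reads <- 2e6
  rpm_true <- if (group == "HPV+") runif(1, 20, 500) else runif(1, 0, 1)
  viral_reads <- rbinom(1, total_reads, rpm_true / 1e6)

  bundle <- tibble(
    sample = id, group = group,
    pileups = list(pileups), lr_profile = list(lr), bafs = list(bafs),
    viral_reads = viral_reads, total_reads = total_reads
  )
  cna_truth <- altered[altered$kind != "mutation",
                       c("gene", "kind"), drop = FALSE]
  cna_truth$copies <- ifelse(cna_truth$kind == "amplification", 7L, 0L)
  truth <- tibble(
    sample = id, group = group, purity = purity, ploidy = ploidy,
    viral_rpm = viral_reads / total_reads * 1e6,
    variants = list(var_truth), cna = list(as_tibble(cna_truth))
  )
  list(bundle = bundle, truth = truth)
}
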