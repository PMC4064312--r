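#' Bayesian base-substitution detection
#'
#' The caller evaluates, at each pileup site, the posterior probability that
#' a mutation is present: `P(F > 0 | R) = 1 - P(R | F = 0) P(F = 0) / Z`,
#' where `R` is the observed 4-allele read count vector, `F` the mutant
#' allele fraction, and `P(F = 0)` the site prior of no mutation. The
#' likelihood `P(R | F)` is a multinomial over the four allele counts whose
#' cell probabilities mix `F` on the candidate alt allele with a per-base
#' error rate spread uniformly over the other alleles. The proportionality
#' is resolved by normalising over a discrete grid of non-zero fractions
#' carrying the complementary prior mass `1 - P(F = 0)` uniformly:
#' `Z = P(R|F=0) P(F=0) + sum_g P(R|F=g) (1 - P(F=0)) / |grid|`.
#'
#' Hotspot sites are given a smaller `P(F = 0)`, which raises the posterior
#' for identical counts and so increases sensitivity at recurrent positions.
#'
#' @name snv-model
NULL

#' Default mutant-fraction grid
#'
#' 50 log-spaced fractions in \[0.005, 1\]; the lower bound sets the lowest
#' callable allele fraction.
#' @param n Number of grid points.
#' @param lo,hi Grid range.
#' @return Sorted numeric vector of fractions.
#' @export
default_maf_grid <- function(n = 50, lo = 0.005, hi = 1) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Default calling parameters
#'
#' @param posterior_threshold Minimum posterior to emit a call.
#' @param min_alt_reads Minimum variant read support.
#' @param base_error Per-base error rate used in the likelihood.
#' @param grid Mutant-fraction grid (see [default_maf_grid()]).
#' @param strand_significance Fisher-test level for the strand-bias filter.
#' @param prior_default,prior_tissue,prior_hotspot `P(F = 0)` by prior class.
#' @return Named list of parameters.
#' @export
snv_params <- function(posterior_threshold = 0.99, min_alt_reads = 3,
                       base_error = 0.001, grid = default_maf_grid(),
                       strand_significance = 0.01,
                       prior_default = 0.999, prior_tissue = 0.99,
                       prior_hotspot = 0.9) {
  list(posterior_threshold = posterior_threshold,
       min_alt_reads = min_alt_reads, base_error = base_error, grid = grid,
       strand_significance = strand_significance,
       prior_default = prior_default, prior_tissue = prior_tissue,
       prior_hotspot = prior_hotspot)
}

# counts: named integer vector over A,C,G,T (strand-collapsed)
# log multinomial likelihood of the counts under mutant fraction f
loglik_counts <- function(counts, f, e, ref, alt) {
  p <- allele_probs(f, e, ref, alt)
  lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)) +
    sum(counts * log(p))
}

#' Posterior probability of mutation at a site
#'
#' @param pileup One-row pileup tibble (see [simulate_pileup()] for the
#'   column layout).
#' @param p_no_mutation Prior probability of no mutation, `P(F = 0)`, in
#'   (0, 1].
#' @param base_error Per-base error rate.
#' @param grid Sorted grid of candidate mutant fractions in (0, 1].
#' @return A one-row tibble per candidate alt allele is reduced to the
#'   best-supported alt: columns `alt`, `posterior`, `maf_estimate` (the
#'   grid argmax of the likelihood, or 0 when the posterior favours no
#'   mutation), `alt_count`.
#' @export
mutation_posterior <- function(pileup, p_no_mutation, base_error = 0.001,
                               grid = default_maf_grid()) {
  assert_that(pileup$depth > 0, "zero-depth pileup")
  assert_that(length(grid) > 0 && all(grid > 0 & grid <= 1) &&
                !is.unsorted(grid), "`grid` must be sorted fractions in (0, 1]")
  assert_that(p_no_mutation > 0 && p_no_mutation <= 1,
              "`p_no_mutation` must be in (0, 1]")
  counts <- strand_collapse(pileup)
  ref <- pileup$ref
  alts <- setdiff(BASES, ref)
  res <- purrr::map(alts, function(alt) {
    ll0 <- loglik_counts(counts, 0, base_error, ref, alt)
    llg <- vapply(grid, function(f) loglik_counts(counts, f, base_error, ref, alt),
                  numeric(1))
    log_num <- ll0 + log(p_no_mutation)
    log_alt <- logsumexp(llg) + log1p(-p_no_mutation) - log(length(grid))
    log_z <- logsumexp(c(log_num, log_alt))
    posterior <- 1 - exp(log_num - log_z)
    maf <- if (posterior > 0.5) grid[which.max(llg)] else 0
    tibble(alt = alt, posterior = posterior, maf_estimate = maf,
           alt_count = counts[[alt]])
  }) |> list_rbind()
  res[which.max(res$posterior), ]
}

strand_collapse <- function(pileup) {
  vapply(BASES, function(b) pileup[[paste0(b, "_fwd")]] + pileup[[paste0(b, "_rev")]],
         numeric(1))
}

#' Strand-bias quality filter
#'
#' Fisher's exact test on the 2x2 allele-by-strand table. A site fails only
#' when the test is significant *and* the variant reads are effectively
#' one-stranded (minor-strand variant fraction < 5%); balanced or
#' small-sample sites always pass.
#'
#' @param pileup One-row pileup tibble.
#' @param alt Alt allele being tested.
#' @param significance Fisher-test level.
#' @return A list with `pass` (logical) and `p` (Fisher p-value).
#' @export
strand_bias_filter <- function(pileup, alt, significance = 0.01) {
  ref <- pileup$ref
  tab <- matrix(c(pileup[[paste0(ref, "_fwd")]], pileup[[paste0(ref, "_rev")]],
                  pileup[[paste0(alt, "_fwd")]], pileup[[paste0(alt, "_rev")]]),
                nrow = 2, byrow = TRUE)
  n_var <- sum(tab[2, ])
  if (sum(tab) < 10 || n_var == 0) return(list(pass = TRUE, p = 1))
  p <- stats::fisher.test(tab)$p.value
  minor_frac <- min(tab[2, ]) / n_var
  list(pass = !(p < significance && minor_frac < 0.05), p = p)
}

#' Read-position bias filter
#'
#' Artifacts cluster near read ends: the filter fails a site when the mean
#' variant offset (as a fraction of read length) is within 10% of either
#' read end and the offsets barely disperse. A missing summary passes with
#' a warning flag.
#'
#' @param pileup One-row pileup tibble with `offset_mean`, `offset_disp`.
#' @param edge Fraction of read length counted as "near an end".
#' @param min_disp Dispersion (variance) below which clustering is called.
#' @return A list with `pass` and `warning` flags.
#' @export
position_bias_filter <- function(pileup, edge = 0.1, min_disp = 0.005) {
  m <- pileup$offset_mean
  d <- pileup$offset_disp
  if (is.na(m) || is.na(d)) return(list(pass = TRUE, warning = TRUE))
  near_end <- m < edge || m > 1 - edge
  list(pass = !(near_end && d < min_disp), warning = FALSE)
}

#' Site databases for somatic annotation
#'
#' Three site lists steer germline filtering and somatic annotation: known
#' sequencing artifacts (derived from normal controls), germline variants
#' (a dbSNP surrogate), and known somatic mutations with an optional hotspot
#' flag (a COSMIC surrogate). Lookups are exact on (contig, pos, alt).
#'
#' @param artifact_sites,germline_sites,somatic_sites Tibbles with columns
#'   `contig`, `pos`, `alt` (and `hotspot` for somatic sites); may be empty.
#' @return A `site_databases` list.
#' @export
site_databases <- function(artifact_sites = empty_sites(),
                           germline_sites = empty_sites(),
                           somatic_sites = empty_sites(hotspot = TRUE)) {
  structure(list(artifact_sites = artifact_sites,
                 germline_sites = germline_sites,
                 somatic_sites = somatic_sites),
            class = "site_databases")
}

empty_sites <- function(hotspot = FALSE) {
  out <- tibble(contig = character(), pos = integer(), alt = character())
  if (hotspot) out$hotspot <- logical()
  out
}

site_in <- function(sites, contig, pos, alt) {
  any(sites$contig == contig & sites$pos == pos & sites$alt == alt)
}

#' Somatic status of a candidate call
#'
#' Known-somatic annotation takes precedence over germline filtering: a site
#' previously confirmed somatic in other tumors is never discarded as
#' germline even if present in the germline list. Unannotated truncating or
#' frameshift changes are classed likely somatic/functional; everything else
#' is of unknown status.
#'
#' @param contig,pos,alt Call site.
#' @param dbs A [site_databases()].
#' @param truncating Logical consequence flag for the call.
#' @return One of "known_somatic", "filtered_germline",
#'   "likely_somatic_or_functional", "unknown".
#' @export
classify_somatic <- function(contig, pos, alt, dbs, truncating = FALSE) {
  if (site_in(dbs$somatic_sites, contig, pos, alt)) return("known_somatic")
  if (site_in(dbs$germline_sites, contig, pos, alt)) return("filtered_germline")
  if (isTRUE(truncating)) return("likely_somatic_or_functional")
  "unknown"
}

site_prior <- function(contig, pos, alt, dbs, params) {
  som <- dbs$somatic_sites
  hit <- som$contig == contig & som$pos == pos & som$alt == alt
  if (any(hit)) {
    if (any(hit & (som$hotspot %||% FALSE))) params$prior_hotspot
    else params$prior_tissue
  } else params$prior_default
}

#' Call base substitutions from a pileup table
#'
#' Runs the Bayesian posterior at every site, applies the quality filters
#' (strand bias, read-position bias, artifact blacklist), discards
#' germline-filtered sites, and emits passing calls sorted by position.
#' Sites listed as somatic hotspots receive the lowered no-mutation prior.
#'
#' @param pileups Pileup tibble, one row per site.
#' @param dbs A [site_databases()].
#' @param params A [snv_params()] list.
#' @param keep_filtered Keep non-passing candidates (flagged) in the output.
#' @return A tibble of calls: `contig`, `pos`, `ref`, `alt`, `maf_estimate`,
#'   `posterior`, `alt_count`, `depth`, `filter` ("PASS" or
#'   semicolon-joined failure flags), `somatic_status`.
#' @export
call_variants <- function(pileups, dbs = site_databases(),
                          params = snv_params(), keep_filtered = FALSE) {
  if (nrow(pileups) == 0) return(empty_calls())
  rows <- purrr::map(seq_len(nrow(pileups)), function(i) {
    pu <- pileups[i, ]
    if (pu$depth == 0) return(NULL)
    # screen all three alts with the default prior, then redo with the
    # site-specific prior for the chosen alt
    best <- mutation_posterior(pu, params$prior_default, params$base_error,
                               params$grid)
    prior <- site_prior(pu$contig, pu$pos, best$alt, dbs, params)
    if (prior != params$prior_default) {
      best <- mutation_posterior(pu, prior, params$base_error, params$grid)
    }
    flags <- character()
    if (best$posterior < params$posterior_threshold ||
        best$alt_count < params$min_alt_reads) {
      if (!keep_filtered) return(NULL)
      flags <- c(flags, "low_posterior")
    }
    if (!strand_bias_filter(pu, best$alt, params$strand_significance)$pass)
      flags <- c(flags, "strand_bias")
    if (!position_bias_filter(pu)$pass) flags <- c(flags, "position_bias")
    if (site_in(dbs$artifact_sites, pu$contig, pu$pos, best$alt))
      flags <- c(flags, "artifact")
    status <- classify_somatic(pu$contig, pu$pos, best$alt, dbs)
    if (status == "filtered_germline") flags <- c(flags, "germline")
    tibble(contig = pu$contig, pos = pu$pos, ref = pu$ref, alt = best$alt,
           maf_estimate = best$maf_estimate, posterior = best$posterior,
           alt_count = as.integer(best$alt_count), depth = pu$depth,
           filter = if (length(flags)) paste(flags, collapse = ";") else "PASS",
           somatic_status = status)
  })
  calls <- list_rbind(purrr::compact(rows))
  if (nrow(calls) == 0) return(empty_calls())
  if (!keep_filtered) calls <- filter(calls, .data$filter == "PASS")
  arrange(calls, .data$contig, .data$pos)
}

empty_calls <- function() {
  tibble(contig = character(), pos = integer(), ref = character(),
         alt = character(), maf_estimate = numeric(), posterior = numeric(),
         alt_count = integer(), depth = integer(), filter = character(),
         somatic_status = character())
}
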