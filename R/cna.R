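#' Copy-number model
#'
#' An exon's expected log2 tumor/normal coverage ratio under absolute copy
#' number `C`, tumor purity `p` and tumor ploidy `psi` is the two-component
#' admixture of tumor (C copies) and normal (2 copies) DNA, referenced to
#' the sample's average content:
#' `lr(C) = log2( (p*C + 2*(1-p)) / (p*psi + 2*(1-p)) )`.
#' The matching heterozygous-SNP B-allele fraction for minor copy number `m`
#' is `(p*m + (1-p)) / (p*C + 2*(1-p))`.
#'
#' @name cna-model
NULL

LR_FLOOR <- -8  # log2 floor standing in for -Inf at C = 0, p = 1

#' Expected log-ratio of a copy state
#'
#' @param C Absolute copy number (>= 0), vectorised.
#' @param purity Tumor purity in (0, 1].
#' @param ploidy Tumor ploidy (> 0).
#' @return Expected log2 tumor/normal ratio; floored at -8 where the tumor
#'   contributes zero copies at full purity.
#' @export
expected_logratio <- function(C, purity, ploidy) {
  assert_that(all(C >= 0), "`C` must be >= 0")
  assert_fraction(purity, "purity", open_left = TRUE)
  assert_that(ploidy > 0, "`ploidy` must be positive")
  num <- purity * C + 2 * (1 - purity)
  den <- purity * ploidy + 2 * (1 - purity)
  pmax(log2(num / den), LR_FLOOR)
}

#' Expected B-allele fraction of a copy state
#'
#' @param C Total copies; `minor` minor-allele copies (`minor <= C`).
#' @param minor Minor-allele copy number.
#' @param purity Tumor purity in (0, 1].
#' @return Expected heterozygous-SNP alt fraction.
#' @export
expected_baf <- function(C, minor, purity) {
  assert_that(all(minor <= C), "`minor` cannot exceed `C`")
  assert_fraction(purity, "purity", open_left = TRUE)
  (purity * minor + (1 - purity)) / (purity * C + 2 * (1 - purity))
}

#' Exon log-ratios against a process-matched normal
#'
#' Joins tumor and normal per-exon coverage on exon identity, drops exons
#' whose normal coverage is below `normal_floor` (logged as a message),
#' computes `log2(tumor/normal)` and median-centres the profile so the
#' modal copy state sits at zero.
#'
#' @param tumor,normal Tibbles with columns `exon` and `coverage` (tumor may
#'   carry panel columns, which are preserved).
#' @param normal_floor Minimum normal coverage for an exon to be retained.
#' @return A log-ratio profile tibble with columns of `tumor` plus `lr`.
#' @export
compute_logratios <- function(tumor, normal, normal_floor = 20) {
  assert_that(all(c("exon", "coverage") %in% names(tumor)) &&
                all(c("exon", "coverage") %in% names(normal)),
              "`tumor` and `normal` need `exon` and `coverage` columns")
  joined <- dplyr::inner_join(tumor,
                              select(normal, "exon", normal_coverage = "coverage"),
                              by = "exon")
  assert_that(nrow(joined) > 0, "tumor and normal share no exons")
  low <- joined$normal_coverage < normal_floor
  if (any(low)) inform(sprintf("dropping %d exons with normal coverage < %g",
                               sum(low), normal_floor))
  joined <- joined[!low, , drop = FALSE]
  lr <- log2(joined$coverage / joined$normal_coverage)
  joined$lr <- lr - stats::median(lr)
  select(joined, -"normal_coverage")
}

#' Segment a log-ratio profile
#'
#' Penalized recursive binary segmentation on exon order: each candidate
#' split maximises the reduction in within-segment sum of squares and is
#' accepted while the reduction exceeds `penalty`. The default penalty
#' scales as `3 * sigma^2 * log(n)` with `sigma` estimated robustly from
#' successive differences, which leaves a flat noisy profile of thousands
#' of exons unsplit while detecting single-gene events of a few exons.
#'
#' @param profile Tibble with an `lr` column in exon order.
#' @param penalty Acceptance penalty for one changepoint; `NULL` for the
#'   adaptive default.
#' @param min_size Minimum exons per segment.
#' @return A segment tibble: `segment`, `start_index`, `end_index`,
#'   `n_exons`, `lr_seg` (arithmetic mean).
#' @export
segment_profile <- function(profile, penalty = NULL, min_size = 2) {
  lr <- profile$lr
  n <- length(lr)
  assert_that(n >= 2, "need at least 2 exons to segment")
  if (is.null(penalty)) {
    sigma <- stats::median(abs(diff(lr))) / (0.6745 * sqrt(2))
    sigma <- max(sigma, 1e-3)
    penalty <- 3 * sigma^2 * log(n)
  }
  bounds <- binary_segment(lr, 1L, n, penalty, as.integer(min_size))
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  tibble(segment = seq_along(starts), start_index = starts, end_index = ends,
         n_exons = ends - starts + 1L,
         lr_seg = purrr::map2_dbl(starts, ends, ~ mean(lr[.x:.y])))
}

# returns sorted breakpoints (last index of each left part) inside [lo, hi]
binary_segment <- function(lr, lo, hi, penalty, min_size) {
  n <- hi - lo + 1L
  if (n < 2L * min_size) return(integer(0))
  x <- lr[lo:hi]
  cs <- cumsum(x); css <- cumsum(x^2)
  tot_sse <- css[n] - cs[n]^2 / n
  ks <- min_size:(n - min_size)
  sse_l <- css[ks] - cs[ks]^2 / ks
  sse_r <- (css[n] - css[ks]) - (cs[n] - cs[ks])^2 / (n - ks)
  gains <- tot_sse - (sse_l + sse_r)
  best <- which.max(gains)
  if (gains[best] <= penalty) return(integer(0))
  cut <- lo + ks[best] - 1L
  sort(c(binary_segment(lr, lo, cut, penalty, min_size),
         cut,
         binary_segment(lr, cut + 1L, hi, penalty, min_size)))
}

#' Fit tumor purity and ploidy to a segmented profile
#'
#' Grid search over (purity, ploidy): for each candidate, every segment is
#' assigned the integer copy number minimising the Gaussian log-ratio
#' residual (weighted by segment size), plus a B-allele-fraction residual
#' term where SNP data overlap the segment (minor copy number chosen by the
#' same minimisation). The maximum-likelihood candidate wins; ties break
#' toward lower ploidy, then higher purity, resolving the usual
#' purity/ploidy degeneracy deterministically. A profile whose segments all
#' sit within noise of zero carries no copy-number signal and is flagged
#' unidentifiable.
#'
#' @param segments Segment tibble from [segment_profile()].
#' @param bafs Optional BAF tibble with columns `segment` and `baf`.
#' @param purity_grid,ploidy_grid Candidate grids.
#' @param max_copies Largest integer copy number considered.
#' @param lr_sd,baf_sd Residual scales for the two likelihood terms.
#' @param baf_weight Relative weight of the BAF term.
#' @param flat_tol Segments all within `flat_tol` of lr 0 =>
#'   unidentifiable.
#' @return A `purity_ploidy_fit` object: list with `purity`, `ploidy`,
#'   `segments` (with fitted `C_seg`), `loglik`, `identifiable`.
#' @export
fit_purity_ploidy <- function(segments, bafs = NULL,
                              purity_grid = seq(0.05, 1, by = 0.01),
                              ploidy_grid = seq(1.2, 6, by = 0.05),
                              max_copies = 12, lr_sd = 0.15, baf_sd = 0.05,
                              baf_weight = 1, flat_tol = 0.1) {
  assert_that(nrow(segments) >= 1, "need at least one segment")
  assert_that(length(purity_grid) > 0 && length(ploidy_grid) > 0,
              "empty parameter grid")
  if (all(abs(segments$lr_seg) < flat_tol)) {
    segments$C_seg <- NA_integer_
    return(structure(list(purity = NA_real_, ploidy = NA_real_,
                          segments = segments, loglik = NA_real_,
                          identifiable = FALSE),
                     class = "purity_ploidy_fit"))
  }
  Cs <- 0:max_copies
  baf_means <- if (!is.null(bafs) && nrow(bafs) > 0) {
    bafs |> group_by(.data$segment) |>
      summarise(baf_mean = mean(.data$baf), n_snp = n(), .groups = "drop")
  } else NULL
  ll_mat <- matrix(-Inf, length(purity_grid), length(ploidy_grid))
  cseg_store <- vector("list", length(purity_grid) * length(ploidy_grid))
  for (ip in seq_along(purity_grid)) for (il in seq_along(ploidy_grid)) {
    p <- purity_grid[ip]; pl <- ploidy_grid[il]
    mu <- pmax(log2((p * Cs + 2 * (1 - p)) / (p * pl + 2 * (1 - p))), LR_FLOOR)
    # per segment: best C by weighted lr residual (+ BAF term)
    ll <- 0
    C_seg <- integer(nrow(segments))
    for (s in seq_len(nrow(segments))) {
      res_lr <- -(segments$lr_seg[s] - mu)^2 / (2 * lr_sd^2) * segments$n_exons[s]
      res <- res_lr
      if (!is.null(baf_means)) {
        hit <- baf_means$segment == segments$segment[s]
        if (any(hit)) {
          bm <- baf_means$baf_mean[hit][1]
          nsnp <- baf_means$n_snp[hit][1]
          res_baf <- vapply(Cs, function(C) {
            ms <- 0:floor(C / 2)
            if (C == 0) ms <- 0
            eb <- expected_baf(C, ms, p)
            max(-(bm - eb)^2 / (2 * baf_sd^2) * nsnp)
          }, numeric(1))
          res <- res + baf_weight * res_baf
        }
      }
      k <- which.max(res)
      C_seg[s] <- Cs[k]
      ll <- ll + res[k]
    }
    ll_mat[ip, il] <- ll
    cseg_store[[(il - 1) * length(purity_grid) + ip]] <- C_seg
  }
  # the (purity, ploidy) surface has an exact whole-genome-doubling
  # degeneracy: a doubled solution differs from the optimum only by grid
  # discretisation (well under one log-lik unit), so candidates within 1
  # unit of the optimum are resolved toward the lowest ploidy, then the
  # highest purity; genuinely different fits sit further away
  tie_tol <- 1
  max_ll <- max(ll_mat)
  cand <- which(ll_mat >= max_ll - tie_tol, arr.ind = TRUE)
  cand <- cand[order(ploidy_grid[cand[, 2]], -purity_grid[cand[, 1]]), ,
               drop = FALSE]
  ip <- cand[1, 1]; il <- cand[1, 2]
  best <- list(purity = purity_grid[ip], ploidy = ploidy_grid[il],
               loglik = ll_mat[ip, il],
               C_seg = cseg_store[[(il - 1) * length(purity_grid) + ip]])
  segments$C_seg <- best$C_seg
  structure(list(purity = best$purity, ploidy = best$ploidy,
                 segments = segments, loglik = best$loglik,
                 identifiable = TRUE),
            class = "purity_ploidy_fit")
}

#' @export
print.purity_ploidy_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("purity/ploidy fit: unidentifiable (flat profile)\n")
  } else {
    cat(sprintf("purity/ploidy fit: purity = %.2f, ploidy = %.2f, loglik = %.1f\n",
                x$purity, x$ploidy, x$loglik))
  }
  print(x$segments, ...)
  invisible(x)
}

#' Call focal amplifications and homozygous deletions
#'
#' Per gene, the modal fitted segment copy number across its exons (ties
#' toward the more extreme value) is compared with the calling rule: focal
#' amplification at >= 6 copies, homozygous deletion at 0 copies, and no
#' calls at all from samples with purity <= 0.20 or an unidentifiable fit.
#'
#' @param fit A `purity_ploidy_fit`.
#' @param profile The exon profile that was segmented (needs `gene`).
#' @param min_purity Purity gate below which no calls are emitted.
#' @param amp_copies Amplification threshold.
#' @return A tibble of calls: `gene`, `type`, `copies`, `segment`. Empty
#'   (with a logged reason) under the purity gate.
#' @export
call_focal_cnas <- function(fit, profile, min_purity = 0.20, amp_copies = 6) {
  empty <- tibble(gene = character(), type = character(),
                  copies = integer(), segment = integer())
  if (!isTRUE(fit$identifiable)) {
    inform("no CNA calls: purity/ploidy fit unidentifiable")
    return(empty)
  }
  if (fit$purity <= min_purity) {
    inform(sprintf("no CNA calls: purity %.2f <= %.2f gate", fit$purity, min_purity))
    return(empty)
  }
  assert_that("gene" %in% names(profile), "`profile` needs a `gene` column")
  segs <- fit$segments
  exon_c <- integer(nrow(profile))
  exon_seg <- integer(nrow(profile))
  for (s in seq_len(nrow(segs))) {
    idx <- segs$start_index[s]:segs$end_index[s]
    exon_c[idx] <- segs$C_seg[s]
    exon_seg[idx] <- segs$segment[s]
  }
  per_gene <- tibble(gene = profile$gene, C = exon_c, segment = exon_seg) |>
    group_by(.data$gene) |>
    summarise(copies = modal_extreme(.data$C),
              segment = .data$segment[which(.data$C == modal_extreme(.data$C))[1]],
              .groups = "drop")
  calls <- per_gene |>
    mutate(type = dplyr::case_when(
      .data$copies >= amp_copies ~ "amplification",
      .data$copies == 0 ~ "homozygous_deletion",
      TRUE ~ NA_character_)) |>
    filter(!is.na(.data$type)) |>
    select("gene", "type", "copies", "segment")
  calls
}

# modal value; ties resolved toward the value furthest from 2 copies
modal_extreme <- function(x) {
  tab <- table(x)
  cand <- as.integer(names(tab)[tab == max(tab)])
  cand[which.max(abs(cand - 2))]
}
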