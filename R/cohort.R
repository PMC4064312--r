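#' Cohort-level alteration analysis
#'
#' The cohort layer reduces per-sample variant and copy-number calls to a
#' samples-by-genes categorical alteration matrix, tests per-gene enrichment
#' between the two HPV groups (Pearson chi-squared with Benjamini-Hochberg
#' FDR), and clusters samples on their binarised alteration profiles
#' (Jaccard distance, average linkage, two-group cut).
#'
#' @name cohort-analysis
NULL

#' Build the samples x genes alteration matrix
#'
#' Gene-level reduction of the calls: a sample-gene pair with only
#' substitutions/indels is `mutation`, with only a copy-number call
#' `amplification` or `deletion`, and with both kinds `multiple`.
#'
#' @param variant_calls Tibble with columns `sample`, `gene` (one row per
#'   passing small variant); may be empty.
#' @param cna_calls Tibble with columns `sample`, `gene`, `type`
#'   ("amplification"/"homozygous_deletion"); may be empty.
#' @param sample_sheet Tibble with columns `sample`, `group` covering every
#'   sample in the cohort.
#' @param genes Character vector of panel genes defining the columns.
#' @return A long tibble: `sample`, `group`, `gene`, `alteration` in
#'   \{none, mutation, amplification, deletion, multiple\}.
#' @export
build_alteration_matrix <- function(variant_calls, cna_calls, sample_sheet,
                                    genes) {
  known <- sample_sheet$sample
  bad <- setdiff(c(variant_calls$sample, cna_calls$sample), known)
  assert_that(length(bad) == 0,
              paste0("calls for samples missing from sheet: ",
                     paste(bad, collapse = ", ")))
  grid <- tidyr::expand_grid(sample = known, gene = genes)
  mut <- variant_calls |> distinct(.data$sample, .data$gene) |>
    mutate(has_mut = TRUE)
  cna <- cna_calls |> distinct(.data$sample, .data$gene, .data$type) |>
    mutate(kind = ifelse(.data$type == "amplification", "amplification",
                         "deletion")) |>
    distinct(.data$sample, .data$gene, .data$kind) |>
    group_by(.data$sample, .data$gene) |>
    summarise(cna_kind = paste(sort(.data$kind), collapse = "+"),
              .groups = "drop")
  grid |>
    left_join(mut, by = c("sample", "gene")) |>
    left_join(cna, by = c("sample", "gene")) |>
    mutate(
      has_mut = !is.na(.data$has_mut),
      has_cna = !is.na(.data$cna_kind),
      alteration = dplyr::case_when(
        has_mut & has_cna ~ "multiple",
        has_cna & grepl("\\+", cna_kind) ~ "multiple",
        has_mut ~ "mutation",
        has_cna ~ cna_kind,
        TRUE ~ "none")) |>
    left_join(select(sample_sheet, "sample", "group"), by = "sample") |>
    select("sample", "group", "gene", "alteration")
}

#' Per-gene enrichment between groups
#'
#' For every gene altered in at least one sample, a Pearson chi-squared test
#' on the 2x2 altered/unaltered-by-group table, with Benjamini-Hochberg
#' FDR across tested genes.
#'
#' @param matrix Long alteration matrix from [build_alteration_matrix()].
#' @param correction Yates correction flag passed through to the test.
#' @return A tibble sorted by q: `gene`, the four cell counts
#'   (`altered_a`, `unaltered_a`, `altered_b`, `unaltered_b`),
#'   `statistic`, `p`, `q`.
#' @export
gene_enrichment <- function(matrix, correction = FALSE) {
  groups <- sort(unique(matrix$group))
  assert_that(length(groups) == 2, "need exactly two groups")
  tab <- matrix |>
    mutate(altered = .data$alteration != "none") |>
    group_by(.data$gene) |>
    summarise(
      altered_a = sum(.data$altered & .data$group == groups[1]),
      unaltered_a = sum(!.data$altered & .data$group == groups[1]),
      altered_b = sum(.data$altered & .data$group == groups[2]),
      unaltered_b = sum(!.data$altered & .data$group == groups[2]),
      .groups = "drop") |>
    filter(.data$altered_a + .data$altered_b > 0)
  if (nrow(tab) == 0) {
    return(mutate(tab, statistic = numeric(0), p = numeric(0), q = numeric(0)))
  }
  tests <- purrr::pmap(tab, function(gene, altered_a, unaltered_a,
                                     altered_b, unaltered_b, ...) {
    m <- matrix(c(altered_a, unaltered_a, altered_b, unaltered_b), nrow = 2)
    ct <- chi_squared_test(m, correction = correction)
    tibble(statistic = ct$statistic, p = ct$p)
  }) |> list_rbind()
  dplyr::bind_cols(tab, tests) |>
    mutate(group_a = groups[1], group_b = groups[2],
           q = bh_fdr(.data$p)) |>
    arrange(.data$q, .data$p)
}

#' Hierarchical clustering of samples on alteration profiles
#'
#' Alterations are binarised (any non-none call), samples are compared by
#' a binary profile distance, clustered hierarchically and cut into two
#' groups; the cut is cross-tabulated against the HPV group labels and
#' summarised as cluster purity (the best achievable agreement between cut
#' labels and groups).
#'
#' The default distance is Hamming (simple matching) with Ward linkage: on
#' a sparse alteration panel the *absence* of an event is informative (an
#' unmutated TP53 is itself characteristic of one group), and Jaccard —
#' which ignores co-absences — places alteration-free samples at maximal
#' distance from everyone, collapsing the group structure. Jaccard distance
#' and other linkages remain available for denser matrices.
#'
#' @param matrix Long alteration matrix from [build_alteration_matrix()].
#' @param distance "hamming" (simple matching; default) or "jaccard".
#' @param linkage An [stats::hclust()] method; default "ward.D2".
#' @return A `cohort_clustering` list: `dist` (distance matrix), `hclust`,
#'   `cut` (named cluster labels), `crosstab`, `purity`, `degenerate`
#'   (TRUE when all profiles are identical).
#' @export
hierarchical_cluster <- function(matrix, distance = c("hamming", "jaccard"),
                                 linkage = "ward.D2") {
  distance <- match.arg(distance)
  wide <- matrix |>
    mutate(altered = as.integer(.data$alteration != "none")) |>
    select("sample", "gene", "altered") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "altered")
  samples <- wide$sample
  assert_that(length(samples) >= 2, "need >= 2 samples to cluster")
  m <- as.matrix(wide[, -1])
  rownames(m) <- samples
  groups <- matrix |> distinct(.data$sample, .data$group) |>
    (\(d) stats::setNames(d$group, d$sample))()
  degenerate <- nrow(unique(as.data.frame(m))) == 1
  d <- if (distance == "jaccard") {
    dj <- stats::dist(m, method = "binary")
    dj[!is.finite(dj)] <- 0  # pairs of all-zero profiles
    dj
  } else {
    stats::dist(m, method = "manhattan") / ncol(m)  # Hamming fraction
  }
  hc <- stats::hclust(d, method = linkage)
  cut <- stats::cutree(hc, k = 2)
  ct <- table(cluster = cut, group = groups[names(cut)])
  purity <- max(sum(diag(ct)), sum(ct[1, 2], ct[2, 1])) / sum(ct)
  structure(list(dist = d, hclust = hc, cut = cut, crosstab = ct,
                 purity = purity, degenerate = degenerate),
            class = "cohort_clustering")
}

#' @export
print.cohort_clustering <- function(x, ...) {
  cat(sprintf("two-group cut vs labels: purity %.1f%%%s\n", 100 * x$purity,
              if (x$degenerate) " (degenerate: identical profiles)" else ""))
  print(x$crosstab)
  invisible(x)
}

#' Clinical covariate association with group
#'
#' Ordinal or continuous covariates are tested with the Wilcoxon rank-sum
#' test; `age` (or any covariate named in `logistic_for`) with a logistic
#' group model. P-values are FDR-adjusted together.
#'
#' @param clinical Tibble with `sample`, `group` and covariate columns.
#' @param covariates Covariate column names to test.
#' @param logistic_for Covariates tested by logistic regression instead.
#' @return Tibble: `covariate`, `test`, `statistic`, `p`, `q`.
#' @export
clinical_associations <- function(clinical, covariates,
                                  logistic_for = "age") {
  groups <- sort(unique(clinical$group))
  assert_that(length(groups) == 2, "need exactly two groups")
  res <- purrr::map(covariates, function(cv) {
    v <- clinical[[cv]]
    if (cv %in% logistic_for) {
      lt <- logistic_group_test(v, clinical$group)
      tibble(covariate = cv, test = "logistic",
             statistic = lt$coefficient, p = lt$p)
    } else {
      x <- v[clinical$group == groups[1]]
      y <- v[clinical$group == groups[2]]
      wt <- wilcoxon_rank_sum(x, y)
      tibble(covariate = cv, test = paste0("wilcoxon (", wt$method, ")"),
             statistic = wt$statistic, p = wt$p)
    }
  }) |> list_rbind()
  mutate(res, q = ifelse(is.na(.data$p), NA_real_,
                         bh_fdr(tidyr::replace_na(.data$p, 1))))
}
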