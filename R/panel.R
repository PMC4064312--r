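#' Target panels
#'
#' A target panel is a tibble of exon capture intervals in BED convention
#' (0-based, half-open) with one row per exon and columns `contig`, `start`,
#' `end`, `gene` and `exon`. [synthetic_panel()] builds an in-silico panel
#' emulating a large cancer gene panel (182 genes, ~3,230 exons by default)
#' with the recurrently altered head-and-neck genes named explicitly;
#' [read_panel()] / [write_panel()] exchange the panel as 4-column BED.
#'
#' @name target-panel
NULL

# Genes with group-specific alteration defaults in head and neck cancer,
# always present in the synthetic panel.
PANEL_KEY_GENES <- c(
  "TP53", "CCND1", "CDKN2A", "CDKN2B", "PIK3CA", "PTEN",
  "FBXW7", "SOX2", "EGFR", "MYC", "NOTCH1", "RB1", "FGFR1", "HRAS"
)

#' Build a synthetic capture panel
#'
#' @param n_genes Total number of genes (named key genes plus `GENE###`
#'   fillers).
#' @param n_exons Total number of exons, distributed over genes roughly as in
#'   a real capture design (every gene gets at least 4 exons).
#' @param exon_width Width of each exon interval in bases.
#' @param seed Optional integer seed controlling the exon-count draw.
#' @return A tibble with columns `contig`, `start`, `end`, `gene`, `exon`,
#'   sorted by genome position.
#' @export
synthetic_panel <- function(n_genes = 182, n_exons = 3230, exon_width = 120,
                            seed = NULL) {
  assert_that(n_genes >= length(PANEL_KEY_GENES),
              "`n_genes` must cover at least the built-in key genes")
  assert_that(n_exons >= 4 * n_genes, "`n_exons` must allow >= 4 exons per gene")
  genes <- c(PANEL_KEY_GENES,
             sprintf("GENE%03d", seq_len(n_genes - length(PANEL_KEY_GENES))))
  with_seed_or_not(seed %||% 181L, {
    extra <- n_exons - 4L * n_genes
    add <- if (extra > 0) tabulate(sample.int(n_genes, extra, replace = TRUE),
                                   nbins = n_genes) else integer(n_genes)
    counts <- 4L + add
    contig <- rep(paste0("chr", 1 + (seq_len(n_genes) - 1) %% 22), counts)
    gene <- rep(genes, counts)
    exon_idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
    gene_offset <- rep((seq_len(n_genes) - 1) %/% 22 * 10^6 + 10^5, counts)
    start <- gene_offset + (exon_idx - 1L) * (exon_width + 500L)
    tibble(
      contig = contig, start = start, end = start + exon_width,
      gene = gene, exon = paste0(gene, "_e", exon_idx)
    ) |>
      arrange(.data$contig, .data$start)
  })
}

#' Read a target panel from BED
#'
#' Expects 4-column BED (contig, start, end, gene name), 0-based half-open.
#' Intervals are validated, sorted, and overlapping exons of the same gene
#' are merged with a warning.
#'
#' @param path Path to a BED file.
#' @return A target panel tibble (see [synthetic_panel()]).
#' @export
read_panel <- function(path) {
  assert_that(file.exists(path), paste0("no such BED file: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4 ||
        is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3]))) ||
        as.numeric(f[2]) >= as.numeric(f[3])) {
      abort(sprintf("malformed BED line %d in %s", lineno[i], path), call = NULL)
    }
  }
  gr <- rtracklayer::import(path, format = "BED")
  panel <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
    end    = GenomicRanges::end(gr),
    gene   = S4Vectors::mcols(gr)$name
  ) |>
    arrange(.data$contig, .data$start)
  merged <- panel |>
    group_by(.data$contig, .data$gene) |>
    dplyr::group_modify(group_modify_merge()) |>
    ungroup() |>
    arrange(.data$contig, .data$start)
  if (nrow(merged) < nrow(panel)) {
    warn("overlapping exons of the same gene merged")
  }
  merged |>
    group_by(.data$gene) |>
    mutate(exon = paste0(.data$gene, "_e", row_number())) |>
    ungroup() |>
    arrange(.data$contig, .data$start) |>
    select("contig", "start", "end", "gene", "exon")
}

# merge overlapping/adjacent intervals within one (contig, gene) group
group_modify_merge <- function() {
  function(df, key) {
    df <- arrange(df, .data$start)
    s <- df$start; e <- df$end
    out_s <- s[1]; out_e <- e[1]; res_s <- c(); res_e <- c()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= out_e) out_e <- max(out_e, e[i])
      else { res_s <- c(res_s, out_s); res_e <- c(res_e, out_e); out_s <- s[i]; out_e <- e[i] }
    }
    tibble(start = c(res_s, out_s), end = c(res_e, out_e))
  }
}

#' @rdname read_panel
#' @param panel A target panel tibble.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(select(panel, "contig", "start", "end", "gene"),
                   path, col_names = FALSE)
  invisible(path)
}
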