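#' Interchange readers and writers
#'
#' Plain-text formats used between stages: pileups and coverage as TSV,
#' panels as BED (see [read_panel()]), small-variant calls as VCF 4.2,
#' segments as SEG, reads as FASTA/FASTQ via Biostrings, ground truth and
#' fit summaries as JSON. Every writer's output is parsed losslessly by its
#' paired reader.
#'
#' @name panelseq-io
NULL

PILEUP_COLS <- c("contig", "pos", "ref",
                 paste0(rep(BASES, each = 2), c("_fwd", "_rev")),
                 "depth", "offset_mean", "offset_disp")

#' Read / write pileup tables
#'
#' TSV with header columns contig, pos (1-based), ref, the eight
#' allele-by-strand counts, depth, offset_mean, offset_disp.
#'
#' @param path File path.
#' @return [read_pileups()] a pileup tibble.
#' @export
read_pileups <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           contig = "c", ref = "c", pos = "i", depth = "i",
                           .default = "d"))
  missing <- setdiff(PILEUP_COLS, names(out))
  assert_that(length(missing) == 0,
              paste0("pileup TSV missing columns: ", paste(missing, collapse = ", ")))
  out[PILEUP_COLS]
}

#' @rdname read_pileups
#' @param pileups Pileup tibble.
#' @export
write_pileups <- function(pileups, path) {
  readr::write_tsv(pileups[PILEUP_COLS], path)
  invisible(path)
}

#' Write calls as VCF 4.2
#'
#' Substitution and indel calls share one stream. INFO carries the
#' posterior (`POST`), allele-fraction estimate (`MAF`), somatic status
#' (`SS`) and supporting-read count (`AC`); the FILTER column carries the
#' quality-filter flags.
#'
#' @param calls Call tibble (columns of [call_variants()]; indel calls from
#'   [call_indels()] are accepted with their `support_fraction` mapped to
#'   MAF).
#' @param path Output path.
#' @param sample Sample name recorded in the header.
#' @return The path, invisibly.
#' @export
write_vcf <- function(calls, path, sample = "SAMPLE") {
  if (nrow(calls) > 0) {
    ord <- order(calls$contig, calls$pos)
    assert_that(identical(ord, seq_len(nrow(calls))), "calls must be sorted")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelseq",
    sprintf("##sample=%s", sample),
    "##INFO=<ID=POST,Number=1,Type=Float,Description=\"Posterior probability of mutation\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Estimated mutant allele fraction\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Variant-supporting read count\">",
    "##INFO=<ID=SS,Number=1,Type=String,Description=\"Somatic status\">",
    "##FILTER=<ID=strand_bias,Description=\"Variant reads one-stranded\">",
    "##FILTER=<ID=position_bias,Description=\"Variant offsets clustered at read end\">",
    "##FILTER=<ID=artifact,Description=\"Site in artifact blacklist\">",
    "##FILTER=<ID=germline,Description=\"Site in germline database\">",
    "##FILTER=<ID=low_posterior,Description=\"Posterior or read support below threshold\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (nrow(calls) > 0) {
    col_or <- function(nm, alt) if (nm %in% names(calls)) calls[[nm]] else alt
    maf <- col_or("maf_estimate", col_or("support_fraction", NA_real_))
    post <- col_or("posterior", rep(NA_real_, nrow(calls)))
    ac <- col_or("alt_count", rep(NA_integer_, nrow(calls)))
    ss <- col_or("somatic_status", rep("unknown", nrow(calls)))
    info <- sprintf("POST=%s;MAF=%s;AC=%s;SS=%s",
                    format_num(post), format_num(maf), format_num(ac), ss)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                    calls$contig, calls$pos, calls$ref, calls$alt,
                    col_or("filter", "PASS"), info)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

format_num <- function(x) ifelse(is.na(x), ".", format(x, digits = 10, trim = TRUE, scientific = FALSE))

#' Read a panelseq VCF back into a call tibble
#'
#' @param path VCF path (as written by [write_vcf()]).
#' @return A call tibble with `contig`, `pos`, `ref`, `alt`, `filter`,
#'   `posterior`, `maf_estimate`, `alt_count`, `somatic_status`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) return(empty_calls())
  f <- stringr::str_split_fixed(body, "\t", 8)
  info_field <- function(info, key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    m
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  tibble(contig = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4],
         alt = f[, 5],
         maf_estimate = num(info_field(f[, 8], "MAF")),
         posterior = num(info_field(f[, 8], "POST")),
         alt_count = as.integer(num(info_field(f[, 8], "AC"))),
         depth = NA_integer_,
         filter = f[, 7],
         somatic_status = info_field(f[, 8], "SS"))
}

#' Write / read segments in SEG format
#'
#' Tab-separated SEG: sample, contig, start, end, n_exons, seg.mean (and
#' fitted copy number when present).
#'
#' @param segments Segment tibble (from [segment_profile()], optionally with
#'   `C_seg`), plus `contig`, `start`, `end` columns when the profile carried
#'   coordinates.
#' @param path File path.
#' @param sample Sample name.
#' @export
write_seg <- function(segments, path, sample = "SAMPLE") {
  col_or <- function(nm, alt) if (nm %in% names(segments)) segments[[nm]] else alt
  out <- tibble(
    sample = sample,
    contig = col_or("contig", "panel"),
    start = col_or("start", segments$start_index),
    end = col_or("end", segments$end_index),
    n_exons = segments$n_exons,
    seg.mean = segments$lr_seg
  )
  if ("C_seg" %in% names(segments)) out$copy_number <- segments$C_seg
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write reads as FASTA or FASTQ
#'
#' FASTQ qualities are constant Sanger-scale Q30 placeholders (the
#' simulator's per-base error is already realised in the sequence).
#'
#' @param reads Read tibble with `read_id` and `seq` (see
#'   [simulate_exon_reads()]).
#' @param path Output path; format chosen by extension (`.fa`/`.fasta` vs
#'   `.fq`/`.fastq`).
#' @export
write_reads <- function(reads, path) {
  set <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  if (grepl("\\.(fq|fastq)$", path)) {
    quals <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(n)
      paste(rep("?", n), collapse = ""), character(1)))  # "?" = Q30
    Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  } else {
    Biostrings::writeXStringSet(set, path, format = "fasta")
  }
  invisible(path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)$", path)) "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble(read_id = names(set), seq = unname(as.character(set)))
}

#' Export a simulated cohort to a directory
#'
#' One subdirectory per sample (pileup TSV, log-ratio TSV, BAF TSV), a
#' cohort-level viral-count TSV and sample sheet, and the ground truth as
#' JSON.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cohort$samples))) {
    row <- cohort$samples[i, ]
    sdir <- file.path(dir, row$sample)
    dir.create(sdir, showWarnings = FALSE)
    write_pileups(row$pileups[[1]], file.path(sdir, "pileups.tsv"))
    readr::write_tsv(row$lr_profile[[1]], file.path(sdir, "logratios.tsv"))
    readr::write_tsv(row$bafs[[1]], file.path(sdir, "bafs.tsv"))
  }
  viral <- select(cohort$samples, "sample", "group", "viral_reads", "total_reads")
  readr::write_tsv(viral, file.path(dir, "viral_counts.tsv"))
  readr::write_tsv(distinct(cohort$samples, .data$sample, .data$group),
                   file.path(dir, "sample_sheet.tsv"))
  truth_json <- cohort$truth
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
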