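#' Local-assembly indel detection
#'
#' Insertions and deletions are detected per targeted exon by de novo local
#' assembly: reads covering the exon window are decomposed into k-mers, a
#' de Bruijn graph is built with the reference flank k-mers as source/sink
#' anchors, weak (error) k-mers are pruned, anchored haplotypes are
#' enumerated by support, and each haplotype is globally aligned to the
#' reference window with affine gaps. Gaps in the alignment become
#' left-aligned, VCF-style anchored indel calls whose support is re-scored
#' by exact read/junction consistency counting.
#'
#' @name indel-assembly
NULL

#' Build a de Bruijn graph from reads over an exon window
#'
#' @param reads Character vector of read sequences (or a tibble with a `seq`
#'   column).
#' @param reference_window Reference sequence of the exon plus flanks.
#' @param k Odd k-mer length, 11..63, shorter than the reads.
#' @param anchor_min_support Minimum read support for a reference k-mer to
#'   serve as an anchor; match it to the pruning threshold so anchors
#'   survive pruning.
#' @return A `debruijn_graph` list: `k`, `nodes` (named support counts),
#'   `edges` (tibble `from`, `to`, `support`), `source`/`sink` anchor
#'   k-mers, `anchored` flag.
#' @export
build_graph <- function(reads, reference_window, k = 21,
                        anchor_min_support = 2) {
  if (is.data.frame(reads)) reads <- reads$seq
  assert_that(k %% 2 == 1 && k >= 11 && k <= 63, "`k` must be odd in [11, 63]")
  assert_that(nchar(reference_window) > k, "window must exceed k")
  reads <- reads[nchar(reads) > k]
  kmers <- unlist(lapply(reads, seq_kmers, k = k), use.names = FALSE)
  # anchors: outermost reference k-mers with enough read support to survive
  # pruning (reads rarely start exactly at the window boundary, so coverage
  # thins toward the window ends)
  ref_kmers <- seq_kmers(reference_window, k)
  ref_support <- as.integer(table(factor(kmers, levels = unique(ref_kmers)))[ref_kmers])
  present <- !is.na(ref_support) & ref_support >= anchor_min_support
  if (any(present)) {
    src_idx <- which(present)[1]
    snk_idx <- which(present)[sum(present)]
  } else {
    src_idx <- 1L
    snk_idx <- length(ref_kmers)
  }
  src <- ref_kmers[src_idx]
  snk <- ref_kmers[snk_idx]
  edges_raw <- unlist(lapply(reads, function(r) {
    km <- seq_kmers(r, k)
    if (length(km) < 2) return(character())
    paste(km[-length(km)], km[-1], sep = ">")
  }), use.names = FALSE)
  nodes <- table_counts(kmers)
  # anchors always exist even without read support
  for (a in unique(c(src, snk))) if (is.na(nodes[a])) nodes[a] <- 0L
  edge_counts <- table_counts(edges_raw)
  parts <- stringr::str_split_fixed(names(edge_counts), ">", 2)
  edges <- tibble(from = parts[, 1], to = parts[, 2],
                  support = as.integer(edge_counts))
  g <- structure(list(k = k, nodes = nodes, edges = edges,
                      source = src, sink = snk,
                      source_offset = src_idx, sink_offset = snk_idx),
                 class = "debruijn_graph")
  g$anchored <- anchors_connected(g)
  g
}

seq_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1
  if (n < 1) return(character())
  substring(seq, 1:n, k:(k + n - 1))
}

table_counts <- function(x) {
  if (length(x) == 0) return(integer(0))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

anchors_connected <- function(g) {
  if (nrow(g$edges) == 0) return(FALSE)
  reach <- g$source
  frontier <- g$source
  while (length(frontier) > 0) {
    nxt <- unique(g$edges$to[g$edges$from %in% frontier])
    frontier <- setdiff(nxt, reach)
    reach <- c(reach, frontier)
  }
  g$sink %in% reach
}

#' Prune weak k-mers and edges from a de Bruijn graph
#'
#' Removes nodes and edges whose support falls below `min_support`; anchor
#' k-mers are never pruned. The anchored flag is recomputed, so pruning that
#' disconnects the anchors is visible to the caller.
#'
#' @param graph A `debruijn_graph`.
#' @param min_support Minimum k-mer support count (>= 1).
#' @param edge_min_support Minimum edge support; defaults to 1 (edges are
#'   kept whenever both endpoint k-mers survive).
#' @return The pruned `debruijn_graph`.
#' @export
prune_graph <- function(graph, min_support = 2, edge_min_support = 1) {
  assert_that(min_support >= 1, "`min_support` must be >= 1")
  keep_nodes <- names(graph$nodes)[graph$nodes >= min_support |
                                     names(graph$nodes) %in% c(graph$source, graph$sink)]
  graph$nodes <- graph$nodes[keep_nodes]
  # error control comes from k-mer (node) support; edges are kept whenever
  # both endpoints survive, since adjacent-k-mer co-occurrence in staggered
  # short reads is much sparser than k-mer coverage itself
  graph$edges <- filter(graph$edges,
                        .data$support >= edge_min_support,
                        .data$from %in% keep_nodes, .data$to %in% keep_nodes)
  graph$anchored <- anchors_connected(graph)
  graph
}

#' Enumerate anchored haplotypes
#'
#' Depth-first search from the source to the sink anchor, forbidding node
#' revisits (which breaks repeat-induced cycles), exploring higher-support
#' edges first, capped at `max_paths` completed paths. Each haplotype's
#' support is the minimum k-mer support along its path.
#'
#' @param graph An anchored `debruijn_graph`.
#' @param max_paths Maximum number of haplotypes returned.
#' @return A tibble: `sequence`, `support`, sorted by decreasing support.
#' @export
enumerate_haplotypes <- function(graph, max_paths = 16) {
  if (!isTRUE(graph$anchored)) return(tibble(sequence = character(), support = integer()))
  k <- graph$k
  adj <- split(seq_len(nrow(graph$edges)), graph$edges$from)
  results <- list()
  # iterative DFS with explicit stack of (node, path_nodes, min edge support)
  stack <- list(list(node = graph$source, path = graph$source, minsup = Inf))
  while (length(stack) > 0 && length(results) < max_paths * 4) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (st$node == graph$sink && length(st$path) > 1) {
      results[[length(results) + 1]] <- st
      next
    }
    eidx <- adj[[st$node]]
    if (is.null(eidx)) next
    eidx <- eidx[order(graph$edges$support[eidx])]  # best pushed last -> popped first
    for (ei in eidx) {
      nxt <- graph$edges$to[ei]
      if (nxt %in% st$path) next
      stack[[length(stack) + 1]] <-
        list(node = nxt, path = c(st$path, nxt),
             minsup = min(st$minsup, graph$edges$support[ei]))
    }
  }
  if (length(results) == 0) {
    return(tibble(sequence = character(), support = integer()))
  }
  haps <- purrr::map(results, function(st) {
    seq <- paste0(st$path[1],
                  paste(substr(st$path[-1], k, k), collapse = ""))
    # min edge support ties on shared flanks; mean k-mer support breaks the
    # tie in favour of the better-covered branch
    tibble(sequence = seq, support = as.integer(st$minsup),
           mean_support = mean(graph$nodes[st$path]))
  }) |> list_rbind() |>
    group_by(.data$sequence) |>
    summarise(support = max(.data$support),
              mean_support = max(.data$mean_support), .groups = "drop") |>
    arrange(dplyr::desc(.data$support), dplyr::desc(.data$mean_support)) |>
    select("sequence", "support")
  utils::head(haps, max_paths)
}

#' Globally align a haplotype to the reference window
#'
#' Affine-gap global (Needleman-Wunsch) alignment via
#' [Biostrings::pairwiseAlignment()], returned as aligned strings plus the
#' score.
#'
#' @param haplotype,reference_window Sequences to align.
#' @param match,mismatch,gap_open,gap_extend Scoring scheme (gap penalties
#'   positive).
#' @return A list: `score`, `aligned_pattern`, `aligned_subject` (gapped
#'   strings of equal length; pattern = haplotype).
#' @export
align_haplotype <- function(haplotype, reference_window, match = 1,
                            mismatch = -2, gap_open = 5, gap_extend = 1) {
  assert_that(nchar(haplotype) > 0 && nchar(reference_window) > 0,
              "sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  al <- Biostrings::pairwiseAlignment(
    pattern = haplotype, subject = reference_window, type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend
  )
  list(score = Biostrings::score(al),
       aligned_pattern = as.character(Biostrings::alignedPattern(al)),
       aligned_subject = as.character(Biostrings::alignedSubject(al)))
}

# Extract indels from a gapped alignment; positions are 1-based on the
# reference window, VCF-anchored (call at the base before the event).
alignment_indels <- function(aligned_pattern, aligned_subject) {
  p <- strsplit(aligned_pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(aligned_subject, "", fixed = TRUE)[[1]]
  ref_pos <- cumsum(s != "-")
  out <- list()
  i <- 1
  while (i <= length(p)) {
    if (s[i] == "-") {          # insertion relative to reference
      j <- i
      while (j < length(p) && s[j + 1] == "-") j <- j + 1
      anchor <- ref_pos[i]      # base before the insertion
      ins <- paste(p[i:j], collapse = "")
      out[[length(out) + 1]] <- tibble(
        pos = anchor, type = "insertion", len = j - i + 1L, seq = ins)
      i <- j + 1
    } else if (p[i] == "-") {   # deletion
      j <- i
      while (j < length(p) && p[j + 1] == "-") j <- j + 1
      anchor <- ref_pos[i] - 1L # base before the deleted run
      del <- paste(s[i:j], collapse = "")
      out[[length(out) + 1]] <- tibble(
        pos = anchor, type = "deletion", len = j - i + 1L, seq = del)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(out) == 0) return(tibble(pos = integer(), type = character(),
                                      len = integer(), seq = character()))
  list_rbind(out)
}

#' Left-align an indel within a reference window
#'
#' Shifts an anchored indel leftwards while the preceding reference base
#' equals the last base of the inserted/deleted sequence (the homopolymer /
#' tandem-repeat ambiguity), yielding the canonical leftmost representation.
#' Idempotent.
#'
#' @param pos 1-based anchor position (base before the event) in the window.
#' @param type "insertion" or "deletion".
#' @param seq Inserted or deleted bases.
#' @param reference_window Reference sequence.
#' @return A list with normalised `pos` and `seq`.
#' @export
left_align_indel <- function(pos, type, seq, reference_window) {
  refc <- strsplit(reference_window, "", fixed = TRUE)[[1]]
  seqc <- strsplit(seq, "", fixed = TRUE)[[1]]
  # rotating the event one base left is allowed while the base at the anchor
  # equals the event's last base; stop at the window edge (pos 1) so the
  # anchored representation keeps a preceding base
  while (pos > 1 && refc[pos] == seqc[length(seqc)]) {
    seqc <- c(refc[pos], seqc[-length(seqc)])
    pos <- pos - 1L
  }
  list(pos = as.integer(pos), seq = paste(seqc, collapse = ""))
}

#' Call indels in one exon window by local assembly
#'
#' @param reads Read sequences (character vector or tibble with `seq`).
#' @param reference_window Reference sequence of the exon plus flanks.
#' @param k K-mer size; retried at `k_retry` if the graph is unanchored.
#' @param k_retry Fallback k-mer size.
#' @param min_support K-mer pruning threshold.
#' @param min_fraction Minimum supporting read fraction for a call.
#' @param max_paths Haplotype cap.
#' @param window_offset 1-based genomic position of the window's first base;
#'   call positions are reported in this frame.
#' @param contig Contig name carried onto calls.
#' @return A tibble of indel calls: `contig`, `pos` (anchored, left-aligned,
#'   1-based), `ref`, `alt`, `type`, `len`, `support_fraction`.
#' @export
call_indels <- function(reads, reference_window, k = 21, k_retry = 31,
                        min_support = 2, min_fraction = 0.10, max_paths = 16,
                        window_offset = 1L, contig = "chr1") {
  if (is.data.frame(reads)) reads <- reads$seq
  g <- prune_graph(build_graph(reads, reference_window, k, min_support),
                   min_support)
  if (!g$anchored && k_retry > k &&
      nchar(reference_window) > k_retry && any(nchar(reads) > k_retry)) {
    g <- prune_graph(build_graph(reads, reference_window, k_retry, min_support),
                     min_support)
  }
  if (!g$anchored) {
    warn("assembly graph unanchored; no indel calls")
    return(empty_indel_calls())
  }
  # haplotypes span the anchored subwindow of the reference
  base_off <- g$source_offset - 1L
  subref <- substr(reference_window, g$source_offset,
                   g$sink_offset + g$k - 1L)
  haps <- enumerate_haplotypes(g, max_paths)
  haps <- filter(haps, .data$sequence != subref)
  if (nrow(haps) == 0) return(empty_indel_calls())
  calls <- purrr::map(seq_len(nrow(haps)), function(i) {
    al <- align_haplotype(haps$sequence[i], subref)
    ind <- alignment_indels(al$aligned_pattern, al$aligned_subject)
    if (nrow(ind) == 0) return(NULL)
    ind$hap_support <- haps$support[i]
    ind
  }) |> purrr::compact() |> list_rbind()
  if (is.null(calls) || nrow(calls) == 0) return(empty_indel_calls())
  # normalise, re-score against reads, deduplicate
  out <- purrr::map(seq_len(nrow(calls)), function(i) {
    nz <- left_align_indel(calls$pos[i] + base_off, calls$type[i],
                           calls$seq[i], reference_window)
    frac <- junction_support(reads, reference_window, nz$pos, calls$type[i],
                             nz$seq, g$k)
    anchor_base <- substr(reference_window, nz$pos, nz$pos)
    if (calls$type[i] == "insertion") {
      ref_a <- anchor_base; alt_a <- paste0(anchor_base, nz$seq)
    } else {
      ref_a <- paste0(anchor_base, nz$seq); alt_a <- anchor_base
    }
    tibble(contig = contig,
           pos = as.integer(window_offset + nz$pos - 1L),
           ref = ref_a, alt = alt_a, type = calls$type[i],
           len = calls$len[i], support_fraction = frac)
  }) |> list_rbind() |>
    distinct(.data$contig, .data$pos, .data$ref, .data$alt, .keep_all = TRUE) |>
    filter(.data$support_fraction >= min_fraction) |>
    arrange(.data$pos)
  out
}

empty_indel_calls <- function() {
  tibble(contig = character(), pos = integer(), ref = character(),
         alt = character(), type = character(), len = integer(),
         support_fraction = numeric())
}

# Fraction of junction-spanning reads consistent with the variant: compares
# occurrences of the variant junction sequence vs the reference junction
# sequence. Flanks are kept short (12 bases) so typical short reads can span
# the junction while the 24-mer stays effectively unique in an exon window.
junction_support <- function(reads, reference_window, pos, type, seq, k) {
  fl <- min(12, k - 1)
  refc <- reference_window
  left <- substr(refc, max(1, pos - fl + 1), pos)
  if (type == "insertion") {
    right <- substr(refc, pos + 1, min(nchar(refc), pos + fl))
    var_j <- paste0(left, seq, right)
    ref_j <- paste0(left, right)
  } else {
    right <- substr(refc, pos + nchar(seq) + 1,
                    min(nchar(refc), pos + nchar(seq) + fl))
    var_j <- paste0(left, right)
    ref_j <- paste0(left, seq, right)
  }
  n_var <- sum(stringr::str_detect(reads, stringr::fixed(var_j)))
  n_ref <- sum(stringr::str_detect(reads, stringr::fixed(ref_j)))
  if (n_var + n_ref == 0) return(0)
  # the longer junction string has fewer spanning start positions per read;
  # normalise each count by its expected span so the fraction is unbiased
  rl <- stats::median(nchar(reads))
  r_var <- n_var / max(1, rl - nchar(var_j) + 1)
  r_ref <- n_ref / max(1, rl - nchar(ref_j) + 1)
  r_var / (r_var + r_ref)
}
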