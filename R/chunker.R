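#' Tile contigs into fixed-size chunks
#'
#' Phasing is deliberately local: each contig is cut into `chunk_size`
#' intervals (25 kb by default) that are processed independently and later
#' merged. Chunks read alignments from a window extended by
#' `overlap_margin` on each side so that reads near a boundary are tagged
#' by both neighbouring chunks, which is what the merge step's label
#' reconciliation votes over.
#'
#' @param contig_lengths named integer vector of contig lengths.
#' @param chunk_size chunk width in bp (default 25000).
#' @param overlap_margin extension in bp on each side (default 5000).
#' @return tibble with columns `contig`, `start`, `end` (0-based
#'   half-open), `margin`.
#' @export
make_chunks <- function(contig_lengths, chunk_size = 25000,
                        overlap_margin = 5000) {
  stopifnot(length(contig_lengths) > 0, all(contig_lengths > 0),
            !is.null(names(contig_lengths)))
  purrr::imap(as.list(contig_lengths), function(len, contig) {
    starts <- seq(0L, len - 1L, by = chunk_size)
    tibble::tibble(contig = contig, start = as.integer(starts),
                   end = as.integer(pmin(starts + chunk_size, len)),
                   margin = as.integer(overlap_margin))
  }) |>
    dplyr::bind_rows()
}

# run candidates -> graph -> DP -> tagging on one chunk; emits tags for
# reads whose leftmost aligned base lies in [start - margin, end), so reads
# starting inside the left margin are shared with the previous chunk
haplotag_chunk <- function(bam, ref, chunk, sites = NULL, ...) {
  args <- list(...)
  win_start <- max(0L, chunk$start - chunk$margin)
  win_end <- chunk$end + chunk$margin
  if (is.null(sites)) {
    region <- sprintf("%s:%d-%d", chunk$contig, win_start + 1L, win_end)
    cand <- do.call(find_candidates, c(list(bam = bam, ref = ref, region = region),
                                       args))
  } else {
    in_win <- sites$position >= win_start & sites$position < win_end
    cand <- observations_at_sites(
      bam, sites[in_win, c("contig", "position", "alleles")],
      min_baseq = args$min_baseq %||% 10, min_mapq = args$min_mapq %||% 5)
  }
  graph <- build_graph(cand$sites, cand$observations)
  ph <- phase_graph(graph)
  tags <- assign_read_haplotags(graph, ph$assignment, ph$blocks,
                                read_ids = cand$read_info$read_id)
  tags <- dplyr::left_join(tags, cand$read_info, by = "read_id")
  tags <- tags[!is.na(tags$pos) &
                 tags$pos >= chunk$start - chunk$margin & tags$pos < chunk$end, ]
  tags$contig <- if (nrow(tags)) chunk$contig else character(0)
  tags$pos <- NULL
  hap_tags(tags)
}

swap_tags <- function(tags) {
  tags$tag <- ifelse(tags$tag == 1L, 2L, ifelse(tags$tag == 2L, 1L, 0L))
  sw <- tags$votes_phase1
  tags$votes_phase1 <- tags$votes_phase2
  tags$votes_phase2 <- sw
  tags
}

#' Merge per-chunk haplotags into one consistent tagging
#'
#' Chunks are phased independently, so their 1/2 labels are arbitrary
#' relative to each other. Walking chunks left to right, a chunk's labels
#' are flipped wholesale when the majority of reads it shares with the
#' already-merged output disagree with their merged tags. A read tagged in
#' several chunks keeps the record with the larger vote total
#' (votes_phase1 + votes_phase2); if vote totals tie and the tags still
#' conflict after flipping, the read is left untagged. The merge is
#' idempotent and equivariant under global label swaps of the inputs.
#'
#' @param per_chunk_tags list of `hap_tags` tibbles in coordinate order.
#' @param reconcile flip chunk labels to agree with the running merge
#'   (default TRUE); when FALSE, chunks keep their own label orientation
#'   and only deduplication is performed.
#' @return a single `hap_tags` tibble, one row per read.
#' @export
merge_chunks <- function(per_chunk_tags, reconcile = TRUE) {
  per_chunk_tags <- purrr::keep(per_chunk_tags, ~ nrow(.x) > 0)
  if (length(per_chunk_tags) == 0) {
    return(hap_tags(tibble::tibble(read_id = character(), tag = integer(),
                                   phase_set = integer(), votes_phase1 = integer(),
                                   votes_phase2 = integer())))
  }
  merged <- per_chunk_tags[[1]]
  for (chunk in per_chunk_tags[-1]) {
    if (reconcile) {
      shared <- dplyr::inner_join(
        merged[merged$tag != 0L, c("read_id", "tag")],
        chunk[chunk$tag != 0L, c("read_id", "tag")],
        by = "read_id", suffix = c("_m", "_c"))
      if (nrow(shared) > 0 &&
          sum(shared$tag_m != shared$tag_c) > sum(shared$tag_m == shared$tag_c)) {
        chunk <- swap_tags(chunk)
      }
    }
    both <- intersect(merged$read_id, chunk$read_id)
    if (length(both)) {
      m <- merged[match(both, merged$read_id), ]
      c2 <- chunk[match(both, chunk$read_id), ]
      vt_m <- m$votes_phase1 + m$votes_phase2
      vt_c <- c2$votes_phase1 + c2$votes_phase2
      keep_c <- vt_c > vt_m
      conflict <- m$tag != c2$tag & m$tag != 0L & c2$tag != 0L & vt_m == vt_c
      resolved <- m
      resolved[keep_c, ] <- c2[keep_c, ]
      # an untagged record never overrides a tagged one at equal vote totals
      tag_only_c <- m$tag == 0L & c2$tag != 0L & !keep_c & vt_c == vt_m
      resolved[tag_only_c, ] <- c2[tag_only_c, ]
      resolved$tag[conflict] <- 0L
      resolved$phase_set[conflict] <- NA_integer_
      merged[match(both, merged$read_id), ] <- resolved
      chunk <- chunk[!chunk$read_id %in% both, ]
    }
    merged <- dplyr::bind_rows(merged, chunk)
  }
  hap_tags(dplyr::arrange(merged, .data$read_id))
}

#' Haplotag a whole alignment file
#'
#' The full pipeline: tile the reference into chunks, and per chunk detect
#' candidate heterozygous sites (or take them from a supplied table/VCF),
#' build the allele graph, phase it by dynamic programming, and tag reads
#' by majority vote; finally merge the per-chunk taggings. Deterministic:
#' identical inputs give identical output.
#'
#' @inheritParams find_candidates
#' @param region optional region string restricting the run.
#' @param chunk_size chunk width in bp (default 25000).
#' @param overlap_margin chunk window extension in bp (default 5000).
#' @param merge reconcile labels across chunks (default TRUE); with FALSE
#'   each chunk keeps its own orientation (phase sets remain per-block
#'   either way).
#' @param sites optional [candidate_sites()] tibble (e.g. from
#'   [read_candidates_vcf()]) to use instead of pileup candidate detection.
#' @details The pipeline's allele-fraction window (`min_alt_fraction`
#'   0.25, i.e. alternate fraction within \[0.25, 0.75\]) is deliberately
#'   stricter than [find_candidates()]'s permissive module default of
#'   0.12. Phasing wants only sites whose allele balance is plausible for
#'   a heterozygote: at 30x a true het site falls outside \[0.25, 0.75\]
#'   with probability under 0.3\%, while a site driven by recurrent
#'   sequencing errors essentially never reaches a 25\% minor fraction.
#'   Skewed sites are worse than useless to the dynamic program — the best
#'   path crosses them through the homozygous diagonal, which carries no
#'   linkage and lets the phase orientation reshuffle mid-block.
#' @return a `hap_tags` tibble with columns `read_id`, `contig`, `tag`,
#'   `phase_set`, `votes_phase1`, `votes_phase2`.
#' @export
run_haplotag <- function(bam, ref, region = NULL, chunk_size = 25000,
                         overlap_margin = 5000, merge = TRUE, sites = NULL,
                         min_alt_count = 2, min_alt_fraction = 0.25,
                         min_baseq = 10, min_mapq = 5, max_alleles = 4) {
  check_bam_indexed(bam)
  lens <- bam_contig_lengths(bam)
  if (!is.null(region)) {
    reg <- parse_region(region, lens)
    lens <- setNames(reg$end0, reg$contig)
    offset <- reg$start0
  } else {
    offset <- 0L
  }
  chunks <- make_chunks(lens, chunk_size, overlap_margin)
  chunks <- chunks[chunks$end > offset, ]
  chunks$start <- pmax(chunks$start, offset)
  per_chunk <- purrr::map(seq_len(nrow(chunks)), function(r) {
    ch <- as.list(chunks[r, ])
    ch_sites <- if (is.null(sites)) NULL else sites[sites$contig == ch$contig, ]
    haplotag_chunk(bam, ref, ch, sites = ch_sites,
                   min_alt_count = min_alt_count,
                   min_alt_fraction = min_alt_fraction,
                   min_baseq = min_baseq, min_mapq = min_mapq,
                   max_alleles = max_alleles)
  })
  # per-contig reconciliation only: labels never cross contigs
  key <- chunks$contig
  merged <- purrr::map(split(per_chunk, key)[unique(key)], function(lst) {
    merge_chunks(lst, reconcile = merge)
  })
  hap_tags(dplyr::bind_rows(merged))
}
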