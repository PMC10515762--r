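#' Parse a region string
#'
#' Accepts the usual `contig:start-end` dialect (1-based, inclusive) or a
#' bare contig name.
#'
#' @param region region string.
#' @param contig_lengths named integer vector (from the BAM header) used to
#'   fill in the end for bare contig names.
#' @return list with `contig`, `start0` (0-based), `end0` (half-open).
#' @export
parse_region <- function(region, contig_lengths = NULL) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9,]+)-([0-9,]+))?$", region))[[1]]
  if (length(m) == 0 || m[2] == "") stop("cannot parse region '", region, "'")
  contig <- m[2]
  if (m[3] == "") {
    if (is.null(contig_lengths) || !contig %in% names(contig_lengths)) {
      stop("region '", region, "' has no coordinates and contig length is unknown")
    }
    return(list(contig = contig, start0 = 0L,
                end0 = unname(contig_lengths[contig])))
  }
  start1 <- as.integer(gsub(",", "", m[4]))
  end1 <- as.integer(gsub(",", "", m[5]))
  if (is.na(start1) || is.na(end1) || start1 < 1 || end1 < start1) {
    stop("cannot parse region '", region, "'")
  }
  list(contig = contig, start0 = start1 - 1L, end0 = end1)
}

bam_contig_lengths <- function(bam) {
  h <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  vapply(h, as.integer, integer(1))
}

check_bam_indexed <- function(bam) {
  if (!file.exists(bam)) stop("alignment file not found: ", bam)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)) &&
      !file.exists(paste0(bam, ".csi"))) {
    stop("alignment file ", bam,
         " is not indexed; sort and index it (samtools sort && samtools index)")
  }
  invisible(bam)
}

# Stack primary alignments over a region into a per-read x per-position
# character matrix (deletions '-', reference skips '.', outside-read '+'),
# masking bases below the quality floor as 'N'. Returns the matrix plus
# per-read leftmost coordinates and covered-column ranges.
stack_region <- function(bam, contig, start0, end0, min_baseq = 10, min_mapq = 5) {
  check_bam_indexed(bam)
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start0 + 1L, end0))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  sbp <- Rsamtools::ScanBamParam(which = gr, flag = flag,
                                 mapqFilter = min_mapq, what = c("qname", "pos"))
  info <- Rsamtools::scanBam(bam, param = sbp)[[1]]
  width <- end0 - start0
  if (length(info$qname) == 0) {
    return(list(mat = matrix(character(0), 0, width), read_id = character(0),
                start0 = start0,
                read_info = tibble::tibble(read_id = character(), pos = integer(),
                                           first_col = integer(), last_col = integer())))
  }
  seqs <- GenomicAlignments::stackStringsFromBam(bam, param = sbp, what = "seq")
  quals <- GenomicAlignments::stackStringsFromBam(bam, param = sbp, what = "qual")
  mat <- as.matrix(seqs)
  qmat <- as.matrix(quals)
  phred <- matrix(match(qmat, PHRED_CHARS) - 1L, nrow = nrow(qmat))
  mask <- !is.na(phred) & phred < min_baseq & mat %in% BASES
  mat[mask] <- "N"
  covered <- mat != "+"
  first_col <- apply(covered, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  last_col <- apply(covered, 1, function(r) if (any(r)) max(which(r)) else NA_integer_)
  list(mat = mat, read_id = info$qname, start0 = start0,
       read_info = tibble::tibble(read_id = info$qname, pos = info$pos - 1L,
                                  first_col = first_col, last_col = last_col))
}

PHRED_CHARS <- strsplit(rawToChar(as.raw(33:126)), "")[[1]]

read_reference_window <- function(ref, contig, start0, end0) {
  fai <- paste0(ref, ".fai")
  if (!file.exists(fai)) Rsamtools::indexFa(ref)
  fa <- Rsamtools::FaFile(ref)
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start0 + 1L, end0))
  as.character(Biostrings::getSeq(fa, gr)[[1]])
}

site_observations_from_stack <- function(stk, sites) {
  if (nrow(sites) == 0 || nrow(stk$read_info) == 0) {
    return(read_observations(tibble::tibble(
      read_id = character(), site_index = integer(), allele_index = integer(),
      read_start_site = integer(), read_end_site = integer())))
  }
  cols <- sites$position - stk$start0 + 1L
  obs <- purrr::map(seq_len(nrow(sites)), function(s) {
    base <- stk$mat[, cols[s]]
    ai <- match(base, sites$alleles[[s]])
    keep <- which(!is.na(ai))
    if (!length(keep)) return(NULL)
    tibble::tibble(read_id = stk$read_id[keep], site_index = sites$site_index[s],
                   allele_index = ai[keep])
  })
  obs <- dplyr::bind_rows(obs)
  if (nrow(obs) == 0) {
    return(read_observations(tibble::tibble(
      read_id = character(), site_index = integer(), allele_index = integer(),
      read_start_site = integer(), read_end_site = integer())))
  }
  # physical-overlap range over candidate sites, per read
  ri <- stk$read_info
  span <- purrr::map(seq_len(nrow(ri)), function(r) {
    within <- which(cols >= ri$first_col[r] & cols <= ri$last_col[r])
    if (!length(within)) return(NULL)
    tibble::tibble(read_id = ri$read_id[r],
                   read_start_site = sites$site_index[min(within)],
                   read_end_site = sites$site_index[max(within)])
  })
  span <- dplyr::bind_rows(span)
  obs <- dplyr::left_join(obs, span, by = "read_id")
  read_observations(obs)
}

#' Detect putative heterozygous sites from an alignment pileup
#'
#' Scans the pileup of primary alignments over a region and emits sites
#' where at least one non-reference allele clears the filters: minimum alt
#' read count, alt fraction within `[min_alt_fraction, 1 - min_alt_fraction]`
#' (so neither allele dominates, the signature of a heterozygous site),
#' minimum base quality (failing bases are ignored entirely) and minimum
#' mapping quality. SNVs only. These candidates seed the allele graph;
#' downstream phasing tolerates noisy candidates, so defaults are
#' permissive.
#'
#' @param bam indexed, coordinate-sorted BAM of long reads.
#' @param ref reference FASTA (indexed on first use).
#' @param region region string `contig:start-end` (1-based inclusive) or
#'   bare contig name.
#' @param min_alt_count minimum reads on an alternate allele (default 2).
#' @param min_alt_fraction minimum allele fraction for an alternate allele,
#'   also bounding it above by `1 - min_alt_fraction` (default 0.12).
#' @param min_baseq minimum base quality for a base to count (default 10).
#' @param min_mapq minimum mapping quality for a read to be used (default 5).
#' @param max_alleles cap on alleles per site, reference always kept,
#'   excess alternates dropped lowest-support-first (default 4).
#' @return list with `sites` ([candidate_sites()] tibble with an
#'   `allele_counts` list-column), `observations`
#'   ([read_observations()] tibble) and `read_info` (tibble: `read_id`,
#'   `pos` 0-based leftmost aligned base).
#' @export
find_candidates <- function(bam, ref, region, min_alt_count = 2,
                            min_alt_fraction = 0.12, min_baseq = 10,
                            min_mapq = 5, max_alleles = 4) {
  reg <- parse_region(region, bam_contig_lengths(bam))
  lens <- bam_contig_lengths(bam)
  if (!reg$contig %in% names(lens)) {
    stop("contig '", reg$contig, "' absent from the alignment header")
  }
  end0 <- min(reg$end0, lens[[reg$contig]])
  stk <- stack_region(bam, reg$contig, reg$start0, end0,
                      min_baseq = min_baseq, min_mapq = min_mapq)
  empty_sites <- candidate_sites(tibble::tibble(
    contig = character(), position = integer(), alleles = list()))
  if (nrow(stk$read_info) == 0) {
    return(list(sites = empty_sites,
                observations = site_observations_from_stack(stk, empty_sites),
                read_info = stk$read_info[, c("read_id", "pos")]))
  }
  counts <- vapply(BASES, function(b) colSums(stk$mat == b),
                   numeric(ncol(stk$mat)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, BASES))
  depth <- rowSums(counts)
  ref_chars <- strsplit(read_reference_window(ref, reg$contig, reg$start0, end0),
                        "")[[1]]

  # vectorized prefilter: any non-reference base passing count + fraction
  any_pass <- rep(FALSE, length(depth))
  for (b in BASES) {
    cb <- counts[, b]
    fb <- ifelse(depth > 0, cb / depth, 0)
    any_pass <- any_pass |
      (ref_chars != b & cb >= min_alt_count &
         fb >= min_alt_fraction & fb <= 1 - min_alt_fraction)
  }
  any_pass <- any_pass & ref_chars %in% BASES & depth > 0
  site_rows <- list()
  for (cc in which(any_pass)) {
    rb <- ref_chars[cc]
    d <- depth[cc]
    alt_bases <- setdiff(BASES, rb)
    acnt <- counts[cc, alt_bases]
    frac <- acnt / d
    pass <- acnt >= min_alt_count & frac >= min_alt_fraction &
      frac <= 1 - min_alt_fraction
    alts <- alt_bases[pass]
    ord <- order(-acnt[pass], alts)
    alts <- alts[ord][seq_len(min(sum(pass), max_alleles - 1L))]
    site_alleles <- c(rb, alts)
    site_counts <- setNames(as.integer(counts[cc, site_alleles]), site_alleles)
    site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
      contig = reg$contig, position = reg$start0 + cc - 1L,
      alleles = list(site_alleles), allele_counts = list(site_counts))
  }
  if (length(site_rows) == 0) {
    return(list(sites = empty_sites,
                observations = site_observations_from_stack(stk, empty_sites),
                read_info = stk$read_info[, c("read_id", "pos")]))
  }
  sites_raw <- dplyr::bind_rows(site_rows)
  sites <- candidate_sites(sites_raw[, c("contig", "position", "alleles")])
  sites$allele_counts <- sites_raw$allele_counts[order(sites_raw$position)]
  obs <- site_observations_from_stack(stk, sites)
  list(sites = sites, observations = obs,
       read_info = stk$read_info[, c("read_id", "pos")])
}

#' Recompute read observations at externally supplied candidate sites
#'
#' Used when candidate sites come from a VCF instead of pileup scanning:
#' the sites are taken as given and only the per-read allele observations
#' are extracted from the alignments.
#'
#' @inheritParams find_candidates
#' @param sites a [candidate_sites()] tibble (one contig).
#' @return list with `sites`, `observations`, `read_info` as in
#'   [find_candidates()].
#' @export
observations_at_sites <- function(bam, sites, min_baseq = 10, min_mapq = 5) {
  sites <- candidate_sites(sites)
  if (nrow(sites) == 0) {
    stk <- list(read_info = tibble::tibble(read_id = character(), pos = integer()))
    return(list(sites = sites,
                observations = read_observations(tibble::tibble(
                  read_id = character(), site_index = integer(),
                  allele_index = integer(), read_start_site = integer(),
                  read_end_site = integer())),
                read_info = stk$read_info))
  }
  contig <- unique(sites$contig)
  stopifnot(length(contig) == 1)
  stk <- stack_region(bam, contig, min(sites$position),
                      max(sites$position) + 1L,
                      min_baseq = min_baseq, min_mapq = min_mapq)
  list(sites = sites, observations = site_observations_from_stack(stk, sites),
       read_info = stk$read_info[, c("read_id", "pos")])
}
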