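#' Simulation settings for a synthetic diploid sample
#'
#' Defaults describe a HiFi-like library: highly accurate reads (per-base
#' substitution error 0.002) with lengths around 18 kb, 30x coverage, and
#' heterozygous SNVs at 1 per kb. `sim_config_ont()` is an ONT-like preset
#' (error 0.03, 30 kb reads) for stress tests. Errors are substitutions
#' only, so reads map to reference coordinates without alignment.
#'
#' @param seed integer seed; every random draw in the simulator flows from it.
#' @param genome_length reference length in bp.
#' @param het_snv_rate per-bp probability of a heterozygous SNV.
#' @param coverage target mean coverage.
#' @param read_length_mean mean read length in bp (lognormal).
#' @param read_length_sd lognormal sdlog of read length.
#' @param per_base_error i.i.d. substitution error rate per base.
#' @param contig name of the simulated contig.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 200000L, het_snv_rate = 0.001,
                       coverage = 30, read_length_mean = 18000,
                       read_length_sd = 0.3, per_base_error = 0.002,
                       contig = "sim1") {
  stopifnot(genome_length > 0, het_snv_rate >= 0, het_snv_rate <= 1,
            per_base_error >= 0, per_base_error <= 1, coverage > 0,
            read_length_mean > 0, read_length_sd >= 0)
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 het_snv_rate = het_snv_rate, coverage = coverage,
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 per_base_error = per_base_error, contig = contig),
            class = "sim_config")
}

#' @rdname sim_config
#' @param ... overrides passed to [sim_config()].
#' @export
sim_config_ont <- function(...) {
  args <- utils::modifyList(list(per_base_error = 0.03, read_length_mean = 30000),
                            list(...))
  do.call(sim_config, args)
}

BASES <- c("A", "C", "G", "T")

with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a diploid sample with known truth haplotypes
#'
#' Draws a random reference, plants heterozygous SNVs (the alternate allele
#' lands on haplotype 1 or 2 with equal probability per site), and samples
#' reads uniformly along the genome, each from a fairly chosen haplotype,
#' with i.i.d. substitution errors. Deterministic given the seed. When
#' `dir` is given, also writes a reference FASTA, a coordinate-sorted and
#' indexed BAM (reads placed at their known positions; no aligner
#' involved), and a truth TSV (`read_id`, `haplotype`, `start`, `length`).
#'
#' @param config a [sim_config()].
#' @param dir output directory, or `NULL` for in-memory only.
#' @return a list of class `sim_data`: `config`, `contig`, `reference`
#'   (character scalar), `sites` (tibble compatible with
#'   [candidate_sites()]: ref and alt allele per het site, plus `alt_hap`),
#'   `reads` (tibble: `read_id`, `haplotype`, `start` 0-based, `length`,
#'   `seq`), `truth` (tibble: `read_id`, `tag` = truth haplotype), and when
#'   written, `paths` (named: fasta, bam, truth_tsv).
#' @export
simulate_diploid <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  sim <- with_sim_seed(config$seed, {
    genome <- sample(BASES, L, replace = TRUE)
    pos0 <- which(runif(L) < config$het_snv_rate) - 1L
    ref_allele <- genome[pos0 + 1L]
    alt_allele <- vapply(ref_allele, function(b) sample(setdiff(BASES, b), 1L),
                         character(1), USE.NAMES = FALSE)
    alt_hap <- sample(1:2, length(pos0), replace = TRUE)

    hap <- list(genome, genome)
    for (h in 1:2) {
      on_h <- alt_hap == h
      hap[[h]][pos0[on_h] + 1L] <- alt_allele[on_h]
    }

    n_reads <- ceiling(config$coverage * L / config$read_length_mean)
    meanlog <- log(config$read_length_mean) - config$read_length_sd^2 / 2
    len <- as.integer(pmin(L, pmax(500, round(
      rlnorm(n_reads, meanlog, config$read_length_sd)))))
    start <- as.integer(floor(runif(n_reads) * (L - len + 1)))
    read_hap <- sample(1:2, n_reads, replace = TRUE)

    seqs <- character(n_reads)
    for (r in seq_len(n_reads)) {
      chars <- hap[[read_hap[r]]][(start[r] + 1L):(start[r] + len[r])]
      if (config$per_base_error > 0) {
        err <- which(runif(len[r]) < config$per_base_error)
        if (length(err)) {
          chars[err] <- vapply(chars[err], function(b) sample(setdiff(BASES, b), 1L),
                               character(1), USE.NAMES = FALSE)
        }
      }
      seqs[r] <- paste(chars, collapse = "")
    }
    list(genome = genome, pos0 = pos0, ref_allele = ref_allele,
         alt_allele = alt_allele, alt_hap = alt_hap,
         len = len, start = start, read_hap = read_hap, seqs = seqs)
  })

  read_id <- sprintf("read%05d", seq_along(sim$seqs))
  sites <- tibble::tibble(
    contig = config$contig, position = sim$pos0,
    alleles = purrr::map2(sim$ref_allele, sim$alt_allele, c),
    alt_hap = sim$alt_hap)
  reads <- tibble::tibble(read_id = read_id, haplotype = sim$read_hap,
                          start = sim$start, length = sim$len, seq = sim$seqs)
  truth <- tibble::tibble(read_id = read_id, tag = sim$read_hap)
  out <- list(config = config, contig = config$contig,
              reference = paste(sim$genome, collapse = ""),
              sites = sites, reads = reads, truth = truth)
  class(out) <- "sim_data"
  if (!is.null(dir)) out <- write_sim(out, dir)
  out
}

write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "reference.fasta")
  ref <- Biostrings::DNAStringSet(sim$reference)
  names(ref) <- sim$contig
  Biostrings::writeXStringSet(ref, fasta)

  truth_tsv <- file.path(dir, "truth.tsv")
  readr::write_tsv(
    dplyr::transmute(sim$reads, read_id = .data$read_id,
                     haplotype = .data$haplotype, start = .data$start,
                     length = .data$length),
    truth_tsv)

  sam <- file.path(dir, "reads.sam")
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", sim$contig, nchar(sim$reference))),
             con)
  rd <- dplyr::arrange(sim$reads, .data$start, .data$read_id)
  # base qualities calibrated to the configured error rate
  q <- max(2L, min(40L, as.integer(round(
    -10 * log10(max(sim$config$per_base_error, 1e-4))))))
  qchar <- rawToChar(as.raw(q + 33L))
  writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                     rd$read_id, sim$contig, rd$start + 1L, rd$length,
                     rd$seq, strrep(qchar, rd$length)),
             con)
  close(con)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  sim$paths <- list(fasta = fasta, bam = bam, truth_tsv = truth_tsv)
  sim
}

#' Read-allele observations straight from a simulation (no alignment file)
#'
#' For every read and every heterozygous site the read physically overlaps,
#' reports the observed allele if the read's base matches the site's ref or
#' alt allele (an error to a third base yields no observation, as a pileup
#' would also discard it). `read_start_site`/`read_end_site` reflect
#' physical overlap, so fresh-read bookkeeping matches the aligned-BAM
#' route exactly.
#'
#' @param sim a `sim_data` object.
#' @return list with `sites` (validated [candidate_sites()] tibble) and
#'   `observations` (validated [read_observations()] tibble).
#' @export
sim_observations <- function(sim) {
  stopifnot(inherits(sim, "sim_data"))
  sites <- candidate_sites(sim$sites[, c("contig", "position", "alleles")])
  pos0 <- sites$position
  if (length(pos0) == 0) {
    return(list(sites = sites,
                observations = read_observations(tibble::tibble(
                  read_id = character(), site_index = integer(),
                  allele_index = integer(), read_start_site = integer(),
                  read_end_site = integer()))))
  }
  rows <- purrr::pmap(sim$reads, function(read_id, haplotype, start, length, seq) {
    idx <- which(pos0 >= start & pos0 < start + length)
    if (!length(idx)) return(NULL)
    off <- pos0[idx] - start + 1L
    base <- substring(seq, off, off)
    ai <- vapply(seq_along(idx), function(t) {
      m <- match(base[t], sites$alleles[[idx[t]]])
      if (is.na(m)) NA_integer_ else m
    }, integer(1))
    keep <- !is.na(ai)
    if (!any(keep)) return(NULL)
    tibble::tibble(read_id = read_id, site_index = idx[keep],
                   allele_index = ai[keep],
                   read_start_site = min(idx), read_end_site = max(idx))
  })
  list(sites = sites,
       observations = read_observations(dplyr::bind_rows(rows)))
}
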