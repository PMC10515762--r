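# Canonical two-site fixture: 11 reads over two heterozygous sites.
# Site 1: allele 1 carried by r1-r5, allele 2 by r6-r11.
# Site 2: allele 1 carried by r1-r3 and r6, allele 2 by r4, r5, r7-r11.
we_fixture <- function() {
  sites <- tibble::tibble(
    contig = "chrT",
    position = c(100L, 200L),
    alleles = list(c("A", "C"), c("G", "T")))
  obs <- tibble::tibble(
    read_id = c(sprintf("read%d", 1:5), sprintf("read%d", 6:11),
                sprintf("read%d", c(1:3, 6)), sprintf("read%d", c(4, 5, 7:11))),
    site_index = c(rep(1L, 11), rep(2L, 11)),
    allele_index = c(rep(1L, 5), rep(2L, 6), rep(1L, 4), rep(2L, 7)))
  list(sites = sites, observations = obs)
}

we_graph <- function() {
  fx <- we_fixture()
  build_graph(fx$sites, fx$observations)
}

# random small phasing instance for oracle-vs-DP checks
random_instance <- function(seed, max_sites = 5, max_alleles = 3, max_reads = 20,
                            keep_prob = 0.85) {
  set.seed(seed)
  n_sites <- sample(2:max_sites, 1)
  n_all <- sample(2:max_alleles, n_sites, replace = TRUE)
  sites <- tibble::tibble(
    contig = "chrR",
    position = as.integer(seq(10, by = 50, length.out = n_sites)),
    alleles = lapply(n_all, function(a) LETTERS[seq_len(a)]))
  n_reads <- sample(3:max_reads, 1)
  rows <- list()
  for (r in seq_len(n_reads)) {
    s0 <- sample(seq_len(n_sites), 1)
    s1 <- sample(s0:n_sites, 1)
    covered <- s0:s1
    # dropped-out sites mimic deletions / missing coverage
    keep <- covered[runif(length(covered)) < keep_prob]
    if (!length(keep)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      read_id = sprintf("r%02d", r),
      site_index = keep,
      allele_index = vapply(keep, function(s) sample(seq_len(n_all[s]), 1L),
                            integer(1)),
      read_start_site = min(covered), read_end_site = max(covered))
  }
  list(sites = sites, observations = dplyr::bind_rows(rows))
}

# tiny BAM with a given pileup column: n_ref reads carrying the reference
# base and n_alt carrying one alternate at position `at` (0-based)
make_column_bam <- function(dir, n_ref, n_alt, at = 50L, read_len = 80L,
                            contig_len = 200L, baseq = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(42)
  genome <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
  ref_base <- genome[at + 1L]
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  fasta <- file.path(dir, "ref.fasta")
  refset <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(refset) <- "ctg"
  Biostrings::writeXStringSet(refset, fasta)
  start0 <- at - read_len %/% 2L
  mk_read <- function(id, base) {
    chars <- genome[(start0 + 1L):(start0 + read_len)]
    chars[at - start0 + 1L] <- base
    paste(chars, collapse = "")
  }
  ids <- sprintf("col%03d", seq_len(n_ref + n_alt))
  seqs <- c(vapply(seq_len(n_ref), function(i) mk_read(i, ref_base), character(1)),
            vapply(seq_len(n_alt), function(i) mk_read(i, alt_base), character(1)))
  qchar <- rawToChar(as.raw(baseq + 33L))
  sam <- file.path(dir, "reads.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:ctg\tLN:%d", contig_len),
               sprintf("%s\t0\tctg\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       ids, start0 + 1L, read_len, seqs,
                       strrep(qchar, read_len))),
             sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                          indexDestination = TRUE)
  list(bam = bam, fasta = fasta, ref_base = ref_base, alt_base = alt_base,
       position = at)
}

# BAM holding exactly the 11 canonical-fixture reads (50 bp each)
make_we_bam <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(7)
  contig_len <- 400L
  genome <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
  ids <- sprintf("read%d", 1:11)
  sam <- file.path(dir, "we.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:chrT\tLN:%d", contig_len),
               sprintf("%s\t0\tchrT\t%d\t60\t50M\t*\t0\t0\t%s\t%s",
                       ids, 90L + seq_along(ids),
                       vapply(seq_along(ids), function(i) {
                         paste(genome[(90L + i):(139L + i)], collapse = "")
                       }, character(1)),
                       strrep("I", 50L))),
             sam)
  Rsamtools::asBam(sam, file.path(dir, "we"), overwrite = TRUE,
                   indexDestination = TRUE)
}

we_expected_tags <- function() {
  tibble::tibble(
    read_id = sprintf("read%d", 1:11),
    tag = c(1L, 1L, 1L, 0L, 0L, 0L, 2L, 2L, 2L, 2L, 2L))
}
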