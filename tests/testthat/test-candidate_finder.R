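test_that("a balanced 6/6 column becomes one biallelic candidate with 12 observations", {
  fx <- make_column_bam(withr::local_tempdir(), n_ref = 6, n_alt = 6)
  cand <- find_candidates(fx$bam, fx$fasta, "ctg:1-200")
  expect_equal(nrow(cand$sites), 1)
  expect_equal(cand$sites$position, fx$position)
  expect_equal(cand$sites$alleles[[1]], c(fx$ref_base, fx$alt_base))
  expect_equal(nrow(cand$observations), 12)
})

test_that("columns without a qualifying alternate allele are not candidates", {
  dir <- withr::local_tempdir()
  pure <- make_column_bam(file.path(dir, "a"), n_ref = 20, n_alt = 0)
  expect_equal(nrow(find_candidates(pure$bam, pure$fasta, "ctg:1-200")$sites), 0)
  # a single alt read fails the min alt count of 2
  singleton <- make_column_bam(file.path(dir, "b"), n_ref = 19, n_alt = 1)
  expect_equal(nrow(find_candidates(singleton$bam, singleton$fasta, "ctg:1-200")$sites), 0)
  # ... but passes when the count threshold is dropped to 1
  relaxed <- find_candidates(singleton$bam, singleton$fasta, "ctg:1-200",
                             min_alt_count = 1, min_alt_fraction = 0.04)
  expect_equal(nrow(relaxed$sites), 1)
})

test_that("an overly skewed allele balance fails the fraction window", {
  fx <- make_column_bam(withr::local_tempdir(), n_ref = 18, n_alt = 2)
  # 2/20 = 0.10 < 0.12
  expect_equal(nrow(find_candidates(fx$bam, fx$fasta, "ctg:1-200")$sites), 0)
  expect_equal(nrow(find_candidates(fx$bam, fx$fasta, "ctg:1-200",
                                    min_alt_fraction = 0.08)$sites), 1)
})

test_that("low base quality silences a column", {
  fx <- make_column_bam(withr::local_tempdir(), n_ref = 6, n_alt = 6, baseq = 5L)
  expect_equal(nrow(find_candidates(fx$bam, fx$fasta, "ctg:1-200")$sites), 0)
  got <- find_candidates(fx$bam, fx$fasta, "ctg:1-200", min_baseq = 3)
  expect_equal(nrow(got$sites), 1)
})

test_that("lowering the fraction floor only grows the candidate set", {
  sim <- simulate_diploid(sim_config(seed = 5, genome_length = 30000,
                                     per_base_error = 0.01),
                          dir = withr::local_tempdir())
  fracs <- c(0.3, 0.2, 0.12, 0.05)
  found <- lapply(fracs, function(f) {
    find_candidates(sim$paths$bam, sim$paths$fasta, "sim1:1-30000",
                    min_alt_fraction = f)$sites$position
  })
  for (k in seq_along(fracs)[-1]) {
    expect_true(all(found[[k - 1]] %in% found[[k]]),
                info = paste("fraction", fracs[k]))
  }
})

test_that("error-free diploid reads recover exactly the simulated het sites", {
  sim <- simulate_diploid(sim_config(seed = 9, genome_length = 40000,
                                     per_base_error = 0),
                          dir = withr::local_tempdir())
  cand <- find_candidates(sim$paths$bam, sim$paths$fasta, "sim1:1-40000")
  # no false sites: every candidate is a simulated het site
  expect_true(all(cand$sites$position %in% sim$sites$position))
  # no misses: every simulated site whose observed allele counts clear the
  # default filters (cross-checked through the alignment-free observation
  # table) is found; only thinly covered sites near the contig end may fail
  so <- sim_observations(sim)
  counts <- so$observations |>
    dplyr::group_by(.data$site_index) |>
    dplyr::summarise(n = dplyr::n(), alt = sum(.data$allele_index == 2L))
  frac <- counts$alt / counts$n
  passing <- counts$site_index[counts$alt >= 2 & frac >= 0.12 & frac <= 0.88]
  expect_setequal(cand$sites$position, so$sites$position[passing])
  # detected alleles match the simulated ref/alt pair
  hit <- match(cand$sites$position, sim$sites$position)
  expect_equal(cand$sites$alleles, sim$sites$alleles[hit])
})

test_that("unindexed alignments are rejected with a diagnostic", {
  sim <- simulate_diploid(sim_config(seed = 3, genome_length = 20000),
                          dir = withr::local_tempdir())
  naked <- sub("\\.bam$", "_noindex.bam", sim$paths$bam)
  file.copy(sim$paths$bam, naked)
  expect_error(find_candidates(naked, sim$paths$fasta, "sim1:1-20000"),
               "not indexed")
})

test_that("a zero-coverage region yields empty output", {
  fx <- make_column_bam(withr::local_tempdir(), n_ref = 6, n_alt = 6,
                        contig_len = 2000L)
  cand <- find_candidates(fx$bam, fx$fasta, "ctg:1000-2000")
  expect_equal(nrow(cand$sites), 0)
  expect_equal(nrow(cand$observations), 0)
})

test_that("region strings parse in the standard 1-based dialect", {
  r <- parse_region("chr2:1,001-25,000")
  expect_equal(r$contig, "chr2")
  expect_equal(r$start0, 1000L)
  expect_equal(r$end0, 25000L)
  expect_error(parse_region("chr2:10-5"), "cannot parse")
  whole <- parse_region("chr3", c(chr3 = 999L))
  expect_equal(whole$end0, 999L)
})

test_that("a 3-in-25 skewed column passes the module default but not the phasing window", {
  fx <- make_column_bam(withr::local_tempdir(), n_ref = 22, n_alt = 3)
  permissive <- find_candidates(fx$bam, fx$fasta, "ctg:1-200")
  expect_equal(nrow(permissive$sites), 1)
  het_grade <- find_candidates(fx$bam, fx$fasta, "ctg:1-200",
                               min_alt_fraction = 0.25)
  expect_equal(nrow(het_grade$sites), 0)
})
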