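test_that("initialization scores are read-set union sizes", {
  g <- we_graph()
  t <- init_scores(g, 1L)
  expect_equal(t$score[[1]][1, 1], 5L)
  expect_equal(t$score[[1]][1, 2], 11L)
  expect_equal(t$score[[1]][2, 2], 6L)
  # only the i <= j triangle is materialized at a block start
  expect_true(is.na(t$score[[1]][2, 1]))
  expect_equal(t$block_starts, 1L)
})

test_that("initialization over an unsupported site gives all-zero scores", {
  sites <- tibble::tibble(contig = "c", position = c(1L, 5L),
                          alleles = list(c("A", "G"), c("C", "T")))
  obs <- tibble::tibble(read_id = "r1", site_index = 2L, allele_index = 1L)
  g <- build_graph(sites, obs)
  t <- init_scores(g, 1L)
  expect_equal(t$score[[1]][upper.tri(t$score[[1]], diag = TRUE)],
               rep(0L, 3))
})

test_that("the recursion reproduces the fixture's transition scores", {
  g <- we_graph()
  t <- recurrence_step(g, init_scores(g, 1L), 2L)
  s2 <- t$score[[2]]
  expect_equal(s2[1, 1], 15L)
  expect_equal(s2[1, 2], 19L)
  expect_equal(s2[2, 1], 14L)
  # (2,2) from the fixture's read sets: max{5+2, 11+7, 6+5}
  expect_equal(s2[2, 2], 18L)
  # backpointers of the best cell point at the heterozygous init pair
  expect_equal(t$bp_i[[2]][1, 2], 1L)
  expect_equal(t$bp_j[[2]][1, 2], 2L)
})

test_that("backtracking selects the 19-scoring path and phases both sites", {
  g <- we_graph()
  ph <- phase_graph(g)
  expect_equal(ph$best_score, 19L)
  expect_equal(nrow(ph$blocks), 1)
  expect_equal(ph$assignment$phase1_allele, c(1L, 1L))
  expect_equal(ph$assignment$phase2_allele, c(2L, 2L))
  expect_equal(ph$blocks$anchor_position, 101L)  # 1-based anchor of site 1
})

test_that("backtracking an empty table yields an empty assignment", {
  g <- build_graph(tibble::tibble(contig = character(), position = integer(),
                                  alleles = list()),
                   tibble::tibble(read_id = character(), site_index = integer(),
                                  allele_index = integer()))
  ph <- phase_graph(g)
  expect_equal(nrow(ph$assignment), 0)
  expect_equal(nrow(ph$blocks), 0)
  expect_equal(ph$best_score, 0L)
})

test_that("ties break toward the lexicographically smallest allele pair", {
  # two alleles with identical, disjoint support: (1,2) and (2,1) tie
  sites <- tibble::tibble(contig = "c", position = 1L, alleles = list(c("A", "G")))
  obs <- tibble::tibble(read_id = sprintf("r%d", 1:4), site_index = 1L,
                        allele_index = c(1L, 1L, 2L, 2L))
  ph <- phase_graph(build_graph(sites, obs))
  expect_equal(ph$assignment$phase1_allele, 1L)
  expect_equal(ph$assignment$phase2_allele, 2L)
})

test_that("a gap with no spanning reads splits the interval into two blocks", {
  sites <- tibble::tibble(contig = "c", position = c(1L, 100L, 5000L, 5100L),
                          alleles = list(c("A", "G"), c("C", "T"),
                                         c("A", "T"), c("G", "C")))
  obs <- dplyr::bind_rows(
    tibble::tibble(read_id = c("r1", "r1", "r2", "r2"),
                   site_index = c(1L, 2L, 1L, 2L), allele_index = c(1L, 1L, 2L, 2L)),
    tibble::tibble(read_id = c("r3", "r3", "r4", "r4"),
                   site_index = c(3L, 4L, 3L, 4L), allele_index = c(1L, 1L, 2L, 2L)))
  ph <- phase_graph(build_graph(sites, obs))
  expect_equal(nrow(ph$blocks), 2)
  expect_equal(ph$blocks$first_site, c(1L, 3L))
  expect_equal(ph$blocks$anchor_position, c(2L, 5001L))
  expect_equal(sort(unique(ph$assignment$block_id)), c(1L, 2L))
})

test_that("scores are monotone non-decreasing along backpointer chains", {
  for (seed in c(11, 17, 23)) {
    inst <- random_instance(seed)
    g <- build_graph(inst$sites, inst$observations)
    ph <- phase_graph(g)
    asg <- ph$assignment
    for (b in unique(asg$block_id)) {
      rows <- asg[asg$block_id == b, ]
      s <- vapply(seq_len(nrow(rows)), function(r) {
        score_path <- ph$table$score[[rows$site_index[r]]]
        score_path[rows$phase1_allele[r], rows$phase2_allele[r]]
      }, integer(1))
      expect_true(all(diff(s) >= 0))
    }
  }
})

test_that("relabeling reads leaves every score unchanged", {
  fx <- we_fixture()
  relabeled <- fx$observations
  relabeled$read_id <- paste0("x_", relabeled$read_id)
  t1 <- recurrence_step(we_graph(), init_scores(we_graph(), 1L), 2L)
  g2 <- build_graph(fx$sites, relabeled)
  t2 <- recurrence_step(g2, init_scores(g2, 1L), 2L)
  expect_equal(t1$score, t2$score)
})

test_that("the DP matches exhaustive enumeration on random small instances", {
  for (seed in 1:100) {
    inst <- random_instance(seed)
    g <- build_graph(inst$sites, inst$observations)
    expect_equal(phase_graph(g)$best_score, brute_force_phase(g),
                 info = paste("seed", seed))
  }
})

test_that("the exhaustive oracle rejects oversized instances", {
  inst <- random_instance(31, max_sites = 5, max_alleles = 3)
  g <- build_graph(inst$sites, inst$observations)
  expect_error(brute_force_phase(g, max_sequences = 2), "too large")
})

test_that("identical graphs phase identically (determinism)", {
  inst <- random_instance(41)
  g1 <- build_graph(inst$sites, inst$observations)
  g2 <- build_graph(inst$sites, inst$observations[sample(nrow(inst$observations)), ])
  expect_equal(phase_graph(g1)$assignment, phase_graph(g2)$assignment)
})

test_that("the DP cell dump has one row per materialized cell", {
  g <- we_graph()
  ph <- phase_graph(g)
  cells <- tidy(ph$table)
  expect_equal(nrow(cells), 8)  # 2 sites x 2x2 ordered pairs
  expect_equal(sum(!is.na(cells$score)), 7)  # init lower triangle absent
})
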