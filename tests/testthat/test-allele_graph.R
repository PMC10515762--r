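test_that("the canonical two-site fixture builds the expected graph", {
  g <- we_graph()
  expect_s3_class(g, "phasing_graph")
  expect_equal(nrow(g$vertices), 4)
  expect_equal(nrow(g$edges), 4)
  span_sizes <- setNames(g$edges$n_span,
                         paste(g$edges$from_allele, g$edges$to_allele, sep = ">"))
  expect_equal(span_sizes[["1>1"]], 3)  # r1, r2, r3
  expect_equal(span_sizes[["1>2"]], 2)  # r4, r5
  expect_equal(span_sizes[["2>1"]], 1)  # r6
  expect_equal(span_sizes[["2>2"]], 5)  # r7-r11
  expect_equal(g$vertices$n_support, c(5L, 6L, 4L, 7L))
  expect_false(any(g$vertices$no_incoming))
})

test_that("duplicate observations are rejected with the read named", {
  fx <- we_fixture()
  dup <- rbind(fx$observations, fx$observations[3, ])
  expect_error(build_graph(fx$sites, dup), "read3")
})

test_that("an empty site list gives an empty graph, not an error", {
  g <- build_graph(tibble::tibble(contig = character(), position = integer(),
                                  alleles = list()),
                   tibble::tibble(read_id = character(), site_index = integer(),
                                  allele_index = integer()))
  expect_equal(nrow(g$vertices), 0)
  expect_equal(nrow(g$edges), 0)
})

test_that("a single site yields vertices but no edges", {
  sites <- tibble::tibble(contig = "c", position = 10L, alleles = list(c("A", "G")))
  obs <- tibble::tibble(read_id = sprintf("r%d", 1:4), site_index = 1L,
                        allele_index = c(1L, 1L, 2L, 2L))
  g <- build_graph(sites, obs)
  expect_equal(nrow(g$vertices), 2)
  expect_equal(nrow(g$edges), 0)
  expect_equal(g$vertices$n_support, c(2L, 2L))
})

test_that("a read starting at the second site is fresh there and spans no edge", {
  fx <- we_fixture()
  fx$observations <- dplyr::bind_rows(
    fx$observations,
    tibble::tibble(read_id = "read12", site_index = 2L, allele_index = 1L))
  g <- build_graph(fx$sites, fx$observations)
  expect_true("read12" %in% g$fresh[["2:1"]])
  span_sizes <- setNames(g$edges$n_span,
                         paste(g$edges$from_allele, g$edges$to_allele, sep = ">"))
  expect_equal(unname(span_sizes[c("1>1", "1>2", "2>1", "2>2")]),
               c(3L, 2L, 1L, 5L))
})

test_that("graph construction is independent of observation order", {
  fx <- we_fixture()
  g1 <- build_graph(fx$sites, fx$observations)
  set.seed(1)
  for (rep in 1:5) {
    g2 <- build_graph(fx$sites,
                      fx$observations[sample(nrow(fx$observations)), ])
    expect_equal(g2$edges, g1$edges)
    expect_equal(g2$support, g1$support)
    expect_equal(g2$fresh, g1$fresh)
  }
})

test_that("support decomposes into incoming spans, fresh reads, and site-1 reads", {
  orc <- function(x) if (is.null(x)) character(0) else x
  # with full observation coverage the decomposition is exact; a read with a
  # dropout at the previous site supports the vertex without riding any edge
  for (seed in c(2, 3, 5, 8)) {
    inst <- random_instance(seed, keep_prob = 1)
    g <- build_graph(inst$sites, inst$observations)
    for (r in seq_len(nrow(g$vertices))) {
      n <- g$vertices$site_index[r]
      i <- g$vertices$allele_index[r]
      sup <- orc(g$support[[paste(n, i, sep = ":")]])
      inc <- g$edges[g$edges$site_index == n & g$edges$to_allele == i, ]
      from_edges <- orc(unique(unlist(inc$span)))
      fresh <- orc(g$fresh[[paste(n, i, sep = ":")]])
      expect_setequal(sup, union(from_edges, fresh))
      # fresh reads never ride an incoming edge
      expect_length(intersect(fresh, from_edges), 0)
    }
  }
  # under dropouts the union can only under-cover the support set
  for (seed in c(2, 3)) {
    inst <- random_instance(seed, keep_prob = 0.7)
    g <- build_graph(inst$sites, inst$observations)
    for (r in seq_len(nrow(g$vertices))) {
      n <- g$vertices$site_index[r]
      i <- g$vertices$allele_index[r]
      sup <- orc(g$support[[paste(n, i, sep = ":")]])
      inc <- g$edges[g$edges$site_index == n & g$edges$to_allele == i, ]
      parts <- union(orc(unique(unlist(inc$span))),
                     orc(g$fresh[[paste(n, i, sep = ":")]]))
      expect_true(all(parts %in% sup))
    }
  }
})

test_that("vertices unreachable by any edge are flagged for the artificial-edge rule", {
  sites <- tibble::tibble(contig = "c", position = c(1L, 2L),
                          alleles = list(c("A", "G"), c("C", "T")))
  obs <- tibble::tibble(
    read_id = c("r1", "r2", "r1", "r3"),
    site_index = c(1L, 1L, 2L, 2L),
    allele_index = c(1L, 2L, 1L, 2L))
  # allele 2 at site 2 carried only by r3, which starts at site 2
  g <- build_graph(sites, obs)
  flagged <- g$vertices[g$vertices$no_incoming, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$site_index, 2L)
  expect_equal(flagged$allele_index, 2L)
})

test_that("the debug JSON dump round-trips vertex and edge counts", {
  g <- we_graph()
  parsed <- jsonlite::fromJSON(graph_to_json(g))
  expect_equal(nrow(parsed$vertices), 4)
  expect_equal(nrow(parsed$edges), 4)
})
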