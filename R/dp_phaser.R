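#' @section Scoring model:
#' For a pair of alleles (i, j) at site n — i carrying phase-1, j carrying
#' phase-2, the diagonal i = j allowed so effectively-homozygous sites pass
#' through — the best score S(n, i, j) counts the reads consistent with the
#' best phasing ending in that pair. At the first site of a block the score
#' is the size of the union of the two alleles' support sets. At later
#' sites it extends the best predecessor pair (k, l) connected by edges
#' k->i and l->j, adding the reads spanning those edges plus the "fresh"
#' reads that start after site n-1. All arithmetic is exact integer set
#' counting; no floating point enters the DP.
#' @name dp_scoring
#' @keywords internal
NULL

n_alleles_at <- function(graph, site) {
  length(graph$sites$alleles[[site]])
}

# predecessor alleles of vertex (site, i): sources of real incoming edges,
# or every allele at site-1 when none exist (artificial edges, empty spans)
predecessors <- function(graph, site, i) {
  e <- graph$edges
  k <- e$from_allele[e$site_index == site & e$to_allele == i]
  if (length(k)) {
    list(alleles = sort(k), artificial = FALSE)
  } else {
    list(alleles = seq_len(n_alleles_at(graph, site - 1L)), artificial = TRUE)
  }
}

new_score_table <- function() {
  structure(list(score = list(), bp_i = list(), bp_j = list(),
                 block_starts = integer()),
            class = "score_table")
}

#' Initialize phasing scores at the first site of a block
#'
#' Sets S(site, i, j) to the number of distinct reads supporting allele i
#' or allele j there, for every pair with i <= j (the diagonal i = j
#' included). Because the score is symmetric in (i, j) and phase labels are
#' arbitrary within a block, only the upper triangle is materialized at a
#' block start — the convention the recursion's predecessor enumeration
#' relies on; every ordered pair is materialized at later sites. Called at
#' the first site of an interval and whenever phasing cannot be extended
#' from the previous site (reinitialization).
#'
#' @param graph a `phasing_graph`.
#' @param site site index at which to (re)initialize.
#' @param table an existing `score_table` to extend, or `NULL` to start one.
#' @return a `score_table` with cells for `site` and `site` recorded as a
#'   block start.
#' @export
init_scores <- function(graph, site, table = NULL) {
  if (is.null(table)) table <- new_score_table()
  a <- n_alleles_at(graph, site)
  s <- matrix(NA_integer_, a, a)
  for (i in seq_len(a)) {
    for (j in i:a) {
      s[i, j] <- length(unique(c(graph_support(graph, site, i),
                                 graph_support(graph, site, j))))
    }
  }
  table$score[[site]] <- s
  table$bp_i[[site]] <- matrix(NA_integer_, a, a)
  table$bp_j[[site]] <- matrix(NA_integer_, a, a)
  table$block_starts <- sort(unique(c(table$block_starts, site)))
  table
}

#' One recursion step of the phasing dynamic program
#'
#' Computes S(site, i, j) for every ordered allele pair at `site` from the
#' scores at `site - 1`. A vertex with no incoming edge is connected to all
#' previous-site alleles by artificial edges that contribute empty read
#' sets; if no vertex at `site` has a real incoming edge the phasing cannot
#' be extended and scores are reinitialized, starting a new phase block.
#' Ties in the max are broken toward the smallest predecessor pair (k, l).
#'
#' @param graph a `phasing_graph`.
#' @param table a `score_table` holding scores for `site - 1`.
#' @param site site index (> block start).
#' @return the updated `score_table`.
#' @export
recurrence_step <- function(graph, table, site) {
  stopifnot(site >= 2, !is.null(table$score[[site - 1L]]))
  v <- graph$vertices
  at_site <- v[v$site_index == site, ]
  if (all(at_site$no_incoming)) {
    return(init_scores(graph, site, table))
  }
  a <- n_alleles_at(graph, site)
  prev_s <- table$score[[site - 1L]]
  s <- matrix(0L, a, a)
  bi <- matrix(NA_integer_, a, a)
  bj <- matrix(NA_integer_, a, a)
  preds <- lapply(seq_len(a), function(i) predecessors(graph, site, i))
  spans <- lapply(seq_len(a), function(i) {
    if (preds[[i]]$artificial) {
      rep(list(character(0)), n_alleles_at(graph, site - 1L))
    } else {
      lapply(seq_len(n_alleles_at(graph, site - 1L)), function(k) {
        graph_span(graph, site, k, i)
      })
    }
  })
  for (i in seq_len(a)) {
    fr_i <- graph_fresh(graph, site, i)
    for (j in seq_len(a)) {
      fr_j <- graph_fresh(graph, site, j)
      best <- -1L
      for (k in preds[[i]]$alleles) {
        for (l in preds[[j]]$alleles) {
          if (is.na(prev_s[k, l])) next  # unmaterialized triangle at a block start
          gain <- length(unique(c(spans[[i]][[k]], spans[[j]][[l]], fr_i, fr_j)))
          cand <- prev_s[k, l] + gain
          if (cand > best) {
            best <- cand
            bi[i, j] <- k
            bj[i, j] <- l
          }
        }
      }
      # no stored predecessor combo reaches this ordered cell; its mirror
      # cell is always reachable, so leave it unmaterialized
      s[i, j] <- if (best < 0L) NA_integer_ else best
    }
  }
  table$score[[site]] <- s
  table$bp_i[[site]] <- bi
  table$bp_j[[site]] <- bj
  table
}

score_at <- function(table, site, i, j) table$score[[site]][i, j]

block_ranges <- function(table) {
  starts <- table$block_starts
  n <- length(table$score)
  tibble::tibble(block_id = seq_along(starts),
                 first_site = starts,
                 last_site = c(starts[-1] - 1L, n))
}

#' Backtrack phase assignments from a completed score table
#'
#' Per block, selects the maximal final-site cell (ties toward the smallest
#' (phase-1 allele, phase-2 allele) pair) and follows backpointers, fixing
#' which allele carries phase-1 and which phase-2 at every site.
#'
#' @param table a completed `score_table`.
#' @return tibble with columns `site_index`, `phase1_allele`,
#'   `phase2_allele`, `block_id`.
#' @export
backtrack <- function(table) {
  empty <- tibble::tibble(site_index = integer(), phase1_allele = integer(),
                          phase2_allele = integer(), block_id = integer())
  if (length(table$score) == 0) return(empty)
  blocks <- block_ranges(table)
  out <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    last <- blocks$last_site[b]
    s <- table$score[[last]]
    best <- -1L; bi <- NA_integer_; bj <- NA_integer_
    for (i in seq_len(nrow(s))) {
      for (j in seq_len(ncol(s))) {
        if (!is.na(s[i, j]) && s[i, j] > best) { best <- s[i, j]; bi <- i; bj <- j }
      }
    }
    sites <- seq(blocks$first_site[b], last)
    p1 <- integer(length(sites)); p2 <- integer(length(sites))
    i <- bi; j <- bj
    for (pos in rev(seq_along(sites))) {
      n <- sites[pos]
      p1[pos] <- i; p2[pos] <- j
      if (pos > 1) {
        k <- table$bp_i[[n]][i, j]; l <- table$bp_j[[n]][i, j]
        i <- k; j <- l
      }
    }
    out[[b]] <- tibble::tibble(site_index = sites, phase1_allele = p1,
                               phase2_allele = p2, block_id = blocks$block_id[b])
  }
  dplyr::bind_rows(out)
}

#' Phase an allele graph
#'
#' Runs the full dynamic program: scores are initialized at the first site,
#' extended site by site through the recursion (reinitializing where no
#' edge reaches a site, which splits the interval into phase blocks), and
#' backtracked from each block's best final-site score.
#'
#' @param graph a `phasing_graph`.
#' @return object of class `hap_phase`: list with `assignment` (tibble:
#'   `site_index`, `phase1_allele`, `phase2_allele`, `block_id`), `blocks`
#'   (tibble: `block_id`, `first_site`, `last_site`, `anchor_position` —
#'   1-based position of the block's first site, the phase-set identifier),
#'   `block_scores` (best score per block), `best_score` (their sum) and
#'   the `table` itself.
#' @export
phase_graph <- function(graph) {
  n <- nrow(graph$sites)
  if (n == 0) {
    res <- list(assignment = backtrack(new_score_table()),
                blocks = tibble::tibble(block_id = integer(), first_site = integer(),
                                        last_site = integer(), anchor_position = integer()),
                block_scores = integer(), best_score = 0L,
                table = new_score_table())
    class(res) <- "hap_phase"
    return(res)
  }
  table <- init_scores(graph, 1L)
  for (site in seq_len(n)[-1]) {
    table <- recurrence_step(graph, table, site)
  }
  assignment <- backtrack(table)
  blocks <- block_ranges(table)
  blocks$anchor_position <- graph$sites$position[blocks$first_site] + 1L
  blocks$block_scores <- vapply(seq_len(nrow(blocks)), function(b) {
    max(table$score[[blocks$last_site[b]]], na.rm = TRUE)
  }, integer(1))
  block_scores <- blocks$block_scores
  blocks$block_scores <- NULL
  res <- list(assignment = assignment, blocks = blocks,
              block_scores = block_scores,
              best_score = sum(block_scores), table = table)
  class(res) <- "hap_phase"
  res
}

#' @export
print.hap_phase <- function(x, ...) {
  cat("<hap_phase> ", nrow(x$assignment), " sites in ", nrow(x$blocks),
      " block(s); best score ", x$best_score, "\n", sep = "")
  invisible(x)
}

#' @rdname phase_graph
#' @param x,object a `hap_phase`.
#' @param ... unused.
#' @export
tidy.hap_phase <- function(x, ...) {
  dplyr::left_join(x$assignment,
                   x$blocks[, c("block_id", "anchor_position")],
                   by = "block_id")
}

#' @rdname phase_graph
#' @export
glance.hap_phase <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x$assignment), n_blocks = nrow(x$blocks),
                 best_score = x$best_score)
}

#' Dump all DP cells as a tibble (debug TSV shape)
#'
#' @param x a `score_table`.
#' @param ... unused.
#' @return tibble with one row per cell: `site_index`, `i`, `j`, `score`,
#'   `bp_i`, `bp_j`.
#' @export
tidy.score_table <- function(x, ...) {
  rows <- lapply(seq_along(x$score), function(n) {
    s <- x$score[[n]]
    if (is.null(s)) return(NULL)
    g <- expand.grid(i = seq_len(nrow(s)), j = seq_len(ncol(s)))
    tibble::tibble(site_index = n, i = g$i, j = g$j,
                   score = s[cbind(g$i, g$j)],
                   bp_i = x$bp_i[[n]][cbind(g$i, g$j)],
                   bp_j = x$bp_j[[n]][cbind(g$i, g$j)])
  })
  dplyr::bind_rows(rows)
}

#' Exhaustive phasing oracle
#'
#' Enumerates every sequence of ordered allele pairs over the graph's sites
#' — the same pair space, edge constraints, artificial-edge rule and
#' reinitialization boundaries as the dynamic program — and accumulates the
#' identical per-transition read counts, returning the maximum achievable
#' total score. Intended as an independent check of [phase_graph()] on
#' small instances only.
#'
#' @param graph a `phasing_graph` with few sites and alleles.
#' @param max_sequences refuse instances whose enumeration would exceed
#'   this many pair sequences per block.
#' @return the best total score (integer, summed over blocks).
#' @export
brute_force_phase <- function(graph, max_sequences = 2e6) {
  n <- nrow(graph$sites)
  if (n == 0) return(0L)
  # block boundaries are structural: sites where no vertex has a real
  # incoming edge restart the scoring
  v <- graph$vertices
  is_start <- vapply(seq_len(n), function(s) {
    s == 1L || all(v$no_incoming[v$site_index == s])
  }, logical(1))
  starts <- which(is_start)
  ends <- c(starts[-1] - 1L, n)
  total <- 0L
  for (b in seq_along(starts)) {
    sites <- seq(starts[b], ends[b])
    a <- vapply(sites, function(s) n_alleles_at(graph, s), integer(1))
    n_pairs <- a^2
    if (prod(n_pairs) > max_sequences) {
      stop("instance too large for exhaustive enumeration")
    }
    pair_i <- lapply(a, function(m) rep(seq_len(m), times = m))
    pair_j <- lapply(a, function(m) rep(seq_len(m), each = m))
    # init vector for first site of block
    s1 <- sites[1]
    init <- vapply(seq_len(n_pairs[1]), function(p) {
      length(unique(c(graph_support(graph, s1, pair_i[[1]][p]),
                      graph_support(graph, s1, pair_j[[1]][p]))))
    }, integer(1))
    if (length(sites) == 1) {
      total <- total + max(init)
      next
    }
    trans <- vector("list", length(sites))
    for (t in seq_along(sites)[-1]) {
      s <- sites[t]
      m <- matrix(-Inf, n_pairs[t - 1], n_pairs[t])
      for (q in seq_len(n_pairs[t])) {
        i <- pair_i[[t]][q]; j <- pair_j[[t]][q]
        pi <- predecessors(graph, s, i); pj <- predecessors(graph, s, j)
        fr <- unique(c(graph_fresh(graph, s, i), graph_fresh(graph, s, j)))
        for (p in seq_len(n_pairs[t - 1])) {
          k <- pair_i[[t - 1]][p]; l <- pair_j[[t - 1]][p]
          if (!(k %in% pi$alleles) || !(l %in% pj$alleles)) next
          sk <- if (pi$artificial) character(0) else graph_span(graph, s, k, i)
          sl <- if (pj$artificial) character(0) else graph_span(graph, s, l, j)
          m[p, q] <- length(unique(c(sk, sl, fr)))
        }
      }
      trans[[t]] <- m
    }
    seqs <- as.matrix(expand.grid(lapply(n_pairs, seq_len)))
    score <- init[seqs[, 1]]
    for (t in seq_along(sites)[-1]) {
      score <- score + trans[[t]][cbind(seqs[, t - 1], seqs[, t])]
    }
    total <- total + as.integer(max(score[is.finite(score)]))
  }
  total
}
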