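#' Candidate heterozygous sites
#'
#' Builds a validated tibble of candidate heterozygous sites for one
#' interval. Each site carries the genomic position, an ordered allele list
#' (reference allele first, then alternates) and its rank within the
#' interval (`site_index`), which is what the phasing dynamic program walks
#' over; base-pair positions are only used for chunking and phase-set
#' anchors.
#'
#' @param df data frame with columns `contig` (character), `position`
#'   (0-based integer) and `alleles` (list-column of character vectors,
#'   reference allele first).
#' @return tibble with columns `contig`, `position`, `site_index`,
#'   `alleles`, sorted by position.
#' @export
candidate_sites <- function(df) {
  stopifnot(is.data.frame(df), all(c("contig", "position", "alleles") %in% names(df)))
  out <- tibble::as_tibble(df)
  out <- dplyr::arrange(out, .data$position)
  if (anyDuplicated(out$position)) {
    stop("candidate sites must have strictly increasing positions")
  }
  bad <- which(vapply(out$alleles, function(a) {
    length(a) == 0 || anyDuplicated(a) > 0
  }, logical(1)))
  if (length(bad)) {
    stop("site at position ", out$position[bad[1]],
         " has an empty or duplicated allele list")
  }
  out$site_index <- seq_len(nrow(out))
  out[, c("contig", "position", "site_index", "alleles")]
}

#' Read-allele observations
#'
#' One row per (read, site) pair recording which allele the read supports
#' there. `read_start_site`/`read_end_site` are the first and last site
#' index the read overlaps; if missing they are filled from the read's
#' observed sites. A read observed at site n but starting after site n-1 is
#' a "fresh" read at n and enters the recursion score separately from the
#' edge read sets.
#'
#' @param df data frame with columns `read_id`, `site_index`,
#'   `allele_index` and optionally `read_start_site`, `read_end_site`.
#' @return validated tibble.
#' @export
read_observations <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("read_id", "site_index", "allele_index") %in% names(df)))
  out <- tibble::as_tibble(df)
  dup <- duplicated(out[, c("read_id", "site_index")])
  if (any(dup)) {
    stop("duplicate observation for read '", out$read_id[which(dup)[1]],
         "' at site ", out$site_index[which(dup)[1]])
  }
  if (!"read_start_site" %in% names(out) || !"read_end_site" %in% names(out)) {
    rng <- out |>
      dplyr::group_by(.data$read_id) |>
      dplyr::summarise(read_start_site = min(.data$site_index),
                       read_end_site = max(.data$site_index), .groups = "drop")
    out$read_start_site <- NULL
    out$read_end_site <- NULL
    out <- dplyr::left_join(out, rng, by = "read_id")
  }
  out[, c("read_id", "site_index", "allele_index",
          "read_start_site", "read_end_site")]
}

vkey <- function(site, allele) paste(site, allele, sep = ":")
ekey <- function(site, k, i) paste(site, k, i, sep = ":")

#' Build the per-interval allele graph
#'
#' Vertices are alleles at candidate heterozygous sites; an edge connects an
#' allele at site n-1 to an allele at site n when at least one read is
#' observed at both. The graph also records, per vertex, the full read
#' support set and the set of "fresh" reads (reads starting after the
#' previous site), which the phasing recursion adds to transition scores.
#' Vertices at site n > 1 with no incoming edge are flagged so the phaser
#' can apply the artificial-edge rule.
#'
#' @param sites tibble from [candidate_sites()].
#' @param observations tibble from [read_observations()]; `allele_index`
#'   must be valid for each site.
#' @return object of class `phasing_graph`: a list with elements `sites`,
#'   `vertices` (tibble), `edges` (tibble with list-column `span` of read
#'   ids), `support` and `fresh` (named lists keyed "site:allele").
#' @export
build_graph <- function(sites, observations) {
  sites <- candidate_sites(sites)
  if (nrow(sites) == 0) {
    g <- list(sites = sites,
              vertices = tibble::tibble(site_index = integer(), allele_index = integer(),
                                        allele = character(), n_support = integer(),
                                        no_incoming = logical()),
              edges = tibble::tibble(site_index = integer(), from_allele = integer(),
                                     to_allele = integer(), span = list(),
                                     n_span = integer()),
              support = list(), fresh = list())
    class(g) <- "phasing_graph"
    return(g)
  }
  obs <- read_observations(observations)
  n_alleles <- vapply(sites$alleles, length, integer(1))
  ok <- obs$site_index >= 1 & obs$site_index <= nrow(sites) &
    obs$allele_index >= 1 & obs$allele_index <= n_alleles[obs$site_index]
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("observation for read '", obs$read_id[bad],
         "' references an invalid site/allele (site ", obs$site_index[bad],
         ", allele ", obs$allele_index[bad], ")")
  }

  vertices <- sites |>
    dplyr::mutate(allele_list = .data$alleles) |>
    tidyr::unnest_longer(col = "allele_list", values_to = "allele",
                         indices_to = "allele_index") |>
    dplyr::select("site_index", "allele_index", "allele")

  support <- split(obs$read_id, vkey(obs$site_index, obs$allele_index))
  support <- lapply(support, sort)

  # fresh reads: observed at (n, i) with read_start_site > n - 1
  fresh_obs <- obs[obs$read_start_site > obs$site_index - 1L, ]
  fresh <- split(fresh_obs$read_id, vkey(fresh_obs$site_index, fresh_obs$allele_index))
  fresh <- lapply(fresh, sort)

  # edges between consecutive site indices: reads observed at both
  prev <- obs |>
    dplyr::transmute(read_id = .data$read_id,
                     site_index = .data$site_index + 1L,
                     from_allele = .data$allele_index)
  pairs <- dplyr::inner_join(prev, obs, by = c("read_id", "site_index"))
  edges <- pairs |>
    dplyr::group_by(.data$site_index, .data$from_allele,
                    to_allele = .data$allele_index) |>
    dplyr::summarise(span = list(sort(.data$read_id)), .groups = "drop") |>
    dplyr::mutate(n_span = lengths(.data$span)) |>
    dplyr::arrange(.data$site_index, .data$from_allele, .data$to_allele)

  vertices$n_support <- vapply(vkey(vertices$site_index, vertices$allele_index),
                               function(k) length(support[[k]]), integer(1),
                               USE.NAMES = FALSE)
  has_in <- vkey(edges$site_index, edges$to_allele)
  vertices$no_incoming <- vertices$site_index > 1L &
    !(vkey(vertices$site_index, vertices$allele_index) %in% has_in)

  g <- list(sites = sites, vertices = vertices, edges = edges,
            support = support, fresh = fresh)
  class(g) <- "phasing_graph"
  g
}

graph_support <- function(graph, site, allele) {
  graph$support[[vkey(site, allele)]] %||% character(0)
}

graph_fresh <- function(graph, site, allele) {
  graph$fresh[[vkey(site, allele)]] %||% character(0)
}

graph_span <- function(graph, site, from, to) {
  hit <- graph$edges$site_index == site &
    graph$edges$from_allele == from & graph$edges$to_allele == to
  if (any(hit)) graph$edges$span[[which(hit)[1]]] else character(0)
}

#' @export
print.phasing_graph <- function(x, ...) {
  cat("<phasing_graph> ", nrow(x$sites), " sites, ", nrow(x$vertices),
      " vertices, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Tidy an allele graph
#'
#' @param x a `phasing_graph`.
#' @param ... unused.
#' @return tibble with one row per vertex (`site_index`, `allele_index`,
#'   `allele`, `n_support`, `n_fresh`, `no_incoming`).
#' @importFrom generics tidy
#' @export
tidy.phasing_graph <- function(x, ...) {
  v <- x$vertices
  v$n_fresh <- vapply(seq_len(nrow(v)), function(r) {
    length(graph_fresh(x, v$site_index[r], v$allele_index[r]))
  }, integer(1))
  v
}

#' Plot an allele graph
#'
#' Vertices are laid out by site index (x) and allele index (y); edge width
#' scales with the number of reads spanning the two alleles.
#'
#' @param object a `phasing_graph`.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.phasing_graph <- function(object, ...) {
  v <- object$vertices
  e <- object$edges
  p <- ggplot2::ggplot()
  if (nrow(e)) {
    seg <- dplyr::mutate(e,
                         x = .data$site_index - 1L, xend = .data$site_index,
                         y = .data$from_allele, yend = .data$to_allele)
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$n_span),
      colour = "grey55") +
      ggplot2::scale_linewidth(range = c(0.3, 2), name = "reads")
  }
  p +
    ggplot2::geom_point(data = v,
                        ggplot2::aes(x = .data$site_index, y = .data$allele_index,
                                     size = .data$n_support)) +
    ggplot2::geom_text(data = v,
                       ggplot2::aes(x = .data$site_index, y = .data$allele_index,
                                    label = .data$allele), vjust = -1.2) +
    ggplot2::scale_size(range = c(1.5, 5), name = "support") +
    ggplot2::labs(x = "site index", y = "allele index") +
    ggplot2::theme_minimal()
}

#' Serialize a graph to a debug JSON string
#'
#' @param graph a `phasing_graph`.
#' @return a JSON string listing vertices, edges and read sets.
#' @export
graph_to_json <- function(graph) {
  jsonlite::toJSON(list(
    sites = graph$sites[, c("contig", "position", "site_index")],
    vertices = graph$vertices,
    edges = dplyr::mutate(graph$edges,
                          span = vapply(.data$span, paste, character(1), collapse = ",")),
    support = lapply(graph$support, identity),
    fresh = lapply(graph$fresh, identity)
  ), auto_unbox = TRUE, pretty = TRUE)
}
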