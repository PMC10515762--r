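#' Assign haplotags to reads by majority vote over phased alleles
#'
#' Each read votes with the alleles it overlaps: an observation whose
#' allele carries phase-1 at that site is a phase-1 vote, likewise for
#' phase-2; an observation of an allele assigned to neither slot (e.g. a
#' third allele) contributes nothing. A strict majority sets the haplotag
#' (1 or 2); a tie or no votes leaves the read untagged (0). Because phase
#' labels are only comparable within a phase block, a read votes only
#' inside the single block holding the majority of its observations (ties
#' toward the earlier block).
#'
#' @param graph a `phasing_graph`.
#' @param assignment tibble from [backtrack()] / `phase_graph()$assignment`.
#' @param blocks tibble from `phase_graph()$blocks`.
#' @param read_ids optional character vector of additional reads (e.g.
#'   reads overlapping no candidate site) to report as untagged.
#' @return tibble of class `hap_tags` with columns `read_id`, `tag` (1, 2
#'   or 0), `phase_set` (block anchor position, NA when untagged),
#'   `votes_phase1`, `votes_phase2`; one row per read.
#' @export
assign_read_haplotags <- function(graph, assignment, blocks, read_ids = NULL) {
  obs_reads <- unique(unlist(graph$support, use.names = FALSE))
  extra <- setdiff(read_ids %||% character(0), obs_reads)
  if (nrow(assignment) == 0 || length(obs_reads) == 0) {
    return(hap_tags(tibble::tibble(
      read_id = sort(c(obs_reads, extra)), tag = 0L, phase_set = NA_integer_,
      votes_phase1 = 0L, votes_phase2 = 0L)))
  }
  # one row per (vertex, read): which phase slot the observed allele holds
  sup <- graph$support
  keys <- names(sup)
  obs <- tibble::tibble(
    site_index = as.integer(sub(":.*", "", keys)),
    allele_index = as.integer(sub(".*:", "", keys)),
    read_id = unname(sup))
  obs <- tidyr::unnest_longer(obs, col = "read_id")
  obs <- dplyr::left_join(obs, assignment, by = "site_index")
  obs$vote1 <- obs$allele_index == obs$phase1_allele
  obs$vote2 <- obs$allele_index == obs$phase2_allele
  # a site where both slots hold the same allele gives no discriminating vote
  both <- obs$vote1 & obs$vote2
  obs$vote1[both] <- FALSE
  obs$vote2[both] <- FALSE

  per_block <- obs |>
    dplyr::group_by(.data$read_id, .data$block_id) |>
    dplyr::summarise(n_obs = dplyr::n(),
                     votes_phase1 = sum(.data$vote1),
                     votes_phase2 = sum(.data$vote2), .groups = "drop")
  home <- per_block |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(dplyr::desc(.data$n_obs), .data$block_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  home$tag <- dplyr::case_when(
    home$votes_phase1 > home$votes_phase2 ~ 1L,
    home$votes_phase2 > home$votes_phase1 ~ 2L,
    TRUE ~ 0L)
  home <- dplyr::left_join(home,
                           blocks[, c("block_id", "anchor_position")],
                           by = "block_id")
  home$phase_set <- ifelse(home$tag == 0L, NA_integer_, home$anchor_position)
  out <- home[, c("read_id", "tag", "phase_set", "votes_phase1", "votes_phase2")]
  if (length(extra)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      read_id = extra, tag = 0L, phase_set = NA_integer_,
      votes_phase1 = 0L, votes_phase2 = 0L))
  }
  hap_tags(dplyr::arrange(out, .data$read_id))
}

hap_tags <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("hap_tags", class(df))
  df
}

#' Plot haplotag composition
#'
#' Bar chart of reads per haplotag, split by phase set.
#'
#' @param object a `hap_tags` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hap_tags <- function(object, ...) {
  d <- dplyr::mutate(object,
                     tag = factor(.data$tag, levels = c(1, 2, 0),
                                  labels = c("haplotag 1", "haplotag 2", "untagged")),
                     phase_set = ifelse(is.na(.data$phase_set), "none",
                                        as.character(.data$phase_set)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phase_set, fill = .data$tag)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = "phase set (block anchor)", y = "reads", fill = NULL) +
    ggplot2::theme_minimal()
}
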