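#' Venn-partition overlap counts of interaction call sets
#'
#' Partitions the union of up to three per-query strain sets into the
#' disjoint membership regions of the Venn diagram and counts each region.
#' With more than three queries a pairwise overlap table is returned
#' instead (with a message).
#'
#' @param call_sets named list mapping query identifiers to character
#'   vectors of called strains.
#' @return For <= 3 queries: a data frame `region` (query names joined by
#'   `&`), `count`, one row per nonempty-signature region (all `2^k - 1`
#'   regions listed), with per-query totals in the attribute
#'   `query_totals`.  For > 3 queries: a data frame `query_a`, `query_b`,
#'   `count` of pairwise intersections.
#' @export
overlap_counts <- function(call_sets) {
  stopifnot(length(call_sets) >= 1, !is.null(names(call_sets)))
  call_sets <- lapply(call_sets, unique)
  qs <- names(call_sets)
  if (length(qs) > 3) {
    message("more than 3 queries; emitting pairwise overlaps")
    pairs <- utils::combn(qs, 2)
    return(data.frame(
      query_a = pairs[1, ], query_b = pairs[2, ],
      count = apply(pairs, 2, function(p)
        length(intersect(call_sets[[p[1]]], call_sets[[p[2]]]))),
      stringsAsFactors = FALSE))
  }
  universe <- unique(unlist(call_sets))
  member <- vapply(call_sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, qs))
  k <- length(qs)
  sigs <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  out <- data.frame(
    region = apply(sigs, 1, function(s) paste(qs[unlist(s)], collapse = "&")),
    count = apply(sigs, 1, function(s)
      sum(apply(member, 1, function(m) all(m == unlist(s))))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "query_totals") <- vapply(call_sets, length, 0L)
  out
}

#' Per-query quantiles of the induction fitness response
#'
#' Summarizes the distribution of normalized colony-size change (Wij) per
#' query at the 5, 25, 50, 75 and 95% quantiles — the table behind the
#' per-screen fitness-change distribution plots.
#'
#' @param records interaction records (the `records` element of an
#'   [score_screen()] fit, or any data frame with `query_id`, `wij` and
#'   optionally a logical `usable` column).
#' @param probs quantile levels.
#' @return A data frame with one row per query and one column per
#'   quantile.
#' @export
fitness_distribution_summary <- function(records,
                                         probs = c(.05, .25, .5, .75, .95)) {
  if (!is.null(records$usable)) records <- records[records$usable, ]
  out <- do.call(rbind, lapply(split(records, records$query_id), function(g)
    data.frame(query_id = g$query_id[1],
               as.list(stats::setNames(
                 stats::quantile(g$wij, probs, na.rm = TRUE),
                 paste0("q", probs * 100))),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
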