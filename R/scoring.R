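#' Median-ratio W statistics for one query
#'
#' Computes, for every strain of a screen, the three median-ratio fitness
#' statistics of the multiplicative interaction model:
#'
#' * `wij` — observed induction effect on strain x: median area of its
#'   retained induced colonies over the median of its retained uninduced
#'   colonies, for query `query`.
#' * `wi` — expected (screen-wide) induction effect of the query: median of
#'   all retained colonies on the induced plates over the median of all on
#'   the uninduced plates.
#' * `wj` — strain x's baseline fitness effect: median of its retained
#'   colonies on the uninduced plates of *all* queries over the median of
#'   all retained colonies on the uninduced plates of all queries.
#'
#' Medians are missing-aware and use the usual even-count convention (mean
#' of the two central order statistics), so every statistic is reproducible
#' bit for bit from the retained areas.
#'
#' @param observations observation table from [collect_observations()] with
#'   a logical `kept` column (`FALSE` = excluded by filtering); rows with
#'   `kept = NA` or missing `area` are ignored.
#' @param query query identifier to score.
#' @return A data frame with one row per strain: `strain_id`, `wij`, `wi`,
#'   `wj`, `usable` (`FALSE` when a denominator median is 0 or a condition
#'   has no retained colonies for the strain).
#' @export
compute_w_triples <- function(observations, query) {
  if (!query %in% observations$query_id)
    stop("query '", query, "' absent from observations", call. = FALSE)
  if (is.null(observations$kept)) observations$kept <- TRUE
  obs <- observations[!is.na(observations$area) &
                        observations$kept %in% TRUE, ]
  oq <- obs[obs$query_id == query, ]
  ind <- oq[oq$condition == "induced", ]
  unind <- oq[oq$condition == "uninduced", ]
  unind_all <- obs[obs$condition == "uninduced", ]

  strains <- sort(unique(oq$strain_id))
  med_ind <- med_by(ind$area, ind$strain_id, strains)
  med_unind <- med_by(unind$area, unind$strain_id, strains)
  med_unind_all <- med_by(unind_all$area, unind_all$strain_id, strains)

  wi_num <- stats::median(ind$area)
  wi_den <- stats::median(unind$area)
  wj_den <- stats::median(unind_all$area)

  wij <- med_ind / med_unind
  wi <- wi_num / wi_den
  wj <- med_unind_all / wj_den
  usable <- is.finite(wij) & is.finite(wj) & is.finite(wi) &
    !is.na(med_unind) & med_unind > 0 & wj_den > 0 & wi_den > 0
  data.frame(strain_id = strains,
             wij = wij, wi = wi, wj = wj,
             usable = usable & !is.na(usable),
             stringsAsFactors = FALSE)
}

#' Multiplicative interaction score
#'
#' `S = Wij - Wi * Wj`: zero when the observed induction effect on a strain
#' equals the product of the screen-wide induction effect and the strain's
#' baseline fitness effect (the multiplicative null); positive scores are
#' alleviating interactions, negative scores aggravating ones.
#'
#' @param wij,wi,wj the W statistics (vectors recycle), or a data frame
#'   with those columns as the first argument.
#' @return Numeric vector of S scores.
#' @export
s_score <- function(wij, wi = NULL, wj = NULL) {
  if (is.data.frame(wij)) {
    wi <- wij$wi; wj <- wij$wj; wij <- wij$wij
  }
  wij - wi * wj
}

#' Compound-interaction W triple (petite / drug-treatment screens)
#'
#' Scores the interaction between induction and a second perturbation — a
#' petite [rho-] background or a drug such as hydroxyurea — from four
#' condition medians of one strain set.  The ratios follow the conditional
#' convention of such screens: `wi` is the variant's baseline effect
#' (variant untreated / parent untreated), `wj` the induction response of
#' the parent (parent treated / parent untreated), and `wij` the induction
#' response *within* the variant (variant treated / variant untreated).
#' Because `wij` and `wj` are both conditional induction responses, the
#' interaction score is the contrast `S = wij - wj`, which is 0 when the
#' variant responds to induction exactly like the parent (independent
#' multiplicative effects); `wi` is reported alongside.  Scores below
#' `sick_max` (default -0.1) are called synthetic sick.
#'
#' @param parent_untreated,parent_treated,variant_untreated,variant_treated
#'   median colony areas of the four conditions (vectors recycle).
#' @param sick_max synthetic-sick call threshold on S.
#' @return A data frame with columns `wij`, `wi`, `wj`, `s`, `usable`,
#'   `synthetic_sick`.
#' @export
compound_w_triple <- function(parent_untreated, parent_treated,
                              variant_untreated, variant_treated,
                              sick_max = -0.1) {
  wi <- variant_untreated / parent_untreated
  wj <- parent_treated / parent_untreated
  wij <- variant_treated / variant_untreated
  usable <- is.finite(wi) & is.finite(wj) & is.finite(wij) &
    parent_untreated > 0 & variant_untreated > 0
  s <- ifelse(usable, wij - wj, NA_real_)
  data.frame(wij = wij, wi = wi, wj = wj, s = s,
             usable = usable,
             synthetic_sick = !is.na(s) & s < sick_max)
}

#' Fitness-defect score
#'
#' `FD = -log2(Wij)` by default: positive when induction shrinks colonies
#' (a fitness defect), matching the orientation of published chemogenomic
#' FD matrices.  The opposite sign is available since correlation results
#' flip coherently either way.
#'
#' @param wij observed induction effect(s); must be > 0 for a defined
#'   score (`wij = 0` gives `NA`).
#' @param sign `"defect_positive"` (default, `-log2`) or
#'   `"defect_negative"` (`+log2`).
#' @return Numeric vector of FD scores.
#' @export
fd_score <- function(wij, sign = c("defect_positive", "defect_negative")) {
  sign <- match.arg(sign)
  out <- ifelse(wij > 0, -log2(wij), NA_real_)
  if (sign == "defect_negative") out <- -out
  out
}

# grouped missing-aware median aligned to a strain vector
med_by <- function(x, g, levels) {
  m <- tapply(x, g, stats::median)
  out <- as.numeric(m[levels])
  names(out) <- levels
  out
}
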