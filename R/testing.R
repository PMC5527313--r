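#' Interaction-test settings
#'
#' @param fold_threshold fold-change the moderated test must exceed
#'   (default 1.3; the null is rejected only for differentials more than
#'   1.3-fold away from the screen-wide expected differential).
#' @param q_max false-discovery-rate gate on calls (default 0.05).
#' @param s_positive_min S scores above this call a positive (alleviating)
#'   interaction (default 0.3).
#' @param s_negative_max S scores below this call a negative (aggravating)
#'   interaction (default -0.3).
#' @param control_window closed interval of acceptable control-query Wij;
#'   strains whose control response leaves \[0.7, 1.3\] interacted with the
#'   control construct itself and are excluded.
#' @param compound_sick_max synthetic-sick threshold for compound screens
#'   (default -0.1).
#' @param d0_override optional fixed prior degrees of freedom for the
#'   variance moderation (`0` disables moderation; `NULL` fits the prior
#'   from the data).
#' @return A list of class `test_config`.
#' @export
test_config <- function(fold_threshold = 1.3,
                        q_max = 0.05,
                        s_positive_min = 0.3,
                        s_negative_max = -0.3,
                        control_window = c(0.7, 1.3),
                        compound_sick_max = -0.1,
                        d0_override = NULL) {
  stopifnot(fold_threshold >= 1, q_max > 0, q_max <= 1,
            s_positive_min > 0, s_negative_max < 0,
            length(control_window) == 2,
            control_window[1] < control_window[2])
  structure(list(fold_threshold = fold_threshold, q_max = q_max,
                 s_positive_min = s_positive_min,
                 s_negative_max = s_negative_max,
                 control_window = control_window,
                 compound_sick_max = compound_sick_max,
                 d0_override = d0_override),
            class = "test_config")
}

#' Paired replicate log2 differentials
#'
#' Pairs induced and uninduced colonies of each strain positionally (same
#' quadruplicate slot on the same plate tile — the replicates share a
#' physical pinning position) and returns the per-pair log2 area
#' differential `d = log2(induced) - log2(uninduced)`.  Pairs with a
#' missing, filtered or zero-area side are dropped (zero areas carry no
#' log-ratio information).
#'
#' @param observations observation table (see [compute_w_triples()]) with a
#'   `kept` column.
#' @param query query identifier.
#' @return A data frame `strain_id`, `layout_id`, `slot`, `d` with one row
#'   per retained pair.
#' @export
replicate_differentials <- function(observations, query) {
  if (is.null(observations$kept)) observations$kept <- TRUE
  oq <- observations[observations$query_id == query &
                       observations$kept %in% TRUE &
                       !is.na(observations$area), ]
  ind <- oq[oq$condition == "induced", ]
  unind <- oq[oq$condition == "uninduced", ]
  m <- merge(ind[, c("strain_id", "layout_id", "slot", "area")],
             unind[, c("strain_id", "layout_id", "slot", "area")],
             by = c("strain_id", "layout_id", "slot"),
             suffixes = c("_ind", "_unind"))
  m <- m[m$area_ind > 0 & m$area_unind > 0, ]
  m$d <- log2(m$area_ind) - log2(m$area_unind)
  m[order(m$strain_id, m$layout_id, m$slot),
    c("strain_id", "layout_id", "slot", "d")]
}

#' Fit the empirical-Bayes variance prior
#'
#' Fits a scaled inverse chi-square prior (`d0` degrees of freedom, scale
#' `s0_sq`) to per-strain sample variances by the standard log-variance
#' moment equations: with `z = log(s^2)` and
#' `e = z - digamma(df/2) + log(df/2)`, the mean of `e` estimates
#' `log(s0_sq) + digamma(d0/2) - log(d0/2)` and the excess variance of `e`
#' over `trigamma(df/2)` estimates `trigamma(d0/2)`.  When the observed
#' variances show no excess spread the prior is degenerate (`d0 = Inf`).
#'
#' @param s2 per-strain sample variances.
#' @param df per-strain residual degrees of freedom (recycled).
#' @return A list of class `variance_prior` with `d0` and `s0_sq`.
#' @seealso [moderate_variances()], [threshold_test()]
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  fin <- is.finite(s2) & df >= 1
  if (sum(fin) < 2)
    stop("need at least 2 finite variances to fit a prior", call. = FALSE)
  ok <- fin & s2 > 0
  s2u <- s2[ok]; dfu <- df[ok]
  n <- length(s2u)
  if (n < 2) {
    # (near-)noiseless data: no spread to moderate, prior collapses
    return(structure(list(d0 = Inf, s0_sq = mean(s2[fin])),
                     class = "variance_prior"))
  }
  z <- log(s2u)
  if (stats::var(z) < 1e-24) {      # degenerate: all variances equal
    return(structure(list(d0 = Inf, s0_sq = mean(s2u)),
                     class = "variance_prior"))
  }
  e <- z - digamma(dfu / 2) + log(dfu / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dfu / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' Posterior (moderated) variances
#'
#' Shrinks each per-strain sample variance toward the prior scale:
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`.  With `d0 = 0` the
#' sample variances are returned unchanged; with `d0 = Inf` every strain
#' gets the prior variance.
#'
#' @param s2,df per-strain sample variances and degrees of freedom.
#' @param prior a `variance_prior` from [fit_variance_prior()].
#' @return Numeric vector of posterior variances.
#' @export
moderate_variances <- function(s2, df, prior) {
  df <- rep_len(df, length(s2))
  if (is.infinite(prior$d0)) return(rep(prior$s0_sq, length(s2)))
  (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df)
}

#' Moderated fold-change-threshold test
#'
#' Tests whether a strain's mean log2 induction differential differs from
#' the screen-wide expected differential (`null_center`, the median over
#' strains of per-strain median differentials) by more than
#' `log2(fold_threshold)`.  With centered effect `delta`, moderated
#' standard error `se = sqrt(s2_post / n_pairs)`, total degrees of freedom
#' `n_pairs - 1 + d0` and threshold `tau = log2(fold_threshold)`, the
#' p-value is the composite tail
#' `P(T >= (|delta| - tau)/se) + P(T >= (|delta| + tau)/se)`,
#' which reduces to the two-sided moderated t-test at `tau = 0`.
#'
#' @param mean_differential per-strain mean log2 differential.
#' @param s2_post posterior variances from [moderate_variances()].
#' @param n_pairs number of replicate pairs per strain.
#' @param prior a `variance_prior` (supplies `d0` for the degrees of
#'   freedom).
#' @param fold_threshold fold threshold (>= 1); 1 means an ordinary
#'   moderated t-test.
#' @param null_center the expected differential under no interaction.
#' @return A data frame with `moderated_stat` (signed threshold statistic
#'   `sign(delta) * (|delta| - tau)/se`) and `p_value`.
#' @export
threshold_test <- function(mean_differential, s2_post, n_pairs, prior,
                           fold_threshold = 1.3, null_center = 0) {
  stopifnot(fold_threshold >= 1)
  n_pairs <- rep_len(n_pairs, length(mean_differential))
  tau <- log2(fold_threshold)
  delta <- mean_differential - null_center
  se <- sqrt(s2_post / n_pairs)
  df <- n_pairs - 1 + prior$d0
  t_right <- (abs(delta) - tau) / se
  t_left <- (abs(delta) + tau) / se
  p <- stats::pt(t_right, df, lower.tail = FALSE) +
    stats::pt(t_left, df, lower.tail = FALSE)
  p <- pmin(p, 1)
  zero_se <- !is.na(se) & se == 0
  p[zero_se] <- ifelse(abs(delta[zero_se]) > tau, 0, 1)
  stat <- sign(delta) * t_right
  stat[zero_se] <- sign(delta[zero_se]) *
    ifelse(abs(delta[zero_se]) > tau, Inf, 0)
  data.frame(moderated_stat = stat, p_value = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: sort ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j`, cap at 1, restore input order.
#' Delegates to [stats::p.adjust()] after validating the inputs.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  bad <- !is.na(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad))
    stop("p-values must lie in [0, 1]; offending value: ",
         p_values[bad][1], call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Classify interactions against the control query
#'
#' A strain is eligible only when its control-query induction response lies
#' inside the control window (it shows no interaction with the control
#' construct itself).  Eligible strains are called positive when
#' `q <= q_max` and `S > s_positive_min`, negative when `q <= q_max` and
#' `S < s_negative_max`, otherwise none.  Unusable or ineligible strains
#' are `filtered`.
#'
#' @param s S scores.
#' @param q BH q-values from the threshold test.
#' @param control_wij the strain's Wij in the control query.
#' @param usable logical; `FALSE` marks strains whose statistics are
#'   undefined (filtered inputs, zero denominators).
#' @param config a [test_config()].
#' @return Character vector with levels `positive`, `negative`, `none`,
#'   `filtered`.
#' @export
classify_interactions <- function(s, q, control_wij, usable = TRUE,
                                  config = test_config()) {
  usable <- rep_len(usable, length(s)) & !is.na(s) & !is.na(q)
  eligible <- usable & !is.na(control_wij) &
    control_wij >= config$control_window[1] &
    control_wij <= config$control_window[2]
  out <- rep("filtered", length(s))
  out[eligible] <- "none"
  out[eligible & q <= config$q_max & s > config$s_positive_min] <- "positive"
  out[eligible & q <= config$q_max & s < config$s_negative_max] <- "negative"
  out
}

# Inverse of trigamma by Newton iteration on 1/x (monotone, convex),
# following the standard empirical-Bayes recipe.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}
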