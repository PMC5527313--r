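#' Correlate a fitness-defect profile with a reference chemogenomic matrix
#'
#' Computes, for every experiment of the reference matrix, the Pearson
#' correlation between the screen's per-strain FD scores and the
#' experiment's FD scores over the shared strains (pairwise-complete), with
#' p-values from the t-transform `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom (two-sided) and Benjamini-Hochberg adjustment
#' across all reported experiments.  Experiments sharing fewer than
#' `min_overlap` strains, or with zero variance over the shared strains,
#' are skipped.
#'
#' @param profile the screen's FD profile: a named numeric vector of FD
#'   scores per strain, or a data frame with columns `strain_id` and `fd`
#'   (as returned by [fd_profile()]).
#' @param ref an `fd_matrix` (see [read_fd_matrix()]).
#' @param min_overlap minimum shared strains per experiment (default 30;
#'   t-transform p-values are unreliable below that).
#' @param corr_q_max significance gate on q (default 0.01).
#' @return A data frame of class `fd_correlations`: `experiment_id`,
#'   `signature_label`, `r`, `n_overlap`, `p_value`, `q_value`,
#'   `significant`, ordered by `q_value` then `-r`.
#' @export
correlate_fd_profiles <- function(profile, ref, min_overlap = 30,
                                  corr_q_max = 0.01) {
  stopifnot(inherits(ref, "fd_matrix"))
  if (is.data.frame(profile))
    profile <- stats::setNames(profile$fd, profile$strain_id)
  profile <- profile[!is.na(profile)]
  shared <- intersect(names(profile), rownames(ref$fd))
  x_all <- profile[shared]
  res <- lapply(colnames(ref$fd), function(ex) {
    y <- ref$fd[shared, ex]
    ok <- !is.na(y)
    n <- sum(ok)
    if (n < min_overlap) return(NULL)
    x <- x_all[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
    r <- stats::cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      t <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(t), df = n - 2)
    }
    data.frame(experiment_id = ex,
               signature_label = unname(ref$signature[ex]),
               r = r, n_overlap = n, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(experiment_id = character(), signature_label =
                        character(), r = numeric(), n_overlap = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- !is.na(out$q_value) & out$q_value <= corr_q_max
  out <- out[order(out$q_value, -out$r), ]
  rownames(out) <- NULL
  class(out) <- c("fd_correlations", "data.frame")
  out
}

#' Summarize significant correlations by response signature
#'
#' Aggregates significant reference experiments by their signature label:
#' per signature, the count of significant experiments, the maximum and the
#' mean correlation among them, ranked by maximum correlation (ties broken
#' by count, then label order).
#'
#' @param results output of [correlate_fd_profiles()].
#' @param top_k keep at most this many signatures (default all).
#' @return A data frame `signature_label`, `n_significant`, `max_r`,
#'   `mean_r`; zero rows when nothing is significant.
#' @export
signature_summary <- function(results, top_k = Inf) {
  sig <- results[results$significant, ]
  if (nrow(sig) == 0)
    return(data.frame(signature_label = character(),
                      n_significant = integer(), max_r = numeric(),
                      mean_r = numeric(), stringsAsFactors = FALSE))
  agg <- do.call(rbind, lapply(split(sig, sig$signature_label), function(g)
    data.frame(signature_label = g$signature_label[1],
               n_significant = nrow(g),
               max_r = max(g$r), mean_r = mean(g$r),
               stringsAsFactors = FALSE)))
  agg <- agg[order(-agg$max_r, -agg$n_significant, agg$signature_label), ]
  rownames(agg) <- NULL
  utils::head(agg, top_k)
}
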