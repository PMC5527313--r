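#' Score an induction SGA screen
#'
#' The end-to-end fitting function: normalizes every plate (spatial
#' moving-median surface, then row/column medians), applies the jackknife
#' and low-area replicate filters, computes the median-ratio W statistics
#' and multiplicative interaction scores `S = Wij - Wi * Wj` and FD scores
#' per strain and query, runs the moderated fold-change-threshold test on
#' paired replicate log2 differentials with per-query Benjamini-Hochberg
#' FDR control, and classifies interactions against the control query.
#'
#' Plate-level normalization is deliberately not performed: it assumes
#' colony-size changes are rare events, which induction screens violate
#' wholesale.  Strains failing the low-area filter in any query are dropped
#' from every query, so the retained strain set is identical across the
#' screens scored together.
#'
#' @param plates named list of [plate_grid()]s (or a `screen_sim` /
#'   [read_screen()] result, in which case `layouts` and `manifest` are
#'   taken from it).
#' @param layouts named list of [array_layout()]s indexed by layout id.
#' @param manifest a [screen_manifest()].
#' @param config a [test_config()].
#' @param filters a [filter_config()].
#' @param spatial_window moving-median window of [spatial_normalize()].
#' @param normalize subset of `c("spatial", "rowcol")`; empty skips
#'   normalization (for pre-normalized inputs).
#'
#' @return An object of class `sga_screen`: a list with
#'   \describe{
#'     \item{records}{data frame, one row per strain x query: `strain_id`,
#'       `query_id`, `wij`, `wi`, `wj`, `usable`, `s`, `fd`, `n_pairs`,
#'       `mean_log2_diff`, `moderated_stat`, `p_value`, `q_value`,
#'       `control_wij`, `class`, `filter_flags`.}
#'     \item{observations}{the per-colony observation table (normalized
#'       area, jackknife flag, `kept`) the statistics were computed from.}
#'     \item{priors, null_centers}{per-query variance priors and expected
#'       differentials.}
#'     \item{filter_report}{per strain x query filter decisions.}
#'   }
#' @seealso [generate_screen()] for simulated input,
#'   [correlate_fd_profiles()] and [overlap_counts()] for downstream
#'   summaries.
#' @export
score_screen <- function(plates, layouts = NULL, manifest = NULL,
                         config = test_config(),
                         filters = filter_config(),
                         spatial_window = 9L,
                         normalize = c("spatial", "rowcol")) {
  if (is.list(plates) && !is.null(plates$plates)) {
    layouts <- plates$layouts
    manifest <- plates$manifest
    plates <- plates$plates
  }
  stopifnot(inherits(manifest, "screen_manifest"))
  if ("spatial" %in% normalize)
    plates <- lapply(plates, function(g) {
      # a sparse final tile can hold fewer colonies than the window needs;
      # the local surface is not estimable there, so leave it unscaled
      if (sum(!is.na(g$area)) < spatial_window^2) g
      else spatial_normalize(g, window = spatial_window)
    })
  if ("rowcol" %in% normalize)
    plates <- lapply(plates, rowcol_normalize)

  obs <- collect_observations(plates, layouts, manifest)

  # jackknife filter per replicate set (strain x condition plate)
  obs$jack_flag <- FALSE
  sets <- split(seq_len(nrow(obs)), paste(obs$plate_id, obs$replicate_group))
  for (ix in sets)
    obs$jack_flag[ix] <- jackknife_filter(obs$area[ix],
                                          filters$jackknife_fraction)
  obs$kept <- !is.na(obs$area) & !obs$jack_flag

  # low-area filter on per-strain condition medians, dropped everywhere
  queries <- unique(manifest$records$query_id)
  strains <- sort(unique(obs$strain_id))
  kept_obs <- obs[obs$kept, ]
  low_fail <- matrix(FALSE, length(strains), length(queries),
                     dimnames = list(strains, queries))
  for (q in queries) {
    oq <- kept_obs[kept_obs$query_id == q, ]
    mi <- med_by(oq$area[oq$condition == "induced"],
                 oq$strain_id[oq$condition == "induced"], strains)
    mu <- med_by(oq$area[oq$condition == "uninduced"],
                 oq$strain_id[oq$condition == "uninduced"], strains)
    mi[is.na(mi)] <- 0; mu[is.na(mu)] <- 0
    low_fail[, q] <- !low_area_filter(mi, mu, filters$low_area_min_sum)
  }
  dropped <- strains[rowSums(low_fail) > 0]
  obs$kept <- obs$kept & !(obs$strain_id %in% dropped)

  control <- manifest$control_query_id
  per_query <- list(); priors <- list(); null_centers <- numeric()
  for (q in queries) {
    wt <- compute_w_triples(obs, q)
    wt$s <- ifelse(wt$usable, s_score(wt), NA_real_)
    wt$fd <- ifelse(wt$usable, fd_score(wt$wij), NA_real_)

    d <- replicate_differentials(obs, q)
    agg <- split(d$d, d$strain_id)
    dstat <- data.frame(
      strain_id = names(agg),
      n_pairs = vapply(agg, length, 0L),
      mean_log2_diff = vapply(agg, mean, 0),
      med_log2_diff = vapply(agg, stats::median, 0),
      s2 = vapply(agg, function(v) if (length(v) > 1) stats::var(v)
                  else NA_real_, 0),
      stringsAsFactors = FALSE)
    testable <- dstat$n_pairs >= 2
    prior <- if (!is.null(config$d0_override)) {
      structure(list(d0 = config$d0_override,
                     s0_sq = mean(dstat$s2[testable], na.rm = TRUE)),
                class = "variance_prior")
    } else fit_variance_prior(dstat$s2[testable],
                              dstat$n_pairs[testable] - 1)
    null_center <- stats::median(dstat$med_log2_diff[testable])
    dstat$p_value <- NA_real_; dstat$moderated_stat <- NA_real_
    if (any(testable)) {
      s2_post <- moderate_variances(dstat$s2[testable],
                                    dstat$n_pairs[testable] - 1, prior)
      tt <- threshold_test(dstat$mean_log2_diff[testable], s2_post,
                           dstat$n_pairs[testable], prior,
                           config$fold_threshold, null_center)
      dstat$moderated_stat[testable] <- tt$moderated_stat
      dstat$p_value[testable] <- tt$p_value
    }
    dstat$q_value <- bh_adjust(dstat$p_value)

    rec <- merge(data.frame(strain_id = strains, stringsAsFactors = FALSE),
                 wt, by = "strain_id", all.x = TRUE)
    rec <- merge(rec, dstat[, c("strain_id", "n_pairs", "mean_log2_diff",
                                "moderated_stat", "p_value", "q_value")],
                 by = "strain_id", all.x = TRUE)
    rec$usable[is.na(rec$usable)] <- FALSE
    rec$query_id <- q
    per_query[[q]] <- rec
    priors[[q]] <- prior
    null_centers[q] <- null_center
  }

  control_wij <- stats::setNames(per_query[[control]]$wij,
                                 per_query[[control]]$strain_id)
  records <- do.call(rbind, lapply(per_query, function(rec) {
    rec$control_wij <- unname(control_wij[rec$strain_id])
    rec$class <- classify_interactions(rec$s, rec$q_value, rec$control_wij,
                                       rec$usable, config)
    rec
  }))
  records$filter_flags <- ifelse(
    records$strain_id %in% dropped, "low_area",
    ifelse(!records$usable, "unusable", ""))
  cols <- c("strain_id", "query_id", "wij", "wi", "wj", "usable", "s", "fd",
            "n_pairs", "mean_log2_diff", "moderated_stat", "p_value",
            "q_value", "control_wij", "class", "filter_flags")
  records <- records[order(records$query_id, records$strain_id), cols]
  rownames(records) <- NULL

  report <- records[records$filter_flags != "",
                    c("strain_id", "query_id", "filter_flags")]
  structure(list(records = records, observations = obs,
                 priors = priors, null_centers = null_centers,
                 dropped_strains = dropped,
                 control_query_id = control,
                 config = config, filters = filters),
            class = "sga_screen")
}

#' @export
print.sga_screen <- function(x, ...) {
  r <- x$records
  qs <- unique(r$query_id)
  cat(sprintf("sga_screen fit: %d strains x %d queries (control '%s')\n",
              length(unique(r$strain_id)), length(qs),
              x$control_query_id))
  tab <- table(r$query_id, factor(r$class, c("positive", "negative",
                                             "none", "filtered")))
  print(tab)
  invisible(x)
}

#' @export
summary.sga_screen <- function(object, ...) {
  r <- object$records
  per_q <- do.call(rbind, lapply(split(r, r$query_id), function(g)
    data.frame(query_id = g$query_id[1],
               wi = g$wi[1],
               null_center = object$null_centers[g$query_id[1]],
               d0 = object$priors[[g$query_id[1]]]$d0,
               s0_sq = object$priors[[g$query_id[1]]]$s0_sq,
               positive = sum(g$class == "positive"),
               negative = sum(g$class == "negative"),
               none = sum(g$class == "none"),
               filtered = sum(g$class == "filtered"),
               stringsAsFactors = FALSE)))
  rownames(per_q) <- NULL
  structure(list(per_query = per_q,
                 n_dropped = length(object$dropped_strains),
                 control_query_id = object$control_query_id),
            class = "summary.sga_screen")
}

#' @export
print.summary.sga_screen <- function(x, ...) {
  cat("Induction-screen interaction scoring\n")
  cat(sprintf("control query: %s; strains dropped by low-area filter: %d\n\n",
              x$control_query_id, x$n_dropped))
  print(x$per_query, digits = 4)
  invisible(x)
}

#' @export
coef.sga_screen <- function(object, ...) {
  r <- object$records
  strains <- sort(unique(r$strain_id))
  qs <- unique(r$query_id)
  m <- matrix(NA_real_, length(strains), length(qs),
              dimnames = list(strains, qs))
  m[cbind(match(r$strain_id, strains), match(r$query_id, qs))] <- r$s
  m
}

#' Plot method: control response versus query response
#'
#' Scatter of each strain's control-query Wij against its Wij in one query,
#' colored by interaction class, with the control window and the identity
#' line drawn — the classic per-screen interaction panel.
#'
#' @param x an `sga_screen` fit.
#' @param query query to display (default: first non-control query).
#' @param ... passed to [graphics::plot()].
#' @export
plot.sga_screen <- function(x, query = NULL, ...) {
  r <- x$records
  qs <- setdiff(unique(r$query_id), x$control_query_id)
  query <- query %||% qs[1]
  g <- r[r$query_id == query & !is.na(r$wij) & !is.na(r$control_wij), ]
  cols <- c(positive = "orange", negative = "blue",
            none = "grey50", filtered = "grey85")
  graphics::plot(g$control_wij, g$wij,
                 col = cols[g$class], pch = 16, cex = 0.6,
                 xlab = sprintf("Wij, control (%s)", x$control_query_id),
                 ylab = sprintf("Wij, %s", query),
                 main = sprintf("Induction response: %s vs control", query),
                 ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(v = x$config$control_window, lty = 3)
  graphics::legend("topleft", legend = names(cols), col = cols,
                   pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Extract a fitness-defect profile
#'
#' @param fit an `sga_screen` fit.
#' @param query query identifier.
#' @return Data frame `strain_id`, `fd` over usable strains with finite FD.
#' @export
fd_profile <- function(fit, query) {
  r <- fit$records
  g <- r[r$query_id == query & r$usable & is.finite(r$fd), ]
  data.frame(strain_id = g$strain_id, fd = g$fd, stringsAsFactors = FALSE)
}

#' Extract interaction call sets
#'
#' @param fit an `sga_screen` fit.
#' @param classes which classes count as a call.
#' @return Named list (per non-control query) of called strain vectors,
#'   ready for [overlap_counts()].
#' @export
call_sets <- function(fit, classes = c("positive", "negative")) {
  r <- fit$records
  qs <- setdiff(unique(r$query_id), fit$control_query_id)
  stats::setNames(lapply(qs, function(q)
    r$strain_id[r$query_id == q & r$class %in% classes]), qs)
}
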