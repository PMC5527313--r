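#' Filter settings for replicate-level quality control
#'
#' @param jackknife_fraction a replicate is flagged when removing it drops
#'   the replicate set's sample variance by more than this fraction
#'   (default 0.9, i.e. the replicate contributes more than 90% of the
#'   variance of its quadruplicate).
#' @param low_area_min_sum a strain is dropped from all screens scored
#'   together when, in any screen, the sum of its median induced and median
#'   uninduced colony areas falls below this value (default 400, on the
#'   normalized area scale).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(jackknife_fraction = 0.9,
                          low_area_min_sum = 400) {
  stopifnot(jackknife_fraction > 0, jackknife_fraction <= 1,
            low_area_min_sum >= 0)
  structure(list(jackknife_fraction = jackknife_fraction,
                 low_area_min_sum = low_area_min_sum),
            class = "filter_config")
}

#' Spatial normalization of a plate grid
#'
#' Divides each colony area by a local moving-median surface (a `window` x
#' `window` neighborhood, missing-aware and truncated at the plate edges)
#' and rescales so the output plate median equals the input plate median.
#' This removes smooth multiplicative artifacts — pinning pressure, agar
#' thickness, incubation gradients — while leaving genuine colony-to-colony
#' differences intact.  Missing cells stay missing.
#'
#' Plate-level normalization (forcing all plates to a common median) is
#' deliberately not part of this step: it assumes colony-size changes are
#' rare, which is false for induction screens where most colonies respond.
#'
#' @param grid a [plate_grid()].
#' @param window odd neighborhood width, at least 3 (default 9).
#' @return A normalized [plate_grid()].
#' @export
spatial_normalize <- function(grid, window = 9L) {
  stopifnot(inherits(grid, "plate_grid"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3", call. = FALSE)
  a <- grid$area
  n_obs <- sum(!is.na(a))
  if (n_obs < window^2)
    stop("plate '", grid$plate_id, "' has fewer than window^2 (",
         window^2, ") non-missing colonies", call. = FALSE)
  med_in <- stats::median(a, na.rm = TRUE)
  if (!is.finite(med_in) || med_in <= 0)
    stop("degenerate plate '", grid$plate_id,
         "': all colonies missing or zero", call. = FALSE)
  h <- window %/% 2L
  nr <- grid$n_rows; nc <- grid$n_cols
  surf <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    rr <- max(1L, r - h):min(nr, r + h)
    for (c in seq_len(nc)) {
      cc <- max(1L, c - h):min(nc, c + h)
      surf[r, c] <- stats::median(a[rr, cc], na.rm = TRUE)
    }
  }
  # a zero local median (>= half the neighborhood dead) cannot scale;
  # fall back to the plate median there
  surf[!is.na(surf) & surf == 0] <- med_in
  out <- a / surf
  med_out <- stats::median(out, na.rm = TRUE)
  out <- out * (med_in / med_out)
  grid$area <- out
  grid
}

#' Row/column normalization of a plate grid
#'
#' One pass dividing each row by (row median / plate median), then each
#' column by (column median / plate median), with missing-aware medians;
#' the plate median is restored at the end.  Rows or columns that are
#' entirely missing are left unscaled.
#'
#' @param grid a [plate_grid()].
#' @return A normalized [plate_grid()].
#' @export
rowcol_normalize <- function(grid) {
  stopifnot(inherits(grid, "plate_grid"))
  a <- grid$area
  med_in <- stats::median(a, na.rm = TRUE)
  if (!is.finite(med_in) || med_in <= 0)
    stop("degenerate plate '", grid$plate_id,
         "': all colonies missing or zero", call. = FALSE)
  skipped <- character()
  row_med <- apply(a, 1, stats::median, na.rm = TRUE)
  for (r in seq_len(grid$n_rows)) {
    if (is.finite(row_med[r]) && row_med[r] > 0) {
      a[r, ] <- a[r, ] / (row_med[r] / med_in)
    } else skipped <- c(skipped, sprintf("row %d", r))
  }
  med_mid <- stats::median(a, na.rm = TRUE)
  col_med <- apply(a, 2, stats::median, na.rm = TRUE)
  for (c in seq_len(grid$n_cols)) {
    if (is.finite(col_med[c]) && col_med[c] > 0) {
      a[, c] <- a[, c] / (col_med[c] / med_mid)
    } else skipped <- c(skipped, sprintf("col %d", c))
  }
  med_out <- stats::median(a, na.rm = TRUE)
  a <- a * (med_in / med_out)
  if (length(skipped))
    message("rowcol_normalize('", grid$plate_id, "'): left unscaled: ",
            paste(skipped, collapse = ", "))
  grid$area <- a
  grid
}

#' Jackknife outlier filter for replicate colonies
#'
#' Flags a replicate whose removal drops the sample variance (n - 1
#' denominator) of its replicate set by more than `fraction` of the total —
#' i.e. the replicate contributes more than that fraction of the variance.
#' At most one replicate (the maximal contributor) is flagged per set;
#' under this variance definition two replicates cannot both exceed a
#' fraction above 1/2, and the cap prevents cascades on small sets.  Sets
#' with zero variance or fewer than 3 usable replicates are left unflagged
#' (the filter is skipped).
#'
#' @param areas numeric vector of replicate colony areas (`NA` = missing).
#' @param fraction variance-contribution threshold in (0, 1], default 0.9.
#' @return A logical vector along `areas`; `TRUE` marks the flagged
#'   replicate.  The attribute `skipped` is `TRUE` when fewer than 3 usable
#'   replicates were available.
#' @export
jackknife_filter <- function(areas, fraction = 0.9) {
  stopifnot(fraction > 0, fraction <= 1)
  flags <- rep(FALSE, length(areas))
  usable <- which(!is.na(areas))
  if (length(usable) < 3L) {
    attr(flags, "skipped") <- TRUE
    return(flags)
  }
  x <- areas[usable]
  v <- stats::var(x)
  if (v == 0) return(flags)
  contrib <- vapply(seq_along(x),
                    function(i) (v - stats::var(x[-i])) / v, 0)
  over <- contrib > fraction
  if (any(over))
    flags[usable[which.max(contrib)]] <- TRUE
  flags
}

#' Low-area replicate-set filter
#'
#' Drops a strain when the sum of its median induced and median uninduced
#' colony areas falls below `min_sum` (tiny colonies carry no usable ratio
#' information).  When screens are scored together, a strain dropped in any
#' one screen is dropped from all of them (see [score_screen()]), so the
#' retained strain set is identical across screens.
#'
#' @param median_induced,median_uninduced median replicate areas per strain
#'   (vectors recycle).
#' @param min_sum drop threshold on the sum of the two medians.
#' @return Logical vector: `TRUE` = keep, `FALSE` = drop.
#' @export
low_area_filter <- function(median_induced, median_uninduced,
                            min_sum = 400) {
  stopifnot(all(median_induced >= 0, na.rm = TRUE),
            all(median_uninduced >= 0, na.rm = TRUE))
  !((median_induced + median_uninduced) < min_sum)
}

#' Assemble per-colony observations from plates and layouts
#'
#' Joins every plate of a screen with its layout into one long table of
#' colony observations, the working format of the scoring layer.
#'
#' @param plates named list of [plate_grid()]s.
#' @param layouts named list of [array_layout()]s, indexed by `layout_id`.
#' @param manifest a [screen_manifest()].
#' @return A data frame with one row per layout position per plate:
#'   `query_id`, `condition`, `plate_id`, `layout_id`, `strain_id`,
#'   `replicate_group`, `slot`, `row`, `col`, `is_border`, `area`.
#' @export
collect_observations <- function(plates, layouts, manifest) {
  recs <- manifest$records
  out <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    g <- plates[[recs$plate_id[i]]]
    if (is.null(g))
      stop("manifest names plate '", recs$plate_id[i],
           "' but it was not supplied", call. = FALSE)
    lay <- layouts[[recs$layout_id[i]]]
    if (is.null(lay))
      stop("manifest names layout '", recs$layout_id[i],
           "' but it was not supplied", call. = FALSE)
    out[[i]] <- data.frame(
      query_id = recs$query_id[i], condition = recs$condition[i],
      plate_id = recs$plate_id[i], layout_id = recs$layout_id[i],
      strain_id = lay$strain_id, replicate_group = lay$replicate_group,
      slot = lay$slot, row = lay$row, col = lay$col,
      is_border = lay$is_border,
      area = g$area[cbind(lay$row + 1L, lay$col + 1L)],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
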