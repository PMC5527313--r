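#' Colony-area plate grid
#'
#' A `plate_grid` holds one plate's quantified colony areas on a rectangular
#' pinning grid, together with per-position quantifier flags and the plate's
#' screen metadata (query, induction condition, growth medium).  Missing
#' colonies (positions with no quantified spot) are `NA`; an area of 0 is a
#' legitimate measurement of a dead spot and is kept distinct from missing.
#'
#' @param area numeric matrix of colony areas, `NA` for missing positions.
#'   Dimensions must match a supported pinning format: 16 x 24 (384) or
#'   32 x 48 (1536).
#' @param plate_id character scalar identifying the physical plate.
#' @param query_id character scalar; the query construct screened on this
#'   plate.
#' @param condition `"induced"` or `"uninduced"`.
#' @param medium free-text growth-medium tag.
#' @param flag character matrix of quantifier flag codes, same dimensions as
#'   `area`; `""` means unflagged.
#'
#' @return An object of class `plate_grid`.
#' @seealso [read_plate_table()], [spatial_normalize()], [rowcol_normalize()]
#' @export
plate_grid <- function(area, plate_id, query_id, condition,
                       medium = "", flag = NULL) {
  if (!is.matrix(area) || !is.numeric(area))
    stop("'area' must be a numeric matrix", call. = FALSE)
  dims <- dim(area)
  ok <- (dims[1] == 16 && dims[2] == 24) || (dims[1] == 32 && dims[2] == 48)
  if (!ok)
    stop("grid dimensions ", dims[1], "x", dims[2],
         " match neither the 384 (16x24) nor the 1536 (32x48) format",
         call. = FALSE)
  if (any(area < 0, na.rm = TRUE))
    stop("colony areas must be nonnegative", call. = FALSE)
  condition <- match.arg(condition, c("induced", "uninduced"))
  if (is.null(flag)) {
    flag <- matrix("", dims[1], dims[2])
  } else if (!identical(dim(flag), dims)) {
    stop("'flag' dimensions must match 'area'", call. = FALSE)
  }
  structure(
    list(plate_id = as.character(plate_id),
         query_id = as.character(query_id),
         condition = condition,
         medium = as.character(medium),
         n_rows = dims[1], n_cols = dims[2],
         area = area,
         flag = flag),
    class = "plate_grid")
}

#' @export
print.plate_grid <- function(x, ...) {
  n_missing <- sum(is.na(x$area))
  cat(sprintf("plate_grid '%s' (%s, %s): %dx%d, %d colonies, %d missing\n",
              x$plate_id, x$query_id, x$condition,
              x$n_rows, x$n_cols,
              x$n_rows * x$n_cols - n_missing, n_missing))
  invisible(x)
}

#' Array layout key
#'
#' Maps grid positions of a plate to strain identifiers and replicate
#' groups.  Positions are 0-based internally (1-based in layout files).  A
#' replicate group collects the pinned replicates of one strain (the 2 x 2
#' quadruplicate block of the 384 -> 1536 pinning scheme); `slot` numbers the
#' replicates within a group so that induced and uninduced colonies of the
#' same physical pinning position can be paired.
#'
#' @param row,col integer vectors of 0-based grid positions.
#' @param strain_id character vector of strain identifiers.
#' @param replicate_group character vector; all positions of one group must
#'   carry the same `strain_id`.
#' @param is_border logical vector marking plate-border positions.
#' @param slot integer replicate index within each group (defaults to order
#'   of appearance).
#'
#' @return An object of class `array_layout`: a data frame with columns
#'   `row`, `col`, `strain_id`, `replicate_group`, `is_border`, `slot`.
#' @export
array_layout <- function(row, col, strain_id, replicate_group,
                         is_border = FALSE, slot = NULL) {
  df <- data.frame(row = as.integer(row), col = as.integer(col),
                   strain_id = as.character(strain_id),
                   replicate_group = as.character(replicate_group),
                   is_border = rep_len(as.logical(is_border), length(row)),
                   stringsAsFactors = FALSE)
  if (is.null(slot)) {
    slot <- stats::ave(seq_len(nrow(df)), df$replicate_group,
                       FUN = seq_along)
  }
  df$slot <- as.integer(slot)
  key <- paste(df$row, df$col)
  if (anyDuplicated(key))
    stop("duplicate grid position in layout: (",
         key[duplicated(key)][1], ")", call. = FALSE)
  bad <- tapply(df$strain_id, df$replicate_group,
                function(s) length(unique(s)) > 1)
  if (any(bad))
    stop("replicate group '", names(bad)[bad][1],
         "' maps to more than one strain", call. = FALSE)
  class(df) <- c("array_layout", "data.frame")
  df
}

#' Screen manifest
#'
#' Pairs the induced and uninduced plates of every query of a screen and
#' names the control query used for interaction classification.  Plates
#' that tile a large array are listed one record per tile, sharing a
#' `layout_id`.
#'
#' @param records data frame with columns `query_id`, `condition`,
#'   `plate_id`, `layout_id` (and, for on-disk manifests, `plate_file` /
#'   `layout_file`).
#' @param control_query_id the query whose induction has no biological
#'   effect; must appear among `records$query_id`.
#'
#' @return An object of class `screen_manifest`.
#' @export
screen_manifest <- function(records, control_query_id) {
  needed <- c("query_id", "condition", "plate_id", "layout_id")
  if (!all(needed %in% names(records)))
    stop("manifest records need columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  records$condition <- as.character(records$condition)
  if (!all(records$condition %in% c("induced", "uninduced")))
    stop("manifest condition must be 'induced' or 'uninduced'",
         call. = FALSE)
  for (q in unique(records$query_id)) {
    have <- unique(records$condition[records$query_id == q])
    if (!all(c("induced", "uninduced") %in% have))
      stop("query '", q, "' lacks an ",
           setdiff(c("induced", "uninduced"), have)[1],
           " plate", call. = FALSE)
  }
  if (!control_query_id %in% records$query_id)
    stop("control query '", control_query_id,
         "' absent from manifest", call. = FALSE)
  structure(list(records = records,
                 control_query_id = as.character(control_query_id)),
            class = "screen_manifest")
}

#' @export
print.screen_manifest <- function(x, ...) {
  cat(sprintf("screen_manifest: %d plates, %d queries (control '%s')\n",
              nrow(x$records), length(unique(x$records$query_id)),
              x$control_query_id))
  invisible(x)
}
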