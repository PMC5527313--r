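#' Read a colony-area plate table
#'
#' Plate tables are TSV files with header `row`, `col`, `size`, `flag` and
#' 1-based grid coordinates, the format emitted by colony quantifiers for a
#' single scanned plate.  Positions absent from the file become missing
#' (`NA`) cells.  Plate metadata may be stored in leading `# key<TAB>value`
#' comment lines (as written by [write_plate_table()]); arguments override
#' file metadata.
#'
#' @param path file to read.
#' @param declared_format `"1536"` (32 x 48) or `"384"` (16 x 24).
#' @param plate_id,query_id,condition,medium metadata overrides; required
#'   (directly or via file comments) to build the grid.
#'
#' @return A [plate_grid()].
#' @export
read_plate_table <- function(path, declared_format = c("1536", "384"),
                             plate_id = NULL, query_id = NULL,
                             condition = NULL, medium = NULL) {
  declared_format <- match.arg(declared_format)
  dims <- if (declared_format == "1536") c(32L, 48L) else c(16L, 24L)
  lines <- readLines(path)
  meta <- parse_meta_comments(lines)
  body <- lines[!startsWith(lines, "#")]
  plate_id <- plate_id %||% meta[["plate_id"]] %||%
    tools::file_path_sans_ext(basename(path))
  query_id <- query_id %||% meta[["query_id"]] %||% ""
  condition <- condition %||% meta[["condition"]] %||%
    stop("no 'condition' in file comments or arguments for ", path,
         call. = FALSE)
  medium <- medium %||% meta[["medium"]] %||% ""

  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  needed <- c("row", "col", "size", "flag")
  if (!all(needed %in% names(tab)))
    stop("plate table ", path, " must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  # line numbers in the original file, for error messages
  lineno <- which(!startsWith(lines, "#"))[-1][seq_len(nrow(tab))]
  bad_pos <- tab$row < 1 | tab$row > dims[1] | tab$col < 1 | tab$col > dims[2]
  if (any(bad_pos))
    stop("plate table ", path, " line ", lineno[which(bad_pos)[1]],
         ": position (", tab$row[which(bad_pos)[1]], ",",
         tab$col[which(bad_pos)[1]], ") outside the declared ",
         declared_format, " format", call. = FALSE)
  if (any(is.na(tab$size) | tab$size < 0))
    stop("plate table ", path, " line ",
         lineno[which(is.na(tab$size) | tab$size < 0)[1]],
         ": negative or non-numeric size", call. = FALSE)
  key <- paste(tab$row, tab$col)
  if (anyDuplicated(key))
    stop("plate table ", path, " line ", lineno[which(duplicated(key))[1]],
         ": duplicate position (", key[duplicated(key)][1], ")",
         call. = FALSE)
  area <- matrix(NA_real_, dims[1], dims[2])
  flag <- matrix("", dims[1], dims[2])
  idx <- cbind(tab$row, tab$col)
  area[idx] <- tab$size
  flag[idx] <- ifelse(is.na(tab$flag), "", as.character(tab$flag))
  plate_grid(area, plate_id = plate_id, query_id = query_id,
             condition = condition, medium = medium, flag = flag)
}

#' Write a colony-area plate table
#'
#' Inverse of [read_plate_table()]: 1-based coordinates on disk, missing
#' cells omitted, metadata stored as `# key<TAB>value` comment lines.
#'
#' @param grid a [plate_grid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(grid, path) {
  stopifnot(inherits(grid, "plate_grid"))
  idx <- which(!is.na(grid$area), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tab <- data.frame(row = idx[, 1], col = idx[, 2],
                    size = grid$area[idx], flag = grid$flag[idx])
  con <- file(path, "w")
  on.exit(close(con))
  for (k in c("plate_id", "query_id", "condition", "medium"))
    writeLines(sprintf("# %s\t%s", k, grid[[k]]), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an array layout key
#'
#' Layout files are TSV with header `row`, `col`, `strain`, `group`,
#' `border` (and optionally `slot`), 1-based coordinates on disk.
#'
#' @param path file to read or write.
#' @return [read_layout()] returns an [array_layout()];
#'   [write_layout()] returns `path` invisibly.
#' @export
read_layout <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("row", "col", "strain", "group", "border")
  if (!all(needed %in% names(tab)))
    stop("layout ", path, " must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  array_layout(row = tab$row - 1L, col = tab$col - 1L,
               strain_id = tab$strain, replicate_group = tab$group,
               is_border = as.logical(tab$border),
               slot = if ("slot" %in% names(tab)) tab$slot else NULL)
}

#' @rdname read_layout
#' @param layout an [array_layout()].
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "array_layout"))
  tab <- data.frame(row = layout$row + 1L, col = layout$col + 1L,
                    strain = layout$strain_id,
                    group = layout$replicate_group,
                    border = as.integer(layout$is_border),
                    slot = layout$slot)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a screen manifest
#'
#' Manifests are JSON files holding the plate records (query, condition,
#' plate file, layout file) and the control query identifier.
#'
#' @param path file to read or write.
#' @return [read_manifest()] returns a [screen_manifest()].
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  recs <- as.data.frame(obj$records, stringsAsFactors = FALSE)
  if (is.null(recs$plate_id) && !is.null(recs$plate_file))
    recs$plate_id <- tools::file_path_sans_ext(basename(recs$plate_file))
  if (is.null(recs$layout_id) && !is.null(recs$layout_file))
    recs$layout_id <- tools::file_path_sans_ext(basename(recs$layout_file))
  screen_manifest(recs, control_query_id = obj$control_query_id)
}

#' @rdname read_manifest
#' @param manifest a [screen_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "screen_manifest"))
  jsonlite::write_json(
    list(control_query_id = manifest$control_query_id,
         records = manifest$records),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a reference fitness-defect matrix
#'
#' Reference chemogenomic matrices are TSV files whose first column holds
#' strain identifiers and remaining columns hold per-experiment FD scores
#' (missing cells allowed).  An optional second header row whose first field
#' is `signature` assigns a response-signature label to each experiment.
#'
#' @param path file to read or write.
#' @return [read_fd_matrix()] returns a list of class `fd_matrix` with
#'   elements `fd` (numeric matrix, strains x experiments) and `signature`
#'   (named character vector per experiment).
#' @export
read_fd_matrix <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  experiments <- header[-1]
  if (anyDuplicated(experiments))
    stop("FD matrix ", path, ": duplicate experiment identifiers",
         call. = FALSE)
  body_start <- 2L
  signature <- stats::setNames(rep("", length(experiments)), experiments)
  second <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (identical(second[1], "signature")) {
    signature[] <- second[-1]
    body_start <- 3L
  }
  tab <- utils::read.delim(text = lines[c(1, body_start:length(lines))],
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  fd <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(fd) <- "double"
  rownames(fd) <- tab[[1]]
  structure(list(fd = fd, signature = signature), class = "fd_matrix")
}

#' @rdname read_fd_matrix
#' @param ref an `fd_matrix` object.
#' @export
write_fd_matrix <- function(ref, path) {
  stopifnot(inherits(ref, "fd_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("strain", colnames(ref$fd)), collapse = "\t"), con)
  if (any(nzchar(ref$signature)))
    writeLines(paste(c("signature", ref$signature), collapse = "\t"), con)
  tab <- data.frame(strain = rownames(ref$fd), ref$fd,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "")
  invisible(path)
}

#' Write an interaction-results table
#'
#' One record per strain x query, carrying the full scoring chain (Wij, Wi,
#' Wj, S, FD, moderated statistic, p, q, class, filter flags) so that every
#' score is independently recomputable from the table.
#'
#' @param records the `records` data frame of an [score_screen()] fit.
#' @param path output TSV.
#' @export
write_interaction_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_meta_comments <- function(lines) {
  com <- lines[startsWith(lines, "#")]
  out <- list()
  for (l in com) {
    parts <- strsplit(sub("^#\\s*", "", l), "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2) out[[parts[1]]] <- parts[2]
  }
  out
}
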