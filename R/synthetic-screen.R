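#' Configuration for a simulated induction screen
#'
#' Describes the generative model of [generate_screen()]: per-strain
#' log-normal baseline colony areas, a global multiplicative induction
#' effect per query (the true Wi), planted multiplicative interactions of
#' configurable magnitude, a smooth multiplicative spatial plate artifact,
#' log-normal replicate noise, sporadic single-replicate outliers, and
#' missing colonies.
#'
#' @param n_strains number of arrayed strains.
#' @param n_queries number of query constructs (the first is the control
#'   query; interactions are never planted in it).
#' @param replicate_count replicates per strain; the quadruplicate
#'   384 -> 1536 pinning scheme fixes this at 4.
#' @param baseline_log_mean,baseline_log_sd log-scale mean and sd of the
#'   per-strain baseline colony area B_x (pixels of colony area; the default
#'   centres uninduced colonies near 500).  The default sd of 0 gives every
#'   strain the same expected baseline, so the true Wj is exactly 1 by
#'   construction; a positive sd (or the slow-strain option) adds
#'   strain-specific uninduced fitness effects that the recovered Wj picks
#'   up but the stored truth does not model.
#' @param induction_effect_per_query true global induction effect Wi of each
#'   query (ratio of induced to uninduced colony area for a non-interacting
#'   strain); defaults to 1 for the control query and 0.8 elsewhere.
#' @param planted_fraction fraction of strains per non-control query given a
#'   planted interaction.
#' @param planted_factor_range one range `c(lo, hi)` or a list of ranges for
#'   the multiplicative interaction factor I; each planted strain draws a
#'   range uniformly, then a factor uniformly within it.
#' @param noise_cv coefficient of variation of the log-normal replicate
#'   noise (median 1, so medians are unbiased).
#' @param outlier_prob probability that one replicate of a strain's
#'   quadruplicate (per condition plate) is multiplied by `outlier_factor`.
#' @param outlier_factor multiplicative shock applied to outlier replicates.
#' @param missing_prob probability that a colony is absent (not pinned or
#'   not quantified).
#' @param spatial_gradient_amplitude the smooth multiplicative plate surface
#'   spans a max/min ratio of `1 + spatial_gradient_amplitude`.
#' @param slow_strain_fraction,slow_strain_factor optional slow-growing
#'   strains whose baseline (both conditions) is multiplied by the factor,
#'   exercising the Wj term; off by default so the stored truth (Wj = 1) is
#'   exact.
#' @param query_ids optional character names for the queries.
#' @param seed integer seed; identical configurations and seeds reproduce
#'   the screen bit for bit.
#'
#' @return A validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_strains,
                              n_queries = 4,
                              replicate_count = 4,
                              baseline_log_mean = log(500),
                              baseline_log_sd = 0,
                              induction_effect_per_query = NULL,
                              planted_fraction = 0.05,
                              planted_factor_range =
                                list(c(0.3, 0.5), c(1.8, 2.2)),
                              noise_cv = 0.1,
                              outlier_prob = 0.01,
                              outlier_factor = 4,
                              missing_prob = 0.01,
                              spatial_gradient_amplitude = 0.2,
                              slow_strain_fraction = 0,
                              slow_strain_factor = 0.5,
                              query_ids = NULL,
                              seed = 1L) {
  if (is.null(induction_effect_per_query))
    induction_effect_per_query <- c(1, rep(0.8, n_queries - 1))
  if (is.null(query_ids))
    query_ids <- sprintf("Q%02d", seq_len(n_queries))
  if (is.numeric(planted_factor_range))
    planted_factor_range <- list(planted_factor_range)
  cfg <- list(n_strains = as.integer(n_strains),
              n_queries = as.integer(n_queries),
              replicate_count = as.integer(replicate_count),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              induction_effect_per_query = induction_effect_per_query,
              planted_fraction = planted_fraction,
              planted_factor_range = planted_factor_range,
              noise_cv = noise_cv,
              outlier_prob = outlier_prob,
              outlier_factor = outlier_factor,
              missing_prob = missing_prob,
              spatial_gradient_amplitude = spatial_gradient_amplitude,
              slow_strain_fraction = slow_strain_fraction,
              slow_strain_factor = slow_strain_factor,
              query_ids = as.character(query_ids),
              seed = as.integer(seed))
  stopifnot(cfg$n_strains >= 1, cfg$n_queries >= 1,
            cfg$replicate_count >= 2,
            cfg$baseline_log_sd >= 0, cfg$noise_cv >= 0,
            cfg$spatial_gradient_amplitude >= 0,
            length(cfg$induction_effect_per_query) == cfg$n_queries,
            all(cfg$induction_effect_per_query > 0),
            length(cfg$query_ids) == cfg$n_queries)
  for (p in c("planted_fraction", "outlier_prob", "missing_prob",
              "slow_strain_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("'", p, "' must lie in [0, 1]", call. = FALSE)
  for (rng in cfg$planted_factor_range)
    if (length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2])
      stop("each planted factor range must be c(lo, hi) with 0 < lo <= hi",
           call. = FALSE)
  if (cfg$outlier_factor <= 0 || cfg$slow_strain_factor <= 0)
    stop("multiplicative factors must be strictly positive", call. = FALSE)
  class(cfg) <- "screen_sim_config"
  cfg
}

#' Quadruplicate pinning positions
#'
#' Maps one parent position of the 384-format (16 x 24) source array to its
#' 2 x 2 replicate block on the 1536-format (32 x 48) screen plate.
#' Positions are 0-based.
#'
#' @param parent_row,parent_col 0-based parent position (row in 0..15,
#'   column in 0..23).
#' @return A 4 x 2 integer matrix of (row, col) positions in slot order:
#'   top-left, top-right, bottom-left, bottom-right.
#' @export
quadruplicate_positions <- function(parent_row, parent_col) {
  if (parent_row < 0 || parent_row > 15 || parent_col < 0 || parent_col > 23)
    stop("parent position (", parent_row, ",", parent_col,
         ") outside the 16x24 (384) grid", call. = FALSE)
  r <- 2L * as.integer(parent_row)
  c <- 2L * as.integer(parent_col)
  cbind(row = c(r, r, r + 1L, r + 1L),
        col = c(c, c + 1L, c, c + 1L))
}

#' Generate a complete synthetic induction screen
#'
#' Produces, for each query, induced and uninduced 1536-format plates
#' (tiled over as many plates as the array needs), the array layouts, a
#' screen manifest, and the planted ground truth.  Uninduced colony area is
#' `B_x * T(r,c) * eps`; induced area is `B_x * Wi_q * I_{x,q} * T(r,c) *
#' eps`, with `B_x` the strain's log-normal baseline, `T` a smooth
#' multiplicative surface, `I` the planted interaction factor, and `eps`
#' median-1 log-normal replicate noise.  The stored truth has
#' `true_S = true_wi * (I - 1)` (Wj = 1 by construction unless slow-growing
#' strains are enabled).
#'
#' @param config a [screen_sim_config()].
#' @return A list of class `screen_sim` with elements `plates` (named list
#'   of [plate_grid()]), `layouts` (named list of [array_layout()], one per
#'   plate tile), `manifest` ([screen_manifest()]), `truth` (data frame:
#'   `strain_id`, `query_id`, `true_wi`, `true_factor`, `true_S`,
#'   `true_class`) and `config`.
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  if (config$replicate_count != 4L)
    stop("the quadruplicate 1536 pinning scheme supports exactly 4 ",
         "replicates per strain", call. = FALSE)
  n <- config$n_strains
  n_tiles <- ceiling(n / 384)
  with_seed(config$seed, {
    strains <- sprintf("S%04d", seq_len(n))
    B <- exp(stats::rnorm(n, config$baseline_log_mean,
                          config$baseline_log_sd))
    wj_true <- rep(1, n)
    if (config$slow_strain_fraction > 0) {
      n_slow <- round(config$slow_strain_fraction * n)
      slow <- sample.int(n, n_slow)
      B[slow] <- B[slow] * config$slow_strain_factor
      wj_true[slow] <- config$slow_strain_factor
    }

    # planted interaction factors, control query excluded
    factors <- matrix(1, n, config$n_queries,
                      dimnames = list(strains, config$query_ids))
    if (config$planted_fraction > 0 && config$n_queries > 1) {
      n_pl <- round(config$planted_fraction * n)
      for (q in 2:config$n_queries) {
        idx <- sample.int(n, n_pl)
        rng_pick <- sample.int(length(config$planted_factor_range),
                               n_pl, replace = TRUE)
        lo <- vapply(config$planted_factor_range, `[`, 0, 1)[rng_pick]
        hi <- vapply(config$planted_factor_range, `[`, 0, 2)[rng_pick]
        factors[idx, q] <- stats::runif(n_pl, lo, hi)
      }
    }

    layouts <- list()
    tile_map <- vector("list", n_tiles)   # per tile: strain idx, positions
    for (t in seq_len(n_tiles)) {
      in_tile <- seq.int((t - 1) * 384 + 1, min(t * 384, n))
      parent <- seq_along(in_tile) - 1L
      pr <- parent %/% 24L
      pc <- parent %% 24L
      pos <- do.call(rbind, lapply(seq_along(in_tile), function(j)
        quadruplicate_positions(pr[j], pc[j])))
      strain_idx <- rep(in_tile, each = 4L)
      slot <- rep.int(1:4, length(in_tile))
      border <- pr == 0L | pr == 15L | pc == 0L | pc == 23L
      lid <- sprintf("T%d", t)
      layouts[[lid]] <- array_layout(
        row = pos[, 1], col = pos[, 2],
        strain_id = strains[strain_idx],
        replicate_group = paste0(strains[strain_idx], "_", lid),
        is_border = rep(border, each = 4L),
        slot = slot)
      tile_map[[t]] <- list(idx = strain_idx, pos = pos, slot = slot,
                            lid = lid)
    }

    surface <- spatial_surface(32L, 48L, config$spatial_gradient_amplitude)
    sdlog <- sqrt(log(1 + config$noise_cv^2))

    plates <- list()
    recs <- NULL
    for (q in seq_len(config$n_queries)) {
      qid <- config$query_ids[q]
      wi <- config$induction_effect_per_query[q]
      for (cond in c("induced", "uninduced")) {
        for (t in seq_len(n_tiles)) {
          tm <- tile_map[[t]]
          npos <- nrow(tm$pos)
          nst <- length(unique(tm$idx))
          expected <- B[tm$idx]
          if (cond == "induced")
            expected <- expected * (wi * factors[tm$idx, q])
          eps <- exp(stats::rnorm(npos, 0, sdlog))
          vals <- expected * surface[tm$pos + 1L] * eps
          # single-replicate outlier shocks
          shock_u <- stats::runif(nst)
          shock_slot <- sample.int(4L, nst, replace = TRUE)
          hit <- which(shock_u < config$outlier_prob)
          if (length(hit)) {
            at <- (hit - 1L) * 4L + shock_slot[hit]
            vals[at] <- vals[at] * config$outlier_factor
          }
          miss <- stats::runif(npos) < config$missing_prob
          vals[miss] <- NA_real_
          area <- matrix(NA_real_, 32L, 48L)
          area[tm$pos + 1L] <- vals
          pid <- sprintf("%s_%s_%s", qid, cond, tm$lid)
          plates[[pid]] <- plate_grid(area, plate_id = pid, query_id = qid,
                                      condition = cond)
          recs <- rbind(recs, data.frame(
            query_id = qid, condition = cond, plate_id = pid,
            layout_id = tm$lid, stringsAsFactors = FALSE))
        }
      }
    }

    truth <- data.frame(
      strain_id = rep(strains, config$n_queries),
      query_id = rep(config$query_ids, each = n),
      true_wi = rep(config$induction_effect_per_query, each = n),
      true_wj = rep(wj_true, config$n_queries),
      true_factor = as.vector(factors),
      stringsAsFactors = FALSE)
    truth$true_S <- truth$true_wi * (truth$true_factor - 1)
    truth$true_class <- ifelse(truth$true_factor > 1, "positive",
                               ifelse(truth$true_factor < 1, "negative",
                                      "none"))

    structure(list(plates = plates, layouts = layouts,
                   manifest = screen_manifest(
                     recs, control_query_id = config$query_ids[1]),
                   truth = truth, config = config),
              class = "screen_sim")
  })
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf(paste0("screen_sim: %d strains, %d queries, %d plates; ",
                     "%d planted interactions\n"),
              x$config$n_strains, x$config$n_queries, length(x$plates),
              sum(x$truth$true_factor != 1)))
  invisible(x)
}

#' Write / read a simulated screen to and from disk
#'
#' [write_screen()] writes every plate table, layout and the manifest (plus
#' the truth table, if present) into a directory using the formats of the
#' I/O layer; [read_screen()] loads a manifest and its referenced files
#' back into the in-memory form expected by [score_screen()].
#'
#' @param sim a `screen_sim` (or any list with `plates`, `layouts`,
#'   `manifest` and optionally `truth`).
#' @param dir output directory, created if needed.
#' @return [write_screen()] returns the manifest path invisibly;
#'   [read_screen()] returns a list with `plates`, `layouts`, `manifest`
#'   and, when a truth table is found alongside, `truth`.
#' @export
write_screen <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- sim$manifest$records
  recs$plate_file <- paste0(recs$plate_id, ".tsv")
  recs$layout_file <- paste0("layout_", recs$layout_id, ".tsv")
  for (i in seq_len(nrow(recs)))
    write_plate_table(sim$plates[[recs$plate_id[i]]],
                      file.path(dir, recs$plate_file[i]))
  for (lid in names(sim$layouts))
    write_layout(sim$layouts[[lid]],
                 file.path(dir, paste0("layout_", lid, ".tsv")))
  man <- screen_manifest(recs, sim$manifest$control_query_id)
  path <- file.path(dir, "manifest.json")
  write_manifest(man, path)
  if (!is.null(sim$truth))
    utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen
#' @param manifest_path path to a manifest JSON written by [write_screen()].
#' @export
read_screen <- function(manifest_path) {
  dir <- dirname(manifest_path)
  manifest <- read_manifest(manifest_path)
  recs <- manifest$records
  plates <- list()
  for (i in seq_len(nrow(recs)))
    plates[[recs$plate_id[i]]] <-
      read_plate_table(file.path(dir, recs$plate_file[i]),
                       plate_id = recs$plate_id[i])
  layouts <- list()
  for (lid in unique(recs$layout_id))
    layouts[[lid]] <- read_layout(file.path(
      dir, recs$layout_file[match(lid, recs$layout_id)]))
  out <- list(plates = plates, layouts = layouts, manifest = manifest)
  tp <- file.path(dir, "truth.tsv")
  if (file.exists(tp))
    out$truth <- utils::read.delim(tp, stringsAsFactors = FALSE)
  out
}

# Smooth multiplicative plate surface: bilinear log-gradient whose
# max/min ratio is exactly 1 + amplitude.
spatial_surface <- function(n_rows, n_cols, amplitude) {
  g <- outer(seq_len(n_rows) - 1, seq_len(n_cols) - 1,
             function(r, c) (r / (n_rows - 1) + c / (n_cols - 1)) / 2)
  (1 + amplitude)^(g - 0.5)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}
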