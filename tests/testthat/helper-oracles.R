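# Independent, unoptimized oracle implementations used to cross-check the
# pipeline.  These deliberately re-derive each quantity from its defining
# formula (loops, plain medians) rather than reusing package internals.

# leave-one-out variance-contribution flags, brute force
oracle_jackknife <- function(areas, fraction = 0.9) {
  flags <- rep(FALSE, length(areas))
  x <- areas[!is.na(areas)]
  if (length(x) < 3) return(flags)
  v <- var(x)
  if (v == 0) return(flags)
  contrib <- numeric(length(x))
  for (i in seq_along(x)) contrib[i] <- (v - var(x[-i])) / v
  if (any(contrib > fraction)) {
    winner <- which(contrib == max(contrib))[1]
    flags[which(!is.na(areas))[winner]] <- TRUE
  }
  flags
}

# straight-line recomputation of the median-ratio W statistics from a
# retained-observation table (columns strain_id, query_id, condition, area,
# kept)
oracle_w_triples <- function(obs, query) {
  obs <- obs[!is.na(obs$area) & obs$kept, ]
  strains <- sort(unique(obs$strain_id[obs$query_id == query]))
  ind_all <- obs$area[obs$query_id == query & obs$condition == "induced"]
  unind_all <- obs$area[obs$query_id == query & obs$condition == "uninduced"]
  unind_every <- obs$area[obs$condition == "uninduced"]
  out <- NULL
  for (s in strains) {
    num_ij <- median(obs$area[obs$query_id == query & obs$strain_id == s &
                                obs$condition == "induced"])
    den_ij <- median(obs$area[obs$query_id == query & obs$strain_id == s &
                                obs$condition == "uninduced"])
    num_j <- median(obs$area[obs$strain_id == s &
                               obs$condition == "uninduced"])
    wij <- num_ij / den_ij
    wi <- median(ind_all) / median(unind_all)
    wj <- num_j / median(unind_every)
    out <- rbind(out, data.frame(strain_id = s, wij = wij, wi = wi,
                                 wj = wj, s = wij - wi * wj,
                                 stringsAsFactors = FALSE))
  }
  out
}

# small helper: a plate filled with one value
uniform_plate <- function(value, query = "Q01", condition = "uninduced",
                          id = "P1") {
  plate_grid(matrix(value, 32, 48), plate_id = id, query_id = query,
             condition = condition)
}

# a two-query, single-tile screen small enough for exact checks
tiny_sim <- function(n_strains = 100, seed = 1, ...) {
  generate_screen(screen_sim_config(n_strains = n_strains, n_queries = 2,
                                    seed = seed, ...))
}
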