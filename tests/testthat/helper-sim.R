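# shared fixtures and small oracles, built in code at test time

# tiny config for fast end-to-end runs
tiny_config <- function(seed = 1, ...) {
  args <- list(grid_rows = 6, grid_cols = 6, n_nestboxes = 80,
               n_years = 6, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# analysis table from a simulation using the TRUE nestbox green-up
# (no satellite estimation), one species
truth_table <- function(sim, species = "great_tit") {
  tab <- merge(sim$records,
               sim$truth$nestbox_truth[c("box_id", "year", "greenup_day")],
               by = c("box_id", "year"))
  names(tab)[names(tab) == "greenup_day"] <- "nestbox_greenup"
  tab <- merge(tab, sim$nestboxes[c("box_id", "pixel_id", "x", "y",
                                    "altitude", "edge_distance",
                                    "oak_density_75m")], by = "box_id")
  tab[tab$species == species, , drop = FALSE]
}

# one synthetic pixel-year EVI2 series via the observation path
pixel_year_series <- function(greenup_day, cloud_pct, noise_sd, seed,
                              ...) {
  cfg <- sim_config(obs_noise_sd = noise_sd, seed = seed, ...)
  tg <- data.frame(pixel_id = "p001", year = 2001,
                   greenup_day = greenup_day)
  cl <- data.frame(year = 2001, period = 1:46, cloud_fraction = cloud_pct)
  aggregate_periods(generate_observations(cfg, tg, cl))
}

# independent Pearson oracle (plain formula, no cor())
pearson_oracle <- function(x, y) {
  xd <- x - mean(x); yd <- y - mean(y)
  sum(xd * yd) / sqrt(sum(xd^2) * sum(yd^2))
}

# all permutations of 1..n (for the exact Mantel oracle)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# exact Mantel correlogram p-values by full enumeration of site
# permutations (two-sided on |r|, counting the identity)
mantel_exact_p <- function(coords, values, class_edges) {
  n <- nrow(coords)
  cg <- mantel_correlogram(coords, values, class_edges = class_edges,
                           n_perm = 9, seed = 1)
  dgeo <- as.vector(stats::dist(coords))
  nc <- length(class_edges) - 1
  eps <- 1e-9 * max(1, abs(class_edges[nc + 1]))
  cls <- findInterval(dgeo, c(class_edges[1:nc], class_edges[nc + 1] + eps))
  cls[cls < 1 | cls > nc] <- NA
  full <- as.matrix(stats::dist(values))
  low <- lower.tri(full)
  stat <- function(dv, k) {
    ind <- as.numeric(cls == k); ind[is.na(cls)] <- 0
    if (stats::sd(dv) < 1e-12 || stats::sd(ind) < 1e-12) return(NA_real_)
    -pearson_oracle(dv, ind)
  }
  perms <- all_perms(n)
  sapply(seq_len(nc), function(k) {
    r_obs <- stat(full[low], k)
    if (!is.finite(r_obs)) return(NA_real_)
    r_all <- apply(perms, 1, function(p) stat(full[p, p][low], k))
    mean(abs(r_all) >= abs(r_obs) - 1e-12)
  })
}
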