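# Independent oracles, deliberately written against the definitions rather
# than the package's code paths.

# even-odd ray-casting containment, scalar, horizontal ray to the west
oracle_point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  if (ring[1, 1] == ring[n, 1] && ring[1, 2] == ring[n, 2]) n <- n - 1
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# spherical law-of-haversines, scalar, R = 6371.0088 km
oracle_haversine_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371.0088 * asin(pmin(1, sqrt(a)))
}

# exact-rational per-cell WE oracle via integer lcm arithmetic; valid while
# lcm of the range sizes stays below 2^53 (range sizes <= 40 here)
oracle_gcd <- function(a, b) if (b == 0) a else oracle_gcd(b, a %% b)
oracle_lcm <- function(a, b) a / oracle_gcd(a, b) * b

# brute-force double loop over (species, cell) pairs
oracle_grid_metrics <- function(presence_df) {
  # presence_df: taxon_id, cell_i, cell_j (binary presence rows)
  range_size <- table(presence_df$taxon_id)
  cells <- unique(presence_df[, c("cell_i", "cell_j")])
  out <- data.frame(cell_i = cells$cell_i, cell_j = cells$cell_j,
                    SR = NA_integer_, WE = NA_real_, CWE = NA_real_)
  for (r in seq_len(nrow(cells))) {
    sp <- presence_df$taxon_id[presence_df$cell_i == cells$cell_i[r] &
                                 presence_df$cell_j == cells$cell_j[r]]
    cs <- as.integer(range_size[sp])
    denom <- Reduce(oracle_lcm, cs)
    num <- sum(denom / cs)        # exact integers below 2^53
    out$SR[r] <- length(sp)
    out$WE[r] <- num / denom
    out$CWE[r] <- num / denom / length(sp)
  }
  out[order(out$cell_j, out$cell_i), ]
}

# closed-form simple OLS via normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / (sxx - sx^2 / n))
  tstat <- slope / se
  list(slope = slope, intercept = intercept,
       r = (n * sxy - sx * sy) /
         sqrt((n * sxx - sx^2) * (n * sum(y * y) - sy^2)),
       p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# small fully hand-checkable checklist
toy_checklist <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3", "t4", "t5", "t6"),
    accepted_name = c("Genus1 a", "Genus1 b", "Genus2 c", "Genus3 d",
                      "Genus4 e", "Genus4 f"),
    family = c("FamA", "FamA", "FamA", "FamB", "FamC", "FamC"),
    genus = c("Genus1", "Genus1", "Genus2", "Genus3", "Genus4", "Genus4"),
    native = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    endemic = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    naturalised = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    cultivated = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    locally_reported = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    growth_habits = c("tree", "tree|shrub", "herb", "climber", "tree",
                      "shrub"),
    in_crop_census = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    is_nus = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
}
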