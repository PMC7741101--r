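# Independent brute-force oracles and shared fixtures.

# Five-point toy curve used for direct-evaluation calibration checks.
toy_curve5 <- function() {
  cal_curve(c(0, 10, 20, 30, 40), c(50, 80, 90, 150, 200),
            c(5, 5, 10, 5, 5), name = "toy5")
}

# Rank-and-threshold HPD oracle: pick years by descending mass (ties to
# older years) until the running total reaches `level`; return the years.
oracle_hpd_years <- function(grid, mass, level) {
  o <- order(-mass, -grid)
  k <- which(cumsum(mass[o]) >= level - 1e-12)[1]
  sort(grid[o[seq_len(k)]], decreasing = TRUE)
}

# Transitive-closure connected-components oracle for single-linkage
# binning: edge between any two dates with |key_i - key_j| <= h, then
# breadth-first components.
oracle_components <- function(keys, h) {
  n <- length(keys)
  adj <- abs(outer(keys, keys, "-")) <= h
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- which(adj[frontier[1], ] & is.na(comp))
      comp[nb] <- cur
      frontier <- c(frontier[-1], nb)
    }
  }
  comp
}

# Contaminant-free simulation settings.
no_contaminants <- function() {
  list(non_archaeological = 0L, sigma_outlier = 0L,
       duplicate_conflict = 0L, exact_duplicate = 0L,
       out_of_area = 0L, out_of_window = 0L, noncutting_symbol = 0L,
       treering_out_of_area = 0L, treering_out_of_window = 0L)
}

# Small clean radiocarbon table for filter tests (all in-area, precise,
# archaeological, mid-window ages).
clean_rc_table <- function(n = 4, county = "Montezuma", state = "CO") {
  data.frame(lab_number = sprintf("CLN-%03d", seq_len(n)),
             site_id = sprintf("S%02d", seq_len(n)),
             county = rep(county, n), state = rep(state, n),
             c14_age = seq(800, by = 60, length.out = n),
             sigma = rep(30, n), is_archaeological = rep(TRUE, n),
             stringsAsFactors = FALSE)
}
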