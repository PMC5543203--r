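# Hand-built cell maps and independent oracles shared across tests.

# Build a cellmap directly from a nuclei data frame (bypasses the generator,
# so tests can state exact geometry).
make_map <- function(nuclei, width = 400, height = 400,
                     microns_per_pixel = 1, stain_contrast = 1) {
  nuclei$id <- seq_len(nrow(nuclei))
  if (is.null(nuclei$stain_od))
    nuclei$stain_od <- ifelse(nuclei$ki67_positive, 1.0, 0.05)
  tum <- nuclei$cell_class == "invasive_tumor"
  structure(list(width = width, height = height,
                 microns_per_pixel = microns_per_pixel,
                 nuclei = nuclei, seed = NA_integer_,
                 true_ki67_fraction = if (any(tum))
                   mean(nuclei$ki67_positive[tum]) else NA_real_,
                 degenerate = !any(tum), streaming = FALSE,
                 stain_contrast = stain_contrast, config = NULL),
            class = "cellmap")
}

# n nuclei on a regular grid with the given spacing (well separated)
separated_nuclei <- function(n, n_pos, spacing = 20, radius = 4,
                            cell_class = "invasive_tumor", x0 = 10) {
  per_row <- floor((400 - 2 * x0) / spacing) + 1
  idx <- seq_len(n) - 1
  data.frame(x = x0 + (idx %% per_row) * spacing,
             y = x0 + (idx %/% per_row) * spacing,
             radius = radius, cell_class = cell_class,
             ki67_positive = seq_len(n) <= n_pos,
             stringsAsFactors = FALSE)
}

# brute-force oracle: count nuclei whose disk meets any counting line
oracle_line_count <- function(map, lines) {
  nuc <- map$nuclei[map$nuclei$cell_class == "invasive_tumor", ]
  hit <- vapply(seq_len(nrow(nuc)), function(i)
    any(abs(nuc$y[i] - lines) <= nuc$radius[i]), logical(1))
  c(total = sum(hit), positive = sum(hit & nuc$ki67_positive))
}

# brute-force 2x2 cross-classification by double loop
oracle_contingency <- function(pairs, cut) {
  a <- b <- c2 <- d <- 0L
  for (i in seq_len(nrow(pairs))) {
    pa <- pairs$score_a[i] > cut
    pb <- pairs$score_b[i] > cut
    if (pa && pb) a <- a + 1L
    else if (pa && !pb) b <- b + 1L
    else if (!pa && pb) c2 <- c2 + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c2, d = d)
}

# brute-force AUC by pair counting with half credit for ties
oracle_auc <- function(pos, values) {
  vp <- values[pos]; vn <- values[!pos]
  s <- 0
  for (p in vp) s <- s + sum(p > vn) + 0.5 * sum(p == vn)
  s / (length(vp) * length(vn))
}

# brute-force log-rank: explicit risk-set table
oracle_logrank <- function(times, events, g1) {
  ts <- sort(unique(times[events]))
  num <- 0; den <- 0
  for (t in ts) {
    n_t <- sum(times >= t); n1 <- sum(times >= t & g1)
    d <- sum(times == t & events); d1 <- sum(times == t & events & g1)
    num <- num + d1 - d * n1 / n_t
    if (n_t > 1)
      den <- den + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  num^2 / den
}
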