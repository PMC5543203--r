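#' Nuclei detection on a rendered H-DAB field
#'
#' Transparent stand-in for a commercial Ki-67 image-analysis algorithm:
#' the RGB image is color-deconvolved into hematoxylin and DAB optical
#' densities (Beer-Lambert, fixed H-DAB stain vectors), a nuclear mask is
#' thresholded, 4-connected components are labelled and size-filtered, and a
#' component is called Ki-67 positive iff its mean DAB density is at least
#' `od_threshold`. All parameters are explicit; the SOP logic around this
#' detector, not the detector itself, is the validated object.
#'
#' @param image numeric array h x w x 3 in \[0,1\] (see [render_field()]).
#' @param od_threshold mean DAB OD for positivity (default 0.3).
#' @param nuclear_threshold total nuclear OD for the mask (default 0.25).
#' @param min_size,max_size component size filter in pixels; the default
#'   minimum (25 px) drops lymphocyte-sized nuclei.
#' @return data frame with one row per detected nucleus: x, y (centroid,
#'   0-based), size_px, mean_dab, positive. Zero rows on a blank image.
#' @export
detect_nuclei <- function(image, od_threshold = 0.3,
                          nuclear_threshold = 0.25,
                          min_size = 25, max_size = 400) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  od <- -log10(pmax(image, 1e-3))
  odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
               as.vector(od[, , 3]))
  conc <- odm %*% t(solve(stain_matrix()))     # columns: hema, dab, residual
  hema <- matrix(conc[, 1], h, w)
  dab  <- matrix(conc[, 2], h, w)
  mask <- (hema > nuclear_threshold) | (dab > nuclear_threshold)
  lab <- label_components(mask)
  if (lab$n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), size_px = integer(0),
                      mean_dab = numeric(0), positive = logical(0)))
  px <- which(lab$labels > 0L)
  comp <- lab$labels[px]
  size <- tabulate(comp, lab$n)
  sum_dab <- as.vector(rowsum(dab[px], comp))
  cx <- as.vector(rowsum(((px - 1L) %/% h), comp)) / size   # 0-based col
  cy <- as.vector(rowsum(((px - 1L) %% h), comp)) / size    # 0-based row
  keep <- size >= min_size & size <= max_size
  out <- data.frame(x = cx[keep], y = cy[keep],
                    size_px = size[keep],
                    mean_dab = (sum_dab / size)[keep])
  out$positive <- out$mean_dab >= od_threshold
  out
}

# 4-connected component labelling of a logical matrix by row runs +
# union-find; pure R, linear in the number of runs.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  runs_row <- integer(0); runs_s <- integer(0); runs_e <- integer(0)
  for (r in seq_len(h)) {
    v <- mask[r, ]
    if (!any(v)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    on <- rl$values
    runs_row <- c(runs_row, rep(r, sum(on)))
    runs_s <- c(runs_s, starts[on])
    runs_e <- c(runs_e, ends[on])
  }
  nr <- length(runs_row)
  if (nr == 0L)
    return(list(labels = matrix(0L, h, w), n = 0L))
  parent <- seq_len(nr)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # runs are emitted in row order; merge overlapping runs of adjacent rows
  row_start <- match(seq_len(h), runs_row)
  for (r in which(!is.na(row_start))) {
    if (r == 1L) next
    prev <- which(runs_row == r - 1L)
    if (length(prev) == 0L) next
    cur <- which(runs_row == r)
    i <- 1L; j <- 1L
    while (i <= length(prev) && j <= length(cur)) {
      a <- prev[i]; b <- cur[j]
      if (runs_s[a] <= runs_e[b] && runs_s[b] <= runs_e[a]) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
      if (runs_e[a] < runs_e[b]) i <- i + 1L else j <- j + 1L
    }
  }
  root <- vapply(seq_len(nr), find, integer(1))
  lab_of_root <- integer(nr)
  uroots <- unique(root)
  lab_of_root[uroots] <- seq_along(uroots)
  labels <- matrix(0L, h, w)
  for (k in seq_len(nr))
    labels[runs_row[k], runs_s[k]:runs_e[k]] <- lab_of_root[root[k]]
  list(labels = labels, n = length(uroots))
}
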