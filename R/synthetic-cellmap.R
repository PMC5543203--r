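#' Histology field configuration
#'
#' Parameters of the synthetic microscopic field generator. Confounder
#' prevalences are expected counts per class expressed as a multiple of the
#' invasive tumor cell count; the lymphocyte infiltration level inflates the
#' lymphocyte prevalence, and the streaming probability governs the
#' sparse-streaming-tumor failure mode (tumor density collapses, fibroblasts
#' triple).
#'
#' @param tumor_density invasive tumor cells per mm^2.
#' @param confounder_prevalences named vector over
#'   dcis, lymphocyte, fibroblast, endothelial, necrotic_debris.
#' @param lymphocyte_infiltration_level \[0,1\]; adds `1.5 * level` to the
#'   lymphocyte prevalence so levels above ~0.25 push the lymphocyte nuclear
#'   fraction past the 0.3 triage threshold.
#' @param streaming_prob probability that the field is sparse/streaming.
#' @param stain_contrast \[0,1\]; 1 = crisp DAB, values below ~0.3 emulate
#'   faint diffuse staining.
#' @param fibroblast_stained_frac fraction of fibroblasts spuriously
#'   DAB-marked ("plump" fibroblast artifact).
#' @param width,height field size in pixels.
#' @param microns_per_pixel scale, default 1.
#' @param theta target Ki-67 positive fraction among invasive tumor cells.
#' @return object of class `histology_config`.
#' @export
histology_config <- function(tumor_density = 1800,
                             confounder_prevalences = c(
                               dcis = 0.05, lymphocyte = 0.15,
                               fibroblast = 0.10, endothelial = 0.03,
                               necrotic_debris = 0.02),
                             lymphocyte_infiltration_level = 0,
                             streaming_prob = 0,
                             stain_contrast = 1,
                             fibroblast_stained_frac = 0.05,
                             width = 400, height = 400,
                             microns_per_pixel = 1,
                             theta = 0.10) {
  assert_prob(lymphocyte_infiltration_level, "lymphocyte_infiltration_level")
  assert_prob(streaming_prob, "streaming_prob")
  assert_prob(stain_contrast, "stain_contrast")
  assert_prob(fibroblast_stained_frac, "fibroblast_stained_frac")
  assert_prob(theta, "theta")
  if (tumor_density < 0) stop_ki67("tumor_density must be >= 0",
                                   "ki67cta_config_error")
  classes <- c("dcis", "lymphocyte", "fibroblast", "endothelial",
               "necrotic_debris")
  prev <- confounder_prevalences[classes]
  prev[is.na(prev)] <- 0
  names(prev) <- classes
  if (any(prev < 0)) stop_ki67("prevalences must be >= 0",
                               "ki67cta_config_error")
  structure(list(tumor_density = tumor_density,
                 confounder_prevalences = prev,
                 lymphocyte_infiltration_level = lymphocyte_infiltration_level,
                 streaming_prob = streaming_prob,
                 stain_contrast = stain_contrast,
                 fibroblast_stained_frac = fibroblast_stained_frac,
                 width = width, height = height,
                 microns_per_pixel = microns_per_pixel,
                 theta = theta),
            class = "histology_config")
}

# DAB optical-density floor below which a nucleus cannot be Ki-67 positive.
POSITIVE_OD_FLOOR <- 0.5

# Hard-core site lattice: jittered grid sites, no two centers closer than
# cell - 2*jitter, which with the radius cap keeps rendered disks disjoint.
site_lattice <- function(width, height, cell = 12, jitter = 1.5) {
  nx <- floor(width / cell); ny <- floor(height / cell)
  gx <- rep(seq_len(nx) - 1L, times = ny)
  gy <- rep(seq_len(ny) - 1L, each = nx)
  n <- nx * ny
  data.frame(
    x = pmin(width - 1, gx * cell + cell / 2 + stats::runif(n, -jitter, jitter)),
    y = pmin(height - 1, gy * cell + cell / 2 + stats::runif(n, -jitter, jitter)))
}

# Allocate sites to classes. DCIS, necrosis and lymphocytes form spatial
# clusters (as in tissue); tumor, fibroblasts and endothelium are scattered.
CLUSTERED <- c(dcis = 30, necrotic_debris = 20, lymphocyte = 40)  # sigma px

allocate_sites <- function(sites, counts, width, height) {
  avail <- seq_len(nrow(sites))
  out <- vector("list", length(counts))
  names(out) <- names(counts)
  for (cls in names(CLUSTERED)) {
    n_c <- min(counts[[cls]] %||% 0L, length(avail))
    if (n_c == 0L) { out[[cls]] <- integer(0); next }
    k <- if (cls == "lymphocyte") stats::rpois(1, 1.5) + 1L else 1L
    cx <- stats::runif(k, 0, width); cy <- stats::runif(k, 0, height)
    s <- CLUSTERED[[cls]]
    w <- rep(1e-8, length(avail))
    for (j in seq_len(k))
      w <- w + exp(-((sites$x[avail] - cx[j])^2 +
                     (sites$y[avail] - cy[j])^2) / (2 * s^2))
    pick <- avail[sample.int(length(avail), n_c, prob = w)]
    out[[cls]] <- pick
    avail <- setdiff(avail, pick)
  }
  scattered <- setdiff(names(counts), names(CLUSTERED))
  n_rest <- vapply(counts[scattered], function(x) as.integer(x), integer(1))
  n_tot <- min(sum(n_rest), length(avail))
  if (sum(n_rest) > n_tot)                       # capacity cap: thin evenly
    n_rest <- diff(round(c(0, cumsum(n_rest)) * n_tot / sum(n_rest)))
  pick <- if (n_tot > 0) avail[sample.int(length(avail), n_tot)] else integer(0)
  idx <- split(pick, rep(seq_along(n_rest), n_rest))
  for (i in seq_along(scattered))
    out[[scattered[i]]] <- idx[[as.character(i)]] %||% integer(0)
  out
}

#' Generate a synthetic cell map
#'
#' Draws invasive tumor nuclei at the configured density, Ki-67 positivity
#' i.i.d. Bernoulli(theta), and confounder nuclei per class prevalence.
#' Streaming fields (Bernoulli of `streaming_prob`) collapse tumor density to
#' 2.5% of nominal and triple the fibroblast prevalence. The realized tumor
#' Ki-67 fraction is recorded as ground truth.
#'
#' @param config a [histology_config()].
#' @param seed integer seed; the map is bit-reproducible given (config, seed).
#' @return object of class `cellmap`: width/height, microns_per_pixel, a
#'   nuclei data frame (id, x, y, radius, cell_class, ki67_positive,
#'   stain_od), `true_ki67_fraction`, and a `degenerate` flag set when the
#'   tumor compartment is empty (fraction then NA, never silently 0).
#' @export
generate_cellmap <- function(config, seed) {
  stopifnot(inherits(config, "histology_config"))
  set.seed(seed)
  area_mm2 <- (config$width * config$microns_per_pixel / 1000) *
              (config$height * config$microns_per_pixel / 1000)
  streaming <- stats::runif(1) < config$streaming_prob
  density <- config$tumor_density * if (streaming) 0.015 else 1
  n_tumor <- stats::rpois(1, density * area_mm2)

  prev <- config$confounder_prevalences
  prev["lymphocyte"] <- prev["lymphocyte"] +
    1.5 * config$lymphocyte_infiltration_level
  if (streaming) prev["fibroblast"] <- prev["fibroblast"] * 3
  # prevalences are relative to the *nominal* tumor compartment so that a
  # streaming field is sparse in tumor but not in stroma
  lam_ref <- config$tumor_density * area_mm2
  counts <- lapply(prev, function(p) stats::rpois(1, p * lam_ref))
  counts$invasive_tumor <- n_tumor

  sites <- site_lattice(config$width, config$height)
  alloc <- allocate_sites(sites, counts, config$width, config$height)
  classes <- rep(names(alloc), lengths(alloc))
  xy <- sites[unlist(alloc, use.names = FALSE), , drop = FALSE]

  n <- length(classes)
  pos <- logical(n)
  is_tum  <- classes == "invasive_tumor"
  is_dcis <- classes == "dcis"
  is_lym  <- classes == "lymphocyte"
  is_fib  <- classes == "fibroblast"
  is_endo <- classes == "endothelial"
  pos[is_tum]  <- stats::runif(sum(is_tum)) < config$theta
  pos[is_dcis] <- stats::runif(sum(is_dcis)) < config$theta
  pos[is_lym]  <- stats::runif(sum(is_lym)) < 0.05
  pos[is_fib]  <- stats::runif(sum(is_fib)) < config$fibroblast_stained_frac
  pos[is_endo] <- stats::runif(sum(is_endo)) < 0.02

  radius <- pmin(4.2, pmax(2, stats::rlnorm(n, log(3.6), 0.12)))
  radius[is_lym] <- pmin(radius[is_lym], 2.5)     # lymphocytes are small
  od <- stats::runif(n, 0.02, 0.15)               # background DAB
  od[pos] <- stats::runif(sum(pos), POSITIVE_OD_FLOOR + 0.3, 1.4)

  nuclei <- data.frame(id = seq_len(n),
                       x = xy$x, y = xy$y,
                       radius = radius,
                       cell_class = classes,
                       ki67_positive = pos,
                       stain_od = od,
                       stringsAsFactors = FALSE)
  rownames(nuclei) <- NULL

  tum <- nuclei$cell_class == "invasive_tumor"
  frac <- if (any(tum)) mean(nuclei$ki67_positive[tum]) else NA_real_
  structure(list(width = config$width, height = config$height,
                 microns_per_pixel = config$microns_per_pixel,
                 nuclei = nuclei, seed = seed,
                 true_ki67_fraction = frac,
                 degenerate = !any(tum),
                 streaming = streaming,
                 stain_contrast = config$stain_contrast,
                 config = config),
            class = "cellmap")
}

#' @export
print.cellmap <- function(x, ...) {
  cat(sprintf("<cellmap %dx%d px, %d nuclei, tumor Ki-67 fraction %s%s>\n",
              x$width, x$height, nrow(x$nuclei),
              ifelse(is.na(x$true_ki67_fraction), "NA",
                     sprintf("%.3f", x$true_ki67_fraction)),
              if (x$degenerate) ", DEGENERATE (no tumor)" else ""))
  invisible(x)
}

# H-DAB stain vectors (unit optical-density directions) and their inverse,
# shared by the renderer and the deconvolution detector.
stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- cbind(h / sqrt(sum(h^2)), d / sqrt(sum(d^2)), r / sqrt(sum(r^2)))
  colnames(m) <- c("hema", "dab", "res")
  m
}

#' Render a cell map as an RGB field image
#'
#' Beer-Lambert rendering: every nucleus contributes hematoxylin optical
#' density over its disk; Ki-67 positive nuclei add DAB density
#' `stain_od * stain_contrast`. Deterministic given the map.
#'
#' @param map a [generate_cellmap()] result.
#' @param stain_contrast in (0,1\]; defaults to the map's own contrast.
#' @return numeric array height x width x 3 with values in \[0,1\]
#'   (RGB, origin top-left, 0-based pixel coordinates).
#' @export
render_field <- function(map, stain_contrast = map$stain_contrast) {
  stopifnot(inherits(map, "cellmap"))
  if (!is.numeric(stain_contrast) || stain_contrast <= 0)
    stop_ki67("stain_contrast must be > 0", "ki67cta_config_error")
  h <- map$height; w <- map$width
  od_h <- matrix(0, h, w)
  od_d <- matrix(0, h, w)
  nuc <- map$nuclei
  for (i in seq_len(nrow(nuc))) {
    px <- disk_pixels(nuc$x[i], nuc$y[i], nuc$radius[i], w, h)
    od_h[px] <- od_h[px] + 0.65
    if (nuc$ki67_positive[i])
      od_d[px] <- od_d[px] + nuc$stain_od[i] * stain_contrast
  }
  m <- stain_matrix()
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- 10^(-(od_h * m[ch, "hema"] + od_d * m[ch, "dab"]))
  img
}

# linear indices (row-major into an h x w matrix) of the disk at (x, y);
# x,y are 0-based image coordinates, matrix rows are y+1, cols x+1
disk_pixels <- function(x, y, r, w, h) {
  x0 <- max(0, floor(x - r)); x1 <- min(w - 1, ceiling(x + r))
  y0 <- max(0, floor(y - r)); y1 <- min(h - 1, ceiling(y + r))
  xs <- x0:x1; ys <- y0:y1
  g <- expand.grid(yy = ys, xx = xs)
  inside <- (g$xx - x)^2 + (g$yy - y)^2 <= r^2
  (g$xx[inside]) * h + g$yy[inside] + 1L
}
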