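#' Select areas of interest on a cell map
#'
#' Greedy tiling follows the scoring guidelines: candidate axis-aligned
#' windows are ranked by invasive-tumor cell count; windows overlapping
#' DCIS-dominant or necrotic zones, or dominated by lymphocytes, are
#' rejected; between `min_aois` and `max_aois` windows are returned.
#' Deterministic given the map and the window grid offset.
#'
#' @param map a `cellmap` with invasive tumor.
#' @param min_aois,max_aois bounds on the number of AOIs (default 3 and 10).
#' @param window window side in pixels (default 100).
#' @param window_offset `c(ox, oy)` origin of the tiling grid, pixels.
#' @return object of class `aoi_set`: list of AOIs (x0, y0, x1, y1, area_px,
#'   n_tumor, n_positive_tumor, exclusion flags); or an object of class
#'   `aoi_failure` when fewer than `min_aois` clean windows exist.
#' @export
select_aois <- function(map, min_aois = 3, max_aois = 10, window = 100,
                        window_offset = c(0, 0)) {
  stopifnot(inherits(map, "cellmap"))
  nuc <- map$nuclei
  ox <- floor(window_offset[1]) %% window
  oy <- floor(window_offset[2]) %% window
  xs <- seq(ox, map$width - window, by = window)
  ys <- seq(oy, map$height - window, by = window)
  if (length(xs) == 0 || length(ys) == 0)
    return(structure(list(reason = "field smaller than one window"),
                     class = "aoi_failure"))
  cand <- list()
  for (x0 in xs) for (y0 in ys) {
    inw <- nuc$x >= x0 & nuc$x < x0 + window &
           nuc$y >= y0 & nuc$y < y0 + window
    cls <- nuc$cell_class[inw]
    n_all <- length(cls)
    n_tum <- sum(cls == "invasive_tumor")
    excl <- c(
      dcis            = sum(cls == "dcis") > 0.05 * n_all,
      necrotic        = sum(cls == "necrotic_debris") > 0.05 * n_all,
      lymphocyte_zone = sum(cls == "lymphocyte") > 0.3 * max(n_all, 1L),
      vessel          = sum(cls == "endothelial") > 0.2 * max(n_all, 1L))
    cand[[length(cand) + 1L]] <- list(
      x0 = x0, y0 = y0, x1 = x0 + window, y1 = y0 + window,
      area_px = window^2, n_tumor = n_tum,
      n_positive_tumor = sum(nuc$ki67_positive[inw] &
                               cls == "invasive_tumor"),
      exclusion = excl)
  }
  clean <- Filter(function(a) !any(a$exclusion) && a$n_tumor > 0, cand)
  if (length(clean) < min_aois)
    return(structure(list(reason = sprintf(
      "only %d clean candidate windows (need >= %d)", length(clean), min_aois)),
      class = "aoi_failure"))
  ord <- order(vapply(clean, `[[`, numeric(1), "n_tumor"), decreasing = TRUE)
  structure(clean[ord[seq_len(min(max_aois, length(clean)))]],
            class = "aoi_set")
}

#' Triage thresholds
#'
#' Quantitative stand-ins for the qualitative algorithm-failure conditions:
#' abundant lymphocyte infiltration, sparse streaming tumor, abundant
#' marking of plump fibroblasts, and faint diffuse staining. Defaults are
#' calibrated so the default synthetic case mixture triages about 17% of
#' cases to VPC.
#'
#' @param lymphocyte_fraction flag when the lymphocyte nuclear fraction
#'   exceeds this (default 0.3).
#' @param tumor_density flag when invasive tumor density falls below this,
#'   cells/mm^2 (default 50).
#' @param fibroblast_stained_fraction flag when the DAB-marked fibroblast
#'   fraction exceeds this (default 0.2).
#' @param stain_contrast flag when contrast falls below this (default 0.3).
#' @return named list of thresholds.
#' @export
triage_thresholds <- function(lymphocyte_fraction = 0.3,
                              tumor_density = 50,
                              fibroblast_stained_fraction = 0.2,
                              stain_contrast = 0.3) {
  as.list(environment())
}

#' Field statistics used by triage
#'
#' @param map a `cellmap`.
#' @return list: lymphocyte_fraction, tumor_density (cells/mm^2),
#'   fibroblast_stained_fraction, stain_contrast.
#' @export
map_statistics <- function(map) {
  stopifnot(inherits(map, "cellmap"))
  nuc <- map$nuclei
  n <- nrow(nuc)
  area_mm2 <- (map$width * map$microns_per_pixel / 1000) *
              (map$height * map$microns_per_pixel / 1000)
  fib <- nuc$cell_class == "fibroblast"
  list(lymphocyte_fraction =
         if (n == 0) 0 else mean(nuc$cell_class == "lymphocyte"),
       tumor_density = sum(nuc$cell_class == "invasive_tumor") / area_mm2,
       fibroblast_stained_fraction =
         if (!any(fib)) 0 else mean(nuc$ki67_positive[fib]),
       stain_contrast = map$stain_contrast)
}

#' Triage decision from field statistics
#'
#' Each flag is its statistic compared to its threshold; the case is routed
#' to VPC iff any flag is set, otherwise to image analysis.
#'
#' @param stats list as returned by [map_statistics()].
#' @param thresholds a [triage_thresholds()] list.
#' @return object of class `triage_decision`: named logical `flags`
#'   (lymphocyte_rich, sparse_streaming_tumor, fibroblast_marking,
#'   faint_diffuse_stain) and `route` ("IMAGE" or "VPC").
#' @export
triage_flags <- function(stats, thresholds = triage_thresholds()) {
  flags <- c(
    lymphocyte_rich = stats$lymphocyte_fraction >
      thresholds$lymphocyte_fraction,
    sparse_streaming_tumor = stats$tumor_density < thresholds$tumor_density,
    fibroblast_marking = stats$fibroblast_stained_fraction >
      thresholds$fibroblast_stained_fraction,
    faint_diffuse_stain = stats$stain_contrast < thresholds$stain_contrast)
  structure(list(flags = flags,
                 route = if (any(flags)) "VPC" else "IMAGE"),
            class = "triage_decision")
}

#' Score one case by the combined imaging/VPC standard operating procedure
#'
#' The scanned-slide stand-in (the first map) is triaged on its field
#' statistics. Image-routed cases are scored by rendering the field,
#' selecting AOIs and running the stand-in detector over them (percent =
#' 100 x detected positives / detected nuclei across AOIs); AOI failure or
#' an empty detection falls through to VPC. VPC-routed cases are scored by
#' [vpc_score()] over all available fields. A case with no tumor anywhere
#' raises an undefined-score error.
#'
#' @param maps list of `cellmap`s for the case (first = scanned section).
#' @param case_id id string carried into the result.
#' @param thresholds [triage_thresholds()].
#' @param spec [grid_spec()] for the VPC fallback.
#' @param seed rater seed: drives VPC field selection and, when
#'   `rater_jitter` is TRUE, the AOI window-grid offset, so two raters with
#'   different seeds draw different AOIs.
#' @param od_threshold detector positivity threshold.
#' @param min_cells,n_fields VPC accumulation rules.
#' @param rater_jitter jitter the AOI grid per rater (default TRUE).
#' @param image optional pre-rendered field (h x w x 3) to avoid
#'   re-rendering when scoring the same case for several raters.
#' @return object of class `sop_result`: case_id, route, `ki67_score`,
#'   triage flags, AOIs used (or NULL).
#' @export
sop_score <- function(maps, case_id = "case", thresholds = triage_thresholds(),
                      spec = grid_spec(), seed = 1L, od_threshold = 0.3,
                      min_cells = 200, n_fields = 3, rater_jitter = TRUE,
                      image = NULL) {
  if (inherits(maps, "cellmap")) maps <- list(maps)
  stopifnot(length(maps) >= 1)
  slide <- maps[[1]]
  dec <- triage_flags(map_statistics(slide), thresholds)
  flags <- dec$flags
  aois <- NULL
  route <- dec$route
  score <- NULL
  if (route == "IMAGE") {
    off <- c(0, 0)
    if (rater_jitter) {
      set.seed(child_seed(seed, "aoi_offset"))
      off <- floor(stats::runif(2, 0, 100))
    }
    aois <- select_aois(slide, window_offset = off)
    if (inherits(aois, "aoi_failure")) {
      route <- "VPC"
      flags <- c(flags, aoi_failure = TRUE)
      aois <- NULL
    } else {
      img <- image %||% render_field(slide)
      tot <- 0L; pos <- 0L
      for (a in aois) {
        crop <- img[(a$y0 + 1):a$y1, (a$x0 + 1):a$x1, , drop = FALSE]
        det <- detect_nuclei(crop, od_threshold = od_threshold)
        tot <- tot + nrow(det)
        pos <- pos + sum(det$positive)
      }
      if (tot == 0L) {                       # detector failure
        route <- "VPC"
        flags <- c(flags, detector_failure = TRUE)
      } else {
        score <- ki67_score(100 * pos / tot, "IMAGE",
                            list(detected = tot, positive = pos,
                                 n_aois = length(aois)))
      }
    }
  }
  if (route == "VPC")
    score <- vpc_score(maps, spec, min_cells = min_cells,
                       n_fields = n_fields, seed = seed)
  structure(list(case_id = case_id, route = route, score = score,
                 flags = flags, aois = aois),
            class = "sop_result")
}
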