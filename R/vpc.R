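#' Counting grid specification
#'
#' Horizontal grid lines at `offset, offset + spacing, ...`; counting is done
#' on every `count_every`-th line starting from the first (the line at the
#' offset), mirroring the printed-photomicrograph protocol of counting on the
#' first grid line and then every third one.
#'
#' @param line_spacing pixels between consecutive grid lines (> 0). The
#'   package default, 4x the median nucleus diameter of the synthetic maps
#'   (about 29 px), approximates systematic uniform random sampling.
#' @param offset pixels in \[0, spacing).
#' @param count_every count on every k-th line (default 3).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(line_spacing = 29, offset = 0, count_every = 3) {
  if (line_spacing <= 0) stop_ki67("line_spacing must be > 0",
                                   "ki67cta_config_error")
  if (offset < 0 || offset >= line_spacing)
    stop_ki67("offset must be in [0, spacing)", "ki67cta_config_error")
  if (count_every < 1) stop_ki67("count_every must be >= 1",
                                 "ki67cta_config_error")
  structure(list(line_spacing = line_spacing, offset = offset,
                 count_every = as.integer(count_every)),
            class = "grid_spec")
}

#' Counting-line ordinates for a field
#'
#' @param extent `c(width, height)` in pixels.
#' @param spec a [grid_spec()].
#' @return numeric vector of y ordinates of the counting lines (0-based,
#'   origin top-left); attribute `degenerate` is TRUE when the spacing
#'   admits at most one line in the field.
#' @export
grid_lines <- function(extent, spec) {
  stopifnot(inherits(spec, "grid_spec"), length(extent) == 2)
  height <- extent[2]
  step <- spec$line_spacing * spec$count_every
  # avoid seq()'s fuzz at the upper end: ordinates strictly inside the field
  k <- floor((height - spec$offset - 1e-9) / step)
  ord <- if (spec$offset > height - 1e-9) numeric(0)
         else spec$offset + step * (0:k)
  if (length(ord) == 0 || spec$line_spacing >= height)
    attr(ord, "degenerate") <- TRUE
  ord
}

#' Count tumor cells intersecting counting lines
#'
#' A nucleus is counted iff its disk intersects a counting line, i.e.
#' `|y_center - line| <= radius` (exact tangency counts); only invasive
#' tumor nuclei are counted and each nucleus at most once even if it touches
#' two lines.
#'
#' @param map a `cellmap`.
#' @param lines numeric vector of line ordinates.
#' @return object of class `count_result`: total_tumor, positive_tumor,
#'   fields_used (1), exhaustive (FALSE).
#' @export
count_on_lines <- function(map, lines) {
  stopifnot(inherits(map, "cellmap"))
  nuc <- map$nuclei[map$nuclei$cell_class == "invasive_tumor", , drop = FALSE]
  hit <- rep(FALSE, nrow(nuc))
  for (ln in lines)
    hit <- hit | abs(nuc$y - ln) <= nuc$radius
  count_result(sum(hit), sum(hit & nuc$ki67_positive), 1L, FALSE)
}

count_result <- function(total, positive, fields_used, exhaustive) {
  stopifnot(positive <= total)
  structure(list(total_tumor = as.integer(total),
                 positive_tumor = as.integer(positive),
                 fields_used = as.integer(fields_used),
                 exhaustive = isTRUE(exhaustive)),
            class = "count_result")
}

# exhaustive count of the tumor compartment of one map
count_all <- function(map) {
  nuc <- map$nuclei[map$nuclei$cell_class == "invasive_tumor", , drop = FALSE]
  count_result(nrow(nuc), sum(nuc$ki67_positive), 1L, TRUE)
}

ki67_score <- function(percent, method, provenance = NULL) {
  stopifnot(percent >= 0, percent <= 100,
            method %in% c("VPC", "IMAGE", "SOP"))
  structure(list(percent = percent, method = method,
                 provenance = provenance),
            class = "ki67_score")
}

#' @export
print.ki67_score <- function(x, ...) {
  cat(sprintf("<ki67_score %.2f%% by %s>\n", x$percent, x$method))
  invisible(x)
}

#' Visual point counting score over randomly selected fields
#'
#' Selects `n_fields` fields at random (without replacement, seeded), counts
#' tumor cells intersecting the counting lines with a per-field random grid
#' offset, and accumulates additional fields until at least `min_cells`
#' total tumor cells have been counted. If all fields are exhausted before
#' reaching `min_cells`, every cell in every field is counted exhaustively
#' and the result is flagged `exhaustive`.
#'
#' @param maps list of `cellmap`s (the available fields of one specimen).
#' @param spec a [grid_spec()]; its offset is re-randomized per field from
#'   the seed unless `fixed_offset = TRUE`.
#' @param min_cells minimum total tumor cells (default 200).
#' @param n_fields initial number of random fields (default 3).
#' @param seed integer seed for field selection and offsets.
#' @param fixed_offset keep the spec's offset on every field (used by the
#'   exhaustive-grid equivalence tests).
#' @return a `ki67_score` with method "VPC" and the accumulated
#'   `count_result` as provenance.
#' @export
vpc_score <- function(maps, spec = grid_spec(), min_cells = 200,
                      n_fields = 3, seed = 1L, fixed_offset = FALSE) {
  if (inherits(maps, "cellmap")) maps <- list(maps)
  stopifnot(length(maps) >= 1)
  set.seed(child_seed(seed, "vpc_fields"))
  order_idx <- sample.int(length(maps))
  total <- 0L; positive <- 0L; used <- 0L
  for (i in order_idx) {
    if (used >= n_fields && total >= min_cells) break
    sp <- spec
    if (!fixed_offset)
      sp$offset <- stats::runif(1, 0, spec$line_spacing)
    cr <- count_on_lines(maps[[i]],
                         grid_lines(c(maps[[i]]$width, maps[[i]]$height), sp))
    total <- total + cr$total_tumor
    positive <- positive + cr$positive_tumor
    used <- used + 1L
  }
  exhaustive <- FALSE
  if (total < min_cells) {            # fields exhausted: count everything
    exhaustive <- TRUE
    total <- 0L; positive <- 0L
    for (m in maps) {
      cr <- count_all(m)
      total <- total + cr$total_tumor
      positive <- positive + cr$positive_tumor
    }
    used <- length(maps)
  }
  if (total == 0L)
    stop_ki67("no tumor cells in any field: Ki-67 score undefined",
              "ki67cta_undefined_score")
  ki67_score(100 * positive / total, "VPC",
             count_result(total, positive, used, exhaustive))
}
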