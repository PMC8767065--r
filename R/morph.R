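# Soma-area morphometry: percent area change from contour pixel counts and
# the spherical area-to-volume fold conversion.

#' Percent change in soma area
#'
#' `100 * (after - before) / before`, from contour pixel counts (any unit:
#' the scale cancels).
#'
#' @param before,after areas in pixels (or um^2), `before > 0`. Vectorized.
#' @return percent change.
#' @export
area_change_percent <- function(before, after) {
  if (any(before <= 0)) stop("area before must be > 0", call. = FALSE)
  100 * (after - before) / before
}

#' Volume fold-change from area fold-change (spherical soma)
#'
#' For a sphere the projected area scales as r^2 and the volume as r^3, so
#' a fold-change `a` in projected area corresponds to `a^(3/2)` in volume.
#'
#' @param area_fold positive fold-change in projected area.
#' @return volume fold-change.
#' @examples
#' volume_fold_from_area_fold(1.427)  # ~1.70
#' volume_fold_from_area_fold(1.22)   # ~1.35
#' @export
volume_fold_from_area_fold <- function(area_fold) {
  if (any(area_fold <= 0)) stop("area fold must be > 0", call. = FALSE)
  area_fold^(3 / 2)
}

#' Area fold-change from volume fold-change (spherical soma)
#'
#' Inverse of [volume_fold_from_area_fold()]: `v^(2/3)`.
#'
#' @param volume_fold positive fold-change in volume.
#' @return area fold-change.
#' @export
area_fold_from_volume_fold <- function(volume_fold) {
  if (any(volume_fold <= 0)) stop("volume fold must be > 0", call. = FALSE)
  volume_fold^(2 / 3)
}

#' Summarize soma-area changes per condition
#'
#' Per-cell percent changes are aggregated to per-experiment means first,
#' then summarized as mean +/- SEM across experiments (`unit =
#' "experiment"`, the default) or across all cells (`unit = "cell"`).
#'
#' @param areas data.frame with columns `experiment`, `condition`,
#'   `area_before`, `area_after`.
#' @param unit aggregation unit, `"experiment"` or `"cell"`.
#' @return tibble with `condition`, `mean_pct`, `sem_pct`, `sd_pct`, `n`,
#'   `volume_fold` (spherical conversion of the mean area fold), `unit`.
#' @export
summarize_area_change <- function(areas, unit = c("experiment", "cell")) {
  unit <- match.arg(unit)
  need <- c("condition", "area_before", "area_after")
  if (!all(need %in% names(areas)))
    stop("areas needs columns condition, area_before, area_after",
         call. = FALSE)
  areas$pct <- area_change_percent(areas$area_before, areas$area_after)
  if (unit == "experiment") {
    if (!"experiment" %in% names(areas))
      stop("experiment column required for unit = 'experiment'", call. = FALSE)
    key <- interaction(areas$condition, areas$experiment, drop = TRUE)
    per <- do.call(rbind, lapply(split(areas, key), function(d)
      data.frame(condition = d$condition[1], pct = mean(d$pct))))
  } else {
    per <- areas[, c("condition", "pct")]
  }
  rows <- lapply(split(per, per$condition), function(d) {
    n <- nrow(d)
    m <- mean(d$pct); s <- stats::sd(d$pct)
    tibble::tibble(condition = d$condition[1], mean_pct = m,
                   sem_pct = s / sqrt(n), sd_pct = s, n = n,
                   volume_fold = volume_fold_from_area_fold(1 + m / 100),
                   unit = unit)
  })
  do.call(rbind, rows)
}
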