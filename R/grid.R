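#' The 24-2 test-point layout
#'
#' Returns the canonical 24-2 perimetric test pattern in right-eye field
#' coordinates: positive `h_deg` is the temporal field (the physiological
#' blind spot sits near +15 degrees), positive `v_deg` the superior field.
#' All 54 coordinates are odd multiples of 3 degrees; the two additional
#' nasal points of the pattern lie at (-27, +/-3). The two locations
#' nearest the expected blind spot centre (15, -1) -- (15, -3) and
#' (15, 3) -- carry no pattern-deviation value, leaving 52 analysis
#' locations.
#'
#' The layout is shipped as a plain-text fixture
#' (`extdata/grid24_2.csv`) which is the single source of truth; this
#' function reads and caches it.
#'
#' @return An object of class `grid24_2`: a list with components
#'   `all_locations` (data frame of 54 rows: `h_deg`, `v_deg`,
#'   `analysis`), `analysis_locations` (52-row subset) and
#'   `excluded_pair` (2-row subset).
#' @examples
#' g <- location_grid_24_2()
#' nrow(g$analysis_locations)  # 52
#' g$excluded_pair
#' @export
location_grid_24_2 <- function() {
  if (!is.null(.grid_cache$grid)) return(.grid_cache$grid)
  path <- system.file("extdata", "grid24_2.csv", package = "nbslvf",
                      mustWork = TRUE)
  g <- utils::read.csv(path)
  stopifnot(nrow(g) == 54L, all(c("h_deg", "v_deg", "analysis") %in% names(g)))
  g <- g[order(-g$v_deg, g$h_deg), , drop = FALSE]
  rownames(g) <- NULL
  out <- structure(list(
    all_locations = g,
    analysis_locations = g[g$analysis == 1L, c("h_deg", "v_deg")],
    excluded_pair = g[g$analysis == 0L, c("h_deg", "v_deg")]
  ), class = "grid24_2")
  rownames(out$analysis_locations) <- NULL
  rownames(out$excluded_pair) <- NULL
  .grid_cache$grid <- out
  out
}

.grid_cache <- new.env(parent = emptyenv())

#' @export
print.grid24_2 <- function(x, ...) {
  cat("24-2 test pattern:", nrow(x$all_locations), "locations,",
      nrow(x$analysis_locations), "with pattern-deviation values\n")
  cat("excluded (blind-spot adjacent):",
      paste(sprintf("(%d,%d)", x$excluded_pair$h_deg, x$excluded_pair$v_deg),
            collapse = " "), "\n")
  invisible(x)
}

#' Column names used for pattern-deviation values
#'
#' One column per analysis location, named `pd_<h>_<v>`, ordered
#' row-major with `v_deg` descending and `h_deg` ascending (the order in
#' which record tables store them).
#'
#' @return Character vector of length 52.
#' @export
pd_column_names <- function() {
  loc <- location_grid_24_2()$analysis_locations
  paste0("pd_", loc$h_deg, "_", loc$v_deg)
}
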