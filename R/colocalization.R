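# Two-channel colocalization by Pearson's correlation over a cell mask.
#
# Plain (unthresholded) within-mask Pearson correlation, the readout of the
# classic WCIF-style colocalization analysis; no Manders or Costes variants.

#' Pearson colocalization of two channels within a mask
#'
#' Sample Pearson correlation of the intensity pairs at mask pixels.
#' Values near 1 indicate reliable colocalization, values near -1
#' exclusion. A constant channel within the mask has no defined
#' correlation and raises an error rather than silently returning 0.
#'
#' @param ch_a,ch_b numeric matrices of identical shape.
#' @param mask logical matrix (e.g. `cell$mask2d`) or an `hq_cell_region`.
#' @return object of class `hq_coloc`: list(r, n).
#' @export
pearson_coloc <- function(ch_a, ch_b, mask) {
  if (inherits(mask, "hq_cell_region")) mask <- mask$mask2d
  if (!identical(dim(ch_a), dim(ch_b)) || !identical(dim(ch_a), dim(mask)))
    stop_hq("domain", "channels and mask must share dimensions")
  a <- ch_a[mask]; b <- ch_b[mask]
  if (length(a) < 2L) stop_hq("domain", "mask must contain at least 2 pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_hq("undefined_correlation",
            "a channel is constant within the mask; correlation undefined")
  structure(list(r = as.numeric(stats::cor(a, b)), n = length(a)),
            class = "hq_coloc")
}

#' @export
print.hq_coloc <- function(x, ...) {
  cat(sprintf("<hq_coloc> r = %.4f over %d pixels\n", x$r, x$n))
  invisible(x)
}

#' Per-cell Pearson correlations for groups of scenes
#'
#' Segments each scene's cell from `mask_channel`, computes the within-mask
#' Pearson correlation of the channel pair on the maximum projections
#' (matching a projection-based workflow; set `project = FALSE` to use a
#' single mid plane) and returns a tidy table ready for a rank test.
#' Per-scene failures are flagged rows (`ok = FALSE`), not aborts.
#'
#' @param scene_groups named list; each element is a list of
#'   [image_stack()]s (or `list(stack=, truth=)` pairs) forming one group.
#' @param pair integer channel pair, default `c(1, 2)`.
#' @param mask_channel channel used to segment the cell mask.
#' @param project use max projections (default) instead of the middle plane.
#' @return data.frame (group, cell, pair, r, n, ok).
#' @export
coloc_by_group <- function(scene_groups, pair = c(1L, 2L), mask_channel = 1L,
                           project = TRUE) {
  rows <- list()
  for (g in names(scene_groups)) {
    scenes <- scene_groups[[g]]
    for (i in seq_along(scenes)) {
      st <- scenes[[i]]
      if (!inherits(st, "hq_stack") && !is.null(st$stack)) st <- st$stack
      res <- tryCatch({
        cell <- segment_cell_body(st, channel = mask_channel)
        img <- function(ch) if (project) max_project(st, ch) else
          get_plane(st, ch, z = max(1L, n_slices(st) %/% 2L))
        cl <- pearson_coloc(img(pair[1]), img(pair[2]), cell$mask2d)
        c(cl$r, cl$n, 1)
      }, error = function(e) c(NA_real_, NA_real_, 0))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, cell = i, pair = paste(pair, collapse = "-"),
        r = res[1], n = res[2], ok = res[3] == 1)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(group = character(0), cell = integer(0),
                      pair = character(0), r = numeric(0), n = numeric(0),
                      ok = logical(0)))
  do.call(rbind, rows)
}
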