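# Connected-component labeling for 2-D and 3-D binary masks.
#
# Adjacency edges are built by array shifts over the requested neighbourhood
# and the partition is obtained from igraph's connected components, which
# keeps the voxel loop out of R. Labels are renumbered 1..n in first-voxel
# (column-major) order so results are deterministic.

neighbour_offsets <- function(ndim, connectivity) {
  full <- as.matrix(expand.grid(rep(list(-1:1), ndim)))
  full <- full[rowSums(abs(full)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "4"  = rowSums(abs(full)) == 1,
    "8"  = rep(TRUE, nrow(full)),
    "6"  = rowSums(abs(full)) == 1,
    "26" = rep(TRUE, nrow(full)),
    stop_hq("domain", "unsupported connectivity %s", connectivity))
  full <- full[keep, , drop = FALSE]
  # half neighbourhood: each undirected adjacency counted once
  full[apply(full, 1L, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  }), , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' @param mask logical (or 0/1) matrix or 3-D array.
#' @param connectivity 4 or 8 for 2-D masks, 6 or 26 for 3-D masks.
#'   Defaults: 8 in 2-D (the particle-analysis convention), 6 in 3-D.
#' @return integer array of the same shape; 0 is background, components are
#'   numbered from 1 in first-voxel order.
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 2L) 8L else 6L) {
  dm <- dim(mask)
  if (is.null(dm)) stop_hq("domain", "mask must be a matrix or 3-D array")
  mask <- array(as.logical(mask), dm)
  ndim <- length(dm)
  fg <- which(mask)
  out <- array(0L, dm)
  if (length(fg) == 0L) return(out)
  id <- array(0L, dm)
  id[fg] <- seq_along(fg)

  offs <- neighbour_offsets(ndim, connectivity)
  edges <- vector("list", nrow(offs))
  idx_ranges <- lapply(dm, seq_len)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    src <- dst <- vector("list", ndim)
    ok <- TRUE
    for (d in seq_len(ndim)) {
      if (o[d] >= 0) {
        src[[d]] <- seq_len(dm[d] - o[d])
      } else {
        src[[d]] <- seq(1L - o[d], dm[d])
      }
      dst[[d]] <- src[[d]] + o[d]
      if (length(src[[d]]) == 0L) ok <- FALSE
    }
    if (!ok) next
    a <- do.call(`[`, c(list(id), src, list(drop = FALSE)))
    b <- do.call(`[`, c(list(id), dst, list(drop = FALSE)))
    sel <- a > 0L & b > 0L
    if (any(sel)) edges[[k]] <- cbind(a[sel], b[sel])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # renumber by first occurrence so labeling is order-stable
  out[fg] <- match(comp, unique(comp))
  out
}
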