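# 3D connected components on logical volumes.
#
# Foreground voxels become vertices of an undirected graph with edges
# between neighbors under the requested connectivity; components are then
# read off with igraph.  This keeps the cost proportional to the (small)
# foreground, not the volume.

neighbor_offsets <- function(connectivity = c(26, 18, 6)) {
  connectivity <- as.integer(match.arg(as.character(connectivity[1]),
                                       c("26", "18", "6")))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6"  = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)))
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3D mask
#'
#' @param mask 3D logical array.
#' @param connectivity neighborhood definition: 6 (faces), 18 (faces +
#'   edges) or 26 (faces + edges + corners).
#' @return 3D integer array; 0 for background, components numbered from 1
#'   in order of their smallest linear voxel index.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  d <- dim(mask)
  out <- array(0L, d)
  fg <- which(mask)
  if (!length(fg)) return(out)
  idmap <- array(0L, d)
  idmap[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  offs <- neighbor_offsets(connectivity)
  # half the offsets suffice for an undirected graph
  half <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  edges <- vector("list", nrow(half))
  for (k in seq_len(nrow(half))) {
    nc <- sweep(co, 2, half[k, ], `+`)
    ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] &
          nc[, 2] >= 1 & nc[, 2] <= d[2] &
          nc[, 3] >= 1 & nc[, 3] <= d[3]
    if (!any(ok)) next
    nb <- idmap[coords_to_index(nc[ok, , drop = FALSE], d)]
    hit <- nb > 0
    if (any(hit)) edges[[k]] <- cbind(which(ok)[hit], nb[hit])
  }
  edges <- do.call(rbind, edges)
  memb <- if (is.null(edges)) seq_along(fg) else {
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    igraph::components(g)$membership
  }
  # renumber components by smallest linear voxel index for determinism
  first <- tapply(fg, memb, min)
  rank <- match(names(sort(first)), names(first))
  relabel <- integer(length(first))
  relabel[as.integer(names(first))[rank]] <- seq_along(first)
  out[fg] <- relabel[memb]
  out
}

#' Restrict a lesion-candidate mask to a single lesion
#'
#' Keeps only the largest connected component of a perfusion-lesion
#' candidate mask, discarding smaller artifactual or erroneous components.
#' Ties in component size are broken in favor of the component containing
#' the smallest linear voxel index.  An empty mask passes through
#' unchanged.
#'
#' @param candidate_mask 3D logical array of perfusion-lesion candidates.
#' @param connectivity see [label_components()].
#' @return 3D logical array holding the surviving component.
#' @export
single_lesion_cleanup <- function(candidate_mask, connectivity = 26) {
  lab <- label_components(candidate_mask, connectivity)
  if (!any(lab > 0L)) return(array(FALSE, dim(candidate_mask)))
  sizes <- tabulate(lab[lab > 0L])
  # components are numbered by smallest voxel index, so which.max picks
  # the lowest-index component among equally sized ones
  lab == which.max(sizes)
}
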