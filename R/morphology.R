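#' Default configuration for the spatial feature scorers
#'
#' The area thresholds that anchor the binary desert/forest calls come from
#' the published scoring criteria (deserts positive at >= 25% of tumor
#' area, forests positive at >= 10%); the remaining knobs make the
#' qualitative parts of those criteria operational and are design values:
#' minimum component sizes exclude speckle (1% of tumor area for deserts,
#' 2% for forests), the strength ladder grades the infiltration fraction at
#' 5% and 15%, the peritumoral band is 2 lattice cells (25 um) deep, and
#' aggregates need >= 2 distal clusters of >= 5 cells.
#'
#' @param connectivity neighborhood for connected components: 4 (edge
#'   adjacency, conservative confluence; default) or 8 (adds diagonals).
#' @param desertMinComponentFrac,forestMinComponentFrac smallest component,
#'   as a fraction of tumor area, that counts towards the respective total.
#' @param desertAreaFracThreshold,forestAreaFracThreshold qualifying-area
#'   fraction at or above which the binary feature scores 1.
#' @param bandWidthCells peritumoral band width in lattice cells.
#' @param strengthCutoffs two ascending fractions (c1, c2): nonzero
#'   infiltration f grades as 1 when f <= c1, 2 when c1 < f <= c2, 3 above.
#' @param aggregateMinCells minimum distal cluster size in cells.
#' @param aggregateMultifocalMin clusters required for a multifocal call.
#' @return a validated [MorphologyConfig-class].
#' @export
#' @examples
#' morphologyConfig()
#' morphologyConfig(connectivity = 8, bandWidthCells = 4)
morphologyConfig <- function(connectivity = 4,
                             desertMinComponentFrac = 0.01,
                             desertAreaFracThreshold = 0.25,
                             forestMinComponentFrac = 0.02,
                             forestAreaFracThreshold = 0.10,
                             bandWidthCells = 2,
                             strengthCutoffs = c(0.05, 0.15),
                             aggregateMinCells = 5,
                             aggregateMultifocalMin = 2) {
  new("MorphologyConfig",
      connectivity = as.integer(connectivity),
      desertMinComponentFrac = desertMinComponentFrac,
      desertAreaFracThreshold = desertAreaFracThreshold,
      forestMinComponentFrac = forestMinComponentFrac,
      forestAreaFracThreshold = forestAreaFracThreshold,
      bandWidthCells = as.integer(bandWidthCells),
      strengthCutoffs = strengthCutoffs,
      aggregateMinCells = as.integer(aggregateMinCells),
      aggregateMultifocalMin = as.integer(aggregateMultifocalMin))
}

#' Read/write a MorphologyConfig as YAML
#'
#' The YAML file mirrors the configuration field for field, using the
#' snake_case names of the scorer output tables.
#'
#' @param path YAML file path.
#' @param cfg a [MorphologyConfig-class].
#' @return `readMorphologyConfig` returns a [MorphologyConfig-class];
#'   `writeMorphologyConfig` returns `path` invisibly.
#' @export
readMorphologyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(morphologyConfig, stats::setNames(y, c(
    connectivity = "connectivity",
    desert_min_component_frac = "desertMinComponentFrac",
    desert_area_frac_threshold = "desertAreaFracThreshold",
    forest_min_component_frac = "forestMinComponentFrac",
    forest_area_frac_threshold = "forestAreaFracThreshold",
    band_width_cells = "bandWidthCells",
    strength_cutoffs = "strengthCutoffs",
    aggregate_min_cells = "aggregateMinCells",
    aggregate_multifocal_min = "aggregateMultifocalMin")[names(y)]))
}

#' @rdname readMorphologyConfig
#' @export
writeMorphologyConfig <- function(cfg, path) {
  yaml::write_yaml(list(
    connectivity = cfg@connectivity,
    desert_min_component_frac = cfg@desertMinComponentFrac,
    desert_area_frac_threshold = cfg@desertAreaFracThreshold,
    forest_min_component_frac = cfg@forestMinComponentFrac,
    forest_area_frac_threshold = cfg@forestAreaFracThreshold,
    band_width_cells = cfg@bandWidthCells,
    strength_cutoffs = cfg@strengthCutoffs,
    aggregate_min_cells = cfg@aggregateMinCells,
    aggregate_multifocal_min = cfg@aggregateMultifocalMin), path)
  invisible(path)
}

#' Connected components of a boolean lattice
#'
#' Labels the maximal connected regions of `TRUE` cells under 4- or
#' 8-neighborhood adjacency.  Components realize the "confluent groups" of
#' the spatial scoring rules.  Adjacency is assembled as an edge list and
#' resolved with igraph's component search.
#'
#' @param grid logical matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (adds diagonals).
#' @return list with `labels` (integer matrix, 0 where `grid` is FALSE,
#'   components numbered 1..k in first-cell order) and `sizes` (integer
#'   vector of component cell counts).
#' @export
#' @examples
#' g <- matrix(FALSE, 3, 3); g[1, 1] <- TRUE; g[2, 2] <- TRUE
#' connectedComponents(g, 4)$sizes   # two singletons
#' connectedComponents(g, 8)$sizes   # one component of 2
connectedComponents <- function(grid, connectivity = 4) {
  stopifnot(is.logical(grid), is.matrix(grid))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) {
    tlsStop("tilscape_parameter_error", "connectivity must be 4 or 8")
  }
  m <- nrow(grid); n <- ncol(grid)
  labels <- matrix(0L, m, n)
  verts <- which(grid)
  if (!length(verts)) return(list(labels = labels, sizes = integer(0)))
  compact <- integer(m * n)
  compact[verts] <- seq_along(verts)
  idx <- matrix(seq_len(m * n), m, n)
  pairUp <- function(a, b, keep) cbind(a[keep], b[keep])
  edges <- rbind(
    if (n > 1L) pairUp(idx[, -n], idx[, -1L], grid[, -n] & grid[, -1L]),
    if (m > 1L) pairUp(idx[-m, ], idx[-1L, ], grid[-m, ] & grid[-1L, ])
  )
  if (connectivity == 8L && m > 1L && n > 1L) {
    edges <- rbind(edges,
      pairUp(idx[-m, -n], idx[-1L, -1L], grid[-m, -n] & grid[-1L, -1L]),
      pairUp(idx[-1L, -n], idx[-m, -1L], grid[-1L, -n] & grid[-m, -1L])
    )
  }
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, t(matrix(compact[edges], ncol = 2L)))
  }
  memb <- igraph::components(g)$membership
  ## renumber so components appear in order of their first cell
  first <- match(unique(memb), memb)
  renum <- integer(max(memb))
  renum[memb[sort(first)]] <- seq_along(first)
  memb <- renum[memb]
  labels[verts] <- memb
  list(labels = labels, sizes = as.integer(tabulate(memb)))
}

## shift a logical matrix by (dr, dc), padding with FALSE
shiftMask <- function(mask, dr, dc) {
  m <- nrow(mask); n <- ncol(mask)
  out <- matrix(FALSE, m, n)
  rs <- seq_len(m) - dr; cs <- seq_len(n) - dc
  rok <- rs >= 1L & rs <= m; cok <- cs >= 1L & cs <= n
  out[rok, cok] <- mask[rs[rok], cs[cok]]
  out
}

#' Binary dilation of a mask on the lattice
#'
#' Grows a boolean mask by `width` cells under the chebyshev metric
#' (8-neighborhood, square structuring element) or the manhattan metric
#' (4-neighborhood, diamond).
#'
#' @param mask logical matrix.
#' @param width dilation radius in cells.
#' @param metric "chebyshev" or "manhattan".
#' @return logical matrix of the same shape.
#' @export
dilateMask <- function(mask, width = 1, metric = c("chebyshev", "manhattan")) {
  metric <- match.arg(metric)
  stopifnot(is.logical(mask), width >= 0)
  shifts <- if (metric == "chebyshev") {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  out <- mask
  for (i in seq_len(width)) {
    grown <- out
    for (s in shifts) grown <- grown | shiftMask(out, s[1], s[2])
    out <- grown
  }
  out
}

#' Peritumoral band of a Tumor-TIL map
#'
#' The band approximating the invasive boundary region: the tumor mask
#' dilated by `bandWidthCells` cells, minus the tumor mask itself.
#' Dilation uses the chebyshev (8-neighborhood) metric by default, the
#' manhattan (4-neighborhood) metric when `metric = "manhattan"`.
#'
#' @param map a [CompositeMap-class] with at least one tumor cell.
#' @param cfg a [MorphologyConfig-class]; `bandWidthCells` sets the depth.
#' @param metric distance metric for the dilation.
#' @return logical matrix marking band cells.
#' @export
#' @examples
#' tum <- matrix(FALSE, 5, 5); tum[3, 3] <- TRUE
#' m <- CompositeMap(tum, matrix(FALSE, 5, 5))
#' sum(peritumoralBand(m, morphologyConfig(bandWidthCells = 1)))  # 8-cell ring
peritumoralBand <- function(map, cfg = morphologyConfig(),
                            metric = c("chebyshev", "manhattan")) {
  stopifnot(is(map, "CompositeMap"), is(cfg, "MorphologyConfig"))
  metric <- match.arg(metric)
  if (!any(map@tumor)) {
    tlsStop("tilscape_undefined_error",
            "slide '%s' has no tumor cells; band undefined", map@slideId)
  }
  dilateMask(map@tumor, cfg@bandWidthCells, metric) & !map@tumor
}
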