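#' Read a patch probability heatmap from CSV or grayscale PNG
#'
#' CSV input is a headerless comma-separated numeric matrix, one row per
#' patch row.  PNG input is an 8- or 16-bit grayscale image whose pixel
#' values map linearly to probability as `value / max_intensity` (no gamma),
#' so intensity 255 in an 8-bit file reads as probability 1.
#'
#' @param path path to a `.csv` or `.png` heatmap file.
#' @param patchSizeUm physical patch edge length in micrometres
#'   (87.5 for the tumor model, 50 for the lymphocyte model).
#' @param slideId slide identifier to attach.
#' @param tissueMask optional logical matrix of analyzable patches.
#' @return a [HeatmapGrid-class] with values clamped to \[0, 1\]
#'   (CSV values outside \[0, 1\] by more than 1e-9 are an error).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("0.2,0.8", "1.0,0.0"), f)
#' readHeatmap(f, patchSizeUm = 87.5, slideId = "s1")
readHeatmap <- function(path, patchSizeUm, slideId = "slide",
                        tissueMask = NULL) {
  if (!file.exists(path)) tlsStop("tilscape_io_error", "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) px <- px[, , 1L]  # collapse gray-encoded RGB
    vals <- px  # readPNG already scales by max intensity
  } else {
    rows <- strsplit(readLines(path, warn = FALSE), ",", fixed = TRUE)
    rows <- rows[lengths(rows) > 0L]
    if (!length(rows)) tlsStop("tilscape_format_error", "empty heatmap: %s", path)
    n <- lengths(rows)
    if (length(unique(n)) != 1L) {
      tlsStop("tilscape_format_error",
              "ragged CSV matrix in %s: row lengths %s", path,
              paste(unique(n), collapse = "/"))
    }
    vals <- suppressWarnings(
      matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
    )
    if (anyNA(vals)) {
      tlsStop("tilscape_format_error", "non-numeric entries in %s", path)
    }
    if (any(vals < -1e-9 | vals > 1 + 1e-9)) {
      tlsStop("tilscape_validation_error",
              "probabilities outside [0, 1] in %s", path)
    }
  }
  vals <- pmin(pmax(vals, 0), 1)
  HeatmapGrid(vals, patchSizeUm, slideId, tissueMask)
}

#' Write a heatmap as a headerless CSV matrix
#'
#' Values are written with full double precision so a read/write round trip
#' reproduces the grid to better than 1e-9.
#'
#' @param grid a [HeatmapGrid-class].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
writeHeatmap <- function(grid, path) {
  stopifnot(is(grid, "HeatmapGrid"))
  lines <- apply(grid@values, 1L, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = ",")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read or write the YAML sidecar of a heatmap file
#'
#' The sidecar records the slide id, the physical patch size and the scan
#' magnification, so heatmap files stay self-describing.
#'
#' @param path sidecar path (`.yaml`).
#' @param slideId,patchSizeUm,magnification fields to record.
#' @return `readSidecar` returns a named list; `writeSidecar` returns
#'   `path` invisibly.
#' @export
readSidecar <- function(path) {
  sc <- yaml::read_yaml(path)
  need <- c("slide_id", "patch_size_um")
  if (!all(need %in% names(sc))) {
    tlsStop("tilscape_format_error",
            "sidecar %s lacks fields: %s", path,
            paste(setdiff(need, names(sc)), collapse = ", "))
  }
  sc
}

#' @rdname readSidecar
#' @export
writeSidecar <- function(path, slideId, patchSizeUm, magnification = 40) {
  yaml::write_yaml(list(slide_id = slideId, patch_size_um = patchSizeUm,
                        magnification = magnification), path)
  invisible(path)
}

#' Binarize a probability heatmap
#'
#' A patch is called positive when its probability is at or above the
#' threshold (default 0.5: probabilities >= 50% positive, < 50% negative).
#' Patches outside the tissue mask are always negative.
#'
#' @param grid a [HeatmapGrid-class].
#' @param threshold probability threshold in \[0, 1\].
#' @return a [BinaryGrid-class] of the same shape.
#' @aliases binarize
#' @export
#' @examples
#' g <- HeatmapGrid(matrix(c(0.5, 0.499), 1), 50)
#' gridValues(binarize(g))   # TRUE FALSE
setMethod("binarize", "HeatmapGrid", function(grid, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    tlsStop("tilscape_parameter_error", "threshold must lie in [0, 1]")
  }
  v <- grid@values
  pos <- !is.na(v) & v >= threshold
  if (!is.null(grid@tissueMask)) pos <- pos & grid@tissueMask
  dim(pos) <- dim(v)
  BinaryGrid(pos, grid@patchSizeUm, grid@slideId)
})

## exact GCD of two (possibly fractional) micrometre pitches, via the
## smallest common integer scaling
gcdUm <- function(a, b) {
  igcd <- function(x, y) if (y == 0) x else igcd(y, x %% y)
  for (m in c(1L, 2L, 4L, 5L, 8L, 10L, 20L, 40L, 100L, 1000L)) {
    am <- a * m; bm <- b * m
    if (abs(am - round(am)) < 1e-6 && abs(bm - round(bm)) < 1e-6) {
      return(igcd(round(am), round(bm)) / m)
    }
  }
  tlsStop("tilscape_parameter_error",
          "patch sizes %g and %g have no exact common subdivision", a, b)
}

## indices of the source patch covering each fine cell (patch (i,j) covers
## the half-open square [ (j-1)*s, j*s ) so the cell center decides)
fineToSourceIndex <- function(nFine, cellUm, patchUm, nSrc) {
  idx <- floor(((seq_len(nFine) - 0.5) * cellUm) / patchUm) + 1L
  pmin(idx, nSrc)
}

#' Resample tumor and lymphocyte grids onto a shared fine lattice
#'
#' The two models tile the slide at different pitches (87.5 um tumor
#' patches, 50 um lymphocyte patches), so their grids cannot be overlaid
#' directly.  Each source patch is replicated onto a fine lattice whose
#' pitch is the greatest common divisor of the two patch sizes (12.5 um
#' for 87.5/50); origins are co-registered at the top-left corner and the
#' result is cropped to the overlapping physical extent.  Replication is
#' exact nearest-source assignment: no interpolation of boolean flags.
#'
#' @param tumor [BinaryGrid-class] from the tumor model.
#' @param lymph [BinaryGrid-class] from the lymphocyte model, same slide.
#' @return a [LatticePair-class] with both grids on the common lattice.
#'   Extents differing by more than one coarse patch in either dimension
#'   are an alignment error.
#' @export
#' @examples
#' tum <- BinaryGrid(matrix(TRUE, 4, 4), 87.5, "s1")
#' lym <- BinaryGrid(matrix(FALSE, 7, 7), 50, "s1")
#' resampleToCommonLattice(tum, lym)   # two 28 x 28 grids @ 12.5 um
resampleToCommonLattice <- function(tumor, lymph) {
  stopifnot(is(tumor, "BinaryGrid"), is(lymph, "BinaryGrid"))
  if (!identical(tumor@slideId, lymph@slideId)) {
    tlsStop("tilscape_alignment_error",
            "grids belong to different slides: '%s' vs '%s'",
            tumor@slideId, lymph@slideId)
  }
  cell <- gcdUm(tumor@patchSizeUm, lymph@patchSizeUm)
  coarse <- max(tumor@patchSizeUm, lymph@patchSizeUm)
  extT <- dim(tumor@values) * tumor@patchSizeUm
  extL <- dim(lymph@values) * lymph@patchSizeUm
  if (any(abs(extT - extL) > coarse + 1e-6)) {
    tlsStop("tilscape_alignment_error",
            "physical extents differ by more than one coarse patch: %s vs %s um",
            paste(extT, collapse = "x"), paste(extL, collapse = "x"))
  }
  ext <- pmin(extT, extL)                    # crop to the overlap
  nFine <- as.integer(floor(ext / cell + 1e-9))
  rep1 <- function(g, patch) {
    ri <- fineToSourceIndex(nFine[1], cell, patch, nrow(g))
    ci <- fineToSourceIndex(nFine[2], cell, patch, ncol(g))
    g[ri, ci, drop = FALSE]
  }
  new("LatticePair",
      tumor = BinaryGrid(rep1(tumor@values, tumor@patchSizeUm), cell,
                         tumor@slideId),
      lymph = BinaryGrid(rep1(lymph@values, lymph@patchSizeUm), cell,
                         lymph@slideId),
      cellSizeUm = cell)
}
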