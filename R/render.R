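## nearest-neighbor resize of a matrix to nr x nc
nnResize <- function(m, nr, nc) {
  ri <- pmax(1L, ceiling(seq_len(nr) / nr * nrow(m)))
  ci <- pmax(1L, ceiling(seq_len(nc) / nc * ncol(m)))
  m[ri, ci, drop = FALSE]
}

## blue (0) -> red (1) probability colormap as an RGB array
probPanel <- function(v) {
  arr <- array(0, c(nrow(v), ncol(v), 3L))
  arr[, , 1] <- v                  # red rises with probability
  arr[, , 2] <- 0.2 * (1 - abs(2 * v - 1))
  arr[, , 3] <- 1 - v              # blue falls
  arr
}

## Tumor-TIL map colors: lymphocytes red (drawn over tumor in co-positive
## cells), tumor-only yellow, background gray
tumorTilPanel <- function(map) {
  nr <- nrow(map@tumor); nc <- ncol(map@tumor)
  arr <- array(0, c(nr, nc, 3L))
  gray <- !map@tumor & !map@lymph
  arr[, , 1][gray] <- 0.75; arr[, , 2][gray] <- 0.75; arr[, , 3][gray] <- 0.75
  tum <- map@tumor & !map@lymph
  arr[, , 1][tum] <- 1; arr[, , 2][tum] <- 0.9; arr[, , 3][tum] <- 0
  arr[, , 1][map@lymph] <- 1; arr[, , 2][map@lymph] <- 0
  arr[, , 3][map@lymph] <- 0
  arr
}

#' Render the four-panel composite image of a slide
#'
#' Writes a PNG with the standard four panels: a low-resolution thumbnail
#' placeholder (upper left; the package does not decode whole-slide
#' images), the tumor probability heatmap (upper right) and lymphocyte
#' probability heatmap (lower left) on a blue-to-red scale, and the
#' Tumor-TIL map (lower right) with tumor in yellow, lymphocytes in red
#' (drawn over tumor in co-positive cells) and background tissue in gray.
#'
#' @param tumorHeatmap,lymphHeatmap the two [HeatmapGrid-class] panels.
#' @param map the [CompositeMap-class] of the same slide.
#' @param out output PNG path.
#' @return `out`, invisibly.
#' @export
renderFourPanel <- function(tumorHeatmap, lymphHeatmap, map, out) {
  stopifnot(is(tumorHeatmap, "HeatmapGrid"), is(lymphHeatmap, "HeatmapGrid"),
            is(map, "CompositeMap"))
  ids <- c(tumorHeatmap@slideId, lymphHeatmap@slideId, map@slideId)
  if (length(unique(ids)) != 1L) {
    tlsStop("tilscape_validation_error",
            "panels belong to different slides: %s",
            paste(unique(ids), collapse = ", "))
  }
  nr <- nrow(map@tumor); nc <- ncol(map@tumor)
  resizeArr <- function(arr) {
    out <- array(0, c(nr, nc, 3L))
    for (k in 1:3) out[, , k] <- nnResize(arr[, , k, drop = FALSE][, , 1L],
                                          nr, nc)
    out
  }
  thumb <- array(0.9, c(nr, nc, 3L))
  thumb[c(1L, nr), , ] <- 0.5; thumb[, c(1L, nc), ] <- 0.5
  panels <- list(
    thumb,
    resizeArr(probPanel(tumorHeatmap@values)),
    resizeArr(probPanel(lymphHeatmap@values)),
    tumorTilPanel(map)
  )
  gut <- 2L
  full <- array(1, c(2L * nr + gut, 2L * nc + gut, 3L))
  put <- function(p, r0, c0) {
    full[r0 + seq_len(nr), c0 + seq_len(nc), ] <<- p
  }
  put(panels[[1]], 0L, 0L)
  put(panels[[2]], 0L, nc + gut)
  put(panels[[3]], nr + gut, 0L)
  put(panels[[4]], nr + gut, nc + gut)
  ok <- tryCatch({
    png::writePNG(full, out)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) tlsStop("tilscape_io_error", "cannot write PNG to %s", out)
  invisible(out)
}
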