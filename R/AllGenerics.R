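## Classed conditions so callers can distinguish failure modes
## (format / validation / parameter / alignment / undefined-feature / io).
tlsStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "tilscape_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @rdname binarize
#' @export
setGeneric("binarize", function(grid, threshold = 0.5) {
  standardGeneric("binarize")
})

#' @rdname composeMap
#' @export
setGeneric("composeMap", function(pair) standardGeneric("composeMap"))

#' @rdname percentInfiltration
#' @export
setGeneric("percentInfiltration", function(map) {
  standardGeneric("percentInfiltration")
})

#' @rdname scoreAll
#' @export
setGeneric("scoreAll", function(map, cfg = morphologyConfig()) {
  standardGeneric("scoreAll")
})
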