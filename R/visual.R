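#' Composite class image
#'
#' Per-point mean TIC raster over the aligned runs of one sample class
#' (biological and analytical replicates combined), the basis of composite
#' class image fingerprinting.
#'
#' @param rasters List of aligned TIC raster matrices of one class.
#' @return Mean raster matrix.
#' @export
composite_class_image <- function(rasters) {
  if (length(rasters) == 0L) stop("empty class: no runs to combine")
  build_composite(rasters)
}

#' Colorized fuzzy-ratio difference image
#'
#' Pairwise visual comparison of two aligned rasters. The per-point signed
#' difference `d = analyzed - reference` is rendered in a
#' hue--intensity--saturation composition on a white background: hue is
#' green where the analyzed class responds more (`d > 0`) and red where the
#' reference does (`d < 0`); saturation `|d| / (|d| + epsilon)` fades to
#' white where responses are nearly equal; brightness follows the response
#' magnitude through `log(1 + |d|)` scaled to the image maximum (a linear
#' option is available). Swapping the arguments exchanges green and red
#' exactly and leaves intensity and saturation unchanged; adding a common
#' constant to both rasters changes nothing.
#'
#' @param analyzed,reference Aligned rasters of identical shape.
#' @param epsilon Near-equality scale in counts (a natural choice is 3x the
#'   composite noise SD).
#' @param scaling `"log"` (default) or `"linear"` intensity scaling.
#' @return Object of class `gc2d_difference_image`: list with `d` (signed
#'   difference), `rgb` (`[nrow, ncol, 3]` array in \[0, 1\]) and the
#'   parameters.
#' @export
fuzzy_ratio_image <- function(analyzed, reference, epsilon,
                              scaling = c("log", "linear")) {
  scaling <- match.arg(scaling)
  if (!all(dim(analyzed) == dim(reference)))
    stop("raster shapes differ: ", paste(dim(analyzed), collapse = "x"),
         " vs ", paste(dim(reference), collapse = "x"))
  stopifnot(epsilon > 0)
  d <- analyzed - reference
  a <- abs(d)
  s <- a / (a + epsilon)
  mx <- max(a)
  i <- if (mx == 0) a else if (scaling == "log") log1p(a) / log1p(mx)
       else a / mx
  # white background composition: channels orthogonal to the hue drop with
  # saturation; the hue channel keeps brightness i at full saturation
  hue_chan <- 1 - s * (1 - i)
  off_chan <- 1 - s
  rgb <- array(0, c(dim(d), 3))
  pos <- d > 0
  rgb[, , 1] <- ifelse(pos, off_chan, hue_chan)  # red channel
  rgb[, , 2] <- ifelse(pos, hue_chan, off_chan)  # green channel
  rgb[, , 3] <- off_chan
  structure(list(d = d, rgb = rgb, epsilon = epsilon, scaling = scaling),
            class = "gc2d_difference_image")
}

#' @export
print.gc2d_difference_image <- function(x, ...) {
  cat("gc2d_difference_image:", paste(dim(x$d), collapse = " x "),
      "; |d| range", format(range(abs(x$d)), digits = 3),
      "; epsilon", x$epsilon, "\n")
  invisible(x)
}

#' Write a difference (or plain raster) image as PNG
#'
#' Retention-plane orientation: first dimension on x, second dimension on
#' y increasing upward.
#'
#' @param img A `gc2d_difference_image`, or a numeric raster (rendered in
#'   grayscale, max-scaled).
#' @param path Output PNG path.
#' @export
write_image_png <- function(img, path) {
  if (inherits(img, "gc2d_difference_image")) {
    arr <- img$rgb
    # [mod, pt, 3] -> image rows = pt (top = high rt2), cols = mod
    out <- array(0, c(dim(arr)[2], dim(arr)[1], 3))
    for (k in 1:3) out[, , k] <- t(arr[, dim(arr)[2]:1, k])
  } else {
    m <- as.matrix(img)
    m <- if (max(m) > 0) m / max(m) else m
    out <- t(m[, ncol(m):1])
  }
  png::writePNG(out, target = path)
  invisible(path)
}
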