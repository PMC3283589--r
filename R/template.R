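#' Polygon shape templates
#'
#' A polygon template is the shape prior of the segmentation: a closed 2D
#' polygon whose vertices are listed in clockwise order (the implicit closing
#' edge runs from the last vertex back to the first). Templates are stored
#' normalized: translated so their centroid is at the origin and scaled so the
#' farthest vertex lies at distance 1 from it. The segmentation then places
#' the template at the seed point and scales it by the physical half-diameter,
#' so the absolute size of the supplied coordinates is irrelevant.
#'
#' @param vertices a two-column numeric matrix or data frame of vertex
#'   coordinates (columns x, y), at least 3 rows, clockwise order.
#' @return A tibble of class `polygon_template` with columns `x`, `y`
#'   (normalized coordinates; maximum vertex radius is exactly 1).
#' @examples
#' polygon_template(cbind(c(-1, 1, 1, -1), c(1, 1, -1, -1)))
#' template_square()
#' @export
polygon_template <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L) {
    stop("`vertices` must be a two-column numeric matrix (x, y)", call. = FALSE)
  }
  if (anyNA(v)) stop("template vertices contain missing values", call. = FALSE)
  if (nrow(v) < 3L) stop("a polygon template needs at least 3 vertices", call. = FALSE)
  d <- v - v[c(2:nrow(v), 1L), , drop = FALSE]
  if (any(rowSums(d^2) == 0)) {
    stop("consecutive template vertices must be distinct", call. = FALSE)
  }
  v <- normalize_template(v)
  out <- tibble::tibble(x = v[, 1L], y = v[, 2L])
  class(out) <- c("polygon_template", class(out))
  out
}

#' @describeIn polygon_template built-in unit square template (clockwise).
#' @export
template_square <- function() {
  polygon_template(cbind(c(-1, 1, 1, -1), c(1, 1, -1, -1)))
}

#' @describeIn polygon_template built-in axis-aligned rectangle of width `w`
#'   and height `h` (aspect ratio is what matters after normalization).
#' @param w,h rectangle width and height in arbitrary units.
#' @export
template_rectangle <- function(w, h) {
  stopifnot(w > 0, h > 0)
  polygon_template(cbind(c(-w, w, w, -w) / 2, c(h, h, -h, -h) / 2))
}

#' Centroid of a polygon template
#'
#' The template's reference point is the arithmetic mean of its vertex
#' coordinates (the center of gravity of the vertex list). Rays are later cast
#' from this point, re-located at the user seed.
#'
#' @param vertices two-column numeric matrix of at least 3 non-collinear
#'   vertices.
#' @return Numeric vector `c(x, y)`.
#' @examples
#' template_centroid(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' @export
template_centroid <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) stop("a polygon template needs at least 3 vertices", call. = FALSE)
  # collinearity: all cross products of edge vectors vanish
  rel <- sweep(v, 2L, v[1L, ])
  cross <- rel[, 1L] * rel[2L, 2L] - rel[, 2L] * rel[2L, 1L]
  if (all(abs(cross) < 1e-12) && sum(rel[2L, ]^2) > 0) {
    stop("template vertices are collinear", call. = FALSE)
  }
  colMeans(v)
}

#' Normalize a polygon template
#'
#' Translates the vertices so the centroid sits at the origin and divides by
#' the maximum vertex-to-centroid distance, so the farthest vertex lies at
#' radius exactly 1.
#'
#' @inheritParams template_centroid
#' @return Two-column numeric matrix of normalized vertices.
#' @export
normalize_template <- function(vertices) {
  v <- as.matrix(vertices)
  ctr <- template_centroid(v)
  v <- sweep(v, 2L, ctr)
  rmax <- sqrt(max(rowSums(v^2)))
  if (rmax == 0) stop("degenerate template: all vertices coincide", call. = FALSE)
  v / rmax
}

#' Read a polygon template from a text file or built-in name
#'
#' Accepts either a plain-text file with one "x y" vertex pair per line
#' (clockwise order, `#` comments and blank lines allowed), or one of the
#' built-in names `"square"` and `"rectangle:<w>:<h>"`.
#'
#' @param spec file path or built-in template name.
#' @return A [polygon_template].
#' @export
read_template <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  if (spec == "square") return(template_square())
  if (grepl("^rectangle:", spec)) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 3L) {
      stop("rectangle template spec must be 'rectangle:<w>:<h>'", call. = FALSE)
    }
    return(template_rectangle(as.numeric(parts[2L]), as.numeric(parts[3L])))
  }
  if (!file.exists(spec)) stop("template file not found: ", spec, call. = FALSE)
  tab <- utils::read.table(spec, comment.char = "#",
                           col.names = c("x", "y"), colClasses = "numeric")
  polygon_template(as.matrix(tab))
}
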