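#' Specify a synthetic phantom
#'
#' Bundles the parameters of the deterministic test-image generators. The
#' default is a bright 40 x 28 rectangle (intensity 200) on a dark background
#' (intensity 50) in a 128 x 128 image with additive Gaussian noise of sd 10
#' and a fixed RNG seed, emulating the appearance the segmentation was
#' designed for. Intensity polarity is free: the cost `|I - mean|` is
#' polarity-agnostic, so dark-on-bright phantoms work identically.
#'
#' @param width,height image size in pixels.
#' @param fg,bg foreground/background intensities (must differ).
#' @param center object center `c(x, y)` in 0-based pixel coordinates.
#' @param obj_width,obj_height object width/height in pixels.
#' @param missing_corners named numeric vector of corner erasures, e.g.
#'   `c(br = 6)` erases a 6 x 6 square at the bottom-right corner (names from
#'   `tl`, `tr`, `bl`, `br`). Rectangle phantom only.
#' @param missing_edges list of border erasures, each a list with elements
#'   `side` (`"top"`, `"bottom"`, `"left"`, `"right"`), `from`, `to`
#'   (fractions of the side length in [0, 1]) and `depth` (pixels).
#'   Rectangle phantom only.
#' @param concavity inward sagitta (pixels) of the circular-arc carving of
#'   the left/right sides; 0 keeps them straight. Vertebra phantom only.
#' @param corner_radius rounding radius of the corners (pixels). Vertebra
#'   phantom only.
#' @param rotation rotation of the object around its center (degrees,
#'   counterclockwise). Vertebra phantom only.
#' @param neighbor_gap if positive, a second identical structure is placed
#'   above the object, its lower border `neighbor_gap` pixels away from the
#'   object's upper border. Vertebra phantom only.
#' @param noise_sd additive Gaussian noise sd (intensities are clamped to
#'   [0, 255] and rounded to integers; `noise_sd = 0` is exactly noiseless).
#' @param seed RNG seed for the noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 128L, height = 128L, fg = 200, bg = 50,
                         center = c(64, 64), obj_width = 40, obj_height = 28,
                         missing_corners = NULL, missing_edges = NULL,
                         concavity = 0, corner_radius = 3, rotation = 0,
                         neighbor_gap = 0, noise_sd = 10, seed = 42L) {
  if (fg == bg) stop("foreground and background intensities must differ", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (concavity >= obj_width / 2) {
    stop("`concavity` must be below half the object width", call. = FALSE)
  }
  spec <- list(width = as.integer(width), height = as.integer(height),
               fg = fg, bg = bg, center = as.numeric(center),
               obj_width = obj_width, obj_height = obj_height,
               missing_corners = missing_corners, missing_edges = missing_edges,
               concavity = concavity, corner_radius = corner_radius,
               rotation = rotation, neighbor_gap = neighbor_gap,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# run fn with a private RNG stream, restoring the caller's state
with_phantom_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

finish_phantom <- function(img, mask, spec) {
  if (spec$noise_sd > 0) {
    img <- with_phantom_seed(spec$seed, function() {
      img + matrix(stats::rnorm(length(img), sd = spec$noise_sd),
                   nrow = nrow(img))
    })
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, truth = mask, spec = spec)
}

rect_bounds <- function(spec) {
  x0 <- round(spec$center[1L] - spec$obj_width / 2)
  y0 <- round(spec$center[2L] - spec$obj_height / 2)
  list(x0 = x0, x1 = x0 + spec$obj_width - 1L,
       y0 = y0, y1 = y0 + spec$obj_height - 1L)
}

#' Rectangle phantom with missing border parts
#'
#' Draws a filled rectangle at the foreground intensity and then reverts the
#' requested border segments and corners to background, so the visible object
#' has gaps while the ground-truth mask stays the FULL rectangle: the
#' reconstruction target for the shape-prior cut.
#'
#' @param spec a [phantom_spec].
#' @return List with `image` (intensity matrix), `truth` (0/1 mask of the
#'   full rectangle) and the `spec`.
#' @export
make_rectangle_phantom <- function(spec = phantom_spec()) {
  b <- rect_bounds(spec)
  if (b$x0 < 0 || b$y0 < 0 || b$x1 >= spec$width || b$y1 >= spec$height) {
    stop("rectangle extends outside the image", call. = FALSE)
  }
  img <- matrix(spec$bg, nrow = spec$height, ncol = spec$width)
  img[(b$y0:b$y1) + 1L, (b$x0:b$x1) + 1L] <- spec$fg
  mask <- matrix(0L, nrow = spec$height, ncol = spec$width)
  mask[(b$y0:b$y1) + 1L, (b$x0:b$x1) + 1L] <- 1L
  for (i in seq_along(spec$missing_corners)) {
    k <- spec$missing_corners[[i]]
    where <- names(spec$missing_corners)[i]
    xs <- if (grepl("l", where)) b$x0:(b$x0 + k - 1L) else (b$x1 - k + 1L):b$x1
    ys <- if (grepl("t", where)) b$y0:(b$y0 + k - 1L) else (b$y1 - k + 1L):b$y1
    img[ys + 1L, xs + 1L] <- spec$bg
  }
  for (e in spec$missing_edges) {
    horiz <- e$side %in% c("top", "bottom")
    len <- if (horiz) spec$obj_width else spec$obj_height
    lo <- round(e$from * (len - 1L))
    hi <- round(e$to * (len - 1L))
    d <- e$depth
    if (e$side == "top") {
      img[(b$y0:(b$y0 + d - 1L)) + 1L, (b$x0 + lo):(b$x0 + hi) + 1L] <- spec$bg
    } else if (e$side == "bottom") {
      img[((b$y1 - d + 1L):b$y1) + 1L, (b$x0 + lo):(b$x0 + hi) + 1L] <- spec$bg
    } else if (e$side == "left") {
      img[(b$y0 + lo):(b$y0 + hi) + 1L, (b$x0:(b$x0 + d - 1L)) + 1L] <- spec$bg
    } else {
      img[(b$y0 + lo):(b$y0 + hi) + 1L, ((b$x1 - d + 1L):b$x1) + 1L] <- spec$bg
    }
  }
  finish_phantom(img, mask, spec)
}

# indicator of the vertebra-like shape on pixel centers, in object
# coordinates; half-open box so the discrete footprint matches the
# rectangle phantom's row/column ranges exactly
vertebra_indicator <- function(u, v, w2, h2, concavity, corner_radius) {
  inside <- u >= -w2 & u < w2 & v >= -h2 & v < h2
  rc <- corner_radius
  if (rc > 0) {
    cu <- pmax(abs(u) - (w2 - rc), 0)
    cv <- pmax(abs(v) - (h2 - rc), 0)
    inside <- inside & cu^2 + cv^2 <= rc^2
  }
  if (concavity > 0) {
    # circular arc through (w2, +/-h2) with sagitta `concavity` at v = 0
    arc_r <- (concavity^2 + h2^2) / (2 * concavity)
    cu0 <- w2 - concavity + arc_r
    inside <- inside & ((abs(u) - cu0)^2 + v^2 >= arc_r^2)
  }
  inside
}

#' Vertebra-like phantom
#'
#' Rounded rectangle with circular-arc concave left/right sides (the typical
#' vertebral body cross-section), optional rotation, and optionally a second
#' identical look-alike structure above the object separated by a small
#' background gap — the configuration in which an over-flexible cut leaks
#' into the neighbor. With zero concavity, rounding and rotation the shape
#' reduces to the plain rectangle. The ground truth contains only the main
#' (central) structure.
#'
#' @param spec a [phantom_spec]; fields `concavity`, `corner_radius`,
#'   `rotation` and `neighbor_gap` apply here.
#' @return List with `image`, `truth` (main structure only) and `spec`.
#' @export
make_vertebra_phantom <- function(spec = phantom_spec(noise_sd = 0)) {
  w2 <- spec$obj_width / 2
  h2 <- spec$obj_height / 2
  xs <- rep(0:(spec$width - 1L), each = spec$height)
  ys <- rep(0:(spec$height - 1L), times = spec$width)
  th <- spec$rotation * pi / 180
  place <- function(cx, cy) {
    du <- xs - cx
    dv <- ys - cy
    u <- cos(th) * du + sin(th) * dv
    v <- -sin(th) * du + cos(th) * dv
    vertebra_indicator(u, v, w2, h2, spec$concavity, spec$corner_radius)
  }
  main <- place(spec$center[1L], spec$center[2L])
  img <- matrix(spec$bg, nrow = spec$height, ncol = spec$width)
  img[cbind(ys + 1L, xs + 1L)[main, , drop = FALSE]] <- spec$fg
  if (spec$neighbor_gap > 0) {
    nb <- place(spec$center[1L],
                spec$center[2L] - spec$obj_height - spec$neighbor_gap)
    img[cbind(ys + 1L, xs + 1L)[nb, , drop = FALSE]] <- spec$fg
  }
  mask <- matrix(0L, nrow = spec$height, ncol = spec$width)
  mask[cbind(ys + 1L, xs + 1L)[main, , drop = FALSE]] <- 1L
  finish_phantom(img, mask, spec)
}

#' Read and write phantom specs as flat key=value text
#'
#' Serializes a [phantom_spec] so phantom generation is scriptable from the
#' command line. Unknown keys error; list-valued fields use compact notation
#' (`missing_corners=br:6,tl:4`;
#' `missing_edges=top:0.2:0.5:2` as `side:from:to:depth`, `;`-separated).
#'
#' @param path text file path.
#' @return `read_phantom_spec()`: a [phantom_spec].
#' @export
read_phantom_spec <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = "="), ""))
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- switch(k,
      width = , height = , seed = as.integer(v),
      fg = , bg = , obj_width = , obj_height = , concavity = ,
      corner_radius = , rotation = , neighbor_gap = , noise_sd = as.numeric(v),
      center = as.numeric(strsplit(v, ",", fixed = TRUE)[[1L]]),
      missing_corners = {
        parts <- strsplit(strsplit(v, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
        stats::setNames(vapply(parts, function(p) as.numeric(p[2L]), 0),
                        vapply(parts, `[`, "", 1L))
      },
      missing_edges = lapply(strsplit(v, ";", fixed = TRUE)[[1L]], function(s) {
        p <- strsplit(s, ":", fixed = TRUE)[[1L]]
        list(side = p[1L], from = as.numeric(p[2L]), to = as.numeric(p[3L]),
             depth = as.numeric(p[4L]))
      }),
      stop("unknown phantom spec key: ", k, call. = FALSE)
    )
  }
  do.call(phantom_spec, args)
}

#' @rdname read_phantom_spec
#' @param spec a [phantom_spec].
#' @export
write_phantom_spec <- function(spec, path) {
  fmt <- function(x) paste(format(x, trim = TRUE, scientific = FALSE), collapse = ",")
  lines <- c(
    paste0("width=", spec$width), paste0("height=", spec$height),
    paste0("fg=", fmt(spec$fg)), paste0("bg=", fmt(spec$bg)),
    paste0("center=", fmt(spec$center)),
    paste0("obj_width=", fmt(spec$obj_width)),
    paste0("obj_height=", fmt(spec$obj_height)),
    paste0("concavity=", fmt(spec$concavity)),
    paste0("corner_radius=", fmt(spec$corner_radius)),
    paste0("rotation=", fmt(spec$rotation)),
    paste0("neighbor_gap=", fmt(spec$neighbor_gap)),
    paste0("noise_sd=", fmt(spec$noise_sd)),
    paste0("seed=", spec$seed)
  )
  if (length(spec$missing_corners)) {
    lines <- c(lines, paste0("missing_corners=",
      paste(names(spec$missing_corners), spec$missing_corners,
            sep = ":", collapse = ",")))
  }
  if (length(spec$missing_edges)) {
    lines <- c(lines, paste0("missing_edges=",
      paste(vapply(spec$missing_edges, function(e) {
        paste(e$side, e$from, e$to, e$depth, sep = ":")
      }, ""), collapse = ";")))
  }
  writeLines(lines, path)
  invisible(path)
}
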