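#' Construct a pixel set
#'
#' A pixel set is the raw material of quantitative iris-color phenotyping: a
#' cloud of RGB pixels sampled from the visible iris, together with two
#' reference colors taken from the same photograph — the whitest part of the
#' sclera and the darkest part of the pupil — used to correct for variable
#' illumination and color casts across photographs.
#'
#' @param pixels numeric matrix (or data frame) with 3 columns (R, G, B),
#'   one row per pixel, channels on the 0--255 scale.
#' @param white_ref,pupil_ref length-3 RGB triples; `white_ref` must be
#'   channel-wise greater than or equal to `pupil_ref`.
#' @return An object of class `pixel_set`: a list with elements `pixels`
#'   (numeric matrix), `white_ref` and `pupil_ref`.
#' @examples
#' ps <- pixel_set(matrix(c(120, 90, 60), 1), c(250, 250, 250), c(5, 5, 5))
#' @export
pixel_set <- function(pixels, white_ref = c(255, 255, 255),
                      pupil_ref = c(0, 0, 0)) {
  pixels <- as.matrix(pixels)
  if (is.null(dim(pixels)) || ncol(pixels) != 3L)
    stop("'pixels' must have 3 columns (R, G, B)")
  storage.mode(pixels) <- "double"
  if (any(pixels < 0 | pixels > 255))
    stop("pixel channels must lie in [0, 255]")
  white_ref <- as.numeric(white_ref); pupil_ref <- as.numeric(pupil_ref)
  stopifnot(length(white_ref) == 3L, length(pupil_ref) == 3L)
  if (any(white_ref < pupil_ref))
    stop("white_ref must be channel-wise >= pupil_ref")
  structure(list(pixels = unname(pixels), white_ref = white_ref,
                 pupil_ref = pupil_ref),
            class = "pixel_set")
}

#' @export
print.pixel_set <- function(x, ...) {
  cat("<pixel_set> ", nrow(x$pixels), " pixels; white_ref = (",
      paste(round(x$white_ref, 1), collapse = ","), "), pupil_ref = (",
      paste(round(x$pupil_ref, 1), collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Normalize pixels against the sclera/pupil references
#'
#' Applies, per channel, the affine map that sends the pupil reference to 0
#' and the white (sclera) reference to 255, so that photographs taken under
#' different illumination become comparable. Results are clipped to
#' \[0, 255\].
#'
#' @param p a [pixel_set].
#' @return A `pixel_set` with remapped pixels and references (0,0,0) /
#'   (255,255,255).
#' @export
normalize_pixels <- function(p) {
  stopifnot(inherits(p, "pixel_set"))
  if (any(p$white_ref <= p$pupil_ref))
    stop("white and pupil references coincide in some channel; cannot normalize")
  scale <- 255 / (p$white_ref - p$pupil_ref)
  px <- sweep(sweep(p$pixels, 2, p$pupil_ref, "-"), 2, scale, "*")
  px[px < 0] <- 0; px[px > 255] <- 255
  pixel_set(px, c(255, 255, 255), c(0, 0, 0))
}

# lightness of each pixel, (max+min)/2 on the [0,1] scale
.pixel_lightness <- function(px) {
  (pmax(px[, 1], px[, 2], px[, 3]) + pmin(px[, 1], px[, 2], px[, 3])) / (2 * 255)
}

#' Remove specular highlights
#'
#' Reflections on the cornea show up as near-white pixels that bias the iris
#' color upward in lightness. This drops pixels whose lightness exceeds
#' `mean + k * SD` of the pixel lightness distribution (an adaptive
#' threshold: it moves with the brightness of each iris). If the rule would
#' remove every pixel, the darkest half is kept instead.
#'
#' @param p a [pixel_set] with at least 3 pixels.
#' @param k positive multiplier of the lightness SD (default 2).
#' @return A `pixel_set` without the flagged pixels.
#' @export
remove_highlights <- function(p, k = 2) {
  stopifnot(inherits(p, "pixel_set"), k > 0)
  if (nrow(p$pixels) < 3L) stop("need at least 3 pixels")
  l <- .pixel_lightness(p$pixels)
  keep <- l <= mean(l) + k * stats::sd(l)
  if (!any(keep)) keep <- l <= stats::median(l)  # darkest half fallback
  pixel_set(p$pixels[keep, , drop = FALSE], p$white_ref, p$pupil_ref)
}

#' Multivariate (geometric) median of a pixel cloud
#'
#' The iris color is summarized as a single point in RGB space: the geometric
#' (spatial, L1) median, i.e. the point minimizing the summed Euclidean
#' distances to all pixels. Computed by Weiszfeld iteration to a per-channel
#' tolerance. Robust to the heavy-tailed pixel clouds real irises produce.
#'
#' @param p a [pixel_set] or a 3-column matrix of pixels.
#' @param tol convergence tolerance per channel (default 1e-6).
#' @param max_iter iteration cap.
#' @param channelwise if `TRUE`, return the vector of per-channel medians
#'   instead (sensitivity-check variant).
#' @return Length-3 numeric RGB triple.
#' @export
multivariate_median <- function(p, tol = 1e-6, max_iter = 1000L,
                                channelwise = FALSE) {
  px <- if (inherits(p, "pixel_set")) p$pixels else as.matrix(p)
  if (nrow(px) == 0L) stop("empty pixel set")
  if (channelwise) return(apply(px, 2, stats::median))
  if (nrow(px) == 1L) return(as.numeric(px[1, ]))
  y <- colMeans(px)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(px, 2, y)^2))
    at_point <- d < 1e-12
    if (any(at_point)) {
      # Weiszfeld with Vardi-Zhang correction when the iterate sits on a data point
      w <- 1 / d[!at_point]
      if (!length(w)) return(as.numeric(y))
      tilde <- colSums(px[!at_point, , drop = FALSE] * w) / sum(w)
      r <- sqrt(sum((colSums(sweep(px[!at_point, , drop = FALSE], 2, y) *
                               w))^2))
      eta <- sum(at_point)
      if (r <= eta) return(as.numeric(y))
      lambda <- eta / r
      y_new <- (1 - lambda) * tilde + lambda * y
    } else {
      w <- 1 / d
      y_new <- colSums(px * w) / sum(w)
    }
    if (max(abs(y_new - y)) < tol) return(as.numeric(y_new))
    y <- y_new
  }
  as.numeric(y)
}

#' Convert RGB to bicone HCL
#'
#' Hue--chroma--lightness coordinates in the RGB-derived bicone: with
#' `M = max(r,g,b)/255` and `m = min(r,g,b)/255`, lightness `L = (M+m)/2`,
#' chroma `C = M - m`, and H the hexagonal hue angle (red 0, green 120,
#' blue 240 degrees). Fully saturated colors sit at the bicone equator
#' (`L = 0.5`); both apexes (black `L = 0`, white `L = 1`) have `C = 0`.
#' H is reported as 0 for achromatic colors (`C = 0`).
#'
#' @param rgb length-3 numeric triple on the 0--255 scale, or a 3-column
#'   matrix of such triples.
#' @return A named numeric vector `c(H, C, L)` (H in degrees in \[0, 360)),
#'   or a 3-column matrix for matrix input.
#' @export
rgb_to_hcl <- function(rgb) {
  if (is.matrix(rgb)) {
    out <- t(apply(rgb, 1, rgb_to_hcl))
    colnames(out) <- c("H", "C", "L")
    return(out)
  }
  rgb <- as.numeric(rgb)
  stopifnot(length(rgb) == 3L)
  if (any(rgb < 0 | rgb > 255)) stop("RGB channels must lie in [0, 255]")
  v <- rgb / 255
  M <- max(v); m <- min(v)
  L <- (M + m) / 2
  C <- M - m
  if (C == 0) {
    H <- 0
  } else {
    r <- v[1]; g <- v[2]; b <- v[3]
    H <- if (M == r) ((g - b) / C) %% 6
         else if (M == g) (b - r) / C + 2
         else (r - g) / C + 4
    H <- (H * 60) %% 360
  }
  c(H = H, C = C, L = L)
}

#' Convert bicone HCL back to RGB
#'
#' Inverse of [rgb_to_hcl]. The chroma attainable at lightness L is
#' `1 - |2L - 1|` (the bicone's radius); a center outside that envelope is
#' rejected.
#'
#' @param h hue in degrees, `[0, 360)`.
#' @param c chroma in `[0, 1]`.
#' @param l lightness in `[0, 1]`.
#' @return Length-3 RGB triple on the 0--255 scale.
#' @export
hcl_to_rgb <- function(h, c, l) {
  stopifnot(c >= 0, l >= 0, l <= 1)
  if (c > 1 - abs(2 * l - 1) + 1e-12)
    stop("chroma ", c, " exceeds the bicone envelope at lightness ", l)
  h <- h %% 360
  hp <- h / 60
  x <- c * (1 - abs(hp %% 2 - 1))
  rgb1 <- if (hp < 1) c(c, x, 0) else if (hp < 2) c(x, c, 0) else
          if (hp < 3) c(0, c, x) else if (hp < 4) c(0, x, c) else
          if (hp < 5) c(x, 0, c) else c(c, 0, x)
  m <- l - c / 2
  pmin(pmax((rgb1 + m) * 255, 0), 255)
}

#' Standardize hue to cos(H - reference)
#'
#' Iris hues concentrate on a plane through the bicone's vertical axis at
#' about 20 degrees, so hue is centered at that reference and mapped to its
#' cosine: +1 for olive/brown/dark-brown eyes (H near the reference), -1 for
#' blue/gray eyes (opposite side of the color wheel). The sine component
#' carries little variation and is dropped.
#'
#' @param H hue(s) in degrees, `[0, 360)`.
#' @param reference reference hue in degrees (default 20).
#' @return `cos(H - reference)`, in `[-1, 1]`.
#' @export
standardize_hue <- function(H, reference = 20) {
  if (any(H < 0 | H >= 360)) stop("H must lie in [0, 360)")
  cos((H - reference) * pi / 180)
}

#' Circular median of hue values
#'
#' The minimizer, over the observed values, of the summed arc-length
#' distances on the circle; ties are broken by the smallest angle. Used to
#' recompute the hue reference from a sample.
#'
#' @param h numeric vector of angles in degrees.
#' @return A single angle in `[0, 360)`.
#' @export
circular_median <- function(h) {
  if (!length(h)) stop("empty hue vector")
  h <- as.numeric(h) %% 360
  arc <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  cost <- vapply(h, function(a) sum(arc(a, h)), numeric(1))
  cand <- h[cost == min(cost)]
  min(cand)
}

#' Inter-rater concordance of extracted iris colors
#'
#' Median, over photographs, of the mean absolute per-channel RGB difference
#' between two raters' extractions (0--255 scale).
#'
#' @param a,b matrices (or data frames) of RGB triples, one row per
#'   photograph, equal row counts.
#' @return A single number on the 0--255 scale.
#' @export
rater_concordance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("rater lists have different lengths")
  if (nrow(a) < 1L) stop("need at least one item")
  stats::median(rowMeans(abs(a - b)))
}

#' Full iris-color phenotyping pipeline
#'
#' Normalize against the sclera/pupil references, remove specular
#' highlights, take the geometric median in RGB, convert to bicone HCL and
#' standardize the hue. This is the per-photograph path from raw pixels to
#' the association-ready variables (L, C, cos(H - 20)).
#'
#' @param p a [pixel_set].
#' @param k highlight-removal SD multiplier (default 2); `Inf` disables
#'   removal.
#' @param hue_reference reference hue in degrees (default 20).
#' @return A one-row data frame with columns `rgb_r`, `rgb_g`, `rgb_b`,
#'   `H_deg`, `C`, `L`, `cosH_std`.
#' @examples
#' ps <- generate_iris_pixels(c(30, 0.3, 0.35), n_pixels = 200, seed = 1)
#' iris_color(ps)
#' @export
iris_color <- function(p, k = 2, hue_reference = 20) {
  p <- normalize_pixels(p)
  if (is.finite(k) && nrow(p$pixels) >= 3L) p <- remove_highlights(p, k)
  med <- multivariate_median(p)
  hcl <- rgb_to_hcl(med)
  data.frame(rgb_r = med[1], rgb_g = med[2], rgb_b = med[3],
             H_deg = unname(hcl["H"]), C = unname(hcl["C"]),
             L = unname(hcl["L"]),
             cosH_std = unname(standardize_hue(hcl["H"], hue_reference)))
}
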