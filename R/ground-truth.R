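#' Leaf area from a binary silhouette image
#'
#' Ground-truth companion measurement: a cut leaf is photographed flat
#' against paper with a ruler, the image is binarized, and the area is
#' the foreground pixel count divided by the squared pixel-per-cm scale
#' read off the ruler.
#'
#' @param image logical or 0/1 numeric matrix (foreground `TRUE`/1), or
#'   the path to a PNG whose pixels are exactly 0 or 1 (grayscale; RGB
#'   channels must agree).
#' @param pixels_per_cm ruler scale (> 0).
#' @return Area in square centimeters.
#' @examples
#' img <- matrix(0, 20, 20); img[5:14, 5:14] <- 1
#' silhouette_leaf_area(img, pixels_per_cm = 10)  # 1 cm^2
#' @export
silhouette_leaf_area <- function(image, pixels_per_cm) {
  if (pixels_per_cm <= 0) stop("pixels_per_cm must be > 0")
  if (is.character(image)) {
    px <- png::readPNG(image)
    if (length(dim(px)) == 3) {
      rng <- apply(px[, , 1:min(3, dim(px)[3]), drop = FALSE], c(1, 2),
                   function(v) diff(range(v)))
      if (any(rng > 0)) stop("image is not binary: RGB channels disagree")
      px <- px[, , 1]
    }
    image <- px
  }
  if (is.logical(image)) image <- image * 1
  image <- as.matrix(image)
  if (!all(image %in% c(0, 1))) {
    stop("image is not binary: values other than 0/1 present")
  }
  sum(image) / pixels_per_cm^2
}

#' Fruit volume from a buoyancy scale reading
#'
#' Ground-truth companion measurement: with a beaker of water tared on
#' a scale, submerging the fruit raises the reading by the weight of
#' displaced water, so reading / water density is the fruit volume.
#'
#' @param scale_reading_g scale reading in grams (>= 0).
#' @param water_density water density in g/cm^3 (default 1.0;
#'   0.9982 at 20 degrees C).
#' @return Volume in cubic centimeters.
#' @examples
#' buoyancy_volume(150)            # 150 cm^3
#' buoyancy_volume(150, 0.9982)    # 150.27 cm^3
#' @export
buoyancy_volume <- function(scale_reading_g, water_density = 1.0) {
  if (any(scale_reading_g < 0)) stop("scale reading must be >= 0")
  if (water_density <= 0) stop("water_density must be > 0")
  scale_reading_g / water_density
}
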