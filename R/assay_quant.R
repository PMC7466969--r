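# CAS siderophore plate quantification: the blue-green Fe-CAS-surfactant
# complex turns yellow where secreted siderophores strip the iron; activity
# is measured as the yellow area of the dish, scaled to cm^2 via the known
# dish diameter.

#' Measure the yellow halo area of a CAS assay plate image
#'
#' The dish is detected as the bright (non-background) pixel region; its
#' pixel area gives the pixel scale via the known dish diameter. Yellow is
#' thresholded in HSV space (default hue 40-70 degrees, saturation >= 0.25,
#' value >= 0.2) inside the dish circle and converted to cm^2.
#'
#' @param image Path to a PNG image, or an `height x width x 3` numeric
#'   array in `[0, 1]`.
#' @param dish_diameter_cm Physical dish diameter (default 5.5 cm).
#' @param hue_range Yellow hue band in degrees (default `c(40, 70)`).
#' @param min_saturation,min_value HSV saturation/value floors.
#' @param bg_value Luminance threshold separating dish from background.
#' @return Yellow area in cm^2.
#' @export
measure_halo_area <- function(image, dish_diameter_cm = 5.5,
                              hue_range = c(40, 70), min_saturation = 0.25,
                              min_value = 0.2, bg_value = 0.2) {
  img <- if (is.character(image)) png::readPNG(image) else image
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  lum <- (r + g + b) / 3
  fg <- lum > bg_value
  if (sum(fg) < 100) stop("no dish detected in image")
  # dish radius from the foreground area; circularity sanity check
  area_px <- sum(fg)
  r_px <- sqrt(area_px / pi)
  rows <- row(fg)[fg]; cols <- col(fg)[fg]
  cy <- mean(rows); cx <- mean(cols)
  inside <- ((row(fg) - cy)^2 + (col(fg) - cx)^2) <= r_px^2
  circularity <- sum(fg & inside) / area_px
  if (circularity < 0.85) stop("no near-circular dish region detected")
  px_per_cm <- 2 * r_px / dish_diameter_cm

  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 1)
  hue <- hsv[1, ] * 360
  yellow <- hue >= hue_range[1] & hue <= hue_range[2] &
    hsv[2, ] >= min_saturation & hsv[3, ] >= min_value
  yellow <- matrix(yellow, nrow(r), ncol(r)) & inside
  sum(yellow) / px_per_cm^2
}

#' Compare siderophore activity across strains
#'
#' One-way ANOVA over per-strain replicate halo areas plus Tukey HSD
#' pairwise comparisons (blank plates and controls are treated as strains).
#'
#' @param measurements Data frame with columns `strain` and
#'   `yellow_area_cm2`, >= 2 strains with >= 2 replicates each.
#' @return List with `anova` (a `stat_result`) and `tukey` (pairwise table).
#' @export
compare_activity <- function(measurements) {
  groups <- split(measurements$yellow_area_cm2, measurements$strain)
  list(anova = anova_oneway(groups), tukey = tukey_hsd(groups))
}
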