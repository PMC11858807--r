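# Heath-Carter anthropometric somatotype: the three component scores, the
# 2-D somatochart projection, dispersion statistics and the 13-category
# classification.

#' Heath-Carter endomorphy
#'
#' Relative adiposity from the triceps, subscapular and supraspinale
#' skinfolds. With `height_correct = TRUE` (the standard form) the skinfold
#' sum is scaled by 170.18/stature so that athletes of different size are
#' compared on proportional adiposity.
#'
#' @param triceps_sf_mm,subscapular_sf_mm,supraspinale_sf_mm Skinfolds (mm).
#' @param stature_cm Stature in cm (required when `height_correct = TRUE`).
#' @param height_correct Apply the 170.18/stature scaling (default TRUE).
#' @return Endomorphy component score, floored at 0.1.
#' @export
#' @examples
#' endomorphy(7.0, 8.4, 7.0, stature_cm = 175.1)
endomorphy <- function(triceps_sf_mm, subscapular_sf_mm, supraspinale_sf_mm,
                       stature_cm = NULL, height_correct = TRUE) {
  s <- triceps_sf_mm + subscapular_sf_mm + supraspinale_sf_mm
  if (height_correct) {
    if (is.null(stature_cm)) abort("Height correction needs 'stature_cm'.")
    check_positive(stature_cm, "stature_cm")
    s <- s * 170.18 / stature_cm
  }
  val <- -0.7182 + 0.1451 * s - 0.00068 * s^2 + 0.0000014 * s^3
  pmax(val, 0.1)
}

#' Heath-Carter mesomorphy
#'
#' Musculoskeletal robustness relative to stature, from the humerus and
#' femur breadths and the skinfold-corrected flexed arm and calf girths
#' (Heath-Carter correction: girth minus skinfold in cm).
#'
#' @param humerus_breadth_cm,femur_breadth_cm Bone breadths (cm).
#' @param flexed_arm_girth_cm,triceps_sf_mm Flexed arm girth and triceps
#'   skinfold.
#' @param calf_girth_cm,calf_sf_mm Calf girth and medial calf skinfold.
#' @param stature_cm Stature in cm.
#' @return Mesomorphy component score, floored at 0.1.
#' @export
#' @examples
#' mesomorphy(7.0, 9.5, 29.1, 7.0, 37.2, 5.9, 175.1)
mesomorphy <- function(humerus_breadth_cm, femur_breadth_cm,
                       flexed_arm_girth_cm, triceps_sf_mm,
                       calf_girth_cm, calf_sf_mm, stature_cm) {
  cag <- corrected_girth(flexed_arm_girth_cm, triceps_sf_mm, "heath_carter")
  ccg <- corrected_girth(calf_girth_cm, calf_sf_mm, "heath_carter")
  val <- 0.858 * humerus_breadth_cm + 0.601 * femur_breadth_cm +
    0.188 * cag + 0.161 * ccg - 0.131 * stature_cm + 4.5
  pmax(val, 0.1)
}

#' Heath-Carter ectomorphy
#'
#' Relative linearity from the height-weight ratio HWR = stature /
#' mass^(1/3), through the standard piecewise rule. The upper branch applies
#' at HWR >= 40.75 (inclusive).
#'
#' @param body_mass_kg Body mass (kg).
#' @param stature_cm Stature (cm).
#' @return Ectomorphy component score, floored at 0.1.
#' @export
#' @examples
#' ectomorphy(65.0, 175.1)
ectomorphy <- function(body_mass_kg, stature_cm) {
  check_positive(body_mass_kg, "body_mass_kg")
  check_positive(stature_cm, "stature_cm")
  hwr <- stature_cm / body_mass_kg^(1 / 3)
  val <- ifelse(hwr >= 40.75, 0.732 * hwr - 28.58,
                ifelse(hwr > 38.25, 0.463 * hwr - 17.63, 0.1))
  pmax(val, 0.1)
}

#' Somatochart coordinates
#'
#' Projects somatotypes onto the 2-D somatochart: X = ectomorphy -
#' endomorphy, Y = 2*mesomorphy - (endomorphy + ectomorphy).
#'
#' @param endo,meso,ecto Component scores (vectors of equal length).
#' @return A tibble with columns `x` and `y`.
#' @export
#' @examples
#' somatochart_xy(2.1, 4.4, 3.3)
somatochart_xy <- function(endo, meso, ecto) {
  tibble::tibble(x = ecto - endo, y = 2 * meso - (endo + ecto))
}

#' Somatotype dispersion distance (SDD)
#'
#' Distance between two somatoplots in somatochart Y-units:
#' sqrt(3*(dx)^2 + (dy)^2). The sqrt(3) weighting on X makes unit steps
#' along either chart axis commensurate on the triangular grid.
#'
#' @param x_a,y_a,x_b,y_b Somatochart coordinates of the two points.
#' @return SDD (Y-units), vectorized.
#' @export
sdd <- function(x_a, y_a, x_b, y_b) {
  sqrt(3 * (x_a - x_b)^2 + (y_a - y_b)^2)
}

#' Somatotype dispersion mean (SDM)
#'
#' Mean SDD of each individual somatoplot from a reference plot (by default
#' the mean somatoplot of the set).
#'
#' @param x,y Individual somatochart coordinates.
#' @param ref_x,ref_y Reference point; defaults to the coordinate means.
#' @return Mean dispersion distance (scalar).
#' @export
sdm <- function(x, y, ref_x = mean(x), ref_y = mean(y)) {
  if (!length(x)) abort("sdm() needs a non-empty set of somatoplots.")
  mean(sdd(x, y, ref_x, ref_y))
}

#' Somatotype attitudinal distance (SAD)
#'
#' 3-D Euclidean distance between two somatotypes in component space.
#'
#' @param endo_a,meso_a,ecto_a,endo_b,meso_b,ecto_b Component scores.
#' @return SAD (component units), vectorized.
#' @export
sad <- function(endo_a, meso_a, ecto_a, endo_b, meso_b, ecto_b) {
  sqrt((endo_a - endo_b)^2 + (meso_a - meso_b)^2 + (ecto_a - ecto_b)^2)
}

#' Somatotype attitudinal mean (SAM)
#'
#' Mean SAD of each somatotype from a reference somatotype (by default the
#' component-wise mean somatotype of the set).
#'
#' @param endo,meso,ecto Individual component scores.
#' @param ref Reference somatotype, numeric length 3 (endo, meso, ecto);
#'   defaults to the component-wise mean.
#' @return Mean attitudinal distance (scalar).
#' @export
sam <- function(endo, meso, ecto, ref = c(mean(endo), mean(meso), mean(ecto))) {
  if (!length(endo)) abort("sam() needs a non-empty set of somatotypes.")
  mean(sad(endo, meso, ecto, ref[1], ref[2], ref[3]))
}

#' Thirteen-category somatotype classification
#'
#' Classifies 1-dp rounded somatotypes by the standard decision rules:
#' \enumerate{
#'   \item \emph{central} when no component differs from any other by more
#'     than 1.0;
#'   \item an edge category ("endomorph-mesomorph", "mesomorph-ectomorph",
#'     "endomorph-ectomorph") when the two largest components differ by at
#'     most 0.5 and both exceed the third;
#'   \item otherwise the strictly greatest component is dominant:
#'     "balanced X" when the other two differ from each other by at most
#'     0.5, else "Y-ic X" naming the second component.
#' }
#' Classification operates on components rounded to one decimal because the
#' rules are stated at that resolution; exact ties on the dominant component
#' resolve deterministically to the edge category.
#'
#' @param endo,meso,ecto Component scores (vectors of equal length).
#' @return Character vector of category labels.
#' @export
#' @examples
#' classify_somatotype(2.1, 4.4, 3.3)  # ectomorphic mesomorph
classify_somatotype <- function(endo, meso, ecto) {
  comp_names <- c("endomorph", "mesomorph", "ectomorph")
  adj <- c("endomorphic", "mesomorphic", "ectomorphic")
  vapply(seq_along(endo), function(i) {
    v <- round(c(endo[i], meso[i], ecto[i]), 1)
    if (anyNA(v)) return(NA_character_)
    if (max(v) - min(v) <= 1.0) return("central")
    ord <- order(v, decreasing = TRUE)  # stable: ties keep chart order
    c1 <- ord[1]; c2 <- ord[2]; c3 <- ord[3]
    if (v[c1] - v[c2] <= 0.5 && v[c2] > v[c3]) {
      pair <- sort(c(c1, c2))  # chart order endo-meso-ecto
      return(paste(comp_names[pair[1]], comp_names[pair[2]], sep = "-"))
    }
    if (v[c2] - v[c3] <= 0.5) return(paste("balanced", comp_names[c1]))
    paste(adj[c2], comp_names[c1])
  }, character(1))
}

#' Compute somatotype columns for a cohort
#'
#' Adds the three Heath-Carter components (full precision), somatochart
#' coordinates and the 13-category label to an athlete data frame in the
#' cohort CSV schema.
#'
#' @param data Athlete data frame (see [cohort_cols()]).
#' @param height_correct Apply the endomorphy height correction (default
#'   TRUE).
#' @return The input with columns `endo`, `meso`, `ecto`, `chart_x`,
#'   `chart_y`, `soma_category` appended.
#' @export
add_somatotype <- function(data, height_correct = TRUE) {
  data <- tibble::as_tibble(data)
  out <- dplyr::mutate(
    data,
    endo = endomorphy(.data$sf_triceps_mm, .data$sf_subscapular_mm,
                      .data$sf_supraspinale_mm, stature_cm = .data$stature_cm,
                      height_correct = height_correct),
    meso = mesomorphy(.data$b_humerus_cm, .data$b_femur_cm,
                      .data$g_flexed_arm_cm, .data$sf_triceps_mm,
                      .data$g_calf_cm, .data$sf_calf_mm, .data$stature_cm),
    ecto = ectomorphy(.data$mass_kg, .data$stature_cm)
  )
  xy <- somatochart_xy(out$endo, out$meso, out$ecto)
  out$chart_x <- xy$x
  out$chart_y <- xy$y
  out$soma_category <- classify_somatotype(out$endo, out$meso, out$ecto)
  out
}

#' Dispersion summary of a set of somatotypes
#'
#' Per-individual dispersion (SDD, in somatochart Y-units) and attitudinal
#' (SAD, in component units) distances from a reference somatotype, plus
#' their means (SDM, SAM). The default reference is the mean somatotype of
#' the set, as used when describing the spread of a group around its mean
#' somatoplot.
#'
#' @param data Data frame with columns `endo`, `meso`, `ecto` (e.g. from
#'   [add_somatotype()]).
#' @param ref Reference somatotype, numeric length 3; defaults to the
#'   component-wise mean of `data`.
#' @return A one-row tibble: `n`, `sdm`, `sam`, plus list-columns `sdd` and
#'   `sad` holding the per-individual distances, and `ref_endo`, `ref_meso`,
#'   `ref_ecto`.
#' @export
somatotype_dispersion <- function(data, ref = NULL) {
  if (!nrow(data)) abort("somatotype_dispersion() needs at least one somatotype.")
  if (is.null(ref)) ref <- c(mean(data$endo), mean(data$meso), mean(data$ecto))
  xy <- somatochart_xy(data$endo, data$meso, data$ecto)
  ref_xy <- somatochart_xy(ref[1], ref[2], ref[3])
  sdd_i <- sdd(xy$x, xy$y, ref_xy$x, ref_xy$y)
  sad_i <- sad(data$endo, data$meso, data$ecto, ref[1], ref[2], ref[3])
  tibble::tibble(
    n = nrow(data), sdm = mean(sdd_i), sam = mean(sad_i),
    sdd = list(sdd_i), sad = list(sad_i),
    ref_endo = ref[1], ref_meso = ref[2], ref_ecto = ref[3]
  )
}

#' Somatochart export table
#'
#' The somatochart CSV contract: one row per athlete with components,
#' chart coordinates and category.
#'
#' @param data Output of [add_somatotype()].
#' @return A tibble with columns `id`, `endo`, `meso`, `ecto`, `x`, `y`,
#'   `category`.
#' @export
somatochart_table <- function(data) {
  tibble::tibble(
    id = data$id, endo = data$endo, meso = data$meso, ecto = data$ecto,
    x = data$chart_x, y = data$chart_y, category = data$soma_category
  )
}
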