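#' Configuration of a synthetic immunofluorescence slide
#'
#' Describes a three-channel labelled-nuclei image: DAPI disks for every
#' nucleus plus sub-threshold debris specks, and marker signal (two channels)
#' on double-positive nuclei only. Merged pairs are rendered as one connected
#' component whose area falls in the two-nucleus band of the counting rule.
#'
#' @param image_size_px Square image edge in pixels (default 512).
#' @param pixel_size_um Pixel edge length, micrometres per pixel (default
#'   0.62, a 20x objective).
#' @param n_nuclei Number of singleton nuclei.
#' @param purity_fraction Fraction of nuclei positive in both marker
#'   channels, in `[0, 1]`.
#' @param n_merged_pairs Number of merged two-nucleus components.
#' @param n_debris Number of sub-30 um^2 debris specks (DAPI channel only).
#' @param nucleus_radius_um Nucleus radius; `pi * r^2` must exceed the 30
#'   um^2 exclusion threshold (default 5, area about 78.5 um^2).
#' @param noise_sd Gaussian pixel noise SD on the 0-255 intensity scale.
#' @param seed Integer seed.
#' @return A list of class `image_sim_config`.
#' @export
image_sim_config <- function(image_size_px = 512L, pixel_size_um = 0.62,
                             n_nuclei = 50L, purity_fraction = 0.9,
                             n_merged_pairs = 0L, n_debris = 0L,
                             nucleus_radius_um = 5, noise_sd = 4, seed = 1L) {
  if (purity_fraction < 0 || purity_fraction > 1) {
    abort("`purity_fraction` must lie in [0, 1].")
  }
  if (pi * nucleus_radius_um^2 <= 30) {
    abort("Nucleus area pi*r^2 must exceed the 30 um^2 exclusion threshold.")
  }
  if (pixel_size_um <= 0 || image_size_px < 32) {
    abort("Need pixel_size_um > 0 and image_size_px >= 32.")
  }
  structure(
    list(image_size_px = as.integer(image_size_px),
         pixel_size_um = pixel_size_um, n_nuclei = as.integer(n_nuclei),
         purity_fraction = purity_fraction,
         n_merged_pairs = as.integer(n_merged_pairs),
         n_debris = as.integer(n_debris),
         nucleus_radius_um = nucleus_radius_um,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "image_sim_config"
  )
}

# Internal: stamp a filled disk (centre in px, radius in px) into a matrix.
.stamp_disk <- function(img, ci, cj, r_px, value) {
  n <- nrow(img)
  ii <- max(1L, floor(ci - r_px)):min(n, ceiling(ci + r_px))
  jj <- max(1L, floor(cj - r_px)):min(ncol(img), ceiling(cj + r_px))
  d2 <- outer((ii - ci)^2, (jj - cj)^2, `+`)
  sub <- img[ii, jj]
  sub[d2 <= r_px^2] <- value
  img[ii, jj] <- sub
  img
}

#' Generate a synthetic immunofluorescence slide with ground truth
#'
#' Channel 1 carries DAPI disks for every nucleus (singletons and merged
#' pairs) plus debris specks; channels 2 and 3 carry marker signal on
#' double-positive nuclei only. Merged pairs are two disks at 1.6 radii
#' centre distance, forming one connected component of about 150 um^2 (the
#' two-nucleus band). Objects are placed by rejection sampling so distinct
#' objects never touch.
#'
#' @param config An [image_sim_config()].
#' @return A list: `image` (array `h x w x 3`, intensities about 20
#'   background / 200 foreground), `truth` (tibble `object_id`, `type` in
#'   nucleus/merged_pair/debris, `n_nuclei`, `double_positive`), and scalar
#'   truth attributes `n_dapi_true` (rule-corrected DAPI count) and
#'   `n_double_positive_true`.
#' @export
gen_if_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  set.seed(config$seed)
  n_px <- config$image_size_px
  psz <- config$pixel_size_um
  r_px <- config$nucleus_radius_um / psz

  n_obj <- config$n_nuclei + config$n_merged_pairs + config$n_debris
  types <- c(rep("nucleus", config$n_nuclei),
             rep("merged_pair", config$n_merged_pairs),
             rep("debris", config$n_debris))
  # merged pairs occupy an oblong footprint: block radius covers both lobes
  block <- ifelse(types == "merged_pair", r_px * 1.8 + 2,
                  ifelse(types == "nucleus", r_px + 2, r_px * 0.5 + 2))
  centres <- matrix(NA_real_, n_obj, 2)
  margin <- block + 1
  for (i in seq_len(n_obj)) {
    placed <- FALSE
    for (try in seq_len(5000L)) {
      cand <- runif(2, min = margin[i] + 1, max = n_px - margin[i])
      if (i == 1L || all(sqrt(rowSums((centres[seq_len(i - 1L), , drop = FALSE] -
                                         matrix(cand, i - 1L, 2, byrow = TRUE))^2)) >
                           block[seq_len(i - 1L)] + block[i] + 2)) {
        centres[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("Could not place all objects; reduce counts or radius.")
  }

  dp <- rep(FALSE, n_obj)
  idx_nuc <- which(types == "nucleus")
  idx_pair <- which(types == "merged_pair")
  n_dp_nuc <- round(config$purity_fraction * config$n_nuclei)
  n_dp_pair <- round(config$purity_fraction * config$n_merged_pairs)
  if (n_dp_nuc > 0) dp[sample(idx_nuc, n_dp_nuc)] <- TRUE
  if (n_dp_pair > 0) dp[sample(idx_pair, n_dp_pair)] <- TRUE

  fg <- 200; bg <- 20
  dapi <- matrix(bg, n_px, n_px)
  m1 <- matrix(bg, n_px, n_px)
  m2 <- matrix(bg, n_px, n_px)
  pair_angle <- runif(n_obj, 0, pi)
  debris_r <- runif(n_obj, 1.2, 2.4) / psz
  for (i in seq_len(n_obj)) {
    ci <- centres[i, 1]; cj <- centres[i, 2]
    if (types[i] == "nucleus") {
      dapi <- .stamp_disk(dapi, ci, cj, r_px, fg)
      if (dp[i]) {
        m1 <- .stamp_disk(m1, ci, cj, r_px, fg)
        m2 <- .stamp_disk(m2, ci, cj, r_px, fg)
      }
    } else if (types[i] == "merged_pair") {
      off <- 0.8 * r_px * c(cos(pair_angle[i]), sin(pair_angle[i]))
      for (s in c(-1, 1)) {
        dapi <- .stamp_disk(dapi, ci + s * off[1], cj + s * off[2], r_px, fg)
        if (dp[i]) {
          m1 <- .stamp_disk(m1, ci + s * off[1], cj + s * off[2], r_px, fg)
          m2 <- .stamp_disk(m2, ci + s * off[1], cj + s * off[2], r_px, fg)
        }
      }
    } else {
      dapi <- .stamp_disk(dapi, ci, cj, debris_r[i], fg)
    }
  }
  img <- array(0, dim = c(n_px, n_px, 3L))
  img[, , 1] <- dapi
  img[, , 2] <- m1
  img[, , 3] <- m2
  if (config$noise_sd > 0) {
    img <- img + array(rnorm(length(img), sd = config$noise_sd), dim = dim(img))
  }
  img <- pmin(pmax(img, 0), 255)

  n_per <- ifelse(types == "nucleus", 1L, ifelse(types == "merged_pair", 2L, 0L))
  truth <- tibble(
    object_id = seq_len(n_obj), type = types,
    n_nuclei = n_per, double_positive = dp,
    centre_row = centres[, 1], centre_col = centres[, 2]
  )
  list(
    image = img, truth = truth,
    n_dapi_true = sum(n_per),
    n_double_positive_true = sum(n_per[dp])
  )
}
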