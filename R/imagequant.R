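#' Area-to-count correction rule
#'
#' Connected components below `exclude_below_um2` are discarded as debris or
#' dead-cell specks; components above `two_above_um2` count as two joined
#' nuclei and above `three_above_um2` as three. "Above" is strict: a
#' component of exactly 130 um^2 counts as one nucleus, exactly 200 um^2 as
#' two.
#'
#' @param exclude_below_um2 Exclusion threshold (default 30).
#' @param two_above_um2 Two-nucleus threshold (default 130).
#' @param three_above_um2 Three-nucleus threshold (default 200).
#' @return A list of class `area_rule`.
#' @export
area_rule <- function(exclude_below_um2 = 30, two_above_um2 = 130,
                      three_above_um2 = 200) {
  if (!(0 < exclude_below_um2 && exclude_below_um2 < two_above_um2 &&
        two_above_um2 < three_above_um2)) {
    abort("Need 0 < exclude_below < two_above < three_above.")
  }
  structure(
    list(exclude_below_um2 = exclude_below_um2,
         two_above_um2 = two_above_um2,
         three_above_um2 = three_above_um2),
    class = "area_rule"
  )
}

#' Number of nuclei a component of a given area represents
#'
#' @param area_um2 Numeric vector of component areas.
#' @param rule An [area_rule()].
#' @return Integer vector of 0, 1, 2 or 3.
#' @export
area_to_count <- function(area_um2, rule = area_rule()) {
  out <- rep.int(1L, length(area_um2))
  out[area_um2 < rule$exclude_below_um2] <- 0L
  out[area_um2 > rule$two_above_um2] <- 2L
  out[area_um2 > rule$three_above_um2] <- 3L
  out
}

#' Maximum-intensity projection of a z-stack
#'
#' @param zstack Numeric array `h x w x z` (or an `h x w` matrix, returned
#'   unchanged).
#' @return An `h x w` matrix of per-pixel maxima over planes.
#' @export
max_project <- function(zstack) {
  if (is.matrix(zstack)) return(zstack)
  if (length(dim(zstack)) != 3L || dim(zstack)[3] < 1L) {
    abort("`zstack` must be an h x w x z array with at least one plane.")
  }
  dims <- dim(zstack)[1:2]
  out <- matrix(zstack[, , 1L], dims[1], dims[2])
  for (k in seq_len(dim(zstack)[3])[-1L]) {
    out <- pmax(out, matrix(zstack[, , k], dims[1], dims[2]))
  }
  out
}

#' Binarise a channel image
#'
#' @param image Numeric matrix.
#' @param method `"otsu"` (automatic, the default) or `"fixed"`.
#' @param threshold Threshold for `method = "fixed"`.
#' @return Logical matrix, `TRUE` where `image >= threshold` (for Otsu the
#'   threshold is placed between the two pixel populations).
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold)) abort("`threshold` is required for method = 'fixed'.")
    return(image >= threshold)
  }
  r <- range(image)
  if (r[1] == r[2]) abort("Degenerate threshold: image is constant.")
  scaled <- (image - r[1]) / (r[2] - r[1])
  t_scaled <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
  image >= r[1] + t_scaled * (r[2] - r[1])
}

# Internal: 8-connected component labelling. EBImage::bwlabel is 4-connected;
# diagonally adjacent 4-labels are merged through an igraph components pass.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(round(lab)), nrow = nrow(mask))
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]  # up-right diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  edges <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(edges) == 0L) return(lab)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges)))
  map <- as.integer(igraph::components(g)$membership)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

#' Count nuclei in a binary mask with area-to-count correction
#'
#' Connected components (8-connectivity) are measured in um^2 and each
#' contributes 0, 1, 2 or 3 nuclei under the [area_rule()].
#'
#' @param mask Logical (or 0/1) matrix.
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @param rule An [area_rule()].
#' @return A list: `count` (total nuclei) and `components` (tibble `label`,
#'   `area_um2`, `n_nuclei`).
#' @export
count_nuclei <- function(mask, pixel_size_um, rule = area_rule()) {
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be > 0.")
  mask <- mask > 0
  if (!any(mask)) {
    return(list(count = 0L,
                components = tibble(label = integer(), area_um2 = numeric(),
                                    n_nuclei = integer())))
  }
  lab <- label_components_8(mask)
  px <- tabulate(lab[lab > 0L])
  area <- px * pixel_size_um^2
  contrib <- area_to_count(area, rule)
  list(
    count = sum(contrib),
    components = tibble(label = seq_along(area), area_um2 = area,
                        n_nuclei = contrib)
  )
}

#' Count colocalized nuclei between two channel masks
#'
#' The colocalized mask is the pixelwise AND of the two binary masks;
#' components are then counted with the same area rule as single-channel
#' nuclei.
#'
#' @param mask_a,mask_b Logical matrices of the same shape.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param rule An [area_rule()].
#' @return A list as in [count_nuclei()].
#' @export
coloc_count <- function(mask_a, mask_b, pixel_size_um, rule = area_rule()) {
  if (!all(dim(mask_a) == dim(mask_b))) abort("Masks differ in shape.")
  count_nuclei((mask_a > 0) & (mask_b > 0), pixel_size_um, rule)
}

#' Purity of a culture from a multi-channel immunofluorescence stack
#'
#' Purity is the percentage of DAPI-positive nuclei that are double positive
#' for the two designated marker channels: each channel is binarised, total
#' nuclei are counted in the DAPI mask, double positives in the intersection
#' of the two marker masks, all with the same area-to-count rule.
#'
#' @param stack Numeric array `h x w x channels` (already projected; pass a
#'   z-stack per channel through [max_project()] first).
#' @param channels Named list designating channel indices: `dapi` (one index)
#'   and `markers` (two indices).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param rule An [area_rule()].
#' @param method Binarisation method passed to [binarize()].
#' @param threshold Fixed threshold if `method = "fixed"`.
#' @return One-row tibble: `n_dapi`, `n_double_positive`, `purity_pct`,
#'   `flagged` (`TRUE` when double positives exceed DAPI nuclei after area
#'   correction; the ratio is reported, never clipped).
#' @export
compute_purity <- function(stack, channels = list(dapi = 1L, markers = c(2L, 3L)),
                           pixel_size_um = 0.62, rule = area_rule(),
                           method = "otsu", threshold = NULL) {
  stopifnot(length(dim(stack)) == 3L)
  if (is.null(channels$dapi) || length(channels$markers) != 2L) {
    abort("`channels` must designate one dapi index and two marker indices.")
  }
  bin <- function(k) binarize(stack[, , k], method = method, threshold = threshold)
  n_dapi <- count_nuclei(bin(channels$dapi), pixel_size_um, rule)$count
  if (n_dapi == 0L) abort("Undefined purity: no DAPI-positive nuclei detected.")
  n_dp <- coloc_count(bin(channels$markers[1]), bin(channels$markers[2]),
                      pixel_size_um, rule)$count
  tibble(
    n_dapi = n_dapi,
    n_double_positive = n_dp,
    purity_pct = 100 * n_dp / n_dapi,
    flagged = n_dp > n_dapi
  )
}
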