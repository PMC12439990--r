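#' Construct a label image container
#'
#' @param cell_labels integer raster (0 = background, k = pixels of cell k;
#'   labels are contiguous positive integers).
#' @param vessel_mask logical raster of vascular pixels, same shape.
#' @param channels named list of real rasters (e.g. `NG2`, `aSMA`, `FN`).
#' @param pixel_size_um physical pixel size in micrometres.
#' @return object of class `label_image`.
#' @export
label_image <- function(cell_labels, vessel_mask, channels, pixel_size_um) {
  check_scalar_number(pixel_size_um, "pixel_size_um", lower = 0,
                      strict_lower = TRUE)
  dims <- dim(cell_labels)
  if (!identical(dim(vessel_mask), dims))
    stop_config("vessel_mask shape differs from cell_labels", "vessel_mask")
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), dims))
      stop_config(sprintf("channel '%s' shape differs from cell_labels", nm),
                  "channels")
  }
  labs <- sort(unique(as.integer(cell_labels[cell_labels > 0])))
  if (length(labs) && !identical(labs, seq_along(labs)))
    stop_config("cell labels must be contiguous positive integers",
                "cell_labels")
  structure(list(cell_labels = cell_labels,
                 vessel_mask = vessel_mask != 0,
                 channels = channels,
                 pixel_size_um = pixel_size_um),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat("label image ", paste(dim(x$cell_labels), collapse = "x"),
      " px (", x$pixel_size_um, " um/px), ",
      max(0, x$cell_labels), " cells, channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Distance (in um) of every pixel to the nearest vessel pixel.
vessel_distance_map <- function(img) {
  if (!any(img$vessel_mask)) stop("vessel mask is empty")
  dm <- EBImage::distmap(1 - img$vessel_mask, metric = "euclidean")
  as.matrix(dm) * img$pixel_size_um
}

# default per-state distance bands (um from the vessel surface) and marker
# intensity means used by the synthetic tissue generator: pericytes abut the
# vessel, intermediates sit near it, myofibroblasts lie in the parenchyma.
default_state_bands <- function() list(pericyte = c(0, 1),
                                       intermediate = c(4, 10),
                                       myofibroblast = c(15, 45))

default_intensity_params <- function() list(
  ng2_mean = c(pericyte = 1, intermediate = 1, myofibroblast = 0.1),
  asma_mean = c(pericyte = 0.1, intermediate = 1, myofibroblast = 1),
  noise_sd = 0.05
)

#' Generate a synthetic labelled tissue image with ground-truth cell states
#'
#' Draws a vertical vessel tube, then places elliptical cells whose distance
#' from the vessel surface follows state-specific bands (pericytes adjacent,
#' intermediates near, myofibroblasts far) and whose NG2/alpha-SMA mean
#' intensities are state-dependent with additive Gaussian noise.  A
#' fibronectin (FN) channel is laid down as halos around
#' myofibroblast-state cells.  Ground-truth states are returned alongside
#' the image.
#'
#' @param n_cells number of cells to place.
#' @param state_mixture named proportions (`pericyte`, `intermediate`,
#'   `myofibroblast`), summing to 1.
#' @param dim image height and width in pixels.
#' @param vessel_width_px width of the vessel tube.
#' @param pixel_size_um physical pixel size (default 0.5 um).
#' @param state_bands_um per-state distance bands from the vessel surface.
#' @param intensity_params list with `ng2_mean`, `asma_mean` (per state) and
#'   `noise_sd`.
#' @param cell_radii_px ellipse semi-axes in pixels.
#' @param seed integer.
#' @param max_tries placement attempts per cell before giving up.
#' @return list with `image` (a [label_image()]) and `truth` (data frame of
#'   `cell_label`, `state`, center coordinates).
#' @export
generate_tissue_image <- function(n_cells = 30,
                                  state_mixture = c(pericyte = 0.4,
                                                    intermediate = 0.3,
                                                    myofibroblast = 0.3),
                                  dim = c(220, 220),
                                  vessel_width_px = 8,
                                  pixel_size_um = 0.5,
                                  state_bands_um = default_state_bands(),
                                  intensity_params = default_intensity_params(),
                                  cell_radii_px = c(4, 3),
                                  seed = 1L,
                                  max_tries = 200L) {
  if (abs(sum(state_mixture) - 1) > 1e-8)
    stop_config("state_mixture must sum to 1", "state_mixture")
  set.seed(derive_seed(seed, "tissue"))
  h <- dim[1]; w <- dim[2]

  vessel <- matrix(FALSE, h, w)
  vx <- round(w / 2)
  vessel[, (vx - floor(vessel_width_px / 2)):(vx + floor(vessel_width_px / 2))] <- TRUE
  dist_px <- as.matrix(EBImage::distmap(1 - vessel, metric = "euclidean"))

  states <- sample(names(state_mixture), n_cells, replace = TRUE,
                   prob = state_mixture)
  labels <- matrix(0L, h, w)
  rows <- row(labels); cols <- col(labels)
  rx <- cell_radii_px[1]; ry <- cell_radii_px[2]
  margin <- max(rx, ry) + 1
  truth <- data.frame(cell_label = integer(0), state = character(0),
                      row = integer(0), col = integer(0))

  for (k in seq_len(n_cells)) {
    band_px <- state_bands_um[[states[k]]] / pixel_size_um
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- which(dist_px >= band_px[1] & dist_px <= band_px[2] &
                    rows > margin & rows <= h - margin &
                    cols > margin & cols <= w - margin &
                    labels == 0L)
      if (!length(cand)) break
      ctr <- cand[sample.int(length(cand), 1)]
      cr <- rows[ctr]; cc <- cols[ctr]
      mask <- ((rows - cr) / rx)^2 + ((cols - cc) / ry)^2 <= 1
      if (any(labels[mask] != 0L)) next
      labels[mask] <- k
      truth <- rbind(truth, data.frame(cell_label = k, state = states[k],
                                       row = cr, col = cc))
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place cell %d after %d tries; use fewer cells or a larger image",
                   k, max_tries))
  }

  ip <- intensity_params
  ng2 <- matrix(rnorm(h * w, 0, ip$noise_sd), h, w)
  asma <- matrix(rnorm(h * w, 0, ip$noise_sd), h, w)
  fn <- matrix(rnorm(h * w, 0, ip$noise_sd), h, w)
  for (k in seq_len(n_cells)) {
    px <- labels == k
    ng2[px] <- ng2[px] + ip$ng2_mean[[states[k]]]
    asma[px] <- asma[px] + ip$asma_mean[[states[k]]]
    if (states[k] == "myofibroblast") {
      halo <- as.matrix(EBImage::dilate(
        px * 1, EBImage::makeBrush(2 * 4 + 1, shape = "disc"))) > 0
      fn[halo] <- fn[halo] + 1
    }
  }
  img <- label_image(labels, vessel,
                     channels = list(NG2 = ng2, aSMA = asma, FN = fn),
                     pixel_size_um = pixel_size_um)
  list(image = img, truth = truth)
}

# Otsu threshold of a channel (EBImage implementation on its value range).
channel_otsu <- function(ch) {
  rng <- range(ch)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(EBImage::Image(ch), range = rng, levels = 256L)
}

#' Classify cells into pericyte / intermediate / myofibroblast states
#'
#' Per cell, the mean intensity of each marker channel over the cell's
#' pixels is compared to its threshold (strict `>`); a cell is "vascular"
#' when its minimum pixel distance to the vessel mask is at most
#' `vascular_max_dist_um`.  States follow the marker rule: pericyte =
#' vascular NG2+/aSMA-; intermediate = NG2+/aSMA+ (any location);
#' myofibroblast = nonvascular NG2-/aSMA+; anything else is unclassified.
#' Per-image proportions are normalized to the number of classified cells.
#'
#' @param img a [label_image()] with `NG2` and `aSMA` channels.
#' @param thresholds named list/vector with `ng2` and `asma` intensity
#'   thresholds; if `NULL`, per-channel Otsu thresholds are used.
#' @param vascular_max_dist_um vessel-attachment distance cutoff (default
#'   2.5 um).
#' @return list with `calls` (per-cell data frame: markers, vascular flag,
#'   `vessel_distance_um` = median pixel distance, `state`) and
#'   `proportions` (over classified cells).
#' @export
classify_cell_states <- function(img, thresholds = NULL,
                                 vascular_max_dist_um = 2.5) {
  for (ch in c("NG2", "aSMA")) {
    if (is.null(img$channels[[ch]]))
      stop(sprintf("channel '%s' missing from the image", ch))
  }
  if (is.null(thresholds)) {
    thresholds <- list(ng2 = channel_otsu(img$channels$NG2),
                       asma = channel_otsu(img$channels$aSMA))
  }
  n_cells <- max(0L, max(img$cell_labels))
  if (n_cells == 0L) stop("image contains no cells")
  dmap <- vessel_distance_map(img)
  lab <- img$cell_labels
  idx <- lab > 0L
  f <- factor(lab[idx], levels = seq_len(n_cells))
  mean_ng2 <- as.numeric(tapply(img$channels$NG2[idx], f, mean))
  mean_asma <- as.numeric(tapply(img$channels$aSMA[idx], f, mean))
  min_dist <- as.numeric(tapply(dmap[idx], f, min))
  med_dist <- as.numeric(tapply(dmap[idx], f, median))

  ng2_pos <- mean_ng2 > thresholds$ng2
  asma_pos <- mean_asma > thresholds$asma
  vascular <- min_dist <= vascular_max_dist_um
  state <- rep("unclassified", n_cells)
  state[vascular & ng2_pos & !asma_pos] <- "pericyte"
  state[ng2_pos & asma_pos] <- "intermediate"
  state[!vascular & !ng2_pos & asma_pos] <- "myofibroblast"

  calls <- data.frame(
    cell_label = seq_len(n_cells),
    mean_ng2 = mean_ng2, mean_asma = mean_asma,
    ng2_positive = ng2_pos, asma_positive = asma_pos,
    vascular = vascular,
    vessel_distance_um = med_dist,
    state = state,
    stringsAsFactors = FALSE
  )
  classified <- state != "unclassified"
  props <- if (any(classified)) {
    tab <- table(factor(state[classified],
                        levels = c("pericyte", "intermediate", "myofibroblast")))
    as.numeric(tab) / sum(tab)
  } else c(NA_real_, NA_real_, NA_real_)
  names(props) <- c("pericyte", "intermediate", "myofibroblast")
  list(calls = calls, proportions = props)
}

#' Median vessel distance of one cell
#'
#' Euclidean distance transform of the non-vessel region (scaled to um),
#' summarized as the median over the cell's pixels (even pixel counts give
#' the mean of the central pair).
#'
#' @param img a [label_image()].
#' @param cell_label positive integer label.
#' @return distance in micrometres.
#' @export
vessel_distance <- function(img, cell_label) {
  px <- img$cell_labels == cell_label
  if (!any(px)) stop(sprintf("no cell with label %s", cell_label))
  dmap <- vessel_distance_map(img)
  median(dmap[px])
}

#' Fraction of source-positive area within a radius of target-positive area
#'
#' Thresholds both channels, dilates the target-positive mask with a disk of
#' pixel radius `round(radius_um / pixel_size_um)`, and returns the fraction
#' of source-positive pixels falling inside the dilated target.  With the
#' defaults this is the fibronectin-near-alpha-SMA fraction (radius 2.5 um).
#'
#' @param img a [label_image()].
#' @param source_channel,target_channel channel names (defaults `FN`,
#'   `aSMA`).
#' @param radius_um proximity radius in micrometres.
#' @param channel_thresholds named list with one strict threshold per
#'   channel used.
#' @return fraction in \[0, 1\].
#' @export
proximity_fraction <- function(img, source_channel = "FN",
                               target_channel = "aSMA", radius_um = 2.5,
                               channel_thresholds = list(FN = 0.5,
                                                         aSMA = 0.5)) {
  for (ch in c(source_channel, target_channel)) {
    if (is.null(img$channels[[ch]]))
      stop(sprintf("channel '%s' missing from the image", ch))
  }
  src <- img$channels[[source_channel]] > channel_thresholds[[source_channel]]
  tgt <- img$channels[[target_channel]] > channel_thresholds[[target_channel]]
  if (!any(src)) stop("no positive source pixels")
  r <- round(radius_um / img$pixel_size_um)
  tgt_dil <- if (r >= 1) {
    as.matrix(EBImage::dilate(tgt * 1,
                              EBImage::makeBrush(2 * r + 1, shape = "disc"))) > 0
  } else tgt
  sum(src & tgt_dil) / sum(src)
}

# One-sample two-sided t test with explicit degenerate handling: zero
# variance at the null value gives p = 1, zero variance elsewhere is flagged.
safe_one_sample_t <- function(x, mu) {
  if (length(x) < 2) stop("need at least 2 samples")
  if (sd(x) == 0) {
    if (mean(x) == mu)
      return(list(t = 0, df = length(x) - 1L, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(x) - mu) * Inf, df = length(x) - 1L, p = 0,
                degenerate = TRUE))
  }
  tt <- t.test(x, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Linear-trend test of vessel distance across ordered cell states
#'
#' For each sample (image, organoid or animal), applies the linear contrast
#' `(-1, 0, +1)` to its mean vessel distances for (pericyte, intermediate,
#' myofibroblast) and tests the per-sample contrast values against zero with
#' a two-sided one-sample t-test -- the post-hoc linear-trend test of a
#' repeated-measures design.  Samples missing a state are excluded with a
#' warning.
#'
#' @param distances data frame with columns `sample`, `state`, `distance`
#'   (one row per sample x state; states named `pericyte`, `intermediate`,
#'   `myofibroblast`).
#' @return list with `mean_contrast`, `t`, `df`, `p`, `contrasts`.
#' @export
state_trend_test <- function(distances) {
  states <- c("pericyte", "intermediate", "myofibroblast")
  cw <- c(pericyte = -1, intermediate = 0, myofibroblast = 1)
  L <- c()
  dropped <- character(0)
  for (s in unique(distances$sample)) {
    sub <- distances[distances$sample == s, ]
    if (!all(states %in% sub$state)) {
      dropped <- c(dropped, as.character(s))
      next
    }
    d <- setNames(sub$distance, sub$state)[states]
    L[as.character(s)] <- sum(cw * d)
  }
  if (length(dropped))
    warning(sprintf("sample(s) missing a state, excluded: %s",
                    paste(dropped, collapse = ", ")))
  if (length(L) < 3) stop("fewer than 3 complete samples")
  tt <- safe_one_sample_t(L, 0)
  list(mean_contrast = mean(L), t = tt$t, df = tt$df, p = tt$p,
       contrasts = L)
}

#' One-sample test of proximity fractions against a chance level
#'
#' Two-sided one-sample t-test of per-sample fractions against `chance`
#' (default 50%).  Zero-variance inputs are handled explicitly: exactly at
#' chance gives p = 1; away from chance the result is flagged degenerate
#' with p = 0.
#'
#' @param fractions per-sample fractions in \[0, 1\].
#' @param chance null value (default 0.5).
#' @return list with `t`, `df`, `p`, `mean`, `degenerate`.
#' @export
fraction_vs_chance_test <- function(fractions, chance = 0.5) {
  tt <- safe_one_sample_t(fractions, chance)
  list(t = tt$t, df = tt$df, p = tt$p, mean = mean(fractions),
       degenerate = tt$degenerate)
}
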