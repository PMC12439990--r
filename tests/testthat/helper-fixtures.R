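# Fixtures are built in code; nothing is read from disk.

# Matrix whose genes form abundance tiers that map 1:1 onto expression bins,
# with one program gene per tier shifted by `delta` in every cell.  Controls
# sampled from a tier are then expression-matched to the program gene of
# that tier, so the binned-control score should recover `delta` up to the
# small contamination of the pool by the program gene itself.
build_shift_matrix <- function(delta, n_bins = 10, bin_size = 40,
                               n_cells = 50) {
  n_g <- n_bins * bin_size
  mu <- rep(seq_len(n_bins), each = bin_size)
  m <- matrix(rep(mu, n_cells), n_g, n_cells,
              dimnames = list(sprintf("G%04d", seq_len(n_g)),
                              sprintf("C%03d", seq_len(n_cells))))
  prog <- sprintf("G%04d", (seq_len(n_bins) - 1L) * bin_size + 5L)
  m[prog, ] <- m[prog, ] + delta
  list(m = m, prog = prog)
}

# Tiny labelled image: vessel along column 1, cells given as a list of
# pixel-index matrices (row, col); channels default to zero.
build_tiny_image <- function(dim = c(12, 12), cells = list(),
                             channels = NULL, pixel_size_um = 1,
                             vessel_cols = 1) {
  lab <- matrix(0L, dim[1], dim[2])
  for (k in seq_along(cells)) {
    px <- cells[[k]]
    lab[cbind(px[, 1], px[, 2])] <- k
  }
  vm <- matrix(FALSE, dim[1], dim[2])
  vm[, vessel_cols] <- TRUE
  if (is.null(channels)) {
    z <- matrix(0, dim[1], dim[2])
    channels <- list(NG2 = z, aSMA = z, FN = z)
  }
  label_image(lab, vm, channels, pixel_size_um)
}

# Small cell table with lineage weights for trajectory tests.
build_traj_cells <- function(n = 150, seed = 1) {
  set.seed(seed)
  w <- rbeta(n, 2, 2)
  data.frame(
    cell_id = sprintf("C%04d", seq_len(n)),
    subject_id = rep(sprintf("S%02d", 1:10), length.out = n),
    pseudotime = runif(n),
    weight_lineage_myo = w,
    weight_lineage_peri = 1 - w
  )
}

noise_free_intensities <- function() {
  list(ng2_mean = c(pericyte = 1, intermediate = 1, myofibroblast = 0.1),
       asma_mean = c(pericyte = 0.1, intermediate = 1, myofibroblast = 1),
       noise_sd = 0)
}
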