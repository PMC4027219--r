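# Image-level path: render synthetic two-channel TIRF-like movies from
# simulated trajectories, then recover trajectories by spot detection,
# donor/acceptor channel pairing and fixed-aperture photometry. Emulates a
# split-sensor EM-CCD geometry (each channel on one half of a 512x512 chip).
#
# Coordinate convention (used everywhere): 0-based pixel centers, x = column,
# y = row; images stored as [row, col] matrices, stacks as [row, col, frame].

#' Optics model for movie rendering and detection
#'
#' @param psf_sigma Gaussian PSF standard deviation in pixels (> 0).
#' @param frame_shape `c(rows, cols)` per channel; default `c(512, 256)`,
#'   one half of a 512 x 512 split sensor.
#' @param background Mean background counts per pixel (>= 0).
#' @param channel_offset `c(dx, dy)` rigid shift (pixels) mapping donor
#'   coordinates to acceptor coordinates.
#' @return Object of class `optics_model`.
#' @export
optics_model <- function(psf_sigma = 1.2, frame_shape = c(512L, 256L),
                         background = 0, channel_offset = c(0, 0)) {
  stopifnot(psf_sigma > 0, length(frame_shape) == 2L, all(frame_shape > 0),
            background >= 0, length(channel_offset) == 2L)
  structure(list(psf_sigma = psf_sigma,
                 frame_shape = as.integer(frame_shape),
                 background = background,
                 channel_offset = as.numeric(channel_offset)),
            class = "optics_model")
}

# Gaussian PSF patch (sums to ~1) evaluated at pixel centers around (x0, y0)
.psf_patch <- function(x0, y0, sigma, radius) {
  cx <- round(x0); cy <- round(y0)
  xs <- (cx - radius):(cx + radius)
  ys <- (cy - radius):(cy + radius)
  gx <- exp(-((xs - x0)^2) / (2 * sigma^2))
  gy <- exp(-((ys - y0)^2) / (2 * sigma^2))
  patch <- outer(gy, gx)
  list(patch = patch / (2 * pi * sigma^2), rows = ys, cols = xs)
}

.draw_positions <- function(n, shape, min_sep, margin) {
  pos <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  max_tries <- 2000L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("cannot place ", n, " molecules at the required separation")
    x <- stats::runif(1L, margin, shape[2L] - 1 - margin)
    y <- stats::runif(1L, margin, shape[1L] - 1 - margin)
    if (placed == 0L ||
        min((pos[seq_len(placed), 1L] - x)^2 +
            (pos[seq_len(placed), 2L] - y)^2) >= min_sep^2) {
      placed <- placed + 1L
      pos[placed, ] <- c(x, y)
    }
  }
  colnames(pos) <- c("x", "y")
  pos
}

#' Render a two-channel movie from trajectories
#'
#' Each frame is `background` plus the sum of the molecules' Gaussian PSFs
#' scaled by that frame's `I_D` (donor channel) and `I_A` (acceptor channel,
#' shifted by `channel_offset`), with optional per-pixel Poisson noise.
#' Molecules are surface-tethered: positions are fixed over time.
#'
#' @param trajs List of `molecule_trajectory` objects (equal frame grids).
#' @param optics An [optics_model()].
#' @param positions Optional n x 2 matrix of donor-channel positions
#'   (`x = col`, `y = row`, 0-based); drawn uniformly with minimum pairwise
#'   separation `4 * psf_sigma` when `NULL`.
#' @param noise Apply Poisson noise (default TRUE).
#' @return List with `donor` and `acceptor` stacks (`[row, col, frame]`
#'   arrays), `positions`, and `optics`.
#' @export
render_movie <- function(trajs, optics, positions = NULL, noise = TRUE) {
  stopifnot(inherits(optics, "optics_model"), length(trajs) >= 0L)
  n_mol <- length(trajs)
  n_frames <- if (n_mol) length(trajs[[1L]]$times) else 0L
  shape <- optics$frame_shape
  radius <- ceiling(4 * optics$psf_sigma)
  if (is.null(positions)) {
    positions <- if (n_mol)
      .draw_positions(n_mol, shape, 4 * optics$psf_sigma, radius + 1)
    else matrix(numeric(0), 0L, 2L)
  }
  stopifnot(nrow(positions) == n_mol)

  donor <- array(optics$background, c(shape[1L], shape[2L], max(n_frames, 1L)))
  acceptor <- donor
  if (n_mol) {
    off <- optics$channel_offset
    patches_d <- lapply(seq_len(n_mol), function(m)
      .psf_patch(positions[m, 1L], positions[m, 2L], optics$psf_sigma, radius))
    patches_a <- lapply(seq_len(n_mol), function(m)
      .psf_patch(positions[m, 1L] + off[1L], positions[m, 2L] + off[2L],
                 optics$psf_sigma, radius))
    for (m in seq_len(n_mol)) {
      pd <- patches_d[[m]]; pa <- patches_a[[m]]
      rd <- pd$rows + 1L; cd <- pd$cols + 1L   # to 1-based indices
      ra <- pa$rows + 1L; ca <- pa$cols + 1L
      if (any(rd < 1L) || any(rd > shape[1L]) || any(cd < 1L) ||
          any(cd > shape[2L]) || any(ra < 1L) || any(ra > shape[1L]) ||
          any(ca < 1L) || any(ca > shape[2L]))
        stop("molecule PSF extends beyond the frame")
      I_D <- trajs[[m]]$I_D; I_A <- trajs[[m]]$I_A
      for (f in seq_len(n_frames)) {
        if (I_D[f] > 0)
          donor[rd, cd, f] <- donor[rd, cd, f] + I_D[f] * pd$patch
        if (I_A[f] > 0)
          acceptor[ra, ca, f] <- acceptor[ra, ca, f] + I_A[f] * pa$patch
      }
    }
  }
  if (noise) {
    donor[] <- stats::rpois(length(donor), donor)
    acceptor[] <- stats::rpois(length(acceptor), acceptor)
  }
  list(donor = donor, acceptor = acceptor, positions = positions,
       optics = optics)
}

#' Detect spots in a single frame
#'
#' Matched-filters the background-subtracted frame with a Gaussian of the
#' configured PSF width, then takes local maxima exceeding
#' `threshold_sigmas` times a robust (MAD) noise estimate of the filtered
#' image. Sub-pixel positions by intensity centroid within a
#' `(2*ceiling(2*sigma)+1)^2` window.
#'
#' @param frame Single-channel image matrix `[row, col]`.
#' @param optics An [optics_model()] (PSF width for the matched filter).
#' @param threshold_sigmas Detection threshold (default 5).
#' @return data.frame with `x`, `y` (0-based, sub-pixel) and `intensity`
#'   (background-subtracted sum over the centroid window).
#' @export
detect_spots <- function(frame, optics, threshold_sigmas = 5) {
  stopifnot(is.matrix(frame), inherits(optics, "optics_model"))
  if (any(!is.finite(frame))) stop("non-finite pixels in frame")
  bg <- stats::median(frame)
  img <- frame - bg
  sigma <- optics$psf_sigma
  kr <- ceiling(3 * sigma)
  kern <- stats::dnorm(-kr:kr, sd = sigma)
  kern <- kern / sum(kern)
  # separable Gaussian convolution with replicate padding
  conv1 <- function(m, k) {
    r <- (length(k) - 1L) / 2L
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(nrow(m), r), , drop = FALSE])
    out <- apply(padded, 2L, function(col)
      stats::filter(col, k, sides = 2L))
    out[(r + 1L):(r + nrow(m)), , drop = FALSE]
  }
  sm <- t(conv1(t(conv1(img, kern)), kern))

  noise <- stats::mad(sm)
  thr <- threshold_sigmas * noise
  nr <- nrow(sm); nc <- ncol(sm)
  # local maxima over the 8-neighborhood (borders excluded)
  inner <- sm[2:(nr - 1L), 2:(nc - 1L)]
  is_max <- inner > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max &
      inner >= sm[2:(nr - 1L) + dr, 2:(nc - 1L) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  wr <- ceiling(2 * sigma)   # centroid window half-size
  out <- lapply(seq_len(nrow(idx)), function(i) {
    r0 <- idx[i, 1L] + 1L; c0 <- idx[i, 2L] + 1L
    rs <- max(1L, r0 - wr):min(nr, r0 + wr)
    cs <- max(1L, c0 - wr):min(nc, c0 + wr)
    win <- img[rs, cs, drop = FALSE]
    win_pos <- pmax(win, 0)
    tot <- sum(win_pos)
    if (tot <= 0) return(NULL)
    y <- sum(rowSums(win_pos) * (rs - 1L)) / tot
    x <- sum(colSums(win_pos) * (cs - 1L)) / tot
    data.frame(x = x, y = y, intensity = sum(win))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}

#' Pair donor and acceptor spot lists
#'
#' Greedy nearest-neighbor matching of acceptor spots to donor spots after
#' applying the channel offset: repeatedly links the globally closest pair
#' with residual distance below `tol_px`. Symmetric in the order of the two
#' lists.
#'
#' @param donor_spots,acceptor_spots Spot tables from [detect_spots()].
#' @param optics An [optics_model()] providing `channel_offset`.
#' @param tol_px Matching tolerance in pixels (> 0, default 2).
#' @return List with `pairs` (data.frame `molecule_id, x_d, y_d, x_a, y_a,
#'   residual_px`), `unmatched_donor`, `unmatched_acceptor`.
#' @export
pair_channels <- function(donor_spots, acceptor_spots, optics, tol_px = 2) {
  stopifnot(inherits(optics, "optics_model"))
  if (tol_px <= 0) stop("tol_px must be positive")
  nd <- nrow(donor_spots); na <- nrow(acceptor_spots)
  empty_pairs <- data.frame(molecule_id = character(0), x_d = numeric(0),
                            y_d = numeric(0), x_a = numeric(0),
                            y_a = numeric(0), residual_px = numeric(0))
  if (nd == 0L || na == 0L)
    return(list(pairs = empty_pairs, unmatched_donor = donor_spots,
                unmatched_acceptor = acceptor_spots))
  off <- optics$channel_offset
  ex <- donor_spots$x + off[1L]   # donor positions mapped into acceptor frame
  ey <- donor_spots$y + off[2L]
  dmat <- sqrt(outer(ex, acceptor_spots$x, "-")^2 +
                 outer(ey, acceptor_spots$y, "-")^2)
  pairs <- list()
  repeat {
    m <- which.min(dmat)
    if (!length(m) || !is.finite(dmat[m]) || dmat[m] > tol_px) break
    i <- (m - 1L) %% nd + 1L
    j <- (m - 1L) %/% nd + 1L
    pairs[[length(pairs) + 1L]] <- data.frame(
      x_d = donor_spots$x[i], y_d = donor_spots$y[i],
      x_a = acceptor_spots$x[j], y_a = acceptor_spots$y[j],
      residual_px = dmat[m])
    dmat[i, ] <- Inf
    dmat[, j] <- Inf
  }
  if (length(pairs)) {
    pairs <- do.call(rbind, pairs)
    pairs <- pairs[order(pairs$y_d, pairs$x_d), , drop = FALSE]
    pairs <- cbind(molecule_id = sprintf("pair%04d", seq_len(nrow(pairs))),
                   pairs)
    rownames(pairs) <- NULL
  } else pairs <- empty_pairs
  matched_d <- donor_spots$x %in% pairs$x_d & donor_spots$y %in% pairs$y_d
  matched_a <- acceptor_spots$x %in% pairs$x_a & acceptor_spots$y %in% pairs$y_a
  list(pairs = pairs,
       unmatched_donor = donor_spots[!matched_d, , drop = FALSE],
       unmatched_acceptor = acceptor_spots[!matched_a, , drop = FALSE])
}

#' Extract trajectories by aperture photometry
#'
#' For each paired molecule and frame, sums background-subtracted counts over
#' a fixed circular aperture at the molecule's (time-invariant) position in
#' each channel. Background is estimated per frame and channel as the median
#' of pixels outside all apertures.
#'
#' @param movie Output of [render_movie()] (or a list with `donor`,
#'   `acceptor` stacks and `optics`).
#' @param pairs Pair table from [pair_channels()].
#' @param aperture_radius_px Aperture radius in pixels (>= 1, default 4).
#' @param dt Frame interval in seconds (default 0.1).
#' @return Named list of `molecule_trajectory` objects (empty `truth`).
#' @export
extract_trajectories <- function(movie, pairs, aperture_radius_px = 4,
                                 dt = 0.1) {
  stopifnot(aperture_radius_px >= 1)
  dstack <- movie$donor; astack <- movie$acceptor
  nr <- dim(dstack)[1L]; nc <- dim(dstack)[2L]; nf <- dim(dstack)[3L]
  times <- (seq_len(nf) - 1L) * dt

  aperture_idx <- function(x0, y0) {
    r <- aperture_radius_px
    cs <- (floor(x0 - r):ceiling(x0 + r)) + 1L
    rs <- (floor(y0 - r):ceiling(y0 + r)) + 1L
    if (any(rs < 1L) || any(rs > nr) || any(cs < 1L) || any(cs > nc))
      stop("aperture extends beyond frame")
    grid <- expand.grid(row = rs, col = cs)
    keep <- (grid$col - 1L - x0)^2 + (grid$row - 1L - y0)^2 <= r^2
    grid <- grid[keep, , drop = FALSE]
    (grid$col - 1L) * nr + grid$row   # linear indices within one frame
  }

  n_pairs <- nrow(pairs)
  ap_d <- lapply(seq_len(n_pairs), function(i)
    aperture_idx(pairs$x_d[i], pairs$y_d[i]))
  ap_a <- lapply(seq_len(n_pairs), function(i)
    aperture_idx(pairs$x_a[i], pairs$y_a[i]))
  out_idx_d <- setdiff(seq_len(nr * nc), unique(unlist(ap_d)))
  out_idx_a <- setdiff(seq_len(nr * nc), unique(unlist(ap_a)))

  I_D <- matrix(0, n_pairs, nf)
  I_A <- matrix(0, n_pairs, nf)
  npx_d <- lengths(ap_d); npx_a <- lengths(ap_a)
  for (f in seq_len(nf)) {
    dfr <- dstack[, , f]; afr <- astack[, , f]
    bg_d <- stats::median(dfr[out_idx_d])
    bg_a <- stats::median(afr[out_idx_a])
    for (i in seq_len(n_pairs)) {
      I_D[i, f] <- sum(dfr[ap_d[[i]]]) - bg_d * npx_d[i]
      I_A[i, f] <- sum(afr[ap_a[[i]]]) - bg_a * npx_a[i]
    }
  }
  trajs <- lapply(seq_len(n_pairs), function(i) structure(
    list(times = times, I_D = I_D[i, ], I_A = I_A[i, ], truth = .empty_truth()),
    class = "molecule_trajectory"))
  stats::setNames(trajs, pairs$molecule_id)
}

#' Write a two-channel movie to multi-page TIFF
#'
#' One 16-bit unsigned file per channel, named `<run>_donor.tif` and
#' `<run>_acceptor.tif`.
#'
#' @param movie Output of [render_movie()].
#' @param run Path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_movie_tiff <- function(movie, run) {
  scale <- 65535
  to_pages <- function(stack) {
    mx <- max(stack, 1)
    lapply(seq_len(dim(stack)[3L]), function(f)
      pmin(pmax(stack[, , f] / mx, 0), 1))
  }
  paths <- c(donor = paste0(run, "_donor.tif"),
             acceptor = paste0(run, "_acceptor.tif"))
  tiff::writeTIFF(to_pages(movie$donor), paths[["donor"]],
                  bits.per.sample = 16L)
  tiff::writeTIFF(to_pages(movie$acceptor), paths[["acceptor"]],
                  bits.per.sample = 16L)
  invisible(paths)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file path.
#' @return `[row, col, frame]` array (values as stored, 0-1 normalized for
#'   16-bit files written by [write_movie_tiff()]).
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
}
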