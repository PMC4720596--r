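# Synthetic phantoms: analytic ellipse objects rendered with a soft
# (partial-volume) edge, so ground truth is exact and frames at slightly
# different geometry are genuinely distinct.

#' Specification of a synthetic phantom acquisition
#'
#' Collects the parameters the phantom generators share. Each generator fills
#' in application-specific defaults for anything left `NULL` (documented
#' there), so `phantom_spec()` with no arguments gives the default phantom of
#' every generator at full scale.
#'
#' @param grid `(Nx, Ny)` image/k-space matrix size.
#' @param n_frames Number of frames; default depends on the generator
#'   (50 for Look-Locker, 20 for cine, `length(bvals)` for DWI).
#' @param noise_sigma Standard deviation, per real/imaginary channel, of the
#'   complex Gaussian noise added in image space. The default 0.01 is 1% of
#'   the reference tissue amplitude (SNR about 100, a realistic preclinical
#'   operating point).
#' @param times Inversion times in seconds (Look-Locker generator).
#' @param bvals b-values in s/mm^2, one per frame (DWI generator).
#' @param directions Unit gradient directions, one row per frame (DWI).
#' @param edge Soft-edge width of the rendered ellipses, in pixels.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(128L, 128L), n_frames = NULL,
                         noise_sigma = 0.01, times = NULL, bvals = NULL,
                         directions = NULL, edge = 1) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 2L, all(grid >= 8L))
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop("`noise_sigma` must be nonnegative", call. = FALSE)
  structure(
    list(grid = grid, n_frames = n_frames, noise_sigma = noise_sigma,
         times = times, bvals = bvals, directions = directions, edge = edge),
    class = "phantom_spec"
  )
}

# fractional coverage of a (rotated) ellipse, soft edge of width `edge` px
ellipse_coverage <- function(Nx, Ny, cx, cy, rx, ry, angle = 0, edge = 1) {
  x <- matrix(seq_len(Nx), Nx, Ny) - cx
  y <- matrix(seq_len(Ny), Nx, Ny, byrow = TRUE) - cy
  if (angle != 0) {
    xr <- cos(angle) * x + sin(angle) * y
    yr <- -sin(angle) * x + cos(angle) * y
    x <- xr; y <- yr
  }
  rho <- sqrt((x / rx)^2 + (y / ry)^2)
  dist <- (rho - 1) * min(rx, ry)          # approx signed distance to boundary
  pmin(pmax(0.5 - dist / max(edge, 1e-6), 0), 1)
}

# overlay `value` onto `base` with weight = coverage
blend <- function(base, coverage, value) base * (1 - coverage) + value * coverage

add_complex_noise <- function(images, sigma) {
  if (sigma == 0) return(images * (1 + 0i))
  d <- dim(images)
  images + complex(real = stats::rnorm(prod(d), sd = sigma),
                   imaginary = stats::rnorm(prod(d), sd = sigma))
}

#' Synthetic Look-Locker T1 inversion-recovery series
#'
#' Ellipse phantom of a short-axis cardiac slice: a torso ellipse, a
#' myocardial annulus and a blood pool, each with its own apparent relaxation
#' time `T1*` and equilibrium amplitude `A`. The per-pixel signal follows the
#' three-parameter inversion-recovery model `s(t) = A - B exp(-t / T1*)` with
#' `B = 2A` (perfect inversion), so the Look-Locker-corrected
#' `T1 = T1* (B/A - 1)` equals `T1*`. Complex Gaussian noise is added in
#' image space and each frame is Fourier transformed to k-space.
#'
#' Defaults emulate a preclinical cardiac protocol: 128 x 128 matrix, 50
#' inversion times 10 ms + 120 ms spacing (spanning about 5 T1), myocardial
#' `T1* = 1.2` s.
#'
#' @param spec A [phantom_spec()].
#' @return List with `images` (complex `(Nx,Ny,Nt)` array before the Fourier
#'   transform), `kspace` (a [kspace_series()] with inversion times as frame
#'   labels) and `truth` (list: `a_map`, `t1_star_map`, `t1_map`, `myo_mask`,
#'   `object_mask`, `times`).
#' @export
make_look_locker_series <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  Nx <- spec$grid[1]; Ny <- spec$grid[2]
  nt <- if (is.null(spec$n_frames)) 50L else as.integer(spec$n_frames)
  times <- if (is.null(spec$times)) 0.01 + (seq_len(nt) - 1) * 0.12 else spec$times
  nt <- length(times)
  if (nt < 8L) stop("need at least 8 inversion times", call. = FALSE)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing",
                                  call. = FALSE)

  cx <- (Nx + 1) / 2; cy <- (Ny + 1) / 2
  tissues <- data.frame(
    rx = c(0.38 * Nx, 0.17 * Nx, 0.094 * Nx),
    ry = c(0.31 * Ny, 0.17 * Ny, 0.094 * Ny),
    A = c(0.6, 1.0, 1.2),
    t1_star = c(0.8, 1.2, 1.6)     # torso, myocardium, blood pool [s]
  )
  if (any(tissues$t1_star <= 0)) stop("T1 must be positive", call. = FALSE)

  a_map <- matrix(0, Nx, Ny)
  t1_map <- matrix(1, Nx, Ny)      # placeholder T1 where A = 0
  cov <- vector("list", nrow(tissues))
  for (i in seq_len(nrow(tissues))) {
    cov[[i]] <- ellipse_coverage(Nx, Ny, cx, cy, tissues$rx[i], tissues$ry[i],
                                 edge = spec$edge)
    a_map <- blend(a_map, cov[[i]], tissues$A[i])
    t1_map <- blend(t1_map, cov[[i]], tissues$t1_star[i])
  }
  myo_mask <- cov[[2]] >= 0.999 & cov[[3]] <= 0.001
  object_mask <- cov[[1]] > 0.5

  images <- array(0, c(Nx, Ny, nt))
  for (j in seq_len(nt))
    images[, , j] <- a_map * (1 - 2 * exp(-times[j] / t1_map))
  images <- add_complex_noise(images, spec$noise_sigma)
  ks <- forward_fft(images, frame_labels = times)
  list(images = images, kspace = ks,
       truth = list(a_map = a_map, t1_star_map = t1_map,
                    t1_map = t1_map,          # B/A = 2 makes T1 = T1*
                    myo_mask = myo_mask, object_mask = object_mask,
                    times = times))
}

#' Synthetic cardiac cine series
#'
#' A beating-heart surrogate: static torso and myocardial outer wall, with a
#' bright blood pool whose radius varies sinusoidally over the cardiac cycle.
#' Frame-to-frame total intensity varies by well under 10% (the blood pool is
#' a small fraction of the object), while the geometry change makes every
#' frame linearly independent, so the noiseless Casorati matrix has full rank
#' `Nt`.
#'
#' Defaults: 128 x 128 matrix, 20 cine frames.
#'
#' @param spec A [phantom_spec()].
#' @param radius_amplitude Fractional amplitude of the blood-pool radius
#'   variation (default 0.25; 0 gives identical frames, Casorati rank 1).
#' @return List with `images`, `kspace` and `truth` (list: `blood_radius`
#'   per frame, `object_mask`).
#' @export
make_cine_series <- function(spec = phantom_spec(), radius_amplitude = 0.25) {
  stopifnot(inherits(spec, "phantom_spec"))
  Nx <- spec$grid[1]; Ny <- spec$grid[2]
  nt <- if (is.null(spec$n_frames)) 20L else as.integer(spec$n_frames)
  if (nt < 2L) stop("need at least 2 cine frames", call. = FALSE)
  cx <- (Nx + 1) / 2; cy <- (Ny + 1) / 2

  r0 <- 0.094 * Nx
  phase <- 2 * pi * (seq_len(nt) - 1) / nt + 0.5  # offset avoids duplicate radii
  radii <- r0 * (1 + radius_amplitude * sin(phase))

  torso <- ellipse_coverage(Nx, Ny, cx, cy, 0.38 * Nx, 0.31 * Ny,
                            edge = spec$edge)
  wall <- ellipse_coverage(Nx, Ny, cx, cy, 0.17 * Nx, 0.17 * Ny,
                           edge = spec$edge)
  base <- blend(blend(matrix(0, Nx, Ny), torso, 0.5), wall, 0.8)

  images <- array(0, c(Nx, Ny, nt))
  for (j in seq_len(nt)) {
    blood <- ellipse_coverage(Nx, Ny, cx, cy, radii[j], radii[j],
                              edge = spec$edge)
    images[, , j] <- blend(base, blood, 1.2)
  }
  images <- add_complex_noise(images, spec$noise_sigma)
  ks <- forward_fft(images, frame_labels = seq_len(nt))
  list(images = images, kspace = ks,
       truth = list(blood_radius = radii, object_mask = torso > 0.5))
}

#' Evenly spread unit gradient directions (deterministic Fibonacci sphere)
#'
#' @param n Number of directions (>= 1).
#' @return `n x 3` matrix of unit row vectors.
#' @export
fibonacci_directions <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Synthetic diffusion-weighted image set
#'
#' Ellipse phantom with piecewise diffusion tensors: an isotropic tissue
#' background, a strongly anisotropic tract-like region (principal axis in
#' plane) and a fast-isotropic fluid region. The per-pixel signal follows the
#' tensor model `s(b, g) = s0 exp(-b g' D g)`; tensor component maps are
#' blended with the same soft edges as the intensity, and the ground-truth FA
#' and MD maps are computed from them.
#'
#' Defaults emulate a scaled-down brain protocol: 64 x 64 matrix, 2 low-b
#' reference frames (b = 100 s/mm^2) and 12 diffusion-weighted frames
#' (b = 1000 s/mm^2) with directions spread over the sphere.
#'
#' @param spec A [phantom_spec()]; `bvals` and `directions` override the
#'   default protocol (at least 6 non-collinear directions are required).
#' @return List with `images`, `kspace` (frame labels: data.frame of `bval`
#'   and direction components) and `truth` (list: `tensor_maps`
#'   `(Nx,Ny,6)` in order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz; `fa`, `md`, `s0_map`,
#'   `object_mask`, `bvals`, `directions`).
#' @export
make_dwi_set <- function(spec = phantom_spec(grid = c(64L, 64L))) {
  stopifnot(inherits(spec, "phantom_spec"))
  Nx <- spec$grid[1]; Ny <- spec$grid[2]
  if (is.null(spec$bvals)) {
    bvals <- c(rep(100, 2), rep(1000, 12))
    directions <- rbind(fibonacci_directions(2), fibonacci_directions(12))
  } else {
    bvals <- spec$bvals
    directions <- spec$directions
    if (is.null(directions) || nrow(directions) != length(bvals))
      stop("`directions` must have one row per b-value", call. = FALSE)
  }
  ndir <- sum(bvals >= max(bvals) * 0.5)
  if (ndir < 6L)
    stop("need at least 6 non-collinear diffusion directions", call. = FALSE)

  cx <- (Nx + 1) / 2; cy <- (Ny + 1) / 2
  # tensors in mm^2/s: rows Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
  iso <- c(0.7, 0.7, 0.7, 0, 0, 0) * 1e-3          # tissue
  tract <- c(1.7, 0.3, 0.3, 0, 0, 0) * 1e-3        # principal axis x
  fluid <- c(2.5, 2.5, 2.5, 0, 0, 0) * 1e-3

  tmaps <- array(0, c(Nx, Ny, 6))
  s0 <- matrix(0, Nx, Ny)
  body <- ellipse_coverage(Nx, Ny, cx, cy, 0.40 * Nx, 0.34 * Ny,
                           edge = spec$edge)
  tract_cov <- ellipse_coverage(Nx, Ny, cx - 0.12 * Nx, cy, 0.10 * Nx,
                                0.20 * Ny, edge = spec$edge)
  fluid_cov <- ellipse_coverage(Nx, Ny, cx + 0.15 * Nx, cy, 0.09 * Nx,
                                0.09 * Ny, edge = spec$edge)
  for (k in 1:6) {
    m <- blend(matrix(0, Nx, Ny), body, iso[k])
    m <- blend(m, tract_cov, tract[k])
    m <- blend(m, fluid_cov, fluid[k])
    tmaps[, , k] <- m
  }
  s0 <- blend(s0, body, 1.0)

  nt <- length(bvals)
  images <- array(0, c(Nx, Ny, nt))
  for (j in seq_len(nt)) {
    g <- directions[j, ]
    expo <- tmaps[, , 1] * g[1]^2 + tmaps[, , 2] * g[2]^2 +
      tmaps[, , 3] * g[3]^2 + 2 * (tmaps[, , 4] * g[1] * g[2] +
                                   tmaps[, , 5] * g[1] * g[3] +
                                   tmaps[, , 6] * g[2] * g[3])
    images[, , j] <- s0 * exp(-bvals[j] * expo)
  }
  images <- add_complex_noise(images, spec$noise_sigma)
  labels <- data.frame(bval = bvals, gx = directions[, 1],
                       gy = directions[, 2], gz = directions[, 3])
  ks <- forward_fft(images, frame_labels = labels)

  mask <- body > 0.5
  fa <- matrix(NA_real_, Nx, Ny); md <- matrix(NA_real_, Nx, Ny)
  for (i in which(mask)) {
    v <- tmaps[i + (0:5) * (Nx * Ny)]
    D <- matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3, 3)
    ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    md[i] <- mean(ev)
    fa[i] <- fa_from_eigenvalues(ev)
  }
  list(images = images, kspace = ks,
       truth = list(tensor_maps = tmaps, fa = fa, md = md, s0_map = s0,
                    object_mask = mask, bvals = bvals,
                    directions = directions))
}

#' Stochastic model of RF spike corruption
#'
#' RF spikes are brief noise bursts corrupting a handful of k-space samples
#' with high-magnitude outliers that rise and decay along the readout
#' (frequency-encode) direction. The model draws a random number of spikes,
#' places them uniformly over k-space (by default excluding the central
#' window, where refilling cannot distinguish spikes from the genuine peak),
#' gives each a complex amplitude with random phase and magnitude
#' log-uniform in `amplitude_range` times the 99th-percentile k-space
#' magnitude, and spreads it along the readout axis with an exponential
#' decay kernel `w(d) = exp(-|d| / (kernel_half_width/2))`, truncated at
#' `±kernel_half_width` and clipped at grid edges.
#'
#' The default central exclusion applies to the whole spike footprint: the
#' excluded region is the central window dilated by the kernel reach along
#' the readout axis plus one pixel of 8-connectivity margin, so no injected
#' sample lies in — or adjacent to — the window that the refill step
#' returns to the low-rank component.
#'
#' @param n_spikes Integer count, or length-2 range from which the count is
#'   drawn uniformly (default 5 to 20 per dataset).
#' @param amplitude_range Length-2 positive range, in multiples of the
#'   99th-percentile k-space magnitude (default `c(5, 50)`).
#' @param kernel_half_width Samples of rise/decay on each side of the spike
#'   centre (default 2; 0 gives single-sample spikes).
#' @param exclude_center Keep spike centres out of the central window
#'   (default `TRUE`; set `FALSE` to study the hard central-spike case).
#' @param exclusion_window Side of the excluded central box (default 16).
#' @param seed Optional integer seed; [add_spikes()] then restores the
#'   caller's RNG state afterwards.
#' @return An object of class `spike_model`.
#' @export
spike_model <- function(n_spikes = c(5L, 20L), amplitude_range = c(5, 50),
                        kernel_half_width = 2L, exclude_center = TRUE,
                        exclusion_window = 16L, seed = NULL) {
  n_spikes <- as.integer(n_spikes)
  if (any(is.na(n_spikes)) || any(n_spikes < 0L) ||
      !length(n_spikes) %in% 1:2)
    stop("`n_spikes` must be a nonnegative count or range", call. = FALSE)
  if (length(n_spikes) == 2L && n_spikes[2] < n_spikes[1])
    stop("`n_spikes` range must be increasing", call. = FALSE)
  stopifnot(length(amplitude_range) == 2L, all(amplitude_range > 0),
            amplitude_range[2] >= amplitude_range[1])
  kernel_half_width <- as.integer(kernel_half_width)
  stopifnot(kernel_half_width >= 0L)
  structure(
    list(n_spikes = n_spikes, amplitude_range = amplitude_range,
         kernel_half_width = kernel_half_width,
         exclude_center = isTRUE(exclude_center),
         exclusion_window = as.integer(exclusion_window), seed = seed),
    class = "spike_model"
  )
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Inject simulated RF spikes into a k-space series
#'
#' Draws spikes from a [spike_model()] and adds them to the series. Every
#' modified sample and the exact complex value added to it are recorded in
#' the returned ledger, which downstream tests use as the ground-truth spike
#' support.
#'
#' @param series A [kspace_series()].
#' @param model A [spike_model()].
#' @return List with `corrupted` (a [kspace_series()]) and `ledger`, a
#'   data.frame with one row per modified sample: `spike` (spike id), `frame`,
#'   `kx`, `ky` (spike centre), `sample_kx`, `sample_ky` (modified sample),
#'   `offset` (readout offset from the centre), `value` (complex amount
#'   added).
#' @export
add_spikes <- function(series, model) {
  stopifnot(inherits(series, "kspace_series"), inherits(model, "spike_model"))
  with_seed(model$seed, {
    d <- dim(series$data)
    n <- if (length(model$n_spikes) == 2L)
      sample(model$n_spikes[1]:model$n_spikes[2], 1L) else model$n_spikes
    empty_ledger <- data.frame(spike = integer(0), frame = integer(0),
                               kx = integer(0), ky = integer(0),
                               sample_kx = integer(0), sample_ky = integer(0),
                               offset = integer(0), value = complex(0))
    if (n == 0L) {
      list(corrupted = series, ledger = empty_ledger)
    } else {
    excl <- if (model$exclude_center) {
      win <- central_window_mask(d[1:2], series$center_index,
                                 min(model$exclusion_window, min(d[1:2])))
      # exclude spike *footprints*, not just centres: dilate the window by the
      # kernel reach along the readout axis plus one pixel of 8-connectivity
      # margin, so no injected sample can lie in or adjacent to the window
      reach_x <- 1L + if (series$readout_axis == 1L) model$kernel_half_width else 0L
      reach_y <- 1L + if (series$readout_axis == 2L) model$kernel_half_width else 0L
      dil <- win
      for (dx in -reach_x:reach_x) for (dy in -reach_y:reach_y) {
        sx <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
        sy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
        dil <- dil | win[sx, sy]
      }
      dil
    } else matrix(FALSE, d[1], d[2])
    allowed <- which(!excl)
    if (length(allowed) == 0L)
      stop("exclusion window covers the whole grid", call. = FALSE)

    p99 <- stats::quantile(Mod(series$data), 0.99, names = FALSE)
    khw <- model$kernel_half_width
    tau_d <- max(khw, 1) / 2
    offs <- if (khw > 0L) seq(-khw, khw) else 0L
    w <- exp(-abs(offs) / tau_d)
    w[offs == 0L] <- 1

    rows <- vector("list", n)
    data <- series$data
    for (s in seq_len(n)) {
      frame <- sample.int(d[3], 1L)
      lin <- allowed[sample.int(length(allowed), 1L)]
      kx <- ((lin - 1L) %% d[1]) + 1L
      ky <- ((lin - 1L) %/% d[1]) + 1L
      amp <- p99 * exp(stats::runif(1, log(model$amplitude_range[1]),
                                    log(model$amplitude_range[2])))
      a <- amp * exp(1i * stats::runif(1, 0, 2 * pi))
      if (series$readout_axis == 1L) {
        sx <- kx + offs; sy <- rep(ky, length(offs))
      } else {
        sx <- rep(kx, length(offs)); sy <- ky + offs
      }
      ok <- sx >= 1L & sx <= d[1] & sy >= 1L & sy <= d[2]
      val <- a * w
      for (m in which(ok))
        data[sx[m], sy[m], frame] <- data[sx[m], sy[m], frame] + val[m]
      rows[[s]] <- data.frame(spike = s, frame = frame, kx = kx, ky = ky,
                              sample_kx = sx[ok], sample_ky = sy[ok],
                              offset = offs[ok], value = val[ok])
    }
    corrupted <- kspace_series(data, readout_axis = series$readout_axis,
                               center_index = series$center_index,
                               frame_labels = series$frame_labels)
    list(corrupted = corrupted, ledger = do.call(rbind, rows))
    }
  })
}
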