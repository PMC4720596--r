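#' Boolean mask of the central k-space window
#'
#' Marks the `window x window` box of samples around `center_index`, clipped
#' at the grid edges. For an even window `w` centred at index `c` the box
#' spans `[c - w/2, c + w/2 - 1]` on each axis (so a 16-point window on a
#' 128-grid centred at 65 covers rows 57..72); for odd `w` it is symmetric,
#' `[c - (w-1)/2, c + (w-1)/2]`.
#'
#' @param shape Length-2 integer vector `(Nx, Ny)`.
#' @param center_index 1-based centre location, inside the grid.
#' @param window Window side length in samples (>= 1).
#' @return Logical `(Nx, Ny)` matrix with at most `window^2` `TRUE` entries
#'   (fewer when the box is clipped at an edge).
#' @export
central_window_mask <- function(shape, center_index, window) {
  shape <- as.integer(shape); center_index <- as.integer(center_index)
  window <- as.integer(window)
  if (length(shape) != 2L || any(shape < 1L))
    stop("`shape` must be two positive integers", call. = FALSE)
  if (is.na(window) || window < 1L)
    stop("`window` must be a positive integer", call. = FALSE)
  if (length(center_index) != 2L || any(center_index < 1L) ||
      any(center_index > shape))
    stop("`center_index` must lie inside the grid", call. = FALSE)
  half <- if (window %% 2L == 0L) window %/% 2L else (window - 1L) %/% 2L
  lo <- center_index - half
  hi <- lo + window - 1L
  m <- matrix(FALSE, shape[1], shape[2])
  rows <- max(1L, lo[1]):min(shape[1], hi[1])
  cols <- max(1L, lo[2]):min(shape[2], hi[2])
  m[rows, cols] <- TRUE
  m
}

#' Label connected components of a binary mask
#'
#' Two-dimensional connected-component labelling with 4- or 8-connectivity
#' (the latter matches the default of MATLAB's `bwlabel`). Components are not
#' wrapped across grid edges: k-space spikes are not periodic objects.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal neighbours).
#' @return Integer matrix of the same shape: 0 for background, and 1..K
#'   labelling the K components.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)

  # neighbour offsets as (drow, dcol) pairs
  dr <- c(-1L, 1L, 0L, 0L)
  dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8L) {
    dr <- c(dr, -1L, -1L, 1L, 1L)
    dc <- c(dc, -1L, 1L, -1L, 1L)
  }

  current <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    current <- current + 1L
    frontier <- start
    labels[start] <- current
    while (length(frontier) > 0L) {
      r0 <- ((frontier - 1L) %% nr) + 1L
      c0 <- ((frontier - 1L) %/% nr) + 1L
      nxt <- integer(0)
      for (k in seq_along(dr)) {
        r <- r0 + dr[k]; cc <- c0 + dc[k]
        ok <- r >= 1L & r <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        lin <- (cc[ok] - 1L) * nr + r[ok]
        lin <- lin[mask[lin] & labels[lin] == 0L]
        if (length(lin) > 0L) {
          labels[lin] <- current
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

#' Refill misclassified central k-space energy into the low-rank component
#'
#' The peaked centre of k-space is easily misclassified as sparse. This step
#' undoes that: every nonzero entry of the sparse frame `S` whose connected
#' component (default 8-connectivity) touches the central `window x window`
#' box is moved back into `L` (`L' = L + S`, `S' = 0` on those samples).
#' Everything else is untouched, so `L' + S' = L + S` holds bit-for-bit.
#'
#' @param L_frame,S_frame Complex matrices of equal shape: one frame of the
#'   low-rank and sparse components.
#' @param center_index 1-based k-space centre location.
#' @param window Side of the central box (default 16 samples).
#' @param connectivity 4 or 8 (default 8).
#' @param nonzero_tol Entries with `Mod(S) > nonzero_tol` count as nonzero.
#'   The sparse component of the ALM solver has exact zeros off-support, so
#'   the default 0 is safe; a small positive value adds robustness for sparse
#'   components produced elsewhere.
#' @return List with components `L`, `S` (the refilled frames) and `report`,
#'   itself a list with `n_refilled_pixels` and the logical `refilled_mask`.
#' @export
refill_center <- function(L_frame, S_frame, center_index,
                          window = 16L, connectivity = 8L, nonzero_tol = 0) {
  if (!is.matrix(L_frame) || !is.matrix(S_frame) ||
      !identical(dim(L_frame), dim(S_frame)))
    stop("`L_frame` and `S_frame` must be matrices of equal shape",
         call. = FALSE)
  d <- dim(L_frame)
  window <- as.integer(window)
  if (window > min(d))
    stop("`window` must not exceed the k-space grid", call. = FALSE)

  nz <- Mod(S_frame) > nonzero_tol
  refilled <- matrix(FALSE, d[1], d[2])
  if (any(nz)) {
    labels <- label_components(nz, connectivity)
    win <- central_window_mask(d, center_index, window)
    touching <- unique(labels[win & nz])
    touching <- touching[touching > 0L]
    if (length(touching) > 0L)
      refilled <- matrix(labels %in% touching, d[1], d[2])
  }
  L2 <- L_frame
  S2 <- S_frame
  L2[refilled] <- L_frame[refilled] + S_frame[refilled]
  S2[refilled] <- 0 + 0i
  list(L = L2, S = S2,
       report = list(n_refilled_pixels = sum(refilled),
                     refilled_mask = refilled))
}
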