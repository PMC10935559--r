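# Marker-data handling: Butterworth and SSA filtering, rigid-body pose
# reconstruction from three non-collinear entities, the synthetic bench
# motion generator, and the marker CSV dialect
# (header frame,time,id,x,y,z; gaps as empty cells).

#' Zero-phase low-pass Butterworth filter
#'
#' Second-order Butterworth applied forward-backward (zero phase, DC gain 1),
#' the standard treatment of optical marker trajectories.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param fs sampling frequency (Hz); must exceed twice the cutoff.
#' @param cutoff cutoff frequency (Hz), default 12.
#' @param order filter order, default 2.
#' @export
butterworth_filter <- function(x, fs, cutoff = 12, order = 2) {
  stopifnot(fs > 2 * cutoff, cutoff > 0, order >= 1)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n <= 3 * (order + 1))
    stop("signal shorter than the filter warm-up (need > ",
         3 * (order + 1), " samples)")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection padding removes the zero-state edge transients of a
  # plain forward-backward pass (a constant signal passes through exactly)
  npad <- min(n - 1L, max(100L, as.integer(ceiling(3 * fs / cutoff))))
  ff <- function(v) {
    head_pad <- 2 * v[1] - v[(npad + 1):2]
    tail_pad <- 2 * v[n] - v[(n - 1):(n - npad)]
    out <- signal::filtfilt(bf, c(head_pad, v, tail_pad))
    out[(npad + 1):(npad + n)]
  }
  if (is.matrix(x)) apply(x, 2, ff) else ff(x)
}

#' Singular-spectrum-analysis filter
#'
#' Embeds the series in its trajectory matrix (window length `window`),
#' decomposes it by SVD, keeps the selected components and reconstructs by
#' diagonal averaging. Components default to the leading ones covering
#' `var_frac` of the trajectory-matrix variance.
#'
#' @param x numeric vector, length > 2 * window.
#' @param window embedding window length (default 30), >= 2.
#' @param components integer indices of components to keep, or NULL to select
#'   by `var_frac`.
#' @param var_frac cumulative squared-singular-value fraction (default 0.99).
#' @return filtered series, same length; attribute `n_components` reports the
#'   number kept.
#' @export
ssa_filter <- function(x, window = 30, components = NULL, var_frac = 0.99) {
  n <- length(x)
  if (window < 2) stop("window must be >= 2")
  if (n <= 2 * window) stop("signal length must exceed 2 * window")
  L <- window; K <- n - L + 1
  X <- matrix(0, L, K)
  for (i in seq_len(L)) X[i, ] <- x[i:(i + K - 1)]
  sv <- svd(X)
  if (is.null(components)) {
    # leading components up to the variance target, guarded by a spectral
    # gap: singular values inside the noise plateau (below 3x the median)
    # are never included, so broadband noise is not chased to the target
    frac <- cumsum(sv$d^2) / sum(sv$d^2)
    k_var <- which(frac >= var_frac)[1]
    k_gap <- max(1L, sum(sv$d > 3 * stats::median(sv$d)))
    components <- seq_len(min(k_var, k_gap))
  }
  Xr <- sv$u[, components, drop = FALSE] %*%
    (sv$d[components] * t(sv$v[, components, drop = FALSE]))
  # diagonal (anti-diagonal) averaging back to a series
  out <- numeric(n); cnt <- numeric(n)
  for (i in seq_len(L)) {
    idx <- i:(i + K - 1)
    out[idx] <- out[idx] + Xr[i, ]
    cnt[idx] <- cnt[idx] + 1
  }
  out <- out / cnt
  attr(out, "n_components") <- length(components)
  out
}

#' Reconstruct rigid-body poses from three non-collinear entities
#'
#' The classical construction: an orthogonal frame is built from an origin
#' entity, an axis entity and a plane entity; the same construction applied
#' to the entities' known body-frame coordinates yields the body pose.
#'
#' @param markers long-format data frame (`frame`, `time`, `id`, `x`, `y`,
#'   `z`) for one body.
#' @param recipe list with `origin`, `axis`, `plane` (entity ids) and
#'   `local`, a named list of the entities' body-frame coordinates.
#' @return object of class `pf_pose_series`: `time`, `x` (n x 3), `q`
#'   (n x 4).
#' @export
vaughan_frames <- function(markers, recipe) {
  need <- c(recipe$origin, recipe$axis, recipe$plane)
  stopifnot(all(need %in% markers$id), all(need %in% names(recipe$local)))
  frame_from <- function(p0, p1, p2) {
    e1 <- p1 - p0
    a <- cross3(e1, p2 - p0)
    if (norm3(a) < 1e-10)
      stop("collinear entities (triangle area < 1e-10 m^2)")
    e1 <- unit3(e1)
    e3 <- unit3(a)
    cbind(e1, cross3(e3, e1), e3)
  }
  Rl <- frame_from(recipe$local[[recipe$origin]],
                   recipe$local[[recipe$axis]],
                   recipe$local[[recipe$plane]])
  frames <- sort(unique(markers$frame))
  xs <- matrix(NA_real_, length(frames), 3)
  qs <- matrix(NA_real_, length(frames), 4)
  times <- numeric(length(frames))
  m0 <- markers[markers$id == recipe$origin, ]
  m1 <- markers[markers$id == recipe$axis, ]
  m2 <- markers[markers$id == recipe$plane, ]
  for (k in seq_along(frames)) {
    fr <- frames[k]
    p0 <- unlist(m0[m0$frame == fr, c("x", "y", "z")])
    p1 <- unlist(m1[m1$frame == fr, c("x", "y", "z")])
    p2 <- unlist(m2[m2$frame == fr, c("x", "y", "z")])
    if (anyNA(c(p0, p1, p2))) next
    Rm <- frame_from(p0, p1, p2)
    Rb <- Rm %*% t(Rl)
    xs[k, ] <- p0 - drop(Rb %*% recipe$local[[recipe$origin]])
    qs[k, ] <- mat_to_quat(Rb)
    times[k] <- m0$time[m0$frame == fr][1]
  }
  structure(list(time = times, x = xs, q = qs, frames = frames),
            class = "pf_pose_series")
}

#' Write / read the marker CSV dialect
#'
#' Long format with header `frame,time,id,x,y,z`; gaps are empty cells.
#' @param markers long-format marker data frame.
#' @param path CSV path.
#' @export
write_markers_csv <- function(markers, path) {
  utils::write.csv(markers[, c("frame", "time", "id", "x", "y", "z")], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_markers_csv
#' @export
read_markers_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time", "id", "x", "y", "z")
  if (!all(need %in% names(df))) stop("marker CSV must have columns ",
                                      paste(need, collapse = ","))
  df
}

#' Fill short marker gaps by linear interpolation
#' @param markers long-format marker data frame.
#' @param max_gap longest gap (frames) filled; longer gaps stay NA.
#' @export
fill_marker_gaps <- function(markers, max_gap = 5L) {
  out <- markers
  for (mid in unique(markers$id)) {
    sel <- which(out$id == mid)
    sub <- out[sel, ]
    o <- order(sub$frame)
    for (col in c("x", "y", "z")) {
      v <- sub[[col]][o]
      if (!anyNA(v) || all(is.na(v))) next
      runs <- rle(is.na(v))
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      filled <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                              xout = seq_along(v), rule = 1)$y
      keep_na <- rep(FALSE, length(v))
      for (rr in which(runs$values & runs$lengths > max_gap))
        keep_na[starts[rr]:ends[rr]] <- TRUE
      v_new <- ifelse(is.na(v) & !keep_na, filled, v)
      sub[[col]][o] <- v_new
    }
    out[sel, ] <- sub
  }
  out
}
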