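#' Enclosure geometry helper
#'
#' @param type `"arena"` (rectangular, default 50 x 30 cm) or `"track"`
#'   (circular, default diameter 60 cm, analysed on a 1-D circularised
#'   axis).
#' @param width,height arena dimensions in cm.
#' @param diameter track diameter in cm.
#' @param pixel pixel/bin size in cm (default 2).
#' @return An object of class `enclosure`.
#' @export
enclosure <- function(type = c("arena", "track"), width = 50, height = 30,
                      diameter = 60, pixel = 2) {
  type <- match.arg(type)
  structure(list(type = type, width = width, height = height,
                 diameter = diameter, pixel = pixel),
            class = "enclosure")
}

# pixel index (arena: 2-D grid as [row=y, col=x]; track: 1-D angular bin)
pixel_index <- function(enc, x, y) {
  if (enc$type == "arena") {
    nx <- ceiling(enc$width / enc$pixel)
    ny <- ceiling(enc$height / enc$pixel)
    cx <- pmin(pmax(floor(x / enc$pixel), 0), nx - 1)
    cy <- pmin(pmax(floor(y / enc$pixel), 0), ny - 1)
    list(idx = cy * nx + cx + 1L, dim = c(ny, nx))
  } else {
    circ <- pi * enc$diameter
    nbin <- ceiling(circ / enc$pixel)
    ang <- atan2(y - enc$diameter / 2, x - enc$diameter / 2) %% (2 * pi)
    bin <- pmin(floor(ang / (2 * pi) * nbin), nbin - 1)
    list(idx = bin + 1L, dim = c(1L, nbin))
  }
}

#' Occupancy map of a position track
#'
#' Accumulates frame durations per spatial pixel (2 x 2 cm by default) with
#' immobility frames excluded. The arena is analysed on a 2-D grid, the
#' circular track on a 1-D circularised axis.
#'
#' @param track a [position_track] with speed.
#' @param state a `behavioral_state` from [behavioral_state()]; frames in
#'   its immobility intervals are excluded.
#' @param enc an [enclosure()].
#' @return An object of class `occupancy_map`: `seconds` (matrix of dwell
#'   time per pixel), `included` (logical frame mask), the enclosure, and
#'   `total_time`.
#' @export
occupancy_map <- function(track, state = NULL, enc = enclosure("arena")) {
  stopifnot(inherits(track, "position_track"))
  tol <- 2 * enc$pixel
  if (enc$type == "arena") {
    if (any(track$x < -tol | track$x > enc$width + tol |
            track$y < -tol | track$y > enc$height + tol))
      warning("positions outside the enclosure beyond tolerance: clipped")
  }
  dt <- c(diff(track$t), stats::median(diff(track$t)))
  include <- rep(TRUE, length(track$t))
  if (!is.null(state)) include <- state$frame_label != "immobility"
  px <- pixel_index(enc, track$x, track$y)
  tab <- tapply(dt[include], px$idx[include], sum)
  flat <- numeric(prod(px$dim))
  flat[as.integer(names(tab))] <- tab
  # pixel_index packs row-major (offset cy * nx + cx)
  secs <- matrix(flat, nrow = px$dim[1], ncol = px$dim[2], byrow = TRUE)
  total <- sum(dt[include])
  if (total < 30) warning("insufficient sampling: under 30 s of included time")
  structure(list(seconds = secs, included = include, enclosure = enc,
                 total_time = total),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %s, %d x %d pixels, %.1f s included\n",
              x$enclosure$type, nrow(x$seconds), ncol(x$seconds), x$total_time))
  invisible(x)
}

#' Occupancy-normalised firing-rate map
#'
#' Each spike is assigned to the pixel of the interpolated position at the
#' spike time; the rate is the spike count divided by the dwell time per
#' pixel. Spikes during excluded (immobility) frames are dropped,
#' consistently with the occupancy exclusion.
#'
#' @param spikes spike times in seconds (e.g. all spikes, burst-class
#'   spikes, or single spikes of one cell).
#' @param occ an `occupancy_map`.
#' @param track the [position_track] used for `occ`.
#' @param spike_class label carried along (`"all"`, `"burst"`, `"single"`).
#' @param smooth_sd optional Gaussian smoothing SD in pixels (0 = none).
#' @return An object of class `rate_map`: `rates` (Hz per pixel; `NA` where
#'   occupancy is 0), `peak_rate`, `n_spikes` (included spikes),
#'   `spike_class`, plus the occupancy.
#' @export
rate_map <- function(spikes, occ, track, spike_class = "all", smooth_sd = 0) {
  enc <- occ$enclosure
  keep <- spikes >= track$t[1] & spikes <= track$t[length(track$t)]
  spikes <- spikes[keep]
  frame <- findInterval(spikes, track$t)
  inc <- occ$included[pmax(frame, 1L)]
  spikes <- spikes[inc]; frame <- frame[inc]
  sx <- stats::approx(track$t, track$x, xout = spikes, rule = 2)$y
  sy <- stats::approx(track$t, track$y, xout = spikes, rule = 2)$y
  px <- pixel_index(enc, sx, sy)
  flat <- numeric(prod(px$dim))
  if (length(spikes)) {
    tab <- tapply(rep(1, length(spikes)), px$idx, sum)
    flat[as.integer(names(tab))] <- tab
  }
  counts <- matrix(flat, nrow = px$dim[1], ncol = px$dim[2], byrow = TRUE)
  rates <- counts / occ$seconds
  rates[occ$seconds == 0] <- NA_real_
  if (smooth_sd > 0) rates <- gauss_smooth_map(rates, smooth_sd,
                                               circular = enc$type == "track")
  structure(list(rates = rates, counts = counts,
                 peak_rate = if (any(!is.na(rates))) max(rates, na.rm = TRUE) else 0,
                 n_spikes = length(spikes), spike_class = spike_class,
                 occupancy = occ),
            class = "rate_map")
}

# separable Gaussian smoothing of a rate map, NA-aware; 1-D maps on the
# track wrap circularly
gauss_smooth_map <- function(m, sd_px, circular = FALSE) {
  half <- ceiling(3 * sd_px)
  k <- stats::dnorm(seq(-half, half), sd = sd_px)
  k <- k / sum(k)
  sm_line <- function(v) {
    n <- length(v)
    w <- !is.na(v)
    v0 <- ifelse(w, v, 0)
    if (circular) {
      num <- as.numeric(stats::filter(c(v0, v0, v0), k, sides = 2))[(n + 1):(2 * n)]
      den <- as.numeric(stats::filter(c(w, w, w), k, sides = 2))[(n + 1):(2 * n)]
    } else {
      num <- as.numeric(stats::filter(v0, k, sides = 2))
      den <- as.numeric(stats::filter(as.numeric(w), k, sides = 2))
    }
    out <- num / den
    out[!w] <- NA_real_
    out
  }
  if (nrow(m) == 1) return(matrix(sm_line(m[1, ]), nrow = 1))
  t(apply(apply(m, 2, sm_line), 1, sm_line))
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map [%s]> peak %.2f Hz, %d spikes\n", x$spike_class,
              x$peak_rate, x$n_spikes))
  invisible(x)
}

#' Detect place fields in a rate map
#'
#' Place fields are 4-connected components of pixels whose rate exceeds the
#' threshold (1 Hz); components smaller than `min_pixels` are discarded.
#' The largest field is the cell's primary field.
#'
#' @param map a `rate_map`.
#' @param threshold rate threshold in Hz (default 1, strict `>`).
#' @param min_pixels minimum component size in pixels (default 2).
#' @return List of fields, largest first; each has `pixels` (index matrix),
#'   `size_cm2`, `peak_rate`. Empty list when nothing exceeds threshold.
#' @export
detect_fields <- function(map, threshold = 1, min_pixels = 2) {
  enc <- map$occupancy$enclosure
  above <- !is.na(map$rates) & map$rates > threshold
  if (!any(above)) return(list())
  lab <- connected_components(above, wrap_cols = enc$type == "track")
  fields <- list()
  for (comp in seq_len(max(lab))) {
    px <- which(lab == comp, arr.ind = TRUE)
    if (nrow(px) < min_pixels) next
    fields[[length(fields) + 1L]] <-
      list(pixels = px,
           size_cm2 = nrow(px) * enc$pixel^2,
           peak_rate = max(map$rates[px]))
  }
  if (!length(fields)) return(list())
  fields[order(-vapply(fields, function(f) nrow(f$pixels), numeric(1)))]
}

# 4-connected component labelling by flood fill; optional circular wrap of
# columns (1-D track maps)
connected_components <- function(mask, wrap_cols = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  for (start in which(mask & lab == 0L)) {
    comp <- comp + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- comp
      r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
      nb <- c(if (r > 1) p - 1L, if (r < nr) p + 1L,
              if (cc > 1) p - nr else if (wrap_cols && nc > 1) p + nr * (nc - 1L),
              if (cc < nc) p + nr else if (wrap_cols && nc > 1) p - nr * (nc - 1L))
      for (q in nb) if (mask[q] && lab[q] == 0L) stack <- c(stack, q)
    }
  }
  lab
}

#' Place-field and spatial-coding statistics
#'
#' Over the defined pixels of a rate map with occupancy fractions p_i and
#' rates lambda_i: sparsity = (sum p_i lambda_i)^2 / sum p_i lambda_i^2,
#' information density = sum p_i (lambda_i / lambda_bar)
#' log2(lambda_i / lambda_bar) bits/spike with lambda_bar = sum p_i
#' lambda_i, and the in-field rate is the occupancy-weighted mean rate over
#' the field pixels.
#'
#' @param map a `rate_map`.
#' @param field a field from [detect_fields()], or `NULL` (in-field rate is
#'   then `NA`).
#' @param occ the `occupancy_map` (defaults to the one attached to `map`).
#' @return List with `peak_rate`, `in_field_rate`, `sparsity`,
#'   `information_density`, `mean_rate`.
#' @export
field_statistics <- function(map, field = NULL, occ = map$occupancy) {
  ok <- occ$seconds > 0 & !is.na(map$rates)
  p <- occ$seconds[ok] / sum(occ$seconds[ok])
  lam <- map$rates[ok]
  lbar <- sum(p * lam)
  if (lbar == 0) stop("mean rate is zero: statistics undefined")
  sparsity <- lbar^2 / sum(p * lam^2)
  rel <- lam / lbar
  info <- sum(p[rel > 0] * rel[rel > 0] * log2(rel[rel > 0]))
  in_rate <- NA_real_
  if (!is.null(field)) {
    fsec <- occ$seconds[field$pixels]
    in_rate <- sum(fsec * map$rates[field$pixels]) / sum(fsec)
  }
  list(peak_rate = map$peak_rate, in_field_rate = in_rate,
       sparsity = sparsity, information_density = info, mean_rate = lbar)
}

#' Fisher z-transformed Pearson correlation of two rate maps
#'
#' Pearson correlation over the jointly defined pixels; r is clipped to
#' +-0.999999 before atanh.
#'
#' @param map_a,map_b `rate_map` objects on the same grid.
#' @return List with `r`, `z`, `n_pixels`, and `flag` (`"ok"`, `"perfect"`).
#' @export
map_correlation <- function(map_a, map_b) {
  if (!all(dim(map_a$rates) == dim(map_b$rates))) stop("map grid mismatch")
  ok <- !is.na(map_a$rates) & !is.na(map_b$rates)
  if (sum(ok) < 10) stop("need at least 10 jointly defined pixels")
  a <- map_a$rates[ok]; b <- map_b$rates[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant map: correlation undefined")
  r <- stats::cor(a, b)
  flag <- if (abs(r) > 0.999999) "perfect" else "ok"
  r_cl <- max(-0.999999, min(0.999999, r))
  list(r = r, z = atanh(r_cl), n_pixels = sum(ok), flag = flag)
}

#' Place-field size decomposition by spike class
#'
#' Builds the all-spike, burst-spike and single-spike rate maps of one cell,
#' detects the primary field of each, and reports each class's field size
#' as a fraction of the all-spike field size.
#'
#' @param seg a `burst_segmentation` of the cell.
#' @param occ an `occupancy_map`.
#' @param track the [position_track].
#' @param threshold,min_pixels field-detection parameters.
#' @param multi_field `"largest"` (default) or `"sum"`: use the primary
#'   field's size or the summed size of all fields.
#' @return List with per-class `maps`, `fields`, `size_cm2` and
#'   `size_fraction` (all-spike class identically 1; `NA` when the class
#'   has no field).
#' @export
field_size_by_class <- function(seg, occ, track, threshold = 1, min_pixels = 2,
                                multi_field = c("largest", "sum")) {
  multi_field <- match.arg(multi_field)
  spk <- list(all = sort(c(burst_spike_times(seg), seg$single_spikes)),
              burst = burst_spike_times(seg),
              single = seg$single_spikes)
  maps <- lapply(names(spk), function(cl) rate_map(spk[[cl]], occ, track, cl))
  names(maps) <- names(spk)
  fields <- lapply(maps, detect_fields, threshold = threshold,
                   min_pixels = min_pixels)
  size_of <- function(fl) {
    if (!length(fl)) return(NA_real_)
    if (multi_field == "largest") fl[[1]]$size_cm2
    else sum(vapply(fl, `[[`, numeric(1), "size_cm2"))
  }
  sizes <- vapply(fields, size_of, numeric(1))
  list(maps = maps, fields = fields, size_cm2 = sizes,
       size_fraction = sizes / sizes[["all"]])
}
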