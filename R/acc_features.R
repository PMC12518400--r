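# Acceleration segmentation, summary-statistic features, pooled F-measure
# evaluation, and the habitat correction of foraging labels.

# Supported fixed segment lengths (seconds) at 20 Hz sampling.
.segment_lengths <- c(0.4, 0.8, 1.6)

#' Cut acceleration bursts into fixed-length segments
#'
#' Bursts are cut into non-overlapping segments of `segment_length` seconds;
#' a trailing remainder shorter than the segment is discarded, so truncated
#' or incomplete bursts contribute only their full segments.
#'
#' @param bursts A tibble of acceleration bursts, one row per burst, with
#'   columns `bird_id`, `burst_start` (POSIXct), `gps_speed_kmh`, list
#'   columns `x`, `y`, `z` (numeric readings in g at `acc_rate` Hz) and
#'   optionally `behaviour` (training label) and `complete`.
#' @param segment_length Segment length in seconds: 0.4, 0.8 or 1.6.
#' @param acc_rate Sampling rate in Hz (default 20).
#' @return A tibble with one row per segment, same columns plus `segment`
#'   (index within burst); the `x`, `y`, `z` list columns hold the segment's
#'   readings.
#' @export
segment_bursts <- function(bursts, segment_length, acc_rate = 20) {
  stopifnot(is.data.frame(bursts))
  if (!segment_length %in% .segment_lengths) {
    stop("segment_length must be one of ",
         paste(.segment_lengths, collapse = ", "), " s", call. = FALSE)
  }
  n_per <- as.integer(round(segment_length * acc_rate))
  lens <- vapply(bursts$x, length, integer(1))
  n_seg <- lens %/% n_per
  idx <- rep.int(seq_len(nrow(bursts)), n_seg)
  seg_no <- sequence(n_seg)
  out <- bursts[idx, setdiff(names(bursts), c("x", "y", "z")), drop = FALSE]
  out$segment <- seg_no
  take <- function(v, k) v[((k - 1L) * n_per + 1L):(k * n_per)]
  out$x <- mapply(take, bursts$x[idx], seg_no, SIMPLIFY = FALSE)
  out$y <- mapply(take, bursts$y[idx], seg_no, SIMPLIFY = FALSE)
  out$z <- mapply(take, bursts$z[idx], seg_no, SIMPLIFY = FALSE)
  out$segment_length <- segment_length
  tibble::as_tibble(out)
}

# Dominant spectral frequency and normalized peak power of one detrended
# axis: Hann window, zero-padded FFT for sub-bin frequency resolution,
# near-DC bins (< 0.3 Hz) excluded so slow trends do not masquerade as a
# behavioural rhythm.
.dominant_freq <- function(v, rate, n_pad = 512) {
  n <- length(v)
  v <- v - mean(v)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  vp <- c(v * w, rep(0, n_pad - n))
  sp <- Mod(stats::fft(vp))[seq_len(n_pad / 2)]^2
  freq <- (seq_len(n_pad / 2) - 1) * rate / n_pad
  use <- freq >= 0.3
  k <- which(use)[which.max(sp[use])]
  c(freq = freq[k], power = sp[k] / (sum(sp[use]) + 1e-12))
}

# Correlation that is 0 (not NA) when either vector is constant.
.safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Summary-statistic features for one acceleration segment
#'
#' Computes per-axis mean, standard deviation, minimum, maximum, skewness
#' and kurtosis; per-axis dominant spectral frequency and its normalized
#' power (Hann-windowed, zero-padded discrete Fourier transform of the
#' mean-centred axis, near-DC excluded); pairwise axis correlations; overall
#' dynamic body acceleration (ODBA, the summed mean absolute deviation of
#' the three axes from their segment means); and the paired GPS speed.
#'
#' All features except the per-axis means, minima and maxima are invariant
#' to adding a constant to all three axes (those three shift with it).
#' Skewness and kurtosis of a constant axis are defined as 0.
#'
#' @param x,y,z Numeric vectors of equal length: surge, sway and heave
#'   readings in g.
#' @param gps_speed Paired GPS speed in km/h (a single number).
#' @param acc_rate Sampling rate in Hz (default 20).
#' @return A named numeric vector of 30 features.
#' @export
featurize <- function(x, y, z, gps_speed, acc_rate = 20) {
  if (!all(is.finite(c(x, y, z))) || !is.finite(gps_speed)) {
    stop("non-finite acceleration readings or GPS speed", call. = FALSE)
  }
  stopifnot(length(x) == length(y), length(y) == length(z))
  axis_stats <- function(v, tag) {
    s <- stats::sd(v)
    sk <- if (s == 0) 0 else e1071::skewness(v, type = 2)
    ku <- if (s == 0) 0 else e1071::kurtosis(v, type = 2)
    dom <- .dominant_freq(v, acc_rate)
    out <- c(mean(v), s, min(v), max(v), sk, ku, dom[["freq"]], dom[["power"]])
    names(out) <- paste0(tag, "_", c("mean", "sd", "min", "max", "skew",
                                     "kurt", "domfreq", "dompow"))
    out
  }
  odba <- mean(abs(x - mean(x))) + mean(abs(y - mean(y))) +
    mean(abs(z - mean(z)))
  c(axis_stats(x, "x"), axis_stats(y, "y"), axis_stats(z, "z"),
    cor_xy = .safe_cor(x, y), cor_xz = .safe_cor(x, z),
    cor_yz = .safe_cor(y, z),
    odba = odba, gps_speed = gps_speed, segment_length = length(x) / acc_rate)
}

#' Feature table for a set of segments
#'
#' Applies [featurize()] to every row of a segment tibble (from
#' [segment_bursts()]). Segments with any non-finite reading are dropped
#' with a message.
#'
#' @param segments A segment tibble from [segment_bursts()].
#' @param acc_rate Sampling rate in Hz (default 20).
#' @return A tibble of features, one row per segment, with the segment's
#'   identifying columns (`bird_id`, `burst_start`, `segment` and, when
#'   present, `behaviour`) prepended.
#' @export
featurize_segments <- function(segments, acc_rate = 20) {
  stopifnot(is.data.frame(segments), nrow(segments) > 0)
  ok <- vapply(seq_len(nrow(segments)), function(i) {
    all(is.finite(c(segments$x[[i]], segments$y[[i]], segments$z[[i]],
                    segments$gps_speed_kmh[i])))
  }, logical(1))
  if (!all(ok)) {
    message(sum(!ok), " segment(s) with non-finite readings dropped")
    segments <- segments[ok, , drop = FALSE]
  }
  feats <- t(vapply(seq_len(nrow(segments)), function(i) {
    featurize(segments$x[[i]], segments$y[[i]], segments$z[[i]],
              segments$gps_speed_kmh[i], acc_rate)
  }, numeric(30)))
  id_cols <- intersect(c("bird_id", "burst_start", "segment", "behaviour"),
                       names(segments))
  tibble::as_tibble(cbind(segments[id_cols], as.data.frame(feats)))
}

#' Pooled behaviour classes
#'
#' The default pooling map used for classifier evaluation: the three
#' foraging behaviours pool to `forage`, sitting and standing to `rest`, the
#' two flight modes to `fly`; `walk` and `beg` stay unpooled.
#'
#' @return Named character vector mapping each of the 9 behaviour classes to
#'   its pooled class.
#' @export
behaviour_pooling <- function() {
  c(search = "forage", handle = "forage", ingest = "forage",
    sit = "rest", stand = "rest",
    `fly-active` = "fly", `fly-passive` = "fly",
    walk = "walk", beg = "beg")
}

#' The nine behaviour classes
#' @return Character vector of class labels.
#' @export
behaviour_classes <- function() names(behaviour_pooling())

#' Per-class F-measure
#'
#' F = 2 * precision * recall / (precision + recall) per class, the balanced
#' measure of sensitivity and precision used to score the behaviour
#' classifier. An optional pooling map is applied to both predictions and
#' truth before scoring, so confusion within a pooled group does not count
#' against it. F is defined as 0 when precision + recall = 0.
#'
#' @param pred,truth Equal-length character vectors of class labels.
#' @param pooling Optional named character vector mapping raw to pooled
#'   labels (e.g. [behaviour_pooling()]); `NULL` scores raw labels.
#' @return Named numeric vector of F scores, one per class present in the
#'   (pooled) truth.
#' @export
f_measure <- function(pred, truth, pooling = NULL) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  pred <- as.character(pred); truth <- as.character(truth)
  if (!is.null(pooling)) {
    stopifnot(!is.null(names(pooling)))
    map <- function(v) ifelse(v %in% names(pooling), unname(pooling[v]), v)
    pred <- map(pred); truth <- map(truth)
  }
  classes <- sort(unique(truth))
  vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
}

# Ray-casting point-in-polygon on lon/lat coordinates (even-odd rule).
# Polygon scale (hundreds of metres and up) dwarfs positional error, so no
# projection is applied. Points exactly on an edge may fall either side.
.point_in_ring <- function(lon, lat, ring_lon, ring_lat) {
  n <- length(ring_lon)
  j <- n
  inside <- rep(FALSE, length(lon))
  for (i in seq_len(n)) {
    xi <- ring_lon[i]; yi <- ring_lat[i]
    xj <- ring_lon[j]; yj <- ring_lat[j]
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Are points inside foraging habitat?
#'
#' @param lat,lon Numeric coordinate vectors.
#' @param habitat A habitat map: a list of polygons, each a data frame with
#'   columns `lon` and `lat` (closed or open rings), marking foraging water
#'   (freshwater, brackish or marine); everything outside is land.
#' @return Logical vector.
#' @export
in_foraging_habitat <- function(lat, lon, habitat) {
  stopifnot(is.list(habitat))
  inside <- rep(FALSE, length(lat))
  for (ring in habitat) {
    inside <- inside | .point_in_ring(lon, lat, ring$lon, ring$lat)
  }
  inside
}

#' Habitat correction of foraging classifications
#'
#' Walking is often confused with foraging in acceleration data, so a fix is
#' accepted as foraging only when it is classified as foraging *and* lies in
#' foraging habitat (water); foraging classifications over land are
#' rewritten to `walk`. All other labels are unchanged.
#'
#' @param labels Character vector of behaviour labels.
#' @param lat,lon Coordinates of the labelled fixes.
#' @param habitat Habitat map as in [in_foraging_habitat()]. Fixes outside
#'   map coverage are treated as land (the default, reported via message)
#'   — every point not inside a water polygon is land.
#' @param forage_classes Labels the rule applies to (default the three
#'   foraging behaviours plus a pooled `"forage"`).
#' @return Corrected label vector.
#' @export
habitat_correct <- function(labels, lat, lon, habitat,
                            forage_classes = c("search", "handle", "ingest",
                                               "forage")) {
  stopifnot(length(labels) == length(lat), length(lat) == length(lon))
  is_forage <- labels %in% forage_classes
  if (!any(is_forage)) return(labels)
  water <- in_foraging_habitat(lat[is_forage], lon[is_forage], habitat)
  out <- labels
  out[which(is_forage)[!water]] <- "walk"
  out
}
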