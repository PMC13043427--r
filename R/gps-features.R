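# Trajectory segmentation and the four location-derived daily variables:
# distance traveled (sum of flight lengths), significant location count and
# entropy, and home duration. Concepts: a *pause* is a maximal run of points
# staying within a small radius of its running centroid; a *flight* is a
# straight-line trip between pauses or directional changes; *significant
# locations* are clusters of >= 15-min pauses whose centers are >= 50 m
# apart, found per patient over the whole follow-up.

# Vertices closer than this (m) are merged before heading computation, so
# residual jitter cannot masquerade as a directional change.
.MIN_VERTEX_DISP_M <- 5

# Restore the caller's RNG state after seeded internals.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Average GPS fixes over fixed epochs
#'
#' Collapses raw fixes to one position per `epoch_s`-second epoch (the mean
#' of member fixes, timestamped at the epoch start). Averaging suppresses
#' per-fix noise by roughly the square root of the burst rate before pause
#' and flight segmentation.
#'
#' @param points a `data.table` with columns `t`, `lat`, `lon`.
#' @param epoch_s epoch length in seconds.
#' @return a `data.table` with `t` (epoch start), `lat`, `lon`, `n_pts`.
#' @export
epoch_positions <- function(points, epoch_s = 10) {
  points <- as.data.table(points)
  if (nrow(points) == 0)
    return(data.table(t = numeric(), lat = numeric(), lon = numeric(),
                      n_pts = integer()))
  ep <- points[, .(lat = mean(lat), lon = mean(lon), n_pts = .N),
               by = .(t = floor(t / epoch_s) * epoch_s)]
  setorder(ep, t)
  ep[]
}

#' Segment a day's GPS points into pauses
#'
#' Scans the time-sorted trace keeping a running centroid: a point within
#' `pause_radius_m` of the current run's centroid extends the run, anything
#' else (or an observation gap longer than `gap_max_s`) closes it. Runs
#' lasting at least `min_pause_s` become pauses; pauses are disjoint and
#' time-ordered.
#'
#' @param points time-sorted `data.table` with `t`, `lat`, `lon`
#'   (raw fixes or [epoch_positions()] output).
#' @param pause_radius_m radius in meters.
#' @param min_pause_s minimum duration in seconds.
#' @param gap_max_s maximum in-pause observation gap (seconds); longer gaps
#'   split the run so unobserved time is not counted as dwell.
#' @param point_span_s nominal span of a single point (seconds), added to
#'   close the last observation of a run (the epoch length when points are
#'   epoch-averaged).
#' @return a `data.table` of pauses: `start`, `end`, `lat`, `lon`
#'   (centroid), `duration_s`.
#' @export
segment_pauses <- function(points, pause_radius_m = 50, min_pause_s = 300,
                           gap_max_s = 900, point_span_s = 10) {
  points <- as.data.table(points)
  empty <- data.table(start = numeric(), end = numeric(), lat = numeric(),
                      lon = numeric(), duration_s = numeric())
  n <- nrow(points)
  if (n == 0) return(empty)
  tt <- points$t; la <- points$lat; lo <- points$lon
  res_start <- numeric(); res_end <- numeric()
  res_lat <- numeric(); res_lon <- numeric()
  run_from <- 1L
  c_lat <- la[1]; c_lon <- lo[1]; c_n <- 1L
  close_run <- function(from, to) {
    dur <- tt[to] - tt[from] + point_span_s
    if (dur >= min_pause_s) {
      res_start <<- c(res_start, tt[from])
      res_end <<- c(res_end, tt[to] + point_span_s)
      res_lat <<- c(res_lat, c_lat)
      res_lon <<- c(res_lon, c_lon)
    }
  }
  if (n > 1) {
    for (i in 2:n) {
      gap <- tt[i] - tt[i - 1L]
      if (gap > gap_max_s ||
          haversine_m(la[i], lo[i], c_lat, c_lon) > pause_radius_m) {
        close_run(run_from, i - 1L)
        run_from <- i
        c_lat <- la[i]; c_lon <- lo[i]; c_n <- 1L
      } else {
        c_n <- c_n + 1L
        c_lat <- c_lat + (la[i] - c_lat) / c_n
        c_lon <- c_lon + (lo[i] - c_lon) / c_n
      }
    }
  }
  close_run(run_from, n)
  if (!length(res_start)) return(empty)
  data.table(start = res_start, end = res_end, lat = res_lat, lon = res_lon,
             duration_s = res_end - res_start)
}

# Split one vertex sequence at heading changes; returns a data.table of
# flights (origin -> destination straight lines).
.split_segment <- function(seg, heading_change_deg) {
  n <- nrow(seg)
  if (n < 2) return(NULL)
  # merge vertices with sub-noise displacement
  keep <- logical(n); keep[1] <- TRUE
  last <- 1L
  for (i in 2:n) {
    if (haversine_m(seg$lat[i], seg$lon[i], seg$lat[last], seg$lon[last]) >=
        .MIN_VERTEX_DISP_M) {
      keep[i] <- TRUE; last <- i
    }
  }
  seg <- seg[keep]
  n <- nrow(seg)
  if (n < 2) return(NULL)
  br <- bearing_deg(seg$lat[-n], seg$lon[-n], seg$lat[-1], seg$lon[-1])
  cut_after <- if (n > 2)
    which(.heading_diff(br[-length(br)], br[-1]) > heading_change_deg) + 1L
  else integer()
  bounds <- c(1L, cut_after, n)
  o <- bounds[-length(bounds)]
  d <- bounds[-1]
  data.table(
    origin_lat = seg$lat[o], origin_lon = seg$lon[o],
    dest_lat = seg$lat[d], dest_lon = seg$lon[d],
    start = seg$t[o], end = seg$t[d],
    length_m = haversine_m(seg$lat[o], seg$lon[o], seg$lat[d], seg$lon[d])
  )
}

#' Extract flights from a day's points and pauses
#'
#' The trace between consecutive pauses (and at the trace edges) is split at
#' vertices where the heading changes by more than `heading_change_deg`;
#' each resulting sub-segment becomes one straight-line flight from its
#' first to its last point. Pause centroids anchor the segment endpoints, so
#' flights and pauses tile the day without overlap.
#'
#' @param points time-sorted `data.table` with `t`, `lat`, `lon`.
#' @param pauses output of [segment_pauses()] on the same points.
#' @param heading_change_deg directional-change threshold in degrees.
#' @return a `data.table` of flights: origin/destination coordinates,
#'   `start`, `end`, `length_m`.
#' @export
extract_flights <- function(points, pauses, heading_change_deg = 30) {
  points <- as.data.table(points)
  empty <- data.table(origin_lat = numeric(), origin_lon = numeric(),
                      dest_lat = numeric(), dest_lon = numeric(),
                      start = numeric(), end = numeric(), length_m = numeric())
  if (nrow(points) < 2) return(empty)
  np <- nrow(pauses)
  segs <- list()
  if (np == 0) {
    segs[[1]] <- points[, .(t, lat, lon)]
  } else {
    lead <- points[t < pauses$start[1]]
    if (nrow(lead) > 0)
      segs[[length(segs) + 1]] <- rbind(
        lead[, .(t, lat, lon)],
        data.table(t = pauses$start[1], lat = pauses$lat[1], lon = pauses$lon[1]))
    if (np > 1) {
      for (j in 1:(np - 1)) {
        mid <- points[t >= pauses$end[j] & t < pauses$start[j + 1]]
        segs[[length(segs) + 1]] <- rbind(
          data.table(t = pauses$end[j], lat = pauses$lat[j], lon = pauses$lon[j]),
          mid[, .(t, lat, lon)],
          data.table(t = pauses$start[j + 1], lat = pauses$lat[j + 1],
                     lon = pauses$lon[j + 1]))
      }
    }
    trail <- points[t >= pauses$end[np]]
    if (nrow(trail) > 0)
      segs[[length(segs) + 1]] <- rbind(
        data.table(t = pauses$end[np], lat = pauses$lat[np], lon = pauses$lon[np]),
        trail[, .(t, lat, lon)])
  }
  out <- rbindlist(Filter(Negate(is.null),
                          lapply(segs, .split_segment, heading_change_deg)))
  if (is.null(out) || nrow(out) == 0) return(empty)
  out[length_m > 0][order(start)]
}

#' Daily distance traveled
#'
#' The sum of the lengths of all of a day's flights, in kilometers.
#'
#' @param flights a flight table from [extract_flights()].
#' @return distance in km (0 for no flights).
#' @export
daily_distance_km <- function(flights) {
  if (is.null(flights) || nrow(flights) == 0) return(0)
  sum(flights$length_m) / 1000
}

# Equirectangular projection to local meters around a reference point;
# adequate at the city scales of daily mobility.
.project_m <- function(lat, lon, lat0, lon0) {
  cbind(x = .deg2rad(lon - lon0) * cos(.deg2rad(lat0)) * .EARTH_RADIUS_M,
        y = .deg2rad(lat - lat0) * .EARTH_RADIUS_M)
}

.unproject_m <- function(x, y, lat0, lon0) {
  list(lat = lat0 + .rad2deg(y / .EARTH_RADIUS_M),
       lon = lon0 + .rad2deg(x / (cos(.deg2rad(lat0)) * .EARTH_RADIUS_M)))
}

# Weighted Lloyd k-means with k-means++ initialisation. Returns centers and
# the max point-to-assigned-center distance. Deterministic given the RNG
# state of the caller.
.kmeans_weighted <- function(pts, w, k, restarts = 10, iter_max = 50) {
  n <- nrow(pts)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- matrix(NA_real_, k, 2)
    centers[1, ] <- pts[sample.int(n, 1, prob = w), ]
    if (k > 1) for (j in 2:k) {
      d2 <- apply(pts, 1, function(p)
        min(colSums((t(centers[1:(j - 1), , drop = FALSE]) - p)^2)))
      if (all(d2 == 0)) centers[j, ] <- pts[sample.int(n, 1), ]
      else centers[j, ] <- pts[sample.int(n, 1, prob = w * d2), ]
    }
    assign_prev <- rep(0L, n)
    for (it in seq_len(iter_max)) {
      d2 <- vapply(seq_len(k), function(j)
        (pts[, 1] - centers[j, 1])^2 + (pts[, 2] - centers[j, 2])^2,
        numeric(n))
      d2 <- matrix(d2, nrow = n)
      a <- max.col(-d2, ties.method = "first")
      for (j in seq_len(k)) {
        m <- a == j
        if (any(m)) centers[j, ] <- colSums(pts[m, , drop = FALSE] * w[m]) / sum(w[m])
      }
      if (identical(a, assign_prev)) break
      assign_prev <- a
    }
    wss <- sum(w * d2[cbind(seq_len(n), a)])
    if (is.null(best) || wss < best$wss)
      best <- list(centers = centers, assign = a, wss = wss,
                   max_dist = sqrt(max(d2[cbind(seq_len(n), a)])))
  }
  best
}

#' Find a patient's significant locations
#'
#' Pauses of at least `min_pause_s` (15 min) from the whole follow-up enter
#' duration-weighted k-means clustering over their centroids; k grows from 1
#' until every pause lies within `separation_m / 2` of its cluster center,
#' so that pause groups more than `separation_m` (50 m) apart resolve into
#' distinct locations while closer groups merge. The cluster centers are
#' the significant locations, ordered by total pause time (id 1 = most
#' visited).
#'
#' @param pauses all follow-up pauses of one patient ([segment_pauses()]
#'   rows, any number of days concatenated).
#' @param min_pause_s qualification threshold in seconds.
#' @param separation_m cluster radius / separation in meters.
#' @param seed integer seed for the k-means++ restarts.
#' @return a `data.table`: `loc_id`, `lat`, `lon`, `total_pause_s`,
#'   `is_home` (all `FALSE`; see [detect_home()]).
#' @export
find_significant_locations <- function(pauses, min_pause_s = 900,
                                       separation_m = 50, seed = 1L) {
  empty <- data.table(loc_id = integer(), lat = numeric(), lon = numeric(),
                      total_pause_s = numeric(), is_home = logical())
  if (is.null(pauses) || nrow(pauses) == 0) return(empty)
  q <- as.data.table(pauses)[duration_s >= min_pause_s]
  if (nrow(q) == 0) return(empty)
  lat0 <- mean(q$lat); lon0 <- mean(q$lon)
  pts <- .project_m(q$lat, q$lon, lat0, lon0)
  w <- q$duration_s
  k_max <- min(nrow(q), 25L)
  fit <- NULL
  .with_seed(seed, {
    for (k in seq_len(k_max)) {
      fit <- .kmeans_weighted(pts, w, k)
      if (fit$max_dist < separation_m / 2) break
    }
  })
  cl <- fit$assign
  tot <- vapply(seq_len(nrow(fit$centers)),
                function(j) sum(w[cl == j]), numeric(1))
  keep <- which(tot > 0)
  ord <- keep[order(-tot[keep])]
  ll <- .unproject_m(fit$centers[ord, 1], fit$centers[ord, 2], lat0, lon0)
  data.table(loc_id = seq_along(ord), lat = ll$lat, lon = ll$lon,
             total_pause_s = tot[ord], is_home = FALSE)
}

# Seconds of [start, end) falling inside local-time night windows
# [20:00, 08:00). Vectorized over intervals.
.night_overlap_s <- function(start, end, tz) {
  if (!length(start)) return(numeric())
  ps <- as.POSIXct(start, origin = "1970-01-01", tz = tz)
  pe <- as.POSIXct(end, origin = "1970-01-01", tz = tz)
  sod <- function(p) as.numeric(p - as.POSIXct(format(p, "%Y-%m-%d"), tz = tz),
                                units = "secs")
  dmid <- as.numeric(as.Date(format(pe, "%Y-%m-%d")) -
                     as.Date(format(ps, "%Y-%m-%d")))
  # cumulative night seconds within a calendar day: 8 h morning + 4 h evening
  g <- function(u) pmin(u, 8 * 3600) + pmax(0, u - 20 * 3600)
  12 * 3600 * dmid + g(sod(pe)) - g(sod(ps))
}

#' Identify the home location
#'
#' Home is the significant location with the greatest total pause time
#' falling inside the 20:00-08:00 local-time windows over the whole
#' follow-up. Ties break by larger all-day pause time, then smaller id.
#'
#' @param sig_locs significant locations ([find_significant_locations()]).
#' @param pauses the same patient's full-follow-up pauses.
#' @param separation_m attribution radius in meters.
#' @param tz IANA timezone of the patient (night windows are local time).
#' @return `sig_locs` with `is_home` set on exactly one row.
#' @export
detect_home <- function(sig_locs, pauses, separation_m = 50, tz = "UTC") {
  if (is.null(sig_locs) || nrow(sig_locs) == 0)
    stop("detect_home: no significant locations; home is not assignable")
  pauses <- as.data.table(pauses)
  loc <- .assign_pauses(pauses, sig_locs, separation_m)
  night <- .night_overlap_s(pauses$start, pauses$end, tz)
  tab <- data.table(loc_id = loc, night_s = night, total_s = pauses$duration_s)
  tab <- tab[!is.na(loc_id),
             .(night_s = sum(night_s), total_s = sum(total_s)), by = loc_id]
  tab <- merge(data.table(loc_id = sig_locs$loc_id), tab,
               by = "loc_id", all.x = TRUE)
  tab[is.na(night_s), `:=`(night_s = 0, total_s = 0)]
  setorder(tab, -night_s, -total_s, loc_id)
  out <- copy(as.data.table(sig_locs))
  out[, is_home := loc_id == tab$loc_id[1]]
  out[]
}

# Nearest significant location within separation_m, else NA.
.assign_pauses <- function(pauses, sig_locs, separation_m) {
  if (nrow(pauses) == 0) return(integer())
  d <- vapply(seq_len(nrow(sig_locs)), function(j)
    haversine_m(pauses$lat, pauses$lon, sig_locs$lat[j], sig_locs$lon[j]),
    numeric(nrow(pauses)))
  d <- matrix(d, nrow = nrow(pauses))
  nearest <- max.col(-d, ties.method = "first")
  dist <- d[cbind(seq_len(nrow(pauses)), nearest)]
  ifelse(dist <= separation_m, sig_locs$loc_id[nearest], NA_integer_)
}

#' Daily home duration
#'
#' Total duration of the day's pauses whose centroid lies within
#' `separation_m` of home, in hours, capped at 24.
#'
#' @param day_pauses one day's pauses.
#' @param home the home row of the significant-location table.
#' @param separation_m attribution radius in meters.
#' @return hours at home.
#' @export
daily_home_duration_h <- function(day_pauses, home, separation_m = 50) {
  if (is.null(day_pauses) || nrow(day_pauses) == 0) return(0)
  d <- haversine_m(day_pauses$lat, day_pauses$lon, home$lat, home$lon)
  min(sum(day_pauses$duration_s[d <= separation_m]) / 3600, 24)
}

#' Daily significant-location occupancy profile
#'
#' Attributes the day's pause seconds to the nearest significant location
#' (within `separation_m`) and returns occupancy proportions `p` normalized
#' over the day's observed significant-location dwell, together with the
#' day's location count (locations with any dwell).
#'
#' @param day_pauses one day's pauses.
#' @param sig_locs the patient's significant locations.
#' @param separation_m attribution radius in meters.
#' @return list with `p` (named numeric, sums to 1 when non-empty),
#'   `occupancy_s` (seconds per location), `count`.
#' @export
day_location_profile <- function(day_pauses, sig_locs, separation_m = 50) {
  if (is.null(sig_locs) || nrow(sig_locs) == 0 ||
      is.null(day_pauses) || nrow(day_pauses) == 0)
    return(list(p = numeric(), occupancy_s = numeric(), count = 0L))
  loc <- .assign_pauses(as.data.table(day_pauses), sig_locs, separation_m)
  occ <- tapply(day_pauses$duration_s, factor(loc, levels = sig_locs$loc_id),
                sum, default = 0)
  occ <- as.numeric(occ)
  names(occ) <- as.character(sig_locs$loc_id)
  occ <- occ[occ > 0]
  if (!length(occ)) return(list(p = numeric(), occupancy_s = numeric(), count = 0L))
  list(p = occ / sum(occ), occupancy_s = occ, count = length(occ))
}

#' Significant-location entropy
#'
#' Shannon entropy, in nats, of an occupancy vector:
#' \eqn{-\sum_{p_i > 0} p_i \ln p_i}. Empty or all-zero input gives 0.
#'
#' @param p occupancy proportions, each in \[0, 1\].
#' @return non-negative entropy in nats.
#' @export
entropy_nats <- function(p) {
  if (!length(p)) return(0)
  if (any(!is.finite(p)) || any(p < 0)) stop("entropy_nats: p must be >= 0")
  if (any(p > 1)) stop("entropy_nats: p must be <= 1")
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log(p))
}
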