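#' Length of a segment inside a disc
#'
#' Internal: exact length of the portion of the segment `p`--`q` lying inside
#' the disc of radius `r` centred at `c`. All coordinates are planar metres.
#'
#' @noRd
.segment_disc_length <- function(px, py, qx, qy, cx, cy, r) {
  dx <- qx - px
  dy <- qy - py
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(0)
  # quadratic |p + t d - c|^2 = r^2 in t
  fx <- px - cx
  fy <- py - cy
  a <- dx^2 + dy^2
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx^2 + fy^2 - r^2
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(0)
  sq <- sqrt(disc)
  t1 <- max((-b - sq) / (2 * a), 0)
  t2 <- min((-b + sq) / (2 * a), 1)
  if (t2 <= t1) return(0)
  (t2 - t1) * len
}

## vectorized over segments: in-disc length for one point against many segments
.segment_disc_length_vec <- function(x1, y1, x2, y2, cx, cy, r) {
  dx <- x2 - x1
  dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  fx <- x1 - cx
  fy <- y1 - cy
  a <- dx^2 + dy^2
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx^2 + fy^2 - r^2
  disc <- b^2 - 4 * a * cc
  out <- numeric(length(x1))
  ok <- disc > 0 & len > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax((-b[ok] - sq) / (2 * a[ok]), 0)
    t2 <- pmin((-b[ok] + sq) / (2 * a[ok]), 1)
    out[ok] <- pmax(t2 - t1, 0) * len[ok]
  }
  out
}

## vectorized over segments: distance from one point to many segments
.point_segment_distance_vec <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  l2 <- dx^2 + dy^2
  t <- ifelse(l2 == 0, 0, ((x - x1) * dx + (y - y1) * dy) / pmax(l2, 1e-300))
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2)
}

#' Distance from a point to a segment
#' @noRd
.point_segment_distance <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  l2 <- dx^2 + dy^2
  if (l2 == 0) return(sqrt((x - x1)^2 + (y - y1)^2))
  t <- ((x - x1) * dx + (y - y1) * dy) / l2
  t <- min(max(t, 0), 1)
  sqrt((x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2)
}

#' Metres of high-traffic road within a circular buffer
#'
#' Sums, over all road segments whose daily vehicle count strictly exceeds
#' `min_vehicles`, the length of the intersection between the segment and the
#' disc of radius `radius` around `point`. Follows the convention that a road
#' qualifies as high-traffic only when its count is strictly above the
#' threshold.
#'
#' @param point numeric length-2 vector `c(x, y)` in metres.
#' @param roads data frame with columns `x1, y1, x2, y2, vehicles_per_day`.
#' @param radius buffer radius in metres (default 150).
#' @param min_vehicles strict lower threshold on vehicles/day (default 10000).
#' @return Length in metres (0 when no qualifying segment intersects).
#' @export
road_length_in_buffer <- function(point, roads, radius = 150, min_vehicles = 10000) {
  if (radius <= 0) stop("`radius` must be positive")
  if (is.null(roads) || nrow(roads) == 0) return(0)
  keep <- roads$vehicles_per_day > min_vehicles
  if (!any(keep)) return(0)
  rr <- roads[keep, , drop = FALSE]
  sum(.segment_disc_length_vec(rr$x1, rr$y1, rr$x2, rr$y2,
                               point[1], point[2], radius))
}

#' Traffic density within a circular buffer
#'
#' For every counted road segment (all segments carried by the scene already
#' satisfy the >4,000 vehicles/day representation rule), multiplies its daily
#' vehicle count by its in-buffer length, sums, and divides by the buffer
#' area \eqn{\pi r^2}. Units: vehicles x m / m^2.
#'
#' @inheritParams road_length_in_buffer
#' @return Traffic density (0 when no segment intersects the buffer).
#' @export
traffic_density_in_buffer <- function(point, roads, radius = 150) {
  if (radius <= 0) stop("`radius` must be positive")
  if (is.null(roads) || nrow(roads) == 0) return(0)
  tot <- sum(roads$vehicles_per_day *
               .segment_disc_length_vec(roads$x1, roads$y1, roads$x2,
                                        roads$y2, point[1], point[2], radius))
  tot / (pi * radius^2)
}

#' Distance to the nearest high-traffic road
#'
#' Minimum Euclidean point-to-segment distance over segments with strictly
#' more than `min_vehicles` vehicles/day. Errors (rather than returning 0)
#' when no segment qualifies, so that "on a road" and "no road exists" stay
#' distinguishable.
#'
#' @inheritParams road_length_in_buffer
#' @return Distance in metres.
#' @export
distance_to_nearest_major_road <- function(point, roads, min_vehicles = 10000) {
  if (is.null(roads) || nrow(roads) == 0 ||
      !any(roads$vehicles_per_day > min_vehicles)) {
    stop("no road segment exceeds ", min_vehicles, " vehicles/day")
  }
  rr <- roads[roads$vehicles_per_day > min_vehicles, , drop = FALSE]
  min(.point_segment_distance_vec(point[1], point[2],
                                  rr$x1, rr$y1, rr$x2, rr$y2))
}

#' Point-in-polygon test (even-odd ray casting)
#' @noRd
.point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((vy[i] > y) != (vy[j] > y)) &&
        (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i])) {
      inside <- !inside
    }
    j <- i
  }
  # count boundary points as inside
  if (!inside) {
    j <- n
    for (i in seq_len(n)) {
      if (.point_segment_distance(x, y, vx[i], vy[i], vx[j], vy[j]) < 1e-9) {
        inside <- TRUE
        break
      }
      j <- i
    }
  }
  inside
}

## all three road statistics for many points in one chunked matrix pass
.road_stats <- function(px, py, roads, radius = 150, min_vehicles = 10000,
                        chunk = 2000) {
  n <- length(px)
  m <- nrow(roads)
  hi <- roads$vehicles_per_day > min_vehicles
  if (!any(hi)) stop("no road segment exceeds ", min_vehicles,
                     " vehicles/day")
  dx <- roads$x2 - roads$x1
  dy <- roads$y2 - roads$y1
  seg_len <- sqrt(dx^2 + dy^2)
  l2 <- pmax(dx^2 + dy^2, 1e-300)
  veh <- roads$vehicles_per_day
  hi_len <- numeric(n); dens <- numeric(n); dist_hi <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    ii <- start:min(start + chunk - 1, n)
    nc <- length(ii)
    PX <- matrix(px[ii], nc, m)
    PY <- matrix(py[ii], nc, m)
    X1 <- matrix(roads$x1, nc, m, byrow = TRUE)
    Y1 <- matrix(roads$y1, nc, m, byrow = TRUE)
    DX <- matrix(dx, nc, m, byrow = TRUE)
    DY <- matrix(dy, nc, m, byrow = TRUE)
    FX <- X1 - PX
    FY <- Y1 - PY
    A <- matrix(l2, nc, m, byrow = TRUE)
    B <- 2 * (FX * DX + FY * DY)
    CC <- FX^2 + FY^2 - radius^2
    DISC <- B^2 - 4 * A * CC
    SQ <- sqrt(pmax(DISC, 0))
    T1 <- pmax((-B - SQ) / (2 * A), 0)
    T2 <- pmin((-B + SQ) / (2 * A), 1)
    LEN_IN <- pmax(T2 - T1, 0) *
      matrix(seg_len, nc, m, byrow = TRUE) * (DISC > 0)
    hi_len[ii] <- rowSums(LEN_IN[, hi, drop = FALSE])
    dens[ii] <- as.numeric(LEN_IN %*% veh) / (pi * radius^2)
    TT <- pmin(pmax(-(FX * DX + FY * DY) / A, 0), 1)
    D2 <- (FX + TT * DX)^2 + (FY + TT * DY)^2
    dist_hi[ii] <- sqrt(do.call(pmin, as.data.frame(D2[, hi, drop = FALSE])))
  }
  list(hi_road_len_150 = hi_len, traffic_density_150 = dens,
       dist_hi_road = dist_hi)
}

#' Canonical predictor schema
#'
#' Fixed ordering of the land-use / traffic predictor columns. The ordering
#' also serves as the tie-break for the stepwise eliminations (ties broken by
#' removing the later predictor).
#'
#' @return Character vector of predictor names.
#' @export
lur_predictors <- function() {
  c("x_coord", "y_coord", "dist_centre", "altitude", "block_size",
    "block_residents", "inv_pop_density", "green_adjacent",
    "hi_road_len_150", "traffic_density_150", "dist_hi_road")
}

#' Default expected coefficient directions
#'
#' Directions enforced by the sign-exclusion rule of the stepwise fit.
#' Traffic-proximity predictors are expected to raise concentrations;
#' distance, altitude, block sparseness and green adjacency to lower them;
#' the raw coordinates are unconstrained (they absorb orography and wind).
#'
#' @return Named character vector over [lur_predictors()], values in
#'   `"positive"`, `"negative"`, `"unconstrained"`.
#' @export
expected_signs <- function() {
  c(x_coord = "unconstrained", y_coord = "unconstrained",
    dist_centre = "negative", altitude = "negative",
    block_size = "negative", block_residents = "positive",
    inv_pop_density = "negative", green_adjacent = "negative",
    hi_road_len_150 = "positive", traffic_density_150 = "positive",
    dist_hi_road = "negative")
}

#' Assemble the predictor table at a set of points
#'
#' Computes one row of land-use and traffic predictors per point: raw
#' coordinates, distance to the city centre, altitude from the scene's
#' altitude field, census-block attributes (size, residents, inverse
#' population density, green adjacency) from the containing block, and the
#' three traffic variables from the road layer (150 m buffer by default).
#'
#' @param points data frame with columns `x`, `y` (metres); an optional `id`
#'   column is carried through.
#' @param city a `city_scene` from [generate_city()] or [read_city_scene()].
#' @param radius buffer radius in metres for the road variables.
#' @return data frame with the columns of [lur_predictors()].
#' @export
assemble_predictor_table <- function(points, city, radius = 150) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  n <- nrow(points)
  blocks <- city$blocks
  # block lookup: containing polygon, ties by smallest block id; regular-grid
  # scenes use direct index arithmetic, general scenes a bounding-box
  # prefilter
  if (!is.null(city$grid)) {
    g <- city$grid$g
    side <- city$grid$side
    ix <- pmin(pmax(ceiling(points$x / side), 1), g)
    iy <- pmin(pmax(ceiling(points$y / side), 1), g)
    outside <- points$x < 0 | points$x > city$extent |
      points$y < 0 | points$y > city$extent
    if (any(outside)) {
      i <- which(outside)[1]
      stop(sprintf("point (%.1f, %.1f) falls in no census block",
                   points$x[i], points$y[i]))
    }
    block_idx <- (iy - 1L) * g + ix
  } else {
    bb <- vapply(city$block_polygons, function(p) {
      c(min(p$x), max(p$x), min(p$y), max(p$y))
    }, numeric(4))
    ord <- order(blocks$id)
    block_idx <- integer(n)
    for (i in seq_len(n)) {
      cand <- which(bb[1, ] <= points$x[i] & points$x[i] <= bb[2, ] &
                      bb[3, ] <= points$y[i] & points$y[i] <= bb[4, ])
      cand <- cand[order(blocks$id[cand])]
      hit <- NA_integer_
      for (b in cand) {
        poly <- city$block_polygons[[b]]
        if (.point_in_polygon(points$x[i], points$y[i], poly$x, poly$y)) {
          hit <- b
          break
        }
      }
      if (is.na(hit)) {
        stop(sprintf("point (%.1f, %.1f) falls in no census block",
                     points$x[i], points$y[i]))
      }
      block_idx[i] <- hit
    }
  }
  bl <- blocks[block_idx, , drop = FALSE]
  rs <- .road_stats(points$x, points$y, city$roads, radius = radius)
  out <- data.frame(
    x_coord = points$x,
    y_coord = points$y,
    dist_centre = sqrt((points$x - city$centre[1])^2 +
                       (points$y - city$centre[2])^2),
    altitude = city$altitude_field(points$x, points$y),
    block_size = bl$area,
    block_residents = bl$residents,
    inv_pop_density = ifelse(bl$residents > 0, bl$area / bl$residents, NA_real_),
    green_adjacent = as.numeric(bl$green_adjacent),
    hi_road_len_150 = rs$hi_road_len_150,
    traffic_density_150 = rs$traffic_density_150,
    dist_hi_road = rs$dist_hi_road
  )
  if (!is.null(points$id)) out <- cbind(id = points$id, out)
  out
}
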