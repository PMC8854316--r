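#' Stimulus geometry configuration
#'
#' Physical layout parameters for the random-dot stimuli. All physical sizes
#' are given in millimetres on the screen; the viewing distance converts them
#' to degrees of visual angle (at the default 57 cm, 1 cm on screen subtends
#' 1 degree). Dot patterns are generated in degrees, origin at the patch
#' centre, y pointing up.
#'
#' @param viewing_distance Viewing distance in cm (default 57, so 1 cm = 1 deg).
#' @param dot_diameter Dot diameter in mm (default 2.5, i.e. 0.25 deg at 57 cm).
#' @param min_spacing Minimum centre-to-centre distance between any two dots,
#'   in mm (default 2.5; two items can never be closer than this).
#' @param connector_length_range Length range (min, max) of the connector
#'   lines joining dot pairs, in mm (default c(10, 15)).
#' @param connector_width Width of the connector lines in mm (default 0.5).
#' @param connect_fraction Fraction of dots cast as connected pairs in
#'   connected patterns (default 0.4).
#' @param field_radius Radius of the circular patch holding the dots, in
#'   degrees of visual angle (default 6).
#' @param clearance_margin Extra clearance, in degrees, required between a
#'   dot edge and a connector edge beyond strict non-overlap (default 0).
#' @param max_attempts Rejection-sampling attempts allowed per element before
#'   placement is declared impossible (default 10000).
#'
#' @return A list of class `geometry_config`. Derived fields `deg_per_mm`,
#'   `dot_radius_deg`, `min_spacing_deg`, `connector_length_deg` and
#'   `connector_width_deg` hold the degree-unit equivalents.
#' @export
geometry_config <- function(viewing_distance = 57,
                            dot_diameter = 2.5,
                            min_spacing = 2.5,
                            connector_length_range = c(10, 15),
                            connector_width = 0.5,
                            connect_fraction = 0.4,
                            field_radius = 6,
                            clearance_margin = 0,
                            max_attempts = 10000) {
  stopifnot(
    viewing_distance > 0, dot_diameter > 0, min_spacing > 0,
    length(connector_length_range) == 2,
    connector_length_range[1] > 0,
    connector_length_range[1] < connector_length_range[2],
    connector_width > 0,
    connect_fraction >= 0, connect_fraction <= 1,
    field_radius > 0, clearance_margin >= 0, max_attempts >= 1
  )
  # 1 cm on screen subtends atan(1/57) rad at 57 cm; the field's convention
  # is the small-angle one: 1 cm = 1 deg exactly at 57 cm.
  deg_per_mm <- 57 / (10 * viewing_distance)
  cfg <- list(
    viewing_distance = viewing_distance,
    dot_diameter = dot_diameter,
    min_spacing = min_spacing,
    connector_length_range = as.numeric(connector_length_range),
    connector_width = connector_width,
    connect_fraction = connect_fraction,
    field_radius = field_radius,
    clearance_margin = clearance_margin,
    max_attempts = as.integer(max_attempts),
    deg_per_mm = deg_per_mm,
    dot_radius_deg = deg_per_mm * dot_diameter / 2,
    min_spacing_deg = deg_per_mm * min_spacing,
    connector_length_deg = deg_per_mm * as.numeric(connector_length_range),
    connector_width_deg = deg_per_mm * connector_width
  )
  class(cfg) <- "geometry_config"
  cfg
}

round_to_even <- function(x) 2 * round(x / 2)

new_dot_pattern <- function(dots, connectors, cfg) {
  p <- list(
    dots = dots,
    connectors = connectors,
    numerosity = nrow(dots),
    cfg = cfg
  )
  class(p) <- "dot_pattern"
  p
}

#' @export
print.dot_pattern <- function(x, ...) {
  cat(sprintf(
    "<dot_pattern> %d dots (%d black / %d white), %d connectors\n",
    x$numerosity, sum(x$dots$colour == "black"),
    sum(x$dots$colour == "white"), nrow(x$connectors)
  ))
  invisible(x)
}

# squared distances from point matrix (n x 2) to a single point
.dist_to_points <- function(xy, x, y) sqrt((xy[, 1] - x)^2 + (xy[, 2] - y)^2)

# distance from points (n x 2) to segment (a, b); vectorized over points
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax
  vy <- by - ay
  L2 <- vx^2 + vy^2
  t <- ((px - ax) * vx + (py - ay) * vy) / L2
  t <- pmin(1, pmax(0, t))
  sqrt((ax + t * vx - px)^2 + (ay + t * vy - py)^2)
}

.orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

.on_segment <- function(ax, ay, bx, by, px, py) {
  # assumes p collinear with a-b
  px >= pmin(ax, bx) & px <= pmax(ax, bx) &
    py >= pmin(ay, by) & py <= pmax(ay, by)
}

#' Do two closed line segments intersect?
#'
#' Orientation-test implementation. Closed segments sharing any point
#' (including a single touching endpoint or a collinear overlap) count as
#' intersecting.
#'
#' @param s1,s2 Segments as length-4 numeric vectors `c(x1, y1, x2, y2)`.
#' @return Logical scalar.
#' @export
segments_intersect <- function(s1, s2) {
  stopifnot(length(s1) == 4, length(s2) == 4)
  if (all(s1[1:2] == s1[3:4]) || all(s2[1:2] == s2[3:4])) {
    stop("segments must have distinct endpoints")
  }
  .segments_intersect_vec(
    s1[1], s1[2], s1[3], s1[4],
    s2[1], s2[2], s2[3], s2[4]
  )
}

# vectorized over the second segment's coordinates
.segments_intersect_vec <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- .orient(cx, cy, dx, dy, ax, ay)
  d2 <- .orient(cx, cy, dx, dy, bx, by)
  d3 <- .orient(ax, ay, bx, by, cx, cy)
  d4 <- .orient(ax, ay, bx, by, dx, dy)
  proper <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  touch <- (d1 == 0 & .on_segment(cx, cy, dx, dy, ax, ay)) |
    (d2 == 0 & .on_segment(cx, cy, dx, dy, bx, by)) |
    (d3 == 0 & .on_segment(ax, ay, bx, by, cx, cy)) |
    (d4 == 0 & .on_segment(ax, ay, bx, by, dx, dy))
  proper | touch
}

.placement_error <- function(what, n, cfg) {
  stop(sprintf(
    paste0(
      "placement failure while casting %s (n = %d): exhausted %d attempts. ",
      "The field (radius %.2f deg) is too crowded for this numerosity at ",
      "min spacing %.3f deg."
    ),
    what, n, cfg$max_attempts, cfg$field_radius, cfg$min_spacing_deg
  ), call. = FALSE)
}

.sample_in_disk <- function(radius) {
  r <- radius * sqrt(stats::runif(1))
  th <- stats::runif(1, 0, 2 * pi)
  c(r * cos(th), r * sin(th))
}

# alternate black/white colours for loose dots so that the final pattern has
# |#black - #white| <= 1 given `pre` already-assigned colours
.balance_colours <- function(n_total, pre) {
  n_loose <- n_total - length(pre)
  n_black_pre <- sum(pre == "black")
  target_black <- floor(n_total / 2)
  # allow the extra dot (odd n) on either colour; prefer the assignment that
  # can be satisfied by the loose dots
  k <- target_black - n_black_pre
  if (k < 0 || k > n_loose) {
    k2 <- (n_total - target_black) - n_black_pre # ceil(n/2) blacks instead
    if (k2 >= 0 && k2 <= n_loose) k <- k2
  }
  if (k < 0 || k > n_loose) {
    stop("cannot balance dot colours under the pair-colouring rule", call. = FALSE)
  }
  sample(c(rep("black", k), rep("white", n_loose - k)))
}

#' Generate a pattern of isolated dots
#'
#' Dots are cast uniformly in a circular patch by rejection sampling, subject
#' only to the minimum centre-to-centre spacing. Half the dots are black and
#' half white (within one), so total luminance does not covary with number.
#'
#' @param n Number of dots (>= 1).
#' @param cfg A [geometry_config()].
#' @return A `dot_pattern`: list with `dots` (data.frame `x`, `y`, `colour`),
#'   `connectors` (two-column integer matrix, here empty), `numerosity`, and
#'   the generating `cfg`.
#' @export
place_isolated <- function(n, cfg = geometry_config()) {
  stopifnot(n >= 1)
  p <- .cast_loose_dots(
    n,
    existing = matrix(numeric(0), 0, 2),
    connectors_xy = matrix(numeric(0), 0, 4),
    cfg = cfg
  )
  dots <- data.frame(x = p[, 1], y = p[, 2], colour = .balance_colours(n, character(0)),
                     stringsAsFactors = FALSE)
  new_dot_pattern(dots, matrix(integer(0), 0, 2,
                               dimnames = list(NULL, c("a", "b"))), cfg)
}

# cast n loose dots avoiding existing dots (matrix n x 2) and connector
# segments (matrix k x 4: ax, ay, bx, by); returns n x 2 matrix
.cast_loose_dots <- function(n, existing, connectors_xy, cfg) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  rmax <- cfg$field_radius - cfg$dot_radius_deg
  clearance <- cfg$dot_radius_deg + cfg$connector_width_deg / 2 + cfg$clearance_margin
  out <- matrix(NA_real_, n, 2)
  all_xy <- existing
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(cfg$max_attempts)) {
      xy <- .sample_in_disk(rmax)
      if (nrow(all_xy) > 0 &&
          min(.dist_to_points(all_xy, xy[1], xy[2])) < cfg$min_spacing_deg) next
      if (nrow(connectors_xy) > 0) {
        d <- point_segment_distance(
          xy[1], xy[2],
          connectors_xy[, 1], connectors_xy[, 2],
          connectors_xy[, 3], connectors_xy[, 4]
        )
        if (min(d) < clearance) next
      }
      ok <- TRUE
      break
    }
    if (!ok) .placement_error("loose dots", n, cfg)
    out[i, ] <- xy
    all_xy <- rbind(all_xy, xy)
  }
  out
}

#' Generate a pattern with a fraction of dots connected in pairs
#'
#' Two-stage casting. Stage 1 places `round_to_even(connect_fraction * n) / 2`
#' dot pairs: the first dot of a pair is cast at random, the second at a
#' uniform-random direction and a uniform-random distance within the connector
#' length range; the pair is joined by a connector line of the pair's colour.
#' Connectors never cross each other and keep clear of all other dots. Stage 2
#' casts the remaining loose dots avoiding both dots and connectors. Pair
#' colours alternate black/white and loose dots restore the global colour
#' balance.
#'
#' @inheritParams place_isolated
#' @return A `dot_pattern`; `connectors` holds one row of dot indices per pair.
#' @export
place_connected <- function(n, cfg = geometry_config()) {
  stopifnot(n >= 2)
  n_paired <- round_to_even(cfg$connect_fraction * n)
  n_pairs <- n_paired / 2
  if (n_pairs == 0) return(place_isolated(n, cfg))
  rmax <- cfg$field_radius - cfg$dot_radius_deg
  clearance <- cfg$dot_radius_deg + cfg$connector_width_deg / 2 + cfg$clearance_margin
  lr <- cfg$connector_length_deg

  dots_xy <- matrix(numeric(0), 0, 2)
  segs <- matrix(numeric(0), 0, 4)
  for (k in seq_len(n_pairs)) {
    ok <- FALSE
    for (attempt in seq_len(cfg$max_attempts)) {
      a <- .sample_in_disk(rmax)
      if (nrow(dots_xy) > 0 &&
          min(.dist_to_points(dots_xy, a[1], a[2])) < cfg$min_spacing_deg) next
      if (nrow(segs) > 0 &&
          min(point_segment_distance(a[1], a[2], segs[, 1], segs[, 2],
                                     segs[, 3], segs[, 4])) < clearance) next
      len <- stats::runif(1, lr[1], lr[2])
      th <- stats::runif(1, 0, 2 * pi)
      b <- a + len * c(cos(th), sin(th))
      if (sqrt(sum(b^2)) > rmax) next
      if (nrow(dots_xy) > 0 &&
          min(.dist_to_points(dots_xy, b[1], b[2])) < cfg$min_spacing_deg) next
      if (sqrt(sum((a - b)^2)) < cfg$min_spacing_deg) next
      if (nrow(segs) > 0) {
        if (min(point_segment_distance(b[1], b[2], segs[, 1], segs[, 2],
                                       segs[, 3], segs[, 4])) < clearance) next
        if (any(.segments_intersect_vec(a[1], a[2], b[1], b[2],
                                        segs[, 1], segs[, 2],
                                        segs[, 3], segs[, 4]))) next
      }
      # the new connector must keep clear of previously placed dots
      if (nrow(dots_xy) > 0 &&
          min(point_segment_distance(dots_xy[, 1], dots_xy[, 2],
                                     a[1], a[2], b[1], b[2])) < clearance) next
      ok <- TRUE
      break
    }
    if (!ok) .placement_error("connected pairs", n, cfg)
    dots_xy <- rbind(dots_xy, a, b)
    segs <- rbind(segs, c(a, b))
  }

  loose_xy <- .cast_loose_dots(n - n_paired, existing = dots_xy,
                               connectors_xy = segs, cfg = cfg)
  pair_cols <- rep(c("black", "white"), length.out = n_pairs)
  pre <- rep(pair_cols, each = 2)
  loose_cols <- .balance_colours(n, pre)
  dots <- data.frame(
    x = c(dots_xy[, 1], loose_xy[, 1]),
    y = c(dots_xy[, 2], loose_xy[, 2]),
    colour = c(pre, loose_cols),
    stringsAsFactors = FALSE
  )
  connectors <- cbind(a = seq(1L, n_paired, by = 2L), b = seq(2L, n_paired, by = 2L))
  new_dot_pattern(dots, connectors, cfg)
}

#' Check every structural invariant of a dot pattern
#'
#' Verifies numerosity bookkeeping, connector indexing, colour balance and
#' the pair-colouring rule, minimum dot spacing, connector length range,
#' non-crossing connectors, and clearance of unconnected dots from connector
#' lines.
#'
#' @param p A `dot_pattern`.
#' @return `TRUE` if all checks pass, otherwise a character vector naming the
#'   violated invariants.
#' @export
validate_pattern <- function(p) {
  cfg <- p$cfg
  bad <- character(0)
  n <- nrow(p$dots)
  if (p$numerosity != n) bad <- c(bad, "numerosity does not match dot count")
  con <- p$connectors
  if (nrow(con) > 0) {
    idx <- as.vector(con)
    if (any(idx < 1 | idx > n)) bad <- c(bad, "connector index out of range")
    if (any(con[, 1] == con[, 2])) bad <- c(bad, "connector joins a dot to itself")
    if (anyDuplicated(idx)) bad <- c(bad, "a dot appears in more than one connector")
    same_col <- p$dots$colour[con[, 1]] == p$dots$colour[con[, 2]]
    if (!all(same_col)) bad <- c(bad, "connected pair dots differ in colour")
  }
  if (abs(sum(p$dots$colour == "black") - sum(p$dots$colour == "white")) > 1) {
    bad <- c(bad, "black/white counts differ by more than 1")
  }
  if (n > 1) {
    d <- stats::dist(p$dots[, c("x", "y")])
    if (min(d) < cfg$min_spacing_deg - 1e-9) {
      bad <- c(bad, "dots closer than min spacing")
    }
  }
  if (nrow(con) > 0) {
    ax <- p$dots$x[con[, 1]]; ay <- p$dots$y[con[, 1]]
    bx <- p$dots$x[con[, 2]]; by <- p$dots$y[con[, 2]]
    len <- sqrt((ax - bx)^2 + (ay - by)^2)
    lr <- cfg$connector_length_deg
    if (any(len < lr[1] - 1e-9 | len > lr[2] + 1e-9)) {
      bad <- c(bad, "connector length outside configured range")
    }
    if (nrow(con) > 1) {
      for (i in seq_len(nrow(con) - 1)) {
        j <- (i + 1):nrow(con)
        if (any(.segments_intersect_vec(ax[i], ay[i], bx[i], by[i],
                                        ax[j], ay[j], bx[j], by[j]))) {
          bad <- c(bad, "connector segments intersect")
          break
        }
      }
    }
    loose <- setdiff(seq_len(n), as.vector(con))
    if (length(loose) > 0) {
      clearance <- cfg$dot_radius_deg + cfg$connector_width_deg / 2
      dmin <- rep(Inf, length(loose))
      for (i in seq_len(nrow(con))) {
        dmin <- pmin(dmin, point_segment_distance(
          p$dots$x[loose], p$dots$y[loose], ax[i], ay[i], bx[i], by[i]
        ))
      }
      if (any(dmin < clearance - 1e-9)) {
        bad <- c(bad, "unconnected dot overlaps a connector line")
      }
    }
  }
  if (length(bad) == 0) TRUE else bad
}

#' Rasterize a dot pattern
#'
#' Renders the pattern as a numeric matrix on a mid-grey background (0.5),
#' with black ink 0 and white ink 1. Dots are hard-edged disks; connectors are
#' hard-edged rectangles (no anti-aliasing). Pixels are classified by their
#' centre coordinates.
#'
#' @param p A `dot_pattern`.
#' @param px_per_deg Resolution in pixels per degree (default 20).
#' @return A square numeric matrix spanning the pattern's field
#'   (2 * field_radius on a side); rows index y from top to bottom.
#' @export
render_pattern <- function(p, px_per_deg = 20) {
  stopifnot(px_per_deg > 0)
  cfg <- p$cfg
  half <- cfg$field_radius
  npx <- ceiling(2 * half * px_per_deg)
  cx <- seq(-half, half, length.out = npx)
  img <- matrix(0.5, npx, npx)
  px <- matrix(cx, npx, npx, byrow = TRUE)          # x increases along columns
  py <- matrix(rev(cx), npx, npx)                    # y decreases down rows
  val <- c(black = 0, white = 1)
  con <- p$connectors
  if (nrow(con) > 0) {
    for (i in seq_len(nrow(con))) {
      a <- con[i, 1]; b <- con[i, 2]
      d <- point_segment_distance(px, py, p$dots$x[a], p$dots$y[a],
                                  p$dots$x[b], p$dots$y[b])
      img[d <= cfg$connector_width_deg / 2] <- val[[p$dots$colour[a]]]
    }
  }
  for (i in seq_len(nrow(p$dots))) {
    d2 <- (px - p$dots$x[i])^2 + (py - p$dots$y[i])^2
    img[d2 <= cfg$dot_radius_deg^2] <- val[[p$dots$colour[i]]]
  }
  img
}

# tiny FNV-1a hash of a character scalar, for config fingerprints in
# manifests; 32-bit arithmetic done in doubles (exact below 2^53)
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x01"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (lo16 * p + ((hi16 * p) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer((h - h %% 65536) / 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

config_hash <- function(cfg) {
  fnv1a_hash(paste(names(unlist(cfg)), format(unlist(cfg), digits = 15),
                   sep = "=", collapse = ";"))
}

#' Serialize a dot pattern to JSON
#'
#' @param p A `dot_pattern`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to file).
#' @export
pattern_to_json <- function(p, path = NULL) {
  obj <- list(
    numerosity = p$numerosity,
    dots = p$dots,
    connectors = unname(apply(p$connectors, 1, function(r) as.integer(r),
                              simplify = FALSE)),
    config = p$cfg[setdiff(names(p$cfg), c(
      "deg_per_mm", "dot_radius_deg", "min_spacing_deg",
      "connector_length_deg", "connector_width_deg"
    ))],
    config_hash = config_hash(p$cfg)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a dot pattern back from JSON
#'
#' @param path File path or JSON string produced by [pattern_to_json()].
#' @return A `dot_pattern`.
#' @export
pattern_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  cfg <- do.call(geometry_config, obj$config[setdiff(names(obj$config), "class")])
  con <- if (length(obj$connectors) == 0) {
    matrix(integer(0), 0, 2)
  } else if (is.matrix(obj$connectors)) {
    matrix(as.integer(obj$connectors), nrow = nrow(obj$connectors))
  } else {
    do.call(rbind, lapply(obj$connectors, as.integer))
  }
  colnames(con) <- c("a", "b")
  new_dot_pattern(obj$dots, con, cfg)
}
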