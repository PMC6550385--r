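#' Rectilinear regions built from grid squares
#'
#' Aggregates delineated on a quadrat grid are, by construction, unions of
#' axis-aligned squares. A `square_region` stores the member squares
#' (row/col indices on the grid) together with the grid geometry (origin
#' and square size), which makes union, intersection, and area exact
#' integer set arithmetic. Polygon rings (outer boundaries and holes) are
#' derived on demand by cancelling shared edges and chaining the remainder
#' into closed loops.
#'
#' @name square_region
NULL

square_region <- function(rows, cols, origin, square_size) {
  stopifnot(length(rows) == length(cols))
  keep <- !duplicated(cbind(rows, cols))
  structure(list(rows = as.integer(rows[keep]), cols = as.integer(cols[keep]),
                 origin = as.numeric(origin), square_size = as.numeric(square_size)),
            class = "square_region")
}

#' Number of member squares of a region
#' @param region A `square_region`.
#' @return Integer count.
#' @export
n_squares <- function(region) length(region$rows)

#' Area of a square-set region
#'
#' Exact by construction: number of member squares times the squared
#' square size.
#'
#' @param region A `square_region`.
#' @return Area in squared coordinate units.
#' @export
region_area <- function(region) n_squares(region) * region$square_size^2

square_key <- function(rows, cols) paste(rows, cols, sep = ":")

check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$origin, b$origin)) ||
      !isTRUE(all.equal(a$square_size, b$square_size)))
    stop("regions live on different grids", call. = FALSE)
}

#' Intersection of two square-set regions on the same grid
#' @param a,b `square_region`s sharing one grid.
#' @return The `square_region` of shared squares (possibly empty).
#' @export
region_intersect <- function(a, b) {
  check_same_grid(a, b)
  keep <- square_key(a$rows, a$cols) %in% square_key(b$rows, b$cols)
  square_region(a$rows[keep], a$cols[keep], a$origin, a$square_size)
}

#' Union of two square-set regions on the same grid
#' @param a,b `square_region`s sharing one grid.
#' @return The `square_region` of all member squares of either.
#' @export
region_union <- function(a, b) {
  check_same_grid(a, b)
  square_region(c(a$rows, b$rows), c(a$cols, b$cols), a$origin, a$square_size)
}

#' @export
print.square_region <- function(x, ...) {
  cat(sprintf("<square_region> %d square(s) of %.6g, area %.6g\n",
              n_squares(x), x$square_size, region_area(x)))
  invisible(x)
}

#' Boundary-inclusive point-in-region test
#'
#' A point is inside the region iff any grid square it touches (including
#' points exactly on a square edge or corner) is a member. This makes the
#' inside/outside split of a cell table an exhaustive partition.
#'
#' @param x,y Numeric coordinate vectors.
#' @param region A `square_region`.
#' @param tol Absolute tolerance for "exactly on a gridline".
#' @return Logical vector.
#' @export
points_in_region <- function(x, y, region, tol = 1e-9) {
  if (!n_squares(region)) return(rep(FALSE, length(x)))
  s <- region$square_size
  x0 <- region$origin[1]; y0 <- region$origin[2]
  member <- square_key(region$rows, region$cols)
  fx <- (x - x0) / s
  fy <- (y - y0) / s
  cand_cols <- function(f) {
    j <- floor(f + tol)
    on_line <- abs(f - round(f)) <= tol
    list(lo = ifelse(on_line, round(f) - 1, j), hi = ifelse(on_line, round(f), j))
  }
  cx <- cand_cols(fx); cy <- cand_cols(fy)
  inside <- logical(length(x))
  for (dc in c("lo", "hi")) for (dr in c("lo", "hi")) {
    inside <- inside | square_key(cy[[dr]], cx[[dc]]) %in% member
  }
  inside
}

# --- polygon ring extraction ------------------------------------------------

# Directed boundary edges with the interior on the left; edges shared by two
# member squares cancel. Chaining the survivors yields closed rings; at a
# checkerboard corner the sharpest right turn is taken, so diagonally
# touching squares yield separate (multi-part) rings rather than a
# self-touching one.
region_rings <- function(region) {
  if (!n_squares(region)) return(list())
  s <- region$square_size
  x0 <- region$origin[1]; y0 <- region$origin[2]
  member <- square_key(region$rows, region$cols)
  has <- function(r, c) square_key(r, c) %in% member

  # vertices keyed by integer lattice coordinates (col, row)
  from <- character(0); to <- character(0)
  fx <- integer(0); fy <- integer(0); tx <- integer(0); ty <- integer(0)
  add_edge <- function(x1, y1, x2, y2) {
    from <<- c(from, paste(x1, y1)); to <<- c(to, paste(x2, y2))
    fx <<- c(fx, x1); fy <<- c(fy, y1); tx <<- c(tx, x2); ty <<- c(ty, y2)
  }
  for (k in seq_along(region$rows)) {
    r <- region$rows[k]; c <- region$cols[k]
    if (!has(r - 1L, c)) add_edge(c,     r,     c + 1L, r)       # bottom, ->
    if (!has(r, c + 1L)) add_edge(c + 1L, r,    c + 1L, r + 1L)  # right, ^
    if (!has(r + 1L, c)) add_edge(c + 1L, r + 1L, c,    r + 1L)  # top, <-
    if (!has(r, c - 1L)) add_edge(c,     r + 1L, c,     r)       # left, v
  }

  used <- rep(FALSE, length(from))
  out_idx <- split(seq_along(from), from)
  rings <- list()
  for (start in seq_along(from)) {
    if (used[start]) next
    path_x <- fx[start]; path_y <- fy[start]
    cur <- start
    repeat {
      used[cur] <- TRUE
      path_x <- c(path_x, tx[cur]); path_y <- c(path_y, ty[cur])
      if (tx[cur] == fx[start] && ty[cur] == fy[start]) break
      nxt <- out_idx[[to[cur]]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) stop("internal error: open boundary chain")
      if (length(nxt) > 1L) {
        # checkerboard vertex: take the sharpest left turn relative to the
        # incoming direction (largest cross product), which keeps the chain
        # on the current square so diagonally touching squares come out as
        # separate rings instead of one self-touching ring
        din <- c(tx[cur] - fx[cur], ty[cur] - fy[cur])
        cross <- vapply(nxt, function(e) {
          dout <- c(tx[e] - fx[e], ty[e] - fy[e])
          din[1] * dout[2] - din[2] * dout[1]
        }, numeric(1))
        nxt <- nxt[which.max(cross)]
      }
      cur <- nxt
    }
    rings[[length(rings) + 1L]] <- cbind(x = x0 + path_x * s, y = y0 + path_y * s)
  }
  rings
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# even-odd point-in-ring for hole assignment (test point strictly inside)
point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring) - 1L
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py) &&
        px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' Polygon representation of a square-set region
#'
#' Extracts boundary rings and groups them into polygon parts: each
#' counter-clockwise ring is an outer boundary, each clockwise ring a hole
#' assigned to the outer ring that contains it.
#'
#' @param region A `square_region`.
#' @return List of parts; each part is a list of rings (first outer, rest
#'   holes), each ring an `n x 2` closed coordinate matrix.
#' @export
region_polygons <- function(region) {
  rings <- region_rings(region)
  if (!length(rings)) return(list())
  areas <- vapply(rings, ring_signed_area, numeric(1))
  outers <- which(areas > 0)
  holes <- which(areas < 0)
  parts <- lapply(outers, function(i) list(rings[[i]]))
  if (length(holes)) {
    for (h in holes) {
      # representative interior point of the hole ring: just inside its
      # first edge midpoint is fragile; use ring vertex centroid, which for
      # rectilinear hole rings of grid squares lies inside the hole
      cx <- mean(rings[[h]][-1, 1]); cy <- mean(rings[[h]][-1, 2])
      owner <- which(vapply(seq_along(outers), function(k)
        point_in_ring(cx, cy, rings[[outers[k]]]), logical(1)))
      if (length(owner)) {
        k <- owner[1]
        parts[[k]] <- c(parts[[k]], list(rings[[h]]))
      }
    }
  }
  parts
}

fmt_num <- function(v) formatC(v, format = "g", digits = 12)

#' Export a region as a WKT string
#'
#' `POLYGON`/`MULTIPOLYGON` (or `POLYGON EMPTY`) in the region's
#' coordinate units.
#'
#' @param region A `square_region`.
#' @return A WKT character scalar.
#' @export
region_to_wkt <- function(region) {
  parts <- region_polygons(region)
  if (!length(parts)) return("POLYGON EMPTY")
  fmt_ring <- function(ring)
    paste0("(", paste(paste(fmt_num(ring[, 1]), fmt_num(ring[, 2])),
                      collapse = ", "), ")")
  fmt_part <- function(part)
    paste0("(", paste(vapply(part, fmt_ring, character(1)), collapse = ", "), ")")
  if (length(parts) == 1L)
    paste0("POLYGON ", fmt_part(parts[[1]]))
  else
    paste0("MULTIPOLYGON (", paste(vapply(parts, fmt_part, character(1)),
                                   collapse = ", "), ")")
}

#' Export regions as GeoJSON
#'
#' Writes a `FeatureCollection` of `MultiPolygon` features (coordinates in
#' microns) with one feature per named region.
#'
#' @param regions Named list of `square_region`s.
#' @param path Output file path.
#' @param properties Optional list (parallel to `regions`) of extra
#'   per-feature properties.
#' @return `path`, invisibly.
#' @export
regions_to_geojson <- function(regions, path, properties = NULL) {
  features <- lapply(seq_along(regions), function(i) {
    region <- regions[[i]]
    parts <- region_polygons(region)
    coords <- lapply(parts, function(part)
      lapply(part, function(ring)
        lapply(seq_len(nrow(ring)), function(j) c(ring[j, 1], ring[j, 2]))))
    props <- c(list(name = names(regions)[i],
                    n_squares = n_squares(region),
                    area_um2 = region_area(region)),
               if (!is.null(properties)) properties[[i]])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
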