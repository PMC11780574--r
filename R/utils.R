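# Small geometry and arithmetic helpers shared across modules.

#' Signed polygon area (shoelace formula)
#'
#' @param xy two-column matrix of vertex coordinates (open ring: the last
#'   vertex is implicitly joined back to the first).
#' @return signed area; positive for counter-clockwise rings in a y-up frame.
#' @keywords internal
shoelace_area <- function(xy) {
  if (is.null(xy) || nrow(xy) < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Chain a set of undirected segments into closed rings
#'
#' Segments are matched at their endpoints after rounding coordinates to
#' `digits` decimals (nm scale: 1e-6 nm default tolerance). Returns a list of
#' vertex matrices, one per closed ring; open chains are dropped.
#' @keywords internal
chain_segments <- function(seg, digits = 6) {
  # seg: matrix with columns x1, y1, x2, y2
  if (nrow(seg) == 0) return(list())
  key <- function(x, y) paste(round(x, digits), round(y, digits), sep = ",")
  k1 <- key(seg[, 1], seg[, 2])
  k2 <- key(seg[, 3], seg[, 4])
  verts <- unique(c(k1, k2))
  vid <- stats::setNames(seq_along(verts), verts)
  e1 <- vid[k1]; e2 <- vid[k2]
  adj <- vector("list", length(verts))
  for (i in seq_along(e1)) {
    adj[[e1[i]]] <- c(adj[[e1[i]]], i)
    adj[[e2[i]]] <- c(adj[[e2[i]]], i)
  }
  coords <- do.call(rbind, strsplit(verts, ","))
  coords <- matrix(as.numeric(coords), ncol = 2)
  used <- logical(length(e1))
  rings <- list()
  for (start_edge in seq_along(e1)) {
    if (used[start_edge]) next
    path <- e1[start_edge]
    cur <- e2[start_edge]
    used[start_edge] <- TRUE
    closed <- FALSE
    repeat {
      path <- c(path, cur)
      nxt <- adj[[cur]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      e <- nxt[1]
      used[e] <- TRUE
      cur <- if (e1[e] == cur) e2[e] else e1[e]
      if (cur == path[1]) { closed <- TRUE; break }
    }
    if (closed && length(path) >= 3) rings[[length(rings) + 1]] <- coords[path, , drop = FALSE]
  }
  rings
}

#' Rescale a numeric vector to [0, 1] by its maximum absolute value
#' @keywords internal
rescale_unit <- function(v) {
  m <- max(abs(v))
  if (m == 0) rep(1, length(v)) else abs(v) / m
}

#' Convex hull area of a point set
#' @keywords internal
hull_area <- function(xy) {
  if (nrow(unique(xy)) < 3) return(0)
  h <- grDevices::chull(xy)
  abs(shoelace_area(xy[h, , drop = FALSE]))
}

#' Polygon to WKT POLYGON string
#' @keywords internal
polygon_wkt <- function(xy) {
  if (is.null(xy) || nrow(xy) < 3) return(NA_character_)
  ring <- rbind(xy, xy[1, ])
  paste0("POLYGON ((", paste(sprintf("%.3f %.3f", ring[, 1], ring[, 2]),
                             collapse = ", "), "))")
}

#' Standard error of the mean
#' @keywords internal
sem <- function(x) stats::sd(x) / sqrt(length(x))

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    abort(paste0("`", name, "` must be a positive finite scalar"))
  invisible(x)
}
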