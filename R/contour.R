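#' Pixel path and outline profile containers
#'
#' A `pixel_path` is an ordered set of `(col, row)` pixels (stored as an
#' `n x 2` matrix) extracted from an edge map; an `outline_profile` is the
#' single-valued wrist outline, one row value per contiguous column.
#'
#' @param coords `n x 2` matrix with columns `col`, `row`.
#' @param closed whether the path closes on itself.
#' @return `pixel_path()` returns an object of class `pixel_path`.
#' @export
pixel_path <- function(coords, closed = FALSE) {
  coords <- matrix(as.numeric(coords), ncol = 2, dimnames = list(NULL, c("col", "row")))
  structure(list(coords = coords, closed = closed), class = "pixel_path")
}

#' @export
print.pixel_path <- function(x, ...) {
  cat(sprintf("<pixel_path> %d px, cols %d..%d%s\n",
              nrow(x$coords), min(x$coords[, 1]), max(x$coords[, 1]),
              if (isTRUE(attr(x, "border_to_border"))) ", border-to-border" else ""))
  invisible(x)
}

#' @rdname pixel_path
#' @param columns strictly increasing, contiguous column indices.
#' @param rows one (possibly interpolated, hence non-integer) row value per
#'   column.
#' @export
outline_profile <- function(columns, rows) {
  if (length(columns) != length(rows)) {
    guan_abort("guan_validation_error", "columns and rows differ in length")
  }
  if (length(columns) > 1 && any(diff(columns) != 1)) {
    guan_abort("guan_validation_error", "outline columns must be contiguous and increasing")
  }
  structure(
    list(columns = as.integer(columns), rows = as.numeric(rows),
         col_start = columns[1], col_end = columns[length(columns)]),
    class = "outline_profile"
  )
}

#' @export
print.outline_profile <- function(x, ...) {
  cat(sprintf("<outline_profile> cols %d..%d, row range [%.1f, %.1f]\n",
              x$col_start, x$col_end, min(x$rows), max(x$rows)))
  invisible(x)
}

# Linear pixel indices of TRUE cells, and (col,row) coordinate helpers.
mask_coords <- function(mask) {
  idx <- which(mask)
  H <- nrow(mask)
  cbind(col = ((idx - 1L) %/% H) + 1L, row = ((idx - 1L) %% H) + 1L)
}

# 8-connected component labels of a logical mask, via an igraph pixel
# adjacency graph. Returns list(coords, membership, sizes).
mask_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  np <- length(idx)
  lookup <- integer(H * W)
  lookup[idx] <- seq_len(np)
  row <- ((idx - 1L) %% H) + 1L
  col <- ((idx - 1L) %/% H) + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + off[1L]; c2 <- col + off[2L]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- integer(np); nb[ok] <- lookup[(c2[ok] - 1L) * H + r2[ok]]
    sel <- ok & nb > 0L
    if (any(sel)) edges <- rbind(edges, cbind(which(sel), nb[sel]))
  }
  g <- igraph::make_empty_graph(n = np, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  list(coords = cbind(col = col, row = row),
       membership = comp$membership, sizes = comp$csize)
}

touches_both_borders <- function(coords, W) {
  any(coords[, 1L] == 1L) && any(coords[, 1L] == W)
}

#' Maximum connected domain of an edge map
#'
#' Returns the 8-connected component of the edge image with the most pixels,
#' the candidate wrist outline. Ties on size are broken in favour of the
#' component with the widest column extent, then the topmost one. The
#' returned path carries attribute `border_to_border`, `TRUE` when the
#' component reaches both lateral image borders (in which case it is taken
#' as the complete wrist edge).
#'
#' @param edges an `edge_map` from [detect_edges()].
#' @return A [pixel_path] with coords ordered by column then row.
#' @export
max_connected_domain <- function(edges) {
  mask <- edges$mask
  if (!any(mask)) guan_abort("guan_no_edge_error", "edge map is empty")
  cp <- mask_components(mask)
  best <- which(cp$sizes == max(cp$sizes))
  if (length(best) > 1L) {
    widths <- vapply(best, function(k) {
      cc <- cp$coords[cp$membership == k, , drop = FALSE]
      diff(range(cc[, 1L]))
    }, numeric(1))
    best <- best[widths == max(widths)]
    if (length(best) > 1L) {
      tops <- vapply(best, function(k) min(cp$coords[cp$membership == k, 2L]), numeric(1))
      best <- best[which.min(tops)]
    } else {
      best <- best[1L]
    }
  }
  coords <- cp$coords[cp$membership == best[1L], , drop = FALSE]
  coords <- coords[order(coords[, 1L], coords[, 2L]), , drop = FALSE]
  p <- pixel_path(coords)
  attr(p, "border_to_border") <- touches_both_borders(coords, ncol(mask))
  p
}

# All pixels of the straight digital line between two points (endpoints
# excluded), Bresenham-style.
bresenham_between <- function(p, q) {
  dc <- q[1L] - p[1L]; dr <- q[2L] - p[2L]
  n <- max(abs(dc), abs(dr))
  if (n <= 1L) return(matrix(numeric(0), 0, 2))
  tt <- seq_len(n - 1L) / n
  cbind(round(p[1L] + tt * dc), round(p[2L] + tt * dr))
}

#' Connect breakpoints of the wrist-edge component
#'
#' Iteratively completes a broken wrist edge: starting from the component's
#' leftmost endpoint, other edge fragments are searched for within a range of
#' 2 pixels in the leftward/vertical directions (up, left-up, left,
#' left-down, down - the left half of a 5x5 neighbourhood); the nearest
#' fragment pixel found is bridged by straight-line pixel interpolation and
#' its whole component merged, until the left image border is reached. The
#' same procedure runs from the rightmost endpoint with mirrored directions
#' until the right border. A component already spanning both borders is
#' returned unchanged.
#'
#' @param edges the full `edge_map` (provides the other fragments).
#' @param component a [pixel_path], normally from [max_connected_domain()].
#' @param search_range Chebyshev search distance in pixels.
#' @return The merged border-to-border [pixel_path].
#' @export
connect_breakpoints <- function(edges, component, search_range = 2L) {
  mask <- edges$mask
  H <- nrow(mask); W <- ncol(mask)
  coords <- component$coords
  if (touches_both_borders(coords, W)) {
    attr(component, "border_to_border") <- TRUE
    return(component)
  }
  cp <- mask_components(mask)
  key <- function(cc) (cc[, 1L] - 1L) * H + cc[, 2L]
  member_of <- integer(H * W)
  member_of[key(cp$coords)] <- cp$membership
  in_path <- logical(H * W)
  in_path[key(coords)] <- TRUE
  merged <- integer(0)  # components already absorbed
  start_comp <- member_of[key(coords)[1L]]
  merged <- start_comp

  offs_left <- as.matrix(expand.grid(dc = -search_range:0, dr = -search_range:search_range))
  offs_left <- offs_left[!(offs_left[, 1L] == 0L & offs_left[, 2L] == 0L), ]
  offs_right <- offs_left; offs_right[, 1L] <- -offs_right[, 1L]

  extend <- function(offs, target_col, pick_endpoint) {
    repeat {
      cur <- mask_coords(matrix(in_path, H, W))
      ep <- pick_endpoint(cur)
      if (ep[1L] == target_col) return(invisible(NULL))
      cand_c <- ep[1L] + offs[, 1L]; cand_r <- ep[2L] + offs[, 2L]
      ok <- cand_c >= 1L & cand_c <= W & cand_r >= 1L & cand_r <= H
      cand_c <- cand_c[ok]; cand_r <- cand_r[ok]
      k <- (cand_c - 1L) * H + cand_r
      hit <- mask[k] & !in_path[k]
      if (!any(hit)) {
        guan_abort("guan_connection_error",
                   sprintf("no edge fragment within range of (col %d, row %d)", ep[1L], ep[2L]),
                   data = list(stuck = ep))
      }
      d2 <- (cand_c[hit] - ep[1L])^2 + (cand_r[hit] - ep[2L])^2
      pick <- order(d2, cand_c[hit], cand_r[hit])[1L]
      q <- c(cand_c[hit][pick], cand_r[hit][pick])
      bridge <- bresenham_between(ep, q)
      if (nrow(bridge) > 0) in_path[(bridge[, 1L] - 1L) * H + bridge[, 2L]] <<- TRUE
      m <- member_of[(q[1L] - 1L) * H + q[2L]]
      add <- cp$coords[cp$membership == m, , drop = FALSE]
      in_path[key(add)] <<- TRUE
      merged <<- c(merged, m)
    }
  }

  extend(offs_left, 1L, function(cur) {
    cur[order(cur[, 1L], cur[, 2L]), , drop = FALSE][1L, ]
  })
  extend(offs_right, W, function(cur) {
    cur[order(-cur[, 1L], cur[, 2L]), , drop = FALSE][1L, ]
  })
  out <- mask_coords(matrix(in_path, H, W))
  out <- out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  p <- pixel_path(out)
  attr(p, "border_to_border") <- TRUE
  p
}

#' Prune short side branches from a connected path
#'
#' Identifies junction pixels (three or more 8-neighbours within the path)
#' and deletes side branches shorter than `max_spur_len` pixels, walking in
#' from each loose end; pruning repeats until stable, mirroring a cutting
#' operator applied along the outline's long axis. If the path reached both
#' lateral borders before pruning but not after, a pruning error is raised.
#'
#' @param path a [pixel_path].
#' @param max_spur_len branches strictly shorter than this many pixels are
#'   removed.
#' @return The pruned [pixel_path].
#' @export
cut_branches <- function(path, max_spur_len = 15L) {
  coords <- path$coords
  W <- max(coords[, 1L])
  had_b2b <- touches_both_borders(coords, W) || isTRUE(attr(path, "border_to_border"))
  stride <- max(coords[, 2L]) + 3L
  n <- nrow(coords)
  alive <- rep(TRUE, n)
  key <- coords[, 1L] * stride + coords[, 2L]
  offs <- as.matrix(expand.grid(dc = -1:1, dr = -1:1))
  offs <- offs[!(offs[, 1L] == 0L & offs[, 2L] == 0L), , drop = FALSE]
  nbrs <- vapply(seq_len(nrow(offs)), function(k) {
    match((coords[, 1L] + offs[k, 1L]) * stride + (coords[, 2L] + offs[k, 2L]), key)
  }, integer(n))
  neighbours <- function(i) {
    nb <- nbrs[i, ]
    nb <- nb[!is.na(nb)]
    nb[alive[nb]]
  }
  adjacent <- function(i, j) {
    abs(coords[i, 1L] - coords[j, 1L]) <= 1 && abs(coords[i, 2L] - coords[j, 2L]) <= 1
  }
  # are the pixels in `set` still mutually connected if `cur` is removed?
  locally_connected <- function(set) {
    m <- length(set)
    if (m <= 1L) return(TRUE)
    seen <- logical(m); seen[1L] <- TRUE
    queue <- 1L
    while (length(queue) > 0) {
      i <- queue[1L]; queue <- queue[-1L]
      for (j in seq_len(m)) {
        if (!seen[j] && adjacent(set[i], set[j])) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    all(seen)
  }
  repeat {
    av <- c(alive, FALSE)
    deg <- rowSums(matrix(av[ifelse(is.na(nbrs), n + 1L, nbrs)], n, ncol(nbrs)))
    deg[!alive] <- 0L
    ends <- which(alive & deg == 1L)
    if (length(ends) == 0L) break
    removed_any <- FALSE
    for (e in ends) {
      if (!alive[e]) next
      walk <- integer(0)
      prev <- 0L; cur <- e
      repeat {
        nxt <- setdiff(neighbours(cur), c(prev, walk))
        if (length(nxt) == 0L) break  # free chain end: not a spur
        if (length(nxt) >= 2L) {
          # cur attaches to a branching structure: the walk (and cur, when
          # its removal keeps the remaining neighbourhood connected) is a
          # candidate spur
          spur <- if (locally_connected(nxt)) c(walk, cur) else walk
          touches_border <- had_b2b && any(coords[spur, 1L] %in% c(1L, W))
          if (length(spur) > 0L && length(spur) < max_spur_len && !touches_border) {
            alive[spur] <- FALSE
            removed_any <- TRUE
          }
          break
        }
        walk <- c(walk, cur)
        if (length(walk) >= max_spur_len) break
        prev <- cur; cur <- nxt
      }
    }
    if (!removed_any) break
  }
  out <- coords[alive, , drop = FALSE]
  if (had_b2b && !touches_both_borders(out, W)) {
    guan_abort("guan_pruning_error", "pruning disconnected the border-to-border path")
  }
  p <- pixel_path(out[order(out[, 1L], out[, 2L]), , drop = FALSE])
  attr(p, "border_to_border") <- touches_both_borders(out, W)
  p
}

#' Reduce a pixel path to a single-valued outline
#'
#' Collapses the path to one row value per column: the minimum row for
#' `side = "upper"` (the radial side lying on top of the image) or the
#' maximum row for `side = "lower"`. Column gaps of at most `max_gap`
#' columns are filled by linear interpolation; larger gaps raise an outline
#' error.
#'
#' @param path a [pixel_path].
#' @param side `"upper"` or `"lower"`.
#' @param max_gap largest interpolatable run of missing columns.
#' @return An [outline_profile] spanning the path's column range.
#' @export
to_outline <- function(path, side = c("upper", "lower"), max_gap = 2L) {
  side <- match.arg(side)
  coords <- path$coords
  agg <- if (side == "upper") min else max
  rows_by_col <- tapply(coords[, 2L], coords[, 1L], agg)
  cols_present <- as.integer(names(rows_by_col))
  full <- seq(min(cols_present), max(cols_present))
  missing <- setdiff(full, cols_present)
  if (length(missing) > 0) {
    runs <- split(missing, cumsum(c(1L, diff(missing) != 1L)))
    if (max(lengths(runs)) > max_gap) {
      guan_abort("guan_outline_error",
                 sprintf("outline gap of %d columns exceeds %d", max(lengths(runs)), max_gap))
    }
  }
  rows <- stats::approx(cols_present, as.numeric(rows_by_col), xout = full)$y
  outline_profile(full, rows)
}

# Wrist-edge completion with fallback: if the largest component cannot be
# completed to both lateral borders (e.g. it is an interior structure such
# as the artery ridge with nothing to bridge to), try the next-largest
# components in turn. The successful path records its size rank in
# attribute "component_rank".
connect_wrist_edge <- function(edges, component, search_range = 2L, max_candidates = 5L) {
  first_err <- NULL
  res <- tryCatch(connect_breakpoints(edges, component, search_range),
                  guan_error = function(e) { first_err <<- e; NULL })
  if (!is.null(res)) { attr(res, "component_rank") <- 1L; return(res) }
  cp <- mask_components(edges$mask)
  ord <- order(cp$sizes, decreasing = TRUE)
  for (rank in 2:min(max_candidates, length(ord))) {
    cc <- cp$coords[cp$membership == ord[rank], , drop = FALSE]
    cand <- pixel_path(cc[order(cc[, 1L], cc[, 2L]), , drop = FALSE])
    res <- tryCatch(connect_breakpoints(edges, cand, search_range),
                    guan_error = function(e) NULL)
    if (!is.null(res)) { attr(res, "component_rank") <- rank; return(res) }
  }
  stop(first_err)
}
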