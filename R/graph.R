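#' Construct a county contiguity graph
#'
#' An undirected simple graph over county identifiers. Nodes are opaque
#' strings (typically FIPS codes or county names); edges join counties that
#' share a boundary. The graph may be disconnected (islands, independent
#' cities separated by water).
#'
#' @param nodes character vector of county identifiers.
#' @param edges two-column matrix or data frame of county id pairs, or
#'   `NULL` for an edgeless graph. Symmetric duplicates are collapsed.
#' @param centroids optional data frame with columns `county`, `lon`, `lat`
#'   (degrees), used by [circular_scan()].
#' @return an object of class `county_graph` with elements `nodes` (sorted
#'   unique ids), `edges` (two-column character matrix, each row ordered),
#'   `adj` (adjacency list of integer node indices) and `centroids`.
#' @examples
#' g <- county_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' g
#' @export
county_graph <- function(nodes, edges = NULL, centroids = NULL) {
  nodes <- csort(unique(as.character(nodes)))
  if (length(nodes) == 0L) stopf("a county graph needs at least one node")
  if (anyNA(nodes) || any(nodes == "")) stopf("county identifiers must be non-missing, non-empty strings")

  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stopf("edges must have exactly two columns")
    storage.mode(em) <- "character"
    if (any(em[, 1L] == em[, 2L])) {
      bad <- em[em[, 1L] == em[, 2L], 1L][1L]
      stopf("self-loop on county '%s' is not allowed", bad)
    }
    unknown <- setdiff(c(em), nodes)
    if (length(unknown)) {
      stopf("edge endpoint(s) not in node roster: %s", paste(csort(unknown), collapse = ", "))
    }
    # order each pair, drop duplicates (covers symmetric duplicates)
    a <- pmin(em[, 1L], em[, 2L])
    b <- pmax(em[, 1L], em[, 2L])
    key <- paste(a, b, sep = "\r")
    keep <- !duplicated(key)
    em <- cbind(a[keep], b[keep])
    o <- order(em[, 1L], em[, 2L], method = "radix")
    em <- em[o, , drop = FALSE]
  }

  adj <- rep(list(integer()), length(nodes))
  if (nrow(em)) {
    ia <- match(em[, 1L], nodes)
    ib <- match(em[, 2L], nodes)
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
    adj <- lapply(adj, sort)
  }

  cen <- NULL
  if (!is.null(centroids)) {
    centroids <- as.data.frame(centroids)
    need <- c("county", "lon", "lat")
    if (!all(need %in% names(centroids))) {
      stopf("centroids must have columns: %s", paste(need, collapse = ", "))
    }
    m <- match(nodes, as.character(centroids$county))
    cen <- cbind(lon = as.numeric(centroids$lon)[m], lat = as.numeric(centroids$lat)[m])
    rownames(cen) <- nodes
  }

  structure(list(nodes = nodes, edges = em, adj = adj, centroids = cen),
            class = "county_graph")
}

#' @export
print.county_graph <- function(x, ...) {
  cat(sprintf("<county_graph> %d nodes, %d edges, centroids: %s\n",
              length(x$nodes), nrow(x$edges),
              if (is.null(x$centroids)) "no" else "yes"))
  invisible(x)
}

# Connected-component labels (integer per node), index-based BFS.
graph_components <- function(graph) {
  n <- length(graph$nodes)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      for (w in graph$adj[[u]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# TRUE iff the county set `members` induces a connected subgraph.
is_connected_set <- function(graph, members) {
  idx <- match(members, graph$nodes)
  if (anyNA(idx)) stopf("unknown county id(s): %s",
                        paste(members[is.na(idx)], collapse = ", "))
  k <- length(idx)
  if (k <= 1L) return(k == 1L)
  inset <- logical(length(graph$nodes))
  inset[idx] <- TRUE
  seen <- logical(length(graph$nodes))
  stack <- idx[1L]
  seen[idx[1L]] <- TRUE
  found <- 1L
  while (length(stack)) {
    u <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in graph$adj[[u]]) {
      if (inset[w] && !seen[w]) {
        seen[w] <- TRUE
        found <- found + 1L
        stack <- c(stack, w)
      }
    }
  }
  found == k
}

#' Load a county adjacency graph from an edge list
#'
#' Reads a `county_a,county_b` edge-list CSV (header required) or an
#' equivalent data frame, applies the symmetric closure (duplicate and
#' reversed pairs collapse to one undirected edge) and validates the result.
#'
#' @param source path to a CSV file, or a data frame with columns
#'   `county_a` and `county_b`.
#' @param roster optional character vector of all county ids; counties in
#'   the roster without edges become isolated nodes, and any edge endpoint
#'   outside the roster is a validation error.
#' @return a [county_graph()].
#' @export
load_adjacency <- function(source, roster = NULL) {
  if (is.character(source) && length(source) == 1L) {
    df <- read.csv(source, colClasses = "character", check.names = FALSE)
  } else {
    df <- as.data.frame(source)
  }
  if (!all(c("county_a", "county_b") %in% names(df))) {
    stopf("adjacency input must have columns 'county_a' and 'county_b'")
  }
  a <- as.character(df$county_a)
  b <- as.character(df$county_b)
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad)) {
    stopf("malformed adjacency row at line %d (after header)", bad[1L])
  }
  if (!is.null(roster)) {
    roster <- as.character(roster)
    unknown <- setdiff(c(a, b), roster)
    if (length(unknown)) {
      stopf("edge references county id(s) not in roster: %s",
            paste(csort(unknown), collapse = ", "))
    }
    nodes <- roster
  } else {
    nodes <- unique(c(a, b))
  }
  if (length(a)) {
    county_graph(nodes, cbind(a, b))
  } else {
    county_graph(nodes)
  }
}

#' Build a contiguity graph from county boundary polygons
#'
#' Reads a GeoJSON FeatureCollection (one feature per county, property
#' `county` carrying the identifier, Polygon or MultiPolygon geometry in
#' longitude/latitude) and connects counties that share boundary points.
#' Following the convention of lattice packages for polygon contiguity,
#' `queen` adjacency requires at least one shared boundary vertex and
#' `rook` at least two (a shared border segment), with coordinates snapped
#' to a tolerance before comparison.
#'
#' @param source path to a GeoJSON file or a GeoJSON string.
#' @param contiguity `"rook"` (default: shared border segment) or
#'   `"queen"` (any shared point, so corner-touching counties are adjacent).
#' @param snap coordinate snapping tolerance in degrees.
#' @return a [county_graph()] with centroids populated from the polygon
#'   area-weighted centroid.
#' @export
graph_from_boundaries <- function(source, contiguity = c("rook", "queen"),
                                  snap = 1e-8) {
  contiguity <- match.arg(contiguity)
  gj <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats) || !length(feats)) stopf("GeoJSON has no features")

  ids <- character(length(feats))
  vkeys <- vector("list", length(feats))
  cents <- matrix(NA_real_, nrow = length(feats), ncol = 2L)

  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties$county
    if (is.null(id)) stopf("feature %d lacks a 'county' property", i)
    ids[i] <- as.character(id)
    geom <- f$geometry
    polys <- switch(geom$type %||% "",
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stopf("county '%s': unsupported geometry type '%s'", ids[i], geom$type %||% "none")
    )
    keys <- character(0)
    area_sum <- 0
    cx <- 0
    cy <- 0
    for (poly in polys) {
      for (ri in seq_along(poly)) {
        ring <- poly[[ri]]
        if (length(ring) < 4L) stopf("county '%s': invalid ring (< 4 coordinates)", ids[i])
        xy <- t(vapply(ring, function(p) c(as.numeric(p[[1L]]), as.numeric(p[[2L]])),
                       numeric(2L)))
        if (anyNA(xy)) stopf("county '%s': non-numeric coordinate", ids[i])
        keys <- c(keys, sprintf("%.0f:%.0f", round(xy[, 1L] / snap), round(xy[, 2L] / snap)))
        if (ri == 1L) { # outer ring drives the centroid
          x <- xy[, 1L]; y <- xy[, 2L]
          j <- c(seq_len(nrow(xy))[-1L], 1L)
          cross <- x * y[j] - x[j] * y
          a <- sum(cross) / 2
          if (abs(a) > 0) {
            cx <- cx + sum((x + x[j]) * cross) / 6
            cy <- cy + sum((y + y[j]) * cross) / 6
            area_sum <- area_sum + a
          }
        }
      }
    }
    if (area_sum == 0) stopf("county '%s': degenerate (zero-area) geometry", ids[i])
    cents[i, ] <- c(cx / area_sum, cy / area_sum)
    vkeys[[i]] <- unique(keys)
  }
  if (anyDuplicated(ids)) stopf("duplicate county ids in boundary file")

  need <- if (contiguity == "queen") 1L else 2L
  ea <- character(0)
  eb <- character(0)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      shared <- sum(vkeys[[i]] %in% vkeys[[j]])
      if (shared >= need) {
        ea <- c(ea, ids[i])
        eb <- c(eb, ids[j])
      }
    }
  }
  cen <- data.frame(county = ids, lon = cents[, 1L], lat = cents[, 2L])
  if (length(ea)) {
    county_graph(ids, cbind(ea, eb), centroids = cen)
  } else {
    county_graph(ids, centroids = cen)
  }
}
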