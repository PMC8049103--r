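# Temporal kNN graph over scored cells, force-directed 2-D layout,
# terminal-day region detection and region quantification.

# Blocked brute-force k-nearest neighbours of query rows among ref rows.
# Ties are broken by ascending ref index. Returns an index matrix
# (nrow(query) x k) into ref; self matches are excluded when self_map gives
# the ref index of each query row (NA otherwise).
knn_index <- function(query, ref, k, metric = "euclidean", self_map = NULL) {
  if (!metric %in% c("euclidean", "manhattan"))
    stop("unknown metric '", metric, "'")
  nq <- nrow(query); nr <- nrow(ref)
  out <- matrix(NA_integer_, nq, k)
  block <- max(1L, min(nq, floor(4e6 / max(nr, 1))))
  if (metric == "euclidean") rn2 <- rowSums(ref^2)
  for (start in seq(1L, nq, by = block)) {
    rows <- start:min(start + block - 1L, nq)
    if (metric == "euclidean") {
      d <- outer(rowSums(query[rows, , drop = FALSE]^2), rn2, "+") -
        2 * tcrossprod(query[rows, , drop = FALSE], ref)
      d[d < 0] <- 0
    } else {
      d <- matrix(0, length(rows), nr)
      for (j in seq_len(ncol(ref)))
        d <- d + abs(outer(query[rows, j], ref[, j], "-"))
    }
    if (!is.null(self_map)) {
      sm <- self_map[rows]
      has <- which(!is.na(sm))
      d[cbind(has, sm[has])] <- Inf
    }
    for (ii in seq_along(rows)) {
      ord <- order(d[ii, ], seq_len(nr))   # ascending index breaks ties
      out[rows[ii], ] <- ord[seq_len(k)]
    }
  }
  out
}

#' Build the temporal k-nearest-neighbour graph
#'
#' Connects each cell to its `k_within` nearest same-day neighbours and its
#' `k_between` nearest neighbours in each adjacent day (the grey cross-day
#' edges of the trajectory map), in normalized-marker space. Edges are
#' deduplicated to an undirected set; distance ties are broken by ascending
#' cell index.
#'
#' @param scored A `scored_events`.
#' @param feature_markers Channels used as coordinates; default all
#'   normalized markers except the gating channels CAR/CD4/CD8.
#' @param k_within,k_between Neighbour counts (`k_within >= 1`); truncated
#'   with a warning when a day stratum is too small.
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @return A `trajectory_graph`: nodes (cell metadata), an edge table with
#'   `from`/`to` row indices and `type` (`WITHIN_DAY`/`CROSS_DAY`), and the
#'   parameters used. Layout coordinates are filled by [layout_graph()].
#' @export
build_temporal_knn <- function(scored, feature_markers = NULL,
                               k_within = 15, k_between = 5,
                               metric = "euclidean") {
  stopifnot(inherits(scored, "scored_events"))
  if (k_within < 1) stop("k_within must be >= 1")
  if (is.null(feature_markers))
    feature_markers <- setdiff(colnames(scored$normalized),
                               c("CAR", "CD4", "CD8"))
  absent <- setdiff(feature_markers, colnames(scored$normalized))
  if (length(absent))
    stop("feature marker(s) not normalized: ", paste(absent, collapse = ", "))
  X <- scored$normalized[, feature_markers, drop = FALSE]
  day <- scored$meta$day
  days <- sort(unique(day))
  idx_by_day <- lapply(days, function(d) which(day == d))
  if (any(vapply(idx_by_day, length, 1L) < 2))
    stop("need at least 2 cells per day")
  edges <- list()
  for (di in seq_along(days)) {
    idx <- idx_by_day[[di]]
    kw <- k_within
    if (kw > length(idx) - 1L) {
      warning("k_within truncated to ", length(idx) - 1L, " on day ",
              days[di])
      kw <- length(idx) - 1L
    }
    nn <- knn_index(X[idx, , drop = FALSE], X[idx, , drop = FALSE], kw,
                    metric, self_map = seq_along(idx))
    edges[[length(edges) + 1L]] <-
      data.frame(from = rep(idx, kw), to = idx[as.vector(nn)],
                 type = "WITHIN_DAY", stringsAsFactors = FALSE)
    if (di < length(days) && k_between >= 1) {
      nxt <- idx_by_day[[di + 1L]]
      kb <- min(k_between, length(nxt))
      if (kb < k_between)
        warning("k_between truncated to ", kb, " between days ",
                days[di], " and ", days[di + 1L])
      nn <- knn_index(X[idx, , drop = FALSE], X[nxt, , drop = FALSE], kb,
                      metric)
      e1 <- data.frame(from = rep(idx, kb), to = nxt[as.vector(nn)],
                       type = "CROSS_DAY", stringsAsFactors = FALSE)
      kb2 <- min(k_between, length(idx))
      nn2 <- knn_index(X[nxt, , drop = FALSE], X[idx, , drop = FALSE], kb2,
                       metric)
      e2 <- data.frame(from = rep(nxt, kb2), to = idx[as.vector(nn2)],
                       type = "CROSS_DAY", stringsAsFactors = FALSE)
      edges[[length(edges) + 1L]] <- rbind(e1, e2)
    }
  }
  edges <- do.call(rbind, edges)
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  keep <- !duplicated(paste(a, b))
  edges <- data.frame(from = a[keep], to = b[keep], type = edges$type[keep],
                      stringsAsFactors = FALSE)
  structure(list(nodes = scored$meta, edges = edges,
                 k_within = k_within, k_between = k_between,
                 metric = metric, feature_markers = feature_markers,
                 layout = NULL),
            class = "trajectory_graph")
}

#' @export
print.trajectory_graph <- function(x, ...) {
  cat(sprintf("trajectory_graph: %d cells, %d edges (%d within-day, %d cross-day)%s\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$type == "WITHIN_DAY"),
              sum(x$edges$type == "CROSS_DAY"),
              if (is.null(x$layout)) "" else "; layout set"))
  invisible(x)
}

#' Compute a force-directed 2-D layout
#'
#' Fruchterman-Reingold spring-repulsion layout with seed-deterministic
#' circular initialization. Disconnected components are laid out separately
#' and placed on a grid (reported via `message()`); the final coordinates
#' are centered at the origin.
#'
#' @param graph A `trajectory_graph`.
#' @param iterations Force-directed iterations.
#' @param seed Integer seed.
#' @return The graph with `layout` filled (`cell_id`, `x`, `y`).
#' @export
layout_graph <- function(graph, iterations = 500, seed = 1) {
  stopifnot(inherits(graph, "trajectory_graph"))
  n <- nrow(graph$nodes)
  if (n == 0) stop("empty graph")
  g <- igraph::graph_from_data_frame(
    graph$edges[c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  coords <- matrix(0, n, 2)
  if (comp$no > 1)
    message("graph has ", comp$no, " components; placing on a grid")
  ncol_grid <- ceiling(sqrt(comp$no))
  spans <- numeric(comp$no)
  layouts <- vector("list", comp$no)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, members)
    set.seed(seed + ci - 1L)
    nm <- length(members)
    init <- cbind(cos(2 * pi * seq_len(nm) / nm),
                  sin(2 * pi * seq_len(nm) / nm))
    xy <- if (nm == 1) matrix(0, 1, 2) else
      igraph::layout_with_fr(sub, coords = init, niter = iterations)
    xy <- sweep(xy, 2, colMeans(xy))
    layouts[[ci]] <- xy
    spans[ci] <- max(1e-6, max(abs(xy)))
  }
  pitch <- 4 * max(spans)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    gx <- (ci - 1) %% ncol_grid
    gy <- (ci - 1) %/% ncol_grid
    coords[members, ] <- sweep(layouts[[ci]], 2,
                               -c(gx * pitch, gy * pitch))
  }
  coords <- sweep(coords, 2, colMeans(coords))
  graph$layout <- data.frame(cell_id = graph$nodes$cell_id,
                             x = coords[, 1], y = coords[, 2],
                             stringsAsFactors = FALSE)
  graph
}

#' Detect terminal-day regions by k-means
#'
#' Clusters terminal-day cells into `R` regions on the normalized feature
#' markers, then relabels regions in descending mean exhaustion score so
#' Region 1 is the most exhausted. Cells are canonically ordered by
#' `cell_id` before clustering so membership is invariant to input row
#' order.
#'
#' @param scored A `scored_events` with scores computed.
#' @param terminal_day Day whose cells are partitioned (default: maximum
#'   observed day).
#' @param R Number of regions (`>= 2`).
#' @param seed Integer seed (fixed number of k-means restarts).
#' @param feature_markers Channels used; default as in
#'   [build_temporal_knn()].
#' @return A `region_assignment`: per-terminal-cell region labels (1..R),
#'   arm labels and supporting metadata.
#' @export
detect_regions <- function(scored, terminal_day = NULL, R = 4, seed = 1,
                           feature_markers = NULL) {
  stopifnot(inherits(scored, "scored_events"))
  if (is.null(scored$exhaustion_score))
    stop("compute_scores must be run before detect_regions")
  if (R < 2) stop("R must be >= 2")
  if (is.null(terminal_day)) terminal_day <- max(scored$meta$day)
  sel <- which(scored$meta$day == terminal_day)
  if (!length(sel)) stop("no cells at terminal day ", terminal_day)
  if (is.null(feature_markers))
    feature_markers <- setdiff(colnames(scored$normalized),
                               c("CAR", "CD4", "CD8"))
  X <- scored$normalized[sel, feature_markers, drop = FALSE]
  if (nrow(unique(X)) < R)
    stop("fewer than R distinct terminal-day points")
  ord <- order(scored$meta$cell_id[sel])        # canonical order
  set.seed(seed)
  km <- stats::kmeans(X[ord, , drop = FALSE], centers = R, nstart = 10,
                      iter.max = 100)
  labels <- integer(length(sel))
  labels[ord] <- km$cluster
  exh <- scored$exhaustion_score[sel]
  mean_exh <- vapply(seq_len(R), function(r) mean(exh[labels == r]), 0)
  relabel <- integer(R)
  relabel[order(mean_exh, decreasing = TRUE)] <- seq_len(R)
  labels <- relabel[labels]
  structure(list(cell_id = scored$meta$cell_id[sel],
                 arm = scored$meta$arm[sel],
                 region = labels, R = R, terminal_day = terminal_day,
                 feature_markers = feature_markers, seed = seed,
                 mean_exhaustion = sort(mean_exh, decreasing = TRUE)),
            class = "region_assignment")
}

#' Arm composition over regions
#'
#' For each arm, the percentage of its terminal-day cells falling in each
#' region; rows sum to 100. An arm with zero terminal cells yields a row of
#' zeros with a warning.
#'
#' @param assignment A `region_assignment`.
#' @param arms Optional per-cell arm labels (default: those stored in the
#'   assignment).
#' @return Data frame `arm`, `region`, `n`, `pct`.
#' @export
region_composition <- function(assignment, arms = NULL) {
  stopifnot(inherits(assignment, "region_assignment"))
  if (is.null(arms)) arms <- assignment$arm
  if (length(arms) != length(assignment$region))
    stop("arms must have one label per terminal cell")
  arm_levels <- unique(arms)
  out <- list()
  for (a in arm_levels) {
    n_r <- vapply(seq_len(assignment$R),
                  function(r) sum(arms == a & assignment$region == r), 0L)
    tot <- sum(n_r)
    if (tot == 0) {
      warning("arm '", a, "' has zero terminal cells")
      pct <- rep(0, assignment$R)
    } else pct <- 100 * n_r / tot
    out[[a]] <- data.frame(arm = a, region = seq_len(assignment$R),
                           n = n_r, pct = pct, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-region score summaries
#'
#' Quartiles (Q1, median, Q3; quantile type 7, linear interpolation) and
#' mean of the exhaustion and memory scores within each region — the
#' quantities drawn as violin quartiles with a band at the mean. An empty
#' region yields `NA` summaries with a warning. The quantile rule is
#' recorded in attribute `quantile_type`.
#'
#' @param scored A `scored_events` with scores computed.
#' @param assignment A `region_assignment` over the same cells.
#' @return Data frame `region`, `score_kind`, `q1`, `median`, `q3`, `mean`,
#'   `n`.
#' @export
region_score_summary <- function(scored, assignment) {
  stopifnot(inherits(scored, "scored_events"),
            inherits(assignment, "region_assignment"))
  pos <- match(assignment$cell_id, scored$meta$cell_id)
  if (anyNA(pos)) stop("assignment cells missing from scored events")
  scores <- list(exhaustion = scored$exhaustion_score[pos],
                 memory = scored$memory_score[pos])
  out <- list()
  for (r in seq_len(assignment$R)) {
    in_r <- assignment$region == r
    if (!any(in_r)) warning("region ", r, " is empty")
    for (kind in names(scores)) {
      v <- scores[[kind]][in_r]
      if (length(v)) {
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        row <- data.frame(region = r, score_kind = kind, q1 = q[1],
                          median = q[2], q3 = q[3], mean = mean(v),
                          n = length(v), stringsAsFactors = FALSE)
      } else {
        row <- data.frame(region = r, score_kind = kind, q1 = NA_real_,
                          median = NA_real_, q3 = NA_real_, mean = NA_real_,
                          n = 0L, stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  attr(out, "quantile_type") <- 7L
  out
}
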