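# Segmentation of spatial coefficient maps into activity clusters and the
# geometry/statistics computed on them: centre of gravity (COG), cluster
# overlap, inter-condition COG displacement, barycenter weights and ratios,
# and the paired Wilcoxon position test.
#
# The two-step segmentation: (1) rank-based histogram equalization of the
# map, then marker-free watershed (4-connectivity, planar grid) to obtain
# catchment regions around local maxima; (2) within each region, electrodes
# with values >= 70% of the regional maximum form the activity cluster.

#' Build a coefficient map from a channel vector
#'
#' @param values Per-channel values (length = grid channels) or a column of
#'   the NNMF coefficient matrix restricted to kept channels.
#' @param grid A [grid_layout()].
#' @param bad_mask Logical mask of excluded channels. When `values` has
#'   `sum(!bad_mask)` entries they are taken to be the kept channels in
#'   channel order.
#' @return `n_cols x n_rows` matrix indexed `[x, y]` with `NA` at masked
#'   electrodes.
#' @export
coefficient_map <- function(values, grid, bad_mask = rep(FALSE, n_channels(grid))) {
  full <- rep(NA_real_, n_channels(grid))
  if (length(values) == n_channels(grid)) {
    full <- values
    full[bad_mask] <- NA_real_
  } else if (length(values) == sum(!bad_mask)) {
    full[!bad_mask] <- values
  } else {
    stop("length of values matches neither all nor kept channels", call. = FALSE)
  }
  channel_vector_to_map(full, grid)
}

# Rank-based histogram equalization over unmasked cells (ties share mean
# rank); masked cells stay NA.
equalize_map <- function(map) {
  ok <- !is.na(map)
  r <- rank(map[ok], ties.method = "average")
  out <- map
  out[ok] <- r / length(r)
  out
}

# Marker-free watershed on a planar map, 4-connectivity: cells are visited
# in order of decreasing height; a cell with no labelled 4-neighbour seeds a
# new basin (local maximum), otherwise it drains to the label of its highest
# labelled neighbour. Masked (NA) cells are skipped.
watershed_labels <- function(map) {
  nc <- nrow(map)
  nr <- ncol(map)
  labels <- matrix(NA_integer_, nc, nr)
  ord <- order(map, decreasing = TRUE, na.last = NA)
  next_label <- 0L
  for (idx in ord) {
    x <- (idx - 1L) %% nc + 1L
    y <- (idx - 1L) %/% nc + 1L
    best_lab <- NA_integer_
    best_val <- -Inf
    for (d in 1:4) {
      nx <- x + c(-1L, 1L, 0L, 0L)[d]
      ny <- y + c(0L, 0L, -1L, 1L)[d]
      if (nx < 1L || nx > nc || ny < 1L || ny > nr) next
      lab <- labels[nx, ny]
      if (!is.na(lab) && map[nx, ny] > best_val) {
        best_val <- map[nx, ny]
        best_lab <- lab
      }
    }
    if (is.na(best_lab)) {
      next_label <- next_label + 1L
      labels[x, y] <- next_label
    } else {
      labels[x, y] <- best_lab
    }
  }
  labels
}

# 4-connected components of a logical map; returns an integer label matrix.
connected_components <- function(mask) {
  nc <- nrow(mask)
  nr <- ncol(mask)
  labels <- matrix(0L, nc, nr)
  cur <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      idx <- queue[1L]
      queue <- queue[-1L]
      x <- (idx - 1L) %% nc + 1L
      y <- (idx - 1L) %/% nc + 1L
      for (d in 1:4) {
        nx <- x + c(-1L, 1L, 0L, 0L)[d]
        ny <- y + c(0L, 0L, -1L, 1L)[d]
        if (nx < 1L || nx > nc || ny < 1L || ny > nr) next
        j <- (ny - 1L) * nc + nx
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Segment a coefficient map into activity clusters
#'
#' @param map `n_cols x n_rows` nonnegative matrix (NA = masked electrode).
#' @param threshold Within-region membership threshold as a fraction of the
#'   regional maximum (default 0.70).
#' @param floor Regions whose maximum falls below this fraction of the
#'   global maximum are discarded as noise (default 0.10).
#' @return List of `activity_cluster` objects, ordered by decreasing total
#'   weight. Each has `electrodes` (matrix with columns `x`, `y`),
#'   `weights`, `cog`, `total_weight`, `barycenter_weight`, `region_max`.
#'   An all-zero map yields an empty list with a warning.
#' @export
segment_map <- function(map, threshold = 0.70, floor = 0.10) {
  vals <- map[!is.na(map)]
  if (!length(vals) || all(vals <= 0)) {
    warning("all-zero map: no activity clusters", call. = FALSE)
    return(list())
  }
  eq <- equalize_map(map)
  labels <- watershed_labels(eq)
  gmax <- max(vals)
  clusters <- list()
  for (lab in seq_len(max(labels, na.rm = TRUE))) {
    in_region <- !is.na(labels) & labels == lab & !is.na(map)
    if (!any(in_region)) next
    rmax <- max(map[in_region])
    if (rmax < floor * gmax) next
    member <- in_region & map >= threshold * rmax
    # keep the 4-connected component containing the regional peak
    comp <- connected_components(member)
    peak_idx <- which(in_region & map == rmax)[1L]
    member <- comp == comp[peak_idx] & comp > 0L
    idx <- which(member)
    xy <- cbind(x = (idx - 1L) %% nrow(map) + 1L,
                y = (idx - 1L) %/% nrow(map) + 1L)
    w <- map[idx]
    cl <- activity_cluster(xy, w, map = map, region_max = rmax)
    clusters[[length(clusters) + 1L]] <- cl
  }
  clusters[order(vapply(clusters, `[[`, numeric(1), "total_weight"),
                 decreasing = TRUE)]
}

#' Activity cluster on the electrode grid
#'
#' @param electrodes Matrix with columns `x`, `y` (1-based grid indices).
#' @param weights Nonnegative per-electrode weights.
#' @param map Optional source map, used to interpolate the barycenter
#'   weight.
#' @param region_max Maximum map value of the watershed region.
#' @return An object of class `activity_cluster`.
#' @export
activity_cluster <- function(electrodes, weights, map = NULL,
                             region_max = max(weights)) {
  electrodes <- as.matrix(electrodes)
  stopifnot(nrow(electrodes) >= 1L, all(weights >= 0))
  A <- sum(weights)
  cg <- c(x = sum(weights * electrodes[, 1L]) / A,
          y = sum(weights * electrodes[, 2L]) / A)
  bw <- if (!is.null(map)) barycenter_weight(map, cg) else NA_real_
  structure(list(electrodes = electrodes, weights = as.numeric(weights),
                 cog = cg, total_weight = A, barycenter_weight = bw,
                 region_max = region_max),
            class = "activity_cluster")
}

#' Centre of gravity of a cluster
#'
#' Weighted mean electrode position:
#' `xbar = sum(c_el x_el) / A`, `ybar = sum(c_el y_el) / A`, with `A` the
#' sum of the member weights. Coordinates are in grid units, i.e. multiples
#' of the inter-electrode distance.
#'
#' @param cluster An `activity_cluster`.
#' @return Named numeric `(x, y)`.
#' @export
cog <- function(cluster) {
  if (sum(cluster$weights) <= 0) stop("zero total weight", call. = FALSE)
  cluster$cog
}

#' Percentage overlap of two clusters
#'
#' Intersection size normalized to the smaller and to the larger cluster.
#'
#' @param cl_a,cl_b `activity_cluster` objects.
#' @return Named numeric `(pct_vs_smallest, pct_vs_largest)`.
#' @export
overlap <- function(cl_a, cl_b) {
  key <- function(cl) paste(cl$electrodes[, 1L], cl$electrodes[, 2L])
  a <- key(cl_a)
  b <- key(cl_b)
  i <- length(intersect(a, b))
  c(pct_vs_smallest = 100 * i / min(length(a), length(b)),
    pct_vs_largest = 100 * i / max(length(a), length(b)))
}

#' COG displacement between two matched clusters
#'
#' @param cl_1,cl_2 `activity_cluster` objects matched to the same module.
#' @param axis `"x"` (ulnar-radial, default), `"y"` (proximal-distal) or
#'   `"euclidean"`.
#' @return Distance in IED units (grid units).
#' @export
cog_shift <- function(cl_1, cl_2, axis = c("x", "y", "euclidean")) {
  axis <- match.arg(axis)
  d <- cog(cl_1) - cog(cl_2)
  switch(axis,
         x = abs(d[["x"]]),
         y = abs(d[["y"]]),
         euclidean = sqrt(sum(d^2)))
}

#' Map value at a continuous grid position (bilinear interpolation)
#'
#' Used to report the module weight at a cluster barycenter. Masked (NA)
#' electrodes are in-painted with the mean of their available 4-neighbours
#' before interpolating.
#'
#' @param map `n_cols x n_rows` matrix.
#' @param pos Named or plain numeric `(x, y)` inside the grid bounds.
#' @return Interpolated scalar.
#' @export
barycenter_weight <- function(map, pos) {
  x <- pos[[1L]]
  y <- pos[[2L]]
  nc <- nrow(map)
  nr <- ncol(map)
  if (x < 1 || x > nc || y < 1 || y > nr) {
    stop("position outside grid bounds", call. = FALSE)
  }
  if (anyNA(map)) map <- inpaint_na(map)
  x0 <- min(floor(x), nc - 1L)
  y0 <- min(floor(y), nr - 1L)
  if (nc == 1L) x0 <- 1L
  if (nr == 1L) y0 <- 1L
  fx <- x - x0
  fy <- y - y0
  x1 <- min(x0 + 1L, nc)
  y1 <- min(y0 + 1L, nr)
  (1 - fx) * (1 - fy) * map[x0, y0] + fx * (1 - fy) * map[x1, y0] +
    (1 - fx) * fy * map[x0, y1] + fx * fy * map[x1, y1]
}

# Replace NA cells by the mean of their available 4-neighbours (iterated
# until filled).
inpaint_na <- function(map) {
  nc <- nrow(map)
  nr <- ncol(map)
  while (anyNA(map)) {
    filled_any <- FALSE
    for (idx in which(is.na(map))) {
      x <- (idx - 1L) %% nc + 1L
      y <- (idx - 1L) %/% nc + 1L
      nb <- c(if (x > 1L) map[x - 1L, y], if (x < nc) map[x + 1L, y],
              if (y > 1L) map[x, y - 1L], if (y < nr) map[x, y + 1L])
      nb <- nb[!is.na(nb)]
      if (length(nb)) {
        map[x, y] <- mean(nb)
        filled_any <- TRUE
      }
    }
    if (!filled_any) {
      map[is.na(map)] <- 0
      break
    }
  }
  map
}

#' Barycenter-weight ratio between two conditions
#'
#' Ratio of the interpolated map values at the cluster barycenters of the
#' same (matched) module in two conditions, e.g. prone over neutral.
#'
#' @param map_a,map_b Coefficient maps of the matched module in the two
#'   conditions.
#' @param cog_a,cog_b Barycenter positions of the matched clusters.
#' @return Scalar ratio `weight_a / weight_b`.
#' @export
weight_ratio <- function(map_a, map_b, cog_a, cog_b) {
  wb <- barycenter_weight(map_b, cog_b)
  if (abs(wb) < 1e-9) stop("reference barycenter weight is ~0", call. = FALSE)
  barycenter_weight(map_a, cog_a) / wb
}

#' Paired Wilcoxon signed-rank test on COG coordinates
#'
#' Two-sided test of a hand-position effect on the chosen COG coordinate;
#' the exact null distribution is used for n <= 25 pairs.
#'
#' @param cogs_1,cogs_2 Matrices (subjects x 2) or vectors of per-subject
#'   COG coordinates under the two conditions.
#' @param axis `"x"` or `"y"` when matrices are given.
#' @return List with `p_value`, `statistic`, `n`.
#' @export
cog_position_test <- function(cogs_1, cogs_2, axis = c("x", "y")) {
  axis <- match.arg(axis)
  pick <- function(m) {
    if (is.matrix(m) || is.data.frame(m)) m[, if (axis == "x") 1L else 2L] else m
  }
  a <- as.numeric(pick(cogs_1))
  b <- as.numeric(pick(cogs_2))
  stopifnot(length(a) == length(b))
  if (length(a) < 5L) stop("need at least 5 paired samples", call. = FALSE)
  d <- a - b
  if (all(d == 0)) {
    warning("all paired differences are zero", call. = FALSE)
    return(list(p_value = 1, statistic = NA_real_, n = length(a)))
  }
  dz <- d[d != 0]
  if (length(dz) <= 25L) {
    res <- signed_rank_exact(dz)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                       correct = FALSE))
    res <- list(p = wt$p.value, W = unname(wt$statistic))
  }
  list(p_value = res$p, statistic = res$W, n = length(a))
}

# Exact two-sided signed-rank p-value by sign-flip enumeration.
# Mid-ranks handle tied |differences|; the null distribution of the
# positive-rank sum is built by convolution over 2^n equally likely sign
# assignments (doubled ranks keep the support integral).
signed_rank_exact <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled mid-ranks
  W2 <- sum(r2[d > 0])
  total <- sum(r2)
  dist <- c(1, numeric(total))  # dist[w + 1] = #assignments with sum w
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1L - r)])
    dist <- dist + shifted
  }
  probs <- dist / sum(dist)
  lo <- sum(probs[seq_len(W2 + 1L)])          # P(W <= w)
  hi <- sum(probs[(W2 + 1L):(total + 1L)])    # P(W >= w)
  list(p = min(1, 2 * min(lo, hi)), W = W2 / 2)
}
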