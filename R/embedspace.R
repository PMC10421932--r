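# Per-protein feature vectors, UMAP projection (with the study parameters),
# clustering by k-means / DBSCAN / OPTICS-xi, and partition concordance.

#' UMAP projection parameters
#'
#' Defaults follow the study settings: n_neighbors = 25, min_dist = 0.5,
#' n_components = 3, seed 42.
#'
#' @param n_neighbors,min_dist,n_components,seed see \pkg{uwot}
#' @return parameter list
#' @export
projection_params <- function(n_neighbors = 25L, min_dist = 0.5,
                              n_components = 3L, seed = 42L) {
  stopifnot(n_neighbors >= 2L, min_dist >= 0, min_dist < 1)
  list(n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
       n_components = as.integer(n_components), seed = as.integer(seed))
}

#' Clustering parameters
#'
#' Defaults follow the study settings: k-means k = 7; DBSCAN eps = 0.55,
#' minimum points = 5; OPTICS xi = 0.01 (OPTICS reuses DBSCAN's minimum
#' points, which the study leaves unstated).
#'
#' @param kmeans_k,dbscan_eps,dbscan_min_pts,optics_xi,optics_min_pts,seed
#'   algorithm settings
#' @return parameter list
#' @export
clustering_params <- function(kmeans_k = 7L, dbscan_eps = 0.55,
                              dbscan_min_pts = 5L, optics_xi = 0.01,
                              optics_min_pts = 5L, seed = 1L) {
  stopifnot(kmeans_k >= 1L, dbscan_eps > 0, dbscan_min_pts >= 1L,
            optics_xi > 0, optics_xi < 1)
  list(kmeans_k = as.integer(kmeans_k), dbscan_eps = dbscan_eps,
       dbscan_min_pts = as.integer(dbscan_min_pts), optics_xi = optics_xi,
       optics_min_pts = as.integer(optics_min_pts), seed = as.integer(seed))
}

#' Build per-protein feature vectors
#'
#' Modes: \code{composition20} (per-residue frequency over the 20 standard
#' amino acids, non-standard residues dropped from numerator and
#' denominator); \code{kmer} (normalised 2-mer counts, 400D);
#' \code{cys_descriptor} (16D: the 10-slot occupancy mask, number of extra
#' cysteines, loop-II extension, tail length, anchored flag, total core
#' cysteines, mature length); \code{imported} (pass-through of externally
#' computed vectors joined by id).  Several modes may be combined; the
#' blocks are concatenated.  Non-composition blocks are z-scored per
#' dimension (zero-variance dimensions left at 0); composition is left raw.
#'
#' @param matures named character vector of mature sequences
#' @param mode character vector, subset of
#'   \code{c("composition20","kmer","cys_descriptor","imported")}
#' @param imported numeric matrix with rownames (required for mode
#'   \code{"imported"})
#' @param standardize z-score non-composition blocks (default TRUE)
#' @param balance_blocks when several modes are combined, rescale each
#'   block to unit total variance so no block dominates the Euclidean
#'   metric by units alone (multiple-factor-analysis convention)
#' @return numeric matrix, one row per protein in input order
#' @export
compose_features <- function(matures, mode = "composition20",
                             imported = NULL, standardize = TRUE,
                             balance_blocks = length(mode) > 1L) {
  stopifnot(length(matures) > 0, !is.null(names(matures)))
  known <- c("composition20", "kmer", "cys_descriptor", "imported")
  bad <- setdiff(mode, known)
  if (length(bad)) stop("unknown feature mode: ", bad[1])
  blocks <- list()
  for (m in mode) {
    block <- switch(m,
      composition20 = t(vapply(matures, composition20_vec, numeric(20L))),
      kmer = t(vapply(matures, kmer2_vec, numeric(400L))),
      cys_descriptor = t(vapply(matures, cys_descriptor_vec, numeric(16L))),
      imported = {
        if (is.null(imported)) stop("mode 'imported' requires a vector matrix")
        missing <- setdiff(names(matures), rownames(imported))
        if (length(missing)) {
          stop("imported vectors missing ids: ", paste(missing, collapse = ", "))
        }
        imported[names(matures), , drop = FALSE]
      })
    if (standardize && m != "composition20") {
      mu <- colMeans(block)
      sd <- apply(block, 2L, stats::sd)
      sd[sd == 0 | is.na(sd)] <- Inf
      block <- sweep(sweep(block, 2L, mu, "-"), 2L, sd, "/")
    }
    if (balance_blocks) {
      tv <- sum(apply(block, 2L, stats::var))
      if (tv > 0) block <- block / sqrt(tv)
    }
    blocks[[m]] <- block
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- names(matures)
  stopifnot(all(is.finite(out)))
  out
}

composition20_vec <- function(seq) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  aa <- aa[aa %in% AA20]
  if (!length(aa)) stop("sequence has no standard residues")
  stats::setNames(as.numeric(table(factor(aa, levels = AA20))) / length(aa),
                  AA20)
}

kmer2_vec <- function(seq) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  keep <- aa %in% AA20
  lv <- as.vector(outer(AA20, AA20, paste0))
  if (length(aa) < 2L) return(stats::setNames(numeric(400L), lv))
  k2 <- paste0(aa[-length(aa)], aa[-1L])
  k2 <- k2[keep[-length(aa)] & keep[-1L]]
  v <- as.numeric(table(factor(k2, levels = lv)))
  if (sum(v) > 0) v <- v / sum(v)
  stats::setNames(v, lv)
}

cys_descriptor_vec <- function(mature) {
  fw <- map_cysteine_framework(mature)
  sec <- detect_mad(fw, mature)
  stats::setNames(
    c(as.numeric(fw$slot_occupancy),
      length(fw$extra_cys), fw$loop2_extension, fw$tail_length,
      as.numeric(sec == "anchored"),
      sum(fw$slot_occupancy) + length(fw$extra_cys),
      nchar(mature)),
    c(paste0("slot", 1:10), "n_extra_cys", "loop2_extension", "tail_length",
      "anchored", "total_cys", "mature_length"))
}

#' Project feature vectors to 3D with UMAP
#'
#' Runs \pkg{uwot} UMAP with exactly the given parameters, single-threaded
#' so that a fixed seed gives bit-reproducible coordinates; output row
#' order equals input order.
#'
#' @param features numeric matrix (rows = proteins)
#' @param params [projection_params()]
#' @return numeric matrix n x n_components, rownames preserved
#' @export
project <- function(features, params = projection_params()) {
  n <- nrow(features)
  if (n < params$n_neighbors + 1L) {
    stop("too few points (", n, ") for n_neighbors = ", params$n_neighbors,
         "; lower n_neighbors")
  }
  set.seed(params$seed)
  coords <- uwot::umap(features, n_neighbors = params$n_neighbors,
                       min_dist = params$min_dist,
                       n_components = params$n_components,
                       n_threads = 1, n_sgd_threads = 0)
  rownames(coords) <- rownames(features)
  coords
}

#' k-means clustering with k-means++ seeding
#'
#' Chooses initial centers by the k-means++ rule under the given seed and
#' runs Lloyd iterations (via \code{stats::kmeans}) to convergence; the
#' best of \code{n_init} restarts (lowest within-cluster sum of squares)
#' is returned, following common practice for k-means++.
#'
#' @param points numeric matrix
#' @param k number of clusters
#' @param seed integer seed
#' @param n_init number of k-means++ restarts
#' @param max_iter,tol iteration cap and convergence tolerance
#' @return integer labels in 0..k-1, in input row order
#' @export
kmeans_cluster <- function(points, k, seed = 1L, n_init = 10L,
                           max_iter = 300L, tol = 1e-6) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < k) stop("fewer points (", n, ") than clusters (", k, ")")
  if (k == 1L) return(rep(0L, n))
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- kmeanspp_init(points, k)
    fit <- suppressWarnings(
      stats::kmeans(points, centers = centers, iter.max = max_iter,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best$cluster - 1L
}

kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  idx <- sample.int(n, 1L)
  for (j in seq_len(k - 1L)) {
    d2 <- apply(points, 1L, function(p) {
      min(colSums((t(points[idx, , drop = FALSE]) - p)^2))
    })
    d2[idx] <- 0
    if (sum(d2) == 0) {
      idx <- c(idx, setdiff(seq_len(n), idx)[1L])
    } else {
      idx <- c(idx, sample.int(n, 1L, prob = d2))
    }
  }
  points[idx, , drop = FALSE]
}

#' Density-based clustering (DBSCAN)
#'
#' Standard definition: a core point has at least \code{min_pts} points
#' (inclusive of itself) within Euclidean \code{eps}; clusters are the
#' connected components of core points, with non-core points assigned to
#' the lowest-indexed cluster containing a core point within \code{eps}
#' (scan order).  Unreachable points are labelled 0 (noise).
#'
#' @param points numeric matrix
#' @param eps neighbourhood radius
#' @param min_pts density threshold
#' @return integer labels; 0 marks noise, clusters are numbered from 1 in
#'   scan order
#' @export
dbscan_cluster <- function(points, eps, min_pts) {
  stopifnot(eps > 0, min_pts >= 1)
  points <- as.matrix(points)
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      reach <- which(nb[p, ] & core & labels == 0L)
      labels[reach] <- cl
      queue <- c(queue, reach)
    }
  }
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    anchors <- which(nb[i, ] & core)
    if (length(anchors)) labels[i] <- min(labels[anchors])
  }
  labels
}

#' OPTICS ordering and xi-cluster extraction
#'
#' Computes the OPTICS reachability ordering (eps = Inf) and extracts the
#' hierarchical xi-clusters: boundaries are placed where the reachability
#' plot is xi-steep (a point is steep down when its reachability exceeds
#' the next by a factor 1/(1-xi), and symmetrically for steep up).  Flat
#' leaf labels (innermost cluster per point, 0 = unclustered) are returned
#' together with the cluster table.
#'
#' @param points numeric matrix
#' @param min_pts density threshold (as in DBSCAN)
#' @param xi steepness threshold in (0,1)
#' @return list: \code{order} (visit order), \code{reachability} (aligned
#'   with \code{order}; \code{Inf} for the first point of a component),
#'   \code{core_dist}, \code{clusters} (data.frame start/end in ordering
#'   coordinates; the whole dataset is always present as the hierarchy
#'   root), \code{labels} (index of the innermost containing cluster, per
#'   input row)
#' @export
optics_xi <- function(points, min_pts = 5L, xi = 0.01) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= min_pts, xi > 0, xi < 1)
  d <- as.matrix(stats::dist(points))
  core_dist <- apply(d, 1L, function(r) sort(r)[min_pts])
  order_out <- integer(0)
  reach <- rep(Inf, n)
  processed <- logical(n)
  reach_out <- numeric(0)
  while (length(order_out) < n) {
    start <- which(!processed)[1]
    processed[start] <- TRUE
    order_out <- c(order_out, start)
    reach_out <- c(reach_out, Inf)
    seeds <- update_seeds(integer(0), start, d, core_dist, processed, reach)
    reach <- seeds$reach; queue <- seeds$queue
    while (length(queue)) {
      r <- reach[queue]
      q <- queue[order(r, queue)][1]
      queue <- setdiff(queue, q)
      processed[q] <- TRUE
      order_out <- c(order_out, q)
      reach_out <- c(reach_out, reach[q])
      upd <- update_seeds(queue, q, d, core_dist, processed, reach)
      reach <- upd$reach; queue <- upd$queue
    }
  }
  clusters <- xi_extract(reach_out, xi, min_pts)
  labels <- integer(n)
  if (nrow(clusters)) {
    # leaves: innermost (smallest) containing cluster wins
    sizes <- clusters$end - clusters$start + 1L
    for (ci in order(-sizes)) {
      span <- seq(clusters$start[ci], clusters$end[ci])
      labels[order_out[span]] <- ci
    }
  }
  list(order = order_out, reachability = reach_out, core_dist = core_dist,
       clusters = clusters, labels = labels)
}

update_seeds <- function(queue, p, d, core_dist, processed, reach) {
  cand <- which(!processed)
  if (length(cand)) {
    newr <- pmax(core_dist[p], d[p, cand])
    better <- newr < reach[cand]
    reach[cand[better]] <- newr[better]
    queue <- union(queue, cand[better])
  }
  list(queue = queue, reach = reach)
}

# xi-steep cluster extraction over the reachability plot (Ankerst et al.
# steep-area scheme): maximal xi-steep-down areas are paired with later
# maximal xi-steep-up areas, filtered by the maximum-in-between, with the
# higher shoulder trimmed so both cluster borders sit at comparable
# reachability.  The trailing sentinel (infinite reachability past the end)
# lets clusters running to the end of the plot close.  The whole dataset is
# always included as the root of the hierarchy.
xi_extract <- function(r, xi, min_pts) {
  n <- length(r)
  root <- data.frame(start = 1L, end = n)
  if (n < 2L) return(root)
  comp <- 1 - xi
  rr <- c(r, Inf)
  ratio <- rr[-length(rr)] / rr[-1L]
  su <- !is.na(ratio) & ratio <= comp          # steep up at i -> i+1
  sd_ <- !is.na(ratio) & ratio >= 1 / comp     # steep down
  up <- !is.na(ratio) & ratio < 1
  down <- !is.na(ratio) & ratio > 1
  # extend a maximal steep region from `start`: tolerate up to min_pts
  # consecutive non-steep points that do not move against the trend
  extend_region <- function(steep, against, start) {
    idx <- start; end <- start; slack <- 0L
    while (idx <= n) {
      if (steep[idx]) { slack <- 0L; end <- idx }
      else if (!against[idx]) {
        slack <- slack + 1L
        if (slack > min_pts) break
      } else break
      idx <- idx + 1L
    }
    end
  }
  filter_sdas <- function(sdas, mib) {
    if (is.infinite(mib)) return(list())
    keep <- Filter(function(a) mib <= rr[a$start] * comp, sdas)
    lapply(keep, function(a) { a$mib <- max(a$mib, mib); a })
  }
  clusters <- data.frame(start = integer(0), end = integer(0))
  sdas <- list()
  index <- 1L
  mib <- 0
  steep_pts <- which(su | sd_)
  for (sp in steep_pts) {
    if (sp < index) next
    mib <- max(mib, max(rr[index:sp]))
    if (sd_[sp]) {
      sdas <- filter_sdas(sdas, mib)
      d_end <- extend_region(sd_, up, sp)
      sdas[[length(sdas) + 1L]] <- list(start = sp, end = d_end, mib = 0)
      index <- d_end + 1L
      mib <- rr[index]
    } else {
      sdas <- filter_sdas(sdas, mib)
      u_start <- sp
      u_end <- extend_region(su, down, sp)
      index <- u_end + 1L
      mib <- rr[index]
      end_r <- rr[u_end + 1L]
      for (a in sdas) {
        if (end_r * comp < a$mib) next
        c_start <- a$start; c_end <- u_end
        d_max <- rr[a$start]
        if (d_max * comp >= end_r) {
          while (c_start < a$end && rr[c_start + 1L] > end_r) {
            c_start <- c_start + 1L
          }
        } else if (end_r * comp >= d_max) {
          while (c_end > u_start && rr[c_end - 1L] > d_max) {
            c_end <- c_end - 1L
          }
        }
        if (c_end - c_start + 1L < max(2L, min_pts)) next
        if (c_start > a$end || c_end < u_start) next
        clusters <- rbind(clusters, data.frame(start = c_start, end = c_end))
      }
    }
  }
  clusters <- unique(rbind(clusters, root))
  clusters[order(clusters$start, -clusters$end), , drop = FALSE]
}

#' Leaf clusters of an OPTICS xi hierarchy
#'
#' @param result output of [optics_xi()]
#' @return the rows of \code{result$clusters} that contain no smaller
#'   cluster
#' @export
optics_leaves <- function(result) {
  cl <- result$clusters
  is_leaf <- vapply(seq_len(nrow(cl)), function(i) {
    !any(cl$start >= cl$start[i] & cl$end <= cl$end[i] &
           (cl$end - cl$start) < (cl$end[i] - cl$start[i]))
  }, TRUE)
  cl[is_leaf, , drop = FALSE]
}

#' Concordance between two partitions (adjusted Rand index)
#'
#' Noise labels (0 or negative) are treated as one regular class of their
#' own rather than dropped.
#'
#' @param labels_a,labels_b equal-length label vectors
#' @return ARI in [-1, 1]
#' @export
concordance <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length: ", length(labels_a), " vs ",
         length(labels_b))
  }
  if (length(labels_a) < 2L) stop("need at least 2 observations")
  mclust::adjustedRandIndex(as.character(labels_a), as.character(labels_b))
}
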