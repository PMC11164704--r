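# Interpreting a trained agent: extract hidden-layer activations along
# trajectories, cluster the activation patterns with k-means, pick k at the
# knee of the SSE curve, and map clusters onto the circling phase theta.

#' Extract hidden-layer activations of the actor network
#'
#' Replays observation vectors through the actor and concatenates the
#' rectified activations of both hidden layers (nominally 2 x 200 = 400
#' non-negative values per timestep).
#'
#' @param agent A [ddpg_agent()] object or checkpoint list.
#' @param observations A numeric matrix (rows = timesteps) or a list of such
#'   matrices (e.g. from several [run_episode()] calls), column count equal
#'   to the agent's observation dimension.
#' @return A matrix of activations, rows aligned with the stacked input
#'   rows, with attribute `layout` giving the per-layer column spans.
#' @export
extract_activations <- function(agent, observations) {
  if (!inherits(agent, "ddpg_agent")) agent <- load_checkpoint(agent)
  if (is.list(observations) && !is.matrix(observations)) {
    observations <- do.call(rbind, observations)
  }
  if (ncol(observations) != agent$obs_dim) {
    stop(sprintf("observation dimension %d does not match the agent's %d",
                 ncol(observations), agent$obs_dim))
  }
  f <- actor_forward(agent, observations)
  acts <- cbind(f$H1, f$H2)
  attr(acts, "layout") <- list(layer1 = seq_len(ncol(f$H1)),
                               layer2 = ncol(f$H1) + seq_len(ncol(f$H2)))
  acts
}

# Knee of a decreasing curve: the point with maximum distance to the chord
# joining the endpoints (in normalized coordinates).
knee_point <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  xn <- (x - min(x)) / max(diff(range(x)), 1e-12)
  yn <- (y - min(y)) / max(diff(range(y)), 1e-12)
  x1 <- xn[1]; y1 <- yn[1]
  x2 <- xn[length(xn)]; y2 <- yn[length(yn)]
  num <- abs((x2 - x1) * (y1 - yn) - (x1 - xn) * (y2 - y1))
  den <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  x[which.max(num / den)]
}

#' Cluster network activation patterns
#'
#' Runs k-means (multiple restarts, fixed seed) on activation rows for each
#' candidate k, repairs any non-monotone SSE by warm-starting from the
#' previous solution, chooses k at the knee of the SSE-vs-k curve, and
#' returns the labels for the chosen k.
#'
#' @param acts Activation matrix (rows = timesteps), e.g. from
#'   [extract_activations()].
#' @param k_candidates Candidate cluster counts. Default 1:10.
#' @param seed Integer seed for the restarts.
#' @param nstart Random restarts per k.
#' @param standardize Standardize columns before clustering. Default FALSE
#'   (raw rectified activations).
#' @return An object of class `activation_clusters`: list with `k` (chosen),
#'   `labels` (per-row, in 1..k), `sse` (tibble k, sse), `centers`.
#'   Degenerate input (all rows identical) yields k = 1 with a warning.
#' @export
cluster_activations <- function(acts, k_candidates = 1:10, seed = 1,
                                nstart = 10, standardize = FALSE) {
  X <- as.matrix(acts)
  if (standardize) {
    s <- apply(X, 2, stats::sd)
    X <- sweep(X, 2, colMeans(X)); X[, s > 0] <- sweep(X[, s > 0, drop = FALSE], 2, s[s > 0], `/`)
  }
  n_distinct <- nrow(unique(X))
  if (n_distinct == 1) {
    warning("degenerate activations (all rows identical): k = 1")
    return(structure(list(k = 1L, labels = rep(1L, nrow(X)),
                          sse = tibble::tibble(k = 1L, sse = 0),
                          centers = matrix(colMeans(X), 1)),
                     class = "activation_clusters"))
  }
  k_candidates <- sort(unique(pmin(k_candidates, n_distinct)))
  set.seed(seed)
  fits <- vector("list", length(k_candidates))
  sse <- numeric(length(k_candidates))
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    if (k == 1) {
      ctr <- matrix(colMeans(X), 1)
      fits[[i]] <- list(cluster = rep(1L, nrow(X)), centers = ctr)
      sse[i] <- sum(sweep(X, 2, ctr[1, ])^2)
      next
    }
    fit <- suppressWarnings(stats::kmeans(X, centers = k, nstart = nstart,
                                          iter.max = 100))
    # monotonicity repair: warm-start by splitting the previous solution
    if (i > 1 && fit$tot.withinss > sse[i - 1]) {
      prev <- fits[[i - 1]]$centers
      far <- which.max(rowSums((X - prev[fits[[i - 1]]$cluster, , drop = FALSE])^2))
      warm <- rbind(prev, X[far, ])[seq_len(k), , drop = FALSE]
      fit2 <- suppressWarnings(stats::kmeans(X, centers = warm, iter.max = 100))
      if (fit2$tot.withinss < fit$tot.withinss) fit <- fit2
    }
    fits[[i]] <- fit
    sse[i] <- fit$tot.withinss
  }
  k_best <- if (length(k_candidates) >= 3) {
    knee_point(k_candidates, sse)
  } else k_candidates[which.min(sse)]
  i_best <- match(k_best, k_candidates)
  structure(list(k = as.integer(k_best),
                 labels = as.integer(fits[[i_best]]$cluster),
                 sse = tibble::tibble(k = k_candidates, sse = sse),
                 centers = fits[[i_best]]$centers),
            class = "activation_clusters")
}

#' @export
print.activation_clusters <- function(x, ...) {
  cat(sprintf("<activation_clusters> k = %d over %d timesteps (knee of SSE curve)\n",
              x$k, length(x$labels)))
  invisible(x)
}

#' Distribution of activation clusters over the circling phase
#'
#' Normalized histogram of theta per cluster over fixed bins, plus an
#' association score: the mean over clusters of the fraction of each
#' cluster's mass inside its best contiguous (circular) arc of
#' `ceiling(bins / k)` bins. Phase-locked clusters score near 1; clusters
#' independent of theta score near `1 / k` x arc width.
#'
#' @param labels Integer cluster labels, one per timestep.
#' @param theta Angle-from-wind series, degrees in (-180, 180\].
#' @param bins Number of theta bins. Default 24.
#' @return A tibble (cluster, theta_bin midpoint, prop) with attribute
#'   `association` (the score). Empty clusters yield no rows, not an error.
#' @export
cluster_theta_distribution <- function(labels, theta, bins = 24) {
  stopifnot(length(labels) == length(theta))
  ok <- !is.na(theta) & !is.na(labels)
  labels <- labels[ok]; theta <- theta[ok]
  edges <- seq(-180, 180, length.out = bins + 1)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  bin <- findInterval(theta, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1; bin[bin > bins] <- bins
  ks <- sort(unique(labels))
  out <- purrr::map_dfr(ks, function(k) {
    cnt <- tabulate(bin[labels == k], nbins = bins)
    tibble::tibble(cluster = k, theta_bin = mids, prop = cnt / max(sum(cnt), 1))
  })
  arc <- ceiling(bins / max(length(ks), 1))
  assoc <- mean(vapply(ks, function(k) {
    p <- out$prop[out$cluster == k]
    wrapped <- c(p, p[seq_len(arc - 1)])
    max(vapply(seq_len(bins), function(i) sum(wrapped[i:(i + arc - 1)]),
               numeric(1)))
  }, numeric(1)))
  attr(out, "association") <- assoc
  out
}

#' Association score between cluster labels and circling phase
#'
#' @inheritParams cluster_theta_distribution
#' @return The association score in (0, 1\] (see
#'   [cluster_theta_distribution()]).
#' @export
theta_association_score <- function(labels, theta, bins = 24) {
  attr(cluster_theta_distribution(labels, theta, bins), "association")
}
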