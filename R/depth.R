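# Half-space (Tukey) depth and distributional-overlap statistics.
#
# The central quantity: for a reference point cloud D and a query point d,
# the half-space depth of d is the smallest fraction of D that any closed
# half-space containing d must include. The 95% depth region of D is the set
# of points at least as deep as the 95% depth cutoff (the lower 5% quantile
# of the self-depths of D); the depth overlap of a new cloud D* is the
# fraction of its points falling inside that region.

#' Construct a gait cloud
#'
#' A gait cloud is a numeric matrix of n observations by K named metrics:
#' one row per per-second gait record, one column per gait metric. It is the
#' container both overlap statistics operate on.
#'
#' @param data A data frame of gait records or a numeric matrix.
#' @param metrics Character vector of metric columns to keep, in order.
#'   Defaults to [gait_metrics()].
#' @param source Optional tag recording where the cloud came from
#'   (subject/cohort/condition).
#' @return A numeric matrix of class `gait_cloud` with named columns and a
#'   `source` attribute.
#' @export
gait_cloud <- function(data, metrics = gait_metrics(), source = NULL) {
  if (is.matrix(data)) {
    if (is.null(colnames(data))) {
      if (ncol(data) != length(metrics)) {
        stop("matrix has no column names and does not match `metrics`",
             call. = FALSE)
      }
      colnames(data) <- metrics
    }
    data <- as.data.frame(data)
  }
  missing_cols <- setdiff(metrics, names(data))
  if (length(missing_cols) > 0) {
    stop("missing metric column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(as.data.frame(data)[metrics])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    stop("gait cloud must not contain missing or non-finite values",
         call. = FALSE)
  }
  structure(m, class = c("gait_cloud", class(m)), source = source)
}

#' Univariate quantile-coverage overlap
#'
#' Computes the fraction of a new sample falling inside the central
#' `coverage_level` interval of a reference sample: the closed interval
#' between the (1-c)/2 and 1-(1-c)/2 reference quantiles, with quantiles by
#' linear interpolation (type 7). For a reference of 1..100 compared against
#' itself at the default 95% level, the interval is [3.475, 97.525] and the
#' overlap is 94/100.
#'
#' @param reference Numeric vector, the reference distribution (n >= 40 so
#'   the central interval is estimable).
#' @param new Numeric vector, the new sample to evaluate.
#' @param coverage_level Central coverage of the reference interval
#'   (default 0.95).
#' @return A proportion in [0, 1].
#' @export
univariate_overlap <- function(reference, new, coverage_level = 0.95) {
  reference <- reference[is.finite(reference)]
  if (length(reference) < 40) {
    stop("reference sample too small to estimate the central interval ",
         "(need >= 40 values)", call. = FALSE)
  }
  if (length(new) == 0) {
    stop("new sample is empty; overlap is undefined", call. = FALSE)
  }
  alpha <- (1 - coverage_level) / 2
  qs <- stats::quantile(reference, c(alpha, 1 - alpha), type = 7,
                        names = FALSE)
  mean(new >= qs[1] & new <= qs[2])
}

#' One-dimensional half-space depth
#'
#' Rank depth of a scalar relative to a reference sample:
#' `min(#\{x <= point\}, #\{x >= point\}) / n`, capped at 0.5 so the depth
#' scale matches the multivariate convention (0 outside the range, 0.5 at
#' the median of a continuous sample).
#'
#' @param point Numeric vector of query values (vectorised).
#' @param reference Numeric vector, nonempty.
#' @return Depth value(s) in [0, 0.5].
#' @export
halfspace_depth_1d <- function(point, reference) {
  if (length(reference) == 0) stop("reference is empty", call. = FALSE)
  n <- length(reference)
  s <- sort(reference)
  n_le <- findInterval(point, s)                  # #{x <= point}
  n_lt <- findInterval(point, s, left.open = TRUE) # #{x <  point}
  pmin(pmin(n_le, n - n_lt) / n, 0.5)
}

#' Exact two-dimensional half-space depth (rotating-line oracle)
#'
#' Exact Tukey depth in the plane by enumerating the finitely many closed
#' half-planes through the query point whose boundary is critical: for each
#' reference point, the two directions perpendicular to its offset from the
#' query, plus tiny angular perturbations either side to realise open-side
#' minima. Intended as a ground-truth oracle for validating the
#' random-direction approximation; cost is quadratic in n.
#'
#' @param point Numeric length-2 query point.
#' @param reference n x 2 numeric matrix (n <= 2000).
#' @return Depth in [0, 0.5].
#' @export
halfspace_depth_exact_2d <- function(point, reference) {
  reference <- as.matrix(reference)
  if (ncol(reference) != 2) stop("reference must be n x 2", call. = FALSE)
  n <- nrow(reference)
  if (n == 0) stop("reference is empty", call. = FALSE)
  if (n > 2000) stop("exact 2-D oracle limited to n <= 2000", call. = FALSE)
  offs <- sweep(reference, 2, as.numeric(point))
  r2 <- rowSums(offs^2)
  scale2 <- max(r2)
  coincident <- r2 <= 1e-24 * max(scale2, 1)
  n0 <- sum(coincident)
  if (n0 == n) return(0.5)
  d <- offs[!coincident, , drop = FALSE]
  ang <- atan2(d[, 2], d[, 1])
  base <- c(ang + pi / 2, ang - pi / 2)
  cand <- c(base, base + 1e-9, base - 1e-9)
  u <- cbind(cos(cand), sin(cand))
  # counts of points in the closed half-plane {x : u . (x - point) >= 0}
  counts <- colSums(d %*% t(u) >= 0)
  min((min(counts) + n0) / n, 0.5)
}

# Standardisation parameters for a reference cloud: per-metric median and
# IQR (falling back to sd, then 1, for degenerate spreads). Standardising
# before projection avoids direction starvation when metrics live on wildly
# different scales (metres vs kN/m).
cloud_standardizer <- function(reference) {
  center <- apply(reference, 2, stats::median)
  scale <- apply(reference, 2, stats::IQR)
  zero <- scale <= 0
  if (any(zero)) {
    sds <- apply(reference[, zero, drop = FALSE], 2, stats::sd)
    scale[zero] <- ifelse(is.finite(sds) & sds > 0, sds, 1)
  }
  list(center = center, scale = scale)
}

# Sample `n_directions` unit vectors uniformly on the (K-1)-sphere as
# normalised standard Gaussian draws. Returns an n_directions x K matrix.
sample_directions <- function(n_directions, k, seed) {
  with_seed(seed, {
    u <- matrix(stats::rnorm(n_directions * k), n_directions, k)
    norms <- sqrt(rowSums(u^2))
    norms[norms == 0] <- 1
    u / norms
  })
}

# Core of the random-direction approximation: depths of the rows of
# `points` w.r.t. `reference`, minimising the 1-D rank depth over the rows
# of the shared `directions` matrix. Both clouds must already be on a
# common (standardised) scale.
random_depth_core <- function(points, reference, directions) {
  n <- nrow(reference)
  proj_ref <- reference %*% t(directions)   # n x n_dir
  proj_pts <- points %*% t(directions)      # m x n_dir
  depth <- rep(0.5, nrow(points))
  for (j in seq_len(ncol(proj_ref))) {
    s <- sort.int(proj_ref[, j], method = "quick")
    p <- proj_pts[, j]
    n_le <- findInterval(p, s)
    n_lt <- findInterval(p, s, left.open = TRUE)
    depth <- pmin(depth, pmin(n_le, n - n_lt) / n)
  }
  depth
}

#' Random-direction Tukey depth
#'
#' Approximates half-space depth as the minimum over a shared set of random
#' unit directions of the one-dimensional rank depth of the projected query
#' relative to the projected reference. The same direction set is used for
#' every query point in a call, so results are reproducible and the
#' approximation never underestimates the exact depth.
#'
#' @param points m x K matrix of query points (a vector is treated as one
#'   point for K > 1, or as m scalar queries when K = 1 references are
#'   supplied as a vector).
#' @param reference n x K matrix, the reference cloud.
#' @param n_directions Number of random projection directions (default 1000).
#' @param seed Integer seed for the direction draw.
#' @param standardize Centre/scale each metric by the reference median and
#'   IQR before projecting (default TRUE). Exact depth is affine invariant,
#'   so this changes only the approximation's direction efficiency.
#' @return Numeric vector of m depths in [0, 0.5].
#' @export
random_tukey_depth <- function(points, reference, n_directions = 1000,
                               seed = 1, standardize = TRUE) {
  if (is.null(dim(reference))) reference <- matrix(reference, ncol = 1)
  reference <- unclass(as.matrix(reference))
  k <- ncol(reference)
  if (is.null(dim(points))) {
    points <- if (k == 1) matrix(points, ncol = 1) else matrix(points, nrow = 1)
  }
  points <- unclass(as.matrix(points))
  if (ncol(points) != k) {
    stop("query points and reference have different dimensions", call. = FALSE)
  }
  if (n_directions < 1) stop("need at least one direction", call. = FALSE)
  std <- if (standardize) cloud_standardizer(reference) else
    list(center = rep(0, k), scale = rep(1, k))
  ref_s <- sweep(sweep(reference, 2, std$center), 2, std$scale, "/")
  pts_s <- sweep(sweep(points, 2, std$center), 2, std$scale, "/")
  dirs <- sample_directions(n_directions, k, seed)
  random_depth_core(pts_s, ref_s, dirs)
}

#' Fit a depth model on a reference gait cloud
#'
#' Computes the random-direction half-space depth of every reference point
#' with respect to the reference cloud itself, then sets the depth cutoff to
#' the largest depth value q such that at least `coverage_level` of the
#' reference points are at least as deep as q (the tie-inclusive lower
#' (1 - coverage) quantile of the self-depths). The resulting model defines
#' the reference's central depth region and can score new clouds with
#' [depth_overlap()].
#'
#' @param reference A [gait_cloud()] (or numeric matrix) of n reference
#'   points; a warning is issued below n = 100.
#' @param coverage_level Nominal coverage of the depth region (default 0.95).
#' @param n_directions Number of shared random directions (default 1000).
#' @param seed Integer seed controlling the direction draw.
#' @param standardize Standardise metrics by reference median/IQR before
#'   projection (default TRUE).
#' @return An object of class `depth_model`: the reference, its self-depths,
#'   the cutoff, the direction set, and the standardisation parameters.
#' @export
fit_depth_model <- function(reference, coverage_level = 0.95,
                            n_directions = 1000, seed = 1,
                            standardize = TRUE) {
  if (is.null(dim(reference))) reference <- matrix(reference, ncol = 1)
  ref <- unclass(as.matrix(reference))
  storage.mode(ref) <- "double"
  n <- nrow(ref)
  if (n < 2) stop("reference cloud needs at least 2 points", call. = FALSE)
  if (n < 100) {
    warning("reference cloud has fewer than 100 points; the depth cutoff ",
            "will be unstable", call. = FALSE)
  }
  if (coverage_level <= 0 || coverage_level > 1) {
    stop("coverage_level must be in (0, 1]", call. = FALSE)
  }
  k <- ncol(ref)
  std <- if (standardize) cloud_standardizer(ref) else
    list(center = rep(0, k), scale = rep(1, k))
  ref_s <- sweep(sweep(ref, 2, std$center), 2, std$scale, "/")
  dirs <- sample_directions(n_directions, k, seed)
  depths <- random_depth_core(ref_s, ref_s, dirs)
  # tie-inclusive cutoff: the ceiling(c * n)-th largest self-depth
  cutoff <- sort(depths, decreasing = TRUE)[min(n, ceiling(coverage_level * n))]
  structure(
    list(reference = ref, depths = depths, cutoff = cutoff,
         coverage_level = coverage_level, n_directions = n_directions,
         seed = seed, directions = dirs, standardize = standardize,
         center = std$center, scale = std$scale,
         metrics = colnames(ref)),
    class = "depth_model"
  )
}

#' @export
print.depth_model <- function(x, ...) {
  cat("Half-space depth model (random-direction approximation)\n")
  cat(sprintf("  reference: %d points x %d metrics\n",
              nrow(x$reference), ncol(x$reference)))
  if (!is.null(x$metrics)) {
    cat("  metrics:  ", paste(x$metrics, collapse = ", "), "\n")
  }
  cat(sprintf("  directions: %d (seed %d)\n", x$n_directions, x$seed))
  cat(sprintf("  %.0f%% depth cutoff: %.4f (self-coverage %.3f)\n",
              100 * x$coverage_level, x$cutoff,
              mean(x$depths >= x$cutoff)))
  invisible(x)
}

#' Depth overlap of a new cloud with a fitted reference model
#'
#' Fraction of points in the new cloud whose half-space depth with respect
#' to the model's reference (computed with the model's stored directions,
#' so results replay bit-exactly) is at least the model's depth cutoff —
#' i.e. the fraction of new points falling inside the reference's central
#' depth region ("as deep or deeper" is tie-inclusive).
#'
#' @param model A `depth_model` from [fit_depth_model()].
#' @param new A [gait_cloud()] or matrix with the same metrics, in the same
#'   order, as the model's reference.
#' @return A proportion in [0, 1].
#' @export
depth_overlap <- function(model, new) {
  stopifnot(inherits(model, "depth_model"))
  if (is.null(dim(new))) new <- matrix(new, ncol = ncol(model$reference))
  new <- unclass(as.matrix(new))
  if (ncol(new) != ncol(model$reference)) {
    stop("new cloud has ", ncol(new), " metrics; model expects ",
         ncol(model$reference), call. = FALSE)
  }
  if (!is.null(model$metrics) && !is.null(colnames(new)) &&
      !identical(colnames(new), model$metrics)) {
    stop("metric names of new cloud (", paste(colnames(new), collapse = ", "),
         ") do not match the model (", paste(model$metrics, collapse = ", "),
         ")", call. = FALSE)
  }
  if (nrow(new) == 0) stop("new cloud is empty", call. = FALSE)
  new_s <- sweep(sweep(new, 2, model$center), 2, model$scale, "/")
  ref_s <- sweep(sweep(model$reference, 2, model$center), 2, model$scale, "/")
  depths <- random_depth_core(new_s, ref_s, model$directions)
  mean(depths >= model$cutoff)
}
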