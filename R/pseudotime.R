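## Elliptical cell-cycle manifold in the (G1S, G2M) score plane and
## rolling-circle pseudo-time expression trajectories with 95% CI bands.

#' Fit an ellipse to 2-D points by direct least squares
#'
#' Direct least-squares conic fit under the ellipse discriminant constraint
#' (numerically stable partitioned formulation), converted to geometric
#' parameters.
#'
#' @param points Matrix or data.frame with two columns (x = G1S score,
#'   y = G2M score by convention).
#' @return Object of class `EllipseModel`: list with `center` (cx, cy),
#'   `semi_axes` (a >= b > 0), `rotation_phi` (radians in [0, pi)), and the
#'   raw `conic` coefficients (A, B, C, D, E, F).
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)
  pts <- pts[complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 6L)
    stop("degenerate-fit error: need at least 6 points")
  x <- pts[, 1]; y <- pts[, 2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)),
                 error = function(e)
                   stop("degenerate-fit error: rank-deficient scatter ",
                        "(collinear points?)"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vec <- ev$vectors
  if (is.complex(vec)) {
    if (max(abs(Im(vec))) > 1e-6 * max(abs(Re(vec))))
      vec <- Re(vec)  # complex pairs cannot satisfy the ellipse condition
    else vec <- Re(vec)
  }
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok))
    stop("degenerate-fit error: no ellipse solution for these points")
  a1 <- vec[, ok[1]]
  conic <- c(a1, as.vector(Tm %*% a1))
  names(conic) <- c("A", "B", "C", "D", "E", "F")
  .conic_to_ellipse(conic)
}

.conic_to_ellipse <- function(conic) {
  A <- conic["A"]; B <- conic["B"]; C <- conic["C"]
  D <- conic["D"]; E <- conic["E"]; F <- conic["F"]
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  if (det(Q) <= 0) stop("degenerate-fit error: conic is not an ellipse")
  center <- as.vector(-0.5 * solve(Q, c(D, E)))
  const <- as.numeric(t(center) %*% Q %*% center + c(D, E) %*% center + F)
  if (Q[1, 1] < 0) { Q <- -Q; const <- -const }   # make Q positive definite
  eg <- eigen(Q, symmetric = TRUE)
  if (any(eg$values <= 0) || -const <= 0)
    stop("degenerate-fit error: conic is not a real ellipse")
  axes <- sqrt(-const / eg$values)       # eigenvalues descending -> axes asc
  i_major <- which.max(axes)
  u <- eg$vectors[, i_major]
  phi <- atan2(u[2], u[1]) %% pi
  structure(list(center = unname(center),
                 semi_axes = c(a = max(axes), b = min(axes)),
                 rotation_phi = unname(phi),
                 conic = conic),
            class = "EllipseModel")
}

#' @export
print.EllipseModel <- function(x, ...) {
  cat(sprintf(
    "EllipseModel: center (%.4g, %.4g), semi-axes a=%.4g b=%.4g, phi=%.4g rad\n",
    x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
    x$rotation_phi))
  invisible(x)
}

#' Points on an ellipse at given parametric angles
#'
#' @param ellipse An `EllipseModel`.
#' @param t Parametric angles (radians).
#' @return length(t) x 2 matrix of (x, y) coordinates.
#' @export
ellipse_points <- function(ellipse, t) {
  phi <- ellipse$rotation_phi
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  ua <- c(cos(phi), sin(phi)); ub <- c(-sin(phi), cos(phi))
  cbind(ellipse$center[1] + a * cos(t) * ua[1] + b * sin(t) * ub[1],
        ellipse$center[2] + a * cos(t) * ua[2] + b * sin(t) * ub[2])
}

#' Parametric angle of the nearest point on an ellipse
#'
#' Projects a point onto the ellipse by minimizing Euclidean distance over
#' the parametric angle (coarse grid then bounded 1-D refinement).
#'
#' @param point Length-2 numeric (x, y).
#' @param ellipse An `EllipseModel`.
#' @return Angle theta in [0, 2*pi).
#' @export
project_angle <- function(point, ellipse) {
  if (sqrt(sum((point - ellipse$center)^2)) < 1e-12)
    stop("ambiguity error: point coincides with the ellipse center")
  phi <- ellipse$rotation_phi
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, byrow = TRUE)
  q <- as.vector(R %*% (point - ellipse$center))  # rotate into ellipse frame
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  f <- function(t) (a * cos(t) - q[1])^2 + (b * sin(t) - q[2])^2
  grid <- seq(0, 2 * pi, length.out = 513L)[-513L]
  i <- which.min(f(grid))
  step <- 2 * pi / 512
  opt <- optimize(f, lower = grid[i] - step, upper = grid[i] + step,
                  tol = 1e-12)
  opt$minimum %% (2 * pi)
}

#' Project many points onto an ellipse
#' @param points n x 2 matrix.
#' @param ellipse An `EllipseModel`.
#' @return Numeric vector of parametric angles in [0, 2*pi).
#' @export
project_angles <- function(points, ellipse) {
  apply(as.matrix(points), 1, project_angle, ellipse = ellipse)
}

#' Rolling-circle pseudo-time expression profile along the ellipse
#'
#' For each anchor point on the fitted ellipse (uniform parametric grid),
#' the window is the set of cells whose (G1S, G2M) score point lies within
#' Euclidean distance `radius` of the anchor; the profile records the
#' windowed mean, SEM, and 95% CI (mean +/- 1.96 SEM, defined where the
#' window holds >= 2 cells) for every gene. When phase assignments are
#' supplied the grid is oriented so pseudo-time increases through
#' G1S -> S -> G2 -> G2M -> MG1 (majority vote along the grid) and the
#' origin is anchored at the angle of maximal smoothed G1S score.
#'
#' @param scores2d n x 2 matrix of (G1S, G2M) scores per cell.
#' @param expression n x G matrix of expression values to smooth.
#' @param ellipse An `EllipseModel` fitted to `scores2d`.
#' @param radius Rolling-circle radius in score units (default 0.5).
#' @param n_anchors Anchor grid size (default 360).
#' @param phases Optional per-cell assigned phases (enables orientation).
#' @param orient Apply phase orientation and G1S origin (default: TRUE when
#'   `phases` is given).
#' @return Object of class `TrajectoryProfile`: `anchor_angles` (oriented
#'   pseudo-time, increasing over [0, 2*pi)), `param_angles` (each anchor's
#'   original parametric angle on the ellipse), matrices `mean`, `sem`,
#'   `ci_low`, `ci_high` (anchors x genes), `n` (window sizes), and
#'   `orientation` metadata.
#' @export
rolling_profile <- function(scores2d, expression, ellipse, radius = 0.5,
                            n_anchors = 360, phases = NULL,
                            orient = !is.null(phases)) {
  if (radius <= 0) stop("radius error: radius must be > 0")
  s <- as.matrix(scores2d)
  ex <- as.matrix(expression)
  stopifnot(nrow(s) == nrow(ex))
  tg <- seq(0, 2 * pi, length.out = n_anchors + 1L)[-(n_anchors + 1L)]
  anchors <- ellipse_points(ellipse, tg)
  d2 <- outer(anchors[, 1], s[, 1], "-")^2 +
        outer(anchors[, 2], s[, 2], "-")^2
  inwin <- d2 <= radius^2
  nwin <- as.integer(rowSums(inwin))
  if (all(nwin == 0))
    stop("radius error: every rolling window is empty; increase radius")
  G <- ncol(ex)
  mean_m <- matrix(NA_real_, n_anchors, G,
                   dimnames = list(NULL, colnames(ex)))
  sem_m <- mean_m
  g1s_smooth <- rep(NA_real_, n_anchors)
  ph_count <- matrix(0L, n_anchors, 5L, dimnames = list(NULL, cc_phases()))
  for (k in seq_len(n_anchors)) {
    w <- which(inwin[k, ])
    if (!length(w)) next
    sub <- ex[w, , drop = FALSE]
    mean_m[k, ] <- colMeans(sub)
    if (length(w) >= 2L)
      sem_m[k, ] <- apply(sub, 2, sd) / sqrt(length(w))
    g1s_smooth[k] <- mean(s[w, 1])
    if (!is.null(phases)) {
      tb <- table(factor(phases[w], levels = cc_phases()))
      ph_count[k, ] <- as.integer(tb)
    }
  }
  angles <- tg
  flipped <- FALSE
  if (orient && !is.null(phases)) {
    circ_mean <- apply(ph_count, 2, function(wt) {
      if (sum(wt) == 0) return(NA_real_)
      atan2(sum(wt * sin(angles)), sum(wt * cos(angles))) %% (2 * pi)
    })
    cm <- circ_mean[!is.na(circ_mean)]
    if (length(cm) >= 3L) {
      gaps <- diff(c(cm, cm[1]))[seq_len(length(cm) - 1L)] %% (2 * pi)
      flipped <- sum(gaps) > (length(cm) - 1L) * pi
    }
    if (flipped) angles <- (2 * pi - angles) %% (2 * pi)
  }
  origin <- 0
  if (orient) {
    if (any(!is.na(g1s_smooth))) {
      origin <- angles[which.max(g1s_smooth)]
      angles <- (angles - origin) %% (2 * pi)
    }
  }
  ord <- order(angles)
  n_ord <- nwin[ord]
  mean_o <- mean_m[ord, , drop = FALSE]
  sem_o <- sem_m[ord, , drop = FALSE]
  ci_half <- 1.96 * sem_o
  structure(list(anchor_angles = angles[ord],
                 param_angles = tg[ord],
                 mean = mean_o, sem = sem_o,
                 ci_low = mean_o - ci_half, ci_high = mean_o + ci_half,
                 n = n_ord,
                 orientation = list(flipped = flipped,
                                    origin_angle = origin,
                                    radius = radius)),
            class = "TrajectoryProfile")
}

#' Long-format view of a trajectory profile
#'
#' @param x A `TrajectoryProfile`.
#' @param ... Unused.
#' @return Data.frame: gene, anchor_angle, mean, sem, ci_low, ci_high, n.
#' @export
as.data.frame.TrajectoryProfile <- function(x, ...) {
  genes <- colnames(x$mean)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(ncol(x$mean)))
  do.call(rbind, lapply(seq_along(genes), function(j) {
    data.frame(gene = genes[j], anchor_angle = x$anchor_angles,
               mean = x$mean[, j], sem = x$sem[, j],
               ci_low = x$ci_low[, j], ci_high = x$ci_high[, j],
               n = x$n, stringsAsFactors = FALSE)
  }))
}

#' Difference between two pseudo-time trajectories with pooled CI
#'
#' Profiles must share the anchor grid. The difference is meanA - meanB per
#' anchor and gene; its 95% CI half-width is
#' 1.96 * sqrt(semA^2 + semB^2). Missing anchors propagate as missing.
#'
#' @param profile_a,profile_b `TrajectoryProfile` objects on the same grid.
#' @return List: `anchor_angles`, matrices `diff`, `ci_low`, `ci_high`.
#' @export
compare_trajectories <- function(profile_a, profile_b) {
  if (length(profile_a$anchor_angles) != length(profile_b$anchor_angles) ||
      max(abs(profile_a$anchor_angles - profile_b$anchor_angles)) > 1e-9)
    stop("profiles are not on a common anchor grid")
  d <- profile_a$mean - profile_b$mean
  half <- 1.96 * sqrt(profile_a$sem^2 + profile_b$sem^2)
  list(anchor_angles = profile_a$anchor_angles,
       diff = d, ci_low = d - half, ci_high = d + half)
}
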