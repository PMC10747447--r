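# Shared fixtures and small independent oracles.

## Random rotation via QR of a Gaussian matrix, det +1.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Random camera ring with jittered parameters, aimed at `target`.
random_ring <- function(n = NULL, target = c(0, 0, 1)) {
  n <- n %||% sample(3:6, 1)
  mvkin::make_camera_ring(
    n = n,
    radius_m = runif(1, 2, 4),
    height_m = runif(1, 0.8, 1.8),
    focal_px = runif(1, 600, 1200),
    image_size_px = c(1920, 1080),
    target = target
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Noise-free pixel observations of a world point in every camera of a rig.
observe_point <- function(rig, X) {
  lapply(rig, function(cm) {
    list(camera = cm, px = mvkin:::project_points(cm, X)[1, 1:2])
  })
}

## Independent oracle: two-way one-observation-per-cell mean squares via
## stats::aov on the long format.
aov_mean_squares <- function(tab) {
  d <- data.frame(
    y = as.numeric(tab),
    subject = factor(rep(seq_len(nrow(tab)), ncol(tab))),
    rater = factor(rep(seq_len(ncol(tab)), each = nrow(tab)))
  )
  sm <- summary(stats::aov(y ~ subject + rater, data = d))[[1]]
  list(MSR = sm["subject", "Mean Sq"],
       MSC = sm["rater", "Mean Sq"],
       MSE = sm["Residuals", "Mean Sq"])
}

## Independent oracle: nonlinear least-squares triangulation minimising the
## summed squared reprojection error, started from the centroid of the
## camera targets and refined by Nelder-Mead then BFGS.
nls_triangulate <- function(observations, start) {
  obj <- function(X) {
    sum(vapply(observations, function(o) {
      uv <- mvkin:::project_points(o$camera, X)[1, 1:2]
      sum((uv - o$px)^2)
    }, numeric(1)))
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  list(point = fit$par, rss = fit$value)
}

## A rigid transform applied to a camera so that the new camera sees the
## transformed world exactly as the old one saw the original.
transform_camera <- function(cm, Q, d) {
  mvkin::camera_model(
    name = cm$name, focal_px = cm$focal_px, principal_px = cm$principal_px,
    image_size_px = cm$image_size_px,
    rotation = cm$rotation %*% t(Q),
    translation = as.numeric(cm$translation - cm$rotation %*% t(Q) %*% d)
  )
}

default_session_config <- function(seed = 42, repetitions = 5, ...) {
  mvkin::sim_config(seed = seed, repetitions = repetitions, ...)
}
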