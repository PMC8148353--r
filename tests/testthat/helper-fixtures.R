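# Shared fixtures and independent oracles, built in code at test time.

# filled disc (circle) mask: center (cx, cy), radius r, on an n x n grid
disc_mask <- function(r, cx = 100, cy = 100, n = 201) {
  x <- matrix(rep(0:(n - 1), each = n), n, n)   # col index = x
  y <- matrix(rep(0:(n - 1), times = n), n, n)  # row index = y
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# circle with one angular arc pushed to a different radius (polar-form
# construction; angles in degrees, package angle convention: y down,
# counter-clockwise on screen)
arc_disc_mask <- function(r, r_arc, arc_from, arc_to, cx = 100, cy = 100,
                          n = 201) {
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), times = n), n, n)
  phi <- (atan2(-(y - cy), x - cx) * 180 / pi) %% 360
  rad <- ifelse(phi >= arc_from & phi < arc_to, r_arc, r)
  sqrt((x - cx)^2 + (y - cy)^2) <= rad
}

# points on an ellipse boundary, optionally noisy
ellipse_points <- function(cx, cy, a, b, theta, n = 100, noise_sd = 0,
                           t = seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]) {
  x <- cx + a * cos(t) * cos(theta) - b * sin(t) * sin(theta)
  y <- cy + a * cos(t) * sin(theta) + b * sin(t) * cos(theta)
  if (noise_sd > 0) {
    x <- x + rnorm(n, 0, noise_sd)
    y <- y + rnorm(n, 0, noise_sd)
  }
  cbind(x, y)
}

# Brute-force Cohen's kappa from the explicit 2x2 contingency table --
# independent of region_kappa's proportion shortcut.
oracle_kappa <- function(a, b, bbox) {
  sa <- a[(bbox$y_min:bbox$y_max) + 1, (bbox$x_min:bbox$x_max) + 1]
  sb <- b[(bbox$y_min:bbox$y_max) + 1, (bbox$x_min:bbox$x_max) + 1]
  n11 <- sum(sa & sb); n10 <- sum(sa & !sb)
  n01 <- sum(!sa & sb); n00 <- sum(!sa & !sb)
  n <- n11 + n10 + n01 + n00
  po <- (n11 + n00) / n
  pe <- ((n11 + n10) / n) * ((n11 + n01) / n) +
        ((n01 + n00) / n) * ((n10 + n00) / n)
  if (pe >= 1) 1 else (po - pe) / (1 - pe)
}

# Independent ellipse-fit oracle: the classic one-shot constrained
# generalized eigenproblem on the full 6x6 scatter matrix (S a = lambda C a,
# solved via eigen(S^-1 C)), as opposed to the package's 3x3 block
# decomposition. Same centering/scaling preconditioning (mathematically
# neutral); needs noisy points so S is invertible.
oracle_fit_ellipse <- function(pts) {
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  s <- sqrt(2) / sqrt(mean((pts[, 1] - mx)^2 + (pts[, 2] - my)^2))
  x <- (pts[, 1] - mx) * s; y <- (pts[, 2] - my) * s
  D <- cbind(x^2, x * y, y^2, x, y, 1)
  S <- crossprod(D)
  C <- matrix(0, 6, 6); C[1, 3] <- C[3, 1] <- 2; C[2, 2] <- -1
  e <- eigen(solve(S) %*% C)
  ev <- Re(e$values); V <- Re(e$vectors)
  ok <- which(ev > 1e-9)
  a <- V[, ok[which.max(ev[ok])]]
  A <- a[1]; B <- a[2]; Cc <- a[3]; D2 <- a[4]; E <- a[5]; F <- a[6]
  v <- c(A * s^2, B * s^2, Cc * s^2,
         -2 * A * s^2 * mx - B * s^2 * my + D2 * s,
         -B * s^2 * mx - 2 * Cc * s^2 * my + E * s,
         A * s^2 * mx^2 + B * s^2 * mx * my + Cc * s^2 * my^2 -
           D2 * s * mx - E * s * my + F)
  conic_to_geometric(v)
}

rand_ellipse_geometry <- function() {
  a <- runif(1, 30, 60)
  list(cx = runif(1, 80, 140), cy = runif(1, 80, 140),
       a = a, b = runif(1, 15, a), theta = runif(1, 0, pi))
}

# small fast observer presets
zero_observer <- function()
  observer_model(radial_jitter_sd = 0, misalignment_prob = 0,
                 smoothing_window = 1)

# tiny-study config helper (single condition, no bias/perturbation)
tiny_config <- function(n = 3, seed = 99, observers = NULL, perturbation = 0,
                        condition = "normal") {
  n_images <- c(glaucoma = 0, dr = 0, normal = 0)
  n_images[condition] <- n
  pert <- c(glaucoma = 0, dr = 0, normal = 0)
  pert[condition] <- perturbation
  if (is.null(observers))
    observers <- list(od1 = zero_observer(), od2 = zero_observer())
  synthetic_study_config(n_images = n_images, perturbation = pert,
                         observers = observers, seed = seed)
}
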