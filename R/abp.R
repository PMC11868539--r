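## Active Brownian particle swimmers confined to a compartment polygon.

#' Simulate confined active Brownian swimmers
#'
#' Each swimmer moves at constant speed `v_umps` while its orientation
#' diffuses with rotational diffusion \eqn{D_r = 1/\tau} (persistence time
#' `tau_s`). Walls of the confining polygon reflect swimmers specularly (both
#' position and swimming direction), and every wall contact is logged with
#' position, incidence angle and the normal momentum transfer per unit mass
#' (\eqn{2 v |\cos\alpha|}) — the microscopic origin of swim pressure.
#'
#' @param domain two-column matrix: a simple polygon (µm), or `NULL` for
#'   unbounded motion.
#' @param n number of swimmers.
#' @param v_umps swimming speed (µm/s), default 3.5.
#' @param tau_s persistence time (s), default 1.
#' @param dt_s integration step (s); must satisfy
#'   `v*dt <= 0.1 * min wall segment length` for reliable wall resolution.
#' @param duration_s simulated duration (s).
#' @param seed integer RNG seed.
#' @param sampling_dt_s output sampling interval (s), default `dt_s`.
#' @return list with `tracks` (data.frame: particle, frame, t_s, x_um, y_um,
#'   theta), and `collisions` (data.frame: particle, t_s, x_um, y_um,
#'   incidence_deg, dv_normal_umps).
#' @export
simulate_abp <- function(domain, n, v_umps = 3.5, tau_s = 1, dt_s = 0.05,
                         duration_s = 60, seed = 1L,
                         sampling_dt_s = dt_s) {
  stopifnot(n >= 1, v_umps > 0, tau_s > 0, dt_s > 0, duration_s > 0)
  if (!is.null(domain)) {
    domain <- as.matrix(domain)
    if (!is_simple_polygon(domain)) stop("domain polygon is not simple")
    wall_len <- sqrt(rowSums((domain - domain[c(2:nrow(domain), 1), ])^2))
    if (v_umps * dt_s > 0.1 * min(wall_len))
      stop(sprintf("dt too large to resolve wall crossings: v*dt = %.3g um > 0.1 * min wall segment = %.3g um",
                   v_umps * dt_s, 0.1 * min(wall_len)))
  }
  set.seed(seed)
  nstep <- ceiling(duration_s / dt_s)
  keep <- max(1L, round(sampling_dt_s / dt_s))
  sig_th <- sqrt(2 * dt_s / tau_s)

  if (is.null(domain)) {
    # unbounded: fully vectorised per particle
    tracks <- do.call(rbind, lapply(seq_len(n), function(p) {
      th <- cumsum(c(runif(1, 0, 2 * pi), rnorm(nstep, 0, sig_th)))
      x <- cumsum(c(0, v_umps * dt_s * cos(th[-(nstep + 1)])))
      y <- cumsum(c(0, v_umps * dt_s * sin(th[-(nstep + 1)])))
      idx <- seq(1, nstep + 1, by = keep)
      data.frame(particle = p, frame = seq_along(idx),
                 t_s = (idx - 1) * dt_s, x_um = x[idx], y_um = y[idx],
                 theta = th[idx])
    }))
    return(list(tracks = tracks, collisions = data.frame()))
  }

  ctr <- poly_centroid(domain)
  nwall <- nrow(domain)
  w1 <- domain; w2 <- domain[c(2:nwall, 1), ]
  # start positions: uniform rejection sampling inside the polygon
  bb <- apply(domain, 2, range)
  pos <- matrix(NA_real_, n, 2)
  filled <- 0L
  while (filled < n) {
    cand <- cbind(runif(n * 4, bb[1, 1], bb[2, 1]),
                  runif(n * 4, bb[1, 2], bb[2, 2]))
    inside <- mgcv::in.out(rbind(domain, domain[1, ]), cand)
    cand <- cand[inside, , drop = FALSE]
    take <- min(nrow(cand), n - filled)
    if (take > 0) pos[filled + seq_len(take), ] <- cand[seq_len(take), ]
    filled <- filled + take
  }
  th <- runif(n, 0, 2 * pi)
  coll <- list()
  out <- vector("list", floor(nstep / keep) + 1L)
  out[[1]] <- cbind(seq_len(n), 0, pos, th)
  oi <- 1L
  for (s in seq_len(nstep)) {
    th <- th + rnorm(n, 0, sig_th)
    for (p in seq_len(n)) {
      res <- advance_reflect(pos[p, ], th[p], v_umps * dt_s, w1, w2, ctr)
      pos[p, ] <- res$pos; th[p] <- res$theta
      if (length(res$hits)) {
        for (h in res$hits)
          coll[[length(coll) + 1L]] <-
            c(p, s * dt_s, h$pt, h$incidence, 2 * v_umps * abs(cos(h$incidence)))
      }
    }
    if (s %% keep == 0L) {
      oi <- oi + 1L
      out[[oi]] <- cbind(seq_len(n), s * dt_s, pos, th)
    }
  }
  tr <- do.call(rbind, out[seq_len(oi)])
  tracks <- data.frame(particle = tr[, 1], t_s = tr[, 2], x_um = tr[, 3],
                       y_um = tr[, 4], theta = tr[, 5])
  tracks <- tracks[order(tracks$particle, tracks$t_s), ]
  tracks$frame <- ave(tracks$t_s, tracks$particle, FUN = seq_along)
  collisions <- if (length(coll)) {
    m <- do.call(rbind, coll)
    data.frame(particle = m[, 1], t_s = m[, 2], x_um = m[, 3], y_um = m[, 4],
               incidence_deg = m[, 5] * 180 / pi, dv_normal_umps = m[, 6])
  } else data.frame()
  list(tracks = tracks, collisions = collisions)
}

# advance one particle by distance `len` along heading `theta`, reflecting
# specularly off polygon walls (w1 -> w2 segments); returns hits for the log
advance_reflect <- function(p, theta, len, w1, w2, ctr, max_bounce = 8L) {
  hits <- list()
  dirv <- c(cos(theta), sin(theta))
  for (b in seq_len(max_bounce)) {
    q <- p + len * dirv
    hit <- first_wall_crossing(p, q, w1, w2)
    if (is.null(hit)) { p <- q; break }
    # move to the wall, reflect remaining path and heading about the wall
    tvec <- hit$tangent
    p <- hit$pt
    remaining <- len * (1 - hit$t)
    # reflect direction: d' = 2 (d.t) t - d
    dt_ <- sum(dirv * tvec)
    newdir <- 2 * dt_ * tvec - dirv
    inc <- acos(pmin(1, abs(sum(dirv * hit$normal))))  # from normal
    hits[[length(hits) + 1L]] <- list(pt = hit$pt, incidence = inc)
    dirv <- newdir / sqrt(sum(newdir^2))
    # nudge off the wall to avoid re-detecting the same crossing
    p <- p + 1e-9 * dirv
    len <- remaining
    if (len <= 0) break
  }
  list(pos = p, theta = atan2(dirv[2], dirv[1]), hits = hits)
}

# earliest intersection of segment p->q with any wall; returns param t, point,
# unit tangent and inward normal
first_wall_crossing <- function(p, q, w1, w2) {
  d <- q - p
  e <- w2 - w1
  denom <- d[1] * e[, 2] - d[2] * e[, 1]
  wp <- cbind(w1[, 1] - p[1], w1[, 2] - p[2])
  t_ <- (wp[, 1] * e[, 2] - wp[, 2] * e[, 1]) / denom
  u_ <- (wp[, 1] * d[2] - wp[, 2] * d[1]) / denom
  ok <- is.finite(t_) & t_ > 1e-12 & t_ <= 1 & u_ >= 0 & u_ <= 1
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.min(t_[ok])]
  tv <- e[i, ] / sqrt(sum(e[i, ]^2))
  nv <- c(-tv[2], tv[1])
  # orient normal against the motion (pointing back into the domain)
  if (sum(nv * d) > 0) nv <- -nv
  list(t = t_[i], pt = p + t_[i] * d, tangent = tv, normal = nv, wall = i)
}

#' Estimate swimmer speed from frame-rate-limited tracks
#'
#' At a frame interval comparable to the persistence time, raw frame-to-frame
#' displacement underestimates the true speed because the path curves between
#' frames. The default `"msd"` method inverts the persistent-random-walk
#' mean-squared displacement
#' \eqn{MSD(\Delta t) = 2 v^2 \tau^2 (\Delta t/\tau + e^{-\Delta t/\tau} - 1)}
#' at lag one using the (independently measured) persistence time;
#' `"displacement"` returns the naive mean |frame displacement| / dt.
#'
#' @param tracks data.frame with `particle`, `t_s`, `x_um`, `y_um`.
#' @param tau_s persistence time used by the `"msd"` correction (s).
#' @param method `"msd"` or `"displacement"`.
#' @return data.frame with per-particle `v_umps`; attribute `mean_v_umps`.
#' @export
estimate_swimmer_speed <- function(tracks, tau_s = 1,
                                   method = c("msd", "displacement")) {
  method <- match.arg(method)
  per <- lapply(split(tracks, tracks$particle), function(d) {
    d <- d[order(d$t_s), ]
    dt <- median(diff(d$t_s))
    dx <- diff(d$x_um); dy <- diff(d$y_um)
    if (method == "displacement") {
      v <- mean(sqrt(dx^2 + dy^2)) / dt
    } else {
      msd1 <- mean(dx^2 + dy^2)
      fac <- 2 * tau_s^2 * (dt / tau_s + exp(-dt / tau_s) - 1)
      v <- sqrt(msd1 / fac)
    }
    data.frame(particle = d$particle[1], v_umps = v)
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  attr(out, "mean_v_umps") <- mean(out$v_umps)
  out
}
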