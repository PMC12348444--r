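# Independent brute-force oracle for the analytic integrating-sphere bounce
# model: geometric ray tracing of diffuse light. Rays start
# cosine-distributed from random wall points, travel chords, and are
# attenuated by the local surface reflectance; weight landing on the
# detector port is tallied. Shares no code with the analytic model.
trace_diffuse_detected <- function(geometry, n_rays, seed,
                                   rho_overrides = list()) {
  set.seed(seed)
  Rs <- geometry$radius_mm
  ports <- geometry$ports
  axes <- vapply(ports, `[[`, numeric(3), "axis")
  cos_caps <- vapply(ports, `[[`, 0, "cos_cap")
  rho_of <- function(nm) {
    if (!is.null(rho_overrides[[nm]])) return(rho_overrides[[nm]])
    r <- ports[[nm]]$rho
    if (is.numeric(r)) r[1] else 0
  }
  wall_rho <- geometry$wall_rho[1]

  sample_wall <- function(n) {
    out <- matrix(NA_real_, n, 3)
    need <- seq_len(n)
    while (length(need)) {
      m <- length(need)
      z <- stats::runif(m, -1, 1); phi <- stats::runif(m, 0, 2 * pi)
      r <- sqrt(1 - z^2)
      P <- cbind(r * cos(phi), r * sin(phi), z)
      in_port <- rep(FALSE, m)
      for (j in seq_len(ncol(axes)))
        in_port <- in_port | (P %*% axes[, j])[, 1] > cos_caps[j]
      ok <- !in_port
      out[need[ok], ] <- P[ok, , drop = FALSE]
      need <- need[!ok]
    }
    out * Rs
  }
  cosine_dir <- function(P) {
    n_in <- -P / Rs
    ct <- sqrt(stats::runif(nrow(P))); st <- sqrt(1 - ct^2)
    phi <- stats::runif(nrow(P), 0, 2 * pi)
    ref <- cbind(-n_in[, 2], n_in[, 1], 0)
    deg <- abs(n_in[, 3]) > 0.99
    ref[deg, ] <- matrix(rep(c(1, 0, 0), sum(deg)), ncol = 3, byrow = TRUE)
    ref <- ref - n_in * rowSums(ref * n_in)
    ref <- ref / sqrt(rowSums(ref^2))
    e2 <- cbind(n_in[, 2] * ref[, 3] - n_in[, 3] * ref[, 2],
                n_in[, 3] * ref[, 1] - n_in[, 1] * ref[, 3],
                n_in[, 1] * ref[, 2] - n_in[, 2] * ref[, 1])
    st * cos(phi) * ref + st * sin(phi) * e2 + ct * n_in
  }

  P <- sample_wall(n_rays)
  w <- rep(1, n_rays)
  detected <- 0
  for (b in 1:400) {
    D <- cosine_dir(P)
    t_chord <- -2 * rowSums(P * D)
    Q <- P + D * t_chord
    # renormalize: radial floating-point error is exponentially amplified
    # by the chord update, so pin landing points back onto the sphere
    qn <- Q / sqrt(rowSums(Q^2))
    Q <- qn * Rs
    region <- rep("wall", nrow(Q))
    for (j in seq_len(ncol(axes))) {
      hit <- (qn %*% axes[, j])[, 1] > cos_caps[j] & region == "wall"
      region[hit] <- names(ports)[j]
    }
    detected <- detected + sum(w[region == "detector"])
    alive <- region != "detector"
    rho <- ifelse(region == "wall", wall_rho, vapply(region, rho_of, 0))
    w <- w * rho
    alive <- alive & w > 1e-9
    if (!any(alive)) break
    P <- Q[alive, , drop = FALSE]
    w <- w[alive]
  }
  detected / n_rays
}
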