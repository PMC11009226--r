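#' Parameters for the toy hydration-trajectory generator
#'
#' Builds trajectories of one amide fragment (OC, N, HN) plus water molecules
#' (OW with two HW) in a cubic periodic box, with three statistical designs:
#'
#' * `"uniform"`: waters placed uniformly at random every frame (ideal-gas
#'   reference for radial-distribution tests).
#' * `"designed_shell"`: `n_shell` waters donate one H each at distances
#'   drawn around `shell_r_peak` from the carbonyl O, pointing inward, so the
#'   first-shell hydrogen count is constructed exactly; remaining waters stay
#'   outside the shell.
#' * `"telegraph_hbond"`: one water is permanently strongly bound (H at
#'   ~1.65 A) and a second, tagged water switches its donated H between a
#'   bound distance (~1.85 A) and an unbound distance (~3.0 A) following a
#'   two-state telegraph process with rates `telegraph_rates` (ps^-1); the
#'   stationary bound fraction is `on / (on + off)`.
#'
#' @param n_frames number of frames (> 0).
#' @param n_waters number of water molecules (> 0).
#' @param box_length cubic box edge, Angstrom; must exceed twice the maximum
#'   shell radius.
#' @param shell_model one of `"uniform"`, `"designed_shell"`,
#'   `"telegraph_hbond"`.
#' @param shell_r_peak target first-shell O...H distance, Angstrom.
#' @param shell_width Gaussian spread of the shell distances, Angstrom.
#' @param n_shell number of donated shell hydrogens (designed_shell mode).
#' @param telegraph_rates named vector `c(on = , off = )`, ps^-1 (>= 0).
#' @param bound_r,unbound_r tagged-water H distances in the two telegraph
#'   states, Angstrom.
#' @param frame_dt frame spacing, ps (> 0).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return An object of class `traj_gen_params`.
#' @export
traj_gen_params <- function(n_frames = 100, n_waters = 20, box_length = 28,
                            shell_model = c("uniform", "designed_shell",
                                            "telegraph_hbond"),
                            shell_r_peak = 1.65, shell_width = 0.08,
                            n_shell = 2,
                            telegraph_rates = c(on = 2, off = 1),
                            bound_r = 1.85, unbound_r = 3.0,
                            frame_dt = 0.1, seed = 1L) {
  shell_model <- match.arg(shell_model)
  stopifnot(n_frames > 0, n_waters > 0, frame_dt > 0, shell_width > 0)
  if (any(telegraph_rates < 0)) stop("telegraph rates must be non-negative")
  if (!all(c("on", "off") %in% names(telegraph_rates)))
    stop("telegraph_rates must be named c(on=, off=)")
  max_shell <- max(shell_r_peak, unbound_r) + 2
  if (box_length <= 2 * max_shell)
    stop("box_length must exceed twice the maximum shell radius (",
         2 * max_shell, " A)")
  structure(list(n_frames = as.integer(n_frames),
                 n_waters = as.integer(n_waters), box_length = box_length,
                 shell_model = shell_model, shell_r_peak = shell_r_peak,
                 shell_width = shell_width, n_shell = as.integer(n_shell),
                 telegraph_rates = telegraph_rates,
                 bound_r = bound_r, unbound_r = unbound_r,
                 frame_dt = frame_dt, seed = as.integer(seed)),
            class = "traj_gen_params")
}

## internal: n random unit vectors (rows)
random_unit_vectors <- function(n) {
  u <- matrix(rnorm(3L * n), ncol = 3L)
  u / sqrt(rowSums(u * u))
}

## internal: water H positions for OW rows and random orientations.
## O-H bond length 0.96 A, H-O-H angle 104.5 degrees.
water_hydrogens <- function(ow) {
  n <- nrow(ow)
  u1 <- random_unit_vectors(n)
  # second bond direction: rotate u1 by 104.5 deg within a random plane
  aux <- random_unit_vectors(n)
  perp <- aux - u1 * rowSums(aux * u1)
  perp <- perp / sqrt(rowSums(perp * perp))
  ang <- 104.5 * pi / 180
  u2 <- cos(ang) * u1 + sin(ang) * perp
  list(h1 = ow + 0.96 * u1, h2 = ow + 0.96 * u2)
}

## internal: water with its donated H fixed at `hpos` pointing toward `target`
## from direction u (unit, target -> H); the second H points outward so its
## distance from `target` always exceeds |OW - target|.
donor_water <- function(target, r_h, u) {
  h1 <- target + r_h * u
  ow <- target + (r_h + 0.96) * u
  aux <- random_unit_vectors(1L)[1L, ]
  perp <- aux - u * sum(aux * u)
  perp <- perp / sqrt(sum(perp * perp))
  ang <- (180 - 104.5) * pi / 180   # measured from the outward direction u
  v <- cos(ang) * u + sin(ang) * perp
  if (sum(v * u) < 0) v <- v - 2 * u * sum(v * u)  # force outward hemisphere
  h2 <- ow + 0.96 * v
  rbind(ow, h1, h2)
}

#' Simulate a toy hydration trajectory
#'
#' See [traj_gen_params()] for the three shell models. The amide fragment sits
#' at the box center; bulk waters are resampled if any two atoms fall closer
#' than 0.5 Angstrom (an error is raised if the density makes this
#' impossible).
#'
#' @param params a [traj_gen_params()] object.
#' @return A [trajectory()] with labels in the order
#'   `OC, N, HN, (OW, HW, HW) * n_waters`.
#' @examples
#' tr <- simulate_trajectory(traj_gen_params(n_frames = 5, n_waters = 5))
#' tr
#' @export
simulate_trajectory <- function(params) {
  stopifnot(inherits(params, "traj_gen_params"))
  L <- params$box_length
  oc <- c(L, L, L) / 2
  nn <- oc + c(2.4, 0, 0)
  hn <- nn + c(0.62, 0.78, 0)   # ~1 A from N, away from the carbonyl
  n_special <- switch(params$shell_model,
                      uniform = 0L,
                      designed_shell = params$n_shell,
                      telegraph_hbond = 2L)
  if (params$n_waters < n_special)
    stop("n_waters too small for shell model ", params$shell_model)
  n_bulk <- params$n_waters - n_special
  labels <- c("OC", "N", "HN",
              rep(c("OW", "HW", "HW"), params$n_waters))
  bulk_min_r <- max(params$shell_r_peak, params$unbound_r) + 0.96 + 0.8

  with_seed(params$seed, {
    # telegraph state path (shared across frames), exact per-frame propagator
    if (params$shell_model == "telegraph_hbond") {
      kon <- params$telegraph_rates[["on"]]
      koff <- params$telegraph_rates[["off"]]
      p <- exchange_populations(koff, kon, params$frame_dt)
      # state 1 = bound (leaves with koff), state 2 = unbound
      p_stat_bound <- if (kon + koff > 0) kon / (kon + koff) else 1
      state <- integer(params$n_frames)
      state[1L] <- if (runif(1L) < p_stat_bound) 1L else 2L
      if (params$n_frames > 1L) for (i in 2:params$n_frames) {
        stay <- p[state[i - 1L], state[i - 1L]]
        state[i] <- if (runif(1L) < stay) state[i - 1L] else 3L - state[i - 1L]
      }
      u_strong <- c(-1, 0, 0)
      u_tagged <- c(0, -1, 0)
    }
    frames <- vector("list", params$n_frames)
    for (fi in seq_len(params$n_frames)) {
      special <- NULL
      if (params$shell_model == "designed_shell" && n_special > 0L) {
        for (k in seq_len(n_special)) {
          r <- -1
          while (r <= 0.9 || r >= bulk_min_r - 1.0)
            r <- rnorm(1L, params$shell_r_peak, params$shell_width)
          u <- random_unit_vectors(1L)[1L, ]
          special <- rbind(special, donor_water(oc, r, u))
        }
      } else if (params$shell_model == "telegraph_hbond") {
        r1 <- abs(rnorm(1L, params$shell_r_peak, 0.03))
        special <- donor_water(oc, r1, u_strong)
        r2 <- if (state[fi] == 1L) params$bound_r else params$unbound_r
        r2 <- abs(rnorm(1L, r2, 0.03))
        special <- rbind(special, donor_water(oc, r2, u_tagged))
      }
      # bulk waters, uniformly random; keep clear of the shell in the
      # structured modes so constructed counts stay exact
      keep_clear <- params$shell_model != "uniform"
      ow <- matrix(runif(3L * n_bulk, 0, L), ncol = 3L)
      if (n_bulk > 0L) {
        for (tries in seq_len(200L)) {
          bad <- rep(FALSE, n_bulk)
          if (keep_clear)
            bad <- bad | (min_image_dist(oc, ow, L) < bulk_min_r)
          # pairwise O-O clashes (0.5 A overlap rule), decoded straight from
          # the packed distance vector: column i of length n-i starts after
          # starts[i] elements
          if (n_bulk > 1L) {
            kk <- which(stats::dist(ow) < 0.5)
            if (length(kk)) {
              starts <- cumsum(c(0L, (n_bulk - 1L):1L))
              i <- findInterval(kk - 1L, starts)
              j <- kk - starts[i] + i
              bad[unique(c(i, j))] <- TRUE
            }
          }
          if (!is.null(special))
            for (k in seq_len(nrow(special)))
              bad <- bad | (min_image_dist(special[k, ], ow, L) < 1.0)
          if (!any(bad)) break
          if (tries == 200L)
            stop("impossible density: could not place waters without overlap")
          ow[bad, ] <- matrix(runif(3L * sum(bad), 0, L), ncol = 3L)
        }
      }
      hw <- water_hydrogens(ow)
      coords <- matrix(NA_real_, 3L + 3L * params$n_waters, 3L)
      coords[1L, ] <- oc; coords[2L, ] <- nn; coords[3L, ] <- hn
      row0 <- 3L
      if (!is.null(special)) {
        coords[row0 + seq_len(nrow(special)), ] <- special
        row0 <- row0 + nrow(special)
      }
      if (n_bulk > 0L) {
        base <- row0 + 3L * (seq_len(n_bulk) - 1L)
        coords[base + 1L, ] <- ow
        coords[base + 2L, ] <- hw$h1
        coords[base + 3L, ] <- hw$h2
      }
      frames[[fi]] <- list(coords = coords,
                           time = (fi - 1L) * params$frame_dt)
    }
    tr <- trajectory(labels, frames, box_length = L)
    if (params$shell_model == "telegraph_hbond")
      tr$telegraph_state <- state
    tr
  })
}
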