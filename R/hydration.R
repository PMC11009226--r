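#' Radial distribution function between two atom roles
#'
#' Minimum-image pair histogram between `center_role` and `partner_role`
#' atoms, normalized per frame and per center by the ideal-gas expectation
#' `rho * V_shell(r)`, with the partner density `rho` taken from the box
#' volume. Exact shell volumes `(4 pi / 3)(r_hi^3 - r_lo^3)` are used rather
#' than the `4 pi r^2 dr` approximation.
#'
#' @param traj a [trajectory()].
#' @param center_role,partner_role atom labels (e.g. `"OC"`, `"HW"`).
#' @param bin_width histogram bin width, Angstrom.
#' @param r_max histogram range, Angstrom; at most half the box edge for a
#'   periodic trajectory.
#' @return An object of class `rdf_result`: `r` (bin centers), `g`,
#'   `counts`, `rho` (partner number density, A^-3), `n_frames`,
#'   `n_centers`.
#' @export
rdf <- function(traj, center_role = "OC", partner_role = "HW",
                bin_width = 0.05, r_max = NULL) {
  stopifnot(inherits(traj, "trajectory"), bin_width > 0)
  box <- traj$box_length
  if (is.null(r_max)) r_max <- if (is.null(box)) 10 else box / 2
  if (!is.null(box) && r_max > box / 2 + 1e-9)
    stop("r_max must not exceed half the box edge (", box / 2, " A)")
  ic <- which(traj$labels == center_role)
  ip <- which(traj$labels == partner_role)
  if (length(ic) == 0L) stop("no atoms with role ", center_role)
  if (length(ip) == 0L) stop("no atoms with role ", partner_role)
  nbin <- ceiling(r_max / bin_width)
  counts <- numeric(nbin)
  for (f in traj$frames) {
    for (c0 in ic) {
      d <- min_image_dist(f$coords[c0, ], f$coords[ip, , drop = FALSE], box)
      idx <- floor(d / bin_width) + 1L
      keep <- idx >= 1L & idx <= nbin
      counts <- counts + tabulate(idx[keep], nbins = nbin)
    }
  }
  edges <- seq(0, by = bin_width, length.out = nbin + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  vol <- if (is.null(box)) (4 / 3) * pi * r_max^3 else box^3
  rho <- length(ip) / vol
  shell <- (4 / 3) * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  norm <- length(traj$frames) * length(ic) * rho * shell
  structure(list(r = centers, g = counts / norm, counts = counts,
                 rho = rho, bin_width = bin_width,
                 n_frames = length(traj$frames), n_centers = length(ic),
                 center_role = center_role, partner_role = partner_role),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("RDF %s-%s: %d bins to %.2f A, peak g = %.2f at r = %.2f A\n",
              x$center_role, x$partner_role, length(x$r),
              max(x$r) + x$bin_width / 2, max(x$g), x$r[which.max(x$g)]))
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, ...) {
  plot(x$r, x$g, type = "l", xlab = "r (A)", ylab = "g(r)", ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Shell coordination number from an RDF
#'
#' `n(r_cut) = rho * integral_0^r_cut g(r) 4 pi r^2 dr` by the trapezoidal
#' rule, equal to the mean number of partner atoms inside `r_cut` up to
#' discretization error.
#'
#' @param rdf_result an [rdf()] result.
#' @param r_cut shell cutoff, Angstrom; must be within the histogram range.
#' @param rho partner density override, A^-3 (defaults to the density stored
#'   in the RDF).
#' @return mean coordination number (dimensionless).
#' @export
coordination_number <- function(rdf_result, r_cut, rho = NULL) {
  stopifnot(inherits(rdf_result, "rdf_result"))
  if (is.null(rho)) rho <- rdf_result$rho
  rmax <- max(rdf_result$r) + rdf_result$bin_width / 2
  if (r_cut <= 0 || r_cut > rmax + 1e-9)
    stop("r_cut must lie inside the RDF range (0, ", rmax, "]")
  keep <- rdf_result$r <= r_cut
  r <- c(0, rdf_result$r[keep])
  g <- c(0, rdf_result$g[keep])
  if (max(r) < r_cut) {
    # close the last partial shell: carry the g of the bin containing r_cut
    i_cut <- min(length(rdf_result$r), findInterval(r_cut, rdf_result$r) + 1L)
    r <- c(r, r_cut)
    g <- c(g, rdf_result$g[i_cut])
  }
  rho * trapz(r, g * 4 * pi * r^2)
}

## internal: map each hydrogen to its covalently bound heavy atom (nearest
## heavy-role atom within 1.25 A)
hydrogen_parents <- function(coords, h_idx, heavy_idx, box) {
  vapply(h_idx, function(ih) {
    d <- min_image_dist(coords[ih, ], coords[heavy_idx, , drop = FALSE], box)
    j <- which.min(d)
    if (d[j] > 1.25) NA_integer_ else heavy_idx[j]
  }, integer(1L))
}

#' Geometric hydrogen-bond counts
#'
#' A donor-hydrogen-acceptor triple counts as a hydrogen bond when the
#' donor-acceptor distance is below `d_max` and the hydrogen-bond angle is
#' below `theta_max`. Two angle conventions are provided because the common
#' literature phrasing "donor-proton-acceptor angle < 40 degrees" is
#' ambiguous: `"deviation"` (default) uses the angle between the D->H and
#' D->A vectors, which keeps near-linear bonds; `"at_proton"` uses the angle
#' D-H-A literally measured at the proton (which would exclude near-linear
#' bonds at small cutoffs).
#'
#' @param traj a [trajectory()].
#' @param donor_role,hydrogen_role,acceptor_role atom labels; hydrogens are
#'   assigned to the nearest donor-role atom within 1.25 Angstrom.
#' @param d_max donor-acceptor cutoff, Angstrom.
#' @param theta_max angle cutoff, degrees.
#' @param angle `"deviation"` or `"at_proton"`.
#' @return list with `per_frame` (integer vector) and `mean`.
#' @export
hbond_count <- function(traj, donor_role = "OW", hydrogen_role = "HW",
                        acceptor_role = "OC", d_max = 3.5, theta_max = 40,
                        angle = c("deviation", "at_proton")) {
  stopifnot(inherits(traj, "trajectory"))
  angle <- match.arg(angle)
  box <- traj$box_length
  id <- which(traj$labels == donor_role)
  ih <- which(traj$labels == hydrogen_role)
  ia <- which(traj$labels == acceptor_role)
  if (!length(id) || !length(ih) || !length(ia))
    stop("missing role among ", donor_role, "/", hydrogen_role, "/",
         acceptor_role)
  cosmax <- cos(theta_max * pi / 180)
  per_frame <- vapply(traj$frames, function(f) {
    parents <- hydrogen_parents(f$coords, ih, id, box)
    n <- 0L
    for (hi in seq_along(ih)) {
      dparent <- parents[hi]
      if (is.na(dparent)) next
      dh <- min_image_disp(f$coords[dparent, ],
                           f$coords[ih[hi], , drop = FALSE], box)[1L, ]
      for (ai in ia) {
        da <- min_image_disp(f$coords[dparent, ],
                             f$coords[ai, , drop = FALSE], box)[1L, ]
        rda <- sqrt(sum(da * da))
        if (rda >= d_max || rda < 1e-9) next
        if (angle == "deviation") {
          cosang <- sum(dh * da) / (sqrt(sum(dh * dh)) * rda)
        } else {
          ha_d <- -dh          # H -> D
          ha_a <- da - dh      # H -> A
          cosang <- sum(ha_d * ha_a) /
            (sqrt(sum(ha_d * ha_d)) * sqrt(sum(ha_a * ha_a)))
        }
        if (cosang > cosmax) n <- n + 1L
      }
    }
    n
  }, integer(1L))
  list(per_frame = per_frame, mean = mean(per_frame))
}

#' Nearest and second-nearest partner-hydrogen distances
#'
#' Per frame, the two smallest minimum-image distances between the carbonyl
#' oxygen (or any single `center_role` atom) and the partner hydrogens,
#' sorted so `r1 <= r2`, with probability-normalized histograms.
#'
#' @param traj a [trajectory()] with >= 2 partner atoms.
#' @param center_role,partner_role atom labels.
#' @param breaks histogram break points, Angstrom; by default 0.05 A bins
#'   spanning the observed distances.
#' @return list with `r1`, `r2` (per-frame vectors) and `r1_hist`,
#'   `r2_hist` (data.frames of bin centers and probabilities summing to 1).
#' @export
nearest_hw_distances <- function(traj, center_role = "OC",
                                 partner_role = "HW",
                                 breaks = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  ic <- which(traj$labels == center_role)
  ip <- which(traj$labels == partner_role)
  if (length(ic) != 1L) stop("need exactly one ", center_role, " atom")
  if (length(ip) < 2L) stop("need at least two ", partner_role, " atoms")
  box <- traj$box_length
  r12 <- vapply(traj$frames, function(f) {
    d <- min_image_dist(f$coords[ic, ], f$coords[ip, , drop = FALSE], box)
    sort(d, partial = 1:2)[1:2]
  }, numeric(2L))
  if (is.null(breaks))
    breaks <- seq(0, (ceiling(max(r12) / 0.05) + 1) * 0.05, by = 0.05)
  hist_of <- function(v) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    data.frame(r = h$mids, probability = h$counts / sum(h$counts))
  }
  list(r1 = r12[1L, ], r2 = r12[2L, ],
       r1_hist = hist_of(r12[1L, ]), r2_hist = hist_of(r12[2L, ]))
}

#' Classify frames as strongly or weakly hydrogen bonded
#'
#' A frame is SHB when the second-nearest carbonyl-O to water-H distance is
#' below `r_cut` (both shell hydrogens bound), otherwise WHB. The default
#' cutoff 2.55 Angstrom is the first minimum of the O...Hw radial
#' distribution, i.e. the edge of the first hydration shell.
#'
#' @param r2_series per-frame second-nearest distances, Angstrom.
#' @param r_cut classification cutoff, Angstrom (> 0).
#' @return list with `labels` (factor SHB/WHB), `shb_fraction`, and the
#'   binomial standard error `shb_fraction_se`.
#' @export
classify_hydration <- function(r2_series, r_cut = 2.55) {
  if (length(r2_series) == 0L) stop("empty r2 series")
  if (r_cut <= 0) stop("r_cut must be positive")
  lab <- factor(ifelse(r2_series < r_cut, "SHB", "WHB"),
                levels = c("SHB", "WHB"))
  p <- mean(lab == "SHB")
  list(labels = lab, shb_fraction = p,
       shb_fraction_se = sqrt(p * (1 - p) / length(lab)))
}
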