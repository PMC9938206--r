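#' Interaction force between the two cells
#'
#' Force exerted on cell i by its partner,
#' \code{F_i = - integral phi_i grad(dF_interaction/dphi_i) dr} with
#' \code{dF_interaction/dphi_1 = (3/4)(1 - phi_1^2) [gamma h(phi_2) -
#' eta lap h(phi_2)]}, gradients evaluated spectrally. In internal units
#' 1 aJ/um = 1 pN, so components are reported directly in piconewtons.
#' The repulsion-only (gamma) and adhesion-only (eta) parts are returned
#' separately; they sum to the total exactly by construction.
#'
#' @param phi1,phi2 \code{\link{pf_field}}s on one grid.
#' @param params a \code{\link{pf_params}}.
#' @return List with 3-vectors (pN) \code{F1}, \code{F2}, \code{F1_rep},
#'   \code{F1_adh}, \code{F2_rep}, \code{F2_adh}.
#' @export
interaction_force <- function(phi1, phi2, params) {
  stopifnot(inherits(phi1, "pf_field"), inherits(phi2, "pf_field"))
  if (!identical(phi1$grid$n, phi2$grid$n)) stop("fields must share one grid")
  g <- phi1$grid
  p <- params$internal
  a <- phi1$values
  b <- phi2$values
  h1 <- h_interp(a)
  h2 <- h_interp(b)
  lh1 <- spectral_laplacian(h1, g)
  lh2 <- spectral_laplacian(h2, g)
  one_cell <- function(phi, om, h_other, lh_other) {
    q_rep <- 0.75 * p$gamma * om * h_other
    q_adh <- -0.75 * p$eta * om * lh_other
    f_part <- function(q) {
      gq <- spectral_gradient(q, g)
      -c(sum(phi * gq$x), sum(phi * gq$y), sum(phi * gq$z)) * g$dV
    }
    list(rep = f_part(q_rep), adh = f_part(q_adh))
  }
  r1 <- one_cell(a, 1 - a^2, h2, lh2)
  r2 <- one_cell(b, 1 - b^2, h1, lh1)
  list(F1 = r1$rep + r1$adh, F2 = r2$rep + r2$adh,
       F1_rep = r1$rep, F1_adh = r1$adh,
       F2_rep = r2$rep, F2_adh = r2$adh)
}

#' Cell-cell contact area
#'
#' Area of cell 1's interface lying in contact with cell 2, measured as the
#' interface-area density of cell 1 weighted by an indicator of the
#' partner's interface presence:
#' \code{(3/(2 sqrt(2))) epsilon integral (grad phi_1)^2
#' 1[1 - phi_2^2 > threshold] dr}. For two membranes in contact the two
#' diffuse interfaces coincide, and this indicator captures essentially the
#' full profile weight of cell 1's interface over the contact patch (99.6\%
#' for coincident tanh profiles at the default threshold), so slab fixtures
#' reduce to the geometric patch area. An indicator on the partner's bulk
#' presence (h(phi_2) above a threshold) would cut roughly half the profile
#' weight at a coincident interface and systematically under-count.
#'
#' @param phi1,phi2 \code{\link{pf_field}}s on one grid.
#' @param epsilon interface width, um.
#' @param threshold indicator threshold on 1 - phi_2^2; default 0.1.
#' @return Contact area in um^2.
#' @export
contact_area <- function(phi1, phi2, epsilon, threshold = 0.1) {
  stopifnot(inherits(phi1, "pf_field"), inherits(phi2, "pf_field"))
  g <- phi1$grid
  gr <- spectral_gradient(phi1$values, g)
  dens <- gr$x^2 + gr$y^2 + gr$z^2
  ind <- (1 - phi2$values^2) > threshold
  3 * epsilon / (2 * sqrt(2)) * sum(dens[ind]) * g$dV
}

# minimum z-separation between the facing surfaces, column by column over
# the shared x-y footprint; negative once the surfaces interleave. This is a
# columnwise surrogate of the true gap, adequate for z-approach protocols.
min_gap_z <- function(phi1, phi2) {
  g <- phi1$grid
  n <- g$n
  in1 <- phi1$values > 0
  in2 <- phi2$values > 0
  dim(in1) <- c(n[1] * n[2], n[3])
  dim(in2) <- c(n[1] * n[2], n[3])
  zidx <- seq_len(n[3])
  both <- (rowSums(in1) > 0) & (rowSums(in2) > 0)
  if (!any(both)) return(NA_real_)
  top1 <- apply(in1[both, , drop = FALSE], 1, function(r) max(zidx[r]))
  bot2 <- apply(in2[both, , drop = FALSE], 1, function(r) min(zidx[r]))
  min(bot2 - top1) * g$dx
}

#' Peak forces of a collision trajectory
#'
#' Summary of the force curve on the right-hand (cell 2) side: with the
#' approach along -z, negative F_z means attraction toward the partner.
#'
#' @param trajectory a \code{pf_trajectory}.
#' @return List with \code{repulsion_peak} (max F_z, pN),
#'   \code{attraction_peak} (max -F_z over the whole run, pN),
#'   \code{post_reversal_attraction_peak} (max -F_z after reversal, pN) and
#'   the corresponding times.
#' @export
peak_forces <- function(trajectory) {
  f <- trajectory$force
  tz <- f$t
  fz <- f$F2z # z-component of force on cell 2
  rev_t <- trajectory$protocol$reversal_time
  post <- tz >= rev_t
  i_rep <- which.max(fz)
  i_att <- which.max(-fz)
  i_post <- which(post)[which.max(-fz[post])]
  list(repulsion_peak = fz[i_rep], repulsion_time = tz[i_rep],
       attraction_peak = -fz[i_att], attraction_time = tz[i_att],
       post_reversal_attraction_peak = -fz[i_post],
       post_reversal_attraction_time = tz[i_post])
}

#' Work to detach the two cells
#'
#' Integral of the attractive interaction force against the separation rate
#' over the retraction phase, \code{W = integral F_z v_rel dt} taken over
#' times after reversal where the force opposes separation, reported
#' positive. The integration runs from the reversal to the first observation
#' where |F_z| falls below \code{force_floor}, mirroring how the work is
#' read off an AFM retraction curve.
#'
#' @param trajectory a \code{pf_trajectory} covering the retraction phase.
#' @param force_floor cut-off force, pN (default 1).
#' @return Detachment work in fJ.
#' @export
detachment_work <- function(trajectory, force_floor = 1) {
  f <- trajectory$force
  rev_t <- trajectory$protocol$reversal_time
  if (max(f$t) <= rev_t)
    stop("trajectory does not cover the retraction phase")
  v_rel <- 2 * trajectory$protocol$speed_v
  sel <- f$t >= rev_t
  t <- f$t[sel]
  fz <- f$F2z[sel]
  # stop at the first force-free observation after the adhesion peak
  ipk <- which.max(-fz)
  small <- which(abs(fz) < force_floor & seq_along(fz) > ipk)
  if (length(small)) {
    keep <- seq_len(small[1])
    t <- t[keep]; fz <- fz[keep]
  }
  attr_f <- pmax(0, -fz) # attractive part opposing separation
  if (length(t) < 2) return(0)
  w_aJ <- v_rel * sum(diff(t) * (head(attr_f, -1) + tail(attr_f, -1)) / 2)
  w_aJ / 1000 # fJ
}

#' Write trajectory outputs to disk
#'
#' Writes the force / energy / contact (and geometry) time series as CSV
#' with full double precision, optional VTK snapshots of the fields, and a
#' JSON run manifest (configuration echo, parameter hash, package version)
#' sufficient to reproduce the run bit-exactly.
#'
#' @param trajectory a \code{pf_trajectory}.
#' @param destination output directory (created if needed).
#' @param snapshots also write stored snapshots as legacy-ASCII VTK
#'   structured-points files (default TRUE).
#' @return Invisibly, the manifest list.
#' @export
write_outputs <- function(trajectory, destination, snapshots = TRUE) {
  dir.create(destination, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    write_csv_full(df, file.path(destination, name))
  }
  wr(trajectory$force, "forces.csv")
  wr(trajectory$energy, "energies.csv")
  wr(trajectory$contact, "contact.csv")
  if (!is.null(trajectory$geometry)) wr(trajectory$geometry, "geometry.csv")
  manifest <- run_manifest(trajectory)
  jsonlite::write_json(manifest, file.path(destination, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (snapshots && length(trajectory$snapshots)) {
    for (i in seq_along(trajectory$snapshots)) {
      sn <- trajectory$snapshots[[i]]
      write_vtk_fields(
        file.path(destination, sprintf("snapshot_%03d.vtk", i)),
        trajectory$grid,
        list(phi1 = sn$phi1, phi2 = sn$phi2,
             h_total = h_interp(sn$phi1) + h_interp(sn$phi2)),
        title = sprintf("t=%.6g s", sn$t))
    }
  }
  invisible(manifest)
}

#' Read back a written trajectory's records
#'
#' @param destination directory written by \code{\link{write_outputs}}.
#' @return List with \code{force}, \code{energy}, \code{contact}, optional
#'   \code{geometry} data frames and the \code{manifest}.
#' @export
read_outputs <- function(destination) {
  rd <- function(name) {
    path <- file.path(destination, name)
    if (file.exists(path)) utils::read.csv(path, comment.char = "#") else NULL
  }
  list(force = rd("forces.csv"), energy = rd("energies.csv"),
       contact = rd("contact.csv"), geometry = rd("geometry.csv"),
       manifest = jsonlite::read_json(file.path(destination, "manifest.json"),
                                      simplifyVector = TRUE))
}

# full-precision CSV (doubles survive the round trip exactly); a comment
# header documents the on-disk units
write_csv_full <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: t s, forces pN, energies aJ, lengths um, areas um^2, volumes um^3", con)
  writeLines(paste(names(df), collapse = ","), con)
  rows <- apply(df, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(rows, con)
}

# manifest: everything needed to reproduce the run, plus a content hash
run_manifest <- function(trajectory) {
  cfg <- list(physics = trajectory$params$display,
              grid = list(n = trajectory$grid$n, dx = trajectory$grid$dx),
              protocol = unclass(trajectory$protocol))
  list(configuration = cfg,
       parameter_hash = config_hash(cfg),
       package_version = as.character(utils::packageVersion("rbcphase")),
       n_observations = nrow(trajectory$force))
}

#' Content hash of a configuration
#'
#' MD5 of the canonical serialisation of the physics/grid/protocol
#' configuration; changes if and only if some parameter changes.
#'
#' @param cfg configuration list.
#' @return Character MD5 digest.
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(canon(cfg)), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

#' Write scalar fields as a legacy-ASCII VTK structured-points file
#'
#' @param path output file.
#' @param grid a \code{\link{grid_spec}}.
#' @param fields named list of 3D arrays on \code{grid}.
#' @param title dataset title line.
#' @return Invisibly, \code{path}.
#' @export
write_vtk_fields <- function(path, grid, fields, title = "rbcphase fields") {
  con <- file(path, "w")
  on.exit(close(con))
  n <- grid$n
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", grid$dx, grid$dx, grid$dx),
               sprintf("POINT_DATA %d", prod(n))), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    # VTK expects x fastest, matching R's column-major order
    writeLines(formatC(as.vector(fields[[nm]]), format = "g", digits = 7),
               con)
  }
  invisible(path)
}
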