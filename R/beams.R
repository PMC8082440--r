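## Beam geometry on the gantry-couch sphere (IEC 61217 style convention).
##
## Patient coordinates: x = patient left, y = anterior, z = superior.
## A beam direction is the unit vector pointing from the isocenter toward the
## source. Gantry g rotates in the axial plane (g = 0 anterior, g = 90
## patient-left lateral); couch rotation c turns the gantry plane about the
## vertical (y) axis, so (g = 0, c) is anterior for every couch angle:
##   u(g, c) = (sin g cos c, cos g, -sin g sin c).

.deg2rad <- function(d) d * pi / 180

#' Normalize a gantry angle to [-180, 180)
#' @param g gantry angle(s) in degrees.
#' @export
normalize_gantry <- function(g) ((g + 180) %% 360) - 180

#' A single beam direction
#'
#' @param gantry_deg gantry angle in degrees (normalized to `[-180, 180)`).
#' @param couch_deg couch angle in degrees in `[-90, 90]`. Following the
#'   convention that couch -90 deliveries are realized at couch +90 with the
#'   gantry sign flipped, a couch of -90 is normalized to +90 with negated
#'   gantry.
#' @return a `beam_direction` with fields `gantry_deg`, `couch_deg`,
#'   `unit_vector`.
#' @export
beam_direction <- function(gantry_deg, couch_deg = 0) {
  stopifnot(couch_deg >= -90, couch_deg <= 90)
  if (couch_deg == -90) { couch_deg <- 90; gantry_deg <- -gantry_deg }
  g <- normalize_gantry(gantry_deg)
  structure(list(gantry_deg = g, couch_deg = as.numeric(couch_deg),
                 unit_vector = beam_unit_vector(g, couch_deg)),
            class = "beam_direction")
}

#' Unit source vector for (gantry, couch) in degrees
#' @param gantry_deg,couch_deg angles in degrees (vectorized).
#' @return 3-column matrix (x, y, z), one row per beam.
#' @export
beam_unit_vector <- function(gantry_deg, couch_deg) {
  g <- .deg2rad(gantry_deg); c <- .deg2rad(couch_deg)
  cbind(sin(g) * cos(c), cos(g), -sin(g) * sin(c))
}

#' Great-circle angular separation between two beam directions, degrees
#' @param a,b `beam_direction`s.
#' @return angle in `[0, 180]` degrees.
#' @export
angular_separation <- function(a, b) {
  d <- sum(a$unit_vector * b$unit_vector)
  acos(min(1, max(-1, d))) * 180 / pi
}

# pairwise separation matrix for a unit-vector matrix (degrees)
.pairwise_sep <- function(U) {
  d <- tcrossprod(U)
  d[d > 1] <- 1; d[d < -1] <- -1
  acos(d) * 180 / pi
}

#' An ordered set of beam directions
#'
#' @param gantry_deg,couch_deg numeric vectors of angles in degrees.
#' @param min_separation_deg minimum pairwise great-circle separation the set
#'   claims (0 = unconstrained); verified at construction.
#' @param label one of `CP_candidates`, `NCP_candidates`, `VMAT`, `BVMAT`,
#'   `selected`.
#' @return a `beam_set`: data frame of angles plus attributes `unit_vectors`,
#'   `min_separation_deg`, `label`.
#' @export
beam_set <- function(gantry_deg, couch_deg, min_separation_deg = 0,
                     label = "selected") {
  stopifnot(length(gantry_deg) == length(couch_deg))
  label <- match.arg(label, c("CP_candidates", "NCP_candidates", "VMAT",
                              "BVMAT", "selected"))
  cd <- as.numeric(couch_deg); gd <- as.numeric(gantry_deg)
  flip <- cd == -90
  gd[flip] <- -gd[flip]; cd[flip] <- 90
  gd <- normalize_gantry(gd)
  U <- beam_unit_vector(gd, cd)
  if (anyDuplicated(round(U, 9))) stop("beam_set: duplicate directions")
  if (min_separation_deg > 0 && length(gd) > 1) {
    S <- .pairwise_sep(U); diag(S) <- Inf
    if (min(S) < min_separation_deg - 1e-9) {
      stop("beam_set: pairwise separation ", round(min(S), 3),
           " below declared minimum ", min_separation_deg)
    }
  }
  structure(data.frame(gantry_deg = gd, couch_deg = cd),
            unit_vectors = U,
            min_separation_deg = min_separation_deg,
            label = label,
            class = c("beam_set", "data.frame"))
}

#' Number of beams in a set
#' @param bs a `beam_set`.
#' @export
n_beams <- function(bs) nrow(bs)

#' Extract beam i of a set as a `beam_direction`
#' @param bs a `beam_set`; @param i index.
#' @export
beam_at <- function(bs, i) beam_direction(bs$gantry_deg[i], bs$couch_deg[i])

# canonical (couch, then gantry) ascending ordering used for determinism
.order_beams <- function(gd, cd) order(cd, gd)

#' Coplanar candidate beams (equiangular, couch 0)
#'
#' @param spacing_deg gantry spacing in degrees; must divide 360. The default
#'   10 degrees yields the 36-beam candidate set.
#' @export
enumerate_coplanar_candidates <- function(spacing_deg = 10) {
  if (spacing_deg <= 0 || abs(360 / spacing_deg - round(360 / spacing_deg)) > 1e-9) {
    stop("spacing_deg must divide 360")
  }
  g <- normalize_gantry(seq(0, 360 - spacing_deg, by = spacing_deg))
  o <- .order_beams(g, rep(0, length(g)))
  beam_set(g[o], rep(0, length(g)), min_separation_deg = spacing_deg,
           label = "CP_candidates")
}

#' Default deliverability (collision) mask
#'
#' A configurable stand-in for machine-specific collision tests: couch-0
#' directions are always deliverable; for |couch| > 20 degrees, posterior
#' gantry angles beyond +/-100 degrees are excluded. This reproduces the
#' shape of a deliverable region (posterior couch-rotated beams collide with
#' the couch), not any specific linac.
#'
#' @return a `collision_mask`: function of (gantry_deg, couch_deg) vectors
#'   returning logicals.
#' @export
default_collision_mask <- function() {
  f <- function(gantry_deg, couch_deg) {
    ifelse(abs(couch_deg) <= 20, TRUE, abs(normalize_gantry(gantry_deg)) <= 100)
  }
  structure(f, class = c("collision_mask", "function"))
}

#' Collision mask admitting only coplanar beams
#' @export
coplanar_only_mask <- function() {
  structure(function(gantry_deg, couch_deg) couch_deg == 0,
            class = c("collision_mask", "function"))
}

#' Non-coplanar candidate beams
#'
#' Deterministic quasi-uniform sampling of the direction sphere: the 36
#' coplanar candidates are force-included first, then spherical-Fibonacci
#' points (restricted to couch angles in `[-90, 90]` and to the deliverable
#' region of `mask`) are greedily thinned so all pairwise great-circle
#' separations stay at or above `min_separation_deg`.
#'
#' @param min_separation_deg minimum pairwise separation in degrees (> 0).
#' @param mask a collision mask predicate, see [default_collision_mask()].
#' @export
enumerate_noncoplanar_candidates <- function(min_separation_deg = 10,
                                             mask = default_collision_mask()) {
  stopifnot(min_separation_deg > 0)
  # coplanar ring spacing: smallest divisor of 360 compatible with the
  # separation rule (10 degrees in the default configuration -> 36 beams)
  divs <- c(10, 12, 15, 18, 20, 24, 30, 36, 40, 45, 60, 90, 120, 180)
  cp_sp <- divs[divs >= min_separation_deg][1]
  if (is.na(cp_sp)) stop("min_separation_deg too large")
  cp <- enumerate_coplanar_candidates(max(10, cp_sp))
  keep_g <- cp$gantry_deg[mask(cp$gantry_deg, cp$couch_deg)]
  if (!length(keep_g)) stop("empty deliverable region")
  sel_g <- keep_g
  sel_c <- rep(0, length(keep_g))
  U <- beam_unit_vector(sel_g, sel_c)

  # spherical Fibonacci lattice, ~4x oversampled relative to the separation
  n_fib <- max(64L, ceiling(4 * 41253 / min_separation_deg^2)) # 41253 deg^2 per sphere
  k <- seq_len(n_fib) - 0.5
  phi <- (1 + sqrt(5)) / 2
  zs <- 1 - 2 * k / n_fib
  th <- 2 * pi * k / phi
  P <- cbind(sqrt(1 - zs^2) * cos(th), sqrt(1 - zs^2) * sin(th), zs)
  ang <- .vec_to_angles(P)
  ok <- mask(ang$gantry_deg, ang$couch_deg)
  P <- P[ok, , drop = FALSE]; ang <- lapply(ang, `[`, ok)

  cos_min <- cos(.deg2rad(min_separation_deg)) + 1e-12
  for (i in seq_len(nrow(P))) {
    if (max(U %*% P[i, ]) < cos_min) {
      U <- rbind(U, P[i, ])
      sel_g <- c(sel_g, ang$gantry_deg[i])
      sel_c <- c(sel_c, ang$couch_deg[i])
    }
  }
  o <- .order_beams(sel_g, sel_c)
  beam_set(sel_g[o], sel_c[o], min_separation_deg = min_separation_deg,
           label = "NCP_candidates")
}

# inverse of beam_unit_vector: unit vectors -> (gantry in [-180,180),
# couch in (-90, 90])
.vec_to_angles <- function(U) {
  g <- atan2(sqrt(U[, 1]^2 + U[, 3]^2), U[, 2]) * 180 / pi  # in [0, 180]
  c_ang <- atan2(-U[, 3], U[, 1]) * 180 / pi                # in (-180, 180]
  neg <- c_ang > 90 | c_ang <= -90
  g[neg] <- -g[neg]
  c_ang[neg] <- c_ang[neg] - sign(c_ang[neg]) * 180
  list(gantry_deg = normalize_gantry(g), couch_deg = c_ang)
}

#' Butterfly-VMAT class solution (20 IMRT beams)
#'
#' Three 60-degree arcs with 10-degree spacing: anterior and posterior
#' coplanar arcs of seven beams each centered at gantry 0 and 180, plus a
#' couch-90 anterior arc of six beams (gantry 0 excluded, already present in
#' the anterior coplanar arc).
#' @export
build_bvmat <- function() {
  g0 <- seq(-30, 30, by = 10)
  g180 <- normalize_gantry(180 + g0)
  g90 <- setdiff(g0, 0)
  gd <- c(g0, g180, g90)
  cd <- c(rep(0, 14), rep(90, 6))
  o <- .order_beams(gd, cd)
  beam_set(gd[o], cd[o], min_separation_deg = 0, label = "BVMAT")
}

#' Full-arc VMAT surrogate (21 coplanar equiangular IMRT beams)
#' @export
build_vmat_surrogate <- function() {
  g <- normalize_gantry(seq(0, 360 - 360 / 21, by = 360 / 21))
  o <- .order_beams(g, rep(0, 21))
  beam_set(g[o], rep(0, 21), min_separation_deg = 0, label = "VMAT")
}

#' Serialize a beam set to CSV (columns label, gantry_deg, couch_deg)
#' @param bs a `beam_set`; @param path output file.
#' @export
write_beam_set <- function(bs, path) {
  utils::write.csv(data.frame(label = attr(bs, "label"),
                              gantry_deg = bs$gantry_deg,
                              couch_deg = bs$couch_deg),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a beam set written by [write_beam_set()]
#' @param path CSV file.
#' @export
read_beam_set <- function(path) {
  d <- utils::read.csv(path)
  beam_set(d$gantry_deg, d$couch_deg, label = as.character(d$label[1]))
}
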