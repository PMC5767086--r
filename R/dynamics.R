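## Implicit-solvent Langevin dynamics: tabulated nonbond forces with cell
## lists and periodic boundaries, bonded terms, restraints, BAOAB NVT
## integration. Units: kJ/mol, nm, ps, amu (1 amu nm^2/ps^2 = 1 kJ/mol).

#' Simulation protocol
#'
#' The NVT Langevin contract of the engine. Defaults are the production
#' membrane settings: effective temperature kT = 2.24 kJ/mol (reproduces
#' liquid-phase bilayer structure), friction gamma = 0.5 / ps, a 5 fs time
#' step and the 1.2 nm nonbond cutoff with the neighbor list rebuilt every
#' step.
#'
#' @param kT Thermal energy, kJ/mol.
#' @param gamma Friction, 1/ps (0 disables the thermostat).
#' @param dt Time step, ps.
#' @param cutoff Nonbond cutoff, nm; must match the force field.
#' @param seed Integer RNG seed; identical seeds give identical
#'   trajectories.
#' @param n_steps Steps to integrate.
#' @return List of class `sim_protocol`.
#' @export
simulation_protocol <- function(kT = 2.24, gamma = 0.5, dt = 0.005,
                                cutoff = 1.2, seed = 1L, n_steps = 1000L) {
  if (dt <= 0) stop("dt must be positive")
  if (gamma < 0) stop("gamma must be non-negative")
  structure(list(kT = kT, gamma = gamma, dt = dt, cutoff = cutoff,
                 seed = as.integer(seed), n_steps = as.integer(n_steps)),
            class = "sim_protocol")
}

#' Simulation state
#'
#' @param positions n x 3 matrix, nm.
#' @param velocities n x 3 matrix, nm/ps (default zero; the thermostat
#'   equilibrates velocities within a few 1/gamma).
#' @param box Orthorhombic edge lengths `c(x, y, z)`, nm.
#' @param time Elapsed time, ps.
#' @return List of class `sim_state`.
#' @export
simulation_state <- function(positions, velocities = NULL, box, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be n x 3")
  if (any(!is.finite(positions))) stop("non-finite coordinates")
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3L)
  velocities <- as.matrix(velocities)
  stopifnot(all(dim(velocities) == dim(positions)))
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive edges")
  structure(list(positions = positions, velocities = velocities,
                 box = box, time = time),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("simulation state: %d sites, box %.3g x %.3g x %.3g nm, t = %.4g ps\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

## Minimum-image displacement for an orthorhombic box (vectorized over rows).
minimum_image <- function(dr, box) {
  dr - sweep(round(sweep(dr, 2L, box, "/")), 2L, box, "*")
}

.pair_id <- function(i, j, n) (pmin(i, j) - 1) * n + pmax(i, j)

#' Neighbor list under periodic boundaries
#'
#' Returns exactly the non-excluded site pairs whose minimum-image distance
#' is below the cutoff. A cell list is used when the box holds at least
#' three cells per dimension, otherwise a vectorized all-pairs sweep; both
#' paths give identical pair sets. Rebuilding every step is the intended
#' usage.
#'
#' @param state A [simulation_state()].
#' @param cutoff Cutoff, nm.
#' @param exclusions Two-column matrix of excluded pairs (order-free).
#' @param method `"auto"`, `"cell"` or `"brute"`.
#' @return Two-column integer matrix of pairs with `i < j`.
#' @export
build_neighbor_list <- function(state, cutoff, exclusions = NULL,
                                method = c("auto", "cell", "brute")) {
  method <- match.arg(method)
  box <- state$box
  if (any(box < 2 * cutoff))
    stop("geometry error: box edge smaller than twice the cutoff")
  pos <- state$positions
  n <- nrow(pos)
  if (n < 2L) return(matrix(integer(), ncol = 2L))
  ncell <- floor(box / cutoff)
  use_cell <- method == "cell" || (method == "auto" && n > 250L)
  if (use_cell && any(ncell < 3)) use_cell <- FALSE
  pairs <- if (use_cell) .pairs_cell(pos, box, ncell)
           else .pairs_brute(n)
  dr <- minimum_image(pos[pairs[, 1], , drop = FALSE] -
                      pos[pairs[, 2], , drop = FALSE], box)
  keep <- rowSums(dr * dr) < cutoff^2
  pairs <- pairs[keep, , drop = FALSE]
  if (!is.null(exclusions) && nrow(exclusions) && nrow(pairs)) {
    ex <- .pair_id(exclusions[, 1], exclusions[, 2], n)
    keep <- !(.pair_id(pairs[, 1], pairs[, 2], n) %in% ex)
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs
}

.pairs_brute <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i, j)
}

.pairs_cell <- function(pos, box, ncell) {
  n <- nrow(pos)
  wrapped <- sweep(pos, 2L, box, function(p, b) p %% b)
  cc <- pmin(floor(sweep(wrapped, 2L, box / ncell, "/")),
             matrix(rep(ncell - 1, each = n), n))
  cid <- cc[, 1] + ncell[1] * (cc[, 2] + ncell[2] * cc[, 3])
  members <- split(seq_len(n), cid)
  occ <- as.integer(names(members))
  ox <- occ %% ncell[1]
  oy <- (occ %/% ncell[1]) %% ncell[2]
  oz <- occ %/% (ncell[1] * ncell[2])
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  lex <- with(offsets, dx > 0 | (dx == 0 & dy > 0) |
                (dx == 0 & dy == 0 & dz > 0))
  offsets <- offsets[lex, , drop = FALSE]
  out_i <- list(); out_j <- list()
  ## pairs within each cell
  for (m in members) {
    if (length(m) > 1L) {
      p <- .pairs_brute(length(m))
      out_i[[length(out_i) + 1L]] <- m[p[, 1]]
      out_j[[length(out_j) + 1L]] <- m[p[, 2]]
    }
  }
  ## pairs across the 13 half-shell neighbor offsets
  for (o in seq_len(nrow(offsets))) {
    nx <- (ox + offsets$dx[o]) %% ncell[1]
    ny <- (oy + offsets$dy[o]) %% ncell[2]
    nz <- (oz + offsets$dz[o]) %% ncell[3]
    nid <- nx + ncell[1] * (ny + ncell[2] * nz)
    hit <- match(as.character(nid), names(members))
    for (ci in which(!is.na(hit))) {
      a <- members[[ci]]
      b <- members[[hit[ci]]]
      out_i[[length(out_i) + 1L]] <- rep(a, each = length(b))
      out_j[[length(out_j) + 1L]] <- rep(b, times = length(a))
    }
  }
  if (!length(out_i)) return(matrix(integer(), ncol = 2L))
  i <- unlist(out_i); j <- unlist(out_j)
  cbind(pmin(i, j), pmax(i, j))
}

#' Center-of-mass umbrella restraint along z
#'
#' Harmonic bias U = k/2 (dz - z0)^2 on the z separation
#' dz = z_COM(group_a) - z_COM(group_b) between two mass centers, the
#' biasing device of the umbrella-sampling workflow (350 kJ/mol/nm^2 for
#' sidechain solutes, 650 for peptides). Forces are distributed over group
#' members by mass fraction.
#'
#' @param group_a,group_b Disjoint, non-empty site index sets (solute and
#'   bilayer).
#' @param k Force constant, kJ/mol/nm^2.
#' @param z0 Target separation, nm.
#' @return List of class `umbrella_restraint`.
#' @export
umbrella_restraint <- function(group_a, group_b, k, z0) {
  if (!length(group_a) || !length(group_b)) stop("empty restraint group")
  if (length(intersect(group_a, group_b))) stop("restraint groups overlap")
  if (k <= 0) stop("k must be positive")
  structure(list(group_a = as.integer(group_a),
                 group_b = as.integer(group_b), k = k, z0 = z0),
            class = "umbrella_restraint")
}

#' Harmonic position restraint
#'
#' Isotropic tether U = k/2 |r - ref|^2 per listed site; used for tethered
#' test particles and for holding solutes during setup.
#'
#' @param sites Site indices.
#' @param ref Reference coordinates, one row per site (or one row recycled).
#' @param k Force constant, kJ/mol/nm^2.
#' @return List of class `position_restraint`.
#' @export
position_restraint <- function(sites, ref, k) {
  ref <- matrix(as.numeric(ref), ncol = 3L)
  if (nrow(ref) == 1L) ref <- ref[rep(1L, length(sites)), , drop = FALSE]
  stopifnot(nrow(ref) == length(sites), k > 0)
  structure(list(sites = as.integer(sites), ref = ref, k = k),
            class = "position_restraint")
}

#' Energy and forces of an umbrella restraint
#'
#' @param state A [simulation_state()].
#' @param restraint An [umbrella_restraint()].
#' @param masses Site masses, amu.
#' @return List with `energy` (kJ/mol), `forces` (n x 3, only restrained
#'   rows non-zero) and the current reaction coordinate `dz` (nm).
#' @export
umbrella_force <- function(state, restraint, masses) {
  a <- restraint$group_a; b <- restraint$group_b
  ma <- masses[a]; mb <- masses[b]
  za <- sum(state$positions[a, 3] * ma) / sum(ma)
  zb <- sum(state$positions[b, 3] * mb) / sum(mb)
  dz <- za - zb
  dev <- dz - restraint$z0
  f <- matrix(0, nrow(state$positions), 3L)
  f[a, 3] <- -restraint$k * dev * ma / sum(ma)
  f[b, 3] <- restraint$k * dev * mb / sum(mb)
  list(energy = 0.5 * restraint$k * dev^2, forces = f, dz = dz)
}

.acc_forces <- function(f, idx, contrib) {
  s <- rowsum(contrib, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(s))
  f[rows, ] <- f[rows, ] + s
  f
}

#' Compute forces and the energy decomposition
#'
#' Sums tabulated nonbond pair forces (cutoff-truncated, minimum image,
#' 1-2/1-3 exclusions), harmonic bonds, fourth-order polynomial angles,
#' GROMOS-96 restraint angles, harmonic torsions and any umbrella/position
#' restraints. Restraint forces are included in `forces` but also returned
#' separately so that Newton's-third-law checks can be made on the internal
#' forces alone.
#'
#' @param state A [simulation_state()].
#' @param topo A [cg_topology()].
#' @param ff A [cg_forcefield()].
#' @param restraints List of [umbrella_restraint()] / [position_restraint()]
#'   objects.
#' @return List with `forces` (n x 3, kJ/mol/nm), `energies` (named vector:
#'   pair, bond, angle, g96_angle, torsion, restraint), `restraint_forces`
#'   and `restraint_coords` (current dz per umbrella restraint).
#' @export
compute_forces <- function(state, topo, ff, restraints = list()) {
  pos <- state$positions
  box <- state$box
  n <- nrow(pos)
  f <- matrix(0, n, 3L)
  en <- c(pair = 0, bond = 0, angle = 0, g96_angle = 0, torsion = 0,
          restraint = 0)

  ## nonbond pair forces
  nl <- build_neighbor_list(state, ff$cutoff, exclusions = topo$exclusions)
  if (nrow(nl)) {
    types <- topo$sites$site_type
    dr <- minimum_image(pos[nl[, 1], , drop = FALSE] -
                        pos[nl[, 2], , drop = FALSE], box)
    r <- sqrt(rowSums(dr * dr))
    keys <- paste(pmin(types[nl[, 1]], types[nl[, 2]]),
                  pmax(types[nl[, 1]], types[nl[, 2]]), sep = "-")
    for (key in unique(keys)) {
      tab <- ff$tables[[key]]
      if (is.null(tab)) stop("missing table for pair ", key)
      sel <- keys == key
      ev <- evaluate_pair(tab, r[sel])
      en["pair"] <- en["pair"] + sum(ev$energy)
      fv <- dr[sel, , drop = FALSE] * (ev$force / r[sel])
      f <- .acc_forces(f, nl[sel, 1], fv)
      f <- .acc_forces(f, nl[sel, 2], -fv)
    }
  }

  ## harmonic bonds
  bd <- topo$bonds
  if (nrow(bd)) {
    dr <- minimum_image(pos[bd$i, , drop = FALSE] -
                        pos[bd$j, , drop = FALSE], box)
    r <- sqrt(rowSums(dr * dr))
    dev <- r - bd$r0
    en["bond"] <- sum(0.5 * bd$k * dev^2)
    fv <- dr * (-bd$k * dev / r)
    f <- .acc_forces(f, bd$i, fv)
    f <- .acc_forces(f, bd$j, -fv)
  }

  ## angle terms (polynomial and GROMOS-96 cosine-harmonic), vectorized
  angle_block <- function(ai, aj, ak, dUdcos_of, U_of) {
    rij <- minimum_image(pos[ai, , drop = FALSE] -
                         pos[aj, , drop = FALSE], box)
    rkj <- minimum_image(pos[ak, , drop = FALSE] -
                         pos[aj, , drop = FALSE], box)
    nij <- sqrt(rowSums(rij^2)); nkj <- sqrt(rowSums(rkj^2))
    cth <- pmax(-1, pmin(1, rowSums(rij * rkj) / (nij * nkj)))
    dUdcos <- dUdcos_of(cth)
    dci <- rkj / (nij * nkj) - rij * (cth / nij^2)
    dck <- rij / (nij * nkj) - rkj * (cth / nkj^2)
    fi <- -dUdcos * dci
    fk <- -dUdcos * dck
    f <<- .acc_forces(f, ai, fi)
    f <<- .acc_forces(f, ak, fk)
    f <<- .acc_forces(f, aj, -fi - fk)
    sum(U_of(cth))
  }
  an <- topo$angles
  if (nrow(an)) {
    cf <- as.matrix(an[c("c0", "c1", "c2", "c3", "c4")])
    en["angle"] <- angle_block(
      an$ai, an$aj, an$ak,
      dUdcos_of = function(cth) {
        th <- acos(cth)
        sth <- pmax(sqrt(1 - cth^2), 1e-8)
        -(cf[, 2] + 2 * cf[, 3] * th + 3 * cf[, 4] * th^2 +
            4 * cf[, 5] * th^3) / sth
      },
      U_of = function(cth) {
        th <- acos(cth)
        rowSums(cf * cbind(1, th, th^2, th^3, th^4))
      })
  }
  g96 <- topo$g96_angles
  if (nrow(g96)) {
    c0 <- cos(g96$theta0 * pi / 180)
    en["g96_angle"] <- angle_block(
      g96$ai, g96$aj, g96$ak,
      dUdcos_of = function(cth) g96$k_theta * (cth - c0),
      U_of = function(cth) 0.5 * g96$k_theta * (cth - c0)^2)
  }

  ## harmonic torsions, vectorized
  tor <- topo$torsions
  if (nrow(tor)) {
    cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                               a[, 3] * b[, 1] - a[, 1] * b[, 3],
                               a[, 1] * b[, 2] - a[, 2] * b[, 1])
    b1 <- minimum_image(pos[tor$aj, , drop = FALSE] -
                        pos[tor$ai, , drop = FALSE], box)
    b2 <- minimum_image(pos[tor$ak, , drop = FALSE] -
                        pos[tor$aj, , drop = FALSE], box)
    b3 <- minimum_image(pos[tor$al, , drop = FALSE] -
                        pos[tor$ak, , drop = FALSE], box)
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    nb2 <- sqrt(rowSums(b2^2))
    phi <- atan2(rowSums(cr(n1, n2) * b2) / nb2, rowSums(n1 * n2))
    dev <- phi - tor$phi0 * pi / 180
    dev <- dev - 2 * pi * round(dev / (2 * pi))
    en["torsion"] <- sum(0.5 * tor$k_phi * dev^2)
    dUdphi <- tor$k_phi * dev
    dpi_ <- n1 * (-nb2 / rowSums(n1 * n1))
    dpl <- n2 * (nb2 / rowSums(n2 * n2))
    dpj <- dpi_ * (-(1 + rowSums(b1 * b2) / nb2^2)) +
      dpl * (rowSums(b3 * b2) / nb2^2)
    dpk <- -dpi_ - dpj - dpl
    f <- .acc_forces(f, tor$ai, -dUdphi * dpi_)
    f <- .acc_forces(f, tor$aj, -dUdphi * dpj)
    f <- .acc_forces(f, tor$ak, -dUdphi * dpk)
    f <- .acc_forces(f, tor$al, -dUdphi * dpl)
  }

  ## restraints
  rforces <- matrix(0, n, 3L)
  rcoords <- numeric()
  masses <- topo$sites$mass
  for (rs in restraints) {
    if (inherits(rs, "umbrella_restraint")) {
      uf <- umbrella_force(state, rs, masses)
      en["restraint"] <- en["restraint"] + uf$energy
      rforces <- rforces + uf$forces
      rcoords <- c(rcoords, uf$dz)
    } else if (inherits(rs, "position_restraint")) {
      dr <- pos[rs$sites, , drop = FALSE] - rs$ref
      en["restraint"] <- en["restraint"] + 0.5 * rs$k * sum(dr * dr)
      rforces[rs$sites, ] <- rforces[rs$sites, ] - rs$k * dr
    } else stop("unknown restraint type")
  }
  f <- f + rforces
  if (any(!is.finite(f))) stop("integration error: non-finite force")
  list(forces = f, energies = en, restraint_forces = rforces,
       restraint_coords = rcoords)
}

#' One BAOAB Langevin substep sequence (B-A-O-A)
#'
#' Applies a half kick with the supplied forces, a half drift, the exact
#' Ornstein-Uhlenbeck velocity update at (gamma, kT), and a second half
#' drift. The caller (normally [run_simulation()]) completes the step with
#' the trailing half kick after recomputing forces at the new positions.
#' With gamma = 0 the noise vanishes and zero force gives exact free
#' flight.
#'
#' @param state A [simulation_state()].
#' @param forces n x 3 force matrix for the current positions, kJ/mol/nm.
#' @param protocol A [simulation_protocol()].
#' @param masses Site masses, amu.
#' @return Updated [simulation_state()] (time advanced by `dt`).
#' @export
langevin_step <- function(state, forces, protocol, masses) {
  if (any(!is.finite(forces))) stop("integration error: non-finite force")
  dt <- protocol$dt
  v <- state$velocities + forces * (dt / 2) / masses
  x <- state$positions + v * (dt / 2)
  c1 <- exp(-protocol$gamma * dt)
  if (protocol$gamma > 0) {
    sd_v <- sqrt(protocol$kT * (1 - c1^2) / masses)
    v <- c1 * v + matrix(stats::rnorm(length(v)), nrow(v), 3L) * sd_v
  }
  x <- x + v * (dt / 2)
  simulation_state(x, v, state$box, state$time + dt)
}

half_kick <- function(state, forces, protocol, masses) {
  state$velocities <- state$velocities + forces * (protocol$dt / 2) / masses
  state
}

#' Kinetic energy of a state
#' @param state A [simulation_state()].
#' @param masses Site masses, amu.
#' @return Kinetic energy, kJ/mol.
#' @export
kinetic_energy <- function(state, masses) {
  0.5 * sum(masses * rowSums(state$velocities^2))
}

#' Run an NVT Langevin simulation
#'
#' Advances `protocol$n_steps` BAOAB steps, rebuilding the neighbor list
#' every step. Frames and restraint-coordinate time series are recorded at
#' the configured strides; trajectories are bitwise reproducible for a
#' given protocol seed (the caller's RNG state is preserved).
#'
#' @param state Initial [simulation_state()].
#' @param topo A [cg_topology()].
#' @param ff A [cg_forcefield()].
#' @param protocol A [simulation_protocol()].
#' @param restraints Restraint list as for [compute_forces()].
#' @param frame_stride Record a position frame every this many steps
#'   (0 = none).
#' @param series_stride Record energies and restraint coordinates every
#'   this many steps.
#' @return List with `state` (final), `frames` (list of `positions`/`time`),
#'   `series` (data frame: time, kinetic, potential, and one `dz_<i>` column
#'   per umbrella restraint).
#' @export
run_simulation <- function(state, topo, ff, protocol, restraints = list(),
                           frame_stride = 0L, series_stride = 1L) {
  stopifnot(inherits(state, "sim_state"), inherits(topo, "cg_topology"))
  if (abs(protocol$cutoff - ff$cutoff) > 1e-9)
    stop("protocol cutoff does not match the force field")
  masses <- topo$sites$mass
  if (length(masses) != nrow(state$positions))
    stop("state and topology disagree on site count")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(protocol$seed)
  frames <- list()
  series <- list()
  fc <- tryCatch(compute_forces(state, topo, ff, restraints),
                 error = function(e) stop("at step 0: ",
                                          conditionMessage(e)))
  n_umb <- sum(vapply(restraints, inherits, logical(1),
                      "umbrella_restraint"))
  record <- function(step, st, fc) {
    row <- c(time = st$time, kinetic = kinetic_energy(st, masses),
             potential = sum(fc$energies))
    if (n_umb > 0)
      row <- c(row, stats::setNames(fc$restraint_coords,
                                    paste0("dz_", seq_len(n_umb))))
    series[[length(series) + 1L]] <<- row
  }
  if (protocol$n_steps == 0L) {
    record(0L, state, fc)
    return(list(state = state, frames = frames,
                series = as.data.frame(do.call(rbind, series))))
  }
  for (step in seq_len(protocol$n_steps)) {
    state <- tryCatch({
      st <- langevin_step(state, fc$forces, protocol, masses)
      fc <- compute_forces(st, topo, ff, restraints)
      half_kick(st, fc$forces, protocol, masses)
    }, error = function(e) stop("at step ", step, ": ",
                                conditionMessage(e)))
    if (series_stride > 0L && step %% series_stride == 0L)
      record(step, state, fc)
    if (frame_stride > 0L && step %% frame_stride == 0L)
      frames[[length(frames) + 1L]] <-
        list(positions = state$positions, time = state$time)
  }
  list(state = state, frames = frames,
       series = as.data.frame(do.call(rbind, series)))
}

#' Write a coordinate frame in GRO format
#'
#' @param state A [simulation_state()].
#' @param topo A [cg_topology()] supplying residue and site names.
#' @param con File path or connection.
#' @param title Title line.
#' @return Invisibly, the lines written.
#' @export
write_gro <- function(state, topo, con, title = "cgmemb frame") {
  s <- topo$sites
  lines <- c(
    sprintf("%s, t= %.3f", title, state$time),
    sprintf("%5d", nrow(s)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            s$residue_index %% 100000L, substr(s$residue_name, 1, 5),
            substr(s$name, 1, 5), s$index %% 100000L,
            state$positions[, 1], state$positions[, 2],
            state$positions[, 3]),
    sprintf("%10.5f%10.5f%10.5f", state$box[1], state$box[2], state$box[3])
  )
  writeLines(lines, con)
  invisible(lines)
}

#' Read a GRO coordinate file
#'
#' @param con File path or connection.
#' @return List with `positions`, `box`, `atom_name`, `residue_index`,
#'   `residue_name`.
#' @export
read_gro <- function(con) {
  lines <- readLines(con)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  list(
    positions = cbind(as.numeric(substr(body, 21, 28)),
                      as.numeric(substr(body, 29, 36)),
                      as.numeric(substr(body, 37, 44))),
    box = box,
    atom_name = trimws(substr(body, 11, 15)),
    residue_index = as.integer(substr(body, 1, 5)),
    residue_name = trimws(substr(body, 6, 10))
  )
}
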