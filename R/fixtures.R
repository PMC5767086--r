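## Synthetic fixtures: toy pair tables, ideal helices, bilayer slabs and 1D
## Boltzmann samplers. Every fixture is a pure function of its arguments
## (plus an explicit seed for the stochastic ones), so tests and examples
## need no external data.

#' Toy tabulated pair potentials
#'
#' Generates analytically-defined pair tables for engine and parser tests:
#' `"flat"` (identically zero), `"harmonic"` (U = k/2 (r - r0)^2, shifted to
#' zero at the cutoff) and `"lj_like"` (12-6 Lennard-Jones with well depth
#' `eps` and size `sigma`, truncated and shifted). The lj_like minimum sits
#' at 2^(1/6) sigma with zero force.
#'
#' @param kind `"flat"`, `"harmonic"` or `"lj_like"`.
#' @param pair Site-type pair for the table.
#' @param cutoff Cutoff, nm.
#' @param k,r0 Harmonic parameters (kJ/mol/nm^2, nm).
#' @param eps,sigma Lennard-Jones parameters (kJ/mol, nm).
#' @param n Grid points before resampling.
#' @return A [tabulated_potential()].
#' @export
#' @examples
#' lj <- make_toy_pair_table("lj_like", c("ap", "ap"))
#' evaluate_pair(lj, 2^(1/6) * 0.47)$force   # ~0 at the minimum
make_toy_pair_table <- function(kind = c("lj_like", "harmonic", "flat"),
                                pair = c("p", "p"), cutoff = 1.2,
                                k = 100, r0 = 0.8, eps = 1, sigma = 0.47,
                                n = 601) {
  kind <- match.arg(kind)
  switch(kind,
    flat = {
      r <- seq(0, cutoff, length.out = n)
      tabulated_potential(pair, r, rep(0, n), cutoff = cutoff)
    },
    harmonic = {
      if (k <= 0 || r0 <= 0 || r0 >= cutoff)
        stop("invalid harmonic parameters")
      r <- seq(0, cutoff, length.out = n)
      tabulated_potential(pair, r, 0.5 * k * (r - r0)^2, cutoff = cutoff)
    },
    lj_like = {
      if (eps <= 0 || sigma <= 0 || 2^(1 / 6) * sigma >= cutoff)
        stop("invalid lj_like parameters")
      r <- seq(0.7 * sigma, cutoff, length.out = n)
      sr6 <- (sigma / r)^6
      tabulated_potential(pair, r, 4 * eps * (sr6^2 - sr6), cutoff = cutoff)
    })
}

#' Toy force field covering a set of site types
#'
#' One [make_toy_pair_table()] per unordered type pair. Convenient for
#' engine tests that need a complete, well-behaved force field.
#'
#' @param types Site types to cover.
#' @param kind Table kind, see [make_toy_pair_table()].
#' @param cutoff Cutoff, nm.
#' @param ... Passed to [make_toy_pair_table()].
#' @return A [cg_forcefield()].
#' @export
make_toy_forcefield <- function(types, kind = "lj_like", cutoff = 1.2, ...) {
  types <- sort(unique(types))
  combos <- expand.grid(a = types, b = types, stringsAsFactors = FALSE)
  combos <- combos[combos$a <= combos$b, , drop = FALSE]
  tabs <- lapply(seq_len(nrow(combos)), function(i)
    make_toy_pair_table(kind, c(combos$a[i], combos$b[i]),
                        cutoff = cutoff, ...))
  cg_forcefield(tabs)
}

#' Ideal right-handed alpha-helix backbone trace
#'
#' Calpha positions on a right-handed helix with the standard alpha-helix
#' geometry: 0.15 nm rise and 100 degrees twist per residue on a 0.23 nm
#' radius, giving a consecutive Calpha-Calpha distance of about 0.38 nm,
#' backbone angles near 89 degrees and backbone torsions near +50 degrees.
#' The helix axis is the z axis.
#'
#' @param sequence One-letter sequence (only its length is used) or an
#'   integer residue count.
#' @param rise Rise per residue, nm.
#' @param twist Twist per residue, degrees.
#' @param radius Helix radius, nm.
#' @return n x 3 matrix of Calpha coordinates, nm.
#' @export
build_ideal_helix <- function(sequence, rise = 0.15, twist = 100,
                              radius = 0.23) {
  n <- if (is.numeric(sequence)) as.integer(sequence)
       else nchar(as.character(sequence)[1])
  if (is.na(n) || n < 1L) stop("need at least one residue")
  i <- seq_len(n) - 1L
  ang <- i * twist * pi / 180
  cbind(x = radius * cos(ang), y = radius * sin(ang), z = i * rise)
}

#' Initial coordinates for a peptide topology on a helical trace
#'
#' Places backbone beads on the supplied Calpha trace and each sidechain
#' bead at its template bond length from its parent, extended radially away
#' from the helix (z) axis. A deterministic starting structure; bonded terms
#' relax it during equilibration.
#'
#' @param topo A peptide [cg_topology()].
#' @param ca_coords Calpha coordinates, one row per residue (default: the
#'   ideal helix for the residue count).
#' @return n_sites x 3 coordinate matrix, nm.
#' @export
place_peptide_coords <- function(topo, ca_coords = NULL) {
  res <- unique(topo$sites$residue_index)
  if (is.null(ca_coords)) ca_coords <- build_ideal_helix(length(res))
  if (nrow(ca_coords) != length(res))
    stop("ca_coords must have one row per residue")
  pos <- matrix(0, n_sites(topo), 3L)
  for (ri in seq_along(res)) {
    rows <- which(topo$sites$residue_index == res[ri])
    ca_row <- rows[topo$sites$name[rows] == "CA"]
    pos[ca_row, ] <- ca_coords[ri, ]
    u <- c(ca_coords[ri, 1], ca_coords[ri, 2], 0)
    nu <- sqrt(sum(u^2))
    u <- if (nu < 1e-9) c(1, 0, 0) else u / nu
    prev <- pos[ca_row, ]
    reach <- 0
    for (rw in setdiff(rows, ca_row)) {
      b <- topo$bonds[topo$bonds$j == rw | topo$bonds$i == rw, , drop = FALSE]
      r0 <- if (nrow(b)) b$r0[1] else 0.2
      reach <- reach + r0
      pos[rw, ] <- pos[ca_row, ] + u * reach
      prev <- pos[rw, ]
    }
  }
  pos
}

#' Build a pre-separated CG bilayer slab
#'
#' Two leaflets of `n_lipids / 2` lipids each on a square lattice, tails
#' pointing inward, with bead depths taken from the template `z0` column
#' (ester beads at +/- 1.45 nm, so the ester-ester thickness is 29 Angstrom
#' by construction). The two tail chains of each lipid are offset laterally
#' and the lower leaflet is staggered by half a lattice spacing, keeping all
#' intersite distances above 0.4 nm so that a short equilibration suffices.
#' Deterministic: no random numbers are used.
#'
#' @param n_lipids Even lipid count.
#' @param box Box edge lengths `c(x, y, z)`, nm.
#' @param template Lipid template, see [dopc_template()].
#' @param ... Passed to [build_dopc_topology()].
#' @return List with `state` (a [simulation_state()]) and `topology`.
#' @export
#' @examples
#' slab <- build_bilayer_slab(16, c(2.6, 2.6, 7))
build_bilayer_slab <- function(n_lipids, box, template = dopc_template(),
                               ...) {
  if (n_lipids %% 2L != 0L) stop("n_lipids must be even")
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be three edges")
  per_leaflet <- n_lipids / 2L
  nx <- ceiling(sqrt(per_leaflet))
  sx <- box[1] / nx
  sy <- box[2] / nx
  if (min(sx, sy) < 0.75)
    stop("box too small: lattice spacing below 0.75 nm")
  if (box[3] < 2 * max(template$z0) + 0.5)
    stop("box too small: z edge does not accommodate the bilayer")
  one <- build_dopc_topology(template, ...)
  topo <- replicate_topology(one, n_lipids, group_prefix = "DOPC")
  npl <- nrow(template)
  ## sn-1 chain (ester e1 + its tail) shifted +dx in x, sn-2 chain -dx and
  ## staggered in y, keeping all contacts near or above 0.4 nm
  chain_a <- template$type == "e1" |
    (grepl("A$", template$name) & template$type %in% c("s1", "sd", "sm"))
  chain_b <- template$type == "e2" |
    (grepl("B$", template$name) & template$type %in% c("s1", "sd", "sm"))
  dx <- min(0.21, (min(sx, sy) - 0.4) / 2)
  chain_dx <- ifelse(chain_a, dx, ifelse(chain_b, -dx, 0))
  chain_dy <- ifelse(chain_b, 0.15, 0)
  pos <- matrix(0, n_lipids * npl, 3L)
  for (l in seq_len(n_lipids)) {
    leaflet <- if (l <= per_leaflet) 1 else -1
    k <- if (leaflet == 1) l - 1L else l - per_leaflet - 1L
    cx <- (k %% nx + 0.5) * sx + if (leaflet == -1) sx / 2 else 0
    cy <- (k %/% nx + 0.5) * sy + if (leaflet == -1) sy / 2 else 0
    rows <- (l - 1L) * npl + seq_len(npl)
    pos[rows, 1] <- (cx + chain_dx) %% box[1]
    pos[rows, 2] <- (cy + chain_dy) %% box[2]
    pos[rows, 3] <- box[3] / 2 + leaflet * template$z0
  }
  state <- simulation_state(pos, box = box)
  list(state = state, topology = topo)
}

#' Draw samples from a 1D Boltzmann distribution
#'
#' Samples x with density proportional to exp(-U(x)/kT), either by
#' Metropolis random walk or by overdamped Brownian dynamics
#' (Euler-Maruyama: dx = -U'(x)/gamma dt + sqrt(2 kT dt / gamma) xi). The
#' Brownian method returns a time-ordered path directly usable as an
#' umbrella-window reaction-coordinate series; the generator is the
#' independent oracle behind the WHAM and Boltzmann-inversion tests.
#'
#' @param U Potential, a function of x returning kJ/mol.
#' @param kT Thermal energy, kJ/mol.
#' @param n Samples to return (after burn-in and thinning).
#' @param seed Integer seed (mandatory; same seed, same samples).
#' @param method `"metropolis"` or `"brownian"`.
#' @param x0 Starting point.
#' @param step Metropolis proposal standard deviation, nm.
#' @param dt,gamma Brownian time step (ps) and friction (amu/ps).
#' @param burn_in Steps discarded before recording.
#' @param thin Keep every `thin`-th step.
#' @param domain Sane coordinate bounds; a walker leaving them means the
#'   potential is divergent (not confining) and raises an error.
#' @return Numeric vector of `n` samples.
#' @export
#' @examples
#' x <- sample_boltzmann_1d(function(x) 50 * x^2, kT = 2.24, n = 1e3,
#'                          seed = 7)
#' var(x)   # ~ kT / k = 0.0224
sample_boltzmann_1d <- function(U, kT = 2.24, n, seed,
                                method = c("metropolis", "brownian"),
                                x0 = 0, step = 0.05, dt = 0.05, gamma = 200,
                                burn_in = 200L, thin = 1L,
                                domain = c(-1e3, 1e3)) {
  method <- match.arg(method)
  if (missing(seed)) stop("seed is mandatory for stochastic fixtures")
  if (!is.finite(U(x0))) stop("divergent potential at the starting point")
  out <- numeric(n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  x <- x0
  total <- burn_in + n * thin
  if (method == "metropolis") {
    prop <- stats::rnorm(total, 0, step)
    u <- stats::runif(total)
    Ux <- U(x)
    kept <- 0L
    for (s in seq_len(total)) {
      xn <- x + prop[s]
      Un <- U(xn)
      if (is.finite(Un) && u[s] < exp((Ux - Un) / kT)) {
        x <- xn
        Ux <- Un
      }
      if (x < domain[1] || x > domain[2])
        stop("divergent potential: sampler left the domain")
      if (s > burn_in && (s - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        out[kept] <- x
      }
    }
  } else {
    noise <- stats::rnorm(total, 0, sqrt(2 * kT * dt / gamma))
    h <- 1e-5
    kept <- 0L
    for (s in seq_len(total)) {
      g <- (U(x + h) - U(x - h)) / (2 * h)
      x <- x - g / gamma * dt + noise[s]
      if (!is.finite(x) || x < domain[1] || x > domain[2])
        stop("divergent potential: sampler left the domain")
      if (s > burn_in && (s - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        out[kept] <- x
      }
    }
  }
  out
}
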