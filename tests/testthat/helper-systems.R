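# Shared helpers: small systems and an independent finite-difference
# gradient oracle for force checks.

fd_gradient <- function(state, topo, ff, restraints = list(), h = 1e-6) {
  n <- nrow(state$positions)
  g <- matrix(0, n, 3L)
  energy_of <- function(p)
    sum(compute_forces(simulation_state(p, box = state$box), topo, ff,
                       restraints)$energies)
  for (i in seq_len(n)) {
    for (d in 1:3) {
      p <- state$positions
      p[i, d] <- p[i, d] + h
      e_plus <- energy_of(p)
      p[i, d] <- p[i, d] - 2 * h
      e_minus <- energy_of(p)
      g[i, d] <- -(e_plus - e_minus) / (2 * h)
    }
  }
  g
}

# a bonded + restrained random small system exercising every force term
random_bonded_system <- function(seed, sequence = "ACDEFGHIKLMNPQ") {
  set.seed(seed)
  topo <- apply_helix_restraints(build_peptide_topology(sequence))
  n <- n_sites(topo)
  pos <- place_peptide_coords(topo) + matrix(rnorm(n * 3, 0, 0.015),
                                             ncol = 3)
  pos <- sweep(pos, 2, c(4, 4, 2.5), "+")
  ff <- make_toy_forcefield(unique(topo$sites$site_type), kind = "lj_like",
                            eps = 0.5)
  st <- simulation_state(pos, box = c(8, 8, 8))
  rest <- list(umbrella_restraint(1:4, 5:n, k = 350, z0 = 0.1))
  list(state = st, topo = topo, ff = ff, restraints = rest)
}

# umbrella windows drawn from a known 1D double-well with the Brownian
# sampler; the generating potential is the oracle for WHAM recovery
double_well_windows <- function(a = 15, b = 0.8, k = 350, kT = 2.24,
                                n_per_window = 1500, seed_base = 1000,
                                centers = seq(-1.4, 1.4, by = 0.2)) {
  U <- function(x) a * (x^2 - b^2)^2
  wins <- lapply(seq_along(centers), function(i) {
    s <- sample_boltzmann_1d(
      function(x) U(x) + 0.5 * k * (x - centers[i])^2,
      kT = kT, n = n_per_window, seed = seed_base + i,
      method = "brownian", x0 = centers[i],
      dt = 0.01, gamma = 200, thin = 10, burn_in = 2000)
    umbrella_window(centers[i], k, s, kT = kT)
  })
  list(windows = wins, potential = U)
}
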