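## CG topology building: residue -> site mapping with version-resolved site
## types, bonded terms, lipid templates, helix restraints, atomistic mapping.

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

## Backbone bead = the -CHR'CONH- unit mapped onto the alpha carbon. For Ala
## the sidechain methyl is merged into the backbone bead (sole CG site).
.backbone_mass <- function(res3) {
  switch(res3, ALA = 71.08, GLY = 57.05, 56.04)
}

#' Sidechain CG template for one residue
#'
#' Returns the sidechain bead layout for a residue under a given force-field
#' version: bead names, site types, masses (amu, heavy atoms + hydrogens of
#' the mapped subgroup), equilibrium bond lengths (nm) and the parent bead
#' each site is bonded to (`"CA"` or a previous sidechain bead). Version 2.4
#' reassignments relative to version 1: Phe gains a polar Cdelta; Tyr polar
#' Cgamma and Cepsilon; Trp polar Cgamma; Gln and Arg/Lys/Asp/Glu polar
#' Cbeta; Asn collapses to a single polar site on a 0.26 nm bond; Cys turns
#' apolar; Val gains a second apolar site. Version 2.3 carries the
#' since-retired Lys p.p.pos, Trp ap-p-ap-p and Asn p-p descriptions.
#' Ala and Gly have no sidechain beads.
#'
#' @param res3 Three-letter residue code.
#' @param version Force-field version, `"1"`, `"2.3"` or `"2.4"`.
#' @return Data frame with columns `name`, `type`, `mass`, `r0`, `parent`
#'   (zero rows for Gly/Ala).
#' @export
sidechain_template <- function(res3, version = "2.4") {
  version <- match.arg(as.character(version), c("2.4", "2.3", "1"))
  v24 <- version == "2.4"
  sc <- function(...) {
    d <- data.frame(...)
    names(d) <- c("name", "type", "mass", "r0", "parent")
    d
  }
  none <- data.frame(name = character(), type = character(),
                     mass = numeric(), r0 = numeric(), parent = character())
  switch(res3,
    GLY = ,
    ALA = none,
    SER = sc("OG", "p", 31.03, 0.20, "CA"),
    THR = sc("CB", "p", 45.06, 0.20, "CA"),
    CYS = sc("SG", if (v24) "ap" else "p", 47.10, 0.20, "CA"),
    PRO = sc("CG", "ap", 42.08, 0.20, "CA"),
    VAL = if (v24)
      sc(c("CB", "CG2"), c("ap", "ap"), c(28.05, 15.03), c(0.20, 0.16),
         c("CA", "CB"))
    else sc("CB", "ap", 43.09, 0.20, "CA"),
    LEU = sc(c("CB", "CG"), c("ap", "ap"), c(14.03, 43.09), c(0.20, 0.16),
             c("CA", "CB")),
    ILE = sc(c("CB", "CG"), c("ap", "ap"), c(29.06, 28.05), c(0.20, 0.25),
             c("CA", "CB")),
    MET = sc(c("CB", "SD"), c("ap", "ap"), c(28.05, 47.10), c(0.20, 0.25),
             c("CA", "CB")),
    PHE = sc(c("CB", "CG", "CD"), c("ap", "ap", if (v24) "p" else "ap"),
             c(14.03, 38.05, 39.06), c(0.20, 0.21, 0.24),
             c("CA", "CB", "CG")),
    TYR = sc(c("CB", "CG", "CE"),
             c("ap", if (v24) "p" else "ap", "p"),
             c(14.03, 38.05, 55.06), c(0.20, 0.21, 0.28),
             c("CA", "CB", "CG")),
    TRP = {
      types <- if (v24) c("ap", "p", "ap", "ap")
               else if (version == "2.3") c("ap", "p", "ap", "p")
               else c("ap", "ap", "p", "ap")
      sc(c("CB", "CG", "CD", "CE"), types,
         c(14.03, 38.05, 39.06, 39.06), c(0.20, 0.21, 0.22, 0.24),
         c("CA", "CB", "CG", "CD"))
    },
    HIS = sc(c("CB", "CG", "CD"), c("ap", "p", "p"),
             c(14.03, 33.04, 34.05), c(0.20, 0.22, 0.22),
             c("CA", "CB", "CG")),
    ASN = if (v24) sc("ND", "p", 58.06, 0.26, "CA")
          else sc(c("CB", "CG"),
                  c(if (version == "2.3") "p" else "ap", "p"),
                  c(14.03, 44.03), c(0.20, 0.22), c("CA", "CB")),
    GLN = sc(c("CB", "CD"), c(if (v24) "p" else "ap", "p"),
             c(28.05, 44.03), c(0.20, 0.25), c("CA", "CB")),
    ASP = sc(c("CB", "CG"), c(if (v24) "p" else "ap", "neg"),
             c(14.03, 44.99), c(0.20, 0.22), c("CA", "CB")),
    GLU = sc(c("CB", "CD"), c(if (v24) "p" else "ap", "neg"),
             c(28.05, 44.99), c(0.20, 0.25), c("CA", "CB")),
    LYS = if (version == "2.3")
      sc(c("CB", "CD", "NZ"), c("p", "p", "pos"),
         c(28.05, 27.05, 17.03), c(0.15, 0.15, 0.15), c("CA", "CB", "CD"))
    else
      sc(c("CB", "NZ"), c(if (v24) "p" else "ap", "pos"),
         c(42.08, 30.05), c(0.25, 0.30), c("CA", "CB")),
    ARG = sc(c("CB", "CZ"), c(if (v24) "p" else "ap", "pos"),
             c(28.05, 72.10), c(0.22, 0.32), c("CA", "CB")),
    stop("unknown residue: ", res3)
  )
}

derive_exclusions <- function(n_sites, bonds) {
  if (!nrow(bonds)) return(matrix(integer(), ncol = 2L))
  adj <- vector("list", n_sites)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  ex <- cbind(bonds$i, bonds$j)                     # 1-2
  for (jc in seq_len(n_sites)) {                    # 1-3 through center jc
    nb <- adj[[jc]]
    if (length(nb) > 1L) {
      pr <- t(utils::combn(sort(nb), 2L))
      ex <- rbind(ex, pr)
    }
  }
  ex <- t(apply(ex, 1L, sort))
  ex[!duplicated(ex), , drop = FALSE]
}

#' Construct a CG topology
#'
#' Container for the sites, bonded terms and restraints of one molecule or a
#' whole system. Nonbond exclusions default to all 1-2 (bonded) and 1-3
#' (angle) pairs derived from the bond list.
#'
#' @param sites Data frame with columns `name`, `site_type`, `mass`,
#'   `residue_index`, `residue_name`, `group`.
#' @param bonds Data frame with columns `i`, `j`, `k` (kJ/mol/nm^2), `r0`
#'   (nm).
#' @param angles Data frame of fourth-order polynomial angle terms: columns
#'   `ai`, `aj`, `ak` (central bead `aj`) and coefficients `c0`..`c4` for
#'   U(theta) = sum c_n theta^n, theta in radians.
#' @param g96_angles Data frame of GROMOS-96 angle restraints: `ai`, `aj`,
#'   `ak`, `theta0` (degrees), `k_theta` (kJ/mol).
#' @param torsions Data frame of harmonic torsions: `ai`..`al`, `phi0`
#'   (degrees), `k_phi` (kJ/mol/rad^2).
#' @param exclusions Two-column integer matrix of excluded pairs, or `NULL`
#'   to derive 1-2 and 1-3 exclusions from `bonds`.
#' @return Object of class `cg_topology`.
#' @export
cg_topology <- function(sites, bonds = NULL, angles = NULL,
                        g96_angles = NULL, torsions = NULL,
                        exclusions = NULL) {
  empty <- function(cols) {
    d <- as.data.frame(stats::setNames(rep(list(numeric()), length(cols)),
                                       cols))
    d
  }
  if (is.null(bonds)) bonds <- empty(c("i", "j", "k", "r0"))
  if (is.null(angles))
    angles <- empty(c("ai", "aj", "ak", "c0", "c1", "c2", "c3", "c4"))
  if (is.null(g96_angles))
    g96_angles <- empty(c("ai", "aj", "ak", "theta0", "k_theta"))
  if (is.null(torsions))
    torsions <- empty(c("ai", "aj", "ak", "al", "phi0", "k_phi"))
  n <- nrow(sites)
  sites$index <- seq_len(n)
  if (any(sites$mass <= 0)) stop("site masses must be positive")
  idx <- c(bonds$i, bonds$j, angles$ai, angles$aj, angles$ak,
           g96_angles$ai, g96_angles$aj, g96_angles$ak,
           torsions$ai, torsions$aj, torsions$ak, torsions$al)
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    stop("bonded term refers to a site index out of range")
  if (nrow(bonds)) {
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bonds")
    if (any(bonds$k <= 0) || any(bonds$r0 <= 0))
      stop("bond parameters must be positive")
  }
  if (is.null(exclusions)) exclusions <- derive_exclusions(n, bonds)
  structure(
    list(sites = sites, bonds = bonds, angles = angles,
         g96_angles = g96_angles, torsions = torsions,
         exclusions = exclusions),
    class = "cg_topology"
  )
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf(
    "CG topology: %d sites, %d bonds, %d angles, %d restraint angles, %d torsions\n",
    nrow(x$sites), nrow(x$bonds), nrow(x$angles), nrow(x$g96_angles),
    nrow(x$torsions)))
  invisible(x)
}

#' Number of sites in a topology
#' @param topo A [cg_topology()].
#' @return Integer count.
#' @export
n_sites <- function(topo) nrow(topo$sites)

#' Build a CG peptide topology from sequence
#'
#' One backbone bead per residue at the alpha-carbon position plus up to
#' four sidechain beads per residue from [sidechain_template()]. Under
#' version 2.4 the Ala backbone bead is apolar and every other backbone bead
#' polar; versions 1 and 2.3 use the legacy `ca` backbone type. With
#' `termini = "charged"` the terminal backbone beads carry the `pos`
#' (N-terminus) and `neg` (C-terminus) types, the anchoring device of the
#' pre-2.4 force field.
#'
#' @param sequence One-letter amino-acid string.
#' @param version Force-field version, `"1"`, `"2.3"` or `"2.4"`.
#' @param termini `"neutral"` (capped) or `"charged"`.
#' @param bond_k Default harmonic bond force constant, kJ/mol/nm^2. Bonded
#'   constants are properties of the parameter set, not the paper text; the
#'   default is a stiff generic value and callers with fitted parameters
#'   should override per bond afterwards.
#' @param ca_ca_r0 Backbone pseudo-bond length, nm.
#' @param group Molecule group label.
#' @return A [cg_topology()].
#' @export
#' @examples
#' walp <- build_peptide_topology(peptide_sequence("WALP23"))
#' n_sites(walp)
build_peptide_topology <- function(sequence, version = "2.4",
                                   termini = c("neutral", "charged"),
                                   bond_k = 20000, ca_ca_r0 = 0.38,
                                   group = "PEP") {
  termini <- match.arg(termini)
  version <- match.arg(as.character(version), c("2.4", "2.3", "1"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty one-letter string")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters1, names(.aa1to3))
  if (length(bad))
    stop("sequence error: unknown residue letter(s) ",
         paste(unique(bad), collapse = ", "))
  res3 <- .aa1to3[letters1]
  sites <- list(); bonds <- list()
  idx <- 0L
  prev_ca <- NA_integer_
  for (ri in seq_along(res3)) {
    rn <- res3[[ri]]
    bb_type <- if (version == "2.4") {
      if (rn == "ALA") "ap" else "p"
    } else "ca"
    idx <- idx + 1L
    ca_idx <- idx
    sites[[length(sites) + 1L]] <- data.frame(
      name = "CA", site_type = bb_type, mass = .backbone_mass(rn),
      residue_index = ri, residue_name = rn, group = group)
    if (!is.na(prev_ca))
      bonds[[length(bonds) + 1L]] <-
        data.frame(i = prev_ca, j = ca_idx, k = bond_k, r0 = ca_ca_r0)
    prev_ca <- ca_idx
    tmpl <- sidechain_template(rn, version)
    local_idx <- c(CA = ca_idx)
    for (si in seq_len(nrow(tmpl))) {
      idx <- idx + 1L
      sites[[length(sites) + 1L]] <- data.frame(
        name = tmpl$name[si], site_type = tmpl$type[si],
        mass = tmpl$mass[si], residue_index = ri, residue_name = rn,
        group = group)
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = unname(local_idx[tmpl$parent[si]]), j = idx,
        k = bond_k, r0 = tmpl$r0[si])
      local_idx[tmpl$name[si]] <- idx
    }
  }
  sites <- do.call(rbind, sites)
  bonds <- if (length(bonds)) do.call(rbind, bonds) else NULL
  if (termini == "charged") {
    ca_rows <- which(sites$name == "CA")
    sites$site_type[ca_rows[1]] <- "pos"
    sites$site_type[ca_rows[length(ca_rows)]] <- "neg"
  }
  cg_topology(sites, bonds)
}

#' Default DOPC lipid template
#'
#' Eleven beads: choline (`ch`), phosphate (`ph`), glycerol (`gl`), two
#' ester beads (`e1`, `e2`) and a three-bead (`s1`, `sd`, `sm`) oleoyl tail
#' per chain, the `sd` bead holding the cis double-bond segment. Masses sum
#' to the DOPC molecular weight; `z0` gives the ideal depth (nm, absolute
#' value) of each bead used by the slab builder, placing the ester beads at
#' 1.45 nm so the ester-ester bilayer thickness is 29 Angstrom by
#' construction.
#'
#' @return Data frame with columns `name`, `type`, `mass`, `parent`, `r0`,
#'   `z0`.
#' @export
dopc_template <- function() {
  data.frame(
    name   = c("CH", "PH", "GL", "E1", "E2",
               "S1A", "SDA", "SMA", "S1B", "SDB", "SMB"),
    type   = c("ch", "ph", "gl", "e1", "e2",
               "s1", "sd", "sm", "s1", "sd", "sm"),
    mass   = c(87.16, 94.97, 41.07, 58.04, 58.04,
               77.15, 73.10, 73.16, 77.15, 73.10, 73.16),
    parent = c(NA, "CH", "PH", "GL", "GL",
               "E1", "S1A", "SDA", "E2", "S1B", "SDB"),
    r0     = c(NA, 0.25, 0.35, 0.37, 0.37,
               0.45, 0.40, 0.35, 0.45, 0.40, 0.35),
    z0     = c(2.35, 2.10, 1.75, 1.45, 1.45,
               1.00, 0.60, 0.25, 1.00, 0.60, 0.25)
  )
}

#' Build a one-molecule DOPC topology
#'
#' @param template Lipid template in the layout of [dopc_template()]. Must
#'   name only registered lipid site types and include the two ester beads
#'   required by the thickness analysis.
#' @param bond_k Harmonic bond force constant, kJ/mol/nm^2.
#' @param angle_k Chain-straightening stiffness, kJ/mol/rad^2: each
#'   grandparent-parent-child triple along the template connectivity gets a
#'   polynomial angle term k (theta - pi)^2 (exactly representable in the
#'   fourth-order form), keeping 1-3 neighbors from folding onto each
#'   other. Set 0 to omit.
#' @param registry A [site_registry()].
#' @param group Molecule group label.
#' @return A [cg_topology()].
#' @export
build_dopc_topology <- function(template = dopc_template(), bond_k = 5000,
                                angle_k = 10,
                                registry = site_registry("2.4"),
                                group = "DOPC") {
  bad <- setdiff(template$type, registry$lipid_types)
  if (length(bad))
    stop("unregistered lipid site type(s): ", paste(unique(bad),
                                                    collapse = ", "))
  if (!all(c("e1", "e2") %in% template$type))
    stop("lipid template must contain the e1 and e2 ester sites")
  n <- nrow(template)
  sites <- data.frame(
    name = template$name, site_type = template$type, mass = template$mass,
    residue_index = 1L, residue_name = "DOPC", group = group)
  have_parent <- which(!is.na(template$parent))
  bonds <- data.frame(
    i = match(template$parent[have_parent], template$name),
    j = have_parent, k = bond_k, r0 = template$r0[have_parent])
  if (any(is.na(bonds$i))) stop("template parent names a missing bead")
  angles <- NULL
  if (angle_k > 0) {
    parent_of <- match(template$parent, template$name)
    trip <- list()
    for (b in seq_len(n)) {
      p <- parent_of[b]
      if (!is.na(p) && !is.na(parent_of[p]))
        trip[[length(trip) + 1L]] <-
          data.frame(ai = parent_of[p], aj = p, ak = b,
                     theta0 = pi)                       # chains straight
    }
    ## splay angle between sibling beads (the two esters on the glycerol)
    for (p in seq_len(n)) {
      kids <- which(parent_of == p)
      if (length(kids) >= 2L) {
        pr <- utils::combn(kids, 2L)
        for (cc in seq_len(ncol(pr)))
          trip[[length(trip) + 1L]] <-
            data.frame(ai = pr[1, cc], aj = p, ak = pr[2, cc],
                       theta0 = 70 * pi / 180)
      }
    }
    if (length(trip)) {
      angles <- do.call(rbind, trip)
      ## harmonic k (theta - theta0)^2 expressed in the quartic form
      angles$c0 <- angle_k * angles$theta0^2
      angles$c1 <- -2 * angle_k * angles$theta0
      angles$c2 <- angle_k
      angles$c3 <- 0
      angles$c4 <- 0
      angles$theta0 <- NULL
    }
  }
  cg_topology(sites, bonds, angles)
}

#' Merge topologies into one system
#'
#' Concatenates sites with shifted indices; groups are kept as labelled.
#'
#' @param ... [cg_topology()] objects.
#' @return A combined [cg_topology()].
#' @export
merge_topologies <- function(...) {
  topos <- list(...)
  if (length(topos) == 1L && is.list(topos[[1]]) &&
      !inherits(topos[[1]], "cg_topology"))
    topos <- topos[[1]]
  offset <- 0L
  parts <- list(sites = list(), bonds = list(), angles = list(),
                g96 = list(), tors = list(), ex = list())
  for (tp in topos) {
    stopifnot(inherits(tp, "cg_topology"))
    parts$sites[[length(parts$sites) + 1L]] <- tp$sites
    shift <- function(d, cols) {
      if (nrow(d)) d[cols] <- d[cols] + offset
      d
    }
    parts$bonds[[length(parts$bonds) + 1L]] <- shift(tp$bonds, c("i", "j"))
    parts$angles[[length(parts$angles) + 1L]] <-
      shift(tp$angles, c("ai", "aj", "ak"))
    parts$g96[[length(parts$g96) + 1L]] <-
      shift(tp$g96_angles, c("ai", "aj", "ak"))
    parts$tors[[length(parts$tors) + 1L]] <-
      shift(tp$torsions, c("ai", "aj", "ak", "al"))
    if (nrow(tp$exclusions))
      parts$ex[[length(parts$ex) + 1L]] <- tp$exclusions + offset
    offset <- offset + nrow(tp$sites)
  }
  sites <- do.call(rbind, parts$sites)
  rownames(sites) <- NULL
  cg_topology(sites,
              do.call(rbind, parts$bonds),
              do.call(rbind, parts$angles),
              do.call(rbind, parts$g96),
              do.call(rbind, parts$tors),
              exclusions = if (length(parts$ex)) do.call(rbind, parts$ex)
                           else matrix(integer(), ncol = 2L))
}

#' Replicate a molecule topology n times
#'
#' @param topo A single-molecule [cg_topology()].
#' @param n Copy count.
#' @param group_prefix Prefix for per-copy group labels.
#' @return A combined [cg_topology()] with `n * n_sites(topo)` sites.
#' @export
replicate_topology <- function(topo, n, group_prefix = NULL) {
  copies <- lapply(seq_len(n), function(i) {
    tp <- topo
    if (!is.null(group_prefix))
      tp$sites$group <- paste0(group_prefix, i)
    else tp$sites$group <- paste0(tp$sites$group, i)
    tp
  })
  merge_topologies(copies)
}

#' Helix restraint parameters
#'
#' Defaults are the ideal right-handed alpha-helix restraint set: a
#' GROMOS-96 angle potential U = k/2 (cos theta - cos theta0)^2 with
#' theta0 = 89 degrees and k = 2000 kJ/mol on every consecutive
#' Calpha-Calpha-Calpha triplet, and a harmonic torsion
#' U = k/2 (phi - phi0)^2 with phi0 = 50 degrees and
#' k = 2000 kJ/mol/rad^2 on every Calpha quadruplet.
#'
#' @param theta0 Angle target, degrees.
#' @param k_theta Angle force constant, kJ/mol.
#' @param phi0 Torsion target, degrees.
#' @param k_phi Torsion force constant, kJ/mol/rad^2.
#' @return List of class `helix_restraint_spec`.
#' @export
helix_restraint_spec <- function(theta0 = 89, k_theta = 2000,
                                 phi0 = 50, k_phi = 2000) {
  structure(list(theta0 = theta0, k_theta = k_theta,
                 phi0 = phi0, k_phi = k_phi),
            class = "helix_restraint_spec")
}

#' Restrain a peptide in an ideal helical conformation
#'
#' Adds one GROMOS-96 angle term per consecutive backbone triplet (N - 2
#' terms for N residues) and one harmonic torsion per quadruplet (N - 3
#' terms), keeping the peptide an ideal right-handed alpha helix during
#' insertion simulations.
#'
#' @param topo A peptide [cg_topology()] with at least 3 backbone beads.
#' @param spec A [helix_restraint_spec()].
#' @return The topology with restraint terms appended.
#' @export
apply_helix_restraints <- function(topo, spec = helix_restraint_spec()) {
  ca <- topo$sites$index[topo$sites$name == "CA"]
  ca <- ca[order(topo$sites$residue_index[match(ca, topo$sites$index)])]
  n <- length(ca)
  if (n < 3L) stop("need at least 3 backbone beads for helix restraints")
  ang <- data.frame(ai = ca[seq_len(n - 2L)], aj = ca[seq_len(n - 2L) + 1L],
                    ak = ca[seq_len(n - 2L) + 2L],
                    theta0 = spec$theta0, k_theta = spec$k_theta)
  topo$g96_angles <- rbind(topo$g96_angles, ang)
  if (n >= 4L) {
    m <- n - 3L
    tor <- data.frame(ai = ca[seq_len(m)], aj = ca[seq_len(m) + 1L],
                      ak = ca[seq_len(m) + 2L], al = ca[seq_len(m) + 3L],
                      phi0 = spec$phi0, k_phi = spec$k_phi)
    topo$torsions <- rbind(topo$torsions, tor)
  }
  topo
}

#' Benchmark peptide sequences
#'
#' `LS3` is the designed amphipathic interfacial peptide (LSSLLSL)3;
#' `WALP23` the single-pass transmembrane peptide GWW(LA)8LWWA; `L24` and
#' `LA12` the lysine-flanked K2-L24-K2 and K2-(LA)12-K2 helices.
#'
#' @param peptide One of `"LS3"`, `"WALP23"`, `"L24"`, `"LA12"`.
#' @return One-letter sequence string.
#' @export
peptide_sequence <- function(peptide = c("LS3", "WALP23", "L24", "LA12")) {
  peptide <- match.arg(toupper(peptide), c("LS3", "WALP23", "L24", "LA12"))
  switch(peptide,
         LS3    = strrep("LSSLLSL", 3L),
         WALP23 = paste0("GWW", strrep("LA", 8L), "LWWA"),
         L24    = paste0("KK", strrep("L", 24L), "KK"),
         LA12   = paste0("KK", strrep("LA", 12L), "KK"))
}

#' Residue pair defining the helix-axis tilt vector
#'
#' The tilt of an inserted helix is measured on the vector spanning two
#' alpha carbons well inside the helical core: residues 5 and 16 for LS3,
#' 5 and 19 for WALP23, and 8 and 26 for the lysine-flanked L24 and (LA)12
#' peptides. Residue numbering is 1-based.
#'
#' @param peptide One of `"LS3"`, `"WALP23"`, `"L24"`, `"LA12"`.
#' @return Integer vector `c(i, j)`.
#' @export
tilt_vector_residues <- function(peptide) {
  peptide <- match.arg(toupper(peptide), c("LS3", "WALP23", "L24", "LA12"))
  switch(peptide,
         LS3    = c(5L, 16L),
         WALP23 = c(5L, 19L),
         L24    = c(8L, 26L),
         LA12   = c(8L, 26L))
}

.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

#' Map an atomistic structure onto CG sites
#'
#' Places every CG site at the mass-weighted center of its atom subgroup;
#' the backbone bead subgroup is conventionally the lone alpha-carbon atom,
#' so it sits exactly on the Calpha position. Subgroups within a residue
#' must be disjoint and complete.
#'
#' @param atoms Data frame of atomistic coordinates with columns `atom`
#'   (atom name), `residue_index`, `residue_name`, `x`, `y`, `z` (nm) and
#'   either `mass` (amu) or `element`.
#' @param mapping Named list: `mapping[[residue_name]]` is a list of site
#'   specs, each `list(name =, type =, atoms = c(...))`, in bead order with
#'   the backbone bead first.
#' @param bond_k,group Passed to the generated topology.
#' @return List with `coords` (n x 3 matrix, nm) and `topology`
#'   (a [cg_topology()]; consecutive beads of a residue are bonded in
#'   template order with the observed distances as r0).
#' @export
map_structure_to_cg <- function(atoms, mapping, bond_k = 20000,
                                group = "PEP") {
  if (is.null(atoms$mass)) {
    if (is.null(atoms$element)) stop("atoms need a mass or element column")
    atoms$mass <- .element_mass[as.character(atoms$element)]
    if (any(is.na(atoms$mass))) stop("unknown element in structure")
  }
  res_ids <- unique(atoms$residue_index)
  sites <- list(); coords <- list(); bonds <- list()
  idx <- 0L
  prev_ca <- NA_integer_
  for (ri in res_ids) {
    sub <- atoms[atoms$residue_index == ri, , drop = FALSE]
    rn <- sub$residue_name[1]
    spec <- mapping[[rn]]
    if (is.null(spec)) stop("mapping error: no mapping for residue ", rn)
    used <- character()
    parent_idx <- NA_integer_
    for (si in seq_along(spec)) {
      s <- spec[[si]]
      hit <- match(s$atoms, sub$atom)
      if (any(is.na(hit)))
        stop("mapping error: residue ", ri, " (", rn, ") is missing atom(s) ",
             paste(s$atoms[is.na(hit)], collapse = ", "))
      if (any(s$atoms %in% used))
        stop("spec error: overlapping subgroups in residue ", rn)
      used <- c(used, s$atoms)
      m <- sub$mass[hit]
      com <- colSums(cbind(sub$x[hit], sub$y[hit], sub$z[hit]) * m) / sum(m)
      idx <- idx + 1L
      coords[[idx]] <- com
      sites[[idx]] <- data.frame(
        name = s$name, site_type = s$type, mass = sum(m),
        residue_index = ri, residue_name = rn, group = group)
      if (si == 1L) {
        if (!is.na(prev_ca)) {
          r0 <- sqrt(sum((coords[[idx]] - coords[[prev_ca]])^2))
          bonds[[length(bonds) + 1L]] <-
            data.frame(i = prev_ca, j = idx, k = bond_k, r0 = r0)
        }
        prev_ca <- idx
        parent_idx <- idx
      } else {
        r0 <- sqrt(sum((coords[[idx]] - coords[[parent_idx]])^2))
        bonds[[length(bonds) + 1L]] <-
          data.frame(i = parent_idx, j = idx, k = bond_k, r0 = r0)
        parent_idx <- idx
      }
    }
  }
  coords <- do.call(rbind, coords)
  topo <- cg_topology(do.call(rbind, sites),
                      if (length(bonds)) do.call(rbind, bonds) else NULL)
  list(coords = coords, topology = topo)
}
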