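# Synthetic PDB fixtures with constructive ground truth.
#
# Every scenario writes valid fixed-column PDB text exercising one
# detection, clustering or statistics rule, together with a ground-truth
# record computed while the geometry is constructed — never by running
# the detector on its own output. Each fixture is randomised per seed
# (ligand distances, orientations, a global rigid motion) without moving
# any quantity a rule depends on across its decision boundary.

FIXTURE_SCENARIOS <- c("SALT", "C4_SITE", "BIDENTATE", "ANGLE_PROBE",
                       "INTERFACE", "COACTIVE", "DUPLICATED_ASU",
                       "BACKBONE_ONLY", "FAMILY")

#' Generate a synthetic structure fixture
#'
#' @param scenario one of `"SALT"` (zinc + chloride + waters, excluded as a
#'   salt), `"C4_SITE"` (tetrahedral Cys4 zinc site; `n_copies > 1` adds
#'   assembly transforms that duplicate the whole site), `"BIDENTATE"`
#'   (Asp donating both carboxylate oxygens plus two His), `"ANGLE_PROBE"`
#'   (two Asp oxygens subtending exactly `theta` degrees at the zinc),
#'   `"INTERFACE"` (one His per chain copy; the site only exists in the
#'   `n_transforms`-fold assembly), `"COACTIVE"` (multi-metal site bridged
#'   by histidines), `"DUPLICATED_ASU"` (`n_copies` identical chains, only
#'   the first in the assembly), `"BACKBONE_ONLY"` (no side-chain atoms) or
#'   `"FAMILY"` (`k` sequence families of mutated chains, no metals).
#' @param seed integer seed; generation is reproducible and the caller's
#'   random-number state is left untouched.
#' @param resolution value stamped into REMARK 2 (Angstroms); `NA` omits
#'   the record (an NMR-like entry).
#' @param theta,d1,d2 ANGLE_PROBE geometry: angle (degrees) and the two
#'   zinc-oxygen distances. The probe is written in its canonical frame so
#'   the constructed angle survives the 3-decimal PDB coordinate
#'   precision; `theta = 45` is represented exactly, but other angles
#'   within ~0.3 degrees of the 45-degree decision boundary may quantize
#'   across it.
#' @param n_transforms INTERFACE: number of assembly rotations.
#' @param n_copies C4_SITE / DUPLICATED_ASU: copies of the site or chain.
#' @param elements COACTIVE: metal elements, first must be `"ZN"`.
#' @param k,mutation_rate,chains_per_family,chain_length FAMILY parameters.
#' @return a `zb_fixture`: list with `text` (PDB-format string), `truth`
#'   (ground-truth record), `scenario` and `seed`.
#' @examples
#' fx <- make_fixture("SALT", seed = 7)
#' fx$truth$exclusions
#' @export
make_fixture <- function(scenario, seed = 1L, resolution = 2.0,
                         theta = 60, d1 = 2.0, d2 = 2.2,
                         n_transforms = 3L, n_copies = NULL,
                         elements = c("ZN", "CU"),
                         k = 3L, mutation_rate = 0.05,
                         chains_per_family = 8L, chain_length = 80L) {
  scenario <- match.arg(scenario, FIXTURE_SCENARIOS)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  fx <- switch(scenario,
    SALT = fx_salt(),
    C4_SITE = fx_c4(n_copies %||% 1L),
    BIDENTATE = fx_bidentate(),
    ANGLE_PROBE = fx_angle_probe(theta, d1, d2),
    INTERFACE = fx_interface(n_transforms),
    COACTIVE = fx_coactive(elements),
    DUPLICATED_ASU = fx_duplicated_asu(n_copies %||% 2L),
    BACKBONE_ONLY = fx_backbone_only(),
    FAMILY = fx_family(k, mutation_rate, chains_per_family, chain_length)
  )
  fx$resolution <- resolution
  structure(list(text = render_fixture(fx), truth = fx$truth,
                 scenario = scenario, seed = seed),
            class = "zb_fixture")
}

#' @export
print.zb_fixture <- function(x, ...) {
  cat(sprintf("zb_fixture %s (seed %d): %d line(s) of PDB text\n",
              x$scenario, x$seed,
              length(gregexpr("\n", x$text, fixed = TRUE)[[1]])))
  invisible(x)
}

#' Exact-angle probe coordinates
#'
#' Places a metal at the origin and two oxygen positions of one residue so
#' that the angle subtended at the metal equals `theta` to within 1e-9
#' degrees; used to exercise the minimum-angle liganding rule at its
#' boundary.
#'
#' @param theta angle in degrees, 0 < theta < 180.
#' @param d1,d2 metal-oxygen distances, `d1 <= d2`.
#' @return list with `metal`, `o1`, `o2` coordinate vectors.
#' @export
make_angle_probe <- function(theta, d1 = 2.0, d2 = 2.2) {
  if (!is.finite(theta) || theta <= 0 || theta >= 180) {
    stop("theta must lie strictly between 0 and 180 degrees")
  }
  if (d1 > d2) stop("d1 must not exceed d2")
  th <- theta * pi / 180
  list(metal = c(0, 0, 0),
       o1 = c(d1, 0, 0),
       o2 = c(d2 * cos(th), d2 * sin(th), 0))
}

# ---- geometry building blocks ------------------------------------------

fx_atom <- function(type, name, resname, chain, resno, pos, element) {
  data.frame(type = type, name = name, altloc = "", resname = resname,
             chain = chain, resno = resno, icode = "",
             x = pos[1], y = pos[2], z = pos[3], occ = 1,
             element = element, stringsAsFactors = FALSE)
}

# standard-ish backbone around a CA position plus explicit side atoms
# (list of name = list(pos, element)); GLY gets no CB
fx_residue <- function(chain, resno, resname, ca, side = list()) {
  rows <- list(
    fx_atom("ATOM", "N", resname, chain, resno, ca + c(-1.46, 0, 0), "N"),
    fx_atom("ATOM", "CA", resname, chain, resno, ca, "C"),
    fx_atom("ATOM", "C", resname, chain, resno, ca + c(1.52, 0, 0), "C"),
    fx_atom("ATOM", "O", resname, chain, resno, ca + c(2.1, 1.05, 0), "O")
  )
  if (resname != "GLY") {
    rows <- c(rows, list(
      fx_atom("ATOM", "CB", resname, chain, resno, ca + c(0, 1.1, 1.1), "C")
    ))
  }
  for (nm in names(side)) {
    rows <- c(rows, list(
      fx_atom("ATOM", nm, resname, chain, resno, side[[nm]]$pos,
              side[[nm]]$element)
    ))
  }
  do.call(rbind, rows)
}

# a liganding residue whose side-chain donor atoms sit at given absolute
# positions, with the backbone pushed out along `dir` clear of the cutoff
fx_ligand_residue <- function(chain, resno, resname, dir, side) {
  fx_residue(chain, resno, resname, ca = 6.0 * dir, side = side)
}

# vectorized N/CA/C/O/CB backbone for a whole chain (CB dropped for GLY)
fx_chain_backbone <- function(chain, seq3, ca_mat) {
  offs <- rbind(c(-1.46, 0, 0), c(0, 0, 0), c(1.52, 0, 0),
                c(2.1, 1.05, 0), c(0, 1.1, 1.1))
  nms <- c("N", "CA", "C", "O", "CB")
  els <- c("N", "C", "C", "O", "C")
  n <- length(seq3)
  ri <- rep(seq_len(n), each = 5)
  ai <- rep(1:5, n)
  pos <- ca_mat[ri, , drop = FALSE] + offs[ai, , drop = FALSE]
  keep <- !(nms[ai] == "CB" & seq3[ri] == "GLY")
  data.frame(type = "ATOM", name = nms[ai][keep], altloc = "",
             resname = seq3[ri][keep], chain = chain,
             resno = ri[keep], icode = "",
             x = pos[keep, 1], y = pos[keep, 2], z = pos[keep, 3],
             occ = 1, element = els[ai][keep], stringsAsFactors = FALSE)
}

# inert far-away protein stretch so the model has a real (non backbone-
# only) chain; LEU side chains are carbon, never liganding candidates
fx_spacer <- function(chain, resno_from, n, origin) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    ca <- origin + c((i - 1) * 3.8, 0, 0)
    fx_residue(chain, resno_from + i - 1L, "LEU", ca,
               side = list(CG = list(pos = ca + c(0.6, 2.3, 1.4),
                                     element = "C")))
  }))
}

unit3 <- function(v) v / sqrt(sum(v^2))

# four tetrahedral directions, randomly oriented
tetra_dirs <- function() {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  R <- random_rotation()
  dirs %*% t(R)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rnorm_clip <- function(mean, sd, lo, hi) {
  min(hi, max(lo, stats::rnorm(1, mean, sd)))
}

# render atoms (+ optional local-frame assembly transforms) to PDB text,
# applying a random global rigid motion; assembly transforms are
# conjugated into the file frame so they still describe the same motion
render_fixture <- function(fx) {
  atoms <- fx$atoms
  if (isTRUE(fx$no_rigid_motion)) {
    R0 <- diag(3)
    t0 <- c(0, 0, 0)
  } else {
    R0 <- random_rotation()
    t0 <- stats::runif(3, -15, 15)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R0)
  atoms$x <- xyz[, 1] + t0[1]
  atoms$y <- xyz[, 2] + t0[2]
  atoms$z <- xyz[, 3] + t0[3]
  assemblies <- lapply(fx$assemblies %||% list(), function(a) {
    a$groups <- lapply(a$groups, function(grp) {
      grp$transforms <- lapply(grp$transforms, function(tr) {
        A <- R0 %*% tr$rotation %*% t(R0)
        b <- as.vector(R0 %*% tr$translation + t0 - A %*% t0)
        list(rotation = A, translation = b)
      })
      grp
    })
    a
  })
  model <- list(pdb_id = fx$pdb_id %||% "9ZZZ",
                molecule_name = fx$molecule_name %||% "SYNTHETIC PROTEIN",
                resolution = fx$resolution %||% NA_real_,
                assemblies = assemblies,
                atoms = atoms)
  write_pdb(model)
}

identity_transform <- function() {
  list(rotation = diag(3), translation = c(0, 0, 0))
}

site_truth <- function(signature, n_metals = 1L, copies = 1L,
                       coordination = NA_integer_, n_residues = NA_integer_,
                       elements = "ZN") {
  list(signature = signature, n_metals = as.integer(n_metals),
       copies = as.integer(copies), coordination = coordination,
       n_residues = n_residues, elements = sort(elements))
}

# ---- scenarios ----------------------------------------------------------

fx_salt <- function() {
  dirs <- tetra_dirs()
  atoms <- rbind(
    fx_spacer("A", 1L, 5L, origin = c(30, 0, 0)),
    fx_atom("HETATM", "ZN", "ZN", "A", 200L, c(0, 0, 0), "ZN"),
    fx_atom("HETATM", "CL", "CL", "A", 201L,
            rnorm_clip(2.25, 0.03, 2.1, 2.4) * dirs[1, ], "CL"),
    fx_atom("HETATM", "O", "HOH", "A", 301L,
            rnorm_clip(2.1, 0.05, 1.9, 2.3) * dirs[2, ], "O"),
    fx_atom("HETATM", "O", "HOH", "A", 302L,
            rnorm_clip(2.1, 0.05, 1.9, 2.3) * dirs[3, ], "O"),
    fx_atom("HETATM", "O", "HOH", "A", 303L,
            rnorm_clip(2.1, 0.05, 1.9, 2.3) * dirs[4, ], "O")
  )
  list(atoms = atoms, pdb_id = "9SLT", molecule_name = "LYSOZYME",
       truth = list(n_zinc = 1L, sites = list(),
                    exclusions = "TOO_FEW_RESIDUES"))
}

fx_c4 <- function(n_copies = 1L) {
  stopifnot(n_copies >= 1)
  dirs <- tetra_dirs()
  lig <- do.call(rbind, lapply(1:4, function(i) {
    d <- rnorm_clip(2.33, 0.04, 2.2, 2.5)
    fx_ligand_residue("A", 2L * i, "CYS", dirs[i, ],
                      side = list(SG = list(pos = d * dirs[i, ],
                                            element = "S")))
  }))
  atoms <- rbind(
    fx_spacer("A", 20L, 3L, origin = c(25, 0, 0)),
    lig,
    fx_atom("HETATM", "ZN", "ZN", "A", 100L, c(0, 0, 0), "ZN")
  )
  assemblies <- list()
  if (n_copies > 1) {
    # rotations about a z axis through (60, 0, 0): every copy of the site
    # lands well apart, so each expands to its own identical-source site
    transforms <- lapply(seq_len(n_copies), function(kk) {
      if (kk == 1) return(identity_transform())
      p <- c(60, 0, 0)
      R <- rotation_about_axis(c(0, 0, 1), 360 * (kk - 1) / n_copies)
      list(rotation = R, translation = as.vector(p - R %*% p))
    })
    assemblies <- list(list(id = "1", energy = NA_real_,
                            groups = list(list(chain_ids = "A",
                                               transforms = transforms))))
  }
  list(atoms = atoms, assemblies = assemblies, pdb_id = "9ZC4",
       molecule_name = "ZINC FINGER PROTEIN",
       truth = list(n_zinc = 1L,
                    sites = list(site_truth("C4", copies = n_copies,
                                            coordination = 4L,
                                            n_residues = 4L)),
                    exclusions = character(0)))
}

fx_bidentate <- function() {
  dirs <- tetra_dirs()
  ang <- stats::runif(1, 50, 70)  # carboxylate bite angle, safely >= 45
  dd1 <- rnorm_clip(2.0, 0.03, 1.9, 2.1)
  dd2 <- rnorm_clip(2.2, 0.03, 2.1, 2.3)
  u <- unit3(dirs[1, ])
  # second oxygen at `ang` degrees from the first, rotated about an axis
  # perpendicular to u
  perp <- unit3(pracma_nullvec(u))
  v <- as.vector(rotation_about_axis(perp, ang) %*% u)
  asp <- fx_ligand_residue("A", 2L, "ASP", u, side = list(
    OD1 = list(pos = dd1 * u, element = "O"),
    OD2 = list(pos = dd2 * v, element = "O")
  ))
  his <- do.call(rbind, lapply(2:3, function(i) {
    d <- rnorm_clip(2.1, 0.03, 2.0, 2.2)
    fx_ligand_residue("A", 2L * i, "HIS", dirs[i, ],
                      side = list(NE2 = list(pos = d * dirs[i, ],
                                             element = "N")))
  }))
  atoms <- rbind(fx_spacer("A", 20L, 3L, origin = c(25, 0, 0)), asp, his,
                 fx_atom("HETATM", "ZN", "ZN", "A", 100L, c(0, 0, 0), "ZN"))
  list(atoms = atoms, pdb_id = "9BDT",
       molecule_name = "CARBONIC ANHYDRASE",
       truth = list(n_zinc = 1L,
                    sites = list(site_truth("D1H2", coordination = 4L,
                                            n_residues = 3L)),
                    exclusions = character(0)))
}

# any unit vector perpendicular to u
pracma_nullvec <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  unit3(v)
}

fx_angle_probe <- function(theta, d1, d2) {
  probe <- make_angle_probe(theta, d1, d2)
  dirs <- tetra_dirs()
  u3 <- dirs[4, ]
  asp <- fx_ligand_residue("A", 2L, "ASP", c(1, 0, 0), side = list(
    OD1 = list(pos = probe$o1, element = "O"),
    OD2 = list(pos = probe$o2, element = "O")
  ))
  his <- fx_ligand_residue("A", 4L, "HIS", u3, side = list(
    NE2 = list(pos = rnorm_clip(2.1, 0.03, 2.0, 2.2) * u3, element = "N")
  ))
  atoms <- rbind(fx_spacer("A", 20L, 3L, origin = c(25, 0, 0)), asp, his,
                 fx_atom("HETATM", "ZN", "ZN", "A", 100L, c(0, 0, 0), "ZN"))
  both_kept <- theta >= 45  # discard rule is strictly < 45 degrees
  truth <- if (both_kept) {
    list(n_zinc = 1L, n_contacts = 3L,
         sites = list(site_truth("D1H1", coordination = 3L,
                                 n_residues = 2L)),
         exclusions = character(0))
  } else {
    # only the closer oxygen survives: 2 protein residues but 2 atoms
    list(n_zinc = 1L, n_contacts = 2L, sites = list(),
         exclusions = "TOO_FEW_ATOMS")
  }
  # written in the canonical frame: PDB coordinates carry 3 decimals, and
  # an arbitrary rigid motion would perturb the constructed angle by up to
  # ~0.03 degrees, enough to flip the strict 45-degree boundary; in this
  # frame the 45-degree probe (equal x/y components) survives quantization
  # exactly. Requested angles within ~0.3 degrees of the boundary, other
  # than exactly 45, are still subject to quantization.
  list(atoms = atoms, pdb_id = "9ANG", molecule_name = "PROBE PROTEIN",
       truth = truth, no_rigid_motion = TRUE)
}

fx_interface <- function(n_transforms = 3L) {
  stopifnot(n_transforms >= 2)
  d <- rnorm_clip(2.1, 0.03, 2.0, 2.2)
  u <- unit3(c(1, 0.3, 0))  # off-axis so rotated copies separate
  his <- fx_ligand_residue("A", 10L, "HIS", u, side = list(
    NE2 = list(pos = d * u, element = "N")
  ))
  atoms <- rbind(
    fx_spacer("A", 1L, 4L, origin = c(20, 5, 0)),
    his,
    fx_atom("HETATM", "ZN", "ZN", "A", 100L, c(0, 0, 0), "ZN")
  )
  transforms <- lapply(seq_len(n_transforms), function(kk) {
    list(rotation = rotation_about_axis(c(0, 0, 1),
                                        360 * (kk - 1) / n_transforms),
         translation = c(0, 0, 0))
  })
  assemblies <- list(list(id = "1", energy = NA_real_,
                          groups = list(list(chain_ids = "A",
                                             transforms = transforms))))
  assembly_truth <- if (n_transforms >= 3) {
    list(n_zinc = 1L,
         sites = list(site_truth(sprintf("H%d", n_transforms),
                                 coordination = n_transforms,
                                 n_residues = n_transforms)),
         exclusions = character(0))
  } else {
    list(n_zinc = 1L, sites = list(), exclusions = "TOO_FEW_ATOMS")
  }
  truth <- c(assembly_truth,
             list(asu = list(n_zinc = 1L, sites = list(),
                             exclusions = "TOO_FEW_RESIDUES")))
  list(atoms = atoms, assemblies = assemblies, pdb_id = "9INS",
       molecule_name = "INSULIN", truth = truth)
}

fx_coactive <- function(elements = c("ZN", "CU")) {
  stopifnot(length(elements) >= 2, elements[1] == "ZN",
            all(elements %in% METAL_ELEMENTS))
  dirs <- tetra_dirs()
  cys <- do.call(rbind, lapply(1:2, function(i) {
    d <- rnorm_clip(2.3, 0.04, 2.2, 2.4)
    fx_ligand_residue("A", 2L * i, "CYS", dirs[i, ],
                      side = list(SG = list(pos = d * dirs[i, ],
                                            element = "S")))
  }))
  extra <- elements[-1]
  rows <- list(cys)
  resno <- 10L
  for (j in seq_along(extra)) {
    u <- unit3(dirs[3, ] + 0.8 * j * dirs[4, ])
    # bridging histidine: NE2 coordinates the central zinc, ND1 the
    # second metal further out along the same direction
    rows[[length(rows) + 1L]] <- fx_ligand_residue(
      "A", resno, "HIS", u,
      side = list(NE2 = list(pos = 2.05 * u, element = "N"),
                  ND1 = list(pos = 4.2 * u, element = "N")))
    rows[[length(rows) + 1L]] <-
      fx_atom("HETATM", extra[j], extra[j], "A", 110L + j, 6.2 * u,
              extra[j])
    resno <- resno + 2L
  }
  atoms <- rbind(do.call(rbind, rows),
                 fx_spacer("A", 30L, 3L, origin = c(25, 10, 0)),
                 fx_atom("HETATM", "ZN", "ZN", "A", 100L, c(0, 0, 0), "ZN"))
  n_extra_zn <- sum(extra == "ZN")
  list(atoms = atoms, pdb_id = "9COA",
       molecule_name = "SUPEROXIDE DISMUTASE",
       truth = list(
         n_zinc = 1L + n_extra_zn,
         sites = list(site_truth(
           sprintf("C2H%d", length(extra)),
           n_metals = length(elements),
           coordination = if (n_extra_zn == 0) 3L else NA_integer_,
           n_residues = 2L + length(extra),
           elements = elements)),
         exclusions = character(0)))
}

fx_duplicated_asu <- function(n_copies = 2L) {
  stopifnot(n_copies >= 2, n_copies <= 8)
  chains <- LETTERS[seq_len(n_copies)]
  pieces <- lapply(seq_along(chains), function(ci) {
    offset <- c(0, 30 * (ci - 1), 0)
    dirs <- tetra_dirs()
    lig <- do.call(rbind, lapply(1:4, function(i) {
      d <- rnorm_clip(2.33, 0.04, 2.2, 2.5)
      r <- fx_ligand_residue(chains[ci], 2L * i, "CYS", dirs[i, ],
                             side = list(SG = list(pos = d * dirs[i, ],
                                                   element = "S")))
      r[, c("x", "y", "z")] <- sweep(r[, c("x", "y", "z")], 2, offset, "+")
      r
    }))
    zn <- fx_atom("HETATM", "ZN", "ZN", chains[ci], 100L, offset, "ZN")
    rbind(lig, zn)
  })
  atoms <- rbind(do.call(rbind, pieces),
                 fx_spacer(chains[1], 20L, 3L, origin = c(25, -10, 0)))
  assemblies <- list(list(
    id = "1", energy = NA_real_,
    groups = list(list(chain_ids = chains[1],
                       transforms = list(identity_transform())))))
  list(atoms = atoms, assemblies = assemblies, pdb_id = "9DUP",
       molecule_name = "ADENOSINE DEAMINASE",
       truth = list(n_zinc = as.integer(n_copies),
                    sites = list(site_truth("C4", coordination = 4L,
                                            n_residues = 4L)),
                    exclusions = rep("NOT_IN_ASSEMBLY", n_copies - 1L)))
}

fx_backbone_only <- function() {
  atoms <- rbind(
    do.call(rbind, lapply(1:6, function(i) {
      ca <- c(4 + (i - 1) * 3.8, 0, 0)
      r <- fx_residue("A", i, "ALA", ca)
      r[r$name != "CB", , drop = FALSE]  # strictly N, CA, C, O
    })),
    fx_atom("HETATM", "ZN", "ZN", "A", 100L, c(0, 0, 0), "ZN")
  )
  list(atoms = atoms, pdb_id = "9BBO", molecule_name = "MODEL PROTEIN",
       truth = list(n_zinc = 1L, sites = list(),
                    exclusions = "NO_SIDECHAINS"))
}

fx_family <- function(k, mutation_rate, chains_per_family, chain_length) {
  stopifnot(k >= 1, mutation_rate >= 0, mutation_rate < 0.5,
            k * chains_per_family <= 52)
  aa1 <- sort(unname(AA_3TO1))
  aa3 <- names(AA_3TO1)[match(aa1, AA_3TO1)]
  chain_ids <- c(LETTERS, letters)[seq_len(k * chains_per_family)]
  # at most floor(rate * L) substitutions per member keeps every pair of
  # family members at >= 1 - 2*rate ungapped identity (>= 0.9 at the
  # default rate), while unrelated random parents align far below 0.9
  n_mut <- floor(mutation_rate * chain_length)
  families <- integer(0)
  seqs <- character(0)
  for (f in seq_len(k)) {
    parent <- sample(aa1, chain_length, replace = TRUE)
    for (m in seq_len(chains_per_family)) {
      s <- parent
      if (n_mut > 0 && m > 1) {
        pos <- sample(chain_length, n_mut)
        s[pos] <- vapply(s[pos], function(ch) {
          sample(setdiff(aa1, ch), 1)
        }, character(1))
      }
      id <- chain_ids[(f - 1) * chains_per_family + m]
      seqs[id] <- paste(s, collapse = "")
      families[id] <- f
    }
  }
  atoms <- do.call(rbind, lapply(seq_along(seqs), function(ci) {
    s <- strsplit(seqs[[ci]], "")[[1]]
    ca <- cbind((seq_along(s) - 1) * 3.8, 20 * ci, 0)
    fx_chain_backbone(names(seqs)[ci], aa3[match(s, aa1)], ca)
  }))
  list(atoms = atoms, pdb_id = "9FAM", molecule_name = "PROTEIN FAMILY SET",
       truth = list(n_zinc = 0L, sites = list(), exclusions = character(0),
                    k = as.integer(k), families = families,
                    sequences = seqs))
}

#' Check a detection result against a fixture's ground truth
#'
#' Compares site count, per-site signature / metal count / copies,
#' exclusion reasons (as multisets) and the zinc accounting identity.
#'
#' @param detection a `zb_detection` from [detect_sites()].
#' @param truth a ground-truth record (`fixture$truth`, or
#'   `fixture$truth$asu` for the asymmetric-unit expectation).
#' @return `TRUE` or `FALSE`; on mismatch the reason is attached as
#'   attribute `"mismatch"`.
#' @export
verify_against_truth <- function(detection, truth) {
  fail <- function(why) structure(FALSE, mismatch = why)
  if (detection$n_zinc != truth$n_zinc) return(fail("zinc count"))
  if (length(detection$sites) != length(truth$sites)) {
    return(fail("site count"))
  }
  got <- sort(vapply(detection$sites, function(s) {
    sprintf("%s/%d/%d", residue_signature(s), nrow(s$metals), s$copies)
  }, character(1)))
  want <- sort(vapply(truth$sites, function(s) {
    sprintf("%s/%d/%d", s$signature, s$n_metals, s$copies)
  }, character(1)))
  if (!identical(got, want)) return(fail("site signatures/copies"))
  if (!identical(sort(detection$exclusions$reason),
                 sort(truth$exclusions))) {
    return(fail("exclusion reasons"))
  }
  zincs_in_sites <- sum(vapply(detection$sites, function(s) {
    length(unique(source_atom_key(
      s$metals[s$metals$element == "ZN", , drop = FALSE])))
  }, integer(1)))
  if (zincs_in_sites + nrow(detection$exclusions) != detection$n_zinc) {
    return(fail("zinc accounting identity"))
  }
  TRUE
}
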