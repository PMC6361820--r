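# Liganding contacts, metal clustering, symmetry dedup, salt
# classification and the full per-structure pipeline.

zn_at_origin <- function(extra) {
  rbind(extra, atom_df("HETATM", "ZN", "ZN", "A", 100, 0, 0, 0, "ZN"))
}

test_that("contacts exclude carbon and respect the distance cutoff", {
  # His imidazole: NE2 nitrogen at 2.10, CD2 carbon at 2.9
  his <- residue_df("A", 1, "HIS", c(6, 0, 0), side = list(
    NE2 = list(pos = c(2.10, 0, 0), element = "N"),
    CD2 = list(pos = c(2.9, 0.4, 0), element = "C")))
  m <- model_from_atoms(zn_at_origin(his))
  zn <- which(m$atoms$element == "ZN")
  ct <- find_liganding_contacts(m, zn)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$name, "NE2")
  expect_equal(ct$distance, 2.10, tolerance = 1e-6)

  far <- residue_df("A", 1, "HIS", c(8, 0, 0), side = list(
    NE2 = list(pos = c(3.5, 0, 0), element = "N")))
  m2 <- model_from_atoms(zn_at_origin(far))
  expect_equal(nrow(find_liganding_contacts(
    m2, which(m2$atoms$element == "ZN"))), 0)

  # boundary: exactly at the cutoff is within it
  edge <- residue_df("A", 1, "HIS", c(8, 0, 0), side = list(
    NE2 = list(pos = c(3.0, 0, 0), element = "N")))
  m3 <- model_from_atoms(zn_at_origin(edge))
  expect_equal(nrow(find_liganding_contacts(
    m3, which(m3$atoms$element == "ZN"))), 1)
})

test_that("the within-residue angle filter agrees with a vector oracle", {
  for (theta in c(30, 60)) {
    probe <- make_angle_probe(theta, 2.0, 2.2)
    expect_equal(oracle_angle(probe$metal, probe$o1, probe$o2), theta,
                 tolerance = 1e-9)
    asp <- residue_df("A", 1, "ASP", c(6, 0, 0), side = list(
      OD1 = list(pos = probe$o1, element = "O"),
      OD2 = list(pos = probe$o2, element = "O")))
    m <- model_from_atoms(zn_at_origin(asp))
    ct <- find_liganding_contacts(m, which(m$atoms$element == "ZN"))
    expect_equal(nrow(ct), if (theta < 45) 1 else 2)
    if (theta < 45) expect_equal(ct$name, "OD1")  # nearest-first retention
  }
})

test_that("dropping the angle constraint never loses contacts", {
  for (seed in 1:10) {
    fx <- make_fixture("BIDENTATE", seed = seed)
    m <- parse_structure(fx$text)
    zn <- which(m$atoms$element == "ZN")
    with_angle <- find_liganding_contacts(m, zn)
    no_angle <- find_liganding_contacts(m, zn,
                                        detection_parameters(min_angle = 0))
    expect_gte(nrow(no_angle), nrow(with_angle))
    # and a wider cutoff never loses contacts either
    wide <- find_liganding_contacts(m, zn,
                                    detection_parameters(cutoff = 3.5))
    expect_gte(nrow(wide), nrow(with_angle))
  }
})

test_that("an errant metal index is rejected", {
  m <- model_from_atoms(residue_df("A", 1, "GLY", c(0, 0, 0)))
  expect_error(find_liganding_contacts(m, 99), "absent")
  expect_error(find_liganding_contacts(m, 1), "not a metal")
})

test_that("metals sharing residues merge, transitively", {
  # disjoint residues: two groups
  inst <- cluster_instance(list(1, 2))
  expect_length(cluster_metal_centers(inst$model, inst$metals,
                                      inst$contacts), 2)
  # one shared histidine bridges both metals (the Cu,Zn dismutase case)
  inst <- cluster_instance(list(c(1, 2), 2))
  grp <- cluster_metal_centers(inst$model, inst$metals, inst$contacts)
  expect_length(grp, 1)
  expect_length(grp[[1]], 2)
  # A-B and B-C share, A-C do not: one group of three
  inst <- cluster_instance(list(1, c(1, 2), 2))
  grp <- cluster_metal_centers(inst$model, inst$metals, inst$contacts)
  expect_length(grp, 1)
  expect_length(grp[[1]], 3)
})

test_that("metal clustering equals brute-force transitive closure", {
  set.seed(404)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    n_res <- sample(1:6, 1)
    sets <- lapply(seq_len(n), function(i) {
      sort(sample(n_res, sample(0:min(3, n_res), 1)))
    })
    inst <- cluster_instance(sets)
    groups <- cluster_metal_centers(inst$model, inst$metals, inst$contacts)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      adj[i, j] <- i != j && length(intersect(sets[[i]], sets[[j]])) > 0
    }
    want <- oracle_components(adj)
    got <- integer(n)
    for (g in seq_along(groups)) {
      got[match(groups[[g]], inst$metals)] <- g
    }
    # same partition up to label renaming
    expect_equal(length(unique(want)), length(unique(got)))
    for (lab in unique(want)) {
      expect_equal(length(unique(got[want == lab])), 1)
    }
  }
})

test_that("coincident symmetry copies collapse to the lowest copy index", {
  dup <- function(pos2) {
    atoms <- rbind(
      atom_df("HETATM", "ZN", "ZN", "A", 100, 0, 0, 0, "ZN"),
      atom_df("HETATM", "ZN", "ZN", "A", 100,
              pos2[1], pos2[2], pos2[3], "ZN"))
    atoms$copy_index <- c(0L, 1L)
    list(atoms = atoms)
  }
  m <- dup(c(0, 0, 0))
  expect_equal(remove_symmetry_duplicates(m, 1:2), 1L)
  # displaced by 0.3 A by a near-axis transform: still a duplicate
  m <- dup(c(0.3, 0, 0))
  expect_equal(remove_symmetry_duplicates(m, 1:2), 1L)
  # two genuinely distinct zincs 4 A apart (different residue numbers)
  atoms <- rbind(
    atom_df("HETATM", "ZN", "ZN", "A", 100, 0, 0, 0, "ZN"),
    atom_df("HETATM", "ZN", "ZN", "A", 101, 4, 0, 0, "ZN"))
  atoms$copy_index <- 0L
  expect_equal(remove_symmetry_duplicates(list(atoms = atoms), 1:2), 1:2)
})

test_that("salt classification applies thresholds in order", {
  waters <- do.call(rbind, lapply(1:4, function(i) {
    atom_df("HETATM", "O", "HOH", "A", 300 + i, 2.1 * i / i, i, 0, "O")
  }))
  m <- model_from_atoms(rbind(residue_df("A", 1, "SER", c(20, 0, 0),
                                         side = list(OG = list(pos = c(21, 1, 1),
                                                               element = "O"))),
                              waters,
                              atom_df("HETATM", "ZN", "ZN", "A", 100,
                                      0, 0, 0, "ZN")))
  zn <- which(m$atoms$element == "ZN")
  ct <- find_liganding_contacts(m, zn)
  expect_equal(classify_zinc(m, zn, ct), "TOO_FEW_RESIDUES")

  # two His giving one atom each: enough residues, too few atoms
  his2 <- rbind(
    residue_df("A", 1, "HIS", c(6, 0, 0), side = list(
      NE2 = list(pos = c(2.1, 0, 0), element = "N"))),
    residue_df("A", 3, "HIS", c(-6, 0, 0), side = list(
      NE2 = list(pos = c(-2.1, 0, 0), element = "N"))))
  m2 <- model_from_atoms(zn_at_origin(his2))
  zn2 <- which(m2$atoms$element == "ZN")
  expect_equal(classify_zinc(m2, zn2, find_liganding_contacts(m2, zn2)),
               "TOO_FEW_ATOMS")

  # bidentate Asp + His: two residues but three atoms -> eligible
  bid <- rbind(
    residue_df("A", 1, "ASP", c(6, 0, 0), side = list(
      OD1 = list(pos = c(2.0, 0, 0), element = "O"),
      OD2 = list(pos = c(1.1, 1.9, 0), element = "O"))),
    residue_df("A", 3, "HIS", c(-6, 0, 0), side = list(
      NE2 = list(pos = c(-2.1, 0, 0), element = "N"))))
  m3 <- model_from_atoms(zn_at_origin(bid))
  zn3 <- which(m3$atoms$element == "ZN")
  expect_equal(classify_zinc(m3, zn3, find_liganding_contacts(m3, zn3)),
               "eligible")
  # raising the atom threshold can only exclude, never admit
  expect_equal(classify_zinc(m3, zn3, find_liganding_contacts(m3, zn3),
                             detection_parameters(min_protein_atoms = 4)),
               "TOO_FEW_ATOMS")
})

test_that("identical assembly-duplicated sites merge with a copy counter", {
  mk <- function(resno_offset = 0) {
    site_stub(codes = c("C", "C", "C", "C"),
              seq_index = 1:4 + resno_offset)
  }
  merged <- deduplicate_identical_sites(list(mk(), mk(), mk(), mk(10)))
  expect_length(merged, 2)
  expect_equal(sort(vapply(merged, function(s) s$copies, integer(1))),
               c(1L, 3L))
  two <- deduplicate_identical_sites(list(mk(), mk(10)))
  expect_equal(vapply(two, function(s) s$copies, integer(1)), c(1L, 1L))
})

test_that("the pipeline matches fixture ground truth end to end", {
  for (sc in c("SALT", "C4_SITE", "BIDENTATE", "COACTIVE",
               "DUPLICATED_ASU", "BACKBONE_ONLY")) {
    for (seed in c(1, 2)) {
      fx <- make_fixture(sc, seed = seed)
      det <- detect_sites(parse_structure(fx$text))
      v <- verify_against_truth(det, fx$truth)
      expect_true(isTRUE(v),
                  label = sprintf("%s seed %d (%s)", sc, seed,
                                  attr(v, "mismatch") %||% "ok"))
    }
  }
})

test_that("assembly duplication of a whole site increments copies", {
  fx <- make_fixture("C4_SITE", seed = 9, n_copies = 3)
  det <- detect_sites(parse_structure(fx$text))
  expect_length(det$sites, 1)
  expect_equal(det$sites[[1]]$copies, 3)
  expect_equal(det$n_zinc, 1)
})

test_that("interface sites exist in the assembly but not the asymmetric unit", {
  fx <- make_fixture("INTERFACE", seed = 13, n_transforms = 3)
  m <- parse_structure(fx$text)
  asu <- detect_sites(m, use_assembly = FALSE)
  expect_length(asu$sites, 0)
  expect_equal(asu$exclusions$reason, "TOO_FEW_RESIDUES")
  asm <- detect_sites(m)
  expect_length(asm$sites, 1)
  expect_equal(residue_signature(asm$sites[[1]]), "H3")
  expect_equal(nrow(asm$exclusions), 0)
})

test_that("every deposited zinc lands in a site or an exclusion record", {
  for (sc in c("SALT", "C4_SITE", "INTERFACE", "COACTIVE",
               "DUPLICATED_ASU", "BACKBONE_ONLY")) {
    for (seed in c(3, 4)) {
      fx <- make_fixture(sc, seed = seed)
      det <- detect_sites(parse_structure(fx$text))
      in_sites <- sum(vapply(det$sites, function(s) {
        zn <- s$metals[s$metals$element == "ZN", ]
        length(unique(paste(zn$chain, zn$resno, zn$icode)))
      }, numeric(1)))
      expect_equal(in_sites + nrow(det$exclusions), det$n_zinc,
                   label = sc)
    }
  }
})

test_that("detection is invariant under consistent chain relabeling", {
  fx <- make_fixture("DUPLICATED_ASU", seed = 17, n_copies = 2)
  det1 <- detect_sites(parse_structure(fx$text))
  # rename chains A -> Q, B -> R in the chain column and REMARK 350 lists
  lines <- strsplit(fx$text, "\n", fixed = TRUE)[[1]]
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  substr(lines[is_atom], 22, 22) <-
    chartr("AB", "QR", substr(lines[is_atom], 22, 22))
  is_chlist <- grepl("TO CHAINS:", lines)
  lines[is_chlist] <- sub("CHAINS: A", "CHAINS: Q",
                          sub("CHAINS: B", "CHAINS: R", lines[is_chlist]))
  relabeled <- paste(lines, collapse = "\n")
  det2 <- detect_sites(parse_structure(relabeled))
  expect_equal(length(det2$sites), length(det1$sites))
  expect_equal(sort(vapply(det2$sites, residue_signature, character(1))),
               sort(vapply(det1$sites, residue_signature, character(1))))
  expect_equal(sort(det2$exclusions$reason), sort(det1$exclusions$reason))
})

test_that("exclusion reasons print with their standard labels", {
  fx <- make_fixture("SALT", seed = 1)
  det <- detect_sites(parse_structure(fx$text))
  expect_equal(det$exclusions$reason_label, "Too few liganding residues")
  fx <- make_fixture("BACKBONE_ONLY", seed = 1)
  det <- detect_sites(parse_structure(fx$text))
  expect_equal(det$exclusions$reason_label, "No side chain information")
})
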