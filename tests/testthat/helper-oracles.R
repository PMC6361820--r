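# Independent oracles and small construction helpers, deliberately written
# without reusing the package's internal code paths.

# angle at a vertex, recomputed from first principles
oracle_angle <- function(vertex, a, b) {
  u <- a - vertex
  v <- b - vertex
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# brute-force transitive closure of a symmetric adjacency matrix via
# boolean matrix powers; returns a component label per node
oracle_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      lab <- lab + 1L
      labels[reach[i, ]] <- lab
    }
  }
  labels
}

# two-sided Fisher exact p by explicit enumeration of all tables with the
# observed margins (hypergeometric masses in log space)
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b
  c1 <- a + c_
  n <- a + b + c_ + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- lchoose(r1, xs) + lchoose(n - r1, c1 - xs) - lchoose(n, c1)
  p <- exp(lp)
  obs <- p[xs == a]
  sum(p[p <= obs * (1 + 1e-7)])
}

# ungapped identity between equal-length sequences (substitution-only
# families never need gaps)
oracle_ungapped_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va == vb) / min(length(va), length(vb))
}

# abstract metal-clustering instance: n metals contacting given residue
# ids; the fake model holds one oxygen atom per distinct residue
cluster_instance <- function(residue_sets) {
  n_res <- max(c(0, unlist(residue_sets)))
  res_atoms <- if (n_res > 0) {
    atom_df("ATOM", "OD1", "ASP", "A", seq_len(n_res),
            5 * seq_len(n_res), 0, 0, "O")
  } else NULL
  metal_atoms <- atom_df("HETATM", "ZN", "ZN", "B",
                         100 + seq_along(residue_sets),
                         0, 10 * seq_along(residue_sets), 0, "ZN")
  atoms <- rbind(res_atoms, metal_atoms)
  atoms$copy_index <- 0L
  model <- list(atoms = atoms)
  metals <- n_res + seq_along(residue_sets)
  contacts <- lapply(residue_sets, function(rs) {
    data.frame(metal = rep(NA_integer_, length(rs)), atom = rs,
               distance = rep(2.0, length(rs)))
  })
  list(model = model, metals = metals, contacts = contacts)
}

# --- tiny structure construction -----------------------------------------

atom_df <- function(type, name, resname, chain, resno, x, y, z, element,
                    icode = "", occ = 1) {
  data.frame(type = type, name = name, altloc = "", resname = resname,
             chain = chain, resno = resno, icode = icode,
             x = x, y = y, z = z, occ = occ, element = element,
             stringsAsFactors = FALSE)
}

# a full backbone'd residue with optional side-chain donor atoms given as
# name = c(x, y, z, element-as-4th-slot-string) lists
residue_df <- function(chain, resno, resname, ca, side = list()) {
  rows <- rbind(
    atom_df("ATOM", "N", resname, chain, resno,
            ca[1] - 1.46, ca[2], ca[3], "N"),
    atom_df("ATOM", "CA", resname, chain, resno, ca[1], ca[2], ca[3], "C"),
    atom_df("ATOM", "C", resname, chain, resno,
            ca[1] + 1.52, ca[2], ca[3], "C"),
    atom_df("ATOM", "O", resname, chain, resno,
            ca[1] + 2.1, ca[2] + 1.05, ca[3], "O")
  )
  for (nm in names(side)) {
    s <- side[[nm]]
    rows <- rbind(rows, atom_df("ATOM", nm, resname, chain, resno,
                                s$pos[1], s$pos[2], s$pos[3], s$element))
  }
  rows
}

# render an atom table (+ optional assemblies) to PDB text through the
# package writer, then a model through the parser
model_from_atoms <- function(atoms, assemblies = list(), resolution = 2,
                             pdb_id = "9TST", molecule = "TEST PROTEIN") {
  txt <- write_pdb(list(pdb_id = pdb_id, molecule_name = molecule,
                        resolution = resolution, assemblies = assemblies,
                        atoms = atoms))
  parse_structure(txt, pdb_id = pdb_id)
}

# minimal site stub carrying just the fields the analytics and clustering
# functions read
site_stub <- function(pdb_id = "9AAA", resolution = 2.0,
                      molecule_name = "TEST PROTEIN",
                      codes = c("C", "C", "C", "C"),
                      chain = "A", seq_index = NULL,
                      prev1 = NULL, next1 = NULL,
                      elements = "ZN", contacts = NULL, copies = 1L) {
  n <- length(codes)
  seq_index <- seq_index %||% seq_len(n)
  code_map <- c(C = "CYS", H = "HIS", D = "ASP", E = "GLU", G = "GLY",
                S = "SER", A = "ALA")
  res <- data.frame(
    chain = chain, copy_index = 0L, resno = seq_index * 2,
    icode = "", resname = unname(code_map[codes]),
    is_protein = TRUE, is_water = FALSE, seq_index = seq_index,
    code1 = codes,
    prev1 = prev1 %||% rep("G", n), next1 = next1 %||% rep("G", n),
    stringsAsFactors = FALSE)
  metals <- data.frame(
    element = elements, chain = chain, copy_index = 0L,
    resno = 100 + seq_along(elements), icode = "",
    name = elements, row = seq_along(elements),
    stringsAsFactors = FALSE)
  structure(list(pdb_id = pdb_id, resolution = resolution,
                 molecule_name = molecule_name, metals = metals,
                 contacts = contacts %||% data.frame(
                   metal = integer(0), distance = numeric(0),
                   element = character(0)),
                 residues = res, copies = copies),
            class = "zb_site")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
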