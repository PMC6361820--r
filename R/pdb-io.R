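# Fixed-column PDB reading and writing.
#
# The structure model is a `zb_structure`: a list with an atom table
# (one row per atom, bio3d-style), header metadata and assembly
# instructions. Chains and residues are derived by grouping the atom
# table; `copy_index` distinguishes assembly copies of a chain
# (0 = asymmetric-unit original).

#' Parse PDB-format text into a structure model
#'
#' Reads ATOM/HETATM records (first model only for multi-model files),
#' REMARK 2 resolution, REMARK 350 biological-assembly instructions and the
#' COMPND/HEADER molecule name. Where an atom has alternate locations, only
#' the highest-occupancy altloc is kept (ties go to the alphabetically
#' first, i.e. 'A').
#'
#' @param text PDB-format text: a single string or a character vector of
#'   lines.
#' @param pdb_id identifier stamped on the model; defaults to the HEADER
#'   id code when present.
#' @return a `zb_structure`: list with elements `pdb_id`, `atoms`
#'   (data.frame with one row per atom), `resolution` (Angstroms or `NA`),
#'   `molecule_name`, `assemblies` (list of assembly instructions) and
#'   `backbone_only`.
#' @examples
#' pdb <- make_fixture("C4_SITE", seed = 1)
#' model <- parse_structure(pdb$text)
#' model
#' @export
parse_structure <- function(text, pdb_id = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  rec <- substr(lines, 1, 6)

  # first model only
  endmdl <- which(trimws(rec) == "ENDMDL")
  atom_line <- rec %in% c("ATOM  ", "HETATM")
  if (length(endmdl) > 0) {
    atom_line[seq_along(lines) > endmdl[1]] <- FALSE
  }
  idx <- which(atom_line)
  if (length(idx) == 0) {
    stop("no ATOM or HETATM records found: empty structure")
  }

  al <- lines[idx]
  short <- nchar(al) < 54
  if (any(short)) {
    stop("malformed ATOM/HETATM record (line ", idx[which(short)[1]],
         "): fewer than 54 columns")
  }

  num_field <- function(s, from, to, what, required = TRUE) {
    raw <- substr(s, from, to)
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v) & (required | trimws(raw) != "")
    if (any(bad)) {
      stop("malformed ATOM/HETATM record (line ", idx[which(bad)[1]],
           "): unreadable ", what, " field")
    }
    v
  }

  atoms <- data.frame(
    type = trimws(rec[idx]),
    serial = num_field(al, 7, 11, "serial"),
    name = trimws(substr(al, 13, 16)),
    altloc = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resno = num_field(al, 23, 26, "residue number"),
    icode = trimws(substr(al, 27, 27)),
    x = num_field(al, 31, 38, "x coordinate"),
    y = num_field(al, 39, 46, "y coordinate"),
    z = num_field(al, 47, 54, "z coordinate"),
    occ = num_field(al, 55, 60, "occupancy", required = FALSE),
    element = toupper(trimws(substr(al, 77, 78))),
    stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$altloc[atoms$altloc == " "] <- ""
  no_el <- atoms$element == ""
  if (any(no_el)) {
    atoms$element[no_el] <- guess_element(atoms$name[no_el],
                                          atoms$type[no_el])
  }

  # altloc resolution: highest occupancy per source atom, tie -> first
  # altloc alphabetically ('A' beats 'B')
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "|")
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$icode, atoms$serial),
                 , drop = FALSE]
  rownames(atoms) <- NULL

  atoms$copy_index <- 0L
  atoms <- annotate_atoms(atoms)

  hdr <- parse_header_id(lines)
  model <- structure(
    list(
      pdb_id = pdb_id %||% hdr %||% "XXXX",
      atoms = atoms,
      resolution = parse_resolution(lines),
      molecule_name = parse_molecule_name(lines),
      assemblies = parse_assemblies(lines),
      backbone_only = FALSE
    ),
    class = "zb_structure"
  )
  model$backbone_only <- is_backbone_only(atoms)
  model
}

#' Read a structure model from a PDB file
#'
#' @param path path to a PDB-format file.
#' @param pdb_id optional identifier; defaults to the HEADER id code, else
#'   the file name without extension.
#' @return a `zb_structure` (see [parse_structure()]).
#' @export
read_structure <- function(path, pdb_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  parse_structure(
    lines,
    pdb_id = pdb_id %||% parse_header_id(lines) %||%
      tools::file_path_sans_ext(basename(path))
  )
}

# residue-level classification: waters, polymer membership (standard amino
# acids on ATOM records, or any non-water residue with an N/CA/C backbone,
# e.g. MSE), protein residues, metals; sequence index per polymer residue.
annotate_atoms <- function(atoms) {
  atoms$is_metal <- atoms$element %in% METAL_ELEMENTS
  atoms$is_water <- atoms$resname %in% WATER_NAMES

  rkey <- residue_key(atoms)
  std <- atoms$resname %in% names(AA_3TO1)
  std_atom_res <- unique(rkey[std & atoms$type == "ATOM"])
  has_n <- unique(rkey[atoms$name == "N"])
  has_ca <- unique(rkey[atoms$name == "CA"])
  has_c <- unique(rkey[atoms$name == "C"])
  backboned <- intersect(intersect(has_n, has_ca), has_c)
  polymer_res <- union(std_atom_res,
                       setdiff(backboned, unique(rkey[atoms$is_water])))
  atoms$is_polymer <- rkey %in% polymer_res
  atoms$is_protein <- atoms$is_polymer & std
  atoms$is_water <- atoms$is_water & !atoms$is_polymer

  # seq_index: 1..n over polymer residues within each chain copy, ordered
  # by (residue number, insertion code)
  atoms$seq_index <- NA_integer_
  pol <- which(atoms$is_polymer)
  if (length(pol) > 0) {
    p <- atoms[pol, , drop = FALSE]
    ckey <- paste(p$chain, p$copy_index, sep = "|")
    for (ck in unique(ckey)) {
      sel <- pol[ckey == ck]
      rk <- residue_key(atoms[sel, , drop = FALSE])
      o <- order(atoms$resno[sel], atoms$icode[sel])
      ranks <- match(rk, unique(rk[o]))
      atoms$seq_index[sel] <- ranks
    }
  }
  atoms
}

is_backbone_only <- function(atoms) {
  prot <- atoms[atoms$is_protein, , drop = FALSE]
  if (nrow(prot) == 0) return(FALSE)
  heavy <- prot[prot$element != "H", , drop = FALSE]
  all(heavy$name %in% BACKBONE_ATOMS)
}

guess_element <- function(name, type) {
  stripped <- toupper(gsub("[0-9']", "", name))
  vapply(seq_along(stripped), function(i) {
    s <- stripped[i]
    if (type[i] == "HETATM" && s %in% METAL_ELEMENTS) s
    else if (nchar(s) >= 1) substr(s, 1, 1)
    else "X"
  }, character(1))
}

parse_header_id <- function(lines) {
  h <- lines[startsWith(lines, "HEADER")]
  if (length(h) == 0) return(NULL)
  id <- trimws(substr(h[1], 63, 66))
  if (nzchar(id)) id else NULL
}

parse_resolution <- function(lines) {
  r2 <- lines[startsWith(lines, "REMARK   2") &
                grepl("RESOLUTION", lines)]
  if (length(r2) == 0) return(NA_real_)
  m <- regmatches(r2[1], regexpr("[0-9]+\\.[0-9]+", r2[1]))
  if (length(m) == 0) return(NA_real_)  # e.g. "NOT APPLICABLE" (NMR)
  res <- as.numeric(m)
  if (res <= 0) stop("REMARK 2 resolution must be positive")
  res
}

parse_molecule_name <- function(lines) {
  cmp <- lines[startsWith(lines, "COMPND")]
  if (length(cmp) > 0) {
    mol <- grep("MOLECULE:", cmp, value = TRUE)
    if (length(mol) > 0) {
      nm <- sub(".*MOLECULE:\\s*", "", mol[1])
      return(trimws(sub(";\\s*$", "", nm)))
    }
    txt <- trimws(substr(cmp[1], 11, 80))
    if (nzchar(txt)) return(txt)
  }
  h <- lines[startsWith(lines, "HEADER")]
  if (length(h) > 0) {
    txt <- trimws(substr(h[1], 11, 50))
    if (nzchar(txt)) return(txt)
  }
  ""
}

# REMARK 350: BIOMOLECULE blocks, each with APPLY ... TO CHAINS lists and
# numbered BIOMT1/2/3 transform rows; the PISA "CHANGE IN SOLVENT FREE
# ENERGY" annotation, when present, is kept as the assembly energy.
parse_assemblies <- function(lines) {
  r350 <- lines[startsWith(lines, "REMARK 350")]
  if (length(r350) == 0) return(list())
  assemblies <- list()
  cur <- NULL
  cur_chains <- character(0)
  rows <- list()  # accumulating BIOMT rows: rows[[transform id]][[1..3]]

  flush_group <- function(cur) {
    if (length(cur_chains) == 0 || length(rows) == 0) return(cur)
    transforms <- lapply(rows, function(r) {
      m <- do.call(rbind, r)
      list(rotation = m[, 1:3, drop = FALSE], translation = m[, 4])
    })
    cur$groups[[length(cur$groups) + 1L]] <-
      list(chain_ids = cur_chains, transforms = transforms)
    cur
  }

  for (ln in r350) {
    body <- substr(ln, 11, nchar(ln))
    if (grepl("BIOMOLECULE:", body)) {
      if (!is.null(cur)) {
        cur <- flush_group(cur)
        if (length(cur$groups) > 0) assemblies[[length(assemblies) + 1L]] <- cur
      }
      cur <- list(id = trimws(sub(".*BIOMOLECULE:", "", body)),
                  energy = NA_real_, groups = list())
      cur_chains <- character(0)
      rows <- list()
    } else if (grepl("CHANGE IN SOLVENT FREE ENERGY", body)) {
      if (!is.null(cur)) {
        m <- regmatches(body, regexpr("-?[0-9]+\\.?[0-9]*", body))
        if (length(m) > 0) cur$energy <- as.numeric(m[1])
      }
    } else if (grepl("APPLY THE FOLLOWING TO CHAINS:", body) ||
               grepl("AND CHAINS:", body)) {
      if (grepl("APPLY THE FOLLOWING TO CHAINS:", body) &&
          length(rows) > 0 && !is.null(cur)) {
        cur <- flush_group(cur)  # new APPLY group within the biomolecule
        cur_chains <- character(0)
        rows <- list()
      }
      ch <- sub(".*CHAINS:", "", body)
      ch <- trimws(strsplit(ch, ",", fixed = TRUE)[[1]])
      cur_chains <- c(cur_chains, ch[nzchar(ch)])
    } else if (grepl("BIOMT[123]", body)) {
      f <- strsplit(trimws(body), "\\s+")[[1]]
      biomt_row <- as.integer(sub("BIOMT", "", f[1]))
      tid <- as.integer(f[2])
      vals <- as.numeric(f[3:6])
      if (anyNA(vals)) stop("malformed BIOMT record in REMARK 350")
      if (length(rows) < tid) rows[[tid]] <- vector("list", 3)
      rows[[tid]][[biomt_row]] <- vals
    }
  }
  if (!is.null(cur)) {
    cur <- flush_group(cur)
    if (length(cur$groups) > 0) assemblies[[length(assemblies) + 1L]] <- cur
  }

  lapply(assemblies, function(a) {
    a$chain_ids <- unique(unlist(lapply(a$groups, `[[`, "chain_ids")))
    a$transforms <- do.call(c, lapply(a$groups, `[[`, "transforms"))
    for (tr in a$transforms) {
      R <- tr$rotation
      if (max(abs(crossprod(R) - diag(3))) > 1e-4) {
        stop("REMARK 350 rotation matrix is not orthonormal")
      }
    }
    a
  })
}

#' Write a structure model as PDB-format text
#'
#' Emits HEADER, COMPND, REMARK 2, REMARK 350 and ATOM/HETATM records that
#' [parse_structure()] reads back (coordinates at PDB precision, 3
#' decimals). Used by the synthetic-fixture generator and for round-trip
#' checks.
#'
#' @param model a `zb_structure`.
#' @return a single string of PDB-format text.
#' @export
write_pdb <- function(model) {
  out <- character(0)
  out <- c(out, sprintf("HEADER    %-40s%12s%4s", "METAL BINDING PROTEIN",
                        "", substr(model$pdb_id, 1, 4)))
  if (nzchar(model$molecule_name)) {
    out <- c(out, sprintf("COMPND    MOLECULE: %s;",
                          toupper(model$molecule_name)))
  }
  if (!is.na(model$resolution)) {
    out <- c(out, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                          model$resolution))
  }
  for (a in model$assemblies) {
    out <- c(out, sprintf("REMARK 350 BIOMOLECULE: %s", a$id))
    if (!is.na(a$energy)) {
      out <- c(out, sprintf(
        "REMARK 350 CHANGE IN SOLVENT FREE ENERGY: %.1f KCAL/MOL", a$energy))
    }
    for (grp in a$groups) {
      out <- c(out, sprintf("REMARK 350 APPLY THE FOLLOWING TO CHAINS: %s",
                            paste(grp$chain_ids, collapse = ", ")))
      for (k in seq_along(grp$transforms)) {
        tr <- grp$transforms[[k]]
        for (r in 1:3) {
          out <- c(out, sprintf(
            "REMARK 350   BIOMT%d %3d%10.6f%10.6f%10.6f%15.5f",
            r, k, tr$rotation[r, 1], tr$rotation[r, 2], tr$rotation[r, 3],
            tr$translation[r]))
        }
      }
    }
  }
  at <- model$atoms
  nm <- ifelse(nchar(at$element) >= 2 | nchar(at$name) >= 4,
               sprintf("%-4s", at$name),
               sprintf(" %-3s", at$name))
  out <- c(out, sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$type, seq_len(nrow(at)) %% 100000L, nm,
    ifelse(at$altloc == "", " ", at$altloc),
    at$resname, at$chain, at$resno,
    ifelse(at$icode == "", " ", at$icode),
    at$x, at$y, at$z, at$occ, 0, sprintf("%2s", at$element)))
  out <- c(out, "END")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Extract the one-letter sequence of a chain
#'
#' One character per polymer residue in residue order, with `X` for
#' nonstandard residues (e.g. selenomethionine); these are the sequences
#' the 90%-identity chain clustering operates on.
#'
#' @param model a `zb_structure`.
#' @param chain chain identifier.
#' @param copy_index which assembly copy (default 0, the asymmetric-unit
#'   original).
#' @return a single string (may be `""` for a chain with no polymer
#'   residues).
#' @export
chain_sequence <- function(model, chain, copy_index = 0L) {
  a <- model$atoms
  sel <- a$is_polymer & a$chain == chain & a$copy_index == copy_index
  if (!any(sel)) return("")
  p <- a[sel, , drop = FALSE]
  first <- !duplicated(p$seq_index)
  p <- p[first, , drop = FALSE]
  p <- p[order(p$seq_index), , drop = FALSE]
  letters1 <- ifelse(p$resname %in% names(AA_3TO1),
                     AA_3TO1[p$resname], "X")
  paste(letters1, collapse = "")
}

#' Sequences of every chain copy in a model
#'
#' @param model a `zb_structure`.
#' @return named character vector, names `"<chain>|<copy_index>"`, empty
#'   sequences dropped.
#' @export
chain_sequences <- function(model) {
  a <- model$atoms
  keys <- unique(paste(a$chain[a$is_polymer], a$copy_index[a$is_polymer],
                       sep = "|"))
  if (length(keys) == 0) return(character(0))
  out <- vapply(keys, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    chain_sequence(model, parts[1], as.integer(parts[2]))
  }, character(1))
  out[nzchar(out)]
}

#' @export
print.zb_structure <- function(x, ...) {
  a <- x$atoms
  n_chain <- length(unique(paste(a$chain, a$copy_index)))
  cat(sprintf("zb_structure %s: %d atoms, %d chain copies, %d zinc atom(s)\n",
              x$pdb_id, nrow(a), n_chain, sum(a$element == "ZN")))
  cat(sprintf("  resolution: %s  molecule: %s\n",
              ifelse(is.na(x$resolution), "n/a",
                     sprintf("%.2f A", x$resolution)),
              ifelse(nzchar(x$molecule_name), x$molecule_name, "n/a")))
  if (length(x$assemblies) > 0) {
    cat(sprintf("  assemblies: %d declared\n", length(x$assemblies)))
  }
  if (x$backbone_only) cat("  backbone-only model\n")
  invisible(x)
}
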