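# Zinc binding-site detection: liganding contacts, metal clustering,
# symmetry dedup, salt classification and site assembly.

#' Detection parameters
#'
#' @param cutoff metal-to-atom centre-to-centre distance cutoff in
#'   Angstroms (inclusive). Default 3.0.
#' @param min_angle minimum angle, in degrees, at the metal between a
#'   candidate liganding atom and any closer retained liganding atom of the
#'   same residue; candidates below it are discarded (strict `<`). Default
#'   45.
#' @param min_protein_residues minimum distinct protein liganding residues
#'   for a zinc to be biologically relevant rather than a salt. Default 2.
#' @param min_protein_atoms minimum protein liganding atoms. Default 3.
#' @param duplicate_tolerance distance (Angstroms) under which assembly
#'   copies of the same deposited metal are considered coincident symmetry
#'   duplicates. Default 0.5.
#' @param metal_elements element symbols treated as metals.
#' @return a `zb_params` list.
#' @export
detection_parameters <- function(cutoff = 3.0, min_angle = 45,
                                 min_protein_residues = 2L,
                                 min_protein_atoms = 3L,
                                 duplicate_tolerance = 0.5,
                                 metal_elements = METAL_ELEMENTS) {
  stopifnot(cutoff > 0, min_angle >= 0, min_angle < 180,
            min_protein_residues >= 0, min_protein_atoms >= 0,
            duplicate_tolerance < cutoff)
  structure(list(cutoff = cutoff, min_angle = min_angle,
                 min_protein_residues = as.integer(min_protein_residues),
                 min_protein_atoms = as.integer(min_protein_atoms),
                 duplicate_tolerance = duplicate_tolerance,
                 metal_elements = metal_elements),
            class = "zb_params")
}

#' Find liganding contacts of one metal atom
#'
#' Candidate liganding atoms are all non-carbon, non-hydrogen, non-metal
#' atoms within the distance cutoff of the metal (centre to centre,
#' inclusive). Within each residue, candidates are taken nearest-first and
#' one is discarded when the angle at the metal between it and any closer
#' retained atom of that residue is below `min_angle` — a bidentate
#' carboxylate subtends a wide enough angle to keep both oxygens, while a
#' second atom nearly collinear with a closer one is a non-coordinating
#' neighbour.
#'
#' @param model a `zb_structure`.
#' @param metal row index of the metal in `model$atoms`.
#' @param params a `zb_params` from [detection_parameters()].
#' @return data.frame of contacts sorted by distance: liganding atom row
#'   index (`atom`), `distance`, and the liganding atom's identifiers.
#' @export
find_liganding_contacts <- function(model, metal,
                                    params = detection_parameters()) {
  a <- model$atoms
  if (length(metal) != 1 || is.na(metal) || metal < 1 || metal > nrow(a)) {
    stop("metal atom index absent from model")
  }
  if (!a$element[metal] %in% params$metal_elements) {
    stop("atom ", metal, " (", a$element[metal], ") is not a metal")
  }
  m <- c(a$x[metal], a$y[metal], a$z[metal])
  d <- sqrt((a$x - m[1])^2 + (a$y - m[2])^2 + (a$z - m[3])^2)
  cand <- which(!(a$element %in% c("C", "H")) &
                  !(a$element %in% params$metal_elements) &
                  d <= params$cutoff)
  if (length(cand) == 0) return(empty_contacts())

  cand <- cand[order(d[cand])]
  rk <- residue_key(a[cand, , drop = FALSE])
  keep <- logical(length(cand))
  for (res in unique(rk)) {
    in_res <- which(rk == res)  # already nearest-first
    retained <- integer(0)
    for (i in in_res) {
      p <- c(a$x[cand[i]], a$y[cand[i]], a$z[cand[i]])
      ok <- TRUE
      for (j in retained) {
        q <- c(a$x[cand[j]], a$y[cand[j]], a$z[cand[j]])
        if (vertex_angle(m, p, q) < params$min_angle) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        retained <- c(retained, i)
        keep[i] <- TRUE
      }
    }
  }
  cand <- cand[keep]
  data.frame(
    metal = metal, atom = cand, distance = d[cand],
    chain = a$chain[cand], copy_index = a$copy_index[cand],
    resno = a$resno[cand], icode = a$icode[cand],
    resname = a$resname[cand], name = a$name[cand],
    element = a$element[cand], is_protein = a$is_protein[cand],
    is_water = a$is_water[cand],
    stringsAsFactors = FALSE
  )
}

empty_contacts <- function() {
  data.frame(metal = integer(0), atom = integer(0), distance = numeric(0),
             chain = character(0), copy_index = integer(0),
             resno = numeric(0), icode = character(0),
             resname = character(0), name = character(0),
             element = character(0), is_protein = logical(0),
             is_water = logical(0), stringsAsFactors = FALSE)
}

#' Group metals that share liganding residues
#'
#' Two metals belong to the same group when they are connected by a chain
#' of shared-liganding-residue relations (transitive closure); a single
#' histidine bridging a zinc and a copper, for example, couples them into
#' one co-active unit. Implemented as union-find over the shared-residue
#' graph.
#'
#' @param model a `zb_structure`.
#' @param metals atom row indices of the metals.
#' @param contacts list of contact data.frames parallel to `metals`
#'   (from [find_liganding_contacts()]).
#' @return list of integer vectors partitioning `metals`; groups ordered by
#'   their smallest member's source atom identifier.
#' @export
cluster_metal_centers <- function(model, metals, contacts) {
  n <- length(metals)
  if (n == 0) return(list())
  stopifnot(length(contacts) == n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  res_sets <- lapply(contacts, function(ct) {
    if (nrow(ct) == 0) character(0)
    else unique(residue_key(model$atoms[ct$atom, , drop = FALSE]))
  })
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(res_sets[[i]], res_sets[[j]])) > 0) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  keys <- vapply(groups, function(g) {
    min(source_atom_key(model$atoms[metals[g], , drop = FALSE]))
  }, character(1))
  groups <- groups[order(keys)]
  lapply(unname(groups), function(g) metals[g])
}

#' Remove coincident symmetry duplicates of metals
#'
#' Assembly generation can place copies of a metal that lies on a rotation
#' axis on top of itself. Among copies sharing a source atom identifier
#' whose positions lie pairwise within the tolerance, only the copy with
#' the lowest `copy_index` is kept; everything else passes through.
#'
#' @param model a `zb_structure` (typically an expanded assembly).
#' @param metals atom row indices of the metals.
#' @param tolerance coincidence distance in Angstroms.
#' @return the kept subset of `metals`, in input order.
#' @export
remove_symmetry_duplicates <- function(model, metals, tolerance = 0.5) {
  if (length(metals) <= 1) return(metals)
  a <- model$atoms[metals, , drop = FALSE]
  src <- source_atom_key(a)
  drop <- logical(length(metals))
  for (s in unique(src)) {
    grp <- which(src == s)
    if (length(grp) == 1) next
    # single-linkage positional clusters within the tolerance
    comp <- seq_along(grp)
    for (i in seq_along(grp)) {
      for (j in seq_len(i - 1L)) {
        dij <- sqrt((a$x[grp[i]] - a$x[grp[j]])^2 +
                      (a$y[grp[i]] - a$y[grp[j]])^2 +
                      (a$z[grp[i]] - a$z[grp[j]])^2)
        if (dij <= tolerance) comp[comp == comp[i]] <- comp[j]
      }
    }
    for (cl in unique(comp)) {
      members <- grp[comp == cl]
      if (length(members) > 1) {
        keep_one <- members[which.min(a$copy_index[members])]
        drop[setdiff(members, keep_one)] <- TRUE
      }
    }
  }
  metals[!drop]
}

#' Classify a zinc as site-eligible or excluded
#'
#' Zinc ions with fewer than two protein liganding residues or fewer than
#' three protein liganding atoms are presumed to be adventitious salts
#' (crystallisation buffer) with no physiological role. Waters and
#' non-protein hetero ligands never count toward either threshold, so a
#' zinc held by one bidentate aspartate plus one histidine (2 residues, 3
#' atoms) is still eligible. Precedence: no-side-chain models first, then
#' absence from the biological assembly, then the residue count, then the
#' atom count.
#'
#' @param model a `zb_structure`.
#' @param zinc atom row index of the zinc.
#' @param contacts contact data.frame for this zinc.
#' @param params a `zb_params`.
#' @param in_assembly whether the zinc's chain is part of the processed
#'   biological assembly.
#' @return `"eligible"` or one of the exclusion codes
#'   `"NO_SIDECHAINS"`, `"NOT_IN_ASSEMBLY"`, `"TOO_FEW_RESIDUES"`,
#'   `"TOO_FEW_ATOMS"`.
#' @export
classify_zinc <- function(model, zinc, contacts,
                          params = detection_parameters(),
                          in_assembly = TRUE) {
  if (model$backbone_only) return("NO_SIDECHAINS")
  if (!in_assembly) return("NOT_IN_ASSEMBLY")
  prot <- contacts[contacts$is_protein, , drop = FALSE]
  n_res <- length(unique(paste(prot$chain, prot$copy_index, prot$resno,
                               prot$icode)))
  if (n_res < params$min_protein_residues) return("TOO_FEW_RESIDUES")
  if (nrow(prot) < params$min_protein_atoms) return("TOO_FEW_ATOMS")
  "eligible"
}

#' Merge sites duplicated by assembly generation
#'
#' Two sites within one structure are identical when the multisets of
#' source identifiers (chain, residue number + insertion code, residue
#' name) of their metals and liganding residues are equal — i.e. they are
#' assembly copies of the same deposited site. One copy is kept and its
#' `copies` counter set to the group size.
#'
#' @param sites list of `zb_site` from one structure.
#' @return list of `zb_site` with `copies` set.
#' @export
deduplicate_identical_sites <- function(sites) {
  if (length(sites) <= 1) {
    for (i in seq_along(sites)) sites[[i]]$copies <- 1L
    return(sites)
  }
  keys <- vapply(sites, site_source_key, character(1))
  out <- list()
  for (k in unique(keys)) {
    grp <- which(keys == k)
    s <- sites[[grp[1]]]
    s$copies <- length(grp)
    out[[length(out) + 1L]] <- s
  }
  out
}

site_source_key <- function(site) {
  paste(sort(c(source_residue_key(site$metals),
               source_residue_key(site$residues))), collapse = ";")
}

#' Detect zinc binding sites in a structure
#'
#' Runs the full per-structure pipeline: select and build the biological
#' assembly (falling back to the asymmetric unit when none is declared, or
#' when `use_assembly = FALSE`), find every metal's liganding contacts,
#' remove coincident symmetry duplicates, group metals that share
#' liganding residues, drop groups without a zinc, classify each zinc
#' against the salt thresholds, and merge assembly-duplicated sites. Every
#' zinc atom deposited in the file ends up either in a site or in exactly
#' one exclusion record.
#'
#' @param model a `zb_structure` (unexpanded).
#' @param params a `zb_params` from [detection_parameters()].
#' @param use_assembly process the declared biological assembly (default)
#'   or the raw asymmetric unit.
#' @return a `zb_detection`: list with `sites` (list of `zb_site`),
#'   `exclusions` (data.frame: chain, resno, icode, reason code and the
#'   printable reason label) and `n_zinc` (zinc atoms deposited in the
#'   file).
#' @examples
#' det <- detect_sites(parse_structure(make_fixture("C4_SITE", seed = 1)$text))
#' det$sites[[1]]
#' @export
detect_sites <- function(model, params = detection_parameters(),
                         use_assembly = TRUE) {
  a <- model$atoms
  src_zinc <- which(a$element == "ZN" & a$copy_index == 0L)
  excl <- data.frame(chain = character(0), resno = numeric(0),
                     icode = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  result <- function(sites, excl) {
    excl$reason_label <- unname(EXCLUSION_REASONS[excl$reason])
    structure(list(sites = sites, exclusions = excl,
                   n_zinc = length(src_zinc), pdb_id = model$pdb_id),
              class = "zb_detection")
  }
  if (length(src_zinc) == 0) return(result(list(), excl))

  if (model$backbone_only) {
    excl <- zinc_exclusions(a, src_zinc, "NO_SIDECHAINS")
    return(result(list(), excl))
  }

  asm <- if (use_assembly) select_assembly(model) else NULL
  built <- if (!is.null(asm)) build_assembly(model, asm) else model

  excluded_src <- integer(0)
  if (!is.null(asm)) {
    outside <- src_zinc[!(a$chain[src_zinc] %in% asm$chain_ids)]
    excl <- rbind(excl, zinc_exclusions(a, outside, "NOT_IN_ASSEMBLY"))
    excluded_src <- outside
  }

  b <- built$atoms
  metals <- which(b$element %in% params$metal_elements)
  metals <- remove_symmetry_duplicates(built, metals,
                                       params$duplicate_tolerance)
  contacts <- lapply(metals, find_liganding_contacts, model = built,
                     params = params)
  groups <- cluster_metal_centers(built, metals, contacts)

  seqs <- chain_sequences(built)
  sites <- list()
  # classification of each built zinc copy, keyed by source atom id
  zinc_class <- character(0)
  for (grp in groups) {
    gi <- match(grp, metals)
    is_zn <- b$element[grp] == "ZN"
    if (!any(is_zn)) next  # metal site without zinc: not stored
    cls <- vapply(which(is_zn), function(k) {
      classify_zinc(built, grp[k], contacts[[gi[k]]], params)
    }, character(1))
    src_keys <- source_atom_key(b[grp[is_zn], , drop = FALSE])
    new <- !(src_keys %in% names(zinc_class))
    zinc_class[src_keys[new]] <- cls[new]
    if (any(cls == "eligible")) {
      sites[[length(sites) + 1L]] <-
        make_site(built, grp, do.call(rbind, contacts[gi]), seqs, model)
    }
  }
  sites <- deduplicate_identical_sites(sites)

  in_site <- unique(unlist(lapply(sites, function(s) {
    source_atom_key(s$metals[s$metals$element == "ZN", , drop = FALSE])
  })))
  src_keys_all <- source_atom_key(a[src_zinc, , drop = FALSE])
  left <- src_zinc[!(src_keys_all %in% in_site) &
                     !(src_zinc %in% excluded_src)]
  for (zi in left) {
    key <- source_atom_key(a[zi, , drop = FALSE])
    reason <- if (key %in% names(zinc_class)) zinc_class[[key]]
              else "NOT_IN_ASSEMBLY"  # copy vanished with its chain
    excl <- rbind(excl, zinc_exclusions(a, zi, reason))
  }
  result(sites, excl)
}

zinc_exclusions <- function(atoms, idx, reason) {
  if (length(idx) == 0) {
    return(data.frame(chain = character(0), resno = numeric(0),
                      icode = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(chain = atoms$chain[idx], resno = atoms$resno[idx],
             icode = atoms$icode[idx], reason = reason,
             stringsAsFactors = FALSE)
}

make_site <- function(built, metal_idx, contacts, seqs, model) {
  b <- built$atoms
  metals <- b[metal_idx, , drop = FALSE]
  metals$row <- metal_idx  # contacts$metal refers to these rows
  metals <- metals[order(source_atom_key(metals), metals$copy_index),
                   , drop = FALSE]
  ct <- contacts[order(contacts$distance), , drop = FALSE]
  rownames(ct) <- rownames(metals) <- NULL

  rk <- residue_key(b[ct$atom, , drop = FALSE])
  first <- !duplicated(rk)
  res <- b[ct$atom[first],
           c("chain", "copy_index", "resno", "icode", "resname",
             "is_protein", "is_water", "seq_index"), drop = FALSE]
  res <- res[order(res$chain, res$copy_index, res$resno, res$icode),
             , drop = FALSE]
  res$code1 <- ifelse(res$resname %in% names(AA_3TO1),
                      unname(AA_3TO1[res$resname]), "X")
  neigh <- function(i, offset) {
    if (!res$is_protein[i]) return(NA_character_)
    s <- seqs[[paste(res$chain[i], res$copy_index[i], sep = "|")]]
    pos <- res$seq_index[i] + offset
    if (is.null(s) || is.na(pos) || pos < 1 || pos > nchar(s)) "-"
    else substr(s, pos, pos)
  }
  res$prev1 <- vapply(seq_len(nrow(res)), neigh, character(1), offset = -1L)
  res$next1 <- vapply(seq_len(nrow(res)), neigh, character(1), offset = 1L)
  rownames(res) <- NULL

  structure(list(
    pdb_id = model$pdb_id,
    resolution = model$resolution,
    molecule_name = model$molecule_name,
    metals = metals,
    contacts = ct,
    residues = res,
    copies = 1L
  ), class = "zb_site")
}

#' @export
print.zb_detection <- function(x, ...) {
  cat(sprintf("zb_detection %s: %d zinc atom(s) -> %d site(s), %d excluded\n",
              x$pdb_id, x$n_zinc, length(x$sites), nrow(x$exclusions)))
  for (s in x$sites) {
    cat("  ", format(s, brief = TRUE), "\n", sep = "")
  }
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$reason_label)
    for (nm in names(tab)) cat(sprintf("  excluded %d: %s\n", tab[[nm]], nm))
  }
  invisible(x)
}

#' @export
format.zb_site <- function(x, brief = FALSE, ...) {
  sig <- tryCatch(residue_signature(x), error = function(e) "?")
  sprintf("site %s [%s] %d metal(s) (%s), %d liganding residue(s), copies=%d",
          x$pdb_id, sig, nrow(x$metals),
          paste(x$metals$element, collapse = "+"),
          nrow(x$residues), x$copies)
}

#' @export
print.zb_site <- function(x, ...) {
  cat(format(x), "\n")
  ct <- x$contacts
  b <- sprintf("  %s %s %s%g%s%s%s at %.2f A", ct$resname, ct$name,
               ct$chain, ct$resno, ifelse(ct$icode == "", "", ct$icode),
               ifelse(ct$copy_index > 0,
                      sprintf(" (copy %d)", ct$copy_index), ""),
               ifelse(ct$is_protein, "", " (het)"), ct$distance)
  cat(b, sep = "\n")
  invisible(x)
}
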