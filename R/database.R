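# Batch database build over a directory of PDB files, SQLite persistence,
# exports and whole-database statistics.

#' Build a zinc binding-site database from a directory of PDB files
#'
#' Runs [detect_sites()] on every `*.pdb` file (alphabetical order), stores
#' structures, zinc atoms (with their exclusion reason when excluded),
#' sites, metals, contacts and liganding residues, then clusters the
#' zinc-binding chains at 90% identity and the sites by fingerprint across
#' the whole store. Per-file failures are logged in a `failures` table and
#' skipped, not fatal. Rebuilding from the same inputs reproduces
#' identical tables.
#'
#' @param input_dir directory containing `.pdb` files.
#' @param db_path path of the SQLite file to (over)write; `NULL` keeps the
#'   database in memory only.
#' @param params a `zb_params` from [detection_parameters()].
#' @param use_assembly process biological assemblies (default) or raw
#'   asymmetric units.
#' @param identity_threshold chain-clustering identity threshold.
#' @return a `zb_database`: list with `tables` (named list of data.frames),
#'   `sites` (list of `zb_site` with `site_id` set) and `path`.
#' @export
build_database <- function(input_dir, db_path = NULL,
                           params = detection_parameters(),
                           use_assembly = TRUE,
                           identity_threshold = 0.9) {
  files <- sort(list.files(input_dir, pattern = "\\.pdb$",
                           full.names = TRUE))
  structures <- zincs <- sites_tab <- metals_tab <- contacts_tab <-
    residues_tab <- chains_tab <- failures <- list()
  all_sites <- list()
  chain_seqs <- character(0)

  for (f in files) {
    res <- tryCatch({
      model <- read_structure(f)
      det <- detect_sites(model, params, use_assembly = use_assembly)
      list(model = model, det = det)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(file = basename(f), error = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    model <- res$model
    det <- res$det
    structures[[length(structures) + 1L]] <- data.frame(
      pdb_id = model$pdb_id, resolution = model$resolution,
      molecule_name = model$molecule_name, n_zinc = det$n_zinc,
      n_sites = length(det$sites), n_exclusions = nrow(det$exclusions),
      stringsAsFactors = FALSE)

    for (i in seq_along(det$sites)) {
      s <- det$sites[[i]]
      s$site_id <- sprintf("%s-%d", model$pdb_id, i)
      all_sites[[length(all_sites) + 1L]] <- s
      sites_tab[[length(sites_tab) + 1L]] <- data.frame(
        site_id = s$site_id, pdb_id = model$pdb_id,
        signature = residue_signature(s), n_metals = nrow(s$metals),
        n_residues = nrow(s$residues), copies = s$copies,
        stringsAsFactors = FALSE)
      metals_tab[[length(metals_tab) + 1L]] <- data.frame(
        site_id = s$site_id, element = s$metals$element,
        chain = s$metals$chain, copy_index = s$metals$copy_index,
        resno = s$metals$resno, icode = s$metals$icode,
        stringsAsFactors = FALSE)
      contacts_tab[[length(contacts_tab) + 1L]] <- data.frame(
        site_id = s$site_id, metal_element =
          s$metals$element[match(s$contacts$metal, s$metals$row)],
        atom_name = s$contacts$name, element = s$contacts$element,
        chain = s$contacts$chain, resno = s$contacts$resno,
        resname = s$contacts$resname, distance = s$contacts$distance,
        is_protein = s$contacts$is_protein,
        is_water = s$contacts$is_water, stringsAsFactors = FALSE)
      residues_tab[[length(residues_tab) + 1L]] <- data.frame(
        site_id = s$site_id, chain = s$residues$chain,
        copy_index = s$residues$copy_index, resno = s$residues$resno,
        icode = s$residues$icode, resname = s$residues$resname,
        is_protein = s$residues$is_protein, stringsAsFactors = FALSE)
      # zinc-binding chains: source chains of the protein liganding
      # residues, stored with their asymmetric-unit sequence
      for (ch in unique(s$residues$chain[s$residues$is_protein])) {
        key <- paste(model$pdb_id, ch, sep = "_")
        if (!(key %in% names(chain_seqs))) {
          chain_seqs[key] <- chain_sequence(model, ch)
          chains_tab[[length(chains_tab) + 1L]] <- data.frame(
            chain_key = key, pdb_id = model$pdb_id, chain = ch,
            sequence = chain_seqs[[key]], stringsAsFactors = FALSE)
        }
      }
      zn <- s$metals[s$metals$element == "ZN", , drop = FALSE]
      zn <- zn[!duplicated(source_atom_key(zn)), , drop = FALSE]
      zincs[[length(zincs) + 1L]] <- data.frame(
        pdb_id = model$pdb_id, chain = zn$chain, resno = zn$resno,
        icode = zn$icode, site_id = s$site_id,
        exclusion_reason = NA_character_, stringsAsFactors = FALSE)
    }
    if (nrow(det$exclusions) > 0) {
      e <- det$exclusions
      zincs[[length(zincs) + 1L]] <- data.frame(
        pdb_id = model$pdb_id, chain = e$chain, resno = e$resno,
        icode = e$icode, site_id = NA_character_,
        exclusion_reason = e$reason_label, stringsAsFactors = FALSE)
    }
  }

  bind <- function(lst, proto) {
    if (length(lst) == 0) proto else do.call(rbind, lst)
  }
  tables <- list(
    structures = bind(structures, data.frame(
      pdb_id = character(0), resolution = numeric(0),
      molecule_name = character(0), n_zinc = integer(0),
      n_sites = integer(0), n_exclusions = integer(0))),
    zincs = bind(zincs, data.frame(
      pdb_id = character(0), chain = character(0), resno = numeric(0),
      icode = character(0), site_id = character(0),
      exclusion_reason = character(0))),
    sites = bind(sites_tab, data.frame(
      site_id = character(0), pdb_id = character(0),
      signature = character(0), n_metals = integer(0),
      n_residues = integer(0), copies = integer(0))),
    metals = bind(metals_tab, data.frame(
      site_id = character(0), element = character(0), chain = character(0),
      copy_index = integer(0), resno = numeric(0), icode = character(0))),
    contacts = bind(contacts_tab, data.frame(
      site_id = character(0), metal_element = character(0),
      atom_name = character(0), element = character(0),
      chain = character(0), resno = numeric(0), resname = character(0),
      distance = numeric(0), is_protein = logical(0),
      is_water = logical(0))),
    residues = bind(residues_tab, data.frame(
      site_id = character(0), chain = character(0), copy_index = integer(0),
      resno = numeric(0), icode = character(0), resname = character(0),
      is_protein = logical(0))),
    chains = bind(chains_tab, data.frame(
      chain_key = character(0), pdb_id = character(0), chain = character(0),
      sequence = character(0))),
    failures = bind(failures, data.frame(file = character(0),
                                         error = character(0)))
  )

  # cross-store clustering
  chain_clusters <- if (length(chain_seqs) > 0) {
    cluster_chains(chain_seqs, threshold = identity_threshold)
  } else list()
  tables$chains$cluster_id <- if (nrow(tables$chains) > 0) {
    unname(chain_cluster_map(chain_clusters)[tables$chains$chain_key])
  } else character(0)

  site_clusters <- if (length(all_sites) > 0) {
    cluster_sites(all_sites, chain_clusters)
  } else list()
  tables$sites$cluster_id <- rep(NA_character_, nrow(tables$sites))
  tables$sites$representative <- rep(FALSE, nrow(tables$sites))
  site_ids <- vapply(all_sites, function(s) s$site_id, character(1))
  sc_rows <- list()
  for (sc in site_clusters) {
    tables$sites$cluster_id[match(site_ids[sc$members],
                                  tables$sites$site_id)] <- sc$id
    tables$sites$representative[match(site_ids[sc$representative],
                                      tables$sites$site_id)] <- TRUE
    sc_rows[[length(sc_rows) + 1L]] <- data.frame(
      cluster_id = sc$id, n_members = length(sc$members),
      representative_site_id = site_ids[sc$representative],
      fingerprint = sc$fingerprint, stringsAsFactors = FALSE)
  }
  tables$site_clusters <- bind(sc_rows, data.frame(
    cluster_id = character(0), n_members = integer(0),
    representative_site_id = character(0), fingerprint = character(0)))

  for (nm in names(tables)) rownames(tables[[nm]]) <- NULL
  db <- structure(list(tables = tables, sites = all_sites,
                       chain_clusters = chain_clusters,
                       site_clusters = site_clusters,
                       path = db_path, params = params),
                  class = "zb_database")
  if (!is.null(db_path)) write_sqlite(db, db_path)
  db
}

write_sqlite <- function(db, path) {
  if (file.exists(path)) file.remove(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  for (nm in names(db$tables)) {
    DBI::dbWriteTable(con, nm, db$tables[[nm]], overwrite = TRUE)
  }
  invisible(path)
}

#' Read the tables of a previously built SQLite database
#'
#' @param path SQLite file written by [build_database()].
#' @return named list of data.frames.
#' @export
read_database_tables <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  out <- lapply(DBI::dbListTables(con), function(nm) {
    DBI::dbReadTable(con, nm)
  })
  names(out) <- DBI::dbListTables(con)
  out
}

#' Check referential integrity and zinc accounting of a database
#'
#' Verifies that every site row references a known structure, every
#' metal/contact/residue row a known site, every cluster representative is
#' a member, and that each zinc appears in exactly one of site membership
#' or exclusion.
#'
#' @param db a `zb_database`.
#' @return `TRUE`, or an error describing the violated constraint.
#' @export
db_integrity <- function(db) {
  t <- db$tables
  check <- function(ok, msg) if (!all(ok)) stop("integrity: ", msg)
  check(t$sites$pdb_id %in% t$structures$pdb_id,
        "site references unknown structure")
  for (nm in c("metals", "contacts", "residues")) {
    check(t[[nm]]$site_id %in% t$sites$site_id,
          paste(nm, "row references unknown site"))
  }
  check(t$site_clusters$representative_site_id %in% t$sites$site_id,
        "cluster representative is not a stored site")
  rep_cl <- t$sites$cluster_id[match(t$site_clusters$representative_site_id,
                                     t$sites$site_id)]
  check(rep_cl == t$site_clusters$cluster_id,
        "cluster representative is not a member of its cluster")
  z <- t$zincs
  check(xor(!is.na(z$site_id), !is.na(z$exclusion_reason)),
        "zinc must have exactly one of site membership or exclusion")
  check(t$structures$n_zinc ==
          vapply(t$structures$pdb_id,
                 function(p) sum(z$pdb_id == p), integer(1)),
        "zinc accounting identity violated")
  TRUE
}

#' Export a database as JSON, FASTA or CSV
#'
#' `json` dumps every table to one JSON file; `fasta` writes the
#' zinc-binding chain sequences (headers `>pdbid_chainid`); `csv` writes
#' the summary statistics tables (co-active metals, liganding residue
#' frequencies, coordination modes, per-contact distances).
#'
#' @param db a `zb_database`.
#' @param format `"json"`, `"fasta"` or `"csv"`.
#' @param dir output directory (created if needed).
#' @return character vector of files written.
#' @export
export_database <- function(db, format, dir = ".") {
  if (!format %in% c("json", "fasta", "csv")) {
    stop("unknown format '", format,
         "'; valid formats are: json, fasta, csv")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "json") {
    path <- file.path(dir, "zincsites.json")
    jsonlite::write_json(db$tables, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
    return(path)
  }
  if (format == "fasta") {
    path <- file.path(dir, "zinc_binding_chains.fasta")
    seqs <- db$tables$chains$sequence
    names(seqs) <- db$tables$chains$chain_key
    write_chain_fasta(seqs, path)
    return(path)
  }
  stats <- database_statistics(db)
  files <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(stats$coactive$table, "coactive_metals.csv")
  wr(stats$residue_frequencies, "liganding_residues.csv")
  wr(data.frame(coordination = names(stats$coordination_modes),
                count = as.integer(stats$coordination_modes)),
     "coordination_modes.csv")
  wr(db$tables$contacts[, c("element", "distance")],
     "contact_distances.csv")
  wr(data.frame(signature = names(stats$signatures_all),
                all = as.integer(stats$signatures_all),
                unique = as.integer(stats$signatures_unique[
                  names(stats$signatures_all)] %||% NA)),
     "residue_signatures.csv")
  files
}

#' Count residue signatures over a set of sites
#'
#' @param sites list of `zb_site`.
#' @return named integer vector, signature -> count; counts sum to the
#'   number of sites.
#' @export
signature_counter <- function(sites) {
  if (length(sites) == 0) return(integer(0))
  sig <- vapply(sites, residue_signature, character(1))
  tab <- table(sig)
  out <- as.integer(tab)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

#' Whole-database summary statistics
#'
#' Computes the site-level summaries the database is built for: residue
#' signature counters over all and over representative (unique) sites,
#' liganding residue-type frequencies, the co-active metal table with the
#' multi-metal size histogram, coordination-mode frequencies and
#' liganding-distance statistics (single-zinc sites, resolution better
#' than `max_resolution`), and the enzymatic enrichment of multi-metal
#' sites with its Fisher exact p-value.
#'
#' @param db a `zb_database`.
#' @param max_resolution resolution cutoff (exclusive) for coordination
#'   and distance statistics. Default 3.0.
#' @return named list of summaries.
#' @export
database_statistics <- function(db, max_resolution = 3.0) {
  sites <- db$sites
  rep_ids <- db$tables$sites$site_id[db$tables$sites$representative]
  site_ids <- vapply(sites, function(s) s$site_id, character(1))
  rep_sites <- sites[site_ids %in% rep_ids]

  res_freq <- function(ss) {
    if (length(ss) == 0) return(integer(0))
    rn <- unlist(lapply(ss, function(s) {
      ifelse(s$residues$is_water, "Water",
             ifelse(s$residues$is_protein, s$residues$resname, "Other"))
    }))
    tab <- sort(table(rn), decreasing = TRUE)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
  }
  freq_all <- res_freq(sites)
  freq_rep <- res_freq(rep_sites)
  res_names <- union(names(freq_all), names(freq_rep))
  residue_frequencies <- data.frame(
    residue = res_names,
    all = as.integer(freq_all[res_names]),
    unique = as.integer(freq_rep[res_names]),
    stringsAsFactors = FALSE)

  single_zn <- Filter(function(s) {
    sum(s$metals$element == "ZN") == 1 && nrow(s$metals) == 1 &&
      !is.na(s$resolution) && s$resolution < max_resolution
  }, sites)
  coord <- if (length(single_zn) > 0) {
    table(vapply(single_zn, coordination_mode, integer(1)))
  } else table(integer(0))

  dist_stats <- lapply(c(N = "N", S = "S", O = "O"), function(el) {
    tryCatch(distance_statistics(sites, el, max_resolution),
             error = function(e) NULL)
  })

  enz <- is_enzymatic(vapply(sites, function(s) s$molecule_name,
                             character(1)))
  multi <- vapply(sites, function(s) nrow(s$metals) > 1, logical(1))
  a <- sum(multi & enz); b <- sum(multi & !enz)
  c_ <- sum(!multi & enz); d <- sum(!multi & !enz)
  enrichment <- tryCatch(enzymatic_enrichment(a, b, c_, d),
                         error = function(e) NULL)

  list(signatures_all = signature_counter(sites),
       signatures_unique = signature_counter(rep_sites),
       residue_frequencies = residue_frequencies,
       coactive = coactive_summary(sites),
       coordination_modes = coord,
       distance_stats = dist_stats,
       enrichment_table = c(multi_enzymatic = a, multi_other = b,
                            single_enzymatic = c_, single_other = d),
       enrichment = enrichment)
}

#' @export
print.zb_database <- function(x, ...) {
  t <- x$tables
  cat(sprintf(paste0("zb_database: %d structure(s), %d zinc atom(s), ",
                     "%d site(s) in %d cluster(s)\n"),
              nrow(t$structures), nrow(t$zincs), nrow(t$sites),
              nrow(t$site_clusters)))
  if (nrow(t$failures) > 0) {
    cat(sprintf("  %d file(s) failed to process\n", nrow(t$failures)))
  }
  if (!is.null(x$path)) cat("  stored at:", x$path, "\n")
  invisible(x)
}
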