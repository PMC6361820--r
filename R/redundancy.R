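# Redundancy removal: 90% sequence-identity chain clustering and
# fingerprint-based binding-site clustering with best-resolution
# representatives.

#' Pairwise sequence identity
#'
#' Global alignment (match +1, mismatch 0, gap -1 via
#' [Biostrings::pairwiseAlignment()]); identity is the number of matched
#' positions divided by the length of the shorter sequence, the convention
#' CD-HIT uses. Symmetric in its arguments.
#'
#' @param seq_a,seq_b one-letter amino-acid strings (may contain `X`).
#' @return fraction in \[0, 1\].
#' @examples
#' pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV")  # 0.9
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("cannot compute identity of an empty sequence")
  }
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = identity_matrix(),
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln) / min(nchar(seq_a), nchar(seq_b))
}

identity_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters1 <- c(sort(unname(AA_3TO1)), "X")
      m <<- diag(1, length(letters1))
      dimnames(m) <<- list(letters1, letters1)
    }
    m
  }
})

#' Cluster chains at a sequence-identity threshold
#'
#' Greedy incremental clustering in the style of CD-HIT: chains are taken
#' in order of decreasing sequence length (ties broken by chain key), and
#' each joins the first existing cluster whose representative it matches
#' at or above the threshold, otherwise it seeds a new cluster.
#'
#' @param sequences named character vector of one-letter sequences; names
#'   are chain keys (conventionally `"<pdb_id>_<chain>"`).
#' @param threshold identity threshold, inclusive. Default 0.9.
#' @return list of chain clusters: each has `id`, `members` (chain keys),
#'   `representative` (chain key) and `representative_sequence`.
#' @export
cluster_chains <- function(sequences, threshold = 0.9) {
  stopifnot(length(sequences) == 0 || !is.null(names(sequences)))
  if (any(!nzchar(sequences))) stop("empty chain sequence")
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  reps <- character(0)      # representative sequences
  members <- list()
  for (i in seq_along(sequences)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(sequences[[i]], reps[[k]]) >= threshold) {
        members[[k]] <- c(members[[k]], names(sequences)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, sequences[[i]])
      members[[length(members) + 1L]] <- names(sequences)[i]
    }
  }
  lapply(seq_along(members), function(k) {
    list(id = sprintf("CC%d", k), members = members[[k]],
         representative = members[[k]][1],
         representative_sequence = unname(reps[[k]]))
  })
}

#' Map from chain key to chain-cluster id
#'
#' @param chain_clusters output of [cluster_chains()].
#' @return named character vector: chain key -> cluster id.
#' @export
chain_cluster_map <- function(chain_clusters) {
  out <- character(0)
  for (cl in chain_clusters) out[cl$members] <- cl$id
  out
}

#' Compute the equivalence fingerprint of a binding site
#'
#' Two sites are equivalent when (i) their protein liganding residues lie
#' on chains of the same 90%-identity cluster(s), (ii) the liganding
#' residue types occur in the same order along each chain and (iii) the
#' residues immediately before and after each liganding residue in the
#' sequence have the same types (`-` at a chain terminus). Non-protein
#' ligands (waters, hetero groups) do not enter the fingerprint. Chains
#' are compared as a multiset, so homodimer interface sites match
#' independently of chain labelling.
#'
#' @param site a `zb_site`.
#' @param chain_map named vector from chain key (`"<pdb_id>_<chain>"`) to
#'   chain-cluster id (see [chain_cluster_map()]).
#' @return a single fingerprint string; equal strings mean equivalent
#'   sites.
#' @export
site_fingerprint <- function(site, chain_map) {
  res <- site$residues[site$residues$is_protein, , drop = FALSE]
  if (nrow(res) == 0) stop("site has no protein liganding residues")
  keys <- paste(site$pdb_id, res$chain, sep = "_")
  if (any(!(keys %in% names(chain_map)))) {
    stop("liganding chain(s) missing from chain-cluster map: ",
         paste(unique(keys[!(keys %in% names(chain_map))]), collapse = ", "))
  }
  grp <- paste(res$chain, res$copy_index, sep = "|")
  parts <- vapply(unique(grp), function(g) {
    r <- res[grp == g, , drop = FALSE]
    r <- r[order(r$seq_index), , drop = FALSE]
    sprintf("%s[%s]{%s}",
            chain_map[[paste(site$pdb_id, r$chain[1], sep = "_")]],
            paste(r$code1, collapse = ""),
            paste(paste0(r$prev1, r$next1), collapse = ","))
  }, character(1))
  paste(sort(parts), collapse = "|")
}

#' Cluster binding sites by fingerprint equality
#'
#' Partitions sites into equivalence classes of identical fingerprints.
#' Within each class the member from the best-resolution structure is
#' flagged as the representative (a missing resolution, e.g. NMR, sorts
#' as +Inf; ties go to the lexicographically smallest PDB id).
#'
#' @param sites list of `zb_site`.
#' @param chain_clusters output of [cluster_chains()] covering every
#'   liganding chain.
#' @return list of site clusters: each has `id`, `members` (indices into
#'   `sites`), `representative` (index) and `fingerprint`.
#' @export
cluster_sites <- function(sites, chain_clusters) {
  if (length(sites) == 0) return(list())
  cmap <- chain_cluster_map(chain_clusters)
  fps <- vapply(sites, site_fingerprint, character(1), chain_map = cmap)
  out <- list()
  for (fp in unique(fps)) {
    members <- which(fps == fp)
    resn <- vapply(sites[members], function(s) {
      if (is.na(s$resolution)) Inf else s$resolution
    }, numeric(1))
    ids <- vapply(sites[members], function(s) s$pdb_id, character(1))
    rep_i <- members[order(resn, ids)[1]]
    out[[length(out) + 1L]] <- list(
      id = sprintf("SC%d", length(out) + 1L),
      members = members, representative = rep_i, fingerprint = fp)
  }
  out
}

#' Write zinc-binding chain sequences as FASTA
#'
#' One record per chain, headers `>pdbid_chainid` — the sequence set a
#' BLAST front-end over the database would index.
#'
#' @param sequences named character vector (names `"<pdb_id>_<chain>"`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chain_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
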