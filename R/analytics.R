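# Site-level statistics: residue signatures, coordination modes,
# liganding-distance distributions, co-active metal tables and
# enzymatic enrichment.

#' Residue signature of a binding site
#'
#' Compact descriptor built from the one-letter codes of the protein
#' liganding residues with their counts, letters in alphabetical order:
#' four cysteines give `"C4"`, three cysteines and a histidine `"C3H1"`.
#' Waters and non-protein ligands are excluded.
#'
#' @param site a `zb_site`.
#' @return signature string.
#' @export
residue_signature <- function(site) {
  res <- site$residues[site$residues$is_protein, , drop = FALSE]
  if (nrow(res) == 0) stop("site has no protein liganding residues")
  tab <- table(res$code1)
  paste0(names(tab), as.integer(tab), collapse = "")
}

#' Coordination mode of a single-zinc site
#'
#' The number of liganding contacts of the zinc, counting water and other
#' non-protein contacts (a coordinating water is part of the coordination
#' sphere even though it never counts toward the salt thresholds).
#'
#' @param site a `zb_site` containing exactly one zinc atom.
#' @return integer contact count.
#' @export
coordination_mode <- function(site) {
  if (sum(site$metals$element == "ZN") != 1) {
    stop("coordination mode is defined for single-zinc sites only")
  }
  zn_row <- site$metals$row[site$metals$element == "ZN"]
  sum(site$contacts$metal == zn_row)
}

#' Liganding distance statistics for one element
#'
#' Pools contact distances whose liganding atom has the given element,
#' over single-zinc sites from structures with resolution strictly better
#' than `max_resolution`, and reports the count, mean and sample standard
#' deviation. Nitrogen and sulphur show characteristically tight
#' distributions; oxygen is broader because carboxylate oxygens and waters
#' both contribute.
#'
#' @param sites list of `zb_site`.
#' @param element element symbol (e.g. `"N"`, `"S"`, `"O"`).
#' @param max_resolution resolution cutoff in Angstroms, exclusive.
#'   Default 3.0.
#' @return list with `element`, `n`, `mean`, `sd` (0 when n = 1).
#' @export
distance_statistics <- function(sites, element, max_resolution = 3.0) {
  pool <- numeric(0)
  for (s in sites) {
    if (sum(s$metals$element == "ZN") != 1) next
    if (is.na(s$resolution) || s$resolution >= max_resolution) next
    d <- s$contacts$distance[s$contacts$element == element]
    pool <- c(pool, d)
  }
  if (length(pool) == 0) {
    stop("no qualifying ", element, " contacts in the site pool")
  }
  list(element = element, n = length(pool), mean = mean(pool),
       sd = if (length(pool) == 1) 0 else stats::sd(pool))
}

#' Co-active metal table and multi-metal site histogram
#'
#' For every multi-metal site, counts each non-zinc metal atom once and
#' each zinc atom beyond the first once (a site with three zincs adds +2
#' to the zinc count), plus the number of sites containing each element
#' (for zinc: sites with more than one zinc). Also returns the histogram
#' of metals per site over all sites.
#'
#' @param sites list of `zb_site`.
#' @return list with `table` (data.frame: element, count, site_count,
#'   zero rows when no multi-metal sites) and `histogram` (named integer
#'   vector: metals-per-site -> number of sites).
#' @export
coactive_summary <- function(sites) {
  n_metals <- vapply(sites, function(s) nrow(s$metals), integer(1))
  hist <- table(factor(n_metals, levels = sort(unique(n_metals))))
  counts <- list()
  site_counts <- list()
  for (s in sites[n_metals > 1]) {
    els <- s$metals$element
    for (el in unique(els)) {
      k <- sum(els == el)
      if (el == "ZN") {
        if (k < 2) next
        add <- k - 1L
      } else {
        add <- k
      }
      counts[[el]] <- (counts[[el]] %||% 0L) + add
      site_counts[[el]] <- (site_counts[[el]] %||% 0L) + 1L
    }
  }
  els <- names(counts) %||% character(0)
  tab <- data.frame(
    element = els,
    count = vapply(els, function(e) as.integer(counts[[e]]), integer(1)),
    site_count = vapply(els, function(e) as.integer(site_counts[[e]]),
                        integer(1)),
    stringsAsFactors = FALSE
  )
  if (nrow(tab) > 0) {
    tab <- tab[order(-tab$count, tab$element), , drop = FALSE]
    rownames(tab) <- NULL
  }
  list(table = tab, histogram = c(unclass(hist)))
}

#' Is a molecule name enzymatic?
#'
#' True when any whitespace-delimited token of the lower-cased name ends
#' in "ase" ("CARBONIC ANHYDRASE II" is, "INSULIN" is not).
#'
#' @param molecule_name protein/molecule name string.
#' @return logical.
#' @export
is_enzymatic <- function(molecule_name) {
  vapply(molecule_name, function(nm) {
    tokens <- strsplit(tolower(trimws(nm)), "\\s+")[[1]]
    any(endsWith(tokens, "ase"))
  }, logical(1), USE.NAMES = FALSE)
}

#' Enzymatic enrichment of multi-metal sites
#'
#' Two-sided Fisher exact test on the 2x2 contingency of
#' (multi-metal vs zinc-only) x (enzymatic vs non-enzymatic) site counts.
#'
#' @param a multi-metal, enzymatic count.
#' @param b multi-metal, non-enzymatic count.
#' @param c_ zinc-only, enzymatic count.
#' @param d zinc-only, non-enzymatic count.
#' @return list with `odds_ratio` (sample odds ratio ad/bc) and `p_value`
#'   (two-sided, by summation of table probabilities no larger than the
#'   observed table's).
#' @export
enzymatic_enrichment <- function(a, b, c_, d) {
  counts <- c(a, b, c_, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("contingency table has a zero margin")
  }
  ft <- stats::fisher.test(m, alternative = "two.sided")
  list(odds_ratio = (a * d) / (b * c_), p_value = ft$p.value)
}
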