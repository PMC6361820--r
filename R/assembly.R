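# Biological assembly selection and generation.

#' Choose the biological assembly to process
#'
#' Among declared assemblies whose chains carry at least one zinc atom,
#' returns the one with the lowest solvent-free-energy annotation; when no
#' energies are annotated, the first-listed zinc-containing assembly (a
#' missing energy sorts as +Inf). If no assembly contains zinc the first
#' assembly is returned, and `NULL` when the file declares none (callers
#' then fall back to the asymmetric unit).
#'
#' @param model a `zb_structure`.
#' @return an assembly instruction (list with `id`, `chain_ids`,
#'   `transforms`, `groups`, `energy`) or `NULL`.
#' @export
select_assembly <- function(model) {
  asms <- model$assemblies
  if (length(asms) == 0) return(NULL)
  zinc_chains <- unique(model$atoms$chain[model$atoms$element == "ZN"])
  has_zinc <- vapply(asms, function(a) {
    any(a$chain_ids %in% zinc_chains)
  }, logical(1))
  if (!any(has_zinc)) return(asms[[1]])
  cand <- asms[has_zinc]
  energies <- vapply(cand, function(a) {
    if (is.na(a$energy)) Inf else a$energy
  }, numeric(1))
  cand[[which.min(energies)]]  # ties and all-Inf: first listed wins
}

#' Generate a biological assembly by applying transform instructions
#'
#' Each chain listed in the instruction is duplicated once per transform
#' with rotated and translated coordinates. The k-th transform produces
#' atoms with `copy_index = k - 1`, so an identity first transform leaves
#' the asymmetric-unit originals at copy 0. Source atom identifiers
#' (chain, residue number + insertion code, atom name) are preserved
#' unchanged; chains not listed in the instruction are dropped.
#'
#' @param model a `zb_structure` (unexpanded, `copy_index` all 0).
#' @param instruction an assembly instruction from `model$assemblies` /
#'   [select_assembly()].
#' @return a new `zb_structure` whose atom count is the sum over
#'   transforms of the atoms in the chains each transform applies to.
#' @export
build_assembly <- function(model, instruction) {
  if (is.null(instruction)) return(model)
  known <- unique(model$atoms$chain)
  missing_ch <- setdiff(instruction$chain_ids, known)
  if (length(missing_ch) > 0) {
    stop("assembly instruction references unknown chain(s): ",
         paste(missing_ch, collapse = ", "))
  }
  pieces <- list()
  copy <- 0L
  for (grp in instruction$groups) {
    base <- model$atoms[model$atoms$chain %in% grp$chain_ids &
                          model$atoms$copy_index == 0L, , drop = FALSE]
    for (tr in grp$transforms) {
      piece <- base
      xyz <- as.matrix(base[, c("x", "y", "z")]) %*% t(tr$rotation)
      piece$x <- xyz[, 1] + tr$translation[1]
      piece$y <- xyz[, 2] + tr$translation[2]
      piece$z <- xyz[, 3] + tr$translation[3]
      piece$copy_index <- copy
      pieces[[length(pieces) + 1L]] <- piece
      copy <- copy + 1L
    }
  }
  out <- model
  out$atoms <- do.call(rbind, pieces)
  rownames(out$atoms) <- NULL
  attr(out, "assembly_id") <- instruction$id
  out
}
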