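# The all-atom structure container used throughout the package.
#
# A memqa_structure is a list with $target_id, $model_id and $atoms, a
# data.frame with one row per atom: chain, resno, icode, resname, atom,
# x, y, z, occ, b, element, hydrogen, plus derived columns res_ord (global
# residue ordinal) and seqpos (position within its chain). Atom rows of one
# residue are contiguous and residues within a chain are ordered by
# (resno, icode).

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns chain, resno, icode, resname, atom,
#'   x, y, z and optionally occ, b, element, hydrogen.
#' @param target_id,model_id identifier strings carried through scoring and
#'   benchmark reports.
#' @return An object of class `memqa_structure`.
#' @export
new_structure <- function(atoms, target_id = "", model_id = "") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  need <- c("chain", "resno", "icode", "resname", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$element)) atoms$element <- element_of(atoms$atom)
  if (is.null(atoms$hydrogen)) atoms$hydrogen <- atoms$element %in% c("H", "D")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$atom))) stop("empty atom name")

  chain_order <- unique(atoms$chain)
  atoms$chain <- factor(atoms$chain, levels = chain_order)
  o <- order(as.integer(atoms$chain), atoms$resno, atoms$icode)
  atoms <- atoms[o, , drop = FALSE]
  atoms$chain <- as.character(atoms$chain)

  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  atoms$res_ord <- match(key, unique(key))
  # position within chain, by residue
  first <- !duplicated(atoms$res_ord)
  res_chain <- atoms$chain[first]
  seqpos_by_res <- stats::ave(seq_along(res_chain), res_chain, FUN = seq_along)
  atoms$seqpos <- seqpos_by_res[atoms$res_ord]
  rownames(atoms) <- NULL

  structure(list(target_id = target_id, model_id = model_id, atoms = atoms),
            class = "memqa_structure")
}

#' Per-residue summary table of a structure
#'
#' @param model a `memqa_structure`.
#' @return data.frame with one row per residue: res_ord, chain, resno, icode,
#'   resname, aa (one-letter), seqpos.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  first <- !duplicated(a$res_ord)
  data.frame(res_ord = a$res_ord[first], chain = a$chain[first],
             resno = a$resno[first], icode = a$icode[first],
             resname = a$resname[first],
             aa = unname(AA1[a$resname[first]]),
             seqpos = a$seqpos[first], stringsAsFactors = FALSE)
}

#' @noRd
n_residues <- function(model) max(model$atoms$res_ord)

# Coordinates of one named atom per residue (NA rows where absent).
#' @noRd
atom_coords_by_residue <- function(model, name) {
  a <- model$atoms
  n <- n_residues(model)
  out <- matrix(NA_real_, n, 3)
  sel <- a$atom == name & !a$hydrogen
  out[a$res_ord[sel], ] <- as.matrix(a[sel, c("x", "y", "z")])
  out
}

#' @noRd
heavy_atoms <- function(model) model$atoms[!model$atoms$hydrogen, , drop = FALSE]

#' @export
print.memqa_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("memqa structure model '%s' (target '%s')\n",
              x$model_id, x$target_id))
  cat(sprintf("  %d chain(s), %d residues, %d atoms (%d hydrogens)\n",
              length(unique(rt$chain)), nrow(rt), nrow(x$atoms),
              sum(x$atoms$hydrogen)))
  invisible(x)
}
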