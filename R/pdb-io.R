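# PDB reading and writing. The dialect is deliberately strict and small:
# first MODEL block only, HETATM ignored, alternate locations resolved by
# highest occupancy (ties: first seen), unknown residue types dropped with a
# warning, hydrogens kept but flagged and excluded from all feature and
# energy computations downstream.

#' Read a protein model from a PDB file
#'
#' Parses ATOM records of the first MODEL block. HETATM records are ignored,
#' alternate locations are resolved by keeping the highest-occupancy copy
#' (ties broken by file order), residues that are not one of the 20 standard
#' amino acids are dropped with a warning, and hydrogens are retained but
#' flagged so that feature and energy code can skip them.
#'
#' @param path PDB file path.
#' @param target_id,model_id identifiers stored on the result; default to the
#'   file name.
#' @return A [new_structure()] object.
#' @export
read_pdb <- function(path, target_id = NULL, model_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  # keep only the first MODEL block if the file has several
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]
  rec <- substr(lines, 1, 6)
  is_atom <- trimws(rec) == "ATOM"
  if (!any(is_atom)) stop("no ATOM records in ", path)
  idx <- which(is_atom)
  ln <- lines[idx]

  num <- function(s, lineno, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    empty <- which(!nzchar(trimws(s)))
    if (what %in% c("x", "y", "z")) bad <- sort(unique(c(bad, empty)))
    if (length(bad) > 0)
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, lineno[bad[1]], trimws(s[bad[1]])))
    v
  }
  atoms <- data.frame(
    chain = substr(ln, 22, 22),
    resno = as.integer(num(substr(ln, 23, 26), idx, "residue number")),
    icode = substr(ln, 27, 27),
    resname = trimws(substr(ln, 18, 20)),
    atom = trimws(substr(ln, 13, 16)),
    altloc = substr(ln, 17, 17),
    x = num(substr(ln, 31, 38), idx, "x"),
    y = num(substr(ln, 39, 46), idx, "y"),
    z = num(substr(ln, 47, 54), idx, "z"),
    occ = num(substr(ln, 55, 60), idx, "occupancy"),
    b = num(substr(ln, 61, 66), idx, "b-factor"),
    element = toupper(trimws(substr(ln, 77, 78))),
    stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  no_el <- !nzchar(atoms$element)
  atoms$element[no_el] <- element_of(atoms$atom[no_el])
  atoms$hydrogen <- atoms$element %in% c("H", "D")

  unknown <- !(atoms$resname %in% AA3)
  if (any(unknown)) {
    warning("dropping ", sum(unknown), " atom(s) of non-standard residue(s): ",
            paste(unique(atoms$resname[unknown]), collapse = ", "))
    atoms <- atoms[!unknown, , drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("no standard amino-acid ATOM records in ", path)

  # altloc resolution: per residue+atom keep the highest occupancy copy,
  # ties resolved by file order (stable sort).
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "|")
  keep <- !duplicated(key[order(-atoms$occ)])[order(order(-atoms$occ))]
  # (order(-occ) is stable, so equal occupancies keep the first-seen record)
  atoms <- atoms[keep, , drop = FALSE]
  atoms$altloc <- NULL

  base <- tools::file_path_sans_ext(basename(path))
  new_structure(atoms,
                target_id = if (is.null(target_id)) base else target_id,
                model_id = if (is.null(model_id)) base else model_id)
}

#' Write a structure model to a PDB file
#'
#' Emits standard fixed-format ATOM records (8.3 coordinates), one TER per
#' chain and a final END. Reading the file back preserves residue count,
#' atom names and coordinates to three decimals.
#'
#' @param model a `memqa_structure`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  lines <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      nm <- sub$atom[i]
      # standard PDB name justification: single-letter elements in col 14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm_fmt, " ", sub$resname[i], ch, sub$resno[i],
        sub$icode[i], sub$x[i], sub$y[i], sub$z[i], sub$occ[i], sub$b[i],
        sub$element[i]))
    }
    serial <- serial + 1L
    last <- nrow(sub)
    lines <- c(lines, sprintf("TER   %5d      %-3s %s%4d%s",
                              serial %% 100000L, sub$resname[last], ch,
                              sub$resno[last], sub$icode[last]))
  }
  lines <- c(lines, "END")
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Extract the one-letter sequence of each chain
#'
#' @param model a `memqa_structure`.
#' @return Named character vector, one string per chain, chain order
#'   preserved.
#' @export
extract_sequence <- function(model) {
  rt <- residue_table(model)
  vapply(split(rt$aa, factor(rt$chain, levels = unique(rt$chain))),
         paste0, character(1), collapse = "")
}

#' Validate a structure model
#'
#' Reports residues missing any backbone heavy atom (N, CA, C, O), chain
#' breaks (consecutive C to N distance above 2.5 Angstrom) and duplicate
#' residue identifiers. An empty data.frame means the model is clean.
#'
#' @param model a `memqa_structure`.
#' @return data.frame with columns `type` ("missing_backbone", "chain_break",
#'   "duplicate_residue") and `residue` (chain:resno label).
#' @export
validate_model <- function(model) {
  a <- heavy_atoms(model)
  rt <- residue_table(model)
  lab <- function(i) paste0(rt$chain[i], ":", rt$resno[i],
                            ifelse(nzchar(trimws(rt$icode[i])), rt$icode[i], ""))
  issues <- list()
  have <- vapply(seq_len(nrow(rt)), function(i) {
    nm <- a$atom[a$res_ord == rt$res_ord[i]]
    all(BACKBONE_ATOMS %in% nm)
  }, logical(1))
  for (i in which(!have))
    issues[[length(issues) + 1L]] <- data.frame(type = "missing_backbone",
                                                residue = lab(i))
  Cc <- atom_coords_by_residue(model, "C")
  Nn <- atom_coords_by_residue(model, "N")
  for (i in seq_len(nrow(rt) - 1L)) {
    j <- i + 1L
    if (rt$chain[i] != rt$chain[j]) next
    if (any(is.na(Cc[i, ])) || any(is.na(Nn[j, ]))) next
    d <- sqrt(sum((Cc[i, ] - Nn[j, ])^2))
    if (d > 2.5)
      issues[[length(issues) + 1L]] <-
        data.frame(type = "chain_break",
                   residue = paste0(lab(i), "-", lab(j)))
  }
  # two residues with the same (chain, resno, icode) collapse onto one
  # ordinal at construction; they are detectable by conflicting residue names
  nn <- tapply(model$atoms$resname, model$atoms$res_ord,
               function(x) length(unique(x)))
  for (i in which(nn > 1))
    issues[[length(issues) + 1L]] <-
      data.frame(type = "duplicate_residue", residue = lab(i))
  if (length(issues) == 0)
    return(data.frame(type = character(0), residue = character(0)))
  do.call(rbind, issues)
}
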