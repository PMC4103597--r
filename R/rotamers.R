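# Backbone-dependent rotamer library.
#
# A library is a data.frame with one row per rotamer: aa, phi_bin, psi_bin
# (30-degree bin indices 0..11, NA = backbone-independent fallback),
# chi1..chi4 means, sd1..sd4 (degrees) and prob. Probabilities within each
# (aa, bin) cell sum to 1; every type has a backbone-independent entry, so
# lookup never fails.

#' @noRd
ROTLIB_HEADER <- "# MEMQA-ROTLIB v1"

#' @noRd
phi_psi_bin <- function(angle) {
  ifelse(is.na(angle), NA_integer_,
         pmin(11L, as.integer(floor(((angle + 180) %% 360) / 30))))
}

#' @noRd
rotlib_row <- function(aa, chi, prob, phi_bin = NA_integer_,
                       psi_bin = NA_integer_, sd = 10) {
  chi <- c(chi, rep(NA_real_, 4 - length(chi)))
  sds <- c(rep(sd, sum(!is.na(chi))), rep(NA_real_, sum(is.na(chi))))
  data.frame(aa = aa, phi_bin = phi_bin, psi_bin = psi_bin,
             chi1 = chi[1], chi2 = chi[2], chi3 = chi[3], chi4 = chi[4],
             sd1 = sds[1], sd2 = sds[2], sd3 = sds[3], sd4 = sds[4],
             prob = prob, stringsAsFactors = FALSE)
}

# Backbone-independent rotamer sets: the dominant rotamers per type with
# rounded literature-style frequencies (declared approximations, not a
# reproduction of any published library).
#' @noRd
BASE_ROTAMERS <- list(
  SER = list(list(c(-65), .48), list(c(62), .30), list(c(180), .22)),
  CYS = list(list(c(-65), .55), list(c(-178), .25), list(c(62), .20)),
  THR = list(list(c(62), .50), list(c(-60), .43), list(c(-175), .07)),
  VAL = list(list(c(175), .60), list(c(-60), .30), list(c(63), .10)),
  LEU = list(list(c(-65, 175), .60), list(c(-175, 65), .30),
             list(c(-85, 65), .10)),
  ILE = list(list(c(-65, 170), .60), list(c(-57, -60), .15),
             list(c(62, 170), .15), list(c(-65, 100), .10)),
  MET = list(list(c(-65, 180, 75), .30), list(c(-65, 180, -75), .30),
             list(c(-178, 180, 75), .20), list(c(-65, -65, 100), .20)),
  PRO = list(list(c(30, -35), .50), list(c(-30, 35), .50)),
  ASP = list(list(c(-70, -15), .50), list(c(-177, 0), .30),
             list(c(62, 0), .20)),
  ASN = list(list(c(-65, -40), .40), list(c(-177, 0), .30),
             list(c(62, 0), .30)),
  GLU = list(list(c(-65, 180, 0), .50), list(c(-178, 180, 0), .30),
             list(c(62, 180, 0), .20)),
  GLN = list(list(c(-65, 180, 0), .50), list(c(-178, 180, 0), .30),
             list(c(62, 180, 0), .20)),
  LYS = list(list(c(-65, 180, 180, 180), .50),
             list(c(-178, 180, 180, 180), .30),
             list(c(62, 180, 180, 180), .20)),
  ARG = list(list(c(-65, 180, 180, 180), .40),
             list(c(-178, 180, 65, 85), .30),
             list(c(62, 180, 180, 180), .30)),
  HIS = list(list(c(-65, -70), .40), list(c(-177, 60), .30),
             list(c(62, -85), .30)),
  PHE = list(list(c(-65, 90), .50), list(c(-177, 75), .35),
             list(c(62, 90), .15)),
  TYR = list(list(c(-65, 90), .50), list(c(-177, 75), .35),
             list(c(62, 90), .15)),
  TRP = list(list(c(-65, 95), .40), list(c(-177, -105), .30),
             list(c(62, -90), .30))
)

#' Built-in minimal backbone-dependent rotamer library
#'
#' Backbone-independent rotamer sets for all chi-bearing types plus
#' helix-bin entries (phi in \[-90, -30), psi in \[-75, -15)) in which the
#' gauche- chi1 rotamer is up-weighted, the dominant backbone dependence in
#' alpha-helical membrane proteins. Richer libraries can be loaded with
#' [read_rotamer_library()].
#'
#' @return Object of class `memqa_rotlib` (a data.frame).
#' @export
default_rotamer_library <- function() {
  if (!is.null(.memqa_cache$default_rotlib))
    return(.memqa_cache$default_rotlib)
  rows <- list()
  for (aa in names(BASE_ROTAMERS)) {
    set <- BASE_ROTAMERS[[aa]]
    for (r in set)
      rows[[length(rows) + 1L]] <- rotlib_row(aa, r[[1]], r[[2]])
    if (aa %in% c("PRO")) next               # ring pucker: no helix reweight
    # helix bins: phi bins 3,4 (-90..-30), psi bins 3,4 (-90..-30):
    # up-weight rotamers whose chi1 is gauche- (near -65)
    p <- vapply(set, `[[`, numeric(1), 2)
    gm <- vapply(set, function(r) abs(r[[1]][1] + 65) < 30, logical(1))
    if (any(gm) && !all(gm)) {
      p2 <- p
      p2[gm] <- p[gm] * 1.8
      p2 <- p2 / sum(p2)
    } else p2 <- p
    for (pb in 3:4) for (sb in 3:4) {
      for (k in seq_along(set))
        rows[[length(rows) + 1L]] <- rotlib_row(aa, set[[k]][[1]], p2[k],
                                                phi_bin = pb, psi_bin = sb)
    }
  }
  lib <- do.call(rbind, rows)
  class(lib) <- c("memqa_rotlib", "data.frame")
  validate_rotamer_library(lib)
  lib <- index_rotamer_library(lib)
  .memqa_cache$default_rotlib <- lib
  lib
}

#' @noRd
.memqa_cache <- new.env(parent = emptyenv())

# attach a lookup index (environment keyed by aa|phi_bin|psi_bin) so that
# per-residue rotamer retrieval avoids data.frame scans
#' @noRd
index_rotamer_library <- function(lib) {
  e <- new.env(parent = emptyenv())
  key <- paste(lib$aa, lib$phi_bin, lib$psi_bin, sep = "|")
  for (k in unique(key))
    assign(k, lib[key == k, , drop = FALSE], envir = e)
  attr(lib, "rotlib_index") <- e
  lib
}

#' @noRd
validate_rotamer_library <- function(lib) {
  key <- paste(lib$aa, lib$phi_bin, lib$psi_bin)
  sums <- tapply(lib$prob, key, sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("rotamer probabilities do not sum to 1 in cell(s): ",
         paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", "))
  fallback <- unique(lib$aa[is.na(lib$phi_bin)])
  missing <- setdiff(unique(lib$aa), fallback)
  if (length(missing) > 0)
    stop("no backbone-independent fallback for: ", paste(missing, collapse = ", "))
  invisible(lib)
}

#' Rotamers of a residue type at given backbone dihedrals
#'
#' Falls back to the backbone-independent set when the (phi, psi) bin has no
#' entry or either angle is undefined (chain termini).
#'
#' @param library a `memqa_rotlib`.
#' @param resname three-letter type.
#' @param phi,psi backbone dihedrals in degrees (NA allowed).
#' @return data.frame subset of the library (possibly 0 rows for GLY/ALA).
#' @export
rotamers_for <- function(library, resname, phi = NA, psi = NA) {
  pb <- phi_psi_bin(phi)
  sb <- phi_psi_bin(psi)
  idx <- attr(library, "rotlib_index")
  if (!is.null(idx)) {
    if (!is.na(pb) && !is.na(sb)) {
      hit <- idx[[paste(resname, pb, sb, sep = "|")]]
      if (!is.null(hit)) return(hit)
    }
    hit <- idx[[paste(resname, NA, NA, sep = "|")]]
    if (!is.null(hit)) return(hit)
    return(library[0, , drop = FALSE])
  }
  sub <- library[library$aa == resname, , drop = FALSE]
  if (nrow(sub) == 0) return(sub)
  if (!is.na(pb) && !is.na(sb)) {
    hit <- sub[!is.na(sub$phi_bin) & sub$phi_bin == pb &
                 !is.na(sub$psi_bin) & sub$psi_bin == sb, , drop = FALSE]
    if (nrow(hit) > 0) return(hit)
  }
  sub[is.na(sub$phi_bin), , drop = FALSE]
}

#' Write a rotamer library to its TSV format
#' @param library a `memqa_rotlib`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_rotamer_library <- function(library, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(ROTLIB_HEADER, con)
  df <- as.data.frame(library)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(df, function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "NA", sprintf("%.12g", x))
    else ifelse(is.na(x), "NA", as.character(x))
  }), sep = "\t")), con)
  invisible(path)
}

#' Read a rotamer library from its TSV format
#' @param path file path.
#' @return A validated `memqa_rotlib`.
#' @export
read_rotamer_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2 || trimws(lines[1]) != ROTLIB_HEADER)
    stop("not a MEMQA-ROTLIB v1 file: ", path)
  lib <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("aa", "phi_bin", "psi_bin", paste0("chi", 1:4),
            paste0("sd", 1:4), "prob")
  if (!all(need %in% colnames(lib))) stop("malformed rotamer library")
  lib$phi_bin <- as.integer(lib$phi_bin)
  lib$psi_bin <- as.integer(lib$psi_bin)
  for (cn in c(paste0("chi", 1:4), paste0("sd", 1:4), "prob"))
    lib[[cn]] <- as.numeric(lib[[cn]])
  class(lib) <- c("memqa_rotlib", "data.frame")
  validate_rotamer_library(lib)
  index_rotamer_library(lib)
}
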