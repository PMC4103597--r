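# Amino-acid reference tables shared across modules.

#' @noRd
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' @noRd
AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

# Heavy-atom van der Waals radii, Chothia/Naccess-style values (Angstrom).
#' @noRd
ELEMENT_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85)

# Maximum accessible surface in a Gly-X-Gly tripeptide (Angstrom^2), used to
# turn residue SASA into relative accessibility. Tien et al. 2013 theoretical
# values.
#' @noRd
MAX_SASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
              GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
              LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
              SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# Kyte-Doolittle hydropathy, used by the membrane burial mismatch term.
#' @noRd
KD_HYDROPATHY <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
                   GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
                   LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
                   SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

#' @noRd
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# 13-class heavy-atom typing for atom-atom contact features. Assignment is by
# (residue type, atom name); anything unmatched falls into class "other".
#' @noRd
ATOM_CLASSES <- c("C_aliph", "C_arom", "C_carbonyl", "C_carbox", "N_amide",
                  "N_pos", "N_arom", "O_carbonyl", "O_carbox", "O_hydroxyl",
                  "S", "CA_GLY", "other")

#' @noRd
classify_atom <- function(resname, atom) {
  n <- length(atom)
  cls <- rep("other", n)
  arom_res <- resname %in% c("PHE", "TYR", "TRP", "HIS")
  ring_c <- atom %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "CZ2",
                        "CZ3", "CH2", "CE3")
  cls[grepl("^C", atom)] <- "C_aliph"
  cls[arom_res & ring_c] <- "C_arom"
  cls[atom == "C"] <- "C_carbonyl"
  cls[resname == "ASN" & atom == "CG"] <- "C_carbonyl"
  cls[resname == "GLN" & atom == "CD"] <- "C_carbonyl"
  cls[resname == "ASP" & atom == "CG"] <- "C_carbox"
  cls[resname == "GLU" & atom == "CD"] <- "C_carbox"
  cls[resname == "ARG" & atom == "CZ"] <- "C_carbox"
  cls[atom == "N"] <- "N_amide"
  cls[resname == "ASN" & atom == "ND2"] <- "N_amide"
  cls[resname == "GLN" & atom == "NE2"] <- "N_amide"
  cls[resname == "LYS" & atom == "NZ"] <- "N_pos"
  cls[resname == "ARG" & atom %in% c("NE", "NH1", "NH2")] <- "N_pos"
  cls[resname == "HIS" & atom %in% c("ND1", "NE2")] <- "N_arom"
  cls[resname == "TRP" & atom == "NE1"] <- "N_arom"
  cls[atom == "O" | atom == "OXT"] <- "O_carbonyl"
  cls[resname == "ASN" & atom == "OD1"] <- "O_carbonyl"
  cls[resname == "GLN" & atom == "OE1"] <- "O_carbonyl"
  cls[resname == "ASP" & atom %in% c("OD1", "OD2")] <- "O_carbox"
  cls[resname == "GLU" & atom %in% c("OE1", "OE2")] <- "O_carbox"
  cls[atom %in% c("OG", "OG1", "OH")] <- "O_hydroxyl"
  cls[grepl("^S", atom)] <- "S"
  cls[resname == "GLY" & atom == "CA"] <- "CA_GLY"
  cls
}

#' @noRd
element_of <- function(atom_name) {
  # PDB element inference from the atom name when the element column is
  # absent: first alphabetic character of the stripped name.
  ch <- sub("^[0-9']*", "", atom_name)
  toupper(substr(ch, 1, 1))
}

#' @noRd
atom_radius <- function(element, atom_name = NULL) {
  r <- ELEMENT_RADII[element]
  if (any(is.na(r))) {
    bad <- if (is.null(atom_name)) element[is.na(r)] else atom_name[is.na(r)]
    stop("no van der Waals radius for atom(s): ",
         paste(unique(bad), collapse = ", "))
  }
  unname(r)
}
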