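# Sequence-profile container and its plain-text format.
#
# A profile carries everything the scorer needs that depends only on the
# target sequence: PSSM log-odds, predicted secondary structure
# probabilities, predicted burial and predicted membrane topology. In the
# original pipeline these come from PSI-BLAST, PSIPRED, Topcons/Zpred and
# MPRAP; here they are read from a documented TSV or produced by the
# synthetic generator.

#' @noRd
TOPOLOGY_LEVELS <- c("membrane", "inside", "outside")

#' Construct a sequence profile
#'
#' @param sequence one-letter amino-acid string.
#' @param pssm numeric matrix length x 20 of log-odds, columns named by
#'   [AA1] codes.
#' @param pred_ss numeric matrix length x 3 (columns H, E, C), rows on the
#'   probability simplex.
#' @param pred_burial numeric vector in \[0,1\].
#' @param pred_topology character vector in {"membrane","inside","outside"}.
#' @return Object of class `memqa_profile`.
#' @export
new_profile <- function(sequence, pssm, pred_ss, pred_burial, pred_topology) {
  L <- nchar(sequence)
  stopifnot(nrow(pssm) == L, ncol(pssm) == 20,
            nrow(pred_ss) == L, ncol(pred_ss) == 3,
            length(pred_burial) == L, length(pred_topology) == L,
            all(pred_topology %in% TOPOLOGY_LEVELS))
  rs <- rowSums(pred_ss)
  if (any(abs(rs - 1) > 1e-6)) stop("pred_ss rows must sum to 1")
  colnames(pssm) <- unname(AA1[AA3])
  colnames(pred_ss) <- c("H", "E", "C")
  structure(list(sequence = sequence, pssm = pssm, pred_ss = pred_ss,
                 pred_burial = pmin(1, pmax(0, pred_burial)),
                 pred_topology = pred_topology),
            class = "memqa_profile")
}

#' @export
print.memqa_profile <- function(x, ...) {
  cat(sprintf("memqa sequence profile, %d residues (%d membrane)\n",
              nchar(x$sequence), sum(x$pred_topology == "membrane")))
  invisible(x)
}

#' @noRd
PROFILE_HEADER <- "# MEMQA-PROFILE v1"

#' Write a sequence profile to its TSV format
#'
#' @param profile a `memqa_profile`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_profile <- function(profile, path) {
  L <- nchar(profile$sequence)
  df <- data.frame(index = seq_len(L),
                   aa = strsplit(profile$sequence, "")[[1]],
                   round(profile$pssm, 6),
                   pH = round(profile$pred_ss[, 1], 6),
                   pE = round(profile$pred_ss[, 2], 6),
                   pC = round(profile$pred_ss[, 3], 6),
                   burial = round(profile$pred_burial, 6),
                   topology = profile$pred_topology,
                   check.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(PROFILE_HEADER, con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(df, format, trim = TRUE,
                                     scientific = FALSE), sep = "\t")), con)
  invisible(path)
}

#' Read a sequence profile, checking it against the expected sequence
#'
#' Secondary-structure probability rows off the simplex by more than 1e-3
#' are an error; smaller deviations are renormalised with a warning.
#'
#' @param path profile TSV path.
#' @param expected_sequence one-letter string the profile must match.
#' @return A `memqa_profile`.
#' @export
read_profile <- function(path, expected_sequence) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2 || trimws(lines[1]) != PROFILE_HEADER)
    stop("not a MEMQA-PROFILE v1 file: ", path)
  df <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  L <- nchar(expected_sequence)
  if (nrow(df) != L)
    stop(sprintf("profile length %d does not match sequence length %d",
                 nrow(df), L))
  if (!identical(paste0(df$aa, collapse = ""), expected_sequence))
    stop("profile residues do not match the expected sequence")
  aa_cols <- unname(AA1[AA3])
  if (!all(aa_cols %in% colnames(df))) stop("malformed profile: PSSM columns missing")
  pssm <- as.matrix(df[, aa_cols])
  ss <- as.matrix(df[, c("pH", "pE", "pC")])
  rs <- rowSums(ss)
  off <- abs(rs - 1) > 1e-6
  if (any(abs(rs - 1) > 1e-3))
    stop("pred_ss probabilities far off the simplex (row ",
         which(abs(rs - 1) > 1e-3)[1], ")")
  if (any(off)) {
    warning("renormalising ", sum(off), " pred_ss row(s)")
    ss[off, ] <- ss[off, , drop = FALSE] / rs[off]
  }
  if (!all(df$topology %in% TOPOLOGY_LEVELS)) stop("malformed topology labels")
  new_profile(expected_sequence, pssm, ss, df$burial, df$topology)
}

#' Per-residue feature matrix for the scorer
#'
#' Builds the windowed per-residue input of the quality predictor. For each
#' residue the row concatenates, over a symmetric window of `window`
#' positions along the chain: PSSM log-odds (20), predicted secondary
#' structure (3), predicted burial (1), observed secondary structure one-hot
#' (3), relative accessibility (1), membrane depth and region one-hot (4),
#' atom-contact class counts (13) and residue-contact type counts (20),
#' plus one padding indicator per window position (1 where the window runs
#' off the chain and the 65 feature slots are zero-filled).
#'
#' Feature values are raw; z-normalisation constants are fitted at training
#' time and stored in the scorer.
#'
#' @param model a `memqa_structure`.
#' @param profile a `memqa_profile` of the model's sequence.
#' @param spec a [membrane_spec()].
#' @param window odd window width, default 9.
#' @param sasa_points sphere sample points per atom for the SASA feature.
#' @param backbone_cache optional list with precomputed `ss` (secondary
#'   structure labels) and `md` (membrane depth data.frame). Secondary
#'   structure and membrane depth depend only on backbone atoms, so they can
#'   be shared across fixed-backbone side-chain decoys of one model; see
#'   [backbone_feature_cache()].
#' @return Numeric matrix residues x features with a `feature_spec`
#'   attribute (ordered column names).
#' @export
build_feature_matrix <- function(model, profile, spec = membrane_spec(),
                                 window = 9, sasa_points = 240,
                                 backbone_cache = NULL) {
  stopifnot(window %% 2 == 1, window >= 1)
  rt <- residue_table(model)
  n <- nrow(rt)
  seq_model <- paste0(rt$aa, collapse = "")
  if (nchar(profile$sequence) != n)
    stop(sprintf("profile length %d does not match model residue count %d",
                 nchar(profile$sequence), n))
  if (!identical(profile$sequence, seq_model))
    stop("profile sequence does not match model sequence")

  ss <- if (is.null(backbone_cache)) assign_secondary_structure(model)
        else backbone_cache$ss
  ss1 <- matrix(0, n, 3, dimnames = list(NULL, c("H", "E", "C")))
  ss1[cbind(seq_len(n), match(ss, c("H", "E", "C")))] <- 1
  sasa <- shrake_rupley_sasa(model, n_points = sasa_points)$residue$rel_acc
  md <- if (is.null(backbone_cache)) membrane_depth(model, spec)
        else backbone_cache$md
  reg1 <- matrix(0, n, 3, dimnames = list(NULL, c("core", "interface", "water")))
  reg1[cbind(seq_len(n), match(md$region, c("core", "interface", "water")))] <- 1
  ac <- atom_contact_counts(model)
  rc <- residue_contact_counts(model)

  per_pos <- cbind(profile$pssm, profile$pred_ss,
                   burial = profile$pred_burial,
                   obs_H = ss1[, 1], obs_E = ss1[, 2], obs_C = ss1[, 3],
                   rel_sasa = sasa, depth = md$depth,
                   reg_core = reg1[, 1], reg_if = reg1[, 2], reg_wat = reg1[, 3],
                   ac, rc)
  colnames(per_pos) <- feature_base_names()
  window_stack(per_pos, rt$chain, window)
}

#' @noRd
feature_base_names <- function() {
  c(paste0("pssm_", unname(AA1[AA3])), "pH", "pE", "pC",
    "burial", "obs_H", "obs_E", "obs_C", "rel_sasa", "depth",
    "reg_core", "reg_if", "reg_wat",
    paste0("ac_", ATOM_CLASSES), paste0("rc_", AA3))
}

# stack per-residue rows over a symmetric window along the chain, with
# zero padding and one padding indicator per window position
#' @noRd
window_stack <- function(per_pos, chains, window) {
  n <- nrow(per_pos)
  base_names <- colnames(per_pos)
  w <- (window - 1L) %/% 2L
  offsets <- -w:w
  cols <- ncol(per_pos)
  out <- matrix(0, n, window * (cols + 1L))
  cn <- character(0)
  for (k in seq_along(offsets)) {
    off <- offsets[k]
    src <- seq_len(n) + off
    # a window position is valid only within the same chain
    valid <- src >= 1 & src <= n
    valid[valid] <- chains[src[valid]] == chains[seq_len(n)[valid]]
    block <- matrix(0, n, cols)
    block[valid, ] <- per_pos[src[valid], , drop = FALSE]
    pad <- as.numeric(!valid)
    out[, ((k - 1L) * (cols + 1L) + 1L):(k * (cols + 1L))] <- cbind(block, pad)
    cn <- c(cn, paste0("w", off, ".", base_names), paste0("w", off, ".pad"))
  }
  colnames(out) <- cn
  attr(out, "feature_spec") <- cn
  out
}

#' Precompute the backbone-only features of a model
#'
#' Secondary structure and membrane depth depend only on backbone atoms;
#' fixed-backbone side-chain decoys of one model share them. Pass the result
#' as `backbone_cache` to [build_feature_matrix()] / [score_model()].
#'
#' @param model a `memqa_structure`.
#' @param spec a [membrane_spec()].
#' @return List with `ss` and `md`.
#' @export
backbone_feature_cache <- function(model, spec = membrane_spec()) {
  list(ss = assign_secondary_structure(model),
       md = membrane_depth(model, spec))
}
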