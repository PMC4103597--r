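# TM-score: length-normalised Calpha structural similarity in (0, 1].
# Residue correspondence is by (chain, residue number, insertion code); no
# sequence alignment is attempted.

#' @noRd
cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' TM-score distance scale d0
#' @param L reference length (residues).
#' @return d0 in Angstrom, floored at 0.5 for short chains.
#' @export
tm_d0 <- function(L) max(0.5, 1.24 * cbrt(L - 15) - 1.8)

#' @noRd
common_ca <- function(model, reference) {
  ca_m <- model$atoms[model$atoms$atom == "CA" & !model$atoms$hydrogen, ]
  ca_r <- reference$atoms[reference$atoms$atom == "CA" & !reference$atoms$hydrogen, ]
  key_m <- paste(ca_m$chain, ca_m$resno, ca_m$icode)
  key_r <- paste(ca_r$chain, ca_r$resno, ca_r$icode)
  i <- match(key_r, key_m)
  keep <- !is.na(i)
  list(model = as.matrix(ca_m[i[keep], c("x", "y", "z")]),
       reference = as.matrix(ca_r[keep, c("x", "y", "z")]),
       key = key_r[keep], L_ref = nrow(ca_r))
}

#' TM-score of a model against a reference structure
#'
#' Computes the TM-score
#' score = (1/L) * sum_i 1 / (1 + (d_i/d0)^2), normalised by the reference
#' length L, with d0 = max(0.5, 1.24 (L-15)^(1/3) - 1.8). The superposition
#' maximising the score is searched heuristically: seed windows of lengths
#' L, L/2 and L/4 (minimum 4) at all offsets with stride max(1, L/20) are
#' superposed by Kabsch, then the included-residue set is iterated (distance
#' cutoff 8 Angstrom shrinking to a d0-scaled floor, 20 iteration cap) and
#' the best score over all seeds is reported.
#'
#' @param model,reference `memqa_structure` objects sharing residue
#'   numbering; at least 5 common Calpha atoms required.
#' @return Object of class `memqa_tmscore`: list with `score`, `d0`,
#'   `n_common`, `transform` (rotation/translation applied to the model) and
#'   `per_residue_d` (named distances under the best transform).
#' @export
tm_score <- function(model, reference) {
  cc <- common_ca(model, reference)
  n <- nrow(cc$model)
  if (n < 5) stop("fewer than 5 common Calpha atoms")
  L <- cc$L_ref
  d0 <- tm_d0(L)
  X <- cc$model; Y <- cc$reference

  score_of <- function(tr) {
    d <- sqrt(rowSums((apply_transform(X, tr) - Y)^2))
    list(score = sum(1 / (1 + (d / d0)^2)) / L, d = d)
  }
  best <- NULL
  seed_lens <- unique(pmax(4L, c(n, floor(n / 2), floor(n / 4))))
  stride <- max(1L, floor(n / 20))
  floor_cut <- max(d0, 3.5)
  for (len in seed_lens) {
    for (off in seq(1L, n - len + 1L, by = stride)) {
      idx <- off:(off + len - 1L)
      for (iter in seq_len(20L)) {
        if (length(idx) < 3) break
        tr <- kabsch_superpose(X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
        sc <- score_of(tr)
        if (is.null(best) || sc$score > best$score)
          best <- list(score = sc$score, d = sc$d, transform = tr)
        cutoff <- if (iter == 1) 8 else if (iter == 2) max(floor_cut, 6) else floor_cut
        new_idx <- which(sc$d < cutoff)
        if (length(new_idx) < 4)
          new_idx <- order(sc$d)[seq_len(min(4L, n))]
        if (identical(new_idx, idx)) break
        idx <- new_idx
      }
    }
  }
  structure(list(score = best$score, d0 = d0, n_common = n,
                 transform = best$transform,
                 per_residue_d = stats::setNames(best$d, cc$key)),
            class = "memqa_tmscore")
}

#' @export
print.memqa_tmscore <- function(x, ...) {
  cat(sprintf("TM-score %.4f (d0 = %.3f A, %d common residues)\n",
              x$score, x$d0, x$n_common))
  invisible(x)
}

#' Per-target Z-scores of first-ranked models
#'
#' For each target the model maximising the selection score is picked (ties:
#' lexicographically smallest model id) and its quality is standardised
#' against all models of that target:
#' Z = (q_selected - mean(q)) / population-sd(q), with Z = 0 when the
#' spread is zero. The sum over targets measures overall selection power.
#'
#' @param score_table named list, one element per target: named numeric
#'   vector of selection scores per model.
#' @param quality same shape: true quality (TM-score) per model.
#' @return Object of class `memqa_zscore`: list with `per_target` (named
#'   numeric), `selected` (named character) and `sum`.
#' @export
z_scores <- function(score_table, quality) {
  stopifnot(identical(names(score_table), names(quality)))
  per <- numeric(0)
  sel <- character(0)
  for (tg in names(score_table)) {
    s <- score_table[[tg]]
    q <- quality[[tg]]
    if (length(s) < 2) stop("target ", tg, " has fewer than 2 models")
    if (!all(names(s) %in% names(q))) stop("score/quality model mismatch for ", tg)
    q <- q[names(s)]
    ids <- names(s)[order(-s, names(s))]
    pick <- ids[1]
    mu <- mean(q)
    sdev <- sqrt(mean((q - mu)^2))      # population sd
    z <- if (sdev == 0) 0 else (q[[pick]] - mu) / sdev
    per[tg] <- z
    sel[tg] <- pick
  }
  structure(list(per_target = per, selected = sel, sum = sum(per)),
            class = "memqa_zscore")
}

#' @export
print.memqa_zscore <- function(x, ...) {
  cat(sprintf("sum-Z over %d target(s): %.3f\n", length(x$per_target), x$sum))
  invisible(x)
}
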