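#' Labeled cell clone
#'
#' A clone is a set of lineage-labeled cells with 2D positions (um), an
#' induction-stage tag, and optional per-cell expression labels.
#'
#' @param clone_id identifier.
#' @param stage induction-stage string, e.g. one of [clone_stages()].
#' @param cells data.frame with `x`, `y` (um) and optionally `label`.
#' @return object of class `clone`.
#' @export
clone <- function(clone_id, stage, cells) {
  if (!all(c("x", "y") %in% names(cells))) stopf("cells need x and y columns")
  if (nrow(cells) < 1L) stopf("clone '%s': needs >= 1 cell", clone_id)
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y)))
    stopf("clone '%s': non-finite cell coordinates", clone_id)
  structure(list(clone_id = as.character(clone_id),
                 stage = as.character(stage), cells = cells),
            class = "clone")
}

#' @export
print.clone <- function(x, ...) {
  cat(sprintf("<clone %s (%s): %d cells>\n", x$clone_id, x$stage,
              nrow(x$cells)))
  invisible(x)
}

#' Standard clone-induction stages
#'
#' Mid-L2, late-L2 and early-L3 heat-shock induction windows.
#' @return character vector of stage tags.
#' @export
clone_stages <- function() c("m-L2", "l-L2", "e-L3")

#' Score one clone against the fold
#'
#' A clone is `restricted` only if every member cell lies strictly on a
#' single side of the fold; a single cell on the other side makes the clone
#' `crossed` (single-cell resolution). Any cell within the on-line tolerance
#' is ambiguous and raises an error rather than an arbitrary call.
#'
#' @param cl a [clone()].
#' @param fold a [fold_line()].
#' @param tol on-line tolerance (um) passed to [side_of_fold()].
#' @return `"restricted"` or `"crossed"`.
#' @export
score_clone <- function(cl, fold, tol = 0.25) {
  sides <- side_of_fold(as.matrix(cl$cells[, c("x", "y")]), fold, tol = tol)
  amb <- which(sides == "on-line")
  if (length(amb))
    stopf("clone '%s': cell(s) %s within %g um of the fold; side call ambiguous",
          cl$clone_id, paste(amb, collapse = ", "), tol)
  if (length(unique(sides)) == 1L) "restricted" else "crossed"
}

#' Restriction fraction for a set of clone calls
#'
#' @param calls character vector of `"restricted"`/`"crossed"` calls (e.g.
#'   from [score_clone()]).
#' @return list with `percent` (restricted, half-up rounded to 2 decimal
#'   places), `n_restricted`, `n_crossed`, `n_total`.
#' @export
restriction_fraction <- function(calls) {
  if (length(calls) == 0L) stopf("no clones to summarize")
  bad <- setdiff(unique(calls), c("restricted", "crossed"))
  if (length(bad)) stopf("unknown call(s): %s", paste(bad, collapse = ", "))
  k <- sum(calls == "restricted")
  list(percent = round_half_up(100 * k / length(calls), 2L),
       n_restricted = k, n_crossed = length(calls) - k,
       n_total = length(calls))
}

#' Phenotype penetrance
#'
#' @param k number of discs showing the phenotype.
#' @param n number of discs scored, >= 1.
#' @return list with `percent` (half-up rounded to 1 decimal place) and
#'   `fraction` (the "k/n" string).
#' @export
penetrance <- function(k, n) {
  if (n < 1L) stopf("n must be >= 1")
  if (k < 0L || k > n) stopf("k must be in 0..n")
  list(percent = round_half_up(100 * k / n, 1L),
       fraction = sprintf("%d/%d", as.integer(k), as.integer(n)))
}

#' Pooled rate over several k/n counts
#'
#' @param k,n integer vectors of event and total counts (all n > 0).
#' @return pooled percentage 100 * sum(k)/sum(n), half-up rounded to the
#'   nearest integer.
#' @export
pooled_rate <- function(k, n) {
  if (length(k) != length(n)) stopf("k and n differ in length")
  if (any(n <= 0)) stopf("all n must be > 0")
  if (any(k < 0) || any(k > n)) stopf("each k must be in 0..n")
  round_half_up(100 * sum(k) / sum(n), 0L)
}

#' Call selector-field mixing in a disc
#'
#' TRUE if any Dll-labeled cell lies on the Lim1 side of the fold or vice
#' versa; cells labeled neither are ignored.
#'
#' @param cells data.frame with `x`, `y` and `label` in
#'   `{"Dll", "Lim1", "none"}`.
#' @param fold a [fold_line()].
#' @param dll_side which side ("A-side"/"B-side") is the Dll field; must be
#'   stated explicitly.
#' @param tol on-line tolerance (um).
#' @return logical mixing call.
#' @export
mixing_call <- function(cells, fold, dll_side, tol = 0.25) {
  if (missing(dll_side) || !dll_side %in% c("A-side", "B-side"))
    stopf("dll_side must be 'A-side' or 'B-side' (fold side labeling required)")
  if (nrow(cells) == 0L) stopf("empty disc: no cells to score")
  bad <- setdiff(unique(cells$label), c("Dll", "Lim1", "none"))
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  lab <- cells$label[cells$label != "none"]
  if (length(lab) == 0L) stopf("no Dll/Lim1-labeled cells in disc")
  keep <- cells$label != "none"
  sides <- side_of_fold(as.matrix(cells[keep, c("x", "y")]), fold, tol = tol)
  lim1_side <- setdiff(c("A-side", "B-side"), dll_side)
  any((lab == "Dll" & sides == lim1_side) |
      (lab == "Lim1" & sides == dll_side))
}
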