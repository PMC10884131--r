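#' Defect grade of a regional uptake value
#'
#' The five-point grading bands: normal 75-100 -> 0, mild defect 65-74 ->
#' 1, moderate defect 50-64 -> 2, severe defect 40-49 -> 3, complete
#' defect below 40 -> 4. Band boundaries are closed on their printed lower
#' bound; fractional uptakes are graded by the same inequalities without
#' rounding (so 64.9 is still moderate).
#'
#' @param u regional uptake percentage(s) in `[0, 100]`.
#' @return integer score(s) 0-4.
#' @export
grade_uptake <- function(u) {
  if (any(u < 0 | u > 100)) stop("uptake out of [0, 100]")
  as.integer(4L - (u >= 40) - (u >= 50) - (u >= 65) - (u >= 75))
}

segment_values <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 17L, "value" %in% names(x))
    return(x$value[order(x$segment)])
  }
  stopifnot(length(x) == 17L)
  as.numeric(x)
}

#' Score one case from its stress and rest segment tables
#'
#' Each table is first normalized to relative uptake (its maximum segment
#' = 100%, matching the relative-uptake display convention), then graded
#' per segment with [grade_uptake()]. Difference scores are
#' `max(stress - rest, 0)` per segment by default (reversibility), and
#' summed scores and coronary-territory sums are populated.
#'
#' @param stress_table,rest_table [segment_table()] data frames (or bare
#'   17-vectors of uptake values).
#' @param territories named list mapping territories to segments
#'   (default [territory_map_default()]).
#' @param floor_diff floor negative per-segment differences at zero
#'   (default TRUE).
#' @return a `score_table` list: `stress_scores`, `rest_scores`,
#'   `diff_scores` (17 integers each), `sss`, `srs`, `sds`, and
#'   `territory_scores` (matrix, territories x c(sss, srs, sds)).
#' @export
score_case <- function(stress_table, rest_table,
                       territories = territory_map_default(),
                       floor_diff = TRUE) {
  territories <- check_territory_map(territories)
  sv <- segment_values(stress_table); rv <- segment_values(rest_table)
  if (max(sv) <= 0 || max(rv) <= 0) stop("degenerate all-zero segment table")
  s_rel <- sv / max(sv) * 100
  r_rel <- rv / max(rv) * 100
  ss <- grade_uptake(s_rel); rs <- grade_uptake(r_rel)
  dd <- ss - rs
  if (floor_diff) dd <- pmax(dd, 0L)
  tmat <- t(vapply(territories, function(seg)
    c(sss = sum(ss[seg]), srs = sum(rs[seg]), sds = sum(dd[seg])),
    c(sss = 0, srs = 0, sds = 0)))
  structure(list(stress_scores = ss, rest_scores = rs, diff_scores = as.integer(dd),
                 sss = sum(ss), srs = sum(rs), sds = sum(dd),
                 territory_scores = tmat),
            class = "score_table")
}

#' Defect presence in a coronary territory
#'
#' A defect is present in a territory when its summed stress, rest, or
#' difference score is one or more.
#'
#' @param score_table a [score_case()] result.
#' @param territory `"RCA"`, `"LAD"` or `"LCX"` (a row of the score
#'   table's territory matrix).
#' @return logical.
#' @export
defect_presence <- function(score_table, territory) {
  stopifnot(inherits(score_table, "score_table"),
            territory %in% rownames(score_table$territory_scores))
  any(score_table$territory_scores[territory, ] >= 1)
}

#' ROC analysis of defect detection
#'
#' AUC by the rank (Mann-Whitney) formulation with ties mid-ranked; the
#' operating point is the Youden-optimal threshold (predict positive when
#' `score >= threshold`; among ties the highest threshold, i.e. the most
#' specific operating point, is reported).
#'
#' @param truth_labels logical (or 0/1) reference labels; both classes
#'   must be present.
#' @param index_scores numeric scores, higher = more likely positive.
#' @return list `auc`, `sensitivity`, `specificity`, `threshold`.
#' @export
roc_defect_detection <- function(truth_labels, index_scores) {
  lab <- as.logical(truth_labels)
  stopifnot(length(lab) == length(index_scores))
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) stop("need at least one positive and one negative label")
  r <- rank(index_scores)
  auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(index_scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(index_scores[lab] >= t), 0)
  spec <- vapply(thr, function(t) mean(index_scores[!lab] < t), 0)
  j <- sens + spec - 1
  best <- which.max(j)  # ties: first = highest threshold (most specific)
  list(auc = auc, sensitivity = sens[best], specificity = spec[best],
       threshold = thr[best])
}
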