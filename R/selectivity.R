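#' Per-drug lineage Selectivity Score
#'
#' Ranks all cell lines screened against a drug by IC50 (ascending, rank 1
#' = most sensitive, ties receive the mean of the tied rank positions),
#' takes the median rank of the target-lineage lines, and normalizes by
#' the number of lines screened. Scores lie in (0, 1]; lower means more
#' selective for the target lineage. A Welch two-sided t-test on log10
#' IC50 (target vs all other lines) accompanies the score when both groups
#' have at least two lines.
#'
#' @param ic50_by_line named numeric vector of IC50s (µM), names = cell
#'   line ids. Lines without a record for the drug are simply absent.
#' @param annotations data frame with columns `cell_line` and `lineage`
#'   (additional columns such as `mycn_amplified`, `tp53_mutant` are
#'   carried along but unused here).
#' @param target_lineage lineage label defining the target group.
#' @param median_lines optional character vector of cell line ids: restrict
#'   the lines whose ranks define the median (e.g. a genotype subgroup of
#'   the target lineage) while all screened lines still define the ranking
#'   and the denominator.
#' @return list of class `selectivity_result`: `score`, `n_screened`,
#'   `n_target`, `median_target_rank`, `t_statistic`, `p_value`.
#' @export
selectivity_score <- function(ic50_by_line, annotations, target_lineage,
                              median_lines = NULL) {
  ic50 <- ic50_by_line[is.finite(ic50_by_line)]
  if (any(ic50 <= 0)) stop("invalid concentration: IC50 must be > 0")
  ann <- annotations[match(names(ic50), annotations$cell_line), , drop = FALSE]
  is_target <- !is.na(ann$lineage) & ann$lineage == target_lineage
  med_set <- is_target
  if (!is.null(median_lines)) {
    med_set <- is_target & names(ic50) %in% median_lines
  }
  if (!any(med_set)) stop("empty target group")
  if (!any(!is_target)) stop("need at least one non-target line")
  rk <- rank(ic50, ties.method = "average")
  med_rank <- stats::median(rk[med_set])
  n <- length(ic50)

  tt <- c(t_statistic = NA_real_, p_value = NA_real_)
  if (sum(is_target) >= 2 && sum(!is_target) >= 2) {
    ok <- tryCatch({
      ts <- lineage_t_test(log10(ic50[is_target]), log10(ic50[!is_target]))
      tt <- c(t_statistic = ts$t_statistic, p_value = ts$p_value)
      TRUE
    }, error = function(e) FALSE)
  }
  structure(list(score = med_rank / n, n_screened = n,
                 n_target = sum(med_set), median_target_rank = med_rank,
                 t_statistic = unname(tt[1]), p_value = unname(tt[2])),
            class = "selectivity_result")
}

#' Rank all drugs in a screen by lineage Selectivity Score
#'
#' Applies [selectivity_score()] to every drug in a long-format screening
#' table and returns the results sorted ascending by score (most selective
#' first). Missing (cell line, drug) records are excluded per drug, so the
#' denominator is drug-specific. Drugs with fewer than `min_target` lines
#' in the (possibly subgroup-filtered) target group are reported as
#' skipped, not scored.
#'
#' @param screen data frame with columns `cell_line`, `drug`, and a
#'   sensitivity column (default `ic50`); one record per (line, drug).
#' @param annotations annotation data frame (see [selectivity_score()]).
#' @param target_lineage lineage label.
#' @param subgroup_filter optional function of the annotation data frame
#'   returning a logical vector; only target-lineage lines passing it
#'   define the median (n_screened still counts all screened lines).
#' @param min_target minimum target-group size to score a drug (default 3).
#' @param value_col name of the sensitivity column to rank on (ascending =
#'   more sensitive); defaults to `"ic50"` but any monotone sensitivity
#'   measure (e.g. a fold change) works, since only ranks are used.
#' @return list with `results` (data frame sorted by score) and `skipped`
#'   (data frame of drug + reason).
#' @export
rank_drugs <- function(screen, annotations, target_lineage,
                       subgroup_filter = NULL, min_target = 3,
                       value_col = "ic50") {
  stopifnot(nrow(screen) > 0, value_col %in% names(screen))
  median_lines <- NULL
  if (!is.null(subgroup_filter)) {
    keep <- subgroup_filter(annotations)
    median_lines <- annotations$cell_line[keep]
  }
  drugs <- unique(screen$drug)
  rows <- list(); skipped <- list()
  for (dg in drugs) {
    sub <- screen[screen$drug == dg, , drop = FALSE]
    v <- stats::setNames(sub[[value_col]], sub$cell_line)
    res <- tryCatch(
      selectivity_score(v, annotations, target_lineage, median_lines),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[dg]] <- data.frame(drug = dg, reason = res)
      next
    }
    if (res$n_target < min_target) {
      skipped[[dg]] <- data.frame(
        drug = dg, reason = sprintf("n_target %d < min_target %d",
                                    res$n_target, min_target))
      next
    }
    rows[[dg]] <- data.frame(drug = dg, score = res$score,
                             n_screened = res$n_screened,
                             n_target = res$n_target,
                             median_target_rank = res$median_target_rank,
                             t_statistic = res$t_statistic,
                             p_value = res$p_value)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug = character(), score = numeric(), n_screened = integer(),
               n_target = integer(), median_target_rank = numeric(),
               t_statistic = numeric(), p_value = numeric())
  results <- results[order(results$score, results$drug), , drop = FALSE]
  rownames(results) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(drug = character(), reason = character())
  rownames(skipped) <- NULL
  list(results = results, skipped = skipped)
}

#' Welch two-sample t-test on log10 IC50
#'
#' Two-sided Welch (unequal-variance) t-test comparing the target lineage
#' against all other lines on the log10 IC50 scale.
#'
#' @param log10_ic50_target,log10_ic50_other numeric vectors (>= 2 each).
#' @return list with `t_statistic` and `p_value`.
#' @export
lineage_t_test <- function(log10_ic50_target, log10_ic50_other) {
  if (length(log10_ic50_target) < 2 || length(log10_ic50_other) < 2) {
    stop("insufficient observations: both groups need >= 2 values")
  }
  if (stats::sd(log10_ic50_target) == 0 && stats::sd(log10_ic50_other) == 0) {
    if (mean(log10_ic50_target) == mean(log10_ic50_other)) {
      return(list(t_statistic = 0, p_value = 1))
    }
    stop("insufficient observations: no variance in either group")
  }
  tt <- stats::t.test(log10_ic50_target, log10_ic50_other,
                      var.equal = FALSE, alternative = "two.sided")
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Concordance between two screens of the same cell lines
#'
#' Pearson correlation (with the usual two-sided t-approximation p-value)
#' of paired log10 IC50s, e.g. an original screen vs an in-house rescreen.
#'
#' @param log10_ic50_a,log10_ic50_b paired numeric vectors, length >= 3.
#' @return list with `pearson_r` and `p_value`.
#' @export
rescreen_concordance <- function(log10_ic50_a, log10_ic50_b) {
  stopifnot(length(log10_ic50_a) == length(log10_ic50_b),
            length(log10_ic50_a) >= 3)
  if (stats::sd(log10_ic50_a) == 0 || stats::sd(log10_ic50_b) == 0) {
    stop("degenerate correlation: zero variance")
  }
  ct <- stats::cor.test(log10_ic50_a, log10_ic50_b, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value)
}
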