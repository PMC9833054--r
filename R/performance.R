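#' Per-day behavioral performance summary
#'
#' Fractions of each rewarded-trial category among non-disregarded rewarded
#' trials, the fraction of unrewarded-reach trials among non-disregarded
#' non-rewarded trials, and the fraction of early reaches among successful
#' trials — the quantities tracked across training days. Disregarded trials
#' are excluded from every denominator; a day whose trials are all
#' disregarded is flagged empty rather than dividing by zero.
#'
#' @param records data.frame with columns `day`, `type`, `category` and
#'   (optionally) `early_reach` (logical; `NA` outside successful trials).
#' @return data.frame, one row per day: category fractions, `unrewarded_reach`
#'   fraction, `early_reach` fraction, trial counts and an `empty` flag.
#'   Rewarded-category fractions sum to 1 on non-empty days.
#' @export
summarize_performance <- function(records) {
  stopifnot(all(c("day", "type", "category") %in% names(records)))
  if (is.null(records$early_reach)) records$early_reach <- NA
  bad_rew <- records$type == "rewarded" &
    !records$category %in% rewarded_categories
  bad_non <- records$type == "nonrewarded" &
    !records$category %in% nonrewarded_categories
  if (any(bad_rew | bad_non)) {
    stop("illegal category for trial type: ",
         paste(unique(records$category[bad_rew | bad_non]), collapse = ", "))
  }
  out <- lapply(split(records, records$day), function(d) {
    rew <- d[d$type == "rewarded" & d$category != "disregard", , drop = FALSE]
    non <- d[d$type == "nonrewarded" & d$category != "disregard", , drop = FALSE]
    frac <- function(x, n) if (n > 0) x / n else NA_real_
    succ <- rew[rew$category == "success", , drop = FALSE]
    data.frame(
      day = d$day[1L],
      n_rewarded = nrow(rew),
      n_nonrewarded = nrow(non),
      success = frac(sum(rew$category == "success"), nrow(rew)),
      partial_fail = frac(sum(rew$category == "partial_fail"), nrow(rew)),
      complete_fail = frac(sum(rew$category == "complete_fail"), nrow(rew)),
      no_reach = frac(sum(rew$category == "no_reach"), nrow(rew)),
      groom = frac(sum(rew$category == "groom"), nrow(rew)),
      unrewarded_reach = frac(sum(non$category == "unrewarded_reach"), nrow(non)),
      early_reach = frac(sum(succ$early_reach, na.rm = TRUE), nrow(succ)),
      empty = nrow(rew) + nrow(non) == 0L
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$day), , drop = FALSE]
}

#' Descriptive genotype contrast of a per-mouse summary measure
#'
#' Genotype means are means of per-mouse values (one value per mouse,
#' itself a within-mouse summary) with SEM over mice — statistics never
#' pool trials across mice. Inferential testing is deliberately left to
#' standard routines on the returned per-mouse table.
#'
#' @param table data.frame with columns `genotype`, `mouse` and the
#'   `measure` column; one row per (mouse, day) or per mouse.
#' @param measure name of the column to contrast.
#' @param by optional extra grouping column (e.g. `"day"`).
#' @return data.frame with genotype (x by) rows: `mean`, `sem`, `n_mice`.
#' @export
genotype_compare <- function(table, measure, by = NULL) {
  stopifnot(measure %in% names(table),
            all(c("genotype", "mouse") %in% names(table)))
  groups <- if (is.null(by)) list(genotype = table$genotype)
            else stats::setNames(list(table$genotype, table[[by]]),
                                 c("genotype", by))
  out <- do.call(rbind, lapply(split(table, groups, drop = TRUE), function(d) {
    per_mouse <- tapply(d[[measure]], d$mouse, mean, na.rm = TRUE)
    per_mouse <- per_mouse[!is.na(per_mouse)]
    n <- length(per_mouse)
    row <- data.frame(genotype = d$genotype[1L],
                      mean = mean(per_mouse),
                      sem = if (n > 1L) stats::sd(per_mouse) / sqrt(n) else NA_real_,
                      n_mice = n)
    if (!is.null(by)) row[[by]] <- d[[by]][1L]
    row
  }))
  rownames(out) <- NULL
  out
}
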