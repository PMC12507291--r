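#' Within-subject standard errors of the mean (Cousineau)
#'
#' Removes each subject's mean, adds back the grand mean, and computes the
#' per-condition SEM of the adjusted values. With `morey = TRUE` the
#' variance is multiplied by the Morey correction factor `J/(J-1)` before
#' taking the square root.
#'
#' @param table data frame with columns `subject`, `condition`, `value`
#'   (long format, complete and balanced).
#' @param morey apply the Morey bias correction (default TRUE).
#' @return data frame with `condition`, `mean`, `sem`, `n`.
#' @export
within_subject_sem <- function(table, morey = TRUE) {
  need <- c("subject", "condition", "value")
  if (!all(need %in% names(table)))
    stop_param("table must have columns subject, condition, value")
  tab <- table
  counts <- table(tab$subject, tab$condition)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    stop_param("table is not complete/balanced; offending cells: ",
               paste(sprintf("%s:%s", rownames(counts)[bad[, 1]],
                             colnames(counts)[bad[, 2]]),
                     collapse = ", "))
  }
  subj_mean <- tapply(tab$value, tab$subject, mean)
  grand <- mean(tab$value)
  adj <- tab$value - subj_mean[as.character(tab$subject)] + grand
  J <- length(unique(tab$condition))
  fac <- if (morey) morey_factor(J) else 1
  out <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$condition),
    function(idx) {
      v <- adj[idx]
      data.frame(condition = tab$condition[idx[1]], mean = mean(tab$value[idx]),
                 sem = sqrt(fac * stats::var(v) / length(v)), n = length(v),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Morey variance correction factor
#'
#' `J / (J - 1)` for `J` within-subject conditions; applied to variances of
#' Cousineau-adjusted values. For J = 10 the factor is 1.11.
#'
#' @param J number of within-subject conditions (integer >= 2).
#' @export
morey_factor <- function(J) {
  if (length(J) != 1 || J != round(J) || J < 2)
    stop_param("J must be a single integer >= 2")
  J / (J - 1)
}
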