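#' @include AllClasses.R
NULL

#' Handedness index from grasping errors
#'
#' `HI = (errRight - errLeft) / (errRight + errLeft)`, bounded in
#' \[-1, 1\]. Because errors count failures, a negative HI means fewer
#' right-hand errors, i.e. better right-hand performance. Subjects with no
#' errors on either hand have no defined index and return `NA`.
#'
#' @param errRight,errLeft error counts per hand (vectorized).
#' @return Numeric HI values; `NA` where the total error count is zero.
#' @examples
#' handednessIndex(5, 15)   # -0.5, right performer
#' handednessIndex(15, 5)   # +0.5, left performer
#' @export
handednessIndex <- function(errRight, errLeft) {
  if (any(errRight < 0 | errLeft < 0))
    stop("error counts must be nonnegative", call. = FALSE)
  tot <- errRight + errLeft
  ifelse(tot == 0, NA_real_, (errRight - errLeft) / tot)
}

#' Classify hand performance from the handedness index
#'
#' Negative HI values classify as right performers, positive as left
#' performers; subjects with HI exactly zero or missing are excluded.
#'
#' @param hi numeric handedness indices.
#' @return Character vector with values `"right_performer"`,
#'   `"left_performer"` or `"excluded"`.
#' @export
classifyHandedness <- function(hi) {
  ifelse(is.na(hi) | hi == 0, "excluded",
         ifelse(hi < 0, "right_performer", "left_performer"))
}

#' Population-level bias test
#'
#' One-sample t test of handedness indices (or any laterality scores)
#' against zero, the test used to establish a population-level hand bias.
#'
#' @param values numeric scores, length >= 2; `NA`s are dropped.
#' @return List with elements `t`, `df`, `p` (two-sided), `mean`, `n`.
#' @export
populationBiasTest <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("zero variance: t statistic undefined", call. = FALSE)
  tt <- stats::t.test(values, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(values), n = length(values))
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with elements `r`, `p`, `n`; the correlation is `NA` with
#'   a warning when either vector has zero variance.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mixed-design ANOVA interaction on asymmetry quotients
#'
#' Two-way mixed-design ANOVA with one between-subject factor (handedness
#' group) and one within-subject factor (atlas threshold), returning the
#' classical univariate F for the group-by-threshold interaction with
#' `df1 = (T - 1)` and `df2 = (T - 1) * (N - G)` (no sphericity
#' correction), where T is the number of thresholds, N the number of
#' subjects and G the number of groups.
#'
#' @param data data.frame with columns `subject`, `threshold`, `aq`, and
#'   `group` (constant within subject).
#' @return List with elements `F`, `df1`, `df2`, `p`.
#' @export
mixedAnovaInteraction <- function(data) {
  req <- c("subject", "threshold", "aq", "group")
  if (!all(req %in% names(data)))
    stop("data must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  data$subject <- factor(data$subject)
  data$threshold <- factor(data$threshold)
  data$group <- factor(data$group)
  tab <- table(data$subject, data$threshold)
  bad <- rownames(tab)[rowSums(tab != 1L) > 0L]
  if (length(bad))
    stop("subjects without exactly one value per threshold: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(table(unique(data[c("subject", "group")])$group) < 2L))
    stop("need at least 2 subjects per group", call. = FALSE)
  fit <- stats::aov(aq ~ group * threshold + Error(subject / threshold),
                    data = data)
  sm <- summary(fit)
  within <- NULL
  for (stratum in sm) {
    tabs <- stratum[[1L]]
    if ("group:threshold" %in% trimws(rownames(tabs))) within <- tabs
  }
  if (is.null(within))
    stop("interaction stratum not found", call. = FALSE)
  rn <- trimws(rownames(within))
  i <- match("group:threshold", rn)
  e <- match("Residuals", rn)
  list(F = within[i, "F value"], df1 = within[i, "Df"],
       df2 = within[e, "Df"], p = within[i, "Pr(>F)"])
}
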