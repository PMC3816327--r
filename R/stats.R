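#' Repeated-measures (within-subject) ANOVA
#'
#' Classical fully within-subject decomposition for a balanced complete
#' design with one observation per subject x cell: each effect is tested
#' against its own interaction with subject, F = MS_effect /
#' MS_(effect x subject), with numerator dof the product of (levels - 1)
#' over the effect's factors and denominator dof that times (n_subjects -
#' 1).  For nine subjects and two-level factors every effect has dof
#' (1, 8).  Sums of squares come from the saturated subject-crossed linear
#' model; sphericity corrections are unnecessary for two-level factors.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject identifier column.
#' @param factors Character vector (1-3) of within-subject factor columns.
#' @return An object of class `fd_anova`: data frame with columns `effect`,
#'   `F`, `df1`, `df2`, `p`, `zero_error` (TRUE when the error mean square
#'   vanished and F is reported as 0).
#' @export
rm_anova <- function(data, dv = "value", subject = "subject", factors) {
  stopifnot(length(factors) >= 1, length(factors) <= 3,
            all(c(dv, subject, factors) %in% names(data)))
  d <- data.frame(.y = data[[dv]], .s = factor(data[[subject]]))
  for (i in seq_along(factors)) d[[paste0(".f", i)]] <-
    factor(data[[factors[i]]])
  fnames <- paste0(".f", seq_along(factors))
  if (nlevels(d$.s) < 2) stop("at least 2 subjects are required")
  cells <- table(d[c(".s", fnames)])
  if (any(cells != 1))
    stop("design must be balanced and complete with one observation per ",
         "subject and cell")

  form <- stats::as.formula(paste(".y ~ .s *", paste(fnames, collapse = " * ")))
  tab <- suppressWarnings(stats::anova(stats::lm(form, data = d)))
  comp <- lapply(strsplit(rownames(tab), ":", fixed = TRUE), sort)
  find <- function(term) {
    hit <- which(vapply(comp, function(x) identical(x, sort(term)),
                        logical(1)))
    if (!length(hit)) stop("term not found: ", paste(term, collapse = ":"))
    hit
  }

  effects <- unlist(lapply(seq_along(fnames), function(k)
    utils::combn(fnames, k, simplify = FALSE)), recursive = FALSE)
  res <- do.call(rbind, lapply(effects, function(eff) {
    ie <- find(eff)
    ierr <- find(c(eff, ".s"))
    ms_eff <- tab$`Sum Sq`[ie] / tab$Df[ie]
    ms_err <- tab$`Sum Sq`[ierr] / tab$Df[ierr]
    zero <- ms_err <= .Machine$double.eps * max(1, abs(ms_eff))
    f <- if (zero) 0 else ms_eff / ms_err
    label <- paste(factors[match(eff, fnames)], collapse = ":")
    data.frame(effect = label, F = f, df1 = tab$Df[ie],
               df2 = tab$Df[ierr],
               p = stats::pf(f, tab$Df[ie], tab$Df[ierr],
                             lower.tail = FALSE),
               zero_error = zero, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  structure(res, class = c("fd_anova", "data.frame"))
}

#' Holm-Bonferroni step-down familywise-error correction
#'
#' Sorts p-values ascending and rejects while p(i) <= alpha / (m - i + 1),
#' stopping at the first failure.  Rejects a superset of plain Bonferroni
#' and a subset of unadjusted testing.
#'
#' @param p Vector of p-values in [0, 1].
#' @param alpha Familywise error level.
#' @return Integer indices (into `p`) of rejected hypotheses.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (!length(p)) return(integer(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  which(stats::p.adjust(p, method = "holm") <= alpha)
}
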