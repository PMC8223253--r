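# Aligned Rank Transform (ART) factorial inference. For each effect the
# responses are aligned (every estimated marginal effect except the one of
# interest is removed via the cell-means decomposition), mid-ranked, and a
# repeated-measures ANOVA with subject as the random stratum is run on the
# ranks; only the effect of interest is read from each fit. Post hoc
# contrasts use composite-factor alignment (the factors of interest collapsed
# into a single factor) so that contrasts across their level combinations
# retain main effects, with Holm correction within the contrast family.

split_effect <- function(effect) {
  if (length(effect) == 1L && grepl(":", effect, fixed = TRUE))
    strsplit(effect, ":", fixed = TRUE)[[1]]
  else effect
}

check_cells <- function(table, factors) {
  cells <- table(interaction(table[factors], sep = ":", drop = FALSE))
  if (any(cells == 0))
    stop("empty design cell(s): ",
         paste(names(cells)[cells == 0], collapse = ", "))
  cells
}

#' Align responses for one effect
#'
#' Subtracts from each response every estimated marginal effect except the
#' effect of interest: `aligned = y - cell_mean + effect_estimate`, where the
#' effect estimate is the inclusion-exclusion combination of marginal means
#' over subsets of the effect's factors (e.g. for A:B it is
#' `mu_AB - mu_A - mu_B + mu`).
#'
#' @param table data.frame of responses and factor columns.
#' @param factors All fixed factors of the model (character vector, order
#'   fixes term naming).
#' @param effect The effect of interest: a factor name, `"A:B"` string, or
#'   character vector of factor names.
#' @param response Response column name.
#' @return List with `aligned` values and their mid-`ranks`.
#' @export
align_and_rank <- function(table, factors, effect, response = "avg_energy") {
  eff <- split_effect(effect)
  stopifnot(all(eff %in% factors), response %in% names(table))
  check_cells(table, factors)
  y <- table[[response]]
  if (any(!is.finite(y))) stop("non-finite responses")
  mu_full <- stats::ave(y, interaction(table[factors], drop = FALSE))
  est <- rep(mean(y) * (-1)^length(eff), length(y))
  for (k in seq_along(eff)) {
    for (sub in combn(eff, k, simplify = FALSE)) {
      mu <- stats::ave(y, interaction(table[sub], drop = FALSE))
      est <- est + (-1)^(length(eff) - k) * mu
    }
  }
  aligned <- y - mu_full + est
  list(aligned = aligned, ranks = rank(aligned))
}

art_term <- function(factors, eff) paste(factors[factors %in% eff],
                                         collapse = ":")

all_effects <- function(factors) {
  unlist(lapply(seq_along(factors), function(k)
    combn(factors, k, FUN = paste, collapse = ":")), use.names = FALSE)
}

fit_rank_anova <- function(table, factors, between, within, subject,
                           ranks, term) {
  dat <- table
  dat$.r <- ranks
  for (f in c(factors, subject)) dat[[f]] <- factor(dat[[f]])
  fixed <- paste(factors, collapse = " * ")
  if (length(within) && !is.null(subject)) {
    fml <- stats::as.formula(paste0(
      ".r ~ ", fixed, " + Error(", subject, "/(",
      paste(within, collapse = " * "), "))"))
  } else {
    fml <- stats::as.formula(paste0(".r ~ ", fixed))
  }
  fit <- suppressWarnings(aov(fml, data = dat))
  sm <- summary(fit)
  # walk strata for the requested term
  strata <- if (inherits(fit, "aovlist")) sm else list(sm)
  for (s in strata) {
    tab <- if (is.list(s) && !is.data.frame(s)) s[[1]] else s
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    if (!is.na(i) && !is.na(tab[i, "F value"])) {
      j <- match("Residuals", rn)
      return(list(F = tab[i, "F value"], df1 = tab[i, "Df"],
                  df2 = tab[j, "Df"], p = tab[i, "Pr(>F)"]))
    }
  }
  stop("term '", term, "' not found in ANOVA strata")
}

#' Aligned-rank-transform factorial ANOVA
#'
#' Runs the ART procedure for every requested effect of a mixed design:
#' align for the effect, rank, fit the full factorial ANOVA on the ranks
#' (with the subject error stratum for within-subject factors) and read that
#' effect's F test. Raw p values are Holm-corrected across the reported
#' effects.
#'
#' Unbalanced between-group designs are accepted with a warning (a single
#' between factor keeps the sequential and marginal tests identical); within
#' cells must be complete.
#'
#' @param table data.frame with one response row per subject x within-cell.
#' @param between,within Character vectors of factor column names.
#' @param subject Subject id column name.
#' @param response Response column name.
#' @param effects Effects to test (default: all mains and interactions).
#' @return An `art_result`: list with `effects` data.frame (`effect`, `F`,
#'   `df1`, `df2`, `p`, `p_holm`) plus the design description used by
#'   [posthoc_pairwise()].
#' @export
art_anova <- function(table, between, within = character(), subject = NULL,
                      response = "avg_energy", effects = NULL) {
  factors <- c(between, within)
  stopifnot(length(factors) >= 1, all(factors %in% names(table)))
  cells <- check_cells(table, factors)
  if (length(unique(cells)) > 1L)
    warning("unbalanced design: cell sizes differ (",
            paste(range(cells), collapse = "-"), ")")
  if (is.null(effects)) effects <- all_effects(factors)
  rows <- lapply(effects, function(e) {
    eff <- split_effect(e)
    term <- art_term(factors, eff)
    ar <- align_and_rank(table, factors, eff, response)
    ft <- fit_rank_anova(table, factors, between, within, subject,
                         ar$ranks, term)
    data.frame(effect = term, F = ft$F, df1 = ft$df1, df2 = ft$df2,
               p = ft$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_holm <- holm_adjust(res$p)
  structure(list(effects = res, table = table, between = between,
                 within = within, subject = subject, response = response),
            class = "art_result")
}

#' @export
print.art_result <- function(x, ...) {
  cat("Aligned-rank-transform ANOVA\n")
  print(x$effects, row.names = FALSE, digits = 4)
  invisible(x)
}

#' ART alignment diagnostic
#'
#' On each effect's aligned (unranked) column, a fixed-effects ANOVA of all
#' model effects is run; correctly aligned data leave an F of (numerically)
#' zero for every effect other than the one aligned for. Returns the maximum
#' other-effect F per aligned column.
#'
#' @inheritParams art_anova
#' @return Named numeric vector: worst other-effect F per effect.
#' @export
art_diagnostics <- function(table, between, within = character(),
                            response = "avg_energy") {
  factors <- c(between, within)
  effects <- all_effects(factors)
  out <- setNames(numeric(length(effects)), effects)
  for (e in effects) {
    eff <- split_effect(e)
    ar <- align_and_rank(table, factors, eff, response)
    dat <- table
    dat$.a <- ar$aligned
    for (f in factors) dat[[f]] <- factor(dat[[f]])
    fml <- stats::as.formula(paste0(".a ~ ", paste(factors, collapse = " * ")))
    tab <- anova(lm(fml, data = dat))
    rn <- trimws(rownames(tab))
    term <- art_term(factors, eff)
    other <- rn != term & rn != "Residuals"
    fv <- tab[other, "F value"]
    out[e] <- if (length(fv)) max(fv, na.rm = TRUE) else 0
  }
  out
}

#' Holm step-down p-value adjustment
#'
#' Sort ascending, set `adj_(i) = max_(j <= i) min(1, (m - j + 1) p_(j))`,
#' return in input order.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order as input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must be finite and in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Post hoc pairwise contrasts on aligned ranks
#'
#' Contrasts between level combinations ("cells") of one or more factors,
#' computed on composite-aligned ranks: the factors of interest are collapsed
#' into a single factor, the responses are aligned for that composite (so
#' main effects of the involved factors are retained, all other effects
#' removed) and ranked. Cell pairs differing only in within-subject factors
#' are compared by a paired t test on per-subject mean ranks; pairs involving
#' a between-subject difference use a Welch t test. p values are
#' Holm-corrected within the returned family.
#'
#' @param result An [art_anova()] result.
#' @param effect The effect whose cells are contrasted, e.g. `"state:band"`.
#' @param cells Optional character vector of cell labels (levels joined by
#'   `":"` in the effect's factor order) restricting the family, or a list of
#'   length-2 character vectors naming exactly the wanted pairs.
#' @return data.frame: `cell_a`, `cell_b`, `estimate` (mean rank difference
#'   a - b), `statistic`, `df`, `test`, `p`, `p_holm`.
#' @export
posthoc_pairwise <- function(result, effect, cells = NULL) {
  stopifnot(inherits(result, "art_result"))
  table <- result$table
  factors <- c(result$between, result$within)
  eff <- split_effect(effect)
  stopifnot(all(eff %in% factors))
  eff <- factors[factors %in% eff]
  y <- table[[result$response]]
  comp <- interaction(table[eff], sep = ":", drop = FALSE, lex.order = TRUE)
  mu_full <- stats::ave(y, interaction(table[factors], drop = FALSE))
  mu_comp <- stats::ave(y, comp)
  r <- rank(y - mu_full + mu_comp - mean(y))
  lev <- levels(comp)
  if (is.list(cells)) {
    pairs <- cells
    bad <- setdiff(unique(unlist(pairs)), lev)
    if (length(bad)) stop("unknown cell(s): ", paste(bad, collapse = ", "))
  } else {
    if (!is.null(cells)) {
      bad <- setdiff(cells, lev)
      if (length(bad)) stop("unknown cell(s): ", paste(bad, collapse = ", "))
      lev <- cells
    }
    if (length(lev) < 2) stop("need at least two cells to contrast")
    pairs <- combn(lev, 2, simplify = FALSE)
  }
  within_only <- all(eff %in% result$within)
  subj <- result$subject
  rows <- lapply(pairs, function(pr) {
    ia <- comp == pr[1]; ib <- comp == pr[2]
    if (within_only && !is.null(subj)) {
      ra <- tapply(r[ia], table[[subj]][ia], mean)
      rb <- tapply(r[ib], table[[subj]][ib], mean)
      common <- intersect(names(ra), names(rb))
      d <- ra[common] - rb[common]
      if (sd(d) == 0) {
        stat <- 0; dfree <- length(d) - 1; p <- 1
      } else {
        tt <- t.test(d)
        stat <- unname(tt$statistic); dfree <- unname(tt$parameter)
        p <- tt$p.value
      }
      data.frame(cell_a = pr[1], cell_b = pr[2], estimate = mean(d),
                 statistic = stat, df = dfree, test = "paired t (ranks)",
                 p = p, stringsAsFactors = FALSE)
    } else {
      tt <- t.test(r[ia], r[ib])
      data.frame(cell_a = pr[1], cell_b = pr[2],
                 estimate = mean(r[ia]) - mean(r[ib]),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), test = "Welch t (ranks)",
                 p = tt$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  out
}

#' Median and interquartile range
#'
#' Linear-interpolation (type 7) quartiles, the convention behind the
#' reported median (Q1, Q3) summaries.
#'
#' @param values Numeric vector.
#' @return Named vector `median`, `q1`, `q3`.
#' @examples
#' describe(1:9)  # 5, 3, 7
#' @export
describe <- function(values) {
  q <- quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Paired before/after comparison with normality gate
#'
#' Shapiro-Wilk on the paired differences; a paired t test when normality is
#' not rejected (p > 0.05), otherwise a Wilcoxon signed-rank test.
#'
#' @param before,after Paired numeric vectors (length >= 3).
#' @return List: `normality_p`, `test` used, `statistic`, `p`, `estimate`
#'   (mean of after - before).
#' @export
paired_compare <- function(before, after) {
  if (length(before) != length(after)) stop("length mismatch in pairs")
  if (length(before) < 3) stop("need at least 3 pairs")
  d <- after - before
  if (sd(d) == 0) {
    return(list(normality_p = NA_real_, test = "paired t", statistic = 0,
                p = 1, estimate = mean(d)))
  }
  sw <- shapiro.test(d)
  if (sw$p.value > 0.05) {
    tt <- t.test(after, before, paired = TRUE)
    list(normality_p = sw$p.value, test = "paired t",
         statistic = unname(tt$statistic), p = tt$p.value,
         estimate = mean(d))
  } else {
    wt <- suppressWarnings(wilcox.test(after, before, paired = TRUE))
    list(normality_p = sw$p.value, test = "wilcoxon signed-rank",
         statistic = unname(wt$statistic), p = wt$p.value,
         estimate = mean(d))
  }
}
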