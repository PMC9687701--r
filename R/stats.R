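# One-way ANOVA over study factors, LSMeans-style pairwise comparisons
# with a connecting-letters report, and grid summaries.

#' One-way analysis of variance
#'
#' Standard between/within decomposition (via `stats::aov`) of
#' observations grouped by a single factor.  When every observation is
#' identical the F statistic is reported as 0 with p = 1.
#'
#' @param values numeric observations (e.g. UTS in MPa or E in GPa)
#' @param group factor or character vector of level labels
#' @return an object of class "AnovaResult": list with `F`, `df` (num,
#'   den), `p`, `means` (per level), `mse` (pooled within-level mean
#'   square), `ssb`, `ssw`, `sst` and `n`
#' @export
oneWayAnova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 factor levels")
  if (length(values) != length(group))
    stop("values and group must have equal length")
  if (any(tabulate(group) == 0)) group <- droplevels(group)
  n <- length(values)
  k <- nlevels(group)
  if (n <= k)
    stop("degenerate design: need more observations than levels")
  fit <- aov(values ~ group)
  tab <- suppressWarnings(anova(fit))   # zero-variance fits warn spuriously
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  mse <- tab$`Mean Sq`[2]
  if (ssb <= .Machine$double.eps * max(1, sum(values^2))) {
    Fval <- 0; p <- 1
  } else {
    Fval <- tab$`F value`[1]
    p <- tab$`Pr(>F)`[1]
  }
  structure(list(F = Fval, df = c(tab$Df[1], tab$Df[2]), p = p,
                 means = tapply(values, group, mean), mse = mse,
                 ssb = ssb, ssw = ssw, sst = ssb + ssw,
                 n = tabulate(group), levels = levels(group)),
            class = "AnovaResult")
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  m <- data.frame(level = x$levels, n = x$n, mean = as.numeric(x$means))
  print(m, row.names = FALSE)
  invisible(x)
}

# pairwise LSMeans Student t p-values on the pooled MSE
pairwisePValues <- function(values, group) {
  a <- oneWayAnova(values, group)
  lev <- a$levels
  k <- length(lev)
  P <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(a$mse * (1 / a$n[i] + 1 / a$n[j]))
    tstat <- (a$means[[i]] - a$means[[j]]) / se
    P[i, j] <- P[j, i] <- 2 * pt(-abs(tstat), df = a$df[2])
  }
  list(p = P, anova = a)
}

#' Connecting-letters report of pairwise LSMeans comparisons
#'
#' Pairwise Student t tests on the pooled ANOVA mean square (uncorrected,
#' the LSMeans convention), summarised by the insert-and-absorb letter
#' algorithm: two levels share a letter if and only if their pairwise
#' difference is not significant at `alpha`.  A Tukey HSD option replaces
#' the raw p-values with Tukey-adjusted ones (stricter).
#'
#' @param values numeric observations
#' @param group level labels (>= 2 levels)
#' @param alpha significance level
#' @param method "lsmeans" (uncorrected Student t) or "tukey"
#' @return an object of class "ConnectingLetters": list with `letters`
#'   (named character, levels ordered by decreasing mean), `pMatrix`,
#'   `alpha`, `means`
#' @export
connectingLetters <- function(values, group, alpha = 0.05,
                              method = c("lsmeans", "tukey")) {
  method <- match.arg(method)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 levels for comparisons")
  pw <- pairwisePValues(values, group)
  P <- pw$p
  if (method == "tukey") {
    fit <- aov(values ~ g, data = data.frame(values = values, g = group))
    tk <- stats::TukeyHSD(fit)$g
    for (r in rownames(tk)) {
      ab <- strsplit(r, "-", fixed = TRUE)[[1]]
      P[ab[1], ab[2]] <- P[ab[2], ab[1]] <- tk[r, "p adj"]
    }
  }
  ord <- order(-as.numeric(pw$anova$means))
  lev <- pw$anova$levels[ord]
  k <- length(lev)
  sig <- function(a, b) P[a, b] < alpha

  # insert-and-absorb: maintain letter groups (columns) of mutually
  # non-separated levels
  cols <- list(lev)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig(lev[i], lev[j])) next
    newCols <- list()
    for (col in cols) {
      if (lev[i] %in% col && lev[j] %in% col) {
        newCols <- c(newCols, list(setdiff(col, lev[i])),
                     list(setdiff(col, lev[j])))
      } else newCols <- c(newCols, list(col))
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(newCols))
    for (a in seq_along(newCols)) for (b in seq_along(newCols)) {
      if (a != b && keep[a] && keep[b] &&
          all(newCols[[a]] %in% newCols[[b]]) &&
          (length(newCols[[a]]) < length(newCols[[b]]) || a > b))
        keep[a] <- FALSE
    }
    cols <- newCols[keep]
  }
  # order columns by the best mean they contain, assign letters
  best <- vapply(cols, function(col) min(match(col, lev)), numeric(1))
  cols <- cols[order(best)]
  letterOf <- vapply(seq_along(cols), function(i)
    paste(letters[((i - 1) %% 26) + 1]), character(1))
  lets <- setNames(vapply(lev, function(l) {
    paste(letterOf[vapply(cols, function(col) l %in% col, logical(1))],
          collapse = "")
  }, character(1)), lev)
  structure(list(letters = lets, pMatrix = P, alpha = alpha,
                 means = pw$anova$means[ord], method = method),
            class = "ConnectingLetters")
}

#' @export
print.ConnectingLetters <- function(x, ...) {
  cat(sprintf("Connecting letters (%s, alpha = %g):\n", x$method, x$alpha))
  df <- data.frame(level = names(x$letters),
                   mean = as.numeric(x$means),
                   letters = unname(x$letters))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summarise a modulus grid by a factor
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of the grid entries
#' for each level of the requested factor; with the canonical 24-entry grid
#' each hydration level summarises 12 values.
#'
#' @param grid a [ModulusGrid-class]
#' @param by "hydration", "orientation" or "surface"
#' @return data.frame with level, n, mean, sd (sd is NA for single-entry
#'   levels)
#' @export
summarizeGrid <- function(grid, by = c("hydration", "orientation",
                                       "surface")) {
  stopifnot(is(grid, "ModulusGrid"))
  by <- match.arg(by)
  d <- grid@data
  full <- expand.grid(orientation = unique(d$orientation),
                      hydration = c("hydrated", "unhydrated"),
                      surface = c("Ca", "OH"), stringsAsFactors = FALSE)
  key <- function(x) paste(x$orientation, x$hydration, x$surface)
  missing <- setdiff(key(full), key(d))
  if (length(missing))
    stop("grid is missing entries: ", paste(missing, collapse = "; "))
  lv <- split(d$E, d[[by]])
  data.frame(level = names(lv),
             n = vapply(lv, length, integer(1)),
             mean = vapply(lv, mean, numeric(1)),
             sd = vapply(lv, function(v)
               if (length(v) > 1) sd(v) else NA_real_, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
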