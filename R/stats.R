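#' Per-group mean, standard error and size
#'
#' @param values numeric vector.
#' @param groups grouping labels, same length.
#' @return data.frame with `group`, `n`, `mean`, `sem` (sd/sqrt(n), with the
#'   n-1 sample standard deviation; `NA` when n = 1).
#' @examples
#' groupSummary(c(1, 2, 3, 5, 5, 5), rep(c("a", "b"), each = 3))
#' @export
groupSummary <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  if (anyNA(groups)) stop("groups must not contain NA")
  sp <- split(values, groups)
  if (any(vapply(sp, length, integer(1)) == 0L)) stop("empty group")
  data.frame(
    group = names(sp),
    n = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Unpaired two-tailed t-test
#'
#' Classic equal-variance Student test by default, with a Welch option. The
#' degenerate zero-variance cases are handled explicitly: equal means give
#' t = 0, p = 1; unequal means with zero pooled variance are flagged
#' degenerate (`NaN` statistic, `NA` p).
#'
#' @param a,b numeric samples, each n >= 2.
#' @param welch use Welch's unequal-variance form.
#' @return A [StatResult-class].
#' @examples
#' ttestUnpaired(c(1, 2, 3), c(4, 5, 6))
#' @export
ttestUnpaired <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  method <- if (welch) "Welch two-sample t (two-tailed)"
            else "Student two-sample t, pooled variance (two-tailed)"
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(statResult("t-test", "t", 0, 1, c(length(a), length(b)),
                        method, note = "zero variance, equal means"))
    return(statResult("t-test", "t", NaN, NA_real_,
                      c(length(a), length(b)), method,
                      note = "degenerate: zero variance, unequal means"))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  statResult("t-test", "t", unname(tt$statistic), tt$p.value,
             c(length(a), length(b)), method)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with midrank tie correction; p-value from the chi-squared
#' distribution with k - 1 degrees of freedom. If all values are identical the
#' result is H = 0, p = 1.
#'
#' @param groups list of numeric samples (>= 2 non-empty groups, total
#'   n >= 3).
#' @return A [StatResult-class].
#' @examples
#' kruskalWallis(list(1:3, 4:6, 7:9))  # H = 7.2
#' @export
kruskalWallis <- function(groups) {
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  if (length(groups) < 2L) stop("need >= 2 non-empty groups")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) stop("need total n >= 3")
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(values)) == 1L)
    return(statResult("kruskal-wallis", "H", 0, 1, length(values),
                      "chi-squared approximation, midrank ties",
                      note = "all values identical"))
  kt <- stats::kruskal.test(values, g)
  statResult("kruskal-wallis", "H", unname(kt$statistic), kt$p.value,
             length(values), "chi-squared approximation, midrank ties")
}

## Spearman rho on midranks; snapped to +/-1 when the ranks agree (or
## reverse) exactly, where floating-point correlation can fall 1 ulp short.
spearmanRho <- function(x, y) {
  r <- stats::cor(rank(x), rank(y))
  if (1 - abs(r) < 1e-12) r <- sign(r)
  r
}

#' Spearman rank correlation
#'
#' Rho is computed on midranks (ties share their average rank). The p-value is
#' either the t-distribution approximation (default) or a permutation null:
#' full enumeration of all n! pairings when n <= 8 (exact), otherwise `nPerm`
#' seeded random permutations with the add-one estimator
#' `(1 + #extreme) / (nPerm + 1)`, so sampled p-values lie in
#' `[1/(nPerm+1), 1]`. Two-sided throughout.
#'
#' @param x,y paired numeric samples, n >= 3.
#' @param method `"approx"` or `"permutation"`.
#' @param nPerm random permutations when enumeration is infeasible
#'   (default 10000).
#' @param seed RNG seed for the sampled permutation null.
#' @return A [StatResult-class]; zero variance in either vector gives an `NA`
#'   rho flagged in the note.
#' @examples
#' spearmanCorr(1:6, c(2, 1, 4, 3, 6, 5), method = "permutation")
#' @export
spearmanCorr <- function(x, y, method = c("approx", "permutation"),
                         nPerm = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3L) stop("need n >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(statResult("spearman", "rho", NA_real_, NA_real_, n,
                      method, note = "degenerate: zero variance"))
  rho <- spearmanRho(x, y)
  if (method == "approx") {
    tStat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tStat), df = n - 2))
    return(statResult("spearman", "rho", rho, p, n,
                      "t-distribution approximation (two-sided)"))
  }
  rx <- rank(x)
  ry <- rank(y)
  tol <- 1e-12
  if (n <= 8L) {
    perms <- allPermutations(n)
    rhos <- apply(perms, 1L, function(pp) stats::cor(rx, ry[pp]))
    p <- mean(abs(rhos) >= abs(rho) - tol)
    return(statResult("spearman", "rho", rho, p, n,
                      sprintf("exact permutation (all %d enumerated, two-sided)",
                              nrow(perms))))
  }
  p <- withSeed(seed, {
    extreme <- sum(vapply(seq_len(nPerm), function(i)
      abs(stats::cor(rx, ry[sample.int(n)])) >= abs(rho) - tol,
      logical(1)))
    (1 + extreme) / (nPerm + 1)
  })
  statResult("spearman", "rho", rho, p, n,
             sprintf("sampled permutation (B = %d, two-sided)", nPerm))
}

#' Mixed model for age trend with a repeated-imaging check
#'
#' Fits the linear mixed model `onh_count ~ age_months + (1 | eye_id)` (random
#' per-eye intercept) and returns the age fixed-effect estimate and p-value.
#' A second fit adds `prior_observations` - the number of earlier imaging
#' sessions of the same eye - as a fixed covariate, testing whether repeated
#' imaging itself shifts the counts. When every eye is observed on the same
#' full age grid that covariate is collinear with age and the repeat effect is
#' unidentifiable; it is then returned as `NA` with an explanatory note.
#'
#' @param cohort cohort data.frame with `eye_id`, `age_months`, `onh_count`
#'   (e.g. from [simulateCohort()]); needs >= 2 eyes with >= 2 ages each.
#' @return A list of two [StatResult-class] objects: `age` (slope in counts
#'   per month; the statistic is the slope estimate) and `repeatEffect`.
#' @export
mixedModelAge <- function(cohort) {
  need <- c("eye_id", "age_months", "onh_count")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns ", paste(need, collapse = ", "))
  perEye <- table(cohort$eye_id)
  if (sum(perEye >= 2L) < 2L)
    stop("degenerate design: need >= 2 eyes with >= 2 ages each")
  df <- cohort[order(cohort$eye_id, cohort$age_months), , drop = FALSE]
  df$prior_observations <- stats::ave(
    df$age_months, df$eye_id, FUN = function(a) seq_along(a) - 1)

  fit <- lmerTest::lmer(onh_count ~ age_months + (1 | eye_id), data = df)
  co <- summary(fit)$coefficients
  ageRes <- statResult("mixed-model age slope", "slope",
                       co["age_months", "Estimate"],
                       co["age_months", "Pr(>|t|)"],
                       c(nrow(df), length(unique(df$eye_id))),
                       "linear mixed model, random per-eye intercept (Satterthwaite df)")

  ## identifiability: prior observations must not be collinear with age
  resid <- stats::resid(stats::lm(prior_observations ~ age_months, data = df))
  if (stats::sd(resid) < 1e-8) {
    repRes <- statResult("repeated-imaging effect", "slope", NA_real_,
                         NA_real_, nrow(df),
                         "linear mixed model, random per-eye intercept",
                         note = "unidentifiable: prior observations collinear with age on a full grid")
  } else {
    fit2 <- lmerTest::lmer(
      onh_count ~ age_months + prior_observations + (1 | eye_id), data = df)
    co2 <- summary(fit2)$coefficients
    repRes <- statResult("repeated-imaging effect", "slope",
                         co2["prior_observations", "Estimate"],
                         co2["prior_observations", "Pr(>|t|)"],
                         c(nrow(df), length(unique(df$eye_id))),
                         "linear mixed model, random per-eye intercept (Satterthwaite df)")
  }
  list(age = ageRes, repeatEffect = repRes)
}

#' Early-count predictor for the microgliosis-gliosis correlation
#'
#' One value per eye: the ONH count at 3 months, falling back to the 4-month
#' count when the 3-month visit is missing, paired with the eye's late glial
#' fraction.
#'
#' @param cohort cohort data.frame.
#' @param primaryAge,fallbackAge months (defaults 3 and 4).
#' @return data.frame with `eye_id`, `early_count`, `glial_fraction_pct`
#'   (eyes with neither visit or no outcome are dropped).
#' @export
earlyCountOutcome <- function(cohort, primaryAge = 3, fallbackAge = 4) {
  sp <- split(cohort, cohort$eye_id)
  rows <- lapply(sp, function(df) {
    i <- which(df$age_months == primaryAge)
    if (!length(i)) i <- which(df$age_months == fallbackAge)
    if (!length(i)) return(NULL)
    gl <- df$glial_fraction_pct[1L]
    if (is.na(gl)) return(NULL)
    data.frame(eye_id = df$eye_id[1L], early_count = df$onh_count[i[1L]],
               glial_fraction_pct = gl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(eye_id = character(0), early_count = numeric(0),
                      glial_fraction_pct = numeric(0))
  rownames(out) <- NULL
  out
}

#' Run the cohort statistics battery
#'
#' Reproduces the analysis battery linking early ONH counts to late outcomes:
#' per adjacent-age-pair unpaired t-tests on counts, a per-age Kruskal-Wallis
#' test of counts across late damage categories, the Spearman correlation of
#' the early (3-month, else 4-month) count with the late glial fraction, and
#' the mixed-model age trend with the repeated-imaging check. Raw p-values
#' are reported without multiplicity correction, matching the field's
#' convention for this battery; a Holm-adjusted column (`p_holm`, over the
#' t-test and Kruskal-Wallis family) is additionally emitted for users who
#' want it.
#'
#' @param cohort cohort data.frame (see [simulateCohort()]).
#' @param spearmanMethod `"approx"` or `"permutation"`.
#' @param nPerm,seed permutation options, see [spearmanCorr()].
#' @return data.frame with one row per test: `name`, `statistic_name`,
#'   `statistic`, `p`, `n`, `method`, `p_holm`.
#' @export
cohortStats <- function(cohort, spearmanMethod = c("approx", "permutation"),
                        nPerm = 10000L, seed = 1L) {
  spearmanMethod <- match.arg(spearmanMethod)
  results <- list()
  ages <- sort(unique(cohort$age_months))

  ## adjacent-age t-tests on counts
  if (length(ages) >= 2L) {
    for (i in seq_len(length(ages) - 1L)) {
      a <- cohort$onh_count[cohort$age_months == ages[i]]
      b <- cohort$onh_count[cohort$age_months == ages[i + 1L]]
      if (length(a) >= 2L && length(b) >= 2L) {
        r <- ttestUnpaired(a, b)
        r@name <- sprintf("t-test counts %gmo vs %gmo", ages[i], ages[i + 1L])
        results[[length(results) + 1L]] <- r
      }
    }
  }

  ## per-age Kruskal-Wallis across damage categories
  if ("category" %in% names(cohort)) {
    for (a in ages) {
      sub <- cohort[cohort$age_months == a & !is.na(cohort$category), ]
      gr <- split(sub$onh_count, sub$category)
      gr <- gr[vapply(gr, length, integer(1)) > 0L]
      if (length(gr) >= 2L && sum(lengths(gr)) >= 3L) {
        r <- kruskalWallis(gr)
        r@name <- sprintf("kruskal-wallis counts by category at %gmo", a)
        results[[length(results) + 1L]] <- r
      }
    }
  }
  nFamily <- length(results)

  ## early count vs late glial fraction
  eo <- earlyCountOutcome(cohort)
  if (nrow(eo) >= 3L) {
    r <- spearmanCorr(eo$early_count, eo$glial_fraction_pct,
                      method = spearmanMethod, nPerm = nPerm, seed = seed)
    r@name <- "spearman early count vs late glial fraction"
    results[[length(results) + 1L]] <- r
  }

  ## mixed model
  mm <- tryCatch(mixedModelAge(cohort), error = function(e) NULL)
  if (!is.null(mm)) {
    results[[length(results) + 1L]] <- mm$age
    results[[length(results) + 1L]] <- mm$repeatEffect
  }

  out <- do.call(rbind, lapply(results, function(r) data.frame(
    name = r@name, statistic_name = r@statisticName,
    statistic = r@statistic, p = r@pValue, n = paste(r@n, collapse = "/"),
    method = r@method, stringsAsFactors = FALSE)))
  out$p_holm <- NA_real_
  if (nFamily > 0L)
    out$p_holm[seq_len(nFamily)] <- stats::p.adjust(out$p[seq_len(nFamily)],
                                                    method = "holm")
  out
}
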