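# Outlier screening: generalized ESD (Rosner) test followed by hard caps on
# CO2 and CH4 areal fluxes. N2O is never capped.

#' Rosner's generalized extreme Studentized deviate (ESD) test
#'
#' Detects up to `k_max` outliers in a univariate sample. At step i the
#' statistic R_i = max |x - mean(x)| / sd(x) is computed on the sample with the
#' i-1 most extreme points removed, and compared with the critical value
#'
#'   lambda_i = (n - i) * t / sqrt((n - i - 1 + t^2) * (n - i + 1)),
#'
#' where t is the upper 1 - alpha / (2 (n - i + 1)) quantile of Student's t
#' with n - i - 1 degrees of freedom. The number of outliers is the largest i
#' with R_i > lambda_i; all points removed up to that step are declared
#' outliers (this guards against masking by clustered extremes).
#'
#' @param values Numeric vector, finite.
#' @param alpha Significance level (default 0.05).
#' @param k_max Maximum number of outliers tested (default 10).
#' @return Integer vector of indices into `values` declared outliers (possibly
#'   empty). A zero-variance sample returns `integer(0)`.
#' @export
#' @examples
#' x <- c(rnorm(30), 100)
#' rosner_test(x)
rosner_test <- function(values, alpha = 0.05, k_max = 10L) {
  assert_that(all(is.finite(values)), "values must be finite")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  k_max <- as.integer(k_max)
  assert_that(k_max >= 1L, "k_max must be >= 1")
  n <- length(values)
  assert_that(n >= k_max + 2L,
              sprintf("need at least k_max + 2 = %d values, got %d", k_max + 2L, n))
  if (sd(values) == 0) return(integer(0))

  remaining <- seq_len(n)
  removed <- integer(0)
  R <- numeric(k_max)
  lambda <- numeric(k_max)
  for (i in seq_len(k_max)) {
    x <- values[remaining]
    s <- sd(x)
    if (s == 0) {
      R[i] <- 0
    } else {
      dev <- abs(x - mean(x))
      j <- which.max(dev)
      R[i] <- dev[j] / s
      removed <- c(removed, remaining[j])
      remaining <- remaining[-j]
    }
    ni <- n - i + 1L                      # sample size at this step
    p <- 1 - alpha / (2 * ni)
    tq <- qt(p, df = ni - 2L)
    lambda[i] <- (ni - 1L) * tq / sqrt((ni - 2L + tq^2) * ni)
  }
  n_out <- if (any(R > lambda)) max(which(R > lambda)) else 0L
  sort(removed[seq_len(n_out)])
}

#' Default screening rules
#'
#' One rule per gas: an upper cap in mmol m^-2 day^-1 (CO2: 86827; CH4: 2400;
#' N2O: uncapped) plus the Rosner-test parameters. The caps retain values
#' strictly below the cap; a value equal to the cap is removed and logged.
#'
#' @param alpha Rosner significance level (default 0.05).
#' @param k_max Maximum outliers per pooled sample (default 10).
#' @return Tibble with columns `gas`, `cap`, `alpha`, `k_max`.
#' @export
screening_rules <- function(alpha = 0.05, k_max = 10L) {
  tibble::tibble(
    gas = ghg_gases(),
    cap = c(86827, 2400, NA_real_),
    alpha = alpha,
    k_max = as.integer(k_max)
  )
}

#' Screen a dataset for extreme flux values
#'
#' Applies, per gas and water-body type, Rosner's test on the pooled flux
#' values and then the hard caps. The Rosner step is skipped for pools too
#' small to test (< `k_max` + 2 values). Every removed observation is recorded
#' in the removal log with its reason. Screening is idempotent: screening an
#' already-screened dataset removes nothing.
#'
#' Idempotence is guaranteed by provenance: the screened dataset carries the
#' rule set it was screened under, and re-screening under identical rules is a
#' no-op. (The ESD statistic itself is not a fixpoint operation on
#' heavy-tailed samples, so without the marker a second pass could flag
#' further points of the tail.)
#'
#' @param ds A `ghg_dataset`.
#' @param rules Screening rules as from [screening_rules()].
#' @return A list with `dataset` (screened `ghg_dataset`) and `removals`
#'   (tibble: `site_id`, `date_or_period`, `gas`, `pathway`, `flux`, `reason`).
#' @export
screen_dataset <- function(ds, rules = screening_rules()) {
  stopifnot(inherits(ds, "ghg_dataset"))
  prior <- attr(ds, "screened_rules")
  if (!is.null(prior) && isTRUE(all.equal(prior, rules))) {
    empty <- ds$fluxes[0, c("site_id", "date_or_period", "gas", "pathway", "flux")]
    empty$reason <- character(0)
    return(list(dataset = ds, removals = empty))
  }
  fl <- ds$fluxes
  body_of <- setNames(ds$sites$water_body, ds$sites$site_id)
  fl_body <- body_of[fl$site_id]

  drop <- rep(FALSE, nrow(fl))
  reason <- rep(NA_character_, nrow(fl))

  for (g in rules$gas) {
    rule <- rules[rules$gas == g, ]
    for (wb in ghg_water_bodies()) {
      pool <- which(!drop & fl$gas == g & fl_body == wb)
      if (length(pool) >= rule$k_max + 2L && sd(fl$flux[pool]) > 0) {
        out <- rosner_test(fl$flux[pool], alpha = rule$alpha, k_max = rule$k_max)
        if (length(out) > 0) {
          idx <- pool[out]
          drop[idx] <- TRUE
          reason[idx] <- sprintf("rosner_esd_%s_%s", g, wb)
        }
      }
    }
    if (!is.na(rule$cap)) {
      idx <- which(!drop & fl$gas == g & fl$flux >= rule$cap)
      drop[idx] <- TRUE
      reason[idx] <- sprintf("cap_%s_%g", g, rule$cap)
    }
  }

  removals <- fl[drop, c("site_id", "date_or_period", "gas", "pathway", "flux")]
  removals$reason <- reason[drop]
  screened <- ds
  screened$fluxes <- fl[!drop, ]
  attr(screened, "screened_rules") <- rules
  list(dataset = screened, removals = removals)
}

#' Write a removal log to delimited text
#'
#' @param removals Removal log from [screen_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_removal_log <- function(removals, path) {
  readr::write_csv(removals, path, progress = FALSE)
  invisible(path)
}
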