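# Design-matrix construction, ordinary-least-squares slope fitting,
# permutation p-values and Benjamini-Hochberg step-up FDR.
#
# Model conventions: the tested effect is always the first column of X.
# Continuous effects (time, age) are mean-centred and accompanied by one
# mean-centred nuisance covariate (age or time) plus four gender indicator
# columns; no intercept (it would be a linear combination of the four
# indicators). Categorical gender effects are coded 0/1, not mean-centred,
# and accompanied by an intercept plus mean-centred time and age covariates.

EFFECT_IDS <- c("time", "age", "female_vs_male", "other_vs_fm",
                "pnts_vs_fm")

#' Specification of one tested effect
#'
#' @param effect One of `"time"`, `"age"`, `"female_vs_male"`,
#'   `"other_vs_fm"`, `"pnts_vs_fm"`.
#' @return A list of class `effect_spec`: effect id, the gender identities
#'   admitted by its inclusion filter, nuisance covariates, indicator set
#'   and intercept flag.
#' @export
effect_spec <- function(effect) {
  effect <- match.arg(effect, EFFECT_IDS)
  switch(effect,
    time = list(effect = "time", genders = GENDERS, covariates = "age",
                indicators = GENDERS, intercept = FALSE),
    age = list(effect = "age", genders = GENDERS, covariates = "time",
               indicators = GENDERS, intercept = FALSE),
    female_vs_male = list(effect = "female_vs_male",
                          genders = c("female", "male"),
                          covariates = c("time", "age"),
                          indicators = character(0), intercept = TRUE),
    other_vs_fm = list(effect = "other_vs_fm",
                       genders = c("female", "male", "other"),
                       covariates = c("time", "age"),
                       indicators = character(0), intercept = TRUE),
    pnts_vs_fm = list(effect = "pnts_vs_fm",
                      genders = c("female", "male", "prefer_not_say"),
                      covariates = c("time", "age"),
                      indicators = character(0), intercept = TRUE)
  ) -> spec
  class(spec) <- "effect_spec"
  spec
}

# Raw (uncentred) value of a model variable for each survey row.
model_variable <- function(surveys, var) {
  switch(var,
    time = as.numeric(surveys$year - 2017L),
    age = as.numeric(surveys$age),
    stop("unknown model variable: ", var, call. = FALSE))
}

effect_values <- function(surveys, effect) {
  switch(effect,
    time = ,
    age = model_variable(surveys, effect),
    female_vs_male = as.numeric(surveys$gender == "female"),
    other_vs_fm = as.numeric(surveys$gender == "other"),
    pnts_vs_fm = as.numeric(surveys$gender == "prefer_not_say"))
}

#' Build the model matrix for one effect and one dependent measure
#'
#' Applies the effect's gender inclusion filter and the measure's
#' complete-case filter, then assembles `X` with column order: effect,
#' optional intercept, mean-centred covariates, 0/1 indicator columns.
#' Continuous effects (time coded 0/1/2 for 2017/2018/2019; age in integer
#' years) are mean-centred; categorical effects are left as 0/1.
#'
#' @param surveys Screened surveys (integer `age`, canonical `gender`).
#' @param effect An id accepted by [effect_spec()], or an `effect_spec`.
#' @param y Numeric vector of the dependent measure, aligned with
#'   `surveys` rows; rows with `NA` are dropped (complete-case analysis).
#' @return A list of class `design_matrix`: `X`, `y`, `n`, `effect`,
#'   `centred` (logical per column), `columns` (role labels).
#' @export
build_design <- function(surveys, effect, y) {
  spec <- if (inherits(effect, "effect_spec")) effect else effect_spec(effect)
  stopifnot(length(y) == nrow(surveys))
  keep <- surveys$gender %in% spec$genders & !is.na(y) &
    !is.na(surveys$age) & !is.na(surveys$year)
  surveys <- surveys[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(surveys)
  if (n == 0L) stop("no rows left after filtering", call. = FALSE)

  x <- effect_values(surveys, spec$effect)
  continuous <- spec$effect %in% c("time", "age")
  if (continuous) x <- x - mean(x)

  cols <- list(x)
  roles <- spec$effect
  centred <- continuous
  if (spec$intercept) {
    cols <- c(cols, list(rep(1, n)))
    roles <- c(roles, "intercept")
    centred <- c(centred, FALSE)
  }
  for (v in spec$covariates) {
    vv <- model_variable(surveys, v)
    cols <- c(cols, list(vv - mean(vv)))
    roles <- c(roles, v)
    centred <- c(centred, TRUE)
  }
  for (g in spec$indicators) {
    ind <- as.numeric(surveys$gender == g)
    if (sum(ind) == 0) next              # level absent after filtering
    cols <- c(cols, list(ind))
    roles <- c(roles, paste0("gender_", g))
    centred <- c(centred, FALSE)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- roles
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- roles[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("degenerate design: collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, y = y, n = n, effect = spec$effect,
                 centred = centred, columns = roles),
            class = "design_matrix")
}

#' Fitted slope of the tested effect
#'
#' Returns the first element of the ordinary-least-squares solution
#' `(X'X)^-1 X'y`, i.e. the fitted coefficient of the effect column.
#'
#' @param design A `design_matrix` from [build_design()], or a list with
#'   elements `X` and `y`.
#' @return The scalar fitted slope.
#' @export
fit_slope <- function(design) {
  X <- design$X
  y <- design$y
  beta <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                   error = function(e) {
                     stop("singular normal equations", call. = FALSE)
                   })
  as.numeric(beta[1L])
}

#' Permutation-test configuration
#'
#' @param iterations Number of permutations B (default 100000).
#' @param seed Integer RNG seed.
#' @param scheme Permutation scheme: `"effect"` (default) shuffles the effect
#'   column across rows, leaving dependent variable and nuisance columns
#'   intact; `"freedman_lane"` permutes the residuals of the
#'   nuisance-only fit.
#' @return Named list of class `perm_config`.
#' @export
perm_config <- function(iterations = 100000L, seed = 1L,
                        scheme = c("effect", "freedman_lane")) {
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  structure(list(iterations = iterations, seed = as.integer(seed),
                 scheme = match.arg(scheme)),
            class = "perm_config")
}

#' Two-tailed permutation test on the fitted slope
#'
#' The observed absolute slope is compared against the absolute slopes
#' refitted under `B` random permutations. Under the default scheme the
#' effect column is shuffled across rows while the dependent variable and
#' nuisance columns stay attached to their rows, preserving the
#' y-nuisance relationship under the null of no conditional effect. The
#' p-value is `(r + 1) / (B + 1)` where `r` counts permutations with
#' `|slope*| >= |slope|` (ties count; the minimum attainable p is
#' `1 / (B + 1)`).
#'
#' @param design A `design_matrix` from [build_design()].
#' @param config A `perm_config`.
#' @return A list of class `perm_test`: `beta1`, `p`, `n`, `r`, `perm_sd`
#'   (standard deviation of the permutation slope distribution, i.e. the
#'   null standard error of the slope), `iterations`, `scheme`, `seed`.
#' @export
permutation_test <- function(design, config = perm_config()) {
  X <- design$X
  y <- design$y
  n <- design$n
  B <- config$iterations
  x <- X[, 1L]
  Z <- X[, -1L, drop = FALSE]

  if (ncol(Z) > 0L) {
    qZ <- qr(Z)
    Q <- qr.Q(qZ)                       # thin orthonormal basis of col(Z)
    e_y <- y - Q %*% crossprod(Q, y)
    Mx <- x - Q %*% crossprod(Q, x)
  } else {
    Q <- NULL
    e_y <- y
    Mx <- x
  }
  e_y <- as.numeric(e_y)
  Mx <- as.numeric(Mx)
  ss_x <- sum(x * x)
  denom_obs <- sum(Mx * Mx)
  tol <- 1e-10 * max(ss_x, 1)
  if (denom_obs <= tol) {
    stop("degenerate design: effect column collinear with nuisance columns",
         call. = FALSE)
  }
  beta1 <- sum(Mx * e_y) / denom_obs

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  target <- abs(beta1) * (1 - 1e-12)
  Qt <- if (is.null(Q)) matrix(0, 0L, n) else t(Q)
  cnt <- perm_count_cpp(x, e_y, Qt, ss_x, denom_obs, target, B,
                        config$scheme == "effect", Mx, tol)
  r <- cnt$r
  n_singular <- cnt$n_singular
  if (n_singular > 0.01 * B) {
    stop(sprintf("singular design in %d of %d permutations", n_singular, B),
         call. = FALSE)
  }
  structure(list(beta1 = beta1, p = (r + 1) / (B + 1), n = n, r = r,
                 perm_sd = cnt$perm_sd, iterations = B,
                 scheme = config$scheme, seed = config$seed),
            class = "perm_test")
}

#' Benjamini-Hochberg step-up false-discovery-rate control
#'
#' Standard step-up rule: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' reject all tests with `p <= p_(k*)` where
#' `k* = max{k : p_(k) <= (k/m) * alpha}`. Tied p-values share a fate.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param alpha Target FDR level in (0, 1); default 0.05.
#' @return A list of class `fdr_result`: `rejected` (logical, input order),
#'   `threshold` (largest rejected p, 0 if none), `n_rejected`, `alpha`,
#'   `m`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (m == 0L) stop("empty p-value vector", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  o <- order(pvalues)
  ps <- pvalues[o]
  ok <- which(ps <= (seq_len(m) / m) * alpha)
  if (length(ok) == 0L) {
    threshold <- 0
    rejected <- rep(FALSE, m)
  } else {
    threshold <- ps[max(ok)]
    rejected <- pvalues <= threshold
  }
  structure(list(rejected = rejected, threshold = threshold,
                 n_rejected = sum(rejected), alpha = alpha, m = m),
            class = "fdr_result")
}
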