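# Multiple imputation by chained equations and Rubin's-rules pooling.
#
# The imputation engine cycles regression models over the incomplete
# variables: predictive mean matching (PMM) with Bayesian parameter draws
# for numeric variables (the default; donors are observed values, so skewed
# costs can never be imputed negative and integer scores stay integer) and
# a Bayesian logistic draw for two-level factors. One master seed spawns a
# per-imputation stream so changing m never alters earlier imputations.

# numeric columns for one variable: factors expand to treatment dummies
.var_columns <- function(x, v) {
  if (is.factor(x)) {
    lev <- levels(x)
    m <- outer(as.integer(x), 2:length(lev), function(i, j) as.numeric(i == j))
    colnames(m) <- paste0(v, lev[-1])
    m
  } else {
    m <- matrix(as.numeric(x), ncol = 1)
    colnames(m) <- v
    m
  }
}

# full numeric design matrix built once per dataset; `map` locates each
# variable's column block so imputed values can be written back in place
.design_state <- function(data) {
  vars <- setdiff(names(data), c("id", .flag_cols))
  mats <- lapply(vars, function(v) .var_columns(data[[v]], v))
  idx <- cumsum(vapply(mats, ncol, integer(1)))
  map <- Map(function(hi, nc) seq.int(hi - nc + 1, hi),
             idx, vapply(mats, ncol, integer(1)))
  names(map) <- vars
  list(M = do.call(cbind, mats), map = map)
}

# Bayesian linear draw + predictive mean matching for one variable.
# Ridge eps stabilises near-collinear dummies.
.impute_pmm <- function(y, X, mis, k = 5L, ridge = 1e-6) {
  obs <- !mis
  Xo <- cbind(1, X[obs, , drop = FALSE])
  Xm <- cbind(1, X[mis, , drop = FALSE])
  yo <- y[obs]
  XtX <- crossprod(Xo)
  diag(XtX) <- diag(XtX) * (1 + ridge) + ridge
  V <- chol2inv(chol(XtX))
  beta_hat <- V %*% crossprod(Xo, yo)
  res <- yo - Xo %*% beta_hat
  df <- max(length(yo) - ncol(Xo), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta_star <- beta_hat + t(chol(V * sigma2)) %*% stats::rnorm(ncol(Xo))
  yhat_obs <- drop(Xo %*% beta_hat)
  yhat_mis <- drop(Xm %*% beta_star)
  # donor search: one sort of the observed predictions, then each target
  # considers the 2k-neighbourhood around its insertion point
  k <- min(k, length(yo))
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  yd <- yo[ord]
  n_o <- length(ys)
  pos <- findInterval(yhat_mis, ys)
  vapply(seq_along(yhat_mis), function(i) {
    w <- max(1L, pos[i] - k + 1L):min(n_o, pos[i] + k)
    d <- abs(ys[w] - yhat_mis[i])
    sel <- w[order(d)[seq_len(min(k, length(w)))]]
    yd[sel[sample.int(length(sel), 1L)]]
  }, numeric(1))
}

# Bayesian logistic draw for a two-level factor (returns level index 1/2)
.impute_logreg <- function(y01, X, mis, ridge = 1e-6) {
  obs <- !mis
  Xo <- cbind(1, X[obs, , drop = FALSE])
  fit <- suppressWarnings(
    stats::glm.fit(Xo, y01[obs], family = stats::binomial())
  )
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  w <- fit$weights
  XtWX <- crossprod(Xo * sqrt(pmax(w, 1e-8)))
  diag(XtWX) <- diag(XtWX) * (1 + ridge) + ridge
  V <- chol2inv(chol(XtWX))
  beta_star <- beta + t(chol(V)) %*% stats::rnorm(length(beta))
  p <- stats::plogis(drop(cbind(1, X[mis, , drop = FALSE]) %*% beta_star))
  stats::rbinom(length(p), 1, p)
}

#' Multiple imputation by chained equations
#'
#' Fills the missing cells of a trial table m times by cycling univariate
#' imputation models over the incomplete variables: every other analysis
#' variable predicts each target (full predictor matrix). Numeric variables
#' use predictive mean matching with Bayesian parameter draws; two-level
#' factors use a Bayesian logistic draw. Observed cells are never touched
#' and are bit-identical across the m copies. A table without missing cells
#' yields m identical copies.
#'
#' @param table Trial table (missing cells as `NA`).
#' @param m Number of completed datasets (default 10).
#' @param iterations Chained-equation cycles per dataset (default 10).
#' @param seed Master seed; imputation i runs on stream `seed + i`.
#' @param methods Optional named character vector overriding the per-variable
#'   method (`"pmm"`, `"norm"`, `"logreg"`).
#' @return Object of class `imputation_set`: list with `imputations` (list of
#'   m completed tables), `m`, `iterations`, `seed`, `methods`, `vars`.
#' @export
impute_chained <- function(table, m = 10L, iterations = 10L, seed = 1L,
                           methods = NULL) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  miss_frac <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  if (any(miss_frac == 1))
    stop("variable(s) with 100% missingness cannot be imputed: ",
         paste(names(miss_frac)[miss_frac == 1], collapse = ", "),
         call. = FALSE)
  vars <- names(miss_frac)[miss_frac > 0]
  method_of <- function(v) {
    if (!is.null(methods) && v %in% names(methods)) return(methods[[v]])
    x <- table[[v]]
    if (is.factor(x) && nlevels(x) == 2) "logreg" else "pmm"
  }
  var_methods <- stats::setNames(vapply(vars, method_of, character(1)), vars)

  run_one <- function(i) {
    set.seed(as.integer(seed) + i)
    work <- table
    # initial fill: random draws from the observed values of each variable
    for (v in vars) {
      mis <- is.na(work[[v]])
      work[[v]][mis] <- sample(work[[v]][!mis], sum(mis), replace = TRUE)
    }
    if (length(vars) == 0) return(work)
    st <- .design_state(work)
    for (it in seq_len(iterations)) {
      for (v in vars) {
        mis <- is.na(table[[v]])
        X <- st$M[, -st$map[[v]], drop = FALSE]
        if (var_methods[[v]] == "logreg") {
          drawn <- .impute_logreg(as.integer(work[[v]]) - 1L, X, mis)
          work[[v]][mis] <- levels(table[[v]])[drawn + 1L]
        } else if (var_methods[[v]] == "norm") {
          y <- work[[v]]
          obs <- !mis
          fit <- stats::lm.fit(cbind(1, X[obs, , drop = FALSE]), y[obs])
          beta <- fit$coefficients
          beta[is.na(beta)] <- 0
          sigma <- sqrt(sum(fit$residuals^2) /
                          stats::rchisq(1, max(fit$df.residual, 1)))
          work[[v]][mis] <- drop(cbind(1, X[mis, , drop = FALSE]) %*% beta) +
            stats::rnorm(sum(mis), 0, sigma)
        } else {
          work[[v]][mis] <- .impute_pmm(work[[v]], X, mis)
        }
        st$M[, st$map[[v]]] <- .var_columns(work[[v]], v)
      }
    }
    work
  }
  out <- list(
    imputations = lapply(seq_len(m), run_one),
    m = as.integer(m), iterations = as.integer(iterations),
    seed = as.integer(seed), methods = var_methods, vars = vars
  )
  class(out) <- "imputation_set"
  out
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set:", x$m, "completed datasets,",
      x$iterations, "chained-equation iterations\n")
  if (length(x$vars))
    cat("Imputed variables:", paste(x$vars, collapse = ", "), "\n")
  else cat("Input was complete; copies are identical\n")
  invisible(x)
}

#' Write an imputation set as delimited text plus a manifest
#'
#' One tab-delimited file per completed dataset (`imp_001.tsv`, ...) and a
#' JSON manifest recording seed, m, iterations and the per-variable methods.
#'
#' @param imps An `imputation_set`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_imputation_set <- function(imps, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(imps$m)) {
    utils::write.table(imps$imputations[[i]],
                       file.path(dir, sprintf("imp_%03d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(m = imps$m, iterations = imps$iterations, seed = imps$seed,
         methods = as.list(imps$methods), vars = imps$vars),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Pool a scalar estimate over multiple imputations (Rubin's rules)
#'
#' Point estimate = mean of the m estimates; within-imputation variance W =
#' mean of the variances; between-imputation variance B = sample variance of
#' the estimates; total variance T = W + (1 + 1/m) B. Degrees of freedom use
#' the Barnard--Rubin small-sample formula given the complete-data df; when
#' B = 0 the pooled inference reduces exactly to a single-dataset analysis
#' with df = `dfcom`.
#'
#' @param estimates Numeric vector of m >= 2 per-imputation estimates.
#' @param variances Their squared standard errors (>= 0).
#' @param dfcom Complete-data degrees of freedom (default `Inf`).
#' @return Object of class `pooled_estimate`: `point`, `W`, `B`, `total_var`,
#'   `se`, `df`, `statistic`, `p_two` (two-sided), `p_exceed`
#'   (one-sided P(estimand > 0)), `m`, `degenerate`.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf) {
  m <- length(estimates)
  if (m < 2) stop("pooling needs m >= 2 estimates", call. = FALSE)
  if (length(variances) != m)
    stop("estimates and variances must have equal length", call. = FALSE)
  if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  point <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / m) * B
  degenerate <- total <= 0
  if (degenerate) {
    out <- list(point = point, W = W, B = B, total_var = total, se = 0,
                df = NA_real_, statistic = NA_real_, p_two = NA_real_,
                p_exceed = NA_real_, m = m, degenerate = TRUE)
    class(out) <- "pooled_estimate"
    return(out)
  }
  if (B == 0) {
    df <- dfcom            # no between-imputation variability: single-dataset df
  } else {
    lambda <- (1 + 1 / m) * B / total
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df_old * df_obs / (df_old + df_obs)
    } else df_old
  }
  se <- sqrt(total)
  stat <- point / se
  p_two <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df)
           else 2 * stats::pnorm(-abs(stat))
  p_exceed <- if (is.finite(df)) stats::pt(stat, df) else stats::pnorm(stat)
  out <- list(point = point, W = W, B = B, total_var = total, se = se,
              df = df, statistic = stat, p_two = p_two, p_exceed = p_exceed,
              m = m, degenerate = FALSE)
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Pooled estimate (m = %d): %.*g (SE %.*g), p = %.3g\n",
              x$m, digits, x$point, digits, x$se,
              if (is.na(x$p_two)) NA else x$p_two))
  if (x$degenerate) cat("  [degenerate: total variance is zero]\n")
  invisible(x)
}
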