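# Statistical procedures used throughout the pipeline.  All permutation
# p-values follow the add-one convention (1 + exceedances) / (n_perm + 1),
# so a permutation p-value is never exactly zero.

#' Construct a test result
#'
#' Light container shared by all tests in the package.
#'
#' @param method character tag.
#' @param statistic numeric statistic.
#' @param df degrees of freedom or NULL.
#' @param p_value p-value in \[0, 1\].
#' @param n_perm permutation count or NULL.
#' @param ... extra named fields stored alongside.
#' @return object of class `ovl_test`.
#' @export
test_result <- function(method, statistic, df = NULL, p_value, n_perm = NULL,
                        ...) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = unname(statistic),
                 df = df, p_value = unname(p_value), n_perm = n_perm, ...),
            class = "ovl_test")
}

#' @export
print.ovl_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g%s, p = %.4g%s\n", x$method,
              x$statistic,
              if (!is.null(x$df)) sprintf(", df = %d", x$df) else "",
              x$p_value,
              if (!is.null(x$n_perm))
                sprintf(" (%d permutations)", x$n_perm) else ""))
  invisible(x)
}

#' Yates continuity-corrected chi-square test on a 2x2 table
#'
#' Statistic \eqn{\sum (|O-E| - 0.5)^2 / E} with the correction floored at
#' zero (cells with \eqn{|O-E| < 0.5} contribute nothing), df = 1.
#'
#' @param table 2x2 numeric matrix of non-negative counts.
#' @return an `ovl_test`.
#' @export
yates_chi_square <- function(table) {
  O <- as.matrix(table)
  if (!all(dim(O) == c(2L, 2L))) abort("need a 2x2 table")
  if (any(O < 0)) abort("counts must be non-negative")
  n <- sum(O)
  if (n <= 0) abort("empty table")
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0))
    abort("zero marginal: expected counts undefined")
  E <- outer(rs, cs) / n
  adj <- pmax(abs(O - E) - 0.5, 0)
  stat <- sum(adj^2 / E)
  test_result("yates_chi_square", stat, df = 1L,
              p_value = pchisq(stat, 1, lower.tail = FALSE))
}

#' Spearman rank correlation test
#'
#' Correlation of mid-ranks (ties averaged).  For n <= 10 the p-value is an
#' exact two-sided permutation probability over all n! orderings; larger
#' samples use the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return an `ovl_test` with extra field `rho`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (n < 3L) abort("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) abort("constant input: rho undefined")
  rho <- cor(rx, ry)
  if (n <= 10L) {
    obs <- abs(rho) - 1e-12
    mx <- mean(rx); my <- mean(ry); sx <- sd2(rx); sy <- sd2(ry)
    hits <- 0; total <- 0
    for (pm in perm_chunks(n)) {
      rx_perm <- matrix(rx[pm], nrow(pm), n)  # rx under each permutation
      s <- drop(rx_perm %*% ry)               # sum rx[perm] * ry
      rr <- (s / n - mx * my) / (sx * sy)     # Pearson on permuted ranks
      hits <- hits + sum(abs(rr) >= obs)
      total <- total + nrow(pm)
    }
    p <- hits / total
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  test_result("spearman", rho, df = NULL, p_value = min(p, 1), rho = rho,
              n = n)
}

# population-style sd used to turn permuted cross-products into rho
sd2 <- function(v) sqrt(mean((v - mean(v))^2))

# all permutations of 1..n as row index matrices, chunked over the first
# element for n >= 9 to bound memory (n = 10: ten chunks of 9! rows)
perm_chunks <- function(n) {
  if (n <= 8L) return(list(all_perms_matrix(n)))
  rest <- all_perms_matrix(n - 1L)
  lapply(seq_len(n), function(first) {
    others <- setdiff(seq_len(n), first)
    cbind(first, matrix(others[rest], nrow(rest), n - 1L))
  })
}

all_perms_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    others <- setdiff(seq_len(n), first)
    cbind(first, matrix(others[sub], nrow(sub), n - 1L))
  }))
}

#' Mantel permutation test between two equally shaped matrices
#'
#' Statistic: Pearson correlation of the flattened matrices.  Null
#' distribution: rows of the dependent matrix are permuted `n_perm` times;
#' two-sided p-value with the add-one convention.
#'
#' @param dep,indep numeric matrices of identical shape.
#' @param n_perm number of row permutations (>= 99).
#' @param seed integer seed for reproducibility (optional).
#' @return an `ovl_test` with extra field `r`.
#' @export
mantel_test <- function(dep, indep, n_perm = 999L, seed = NULL) {
  dep <- as.matrix(dep); indep <- as.matrix(indep)
  if (!all(dim(dep) == dim(indep))) abort("matrices must share a shape")
  if (n_perm < 99L) abort("n_perm must be >= 99")
  v_dep <- as.vector(dep); v_ind <- as.vector(indep)
  if (sd(v_dep) == 0 || sd(v_ind) == 0)
    abort("correlation undefined: zero-variance matrix")
  r_obs <- cor(v_dep, v_ind)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      cor(as.vector(dep[sample.int(nrow(dep)), , drop = FALSE]), v_ind)
    }, numeric(1))
  })
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  test_result("mantel", r_obs, p_value = p, n_perm = as.integer(n_perm),
              r = r_obs, seed = seed)
}

#' Multi-matrix Mantel regression
#'
#' Multiple linear regression of the flattened dependent matrix on the
#' flattened predictor matrices; per-predictor significance by permuting
#' the rows of the dependent matrix and refitting.
#'
#' @param dep dependent matrix.
#' @param indeps list of predictor matrices (same shape as `dep`).
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list with `coefficients` (incl. intercept), `p_perm` (one per
#'   predictor), `r_squared`, `n_perm`, `seed`.
#' @export
multi_mantel <- function(dep, indeps, n_perm = 999L, seed = NULL) {
  dep <- as.matrix(dep)
  if (!is.list(indeps)) indeps <- list(indeps)
  X <- cbind(intercept = 1, sapply(indeps, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == dim(dep))) abort("matrices must share a shape")
    as.vector(m)
  }))
  if (is.null(names(indeps)))
    colnames(X) <- c("intercept", paste0("X", seq_along(indeps)))
  else colnames(X) <- c("intercept", names(indeps))
  y <- as.vector(dep)
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, y)
  fit <- qr.fitted(qr_x, y)
  r2 <- if (sd(y) > 0) 1 - sum((y - fit)^2) / sum((y - mean(y))^2) else NA
  slopes <- beta[-1L]
  exceed <- rep(0L, length(slopes))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      yp <- as.vector(dep[sample.int(nrow(dep)), , drop = FALSE])
      bp <- qr.coef(qr_x, yp)[-1L]
      exceed <- exceed + (abs(bp) >= abs(slopes) - 1e-12)
    }
  })
  list(coefficients = beta,
       p_perm = setNames((1 + exceed) / (n_perm + 1), names(slopes)),
       r_squared = r2, n_perm = as.integer(n_perm), seed = seed)
}

#' Binary logit regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression with Wald standard errors from
#' the observed information.  Perfect or quasi-separation is flagged (the
#' fit is returned with `converged = FALSE` and `separated = TRUE`), never
#' silently reported as converged.
#'
#' @param x design matrix (without intercept column) or a `dnds_table`, in
#'   which case the four rate columns are the predictors and
#'   `overlap_status` the outcome.
#' @param y binary outcome vector (ignored when `x` is a `dnds_table`).
#' @param max_iter,tol IRLS iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return object of class `logit_fit`: coefficients, `se`, `z`,
#'   `p_value` (Wald), `log_lik`, `converged`, `separated`, `iterations`.
#' @export
logit_fit <- function(x, y = NULL, max_iter = 100L, tol = 1e-10) {
  if (inherits(x, "dnds_table")) {
    y <- x$overlap_status
    x <- as.matrix(x[, c("gene1_dS", "gene1_dN", "gene2_dS", "gene2_dN")])
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (length(y) != nrow(x)) abort("x and y dimensions disagree")
  if (nrow(x) < 6L) abort("need at least 6 observations")
  if (!all(y %in% c(0, 1))) abort("y must be 0/1")
  if (length(unique(y)) < 2L) abort("both outcome classes must be present")
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  beta <- rep(0, p)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    # log(1 + e^eta) computed overflow-safely
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  ll <- loglik(beta)
  ll_trace <- ll
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XtWX <- crossprod(X * w, X)
    score <- crossprod(X, y - mu)
    step <- tryCatch(drop(solve(XtWX, score)), error = function(e) NULL)
    if (is.null(step)) break
    # step halving keeps the likelihood non-decreasing
    lam <- 1
    repeat {
      ll_new <- loglik(beta + lam * step)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    beta <- beta + lam * step
    ll_new <- loglik(beta)
    ll_trace <- c(ll_trace, ll_new)
    if (abs(ll_new - ll) < tol * (abs(ll_new) + tol)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  ll <- loglik(beta)
  separated <- max(abs(beta)) > 15 ||
    all(abs(mu - y) < 1e-8)
  if (separated) converged <- FALSE
  info <- crossprod(X * (mu * (1 - mu)), X)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e)
    rep(NA_real_, p))
  z <- beta / se
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 se = setNames(se, colnames(X)),
                 z = setNames(z, colnames(X)),
                 p_value = setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
                 log_lik = ll, ll_trace = ll_trace,
                 converged = converged, separated = separated,
                 iterations = it, n = nrow(X)),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> n = %d, logLik = %.4f, converged = %s%s\n",
              x$n, x$log_lik, x$converged,
              if (x$separated) " [SEPARATION FLAGGED]" else ""))
  print(data.frame(coef = x$coefficients, se = x$se, z = x$z,
                   p = x$p_value))
  invisible(x)
}

#' Likelihood-ratio test between nested models
#'
#' @param ll_null,ll_alt log-likelihoods of the null and alternative model.
#' @param df difference in free parameters.
#' @return an `ovl_test`; the statistic 2(ll_alt - ll_null) is clipped at 0.
#' @export
likelihood_ratio_test <- function(ll_null, ll_alt, df) {
  stat <- max(0, 2 * (ll_alt - ll_null))
  test_result("likelihood_ratio", stat, df = as.integer(df),
              p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Average-linkage hierarchical clustering under city-block distance
#'
#' Agglomerative clustering of matrix rows with Manhattan (city-block)
#' distance and average linkage (UPGMA).
#'
#' @param m numeric matrix; rows are clustered.
#' @return an [stats::hclust] object.
#' @export
hcluster_cityblock <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) abort("need at least two rows")
  hclust(dist(m, method = "manhattan"), method = "average")
}

#' Write a set of test results as a TSV report
#'
#' @param tests named list of `ovl_test` objects.
#' @param path output file.
#' @param seed seed recorded with every row (optional).
#' @export
write_test_report <- function(tests, path, seed = NA) {
  df <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(name = nm, method = t$method, statistic = t$statistic,
               df = t$df %||% NA, p_value = t$p_value,
               n_perm = t$n_perm %||% NA, seed = seed,
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
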