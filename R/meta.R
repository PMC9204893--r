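#' Per-arm odds ratio of pCR, non-LAR versus LAR
#'
#' `OR = (nonlar_yes * lar_no) / (nonlar_no * lar_yes)`, vectorized over arms.
#' With `zero_cell = "haldane"`, 0.5 is added to every cell of an arm only
#' when that arm has a zero cell; with `"none"` a zero denominator is an
#' error.
#'
#' @param arms an `arm_table` (see [arm_table()]).
#' @param zero_cell `"none"` or `"haldane"`.
#' @return numeric vector of odds ratios, one per arm.
#' @export
arm_odds_ratio <- function(arms, zero_cell = c("none", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  cells <- as.matrix(arms[, c("lar_yes", "lar_no", "nonlar_yes", "nonlar_no")])
  if (zero_cell == "haldane") {
    has_zero <- rowSums(cells == 0) > 0
    cells[has_zero, ] <- cells[has_zero, ] + 0.5
  } else if (any(cells[, "lar_yes"] == 0 | cells[, "nonlar_no"] == 0)) {
    stop("zero cell in denominator; use zero_cell = \"haldane\"")
  }
  unname((cells[, "nonlar_yes"] * cells[, "lar_no"]) /
           (cells[, "nonlar_no"] * cells[, "lar_yes"]))
}

#' Per-arm pCR rate summary
#'
#' Percent pCR by group per arm, group-wise ranges, and the number of arms in
#' which the non-LAR rate strictly exceeds the LAR rate.
#'
#' Alongside the all-arm ranges, ranges restricted to the arms where the
#' non-LAR rate strictly exceeds the LAR rate are reported (`*_range_exceed`),
#' the form in which such ranges are usually quoted for concordant arms.
#'
#' @param arms an `arm_table`.
#' @return list with `per_arm` (data.frame: trial, arm, lar_pct, nonlar_pct),
#'   `lar_range`, `nonlar_range`, `lar_range_exceed`, `nonlar_range_exceed`
#'   and `n_nonlar_higher`.
#' @export
rate_summary <- function(arms) {
  lar_pct <- 100 * arms$lar_yes / (arms$lar_yes + arms$lar_no)
  non_pct <- 100 * arms$nonlar_yes / (arms$nonlar_yes + arms$nonlar_no)
  higher <- non_pct > lar_pct
  list(per_arm = data.frame(trial = arms$trial, arm = arms$arm,
                            lar_pct = lar_pct, nonlar_pct = non_pct),
       lar_range = range(lar_pct), nonlar_range = range(non_pct),
       lar_range_exceed = if (any(higher)) range(lar_pct[higher]) else c(NA, NA),
       nonlar_range_exceed = if (any(higher)) range(non_pct[higher]) else c(NA, NA),
       n_nonlar_higher = sum(higher))
}

# Gauss-Hermite nodes/weights for weight exp(-x^2), by Golub-Welsch
gauss_hermite <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1L, ]^2)
}

# joint log-density of one arm's data and random effects (u, v)
arm_logjoint <- function(u, v, b0, bL, su, sv, yL, nL, yN, nN) {
  e1 <- b0 + u
  e2 <- b0 + u + bL + v
  yL * e1 - nL * log1p(exp(e1)) + yN * e2 - nN * log1p(exp(e2)) -
    u^2 / (2 * su^2) - log(su) - v^2 / (2 * sv^2) - log(sv) - log(2 * pi)
}

# Newton mode search of arm_logjoint in (u, v); always concave
arm_mode <- function(b0, bL, su, sv, yL, nL, yN, nN) {
  u <- 0; v <- 0
  for (it in 1:50) {
    p1 <- stats::plogis(b0 + u)
    p2 <- stats::plogis(b0 + u + bL + v)
    g <- c(yL - nL * p1 + yN - nN * p2 - u / su^2,
           yN - nN * p2 - v / sv^2)
    w1 <- nL * p1 * (1 - p1); w2 <- nN * p2 * (1 - p2)
    H <- -matrix(c(w1 + w2 + 1 / su^2, w2, w2, w2 + 1 / sv^2), 2, 2)
    step <- solve(H, g)
    u <- u - step[1L]; v <- v - step[2L]
    if (max(abs(step)) < 1e-10) break
  }
  p1 <- stats::plogis(b0 + u)
  p2 <- stats::plogis(b0 + u + bL + v)
  w1 <- nL * p1 * (1 - p1); w2 <- nN * p2 * (1 - p2)
  list(u = u, v = v,
       H = -matrix(c(w1 + w2 + 1 / su^2, w2, w2, w2 + 1 / sv^2), 2, 2))
}

# log marginal likelihood of one arm by adaptive 2-D Gauss-Hermite quadrature
arm_loglik <- function(b0, bL, su, sv, yL, nL, yN, nN, gh) {
  cst <- lchoose(nL, yL) + lchoose(nN, yN)
  m <- arm_mode(b0, bL, su, sv, yL, nL, yN, nN)
  A <- solve(chol(-m$H))            # (-H)^{-1} = A %*% t(A)
  q <- length(gh$x)
  xg <- expand.grid(x1 = gh$x, x2 = gh$x)
  z <- sqrt(2) * as.matrix(xg) %*% t(A)
  u <- m$u + z[, 1L]; v <- m$v + z[, 2L]
  lw <- log(rep(gh$w, q)) + log(rep(gh$w, each = q)) + xg$x1^2 + xg$x2^2 +
    arm_logjoint(u, v, b0, bL, su, sv, yL, nL, yN, nN)
  mx <- max(lw)
  cst + log(2) + sum(log(diag(A))) + mx + log(sum(exp(lw - mx)))
}

#' Random-effects logit meta-analysis of pCR across treatment arms
#'
#' Fits, by maximum marginal likelihood, the model in which arm i's LAR
#' response probability is `plogis(b0 + u_i)` and its non-LAR probability is
#' `plogis(b0 + u_i + bL + v_i)`, with independent arm-level random effects
#' `u_i ~ N(0, sigma_u^2)` (baseline) and `v_i ~ N(0, sigma_v^2)` (group
#' effect). The marginal likelihood factors over arms; each arm's 2-D integral
#' is evaluated by adaptive Gauss-Hermite product quadrature recentered at the
#' arm's posterior mode. The pooled odds ratio is `exp(bL)` with a Wald 95% CI
#' from the observed information, computed on the log scale and exponentiated.
#'
#' @param arms an `arm_table` with at least 3 arms (unless both variance
#'   components are fixed).
#' @param quad_points Gauss-Hermite nodes per dimension.
#' @param max_iter optimizer iteration cap.
#' @param tol relative convergence tolerance passed to the optimizer.
#' @param fix_sigma_u,fix_sigma_v optionally fix a variance component (e.g. 0
#'   for a common-effect fit); `NULL` means estimate it.
#' @return object of class `relogit_meta`; see [print.relogit_meta()]. Key
#'   fields: `b0`, `bL`, `sigma_u`, `sigma_v`, `or`, `ci` (95% Wald on the
#'   OR), `se_bL`, `loglik`, `convergence` (`TRUE` when the optimizer
#'   converged), `boundary` (variance component pinned at 0), `per_arm_or`.
#' @export
fit_random_effects_logit <- function(arms, quad_points = 15, max_iter = 500,
                                     tol = 1e-10, fix_sigma_u = NULL,
                                     fix_sigma_v = NULL) {
  stopifnot(inherits(arms, "data.frame"))
  free_u <- is.null(fix_sigma_u); free_v <- is.null(fix_sigma_v)
  if (nrow(arms) < 3L && (free_u || free_v))
    stop("need >= 3 arms to identify the variance components")
  yL <- arms$lar_yes; nL <- arms$lar_yes + arms$lar_no
  yN <- arms$nonlar_yes; nN <- arms$nonlar_yes + arms$nonlar_no
  gh <- gauss_hermite(quad_points)
  lo_ls <- log(1e-4)                 # sigma floor: effectively zero
  hi_ls <- log(20)

  nll <- function(th) {
    b0 <- th[1L]; bL <- th[2L]
    i <- 3L
    su <- if (free_u) exp(th[i]) else fix_sigma_u
    if (free_u) i <- i + 1L
    sv <- if (free_v) exp(th[i]) else fix_sigma_v
    su_eff <- max(su, 1e-6); sv_eff <- max(sv, 1e-6)
    ll <- sum(vapply(seq_along(yL), function(a)
      arm_loglik(b0, bL, su_eff, sv_eff, yL[a], nL[a], yN[a], nN[a], gh), 0))
    if (!is.finite(ll)) 1e10 else -ll
  }

  # starting values from the pooled fixed-effects logistic fit
  pL <- (sum(yL) + 0.5) / (sum(nL) + 1)
  pN <- (sum(yN) + 0.5) / (sum(nN) + 1)
  start <- c(stats::qlogis(pL), stats::qlogis(pN) - stats::qlogis(pL))
  lower <- c(-20, -20); upper <- c(20, 20)
  if (free_u) { start <- c(start, log(0.5)); lower <- c(lower, lo_ls)
                upper <- c(upper, hi_ls) }
  if (free_v) { start <- c(start, log(0.5)); lower <- c(lower, lo_ls)
                upper <- c(upper, hi_ls) }
  opt <- stats::optim(start, nll, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = max_iter, factr = tol / 1e-15))
  th <- opt$par
  b0 <- th[1L]; bL <- th[2L]
  i <- 3L
  su <- if (free_u) exp(th[i]) else fix_sigma_u
  if (free_u) i <- i + 1L
  sv <- if (free_v) exp(th[i]) else fix_sigma_v
  boundary <- c(sigma_u = free_u && th[3L] <= lo_ls + 1e-6,
                sigma_v = free_v && th[length(th)] <= lo_ls + 1e-6)

  H <- tryCatch(stats::optimHess(th, nll), error = function(e) NULL)
  se_bL <- NA_real_
  if (!is.null(H)) {
    vc <- tryCatch(solve(H), error = function(e) pracma::pinv(H))
    if (vc[2L, 2L] > 0) se_bL <- sqrt(vc[2L, 2L])
  }
  ci <- exp(bL + c(-1, 1) * stats::qnorm(0.975) * se_bL)
  structure(list(b0 = b0, bL = bL,
                 sigma_u = if (boundary["sigma_u"]) 0 else su,
                 sigma_v = if (boundary["sigma_v"]) 0 else sv,
                 or = exp(bL), ci = ci, se_bL = se_bL,
                 loglik = -opt$value,
                 convergence = opt$convergence == 0L,
                 boundary = boundary,
                 per_arm_or = arm_odds_ratio(arms, zero_cell = "haldane"),
                 n_arms = nrow(arms), quad_points = quad_points),
            class = "relogit_meta")
}

#' @export
#' @rdname fit_random_effects_logit
#' @param x,object a `relogit_meta` fit.
#' @param ... unused.
print.relogit_meta <- function(x, ...) {
  cat(sprintf("random-effects logit meta-analysis over %d arms\n", x$n_arms))
  cat(sprintf("pooled OR (non-LAR vs LAR) = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$or, x$ci[1L], x$ci[2L]))
  cat(sprintf("b0 = %.3f, bL = %.3f (SE %.3f), sigma_u = %.3f, sigma_v = %.3f\n",
              x$b0, x$bL, x$se_bL, x$sigma_u, x$sigma_v))
  cat(sprintf("log-likelihood %.3f, converged: %s%s\n", x$loglik,
              x$convergence,
              if (any(x$boundary)) " (variance component at boundary)" else ""))
  invisible(x)
}

#' @export
#' @rdname fit_random_effects_logit
coef.relogit_meta <- function(object, ...)
  c(b0 = object$b0, bL = object$bL, sigma_u = object$sigma_u,
    sigma_v = object$sigma_v)

#' @export
#' @rdname fit_random_effects_logit
summary.relogit_meta <- function(object, ...) {
  out <- data.frame(
    estimate = c(object$b0, object$bL, object$sigma_u, object$sigma_v,
                 object$or),
    row.names = c("b0", "bL", "sigma_u", "sigma_v", "OR"))
  print(object)
  invisible(out)
}

#' Exact test of independence for an r x 2 contingency table
#'
#' 2 x 2 tables use the two-sided exact hypergeometric test (summing tables no
#' more probable than the observed one). Larger tables are tested by complete
#' enumeration when the total count is at most 500, otherwise by Monte Carlo
#' with at least `1e5` draws under a fixed seed.
#'
#' @param table matrix of non-negative counts, r rows x 2 columns.
#' @param mc_draws Monte Carlo draws for large tables.
#' @param seed RNG seed for the Monte Carlo branch.
#' @return the p-value.
#' @export
contingency_exact_test <- function(table, mc_draws = 1e5, seed = 1) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative counts")
  if (nrow(table) < 2L || ncol(table) != 2L) stop("need an r x 2 table, r >= 2")
  if (nrow(table) == 2L || sum(table) <= 500) {
    stats::fisher.test(table)$p.value
  } else {
    restore <- local_seed(seed); on.exit(restore())
    stats::fisher.test(table, simulate.p.value = TRUE,
                       B = max(mc_draws, 1e5))$p.value
  }
}
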