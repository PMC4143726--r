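#' Censored normal regression of one exam with pedigree random intercepts
#'
#' Fits, by maximum likelihood, the model
#' \deqn{Y_{pi} = x_{pi}'\beta + u_p + \varepsilon_{pi},\qquad
#'   u_p \sim N(0, \tau^2),\ \varepsilon_{pi} \sim N(0, \sigma^2),}
#' to one exam's systolic blood pressure measurements, where an individual
#' on antihypertensive medication contributes a right-censoring survival
#' term \eqn{P(Y > y_{obs})} (the underlying untreated value exceeds the
#' observed one; censoring is assumed noninformative) and an unmedicated
#' individual contributes the usual density term.  The pedigree random
#' intercept is integrated out by adaptive Gauss-Hermite quadrature
#' (posterior mode and curvature per pedigree).  Covariates are sex,
#' exam-specific age and smoking status.
#'
#' @param records data.frame with columns `id`, `exam`, `sbp` (mmHg), `age`
#'   (years), `sex` (`"male"`/`"female"` or 1/2), `smoke` (`"yes"`/`"no"`,
#'   logical or 0/1), `med` (medication / censoring indicator, same
#'   codings), and either a `fam` column or `fam_map`; all rows must share
#'   one exam index.
#' @param fam_map optional named character vector mapping individual ID to
#'   family ID, used when `records` has no `fam` column.
#' @param quad_points Gauss-Hermite order (default 20).
#' @param restarts random restarts on non-convergence (default 3).
#' @return A `censored_fit`: list with `coefficients` (intercept, sexmale,
#'   age, smokeyes; mmHg per unit), `sigma`, `tau` (mmHg), `ranef`
#'   (per-pedigree posterior modes), `loglik`, `convergence`,
#'   `boundary_tau`, `n`, `n_censored`, `exam`.
#' @export
fit_censored_exam <- function(records, fam_map = NULL, quad_points = 20,
                              restarts = 3) {
  rec <- normalize_exam_records(records, fam_map)
  if (length(unique(rec$exam)) > 1L)
    stop("fit_censored_exam expects records from a single exam; got exams ",
         paste(sort(unique(rec$exam)), collapse = ", "))
  X <- cbind(intercept = 1, sexmale = rec$male, age = rec$age,
             smokeyes = rec$smoke)
  if (qr(X)$rank < ncol(X))
    stop("design matrix (intercept, sex, age, smoking) is rank deficient")
  fam <- factor(rec$fam)
  P <- nlevels(fam)
  if (P < 2) stop("censored mixed fit requires records from >= 2 pedigrees")
  pidx <- as.integer(fam)
  y <- rec$y
  cens <- rec$cens
  gh <- pracma::gaussHermite(quad_points)
  npar <- ncol(X)

  u_warm <- numeric(P)   # warm-started posterior modes across evaluations
  nll <- function(par) {
    beta <- par[1:npar]
    sig <- exp(par[npar + 1])
    tau <- exp(par[npar + 2])
    r0 <- as.numeric(y - X %*% beta)
    post <- ceh_posterior_modes(r0, cens, pidx, P, sig, tau, u0 = u_warm)
    if (is.null(post)) return(1e10)
    u_warm <<- post$u
    -sum(ceh_gh_loglik(r0, cens, pidx, P, sig, tau, post$u, post$shat, gh))
  }

  ols <- stats::lm.fit(X, y)
  sig0 <- max(sd(ols$residuals), 1e-3)
  fmean <- tapply(ols$residuals, fam, mean)
  tau0 <- max(sd(fmean), 0.05 * sig0)
  start <- c(ols$coefficients, log(sig0), log(tau0))
  lower <- c(rep(-Inf, npar), log(sig0) - 8, log(sig0) - 10)

  best <- NULL
  for (r in 0:restarts) {
    st <- if (r == 0) start else
      start + c(rnorm(npar, 0, 0.2 * sig0), rnorm(2, 0, 0.3))
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B", lower = lower,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
    if (!is.null(best) && best$convergence == 0 && r == 0) break
  }
  if (is.null(best) || !is.finite(best$value))
    stop("censored mixed model failed to converge after ", restarts,
         " restarts")
  # polish: quasi-Newton without bounds tightens the flat directions
  pol <- tryCatch(
    stats::optim(best$par, nll, method = "BFGS",
                 control = list(maxit = 50, reltol = 1e-13)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value <= best$value &&
      pol$par[npar + 2] >= lower[npar + 2]) {
    pol$convergence <- best$convergence
    best <- pol
  }
  par <- best$par
  beta <- par[1:npar]
  names(beta) <- colnames(X)
  sig <- exp(par[npar + 1])
  tau <- exp(par[npar + 2])
  boundary <- par[npar + 2] <= lower[npar + 2] + 1e-6
  r0 <- as.numeric(y - X %*% beta)
  post <- ceh_posterior_modes(r0, cens, pidx, P, sig, tau)
  ranef <- setNames(post$u, levels(fam))
  structure(list(coefficients = beta, sigma = sig,
                 tau = if (boundary) 0 else tau,
                 ranef = ranef, loglik = -best$value,
                 convergence = best$convergence, boundary_tau = boundary,
                 n = length(y), n_censored = sum(cens),
                 exam = unique(rec$exam)),
            class = "censored_fit")
}

#' @export
print.censored_fit <- function(x, ...) {
  cat("Censored normal mixed fit (exam ", x$exam, "): n = ", x$n, " (",
      x$n_censored, " censored), logLik = ", format(x$loglik), "\n", sep = "")
  print(round(x$coefficients, 4))
  cat("sigma =", round(x$sigma, 4), " tau =", round(x$tau, 4),
      if (x$boundary_tau) "(boundary)", "\n")
  invisible(x)
}

# Newton posterior modes of the pedigree random intercepts, vectorised over
# pedigrees; returns modes and Laplace sd, or NULL on numerical failure
ceh_posterior_modes <- function(r0, cens, pidx, P, sig, tau, maxit = 40,
                                u0 = NULL) {
  u <- if (is.null(u0)) numeric(P) else u0
  for (it in seq_len(maxit)) {
    z <- (r0 - u[pidx]) / sig
    g1 <- z / sig
    g2 <- rep(-1 / sig^2, length(z))
    if (any(cens)) {
      zc <- z[cens]
      lam <- exp(dnorm(zc, log = TRUE) -
                   pnorm(zc, lower.tail = FALSE, log.p = TRUE))
      g1[cens] <- lam / sig
      g2[cens] <- -lam * (lam - zc) / sig^2
    }
    G1 <- rowsum(g1, pidx)[, 1] - u / tau^2
    G2 <- rowsum(g2, pidx)[, 1] - 1 / tau^2
    if (any(!is.finite(G1)) || any(!is.finite(G2)) || any(G2 >= 0))
      return(NULL)
    step <- G1 / G2
    step <- pmax(pmin(step, 3 * sig), -3 * sig)   # damped Newton
    u <- u - step
    if (max(abs(step)) < 1e-9 * sig) break
  }
  list(u = u, shat = sqrt(-1 / G2))
}

# per-pedigree log marginal likelihood by adaptive Gauss-Hermite quadrature
ceh_gh_loglik <- function(r0, cens, pidx, P, sig, tau, u, shat, gh) {
  K <- length(gh$x)
  # nodes: P x K matrix of random-effect values, expanded to records
  U <- u + sqrt(2) * outer(shat, gh$x)
  Z <- (r0 - U[pidx, , drop = FALSE]) / sig
  L <- -0.91893853320467267 - 0.5 * Z * Z - log(sig)   # normal log-density
  if (any(cens))
    L[cens, ] <- pnorm(Z[cens, , drop = FALSE], lower.tail = FALSE,
                       log.p = TRUE)
  H <- rowsum(L, pidx) -   # rows sorted by pedigree index 1..P
    (0.91893853320467267 + log(tau) + 0.5 * (U / tau)^2)
  lg <- sweep(H, 2, log(gh$w) + gh$x^2, "+")
  m <- lg[cbind(seq_len(P), max.col(lg, ties.method = "first"))]
  m + log(rowSums(exp(lg - m))) + 0.5 * log(2) + log(shat)
}

#' Conditional expectation of a right-censored normal observation
#'
#' For an individual under medication the observed value is a lower bound on
#' the underlying trait; assuming \eqn{Y \sim N(\mu, \sigma^2)}, the
#' expected underlying value is
#' \deqn{Y^* = E[Y \mid Y > y_{obs}] = \mu + \sigma
#'   \frac{\phi(\alpha)}{1 - \Phi(\alpha)},\qquad
#'   \alpha = (y_{obs} - \mu)/\sigma,}
#' which always exceeds `y_obs`.  `mu` should include covariate effects and
#' the pedigree random effect (posterior mode).  For `alpha` beyond
#' `alpha_max` the inverse Mills ratio is replaced by its asymptotic form
#' `alpha + 1/alpha` with a warning (numerically degenerate tail).
#'
#' @param y_obs,mu,sigma numeric vectors (mmHg); `sigma > 0`.
#' @param alpha_max tail clipping bound (default 30).
#' @return `Y*`, same length as `y_obs`.
#' @export
conditional_expectation_censored <- function(y_obs, mu, sigma,
                                             alpha_max = 30) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  alpha <- (y_obs - mu) / sigma
  mills <- exp(dnorm(alpha, log = TRUE) -
                 pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
  clip <- alpha > alpha_max
  if (any(clip)) {
    warning(sum(clip), " observation(s) beyond the alpha_max tail bound; ",
            "inverse Mills ratio clipped to its asymptote")
    mills[clip] <- alpha[clip] + 1 / alpha[clip]
  }
  mu + sigma * mills
}

#' Build the adjusted phenotype R from per-exam censored fits
#'
#' For each exam in 1..3, residuals are `Y - Yhat` for unmedicated records
#' and `Y* - Yhat` for medicated ones, where `Yhat` is the fitted value from
#' covariates plus the pedigree random-effect posterior mode and `Y*` is the
#' censoring-corrected conditional expectation.  The adjusted phenotype `R`
#' is the mean residual over the exams (among 1..3) at which the individual
#' was measured; exam 4 is ignored; individuals with no exam in 1..3 are
#' excluded and listed in the `skipped` attribute.
#'
#' @param fits named list of `censored_fit` objects, names = exam indices.
#' @param records the full exam record table (see [fit_censored_exam]).
#' @inheritParams fit_censored_exam
#' @param exams exams to average over (default `1:3`).
#' @return data.frame with columns `id`, `R`, `n_exams_used`; attribute
#'   `skipped` lists excluded individuals.
#' @export
build_adjusted_phenotype <- function(fits, records, fam_map = NULL,
                                     exams = 1:3) {
  rec <- normalize_exam_records(records, fam_map)
  keep <- rec$exam %in% exams
  need <- sort(unique(rec$exam[keep]))
  miss <- setdiff(as.character(need), names(fits))
  if (length(miss))
    stop("no censored fit supplied for exam(s) ", paste(miss, collapse = ", "))
  res <- rep(NA_real_, nrow(rec))
  for (e in need) {
    f <- fits[[as.character(e)]]
    sel <- which(rec$exam == e)
    X <- cbind(1, rec$male[sel], rec$age[sel], rec$smoke[sel])
    u <- f$ranef[rec$fam[sel]]
    u[is.na(u)] <- 0
    yhat <- as.numeric(X %*% f$coefficients) + u
    r <- rec$y[sel] - yhat
    if (any(rec$cens[sel])) {
      ci <- sel[rec$cens[sel]]
      ystar <- conditional_expectation_censored(rec$y[ci],
                                                yhat[rec$cens[sel]], f$sigma)
      r[rec$cens[sel]] <- ystar - yhat[rec$cens[sel]]
    }
    res[sel] <- r
  }
  used <- keep & !is.na(res)
  agg <- tapply(res[used], rec$id[used], mean)
  cnt <- tapply(res[used], rec$id[used], length)
  out <- data.frame(id = names(agg), R = as.numeric(agg),
                    n_exams_used = as.integer(cnt), stringsAsFactors = FALSE)
  skipped <- setdiff(unique(rec$id), out$id)
  attr(out, "skipped") <- skipped
  out
}

#' Write / read adjusted phenotypes and fit reports
#' @param adj data.frame from [build_adjusted_phenotype].
#' @param path output CSV path.
#' @export
write_adjusted_phenotype <- function(adj, path) {
  utils::write.table(adj, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjusted_phenotype
#' @param fits named list of `censored_fit` objects.
#' @export
write_fit_report <- function(fits, path) {
  rep <- lapply(fits, function(f)
    list(coefficients = as.list(f$coefficients), sigma = f$sigma,
         tau = f$tau, loglik = f$loglik, convergence = f$convergence,
         boundary_tau = f$boundary_tau, n = f$n, n_censored = f$n_censored))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# coerce heterogeneous codings to a canonical exam record data.frame
normalize_exam_records <- function(records, fam_map = NULL) {
  req <- c("id", "exam", "sbp", "age", "sex", "smoke", "med")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("exam records missing column(s): ", paste(miss, collapse = ", "))
  if (any(records$sbp <= 0, na.rm = TRUE))
    stop("sbp must be positive")
  if (anyDuplicated(records[c("id", "exam")]))
    stop("duplicate (individual, exam) record(s)")
  fam <- if ("fam" %in% names(records)) as.character(records$fam)
  else {
    if (is.null(fam_map)) stop("need a `fam` column or `fam_map`")
    unname(fam_map[as.character(records$id)])
  }
  if (any(is.na(fam))) stop("family unknown for some individuals")
  to01 <- function(x, yes, what) {
    if (is.logical(x)) return(as.numeric(x))
    if (is.numeric(x)) {
      if (!all(x %in% 0:1)) stop(what, " must be coded 0/1")
      return(as.numeric(x))
    }
    as.numeric(tolower(as.character(x)) %in% yes)
  }
  male <- if (is.numeric(records$sex)) as.numeric(records$sex == 1)
  else as.numeric(tolower(as.character(records$sex)) %in% c("male", "m", "1"))
  data.frame(id = as.character(records$id), fam = fam,
             exam = as.integer(records$exam), y = as.numeric(records$sbp),
             age = as.numeric(records$age), male = male,
             smoke = to01(records$smoke, c("yes", "y", "true"), "smoke"),
             cens = to01(records$med, c("yes", "y", "true"), "med") > 0,
             stringsAsFactors = FALSE)
}
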