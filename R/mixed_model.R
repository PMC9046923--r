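#' Model specification for the animal model
#'
#' Describes the single-trait animal model `y = Xb + Za + e`: which phenotype
#' column is the response, which columns enter as categorical fixed effects
#' (e.g. tank) and which as continuous covariates (e.g. initial body size),
#' and which relationship matrix family the random animal effect uses.
#'
#' @param trait response column name.
#' @param fixed_factors character vector of categorical fixed-effect columns.
#' @param covariates character vector of continuous covariate columns.
#' @param relationship one of "pedigree", "single-step", "genomic".
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(trait = "trait", fixed_factors = "tank",
                       covariates = "covariate",
                       relationship = c("pedigree", "single-step", "genomic")) {
  structure(list(trait = trait, fixed_factors = fixed_factors,
                 covariates = covariates,
                 relationship = match.arg(relationship)),
            class = "model_spec")
}

#' Build design matrices for the animal model
#'
#' Fixed effects use full-rank reference-level coding (first level dropped per
#' factor) with an intercept; covariates are centered. `Z` maps records to the
#' full animal universe, so animals without records get all-zero columns and
#' still receive breeding values through kinship. Records with missing
#' response or covariates are excluded with a warning; single-level factors
#' are dropped with a warning.
#'
#' @param phenotypes tibble with at least `id` and the columns named in
#'   `spec`.
#' @param spec a [model_spec()].
#' @param animal_ids the full vector of animal ids (pedigree or genotype
#'   universe); every phenotyped animal must appear in it.
#' @return A list with `y`, `X` (with column names), `Z`
#'   (records x animals, column names = `animal_ids`), and `data` (records
#'   used).
#' @export
build_design <- function(phenotypes, spec, animal_ids) {
  stopifnot(inherits(spec, "model_spec"))
  if (nrow(phenotypes) == 0) stop("empty phenotype table")
  cols <- c(spec$trait, spec$fixed_factors, spec$covariates)
  missing_cols <- setdiff(c("id", cols), names(phenotypes))
  if (length(missing_cols) > 0) {
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  animal_ids <- as.character(animal_ids)
  ph <- phenotypes
  ph$id <- as.character(ph$id)
  stray <- setdiff(ph$id, animal_ids)
  if (length(stray) > 0) {
    stop("phenotyped animals missing from animal universe: ",
         paste(head(stray, 5), collapse = ", "))
  }
  ok <- complete.cases(ph[, cols, drop = FALSE])
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with missing response/covariate excluded")
    ph <- ph[ok, , drop = FALSE]
  }
  if (nrow(ph) == 0) stop("no complete records left")

  X <- matrix(1, nrow(ph), 1, dimnames = list(NULL, "(Intercept)"))
  for (f in spec$fixed_factors) {
    v <- factor(ph[[f]])
    if (nlevels(v) < 2) {
      warning("fixed factor '", f, "' has a single level; dropped")
      next
    }
    mm <- model.matrix(~v)[, -1, drop = FALSE]
    colnames(mm) <- paste0(f, levels(v)[-1])
    X <- cbind(X, mm)
  }
  for (cv in spec$covariates) {
    v <- as.numeric(ph[[cv]])
    X <- cbind(X, setNames(data.frame(v - mean(v)), cv))
    X <- as.matrix(X)
  }
  Z <- matrix(0, nrow(ph), length(animal_ids),
              dimnames = list(NULL, animal_ids))
  Z[cbind(seq_len(nrow(ph)), match(ph$id, animal_ids))] <- 1
  list(y = as.numeric(ph[[spec$trait]]), X = X, Z = Z, data = ph)
}

#' REML variance components by average information with EM fallback
#'
#' Estimates additive and residual variances for the animal model
#' `y = Xb + Za + e`, `a ~ N(0, K sigma2_a)`, `e ~ N(0, I sigma2_e)`.
#' Internally the marginal covariance `V = ZKZ' sigma2_a + I sigma2_e` is
#' diagonalized once (eigendecomposition of `ZKZ'`), making each AI iteration
#' O(n p^2). An AI (quasi-Newton) update is attempted each iteration; if it
#' leaves the parameter space the iteration falls back to a multiplicative
#' EM-style update, with step-halving so the restricted likelihood never
#' decreases. Convergence: relative parameter change below `tol`.
#'
#' The standard error of h2 comes from the inverse AI matrix at convergence
#' via the delta method.
#'
#' @param y response vector.
#' @param X fixed-effects design (full rank).
#' @param Z records-by-animals incidence matrix.
#' @param K relationship matrix over the animals in `Z`'s columns (A, H or
#'   G). Supply the matrix itself, not its inverse.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return A list of class `reml_fit`: `sigma2_a`, `sigma2_e`, `h2`, `se_h2`,
#'   `converged`, `n_iterations`, `loglik`, `beta`.
#' @export
reml_estimate <- function(y, X, Z, K, tol = 1e-8, max_iter = 200) {
  n <- length(y)
  p <- qr(X)$rank
  if (p < ncol(X)) stop("fixed-effects design is rank deficient")
  M <- Z %*% K %*% t(Z)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  # restricted log-likelihood and derivative pieces at (sa, se)
  pieces <- function(sa, se) {
    w <- sa * d + se
    if (any(w <= 0)) return(NULL)
    iw <- 1 / w
    XtW <- Xt * iw
    S <- crossprod(Xt, XtW)
    cS <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(cS)) return(NULL)
    beta <- backsolve(cS, forwardsolve(t(cS), crossprod(XtW, yt)))
    r <- yt - drop(Xt %*% beta)
    e <- r * iw                      # rotated P y
    yPy <- sum(r * e)
    ll <- -0.5 * (sum(log(w)) + 2 * sum(log(diag(cS))) + yPy)
    # tr(P A) for A in {M (a = d), I (a = 1)}
    trP <- function(a) {
      B <- Xt * (a * iw * iw)
      sum(a * iw) - sum(diag(solve(S, crossprod(Xt, B))))
    }
    # P applied to a rotated vector
    Pv <- function(v) {
      v1 <- v * iw
      v1 - (Xt %*% solve(S, crossprod(Xt, v1))) * iw
    }
    list(w = w, iw = iw, S = S, beta = beta, e = e, yPy = yPy, ll = ll,
         trP = trP, Pv = Pv)
  }

  sp <- var(y)
  sa <- 0.5 * sp
  se <- 0.5 * sp
  pc <- pieces(sa, se)
  if (is.null(pc)) stop("could not initialize REML (K not PSD on records?)")
  converged <- FALSE
  AI <- NULL
  iter <- 0
  for (iter in seq_len(max_iter)) {
    e <- pc$e
    yPMPy <- sum(d * e^2)
    yPIPy <- sum(e^2)
    trPM <- pc$trP(d)
    trPI <- pc$trP(rep(1, n))
    score <- -0.5 * c(trPM - yPMPy, trPI - yPIPy)
    # average-information matrix
    PMe <- pc$Pv(d * e)
    PIe <- pc$Pv(e)
    AI <- 0.5 * matrix(c(sum(d * e * PMe), sum(d * e * PIe),
                         sum(e * PMe), sum(e * PIe)), 2, 2)
    AI <- (AI + t(AI)) / 2
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    new <- if (is.null(step)) c(-1, -1) else c(sa, se) + step
    floor_a <- 1e-10 * sp
    floor_e <- 1e-6 * sp  # keep the residual off the boundary so downstream
                          # mixed-model equations stay numerically solvable
    used_em <- FALSE
    if (any(!is.finite(new)) || new[2] <= floor_e || new[1] < 0) {
      # EM-style multiplicative fallback (positive by construction)
      new <- c(sa * yPMPy / max(trPM, 1e-300),
               se * yPIPy / max(trPI, 1e-300))
      new[1] <- max(new[1], floor_a)
      used_em <- TRUE
    }
    new[1] <- max(new[1], 0)
    new[2] <- max(new[2], floor_e)
    pc_new <- pieces(new[1], new[2])
    # step-halving toward the current point if the likelihood dropped
    h <- 0
    while ((is.null(pc_new) || pc_new$ll < pc$ll - 1e-10) && h < 30) {
      new <- (new + c(sa, se)) / 2
      pc_new <- pieces(new[1], new[2])
      h <- h + 1
    }
    if (is.null(pc_new)) break
    delta <- max(abs(new - c(sa, se)) / pmax(abs(c(sa, se)), 1e-12))
    sa <- new[1]
    se <- new[2]
    pc <- pc_new
    if (delta < tol || (used_em && sa <= floor_a * 1.01 && delta < 1e-6)) {
      converged <- TRUE
      break
    }
  }

  h2 <- sa / (sa + se)
  se_h2 <- NA_real_
  Vth <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(Vth)) {
    gr <- c(se, -sa) / (sa + se)^2
    v <- drop(t(gr) %*% Vth %*% gr)
    if (is.finite(v) && v >= 0) se_h2 <- sqrt(v)
  }
  structure(list(sigma2_a = sa, sigma2_e = se, h2 = h2, se_h2 = se_h2,
                 converged = converged, n_iterations = iter,
                 loglik = pc$ll, beta = setNames(drop(pc$beta), colnames(X))),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "REML fit: sigma2_a = %.4g, sigma2_e = %.4g, h2 = %.3f (SE %.3f), %s in %d iter\n",
    x$sigma2_a, x$sigma2_e, x$h2, x$se_h2,
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma2_a", "sigma2_e", "h2"),
    estimate = c(x$sigma2_a, x$sigma2_e, x$h2),
    std.error = c(NA_real_, NA_real_, x$se_h2)
  )
}

#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, se_h2 = x$se_h2, sigma2_a = x$sigma2_a,
                 sigma2_e = x$sigma2_e, logLik = x$loglik,
                 converged = x$converged, n_iterations = x$n_iterations)
}

#' Solve Henderson's mixed-model equations
#'
#' Solves `[[X'X, X'Z], [Z'X, Z'Z + K^-1 lambda]] [b, a] = [X'y, Z'y]` with
#' `lambda = sigma2_e / sigma2_a`, returning fixed-effect estimates and
#' breeding values for every animal in the relationship matrix (animals
#' without records are predicted through kinship).
#'
#' @param y,X,Z as in [reml_estimate()].
#' @param K_inv inverse relationship matrix (A^-1, H^-1 or G^-1) over `Z`'s
#'   animal columns.
#' @param vc a [reml_estimate()] fit or list with `sigma2_a`, `sigma2_e`.
#' @return A list of class `blup_solutions`: `fixed` (tibble term/estimate),
#'   `ebv` (tibble id/ebv), `residuals`.
#' @export
solve_mme <- function(y, X, Z, K_inv, vc) {
  if (vc$sigma2_a <= 0) stop("sigma2_a must be positive (infinite shrinkage)")
  lambda <- vc$sigma2_e / vc$sigma2_a
  if (!is.finite(lambda)) stop("lambda = sigma2_e/sigma2_a is not finite")
  XtX <- crossprod(X)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) {
    keep <- qr(X)$pivot[seq_len(qr(X)$rank)]
    stop("singular fixed-effects block; aliased columns: ",
         paste(setdiff(colnames(X), colnames(X)[keep]), collapse = ", "))
  }
  LHS <- rbind(cbind(XtX, crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + K_inv * lambda))
  RHS <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(LHS, RHS)
  nb <- ncol(X)
  beta <- sol[seq_len(nb)]
  a <- sol[-seq_len(nb)]
  structure(list(
    fixed = tibble::tibble(term = colnames(X), estimate = unname(beta)),
    ebv = tibble::tibble(id = colnames(Z), ebv = unname(a)),
    residuals = drop(y - X %*% beta - Z %*% a)
  ), class = "blup_solutions")
}

#' @export
print.blup_solutions <- function(x, ...) {
  cat(sprintf("<blup_solutions> %d fixed effects, %d breeding values\n",
              nrow(x$fixed), nrow(x$ebv)))
  invisible(x)
}

#' @export
tidy.blup_solutions <- function(x, ...) x$ebv

#' Narrow-sense heritability
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`.
#'
#' @param sigma2_a additive genetic variance (>= 0).
#' @param sigma2_e residual variance (> 0, unless sigma2_a > 0).
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(sigma2_a, sigma2_e) {
  if (sigma2_a < 0) stop("sigma2_a must be non-negative")
  if (sigma2_e < 0) stop("sigma2_e must be non-negative")
  if (sigma2_a + sigma2_e == 0) stop("both variance components are zero")
  sigma2_a / (sigma2_a + sigma2_e)
}
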