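#' Adjusted line means across experiments
#'
#' Ordinary least squares on fixed line and experiment effects. The adjusted
#' mean of a line is its estimated marginal mean: line effect plus the
#' unweighted average of the experiment effects, so that with balanced data
#' and no experiment shift it reduces to the raw line mean.
#'
#' @param data long-format plant table with the trait column, a line column
#'   and an experiment column; records with stage "baseline" are excluded
#'   when a \code{stage} column is present.
#' @param trait name of the trait column.
#' @param line,experiment column names (defaults "line", "experiment").
#' @return an \code{adjusted_means} object: data.frame with columns
#'   \code{line} and \code{value}, one row per line with any data, plus
#'   attributes \code{trait}, \code{n_experiments}, \code{n_plants}.
#' @export
adjusted_means <- function(data, trait, line = "line", experiment = "experiment") {
  df <- as.data.frame(data)
  if ("stage" %in% names(df)) df <- df[df$stage == "final", , drop = FALSE]
  if (!trait %in% names(df)) stop("no trait column '", trait, "'")
  df <- df[!is.na(df[[trait]]), , drop = FALSE]
  if (nrow(df) == 0) stop("no observations for trait '", trait, "'")
  y <- df[[trait]]
  L <- factor(df[[line]])
  E <- factor(df[[experiment]])
  if (nlevels(E) > 1) {
    fit <- stats::lm(y ~ L + E)
    cf <- stats::coef(fit)
    if (anyNA(cf)) stop("design is rank deficient beyond the standard ",
                        "one redundancy per factor")
    e_eff <- c(0, cf[paste0("E", levels(E)[-1])])
    l_eff <- c(0, cf[paste0("L", levels(L)[-1])])
    adj <- cf[["(Intercept)"]] + l_eff + mean(e_eff)
  } else {
    adj <- tapply(y, L, mean)
  }
  out <- data.frame(line = levels(L), value = as.numeric(adj),
                    stringsAsFactors = FALSE)
  structure(out, class = c("adjusted_means", "data.frame"),
            trait = trait, n_experiments = nlevels(E), n_plants = nrow(df))
}

#' Adjusted means for several traits as a lines x traits matrix
#'
#' @inheritParams adjusted_means
#' @param traits character vector of trait columns.
#' @return numeric matrix, rows = union of lines, columns = traits.
#' @export
adjusted_means_matrix <- function(data, traits, line = "line",
                                  experiment = "experiment") {
  ams <- lapply(traits, function(tr) adjusted_means(data, tr, line, experiment))
  lines <- sort(unique(unlist(lapply(ams, `[[`, "line"))))
  out <- matrix(NA_real_, length(lines), length(traits),
                dimnames = list(lines, traits))
  for (k in seq_along(traits)) {
    out[ams[[k]]$line, k] <- ams[[k]]$value
  }
  out
}

## ---------------------------------------------------------------------------
## Restricted-likelihood machinery.
##
## Model: y = X beta + Z u_a + Z u_n + e,  u_a ~ N(0, sa G), u_n ~ N(0, sn I),
## e ~ N(0, se I). Both random terms share the line incidence Z, so every
## quantity of the restricted likelihood, its score and the average-
## information matrix reduces to q-dimensional (lines) algebra through the
## Woodbury identity: V^-1 = (I - Z A Z')/se with A = (se H^-1 + Z'Z)^-1 and
## H = sa G + sn I.
## ---------------------------------------------------------------------------

reml_precompute <- function(y, X, Z, G) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  eG <- eigen((G + t(G)) / 2, symmetric = TRUE)
  list(y = y, X = X, Z = Z, G = G, n = length(y), q = ncol(Z), p = ncol(X),
       U = eG$vectors, d = pmax(eG$values, 0),
       M = crossprod(Z), ZtX = crossprod(Z, X), Zty = drop(crossprod(Z, y)),
       XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y^2))
}

## Restricted likelihood via A = (se H^-1 + M)^-1 computed through the
## push-through identity A = L (se I + L'ML)^-1 L' with H = LL', which stays
## exact when H is singular (the centred VanRaden G always has a zero
## eigenvalue along the all-ones vector).
reml_eval <- function(theta, pre, use_a, use_n) {
  se <- theta[["se"]]
  if (!is.finite(se) || se <= 0) return(NULL)
  sa <- if (use_a) theta[["sa"]] else 0
  sn <- if (use_n) theta[["sn"]] else 0
  q <- pre$q; n <- pre$n
  lam <- sa * pre$d + sn                 # eigenvalues of H = sa G + sn I
  if (any(!is.finite(lam)) || all(lam <= 0)) return(NULL)
  L <- pre$U * rep(sqrt(lam), each = q)  # U diag(sqrt(lam))
  C0 <- crossprod(L, pre$M %*% L)
  diag(C0) <- diag(C0) + se
  cholC <- tryCatch(chol((C0 + t(C0)) / 2), error = function(e) NULL)
  if (is.null(cholC)) return(NULL)
  A <- L %*% chol2inv(cholC) %*% t(L)
  logdetV <- (n - q) * log(se) + 2 * sum(log(diag(cholC)))
  AZtX <- A %*% pre$ZtX
  AZty <- A %*% pre$Zty
  B <- (pre$XtX - crossprod(pre$ZtX, AZtX)) / se
  B <- (B + t(B)) / 2
  cholB <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(cholB)) return(NULL)
  Binv <- chol2inv(cholB)
  XVy <- (pre$Xty - crossprod(pre$ZtX, AZty)) / se
  yVy <- (pre$yty - sum(pre$Zty * AZty)) / se
  beta <- drop(Binv %*% XVy)
  yPy <- drop(yVy - sum(XVy * beta))
  logl <- -0.5 * (logdetV + 2 * sum(log(diag(cholB))) + yPy)
  list(theta = theta, logl = logl, A = A, B = B, Binv = Binv,
       beta = beta, yPy = yPy, AZtX = AZtX, AZty = AZty)
}

reml_derivs <- function(ev, pre, use_a, use_n) {
  se <- ev$theta[["se"]]
  q <- pre$q; n <- pre$n
  r <- pre$y - drop(pre$X %*% ev$beta)
  Ztr <- pre$Zty - drop(pre$ZtX %*% ev$beta)
  Py <- (r - drop(pre$Z %*% (ev$A %*% Ztr))) / se
  u <- drop(crossprod(pre$Z, Py))          # Z' P y
  MA <- pre$M %*% ev$A
  S <- (pre$M - MA %*% pre$M) / se          # Z' V^-1 Z
  Tm <- (pre$ZtX - MA %*% pre$ZtX) / se     # Z' V^-1 X
  ViX <- (pre$X - pre$Z %*% ev$AZtX) / se   # V^-1 X
  Gu <- drop(pre$G %*% u)
  comp <- c(if (use_a) "sa", if (use_n) "sn", "se")
  trV <- c(sa = if (use_a) sum(S * pre$G) else NA,
           sn = sum(diag(S)), se = (n - sum(ev$A * pre$M)) / se)
  QB <- list(sa = if (use_a) crossprod(Tm, pre$G %*% Tm),
             sn = crossprod(Tm), se = crossprod(ViX))
  yPVPy <- c(sa = sum(u * Gu), sn = sum(u^2), se = sum(Py^2))
  trP <- vapply(comp, function(k) trV[[k]] - sum(ev$Binv * QB[[k]]), numeric(1))
  score <- -0.5 * (trP - yPVPy[comp])
  W <- cbind(sa = if (use_a) drop(pre$Z %*% Gu),
             sn = if (use_n) drop(pre$Z %*% u), se = Py)
  colnames(W) <- comp
  Pvec <- function(w) {
    Viw <- (w - drop(pre$Z %*% (ev$A %*% crossprod(pre$Z, w)))) / se
    Viw - drop(ViX %*% (ev$Binv %*% crossprod(pre$X, Viw)))
  }
  PW <- apply(W, 2, Pvec)
  AI <- 0.5 * crossprod(W, PW)
  AI <- (AI + t(AI)) / 2
  ZPZ <- S - Tm %*% ev$Binv %*% t(Tm)       # Z' P Z
  list(score = score, AI = AI, trP = trP, yPVPy = yPVPy[comp], Py = Py, u = u,
       S = S, Tm = Tm, ZPZ = ZPZ)
}

## Fixed-effects-only reduced model (both genetic components pruned):
## closed-form REML of sigma_e^2, with u = Z'Py and Z'PZ for the BLUP step.
reml_ols <- function(pre) {
  XtXi <- solve(pre$XtX)
  beta <- drop(XtXi %*% pre$Xty)
  rss <- pre$yty - sum(pre$Xty * beta)
  se <- rss / (pre$n - pre$p)
  logl <- -0.5 * ((pre$n - pre$p) * log(se) +
                    determinant(pre$XtX, logarithm = TRUE)$modulus[1] + rss / se)
  Py <- (pre$y - drop(pre$X %*% beta)) / se
  ZPZ <- (pre$M - pre$ZtX %*% XtXi %*% t(pre$ZtX)) / se
  list(theta = c(sa = 0, sn = 0, se = se), logl = logl,
       ev = list(beta = beta, Binv = XtXi * se), u = drop(crossprod(pre$Z, Py)),
       ZPZ = ZPZ, iterations = 0L, converged = TRUE, trace = NULL)
}

reml_core <- function(y, X, Z, G, use_a = TRUE, use_n = TRUE, start = NULL,
                      max_iter = 200, tol_par = 1e-8, tol_logl = 1e-9,
                      verbose = FALSE) {
  pre <- reml_precompute(y, X, Z, G)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) stop("response has zero variance")
  if (!use_a && !use_n) {
    out <- reml_ols(pre)
    out$boundary <- character(0)
    out$pre <- pre
    return(out)
  }
  lower <- 1e-10 * vy
  prune_at <- 1e-8 * vy
  comp <- c(if (use_a) "sa", if (use_n) "sn", "se")
  theta <- if (!is.null(start)) pmax(start[comp], lower) else {
    stats::setNames(c(0.3, 0.2, 0.5)[c(use_a, use_n, TRUE)] * vy, comp)
  }
  ev <- reml_eval(theta, pre, use_a, use_n)
  if (is.null(ev)) stop("restricted likelihood not evaluable at start values")
  trace <- matrix(NA_real_, 0, length(comp) + 1,
                  dimnames = list(NULL, c(comp, "logl")))
  converged <- FALSE
  iter <- 0
  prune <- NULL
  stuck <- c(sa = 0L, sn = 0L)
  while (iter < max_iter) {
    iter <- iter + 1
    dv <- reml_derivs(ev, pre, use_a, use_n)
    ## a genetic component pinned at the zero bound with a non-positive
    ## score is a genuine boundary optimum: prune it and refit reduced.
    ## (A component merely overshot to the bound has a positive score and
    ## is left free to climb back.)
    for (k in intersect(comp, c("sa", "sn"))) {
      if (theta[[k]] <= prune_at && dv$score[[k]] <= 0) {
        stuck[k] <- stuck[k] + 1L
      } else stuck[k] <- 0L
    }
    if (any(stuck >= 2L)) { prune <- names(which.max(stuck)); break }
    ## AI step with step-halving, EM fallback
    delta <- tryCatch(solve(dv$AI, dv$score), error = function(e) NULL)
    new_ev <- NULL
    if (!is.null(delta)) {
      step <- 1
      for (h in 1:12) {
        cand <- pmax(theta + step * delta, lower)
        cand_ev <- reml_eval(cand, pre, use_a, use_n)
        if (!is.null(cand_ev) && cand_ev$logl >= ev$logl - 1e-10) {
          new_ev <- cand_ev; break
        }
        step <- step / 2
      }
    }
    if (is.null(new_ev)) {
      rankk <- c(sa = pre$q, sn = pre$q, se = pre$n)[comp]
      cand <- pmax(theta + theta^2 * (dv$yPVPy - dv$trP) / rankk, lower)
      new_ev <- reml_eval(cand, pre, use_a, use_n)
      if (is.null(new_ev)) break
    }
    dpar <- max(abs(new_ev$theta - theta) / (theta + 1))
    dlogl <- abs(new_ev$logl - ev$logl)
    theta <- new_ev$theta
    ev <- new_ev
    trace <- rbind(trace, c(theta, ev$logl))
    if (verbose) message(sprintf("iter %d logL %.6f  %s", iter, ev$logl,
                                 paste(sprintf("%s=%.4g", comp, theta), collapse = " ")))
    if (dpar < tol_par || dlogl < tol_logl) {
      bound <- intersect(comp, c("sa", "sn"))
      bound <- bound[theta[bound] <= prune_at]
      if (!length(bound)) { converged <- TRUE; break }
      ## converged onto the bound: prune the component the likelihood does
      ## not want to move off it (score computed at the top of the loop)
      neg <- bound[dv$score[bound] <= 0]
      if (length(neg)) { prune <- neg[1]; break }
    }
  }
  if (is.null(prune) && !converged && iter >= max_iter) {
    stop("REML did not converge in ", max_iter, " iterations; trace:\n",
         paste(utils::capture.output(print(utils::tail(trace, 5))), collapse = "\n"))
  }
  if (!is.null(prune)) {
    red <- reml_core(y, X, Z, G, use_a = use_a && prune != "sa",
                     use_n = use_n && prune != "sn",
                     start = theta[setdiff(comp, prune)],
                     max_iter = max_iter, tol_par = tol_par,
                     tol_logl = tol_logl, verbose = verbose)
    red$theta[prune] <- 0
    red$boundary <- union(red$boundary, prune)
    red$iterations <- red$iterations + iter
    return(red)
  }
  dv <- reml_derivs(ev, pre, use_a, use_n)
  theta_full <- c(sa = if (use_a) theta[["sa"]] else 0,
                  sn = if (use_n) theta[["sn"]] else 0,
                  se = theta[["se"]])
  list(theta = theta_full, logl = ev$logl, iterations = iter,
       converged = converged, trace = trace, boundary = character(0),
       ev = ev, u = dv$u, ZPZ = dv$ZPZ, pre = pre)
}

## BLUPs and prediction error (co)variance matrices at the REML estimates,
## computed without inverting G:
##   u_hat_a = sa G Z'Py ;  PEV_a = sa G - sa^2 G (Z'PZ) G
##   g = u_a + u_n       ;  PEV_g = H  - H (Z'PZ) H,  H = sa G + sn I
reml_blup <- function(core) {
  th <- core$theta
  sa <- th[["sa"]]; sn <- th[["sn"]]
  G <- core$pre$G; q <- core$pre$q
  u <- core$u
  ZPZ <- core$ZPZ
  ua <- sa * drop(G %*% u)
  un <- sn * u
  GZ <- sa * G
  PEV_a <- GZ - GZ %*% ZPZ %*% GZ
  H <- sa * G; diag(H) <- diag(H) + sn
  PEV_g <- H - H %*% ZPZ %*% H
  list(ua = ua, un = un, PEV_a = PEV_a, PEV_g = PEV_g)
}

#' Fit a GBLUP model with additive and residual genetic effects
#'
#' Fits, by average-information REML (with EM fallback steps), the linear
#' mixed model y = X b + Z u_a + Z u_n + e where u_a ~ N(0, sigma_a^2 G) are
#' the genomic breeding values with G the VanRaden genomic relationship
#' matrix, u_n ~ N(0, sigma_n^2 I) captures line-level genetic variation not
#' tracked by the markers, and e ~ N(0, sigma_e^2 I). Fixed effects default
#' to the experiment factor. Variance components are constrained
#' non-negative; a component estimated at the zero boundary is reported as
#' exactly zero (in which case the narrow- and broad-sense Cullis
#' heritabilities coincide).
#'
#' Two data interfaces are supported: plant-level records (default, as the
#' model is defined) and line-level adjusted means. On means there is a
#' single observation per line, so the residual genetic and residual
#' components are confounded and the model reduces to u_a plus residual;
#' this mode exists mainly to make cross-validation cheap.
#'
#' @param data plant-level data.frame (with the trait, line and experiment
#'   columns; baseline-stage rows are dropped), an \code{adjusted_means}
#'   object, or a named numeric vector of line means.
#' @param grm a \code{\link{vanraden_grm}} (or any PSD relationship matrix
#'   with line IDs as dimnames) covering at least the phenotyped lines.
#' @param trait trait column name (ignored for a numeric vector).
#' @param fixed one-sided formula of fixed effects for plant-level data;
#'   default \code{~ experiment}. Reference-level (treatment) coding with
#'   the first experiment as reference.
#' @param line line ID column, default \code{"line"}.
#' @param partition logical; include the residual genetic term u_n
#'   (\code{TRUE} for plant-level data, forcibly \code{FALSE} on means).
#' @param varcomp optional named vector \code{c(sa=, sn=, se=)} of fixed
#'   variance components: skips REML and computes BLUPs/PEV at these values
#'   (used for fast cross-validation).
#' @param start optional named start values for REML.
#' @param max_iter,tol_par,tol_logl convergence control: stop when the
#'   largest relative component change is below \code{tol_par} or the
#'   restricted log-likelihood change is below \code{tol_logl}.
#' @param cullis_vd logical; additionally compute the pairwise
#'   variance-of-differences form of the Cullis heritabilities.
#' @param verbose print the iteration trace.
#' @return an object of class \code{gblup}; see
#'   \code{\link{heritability}}, \code{\link{genetic_cv}},
#'   \code{\link{predict.gblup}}.
#' @export
gblup <- function(data, grm, trait = NULL, fixed = ~ experiment,
                  line = "line", partition = TRUE, varcomp = NULL,
                  start = NULL, max_iter = 200, tol_par = 1e-8,
                  tol_logl = 1e-9, cullis_vd = FALSE, verbose = FALSE) {
  cl <- match.call()
  Gfull <- unclass(grm)
  gids <- rownames(Gfull)
  if (is.null(gids)) stop("grm must carry line IDs as dimnames")
  means_mode <- FALSE
  if (inherits(data, "adjusted_means")) {
    y <- stats::setNames(data$value, data$line)
    if (is.null(trait)) trait <- attr(data, "trait")
    means_mode <- TRUE
  } else if (is.numeric(data) && !is.null(names(data))) {
    y <- data
    means_mode <- TRUE
  }
  if (means_mode) {
    y <- y[!is.na(y)]
    ids <- names(y)
    if (!all(ids %in% gids)) stop("GRM does not cover all phenotyped lines")
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
    Z <- diag(length(y))
    partition <- FALSE
  } else {
    df <- as.data.frame(data)
    if (is.null(trait)) stop("trait must be given for plant-level data")
    if ("stage" %in% names(df)) df <- df[df$stage == "final", , drop = FALSE]
    df <- df[!is.na(df[[trait]]), , drop = FALSE]
    if (!nrow(df)) stop("no observations for trait '", trait, "'")
    if (!all(df[[line]] %in% gids)) stop("GRM does not cover all phenotyped lines")
    y <- df[[trait]]
    fx <- stats::as.formula(fixed)
    vars <- all.vars(fx)
    for (v in vars) df[[v]] <- factor(df[[v]])
    X <- if (length(vars)) stats::model.matrix(fx, df)
         else matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
    ids <- sort(unique(as.character(df[[line]])))
    Lf <- factor(df[[line]], levels = ids)
    Z <- stats::model.matrix(~ 0 + Lf)
    colnames(Z) <- ids
  }
  G <- Gfull[ids, ids, drop = FALSE]
  q <- length(ids)
  if (q < 2) stop("need at least 2 phenotyped lines")
  if (!is.null(varcomp)) {
    use_a <- !is.na(varcomp["sa"]) && varcomp[["sa"]] > 0
    use_n <- partition && !is.na(varcomp["sn"]) && varcomp[["sn"]] > 0
    comp <- c(if (use_a) "sa", if (use_n) "sn", "se")
    pre <- reml_precompute(y, X, Z, G)
    ev <- reml_eval(varcomp[comp], pre, use_a, use_n)
    if (is.null(ev)) stop("likelihood not evaluable at the supplied varcomp")
    dv <- reml_derivs(ev, pre, use_a, use_n)
    core <- list(theta = c(sa = if (use_a) varcomp[["sa"]] else 0,
                           sn = if (use_n) varcomp[["sn"]] else 0,
                           se = varcomp[["se"]]),
                 logl = ev$logl, iterations = 0L, converged = TRUE,
                 trace = NULL, boundary = character(0), ev = ev,
                 u = dv$u, ZPZ = dv$ZPZ, pre = pre)
  } else {
    core <- reml_core(y, X, Z, G, use_n = partition, start = start,
                      max_iter = max_iter, tol_par = tol_par,
                      tol_logl = tol_logl, verbose = verbose)
  }
  th <- core$theta
  sa <- th[["sa"]]; se <- th[["se"]]
  sn <- if (partition) th[["sn"]] else NA_real_
  sg <- sa + if (is.na(sn)) 0 else sn
  bl <- reml_blup(core)
  names(bl$ua) <- names(bl$un) <- ids
  pev_a <- mean(diag(bl$PEV_a))
  pev_g <- mean(diag(bl$PEV_g))
  clamp <- function(x) min(max(x, 0), 1)
  H2 <- if (sg > 0) clamp(1 - pev_g / sg) else NA_real_
  h2 <- if (sa > 0) clamp(1 - pev_a / sa) else NA_real_
  clamped <- c(H2 = isTRUE(sg > 0 && (1 - pev_g / sg) != H2),
               h2 = isTRUE(sa > 0 && (1 - pev_a / sa) != h2))
  vd <- NULL
  if (cullis_vd) {
    vd_mean <- function(P) {
      qn <- nrow(P)
      2 * (mean(diag(P)) - (sum(P) - sum(diag(P))) / (qn * (qn - 1)))
    }
    vd <- c(H2 = if (sg > 0) clamp(1 - vd_mean(bl$PEV_g) / (2 * sg)) else NA_real_,
            h2 = if (sa > 0) clamp(1 - vd_mean(bl$PEV_a) / (2 * sa)) else NA_real_)
  }
  beta <- stats::setNames(core$ev$beta, colnames(core$pre$X))
  fit <- list(trait = trait, varcomp = c(sa = sa, sn = sn, se = se),
              sigma_g2 = sg, gebv = bl$ua, u_n = bl$un,
              pev_a = pev_a, pev_g = pev_g, H2 = H2, h2 = h2,
              clamped = clamped, heritability_vd = vd,
              beta = beta, beta_se = sqrt(diag(core$ev$Binv)),
              logLik = core$logl, converged = core$converged,
              iterations = core$iterations, trace = core$trace,
              boundary = core$boundary, line_ids = ids,
              trait_mean = mean(y), n = length(y), q = q,
              means_mode = means_mode, u = core$u,
              y = y, X = core$pre$X, Z = core$pre$Z, grm_train = G,
              call = cl)
  class(fit) <- "gblup"
  fit
}

#' @method print gblup
#' @export
print.gblup <- function(x, ...) {
  cat("GBLUP fit", if (!is.null(x$trait)) paste0("for trait '", x$trait, "'"),
      "\n")
  cat(sprintf("  %d observations, %d lines%s\n", x$n, x$q,
              if (x$means_mode) " (adjusted-means mode)" else ""))
  vc <- x$varcomp
  cat(sprintf("  sigma_a^2 = %.4g  sigma_n^2 = %s  sigma_e^2 = %.4g\n",
              vc[["sa"]],
              if (is.na(vc[["sn"]])) "-" else sprintf("%.4g", vc[["sn"]]),
              vc[["se"]]))
  cat(sprintf("  H2 = %.3f  h2 = %.3f   REML logLik = %.4f (%d iterations)\n",
              x$H2, x$h2, x$logLik, x$iterations))
  if (length(x$boundary)) cat("  boundary component(s):",
                              paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  structure(list(fit = object), class = "summary.gblup")
}

#' @export
print.summary.gblup <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nFixed effects:\n")
  print(data.frame(estimate = f$beta, se = f$beta_se))
  cat(sprintf("\nMean PEV (additive) %.4g, (total genotypic) %.4g\n",
              f$pev_a, f$pev_g))
  cat(sprintf("gCV = %.2f%% (SD-based)\n", genetic_cv(f)))
  top <- utils::head(sort(f$gebv, decreasing = TRUE), 5)
  cat("\nTop GEBVs:\n"); print(round(top, 4))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$beta

#' @export
logLik.gblup <- function(object, ...) {
  structure(object$logLik, df = sum(!is.na(object$varcomp)) + length(object$beta),
            class = "logLik")
}

#' @export
fitted.gblup <- function(object, ...) {
  unname(drop(object$X %*% object$beta +
                object$Z %*% (object$gebv + object$u_n)))
}

#' @export
residuals.gblup <- function(object, ...) object$y - fitted(object)

#' Genomic estimated breeding values of a fit
#' @param fit a \code{gblup} object.
#' @param total logical; return total genotypic values u_a + u_n instead of
#'   the additive GEBVs.
#' @return named numeric vector over the phenotyped lines.
#' @export
gebv <- function(fit, total = FALSE) {
  stopifnot(inherits(fit, "gblup"))
  if (total) fit$gebv + fit$u_n else fit$gebv
}

#' Cullis heritabilities of a GBLUP fit
#'
#' Broad sense: H2 = 1 - PEV_g / sigma_g^2 with sigma_g^2 = sigma_a^2 +
#' sigma_n^2 and PEV_g the mean prediction error variance of the total
#' genotypic estimates; narrow sense: h2 = 1 - PEV_a / sigma_a^2 with the
#' additive PEV. Values are clamped to [0, 1] (clamping recorded in the fit).
#' When sigma_n^2 is estimated at zero the two coincide exactly.
#'
#' @param fit a \code{gblup} object.
#' @param vd logical; return the pairwise variance-of-differences variant
#'   (requires \code{cullis_vd = TRUE} at fit time).
#' @return named vector \code{c(H2=, h2=)}; NA where the variance
#'   denominator is zero.
#' @export
heritability <- function(fit, vd = FALSE) {
  stopifnot(inherits(fit, "gblup"))
  if (vd) {
    if (is.null(fit$heritability_vd)) {
      stop("fit was not computed with cullis_vd = TRUE")
    }
    return(fit$heritability_vd)
  }
  c(H2 = fit$H2, h2 = fit$h2)
}

#' Genetic coefficient of variation
#'
#' Default mode reports 100 * sigma_g / mu, the genetic standard deviation
#' as a percentage of the trait mean, which is the scale on which gCV values
#' are comparable across traits. A literal variance-over-mean mode
#' (sigma_g^2 / mu) is also provided.
#'
#' @param fit a \code{gblup} object.
#' @param trait_mean trait mean mu > 0; defaults to the mean of the fitted
#'   response.
#' @param mode \code{"sd"} (default) or \code{"literal"}.
#' @return gCV value.
#' @export
genetic_cv <- function(fit, trait_mean = fit$trait_mean,
                       mode = c("sd", "literal")) {
  stopifnot(inherits(fit, "gblup"))
  mode <- match.arg(mode)
  if (trait_mean <= 0) stop("trait_mean must be positive")
  if (mode == "sd") 100 * sqrt(fit$sigma_g2) / trait_mean
  else fit$sigma_g2 / trait_mean
}

#' Predict additive genetic values of unphenotyped lines
#'
#' Conditional-expectation prediction u_new = G_{new,train}
#' G_{train,train}^-1 u_hat_train, which is algebraically identical to
#' solving the joint mixed-model equations with the new lines' phenotypes
#' missing (\code{method = "joint"} computes that route directly as
#' sigma_a^2 G_{new,train} Z'Py).
#'
#' @param object a \code{gblup} fit.
#' @param grm relationship matrix covering training and new lines (e.g. the
#'   full-population \code{\link{vanraden_grm}}).
#' @param lines IDs of the lines to predict; default all GRM lines not in
#'   the training set.
#' @param method \code{"conditional"} (default) or \code{"joint"}.
#' @param ... unused.
#' @return named numeric vector of predicted GEBVs.
#' @export
predict.gblup <- function(object, grm = NULL, lines = NULL,
                          method = c("conditional", "joint"), ...) {
  method <- match.arg(method)
  if (is.null(grm)) return(object$gebv)
  Gall <- unclass(grm)
  ids <- rownames(Gall)
  train <- object$line_ids
  if (!all(train %in% ids)) stop("grm does not cover the training lines")
  if (is.null(lines)) lines <- setdiff(ids, train)
  if (!all(lines %in% ids)) stop("grm does not cover the requested lines")
  Gnt <- Gall[lines, train, drop = FALSE]
  if (method == "joint") {
    return(drop(object$varcomp[["sa"]] * Gnt %*% object$u))
  }
  Gtt <- Gall[train, train, drop = FALSE]
  sol <- tryCatch(solve(Gtt, object$gebv), error = function(e) NULL)
  if (is.null(sol)) {
    ridge <- 1e-8 * mean(diag(Gtt))
    for (k in 1:3) {
      sol <- tryCatch(solve(Gtt + diag(ridge, nrow(Gtt)), object$gebv),
                      error = function(e) NULL)
      if (!is.null(sol)) break
      ridge <- ridge * 100
    }
    if (is.null(sol)) stop("training GRM block is singular even after bending")
  }
  drop(Gnt %*% sol)
}

#' Diagnostic plot of a GBLUP fit
#'
#' Observed against fitted values with the identity line.
#'
#' @param x a \code{gblup} fit.
#' @param ... passed to \code{plot}.
#' @method plot gblup
#' @export
plot.gblup <- function(x, ...) {
  f <- fitted(x)
  graphics::plot(f, x$y, xlab = "fitted", ylab = "observed",
                 main = if (!is.null(x$trait)) x$trait else "", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate responses from a fitted GBLUP model
#'
#' Draws new phenotype vectors from the fitted model: fresh additive effects
#' from N(0, sigma_a^2 G), residual genetic effects from N(0, sigma_n^2 I)
#' and residuals from N(0, sigma_e^2 I), added to the estimated fixed
#' effects.
#'
#' @param object a \code{gblup} fit.
#' @param nsim number of response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with \code{nsim} columns, one row per observation.
#' @method simulate gblup
#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  th <- object$varcomp
  sn <- if (is.na(th[["sn"]])) 0 else th[["sn"]]
  q <- object$q; n <- object$n
  eg <- eigen(object$grm_train, symmetric = TRUE)
  rt <- sqrt(pmax(th[["sa"]] * eg$values, 0))
  mu <- drop(object$X %*% object$beta)
  out <- matrix(NA_real_, n, nsim)
  for (s in seq_len(nsim)) {
    ua <- drop(eg$vectors %*% (rt * stats::rnorm(q)))
    un <- stats::rnorm(q, 0, sqrt(sn))
    out[, s] <- mu + drop(object$Z %*% (ua + un)) +
      stats::rnorm(n, 0, sqrt(th[["se"]]))
  }
  as.data.frame(out)
}
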