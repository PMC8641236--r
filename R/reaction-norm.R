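#' Legendre polynomial basis on a standardized temperature scale
#'
#' Temperatures are standardized to t* = 2 (T - t_min) / (t_max - t_min) - 1
#' in [-1, 1]; the basis columns are the (unnormalized) Legendre polynomials
#' P0 = 1, P1 = t*, P2 = (3 t*^2 - 1)/2, ... up to \code{order}.
#'
#' @param temp numeric temperatures (degrees C).
#' @param order highest polynomial order (>= 0).
#' @param bounds length-2 numeric, the standardization bounds (t_min, t_max);
#'   defaults to \code{range(temp)}.
#' @param derivative logical; TRUE returns d/dT of each basis column
#'   (including the standardization Jacobian 2 / (t_max - t_min)).
#' @return matrix with \code{order + 1} columns named \code{phi0}, ...
#' @export
legendre_basis <- function(temp, order = 2L, bounds = range(temp),
                           derivative = FALSE) {
  stopifnot(order >= 0L, length(bounds) == 2L, bounds[2L] > bounds[1L])
  x <- 2 * (temp - bounds[1L]) / (bounds[2L] - bounds[1L]) - 1
  jac <- 2 / (bounds[2L] - bounds[1L])
  k <- order + 1L
  P <- matrix(0, length(x), k)
  P[, 1L] <- 1
  if (k >= 2L) P[, 2L] <- x
  if (k >= 3L) for (j in 3L:k) {
    nn <- j - 2L  # recurrence (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1}
    P[, j] <- ((2 * nn + 1) * x * P[, j - 1L] - nn * P[, j - 2L]) / (nn + 1)
  }
  if (derivative) {
    D <- matrix(0, length(x), k)
    if (k >= 2L) D[, 2L] <- 1
    if (k >= 3L) for (j in 3L:k) {
      # P'_{n+1} = P'_{n-1} + (2n+1) P_n
      nn <- j - 2L
      D[, j] <- D[, j - 2L] + (2 * nn + 1) * P[, j - 1L]
    }
    P <- D * jac
  }
  colnames(P) <- paste0("phi", 0:order)
  P
}

check_records <- function(recs) {
  need <- c("animal", "farm", "lactation", "year_lambing", "month_lambing",
            "dim", "temperature", "milk")
  miss <- setdiff(need, names(recs))
  if (length(miss))
    stop("phenotype records are missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(recs$temperature)))
    stop("temperatures must be finite")
  if (any(recs$dim < 0)) stop("days-in-milk must be >= 0")
  invisible(recs)
}

#' Fit reaction-norm curves to longitudinal milk records
#'
#' Random-regression linear mixed model for test-day milk yield:
#' fixed effects of farm, lactation number, calendar year and month of
#' lambing, and days-from-lambing in monthly classes, plus a population mean
#' curve in Legendre polynomials of the standardized daily temperature;
#' random per-animal regression coefficients on the same basis with an
#' unstructured covariance matrix, estimated by REML (via lme4). An animal's
#' reaction norm is the population curve plus its predicted coefficient
#' deviations.
#'
#' @param recs data.frame of test-day records with columns \code{animal},
#'   \code{farm}, \code{lactation}, \code{year_lambing}, \code{month_lambing},
#'   \code{dim} (days from lambing), \code{temperature} (degrees C),
#'   \code{milk} (kg).
#' @param order Legendre order of the reaction norm (default 2, a quadratic).
#' @param bounds temperature standardization bounds; default
#'   \code{range(recs$temperature)}.
#' @return object of class \code{reaction_norm_fit}: per-animal total
#'   coefficients (population + deviation), the lme4 fit, basis metadata and
#'   residual variance.
#' @export
fit_reaction_norms <- function(recs, order = 2L,
                               bounds = range(recs$temperature)) {
  check_records(recs)
  if (length(unique(recs$temperature)) < 2L)
    stop("need at least 2 distinct temperatures to fit a reaction norm")
  phi <- legendre_basis(recs$temperature, order = order, bounds = bounds)
  dat <- data.frame(
    milk = recs$milk,
    animal = factor(recs$animal),
    farm = factor(recs$farm),
    lactation = factor(recs$lactation),
    year_lambing = factor(recs$year_lambing),
    month_lambing = factor(recs$month_lambing),
    dim_class = factor(pmin(recs$dim %/% 30L, 9L)))
  dat <- cbind(dat, phi)

  fixed_terms <- c("farm", "lactation", "year_lambing", "month_lambing",
                   "dim_class")
  fixed_terms <- fixed_terms[vapply(dat[fixed_terms], nlevels, 1L) > 1L]
  basis_terms <- paste0("phi", seq_len(order))  # phi0 is the intercept
  rand <- paste0("(0 + ", paste(colnames(phi), collapse = " + "),
                 " | animal)")
  fml <- stats::reformulate(c(fixed_terms, basis_terms, rand),
                            response = "milk")
  Wchk <- stats::model.matrix(
    stats::reformulate(c(fixed_terms, basis_terms)), dat)
  qw <- qr(Wchk)
  if (qw$rank < ncol(Wchk))
    stop("singular fixed design; aliased columns: ",
         paste(colnames(Wchk)[qw$pivot[-seq_len(qw$rank)]], collapse = ", "))

  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))))
  fe <- lme4::fixef(fit)
  pop_coef <- numeric(order + 1L)
  pop_coef[1L] <- fe[["(Intercept)"]]
  for (j in seq_len(order))
    pop_coef[j + 1L] <- fe[[paste0("phi", j)]]
  re <- lme4::ranef(fit)$animal
  re <- re[, colnames(phi), drop = FALSE]
  animals <- rownames(re)
  coefs <- sweep(as.matrix(re), 2L, pop_coef, "+")
  vc <- as.data.frame(lme4::VarCorr(fit))
  resid_var <- vc$vcov[vc$grp == "Residual"]
  structure(list(coefs = coefs, deviations = as.matrix(re),
                 pop_coef = pop_coef, animals = animals, order = order,
                 bounds = bounds, resid_var = resid_var, model = fit),
            class = "reaction_norm_fit")
}

#' @export
print.reaction_norm_fit <- function(x, ...) {
  cat("Reaction-norm fit: order", x$order, "Legendre basis on [",
      x$bounds[1L], ",", x$bounds[2L], "] degrees C;",
      length(x$animals), "animals\n")
  cat(sprintf("  residual variance %.4g\n", x$resid_var))
  invisible(x)
}

#' Per-animal reaction-norm slopes at chosen temperatures
#'
#' The slope is the analytical derivative of each animal's fitted curve,
#' d/dT sum_k a_ik phi_k(t*(T)), including the standardization Jacobian.
#' Temperatures outside the standardization bounds are extrapolated with a
#' warning.
#'
#' @param fit a [fit_reaction_norms()] result.
#' @param temperatures numeric vector of temperatures (degrees C).
#' @return data.frame with column \code{animal} and one \code{slope_T<t>}
#'   column per requested temperature (kg per degree C).
#' @export
slopes_at <- function(fit, temperatures = c(10, 25)) {
  stopifnot(inherits(fit, "reaction_norm_fit"))
  outside <- temperatures < fit$bounds[1L] | temperatures > fit$bounds[2L]
  if (any(outside))
    warning("temperature(s) ", paste(temperatures[outside], collapse = ", "),
            " outside the standardization bounds [", fit$bounds[1L], ", ",
            fit$bounds[2L], "]; slopes are extrapolated")
  out <- data.frame(animal = fit$animals, stringsAsFactors = FALSE)
  for (tt in temperatures) {
    dphi <- legendre_basis(tt, order = fit$order, bounds = fit$bounds,
                           derivative = TRUE)
    out[[sprintf("slope_T%g", tt)]] <- drop(fit$coefs %*% t(dphi))
  }
  out
}

#' Lifetime milk yield and length of productive life
#'
#' Lifetime milk uses the Fleischmann test-interval method within each
#' lactation: first-test yield times its days-in-milk, plus the mean of
#' adjacent test yields times the interval between them, summed over
#' lactations. A single-record lactation with zero or missing days-in-milk
#' contributes yield times \code{default_interval}. Productive life is the
#' number of calendar days from an animal's first to last milk record,
#' inclusive.
#'
#' @param recs test-day records (as in [fit_reaction_norms()]) with a
#'   \code{date} column (Date or numeric day index).
#' @param default_interval fallback test interval in days (default 30).
#' @return data.frame (animal, lifetime_milk, productive_days).
#' @export
lifetime_traits <- function(recs, default_interval = 30) {
  check_records(recs)
  if (is.null(recs$date)) stop("records need a 'date' column")
  date_num <- as.numeric(recs$date)
  out <- lapply(split(seq_len(nrow(recs)), recs$animal), function(ii) {
    pdays <- max(date_num[ii]) - min(date_num[ii]) + 1
    milk <- 0
    for (jj in split(ii, recs$lactation[ii])) {
      o <- jj[order(recs$dim[jj])]
      y <- recs$milk[o]
      dim <- recs$dim[o]
      first_int <- if (is.na(dim[1L]) || dim[1L] <= 0) default_interval
        else dim[1L]
      milk <- milk + y[1L] * first_int
      if (length(o) > 1L) {
        dt <- diff(dim)
        milk <- milk + sum((y[-length(y)] + y[-1L]) / 2 * dt)
      }
    }
    c(milk, pdays)
  })
  res <- data.frame(animal = names(out),
                    lifetime_milk = vapply(out, `[`, 0, 1L),
                    productive_days = vapply(out, `[`, 0, 2L),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
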