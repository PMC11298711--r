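#' Fit an empirical-Bayes batch harmonization model
#'
#' Location/scale (ComBat-style) harmonization of edge values across scanner
#' batches, preserving specified biological covariates. Per edge, values are
#' modeled as
#' \deqn{y = \alpha + X\beta + \gamma_b + \delta_b \epsilon}
#' where \eqn{\gamma_b} (additive, on the bias) and \eqn{\delta_b}
#' (multiplicative, on the variance) are batch effects constrained so that
#' batch effects weighted by batch size sum to zero. Naive per-batch,
#' per-edge estimates on standardized residuals are shrunk toward empirical
#' priors shared across edges (normal prior for \eqn{\gamma}, inverse-gamma
#' for \eqn{\delta^2}, hyperparameters by method of moments) by iterating
#' the conditional posterior means to convergence.
#'
#' @param dataset a `cohort_dataset`, normally on the log scale.
#' @param batch name of the batch column in `dataset$covariates`.
#' @param preserve covariate columns whose effects must be preserved
#'   (default group, age, sex).
#' @param tol convergence tolerance on the absolute change of both
#'   \eqn{\gamma^*} and \eqn{\delta^{*2}}.
#' @param max_iter maximum posterior-mean iterations; `0` returns the naive
#'   (unshrunk) estimates.
#' @return A list of class `harmonization_model`: `alpha_hat`, `beta_hat`,
#'   `gamma_star`, `delta_star` (batches x edges), `pooled_var`, `hyper`
#'   (per-batch gamma_bar, tau2, lambda, theta), plus design bookkeeping.
#' @export
fit_combat <- function(dataset, batch = "batch",
                       preserve = c("group", "age", "sex"),
                       tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  cov <- dataset$covariates
  if (!batch %in% names(cov)) stop("no batch column '", batch, "'")
  missing_cols <- setdiff(preserve, names(cov))
  if (length(missing_cols))
    stop("preserve columns not in covariates: ",
         paste(missing_cols, collapse = ", "))
  batch_f <- factor(cov[[batch]])
  n_b <- table(batch_f)
  if (any(n_b < 2))
    stop("every batch needs at least 2 subjects (variance undefined); ",
         "offending: ", paste(names(n_b)[n_b < 2], collapse = ", "))

  Y <- dataset$Y
  n <- ncol(Y)
  nb <- nlevels(batch_f)

  B <- matrix(0, n, nb)
  B[cbind(seq_len(n), as.integer(batch_f))] <- 1
  colnames(B) <- levels(batch_f)
  pform <- stats::as.formula(paste("~", paste(preserve, collapse = " + ")))
  mf <- stats::model.frame(pform, cov)
  X <- model.matrix(pform, mf)[, -1, drop = FALSE] # batch dummies span 1
  D <- cbind(B, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("design [batch | preserve] is rank deficient")

  beta_all <- qr.coef(qrD, t(Y))              # (nb + q) x E
  gamma_ls <- beta_all[seq_len(nb), , drop = FALSE]
  beta_x <- beta_all[-seq_len(nb), , drop = FALSE]
  wts <- as.numeric(n_b) / n
  alpha_hat <- drop(crossprod(gamma_ls, wts))  # size-weighted grand intercept

  fit <- t(D %*% beta_all)                     # E x n
  pooled_var <- rowMeans((Y - fit)^2)          # denominator n
  if (any(pooled_var <= 0))
    stop("zero pooled residual variance on some edge; data degenerate")

  stand_mean <- alpha_hat + t(X %*% beta_x)    # E x n
  Z <- (Y - stand_mean) / sqrt(pooled_var)

  E_n <- nrow(Y)
  gamma_hat <- matrix(0, nb, E_n)
  delta2_hat <- matrix(0, nb, E_n)
  for (b in seq_len(nb)) {
    Zb <- Z[, batch_f == levels(batch_f)[b], drop = FALSE]
    gamma_hat[b, ] <- rowMeans(Zb)
    delta2_hat[b, ] <- rowMeans((Zb - gamma_hat[b, ])^2) # MLE denominator
  }

  # method-of-moments hyperpriors across edges
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, var)
  m_d <- rowMeans(delta2_hat)
  s2_d <- apply(delta2_hat, 1, var)
  lambda <- (m_d^2 + 2 * s2_d) / s2_d
  theta <- (m_d^3 + m_d * s2_d) / s2_d

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  n_iter <- 0L
  if (max_iter > 0L) {
    for (b in seq_len(nb)) {
      nb_i <- as.numeric(n_b[b])
      Zb <- Z[, batch_f == levels(batch_f)[b], drop = FALSE]
      degenerate_var <- !is.finite(s2_d[b]) || s2_d[b] < 1e-12
      g <- gamma_hat[b, ]
      d2 <- delta2_hat[b, ]
      iter <- 0L
      repeat {
        g_new <- if (is.finite(tau2[b]) && tau2[b] > 0) {
          (nb_i * tau2[b] * gamma_hat[b, ] + d2 * gamma_bar[b]) /
            (nb_i * tau2[b] + d2)
        } else rep(gamma_bar[b], E_n)
        d2_new <- if (degenerate_var) {
          delta2_hat[b, ]
        } else {
          ss <- rowSums((Zb - g_new)^2)
          (theta[b] + 0.5 * ss) / (nb_i / 2 + lambda[b] - 1)
        }
        change <- max(max(abs(g_new - g)), max(abs(d2_new - d2)))
        g <- g_new
        d2 <- d2_new
        iter <- iter + 1L
        if (change < tol) break
        if (iter >= max_iter) {
          err <- simpleError(paste0(
            "posterior-mean iteration did not converge for batch '",
            levels(batch_f)[b], "' after ", max_iter,
            " iterations (last change ", signif(change, 3), ")"))
          err$gamma_star <- g
          err$delta2_star <- d2
          stop(err)
        }
      }
      gamma_star[b, ] <- g
      delta2_star[b, ] <- d2
      n_iter <- max(n_iter, iter)
    }
  }
  if (any(delta2_star <= 0))
    stop("non-positive posterior variance effect; data degenerate")

  out <- list(
    alpha_hat = alpha_hat,
    beta_hat = beta_x,
    gamma_star = gamma_star,
    delta_star = sqrt(delta2_star),
    gamma_hat = gamma_hat,
    delta2_hat = delta2_hat,
    pooled_var = pooled_var,
    hyper = data.frame(batch = levels(batch_f), gamma_bar = gamma_bar,
                       tau2 = tau2, lambda = lambda, theta = theta),
    batch_levels = levels(batch_f),
    batch_column = batch,
    preserve = preserve,
    preserve_formula = pform,
    xlevels = stats::.getXlevels(stats::terms(mf), mf),
    edges = dataset$edges,
    n_iter = n_iter
  )
  class(out) <- "harmonization_model"
  out
}

#' @export
print.harmonization_model <- function(x, ...) {
  cat("harmonization_model:", length(x$pooled_var), "edges,",
      length(x$batch_levels), "batches (",
      paste(x$batch_levels, collapse = ", "), ")\n")
  cat("preserved covariates:", paste(x$preserve, collapse = ", "),
      "| iterations:", x$n_iter, "\n")
  invisible(x)
}

#' Apply a fitted harmonization model
#'
#' Removes the posterior batch location/scale effects and restores the
#' preserved covariate fit:
#' \eqn{y^{harm} = (z - \gamma^*_b)/\delta^*_b \cdot \hat\sigma + \hat\alpha
#' + X\hat\beta}.
#'
#' @param model a [fit_combat()] result.
#' @param dataset a `cohort_dataset` with the same edge set; batch labels
#'   must all have been seen at fit time.
#' @return The dataset with harmonized `Y`.
#' @export
apply_combat <- function(model, dataset) {
  stopifnot(inherits(model, "harmonization_model"),
            inherits(dataset, "cohort_dataset"))
  if (nrow(dataset$Y) != length(model$pooled_var))
    stop("dataset edge count differs from the fitted model")
  cov <- dataset$covariates
  batch_f <- factor(cov[[model$batch_column]], levels = model$batch_levels)
  if (anyNA(batch_f))
    stop("dataset contains batch labels unseen at fit time: ",
         paste(unique(cov[[model$batch_column]][is.na(batch_f)]),
               collapse = ", "))
  mf <- stats::model.frame(model$preserve_formula, cov,
                           xlev = model$xlevels)
  X <- model.matrix(model$preserve_formula, mf)[, -1, drop = FALSE]

  Y <- dataset$Y
  stand_mean <- model$alpha_hat + t(X %*% model$beta_hat)
  Z <- (Y - stand_mean) / sqrt(model$pooled_var)
  b_idx <- as.integer(batch_f)
  # per-subject batch effects enter column-wise (subjects are columns)
  Zc <- Z - t(model$gamma_star[b_idx, , drop = FALSE])
  Zc <- Zc / t(model$delta_star[b_idx, , drop = FALSE])
  dataset$Y <- Zc * sqrt(model$pooled_var) + stand_mean
  dataset
}
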