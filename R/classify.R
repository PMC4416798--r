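# PCA reduction at 90% retained variance and sparse logistic regression
# (L1 path with internal cross-validation).

#' Fit a PCA reduction on training features
#'
#' Centred PCA retaining the smallest dimension whose cumulative
#' explained variance reaches `var_frac`.
#'
#' @param X Trials x features matrix.
#' @param var_frac Retained variance fraction (default 0.90).
#' @return A `pca_model`: `mean`, `loadings` (features x retained),
#'   `var_fractions`, `dim`.
#' @export
fit_pca <- function(X, var_frac = 0.90) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two training trials")
  mu <- colMeans(X)
  sv <- svd(sweep(X, 2, mu), nu = 0)
  ev <- sv$d^2
  if (sum(ev) == 0) stop("training features have zero variance")
  frac <- ev / sum(ev)
  m <- which(cumsum(frac) >= var_frac - 1e-12)[1]
  structure(list(mean = mu, loadings = sv$v[, seq_len(m), drop = FALSE],
                 var_fractions = frac, dim = m, var_frac = var_frac),
            class = "pca_model")
}

#' Project features onto a fitted PCA model
#'
#' Subtracts the training mean and multiplies by the loadings.
#'
#' @param X Trials x features matrix.
#' @param model A [fit_pca()] result.
#' @return Trials x retained-dim matrix.
#' @export
project_pca <- function(X, model) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean)) stop("feature dimension mismatch")
  sweep(X, 2, model$mean) %*% model$loadings
}

# shared glmnet backend: standardised L1 logistic regression with
# regularisation chosen by seeded internal CV; returns the weights on
# the original feature scale
.slr_glmnet <- function(X, y, seed = 1, nfolds = 5) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  nfolds <- min(nfolds, min(table(y)))
  foldid <- .rng_local(seed, {
    f <- numeric(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    f
  })
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          foldid = foldid, standardize = TRUE,
                          nlambda = 40)
  lam <- cv$lambda.min
  co <- as.numeric(stats::coef(cv, s = lam))
  if (all(co[-1] == 0)) {
    # the internal CV preferred the null model; use the largest penalty
    # on the path that still selects at least one feature
    nz <- cv$nzero > 0
    if (any(nz)) {
      lam <- max(cv$lambda[nz])
      co <- as.numeric(stats::coef(cv, s = lam))
    }
  }
  list(intercept = co[1], weights = co[-1], lambda = lam, cv = cv)
}

#' Fit the sparse logistic regression classifier
#'
#' L1-regularised logistic regression on standardised features, with the
#' regularisation strength chosen by seeded internal cross-validation on
#' the training set. Predicted probability refers to the change-speed
#' class; the decision rule is change-speed iff P > 0.5.
#'
#' @param X Trials x features matrix.
#' @param y Labels (`"change"`/`"constant"`, logical, or 0/1 with 1 =
#'   change).
#' @param seed Integer seed.
#' @param nfolds Internal CV folds (default 5).
#' @return An `slr_model`: `intercept`, `weights`, `nonzero` (index
#'   set), `lambda`, `seed`.
#' @export
fit_slr <- function(X, y, seed = 1, nfolds = 5) {
  y01 <- .as_change01(y)
  fit <- .slr_glmnet(as.matrix(X), y01, seed = seed, nfolds = nfolds)
  structure(list(intercept = fit$intercept, weights = fit$weights,
                 nonzero = which(fit$weights != 0), lambda = fit$lambda,
                 seed = seed),
            class = "slr_model")
}

.as_change01 <- function(y) {
  if (is.character(y) || is.factor(y)) as.integer(as.character(y) == "change")
  else as.integer(y)
}

#' Predict change-speed probabilities
#'
#' @param model An [fit_slr()] result.
#' @param X Trials x features matrix.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_slr <- function(model, X) {
  eta <- model$intercept + as.numeric(as.matrix(X) %*% model$weights)
  1 / (1 + exp(-eta))
}

#' Quantise probabilities into class labels
#' @param p Probabilities of the change-speed class.
#' @return Character labels: `"change"` iff `p > 0.5`, else
#'   `"constant"`.
#' @export
classify_proba <- function(p) ifelse(p > 0.5, "change", "constant")
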