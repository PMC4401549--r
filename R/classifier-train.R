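# Classifier-development pipeline: node prescreening, penalized fits,
# 2-to-4 node combination models, bootstrap optimism adjustment, OOB AUROC.

# plain logistic fit on a numeric matrix (no penalty) via Newton/IRLS with a
# tiny ridge for numerical stability; agreement with stats::glm is covered by
# a unit test. The bootstrap optimism/OOB loops refit this model tens of
# thousands of times per cohort, so the solver is kept lean. Under complete
# separation the iteration cap bounds the coefficients; the fitted
# probabilities remain usable for rank-based AUROC.
logit_irls <- function(Xm, y, maxit = 30L, tol = 1e-9, ridge = 1e-8,
                       beta_init = NULL) {
  p <- ncol(Xm)
  beta <- beta_init %||% numeric(p)
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(drop(Xm %*% beta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xm, Xm * w) + diag(ridge, p)
    g <- crossprod(Xm, y - mu)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

logit_fit <- function(X, y) {
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  beta <- logit_irls(Xm, y)
  names(beta) <- colnames(Xm)
  list(coefficients = beta,
       predict = function(Xnew) {
         Xn <- cbind(1, as.matrix(Xnew))
         as.numeric(stats::plogis(Xn %*% beta))
       })
}

#' Prescreen node metrics for classifier development
#'
#' Builds the initial candidate node-metric subset as the union (with
#' provenance) of three screens run on the training data: (1) nodes with a
#' univariate two-sample Mann-Whitney test of responders vs resistant below
#' `alpha_level`; (2) the `top_k` nodes by random-forest permutation
#' importance; (3) nodes with non-zero coefficients in an all-node
#' L1-penalized logistic fit. Columns with no observed values are dropped
#' with a message; remaining missing values are median-imputed for the
#' random-forest and penalized screens only (the univariate screen uses
#' per-node complete cases).
#'
#' @param X data.frame/matrix of node-metric features (rows = patients),
#'   `NA` allowed.
#' @param y binary outcomes (see [auroc_trapezoid()]).
#' @param alpha_level univariate screen level.
#' @param top_k number of top random-forest importances retained.
#' @param seed RNG seed for the stochastic screens.
#' @return list with `candidates` (character vector of selected feature
#'   names) and `table` (per-feature screen results and provenance).
#' @export
prescreen_nodes <- function(X, y, alpha_level = 0.05, top_k = 15L, seed = NULL) {
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) stop("need both outcome classes")
  if (!is.null(seed)) set.seed(seed)
  X <- as.data.frame(X)
  all_missing <- vapply(X, function(col) all(is.na(col)), logical(1))
  if (any(all_missing)) {
    message("dropping all-missing node(s): ",
            paste(names(X)[all_missing], collapse = ", "))
    X <- X[!all_missing]
  }
  if (ncol(X) == 0L) stop("no usable features")
  up <- vapply(X, function(col) {
    ok <- !is.na(col)
    if (length(unique(col[ok])) < 2L || length(unique(y[ok])) < 2L) return(NA_real_)
    suppressWarnings(stats::wilcox.test(col[ok & y == 1L],
                                        col[ok & y == 0L])$p.value)
  }, numeric(1))
  Ximp <- as.data.frame(lapply(X, function(col) {
    col[is.na(col)] <- stats::median(col, na.rm = TRUE); col
  }))
  # positional mapping: node names contain characters model formulas mangle
  Xmat <- as.matrix(Ximp)
  colnames(Xmat) <- paste0("V", seq_len(ncol(Xmat)))
  rf <- randomForest::randomForest(x = Xmat, y = factor(y), ntree = 500L,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1)[, 1]
  rf_rank <- rank(-imp, ties.method = "first")
  cv <- glmnet::cv.glmnet(Xmat, y, family = "binomial",
                          alpha = 1, nfolds = min(10L, max(3L, length(y) %/% 3L)))
  beta <- as.numeric(stats::coef(cv, s = "lambda.1se"))[-1]
  tab <- data.frame(feature = names(X), univariate_p = unname(up),
                    rf_rank = unname(rf_rank),
                    lasso_nonzero = beta != 0, stringsAsFactors = FALSE)
  tab$univariate_hit <- !is.na(tab$univariate_p) & tab$univariate_p < alpha_level
  tab$rf_hit <- tab$rf_rank <= top_k
  tab$selected <- tab$univariate_hit | tab$rf_hit | tab$lasso_nonzero
  tab$provenance <- apply(tab[c("univariate_hit", "rf_hit", "lasso_nonzero")],
                          1, function(h)
                            paste(c("univariate", "rf", "lasso")[h], collapse = "+"))
  list(candidates = tab$feature[tab$selected], table = tab)
}

#' L1-penalized logistic regression with cross-validated penalty
#'
#' LASSO logistic fit with the penalty chosen by cross-validated deviance
#' (one-standard-error rule by default). Coefficients shrunk to zero are
#' reported as zero; an all-zero solution indicates that no classifier can
#' be constructed from the inputs. The penalty itself guards against
#' separation — there is no unpenalized fallback.
#'
#' @param X feature matrix/data.frame (complete cases required).
#' @param y binary outcomes.
#' @param rule `"1se"` or `"min"` penalty-selection rule.
#' @param nfolds cross-validation folds.
#' @param seed RNG seed for fold assignment.
#' @return list with `coefficients` (named, including intercept), `lambda`,
#'   `rule`, `nonzero` (feature names with non-zero coefficients), `fit`.
#' @export
fit_penalized_logistic <- function(X, y, rule = c("1se", "min"), nfolds = 10L,
                                   seed = NULL) {
  rule <- match.arg(rule)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) stop("outcome is constant; nothing to fit")
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete; impute or subset first")
  if (!is.null(seed)) set.seed(seed)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          nfolds = min(nfolds, max(3L, length(y) %/% 3L)))
  s <- if (rule == "1se") "lambda.1se" else "lambda.min"
  beta <- as.numeric(stats::coef(cv, s = s))
  names(beta) <- rownames(stats::coef(cv, s = s))
  list(coefficients = beta, lambda = cv[[s]], rule = rule,
       nonzero = names(beta)[-1][beta[-1] != 0], fit = cv)
}

#' Optimism-adjusted AUROC by bootstrap resampling
#'
#' Harrell-style optimism correction for a logistic model on the given
#' feature columns: the apparent AUROC (model fit and evaluated on the full
#' data) minus the mean over bootstrap resamples of
#' (AUROC of the bootstrap-refitted model on its bootstrap sample − AUROC of
#' that model on the original data). Bootstrap draws with a degenerate
#' outcome class are redrawn (counted in `redraws`).
#'
#' @param X feature matrix/data.frame (complete cases required).
#' @param y binary outcomes.
#' @param B bootstrap resamples.
#' @param seed RNG seed.
#' @param boot_indices optional list of prespecified bootstrap index vectors
#'   (diagnostics; overrides random resampling and `B`).
#' @return list with `apparent`, `optimism`, `adjusted`, `B`, `redraws`.
#' @export
adjust_auroc_optimism <- function(X, y, B = 500L, seed = NULL,
                                  boot_indices = NULL) {
  y <- as_binary_labels(y)
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete")
  if (is.null(boot_indices) && B < 1L) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  Xm <- cbind(1, X)
  pos <- y == 1L
  # AUROC is rank-based, so the linear predictor scores directly
  auc_lp <- function(lp, yy) scaled_u(lp[yy == 1L], lp[yy == 0L])
  # iteration cap 15: under separation the coefficients keep growing but the
  # score ordering (all the AUROC uses) stabilizes within a few iterations
  beta0 <- logit_irls(Xm, y, maxit = 15L)
  apparent <- auc_lp(drop(Xm %*% beta0), y)
  idx_list <- boot_indices %||% vector("list", B)
  opt <- numeric(length(idx_list))
  redraws <- 0L
  for (b in seq_along(idx_list)) {
    idx <- idx_list[[b]]
    if (is.null(idx)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (any(pos[idx]) && any(!pos[idx])) break
        redraws <- redraws + 1L
      }
    }
    bb <- logit_irls(Xm[idx, , drop = FALSE], y[idx], maxit = 15L,
                     beta_init = beta0)   # warm start at the full-data fit
    lp_all <- drop(Xm %*% bb)
    opt[b] <- auc_lp(lp_all[idx], y[idx]) - auc_lp(lp_all, y)
  }
  list(apparent = apparent, optimism = mean(opt),
       adjusted = apparent - mean(opt), B = length(idx_list), redraws = redraws)
}

#' Out-of-bag AUROC of a logistic model
#'
#' Each bootstrap resample refits the model and scores the patients left out
#' of that resample; per-patient out-of-bag scores are averaged over
#' resamples and the AUROC of the averaged scores against the outcomes is
#' returned. Patients never out of bag after `B` draws are excluded with a
#' warning (increase `B`).
#'
#' @inheritParams adjust_auroc_optimism
#' @param B bootstrap resamples (at least 50).
#' @return list with `auroc`, `oob_scores` (per patient; `NA` if never out
#'   of bag), `B`, `n_never_oob`.
#' @export
oob_auroc <- function(X, y, B = 200L, seed = NULL) {
  if (B < 50L) stop("B must be >= 50")
  y <- as_binary_labels(y)
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete")
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  ssum <- numeric(n); cnt <- integer(n)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
    }
    oob <- setdiff(seq_len(n), unique(idx))
    if (!length(oob)) next
    fb <- logit_fit(X[idx, , drop = FALSE], y[idx])
    ssum[oob] <- ssum[oob] + fb$predict(X[oob, , drop = FALSE])
    cnt[oob] <- cnt[oob] + 1L
  }
  never <- cnt == 0L
  if (any(never))
    warning(sum(never), " patient(s) never out of bag; increase B")
  scores <- ifelse(never, NA_real_, ssum / pmax(cnt, 1L))
  ok <- !never
  list(auroc = auroc_trapezoid(scores[ok], y[ok]), oob_scores = scores,
       B = B, n_never_oob = sum(never))
}

#' Enumerate and rank 2-to-4 node combination models
#'
#' Fits a logistic regression for every subset of 2 to `kmax` candidate node
#' metrics (complete cases per subset), scores each by its optimism-adjusted
#' AUROC, and returns the models ranked by adjusted AUROC. Candidates are
#' sorted internally, so the ranking is invariant to input order. Subsets
#' with fewer than 2 complete cases in either outcome class are skipped and
#' logged in the `skipped` attribute.
#'
#' @param candidates character vector of feature (column) names.
#' @param X feature data.frame (`NA` allowed; complete cases taken per
#'   subset).
#' @param y binary outcomes.
#' @param kmax maximum subset size (2 to 4 per the development design).
#' @param B bootstrap resamples per model for the optimism adjustment.
#' @param seed RNG seed.
#' @return data.frame of class `scnp_model_ranking`, one row per model:
#'   `model` (feature names joined by " + "), `k`, `n_used`, `apparent`,
#'   `adjusted`, ranked by decreasing adjusted AUROC.
#' @export
enumerate_combination_models <- function(candidates, X, y, kmax = 4L,
                                         B = 500L, seed = NULL) {
  if (length(candidates) < 2L) stop("need at least 2 candidate nodes")
  if (kmax < 2L || kmax > 4L) stop("kmax must be between 2 and 4")
  y <- as_binary_labels(y)
  X <- as.data.frame(X)
  miss <- setdiff(candidates, names(X))
  if (length(miss)) stop("unknown candidate(s): ", paste(miss, collapse = ", "))
  candidates <- sort(unique(candidates))
  if (!is.null(seed)) set.seed(seed)
  Xmat <- as.matrix(X[candidates])
  ok <- !is.na(Xmat)
  rows <- list(); skipped <- character(0)
  for (k in 2:min(kmax, length(candidates))) {
    subsets <- utils::combn(candidates, k, simplify = FALSE)
    for (sub in subsets) {
      j <- match(sub, candidates)
      cc <- rowSums(ok[, j, drop = FALSE]) == k
      ys <- y[cc]
      if (sum(ys == 1L) < 2L || sum(ys == 0L) < 2L) {
        skipped <- c(skipped, paste(sub, collapse = " + "))
        next
      }
      adj <- adjust_auroc_optimism(Xmat[cc, j, drop = FALSE], ys, B = B)
      rows[[length(rows) + 1L]] <-
        data.frame(model = paste(sub, collapse = " + "), k = k,
                   n_used = sum(cc), apparent = adj$apparent,
                   adjusted = adj$adjusted, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no fittable subsets")
  out <- do.call(rbind, rows)
  out <- out[order(-out$adjusted, out$model), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("scnp_model_ranking", "data.frame")
  out
}

#' Run the full classifier-development pipeline
#'
#' Prescreens node metrics, enumerates 2-to-4 node combination logistic
#' models, ranks them by optimism-adjusted AUROC, and reports the out-of-bag
#' AUROC of the top-ranked model.
#'
#' @param X node-metric feature data.frame (e.g. from [node_table_wide()],
#'   metadata columns removed).
#' @param y binary outcomes aligned with the rows of `X`.
#' @param alpha_level,top_k prescreen settings (see [prescreen_nodes()]).
#' @param kmax,B combination-model settings (see
#'   [enumerate_combination_models()]).
#' @param B_oob bootstrap resamples for the top model's OOB AUROC.
#' @param seed RNG seed covering all stochastic steps.
#' @return list with `prescreen`, `ranking`, `top_model` (feature names),
#'   `top_adjusted`, `top_oob` and `seed`.
#' @export
train_dx_pipeline <- function(X, y, alpha_level = 0.05, top_k = 15L,
                              kmax = 4L, B = 500L, B_oob = 200L, seed = 1L) {
  set.seed(seed)
  pre <- prescreen_nodes(X, y, alpha_level = alpha_level, top_k = top_k)
  if (length(pre$candidates) < 2L)
    stop("prescreen selected fewer than 2 candidates")
  rank_tab <- enumerate_combination_models(pre$candidates, X, y,
                                           kmax = kmax, B = B)
  top_feats <- strsplit(rank_tab$model[1], " + ", fixed = TRUE)[[1]]
  cc <- stats::complete.cases(X[top_feats])
  oob <- oob_auroc(X[cc, top_feats, drop = FALSE], as_binary_labels(y)[cc],
                   B = max(B_oob, 50L))
  list(prescreen = pre, ranking = rank_tab, top_model = top_feats,
       top_adjusted = rank_tab$adjusted[1], top_oob = oob$auroc, seed = seed)
}
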