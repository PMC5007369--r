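# Multivariate adaptive regression splines (MARS), written from scratch.
#
# A MARS model is a linear combination of an intercept and products of
# hinge functions max(0, x - k) / max(0, k - x) with knots k at observed
# data values.  Fitting is the classic two-stage procedure: a greedy
# forward pass adds the reflected hinge pair that most reduces the
# residual sum of squares, then a backward pass deletes bases one at a
# time and returns the subset minimizing the generalized cross-validation
# score GCV = (RSS/n) / (1 - C(M)/n)^2 with C(M) = #coefficients +
# penalty * #knots.  Two-class labels are fit by least squares on 0/1
# with a 0.5 score threshold (classic MARS classification).

# a term is a list(vars, knots, dirs); the intercept has zero factors
.intercept_term <- function() list(vars = integer(0), knots = numeric(0), dirs = numeric(0))

.term_degree <- function(term) length(term$vars)

.term_col <- function(term, data) {
  col <- rep(1, nrow(data))
  for (f in seq_along(term$vars)) {
    col <- col * pmax(0, term$dirs[f] * (data[, term$vars[f]] - term$knots[f]))
  }
  col
}

.mars_design <- function(X, terms) {
  vapply(terms, .term_col, numeric(nrow(X)), data = X)
}

.rss_fit <- function(D, y) {
  fit <- stats::lm.fit(D, y)
  sum(fit$residuals^2)
}

# distinct (variable, knot) pairs across all hinge factors of a model
.n_knots <- function(terms) {
  keys <- unlist(lapply(terms, function(t) {
    if (.term_degree(t) == 0) character(0)
    else paste(t$vars, format(t$knots, digits = 17))
  }))
  length(unique(keys))
}

.gcv_score <- function(rss, n, n_coef, n_knots, penalty) {
  C <- n_coef + penalty * n_knots
  if (C >= n) return(Inf)
  (rss / n) / (1 - C / n)^2
}

#' MARS forward pass
#'
#' Greedy basis construction: starting from the intercept, each step
#' scans every (parent basis, variable, observed knot) candidate, adds
#' the reflected hinge pair giving the largest residual-sum-of-squares
#' reduction of the least-squares fit, and stops at `max_bases` basis
#' functions or when the relative RSS improvement falls below `rel_tol`.
#' With `max_interaction = 1` only the intercept can parent, so the model
#' stays additive.
#'
#' @param X numeric feature matrix (samples x variables), no missing
#'   values.
#' @param y numeric response; for classification use 0/1 labels.
#' @param max_bases maximum number of (non-intercept) basis functions.
#' @param max_interaction maximum degree of a basis (1 = additive).
#' @param rel_tol minimum RSS improvement per step, relative to the total
#'   sum of squares.
#' @return list with `terms` (the intercept followed by hinge terms) and
#'   `rss_trace` (RSS after each accepted step).
#' @export
mars_forward <- function(X, y, max_bases = 21, max_interaction = 1,
                         rel_tol = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported", call. = FALSE)
  if (max_bases < 1) stop("max_bases must be >= 1", call. = FALSE)
  n <- nrow(X)
  terms <- list(.intercept_term())
  D <- matrix(1, n, 1)
  tss <- sum((y - mean(y))^2)
  rss <- tss
  trace <- rss
  if (tss == 0) {
    return(list(terms = terms, rss_trace = trace))
  }
  repeat {
    if (length(terms) - 1 + 2 > max_bases) break
    best <- NULL
    best_rss <- rss
    for (pi in seq_along(terms)) {
      parent <- terms[[pi]]
      if (.term_degree(parent) >= max_interaction) next
      pcol <- D[, pi]
      active <- pcol > 0
      if (!any(active)) next
      for (v in seq_len(ncol(X))) {
        if (v %in% parent$vars) next
        knots <- unique(X[active, v])
        for (k in knots) {
          c1 <- pcol * pmax(0, X[, v] - k)
          c2 <- pcol * pmax(0, k - X[, v])
          keep <- c(any(c1 != 0), any(c2 != 0))
          if (!any(keep)) next
          Dc <- cbind(D, c1, c2)[, c(rep(TRUE, ncol(D)), keep), drop = FALSE]
          r <- .rss_fit(Dc, y)
          if (r < best_rss - 1e-12) {
            best_rss <- r
            best <- list(parent = pi, var = v, knot = k, keep = keep)
          }
        }
      }
    }
    if (is.null(best) || (rss - best_rss) < rel_tol * tss) break
    parent <- terms[[best$parent]]
    mk <- function(dir) list(vars = c(parent$vars, best$var),
                             knots = c(parent$knots, best$knot),
                             dirs = c(parent$dirs, dir))
    new_terms <- list(mk(1), mk(-1))[best$keep]
    terms <- c(terms, new_terms)
    D <- .mars_design(X, terms)
    rss <- best_rss
    trace <- c(trace, rss)
  }
  list(terms = terms, rss_trace = trace)
}

#' MARS backward pass and GCV model selection
#'
#' Starting from the forward-pass model, repeatedly deletes the basis
#' function whose removal least increases the RSS, and returns the model
#' in the resulting nested sequence with the smallest GCV.  Candidates
#' whose complexity `C(M)` reaches the sample size are skipped.
#'
#' @param forward result of [mars_forward()].
#' @inheritParams mars_forward
#' @param penalty GCV penalty per knot (2 is standard for additive
#'   models).
#' @return an object of class `mars_model`: list with `terms`, `coef`,
#'   `gcv`, `gcv_trace`, `rss`, `penalty`, `max_interaction`.
#' @export
mars_backward <- function(forward, X, y, penalty = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  terms <- forward$terms
  eval_model <- function(terms) {
    D <- .mars_design(X, terms)
    fit <- stats::lm.fit(D, y)
    rss <- sum(fit$residuals^2)
    gcv <- .gcv_score(rss, n, length(terms), .n_knots(terms), penalty)
    list(terms = terms, rss = rss, gcv = gcv,
         coef = ifelse(is.na(fit$coefficients), 0, fit$coefficients))
  }
  seq_models <- list(eval_model(terms))
  cur <- terms
  while (length(cur) > 1) {
    drop_rss <- vapply(2:length(cur), function(i) {
      .rss_fit(.mars_design(X, cur[-i]), y)
    }, numeric(1))
    i_drop <- which.min(drop_rss) + 1L
    cur <- cur[-i_drop]
    seq_models <- c(seq_models, list(eval_model(cur)))
  }
  gcvs <- vapply(seq_models, `[[`, numeric(1), "gcv")
  if (all(!is.finite(gcvs))) {
    warning("all candidate models exceed the sample size; returning intercept-only")
    best <- seq_models[[length(seq_models)]]
  } else {
    best <- seq_models[[which.min(gcvs)]]
  }
  structure(list(terms = best$terms, coef = best$coef, gcv = best$gcv,
                 rss = best$rss, gcv_trace = gcvs, penalty = penalty,
                 n_train = n,
                 variable_names = colnames(X)),
            class = "mars_model")
}

#' Fit a MARS model (forward + backward pass)
#'
#' @inheritParams mars_forward
#' @inheritParams mars_backward
#' @return a `mars_model` with a `importance` element (see
#'   [variable_importance()]).
#' @export
mars_fit <- function(X, y, max_bases = 21, max_interaction = 1, penalty = 2,
                     rel_tol = 1e-8) {
  X <- as.matrix(X)
  fw <- mars_forward(X, y, max_bases = max_bases,
                     max_interaction = max_interaction, rel_tol = rel_tol)
  model <- mars_backward(fw, X, y, penalty = penalty)
  model$max_bases <- max_bases
  model$max_interaction <- max_interaction
  model$importance <- variable_importance(model, X, y)
  model
}

#' @export
print.mars_model <- function(x, ...) {
  nb <- length(x$terms) - 1
  cat(sprintf("MARS model: %d basis function(s) + intercept, GCV %.4g\n",
              nb, x$gcv))
  used <- sort(unique(unlist(lapply(x$terms, `[[`, "vars"))))
  if (length(used)) {
    nm <- if (!is.null(x$variable_names)) x$variable_names[used] else used
    cat("variables:", paste(nm, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict from a MARS model
#'
#' @param object a `mars_model`.
#' @param newdata feature matrix with the training columns.
#' @param type `"score"` for the raw least-squares score, `"class"` for
#'   the 0/1 call at threshold 0.5.
#' @param ... unused.
#' @return numeric scores or integer class labels.
#' @export
predict.mars_model <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  score <- drop(.mars_design(X, object$terms) %*% object$coef)
  if (type == "class") as.integer(score >= 0.5) else score
}

#' Per-variable importance of a fitted MARS model
#'
#' For each variable appearing in the model, importance is the increase
#' in GCV when all bases involving that variable are removed (and the
#' remaining coefficients refit), rescaled so the top variable scores
#' 100.  Variables absent from the model score 0.
#'
#' @param model a `mars_model`.
#' @inheritParams mars_forward
#' @return named numeric vector of scores in `[0, 100]`, one per column
#'   of `X`.
#' @export
variable_importance <- function(model, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  raw <- stats::setNames(numeric(p), nm)
  used <- sort(unique(unlist(lapply(model$terms, `[[`, "vars"))))
  if (length(used) == 0) return(raw)
  full_gcv <- model$gcv
  for (v in used) {
    keep <- vapply(model$terms, function(t) !(v %in% t$vars), logical(1))
    terms_wo <- model$terms[keep]
    D <- .mars_design(X, terms_wo)
    rss <- .rss_fit(D, y)
    gcv_wo <- .gcv_score(rss, n, length(terms_wo), .n_knots(terms_wo),
                         model$penalty)
    raw[v] <- max(0, gcv_wo - full_gcv)
  }
  if (max(raw) > 0) raw <- 100 * raw / max(raw)
  raw
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney concordance probability (ties counted
#' one-half), computed from ranks; the ROC polyline is a threshold sweep
#' over the unique scores from (0,0) to (1,1).
#'
#' @param scores numeric classifier scores (larger = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cut <- c(which(diff(s) != 0), length(s))  # last index of each tie block
  tpr <- c(0, cumsum(l)[cut] / n1)
  fpr <- c(0, cumsum(1 - l)[cut] / n0)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# stratified fold assignment: within each class, shuffled samples are
# dealt round-robin into k folds
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Validate a MARS classifier by cross-validation or an 80/20 split
#'
#' `cv10`: class-stratified 10-fold cross-validation; out-of-fold scores
#' are pooled into a single test ROC, and the training ROC comes from a
#' fit on the full data.  `split80_20`: a stratified 80/20 split; the
#' model is fit on the 80% and scored on the held-out 20%, with the
#' training ROC on the fitted 80%.
#'
#' @inheritParams mars_forward
#' @param y 0/1 class labels.
#' @param scheme `"cv10"` or `"split80_20"`.
#' @param seed integer seed controlling fold/split assignment.
#' @param penalty GCV penalty per knot.
#' @return an object of class `mars_validation`: list with `scheme`,
#'   `seed`, `auc_train`, `auc_test`, `roc_train`, `roc_test`,
#'   `test_scores`, `model` (full- or train-data fit) and
#'   `selected_variables` (importance > 0).
#' @export
mars_validate <- function(X, y, scheme = c("cv10", "split80_20"), seed = 1L,
                          max_bases = 21, max_interaction = 1, penalty = 2) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  set.seed(as.integer(seed))
  fit1 <- function(Xtr, ytr) mars_fit(Xtr, ytr, max_bases = max_bases,
                                      max_interaction = max_interaction,
                                      penalty = penalty)
  if (scheme == "cv10") {
    k <- 10L
    if (min(table(y)) < 5) {
      stop("cv10 requires >= 5 samples per class", call. = FALSE)
    }
    fold <- .stratified_folds(y, k)
    test_scores <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) {
        stop("a training fold contains one class only", call. = FALSE)
      }
      m <- fit1(X[tr, , drop = FALSE], y[tr])
      test_scores[!tr] <- predict(m, X[!tr, , drop = FALSE])
    }
    model <- fit1(X, y)
    train_scores <- predict(model, X)
    roc_tr <- roc_auc(train_scores, y)
    roc_te <- roc_auc(test_scores, y)
  } else {
    fold <- .stratified_folds(y, 5L)  # fold 5 = the held-out 20%
    tr <- fold != 5L
    if (min(table(y[tr])) < 2 || min(table(y[!tr])) < 1) {
      stop("split80_20 needs both classes in both parts", call. = FALSE)
    }
    model <- fit1(X[tr, , drop = FALSE], y[tr])
    train_scores <- predict(model, X[tr, , drop = FALSE])
    test_scores <- predict(model, X[!tr, , drop = FALSE])
    roc_tr <- roc_auc(train_scores, y[tr])
    roc_te <- roc_auc(test_scores, y[!tr])
  }
  imp <- model$importance
  structure(list(scheme = scheme, seed = as.integer(seed),
                 auc_train = roc_tr$auc, auc_test = roc_te$auc,
                 roc_train = roc_tr$points, roc_test = roc_te$points,
                 test_scores = test_scores, model = model,
                 selected_variables = names(imp)[imp > 0]),
            class = "mars_validation")
}

#' @export
print.mars_validation <- function(x, ...) {
  cat(sprintf("MARS validation (%s, seed %d): AUC train %.3f, test %.3f\n",
              x$scheme, x$seed, x$auc_train, x$auc_test))
  if (length(x$selected_variables)) {
    cat("selected variables:", paste(x$selected_variables, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a MARS model to JSON
#'
#' @param model a `mars_model`.
#' @param path output path.
#' @export
write_mars_model <- function(model, path) {
  terms <- lapply(model$terms, function(t) {
    list(vars = t$vars, knots = t$knots, dirs = t$dirs)
  })
  jsonlite::write_json(
    list(terms = terms, coef = unname(model$coef), gcv = model$gcv,
         penalty = model$penalty,
         importance = as.list(model$importance)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
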