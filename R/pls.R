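# Single-component PLS response classifier: a unit-norm weight vector W
# maximizing the squared covariance between the linear score Xw and the
# response, a linear score S = sum_i W_i * scaled(L_i), and a
# Youden-optimal decision threshold T with "responder iff S > T".

code_response <- function(y) {
  if (is.data.frame(y)) y <- y$response
  y <- as.character(y)
  bad <- setdiff(unique(y), c("responder", "nonresponder"))
  if (length(bad))
    stop("unknown response labels: ", paste(bad, collapse = ", "), call. = FALSE)
  ifelse(y == "responder", 1, -1)
}

#' Fit the unit-norm PLS weight vector
#'
#' Predictors are standardized (center, unit variance), the response is
#' coded +1 responder / -1 nonresponder and centered, and the weight
#' vector is the closed-form maximizer of cov^2(Xw, Y) over unit vectors:
#' W = c / ||c||, where c holds the sample covariances between each
#' standardized predictor and the centered response. The sign is fixed so
#' that the mean score of responders exceeds that of nonresponders.
#'
#' @param X samples x genes numeric matrix (column names = panel gene ids).
#' @param y response labels (`"responder"` / `"nonresponder"`), a factor,
#'   or a labels data.frame aligned with the rows of `X`.
#' @return list: `weights` (unit-norm, named), `center`, `scale`.
#' @export
fit_weights <- function(X, y) {
  X <- as.matrix(X)
  yy <- code_response(y)
  if (length(yy) != nrow(X)) stop("X and y dimensions disagree", call. = FALSE)
  if (length(unique(yy)) < 2L) stop("response has a single class", call. = FALSE)
  if (min(table(yy)) < 2L) stop("need at least 2 samples per class", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  zero <- scl == 0
  if (any(zero))
    stop("zero-variance gene(s): ",
         paste(colnames(X)[zero], collapse = ", "), call. = FALSE)
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  yc <- yy - mean(yy)
  cv <- drop(crossprod(Xs, yc)) / (nrow(X) - 1)
  nrm <- sqrt(sum(cv^2))
  if (nrm == 0) stop("all predictor-response covariances are zero", call. = FALSE)
  w <- cv / nrm
  s <- drop(Xs %*% w)
  if (mean(s[yy == 1]) <= mean(s[yy == -1])) w <- -w
  list(weights = stats::setNames(w, colnames(X)),
       center = stats::setNames(ctr, colnames(X)),
       scale = stats::setNames(scl, colnames(X)))
}

#' Fit a complete single-component PLS classifier
#'
#' [fit_weights()] plus a decision threshold chosen by
#' [select_threshold()] on the training scores.
#'
#' @inheritParams fit_weights
#' @param reference_gene optional id of the qPCR internal reference the
#'   expression was normalized by; recorded in the model.
#' @return object of class `pls_model`: `panel`, `weights`, `threshold`,
#'   `center`, `scale`, `reference_gene`, `degenerate` (TRUE when all
#'   training scores coincide).
#' @export
pls_fit <- function(X, y, reference_gene = NA_character_) {
  fw <- fit_weights(X, y)
  model <- structure(list(panel = names(fw$weights), weights = fw$weights,
                          threshold = NA_real_, center = fw$center,
                          scale = fw$scale, reference_gene = reference_gene,
                          degenerate = FALSE),
                     class = "pls_model")
  s <- pls_score(model, X)
  thr <- select_threshold(s, y)
  model$threshold <- as.numeric(thr)
  model$degenerate <- isTRUE(attr(thr, "degenerate"))
  model
}

#' Linear PLS score
#'
#' S = sum_i W_i * (L_i - center_i) / scale_i over the panel genes.
#'
#' @param model a `pls_model` (threshold not required).
#' @param X samples x genes matrix containing every panel gene.
#' @return numeric score per sample.
#' @export
pls_score <- function(model, X) {
  X <- as.matrix(X)
  missing <- setdiff(model$panel, colnames(X))
  if (length(missing))
    stop("missing panel gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  Xp <- X[, model$panel, drop = FALSE]
  Xs <- sweep(sweep(Xp, 2L, model$center), 2L, model$scale, "/")
  drop(Xs %*% model$weights)
}

#' Youden-optimal score threshold
#'
#' Candidate cutoffs are the midpoints between adjacent distinct sorted
#' scores; the returned T maximizes Youden's J = sensitivity +
#' specificity - 1 under the rule "responder iff score > T", with ties
#' broken toward the smallest T. When all scores coincide J is 0
#' everywhere and that score is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param scores numeric scores.
#' @param y response labels as in [fit_weights()].
#' @return numeric threshold with attributes `youden` and `degenerate`.
#' @export
select_threshold <- function(scores, y) {
  yy <- code_response(y)
  if (length(unique(yy)) < 2L) stop("response has a single class", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) == 1L)
    return(structure(u, youden = 0, degenerate = TRUE))
  cand <- (u[-1] + u[-length(u)]) / 2
  pos <- scores[yy == 1]; neg <- scores[yy == -1]
  n1 <- length(pos); n2 <- length(neg)
  # maximize J on the integer scale n1*n2*J so exact ties break cleanly
  jn <- vapply(cand, function(t) sum(pos > t) * n2 + sum(neg <= t) * n1, 0)
  best <- which(jn == max(jn))[1L]          # candidates ascending: smallest T
  structure(cand[best], youden = max(jn) / (n1 * n2) - 1, degenerate = FALSE)
}

#' Predict responder status with a fitted PLS model
#'
#' A sample is called a responder iff its score strictly exceeds the
#' model threshold.
#'
#' @param object a `pls_model`.
#' @param newdata samples x genes matrix.
#' @param ... unused.
#' @return character vector of `"responder"` / `"nonresponder"`.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  s <- pls_score(object, newdata)
  ifelse(s > object$threshold, "responder", "nonresponder")
}
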