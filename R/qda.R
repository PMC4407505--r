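#' Median split into high/low preference classes
#'
#' Values above the median are labeled `"high"`, values below `"low"`.
#' Values exactly equal to the median are assigned alternately — starting
#' with whichever class is currently smaller (`"low"` on a tie) — so class
#' sizes stay balanced; 307 distinct values yield classes of 153 and 154.
#'
#' @param values numeric vector, length >= 4.
#' @return Character vector of `"high"` / `"low"` labels.
#' @examples
#' median_split(c(1, 2, 3, 4))
#' median_split(c(1, 2, 2, 3))  # the two ties split one to each class
#' @export
median_split <- function(values) {
  if (length(values) < 4) stop("need at least 4 values for a median split")
  if (length(unique(values)) == 1) {
    stop("degenerate split: all values identical")
  }
  med <- stats::median(values)
  labels <- ifelse(values > med, "high", ifelse(values < med, "low", NA))
  ties <- which(is.na(labels))
  n_high <- sum(labels == "high", na.rm = TRUE)
  n_low <- sum(labels == "low", na.rm = TRUE)
  for (i in ties) {
    labels[i] <- if (n_high < n_low) "high" else "low"
    if (labels[i] == "high") n_high <- n_high + 1 else n_low <- n_low + 1
  }
  labels
}

# Internal: per-class Gaussian log-density pieces from mean/covariance.
.gauss_model <- function(mu, sigma, what = "class") {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("singular covariance for ", what,
         "; consider reducing the feature subset", call. = FALSE)
  }
  list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))))
}

# Internal: log N(x; mu, Sigma) for rows of x, given a .gauss_model.
.gauss_logdens <- function(x, gm) {
  d <- length(gm$mu)
  z <- backsolve(gm$chol, t(x) - gm$mu, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + gm$logdet + colSums(z^2))
}

#' Fit a quadratic discriminant model
#'
#' Models each class as a multivariate Gaussian with its own mean vector and
#' covariance matrix (no homoscedasticity assumption; sample covariance with
#' `n_c - 1` denominator) and empirical class priors. The resulting decision
#' surface is quadratic.
#'
#' @param X numeric matrix or data frame of features.
#' @param labels class labels, one per row of `X`.
#' @return A `qd_model`: per-class means, covariances and priors, plus the
#'   feature names used.
#' @export
qd_fit <- function(X, labels) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stop("need at least two classes")
  d <- ncol(X)
  models <- lapply(classes, function(cl) {
    Xc <- X[labels == cl, , drop = FALSE]
    if (nrow(Xc) < d + 2) {
      stop("class ", cl, " has fewer than d + 2 = ", d + 2, " members")
    }
    gm <- .gauss_model(colMeans(Xc), stats::cov(Xc), paste("class", cl))
    gm$n <- nrow(Xc)
    gm$cov <- stats::cov(Xc)
    gm
  })
  names(models) <- classes
  structure(list(classes = classes, models = models,
                 priors = stats::setNames(
                   vapply(models, `[[`, 0, "n") / nrow(X), classes),
                 features = colnames(X)),
            class = "qd_model")
}

#' Classify observations with a quadratic discriminant model
#'
#' Assigns each row to the class with the highest posterior probability
#' (Gaussian class-conditional density times prior, normalized). Exact
#' posterior ties go to the first class in sorted label order.
#'
#' @param model a `qd_model` from [qd_fit()].
#' @param x numeric matrix (rows = observations) or vector (one observation).
#' @return List with `label` (character vector) and `posterior` (matrix,
#'   one column per class).
#' @export
qd_predict <- function(model, x) {
  stopifnot(inherits(model, "qd_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  logp <- vapply(model$classes, function(cl) {
    .gauss_logdens(x, model$models[[cl]]) + log(model$priors[[cl]])
  }, numeric(nrow(x)))
  if (is.null(dim(logp))) logp <- matrix(logp, nrow = 1)
  colnames(logp) <- model$classes
  m <- apply(logp, 1, max)
  post <- exp(logp - m)
  post <- post / rowSums(post)
  list(label = model$classes[max.col(post, ties.method = "first")],
       posterior = post)
}

# Internal: leave-one-out downdated Gaussian models for one class.
# Returns a list of .gauss_model objects, one per held-out row.
.downdated_models <- function(Xc) {
  n <- nrow(Xc)
  mu <- colMeans(Xc)
  m2 <- crossprod(Xc)
  lapply(seq_len(n), function(i) {
    x <- Xc[i, ]
    mu_i <- (n * mu - x) / (n - 1)
    cov_i <- (m2 - tcrossprod(x) - (n - 1) * tcrossprod(mu_i)) / (n - 2)
    .gauss_model(mu_i, cov_i, "downdated class")
  })
}

#' Pairwise leave-one-out QD prediction accuracy
#'
#' For every pair of one high-labeled and one low-labeled observation, trains
#' a quadratic discriminant on the remaining `n - 2` observations and
#' classifies both held-out points. Each pair contributes 0, 0.5 or 1
#' (fraction of its two points classified correctly); accuracy is the mean
#' over all `n_high * n_low` pairs. Chance level is 50%.
#'
#' Training models are obtained by downdating class sufficient statistics
#' (sums and scatter matrices) for the held-out points; results are identical
#' to refitting from scratch for each pair.
#'
#' @param X numeric matrix or data frame of features.
#' @param labels `"high"` / `"low"` labels from [median_split()].
#' @return A `loo_result`: list with `accuracy`, `pair_outcomes`
#'   (`n_high x n_low` matrix of 0/0.5/1), `per_image` (per-observation
#'   fraction of pairs classified correctly), `features`, `n_high`, `n_low`.
#' @export
loo_pairwise_accuracy <- function(X, labels) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("high", "low")))
  d <- ncol(X)
  Xh <- X[labels == "high", , drop = FALSE]
  Xl <- X[labels == "low", , drop = FALSE]
  nh <- nrow(Xh); nl <- nrow(Xl)
  if (nh < d + 3 || nl < d + 3) {
    stop("each class needs at least d + 3 members for pairwise LOO")
  }
  # Downdated models: removing one point from a class leaves the other class
  # untouched, so each pair (i, j) combines model H\i with model L\j.
  mh <- .downdated_models(Xh)
  ml <- .downdated_models(Xl)
  log_ph <- log((nh - 1) / (nh + nl - 2))
  log_pl <- log((nl - 1) / (nh + nl - 2))

  # Scores of held-out high points under their own downdated class model.
  s_hh <- vapply(seq_len(nh), function(i) {
    .gauss_logdens(Xh[i, , drop = FALSE], mh[[i]])
  }, 0) + log_ph
  s_ll <- vapply(seq_len(nl), function(j) {
    .gauss_logdens(Xl[j, , drop = FALSE], ml[[j]])
  }, 0) + log_pl
  # Cross scores: all high points under each downdated low model and v.v.
  s_hl <- vapply(ml, function(gm) .gauss_logdens(Xh, gm), numeric(nh)) + log_pl
  s_lh <- vapply(mh, function(gm) .gauss_logdens(Xl, gm), numeric(nl)) + log_ph
  if (is.null(dim(s_hl))) s_hl <- matrix(s_hl, nrow = nh)
  if (is.null(dim(s_lh))) s_lh <- matrix(s_lh, nrow = nl)

  correct_high <- s_hh >= s_hl            # nh x nl (ties predict "high")
  correct_low <- s_ll > s_lh              # nl x nh
  pair_outcomes <- (correct_high + t(correct_low)) / 2

  structure(list(
    accuracy = mean(pair_outcomes),
    pair_outcomes = pair_outcomes,
    per_image = stats::setNames(
      c(rowMeans(correct_high), rowMeans(correct_low)),
      c(paste0("high_", seq_len(nh)), paste0("low_", seq_len(nl)))),
    features = colnames(X), n_high = nh, n_low = nl
  ), class = "loo_result")
}

#' Greedy backward feature elimination under pairwise LOO accuracy
#'
#' Starting from `start_features`, repeatedly drops the single feature whose
#' removal most increases the pairwise leave-one-out QD accuracy, stopping
#' when no removal improves on the current accuracy. Ties are broken
#' deterministically by dropping the later-listed feature. Subsets whose QD
#' fit fails (singular class covariance, e.g. perfectly collinear features)
#' score `NA` and any valid removal counts as an improvement over them.
#'
#' @param X numeric matrix or data frame of features.
#' @param labels `"high"` / `"low"` labels.
#' @param start_features feature names to start from (default all columns).
#' @return List with `features` (the selected subset), `accuracy`, and
#'   `trace`, a tibble logging each elimination step.
#' @export
backward_elimination <- function(X, labels, start_features = NULL) {
  X <- as.data.frame(X)
  if (is.null(start_features)) start_features <- names(X)
  evaluate <- function(feats) {
    tryCatch(loo_pairwise_accuracy(X[, feats, drop = FALSE], labels)$accuracy,
             error = function(e) NA_real_)
  }
  current <- start_features
  acc <- evaluate(current)
  trace <- tibble::tibble(step = 0L, dropped = NA_character_,
                          n_features = length(current), accuracy = acc)
  step <- 0L
  while (length(current) > 1) {
    cand <- vapply(current, function(f) evaluate(setdiff(current, f)), 0)
    if (all(is.na(cand))) break
    best <- max(cand, na.rm = TRUE)
    improves <- if (is.na(acc)) TRUE else best > acc
    if (!improves) break
    # later-listed feature dropped on ties
    drop_f <- current[max(which(!is.na(cand) & cand == best))]
    current <- setdiff(current, drop_f)
    acc <- best
    step <- step + 1L
    trace <- rbind(trace, tibble::tibble(step = step, dropped = drop_f,
                                         n_features = length(current),
                                         accuracy = acc))
  }
  list(features = current, accuracy = acc, trace = trace)
}
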