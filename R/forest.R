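#' Train the slide-level random-forest classifier
#'
#' Fits a bagged ensemble of CART trees (Gini splits, per-split feature
#' subsampling) mapping slide feature vectors to the five TBS slide
#' grades. Class probabilities are the across-tree average of leaf
#' class distributions; out-of-bag (OOB) accuracy is reported from the
#' bootstrap.
#'
#' @param X Numeric feature matrix (slides in rows) from
#'   [extract_feature_matrix()], or a list of feature vectors.
#' @param labels Character vector of true slide grades; at least two
#'   distinct grades required.
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param min_node Minimum samples per child node (default 1).
#' @param max_depth Maximum tree depth (default 25).
#' @param seed Integer seed making training reproducible
#'   (default 20140101).
#' @return A `slide_classifier` with elements `trees`, `importance`,
#'   `oob_accuracy`, `feature_names`, `classes`, `seed`.
#' @export
train_slide_classifier <- function(X, labels, ntree = 500, mtry = NULL,
                                   min_node = 1, max_depth = 25,
                                   seed = 20140101) {
  if (is.list(X) && !is.matrix(X)) X <- do.call(rbind, X)
  stopifnot(is.matrix(X), nrow(X) == length(labels))
  .assert_slide_grade(labels)
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class; need at least two ",
         "slide grades to fit a classifier")
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  classes <- slide_grades()
  y <- match(labels, classes) - 1L
  set.seed(seed)
  fit <- cpp_rf_train(X, as.integer(y), length(classes), as.integer(ntree),
                      as.integer(mtry), as.integer(min_node),
                      as.integer(max_depth))
  oob_ok <- fit$oob_n > 0
  oob_pred <- classes[max.col(fit$oob_prob[oob_ok, , drop = FALSE],
                              ties.method = "first")]
  structure(
    list(trees = fit$trees,
         importance = setNames(as.numeric(fit$importance), colnames(X)),
         oob_accuracy = mean(oob_pred == labels[oob_ok]),
         feature_names = colnames(X), classes = classes,
         ntree = ntree, mtry = mtry, seed = seed),
    class = "slide_classifier"
  )
}

#' @export
print.slide_classifier <- function(x, ...) {
  cat(sprintf("<slide_classifier> %d trees, mtry %d, %d features\n",
              x$ntree, x$mtry, length(x$feature_names)))
  cat(sprintf("  OOB accuracy: %.3f\n", x$oob_accuracy))
  invisible(x)
}

.predict_prob_matrix <- function(model, X) {
  stopifnot(inherits(model, "slide_classifier"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1,
                                 dimnames = list(NULL, names(X)))
  if (ncol(X) != length(model$feature_names)) {
    stop("feature length (", ncol(X), ") does not match the model (",
         length(model$feature_names), ")")
  }
  P <- cpp_rf_predict(model$trees, X, length(model$classes))
  colnames(P) <- model$classes
  P
}

.argmax_severity <- function(p, classes) {
  # argmax with severity tie-break: among near-tied maxima the more
  # severe grade wins (screening favours sensitivity)
  sev <- slide_grade_severity()
  top <- which(p >= max(p) - 1e-12)
  cand <- classes[top]
  cand[which.max(match(cand, sev))]
}

#' Predict a slide grade with probabilities and abnormality score
#'
#' Grade is the probability argmax with ties broken toward the more
#' severe grade. The abnormality score is `1 - P(NILM)`; per-stratum
#' scores are sums of member-grade probabilities (see
#' [stratum_score()]).
#'
#' @param model A fitted `slide_classifier`.
#' @param f One feature vector, or a matrix of them (rows = slides).
#' @return For a single vector: list with `grade`, `prob` (named
#'   probability vector), `abnormality`. For a matrix: list with
#'   `grade` (character vector), `prob` (matrix), `abnormality`
#'   (vector).
#' @export
predict_slide_grade <- function(model, f) {
  P <- .predict_prob_matrix(model, f)
  grade <- apply(P, 1, .argmax_severity, classes = model$classes)
  abnormality <- 1 - P[, "NILM"]
  if (nrow(P) == 1) {
    list(grade = grade[[1]], prob = P[1, ], abnormality = unname(abnormality))
  } else {
    list(grade = unname(grade), prob = P, abnormality = unname(abnormality))
  }
}

#' @export
predict.slide_classifier <- function(object, newdata, ...) {
  predict_slide_grade(object, newdata)
}

#' Risk-stratum score from slide-grade probabilities
#'
#' Sum of the probabilities of the stratum's member slide grades, e.g.
#' `P(HSIL+)` for the HSIL+ stratum or
#' `P(ASC-US) + P(LSIL) + P(HSIL+)` for ASC-US+.
#'
#' @param prob Named probability vector (or matrix with named columns)
#'   over [slide_grades()].
#' @param stratum One of [risk_strata()].
#' @return Numeric score(s) in `[0, 1]`.
#' @export
stratum_score <- function(prob, stratum) {
  members <- slide_grades()[stratum_membership(slide_grades(), stratum)]
  if (is.matrix(prob)) rowSums(prob[, members, drop = FALSE])
  else sum(prob[members])
}

#' Top-k feature importances
#'
#' Mean decrease in Gini impurity accumulated over the ensemble,
#' ranked descending. Deterministic for a fixed training seed.
#'
#' @param model A fitted `slide_classifier`.
#' @param k Number of features to return (default 20; capped at the
#'   feature count).
#' @return Data frame with columns `feature`, `importance`.
#' @export
feature_importances <- function(model, k = 20) {
  if (!inherits(model, "slide_classifier")) {
    stop("`model` must be a fitted slide_classifier")
  }
  imp <- sort(model$importance, decreasing = TRUE)
  k <- min(k, length(imp))
  data.frame(feature = names(imp)[seq_len(k)],
             importance = unname(imp[seq_len(k)]))
}

#' Serialize / restore a fitted slide classifier
#'
#' Writes the model to a single artifact with version metadata (an RDS
#' payload; a runtime artifact, not a source file).
#'
#' @param model A `slide_classifier`.
#' @param path Artifact path.
#' @return `write_slide_classifier` returns `path` invisibly.
#' @export
write_slide_classifier <- function(model, path) {
  stopifnot(inherits(model, "slide_classifier"))
  saveRDS(list(format = "cytoscreen/slide_classifier",
               package_version = as.character(packageVersion("cytoscreen")),
               created = format(Sys.time(), tz = "UTC"),
               model = model),
          path)
  invisible(path)
}

#' @rdname write_slide_classifier
#' @export
read_slide_classifier <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "cytoscreen/slide_classifier")) {
    stop("not a cytoscreen slide_classifier artifact")
  }
  x$model
}
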