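# Feature construction (CSP log-likelihood scores, PCA-reduced
# enrichment and all-states blocks), logistic classifiers of risk vs.
# null variants, and precision-recall evaluation under repeated splits.

#' CSP log-likelihood features
#'
#' For each variant, the Dirichlet-multinomial log marginal of its
#' state vector under each catalog pattern: C scores per variant.
#'
#' @param variant_states n x N integer matrix (or a \code{VariantSet}).
#' @param catalog fitted \code{CSPCatalog}.
#' @param alpha Dirichlet state prior; defaults to the catalog's.
#' @return n x C numeric matrix (columns \code{csp1..cspC}).
#' @export
csp_features <- function(variant_states, catalog, alpha = NULL) {
  if (inherits(variant_states, "VariantSet"))
    variant_states <- variant_states$states
  if (is.null(alpha)) alpha <- catalog$alpha
  C <- length(catalog$patterns)
  if (C == 0L) stop("empty catalog")
  out <- vapply(seq_len(C), function(c)
    position_log_marginal(variant_states, catalog$patterns[[c]],
                          alpha), numeric(nrow(variant_states)))
  out <- matrix(out, nrow = nrow(variant_states))
  colnames(out) <- paste0("csp", seq_len(C))
  out
}

## Principal-component map: centers (no rescaling; inputs share a
## scale) and keeps at most n_components full-rank directions.
.fit_component_map <- function(x, n_components) {
  if (nrow(x) < 2L) stop("need at least two rows to fit components")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  keep <- min(n_components, rank)
  if (keep < n_components)
    warning("input rank ", rank, " below requested ", n_components,
            " components; returning ", keep)
  list(center = pc$center,
       rotation = pc$rotation[, seq_len(keep), drop = FALSE],
       sdev = pc$sdev[seq_len(keep)], n_components = keep)
}

.apply_component_map <- function(x, map) {
  sweep(x, 2L, map$center) %*% map$rotation
}

#' PCA-reduced state-enrichment features
#'
#' Builds the transformed (sign-log) state-by-cluster z-scores of each
#' variant and projects them onto the leading principal components
#' learned from the training variants. Pass the returned \code{map} to
#' project test variants with the training components.
#'
#' @param variant_states n x N matrix or \code{VariantSet}.
#' @param clusters a \code{ClusterDefinition}.
#' @param S number of states.
#' @param n_components components to retain (capped at the input rank,
#'   with a warning).
#' @param map a previously fitted component map (test projection).
#' @return list with \code{features} (n x k matrix) and \code{map}.
#' @export
enrichment_features <- function(variant_states, clusters, S,
                                n_components = 48, map = NULL) {
  if (inherits(variant_states, "VariantSet"))
    variant_states <- variant_states$states
  z <- variant_zscores(variant_states, clusters, S, transformed = TRUE)
  if (is.null(map)) map <- .fit_component_map(z, n_components)
  list(features = .apply_component_map(z, map), map = map)
}

#' PCA-reduced all-states indicator features
#'
#' One-hot encodes the state of every epigenome (S x N indicator
#' columns per variant; each row sums to N) and reduces to the leading
#' principal components.
#'
#' @inheritParams enrichment_features
#' @param N number of epigenomes.
#' @return list with \code{features} and \code{map}.
#' @export
allstate_features <- function(variant_states, S, N = NULL,
                              n_components = 96, map = NULL) {
  if (inherits(variant_states, "VariantSet"))
    variant_states <- variant_states$states
  if (is.null(N)) N <- ncol(variant_states)
  stopifnot(ncol(variant_states) == N)
  n <- nrow(variant_states)
  ind <- matrix(0, n, S * N)
  for (i in seq_len(N)) {
    ind[cbind(seq_len(n),
              (i - 1L) * S + variant_states[, i])] <- 1
  }
  colnames(ind) <- paste0("e", rep(seq_len(N), each = S), "_s",
                          rep(seq_len(S), N))
  if (is.null(map)) map <- .fit_component_map(ind, n_components)
  list(features = .apply_component_map(ind, map), map = map)
}

#' One-hot indicator matrix of all epigenome states (no reduction)
#'
#' @inheritParams allstate_features
#' @return n x (S*N) 0/1 matrix.
#' @export
allstate_indicators <- function(variant_states, S, N = NULL) {
  if (inherits(variant_states, "VariantSet"))
    variant_states <- variant_states$states
  if (is.null(N)) N <- ncol(variant_states)
  n <- nrow(variant_states)
  ind <- matrix(0, n, S * N)
  for (i in seq_len(N))
    ind[cbind(seq_len(n), (i - 1L) * S + variant_states[, i])] <- 1
  ind
}

#' Fit a logistic risk-vs-null classifier
#'
#' Plain binomial GLM; on complete separation (fitted probabilities
#' degenerate) the fit falls back to a weak ridge penalty so scores
#' stay finite and ordered.
#'
#' @param features numeric matrix (rows = variants).
#' @param labels \code{"risk"}/\code{"null"} or 0/1 vector.
#' @return object of class \code{csp_glm} with a
#'   \code{\link{predict_scores}} method.
#' @export
train_glm <- function(features, labels) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "risk") else as.integer(labels)
  stopifnot(length(y) == nrow(features), all(y %in% c(0L, 1L)))
  x <- as.matrix(features)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, x), y,
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || any(!is.finite(fit$coefficients))) {
    varying <- which(apply(x, 2L, function(v) stats::var(v) > 0))
    coef <- c(stats::qlogis(mean(y)), rep(0, ncol(x)))
    if (length(varying) == 1L) {
      ## glmnet needs >= 2 columns; a duplicated column shares the
      ## ridge coefficient, so the sum recovers the effective slope
      rf <- glmnet::glmnet(x[, c(varying, varying), drop = FALSE], y,
                           family = "binomial", alpha = 0,
                           lambda = 1e-3, standardize = FALSE)
      coef[1L] <- as.numeric(rf$a0)
      coef[1L + varying] <- sum(as.numeric(rf$beta))
    } else if (length(varying) > 1L) {
      rf <- glmnet::glmnet(x[, varying, drop = FALSE], y,
                           family = "binomial", alpha = 0,
                           lambda = 1e-3, standardize = FALSE)
      coef[1L] <- as.numeric(rf$a0)
      coef[1L + varying] <- as.numeric(rf$beta)
    }
  } else {
    coef <- fit$coefficients
    coef[is.na(coef)] <- 0
  }
  structure(list(coef = coef, ridge = separated), class = "csp_glm")
}

#' Score variants with a fitted classifier
#'
#' @param model a \code{csp_glm} from \code{\link{train_glm}}.
#' @param features matrix with the training columns.
#' @return risk probabilities in (0, 1).
#' @export
predict_scores <- function(model, features) {
  eta <- drop(cbind(1, as.matrix(features)) %*% model$coef)
  stats::plogis(eta)
}

#' Precision-recall AUC (average precision)
#'
#' Step-wise average precision: variants are ranked by decreasing
#' score (ties broken by input order) and precision is averaged at the
#' rank of every positive.
#'
#' @param scores numeric prediction scores.
#' @param labels \code{"risk"}/\code{"null"} or 0/1.
#' @return value in [0, 1].
#' @export
pr_auc <- function(scores, labels) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "risk") else as.integer(labels)
  stopifnot(length(scores) == length(y))
  if (sum(y) == 0L || sum(y) == length(y))
    stop("pr_auc needs at least one positive and one negative")
  ord <- order(-scores)
  ys <- y[ord]
  prec <- cumsum(ys) / seq_along(ys)
  mean(prec[ys == 1L])
}

#' Per-cell-type categorical classifier
#'
#' Uses one epigenome's state as a categorical predictor. Levels absent
#' from training collapse to the reference level at test time.
#'
#' @param train_states,test_states integer state vectors of the chosen
#'   epigenome.
#' @param train_labels labels for the training variants.
#' @param S number of states.
#' @return test scores (risk probabilities).
#' @export
single_celltype_scores <- function(train_states, train_labels,
                                   test_states, S) {
  levels_seen <- sort(unique(train_states))
  enc <- function(x) {
    ## indicator columns for non-reference seen levels; unseen -> all 0
    ref <- levels_seen[1L]
    cols <- setdiff(levels_seen, ref)
    out <- matrix(0, length(x), length(cols))
    for (ci in seq_along(cols)) out[, ci] <- as.numeric(x == cols[ci])
    out
  }
  if (length(levels_seen) == 1L) {
    ## constant predictor: intercept-only model
    p <- mean(if (is.character(train_labels)) train_labels == "risk"
              else train_labels == 1)
    return(rep(p, length(test_states)))
  }
  model <- train_glm(enc(train_states), train_labels)
  predict_scores(model, enc(test_states))
}

#' Select the best single cell type on training data
#'
#' Splits the training half again (internally, 50/50, seeded by the
#' caller's RNG state) and picks the epigenome whose categorical state
#' predictor attains the highest PR-AUC; ties go to the lowest index.
#' Selection never sees the test half.
#'
#' @param train_states n x N matrix of training-variant states.
#' @param train_labels training labels.
#' @param S number of states.
#' @return epigenome column index.
#' @export
select_best_celltype <- function(train_states, train_labels, S) {
  n <- nrow(train_states)
  y <- if (is.character(train_labels) || is.factor(train_labels))
    as.integer(as.character(train_labels) == "risk")
  else as.integer(train_labels)
  idx_pos <- which(y == 1L); idx_neg <- which(y == 0L)
  sel <- c(sample(idx_pos, ceiling(length(idx_pos) / 2)),
           sample(idx_neg, ceiling(length(idx_neg) / 2)))
  hold <- setdiff(seq_len(n), sel)
  if (length(hold) == 0L || sum(y[hold]) == 0L ||
      sum(y[hold]) == length(hold)) {
    sel <- seq_len(n); hold <- seq_len(n)  # degenerate: score in-sample
  }
  aucs <- vapply(seq_len(ncol(train_states)), function(i) {
    sc <- single_celltype_scores(train_states[sel, i], y[sel],
                                 train_states[hold, i], S)
    if (sum(y[hold]) == 0L || sum(y[hold]) == length(hold)) return(0)
    pr_auc(sc, y[hold])
  }, numeric(1))
  which.max(aucs)
}

#' Evaluate risk-vs-null prediction for one trait
#'
#' Repeated 50/50 splits of the risk and null variants; the classifier,
#' any principal-component map and the best-cell-type choice are fitted
#' on the training half only and scored on the held-out half by
#' precision-recall AUC. Risk variants are split by LD cluster (a lead
#' variant and its proxies stay in the same half) so tightly linked
#' near-duplicates cannot leak between training and testing. Repeats
#' with fewer than \code{min_per_side} risk variants in either half are
#' skipped (trait-removal rule).
#'
#' @param risk,null \code{VariantSet}s for the trait.
#' @param feature_set \code{"csp+enrichment"}, \code{"all-states"} or
#'   \code{"single-cell-type"}.
#' @param catalog fitted \code{CSPCatalog} (needed for
#'   \code{"csp+enrichment"}).
#' @param clusters \code{ClusterDefinition} (ditto).
#' @param S number of states.
#' @param n_repeats independent splits.
#' @param split training fraction.
#' @param n_components components for the enrichment block (the
#'   all-states model uses \code{2 * n_components} to match widths).
#' @param min_per_side minimum risk variants per half.
#' @param seed integer seed.
#' @return list of class \code{EvalResult}: \code{aucs} per completed
#'   repeat, \code{mean_auc}, \code{n_repeats}, \code{feature_set}.
#' @export
evaluate_trait <- function(risk, null, feature_set = "csp+enrichment",
                           catalog = NULL, clusters = NULL, S,
                           n_repeats = 10, split = 0.5,
                           n_components = 48, min_per_side = 5,
                           seed = NULL) {
  feature_set <- match.arg(feature_set,
                           c("csp+enrichment", "all-states",
                             "single-cell-type"))
  if (!is.null(seed)) set.seed(seed)
  Xr <- risk$states; Xn <- null$states
  nr <- nrow(Xr); nn <- nrow(Xn)
  clus <- as.character(risk$variants$ld_cluster)
  clev <- unique(clus)
  aucs <- numeric(0)
  for (rep_i in seq_len(n_repeats)) {
    tr_clus <- sample(clev, floor(length(clev) * split))
    tr_r <- which(clus %in% tr_clus)
    tr_n <- sample.int(nn, floor(nn * split))
    te_r <- setdiff(seq_len(nr), tr_r)
    te_n <- setdiff(seq_len(nn), tr_n)
    if (length(tr_r) < min_per_side || length(te_r) < min_per_side) {
      warning("repeat ", rep_i, " skipped: fewer than ", min_per_side,
              " risk variants in a half")
      next
    }
    x_tr <- rbind(Xr[tr_r, , drop = FALSE], Xn[tr_n, , drop = FALSE])
    x_te <- rbind(Xr[te_r, , drop = FALSE], Xn[te_n, , drop = FALSE])
    y_tr <- c(rep(1L, length(tr_r)), rep(0L, length(tr_n)))
    y_te <- c(rep(1L, length(te_r)), rep(0L, length(te_n)))
    if (feature_set == "csp+enrichment") {
      f_csp_tr <- csp_features(x_tr, catalog)
      f_en <- enrichment_features(x_tr, clusters, S,
                                  n_components = n_components)
      f_tr <- cbind(f_csp_tr, f_en$features)
      f_te <- cbind(csp_features(x_te, catalog),
                    enrichment_features(x_te, clusters, S,
                                        map = f_en$map)$features)
      model <- train_glm(f_tr, y_tr)
      sc <- predict_scores(model, f_te)
    } else if (feature_set == "all-states") {
      f_all <- allstate_features(x_tr, S,
                                 n_components = 2 * n_components)
      model <- train_glm(f_all$features, y_tr)
      sc <- predict_scores(model, allstate_features(
        x_te, S, map = f_all$map)$features)
    } else {
      best <- select_best_celltype(x_tr, y_tr, S)
      sc <- single_celltype_scores(x_tr[, best], y_tr, x_te[, best], S)
    }
    aucs <- c(aucs, pr_auc(sc, y_te))
  }
  structure(list(aucs = aucs,
                 mean_auc = if (length(aucs)) mean(aucs) else NA_real_,
                 n_repeats = length(aucs), feature_set = feature_set),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("EvalResult [%s]: mean PR-AUC %.3f over %d repeats\n",
              x$feature_set, x$mean_auc, x$n_repeats))
  invisible(x)
}

#' Sample MAF- and annotation-matched null variants
#'
#' Bins minor allele frequencies at \code{maf_bin_width} and samples,
#' without replacement, nulls from the pool so the joint
#' (MAF bin x annotation) histogram matches the risk variants. When an
#' occupied cell is empty in the pool the nearest MAF bin within the
#' same annotation (then any annotation) supplies the shortfall, with a
#' warning.
#'
#' @param risk \code{VariantSet} of risk variants.
#' @param pool \code{VariantSet} of candidate nulls.
#' @param maf_bin_width bin width on [0, 0.5].
#' @param seed integer seed.
#' @return a \code{VariantSet} of matched nulls.
#' @export
match_nulls <- function(risk, pool, maf_bin_width = 0.05,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bin <- function(maf) pmin(floor(maf / maf_bin_width),
                            ceiling(0.5 / maf_bin_width) - 1L)
  rb <- bin(risk$variants$maf); pb <- bin(pool$variants$maf)
  ra <- risk$variants$annotation; pa <- pool$variants$annotation
  taken <- rep(FALSE, length(pb))
  picked <- integer(0)
  cells <- unique(data.frame(b = rb, a = ra))
  fallback_used <- FALSE
  for (ci in seq_len(nrow(cells))) {
    b <- cells$b[ci]; a <- cells$a[ci]
    need <- sum(rb == b & ra == a)
    avail <- which(!taken & pb == b & pa == a)
    take <- if (length(avail) <= need) avail else
      sample(avail, need)
    short <- need - length(take)
    if (short > 0) {
      fallback_used <- TRUE
      cand <- which(!taken & pa == a & !(seq_along(pb) %in% take))
      if (length(cand) < short)
        cand <- which(!taken & !(seq_along(pb) %in% take))
      if (length(cand) < short)
        stop("null pool exhausted while matching")
      cand <- cand[order(abs(pb[cand] - b))]
      take <- c(take, cand[seq_len(short)])
    }
    taken[take] <- TRUE
    picked <- c(picked, take)
  }
  if (fallback_used)
    warning("empty (maf bin x annotation) cell in pool; ",
            "nearest-bin fallback used")
  pool[sort(picked)]
}
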