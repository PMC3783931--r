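#' Gini diversity index
#'
#' Node impurity `1 - sum(p_c^2)` over the class proportions of a label
#' vector. Zero for a pure node; 0.5 for a balanced binary node.
#'
#' @param labels non-empty vector of class labels (any atomic type).
#' @return Gini impurity in \[0, 1).
#' @export
gini_impurity <- function(labels) {
  if (!length(labels)) stop("'labels' must be non-empty")
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

#' Fit a classification tree by Gini impurity optimization
#'
#' Greedy recursive binary partitioning in the CART style: at each node,
#' every feature and every candidate threshold (midpoints between
#' consecutive distinct sorted values) is scored by the decrease in Gini
#' impurity, and the best split is taken. Ties are broken deterministically
#' by feature order (column order of `features`) and then by the lowest
#' threshold; the first best split encountered in that scan order wins.
#' Splitting stops on node purity, fewer than `2 * min_leaf` samples, depth
#' `max_depth`, or when no split with a strictly positive impurity decrease
#' leaves both children with at least `min_leaf` samples. Leaf labels are
#' the majority class (ties to the class that sorts first). Binary flags
#' are treated as numeric 0/1 features (split at 0.5).
#'
#' @param features data frame of numeric/logical predictor columns, no
#'   missing values (imputation is out of scope).
#' @param labels binary class vector, length `nrow(features)`.
#' @param min_leaf minimum samples per leaf (default 5).
#' @param max_depth maximum tree depth (default 4; the root is depth 0).
#' @return An object of class `stroke_cart` wrapping the root node. Each
#'   node carries `n_samples`, `impurity`, `label` (majority class),
#'   `split` (`NULL` for leaves, else `variable`, `threshold`, `decrease`)
#'   and `left`/`right` children (left: `value < threshold`).
#' @export
fit_cart <- function(features, labels, min_leaf = 5L, max_depth = 4L) {
  features <- as.data.frame(features)
  if (!nrow(features)) stop("no samples")
  if (nrow(features) != length(labels))
    stop("'labels' length must match the number of feature rows")
  if (nrow(features) < 2 * min_leaf)
    stop("need at least 2 * min_leaf samples")
  X <- vapply(features, function(col) {
    if (is.logical(col)) col <- as.numeric(col)
    if (!is.numeric(col)) stop("features must be numeric or logical")
    col
  }, numeric(nrow(features)))
  X <- matrix(X, nrow = nrow(features),
              dimnames = list(NULL, names(features)))
  if (anyNA(X)) stop("missing feature values are not supported")
  if (anyNA(labels)) stop("missing labels are not supported")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) > 2) stop("only binary labels are supported")
  root <- .grow_node(X, labels, classes, depth = 0L,
                     min_leaf = as.integer(min_leaf),
                     max_depth = as.integer(max_depth))
  structure(list(root = root, classes = classes,
                 variables = colnames(X),
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth)),
            class = "stroke_cart")
}

.gini_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

.majority <- function(labels, classes) {
  counts <- table(factor(labels, levels = classes))
  classes[which.max(counts)] # ties: first in sorted class order
}

.grow_node <- function(X, labels, classes, depth, min_leaf, max_depth) {
  n <- length(labels)
  imp <- gini_impurity(labels)
  node <- list(n_samples = n, impurity = imp,
               label = .majority(labels, classes),
               depth = depth, split = NULL, left = NULL, right = NULL)
  if (imp == 0 || n < 2 * min_leaf || depth >= max_depth) return(node)
  best <- .best_split(X, labels, classes, min_leaf)
  if (is.null(best)) return(node)
  node$split <- best[c("variable", "threshold", "decrease")]
  go_left <- X[, best$j] < best$threshold
  node$left <- .grow_node(X[go_left, , drop = FALSE], labels[go_left],
                          classes, depth + 1L, min_leaf, max_depth)
  node$right <- .grow_node(X[!go_left, , drop = FALSE], labels[!go_left],
                           classes, depth + 1L, min_leaf, max_depth)
  node
}

# scan features in column order, thresholds ascending; keep the first split
# with the strictly largest impurity decrease
.best_split <- function(X, labels, classes, min_leaf) {
  n <- length(labels)
  parent_imp <- gini_impurity(labels)
  y <- labels == classes[length(classes)] # indicator of the last class
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]
    ys <- y[ord]
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    cum_pos <- cumsum(ys)
    nl <- distinct                       # left sizes at each cut
    keep <- nl >= min_leaf & (n - nl) >= min_leaf
    if (!any(keep)) next
    nl <- nl[keep]
    cuts <- distinct[keep]
    thr <- (xs[cuts] + xs[cuts + 1]) / 2
    pos_l <- cum_pos[cuts]
    pos_r <- sum(ys) - pos_l
    nr <- n - nl
    gini_l <- 1 - ((pos_l / nl)^2 + ((nl - pos_l) / nl)^2)
    gini_r <- 1 - ((pos_r / nr)^2 + ((nr - pos_r) / nr)^2)
    dec <- parent_imp - (nl * gini_l + nr * gini_r) / n
    k <- which.max(dec) # first maximum -> lowest threshold on ties
    if (dec[k] > 1e-12 && (is.null(best) || dec[k] > best$decrease + 1e-12)) {
      best <- list(variable = colnames(X)[j], j = j, threshold = thr[k],
                   decrease = dec[k])
    }
  }
  best
}

#' @export
print.stroke_cart <- function(x, ...) {
  cat("<stroke_cart> classification tree (Gini impurity)\n")
  .print_node(x$root, indent = "")
  invisible(x)
}

.print_node <- function(node, indent) {
  if (is.null(node$split)) {
    cat(sprintf("%s* leaf: %s (n = %d, gini = %.3f)\n",
                indent, node$label, node$n_samples, node$impurity))
  } else {
    cat(sprintf("%s%s < %.4g? (n = %d, gini = %.3f, decrease = %.4f)\n",
                indent, node$split$variable, node$split$threshold,
                node$n_samples, node$impurity, node$split$decrease))
    .print_node(node$left, paste0(indent, "  "))
    .print_node(node$right, paste0(indent, "  "))
  }
}

#' Predict classes from a fitted tree
#'
#' @param object a `stroke_cart`.
#' @param newdata data frame with the training feature columns.
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.stroke_cart <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  vapply(seq_len(nrow(newdata)), function(i) {
    node <- object$root
    while (!is.null(node$split)) {
      v <- as.numeric(newdata[[node$split$variable]][i])
      node <- if (v < node$split$threshold) node$left else node$right
    }
    node$label
  }, character(1))
}

#' Convert a fitted tree to a plain nested list (JSON-ready)
#'
#' @param tree a `stroke_cart` (or a node of one).
#' @return Nested list mirroring the tree structure.
#' @export
cart_to_list <- function(tree) {
  node <- if (inherits(tree, "stroke_cart")) tree$root else tree
  if (is.null(node$split)) {
    list(leaf = TRUE, label = node$label, n_samples = node$n_samples,
         impurity = node$impurity)
  } else {
    list(leaf = FALSE, variable = node$split$variable,
         threshold = node$split$threshold,
         impurity_decrease = node$split$decrease,
         n_samples = node$n_samples, impurity = node$impurity,
         left = cart_to_list(node$left), right = cart_to_list(node$right))
  }
}

# depth of the first split on each variable (Inf when unused); used to
# inspect whether a tree recovers a known generating hierarchy
.split_depths <- function(tree) {
  depths <- stats::setNames(rep(Inf, length(tree$variables)),
                            tree$variables)
  walk <- function(node) {
    if (is.null(node$split)) return(invisible())
    v <- node$split$variable
    depths[v] <<- min(depths[v], node$depth)
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  depths
}
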