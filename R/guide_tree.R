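#' @name guide_tree
#' @title Gain-ratio decision tree over study characteristics
#'
#' @description
#' A small C4.5-family classifier used as a guide for predicting which
#' retention pattern a planned study is likely to produce from its coded
#' characteristics. Splits are chosen by information gain ratio (information
#' gain divided by the split information); numeric predictors get binary
#' threshold splits at candidate midpoints, categorical predictors split
#' multiway on their observed levels. This is a generic gain-ratio tree: no
#' attempt is made to match any particular C4.5 implementation's pruning or
#' tie-breaking byte for byte.
NULL

entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Best split of one predictor; returns NULL if nothing improves.
best_split <- function(x, labels, min_leaf) {
  n <- length(labels)
  h0 <- entropy(labels)
  if (is.numeric(x)) {
    ux <- sort(unique(x))
    if (length(ux) < 2L) return(NULL)
    cuts <- (ux[-1L] + ux[-length(ux)]) / 2
    best <- NULL
    for (cut in cuts) {
      left <- x <= cut
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      h <- (nl * entropy(labels[left]) +
              (n - nl) * entropy(labels[!left])) / n
      gain <- h0 - h
      split_info <- entropy(left)
      if (gain <= 1e-12 || split_info <= 1e-12) next
      ratio <- gain / split_info
      if (is.null(best) || ratio > best$ratio) {
        best <- list(type = "numeric", threshold = cut, ratio = ratio,
                     gain = gain)
      }
    }
    best
  } else {
    x <- as.character(x)
    lvls <- unique(x)
    if (length(lvls) < 2L) return(NULL)
    sizes <- table(x)
    if (any(sizes < min_leaf)) return(NULL)
    h <- sum(vapply(lvls, function(l) {
      sum(x == l) * entropy(labels[x == l])
    }, numeric(1))) / n
    gain <- h0 - h
    split_info <- entropy(x)
    if (gain <= 1e-12 || split_info <= 1e-12) return(NULL)
    list(type = "categorical", levels = lvls, ratio = gain / split_info,
         gain = gain)
  }
}

leaf_node <- function(labels) {
  dist <- table(labels)
  list(kind = "leaf", class = names(dist)[which.max(dist)],
       n = length(labels), dist = as.list(dist))
}

grow_tree <- function(data, labels, predictors, depth, max_depth, min_leaf,
                      min_split) {
  if (depth >= max_depth || length(labels) < min_split ||
      length(unique(labels)) == 1L) {
    return(leaf_node(labels))
  }
  splits <- lapply(predictors, function(p) best_split(data[[p]], labels,
                                                      min_leaf))
  names(splits) <- predictors
  splits <- Filter(Negate(is.null), splits)
  if (!length(splits)) return(leaf_node(labels))
  ratios <- vapply(splits, `[[`, numeric(1), "ratio")
  pred <- names(splits)[which.max(ratios)]
  sp <- splits[[pred]]
  node <- list(kind = "split", predictor = pred, n = length(labels),
               dist = as.list(table(labels)))
  if (sp$type == "numeric") {
    node$threshold <- sp$threshold
    left <- data[[pred]] <= sp$threshold
    node$children <- list(
      le = grow_tree(data[left, , drop = FALSE], labels[left], predictors,
                     depth + 1L, max_depth, min_leaf, min_split),
      gt = grow_tree(data[!left, , drop = FALSE], labels[!left], predictors,
                     depth + 1L, max_depth, min_leaf, min_split)
    )
  } else {
    node$levels <- sp$levels
    node$children <- lapply(sp$levels, function(l) {
      keep <- as.character(data[[pred]]) == l
      grow_tree(data[keep, , drop = FALSE], labels[keep], predictors,
                depth + 1L, max_depth, min_leaf, min_split)
    })
    names(node$children) <- sp$levels
  }
  node
}

#' Train the guide tree
#'
#' @param characteristics Characteristics data frame.
#' @param labels Category label per row (the training classes).
#' @param predictors Columns to consider for splits.
#' @param max_depth Maximum tree depth (root is depth 0).
#' @param min_leaf Minimum records in any child of a split.
#' @param min_split Minimum records for a node to be split at all.
#' @return An object of class `guide_tree`.
#' @export
train_guide_tree <- function(characteristics, labels, predictors,
                             max_depth = 5L, min_leaf = 5L,
                             min_split = 10L) {
  if (length(labels) != nrow(characteristics)) {
    stop("one label per characteristics row is required", call. = FALSE)
  }
  if (length(labels) < 50L) {
    stop("the guide tree needs a labeled corpus of at least 50 data sets",
         call. = FALSE)
  }
  missing <- setdiff(predictors, names(characteristics))
  if (length(missing)) {
    stop("predictor column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  root <- grow_tree(characteristics[, predictors, drop = FALSE],
                    as.character(labels), predictors, 0L, max_depth,
                    min_leaf, min_split)
  structure(list(root = root, predictors = predictors,
                 max_depth = max_depth, min_leaf = min_leaf,
                 min_split = min_split),
            class = "guide_tree")
}

descend <- function(node, row) {
  while (node$kind == "split") {
    value <- row[[node$predictor]]
    if (!is.null(node$threshold)) {
      node <- if (value <= node$threshold) node$children$le
              else node$children$gt
    } else {
      child <- node$children[[as.character(value)]]
      if (is.null(child)) {
        warning("unseen level '", value, "' for predictor ",
                node$predictor, "; routed to majority child", call. = FALSE)
        sizes <- vapply(node$children, `[[`, numeric(1), "n")
        child <- node$children[[which.max(sizes)]]
      }
      node <- child
    }
  }
  node
}

#' Predict categories from a guide tree
#'
#' @param tree A [train_guide_tree()] result.
#' @param characteristics New characteristics data frame.
#' @return Data frame with the predicted `category` and the leaf's class
#'   distribution as a list column `leaf_dist`.
#' @export
predict_category <- function(tree, characteristics) {
  stopifnot(inherits(tree, "guide_tree"))
  leaves <- lapply(seq_len(nrow(characteristics)), function(i) {
    descend(tree$root, characteristics[i, , drop = FALSE])
  })
  out <- data.frame(
    category = vapply(leaves, `[[`, character(1), "class"),
    stringsAsFactors = FALSE
  )
  out$leaf_dist <- lapply(leaves, `[[`, "dist")
  out
}

format_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (node$kind == "leaf") {
    return(sprintf("%s-> %s (n = %d)", pad, node$class, node$n))
  }
  if (!is.null(node$threshold)) {
    c(sprintf("%sif %s <= %.6g:", pad, node$predictor, node$threshold),
      format_node(node$children$le, indent + 1L),
      sprintf("%selse:", pad),
      format_node(node$children$gt, indent + 1L))
  } else {
    unlist(lapply(names(node$children), function(l) {
      c(sprintf("%sif %s == %s:", pad, node$predictor, l),
        format_node(node$children[[l]], indent + 1L))
    }))
  }
}

#' @export
format.guide_tree <- function(x, ...) {
  paste(format_node(x$root, 0L), collapse = "\n")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Serialize a guide tree to JSON
#'
#' @param tree A `guide_tree`.
#' @return A JSON string.
#' @export
guide_tree_json <- function(tree) {
  jsonlite::toJSON(unclass(tree), auto_unbox = TRUE, digits = NA)
}
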