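# Tree-structured multi-cluster classification: a nested grouping of
# cluster labels defines a binary tree; each internal node carries a
# binary SVM trained on its subtree's samples with labels collapsed to
# the node's two super-classes, and classification descends from the
# root. With imbalanced clusters the grouping matters: pairing a tiny
# cluster against everything else trains a lopsided node.

tree_leaf_labels <- function(structure) {
  if (is.character(structure)) return(structure)
  if (is.list(structure)) {
    return(unlist(lapply(structure, tree_leaf_labels), use.names = FALSE))
  }
  stop("malformed grouping spec", call. = FALSE)
}

validate_structure <- function(structure) {
  if (is.character(structure) && length(structure) == 1) return(invisible())
  if (!is.list(structure) || length(structure) != 2) {
    stop("grouping spec must nest labels into binary groups", call. = FALSE)
  }
  lab <- tree_leaf_labels(structure)
  if (anyDuplicated(lab)) {
    stop("grouping spec repeats a label: ",
         lab[duplicated(lab)][1], call. = FALSE)
  }
  validate_structure(structure[[1]])
  validate_structure(structure[[2]])
}

build_node <- function(structure, x, labels, config, warn_min) {
  if (is.character(structure) && length(structure) == 1) {
    return(list(leaf = TRUE, label = structure))
  }
  left_lab <- tree_leaf_labels(structure[[1]])
  right_lab <- tree_leaf_labels(structure[[2]])
  keep <- labels %in% c(left_lab, right_lab)
  super <- ifelse(labels[keep] %in% left_lab, "L", "R")
  n_l <- sum(super == "L"); n_r <- sum(super == "R")
  if (min(n_l, n_r) < warn_min) {
    warning(sprintf("highly imbalanced node (%d vs %d training samples)",
                    n_l, n_r), call. = FALSE)
  }
  model <- train_svm(x[keep, , drop = FALSE], super, config = config)
  list(leaf = FALSE, model = model,
       left = build_node(structure[[1]], x, labels, config, warn_min),
       right = build_node(structure[[2]], x, labels, config, warn_min))
}

#' Build a classification tree from a nested grouping spec
#'
#' The grouping is given as a nested list of cluster labels: e.g.
#' `list(list("C1", "C3"), "C10")` first separates C1+C3 from C10, then
#' C1 from C3. One binary SVM is trained per internal node on the
#' samples of its subtree, with labels collapsed to the two
#' super-classes. Decision-value ties break toward the group listed
#' first.
#'
#' @param structure Nested list/character grouping spec; a single label
#'   yields a classifier-free single-leaf tree.
#' @param x Feature matrix.
#' @param labels Cluster label per row; must cover every leaf label.
#' @param config [svm_config()] used at every node.
#' @param warn_min Warn when a node super-class has fewer training
#'   samples than this (default 5).
#' @return Object of class `classification_tree`.
#' @export
build_tree <- function(structure, x, labels, config = svm_config(),
                       warn_min = 5L) {
  validate_structure(structure)
  labels <- as.character(labels)
  leaves <- tree_leaf_labels(structure)
  missing <- setdiff(leaves, labels)
  if (length(missing) > 0) {
    stop("labels missing from data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(x)
  root <- build_node(structure, x, labels, config, warn_min)
  structure(list(root = root, leaves = leaves, spec = structure),
            class = "classification_tree")
}

descend <- function(node, xrow) {
  while (!node$leaf) {
    side <- predict(node$model, xrow)
    node <- if (side == "L") node$left else node$right
  }
  node$label
}

#' Classify samples by descending a classification tree
#'
#' @param tree A [build_tree()] result.
#' @param x Feature matrix (rows are samples).
#' @return One leaf label per row.
#' @export
tree_classify <- function(tree, x) {
  stopifnot(inherits(tree, "classification_tree"))
  x <- as.matrix(x)
  vapply(seq_len(nrow(x)), function(i)
    descend(tree$root, x[i, , drop = FALSE]), character(1))
}

#' @export
print.classification_tree <- function(x, ...) {
  fmt <- function(s) {
    if (is.character(s)) return(s)
    paste0("[", fmt(s[[1]]), " | ", fmt(s[[2]]), "]")
  }
  cat("<classification_tree>", fmt(x$spec), "\n")
  invisible(x)
}

canonical_structure <- function(s) {
  if (is.character(s)) return(s)
  a <- canonical_structure(s[[1]])
  b <- canonical_structure(s[[2]])
  ka <- paste(sort(tree_leaf_labels(a)), collapse = ",")
  kb <- paste(sort(tree_leaf_labels(b)), collapse = ",")
  if (ka <= kb) list(a, b) else list(b, a)
}

structure_key <- function(s) {
  if (is.character(s)) return(s)
  paste0("(", structure_key(s[[1]]), "|", structure_key(s[[2]]), ")")
}

# all splits of labels into two non-empty subsets (first subset contains
# the first label, avoiding mirror duplicates)
two_subsets <- function(labels) {
  n <- length(labels)
  out <- list()
  for (mask in 0:(2^(n - 1) - 1)) {
    sel <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2))) > 0))[seq_len(n)]
    if (all(sel) || !any(sel)) next
    out[[length(out) + 1]] <- list(labels[sel], labels[!sel])
  }
  out
}

enumerate_all <- function(labels) {
  if (length(labels) == 1) return(list(labels))
  out <- list()
  for (sp in two_subsets(labels)) {
    for (l in enumerate_all(sp[[1]])) {
      for (r in enumerate_all(sp[[2]])) {
        out[[length(out) + 1]] <- list(l, r)
      }
    }
  }
  out
}

# a right-leaning chain peeling labels in the given order
chain_structure <- function(labels) {
  if (length(labels) == 1) return(labels[1])
  list(labels[1], chain_structure(labels[-1]))
}

#' Enumerate candidate tree structures over a label set
#'
#' @param labels 2 to 5 cluster labels.
#' @param family `"all"` for every full binary nesting (3 structures for
#'   3 labels, 15 for 4, 105 for 5), or `"two_level"` for the named
#'   shallow family: the pair-vs-pair forms (both root groups of size 2,
#'   split directly; 3 forms for 4 labels) plus, per label, one
#'   one-vs-rest form whose remainder is peeled in the given label
#'   order (4 forms for 4 labels).
#' @return List of grouping specs accepted by [build_tree()],
#'   deduplicated up to child order.
#' @export
enumerate_structures <- function(labels, family = c("all", "two_level")) {
  family <- match.arg(family)
  labels <- as.character(labels)
  if (length(labels) < 2 || length(labels) > 5) {
    stop("2 to 5 labels are supported", call. = FALSE)
  }
  if (family == "all") {
    cand <- enumerate_all(labels)
  } else {
    cand <- list()
    if (length(labels) == 2) {
      cand <- list(list(labels[1], labels[2]))
    } else {
      if (length(labels) == 4) {
        for (sp in two_subsets(labels)) {
          if (length(sp[[1]]) == 2 && length(sp[[2]]) == 2) {
            cand[[length(cand) + 1]] <- list(list(sp[[1]][1], sp[[1]][2]),
                                             list(sp[[2]][1], sp[[2]][2]))
          }
        }
      }
      for (i in seq_along(labels)) {
        cand[[length(cand) + 1]] <- list(labels[i],
                                         chain_structure(labels[-i]))
      }
    }
  }
  cand <- lapply(cand, canonical_structure)
  keys <- vapply(cand, structure_key, character(1))
  cand[!duplicated(keys)]
}
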