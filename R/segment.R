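# Spatial segmentation by divisive (bisecting) k-means clustering with a
# binary tree, Euclidean metric, and depth cutting.
#
# At each step the leaf with the largest within-cluster sum of squares
# (WCSS) is split by 2-means (k-means++ initialization, several restarts,
# Lloyd iterations via stats::kmeans). Rows are processed in the canonical
# order of their pixel keys, so the resulting partition does not depend on
# the order in which pixels were supplied.

wcss_of <- function(x) {
  if (nrow(x) <= 1L) return(0)
  mu <- colMeans(x)
  sum(sweep(x, 2L, mu)^2)
}

kmeanspp_init <- function(x, k = 2L) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1L], ])^2)
  for (j in 2L:k) {
    if (all(d2 == 0)) {
      idx[j] <- sample.int(n, 1L)
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j], ])^2))
  }
  idx
}

split_2means <- function(x, seed, restarts) {
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- with_preserved_seed(derive_seed(seed, paste0("restart", r)), {
      init <- kmeanspp_init(x, 2L)
      if (isTRUE(all.equal(x[init[1L], ], x[init[2L], ]))) NULL else {
        tryCatch(
          stats::kmeans(x, centers = x[init, , drop = FALSE],
                        algorithm = "Lloyd", iter.max = 100L),
          error = function(e) NULL, warning = function(w) suppressWarnings(
            stats::kmeans(x, centers = x[init, , drop = FALSE],
                          algorithm = "Lloyd", iter.max = 100L))
        )
      }
    })
    if (is.null(res) || length(unique(res$cluster)) < 2L) next
    if (is.null(best) || res$tot.withinss < best$tot.withinss) best <- res
  }
  best
}

#' Bisecting k-means segmentation
#'
#' @param features A [feature_matrix] or plain numeric matrix (rows =
#'   pixels). With a feature matrix, rows are internally sorted by pixel key
#'   so the partition is permutation-invariant.
#' @param n_leaves Number of leaves to produce (>= 2).
#' @param seed Integer seed; the clustering is deterministic given it.
#' @param restarts k-means++ restarts per split (lowest-WCSS kept).
#' @return Object of class `segmentation_tree`: a list of nodes (id, parent,
#'   children, depth, wcss, pixel indices in the original row order,
#'   terminal flag) plus the pixel keys.
#' @export
bisecting_kmeans <- function(features, n_leaves = 2L, seed = 1L,
                             restarts = 5L) {
  if (inherits(features, "feature_matrix")) {
    keys <- features$keys
    x <- features$values
  } else {
    x <- as.matrix(features)
    keys <- data.frame(section = 1L, x = seq_len(nrow(x)), y = 0L)
  }
  stopifnot(n_leaves >= 2L)
  if (!all(is.finite(x))) msi_stop("features must be finite")
  if (n_leaves > nrow(x)) msi_stop("n_leaves exceeds the number of pixels")
  ord <- order(keys$section, keys$y, keys$x)
  xo <- x[ord, , drop = FALSE]
  nodes <- list(list(id = 1L, parent = NA_integer_, children = NULL,
                     depth = 0L, rows = seq_len(nrow(xo)),
                     wcss = wcss_of(xo), terminal = FALSE))
  leaves <- 1L
  next_id <- 2L
  while (length(leaves) < n_leaves) {
    cand <- leaves[!vapply(nodes[leaves], `[[`, logical(1), "terminal")]
    if (!length(cand)) break
    w <- vapply(nodes[cand], `[[`, numeric(1), "wcss")
    # largest WCSS; exact ties broken by lower node-creation index
    target <- cand[order(-w, cand)][1L]
    rows <- nodes[[target]]$rows
    if (nodes[[target]]$wcss <= 0 || length(rows) < 2L) {
      nodes[[target]]$terminal <- TRUE
      next
    }
    fit <- split_2means(xo[rows, , drop = FALSE],
                        derive_seed(seed, paste0("node", target)), restarts)
    if (is.null(fit)) {
      nodes[[target]]$terminal <- TRUE
      next
    }
    for (cl in 1L:2L) {
      rws <- rows[fit$cluster == cl]
      nodes[[next_id]] <- list(id = next_id, parent = target, children = NULL,
                               depth = nodes[[target]]$depth + 1L, rows = rws,
                               wcss = wcss_of(xo[rws, , drop = FALSE]),
                               terminal = FALSE)
      nodes[[target]]$children <- c(nodes[[target]]$children, next_id)
      next_id <- next_id + 1L
    }
    leaves <- setdiff(leaves, target)
    leaves <- c(leaves, nodes[[target]]$children)
  }
  # map sorted row indices back to the caller's row order
  inv <- order(ord)
  for (i in seq_along(nodes)) {
    nodes[[i]]$rows <- sort(ord[nodes[[i]]$rows])
  }
  structure(list(nodes = nodes, keys = keys, n_rows = nrow(x)),
            class = "segmentation_tree")
}

#' @export
print.segmentation_tree <- function(x, ...) {
  leaves <- sum(vapply(x$nodes, function(n) is.null(n$children), logical(1)))
  cat(sprintf("segmentation_tree: %d nodes (%d leaves) over %d pixels\n",
              length(x$nodes), leaves, x$n_rows))
  invisible(x)
}

#' Cut a segmentation tree at a depth
#'
#' Pixels are labelled by the node they belong to at the given depth; leaves
#' shallower than the cut keep their own label.
#'
#' @param tree A `segmentation_tree`.
#' @param depth Cut depth (1 = the first binary split).
#' @return Integer vector of node-id labels, one per pixel (original row
#'   order), with the pixel keys attached as attribute `keys`.
#' @export
cut_tree <- function(tree, depth = 1L) {
  stopifnot(depth >= 1L)
  labels <- integer(tree$n_rows)
  assign_node <- function(id) {
    nd <- tree$nodes[[id]]
    if (is.null(nd$children) || nd$depth >= depth) {
      labels[nd$rows] <<- id
    } else {
      for (ch in nd$children) assign_node(ch)
    }
  }
  assign_node(1L)
  attr(labels, "keys") <- tree$keys
  labels
}

#' Render per-section label maps from a depth cut
#'
#' @param labels Output of [cut_tree()].
#' @return Named list of integer matrices (one per section; 0 = no pixel).
#' @export
label_maps <- function(labels) {
  keys <- attr(labels, "keys")
  lapply(split(seq_along(labels), keys$section), function(ii) {
    grid_to_image(labels[ii], keys[ii, ], fill = 0L)
  })
}

#' Hierarchical overview segmentation of a multi-segment study
#'
#' Runs [bisecting_kmeans()] on the concatenated feature matrix of all
#' sections/segments, giving the study-wide divisive dendrogram used for a
#' first overview of gray- vs white-matter spectra.
#'
#' @inheritParams bisecting_kmeans
#' @export
hierarchical_overview <- function(features, n_leaves = 4L, seed = 1L,
                                  restarts = 5L) {
  bisecting_kmeans(features, n_leaves = n_leaves, seed = seed,
                   restarts = restarts)
}

#' Export a segmentation tree as JSON
#' @param tree A `segmentation_tree`.
#' @param path Output path.
#' @export
write_tree_json <- function(tree, path) {
  nodes <- lapply(tree$nodes, function(n) {
    list(id = n$id, parent = n$parent, children = n$children,
         depth = n$depth, n_pixels = length(n$rows), wcss = n$wcss,
         terminal = n$terminal)
  })
  jsonlite::write_json(nodes, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
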