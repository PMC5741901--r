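#' Hierarchical clustering of expression profiles
#'
#' Agglomerative complete-linkage clustering of miRNA (or sample) dCt
#' profiles, as used for the study heatmaps. Distance is Euclidean by
#' default (the original heatmap software's metric is undocumented;
#' correlation distance, its common default, is available as an option).
#' Rows/columns containing missing cells on the clustered axis are dropped
#' with a warning. The leaf order is canonicalised so that at every merge
#' the subtree containing the smallest original index comes first; the
#' result is therefore invariant to input permutation whenever merge
#' heights are unique.
#'
#' @param x a [DctExperiment-class] or numeric matrix (rows are clustered).
#' @param axis `"mirnas"` (cluster rows) or `"samples"` (cluster columns).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param standardize z-score each profile before computing distances
#'   (display parity option; off by default).
#' @return list of class `profileClustering`: `hclust` (the merge tree),
#'   `order` (canonical leaf order, indices into the retained items),
#'   `labels` (ids in canonical order), `dropped` (ids removed for missing
#'   values), `newick` (a newick serialisation with merge heights).
#' @export
clusterProfiles <- function(x, axis = c("mirnas", "samples"),
                            distance = c("euclidean", "correlation"),
                            standardize = FALSE) {
    axis <- match.arg(axis)
    distance <- match.arg(distance)
    mat <- if (is(x, "DctExperiment")) dctValues(x) else as.matrix(x)
    if (axis == "samples") mat <- t(mat)
    keep <- rowSums(is.na(mat)) == 0
    if (!all(keep)) {
        warning("dropping ", sum(!keep),
                " item(s) with missing cells: ",
                paste(utils::head(rownames(mat)[!keep]), collapse = ", "))
        mat <- mat[keep, , drop = FALSE]
    }
    if (nrow(mat) < 2) stop("need at least 2 items to cluster")
    if (standardize) {
        mat <- t(scale(t(mat)))
        mat[is.nan(mat)] <- 0
    }
    dd <- if (distance == "euclidean") stats::dist(mat)
          else stats::as.dist(1 - stats::cor(t(mat)))
    hc <- stats::hclust(dd, method = "complete")
    ord <- .canonicalLeafOrder(hc$merge, rownames(mat))
    list(hclust = hc,
         order = ord,
         labels = rownames(mat)[ord],
         dropped = if (is.null(rownames(mat))) character() else
             setdiff(names(keep)[!keep], character(0)),
         newick = .mergeToNewick(hc$merge, hc$height,
                                 rownames(mat))) |>
        structure(class = "profileClustering")
}

#' Canonical leaf order: the subtree whose smallest label (lexicographic;
#' original index when unlabelled) comes first is emitted first, making the
#' order reproducible and independent of input permutation.
#' @noRd
.canonicalLeafOrder <- function(merge, labels = NULL) {
    n <- nrow(merge) + 1L
    key <- if (is.null(labels)) as.character(seq_len(n)) else labels
    leaves <- vector("list", nrow(merge))
    getLeaves <- function(k) if (k < 0) -k else leaves[[k]]
    for (i in seq_len(nrow(merge))) {
        a <- getLeaves(merge[i, 1]); b <- getLeaves(merge[i, 2])
        leaves[[i]] <- if (min(key[a]) <= min(key[b])) c(a, b) else c(b, a)
    }
    leaves[[nrow(merge)]]
}

#' @noRd
.mergeToNewick <- function(merge, height, labels) {
    if (is.null(labels)) labels <- as.character(seq_len(nrow(merge) + 1L))
    sub <- vector("character", nrow(merge))
    minIdx <- vector("character", nrow(merge))
    get <- function(k) if (k < 0) list(s = labels[-k], m = labels[-k])
                       else list(s = sub[k], m = minIdx[k])
    for (i in seq_len(nrow(merge))) {
        a <- get(merge[i, 1]); b <- get(merge[i, 2])
        pair <- if (a$m <= b$m) c(a$s, b$s) else c(b$s, a$s)
        sub[i] <- sprintf("(%s,%s):%g", pair[1], pair[2], height[i])
        minIdx[i] <- min(a$m, b$m)
    }
    paste0(sub[nrow(merge)], ";")
}

#' @export
print.profileClustering <- function(x, ...) {
    cat("complete-linkage clustering of", length(x$order), "profiles\n")
    cat("leaf order:", paste(utils::head(x$labels, 8), collapse = ", "),
        if (length(x$labels) > 8) "..." else "", "\n")
    invisible(x)
}

#' Export a reordered dCt matrix for heatmap rendering
#'
#' Writes the matrix with rows/columns permuted into dendrogram order;
#' optionally renders a PNG with a green-black-red diverging palette in
#' which low dCt (high expression) maps to red.
#'
#' @param mat numeric matrix (or [DctExperiment-class]).
#' @param rowOrder,colOrder permutations of the row/column indices or
#'   names; `NULL` keeps the current order.
#' @param path output CSV path.
#' @param image optional PNG path.
#' @return `path`, invisibly.
#' @export
exportHeatmapMatrix <- function(mat, rowOrder = NULL, colOrder = NULL,
                                path, image = NULL) {
    if (is(mat, "DctExperiment")) mat <- dctValues(mat)
    mat <- as.matrix(mat)
    .checkPerm <- function(ord, n, what) {
        if (is.null(ord)) return(seq_len(n))
        if (is.character(ord)) return(ord)
        if (length(ord) != n || !setequal(ord, seq_len(n)))
            stop(what, "Order must be a permutation of the ", what, " axis")
        ord
    }
    ro <- .checkPerm(rowOrder, nrow(mat), "row")
    co <- .checkPerm(colOrder, ncol(mat), "col")
    if (is.character(ro) && !setequal(ro, rownames(mat)))
        stop("rowOrder must be a permutation of the row names")
    if (is.character(co) && !setequal(co, colnames(mat)))
        stop("colOrder must be a permutation of the column names")
    out <- mat[ro, co, drop = FALSE]
    utils::write.csv(out, path, row.names = TRUE)
    if (!is.null(image)) {
        pal <- grDevices::colorRampPalette(c("red", "black", "green"))(255)
        grDevices::png(image, width = 640, height = 640)
        op <- graphics::par(mar = c(6, 2, 2, 6))
        # image() draws rows bottom-up; flip so the first row is on top.
        graphics::image(t(out[rev(seq_len(nrow(out))), , drop = FALSE]),
                        col = pal, axes = FALSE)
        graphics::par(op)
        grDevices::dev.off()
    }
    invisible(path)
}
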