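# Pangenome construction: ORF similarity graph (maxbit normalization) ->
# Markov clustering (MCL) -> gene-cluster presence/absence matrix ->
# dendrogram / uniquely-shared clusters / COG-category enrichment.

#' Build a maxbit similarity graph from pairwise ORF scores
#'
#' The maxbit weight of a pair is `score(a, b) / min(self(a), self(b))`;
#' edges are kept iff the weight is at least `threshold` (the 0.3 boundary
#' value itself is kept).
#'
#' @param scores Data.frame with columns `orf_a`, `orf_b`, `score`,
#'   including a self row (`orf_a == orf_b`) for every ORF.
#' @param threshold Minimum maxbit weight for an edge.
#' @return List of class `"similarity_graph"`: `nodes` (character) and
#'   `edges` (data.frame `a`, `b`, `weight` with `a < b`).
#' @export
build_maxbit_graph <- function(scores, threshold = 0.3) {
  need <- c("orf_a", "orf_b", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss) > 0L) {
    stop("scores missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  selfrows <- scores$orf_a == scores$orf_b
  self <- stats::setNames(scores$score[selfrows], scores$orf_a[selfrows])
  nodes <- sort(unique(c(scores$orf_a, scores$orf_b)))
  no_self <- setdiff(nodes, names(self))
  if (length(no_self) > 0L) {
    stop("missing self-score for ORF(s): ", paste(no_self, collapse = ", "),
         call. = FALSE)
  }
  pair <- scores[!selfrows, , drop = FALSE]
  if (nrow(pair) > 0L) {
    w <- pmin(1, pair$score / pmin(self[pair$orf_a], self[pair$orf_b]))
    a <- pmin(pair$orf_a, pair$orf_b)
    b <- pmax(pair$orf_a, pair$orf_b)
    edges <- data.frame(a = a, b = b, weight = w, stringsAsFactors = FALSE)
    edges <- edges[edges$weight >= threshold & edges$weight > 0, , drop = FALSE]
    # collapse duplicate pairs (e.g. both orientations supplied): keep max
    if (nrow(edges) > 0L) {
      key <- paste(edges$a, edges$b)
      edges <- edges[order(key, -edges$weight), , drop = FALSE]
      edges <- edges[!duplicated(paste(edges$a, edges$b)), , drop = FALSE]
    }
  } else {
    edges <- data.frame(a = character(0), b = character(0), weight = numeric(0))
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' All-vs-all protein similarity scores (Smith-Waterman)
#'
#' Local alignment scores with BLOSUM62 and affine gaps (open 11, extend 1),
#' including self-scores, sized for synthetic-scale pangenomes. Large real
#' datasets should supply precomputed scores to [build_maxbit_graph()]
#' instead.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @return Data.frame with `orf_a`, `orf_b`, `score` (self rows included).
#' @export
score_orf_similarities <- function(proteins) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  ids <- names(proteins)
  n <- length(ids)
  rows <- list()
  m <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      sc <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(proteins[[i]]), Biostrings::AAString(proteins[[j]]),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
      )
      m <- m + 1L
      rows[[m]] <- data.frame(orf_a = ids[i], orf_b = ids[j], score = sc,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Markov clustering of a similarity graph
#'
#' Classic MCL on the column-stochastic adjacency matrix with self-loops
#' (each node's loop weight is its maximum incident edge weight; isolated
#' nodes get 1): alternate expansion (matrix squaring) and inflation
#' (elementwise power `inflation` followed by column renormalization), prune
#' entries below `prune`, and stop when the largest entry change falls below
#' `tol`. Clusters are read off the attractor rows; a node supported by
#' several attractors goes to the one holding the largest weight for it
#' (lexicographic tie-break), so the result is always a partition.
#'
#' @param graph A [build_maxbit_graph()] object.
#' @param inflation Inflation exponent (2 by convention).
#' @param max_iter Iteration cap; exceeded means non-convergence (error).
#' @param prune Entries below this are zeroed each iteration.
#' @param tol Convergence threshold on the max entry change.
#' @return List of class `"mcl_clusters"`: `membership` (named character
#'   vector node -> cluster id) and `clusters` (named list of node vectors,
#'   ordered by decreasing size).
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 200L, prune = 1e-6,
                        tol = 1e-8) {
  stopifnot(inherits(graph, "similarity_graph"))
  nodes <- graph$nodes
  n <- length(nodes)
  if (n < 1L) stop("graph has no nodes", call. = FALSE)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e) > 0L) {
    ia <- match(e$a, nodes)
    ib <- match(e$b, nodes)
    A[cbind(ia, ib)] <- e$weight
    A[cbind(ib, ia)] <- e$weight
  }
  loops <- apply(A, 2L, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  normalize <- function(m) sweep(m, 2L, colSums(m), "/")
  M <- normalize(A)
  converged <- FALSE
  delta <- Inf
  for (it in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M               # expansion
    M <- M^inflation           # inflation
    M[M < prune] <- 0          # pruning
    M <- normalize(M)
    delta <- max(abs(M - prev))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("MCL did not converge after ", max_iter,
         " iterations (residual ", format(delta), ")", call. = FALSE)
  }
  attractors <- which(diag(M) > prune)
  membership <- character(n)
  for (j in seq_len(n)) {
    support <- attractors[M[attractors, j] > 0]
    if (length(support) == 0L) {
      membership[j] <- nodes[j]  # orphan: its own singleton
      next
    }
    w <- M[support, j]
    best <- support[w == max(w)]
    membership[j] <- nodes[min(best)]  # lexicographic-by-order tie-break
  }
  groups <- split(nodes, membership)
  groups <- groups[order(-lengths(groups), names(groups))]
  cluster_ids <- sprintf("GC_%04d", seq_along(groups))
  names(groups) <- cluster_ids
  mem <- stats::setNames(rep(cluster_ids, lengths(groups)),
                         unlist(groups, use.names = FALSE))
  mem <- mem[nodes]
  structure(list(membership = mem, clusters = groups), class = "mcl_clusters")
}

#' @export
print.mcl_clusters <- function(x, ...) {
  cat("<MCL clustering>", length(x$membership), "nodes in",
      length(x$clusters), "clusters\n")
  invisible(x)
}

#' Gene-cluster presence/absence matrix
#'
#' @param clusters A [mcl_cluster()] object (or a named list of ORF id
#'   vectors).
#' @param orf_to_mag Named character vector mapping every ORF to its MAG.
#' @return Binary integer matrix, clusters x MAGs.
#' @export
presence_absence <- function(clusters, orf_to_mag) {
  cl <- if (inherits(clusters, "mcl_clusters")) clusters$clusters else clusters
  if (length(cl) == 0L) stop("no gene clusters given", call. = FALSE)
  orfs <- unlist(cl, use.names = FALSE)
  unassigned <- setdiff(orfs, names(orf_to_mag))
  if (length(unassigned) > 0L) {
    stop("ORF(s) not assigned to a MAG: ",
         paste(utils::head(unassigned, 5L), collapse = ", "), call. = FALSE)
  }
  mags <- sort(unique(unname(orf_to_mag)))
  m <- matrix(0L, nrow = length(cl), ncol = length(mags),
              dimnames = list(names(cl), mags))
  for (i in seq_along(cl)) {
    m[i, unique(orf_to_mag[cl[[i]]])] <- 1L
  }
  m
}

#' Hierarchical clustering dendrogram of MAG gene content
#'
#' Euclidean distance on the binary presence/absence profiles and
#' agglomerative clustering with complete linkage (the `dist`/`hclust`
#' defaults); both are configurable. The tree is also rendered as a Newick
#' string with branch lengths derived from merge heights.
#'
#' @param pa_matrix Binary matrix, clusters x MAGs (MAGs in columns).
#' @param distance `dist` method.
#' @param linkage `hclust` method.
#' @return List of class `"mag_dendrogram"`: `hclust`, `newick`.
#' @export
cluster_dendrogram <- function(pa_matrix, distance = "euclidean",
                               linkage = "complete") {
  if (ncol(pa_matrix) < 2L) stop("need at least 2 MAGs", call. = FALSE)
  d <- stats::dist(t(pa_matrix), method = distance)
  hc <- stats::hclust(d, method = linkage)
  nw <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, newick = nw), class = "mag_dendrogram")
}

#' @export
print.mag_dendrogram <- function(x, ...) {
  cat("<dendrogram>", x$newick, "\n")
  invisible(x)
}

#' Gene clusters uniquely shared by a focal MAG set
#'
#' Clusters present in every focal MAG and absent from every other MAG.
#'
#' @param pa_matrix Binary matrix, clusters x MAGs.
#' @param focal Character vector of focal MAG ids; a non-empty proper subset
#'   of the matrix columns.
#' @return Character vector of cluster ids.
#' @export
uniquely_shared <- function(pa_matrix, focal) {
  mags <- colnames(pa_matrix)
  if (length(focal) == 0L) stop("focal set is empty", call. = FALSE)
  if (!all(focal %in% mags)) {
    stop("unknown focal MAG(s): ", paste(setdiff(focal, mags), collapse = ", "),
         call. = FALSE)
  }
  others <- setdiff(mags, focal)
  if (length(others) == 0L) {
    stop("focal set must be a proper subset of the MAGs", call. = FALSE)
  }
  inside <- rowSums(pa_matrix[, focal, drop = FALSE]) == length(focal)
  outside <- rowSums(pa_matrix[, others, drop = FALSE]) == 0L
  rownames(pa_matrix)[inside & outside]
}

# split multi-letter COG annotations into a gene x category logical matrix
cog_membership <- function(labels, categories) {
  letters_per_gene <- strsplit(labels, "", fixed = TRUE)
  m <- matrix(FALSE, nrow = length(labels), ncol = length(categories),
              dimnames = list(NULL, categories))
  for (i in seq_along(letters_per_gene)) {
    hit <- intersect(letters_per_gene[[i]], categories)
    if (length(hit) > 0L) m[i, hit] <- TRUE
  }
  m
}

#' Resampling test for COG-category enrichment
#'
#' Non-parametric enrichment of functional categories in a focal gene set
#' relative to a background pool. For each repetition, `sample_size` genes
#' are drawn from the background without replacement and each category's
#' proportion recorded; a category is enriched at confidence level `L` iff
#' its proportion in the focal set exceeds the `L`-quantile of its null
#' proportions. The achieved confidence is the fraction of null draws
#' strictly below the observed proportion. Multi-letter annotations are
#' split and counted once per letter; proportions are per gene.
#'
#' @param focal_labels Character vector of COG letters for the focal genes.
#' @param background_labels Character vector for the background pool
#'   (size >= `sample_size`).
#' @param repetitions Number of null resamples.
#' @param sample_size Genes drawn per resample.
#' @param levels Confidence levels reported.
#' @param seed Integer seed.
#' @return Data.frame of class `"enrichment_result"`, one row per category:
#'   `category`, `focal_proportion`, `background_proportion`,
#'   `achieved_confidence`, one `null_qXX` column and one `enriched_XX` flag
#'   per level.
#' @export
cog_enrichment <- function(focal_labels, background_labels,
                           repetitions = 500L, sample_size = 200L,
                           levels = c(0.90, 0.93, 0.99), seed = 1L) {
  if (length(focal_labels) == 0L) stop("focal gene set is empty", call. = FALSE)
  if (sample_size > length(background_labels)) {
    stop("sample_size exceeds the background pool", call. = FALSE)
  }
  categories <- sort(unique(unlist(strsplit(
    c(focal_labels, background_labels), "", fixed = TRUE))))
  categories <- intersect(categories, COG_LETTERS)
  fm <- cog_membership(focal_labels, categories)
  bm <- cog_membership(background_labels, categories)
  obs <- colMeans(fm)
  null <- with_seed(seed, {
    t(vapply(seq_len(repetitions), function(r) {
      colMeans(bm[sample.int(nrow(bm), sample_size), , drop = FALSE])
    }, numeric(length(categories))))
  })
  out <- data.frame(category = categories,
                    focal_proportion = unname(obs),
                    background_proportion = unname(colMeans(bm)),
                    achieved_confidence = vapply(seq_along(categories),
                      function(i) mean(null[, i] < obs[i]), numeric(1)),
                    stringsAsFactors = FALSE)
  for (L in levels) {
    q <- apply(null, 2L, stats::quantile, probs = L, names = FALSE)
    out[[sprintf("null_q%02d", round(100 * L))]] <- q
    out[[sprintf("enriched_%02d", round(100 * L))]] <- obs > q
  }
  class(out) <- c("enrichment_result", "data.frame")
  out
}
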