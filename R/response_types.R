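#' Canonical enumeration of the 27 qualitative response patterns
#'
#' A response pattern is an ordered triple of states at the ND, CD and pCD
#' transitions, each U (up), D (down) or S (sustained).  The canonical
#' order sorts patterns by the earliest transition showing a change, puts
#' upregulation before downregulation, places each pattern next to its
#' complement (U and D swapped everywhere), and puts the all-sustained
#' triple last.  The mapping pattern <-> id is a bijection.
#'
#' @return data.frame: type_id ("r01".."r27"), pattern (e.g. "UDS"), nd,
#'   cd, pcd, changing (FALSE only for "SSS").
#' @export
response_type_table <- function() {
  states <- c("U", "D", "S")
  pats <- apply(expand.grid(states, states, states), 1, paste, collapse = "")
  complement <- function(s) chartr("UD", "DU", s)
  first_change <- function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- which(ch != "S")
    if (length(i)) i[1] else 4L
  }
  e <- vapply(pats, first_change, 1L)
  positives <- pats[e < 4L &
                      substr(pats, e, e) == "U"]
  # lexicographic rank with U < S < D per position, grouped by first change
  val <- function(s) {
    v <- match(strsplit(s, "")[[1]], c("U", "S", "D")) - 1L
    sum(v * c(9L, 3L, 1L))
  }
  ord <- order(vapply(positives, first_change, 1L),
               vapply(positives, val, 1L))
  positives <- positives[ord]
  ordered <- c(rbind(positives, vapply(positives, complement, "")), "SSS")
  stopifnot(length(ordered) == 27L, !anyDuplicated(ordered))
  st <- do.call(rbind, strsplit(ordered, ""))
  data.frame(type_id = sprintf("r%02d", seq_along(ordered)),
             pattern = ordered,
             nd = st[, 1], cd = st[, 2], pcd = st[, 3],
             changing = ordered != "SSS")
}

#' Discretise per-gene transition statistics into response profiles
#'
#' For each of the three consecutive transitions (t2 vs t1 = ND, t3 vs t2 =
#' CD, t4 vs t3 = pCD), a gene is U if its log2 fold-change is at least
#' `log2(fold_threshold)` with `p_adj < alpha`, D if at most
#' `-log2(fold_threshold)` with `p_adj < alpha`, and S otherwise.  The
#' state triple is mapped to its canonical type id.
#'
#' @param lfc Genes x 3 matrix of log2 fold-changes (columns ND, CD, pCD).
#' @param padj Genes x 3 matrix of adjusted p values.
#' @param fold_threshold Fold-change threshold (on the natural scale).
#' @param alpha Adjusted-p cutoff.
#' @return data.frame: gene_id, nd, cd, pcd, pattern, type_id, changing.
#' @export
classify_response <- function(lfc, padj, fold_threshold = 2, alpha = 0.01) {
  lfc <- as.matrix(lfc)
  padj <- as.matrix(padj)
  if (ncol(lfc) != 3 || !identical(dim(lfc), dim(padj))) {
    stop("need log2 fold-changes and adjusted p for exactly 3 transitions")
  }
  lt <- log2(fold_threshold)
  sig <- !is.na(padj) & padj < alpha
  up <- sig & !is.na(lfc) & lfc >= lt
  dn <- sig & !is.na(lfc) & lfc <= -lt
  st <- matrix("S", nrow(lfc), 3)
  st[up] <- "U"
  st[dn] <- "D"
  pattern <- paste0(st[, 1], st[, 2], st[, 3])
  tab <- response_type_table()
  idx <- match(pattern, tab$pattern)
  data.frame(gene_id = rownames(lfc) %||% seq_len(nrow(lfc)),
             nd = st[, 1], cd = st[, 2], pcd = st[, 3],
             pattern = pattern,
             type_id = tab$type_id[idx],
             changing = tab$changing[idx])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Response profiles from a count matrix
#'
#' Runs the three consecutive pairwise Wald contrasts (with BH adjustment
#' within each contrast) and discretises them with [classify_response()].
#'
#' @param counts Genes x samples matrix.
#' @param metadata data.frame with `time_point` per sample (levels t1..t4).
#' @param sf Size factors (computed once from the full matrix if `NULL`).
#' @param fold_threshold,alpha Passed to [classify_response()].
#' @param ... Passed to [test_pairwise()].
#' @return List: `profiles` (classification data.frame), `contrasts`
#'   (list of the three [test_pairwise()] tables).
#' @export
response_profiles <- function(counts, metadata, sf = NULL,
                              fold_threshold = 2, alpha = 0.01, ...) {
  counts <- as.matrix(counts)
  tps <- paste0("t", 1:4)
  if (!all(tps %in% metadata$time_point)) stop("need time points t1..t4")
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  contrasts <- list(
    nd = test_pairwise(counts, metadata, "t2", "t1", sf = sf, ...),
    cd = test_pairwise(counts, metadata, "t3", "t2", sf = sf, ...),
    pcd = test_pairwise(counts, metadata, "t4", "t3", sf = sf, ...))
  lfc <- sapply(contrasts, `[[`, "lfc")
  padj <- sapply(contrasts, `[[`, "p_adj")
  rownames(lfc) <- rownames(padj) <- rownames(counts)
  list(profiles = classify_response(lfc, padj, fold_threshold, alpha),
       contrasts = contrasts)
}

#' Count genes per response type
#'
#' @param profiles Classification data.frame from [classify_response()].
#' @return List: `counts` (data.frame type_id, pattern, n over the 26
#'   changing types), `n_types` (number of nonempty changing types),
#'   `n_changing` (number of changing genes).
#' @export
count_types <- function(profiles) {
  tab <- response_type_table()
  changing <- tab[tab$changing, ]
  n <- table(factor(profiles$type_id[profiles$changing],
                    levels = changing$type_id))
  counts <- data.frame(type_id = changing$type_id,
                       pattern = changing$pattern,
                       n = as.integer(n))
  list(counts = counts,
       n_types = sum(counts$n > 0),
       n_changing = sum(counts$n))
}

#' Build an annotation hierarchy from category paths
#'
#' Paths are delimiter-separated (e.g. "SOM/CAZyme/GH28"); every prefix is
#' a node and each gene attaches at its deepest stated node.  The top-level
#' path element determines the partition: paths rooted at "SOM" are
#' SOM-interaction (decomposition of plant-cell-wall-derived polymers and
#' organic-N assimilation), everything else is metabolism.  Genes whose
#' path is "null" or NA are unannotated and excluded.
#'
#' @param annotations data.frame with `gene_id` and `category_path`.
#' @param sep Path delimiter.
#' @return Object of class `annotation_hierarchy`: `nodes` (path, parent,
#'   depth, partition), `genes` (gene_id, path, partition).
#' @export
build_hierarchy <- function(annotations, sep = "/") {
  annotations <- as.data.frame(annotations)
  if (!all(c("gene_id", "category_path") %in% names(annotations))) {
    stop("annotations must have columns gene_id and category_path")
  }
  ann <- annotations[!is.na(annotations$category_path) &
                       annotations$category_path != "null", , drop = FALSE]
  ann <- unique(ann[c("gene_id", "category_path")])
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup)) {
    stop("conflicting annotation paths for gene(s): ",
         paste(unique(dup), collapse = ", "))
  }
  partition_of <- function(path) {
    top <- vapply(strsplit(path, sep, fixed = TRUE), `[[`, "", 1L)
    ifelse(top == "SOM", "SOM-interaction", "metabolism")
  }
  all_prefixes <- function(path) {
    parts <- strsplit(path, sep, fixed = TRUE)[[1]]
    vapply(seq_along(parts), function(i) paste(parts[1:i], collapse = sep), "")
  }
  paths <- unique(as.character(unlist(lapply(unique(ann$category_path),
                                             all_prefixes))))
  depth <- lengths(strsplit(paths, sep, fixed = TRUE))
  parent <- ifelse(depth == 1, "",
                   vapply(strsplit(paths, sep, fixed = TRUE), function(p) {
                     paste(p[-length(p)], collapse = sep)
                   }, ""))
  nodes <- data.frame(path = c("", paths),
                      parent = c(NA, parent),
                      depth = c(0L, depth))
  nodes$partition <- c(NA, partition_of(paths))
  nodes <- nodes[order(nodes$depth, nodes$path), ]
  rownames(nodes) <- NULL
  genes <- data.frame(gene_id = ann$gene_id,
                      path = ann$category_path,
                      partition = partition_of(ann$category_path))
  structure(list(nodes = nodes, genes = genes), class = "annotation_hierarchy")
}

#' Annotation-guided single-linkage clustering of expression profiles
#'
#' Within each deepest annotation node, genes are grouped by single-linkage
#' clustering on Pearson correlation of their per-time-point mean log2
#' expression profiles, cut so that genes joined at correlation >=
#' `corr_threshold` share a cluster.  Each cluster carries its node's
#' label; singletons are allowed.  Input genes must be annotated (callers
#' restrict to time-DEGs upstream).
#'
#' @param profiles Genes x time-points matrix of mean log2 expression with
#'   gene ids as rownames.
#' @param hierarchy An [build_hierarchy()] object covering all input genes.
#' @param corr_threshold Pearson correlation linkage threshold.
#' @return data.frame: gene_id, node, partition, cluster_id.
#' @export
cluster_genes <- function(profiles, hierarchy, corr_threshold = 0.8) {
  profiles <- as.matrix(profiles)
  if (!nrow(profiles)) {
    return(data.frame(gene_id = character(), node = character(),
                      partition = character(), cluster_id = character()))
  }
  gmap <- hierarchy$genes
  missing <- setdiff(rownames(profiles), gmap$gene_id)
  if (length(missing)) {
    stop("unannotated input gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
  }
  idx <- match(rownames(profiles), gmap$gene_id)
  out <- data.frame(gene_id = rownames(profiles),
                    node = gmap$path[idx],
                    partition = gmap$partition[idx],
                    cluster_id = NA_character_)
  for (node in unique(out$node)) {
    rows <- which(out$node == node)
    if (length(rows) == 1L) {
      out$cluster_id[rows] <- paste0(node, "#1")
      next
    }
    r <- suppressWarnings(stats::cor(t(profiles[rows, , drop = FALSE])))
    r[!is.finite(r)] <- -1   # constant profiles: treat as uncorrelated
    h <- stats::hclust(stats::as.dist(1 - r), method = "single")
    ct <- stats::cutree(h, h = 1 - corr_threshold)
    out$cluster_id[rows] <- paste0(node, "#", ct)
  }
  out
}

#' Permutation test of time points for response-type enrichment
#'
#' For each of B permutations, the time-point labels are shuffled within
#' each replicate block (preserving the replicate structure), the pairwise
#' DE -> discretisation -> counting chain is re-run, and the number of
#' SOM-interaction genes in each response type is recorded.  The empirical
#' p value for a type is `(1 + #\{null counts >= observed\}) / (B + 1)`.
#' A closed-form hypergeometric enrichment p (SOM genes in the type versus
#' the annotated universe) is available as an alternative statistic.
#'
#' @param counts Genes x samples matrix.
#' @param metadata data.frame with `time_point` and `replicate` per sample.
#' @param hierarchy [build_hierarchy()] object; genes not in it are treated
#'   as unannotated and never counted.
#' @param B Number of permutations (>= 19).
#' @param seed Seed for the permutation draws.
#' @param fold_threshold,alpha Discretisation thresholds.
#' @param statistic `"count"` (permutation, default) or `"hypergeom"`.
#' @return Object of class `permutation_result`: `table` (type_id, pattern,
#'   type size n, observed SOM count, null_mean, null_q95, p), `B`, `seed`,
#'   `statistic`.
#' @export
permutation_test <- function(counts, metadata, hierarchy, B = 999, seed = 1L,
                             fold_threshold = 2, alpha = 0.01,
                             statistic = c("count", "hypergeom")) {
  statistic <- match.arg(statistic)
  if (statistic == "count" && B < 19) {
    stop("B must be >= 19 for usable p-value resolution")
  }
  counts <- as.matrix(counts)
  sf <- size_factors(counts, pseudo_reference = TRUE)
  som_genes <- hierarchy$genes$gene_id[hierarchy$genes$partition == "SOM-interaction"]

  som_counts <- function(meta) {
    prof <- response_profiles(counts, meta, sf = sf,
                              fold_threshold = fold_threshold, alpha = alpha)$profiles
    ch <- prof[prof$changing, , drop = FALSE]
    tab <- response_type_table()
    lv <- tab$type_id[tab$changing]
    list(som = table(factor(ch$type_id[ch$gene_id %in% som_genes], levels = lv)),
         all = table(factor(ch$type_id, levels = lv)))
  }

  obs <- som_counts(metadata)
  tab <- response_type_table()
  out <- data.frame(type_id = tab$type_id[tab$changing],
                    pattern = tab$pattern[tab$changing],
                    n = as.integer(obs$all),
                    observed_som = as.integer(obs$som))

  if (statistic == "hypergeom") {
    n_ann <- nrow(hierarchy$genes)
    m <- sum(hierarchy$genes$partition == "SOM-interaction")
    out$p <- stats::phyper(out$observed_som - 1L, m, n_ann - m, out$n,
                           lower.tail = FALSE)
    out$null_mean <- out$n * m / max(n_ann, 1L)
    out$null_q95 <- NA_real_
    return(structure(list(table = out, B = 0L, seed = seed,
                          statistic = statistic),
                     class = "permutation_result"))
  }

  set.seed(seed)
  null <- matrix(0L, B, nrow(out))
  for (b in seq_len(B)) {
    meta <- metadata
    for (r in unique(metadata$replicate)) {
      idx <- which(metadata$replicate == r)
      meta$time_point[idx] <- sample(metadata$time_point[idx])
    }
    null[b, ] <- as.integer(som_counts(meta)$som)
  }
  out$null_mean <- colMeans(null)
  out$null_q95 <- apply(null, 2, stats::quantile, probs = 0.95, names = FALSE)
  out$p <- (1 + colSums(null >= matrix(out$observed_som, B, nrow(out),
                                       byrow = TRUE))) / (B + 1)
  structure(list(table = out, B = B, seed = seed, statistic = statistic),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s statistic, B = %d)\n", x$statistic, x$B))
  print(x$table[x$table$n > 0, ], row.names = FALSE)
  invisible(x)
}
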