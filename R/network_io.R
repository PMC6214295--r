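#' Disease module set container
#'
#' Maps disease ids to member node ids, with an optional per-disease category
#' label (e.g. an ICD-10 chapter).
#'
#' @param modules Named list of character vectors of member node ids.
#' @param categories Optional named character vector (names = disease ids).
#' @return An object of class \code{disease_module_set}.
#' @export
disease_module_set <- function(modules, categories = NULL) {
  stopifnot(is.list(modules), !is.null(names(modules)))
  modules <- lapply(modules, function(m) unique(as.character(m)))
  if (!is.null(categories)) {
    categories <- categories[names(modules)]
    names(categories) <- names(modules)
  }
  structure(list(modules = modules, categories = categories),
            class = "disease_module_set")
}

#' @export
print.disease_module_set <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat(sprintf("<disease_module_set> %d diseases; module sizes %d-%d\n",
              length(x$modules), min(sizes), max(sizes)))
  invisible(x)
}

read_tsv_table <- function(path, col_names) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) stop(path, ": no data rows")
  dt <- tryCatch(
    data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t",
                      header = "auto", data.table = FALSE),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  if (ncol(dt) < length(col_names) - 1) {
    stop(sprintf("%s: expected at least %d columns, found %d",
                 path, length(col_names) - 1, ncol(dt)))
  }
  dt
}

#' Read a scored edge list from TSV
#'
#' Expected columns: \code{protein_a<TAB>protein_b[<TAB>score]}; a header is
#' optional and lines starting with \code{#} are ignored. Missing scores
#' default to 1.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns \code{protein_a}, \code{protein_b},
#'   \code{score}.
#' @export
read_edge_list <- function(path) {
  dt <- read_tsv_table(path, c("protein_a", "protein_b", "score"))
  if (ncol(dt) == 2) dt$score <- 1
  dt <- dt[, 1:3]
  names(dt) <- c("protein_a", "protein_b", "score")
  bad <- which(is.na(dt$protein_a) | is.na(dt$protein_b) |
                 !is.finite(suppressWarnings(as.numeric(dt$score))))
  if (length(bad) > 0) {
    stop(sprintf("malformed edge row(s) at line(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  dt$protein_a <- as.character(dt$protein_a)
  dt$protein_b <- as.character(dt$protein_b)
  dt$score <- as.numeric(dt$score)
  dt
}

#' Write an edge list to TSV
#' @param net An \code{embedded_network}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  sc <- igraph::E(net$graph)$score
  df <- data.frame(protein_a = el[, 1], protein_b = el[, 2],
                   score = if (is.null(sc)) rep(1, nrow(el)) else sc)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read node coordinates from TSV (\code{node_id<TAB>r<TAB>theta})
#' @param path Path to the TSV file.
#' @return data.frame with columns \code{node}, \code{r}, \code{theta}.
#' @export
read_coords <- function(path) {
  dt <- read_tsv_table(path, c("node", "r", "theta"))
  dt <- dt[, 1:3]
  names(dt) <- c("node", "r", "theta")
  dt$node <- as.character(dt$node)
  dt
}

#' Write node coordinates to TSV
#' @param net An \code{embedded_network} with coordinates.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_coords <- function(net, path) {
  co <- net_coords(net)
  names(co)[1] <- "node_id"
  data.table::fwrite(co, path, sep = "\t")
  invisible(path)
}

#' Read a gene-disease association table
#' (\code{gene<TAB>disease<TAB>n_publications})
#'
#' Duplicate (gene, disease) pairs are collapsed keeping the maximum
#' publication count.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns \code{gene}, \code{disease}, \code{n_pubs}.
#' @export
read_gene_disease <- function(path) {
  dt <- read_tsv_table(path, c("gene", "disease", "n_pubs"))
  dt <- dt[, 1:3]
  names(dt) <- c("gene", "disease", "n_pubs")
  dt$gene <- as.character(dt$gene)
  dt$disease <- as.character(dt$disease)
  dt$n_pubs <- as.integer(dt$n_pubs)
  if (any(is.na(dt$n_pubs)) || any(dt$n_pubs < 1)) {
    stop("n_publications must be integers >= 1")
  }
  agg <- stats::aggregate(n_pubs ~ gene + disease, data = dt, FUN = max)
  agg[order(agg$disease, agg$gene), , drop = FALSE]
}

#' Write a gene-disease association table to TSV
#' @param table data.frame as returned by \code{\link{read_gene_disease}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_disease <- function(table, path) {
  out <- table
  names(out) <- c("gene", "disease", "n_publications")
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read class annotations (\code{node_id<TAB>class}, multi-row per node)
#' @param path Path to the TSV file.
#' @param classes Allowed class vocabulary.
#' @return Named list: node id -> character vector of classes.
#' @export
read_class_annotations <- function(path,
                                   classes = c("TF", "Rec", "RBP", "Trans",
                                               "Skel", "Ubi")) {
  dt <- read_tsv_table(path, c("node", "class"))
  dt <- dt[, 1:2]
  names(dt) <- c("node", "class")
  bad <- setdiff(unique(dt$class), classes)
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  split(as.character(dt$class), as.character(dt$node))
}

#' Write class annotations to TSV
#' @param annotations Named list node -> classes.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_class_annotations <- function(annotations, path) {
  df <- data.frame(
    node_id = rep(names(annotations), lengths(annotations)),
    class = unlist(annotations, use.names = FALSE)
  )
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read drug-target flags (\code{node_id<TAB>fda|potential})
#' @param path Path to the TSV file.
#' @return data.frame with columns \code{node}, \code{flag}.
#' @export
read_target_flags <- function(path) {
  dt <- read_tsv_table(path, c("node", "flag"))
  dt <- dt[, 1:2]
  names(dt) <- c("node", "flag")
  bad <- setdiff(unique(dt$flag), c("fda", "potential"))
  if (length(bad) > 0) stop("unknown target flag(s): ", paste(bad, collapse = ", "))
  dt$node <- as.character(dt$node)
  dt
}

#' Read a disease to category map (\code{disease<TAB>icd10_chapter})
#' @param path Path to the TSV file.
#' @return Named character vector disease -> category.
#' @export
read_icd_map <- function(path) {
  dt <- read_tsv_table(path, c("disease", "chapter"))
  stats::setNames(as.character(dt[[2]]), as.character(dt[[1]]))
}

#' Build the analysis network from a scored edge list
#'
#' Keeps the \code{top_k} interactions by score (all ties at the cut-off score
#' are kept and a message is logged), drops self-interactions, deduplicates
#' redundant pairs keeping the maximum score, and returns the largest
#' connected component.
#'
#' @param edges data.frame with columns \code{protein_a}, \code{protein_b},
#'   \code{score} (see \code{\link{read_edge_list}}).
#' @param top_k Number of top-scoring interactions to keep;
#'   \code{Inf} keeps all.
#' @return An \code{embedded_network} (simple, connected, no coordinates).
#' @export
build_network <- function(edges, top_k = Inf) {
  stopifnot(all(c("protein_a", "protein_b", "score") %in% names(edges)))
  edges <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
  if (nrow(edges) == 0) stop("no non-self edges in input")
  if (is.finite(top_k) && top_k < nrow(edges)) {
    cut_score <- sort(edges$score, decreasing = TRUE)[top_k]
    keep <- edges$score >= cut_score
    if (sum(keep) > top_k) {
      message(sprintf("build_network: kept %d edges (ties at score %g inflate top_k=%d)",
                      sum(keep), cut_score, as.integer(top_k)))
    }
    edges <- edges[keep, , drop = FALSE]
  }
  # canonical orientation, then dedupe keeping max score
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(edges$score, key, max)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  el <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$score <- as.numeric(agg)
  comp <- igraph::components(g)
  lcc <- which.max(comp$csize)
  g <- igraph::induced_subgraph(g, which(comp$membership == lcc))
  embedded_network(g)
}

#' Filter a gene-disease table by evidence and disease size
#'
#' First removes associations supported by fewer than \code{min_pubs}
#' publications, then removes diseases left with fewer than \code{min_genes}
#' associated genes. Both thresholds are inclusive
#' (\code{n_pubs >= min_pubs}, \code{n_genes >= min_genes} are kept).
#'
#' @param table data.frame with columns \code{gene}, \code{disease},
#'   \code{n_pubs}.
#' @param min_pubs Minimum supporting publications per association.
#' @param min_genes Minimum genes per disease after the publication filter.
#' @return The filtered table.
#' @export
filter_gene_disease <- function(table, min_pubs = 3, min_genes = 50) {
  table <- table[table$n_pubs >= min_pubs, , drop = FALSE]
  sizes <- table(table$disease)
  keep <- names(sizes)[sizes >= min_genes]
  table[table$disease %in% keep, , drop = FALSE]
}

#' Merge diseases with very similar gene sets
#'
#' Builds the Jaccard distance matrix \eqn{1 - |X \cap Y| / |X \cup Y|}
#' between disease gene sets, clusters it hierarchically (complete linkage by
#' default), cuts the dendrogram at \code{cut_height}, and unions gene sets
#' within each resulting cluster. Merged disease ids are the original ids
#' sorted and joined with \code{"+"}.
#'
#' @param table Filtered gene-disease data.frame.
#' @param cut_height Raw dendrogram height at which to cut.
#' @param linkage \code{hclust} method; complete linkage merges conservatively.
#' @return A \code{\link{disease_module_set}} mapping (merged) disease ids to
#'   gene ids.
#' @export
merge_similar_diseases <- function(table, cut_height = 6, linkage = "complete") {
  sets <- split(table$gene, table$disease)
  ids <- names(sets)
  n <- length(sets)
  if (n < 2) stop("at least two diseases are required")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d[i, j] <- d[j, i] <- jaccard_distance(sets[[i]], sets[[j]])
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  cl <- stats::cutree(hc, h = cut_height)
  merged <- lapply(split(ids, cl), function(group) {
    sort(unique(unlist(sets[group], use.names = FALSE)))
  })
  names(merged) <- vapply(split(ids, cl),
                          function(group) paste(sort(group), collapse = "+"), "")
  disease_module_set(merged)
}

#' Pipeline configuration defaults
#'
#' @param alpha Significance level for all hypothesis tests.
#' @param n_null_samples Random samples per null distribution.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A named list of settings.
#' @export
pipeline_config <- function(alpha = 0.05, n_null_samples = 1000, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  list(alpha = alpha, n_null_samples = as.integer(n_null_samples),
       seed = as.integer(seed))
}
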